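mk_event <- function(id = "e1") {
  tibble::tibble(
    event_id = id, id_a = paste0(id, "_t1"), id_b = paste0(id, "_t2"),
    event_type = "UNTYPED",
    start_a = 1L, end_a = 50L, start_b = 1L, end_b = 0L
  )
}

test_that("PSI is the inclusion fraction with NA at zero coverage", {
  ev <- mk_event()
  ab <- tibble::tibble(transcript_id = c("e1_t1", "e1_t2"), abundance = c(3, 1))
  expect_equal(compute_psi(ev, ab)$psi, 0.75)
  ab$abundance <- c(0, 0)
  expect_true(is.na(compute_psi(ev, ab)$psi))
  ab$abundance <- c(5, 0)
  expect_equal(compute_psi(ev, ab)$psi, 1)
  expect_error(compute_psi(ev, ab[1, ]), "lacks transcript")
})

test_that("swapping the inclusion side complements PSI", {
  ev <- mk_event()
  flipped <- ev
  flipped$start_a <- 1L; flipped$end_a <- 0L
  flipped$start_b <- 1L; flipped$end_b <- 50L # now t2 is the inclusion side
  ab <- tibble::tibble(transcript_id = c("e1_t1", "e1_t2"), abundance = c(3, 1))
  expect_equal(compute_psi(ev, ab)$psi + compute_psi(flipped, ab)$psi, 1)
})

test_that("the exact permutation p-value matches hand enumeration", {
  psi <- tibble::tibble(
    event_id = "e1",
    condition = rep(c("A", "B"), each = 3),
    replicate = rep(as.character(1:3), 2),
    psi = c(0.1, 0.1, 0.1, 0.9, 0.9, 0.9)
  )
  # plain convention: 2 of the C(6,3)=20 label arrangements reach |delta|>=0.8
  plain <- diff_splice(psi, "A", "B", midp = FALSE)
  expect_equal(plain$delta_psi, 0.8)
  expect_equal(plain$p_value, 2 / 20)
  # mid-p: the two tying arrangements count half
  mid <- diff_splice(psi, "A", "B", midp = TRUE)
  expect_equal(mid$p_value, 1 / 20)

  # identical PSI vectors: no evidence under either convention
  null_psi <- dplyr::mutate(psi, psi = 0.5)
  expect_equal(diff_splice(null_psi, "A", "B", midp = FALSE)$p_value, 1)
  expect_equal(diff_splice(null_psi, "A", "B", midp = FALSE)$delta_psi, 0)
})

test_that("results are invariant to replicate order and validate input", {
  ps <- gen_psi_dataset(n_events = 12, n_true = 3, seed = 50)
  psi <- compute_psi(ps$events, ps$abundances)
  d1 <- diff_splice(psi, "A", "B", seed = 1)
  d2 <- diff_splice(psi[sample(nrow(psi)), ], "A", "B", seed = 1)
  expect_equal(d1, d2)
  expect_error(diff_splice(psi, "A", "C"), "unknown condition")
  expect_true(all(d1$q_value >= d1$p_value - 1e-12, na.rm = TRUE))
})

test_that("events with missing PSI or too few replicates report NA", {
  psi <- tibble::tibble(
    event_id = rep(c("e1", "e2"), each = 4),
    condition = rep(rep(c("A", "B"), each = 2), 2),
    replicate = rep(as.character(1:2), 4),
    psi = c(0.2, 0.3, 0.8, 0.9, NA, 0.3, 0.8, 0.9)
  )
  d <- diff_splice(psi, "A", "B")
  expect_false(is.na(d$p_value[d$event_id == "e1"]))
  expect_true(is.na(d$p_value[d$event_id == "e2"]))
  one_rep <- psi[psi$replicate == "1" | psi$condition == "A", ]
  d2 <- diff_splice(one_rep[one_rep$event_id == "e1", ], "A", "B")
  expect_true(is.na(d2$p_value))
})

test_that("planted PSI differences are recovered on simulated abundances", {
  ps <- gen_psi_dataset(n_events = 60, n_true = 10, delta = 0.4, n_reps = 5,
                        seed = 51)
  psi <- compute_psi(ps$events, ps$abundances)
  # mean estimated PSI tracks the planted value
  est <- psi |>
    dplyr::filter(condition == "A") |>
    dplyr::group_by(event_id) |>
    dplyr::summarise(psi = mean(psi))
  joined <- dplyr::inner_join(est, ps$truth, by = "event_id")
  expect_lt(mean(abs(joined$psi - joined$psi_a)), 0.05)

  d <- diff_splice(psi, "A", "B", seed = 52)
  hit <- d$q_value < 0.05
  truth <- ps$truth$is_true[match(d$event_id, ps$truth$event_id)]
  expect_gte(sum(hit & truth), 8)
  expect_lte(sum(hit & !truth), 3)
})
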