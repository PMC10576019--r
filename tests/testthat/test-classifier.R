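# small separable clouds for preprocessing tests
cloud4 <- function(counts, seed = 1) {
  withr::with_seed(seed, {
    centers <- matrix(c(0, 0, 5, 0, 0, 5, 5, 5), ncol = 2, byrow = TRUE)
    X <- do.call(rbind, lapply(seq_along(counts), function(i) {
      matrix(rnorm(counts[i] * 2, centers[i, ], 0.8), ncol = 2, byrow = TRUE)
    }))
    X <- cbind(X, constant = 1) # a constant feature: importance zero
    colnames(X) <- c("f1", "f2", "constant")
    list(X = X, y = rep(c("ES", "AA", "AD", "IR"), counts))
  })
}

test_that("borderline oversampling balances class counts", {
  d <- cloud4(c(100, 100, 100, 25))
  bal <- borderline_smote(scale(d$X[, 1:2]), d$y, seed = 2)
  expect_equal(as.integer(table(bal$y)), rep(100L, 4))
  expect_equal(nrow(bal$X), 400L)
  # balanced input: identity
  d2 <- cloud4(c(50, 50, 50, 50))
  bal2 <- borderline_smote(d2$X[, 1:2], d2$y, seed = 2)
  expect_identical(bal2$X, d2$X[, 1:2])
})

test_that("preprocessing scales, drops constant features and balances", {
  d <- cloud4(c(80, 80, 80, 30))
  prep <- preprocess_fit(d$X, d$y, seed = 3)
  expect_false(3L %in% prep$selected) # constant feature never selected
  expect_equal(as.integer(table(prep$y)), rep(80L, 4))
  expect_error(preprocess_fit(d$X[c(1, 101, 181, 251), ],
                              d$y[c(1, 101, 181, 251)], seed = 3),
               "at least 2")
})

test_that("training is reproducible and accurate on separable events", {
  lab <- gen_labeled_dataset(n_per_class = 30, seed = 40)
  feats <- featurize(lab$events, lab$transcripts)
  grid <- tibble::as_tibble(default_hyperparams("animal"))
  m1 <- train_classifier(feats, lab$labels, grid = grid, seed = 5, n_folds = 5)
  expect_gte(m1$metrics$holdout_accuracy, 0.8)

  # end-dinucleotide flags of the alternative region drive the classes and
  # must survive feature selection
  expect_true(any(grepl("incl_as_end5_GT", m1$selected_names)))
  expect_true(any(grepl("incl_as_end3_AG", m1$selected_names)))

  m2 <- train_classifier(feats, lab$labels, grid = grid, seed = 5, n_folds = 5)
  expect_identical(m1$hash, m2$hash)
  p1 <- predict(m1, feats)
  p2 <- predict(m2, feats)
  expect_identical(p1, p2)
  probs <- as.matrix(p1[, paste0("prob_", c("ES", "AA", "AD", "IR"))])
  expect_true(all(abs(rowSums(probs) - 1) < 1e-6))

  # an IR-like event is called IR
  ir_idx <- which(lab$labels == "IR")[1]
  expect_equal(predict(m1, feats[ir_idx, ])$event_type, "IR")

  # broom-style accessors
  expect_equal(nrow(tidy(m1)), length(m1$selected))
  expect_equal(glance(m1)$n_selected, length(m1$selected))

  # serialization round trip preserves predictions
  path <- withr::local_tempfile(fileext = ".json")
  write_model(m1, path)
  m3 <- read_model(path)
  expect_equal(predict(m3, feats), p1)

  # guard rails
  expect_error(predict(m1, feats[, 1:100]), "dimension mismatch")
  expect_error(predict(m1, feats, motifs = c("AAAA")), "motif list")

  # classify_events fills types and probabilities for untyped events only
  ev <- classify_events(lab$events[1:8, ], lab$transcripts, m1)
  expect_true(all(ev$event_type %in% c("ES", "AA", "AD", "IR")))
  expect_true(all(ev$source == "classifier"))
  expect_true(all(abs(ev$prob_ES + ev$prob_AA + ev$prob_AD + ev$prob_IR - 1) < 1e-6))
})

test_that("duplicated feature rows are dropped before splitting", {
  lab <- gen_labeled_dataset(n_per_class = 8, seed = 41)
  feats <- featurize(lab$events, lab$transcripts)
  dup_feats <- dplyr::bind_rows(feats, feats[1, ])
  expect_warning(
    train_classifier(dup_feats, c(lab$labels, lab$labels[1]),
                     grid = tibble::as_tibble(default_hyperparams("plant")),
                     seed = 6, n_folds = 3),
    "duplicated"
  )
})
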