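AS_CLASSES <- c("ES", "AA", "AD", "IR")

#' Default hyperparameter search grid
#'
#' The Cartesian grid searched by [train_classifier()]; the shipped per-kingdom
#' default parameter profiles (see [default_hyperparams()]) both lie inside
#' it. Any tibble/data.frame with these five columns can be supplied instead.
#'
#' @return Tibble of hyperparameter combinations.
#' @export
default_grid <- function() {
  tidyr::expand_grid(
    colsample_bytree = c(0.5, 0.6, 0.7, 0.8),
    learning_rate = c(0.05, 0.1, 0.2),
    max_depth = c(6L, 7L, 8L, 9L),
    min_child_weight = c(1L, 2L, 4L),
    subsample = c(0.6, 0.7, 0.8)
  )
}

#' Shipped default hyperparameter profiles
#'
#' Grid-search optima for the two published model profiles: `"animal"`
#' (trained on human events) and `"plant"` (trained on Arabidopsis events).
#'
#' @param profile `"animal"` or `"plant"`.
#' @return Named list of XGBoost hyperparameters.
#' @export
default_hyperparams <- function(profile = c("animal", "plant")) {
  profile <- match.arg(profile)
  if (profile == "animal") {
    list(colsample_bytree = 0.6, learning_rate = 0.2, max_depth = 8L,
         min_child_weight = 4L, subsample = 0.8)
  } else {
    list(colsample_bytree = 0.5, learning_rate = 0.2, max_depth = 9L,
         min_child_weight = 4L, subsample = 0.7)
  }
}

# Stratified fold assignment: within each class, replicates are dealt round-
# robin over shuffled order. Deterministic given the RNG state.
stratified_folds <- function(y, n_folds) {
  folds <- integer(length(y))
  for (cls in unique(y)) {
    idx <- which(y == cls)
    idx <- sample(idx)
    folds[idx] <- rep_len(seq_len(n_folds), length(idx))
  }
  folds
}

#' Borderline oversampling of minority classes
#'
#' Borderline-SMOTE (variant 1): for each minority class, samples whose
#' m-nearest-neighborhood contains more than m/2 but fewer than m
#' majority-class samples form the DANGER set; synthetic samples are drawn on
#' segments from DANGER points toward their k nearest same-class neighbors
#' (`x + u * (x_nn - x)`, `u ~ U(0,1)`) until every class reaches the majority
#' count. When a class has no DANGER points (the classes are separable), base
#' points are drawn from the whole class instead so that balancing still
#' happens.
#'
#' @param X Numeric matrix (samples in rows).
#' @param y Class labels.
#' @param m Neighborhood size for the danger test (default 10).
#' @param k Number of same-class neighbors for interpolation (default 5).
#' @param seed Seed.
#' @return List with balanced `X` and `y`.
#' @export
borderline_smote <- function(X, y, m = 10L, k = 5L, seed = 1L) {
  withr::with_seed(seed, {
    counts <- table(y)
    n_major <- max(counts)
    if (min(counts) < 2L) {
      rlang::abort("cannot oversample a class with fewer than 2 samples")
    }
    if (all(counts == n_major)) return(list(X = X, y = y))
    D <- as.matrix(stats::dist(X))
    diag(D) <- Inf
    X_new <- list(); y_new <- character(0)
    for (cls in names(counts)[counts < n_major]) {
      cls_idx <- which(y == cls)
      m_use <- min(m, nrow(X) - 1L)
      maj_frac <- vapply(cls_idx, function(i) {
        nn <- order(D[i, ])[seq_len(m_use)]
        sum(y[nn] != cls)
      }, numeric(1))
      danger <- cls_idx[maj_frac > m_use / 2 & maj_frac < m_use]
      base <- if (length(danger) > 0L) danger else cls_idx
      need <- n_major - length(cls_idx)
      k_use <- min(k, length(cls_idx) - 1L)
      picks <- sample(base, need, replace = TRUE)
      synth <- lapply(picks, function(i) {
        nn_cls <- cls_idx[cls_idx != i]
        nn <- nn_cls[order(D[i, nn_cls])][seq_len(k_use)]
        j <- nn[sample.int(k_use, 1L)]
        u <- stats::runif(1)
        X[i, ] + u * (X[j, ] - X[i, ])
      })
      X_new <- c(X_new, synth)
      y_new <- c(y_new, rep(cls, need))
    }
    list(
      X = rbind(X, do.call(rbind, X_new)),
      y = c(y, y_new)
    )
  })
}

#' Fit the preprocessing pipeline: scaling, selection, balancing
#'
#' Standardizes each feature (zero mean, unit variance; constant features are
#' left centered), ranks features with an extremely-randomized-trees
#' importance and keeps those above the mean importance, then balances class
#' counts on the selected scaled features with [borderline_smote()].
#'
#' @param X Numeric matrix or feature tibble (an `event_id` column is
#'   dropped).
#' @param y Class labels (one of `ES`, `AA`, `AD`, `IR`).
#' @param seed Seed.
#' @return List with `center`, `scale`, `selected` (column indices),
#'   `feature_names`, and the balanced `X`, `y`.
#' @export
preprocess_fit <- function(X, y, seed = 1L) {
  X <- as_feature_matrix(X)
  if (any(table(y) < 2L)) {
    rlang::abort("every class needs at least 2 samples")
  }
  center <- colMeans(X)
  scale_ <- apply(X, 2, stats::sd)
  scale_[scale_ == 0 | is.na(scale_)] <- 1
  Xs <- sweep(sweep(X, 2, center), 2, scale_, "/")
  rf <- ranger::ranger(
    x = Xs, y = factor(y, AS_CLASSES),
    splitrule = "extratrees", num.random.splits = 1L,
    importance = "impurity", num.trees = 200L,
    seed = seed, num.threads = 1L
  )
  imp <- rf$variable.importance
  selected <- which(imp > mean(imp))
  bal <- borderline_smote(Xs[, selected, drop = FALSE], y, seed = seed)
  list(
    center = center, scale = scale_,
    selected = unname(selected),
    feature_names = colnames(X),
    selected_names = colnames(X)[selected],
    X = bal$X, y = bal$y
  )
}

as_feature_matrix <- function(X) {
  if (is.data.frame(X)) {
    X <- X[, setdiff(colnames(X), "event_id"), drop = FALSE]
    X <- as.matrix(X)
  }
  storage.mode(X) <- "double"
  X
}

xgb_fit <- function(X, y, params, nrounds, seed) {
  y_num <- as.integer(factor(y, AS_CLASSES)) - 1L
  dtrain <- xgboost::xgb.DMatrix(X, label = y_num)
  withr::with_seed(seed, {
    xgboost::xgb.train(
      params = list(
        objective = "multi:softprob",
        num_class = length(AS_CLASSES),
        eval_metric = "mlogloss",
        eta = params$learning_rate,
        max_depth = params$max_depth,
        min_child_weight = params$min_child_weight,
        subsample = params$subsample,
        colsample_bytree = params$colsample_bytree,
        nthread = 1L
      ),
      data = dtrain, nrounds = nrounds, verbose = 0
    )
  })
}

xgb_prob <- function(booster, X) {
  p <- stats::predict(booster, xgboost::xgb.DMatrix(X))
  if (!is.matrix(p)) {
    p <- matrix(p, ncol = length(AS_CLASSES), byrow = TRUE)
  }
  dimnames(p) <- list(NULL, AS_CLASSES)
  p
}

#' Train the four-class AS event classifier
#'
#' Deduplicates identical feature rows, splits the data stratified 7:3,
#' fits the preprocessing pipeline on the training portion, selects
#' hyperparameters by 10-fold cross-validated accuracy over `grid`, refits on
#' the full (balanced) training portion with the best combination and records
#' the held-out accuracy. Fully reproducible given `seed`.
#'
#' @param features Feature tibble from [featurize()] (or a numeric matrix).
#' @param labels Class labels in `ES`, `AA`, `AD`, `IR`, parallel to the rows.
#' @param grid Hyperparameter grid (default [default_grid()]); an empty grid
#'   falls back to the shipped `"animal"` profile.
#' @param seed Seed.
#' @param nrounds Boosting rounds (default 60).
#' @param n_folds Inner CV folds (default 10).
#' @param motifs Motif list whose hash is stored with the model.
#' @return An object of class `as_model`.
#' @export
train_classifier <- function(features, labels, grid = default_grid(),
                             seed = 1L, nrounds = 60L, n_folds = 10L,
                             motifs = default_motifs()) {
  X <- as_feature_matrix(features)
  y <- as.character(labels)
  stopifnot(nrow(X) == length(y), all(y %in% AS_CLASSES))

  # drop duplicated feature rows (identical events must not straddle splits)
  dup <- duplicated(X)
  if (any(dup)) {
    rlang::warn(sprintf("dropping %d duplicated feature row(s)", sum(dup)))
    X <- X[!dup, , drop = FALSE]
    y <- y[!dup]
  }
  if (nrow(grid) == 0L) {
    grid <- tibble::as_tibble(default_hyperparams("animal"))
  }

  split <- withr::with_seed(seed, stratified_folds(y, 10L))
  test_idx <- split %in% c(1L, 2L, 3L) # stratified 7:3
  X_test <- X[test_idx, , drop = FALSE]
  y_test <- y[test_idx]
  X_train <- X[!test_idx, , drop = FALSE]
  y_train <- y[!test_idx]

  prep <- preprocess_fit(X_train, y_train, seed = seed)
  Xb <- prep$X
  yb <- prep$y

  folds <- withr::with_seed(seed + 1L, stratified_folds(yb, n_folds))
  cv_acc <- vapply(seq_len(nrow(grid)), function(g) {
    params <- as.list(grid[g, ])
    accs <- vapply(seq_len(n_folds), function(f) {
      in_fold <- folds == f
      fit <- xgb_fit(Xb[!in_fold, , drop = FALSE], yb[!in_fold],
                     params, nrounds, seed + g)
      pred <- AS_CLASSES[max.col(xgb_prob(fit, Xb[in_fold, , drop = FALSE]))]
      mean(pred == yb[in_fold])
    }, numeric(1))
    mean(accs)
  }, numeric(1))
  best <- which.max(cv_acc)
  best_params <- as.list(grid[best, ])

  booster <- xgb_fit(Xb, yb, best_params, nrounds, seed)
  raw <- xgboost::xgb.save.raw(booster)

  scale_select <- function(M) {
    M <- sweep(sweep(M, 2, prep$center), 2, prep$scale, "/")
    M[, prep$selected, drop = FALSE]
  }
  holdout_pred <- AS_CLASSES[max.col(xgb_prob(booster, scale_select(X_test)))]

  model <- structure(
    list(
      center = prep$center, scale = prep$scale,
      selected = prep$selected, selected_names = prep$selected_names,
      feature_names = prep$feature_names,
      booster_raw = raw,
      hyperparams = best_params,
      nrounds = nrounds,
      classes = AS_CLASSES,
      motif_hash = motif_hash(motifs),
      metrics = list(
        holdout_accuracy = mean(holdout_pred == y_test),
        cv_accuracy = max(cv_acc),
        cv_table = dplyr::mutate(grid, cv_accuracy = cv_acc),
        n_train = length(y_train), n_test = length(y_test),
        n_selected = length(prep$selected)
      ),
      seed = seed
    ),
    class = "as_model"
  )
  model$hash <- rlang::hash(list(raw, prep$center, prep$scale, prep$selected))
  model
}

#' @export
print.as_model <- function(x, ...) {
  cat(sprintf(
    "<as_model> 4-class AS event classifier\n  %d/%d features selected, held-out accuracy %.3f (CV %.3f)\n",
    length(x$selected), length(x$feature_names),
    x$metrics$holdout_accuracy, x$metrics$cv_accuracy
  ))
  invisible(x)
}

#' Predict AS event types
#'
#' @param object An `as_model`.
#' @param features Feature tibble from [featurize()] built with the same
#'   motif list as training (or a numeric matrix with matching columns).
#' @param motifs Motif list used to build `features`; checked against the
#'   model's stored hash unless `force = TRUE`.
#' @param force Skip the motif-hash check.
#' @param ... Unused.
#' @return Tibble with `event_id` (when available), predicted `event_type`
#'   and the four class probabilities (rows sum to 1).
#' @export
predict.as_model <- function(object, features, motifs = NULL, force = FALSE, ...) {
  event_id <- if (is.data.frame(features) && "event_id" %in% colnames(features)) {
    features$event_id
  } else {
    NULL
  }
  X <- as_feature_matrix(features)
  if (!is.null(colnames(X)) && all(object$feature_names %in% colnames(X))) {
    X <- X[, object$feature_names, drop = FALSE]
  }
  if (ncol(X) != length(object$feature_names)) {
    rlang::abort(sprintf("feature dimension mismatch: model expects %d, got %d",
                         length(object$feature_names), ncol(X)))
  }
  if (!force && !is.null(motifs) && motif_hash(motifs) != object$motif_hash) {
    rlang::abort("motif list does not match the one the model was trained with (use force = TRUE to override)")
  }
  Xs <- sweep(sweep(X, 2, object$center), 2, object$scale, "/")
  Xs <- Xs[, object$selected, drop = FALSE]
  booster <- xgboost::xgb.load.raw(object$booster_raw)
  probs <- xgb_prob(booster, Xs)
  out <- tibble::as_tibble(probs) |>
    rlang::set_names(paste0("prob_", AS_CLASSES)) |>
    dplyr::mutate(event_type = AS_CLASSES[max.col(probs)], .before = 1)
  if (!is.null(event_id)) {
    out <- dplyr::mutate(out, event_id = event_id, .before = 1)
  }
  out
}

#' Type untyped events with a trained classifier
#'
#' Featurizes the `UNTYPED` events of an identification run and fills in
#' their predicted type and class probabilities; graph-typed events (AF, AL,
#' MX) pass through unchanged.
#'
#' @param events Events tibble from [identify_events()].
#' @param transcripts Transcript tibble.
#' @param model An `as_model`.
#' @param motifs Motif list (must match the model's).
#' @return The events tibble with types and probabilities filled in.
#' @export
classify_events <- function(events, transcripts, model,
                            motifs = default_motifs()) {
  untyped <- events$event_type == "UNTYPED"
  if (!any(untyped)) return(events)
  feats <- featurize(events[untyped, ], transcripts, motifs)
  pred <- stats::predict(model, feats, motifs = motifs)
  events$event_type[untyped] <- pred$event_type
  events$prob_ES[untyped] <- pred$prob_ES
  events$prob_AA[untyped] <- pred$prob_AA
  events$prob_AD[untyped] <- pred$prob_AD
  events$prob_IR[untyped] <- pred$prob_IR
  events$source[untyped] <- "classifier"
  events
}

#' Serialize a trained model to a JSON container
#'
#' @param model An `as_model`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_model <- function(model, path) {
  obj <- list(
    format = "dbgsplice_model", version = 1L,
    classes = model$classes,
    center = model$center, scale = model$scale,
    selected = model$selected, selected_names = model$selected_names,
    feature_names = model$feature_names,
    hyperparams = model$hyperparams,
    nrounds = model$nrounds,
    motif_hash = model$motif_hash,
    metrics = model$metrics[c("holdout_accuracy", "cv_accuracy",
                              "n_train", "n_test", "n_selected")],
    seed = model$seed,
    hash = model$hash,
    booster_raw = jsonlite::base64_enc(model$booster_raw)
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = I(17))
  invisible(path)
}

#' Read a model written by [write_model()]
#'
#' @param path Path to the JSON model file.
#' @return An `as_model`.
#' @export
read_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$format, "dbgsplice_model")) {
    rlang::abort("not a dbgsplice model file")
  }
  structure(
    list(
      center = obj$center, scale = obj$scale,
      selected = as.integer(obj$selected),
      selected_names = obj$selected_names,
      feature_names = obj$feature_names,
      booster_raw = jsonlite::base64_dec(obj$booster_raw),
      hyperparams = as.list(obj$hyperparams),
      nrounds = obj$nrounds,
      classes = obj$classes,
      motif_hash = obj$motif_hash,
      metrics = as.list(obj$metrics),
      seed = obj$seed,
      hash = obj$hash
    ),
    class = "as_model"
  )
}
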