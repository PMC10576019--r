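#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a trained AS classifier
#'
#' One row per selected feature with its standardization parameters, ordered
#' as stored in the model.
#'
#' @param x An `as_model`.
#' @param ... Unused.
#' @return Tibble with columns `feature`, `index`, `center`, `scale`.
#' @export
tidy.as_model <- function(x, ...) {
  tibble::tibble(
    feature = x$selected_names,
    index = x$selected,
    center = unname(x$center[x$selected]),
    scale = unname(x$scale[x$selected])
  )
}

#' One-row model summary
#'
#' @param x An `as_model`.
#' @param ... Unused.
#' @return Tibble with accuracy metrics, dimensions and the selected
#'   hyperparameters.
#' @export
glance.as_model <- function(x, ...) {
  dplyr::bind_cols(
    tibble::tibble(
      holdout_accuracy = x$metrics$holdout_accuracy,
      cv_accuracy = x$metrics$cv_accuracy,
      n_train = x$metrics$n_train,
      n_test = x$metrics$n_test,
      n_features = length(x$feature_names),
      n_selected = length(x$selected)
    ),
    tibble::as_tibble(x$hyperparams)
  )
}
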