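# broom-style tidiers for the fitted objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a posterior sample
#'
#' One row per accepted draw, in long format.
#'
#' @param x a `posterior_sample`.
#' @param ... unused.
#' @return A tibble with columns `draw`, `parameter`, `value`, `distance`.
#' @export
#' @exportS3Method generics::tidy
tidy.posterior_sample <- function(x, ...) {
  acc <- tibble::as_tibble(x$accepted)
  acc$draw <- seq_len(nrow(acc))
  acc$distance <- x$distances
  tidyr::pivot_longer(acc, cols = -c("draw", "distance"),
                      names_to = "parameter", values_to = "value") |>
    dplyr::relocate("draw", "parameter", "value", "distance")
}

#' @rdname tidy.posterior_sample
#' @export
#' @exportS3Method generics::glance
glance.posterior_sample <- function(x, ...) {
  tibble::tibble(n_accepted = nrow(x$accepted), n_sims = x$n_sims,
                 tolerance = x$tolerance,
                 min_distance = min(x$distances),
                 max_distance = max(x$distances))
}

#' Tidy a model-choice result
#'
#' @param x a `model_choice_result`.
#' @param ... unused.
#' @return A tibble with one row per model.
#' @export
#' @exportS3Method generics::tidy
tidy.model_choice_result <- function(x, ...) {
  tibble::tibble(model = c("transition", "size_change"),
                 n_accepted = as.integer(x$accepted),
                 posterior_prob = c(x$p_model1, 1 - x$p_model1))
}

#' @rdname tidy.model_choice_result
#' @export
#' @exportS3Method generics::glance
glance.model_choice_result <- function(x, ...) {
  tibble::tibble(p_model1 = x$p_model1, bayes_factor = x$bayes_factor,
                 method = x$method, capped = x$capped, detected = x$detected,
                 threshold = x$threshold, tolerance = x$tolerance)
}

#' Tidy a reference table
#'
#' @param x a `reference_table`.
#' @param ... unused.
#' @return A tibble binding the parameter draws to their summary statistics.
#' @export
#' @exportS3Method generics::tidy
tidy.reference_table <- function(x, ...) {
  dplyr::bind_cols(tibble::as_tibble(x$params),
                   tibble::as_tibble(x$stats))
}

#' @rdname tidy.reference_table
#' @export
#' @exportS3Method generics::glance
glance.reference_table <- function(x, ...) {
  tibble::tibble(model_id = x$model_id, n_sims = nrow(x$stats),
                 n_stats = ncol(x$stats), n_retained = sum(x$keep),
                 spec = x$spec,
                 n_pls = if (is.null(x$n_comp)) NA_integer_ else x$n_comp)
}
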