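# broom-style tidiers for fitted objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @describeIn fit_expansion_threshold One row per mixture component
#'   (mean, sd, weight on the log10 percent scale).
#' @param x An `expansion_model`.
#' @param ... Unused.
#' @export
tidy.expansion_model <- function(x, ...) {
  tibble(component = seq_along(x$means),
         mean = x$means, sd = x$sds, weight = x$weights) %>%
    arrange(.data$mean)
}

#' @describeIn fit_expansion_threshold One-row model summary (cutoff,
#'   expanded fraction, BIC, fallback flag).
#' @export
glance.expansion_model <- function(x, ...) {
  tibble(cutoff = x$cutoff, frac_expanded = x$frac_expanded,
         n = x$n, n_components = x$n_components, bic = x$bic,
         fallback = x$fallback)
}

#' @describeIn evaluate_degree_classifier Returns the per-cutoff metric
#'   table as a plain tibble.
#' @param x A `degree_classifier_eval`.
#' @param ... Unused.
#' @export
tidy.degree_classifier_eval <- function(x, ...) {
  out <- x
  class(out) <- setdiff(class(out), "degree_classifier_eval")
  out
}

#' @describeIn build_clone_networks One row per clone: variant count, MST
#'   edge count, total MST weight, max degree.
#' @param x A `clone_network_set`.
#' @param ... Unused.
#' @export
tidy.clone_network_set <- function(x, ...) {
  v <- x$variants %>%
    group_by(.data$participant_id, .data$clone_id) %>%
    summarise(n_variants = dplyr::first(.data$n_variants),
              max_degree = max(.data$degree), .groups = "drop")
  e <- x$edges %>%
    group_by(.data$participant_id, .data$clone_id) %>%
    summarise(n_edges = n(), mst_weight = sum(.data$weight),
              .groups = "drop")
  left_join(v, e, by = c("participant_id", "clone_id"))
}
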