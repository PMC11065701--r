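# ggplot2 visualisations for the main result types.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Heat map of pairwise sharing statistics
#'
#' @param sharing Long tibble from [sharing_table()].
#' @return A ggplot object (tile heat map, symmetrised).
#' @export
plot_sharing_matrix <- function(sharing) {
  full <- bind_rows(
    sharing,
    rename(sharing, sample_a = "sample_b", sample_b = "sample_a")
  )
  ggplot2::ggplot(full, ggplot2::aes(.data$sample_a, .data$sample_b,
                                     fill = .data$median)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(name = sharing$statistic[1]) +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}

#' @describeIn evaluate_degree_classifier Profile plot of sensitivity,
#'   specificity and accuracy across degree cutoffs.
#' @param object A `degree_classifier_eval`.
#' @export
autoplot.degree_classifier_eval <- function(object, ...) {
  long <- object %>%
    select("cutoff", "sensitivity", "specificity", "accuracy") %>%
    tidyr::pivot_longer(-"cutoff", names_to = "metric")
  ggplot2::ggplot(long, ggplot2::aes(factor(.data$cutoff), .data$value,
                                     group = .data$metric,
                                     colour = .data$metric)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = "degree cutoff (predict positive when degree > cutoff)",
                  y = NULL, colour = NULL) +
    ggplot2::theme_minimal()
}

#' @describeIn fit_expansion_threshold Density of the fitted mixture with
#'   the expansion cutoff.
#' @param object An `expansion_model`.
#' @export
autoplot.expansion_model <- function(object, ...) {
  grid <- seq(min(object$means) - 3 * max(object$sds),
              max(object$means) + 3 * max(object$sds), length.out = 400)
  comp <- purrr::map_dfr(seq_along(object$means), function(k)
    tibble(component = factor(k), x = grid,
           density = object$weights[k] *
             dnorm(grid, object$means[k], object$sds[k])))
  ggplot2::ggplot(comp, ggplot2::aes(.data$x, .data$density,
                                     colour = .data$component)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = object$cutoff, linetype = 2) +
    ggplot2::labs(x = "log10 clone size (% of sample UMIs)", y = "density") +
    ggplot2::theme_minimal()
}

#' Plot one clone's lineage network
#'
#' MST layout with vertex size proportional to summed UMI share and colour
#' by number of sites; edge width inversely related to Hamming distance.
#'
#' @param networks A `clone_network_set`.
#' @param clone_id Clone to plot.
#' @param seed Layout seed.
#' @return A ggplot object.
#' @export
plot_clone_network <- function(networks, clone_id, seed = 1L) {
  g <- export_clone_network(networks, clone_id)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  xy <- igraph::layout_with_fr(g)
  v <- networks$variants %>% filter(.data$clone_id == !!clone_id) %>%
    mutate(x = xy[, 1], y = xy[, 2])
  e <- networks$edges %>% filter(.data$clone_id == !!clone_id) %>%
    mutate(x = xy[.data$from, 1], y = xy[.data$from, 2],
           xend = xy[.data$to, 1], yend = xy[.data$to, 2])
  ggplot2::ggplot() +
    ggplot2::geom_segment(data = e,
                          ggplot2::aes(x = .data$x, y = .data$y,
                                       xend = .data$xend,
                                       yend = .data$yend),
                          colour = "grey60") +
    ggplot2::geom_point(data = v,
                        ggplot2::aes(.data$x, .data$y,
                                     size = .data$frequency,
                                     colour = factor(.data$n_sites))) +
    ggplot2::labs(colour = "sites", size = "UMI share",
                  title = clone_id) +
    ggplot2::theme_void()
}
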