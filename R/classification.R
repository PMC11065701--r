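# Clone topology (stem/clade/private), expansion threshold fitting and
# clone classes A-D.

#' Per-clone per-sample UMI proportions
#'
#' The clone proportion in a sample is the clone's UMI count divided by the
#' sample's total UMI count, so proportions sum to 1 over the clones present
#' in each sample.
#'
#' @param records Repertoire tibble with `clone_id` assigned.
#' @return Tibble: `participant_id`, `sample_id`, `clone_id`, `umi`,
#'   `proportion`.
#' @export
clone_proportions <- function(records) {
  if (nrow(records) == 0L) abort("no records supplied")
  totals <- records %>%
    group_by(.data$sample_id) %>%
    summarise(sample_umi = sum(.data$umi_count), .groups = "drop")
  if (any(totals$sample_umi <= 0)) abort("sample with zero UMIs")
  records %>%
    group_by(.data$participant_id, .data$sample_id, .data$clone_id) %>%
    summarise(umi = sum(.data$umi_count), .groups = "drop") %>%
    left_join(totals, by = "sample_id") %>%
    mutate(proportion = .data$umi / .data$sample_umi) %>%
    select(-"sample_umi")
}

#' Classify clone topology as stem, clade or private
#'
#' Within each participant, a clone observed in all samples is a stem clone,
#' in more than one but not all a clade clone, and in exactly one a private
#' clone. Stem and clade clones are flagged immunosurveilling (present in
#' more than one sample of the participant). Participants with a single
#' sample cannot support the classification; their clones are marked
#' `unclassifiable`.
#'
#' @param records Repertoire tibble with `clone_id`.
#' @return Tibble: `participant_id`, `clone_id`, `n_samples_observed`,
#'   `n_participant_samples`, `topology`, `immunosurveilling`.
#' @export
classify_topology <- function(records) {
  n_samp <- records %>%
    group_by(.data$participant_id) %>%
    summarise(n_participant_samples = n_distinct(.data$sample_id),
              .groups = "drop")
  records %>%
    group_by(.data$participant_id, .data$clone_id) %>%
    summarise(n_samples_observed = n_distinct(.data$sample_id),
              .groups = "drop") %>%
    left_join(n_samp, by = "participant_id") %>%
    mutate(
      topology = dplyr::case_when(
        .data$n_participant_samples < 2L ~ "unclassifiable",
        .data$n_samples_observed == .data$n_participant_samples ~ "stem",
        .data$n_samples_observed > 1L ~ "clade",
        TRUE ~ "private"
      ),
      immunosurveilling = .data$topology %in% c("stem", "clade")
    )
}

# Posterior-equality crossing between the top-mean Gaussian component and
# the remaining mixture, located on a fine grid between the two largest
# component means.
mixture_crossing <- function(means, sds, weights) {
  ord <- order(means)
  top <- ord[length(ord)]
  rest <- setdiff(seq_along(means), top)
  lo <- max(means[rest]); hi <- means[top]
  grid <- seq(lo, hi, length.out = 4096L)
  dens_top <- weights[top] * dnorm(grid, means[top], sds[top])
  dens_rest <- rowSums(vapply(rest, function(k)
    weights[k] * dnorm(grid, means[k], sds[k]), numeric(length(grid))))
  above <- dens_top >= dens_rest
  if (!any(above)) return(hi)
  grid[which(above)[1L]]
}

#' Fit the clonal-expansion size threshold
#'
#' Fits a Gaussian mixture model to pooled log10 clone-size percentages
#' (per clone per sample) and places the expanded/unexpanded cutoff at the
#' posterior-equality crossing between the largest-mean component and the
#' rest of the mixture. The cutoff is raised when necessary so that strictly
#' fewer than 10% of the constraint values (one per clone) fall above it. A
#' degenerate fit (top two component means closer than `tol` on the log10
#' scale, or BIC preferring a single component) falls back to that
#' percentile cutoff with a warning.
#'
#' @param log10_pct Numeric vector of log10 clone-size percentages, pooled
#'   across samples (>= 100 observations).
#' @param n_components Number of mixture components (default 2); set
#'   `select_bic = TRUE` to let BIC choose up to `n_components`.
#' @param select_bic Use BIC model selection over `1:n_components`.
#' @param tol Minimal component-mean separation treated as non-degenerate.
#' @param constraint_values Values on which the "<10% expanded" check is
#'   evaluated; pass one value per clone (e.g. the per-clone maximum over
#'   samples) so the constraint counts clones rather than clone-sample
#'   observations. Defaults to `log10_pct`.
#' @return An object of class `expansion_model`: component means, sds and
#'   weights, the cutoff (log10 percent scale), and fit metadata.
#' @export
fit_expansion_threshold <- function(log10_pct, n_components = 2,
                                    select_bic = FALSE, tol = 0.1,
                                    constraint_values = log10_pct) {
  x <- log10_pct[is.finite(log10_pct)]
  if (length(x) < 100L) abort("need >= 100 clone-size observations")
  G <- if (select_bic) seq_len(n_components) else n_components
  fit <- mclust::Mclust(x, G = G, modelNames = "V", verbose = FALSE)
  fit1 <- mclust::Mclust(x, G = 1L, modelNames = "V", verbose = FALSE)
  means <- as.numeric(fit$parameters$mean)
  sds <- sqrt(as.numeric(fit$parameters$variance$sigmasq))
  if (length(sds) == 1L) sds <- rep(sds, length(means))
  weights <- as.numeric(fit$parameters$pro)
  cv <- constraint_values[is.finite(constraint_values)]
  # smallest cutoff leaving strictly fewer than 10% of the constraint
  # values above it
  percentile_cutoff <- function(cv) {
    s <- sort(unique(cv))
    s[which(vapply(s, function(q) mean(cv > q) < 0.10, logical(1)))[1L]]
  }
  fallback <- FALSE
  # degeneracy: no BIC evidence for more than one component, or the top
  # two component means (the expanded/unexpanded boundary) collapse.
  # Lower components may sit arbitrarily close without harm.
  top_gap <- if (length(means) < 2L) 0 else
    diff(sort(means, decreasing = TRUE)[2:1])
  if (length(means) < 2L || top_gap < tol || fit1$bic >= fit$bic) {
    warn("degenerate mixture; falling back to percentile cutoff")
    cutoff <- percentile_cutoff(cv)
    fallback <- TRUE
  } else {
    cutoff <- mixture_crossing(means, sds, weights)
    if (mean(cv > cutoff) >= 0.10) {
      cutoff <- percentile_cutoff(cv)
    }
  }
  structure(
    list(means = means, sds = sds, weights = weights,
         cutoff = cutoff, fallback = fallback, n = length(x),
         frac_expanded = mean(cv > cutoff), bic = fit$bic,
         n_components = length(means)),
    class = "expansion_model"
  )
}

#' @export
print.expansion_model <- function(x, ...) {
  cat("Clonal expansion model (", x$n_components, "-component GMM, n = ",
      x$n, ")\n", sep = "")
  cat("  cutoff: log10(% UMI) > ", signif(x$cutoff, 4),
      if (x$fallback) "  [percentile fallback]", "\n", sep = "")
  cat("  fraction expanded: ", signif(x$frac_expanded, 3), "\n", sep = "")
  invisible(x)
}

#' Assign clone classes A-D
#'
#' Combines topology with expansion: a clone is expanded when its clone-size
#' percentage exceeds the fitted cutoff in at least one sample (clones above
#' the cutoff in some sites and below in others count as expanded). Classes:
#' A = private expanded, B = shared expanded, C = private unexpanded,
#' D = shared unexpanded; unclassifiable topologies get `NA`.
#'
#' @param proportions Output of [clone_proportions()].
#' @param topology Output of [classify_topology()].
#' @param model An `expansion_model` from [fit_expansion_threshold()].
#' @return Clone-level tibble with `expanded`, `clone_class` and the
#'   topology columns.
#' @export
classify_clone_class <- function(proportions, topology, model) {
  expanded <- proportions %>%
    group_by(.data$participant_id, .data$clone_id) %>%
    summarise(max_log10_pct = log10(100 * max(.data$proportion)),
              .groups = "drop") %>%
    mutate(expanded = .data$max_log10_pct > model$cutoff)
  topology %>%
    left_join(expanded, by = c("participant_id", "clone_id")) %>%
    mutate(clone_class = dplyr::case_when(
      .data$topology == "unclassifiable" ~ NA_character_,
      .data$topology == "private" & .data$expanded ~ "A",
      .data$topology != "private" & .data$expanded ~ "B",
      .data$topology == "private" ~ "C",
      TRUE ~ "D"
    ))
}

#' Per-site mean proportions of immunosurveilling clones
#'
#' Retains clones present in more than one site with at least `min_vdjs`
#' unique VDJ sequences in at least one site; for each retained clone the
#' per-sample share of its unique VDJs is computed (summing to 1 across the
#' participant's samples), and shares are averaged per site.
#'
#' @param records Repertoire tibble with `clone_id`.
#' @param min_vdjs Minimum unique VDJs required in at least one site
#'   (default 4).
#' @return Tibble: `site`, `mean_proportion`, `n_clones`.
#' @export
surveilling_site_proportions <- function(records, min_vdjs = 4) {
  per_site <- records %>%
    group_by(.data$participant_id, .data$clone_id, .data$site) %>%
    summarise(n_vdj_site = n_distinct(.data$vdj_nt), .groups = "drop")
  keep <- per_site %>%
    group_by(.data$participant_id, .data$clone_id) %>%
    summarise(n_sites = n_distinct(.data$site),
              max_vdj = max(.data$n_vdj_site), .groups = "drop") %>%
    filter(.data$n_sites > 1L, .data$max_vdj >= min_vdjs)
  if (nrow(keep) == 0L) {
    warn("no clone passes the immunosurveilling-clone filter")
    return(tibble(site = character(), mean_proportion = numeric(),
                  n_clones = integer()))
  }
  records %>%
    dplyr::semi_join(keep, by = c("participant_id", "clone_id")) %>%
    group_by(.data$participant_id, .data$clone_id, .data$sample_id,
             .data$site) %>%
    summarise(n_vdj = n_distinct(.data$vdj_nt), .groups = "drop_last") %>%
    group_by(.data$participant_id, .data$clone_id) %>%
    mutate(proportion = .data$n_vdj / sum(.data$n_vdj)) %>%
    ungroup() %>%
    group_by(.data$site) %>%
    summarise(mean_proportion = mean(.data$proportion),
              n_clones = n_distinct(paste(.data$participant_id,
                                          .data$clone_id)),
              .groups = "drop")
}
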