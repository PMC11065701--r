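# Diversity indices under UMI subsampling; SHM categories, isotype usage
# and antigen-experience annotation.

#' Gini coefficient of clone sizes
#'
#' Mean-absolute-difference form `sum_ij |x_i - x_j| / (2 n^2 xbar)`;
#' 0 for perfectly even repertoires, approaching `(K - 1) / K` when one of
#' `K` clones holds everything. Invariant under uniform scaling.
#'
#' @param x Non-negative clone sizes.
#' @return Gini coefficient in `[0, 1]`.
#' @export
gini_index <- function(x) {
  if (length(x) == 0L || all(x == 0)) abort("clone sizes must be positive")
  n <- length(x)
  sum(abs(outer(x, x, "-"))) / (2 * n^2 * mean(x))
}

#' Shannon entropy of clone sizes (natural log)
#'
#' @param x Non-negative clone sizes; zeros are dropped.
#' @return Entropy in nats, at most `ln(K)` for `K` clones.
#' @param normalized Divide by `ln(K)` (evenness); default `FALSE`.
#' @export
shannon_index <- function(x, normalized = FALSE) {
  x <- x[x > 0]
  p <- x / sum(x)
  h <- -sum(p * log(p))
  if (normalized && length(x) > 1L) h <- h / log(length(x)) else h
}

# One subsample's indices over clone UMI counts.
diversity_once <- function(clone_umis, mean_clone_size_mode) {
  k <- length(clone_umis)
  total <- sum(clone_umis)
  mcs <- switch(mean_clone_size_mode,
                umi = mean(clone_umis),
                share = mean(clone_umis) / total)
  c(gini = gini_index(clone_umis),
    shannon = shannon_index(clone_umis),
    mean_clone_size = mcs,
    n_clones = k)
}

#' Depth-matched diversity of a sample
#'
#' Subsamples `depth` UMIs without replacement (UMI-weighted, i.e. each UMI
#' is a draw unit) `n_iter` times and averages the Gini coefficient, Shannon
#' entropy (natural log) and mean clone size computed on the subsampled
#' per-clone UMI counts. With `depth` equal to the sample total the indices
#' equal their closed-form values and the iteration loop is skipped.
#'
#' @param records Repertoire tibble for one sample with `clone_id`.
#' @param depth Number of UMIs to draw; typically 90% of the shallowest
#'   sample's UMI total across the compared samples.
#' @param n_iter Number of subsampling iterations (default 1000).
#' @param seed Integer seed (local stream).
#' @param mean_clone_size_mode `"umi"` (mean UMIs per observed clone) or
#'   `"share"` (the same divided by depth, i.e. inverse observed richness).
#' @return One-row tibble: `sample_id`, `gini`, `shannon`,
#'   `mean_clone_size`, `n_clones`, `depth`, `n_iter`.
#' @export
diversity <- function(records, depth, n_iter = 1000, seed = 1L,
                      mean_clone_size_mode = c("umi", "share")) {
  mean_clone_size_mode <- arg_match(mean_clone_size_mode)
  if (n_distinct(records$sample_id) != 1L) {
    abort("diversity() works on one sample at a time")
  }
  clone_umis <- records %>%
    group_by(.data$clone_id) %>%
    summarise(umi = sum(.data$umi_count), .groups = "drop")
  total <- sum(clone_umis$umi)
  if (depth > total) abort("depth exceeds the sample's UMI total")
  if (depth == total) {
    v <- diversity_once(clone_umis$umi, mean_clone_size_mode)
    n_iter <- 0L
  } else {
    units <- rep.int(seq_len(nrow(clone_umis)), clone_umis$umi)
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old))
    set.seed(seed)
    acc <- matrix(0, n_iter, 4L)
    for (it in seq_len(n_iter)) {
      drawn <- tabulate(units[sample.int(total, depth)],
                        nbins = nrow(clone_umis))
      acc[it, ] <- diversity_once(drawn[drawn > 0L], mean_clone_size_mode)
    }
    v <- colMeans(acc)
    names(v) <- c("gini", "shannon", "mean_clone_size", "n_clones")
  }
  tibble(sample_id = records$sample_id[1],
         gini = unname(v["gini"]), shannon = unname(v["shannon"]),
         mean_clone_size = unname(v["mean_clone_size"]),
         n_clones = unname(v["n_clones"]),
         depth = as.integer(depth), n_iter = as.integer(n_iter))
}

SHM_LEVELS <- c("no", "low", "high", "very_high")

#' Categorise somatic hypermutation load
#'
#' Fixed mode applies the standard category bounds: `no` 0-1 mutations,
#' `low` 2-10, `high` 11-33, `very_high` >33. Refit mode fits a 4-component
#' Gaussian mixture to `log(shm + 1)` and derives the three adjacent
#' posterior-crossing thresholds from the fitted components; with fewer than
#' 200 usable records it falls back to fixed with a warning. "Highly
#' mutated" means high or very high.
#'
#' @param shm_count Integer vector of per-record mutation counts.
#' @param mode `"fixed"` or `"refit"`.
#' @return List: `category` (factor aligned with input), `thresholds`
#'   (upper bounds of the first three categories, mutation-count scale) and
#'   `mode`.
#' @export
classify_shm <- function(shm_count, mode = c("fixed", "refit")) {
  mode <- arg_match(mode)
  thresholds <- c(no = 1, low = 10, high = 33)
  x <- shm_count[!is.na(shm_count)]
  if (mode == "refit") {
    if (length(x) < 200L) {
      warn("fewer than 200 records; falling back to fixed SHM thresholds")
      mode <- "fixed"
    } else {
      fit <- mclust::Mclust(log(x + 1), G = 4L, modelNames = "V",
                            verbose = FALSE)
      mu <- as.numeric(fit$parameters$mean)
      sg <- sqrt(as.numeric(fit$parameters$variance$sigmasq))
      if (length(sg) == 1L) sg <- rep(sg, 4L)
      w <- as.numeric(fit$parameters$pro)
      ord <- order(mu)
      cross <- vapply(seq_len(3L), function(k) {
        i <- ord[k]; j <- ord[k + 1L]
        grid <- seq(mu[i], mu[j], length.out = 2048L)
        di <- w[i] * dnorm(grid, mu[i], sg[i])
        dj <- w[j] * dnorm(grid, mu[j], sg[j])
        ix <- which(dj >= di)
        if (length(ix)) grid[ix[1L]] else mean(c(mu[i], mu[j]))
      }, numeric(1))
      thresholds <- exp(cross) - 1
      names(thresholds) <- c("no", "low", "high")
    }
  }
  category <- cut(shm_count,
                  breaks = c(-Inf, thresholds, Inf),
                  labels = SHM_LEVELS)
  list(category = category, thresholds = thresholds, mode = mode)
}

#' Isotype usage of a sample
#'
#' UMI proportions per isotype over records with a known isotype; the
#' unswitched fraction is the summed IGHD + IGHM proportion.
#'
#' @param records IGH repertoire tibble for one sample.
#' @return List: `usage` (tibble isotype/umi/proportion) and `unswitched`.
#' @export
isotype_usage <- function(records) {
  known <- records %>% filter(!is.na(.data$isotype))
  if (nrow(known) == 0L) {
    warn("all isotypes unknown")
    return(list(usage = tibble(isotype = character(), umi = integer(),
                               proportion = numeric()),
                unswitched = NA_real_))
  }
  usage <- known %>%
    group_by(.data$isotype) %>%
    summarise(umi = sum(.data$umi_count), .groups = "drop") %>%
    mutate(proportion = .data$umi / sum(.data$umi)) %>%
    arrange(dplyr::desc(.data$proportion))
  unswitched <- sum(usage$proportion[usage$isotype %in% c("IGHD", "IGHM")])
  list(usage = usage, unswitched = unswitched)
}

SWITCHED_ISOTYPES <- c("IGHA1", "IGHA2", "IGHG1", "IGHG2", "IGHG3",
                       "IGHG4", "IGHE")

#' Antigen-experience annotation of BCRs
#'
#' Antigen-experienced: class switched (IgA, IgG, IgE) with more than four
#' somatic mutations. Antigen-inexperienced: unswitched (IgD, IgM) with four
#' or fewer mutations. Everything else (including missing annotations) is
#' unclassified.
#'
#' @param isotype,shm_count Vectors aligned per record.
#' @return Character vector in
#'   `{experienced, inexperienced, unclassified}`.
#' @export
antigen_experience <- function(isotype, shm_count) {
  dplyr::case_when(
    isotype %in% SWITCHED_ISOTYPES & shm_count > 4 ~ "experienced",
    isotype %in% c("IGHD", "IGHM") & shm_count <= 4 ~ "inexperienced",
    TRUE ~ "unclassified"
  )
}

#' Mean sample SHM via per-clone means
#'
#' Computes the mean SHM per clone first and then averages over clones, so
#' large clones are not overrepresented in the sample mean.
#'
#' @param records Repertoire tibble for one sample with `clone_id` and
#'   `shm_count`.
#' @return Numeric scalar.
#' @export
mean_sample_shm <- function(records) {
  records %>%
    filter(!is.na(.data$shm_count)) %>%
    group_by(.data$clone_id) %>%
    summarise(clone_shm = mean(.data$shm_count), .groups = "drop") %>%
    pull(.data$clone_shm) %>%
    mean()
}
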