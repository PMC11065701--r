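# Depth-matched subsampled clonal sharing between samples.

#' Common subsampling depth across samples
#'
#' The shared depth is a fixed fraction (default 90%) of the number of unique
#' VDJ sequences in the shallowest sample, floored to an integer, so that all
#' pairwise overlap statistics are computed at matched depth.
#'
#' @param unique_counts Named or unnamed integer vector of per-sample unique
#'   VDJ sequence counts.
#' @param fraction Fraction of the minimum depth to retain (default 0.9).
#' @return Integer subsampling depth.
#' @export
subsample_depth <- function(unique_counts, fraction = 0.9) {
  if (length(unique_counts) == 0L) abort("no sample depths supplied")
  if (any(unique_counts < 1L)) abort("unique counts must be >= 1")
  as.integer(floor(fraction * min(unique_counts)))
}

# Lower median: for even n the smaller of the two central order statistics.
# Subsampled overlap counts are integers; the lower median keeps the
# estimator on the observable grid.
lower_median <- function(x) {
  s <- sort(x)
  s[ceiling(length(s) / 2)]
}

#' Subsampled overlap between two samples
#'
#' Repeatedly draws `depth` unique VDJ sequences without replacement from
#' each sample's unique-sequence set and computes the shared-sequence count
#' and Jaccard coefficient of the two draws; the clone-count variant
#' intersects the clone-id sets carried by the drawn sequences. Medians
#' (lower-median convention) over iterations are returned.
#'
#' @param set_a,set_b Character vectors: unique VDJ sequences of each sample.
#' @param depth Subsampling depth; must not exceed either set size.
#' @param n_iter Number of subsampling iterations (default 10000).
#' @param clone_a,clone_b Optional clone ids aligned with `set_a`/`set_b`,
#'   required for the clone-count statistic.
#' @param seed Integer seed; the draw stream is local to this call.
#' @return One-row tibble: `depth`, `n_iter`, `median_shared`,
#'   `median_jaccard`, `iqr_shared` and (when clone ids are given)
#'   `median_shared_clones`.
#' @export
shared_overlap <- function(set_a, set_b, depth, n_iter = 10000,
                           clone_a = NULL, clone_b = NULL, seed = 1L) {
  set_a <- unique(set_a); set_b <- unique(set_b)
  if (depth > length(set_a) || depth > length(set_b)) {
    abort("depth exceeds a sample's unique sequence count")
  }
  with_clones <- !is.null(clone_a) && !is.null(clone_b)
  if (with_clones) {
    clone_a <- clone_a[!duplicated(set_a)]
    clone_b <- clone_b[!duplicated(set_b)]
  }
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  shared <- integer(n_iter); jac <- numeric(n_iter)
  shared_cl <- if (with_clones) integer(n_iter) else NULL
  for (it in seq_len(n_iter)) {
    ia <- sample.int(length(set_a), depth)
    ib <- sample.int(length(set_b), depth)
    a <- set_a[ia]; b <- set_b[ib]
    ninter <- sum(a %in% b)
    shared[it] <- ninter
    jac[it] <- ninter / (2L * depth - ninter)
    if (with_clones) {
      shared_cl[it] <- length(intersect(unique(clone_a[ia]),
                                        unique(clone_b[ib])))
    }
  }
  out <- tibble(
    depth = as.integer(depth), n_iter = as.integer(n_iter),
    median_shared = lower_median(shared),
    median_jaccard = lower_median(jac),
    iqr_shared = unname(diff(quantile(shared, c(0.25, 0.75))))
  )
  if (with_clones) out$median_shared_clones <- lower_median(shared_cl)
  out
}

# Save/restore the global RNG state so seeded helpers do not disturb callers.
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Pairwise sharing statistics across samples of a participant
#'
#' Computes subsampled overlap ([shared_overlap()]) for every sample pair at
#' a common depth ([subsample_depth()]). Per-pair seeds are derived
#' deterministically from `seed` and the pair labels so the matrix is
#' reproducible and order-invariant.
#'
#' @param records Repertoire tibble (one participant); needs `sample_id` and
#'   `vdj_nt`, plus `clone_id` for `statistic = "clone_count"`.
#' @param statistic One of `"jaccard"`, `"count"`, `"clone_count"`.
#' @param fraction Depth fraction passed to [subsample_depth()].
#' @param n_iter Iterations per pair.
#' @param seed Base seed for the per-pair streams.
#' @return Long tibble: `sample_a`, `sample_b`, `statistic`, `depth`,
#'   `median`, `iqr`.
#' @export
sharing_table <- function(records, statistic = c("jaccard", "count",
                                                 "clone_count"),
                          fraction = 0.9, n_iter = 10000, seed = 1L) {
  statistic <- arg_match(statistic)
  samples <- sort(unique(records$sample_id))
  if (length(samples) < 2L) abort("need at least two samples")
  sets <- lapply(samples, function(s) {
    ix <- records$sample_id == s
    list(vdj = records$vdj_nt[ix],
         clone = if ("clone_id" %in% names(records))
           records$clone_id[ix] else NULL)
  })
  names(sets) <- samples
  depth <- subsample_depth(vapply(sets, function(x)
    length(unique(x$vdj)), integer(1)), fraction)
  prs <- combn(samples, 2L)
  rows <- lapply(seq_len(ncol(prs)), function(k) {
    a <- prs[1L, k]; b <- prs[2L, k]
    res <- shared_overlap(
      sets[[a]]$vdj, sets[[b]]$vdj, depth, n_iter,
      clone_a = if (statistic == "clone_count") sets[[a]]$clone,
      clone_b = if (statistic == "clone_count") sets[[b]]$clone,
      seed = derive_seed(seed, paste(a, b, sep = "|"))
    )
    med <- switch(statistic,
                  jaccard = res$median_jaccard,
                  count = res$median_shared,
                  clone_count = res$median_shared_clones)
    tibble(sample_a = a, sample_b = b, statistic = statistic,
           depth = res$depth, median = as.numeric(med),
           iqr = res$iqr_shared)
  })
  bind_rows(rows)
}

#' Square sharing matrix from the long sharing table
#'
#' @param sharing Long tibble from [sharing_table()].
#' @return Symmetric numeric matrix over samples; the diagonal is 1 for the
#'   Jaccard statistic and the subsampling depth for count statistics.
#' @export
sharing_matrix <- function(sharing) {
  samples <- sort(unique(c(sharing$sample_a, sharing$sample_b)))
  m <- matrix(0, length(samples), length(samples),
              dimnames = list(samples, samples))
  for (k in seq_len(nrow(sharing))) {
    m[sharing$sample_a[k], sharing$sample_b[k]] <- sharing$median[k]
    m[sharing$sample_b[k], sharing$sample_a[k]] <- sharing$median[k]
  }
  diag(m) <- if (sharing$statistic[1] == "jaccard") 1 else sharing$depth[1]
  m
}

#' Exact (non-subsampled) Jaccard coefficient between two samples
#'
#' @param set_a,set_b Character vectors of unique sequences.
#' @return `|A n B| / |A u B|`.
#' @export
exact_jaccard <- function(set_a, set_b) {
  a <- unique(set_a); b <- unique(set_b)
  length(intersect(a, b)) / length(union(a, b))
}
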