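# Per-clone lineage graphs: alignment trimming, Hamming distances, minimum
# spanning tree, degree centrality, and the degree-threshold predictor of
# immunosurveilling / temporally persistent BCRs.

#' Select clones eligible for network analysis
#'
#' Retains clones observed in at least `min_samples` tumour samples of the
#' participant and carrying at least `min_seqs` unique BCR sequences.
#'
#' @param records Repertoire tibble with `clone_id`.
#' @param min_samples Minimum samples a clone must appear in (default 2).
#' @param min_seqs Minimum unique VDJ sequences per clone (default 10).
#' @return Tibble of retained `participant_id`, `clone_id` pairs with the
#'   counts used for the filter.
#' @export
select_network_clones <- function(records, min_samples = 2, min_seqs = 10) {
  records %>%
    group_by(.data$participant_id, .data$clone_id) %>%
    summarise(n_samples_observed = n_distinct(.data$sample_id),
              n_unique_vdj = n_distinct(.data$vdj_nt), .groups = "drop") %>%
    filter(.data$n_samples_observed >= min_samples,
           .data$n_unique_vdj >= min_seqs)
}

#' Trim a multiple sequence alignment to well-occupied ends
#'
#' Removes leading and trailing alignment columns, moving inward from each
#' end, until the terminal column has a non-gap occupancy of at least
#' `occupancy`. Alignments shorter than `min_len` after trimming are
#' signalled as skipped (`NULL`).
#'
#' @param msa Character matrix (rows = sequences, cols = aligned positions,
#'   gap `-`) or character vector of equal-length aligned sequences.
#' @param occupancy Required terminal-column non-gap fraction (default
#'   0.95).
#' @param min_len Minimum trimmed length in nucleotides (default 80).
#' @return Trimmed character matrix, or `NULL` when the trimmed length falls
#'   below `min_len`.
#' @export
trim_alignment <- function(msa, occupancy = 0.95, min_len = 80) {
  if (is.character(msa) && !is.matrix(msa)) msa <- seq_char_matrix(msa)
  if (length(msa) == 0L || nrow(msa) == 0L) abort("empty alignment")
  occ <- colMeans(msa != "-")
  lo <- 1L; hi <- ncol(msa)
  while (lo <= hi && occ[lo] < occupancy) lo <- lo + 1L
  while (hi >= lo && occ[hi] < occupancy) hi <- hi - 1L
  if (hi - lo + 1L < min_len) return(NULL)
  msa[, lo:hi, drop = FALSE]
}

#' MST degree centrality from a Hamming distance matrix
#'
#' Computes the minimum spanning tree of the distance matrix (deterministic
#' (weight, i, j) tie-breaking; [mst_edges()]) and each variant's degree,
#' the number of incident MST edges. Degree 1 marks a lineage end with no
#' progeny variants.
#'
#' @param d Symmetric distance matrix over unique variants (n >= 2).
#' @return List: `degree` (integer vector, names from `d`) and `edges`
#'   (tibble from [mst_edges()]).
#' @export
mst_degree <- function(d) {
  edges <- mst_edges(d)
  deg <- mst_degrees(edges, nrow(d))
  names(deg) <- rownames(d)
  list(degree = deg, edges = edges)
}

# Reduce one clone's records to a trimmed unique-variant set with the
# record-to-variant mapping retained. Sequences whose length differs from
# the clone's modal length cannot enter the substitution-only distance model
# and are excluded (counted in the result).
clone_variants <- function(clone_records, occupancy = 0.95, min_len = 80) {
  lens <- nchar(clone_records$vdj_nt)
  modal <- as.integer(names(sort(table(lens), decreasing = TRUE))[1])
  keep <- lens == modal
  recs <- clone_records[keep, , drop = FALSE]
  trimmed <- trim_alignment(recs$vdj_nt, occupancy, min_len)
  if (is.null(trimmed)) {
    return(list(skipped = "too_short", n_off_length = sum(!keep)))
  }
  seqs <- apply(trimmed, 1L, paste, collapse = "")
  # canonical (lexicographic) variant order: degrees must not depend on
  # record row order when tied Hamming weights admit several MSTs
  variant_seq <- sort(unique(seqs), method = "radix")
  variant_of <- match(seqs, variant_seq)
  list(records = recs, variant_seq = variant_seq,
       variant_of = variant_of, n_off_length = sum(!keep))
}

#' Build per-clone lineage graphs with MST degree centrality
#'
#' For every clone passing [select_network_clones()]: trims the clone's
#' equal-length sequence stack ([trim_alignment()]), groups identical
#' trimmed sequences into variants, computes the pairwise Hamming matrix and
#' its minimum spanning tree, and annotates each variant with its MST
#' degree, the number of distinct sites and timepoints in which it is
#' observed, and its summed UMI share across samples.
#'
#' @param records Full repertoire tibble with `clone_id` (all samples; the
#'   UMI share denominator is each sample's total UMI count).
#' @param min_samples,min_seqs Clone filter; see [select_network_clones()].
#' @param occupancy,min_len Trimming parameters; see [trim_alignment()].
#' @return List of class `clone_network_set`:
#'   `variants` (tibble: clone_id, variant_id, sequence, degree, n_sites,
#'   n_timepoints, frequency, shm, n_variants), `edges` (tibble: clone_id,
#'   from, to, weight) and `skipped` (tibble with reasons).
#' @export
build_clone_networks <- function(records, min_samples = 2, min_seqs = 10,
                                 occupancy = 0.95, min_len = 80) {
  eligible <- select_network_clones(records, min_samples, min_seqs)
  sample_totals <- records %>%
    group_by(.data$sample_id) %>%
    summarise(sample_umi = sum(.data$umi_count), .groups = "drop")
  variants_out <- list(); edges_out <- list(); skipped <- list()
  for (k in seq_len(nrow(eligible))) {
    cid <- eligible$clone_id[k]; pid <- eligible$participant_id[k]
    recs <- records %>%
      filter(.data$participant_id == pid, .data$clone_id == cid)
    cv <- clone_variants(recs, occupancy, min_len)
    if (!is.null(cv$skipped)) {
      skipped[[length(skipped) + 1L]] <-
        tibble(participant_id = pid, clone_id = cid, reason = cv$skipped)
      next
    }
    nv <- length(cv$variant_seq)
    ann <- cv$records %>%
      mutate(variant_id = cv$variant_of) %>%
      left_join(sample_totals, by = "sample_id") %>%
      group_by(.data$variant_id) %>%
      summarise(
        n_sites = n_distinct(.data$site),
        n_timepoints = n_distinct(.data$timepoint[!is.na(.data$timepoint)]),
        frequency = sum(.data$umi_count / .data$sample_umi),
        shm = .data$shm_count[which.max(.data$umi_count)],
        .groups = "drop"
      ) %>%
      arrange(.data$variant_id)
    if (nv < 2L) {
      skipped[[length(skipped) + 1L]] <-
        tibble(participant_id = pid, clone_id = cid,
               reason = "single_variant")
      next
    }
    d <- hamming_matrix(setNames(cv$variant_seq,
                                 paste0("v", seq_len(nv))))
    md <- mst_degree(d)
    variants_out[[length(variants_out) + 1L]] <- ann %>%
      mutate(participant_id = pid, clone_id = cid,
             sequence = cv$variant_seq[.data$variant_id],
             degree = as.integer(md$degree[.data$variant_id]),
             n_variants = nv) %>%
      select("participant_id", "clone_id", "variant_id", "sequence",
             "degree", "n_sites", "n_timepoints", "frequency", "shm",
             "n_variants")
    edges_out[[length(edges_out) + 1L]] <- md$edges %>%
      mutate(participant_id = pid, clone_id = cid)
  }
  structure(
    list(variants = bind_rows(variants_out),
         edges = bind_rows(edges_out),
         skipped = bind_rows(skipped)),
    class = "clone_network_set"
  )
}

#' @export
print.clone_network_set <- function(x, ...) {
  cat("Clone lineage networks: ", n_distinct(x$variants$clone_id),
      " clones, ", nrow(x$variants), " variants (",
      nrow(x$skipped), " clones skipped)\n", sep = "")
  invisible(x)
}

#' Degree-cutoff classification of immunosurveilling/persistent BCRs
#'
#' Predicts a variant positive when its MST degree exceeds the cutoff and
#' scores the prediction against a boolean label (immunosurveilling =
#' observed in >= 2 sites; persistent = observed in >= 2 timepoints) via the
#' 2x2 confusion matrix. When a label class is absent the undefined metric
#' is reported `NA`.
#'
#' @param degree Integer vector of variant degrees.
#' @param label Logical vector, same length.
#' @param cutoffs Degree cutoffs; prediction is `degree > cutoff`
#'   (default 1, 2, 10).
#' @return Tibble of class `degree_classifier_eval`: one row per cutoff with
#'   `tp`, `fp`, `tn`, `fn`, `sensitivity`, `specificity`, `accuracy`.
#' @export
evaluate_degree_classifier <- function(degree, label,
                                       cutoffs = c(1, 2, 10)) {
  stopifnot(length(degree) == length(label))
  ok <- !is.na(degree) & !is.na(label)
  degree <- degree[ok]; label <- as.logical(label[ok])
  out <- lapply(cutoffs, function(ct) {
    pred <- degree > ct
    tp <- sum(pred & label); fp <- sum(pred & !label)
    tn <- sum(!pred & !label); fn <- sum(!pred & label)
    tibble(cutoff = ct, tp = tp, fp = fp, tn = tn, fn = fn,
           sensitivity = if (tp + fn > 0L) tp / (tp + fn) else NA_real_,
           specificity = if (tn + fp > 0L) tn / (tn + fp) else NA_real_,
           accuracy = (tp + tn) / length(degree))
  })
  out <- bind_rows(out)
  class(out) <- c("degree_classifier_eval", class(out))
  out
}

#' Export one clone's lineage network as an igraph graph (and GraphML)
#'
#' Nodes carry the variant degree, abundance and occupancy annotations;
#' edges carry the Hamming-distance weight.
#'
#' @param networks A `clone_network_set` from [build_clone_networks()].
#' @param clone_id Clone to export.
#' @param path Optional GraphML output path.
#' @return The `igraph` graph, invisibly when `path` is given.
#' @export
export_clone_network <- function(networks, clone_id, path = NULL) {
  v <- networks$variants %>% filter(.data$clone_id == !!clone_id)
  e <- networks$edges %>% filter(.data$clone_id == !!clone_id)
  if (nrow(v) == 0L) abort(paste0("clone not in network set: ", clone_id))
  g <- igraph::graph_from_data_frame(
    d = tibble(from = paste0("v", e$from), to = paste0("v", e$to),
               weight = e$weight),
    directed = FALSE,
    vertices = tibble(name = paste0("v", v$variant_id),
                      degree = v$degree, n_sites = v$n_sites,
                      n_timepoints = v$n_timepoints,
                      frequency = v$frequency)
  )
  if (!is.null(path)) {
    igraph::write_graph(g, path, format = "graphml")
    return(invisible(g))
  }
  g
}
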