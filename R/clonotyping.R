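# Clonotype assembly: single-nucleotide sequence networks and
# CDR3-identity single-linkage clustering.

#' Build the single-substitution sequence network of a sample
#'
#' Vertices are unique VDJ nucleotide sequences weighted by UMI count; an
#' edge joins two vertices iff they have equal length and Hamming distance
#' exactly 1 (single-nucleotide, non-indel difference). Connected components
#' are the network clusters from which clones are derived.
#'
#' @param records Collapsed repertoire tibble (one row per unique sequence).
#' @return An `igraph` graph with vertex attributes `name` (sequence_id),
#'   `vdj_nt`, `umi_count` and `component`.
#' @export
build_sequence_network <- function(records) {
  n <- nrow(records)
  g <- igraph::make_empty_graph(n = n, directed = FALSE)
  g <- igraph::set_vertex_attr(g, "name", value = records$sequence_id)
  g <- igraph::set_vertex_attr(g, "vdj_nt", value = records$vdj_nt)
  g <- igraph::set_vertex_attr(g, "umi_count", value = records$umi_count)
  by_len <- split(seq_len(n), nchar(records$vdj_nt))
  edges <- lapply(by_len, function(ix) {
    prs <- hamming1_pairs(records$vdj_nt[ix])
    if (nrow(prs)) cbind(ix[prs[, 1L]], ix[prs[, 2L]]) else NULL
  })
  edges <- do.call(rbind, edges[!vapply(edges, is.null, logical(1))])
  if (!is.null(edges) && nrow(edges)) {
    g <- igraph::add_edges(g, t(edges))
  }
  comp <- igraph::components(g)$membership
  igraph::set_vertex_attr(g, "component", value = comp)
}

# Single-linkage CDR3-identity pairs within one (v_call, CDR3 length) group.
# Identity = matches / length for equal-length CDR3s; unequal lengths never
# pair at this stage (the edge rule is substitution-only).
cdr3_identity_pairs <- function(cdr3, threshold) {
  n <- length(cdr3)
  if (n < 2L) return(matrix(integer(), 0L, 2L))
  L <- unique(nchar(cdr3))
  stopifnot(length(L) == 1L)
  max_mm <- floor(L * (1 - threshold) + 1e-9)
  d <- hamming_matrix(cdr3)
  idx <- which(upper.tri(d) & d <= max_mm, arr.ind = TRUE)
  idx
}

#' Assign receptor records of one participant to clones
#'
#' Clones are connected components of the union of two graphs over the
#' participant's collapsed records (all samples, one chain):
#' \itemize{
#'   \item the single-substitution sequence network on the full VDJ
#'     nucleotide sequence ([build_sequence_network()]), and
#'   \item single-linkage pairs sharing the gene-level V call and an
#'     equal-length CDR3 with amino-acid identity >= `identity_threshold`.
#' }
#' Clone ids are deterministic: the lexicographically smallest
#' `sample_id:sequence_id` among members.
#'
#' @param records Repertoire tibble for one participant and one chain
#'   (collapse per sample first; [collapse_identical()]).
#' @param identity_threshold CDR3 identity threshold in (0, 1]; default 0.95.
#' @return The input tibble with a `clone_id` column appended.
#' @export
assign_clones <- function(records, identity_threshold = 0.95) {
  if (identity_threshold <= 0 || identity_threshold > 1) {
    abort("identity_threshold must be in (0, 1]")
  }
  if (n_distinct(records$participant_id) > 1L) {
    abort("assign_clones() clusters one participant at a time")
  }
  if (n_distinct(records$chain) > 1L) {
    abort("assign_clones() clusters one chain at a time")
  }
  n <- nrow(records)
  if (n == 0L) return(mutate(records, clone_id = character()))
  # graph 1: Hamming-1 full-VDJ edges, within equal length
  by_len <- split(seq_len(n), nchar(records$vdj_nt))
  e1 <- lapply(by_len, function(ix) {
    prs <- hamming1_pairs(records$vdj_nt[ix])
    if (nrow(prs)) cbind(ix[prs[, 1L]], ix[prs[, 2L]]) else NULL
  })
  # graph 2: CDR3 identity within (v_call, CDR3 length)
  key <- paste(records$v_call, nchar(records$cdr3_aa), sep = "|")
  by_key <- split(seq_len(n), key)
  e2 <- lapply(by_key, function(ix) {
    prs <- cdr3_identity_pairs(records$cdr3_aa[ix], identity_threshold)
    if (nrow(prs)) cbind(ix[prs[, 1L]], ix[prs[, 2L]]) else NULL
  })
  edges <- do.call(rbind, c(e1[!vapply(e1, is.null, logical(1))],
                            e2[!vapply(e2, is.null, logical(1))]))
  if (is.null(edges)) edges <- matrix(integer(), 0L, 2L)
  comp <- uf_union_edges(n, edges)
  member_key <- paste(records$sample_id, records$sequence_id, sep = ":")
  clone_of <- vapply(split(member_key, comp), min, character(1))
  records %>%
    mutate(clone_id = unname(clone_of[as.character(comp)]))
}

#' Summarise clones across a participant's samples
#'
#' @param records Tibble with `clone_id` assigned.
#' @return One row per clone: member count, unique VDJ count, per-clone UMI
#'   total, number of samples and sites observed, and the dominant V call.
#' @export
summarise_clones <- function(records) {
  records %>%
    group_by(.data$participant_id, .data$clone_id) %>%
    summarise(
      n_records = n(),
      n_unique_vdj = n_distinct(.data$vdj_nt),
      umi_total = sum(.data$umi_count),
      n_samples_observed = n_distinct(.data$sample_id),
      n_sites_observed = n_distinct(.data$site),
      v_call = names(sort(table(.data$v_call), decreasing = TRUE))[1],
      .groups = "drop"
    )
}
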