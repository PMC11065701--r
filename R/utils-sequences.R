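#' @keywords internal
"_PACKAGE"

#' @import rlang
#' @importFrom dplyr %>% across all_of arrange bind_rows count distinct filter
#'   group_by left_join mutate n n_distinct pull rename row_number select
#'   slice_max summarise ungroup
#' @importFrom tibble tibble as_tibble
#' @importFrom stats cophenetic cor dist hclust median quantile rbinom rgeom
#'   rlnorm rmultinom rnorm rpois runif sd setNames as.dist dnorm cutree
#' @importFrom utils head combn
#' @importFrom mclust Mclust mclustBIC
NULL

# Split equal-length sequences into an n x L character matrix.
seq_char_matrix <- function(seqs) {
  if (length(seqs) == 0L) return(matrix(character(), 0L, 0L))
  L <- unique(nchar(seqs))
  if (length(L) != 1L) {
    abort("sequences must have equal length")
  }
  matrix(unlist(strsplit(seqs, "", fixed = TRUE), use.names = FALSE),
         nrow = length(seqs), ncol = L, byrow = TRUE)
}

#' Pairwise Hamming distance matrix
#'
#' Counts, for every pair of equal-length sequences, the number of positions
#' at which their symbols differ. Any symbols are compared literally, so after
#' alignment trimming a residual gap (`-`) counts as a mismatch against a base
#' and as a match against another gap.
#'
#' @param seqs Character vector of equal-length sequences (nucleotide or
#'   amino acid).
#' @return A symmetric integer matrix with zero diagonal, dimnames taken from
#'   `names(seqs)` (or the sequences themselves when unnamed).
#' @examples
#' hamming_matrix(c("ACGT", "ACGA", "TCGA"))
#' @export
hamming_matrix <- function(seqs) {
  if (length(seqs) == 0L) abort("no sequences supplied")
  if (length(unique(nchar(seqs))) != 1L) {
    abort("hamming_matrix() requires equal-length sequences")
  }
  ch <- seq_char_matrix(seqs)
  n <- nrow(ch)
  d <- matrix(0L, n, n)
  for (p in seq_len(ncol(ch))) {
    d <- d + outer(ch[, p], ch[, p], FUN = "!=")
  }
  storage.mode(d) <- "integer"
  lab <- if (!is.null(names(seqs))) names(seqs) else seqs
  dimnames(d) <- list(lab, lab)
  d
}

# All unordered pairs (i, j) with Hamming distance exactly 1, among
# equal-length sequences. Uses one-position wildcard hashing: two sequences
# differ at exactly position p iff they collide after masking p and nowhere
# else; collecting collisions over all p yields pairs at distance <= 1, and
# exact duplicates are expected to have been collapsed upstream.
hamming1_pairs <- function(seqs) {
  n <- length(seqs)
  if (n < 2L) return(matrix(integer(), 0L, 2L))
  L <- unique(nchar(seqs))
  stopifnot(length(L) == 1L)
  out <- vector("list", L)
  for (p in seq_len(L)) {
    masked <- paste0(substr(seqs, 1L, p - 1L), ".", substr(seqs, p + 1L, L))
    grp <- split(seq_len(n), masked)
    grp <- grp[lengths(grp) > 1L]
    if (length(grp)) {
      prs <- lapply(grp, function(ix) {
        # sequences identical outside p; keep pairs that actually differ at p
        ch <- substr(seqs[ix], p, p)
        cmb <- combn(seq_along(ix), 2L)
        keep <- ch[cmb[1L, ]] != ch[cmb[2L, ]]
        cbind(ix[cmb[1L, keep]], ix[cmb[2L, keep]])
      })
      out[[p]] <- do.call(rbind, prs)
    }
  }
  prs <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  if (is.null(prs) || nrow(prs) == 0L) return(matrix(integer(), 0L, 2L))
  prs <- cbind(pmin(prs[, 1L], prs[, 2L]), pmax(prs[, 1L], prs[, 2L]))
  unique(prs)
}

# Union-find with path compression (used by clustering and Kruskal MST).
uf_new <- function(n) seq_len(n)

uf_find <- function(parent, i) {
  while (parent[i] != i) i <- parent[i]
  i
}

# Merge components containing edge endpoints; returns parent vector.
uf_union_edges <- function(n, edges) {
  parent <- uf_new(n)
  if (nrow(edges)) {
    for (k in seq_len(nrow(edges))) {
      ri <- uf_find(parent, edges[k, 1L])
      rj <- uf_find(parent, edges[k, 2L])
      if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
    }
  }
  vapply(seq_len(n), function(i) uf_find(parent, i), integer(1))
}

#' Minimum spanning tree of a distance matrix with deterministic tie-breaking
#'
#' Kruskal's algorithm over all vertex pairs, with candidate edges ordered by
#' (weight, i, j). Integer Hamming weights tie frequently in BCR lineage
#' graphs, so the tie order is fixed rather than implementation-dependent.
#'
#' @param d Symmetric numeric distance matrix (n >= 2).
#' @return Tibble of MST edges with columns `from`, `to` (row indices,
#'   from < to) and `weight`; exactly `n - 1` rows.
#' @export
mst_edges <- function(d) {
  n <- nrow(d)
  if (is.null(n) || n < 2L) abort("mst_edges() needs at least two vertices")
  if (!isTRUE(all.equal(d, t(d)))) abort("distance matrix must be symmetric")
  idx <- which(upper.tri(d), arr.ind = TRUE)
  w <- d[upper.tri(d)]
  ord <- order(w, idx[, 1L], idx[, 2L])
  parent <- uf_new(n)
  from <- to <- integer(n - 1L); wt <- numeric(n - 1L)
  k <- 0L
  for (e in ord) {
    i <- idx[e, 1L]; j <- idx[e, 2L]
    ri <- uf_find(parent, i); rj <- uf_find(parent, j)
    if (ri != rj) {
      parent[max(ri, rj)] <- min(ri, rj)
      k <- k + 1L
      from[k] <- i; to[k] <- j; wt[k] <- w[e]
      if (k == n - 1L) break
    }
  }
  if (k < n - 1L) abort("distance matrix is not connected") # unreachable for finite d
  tibble(from = from, to = to, weight = wt)
}

# Per-vertex degree from an MST edge list.
mst_degrees <- function(edges, n) {
  tabulate(c(edges$from, edges$to), nbins = n)
}

# Derive a reproducible child seed from a base seed and a label.
# Kept below 2^31 - 1; stable across platforms.
derive_seed <- function(seed, label) {
  h <- sum(utf8ToInt(paste0(label)) * (seq_along(utf8ToInt(paste0(label))) %% 31L + 1L))
  (as.integer(seed) * 7919L + as.integer(h %% 104729L)) %% 2147483647L
}
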