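# Clonal-similarity dendrograms and concordance with tumour phylogenies.

#' Ward-D2 similarity tree from a Jaccard matrix
#'
#' Converts the similarity matrix to a distance `D = 1 - J` and runs
#' agglomerative clustering with the Ward-D2 criterion; merge heights define
#' the dendrogram's cophenetic structure.
#'
#' @param jaccard_matrix Symmetric matrix of Jaccard coefficients in `[0, 1]`
#'   with sample dimnames.
#' @return An `hclust` object.
#' @export
similarity_tree <- function(jaccard_matrix) {
  if (!isTRUE(all.equal(jaccard_matrix, t(jaccard_matrix)))) {
    abort("similarity matrix must be symmetric")
  }
  d <- as.dist(1 - jaccard_matrix)
  hclust(d, method = "ward.D2")
}

#' Cophenetic distance matrix of a tree
#'
#' For a dendrogram (`hclust`), the distance between two leaves is the merge
#' height at which they are first joined. For an edge-weighted phylogeny
#' (`ape::phylo`, e.g. read from Newick), it is the sum of branch lengths
#' along the path connecting the two leaves.
#'
#' @param tree An `hclust` object or an `ape` `phylo` object.
#' @return Symmetric matrix of cophenetic distances with leaf-label dimnames.
#' @export
cophenetic_matrix <- function(tree) {
  if (inherits(tree, "hclust")) {
    as.matrix(cophenetic(tree))
  } else if (inherits(tree, "phylo")) {
    ape::cophenetic.phylo(tree)
  } else {
    abort("tree must be an hclust or phylo object")
  }
}

# Upper-triangular vector of a matrix, rows/cols ordered by `labels`.
upper_by_labels <- function(m, labels) {
  m <- m[labels, labels, drop = FALSE]
  m[upper.tri(m)]
}

#' Cophenetic correlation between two trees
#'
#' Pearson correlation between the two trees' cophenetic distances, paired by
#' leaf pair over the shared label set. Both trees must carry identical leaf
#' labels.
#'
#' @param tree_a,tree_b Trees accepted by [cophenetic_matrix()] (an `hclust`
#'   dendrogram or an edge-weighted `phylo`), or precomputed cophenetic
#'   matrices.
#' @return Correlation in `[-1, 1]`.
#' @export
cophenetic_correlation <- function(tree_a, tree_b) {
  ma <- if (is.matrix(tree_a)) tree_a else cophenetic_matrix(tree_a)
  mb <- if (is.matrix(tree_b)) tree_b else cophenetic_matrix(tree_b)
  la <- sort(rownames(ma)); lb <- sort(rownames(mb))
  if (!identical(la, lb)) abort("trees must share identical leaf labels")
  cor(upper_by_labels(ma, la), upper_by_labels(mb, la))
}

#' One-sided permutation p value for tree concordance
#'
#' Shuffles the leaf labels of the second tree (topology held fixed)
#' `n_perm` times and counts permutations whose cophenetic correlation
#' reaches the observed one. The add-one estimator
#' `p = (1 + #{r_perm >= r_obs}) / (1 + n_perm)` keeps p strictly positive.
#'
#' @inheritParams cophenetic_correlation
#' @param n_perm Number of label permutations (default 100).
#' @param seed Integer seed for the permutation stream.
#' @param exact Enumerate all `n!` label permutations instead of sampling
#'   (feasible for few leaves); `p = #\{r_perm >= r_obs\} / n!` then, with
#'   the identity permutation counted in the numerator.
#' @return List with `r_obs`, `p_value`, `n_perm` and the permuted
#'   correlations `r_perm`.
#' @export
permutation_pvalue <- function(tree_a, tree_b, n_perm = 100, seed = 1L,
                               exact = FALSE) {
  if (!exact && n_perm < 1L) abort("n_perm must be >= 1")
  ma <- if (is.matrix(tree_a)) tree_a else cophenetic_matrix(tree_a)
  mb <- if (is.matrix(tree_b)) tree_b else cophenetic_matrix(tree_b)
  labels <- sort(rownames(ma))
  if (!identical(labels, sort(rownames(mb)))) {
    abort("trees must share identical leaf labels")
  }
  va <- upper_by_labels(ma, labels)
  mb <- mb[labels, labels]
  # a zero-variance distance vector (e.g. a star tree with equal heights)
  # carries no association; score it 0 so all permutations tie and p = 1
  safe_cor <- function(x, y) {
    r <- suppressWarnings(cor(x, y))
    if (is.finite(r)) r else 0
  }
  r_obs <- safe_cor(va, mb[upper.tri(mb)])
  n <- length(labels)
  perm_cor <- function(p) {
    mp <- mb[p, p]
    safe_cor(va, mp[upper.tri(mp)])
  }
  if (exact) {
    if (n > 8L) abort("exact enumeration supported for at most 8 leaves")
    perms <- all_permutations(n)
    r_perm <- vapply(perms, perm_cor, numeric(1))
    p <- sum(r_perm >= r_obs - 1e-12) / length(perms)
    n_perm <- length(perms)
  } else {
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old))
    set.seed(seed)
    r_perm <- vapply(seq_len(n_perm), function(i) perm_cor(sample.int(n)),
                     numeric(1))
    p <- (1 + sum(r_perm >= r_obs - 1e-12)) / (1 + n_perm)
  }
  list(r_obs = r_obs, p_value = p, n_perm = n_perm, r_perm = r_perm)
}

# All permutations of 1..n (n small), recursively.
all_permutations <- function(n) {
  if (n == 1L) return(list(1L))
  sub <- all_permutations(n - 1L)
  out <- vector("list", n * length(sub))
  k <- 0L
  for (i in seq_len(n)) {
    for (s in sub) {
      k <- k + 1L
      v <- integer(n); v[i] <- n
      v[-i] <- s
      out[[k]] <- v
    }
  }
  out
}

#' Read an edge-weighted tree from a Newick file
#'
#' Thin wrapper over `ape::read.tree()`, used for externally supplied tumour
#' phylogenies whose cophenetic distances are branch-length path sums.
#'
#' @param path Newick file path.
#' @return An `ape` `phylo` object.
#' @export
read_genomic_tree <- function(path) {
  ape::read.tree(path)
}
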