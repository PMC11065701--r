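# Lineage graphs: trimming, Hamming, MST degree, degree classifier.

test_that("network clone selection applies both filters", {
  rec <- bind_rows(
    make_records(10, sample_id = "s1"),          # 10 seqs, 1 sample
    { r <- make_records(5, sample_id = "s2"); r$sequence_id <-
      paste0("x", 1:5); r }
  )
  rec$clone_id <- c(rep("inOne", 10), rep("inTwo", 5))
  # clone "inTwo" shares 5 extra seqs in s1 to reach 10 across 2 samples
  extra <- make_records(5, sample_id = "s1")
  extra$sequence_id <- paste0("y", 1:5)
  extra$clone_id <- "inTwo"
  rec <- bind_rows(rec, extra)
  sel <- select_network_clones(rec)
  expect_equal(sel$clone_id, "inTwo")

  # boundary: 9 unique seqs in 3 samples excluded
  rec9 <- bind_rows(lapply(1:3, function(s) {
    r <- make_records(3, sample_id = paste0("s", s))
    r$sequence_id <- paste0("s", s, "_", 1:3)
    r
  }))
  rec9$clone_id <- "nine"
  expect_equal(nrow(select_network_clones(rec9)), 0L)
})

test_that("alignment trimming walks in from low-occupancy ends", {
  # gap-free alignment unchanged
  msa <- do.call(rbind, strsplit(random_seqs(10, 100), ""))
  expect_equal(dim(trim_alignment(msa)), c(10L, 100L))

  # 100 seqs: first column 90% occupied -> removed; second 96% -> kept
  m <- matrix("A", 100, 100)
  m[1:10, 1] <- "-"
  m[1:4, 2] <- "-"
  tm <- trim_alignment(m)
  expect_equal(ncol(tm), 99L)
  expect_equal(tm[1, 1], "-")  # residual internal gap in kept column

  # trimmed length below 80 signals a skip
  short <- matrix("A", 10, 85)
  short[1:5, 1:6] <- "-"   # 50% occupancy over six leading columns
  expect_null(trim_alignment(short))
  expect_error(trim_alignment(matrix(character(), 0, 0)), "empty")
})

test_that("hamming matrix matches the brute-force oracle", {
  expect_equal(unname(hamming_matrix(c("ACGT", "ACGA"))[1, 2]), 1L)
  set.seed(20)
  for (rep in 1:30) {
    seqs <- random_seqs(8, 40)
    expect_equal(unname(hamming_matrix(seqs)), brute_hamming_matrix(seqs))
  }
  expect_error(hamming_matrix(c("ACG", "ACGT")), "equal-length")
})

test_that("MST recovers forced topologies with exact degrees", {
  # star: hub at distance 1 from all, leaves pairwise 2
  n <- 6
  d <- matrix(2, n, n); d[1, ] <- d[, 1] <- 1; diag(d) <- 0
  dimnames(d) <- list(paste0("v", 1:n), paste0("v", 1:n))
  md <- mst_degree(d)
  expect_equal(unname(md$degree), c(n - 1L, rep(1L, n - 1L)))

  # chain: path metric gives interior degree 2, ends 1
  dc <- abs(outer(1:5, 1:5, "-"))
  dimnames(dc) <- list(paste0("v", 1:5), paste0("v", 1:5))
  mdc <- mst_degree(dc)
  expect_equal(unname(mdc$degree), c(1L, 2L, 2L, 2L, 1L))
})

test_that("MST weight matches exhaustive enumeration on small instances", {
  # enumerate all spanning trees of K_n via Prufer sequences (n <= 7)
  prufer_tree_edges <- function(pr, n) {
    degree <- rep(1L, n)
    for (v in pr) degree[v] <- degree[v] + 1L
    edges <- matrix(0L, n - 1L, 2L)
    for (k in seq_along(pr)) {
      leaf <- min(which(degree == 1L))
      edges[k, ] <- c(leaf, pr[k])
      degree[leaf] <- degree[leaf] - 1L
      degree[pr[k]] <- degree[pr[k]] - 1L
    }
    edges[n - 1L, ] <- which(degree == 1L)
    edges
  }
  set.seed(33)
  for (rep in 1:5) {
    n <- 6
    d <- matrix(sample(1:6, n * n, TRUE), n, n)
    d <- d + t(d); diag(d) <- 0
    dimnames(d) <- list(paste0("v", 1:n), paste0("v", 1:n))
    best <- Inf
    grid <- as.matrix(expand.grid(rep(list(1:n), n - 2L)))
    for (g in seq_len(nrow(grid))) {
      e <- prufer_tree_edges(grid[g, ], n)
      w <- sum(d[e])
      if (w < best) best <- w
    }
    md <- mst_degree(d)
    expect_equal(sum(md$edges$weight), best)
  }
})

test_that("MST agrees with independent implementations on larger instances", {
  set.seed(34)
  for (rep in 1:10) {
    seqs <- unique(random_seqs(40, 30))
    d <- hamming_matrix(seqs)
    md <- mst_degree(d)
    # igraph oracle: total weight (MST is weight-unique only up to ties)
    g <- igraph::graph_from_adjacency_matrix(d, mode = "undirected",
                                             weighted = TRUE)
    w_igraph <- sum(igraph::E(igraph::mst(g))$weight)
    expect_equal(sum(md$edges$weight), w_igraph)
    # ape oracle on one instance class
    expect_equal(nrow(md$edges), length(seqs) - 1L)
    expect_equal(sum(md$degree), 2L * (length(seqs) - 1L))
  }
})

test_that("degree distribution is invariant under variant relabeling", {
  # tie-free weights: the MST is unique, so relabeling cannot change the
  # degree multiset (with tied integer weights, distinct tie-broken MSTs
  # may legitimately differ; lineage metrics are additive and tie-safe)
  set.seed(35)
  for (rep in 1:5) {
    n <- 15
    d <- matrix(0, n, n)
    d[upper.tri(d)] <- runif(n * (n - 1) / 2)
    d <- d + t(d)
    md <- mst_degree(d)
    perm <- sample(n)
    md2 <- mst_degree(d[perm, perm])
    expect_equal(sort(unname(md$degree)), sort(unname(md2$degree)))
  }
  # simulated lineage: tree-additive distances, degrees invariant under
  # record order
  sim <- default_sim()
  rec <- default_asg()
  big <- names(sort(table(rec$clone_id), decreasing = TRUE))[1]
  cl <- rec[rec$clone_id == big, ]
  net1 <- build_clone_networks(cl, min_samples = 1, min_seqs = 2)
  net2 <- build_clone_networks(cl[rev(seq_len(nrow(cl))), ],
                               min_samples = 1, min_seqs = 2)
  expect_equal(sort(net1$variants$degree), sort(net2$variants$degree))
})

test_that("confusion-matrix metrics match hand-computed tables", {
  # TP 8, FN 2, TN 85, FP 5 at cutoff 2: build degrees accordingly
  degree <- c(rep(5L, 8), rep(1L, 2), rep(1L, 85), rep(5L, 5))
  label <- c(rep(TRUE, 10), rep(FALSE, 90))
  ev <- evaluate_degree_classifier(degree, label, cutoffs = 2)
  expect_equal(ev$sensitivity, 0.8)
  expect_equal(ev$specificity, 85 / 90)
  expect_equal(ev$accuracy, 0.93)

  # cutoff 0 predicts everything positive
  ev0 <- evaluate_degree_classifier(degree, label, cutoffs = 0)
  expect_equal(ev0$sensitivity, 1)

  # single-class labels leave the undefined metric missing
  evna <- evaluate_degree_classifier(degree, rep(TRUE, 100), cutoffs = 2)
  expect_true(is.na(evna$specificity))
})

test_that("metrics agree with caret's confusion matrix", {
  skip_if_not_installed("caret")
  set.seed(40)
  degree <- sample(1:12, 200, TRUE)
  label <- runif(200) < plogis((degree - 4) / 2)
  ev <- evaluate_degree_classifier(degree, label, cutoffs = 2)
  cm <- caret::confusionMatrix(factor(degree > 2, c("TRUE", "FALSE")),
                               factor(label, c("TRUE", "FALSE")),
                               positive = "TRUE")
  expect_equal(ev$sensitivity, unname(cm$byClass["Sensitivity"]))
  expect_equal(ev$specificity, unname(cm$byClass["Specificity"]))
  expect_equal(ev$accuracy, unname(cm$overall["Accuracy"]))
})

test_that("sweeping cutoffs is monotone in sensitivity and specificity", {
  set.seed(41)
  degree <- sample(1:15, 500, TRUE)
  label <- runif(500) < plogis((degree - 5))
  ev <- evaluate_degree_classifier(degree, label, cutoffs = c(1, 2, 10))
  expect_true(all(diff(ev$sensitivity) <= 0))
  expect_true(all(diff(ev$specificity) >= 0))
})

test_that("clone networks annotate occupancy and export round-trips", {
  # two samples; a 3-variant clone whose hub variant spans both sites
  base <- strrep("ACGT", 30)
  mut <- function(s, i, to) { substr(s, i, i) <- to; s }
  v1 <- base; v2 <- mut(base, 5, "T"); v3 <- mut(v2, 40, "A")
  rec <- bind_rows(
    make_records(3, sample_id = "s1", site = "lymph_node",
                 vdj_nt = c(v1, v2, v3)),
    { r <- make_records(1, sample_id = "s2", site = "liver", vdj_nt = v2)
      r$sequence_id <- "seqX"; r }
  )
  rec <- bind_rows(rec, {
    # pad the clone to 10 unique sequences with a mutation ladder
    extra <- Reduce(function(s, i)
      mut(s, i, if (substr(s, i, i) == "C") "G" else "C"),
      50:56, init = v1, accumulate = TRUE)[-1]
    r <- make_records(7, sample_id = "s1", site = "lymph_node",
                      vdj_nt = extra)
    r$sequence_id <- paste0("pad", 1:7); r
  })
  rec$clone_id <- "cl1"
  rec$timepoint <- c(1L, 1L, 1L, 2L, rep(1L, 7))
  net <- build_clone_networks(rec, min_samples = 2, min_seqs = 10)
  v <- net$variants
  expect_equal(nrow(v), 10L)
  hub <- v[v$sequence == v2, ]
  expect_equal(hub$n_sites, 2L)
  expect_equal(hub$n_timepoints, 2L)
  expect_true(all(v$n_sites[v$sequence != v2] == 1L))
  expect_equal(sum(v$degree), 2L * (nrow(v) - 1L))

  g <- export_clone_network(net, "cl1")
  expect_equal(igraph::ecount(g), nrow(v) - 1L)
  expect_equal(sort(unname(igraph::degree(g))), sort(v$degree))
  path <- withr::local_tempfile(fileext = ".graphml")
  export_clone_network(net, "cl1", path)
  g2 <- igraph::read_graph(path, format = "graphml")
  expect_equal(sort(unname(igraph::degree(g2))), sort(v$degree))
})

test_that("single-variant clones are reported as degenerate skips", {
  rec <- bind_rows(
    make_records(1, sample_id = "s1"),
    { r <- make_records(1, sample_id = "s2"); r$sequence_id <- "o"; r }
  )
  rec$vdj_nt <- strrep("ACGT", 25)
  rec$clone_id <- "cl"
  net <- build_clone_networks(rec, min_samples = 2, min_seqs = 1)
  expect_equal(net$skipped$reason, "single_variant")
  expect_equal(nrow(net$variants), 0L)
})
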