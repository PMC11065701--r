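# Topology classes, expansion threshold and clone classes A-D.

test_that("clone proportions normalize per sample", {
  rec <- make_records(2, umi_count = c(2L, 8L))
  rec$clone_id <- c("cl1", "cl2")
  pr <- clone_proportions(rec)
  expect_equal(sort(pr$proportion), c(0.2, 0.8))

  # one clone, one sample
  rec1 <- make_records(1, umi_count = 7L); rec1$clone_id <- "c"
  expect_equal(clone_proportions(rec1)$proportion, 1)

  # 3 samples x 5 clones: every column sums to 1
  set.seed(5)
  rec3 <- bind_rows(lapply(1:3, function(s) {
    r <- make_records(5, sample_id = paste0("s", s),
                      umi_count = sample(1:50, 5))
    r$clone_id <- paste0("cl", 1:5)
    r
  }))
  pr3 <- clone_proportions(rec3)
  sums <- tapply(pr3$proportion, pr3$sample_id, sum)
  expect_true(all(abs(sums - 1) < 1e-12))
})

test_that("topology follows the all/some/one rule", {
  rec <- bind_rows(lapply(1:3, function(s)
    make_records(3, sample_id = paste0("s", s))))
  rec$clone_id <- c("stemC", "cladeC", "privC",
                    "stemC", "cladeC", "privB",
                    "stemC", "privA", "privD")
  topo <- classify_topology(rec)
  expect_equal(topo$topology[topo$clone_id == "stemC"], "stem")
  expect_equal(topo$topology[topo$clone_id == "cladeC"], "clade")
  expect_equal(topo$topology[topo$clone_id == "privC"], "private")
  expect_true(all(topo$immunosurveilling[topo$clone_id %in%
                                           c("stemC", "cladeC")]))

  # single-sample participant: unclassifiable
  one <- make_records(2); one$clone_id <- c("a", "b")
  expect_true(all(classify_topology(one)$topology == "unclassifiable"))
})

test_that("expansion cutoff recovers the analytic crossing of two components", {
  set.seed(10)
  n1 <- 1850; n2 <- 150
  x <- c(rnorm(n1, -3, 0.3), rnorm(n2, -1, 0.3))
  mod <- fit_expansion_threshold(x)
  # closed-form posterior-equality crossing of the two planted Gaussians
  w1 <- n1 / (n1 + n2); w2 <- n2 / (n1 + n2)
  grid <- seq(-3, -1, length.out = 20000)
  cross <- grid[which(w2 * dnorm(grid, -1, 0.3) >=
                        w1 * dnorm(grid, -3, 0.3))[1]]
  expect_lt(abs(mod$cutoff - cross), 0.15)
  expect_lt(mod$frac_expanded, 0.10)
})

test_that("single-component data falls back to a percentile cutoff", {
  set.seed(3)
  x <- rnorm(500, -2, 0.2)
  expect_warning(mod <- fit_expansion_threshold(x), "degenerate")
  expect_true(mod$fallback)
  expect_lt(mod$frac_expanded, 0.10)
  expect_lt(abs(mod$cutoff - quantile(x, 0.9)), 0.05)
})

test_that("tidy and glance summarise the expansion model", {
  set.seed(10)
  x <- c(rnorm(900, -3, 0.3), rnorm(100, -1, 0.3))
  mod <- fit_expansion_threshold(x)
  td <- tidy(mod)
  expect_equal(nrow(td), 2L)
  expect_true(all(diff(td$mean) > 0))
  gl <- glance(mod)
  expect_equal(gl$cutoff, mod$cutoff)
  expect_equal(gl$n, 1000L)
})

test_that("clone classes follow the A-D table with max-over-samples expansion", {
  rec <- bind_rows(lapply(1:3, function(s)
    make_records(4, sample_id = paste0("s", s),
                 umi_count = c(80L, 10L, 5L, 5L))))
  rec$clone_id <- rep(c("big", "mid", "smallShared", "smallPriv"), 3)
  rec <- rec[!(rec$clone_id == "smallPriv" & rec$sample_id != "s1"), ]
  rec <- rec[!(rec$clone_id == "big" & rec$sample_id == "s3"), ]
  props <- clone_proportions(rec)
  topo <- classify_topology(rec)
  model <- structure(list(cutoff = log10(100 * 0.4)), # 40% of sample UMIs
                     class = "expansion_model")
  cls <- classify_clone_class(props, topo, model)
  get <- function(id) cls$clone_class[cls$clone_id == id]
  expect_equal(get("big"), "B")          # shared, above cutoff in >= 1 site
  expect_equal(get("smallShared"), "D")  # shared, below everywhere
  expect_equal(get("smallPriv"), "C")    # private, below

  # partition: exhaustive and exclusive
  expect_false(anyNA(cls$clone_class))
  expect_true(all(cls$clone_class %in% c("A", "B", "C", "D")))

  # raising the cutoff never moves a clone to expanded
  model_hi <- structure(list(cutoff = model$cutoff + 1),
                        class = "expansion_model")
  cls_hi <- classify_clone_class(props, topo, model_hi)
  expect_true(all(!cls_hi$expanded | cls$expanded))
})

test_that("planted expanded clones are recalled at the fitted cutoff", {
  sim <- default_sim()
  rec <- default_asg()
  props <- clone_proportions(rec)
  cl_max <- props %>%
    group_by(participant_id, clone_id) %>%
    summarise(m = log10(100 * max(proportion)), .groups = "drop")
  mod <- fit_expansion_threshold(log10(100 * props$proportion),
                                 n_components = 4, select_bic = TRUE,
                                 constraint_values = cl_max$m)
  truth <- sim$truth %>% distinct(clone_true, expanded_clone)
  # map each planted clone to its majority recovered cluster; fragments
  # are scored by the clonotyping ARI checks, not here
  joined <- rec %>%
    count(clone_true, clone_id) %>%
    group_by(clone_true) %>% slice_max(n, n = 1, with_ties = FALSE) %>%
    ungroup() %>%
    left_join(truth, by = "clone_true") %>%
    left_join(cl_max, by = "clone_id")
  recall <- joined %>%
    filter(expanded_clone) %>%
    summarise(r = mean(m > mod$cutoff)) %>% pull(r)
  expect_gte(recall, 0.9)
})

test_that("clone size increases with the number of samples observed", {
  sim <- default_sim()
  rec <- default_asg()
  summ <- summarise_clones(rec)
  props <- clone_proportions(rec) %>%
    group_by(clone_id) %>%
    summarise(mean_size = mean(proportion), .groups = "drop") %>%
    left_join(summ, by = "clone_id")
  expect_gt(cor(props$mean_size, props$n_samples_observed,
                method = "spearman"), 0)
})

test_that("immunosurveilling-clone site proportions honour the VDJ filters", {
  rec <- bind_rows(
    make_records(4, sample_id = "s1", site = "lymph_node"),
    make_records(4, sample_id = "s2", site = "liver")
  )
  rec$clone_id <- "cl1"
  out <- surveilling_site_proportions(rec, min_vdjs = 4)
  expect_equal(sort(out$site), c("liver", "lymph_node"))
  expect_equal(out$mean_proportion, c(0.5, 0.5))

  # single-site clone excluded
  rec2 <- make_records(8, sample_id = "s1", site = "liver")
  rec2$clone_id <- "cl1"
  expect_warning(out2 <- surveilling_site_proportions(rec2), "no clone")
  expect_equal(nrow(out2), 0L)

  # max unique VDJs < 4 in every site: excluded
  rec3 <- bind_rows(
    make_records(3, sample_id = "s1", site = "lymph_node"),
    make_records(3, sample_id = "s2", site = "liver")
  )
  rec3$clone_id <- "cl1"
  expect_warning(out3 <- surveilling_site_proportions(rec3), "no clone")
  expect_equal(nrow(out3), 0L)
})
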