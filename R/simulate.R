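# Synthetic multi-site, multi-timepoint BCR repertoires with planted
# ground truth: clonal lineages related by point mutations, heavy-tailed
# two-component clone sizes, depth-increasing class switching, and hub
# variants disseminated across sites and timepoints.

DEFAULT_SITES <- c("lymph_node", "liver", "lung_pleura", "breast", "skin",
                   "bone", "brain", "ovary")

#' Simulation configuration
#'
#' Defaults define the package's reference study conditions: 4 participants,
#' 8 sites x 2 therapy timepoints, 200 clones per participant, a
#' two-component lognormal clone-size distribution on the log10-percent
#' scale (unexpanded mean -3, expanded mean -1, sd 0.3, 5% expanded),
#' germline length 350 nt with a 60 nt (20 aa) CDR3, per-edge mutation
#' counts 1 + Geometric (mean 1.25, substitution-only), chain-like lineage
#' growth in segments of at most 6 steps, and hub variants (marked at rate
#' 0.05 at node creation) disseminated to 3 sites (always including the
#' lymph-node origin) and both timepoints, each hub seeding a progeny
#' burst of 3 + Poisson(5) local descendants.
#'
#' @param n_participants,sites,timepoints Cohort layout.
#' @param n_clones Clones per participant.
#' @param p_expanded,size_mean_unexp,size_mean_exp,size_sd Clone-size
#'   mixture on the log10 percent scale.
#' @param nv_unexpanded_mu,nv_expanded_mu Mean lineage sizes (negative
#'   binomial) for unexpanded/expanded clones.
#' @param branch_prob Probability that a new skeleton node starts a side
#'   branch instead of extending the current chain tip; branches restart
#'   from an existing hub when one exists (diversification re-seeds at
#'   disseminated variants), otherwise from a random node.
#' @param seg_max Maximum chain-segment length before a forced restart.
#' @param edge_mut_mean Mean of the 1 + Geometric per-edge mutation count.
#' @param hub_fraction Fraction of internal skeleton nodes marked as hubs.
#' @param hub_breadth Number of sites a hub is disseminated to.
#' @param burst_min,burst_mean Hub progeny burst: `burst_min + Poisson(burst_mean)`.
#' @param burst_mut_mean Mean per-edge mutation count for burst progeny
#'   (the locally expanded subtree is sampled more sparsely than a chain).
#' @param germline_length,cdr3_length Sequence geometry (nt).
#' @param sample_umi Target UMI total per sample.
#' @param csr_intercept,csr_slope Logistic class-switch probability in
#'   lineage depth.
#' @param n_v_genes Size of the V gene pool clones draw from.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_participants = 4,
                       sites = DEFAULT_SITES,
                       timepoints = 2,
                       n_clones = 200,
                       p_expanded = 0.05,
                       size_mean_unexp = -3, size_mean_exp = -1,
                       size_sd = 0.3,
                       nv_unexpanded_mu = 2.5, nv_expanded_mu = 60,
                       branch_prob = 0.02,
                       seg_max = 6,
                       edge_mut_mean = 1.25,
                       hub_fraction = 0.05,
                       hub_breadth = 3,
                       burst_min = 3, burst_mean = 5,
                       burst_mut_mean = 2.5,
                       germline_length = 350, cdr3_length = 60,
                       sample_umi = 30000,
                       csr_intercept = -2, csr_slope = 0.6,
                       n_v_genes = 40) {
  stopifnot(germline_length >= 80, hub_fraction >= 0, hub_fraction <= 1,
            hub_breadth <= length(sites), cdr3_length %% 3 == 0)
  structure(as.list(environment()), class = "sim_config")
}

NT <- c("A", "C", "G", "T")

# Mutate `m` uniformly chosen positions of a nucleotide vector to a
# different base; returns the vector and the mutated positions.
mutate_seq <- function(ntvec, m) {
  pos <- sample.int(length(ntvec), min(m, length(ntvec)))
  for (p in pos) {
    ntvec[p] <- sample(setdiff(NT, ntvec[p]), 1L)
  }
  list(seq = ntvec, pos = pos)
}

# Grow one clone's lineage. Returns per-node tibble with sequences, truth
# annotations, and per-node (site, timepoint) observation lists.
simulate_clone <- function(cfg, participant, clone_idx, v_call) {
  expanded <- runif(1) < cfg$p_expanded
  log10_pct <- rnorm(1, if (expanded) cfg$size_mean_exp else
    cfg$size_mean_unexp, cfg$size_sd)
  nv_mu <- if (expanded) cfg$nv_expanded_mu else cfg$nv_unexpanded_mu
  nv <- 1L + stats::rnbinom(1L, size = 3, mu = nv_mu)

  L <- cfg$germline_length
  cdr3_start <- L - cfg$cdr3_length - 30L  # CDR3 near the 3' end of V(D)J
  cdr3_aa_len <- cfg$cdr3_length / 3L
  germ_nt <- sample(NT, L, replace = TRUE)
  germ_aa <- sample(AA20, cdr3_aa_len, replace = TRUE)

  seqs <- vector("list", nv); aas <- vector("list", nv)
  parent <- integer(nv); depth <- integer(nv); shm <- integer(nv)
  seqs[[1L]] <- germ_nt; aas[[1L]] <- germ_aa
  parent[1L] <- NA_integer_; depth[1L] <- 0L; shm[1L] <- 0L
  tip <- 1L
  add_child <- function(par, i, mut_mean = cfg$edge_mut_mean) {
    m <- 1L + rgeom(1L, 1 / mut_mean)  # 1 + Geom(p), mean = mut_mean
    mut <- mutate_seq(seqs[[par]], m)
    seqs[[i]] <<- mut$seq
    aa <- aas[[par]]
    hits <- mut$pos[mut$pos >= cdr3_start &
                      mut$pos < cdr3_start + cfg$cdr3_length]
    for (p in hits) {
      if (runif(1) < 0.75) {  # non-synonymous fraction
        ai <- (p - cdr3_start) %/% 3L + 1L
        aa[ai] <- sample(setdiff(AA20, aa[ai]), 1L)
      }
    }
    aas[[i]] <<- aa
    parent[i] <<- par
    depth[i] <<- depth[par] + 1L
    shm[i] <<- shm[par] + m
  }
  # chain-like skeleton: extend the current tip up to seg_max steps, then
  # (or on a rare branch event) restart a new chain from an existing hub
  # when one exists, else from a random node. Hub status is drawn at node
  # creation so hub placement is depth-agnostic.
  is_hub <- rep(FALSE, nv)
  is_hub[1L] <- runif(1) < cfg$hub_fraction
  seg_len <- 0L
  if (nv > 1L) {
    for (i in 2:nv) {
      restart <- seg_len >= cfg$seg_max || runif(1) < cfg$branch_prob
      par <- if (restart) {
        hubs_so_far <- which(is_hub[seq_len(i - 1L)])
        seg_len <- 0L
        if (length(hubs_so_far)) hubs_so_far[sample.int(length(hubs_so_far), 1L)]
        else sample.int(i - 1L, 1L)
      } else tip
      add_child(par, i)
      is_hub[i] <- runif(1) < cfg$hub_fraction
      tip <- i
      seg_len <- seg_len + 1L
    }
  }

  # observation sets: clone founder lives in one (site, timepoint);
  # hubs disseminate to hub_breadth sites (always incl. the lymph-node
  # origin) and all timepoints; non-hub children of a hub settle in one
  # draw from the hub's set, other children inherit the parent's location.
  other_sites <- setdiff(cfg$sites, cfg$sites[1L])
  root_site <- sample(cfg$sites, 1L)
  root_tp <- sample.int(cfg$timepoints, 1L)
  site_of <- vector("list", nv); tp_of <- vector("list", nv)
  assign_obs <- function(i) {
    if (is_hub[i]) {
      site_of[[i]] <<- c(cfg$sites[1L],
                         sample(other_sites, cfg$hub_breadth - 1L))
      tp_of[[i]] <<- seq_len(cfg$timepoints)
    } else if (is.na(parent[i])) {
      site_of[[i]] <<- root_site; tp_of[[i]] <<- root_tp
    } else if (is_hub[parent[i]]) {
      site_of[[i]] <<- sample(site_of[[parent[i]]], 1L)
      tp_of[[i]] <<- sample(tp_of[[parent[i]]], 1L)
    } else {
      site_of[[i]] <<- site_of[[parent[i]]][1L]
      tp_of[[i]] <<- tp_of[[parent[i]]][1L]
    }
  }
  for (i in seq_len(nv)) assign_obs(i)

  # hub progeny bursts: local descendants seeded by the disseminated hub
  hubs <- which(is_hub)
  for (h in hubs) {
    nb <- cfg$burst_min + rpois(1L, cfg$burst_mean)
    for (b in seq_len(nb)) {
      i <- length(seqs) + 1L
      seqs[[i]] <- list(); aas[[i]] <- list()
      parent <- c(parent, NA_integer_); depth <- c(depth, 0L)
      shm <- c(shm, 0L)
      add_child(h, i, mut_mean = cfg$burst_mut_mean)
      is_hub <- c(is_hub, FALSE)
      site_of[[i]] <- sample(site_of[[h]], 1L)
      tp_of[[i]] <- sample(tp_of[[h]], 1L)
    }
  }
  nv <- length(seqs)

  # isotype: class-switch probability increases with lineage depth
  p_switch <- stats::plogis(cfg$csr_intercept + cfg$csr_slope * depth)
  switched <- runif(nv) < p_switch
  isotype <- ifelse(
    switched,
    sample(SWITCHED_ISOTYPES, nv, replace = TRUE,
           prob = c(0.25, 0.1, 0.35, 0.1, 0.08, 0.02, 0.1)),
    sample(c("IGHM", "IGHD"), nv, replace = TRUE, prob = c(0.8, 0.2)))

  hamming_to_germ <- vapply(seqs, function(s) sum(s != germ_nt), integer(1))
  tibble(
    clone = sprintf("c%03d", clone_idx),
    node = seq_len(nv),
    parent_node = parent,
    vdj_nt = vapply(seqs, paste, character(1), collapse = ""),
    cdr3_aa = vapply(aas, paste, character(1), collapse = ""),
    v_call = v_call,
    isotype = isotype,
    depth = depth,
    shm_true = shm,
    hamming_germline = hamming_to_germ,
    is_hub = is_hub,
    sites = lapply(site_of, identity),
    tps = lapply(tp_of, identity),
    expanded_clone = expanded,
    log10_pct = log10_pct,
    hub_weight = ifelse(is_hub, 3, 1)
  )
}

#' Simulate a multi-site, multi-timepoint repertoire with planted truth
#'
#' Generates, per participant, `n_clones` clonal lineages (distinct random
#' germlines and V genes), marks hub variants for cross-site/timepoint
#' dissemination, draws per-sample UMI counts from the two-component
#' clone-size mixture via a per-sample multinomial, and emits validated
#' repertoire records together with the ground-truth table.
#'
#' @param config A [sim_config()].
#' @param seed Integer seed; the full simulation stream derives from it.
#' @return List of class `sim_repertoire`: `records` (canonical repertoire
#'   tibble), `samples` (metadata tibble), `truth` (per unique sequence:
#'   clone, parent, is_hub, depth, true SHM, true n_sites/n_timepoints,
#'   expanded flag), and `n_shm_collisions` (sequences whose realised
#'   Hamming distance to germline differs from the summed edge mutations).
#' @export
simulate_repertoire <- function(config = sim_config(), seed = 1L) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  v_pool <- sprintf("IGHV%d-%d", sample(1:7, config$n_v_genes, TRUE),
                    sample(1:80, config$n_v_genes, TRUE))
  all_records <- list(); all_truth <- list()
  for (p in seq_len(config$n_participants)) {
    pid <- sprintf("P%02d", p)
    clones <- lapply(seq_len(config$n_clones), function(ci)
      simulate_clone(config, pid, ci,
                     v_call = sample(v_pool, 1L)))
    nodes <- bind_rows(clones) %>%
      mutate(participant_id = pid,
             sequence_id = paste0(.data$clone, "n",
                                  sprintf("%04d", .data$node)))
    # one record per (node, site, timepoint) observation
    obs <- nodes %>%
      mutate(obs = purrr::map2(.data$sites, .data$tps, function(s, t)
        tidyr::expand_grid(site = s, timepoint = t))) %>%
      select(-"sites", -"tps") %>%
      tidyr::unnest("obs") %>%
      mutate(sample_id = paste0(pid, "_", .data$site, "_t",
                                .data$timepoint))
    # per-sample multinomial UMI allocation; a clone's weight in each
    # sample is its planted mixture weight, split over the variants it
    # carries in that sample (hubs weighted up)
    obs <- obs %>%
      group_by(.data$clone, .data$sample_id) %>%
      mutate(rec_weight = 10^.data$log10_pct * .data$hub_weight /
               sum(.data$hub_weight)) %>%
      ungroup()
    obs <- obs %>%
      group_by(.data$sample_id) %>%
      mutate(umi_count = pmax(1L, as.integer(
        rmultinom(1L, config$sample_umi,
                  .data$rec_weight / sum(.data$rec_weight))))) %>%
      ungroup()
    all_records[[p]] <- obs %>%
      mutate(chain = "IGH", shm_count = .data$shm_true,
             clone_true = paste0(pid, "_", .data$clone)) %>%
      select("sequence_id", "participant_id", "sample_id", "site",
             "timepoint", "chain", "vdj_nt", "cdr3_aa", "v_call",
             "isotype", "umi_count", "shm_count", "clone_true")
    all_truth[[p]] <- nodes %>%
      mutate(clone_true = paste0(pid, "_", .data$clone),
             true_n_sites = lengths(.data$sites),
             true_n_timepoints = lengths(.data$tps)) %>%
      select("participant_id", "clone_true", "sequence_id", "node",
             "parent_node", "is_hub", "depth", "shm_true",
             "hamming_germline", "true_n_sites", "true_n_timepoints",
             "expanded_clone", "log10_pct")
  }
  records <- bind_rows(all_records) %>% mutate(pgen = NA_real_)
  truth <- bind_rows(all_truth)
  if (nrow(records) == 0L) abort("configuration produced zero sequences")
  samples <- records %>%
    distinct(.data$sample_id, .data$participant_id, .data$site,
             .data$timepoint)
  records <- validate_repertoire(records)
  structure(
    list(records = records, samples = samples, truth = truth,
         n_shm_collisions = sum(truth$shm_true != truth$hamming_germline)),
    class = "sim_repertoire"
  )
}

#' @export
print.sim_repertoire <- function(x, ...) {
  cat("Simulated repertoire: ", nrow(x$records), " records, ",
      n_distinct(x$truth$clone_true), " clones, ",
      nrow(x$samples), " samples; ", sum(x$truth$is_hub),
      " planted hubs (", x$n_shm_collisions, " SHM collisions)\n",
      sep = "")
  invisible(x)
}

#' UMI-weighted downsampling of a repertoire
#'
#' Draws, per sample and without replacement, a fixed fraction of the
#' sample's UMIs (each UMI is a draw unit) and reduces record counts
#' consistently; records losing all UMIs are dropped.
#'
#' @param records Repertoire tibble.
#' @param fraction Fraction of each sample's UMIs to keep, in (0, 1].
#' @param seed Integer seed.
#' @return Downsampled repertoire tibble.
#' @export
downsample_repertoire <- function(records, fraction, seed = 1L) {
  if (fraction <= 0 || fraction > 1) abort("fraction must be in (0, 1]")
  if (fraction == 1) return(records)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  records %>%
    group_by(.data$sample_id) %>%
    group_modify(function(df, key) {
      total <- sum(df$umi_count)
      depth <- max(1L, as.integer(round(fraction * total)))
      units <- rep.int(seq_len(nrow(df)), df$umi_count)
      kept <- tabulate(units[sample.int(total, depth)], nbins = nrow(df))
      df$umi_count <- kept
      df[kept > 0L, , drop = FALSE]
    }) %>%
    ungroup()
}
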