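# Shared fixtures built in code.

suppressPackageStartupMessages(library(dplyr))

# Minimal valid record tibble; fields overridable per test.
make_records <- function(n = 3, sample_id = "s1", participant_id = "p1",
                         site = "liver", timepoint = 1L,
                         vdj_nt = NULL, cdr3_aa = NULL, v_call = "IGHV1-1",
                         isotype = "IGHM", umi_count = 1L,
                         shm_count = 0L) {
  if (is.null(vdj_nt)) {
    vdj_nt <- replicate(n, paste(sample(c("A", "C", "G", "T"), 100,
                                        replace = TRUE), collapse = ""))
  }
  n <- length(vdj_nt)
  if (is.null(cdr3_aa)) cdr3_aa <- strrep("CARDY", 3)
  tibble(
    sequence_id = sprintf("seq%03d", seq_len(n)),
    participant_id = participant_id, sample_id = sample_id,
    site = site, timepoint = timepoint, chain = "IGH",
    vdj_nt = vdj_nt,
    cdr3_aa = rep_len(cdr3_aa, n),
    v_call = rep_len(v_call, n),
    isotype = rep_len(isotype, n),
    umi_count = rep_len(as.integer(umi_count), n),
    shm_count = rep_len(as.integer(shm_count), n),
    pgen = NA_real_
  )
}

# Random equal-length sequences over an alphabet.
random_seqs <- function(n, len, alphabet = c("A", "C", "G", "T")) {
  replicate(n, paste(sample(alphabet, len, replace = TRUE), collapse = ""))
}

# Brute-force Hamming distance between two strings (independent oracle).
brute_hamming <- function(a, b) {
  va <- strsplit(a, "")[[1]]; vb <- strsplit(b, "")[[1]]
  sum(va != vb)
}

# Brute-force all-pairs Hamming matrix oracle.
brute_hamming_matrix <- function(seqs) {
  n <- length(seqs)
  d <- matrix(0L, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    d[i, j] <- brute_hamming(seqs[i], seqs[j])
  }
  d
}

# Posterior-equality crossings between adjacent truth-labelled groups of a
# realised SHM draw, on the log(x + 1) scale (independent planted reference
# for mixture-refit recovery).
planted_shm_crossings <- function(x, lab) {
  lx <- log(x + 1)
  mu <- tapply(lx, lab, mean); sg <- tapply(lx, lab, sd)
  w <- as.vector(table(lab)) / length(lab)
  vapply(seq_len(max(lab) - 1L), function(k) {
    grid <- seq(mu[k], mu[k + 1], length.out = 5000)
    ix <- which(w[k + 1] * dnorm(grid, mu[k + 1], sg[k + 1]) >=
                  w[k] * dnorm(grid, mu[k], sg[k]))
    exp(grid[ix[1]]) - 1
  }, numeric(1))
}

# A small default simulation shared across tests (cached per session).
default_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- simulate_repertoire(
        sim_config(n_participants = 1, n_clones = 200), seed = 42)
    }
    cache
  }
})

# Clone assignment on the shared simulation (cached).
default_asg <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- assign_clones(default_sim()$records)
    cache
  }
})
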