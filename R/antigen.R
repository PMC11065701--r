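# Screening tumour CDR3s against a reference library of antibodies with
# known anti-pathogen specificity.

#' Load and filter a reference antibody database
#'
#' Reads (or accepts) a table of reference antibody CDR3s with their antigen
#' source, drops entries flagged as synthetic fusion proteins or
#' animal-derived, deduplicates on (cdr3_aa, antigen_source), and reports
#' per-source counts.
#'
#' @param table Tibble/data frame or TSV path with columns `cdr3_aa`,
#'   `antigen_source` and optional logical flags `synthetic_fusion`,
#'   `animal_derived`.
#' @return List of class `reference_db`: `entries` (retained tibble),
#'   `source_counts` (tibble antigen_source/n), `n_total`, `n_excluded`,
#'   `n_deduplicated`, `n_malformed`.
#' @export
load_reference_db <- function(table) {
  if (is.character(table)) {
    table <- readr::read_tsv(table, show_col_types = FALSE, progress = FALSE)
  }
  db <- as_tibble(table)
  if (!all(c("cdr3_aa", "antigen_source") %in% names(db))) {
    abort("reference table needs cdr3_aa and antigen_source columns")
  }
  for (fl in c("synthetic_fusion", "animal_derived")) {
    if (!fl %in% names(db)) db[[fl]] <- FALSE
  }
  n_total <- nrow(db)
  db$cdr3_aa <- toupper(as.character(db$cdr3_aa))
  malformed <- is.na(db$cdr3_aa) | db$cdr3_aa == "" |
    stringr::str_detect(db$cdr3_aa,
                        paste0("[^", paste(AA20, collapse = ""), "]"))
  db <- db[!malformed, , drop = FALSE]
  flagged <- db$synthetic_fusion | db$animal_derived
  db <- db[!flagged, , drop = FALSE]
  n_before_dedup <- nrow(db)
  db <- distinct(db, .data$cdr3_aa, .data$antigen_source, .keep_all = TRUE)
  structure(
    list(entries = select(db, "cdr3_aa", "antigen_source"),
         source_counts = count(db, .data$antigen_source, sort = TRUE,
                               name = "n"),
         n_total = n_total,
         n_excluded = sum(flagged),
         n_deduplicated = n_before_dedup - nrow(db),
         n_malformed = sum(malformed)),
    class = "reference_db"
  )
}

#' @export
print.reference_db <- function(x, ...) {
  cat("Reference antibody DB: ", nrow(x$entries), " entries retained (",
      x$n_excluded, " flagged excluded, ", x$n_deduplicated,
      " duplicates)\n", sep = "")
  print(x$source_counts, n = 12)
  invisible(x)
}

#' Fuzzy-match a CDR3 against the reference database
#'
#' A database entry matches when it has the same amino-acid length as the
#' query and at most `max_mismatch` substitutions (Hamming distance); the
#' metric is substitution-only, so length-changing edits never match.
#'
#' @param query_cdr3 Single CDR3 amino-acid string.
#' @param db A `reference_db` from [load_reference_db()].
#' @param max_mismatch Maximum amino-acid mismatches (default 3).
#' @return Tibble of matching entries with `mismatches`.
#' @export
fuzzy_match_cdr3 <- function(query_cdr3, db, max_mismatch = 3) {
  if (is.na(query_cdr3) || nchar(query_cdr3) == 0L) {
    abort("query CDR3 must be non-empty")
  }
  cand <- db$entries %>% filter(nchar(.data$cdr3_aa) == nchar(query_cdr3))
  if (nrow(cand) == 0L) {
    return(tibble(cdr3_aa = character(), antigen_source = character(),
                  mismatches = integer()))
  }
  qs <- strsplit(query_cdr3, "", fixed = TRUE)[[1]]
  mm <- vapply(strsplit(cand$cdr3_aa, "", fixed = TRUE),
               function(es) sum(es != qs), integer(1))
  cand %>%
    mutate(mismatches = mm) %>%
    filter(.data$mismatches <= max_mismatch) %>%
    arrange(.data$mismatches, .data$cdr3_aa)
}

#' Vectorised database-match indicator
#'
#' For each query CDR3, reports whether at least one database entry of the
#' same length lies within `max_mismatch` substitutions. Length-bucketed so
#' only equal-length candidates are compared.
#'
#' @param queries Character vector of CDR3 amino-acid strings.
#' @inheritParams fuzzy_match_cdr3
#' @return Logical vector aligned with `queries`.
#' @export
has_db_match <- function(queries, db, max_mismatch = 3) {
  out <- logical(length(queries))
  by_len <- split(seq_along(queries), nchar(queries))
  db_by_len <- split(db$entries$cdr3_aa, nchar(db$entries$cdr3_aa))
  for (L in names(by_len)) {
    ents <- db_by_len[[L]]
    if (is.null(ents)) next
    ech <- seq_char_matrix(ents)
    qix <- by_len[[L]]
    qch <- seq_char_matrix(queries[qix])
    for (i in seq_along(qix)) {
      mm <- rowSums(ech != matrix(qch[i, ], nrow(ech), ncol(ech),
                                  byrow = TRUE))
      out[qix[i]] <- any(mm <= max_mismatch)
    }
  }
  out
}

#' Per-group proportion of records matching the reference database
#'
#' Annotates each record with whether its CDR3 has any database match within
#' `max_mismatch` substitutions, then reports the matched proportion per
#' sample and group (clone class or degree bin); enrichment testing between
#' groups is left to standard tests.
#'
#' @param records Repertoire tibble; needs `cdr3_aa`, `sample_id` and the
#'   grouping column.
#' @param db A `reference_db`.
#' @param grouping Column name: `"clone_class"` or `"degree_bin"`.
#' @param max_mismatch Maximum amino-acid mismatches (default 3).
#' @return Tibble: `sample_id`, group, `n`, `n_matched`, `proportion`
#'   (`NA` for empty groups).
#' @export
match_enrichment <- function(records, db,
                             grouping = c("clone_class", "degree_bin"),
                             max_mismatch = 3) {
  grouping <- arg_match(grouping)
  if (!grouping %in% names(records)) {
    abort(paste0("records lack grouping column ", grouping))
  }
  records %>%
    mutate(matched = has_db_match(.data$cdr3_aa, db, max_mismatch)) %>%
    group_by(.data$sample_id, .data[[grouping]]) %>%
    summarise(n = n(), n_matched = sum(.data$matched),
              proportion = ifelse(n() > 0L, sum(.data$matched) / n(),
                                  NA_real_),
              .groups = "drop")
}

# Published composition of the retained reference antibody library
# (per-source entry counts after exclusions; the residual category "other"
# brings the total to 5,800).
reference_db_composition <- function() {
  tibble(
    antigen_source = c(
      "human_immunodeficiency_virus_1", "clostridium_tetani",
      "influenza_a", "vaccinia_virus", "hepatitis_c_virus",
      "streptococcus_pneumoniae", "staphylococcus_aureus",
      "human_betaherpesvirus_5", "other"),
    n = c(3525L, 817L, 486L, 92L, 80L, 59L, 38L, 32L, 671L)
  )
}

#' Synthetic stand-in reference antibody database
#'
#' The real reference library (built from public structural/abYsis/IEDB
#' antibody resources) is not redistributable here, so this generator emits
#' a synthetic stand-in with the same retained per-source composition
#' (5,800 entries; see `reference_db_composition()`), plus planted flagged
#' rows (synthetic fusion proteins, animal-derived) and duplicate rows that
#' [load_reference_db()] must remove. CDR3s are random 10-18 aa strings.
#'
#' @param seed Integer seed.
#' @param n_flagged Number of planted excluded rows (default 120).
#' @param n_duplicate Number of planted duplicate rows (default 25).
#' @return Tibble suitable for [load_reference_db()].
#' @export
synthetic_reference_db <- function(seed = 1L, n_flagged = 120,
                                   n_duplicate = 25) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  comp <- reference_db_composition()
  make_cdr3 <- function(n) {
    lens <- sample(10:18, n, replace = TRUE)
    vapply(lens, function(L)
      paste(sample(AA20, L, replace = TRUE), collapse = ""), character(1))
  }
  entries <- tibble(
    cdr3_aa = make_cdr3(sum(comp$n)),
    antigen_source = rep(comp$antigen_source, comp$n),
    synthetic_fusion = FALSE, animal_derived = FALSE
  )
  flagged <- tibble(
    cdr3_aa = make_cdr3(n_flagged),
    antigen_source = sample(comp$antigen_source, n_flagged, replace = TRUE),
    synthetic_fusion = seq_len(n_flagged) %% 2L == 0L,
    animal_derived = seq_len(n_flagged) %% 2L == 1L
  )
  dups <- entries[sample.int(nrow(entries), n_duplicate), ]
  out <- bind_rows(entries, flagged, dups)
  out[sample.int(nrow(out)), ]
}
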