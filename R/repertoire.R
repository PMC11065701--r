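# Repertoire data model and AIRR-style TSV I/O.
#
# A repertoire is a plain tibble with one row per unique receptor sequence:
#   sequence_id, participant_id, sample_id, site, timepoint, chain,
#   vdj_nt, cdr3_aa, v_call, isotype, umi_count, shm_count, pgen
# Sample metadata (participant, site, timepoint) is joined onto the records
# at load time so downstream verbs need only one table.

ISOTYPE_LEVELS <- c("IGHM", "IGHD", "IGHG1", "IGHG2", "IGHG3", "IGHG4",
                    "IGHA1", "IGHA2", "IGHE")
CHAIN_LEVELS <- c("IGH", "TRA", "TRB")
AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

# Default mapping from AIRR Rearrangement column names to canonical names.
default_col_map <- function() {
  c(sequence_id = "sequence_id",
    vdj_nt = "sequence",
    v_call = "v_call",
    cdr3_aa = "junction_aa",
    umi_count = "duplicate_count",
    isotype = "c_call",
    chain = "locus",
    sample_id = "sample_id",
    shm_count = "shm_count",
    pgen = "pgen")
}

#' Strip the allele suffix from a V gene call
#'
#' Clone definitions operate at the gene level (e.g. `IGHV3-23`), so
#' `IGHV3-23*01` and comma-separated multi-calls are reduced to the first
#' gene-level call.
#'
#' @param v_call Character vector of V calls.
#' @return Character vector of gene-level calls.
#' @export
normalize_v_call <- function(v_call) {
  first <- stringr::str_split_i(v_call, stringr::fixed(","), 1)
  stringr::str_split_i(first, stringr::fixed("*"), 1)
}

#' Read an AIRR-style rearrangement table into a validated repertoire
#'
#' Reads a TSV with one row per unique receptor sequence, maps columns to the
#' canonical schema, joins sample metadata, and drops rows violating the data
#' model (empty or non-ACGTN VDJ, CDR3 with symbols outside the 20 amino
#' acids, UMI count < 1). Unrecognised isotype strings are kept with isotype
#' set to `NA` (unknown) and a warning. The drop accounting is attached as
#' `attr(x, "load_report")`.
#'
#' @param path Path to the rearrangement TSV (header required).
#' @param metadata Optional tibble or TSV path with columns `sample_id`,
#'   `participant_id`, `site`, `timepoint`. When absent these columns must be
#'   present in the rearrangement table itself.
#' @param col_map Named character vector mapping canonical names to file
#'   column names; defaults follow the AIRR Rearrangement dialect
#'   (`sequence`, `junction_aa`, `duplicate_count`, `c_call`, ...).
#' @return A tibble of validated records with a `load_report` attribute
#'   (list: `n_read`, `n_kept`, `drop_count`, `drops` by reason).
#' @export
read_repertoire <- function(path, metadata = NULL, col_map = default_col_map()) {
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  raw <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  if (nrow(raw) == 0L) abort("empty repertoire file")
  map <- default_col_map()
  map[names(col_map)] <- col_map
  required <- c("sequence_id", "vdj_nt", "v_call", "cdr3_aa", "umi_count")
  missing <- required[!map[required] %in% names(raw)]
  if (length(missing)) {
    abort(paste0("missing required column(s): ",
                 paste(map[missing], collapse = ", ")))
  }
  rec <- tibble(
    sequence_id = as.character(raw[[map["sequence_id"]]]),
    sample_id = if (map["sample_id"] %in% names(raw))
      as.character(raw[[map["sample_id"]]]) else NA_character_,
    chain = if (map["chain"] %in% names(raw))
      as.character(raw[[map["chain"]]]) else "IGH",
    vdj_nt = toupper(as.character(raw[[map["vdj_nt"]]])),
    cdr3_aa = toupper(as.character(raw[[map["cdr3_aa"]]])),
    v_call = normalize_v_call(as.character(raw[[map["v_call"]]])),
    isotype = if (map["isotype"] %in% names(raw))
      as.character(raw[[map["isotype"]]]) else NA_character_,
    umi_count = as.integer(raw[[map["umi_count"]]]),
    shm_count = if (map["shm_count"] %in% names(raw))
      as.integer(raw[[map["shm_count"]]]) else NA_integer_,
    pgen = if (map["pgen"] %in% names(raw))
      as.numeric(raw[[map["pgen"]]]) else NA_real_
  )
  if (!is.null(metadata)) {
    if (is.character(metadata)) {
      metadata <- readr::read_tsv(metadata, show_col_types = FALSE,
                                  progress = FALSE)
    }
    metadata <- as_tibble(metadata) %>%
      mutate(sample_id = as.character(.data$sample_id))
    rec <- left_join(rec, metadata, by = "sample_id")
  } else {
    # sample annotations embedded in the rearrangement table itself
    if ("participant_id" %in% names(raw))
      rec$participant_id <- as.character(raw$participant_id)
    if ("site" %in% names(raw)) rec$site <- as.character(raw$site)
    if ("timepoint" %in% names(raw))
      rec$timepoint <- as.integer(raw$timepoint)
  }
  for (col in c("participant_id", "site")) {
    if (!col %in% names(rec)) rec[[col]] <- NA_character_
  }
  if (!"timepoint" %in% names(rec)) rec$timepoint <- NA_integer_
  validate_repertoire(rec)
}

#' Validate repertoire records against the data model
#'
#' @param records Tibble in the canonical schema.
#' @return The retained rows, with a `load_report` attribute.
#' @export
validate_repertoire <- function(records) {
  records <- as_tibble(records)
  n_read <- nrow(records)
  bad_umi <- is.na(records$umi_count) | records$umi_count < 1L
  bad_vdj <- is.na(records$vdj_nt) | records$vdj_nt == "" |
    stringr::str_detect(records$vdj_nt, "[^ACGTN]")
  bad_cdr3 <- !is.na(records$cdr3_aa) &
    stringr::str_detect(records$cdr3_aa,
                        paste0("[^", paste(AA20, collapse = ""), "]"))
  unknown_iso <- !is.na(records$isotype) &
    records$chain == "IGH" & !records$isotype %in% ISOTYPE_LEVELS
  if (any(unknown_iso)) {
    warn(paste0(sum(unknown_iso),
                " record(s) with unrecognised isotype kept as unknown"))
    records$isotype[unknown_iso] <- NA_character_
  }
  drop <- bad_umi | bad_vdj | bad_cdr3
  kept <- records[!drop, , drop = FALSE]
  dup <- kept %>%
    count(.data$sample_id, .data$sequence_id) %>%
    filter(n > 1L)
  if (nrow(dup)) {
    abort("sequence_id values must be unique within a sample")
  }
  report <- list(
    n_read = n_read,
    n_kept = nrow(kept),
    drop_count = sum(drop),
    drops = c(bad_umi = sum(bad_umi), bad_vdj = sum(bad_vdj),
              bad_cdr3 = sum(bad_cdr3))
  )
  attr(kept, "load_report") <- report
  kept
}

#' Write a repertoire back to the AIRR-style TSV dialect
#'
#' Inverse of [read_repertoire()]: canonical columns are renamed to the file
#' dialect so that a write/read round trip is lossless for valid records.
#'
#' @param records Repertoire tibble.
#' @param path Output TSV path.
#' @param col_map As in [read_repertoire()].
#' @return `path`, invisibly.
#' @export
write_repertoire <- function(records, path, col_map = default_col_map()) {
  map <- default_col_map()
  map[names(col_map)] <- col_map
  out <- records
  keep <- intersect(names(map), names(out))
  names(out)[match(keep, names(out))] <- map[keep]
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' Write a load report to JSON
#'
#' Serialises the `load_report` attribute attached by [read_repertoire()]
#' / [validate_repertoire()].
#'
#' @param records Validated repertoire tibble.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_load_report <- function(records, path) {
  report <- attr(records, "load_report")
  if (is.null(report)) abort("records carry no load_report attribute")
  jsonlite::write_json(report, path, auto_unbox = TRUE)
  invisible(path)
}

#' Collapse records with identical VDJ nucleotide sequences
#'
#' Within one sample and chain, rows sharing an identical `vdj_nt` are merged
#' into one vertex: UMI counts are summed and all other annotations are taken
#' from the highest-abundance member (ties broken by `sequence_id`).
#'
#' @param records Repertoire tibble from a single sample and chain.
#' @return Collapsed tibble; total UMI count is conserved.
#' @export
collapse_identical <- function(records) {
  if (nrow(records) == 0L) return(records)
  if (n_distinct(records$sample_id) > 1L || n_distinct(records$chain) > 1L) {
    abort("collapse_identical() expects records from one sample and chain")
  }
  records %>%
    group_by(.data$vdj_nt) %>%
    arrange(dplyr::desc(.data$umi_count), .data$sequence_id,
            .by_group = TRUE) %>%
    mutate(total_umi = sum(.data$umi_count)) %>%
    dplyr::slice(1L) %>%
    ungroup() %>%
    mutate(umi_count = .data$total_umi, total_umi = NULL) %>%
    arrange(.data$sequence_id)
}
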