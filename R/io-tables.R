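#' Read an identified-peptide table
#'
#' Reads the TSV peptide table produced by search-engine export (or by
#' [simulate_immunopeptidome()]) into a tidy tibble, one row per identified
#' peptide per sample.
#'
#' Required columns: `sequence`, `sample_id`, `condition`, `timepoint_h`,
#' `intensity`. Recognised optional columns: `modifications` (encoded
#' `name@pos;name@pos`, empty for none), `source_proteins` (`;`-separated
#' accessions), `is_decoy`, `search_score`, and `allele_ranks` (encoded
#' `rank@allele;rank@allele`, spread into one `rank_<allele>` column per
#' allele). Unknown columns are preserved untouched.
#'
#' @param path Path to a tab-separated peptide table.
#' @return Tibble of peptide records.
#' @export
read_peptide_table <- function(path) {
  tbl <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  required <- c("sequence", "sample_id", "condition", "timepoint_h", "intensity")
  check_columns(tbl, required, "peptide table")
  tbl <- dplyr::mutate(
    tbl,
    sequence = toupper(.data$sequence),
    timepoint_h = as.integer(.data$timepoint_h),
    intensity = as.numeric(.data$intensity)
  )
  if (any(tbl$intensity < 0, na.rm = TRUE)) abort("negative intensity in peptide table")

  if (!"modifications" %in% names(tbl)) tbl$modifications <- ""
  tbl$modifications <- dplyr::coalesce(as.character(tbl$modifications), "")
  validate_modifications(tbl$modifications, nchar(tbl$sequence))

  if (!"source_proteins" %in% names(tbl)) tbl$source_proteins <- ""
  tbl$source_proteins <- dplyr::coalesce(as.character(tbl$source_proteins), "")
  if (!"is_decoy" %in% names(tbl)) tbl$is_decoy <- FALSE
  tbl$is_decoy <- as.logical(tbl$is_decoy)

  if ("allele_ranks" %in% names(tbl)) {
    ranks <- parse_allele_ranks(tbl$allele_ranks)
    tbl <- dplyr::bind_cols(dplyr::select(tbl, -"allele_ranks"), ranks)
  }
  tbl
}

# Parse "rank@allele;rank@allele" strings into a tibble of rank_<allele> cols.
parse_allele_ranks <- function(x) {
  x <- dplyr::coalesce(as.character(x), "")
  parsed <- lapply(x, function(s) {
    if (!nzchar(s)) return(NULL)
    parts <- strsplit(strsplit(s, ";", fixed = TRUE)[[1]], "@", fixed = TRUE)
    bad <- lengths(parts) != 2
    if (any(bad)) abort(paste0("malformed allele_ranks entry: ", s))
    vals <- suppressWarnings(as.numeric(vapply(parts, `[`, "", 1)))
    if (any(is.na(vals)) || any(vals < 0)) {
      abort(paste0("allele rank must be a non-negative number: ", s))
    }
    setNames(vals, paste0("rank_", vapply(parts, `[`, "", 2)))
  })
  alleles <- unique(unlist(lapply(parsed, names)))
  out <- lapply(alleles, function(a) {
    vapply(parsed, function(p) if (a %in% names(p)) p[[a]] else NA_real_, 0)
  })
  tibble::as_tibble(setNames(out, alleles))
}

# Validate "name@pos;name@pos" modification strings against peptide lengths.
validate_modifications <- function(mods, pep_len) {
  for (i in seq_along(mods)) {
    if (!nzchar(mods[i])) next
    parts <- strsplit(strsplit(mods[i], ";", fixed = TRUE)[[1]], "@", fixed = TRUE)
    if (any(lengths(parts) != 2)) {
      abort(paste0("malformed modification entry: ", mods[i]))
    }
    pos <- suppressWarnings(as.integer(vapply(parts, `[`, "", 2)))
    if (any(is.na(pos)) || any(pos < 1) || any(pos > pep_len[i])) {
      abort(sprintf(
        "modification position outside peptide of length %d: %s",
        pep_len[i], mods[i]
      ))
    }
  }
  invisible(mods)
}

#' Parse a modification string into a tibble
#'
#' @param mods Character vector of `name@pos;name@pos` encodings.
#' @return Tibble with columns `index` (input row), `name`, `position`.
#' @export
parse_modifications <- function(mods) {
  mods <- dplyr::coalesce(as.character(mods), "")
  rows <- lapply(seq_along(mods), function(i) {
    if (!nzchar(mods[i])) return(NULL)
    parts <- strsplit(strsplit(mods[i], ";", fixed = TRUE)[[1]], "@", fixed = TRUE)
    tibble::tibble(
      index = i,
      name = vapply(parts, `[`, "", 1),
      position = as.integer(vapply(parts, `[`, "", 2))
    )
  })
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0) {
    out <- tibble::tibble(index = integer(), name = character(),
                          position = integer())
  }
  out
}

#' Read transcript models from the packaged TSV format
#'
#' Transcript geometry is supplied as a documented TSV with one row per
#' transcript rather than full GTF semantics: columns `transcript_id`,
#' `gene_id`, `contig`, `strand` (`+`/`-`), `exon_starts` and `exon_ends`
#' (comma-separated 1-based inclusive genomic coordinates, ascending),
#' `cds_start`, `cds_end` (genomic, 1-based inclusive), `gene_biotype`, and
#' `transcript_biotypes` (`;`-separated labels such as `NMD_mediated_decay`).
#'
#' @param path Path to the transcript model TSV.
#' @return Tibble with `exon_starts`, `exon_ends` and `transcript_biotypes`
#'   as list-columns.
#' @export
read_transcript_models <- function(path) {
  tbl <- readr::read_tsv(
    path, show_col_types = FALSE, progress = FALSE,
    col_types = readr::cols(
      exon_starts = readr::col_character(),
      exon_ends = readr::col_character(),
      transcript_biotypes = readr::col_character()
    )
  )
  check_columns(tbl, c(
    "transcript_id", "gene_id", "contig", "strand", "exon_starts", "exon_ends",
    "cds_start", "cds_end", "gene_biotype", "transcript_biotypes"
  ), "transcript model table")
  split_int <- function(x) lapply(strsplit(as.character(x), ",", fixed = TRUE), as.integer)
  tbl$exon_starts <- split_int(tbl$exon_starts)
  tbl$exon_ends <- split_int(tbl$exon_ends)
  tbl$transcript_biotypes <- strsplit(
    dplyr::coalesce(as.character(tbl$transcript_biotypes), ""), ";", fixed = TRUE
  )
  for (i in seq_len(nrow(tbl))) {
    s <- tbl$exon_starts[[i]]; e <- tbl$exon_ends[[i]]
    if (length(s) != length(e) || any(e < s) || is.unsorted(s)) {
      abort(paste0("malformed exon list for transcript ", tbl$transcript_id[i]))
    }
    if (any(s[-1] <= e[-length(e)])) {
      abort(paste0("overlapping exons for transcript ", tbl$transcript_id[i]))
    }
  }
  tbl
}

#' Write transcript models to the packaged TSV format
#'
#' Inverse of [read_transcript_models()].
#'
#' @param transcripts Transcript tibble with list-columns.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_transcript_models <- function(transcripts, path) {
  out <- dplyr::mutate(
    transcripts,
    exon_starts = vapply(.data$exon_starts, paste, "", collapse = ","),
    exon_ends = vapply(.data$exon_ends, paste, "", collapse = ","),
    transcript_biotypes = vapply(.data$transcript_biotypes, paste, "",
                                 collapse = ";")
  )
  readr::write_tsv(out, path)
  invisible(path)
}

#' Write a peptide table as TSV
#'
#' Inverse of [read_peptide_table()]; wide `rank_<allele>` columns are
#' written as-is.
#'
#' @param records Peptide tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_peptide_table <- function(records, path) {
  readr::write_tsv(records, path, na = "")
  invisible(path)
}

#' Read a feature-by-sample quantitation table
#'
#' Wide abundance table: first column `feature_id`, one column per sample.
#' Missing values are encoded as empty fields (never 0, which is a legal
#' abundance) and become `NA`.
#'
#' @param path Path to the abundance TSV.
#' @param meta_path Optional path to a sample metadata TSV with columns
#'   `sample_id`, `condition`, `timepoint_h`, `replicate`; attached as the
#'   `"sample_meta"` attribute when given.
#' @return Tibble of abundances, negative values rejected.
#' @export
read_quant_table <- function(path, meta_path = NULL) {
  tbl <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  check_columns(tbl, "feature_id", "quant table")
  vals <- dplyr::select(tbl, -"feature_id")
  if (any(vapply(vals, function(v) any(v < 0, na.rm = TRUE), TRUE))) {
    abort("negative abundance in quant table")
  }
  if (!is.null(meta_path)) {
    meta <- readr::read_tsv(meta_path, show_col_types = FALSE, progress = FALSE)
    check_columns(meta, c("sample_id", "condition", "timepoint_h", "replicate"),
                  "sample metadata")
    attr(tbl, "sample_meta") <- meta
  }
  tbl
}

# Wide quant tibble -> numeric matrix with feature_id rownames.
quant_to_matrix <- function(tbl) {
  m <- as.matrix(dplyr::select(tbl, -"feature_id"))
  rownames(m) <- tbl$feature_id
  storage.mode(m) <- "double"
  m
}

matrix_to_quant <- function(m) {
  tibble::as_tibble(m, rownames = "feature_id")
}

#' Packaged CT26 radiation-specific strong-binder table
#'
#' Loads the packaged table of radiation-specific MHC class I peptides from
#' the CT26 immunopeptidome: strong binders (best allele percent rank below
#' 0.5) ranked by their minimum percent rank across H-2-Kd/Dd/Ld and the
#' non-classical Qa alleles. Columns: `sequence`, `allele`, `rank`, `entry`
#' (UniProt-style accession), `protein_name`, `footnotes` (`a` catecholamine
#' signalling, `b` multi-peptide source protein, `c` cancer-testis antigen).
#'
#' @return Tibble with one row per peptide.
#' @export
ct26_radiation_peptides <- function() {
  path <- system.file("extdata", "table1_ct26.tsv", package = "radpep",
                      mustWork = TRUE)
  tbl <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  tbl$footnotes <- dplyr::coalesce(as.character(tbl$footnotes), "")
  tbl
}
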