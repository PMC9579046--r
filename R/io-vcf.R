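#' Read a Strelka-dialect somatic VCF
#'
#' Parses a VCF v4.x file (as emitted by the Strelka somatic caller) into a
#' tidy variant table, one row per ALT allele. Multi-allelic lines are split
#' into one record per alternate allele sharing position and reference.
#'
#' Read depth follows the Strelka convention: the `DP` key for SNVs/MNVs and
#' the `DPI` key for indels. Both FORMAT (per-sample) and INFO placements are
#' accepted, with FORMAT preferred when present; when several samples are
#' genotyped the `TUMOR` sample is used (falling back to the last sample),
#' since the coverage filter concerns the mutated reads. Absent depth is
#' recorded as `NA`, never 0. The highest population allele frequency is read
#' from the INFO key `MAX_AF` when present.
#'
#' @param path Path to a VCF text file (uncompressed or bgzipped).
#' @param tumor_sample Optional name of the genotype column carrying the
#'   tumour reads. Defaults to `"TUMOR"` when present, else the last sample.
#' @return Tibble with columns `contig`, `pos`, `ref`, `alt`, `filter`,
#'   `depth`, `max_pop_af`, `vtype` (`SNV`, `MNV`, `insertion`, `deletion`).
#' @export
read_strelka_vcf <- function(path, tumor_sample = NULL) {
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  vcf <- suppressWarnings(vcfR::read.vcfR(path, verbose = FALSE))
  fix <- vcf@fix
  if (is.null(fix) || nrow(fix) == 0) {
    return(tibble::tibble(
      contig = character(), pos = integer(), ref = character(),
      alt = character(), filter = character(), depth = integer(),
      max_pop_af = double(), vtype = character()
    ))
  }
  n_header <- sum(startsWith(readLines(path, warn = FALSE), "#"))

  gt <- vcf@gt
  sample_col <- NULL
  if (!is.null(gt) && ncol(gt) > 1) {
    samples <- colnames(gt)[-1]
    sample_col <- tumor_sample %||%
      (if ("TUMOR" %in% samples) "TUMOR" else samples[length(samples)])
    if (!sample_col %in% samples) {
      abort(paste0("sample not found in VCF: ", sample_col))
    }
  }

  format_value <- function(i, key) {
    if (is.null(sample_col)) return(NA_character_)
    keys <- strsplit(gt[i, "FORMAT"], ":", fixed = TRUE)[[1]]
    j <- match(key, keys)
    if (is.na(j)) return(NA_character_)
    vals <- strsplit(gt[i, sample_col], ":", fixed = TRUE)[[1]]
    if (j > length(vals)) NA_character_ else vals[j]
  }
  info_value <- function(info, key) {
    if (is.na(info)) return(NA_character_)
    fields <- strsplit(info, ";", fixed = TRUE)[[1]]
    hit <- grep(paste0("^", key, "="), fields, value = TRUE)
    if (length(hit) == 0) NA_character_ else sub("^[^=]+=", "", hit[1])
  }

  out <- vector("list", nrow(fix))
  for (i in seq_len(nrow(fix))) {
    line_no <- n_header + i
    pos <- suppressWarnings(as.integer(fix[i, "POS"]))
    if (is.na(pos) || pos < 1) {
      abort(sprintf("malformed coordinate at line %d: %s", line_no, fix[i, "POS"]))
    }
    ref <- toupper(fix[i, "REF"])
    alts <- toupper(strsplit(fix[i, "ALT"], ",", fixed = TRUE)[[1]])
    if (!grepl("^[ACGT]+$", ref) || any(!grepl("^[ACGT]+$", alts))) {
      abort(sprintf("REF/ALT outside ACGT alphabet at line %d", line_no))
    }
    info <- fix[i, "INFO"]
    af <- suppressWarnings(as.numeric(info_value(info, "MAX_AF")))
    vtype <- vapply(alts, function(a) {
      if (nchar(a) == nchar(ref)) {
        if (nchar(a) == 1L) "SNV" else "MNV"
      } else if (nchar(a) > nchar(ref)) "insertion" else "deletion"
    }, character(1))
    depth <- vapply(vtype, function(vt) {
      key <- if (vt %in% c("SNV", "MNV")) "DP" else "DPI"
      raw <- format_value(i, key)
      if (is.na(raw)) raw <- info_value(info, key)
      suppressWarnings(as.integer(raw))
    }, integer(1))
    out[[i]] <- tibble::tibble(
      contig = unname(fix[i, "CHROM"]), pos = pos, ref = unname(ref),
      alt = unname(alts), filter = unname(fix[i, "FILTER"]),
      depth = unname(depth), max_pop_af = unname(af), vtype = unname(vtype)
    )
  }
  dplyr::bind_rows(out)
}
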