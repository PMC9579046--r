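#' Read a FASTA file into a named character vector
#'
#' Thin wrapper around [Biostrings::readBStringSet()] that enforces the
#' contracts the rest of the pipeline relies on: unique record identifiers,
#' non-empty sequences, and uppercase residues. Line wrapping is irrelevant.
#'
#' Identifiers are taken as the first whitespace-delimited token of each
#' header line.
#'
#' @param path Path to a FASTA file.
#' @return Named character vector, one uppercase sequence per record.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  set <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(set))
  seqs <- toupper(as.character(set))
  if (any(!nzchar(seqs))) {
    abort(paste0("empty record: ", paste(ids[!nzchar(seqs)], collapse = ", ")))
  }
  dup <- unique(ids[duplicated(ids)])
  if (length(dup) > 0) {
    abort(paste0("duplicate id ", paste(dup, collapse = ", ")))
  }
  setNames(seqs, ids)
}

#' Write paired normal/mutant context sequences as FASTA
#'
#' Writes two adjacent FASTA records per context pair, normal first, with the
#' header grammar `>{variant_id}|{gene}|{aa_change}|{normal|mutant}`. The
#' output round-trips through [read_fasta()].
#'
#' @param pairs Tibble of context pairs as built by [build_context_pair()]:
#'   columns `variant_id`, `gene_id`, `aa_change`, `normal_seq`, `mutant_seq`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_paired_fasta <- function(pairs, path) {
  check_columns(pairs, c("variant_id", "gene_id", "aa_change", "normal_seq", "mutant_seq"),
                "context pair table")
  if (nrow(pairs) == 0) {
    writeLines(character(0), path)
    return(invisible(path))
  }
  stem <- paste(pairs$variant_id, pairs$gene_id, pairs$aa_change, sep = "|")
  ids <- c(rbind(paste0(stem, "|normal"), paste0(stem, "|mutant")))
  if (anyDuplicated(ids)) {
    abort(paste0("id collision in FASTA output: ",
                 paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  }
  seqs <- c(rbind(pairs$normal_seq, pairs$mutant_seq))
  set <- Biostrings::BStringSet(setNames(seqs, ids))
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}
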