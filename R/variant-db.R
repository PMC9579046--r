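#' Filter somatic variants on caller status and read depth
#'
#' Retains variants marked `PASS` by the caller with mutation read coverage
#' of at least `min_depth` reads (the `DP` field for SNVs, `DPI` for indels,
#' as parsed by [read_strelka_vcf()]). Variants with absent depth are
#' rejected. Input order is preserved and the filter is idempotent.
#'
#' @param variants Variant tibble from [read_strelka_vcf()].
#' @param min_depth Minimum read depth (inclusive).
#' @return Filtered tibble; the dropped rows with a `reason` column
#'   (`non_pass`, `no_depth`, `low_depth`) are attached as the `"rejected"`
#'   attribute.
#' @export
filter_variants <- function(variants, min_depth = 10) {
  check_columns(variants, c("filter", "depth"), "variant table")
  reason <- dplyr::case_when(
    variants$filter != "PASS" ~ "non_pass",
    is.na(variants$depth) ~ "no_depth",
    variants$depth < min_depth ~ "low_depth",
    TRUE ~ NA_character_
  )
  kept <- variants[is.na(reason), , drop = FALSE]
  rejected <- variants[!is.na(reason), , drop = FALSE]
  rejected$reason <- reason[!is.na(reason)]
  attr(kept, "rejected") <- rejected
  kept
}

# 5'->3' genomic positions of the coding sequence of one transcript row.
cds_positions <- function(tx) {
  starts <- tx$exon_starts[[1]]
  ends <- tx$exon_ends[[1]]
  pos <- unlist(lapply(seq_along(starts), function(i) {
    lo <- max(starts[i], tx$cds_start)
    hi <- min(ends[i], tx$cds_end)
    if (lo > hi) integer(0) else seq.int(lo, hi)
  }))
  if (tx$strand == "-") rev(pos) else pos
}

COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A")

#' Spliced coding sequence of a transcript
#'
#' Concatenates the exonic bases between the CDS bounds in transcript
#' orientation (reverse-complemented for minus-strand transcripts).
#'
#' @param tx One-row transcript tibble (see [read_transcript_models()]).
#' @param contigs Named character vector of contig sequences.
#' @return Uppercase DNA string.
#' @export
cds_sequence <- function(tx, contigs) {
  contig <- contigs[[tx$contig]]
  if (is.null(contig)) abort(paste0("contig not found: ", tx$contig))
  pos <- cds_positions(tx)
  bases <- strsplit(toupper(contig), "")[[1]][pos]
  if (tx$strand == "-") bases <- COMPLEMENT[bases]
  paste(bases, collapse = "")
}

#' Translate a coding DNA sequence
#'
#' Standard-code translation; a trailing partial codon is truncated, stop
#' codons become `*`.
#'
#' @param dna Uppercase DNA string.
#' @return Amino-acid string.
#' @export
translate_dna <- function(dna) {
  n <- nchar(dna) - nchar(dna) %% 3
  if (n < 3) return("")
  codons <- substring(dna, seq(1, n, 3), seq(3, n, 3))
  aa <- Biostrings::GENETIC_CODE[codons]
  if (anyNA(aa)) abort("non-ACGT base in coding sequence")
  paste(aa, collapse = "")
}

# Translate to the mature protein: sequence up to the first stop.
protein_from_cds <- function(dna) {
  aa <- translate_dna(dna)
  sub("\\*.*$", "", aa)
}

#' Protein sequence of a transcript
#'
#' @inheritParams cds_sequence
#' @return Amino-acid string of the translated spliced CDS, truncated at the
#'   first stop codon.
#' @export
transcript_protein <- function(tx, contigs) {
  protein_from_cds(cds_sequence(tx, contigs))
}

#' Call the protein-level consequence of a somatic variant
#'
#' Stand-in for a full variant-effect predictor restricted to what the
#' downstream neoantigen-context stage needs. Transcripts with a gene
#' biotype other than `protein_coding`, or carrying the transcript biotype
#' `NMD_mediated_decay`, are called `non_coding` and excluded downstream.
#' SNVs/MNVs are mapped through splicing and strand to their codon; indels
#' are classified by length modulo 3. Frameshift and stop-lost translation
#' continues through the mutated CDS to its first new stop (downstream UTR
#' read-through is not modelled).
#'
#' @param variant One-row variant tibble (see [read_strelka_vcf()]).
#' @param tx One-row transcript tibble (see [read_transcript_models()]).
#' @param contigs Named character vector of contig sequences.
#' @return One-row tibble: `variant_id`, `transcript_id`, `gene_id`,
#'   `consequence`, `protein_pos`, `ref_aa`, `alt_aa`, `max_pop_af`, and the
#'   full `normal_protein`/`mutant_protein` sequences (empty for
#'   `non_coding`).
#' @export
call_consequence <- function(variant, tx, contigs) {
  starts <- tx$exon_starts[[1]]
  ends <- tx$exon_ends[[1]]
  pos <- variant$pos
  if (variant$contig != tx$contig || pos < min(starts) || pos > max(ends)) {
    abort("variant outside transcript")
  }
  contig <- toupper(contigs[[tx$contig]])
  observed <- substr(contig, pos, pos + nchar(variant$ref) - 1L)
  if (observed != variant$ref) {
    abort(sprintf("reference mismatch at %s:%d (VCF %s, contig %s)",
                  variant$contig, pos, variant$ref, observed))
  }
  variant_id <- sprintf("%s:%d%s>%s", variant$contig, pos, variant$ref, variant$alt)
  call <- function(consequence, protein_pos = NA_integer_, ref_aa = "",
                   alt_aa = "", normal = "", mutant = "") {
    tibble::tibble(
      variant_id = variant_id, transcript_id = tx$transcript_id,
      gene_id = tx$gene_id, consequence = consequence,
      protein_pos = protein_pos, ref_aa = ref_aa, alt_aa = alt_aa,
      max_pop_af = variant$max_pop_af %||% NA_real_,
      normal_protein = normal, mutant_protein = mutant
    )
  }

  if (tx$gene_biotype != "protein_coding" ||
      "NMD_mediated_decay" %in% tx$transcript_biotypes[[1]]) {
    return(call("non_coding"))
  }

  cds_pos <- cds_positions(tx)
  ref_len <- nchar(variant$ref)
  affected <- seq.int(pos, pos + ref_len - 1L)
  idx <- match(affected, cds_pos)
  if (all(is.na(idx))) {
    return(call("non_coding"))  # exonic UTR or intronic within the transcript
  }
  if (anyNA(idx)) {
    abort("variant partially overlaps the CDS; not supported")
  }

  cds <- cds_sequence(tx, contigs)
  ref_tx <- variant$ref
  alt_tx <- variant$alt
  if (tx$strand == "-") {
    revcomp <- function(s) paste(rev(COMPLEMENT[strsplit(s, "")[[1]]]), collapse = "")
    ref_tx <- revcomp(ref_tx)
    alt_tx <- revcomp(alt_tx)
    idx <- rev(idx)
  }
  stopifnot(substr(cds, idx[1], idx[1] + nchar(ref_tx) - 1L) == ref_tx)
  mutant_cds <- paste0(
    substr(cds, 1, idx[1] - 1L), alt_tx,
    substr(cds, idx[1] + nchar(ref_tx), nchar(cds))
  )

  normal_aa <- translate_dna(cds)
  mutant_aa <- translate_dna(mutant_cds)
  normal <- sub("\\*.*$", "", normal_aa)
  mutant <- sub("\\*.*$", "", mutant_aa)

  len_diff <- nchar(variant$alt) - nchar(variant$ref)
  first_codon <- (idx[1] - 1L) %/% 3L + 1L

  if (len_diff != 0) {
    if (len_diff %% 3 != 0) {
      cons <- "frameshift"
    } else {
      cons <- if (len_diff > 0) "inframe_insertion" else "inframe_deletion"
    }
    p <- first_diff_position(normal, mutant) %||% first_codon
    return(call(
      cons, protein_pos = p,
      ref_aa = substr(normal, p, p), alt_aa = substr(mutant, p, p),
      normal = normal, mutant = mutant
    ))
  }

  # Substitution (SNV or length-matched MNV)
  if (normal_aa == mutant_aa) {
    return(call("synonymous", protein_pos = first_codon,
                ref_aa = substr(normal, first_codon, first_codon),
                alt_aa = substr(normal, first_codon, first_codon),
                normal = normal, mutant = mutant))
  }
  p <- first_diff_position(normal_aa, mutant_aa)
  ref_res <- substr(normal_aa, p, p)
  alt_res <- substr(mutant_aa, p, p)
  cons <- if (alt_res == "*") "stop_gained"
          else if (ref_res == "*") "stop_lost"
          else "missense"
  call(cons, protein_pos = p, ref_aa = ref_res, alt_aa = alt_res,
       normal = normal, mutant = mutant)
}

first_diff_position <- function(a, b) {
  n <- min(nchar(a), nchar(b))
  if (n > 0) {
    av <- strsplit(a, "")[[1]][seq_len(n)]
    bv <- strsplit(b, "")[[1]][seq_len(n)]
    d <- which(av != bv)
    if (length(d) > 0) return(d[1])
  }
  if (nchar(a) != nchar(b)) n + 1L else NULL
}

#' Build the paired normal/mutant context window for a consequence call
#'
#' Extracts the short protein context around the altered residue: for
#' substitutions a window of `desired_len` (default 31, i.e. 15 residues of
#' flank either side) centred on the mutated position and truncated at the
#' protein ends without padding; for stop-gains the mutant context runs from
#' the left flank to the residue before the new stop (emitted only if at
#' least `min_mutant_len` mutant residues remain — the minimum MHC ligand
#' length); for frameshifts and stop-losses the mutant context runs from 15
#' residues before the first altered position to the new C terminus, with
#' the wild-type window taken at the same coordinates.
#'
#' @param call One-row consequence tibble from [call_consequence()].
#' @param protein_seq Wild-type protein (defaults to `call$normal_protein`).
#' @param mutant_protein_seq Mutant protein (defaults to
#'   `call$mutant_protein`).
#' @param desired_len Odd target window length.
#' @param min_mutant_len Minimum surviving mutant context length for
#'   truncating consequences.
#' @return One-row tibble (`variant_id`, `gene_id`, `aa_change`,
#'   `normal_seq`, `mutant_seq`, `desired_len`, `max_pop_af`), or a zero-row
#'   tibble when a truncating mutant context is shorter than
#'   `min_mutant_len`.
#' @export
build_context_pair <- function(call, protein_seq = NULL,
                               mutant_protein_seq = NULL, desired_len = 31,
                               min_mutant_len = 8) {
  if (desired_len %% 2 != 1) abort("desired_len must be odd")
  cons <- call$consequence
  if (cons %in% c("synonymous", "non_coding")) {
    abort("no peptide-level change")
  }
  normal <- protein_seq %||% call$normal_protein
  mutant <- mutant_protein_seq %||% call$mutant_protein
  p <- call$protein_pos
  flank <- (desired_len - 1L) %/% 2L
  start <- max(1L, p - flank)

  aa_change <- switch(
    cons,
    missense = ,
    inframe_insertion = ,
    inframe_deletion = paste0(call$ref_aa, p, call$alt_aa),
    stop_gained = paste0(call$ref_aa, p, "*"),
    stop_lost = paste0("*", p, call$alt_aa),
    frameshift = paste0(call$ref_aa, p, "fs"),
    abort(paste0("unknown consequence: ", cons))
  )
  empty <- tibble::tibble(
    variant_id = character(), gene_id = character(), aa_change = character(),
    normal_seq = character(), mutant_seq = character(),
    desired_len = integer(), max_pop_af = double()
  )

  if (cons %in% c("missense", "inframe_insertion", "inframe_deletion")) {
    normal_seq <- substr(normal, start, min(nchar(normal), p + flank))
    mutant_seq <- substr(mutant, start, min(nchar(mutant), p + flank))
  } else if (cons == "stop_gained") {
    mutant_seq <- substr(mutant, start, nchar(mutant))
    normal_seq <- substr(normal, start, min(nchar(normal), p + flank))
    if (nchar(mutant_seq) < min_mutant_len) return(empty)
  } else {  # frameshift, stop_lost
    mutant_seq <- substr(mutant, start, nchar(mutant))
    normal_seq <- substr(normal, start,
                         min(nchar(normal), start + nchar(mutant_seq) - 1L))
    if (nchar(mutant_seq) < min_mutant_len) return(empty)
  }
  if (identical(normal_seq, mutant_seq)) {
    abort("no peptide-level change within the context window")
  }
  tibble::tibble(
    variant_id = call$variant_id, gene_id = call$gene_id,
    aa_change = aa_change, normal_seq = normal_seq, mutant_seq = mutant_seq,
    desired_len = as.integer(desired_len),
    max_pop_af = call$max_pop_af %||% NA_real_
  )
}

#' Filter context pairs on population allele frequency
#'
#' Keeps pairs whose variant is absent from population surveys
#' (`max_pop_af` missing — the common case for somatic variants) or observed
#' at a highest population allele frequency strictly below `max_af`.
#'
#' @param pairs Context pair tibble.
#' @param max_af Exclusive upper bound on the population frequency.
#' @return Filtered tibble, order preserved.
#' @export
apply_af_filter <- function(pairs, max_af = 0.01) {
  check_columns(pairs, "max_pop_af", "context pair table")
  dplyr::filter(pairs, is.na(.data$max_pop_af) | .data$max_pop_af < max_af)
}

#' Build a paired normal/mutant context-sequence database from a VCF
#'
#' Composes the full proteogenomic stage: depth/PASS filtering, consequence
#' calling against transcript models, context-window construction,
#' population-frequency filtering and paired FASTA output. Each variant is
#' annotated against the first protein-coding transcript whose exons contain
#' it (in transcript-table order).
#'
#' @param variants Variant tibble from [read_strelka_vcf()], or a VCF path.
#' @param transcripts Transcript tibble from [read_transcript_models()].
#' @param contigs Named character vector of contig sequences, or FASTA path.
#' @param out_fasta Optional output path for the paired FASTA.
#' @param desired_len Context window length.
#' @param max_af Population allele-frequency cutoff (exclusive).
#' @param min_depth Read-depth cutoff (inclusive).
#' @return List with `pairs` (context pair tibble), `report` (counts per
#'   rejection reason; input = kept + sum of rejections), and `fasta` (the
#'   output path or `NULL`).
#' @export
build_context_database <- function(variants, transcripts, contigs,
                                   out_fasta = NULL, desired_len = 31,
                                   max_af = 0.01, min_depth = 10) {
  if (is.character(variants) && length(variants) == 1 &&
      file.exists(variants)) {
    variants <- read_strelka_vcf(variants)
  }
  if (is.character(contigs) && is.null(names(contigs))) {
    contigs <- read_fasta(contigs)
  }
  n_input <- nrow(variants)
  kept <- filter_variants(variants, min_depth = min_depth)
  rejected <- attr(kept, "rejected")
  counts <- c(
    non_pass = sum(rejected$reason == "non_pass"),
    no_depth = sum(rejected$reason == "no_depth"),
    low_depth = sum(rejected$reason == "low_depth"),
    no_transcript = 0L, non_coding = 0L, synonymous = 0L,
    too_short = 0L, af_filtered = 0L
  )

  pairs <- list()
  for (i in seq_len(nrow(kept))) {
    v <- kept[i, ]
    hit <- NULL
    for (j in seq_len(nrow(transcripts))) {
      tx <- transcripts[j, ]
      span_ok <- v$contig == tx$contig &&
        any(v$pos >= tx$exon_starts[[1]] & v$pos <= tx$exon_ends[[1]])
      if (span_ok) { hit <- tx; break }
    }
    if (is.null(hit)) {
      counts["no_transcript"] <- counts["no_transcript"] + 1L
      next
    }
    call <- call_consequence(v, hit, contigs)
    if (call$consequence == "non_coding") {
      counts["non_coding"] <- counts["non_coding"] + 1L
      next
    }
    if (call$consequence == "synonymous") {
      counts["synonymous"] <- counts["synonymous"] + 1L
      next
    }
    pair <- build_context_pair(call, desired_len = desired_len)
    if (nrow(pair) == 0) {
      counts["too_short"] <- counts["too_short"] + 1L
      next
    }
    pairs[[length(pairs) + 1L]] <- pair
  }
  pairs <- dplyr::bind_rows(pairs)
  if (nrow(pairs) > 0) {
    filtered <- apply_af_filter(pairs, max_af = max_af)
    counts["af_filtered"] <- nrow(pairs) - nrow(filtered)
    pairs <- filtered
  } else {
    pairs <- tibble::tibble(
      variant_id = character(), gene_id = character(), aa_change = character(),
      normal_seq = character(), mutant_seq = character(),
      desired_len = integer(), max_pop_af = double()
    )
  }
  if (!is.null(out_fasta)) write_paired_fasta(pairs, out_fasta)
  report <- tibble::tibble(
    reason = c("input", names(counts), "kept"),
    count = c(n_input, unname(counts), nrow(pairs))
  )
  list(pairs = pairs, report = report, fasta = out_fasta)
}

#' Locate a wild-type/mutant peptide pair within a protein
#'
#' Finds the wild-type peptide in a protein sequence and maps the
#' substitution to protein coordinates — e.g. locating KYLSVQGQL in a
#' carrier-protein sequence and diffing against KYLSVQSQL recovers the
#' position of the underlying G>S substitution.
#'
#' @param protein_seq Protein sequence to search.
#' @param wt_peptide Wild-type peptide contained in `protein_seq`.
#' @param mut_peptide Mutant peptide of the same length.
#' @return One-row tibble: `peptide_start`, `peptide_pos` (1-based within
#'   the peptide), `protein_pos`, `ref_aa`, `alt_aa`, `aa_change`.
#' @export
locate_peptide_variant <- function(protein_seq, wt_peptide, mut_peptide) {
  if (nchar(wt_peptide) != nchar(mut_peptide)) {
    abort("peptides must have equal length")
  }
  start <- as.integer(regexpr(wt_peptide, protein_seq, fixed = TRUE))
  if (start < 1) abort("wild-type peptide not found in protein")
  d <- first_diff_position(wt_peptide, mut_peptide)
  if (is.null(d)) abort("peptides are identical")
  tibble::tibble(
    peptide_start = start,
    peptide_pos = d,
    protein_pos = start + d - 1L,
    ref_aa = substr(wt_peptide, d, d),
    alt_aa = substr(mut_peptide, d, d),
    aa_change = paste0(substr(wt_peptide, d, d), start + d - 1L,
                       substr(mut_peptide, d, d))
  )
}
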