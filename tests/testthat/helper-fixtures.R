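# Independent brute-force codon table for translation oracles (kept separate
# from the package's translation path).
ORACLE_CODONS <- local({
  bases <- c("T", "C", "A", "G")
  aas <- strsplit(paste0(
    "FFLLSSSSYY**CC*W", "LLLLPPPPHHQQRRRR",
    "IIIMTTTTNNKKSSRR", "VVVVAAAADDEEGGGG"
  ), "")[[1]]
  codons <- as.vector(t(outer(
    as.vector(t(outer(bases, bases, paste0))), bases, paste0
  )))
  stats::setNames(aas, codons)
})

oracle_translate <- function(dna) {
  n <- nchar(dna) - nchar(dna) %% 3
  if (n < 3) return("")
  aa <- ORACLE_CODONS[substring(dna, seq(1, n, 3), seq(3, n, 3))]
  sub("\\*.*$", "", paste(aa, collapse = ""))
}

# One-exon plus-strand transcript around a supplied CDS, with UTRs.
make_transcript <- function(cds, utr5 = "AAAAA", utr3 = "TTTTT",
                            id = "tx1", gene = "gene1",
                            gene_biotype = "protein_coding",
                            tx_biotypes = "protein_coding") {
  genomic <- paste0(utr5, cds, utr3)
  list(
    tx = tibble::tibble(
      transcript_id = id, gene_id = gene, contig = "ctg1", strand = "+",
      exon_starts = list(1L), exon_ends = list(nchar(genomic)),
      cds_start = nchar(utr5) + 1L, cds_end = nchar(utr5) + nchar(cds),
      gene_biotype = gene_biotype, transcript_biotypes = list(tx_biotypes)
    ),
    contigs = c(ctg1 = genomic)
  )
}

# Back-translate a protein with the first codon of each amino acid (oracle
# side; deterministic).
simple_cds <- function(protein) {
  inv <- split(names(ORACLE_CODONS), unname(ORACLE_CODONS))
  paste0(paste(vapply(strsplit(protein, "")[[1]],
                      function(a) inv[[a]][1], ""), collapse = ""), "TAA")
}

variant_row <- function(contig, pos, ref, alt, filter = "PASS", depth = 15L,
                        max_pop_af = NA_real_) {
  vtype <- if (nchar(ref) == nchar(alt)) {
    if (nchar(ref) == 1) "SNV" else "MNV"
  } else if (nchar(alt) > nchar(ref)) "insertion" else "deletion"
  tibble::tibble(contig = contig, pos = pos, ref = ref, alt = alt,
                 filter = filter, depth = depth, max_pop_af = max_pop_af,
                 vtype = vtype)
}
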