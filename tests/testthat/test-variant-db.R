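test_that("PASS/depth filter applies the >= 10 read boundary", {
  v <- dplyr::bind_rows(
    variant_row("c", 1L, "A", "G", depth = 9L),
    variant_row("c", 2L, "A", "G", depth = 10L),
    variant_row("c", 3L, "A", "G", filter = "LowEVS", depth = 50L),
    variant_row("c", 4L, "A", "G", depth = NA_integer_)
  )
  kept <- filter_variants(v)
  expect_equal(kept$pos, 2L)
  expect_equal(sort(attr(kept, "rejected")$reason),
               c("low_depth", "no_depth", "non_pass"))
  # idempotent and order-stable
  again <- filter_variants(kept)
  expect_equal(again$pos, kept$pos)
})

test_that("SNV consequences are called through the codon table", {
  # protein M G K L ... with a GGC codon for G at position 2
  cds <- paste0("ATG", "GGC", "AAA", "CTG", "TAA")
  fx <- make_transcript(cds)
  # GGC -> AGC is G>S at protein position 2 (genomic pos of G codon start = 9)
  v <- variant_row("ctg1", 9L, "G", "A")
  call <- call_consequence(v, fx$tx, fx$contigs)
  expect_equal(call$consequence, "missense")
  expect_equal(call$ref_aa, "G")
  expect_equal(call$alt_aa, "S")
  expect_equal(call$protein_pos, 2L)
  expect_equal(call$mutant_protein, "MSKL")

  # third-position wobble: GGC -> GGT stays G
  v2 <- variant_row("ctg1", 11L, "C", "T")
  expect_equal(call_consequence(v2, fx$tx, fx$contigs)$consequence,
               "synonymous")

  # AAA -> TAA gives a stop at protein position 3
  v3 <- variant_row("ctg1", 12L, "A", "T")
  call3 <- call_consequence(v3, fx$tx, fx$contigs)
  expect_equal(call3$consequence, "stop_gained")
  expect_equal(call3$mutant_protein, "MG")

  # 2-bp anchored deletion is a frameshift (2 mod 3 != 0)
  v4 <- variant_row("ctg1", 9L, "GGC", "G")
  expect_equal(call_consequence(v4, fx$tx, fx$contigs)$consequence,
               "frameshift")
})

test_that("biotype exclusions and error contracts are honoured", {
  cds <- paste0("ATG", "GGC", "AAA", "TAA")
  nc <- make_transcript(cds, gene_biotype = "lncRNA")
  v <- variant_row("ctg1", 9L, "G", "A")
  expect_equal(call_consequence(v, nc$tx, nc$contigs)$consequence,
               "non_coding")
  nmd <- make_transcript(cds, tx_biotypes = c("protein_coding",
                                              "NMD_mediated_decay"))
  expect_equal(call_consequence(v, nmd$tx, nmd$contigs)$consequence,
               "non_coding")
  fx <- make_transcript(cds)
  # UTR positions are exonic but non-coding
  expect_equal(call_consequence(variant_row("ctg1", 2L, "A", "G"),
                                fx$tx, fx$contigs)$consequence, "non_coding")
  expect_error(call_consequence(variant_row("ctg1", 999L, "A", "G"),
                                fx$tx, fx$contigs), "outside transcript")
  expect_error(call_consequence(variant_row("ctg1", 9L, "T", "A"),
                                fx$tx, fx$contigs), "reference mismatch")
})

test_that("pipeline translation matches a brute-force codon oracle", {
  cfg <- sim_config(seed = 11, n_transcripts = 10)
  tx <- simulate_transcriptome(cfg)
  for (id in names(tx$proteome)) {
    row <- tx$transcripts[tx$transcripts$transcript_id == id, ]
    spliced <- cds_sequence(row, tx$contigs)
    expect_equal(transcript_protein(row, tx$contigs),
                 oracle_translate(spliced))
    expect_equal(tx$proteome[[id]], oracle_translate(spliced))
  }
})

test_that("substitution context windows centre the variant at position 16", {
  protein <- paste(rep("A", 400), collapse = "")
  mutant <- protein
  substr(mutant, 367, 367) <- "S"
  substr(protein, 367, 367) <- "G"
  call <- tibble::tibble(
    variant_id = "v1", transcript_id = "tx1", gene_id = "g1",
    consequence = "missense", protein_pos = 367L, ref_aa = "G", alt_aa = "S",
    max_pop_af = NA_real_, normal_protein = protein, mutant_protein = mutant
  )
  pair <- build_context_pair(call)
  expect_equal(nchar(pair$normal_seq), 31L)
  expect_equal(nchar(pair$mutant_seq), 31L)
  expect_equal(substr(pair$normal_seq, 16, 16), "G")
  expect_equal(substr(pair$mutant_seq, 16, 16), "S")
  expect_equal(pair$aa_change, "G367S")
  # Hamming distance exactly 1 for substitutions
  expect_equal(sum(strsplit(pair$normal_seq, "")[[1]] !=
                     strsplit(pair$mutant_seq, "")[[1]]), 1L)
})

test_that("context windows truncate at protein ends without padding", {
  protein <- "MAWDEFGHIKLMNPQRSTVW"
  mutant <- protein
  substr(mutant, 3, 3) <- "V"
  call <- tibble::tibble(
    variant_id = "v1", transcript_id = "tx1", gene_id = "g1",
    consequence = "missense", protein_pos = 3L, ref_aa = "W", alt_aa = "V",
    max_pop_af = NA_real_, normal_protein = protein, mutant_protein = mutant
  )
  pair <- build_context_pair(call)
  expect_equal(nchar(pair$normal_seq), 18L)  # 2 left flank + site + 15 right
  expect_equal(substr(pair$normal_seq, 3, 3), "W")
})

test_that("G>S mutant context contains the expected neoantigen 9-mer", {
  base <- paste(rep("L", 360), collapse = "")
  normal <- paste0(base, "KYLSVQGQLAAAAAAAAAAAAAAAAAAAAAA")
  mutant <- sub("KYLSVQGQL", "KYLSVQSQL", normal)
  call <- tibble::tibble(
    variant_id = "v1", transcript_id = "tx1", gene_id = "Mtch1",
    consequence = "missense", protein_pos = 367L, ref_aa = "G", alt_aa = "S",
    max_pop_af = NA_real_, normal_protein = normal, mutant_protein = mutant
  )
  pair <- build_context_pair(call)
  expect_match(pair$normal_seq, "KYLSVQGQL")
  expect_match(pair$mutant_seq, "KYLSVQSQL")
})

test_that("synonymous and non-coding calls cannot form context pairs", {
  call <- tibble::tibble(
    variant_id = "v", transcript_id = "t", gene_id = "g",
    consequence = "synonymous", protein_pos = 5L, ref_aa = "G", alt_aa = "G",
    max_pop_af = NA_real_, normal_protein = "MGGGGGGGG",
    mutant_protein = "MGGGGGGGG"
  )
  expect_error(build_context_pair(call), "no peptide-level change")
})

test_that("population AF filter is strict and keeps novel variants", {
  pairs <- tibble::tibble(
    variant_id = c("a", "b", "c"), gene_id = "g", aa_change = "G1S",
    normal_seq = "G", mutant_seq = "S", desired_len = 31L,
    max_pop_af = c(0.05, NA, 0.01)
  )
  kept <- apply_af_filter(pairs)
  expect_equal(kept$variant_id, "b")
  expect_equal(apply_af_filter(kept)$variant_id, "b")  # idempotent
})

test_that("database build conserves counts and writes paired records", {
  cfg <- sim_config(seed = 23)
  tx <- simulate_transcriptome(cfg)
  vcf <- withr::local_tempfile(fileext = ".vcf")
  sim <- simulate_variants(cfg, tx, vcf)
  fa <- withr::local_tempfile(fileext = ".fasta")
  db <- build_context_database(vcf, tx$transcripts, tx$contigs, out_fasta = fa)

  rep <- setNames(db$report$count, db$report$reason)
  expect_equal(rep[["input"]],
               rep[["kept"]] + sum(rep[setdiff(names(rep), c("input", "kept"))]))
  expect_equal(length(read_fasta(fa)), 2 * nrow(db$pairs))

  # every surviving variant matches the simulation truth expectation
  truth <- sim$truth
  expected <- truth$variant_id[truth$expect_in_db]
  expect_true(all(db$pairs$variant_id %in% expected))
  # the only admissible losses are truncating consequences whose mutant
  # context fell below the minimum ligand length
  missing <- setdiff(expected, db$pairs$variant_id)
  expect_true(all(truth$class[truth$variant_id %in% missing] %in%
                    c("stop_gained", "frameshift")))
  expect_lte(length(missing), rep[["too_short"]])
})

test_that("all-non-PASS input yields an empty database with explanation", {
  cfg <- sim_config(seed = 31, frac_non_pass = 1)
  tx <- simulate_transcriptome(cfg)
  vcf <- withr::local_tempfile(fileext = ".vcf")
  simulate_variants(cfg, tx, vcf)
  db <- build_context_database(vcf, tx$transcripts, tx$contigs)
  expect_equal(nrow(db$pairs), 0)
  rep <- setNames(db$report$count, db$report$reason)
  expect_equal(rep[["non_pass"]], rep[["input"]])
})

test_that("peptide variant location recovers the protein position", {
  prot <- synthetic_mtch1_protein()
  hit <- locate_peptide_variant(prot, "KYLSVQGQL", "KYLSVQSQL")
  expect_equal(hit$protein_pos, 367L)
  expect_equal(hit$aa_change, "G367S")
  expect_equal(hit$peptide_pos, 7L)
})
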