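#' Simulation configuration
#'
#' Collects every tunable of the synthetic-data generators with defaults
#' that emulate the study conditions the analyses assume: triplicate
#' biological replicates, immunopeptidome time points at 24 and 48 h with
#' the global post-irradiation intensity boosts, proteome time
#' points at 0/24/48/72 h, 8-12-mer peptides with a 9-mer mode and H-2
#' anchor motifs, abundance-dependent missingness, reversed-sequence
#' decoys, and the seven-point PRM calibration series (0, 5, 10, 25, 50,
#' 100, 150 fmol of light peptide against 100 fmol of heavy standard).
#'
#' One global seed drives every generator through named substreams, so each
#' stage is reproducible when re-run independently.
#'
#' @param seed Integer master seed.
#' @param ... Overrides for any default listed in the function body.
#' @return A `sim_config` list.
#' @export
sim_config <- function(seed = 1, ...) {
  cfg <- list(
    seed = as.integer(seed),
    # transcriptome
    n_transcripts = 12,
    protein_len_range = c(80, 250),
    frac_noncoding = 0.15,
    frac_nmd = 0.1,
    # variants
    n_missense = 6, n_synonymous = 3, n_stop_gained = 2, n_frameshift = 2,
    dp_range = c(5, 20),
    frac_non_pass = 0.2,
    frac_with_af = 0.3,
    af_values = c(0.001, 0.005, 0.02, 0.05),
    # immunopeptidome
    ipp_timepoints = c(24L, 48L),
    n_replicates = 3,
    n_pool_samples = 3,
    n_universe = 250,
    n_radiation_only = 25,
    detect_rate = 0.8,
    length_probs = c(`8` = 0.15, `9` = 0.5, `10` = 0.15, `11` = 0.12,
                     `12` = 0.08),
    allele_motifs = h2_motifs(),
    anchor_rate = 0.8,
    intensity_meanlog = log(1e6),
    intensity_sdlog = 1,
    # global post-irradiation intensity fold changes (24 h, 48 h)
    boost = c(`24` = 1.49, `48` = 3.17),
    decoy_fraction = 0.5,
    false_target_fraction = 0.1,
    target_score = c(mean = 10, sd = 1),
    null_score = c(mean = 5, sd = 1),
    ptm_rate = 0.1,
    ptm_names = c("Oxidation", "Deamidation", "Phospho"),
    ptm_position7_boost = 0,
    rank_n_ref = 2e4,
    # proteome quant
    n_proteins = 400,
    prot_timepoints = c(0L, 24L, 48L, 72L),
    base_log2_mean = 20, base_log2_sd = 2,
    noise_sd = 0.3,
    n_de = 40,
    de_log2fc_range = c(1, 3),
    missing_midpoint = 16.5, missing_scale = 0.8,
    # PRM
    calibration_amounts = c(0, 5, 10, 25, 50, 100, 150),
    heavy_spike_fmol = 100,
    prm_noise = 0.05,
    # endogenous amounts consistent with ~100 and ~200 copies/cell at 3e8 cells
    endogenous_fmol = c(control = 51.3, irradiated = 99.6),
    n_cells = 3e8
  )
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown) > 0) {
    abort(paste0("unknown sim_config parameter: ", paste(unknown, collapse = ", ")))
  }
  cfg[names(dots)] <- dots
  structure(cfg, class = "sim_config")
}

# Deterministic per-generator substream seed below 2^31.
substream_seed <- function(cfg, name) {
  h <- sum(utf8ToInt(name) * seq_along(utf8ToInt(name)))
  (cfg$seed * 10007L + h * 97L) %% 2147483647L
}

CODON_TABLE <- local({
  gc <- Biostrings::GENETIC_CODE
  split(names(gc), unname(gc))
})

back_translate <- function(aa) {
  codons <- vapply(strsplit(aa, "")[[1]], function(a) {
    opts <- CODON_TABLE[[a]]
    opts[sample.int(length(opts), 1)]
  }, "")
  paste(codons, collapse = "")
}

random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                                collapse = "")
revcomp <- function(s) paste(rev(COMPLEMENT[strsplit(s, "")[[1]]]), collapse = "")

#' Simulate a small transcriptome with known translations
#'
#' Generates one contig per transcript: a coding sequence back-translated
#' from a random protein (guaranteeing translation without internal stops),
#' flanked by UTRs, split into 1-3 exons with random introns, and placed on
#' a random strand (minus-strand transcripts store the reverse-complemented
#' contig with genomically ordered exon coordinates). Configured fractions
#' of transcripts carry a non-protein-coding gene biotype or the
#' `NMD_mediated_decay` transcript biotype.
#'
#' @param cfg A [sim_config()].
#' @return List: `contigs` (named DNA vector), `transcripts` (tibble in
#'   [read_transcript_models()] layout), `proteome` (named protein vector,
#'   coding transcripts only).
#' @export
simulate_transcriptome <- function(cfg = sim_config()) {
  withr::with_seed(substream_seed(cfg, "transcriptome"), {
    n <- cfg$n_transcripts
    contigs <- character(0)
    rows <- list()
    proteome <- character(0)
    aa_pool <- setdiff(AA_ALPHABET, "M")
    for (i in seq_len(n)) {
      len <- sample(seq(cfg$protein_len_range[1], cfg$protein_len_range[2]), 1)
      protein <- paste0("M", paste(sample(aa_pool, len - 1, replace = TRUE),
                                   collapse = ""))
      cds <- paste0(back_translate(protein),
                    sample(c("TAA", "TAG", "TGA"), 1))
      utr5 <- random_dna(sample(20:40, 1))
      utr3 <- random_dna(sample(20:40, 1))
      exonic <- paste0(utr5, cds, utr3)
      n_exons <- sample(1:3, 1)
      cuts <- sort(sample(seq_len(nchar(exonic) - 1), n_exons - 1))
      bounds <- cbind(c(1, cuts + 1), c(cuts, nchar(exonic)))
      # lay exons down with random introns; track genomic sense coordinates
      genomic <- ""
      exon_starts <- exon_ends <- integer(n_exons)
      offset_of <- integer(nchar(exonic))  # exonic index -> genomic index
      for (e in seq_len(n_exons)) {
        if (e > 1) genomic <- paste0(genomic, random_dna(sample(20:50, 1)))
        exon_starts[e] <- nchar(genomic) + 1L
        piece <- substr(exonic, bounds[e, 1], bounds[e, 2])
        offset_of[bounds[e, 1]:bounds[e, 2]] <-
          seq.int(nchar(genomic) + 1L, nchar(genomic) + nchar(piece))
        genomic <- paste0(genomic, piece)
        exon_ends[e] <- nchar(genomic)
      }
      cds_start <- offset_of[nchar(utr5) + 1L]
      cds_end <- offset_of[nchar(utr5) + nchar(cds)]
      strand <- sample(c("+", "-"), 1)
      if (strand == "-") {
        L <- nchar(genomic)
        genomic <- revcomp(genomic)
        new_starts <- L - exon_ends + 1L
        new_ends <- L - exon_starts + 1L
        ord <- order(new_starts)
        exon_starts <- new_starts[ord]
        exon_ends <- new_ends[ord]
        tmp <- cds_start
        cds_start <- L - cds_end + 1L
        cds_end <- L - tmp + 1L
      }
      gene_biotype <- "protein_coding"
      tx_biotypes <- "protein_coding"
      u <- runif(1)
      if (u < cfg$frac_noncoding) {
        gene_biotype <- "lncRNA"
      } else if (u < cfg$frac_noncoding + cfg$frac_nmd) {
        tx_biotypes <- c("protein_coding", "NMD_mediated_decay")
      }
      contigs[paste0("ctg", i)] <- genomic
      rows[[i]] <- tibble::tibble(
        transcript_id = paste0("tx", i), gene_id = paste0("gene", i),
        contig = paste0("ctg", i), strand = strand,
        exon_starts = list(exon_starts), exon_ends = list(exon_ends),
        cds_start = cds_start, cds_end = cds_end,
        gene_biotype = gene_biotype, transcript_biotypes = list(tx_biotypes)
      )
      if (gene_biotype == "protein_coding" &&
          !"NMD_mediated_decay" %in% tx_biotypes) {
        proteome[paste0("tx", i)] <- protein
      }
    }
    list(contigs = contigs, transcripts = dplyr::bind_rows(rows),
         proteome = proteome)
  })
}

# Search a transcript CDS for an SNV of the requested consequence class.
find_snv <- function(cds, class) {
  n_codons <- nchar(cds) %/% 3
  for (k in sample(2:(n_codons - 2))) {
    codon <- substr(cds, 3 * k - 2, 3 * k)
    ref_aa <- Biostrings::GENETIC_CODE[codon]
    if (ref_aa == "*") next
    for (off in sample(0:2)) {
      ref_base <- substr(codon, off + 1, off + 1)
      for (alt_base in sample(setdiff(c("A", "C", "G", "T"), ref_base))) {
        alt_codon <- codon
        substr(alt_codon, off + 1, off + 1) <- alt_base
        alt_aa <- Biostrings::GENETIC_CODE[alt_codon]
        hit <- switch(class,
          missense = alt_aa != ref_aa && alt_aa != "*",
          synonymous = alt_aa == ref_aa,
          stop_gained = alt_aa == "*"
        )
        if (hit) {
          return(list(cds_index = 3L * (k - 1L) + off + 1L, codon = k,
                      ref_base = ref_base, alt_base = alt_base,
                      ref_aa = unname(ref_aa), alt_aa = unname(alt_aa)))
        }
      }
    }
  }
  NULL
}

#' Simulate a Strelka-style somatic VCF with a known truth table
#'
#' Injects SNVs of known consequence (missense, synonymous, stop-gained)
#' and anchored frameshift deletions into the coding transcripts of a
#' simulated transcriptome, with read depths drawn uniformly across the
#' depth filter boundary, a configured fraction of non-PASS records, and a
#' configured fraction carrying population allele frequencies on both sides
#' of the 1% cutoff. SNV depth is written as FORMAT `DP`, indel depth as
#' FORMAT `DPI`.
#'
#' @param cfg A [sim_config()].
#' @param transcriptome Output of [simulate_transcriptome()].
#' @param path Path the VCF text is written to.
#' @return Invisibly, a list with `vcf` (the path) and `truth`: one row per
#'   variant with the injected class, amino-acid change, depth, filter,
#'   population frequency and the expected fate under the PASS/depth/AF
#'   filters.
#' @export
simulate_variants <- function(cfg, transcriptome, path) {
  withr::with_seed(substream_seed(cfg, "variants"), {
    txs <- transcriptome$transcripts
    coding <- dplyr::filter(
      txs, .data$gene_biotype == "protein_coding",
      !vapply(.data$transcript_biotypes, function(b) "NMD_mediated_decay" %in% b, TRUE)
    )
    plus_coding <- dplyr::filter(coding, .data$strand == "+")
    classes <- c(rep("missense", cfg$n_missense),
                 rep("synonymous", cfg$n_synonymous),
                 rep("stop_gained", cfg$n_stop_gained),
                 rep("frameshift", cfg$n_frameshift))
    rows <- list()
    for (class in classes) {
      pool <- if (class == "frameshift") plus_coding else coding
      tx <- pool[sample.int(nrow(pool), 1), ]
      cds <- cds_sequence(tx, transcriptome$contigs)
      cds_pos <- cds_positions(tx)
      contig_seq <- transcriptome$contigs[[tx$contig]]
      if (class == "frameshift") {
        # anchored deletion of 1-2 bases, wholly inside one exon of the CDS
        repeat {
          d <- sample(1:2, 1)
          i <- sample(seq(5, length(cds_pos) - d - 5), 1)
          span <- cds_pos[(i - 1):(i + d - 1)]
          if (all(diff(span) == 1)) break
        }
        g <- cds_pos[i - 1]
        ref <- substr(contig_seq, g, g + d)
        alt <- substr(contig_seq, g, g)
        protein_pos <- (i - 1L) %/% 3L + 1L
        ref_aa <- alt_aa <- ""
        pos <- g
      } else {
        hit <- find_snv(cds, class)
        g <- cds_pos[hit$cds_index]
        ref <- substr(contig_seq, g, g)
        alt <- if (tx$strand == "-") unname(COMPLEMENT[hit$alt_base]) else hit$alt_base
        stopifnot(ref == (if (tx$strand == "-") unname(COMPLEMENT[hit$ref_base]) else hit$ref_base))
        protein_pos <- hit$codon
        ref_aa <- hit$ref_aa
        alt_aa <- if (class == "stop_gained") "*" else hit$alt_aa
        pos <- g
      }
      dp <- sample(seq(cfg$dp_range[1], cfg$dp_range[2]), 1)
      filter <- if (runif(1) < cfg$frac_non_pass) "LowEVS" else "PASS"
      af <- if (runif(1) < cfg$frac_with_af) sample(cfg$af_values, 1) else NA_real_
      rows[[length(rows) + 1]] <- tibble::tibble(
        contig = tx$contig, pos = pos, ref = ref, alt = alt,
        transcript_id = tx$transcript_id, class = class,
        protein_pos = protein_pos, ref_aa = ref_aa, alt_aa = alt_aa,
        depth = dp, filter = filter, max_pop_af = af,
        is_indel = class == "frameshift"
      )
    }
    truth <- dplyr::bind_rows(rows)
    truth <- dplyr::arrange(truth, .data$contig, .data$pos)
    truth$variant_id <- sprintf("%s:%d%s>%s", truth$contig, truth$pos,
                                truth$ref, truth$alt)
    truth$pass_filters <- truth$filter == "PASS" & truth$depth >= 10
    truth$af_ok <- is.na(truth$max_pop_af) | truth$max_pop_af < 0.01
    truth$expect_in_db <- truth$pass_filters & truth$af_ok &
      truth$class != "synonymous"

    header <- c(
      "##fileformat=VCFv4.2",
      "##source=radpep-simulate",
      "##INFO=<ID=MAX_AF,Number=1,Type=Float,Description=\"Highest population allele frequency\">",
      "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
      "##FORMAT=<ID=DPI,Number=1,Type=Integer,Description=\"Read depth for indels\">",
      "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tTUMOR"
    )
    body <- vapply(seq_len(nrow(truth)), function(i) {
      r <- truth[i, ]
      info <- if (is.na(r$max_pop_af)) "." else sprintf("MAX_AF=%g", r$max_pop_af)
      fmt <- if (r$is_indel) "DPI" else "DP"
      paste(r$contig, r$pos, ".", r$ref, r$alt, ".", r$filter, info, fmt,
            r$depth, sep = "\t")
    }, "")
    writeLines(c(header, body), path)
    invisible(list(vcf = path, truth = truth))
  })
}

sample_peptide <- function(proteome, length_probs) {
  repeat {
    prot <- sample(names(proteome), 1)
    len <- as.integer(sample(names(length_probs), 1, prob = length_probs))
    if (nchar(proteome[[prot]]) < len + 2) next
    start <- sample.int(nchar(proteome[[prot]]) - len + 1, 1)
    return(list(sequence = substr(proteome[[prot]], start, start + len - 1),
                protein = prot))
  }
}

impose_anchor <- function(sequence, motif) {
  for (pos_name in names(motif$anchors)) {
    pos <- if (pos_name == "C") nchar(sequence) else as.integer(pos_name)
    preferred <- motif$anchors[[pos_name]]
    substr(sequence, pos, pos) <- sample(preferred, 1)
  }
  sequence
}

reverse_decoy <- function(sequence) {
  n <- nchar(sequence)
  paste0(paste(rev(strsplit(substr(sequence, 1, n - 1), "")[[1]]),
               collapse = ""), substr(sequence, n, n))
}

#' Simulate an identified immunopeptidome table
#'
#' Draws a peptide universe from proteome substrings (8-12-mers, 9-mer
#' mode) with allele anchor residues imposed at the configured rate, then
#' builds per-sample records for triplicate control and irradiated samples
#' at 24/48 h: log-normal intensities with the configured global
#' irradiation boosts, a set of injected radiation-only peptides absent
#' from every control (including the expanded control pool), target search
#' scores with a configured fraction of false targets drawn from the null
#' score distribution, reversed-sequence decoy records (terminal residue
#' kept), random PTM annotations (optionally position-7-biased in
#' irradiated 9-mers), and mock percent ranks from [rank_peptides()].
#'
#' @param cfg A [sim_config()].
#' @param proteome Named protein vector, e.g. from
#'   [simulate_transcriptome()].
#' @return List: `records` (peptide tibble with `replicate` column),
#'   `pool_records` (expanded control pool samples), and `truth`
#'   (radiation-only sequences, false-target sequences, boosts, universe).
#' @export
simulate_immunopeptidome <- function(cfg, proteome) {
  withr::with_seed(substream_seed(cfg, "immunopeptidome"), {
    alleles <- names(cfg$allele_motifs)
    draw_universe <- function(n, existing = character(0)) {
      out <- character(0)
      prot <- character(0)
      while (length(out) < n) {
        p <- sample_peptide(proteome, cfg$length_probs)
        s <- p$sequence
        if (runif(1) < cfg$anchor_rate) {
          s <- impose_anchor(s, cfg$allele_motifs[[sample(alleles, 1)]])
        }
        if (s %in% c(out, existing)) next
        out <- c(out, s)
        prot <- c(prot, p$protein)
      }
      tibble::tibble(sequence = out, source_proteins = prot)
    }
    universe <- draw_universe(cfg$n_universe)
    rad_only <- draw_universe(cfg$n_radiation_only, existing = universe$sequence)
    false_targets <- sample(universe$sequence,
                            round(cfg$false_target_fraction * nrow(universe)))

    mk_sample <- function(sample_id, condition, timepoint, pool,
                          replicate = NA_integer_) {
      present <- universe[runif(nrow(universe)) < cfg$detect_rate, ]
      if (condition == "irradiated" && !pool) {
        present <- dplyr::bind_rows(
          present,
          rad_only[runif(nrow(rad_only)) < cfg$detect_rate, ]
        )
      }
      boost <- if (condition == "irradiated")
        cfg$boost[[as.character(timepoint)]] else 1
      n <- nrow(present)
      score <- rnorm(n, cfg$target_score[["mean"]], cfg$target_score[["sd"]])
      false <- present$sequence %in% false_targets
      score[false] <- rnorm(sum(false), cfg$null_score[["mean"]],
                            cfg$null_score[["sd"]])
      mods <- character(n)
      has_mod <- runif(n) < cfg$ptm_rate
      for (i in which(has_mod)) {
        len <- nchar(present$sequence[i])
        probs <- rep(1, len)
        if (condition == "irradiated" && len == 9) {
          probs[7] <- 1 + cfg$ptm_position7_boost
        }
        pos <- sample.int(len, 1, prob = probs)
        mods[i] <- paste0(sample(cfg$ptm_names, 1), "@", pos)
      }
      tibble::tibble(
        sequence = present$sequence,
        sample_id = sample_id, condition = condition,
        timepoint_h = as.integer(timepoint), replicate = replicate,
        intensity = rlnorm(n, cfg$intensity_meanlog + log(boost),
                           cfg$intensity_sdlog),
        modifications = mods,
        source_proteins = present$source_proteins,
        is_decoy = FALSE,
        search_score = score
      )
    }

    records <- list()
    for (tp in cfg$ipp_timepoints) {
      for (cond in .conditions) {
        for (r in seq_len(cfg$n_replicates)) {
          id <- sprintf("%s_%dh_r%d",
                        if (cond == "control") "ctrl" else "ir", tp, r)
          records[[id]] <- mk_sample(id, cond, tp, pool = FALSE, replicate = r)
        }
      }
    }
    records <- dplyr::bind_rows(records)

    pool_records <- dplyr::bind_rows(lapply(seq_len(cfg$n_pool_samples),
      function(r) {
        mk_sample(sprintf("pool_r%d", r), "control", cfg$ipp_timepoints[1],
                  pool = TRUE, replicate = r)
      }))

    # decoys: reversed target sequences at the configured fraction
    n_decoys <- round(cfg$decoy_fraction * nrow(records))
    decoy_idx <- sample.int(nrow(records), n_decoys)
    decoys <- records[decoy_idx, ]
    decoys$sequence <- vapply(decoys$sequence, reverse_decoy, "")
    decoys$is_decoy <- TRUE
    decoys$search_score <- rnorm(n_decoys, cfg$null_score[["mean"]],
                                 cfg$null_score[["sd"]])
    decoys$modifications <- ""
    records <- dplyr::bind_rows(records, decoys)

    ranks <- rank_peptides(unique(records$sequence), cfg$allele_motifs,
                           n_ref = cfg$rank_n_ref, seed = cfg$seed)
    records <- dplyr::left_join(records, ranks, by = "sequence")
    pool_records <- dplyr::left_join(
      pool_records,
      rank_peptides(unique(pool_records$sequence), cfg$allele_motifs,
                    n_ref = cfg$rank_n_ref, seed = cfg$seed),
      by = "sequence"
    )

    list(
      records = records, pool_records = pool_records,
      truth = list(
        radiation_only = rad_only$sequence,
        false_targets = false_targets,
        boost = cfg$boost,
        universe = universe
      )
    )
  })
}

#' Simulate a proteome quantitation matrix with injected effects
#'
#' Log-normal protein abundances for triplicate control/irradiated samples
#' across the proteome time course, with time-scaled log2 effects injected
#' into a subset of proteins under irradiation only (an interaction
#' structure), Gaussian log-scale noise, and missingness whose probability
#' rises logistically as abundance falls.
#'
#' @param cfg A [sim_config()].
#' @return List: `quant` (wide log2-scale tibble with `"sample_meta"`
#'   attribute), `sample_meta`, and `truth` (per-protein per-timepoint
#'   injected log2 fold changes).
#' @export
simulate_proteome <- function(cfg = sim_config()) {
  withr::with_seed(substream_seed(cfg, "proteome"), {
    proteins <- sprintf("P%04d", seq_len(cfg$n_proteins))
    base <- rnorm(cfg$n_proteins, cfg$base_log2_mean, cfg$base_log2_sd)
    de_idx <- sample.int(cfg$n_proteins, cfg$n_de)
    max_effect <- runif(cfg$n_de, cfg$de_log2fc_range[1], cfg$de_log2fc_range[2]) *
      sample(c(-1, 1), cfg$n_de, replace = TRUE)
    t_max <- max(cfg$prot_timepoints)

    meta <- tidyr::expand_grid(
      condition = .conditions, timepoint_h = cfg$prot_timepoints,
      replicate = seq_len(cfg$n_replicates)
    )
    meta$sample_id <- sprintf("%s_%dh_r%d",
                              ifelse(meta$condition == "control", "ctrl", "ir"),
                              meta$timepoint_h, meta$replicate)
    meta <- meta[c("sample_id", "condition", "timepoint_h", "replicate")]

    effect_at <- function(tp) {
      eff <- numeric(cfg$n_proteins)
      eff[de_idx] <- max_effect * tp / t_max
      eff
    }
    m <- matrix(NA_real_, cfg$n_proteins, nrow(meta),
                dimnames = list(proteins, meta$sample_id))
    for (j in seq_len(nrow(meta))) {
      eff <- if (meta$condition[j] == "irradiated")
        effect_at(meta$timepoint_h[j]) else 0
      vals <- base + eff + rnorm(cfg$n_proteins, 0, cfg$noise_sd)
      p_miss <- stats::plogis((cfg$missing_midpoint - vals) / cfg$missing_scale)
      vals[runif(cfg$n_proteins) < p_miss] <- NA
      m[, j] <- vals
    }
    quant <- matrix_to_quant(m)
    attr(quant, "sample_meta") <- meta
    truth <- tidyr::expand_grid(
      feature_id = proteins[de_idx], timepoint_h = cfg$prot_timepoints
    )
    truth$log2fc <- rep(max_effect, each = length(cfg$prot_timepoints)) *
      truth$timepoint_h / t_max
    list(quant = quant, sample_meta = meta, truth = truth)
  })
}

#' Simulate a PRM calibration series and sample ratio table
#'
#' Light/heavy calibration ratios `amount / heavy * (1 + eps)` at the
#' default seven light-peptide amounts against the constant heavy spike,
#' with multiplicative Gaussian noise, plus per-replicate endogenous
#' light/heavy ratios for control and irradiated samples at the configured
#' true endogenous amounts.
#'
#' @param cfg A [sim_config()].
#' @return List: `calibration` (`fmol`, `ratio`), `samples` (`sample_id`,
#'   `condition`, `replicate`, `ratio`), `truth` (true slope and endogenous
#'   fmol).
#' @export
simulate_prm <- function(cfg = sim_config()) {
  withr::with_seed(substream_seed(cfg, "prm"), {
    amounts <- cfg$calibration_amounts
    ratio <- amounts / cfg$heavy_spike_fmol *
      (1 + rnorm(length(amounts), 0, cfg$prm_noise))
    calibration <- tibble::tibble(fmol = amounts, ratio = ratio)
    samples <- tidyr::expand_grid(condition = .conditions,
                                  replicate = seq_len(cfg$n_replicates))
    samples$sample_id <- sprintf("%s_r%d",
                                 ifelse(samples$condition == "control",
                                        "ctrl", "ir"),
                                 samples$replicate)
    true_fmol <- cfg$endogenous_fmol[samples$condition]
    samples$ratio <- true_fmol / cfg$heavy_spike_fmol *
      (1 + rnorm(nrow(samples), 0, cfg$prm_noise))
    samples <- samples[c("sample_id", "condition", "replicate", "ratio")]
    list(
      calibration = calibration, samples = samples,
      truth = list(slope = 1 / cfg$heavy_spike_fmol,
                   endogenous_fmol = cfg$endogenous_fmol)
    )
  })
}

#' Synthetic mitochondrial-carrier-like protein embedding KYLSVQGQL
#'
#' A deterministic synthetic stand-in (not the database sequence) for a
#' 389-residue mitochondrial carrier protein: random residues with the
#' wild-type peptide KYLSVQGQL embedded so that its glycine sits at protein
#' position 367, the position of the G>S neoantigen substitution. Useful
#' for exercising [locate_peptide_variant()] without network access to a
#' sequence database.
#'
#' @return A single protein string of length 389.
#' @export
synthetic_mtch1_protein <- function() {
  withr::with_seed(3670L, {
    aa <- sample(AA_ALPHABET, 389, replace = TRUE)
    aa[1] <- "M"
    aa[361:369] <- strsplit("KYLSVQGQL", "")[[1]]
    paste(aa, collapse = "")
  })
}

#' Write a complete simulated dataset directory
#'
#' Generates every pipeline input under one directory: contig FASTA,
#' transcript model TSV, somatic VCF, peptide tables (samples and control
#' pool), proteome quantitation and metadata TSVs, PRM calibration and
#' ratio TSVs, a machine-readable `truth.json`, and an echo of the
#' configuration.
#'
#' @param cfg A [sim_config()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the directory path.
#' @export
simulate_dataset <- function(cfg = sim_config(), dir) {
  if (!requireNamespace("jsonlite", quietly = TRUE)) {
    abort("simulate_dataset requires the jsonlite package")
  }
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(...) file.path(dir, ...)
  txome <- simulate_transcriptome(cfg)
  writeLines(paste0(">", names(txome$contigs), "\n", txome$contigs),
             p("contigs.fasta"))
  write_transcript_models(txome$transcripts, p("transcripts.tsv"))
  vars <- simulate_variants(cfg, txome, p("somatic.vcf"))
  ipp <- simulate_immunopeptidome(cfg, txome$proteome)
  write_peptide_table(ipp$records, p("peptides.tsv"))
  write_peptide_table(ipp$pool_records, p("peptides_control_pool.tsv"))
  prot <- simulate_proteome(cfg)
  readr::write_tsv(prot$quant, p("proteome_quant.tsv"), na = "")
  readr::write_tsv(prot$sample_meta, p("proteome_meta.tsv"))
  prm <- simulate_prm(cfg)
  readr::write_tsv(prm$calibration, p("prm_calibration.tsv"))
  readr::write_tsv(prm$samples, p("prm_ratios.tsv"))
  truth <- list(
    variants = vars$truth,
    radiation_only = ipp$truth$radiation_only,
    false_targets = ipp$truth$false_targets,
    proteome_effects = prot$truth,
    prm = prm$truth
  )
  jsonlite::write_json(truth, p("truth.json"), auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(unclass(cfg)[!vapply(cfg, is.list, TRUE)],
                       p("config.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
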