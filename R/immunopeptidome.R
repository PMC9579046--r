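#' Target-decoy peptide-level FDR filtering
#'
#' Estimates a score threshold controlling the peptide-level false
#' discovery rate by parallel decoy counting. Records are first collapsed to
#' their best (highest) search score per distinct sequence, separately for
#' targets and decoys; the threshold is the smallest observed target score
#' `t` at which `#decoys(score >= t) / #targets(score >= t)` falls strictly
#' below `alpha` (ties at the threshold are resolved conservatively, i.e.
#' excluded). Decoy records are removed from the output. Lowering `alpha`
#' never adds peptides.
#'
#' @param records Peptide tibble with `sequence`, `search_score`,
#'   `is_decoy`.
#' @param alpha Target peptide-level FDR (default 1%).
#' @return Target records at or above the threshold; the threshold and the
#'   estimated FDR at the threshold are attached as attributes
#'   `"score_threshold"` and `"fdr_at_threshold"`.
#' @export
fdr_filter <- function(records, alpha = 0.01) {
  check_columns(records, c("sequence", "search_score", "is_decoy"),
                "peptide table")
  targets <- dplyr::filter(records, !.data$is_decoy)
  decoys <- dplyr::filter(records, .data$is_decoy)
  if (nrow(decoys) == 0) abort("cannot estimate FDR: no decoy records")
  best <- function(x) {
    dplyr::summarise(dplyr::group_by(x, .data$sequence),
                     score = max(.data$search_score), .groups = "drop")$score
  }
  t_scores <- sort(best(targets))
  d_scores <- sort(best(decoys))
  n_t <- length(t_scores)
  n_d <- length(d_scores)
  candidates <- unique(t_scores)
  # counts of scores >= t via position in the sorted vectors
  fdr_at <- function(t) {
    nt <- n_t - findInterval(t, t_scores, left.open = TRUE)
    nd <- n_d - findInterval(t, d_scores, left.open = TRUE)
    nd / nt
  }
  fdrs <- vapply(candidates, fdr_at, 0)
  eligible <- candidates[fdrs < alpha]
  if (length(eligible) == 0) {
    threshold <- Inf
    fdr <- NA_real_
  } else {
    threshold <- min(eligible)
    fdr <- fdr_at(threshold)
  }
  best_by_seq <- dplyr::summarise(
    dplyr::group_by(targets, .data$sequence),
    best_score = max(.data$search_score), .groups = "drop"
  )
  keep_seqs <- best_by_seq$sequence[best_by_seq$best_score >= threshold]
  out <- dplyr::filter(targets, .data$sequence %in% keep_seqs)
  attr(out, "score_threshold") <- threshold
  attr(out, "fdr_at_threshold") <- fdr
  out
}

#' Default H-2 allele anchor motifs
#'
#' Simplified position-weight anchor motifs for the BALB/c MHC class I
#' alleles: H-2-Kd prefers tyrosine at P2 and an aliphatic C terminus,
#' H-2-Dd glycine at P2 (with proline at P3) and an aliphatic/aromatic C
#' terminus, H-2-Ld proline at P2. `anchor_prob` is the total probability
#' mass the motif places on the preferred residues at an anchor position.
#'
#' @return Named list of motifs, each `list(anchors = list(<position> =
#'   residues), anchor_prob)`. Position `"C"` denotes the C-terminal
#'   residue.
#' @export
h2_motifs <- function() {
  list(
    `H-2-Kd` = list(anchors = list(`2` = "Y", C = c("L", "I")), anchor_prob = 0.7),
    `H-2-Dd` = list(anchors = list(`2` = "G", `3` = "P", C = c("L", "I", "F")),
                    anchor_prob = 0.7),
    `H-2-Ld` = list(anchors = list(`2` = "P", C = c("L", "F")), anchor_prob = 0.7)
  )
}

AA_ALPHABET <- c("G", "A", "S", "P", "V", "T", "C", "L", "I", "N",
                 "D", "Q", "E", "K", "M", "H", "F", "R", "Y", "W")

# Position-probability matrix for a motif at a given peptide length.
motif_ppm <- function(motif, length) {
  ppm <- matrix(1 / 20, nrow = 20, ncol = length,
                dimnames = list(AA_ALPHABET, NULL))
  for (pos_name in names(motif$anchors)) {
    pos <- if (pos_name == "C") length else as.integer(pos_name)
    if (pos > length) next
    preferred <- motif$anchors[[pos_name]]
    p <- motif$anchor_prob %||% 0.7
    ppm[, pos] <- (1 - p) / (20 - length(preferred))
    ppm[preferred, pos] <- p / length(preferred)
  }
  ppm
}

# Log-odds motif score of a residue matrix (rows = peptides) against a motif.
score_matrix <- function(mat, motif) {
  ppm <- motif_ppm(motif, ncol(mat))
  scores <- numeric(nrow(mat))
  for (j in seq_len(ncol(mat))) {
    scores <- scores + log(ppm[mat[, j], j] * 20)
  }
  scores
}

# Log-odds motif score of peptides (same length) against a motif.
score_peptides <- function(peptides, motif) {
  lens <- unique(nchar(peptides))
  stopifnot(length(lens) == 1)
  score_matrix(do.call(rbind, strsplit(peptides, "")), motif)
}

#' Mock percent-rank scoring of peptides against allele motifs
#'
#' A calibrated stand-in for an external MHC binding predictor, used to
#' score synthetic data: each peptide receives a log-odds position-weight
#' score per allele, converted to a percent rank as its empirical quantile
#' (in percent, smaller = stronger) among `n_ref` random uniform peptides of
#' the same length, seeded per allele and length for reproducibility.
#'
#' @param peptides Character vector of peptide sequences (lengths may mix).
#' @param motifs Named list of motifs (see [h2_motifs()]).
#' @param n_ref Size of the random reference sample per allele and length.
#' @param seed Integer seed fixing the reference sample.
#' @return Tibble with `sequence` and one `rank_<allele>` column per motif.
#' @export
rank_peptides <- function(peptides, motifs = h2_motifs(), n_ref = 1e5,
                          seed = 1) {
  out <- tibble::tibble(sequence = peptides)
  lens <- nchar(peptides)
  for (allele in names(motifs)) {
    ranks <- rep(NA_real_, length(peptides))
    for (L in unique(lens)) {
      idx <- lens == L
      ref_mat <- withr::with_seed(
        (seed + L * 131L + match(allele, names(motifs)) * 7919L) %% .Machine$integer.max,
        matrix(sample(AA_ALPHABET, n_ref * L, replace = TRUE), nrow = n_ref)
      )
      ref_scores <- sort(score_matrix(ref_mat, motifs[[allele]]))
      obs <- score_peptides(peptides[idx], motifs[[allele]])
      # percent of random peptides scoring at least as high
      ranks[idx] <- 100 * (n_ref - findInterval(obs, ref_scores, left.open = TRUE)) / n_ref
    }
    out[[paste0("rank_", allele)]] <- ranks
  }
  out
}

#' Assign each peptide to its best-ranking allele
#'
#' Takes the minimum percent rank across alleles per distinct sequence and
#' classifies binding strength with the conventional strict thresholds:
#' strong binder below 0.5, binder below 2, otherwise non-binder (with no
#' assigned allele).
#'
#' @param records Tibble with `sequence` and `rank_<allele>` columns (e.g.
#'   from [read_peptide_table()] or [rank_peptides()]).
#' @param alleles Alleles to consider; defaults to every `rank_` column.
#' @param strong_cut,binder_cut Strict (`<`) rank thresholds.
#' @return Tibble, one row per distinct sequence: `sequence`, `best_allele`
#'   (`NA` for non-binders), `best_rank`, `binder_class`.
#' @export
assign_alleles <- function(records, alleles = NULL, strong_cut = 0.5,
                           binder_cut = 2) {
  check_columns(records, "sequence", "peptide table")
  rank_cols <- if (is.null(alleles)) {
    grep("^rank_", names(records), value = TRUE)
  } else paste0("rank_", alleles)
  check_columns(records, rank_cols, "peptide table")
  long <- tidyr::pivot_longer(
    dplyr::select(records, "sequence", dplyr::all_of(rank_cols)),
    -"sequence", names_to = "allele", names_prefix = "rank_",
    values_to = "rank"
  )
  long <- dplyr::filter(long, !is.na(.data$rank))
  best <- dplyr::slice_min(
    dplyr::group_by(long, .data$sequence),
    order_by = .data$rank, n = 1, with_ties = FALSE
  )
  out <- dplyr::ungroup(dplyr::transmute(
    best, sequence = .data$sequence,
    best_allele = .data$allele, best_rank = .data$rank
  ))
  dplyr::mutate(
    out,
    binder_class = dplyr::case_when(
      .data$best_rank < strong_cut ~ "strong",
      .data$best_rank < binder_cut ~ "binder",
      TRUE ~ "non-binder"
    ),
    best_allele = dplyr::if_else(.data$binder_class == "non-binder",
                                 NA_character_, .data$best_allele)
  )
}

#' Peptide length distribution per condition
#'
#' Counts unique peptide sequences and sums intensity per length and
#' condition within a length window (8-12 by default; an 8-14 window suits
#' H-2-b haplotype data). Records outside the window are excluded.
#'
#' @param records Peptide tibble (`sequence`, `condition`, `intensity`).
#' @param min_len,max_len Inclusive length window.
#' @return Tibble `condition`, `length`, `n_unique`, `total_intensity`,
#'   complete over the window.
#' @export
length_distribution <- function(records, min_len = 8, max_len = 12) {
  check_columns(records, c("sequence", "condition", "intensity"),
                "peptide table")
  if ("is_decoy" %in% names(records)) {
    records <- dplyr::filter(records, !.data$is_decoy)
  }
  records <- dplyr::mutate(records, length = nchar(.data$sequence))
  records <- dplyr::filter(records, .data$length >= min_len,
                           .data$length <= max_len)
  out <- dplyr::summarise(
    dplyr::group_by(records, .data$condition, .data$length),
    n_unique = dplyr::n_distinct(.data$sequence),
    total_intensity = sum(.data$intensity, na.rm = TRUE),
    .groups = "drop"
  )
  tidyr::complete(out, .data$condition,
                  length = seq.int(min_len, max_len),
                  fill = list(n_unique = 0L, total_intensity = 0))
}

#' Roll up immunopeptidome intensities to source proteins
#'
#' Unlike the proteome top-3 roll-up, label-free quantification of the
#' immunopeptidome uses all peptides associated with each source protein.
#' Peptides mapping to several source proteins contribute to each and the
#' protein is flagged ambiguous, so total rolled-up intensity is at least
#' the total peptide intensity (equal exactly when no peptide is shared).
#'
#' @param records Peptide tibble with `sequence`, `sample_id`, `intensity`,
#'   `source_proteins` (`;`-separated accessions).
#' @return Wide tibble `feature_id` x samples (summed intensity; samples
#'   without the protein get 0); proteins receiving any shared peptide are
#'   listed in the `"ambiguous_proteins"` attribute.
#' @export
rollup_all_peptides <- function(records) {
  check_columns(records, c("sequence", "sample_id", "intensity",
                           "source_proteins"), "peptide table")
  if ("is_decoy" %in% names(records)) {
    records <- dplyr::filter(records, !.data$is_decoy)
  }
  records <- dplyr::filter(records, nzchar(.data$source_proteins))
  records$n_sources <- lengths(strsplit(records$source_proteins, ";", fixed = TRUE))
  long <- tidyr::separate_rows(records, "source_proteins", sep = ";")
  sums <- dplyr::summarise(
    dplyr::group_by(long, feature_id = .data$source_proteins, .data$sample_id),
    intensity = sum(.data$intensity, na.rm = TRUE),
    any_ambiguous = any(.data$n_sources > 1),
    .groups = "drop"
  )
  ambiguous <- unique(sums$feature_id[sums$any_ambiguous])
  out <- tidyr::pivot_wider(
    dplyr::select(sums, -"any_ambiguous"),
    names_from = "sample_id", values_from = "intensity", values_fill = 0
  )
  out <- dplyr::arrange(out, .data$feature_id)
  attr(out, "ambiguous_proteins") <- ambiguous
  out
}

#' Per-condition peptide sets and radiation-specific antigens
#'
#' Computes unique-sequence sets per condition, per-replicate overlap (Venn)
#' counts, and the radiation-specific set: sequences seen in at least one
#' irradiated sample and absent from every control sample including the
#' expanded control pool. Peptide identity is the bare sequence
#' (modifications ignored). Enlarging the control pool can only shrink the
#' radiation-specific set.
#'
#' @param records Peptide tibble (`sequence`, `sample_id`, `condition`,
#'   `timepoint_h`).
#' @param expanded_controls Additional control-pool sequences: a character
#'   vector or a tibble with a `sequence` column.
#' @return List: `sets` (named list of unique sequence vectors per
#'   condition, plus `control_pool`), `radiation_specific` (character),
#'   `unique_counts` (per condition and per condition x time point),
#'   `replicate_overlap` (sequences by number of supporting samples per
#'   condition).
#' @export
condition_sets <- function(records, expanded_controls = NULL) {
  check_columns(records, c("sequence", "sample_id", "condition"),
                "peptide table")
  if ("is_decoy" %in% names(records)) {
    records <- dplyr::filter(records, !.data$is_decoy)
  }
  pool <- if (is.null(expanded_controls)) character(0)
          else if (is.character(expanded_controls)) unique(expanded_controls)
          else unique(expanded_controls$sequence)
  sets <- lapply(split(records$sequence, records$condition), unique)
  sets$control_pool <- pool
  control_all <- unique(c(sets[["control"]], pool))
  radiation_specific <- setdiff(sets[["irradiated"]] %||% character(0),
                                control_all)
  by_cond <- dplyr::summarise(
    dplyr::group_by(records, .data$condition),
    n_unique = dplyr::n_distinct(.data$sequence), .groups = "drop"
  )
  by_cond_time <- if ("timepoint_h" %in% names(records)) {
    dplyr::summarise(
      dplyr::group_by(records, .data$condition, .data$timepoint_h),
      n_unique = dplyr::n_distinct(.data$sequence), .groups = "drop"
    )
  } else NULL
  replicate_overlap <- dplyr::count(
    dplyr::summarise(
      dplyr::group_by(records, .data$condition, .data$sequence),
      n_samples = dplyr::n_distinct(.data$sample_id), .groups = "drop"
    ),
    .data$condition, .data$n_samples, name = "n_sequences"
  )
  list(
    sets = sets,
    radiation_specific = radiation_specific,
    unique_counts = list(by_condition = by_cond,
                         by_condition_timepoint = by_cond_time),
    replicate_overlap = replicate_overlap
  )
}

#' Ranked table of strong-binding radiation-specific antigens
#'
#' Restricts an allele-assignment table to strong binders (best percent
#' rank strictly below `rank_cut`), optionally intersecting with a
#' radiation-specific sequence set, sorts ascending by rank, and flags
#' source proteins represented by two or more distinct peptides (candidates
#' most closely linked with the treatment).
#'
#' @param assignments Tibble with columns `sequence`, a rank column
#'   (`best_rank` or `rank`), optionally an allele column (`best_allele` or
#'   `allele`) and a source-protein column (`source_protein` or `entry`).
#' @param radiation_specific Optional character vector restricting the
#'   sequences.
#' @param rank_cut Strict upper bound on the rank.
#' @return Sorted tibble with a `multi_peptide` flag; the multi-peptide
#'   source proteins are attached as attribute `"multi_peptide_proteins"`.
#' @export
radiation_antigen_table <- function(assignments, radiation_specific = NULL,
                                    rank_cut = 0.5) {
  tbl <- assignments
  if (!"best_rank" %in% names(tbl) && "rank" %in% names(tbl)) {
    tbl <- dplyr::rename(tbl, best_rank = "rank")
  }
  if (!"best_allele" %in% names(tbl) && "allele" %in% names(tbl)) {
    tbl <- dplyr::rename(tbl, best_allele = "allele")
  }
  if (!"source_protein" %in% names(tbl) && "entry" %in% names(tbl)) {
    tbl <- dplyr::rename(tbl, source_protein = "entry")
  }
  check_columns(tbl, c("sequence", "best_rank"), "assignment table")
  if (!is.null(radiation_specific)) {
    tbl <- dplyr::filter(tbl, .data$sequence %in% radiation_specific)
  }
  tbl <- dplyr::arrange(dplyr::filter(tbl, .data$best_rank < rank_cut),
                        .data$best_rank)
  multi <- character(0)
  if ("source_protein" %in% names(tbl) && nrow(tbl) > 0) {
    per_prot <- dplyr::summarise(
      dplyr::group_by(tbl, .data$source_protein),
      n_peptides = dplyr::n_distinct(.data$sequence), .groups = "drop"
    )
    multi <- sort(per_prot$source_protein[per_prot$n_peptides >= 2])
    tbl$multi_peptide <- tbl$source_protein %in% multi
  } else {
    tbl$multi_peptide <- logical(nrow(tbl))
  }
  attr(tbl, "multi_peptide_proteins") <- multi
  tbl
}

#' Position-by-residue frequency matrix of allele-assigned peptides
#'
#' Residue frequencies per position across the 9-mers (by default) assigned
#' to one allele — the numerical content of a sequence logo. Frequencies at
#' each position sum to 1.
#'
#' @param assignments Allele-assignment tibble ([assign_alleles()]) with a
#'   `best_allele` column, or any tibble with `sequence` (then `allele` is
#'   not filtered).
#' @param allele Allele whose peptides to summarise.
#' @param length Peptide length to restrict to.
#' @param binders_only Keep only `strong`/`binder` classes when a
#'   `binder_class` column is present.
#' @return Tibble `position`, `residue`, `freq` complete over the 20
#'   residues; the underlying 20 x length matrix is attached as attribute
#'   `"matrix"`.
#' @export
motif_matrix <- function(assignments, allele = NULL, length = 9,
                         binders_only = TRUE) {
  check_columns(assignments, "sequence", "assignment table")
  tbl <- assignments
  if (!is.null(allele) && "best_allele" %in% names(tbl)) {
    tbl <- dplyr::filter(tbl, .data$best_allele == allele)
  }
  if (binders_only && "binder_class" %in% names(tbl)) {
    tbl <- dplyr::filter(tbl, .data$binder_class != "non-binder")
  }
  seqs <- unique(tbl$sequence[nchar(tbl$sequence) == length])
  if (length(seqs) == 0) abort("no peptides match the allele/length filter")
  mat <- do.call(rbind, strsplit(seqs, ""))
  freq <- vapply(seq_len(ncol(mat)), function(j) {
    tab <- table(factor(mat[, j], levels = AA_ALPHABET))
    as.numeric(tab) / nrow(mat)
  }, numeric(20))
  rownames(freq) <- AA_ALPHABET
  out <- tidyr::pivot_longer(
    tibble::as_tibble(t(freq), rownames = "position"),
    -"position", names_to = "residue", values_to = "freq"
  )
  out$position <- as.integer(out$position)
  out <- dplyr::arrange(out, .data$position, .data$residue)
  attr(out, "matrix") <- freq
  attr(out, "n_peptides") <- length(seqs)
  out
}

#' Plot a peptide length distribution
#'
#' @param records Peptide tibble passed to [length_distribution()].
#' @param ... Passed to [length_distribution()].
#' @return A ggplot of unique-peptide counts per length and condition.
#' @export
plot_length_distribution <- function(records, ...) {
  d <- length_distribution(records, ...)
  ggplot2::ggplot(d, ggplot2::aes(x = factor(.data$length), y = .data$n_unique,
                                  fill = .data$condition)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = "peptide length (aa)", y = "unique peptides",
                  fill = NULL)
}

#' Plot a binding-motif frequency matrix
#'
#' @param motif Tibble from [motif_matrix()].
#' @return A ggplot heatmap of residue frequencies per position.
#' @export
plot_motif_matrix <- function(motif) {
  ggplot2::ggplot(motif, ggplot2::aes(x = factor(.data$position),
                                      y = .data$residue, fill = .data$freq)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient(low = "white", high = "darkred") +
    ggplot2::labs(x = "position", y = "residue", fill = "frequency")
}
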