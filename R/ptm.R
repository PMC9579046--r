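ptm_prepare <- function(records) {
  check_columns(records, c("sequence", "sample_id", "condition"),
                "peptide table")
  if ("is_decoy" %in% names(records)) {
    records <- dplyr::filter(records, !.data$is_decoy)
  }
  if (!"modifications" %in% names(records)) records$modifications <- ""
  records$modifications <- dplyr::coalesce(as.character(records$modifications), "")
  records
}

# Distinct unmodified peptides per sample.
unmodified_counts <- function(records) {
  dplyr::summarise(
    dplyr::group_by(records, .data$sample_id),
    n_unmodified = dplyr::n_distinct(.data$sequence[!nzchar(.data$modifications)]),
    .groups = "drop"
  )
}

sample_grouping <- function(records) {
  keys <- intersect(c("sample_id", "condition", "timepoint_h", "replicate"),
                    names(records))
  dplyr::distinct(records[keys])
}

#' Ratio of modified to unmodified peptides per sample
#'
#' For each sample (biological replicate) the number of distinct modified
#' peptidoforms (sequence + modification set) is divided by the number of
#' distinct unmodified peptide sequences — the per-condition representation
#' used to ask whether treatment changes the overall modification load.
#'
#' @param records Peptide tibble with `sequence`, `sample_id`, `condition`
#'   and `modifications` (`name@pos;...` encoding, empty for none).
#' @return Tibble per sample: `n_modified`, `n_unmodified`, `ptm_ratio`
#'   (`NA` and flagged when a sample has no unmodified peptides).
#' @export
ptm_ratio <- function(records) {
  records <- ptm_prepare(records)
  per_sample <- dplyr::summarise(
    dplyr::group_by(records, .data$sample_id),
    n_modified = dplyr::n_distinct(
      paste(.data$sequence, .data$modifications)[nzchar(.data$modifications)]
    ),
    n_unmodified = dplyr::n_distinct(.data$sequence[!nzchar(.data$modifications)]),
    .groups = "drop"
  )
  out <- dplyr::left_join(sample_grouping(records), per_sample, by = "sample_id")
  dplyr::mutate(
    out,
    ptm_ratio = dplyr::if_else(.data$n_unmodified > 0,
                               .data$n_modified / .data$n_unmodified, NA_real_),
    undefined = .data$n_unmodified == 0
  )
}

paired_position_test <- function(per_sample, value_col) {
  pair_keys <- intersect(c("timepoint_h", "replicate"), names(per_sample))
  if (length(pair_keys) == 0) {
    abort("paired test requires a replicate (and/or timepoint_h) column")
  }
  wide <- tidyr::pivot_wider(
    per_sample[c(pair_keys, "condition", value_col)],
    names_from = "condition", values_from = dplyr::all_of(value_col)
  )
  if (!all(.conditions %in% names(wide))) {
    return(tibble::tibble(estimate = NA_real_, p_value = NA_real_,
                          n_pairs = 0L))
  }
  ok <- stats::complete.cases(wide[.conditions])
  x <- wide$irradiated[ok]
  y <- wide$control[ok]
  if (sum(ok) < 2 || sd(x - y) == 0) {
    return(tibble::tibble(estimate = mean(x - y), p_value = NA_real_,
                          n_pairs = sum(ok)))
  }
  tt <- t.test(x, y, paired = TRUE)
  tibble::tibble(estimate = unname(tt$estimate), p_value = tt$p.value,
                 n_pairs = sum(ok))
}

#' Positional modification ratios on 9-mers with paired tests
#'
#' For each peptide position 1..`length`, the number of distinct `length`-mer
#' peptidoforms carrying a modification at that position is divided by the
#' number of distinct unmodified `length`-mers in the same sample (a global
#' unmodified denominator). Control and irradiated replicates are then
#' compared per position with a paired two-sided t-test (pairing on
#' replicate and time point), BH-adjusted across positions — the analysis
#' that localises treatment-induced modification gains to specific anchor or
#' solvent-exposed positions.
#'
#' @param records Peptide tibble with `sequence`, `sample_id`, `condition`,
#'   `replicate` (and optionally `timepoint_h`), `modifications`.
#' @param length Peptide length analysed; other lengths are excluded from
#'   numerator and denominator.
#' @return List: `per_sample` (position x sample ratios) and `tests` (per
#'   position: mean paired difference, `p_value`, `q_value`).
#' @export
positional_ratio <- function(records, length = 9) {
  records <- ptm_prepare(records)
  records <- dplyr::filter(records, nchar(.data$sequence) == length)
  denom <- unmodified_counts(records)
  mods <- parse_modifications(records$modifications)
  meta <- sample_grouping(records)

  per_sample <- tidyr::expand_grid(
    sample_id = unique(records$sample_id), position = seq_len(length)
  )
  mod_counts <- dplyr::bind_rows(lapply(seq_len(length), function(pos) {
    hit <- unique(mods$index[mods$position == pos])
    if (length(hit) == 0) {
      return(tibble::tibble(sample_id = character(), position = integer(),
                            n_modified = integer()))
    }
    d <- dplyr::distinct(tibble::tibble(
      sample_id = records$sample_id[hit],
      form = paste(records$sequence, records$modifications)[hit],
      position = pos
    ))
    dplyr::count(d, .data$sample_id, .data$position, name = "n_modified")
  }))
  per_sample <- dplyr::left_join(per_sample, mod_counts,
                                 by = c("sample_id", "position"))
  per_sample$n_modified <- dplyr::coalesce(per_sample$n_modified, 0L)
  per_sample <- dplyr::left_join(per_sample, denom, by = "sample_id")
  per_sample <- dplyr::left_join(per_sample, meta, by = "sample_id")
  per_sample <- dplyr::mutate(
    per_sample,
    ratio = dplyr::if_else(.data$n_unmodified > 0,
                           .data$n_modified / .data$n_unmodified, NA_real_)
  )
  tests <- dplyr::bind_rows(lapply(seq_len(length), function(pos) {
    res <- paired_position_test(
      dplyr::filter(per_sample, .data$position == pos), "ratio"
    )
    dplyr::mutate(res, position = pos, .before = 1)
  }))
  tests$q_value <- p.adjust(tests$p_value, "BH")
  list(per_sample = per_sample, tests = tests)
}

#' Per-modification-type ratio comparison between conditions
#'
#' The modified/unmodified ratio machinery applied per modification name:
#' for each PTM the distinct peptidoforms carrying it are counted per sample
#' against the sample's distinct unmodified peptides, and conditions are
#' compared with a paired two-sided t-test. A pseudocount of 0.5 replaces
#' zero cells (flagged) so a PTM absent from one condition still yields a
#' finite ratio. Peptidoforms carrying several PTM types count once per
#' type, so per-PTM modified counts total at least the number of modified
#' peptidoforms.
#'
#' @param records Peptide tibble as in [positional_ratio()].
#' @return Tibble per modification name: mean ratio per condition, paired
#'   mean difference, `p_value`, `q_value`, `pseudocount_used`.
#' @export
per_ptm_compare <- function(records) {
  records <- ptm_prepare(records)
  denom <- unmodified_counts(records)
  meta <- sample_grouping(records)
  mods <- parse_modifications(records$modifications)
  if (nrow(mods) == 0) {
    return(tibble::tibble(
      modification = character(), mean_ratio_control = double(),
      mean_ratio_irradiated = double(), estimate = double(),
      p_value = double(), q_value = double(), pseudocount_used = logical()
    ))
  }
  out <- dplyr::bind_rows(lapply(unique(mods$name), function(ptm) {
    hit <- unique(mods$index[mods$name == ptm])
    counts <- dplyr::count(
      dplyr::distinct(tibble::tibble(
        sample_id = records$sample_id[hit],
        form = paste(records$sequence, records$modifications)[hit]
      )),
      .data$sample_id, name = "n_modified"
    )
    per_sample <- dplyr::left_join(meta, counts, by = "sample_id")
    per_sample <- dplyr::left_join(per_sample, denom, by = "sample_id")
    pseudo <- any(is.na(per_sample$n_modified) | per_sample$n_modified == 0 |
                    per_sample$n_unmodified == 0)
    per_sample <- dplyr::mutate(
      per_sample,
      n_modified = pmax(dplyr::coalesce(as.numeric(.data$n_modified), 0), 0.5),
      n_unmodified = pmax(.data$n_unmodified, 0.5),
      ratio = .data$n_modified / .data$n_unmodified
    )
    test <- paired_position_test(per_sample, "ratio")
    means <- dplyr::summarise(dplyr::group_by(per_sample, .data$condition),
                              mean_ratio = mean(.data$ratio), .groups = "drop")
    tibble::tibble(
      modification = ptm,
      mean_ratio_control = means$mean_ratio[means$condition == "control"][1],
      mean_ratio_irradiated = means$mean_ratio[means$condition == "irradiated"][1],
      estimate = test$estimate, p_value = test$p_value,
      pseudocount_used = pseudo
    )
  }))
  out$q_value <- p.adjust(out$p_value, "BH")
  out
}
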