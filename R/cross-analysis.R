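#' Join proteome and immunopeptidome differential-expression results
#'
#' Inner join of the per-protein fold changes from the proteome and the
#' per-source-protein fold changes from the immunopeptidome roll-up, to
#' study whether changes in protein expression translate into changes in
#' MHC presentation. Overlap bookkeeping (proteins shared, immunopeptidome-
#' only proteins, and optionally immunopeptidome-only unique peptides) is
#' attached as the `"overlap"` attribute. The join is symmetric in input
#' order up to column naming.
#'
#' @param proteome_de Tidy DE tibble (`feature_id`, `log2fc`, `p_value`) or
#'   `radpep_de` object for the proteome.
#' @param ipp_de Same for the immunopeptidome roll-up.
#' @param ipp_records Optional peptide tibble used to count
#'   immunopeptidome-only unique peptides (each sequence counted once).
#' @return Tibble `accession`, `proteome_log2fc`, `proteome_p`,
#'   `ipp_log2fc`, `ipp_p`.
#' @export
join_ratios <- function(proteome_de, ipp_de, ipp_records = NULL) {
  as_de <- function(x) if (inherits(x, "radpep_de")) x$table else x
  p <- as_de(proteome_de)
  i <- as_de(ipp_de)
  check_columns(p, c("feature_id", "log2fc", "p_value"), "proteome DE table")
  check_columns(i, c("feature_id", "log2fc", "p_value"), "immunopeptidome DE table")
  joined <- dplyr::inner_join(
    dplyr::select(p, accession = "feature_id", proteome_log2fc = "log2fc",
                  proteome_p = "p_value"),
    dplyr::select(i, accession = "feature_id", ipp_log2fc = "log2fc",
                  ipp_p = "p_value"),
    by = "accession"
  )
  ipp_only <- setdiff(i$feature_id, p$feature_id)
  n_ipp_only_peptides <- NA_integer_
  if (!is.null(ipp_records)) {
    long <- tidyr::separate_rows(ipp_records, "source_proteins", sep = ";")
    only <- dplyr::filter(long, .data$source_proteins %in% ipp_only)
    n_ipp_only_peptides <- dplyr::n_distinct(only$sequence)
  }
  attr(joined, "overlap") <- tibble::tibble(
    n_overlap = nrow(joined),
    n_proteome_only = length(setdiff(p$feature_id, i$feature_id)),
    n_ipp_only = length(ipp_only),
    n_ipp_only_peptides = n_ipp_only_peptides
  )
  joined
}

#' Classify joined proteome/immunopeptidome records into quadrants
#'
#' Each protein is placed in a fold-change quadrant by the sign pair of its
#' proteome and immunopeptidome log2 fold changes (`up_up`, `up_down`,
#' `down_up`, `down_down`; zero fold change gets no quadrant), and into a
#' significance class by unadjusted p < `p_cut` on each axis
#' (`proteome_only`, `ipp_only`, `both`, `neither`). BH q-values across the
#' joined set are reported alongside.
#'
#' @param records Tibble from [join_ratios()].
#' @param p_cut Significance threshold on each axis.
#' @return Input with `sig_class`, `quadrant`, `proteome_q`, `ipp_q`
#'   columns; per-quadrant counts (over records with both signs nonzero)
#'   attached as attribute `"quadrant_counts"`.
#' @export
classify_quadrants <- function(records, p_cut = 0.05) {
  check_columns(records, c("proteome_log2fc", "proteome_p", "ipp_log2fc",
                           "ipp_p"), "cross table")
  out <- dplyr::mutate(
    records,
    sig_class = dplyr::case_when(
      .data$proteome_p < p_cut & .data$ipp_p < p_cut ~ "both",
      .data$proteome_p < p_cut ~ "proteome_only",
      .data$ipp_p < p_cut ~ "ipp_only",
      TRUE ~ "neither"
    ),
    quadrant = dplyr::case_when(
      .data$proteome_log2fc > 0 & .data$ipp_log2fc > 0 ~ "up_up",
      .data$proteome_log2fc > 0 & .data$ipp_log2fc < 0 ~ "up_down",
      .data$proteome_log2fc < 0 & .data$ipp_log2fc > 0 ~ "down_up",
      .data$proteome_log2fc < 0 & .data$ipp_log2fc < 0 ~ "down_down",
      TRUE ~ NA_character_
    ),
    proteome_q = p.adjust(.data$proteome_p, "BH"),
    ipp_q = p.adjust(.data$ipp_p, "BH")
  )
  counts <- dplyr::count(dplyr::filter(out, !is.na(.data$quadrant)),
                         .data$quadrant, name = "n")
  attr(out, "quadrant_counts") <- counts
  out
}

#' Plot the proteome/immunopeptidome fold-change correlation
#'
#' @param records Classified cross table from [classify_quadrants()] (a
#'   table from [join_ratios()] is classified with defaults first).
#' @param p_cut Threshold used if classification is still needed.
#' @return A ggplot scatter of immunopeptidome against proteome log2 fold
#'   change coloured by significance class.
#' @export
plot_cross_quadrants <- function(records, p_cut = 0.05) {
  if (!"sig_class" %in% names(records)) {
    records <- classify_quadrants(records, p_cut = p_cut)
  }
  ggplot2::ggplot(records, ggplot2::aes(x = .data$proteome_log2fc,
                                        y = .data$ipp_log2fc,
                                        colour = .data$sig_class)) +
    ggplot2::geom_point(alpha = 0.7, size = 0.9) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dotted") +
    ggplot2::geom_vline(xintercept = 0, linetype = "dotted") +
    ggplot2::scale_colour_manual(values = c(
      both = "purple", proteome_only = "darkorange",
      ipp_only = "steelblue", neither = "grey70"
    )) +
    ggplot2::labs(x = "proteome log2 fold change",
                  y = "immunopeptidome log2 fold change", colour = NULL)
}
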