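#' Top-3 roll-up of peptide abundances to protein level
#'
#' Computes a label-free protein abundance per sample as the sum of the
#' three largest abundances among the protein's unique peptides (all
#' available if fewer than three). A peptide is unique when it maps to
#' exactly one protein across the whole table; shared peptides are excluded
#' from every protein. The result is invariant to peptide row order.
#'
#' @param peptide_quant Wide tibble: columns `peptide`, `protein`, then one
#'   abundance column per sample (missing = `NA`).
#' @param top_n Number of top peptides summed.
#' @param unique_only Drop peptides mapping to more than one protein.
#' @param agg `"sum"` (Hi-3 style, default) or `"mean"` of the top peptides.
#' @return Wide tibble `feature_id` x samples. Proteins left with zero
#'   unique peptides are omitted and listed in the `"dropped_proteins"`
#'   attribute.
#' @export
rollup_top3 <- function(peptide_quant, top_n = 3, unique_only = TRUE,
                        agg = c("sum", "mean")) {
  agg <- match.arg(agg)
  check_columns(peptide_quant, c("peptide", "protein"), "peptide quant table")
  sample_cols <- setdiff(names(peptide_quant), c("peptide", "protein"))
  if (length(sample_cols) == 0) abort("no sample columns in peptide quant table")

  all_proteins <- unique(peptide_quant$protein)
  if (unique_only) {
    n_prot <- dplyr::summarise(
      dplyr::group_by(peptide_quant, .data$peptide),
      n_proteins = dplyr::n_distinct(.data$protein), .groups = "drop"
    )
    shared <- n_prot$peptide[n_prot$n_proteins > 1]
    peptide_quant <- dplyr::filter(peptide_quant, !.data$peptide %in% shared)
  }
  top_fun <- function(x) {
    x <- sort(x[!is.na(x)], decreasing = TRUE)
    if (length(x) == 0) return(NA_real_)
    x <- x[seq_len(min(top_n, length(x)))]
    if (agg == "sum") sum(x) else mean(x)
  }
  out <- dplyr::summarise(
    dplyr::group_by(peptide_quant, feature_id = .data$protein),
    dplyr::across(dplyr::all_of(sample_cols), top_fun),
    .groups = "drop"
  )
  out <- dplyr::arrange(out, .data$feature_id)
  attr(out, "dropped_proteins") <- setdiff(all_proteins, out$feature_id)
  out
}

#' Scalar-factor normalisation of an abundance matrix
#'
#' Multiplies every sample by a single scalar chosen against a
#' feature-wise geometric-mean pseudo-reference:
#' `factor = exp(median over shared features of log(reference/sample))`,
#' recentred so the factors have geometric mean 1. After normalisation the
#' median log-ratio of every sample to the recomputed reference is 0, and
#' re-normalising yields factors of 1 (idempotence).
#'
#' @param quant Wide abundance tibble (`feature_id` + sample columns), raw
#'   (non-log) scale; missing = `NA`, zeros ignored when forming logs.
#' @return Normalised tibble with the named per-sample `factors` attached as
#'   the `"norm_factors"` attribute.
#' @export
normalize_scalar <- function(quant) {
  m <- quant_to_matrix(quant)
  logm <- log(m)
  logm[!is.finite(logm)] <- NA
  ref <- rowMeans(logm, na.rm = TRUE)
  ref[is.nan(ref)] <- NA
  log_factors <- vapply(seq_len(ncol(logm)), function(j) {
    shared <- !is.na(logm[, j]) & !is.na(ref)
    if (sum(shared) < 10) {
      abort(sprintf("sample %s shares fewer than 10 features with the reference",
                    colnames(logm)[j]))
    }
    median(ref[shared] - logm[shared, j])
  }, 0)
  log_factors <- log_factors - mean(log_factors)
  factors <- setNames(exp(log_factors), colnames(m))
  out <- matrix_to_quant(sweep(m, 2, factors, `*`))
  attr(out, "norm_factors") <- factors
  out
}

#' Maximum-likelihood imputation of missing abundances
#'
#' Imputes missing log-scale abundances under a per-feature Gaussian model
#' fitted across the samples of each condition group (condition x time
#' point): the EM fixed point sets each missing entry to the converged
#' conditional mean, i.e. the observed within-group mean of the feature.
#' Grouping within conditions avoids shrinking true treatment effects.
#' Features fully missing in a group stay missing and are flagged.
#'
#' @param quant Wide log-scale abundance tibble.
#' @param sample_meta Tibble `sample_id`, `condition`, `timepoint_h`
#'   (defaults to the `"sample_meta"` attribute of `quant`).
#' @param group_vars Metadata columns defining the imputation groups.
#' @return Imputed tibble; combinations still missing are recorded in the
#'   `"incomplete"` attribute (`feature_id`, `group`).
#' @export
impute_mle <- function(quant, sample_meta = NULL,
                       group_vars = c("condition", "timepoint_h")) {
  sample_meta <- sample_meta %||% attr(quant, "sample_meta")
  if (is.null(sample_meta)) abort("sample metadata required for imputation")
  m <- quant_to_matrix(quant)
  if (max(m, na.rm = TRUE) > 50) {
    warn("abundances look unlogged (max > 50); impute_mle expects log scale")
  }
  meta <- sample_meta[match(colnames(m), sample_meta$sample_id), , drop = FALSE]
  if (anyNA(meta$sample_id)) abort("sample metadata does not cover all samples")
  group <- do.call(paste, c(unname(meta[group_vars]), sep = "/"))

  incomplete <- list()
  for (g in unique(group)) {
    cols <- which(group == g)
    sub <- m[, cols, drop = FALSE]
    mu <- rowMeans(sub, na.rm = TRUE)
    all_missing <- !is.finite(mu)
    for (j in seq_along(cols)) {
      miss <- is.na(sub[, j]) & !all_missing
      m[miss, cols[j]] <- mu[miss]
    }
    if (any(all_missing)) {
      incomplete[[g]] <- tibble::tibble(
        feature_id = rownames(m)[all_missing], group = g
      )
    }
  }
  out <- matrix_to_quant(m)
  attr(out, "sample_meta") <- sample_meta
  attr(out, "incomplete") <- dplyr::bind_rows(incomplete)
  out
}

# Solve trigamma(x) = y by Newton iteration on 1/trigamma.
trigamma_inverse <- function(y) {
  if (y > 1e7) return(1 / sqrt(y))
  if (y < 1e-6) return(1 / y)
  x <- 0.5 + 1 / y
  for (i in 1:60) {
    tri <- trigamma(x)
    dif <- tri * (1 - tri / y) / psigamma(x, 2)
    x <- x + dif
    if (abs(dif) / x < 1e-10) break
  }
  x
}

#' Empirical-Bayes moderated two-group differential expression
#'
#' Moderated t-test on log2-scale abundances: the per-feature residual
#' variances are shrunk toward a common prior estimated by method of
#' moments under the scaled inverse-chi-square model (prior df `d0`, prior
#' variance `s0^2`), and the moderated t-statistic is referred to a t
#' distribution with `d0 + df_residual` degrees of freedom (capped at the
#' pooled residual df across features). `log2fc` is
#' `mean(group_b) - mean(group_a)`. As `d0` tends to infinity the test
#' approaches a z-test against the pooled prior variance.
#'
#' @param quant Wide log2-scale abundance tibble.
#' @param group_a,group_b Character vectors of sample column names (group A
#'   is the reference, e.g. control).
#' @return Object of class `radpep_de` with [tidy()] (per-feature
#'   `log2fc`, `t`, `p_value`, BH `q_value`), [glance()] (prior df and
#'   variance) and [autoplot()] (volcano) methods.
#' @export
moderated_de <- function(quant, group_a, group_b) {
  m <- quant_to_matrix(quant)
  missing_samples <- setdiff(c(group_a, group_b), colnames(m))
  if (length(missing_samples) > 0) {
    abort(paste0("samples not in quant table: ",
                 paste(missing_samples, collapse = ", ")))
  }
  if (length(group_a) < 2 || length(group_b) < 2) {
    abort("each group needs at least 2 samples")
  }
  a <- m[, group_a, drop = FALSE]
  b <- m[, group_b, drop = FALSE]
  n_a <- rowSums(!is.na(a))
  n_b <- rowSums(!is.na(b))
  mean_a <- rowMeans(a, na.rm = TRUE)
  mean_b <- rowMeans(b, na.rm = TRUE)
  var_a <- apply(a, 1, var, na.rm = TRUE)
  var_b <- apply(b, 1, var, na.rm = TRUE)
  df <- n_a + n_b - 2
  ok <- n_a >= 2 & n_b >= 2
  s2 <- ifelse(ok, ((n_a - 1) * var_a + (n_b - 1) * var_b) / df, NA)

  use <- ok & is.finite(s2) & s2 > 0
  e <- log(s2[use])
  dfu <- df[use]
  e_centered <- e - digamma(dfu / 2) + log(dfu / 2)
  target <- var(e) - mean(trigamma(dfu / 2))
  if (is.na(target) || target <= 0) {
    # under-dispersed variances: infinite prior df, arithmetic-mean scale
    d0 <- Inf
    s0_sq <- mean(s2[use])
  } else {
    d0 <- 2 * trigamma_inverse(target)
    s0_sq <- exp(mean(e_centered) + digamma(d0 / 2) - log(d0 / 2))
  }

  post_var <- if (is.infinite(d0)) rep(s0_sq, length(s2))
              else (d0 * s0_sq + df * s2) / (d0 + df)
  post_var[!ok] <- NA
  tstat <- (mean_b - mean_a) / sqrt(post_var * (1 / n_a + 1 / n_b))
  # total df capped at the pooled residual df across features
  df_total <- pmin(df + d0, sum(df[ok]))
  p <- ifelse(is.infinite(df_total), 2 * stats::pnorm(-abs(tstat)),
              2 * pt(-abs(tstat), df_total))

  table <- tibble::tibble(
    feature_id = rownames(m),
    mean_a = unname(mean_a), mean_b = unname(mean_b),
    log2fc = unname(mean_b - mean_a),
    t = unname(tstat), df_total = unname(df_total),
    p_value = unname(p), q_value = unname(p.adjust(p, "BH")),
    n_a = unname(n_a), n_b = unname(n_b)
  )
  structure(
    list(table = table, d0 = d0, s0_sq = s0_sq,
         group_a = group_a, group_b = group_b),
    class = "radpep_de"
  )
}

#' @export
print.radpep_de <- function(x, ...) {
  cat(sprintf(
    "Moderated differential expression: %d features, prior df %.3g, prior variance %.4g\n",
    nrow(x$table), x$d0, x$s0_sq
  ))
  print(x$table, ...)
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.radpep_de <- function(x, ...) x$table

#' @exportS3Method generics::glance
glance.radpep_de <- function(x, ...) {
  tibble::tibble(
    n_features = nrow(x$table), df_prior = x$d0, s2_prior = x$s0_sq,
    n_group_a = length(x$group_a), n_group_b = length(x$group_b)
  )
}

#' @exportS3Method ggplot2::autoplot
autoplot.radpep_de <- function(object, p_cut = 1e-5, lfc_cut = 1, ...) {
  d <- classify_volcano(object$table, p_cut = p_cut, lfc_cut = lfc_cut)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$log2fc, y = -log10(.data$p_value),
                                  colour = .data$volcano_class)) +
    ggplot2::geom_point(alpha = 0.6, size = 0.8) +
    ggplot2::scale_colour_manual(
      values = c(up = "firebrick", down = "steelblue", ns = "grey60")
    ) +
    ggplot2::geom_hline(yintercept = -log10(p_cut), linetype = "dashed") +
    ggplot2::geom_vline(xintercept = c(-lfc_cut, lfc_cut), linetype = "dashed") +
    ggplot2::labs(x = "log2 fold change", y = "-log10 p", colour = NULL)
}

#' Per-feature two-way ANOVA interaction test
#'
#' Balanced fixed-effects treatment x time ANOVA fitted per feature,
#' returning the interaction F statistic and p-value — the criterion used to
#' rank proteins for time-dependent treatment response. Features that lack a
#' complete design (an empty condition x time cell, or no residual degrees
#' of freedom) get `NA` and are flagged.
#'
#' @param quant Wide log-scale abundance tibble.
#' @param sample_meta Tibble `sample_id`, `condition`, `timepoint_h`
#'   (defaults to the `"sample_meta"` attribute).
#' @return Tibble `feature_id`, `f_interaction`, `df1`, `df2`,
#'   `p_interaction`, `complete_design`.
#' @export
twoway_anova <- function(quant, sample_meta = NULL) {
  sample_meta <- sample_meta %||% attr(quant, "sample_meta")
  if (is.null(sample_meta)) abort("sample metadata required")
  m <- quant_to_matrix(quant)
  meta <- sample_meta[match(colnames(m), sample_meta$sample_id), , drop = FALSE]
  condition <- factor(meta$condition)
  timepoint <- factor(meta$timepoint_h)
  x_full <- stats::model.matrix(~ condition * timepoint)
  x_red <- stats::model.matrix(~ condition + timepoint)
  df1 <- ncol(x_full) - ncol(x_red)
  df2 <- ncol(m) - ncol(x_full)
  if (df1 < 1) abort("design has no interaction term")

  rss <- function(x, y) {
    fit <- stats::lm.fit(x, y)
    colSums(as.matrix(fit$residuals)^2)
  }
  f <- p <- rep(NA_real_, nrow(m))
  complete <- rep(FALSE, nrow(m))
  full_rows <- complete.cases(m)
  if (df2 >= 1 && any(full_rows)) {
    y <- t(m[full_rows, , drop = FALSE])
    rss_full <- rss(x_full, y)
    rss_red <- rss(x_red, y)
    fval <- ((rss_red - rss_full) / df1) / (rss_full / df2)
    f[full_rows] <- fval
    p[full_rows] <- pf(fval, df1, df2, lower.tail = FALSE)
    complete[full_rows] <- TRUE
  }
  # Features with missing values: refit on available samples when the design
  # still has every cell occupied and residual df.
  for (i in which(!full_rows)) {
    obs <- !is.na(m[i, ])
    cells <- table(condition[obs], timepoint[obs])
    if (any(cells == 0)) next
    xf <- stats::model.matrix(~ condition[obs] * timepoint[obs])
    d2 <- sum(obs) - ncol(xf)
    if (d2 < 1) next
    xr <- stats::model.matrix(~ condition[obs] + timepoint[obs])
    d1 <- ncol(xf) - ncol(xr)
    rf <- sum(stats::lm.fit(xf, m[i, obs])$residuals^2)
    rr <- sum(stats::lm.fit(xr, m[i, obs])$residuals^2)
    f[i] <- ((rr - rf) / d1) / (rf / d2)
    p[i] <- pf(f[i], d1, d2, lower.tail = FALSE)
    complete[i] <- TRUE
  }
  tibble::tibble(
    feature_id = rownames(m), f_interaction = f,
    df1 = df1, df2 = df2, p_interaction = p, complete_design = complete
  )
}

#' Classify differential-expression results into volcano classes
#'
#' Labels each feature `up` (`log2fc > lfc_cut` and `p < p_cut`), `down`
#' (symmetric), or `ns`. Raw p-values are used for the classification, with
#' BH q-values reported alongside by [moderated_de()].
#'
#' @param de Tidy DE tibble with `log2fc` and `p_value` columns (e.g.
#'   `tidy(moderated_de(...))`); an optional `timepoint_h` column groups the
#'   counts.
#' @param p_cut Raw p-value cutoff (default `1e-5`, i.e. 5 on the -log10
#'   scale).
#' @param lfc_cut Absolute log2 fold-change cutoff.
#' @return Input with a `volcano_class` column; per-timepoint
#'   `(n_down, n_up, n_ns)` counts attached as the `"counts"` attribute.
#' @export
classify_volcano <- function(de, p_cut = 1e-5, lfc_cut = 1.0) {
  if (inherits(de, "radpep_de")) de <- de$table
  check_columns(de, c("log2fc", "p_value"), "DE table")
  de <- dplyr::mutate(de, volcano_class = dplyr::case_when(
    .data$log2fc > lfc_cut & .data$p_value < p_cut ~ "up",
    .data$log2fc < -lfc_cut & .data$p_value < p_cut ~ "down",
    TRUE ~ "ns"
  ))
  grouping <- if ("timepoint_h" %in% names(de)) "timepoint_h" else character(0)
  counts <- dplyr::summarise(
    dplyr::group_by(de, dplyr::across(dplyr::all_of(grouping))),
    n_down = sum(.data$volcano_class == "down"),
    n_up = sum(.data$volcano_class == "up"),
    n_ns = sum(.data$volcano_class == "ns"),
    .groups = "drop"
  )
  attr(de, "counts") <- counts
  de
}

#' Gene-set over-representation by Fisher's exact test
#'
#' Generic over-representation stand-in: a one-sided (enrichment) Fisher
#' exact test of each gene set against the chosen foreground, with BH
#' q-values. The foreground can be given directly or derived from a DE
#' table with the conventional fold-change cutoff of 0.58 log2 units
#' (1.5-fold) and p < 0.05.
#'
#' @param de DE tibble (`feature_id`, `log2fc`, `p_value`) or a character
#'   vector of foreground feature ids.
#' @param gene_sets Named list of character vectors.
#' @param background Universe of feature ids; defaults to all features of
#'   the DE table (required when `de` is a bare id vector).
#' @param lfc_cut,p_cut Foreground thresholds applied to a DE table.
#' @param direction `"up"` (increased fold change only, default), `"down"`,
#'   or `"both"`.
#' @return Tibble per set: overlap counts, `odds_ratio`, `p_value`,
#'   `q_value`.
#' @export
over_representation <- function(de, gene_sets, background = NULL,
                                lfc_cut = 0.58, p_cut = 0.05,
                                direction = c("up", "both", "down")) {
  direction <- match.arg(direction)
  if (is.character(de)) {
    foreground <- unique(de)
    if (is.null(background)) abort("background required with a bare foreground")
  } else {
    if (inherits(de, "radpep_de")) de <- de$table
    check_columns(de, c("feature_id", "log2fc", "p_value"), "DE table")
    keep <- switch(direction,
      up = de$log2fc > lfc_cut,
      down = de$log2fc < -lfc_cut,
      both = abs(de$log2fc) > lfc_cut
    ) & de$p_value < p_cut
    foreground <- unique(de$feature_id[keep & !is.na(keep)])
    background <- background %||% unique(de$feature_id)
  }
  background <- unique(background)
  foreground <- intersect(foreground, background)
  rows <- purrr::imap(gene_sets, function(set, name) {
    set <- intersect(unique(set), background)
    a <- length(intersect(foreground, set))
    b <- length(foreground) - a
    c_ <- length(set) - a
    d <- length(background) - length(foreground) - c_
    ft <- fisher.test(matrix(c(a, b, c_, d), 2, byrow = TRUE),
                      alternative = "greater")
    tibble::tibble(
      set = name, set_size = length(set),
      n_foreground = length(foreground), n_overlap = a,
      odds_ratio = unname(ft$estimate), p_value = ft$p.value
    )
  })
  out <- dplyr::bind_rows(rows)
  out$q_value <- p.adjust(out$p_value, "BH")
  dplyr::arrange(out, .data$p_value)
}
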