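test_that("top-3 roll-up sums the largest unique peptides", {
  tbl <- tibble::tibble(
    peptide = c("p1", "p2", "p3", "p4", "p5", "p6", "shared", "shared"),
    protein = c("A", "A", "A", "A", "B", "B", "A", "B"),
    s1 = c(10, 5, 2, 1, 10, 5, 100, 100)
  )
  out <- rollup_top3(tbl)
  expect_equal(out$s1[out$feature_id == "A"], 17)  # 10 + 5 + 2
  expect_equal(out$s1[out$feature_id == "B"], 15)  # fewer than 3 available
})

test_that("top-3 roll-up matches a brute-force oracle on random tables", {
  brute <- function(tbl, sample_col) {
    shared <- names(which(tapply(tbl$protein, tbl$peptide,
                                 function(p) length(unique(p))) > 1))
    tbl <- tbl[!tbl$peptide %in% shared, ]
    vapply(split(tbl[[sample_col]], tbl$protein), function(x) {
      x <- sort(x[!is.na(x)], decreasing = TRUE)
      if (length(x) == 0) NA_real_ else sum(x[seq_len(min(3, length(x)))])
    }, 0)
  }
  withr::with_seed(99, {
    for (rep in 1:200) {
      n <- sample(4:14, 1)
      tbl <- tibble::tibble(
        peptide = paste0("p", seq_len(n)),
        protein = sample(paste0("prot", 1:4), n, replace = TRUE),
        s1 = round(stats::runif(n, 0, 100), 1),
        s2 = round(stats::runif(n, 0, 100), 1)
      )
      # some shared peptides and some missing values
      if (n > 5) tbl$protein[1:2] <- c("prot1", "prot1")
      dup <- tbl[1, ]; dup$protein <- "prot2"
      tbl <- dplyr::bind_rows(tbl, dup)
      tbl$s1[sample.int(nrow(tbl), 2)] <- NA
      out <- rollup_top3(tbl)
      for (sc in c("s1", "s2")) {
        expected <- brute(tbl, sc)
        expected <- expected[!is.na(expected)]
        got <- setNames(out[[sc]], out$feature_id)[names(expected)]
        expect_equal(got, expected)
      }
      # permutation invariance in peptide order
      perm <- rollup_top3(tbl[sample.int(nrow(tbl)), ])
      expect_equal(perm, out, ignore_attr = TRUE)
    }
  })
})

test_that("scalar normalisation recovers known factors and is idempotent", {
  withr::with_seed(5, {
    base <- exp(stats::rnorm(60, 10, 1))
    scales <- c(s1 = 2, s2 = 0.5, s3 = 1)  # geometric mean 1
    q <- tibble::tibble(feature_id = paste0("f", 1:60),
                        s1 = base * 2, s2 = base * 0.5, s3 = base)
    out <- normalize_scalar(q)
    factors <- attr(out, "norm_factors")
    # the sample at twice the reference gets factor 0.5
    expect_equal(unname(factors), c(0.5, 2, 1), tolerance = 1e-9)
    # identical samples all get factor 1
    ident <- tibble::tibble(feature_id = paste0("f", 1:60),
                            s1 = base, s2 = base)
    expect_equal(unname(attr(normalize_scalar(ident), "norm_factors")),
                 c(1, 1), tolerance = 1e-12)
    # idempotence
    again <- normalize_scalar(out)
    expect_true(all(abs(attr(again, "norm_factors") - 1) < 1e-9))
  })
})

test_that("scalar normalisation needs enough shared features", {
  q <- tibble::tibble(feature_id = paste0("f", 1:5),
                      s1 = 1:5, s2 = c(1, NA, NA, NA, NA))
  expect_error(normalize_scalar(q), "fewer than 10")
})

test_that("ML imputation fills the within-group mean and flags gaps", {
  meta <- tibble::tibble(
    sample_id = c("a1", "a2", "a3", "b1", "b2"),
    condition = c("control", "control", "control", "irradiated", "irradiated"),
    timepoint_h = 24L, replicate = c(1L, 2L, 3L, 1L, 2L)
  )
  q <- tibble::tibble(
    feature_id = c("f1", "f2", "f3"),
    a1 = c(5, 4, NA), a2 = c(NA, 4, NA), a3 = c(7, 4, NA),
    b1 = c(1, 2, 3), b2 = c(NA, 2, 3)
  )
  out <- impute_mle(q, meta)
  expect_equal(out$a2[1], 6)        # EM fixed point = observed mean
  expect_equal(out$b2[1], 1)
  expect_true(is.na(out$a1[3]))     # fully missing group stays missing
  inc <- attr(out, "incomplete")
  expect_equal(inc$feature_id, "f3")
  # no missing values -> unchanged
  expect_equal(impute_mle(q, meta)$a1[2], 4)
  expect_warning(impute_mle(dplyr::mutate(q, a1 = a1 + 100), meta),
                 "log scale")
})

test_that("moderated DE matches limma on a shared fixture", {
  withr::with_seed(21, {
    m <- matrix(stats::rnorm(500 * 6, 20, 1), 500,
                dimnames = list(paste0("f", 1:500), paste0("s", 1:6)))
    m[1:20, 4:6] <- m[1:20, 4:6] + 2
    q <- tibble::as_tibble(m, rownames = "feature_id")
    de <- moderated_de(q, paste0("s", 1:3), paste0("s", 4:6))
    fit <- limma::eBayes(limma::lmFit(m, cbind(1, rep(0:1, each = 3))))
    expect_equal(de$d0, fit$df.prior, tolerance = 1e-8)
    expect_equal(de$s0_sq, fit$s2.prior, tolerance = 1e-8)
    expect_equal(de$table$log2fc, unname(fit$coefficients[, 2]))
    expect_equal(de$table$p_value, unname(fit$p.value[, 2]), tolerance = 1e-12)
  })
})

test_that("moderated DE null p-values are uniform", {
  withr::with_seed(31, {
    m <- matrix(stats::rnorm(2000 * 6, 20, 1), 2000,
                dimnames = list(paste0("f", 1:2000), paste0("s", 1:6)))
    de <- moderated_de(tibble::as_tibble(m, rownames = "feature_id"),
                       paste0("s", 1:3), paste0("s", 4:6))
    ks <- stats::ks.test(de$table$p_value, "punif")
    expect_gt(ks$p.value, 0.01)
  })
})

test_that("moderated DE recovers injected effects exactly without noise", {
  base <- rep(20, 6)
  q <- tibble::tibble(
    feature_id = c("f1", "f2"),
    s1 = c(20, 20), s2 = c(20.1, 20.1), s3 = c(19.9, 19.9),
    s4 = c(21, 20), s5 = c(21.1, 20.1), s6 = c(20.9, 19.9)
  )
  de <- moderated_de(q, c("s1", "s2", "s3"), c("s4", "s5", "s6"))
  expect_equal(de$table$log2fc, c(1, 0))
})

test_that("equal per-feature variances drive the prior df to infinity", {
  # every feature has identical within-group spread -> var(log s2) = 0
  q <- tibble::tibble(
    feature_id = paste0("f", 1:50),
    s1 = 1:50, s2 = 1:50 + 1, s3 = 51:100, s4 = 51:100 + 1
  )
  de <- moderated_de(q, c("s1", "s2"), c("s3", "s4"))
  expect_equal(de$d0, Inf)
  # in the limit the test approaches a z-test with the pooled prior variance
  # (total df is capped at the pooled residual df, here 50)
  z <- de$table$log2fc / sqrt(de$s0_sq * (1 / 2 + 1 / 2))
  expect_equal(de$table$t, z)
  expect_equal(de$table$p_value, 2 * stats::pnorm(-abs(z)), tolerance = 0.05)
})

test_that("two-way ANOVA controls type-I error under the null", {
  meta <- tidyr::expand_grid(condition = c("control", "irradiated"),
                             timepoint_h = c(0L, 24L, 48L),
                             replicate = 1:3)
  meta$sample_id <- sprintf("%s_%d_%d", meta$condition, meta$timepoint_h,
                            meta$replicate)
  withr::with_seed(17, {
    m <- matrix(stats::rnorm(5000 * nrow(meta), 20, 1), 5000,
                dimnames = list(paste0("f", 1:5000), meta$sample_id))
    q <- tibble::as_tibble(m, rownames = "feature_id")
    res <- twoway_anova(q, meta)
    expect_equal(mean(res$p_interaction < 0.05), 0.05, tolerance = 0.2)
    expect_true(abs(mean(res$p_interaction < 0.05) - 0.05) < 0.01)
  })
})

test_that("two-way ANOVA detects an injected interaction", {
  meta <- tidyr::expand_grid(condition = c("control", "irradiated"),
                             timepoint_h = c(0L, 24L, 48L),
                             replicate = 1:3)
  meta$sample_id <- sprintf("s%d", seq_len(nrow(meta)))
  withr::with_seed(23, {
    effect <- ifelse(meta$condition == "irradiated",
                     meta$timepoint_h / 24, 0)
    vals <- 20 + effect + stats::rnorm(nrow(meta), 0, 0.05)
    q <- tibble::tibble(feature_id = "f1", !!!setNames(as.list(vals),
                                                       meta$sample_id))
    res <- twoway_anova(q, meta)
    expect_lt(res$p_interaction, 1e-4)
  })
})

test_that("single-replicate designs are flagged without a result", {
  meta <- tidyr::expand_grid(condition = c("control", "irradiated"),
                             timepoint_h = c(0L, 24L), replicate = 1L)
  meta$sample_id <- sprintf("s%d", seq_len(nrow(meta)))
  q <- tibble::tibble(feature_id = "f1",
                      !!!setNames(as.list(rnorm(4)), meta$sample_id))
  res <- twoway_anova(q, meta)
  expect_true(is.na(res$p_interaction))
  expect_false(res$complete_design)
})

test_that("volcano classification respects both cutoffs and conserves counts", {
  de <- tibble::tibble(
    feature_id = c("a", "b", "c", "d"),
    log2fc = c(1.2, 1.2, -1.5, 0.2),
    p_value = c(1e-6, 1e-4, 1e-7, 1e-9)
  )
  out <- classify_volcano(de)
  expect_equal(out$volcano_class, c("up", "ns", "down", "ns"))
  counts <- attr(out, "counts")
  expect_equal(counts$n_up + counts$n_down + counts$n_ns, nrow(de))
})

test_that("over-representation equals the hypergeometric tail", {
  # 2x2 with 10/100 in the foreground vs 5/900 in the rest
  fg <- paste0("f", 1:100)
  bg <- paste0("f", 1:1000)
  set <- c(paste0("f", 1:10), paste0("b", 1:5))
  bg <- union(bg, set)
  res <- over_representation(fg, list(s = set), background = bg)
  # brute-force hypergeometric upper tail
  k <- length(intersect(fg, set))
  expected <- sum(stats::dhyper(k:length(intersect(set, bg)),
                                length(intersect(set, bg)),
                                length(bg) - length(intersect(set, bg)),
                                length(fg)))
  expect_equal(res$p_value, expected, tolerance = 1e-12)
})

test_that("random foregrounds yield no q-significant sets", {
  withr::with_seed(41, {
    bg <- paste0("f", 1:2000)
    fg <- sample(bg, 100)
    sets <- lapply(1:200, function(i) sample(bg, 40))
    names(sets) <- paste0("set", 1:200)
    res <- over_representation(fg, sets, background = bg)
    expect_lte(sum(res$q_value < 0.05), 1)
  })
})

test_that("a set equal to the foreground is maximally enriched", {
  bg <- paste0("f", 1:500)
  fg <- paste0("f", 1:30)
  res <- over_representation(fg, list(s = fg), background = bg)
  expect_lt(res$p_value, 1e-30)
})

test_that("DE-table foregrounds honour the 1.5-fold (0.58 log2) cutoff", {
  de <- tibble::tibble(
    feature_id = c("a", "b", "c"),
    log2fc = c(0.6, 0.5, 2),
    p_value = c(0.01, 0.01, 0.5)
  )
  res <- over_representation(de, list(s = c("a", "b", "c")),
                             background = de$feature_id)
  expect_equal(res$n_foreground, 1)  # only "a": lfc > 0.58 and p < 0.05
})
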