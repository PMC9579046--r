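make_records <- function(seq, score, decoy) {
  tibble::tibble(sequence = seq, search_score = score, is_decoy = decoy)
}

test_that("FDR threshold matches brute-force enumeration", {
  rec <- make_records(c("A", "B", "C", "D", "E"),
                      c(10, 9, 8, 7, 7.5),
                      c(FALSE, FALSE, FALSE, FALSE, TRUE))
  out <- fdr_filter(rec, alpha = 0.25)
  expect_equal(nrow(out), 3)  # 1/4 decoy/target ratio at t = 7 is not < 0.25
  expect_equal(attr(out, "score_threshold"), 8)
  expect_setequal(out$sequence, c("A", "B", "C"))

  # brute force over all candidate thresholds agrees
  brute <- function(rec, alpha) {
    t_sc <- tapply(rec$search_score[!rec$is_decoy],
                   rec$sequence[!rec$is_decoy], max)
    d_sc <- tapply(rec$search_score[rec$is_decoy],
                   rec$sequence[rec$is_decoy], max)
    cand <- sort(unique(t_sc))
    ok <- vapply(cand, function(t) sum(d_sc >= t) / sum(t_sc >= t) < alpha, TRUE)
    if (!any(ok)) Inf else min(cand[ok])
  }
  for (alpha in c(0.1, 0.25, 0.5, 1)) {
    out <- fdr_filter(rec, alpha = alpha)
    expect_equal(attr(out, "score_threshold"), brute(rec, alpha))
  }
})

test_that("FDR filtering is permissive at alpha = 1 and monotone in alpha", {
  withr::with_seed(7, {
    rec <- make_records(
      paste0("p", 1:300),
      c(stats::rnorm(200, 9, 1), stats::rnorm(100, 5, 1)),
      rep(c(FALSE, TRUE), c(200, 100))
    )
    all_kept <- fdr_filter(rec, alpha = 1)
    expect_equal(nrow(all_kept), 200)
    prev <- NULL
    for (alpha in c(0.5, 0.2, 0.1, 0.05, 0.01)) {
      kept <- fdr_filter(rec, alpha = alpha)$sequence
      if (!is.null(prev)) expect_true(all(kept %in% prev))
      prev <- kept
    }
  })
})

test_that("duplicate sequences collapse to their best score first", {
  rec <- make_records(c("A", "A", "B", "D1"), c(3, 10, 9, 4),
                      c(FALSE, FALSE, FALSE, TRUE))
  out <- fdr_filter(rec, alpha = 0.4)
  # A's best score (10) rescues both A records
  expect_equal(sum(out$sequence == "A"), 2)
  expect_error(fdr_filter(make_records("A", 1, FALSE)), "no decoy")
})

test_that("realized FDP stays controlled across simulations", {
  withr::with_seed(2024, {
    fdp <- replicate(100, {
      rec <- make_records(
        paste0("p", 1:1200),
        c(stats::rnorm(300, 10, 1), stats::rnorm(300, 5, 1),
          stats::rnorm(600, 5, 1)),
        rep(c(FALSE, TRUE), c(600, 600))
      )
      kept <- fdr_filter(rec, alpha = 0.01)
      if (nrow(kept) == 0) 0 else mean(kept$sequence %in% paste0("p", 301:600))
    })
    expect_lte(mean(fdp), 1.5 * 0.01)
  })
})

test_that("allele assignment takes the argmin rank with strict thresholds", {
  rec <- tibble::tibble(
    sequence = c("AYSSLVTSL", "WWWWWWWWW", "EDGECASEL"),
    `rank_H-2-Kd` = c(0.0029, 50, 0.5),
    `rank_H-2-Dd` = c(1.5, 30, 3)
  )
  out <- assign_alleles(rec)
  out <- out[match(rec$sequence, out$sequence), ]
  expect_equal(out$best_allele, c("H-2-Kd", NA, "H-2-Kd"))
  expect_equal(out$binder_class, c("strong", "non-binder", "binder"))
  expect_equal(out$best_rank, c(0.0029, 30, 0.5))
})

test_that("length distributions window and count unique sequences", {
  rec <- tibble::tibble(
    sequence = c("AAAAAAAAA", "AAAAAAAAA", "CCCCCCCCC", "DDDDDDD",
                 "EEEEEEEEEEEEE"),
    condition = c("control", "control", "control", "control", "control"),
    intensity = c(1, 2, 4, 8, 16),
    sample_id = "s1"
  )
  d <- length_distribution(rec)
  expect_equal(d$n_unique[d$length == 9], 2)       # duplicates collapse
  expect_equal(d$total_intensity[d$length == 9], 7)
  expect_equal(sum(d$n_unique), 2)                 # 7-mer and 13-mer excluded
  wide <- length_distribution(rec, max_len = 14)
  expect_equal(sum(wide$n_unique), 3)              # 13-mer now included
})

test_that("9-mers dominate the simulated length distribution", {
  cfg <- sim_config(seed = 13, rank_n_ref = 2000)
  tx <- simulate_transcriptome(cfg)
  ipp <- simulate_immunopeptidome(cfg, tx$proteome)
  d <- length_distribution(ipp$records)
  by_len <- tapply(d$n_unique, d$length, sum)
  expect_equal(as.integer(names(which.max(by_len))), 9L)
})

test_that("all-peptide roll-up keeps shared peptides in every protein", {
  rec <- tibble::tibble(
    sequence = c("AAA", "CCC", "GGG"),
    sample_id = "s1",
    intensity = c(1e5, 2e5, 5e4),
    source_proteins = c("P1", "P1", "P1;P2")
  )
  out <- rollup_all_peptides(rec)
  expect_equal(out$s1[out$feature_id == "P1"], 3.5e5)
  expect_equal(out$s1[out$feature_id == "P2"], 5e4)
  expect_equal(attr(out, "ambiguous_proteins"), c("P1", "P2"))
  # intensity over proteins >= intensity over peptides; equality iff no sharing
  expect_gte(sum(out$s1), sum(rec$intensity))
  solo <- rollup_all_peptides(rec[1:2, ])
  expect_equal(sum(solo$s1), sum(rec$intensity[1:2]))
})

test_that("condition sets identify radiation-specific peptides", {
  rec <- tibble::tibble(
    sequence = c("PEPA", "PEPB", "PEPC", "PEPA"),
    sample_id = c("ir1", "ir1", "ir2", "ctrl1"),
    condition = c("irradiated", "irradiated", "irradiated", "control"),
    timepoint_h = 24L
  )
  cs <- condition_sets(rec, expanded_controls = "PEPB")
  # PEPA is in a control sample, PEPB in the expanded pool; only PEPC remains
  expect_equal(cs$radiation_specific, "PEPC")
})

test_that("enlarging the control pool never enlarges the specific set", {
  cfg <- sim_config(seed = 29, rank_n_ref = 2000)
  tx <- simulate_transcriptome(cfg)
  ipp <- simulate_immunopeptidome(cfg, tx$proteome)
  base <- condition_sets(ipp$records)
  pooled <- condition_sets(ipp$records, ipp$pool_records)
  expect_true(all(pooled$radiation_specific %in% base$radiation_specific))
})

test_that("injected radiation-only peptides are recovered exactly", {
  cfg <- sim_config(seed = 37, rank_n_ref = 2000)
  tx <- simulate_transcriptome(cfg)
  ipp <- simulate_immunopeptidome(cfg, tx$proteome)
  cs <- condition_sets(ipp$records, ipp$pool_records)
  detected <- intersect(ipp$truth$radiation_only,
                        ipp$records$sequence[!ipp$records$is_decoy])
  expect_setequal(cs$radiation_specific, detected)
  # injected radiation-only peptides never appear in control samples
  ctrl <- ipp$records$sequence[ipp$records$condition == "control"]
  expect_length(intersect(ipp$truth$radiation_only, ctrl), 0)
})

test_that("the packaged strong-binder table yields the expected antigen analytics", {
  tbl <- ct26_radiation_peptides()
  ranked <- radiation_antigen_table(tbl)
  expect_equal(nrow(ranked), nrow(tbl))  # all rows already below rank 0.5
  expect_equal(ranked$sequence[1], "AYSSLVTSL")
  expect_equal(ranked$best_rank[1], 0.0029)
  expect_equal(attr(ranked, "multi_peptide_proteins"),
               c("ADCY7_MOUSE", "S14L1_MOUSE"))
  expect_true(all(diff(ranked$best_rank) >= 0))
  expect_equal(nrow(radiation_antigen_table(tbl[0, ])), 0)
})

test_that("motif matrices are column-normalised and recover anchors", {
  # identical peptides give a one-hot matrix
  one <- motif_matrix(tibble::tibble(sequence = rep("AYSSLVTSL", 3)))
  m <- attr(one, "matrix")
  expect_true(all(colSums(m) - 1 < 1e-12))
  expect_true(all(m %in% c(0, 1)))
  expect_equal(unname(m["Y", 2]), 1)

  cfg <- sim_config(seed = 43, rank_n_ref = 5000)
  tx <- simulate_transcriptome(cfg)
  ipp <- simulate_immunopeptidome(cfg, tx$proteome)
  asn <- assign_alleles(dplyr::filter(ipp$records, !ipp$records$is_decoy))
  mm <- motif_matrix(asn, allele = "H-2-Kd")
  freq <- attr(mm, "matrix")
  expect_equal(unname(colSums(freq)), rep(1, 9), tolerance = 1e-12)
  # configured Kd anchor: Y is the modal residue at P2
  expect_equal(names(which.max(freq[, 2])), "Y")
})

test_that("mock percent ranks are calibrated against random peptides", {
  aa20 <- c("G", "A", "S", "P", "V", "T", "C", "L", "I", "N",
            "D", "Q", "E", "K", "M", "H", "F", "R", "Y", "W")
  withr::with_seed(3, {
    random <- vapply(1:200, function(i) {
      paste(sample(aa20, 9, replace = TRUE), collapse = "")
    }, "")
  })
  ranks <- rank_peptides(random, n_ref = 5000, seed = 2)
  kd <- ranks$`rank_H-2-Kd`
  expect_true(all(kd >= 0 & kd <= 100))
  # the empirical-quantile calibration keeps strong ranks rare among
  # random peptides
  expect_lt(mean(kd < 2), 0.05)
  expect_lt(mean(kd < 0.5), 0.02)
  # an anchor-perfect peptide ranks far better than random ones
  strong <- rank_peptides("AYAAAAAAL", n_ref = 5000, seed = 2)
  expect_lt(strong$`rank_H-2-Kd`, 5)
  # ranks are monotone non-increasing in the motif score
  scored <- data.frame(rank = kd, y2 = substr(random, 2, 2) == "Y")
  expect_lt(mean(scored$rank[scored$y2]), mean(scored$rank[!scored$y2]))
})
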