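# Parental calling, non-parental frequencies, the x2 estimator, amplicon
# selection, parental flow and the replicate-level t-tests.

filtered_from_counts <- function(df) {
  frg <- df[rep(seq_len(nrow(df)), df$count),
            c("library_id", "amplicon_id", "haplotype")]
  apply_frequency_filters(count_haplotypes(frg), min_freq = 0,
                          min_samples = 1L)
}

leaf_sheet <- function(lines = "G") {
  parse_sample_sheet(data.frame(
    library_id = paste0("leaf_", lines), fastq1 = "x", fastq2 = "y",
    role = "parental_leaf", maternal_line = lines, treatment = "none",
    replicate = "0"))
}

test_that("parental haplotypes are called above the leaf threshold", {
  df <- data.frame(library_id = "leaf_G", amplicon_id = "a",
                   haplotype = c("H", "err"), count = c(980L, 20L))
  suppressWarnings(
    par <- call_parental_haplotypes(filtered_from_counts(df),
                                    leaf_sheet()))
  expect_identical(as.data.frame(par)$haplotype, "H")

  het <- data.frame(library_id = "leaf_G", amplicon_id = "a",
                    haplotype = c("H1", "H2", "err"),
                    count = c(490L, 480L, 30L))
  suppressWarnings(
    par2 <- call_parental_haplotypes(filtered_from_counts(het),
                                     leaf_sheet()))
  expect_setequal(as.data.frame(par2)$haplotype, c("H1", "H2"))

  tri <- data.frame(library_id = "leaf_G", amplicon_id = "a",
                    haplotype = c("H1", "H2", "H3"),
                    count = c(400L, 350L, 250L))
  expect_warning(
    par3 <- call_parental_haplotypes(filtered_from_counts(tri),
                                     leaf_sheet()),
    "unexpected size")
  expect_identical(nrow(as.data.frame(par3)), 3L)

  expect_error(call_parental_haplotypes(filtered_from_counts(df),
                                        leaf_sheet()[0, ]),
               "parental_leaf")
})

test_that("non-parental frequency supports both counting modes", {
  par <- parental_haplotypes(data.frame(
    maternal_line = c("G", "R"), amplicon_id = "a",
    haplotype = c("P1", "P2")))
  df <- data.frame(library_id = "s1", amplicon_id = "a",
                   haplotype = c("P1", "X"), count = c(850L, 150L))
  filt <- filtered_from_counts(df)
  expect_equal(nonparental_frequency(filt, par, "s1", "a", "G"), 0.15)

  # lines differ at the amplicon: focal counting would score the other
  # line's haplotype as outcrossing; exclude_all_parents does not
  df2 <- data.frame(library_id = "s1", amplicon_id = "a",
                    haplotype = c("P1", "P2", "X"),
                    count = c(500L, 300L, 200L))
  filt2 <- filtered_from_counts(df2)
  expect_equal(nonparental_frequency(filt2, par, "s1", "a", "G",
                                     mode = "focal_only"), 0.5)
  expect_equal(nonparental_frequency(filt2, par, "s1", "a", "G",
                                     mode = "exclude_all_parents"), 0.2)
  # focal_only >= exclude_all_parents always (same denominator)
  expect_gte(nonparental_frequency(filt2, par, "s1", "a", "G"),
             nonparental_frequency(filt2, par, "s1", "a", "G",
                                   mode = "exclude_all_parents"))

  all_par <- filtered_from_counts(data.frame(
    library_id = "s1", amplicon_id = "a", haplotype = "P1", count = 100L))
  expect_equal(nonparental_frequency(all_par, par, "s1", "a", "G"), 0)
  expect_true(is.na(nonparental_frequency(all_par, par, "s2", "a", "G")))
})

test_that("the estimate doubles the mean non-parental frequency exactly", {
  f <- setNames(rep(0.18, 8), as.character(c(1, 3, 4, 5, 8, 9, 11, 12)))
  est <- estimate_outcrossing(f)
  expect_identical(est$rate, 2 * est$mean_freq)
  expect_equal(est$rate, 0.36)
  expect_equal(estimate_outcrossing(setNames(rep(0, 3), c("a", "b", "c")))$rate,
               0)
  # permutation invariance and linearity
  perm <- sample(names(f))
  expect_equal(estimate_outcrossing(f[perm])$rate, est$rate)
  # over-unity estimates are flagged, not clamped
  over <- estimate_outcrossing(c(a = 0.6), subset = "a")
  expect_equal(over$rate, 1.2)
  expect_true("over_unity" %in% over$flags)
  # empty amplicons are dropped with a flag
  est2 <- estimate_outcrossing(c(a = 0.2, b = NA), subset = c("a", "b"))
  expect_identical(est2$subset, "a")
  expect_true(any(grepl("empty_amplicon:b", est2$flags)))
  expect_error(estimate_outcrossing(c(a = NA_real_), subset = "a"),
               "no amplicons")
  expect_error(estimate_outcrossing(c(a = 0.1), subset = "zz"), "unknown")
})

test_that("amplicon selection excludes low-signal outliers", {
  med <- c(0.15, 0.05, 0.16, 0.17, 0.14, 0.04, 0.15, 0.16)
  ft <- data.frame(library_id = "c1",
                   amplicon_id = as.character(1:8), f = med)
  got <- select_amplicons(ft, "low_outlier")
  expect_setequal(got, as.character(c(1, 3, 4, 5, 7, 8)))
  # manual passes through verbatim, unknown ids error
  ft12 <- data.frame(library_id = "c1", amplicon_id = as.character(1:12),
                     f = 0.1)
  expect_identical(select_amplicons(ft12, "manual",
                                    manual = c("1", "3", "4", "5", "8",
                                               "9", "11", "12")),
                   c("1", "3", "4", "5", "8", "9", "11", "12"))
  expect_error(select_amplicons(ft, "manual", manual = "99"), "unknown")
  # equal medians exclude nothing
  same <- data.frame(library_id = "c1", amplicon_id = as.character(1:5),
                     f = 0.2)
  expect_setequal(select_amplicons(same, "low_outlier"),
                  as.character(1:5))
})

test_that("parental flow splits the two parental haplotypes", {
  expect_equal(parental_flow(c(P1 = 300, P2 = 100, other = 50), "P1", "P2"),
               c(share_P1 = 0.75, share_P2 = 0.25))
  expect_equal(parental_flow(c(P1 = 0, P2 = 200), "P1", "P2"),
               c(share_P1 = 0, share_P2 = 1))
  none <- parental_flow(c(other = 10), "P1", "P2")
  expect_true(all(is.na(none)))
  expect_identical(attr(none, "flag"), "no_parental_fragments")
  expect_error(parental_flow(c(P1 = 1), "P1", "P1"), "disjoint")
  # oracle recount on a randomized cell
  set.seed(5)
  cnt <- setNames(rpois(6, 40), paste0("H", 1:6))
  got <- parental_flow(cnt, c("H1", "H2"), c("H3", "H4"))
  tot <- sum(cnt[c("H1", "H2", "H3", "H4")])
  expect_equal(got[["share_P1"]], sum(cnt[c("H1", "H2")]) / tot)
  expect_equal(sum(got), 1)
})

test_that("Welch test matches closed-form arithmetic and stats::t.test", {
  w <- welch_t_test(c(1, 2, 3), c(2, 3, 4))
  expect_equal(w$statistic, -sqrt(3 / 2), tolerance = 1e-12)
  expect_equal(w$df, 4)
  expect_equal(w$p.value, 0.2878641, tolerance = 1e-6)
  # independent oracle on random draws
  set.seed(3)
  for (i in 1:5) {
    a <- rnorm(sample(3:9, 1)); b <- rnorm(sample(3:9, 1), sd = 2)
    tt <- t.test(a, b)
    w <- welch_t_test(a, b)
    expect_equal(w$statistic, unname(tt$statistic), tolerance = 1e-12)
    expect_equal(w$df, unname(tt$parameter), tolerance = 1e-12)
    expect_equal(w$p.value, tt$p.value, tolerance = 1e-12)
  }
  deg <- welch_t_test(c(1, 1), c(1, 1))
  expect_equal(deg$p.value, 1)
  expect_identical(deg$flags, "degenerate_zero_variance")
  expect_equal(welch_t_test(c(2, 2), c(1, 1))$p.value, 0)
})

test_that("paired test matches stats::t.test and handles degeneracy", {
  p1 <- paired_t_test(c(0.36, 0.29, 0.25), c(0.18, 0.16, 0.35))
  tt <- t.test(c(0.36, 0.29, 0.25), c(0.18, 0.16, 0.35), paired = TRUE)
  expect_equal(p1$statistic, unname(tt$statistic), tolerance = 1e-12)
  expect_equal(p1$df, 2)
  expect_equal(p1$p.value, tt$p.value, tolerance = 1e-12)
  expect_gt(p1$p.value, 0.05)
  same <- paired_t_test(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$p.value, 1)
  # two-column matrix input
  m <- cbind(c(1, 2, 4), c(0, 1, 2))
  expect_equal(paired_t_test(m)$p.value,
               t.test(m[, 1], m[, 2], paired = TRUE)$p.value,
               tolerance = 1e-12)
})

test_that("both tests are scale invariant", {
  set.seed(9)
  a <- runif(6); b <- runif(6)
  for (k in c(2, -3, 0.5)) {
    w1 <- welch_t_test(a, b); w2 <- welch_t_test(k * a, k * b)
    expect_equal(abs(w1$statistic), abs(w2$statistic), tolerance = 1e-12)
    expect_equal(w1$df, w2$df, tolerance = 1e-12)
    expect_equal(w1$p.value, w2$p.value, tolerance = 1e-12)
    p1 <- paired_t_test(a, b); p2 <- paired_t_test(k * a, k * b)
    expect_equal(p1$p.value, p2$p.value, tolerance = 1e-12)
  }
})
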