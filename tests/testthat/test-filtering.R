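# Haplotype counting and the two frequency filters.

entries_table <- function(df) {
  # build a haplotype_table from explicit counts via fragment expansion
  frg <- df[rep(seq_len(nrow(df)), df$count), c("library_id",
                                                "amplicon_id",
                                                "haplotype")]
  count_haplotypes(frg)
}

test_that("counting is exact multiset counting with conserved totals", {
  tab <- count_haplotypes(data.frame(
    library_id = "s1", amplicon_id = "a",
    haplotype = c("H1", "H1", "H2")))
  e <- tab$entries
  expect_identical(e$count[e$haplotype == "H1"], 2L)
  expect_identical(e$count[e$haplotype == "H2"], 1L)
  expect_identical(tab$totals$raw_total, 3L)
  expect_identical(tab$totals$retained_total, 3L)

  empty <- count_haplotypes(data.frame(library_id = character(),
                                       amplicon_id = character(),
                                       haplotype = character()))
  expect_identical(nrow(empty$entries), 0L)

  set.seed(1)
  big <- data.frame(library_id = sample(c("s1", "s2"), 10000, TRUE),
                    amplicon_id = sample(c("a", "b"), 10000, TRUE),
                    haplotype = sample(paste0("H", 1:50), 10000, TRUE))
  expect_identical(sum(count_haplotypes(big)$entries$count), 10000L)
})

test_that("the 1% and single-sample rules act as specified", {
  df <- rbind(
    data.frame(library_id = "s1", amplicon_id = "a",
               haplotype = c("H1", "H2", "H3"), count = c(980L, 15L, 5L)),
    data.frame(library_id = "s2", amplicon_id = "a",
               haplotype = c("H1", "H2"), count = c(900L, 100L)))
  filt <- apply_frequency_filters(entries_table(df))
  e <- filt$entries[filt$entries$library_id == "s1", ]
  expect_identical(e$retained[e$haplotype == "H1"], TRUE)
  expect_identical(e$retained[e$haplotype == "H2"], TRUE)
  expect_identical(e$retained[e$haplotype == "H3"], FALSE)  # 0.5% < 1%
  tt <- filt$totals
  expect_identical(tt$retained_total[tt$library_id == "s1"], 995L)

  # 5% in exactly one library, absent elsewhere -> removed everywhere
  df2 <- rbind(
    data.frame(library_id = "s1", amplicon_id = "a",
               haplotype = c("H1", "J"), count = c(950L, 50L)),
    data.frame(library_id = "s2", amplicon_id = "a",
               haplotype = "H1", count = 1000L))
  filt2 <- apply_frequency_filters(entries_table(df2))
  e2 <- filt2$entries
  expect_false(any(e2$retained[e2$haplotype == "J"]))

  # exactly 1.0% is retained: the rule excludes strictly below 1%
  df3 <- rbind(
    data.frame(library_id = "s1", amplicon_id = "a",
               haplotype = c("H1", "B"), count = c(990L, 10L)),
    data.frame(library_id = "s2", amplicon_id = "a",
               haplotype = c("H1", "B"), count = c(990L, 10L)))
  filt3 <- apply_frequency_filters(entries_table(df3))
  expect_true(all(filt3$entries$retained))

  expect_error(apply_frequency_filters(filt3, min_freq = 1), "min_freq")
})

test_that("filtering is monotone, idempotent and disabled by trivial limits", {
  set.seed(11)
  df <- expand.grid(library_id = paste0("s", 1:4),
                    amplicon_id = c("a", "b"),
                    haplotype = paste0("H", 1:20),
                    stringsAsFactors = FALSE)
  df$count <- rpois(nrow(df), 12) * rbinom(nrow(df), 1, 0.6)
  df <- df[df$count > 0, ]
  tab <- entries_table(df)
  filt <- apply_frequency_filters(tab)
  # monotone: no retained total exceeds its raw total
  expect_true(all(filt$totals$retained_total <= filt$totals$raw_total))
  # idempotent
  again <- apply_frequency_filters(filt)
  expect_identical(sort(paste(filt$entries$library_id,
                              filt$entries$haplotype,
                              filt$entries$retained)),
                   sort(paste(again$entries$library_id,
                              again$entries$haplotype,
                              again$entries$retained)))
  # trivial limits return everything
  off <- apply_frequency_filters(tab, min_freq = 0, min_samples = 1L)
  expect_true(all(off$entries$retained))
  # any_count retains a superset of at_threshold
  anyc <- apply_frequency_filters(tab, presence_mode = "any_count")
  key <- function(x) paste(x$entries$library_id, x$entries$amplicon_id,
                           x$entries$haplotype)[x$entries$retained]
  expect_true(all(key(filt) %in% key(anyc)))
})

test_that("filtering matches the brute-force oracle on random tables", {
  set.seed(23)
  for (rep_i in 1:3) {
    df <- expand.grid(library_id = paste0("s", 1:5),
                      amplicon_id = c("a", "b"),
                      haplotype = paste0("H", 1:10),
                      stringsAsFactors = FALSE)
    df$count <- rnbinom(nrow(df), mu = 30, size = 0.4)
    df <- df[df$count > 0, ]
    tab <- entries_table(df)
    for (mode in c("at_threshold", "any_count")) {
      got <- apply_frequency_filters(tab, min_freq = 0.02,
                                     presence_mode = mode,
                                     min_samples = 2L)$entries
      want <- bf_filter(as.data.frame(tab$entries), min_freq = 0.02,
                        presence_mode = mode, min_samples = 2L)
      g <- got[order(got$library_id, got$amplicon_id, got$haplotype), ]
      w <- want[order(want$library_id, want$amplicon_id, want$haplotype), ]
      expect_identical(g$retained, w$retained)
    }
  }
})

test_that("filtering summary reports retained fractions", {
  df <- rbind(
    data.frame(library_id = "s1", amplicon_id = "a",
               haplotype = c("H1", "H2"), count = c(500L, 500L)),
    data.frame(library_id = "s2", amplicon_id = "a",
               haplotype = "H1", count = 100L))
  tab <- entries_table(df)
  # identical before/after -> fraction 1 everywhere
  sm <- filtering_summary(tab, tab)
  expect_true(all(sm$retained_fraction == 1))
  # H2 is private to s1 at 50% -> removed by the single-sample rule
  filt <- apply_frequency_filters(tab)
  sm2 <- filtering_summary(tab, filt)
  expect_identical(sm2$retained_fraction[sm2$library_id == "s1"], 0.5)
  expect_identical(sm2$retained_fraction[sm2$library_id == "s2"], 1)
})

test_that("haplotype tables round-trip through disk", {
  df <- data.frame(library_id = c("s1", "s1", "s2"),
                   amplicon_id = "a", haplotype = c("H1", "H2", "H1"),
                   count = c(5L, 3L, 7L))
  tab <- apply_frequency_filters(entries_table(df), min_freq = 0.3)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_haplotype_table(tab, path)
  back <- read_haplotype_table(path)
  expect_identical(as.data.frame(tab$entries), as.data.frame(back$entries))
  expect_identical(as.data.frame(tab$totals), as.data.frame(back$totals))
})
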