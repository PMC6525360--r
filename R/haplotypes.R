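# Haplotype counting and the two frequency filters that define major
# haplotypes:
#   (i)  haplotypes below the minimum frequency (default 1%) in a
#        (library x amplicon) cell are removed there (sequencing errors);
#   (ii) haplotypes that reach the threshold in fewer than `min_samples`
#        libraries of an amplicon are removed everywhere (early-cycle PCR
#        jackpot artifacts are private to one library).
# Frequencies for filtering use the pre-filter (raw) cell totals; the sums
# of the surviving fragments are the baseline for all later proportions.

new_haplotype_table <- function(entries, filtered, params = list()) {
  setcolorder(entries, c("library_id", "amplicon_id", "haplotype",
                         "count", "freq_raw", "retained"))
  entries <- entries[order(library_id, amplicon_id, -count, haplotype)]
  totals <- entries[, .(raw_total = sum(count)),
                    by = .(library_id, amplicon_id)]
  ret <- entries[retained == TRUE,
                 .(retained_total = sum(count)),
                 by = .(library_id, amplicon_id)]
  totals <- merge(totals, ret, by = c("library_id", "amplicon_id"),
                  all.x = TRUE)
  totals[is.na(retained_total), retained_total := 0L]
  structure(list(entries = entries[], totals = totals[],
                 filtered = filtered, params = params),
            class = "haplotype_table")
}

#' Count haplotype fragments per library and amplicon
#'
#' Exact multiset counting of assigned fragments. The returned table is
#' unfiltered: every haplotype is marked retained and retained totals
#' equal raw totals.
#'
#' @param fragments data.table with columns `library_id`, `amplicon_id`,
#'   `haplotype` (e.g. the `fragments` element of [assign_library()]).
#' @return A `haplotype_table`: list with `entries` (`library_id`,
#'   `amplicon_id`, `haplotype`, `count`, `freq_raw`, `retained`),
#'   `totals` (`raw_total`, `retained_total` per cell), `filtered` flag
#'   and `params`.
#' @export
count_haplotypes <- function(fragments) {
  frg <- as.data.table(fragments)
  if (nrow(frg) == 0L) {
    e <- data.table(library_id = character(), amplicon_id = character(),
                    haplotype = character(), count = integer(),
                    freq_raw = numeric(), retained = logical())
    return(new_haplotype_table(e, filtered = FALSE))
  }
  e <- frg[, .(count = .N), by = .(library_id, amplicon_id, haplotype)]
  e[, freq_raw := count / sum(count), by = .(library_id, amplicon_id)]
  e[, retained := TRUE]
  new_haplotype_table(e, filtered = FALSE)
}

#' Apply the frequency and shared-presence filters
#'
#' A haplotype is retained in cell (library, amplicon) iff (i) its raw
#' frequency in that cell is at least `min_freq`, and (ii) it satisfies
#' the presence condition for that amplicon: under
#' `presence_mode = "at_threshold"` (default) it reaches `min_freq` in at
#' least `min_samples` distinct libraries (leaf libraries count); under
#' `"any_count"` a nonzero count in `min_samples` libraries suffices.
#' Re-application is idempotent; `min_freq = 0` and `min_samples = 1`
#' disable the rules and return the unfiltered table.
#'
#' @param table A `haplotype_table`.
#' @param min_freq Minimum cell frequency, in `[0, 1)`; default 0.01.
#'   A haplotype at exactly `min_freq` is retained (only those *below*
#'   the threshold are errors by assumption).
#' @param presence_mode `"at_threshold"` or `"any_count"`.
#' @param min_samples Minimum number of libraries (default 2).
#' @return A filtered `haplotype_table`; `params$removed_fraction` holds
#'   the overall removed count mass.
#' @export
apply_frequency_filters <- function(table, min_freq = 0.01,
                                    presence_mode = c("at_threshold",
                                                      "any_count"),
                                    min_samples = 2L) {
  stopifnot(inherits(table, "haplotype_table"))
  presence_mode <- match.arg(presence_mode)
  if (!is.numeric(min_freq) || min_freq < 0 || min_freq >= 1)
    stop("min_freq must be in [0, 1)")
  e <- copy(table$entries)
  if (nrow(e) == 0L)
    return(new_haplotype_table(e, TRUE,
                               list(min_freq = min_freq,
                                    presence_mode = presence_mode,
                                    min_samples = min_samples)))
  # condition (ii) needs presence across libraries, per amplicon
  pres <- e[, .(n_at = sum(freq_raw >= min_freq), n_any = .N),
            by = .(amplicon_id, haplotype)]
  e <- merge(e, pres, by = c("amplicon_id", "haplotype"), sort = FALSE)
  # condition (i): per-cell raw frequency
  cond1 <- e$freq_raw >= min_freq
  cond2 <- if (presence_mode == "at_threshold") e$n_at >= min_samples
           else e$n_any >= min_samples
  e[, retained := cond1 & cond2]
  e[, c("n_at", "n_any") := NULL]
  removed <- e[retained == FALSE, sum(count)] / max(e[, sum(count)], 1L)
  new_haplotype_table(e, TRUE, list(min_freq = min_freq,
                                    presence_mode = presence_mode,
                                    min_samples = min_samples,
                                    removed_fraction = removed))
}

#' Retained-fraction report per library (and per cell)
#'
#' Fraction of fragments surviving the filters, the quantity the original
#' study reports per sample (around half the fragments survive at typical
#' error rates).
#'
#' @param before A `haplotype_table` (unfiltered), or a filtered one if
#'   `after` is omitted.
#' @param after The filtered `haplotype_table`; defaults to `before`
#'   when `before` is already filtered.
#' @param by `"library"` (default) or `"cell"` for per
#'   (library, amplicon) rows.
#' @return data.table with `raw_total`, `retained_total`,
#'   `retained_fraction`.
#' @export
filtering_summary <- function(before, after = NULL, by = c("library", "cell")) {
  by <- match.arg(by)
  if (is.null(after)) {
    if (!before$filtered) stop("need a filtered table")
    after <- before
  }
  tot <- merge(before$totals[, .(library_id, amplicon_id, raw_total)],
               after$totals[, .(library_id, amplicon_id, retained_total)],
               by = c("library_id", "amplicon_id"), all = TRUE)
  tot[is.na(retained_total), retained_total := 0L]
  if (by == "library")
    tot <- tot[, .(raw_total = sum(raw_total),
                   retained_total = sum(retained_total)),
               by = library_id]
  tot[, retained_fraction := ifelse(raw_total > 0,
                                    retained_total / raw_total, NA_real_)]
  tot[]
}

#' Read/write haplotype tables as long-format TSV
#'
#' @param table A `haplotype_table`.
#' @param path File path.
#' @export
write_haplotype_table <- function(table, path) {
  stopifnot(inherits(table, "haplotype_table"))
  fwrite(table$entries[, .(library_id, amplicon_id, haplotype, count,
                           freq_raw, retained)], path, sep = "\t")
  invisible(path)
}

#' @rdname write_haplotype_table
#' @param filtered Whether the file holds a filtered table.
#' @export
read_haplotype_table <- function(path, filtered = NA) {
  e <- fread(path, sep = "\t",
             colClasses = list(character = c("library_id", "amplicon_id",
                                             "haplotype")))
  if (is.na(filtered)) filtered <- any(!e$retained)
  new_haplotype_table(e, filtered)
}

#' @export
print.haplotype_table <- function(x, ...) {
  cat("haplotype_table:", nrow(x$entries), "entries over",
      nrow(x$totals), "library x amplicon cells",
      if (x$filtered) "(filtered)" else "(unfiltered)", "\n")
  invisible(x)
}
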