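# Outcrossing-rate estimation. Fragments in a seed-pool cell are parental
# (matching the maternal line's leaf haplotypes) or non-parental (evidence
# of an outcrossed paternal allele). Every outcrossed diploid seed
# contributes one maternal and one paternal allele to the pool, so the
# non-parental fragment frequency is doubled to estimate the fraction of
# outcrossed seeds. Outcrossing through pollen that carries a maternal
# haplotype is invisible: at sharing q the detectable fraction is
# (t/2)(1-q) and the estimate converges to t(1-q).

#' Call parental haplotypes from leaf libraries
#'
#' For every (maternal line, amplicon) with leaf data, the parental set is
#' the haplotypes whose retained frequency in the leaf library reaches
#' `min_parent_freq`. Near-homozygous lines yield one haplotype,
#' heterozygous ones two; sets of size 0 or > 2 are flagged.
#'
#' @param filtered A filtered `haplotype_table` including the leaf
#'   libraries.
#' @param sheet A `sample_sheet` declaring `parental_leaf` roles.
#' @param min_parent_freq Calling threshold on the retained frequency
#'   (default 0.05, well above the 1% noise floor).
#' @return A `parental_haplotypes` object: data.table (`maternal_line`,
#'   `amplicon_id`, `haplotype`) with a `warnings` attribute.
#' @export
call_parental_haplotypes <- function(filtered, sheet,
                                     min_parent_freq = 0.05) {
  stopifnot(inherits(filtered, "haplotype_table"))
  s <- as.data.table(sheet)
  leaf <- s[role == "parental_leaf"]
  if (nrow(leaf) == 0L)
    stop("no parental_leaf libraries in sheet; supply parental haplotypes ",
         "explicitly via parental_haplotypes()")
  e <- merge(filtered$entries[retained == TRUE],
             leaf[, .(library_id, maternal_line)], by = "library_id")
  # pool counts when a line has several leaf libraries
  e <- e[, .(count = sum(count)), by = .(maternal_line, amplicon_id,
                                         haplotype)]
  e[, freq := count / sum(count), by = .(maternal_line, amplicon_id)]
  called <- e[freq >= min_parent_freq,
              .(maternal_line, amplicon_id, haplotype)]
  sizes <- called[, .N, by = .(maternal_line, amplicon_id)]
  warn <- sizes[N > 2L | N == 0L]
  if (nrow(warn))
    warning("parental haplotype sets of unexpected size for: ",
            paste(warn$maternal_line, warn$amplicon_id, sep = "/",
                  collapse = ", "))
  parental_haplotypes(called, warnings = warn)
}

#' Construct parental haplotypes explicitly
#'
#' @param x data.frame with columns `maternal_line`, `amplicon_id`,
#'   `haplotype`.
#' @param warnings Optional table of flagged (line, amplicon) cells.
#' @return A `parental_haplotypes` object.
#' @export
parental_haplotypes <- function(x, warnings = NULL) {
  x <- as.data.table(x)[, .(maternal_line = as.character(maternal_line),
                            amplicon_id = as.character(amplicon_id),
                            haplotype = as.character(haplotype))]
  structure(x[], warnings = warnings,
            class = c("parental_haplotypes", "data.table", "data.frame"))
}

parental_set <- function(parents, line, amplicon) {
  p <- as.data.table(parents)
  p[maternal_line == line & amplicon_id == amplicon, haplotype]
}

#' Non-parental haplotype frequency of one cell
#'
#' Fraction of a cell's retained fragments whose haplotype is absent from
#' the focal maternal line's parental set. Under
#' `mode = "exclude_all_parents"` (appropriate for amplicons where the
#' parental lines differ, so the other line's haplotype would otherwise be
#' scored as outcrossing) the numerator additionally excludes haplotypes
#' found in any parental line; the denominator is unchanged.
#'
#' @param filtered A filtered `haplotype_table`.
#' @param parents A `parental_haplotypes` object.
#' @param library_id,amplicon_id Cell coordinates.
#' @param maternal_line Focal line of the library.
#' @param mode `"focal_only"` (default) or `"exclude_all_parents"`.
#' @return Fraction in `[0, 1]`, or `NA_real_` when the cell has no
#'   retained fragments.
#' @export
nonparental_frequency <- function(filtered, parents, library_id,
                                  amplicon_id, maternal_line,
                                  mode = c("focal_only",
                                           "exclude_all_parents")) {
  mode <- match.arg(mode)
  stopifnot(inherits(filtered, "haplotype_table"))
  lib <- library_id; amp <- amplicon_id
  cell <- filtered$entries[retained == TRUE & library_id == lib &
                             amplicon_id == amp]
  total <- sum(cell$count)
  if (total == 0L) return(NA_real_)
  focal <- parental_set(parents, maternal_line, amp)
  nonpar <- !(cell$haplotype %in% focal)
  if (mode == "exclude_all_parents") {
    all_par <- as.data.table(parents)[amplicon_id == amp, haplotype]
    nonpar <- nonpar & !(cell$haplotype %in% all_par)
  }
  sum(cell$count[nonpar]) / total
}

#' Outcrossing-rate estimate from per-amplicon frequencies
#'
#' The estimate is twice the arithmetic mean of the per-amplicon
#' non-parental frequencies over the amplicon subset: each outcrossed seed
#' contributes one detectable (paternal) and one maternal allele.
#' Estimates above 1 are flagged, never clamped.
#'
#' @param freqs Named numeric vector of per-amplicon non-parental
#'   frequencies (NA for empty amplicons).
#' @param subset Amplicon ids to average over; default all with data.
#' @param library_id Optional label.
#' @return An `outcrossing_estimate`: list with `library_id`, `freqs`,
#'   `subset`, `mean_freq`, `rate` and `flags`.
#' @export
estimate_outcrossing <- function(freqs, subset = NULL, library_id = NA) {
  if (is.null(names(freqs))) stop("freqs must be named by amplicon")
  if (is.null(subset)) subset <- names(freqs)[!is.na(freqs)]
  if (!all(subset %in% names(freqs)))
    stop("subset names unknown amplicons: ",
         paste(setdiff(subset, names(freqs)), collapse = ", "))
  flags <- character()
  empty <- subset[is.na(freqs[subset])]
  if (length(empty)) {
    flags <- c(flags, paste0("empty_amplicon:", empty))
    subset <- setdiff(subset, empty)
  }
  if (length(subset) == 0L) stop("no amplicons with data to average over")
  m <- mean(freqs[subset])
  rate <- 2 * m
  if (rate > 1) flags <- c(flags, "over_unity")
  structure(list(library_id = library_id, freqs = freqs, subset = subset,
                 mean_freq = m, rate = rate, flags = flags),
            class = "outcrossing_estimate")
}

#' @export
print.outcrossing_estimate <- function(x, ...) {
  cat("outcrossing_estimate", if (!is.na(x$library_id)) x$library_id else "",
      ": t-hat =", format(x$rate, digits = 4), "over",
      length(x$subset), "amplicons",
      if (length(x$flags)) paste0("[", paste(x$flags, collapse = ","), "]")
      else "", "\n")
  invisible(x)
}

#' Choose the amplicon subset for averaging
#'
#' Amplicons at which the maternal haplotypes are common in the pollen
#' pool underestimate outcrossing; the original study excluded three such
#' low-signal amplicons by judgment. `method = "manual"` takes an explicit
#' list; `"low_outlier"` is a heuristic stand-in that drops amplicons
#' whose median non-parental frequency across open-pollinated control
#' libraries falls below `ratio` times the overall median of the
#' amplicon medians; `"all"` (default) keeps every amplicon with data.
#'
#' @param freq_table data.table (`library_id`, `amplicon_id`, `f`) of
#'   per-cell non-parental frequencies for the control libraries.
#' @param method `"all"`, `"manual"` or `"low_outlier"`.
#' @param manual Character vector of amplicon ids for `"manual"`.
#' @param ratio Cutoff ratio for `"low_outlier"` (default 0.5).
#' @return Character vector of amplicon ids.
#' @export
select_amplicons <- function(freq_table, method = c("all", "manual",
                                                    "low_outlier"),
                             manual = NULL, ratio = 0.5) {
  method <- match.arg(method)
  ft <- as.data.table(freq_table)
  amps <- unique(ft$amplicon_id[!is.na(ft$f)])
  if (method == "manual") {
    if (is.null(manual)) stop("manual subset not given")
    manual <- as.character(manual)
    unknown <- setdiff(manual, unique(ft$amplicon_id))
    if (length(unknown))
      stop("manual subset names unknown amplicons: ",
           paste(unknown, collapse = ", "))
    return(manual)
  }
  if (method == "all") return(amps)
  med <- ft[!is.na(f), .(m = median(f)), by = amplicon_id]
  cutoff <- ratio * median(med$m)
  med[m >= cutoff, amplicon_id]
}

#' Relative flow between the two parental haplotypes
#'
#' For an amplicon where the two parental lines carry distinct haplotype
#' sets, the share of each line's haplotypes among the fragments matching
#' either set (all other haplotypes ignored).
#'
#' @param cell data.table (`haplotype`, `count`) of one cell's retained
#'   entries, or a named count vector.
#' @param p1,p2 Character vectors: the two parental haplotype sets
#'   (disjoint).
#' @return Named numeric `c(share_P1, share_P2)` summing to 1, or both
#'   `NA` with a `"no_parental_fragments"` attribute when the cell holds
#'   no parental fragments.
#' @export
parental_flow <- function(cell, p1, p2) {
  if (length(intersect(p1, p2)))
    stop("parental haplotype sets must be disjoint")
  if (is.numeric(cell) && !is.null(names(cell)))
    cell <- data.table(haplotype = names(cell), count = as.numeric(cell))
  cell <- as.data.table(cell)
  c1 <- sum(cell$count[cell$haplotype %in% p1])
  c2 <- sum(cell$count[cell$haplotype %in% p2])
  if (c1 + c2 == 0) {
    out <- c(share_P1 = NA_real_, share_P2 = NA_real_)
    attr(out, "flag") <- "no_parental_fragments"
    return(out)
  }
  c(share_P1 = c1 / (c1 + c2), share_P2 = c2 / (c1 + c2))
}
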