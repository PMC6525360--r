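# Read-to-amplicon assignment by anchored primer matching.
#
# A read belongs to an amplicon when its 5' end carries that amplicon's
# gene-specific primer (optionally preceded by the heterogeneity A/T).
# Matching is anchored at position 0 and substitution-only: the downstream
# exact-length filter would discard indel-shifted reads anyway, so indels
# are not modelled. N bases count as mismatches.

REJECT_REASONS <- c("no_forward_match", "no_reverse_match",
                    "amplicon_conflict", "wrong_length")

# character matrix of the first n_char positions of each sequence,
# space-padded so short reads never spuriously match
prefix_matrix <- function(seqs, n_char) {
  pad <- substr(paste0(seqs, strrep(" ", n_char)), 1L, n_char)
  matrix(unlist(strsplit(pad, NULL), use.names = FALSE), nrow = n_char)
}

#' Match read prefixes against primer variants of one direction
#'
#' Each read prefix is compared to every variant's match string (het_base +
#' gene_seq for heterogeneity variants, gene_seq for plain ones), anchored
#' at the first base, substitutions only. A variant hits when its mismatch
#' count is at most `floor(max_error_rate * match_length)`. Among hits the
#' one with the fewest mismatches wins; ties go to the longer match string
#' (so the heterogeneity variant beats the plain one), then to panel order.
#'
#' @param read_seq Character vector of read sequences.
#' @param variants data.table of primer variants for a single direction
#'   (rows of `panel$variants`).
#' @param max_error_rate Allowed mismatch fraction in `[0, 0.5)`;
#'   default 0.1.
#' @return data.table with one row per read: `amplicon_id` (NA when
#'   unmatched), `het_base`, `trim_length`, `mismatches`.
#' @export
match_primer <- function(read_seq, variants, max_error_rate = 0.1) {
  stopifnot(max_error_rate >= 0, max_error_rate < 0.5)
  v <- as.data.table(variants)
  if (length(unique(v$direction)) > 1L)
    stop("variants must all have the same direction")
  n <- length(read_seq)
  if (n == 0L)
    return(data.table(amplicon_id = character(), het_base = character(),
                      trim_length = integer(), mismatches = integer()))
  chm <- prefix_matrix(read_seq, max(v$match_len))
  best_key <- rep(Inf, n)
  best_idx <- rep(NA_integer_, n)
  best_mm <- rep(NA_integer_, n)
  for (i in seq_len(nrow(v))) {
    L <- v$match_len[i]
    pat <- strsplit(v$match_seq[i], NULL)[[1L]]
    mm <- .colSums(chm[seq_len(L), , drop = FALSE] != pat, L, n)
    allowed <- floor(max_error_rate * L)
    # rank: mismatches, then longer match, then variant (panel) order
    key <- mm * 1e6 + (1000L - L) * 100 + i
    hit <- mm <= allowed & key < best_key
    if (any(hit)) {
      best_key[hit] <- key[hit]
      best_idx[hit] <- i
      best_mm[hit] <- mm[hit]
    }
  }
  data.table(amplicon_id = v$amplicon_id[best_idx],
             het_base = v$het_base[best_idx],
             trim_length = v$match_len[best_idx],
             mismatches = as.integer(best_mm))
}

#' Process read pairs into haplotype fragments
#'
#' Read 1 is matched against the forward primer variants, read 2 against
#' the reverse ones; both must name the same amplicon. Primers are removed
#' (including the heterogeneity base when present); plain-matched reads
#' lose one additional 3' base so both primer versions keep
#' `read_length - plain_primer_length - 1` bases. Reads whose kept length
#' differs from that expectation are rejected. The haplotype is the
#' concatenation kept1 + kept2 in as-sequenced orientation.
#'
#' @param seq1,seq2 Character vectors of mate sequences (same length).
#' @param panel An `amplicon_panel`.
#' @param max_error_rate Passed to [match_primer()].
#' @return data.table with one row per pair: `amplicon_id`, `haplotype`
#'   and `reason` (NA for assigned pairs, otherwise one of
#'   `no_forward_match`, `no_reverse_match`, `amplicon_conflict`,
#'   `wrong_length`).
#' @export
process_read_pairs <- function(seq1, seq2, panel, max_error_rate = 0.1) {
  stopifnot(inherits(panel, "amplicon_panel"), length(seq1) == length(seq2))
  v <- panel$variants
  m1 <- match_primer(seq1, v[direction == "forward"], max_error_rate)
  m2 <- match_primer(seq2, v[direction == "reverse"], max_error_rate)

  n <- length(seq1)
  reason <- rep(NA_character_, n)
  reason[is.na(m1$amplicon_id)] <- "no_forward_match"
  sel <- is.na(reason) & is.na(m2$amplicon_id)
  reason[sel] <- "no_reverse_match"
  sel <- is.na(reason) & m1$amplicon_id != m2$amplicon_id
  reason[sel] <- "amplicon_conflict"

  exp_len <- expected_lengths(panel)
  kf <- setNames(exp_len$kept_fwd, exp_len$amplicon_id)
  kr <- setNames(exp_len$kept_rev, exp_len$amplicon_id)

  trim_keep <- function(seqs, m) {
    kept <- substr(seqs, m$trim_length + 1L, nchar(seqs))
    plain <- !is.na(m$het_base) & m$het_base == "none"
    kept[plain] <- substr(kept[plain], 1L, nchar(kept[plain]) - 1L)
    kept
  }
  k1 <- trim_keep(seq1, m1)
  k2 <- trim_keep(seq2, m2)
  ok <- is.na(reason)
  badlen <- ok & (nchar(k1) != kf[m1$amplicon_id] |
                    nchar(k2) != kr[m2$amplicon_id])
  reason[badlen] <- "wrong_length"

  hap <- rep(NA_character_, n)
  ok <- is.na(reason)
  hap[ok] <- paste0(k1[ok], k2[ok])
  data.table(amplicon_id = ifelse(is.na(reason), m1$amplicon_id,
                                  NA_character_),
             haplotype = hap, reason = reason)
}

# first whitespace token of a FASTQ name, without a trailing /1 or /2
mate_key <- function(names) sub("/[12]$", "", sub("\\s.*$", "", names))

#' Assign a library's read pairs to amplicons
#'
#' Streams both FASTQ files (plain or gzip), checks that mates are in
#' matching order, and processes every pair. Every pair is accounted for:
#' assigned counts plus per-reason rejection counts equal the total.
#'
#' @param fastq1,fastq2 Paths to the mate FASTQ files.
#' @param panel An `amplicon_panel`.
#' @param library_id Library label attached to the fragments.
#' @param max_error_rate Passed to [match_primer()].
#' @return List with `fragments` (data.table `library_id`, `amplicon_id`,
#'   `haplotype`) and `stats` (an `assignment_stats` list: `library_id`,
#'   `total`, named vector `assigned` per amplicon, named vector
#'   `rejected` per reason).
#' @export
assign_library <- function(fastq1, fastq2, panel, library_id,
                           max_error_rate = 0.1) {
  r1 <- readDNAStringSet(fastq1, format = "fastq")
  r2 <- readDNAStringSet(fastq2, format = "fastq")
  if (length(r1) != length(r2))
    stop("mate FASTQ files differ in read count")
  if (length(r1) > 0L && !identical(mate_key(names(r1)), mate_key(names(r2))))
    stop("mate FASTQ files are desynchronized (read ids differ in order)")
  res <- process_read_pairs(as.character(r1), as.character(r2), panel,
                            max_error_rate)
  frg <- res[is.na(reason), .(library_id = library_id, amplicon_id,
                              haplotype)]
  assigned <- table(factor(res$amplicon_id[is.na(res$reason)],
                           levels = panel$amplicon_ids))
  rejected <- table(factor(res$reason, levels = REJECT_REASONS))
  stats <- structure(list(library_id = library_id, total = nrow(res),
                          assigned = setNames(as.integer(assigned),
                                              names(assigned)),
                          rejected = setNames(as.integer(rejected),
                                              names(rejected))),
                     class = "assignment_stats")
  list(fragments = frg, stats = stats)
}

#' Tabulate assignment statistics across libraries
#'
#' One row per library with total pairs, fraction assigned, per-amplicon
#' assigned counts and per-reason rejection counts.
#'
#' @param stats A single `assignment_stats` or a list of them.
#' @return data.table.
#' @export
assignment_report <- function(stats) {
  if (inherits(stats, "assignment_stats")) stats <- list(stats)
  rbindlist(lapply(stats, function(s) {
    row <- data.table(library_id = s$library_id, total = s$total,
                      assigned = sum(s$assigned),
                      assigned_fraction =
                        if (s$total > 0) sum(s$assigned) / s$total else NA_real_)
    for (a in names(s$assigned)) set(row, j = paste0("amp_", a),
                                     value = s$assigned[[a]])
    for (r in names(s$rejected)) set(row, j = r, value = s$rejected[[r]])
    row
  }), fill = TRUE)
}

#' @export
print.assignment_stats <- function(x, ...) {
  cat("assignment_stats for", x$library_id, "-", x$total, "pairs,",
      sum(x$assigned), "assigned,", sum(x$rejected), "rejected\n")
  invisible(x)
}
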