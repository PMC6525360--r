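# Shared fixtures and independent brute-force oracles. The oracles are
# deliberately naive (character-by-character loops) and share no code with
# the package implementation.

# A small 3-amplicon panel with 8-nt primers and 30-nt reads: fast enough
# for property-style loops. Amplicon Z has no heterogeneity variant.
tiny_panel <- function(read_length = 30L) {
  df <- data.frame(
    amplicon_id = c("X", "X", "X", "X", "Y", "Y", "Y", "Y", "Z", "Z"),
    direction = c("forward", "reverse", "forward", "reverse",
                  "forward", "reverse", "forward", "reverse",
                  "forward", "reverse"),
    het_base = c("none", "none", "A", "A",
                 "none", "none", "T", "T", "none", "none"),
    tail_seq = rep(c("ACGTACGTAC", "TGCATGCATGC"), 5),
    gene_seq = c("ACGGTTCA", "GGATCCTA", "ACGGTTCA", "GGATCCTA",
                 "TTCAGGCA", "CATGGTAC", "TTCAGGCA", "CATGGTAC",
                 "GACCATTG", "TGGCAACT"))
  parse_primer_panel(df, read_length = read_length)
}

revcomp_chr <- function(x)
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))

random_seq <- function(n, len) {
  vapply(seq_len(n), function(i)
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE),
          collapse = ""), character(1))
}

# Brute-force anchored matcher: direct string comparison of every variant
# at every read, with the documented tie-breaks.
bf_match <- function(read_seq, variants, max_error_rate = 0.1) {
  v <- as.data.frame(variants)
  out <- data.frame(amplicon_id = rep(NA_character_, length(read_seq)),
                    trim_length = NA_integer_, mismatches = NA_integer_,
                    stringsAsFactors = FALSE)
  for (r in seq_along(read_seq)) {
    rb <- strsplit(read_seq[r], NULL)[[1L]]
    best <- NULL
    for (i in seq_len(nrow(v))) {
      pb <- strsplit(v$match_seq[i], NULL)[[1L]]
      L <- length(pb)
      if (length(rb) < L) {
        mm <- sum(head(rb, L) != head(pb, length(rb))) + (L - length(rb))
      } else {
        mm <- sum(rb[seq_len(L)] != pb)
      }
      if (mm > floor(max_error_rate * L)) next
      better <- is.null(best) || mm < best$mm ||
        (mm == best$mm && L > best$L)
      if (better) best <- list(i = i, mm = mm, L = L)
    }
    if (!is.null(best)) {
      out$amplicon_id[r] <- v$amplicon_id[best$i]
      out$trim_length[r] <- best$L
      out$mismatches[r] <- best$mm
    }
  }
  out
}

# Brute-force filter oracle: double loop over haplotypes x libraries.
bf_filter <- function(entries, min_freq = 0.01,
                      presence_mode = "at_threshold", min_samples = 2L) {
  e <- as.data.frame(entries)
  e$retained <- FALSE
  for (r in seq_len(nrow(e))) {
    cell <- e[e$library_id == e$library_id[r] &
                e$amplicon_id == e$amplicon_id[r], ]
    freq <- e$count[r] / sum(cell$count)
    if (freq < min_freq) next
    carriers <- 0L
    same <- e[e$amplicon_id == e$amplicon_id[r] &
                e$haplotype == e$haplotype[r], ]
    for (lib in unique(same$library_id)) {
      row <- same[same$library_id == lib, ]
      tot <- sum(e$count[e$library_id == lib &
                           e$amplicon_id == e$amplicon_id[r]])
      f <- sum(row$count) / tot
      if (presence_mode == "at_threshold") {
        if (f >= min_freq) carriers <- carriers + 1L
      } else if (sum(row$count) > 0) carriers <- carriers + 1L
    }
    if (carriers >= min_samples) e$retained[r] <- TRUE
  }
  e
}

# Write a pair of FASTQ files from sequence vectors.
write_test_fastq <- function(seq1, seq2, dir = NULL,
                             ids = sprintf("read%03d", seq_along(seq1))) {
  if (is.null(dir)) {
    dir <- tempfile("fq")
    dir.create(dir)
  }
  fq1 <- file.path(dir, "r1.fastq"); fq2 <- file.path(dir, "r2.fastq")
  rec <- function(seqs) {
    if (length(seqs) == 0L) return(character())
    as.vector(rbind(paste0("@", ids), seqs, rep("+", length(seqs)),
                    strrep("I", nchar(seqs))))
  }
  writeLines(rec(seq1), fq1)
  writeLines(rec(seq2), fq2)
  c(fq1, fq2)
}

# Build a valid read pair for an amplicon of a panel from an insert
# sequence, optionally using the heterogeneity variants.
make_pair <- function(panel, amplicon, insert, het_fwd = FALSE,
                      het_rev = FALSE) {
  v <- panel$variants
  pick <- function(dir, het) {
    rows <- v[v$amplicon_id == amplicon & v$direction == dir &
                (v$het_base != "none") == het, ]
    rows$match_seq[1L]
  }
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAStringSet(insert)))
  p1 <- pick("forward", het_fwd); p2 <- pick("reverse", het_rev)
  list(seq1 = paste0(p1, substr(insert, 1L, panel$read_length - nchar(p1))),
       seq2 = paste0(p2, substr(rc, 1L, panel$read_length - nchar(p2))))
}
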