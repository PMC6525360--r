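# Simplified conserved-primer design: in a population alignment of a
# single-copy gene, find fully invariant primer windows flanking a
# suitably long variable region, and emit tailed primer pairs with
# heterogeneity variants. Melting temperature uses the Wallace rule
# (2(A+T) + 4(G+C) for short oligos); thermodynamic design is out of
# scope, the module demonstrates the window-search strategy.

#' Load a population alignment from aligned FASTA
#'
#' @param path Aligned FASTA file (equal-length sequences, alphabet
#'   A/C/G/T/-/N, case-insensitive).
#' @param gene_id Label; default the file name without extension.
#' @return A `population_alignment`: list with `gene_id`, `seqs`
#'   (character vector) and `mat` (character matrix, sequences x columns).
#' @export
read_alignment <- function(path, gene_id = NULL) {
  s <- readDNAStringSet(path)
  if (is.null(gene_id))
    gene_id <- sub("\\.[^.]*$", "", basename(path))
  population_alignment(as.character(s), gene_id)
}

#' @rdname read_alignment
#' @param seqs Character vector of aligned sequences.
#' @export
population_alignment <- function(seqs, gene_id = "gene") {
  seqs <- toupper(as.character(seqs))
  if (length(seqs) < 2L) stop("alignment needs at least 2 sequences")
  if (length(unique(nchar(seqs))) != 1L)
    stop("ragged alignment: sequences differ in length")
  mat <- matrix(unlist(strsplit(seqs, NULL), use.names = FALSE),
                nrow = length(seqs), byrow = TRUE)
  if (!all(mat %in% c("A", "C", "G", "T", "-", "N")))
    stop("alignment alphabet must be A/C/G/T/-/N")
  structure(list(gene_id = gene_id, seqs = seqs, mat = mat),
            class = "population_alignment")
}

#' Per-column variability flags
#'
#' A column is `invariant` when all residues are identical and in
#' {A,C,G,T}; `gap_or_n` when any residue is `-` or `N`; otherwise
#' `polymorphic`.
#'
#' @param alignment A `population_alignment`.
#' @return Character vector, one flag per column.
#' @export
column_variability <- function(alignment) {
  stopifnot(inherits(alignment, "population_alignment"))
  m <- alignment$mat
  vapply(seq_len(ncol(m)), function(j) {
    col <- m[, j]
    if (any(col %in% c("-", "N"))) return("gap_or_n")
    if (all(col == col[1L])) "invariant" else "polymorphic"
  }, character(1))
}

wallace_tm <- function(seq) {
  b <- strsplit(seq, NULL)[[1L]]
  2 * sum(b %in% c("A", "T")) + 4 * sum(b %in% c("G", "C"))
}

#' Find candidate primer windows in an alignment
#'
#' All windows of exactly `window_len` consecutive invariant columns
#' whose GC fraction lies within `gc_bounds` and whose Wallace-rule
#' melting temperature lies within `tm_target` +/- `tm_tol` (bounds
#' inclusive).
#'
#' @param alignment A `population_alignment`.
#' @param window_len Window length in nt (default 20).
#' @param gc_bounds GC fraction bounds (default 0.4-0.6).
#' @param tm_target,tm_tol Melting-temperature target and tolerance in
#'   degrees C (defaults 55 and 5).
#' @return data.table with 1-based inclusive columns `start_col`,
#'   `end_col`, plus `seq`, `gc`, `tm`.
#' @export
find_primer_windows <- function(alignment, window_len = 20L,
                                gc_bounds = c(0.4, 0.6),
                                tm_target = 55, tm_tol = 5) {
  flags <- column_variability(alignment)
  nc <- length(flags)
  out <- list()
  consensus <- alignment$mat[1L, ]
  for (s in seq_len(max(0L, nc - window_len + 1L))) {
    e <- s + window_len - 1L
    if (!all(flags[s:e] == "invariant")) next
    wseq <- paste(consensus[s:e], collapse = "")
    gcf <- mean(strsplit(wseq, NULL)[[1L]] %in% c("G", "C"))
    tm <- wallace_tm(wseq)
    if (gcf < gc_bounds[1L] || gcf > gc_bounds[2L]) next
    if (abs(tm - tm_target) > tm_tol) next
    out[[length(out) + 1L]] <- data.table(start_col = s, end_col = e,
                                          seq = wseq, gc = gcf, tm = tm)
  }
  if (!length(out))
    return(data.table(start_col = integer(), end_col = integer(),
                      seq = character(), gc = numeric(), tm = numeric()))
  rbindlist(out)
}

#' Design a tailed primer panel from population alignments
#'
#' For each gene, chooses the forward/reverse window pair that maximizes
#' the number of polymorphic columns enclosed between the primers,
#' subject to the enclosed variable-region length lying within
#' `variable_region_bounds`. The reverse primer is the reverse complement
#' of its window. Emitted primers get the adapter tails and a
#' heterogeneity variant whose extra base alternates A/T across the
#' panel. Genes without a feasible pair are reported as undesignable.
#'
#' @param alignments A `population_alignment` or list of them.
#' @param variable_region_bounds Enclosed-length bounds in nt
#'   (default 300-400).
#' @param tails Adapter tails, named `forward`/`reverse`
#'   (default [adapter_tails()]).
#' @param window_len,gc_bounds,tm_target,tm_tol Passed to
#'   [find_primer_windows()].
#' @param read_length Passed to the emitted panel.
#' @return List with `panel` (an `amplicon_panel` of the designable
#'   genes, or NULL when none) and `report` (data.table per gene:
#'   feasibility, chosen windows, enclosed length, enclosed polymorphic
#'   columns, forward Tm).
#' @export
design_panel <- function(alignments, variable_region_bounds = c(300, 400),
                         tails = adapter_tails(), window_len = 20L,
                         gc_bounds = c(0.4, 0.6), tm_target = 55,
                         tm_tol = 5, read_length = 150L) {
  if (inherits(alignments, "population_alignment"))
    alignments <- list(alignments)
  report <- list(); rows <- list()
  het_cycle <- c("A", "T")
  n_emitted <- 0L
  for (aln in alignments) {
    flags <- column_variability(aln)
    win <- find_primer_windows(aln, window_len, gc_bounds, tm_target,
                               tm_tol)
    best <- NULL
    if (nrow(win) >= 2L) {
      poly_cum <- cumsum(flags == "polymorphic")
      for (i in seq_len(nrow(win))) {
        for (j in seq_len(nrow(win))) {
          enc_s <- win$end_col[i] + 1L
          enc_e <- win$start_col[j] - 1L
          enc_len <- enc_e - enc_s + 1L
          if (enc_len < variable_region_bounds[1L] ||
                enc_len > variable_region_bounds[2L]) next
          npoly <- poly_cum[enc_e] - poly_cum[enc_s - 1L]
          if (is.null(best) || npoly > best$npoly)
            best <- list(i = i, j = j, npoly = npoly, len = enc_len)
        }
      }
    }
    if (is.null(best)) {
      report[[length(report) + 1L]] <- data.table(
        gene_id = aln$gene_id, designable = FALSE,
        fwd_start = NA_integer_, fwd_end = NA_integer_,
        rev_start = NA_integer_, rev_end = NA_integer_,
        enclosed_length = NA_integer_, enclosed_polymorphic = NA_integer_,
        fwd_tm = NA_real_)
      next
    }
    n_emitted <- n_emitted + 1L
    het <- het_cycle[(n_emitted - 1L) %% 2L + 1L]
    fwd_seq <- win$seq[best$i]
    rev_seq <- revcomp(win$seq[best$j])
    rows[[length(rows) + 1L]] <- data.table(
      amplicon_id = aln$gene_id,
      direction = c("forward", "reverse", "forward", "reverse"),
      het_base = c("none", "none", het, het),
      tail_seq = unname(tails[c("forward", "reverse", "forward",
                                "reverse")]),
      gene_seq = c(fwd_seq, rev_seq, fwd_seq, rev_seq))
    report[[length(report) + 1L]] <- data.table(
      gene_id = aln$gene_id, designable = TRUE,
      fwd_start = win$start_col[best$i], fwd_end = win$end_col[best$i],
      rev_start = win$start_col[best$j], rev_end = win$end_col[best$j],
      enclosed_length = best$len, enclosed_polymorphic = best$npoly,
      fwd_tm = win$tm[best$i])
  }
  panel <- if (length(rows))
    parse_primer_panel(rbindlist(rows), read_length = read_length)
  else NULL
  list(panel = panel, report = rbindlist(report))
}
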