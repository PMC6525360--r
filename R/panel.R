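# Amplicon panel: gene-specific primer pairs (plain + heterogeneity variants)
# with adapter tails. The panel fixes the coordinate system of read trimming:
# every read keeps read_length - plain_primer_length - 1 bases after primer
# removal, regardless of which primer variant generated it.

#' Adapter tails used by the bundled Capsella panel
#'
#' The 33-nt forward and 34-nt reverse sequences complementary to the
#' indexing primers. They sit upstream of the gene-specific primer sequence
#' in the synthesized oligo and are not part of the sequenced insert.
#'
#' @return Named character vector with elements `forward` and `reverse`.
#' @export
adapter_tails <- function() {
  c(forward = "TCGTCGGCAGCGTCAGATGTGTATAAGAGACAG",
    reverse = "GTCTCGTGGGCTCGGAGATGTGTATAAGAGACAG")
}

#' Parse an amplicon primer panel
#'
#' Reads a tab-separated table (or takes a data.frame) with columns
#' `amplicon_id`, `direction` (`forward`/`reverse`), `het_base`
#' (`none`, `A` or `T`), `tail_seq` and `gene_seq`, validates it and
#' returns an `amplicon_panel` object. The heterogeneity variant of a primer
#' carries a single A or T between tail and gene-specific sequence; its
#' effective match string against a read is `het_base + gene_seq`.
#'
#' @param panel A file path or a data.frame with the columns above.
#' @param read_length Sequencing read length in nt (default 150).
#' @return An object of class `amplicon_panel`: a list with `variants`
#'   (a data.table with one row per primer variant, including the derived
#'   `match_seq`/`match_len` columns used for read matching) and
#'   `read_length`.
#' @export
parse_primer_panel <- function(panel, read_length = 150L) {
  if (is.character(panel) && length(panel) == 1L) {
    if (!file.exists(panel)) stop("panel file not found: ", panel)
    panel <- fread(panel, sep = "\t", colClasses = "character")
  }
  v <- as.data.table(panel)
  need <- c("amplicon_id", "direction", "het_base", "tail_seq", "gene_seq")
  if (!all(need %in% names(v)))
    stop("panel table must have columns: ", paste(need, collapse = ", "))
  v <- v[, ..need]
  for (col in need) set(v, j = col, value = as.character(v[[col]]))
  v[is.na(het_base) | het_base == "", het_base := "none"]

  if (any(v$gene_seq != toupper(v$gene_seq) | v$tail_seq != toupper(v$tail_seq))) {
    message("panel contains lowercase sequence; converting to uppercase")
    v[, `:=`(gene_seq = toupper(gene_seq), tail_seq = toupper(tail_seq))]
  }
  if (!all(v$direction %in% c("forward", "reverse")))
    stop("direction must be 'forward' or 'reverse'")
  if (!all(v$het_base %in% c("none", "A", "T")))
    stop("het_base must be 'none', 'A' or 'T'")
  if (any(!nzchar(v$gene_seq)) || any(grepl("[^ACGT]", v$gene_seq)))
    stop("gene_seq must be non-empty over the alphabet {A,C,G,T}")
  if (any(grepl("[^ACGT]", v$tail_seq)))
    stop("tail_seq must be over the alphabet {A,C,G,T}")
  if (anyDuplicated(v[, .(amplicon_id, direction, het_base)]))
    stop("duplicate (amplicon_id, direction, het_base) rows in panel")

  # the study's tails have fixed lengths; validate when they are in use
  tails <- adapter_tails()
  bad <- v[tail_seq %in% tails & nchar(tail_seq) !=
             ifelse(direction == "forward", 33L, 34L)]
  if (nrow(bad) > 0L) stop("study adapter tail used in the wrong direction")

  ids <- unique(v$amplicon_id)
  for (id in ids) {
    for (d in c("forward", "reverse")) {
      if (nrow(v[amplicon_id == id & direction == d & het_base == "none"]) == 0L)
        stop("amplicon ", id, " lacks a plain ", d, " primer variant")
    }
  }

  v[, match_seq := ifelse(het_base == "none", gene_seq,
                          paste0(het_base, gene_seq))]
  v[, match_len := nchar(match_seq)]
  v[, plain := het_base == "none"]
  v[, amplicon_id := factor(amplicon_id, levels = ids)]
  setorder(v, amplicon_id, direction, plain)  # het (plain=FALSE) first
  v[, amplicon_id := as.character(amplicon_id)]

  read_length <- as.integer(read_length)
  plain_len <- v[plain == TRUE,
                 .(len = nchar(gene_seq)), by = .(amplicon_id, direction)]
  if (any(read_length - plain_len$len - 1L <= 0L))
    stop("expected trimmed length must be positive; read_length too short")

  structure(list(variants = v[], read_length = read_length,
                 amplicon_ids = ids),
            class = "amplicon_panel")
}

#' Build a panel table from full primer strings
#'
#' Splits synthesized full primers (tail + optional heterogeneity base +
#' gene-specific sequence) into panel columns, given the known adapter
#' tails. Each primer must start with the tail of its direction and, for
#' heterogeneity variants, continue with the declared A/T base.
#'
#' @param primers data.frame with columns `amplicon_id`, `direction`,
#'   `het_base`, `full_primer`.
#' @param tails Named character vector of tails (`forward`, `reverse`).
#' @param read_length Passed to [parse_primer_panel()].
#' @return An `amplicon_panel`.
#' @export
panel_from_full_primers <- function(primers, tails = adapter_tails(),
                                    read_length = 150L) {
  p <- as.data.table(primers)
  p[, full_primer := toupper(full_primer)]
  p[is.na(het_base) | het_base == "", het_base := "none"]
  tail_seq <- unname(tails[p$direction])
  if (any(substr(p$full_primer, 1L, nchar(tail_seq)) != tail_seq))
    stop("full primer does not start with the declared adapter tail")
  rest <- substr(p$full_primer, nchar(tail_seq) + 1L, nchar(p$full_primer))
  het <- p$het_base != "none"
  if (any(het & substr(rest, 1L, 1L) != p$het_base))
    stop("heterogeneity base in primer does not match het_base column")
  gene <- ifelse(het, substr(rest, 2L, nchar(rest)), rest)
  parse_primer_panel(data.table(amplicon_id = p$amplicon_id,
                                direction = p$direction,
                                het_base = p$het_base,
                                tail_seq = tail_seq, gene_seq = gene),
                     read_length = read_length)
}

#' Write a panel back to a tab-separated file
#'
#' Writing then re-parsing yields an identical panel.
#'
#' @param panel An `amplicon_panel`.
#' @param path Output file path.
#' @export
write_primer_panel <- function(panel, path) {
  stopifnot(inherits(panel, "amplicon_panel"))
  fwrite(panel$variants[, .(amplicon_id, direction, het_base, tail_seq,
                            gene_seq)],
         path, sep = "\t")
  invisible(path)
}

#' The bundled Capsella primer panel
#'
#' The 12 gene-specific primer pairs (plus heterogeneity variants for all
#' amplicons except 10, which failed amplification in the original screen)
#' with their adapter tails.
#'
#' @param read_length Sequencing read length (default 150).
#' @return An `amplicon_panel`.
#' @export
capsella_panel <- function(read_length = 150L) {
  parse_primer_panel(system.file("extdata", "capsella_primer_panel.tsv",
                                 package = "poolcross", mustWork = TRUE),
                     read_length = read_length)
}

# plain gene-specific primer length per (amplicon, direction)
plain_primer_length <- function(panel, amplicon_id, direction) {
  v <- panel$variants
  v$match_len[v$amplicon_id == amplicon_id & v$direction == direction &
                v$plain]
}

#' Expected kept read length after primer trimming
#'
#' For every read of an amplicon, the kept length is
#' `read_length - plain_primer_length - 1`: heterogeneity-matched reads lose
#' the extra A/T with the primer, plain-matched reads lose one additional
#' 3' base so both primer versions yield identical lengths.
#'
#' @param panel An `amplicon_panel`.
#' @param amplicon_id Amplicon identifier(s); default all.
#' @return data.table with columns `amplicon_id`, `kept_fwd`, `kept_rev`,
#'   `fragment_length`.
#' @export
expected_lengths <- function(panel, amplicon_id = NULL) {
  stopifnot(inherits(panel, "amplicon_panel"))
  ids <- if (is.null(amplicon_id)) panel$amplicon_ids else amplicon_id
  out <- data.table(amplicon_id = ids)
  out[, kept_fwd := vapply(amplicon_id, function(a)
    panel$read_length - plain_primer_length(panel, a, "forward") - 1L,
    integer(1))]
  out[, kept_rev := vapply(amplicon_id, function(a)
    panel$read_length - plain_primer_length(panel, a, "reverse") - 1L,
    integer(1))]
  out[, fragment_length := kept_fwd + kept_rev]
  out[]
}

#' @export
print.amplicon_panel <- function(x, ...) {
  cat("amplicon_panel:", length(x$amplicon_ids), "amplicons,",
      nrow(x$variants), "primer variants, read_length", x$read_length, "\n")
  invisible(x)
}
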