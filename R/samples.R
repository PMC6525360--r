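# Sample sheet: one row per sequencing library. Roles are restricted to
# seed_pool (pooled progeny of one maternal line x treatment x replicate)
# and parental_leaf (leaf tissue of a maternal line, used to call the
# parental haplotypes).

#' Parse an experiment sample sheet
#'
#' @param sheet A tab-separated file path or a data.frame with columns
#'   `library_id`, `fastq1`, `fastq2`, `role`, `maternal_line`,
#'   `treatment`, `replicate`.
#' @param check_paths If TRUE, error when a referenced FASTQ file does not
#'   exist on disk (default FALSE so sheets can be built before
#'   simulation output exists).
#' @return A `sample_sheet` (data.table subclass).
#' @export
parse_sample_sheet <- function(sheet, check_paths = FALSE) {
  if (is.character(sheet) && length(sheet) == 1L) {
    if (!file.exists(sheet)) stop("sample sheet file not found: ", sheet)
    sheet <- fread(sheet, sep = "\t", colClasses = "character")
  }
  s <- as.data.table(sheet)
  need <- c("library_id", "fastq1", "fastq2", "role", "maternal_line",
            "treatment", "replicate")
  if (nrow(s) == 0L) {
    warning("empty sample sheet")
    s <- data.table(library_id = character(), fastq1 = character(),
                    fastq2 = character(), role = character(),
                    maternal_line = character(), treatment = character(),
                    replicate = character())
    return(structure(s, class = c("sample_sheet", class(s))))
  }
  if (!all(need %in% names(s)))
    stop("sample sheet must have columns: ", paste(need, collapse = ", "))
  s <- s[, ..need]
  for (col in need) set(s, j = col, value = as.character(s[[col]]))
  if (anyDuplicated(s$library_id)) stop("duplicate library_id in sheet")
  if (!all(s$role %in% c("seed_pool", "parental_leaf")))
    stop("role must be 'seed_pool' or 'parental_leaf', got: ",
         paste(setdiff(s$role, c("seed_pool", "parental_leaf")),
               collapse = ", "))
  if (any(is.na(s$fastq1) | !nzchar(s$fastq1) |
            is.na(s$fastq2) | !nzchar(s$fastq2)))
    stop("every library needs both FASTQ paths")
  if (check_paths) {
    missing <- setdiff(c(s$fastq1, s$fastq2), "")
    missing <- missing[!file.exists(missing)]
    if (length(missing))
      stop("FASTQ file(s) not found: ", paste(missing, collapse = ", "))
  }
  orphan <- setdiff(s[role == "seed_pool", unique(maternal_line)],
                    s[role == "parental_leaf", unique(maternal_line)])
  if (length(orphan))
    warning("no parental_leaf library for maternal line(s) ",
            paste(orphan, collapse = ", "),
            "; estimation will require explicit parental haplotypes")
  structure(s[], class = c("sample_sheet", "data.table", "data.frame"))
}

#' Write a sample sheet
#' @param sheet A `sample_sheet`.
#' @param path Output path.
#' @export
write_sample_sheet <- function(sheet, path) {
  fwrite(as.data.table(sheet), path, sep = "\t")
  invisible(path)
}
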