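# End-to-end orchestration: FASTQ -> assignment -> counting -> filtering
# -> parental calling -> per-amplicon non-parental frequencies ->
# outcrossing estimates -> replicate-level statistics. Deterministic given
# inputs and configuration; every intermediate can be written to disk.

#' Run the full estimation pipeline
#'
#' @param panel An `amplicon_panel` or a panel file path.
#' @param sheet A `sample_sheet` or a sheet file path.
#' @param out_dir Optional directory; when given, every intermediate
#'   table is written there as TSV.
#' @param max_error_rate Primer-match mismatch fraction (default 0.1).
#' @param min_freq,presence_mode,min_samples Filter parameters, see
#'   [apply_frequency_filters()].
#' @param min_parent_freq Parental-call threshold, see
#'   [call_parental_haplotypes()].
#' @param amplicons Optional manual amplicon subset for averaging;
#'   default all amplicons with data (`select_method` is then ignored).
#' @param select_method `"all"` (default) or `"low_outlier"`; used when
#'   `amplicons` is NULL. Control libraries for `"low_outlier"` are the
#'   seed pools of `control_treatment` (default: all seed pools).
#' @param control_treatment Treatment label of open-pollinated controls.
#' @param parents Optional explicit `parental_haplotypes`; default
#'   called from the sheet's leaf libraries.
#' @param mode Non-parental counting mode: `"auto"` (default) switches
#'   to `exclude_all_parents` for amplicons where the declared parental
#'   lines' haplotype sets differ, `"focal_only"` or
#'   `"exclude_all_parents"` force one mode everywhere.
#' @return List with `stats_assignment` (data.table),
#'   `haplotypes_raw` and `haplotypes` (unfiltered/filtered
#'   `haplotype_table`), `filter_summary`, `parents`, `frequencies`
#'   (per library x amplicon non-parental frequency), `subset`,
#'   `estimates` (data.table: library, genotype, treatment, replicate,
#'   outcrossing rate, flags, plus per-amplicon frequency columns) and
#'   `tests` (the [run_stats()] report).
#' @export
run_estimate <- function(panel, sheet, out_dir = NULL,
                         max_error_rate = 0.1, min_freq = 0.01,
                         presence_mode = "at_threshold", min_samples = 2L,
                         min_parent_freq = 0.05, amplicons = NULL,
                         select_method = "all", control_treatment = NULL,
                         parents = NULL,
                         mode = c("auto", "focal_only",
                                  "exclude_all_parents")) {
  mode <- match.arg(mode)
  if (!inherits(panel, "amplicon_panel")) panel <- parse_primer_panel(panel)
  if (!inherits(sheet, "sample_sheet"))
    sheet <- parse_sample_sheet(sheet, check_paths = TRUE)
  s <- as.data.table(sheet)

  res <- lapply(seq_len(nrow(s)), function(i)
    assign_library(s$fastq1[i], s$fastq2[i], panel, s$library_id[i],
                   max_error_rate))
  fragments <- rbindlist(lapply(res, `[[`, "fragments"))
  stats_tab <- assignment_report(lapply(res, `[[`, "stats"))

  raw <- count_haplotypes(fragments)
  filtered <- apply_frequency_filters(raw, min_freq = min_freq,
                                      presence_mode = presence_mode,
                                      min_samples = min_samples)
  fsummary <- filtering_summary(raw, filtered)

  if (is.null(parents))
    parents <- call_parental_haplotypes(filtered, sheet, min_parent_freq)

  # per-amplicon counting mode
  p <- as.data.table(parents)
  amp_mode <- setNames(rep("focal_only", length(panel$amplicon_ids)),
                       panel$amplicon_ids)
  if (mode == "exclude_all_parents") {
    amp_mode[] <- "exclude_all_parents"
  } else if (mode == "auto" && length(unique(p$maternal_line)) > 1L) {
    div <- p[, .(key = paste(sort(haplotype), collapse = "|")),
             by = .(amplicon_id, maternal_line)][
               , .(differs = uniqueN(key) > 1L), by = amplicon_id]
    for (a in div[differs == TRUE, amplicon_id]) {
      amp_mode[a] <- "exclude_all_parents"
      message("amplicon ", a,
              ": parental lines differ; counting non-parental as ",
              "haplotypes absent from every parental line")
    }
  }

  pools <- s[role == "seed_pool"]
  grid <- CJ(library_id = pools$library_id,
             amplicon_id = panel$amplicon_ids, sorted = FALSE)
  grid <- merge(grid, pools[, .(library_id, maternal_line)],
                by = "library_id", sort = FALSE)
  grid[, f := mapply(function(lib, a, line)
    nonparental_frequency(filtered, parents, lib, a, line,
                          mode = amp_mode[[a]]),
    library_id, amplicon_id, maternal_line)]
  freqs <- grid[, .(library_id, amplicon_id, f)]

  if (!is.null(amplicons)) {
    subset <- select_amplicons(freqs, "manual", manual = amplicons)
  } else if (select_method == "low_outlier") {
    ctl <- if (is.null(control_treatment)) pools$library_id
           else pools[treatment == control_treatment, library_id]
    subset <- select_amplicons(freqs[library_id %in% ctl], "low_outlier")
  } else {
    subset <- select_amplicons(freqs, "all")
  }

  est_rows <- lapply(pools$library_id, function(lib) {
    fv <- setNames(freqs[library_id == lib, f],
                   freqs[library_id == lib, amplicon_id])
    est <- estimate_outcrossing(fv, subset = intersect(subset, names(fv)),
                                library_id = lib)
    meta <- pools[library_id == lib]
    row <- data.table(library_id = lib, genotype = meta$maternal_line,
                      treatment = meta$treatment,
                      replicate = meta$replicate,
                      outcrossing_rate = est$rate,
                      mean_nonparental = est$mean_freq,
                      n_amplicons = length(est$subset),
                      flags = paste(est$flags, collapse = ";"))
    for (a in names(fv)) set(row, j = paste0("f_", a), value = fv[[a]])
    row
  })
  estimates <- rbindlist(est_rows, fill = TRUE)
  tests <- run_stats(estimates)

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    fwrite(stats_tab, file.path(out_dir, "assignment_stats.tsv"),
           sep = "\t")
    write_haplotype_table(filtered,
                          file.path(out_dir, "haplotypes_filtered.tsv"))
    fwrite(fsummary, file.path(out_dir, "filter_summary.tsv"), sep = "\t")
    fwrite(p, file.path(out_dir, "parental_haplotypes.tsv"), sep = "\t")
    fwrite(freqs, file.path(out_dir, "nonparental_frequencies.tsv"),
           sep = "\t")
    fwrite(estimates, file.path(out_dir, "outcrossing_estimates.tsv"),
           sep = "\t")
    fwrite(tests, file.path(out_dir, "statistics.tsv"), sep = "\t")
  }

  list(stats_assignment = stats_tab, haplotypes_raw = raw,
       haplotypes = filtered, filter_summary = fsummary,
       parents = parents, frequencies = freqs, subset = subset,
       estimates = estimates, tests = tests)
}

#' Replicate-level statistical comparisons of outcrossing estimates
#'
#' For every pair of treatments, a Welch two-sample t-test on the
#' estimates; within every treatment with two genotypes, a paired t-test
#' between genotypes, paired by replicate. Groups with fewer than two
#' values are skipped with a note. Raw p-values are reported (no
#' multiple-testing correction, matching the original analysis);
#' `bonferroni = TRUE` adds an adjusted column.
#'
#' @param estimates data.frame with at least the grouping columns and
#'   `value_col`.
#' @param treatment_col,genotype_col,replicate_col,value_col Column
#'   names (defaults match [run_estimate()] output).
#' @param bonferroni Add Bonferroni-adjusted p-values (default FALSE).
#' @return data.table: `test`, `group_a`, `group_b`, `n_a`, `n_b`, `t`,
#'   `df`, `p`, `note`.
#' @export
run_stats <- function(estimates, treatment_col = "treatment",
                      genotype_col = "genotype",
                      replicate_col = "replicate",
                      value_col = "outcrossing_rate",
                      bonferroni = FALSE) {
  e <- as.data.table(estimates)
  for (col in c(treatment_col, genotype_col, replicate_col, value_col))
    if (!col %in% names(e)) stop("column not found: ", col)
  rows <- list()
  trts <- unique(e[[treatment_col]])
  if (length(trts) >= 2L) {
    for (i in seq_len(length(trts) - 1L)) for (j in (i + 1L):length(trts)) {
      a <- e[e[[treatment_col]] == trts[i]][[value_col]]
      b <- e[e[[treatment_col]] == trts[j]][[value_col]]
      if (length(a) < 2L || length(b) < 2L) {
        rows[[length(rows) + 1L]] <- data.table(
          test = "welch", group_a = trts[i], group_b = trts[j],
          n_a = length(a), n_b = length(b), t = NA_real_, df = NA_real_,
          p = NA_real_, note = "skipped: group size < 2")
        next
      }
      w <- welch_t_test(a, b)
      rows[[length(rows) + 1L]] <- data.table(
        test = "welch", group_a = trts[i], group_b = trts[j],
        n_a = length(a), n_b = length(b), t = w$statistic, df = w$df,
        p = w$p.value, note = paste(w$flags, collapse = ";"))
    }
  }
  for (tr in trts) {
    sub <- e[e[[treatment_col]] == tr]
    gts <- sort(unique(sub[[genotype_col]]))
    if (length(gts) != 2L) next
    a <- sub[sub[[genotype_col]] == gts[1L]]
    b <- sub[sub[[genotype_col]] == gts[2L]]
    reps <- intersect(a[[replicate_col]], b[[replicate_col]])
    if (length(reps) < 2L) {
      rows[[length(rows) + 1L]] <- data.table(
        test = paste0("paired[", tr, "]"), group_a = gts[1L],
        group_b = gts[2L], n_a = length(reps), n_b = length(reps),
        t = NA_real_, df = NA_real_, p = NA_real_,
        note = "skipped: fewer than 2 shared replicates")
      next
    }
    av <- a[[value_col]][match(reps, a[[replicate_col]])]
    bv <- b[[value_col]][match(reps, b[[replicate_col]])]
    pt_ <- paired_t_test(av, bv)
    rows[[length(rows) + 1L]] <- data.table(
      test = paste0("paired[", tr, "]"), group_a = gts[1L],
      group_b = gts[2L], n_a = length(reps), n_b = length(reps),
      t = pt_$statistic, df = pt_$df, p = pt_$p.value,
      note = paste(pt_$flags, collapse = ";"))
  }
  out <- rbindlist(rows)
  if (bonferroni) out[, p_bonferroni := pmin(1, p * .N)]
  out[]
}

#' Simulate an experiment (pipeline wrapper)
#'
#' Thin wrapper over [simulate_experiment()] for symmetry with
#' [run_estimate()].
#'
#' @param config A `simulation_config`.
#' @param dir Output directory.
#' @return See [simulate_experiment()].
#' @export
run_simulate <- function(config, dir) simulate_experiment(config, dir)

#' The original field trial's published outcrossing-rate table
#'
#' Twelve estimates (two genotypes x bird/insect net x three replicates)
#' as printed, used as input for the statistics reproduction.
#'
#' @return data.table with columns `genotype`, `net`, `replicate`,
#'   `outcrossing_rate`.
#' @export
capsella_field_rates <- function() {
  fread(system.file("extdata", "field_outcrossing_rates.tsv",
                    package = "poolcross", mustWork = TRUE),
        sep = "\t",
        colClasses = list(character = c("genotype", "net", "replicate")))
}
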