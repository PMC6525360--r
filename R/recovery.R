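# Replicated end-to-end recovery runs: simulate -> assign -> filter ->
# estimate, collecting the per-library outcrossing estimates against the
# known truth. Used for validating the estimator (the mean estimate
# converges to t(1-q)) and for power exploration.

#' Replicated pipeline recovery simulations
#'
#' Runs `n_sims` independent simulated experiments (each with
#' `replicates` seed pools of one maternal line plus its leaf library)
#' through the full pipeline and returns every library's outcrossing
#' estimate next to the simulation truth. Under haplotype sharing `q`
#' the estimates converge to `t * (1 - q)`, the detectable outcrossing
#' rate.
#'
#' @param n_sims Number of independent simulations (default 20).
#' @param t True outcrossing rate (default 0.3).
#' @param q Maternal-haplotype sharing in the pollen pool (default 0).
#' @param seed Base RNG seed; simulation `i` uses `seed * 1000 + i`.
#' @param replicates Seed pools per simulation (default 3, one block
#'   each).
#' @param reads_per_amplicon,n_seeds,error_rate,amplicons,panel Passed
#'   to [simulation_config()].
#' @param ... Further [simulation_config()] overrides.
#' @return data.table with one row per (simulation, seed-pool library):
#'   `sim`, `library_id`, `t_hat`, `t_true`, `expected` (`t * (1 - q)`).
#' @export
simulate_recovery <- function(n_sims = 20L, t = 0.3, q = 0, seed = 1L,
                              replicates = 3L,
                              reads_per_amplicon = 2000L, n_seeds = 300L,
                              error_rate = 0.005,
                              amplicons = c("1", "3", "4", "5", "8", "9",
                                            "11", "12"),
                              panel = capsella_panel(), ...) {
  rows <- vector("list", n_sims)
  for (i in seq_len(n_sims)) {
    cfg <- simulation_config(seed = as.integer(seed) * 1000L + i,
                             panel = panel, amplicons = amplicons,
                             n_seeds = n_seeds,
                             reads_per_amplicon = reads_per_amplicon,
                             error_rate = error_rate, q = q,
                             genotypes = "CNL1_G",
                             treatments = list(open = t),
                             replicates = replicates, ...)
    dir <- tempfile("recovery")
    sim <- simulate_experiment(cfg, dir)
    res <- run_estimate(panel, sim$sheet)
    rows[[i]] <- data.table(sim = i,
                            library_id = res$estimates$library_id,
                            t_hat = res$estimates$outcrossing_rate,
                            t_true = t, expected = t * (1 - q))
    unlink(dir, recursive = TRUE)
  }
  rbindlist(rows)
}
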