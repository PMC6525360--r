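# Simulator of pooled-progeny amplicon sequencing. Each seed pool holds
# n_seeds diploid seeds of one maternal line; every seed carries one
# maternal allele plus a paternal allele that is maternal again (selfed,
# probability 1 - t) or drawn from the pollen-donor pool (outcrossed,
# probability t). A donor allele equals the maternal haplotype with the
# sharing probability q_a, so the expected detectable non-parental allele
# fraction is (t/2)(1 - q_a). Reads sample alleles uniformly, carry the
# gene-specific primer (het and plain variants with equal probability),
# per-base substitution errors, and optionally a sample-private jackpot
# haplotype in a configurable frequency band.

random_dna <- function(n, len) {
  vapply(seq_len(n), function(i)
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE),
          collapse = ""), character(1))
}

revcomp <- function(x) as.character(reverseComplement(DNAStringSet(x)))

#' Simulation configuration
#'
#' Defaults emulate the original field trial: two maternal genotypes under
#' two treatments (open pollination vs insect exclusion) in three
#' replicated blocks, pools of 300 seeds, 150-nt paired reads over
#' amplicons whose variable region is 260 nt (about 300 bp with primers),
#' and a pollen-donor pool carrying two distinct non-maternal haplotypes
#' per amplicon.
#'
#' @param seed RNG seed (integer).
#' @param panel An `amplicon_panel`; default the bundled Capsella panel.
#' @param amplicons Amplicon ids to simulate; default the study's
#'   eight-amplicon averaging subset.
#' @param insert_length Variable-region length in nt (default 260).
#' @param n_seeds Seeds per pool (default 300).
#' @param reads_per_amplicon Read pairs per amplicon per library
#'   (default 2000).
#' @param error_rate Per-base substitution error probability
#'   (default 0.005).
#' @param q Maternal-haplotype sharing in the donor pool: scalar or named
#'   per-amplicon vector of probabilities (default 0).
#' @param n_donor_haplotypes Distinct non-maternal donor haplotypes per
#'   amplicon. Default 2: the field trial's pollen donors were two SAP
#'   near-isogenic lines (sharing one background haplotype away from the
#'   SAP locus) and one inbred C. grandiflora-like line.
#' @param treatments Named list mapping treatment label to true
#'   outcrossing rate t (default `list(bird = 0.3, insect = 0)`).
#' @param genotypes Maternal line labels (default CNL1_G, CNL1_R).
#' @param replicates Number of replicate blocks (default 3).
#' @param jackpot_prob Probability that a (library, amplicon) cell
#'   receives one private PCR-jackpot haplotype (default 0.2).
#' @param jackpot_range Frequency band of the jackpot haplotype
#'   (default 1-5%).
#' @param maternal_efficiency Relative amplification efficiency of
#'   maternal alleles versus all others (default 1, no bias). Values
#'   away from 1 exercise the caveat that even slight amplification
#'   biases between haplotypes distort pooled frequency estimates.
#' @param heterozygous_lines Genotype labels simulated as heterozygous
#'   (two maternal haplotypes per amplicon); default none (qILs are
#'   near-homozygous).
#' @param divergent_amplicons Amplicon ids at which the two maternal
#'   lines carry different haplotypes (the amplicon-6 situation);
#'   default none.
#' @param compress Write gzip FASTQ (default FALSE).
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(seed = 1L, panel = capsella_panel(),
                              amplicons = c("1", "3", "4", "5", "8", "9",
                                            "11", "12"),
                              insert_length = 260L, n_seeds = 300L,
                              reads_per_amplicon = 2000L,
                              error_rate = 0.005, q = 0,
                              n_donor_haplotypes = 2L,
                              treatments = list(bird = 0.3, insect = 0),
                              genotypes = c("CNL1_G", "CNL1_R"),
                              replicates = 3L,
                              jackpot_prob = 0.2,
                              jackpot_range = c(0.01, 0.05),
                              maternal_efficiency = 1,
                              heterozygous_lines = character(),
                              divergent_amplicons = character(),
                              compress = FALSE) {
  stopifnot(inherits(panel, "amplicon_panel"),
            all(amplicons %in% panel$amplicon_ids),
            insert_length > 0, n_seeds > 0, reads_per_amplicon > 0,
            error_rate >= 0, error_rate < 1,
            all(unlist(treatments) >= 0), all(unlist(treatments) <= 1),
            jackpot_prob >= 0, jackpot_prob <= 1,
            length(jackpot_range) == 2L)
  qv <- if (length(q) == 1L) setNames(rep(q, length(amplicons)), amplicons)
        else q[amplicons]
  if (any(is.na(qv)) || any(qv < 0) || any(qv > 1))
    stop("q must give a probability for every simulated amplicon")
  # every plain-matched read must be fillable from the insert
  max_plain <- max(panel$variants[plain == TRUE & amplicon_id %in% amplicons,
                                  nchar(gene_seq)])
  if (insert_length < panel$read_length - min(
        panel$variants[plain == TRUE & amplicon_id %in% amplicons,
                       nchar(gene_seq)]))
    stop("insert_length too short to fill a plain-primer read")
  structure(list(seed = as.integer(seed), panel = panel,
                 amplicons = amplicons,
                 insert_length = as.integer(insert_length),
                 n_seeds = as.integer(n_seeds),
                 reads_per_amplicon = as.integer(reads_per_amplicon),
                 error_rate = error_rate, q = qv,
                 n_donor_haplotypes = as.integer(n_donor_haplotypes),
                 treatments = treatments, genotypes = genotypes,
                 replicates = as.integer(replicates),
                 jackpot_prob = jackpot_prob,
                 jackpot_range = jackpot_range,
                 maternal_efficiency = maternal_efficiency,
                 heterozygous_lines = heterozygous_lines,
                 divergent_amplicons = divergent_amplicons,
                 compress = compress),
            class = "simulation_config")
}

# Maternal haplotypes per (line, amplicon) and the non-maternal donor pool
# per amplicon, drawn from the current RNG stream.
simulate_founders <- function(config) {
  amps <- config$amplicons
  lines <- config$genotypes
  maternal <- list()
  base <- setNames(random_dna(length(amps), config$insert_length), amps)
  for (ln in lines) {
    m <- base
    div <- intersect(config$divergent_amplicons, amps)
    if (ln != lines[1L] && length(div))
      m[div] <- random_dna(length(div), config$insert_length)
    hap2 <- if (ln %in% config$heterozygous_lines)
      setNames(random_dna(length(amps), config$insert_length), amps)
    else m
    maternal[[ln]] <- list(h1 = m, h2 = hap2)
  }
  donors <- lapply(setNames(amps, amps), function(a)
    random_dna(config$n_donor_haplotypes, config$insert_length))
  list(maternal = maternal, donors = donors)
}

#' Simulate the allele pool of one seed library
#'
#' Draws the outcrossed/selfed status of each seed once (it is a property
#' of the seed, shared across amplicons), then the paternal allele per
#' amplicon: maternal under selfing, and under outcrossing maternal with
#' probability `q_a` (sharing) or one of the non-maternal donor
#' haplotypes otherwise.
#'
#' @param config A `simulation_config`.
#' @param founders Output of the internal founder generator; when NULL a
#'   fresh founder set is drawn.
#' @param line Maternal genotype label.
#' @param t True outcrossing rate of this library.
#' @return List with `alleles` (per amplicon, character vector of
#'   `2 * n_seeds` alleles) and `truth` (data.table per amplicon:
#'   realized non-parental allele count and fraction, expected detectable
#'   fraction `(t/2)(1-q)`).
#' @export
simulate_seed_pool <- function(config, line, t, founders = NULL) {
  stopifnot(inherits(config, "simulation_config"), t >= 0, t <= 1)
  if (is.null(founders)) founders <- simulate_founders(config)
  amps <- config$amplicons
  n <- config$n_seeds
  mat <- founders$maternal[[line]]
  outcrossed <- runif(n) < t
  alleles <- list(); truth <- list()
  for (a in amps) {
    m1 <- mat$h1[[a]]; m2 <- mat$h2[[a]]
    mat_set <- unique(c(m1, m2))
    # maternal allele of each seed: one of the line's haplotypes
    maternal_allele <- ifelse(runif(n) < 0.5, m1, m2)
    # paternal allele: selfed seeds re-draw from the maternal pair
    paternal <- ifelse(runif(n) < 0.5, m1, m2)
    k <- sum(outcrossed)
    if (k > 0L) {
      shared <- runif(k) < config$q[[a]]
      # the pollen cloud includes the other maternal line's plants: at
      # divergent amplicons their haplotype is a legitimate donor allele
      donor_set <- founders$donors[[a]]
      if (a %in% config$divergent_amplicons)
        donor_set <- unique(c(donor_set, vapply(founders$maternal,
                                                function(x)
                                                  x$h1[[a]], "")))
      donor_set <- setdiff(donor_set, mat_set)
      donor <- sample(donor_set, k, replace = TRUE)
      pat_out <- ifelse(shared,
                        ifelse(runif(k) < 0.5, m1, m2),
                        donor)
      paternal[outcrossed] <- pat_out
    }
    alleles[[a]] <- c(maternal_allele, paternal)
    nonpar <- sum(!(alleles[[a]] %in% mat_set))
    truth[[a]] <- data.table(amplicon_id = a, q = config$q[[a]],
                             nonparental_alleles = nonpar,
                             nonparental_fraction = nonpar / (2 * n),
                             expected_detectable = t / 2 * (1 - config$q[[a]]))
  }
  list(alleles = alleles, truth = rbindlist(truth))
}

# vectorized per-base substitution errors at the given rate
add_substitution_errors <- function(seqs, rate) {
  if (rate <= 0 || length(seqs) == 0L) return(seqs)
  L <- nchar(seqs)
  stopifnot(length(unique(L)) == 1L)
  L <- L[1L]
  k <- rbinom(length(seqs), L, rate)
  idx <- which(k > 0L)
  if (!length(idx)) return(seqs)
  pos_list <- lapply(k[idx], function(m) sample.int(L, m))
  bases <- c("A", "C", "G", "T")
  maxk <- max(k)
  for (j in seq_len(maxk)) {
    sel <- which(vapply(pos_list, length, integer(1)) >= j)
    if (!length(sel)) break
    ii <- idx[sel]
    pp <- vapply(pos_list[sel], `[`, integer(1), j)
    old <- substr(seqs[ii], pp, pp)
    # substitute with a uniformly drawn *different* base
    shift <- sample.int(3L, length(ii), replace = TRUE)
    new <- bases[(match(old, bases) - 1L + shift) %% 4L + 1L]
    substr(seqs[ii], pp, pp) <- new
  }
  seqs
}

#' Simulate read pairs for one amplicon of one library
#'
#' Reads sample alleles uniformly with replacement. Read 1 carries the
#' forward primer (heterogeneity or plain variant with equal probability
#' when both exist) followed by the leading insert bases; read 2 carries
#' the reverse primer followed by the reverse complement of the insert.
#' Substitution errors apply to every base at `error_rate`; qualities are
#' the constant "I". A jackpot artifact, when injected, replaces a
#' uniform fraction of read slots (drawn from `jackpot_range`) with one
#' private random haplotype.
#'
#' @param alleles Character vector of allele (insert) sequences.
#' @param config A `simulation_config`.
#' @param amplicon_id The amplicon being sequenced.
#' @param library_id Label used in read ids.
#' @param inject_jackpot Overrides the config's jackpot coin flip;
#'   NULL (default) draws with `jackpot_prob`.
#' @param weights Optional per-allele sampling weights (relative
#'   amplification efficiencies); NULL for uniform sampling.
#' @return List with `id`, `seq1`, `seq2`, `jackpot` (the injected
#'   haplotype sequence or NA).
#' @export
simulate_reads <- function(alleles, config, amplicon_id, library_id,
                           inject_jackpot = NULL, weights = NULL) {
  stopifnot(inherits(config, "simulation_config"))
  nr <- config$reads_per_amplicon
  rl <- config$panel$read_length
  amp <- amplicon_id  # local alias: the column would shadow the argument
  v <- config$panel$variants
  v <- v[v[["amplicon_id"]] == amp]
  if (nrow(v) == 0L) stop("amplicon not in panel: ", amplicon_id)
  picks <- sample(alleles, nr, replace = TRUE, prob = weights)

  jack <- NA_character_
  do_jack <- if (is.null(inject_jackpot)) runif(1) < config$jackpot_prob
             else inject_jackpot
  if (do_jack) {
    jack <- random_dna(1L, config$insert_length)
    f <- runif(1, config$jackpot_range[1L], config$jackpot_range[2L])
    nj <- max(1L, round(f * nr))
    picks[sample.int(nr, nj)] <- jack
  }

  build_mate <- function(insert, dir) {
    vd <- v[direction == dir]
    het <- vd[plain == FALSE]
    plain_row <- vd[plain == TRUE]
    use_het <- if (nrow(het)) runif(length(insert)) < 0.5 else
      rep(FALSE, length(insert))
    primer <- ifelse(use_het, het$match_seq[1L], plain_row$match_seq[1L])
    fill <- rl - nchar(primer)
    paste0(primer, substr(insert, 1L, fill))
  }
  seq1 <- build_mate(picks, "forward")
  seq2 <- build_mate(revcomp(picks), "reverse")
  seq1 <- add_substitution_errors(seq1, config$error_rate)
  seq2 <- add_substitution_errors(seq2, config$error_rate)
  list(id = sprintf("%s:%s:%06d", library_id, amplicon_id, seq_len(nr)),
       seq1 = seq1, seq2 = seq2, jackpot = jack)
}

write_fastq_pair <- function(id, seq1, seq2, fq1, fq2, compress) {
  qual <- BStringSet(strrep("I", nchar(seq1)))
  s1 <- DNAStringSet(seq1); names(s1) <- id
  s2 <- DNAStringSet(seq2); names(s2) <- id
  writeXStringSet(s1, fq1, format = "fastq", qualities = qual,
                  compress = compress)
  writeXStringSet(s2, fq2, format = "fastq", qualities = qual,
                  compress = compress)
}

#' Simulate a full pooled-progeny sequencing experiment
#'
#' Generates per-library paired FASTQ files, a sample sheet and a truth
#' table under `dir`. The default design is
#' `genotypes x treatments x replicates` seed pools plus one leaf library
#' per maternal line (14 libraries with the defaults). Leaf libraries
#' sequence the maternal haplotypes only. Identical seeds give identical
#' output.
#'
#' @param config A `simulation_config`.
#' @param dir Output directory (created if needed).
#' @return List with `sheet` (a `sample_sheet`), `truth` (data.table:
#'   library, amplicon, t, q, realized and expected non-parental
#'   fractions, injected jackpot), `founders`, `dir`.
#' @export
simulate_experiment <- function(config, dir) {
  stopifnot(inherits(config, "simulation_config"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(config$seed)
  founders <- simulate_founders(config)
  ext <- if (config$compress) ".fastq.gz" else ".fastq"

  sheet_rows <- list(); truth_rows <- list()
  emit_library <- function(library_id, role, line, treatment, replicate,
                           alleles, truth) {
    ids <- c(); s1 <- c(); s2 <- c()
    for (a in config$amplicons) {
      w <- if (config$maternal_efficiency != 1) {
        mat <- founders$maternal[[line]]
        ifelse(alleles[[a]] %in% c(mat$h1[[a]], mat$h2[[a]]),
               config$maternal_efficiency, 1)
      } else NULL
      rd <- simulate_reads(alleles[[a]], config, a, library_id,
                           weights = w)
      ids <- c(ids, rd$id); s1 <- c(s1, rd$seq1); s2 <- c(s2, rd$seq2)
      if (!is.null(truth))
        truth[amplicon_id == a, jackpot := rd$jackpot]
    }
    ord <- sample.int(length(ids))  # shuffle amplicons together
    fq1 <- file.path(dir, paste0(library_id, "_R1", ext))
    fq2 <- file.path(dir, paste0(library_id, "_R2", ext))
    write_fastq_pair(ids[ord], s1[ord], s2[ord], fq1, fq2, config$compress)
    sheet_rows[[length(sheet_rows) + 1L]] <<- data.table(
      library_id = library_id, fastq1 = fq1, fastq2 = fq2, role = role,
      maternal_line = line, treatment = treatment,
      replicate = as.character(replicate))
    if (!is.null(truth))
      truth_rows[[length(truth_rows) + 1L]] <<- truth
  }

  for (line in config$genotypes) {
    for (tr in names(config$treatments)) {
      t <- config$treatments[[tr]]
      for (rep_i in seq_len(config$replicates)) {
        lib <- paste(line, tr, rep_i, sep = "_")
        pool <- simulate_seed_pool(config, line, t, founders)
        tru <- copy(pool$truth)
        tru[, `:=`(library_id = lib, t = t, jackpot = NA_character_)]
        emit_library(lib, "seed_pool", line, tr, rep_i, pool$alleles, tru)
      }
    }
  }
  for (line in config$genotypes) {
    mat <- founders$maternal[[line]]
    alleles <- lapply(setNames(config$amplicons, config$amplicons),
                      function(a) c(mat$h1[[a]], mat$h2[[a]]))
    lib <- paste0(line, "_leaf")
    tru <- data.table(amplicon_id = config$amplicons,
                      q = unname(config$q[config$amplicons]),
                      nonparental_alleles = 0L, nonparental_fraction = 0,
                      expected_detectable = 0, library_id = lib, t = 0,
                      jackpot = NA_character_)
    emit_library(lib, "parental_leaf", line, "none", 0, alleles, tru)
  }

  sheet <- parse_sample_sheet(rbindlist(sheet_rows), check_paths = TRUE)
  truth <- rbindlist(truth_rows)
  setcolorder(truth, c("library_id", "amplicon_id", "t", "q"))
  write_sample_sheet(sheet, file.path(dir, "sample_sheet.tsv"))
  fwrite(truth, file.path(dir, "truth.tsv"), sep = "\t")
  list(sheet = sheet, truth = truth[], founders = founders, dir = dir)
}
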