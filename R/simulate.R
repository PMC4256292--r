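#' Simulation configuration
#'
#' Parameters for the synthetic-data generators. Defaults describe the
#' study conditions the analysis modules are pointed at: a forward-mutation
#' reporter assayed by ~24 parallel cultures grown to 1e7 cells, a
#' wild-type overall mutation rate of 4.2e-7 per locus per generation, and
#' sequencing of 173 independent mutant isolates per strain. The propensity
#' parameters encode the mechanistic model: misinsertion of an
#' excess dNTP opposite a pyrimidine-rich template is strongly favoured,
#' mismatches are stabilised by rapid extension when downstream incorporations
#' also draw on excess dNTPs, and slippage indels in homopolymer runs
#' increase exponentially with run length. Mismatch repair is modelled as a
#' per-category retention probability (1 / true correction factor):
#' efficient at A:T-run indels (CF ~300), much weaker at G:C-run indels
#' (CF ~10), intermediate at substitutions.
#'
#' @param seed Integer seed; mandatory, every stochastic call is seeded.
#' @param true_rate Mutation rate per locus per generation (raw scale, e.g.
#'   `4.2e-7`). For [simulate_spectrum()] this is the pre-repair error rate.
#' @param n_initial,n_final Cells per culture at inoculation and plating.
#' @param n_cultures Number of parallel cultures per fluctuation experiment.
#' @param n_isolates Number of mutant isolates sequenced per strain.
#' @param plating_fraction Fraction of each culture plated.
#' @param sub_weight Baseline propensity of any single-base substitution,
#'   per site and template-strand pathway. The default is calibrated so
#'   that, on a ~2 kb locus under the default pyrimidine excess, single-base
#'   indels and substitutions contribute comparably to the spectrum —
#'   indels the major class, as observed under this pool imbalance.
#' @param excess_mult Multiplier when the misinserted dNTP is in the excess
#'   set.
#' @param extension_mult Multiplier per downstream template base (of the
#'   next 3) whose complementary dNTP is in the excess set (mismatch
#'   extension support).
#' @param indel_slope Exponential slope of slippage propensity per unit run
#'   length.
#' @param indel_next_excess_mult Multiplier when the nucleotide incorporated
#'   immediately past the run is in the excess set.
#' @param deletion_fraction Fraction of run slippage events that are
#'   deletions (the rest are insertions).
#' @param mmr_retention Named numeric: probability that an error of each
#'   category (`substitution`, `indel_AT`, `indel_GC`, `complex`) escapes
#'   mismatch repair; all in \[0, 1\].
#' @param multi_mutation_rate Probability that a sequenced isolate carries a
#'   second mutation.
#' @return An object of class `SimulationConfig`.
#' @export
sim_config <- function(seed,
                       true_rate = 4.2e-7,
                       n_initial = 10, n_final = 1e7, n_cultures = 24,
                       n_isolates = 173, plating_fraction = 1,
                       sub_weight = 0.01, excess_mult = 50, extension_mult = 2,
                       indel_slope = 0.9, indel_next_excess_mult = 2,
                       deletion_fraction = 0.8,
                       mmr_retention = c(substitution = 1 / 50,
                                         indel_AT = 1 / 300,
                                         indel_GC = 1 / 10,
                                         complex = 1),
                       multi_mutation_rate = 0.05) {
  if (missing(seed) || !is.finite(seed)) stop2("seed is mandatory")
  stopifnot(true_rate >= 0, n_final > n_initial, n_initial > 0,
            n_cultures >= 2, n_isolates >= 1,
            plating_fraction > 0, plating_fraction <= 1,
            sub_weight > 0, excess_mult >= 1, extension_mult >= 1,
            indel_next_excess_mult >= 1,
            deletion_fraction >= 0, deletion_fraction <= 1,
            all(mmr_retention >= 0), all(mmr_retention <= 1),
             multi_mutation_rate >= 0, multi_mutation_rate <= 1)
  structure(as.list(environment()), class = "SimulationConfig")
}

#' Simulate a Luria-Delbruck fluctuation experiment
#'
#' Each culture grows by deterministic doubling from `n_initial` to
#' `n_final` cells. At each generation, the number of new mutational events
#' is Poisson with mean (cells dividing) x (rate per division); a mutant
#' arising at generation g of G contributes a clone of `2^(G - g)` resistant
#' cells at plating, giving the characteristic heavy-tailed ("jackpot")
#' count distribution whose zero class has probability `exp(-m)`.
#'
#' @param config A [sim_config()].
#' @return A [fluctuation_experiment()] with one count per culture.
#' @examples
#' expt <- simulate_fluctuation(sim_config(seed = 1, n_cultures = 30))
#' estimate_rate(expt)
#' @export
simulate_fluctuation <- function(config) {
  stopifnot(inherits(config, "SimulationConfig"))
  set.seed(config$seed)
  G <- ceiling(log2(config$n_final / config$n_initial))
  n0 <- config$n_final / 2^G   # back-computed so growth is exactly G doublings
  counts <- numeric(config$n_cultures)
  for (g in seq_len(G)) {
    dividing <- n0 * 2^(g - 1)
    k <- stats::rpois(config$n_cultures, dividing * config$true_rate)
    counts <- counts + k * 2^(G - g)
  }
  if (config$plating_fraction < 1) {
    counts <- stats::rbinom(length(counts), size = counts,
                            prob = config$plating_fraction)
  }
  fluctuation_experiment(counts, n_final = config$n_final,
                         plating_fraction = config$plating_fraction)
}

# Per-error-mode propensity table for a locus under a pool imbalance.
# One row per (site, change); substitution weight sums the two template
# strand pathways, each pathway scored as
#   sub_weight * excess_mult^[misinserted dNTP in E]
#              * extension_mult^(# of 3 downstream template bases whose
#                                complementary dNTP is in E)
# and run indels as exp(indel_slope * L) * next_mult^[next dNTP in E] per
# strand, split deletion_fraction / (1 - deletion_fraction) into -/+ rows.
.propensity_table <- function(locus, pools, config) {
  bases <- strsplit(locus$coding_sequence, "", fixed = TRUE)[[1]]
  n <- length(bases)
  E <- excess_set(pools)
  in_E <- function(b) !is.na(b) & b %in% E
  comp_in_E <- function(b) !is.na(b) & comp_base(b) %in% E

  # extension support per position for each template-strand pathway
  shift <- function(x, k) {
    if (k > 0) c(rep(NA, k), x[seq_len(n - k)]) else c(x[-seq_len(-k)], rep(NA, -k))
  }
  cnt_cod <- cnt_non <- numeric(n)
  for (k in 1:3) {
    cnt_cod <- cnt_cod + as.numeric(comp_in_E(shift(bases, k)))   # p-1..p-3
    cnt_non <- cnt_non + as.numeric(in_E(shift(bases, -k)))       # p+1..p+3
  }
  ext_cod <- config$extension_mult^cnt_cod
  ext_non <- config$extension_mult^cnt_non

  alts <- c("A", "C", "G", "T")
  sub_rows <- list()
  for (a in alts) {
    pos <- which(bases != a)
    mis_cod <- comp_base(a)   # coding-template pathway misinserts comp(alt)
    mis_non <- a              # noncoding-template pathway misinserts alt
    w_cod <- ifelse(rep(in_E(mis_cod), length(pos)), config$excess_mult, 1) *
      ext_cod[pos]
    w_non <- ifelse(rep(in_E(mis_non), length(pos)), config$excess_mult, 1) *
      ext_non[pos]
    sub_rows[[a]] <- data.frame(
      position = pos, ref = bases[pos], alt = a,
      category = "substitution",
      weight = config$sub_weight * (w_cod + w_non),
      stringsAsFactors = FALSE)
  }
  tab <- do.call(rbind, sub_rows)

  runs <- annotate_runs(locus$coding_sequence, min_len = 2)
  if (nrow(runs)) {
    w_run <- numeric(nrow(runs))
    for (i in seq_len(nrow(runs))) {
      s <- runs$start[i]; e <- runs$end[i]
      base_w <- exp(config$indel_slope * runs$length[i])
      nd_cod <- if (s > 1L) comp_base(bases[s - 1L]) else NA_character_
      nd_non <- if (e < n) bases[e + 1L] else NA_character_
      w <- 0
      for (nd in c(nd_cod, nd_non)) {
        if (!is.na(nd)) {
          w <- w + base_w * if (in_E(nd)) config$indel_next_excess_mult else 1
        }
      }
      w_run[i] <- w
    }
    cat_run <- ifelse(runs$base %in% c("A", "T"), "indel_AT", "indel_GC")
    del <- data.frame(position = runs$start, ref = runs$base, alt = "",
                      category = cat_run,
                      weight = w_run * config$deletion_fraction,
                      stringsAsFactors = FALSE)
    ins <- data.frame(position = runs$start, ref = "", alt = runs$base,
                      category = cat_run,
                      weight = w_run * (1 - config$deletion_fraction),
                      stringsAsFactors = FALSE)
    tab <- rbind(tab, del[del$weight > 0, ], ins[ins$weight > 0, ])
  }
  if (!nrow(tab) || sum(tab$weight) <= 0) stop2("zero total error propensity")
  rownames(tab) <- NULL
  tab
}

# weights: sampling distribution for the extra (multi-mutation) events;
# for a repair-proficient strain this must be the repair-thinned
# distribution, not the raw propensities.
.events_from_rows <- function(tab, idx, strain, multi_rate, weights = tab$weight) {
  n_iso <- length(idx)
  iso <- sprintf("iso%04d", seq_len(n_iso))
  n_extra <- stats::rbinom(1, n_iso, multi_rate)
  if (n_extra > 0) {
    extra_idx <- sample(nrow(tab), n_extra, replace = TRUE, prob = weights)
    idx <- c(idx, extra_idx)
    iso <- c(iso, sample(iso, n_extra, replace = TRUE))
  }
  data.frame(strain = strain, isolate = iso,
             position = tab$position[idx], ref = tab$ref[idx],
             alt = tab$alt[idx], stringsAsFactors = FALSE)
}

#' Simulate paired MMR-proficient / MMR-deficient mutation spectra
#'
#' Builds the per-site error propensity table for the locus under the given
#' pools (see [sim_config()] for the mechanistic parameters), then samples
#' `n_isolates` errors for the repair-deficient strain directly from the
#' raw propensities, and for the repair-proficient strain by thinning: each
#' drawn error escapes repair with its category's retention probability and
#' draws continue until `n_isolates` errors are retained. The overall rates
#' carried by the two datasets are `true_rate` (x1e7) for the deficient
#' strain and `true_rate x realised retention` for the proficient strain,
#' so the ratio of the two dataset rates equals the realised event
#' retention — which makes correction-factor recovery a closed test.
#'
#' @param locus A [reporter_locus()].
#' @param pools A [dntp_pools()].
#' @param config A [sim_config()].
#' @param strain_prefix Prefix for the two strain names.
#' @return List with `mmr_plus` and `mmr_minus` [spectrum_dataset()]s and
#'   `diagnostics` (per-category drawn/retained counts and the realised
#'   retention).
#' @export
simulate_spectrum <- function(locus, pools, config, strain_prefix = "sim") {
  stopifnot(inherits(locus, "ReporterLocus"), inherits(pools, "DNTPPools"),
            inherits(config, "SimulationConfig"))
  set.seed(config$seed)
  tab <- .propensity_table(locus, pools, config)
  n_iso <- config$n_isolates
  ret <- config$mmr_retention

  idx_minus <- sample(nrow(tab), n_iso, replace = TRUE, prob = tab$weight)
  ev_minus <- .events_from_rows(tab, idx_minus,
                                paste0(strain_prefix, "_msh2"),
                                config$multi_mutation_rate)

  # rejection-sample the repaired spectrum; track realised retention
  drawn <- stats::setNames(numeric(length(ret)), names(ret))
  kept <- drawn
  idx_plus <- integer(0)
  while (length(idx_plus) < n_iso) {
    chunk <- sample(nrow(tab), max(1000L, n_iso), replace = TRUE,
                    prob = tab$weight)
    cat_chunk <- tab$category[chunk]
    keep <- stats::runif(length(chunk)) < ret[cat_chunk]
    for (cc in unique(cat_chunk)) {
      drawn[cc] <- drawn[cc] + sum(cat_chunk == cc)
      kept[cc] <- kept[cc] + sum(keep & cat_chunk == cc)
    }
    idx_plus <- c(idx_plus, chunk[keep])
  }
  over <- length(idx_plus) - n_iso
  idx_plus <- idx_plus[seq_len(n_iso)]
  realised_retention <- (sum(kept) - over) / sum(drawn)
  ev_plus <- .events_from_rows(tab, idx_plus, strain_prefix,
                               config$multi_mutation_rate,
                               weights = tab$weight * ret[tab$category])

  rate_minus <- config$true_rate * 1e7
  rate_plus <- rate_minus * realised_retention
  imb <- length(excess_set(pools)) > 0
  list(
    mmr_plus = spectrum_dataset(strain_prefix, locus, ev_plus, n_iso,
                                rate_plus, pool_imbalanced = imb,
                                mmr_deficient = FALSE),
    mmr_minus = spectrum_dataset(paste0(strain_prefix, "_msh2"), locus,
                                 ev_minus, n_iso, rate_minus,
                                 pool_imbalanced = imb, mmr_deficient = TRUE),
    diagnostics = list(drawn = drawn, kept = kept,
                       realised_retention = realised_retention)
  )
}

#' Seeded random locus with planted homopolymer runs
#'
#' Generates a random ACGT sequence that is guaranteed to contain at least
#' one maximal run of each base at each length 3 to 6 (planted with flanking
#' bases chosen so the runs are maximal), so repeat-length analyses always
#' have support. Identical seeds give identical sequences.
#'
#' @param length Sequence length, at least 100.
#' @param seed Integer seed.
#' @param orientation,fork_entry Passed to [reporter_locus()].
#' @return A synthetic [reporter_locus()].
#' @export
fixture_locus <- function(length, seed, orientation = "OR1",
                          fork_entry = "5prime") {
  if (length < 100) stop2("fixture_locus needs length >= 100")
  set.seed(seed)
  bases <- c("A", "C", "G", "T")
  plan <- expand.grid(base = bases, len = 3:6, stringsAsFactors = FALSE)
  plan <- plan[sample(nrow(plan)), ]
  pieces <- character(0)
  last <- ""
  for (i in seq_len(nrow(plan))) {
    b <- plan$base[i]
    sep <- sample(setdiff(bases, c(b, last)), 1)   # keeps planted runs maximal
    pieces <- c(pieces, sep, strrep(b, plan$len[i]))
    last <- b
  }
  core <- paste(pieces, collapse = "")
  pad_n <- length - nchar(core)
  if (pad_n < 0) stop2("length %d too short for the planted runs (need >= %d)",
                       length, nchar(core))
  if (pad_n > 0) {
    pad1 <- sample(setdiff(bases, last), 1)
    pad <- c(pad1, sample(bases, pad_n - 1, replace = TRUE))
    core <- paste0(core, paste(pad[seq_len(pad_n)], collapse = ""))
  }
  reporter_locus(sprintf("synthetic_locus_seed%d", seed), core,
                 orientation, fork_entry)
}

#' Write a complete synthetic fixture directory
#'
#' Emits the same formats the readers consume: a single-record FASTA of the
#' locus, one events TSV per simulated strain, and a culture-counts TSV for
#' a simulated fluctuation experiment.
#'
#' @param dir Output directory (created if needed).
#' @param locus,pools,config As for [simulate_spectrum()].
#' @return Invisibly, the paths written.
#' @export
write_fixture_dir <- function(dir, locus, pools, config) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fasta <- file.path(dir, "locus.fa")
  writeLines(c(paste0(">", locus$name), locus$coding_sequence), fasta)
  sim <- simulate_spectrum(locus, pools, config)
  p1 <- file.path(dir, "events_mmr_plus.tsv")
  p2 <- file.path(dir, "events_mmr_minus.tsv")
  write_table(sim$mmr_plus$events, p1)
  write_table(sim$mmr_minus$events, p2)
  expt <- simulate_fluctuation(config)
  p3 <- file.path(dir, "culture_counts.tsv")
  write_table(data.frame(experiment_id = "sim1", count = expt$counts), p3)
  invisible(c(fasta, p1, p2, p3))
}
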