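# Synthetic experiment generators: probe universes, Latin-Square
# spike-in designs and two-tissue mixture series, with intensities
# produced by the same Langmuir model the preprocessing inverts.

#' Latin-Square spike-in design
#'
#' The design of the classic spike-in benchmark: `n_conditions` groups
#' of `group_size` probesets, each group spiked on a doubling
#' concentration ladder that rotates cyclically through the conditions,
#' plus a set of unspiked background probesets. The default is the
#' 14-condition, triplicate design with 14 groups of 3 probesets (42
#' spiked probesets) on the ladder 0, 0.25, 0.5, ..., 1024 pM.
#'
#' @param n_conditions Number of conditions (= number of spike groups).
#' @param group_size Spiked probesets per group.
#' @param replicates Arrays per condition (>= 2).
#' @param ladder Ordered spike concentrations (pM), one per condition;
#'   nonnegative and strictly increasing after the leading 0.
#' @param n_background_probesets Unspiked probesets carrying a constant
#'   baseline concentration.
#' @return An object of class `latin_square_design`.
#' @export
latin_square_design <- function(n_conditions = 14,
                                group_size = 3,
                                replicates = 3,
                                ladder = c(0, 0.25, 0.5, 1, 2, 4, 8, 16,
                                           32, 64, 128, 256, 512, 1024),
                                n_background_probesets = 1000) {
  stopifnot(n_conditions >= 2, group_size >= 1, replicates >= 2,
            n_background_probesets >= 0)
  if (length(ladder) != n_conditions) {
    stop("ladder length must equal n_conditions")
  }
  if (any(ladder < 0) || any(diff(ladder) <= 0)) {
    stop("ladder must be nonnegative and strictly increasing")
  }
  structure(list(n_conditions = n_conditions,
                 n_groups = n_conditions,
                 group_size = group_size,
                 replicates = replicates,
                 ladder = ladder,
                 n_background_probesets = n_background_probesets),
            class = "latin_square_design")
}

#' Random probe universe
#'
#' Generates `n_probesets * probes_per_probeset` random 25-mer probe
#' sequences (uniform over ACGT, hence GC content 0.5 on average),
#' grouped into probesets with unique ids. Deterministic under the
#' seed.
#'
#' @param n_probesets Number of probesets (>= 1).
#' @param probes_per_probeset Probes per probeset (>= 1; 11 mirrors a
#'   typical chip).
#' @param seed Integer seed.
#' @param probe_length Probe length in nucleotides (default 25).
#' @return Annotation data frame with columns `probe_id`,
#'   `probeset_id`, `sequence`.
#' @export
make_probe_universe <- function(n_probesets, probes_per_probeset = 11,
                                seed = 1, probe_length = 25) {
  stopifnot(n_probesets >= 1, probes_per_probeset >= 1, probe_length >= 2)
  set.seed(seed)
  n <- n_probesets * probes_per_probeset
  bases <- sample(c("A", "C", "G", "T"), n * probe_length, replace = TRUE)
  seqs <- apply(matrix(bases, nrow = n), 1, paste, collapse = "")
  sets <- sprintf("ps%05d", rep(seq_len(n_probesets),
                                each = probes_per_probeset))
  data.frame(probe_id = sprintf("%s_p%02d", sets,
                                rep(seq_len(probes_per_probeset),
                                    times = n_probesets)),
             probeset_id = sets,
             sequence = seqs,
             stringsAsFactors = FALSE)
}

#' Latin-Square concentration truth
#'
#' Builds the probeset x condition design concentration matrix: spike
#' group `g` receives `ladder[(g + k) mod n]` in condition `k` (cyclic
#' Latin square), so every condition uses each ladder value exactly
#' once and any two conditions assign different concentrations to every
#' spiked group. Background probesets receive a per-probeset lognormal
#' baseline (median 10 pM, sdlog 1) held constant across conditions, so
#' their fold change is exactly 1.
#'
#' @param design A [latin_square_design()].
#' @param seed Integer seed (for the background baselines).
#' @return List with `concentrations` (probesets x conditions matrix,
#'   pM), `spiked_ids`, `group_of` (named group index per spiked
#'   probeset), and `design`.
#' @export
make_latin_square <- function(design = latin_square_design(), seed = 1) {
  stopifnot(inherits(design, "latin_square_design"))
  set.seed(seed)
  n <- design$n_conditions
  n_spiked <- design$n_groups * design$group_size
  n_total <- n_spiked + design$n_background_probesets
  ids <- sprintf("ps%05d", seq_len(n_total))
  spiked_ids <- ids[seq_len(n_spiked)]
  group_of <- stats::setNames(rep(seq_len(design$n_groups),
                                  each = design$group_size), spiked_ids)
  conc <- matrix(NA_real_, nrow = n_total, ncol = n,
                 dimnames = list(ids, sprintf("c%02d", seq_len(n))))
  for (k in seq_len(n)) {
    conc[seq_len(n_spiked), k] <-
      design$ladder[((group_of + k - 1) %% n) + 1]
  }
  if (design$n_background_probesets > 0) {
    baseline <- exp(stats::rnorm(design$n_background_probesets,
                                 mean = log(10), sd = 1))
    conc[(n_spiked + 1):n_total, ] <- baseline
  }
  list(concentrations = conc, spiked_ids = spiked_ids,
       group_of = group_of, design = design)
}

#' Expand a condition-level truth matrix to arrays
#'
#' Replicates each condition column into `replicates` array columns
#' named `c<k>_r<j>` and returns the per-array concentration matrix
#' plus the array-to-condition map.
#'
#' @param concentrations Probesets x conditions matrix.
#' @param replicates Arrays per condition.
#' @return List with `concentrations` (probesets x arrays) and
#'   `condition_of` (named integer vector, array id -> condition
#'   index).
#' @export
expand_conditions <- function(concentrations, replicates = 3) {
  stopifnot(replicates >= 1)
  n <- ncol(concentrations)
  idx <- rep(seq_len(n), each = replicates)
  arrays <- sprintf("%s_r%d", colnames(concentrations)[idx],
                    rep(seq_len(replicates), times = n))
  out <- concentrations[, idx, drop = FALSE]
  colnames(out) <- arrays
  list(concentrations = out,
       condition_of = stats::setNames(idx, arrays))
}

#' Two-tissue mixture design
#'
#' The mixture-series design: brain and heart samples mixed in fixed
#' proportions, including three replicated 50/50 mixes, each mixture
#' hybridized in triplicate.
#'
#' @param replicates Arrays per mixture (default 3).
#' @return An object of class `mixture_design`: data frame with
#'   columns `sample_name`, `brain_fraction`, `heart_fraction` and
#'   attribute `replicates`.
#' @export
mixture_design <- function(replicates = 3) {
  stopifnot(replicates >= 2)
  brain <- c(0, 0.05, 0.10, 0.25, 0.50, 0.50, 0.50, 0.75, 0.90, 0.95, 1)
  out <- data.frame(
    sample_name = c("mix1", "mix2", "mix3", "mix4", "mix5a", "mix5b",
                    "mix5c", "mix6", "mix7", "mix8", "mix9"),
    brain_fraction = brain,
    heart_fraction = 1 - brain,
    stringsAsFactors = FALSE)
  attr(out, "replicates") <- replicates
  class(out) <- c("mixture_design", "data.frame")
  out
}

#' Synthetic tissue expression profiles
#'
#' Lognormal baseline concentrations for two tissues sharing a probeset
#' universe, with a fraction of probesets differentially expressed
#' between the tissues (log2 fold changes drawn from a normal).
#'
#' @param probeset_ids Character vector of probeset ids.
#' @param seed Integer seed.
#' @param de_fraction Fraction of probesets differing between tissues.
#' @param lfc_sd Standard deviation of the log2 fold changes.
#' @param baseline_meanlog,baseline_sdlog Lognormal baseline parameters
#'   (pM scale).
#' @return List with named concentration vectors `brain` and `heart`.
#' @export
make_tissue_profiles <- function(probeset_ids, seed = 1,
                                 de_fraction = 0.3, lfc_sd = 2,
                                 baseline_meanlog = log(10),
                                 baseline_sdlog = 1) {
  set.seed(seed)
  n <- length(probeset_ids)
  heart <- exp(stats::rnorm(n, baseline_meanlog, baseline_sdlog))
  lfc <- rep(0, n)
  de <- sample(n, round(de_fraction * n))
  lfc[de] <- stats::rnorm(length(de), 0, lfc_sd)
  brain <- heart * 2^lfc
  list(brain = stats::setNames(brain, probeset_ids),
       heart = stats::setNames(heart, probeset_ids))
}

#' Mixture-series concentration truth
#'
#' Concentration of each probeset in each mixture as the convex
#' combination of the two pure-tissue profiles:
#' `c = f_brain * c_brain + (1 - f_brain) * c_heart`.
#'
#' @param brain_profile,heart_profile Named concentration vectors over
#'   the same probeset ids.
#' @param design A [mixture_design()].
#' @return Probesets x mixtures concentration matrix (pM).
#' @export
make_mixture_series <- function(brain_profile, heart_profile,
                                design = mixture_design()) {
  if (!identical(sort(names(brain_profile)), sort(names(heart_profile)))) {
    stop("brain and heart profiles must share probeset ids")
  }
  heart_profile <- heart_profile[names(brain_profile)]
  out <- vapply(seq_len(nrow(design)), function(i) {
    f <- design$brain_fraction[i]
    f * brain_profile + (1 - f) * heart_profile
  }, numeric(length(brain_profile)))
  dimnames(out) <- list(names(brain_profile), design$sample_name)
  out
}

#' Measurement noise model for simulated intensities
#'
#' @param multiplicative_sd Standard deviation of the lognormal
#'   multiplicative intensity noise (default 0.1, i.e. ~10% CV).
#' @param additive_sd Standard deviation of additive intensity noise
#'   (intensity units, default 0).
#' @param nonspecific_pM Nonspecific-binding concentration floor (pM)
#'   added to every true target concentration before the isotherm, so
#'   that absent targets still produce signal as on real chips
#'   (default 0.05).
#' @param seed Integer seed.
#' @return An object of class `noise_model`.
#' @export
noise_model <- function(multiplicative_sd = 0.1, additive_sd = 0,
                        nonspecific_pM = 0.05, seed = 1) {
  stopifnot(multiplicative_sd >= 0, additive_sd >= 0, nonspecific_pM >= 0)
  structure(list(multiplicative_sd = multiplicative_sd,
                 additive_sd = additive_sd,
                 nonspecific_pM = nonspecific_pM,
                 seed = seed),
            class = "noise_model")
}

#' Simulate a probe intensity matrix from concentration truth
#'
#' Forward-simulates fluorescence intensities: each probe's binding
#' constant follows from its sequence, the Langmuir isotherm converts
#' the (truth + nonspecific floor) concentration of its probeset into a
#' mean intensity, and lognormal multiplicative plus normal additive
#' noise are applied (clipped at 0). Deterministic under the noise
#' model's seed.
#'
#' @param truth Probesets x arrays concentration matrix (pM).
#' @param annotation Probe annotation covering all probesets of
#'   `truth`.
#' @param nn An [nn_params()] table.
#' @param params A [langmuir_params()] object.
#' @param noise A [noise_model()].
#' @return Probes x arrays intensity matrix with probe/array ids.
#' @export
simulate_intensities <- function(truth, annotation, nn,
                                 params = langmuir_params(),
                                 noise = noise_model()) {
  missing_sets <- setdiff(rownames(truth), annotation$probeset_id)
  if (length(missing_sets) > 0) {
    stop("probesets without probes: ",
         paste(utils::head(missing_sets, 5), collapse = ", "))
  }
  ann <- annotation[annotation$probeset_id %in% rownames(truth), ,
                    drop = FALSE]
  set.seed(noise$seed)
  dg <- .free_energy_many(ann$sequence, nn)
  k <- as.numeric(binding_constant(dg, params$thermo))
  conc <- truth[ann$probeset_id, , drop = FALSE] + noise$nonspecific_pM
  mean_i <- langmuir_intensity(conc, k, params)
  n <- length(mean_i)
  i <- mean_i * exp(stats::rnorm(n, 0, noise$multiplicative_sd))
  if (noise$additive_sd > 0) {
    i <- i + stats::rnorm(n, 0, noise$additive_sd)
  }
  i <- pmax(i, 0)
  dim(i) <- dim(mean_i)
  dimnames(i) <- list(ann$probe_id, colnames(truth))
  i
}
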