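# End-to-end pipeline: simulate (or load) a spike-in experiment, invert
# intensities to concentrations, rescale, summarize, test all pairwise
# comparisons and evaluate against the design truth.

.PIPELINE_DEFAULTS <- list(
  seed = 1,
  out_dir = NULL,
  # spike-in design
  n_conditions = 14,
  group_size = 3,
  replicates = 3,
  n_background = 1000,
  probes_per_probeset = 11,
  # noise
  multiplicative_sd = 0.1,
  additive_sd = 0,
  nonspecific_pM = 0.05,
  # Langmuir / thermodynamics
  saturation_A = 1e4,
  background_I0 = 0,
  temperature_K = 318.15,
  gas_constant = 0.0019872,
  dg_reference = -37.7,
  rescale = TRUE,
  # summarization
  summary_method = "medianpolish",
  use_log = NULL,
  transposed = FALSE,
  # differential test
  test_method = "window",
  prior_df = 10,
  window_halfwidth = 50,
  # evaluation
  exclude_ids = character(0))

#' Pipeline configuration
#'
#' Flat configuration for [run_pipeline()]. Every key has the default
#' declared by its owning stage; unknown keys are rejected, and values
#' are validated by the stage constructors before any computation.
#'
#' @param ... Overrides of the defaults; see `langmuirchip:::.PIPELINE_DEFAULTS`
#'   for the full key set (design sizes, noise model, Langmuir and
#'   thermodynamic constants, summarizer, test and evaluation options,
#'   `seed`, `out_dir`).
#' @return An object of class `pipeline_config` (a named list).
#' @export
pipeline_config <- function(...) {
  override <- list(...)
  unknown <- setdiff(names(override), names(.PIPELINE_DEFAULTS))
  if (length(unknown) > 0) {
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  }
  if (length(override) > 0 &&
      (is.null(names(override)) || any(!nzchar(names(override))))) {
    stop("all configuration values must be named")
  }
  cfg <- utils::modifyList(.PIPELINE_DEFAULTS, override,
                           keep.null = TRUE)
  class(cfg) <- "pipeline_config"
  cfg
}

.cfg_objects <- function(cfg) {
  ladder_default <- c(0, 0.25, 0.5, 1, 2, 4, 8, 16, 32, 64, 128, 256,
                      512, 1024)
  ladder <- if (cfg$n_conditions == 14) ladder_default else
    c(0, 2^seq(0, length.out = cfg$n_conditions - 1))
  list(
    design = latin_square_design(
      n_conditions = cfg$n_conditions, group_size = cfg$group_size,
      replicates = cfg$replicates, ladder = ladder,
      n_background_probesets = cfg$n_background),
    params = langmuir_params(
      saturation_A = cfg$saturation_A, background_I0 = cfg$background_I0,
      thermo = thermo_config(temperature_K = cfg$temperature_K,
                             gas_constant = cfg$gas_constant,
                             dg_reference = cfg$dg_reference)),
    noise = noise_model(multiplicative_sd = cfg$multiplicative_sd,
                        additive_sd = cfg$additive_sd,
                        nonspecific_pM = cfg$nonspecific_pM,
                        seed = cfg$seed + 1L),
    sum_config = summarization_config(method = cfg$summary_method,
                                      use_log = cfg$use_log,
                                      transposed = cfg$transposed),
    test_config = shrinkage_config(prior_df = cfg$prior_df,
                                   window_halfwidth = cfg$window_halfwidth))
}

#' Run the full simulate-preprocess-test-evaluate pipeline
#'
#' Executes, in order: spike-in simulation (probe universe, Latin-Square
#' truth, noisy Langmuir intensities), concentration estimation, global
#' rescaling (optional), probeset summarization, differential testing
#' over all pairwise condition comparisons, and evaluation against the
#' design truth. When `out_dir` is set, each stage's artifact is written
#' as a tab-separated table (intensities, annotation, design truth,
#' concentrations, expression, concatenated p-values and truth, curve)
#' plus a `manifest.txt` recording the full parameter set; rerunning
#' with the same configuration reproduces the files byte for byte.
#'
#' @param config A [pipeline_config()].
#' @param nn An [nn_params()] table; default the packaged RNA/DNA
#'   parameters.
#' @return List with `annotation`, `truth` (per-condition design
#'   concentrations), `condition_of`, `intensities`, `conc`,
#'   `scaling`, `expr`, `evaluation` (from [spikein_evaluation()]) and
#'   `paths` (written files, if any), invisibly.
#' @export
run_pipeline <- function(config = pipeline_config(),
                         nn = load_nn_params(
                           system.file("extdata",
                                       "sugimoto1995_rnadna_dg37.tsv",
                                       package = "langmuirchip"))) {
  stopifnot(inherits(config, "pipeline_config"))
  obj <- .cfg_objects(config)

  n_sets <- obj$design$n_groups * obj$design$group_size +
    obj$design$n_background_probesets
  annotation <- make_probe_universe(n_sets, config$probes_per_probeset,
                                    seed = config$seed)
  ls <- make_latin_square(obj$design, seed = config$seed)
  per_array <- expand_conditions(ls$concentrations, obj$design$replicates)
  intensities <- simulate_intensities(per_array$concentrations,
                                      annotation, nn, obj$params,
                                      obj$noise)

  conc <- estimate_concentrations(intensities, annotation, nn, obj$params)
  scaling <- NULL
  if (isTRUE(config$rescale)) {
    rs <- rescale_arrays(conc)
    conc <- rs$conc
    scaling <- rs$scaling
  }
  expr <- summarize_probesets(conc, annotation, obj$sum_config)
  evaluation <- spikein_evaluation(expr, per_array$condition_of,
                                   ls$concentrations,
                                   method = config$test_method,
                                   config = obj$test_config,
                                   exclusion_ids = config$exclude_ids)

  paths <- character(0)
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    prov <- config[setdiff(names(config), "out_dir")]
    w <- function(x, name, kind) {
      p <- file.path(config$out_dir, name)
      write_table(x, p, kind, params = prov)
      p
    }
    paths <- c(
      intensities = w(intensities, "intensities.tsv", "intensity"),
      annotation = w(annotation, "annotation.tsv", "annotation"),
      design_truth = w(ls$concentrations, "design_concentrations.tsv",
                       "expression"),
      concentrations = w(conc$values, "concentrations.tsv",
                         "concentration"),
      expression = w(expr, "expression.tsv", "expression"),
      pvalues = w(evaluation$pvalues, "pvalues.tsv", "pvalues"),
      truth = w(evaluation$truth, "truth.tsv", "truth"),
      curve = w(as.data.frame(evaluation$curve), "curve.tsv", "curve"))
    manifest <- file.path(config$out_dir, "manifest.txt")
    writeLines(c("# langmuirchip pipeline manifest",
                 paste0(names(prov), "=",
                        vapply(prov, function(p)
                          paste(format(p), collapse = ","),
                          character(1)))),
               manifest)
    paths <- c(paths, manifest = manifest)
  }
  invisible(list(annotation = annotation, truth = ls$concentrations,
                 condition_of = per_array$condition_of,
                 intensities = intensities, conc = conc,
                 scaling = scaling, expr = expr,
                 evaluation = evaluation, paths = paths))
}
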