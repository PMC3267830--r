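# Shared fixtures and independent oracle implementations used across the
# test files. Oracles are deliberately written as plain, slow loops so
# they stay independent of the vectorized package code they check.

packaged_nn <- function() {
  load_nn_params(system.file("extdata", "sugimoto1995_rnadna_dg37.tsv",
                             package = "langmuirchip"))
}

uniform_nn <- function(stack = -1, init = 0) {
  keys <- as.vector(t(outer(c("A", "C", "G", "T"),
                            c("A", "C", "G", "T"), paste0)))
  nn_params(setNames(rep(stack, 16), keys), init)
}

random_seq <- function(n, len = 25) {
  vapply(seq_len(n), function(i) {
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE),
          collapse = "")
  }, character(1))
}

# Brute-force sliding-window free-energy sum (explicit loop).
oracle_free_energy <- function(seq, params) {
  total <- params$initiation_dg
  for (i in seq_len(nchar(seq) - 1)) {
    total <- total + params$stack_dg[[substr(seq, i, i + 1)]]
  }
  total
}

# Hand-coded median polish sweeps (rows first), independent of
# stats::medpolish.
oracle_medianpolish <- function(x, max_iter = 10, tol = 0.01) {
  overall <- 0
  row_eff <- rep(0, nrow(x))
  col_eff <- rep(0, ncol(x))
  res <- x
  old_sum <- sum(abs(res), na.rm = TRUE)
  for (it in seq_len(max_iter)) {
    rmed <- apply(res, 1, median, na.rm = TRUE)
    res <- res - rmed
    row_eff <- row_eff + rmed
    cmed_r <- median(col_eff, na.rm = TRUE)
    col_eff <- col_eff - cmed_r
    overall <- overall + cmed_r
    cmed <- apply(res, 2, median, na.rm = TRUE)
    res <- sweep(res, 2, cmed)
    col_eff <- col_eff + cmed
    rmed_c <- median(row_eff, na.rm = TRUE)
    row_eff <- row_eff - rmed_c
    overall <- overall + rmed_c
    new_sum <- sum(abs(res), na.rm = TRUE)
    if (new_sum == 0 || abs(new_sum - old_sum) < tol) break
    old_sum <- new_sum
  }
  list(overall = overall, row = row_eff, col = col_eff, residuals = res)
}

# Quadratic brute-force confusion counts at every distinct threshold.
oracle_curve <- function(p, truth) {
  thr <- sort(unique(p))
  do.call(rbind, lapply(thr, function(t) {
    called <- p <= t
    tp <- sum(called & truth)
    fp <- sum(called & !truth)
    data.frame(threshold = t, TP = tp, FP = fp,
               TN = sum(!called & !truth), FN = sum(!called & truth),
               sensitivity = tp / sum(truth),
               fdr = if (tp + fp == 0) 0 else fp / (tp + fp),
               one_minus_specificity = fp / sum(!truth))
  }))
}

# Tiny annotated universe plus exactly-invertible intensities.
tiny_experiment <- function(n_sets = 6, probes = 4, arrays = 5,
                            seed = 42, conc_range = c(0.1, 50)) {
  set.seed(seed)
  ann <- make_probe_universe(n_sets, probes, seed = seed)
  nn <- packaged_nn()
  params <- langmuir_params()
  conc <- matrix(exp(runif(n_sets * arrays, log(conc_range[1]),
                           log(conc_range[2]))),
                 nrow = n_sets,
                 dimnames = list(unique(ann$probeset_id),
                                 paste0("a", seq_len(arrays))))
  intens <- simulate_intensities(conc, ann, nn, params,
                                 noise_model(0, 0, 0, seed = seed))
  list(ann = ann, nn = nn, params = params, conc = conc,
       intensities = intens)
}
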