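# Probe-set summarization: collapse probe-level concentrations into one
# expression value per probeset and array, with the five summarizers
# historically used by GeneChip preprocessing pipelines.

#' Summarization configuration
#'
#' @param method One of `"medianpolish"`, `"median"`,
#'   `"average_difference"`, `"tukey_biweight"`, `"mbei"`.
#' @param use_log Take log2 of (positive) values before summarizing and
#'   report on the log2 scale. Defaults to `TRUE` for median polish (the
#'   combination that performs best, and the convention of the
#'   polish-based pipelines it mirrors) and `FALSE` otherwise.
#' @param transposed Median polish only: run the polish on the
#'   transposed matrix (arrays as rows), the variant introduced to avoid
#'   polish-induced inter-array correlation.
#' @param biweight_c Biweight tuning constant (> 0), default 5.
#' @param biweight_eps Small positive stabilizer added to `c * MAD`,
#'   default 1e-4.
#' @param mbei_max_iter Iteration cap for the MBEI alternating least
#'   squares.
#' @param polish_max_iter Sweep cap for median polish.
#' @param polish_tol Convergence tolerance on the change in the sum of
#'   absolute residuals of the polish.
#' @return An object of class `summarization_config`.
#' @export
summarization_config <- function(method = c("medianpolish", "median",
                                            "average_difference",
                                            "tukey_biweight", "mbei"),
                                 use_log = NULL,
                                 transposed = FALSE,
                                 biweight_c = 5,
                                 biweight_eps = 1e-4,
                                 mbei_max_iter = 100,
                                 polish_max_iter = 10,
                                 polish_tol = 0.01) {
  method <- match.arg(method)
  if (is.null(use_log)) use_log <- method == "medianpolish"
  stopifnot(biweight_c > 0, biweight_eps > 0,
            mbei_max_iter >= 1, polish_max_iter >= 1, polish_tol > 0)
  if (transposed && method != "medianpolish") {
    stop("'transposed' is only meaningful for method = 'medianpolish'")
  }
  structure(list(method = method, use_log = use_log,
                 transposed = transposed,
                 biweight_c = biweight_c, biweight_eps = biweight_eps,
                 mbei_max_iter = mbei_max_iter,
                 polish_max_iter = polish_max_iter,
                 polish_tol = polish_tol),
            class = "summarization_config")
}

#' Median summarizer
#'
#' Sample median of the finite values (midpoint of the two central
#' values for even counts); `NA` if no finite value remains.
#'
#' @param x Numeric vector of probe values for one probeset on one array.
#' @return Scalar summary.
#' @export
summarize_median <- function(x) {
  x <- x[is.finite(x)]
  if (length(x) == 0) return(NA_real_)
  stats::median(x)
}

#' Average-difference summarizer
#'
#' The outlier-trimmed mean of the earliest GeneChip software: remove the
#' single largest and single smallest value, compute mean and standard
#' deviation of the remainder, and average all original values lying
#' within three standard deviations of that trimmed mean. With fewer
#' than 3 finite values the plain mean is returned.
#'
#' @param x Numeric vector of probe values.
#' @return Scalar summary (`NA` if no finite value).
#' @export
summarize_avgdiff <- function(x) {
  x <- x[is.finite(x)]
  n <- length(x)
  if (n == 0) return(NA_real_)
  if (n < 3) return(mean(x))
  trimmed <- x[-c(which.max(x), which.min(x))]
  mu <- mean(trimmed)
  s <- stats::sd(trimmed)
  if (length(trimmed) < 2 || is.na(s)) s <- 0
  inside <- x >= mu - 3 * s & x <= mu + 3 * s
  if (!any(inside)) return(mu)
  mean(x[inside])
}

#' One-step Tukey biweight summarizer
#'
#' Robust location estimate with bisquare weights around the median:
#' `u_i = (x_i - M) / (c S + eps)` with `M` the median and `S` the
#' median absolute deviation from `M`; weights `(1 - u_i^2)^2` inside
#' `|u| < 1`, zero outside. Returns `M` when all weights vanish.
#'
#' @param x Numeric vector of probe values.
#' @param c Tuning constant (default 5, the historical convention).
#' @param eps Stabilizer (default 1e-4).
#' @return Scalar summary (`NA` if no finite value).
#' @export
summarize_biweight <- function(x, c = 5, eps = 1e-4) {
  x <- x[is.finite(x)]
  if (length(x) == 0) return(NA_real_)
  m <- stats::median(x)
  s <- stats::median(abs(x - m))
  u <- (x - m) / (c * s + eps)
  w <- ifelse(abs(u) < 1, (1 - u^2)^2, 0)
  if (sum(w) == 0) return(m)
  sum(w * x) / sum(w)
}

#' Li-Wong model-based expression index (MBEI)
#'
#' Fits the multiplicative model `y_pj = phi_p * theta_j` (probe affinity
#' times array expression) by alternating least squares, with the
#' identifiability constraint `sum(phi^2) = P` (the probe count) imposed
#' after each sweep. Missing entries are excluded from all sums. The
#' per-array expression index `theta` is the probeset summary.
#'
#' @param mat Numeric matrix, probes x arrays, for one probeset.
#' @param max_iter Sweep cap (default 100).
#' @param tol Relative change in `theta` at which to stop (default 1e-8).
#' @return An object of class `mbei_fit`: list with `theta` (per-array
#'   index), `phi` (per-probe affinity), `iterations`, `converged`, and
#'   `zero_fit` (`TRUE`, with a warning, for an all-zero input).
#' @export
summarize_mbei <- function(mat, max_iter = 100, tol = 1e-8) {
  mat <- as.matrix(mat)
  mask <- is.finite(mat)
  y <- ifelse(mask, mat, 0)
  p_count <- nrow(y)
  if (all(y == 0)) {
    warning("all-zero probeset matrix: returning zero MBEI fit")
    return(structure(list(theta = stats::setNames(rep(0, ncol(y)),
                                                  colnames(y)),
                          phi = rep(0, p_count),
                          iterations = 0L, converged = TRUE,
                          zero_fit = TRUE),
                     class = "mbei_fit"))
  }
  phi <- rep(1, p_count)
  theta <- rep(0, ncol(y))
  converged <- FALSE
  iter <- 0L
  for (iter in seq_len(max_iter)) {
    denom_t <- colSums(mask * phi^2)
    theta_new <- ifelse(denom_t > 0, colSums(y * phi) / denom_t, 0)
    denom_p <- rowSums(sweep(mask, 2, theta_new^2, "*"))
    phi <- ifelse(denom_p > 0,
                  rowSums(sweep(y, 2, theta_new, "*")) / denom_p, 0)
    norm <- sqrt(sum(phi^2) / p_count)
    if (norm > 0) {
      phi <- phi / norm
      theta_new <- theta_new * norm
    }
    delta <- sqrt(sum((theta_new - theta)^2)) /
      max(sqrt(sum(theta_new^2)), .Machine$double.eps)
    theta <- theta_new
    if (delta < tol) {
      converged <- TRUE
      break
    }
  }
  names(theta) <- colnames(y)
  structure(list(theta = theta, phi = phi, iterations = iter,
                 converged = converged, zero_fit = FALSE),
            class = "mbei_fit")
}

#' Tukey median polish summarizer
#'
#' Decomposes a probes x arrays matrix into overall + probe (row) +
#' array (column) effects + residuals by alternately sweeping out row
#' and column medians (via [stats::medpolish()]); the per-array summary
#' is `overall + column effect`. The transposed variant runs the same
#' algorithm with arrays as rows and probes as columns and reads the
#' summaries from the corresponding effects; it was proposed to avoid
#' polish-induced inter-array correlation with few replicates.
#'
#' @param mat Numeric matrix, probes x arrays (missing values allowed).
#' @param transposed Run the polish on the transposed matrix.
#' @param max_iter Sweep cap (default 10).
#' @param tol Convergence tolerance on the change of the sum of absolute
#'   residuals (default 0.01).
#' @return List with `summaries` (per-array) and `fit`, a list with
#'   `overall`, `row_effects` (probes), `col_effects` (arrays) and
#'   `residuals`, satisfying `overall + row + col + residuals == mat`
#'   exactly.
#' @export
summarize_medianpolish <- function(mat, transposed = FALSE,
                                   max_iter = 10, tol = 0.01) {
  mat <- as.matrix(mat)
  if (length(mat) == 0) stop("empty probeset matrix")
  if (nrow(mat) == 1 || ncol(mat) == 1) {
    # degenerate polish: a single sweep already zeroes the residuals
    if (nrow(mat) == 1) {
      overall <- stats::median(mat[1, ], na.rm = TRUE)
      if (!is.finite(overall)) overall <- 0
      col_eff <- mat[1, ] - overall
      row_eff <- 0
    } else {
      overall <- stats::median(mat[, 1], na.rm = TRUE)
      if (!is.finite(overall)) overall <- 0
      row_eff <- mat[, 1] - overall
      col_eff <- 0
    }
    res <- mat - (overall + outer(row_eff, col_eff, "+"))
    fit <- list(overall = overall, row_effects = row_eff,
                col_effects = col_eff, residuals = res)
    return(list(summaries = overall + rep(col_eff, length.out = ncol(mat)),
                fit = fit))
  }
  m <- if (transposed) t(mat) else mat
  # medpolish's eps is relative to the residual sum; the tolerance here
  # is absolute on the change of sum(|residual|), so rescale it
  eps_rel <- tol / (1 + sum(abs(m), na.rm = TRUE))
  mp <- suppressWarnings(
    stats::medpolish(m, eps = eps_rel, maxiter = max_iter,
                     trace.iter = FALSE, na.rm = TRUE))
  if (transposed) {
    fit <- list(overall = mp$overall,
                row_effects = mp$col,
                col_effects = mp$row,
                residuals = t(mp$residuals))
  } else {
    fit <- list(overall = mp$overall,
                row_effects = mp$row,
                col_effects = mp$col,
                residuals = mp$residuals)
  }
  list(summaries = fit$overall + fit$col_effects, fit = fit)
}

.summarizer_columnwise <- function(sub, config) {
  fun <- switch(config$method,
                median = summarize_median,
                average_difference = summarize_avgdiff,
                tukey_biweight = function(x)
                  summarize_biweight(x, config$biweight_c,
                                     config$biweight_eps))
  apply(sub, 2, fun)
}

#' Summarize probe-level concentrations into probeset expression
#'
#' Applies the configured summarizer to every probeset of a probe-level
#' concentration (or intensity) matrix. With `use_log = TRUE` the log2
#' of the positive values is taken first (non-positive and censored
#' values become missing) and the output is on the log2 scale.
#' Missing/censored values are dropped by each summarizer, never
#' imputed.
#'
#' @param conc A `conc_matrix` from [estimate_concentrations()] (or from
#'   [rescale_arrays()]), or a plain probes x arrays matrix with probe
#'   ids as row names.
#' @param annotation Data frame with `probe_id` and `probeset_id`
#'   covering all probes.
#' @param config A [summarization_config()].
#' @return A probesets x arrays numeric matrix with attribute
#'   `scale_tag` (`"log2"` or `"linear"`), probesets in order of first
#'   appearance in the annotation.
#' @export
summarize_probesets <- function(conc, annotation,
                                config = summarization_config()) {
  v <- .conc_values(conc)
  if (is.null(rownames(v))) stop("probe matrix must carry row names")
  hit <- match(rownames(v), annotation$probe_id)
  if (anyNA(hit)) {
    stop("unannotated probes: ",
         paste(utils::head(rownames(v)[is.na(hit)], 5), collapse = ", "))
  }
  if (config$use_log) {
    v[!is.finite(v) | v <= 0] <- NA_real_
    v <- log2(v)
  }
  sets <- factor(annotation$probeset_id[hit],
                 levels = unique(annotation$probeset_id))
  rows <- split(seq_len(nrow(v)), sets)
  out <- matrix(NA_real_, nrow = length(rows), ncol = ncol(v),
                dimnames = list(names(rows), colnames(v)))
  for (i in seq_along(rows)) {
    sub <- v[rows[[i]], , drop = FALSE]
    if (!any(is.finite(sub))) next
    out[i, ] <- switch(
      config$method,
      mbei = {
        th <- summarize_mbei(sub, config$mbei_max_iter)$theta
        th[colSums(is.finite(sub)) == 0] <- NA_real_
        th
      },
      medianpolish = summarize_medianpolish(
        sub, transposed = config$transposed,
        max_iter = config$polish_max_iter,
        tol = config$polish_tol)$summaries,
      .summarizer_columnwise(sub, config))
  }
  attr(out, "scale_tag") <- if (config$use_log) "log2" else "linear"
  out
}
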