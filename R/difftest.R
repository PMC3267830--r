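# Two-group differential expression tests: Student t, regularized
# (variance-shrinkage) t, and window t, with the NA filtering rule used
# for pairwise comparisons.

#' Two-group design
#'
#' @param assignments Named character vector mapping array ids to group
#'   labels.
#' @param group_a,group_b The two (distinct) labels to compare; each
#'   must cover at least 2 arrays.
#' @return An object of class `group_design` with elements
#'   `arrays_a` and `arrays_b`.
#' @export
group_design <- function(assignments, group_a, group_b) {
  if (is.null(names(assignments))) {
    stop("assignments must be named by array id")
  }
  if (identical(group_a, group_b)) stop("group labels must be distinct")
  arrays_a <- names(assignments)[assignments == group_a]
  arrays_b <- names(assignments)[assignments == group_b]
  if (length(arrays_a) < 2 || length(arrays_b) < 2) {
    stop("each group needs at least 2 arrays")
  }
  structure(list(assignments = assignments,
                 group_a = group_a, group_b = group_b,
                 arrays_a = arrays_a, arrays_b = arrays_b),
            class = "group_design")
}

.t_result <- function(statistic = NA_real_, df = NA_real_,
                      p_value = NA_real_, filtered = FALSE,
                      degenerate = FALSE) {
  list(statistic = statistic, df = df, p_value = p_value,
       filtered = filtered, degenerate = degenerate)
}

#' Pooled-variance Student t-test
#'
#' Classic two-sample t-test with pooled variance and
#' `df = n_A + n_B - 2`; two-sided p-value. Zero pooled variance with
#' equal means gives `t = 0, p = 1`; zero variance with unequal means
#' gives `p = 0` flagged `degenerate`. Fewer than 2 finite values in a
#' group yields a `filtered` result with no p-value.
#'
#' @param x,y Numeric vectors of expression values for groups A and B.
#' @return List with `statistic`, `df`, `p_value`, `filtered`,
#'   `degenerate`.
#' @examples
#' student_t(c(1, 2, 3), c(4, 5, 6))
#' @export
student_t <- function(x, y) {
  regularized_t(x, y, sigma0_sq = 0, nu0 = 0)
}

#' Regularized (variance-shrinkage) t-test
#'
#' Pooled-variance t-test whose variance is shrunk toward a background
#' variance `sigma0_sq` with `nu0` pseudo-degrees of freedom:
#' `s~^2 = (nu0 sigma0^2 + (nA + nB - 2) s_p^2) / (nu0 + nA + nB - 2)`,
#' `df = nu0 + nA + nB - 2`. With `nu0 = 0` this is exactly
#' [student_t()]. In the pipeline, `sigma0_sq` is estimated per probeset
#' as the mean pooled variance inside a window of rank-neighbors on mean
#' expression (see [run_differential()]).
#'
#' @param x,y Numeric vectors for groups A and B.
#' @param sigma0_sq Background variance (>= 0).
#' @param nu0 Prior pseudo-degrees of freedom (>= 0).
#' @return List as in [student_t()].
#' @export
regularized_t <- function(x, y, sigma0_sq, nu0) {
  stopifnot(sigma0_sq >= 0, nu0 >= 0)
  x <- x[is.finite(x)]
  y <- y[is.finite(y)]
  na <- length(x)
  nb <- length(y)
  if (na < 2 || nb < 2) return(.t_result(filtered = TRUE))
  df0 <- na + nb - 2
  sp2 <- ((na - 1) * stats::var(x) + (nb - 1) * stats::var(y)) / df0
  s2 <- (nu0 * sigma0_sq + df0 * sp2) / (nu0 + df0)
  df <- nu0 + df0
  delta <- mean(x) - mean(y)
  se <- sqrt(s2 * (1 / na + 1 / nb))
  if (se == 0) {
    if (delta == 0) return(.t_result(0, df, 1))
    return(.t_result(sign(delta) * Inf, df, 0, degenerate = TRUE))
  }
  tt <- delta / se
  .t_result(tt, df, 2 * stats::pt(-abs(tt), df))
}

#' Shrinkage configuration for regularized and window t-tests
#'
#' @param prior_df Pseudo-degrees of freedom `nu0` for the regularized
#'   t-test (default 10).
#' @param window_halfwidth Half-width `h` of the rank window (the window
#'   covers `2h + 1` probesets ranked by mean expression, truncated at
#'   the ends; default 50).
#' @return An object of class `shrinkage_config`.
#' @export
shrinkage_config <- function(prior_df = 10, window_halfwidth = 50) {
  stopifnot(prior_df >= 0, window_halfwidth >= 0,
            window_halfwidth == round(window_halfwidth))
  structure(list(prior_df = prior_df,
                 window_halfwidth = as.integer(window_halfwidth)),
            class = "shrinkage_config")
}

# Running mean of v over windows of half-width h on an already-ordered
# vector, truncated at the ends.
.window_mean <- function(v, h) {
  n <- length(v)
  if (h == 0 || n == 1) return(v)
  cs <- cumsum(c(0, v))
  lo <- pmax(seq_len(n) - h, 1)
  hi <- pmin(seq_len(n) + h, n)
  (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
}

#' Run a differential expression test over all probesets
#'
#' Applies the NA filter (a probeset is flagged `filtered`, with no
#' p-value, when either group has fewer than 2 finite values; in
#' particular when one group is entirely missing), then the chosen test
#' row by row:
#'
#' * `"student"`: pooled-variance t, `df = nA + nB - 2`;
#' * `"window"`: the pooled variance is replaced by the mean pooled
#'   variance over the `2h + 1` probesets neighboring in the ranking by
#'   overall mean expression (truncated at the ends; ties in the
#'   ranking broken by probeset id), `df = nA + nB - 2`;
#' * `"regularized"`: shrinkage of the pooled variance toward that same
#'   window-estimated background variance with `nu0` prior degrees of
#'   freedom, `df = nu0 + nA + nB - 2`.
#'
#' @param expr Probesets x arrays numeric matrix (from
#'   [summarize_probesets()]) with probeset ids as row names.
#' @param design A [group_design()].
#' @param method `"student"`, `"regularized"` or `"window"`.
#' @param config A [shrinkage_config()] (used by the regularized and
#'   window tests).
#' @return Data frame with columns `probeset_id`, `statistic`, `df`,
#'   `p_value`, `filtered`, one row per probeset of `expr`.
#' @export
run_differential <- function(expr, design,
                             method = c("student", "regularized", "window"),
                             config = shrinkage_config()) {
  method <- match.arg(method)
  expr <- as.matrix(expr)
  if (nrow(expr) == 0) stop("empty expression matrix")
  missing_arrays <- setdiff(c(design$arrays_a, design$arrays_b),
                            colnames(expr))
  if (length(missing_arrays) > 0) {
    stop("design references absent arrays: ",
         paste(missing_arrays, collapse = ", "))
  }
  a <- expr[, design$arrays_a, drop = FALSE]
  b <- expr[, design$arrays_b, drop = FALSE]
  na <- rowSums(is.finite(a))
  nb <- rowSums(is.finite(b))
  filtered <- na < 2 | nb < 2
  mean_a <- rowMeans(a, na.rm = TRUE)
  mean_b <- rowMeans(b, na.rm = TRUE)
  var_a <- apply(a, 1, stats::var, na.rm = TRUE)
  var_b <- apply(b, 1, stats::var, na.rm = TRUE)
  df0 <- na + nb - 2
  sp2 <- ((na - 1) * ifelse(is.na(var_a), 0, var_a) +
          (nb - 1) * ifelse(is.na(var_b), 0, var_b)) / pmax(df0, 1)

  ids <- rownames(expr)
  if (is.null(ids)) ids <- as.character(seq_len(nrow(expr)))
  s2 <- sp2
  df <- df0
  if (method %in% c("regularized", "window")) {
    ok <- which(!filtered)
    grand <- rowMeans(cbind(a, b), na.rm = TRUE)
    ord <- ok[order(grand[ok], ids[ok])]
    sw2 <- rep(NA_real_, nrow(expr))
    sw2[ord] <- .window_mean(sp2[ord], config$window_halfwidth)
    if (method == "window") {
      s2 <- sw2
    } else {
      nu0 <- config$prior_df
      s2 <- (nu0 * sw2 + df0 * sp2) / (nu0 + df0)
      df <- nu0 + df0
    }
  }
  se <- sqrt(s2 * (1 / na + 1 / nb))
  delta <- mean_a - mean_b
  tt <- ifelse(se > 0, delta / se,
               ifelse(delta == 0, 0, sign(delta) * Inf))
  p <- ifelse(is.infinite(tt), 0,
              2 * stats::pt(-abs(tt), pmax(df, 1)))
  p[which(tt == 0 & se == 0)] <- 1
  tt[filtered] <- NA_real_
  p[filtered] <- NA_real_
  df[filtered] <- NA_real_
  data.frame(probeset_id = ids, statistic = unname(tt), df = unname(df),
             p_value = unname(p), filtered = unname(filtered),
             stringsAsFactors = FALSE)
}

#' Window t-test over an expression matrix
#'
#' Convenience wrapper around [run_differential()] with
#' `method = "window"`: probesets are ranked by overall mean expression
#' and each probeset's variance is replaced by the mean pooled variance
#' of its `2h + 1` rank-neighbors before forming the t statistic
#' (`df = nA + nB - 2`).
#'
#' @inheritParams run_differential
#' @return As [run_differential()].
#' @export
window_t <- function(expr, design, config = shrinkage_config()) {
  run_differential(expr, design, method = "window", config = config)
}
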