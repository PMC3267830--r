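test_that("median and average-difference summarizers follow their rules", {
  expect_equal(summarize_median(c(1, 2, 3)), 2)
  expect_equal(summarize_median(c(1, 2, 3, 4)), 2.5)
  expect_true(is.na(summarize_median(c(NA, NA))))

  expect_equal(summarize_avgdiff(c(5, 5, 5, 5)), 5)
  expect_equal(summarize_avgdiff(c(1, 1, 1, 1, 100)), 1)
  expect_equal(summarize_avgdiff(c(2, 8)), 5)  # < 3 values: plain mean

  # step-by-step oracle of the trimmed-band rule
  set.seed(21)
  for (rep in 1:200) {
    x <- rnorm(sample(3:12, 1), sd = sample(c(0.1, 1, 10), 1))
    trimmed <- x[-c(which.max(x), which.min(x))]
    mu <- mean(trimmed)
    s <- if (length(trimmed) >= 2) sd(trimmed) else 0
    inside <- x >= mu - 3 * s & x <= mu + 3 * s
    want <- if (any(inside)) mean(x[inside]) else mu
    expect_equal(summarize_avgdiff(x), want)
    # median against the sort-based definition
    xs <- sort(x)
    n <- length(xs)
    med <- if (n %% 2 == 1) xs[(n + 1) / 2] else
      (xs[n / 2] + xs[n / 2 + 1]) / 2
    expect_equal(summarize_median(x), med)
  }
})

test_that("one-step biweight weights outliers down and tends to the mean", {
  expect_equal(summarize_biweight(c(5, 5, 5)), 5)
  expect_equal(summarize_biweight(c(1, 2, 3)), 2)
  # direct hand evaluation of the weight formula
  x <- c(1, 2, 3, 4, 100)
  u <- (x - 3) / (5 * 1 + 1e-4)
  w <- ifelse(abs(u) < 1, (1 - u^2)^2, 0)
  expect_equal(summarize_biweight(x, c = 5, eps = 1e-4),
               sum(w * x) / sum(w))
  expect_equal(summarize_biweight(x, c = 5, eps = 1e-4), 2.602,
               tolerance = 1e-3)
  # c -> infinity recovers the arithmetic mean
  set.seed(22)
  y <- rnorm(20)
  expect_equal(summarize_biweight(y, c = 1e6), mean(y), tolerance = 1e-8)
})

test_that("MBEI recovers the rank-1 model and its normalization", {
  set.seed(23)
  phi <- runif(7, 0.5, 2)
  theta <- runif(5, 1, 30)
  y <- outer(phi, theta)
  fit <- summarize_mbei(y)
  expect_s3_class(fit, "mbei_fit")
  expect_equal(sum(fit$phi^2), nrow(y), tolerance = 1e-8)
  # theta recovered up to the sum(phi^2) = P normalization
  scale <- sqrt(sum(phi^2) / nrow(y))
  expect_equal(unname(fit$theta), theta * scale, tolerance = 1e-6)
  expect_equal(outer(fit$phi, unname(fit$theta)), y, tolerance = 1e-6)
  # exact rank-1 data: residuals vanish within 3 sweeps
  fit3 <- summarize_mbei(y, max_iter = 3)
  expect_equal(outer(fit3$phi, unname(fit3$theta)), y, tolerance = 1e-6)

  # identical columns give identical expression indexes
  yc <- matrix(rep(c(1, 2, 5), 4), nrow = 3)
  fitc <- summarize_mbei(yc)
  expect_equal(unname(fitc$theta), rep(fitc$theta[[1]], 4))

  expect_warning(fit0 <- summarize_mbei(matrix(0, 3, 3)), "all-zero")
  expect_true(fit0$zero_fit)
  expect_equal(unname(fit0$theta), rep(0, 3))
})

test_that("MBEI theta is within 2% of truth under 1% noise", {
  set.seed(24)
  phi <- runif(10, 0.5, 2)
  theta <- runif(6, 5, 50)
  y <- outer(phi, theta) * matrix(exp(rnorm(60, 0, 0.01)), 10, 6)
  fit <- summarize_mbei(y)
  scale <- sqrt(sum(fit$phi^2) / 10)  # = 1 by construction
  rel <- abs(unname(fit$theta) / sqrt(sum(phi^2) / 10) - theta) / theta
  expect_lt(max(rel), 0.02)
})

test_that("median polish reconstructs, converges, and transposes cleanly", {
  m <- matrix(c(1, 1, 1, 2, 2, 2), nrow = 3,
              dimnames = list(paste0("p", 1:3), c("a1", "a2")))
  mp <- summarize_medianpolish(m)
  expect_equal(unname(mp$summaries), c(1, 2))

  set.seed(25)
  for (rep in 1:20) {
    x <- matrix(rnorm(7 * 5, sd = 3), 7, 5)
    if (rep > 15) x[sample(35, 4)] <- NA  # censored entries
    fit <- summarize_medianpolish(x, max_iter = 50, tol = 1e-9)$fit
    recon <- fit$overall + outer(fit$row_effects, fit$col_effects, "+") +
      fit$residuals
    expect_equal(recon, x)
    if (rep <= 15) {
      expect_lt(max(abs(apply(fit$residuals, 1, median))), 1e-9)
      expect_lt(max(abs(apply(fit$residuals, 2, median))), 1e-9)
    }
    # transposed polish of the transpose equals the straight polish
    straight <- summarize_medianpolish(x, max_iter = 50, tol = 1e-9)
    twisted <- summarize_medianpolish(t(x), transposed = TRUE,
                                      max_iter = 50, tol = 1e-9)
    expect_equal(twisted$summaries, straight$fit$overall +
                   straight$fit$row_effects)
  }

  # independently coded reference polish
  x <- matrix(c(1, 3, 5, 2, 4, 7), nrow = 3)
  want <- oracle_medianpolish(x, max_iter = 100, tol = 1e-10)
  got <- summarize_medianpolish(x, max_iter = 100, tol = 1e-10)
  expect_equal(unname(got$summaries), want$overall + want$col)

  expect_error(summarize_medianpolish(matrix(numeric(0), 0, 0)), "empty")
})

test_that("summarizers are location-equivariant and permutation-invariant", {
  set.seed(26)
  x <- rnorm(9)
  shift <- 3.7
  for (f in list(summarize_median, summarize_avgdiff,
                 function(v) summarize_biweight(v))) {
    expect_equal(f(x + shift), f(x) + shift, tolerance = 1e-9)
    expect_equal(f(sample(x)), f(x))
  }
  m <- matrix(rnorm(24), 6, 4)
  perm <- sample(6)
  mp <- summarize_medianpolish(m, max_iter = 50, tol = 1e-10)
  mp_shift <- summarize_medianpolish(m + shift, max_iter = 50,
                                     tol = 1e-10)
  mp_perm <- summarize_medianpolish(m[perm, ], max_iter = 50,
                                    tol = 1e-10)
  expect_equal(mp_shift$summaries, mp$summaries + shift,
               tolerance = 1e-9)
  expect_equal(mp_perm$summaries, mp$summaries, tolerance = 1e-9)
})

test_that("probeset-level summarization respects structure and scales", {
  exp_data <- tiny_experiment(n_sets = 8, probes = 3, arrays = 4)
  conc <- estimate_concentrations(exp_data$intensities, exp_data$ann,
                                  exp_data$nn, exp_data$params)
  for (method in c("median", "average_difference", "tukey_biweight",
                   "mbei", "medianpolish")) {
    expr <- summarize_probesets(conc, exp_data$ann,
                                summarization_config(method))
    expect_equal(dim(expr), c(8, 4))
    expect_identical(rownames(expr), unique(exp_data$ann$probeset_id))
    expect_identical(attr(expr, "scale_tag"),
                     if (method == "medianpolish") "log2" else "linear")
  }

  # a single-probe probeset passes its values through unchanged
  one <- make_probe_universe(3, 1, seed = 9)
  m <- matrix(1:12, nrow = 3, dimnames = list(one$probe_id, paste0("a", 1:4)))
  expr <- summarize_probesets(m, one, summarization_config(
    "median", use_log = FALSE))
  expect_equal(unname(expr), unname(m) * 1.0, ignore_attr = TRUE)

  # non-positive values become missing on the log scale
  m[1, 1] <- 0
  expr_log <- summarize_probesets(m, one, summarization_config(
    "median", use_log = TRUE))
  expect_true(is.na(expr_log[1, 1]))
  expect_equal(expr_log[2, ], log2(m[2, ]))

  expect_error(summarization_config("nearest"), "arg")
  expect_error(summarization_config("median", transposed = TRUE),
               "transposed")
})
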