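make_plist <- function(ids, p) data.frame(probeset_id = ids, p_value = p,
                                          stringsAsFactors = FALSE)

test_that("log10 p-value correlation behaves like its textbook formula", {
  set.seed(41)
  ids <- sprintf("ps%03d", 1:50)
  a <- make_plist(ids, runif(50))
  for (m in c("pearson", "kendall", "spearman")) {
    expect_equal(correlate_pvalue_lists(a, a, m), 1)
  }
  # an elementwise power is exactly linear in log space
  b <- make_plist(ids, a$p_value^2)
  expect_equal(correlate_pvalue_lists(a, b, "pearson"), 1,
               tolerance = 1e-12)

  # textbook-formula oracle on the log10 values of the intersection
  b2 <- make_plist(sample(ids), runif(50))
  la <- log10(a$p_value[match(b2$probeset_id, a$probeset_id)])
  lb <- log10(b2$p_value)
  oracle <- sum((la - mean(la)) * (lb - mean(lb))) /
    sqrt(sum((la - mean(la))^2) * sum((lb - mean(lb))^2))
  expect_equal(correlate_pvalue_lists(a, b2, "pearson"), oracle,
               tolerance = 1e-12)

  # underflowing p-values are floored, not -Inf
  tiny <- make_plist(ids[1:3], c(1e-320, 1e-310, 0.5))
  expect_true(is.finite(correlate_pvalue_lists(tiny, tiny)))
  expect_error(correlate_pvalue_lists(a[1:2, ], a), "3 common")
})

test_that("cross-platform subsetting keeps only unique shared mappings", {
  a <- make_plist(c("A1", "A2", "A3", "A4"), c(0.1, 0.2, 0.3, 0.4))
  b <- make_plist(c("B1", "B2", "B3", "B5"), c(0.5, 0.6, 0.7, 0.8))
  mapping <- data.frame(a = c("A1", "A1", "A2", "A3", "A9"),
                        b = c("B1", "B2", "B3", "B4", "B5"))
  # A1 maps twice -> both rows dropped; A3->B4 and A9->B5 miss a list
  sub <- crossplatform_subset(a, b, mapping)
  expect_equal(names(sub$a), "A2")
  expect_equal(unname(sub$b), 0.7)

  # identity mapping reduces to the intersection of the lists
  ident <- data.frame(a = c("A1", "A2", "A9"), b = c("A1", "A2", "A9"))
  sub2 <- crossplatform_subset(a, a, ident)
  expect_equal(names(sub2$a), c("A1", "A2"))

  # retained count equals a brute-force uniqueness scan
  set.seed(42)
  ids_a <- sprintf("A%02d", sample(30, 40, replace = TRUE))
  ids_b <- sprintf("B%02d", sample(30, 40, replace = TRUE))
  la <- make_plist(sprintf("A%02d", 1:30), runif(30))
  lb <- make_plist(sprintf("B%02d", 1:30), runif(30))
  keep <- vapply(seq_along(ids_a), function(i) {
    sum(ids_a == ids_a[i]) == 1 && sum(ids_b == ids_b[i]) == 1
  }, logical(1))
  got <- crossplatform_subset(la, lb, data.frame(ids_a, ids_b))
  expect_equal(length(got$a), sum(keep))

  expect_error(crossplatform_subset(a, b, mapping[0, ]), "empty")
  expect_error(crossplatform_subset(a, b,
                                    data.frame(a = "A1", b = "B9")[0, ]),
               "empty")
})

test_that("condition pairs enumerate the full unordered set", {
  expect_equal(nrow(enumerate_condition_pairs(14)), 91)
  expect_equal(nrow(enumerate_condition_pairs(2)), 1)
  # brute-force double loop
  want <- 0
  for (i in 1:4) for (j in 1:5) if (i < j) want <- want + 1
  p5 <- enumerate_condition_pairs(5)
  expect_equal(nrow(p5), want)
  expect_true(all(p5$cond_a < p5$cond_b))
  expect_false(any(duplicated(p5)))
  expect_error(enumerate_condition_pairs(1), "2 conditions")
})

test_that("truth construction marks exactly the changed concentrations", {
  conc <- matrix(c(4, 4,
                   0.25, 1024,
                   0, 2,
                   7, 7), nrow = 4, byrow = TRUE,
                 dimnames = list(paste0("ps", 1:4), c("c1", "c2")))
  tr <- build_truth(conc, c(1, 2))
  expect_equal(tr$is_spiked_change, c(FALSE, TRUE, TRUE, FALSE))
  expect_equal(unique(tr$comparison_id), "c1_vs_c2")
})

test_that("exclusion removes matched entries and warns on unknowns", {
  p <- make_plist(sprintf("ps%02d", 1:20), runif(20))
  expect_identical(exclude_probesets(p, character(0)), p)
  out <- exclude_probesets(p, c("ps01", "ps05"))
  expect_equal(nrow(out), 18)
  expect_warning(exclude_probesets(p, "nothere"), "nothere")
  # set-difference oracle on a list of aligned tables
  tr <- data.frame(probeset_id = p$probeset_id, is_spiked_change = FALSE)
  ids <- sprintf("ps%02d", sample(20, 10))
  both <- exclude_probesets(list(p = p, truth = tr), ids)
  expect_equal(both$p$probeset_id, setdiff(p$probeset_id, ids))
  expect_equal(both$truth$probeset_id, both$p$probeset_id)
})

test_that("concatenation preserves order, identity and alignment", {
  ids <- sprintf("ps%02d", 1:6)
  p_lists <- list(one = make_plist(ids, runif(6)),
                  two = make_plist(ids, runif(6)))
  t_lists <- list(one = data.frame(probeset_id = ids,
                                   is_spiked_change = c(TRUE, rep(FALSE, 5))),
                  two = data.frame(probeset_id = ids,
                                   is_spiked_change = c(rep(FALSE, 5), TRUE)))
  cc <- concatenate_comparisons(p_lists, t_lists)
  expect_equal(nrow(cc$pvalues), 12)
  expect_identical(cc$pvalues$probeset_id, cc$truth$probeset_id)
  expect_identical(cc$pvalues$comparison_id, cc$truth$comparison_id)
  # spot audit by id
  expect_true(cc$truth$is_spiked_change[cc$truth$probeset_id == "ps01" &
                                          cc$truth$comparison_id == "one"])
  expect_equal(cc$pvalues$p_value[7:12], p_lists$two$p_value)
  # single list is the identity
  one <- concatenate_comparisons(p_lists[1], t_lists[1])
  expect_equal(one$pvalues$p_value, p_lists$one$p_value)

  t_bad <- t_lists
  t_bad$two <- t_bad$two[1:5, ]
  expect_error(concatenate_comparisons(p_lists, t_bad), "two")
})

test_that("the curve engine reproduces printed-rate arithmetic and the brute force", {
  # direct application of the confusion-rate formulas
  p <- c(rep(0.001, 8), rep(0.002, 2), rep(0.5, 2), rep(0.9, 88))
  truth <- c(rep(TRUE, 8), rep(FALSE, 2), rep(TRUE, 2), rep(FALSE, 88))
  cv <- compute_curves(p, truth)
  at <- cv[cv$threshold == 0.002, ]
  expect_equal(at$TP, 8)
  expect_equal(at$FP, 2)
  expect_equal(at$sensitivity, 0.8)
  expect_equal(at$fdr, 0.2)
  expect_equal(at$one_minus_specificity, 2 / 90)

  # perfectly separated lists reach sensitivity 1 at FDR 0
  sep <- compute_curves(c(runif(10, 0, 0.1), runif(50, 0.5, 1)),
                        c(rep(TRUE, 10), rep(FALSE, 50)))
  expect_true(any(sep$sensitivity == 1 & sep$fdr == 0))

  # invariants along every curve
  set.seed(43)
  for (rep in 1:5) {
    n <- sample(50:300, 1)
    p <- sample(round(runif(n), 3))  # force ties
    tr <- runif(n) < 0.2
    if (!any(tr)) tr[1] <- TRUE
    cv <- compute_curves(p, tr)
    expect_true(all(cv$TP + cv$FN == sum(tr)))
    expect_true(all(cv$FP + cv$TN == sum(!tr)))
    expect_true(all(diff(cv$sensitivity) >= 0))
    expect_true(all(diff(cv$one_minus_specificity) >= 0))
    expect_equal(as.data.frame(cv), oracle_curve(p, tr),
                 ignore_attr = TRUE)
  }
  expect_error(compute_curves(c(0.1, 0.2), c(TRUE, TRUE)), "negative")
})

test_that("randomly permuted truth gives a near-diagonal ROC", {
  set.seed(44)
  p <- runif(4000)
  truth <- sample(c(rep(TRUE, 400), rep(FALSE, 3600)))
  cv <- compute_curves(p, truth)
  x <- c(0, cv$one_minus_specificity)
  y <- c(0, cv$sensitivity)
  auc <- sum(diff(x) * (head(y, -1) + tail(y, -1)) / 2) +
    (1 - max(x)) * 1
  expect_lt(abs(auc - 0.5), 0.05)
})

test_that("the reference correlation study degrades with biological noise", {
  set.seed(45)
  ids <- sprintf("ps%04d", 1:400)
  profiles <- make_tissue_profiles(ids, seed = 45, de_fraction = 0.4,
                                   lfc_sd = 3)
  series <- make_mixture_series(profiles$brain, profiles$heart)
  per_array <- expand_conditions(series, 3)
  # expression = log2 concentration + replicate noise (no chip layer
  # here: this isolates the correlation machinery)
  expr <- log2(per_array$concentrations) +
    matrix(rnorm(length(per_array$concentrations), 0, 0.15),
           nrow = nrow(per_array$concentrations))
  dimnames(expr) <- dimnames(per_array$concentrations)
  cond <- setNames(colnames(series)[per_array$condition_of],
                   names(per_array$condition_of))

  res <- reference_correlation_study(
    expr, cond,
    comparisons = list(c("mix1", "mix9"), c("mix2", "mix8"),
                       c("mix3", "mix7"), c("mix4", "mix6")),
    reference = c("mix1", "mix9"), method = "window")
  expect_equal(res$correlation[1], 1)
  # correlations fall as the mixtures approach 50/50
  expect_true(all(diff(res$correlation) < 0))
  expect_true(all(res$correlation > 0))

  expect_error(reference_correlation_study(
    expr, cond, comparisons = list(c("mix2", "mix8")),
    reference = c("mix1", "nope")), "nope")
})
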