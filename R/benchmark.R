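# Benchmarking apparatus: log10 p-value correlation study across
# comparisons and platforms, and the spike-in evaluation turning
# concatenated pairwise comparisons into sensitivity/FDR and ROC curves.

.P_FLOOR <- 1e-300

.as_pvalue_vector <- function(x) {
  if (is.data.frame(x)) {
    if (!all(c("probeset_id", "p_value") %in% names(x))) {
      stop("p-value table needs columns 'probeset_id' and 'p_value'")
    }
    v <- stats::setNames(x$p_value, x$probeset_id)
  } else {
    v <- x
  }
  if (is.null(names(v))) stop("p-value list must be named by probeset id")
  if (anyDuplicated(names(v))) stop("duplicate probeset ids in p-value list")
  v
}

#' Correlate two p-value lists on the log10 scale
#'
#' Intersects the two lists by probeset id, floors the p-values at
#' 1e-300 (avoiding `-Inf` while preserving order), takes log10 and
#' computes the requested correlation coefficient. Pearson spans the
#' widest range of values across methods and is the reporting default;
#' Kendall and Spearman are available as rank-based alternatives.
#'
#' @param a,b Named numeric vectors of p-values (names = probeset ids),
#'   or data frames with columns `probeset_id` and `p_value`. At least
#'   3 common ids are required.
#' @param method `"pearson"` (default), `"kendall"` or `"spearman"`.
#' @return Correlation coefficient in `[-1, 1]`.
#' @export
correlate_pvalue_lists <- function(a, b,
                                   method = c("pearson", "kendall",
                                              "spearman")) {
  method <- match.arg(method)
  a <- .as_pvalue_vector(a)
  b <- .as_pvalue_vector(b)
  common <- intersect(names(a), names(b))
  if (length(common) < 3) {
    stop("need at least 3 common probeset ids, got ", length(common))
  }
  la <- log10(pmax(a[common], .P_FLOOR))
  lb <- log10(pmax(b[common], .P_FLOOR))
  stats::cor(la, lb, method = method)
}

#' Cross-platform subset of two p-value lists through a mapping table
#'
#' Retains only mapping rows whose platform-A id and platform-B id each
#' occur exactly once in the whole table (unique mappings) and exist in
#' both lists; transcripts covered by only one platform are discarded.
#' The returned lists are aligned row by row.
#'
#' @param a,b P-value lists as in [correlate_pvalue_lists()].
#' @param mapping Two-column data frame pairing platform-A ids (column
#'   1) with platform-B ids (column 2).
#' @return List with aligned named vectors `a` and `b`.
#' @export
crossplatform_subset <- function(a, b, mapping) {
  if (nrow(mapping) == 0) stop("empty mapping table")
  a <- .as_pvalue_vector(a)
  b <- .as_pvalue_vector(b)
  ida <- as.character(mapping[[1]])
  idb <- as.character(mapping[[2]])
  unique_rows <- !(ida %in% ida[duplicated(ida)]) &
    !(idb %in% idb[duplicated(idb)])
  keep <- unique_rows & ida %in% names(a) & idb %in% names(b)
  if (!any(keep)) stop("no unique mappings shared by both lists")
  list(a = a[ida[keep]], b = stats::setNames(b[idb[keep]], ida[keep]))
}

#' Reference correlation study over mixture comparisons
#'
#' The mixture-study benchmark: a reference comparison (pure tissue A
#' versus pure tissue B) defines the reference list of p-values; every
#' other pairwise mixture comparison is tested with the same method and
#' correlated against the reference on the log10 p-value scale. High
#' correlations indicate robustness of the preprocessing/test
#' combination against the biological noise introduced by mixing.
#'
#' @param expr Probesets x arrays expression matrix.
#' @param condition_of Named character vector mapping array ids to
#'   condition (mixture) labels.
#' @param comparisons List of length-2 character vectors of condition
#'   labels, the non-reference comparisons.
#' @param reference Length-2 character vector, the reference comparison
#'   (default `c("mix1", "mix9")`).
#' @param method Test passed to [run_differential()].
#' @param config [shrinkage_config()] for the test.
#' @param cor_method Correlation coefficient (default `"pearson"`).
#' @return Data frame with columns `comparison` and `correlation`, one
#'   row per non-reference comparison.
#' @export
reference_correlation_study <- function(expr, condition_of, comparisons,
                                        reference = c("mix1", "mix9"),
                                        method = "student",
                                        config = shrinkage_config(),
                                        cor_method = "pearson") {
  if (!all(reference %in% condition_of)) {
    stop("reference conditions absent from the design: ",
         paste(setdiff(reference, condition_of), collapse = ", "))
  }
  run_pair <- function(pair) {
    d <- group_design(condition_of, pair[1], pair[2])
    res <- run_differential(expr, d, method = method, config = config)
    res <- res[!res$filtered & !is.na(res$p_value), ]
    stats::setNames(res$p_value, res$probeset_id)
  }
  ref_p <- run_pair(reference)
  cors <- vapply(comparisons, function(pair) {
    if (!all(pair %in% condition_of)) {
      stop("comparison conditions absent from the design: ",
           paste(setdiff(pair, condition_of), collapse = ", "))
    }
    correlate_pvalue_lists(ref_p, run_pair(pair), method = cor_method)
  }, numeric(1))
  data.frame(comparison = vapply(comparisons, paste, character(1),
                                 collapse = "_vs_"),
             correlation = cors, stringsAsFactors = FALSE,
             row.names = NULL)
}

#' Enumerate all unordered condition pairs
#'
#' All `n (n - 1) / 2` unordered pairs of conditions in a fixed,
#' deterministic order (lexicographic on the first then second index).
#' A 14-condition spike-in design yields 91 pairwise comparisons.
#'
#' @param n_conditions Number of conditions (>= 2).
#' @return Data frame with integer columns `cond_a < cond_b`.
#' @examples
#' nrow(enumerate_condition_pairs(14))  # 91
#' @export
enumerate_condition_pairs <- function(n_conditions) {
  if (n_conditions < 2) stop("need at least 2 conditions")
  pairs <- utils::combn(n_conditions, 2)
  data.frame(cond_a = pairs[1, ], cond_b = pairs[2, ])
}

#' Ground truth for one pairwise comparison of a spike-in design
#'
#' A probeset is a true change for the pair iff its two design
#' concentrations differ (fold change != 1); this includes absent
#' (0 pM) versus present. Unspiked probesets carry the same baseline in
#' every condition, hence fold change 1 and truth `FALSE`.
#'
#' @param concentrations Probesets x conditions matrix of design
#'   concentrations (pM) with probeset ids as row names.
#' @param pair Length-2 vector of condition indices (or column names).
#' @return Data frame with `probeset_id`, `comparison_id`,
#'   `is_spiked_change`.
#' @export
build_truth <- function(concentrations, pair) {
  ca <- concentrations[, pair[1]]
  cb <- concentrations[, pair[2]]
  data.frame(probeset_id = rownames(concentrations),
             comparison_id = paste0("c", pair[1], "_vs_c", pair[2]),
             is_spiked_change = ca != cb,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Remove excluded probesets from evaluation lists
#'
#' Drops every entry of the given probesets from a p-value or truth
#' table (or from each element of a list of such tables), as done for
#' probesets that cross-hybridize with spiked transcripts. Excluded ids
#' absent from the data trigger a warning, not an error.
#'
#' @param lists A data frame with a `probeset_id` column, or a list of
#'   such data frames.
#' @param exclusion_ids Character vector of probeset ids (possibly
#'   empty).
#' @return Object of the same shape with the excluded rows removed.
#' @export
exclude_probesets <- function(lists, exclusion_ids) {
  if (length(exclusion_ids) == 0) return(lists)
  drop_from <- function(df) df[!(df$probeset_id %in% exclusion_ids), ,
                               drop = FALSE]
  present <- if (is.data.frame(lists)) {
    exclusion_ids %in% lists$probeset_id
  } else {
    exclusion_ids %in% unlist(lapply(lists, `[[`, "probeset_id"))
  }
  if (any(!present)) {
    warning("exclusion ids absent from the data: ",
            paste(exclusion_ids[!present], collapse = ", "))
  }
  if (is.data.frame(lists)) drop_from(lists) else lapply(lists, drop_from)
}

#' Concatenate per-comparison p-value and truth lists
#'
#' Order-preserving concatenation of the pairwise comparison results
#' into one p-value list and one aligned binary truth list, keeping the
#' (probeset, comparison) identity of every entry. Each pair of lists
#' must match in length and probeset order.
#'
#' @param pvalue_lists Named list of data frames with `probeset_id` and
#'   `p_value` (one per comparison).
#' @param truth_lists List of matching data frames with `probeset_id`
#'   and `is_spiked_change`, same names/order.
#' @return List with data frames `pvalues` (`probeset_id`,
#'   `comparison_id`, `p_value`) and `truth` (`probeset_id`,
#'   `comparison_id`, `is_spiked_change`), row-aligned.
#' @export
concatenate_comparisons <- function(pvalue_lists, truth_lists) {
  if (length(pvalue_lists) != length(truth_lists)) {
    stop("p-value and truth list collections differ in length")
  }
  nm <- names(pvalue_lists)
  if (is.null(nm)) nm <- as.character(seq_along(pvalue_lists))
  pieces_p <- vector("list", length(nm))
  pieces_t <- vector("list", length(nm))
  for (i in seq_along(nm)) {
    p <- pvalue_lists[[i]]
    tr <- truth_lists[[i]]
    if (nrow(p) != nrow(tr) ||
        !identical(as.character(p$probeset_id),
                   as.character(tr$probeset_id))) {
      stop("p-value/truth mismatch for comparison ", nm[i])
    }
    pieces_p[[i]] <- data.frame(probeset_id = p$probeset_id,
                                comparison_id = nm[i],
                                p_value = p$p_value,
                                stringsAsFactors = FALSE)
    pieces_t[[i]] <- data.frame(probeset_id = tr$probeset_id,
                                comparison_id = nm[i],
                                is_spiked_change = tr$is_spiked_change,
                                stringsAsFactors = FALSE)
  }
  list(pvalues = do.call(rbind, pieces_p),
       truth = do.call(rbind, pieces_t))
}

#' Confusion-count curves over increasing p-value thresholds
#'
#' Sweeps the threshold through every distinct p-value in ascending
#' order; an entry is called positive when `p <= threshold` (ties enter
#' together). At each threshold the confusion counts against the truth
#' labels give sensitivity (recall, `TP/(TP+FN)`), false discovery rate
#' (`FP/(FP+TP)`, defined 0 when no calls) and 1-specificity
#' (`FP/(TN+FP)`), the coordinates of the sensitivity-vs-FDR
#' ("alternative ROC") and classic ROC curves.
#'
#' @param p Numeric vector of p-values (no missing values; drop
#'   filtered probesets first).
#' @param truth Logical vector aligned with `p`; at least one `TRUE`
#'   and one `FALSE`.
#' @return Data frame of class `eval_curve` with columns `threshold`,
#'   `TP`, `FP`, `TN`, `FN`, `sensitivity`, `fdr`,
#'   `one_minus_specificity`, ordered by threshold.
#' @export
compute_curves <- function(p, truth) {
  if (is.data.frame(p)) p <- p$p_value
  if (is.data.frame(truth)) truth <- truth$is_spiked_change
  if (length(p) != length(truth)) stop("p and truth must be aligned")
  if (anyNA(p) || anyNA(truth)) stop("missing values in p or truth")
  npos <- sum(truth)
  nneg <- sum(!truth)
  if (npos == 0 || nneg == 0) {
    stop("need at least one positive and one negative truth label")
  }
  ord <- order(p)
  ps <- p[ord]
  tr <- truth[ord]
  n <- length(ps)
  last <- which(c(ps[-1] != ps[-n], TRUE))
  tp <- cumsum(tr)[last]
  fp <- last - tp
  out <- data.frame(threshold = ps[last],
                    TP = tp, FP = fp,
                    TN = nneg - fp, FN = npos - tp,
                    sensitivity = tp / npos,
                    fdr = ifelse(tp + fp == 0, 0, fp / (tp + fp)),
                    one_minus_specificity = fp / nneg)
  class(out) <- c("eval_curve", "data.frame")
  attr(out, "n_pos") <- npos
  attr(out, "n_neg") <- nneg
  out
}

#' Plot an evaluation curve
#'
#' Draws either the sensitivity-versus-FDR curve ("alternative ROC",
#' equivalent to a precision/recall curve) or the classic ROC curve
#' (sensitivity versus 1-specificity).
#'
#' @param curve An `eval_curve` from [compute_curves()].
#' @param type `"fdr"` (default) or `"roc"`.
#' @param add Add to an existing plot.
#' @param ... Passed to [graphics::plot()] / [graphics::lines()].
#' @return The curve, invisibly.
#' @export
plot_eval_curve <- function(curve, type = c("fdr", "roc"), add = FALSE,
                            ...) {
  type <- match.arg(type)
  x <- if (type == "fdr") curve$fdr else curve$one_minus_specificity
  xlab <- if (type == "fdr") "False discovery rate" else "1 - specificity"
  if (add) {
    graphics::lines(x, curve$sensitivity, ...)
  } else {
    graphics::plot(x, curve$sensitivity, type = "l", xlab = xlab,
                   ylab = "Sensitivity", xlim = c(0, 1), ylim = c(0, 1),
                   ...)
  }
  invisible(curve)
}

#' Best sensitivity attainable at a bounded error rate
#'
#' Maximum sensitivity over all thresholds whose FDR (or 1-specificity)
#' does not exceed `limit`; 0 when no threshold qualifies.
#'
#' @param curve An `eval_curve`.
#' @param limit Upper bound on the error rate.
#' @param type `"fdr"` or `"roc"`.
#' @return Scalar sensitivity.
#' @export
sensitivity_at <- function(curve, limit, type = c("fdr", "roc")) {
  type <- match.arg(type)
  err <- if (type == "fdr") curve$fdr else curve$one_minus_specificity
  ok <- err <= limit
  if (!any(ok)) return(0)
  max(curve$sensitivity[ok])
}

#' Full spike-in evaluation over all pairwise comparisons
#'
#' Runs the chosen differential test for every pairwise comparison of
#' the spike-in design, drops filtered probesets (and, consistently,
#' their truth entries), applies the optional cross-hybridization
#' exclusion list, concatenates all comparisons and computes the
#' evaluation curves. A 14-condition triplicate design yields 91
#' comparisons.
#'
#' @param expr Probesets x arrays expression matrix.
#' @param condition_of Named vector mapping array ids to condition
#'   indices (1..n).
#' @param concentrations Probesets x conditions design concentration
#'   matrix (the spike-in truth).
#' @param method,config Test specification as in [run_differential()].
#' @param exclusion_ids Probesets to discard before evaluation.
#' @return List with `curve` (an `eval_curve`), `pvalues` and `truth`
#'   (the concatenated, aligned lists).
#' @export
spikein_evaluation <- function(expr, condition_of, concentrations,
                               method = "window",
                               config = shrinkage_config(),
                               exclusion_ids = character(0)) {
  conds <- sort(unique(condition_of))
  pairs <- enumerate_condition_pairs(length(conds))
  p_lists <- list()
  t_lists <- list()
  for (i in seq_len(nrow(pairs))) {
    ka <- conds[pairs$cond_a[i]]
    kb <- conds[pairs$cond_b[i]]
    d <- group_design(stats::setNames(as.character(condition_of),
                                      names(condition_of)),
                      as.character(ka), as.character(kb))
    res <- run_differential(expr, d, method = method, config = config)
    res <- res[!res$filtered & !is.na(res$p_value), ]
    tr <- build_truth(concentrations, c(ka, kb))
    tr <- tr[match(res$probeset_id, tr$probeset_id), ]
    nm <- paste0("c", ka, "_vs_c", kb)
    p_lists[[nm]] <- res[, c("probeset_id", "p_value")]
    t_lists[[nm]] <- tr[, c("probeset_id", "is_spiked_change")]
  }
  cat_lists <- concatenate_comparisons(p_lists, t_lists)
  if (length(exclusion_ids) > 0) {
    cat_lists <- exclude_probesets(cat_lists, exclusion_ids)
  }
  curve <- compute_curves(cat_lists$pvalues$p_value,
                          cat_lists$truth$is_spiked_change)
  list(curve = curve, pvalues = cat_lists$pvalues,
       truth = cat_lists$truth)
}
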