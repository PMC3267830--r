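# Tabular text interchange: every table the pipeline reads or writes is
# tab-separated with '#' comment lines; matrices carry an id column and
# an array-id header. Writers emit a fixed provenance header so that
# writing the same object twice gives byte-identical files.

.TABLE_KINDS <- c("intensity", "annotation", "expression", "concentration",
                  "pvalues", "mapping", "design", "truth", "curve")

.matrix_kinds <- c(intensity = "probe_id", expression = "probeset_id",
                   concentration = "probe_id")

.fmt_num <- function(x) {
  out <- vapply(x, function(v) {
    if (is.na(v)) "" else sprintf("%.17g", v)
  }, character(1))
  out
}

#' Write a pipeline table
#'
#' Serializes the package's tabular objects to tab-separated text with a
#' `#`-prefixed provenance header (tool version, table kind, caller
#' parameters). Numeric values are written with full (17 significant
#' digit) precision so the file round-trips losslessly; missing values
#' become empty cells. Writing the same object twice produces
#' byte-identical files.
#'
#' @param x Matrix (for `intensity`/`concentration`/`expression`) or
#'   data frame (other kinds).
#' @param path Output file path.
#' @param kind One of `"intensity"`, `"annotation"`, `"expression"`,
#'   `"concentration"`, `"pvalues"`, `"mapping"`, `"design"`, `"truth"`,
#'   `"curve"`.
#' @param params Named list of parameters to record in the header.
#' @return `path`, invisibly.
#' @export
write_table <- function(x, path, kind, params = list()) {
  kind <- match.arg(kind, .TABLE_KINDS)
  header <- c(
    paste0("# langmuirchip ",
           as.character(utils::packageVersion("langmuirchip"))),
    paste0("# kind=", kind))
  if (length(params) > 0) {
    header <- c(header, paste0("# param:", names(params), "=",
                               vapply(params, function(p)
                                 paste(format(p), collapse = ","),
                                 character(1))))
  }
  if (kind %in% names(.matrix_kinds)) {
    m <- as.matrix(x)
    if (is.null(rownames(m)) || is.null(colnames(m))) {
      stop("matrix tables need row and column names")
    }
    df <- data.frame(id = rownames(m), stringsAsFactors = FALSE)
    names(df) <- .matrix_kinds[[kind]]
    for (j in seq_len(ncol(m))) df[[colnames(m)[j]]] <- .fmt_num(m[, j])
  } else {
    df <- as.data.frame(x)
    for (j in seq_along(df)) {
      if (is.numeric(df[[j]])) df[[j]] <- .fmt_num(df[[j]])
      if (is.logical(df[[j]])) df[[j]] <- ifelse(df[[j]], "TRUE", "FALSE")
    }
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(header, con)
  utils::write.table(df, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE, na = "")
  invisible(path)
}

.required_cols <- list(
  annotation = c("probe_id", "probeset_id", "sequence"),
  pvalues = c("probeset_id", "p_value"),
  design = c("array_id", "condition"),
  truth = c("probeset_id", "comparison_id", "is_spiked_change"))

#' Read a pipeline table
#'
#' Parses a tab-separated table written by [write_table()] (or prepared
#' externally in the same layout), skipping `#` comment lines, and
#' validates it against the invariants of the requested kind: required
#' columns, unique ids, nonnegative intensities, p-values in (0, 1].
#' Provenance header parameters are returned in the `provenance`
#' attribute.
#'
#' @param path File path.
#' @param kind Table kind as in [write_table()].
#' @return A matrix (intensity/concentration/expression kinds) or data
#'   frame, with attribute `provenance` (named character vector of the
#'   header parameters).
#' @export
read_table <- function(path, kind) {
  kind <- match.arg(kind, .TABLE_KINDS)
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  comment <- grepl("^#", lines)
  prov_lines <- grep("^# param:", lines, value = TRUE)
  prov <- character(0)
  if (length(prov_lines) > 0) {
    kv <- sub("^# param:", "", prov_lines)
    prov <- stats::setNames(sub("^[^=]*=", "", kv), sub("=.*$", "", kv))
  }
  body <- lines[!comment & nzchar(lines)]
  if (length(body) < 2 && !(length(body) == 1)) {
    stop("no table body in ", path)
  }
  df <- utils::read.delim(text = body, header = TRUE, sep = "\t",
                          na.strings = "", check.names = FALSE,
                          stringsAsFactors = FALSE)
  if (kind %in% names(.matrix_kinds)) {
    idcol <- .matrix_kinds[[kind]]
    if (names(df)[1] != idcol) {
      stop("expected first column '", idcol, "' in ", path,
           ", found '", names(df)[1], "'")
    }
    ids <- as.character(df[[1]])
    if (anyDuplicated(ids)) {
      stop("duplicate ids in ", path, ": ",
           paste(utils::head(unique(ids[duplicated(ids)]), 3),
                 collapse = ", "))
    }
    m <- as.matrix(df[, -1, drop = FALSE])
    storage.mode(m) <- "double"
    rownames(m) <- ids
    if (kind == "intensity" && any(m < 0, na.rm = TRUE)) {
      bad <- which(m < 0, arr.ind = TRUE)[1, ]
      stop("negative intensity at probe '", ids[bad[1]], "', array '",
           colnames(m)[bad[2]], "' in ", path)
    }
    attr(m, "provenance") <- prov
    return(m)
  }
  req <- .required_cols[[kind]]
  if (!is.null(req) && !all(req %in% names(df))) {
    stop("missing column(s) in ", path, ": ",
         paste(setdiff(req, names(df)), collapse = ", "))
  }
  if (kind == "annotation" && anyDuplicated(df$probe_id)) {
    stop("duplicate probe ids in ", path)
  }
  if (kind == "pvalues") {
    bad <- which(!is.na(df$p_value) &
                   (df$p_value <= 0 | df$p_value > 1))
    if (length(bad) > 0) {
      stop("p-value outside (0, 1] on data row ", bad[1], " of ", path)
    }
  }
  if (kind == "truth") df$is_spiked_change <- as.logical(df$is_spiked_change)
  attr(df, "provenance") <- prov
  df
}
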