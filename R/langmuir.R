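# Langmuir isotherm: forward model, inversion to concentrations, and the
# global multiplicative per-array rescaling.

#' Langmuir model parameters
#'
#' Saturation amplitude and constant optical background of the Langmuir
#' isotherm `I = I0 + A cK / (1 + cK)`, together with the thermodynamic
#' configuration used to turn probe free energies into binding constants.
#' The background defaults to 0: background correction is deliberately
#' not part of this preprocessing (concentrations may then be somewhat
#' over-estimated for weakly expressed targets, which is why
#' variance-stabilized t-tests are provided downstream).
#'
#' @param saturation_A Asymptotic fluorescence signal (intensity units,
#'   > 0). Default 1e4.
#' @param background_I0 Constant background intensity (>= 0). Default 0.
#' @param thermo A [thermo_config()]; the default uses the package's
#'   pM-scale convention `dg_reference = -37.7` kcal/mol.
#' @return An object of class `langmuir_params`.
#' @export
langmuir_params <- function(saturation_A = 1e4,
                            background_I0 = 0,
                            thermo = thermo_config(dg_reference = -37.7)) {
  stopifnot(is.numeric(saturation_A), length(saturation_A) == 1,
            is.finite(saturation_A), saturation_A > 0,
            is.numeric(background_I0), length(background_I0) == 1,
            is.finite(background_I0), background_I0 >= 0,
            inherits(thermo, "thermo_config"))
  structure(list(saturation_A = saturation_A,
                 background_I0 = background_I0,
                 thermo = thermo),
            class = "langmuir_params")
}

#' Langmuir isotherm: concentration to intensity
#'
#' Forward hybridization model `I = I0 + A cK / (1 + cK)`: the measured
#' fluorescence is proportional to the equilibrium fraction of probe
#' molecules in duplex with the target at concentration `c`.
#'
#' @param conc Target concentration(s) in pM (>= 0).
#' @param K Binding constant(s), > 0 (recycled against `conc`).
#' @param params A [langmuir_params()] object.
#' @return Intensity values, monotone increasing in `conc` and bounded
#'   above by `background_I0 + saturation_A`.
#' @examples
#' langmuir_intensity(1, 1, langmuir_params(saturation_A = 1e4)) # 5000
#' @export
langmuir_intensity <- function(conc, K, params = langmuir_params()) {
  if (any(conc < 0, na.rm = TRUE)) stop("concentrations must be >= 0")
  if (any(K <= 0, na.rm = TRUE)) stop("binding constants must be > 0")
  x <- conc * as.numeric(K)
  frac <- ifelse(is.infinite(x), 1, x / (1 + x))
  params$background_I0 + params$saturation_A * frac
}

#' Invert the Langmuir isotherm
#'
#' Exact inverse of [langmuir_intensity()] on the open interval
#' `(I0, I0 + A)`: `c = (I - I0) / (K (A - (I - I0)))`. Intensities at or
#' below the background are mapped to concentration 0 and flagged
#' `below_background`; intensities at or above `I0 + A` sit at the pole
#' of the isotherm and are censored (`NA` concentration, `censored`
#' flag) rather than extrapolated.
#'
#' @param intensity Intensity value(s); `NA` propagates.
#' @param K Binding constant(s), > 0 (recycled by row when `intensity`
#'   is a matrix).
#' @param params A [langmuir_params()] object.
#' @return A list with elements `concentration` (pM, `NA` where censored
#'   or missing), `censored` and `below_background` (logicals of the
#'   same shape as `intensity`).
#' @examples
#' invert_langmuir(5000, 1, langmuir_params(saturation_A = 1e4))
#' @export
invert_langmuir <- function(intensity, K, params = langmuir_params()) {
  if (any(K <= 0, na.rm = TRUE)) stop("binding constants must be > 0")
  a <- params$saturation_A
  net <- intensity - params$background_I0
  censored <- !is.na(net) & net >= a
  below <- !is.na(net) & net <= 0
  conc <- net / (as.numeric(K) * (a - net))
  conc[censored] <- NA_real_
  conc[below] <- 0
  list(concentration = conc, censored = censored, below_background = below)
}

#' Estimate transcript concentrations for a probe intensity matrix
#'
#' The core preprocessing step: each probe's 25-mer sequence is converted
#' to a nearest-neighbor free energy, then to a binding constant, and the
#' measured intensity of that probe on each array is inverted through the
#' Langmuir isotherm into a transcript concentration in pM. Saturated
#' intensities are censored and propagate as missing values; missing
#' intensities stay missing.
#'
#' @param intensities Numeric matrix, probes x arrays, with probe ids as
#'   row names and array ids as column names; values >= 0 or `NA`.
#' @param annotation Data frame with columns `probe_id`, `probeset_id`,
#'   `sequence` covering every row of `intensities`.
#' @param nn An [nn_params()] table.
#' @param params A [langmuir_params()] object.
#' @return An object of class `conc_matrix`: a list with `values`
#'   (probes x arrays concentration matrix, pM), `censored` and
#'   `below_background` masks, `free_energy` and `K` per probe.
#' @export
estimate_concentrations <- function(intensities, annotation, nn,
                                    params = langmuir_params()) {
  intensities <- as.matrix(intensities)
  if (length(intensities) == 0) stop("empty intensity matrix")
  if (is.null(rownames(intensities))) {
    stop("intensity matrix must carry probe ids as row names")
  }
  if (any(intensities < 0, na.rm = TRUE)) {
    stop("negative intensities are not allowed")
  }
  hit <- match(rownames(intensities), annotation$probe_id)
  if (anyNA(hit)) {
    stop("unannotated probes: ",
         paste(utils::head(rownames(intensities)[is.na(hit)], 5),
               collapse = ", "))
  }
  dg <- .free_energy_many(annotation$sequence[hit], nn)
  k <- as.numeric(binding_constant(dg, params$thermo))
  inv <- invert_langmuir(intensities, k, params)
  structure(list(values = inv$concentration,
                 censored = inv$censored,
                 below_background = inv$below_background,
                 probe_ids = rownames(intensities),
                 array_ids = colnames(intensities),
                 free_energy = dg,
                 K = k),
            class = "conc_matrix")
}

#' @export
print.conc_matrix <- function(x, ...) {
  cat("Probe-level concentration matrix:",
      nrow(x$values), "probes x", ncol(x$values), "arrays\n")
  cat("  censored (saturated):", sum(x$censored), "entries;",
      "below background:", sum(x$below_background), "entries\n")
  invisible(x)
}

.conc_values <- function(conc) {
  if (inherits(conc, "conc_matrix")) conc$values else as.matrix(conc)
}

#' Global multiplicative rescaling of concentrations across arrays
#'
#' Differences between arrays are assumed to stem mainly from the amount
#' of hybridized material, so estimated concentrations are rescaled by a
#' single multiplicative factor per array, chosen so that the pairwise
#' comparison of concentrations between arrays has slope one. The
#' pseudo-reference for each probe is its median concentration across
#' arrays; the factor of an array is the median across probes of the
#' ratio to the pseudo-reference. Because the pseudo-reference itself
#' moves when arrays are rescaled, the sweep is iterated to its fixed
#' point, at which the median ratio of every array to the reference is
#' exactly 1 and a second application returns factors of 1.
#'
#' Censored and non-positive entries are excluded from the factor
#' computation (they would bias the median near the isotherm pole) but
#' are still divided by the final factors.
#'
#' @param conc A `conc_matrix` from [estimate_concentrations()] or a
#'   plain probes x arrays matrix (>= 2 arrays).
#' @param tol Convergence tolerance on `max |factor - 1|` per sweep.
#' @param max_iter Sweep cap.
#' @return A list with `conc` (same class as the input, rescaled) and
#'   `scaling`, itself a list with the accumulated per-array `factors`
#'   and a `reference_description` string.
#' @export
rescale_arrays <- function(conc, tol = 1e-13, max_iter = 100) {
  v <- .conc_values(conc)
  if (ncol(v) < 2) stop("rescaling needs at least 2 arrays")
  work <- v
  work[!is.finite(work) | work <= 0] <- NA_real_
  total <- rep(1, ncol(v))
  for (iter in seq_len(max_iter)) {
    ref <- apply(work, 1, stats::median, na.rm = TRUE)
    ratio <- work / ref
    ratio[!is.finite(ratio) | ratio <= 0] <- NA_real_
    f <- apply(ratio, 2, stats::median, na.rm = TRUE)
    if (anyNA(f)) {
      bad <- if (is.null(colnames(v))) which(is.na(f)) else
        colnames(v)[is.na(f)]
      stop("no usable probes to scale array(s): ",
           paste(bad, collapse = ", "))
    }
    work <- sweep(work, 2, f, "/")
    total <- total * f
    if (max(abs(f - 1)) < tol) break
  }
  names(total) <- colnames(v)
  scaled <- sweep(v, 2, total, "/")
  if (inherits(conc, "conc_matrix")) {
    conc$values <- scaled
  } else {
    conc <- scaled
  }
  list(conc = conc,
       scaling = list(
         factors = total,
         reference_description = paste(
           "per-probe median across arrays;",
           "per-array factor = median of ratios to the reference,",
           "iterated to a fixed point")))
}
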