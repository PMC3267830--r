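# Sequence-specific hybridization thermodynamics: nearest-neighbor free
# energies of probe/target duplexes and the resulting binding constants.

.DINUCLEOTIDES <- as.vector(t(outer(c("A", "C", "G", "T"),
                                    c("A", "C", "G", "T"), paste0)))

#' Nearest-neighbor free-energy parameter table
#'
#' Container for the 16 dinucleotide stacking contributions and the duplex
#' initiation offset of a nearest-neighbor hybridization model. Stacks are
#' indexed by the probe-strand dinucleotide read 5'->3' over the alphabet
#' ACGT; the value is the free-energy contribution (kcal/mol) of the stack
#' formed with the antiparallel complementary target dinucleotide.
#'
#' The package ships the RNA/DNA hybrid dG37 parameters of Sugimoto and
#' co-workers (1995), re-keyed to the DNA probe strand, in
#' `system.file("extdata", "sugimoto1995_rnadna_dg37.tsv", package =
#' "langmuirchip")`. Any table in the same format can be substituted.
#'
#' @param stack_dg Named numeric vector with exactly the 16 dinucleotide
#'   keys `AA`, `AC`, ..., `TT`; free-energy contributions in kcal/mol.
#' @param initiation_dg Scalar initiation free energy (kcal/mol).
#' @return An object of class `nn_params` with elements `stack_dg` and
#'   `initiation_dg`.
#' @seealso [load_nn_params()], [probe_free_energy()]
#' @examples
#' p <- nn_params(setNames(rep(-1, 16), langmuirchip:::.DINUCLEOTIDES))
#' probe_free_energy(strrep("A", 25), p)
#' @export
nn_params <- function(stack_dg, initiation_dg = 0) {
  if (is.null(names(stack_dg))) {
    stop("stack_dg must be a named vector of dinucleotide free energies")
  }
  missing <- setdiff(.DINUCLEOTIDES, names(stack_dg))
  if (length(missing) > 0) {
    stop("incomplete parameter table: missing ",
         paste(missing, collapse = ", "))
  }
  extra <- setdiff(names(stack_dg), .DINUCLEOTIDES)
  if (length(extra) > 0) {
    stop("unknown dinucleotide keys: ", paste(extra, collapse = ", "))
  }
  stack_dg <- stack_dg[.DINUCLEOTIDES]
  if (!all(is.finite(stack_dg)) || !is.finite(initiation_dg)) {
    stop("all free-energy values must be finite")
  }
  structure(list(stack_dg = stack_dg, initiation_dg = initiation_dg),
            class = "nn_params")
}

#' @export
print.nn_params <- function(x, ...) {
  cat("Nearest-neighbor parameter table (kcal/mol)\n")
  cat("  initiation:", format(x$initiation_dg), "\n")
  cat("  stacks:\n")
  print(x$stack_dg)
  invisible(x)
}

#' Read a nearest-neighbor parameter file
#'
#' Parses a plain-text, tab-separated table of nearest-neighbor stacking
#' free energies: one line `XY<TAB>value` per dinucleotide (16 required)
#' plus one `INIT<TAB>value` line for the initiation term. Lines starting
#' with `#` and blank lines are ignored.
#'
#' @param path Path to the parameter file.
#' @return An [nn_params()] object.
#' @examples
#' f <- system.file("extdata", "sugimoto1995_rnadna_dg37.tsv",
#'                  package = "langmuirchip")
#' load_nn_params(f)
#' @export
load_nn_params <- function(path) {
  if (!file.exists(path)) stop("parameter file not found: ", path)
  lines <- readLines(path)
  keep <- !grepl("^\\s*(#|$)", lines)
  stacks <- numeric(0)
  init <- NULL
  for (i in which(keep)) {
    fields <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    if (length(fields) != 2) {
      stop("malformed parameter line ", i, ": '", lines[i], "'")
    }
    value <- suppressWarnings(as.numeric(fields[2]))
    if (is.na(value)) {
      stop("non-numeric free-energy value on line ", i, ": '", fields[2], "'")
    }
    key <- toupper(fields[1])
    if (key == "INIT") {
      init <- value
    } else if (key %in% .DINUCLEOTIDES) {
      stacks[key] <- value
    } else {
      stop("unknown key on line ", i, ": '", fields[1], "'")
    }
  }
  missing <- setdiff(.DINUCLEOTIDES, names(stacks))
  if (length(missing) > 0) {
    stop("incomplete parameter table: missing ",
         paste(missing, collapse = ", "))
  }
  nn_params(stacks, if (is.null(init)) 0 else init)
}

#' Thermodynamic configuration
#'
#' Temperature and gas constant entering the binding constant
#' `K = exp(-(dG - dG_ref) / (R T))`, plus an optional reference free
#' energy `dg_reference` (kcal/mol, default 0). The reference shifts all
#' free energies by a common offset and thereby fixes the scale of `K`;
#' with the default 0 the binding constant is the textbook
#' `exp(-dG/RT)`. The pipeline defaults use `dg_reference = -37.7` so
#' that `c` in pM times `K` is a dimensionless coverage of order one for
#' typical 25-mer probes (see the methods vignette for the convention).
#'
#' @param temperature_K Hybridization temperature in kelvin (> 0).
#'   Default 318.15 K (45 C, standard GeneChip hybridization).
#' @param gas_constant Gas constant in kcal/(mol K) (> 0).
#' @param dg_reference Reference free energy in kcal/mol subtracted from
#'   every probe free energy before exponentiation.
#' @return An object of class `thermo_config`.
#' @export
thermo_config <- function(temperature_K = 318.15,
                          gas_constant = 0.0019872,
                          dg_reference = 0) {
  stopifnot(is.numeric(temperature_K), length(temperature_K) == 1,
            temperature_K > 0,
            is.numeric(gas_constant), length(gas_constant) == 1,
            gas_constant > 0,
            is.numeric(dg_reference), length(dg_reference) == 1,
            is.finite(dg_reference))
  structure(list(temperature_K = temperature_K,
                 gas_constant = gas_constant,
                 dg_reference = dg_reference),
            class = "thermo_config")
}

.check_sequences <- function(sequences) {
  if (length(sequences) == 0) stop("no sequences supplied")
  bad <- regexpr("[^ACGT]", sequences)
  if (any(bad > 0)) {
    i <- which(bad > 0)[1]
    stop("invalid character in sequence ", i, " at position ", bad[i],
         ": '", substr(sequences[i], bad[i], bad[i]), "'")
  }
  if (any(nchar(sequences) < 2)) {
    stop("sequences must have length >= 2")
  }
  invisible(TRUE)
}

# Vectorized nearest-neighbor sum over many sequences; used throughout the
# pipeline (tens of thousands of probes at a time).
.free_energy_many <- function(sequences, params) {
  .check_sequences(sequences)
  len <- nchar(sequences)
  out <- rep(params$initiation_dg, length(sequences))
  for (i in seq_len(max(len) - 1)) {
    idx <- which(len > i)
    out[idx] <- out[idx] +
      unname(params$stack_dg[substr(sequences[idx], i, i + 1)])
  }
  names(out) <- names(sequences)
  out
}

#' Hybridization free energy of a probe sequence
#'
#' Nearest-neighbor free energy of the duplex formed by a probe and its
#' complementary target: the initiation term plus the sum of the stacking
#' contributions of the `L - 1` overlapping dinucleotides of the probe
#' strand read 5'->3'.
#'
#' @param sequence Character vector of probe sequences over ACGT, each of
#'   length >= 2 (25-mers on standard chips).
#' @param params An [nn_params()] table.
#' @return Numeric vector of free energies (kcal/mol), one per sequence.
#' @examples
#' p <- load_nn_params(system.file("extdata", "sugimoto1995_rnadna_dg37.tsv",
#'                                 package = "langmuirchip"))
#' probe_free_energy("ACGTACGTACGTACGTACGTACGTA", p)
#' @export
probe_free_energy <- function(sequence, params) {
  stopifnot(inherits(params, "nn_params"))
  .free_energy_many(sequence, params)
}

#' Binding constant from a hybridization free energy
#'
#' Converts free energies to equilibrium binding constants,
#' `K = exp(-(dG - dG_ref) / (R T))`, with `R`, `T` and `dG_ref` taken
#' from the thermodynamic configuration (with the default configuration,
#' `K = exp(-dG/RT)`). `K` is expressed so that a concentration in pM
#' times `K` is the dimensionless occupancy argument of the Langmuir
#' isotherm; any residual scale is absorbed by the saturation amplitude.
#'
#' Exponents above 700 are clamped to avoid silent overflow to `Inf`; in
#' that case the result carries a logical attribute `clamped` marking the
#' affected entries.
#'
#' @param dg Numeric vector of free energies (kcal/mol), finite.
#' @param config A [thermo_config()].
#' @return Numeric vector of binding constants (> 0).
#' @examples
#' binding_constant(0, thermo_config())           # exactly 1
#' cfg <- thermo_config()
#' rt <- cfg$gas_constant * cfg$temperature_K
#' binding_constant(-rt * log(10), cfg)           # exactly 10
#' @export
binding_constant <- function(dg, config = thermo_config()) {
  stopifnot(inherits(config, "thermo_config"))
  if (!all(is.finite(dg))) stop("free energies must be finite")
  rt <- config$gas_constant * config$temperature_K
  expo <- -(dg - config$dg_reference) / rt
  clamped <- expo > 700
  expo[clamped] <- 700
  k <- exp(expo)
  if (any(clamped)) attr(k, "clamped") <- clamped
  k
}
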