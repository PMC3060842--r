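# Mass tables and peptide mass / m/z arithmetic.
#
# The residue and constant tables are shipped as plain-text TSV resources
# under inst/extdata (single source of truth, with provenance notes in the
# file headers) and loaded once per session.

load_mass_resources <- function() {
  if (!is.null(.pu$masses)) {
    return(invisible(.pu$masses))
  }
  res <- utils::read.delim(
    system.file("extdata", "residue_masses.tsv", package = "protutils", mustWork = TRUE),
    comment.char = "#", stringsAsFactors = FALSE
  )
  con <- utils::read.delim(
    system.file("extdata", "mass_constants.tsv", package = "protutils", mustWork = TRUE),
    comment.char = "#", stringsAsFactors = FALSE
  )
  constants <- stats::setNames(as.list(con$value), con$name)
  .pu$masses <- list(residues = res, constants = constants)
  invisible(.pu$masses)
}

#' Amino-acid residue mass table
#'
#' Returns the residue mass tables and physical constants used by all mass
#' computations. Residue masses are the masses amino acids contribute
#' inside a peptide chain (free amino acid minus one water).
#'
#' @param permissive if `TRUE`, the table additionally contains the
#'   non-canonical residues U (selenocysteine) and O (pyrrolysine). The
#'   default table rejects them so that unusual sequences fail loudly.
#' @return a list with elements `residue_mono` and `residue_avg` (named
#'   numeric vectors, one-letter codes) and `constants` (named list with
#'   `proton`, `water_mono`, `water_avg`, `nh3`, `co`, `h2`, `hydrogen`,
#'   all in Da).
#' @examples
#' mt <- mass_table()
#' mt$residue_mono[["G"]]
#' mt$constants$water_mono
#' @export
mass_table <- function(permissive = FALSE) {
  m <- load_mass_resources()
  res <- m$residues
  if (!permissive) {
    res <- res[res$standard == 1L, ]
  }
  list(
    residue_mono = stats::setNames(res$mono, res$residue),
    residue_avg  = stats::setNames(res$avg, res$residue),
    constants    = m$constants
  )
}

#' Define a fixed-mass modification
#'
#' A modification is a named mass shift attached to a residue or a peptide
#' terminus (e.g. oxidation +15.994915 Da on M, or an N-terminal acetyl
#' +42.010565 Da).
#'
#' @param name display name, e.g. `"Oxidation"`
#' @param mass_shift signed monoisotopic mass shift in Da; must be finite
#' @param target one-letter residue code, `"N-term"` or `"C-term"`
#' @return an object of class `modification`
#' @examples
#' modification("Oxidation", 15.994915, "M")
#' @export
modification <- function(name, mass_shift, target) {
  stopifnot(is.character(name), length(name) == 1L)
  if (!is.numeric(mass_shift) || length(mass_shift) != 1L || !is.finite(mass_shift)) {
    pu_stop("invalid_modification", "modification mass_shift must be a finite number")
  }
  mt <- mass_table(permissive = TRUE)
  if (!(target %in% c(names(mt$residue_mono), "N-term", "C-term"))) {
    pu_stop(
      "invalid_modification",
      "modification target must be a residue code, \"N-term\" or \"C-term\", got \"", target, "\""
    )
  }
  structure(
    list(name = name, mass_shift = as.numeric(mass_shift), target = target),
    class = "modification"
  )
}

#' @export
print.modification <- function(x, ...) {
  cat(sprintf(
    "<modification> %s %+0.6f Da on %s\n", x$name, x$mass_shift, x$target
  ))
  invisible(x)
}

# Validate a residue sequence against the active table; returns the
# per-residue mass vector. Errors name the offending character and its
# 1-based position.
residue_masses <- function(sequence, table, kind = c("mono", "avg")) {
  kind <- match.arg(kind)
  if (!is.character(sequence) || length(sequence) != 1L || is.na(sequence) ||
      nchar(sequence) == 0L) {
    pu_stop("invalid_sequence", "sequence must be a non-empty string")
  }
  chars <- strsplit(sequence, "", fixed = TRUE)[[1L]]
  tab <- if (kind == "mono") table$residue_mono else table$residue_avg
  idx <- match(chars, names(tab))
  if (anyNA(idx)) {
    bad <- which(is.na(idx))[1L]
    pu_stop(
      "invalid_residue",
      "unknown residue '", chars[bad], "' at position ", bad, " in \"", sequence, "\""
    )
  }
  unname(tab[idx])
}

# Validate a modification list against a sequence of length n. Each element
# is list(position = <0..n+1>, mod = <modification>). Returns total shift.
modification_shift <- function(modifications, n) {
  if (length(modifications) == 0L) {
    return(0)
  }
  total <- 0
  for (m in modifications) {
    if (is.null(m$position) || is.null(m$mod) || !inherits(m$mod, "modification")) {
      pu_stop(
        "invalid_modification",
        "each modification must be list(position =, mod = modification(...))"
      )
    }
    p <- m$position
    if (!is.numeric(p) || length(p) != 1L || p != round(p) || p < 0 || p > n + 1) {
      pu_stop(
        "invalid_modification",
        "modification position ", format(p), " outside [0, ", n + 1,
        "] (0 = N-term, 1..n = residues, n+1 = C-term)"
      )
    }
    total <- total + m$mod$mass_shift
  }
  total
}

#' Monoisotopic mass of a peptide
#'
#' Computes the neutral monoisotopic mass as the sum of residue masses plus
#' one water, plus the mass shifts of any attached modifications.
#' Modification positions follow the convention 0 = N-terminus,
#' 1..n = residues, n+1 = C-terminus.
#'
#' @param sequence residue string (one-letter codes, uppercase)
#' @param modifications list of `list(position =, mod = modification(...))`
#' @param permissive allow U and O residues (see [mass_table()])
#' @return neutral mass in Da
#' @examples
#' monoisotopic_mass("G") # glycine: 57.021464 + 18.010565
#' monoisotopic_mass("PEPTIDE")
#' ox <- modification("Oxidation", 15.994915, "M")
#' monoisotopic_mass("AMK", modifications = list(list(position = 2, mod = ox)))
#' @export
monoisotopic_mass <- function(sequence, modifications = list(), permissive = FALSE) {
  tab <- mass_table(permissive = permissive)
  rm_ <- residue_masses(sequence, tab, "mono")
  sum(rm_) + tab$constants$water_mono +
    modification_shift(modifications, nchar(sequence))
}

#' Average mass of a peptide
#'
#' As [monoisotopic_mass()], but using abundance-weighted average residue
#' masses and average water. Modification shifts are applied as given.
#'
#' @inheritParams monoisotopic_mass
#' @return neutral average mass in Da
#' @export
average_mass <- function(sequence, modifications = list(), permissive = FALSE) {
  tab <- mass_table(permissive = permissive)
  rm_ <- residue_masses(sequence, tab, "avg")
  sum(rm_) + tab$constants$water_avg +
    modification_shift(modifications, nchar(sequence))
}

#' Mass-to-charge ratio of a neutral mass
#'
#' m/z = (M + z * proton) / z for a positive ion of charge z.
#'
#' @param neutral_mass neutral mass in Da
#' @param charge positive integer charge state
#' @return m/z in Th
#' @examples
#' mz(monoisotopic_mass("PEPTIDE"), 2)
#' @export
mz <- function(neutral_mass, charge) {
  check_charge(charge)
  p <- mass_table()$constants$proton
  (neutral_mass + charge * p) / charge
}

#' Neutral mass from an observed m/z
#'
#' Exact inverse of [mz()]: M = m/z * z - z * proton.
#'
#' @param mz_value observed m/z in Th
#' @param charge positive integer charge state
#' @return neutral mass in Da
#' @export
neutral_mass_from_mz <- function(mz_value, charge) {
  check_charge(charge)
  p <- mass_table()$constants$proton
  mz_value * charge - charge * p
}

check_charge <- function(charge) {
  if (!is.numeric(charge) || length(charge) != 1L || !is.finite(charge) ||
      charge < 1 || charge != round(charge)) {
    pu_stop("invalid_charge", "charge must be a positive integer, got ", format(charge))
  }
  invisible(TRUE)
}
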