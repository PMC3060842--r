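# Theoretical fragment-ion generation and matching of theoretical ions to
# observed peaks.
#
# Series definitions (monoisotopic, singly protonated):
#   b_i = sum(residues 1..i) + proton
#   y_i = sum(last i residues) + H2O + proton
#   a = b - CO;  c = b + NH3;  x = y + CO - H2;  z = y - NH3
# z is emitted as z-dot (z + 1 H) by default, the radical species ETD
# spectra conventionally show; plain z is available via `z_style`.

loss_residues <- list(H2O = c("S", "T", "E", "D"), NH3 = c("R", "K", "N", "Q"))

ion_label <- function(series, index, charge, loss) {
  paste0(
    series, index,
    if (loss != "none") paste0("-", loss) else "",
    strrep("+", charge)
  )
}

#' Generate theoretical fragment ions for a peptide
#'
#' Produces all ions of the requested series (a, b, c, x, y, z) at indices
#' 1..n-1 and charges 1..`max_charge`, optionally with H2O / NH3 neutral
#' losses. Modifications attached to the peptide shift the fragments that
#' contain them (N-terminal mods shift the a/b/c series, C-terminal mods
#' the x/y/z series, residue mods whichever fragments span the residue).
#'
#' With `chemically_aware = TRUE` (default) a neutral loss is generated
#' only when the fragment contains a residue able to lose it (H2O:
#' S, T, E, D; NH3: R, K, N, Q); with `FALSE` every fragment gets every
#' requested loss.
#'
#' @param pep a `peptide` object or residue string
#' @param series character vector drawn from `c("a","b","c","x","y","z")`
#' @param max_charge maximum fragment charge state (>= 1)
#' @param losses character vector drawn from `c("H2O", "NH3")`
#' @param chemically_aware restrict losses to chemically plausible
#'   fragments
#' @param z_style `"z_dot"` (default) or `"z"` for the plain z-ion offset
#' @return a data.frame with columns `series`, `index`, `charge`,
#'   `neutral_loss`, `mz`, `label`; a single-residue peptide yields zero
#'   rows (no internal bonds)
#' @examples
#' fragment_ions("PEPTIDE", series = c("b", "y"))
#' @export
fragment_ions <- function(pep, series = c("b", "y"), max_charge = 1L,
                          losses = character(), chemically_aware = TRUE,
                          z_style = c("z_dot", "z")) {
  z_style <- match.arg(z_style)
  pep <- as_peptide(pep)
  series <- match.arg(series, c("a", "b", "c", "x", "y", "z"), several.ok = TRUE)
  if (length(losses)) {
    losses <- match.arg(losses, c("H2O", "NH3"), several.ok = TRUE)
  }
  check_charge(max_charge)

  tab <- mass_table(permissive = pep$permissive)
  k <- tab$constants
  chars <- strsplit(pep$sequence, "", fixed = TRUE)[[1L]]
  n <- length(chars)
  empty <- data.frame(
    series = character(), index = integer(), charge = integer(),
    neutral_loss = character(), mz = numeric(), label = character(),
    stringsAsFactors = FALSE
  )
  if (n < 2L) {
    return(empty)
  }

  res <- unname(tab$residue_mono[chars])
  nterm_shift <- 0
  cterm_shift <- 0
  for (m in pep$modifications) {
    p <- m$position
    if (p == 0) {
      nterm_shift <- nterm_shift + m$mod$mass_shift
    } else if (p == n + 1) {
      cterm_shift <- cterm_shift + m$mod$mass_shift
    } else {
      res[p] <- res[p] + m$mod$mass_shift
    }
  }
  prefix <- cumsum(res) + nterm_shift           # neutral a/b/c backbone sums
  suffix <- rev(cumsum(rev(res))) + cterm_shift # suffix[i] = sum residues i..n

  idx <- seq_len(n - 1L)
  neutral_for <- function(s) {
    switch(s,
      b = prefix[idx],
      a = prefix[idx] - k$co,
      c = prefix[idx] + k$nh3,
      y = suffix[n - idx + 1L] + k$water_mono,
      x = suffix[n - idx + 1L] + k$water_mono + k$co - k$h2,
      z = suffix[n - idx + 1L] + k$water_mono - k$nh3 +
        if (z_style == "z_dot") k$hydrogen else 0
    )
  }
  # residues contained in fragment i of each side, for loss eligibility
  nterm_frag <- function(i) chars[seq_len(i)]
  cterm_frag <- function(i) chars[seq.int(n - i + 1L, n)]

  rows <- list()
  for (s in sort(series)) {
    neutral <- neutral_for(s)
    nterm_side <- s %in% c("a", "b", "c")
    for (i in idx) {
      frag_res <- if (nterm_side) nterm_frag(i) else cterm_frag(i)
      loss_set <- "none"
      for (L in losses) {
        if (!chemically_aware || any(frag_res %in% loss_residues[[L]])) {
          loss_set <- c(loss_set, L)
        }
      }
      for (L in loss_set) {
        loss_mass <- switch(L, none = 0, H2O = k$water_mono, NH3 = k$nh3)
        for (z in seq_len(max_charge)) {
          rows[[length(rows) + 1L]] <- data.frame(
            series = s, index = i, charge = z, neutral_loss = L,
            mz = (neutral[i] - loss_mass + z * k$proton) / z,
            label = ion_label(s, i, z, L),
            stringsAsFactors = FALSE
          )
        }
      }
    }
  }
  out <- do.call(rbind, c(list(empty), rows))
  rownames(out) <- NULL
  out
}

#' Annotate spectrum peaks with theoretical fragment ions
#'
#' Each ion is matched to at most one peak: the peak minimizing
#' |observed - theoretical| within the tolerance, with ties broken by
#' higher intensity, then lower m/z. Multiple ions may annotate the same
#' peak. Unmatched ions are simply absent from the result, which is sorted
#' by (theoretical m/z, series, index, charge) and therefore invariant
#' under permutation of the input ion list.
#'
#' @param spec a `spectrum` (peaks ascending in m/z)
#' @param ions data.frame from [fragment_ions()]
#' @param tolerance numeric matching tolerance
#' @param unit `"Da"` or `"ppm"` (ppm is relative to the theoretical m/z)
#' @return a data.frame with columns `peak_index`, `series`, `index`,
#'   `charge`, `neutral_loss`, `label`, `theoretical_mz`, `observed_mz`,
#'   `intensity`, `error_mz` (signed, observed - theoretical)
#' @examples
#' sp <- spectrum(c(76.039, 147.113), c(100, 40))
#' annotate_spectrum(sp, fragment_ions("GK"), tolerance = 0.01)
#' @export
annotate_spectrum <- function(spec, ions, tolerance, unit = c("Da", "ppm")) {
  unit <- match.arg(unit)
  if (!is.numeric(tolerance) || tolerance <= 0) {
    pu_stop("invalid_tolerance", "tolerance must be a positive number")
  }
  stopifnot(inherits(spec, "spectrum"))
  obs_mz <- spec$mz
  obs_int <- spec$intensity
  out <- vector("list", nrow(ions))
  for (r in seq_len(nrow(ions))) {
    theo <- ions$mz[r]
    tol_da <- if (unit == "Da") tolerance else tolerance * theo / 1e6
    if (length(obs_mz) == 0L) next
    err <- obs_mz - theo
    inside <- which(abs(err) <= tol_da)
    if (length(inside) == 0L) next
    # min |error|, tie: higher intensity, then lower m/z
    o <- inside[order(abs(err[inside]), -obs_int[inside], obs_mz[inside])][1L]
    out[[r]] <- data.frame(
      peak_index = o,
      series = ions$series[r], index = ions$index[r], charge = ions$charge[r],
      neutral_loss = ions$neutral_loss[r], label = ions$label[r],
      theoretical_mz = theo, observed_mz = obs_mz[o], intensity = obs_int[o],
      error_mz = obs_mz[o] - theo,
      stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, c(
    list(data.frame(
      peak_index = integer(), series = character(), index = integer(),
      charge = integer(), neutral_loss = character(), label = character(),
      theoretical_mz = numeric(), observed_mz = numeric(),
      intensity = numeric(), error_mz = numeric(), stringsAsFactors = FALSE
    )),
    out[!vapply(out, is.null, logical(1L))]
  ))
  out <- out[order(out$theoretical_mz, out$series, out$index, out$charge,
                   out$neutral_loss), , drop = FALSE]
  rownames(out) <- NULL
  out
}
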