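# Spectrum and chromatogram models and MGF (Mascot Generic Format) I/O.

#' Construct a mass spectrum
#'
#' Peaks are sorted ascending by m/z on construction (stable, so duplicate
#' m/z values are retained in input order).
#'
#' @param mz_values numeric vector of m/z values (Th)
#' @param intensity nonnegative numeric vector, same length
#' @param precursor_mz precursor m/z or `NA`
#' @param precursor_charge integer precursor charge or `NA`
#' @param title spectrum title
#' @param level MS level (1 = MS, 2 = MS/MS)
#' @return an object of class `spectrum`
#' @examples
#' spectrum(c(100.1, 200.2, 300.3), c(10, 50, 20), precursor_mz = 500.25,
#'          precursor_charge = 2, title = "demo")
#' @export
spectrum <- function(mz_values, intensity, precursor_mz = NA_real_,
                     precursor_charge = NA_integer_, title = "", level = 2L) {
  if (length(mz_values) != length(intensity)) {
    pu_stop("invalid_spectrum", "mz and intensity must have equal length")
  }
  if (length(intensity) && any(intensity < 0)) {
    pu_stop("invalid_spectrum", "intensities must be >= 0")
  }
  ord <- order(mz_values) # stable radix sort
  structure(
    list(
      mz = as.numeric(mz_values[ord]), intensity = as.numeric(intensity[ord]),
      precursor_mz = as.numeric(precursor_mz),
      precursor_charge = as.integer(precursor_charge),
      title = title, level = as.integer(level)
    ),
    class = "spectrum"
  )
}

#' @export
print.spectrum <- function(x, ...) {
  cat(sprintf(
    "<spectrum> \"%s\" MS%d, %d peaks%s\n", x$title, x$level, length(x$mz),
    if (!is.na(x$precursor_mz)) {
      sprintf(", precursor %.4f (%s+)", x$precursor_mz,
              ifelse(is.na(x$precursor_charge), "?", x$precursor_charge))
    } else ""
  ))
  invisible(x)
}

#' Construct a chromatogram
#'
#' @param time ascending numeric vector of retention times (seconds)
#' @param signal nonnegative numeric vector, same length
#' @param label trace label
#' @return an object of class `chromatogram`
#' @export
chromatogram <- function(time, signal, label = "") {
  if (length(time) != length(signal)) {
    pu_stop("invalid_chromatogram", "time and signal must have equal length")
  }
  if (length(time) > 1L && any(diff(time) <= 0)) {
    pu_stop("invalid_chromatogram", "time must be strictly ascending")
  }
  if (length(signal) && any(signal < 0)) {
    pu_stop("invalid_chromatogram", "signal must be >= 0")
  }
  structure(
    list(time = as.numeric(time), signal = as.numeric(signal), label = label),
    class = "chromatogram"
  )
}

#' Read spectra from an MGF peak list
#'
#' Accepts the common MGF dialect: `BEGIN IONS`/`END IONS` blocks with
#' `TITLE`, `PEPMASS` and `CHARGE` keys and `m/z intensity` peak lines
#' (`CHARGE=2+` is parsed to +2). Peaks are sorted ascending by m/z.
#'
#' @param source file path or MGF text
#' @return a list of `spectrum` objects
#' @export
read_mgf <- function(source) {
  lines <- fasta_lines(source)
  spectra <- list()
  in_block <- FALSE
  block_line <- NA_integer_
  title <- ""
  pmz <- NA_real_
  pz <- NA_integer_
  pk_mz <- numeric()
  pk_int <- numeric()
  for (i in seq_along(lines)) {
    line <- trimws(lines[i])
    if (!nzchar(line) || startsWith(line, "#")) next
    if (line == "BEGIN IONS") {
      if (in_block) {
        pu_stop("malformed_mgf", "BEGIN IONS inside open block at line ", i)
      }
      in_block <- TRUE
      block_line <- i
      title <- ""
      pmz <- NA_real_
      pz <- NA_integer_
      pk_mz <- numeric()
      pk_int <- numeric()
    } else if (line == "END IONS") {
      if (!in_block) {
        pu_stop("malformed_mgf", "END IONS without BEGIN IONS at line ", i)
      }
      spectra[[length(spectra) + 1L]] <- spectrum(
        pk_mz, pk_int,
        precursor_mz = pmz, precursor_charge = pz, title = title
      )
      in_block <- FALSE
    } else if (!in_block) {
      pu_stop("malformed_mgf", "data outside BEGIN IONS/END IONS at line ", i)
    } else if (grepl("=", line, fixed = TRUE)) {
      key <- toupper(sub("=.*$", "", line))
      val <- sub("^[^=]*=", "", line)
      if (key == "TITLE") {
        title <- val
      } else if (key == "PEPMASS") {
        pmz <- suppressWarnings(as.numeric(strsplit(trimws(val), "[ \t]+")[[1L]][1L]))
        if (is.na(pmz)) pu_stop("malformed_mgf", "non-numeric PEPMASS at line ", i)
      } else if (key == "CHARGE") {
        zm <- regmatches(val, regexec("^([0-9]+)([+-]?)$", trimws(val)))[[1L]]
        if (length(zm) == 0L) pu_stop("malformed_mgf", "unparseable CHARGE at line ", i)
        pz <- as.integer(zm[2L]) * if (identical(zm[3L], "-")) -1L else 1L
      } # other keys ignored
    } else {
      vals <- suppressWarnings(as.numeric(strsplit(line, "[ \t]+")[[1L]]))
      if (length(vals) < 2L || anyNA(vals[1:2])) {
        pu_stop("malformed_mgf", "non-numeric peak line at line ", i)
      }
      pk_mz <- c(pk_mz, vals[1L])
      pk_int <- c(pk_int, vals[2L])
    }
  }
  if (in_block) {
    pu_stop("malformed_mgf", "block opened at line ", block_line,
            " is missing END IONS")
  }
  spectra
}

#' Write spectra to an MGF peak list
#'
#' Fixed numeric formatting: m/z with 4 decimals, intensity with 2.
#' A spectrum without a precursor omits the PEPMASS line. Inverse of
#' [read_mgf()] on its own output (to printed precision).
#'
#' @param spectra list of `spectrum` objects
#' @param path output file path, or `NULL` to return the text
#' @param mz_digits decimals for m/z values
#' @param intensity_digits decimals for intensities
#' @return invisibly, the MGF text
#' @export
write_mgf <- function(spectra, path = NULL, mz_digits = 4L, intensity_digits = 2L) {
  out <- character()
  for (sp in spectra) {
    block <- "BEGIN IONS"
    if (nzchar(sp$title)) block <- c(block, paste0("TITLE=", sp$title))
    if (!is.na(sp$precursor_mz)) {
      block <- c(block, sprintf("PEPMASS=%.*f", mz_digits, sp$precursor_mz))
    }
    if (!is.na(sp$precursor_charge)) {
      block <- c(block, sprintf(
        "CHARGE=%d%s", abs(sp$precursor_charge),
        if (sp$precursor_charge < 0) "-" else "+"
      ))
    }
    if (length(sp$mz)) {
      block <- c(block, sprintf(
        "%.*f %.*f", mz_digits, sp$mz, intensity_digits, sp$intensity
      ))
    }
    out <- c(out, block, "END IONS", "")
  }
  text <- paste0(paste(out, collapse = "\n"), if (length(out)) "\n" else "")
  if (!is.null(path)) {
    writeLines(out, path)
  }
  invisible(text)
}

# ---- view states and linked zooming --------------------------------------

#' Create a view state (axis window)
#'
#' A view state models the visible x-axis window of a spectrum or
#' chromatogram panel. Views can be linked with [link_views()] so that
#' zooming one propagates to all members of the group.
#'
#' @param x_min,x_max window bounds, `x_min < x_max`
#' @return an object of class `view_state` (mutable handle)
#' @export
view_state <- function(x_min, x_max) {
  if (!(x_min < x_max)) {
    pu_stop("invalid_view", "x_min must be < x_max")
  }
  v <- new.env(parent = emptyenv())
  v$x_min <- x_min
  v$x_max <- x_max
  v$group <- NULL
  v$updates <- 0L
  class(v) <- "view_state"
  v
}

#' Current window of a view state
#' @param view a `view_state`
#' @return numeric `c(x_min, x_max)`
#' @export
view_window <- function(view) {
  c(view$x_min, view$x_max)
}

#' Link view states into a zoom group
#'
#' After linking, [set_window()] on any member propagates the window to
#' every member of the group. Propagation is idempotent: re-setting the
#' current window fires no further updates.
#'
#' @param views list of at least two `view_state` objects
#' @return the group handle (invisibly); the views are modified in place
#' @export
link_views <- function(views) {
  if (length(views) < 2L) {
    pu_stop("invalid_view", "need at least two views to link")
  }
  group <- new.env(parent = emptyenv())
  group$members <- views
  for (v in views) v$group <- group
  invisible(group)
}

#' Remove a view from its zoom group
#' @param view a linked `view_state`
#' @return the view, invisibly
#' @export
unlink_view <- function(view) {
  g <- view$group
  if (!is.null(g)) {
    keep <- !vapply(g$members, identical, logical(1L), view)
    g$members <- g$members[keep]
    view$group <- NULL
  }
  invisible(view)
}

#' Set the window of a view, propagating to linked views
#'
#' @param view a `view_state`
#' @param x_min,x_max new window bounds
#' @return the view, invisibly
#' @export
set_window <- function(view, x_min, x_max) {
  if (!(x_min < x_max)) {
    pu_stop("invalid_view", "x_min must be < x_max")
  }
  targets <- if (is.null(view$group)) list(view) else view$group$members
  for (v in targets) {
    if (identical(v$x_min, x_min) && identical(v$x_max, x_max)) next
    v$x_min <- x_min
    v$x_max <- x_max
    v$updates <- v$updates + 1L
  }
  invisible(view)
}
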