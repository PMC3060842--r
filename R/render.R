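# Static rendering of spectra and chromatograms.
#
# SVG output is produced by a small deterministic generator: identical
# input yields byte-identical files, and annotation labels appear as
# literal <text> strings. PNG export goes through grDevices::png() with
# the same layout.

xml_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  gsub(">", "&gt;", x, fixed = TRUE)
}

fmt_num <- function(x) sprintf("%.2f", x)

# Deterministic label stacking: labels closer horizontally than 1% of the
# window width must not share a line; the higher-intensity peak keeps the
# base line and lower-intensity labels move up one line per conflict.
label_levels <- function(x, intensity, window_width) {
  n <- length(x)
  lev <- integer(n)
  if (n == 0L) {
    return(lev)
  }
  ord <- order(-intensity, x)
  placed_x <- numeric(0)
  placed_lev <- integer(0)
  for (i in ord) {
    L <- 0L
    repeat {
      clash <- any(placed_lev == L & abs(placed_x - x[i]) < 0.01 * window_width)
      if (!clash) break
      L <- L + 1L
    }
    lev[i] <- L
    placed_x <- c(placed_x, x[i])
    placed_lev <- c(placed_lev, L)
  }
  lev
}

render_geometry <- function(x_data, y_data, view, width, height) {
  mar <- c(left = 60, right = 20, top = 40, bottom = 50)
  if (is.null(view)) {
    if (length(x_data)) {
      r <- range(x_data)
      pad <- if (diff(r) > 0) 0.02 * diff(r) else 1
      xw <- c(r[1L] - pad, r[2L] + pad)
    } else {
      xw <- c(0, 1)
    }
  } else {
    xw <- view_window(view)
  }
  inside <- which(x_data >= xw[1L] & x_data <= xw[2L])
  ymax <- if (length(inside)) max(y_data[inside]) else 0
  yw <- c(0, if (ymax > 0) 1.05 * ymax else 1)
  list(
    xw = xw, yw = yw, inside = inside, mar = mar,
    px = function(x) mar[["left"]] + (x - xw[1L]) / diff(xw) * (width - mar[["left"]] - mar[["right"]]),
    py = function(y) height - mar[["bottom"]] - (y - yw[1L]) / diff(yw) * (height - mar[["top"]] - mar[["bottom"]])
  )
}

svg_header <- function(width, height, title) {
  c(
    "<?xml version=\"1.0\" encoding=\"UTF-8\"?>",
    sprintf(
      "<svg xmlns=\"http://www.w3.org/2000/svg\" width=\"%d\" height=\"%d\" viewBox=\"0 0 %d %d\">",
      width, height, width, height
    ),
    sprintf("<rect x=\"0\" y=\"0\" width=\"%d\" height=\"%d\" fill=\"white\"/>", width, height),
    if (nzchar(title)) {
      sprintf(
        "<text x=\"%s\" y=\"20\" font-family=\"sans-serif\" font-size=\"14\" text-anchor=\"middle\">%s</text>",
        fmt_num(width / 2), xml_escape(title)
      )
    }
  )
}

svg_axes <- function(g, width, height, xlab, ylab) {
  mar <- g$mar
  out <- c(
    sprintf(
      "<line x1=\"%s\" y1=\"%s\" x2=\"%s\" y2=\"%s\" stroke=\"black\"/>",
      fmt_num(mar[["left"]]), fmt_num(height - mar[["bottom"]]),
      fmt_num(width - mar[["right"]]), fmt_num(height - mar[["bottom"]])
    ),
    sprintf(
      "<line x1=\"%s\" y1=\"%s\" x2=\"%s\" y2=\"%s\" stroke=\"black\"/>",
      fmt_num(mar[["left"]]), fmt_num(mar[["top"]]),
      fmt_num(mar[["left"]]), fmt_num(height - mar[["bottom"]])
    )
  )
  for (t in pretty(g$xw, n = 6)) {
    if (t < g$xw[1L] || t > g$xw[2L]) next
    out <- c(out, sprintf(
      "<line x1=\"%s\" y1=\"%s\" x2=\"%s\" y2=\"%s\" stroke=\"black\"/><text x=\"%s\" y=\"%s\" font-family=\"sans-serif\" font-size=\"10\" text-anchor=\"middle\">%s</text>",
      fmt_num(g$px(t)), fmt_num(height - g$mar[["bottom"]]),
      fmt_num(g$px(t)), fmt_num(height - g$mar[["bottom"]] + 5),
      fmt_num(g$px(t)), fmt_num(height - g$mar[["bottom"]] + 18), format(t)
    ))
  }
  for (t in pretty(g$yw, n = 5)) {
    if (t < g$yw[1L] || t > g$yw[2L]) next
    out <- c(out, sprintf(
      "<line x1=\"%s\" y1=\"%s\" x2=\"%s\" y2=\"%s\" stroke=\"black\"/><text x=\"%s\" y=\"%s\" font-family=\"sans-serif\" font-size=\"10\" text-anchor=\"end\">%s</text>",
      fmt_num(g$mar[["left"]] - 5), fmt_num(g$py(t)),
      fmt_num(g$mar[["left"]]), fmt_num(g$py(t)),
      fmt_num(g$mar[["left"]] - 8), fmt_num(g$py(t) + 3), format(t)
    ))
  }
  c(out, sprintf(
    "<text x=\"%s\" y=\"%s\" font-family=\"sans-serif\" font-size=\"12\" text-anchor=\"middle\">%s</text>",
    fmt_num((mar[["left"]] + width - mar[["right"]]) / 2), fmt_num(height - 10), xml_escape(xlab)
  ), sprintf(
    "<text x=\"15\" y=\"%s\" font-family=\"sans-serif\" font-size=\"12\" text-anchor=\"middle\" transform=\"rotate(-90 15 %s)\">%s</text>",
    fmt_num(height / 2), fmt_num(height / 2), xml_escape(ylab)
  ))
}

svg_spectrum <- function(sp, annotations, view, width, height) {
  g <- render_geometry(sp$mz, sp$intensity, view, width, height)
  out <- c(svg_header(width, height, sp$title), svg_axes(g, width, height, "m/z", "intensity"))
  ann_idx <- if (is.null(annotations) || nrow(annotations) == 0L) {
    integer()
  } else {
    annotations$peak_index
  }
  for (i in g$inside) {
    col <- if (i %in% ann_idx) "red" else "black"
    out <- c(out, sprintf(
      "<line x1=\"%s\" y1=\"%s\" x2=\"%s\" y2=\"%s\" stroke=\"%s\"/>",
      fmt_num(g$px(sp$mz[i])), fmt_num(g$py(0)),
      fmt_num(g$px(sp$mz[i])), fmt_num(g$py(sp$intensity[i])), col
    ))
  }
  if (length(ann_idx)) {
    keep <- annotations$peak_index %in% g$inside
    ann <- annotations[keep, , drop = FALSE]
    if (nrow(ann)) {
      ax <- sp$mz[ann$peak_index]
      ay <- sp$intensity[ann$peak_index]
      lev <- label_levels(ax, ay, diff(g$xw))
      for (r in seq_len(nrow(ann))) {
        out <- c(out, sprintf(
          "<text x=\"%s\" y=\"%s\" font-family=\"sans-serif\" font-size=\"10\" fill=\"red\" text-anchor=\"middle\">%s</text>",
          fmt_num(g$px(ax[r])), fmt_num(g$py(ay[r]) - 4 - 12 * lev[r]),
          xml_escape(ann$label[r])
        ))
      }
    }
  }
  c(out, "</svg>")
}

svg_chromatogram <- function(ch, annotations, view, width, height) {
  g <- render_geometry(ch$time, ch$signal, view, width, height)
  out <- c(svg_header(width, height, ch$label), svg_axes(g, width, height, "time (s)", "signal"))
  if (length(g$inside) > 1L) {
    pts <- paste(
      fmt_num(g$px(ch$time[g$inside])), fmt_num(g$py(ch$signal[g$inside])),
      sep = ",", collapse = " "
    )
    out <- c(out, sprintf(
      "<polyline points=\"%s\" fill=\"none\" stroke=\"steelblue\"/>", pts
    ))
  }
  if (!is.null(annotations) && nrow(annotations)) {
    keep <- annotations$x >= g$xw[1L] & annotations$x <= g$xw[2L]
    ann <- annotations[keep, , drop = FALSE]
    for (r in seq_len(nrow(ann))) {
      yy <- if (length(g$inside)) {
        stats::approx(ch$time, ch$signal, ann$x[r], rule = 2)$y
      } else {
        0
      }
      out <- c(out, sprintf(
        "<text x=\"%s\" y=\"%s\" font-family=\"sans-serif\" font-size=\"10\" fill=\"red\" text-anchor=\"middle\">%s</text>",
        fmt_num(g$px(ann$x[r])), fmt_num(g$py(yy) - 6), xml_escape(ann$label[r])
      ))
    }
  }
  c(out, "</svg>")
}

#' Render a spectrum or chromatogram to an image file
#'
#' SVG files are produced by a deterministic generator (identical inputs
#' yield byte-identical files; annotation labels are searchable text).
#' PNG files are produced through the standard graphics device. Only data
#' inside the view window is drawn; annotated peaks are highlighted and
#' labelled, with horizontally colliding labels (closer than 1% of the
#' window width) stacked deterministically, lower-intensity labels moving
#' up one line per conflict.
#'
#' @param x a `spectrum` or `chromatogram`
#' @param file output file path
#' @param format `"svg"` or `"png"`
#' @param annotations for spectra, a data.frame from
#'   [annotate_spectrum()]; for chromatograms, a data.frame with columns
#'   `x` and `label`
#' @param view optional `view_state` restricting the x window
#' @param width,height image size in pixels
#' @return invisibly, the output file path
#' @examples
#' sp <- spectrum(c(100, 200, 300), c(5, 10, 2), title = "demo")
#' f <- tempfile(fileext = ".svg")
#' render(sp, f, format = "svg")
#' @export
render <- function(x, file, format = c("svg", "png"), annotations = NULL,
                   view = NULL, width = 800L, height = 500L) {
  if (!is.character(format) || length(format) > 2L) {
    pu_stop("unsupported_format", "format must be \"svg\" or \"png\"")
  }
  if (length(format) == 1L && !format %in% c("svg", "png")) {
    pu_stop("unsupported_format", "unsupported image format \"", format,
            "\"; supported: svg, png")
  }
  format <- match.arg(format)
  stopifnot(inherits(x, "spectrum") || inherits(x, "chromatogram"))
  if (format == "svg") {
    lines <- if (inherits(x, "spectrum")) {
      svg_spectrum(x, annotations, view, width, height)
    } else {
      svg_chromatogram(x, annotations, view, width, height)
    }
    con <- file(file, open = "wb")
    on.exit(close(con))
    writeLines(lines[!vapply(lines, is.null, logical(1L))], con, sep = "\n")
  } else {
    grDevices::png(file, width = width, height = height)
    on.exit(grDevices::dev.off())
    plot_panel(x, annotations, view)
  }
  invisible(file)
}

# base-graphics version of the same layout, used for PNG export and
# interactive display
plot_panel <- function(x, annotations = NULL, view = NULL) {
  if (inherits(x, "spectrum")) {
    g <- render_geometry(x$mz, x$intensity, view, 800, 500)
    graphics::plot(
      NA,
      xlim = g$xw, ylim = g$yw, xlab = "m/z", ylab = "intensity",
      main = x$title
    )
    if (length(g$inside)) {
      ann_idx <- if (is.null(annotations)) integer() else annotations$peak_index
      cols <- ifelse(g$inside %in% ann_idx, "red", "black")
      graphics::segments(x$mz[g$inside], 0, x$mz[g$inside], x$intensity[g$inside], col = cols)
      if (!is.null(annotations) && nrow(annotations)) {
        keep <- annotations$peak_index %in% g$inside
        ann <- annotations[keep, , drop = FALSE]
        if (nrow(ann)) {
          graphics::text(
            x$mz[ann$peak_index], x$intensity[ann$peak_index],
            labels = ann$label, pos = 3, col = "red", cex = 0.8
          )
        }
      }
    }
  } else {
    g <- render_geometry(x$time, x$signal, view, 800, 500)
    graphics::plot(
      x$time, x$signal,
      type = "l", xlim = g$xw, ylim = g$yw,
      xlab = "time (s)", ylab = "signal", main = x$label, col = "steelblue"
    )
    if (!is.null(annotations) && nrow(annotations)) {
      graphics::text(annotations$x, 0, labels = annotations$label, pos = 3, col = "red")
    }
  }
  invisible(NULL)
}
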