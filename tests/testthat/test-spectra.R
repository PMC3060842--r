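test_that("MGF blocks parse to spectra with precursor metadata", {
  txt <- paste(
    "BEGIN IONS",
    "TITLE=demo scan",
    "PEPMASS=500.2500",
    "CHARGE=2+",
    "100.0000 10.00",
    "200.0000 20.00",
    "300.0000 5.00",
    "END IONS",
    sep = "\n"
  )
  sps <- read_mgf(txt)
  expect_length(sps, 1)
  sp <- sps[[1]]
  expect_identical(length(sp$mz), 3L)
  expect_equal(sp$precursor_mz, 500.25)
  expect_identical(sp$precursor_charge, 2L)
  expect_identical(sp$title, "demo scan")
})

test_that("MGF round-trips randomly generated spectra to printed precision", {
  for (seed in c(3, 17, 99)) {
    txt <- make_mgf(fixture_spec(seed = seed))
    sps <- read_mgf(txt)
    expect_identical(write_mgf(sps), txt)
    # values survive a second cycle exactly (printing is idempotent)
    sps2 <- read_mgf(write_mgf(sps))
    expect_identical(length(sps2), length(sps))
    for (i in seq_along(sps)) {
      expect_identical(length(sps2[[i]]$mz), length(sps[[i]]$mz))
      expect_equal(sps2[[i]]$mz, sps[[i]]$mz, tolerance = 1e-12)
    }
  }
})

test_that("malformed MGF input fails with line numbers", {
  err <- tryCatch(
    read_mgf("BEGIN IONS\n100 10\nBEGIN IONS\nEND IONS"),
    error = identity
  )
  expect_s3_class(err, "protutils_malformed_mgf")
  expect_match(conditionMessage(err), "line 3")
  err2 <- tryCatch(read_mgf("BEGIN IONS\n100 ten\nEND IONS"), error = identity)
  expect_match(conditionMessage(err2), "line 2")
  expect_error(read_mgf("BEGIN IONS\n100 10"), class = "protutils_malformed_mgf")
  expect_identical(read_mgf(""), list())
  # spectrum without precursor omits PEPMASS on write
  txt <- write_mgf(list(spectrum(100, 1, title = "no precursor")))
  expect_false(grepl("PEPMASS", txt))
})

test_that("spectrum and chromatogram constructors enforce invariants", {
  expect_error(spectrum(1:3, 1:2), class = "protutils_invalid_spectrum")
  expect_error(spectrum(1, -1), class = "protutils_invalid_spectrum")
  sp <- spectrum(c(300, 100, 200), c(3, 1, 2))
  expect_identical(sp$mz, c(100, 200, 300))
  expect_identical(sp$intensity, c(1, 2, 3))
  expect_error(chromatogram(c(1, 1), c(0, 0)), class = "protutils_invalid_chromatogram")
})

test_that("SVG rendering is deterministic and labels are searchable", {
  res <- make_spectrum_for("PEPTIDER", noise_peaks = 5, seed = 12)
  ann <- annotate_spectrum(res$spectrum, res$ions, 0.01)
  f1 <- tempfile(fileext = ".svg")
  f2 <- tempfile(fileext = ".svg")
  render(res$spectrum, f1, "svg", annotations = ann)
  render(res$spectrum, f2, "svg", annotations = ann)
  b1 <- readBin(f1, "raw", file.size(f1))
  expect_identical(b1, readBin(f2, "raw", file.size(f2)))
  svg <- rawToChar(b1)
  for (lab in ann$label) {
    expect_true(grepl(lab, svg, fixed = TRUE), label = lab)
  }
  # a window excluding all peaks still renders axes without error
  f3 <- tempfile(fileext = ".svg")
  render(res$spectrum, f3, "svg", view = view_state(5000, 6000))
  expect_gt(file.size(f3), 0)
  expect_error(
    render(res$spectrum, tempfile(), format = "bmp"),
    class = "protutils_unsupported_format"
  )
})

test_that("PNG export writes a nonempty image file", {
  f <- tempfile(fileext = ".png")
  render(spectrum(c(100, 200), c(1, 2), title = "png demo"), f, "png")
  expect_gt(file.size(f), 0)
  expect_identical(readBin(f, "raw", 4), as.raw(c(0x89, 0x50, 0x4e, 0x47)))
})

test_that("chromatogram rendering draws the trace and time labels", {
  ch <- chromatogram(seq(0, 60, by = 0.5), abs(sin(seq(0, 60, by = 0.5) / 5)) * 100, "TIC")
  f <- tempfile(fileext = ".svg")
  render(ch, f, "svg", annotations = data.frame(x = 30, label = "elution apex"))
  svg <- paste(readLines(f), collapse = "\n")
  expect_true(grepl("polyline", svg))
  expect_true(grepl("elution apex", svg, fixed = TRUE))
})

test_that("zooming a linked view propagates to all members exactly once", {
  v <- lapply(1:3, function(i) view_state(0, 1000))
  link_views(v)
  set_window(v[[2]], 200, 400)
  for (x in v) expect_identical(view_window(x), c(200, 400))
  # idempotence: re-setting the same window fires no further updates
  counts <- vapply(v, function(x) x$updates, integer(1))
  set_window(v[[1]], 200, 400)
  expect_identical(vapply(v, function(x) x$updates, integer(1)), counts)
  # unlinked views stop following the group
  unlink_view(v[[3]])
  set_window(v[[1]], 100, 300)
  expect_identical(view_window(v[[1]]), c(100, 300))
  expect_identical(view_window(v[[2]]), c(100, 300))
  expect_identical(view_window(v[[3]]), c(200, 400))
  expect_error(view_state(5, 2), class = "protutils_invalid_view")
})

test_that("colliding annotation labels are stacked deterministically", {
  label_y <- function(mz2) {
    sp <- spectrum(c(500.00, mz2), c(100, 50))
    ions <- data.frame(
      series = "b", index = 1:2, charge = 1L, neutral_loss = "none",
      mz = c(500.00, mz2), label = c("big", "small"),
      stringsAsFactors = FALSE
    )
    ann <- annotate_spectrum(sp, ions, 0.01)
    f <- tempfile(fileext = ".svg")
    render(sp, f, "svg", annotations = ann, view = view_state(400, 600))
    svg <- readLines(f)
    pick <- function(tag) {
      as.numeric(sub(".*y=\"([0-9.]+)\".*", "\\1", grep(tag, svg, value = TRUE)))
    }
    c(big = pick(">big<"), small = pick(">small<"))
  }
  # peaks 0.05 Th apart collide inside a 200 Th window (1% = 2 Th); the
  # lower-intensity label is lifted one 12 px line relative to where the
  # same label sits without a collision (peak at 540, same intensities)
  collided <- label_y(500.05)
  apart <- label_y(540)
  expect_equal(collided[["big"]], apart[["big"]])
  expect_equal(collided[["small"]], apart[["small"]] - 12)
})
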