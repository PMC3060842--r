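test_that("b and y ions match hand-summed residue masses", {
  k <- mass_table()$constants
  fi <- fragment_ions("AG", series = c("b", "y"))
  b1 <- fi$mz[fi$series == "b" & fi$index == 1]
  y1 <- fi$mz[fi$series == "y" & fi$index == 1]
  expect_equal(b1, 71.037114 + k$proton, tolerance = 1e-5) # 72.04439
  expect_equal(y1, 57.021464 + k$water_mono + k$proton, tolerance = 1e-5) # 76.03930
  # single residue: no internal bonds
  expect_identical(nrow(fragment_ions("A")), 0L)
})

test_that("sibling series carry their fixed offsets from b and y", {
  k <- mass_table()$constants
  fi <- fragment_ions("PEPTIDEK", series = c("a", "b", "c", "x", "y", "z"))
  get <- function(s, i) fi$mz[fi$series == s & fi$index == i]
  for (i in c(1, 4, 7)) {
    expect_equal(get("a", i), get("b", i) - k$co, tolerance = 1e-9)
    expect_equal(get("c", i), get("b", i) + k$nh3, tolerance = 1e-9)
    expect_equal(get("x", i), get("y", i) + k$co - k$h2, tolerance = 1e-9)
    # default z is z-dot = z + 1 H
    expect_equal(get("z", i), get("y", i) - k$nh3 + k$hydrogen, tolerance = 1e-9)
  }
  plain <- fragment_ions("PEPTIDEK", series = "z", z_style = "z")
  expect_equal(
    plain$mz[plain$index == 2], get("y", 2) - k$nh3, tolerance = 1e-9
  )
})

test_that("b/y complementarity holds for random modified peptides", {
  k <- mass_table()$constants
  set.seed(5)
  for (rep in 1:30) {
    pseq <- random_peptide(sample(2:30, 1))
    mods <- if (rep %% 3 == 0) {
      list(list(
        position = sample(0:(nchar(pseq) + 1), 1),
        mod = modification("Test", runif(1, -10, 90), "N-term")
      ))
    } else {
      list()
    }
    pep <- peptide(pseq, mods)
    m <- monoisotopic_mass(pseq, mods)
    fi <- fragment_ions(pep, series = c("b", "y"))
    n <- nchar(pseq)
    for (i in seq_len(n - 1)) {
      b_i <- fi$mz[fi$series == "b" & fi$index == i]
      y_ni <- fi$mz[fi$series == "y" & fi$index == n - i]
      expect_equal(b_i + y_ni, m + 2 * k$proton, tolerance = 1e-6)
    }
  }
})

test_that("neutral losses follow residue chemistry when chemically aware", {
  # GG has no loss-capable residue; no H2O/NH3 ions at all
  fi <- fragment_ions("GGG", series = "b", losses = c("H2O", "NH3"))
  expect_identical(unique(fi$neutral_loss), "none")
  # but chemically_aware = FALSE forces all losses
  fi2 <- fragment_ions("GGG", series = "b", losses = c("H2O", "NH3"),
                       chemically_aware = FALSE)
  expect_setequal(unique(fi2$neutral_loss), c("none", "H2O", "NH3"))
  # serine enables H2O loss only for fragments containing it
  fi3 <- fragment_ions("GSK", series = "b", losses = "H2O")
  expect_identical(fi3$neutral_loss[fi3$index == 1], "none")
  expect_setequal(fi3$neutral_loss[fi3$index == 2], c("none", "H2O"))
  k <- mass_table()$constants
  b2 <- fi3$mz[fi3$index == 2 & fi3$neutral_loss == "none"]
  b2w <- fi3$mz[fi3$index == 2 & fi3$neutral_loss == "H2O"]
  expect_equal(b2 - b2w, k$water_mono, tolerance = 1e-9)
})

test_that("annotation picks the nearest peak with documented tie-breaks", {
  fi <- fragment_ions("GK", series = "y") # y1 = K + water + proton
  y1 <- fi$mz[fi$series == "y"]
  # nearest within tolerance, signed error recorded
  sp <- spectrum(c(y1 - 0.0003, 500), c(100, 10))
  ann <- annotate_spectrum(sp, fi, 0.01)
  expect_identical(nrow(ann), 1L)
  expect_equal(ann$error_mz, -0.0003, tolerance = 1e-9)
  # out of tolerance: unmatched ions are absent
  expect_identical(nrow(annotate_spectrum(spectrum(c(y1 + 0.05), 1), fi, 0.01)), 0L)
  # empty spectrum
  expect_identical(nrow(annotate_spectrum(spectrum(numeric(), numeric()), fi, 0.01)), 0L)
  # equidistant peaks: the higher-intensity one wins
  sp2 <- spectrum(c(y1 - 0.002, y1 + 0.002), c(10, 100))
  ann2 <- annotate_spectrum(sp2, fi, 0.01)
  expect_identical(ann2$peak_index, 2L)
  # equidistant and equally intense: the lower m/z wins
  sp3 <- spectrum(c(y1 - 0.002, y1 + 0.002), c(50, 50))
  expect_identical(annotate_spectrum(sp3, fi, 0.01)$peak_index, 1L)
})

test_that("ppm and Da tolerances agree at the equivalence point", {
  set.seed(3)
  for (i in 1:20) {
    pep <- random_peptide(sample(4:15, 1))
    fi <- fragment_ions(pep)
    target <- fi[sample(nrow(fi), 1), ]
    offset <- runif(1, -0.008, 0.008)
    sp <- spectrum(target$mz + offset, 100)
    tol_da <- 0.01
    tol_ppm <- tol_da / target$mz * 1e6
    a_da <- annotate_spectrum(sp, target, tol_da, unit = "Da")
    a_ppm <- annotate_spectrum(sp, target, tol_ppm, unit = "ppm")
    expect_identical(nrow(a_da), nrow(a_ppm))
    if (nrow(a_da)) expect_equal(a_da$error_mz, a_ppm$error_mz)
  }
})

test_that("annotation output is invariant under ion-list permutation", {
  set.seed(8)
  res <- make_spectrum_for("PEPTIDERK", noise_peaks = 20, seed = 4)
  ions <- res$ions
  a1 <- annotate_spectrum(res$spectrum, ions, 0.01)
  a2 <- annotate_spectrum(res$spectrum, ions[sample(nrow(ions)), ], 0.01)
  rownames(a2) <- NULL
  expect_identical(a1, a2)
})
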