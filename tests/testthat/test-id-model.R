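ids <- make_identifications(fixture_spec(seed = 101, n_psms = 6))

test_that("format sniffing identifies all three dialects and rejects others", {
  expect_identical(detect_format(ids$files$mascot_like), "mascot_like")
  expect_identical(detect_format(ids$files$xtandem_like), "xtandem_like")
  expect_identical(detect_format(ids$files$omssa_like), "omssa_like")
  err <- tryCatch(
    detect_format(">sp|P12345|X_HUMAN a fasta file\nPEPTIDE"),
    error = identity
  )
  expect_s3_class(err, "protutils_unknown_format")
  # the error enumerates the three sniff rules that failed
  for (tok in c("xtandem_like", "mascot_like", "omssa_like")) {
    expect_match(conditionMessage(err), tok)
  }
})

test_that("detection is stable under a UTF-8 BOM and Windows line endings", {
  for (f in names(ids$files)) {
    crlf <- gsub("\n", "\r\n", ids$files[[f]], fixed = TRUE)
    bom <- c(as.raw(c(0xEF, 0xBB, 0xBF)), charToRaw(crlf))
    expect_identical(detect_format(charToRaw(crlf)), f)
    expect_identical(detect_format(bom), f)
  }
})

test_that("one ground truth parses identically from all three dialects", {
  gt <- ids$ground_truth
  parsed <- lapply(ids$files, function(txt) read_identifications(txt))
  for (f in names(parsed)) {
    expect_identical(parsed[[f]]$detected_format, f)
    expect_matches_equal(parsed[[f]]$matches, gt)
  }
  # per-engine metadata is the only difference
  expect_identical(unique(parsed$mascot_like$matches$score_name), "ionscore")
  expect_identical(unique(parsed$mascot_like$matches$score_orientation), "higher_better")
  expect_identical(unique(parsed$xtandem_like$matches$score_name), "expect")
  expect_identical(unique(parsed$omssa_like$matches$score_name), "E-value")
  expect_identical(unique(parsed$omssa_like$matches$score_orientation), "lower_better")
  # parsing from a file path gives the same result as from text
  f <- tempfile(fileext = ".csv")
  writeLines(sub("\n$", "", ids$files$omssa_like), f)
  expect_matches_equal(read_identifications(f)$matches, gt)
})

test_that("search parameters ride along from the mascot-like dialect", {
  idf <- read_identifications(ids$files$mascot_like)
  expect_identical(idf$search_parameters$DB, "fixture")
})

test_that("empty result shells parse to zero matches", {
  empty <- make_identifications(fixture_spec(seed = 1, n_psms = 0))
  for (f in names(empty$files)) {
    idf <- read_identifications(empty$files[[f]])
    expect_identical(nrow(idf$matches), 0L)
  }
})

test_that("a rank-2 hit without a rank-1 hit parses with a warning", {
  gt <- ids$ground_truth
  only2 <- gt[gt$rank == 2L, ][1, ]
  txt <- protutils:::write_mascot_like(only2)
  expect_warning(
    idf <- read_identifications(txt),
    class = "protutils_missing_rank"
  )
  expect_identical(nrow(idf$matches), 1L)
  expect_identical(idf$matches$rank, 2L)
})

test_that("best_match_per_spectrum returns rank-1 hits with stated tie-breaks", {
  gt <- ids$ground_truth
  idf <- read_identifications(ids$files$xtandem_like)
  best <- best_match_per_spectrum(idf)
  expect_identical(nrow(best), length(unique(gt$spectrum_title)))
  expect_true(all(best$rank == 1L))
  # score-based selection when ranks are absent, tie -> lexicographic peptide
  m <- rbind(
    spectrum_match("s1", "YYYY", 10, "expect", "lower_better", 2, 500, "xtandem_like", "A", rank = 1L),
    spectrum_match("s1", "AAAA", 10, "expect", "lower_better", 2, 500, "xtandem_like", "A", rank = 1L)
  )
  m$rank <- NA_integer_
  fake <- structure(
    list(path = "x", detected_format = "xtandem_like", matches = m,
         search_parameters = list()),
    class = "id_file"
  )
  expect_identical(best_match_per_spectrum(fake)$peptide_sequence, "AAAA")
})

test_that("matches arrive ordered and re-ranking never promotes a match", {
  for (f in names(ids$files)) {
    m <- read_identifications(ids$files[[f]])$matches
    o <- order(m$spectrum_title, m$rank)
    expect_identical(o, seq_len(nrow(m)))
    # within each spectrum, rank 1..k contiguous from parse order
    for (t in unique(m$spectrum_title)) {
      expect_identical(m$rank[m$spectrum_title == t], seq_len(sum(m$spectrum_title == t)))
    }
  }
})

test_that("flatten_matches emits one atomic row per PSM", {
  flat <- flatten_matches(ids$ground_truth)
  expect_identical(nrow(flat), nrow(ids$ground_truth))
  expect_false(any(vapply(flat, is.list, logical(1))))
})
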