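# Independent oracles and shared helpers for the test suite.

# IUPAC standard atomic masses, used to recompute residue masses from
# elemental formulas independently of the shipped tables.
atomic_mono <- c(
  C = 12.000000, H = 1.0078250319, N = 14.0030740052,
  O = 15.9949146221, S = 31.97207069
)

formula_mass <- function(counts) {
  sum(atomic_mono[names(counts)] * unlist(counts))
}

# brute-force digestion oracle: enumerate every substring and keep those
# bounded by cleavage boundaries with at most m internal sites
digest_oracle <- function(sequence, enz, missed_max) {
  n <- nchar(sequence)
  chars <- strsplit(sequence, "", fixed = TRUE)[[1L]]
  sites <- integer()
  for (i in seq_len(max(0L, n - 1L))) {
    if (chars[i] %in% enz$cleave_after && !(chars[i + 1L] %in% enz$restrict_before)) {
      sites <- c(sites, i)
    }
  }
  bounds <- c(0L, sites, n)
  out <- list()
  for (s in 1:n) {
    for (e in s:n) {
      if (!((s - 1L) %in% bounds && e %in% bounds)) next
      internal <- sum(sites > (s - 1L) & sites < e)
      if (internal > missed_max) next
      out[[length(out) + 1L]] <- data.frame(
        sequence = substr(sequence, s, e), start = s, end = e,
        missed_cleavages = internal, stringsAsFactors = FALSE
      )
    }
  }
  df <- do.call(rbind, out)
  df <- df[order(df$start, df$end - df$start), ]
  rownames(df) <- NULL
  df
}

random_peptide <- function(len) {
  paste(sample(c(
    "G", "A", "S", "P", "V", "T", "C", "L", "I", "N",
    "D", "Q", "K", "E", "M", "H", "F", "R", "Y", "W"
  ), len, replace = TRUE), collapse = "")
}

sqlite_memory <- function() {
  DBI::dbConnect(RSQLite::SQLite(), ":memory:")
}

# equality of match tables up to the per-engine metadata columns
expect_matches_equal <- function(a, b) {
  core <- c(
    "spectrum_title", "peptide_sequence", "score", "charge",
    "precursor_mz", "rank"
  )
  expect_identical(a[core], b[core])
  expect_identical(a$modifications, b$modifications)
  expect_identical(a$protein_accessions, b$protein_accessions)
}
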