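# Deterministic generators for all test inputs: FASTA databases per header
# dialect, MGF peak lists, ground-truth PSM lists rendered into the three
# identification dialects, spectra with planted fragment ions, and random
# relational schemas. Every generator is a pure function of (seed, spec):
# the caller's RNG state is never touched.

amino_acids <- c(
  "G", "A", "S", "P", "V", "T", "C", "L", "I", "N",
  "D", "Q", "K", "E", "M", "H", "F", "R", "Y", "W"
)

word_pool <- c(
  "putative", "kinase", "receptor", "binding", "protein", "membrane",
  "transport", "factor", "subunit", "domain", "homolog", "precursor"
)

#' Fixture generation parameters
#'
#' @param seed central integer seed threaded to all sub-generators
#' @param n_proteins proteins per generated FASTA database
#' @param protein_length_range min/max protein length (residues)
#' @param n_spectra spectra per generated MGF file
#' @param peaks_per_spectrum_range min/max peaks per spectrum
#' @param n_psms peptide-spectrum matches per identification fixture
#' @param schema_count random schemas for data-access tests
#' @return an object of class `fixture_spec`
#' @export
fixture_spec <- function(seed = 1L, n_proteins = 5L,
                         protein_length_range = c(50L, 300L),
                         n_spectra = 5L, peaks_per_spectrum_range = c(10L, 60L),
                         n_psms = 6L, schema_count = 5L) {
  structure(
    list(
      seed = as.integer(seed), n_proteins = n_proteins,
      protein_length_range = protein_length_range, n_spectra = n_spectra,
      peaks_per_spectrum_range = peaks_per_spectrum_range,
      n_psms = n_psms, schema_count = schema_count
    ),
    class = "fixture_spec"
  )
}

random_sequence <- function(len) {
  paste(sample(amino_acids, len, replace = TRUE), collapse = "")
}

random_words <- function(n = 3L) {
  paste(sample(word_pool, n), collapse = " ")
}

make_header_line <- function(dialect, i) {
  switch(dialect,
    uniprot = sprintf(
      ">sp|P%05d|%s_HUMAN %s OS=Homo sapiens OX=9606",
      sample.int(99999, 1L),
      paste(sample(LETTERS, 4L), collapse = ""), random_words()
    ),
    ncbi_gi = sprintf(
      ">gi|%d|ref|NP_%06d.1| %s [Homo sapiens]",
      sample.int(9999999, 1L), sample.int(999999, 1L), random_words()
    ),
    ipi = sprintf(
      ">IPI:IPI%08d.1|SWISS-PROT:P%05d Tax_Id=9606 Gene_Symbol=%s %s",
      sample.int(99999999, 1L), sample.int(99999, 1L),
      paste(sample(LETTERS, 3L), collapse = ""), random_words()
    ),
    generic = sprintf(">fixture_%03d %s", i, random_words()),
    pu_stop("unknown_dialect", "unknown FASTA header dialect \"", dialect, "\"")
  )
}

#' Generate a FASTA database in a given header dialect
#'
#' @param spec a [fixture_spec()]
#' @param dialect `"uniprot"`, `"ncbi_gi"`, `"ipi"` or `"generic"`
#' @return FASTA text
#' @export
make_fasta <- function(spec = fixture_spec(), dialect = "uniprot") {
  if (!dialect %in% c("uniprot", "ncbi_gi", "ipi", "generic")) {
    pu_stop("unknown_dialect", "unknown FASTA header dialect \"", dialect, "\"")
  }
  with_seed(spec$seed, {
    out <- character()
    for (i in seq_len(spec$n_proteins)) {
      len <- sample(spec$protein_length_range[1L]:spec$protein_length_range[2L], 1L)
      seqs <- random_sequence(len)
      starts <- seq(1L, len, by = 60L)
      out <- c(
        out, make_header_line(dialect, i),
        substring(seqs, starts, pmin(starts + 59L, len))
      )
    }
    paste0(paste(out, collapse = "\n"), "\n")
  })
}

#' Generate random spectra as MGF text
#'
#' @param spec a [fixture_spec()]
#' @return MGF text
#' @export
make_mgf <- function(spec = fixture_spec()) {
  with_seed(spec$seed, {
    spectra <- lapply(seq_len(spec$n_spectra), function(i) {
      n <- sample(
        spec$peaks_per_spectrum_range[1L]:spec$peaks_per_spectrum_range[2L], 1L
      )
      spectrum(
        sort(stats::runif(n, 100, 1500)), stats::runif(n, 1, 1000),
        precursor_mz = round4(stats::runif(1, 300, 900)),
        precursor_charge = sample(2:3, 1L),
        title = sprintf("fixture spectrum %d", i)
      )
    })
    write_mgf(spectra)
  })
}

# ---- ground-truth PSMs and the three identification dialects -------------

mascot_boundary <- "gc0p4Jq0M2Yt08jU534c0p"

random_psm_set <- function(spec) {
  n_spec <- max(1L, ceiling(spec$n_psms / 2L))
  psms <- empty_matches()
  k <- 0L
  for (s in seq_len(n_spec)) {
    title <- sprintf("fixture scan %d elution %.1f", s, stats::runif(1, 10, 90))
    z <- sample(2:3, 1L)
    ranks <- min(2L, spec$n_psms - k)
    seq1 <- random_sequence(sample(7:14, 1L))
    pm <- round4(mz(monoisotopic_mass(seq1), z))
    for (r in seq_len(ranks)) {
      k <- k + 1L
      pep <- if (r == 1L) seq1 else random_sequence(sample(7:14, 1L))
      n_mod <- sample(0:2, 1L)
      mods <- if (n_mod > 0L) {
        data.frame(
          position = sort(sample(0:(nchar(pep) + 1L), n_mod)),
          mass = as.numeric(sprintf("%.6f", stats::runif(n_mod, -2, 80))),
          name = sample(c("Oxidation", "Acetyl", "Phospho"), n_mod, replace = TRUE),
          stringsAsFactors = FALSE
        )
      } else {
        empty_mods()
      }
      psms <- rbind(psms, spectrum_match(
        spectrum_title = title, peptide_sequence = pep,
        score = as.numeric(sprintf("%.6f", stats::runif(1, 0.001, 60))),
        score_name = "score", score_orientation = "higher_better",
        charge = z, precursor_mz = pm, engine = "ground_truth",
        protein_accessions = sprintf("FIXP%04d", sample.int(9999, sample(1:2, 1L))),
        rank = r, modifications = mods
      ))
      if (k >= spec$n_psms) break
    }
    if (k >= spec$n_psms) break
  }
  order_matches(psms)
}

write_mascot_like <- function(psms, parameters = list(DB = "fixture", SEARCH = "MIS")) {
  b <- paste0("--", mascot_boundary)
  titles <- unique(psms$spectrum_title)
  qi <- match(psms$spectrum_title, titles)
  section <- function(name, body) {
    c(b, sprintf("Content-Type: application/x-Mascot; name=\"%s\"", name), "", body)
  }
  out <- c(
    "MIME-Version: 1.0 (Generated by protutils fixture writer)",
    sprintf("Content-Type: multipart/mixed; boundary=%s", mascot_boundary),
    "",
    section("parameters", sprintf("%s=%s", names(parameters), unlist(parameters)))
  )
  summ <- vapply(seq_along(titles), function(q) {
    r1 <- which(qi == q)[1L]
    sprintf("qexp%d=%.4f,%d+", q, psms$precursor_mz[r1], psms$charge[r1])
  }, character(1L))
  out <- c(out, section("summary", summ))
  peps <- vapply(seq_len(nrow(psms)), function(r) {
    sprintf(
      "q%d_p%d=%s;%.6f;%s;%s",
      qi[r], psms$rank[r], psms$peptide_sequence[r], psms$score[r],
      encode_mods(psms$modifications[[r]]),
      paste(psms$protein_accessions[[r]], collapse = ",")
    )
  }, character(1L))
  out <- c(out, section("peptides", peps))
  for (q in seq_along(titles)) {
    out <- c(out, section(
      sprintf("query%d", q),
      sprintf("title=%s", utils::URLencode(titles[q], reserved = TRUE))
    ))
  }
  out <- c(out, paste0(b, "--"))
  paste0(paste(out, collapse = "\n"), "\n")
}

write_xtandem_like <- function(psms) {
  p <- mass_table()$constants$proton
  titles <- unique(psms$spectrum_title)
  out <- c(
    "<?xml version=\"1.0\" encoding=\"UTF-8\"?>",
    "<bioml label=\"protutils fixture models\">"
  )
  for (q in seq_along(titles)) {
    rows <- which(psms$spectrum_title == titles[q])
    z <- psms$charge[rows[1L]]
    mh <- psms$precursor_mz[rows[1L]] * z - (z - 1) * p
    out <- c(out, sprintf(
      "<group id=\"%d\" type=\"model\" z=\"%d\" mh=\"%.6f\">", q, z, mh
    ), sprintf(
      "<note label=\"Description\">%s</note>", xml_escape(titles[q])
    ))
    for (r in rows[order(psms$rank[rows])]) {
      out <- c(out, sprintf(
        "<protein label=\"%s\">",
        xml_escape(paste(psms$protein_accessions[[r]], collapse = ","))
      ), "<peptide>", sprintf(
        "<domain seq=\"%s\" expect=\"%.6f\">",
        psms$peptide_sequence[r], psms$score[r]
      ))
      mods <- psms$modifications[[r]]
      if (nrow(mods)) {
        out <- c(out, sprintf(
          "<aa at=\"%d\" modified=\"%.6f\" name=\"%s\"/>",
          mods$position, mods$mass, xml_escape(mods$name)
        ))
      }
      out <- c(out, "</domain>", "</peptide>", "</protein>")
    }
    out <- c(out, "</group>")
  }
  paste0(paste(c(out, "</bioml>"), collapse = "\n"), "\n")
}

csv_field <- function(x) paste0("\"", gsub("\"", "\"\"", x), "\"")

write_omssa_like <- function(psms) {
  p <- mass_table()$constants$proton
  titles <- unique(psms$spectrum_title)
  qi <- match(psms$spectrum_title, titles)
  rows <- vapply(seq_len(nrow(psms)), function(r) {
    z <- psms$charge[r]
    neutral <- psms$precursor_mz[r] * z - z * p
    paste(
      qi[r], csv_field(psms$spectrum_title[r]),
      psms$peptide_sequence[r], sprintf("%.6f", psms$score[r]),
      sprintf("%.6f", neutral), "",
      csv_field(paste(psms$protein_accessions[[r]], collapse = ",")),
      1L, nchar(psms$peptide_sequence[r]), csv_field("fixture defline"),
      csv_field(encode_mods(psms$modifications[[r]])), z,
      sprintf("%.6f", neutral), sprintf("%.6f", psms$score[r]), 0L,
      sep = ","
    )
  }, character(1L))
  paste0(paste(c(omssa_header, rows), collapse = "\n"), "\n")
}

#' Generate a ground-truth PSM list and its three dialect encodings
#'
#' The same matches are rendered into the Mascot-dat-like, X!Tandem-like
#' and OMSSA-like subset formats; parsing any of the three files with
#' [read_identifications()] reproduces the ground truth (up to the
#' engine, score-name and score-orientation metadata, which are
#' per-engine by definition).
#'
#' @param spec a [fixture_spec()]
#' @return list with `ground_truth` (match data.frame) and `files`
#'   (named list of file texts: `mascot_like`, `xtandem_like`,
#'   `omssa_like`)
#' @export
make_identifications <- function(spec = fixture_spec()) {
  with_seed(spec$seed, {
    psms <- random_psm_set(spec)
    list(
      ground_truth = psms,
      files = list(
        mascot_like = write_mascot_like(psms),
        xtandem_like = write_xtandem_like(psms),
        omssa_like = write_omssa_like(psms)
      )
    )
  })
}

#' Generate a spectrum containing planted theoretical fragment ions
#'
#' Peaks are placed at the theoretical m/z of every ion of the requested
#' series (jittered by less than `jitter`), plus uniformly distributed
#' noise peaks. Annotating the result at a tolerance above `jitter`
#' recovers at least the planted ions.
#'
#' @param pep a `peptide` or residue string
#' @param series fragment series to plant
#' @param noise_peaks number of uniform noise peaks to add
#' @param seed integer seed
#' @param jitter maximum absolute m/z jitter (Th) applied to planted peaks
#' @return a list with `spectrum` and the planted `ions` table
#' @export
make_spectrum_for <- function(pep, series = c("b", "y"), noise_peaks = 0L,
                              seed = 1L, jitter = 0.002) {
  pep <- as_peptide(pep)
  ions <- fragment_ions(pep, series = series)
  with_seed(seed, {
    mz_planted <- ions$mz + stats::runif(nrow(ions), -jitter, jitter)
    int_planted <- stats::runif(nrow(ions), 50, 100)
    if (noise_peaks > 0L) {
      lo <- min(ions$mz) * 0.5
      hi <- max(ions$mz) * 1.2
      mz_noise <- stats::runif(noise_peaks, lo, hi)
      int_noise <- stats::runif(noise_peaks, 1, 30)
    } else {
      mz_noise <- numeric()
      int_noise <- numeric()
    }
    list(
      spectrum = spectrum(
        c(mz_planted, mz_noise), c(int_planted, int_noise),
        precursor_mz = mz(
          monoisotopic_mass(pep$sequence, pep$modifications), 2L
        ),
        precursor_charge = 2L,
        title = paste0("synthetic ", pep$sequence)
      ),
      ions = ions
    )
  })
}

# ---- random relational schemas -------------------------------------------

sql_of_type <- c(
  integer = "INTEGER", real = "REAL", text = "TEXT",
  blob = "BLOB", timestamp = "TIMESTAMP"
)

random_value <- function(type) {
  switch(type,
    integer = sample.int(100000, 1L),
    real = round(stats::runif(1, -1000, 1000), 6),
    text = paste(sample(letters, 12L, replace = TRUE), collapse = ""),
    blob = as.raw(sample(0:255, 1024L, replace = TRUE)),
    timestamp = sprintf(
      "2025-%02d-%02d 12:00:00.000000", sample.int(12, 1L), sample.int(28, 1L)
    )
  )
}

mutate_value <- function(type, v) {
  switch(type,
    integer = v + 1L,
    real = v + 1.5,
    text = paste0(v, "x"),
    blob = as.raw(rev(as.integer(v))),
    timestamp = "2025-12-31 23:59:59.000000"
  )
}

#' Generate a random table schema with values for a CRUD exercise
#'
#' Produces a CREATE TABLE statement (1-8 data columns drawn from the five
#' supported types, an autogenerated integer key, and audit columns for
#' half the schemas) plus an initial record and a mutation for the update
#' step.
#'
#' @param seed integer seed
#' @param table_name table name
#' @return list with `table_name`, `create_sql`, `values`, `mutate`
#' @export
make_schema <- function(seed = 1L, table_name = "fixture_table") {
  with_seed(seed, {
    n_cols <- sample.int(8L, 1L)
    types <- sample(names(sql_of_type), n_cols, replace = TRUE)
    names(types) <- sprintf("col_%s%d", letters[seq_len(n_cols)], seq_len(n_cols))
    with_audit <- stats::runif(1) < 0.5
    defs <- c(
      "id INTEGER PRIMARY KEY",
      sprintf("%s %s", names(types), sql_of_type[types]),
      if (with_audit) c("creationdate TIMESTAMP", "modificationdate TIMESTAMP")
    )
    values <- lapply(types, random_value)
    mut_col <- names(types)[1L]
    list(
      table_name = table_name,
      create_sql = sprintf(
        "CREATE TABLE %s (%s)", quote_ident(table_name),
        paste(defs, collapse = ", ")
      ),
      values = values,
      mutate = stats::setNames(
        list(mutate_value(types[[1L]], values[[mut_col]])), mut_col
      )
    )
  })
}

#' Materialize a demonstration fixture corpus on disk
#'
#' Writes one FASTA database per header dialect, an MGF peak list, the
#' three identification dialect files, and a schema SQL file.
#'
#' @param seed central seed
#' @param dir output directory (created if missing)
#' @return invisibly, the paths written
#' @export
make_fixture_corpus <- function(seed = 1L, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  spec <- fixture_spec(seed = seed)
  paths <- character()
  put <- function(name, text) {
    p <- file.path(dir, name)
    writeLines(sub("\n$", "", text), p)
    paths <<- c(paths, p)
  }
  for (d in c("uniprot", "ncbi_gi", "ipi", "generic")) {
    put(paste0("proteins_", d, ".fasta"), make_fasta(spec, d))
  }
  put("spectra.mgf", make_mgf(spec))
  ids <- make_identifications(spec)
  put("identifications_mascot_like.dat", ids$files$mascot_like)
  put("identifications_xtandem_like.xml", ids$files$xtandem_like)
  put("identifications_omssa_like.csv", ids$files$omssa_like)
  put("schema.sql", paste0(make_schema(seed)$create_sql, ";\n"))
  invisible(paths)
}
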