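# Engine-agnostic identification model plus auto-detecting adapters for
# three search-engine result dialects.
#
# The dialects are documented minimal subsets (defined bit-exactly by the
# fixture generator in fixtures.R) of a Mascot-dat-like sectioned text
# format, an X!Tandem-like XML format and an OMSSA-like CSV format. All
# adapters emit identical match semantics: 1-based modification positions,
# scores copied verbatim with per-engine orientation metadata, matches
# ordered by (spectrum_title, rank). Precursor m/z is carried at 4-decimal
# printed precision and scores at 6-decimal precision in all three
# dialects, so the parsed values are bit-identical across adapters.

omssa_header <- paste(
  "Spectrum number, Filename/id, Peptide, E-value, Mass, gi, Accession,",
  "Start, Stop, Defline, Mods, Charge, Theo Mass, P-value, NIST score"
)

engine_score <- list(
  mascot_like  = list(name = "ionscore", orientation = "higher_better"),
  xtandem_like = list(name = "expect", orientation = "lower_better"),
  omssa_like   = list(name = "E-value", orientation = "lower_better")
)

#' Construct an engine-agnostic peptide-spectrum match
#'
#' @param spectrum_title title of the matched spectrum
#' @param peptide_sequence residue string
#' @param score engine score, copied verbatim
#' @param score_name engine-specific score name (e.g. `"ionscore"`)
#' @param score_orientation `"higher_better"` or `"lower_better"`
#' @param charge precursor charge
#' @param precursor_mz precursor m/z (Th)
#' @param engine `"mascot_like"`, `"xtandem_like"` or `"omssa_like"`
#' @param protein_accessions character vector of protein accessions
#' @param rank integer rank >= 1 within the spectrum
#' @param modifications data.frame with columns `position` (0 = N-term,
#'   1..n residues, n+1 = C-term), `mass` (Da) and `name`
#' @return a one-row data.frame with list-columns `modifications` and
#'   `protein_accessions`
#' @export
spectrum_match <- function(spectrum_title, peptide_sequence, score, score_name,
                           score_orientation = c("higher_better", "lower_better"),
                           charge, precursor_mz, engine, protein_accessions,
                           rank = 1L, modifications = empty_mods()) {
  score_orientation <- match.arg(score_orientation)
  if (!is.finite(score)) pu_stop("invalid_match", "score must be finite")
  if (rank < 1L) pu_stop("invalid_match", "rank must be >= 1")
  residue_masses(peptide_sequence, mass_table(permissive = TRUE), "mono")
  df <- data.frame(
    spectrum_title = spectrum_title, peptide_sequence = peptide_sequence,
    score = as.numeric(score), score_name = score_name,
    score_orientation = score_orientation, charge = as.integer(charge),
    precursor_mz = as.numeric(precursor_mz), engine = engine,
    rank = as.integer(rank), stringsAsFactors = FALSE
  )
  df$modifications <- list(modifications)
  df$protein_accessions <- list(as.character(protein_accessions))
  df
}

empty_mods <- function() {
  data.frame(
    position = integer(), mass = numeric(), name = character(),
    stringsAsFactors = FALSE
  )
}

empty_matches <- function() {
  df <- data.frame(
    spectrum_title = character(), peptide_sequence = character(),
    score = numeric(), score_name = character(), score_orientation = character(),
    charge = integer(), precursor_mz = numeric(), engine = character(),
    rank = integer(), stringsAsFactors = FALSE
  )
  df$modifications <- list()
  df$protein_accessions <- list()
  df
}

order_matches <- function(matches) {
  if (nrow(matches) == 0L) {
    return(matches)
  }
  out <- matches[order(matches$spectrum_title, matches$rank), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# shared textual encodings: modifications "pos:mass:name|..." ("-" if none),
# accession lists comma-joined
encode_mods <- function(mods) {
  if (nrow(mods) == 0L) {
    return("-")
  }
  paste(sprintf("%d:%.6f:%s", mods$position, mods$mass, mods$name), collapse = "|")
}

decode_mods <- function(s) {
  s <- trimws(s)
  if (!nzchar(s) || s == "-") {
    return(empty_mods())
  }
  parts <- strsplit(strsplit(s, "|", fixed = TRUE)[[1L]], ":", fixed = TRUE)
  data.frame(
    position = vapply(parts, function(p) as.integer(p[1L]), integer(1L)),
    mass = vapply(parts, function(p) as.numeric(p[2L]), numeric(1L)),
    name = vapply(parts, function(p) p[3L], character(1L)),
    stringsAsFactors = FALSE
  )
}

round4 <- function(x) as.numeric(sprintf("%.4f", x))

# ---- format detection ----------------------------------------------------

sniff_window <- function(path, n = 4096L) {
  if (is.raw(path)) {
    bytes <- path
  } else if (length(path) == 1L && !grepl("\n", path) && file.exists(path)) {
    bytes <- readBin(path, "raw", n = n)
  } else {
    bytes <- charToRaw(paste(path, collapse = "\n"))
  }
  # strip UTF-8 byte-order mark, normalize Windows line endings
  if (length(bytes) >= 3L && identical(bytes[1:3], as.raw(c(0xEF, 0xBB, 0xBF)))) {
    bytes <- bytes[-(1:3)]
  }
  txt <- rawToChar(bytes[seq_len(min(length(bytes), n))])
  Encoding(txt) <- "UTF-8"
  gsub("\r\n", "\n", txt, fixed = TRUE)
}

#' Auto-detect the format of a search-engine result file
#'
#' Sniff rules, applied to the first bytes of the file:
#' * `xtandem_like`: an XML declaration plus a `<bioml` root token;
#' * `mascot_like`: a MIME multipart `boundary=` plus a `Mascot` token;
#' * `omssa_like`: a first line equal to the documented CSV header.
#'
#' Detection is a pure function of the content and is stable under a
#' UTF-8 byte-order mark and Windows line endings.
#'
#' @param path file path, raw bytes, or file text
#' @return `"mascot_like"`, `"xtandem_like"` or `"omssa_like"`
#' @export
detect_format <- function(path) {
  txt <- sniff_window(path)
  if (grepl("<\\?xml", txt) && grepl("<bioml", txt)) {
    return("xtandem_like")
  }
  if (grepl("boundary=", txt, fixed = TRUE) && grepl("Mascot", txt, fixed = TRUE)) {
    return("mascot_like")
  }
  first <- strsplit(txt, "\n", fixed = TRUE)[[1L]][1L]
  if (!is.na(first) && identical(trimws(first), omssa_header)) {
    return("omssa_like")
  }
  pu_stop(
    "unknown_format",
    "unrecognized identification format; none of the sniff rules matched:\n",
    "  - xtandem_like: XML declaration + <bioml root\n",
    "  - mascot_like: MIME multipart boundary= + Mascot token\n",
    "  - omssa_like: first line equal to the documented CSV header"
  )
}

# ---- dialect adapters ----------------------------------------------------

read_mascot_like <- function(lines) {
  pre <- utils::head(lines, 5L)
  boundary <- regmatches(pre, regexec("boundary=(\\S+)", pre))
  boundary <- unlist(lapply(boundary, function(m) if (length(m) == 2L) m[2L]))
  if (is.null(boundary)) {
    pu_stop("parse_error", "mascot_like: no multipart boundary in preamble")
  }
  marker <- paste0("--", boundary[1L])
  sec_starts <- which(startsWith(lines, marker))
  sections <- list()
  for (i in seq_along(sec_starts)) {
    a <- sec_starts[i]
    if (startsWith(lines[a], paste0(marker, "--"))) break
    b <- if (i < length(sec_starts)) sec_starts[i + 1L] - 1L else length(lines)
    body <- lines[(a + 1L):b]
    nm <- regmatches(body[1L], regexec("name=\"([^\"]*)\"", body[1L]))[[1L]]
    if (length(nm) != 2L) {
      pu_stop("parse_error", "mascot_like: section at line ", a,
              " has no Content-Type name")
    }
    sections[[nm[2L]]] <- body[-1L][nzchar(trimws(body[-1L]))]
  }
  kv <- function(sec) {
    if (is.null(sec)) {
      return(list())
    }
    keys <- sub("=.*$", "", sec)
    vals <- sub("^[^=]*=", "", sec)
    stats::setNames(as.list(vals), keys)
  }
  params <- kv(sections$parameters)
  summary <- kv(sections$summary)
  peptides <- kv(sections$peptides)

  matches <- empty_matches()
  seen_q <- integer()
  for (key in names(peptides)) {
    m <- regmatches(key, regexec("^q([0-9]+)_p([0-9]+)$", key))[[1L]]
    if (length(m) != 3L) next
    qi <- as.integer(m[2L])
    rank <- as.integer(m[3L])
    fields <- strsplit(peptides[[key]], ";", fixed = TRUE)[[1L]]
    if (length(fields) != 4L) {
      pu_stop("parse_error", "mascot_like: malformed peptides entry ", key)
    }
    qexp <- summary[[paste0("qexp", qi)]]
    if (is.null(qexp)) {
      pu_stop("parse_error", "mascot_like: missing qexp", qi, " in summary section")
    }
    qv <- strsplit(qexp, ",", fixed = TRUE)[[1L]]
    title_enc <- kv(sections[[paste0("query", qi)]])$title
    title <- if (is.null(title_enc)) paste0("query ", qi) else utils::URLdecode(title_enc)
    matches <- rbind(matches, spectrum_match(
      spectrum_title = title, peptide_sequence = fields[1L],
      score = as.numeric(fields[2L]),
      score_name = engine_score$mascot_like$name,
      score_orientation = engine_score$mascot_like$orientation,
      charge = as.integer(sub("[+-]$", "", qv[2L])),
      precursor_mz = round4(as.numeric(qv[1L])),
      engine = "mascot_like",
      protein_accessions = strsplit(fields[4L], ",", fixed = TRUE)[[1L]],
      rank = rank, modifications = decode_mods(fields[3L])
    ))
    seen_q <- c(seen_q, qi * 1000L + rank)
  }
  # contract: a rank-2 hit with no rank-1 hit parses but is flagged
  qs <- unique(seen_q %/% 1000L)
  for (q in qs) {
    ranks <- seen_q[seen_q %/% 1000L == q] %% 1000L
    if (!1L %in% ranks) {
      pu_warn("missing_rank", "query ", q, " has hits but no rank-1 hit")
    }
  }
  list(matches = matches, parameters = params)
}

read_xtandem_like <- function(path_or_text) {
  doc <- tryCatch(
    xml2::read_xml(
      if (length(path_or_text) == 1L && !grepl("\n", path_or_text) &&
          file.exists(path_or_text)) {
        path_or_text
      } else {
        paste(path_or_text, collapse = "\n")
      }
    ),
    error = function(e) pu_stop("parse_error", "xtandem_like: ", conditionMessage(e))
  )
  matches <- empty_matches()
  for (grp in xml2::xml_find_all(doc, "/bioml/group[@type='model']")) {
    z <- as.integer(xml2::xml_attr(grp, "z"))
    mh <- as.numeric(xml2::xml_attr(grp, "mh"))
    title <- xml2::xml_text(
      xml2::xml_find_first(grp, "./note[@label='Description']")
    )
    p <- mass_table()$constants$proton
    pmz <- round4((mh + (z - 1) * p) / z)
    rank <- 0L
    for (prot in xml2::xml_find_all(grp, "./protein")) {
      accs <- strsplit(xml2::xml_attr(prot, "label"), ",", fixed = TRUE)[[1L]]
      for (dom in xml2::xml_find_all(prot, "./peptide/domain")) {
        rank <- rank + 1L
        aa <- xml2::xml_find_all(dom, "./aa")
        mods <- if (length(aa)) {
          data.frame(
            position = as.integer(xml2::xml_attr(aa, "at")),
            mass = as.numeric(xml2::xml_attr(aa, "modified")),
            name = xml2::xml_attr(aa, "name"),
            stringsAsFactors = FALSE
          )
        } else {
          empty_mods()
        }
        matches <- rbind(matches, spectrum_match(
          spectrum_title = title,
          peptide_sequence = xml2::xml_attr(dom, "seq"),
          score = as.numeric(xml2::xml_attr(dom, "expect")),
          score_name = engine_score$xtandem_like$name,
          score_orientation = engine_score$xtandem_like$orientation,
          charge = z, precursor_mz = pmz, engine = "xtandem_like",
          protein_accessions = accs, rank = rank, modifications = mods
        ))
      }
    }
  }
  list(matches = matches, parameters = list())
}

read_omssa_like <- function(lines) {
  txt <- paste(lines, collapse = "\n")
  df <- tryCatch(
    utils::read.csv(text = txt, check.names = FALSE, stringsAsFactors = FALSE,
                    strip.white = TRUE),
    error = function(e) pu_stop("parse_error", "omssa_like: ", conditionMessage(e))
  )
  matches <- empty_matches()
  p <- mass_table()$constants$proton
  if (nrow(df)) {
    for (r in seq_len(nrow(df))) {
      z <- as.integer(df$Charge[r])
      rank <- sum(df$`Spectrum number`[seq_len(r)] == df$`Spectrum number`[r])
      matches <- rbind(matches, spectrum_match(
        spectrum_title = df$`Filename/id`[r],
        peptide_sequence = df$Peptide[r],
        score = as.numeric(df$`E-value`[r]),
        score_name = engine_score$omssa_like$name,
        score_orientation = engine_score$omssa_like$orientation,
        charge = z,
        precursor_mz = round4((as.numeric(df$Mass[r]) + z * p) / z),
        engine = "omssa_like",
        protein_accessions = strsplit(df$Accession[r], ",", fixed = TRUE)[[1L]],
        rank = rank, modifications = decode_mods(df$Mods[r])
      ))
    }
  }
  list(matches = matches, parameters = list())
}

#' Read a search-engine result file into the engine-agnostic model
#'
#' The format is auto-detected (see [detect_format()]) and the matching
#' adapter invoked. All adapters emit identical match semantics: 1-based
#' modification positions, scores copied verbatim with orientation set per
#' engine (mascot-like ionscore higher-is-better; X!Tandem-like expect and
#' OMSSA-like E-value lower-is-better), matches ordered by
#' (spectrum_title, rank).
#'
#' @param path file path or file text
#' @return an object of class `id_file` with fields `path`,
#'   `detected_format`, `matches` (data.frame, see [spectrum_match()]) and
#'   `search_parameters`
#' @export
read_identifications <- function(path) {
  fmt <- detect_format(path)
  lines <- fasta_lines(path)
  lines <- sub("\r$", "", lines)
  if (length(lines)) {
    lines[1L] <- sub("^\uFEFF", "", lines[1L], useBytes = FALSE)
  }
  parsed <- switch(fmt,
    mascot_like = read_mascot_like(lines),
    xtandem_like = read_xtandem_like(path),
    omssa_like = read_omssa_like(lines)
  )
  structure(
    list(
      path = if (length(path) == 1L && !grepl("\n", path)) path else "<text>",
      detected_format = fmt,
      matches = order_matches(parsed$matches),
      search_parameters = parsed$parameters
    ),
    class = "id_file"
  )
}

#' @export
print.id_file <- function(x, ...) {
  cat(sprintf(
    "<id_file> %s [%s]: %d match(es), %d search parameter(s)\n",
    x$path, x$detected_format, nrow(x$matches), length(x$search_parameters)
  ))
  invisible(x)
}

#' Best match per spectrum
#'
#' Returns, for each spectrum title, the rank-1 match; when ranks are
#' absent, the best score respecting the score orientation. Ties are
#' broken deterministically by lexicographically smaller peptide sequence.
#'
#' @param idfile an `id_file`
#' @return a data.frame of matches, one row per spectrum title
#' @export
best_match_per_spectrum <- function(idfile) {
  m <- idfile$matches
  if (nrow(m) == 0L) {
    return(m)
  }
  pick <- unlist(lapply(split(seq_len(nrow(m)), m$spectrum_title), function(idx) {
    sub <- m[idx, , drop = FALSE]
    if (all(is.na(sub$rank))) {
      score_key <- if (sub$score_orientation[1L] == "higher_better") {
        -sub$score
      } else {
        sub$score
      }
    } else {
      score_key <- sub$rank
    }
    idx[order(score_key, sub$peptide_sequence)][1L]
  }), use.names = FALSE)
  out <- m[sort(pick), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Flatten matches to a plain table
#'
#' Turns the list-columns of a match data.frame into text (modifications
#' as `pos:mass:name|...`, accessions comma-joined) for TSV export.
#'
#' @param matches match data.frame from an `id_file`
#' @return a data.frame of atomic columns
#' @export
flatten_matches <- function(matches) {
  data.frame(
    spectrum_title = matches$spectrum_title,
    peptide_sequence = matches$peptide_sequence,
    score = matches$score, score_name = matches$score_name,
    score_orientation = matches$score_orientation,
    charge = matches$charge, precursor_mz = matches$precursor_mz,
    engine = matches$engine, rank = matches$rank,
    modifications = vapply(matches$modifications, encode_mods, character(1L)),
    protein_accessions = vapply(
      matches$protein_accessions, paste, character(1L), collapse = ","
    ),
    stringsAsFactors = FALSE
  )
}
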