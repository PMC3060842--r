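# FASTA reading/writing and heterogeneous-header parsing.
#
# Header dialects are matched by ordered grammars (uniprot, ncbi_gi, ipi,
# then the generic fallback); specific grammars come first so the fallback
# cannot shadow them. The raw header is always retained so that writing is
# byte-identical to reading.

uniprot_rx <- "^(sp|tr)\\|([A-Za-z0-9-]+)\\|(\\S+)[ \t]*(.*)$"
ncbi_gi_rx <- "^gi\\|([0-9]+)\\|([A-Za-z]+)\\|([^|]*)\\|[ \t]*(.*)$"
ipi_rx <- "^IPI:(IPI[0-9]+(?:\\.[0-9]+)?)\\|?(\\S*)[ \t]*(.*)$"

new_fasta_header <- function(raw, dialect, accession, db_tag = "",
                             protein_name = "", description = "",
                             species = "", gi = "") {
  structure(
    list(
      raw = raw, dialect = dialect, accession = accession, db_tag = db_tag,
      protein_name = protein_name, description = description,
      species = species, gi = gi
    ),
    class = "fasta_header"
  )
}

#' Parse a FASTA header line into its constituent parts
#'
#' The dialect is auto-detected by trying the UniProt, NCBI gi and IPI
#' grammars in that order; a header matching none of them falls back to
#' `generic` (first whitespace-delimited token = accession, remainder =
#' description). The raw header is kept verbatim, so writing a parsed
#' header reproduces the input byte-for-byte.
#'
#' For NCBI gi headers the primary accession is the innermost database
#' accession (gi numbers are deprecated); the gi number is kept in the
#' `gi` field.
#'
#' @param line header line, with or without the leading `">"`
#' @return an object of class `fasta_header` with fields `raw`, `dialect`
#'   (one of `"uniprot"`, `"ncbi_gi"`, `"ipi"`, `"generic"`), `accession`,
#'   `db_tag`, `protein_name`, `description`, `species`, `gi`
#' @examples
#' parse_fasta_header(">sp|P12345|ALBU_HUMAN Serum albumin OS=Homo sapiens")
#' parse_fasta_header(">gi|12345|ref|NP_000001.1| some protein")
#' parse_fasta_header(">myProt hand-made entry")
#' @export
parse_fasta_header <- function(line) {
  if (!is.character(line) || length(line) != 1L || is.na(line)) {
    pu_stop("invalid_header", "header must be a single string")
  }
  raw <- sub("^>", "", line)
  if (!nzchar(trimws(raw))) {
    pu_stop("invalid_header", "empty FASTA header")
  }

  if (grepl(uniprot_rx, raw)) {
    m <- regmatches(raw, regexec(uniprot_rx, raw))[[1L]]
    desc <- m[5L]
    species <- ""
    os <- regmatches(desc, regexec("OS=(.*?)(?: [A-Z]{2}=.*)?$", desc, perl = TRUE))[[1L]]
    if (length(os) == 2L) species <- os[2L]
    return(new_fasta_header(
      raw, "uniprot",
      accession = m[3L], db_tag = m[2L], protein_name = m[4L],
      description = desc, species = species
    ))
  }
  if (grepl(ncbi_gi_rx, raw)) {
    m <- regmatches(raw, regexec(ncbi_gi_rx, raw))[[1L]]
    return(new_fasta_header(
      raw, "ncbi_gi",
      accession = m[4L], db_tag = m[3L], description = m[5L], gi = m[2L]
    ))
  }
  if (grepl(ipi_rx, raw)) {
    m <- regmatches(raw, regexec(ipi_rx, raw))[[1L]]
    desc <- m[4L]
    species <- ""
    tax <- regmatches(desc, regexec("Tax_Id=(\\S+)", desc))[[1L]]
    if (length(tax) == 2L) species <- tax[2L]
    gene <- regmatches(desc, regexec("Gene_Symbol=(\\S+)", desc))[[1L]]
    return(new_fasta_header(
      raw, "ipi",
      accession = m[2L], db_tag = "IPI",
      protein_name = if (length(gene) == 2L) gene[2L] else "",
      description = desc, species = species
    ))
  }
  toks <- regmatches(raw, regexec("^(\\S+)[ \t]*(.*)$", raw))[[1L]]
  new_fasta_header(raw, "generic", accession = toks[2L], description = toks[3L])
}

#' @export
print.fasta_header <- function(x, ...) {
  cat(sprintf("<fasta_header> [%s] %s\n", x$dialect, x$accession))
  for (f in c("db_tag", "protein_name", "species", "gi", "description")) {
    if (nzchar(x[[f]])) cat(sprintf("  %-13s %s\n", f, x[[f]]))
  }
  invisible(x)
}

# Accept a file path or FASTA text (single string with newlines, or a
# character vector of lines).
fasta_lines <- function(source) {
  if (is.character(source) && length(source) == 1L && !grepl("\n", source) &&
      file.exists(source)) {
    return(readLines(source, warn = FALSE))
  }
  unlist(strsplit(source, "\n", fixed = TRUE), use.names = FALSE)
}

#' Read a FASTA database
#'
#' Sequence lines are concatenated across wrapping and uppercased; entry
#' order is preserved. Every entry carries its parsed [fasta_header()] in
#' `$header`. Duplicate accessions are permitted but flagged with a
#' warning.
#'
#' @param source file path, or FASTA text
#' @param permissive allow U and O residues in sequences
#' @return a list of `protein` objects
#' @examples
#' txt <- ">sp|P12345|TEST_HUMAN Test protein OS=Homo sapiens\nPEPTIDEK\n"
#' read_fasta(txt)[[1L]]
#' @export
read_fasta <- function(source, permissive = FALSE) {
  lines <- fasta_lines(source)
  keep <- nzchar(trimws(lines))
  entries <- list()
  cur_header <- NULL
  cur_seq <- character()
  cur_line <- NA_integer_
  flush <- function() {
    if (is.null(cur_header)) {
      return()
    }
    h <- parse_fasta_header(cur_header)
    seqs <- toupper(paste0(cur_seq, collapse = ""))
    if (!nzchar(seqs)) {
      pu_stop("malformed_fasta", "entry \"", h$accession, "\" at line ",
              cur_line, " has no sequence")
    }
    entries[[length(entries) + 1L]] <<- protein(
      h$accession, seqs,
      description = h$description, header = h, permissive = permissive
    )
  }
  for (i in seq_along(lines)) {
    if (!keep[i]) next
    line <- lines[i]
    if (startsWith(line, ">")) {
      flush()
      cur_header <- line
      cur_seq <- character()
      cur_line <- i
    } else {
      if (is.null(cur_header)) {
        pu_stop("malformed_fasta", "sequence data before first header at line ", i)
      }
      cur_seq <- c(cur_seq, trimws(line))
    }
  }
  flush()
  acc <- vapply(entries, function(p) p$accession, character(1L))
  if (anyDuplicated(acc)) {
    pu_warn(
      "duplicate_accession",
      "duplicate accession(s) in database: ",
      paste(unique(acc[duplicated(acc)]), collapse = ", ")
    )
  }
  entries
}

#' Write proteins to a FASTA file
#'
#' Headers are emitted verbatim from the stored raw header when present
#' (byte-identical round-trip), otherwise regenerated as
#' `">accession description"`.
#'
#' @param proteins list of `protein` objects
#' @param path output file path, or `NULL` to return the text
#' @param wrap sequence line width; `0` disables wrapping; otherwise must
#'   be >= 10
#' @return invisibly, the FASTA text
#' @export
write_fasta <- function(proteins, path = NULL, wrap = 60L) {
  if (wrap != 0L && wrap < 10L) {
    pu_stop("invalid_wrap", "wrap must be 0 (no wrapping) or >= 10")
  }
  out <- character()
  for (p in proteins) {
    hdr <- if (!is.null(p$header)) {
      paste0(">", p$header$raw)
    } else {
      paste0(">", p$accession, if (nzchar(p$description)) paste0(" ", p$description))
    }
    seqs <- p$sequence
    body <- if (wrap == 0L) {
      seqs
    } else {
      starts <- seq(1L, nchar(seqs), by = wrap)
      substring(seqs, starts, pmin(starts + wrap - 1L, nchar(seqs)))
    }
    out <- c(out, hdr, body)
  }
  text <- paste0(paste(out, collapse = "\n"), if (length(out)) "\n" else "")
  if (!is.null(path)) {
    writeLines(out, path)
  }
  invisible(text)
}

#' Summarize header dialects in a FASTA database
#'
#' @param source file path or FASTA text
#' @return a data.frame with one row per entry: `accession`, `dialect`,
#'   `length`
#' @export
fasta_info <- function(source) {
  prots <- read_fasta(source)
  data.frame(
    accession = vapply(prots, function(p) p$accession, character(1L)),
    dialect = vapply(prots, function(p) p$header$dialect, character(1L)),
    length = vapply(prots, function(p) nchar(p$sequence), integer(1L)),
    stringsAsFactors = FALSE
  )
}
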