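# Protein and peptide sequence types and in-silico enzymatic digestion.
# All coordinates are 1-based and inclusive.

#' Construct a protein
#'
#' @param accession protein accession (non-empty string)
#' @param sequence residue string; lowercase input is uppercased, then
#'   validated against the residue alphabet
#' @param description free-text description
#' @param header optional `fasta_header` object the protein was read from
#' @param permissive allow U and O residues
#' @return an object of class `protein`
#' @examples
#' protein("P1", "MKWVTFISLLFLFSSAYSR")
#' @export
protein <- function(accession, sequence, description = "", header = NULL,
                    permissive = FALSE) {
  if (!is.character(accession) || length(accession) != 1L || !nzchar(accession)) {
    pu_stop("invalid_protein", "accession must be a non-empty string")
  }
  sequence <- toupper(sequence)
  # validates alphabet; errors carry residue + position
  residue_masses(sequence, mass_table(permissive = permissive), "mono")
  structure(
    list(
      accession = accession, sequence = sequence,
      description = description, header = header
    ),
    class = "protein"
  )
}

#' @export
print.protein <- function(x, ...) {
  cat(sprintf(
    "<protein> %s (%d aa) %s\n", x$accession, nchar(x$sequence),
    if (nzchar(x$description)) x$description else ""
  ))
  invisible(x)
}

#' Construct a peptide with optional modifications
#'
#' The unit of mass and fragmentation computation: a residue string plus
#' fixed-mass modification attachments. Positions: 0 = N-terminus,
#' 1..n = residues, n+1 = C-terminus.
#'
#' @param sequence residue string
#' @param modifications list of `list(position =, mod = modification(...))`
#' @param permissive allow U and O residues
#' @return an object of class `peptide`
#' @export
peptide <- function(sequence, modifications = list(), permissive = FALSE) {
  sequence <- toupper(sequence)
  residue_masses(sequence, mass_table(permissive = permissive), "mono")
  modification_shift(modifications, nchar(sequence)) # validates
  structure(
    list(sequence = sequence, modifications = modifications, permissive = permissive),
    class = "peptide"
  )
}

as_peptide <- function(x) {
  if (inherits(x, "peptide")) x else peptide(x)
}

#' @export
print.peptide <- function(x, ...) {
  cat(sprintf(
    "<peptide> %s (%d mods, M = %.6f Da)\n", x$sequence,
    length(x$modifications),
    monoisotopic_mass(x$sequence, x$modifications, permissive = x$permissive)
  ))
  invisible(x)
}

#' Define a proteolytic enzyme
#'
#' Cleavage occurs after a residue in `cleave_after` unless the next
#' residue is in `restrict_before` (the classic trypsin
#' not-before-proline rule).
#'
#' @param name enzyme name
#' @param cleave_after character vector of residues cleaved after
#' @param restrict_before residues blocking cleavage when they follow the
#'   site
#' @param missed_cleavages_max default maximum number of missed cleavages
#' @return an object of class `enzyme`
#' @examples
#' enzyme("trypsin", c("K", "R"), "P", 2)
#' @export
enzyme <- function(name, cleave_after, restrict_before = character(),
                   missed_cleavages_max = 0L) {
  if (length(cleave_after) == 0L) {
    pu_stop("invalid_enzyme", "cleave_after must name at least one residue")
  }
  if (missed_cleavages_max < 0) {
    pu_stop("invalid_enzyme", "missed_cleavages_max must be >= 0")
  }
  structure(
    list(
      name = name,
      cleave_after = toupper(cleave_after),
      restrict_before = toupper(restrict_before),
      missed_cleavages_max = as.integer(missed_cleavages_max)
    ),
    class = "enzyme"
  )
}

#' Built-in enzyme definitions
#'
#' Standard definitions for trypsin, Lys-C, Arg-C, chymotrypsin (high
#' specificity) and Glu-C.
#'
#' @param name optional enzyme name; omit to get the full named list
#' @param missed_cleavages_max maximum missed cleavages for the returned
#'   enzyme(s)
#' @return an `enzyme`, or a named list of them when `name` is missing
#' @examples
#' builtin_enzymes("trypsin")
#' names(builtin_enzymes())
#' @export
builtin_enzymes <- function(name = NULL, missed_cleavages_max = 0L) {
  defs <- list(
    trypsin      = list(c("K", "R"), "P"),
    lys_c        = list("K", character()),
    arg_c        = list("R", "P"),
    chymotrypsin = list(c("F", "W", "Y"), "P"),
    glu_c        = list("E", character())
  )
  build <- function(nm) {
    enzyme(nm, defs[[nm]][[1L]], defs[[nm]][[2L]], missed_cleavages_max)
  }
  if (is.null(name)) {
    return(stats::setNames(lapply(names(defs), build), names(defs)))
  }
  if (!name %in% names(defs)) {
    pu_stop(
      "unknown_enzyme",
      "unknown enzyme \"", name, "\"; built-ins: ", paste(names(defs), collapse = ", ")
    )
  }
  build(name)
}

# 0-based cleavage boundaries: cut after position i (1..n-1) when residue i
# is in cleave_after and residue i+1 is not in restrict_before.
cleavage_sites <- function(sequence, enz) {
  chars <- strsplit(sequence, "", fixed = TRUE)[[1L]]
  n <- length(chars)
  if (n < 2L) {
    return(integer())
  }
  i <- seq_len(n - 1L)
  i[chars[i] %in% enz$cleave_after & !(chars[i + 1L] %in% enz$restrict_before)]
}

#' In-silico enzymatic digestion
#'
#' Produces every peptide obtainable with 0 to `missed_cleavages` missed
#' cleavage sites. The 0-missed-cleavage peptides, concatenated in order,
#' reconstruct the parent sequence. Output is ordered by start position,
#' then peptide length.
#'
#' @param prot a `protein` (or a bare residue string)
#' @param enz an `enzyme`; defaults to trypsin
#' @param missed_cleavages maximum missed cleavages; defaults to the
#'   enzyme's `missed_cleavages_max`
#' @return a data.frame with columns `sequence`, `start`, `end`
#'   (1-based inclusive coordinates in the parent) and `missed_cleavages`
#' @examples
#' digest(protein("P1", "AKPRLKR"), builtin_enzymes("trypsin"))
#' @export
digest <- function(prot, enz = builtin_enzymes("trypsin"),
                   missed_cleavages = enz$missed_cleavages_max) {
  if (!inherits(prot, "protein")) {
    prot <- protein("query", prot)
  }
  seqs <- prot$sequence
  sites <- cleavage_sites(seqs, enz)
  bounds <- c(0L, sites, nchar(seqs)) # fragment boundaries, 0-based
  nfrag <- length(bounds) - 1L
  out <- vector("list", nfrag * (missed_cleavages + 1L))
  k <- 0L
  for (i in seq_len(nfrag)) {
    for (m in 0:missed_cleavages) {
      j <- i + m
      if (j > nfrag) break
      k <- k + 1L
      out[[k]] <- c(bounds[i] + 1L, bounds[j + 1L], m)
    }
  }
  out <- out[seq_len(k)]
  start <- vapply(out, `[`, integer(1L), 1L)
  end <- vapply(out, `[`, integer(1L), 2L)
  mc <- vapply(out, `[`, integer(1L), 3L)
  ord <- order(start, end - start)
  data.frame(
    sequence = substring(seqs, start, end)[ord],
    start = start[ord], end = end[ord], missed_cleavages = mc[ord],
    stringsAsFactors = FALSE
  )
}

#' Find all occurrences of a peptide in a protein
#'
#' Overlapping matches are reported; positions are 1-based.
#'
#' @param prot a `protein` (or residue string)
#' @param pep peptide residue string
#' @return integer vector of start positions, ascending (empty when absent)
#' @examples
#' find_peptide(protein("P1", "AAA"), "AA") # 1 2
#' @export
find_peptide <- function(prot, pep) {
  if (!inherits(prot, "protein")) {
    prot <- protein("query", prot)
  }
  pep <- toupper(pep)
  if (!nzchar(pep)) {
    pu_stop("invalid_sequence", "peptide must be a non-empty string")
  }
  hits <- gregexpr(
    paste0("(?=", gsub("([^A-Za-z0-9])", "\\\\\\1", pep), ")"),
    prot$sequence,
    perl = TRUE
  )[[1L]]
  if (hits[1L] == -1L) integer() else as.integer(hits)
}
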