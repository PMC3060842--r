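test_that("header dialects are parsed into their constituent parts", {
  h <- parse_fasta_header(">sp|P12345|ALBU_HUMAN Serum albumin OS=Homo sapiens")
  expect_identical(h$dialect, "uniprot")
  expect_identical(h$db_tag, "sp")
  expect_identical(h$accession, "P12345")
  expect_identical(h$protein_name, "ALBU_HUMAN")
  expect_identical(h$species, "Homo sapiens")

  # trailing UniProt key=value tags do not leak into the species
  h2 <- parse_fasta_header(
    ">tr|A0A024|NAME_HUMAN Some protein OS=Mus musculus OX=10090 GN=Alb PE=1 SV=2"
  )
  expect_identical(h2$species, "Mus musculus")

  g <- parse_fasta_header(">gi|12345|ref|NP_000001.1| some protein")
  expect_identical(g$dialect, "ncbi_gi")
  expect_identical(g$accession, "NP_000001.1") # innermost accession, not the gi
  expect_identical(g$db_tag, "ref")
  expect_identical(g$gi, "12345")

  i <- parse_fasta_header(
    ">IPI:IPI00000001.1|SWISS-PROT:P01023 Tax_Id=9606 Gene_Symbol=A2M Alpha-2-macroglobulin"
  )
  expect_identical(i$dialect, "ipi")
  expect_identical(i$accession, "IPI00000001.1")
  expect_identical(i$species, "9606")
  expect_identical(i$protein_name, "A2M")

  m <- parse_fasta_header(">myProt hand-made entry")
  expect_identical(m$dialect, "generic")
  expect_identical(m$accession, "myProt")
  expect_identical(m$description, "hand-made entry")

  expect_error(parse_fasta_header(">"), class = "protutils_invalid_header")
})

test_that("dialect detection is 100% correct on the generated corpus", {
  spec <- fixture_spec(seed = 20, n_proteins = 6)
  for (d in c("uniprot", "ncbi_gi", "ipi", "generic")) {
    info <- fasta_info(make_fasta(spec, d))
    expect_identical(unique(info$dialect), d)
    expect_identical(nrow(info), 6L)
  }
})

test_that("read/write round-trips raw headers byte-identically", {
  spec <- fixture_spec(seed = 9, n_proteins = 4)
  for (d in c("uniprot", "ncbi_gi", "ipi", "generic")) {
    txt <- make_fasta(spec, d)
    prots <- read_fasta(txt)
    expect_identical(write_fasta(prots, wrap = 60), txt)
    # wrap width changes the layout but not the content
    again <- read_fasta(write_fasta(prots, wrap = 0))
    expect_identical(
      vapply(again, function(p) p$sequence, character(1)),
      vapply(prots, function(p) p$sequence, character(1))
    )
    expect_identical(
      vapply(again, function(p) p$header$raw, character(1)),
      vapply(prots, function(p) p$header$raw, character(1))
    )
  }
})

test_that("read_fasta agrees with Biostrings on the same file", {
  skip_if_not_installed("Biostrings")
  f <- tempfile(fileext = ".fasta")
  writeLines(sub("\n$", "", make_fasta(fixture_spec(seed = 31), "uniprot")), f)
  ours <- read_fasta(f)
  ref <- Biostrings::readAAStringSet(f)
  expect_identical(length(ours), length(ref))
  expect_identical(
    vapply(ours, function(p) p$sequence, character(1)),
    unname(as.character(ref))
  )
  expect_identical(
    vapply(ours, function(p) p$header$raw, character(1)),
    unname(names(ref))
  )
})

test_that("sequence wrapping arithmetic is exact", {
  p <- protein("acc80", random_peptide(80))
  txt <- write_fasta(list(p), wrap = 60)
  lines <- strsplit(txt, "\n")[[1]]
  expect_identical(nchar(lines), c(nchar(">acc80"), 60L, 20L))
  expect_identical(length(strsplit(write_fasta(list(p), wrap = 0), "\n")[[1]]), 2L)
  expect_error(write_fasta(list(p), wrap = 5), class = "protutils_invalid_wrap")
})

test_that("malformed input and duplicates are reported with context", {
  err <- tryCatch(read_fasta("PEPTIDE\n>ok\nAAA"), error = identity)
  expect_s3_class(err, "protutils_malformed_fasta")
  expect_match(conditionMessage(err), "line 1")
  expect_identical(read_fasta(""), list())
  expect_warning(
    read_fasta(">dup\nAAA\n>dup\nCCC"),
    class = "protutils_duplicate_accession"
  )
})
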