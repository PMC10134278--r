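test_that("GFF3/FASTA gene models read back identically on both strands", {
  set.seed(11)
  seqs <- vapply(c(10L, 20L, 30L), function(n)
    paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = ""),
    character(1))
  es <- exon_set("g1", c(10L, 20L, 30L), seqs)
  dir <- withr::local_tempdir()
  write_gene_model(es, file.path(dir, "p.gff3"), file.path(dir, "p.fa"),
                   strand = "+")
  plus <- load_gene_model(file.path(dir, "p.gff3"), file.path(dir, "p.fa"), "g1")
  expect_equal(plus$exons$length, c(10L, 20L, 30L))
  expect_equal(plus$exons$sequence, seqs)

  write_gene_model(es, file.path(dir, "m.gff3"), file.path(dir, "m.fa"),
                   strand = "-")
  minus <- load_gene_model(file.path(dir, "m.gff3"), file.path(dir, "m.fa"), "g1")
  expect_equal(minus$exons$sequence, plus$exons$sequence)
  expect_equal(minus$exons$exon_id, 1:3)

  expect_error(
    load_gene_model(file.path(dir, "p.gff3"), file.path(dir, "p.fa"), "nope"),
    "gene not found")
})

test_that("isoform table parsing reproduces the packaged POSTN catalogue", {
  fx <- postn_fx()
  isos <- fx$isoforms
  expect_length(isos, 11L)
  expect_equal(sum(!vapply(isos, function(i) is.na(i$reference), logical(1))),
               8L)
  # spot-checked skip sets
  expect_equal(isos$Iso5$skipped, 17L)
  expect_equal(isos$Iso3$skipped, c(17L, 21L))
  expect_equal(isos$Iso7$skipped, c(17L, 18L, 19L, 21L))
  expect_equal(isos$Iso1$skipped, integer())
  # Iso1 reproduces the full-length transcript exactly
  expect_identical(isos$Iso1$transcript,
                   paste(fx$exon_set$exons$sequence, collapse = ""))

  # malformed tables are rejected
  dir <- withr::local_tempdir()
  bad <- file.path(dir, "bad.tsv")
  writeLines(c("name\texons_missing", "IsoA\t99"), bad)
  expect_error(load_isoform_table(bad, fx$exon_set), "unknown exon")
  writeLines(c("name\texons_missing", "IsoA\tNone", "IsoA\t17"), bad)
  expect_error(load_isoform_table(bad, fx$exon_set), "duplicate")
})

test_that("isoform assembly conserves length and respects skip arithmetic", {
  fx <- postn_fx()
  full_len <- fx$isoforms$Iso1$length
  exon_len <- function(id) fx$exon_set$exons$length[id]
  for (iso in fx$isoforms) {
    expect_equal(iso$length + sum(exon_len(iso$skipped)), full_len,
                 info = iso$name)
    expect_equal(nchar(iso$transcript), iso$length)
  }
  # skipping exon 17 (84 bp) shortens by 84; {17,21} vs {17} differ by len(21)
  expect_equal(full_len - fx$isoforms$Iso5$length, 84L)
  expect_equal(fx$isoforms$Iso5$length - fx$isoforms$Iso3$length,
               exon_len(21L))
  expect_error(build_isoform(fx$exon_set, "x", 1:23), "empty transcript")
})

test_that("transcript coordinates round-trip and respect exon boundaries", {
  fx <- postn_fx()
  cm1 <- coord_map(fx$isoforms$Iso1)
  expect_equal(map_coordinate(cm1, 1L)$exon_id, 1L)
  expect_equal(map_coordinate(cm1, 1L)$offset, 1L)
  len1 <- fx$exon_set$exons$length[1]
  hit <- map_coordinate(cm1, len1 + 1L)
  expect_equal(hit$exon_id, 2L)
  expect_equal(hit$offset, 1L)
  expect_error(map_coordinate(cm1, 0L), "out of bounds")
  expect_error(map_coordinate(cm1, fx$isoforms$Iso1$length + 1L),
               "out of bounds")

  set.seed(99)
  for (iso in fx$isoforms) {
    cm <- coord_map(iso)
    pos <- sample.int(iso$length, 1000L, replace = TRUE)
    m <- map_coordinate(cm, pos)
    back <- transcript_position(cm, m$exon_id, m$offset)
    expect_equal(back, pos, info = iso$name)
  }
  # skipped exons have no transcript image
  cm5 <- coord_map(fx$isoforms$Iso5)
  expect_error(transcript_position(cm5, 17L, 1L), "skipped exon")
})

test_that("the siRNA reference interval is 21 nt in a constitutive exon", {
  fx <- postn_fx()
  expect_equal(2417L - 2397L + 1L, 21L)
  cm <- coord_map(fx$isoforms$Iso1)
  ex <- unique(map_coordinate(cm, 2397:2417)$exon_id)
  expect_length(ex, 1L)
  expect_false(ex %in% unlist(lapply(fx$isoforms, function(i) i$skipped)))
})

test_that("translation follows the CDS frame, skips and degenerate input", {
  es <- exon_set("t", c(6L, 3L), c("ATGGCC", "TAA"))
  iso <- build_isoform(es, "t1")
  expect_equal(translate_region(iso, 1L, 1L, 6L), "MA")
  expect_equal(translate_cds(iso), "MA")

  # a frame-preserving skip leaves the downstream peptide unchanged
  fx <- postn_fx()
  pep1 <- translate_cds(fx$isoforms$Iso1, fx$cds_start)
  pep5 <- translate_cds(fx$isoforms$Iso5, fx$cds_start)
  expect_true(fx$isoforms$Iso5$frame_preserving)
  expect_equal(nchar(pep1) - nchar(pep5), 84L / 3L)
  # removing the exon-17 amino-acid block from Iso1's peptide yields Iso5's
  cm <- coord_map(fx$isoforms$Iso1)
  aa_start <- (transcript_position(cm, 17L, 1L) - 1L) / 3L + 1L
  expect_equal(paste0(substr(pep1, 1L, aa_start - 1L),
                      substr(pep1, aa_start + 28L, nchar(pep1))), pep5)

  # a non-multiple-of-3 skip shifts the frame
  es2 <- exon_set("t2", c(6L, 4L, 9L), c("ATGGCC", "GGGG", "GCCGCCTAA"))
  shifted <- build_isoform(es2, "short", 2L)
  expect_false(shifted$frame_preserving)
  expect_false(identical(substr(translate_cds(build_isoform(es2, "full")), 3L, 4L),
                         substr(translate_cds(shifted), 3L, 4L)))

  # truncation warning and ambiguity handling
  expect_warning(p <- translate_region(iso, 1L, 1L, 5L), "trimmed")
  expect_equal(p, "M")
  esN <- exon_set("tN", 6L, "ATGNCC")
  expect_equal(translate_cds(build_isoform(esN, "n1")), "MX")
})
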