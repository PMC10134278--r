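# Synthetic cassette-exon genes and the packaged POSTN model.
#
# Every module is testable offline: synth_gene() builds arbitrary seeded
# cassette-exon genes, and build_postn_fixture() builds the 23-exon human
# periostin (POSTN) gene with its 11 exon-skip isoforms (Iso1..Iso11) and
# the published screening primers F1/F2/R1/R2.

SENSE_CODONS <- local({
  gc <- Biostrings::GENETIC_CODE
  names(gc)[gc != "*"]
})

random_codons <- function(n) paste(sample(SENSE_CODONS, n, replace = TRUE),
                                   collapse = "")

random_bases <- function(n, gc_fraction = 0.5) {
  p <- c(A = (1 - gc_fraction) / 2, C = gc_fraction / 2,
         G = gc_fraction / 2, T = (1 - gc_fraction) / 2)
  paste(sample(names(p), n, replace = TRUE, prob = p), collapse = "")
}

# Run `expr` under a fixed seed without disturbing the caller's RNG stream.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

count_occurrences <- function(pattern, subject) {
  nrow(scan_sites(pattern, subject))
}

#' Specify a synthetic cassette-exon gene
#'
#' @param exon_lengths Integer vector of exon lengths (exon ids 1..N).
#' @param cassette_exons Exon ids that may be skipped.
#' @param isoform_defs Named list: isoform name -> integer vector of skipped
#'   exon ids. Default: the full-length transcript plus one single-skip
#'   isoform per cassette exon.
#' @param gc_fraction GC content of the random sequence.
#' @param seed RNG seed; the same spec and seed give byte-identical output.
#' @param gene_id Gene name.
#' @return An object of class `FixtureSpec`.
#' @export
fixture_spec <- function(exon_lengths, cassette_exons, isoform_defs = NULL,
                         gc_fraction = 0.5, seed = 1L, gene_id = "synth") {
  exon_lengths <- as.integer(exon_lengths)
  cassette_exons <- sort(as.integer(cassette_exons))
  n <- length(exon_lengths)
  if (!all(cassette_exons %in% seq_len(n)))
    stop("cassette exon outside the gene")
  if (is.null(isoform_defs)) {
    isoform_defs <- c(list(Full = integer()),
                      stats::setNames(as.list(cassette_exons),
                                      paste0("Skip", cassette_exons)))
  }
  structure(
    list(exon_lengths = exon_lengths, cassette_exons = cassette_exons,
         isoform_defs = isoform_defs, gc_fraction = gc_fraction,
         seed = as.integer(seed), gene_id = gene_id),
    class = "FixtureSpec"
  )
}

# Anchor exons for the suggested primers: the constitutive exon immediately
# before the first cassette (forward), the first constitutive exon strictly
# inside the cassette span (internal reverse/forward, when one exists) and
# the first constitutive exon after the last cassette (outer reverse).
fixture_anchors <- function(spec) {
  n <- length(spec$exon_lengths)
  constitutive <- setdiff(seq_len(n), spec$cassette_exons)
  lo <- min(spec$cassette_exons); hi <- max(spec$cassette_exons)
  f <- max(constitutive[constitutive < lo], -Inf)
  r2 <- min(constitutive[constitutive > hi], Inf)
  if (!is.finite(f) || !is.finite(r2))
    stop("cassette exons must be flanked by constitutive exons")
  internal <- constitutive[constitutive > lo & constitutive < hi]
  list(forward = f, internal = if (length(internal)) internal[1] else NA,
       outer = r2)
}

#' Generate a synthetic cassette-exon gene with primer anchor sites
#'
#' Exon sequences are random (seeded); the suggested primers are 21-mers
#' lifted from constitutive anchor exons flanking (and, when available,
#' inside) the cassette span. Sequences are rejection-sampled until every
#' primer site is unique on the full-length transcript.
#'
#' @param spec A [fixture_spec()].
#' @param max_retries Resampling attempts before giving up.
#' @return List with `exon_set`, `isoforms` (named list) and `pairs` (list
#'   of `list(forward, reverse)` primer pairs; an internal anchor yields the
#'   three-pair layout F1/R1, F1/R2, F2/R2, otherwise the single flanking
#'   pair F1/R2).
#' @export
synth_gene <- function(spec, max_retries = 50L) {
  stopifnot(inherits(spec, "FixtureSpec"))
  anch <- fixture_anchors(spec)
  k <- 21L
  need <- c(anch$forward, anch$outer, if (!is.na(anch$internal)) anch$internal)
  if (any(spec$exon_lengths[need] < k + 10L))
    stop("anchor exons must be at least ", k + 10L, " bp")
  for (attempt in seq_len(max_retries)) {
    seqs <- with_seed(spec$seed + (attempt - 1L) * 7919L, {
      vapply(spec$exon_lengths, random_bases, character(1),
             gc_fraction = spec$gc_fraction)
    })
    full <- paste(seqs, collapse = "")
    window <- function(exon_id) substr(seqs[exon_id], 6L, 6L + k - 1L)
    f1_seq <- window(anch$forward)
    r2_seq <- revcomp(window(anch$outer))
    sites <- c(f1_seq, window(anch$outer))
    if (!is.na(anch$internal)) {
      f2_seq <- window(anch$internal)
      r1_seq <- revcomp(f2_seq)
      sites <- c(sites, f2_seq)
    }
    ok <- all(vapply(sites, function(s)
      count_occurrences(s, full) == 1L &&
        count_occurrences(revcomp(s), full) == 0L, logical(1)))
    if (ok) break
    if (attempt == max_retries)
      stop("could not embed unique primer sites after ", max_retries,
           " attempts")
  }
  es <- exon_set(spec$gene_id, spec$exon_lengths, seqs,
                 source = sprintf("synth_gene seed %d", spec$seed))
  isoforms <- lapply(names(spec$isoform_defs), function(nm)
    build_isoform(es, nm, spec$isoform_defs[[nm]]))
  isoforms <- name_isoforms(isoforms)
  f1 <- primer("F1", f1_seq, "forward")
  r2 <- primer("R2", r2_seq, "reverse")
  pairs <- if (!is.na(anch$internal)) {
    f2 <- primer("F2", f2_seq, "forward")
    r1 <- primer("R1", r1_seq, "reverse")
    list(list(f1, r1), list(f1, r2), list(f2, r2))
  } else {
    list(list(f1, r2))
  }
  list(exon_set = es, isoforms = isoforms, pairs = pairs)
}

## ---- POSTN fixture ----------------------------------------------------

postn_extdata <- function(file) {
  path <- system.file("extdata", file, package = "isopanel")
  if (!nzchar(path)) stop("packaged file not found: ", file)
  path
}

# Exon-21 CDS segment encoding the epitope peptide GHLFEDEEIKRLLQGC with the
# codon spelling whose EDEEIKR core is exactly the published siEx21 21-mer
# (5'-GAAGAUGAAGAAAUUAAAAGA-3' as RNA).
POSTN_EPITOPE_CDS <- "GGACATCTGTTTGAAGATGAAGAAATTAAAAGACTGCTTCAGGGCTGC"

# The 23-nt exon-20 segment carrying both primer footprints of the shared
# locus: reverse-complement(R1) at its first 21 nt, F2 at nt 2-23.
POSTN_SHARED_LOCUS <- "TGGAGGTGGAGAAACAGAAGAAA"

#' Build the POSTN gene fixture (23 exons, 11 isoforms, 4 primers)
#'
#' `"idealized"` mode is fully offline: a 23-exon gene model with cassette
#' exons 17, 18, 19 and 21 of equal length 84 bp (a frame-preserving fixture
#' choice consistent with the published band groupings, not a measured exon
#' length), the published primers F1/F2/R1/R2 embedded at their constitutive
#' anchor sites (F1 in exon 16, the shared F2/R1 locus in exon 20, R2 in
#' exon 22), the exon-21 siRNA site and epitope coding sequence embedded in
#' exon 21, and a CDS running from position 1 to a stop codon in exon 22.
#' `"reference"` mode instead loads true exon lengths and sequences from a
#' local cache of the reference records (GenBank D13664 / RefSeq), which
#' must have been fetched once with `scripts/fetch_reference.R`.
#'
#' @param mode `"idealized"` or `"reference"`.
#' @param cache_dir Directory holding the cached reference exon table
#'   (reference mode only).
#' @return List with `exon_set`, `isoforms` (named list of the 11 isoform
#'   models), `primers` (named list F1/F2/R1/R2), `pairs` (the screening
#'   panel F1/R1, F1/R2, F2/R2) and `cds_start` (1).
#' @export
build_postn_fixture <- function(mode = c("idealized", "reference"),
                                cache_dir = tools::R_user_dir("isopanel", "cache")) {
  mode <- match.arg(mode)
  primers <- read_primers(postn_extdata("postn_primers.tsv"))
  if (mode == "reference") {
    ref <- file.path(cache_dir, "postn_reference_exons.tsv")
    if (!file.exists(ref))
      stop("reference records not cached at ", ref,
           "; fetch them once (network required) with ",
           "Rscript scripts/fetch_reference.R")
    tab <- utils::read.delim(ref, stringsAsFactors = FALSE)
    es <- exon_set("POSTN", tab$length, tab$sequence,
                   source = "cached reference records")
  } else {
    es <- postn_idealized_exons()
  }
  isoforms <- load_isoform_table(postn_extdata("postn_isoforms.tsv"), es)
  pairs <- list(list(primers$F1, primers$R1),
                list(primers$F1, primers$R2),
                list(primers$F2, primers$R2))
  list(exon_set = es, isoforms = isoforms, primers = primers, pairs = pairs,
       cds_start = 1L)
}

# Deterministic idealized 23-exon POSTN model. Constitutive filler is drawn
# as random sense codons under a fixed internal seed (rejection-sampled so
# every embedded primer/siRNA site is unique), so the fixture is
# byte-identical across calls and independent of the caller's RNG.
postn_idealized_exons <- function() {
  primers <- read_primers(postn_extdata("postn_primers.tsv"))
  f1 <- primers$F1$sequence
  rc_r2 <- revcomp(primers$R2$sequence)
  lengths <- c(201L, rep(162L, 15L), 84L, 84L, 84L, 99L, 84L, 150L, 240L)
  si_ex21 <- "GAAGATGAAGAAATTAAAAGA"
  for (attempt in 0:49) {
    seqs <- with_seed(20230123L + attempt, {
      s <- character(23L)
      s[1] <- paste0("ATG", random_codons(66L))
      for (i in 2:15) s[i] <- random_codons(54L)
      s[16] <- paste0(random_codons(3L), f1, random_codons(44L))
      for (i in 17:19) s[i] <- random_codons(28L)
      s[20] <- paste0(random_codons(10L), POSTN_SHARED_LOCUS, "T",
                      random_codons(15L))
      s[21] <- paste0(random_codons(5L), POSTN_EPITOPE_CDS, random_codons(7L))
      s[22] <- paste0(random_codons(10L), "TAA", random_bases(27L),
                      rc_r2, random_bases(70L))
      s[23] <- random_bases(240L)
      s
    })
    full <- paste(seqs, collapse = "")
    sites <- c(f1, primers$F2$sequence, revcomp(primers$R1$sequence),
               rc_r2, si_ex21)
    ok <- all(vapply(sites, function(x)
      count_occurrences(x, full) == 1L, logical(1))) &&
      all(vapply(c(primers$F1$sequence, primers$F2$sequence), function(x)
        count_occurrences(revcomp(x), full) == 0L, logical(1))) &&
      all(vapply(c(primers$R1$sequence, primers$R2$sequence), function(x)
        count_occurrences(x, full) == 0L, logical(1)))
    if (ok)
      return(exon_set("POSTN", lengths, seqs,
                      source = "idealized offline model"))
  }
  stop("could not build a collision-free idealized model")  # nocov
}

#' The published siRNA and epitope targets for the POSTN fixture
#'
#' `siEx21` is the exon-21 siRNA (knocks down only exon-21-retaining
#' isoforms, i.e. Iso5 among Iso3/Iso5); `siPOSTN` is the pan-isoform siRNA
#' read off the constitutive reference positions 2397-2417; `epitope` is the
#' exon-21 peptide used to raise the isoform-specific antibody.
#'
#' @param fixture A [build_postn_fixture()] result.
#' @return Named list of [target_region()] objects.
#' @export
postn_targets <- function(fixture) {
  full <- build_isoform(fixture$exon_set, "full", integer())
  list(
    siEx21 = target_region("siEx21", "GAAGAUGAAGAAAUUAAAAGA", "rna"),
    siPOSTN = target_region("siPOSTN",
                            substr(full$transcript, 2397L, 2417L), "dna"),
    epitope = target_region("Ex21-epitope", "GHLFEDEEIKRLLQGC", "protein")
  )
}

#' Write a fixture to disk (FASTA, GFF3, isoform table, primer TSV)
#'
#' @param fixture A [build_postn_fixture()] or [synth_gene()] result.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the named vector of written paths.
#' @export
write_fixture <- function(fixture, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    transcripts = file.path(dir, "transcripts.fa"),
    annotation = file.path(dir, "gene.gff3"),
    genome = file.path(dir, "genome.fa"),
    isoforms = file.path(dir, "isoforms.json"),
    primers = file.path(dir, "primers.tsv")
  )
  write_isoform_fasta(fixture$isoforms, paths["transcripts"])
  write_gene_model(fixture$exon_set, paths["annotation"], paths["genome"])
  iso_tab <- data.frame(
    name = names(fixture$isoforms),
    exons_missing = vapply(fixture$isoforms, function(i)
      if (length(i$skipped)) paste(i$skipped, collapse = ", ") else "None",
      character(1)),
    accession = vapply(fixture$isoforms, function(i)
      if (is.na(i$reference)) "" else i$reference, character(1)),
    stringsAsFactors = FALSE)
  jsonlite::write_json(iso_tab, paths["isoforms"], dataframe = "columns")
  prim <- unique(do.call(rbind, lapply(fixture$pairs, function(p)
    data.frame(name = c(p[[1]]$name, p[[2]]$name),
               sequence = c(p[[1]]$sequence, p[[2]]$sequence),
               role = c("forward", "reverse"), stringsAsFactors = FALSE))))
  utils::write.table(prim, paths["primers"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(paths)
}
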