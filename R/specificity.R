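# Isoform-specific target design: which isoforms contain a nucleotide or
# peptide target, and which k-mers of one isoform are absent from every other
# co-expressed isoform (the siRNA / epitope problem).
#
# Specificity is exact-substring containment. Skipping an exon removes its
# sequence from the transcript but also *creates* a novel junction k-mer in
# the shorter isoform; both kinds of uniqueness are found by the same k-mer
# scan, so a target can discriminate either the exon-retaining or the
# exon-skipping isoform.

#' Construct a target region (nucleotide or peptide)
#'
#' @param name Target name.
#' @param sequence Target sequence; RNA input (`U`) is normalized to DNA.
#' @param alphabet `"dna"`, `"rna"` or `"protein"`.
#' @return An object of class `TargetRegion`.
#' @export
target_region <- function(name, sequence, alphabet = c("dna", "rna", "protein")) {
  alphabet <- match.arg(alphabet)
  sequence <- toupper(as.character(sequence))
  if (!nzchar(sequence)) stop("empty target")
  if (alphabet %in% c("dna", "rna")) sequence <- normalize_dna(sequence)
  structure(list(name = as.character(name), sequence = sequence,
                 alphabet = alphabet),
            class = "TargetRegion")
}

#' @export
print.TargetRegion <- function(x, ...) {
  cat(sprintf("TargetRegion %s (%s, %d letters): %s\n",
              x$name, x$alphabet, nchar(x$sequence), x$sequence))
  invisible(x)
}

#' Which isoforms contain a target sequence
#'
#' Nucleotide targets are matched as exact substrings of the spliced
#' transcript; peptide targets as exact substrings of the translated CDS
#' (single frame from `cds_start` on the full-length reference). Isoforms
#' whose skip shifts the reading frame are excluded from peptide containment
#' with a warning.
#'
#' @param target A [target_region()].
#' @param isoforms Named list of isoforms with transcripts.
#' @param cds_start CDS start on each transcript (used for peptide targets).
#' @return Character vector of containing isoform names.
#' @export
containing_isoforms <- function(target, isoforms, cds_start = 1L) {
  stopifnot(inherits(target, "TargetRegion"))
  isoforms <- name_isoforms(isoforms)
  if (target$alphabet == "protein") {
    shifted <- vapply(isoforms, function(i) !i$frame_preserving, logical(1))
    if (any(shifted))
      warning("frame-shifted isoforms excluded from peptide containment: ",
              paste(names(isoforms)[shifted], collapse = ", "))
    isoforms <- isoforms[!shifted]
    hits <- vapply(isoforms, function(i)
      grepl(target$sequence, translate_cds(i, cds_start), fixed = TRUE),
      logical(1))
  } else {
    hits <- vapply(isoforms, function(i)
      grepl(target$sequence, i$transcript, fixed = TRUE), logical(1))
  }
  names(isoforms)[hits]
}

#' Locate every hit of a target on each isoform
#'
#' @inheritParams containing_isoforms
#' @return data.frame with columns `isoform`, `start`, `end` (transcript
#'   positions for nucleotide targets, peptide positions for protein
#'   targets); zero rows when the target is absent everywhere.
#' @export
locate_target <- function(target, isoforms, cds_start = 1L) {
  stopifnot(inherits(target, "TargetRegion"))
  isoforms <- name_isoforms(isoforms)
  if (target$alphabet == "protein")
    isoforms <- Filter(function(i) i$frame_preserving, isoforms)
  rows <- lapply(isoforms, function(i) {
    subject <- if (target$alphabet == "protein")
      translate_cds(i, cds_start) else i$transcript
    m <- gregexpr(target$sequence, subject, fixed = TRUE)[[1]]
    if (m[1] == -1L) return(NULL)
    data.frame(isoform = i$name, start = as.integer(m),
               end = as.integer(m) + nchar(target$sequence) - 1L,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(isoform = character(), start = integer(),
                      end = integer(), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

all_kmers <- function(seq, k) {
  n <- nchar(seq)
  if (n < k) return(character())
  substring(seq, 1:(n - k + 1L), k:n)
}

#' Find k-mers unique to one isoform among an expressed set
#'
#' Reports every k-mer of the target isoform's transcript that is absent
#' from the transcript of every other expressed isoform — candidate
#' isoform-specific siRNA (or probe) sites. Each hit is annotated with the
#' exons it covers and whether it spans a splice junction (junction k-mers
#' created by exon skipping are reported on the same footing as
#' exon-presence k-mers).
#'
#' @param target_iso Name of the isoform to discriminate.
#' @param expressed Named list of co-expressed isoforms (must contain
#'   `target_iso`).
#' @param k Target length in nt (default 21, the classic siRNA duplex
#'   length; minimum 15).
#' @return data.frame with columns `start`, `end`, `sequence`, `exons`
#'   (comma-joined ids) and `junction` (logical); zero rows when the target
#'   isoform has no unique k-mer.
#' @export
design_discriminating_target <- function(target_iso, expressed, k = 21L) {
  if (k < 15L) stop("k must be at least 15")
  expressed <- name_isoforms(expressed)
  if (!target_iso %in% names(expressed))
    stop("target isoform not in the expressed set")
  iso <- expressed[[target_iso]]
  others <- expressed[setdiff(names(expressed), target_iso)]
  kmers <- all_kmers(iso$transcript, k)
  other_kmers <- unique(unlist(lapply(others, function(o)
    all_kmers(o$transcript, k)), use.names = FALSE))
  unique_pos <- which(!kmers %in% other_kmers)
  if (!length(unique_pos))
    return(data.frame(start = integer(), end = integer(),
                      sequence = character(), exons = character(),
                      junction = logical(), stringsAsFactors = FALSE))
  cm <- coord_map(iso)
  exons <- lapply(unique_pos, function(s) exons_in_interval(cm, s, s + k - 1L))
  data.frame(
    start = unique_pos, end = unique_pos + k - 1L,
    sequence = kmers[unique_pos],
    exons = vapply(exons, paste, character(1), collapse = ","),
    junction = lengths(exons) > 1L,
    stringsAsFactors = FALSE
  )
}

#' Presence of a full-length-transcript interval across isoforms
#'
#' The interval is given in coordinates of the full-length (skip-free)
#' transcript; for each isoform it is classified as fully retained,
#' partially lost, or fully lost depending on how much of it falls in
#' skipped exons.
#'
#' @param start,end Interval on the full-length transcript, 1-based
#'   inclusive.
#' @param exon_set The gene's [exon_set()].
#' @param isoforms Named list of isoforms of that gene.
#' @return data.frame with columns `isoform` and `status` (factor levels
#'   `retained`, `partial`, `lost`).
#' @export
region_presence <- function(start, end, exon_set, isoforms) {
  stopifnot(inherits(exon_set, "ExonSet"), end >= start)
  full <- build_isoform(exon_set, ".full", integer())
  cm <- coord_map(full)
  if (start < 1L || end > full$length) stop("coordinate out of bounds")
  pos_exons <- map_coordinate(cm, start:end)$exon_id
  isoforms <- name_isoforms(isoforms)
  status <- vapply(isoforms, function(iso) {
    lost <- sum(pos_exons %in% iso$skipped)
    if (lost == 0L) "retained"
    else if (lost == length(pos_exons)) "lost"
    else "partial"
  }, character(1))
  data.frame(isoform = names(isoforms),
             status = factor(status, levels = c("retained", "partial", "lost")),
             row.names = NULL, stringsAsFactors = FALSE)
}
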