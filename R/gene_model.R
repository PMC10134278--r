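# Exon-level gene models and skip-defined isoforms.
#
# An ExonSet is the ordered exon catalogue of one gene (ids 1..N in transcript
# order); an IsoformModel is that catalogue minus a set of skipped exons, with
# the spliced transcript assembled by concatenating the retained exons. All
# transcript coordinates are 1-based and inclusive.

#' Construct an exon catalogue
#'
#' @param gene_id Gene identifier.
#' @param lengths Integer vector of exon lengths in bp, in transcript order.
#' @param sequences Optional character vector of exon sequences (DNA, one per
#'   exon); when given, `nchar(sequences)` must equal `lengths`.
#' @param source Free-text provenance note.
#' @return An object of class `ExonSet`.
#' @export
exon_set <- function(gene_id, lengths, sequences = NULL, source = "") {
  lengths <- as.integer(lengths)
  if (any(is.na(lengths)) || any(lengths < 1L))
    stop("every exon length must be a positive integer")
  n <- length(lengths)
  if (n < 1L) stop("an ExonSet needs at least one exon")
  if (!is.null(sequences)) {
    sequences <- normalize_dna(sequences)
    if (length(sequences) != n)
      stop("sequences must have one entry per exon")
    if (!all(nchar(sequences) == lengths))
      stop("sequence lengths disagree with the length field")
  }
  exons <- data.frame(
    exon_id = seq_len(n),
    length = lengths,
    stringsAsFactors = FALSE
  )
  exons$sequence <- if (is.null(sequences)) NA_character_ else sequences
  structure(
    list(gene_id = as.character(gene_id), exons = exons, source = source),
    class = "ExonSet"
  )
}

#' @export
print.ExonSet <- function(x, ...) {
  cat("ExonSet:", x$gene_id, "-", nrow(x$exons), "exons,",
      sum(x$exons$length), "bp spliced\n")
  if (nzchar(x$source)) cat("  source:", x$source, "\n")
  invisible(x)
}

# Uppercase, RNA U -> T; validates the DNA alphabet (N allowed).
normalize_dna <- function(x) {
  x <- chartr("u", "U", toupper(as.character(x)))
  x <- chartr("U", "T", x)
  bad <- grepl("[^ACGTN]", x)
  if (any(bad))
    stop("sequence contains characters outside A/C/G/T/N/U")
  x
}

has_sequences <- function(exon_set) !anyNA(exon_set$exons$sequence)

#' Build a skip-defined isoform from an exon catalogue
#'
#' The transcript is the concatenation of the retained exons in catalogue
#' order. The skip is frame-preserving when the total skipped length is a
#' multiple of 3.
#'
#' @param exon_set An [exon_set()].
#' @param name Isoform name (e.g. `"Iso5"`).
#' @param skipped Integer vector of skipped exon ids (possibly empty).
#' @param reference Optional accession of a matching database record.
#' @return An object of class `IsoformModel`.
#' @export
build_isoform <- function(exon_set, name, skipped = integer(), reference = NA_character_) {
  stopifnot(inherits(exon_set, "ExonSet"))
  skipped <- sort(unique(as.integer(skipped)))
  ids <- exon_set$exons$exon_id
  if (length(skipped) && !all(skipped %in% ids))
    stop("unknown exon: ", paste(setdiff(skipped, ids), collapse = ", "))
  retained <- setdiff(ids, skipped)
  if (!length(retained)) stop("empty transcript: all exons skipped")
  keep <- exon_set$exons[match(retained, ids), , drop = FALSE]
  transcript <- if (has_sequences(exon_set)) {
    paste(keep$sequence, collapse = "")
  } else {
    NA_character_
  }
  skipped_len <- sum(exon_set$exons$length[match(skipped, ids)])
  structure(
    list(
      name = as.character(name),
      gene_id = exon_set$gene_id,
      skipped = skipped,
      retained = retained,
      retained_lengths = keep$length,
      transcript = transcript,
      length = sum(keep$length),
      frame_preserving = (skipped_len %% 3L) == 0L,
      reference = reference
    ),
    class = "IsoformModel"
  )
}

#' @export
print.IsoformModel <- function(x, ...) {
  skip <- if (length(x$skipped)) paste(x$skipped, collapse = ",") else "none"
  cat(sprintf("IsoformModel %s (%s): %d bp, skipped exons: %s, frame %s\n",
              x$name, x$gene_id, x$length, skip,
              if (x$frame_preserving) "preserved" else "shifted"))
  invisible(x)
}

#' Read a gene model from GFF3/GTF annotation plus a genome FASTA
#'
#' Exon features of the requested gene are collected, ordered in transcript
#' orientation (strand-aware), their sequences extracted from the genome
#' (reverse-complemented for minus-strand genes) and renumbered 1..N. All
#' downstream logic is strand-free.
#'
#' @param annotation_path GFF3 or GTF file.
#' @param genome_path FASTA file with the referenced contig(s).
#' @param gene_id Gene identifier matched against `gene_id`/`ID`/`Parent`/
#'   `gene` attributes of exon features.
#' @return An [exon_set()] with sequences.
#' @export
load_gene_model <- function(annotation_path, genome_path, gene_id) {
  anno <- rtracklayer::import(annotation_path)
  feat <- anno[tolower(as.character(anno$type)) == "exon"]
  m <- S4Vectors::mcols(feat)
  hit <- rep(FALSE, length(feat))
  for (key in c("gene_id", "gene", "ID", "Parent", "transcript_id")) {
    if (!key %in% names(m)) next
    v <- m[[key]]
    if (methods::is(v, "CharacterList") || is.list(v)) {
      hit <- hit | vapply(v, function(p) any(p == gene_id), logical(1))
    } else {
      hit <- hit | (!is.na(v) & v == gene_id)
    }
  }
  feat <- feat[hit]
  if (!length(feat)) stop("gene not found: ", gene_id)
  genome <- Biostrings::readDNAStringSet(genome_path)
  names(genome) <- sub("\\s.*$", "", names(genome))
  chrom <- unique(as.character(GenomicRanges::seqnames(feat)))
  if (length(chrom) != 1L)
    stop("gene ", gene_id, " spans multiple contigs")
  if (!chrom %in% names(genome))
    stop("coordinate error: contig ", chrom, " absent from genome")
  contig <- genome[[chrom]]
  if (max(GenomicRanges::end(feat)) > length(contig) ||
      min(GenomicRanges::start(feat)) < 1L)
    stop("coordinate error: exon outside contig bounds")
  strand <- unique(as.character(GenomicRanges::strand(feat)))
  strand <- setdiff(strand, "*")
  if (length(strand) > 1L) stop("gene ", gene_id, " has mixed strands")
  minus <- identical(strand, "-")
  ord <- order(GenomicRanges::start(feat), decreasing = minus)
  feat <- feat[ord]
  seqs <- vapply(seq_along(feat), function(i) {
    s <- Biostrings::subseq(contig, GenomicRanges::start(feat)[i],
                            GenomicRanges::end(feat)[i])
    if (minus) s <- Biostrings::reverseComplement(s)
    as.character(s)
  }, character(1))
  exon_set(gene_id, GenomicRanges::width(feat), seqs,
           source = paste0(annotation_path, " [", chrom,
                           if (minus) ", -" else ", +", "]"))
}

# "None", "" or NA -> empty skip set; otherwise a comma list of exon ids.
parse_skip_list <- function(x) {
  x <- trimws(as.character(x))
  if (is.na(x) || !nzchar(x) || tolower(x) == "none") return(integer())
  out <- suppressWarnings(as.integer(trimws(strsplit(x, ",")[[1]])))
  if (anyNA(out)) stop("malformed skip list: ", x)
  out
}

#' Read an isoform table (TSV or JSON)
#'
#' The table is a direct serialization of an isoform catalogue: columns
#' `name`, `exons_missing` (`"None"` or a comma list of exon ids) and an
#' optional `accession`.
#'
#' @param table_path Path to a `.tsv`/`.txt` or `.json` file.
#' @param exon_set The parent [exon_set()].
#' @return Named list of [build_isoform()] models, in table order.
#' @export
load_isoform_table <- function(table_path, exon_set) {
  ext <- tolower(tools::file_ext(table_path))
  tab <- if (ext == "json") {
    as.data.frame(jsonlite::fromJSON(table_path), stringsAsFactors = FALSE)
  } else {
    utils::read.delim(table_path, stringsAsFactors = FALSE,
                      colClasses = "character")
  }
  if (!all(c("name", "exons_missing") %in% names(tab)))
    stop("isoform table needs 'name' and 'exons_missing' columns")
  if (anyDuplicated(tab$name))
    stop("duplicate isoform name: ",
         paste(unique(tab$name[duplicated(tab$name)]), collapse = ", "))
  acc <- if ("accession" %in% names(tab)) tab$accession else
    rep(NA_character_, nrow(tab))
  acc[!is.na(acc) & !nzchar(trimws(acc))] <- NA_character_
  isos <- lapply(seq_len(nrow(tab)), function(i) {
    build_isoform(exon_set, tab$name[i], parse_skip_list(tab$exons_missing[i]),
                  reference = acc[i])
  })
  names(isos) <- tab$name
  isos
}

#' Write isoform transcripts as FASTA
#'
#' @param isoforms List of [build_isoform()] models with sequences.
#' @param path Output FASTA path.
#' @export
write_isoform_fasta <- function(isoforms, path) {
  seqs <- vapply(isoforms, function(i) i$transcript, character(1))
  if (anyNA(seqs)) stop("isoforms carry no sequences")
  x <- Biostrings::DNAStringSet(seqs)
  names(x) <- vapply(isoforms, function(i) i$name, character(1))
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Write a gene model as GFF3 plus genome FASTA
#'
#' Lays the exons on a synthetic contig separated by fixed-length spacer
#' introns; for minus-strand output the exon order and sequences are
#' reversed/complemented so that reading the files back reproduces the same
#' transcript-oriented catalogue.
#'
#' @param exon_set An [exon_set()] with sequences.
#' @param annotation_path,genome_path Output paths.
#' @param strand `"+"` or `"-"`.
#' @param intron_length Spacer intron length in bp.
#' @param chrom Contig name.
#' @export
write_gene_model <- function(exon_set, annotation_path, genome_path,
                             strand = "+", intron_length = 200L,
                             chrom = "chrSyn") {
  stopifnot(inherits(exon_set, "ExonSet"), has_sequences(exon_set))
  ex <- exon_set$exons
  n <- nrow(ex)
  genomic_seqs <- ex$sequence
  order_on_genome <- seq_len(n)
  if (strand == "-") {
    order_on_genome <- rev(order_on_genome)
    genomic_seqs <- vapply(
      genomic_seqs,
      function(s) as.character(Biostrings::reverseComplement(Biostrings::DNAString(s))),
      character(1), USE.NAMES = FALSE)
    genomic_seqs <- rev(genomic_seqs)
  }
  intron <- strrep("N", intron_length)
  contig <- paste0(intron, paste(genomic_seqs, collapse = intron), intron)
  lens <- nchar(genomic_seqs)
  starts <- intron_length + 1L +
    cumsum(c(0L, lens[-n] + intron_length))
  ends <- starts + lens - 1L
  ids <- ex$exon_id[order_on_genome]
  gff <- c(
    "##gff-version 3",
    sprintf("%s\tisopanel\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
            chrom, min(starts), max(ends), strand, exon_set$gene_id),
    sprintf("%s\tisopanel\texon\t%d\t%d\t.\t%s\t.\tID=%s:exon%d;Parent=%s",
            chrom, starts, ends, strand, exon_set$gene_id, ids,
            exon_set$gene_id)
  )
  writeLines(gff, annotation_path)
  fa <- Biostrings::DNAStringSet(contig)
  names(fa) <- chrom
  Biostrings::writeXStringSet(fa, genome_path)
  invisible(list(annotation = annotation_path, genome = genome_path))
}

## ---- coordinate mapping -----------------------------------------------

#' Transcript/exon coordinate map for one isoform
#'
#' Maps 1-based inclusive transcript positions to (exon id, offset within
#' exon) and back. Positions in skipped exons have no transcript image.
#'
#' @param iso An [build_isoform()] model.
#' @return An object of class `CoordMap`.
#' @export
coord_map <- function(iso) {
  stopifnot(inherits(iso, "IsoformModel"))
  ends <- cumsum(iso$retained_lengths)
  structure(
    list(isoform = iso$name, retained = iso$retained,
         lengths = iso$retained_lengths,
         starts = c(1L, utils::head(ends, -1L) + 1L), ends = ends,
         transcript_length = iso$length),
    class = "CoordMap"
  )
}

#' Map a transcript position to its exon
#'
#' @param cm A [coord_map()].
#' @param pos Transcript position(s), 1-based inclusive.
#' @return data.frame with columns `pos`, `exon_id`, `offset` (1-based
#'   offset within the exon).
#' @export
map_coordinate <- function(cm, pos) {
  stopifnot(inherits(cm, "CoordMap"))
  pos <- as.integer(pos)
  if (any(is.na(pos)) || any(pos < 1L) || any(pos > cm$transcript_length))
    stop("coordinate out of bounds")
  idx <- findInterval(pos, cm$starts)
  data.frame(pos = pos, exon_id = cm$retained[idx],
             offset = pos - cm$starts[idx] + 1L)
}

#' Map an (exon, offset) pair to its transcript position
#'
#' @param cm A [coord_map()].
#' @param exon_id Exon id in the parent catalogue.
#' @param offset 1-based offset within that exon.
#' @return Integer transcript position.
#' @export
transcript_position <- function(cm, exon_id, offset = 1L) {
  stopifnot(inherits(cm, "CoordMap"))
  idx <- match(as.integer(exon_id), cm$retained)
  if (anyNA(idx))
    stop("position in skipped exon: no transcript image")
  offset <- as.integer(offset)
  if (any(offset < 1L) || any(offset > cm$lengths[idx]))
    stop("coordinate out of bounds")
  cm$starts[idx] + offset - 1L
}

# Exon ids touched by a transcript interval.
exons_in_interval <- function(cm, start, end) {
  stopifnot(end >= start)
  unique(map_coordinate(cm, start:end)$exon_id)
}

## ---- translation ------------------------------------------------------

codon_table <- function() {
  gc <- Biostrings::GENETIC_CODE
  names(gc) <- as.character(names(gc))
  gc
}

translate_codons <- function(dna) {
  n <- nchar(dna) %/% 3L
  if (n == 0L) return("")
  codons <- substring(dna, 3L * seq_len(n) - 2L, 3L * seq_len(n))
  gc <- codon_table()
  aa <- gc[codons]
  aa[is.na(aa)] <- "X"  # ambiguity letters
  paste(aa, collapse = "")
}

#' Translate a transcript region in CDS frame
#'
#' The region is snapped to whole codons of the reading frame defined by
#' `cds_start` (with a warning when trimming is needed); stop codons render
#' as `*` and codons containing ambiguity letters as `X`.
#'
#' @param iso An isoform with a transcript.
#' @param cds_start Transcript position of the first CDS base.
#' @param start,end Region to translate, 1-based inclusive.
#' @return Peptide string.
#' @export
translate_region <- function(iso, cds_start, start, end) {
  stopifnot(inherits(iso, "IsoformModel"), !is.na(iso$transcript))
  if (start < 1L || end > iso$length || end < start)
    stop("coordinate out of bounds")
  s2 <- start + (cds_start - start) %% 3L
  n_codons <- (end - s2 + 1L) %/% 3L
  if (n_codons < 1L) {
    warning("region shorter than one codon in CDS frame")
    return("")
  }
  e2 <- s2 + 3L * n_codons - 1L
  if (s2 != start || e2 != end)
    warning("region trimmed to whole codons (", s2, "-", e2, ")")
  translate_codons(substr(iso$transcript, s2, e2))
}

#' Translate an isoform's CDS up to the first stop codon
#'
#' @param iso An isoform with a transcript.
#' @param cds_start Transcript position of the first CDS base.
#' @return Peptide string (stop codon not included).
#' @export
translate_cds <- function(iso, cds_start = 1L) {
  stopifnot(inherits(iso, "IsoformModel"), !is.na(iso$transcript))
  pep <- translate_codons(substr(iso$transcript, cds_start, iso$length))
  sub("\\*.*$", "", pep)
}
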