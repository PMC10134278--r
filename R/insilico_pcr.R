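# In-silico PCR on spliced transcripts: primer binding sites and amplicons.
#
# Matching is junction-aware by construction — primers are matched against the
# contiguous spliced transcript, so a footprint straddling an exon-exon
# junction binds only when the fused sequence matches. No genomic (unspliced)
# matching is attempted.

#' Construct a PCR primer
#'
#' @param name Primer name.
#' @param sequence 5'->3' sequence as ordered (RNA `U` is accepted and
#'   normalized to `T`; `N` is a wildcard).
#' @param role `"forward"` or `"reverse"`.
#' @return An object of class `Primer`.
#' @export
primer <- function(name, sequence, role = c("forward", "reverse")) {
  role <- match.arg(role)
  sequence <- normalize_dna(sequence)
  if (nchar(sequence) < 15L)
    warning("primer ", name, " is shorter than 15 nt")
  structure(list(name = as.character(name), sequence = sequence, role = role),
            class = "Primer")
}

#' @export
print.Primer <- function(x, ...) {
  cat(sprintf("Primer %s (%s): 5'-%s-3' (%d nt)\n",
              x$name, x$role, x$sequence, nchar(x$sequence)))
  invisible(x)
}

#' Read primers from TSV (columns name, sequence, role)
#'
#' @param path TSV file.
#' @return Named list of [primer()] objects.
#' @export
read_primers <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("name", "sequence", "role") %in% names(tab)))
    stop("primer table needs 'name', 'sequence' and 'role' columns")
  out <- lapply(seq_len(nrow(tab)),
                function(i) primer(tab$name[i], tab$sequence[i], tab$role[i]))
  names(out) <- tab$name
  out
}

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

# All start positions where `pattern` matches `subject` with at most
# `max_mismatches` mismatches ('N' in the pattern matches anything) and the
# positions `anchor` of the pattern matching exactly. Plain character scan;
# subjects here are a few kb so this stays cheap and dependency-free.
scan_sites <- function(pattern, subject, max_mismatches = 0L,
                       anchor = integer()) {
  np <- nchar(pattern); ns <- nchar(subject)
  if (np > ns) return(data.frame(start = integer(), mismatches = integer()))
  pat <- strsplit(pattern, "")[[1]]
  fixed_pos <- which(pat != "N")
  sub_chars <- strsplit(subject, "")[[1]]
  starts <- integer(); mm <- integer()
  if (max_mismatches == 0L) {
    # exact match path (N still wildcard)
    if (!length(fixed_pos)) {
      starts <- seq_len(ns - np + 1L); mm <- rep(0L, length(starts))
    } else if (length(fixed_pos) == np) {
      # full-window scan so overlapping occurrences are kept
      starts <- which(vapply(seq_len(ns - np + 1L), function(i)
        substr(subject, i, i + np - 1L) == pattern, logical(1)))
      mm <- rep(0L, length(starts))
    } else {
      for (i in seq_len(ns - np + 1L)) {
        if (all(sub_chars[i + fixed_pos - 1L] == pat[fixed_pos])) {
          starts <- c(starts, i); mm <- c(mm, 0L)
        }
      }
    }
  } else {
    for (i in seq_len(ns - np + 1L)) {
      window <- sub_chars[i:(i + np - 1L)]
      bad <- fixed_pos[window[fixed_pos] != pat[fixed_pos]]
      if (length(bad) <= max_mismatches && !any(bad %in% anchor)) {
        starts <- c(starts, i); mm <- c(mm, length(bad))
      }
    }
  }
  data.frame(start = starts, mismatches = mm)
}

#' Find primer binding sites on an isoform transcript
#'
#' Forward primers are matched against the transcript as given; reverse
#' primers are matched as their reverse complement (antisense binding). The
#' final 5 nt at the primer 3' end must match exactly even when mismatches
#' are allowed elsewhere.
#'
#' @param primer A [primer()].
#' @param iso An isoform with a transcript.
#' @param max_mismatches Mismatch allowance outside the 3' anchor (default 0,
#'   exact matching).
#' @return data.frame with columns `start`, `end`, `strand` (`+` sense for
#'   forward primers, `-` antisense for reverse), `mismatches`, sorted by
#'   `start`. Empty when the primer does not bind.
#' @export
find_binding_sites <- function(primer, iso, max_mismatches = 0L) {
  stopifnot(inherits(primer, "Primer"), inherits(iso, "IsoformModel"),
            !is.na(iso$transcript), max_mismatches >= 0L)
  np <- nchar(primer$sequence)
  if (primer$role == "forward") {
    pattern <- primer$sequence
    strand <- "+"
    anchor <- (np - 4L):np          # primer 3' end = pattern right end
  } else {
    pattern <- revcomp(primer$sequence)
    strand <- "-"
    anchor <- 1L:5L                 # primer 3' end = pattern left end
  }
  hits <- scan_sites(pattern, iso$transcript, max_mismatches, anchor)
  out <- data.frame(
    start = hits$start, end = hits$start + np - 1L,
    strand = rep(strand, nrow(hits)), mismatches = hits$mismatches,
    stringsAsFactors = FALSE
  )
  out[order(out$start), , drop = FALSE]
}

#' Predict PCR amplicons for a primer pair on one isoform
#'
#' One amplicon is reported per (sense forward site, downstream antisense
#' reverse site) combination whose product length is at least the two primer
#' footprints and at most `max_product`. The product spans both footprints,
#' 1-based inclusive. An empty result signals "no product" (the isoform is
#' not recognized by the pair).
#'
#' @param forward,reverse [primer()] objects.
#' @param iso An isoform with a transcript.
#' @param max_product Maximum product size in bp (default 3000).
#' @param max_mismatches Passed to [find_binding_sites()].
#' @return data.frame with columns `isoform`, `pair`, `start`, `end`,
#'   `length`, `exons` (comma-joined exon ids covered).
#' @export
predict_amplicons <- function(forward, reverse, iso, max_product = 3000L,
                              max_mismatches = 0L) {
  stopifnot(forward$role == "forward", reverse$role == "reverse")
  pair <- paste0(forward$name, "/", reverse$name)
  fwd <- find_binding_sites(forward, iso, max_mismatches)
  rev <- find_binding_sites(reverse, iso, max_mismatches)
  empty <- data.frame(isoform = character(), pair = character(),
                      start = integer(), end = integer(), length = integer(),
                      exons = character(), stringsAsFactors = FALSE)
  if (!nrow(fwd) || !nrow(rev)) return(empty)
  min_len <- nchar(forward$sequence) + nchar(reverse$sequence)
  cm <- coord_map(iso)
  rows <- list()
  for (i in seq_len(nrow(fwd))) {
    for (j in seq_len(nrow(rev))) {
      len <- rev$end[j] - fwd$start[i] + 1L
      if (len >= min_len && len <= max_product) {
        ex <- exons_in_interval(cm, fwd$start[i], rev$end[j])
        rows[[length(rows) + 1L]] <- data.frame(
          isoform = iso$name, pair = pair,
          start = fwd$start[i], end = rev$end[j], length = len,
          exons = paste(ex, collapse = ","), stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(rows)) return(empty)
  out <- do.call(rbind, rows)
  out[order(out$start, out$end), , drop = FALSE]
}

#' Amplicon sizes for a set of primer pairs over a set of isoforms
#'
#' @param pairs List of primer pairs; each element is `list(forward, reverse)`
#'   of [primer()] objects.
#' @param isoforms Named list of isoforms.
#' @param ... Passed to [predict_amplicons()].
#' @return Named list (by pair name) of named lists (by isoform) of integer
#'   size vectors; an isoform a pair does not recognize maps to an empty
#'   vector.
#' @export
amplicon_sizes <- function(pairs, isoforms, ...) {
  stopifnot(length(pairs) >= 1L, length(isoforms) >= 1L)
  isoforms <- name_isoforms(isoforms)
  out <- lapply(pairs, function(p) {
    sizes <- lapply(isoforms, function(iso)
      predict_amplicons(p[[1]], p[[2]], iso, ...)$length)
    sizes
  })
  names(out) <- vapply(pairs, function(p)
    paste0(p[[1]]$name, "/", p[[2]]$name), character(1))
  out
}

#' Amplicon size matrix (pair x isoform)
#'
#' @inheritParams amplicon_sizes
#' @return Character matrix; cells hold a product size in bp (comma-joined
#'   when a pair yields several products) or `"none"`.
#' @export
amplicon_table <- function(pairs, isoforms, ...) {
  sizes <- amplicon_sizes(pairs, isoforms, ...)
  iso_names <- names(sizes[[1]])
  mat <- t(vapply(sizes, function(row)
    vapply(row, function(s)
      if (length(s)) paste(s, collapse = ",") else "none", character(1)),
    character(length(iso_names))))
  dimnames(mat) <- list(names(sizes), iso_names)
  mat
}

# Ensure a list of isoforms is named by isoform name.
name_isoforms <- function(isoforms) {
  if (inherits(isoforms, "IsoformModel")) isoforms <- list(isoforms)
  nm <- vapply(isoforms, function(i) i$name, character(1))
  if (anyDuplicated(nm)) stop("duplicate isoform names")
  names(isoforms) <- nm
  isoforms
}
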