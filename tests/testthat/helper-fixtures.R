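# Shared fixtures, built once per test run.

.fixture_env <- new.env(parent = emptyenv())

postn_fx <- function() {
  if (is.null(.fixture_env$postn))
    .fixture_env$postn <- build_postn_fixture("idealized")
  .fixture_env$postn
}

postn_profile <- function() {
  if (is.null(.fixture_env$profile)) {
    fx <- postn_fx()
    .fixture_env$profile <- pcr_profile(fx$pairs, fx$isoforms)
  }
  .fixture_env$profile
}

# Tiny fully hand-specified gene: 4 exons, middle two skippable.
# Sequences chosen so every 15-mer is unique.
tiny_gene <- function() {
  if (is.null(.fixture_env$tiny)) {
    set.seed(42)
    seqs <- vapply(c(60L, 30L, 33L, 60L), function(n)
      paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = ""),
      character(1))
    es <- exon_set("tiny", nchar(seqs), seqs)
    .fixture_env$tiny <- es
  }
  .fixture_env$tiny
}

# A small synthetic cassette gene mirroring the POSTN exon layout at
# miniature scale: exon ids 1..8, cassettes 3/4/5/7 (equal length), internal
# constitutive exon 6 and flanking anchors 2 and 8. Skip sets follow the
# 11-isoform catalogue with 17->3, 18->4, 19->5, 21->7.
mini_postn_spec <- function(seed = 7L, cassette_len = 30L) {
  defs <- list(
    Iso1 = integer(), Iso2 = c(3L, 4L), Iso3 = c(3L, 7L),
    Iso4 = c(3L, 4L, 7L), Iso5 = 3L, Iso6 = c(3L, 4L, 5L),
    Iso7 = c(3L, 4L, 5L, 7L), Iso8 = 7L, Iso9 = c(4L, 7L),
    Iso10 = 4L, Iso11 = c(4L, 5L)
  )
  fixture_spec(
    exon_lengths = c(60L, 40L, cassette_len, cassette_len, cassette_len,
                     40L, cassette_len, 60L),
    cassette_exons = c(3L, 4L, 5L, 7L),
    isoform_defs = defs, seed = seed, gene_id = "miniPOSTN"
  )
}

# Random partition of `universe` into up to `max_classes` classes.
random_partition <- function(universe, max_classes = 4L) {
  labels <- sample(seq_len(max_classes), length(universe), replace = TRUE)
  as_partition(unname(split(universe, labels)))
}

# Brute-force common refinement: two elements share a joint class iff they
# share a class in every partition (pairwise intersection oracle).
oracle_joint <- function(partitions) {
  universe <- partitions[[1]]$universe
  same <- function(a, b) all(vapply(partitions, function(p)
    any(vapply(partition_classes(p), function(m) a %in% m && b %in% m,
               logical(1))), logical(1)))
  classes <- list()
  for (x in universe) {
    placed <- FALSE
    for (i in seq_along(classes)) {
      if (same(x, classes[[i]][1])) {
        classes[[i]] <- c(classes[[i]], x); placed <- TRUE; break
      }
    }
    if (!placed) classes[[length(classes) + 1L]] <- x
  }
  classes
}

# Canonical string form of a set-of-sets, for order-free comparison.
canon_classes <- function(classes) {
  sort(vapply(classes, function(m) paste(sort(m), collapse = ","),
              character(1)))
}

canon_subsets <- function(subsets) {
  sort(vapply(subsets, function(s) paste(sort(s), collapse = ","),
              character(1)))
}
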