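# Band-pattern decoding: the gel screen run in reverse.
#
# Given the band sizes observed for each primer pair, enumerate the isoform
# subsets whose predicted band pattern matches the observation and report
# them all, plus the inclusion-minimal (most parsimonious) explanations.
# Gels report presence, not intensity or multiplicity, so a subset's pattern
# is the union of its members' product sizes merged under the gel tolerance,
# and matching is set equality under tolerance.

#' Precompute a PCR size profile for decoding
#'
#' Caches every isoform's product sizes for every primer pair so that
#' repeated pattern prediction and decoding do not re-run the in-silico PCR.
#'
#' @param pairs List of primer pairs (`list(forward, reverse)` each).
#' @param isoforms Named list of isoforms.
#' @param ... Passed to [predict_amplicons()].
#' @return An object of class `PCRProfile`.
#' @export
pcr_profile <- function(pairs, isoforms, ...) {
  sizes <- amplicon_sizes(pairs, isoforms, ...)
  structure(
    list(pair_names = names(sizes), universe = names(sizes[[1]]),
         sizes = sizes, cache = new.env(parent = emptyenv())),
    class = "PCRProfile"
  )
}

#' @export
print.PCRProfile <- function(x, ...) {
  cat("PCRProfile:", length(x$pair_names), "primer pairs x",
      length(x$universe), "isoforms\n")
  invisible(x)
}

#' Construct an observed band pattern
#'
#' @param ... Named numeric vectors: one per primer pair, the band sizes in
#'   bp seen on the gel (may be empty for a pair with no product).
#' @return An object of class `ObservedPattern` (named list of size vectors).
#' @export
observed_pattern <- function(...) {
  x <- list(...)
  if (length(x) == 1L && is.list(x[[1]]) && is.null(names(x)[1])) x <- x[[1]]
  if (is.null(names(x)) || any(!nzchar(names(x))))
    stop("every element must be named by its primer pair")
  x <- lapply(x, function(v) sort(as.numeric(v)))
  if (any(unlist(x) <= 0)) stop("band sizes must be positive")
  structure(x, class = "ObservedPattern")
}

#' Read an observed band pattern from TSV (columns pair, size)
#'
#' Rows with an empty `size` record a pair that showed no band.
#'
#' @param path TSV file.
#' @return An `ObservedPattern`.
#' @export
read_observed_pattern <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("pair", "size") %in% names(tab)))
    stop("pattern table needs 'pair' and 'size' columns")
  sizes <- suppressWarnings(as.numeric(tab$size))
  split_sizes <- split(sizes, tab$pair)
  observed_pattern(lapply(split_sizes, function(v) v[!is.na(v)]))
}

# Per-pair band clusters of the whole profile under a tolerance, plus each
# isoform's membership bitmask. Cached on the profile.
profile_clusters <- function(profile, tolerance) {
  key <- paste0("tol:", paste(deparse(tolerance), collapse = ""))
  if (!is.null(profile$cache[[key]])) return(profile$cache[[key]])
  out <- lapply(profile$sizes, function(pair_sizes) {
    all_sizes <- unlist(pair_sizes, use.names = FALSE)
    cl <- cluster_sizes(all_sizes, tolerance)
    n_cl <- if (length(cl)) max(cl) else 0L
    reps <- if (n_cl) as.numeric(tapply(all_sizes, cl, mean)) else numeric()
    idx <- rep(seq_along(pair_sizes), lengths(pair_sizes))
    masks <- vapply(seq_along(pair_sizes), function(i) {
      ids <- unique(cl[idx == i])
      sum(bitwShiftL(1L, ids - 1L))
    }, integer(1))
    names(masks) <- names(pair_sizes)
    list(reps = reps, masks = masks)
  })
  profile$cache[[key]] <- out
  out
}

# Signature (integer bitmask per pair) of a subset of isoforms.
subset_signature <- function(clusters, members) {
  vapply(clusters, function(p) {
    if (!length(members)) return(0L)
    Reduce(bitwOr, p$masks[members], accumulate = FALSE)
  }, integer(1))
}

# Map observed sizes onto the profile's band clusters by greedy nearest
# matching within tolerance. Returns the bitmask, or NA when a band matches
# no predicted cluster (pattern inconsistent with the universe).
observed_signature <- function(clusters, obs, tolerance) {
  thr <- resolve_tolerance(tolerance)
  sig <- integer(length(clusters))
  for (i in seq_along(clusters)) {
    pair_name <- names(clusters)[i]
    bands <- if (pair_name %in% names(obs)) obs[[pair_name]] else numeric()
    mask <- 0L
    for (b in bands) {
      reps <- clusters[[i]]$reps
      if (!length(reps)) return(NA_integer_)
      d <- abs(reps - b)
      j <- which.min(d)
      if (d[j] > thr(max(reps[j], b))) return(NA_integer_)
      mask <- bitwOr(mask, bitwShiftL(1L, j - 1L))
    }
    sig[i] <- mask
  }
  sig
}

#' Predict the gel band pattern of an isoform subset
#'
#' The union of the member isoforms' product sizes per primer pair, with
#' co-migrating sizes merged to one band (reported at the mean size of the
#' merged cluster). The empty subset yields an empty pattern.
#'
#' @param subset Character vector of isoform names (subset of the profile's
#'   universe).
#' @param profile A [pcr_profile()].
#' @param tolerance Gel tolerance (see [partition_by_size()]).
#' @return An `ObservedPattern`.
#' @export
predict_band_pattern <- function(subset, profile, tolerance = "standard") {
  stopifnot(inherits(profile, "PCRProfile"))
  subset <- as.character(subset)
  if (!all(subset %in% profile$universe))
    stop("subset contains isoforms outside the universe")
  clusters <- profile_clusters(profile, tolerance)
  sig <- subset_signature(clusters, subset)
  out <- lapply(seq_along(clusters), function(i) {
    ids <- which(bitwAnd(sig[i], bitwShiftL(1L, seq_along(clusters[[i]]$reps) - 1L)) != 0L)
    sort(clusters[[i]]$reps[ids])
  })
  names(out) <- names(clusters)
  structure(out, class = "ObservedPattern")
}

# Enumerate all subsets of `universe` as a list of character vectors,
# ordered by size then lexicographically (bitmask order after sorting).
enumerate_subsets <- function(universe) {
  n <- length(universe)
  masks <- 0:(2^n - 1)
  subsets <- lapply(masks, function(m)
    universe[bitwAnd(m, bitwShiftL(1L, seq_len(n) - 1L)) != 0L])
  sizes <- lengths(subsets)
  keys <- vapply(subsets, paste, character(1), collapse = ",")
  subsets[order(sizes, keys)]
}

#' Decode an observed band pattern into consistent isoform subsets
#'
#' Exhaustively enumerates subsets of the universe (bounded at 24 isoforms)
#' and reports every subset whose predicted pattern matches the observation
#' under the gel tolerance, plus the inclusion-minimal ones (the parsimony
#' calls). Decoding never silently picks one explanation: all minimal
#' subsets are reported and residual interchangeability is summarized in the
#' ambiguity note — resolving it requires sequencing the ambiguous products.
#'
#' @param obs An [observed_pattern()] naming each panel pair's bands.
#' @param profile A [pcr_profile()] over the candidate isoform universe.
#' @param tolerance Gel tolerance (see [partition_by_size()]).
#' @return An object of class `DecodeResult` with elements `consistent`
#'   (list of isoform sets, ordered by size then lexicographically),
#'   `minimal` (the inclusion-minimal ones), `predicted` (predicted pattern
#'   of each minimal subset) and `note`.
#' @export
decode_bands <- function(obs, profile, tolerance = "standard") {
  stopifnot(inherits(profile, "PCRProfile"))
  universe <- profile$universe
  n <- length(universe)
  if (n > 24L) stop("universe too large for exhaustive decoding (> 24)")
  unknown <- setdiff(names(obs), profile$pair_names)
  if (length(unknown))
    stop("observed pattern references unknown pairs: ",
         paste(unknown, collapse = ", "))
  clusters <- profile_clusters(profile, tolerance)
  target <- observed_signature(clusters, obs, tolerance)
  if (anyNA(target))
    stop("pattern inconsistent with universe: a band matches no predicted product")
  sig_key <- paste0("sig:", paste(deparse(tolerance), collapse = ""))
  sigs <- profile$cache[[sig_key]]
  if (is.null(sigs)) {
    # signature matrix over all subsets, built once per tolerance
    npair <- length(clusters)
    masks_per_pair <- lapply(clusters, function(p) p$masks[universe])
    sigs <- matrix(0L, nrow = 2^n, ncol = npair)
    for (j in seq_len(npair)) {
      m <- masks_per_pair[[j]]
      col <- integer(2^n)
      for (i in seq_len(n)) {
        bit <- bitwShiftL(1L, i - 1L)
        has <- bitwAnd(0:(2^n - 1), bit) != 0L
        col[has] <- bitwOr(col[has], m[i])
      }
      sigs[, j] <- col
    }
    profile$cache[[sig_key]] <- sigs
  }
  ok <- rep(TRUE, 2^n)
  for (j in seq_len(ncol(sigs))) ok <- ok & (sigs[, j] == target[j])
  hit_masks <- which(ok) - 1L
  if (!length(hit_masks))
    stop("pattern inconsistent with universe")
  consistent <- lapply(hit_masks, function(m)
    universe[bitwAnd(m, bitwShiftL(1L, seq_len(n) - 1L)) != 0L])
  sizes <- lengths(consistent)
  keys <- vapply(consistent, paste, character(1), collapse = ",")
  o <- order(sizes, keys)
  consistent <- consistent[o]; hit_masks <- hit_masks[o]
  minimal_idx <- find_minimal(hit_masks)
  minimal <- consistent[minimal_idx]
  predicted <- lapply(minimal, predict_band_pattern, profile = profile,
                      tolerance = tolerance)
  note <- if (length(minimal) > 1L) {
    sprintf("%d minimal explanations; co-migrating members are interchangeable and require sequencing to resolve", length(minimal))
  } else "unique minimal explanation"
  structure(
    list(consistent = consistent, minimal = minimal, predicted = predicted,
         note = note, observation = obs, tolerance = tolerance),
    class = "DecodeResult"
  )
}

# Indices of the inclusion-minimal bitmasks (masks sorted by popcount).
find_minimal <- function(masks) {
  keep <- logical(length(masks))
  minimal <- integer()
  for (i in seq_along(masks)) {
    m <- masks[i]
    dominated <- any(bitwAnd(minimal, m) == minimal)
    if (!dominated) { keep[i] <- TRUE; minimal <- c(minimal, m) }
  }
  which(keep)
}

#' @export
print.DecodeResult <- function(x, ...) {
  cat("DecodeResult:", length(x$consistent), "consistent subsets,",
      length(x$minimal), "minimal\n")
  for (m in x$minimal)
    cat("  minimal: {", paste(m, collapse = ", "), "}\n")
  cat(" ", x$note, "\n")
  invisible(x)
}

#' Reference decoder: naive enumeration without pruning or caching
#'
#' Predicts each candidate subset's pattern directly and compares it to the
#' observation by mutual nearest-band matching. Intended as an independent
#' cross-check in tests; bounded at 12 isoforms.
#'
#' @inheritParams decode_bands
#' @return A `DecodeResult` (without per-subset predicted patterns).
#' @export
oracle_decode <- function(obs, profile, tolerance = "standard") {
  stopifnot(inherits(profile, "PCRProfile"))
  universe <- profile$universe
  if (length(universe) > 12L) stop("oracle decoder bounded at 12 isoforms")
  thr <- resolve_tolerance(tolerance)
  match_sets <- function(a, b) {
    if (!length(a) && !length(b)) return(TRUE)
    if (!length(a) || !length(b)) return(FALSE)
    fwd <- all(vapply(a, function(x)
      any(abs(b - x) <= thr(pmax(b, x))), logical(1)))
    bwd <- all(vapply(b, function(x)
      any(abs(a - x) <= thr(pmax(a, x))), logical(1)))
    fwd && bwd
  }
  subsets <- enumerate_subsets(universe)
  consistent <- Filter(function(s) {
    pred <- predict_band_pattern(s, profile, tolerance)
    all(vapply(profile$pair_names, function(pn) {
      o <- if (pn %in% names(obs)) obs[[pn]] else numeric()
      match_sets(pred[[pn]], o)
    }, logical(1)))
  }, subsets)
  if (!length(consistent)) stop("pattern inconsistent with universe")
  masks <- vapply(consistent, function(s)
    sum(bitwShiftL(1L, match(s, universe) - 1L)), numeric(1))
  minimal <- consistent[find_minimal(as.integer(masks))]
  structure(
    list(consistent = consistent, minimal = minimal, predicted = NULL,
         note = "oracle", observation = obs, tolerance = tolerance),
    class = "DecodeResult"
  )
}
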