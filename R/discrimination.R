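# Gel co-migration classes and diagnostic panel selection.
#
# A BandPartition groups isoforms whose PCR products are indistinguishable on
# a gel for one primer pair. Co-migration is modelled by single-linkage
# clustering of product sizes under a merge tolerance; because single linkage
# chains, a class's extreme members can differ by more than one merge step —
# this is deliberate (a ladder of barely-resolved bands reads as one smear).
# Running several primer pairs jointly corresponds to the common refinement
# of their partitions.

# Gel presets: the screening gels are 1.2% agarose (coarse routine gel) and
# 3.0% agarose (fine gel used to split close bands). The paper states the
# percentages but no resolution figures; the merge fractions are exposed
# configuration, not constants of nature.
GEL_PRESETS <- list(
  standard = list(fraction = 0.05,  floor_bp = 4),
  fine     = list(fraction = 0.015, floor_bp = 4)
)

# Normalize a tolerance argument: a preset name, an absolute bp value, or a
# list(fraction, floor_bp). Returns a function thr(larger_size) -> bp.
resolve_tolerance <- function(tolerance) {
  if (is.character(tolerance)) {
    if (!tolerance %in% names(GEL_PRESETS))
      stop("unknown gel preset: ", tolerance)
    tolerance <- GEL_PRESETS[[tolerance]]
  }
  if (is.numeric(tolerance)) {
    tol <- tolerance
    return(function(larger) rep(tol, length(larger)))
  }
  stopifnot(is.list(tolerance), all(c("fraction", "floor_bp") %in% names(tolerance)))
  function(larger) pmax(tolerance$floor_bp, tolerance$fraction * larger)
}

# Single-linkage clustering of sizes. Returns an integer cluster id per
# input size (ids ordered by ascending size).
cluster_sizes <- function(sizes, tolerance) {
  thr <- resolve_tolerance(tolerance)
  u <- sort(unique(sizes))
  if (!length(u)) return(integer())
  gaps <- diff(u)
  new_cluster <- c(TRUE, gaps > thr(u[-1L]))
  cl_of_u <- cumsum(new_cluster)
  cl_of_u[match(sizes, u)]
}

#' Partition isoforms into gel co-migration classes for one primer pair
#'
#' Product sizes are clustered by single linkage under the merge tolerance;
#' two isoforms share a class when their products fall in the same size
#' cluster(s). Isoforms the pair does not amplify form their own `"none"`
#' class, which never merges with sized bands.
#'
#' @param forward,reverse [primer()] objects (or pass `sizes` directly).
#' @param isoforms Named list of isoforms.
#' @param tolerance A gel preset (`"standard"` = 1.2% agarose, merge < 5% of
#'   the larger size; `"fine"` = 3.0% agarose, merge < 1.5%; both with a 4 bp
#'   floor), an absolute bp value, or `list(fraction, floor_bp)`.
#' @param ... Passed to [predict_amplicons()].
#' @return An object of class `BandPartition`.
#' @export
partition_by_size <- function(forward, reverse, isoforms,
                              tolerance = "standard", ...) {
  sizes <- amplicon_sizes(list(list(forward, reverse)), isoforms, ...)[[1]]
  partition_from_sizes(sizes, paste0(forward$name, "/", reverse$name),
                       tolerance)
}

#' Build a band partition from precomputed product sizes
#'
#' @param sizes Named list: isoform name -> integer vector of product sizes
#'   (empty vector = no product).
#' @param pair_name Label for the primer pair.
#' @inheritParams partition_by_size
#' @return An object of class `BandPartition`.
#' @export
partition_from_sizes <- function(sizes, pair_name = "pair",
                                 tolerance = "standard") {
  universe <- names(sizes)
  stopifnot(!is.null(universe), !anyDuplicated(universe))
  all_sizes <- unlist(sizes, use.names = FALSE)
  cl <- cluster_sizes(all_sizes, tolerance)
  idx <- rep(seq_along(sizes), lengths(sizes))
  signature <- vapply(seq_along(sizes), function(i) {
    s <- sort(unique(cl[idx == i]))
    if (!length(s)) "none" else paste(s, collapse = "+")
  }, character(1))
  # representative size per cluster: mean of member sizes
  reps <- if (length(all_sizes))
    tapply(all_sizes, cl, function(s) mean(s)) else numeric()
  classes <- lapply(split(universe, signature), identity)
  # deterministic ordering: ascending representative size, "none" last
  keys <- names(classes)
  ord_key <- vapply(keys, function(k) {
    if (k == "none") Inf else min(reps[strsplit(k, "+", fixed = TRUE)[[1]]])
  }, numeric(1))
  o <- order(ord_key)
  classes <- classes[o]; keys <- keys[o]
  class_list <- lapply(seq_along(classes), function(i) {
    k <- keys[i]
    sz <- if (k == "none") numeric() else
      unname(reps[strsplit(k, "+", fixed = TRUE)[[1]]])
    list(representative_size = if (length(sz)) sz[1] else "none",
         sizes = sz, members = sort(classes[[i]]))
  })
  structure(
    list(pair_name = pair_name, classes = class_list,
         tolerance = tolerance, universe = sort(universe),
         iso_sizes = sizes),
    class = "BandPartition"
  )
}

#' @export
print.BandPartition <- function(x, ...) {
  cat(sprintf("BandPartition %s: %d classes over %d isoforms\n",
              x$pair_name, length(x$classes), length(x$universe)))
  for (cl in x$classes) {
    lab <- if (identical(cl$representative_size, "none")) "none" else
      paste(round(cl$sizes), collapse = "+")
    cat(sprintf("  %8s bp: %s\n", lab, paste(cl$members, collapse = ", ")))
  }
  invisible(x)
}

#' Members of each band class
#'
#' @param p A `BandPartition`.
#' @return List of character vectors (sorted members per class).
#' @export
partition_classes <- function(p) lapply(p$classes, function(cl) cl$members)

#' Number of band classes
#' @param p A `BandPartition`.
#' @export
n_classes <- function(p) length(p$classes)

#' Build a BandPartition directly from class member sets
#'
#' Mostly useful for tests and for representing partitions with no size
#' model (e.g. joint partitions).
#'
#' @param members List of character vectors, disjoint, covering the universe.
#' @param pair_name Label.
#' @param tolerance Recorded tolerance (informational).
#' @return A `BandPartition` without size information.
#' @export
as_partition <- function(members, pair_name = "manual", tolerance = NA) {
  universe <- sort(unlist(members, use.names = FALSE))
  if (anyDuplicated(universe)) stop("classes are not disjoint")
  class_list <- lapply(members, function(m)
    list(representative_size = NA_real_, sizes = numeric(), members = sort(m)))
  structure(
    list(pair_name = pair_name, classes = class_list, tolerance = tolerance,
         universe = universe, iso_sizes = NULL),
    class = "BandPartition"
  )
}

#' Common refinement of several band partitions
#'
#' Two isoforms share a joint class iff they share a class in every input
#' partition — the partition obtained by reading all primer pairs' gels
#' together.
#'
#' @param partitions List of `BandPartition`s over the same isoform universe.
#' @return A `BandPartition` named `"joint"` (no size model).
#' @export
joint_partition <- function(partitions) {
  stopifnot(length(partitions) >= 1L)
  universe <- partitions[[1]]$universe
  for (p in partitions)
    if (!identical(p$universe, universe)) stop("inconsistent universes")
  sig <- vapply(universe, function(iso) {
    paste(vapply(partitions, function(p) {
      which(vapply(partition_classes(p), function(m) iso %in% m, logical(1)))
    }, integer(1)), collapse = "|")
  }, character(1))
  groups <- split(universe, sig)
  # deterministic: order classes by their first member's position in the
  # first partition's class order, then lexicographically
  first_part_rank <- vapply(groups, function(g) {
    which(vapply(partition_classes(partitions[[1]]),
                 function(m) g[1] %in% m, logical(1)))
  }, integer(1))
  groups <- groups[order(first_part_rank,
                         vapply(groups, function(g) g[1], character(1)))]
  as_partition(unname(groups), pair_name = "joint")
}

#' Discrimination power of a band partition
#'
#' @param p A `BandPartition`.
#' @return List with `n_classes`, `singleton_fraction` (fraction of isoforms
#'   that are uniquely identified, i.e. sit in a singleton class) and
#'   `entropy` (Shannon partition entropy in bits).
#' @export
discrimination_power <- function(p) {
  sizes <- lengths(partition_classes(p))
  n <- sum(sizes)
  frac <- sizes / n
  list(
    n_classes = length(sizes),
    singleton_fraction = sum(sizes[sizes == 1L]) / n,
    entropy = -sum(frac * log2(frac))
  )
}

#' Select a minimal discriminating primer-pair panel
#'
#' Searches subsets of the candidate pairs for the panel whose joint
#' partition has the most band classes. With at most 12 candidates the
#' search is exhaustive over subsets of size `<= k_max` (preferring fewer
#' pairs, ties broken by candidate order); with more candidates a greedy
#' refinement is used (each step adds the pair maximizing joint class count,
#' ties broken by smaller pair index). Residual non-singleton joint classes
#' are flagged: `"gel-resolvable at high percentage"` when some chosen pair
#' separates the class members under the fine-gel tolerance, otherwise
#' `"requires sequencing"`.
#'
#' @param pairs List of primer pairs (`list(forward, reverse)` each).
#' @param isoforms Named list of isoforms.
#' @param k_max Maximum panel size.
#' @param tolerance Gel tolerance for the working partitions (see
#'   [partition_by_size()]).
#' @param method `"auto"` (exhaustive up to 12 candidates, greedy beyond),
#'   `"exhaustive"` or `"greedy"`.
#' @param ... Passed to [predict_amplicons()].
#' @return An object of class `PanelReport`.
#' @export
select_panel <- function(pairs, isoforms, k_max = 3L, tolerance = "standard",
                         method = c("auto", "exhaustive", "greedy"), ...) {
  sizes <- amplicon_sizes(pairs, isoforms, ...)
  select_panel_from_sizes(sizes, k_max, tolerance, method)
}

#' Select a panel from precomputed product sizes
#'
#' Same search as [select_panel()] but starting from a size table instead of
#' primers, which is convenient when sizes come from an external prediction
#' or measurement.
#'
#' @param sizes Named list (pair name -> named list isoform -> numeric size
#'   vector), as returned by [amplicon_sizes()].
#' @inheritParams select_panel
#' @return An object of class `PanelReport`.
#' @export
select_panel_from_sizes <- function(sizes, k_max = 3L, tolerance = "standard",
                                    method = c("auto", "exhaustive", "greedy")) {
  method <- match.arg(method)
  stopifnot(length(sizes) >= 1L, k_max >= 1L)
  if (all(vapply(sizes, function(s) all(lengths(s) == 0L), logical(1))))
    stop("panel infeasible: no candidate pair produces any amplicon")
  parts <- lapply(names(sizes), function(nm)
    partition_from_sizes(sizes[[nm]], nm, tolerance))
  names(parts) <- names(sizes)
  score <- function(idx) n_classes(joint_partition(parts[idx]))
  np <- length(parts)
  if (method == "auto") method <- if (np <= 12L) "exhaustive" else "greedy"
  if (method == "exhaustive") {
    # exhaustive, enumerated smallest-first and in candidate order, keeping
    # only strict improvements: ties resolve to fewer pairs / earlier pairs
    best <- NULL; best_score <- -1L
    for (k in seq_len(min(k_max, np))) {
      for (idx in utils::combn(np, k, simplify = FALSE)) {
        s <- score(idx)
        if (s > best_score) { best <- idx; best_score <- s }
      }
    }
    chosen <- best
  } else {
    chosen <- integer()
    repeat {
      if (length(chosen) >= k_max) break
      cand <- setdiff(seq_len(np), chosen)
      gains <- vapply(cand, function(i) score(c(chosen, i)), integer(1))
      cur <- if (length(chosen)) score(chosen) else 0L
      if (max(gains) <= cur && length(chosen)) break
      chosen <- c(chosen, cand[which.max(gains)])
    }
  }
  chosen_parts <- parts[chosen]
  joint <- joint_partition(chosen_parts)
  residual <- Filter(function(m) length(m) > 1L, partition_classes(joint))
  resolution <- vapply(residual, function(members) {
    for (p in chosen_parts) {
      sub <- p$iso_sizes[members]
      fine <- partition_from_sizes(sub, p$pair_name, "fine")
      if (n_classes(fine) > 1L) return("gel-resolvable at high percentage")
    }
    "requires sequencing"
  }, character(1))
  structure(
    list(pairs = names(parts)[chosen], per_pair = chosen_parts,
         joint = joint, residual = residual, resolution = resolution,
         all_partitions = parts),
    class = "PanelReport"
  )
}

#' @export
print.PanelReport <- function(x, ...) {
  cat("PanelReport:", paste(x$pairs, collapse = " + "), "\n")
  cat("  joint classes:", n_classes(x$joint), "\n")
  if (length(x$residual)) {
    for (i in seq_along(x$residual))
      cat("  ambiguous:", paste(x$residual[[i]], collapse = "/"),
          "->", x$resolution[i], "\n")
  } else cat("  fully discriminating\n")
  invisible(x)
}

#' Human-readable decision table for a panel
#'
#' @param panel A `PanelReport`.
#' @return List with `bands` (data.frame: pair, size, members — one row per
#'   gel band) and `residual` (data.frame: members, resolution).
#' @export
decision_report <- function(panel) {
  stopifnot(inherits(panel, "PanelReport"))
  rows <- list()
  for (p in panel$per_pair) {
    for (cl in p$classes) {
      rows[[length(rows) + 1L]] <- data.frame(
        pair = p$pair_name,
        size = if (identical(cl$representative_size, "none")) "none" else
          paste(round(cl$sizes), collapse = "+"),
        members = paste(cl$members, collapse = "/"),
        stringsAsFactors = FALSE)
    }
  }
  residual <- data.frame(
    members = vapply(panel$residual, paste, character(1), collapse = "/"),
    resolution = unname(panel$resolution),
    stringsAsFactors = FALSE)
  list(bands = do.call(rbind, rows), residual = residual)
}
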