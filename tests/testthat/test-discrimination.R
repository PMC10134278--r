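test_that("band partitions group isoforms by co-migrating product size", {
  fx <- postn_fx()
  p_f1r1 <- partition_by_size(fx$primers$F1, fx$primers$R1, fx$isoforms)
  expect_equal(n_classes(p_f1r1), 4L)
  # the four-band grouping, by membership
  expect_setequal(canon_classes(partition_classes(p_f1r1)),
                  c("Iso1,Iso8", "Iso10,Iso3,Iso5,Iso9",
                    "Iso11,Iso2,Iso4", "Iso6,Iso7"))

  p_f1r2 <- partition_by_size(fx$primers$F1, fx$primers$R2, fx$isoforms)
  expect_equal(n_classes(p_f1r2), 5L)
  # isoforms indistinguishable in the amplified interval form one class
  sub <- fx$isoforms[c("Iso5", "Iso10")]
  p_sub <- partition_by_size(fx$primers$F1, fx$primers$R2, sub)
  expect_equal(n_classes(p_sub), 1L)
  # isoforms a pair does not amplify sit in their own "none" class
  no16 <- list(fx$isoforms$Iso1, build_isoform(fx$exon_set, "no16", 16L))
  p_none <- partition_by_size(fx$primers$F1, fx$primers$R1, no16)
  expect_equal(n_classes(p_none), 2L)
  none_class <- p_none$classes[[n_classes(p_none)]]
  expect_identical(none_class$representative_size, "none")
  expect_equal(none_class$members, "no16")
})

test_that("joint partition is the coarsest common refinement", {
  # idempotence and the textbook refinement example
  p1 <- as_partition(list(c("A", "B"), "C"))
  p2 <- as_partition(list("A", c("B", "C")))
  expect_equal(canon_classes(partition_classes(joint_partition(list(p1, p1)))),
               canon_classes(partition_classes(p1)))
  expect_equal(canon_classes(partition_classes(joint_partition(list(p1, p2)))),
               c("A", "B", "C"))
  expect_error(joint_partition(list(p1, as_partition(list("A", "B")))),
               "inconsistent universes")

  # against the brute-force pairwise-intersection oracle
  set.seed(202)
  universe <- paste0("i", 1:8)
  for (rep in 1:100) {
    parts <- replicate(sample(2:4, 1L), random_partition(universe),
                       simplify = FALSE)
    joint <- joint_partition(parts)
    expect_equal(canon_classes(partition_classes(joint)),
                 canon_classes(oracle_joint(parts)))
    # refinement law
    expect_gte(n_classes(joint), max(vapply(parts, n_classes, integer(1))))
  }
})

test_that("class counts are monotone in tolerance and exact at tolerance 0", {
  set.seed(303)
  for (rep in 1:20) {
    sizes <- as.list(sample(100:400, 9L, replace = TRUE))
    names(sizes) <- paste0("i", 1:9)
    tols <- c(100, 50, 20, 10, 5, 1, 0)
    counts <- vapply(tols, function(t)
      n_classes(partition_from_sizes(sizes, tolerance = t)), integer(1))
    expect_true(all(diff(counts) >= 0L))
    expect_equal(counts[length(counts)],
                 length(unique(unlist(sizes))))
  }
})

test_that("discrimination metrics match their closed forms", {
  discrete <- as_partition(as.list(paste0("i", 1:11)))
  m <- discrimination_power(discrete)
  expect_equal(m$n_classes, 11L)
  expect_equal(m$singleton_fraction, 1)
  expect_equal(m$entropy, log2(11))

  single <- as_partition(list(paste0("i", 1:11)))
  expect_equal(discrimination_power(single)$entropy, 0)

  # the four-band class-size profile {2,4,3,2}, against a hand calculation
  fx <- postn_fx()
  p <- partition_by_size(fx$primers$F1, fx$primers$R1, fx$isoforms)
  expect_setequal(lengths(partition_classes(p)), c(2L, 4L, 3L, 2L))
  hand <- -sum(c(2, 4, 3, 2) / 11 * log2(c(2, 4, 3, 2) / 11))
  expect_equal(discrimination_power(p)$entropy, hand)
})

test_that("panel selection finds minimal panels; greedy agrees on small cases", {
  fx <- postn_fx()
  # a pair that is already discrete needs no companion: mini gene with one
  # cassette and two isoforms
  spec <- fixture_spec(c(60L, 40L, 30L, 60L), 3L,
                       isoform_defs = list(Full = integer(), Skip = 3L),
                       seed = 5L)
  g <- synth_gene(spec)
  panel1 <- select_panel(g$pairs, g$isoforms, k_max = 2L)
  expect_length(panel1$pairs, 1L)
  expect_equal(n_classes(panel1$joint), 2L)
  expect_length(panel1$residual, 0L)

  # exhaustive and greedy searches agree on random small candidate sets
  set.seed(404)
  for (rep in 1:25) {
    n_pairs <- sample(3:5, 1L)
    n_iso <- sample(5:8, 1L)
    sizes <- lapply(seq_len(n_pairs), function(i) {
      s <- lapply(seq_len(n_iso), function(j) {
        x <- sample(c(10L * sample(10:40, 1L), NA), 1L)
        if (is.na(x)) integer() else x
      })
      names(s) <- paste0("i", seq_len(n_iso))
      s
    })
    names(sizes) <- paste0("p", seq_len(n_pairs))
    exh <- select_panel_from_sizes(sizes, k_max = n_pairs, tolerance = 0,
                                   method = "exhaustive")
    gre <- select_panel_from_sizes(sizes, k_max = n_pairs, tolerance = 0,
                                   method = "greedy")
    expect_equal(n_classes(gre$joint), n_classes(exh$joint))
  }

  # no amplifiable pair at all is infeasible
  bad <- suppressWarnings(list(list(primer("fx", "AAAAAAAAAAAAAAAAAAAAA", "forward"),
                                    primer("rx", "AAAAAAAAAAAAAAAAAAAAA", "reverse"))))
  expect_error(select_panel(bad, fx$isoforms), "panel infeasible")
})

test_that("the three-pair screening panel leaves sequencing-only ambiguities", {
  fx <- postn_fx()
  panel <- select_panel(fx$pairs, fx$isoforms, k_max = 3L)
  expect_gt(length(panel$residual), 0L)
  residual_members <- unlist(panel$residual)
  # the exon-17-skipping isoforms of interest stay unresolved by size alone
  expect_true("Iso3" %in% residual_members)
  expect_true("Iso5" %in% residual_members)
  # equal-length cassettes cannot be separated by a finer gel
  expect_true(all(panel$resolution == "requires sequencing"))

  rep <- decision_report(panel)
  expect_true(all(c("pair", "size", "members") %in% names(rep$bands)))
  # Iso5 and Iso10 appear as one F1/R2 band
  f1r2 <- rep$bands[rep$bands$pair == "F1/R2", ]
  expect_true(any(vapply(strsplit(f1r2$members, "/"), function(m)
    setequal(intersect(m, c("Iso5", "Iso10")), c("Iso5", "Iso10")),
    logical(1))))
})
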