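test_that("the published siRNAs hit exactly the intended isoform sets", {
  fx <- postn_fx()
  tg <- postn_targets(fx)
  # the exon-21 siRNA discriminates Iso5 from Iso3 (only Iso5 retains exon 21)
  expect_equal(containing_isoforms(tg$siEx21, fx$isoforms[c("Iso3", "Iso5")]),
               "Iso5")
  # the constitutive 21-mer at reference positions 2397-2417 hits all 11
  expect_setequal(containing_isoforms(tg$siPOSTN, fx$isoforms),
                  names(fx$isoforms))
  # hit positions verify by substring equality
  hits <- locate_target(tg$siEx21, fx$isoforms)
  expect_true(all(vapply(seq_len(nrow(hits)), function(i)
    substr(fx$isoforms[[hits$isoform[i]]]$transcript,
           hits$start[i], hits$end[i]) == tg$siEx21$sequence, logical(1))))
  expect_error(target_region("empty", "", "dna"), "empty target")
})

test_that("the exon-21 epitope marks exactly the exon-21-retaining isoforms", {
  fx <- postn_fx()
  tg <- postn_targets(fx)
  expect_true(all(vapply(fx$isoforms, function(i) i$frame_preserving,
                         logical(1))))
  retaining <- names(Filter(function(i) !(21L %in% i$skipped), fx$isoforms))
  expect_setequal(containing_isoforms(tg$epitope, fx$isoforms,
                                      cds_start = fx$cds_start), retaining)
  # in particular the antibody separates Iso5 from Iso3
  expect_equal(containing_isoforms(tg$epitope, fx$isoforms[c("Iso3", "Iso5")]),
               "Iso5")
})

test_that("containment is monotone and ignores the RNA/DNA distinction", {
  fx <- postn_fx()
  set.seed(808)
  iso <- fx$isoforms$Iso5
  for (i in 1:20) {
    start <- sample.int(iso$length - 40L, 1L)
    short <- target_region("s", substr(iso$transcript, start, start + 20L))
    long <- target_region("l", substr(iso$transcript, start, start + 39L))
    hit_s <- containing_isoforms(short, fx$isoforms)
    hit_l <- containing_isoforms(long, fx$isoforms)
    expect_true(all(hit_l %in% hit_s))
  }
  dna <- target_region("d", "GAAGATGAAGAAATTAAAAGA", "dna")
  rna <- target_region("r", "GAAGAUGAAGAAAUUAAAAGA", "rna")
  expect_equal(containing_isoforms(dna, fx$isoforms),
               containing_isoforms(rna, fx$isoforms))
})

test_that("discriminating k-mers are exon-21-linked for Iso5 vs Iso3", {
  fx <- postn_fx()
  d <- design_discriminating_target("Iso5", fx$isoforms[c("Iso3", "Iso5")], 21L)
  expect_gt(nrow(d), 0L)
  # both isoforms skip exon 17, so the only Iso5-specific sequence is the
  # exon-21 region (and its junctions); every hit touches exon 21
  expect_true(all(vapply(strsplit(d$exons, ","), function(e) "21" %in% e,
                         logical(1))))
  # round trip: every reported k-mer is contained only in the target
  for (i in seq_len(nrow(d))) {
    hit <- containing_isoforms(target_region("k", d$sequence[i]),
                               fx$isoforms[c("Iso3", "Iso5")])
    expect_equal(hit, "Iso5")
  }
  # the published siEx21 21-mer is one of the reported candidates
  expect_true("GAAGATGAAGAAATTAAAAGA" %in% d$sequence)
})

test_that("skipping creates junction k-mers usable against retaining isoforms", {
  fx <- postn_fx()
  # Iso3 vs Iso4 differ only by exon 18: Iso3-specific k-mers must touch
  # exon 18 or the junctions it participates in
  d <- design_discriminating_target("Iso3", fx$isoforms[c("Iso3", "Iso4")], 21L)
  expect_gt(nrow(d), 0L)
  expect_true(all(vapply(strsplit(d$exons, ","), function(e) "18" %in% e,
                         logical(1))))
  # conversely the skipping isoform owns the novel junction: Iso4-specific
  # k-mers span the 16|19 junction absent from Iso3
  d4 <- design_discriminating_target("Iso4", fx$isoforms[c("Iso3", "Iso4")], 21L)
  expect_gt(nrow(d4), 0L)
  expect_true(all(d4$junction))
  expect_true(all(vapply(strsplit(d4$exons, ","), function(e)
    all(c("16", "19") %in% e), logical(1))))

  # a transcript with no unique k-mer yields an empty result
  twin <- fx$isoforms$Iso5; twin$name <- "twin"
  none <- design_discriminating_target("twin",
                                       list(fx$isoforms$Iso5, twin), 21L)
  expect_equal(nrow(none), 0L)
  # alone in the expressed set, every k-mer qualifies
  alone <- design_discriminating_target("Iso1", fx$isoforms["Iso1"], 21L)
  expect_equal(nrow(alone), fx$isoforms$Iso1$length - 20L)
  expect_error(design_discriminating_target("Iso1", fx$isoforms["Iso1"], 10L),
               "at least 15")
})

test_that("region presence classifies retained, partial and lost intervals", {
  fx <- postn_fx()
  # inside exon 1: retained everywhere
  r1 <- region_presence(10L, 30L, fx$exon_set, fx$isoforms)
  expect_true(all(r1$status == "retained"))

  # inside exon 17: lost exactly in the exon-17 skippers
  cm <- coord_map(fx$isoforms$Iso1)
  e17 <- transcript_position(cm, 17L, 1L)
  r17 <- region_presence(e17, e17 + 20L, fx$exon_set, fx$isoforms)
  skip17 <- vapply(fx$isoforms, function(i) 17L %in% i$skipped, logical(1))
  expect_equal(r17$status == "lost", unname(skip17))

  # straddling the 17/18 boundary: partial in Iso5 (only exon 17 skipped),
  # lost in Iso2 (both skipped), retained in Iso1
  e18 <- transcript_position(cm, 18L, 1L)
  rs <- region_presence(e18 - 10L, e18 + 10L, fx$exon_set, fx$isoforms)
  expect_equal(as.character(rs$status[rs$isoform == "Iso5"]), "partial")
  expect_equal(as.character(rs$status[rs$isoform == "Iso2"]), "lost")
  expect_equal(as.character(rs$status[rs$isoform == "Iso1"]), "retained")
  expect_error(region_presence(1L, 10^6, fx$exon_set, fx$isoforms),
               "out of bounds")
})
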