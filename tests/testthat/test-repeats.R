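test_that("a planted target-site duplication is reported", {
  set.seed(91)
  word <- "ACGTT"
  lf <- paste0("CCCCCCCCCC", word)
  rf <- paste0(word, "CCCCCCCCCC")
  ins <- "GTAAGTTTTTTTTTTTTTTTTTTTTAG"
  reps <- findDirectRepeats(lf, ins, rf, minLen = 3, maxLen = 8)
  arms <- vapply(reps, function(r) r@arm1Seq, "")
  expect_true(word %in% arms)
  hit <- reps[[which(arms == word)[1]]]
  expect_identical(hit@armLength, 5L)
  expect_identical(hit@mismatches, 0L)
  expect_error(findDirectRepeats(lf, ins, rf, minLen = 5, maxLen = 3),
               "minLen")
})

test_that("junctions without shared words yield no direct repeats", {
  reps <- findDirectRepeats(strrep("A", 20), strrep("C", 30),
                            strrep("G", 20), minLen = 3, maxLen = 8)
  expect_length(reps, 0L)
})

test_that("direct repeats match the exhaustive oracle on random junctions", {
  set.seed(92)
  for (i in 1:60) {
    lf <- randSeq(sample(8:30, 1))
    ins <- randSeq(sample(10:60, 1))
    rf <- randSeq(sample(8:30, 1))
    got <- findDirectRepeats(lf, ins, rf, minLen = 3, maxLen = 8)
    want <- bruteDirectRepeats(lf, ins, rf, 3L, 8L)
    gotKeys <- sort(vapply(got, function(r)
      paste(r@arm1Start, r@arm2Start, r@armLength), ""))
    wantKeys <- sort(vapply(want, function(v) paste(v[1], v[2], v[3]), ""))
    expect_identical(gotKeys, wantKeys)
  }
})

test_that("a planted inverted repeat across the junction is reported", {
  set.seed(93)
  arm <- "GCATTGCC"
  exon <- paste0(randSeq(20), arm)
  intron <- paste0("GTAAGT", randSeq(60), rcOracle(arm), "TTTAG")
  reps <- findInvertedRepeats(exon, intron, minLen = 8, maxLen = 12)
  expect_gte(length(reps), 1L)
  found <- any(vapply(reps, function(r)
    grepl(arm, r@arm1Seq, fixed = TRUE) ||
      grepl(r@arm1Seq, arm, fixed = TRUE), logical(1)))
  expect_true(found)
  ## poly-A exon against poly-A intron: reverse complement is poly-T
  expect_length(findInvertedRepeats(strrep("A", 30), strrep("A", 30)), 0L)
  expect_error(findInvertedRepeats(exon, intron, minLen = 9, maxLen = 8),
               "minLen")
})

test_that("inverted repeats match the exhaustive oracle on random inputs", {
  set.seed(94)
  for (i in 1:40) {
    exon <- randSeq(sample(20:60, 1))
    intron <- randSeq(sample(20:80, 1))
    ## plant an arm in half the cases so hits actually occur
    if (i %% 2 == 0) {
      arm <- randSeq(sample(8:12, 1))
      exon <- paste0(substr(exon, 1, nchar(exon) - nchar(arm)), arm)
      intron <- paste0(substr(intron, 1, nchar(intron) - nchar(arm) - 4),
                       rcOracle(arm),
                       substr(intron, nchar(intron) - 3, nchar(intron)))
    }
    got <- findInvertedRepeats(exon, intron)
    want <- bruteInvertedRepeats(exon, intron, 8L, 12L)
    gotKeys <- sort(vapply(got, function(r)
      paste(r@arm1Start, r@arm2Start, r@armLength), ""))
    wantKeys <- sort(vapply(want, function(v) paste(v[1], v[2], v[3]), ""))
    expect_identical(gotKeys, wantKeys)
  }
})

test_that("no reported repeat is extendable into another reportable pair", {
  set.seed(95)
  for (i in 1:20) {
    exon <- randSeq(40)
    arm <- randSeq(10)
    exon <- paste0(substr(exon, 1, 30), arm)
    intron <- paste0(randSeq(50), rcOracle(arm), randSeq(4))
    reps <- findInvertedRepeats(exon, intron)
    for (r in reps) {
      ## extending one nt on either side must break the pairing or a bound
      s1 <- r@arm1Start; s2 <- r@arm2Start; L <- r@armLength
      extendable <- function(s1e, s2e, Le) {
        Le <= 12L && s1e >= nchar(exon) - 20L && s2e >= nchar(intron) - 20L &&
          s1e >= 0L && s2e >= 0L && s1e + Le <= nchar(exon) &&
          s2e + Le <= nchar(intron) &&
          hammingOracle(substr(intron, s2e + 1, s2e + Le),
                        rcOracle(substr(exon, s1e + 1, s1e + Le))) == 0L
      }
      expect_false(extendable(s1 - 1L, s2, L + 1L))
      expect_false(extendable(s1, s2 - 1L, L + 1L))
    }
  }
})

test_that("inverted-repeat pairs swap one-to-one with swapped inputs", {
  ## padding chosen so the planted pair cannot extend in either direction
  arm <- "ACGTACGTA"
  x <- paste0(strrep("C", 25), arm)
  y <- paste0(strrep("C", 40), rcOracle(arm), "TTTT")
  fwd <- findInvertedRepeats(x, y)
  rev <- findInvertedRepeats(y, x)
  expect_length(fwd, 1L)
  expect_length(rev, 1L)
  expect_identical(fwd[[1]]@arm1Seq, rev[[1]]@arm2Seq)
  expect_identical(fwd[[1]]@arm2Seq, rev[[1]]@arm1Seq)
})

test_that("event junctions gain the planted repeat evidence", {
  cfg <- tinyConfig(seed = 97, exonLengthRange = c(40L, 60L))
  anc <- buildAncestralCluster(cfg)
  exc <- applyExcisionInsertion(buildAncestralCluster(cfg), "snR51",
                                config = cfg)
  detail <- jsonlite::fromJSON(exc$eventRecord$detail)
  ev <- EvolutionEvent("excision_insertion", "forced", "snR51",
                       evidence = list(locus = list(
                         species = "S", start = detail$target_interval[1],
                         end = detail$target_interval[2])))
  ev <- annotateEventJunctions(ev, c(S = unname(exc$genome[[1]])))
  reps <- ev@evidence$repeats
  expect_true(any(vapply(reps, function(r)
    r@kind == "direct" && r@armLength == detail$repeat_length, logical(1))))

  gain <- applyIntronGain(buildAncestralCluster(cfg), "exon",
                          exonIndex = 2L, config = cfg)
  gd <- Filter(function(x) is.na(snornaFamily(x)), gain$introns)[[1]]
  ev2 <- EvolutionEvent("intron_gain", "forced", "gained1",
                        evidence = list(locus = list(
                          species = "S", start = featureStart(gd),
                          end = featureEnd(gd))))
  ev2 <- annotateEventJunctions(ev2, c(S = unname(gain$genome[[1]])))
  reps2 <- ev2@evidence$repeats
  expect_true(any(vapply(reps2, function(r)
    r@kind == "inverted" && r@armLength >= 8L && r@armLength <= 12L,
    logical(1))))

  ## a deletion event resolves no junction; evidence marked unavailable
  ev3 <- annotateEventJunctions(
    EvolutionEvent("deletion_loss", "forced", "snR51"),
    c(S = unname(anc$genome[[1]])))
  expect_length(ev3@evidence$repeats, 0L)
  expect_true(is.na(ev3@evidence$repeats_available))
})
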