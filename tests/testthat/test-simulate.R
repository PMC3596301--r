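test_that("ancestral cluster has the exon/intron/snoRNA layout", {
  anc <- buildAncestralCluster(tinyConfig(seed = 5))
  el <- elements(anc$architecture)
  expect_identical(el$kind,
                   c("exon", "intron", "exon", "intron", "exon", "intron",
                     "exon"))
  expect_identical(el$family[el$kind == "intron"],
                   c("snR41", "snR70", "snR51"))
  g <- anc$genome[[1]]
  for (ia in anc$introns) {
    expect_identical(substr(g, featureStart(ia) + 1, featureStart(ia) + 2),
                     "GT")
    expect_identical(substr(g, featureEnd(ia) - 1, featureEnd(ia)), "AG")
  }
  for (sn in anc$snornas) {
    expect_identical(substr(g, sn@boxCStart + 1, sn@boxCStart + 6), "TGATGA")
    expect_identical(substr(g, sn@boxDStart + 1, sn@boxDStart + 4), "CTGA")
    guide <- substr(g, sn@guideStart + 1, sn@guideEnd)
    target <- substr(anc$rRNA, sn@guideRRNAOffset + 1,
                     sn@guideRRNAOffset + nchar(guide))
    expect_identical(guide, rcOracle(target))
  }
})

test_that("identical configs give byte-identical simulations", {
  cfg <- simulationConfig(seed = 77, tree = "((A,B),(C,D));",
                          nSnornaFamilies = 3L, flankLength = 1000L)
  s1 <- simulateEvolution(cfg)
  s2 <- simulateEvolution(cfg)
  expect_identical(s1@genomes, s2@genomes)
  expect_identical(s1@eventLog, s2@eventLog)
  expect_identical(s1@references, s2@references)
})

test_that("zero rates and zero mutation reproduce the ancestor everywhere", {
  cfg <- tinyConfig(seed = 2)
  anc <- buildAncestralCluster(cfg)
  sim <- evolveAlongTree(anc, cfg)
  expect_identical(nrow(sim@eventLog), 0L)
  for (sp in names(sim@genomes))
    expect_identical(unname(sim@genomes[[sp]]), unname(anc$genome[[1]]))
})

test_that("forced deletion loss removes the intron but leaves a 5' stub", {
  cfg <- tinyConfig(seed = 3)
  anc <- buildAncestralCluster(cfg)
  before <- anc$genome[[1]]
  intr <- anc$introns[[2]]
  intronSeq <- substr(before, featureStart(intr) + 1, featureEnd(intr))
  res <- applyDeletionLoss(anc, "snR70")
  expect_false(any(vapply(res$snornas, snornaFamily, "") == "snR70"))
  rec <- res$eventRecord
  expect_identical(rec$kind, "deletion_loss")
  stub <- jsonlite::fromJSON(rec$detail)$stub
  expect_gte(nchar(stub), 5L)
  expect_lte(nchar(stub), 25L)
  expect_identical(stub, substr(intronSeq, 1, nchar(stub)))
  expect_true(grepl(stub, res$genome[[1]], fixed = TRUE))
})

test_that("forced excision-insertion relocates the complete intron unit", {
  cfg <- tinyConfig(seed = 4)
  anc <- buildAncestralCluster(cfg)
  before <- anc$genome[[1]]
  intr <- anc$introns[[3]]
  unit <- substr(before, featureStart(intr) + 1, featureEnd(intr))
  res <- applyExcisionInsertion(anc, "snR51")
  detail <- jsonlite::fromJSON(res$eventRecord$detail)
  after <- res$genome[[1]]
  ## exactly one copy, at the logged target, flanked by the planted repeat
  expect_identical(lengths(regmatches(after, gregexpr(unit, after,
                                                      fixed = TRUE))), 1L)
  tgt <- detail$target_interval
  expect_identical(substr(after, tgt[1] + 1, tgt[2]), unit)
  w <- detail$repeat_length
  expect_gte(w, 3L); expect_lte(w, 8L)
  expect_identical(substr(after, tgt[1] - w + 1, tgt[1]), detail$repeat_seq)
  expect_identical(substr(after, tgt[2] + 1, tgt[2] + w), detail$repeat_seq)
  ## the donor site no longer holds the family, the copy is >= 500 nt away
  el <- elements(res$architecture)
  expect_false("snR51" %in% el$family)
  expect_true(tgt[1] >= max(el$end) + 500 || tgt[2] <= min(el$start) - 500)
})

test_that("forced recombination yields a one-boxC one-boxD chimera", {
  cfg <- tinyConfig(seed = 6)
  anc <- buildAncestralCluster(cfg)
  refs <- anc$references
  res <- applyRecombination(anc, "snR41", "snR70")
  chim <- NULL
  for (sn in res$snornas) if (length(sn@chimeric)) chim <- sn
  expect_false(is.null(chim))
  expect_identical(chim@chimeric$family5, "snR41")
  expect_identical(chim@chimeric$family3, "snR70")
  seq <- substr(res$genome[[1]], featureStart(chim) + 1, featureEnd(chim))
  ## exactly one box C and (at mutation zero) a 5' part from snR41 and a
  ## 3' part from snR70 split at the logged breakpoint
  bp <- chim@chimeric$breakpoint
  expect_identical(substr(seq, 1, bp), substr(refs[["snR41"]], 1, bp))
  tail3 <- nchar(seq) - bp
  expect_identical(substr(seq, bp + 1, nchar(seq)),
                   substr(refs[["snR70"]],
                          nchar(refs[["snR70"]]) - tail3 + 1,
                          nchar(refs[["snR70"]])))
  expect_identical(
    lengths(regmatches(seq, gregexpr("TGATGA", seq, fixed = TRUE))), 1L)
  ## both parent families are gone from the cluster as separate introns
  el <- elements(res$architecture)
  expect_false(any(c("snR41", "snR70") %in% el$family))
  expect_error(applyRecombination(anc, "snR41", "snR41"), "distinct")
})

test_that("forced de-intronization degrades the signals in place", {
  cfg <- tinyConfig(seed = 8)
  anc <- buildAncestralCluster(cfg)
  res <- applyDeintronization(anc, "snR70")
  ## the snoRNA survives in sequence but no intron hosts it
  expect_true("snR70" %in% vapply(res$snornas, snornaFamily, ""))
  expect_false("snR70" %in% vapply(res$introns, snornaFamily, ""))
  sn <- Filter(function(x) snornaFamily(x) == "snR70", res$snornas)[[1]]
  others <- Filter(function(x) snornaFamily(x) != "snR70", res$snornas)
  expect_null(delineateIntron(sn, res$genome[[1]],
                              searchFrom = featureEnd(others[[1]]),
                              searchTo = featureStart(others[[2]])))
})

test_that("forced exon loss juxtaposes the neighbour introns", {
  cfg <- tinyConfig(seed = 9)
  anc <- buildAncestralCluster(cfg)
  res <- applyExonLoss(anc, 1L)
  el <- elements(res$architecture)
  kinds <- el$kind
  expect_true(any(kinds[-length(kinds)] == "intron" &
                    kinds[-1] == "intron"))
  runs <- detectComplexIntrons(res$architecture)
  expect_length(runs, 1L)
  expect_identical(runs[[1]]$intronIndices, 1:2)
})

test_that("forced intron gain plants an inverted repeat at the junction", {
  cfg <- tinyConfig(seed = 10, exonLengthRange = c(40L, 60L))
  anc <- buildAncestralCluster(cfg)
  res <- applyIntronGain(anc, "exon", exonIndex = 2L)
  detail <- jsonlite::fromJSON(res$eventRecord$detail)
  expect_gte(detail$arm_length, 8L)
  expect_lte(detail$arm_length, 12L)
  gained <- Filter(function(x) is.na(snornaFamily(x)), res$introns)[[1]]
  g <- res$genome[[1]]
  intronSeq <- substr(g, featureStart(gained) + 1, featureEnd(gained))
  expect_identical(substr(intronSeq, 1, 6), "GTAAGT")
  ## the reverse complement of the exon-side arm sits in the intron's last
  ## 20 nt
  last20 <- substr(intronSeq, nchar(intronSeq) - 19, nchar(intronSeq))
  expect_true(grepl(rcOracle(detail$arm), last20, fixed = TRUE))
})

test_that("intron gain into a snoRNA sits between guide and box D", {
  cfg <- tinyConfig(seed = 12)
  anc <- buildAncestralCluster(cfg)
  res <- applyIntronGain(anc, target = "snR70")
  sn <- Filter(function(x) snornaFamily(x) == "snR70", res$snornas)[[1]]
  expect_length(sn@embeddedIntron, 2L)
  expect_identical(sn@embeddedIntron$start, sn@guideEnd)
  expect_identical(sn@embeddedIntron$end, sn@boxDStart)
  emb <- substr(res$genome[[1]], sn@embeddedIntron$start + 1,
                sn@embeddedIntron$end)
  expect_identical(substr(emb, 1, 2), "GT")
  expect_identical(substr(emb, nchar(emb) - 1, nchar(emb)), "AG")
})

test_that("single-branch architecture differences match the event log", {
  ## brute-force oracle at tiny n: on a two-leaf star with one eventful
  ## branch, each logged intron-level event must correspond to exactly one
  ## family-level difference between leaf and ancestor
  cfg <- simulationConfig(seed = 21, tree = "(X,Y);", nSnornaFamilies = 7L,
                          pointMutationRate = 0, pIntronGain = 0,
                          pExonLoss = 0, pRecombination = 0,
                          pDeintronization = 0.3, pDeletionLoss = 0.3,
                          pExcisionInsertion = 0.3)
  anc <- buildAncestralCluster(cfg)
  sim <- evolveAlongTree(anc, cfg)
  for (leaf in c("X", "Y")) {
    ev <- sim@eventLog[sim@eventLog$branch == leaf, ]
    ancFams <- vapply(anc$introns, snornaFamily, "")
    el <- elements(sim@architectures[[leaf]])
    leafFams <- el$family[el$kind == "intron" & !is.na(el$family)]
    lost <- setdiff(ancFams, leafFams)
    expect_setequal(lost, ev$subject)
  }
})

test_that("snoRNA copy number is conserved except by deletion/recombination", {
  sim <- simulateEvolution(simulationConfig(seed = 31))
  for (sp in names(sim@genomes)) {
    log <- sim@eventLog
    ## events on this leaf's root path
    onPath <- function(branch) {
      below <- if (branch %in% sim@tree$tip.label) branch
        else snoEvol:::leavesUnder(
          sim@tree, length(sim@tree$tip.label) +
            match(branch, sim@tree$node.label))
      sp %in% below
    }
    consumed <- character(0)
    for (r in seq_len(nrow(log))) {
      if (!onPath(log$branch[r])) next
      if (log$kind[r] == "deletion_loss") consumed <- c(consumed, log$subject[r])
      if (log$kind[r] == "recombination")
        consumed <- c(consumed, strsplit(log$subject[r], "|",
                                         fixed = TRUE)[[1]])
    }
    fams <- vapply(sim@annotations[[sp]]$snornas, snornaFamily, "")
    for (f in sim@config@familyNames) {
      expected <- if (f %in% consumed) 0L else 1L
      expect_identical(sum(fams == f), expected,
                       label = paste(sp, f, "copy number"))
    }
  }
})

test_that("every surviving planted intron keeps GT..AG ends", {
  sim <- simulateEvolution(simulationConfig(seed = 51))
  for (sp in names(sim@genomes)) {
    g <- sim@genomes[[sp]]
    for (ia in sim@annotations[[sp]]$introns) {
      expect_identical(substr(g, featureStart(ia) + 1,
                              featureStart(ia) + 2), "GT")
      expect_identical(substr(g, featureEnd(ia) - 1, featureEnd(ia)), "AG")
    }
  }
})

test_that("stepwise transcripts remove only 5' prefixes", {
  anc <- buildAncestralCluster(tinyConfig(seed = 13))
  tx <- simulateTranscripts(anc$genome, anc$architecture, "stepwise",
                            n = 60, seed = 2)
  sets <- strsplit(tx$truth$removed, ",")
  for (s in sets) {
    idx <- as.integer(s[s != ""])
    expect_true(length(idx) == 0 || identical(idx, seq_len(max(idx))))
  }
  ## never a non-prefix set such as {2} or {2,3}
  expect_false(any(tx$truth$removed %in% c("2", "3", "2,3")))
})

test_that("violation-mode batches always contain a stepwise breach", {
  anc <- buildAncestralCluster(tinyConfig(seed = 14))
  for (s in 1:5) {
    tx <- simulateTranscripts(anc$genome, anc$architecture, "violation",
                              n = 10, seed = s)
    sets <- lapply(strsplit(tx$truth$removed, ","), function(x)
      as.integer(x[x != ""]))
    isPrefix <- vapply(sets, function(idx)
      length(idx) == 0 || identical(idx, seq_len(max(idx))), logical(1))
    expect_true(any(!isPrefix))
  }
  expect_error(simulateTranscripts(anc$genome, anc$architecture,
                                   "stepwise", n = 0), "positive")
})

test_that("infeasible intron ranges are rejected at config time", {
  expect_error(simulationConfig(intronLengthRange = c(40L, 60L)),
               "cannot fit")
})
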