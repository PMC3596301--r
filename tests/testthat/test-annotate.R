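test_that("splice signals are found at planted consensus positions", {
  seq <- paste0(randSeq(10), "GTAAGT", randSeq(40), "TACTAAC", randSeq(20),
                "AG", randSeq(10))
  sig <- findSpliceSignals(seq)
  expect_true(10L %in% sig$donors$pos)
  expect_identical(sig$donors$score[sig$donors$pos == 10L], 6L)
  expect_true(56L %in% sig$branches$pos)
  expect_identical(sig$branches$score[sig$branches$pos == 56L], 7L)
  expect_true(83L %in% sig$acceptors$pos)
  sigGC <- findSpliceSignals(strrep("CA", 30))
  expect_identical(nrow(sigGC$donors), 0L)
})

test_that("splice signals match the exhaustive matcher on random regions", {
  set.seed(202)
  for (i in 1:20) {
    seq <- randSeq(300)
    got <- findSpliceSignals(seq)
    want <- bruteSignals(seq)
    expect_identical(got$donors$pos, as.integer(want$donors[, 1]))
    expect_identical(got$donors$score, as.integer(want$donors[, 2]))
    expect_identical(got$acceptors$pos, want$acceptors)
    if (is.null(want$branches)) expect_identical(nrow(got$branches), 0L)
    else expect_identical(got$branches$pos, as.integer(want$branches[, 1]))
  }
})

test_that("planted introns are recovered with exact boundaries", {
  anc <- buildAncestralCluster(tinyConfig(seed = 41))
  g <- anc$genome[[1]]
  for (i in seq_along(anc$snornas)) {
    got <- delineateIntron(anc$snornas[[i]], g)
    want <- anc$introns[[i]]
    expect_identical(featureStart(got), featureStart(want))
    expect_identical(featureEnd(got), featureEnd(want))
    expect_identical(got@branchStart, want@branchStart)
  }
  expect_error(
    delineateIntron(SnoRNAAnnotation("r", 10L, 100000L, boxCStart = 12L,
                                     boxCSeq = "TGATGA", boxDStart = 99990L,
                                     boxDSeq = "CTGA"), g),
    "bounds")
})

test_that("intronic/exonic labels are perfect at 2% mutation with protection", {
  hits <- 0L; total <- 0L
  for (s in 1:6) {
    cfg <- nullConfig(seed = 300 + s, pointMutationRate = 0.02,
                      tree = "((A,B),(C,D));")
    sim <- simulateEvolution(cfg)
    for (sp in names(sim@genomes)) {
      an <- annotateGenome(sim@genomes[[sp]],
                           paste0(sp, "_cluster_region"),
                           sim@references, sim@rRNA)
      el <- elements(an$architecture)
      total <- total + length(sim@config@familyNames)
      hits <- hits +
        sum(sim@config@familyNames %in% el$family[el$kind == "intron"])
      expect_length(an$exonicFamilies, 0L)
    }
  }
  expect_identical(hits, total)
})

test_that("architectures assemble with and without intervening exons", {
  g <- randSeq(400)
  mkIntron <- function(s, e, fam)
    IntronAnnotation("r", s, e, donorSeq = "GTAAGT", acceptorSeq = "AG",
                     snornaFamily = fam)
  sep <- list(mkIntron(50L, 120L, "f1"), mkIntron(150L, 230L, "f2"),
              mkIntron(260L, 330L, "f3"))
  arch <- assembleArchitecture(g, list(), sep)
  expect_identical(elements(arch)$kind,
                   c("exon", "intron", "exon", "intron", "exon", "intron",
                     "exon"))
  ## abutting introns: no exon element between them
  abut <- list(mkIntron(50L, 120L, "f1"), mkIntron(120L, 200L, "f2"))
  arch2 <- assembleArchitecture(g, list(), abut)
  expect_identical(elements(arch2)$kind,
                   c("exon", "intron", "intron", "exon"))
  ## partially overlapping introns are a hard conflict
  expect_error(assembleArchitecture(g, list(),
                                    list(mkIntron(50L, 120L, "f1"),
                                         mkIntron(100L, 200L, "f2"))),
               "conflict")
})

test_that("architecture elements tile the cluster span contiguously", {
  sim <- simulateEvolution(tinyConfig(seed = 47))
  for (sp in names(sim@genomes)) {
    el <- elements(sim@architectures[[sp]])
    expect_identical(el$start[-1], el$end[-nrow(el)])
    ## concatenating element sequences reproduces the span sequence
    g <- sim@genomes[[sp]]
    pieces <- vapply(seq_len(nrow(el)), function(i)
      substr(g, el$start[i] + 1, el$end[i]), "")
    expect_identical(paste(pieces, collapse = ""),
                     substr(g, min(el$start) + 1, max(el$end)))
  }
})

test_that("complex intron runs match an independent linear scan", {
  mk <- function(kinds) {
    pos <- 0L
    rows <- lapply(kinds, function(k) {
      w <- if (k == "exon") 20L else 60L
      r <- data.frame(kind = k, start = pos, end = pos + w,
                      family = NA_character_)
      pos <<- pos + w
      r
    })
    ClusterArchitecture("c", "r", do.call(rbind, rows))
  }
  runs3 <- detectComplexIntrons(mk(c("exon", "intron", "intron", "intron",
                                     "exon")))
  expect_length(runs3, 1L)
  expect_identical(runs3[[1]]$intronIndices, 1:3)
  expect_length(detectComplexIntrons(mk(c("exon", "intron", "exon",
                                          "intron", "exon"))), 0L)
  set.seed(404)
  for (i in 1:25) {
    kinds <- sample(c("exon", "intron"), sample(3:12, 1), replace = TRUE)
    got <- detectComplexIntrons(mk(kinds))
    want <- bruteComplexRuns(kinds)
    expect_length(got, length(want))
    for (j in seq_along(want))
      expect_identical(got[[j]]$intronIndices, want[[j]])
  }
})

test_that("exact-signal snoRNA-free introns are detected inside exons", {
  set.seed(71)
  left <- randSeq(30)
  intron <- paste0("GTAAGT", randSeq(60), "TACTAAC",
                   gsub("AG", "CC", randSeq(20)), "AG")
  right <- randSeq(30)
  region <- paste0(left, intron, right)
  hits <- detectPlainIntrons(region, c(0L, nchar(region)), "r")
  expect_length(hits, 1L)
  expect_identical(featureStart(hits[[1]]), 30L)
  expect_identical(featureEnd(hits[[1]]), 30L + nchar(intron))
})
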