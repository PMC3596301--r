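test_that("box motif pairs are found at planted positions", {
  seq <- paste0(strrep("A", 10), "TGATGA", strrep("A", 70), "CTGA",
                strrep("A", 10))
  hits <- scanBoxMotifs(seq, maxMismatchC = 0, maxMismatchD = 0)
  expect_identical(nrow(hits), 1L)
  expect_identical(hits$boxCStart, 10L)
  expect_identical(hits$boxDStart, 86L)
  expect_identical(nrow(scanBoxMotifs(strrep("A", 200))), 0L)
})

test_that("box scan matches the exhaustive oracle on random sequences", {
  set.seed(101)
  for (i in 1:15) {
    seq <- randSeq(500)
    for (mm in list(c(0L, 0L), c(1L, 0L))) {
      got <- scanBoxMotifs(seq, mm[1], mm[2])
      want <- bruteBoxScan(seq, mm[1], mm[2])
      rownames(got) <- rownames(want) <- NULL
      expect_identical(got, want)
    }
  }
})

test_that("box scan is translation-equivariant", {
  set.seed(55)
  seq <- paste0(randSeq(40), "TGATGA", randSeq(80), "CTGA", randSeq(40))
  base <- scanBoxMotifs(seq)
  for (k in c(1L, 17L, 63L)) {
    shifted <- scanBoxMotifs(paste0(randSeq(k), seq))
    keep <- shifted[shifted$boxCStart >= k, , drop = FALSE]
    expect_identical(keep$boxCStart - k, base$boxCStart)
    expect_identical(keep$boxDStart - k, base$boxDStart)
  }
})

test_that("guide scoring finds a planted reverse-complement window", {
  set.seed(9)
  rRNA <- randSeq(300)
  target <- substr(rRNA, 101, 112)
  cand <- paste0(randSeq(20), rcOracle(target), randSeq(20))
  hit <- scoreGuide(cand, rRNA, minLength = 10, maxMismatch = 0)
  expect_identical(hit$length, 12L)
  expect_identical(hit$rRNAOffset, 100L)
  expect_identical(hit$candidateOffset, 20L)
  expect_null(scoreGuide(strrep("A", 40), strrep("C", 200), minLength = 10))
})

test_that("guide scoring agrees with exhaustive search", {
  skip_if_not_installed("S4Vectors")
  set.seed(19)
  for (i in 1:12) {
    cand <- randSeq(60)
    rRNA <- randSeq(400)
    ## plant a hit in half of the cases
    if (i %% 2 == 0) {
      off <- sample(1:380, 1)
      cand <- paste0(substr(cand, 1, 25),
                     rcOracle(substr(rRNA, off, off + 11)),
                     substr(cand, 38, 60))
    }
    got <- scoreGuide(cand, rRNA, minLength = 10, maxMismatch = 0)
    want <- bruteGuideExact(cand, rRNA, minLength = 10)
    expect_identical(got, want)
  }
  ## mismatch-tolerant path against the full triple-loop oracle (tiny n)
  for (i in 1:6) {
    cand <- randSeq(30)
    rRNA <- randSeq(80)
    got <- scoreGuide(cand, rRNA, minLength = 8, maxMismatch = 1)
    want <- bruteGuideMM(cand, rRNA, minLength = 8, maxMismatch = 1)
    if (is.null(want)) expect_null(got)
    else {
      expect_identical(got$length, want$length)
      expect_identical(got$mismatches, want$mismatches)
      expect_identical(got$candidateOffset, want$candidateOffset)
    }
  }
})

test_that("family assignment recovers mutated references", {
  set.seed(77)
  refs <- setNames(vapply(1:5, function(i) randSeq(85), ""),
                   paste0("fam", 1:5))
  exact <- assignFamily(refs[["fam3"]], refs)
  expect_identical(exact$family, "fam3")
  expect_identical(exact$identity, 1)
  expect_identical(assignFamily(randSeq(85), refs, minIdentity = 0.7)$family,
                   "novel")
  ## 20 mutated copies at 10% substitution return to their source family
  for (i in 1:20) {
    src <- sample(names(refs), 1)
    v <- strsplit(refs[[src]], "")[[1]]
    pos <- sample(length(v), round(0.1 * length(v)))
    for (p in pos) v[p] <- sample(setdiff(c("A", "C", "G", "T"), v[p]), 1)
    got <- assignFamily(paste(v, collapse = ""), refs)
    expect_identical(got$family, src)
  }
})

test_that("chimera detection recovers constructed fusions", {
  set.seed(33)
  refs <- setNames(vapply(1:4, function(i) randSeq(90), ""),
                   c("snR78", "snR77", "snR73", "snR72"))
  fusion <- paste0(substr(refs[["snR78"]], 1, 45),
                   substr(refs[["snR72"]], 46, 90))
  ch <- detectChimera(fusion, refs)
  expect_identical(ch$family5, "snR78")
  expect_identical(ch$family3, "snR72")
  expect_lte(abs(ch$breakpoint - 45L), 2L)
  expect_null(detectChimera(refs[["snR78"]], refs))
})

test_that("chimera breakpoints survive 5% mutation for >= 9 of 10 fusions", {
  set.seed(44)
  refs <- setNames(vapply(1:5, function(i) randSeq(90), ""),
                   paste0("snF", 1:5))
  ok <- 0L
  for (i in 1:10) {
    pair <- sample(names(refs), 2)
    bp <- sample(35:55, 1)
    fusion <- paste0(substr(refs[[pair[1]]], 1, bp),
                     substr(refs[[pair[2]]], bp + 1, 90))
    v <- strsplit(fusion, "")[[1]]
    pos <- which(runif(length(v)) < 0.05)
    for (p in pos) v[p] <- sample(setdiff(c("A", "C", "G", "T"), v[p]), 1)
    ch <- detectChimera(paste(v, collapse = ""), refs)
    if (!is.null(ch) && identical(ch$family5, pair[1]) &&
        identical(ch$family3, pair[2]) && abs(ch$breakpoint - bp) <= 3L)
      ok <- ok + 1L
  }
  expect_gte(ok, 9L)
})

test_that("genome scan has perfect recall and precision at mutation zero", {
  sim <- simulateEvolution(tinyConfig(seed = 23))
  for (sp in names(sim@genomes)) {
    got <- scanSnoRNAs(sim@genomes[[sp]], "r", sim@references, sim@rRNA)
    want <- sim@annotations[[sp]]$snornas
    expect_identical(
      sort(vapply(got, function(x)
        sprintf("%s:%d-%d", snornaFamily(x), featureStart(x),
                featureEnd(x)), "")),
      sort(vapply(want, function(x)
        sprintf("%s:%d-%d", snornaFamily(x), featureStart(x),
                featureEnd(x)), "")))
    expect_true(all(vapply(got, validObject, TRUE)))
  }
})
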