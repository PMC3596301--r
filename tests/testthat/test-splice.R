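test_that("planted spliced products resolve to their removed sets", {
  anc <- buildAncestralCluster(tinyConfig(seed = 111))
  el <- elements(anc$architecture)
  iv <- el[el$kind == "intron", ]
  span <- c(min(el$start), max(el$end))
  g <- anc$genome[[1]]
  spliceOut <- function(removed) {
    pos <- span[1]; out <- ""
    for (j in seq_len(nrow(iv))) {
      if (j %in% removed) {
        out <- paste0(out, substr(g, pos + 1, iv$start[j]))
        pos <- iv$end[j]
      }
    }
    paste0(out, substr(g, pos + 1, span[2]))
  }
  p12 <- resolveProduct(spliceOut(c(1, 2)), anc$genome, anc$architecture)
  expect_identical(removedIntrons(p12), c(1L, 2L))
  expect_identical(retainedIntrons(p12), 3L)
  expect_identical(p12@classification, "I+II_removed")
  expect_identical(p12@mismatches, 0L)

  pu <- resolveProduct(spliceOut(integer(0)), anc$genome, anc$architecture)
  expect_identical(removedIntrons(pu), integer(0))
  expect_identical(pu@classification, "unspliced")

  pall <- resolveProduct(spliceOut(1:3), anc$genome, anc$architecture)
  expect_identical(pall@classification, "all_removed")

  ## a sequence unrelated to any splicing hypothesis resolves to nothing
  expect_null(resolveProduct(randSeq(400), anc$genome, anc$architecture))
})

test_that("truth labels are recovered for all noiseless transcripts", {
  anc <- buildAncestralCluster(tinyConfig(seed = 112))
  tx <- simulateTranscripts(anc$genome, anc$architecture, "stepwise",
                            n = 40, seed = 3)
  prods <- resolveProducts(tx$transcripts, anc$genome, anc$architecture)
  expect_length(prods, 40L)
  got <- vapply(prods, function(p) paste(removedIntrons(p), collapse = ","),
                "")
  expect_identical(got, tx$truth$removed)
})

test_that("the 12-intron hypothesis cap is enforced", {
  el <- do.call(rbind, lapply(0:12, function(i)
    rbind(data.frame(kind = "exon", start = i * 100L, end = i * 100L + 40L,
                     family = NA_character_),
          data.frame(kind = "intron", start = i * 100L + 40L,
                     end = (i + 1L) * 100L, family = NA_character_))))
  arch <- ClusterArchitecture("big", "r", el)
  genome <- c(r = randSeq(1400))
  expect_error(resolveProduct(randSeq(100), genome, arch), "12")
})

test_that("product classes are tallied per removed-set label", {
  mk <- function(removed, k = 3L)
    new("SplicedProduct", transcriptId = "t", clusterId = "c",
        removed = as.integer(removed),
        retained = setdiff(seq_len(k), as.integer(removed)),
        mismatches = 0L,
        classification = snoEvol:::romanLabel(as.integer(removed), k))
  prods <- c(lapply(1:2, function(i) mk(1L)), list(mk(1:2)), list(mk(1:3)))
  counts <- classifyProducts(prods)
  expect_identical(counts[["I_removed"]], 2L)
  expect_identical(counts[["I+II_removed"]], 1L)
  expect_identical(counts[["all_removed"]], 1L)
  expect_identical(counts[["total"]], 4L)
  expect_identical(classifyProducts(list())[["total"]], 0L)
  bad <- mk(1L); bad@clusterId <- "other"
  expect_error(classifyProducts(c(prods, list(bad))), "mixed")
})

test_that("class frequencies follow the prefix weights", {
  anc <- buildAncestralCluster(tinyConfig(seed = 113))
  w <- c(0, 0.43, 0.33, 0.24)
  tx <- simulateTranscripts(anc$genome, anc$architecture, "stepwise",
                            n = 500, seed = 7, prefixWeights = w)
  prods <- resolveProducts(tx$transcripts, anc$genome, anc$architecture)
  counts <- classifyProducts(prods)
  for (cl in c("I_removed", "I+II_removed", "all_removed")) {
    p <- w[match(cl, c("unspliced", "I_removed", "I+II_removed",
                       "all_removed"))]
    se <- sqrt(p * (1 - p) / 500)
    expect_lt(abs(counts[[cl]] / 500 - p), 3 * se)
  }
})

test_that("the stepwise verdict flags exactly the non-prefix products", {
  mk <- function(removed, k = 3L)
    new("SplicedProduct", transcriptId = paste(removed, collapse = ""),
        clusterId = "c", removed = as.integer(removed),
        retained = setdiff(seq_len(k), as.integer(removed)),
        mismatches = 0L, classification = "x")
  ok <- list(mk(integer(0)), mk(1L), mk(1:2), mk(1:3))
  expect_identical(testStepwise(ok)$verdict, "consistent")
  bad <- c(ok, list(mk(3L)))
  v <- testStepwise(bad)
  expect_identical(v$verdict, "violated")
  expect_length(v$violations, 1L)
  expect_identical(removedIntrons(v$violations[[1]]), 3L)
  ## invariant to order and duplication
  expect_identical(testStepwise(rev(bad))$verdict, "violated")
  expect_identical(testStepwise(c(ok, ok))$verdict, "consistent")
})

test_that("the alternative single-donor model matches the stepwise verdict", {
  mk <- function(removed, k = 3L)
    new("SplicedProduct", transcriptId = "t", clusterId = "c",
        removed = as.integer(removed),
        retained = setdiff(seq_len(k), as.integer(removed)),
        mismatches = 0L, classification = "x")
  prefixOnly <- list(mk(1L), mk(1:2))
  expect_true(noteAlternativeModel(prefixOnly))
  withBad <- c(prefixOnly, list(mk(2:3)))
  expect_false(noteAlternativeModel(withBad))
  expect_identical(testStepwise(withBad)$verdict, "violated")
  expect_true(noteAlternativeModel(list()))
})

test_that("simulator splicing modes drive the verdict", {
  anc <- buildAncestralCluster(tinyConfig(seed = 114))
  for (s in 1:4) {
    st <- simulateTranscripts(anc$genome, anc$architecture, "stepwise",
                              n = 15, seed = s)
    pv <- resolveProducts(st$transcripts, anc$genome, anc$architecture)
    expect_identical(testStepwise(pv)$verdict, "consistent")
    vi <- simulateTranscripts(anc$genome, anc$architecture, "violation",
                              n = 15, seed = s)
    pv2 <- resolveProducts(vi$transcripts, anc$genome, anc$architecture)
    expect_identical(testStepwise(pv2)$verdict, "violated")
  }
})
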