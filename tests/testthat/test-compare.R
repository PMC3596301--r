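test_that("Fitch parsimony places a single aberrant leaf on its own edge", {
  tree <- readSpeciesTreeText("(A,B,C,D,E);")   # star tree
  states <- c(A = "intronic", B = "intronic", C = "absent", D = "intronic",
              E = "intronic")
  fit <- fitchParsimony(tree, states, c("intronic", "exonic", "absent"),
                        rootPrior = "intronic")
  expect_identical(nrow(fit$changes), 1L)
  expect_identical(fit$changes$branch, "C")
  expect_identical(fit$changes$to, "absent")
})

test_that("Fitch handles missing leaves and ties toward the root prior", {
  tree <- readSpeciesTreeText("((A,B),(C,D));")
  states <- c(A = "intronic", B = NA, C = "absent", D = "absent")
  fit <- fitchParsimony(tree, states, c("intronic", "absent"),
                        rootPrior = "intronic")
  expect_identical(fit$nodeStates[["n1"]], "intronic")
  expect_identical(nrow(fit$changes), 1L)
})

test_that("identical species give a monomorphic matrix", {
  cfg <- tinyConfig(seed = 61)
  sim <- simulateEvolution(cfg)
  annots <- lapply(names(sim@genomes), function(sp)
    annotateGenome(sim@genomes[[sp]], paste0(sp, "_cluster_region"),
                   sim@references, sim@rRNA))
  names(annots) <- names(sim@genomes)
  pam <- buildPresenceAbsenceMatrix(annots, sim@genomes, sim@references)
  st <- cellStates(pam)
  expect_true(all(st[sim@config@familyNames, ] == "intronic"))
  expect_identical(nrow(st), length(sim@config@familyNames))
})

test_that("a forced deletion makes its family row polymorphic", {
  cfg <- tinyConfig(seed = 62)
  anc <- buildAncestralCluster(cfg)
  del <- applyDeletionLoss(anc, "snR70", branch = "B")
  genomes <- c(A = unname(anc$genome[[1]]), B = unname(del$genome[[1]]))
  tree <- readSpeciesTreeText("(A,B);")
  res <- compareClusters(genomes, tree, anc$references, anc$rRNA)
  st <- cellStates(res$matrix)
  expect_identical(unname(st["snR70", ]), c("absent", "intronic")[
    match(colnames(st), c("B", "A"))])
  det <- eventsAsDataFrame(res$events)
  expect_identical(det$kind, "deletion_loss")
  expect_identical(det$branch, "B")
})

test_that("residual stubs are found at the junction and not in clean joins", {
  set.seed(81)
  intron <- paste0("GTAAGT", randSeq(120), "AG")
  stub <- substr(intron, 1, 15)
  junction <- paste0(randSeq(40), stub, randSeq(40))
  hit <- detectResidualStub(junction, intron)
  expect_identical(hit$end, "5prime")
  expect_gte(hit$length, 15L)
  expect_lte(abs(hit$offset - 40L), 2L)
  expect_gte(hit$identity, 0.85)
  expect_null(detectResidualStub(randSeq(60), intron))
  expect_null(detectResidualStub(randSeq(5), intron))
})

test_that("stub detection is monotone in its identity threshold", {
  set.seed(82)
  intron <- paste0("GTAAGT", randSeq(100), "AG")
  for (i in 1:10) {
    stub <- substr(intron, 1, sample(10:25, 1))
    v <- strsplit(stub, "")[[1]]
    p <- sample(length(v), 1)
    v[p] <- sample(setdiff(c("A", "C", "G", "T"), v[p]), 1)
    junction <- paste0(randSeq(30), paste(v, collapse = ""), randSeq(30))
    strict <- detectResidualStub(junction, intron, minIdentity = 0.95)
    loose <- detectResidualStub(junction, intron, minIdentity = 0.8)
    if (!is.null(strict)) expect_false(is.null(loose))
    if (!is.null(loose) && !is.null(strict))
      expect_gte(loose$length, strict$length)
  }
})

test_that("relocated units are located genome-wide with full coverage", {
  set.seed(83)
  unit <- paste0("GTAAGT", randSeq(140), "AG")
  genome <- paste0(randSeq(800), unit, randSeq(800))
  hit <- searchRelocated(genome, unit, exclude = c(1700, 1748))
  expect_identical(hit$start, 800L)
  expect_identical(hit$end, 800L + nchar(unit))
  expect_identical(hit$identity, 1)
  expect_identical(hit$coverage, 1)
  expect_null(searchRelocated(randSeq(2000), unit))
  expect_error(searchRelocated(genome, "GTAAGT"), "40")
})

test_that("relocation search is monotone in its identity threshold", {
  set.seed(84)
  unit <- paste0("GTAAGT", randSeq(140), "AG")
  v <- strsplit(unit, "")[[1]]
  pos <- sample(length(v), 15)
  for (p in pos) v[p] <- sample(setdiff(c("A", "C", "G", "T"), v[p]), 1)
  genome <- paste0(randSeq(500), paste(v, collapse = ""), randSeq(500))
  loose <- searchRelocated(genome, unit, minIdentity = 0.7)
  strict <- searchRelocated(genome, unit, minIdentity = 0.95)
  expect_false(is.null(loose))
  expect_null(strict)
})

test_that("mechanisms are discriminated with their own evidence", {
  cfg <- nullConfig(seed = 65, tree = "((wt,del),(dei,exc));",
                    residualStubLengthRange = c(15L, 15L))
  anc <- buildAncestralCluster(cfg)
  del <- applyDeletionLoss(buildAncestralCluster(cfg), "snR75",
                           config = cfg)
  dei <- applyDeintronization(buildAncestralCluster(cfg), "snR75")
  exc <- applyExcisionInsertion(buildAncestralCluster(cfg), "snR75",
                                config = cfg)
  genomes <- c(wt = unname(anc$genome[[1]]), del = unname(del$genome[[1]]),
               dei = unname(dei$genome[[1]]), exc = unname(exc$genome[[1]]))
  tree <- readSpeciesTreeText(cfg@tree)
  res <- compareClusters(genomes, tree, anc$references, anc$rRNA)
  det <- eventsAsDataFrame(res$events)
  det <- det[det$subject == "snR75", ]
  expect_setequal(det$kind, c("deletion_loss", "deintronization",
                              "excision_insertion"))
  expect_identical(det$branch[det$kind == "deletion_loss"], "del")
  expect_identical(det$branch[det$kind == "deintronization"], "dei")
  expect_identical(det$branch[det$kind == "excision_insertion"], "exc")
  expect_identical(det$evidence_type[det$kind == "deletion_loss"],
                   "stub_alignment")
  expect_identical(det$evidence_type[det$kind == "deintronization"],
                   "degraded_signals")
  expect_identical(det$evidence_type[det$kind == "excision_insertion"],
                   "relocated_locus")
})

test_that("exon losses are counted and placed from juxtaposed introns", {
  cfg <- tinyConfig(seed = 66)
  anc <- buildAncestralCluster(cfg)
  lost <- applyExonLoss(buildAncestralCluster(cfg), 1L, config = cfg,
                        branch = "B")
  genomes <- c(A = unname(anc$genome[[1]]), B = unname(lost$genome[[1]]))
  tree <- readSpeciesTreeText("(A,B);")
  annots <- lapply(names(genomes), function(sp)
    annotateGenome(genomes[[sp]], paste0(sp, "_cluster_region"),
                   anc$references, anc$rRNA))
  names(annots) <- names(genomes)
  exl <- countExonLoss(annots, tree, anc$references)
  expect_identical(exl$count, 1L)
  expect_identical(eventBranch(exl$events[[1]]), "B")
  expect_identical(eventSubject(exl$events[[1]]), "exon:snR41|snR70")
  ## no losses on identical architectures
  exl0 <- countExonLoss(list(A = annots$A, B = annots$A), tree,
                        anc$references)
  expect_identical(exl0$count, 0L)
})

test_that("zero-event simulations yield zero events", {
  cfg <- nullConfig(seed = 67)
  sim <- simulateEvolution(cfg)
  res <- compareClusters(sim@genomes, sim@tree, sim@references, sim@rRNA)
  expect_length(res$events, 0L)
  expect_identical(res$exonLossCount, 0L)
})
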