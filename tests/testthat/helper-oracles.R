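# Independent brute-force oracles and small fixtures used across the suite.
# Oracles re-derive expected values from first principles; they never call
# the implementation paths they check.

rcOracle <- function(x) {
  paste(rev(strsplit(chartr("ACGT", "TGCA", x), "")[[1L]]), collapse = "")
}

hammingOracle <- function(a, b) {
  av <- strsplit(a, "")[[1L]]; bv <- strsplit(b, "")[[1L]]
  sum(av != bv | av == "N" | bv == "N")
}

randSeq <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                             collapse = "")

## positionwise exhaustive box C/D pair scan
bruteBoxScan <- function(seq, mmC, mmD, sep = c(50L, 150L)) {
  n <- nchar(seq)
  cv <- strsplit(seq, "")[[1L]]
  winMM <- function(motif) {
    mv <- strsplit(motif, "")[[1L]]
    m <- length(mv)
    vapply(0:(n - m), function(p)
      sum(cv[(p + 1L):(p + m)] != mv | cv[(p + 1L):(p + m)] == "N"), 0L)
  }
  cpos <- which(winMM("TGATGA") <= mmC) - 1L
  dpos <- which(pmin(winMM("CTGA"), winMM("ATGA")) <= mmD) - 1L
  out <- NULL
  for (cp in cpos) for (dp in dpos)
    if (dp - cp >= sep[1L] && dp - cp <= sep[2L])
      out <- rbind(out, c(cp, dp))
  if (is.null(out))
    return(data.frame(boxCStart = integer(), boxDStart = integer()))
  out <- out[order(out[, 1L], out[, 2L]), , drop = FALSE]
  data.frame(boxCStart = out[, 1L], boxDStart = out[, 2L])
}

## exhaustive guide search (exact case) via constant-width dictionary
## matching of every candidate window against the reverse-complemented rRNA
bruteGuideExact <- function(candidate, rRNA, minLength,
                            maxLength = min(nchar(candidate), nchar(rRNA))) {
  rcr <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(rRNA)))
  nq <- nchar(candidate); ns <- nchar(rRNA)
  for (L in seq.int(maxLength, minLength)) {
    wins <- vapply(0:(nq - L), function(a) substr(candidate, a + 1L, a + L),
                   "")
    hits <- Biostrings::matchPDict(
      Biostrings::PDict(Biostrings::DNAStringSet(wins)),
      Biostrings::DNAString(rcr))
    cnt <- S4Vectors::elementNROWS(hits)
    if (any(cnt > 0L)) {
      a <- which(cnt > 0L)[1L] - 1L
      s <- BiocGenerics::start(hits[[which(cnt > 0L)[1L]]])[1L] - 1L
      return(list(candidateOffset = a, rRNAOffset = ns - s - L,
                  length = L, mismatches = 0L))
    }
  }
  NULL
}

## full triple-loop guide oracle with mismatches (tiny inputs only)
bruteGuideMM <- function(candidate, rRNA, minLength, maxMismatch) {
  nq <- nchar(candidate); ns <- nchar(rRNA)
  best <- NULL
  for (L in seq.int(min(nq, ns), minLength)) {
    for (a in 0:(nq - L)) {
      w <- substr(candidate, a + 1L, a + L)
      for (r in 0:(ns - L)) {
        mm <- hammingOracle(w, rcOracle(substr(rRNA, r + 1L, r + L)))
        if (mm <= maxMismatch &&
            (is.null(best) || L > best$length ||
             (L == best$length && mm < best$mismatches) ||
             (L == best$length && mm == best$mismatches &&
              a < best$candidateOffset)))
          best <- list(candidateOffset = a, rRNAOffset = r, length = L,
                       mismatches = mm)
      }
    }
    if (!is.null(best)) return(best)   # longer L already covered
  }
  best
}

## exhaustive splice-signal matcher
bruteSignals <- function(seq, branchMM = 2L) {
  n <- nchar(seq)
  donors <- NULL; branches <- NULL; acceptors <- integer(0L)
  for (p in 0:(n - 2L)) {
    if (substr(seq, p + 1L, p + 2L) == "GT" && p <= n - 6L)
      donors <- rbind(donors,
                      c(p, 6L - hammingOracle(substr(seq, p + 1L, p + 6L),
                                              "GTAAGT")))
    if (substr(seq, p + 1L, p + 2L) == "AG")
      acceptors <- c(acceptors, p)
    if (p <= n - 7L) {
      mm <- hammingOracle(substr(seq, p + 1L, p + 7L), "TACTAAC")
      if (mm <= branchMM) branches <- rbind(branches, c(p, 7L - mm))
    }
  }
  list(donors = donors, branches = branches, acceptors = acceptors)
}

## exhaustive junction direct-repeat oracle mirroring the documented
## definition (anchored arms, maximal-among-reportable)
bruteDirectRepeats <- function(lf, ins, rf, minLen, maxLen, maxMM = 0L) {
  nl <- nchar(lf); ni <- nchar(ins); nr <- nchar(rf)
  reportable <- list()
  key <- function(side, a1, a2, L) paste(side, a1, a2, L)
  for (L in minLen:maxLen) {
    if (L <= nl) {
      a1 <- substr(lf, nl - L + 1L, nl)
      if (ni >= L)
        for (s in 0:(min(maxLen, ni) - L))
          if (hammingOracle(a1, substr(ins, s + 1L, s + L)) <= maxMM)
            reportable[[key("A", nl - L, s, L)]] <-
              list(side = "A", a1s = nl - L, a2s = s, L = L)
      if (L <= nr && hammingOracle(a1, substr(rf, 1L, L)) <= maxMM)
        reportable[[key("F", nl - L, 0L, L)]] <-
          list(side = "F", a1s = nl - L, a2s = 0L, L = L)
    }
    if (L <= nr && ni >= L) {
      a1 <- substr(rf, 1L, L)
      for (s in max(0L, ni - maxLen):(ni - L))
        if (hammingOracle(a1, substr(ins, s + 1L, s + L)) <= maxMM)
          reportable[[key("B", 0L, s, L)]] <-
            list(side = "B", a1s = 0L, a2s = s, L = L)
    }
  }
  keep <- Filter(function(cc) {
    ext <- switch(cc$side,
                  A = key("A", cc$a1s - 1L, cc$a2s - 1L, cc$L + 1L),
                  B = key("B", 0L, cc$a2s - 1L, cc$L + 1L),
                  F = key("F", cc$a1s - 1L, 0L, cc$L + 1L))
    is.null(reportable[[ext]])
  }, reportable)
  unname(lapply(keep, function(cc) c(cc$a1s, cc$a2s, cc$L)))
}

## exhaustive inverted-repeat oracle
bruteInvertedRepeats <- function(ex, intr, minLen, maxLen, maxMM = 0L,
                                 win = 20L) {
  ne <- nchar(ex); ni <- nchar(intr)
  reportable <- list()
  key <- function(s1, s2, L) paste(s1, s2, L)
  for (L in minLen:maxLen)
    for (s1 in max(0L, ne - win):(ne - L))
      for (s2 in max(0L, ni - win):(ni - L)) {
        if (s1 < 0L || s2 < 0L) next
        if (hammingOracle(substr(intr, s2 + 1L, s2 + L),
                          rcOracle(substr(ex, s1 + 1L, s1 + L))) <= maxMM)
          reportable[[key(s1, s2, L)]] <- c(s1, s2, L)
      }
  keep <- Filter(function(v)
    is.null(reportable[[key(v[1L] - 1L, v[2L], v[3L] + 1L)]]) &&
      is.null(reportable[[key(v[1L], v[2L] - 1L, v[3L] + 1L)]]),
    reportable)
  unname(keep)
}

## independent linear scan for runs of >= 2 adjacent introns
bruteComplexRuns <- function(kinds) {
  runs <- list(); cur <- 0L; idx <- 0L
  for (k in kinds) {
    if (k == "intron") { idx <- idx + 1L; cur <- cur + 1L }
    else { if (cur >= 2L) runs[[length(runs) + 1L]] <- (idx - cur + 1L):idx
           cur <- 0L }
  }
  if (cur >= 2L) runs[[length(runs) + 1L]] <- (idx - cur + 1L):idx
  runs
}

## ---- fixtures -------------------------------------------------------------

nullConfig <- function(seed = 42L, pointMutationRate = 0, ...) {
  simulationConfig(seed = seed, pointMutationRate = pointMutationRate,
                   pDeintronization = 0, pDeletionLoss = 0,
                   pExcisionInsertion = 0, pRecombination = 0,
                   pExonLoss = 0, pIntronGain = 0, ...)
}

tinyConfig <- function(seed = 1L, ...) {
  nullConfig(seed = seed, tree = "((A,B),(C,D));", nSnornaFamilies = 3L,
             flankLength = 1500L, ...)
}

annotKey <- function(anns) {
  sort(vapply(anns, function(a)
    sprintf("%s:%d-%d:%s", snornaFamily(a), featureStart(a),
            featureEnd(a), class(a)), ""))
}
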