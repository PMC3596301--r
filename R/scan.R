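## snorna_scan: detection of box C/D snoRNAs in genomic sequence by box
## motif scanning, guide-element scoring against an rRNA reference, family
## assignment by global alignment, and chimera (fusion) detection by
## exhaustive breakpoint scan.

BOX_C_MOTIF <- "TGATGA"
BOX_D_MOTIFS <- c("CTGA", "ATGA")

#' Scan a sequence for box C / box D motif pairs
#'
#' Reports all position pairs where a match to box C (TGATGA, up to
#' \code{maxMismatchC} mismatches) precedes a match to box D (CTGA or ATGA,
#' up to \code{maxMismatchD} mismatches) at a start-to-start separation
#' within \code{separation}. Box D is only 4 nt, so its default mismatch
#' allowance is 0. N never matches.
#'
#' @param sequence DNA string
#' @param maxMismatchC,maxMismatchD mismatch allowances
#' @param separation inclusive separation window (nt, box C start to box D
#'   start)
#' @return data.frame(boxCStart, boxDStart), 0-based, ordered by box C then
#'   box D position
#' @export
scanBoxMotifs <- function(sequence, maxMismatchC = 1L, maxMismatchD = 0L,
                          separation = c(50L, 150L)) {
  stopifnot(nchar(sequence) > 0L)
  cPos <- motifHits(sequence, BOX_C_MOTIF, maxMismatchC)
  dPos <- sort(unique(unlist(lapply(BOX_D_MOTIFS, motifHits,
                                    seq = sequence,
                                    maxMismatch = maxMismatchD))))
  out <- list()
  for (cp in cPos) {
    dp <- dPos[dPos >= cp + separation[1L] & dPos <= cp + separation[2L]]
    if (length(dp))
      out[[length(out) + 1L]] <- data.frame(boxCStart = cp, boxDStart = dp)
  }
  res <- if (length(out)) do.call(rbind, out)
    else data.frame(boxCStart = integer(), boxDStart = integer())
  res[order(res$boxCStart, res$boxDStart), , drop = FALSE]
}

#' Score the antisense guide element of a candidate region
#'
#' Finds the longest window of \code{candidate} whose reverse complement
#' matches a window of \code{rRNA} with at most \code{maxMismatch}
#' mismatches and length at least \code{minLength}. Ties are broken by
#' fewer mismatches, then by leftmost candidate offset.
#'
#' @param candidate DNA string (the region 5' of box D)
#' @param rRNA rRNA reference DNA string
#' @param minLength minimum guide length (>= 8)
#' @param maxMismatch mismatch allowance
#' @return \code{NULL} if no qualifying window, else
#'   \code{list(candidateOffset, rRNAOffset, length, mismatches)} (0-based)
#' @export
scoreGuide <- function(candidate, rRNA, minLength = 10L, maxMismatch = 0L) {
  stopifnot(minLength >= 8L)
  nq <- nchar(candidate); ns <- nchar(rRNA)
  if (nq < minLength || ns < minLength) return(NULL)
  rcr <- revcompChr(rRNA)
  if (maxMismatch == 0L) {
    ## exact case: longest candidate substring present in revcomp(rRNA);
    ## a guide window at candidate offset a corresponds to an rRNA window
    ## at offset ns - a' - L of the forward rRNA, a' being its offset in
    ## the reverse complement
    for (L in seq.int(min(nq, ns), minLength)) {
      for (a in seq.int(0L, nq - L)) {
        hit <- as.integer(regexpr(substr(candidate, a + 1L, a + L), rcr,
                                  fixed = TRUE))
        if (hit > 0L) {
          return(list(candidateOffset = a,
                      rRNAOffset = ns - (hit - 1L) - L,
                      length = L, mismatches = 0L))
        }
      }
    }
    return(NULL)
  }
  m <- bestUngappedMatch(candidate, rcr, minLength, maxMismatch)
  if (is.null(m)) return(NULL)
  list(candidateOffset = m$qStart0,
       rRNAOffset = ns - m$sStart0 - m$length,
       length = m$length, mismatches = m$mismatches)
}

#' Assign a candidate snoRNA to a reference family
#'
#' Global alignment (unit match/mismatch scores, affine gaps open 2 extend
#' 1) of the candidate against each family reference; identity is matches
#' over the length of the longer sequence. The best family is reported if
#' its identity reaches \code{minIdentity}, otherwise "novel".
#'
#' @param candidate DNA string
#' @param references named character vector of family reference sequences
#' @param minIdentity identity threshold for a family call
#' @return list(family, identity)
#' @export
assignFamily <- function(candidate, references, minIdentity = 0.7) {
  stopifnot(length(references) > 0L, !is.null(names(references)))
  ids <- globalIdentityMany(unname(references), candidate)
  best <- which.max(ids)
  list(family = if (ids[best] >= minIdentity) names(references)[best]
                else "novel",
       identity = ids[best])
}

## identity of a segment against the best-matching part of a reference
## (segment globally aligned within the reference), matches / segment length
segmentIdentities <- function(segments, ref) {
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1,
                                                  baseOnly = FALSE)
  aln <- Biostrings::pairwiseAlignment(Biostrings::DNAStringSet(segments),
                                       Biostrings::DNAString(ref),
                                       type = "global-local",
                                       substitutionMatrix = mat,
                                       gapOpening = 2, gapExtension = 1)
  Biostrings::nmatch(aln) / nchar(segments)
}

#' Detect a chimeric (fused) snoRNA by exhaustive breakpoint scan
#'
#' For every split position, the 5' and 3' segments are aligned
#' independently against all family references (each segment globally,
#' within the best-matching part of the reference). The split maximising
#' the summed identity is reported when both segments reach
#' \code{minSegmentIdentity} over at least \code{minSegmentLength} nt and
#' the two best families differ.
#'
#' @param candidate DNA string of the candidate snoRNA
#' @param references named character vector of family references
#' @param minSegmentIdentity per-segment identity threshold
#' @param minSegmentLength minimum segment length (nt)
#' @return \code{NULL}, or list(family5, family3, breakpoint, identity5,
#'   identity3); breakpoint is the 0-based position where the 3' parent
#'   begins
#' @export
detectChimera <- function(candidate, references, minSegmentIdentity = 0.75,
                          minSegmentLength = 25L) {
  L <- nchar(candidate)
  if (L < 2L * minSegmentLength) return(NULL)
  splits <- seq.int(minSegmentLength, L - minSegmentLength)
  prefixes <- vapply(splits, function(s) substr(candidate, 1L, s), "")
  suffixes <- vapply(splits, function(s) substr(candidate, s + 1L, L), "")
  fams <- names(references)
  id5 <- vapply(references, function(r) segmentIdentities(prefixes, r),
                numeric(length(splits)))
  id3 <- vapply(references, function(r) segmentIdentities(suffixes, r),
                numeric(length(splits)))
  id5 <- matrix(id5, nrow = length(splits))
  id3 <- matrix(id3, nrow = length(splits))
  best <- NULL
  for (si in seq_along(splits)) {
    for (f5 in seq_along(fams)) {
      if (id5[si, f5] < minSegmentIdentity) next
      for (f3 in seq_along(fams)) {
        if (f3 == f5 || id3[si, f3] < minSegmentIdentity) next
        tot <- id5[si, f5] + id3[si, f3]
        if (is.null(best) || tot > best$total + 1e-12) {
          best <- list(family5 = fams[f5], family3 = fams[f3],
                       breakpoint = splits[si],
                       identity5 = id5[si, f5], identity3 = id3[si, f3],
                       total = tot)
        }
      }
    }
  }
  if (is.null(best)) return(NULL)
  best$total <- NULL
  best
}

## search for an exact snoRNA-free intron (exact donor, exact branch,
## AG acceptor) ending within tol nt of `endAt` (the downstream box D),
## inside genome[from, to)
findEmbeddedIntron <- function(seq, from, to, endAt, tol = 2L,
                               donor = "GTAAGT", branch = "TACTAAC",
                               minLen = 40L, maxLen = 500L) {
  region <- subseq0(seq, from, to)
  dPos <- motifHits(region, donor, 0L) + from
  if (!length(dPos)) return(NULL)
  bAll <- motifHits(region, branch, 0L) + from
  for (g0 in dPos) {
    bs <- bAll[bAll >= g0 + nchar(donor)]
    for (b in bs) {
      for (e in seq.int(endAt - tol, endAt + tol)) {
        if (e > nchar(seq) || e < 2L) next
        if (substr(seq, e - 1L, e) != "AG") next
        gap <- e - (b + nchar(branch))
        if (gap < 5L || gap > 100L) next
        len <- e - g0
        if (len < minLen || len > maxLen) next
        return(c(start = g0, end = e, branch = b))
      }
    }
  }
  NULL
}

#' Scan a genome record for box C/D snoRNAs
#'
#' The full detection pipeline for one genome sequence: box C/D pair
#' scanning, guide-element scoring (the guide must abut box D on its 5'
#' side), family assignment, chimera detection for unassigned candidates,
#' and resolution of overlapping candidates (better guide, then higher
#' family identity, then longer, then leftmost). Candidates without a
#' guide, and candidates assignable to no family and no chimera, are
#' discarded. Pairs whose box separation exceeds the snoRNA-internal window
#' are additionally tested for a gained intron inserted between guide and
#' box D (an exact-signal snoRNA-free intron ending at box D); such
#' snoRNAs are reported with an \code{embeddedIntron}.
#'
#' @param genomeSeq DNA string
#' @param recId record id for the emitted annotations
#' @param references named character vector of family reference sequences
#' @param rRNA rRNA reference string for guide scoring
#' @param maxMismatchC,maxMismatchD box mismatch allowances
#' @param separation box C-D separation window of an uninterrupted snoRNA
#' @param guideMinLength,guideMaxMismatch guide-element thresholds
#' @param minIdentity family-assignment identity threshold
#' @param maxEmbedded maximum length of an embedded gained intron
#' @return list of \code{SnoRNAAnnotation}
#' @export
scanSnoRNAs <- function(genomeSeq, recId, references, rRNA,
                        maxMismatchC = 1L, maxMismatchD = 0L,
                        separation = c(50L, 150L),
                        guideMinLength = 10L, guideMaxMismatch = 0L,
                        minIdentity = 0.7, maxEmbedded = 500L) {
  n <- nchar(genomeSeq)
  pairs <- scanBoxMotifs(genomeSeq, maxMismatchC, maxMismatchD,
                         separation = c(separation[1L],
                                        separation[2L] + maxEmbedded))
  cands <- list()
  for (r in seq_len(nrow(pairs))) {
    cp <- pairs$boxCStart[r]; dp <- pairs$boxDStart[r]
    sep <- dp - cp
    start <- cp - 5L; end <- dp + 4L + 5L
    if (start < 0L || end > n) next
    guideRegionFrom <- max(cp + 6L, dp - 25L)
    emb <- NULL
    guide <- NULL
    if (sep <= separation[2L]) {
      g <- scoreGuide(subseq0(genomeSeq, guideRegionFrom, dp), rRNA,
                      guideMinLength, guideMaxMismatch)
      ## the guide must abut box D on its 5' side
      if (!is.null(g) &&
          guideRegionFrom + g$candidateOffset + g$length >= dp - 2L)
        guide <- list(start = guideRegionFrom + g$candidateOffset,
                      end = guideRegionFrom + g$candidateOffset + g$length,
                      rRNAOffset = g$rRNAOffset, length = g$length)
    }
    if (is.null(guide) && sep - separation[1L] >= 40L) {
      ## inflated separation: try a gained intron between guide and box D
      emb <- findEmbeddedIntron(genomeSeq, cp + 6L, dp, endAt = dp,
                                maxLen = maxEmbedded)
      if (!is.null(emb)) {
        splicedSep <- sep - (emb[["end"]] - emb[["start"]])
        if (splicedSep >= separation[1L] && splicedSep <= separation[2L]) {
          gFrom <- max(cp + 6L, emb[["start"]] - 25L)
          g <- scoreGuide(subseq0(genomeSeq, gFrom, emb[["start"]]), rRNA,
                          guideMinLength, guideMaxMismatch)
          if (!is.null(g) &&
              gFrom + g$candidateOffset + g$length >= emb[["start"]] - 2L)
            guide <- list(start = gFrom + g$candidateOffset,
                          end = gFrom + g$candidateOffset + g$length,
                          rRNAOffset = g$rRNAOffset, length = g$length)
        }
        if (is.null(guide)) emb <- NULL
      }
    }
    if (is.null(guide)) next
    spliced <- if (is.null(emb)) subseq0(genomeSeq, start, end)
      else paste0(subseq0(genomeSeq, start, emb[["start"]]),
                  subseq0(genomeSeq, emb[["end"]], end))
    fam <- assignFamily(spliced, references, minIdentity)
    ## test every candidate for a fusion of two families; accept only when
    ## both segments match their parents at least as well as the whole
    ## candidate matches its best single family
    chim <- list()
    ch <- detectChimera(spliced, references)
    if (!is.null(ch) &&
        min(ch$identity5, ch$identity3) >= max(0.75, fam$identity))
      chim <- list(family5 = ch$family5, family3 = ch$family3,
                   breakpoint = ch$breakpoint)
    if (fam$family == "novel" && !length(chim)) next
    cands[[length(cands) + 1L]] <- list(
      start = start, end = end, family = fam$family,
      identity = fam$identity, boxC = cp, boxD = dp, guide = guide,
      chimeric = chim,
      embedded = if (is.null(emb)) list()
                 else list(start = emb[["start"]], end = emb[["end"]],
                           branchStart = emb[["branch"]]))
  }
  ## resolve overlapping candidates
  keep <- resolveOverlaps(cands)
  lapply(keep, function(cc) {
    SnoRNAAnnotation(
      recordId = recId, start = cc$start, end = cc$end, family = cc$family,
      familyIdentity = cc$identity,
      boxCStart = cc$boxC, boxCSeq = subseq0(genomeSeq, cc$boxC, cc$boxC + 6L),
      boxDStart = cc$boxD, boxDSeq = subseq0(genomeSeq, cc$boxD, cc$boxD + 4L),
      guideStart = cc$guide$start, guideEnd = cc$guide$end,
      guideRRNAOffset = cc$guide$rRNAOffset,
      chimeric = cc$chimeric, embeddedIntron = cc$embedded)
  })
}

## among mutually overlapping candidates keep the best by: longer guide,
## then higher family identity, then longer candidate, then leftmost
resolveOverlaps <- function(cands) {
  if (length(cands) <= 1L) return(cands)
  betterThan <- function(a, b) {
    if (a$guide$length != b$guide$length) return(a$guide$length > b$guide$length)
    if (abs(a$identity - b$identity) > 1e-9) return(a$identity > b$identity)
    la <- a$end - a$start; lb <- b$end - b$start
    if (la != lb) return(la > lb)
    a$start < b$start
  }
  keep <- rep(TRUE, length(cands))
  for (i in seq_along(cands)) {
    if (!keep[i]) next
    for (j in seq_along(cands)) {
      if (i == j || !keep[j]) next
      if (cands[[i]]$start < cands[[j]]$end &&
          cands[[j]]$start < cands[[i]]$end) {
        if (betterThan(cands[[i]], cands[[j]])) keep[j] <- FALSE
        else keep[i] <- FALSE
      }
      if (!keep[i]) break
    }
  }
  cands[keep]
}
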