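## repeat_junction: short direct repeats (target-site duplications of
## staggered double-strand-break repair) and short inverted repeats at
## intron insertion junctions.

#' Find short direct repeats at an insertion junction
#'
#' One arm is anchored at the junction (the word ending the left flank, or
#' the word starting the right flank); its partner lies within the first or
#' last \code{maxLen} nt of the insert, or is the junction word of the
#' opposite flank (a classic target-site duplication). Arms have length in
#' \code{[minLen, maxLen]} and at most \code{maxMismatch} mismatches. Only
#' pairs maximal among reportable pairs are returned (no reported pair can
#' be extended by one nt into another pair satisfying the length, window
#' and mismatch constraints), sorted by decreasing arm length.
#'
#' @param leftFlank,insert,rightFlank junction sequences (flank - inserted
#'   unit - flank)
#' @param minLen,maxLen arm length bounds (nt)
#' @param maxMismatch mismatch allowance between arms
#' @return list of \code{JunctionRepeat} (kind "direct"); arm intervals are
#'   0-based within the sequence each arm came from
#' @export
findDirectRepeats <- function(leftFlank, insert, rightFlank,
                              minLen = 3L, maxLen = 8L, maxMismatch = 0L) {
  if (minLen > maxLen) stop("minLen must not exceed maxLen")
  nl <- nchar(leftFlank); ni <- nchar(insert); nr <- nchar(rightFlank)
  mm <- function(a, b) countMismatches(a, b)
  cands <- list()
  addCand <- function(side, arm1Start, arm2Start, L, a1, a2) {
    cands[[length(cands) + 1L]] <<- list(side = side, arm1Start = arm1Start,
                                         arm2Start = arm2Start, L = L,
                                         a1 = a1, a2 = a2,
                                         mm = mm(a1, a2))
  }
  ## configuration A: arm1 = left-flank suffix, partner in insert's first
  ## maxLen nt; configuration B: arm1 = right-flank prefix, partner in
  ## insert's last maxLen nt; configuration F: the two junction words
  for (L in seq.int(minLen, maxLen)) {
    if (L > nl && L > nr) next
    a1L <- if (L <= nl) substr(leftFlank, nl - L + 1L, nl) else NULL
    a1R <- if (L <= nr) substr(rightFlank, 1L, L) else NULL
    if (!is.null(a1L)) {
      for (s in seq_len(max(0L, min(maxLen, ni) - L + 1L)) - 1L)
        addCand("A", nl - L, s, L, a1L, substr(insert, s + 1L, s + L))
      if (!is.null(a1R)) addCand("F", nl - L, 0L, L, a1L, a1R)
    }
    if (!is.null(a1R)) {
      lo <- max(0L, ni - maxLen)
      for (s in seq.int(lo, ni - L))
        addCand("B", 0L, s, L, a1R, substr(insert, s + 1L, s + L))
    }
  }
  ok <- vapply(cands, function(cc) cc$mm <= maxMismatch, logical(1L))
  cands <- cands[ok]
  if (!length(cands)) return(list())
  key <- vapply(cands, function(cc)
    paste(cc$side, cc$arm1Start, cc$arm2Start, cc$L), "")
  keys <- new.env(parent = emptyenv())
  for (k in key) assign(k, TRUE, keys)
  ## maximality among reportable pairs: the 1-nt left-extension of an
  ## anchored pair (or symmetric extension of the flank-flank pair) must
  ## not itself be reportable
  isMax <- vapply(cands, function(cc) {
    extKey <- switch(cc$side,
      A = paste("A", cc$arm1Start - 1L, cc$arm2Start - 1L, cc$L + 1L),
      B = paste("B", 0L, cc$arm2Start - 1L, cc$L + 1L),
      F = paste("F", cc$arm1Start - 1L, 0L, cc$L + 1L))
    !exists(extKey, keys)
  }, logical(1L))
  cands <- cands[isMax]
  cands <- cands[order(-vapply(cands, `[[`, 0L, "L"))]
  lapply(cands, function(cc)
    new("JunctionRepeat", kind = "direct", armLength = cc$L,
        arm1Start = as.integer(cc$arm1Start), arm1Seq = cc$a1,
        arm2Start = as.integer(cc$arm2Start), arm2Seq = cc$a2,
        mismatches = as.integer(cc$mm)))
}

#' Find short inverted repeats at an intron insertion junction
#'
#' One arm lies within the last \code{searchWindow} nt of the adjacent exon
#' (the sequence ending at the insertion junction) and the other within
#' the window at the opposite (3') end of the inserted intron; the second
#' arm is the reverse complement of the first, up to \code{maxMismatch}
#' mismatches, with arm length in \code{[minLen, maxLen]} (8-12 bp by
#' default). Only pairs maximal among reportable pairs are returned.
#'
#' @param exonEnd exon sequence ending at the insertion junction
#' @param intron the inserted intron sequence
#' @param minLen,maxLen arm length bounds
#' @param maxMismatch mismatch allowance (after reverse complementing)
#' @param searchWindow window size at the exon end and intron end (nt)
#' @return list of \code{JunctionRepeat} (kind "inverted")
#' @export
findInvertedRepeats <- function(exonEnd, intron, minLen = 8L, maxLen = 12L,
                                maxMismatch = 0L, searchWindow = 20L) {
  if (minLen > maxLen) stop("minLen must not exceed maxLen")
  ne <- nchar(exonEnd); ni <- nchar(intron)
  w1lo <- max(0L, ne - searchWindow)
  w2lo <- max(0L, ni - searchWindow)
  cands <- list()
  for (L in seq.int(minLen, maxLen)) {
    for (s1 in seq.int(w1lo, ne - L)) {
      if (s1 < 0L) next
      a1 <- substr(exonEnd, s1 + 1L, s1 + L)
      rc1 <- revcompChr(a1)
      for (s2 in seq.int(w2lo, ni - L)) {
        if (s2 < 0L) next
        a2 <- substr(intron, s2 + 1L, s2 + L)
        d <- countMismatches(a2, rc1)
        if (d <= maxMismatch)
          cands[[length(cands) + 1L]] <- list(s1 = s1, s2 = s2, L = L,
                                              a1 = a1, a2 = a2, mm = d)
      }
    }
  }
  if (!length(cands)) return(list())
  keys <- new.env(parent = emptyenv())
  for (cc in cands) assign(paste(cc$s1, cc$s2, cc$L), TRUE, keys)
  ## extensions: arm1 left + arm2 right, or arm1 right + arm2 left
  isMax <- vapply(cands, function(cc) {
    !exists(paste(cc$s1 - 1L, cc$s2, cc$L + 1L), keys) &&
      !exists(paste(cc$s1, cc$s2 - 1L, cc$L + 1L), keys)
  }, logical(1L))
  cands <- cands[isMax]
  cands <- cands[order(-vapply(cands, `[[`, 0L, "L"),
                       vapply(cands, `[[`, 0L, "s1"))]
  lapply(cands, function(cc)
    new("JunctionRepeat", kind = "inverted", armLength = cc$L,
        arm1Start = as.integer(cc$s1), arm1Seq = cc$a1,
        arm2Start = as.integer(cc$s2), arm2Seq = cc$a2,
        mismatches = as.integer(cc$mm)))
}

#' Attach junction-repeat evidence to an evolution event
#'
#' Runs both repeat detectors on the insertion junctions the event's
#' evidence resolves to. For an excision-insertion event the relocated
#' locus' flanks and insert are searched for direct repeats (target-site
#' duplications); for an intron-gain event the upstream exon end and the
#' gained intron are searched for inverted repeats. The event's kind is
#' never changed; when the loci cannot be resolved the evidence is marked
#' unavailable.
#'
#' @param event an \code{EvolutionEvent}
#' @param genomes named character vector of per-species genome sequences
#' @param flankWindow nt of flank sequence to search
#' @return the event with \code{evidence$repeats} attached
#' @export
annotateEventJunctions <- function(event, genomes, flankWindow = 20L) {
  ev <- event@evidence
  reps <- list()
  locus <- ev$locus
  if (event@kind == "excision_insertion" && !is.null(locus)) {
    g <- genomes[[locus$species]]
    s <- locus$start; e <- locus$end
    if (!is.null(g) && !is.na(s) && s >= 0L && e <= nchar(g)) {
      reps <- findDirectRepeats(subseq0(g, max(0L, s - flankWindow), s),
                                subseq0(g, s, e),
                                subseq0(g, e, min(nchar(g), e + flankWindow)))
    }
  } else if (event@kind == "intron_gain" && !is.null(locus)) {
    g <- genomes[[locus$species]]
    s <- locus$start; e <- locus$end
    if (!is.null(g) && !is.na(s) && s >= flankWindow && e <= nchar(g)) {
      reps <- findInvertedRepeats(subseq0(g, max(0L, s - flankWindow), s),
                                  subseq0(g, s, e))
    }
  }
  ev$repeats <- reps
  ev$repeats_available <- length(reps) > 0L
  if (is.null(locus)) ev$repeats_available <- NA
  event@evidence <- ev
  event
}
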