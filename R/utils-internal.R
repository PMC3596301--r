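# Internal helpers shared across modules. All coordinates in this package are
# 0-based half-open [start, end) on the forward strand; conversion to the
# 1-based inclusive convention happens only at the GFF3 file boundary.

DNA_BASES <- c("A", "C", "G", "T")

randomDNA <- function(n) {
  if (n <= 0L) return("")
  paste(sample(DNA_BASES, n, replace = TRUE), collapse = "")
}

## random DNA avoiding a set of forbidden substrings; an "AG" constraint is
## enforced constructively (never drawing G after A) because long AG-free
## tracts are vanishingly rare under rejection sampling
randomDNAAvoiding <- function(n, forbidden = character()) {
  if (n <= 0L) return("")
  noAG <- "AG" %in% forbidden
  rest <- setdiff(forbidden, "AG")
  for (i in seq_len(200L)) {
    s <- if (noAG) {
      v <- character(n)
      prev <- ""
      for (k in seq_len(n)) {
        v[k] <- if (prev == "A") sample(c("A", "C", "T"), 1L)
                else sample(DNA_BASES, 1L)
        prev <- v[k]
      }
      paste(v, collapse = "")
    } else randomDNA(n)
    if (!any(vapply(rest, function(f) grepl(f, s, fixed = TRUE),
                    logical(1L))))
      return(s)
  }
  stop("could not generate ", n, " nt avoiding ",
       paste(forbidden, collapse = ","))
}

revcompChr <- function(x) {
  vapply(x, function(s) {
    if (nchar(s) == 0L) return("")
    paste(rev(strsplit(chartr("ACGTNacgtn", "TGCANtgcan", s), "", fixed = TRUE)[[1L]]),
          collapse = "")
  }, character(1L), USE.NAMES = FALSE)
}

## Hamming mismatches between two equal-length strings; N counts as mismatch.
countMismatches <- function(a, b) {
  stopifnot(nchar(a) == nchar(b))
  if (nchar(a) == 0L) return(0L)
  av <- strsplit(a, "", fixed = TRUE)[[1L]]
  bv <- strsplit(b, "", fixed = TRUE)[[1L]]
  sum(av != bv | av == "N" | bv == "N")
}

## substring by 0-based half-open interval
subseq0 <- function(x, start0, end0) {
  if (end0 <= start0) return("")
  substr(x, start0 + 1L, end0)
}

isWholeNumber <- function(x) {
  is.numeric(x) && length(x) == 1L && !is.na(x) && x == floor(x)
}

checkRange <- function(r, name) {
  if (!is.numeric(r) || length(r) != 2L || any(is.na(r)) || r[1L] > r[2L] || r[1L] < 0)
    stop("'", name, "' must be a nonempty range c(low, high) with low <= high")
  invisible(as.integer(r))
}

drawFromRange <- function(r) {
  if (r[1L] == r[2L]) as.integer(r[1L]) else sample(seq.int(r[1L], r[2L]), 1L)
}

## apply substitutions at given 1-based positions of a string, never keeping
## the original base
substitutePositions <- function(seq, pos) {
  if (length(pos) == 0L) return(seq)
  v <- strsplit(seq, "", fixed = TRUE)[[1L]]
  for (p in pos) {
    v[p] <- sample(setdiff(DNA_BASES, v[p]), 1L)
  }
  paste(v, collapse = "")
}

## global pairwise identity: matches / length of the longer sequence.
## Unit match/mismatch scores, affine gaps (open 2, extend 1).
globalIdentity <- function(a, b) {
  if (nchar(a) == 0L || nchar(b) == 0L) return(0)
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1,
                                                  baseOnly = FALSE)
  aln <- Biostrings::pairwiseAlignment(Biostrings::DNAString(a),
                                       Biostrings::DNAString(b),
                                       type = "global",
                                       substitutionMatrix = mat,
                                       gapOpening = 2, gapExtension = 1)
  Biostrings::nmatch(aln) / max(nchar(a), nchar(b))
}

## vectorised variant: identities of many patterns against one subject
globalIdentityMany <- function(patterns, subject) {
  if (length(patterns) == 0L) return(numeric(0L))
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1,
                                                  baseOnly = FALSE)
  aln <- Biostrings::pairwiseAlignment(Biostrings::DNAStringSet(patterns),
                                       Biostrings::DNAString(subject),
                                       type = "global",
                                       substitutionMatrix = mat,
                                       gapOpening = 2, gapExtension = 1)
  Biostrings::nmatch(aln) / pmax(nchar(patterns), nchar(subject))
}

## Best ungapped local match of `query` (as given) against `subject`:
## maximise length among windows with <= maxMismatch mismatches, then fewer
## mismatches, then leftmost query offset, then leftmost subject offset.
## Returns NULL or list(qStart0, sStart0, length, mismatches).
bestUngappedMatch <- function(query, subject, minLength, maxMismatch = 0L) {
  nq <- nchar(query); ns <- nchar(subject)
  if (nq < minLength || ns < minLength) return(NULL)
  qv <- strsplit(query, "", fixed = TRUE)[[1L]]
  sv <- strsplit(subject, "", fixed = TRUE)[[1L]]
  best <- NULL
  ## diagonals: offset d = sIndex - qIndex
  for (d in seq.int(-(nq - minLength), ns - minLength)) {
    qlo <- max(1L, 1L - d); qhi <- min(nq, ns - d)
    len <- qhi - qlo + 1L
    if (len < minLength) next
    qs <- qv[qlo:qhi]
    ss <- sv[(qlo + d):(qhi + d)]
    mm <- as.integer(qs != ss | qs == "N" | ss == "N")
    ## longest window with <= maxMismatch mismatches (two-pointer)
    csum <- c(0L, cumsum(mm))
    lo <- 1L
    for (hi in seq_len(len)) {
      while (csum[hi + 1L] - csum[lo] > maxMismatch) lo <- lo + 1L
      w <- hi - lo + 1L
      if (w < minLength) next
      cand <- list(qStart0 = qlo + lo - 2L,
                   sStart0 = qlo + d + lo - 2L,
                   length = w,
                   mismatches = csum[hi + 1L] - csum[lo])
      if (is.null(best) ||
          cand$length > best$length ||
          (cand$length == best$length && cand$mismatches < best$mismatches) ||
          (cand$length == best$length && cand$mismatches == best$mismatches &&
           (cand$qStart0 < best$qStart0 ||
            (cand$qStart0 == best$qStart0 && cand$sStart0 < best$sStart0))))
        best <- cand
    }
  }
  best
}

## all 0-based start positions where `motif` matches `seq` with <= maxMismatch
## mismatches (N treated as mismatch)
motifHits <- function(seq, motif, maxMismatch = 0L) {
  n <- nchar(seq); m <- nchar(motif)
  if (n < m) return(integer(0L))
  hits <- Biostrings::matchPattern(motif, Biostrings::DNAString(seq),
                                   max.mismatch = maxMismatch,
                                   with.indels = FALSE, fixed = TRUE)
  sort(BiocGenerics::start(hits)) - 1L
}

`%||%` <- function(a, b) if (is.null(a)) b else a
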