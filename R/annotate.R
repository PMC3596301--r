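## intron_annotate: delineate host introns around detected snoRNAs from
## canonical splice signals, classify snoRNAs as intronic or exonic,
## assemble the exon/intron cluster architecture, and flag complex introns
## (adjacent introns with no intercalating exon).

#' Find candidate splice signals in a region
#'
#' Donors are GT-initial positions scored by matches to the donor consensus
#' (default GTAAGT); branch points are matches to the branch consensus
#' (default TACTAAC) with up to \code{branchMaxMismatch} mismatches, scored
#' by matches; acceptors are AG dinucleotide positions. All positions are
#' 0-based starts within the full sequence.
#'
#' @param sequence DNA string
#' @param region 0-based half-open interval to scan (default whole sequence)
#' @param donorConsensus,branchConsensus,branchMaxMismatch consensus config
#' @return list(donors, branches, acceptors) of data.frames with columns
#'   pos and (for donors/branches) score, each sorted by position
#' @export
findSpliceSignals <- function(sequence, region = NULL,
                              donorConsensus = "GTAAGT",
                              branchConsensus = "TACTAAC",
                              branchMaxMismatch = 2L) {
  if (is.null(region)) region <- c(0L, nchar(sequence))
  seq <- subseq0(sequence, region[1L], region[2L])
  dlen <- nchar(donorConsensus); blen <- nchar(branchConsensus)
  gt <- motifHits(seq, "GT", 0L)
  donorScore <- vapply(gt, function(p) {
    w <- subseq0(seq, p, p + dlen)
    if (nchar(w) < dlen) return(NA_integer_)
    dlen - countMismatches(w, donorConsensus)
  }, 0L)
  ok <- !is.na(donorScore)
  donors <- data.frame(pos = gt[ok] + region[1L], score = donorScore[ok])
  bp <- motifHits(seq, branchConsensus, branchMaxMismatch)
  branches <- data.frame(pos = bp + region[1L],
                         score = vapply(bp, function(p)
                           blen - countMismatches(subseq0(seq, p, p + blen),
                                                  branchConsensus), 0L))
  ag <- motifHits(seq, "AG", 0L)
  acceptors <- data.frame(pos = ag + region[1L])
  list(donors = donors[order(donors$pos), , drop = FALSE],
       branches = branches[order(branches$pos), , drop = FALSE],
       acceptors = acceptors[order(acceptors$pos), , drop = FALSE])
}

#' Delineate the host intron of a snoRNA, or classify it as exonic
#'
#' Searches upstream of the snoRNA for a donor and downstream for a branch
#' point and acceptor. A qualifying triple has a GT-initial donor scoring
#' at least \code{minDonorScore} against the donor consensus, a branch
#' point scoring at least \code{minBranchScore}, an acceptor that is the
#' first AG 5-100 nt downstream of the branch point (the spliceosome's
#' AG-scanning rule) and beyond the snoRNA 3' end, intron length within
#' \code{c(minIntronLength, maxIntronLength)}, and combined signal score
#' (donor + branch + 2 for the acceptor) of at least \code{minTotalScore}.
#' The highest-scoring triple wins; ties go to the shortest intron, then
#' the leftmost donor; among equal intron boundaries the most 3' branch
#' point is kept. When no triple qualifies the snoRNA is exonic and
#' \code{NULL} is returned.
#'
#' @param snorna a \code{SnoRNAAnnotation}
#' @param genomeSeq DNA string of the snoRNA's record
#' @param minIntronLength,maxIntronLength intron length bounds (nt)
#' @param minDonorScore,minBranchScore,minTotalScore score thresholds
#' @param branchWindow distance window from branch-point end to intron end
#' @param donorConsensus,branchConsensus consensus sequences
#' @param searchFrom,searchTo optional 0-based bounds restricting the
#'   intron to \[searchFrom, searchTo); used to stop the search at
#'   neighbouring snoRNAs so one snoRNA's intron can never span another
#' @return an \code{IntronAnnotation}, or \code{NULL} meaning "exonic"
#' @export
delineateIntron <- function(snorna, genomeSeq,
                            minIntronLength = 40L, maxIntronLength = 500L,
                            minDonorScore = 5L, minBranchScore = 7L,
                            minTotalScore = 14L, branchWindow = c(5L, 100L),
                            donorConsensus = "GTAAGT",
                            branchConsensus = "TACTAAC",
                            searchFrom = NULL, searchTo = NULL) {
  n <- nchar(genomeSeq)
  s0 <- featureStart(snorna); s1 <- featureEnd(snorna)
  if (s0 < 0L || s1 > n) stop("snoRNA outside genome bounds")
  dlen <- nchar(donorConsensus); blen <- nchar(branchConsensus)
  from <- max(0L, s0 - maxIntronLength, searchFrom %||% 0L)
  to <- min(n, s1 + maxIntronLength, searchTo %||% n)
  sig <- findSpliceSignals(genomeSeq, c(from, to), donorConsensus,
                           branchConsensus, blen - minBranchScore)
  donors <- sig$donors[sig$donors$pos < s0 &
                         sig$donors$score >= minDonorScore, , drop = FALSE]
  branches <- sig$branches[sig$branches$pos >= s1 &
                             sig$branches$score >= minBranchScore, ,
                           drop = FALSE]
  acceptors <- sig$acceptors$pos
  best <- NULL
  for (bi in seq_len(nrow(branches))) {
    b <- branches$pos[bi]; bScore <- branches$score[bi]
    agMin <- max(b + blen + branchWindow[1L] - 2L, s1)
    ag <- acceptors[acceptors >= agMin]
    if (!length(ag)) next
    a <- ag[1L]                       # first AG: the acceptor-scanning rule
    e <- a + 2L
    if (e - (b + blen) > branchWindow[2L]) next
    for (di in seq_len(nrow(donors))) {
      p <- donors$pos[di]; dScore <- donors$score[di]
      len <- e - p
      if (len < minIntronLength || len > maxIntronLength) next
      total <- dScore + bScore + 2L
      if (total < minTotalScore) next
      cand <- list(p = p, b = b, e = e, dScore = dScore, bScore = bScore,
                   total = total, len = len)
      if (is.null(best) ||
          cand$total > best$total ||
          (cand$total == best$total && cand$len < best$len) ||
          (cand$total == best$total && cand$len == best$len &&
           cand$p < best$p) ||
          (cand$total == best$total && cand$len == best$len &&
           cand$p == best$p && cand$b > best$b))
        best <- cand
    }
  }
  if (is.null(best)) return(NULL)
  IntronAnnotation(recordId = recordId(snorna), start = best$p, end = best$e,
                   donorSeq = subseq0(genomeSeq, best$p, best$p + dlen),
                   branchStart = best$b,
                   branchSeq = subseq0(genomeSeq, best$b, best$b + blen),
                   acceptorSeq = subseq0(genomeSeq, best$e - 2L, best$e),
                   snornaFamily = snornaFamily(snorna),
                   signalScore = best$total)
}

#' Detect snoRNA-free introns with exact canonical signals in a region
#'
#' Gained introns carry no snoRNA anchor, so they are called only on
#' full-strength evidence: an exact donor consensus, an exact branch-point
#' consensus, and the first AG 5-100 nt downstream, with intron length
#' within bounds and at least \code{margin} nt of the region left on both
#' sides.
#'
#' @param genomeSeq DNA string
#' @param region 0-based half-open interval to scan (an exon)
#' @param minIntronLength,maxIntronLength intron length bounds
#' @param margin minimum exonic nt that must remain on each side
#' @param donorConsensus,branchConsensus consensus signals
#' @param recId record id for emitted annotations
#' @return list of \code{IntronAnnotation} (possibly empty)
#' @export
detectPlainIntrons <- function(genomeSeq, region, recId,
                               minIntronLength = 40L, maxIntronLength = 500L,
                               margin = 3L, donorConsensus = "GTAAGT",
                               branchConsensus = "TACTAAC") {
  seq <- subseq0(genomeSeq, region[1L], region[2L])
  dlen <- nchar(donorConsensus); blen <- nchar(branchConsensus)
  dPos <- motifHits(seq, donorConsensus, 0L)
  bPos <- motifHits(seq, branchConsensus, 0L)
  out <- list()
  lastEnd <- -1L
  for (p in dPos) {
    if (p < margin) next
    if (p < lastEnd) next          # no nested calls
    for (b in bPos[bPos >= p + dlen]) {
      agRegion <- subseq0(seq, b + blen + 3L, min(b + blen + 98L, nchar(seq)))
      ag <- motifHits(agRegion, "AG", 0L)
      if (!length(ag)) next
      e <- b + blen + 3L + ag[1L] + 2L
      len <- e - p
      if (len < minIntronLength || len > maxIntronLength) next
      if (nchar(seq) - e < margin) next
      out[[length(out) + 1L]] <- IntronAnnotation(
        recordId = recId, start = region[1L] + p, end = region[1L] + e,
        donorSeq = subseq0(seq, p, p + dlen),
        branchStart = region[1L] + b,
        branchSeq = subseq0(seq, b, b + blen),
        acceptorSeq = subseq0(seq, e - 2L, e),
        snornaFamily = NA_character_, signalScore = 15)
      lastEnd <- e
      break
    }
  }
  out
}

## partial overlaps between intron calls cannot tile; keep the call with
## the higher signal score (ties: snoRNA-hosting first, then leftmost);
## strict nesting is allowed and handled by the assembler
dropOverlappingIntrons <- function(introns) {
  if (length(introns) < 2L) return(introns)
  keep <- rep(TRUE, length(introns))
  iv <- data.frame(start = vapply(introns, featureStart, 0L),
                   end = vapply(introns, featureEnd, 0L),
                   score = vapply(introns, function(x)
                     if (is.na(x@signalScore)) 0 else x@signalScore, 0),
                   hasSno = !is.na(vapply(introns, snornaFamily, "")))
  better <- function(i, j) {
    if (iv$score[i] != iv$score[j]) return(iv$score[i] > iv$score[j])
    if (iv$hasSno[i] != iv$hasSno[j]) return(iv$hasSno[i])
    iv$start[i] < iv$start[j]
  }
  for (i in seq_along(introns)) {
    if (!keep[i]) next
    for (j in seq_along(introns)) {
      if (i == j || !keep[j]) next
      overlap <- iv$start[i] < iv$end[j] && iv$start[j] < iv$end[i]
      nested <- (iv$start[i] <= iv$start[j] && iv$end[j] <= iv$end[i]) ||
        (iv$start[j] <= iv$start[i] && iv$end[i] <= iv$end[j])
      if (overlap && !nested) {
        if (better(i, j)) keep[j] <- FALSE else keep[i] <- FALSE
      }
      if (!keep[i]) break
    }
  }
  introns[keep]
}

#' Assemble the exon/intron architecture of one cluster
#'
#' Partitions the cluster span into intron elements (the given annotations)
#' and the exons between and around them. Introns nested strictly inside
#' another intron (gained introns within a snoRNA) are kept as annotations
#' but excluded from the top-level tiling; partially overlapping introns
#' are an error.
#'
#' @param genomeSeq DNA string of the record
#' @param snornas list of \code{SnoRNAAnnotation} of the cluster
#' @param introns list of \code{IntronAnnotation} of the cluster
#' @param clusterId identifier for the architecture
#' @param margin5,margin3 exon margins beyond the outermost annotation (nt)
#' @return a \code{ClusterArchitecture}
#' @export
assembleArchitecture <- function(genomeSeq, snornas, introns,
                                 clusterId = "cluster",
                                 margin5 = 30L, margin3 = 30L) {
  recId <- if (length(introns)) recordId(introns[[1L]])
    else if (length(snornas)) recordId(snornas[[1L]])
    else stop("no annotations to assemble")
  iv <- data.frame(start = vapply(introns, featureStart, 0L),
                   end = vapply(introns, featureEnd, 0L),
                   family = vapply(introns, snornaFamily, ""))
  iv <- iv[order(iv$start, iv$end), , drop = FALSE]
  ## drop nested introns from the tiling
  if (nrow(iv) > 1L) {
    nested <- vapply(seq_len(nrow(iv)), function(i)
      any(iv$start <= iv$start[i] & iv$end >= iv$end[i] &
            (iv$start < iv$start[i] | iv$end > iv$end[i])), logical(1L))
    iv <- iv[!nested, , drop = FALSE]
  }
  if (nrow(iv) > 1L) {
    ov <- which(iv$start[-1L] < iv$end[-nrow(iv)])
    if (length(ov))
      stop("annotation conflict: overlapping introns at rows ",
           paste(ov, collapse = ","))
  }
  allStarts <- c(iv$start, vapply(snornas, featureStart, 0L))
  allEnds <- c(iv$end, vapply(snornas, featureEnd, 0L))
  span <- c(max(0L, min(allStarts) - margin5),
            min(nchar(genomeSeq), max(allEnds) + margin3))
  el <- list()
  pos <- span[1L]
  for (i in seq_len(nrow(iv))) {
    if (iv$start[i] > pos)
      el[[length(el) + 1L]] <- data.frame(kind = "exon", start = pos,
                                          end = iv$start[i],
                                          family = NA_character_)
    el[[length(el) + 1L]] <- data.frame(kind = "intron", start = iv$start[i],
                                        end = iv$end[i],
                                        family = iv$family[i])
    pos <- iv$end[i]
  }
  if (pos < span[2L])
    el[[length(el) + 1L]] <- data.frame(kind = "exon", start = pos,
                                        end = span[2L],
                                        family = NA_character_)
  ClusterArchitecture(clusterId, recId, do.call(rbind, el))
}

#' Detect complex introns: maximal runs of adjacent introns
#'
#' Reports every maximal run of two or more intron elements lying in
#' juxtaposition with no intercalating exon.
#'
#' @param architecture a \code{ClusterArchitecture}
#' @return list of list(intronIndices, start, end); empty when all introns
#'   are exon-separated
#' @export
detectComplexIntrons <- function(architecture) {
  el <- elements(architecture)
  runs <- list()
  intronNo <- 0L
  cur <- integer(0L); curStart <- NA_integer_; curEnd <- NA_integer_
  flush <- function() {
    if (length(cur) >= 2L)
      runs[[length(runs) + 1L]] <<- list(intronIndices = cur,
                                         start = curStart, end = curEnd)
    cur <<- integer(0L)
  }
  for (i in seq_len(nrow(el))) {
    if (el$kind[i] == "intron") {
      intronNo <- intronNo + 1L
      if (!length(cur)) curStart <- el$start[i]
      cur <- c(cur, intronNo)
      curEnd <- el$end[i]
    } else flush()
  }
  flush()
  runs
}

#' Scan and annotate one genome end to end
#'
#' Runs the snoRNA scan, delineates every snoRNA's host intron (or
#' classifies it exonic), groups snoRNAs into clusters (maximal chains with
#' inter-snoRNA gaps of at most \code{clusterGap} nt), assembles the
#' architecture of the main (largest) cluster, scans its exons for gained
#' snoRNA-free introns, and separates relocated snoRNA copies lying
#' outside the main cluster.
#'
#' @param genomeSeq DNA string
#' @param recId record id
#' @param references,rRNA family references and rRNA decoy
#' @param clusterGap maximum gap (nt) between snoRNAs of one cluster
#' @param ... passed to \code{\link{scanSnoRNAs}}
#' @return list(snornas, introns, architecture, relocated, exonicFamilies)
#'   where \code{relocated} is a list of list(snorna, intron-or-NULL) for
#'   copies outside the main cluster
#' @export
annotateGenome <- function(genomeSeq, recId, references, rRNA,
                           clusterGap = 700L, ...) {
  snornas <- scanSnoRNAs(genomeSeq, recId, references, rRNA, ...)
  if (!length(snornas))
    return(list(snornas = list(), introns = list(), architecture = NULL,
                relocated = list(), exonicFamilies = character()))
  starts <- vapply(snornas, featureStart, 0L)
  ord <- order(starts)
  snornas <- snornas[ord]
  starts <- starts[ord]
  ends <- vapply(snornas, featureEnd, 0L)
  ## group into clusters by effective gap: the raw gap between consecutive
  ## snoRNAs minus any exact-signal introns lying in it (gained introns can
  ## widen a cluster's internal gaps; relocated units sit in plain
  ## background far from the cluster)
  effGap <- function(i) {
    gap <- starts[i + 1L] - ends[i]
    if (gap <= clusterGap) return(gap)
    hits <- detectPlainIntrons(genomeSeq, c(ends[i], starts[i + 1L]), recId,
                               margin = 0L)
    gap - sum(vapply(hits, function(h) featureEnd(h) - featureStart(h), 0L))
  }
  gaps <- if (length(snornas) > 1L)
    vapply(seq_len(length(snornas) - 1L), effGap, 0) else numeric(0L)
  grp <- cumsum(c(1L, as.integer(gaps > clusterGap)))
  sizes <- table(grp)
  main <- as.integer(names(sizes)[which.max(sizes)])
  introns <- list(); exonic <- character(); relocated <- list()
  clusterSno <- list(); clusterIntrons <- list()
  for (i in seq_along(snornas)) {
    sn <- snornas[[i]]
    prevEnd <- if (i > 1L) ends[i - 1L] else NULL
    nextStart <- if (i < length(snornas)) starts[i + 1L] else NULL
    intr <- delineateIntron(sn, genomeSeq, searchFrom = prevEnd,
                            searchTo = nextStart)
    emb <- NULL
    if (length(sn@embeddedIntron)) {
      e <- sn@embeddedIntron
      emb <- IntronAnnotation(
        recordId = recId, start = e$start, end = e$end,
        donorSeq = subseq0(genomeSeq, e$start, e$start + 6L),
        branchStart = NA_integer_, branchSeq = NA_character_,
        acceptorSeq = subseq0(genomeSeq, e$end - 2L, e$end),
        snornaFamily = NA_character_, signalScore = 15)
    }
    if (grp[i] == main) {
      clusterSno[[length(clusterSno) + 1L]] <- sn
      if (!is.null(intr))
        clusterIntrons[[length(clusterIntrons) + 1L]] <- intr
      else exonic <- c(exonic, snornaFamily(sn))
      if (!is.null(emb))
        clusterIntrons[[length(clusterIntrons) + 1L]] <- emb
    } else {
      relocated[[length(relocated) + 1L]] <- list(snorna = sn, intron = intr)
    }
  }
  clusterIntrons <- dropOverlappingIntrons(clusterIntrons)
  arch <- assembleArchitecture(genomeSeq, clusterSno, clusterIntrons,
                               clusterId = paste0(recId, "_cluster"))
  ## scan exon elements (extended outward) for gained snoRNA-free introns
  el <- elements(arch)
  gained <- list()
  for (i in seq_len(nrow(el))) {
    if (el$kind[i] != "exon") next
    lo <- el$start[i]; hi <- el$end[i]
    if (i == 1L) lo <- max(0L, lo - 300L)
    if (i == nrow(el)) hi <- min(nchar(genomeSeq), hi + 300L)
    gained <- c(gained, detectPlainIntrons(genomeSeq, c(lo, hi), recId))
  }
  if (length(gained)) {
    clusterIntrons <- dropOverlappingIntrons(c(clusterIntrons, gained))
    arch <- assembleArchitecture(genomeSeq, clusterSno, clusterIntrons,
                                 clusterId = paste0(recId, "_cluster"))
  }
  allIntrons <- c(clusterIntrons,
                  unlist(lapply(relocated, function(x)
                    if (is.null(x$intron)) NULL else list(x$intron)),
                    recursive = FALSE))
  list(snornas = snornas, introns = allIntrons, architecture = arch,
       relocated = relocated, exonicFamilies = exonic)
}
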