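## simulate_evolution: synthetic fungal-like genomes carrying a polycistronic
## box C/D snoRNA cluster, evolved along a species tree under six event
## mechanisms (de-intronization, genomic deletion loss, excision-and-
## insertion, recombination, exon loss, intron gain) plus neutral point
## mutation, with a complete ground-truth event log.
##
## Internal genome representation: an ordered list of "segments", each a
## contiguous sequence block of kind "background", "exon" or "intron".
## Intron segments carry relative feature offsets (splice signals, hosted
## snoRNA boxes/guide) and a set of mutation-protected positions. The
## cluster is the run of exon/intron segments between the two background
## flanks; excised intron units re-inserted into a flank become intron
## segments with inCluster = FALSE.

DEFAULT_TREE_12 <- paste0(
  "((((sp01,sp02),(sp03,sp04)),((sp05,sp06),(sp07,sp08))),",
  "((sp09,sp10),(sp11,sp12)));")

CLUSTER_I_FAMILIES <- c("snR78", "snR77", "snR76", "snR75", "snR74",
                        "snR73", "snR72")
CLUSTER_II_FAMILIES <- c("snR57", "snR55", "snR61")
CLUSTER_III_FAMILIES <- c("snR41", "snR70", "snR51")

#' Create a simulation configuration
#'
#' Defaults describe the study conditions used throughout this package: a
#' 12-species balanced tree, a seven-family cluster (the snR78..snR72
#' layout), snoRNAs of 70-100 nt with exact box C (TGATGA) and box D (CTGA)
#' and a 10-21 nt guide copied as the reverse complement of a decoy rRNA
#' segment, introns of 60-200 nt with canonical GTAAGT donor, TACTAAC
#' branch point and AG acceptor, exons of 5-80 nt, and 2 kb background
#' flanks. Per-branch event probabilities are small (a few percent) so that
#' a 12-leaf run accrues roughly thirty events across all six kinds; 2%
#' point mutation per branch with functional motifs protected.
#'
#' @param seed integer RNG seed
#' @param tree newick string of the rooted species tree
#' @param nSnornaFamilies number of snoRNA families
#' @param familyNames family labels 5' to 3' (defaults to the cluster I
#'   names for 7 families, cluster III names for 3)
#' @param snornaLengthRange,intronLengthRange,exonLengthRange length ranges
#' @param flankLength background nt per side
#' @param pointMutationRate substitutions per site per branch-length unit
#' @param pDeintronization,pDeletionLoss,pExcisionInsertion,pRecombination,pExonLoss,pIntronGain
#'   per-element per-branch event probabilities
#' @param residualStubLengthRange nt of 5' intron retained by deletion loss
#' @param directRepeatLengthRange planted target-site-duplication length (nt)
#' @param invertedRepeatLengthRange planted inverted-repeat arm length (nt)
#' @param spliceDonor,spliceBranch,spliceAcceptor consensus splice signals
#' @param protectMotifs protect boxes, guides, repeats and splice signals
#'   from point mutation
#' @param rRNALength length of the generated rRNA decoy
#' @return a \code{SimulationConfig}
#' @export
simulationConfig <- function(seed = 1L,
                             tree = DEFAULT_TREE_12,
                             nSnornaFamilies = 7L,
                             familyNames = NULL,
                             snornaLengthRange = c(70L, 100L),
                             intronLengthRange = c(60L, 200L),
                             exonLengthRange = c(5L, 80L),
                             flankLength = 2000L,
                             pointMutationRate = 0.02,
                             pDeintronization = 0.07,
                             pDeletionLoss = 0.07,
                             pExcisionInsertion = 0.07,
                             pRecombination = 0.06,
                             pExonLoss = 0.09,
                             pIntronGain = 0.04,
                             residualStubLengthRange = c(5L, 25L),
                             directRepeatLengthRange = c(3L, 8L),
                             invertedRepeatLengthRange = c(8L, 12L),
                             spliceDonor = "GTAAGT",
                             spliceBranch = "TACTAAC",
                             spliceAcceptor = "AG",
                             protectMotifs = TRUE,
                             rRNALength = 1500L) {
  if (is.null(familyNames)) {
    familyNames <- if (nSnornaFamilies == 7L) CLUSTER_I_FAMILIES
      else if (nSnornaFamilies == 3L) CLUSTER_III_FAMILIES
      else paste0("snF", seq_len(nSnornaFamilies))
  }
  new("SimulationConfig", seed = as.integer(seed), tree = tree,
      nSnornaFamilies = as.integer(nSnornaFamilies),
      familyNames = familyNames,
      snornaLengthRange = checkRange(snornaLengthRange, "snornaLengthRange"),
      intronLengthRange = checkRange(intronLengthRange, "intronLengthRange"),
      exonLengthRange = checkRange(exonLengthRange, "exonLengthRange"),
      flankLength = as.integer(flankLength),
      pointMutationRate = pointMutationRate,
      pDeintronization = pDeintronization, pDeletionLoss = pDeletionLoss,
      pExcisionInsertion = pExcisionInsertion, pRecombination = pRecombination,
      pExonLoss = pExonLoss, pIntronGain = pIntronGain,
      residualStubLengthRange = checkRange(residualStubLengthRange,
                                           "residualStubLengthRange"),
      directRepeatLengthRange = checkRange(directRepeatLengthRange,
                                           "directRepeatLengthRange"),
      invertedRepeatLengthRange = checkRange(invertedRepeatLengthRange,
                                             "invertedRepeatLengthRange"),
      spliceDonor = spliceDonor, spliceBranch = spliceBranch,
      spliceAcceptor = spliceAcceptor,
      protectMotifs = protectMotifs, rRNALength = as.integer(rRNALength))
}

## ---- segments -------------------------------------------------------------

.segCounter <- new.env(parent = emptyenv())
.segCounter$n <- 0L

newSegmentId <- function() {
  .segCounter$n <- .segCounter$n + 1L
  .segCounter$n
}

newSegment <- function(kind, seq, inCluster = FALSE, meta = NULL,
                       protect = integer(0L), frozen = FALSE,
                       deintronized = FALSE, gained = FALSE,
                       relocated = FALSE) {
  list(id = newSegmentId(), kind = kind, seq = seq, inCluster = inCluster,
       meta = meta, protect = as.integer(protect), frozen = frozen,
       deintronized = deintronized, gained = gained, relocated = relocated)
}

segLen <- function(seg) nchar(seg$seq)

## ---- ancestral cluster ----------------------------------------------------

## one snoRNA: 5nt leader | box C (6) | internal | guide | box D (4) |
## 5nt trailer. Returns seq, relative offsets and protected positions.
buildSnorna <- function(family, rRNA, config) {
  snoLen <- drawFromRange(config@snornaLengthRange)
  maxGuide <- min(21L, snoLen - 25L)
  guideLen <- drawFromRange(c(10L, maxGuide))
  rOff <- sample.int(nchar(rRNA) - guideLen + 1L, 1L) - 1L
  guide <- revcompChr(subseq0(rRNA, rOff, rOff + guideLen))
  internalLen <- snoLen - 5L - 6L - guideLen - 4L - 5L
  leader <- randomDNAAvoiding(5L, "TGATGA")
  internal <- randomDNAAvoiding(internalLen, c("TGATGA", "CTGA", "ATGA"))
  trailer <- randomDNAAvoiding(5L, "TGATGA")
  seq <- paste0(leader, "TGATGA", internal, guide, "CTGA", trailer)
  boxC <- 5L
  guideStart <- 5L + 6L + internalLen
  boxD <- guideStart + guideLen
  list(family = family, seq = seq, len = snoLen,
       boxCStart = boxC, boxDStart = boxD,
       guideStart = guideStart, guideEnd = boxD, guideRRNAOffset = rOff,
       protect = c(seq.int(boxC + 1L, boxC + 6L),
                   seq.int(guideStart + 1L, boxD),
                   seq.int(boxD + 1L, boxD + 4L)))
}

## one intron hosting a snoRNA:
## GTAAGT | spacer1 | snoRNA | spacer2 | TACTAAC | spacer3 (AG-free) | AG
## spacer2 and spacer3 are kept AG-free so that the acceptor is the first AG
## downstream of the branch point (the spliceosome's AG-scanning rule), and
## all spacers avoid spurious donor/branch motifs.
buildIntronAround <- function(sno, config) {
  dlen <- nchar(config@spliceDonor)
  blen <- nchar(config@spliceBranch)
  minLen <- dlen + 1L + sno$len + 1L + blen + 13L + 2L
  lo <- max(config@intronLengthRange[1L], minLen)
  hi <- config@intronLengthRange[2L]
  if (lo > hi)
    stop("config error: intronLengthRange cannot fit snoRNA plus signals")
  intronLen <- drawFromRange(c(lo, hi))
  spacer3Len <- drawFromRange(c(13L, min(38L, intronLen - dlen - sno$len -
                                           blen - 2L - 2L)))
  rem <- intronLen - dlen - sno$len - blen - spacer3Len - 2L
  spacer1Len <- drawFromRange(c(1L, rem - 1L))
  spacer2Len <- rem - spacer1Len
  spacer1 <- randomDNAAvoiding(spacer1Len,
                               c(config@spliceDonor, config@spliceBranch,
                                 "TGATGA"))
  spacer2 <- randomDNAAvoiding(spacer2Len,
                               c("AG", config@spliceDonor, config@spliceBranch))
  spacer3 <- randomDNAAvoiding(spacer3Len, c("AG", config@spliceBranch))
  seq <- paste0(config@spliceDonor, spacer1, sno$seq, spacer2,
                config@spliceBranch, spacer3, "AG")
  snoStart <- dlen + spacer1Len
  branchStart <- snoStart + sno$len + spacer2Len
  protect <- c(seq_len(dlen),                          # donor
               snoStart + sno$protect,                 # boxes + guide
               seq.int(branchStart + 1L, branchStart + blen),
               c(intronLen - 1L, intronLen))           # acceptor AG
  meta <- list(family = sno$family, snoStart = snoStart,
               snoEnd = snoStart + sno$len,
               boxCStart = snoStart + sno$boxCStart,
               boxDStart = snoStart + sno$boxDStart,
               guideStart = snoStart + sno$guideStart,
               guideEnd = snoStart + sno$guideEnd,
               guideRRNAOffset = sno$guideRRNAOffset,
               branchStart = branchStart, chimeric = list(),
               embedded = list())
  newSegment("intron", seq, inCluster = TRUE, meta = meta, protect = protect)
}

#' Build the ancestral genome carrying one polycistronic snoRNA cluster
#'
#' Constructs a genome of the form
#' flank - exon - (intron with snoRNA - exon) x nSnornaFamilies - flank,
#' where every intron carries canonical splice signals and every snoRNA
#' carries exact box C (TGATGA), box D (CTGA) and a guide element copied as
#' the reverse complement of a segment of a generated rRNA decoy. The
#' returned object is the ancestor consumed by \code{\link{evolveAlongTree}}
#' and by the forced-event operators.
#'
#' @param config a \code{SimulationConfig}
#' @return a list with components \code{genome} (named character),
#'   \code{architecture} (\code{ClusterArchitecture}), \code{snornas} and
#'   \code{introns} (truth annotation lists), \code{references} (ancestral
#'   snoRNA sequences), \code{rRNA}, \code{config}, and the internal
#'   \code{state}
#' @export
buildAncestralCluster <- function(config) {
  stopifnot(is(config, "SimulationConfig"))
  validObject(config)
  set.seed(config@seed)
  rRNA <- randomDNA(config@rRNALength)
  segs <- list()
  segs[[1L]] <- newSegment("background", randomDNA(config@flankLength))
  segs[[2L]] <- newSegment("exon", randomDNAAvoiding(
    drawFromRange(config@exonLengthRange), "TGATGA"), inCluster = TRUE)
  refs <- character(0L)
  for (fam in config@familyNames) {
    sno <- buildSnorna(fam, rRNA, config)
    refs[fam] <- sno$seq
    segs[[length(segs) + 1L]] <- buildIntronAround(sno, config)
    segs[[length(segs) + 1L]] <- newSegment(
      "exon", randomDNAAvoiding(drawFromRange(config@exonLengthRange),
                                "TGATGA"),
      inCluster = TRUE)
  }
  segs[[length(segs) + 1L]] <- newSegment("background",
                                          randomDNA(config@flankLength))
  state <- list(segments = segs)
  out <- renderState(state, recordIdOf("ancestor"), "ancestor")
  list(genome = out$genome, architecture = out$architecture,
       snornas = out$snornas, introns = out$introns,
       references = refs, rRNA = rRNA, config = config, state = state)
}

recordIdOf <- function(species) paste0(species, "_cluster_region")

## ---- rendering ------------------------------------------------------------

## turn a segment state into genome sequence + truth annotations +
## architecture for one species
renderState <- function(state, recordId, species) {
  segs <- state$segments
  seqs <- vapply(segs, `[[`, "", "seq")
  genome <- setNames(paste(seqs, collapse = ""), recordId)
  offs <- cumsum(c(0L, nchar(seqs)))
  snornas <- list(); introns <- list()
  clusterEl <- list()
  for (i in seq_along(segs)) {
    seg <- segs[[i]]
    off <- offs[i]
    len <- segLen(seg)
    isIntron <- seg$kind == "intron" && !seg$deintronized &&
      substr(seg$seq, 1L, 2L) == "GT" &&
      substr(seg$seq, len - 1L, len) == "AG"
    if (seg$kind == "intron") {
      m <- seg$meta
      if (isIntron) {
        blen <- if (!is.null(m$branchStart)) 7L else NA_integer_
        introns[[length(introns) + 1L]] <- IntronAnnotation(
          recordId = recordId, start = off, end = off + len,
          donorSeq = substr(seg$seq, 1L, 6L),
          branchStart = if (is.null(m$branchStart)) NA_integer_
                        else off + m$branchStart,
          branchSeq = if (is.null(m$branchStart)) NA_character_
                      else subseq0(seg$seq, m$branchStart, m$branchStart + 7L),
          acceptorSeq = substr(seg$seq, len - 1L, len),
          snornaFamily = if (is.null(m$family)) NA_character_ else m$family,
          signalScore = 15)
      }
      if (!is.null(m$family)) {
        emb <- list()
        if (length(m$embedded))
          emb <- list(start = off + m$embedded$start,
                      end = off + m$embedded$end)
        snornas[[length(snornas) + 1L]] <- SnoRNAAnnotation(
          recordId = recordId, start = off + m$snoStart,
          end = off + m$snoEnd, family = m$family, familyIdentity = 1,
          boxCStart = off + m$boxCStart,
          boxCSeq = subseq0(seg$seq, m$boxCStart, m$boxCStart + 6L),
          boxDStart = off + m$boxDStart,
          boxDSeq = subseq0(seg$seq, m$boxDStart, m$boxDStart + 4L),
          guideStart = off + m$guideStart, guideEnd = off + m$guideEnd,
          guideRRNAOffset = m$guideRRNAOffset,
          chimeric = m$chimeric, embeddedIntron = emb)
      }
      if (length(seg$meta$embedded)) {
        e <- seg$meta$embedded
        introns[[length(introns) + 1L]] <- IntronAnnotation(
          recordId = recordId, start = off + e$start, end = off + e$end,
          donorSeq = subseq0(seg$seq, e$start, e$start + 6L),
          branchStart = off + e$branchStart,
          branchSeq = subseq0(seg$seq, e$branchStart, e$branchStart + 7L),
          acceptorSeq = subseq0(seg$seq, e$end - 2L, e$end),
          snornaFamily = NA_character_, signalScore = 15)
      }
    }
    if (seg$inCluster) {
      kind <- if (seg$kind == "intron" && isIntron) "intron" else "exon"
      fam <- if (seg$kind == "intron" && !is.null(seg$meta$family) && isIntron)
        seg$meta$family else NA_character_
      clusterEl[[length(clusterEl) + 1L]] <-
        data.frame(kind = kind, start = off, end = off + len, family = fam,
                   stringsAsFactors = FALSE)
    }
  }
  el <- do.call(rbind, clusterEl)
  ## merge adjacent exon elements
  if (!is.null(el) && nrow(el) > 1L) {
    keep <- rep(TRUE, nrow(el))
    for (i in seq.int(2L, nrow(el))) {
      j <- max(which(keep[seq_len(i - 1L)]))
      if (el$kind[i] == "exon" && el$kind[j] == "exon") {
        el$end[j] <- el$end[i]
        keep[i] <- FALSE
      }
    }
    el <- el[keep, , drop = FALSE]
  }
  arch <- ClusterArchitecture(paste0(species, "_cluster"), recordId,
                              el %||% data.frame(kind = character(),
                                                 start = integer(),
                                                 end = integer(),
                                                 family = character()))
  list(genome = genome, snornas = snornas, introns = introns,
       architecture = arch)
}

## ---- event operators ------------------------------------------------------

clusterIntronIdx <- function(segs) {
  which(vapply(segs, function(s) s$kind == "intron" && s$inCluster &&
                 !s$deintronized, logical(1L)))
}

eligibleIntronIdx <- function(segs) {
  idx <- clusterIntronIdx(segs)
  idx[!vapply(segs[idx], `[[`, logical(1L), "frozen")]
}

## maximal runs of exonic segments strictly between two splicing-competent
## cluster introns (de-intronized introns count as exonic sequence)
internalExonRuns <- function(segs) {
  cl <- which(vapply(segs, `[[`, logical(1L), "inCluster"))
  if (!length(cl)) return(list())
  runs <- list(); cur <- integer(0L)
  sawIntron <- FALSE
  for (i in cl) {
    if (segs[[i]]$kind == "intron" && !segs[[i]]$deintronized) {
      if (length(cur) && sawIntron) runs[[length(runs) + 1L]] <- cur
      cur <- integer(0L); sawIntron <- TRUE
    } else cur <- c(cur, i)
  }
  runs
}

## record one event into the log (a data.frame accumulated as list of rows)
logEvent <- function(log, kind, branch, subject, detail = list()) {
  log[[length(log) + 1L]] <- data.frame(
    kind = kind, branch = branch, subject = subject,
    detail = as.character(jsonlite::toJSON(detail, auto_unbox = TRUE)),
    stringsAsFactors = FALSE)
  log
}

segOffsets <- function(segs) cumsum(c(0L, vapply(segs, segLen, 0L)))

doDeletionLoss <- function(state, i, config, branch, log) {
  segs <- state$segments
  seg <- segs[[i]]
  stubLen <- drawFromRange(config@residualStubLengthRange)
  stub <- substr(seg$seq, 1L, stubLen)
  offs <- segOffsets(segs)
  segs[[i]] <- newSegment("exon", stub, inCluster = seg$inCluster,
                          frozen = TRUE)
  state$segments <- segs
  log <- logEvent(log, "deletion_loss", branch, seg$meta$family,
                  list(stub = stub, stub_end = "5prime",
                       donor_interval = c(offs[i], offs[i] + segLen(seg))))
  list(state = state, log = log)
}

doExcisionInsertion <- function(state, i, config, branch, log) {
  segs <- state$segments
  seg <- segs[[i]]
  offs <- segOffsets(segs)
  donorIv <- c(offs[i], offs[i] + segLen(seg))
  w <- drawFromRange(config@directRepeatLengthRange)
  ## excise the intron unit first, then choose an insertion point in a
  ## background segment at least 900 nt from the (rejoined) cluster (well
  ## beyond the 700 nt chaining distance that delimits a cluster), at
  ## least 700 nt from any previously relocated unit (independent
  ## insertions in a real genome are effectively unlinked; the short
  ## simulated flanks must not make them adjacent), and at least w nt from
  ## the segment start. If no such site exists the event does not happen.
  segs[[i]] <- NULL
  offs <- segOffsets(segs)
  cl <- which(vapply(segs, `[[`, logical(1L), "inCluster"))
  clStart <- offs[min(cl)]; clEnd <- offs[max(cl) + 1L]
  reloc <- which(vapply(segs, `[[`, logical(1L), "relocated"))
  cand <- list()
  for (j in which(vapply(segs, function(s) s$kind == "background",
                         logical(1L)))) {
    rel <- seq.int(w, segLen(segs[[j]]))
    abs <- offs[j] + rel
    ok <- abs <= clStart - 900L | abs >= clEnd + 900L
    for (k in reloc)
      ok <- ok & (abs <= offs[k] - 700L | abs >= offs[k + 1L] + 700L)
    rel <- rel[ok]
    if (length(rel)) cand[[length(cand) + 1L]] <- list(j = j, rel = rel)
  }
  if (!length(cand)) return(NULL)
  pick <- cand[[sample.int(length(cand), 1L)]]
  p <- pick$rel[sample.int(length(pick$rel), 1L)]
  j <- pick$j
  bg <- segs[[j]]
  word <- substr(bg$seq, p - w + 1L, p)
  left <- newSegment("background", substr(bg$seq, 1L, p),
                     protect = if (config@protectMotifs)
                       seq.int(p - w + 1L, p) else integer(0L))
  unit <- seg
  unit$inCluster <- FALSE
  unit$frozen <- TRUE
  unit$relocated <- TRUE
  right <- newSegment("background",
                      paste0(word, substr(bg$seq, p + 1L, segLen(bg))),
                      protect = if (config@protectMotifs) seq_len(w)
                                else integer(0L))
  segs <- append(segs[-j], list(left, unit, right), after = j - 1L)
  state$segments <- segs
  offs2 <- segOffsets(segs)
  k <- which(vapply(segs, function(s) identical(s$id, unit$id), logical(1L)))
  log <- logEvent(log, "excision_insertion", branch, seg$meta$family,
                  list(donor_interval = donorIv,
                       target_interval = c(offs2[k], offs2[k] + segLen(unit)),
                       repeat_seq = word, repeat_length = w))
  list(state = state, log = log)
}

doRecombination <- function(state, ia, ib, config, branch, log) {
  segs <- state$segments
  A <- segs[[ia]]; B <- segs[[ib]]
  ma <- A$meta; mb <- B$meta
  if (identical(ma$family, mb$family)) stop("config error: identical families")
  ## cut the 5' parent after its box C (keeping box C + some internal
  ## sequence, before its guide) and the 3' parent symmetrically, so that
  ## the chimera keeps exactly one box C (from a), one box D and the guide
  ## (from b); each parent must contribute a substantial (>= 30 nt)
  ## segment, as in the real fusions
  bLen <- mb$snoEnd - mb$snoStart
  loA <- max(ma$boxCStart + 6L - ma$snoStart + 3L, 30L)
  hiA <- ma$guideStart - ma$snoStart - 1L
  loB <- mb$boxCStart + 6L - mb$snoStart + 3L
  hiB <- min(mb$guideStart - mb$snoStart - 1L, bLen - 30L)
  if (loA > hiA || loB > hiB) return(NULL)
  cutA <- drawFromRange(c(loA, hiA))
  cutB <- drawFromRange(c(loB, hiB))
  aEndRel <- ma$snoStart + cutA          # end of the a-derived part (rel in A)
  bFromRel <- mb$snoStart + cutB         # start of the b-derived part (rel in B)
  seq <- paste0(substr(A$seq, 1L, aEndRel),
                substr(B$seq, bFromRel + 1L, segLen(B)))
  shift <- aEndRel - bFromRel
  fam <- paste0(ma$family, "/", mb$family)
  meta <- list(family = fam, snoStart = ma$snoStart,
               snoEnd = mb$snoEnd + shift,
               boxCStart = ma$boxCStart, boxDStart = mb$boxDStart + shift,
               guideStart = mb$guideStart + shift,
               guideEnd = mb$guideEnd + shift,
               guideRRNAOffset = mb$guideRRNAOffset,
               branchStart = mb$branchStart + shift,
               chimeric = list(family5 = ma$family, family3 = mb$family,
                               breakpoint = cutA),
               embedded = list())
  protect <- c(A$protect[A$protect <= aEndRel],
               B$protect[B$protect > bFromRel] + shift)
  chim <- newSegment("intron", seq, inCluster = TRUE, meta = meta,
                     protect = protect, frozen = TRUE)
  ## replace [ia .. ib] (both introns and any intervening exons)
  segs <- append(segs[-seq.int(ia, ib)], list(chim), after = ia - 1L)
  state$segments <- segs
  log <- logEvent(log, "recombination", branch,
                  paste0(ma$family, "|", mb$family),
                  list(family5 = ma$family, family3 = mb$family,
                       breakpoint = cutA))
  list(state = state, log = log)
}

doDeintronization <- function(state, i, config, branch, log) {
  segs <- state$segments
  seg <- segs[[i]]
  m <- seg$meta
  len <- segLen(seg)
  v <- strsplit(seg$seq, "", fixed = TRUE)[[1L]]
  ## degrade donor GT, branch motif and acceptor AG
  v[1L] <- sample(setdiff(DNA_BASES, "G"), 1L)
  v[2L] <- sample(setdiff(DNA_BASES, "T"), 1L)
  bpos <- m$branchStart + sample.int(7L, 3L)
  for (p in bpos) v[p] <- sample(setdiff(DNA_BASES, v[p]), 1L)
  v[len - 1L] <- sample(setdiff(DNA_BASES, "A"), 1L)
  v[len] <- sample(setdiff(DNA_BASES, "G"), 1L)
  seg$seq <- paste(v, collapse = "")
  degraded <- c(1L, 2L, bpos, len - 1L, len)
  seg$protect <- setdiff(seg$protect, degraded)
  seg$deintronized <- TRUE
  seg$frozen <- TRUE
  segs[[i]] <- seg
  state$segments <- segs
  log <- logEvent(log, "deintronization", branch, m$family,
                  list(degraded_positions = degraded))
  list(state = state, log = log)
}

doExonLoss <- function(state, run, config, branch, log) {
  segs <- state$segments
  ## revalidate at apply time: an earlier event on this branch may have
  ## turned a flanking intron into something else
  okFlank <- function(i) {
    i >= 1L && i <= length(segs) && segs[[i]]$kind == "intron" &&
      !segs[[i]]$deintronized && !is.null(segs[[i]]$meta$family) &&
      !grepl("/", segs[[i]]$meta$family, fixed = TRUE)
  }
  if (!okFlank(min(run) - 1L) || !okFlank(max(run) + 1L)) return(NULL)
  if (!all(vapply(segs[run], function(s) s$kind != "intron" ||
                    s$deintronized, logical(1L)))) return(NULL)
  famL <- segs[[min(run) - 1L]]$meta$family %||% NA_character_
  famR <- segs[[max(run) + 1L]]$meta$family %||% NA_character_
  exonSeq <- paste(vapply(segs[run], `[[`, "", "seq"), collapse = "")
  segs <- segs[-run]
  state$segments <- segs
  log <- logEvent(log, "exon_loss", branch,
                  paste0("exon:", famL, "|", famR),
                  list(exon_length = nchar(exonSeq)))
  list(state = state, log = log)
}

## build a snoRNA-free gained intron; arm (if not NULL) is the inverted-
## repeat arm to plant near the 3' end (as given; it will sit revcomp'd
## relative to the exon-side arm which the caller guarantees)
buildGainedIntron <- function(config, armRC) {
  dlen <- nchar(config@spliceDonor); blen <- nchar(config@spliceBranch)
  L <- if (is.null(armRC)) 0L else nchar(armRC)
  intronLen <- drawFromRange(c(max(config@intronLengthRange[1L],
                                   dlen + 5L + blen + max(13L, L + 5L) + 2L),
                               config@intronLengthRange[2L]))
  spacer3Len <- drawFromRange(c(max(13L, L + 5L),
                                min(38L, intronLen - dlen - blen - 2L - 5L)))
  bodyLen <- intronLen - dlen - blen - spacer3Len - 2L
  body <- randomDNAAvoiding(bodyLen, c(config@spliceDonor, config@spliceBranch,
                                       "TGATGA"))
  armStartRel <- NA_integer_
  for (try in seq_len(100L)) {
    spacer3 <- randomDNAAvoiding(spacer3Len, c("AG", config@spliceBranch))
    if (is.null(armRC)) break
    ## plant the arm so that it ends 3 nt before the acceptor AG; the
    ## whole spacer (arm junctions included) must stay AG-free so the
    ## acceptor remains the first AG after the branch point
    s <- spacer3Len - 3L - L + 1L
    spacer3 <- paste0(substr(spacer3, 1L, s - 1L), armRC,
                      substr(spacer3, s + L, spacer3Len))
    if (!grepl("AG", spacer3, fixed = TRUE)) {
      armStartRel <- dlen + bodyLen + blen + s - 1L   # 0-based within intron
      break
    }
  }
  seq <- paste0(config@spliceDonor, body, config@spliceBranch, spacer3, "AG")
  branchStart <- dlen + bodyLen
  protect <- c(seq_len(dlen), seq.int(branchStart + 1L, branchStart + blen),
               c(intronLen - 1L, intronLen))
  if (!is.null(armRC) && !is.na(armStartRel))
    protect <- c(protect, seq.int(armStartRel + 1L, armStartRel + L))
  list(seq = seq, len = intronLen, branchStart = branchStart,
       protect = protect, armStartRel = armStartRel)
}

## choose the inverted-repeat arm ending at or just before (offset <= 3 nt)
## the 0-based insertion point p of string s; the arm's reverse complement
## must be AG-free so that the acceptor-scanning rule stays intact when the
## complement is planted near the intron's acceptor
chooseArm <- function(s, p, config) {
  for (o in 0:3) {
    for (L in sample(seq.int(config@invertedRepeatLengthRange[1L],
                             config@invertedRepeatLengthRange[2L]))) {
      if (p - o < L) next
      arm <- substr(s, p - o - L + 1L, p - o)
      if (!grepl("AG", revcompChr(arm), fixed = TRUE) &&
          !grepl("N", arm, fixed = TRUE))
        return(list(arm = arm, len = L, offset = o))
    }
  }
  L <- min(config@invertedRepeatLengthRange[1L], p)
  list(arm = substr(s, p - L + 1L, p), len = L, offset = 0L)
}

doIntronGainExon <- function(state, i, config, branch, log) {
  segs <- state$segments
  ex <- segs[[i]]
  len <- segLen(ex)
  ## the insertion point must leave >= 3 nt exon either side and enough
  ## upstream exon to host the inverted-repeat arm
  pMin <- max(3L, config@invertedRepeatLengthRange[1L])
  if (len < pMin + 3L) return(NULL)
  p <- drawFromRange(c(pMin, len - 3L))   # insertion point, 0-based offset
  offs <- segOffsets(segs)
  ## exon-side arm: the word ending at the insertion point (may reach into
  ## upstream sequence; here kept within the exon for simplicity)
  armInfo <- chooseArm(ex$seq, p, config)
  gained <- buildGainedIntron(config, revcompChr(armInfo$arm))
  leftProtect <- ex$protect[ex$protect <= p]
  if (config@protectMotifs && armInfo$len > 0L)
    leftProtect <- c(leftProtect,
                     seq.int(p - armInfo$offset - armInfo$len + 1L,
                             p - armInfo$offset))
  left <- newSegment("exon", substr(ex$seq, 1L, p), inCluster = ex$inCluster,
                     protect = leftProtect, frozen = ex$frozen)
  mid <- newSegment("intron", gained$seq, inCluster = ex$inCluster,
                    meta = list(family = NULL,
                                branchStart = gained$branchStart,
                                chimeric = list(), embedded = list(),
                                armStart = gained$armStartRel,
                                armLength = armInfo$len),
                    protect = gained$protect, frozen = TRUE, gained = TRUE)
  right <- newSegment("exon", substr(ex$seq, p + 1L, len),
                      inCluster = ex$inCluster,
                      protect = ex$protect[ex$protect > p] - p,
                      frozen = ex$frozen)
  segs <- append(segs[-i], list(left, mid, right), after = i - 1L)
  state$segments <- segs
  log <- logEvent(log, "intron_gain", branch, "gained",
                  list(target = "exon",
                       insert_point = offs[i] + p,
                       arm = armInfo$arm, arm_length = armInfo$len,
                       intron_length = gained$len))
  list(state = state, log = log)
}

doIntronGainSnorna <- function(state, i, config, branch, log) {
  segs <- state$segments
  seg <- segs[[i]]
  m <- seg$meta
  p <- m$guideEnd    # insertion point: between guide and box D
  armInfo <- chooseArm(seg$seq, p, config)   # arm = 3' end of the guide
  gained <- buildGainedIntron(config, revcompChr(armInfo$arm))
  offs <- segOffsets(segs)
  seg$seq <- paste0(substr(seg$seq, 1L, p), gained$seq,
                    substr(seg$seq, p + 1L, segLen(seg)))
  d <- gained$len
  shiftPos <- function(x) ifelse(x >= p, x + d, x)
  seg$protect <- c(ifelse(seg$protect > p, seg$protect + d, seg$protect),
                   p + gained$protect)
  m$snoEnd <- m$snoEnd + d
  m$boxDStart <- m$boxDStart + d
  m$branchStart <- m$branchStart + d
  m$embedded <- list(start = p, end = p + d,
                     branchStart = p + gained$branchStart,
                     armStart = p + gained$armStartRel,
                     armLength = armInfo$len)
  seg$meta <- m
  seg$frozen <- TRUE
  segs[[i]] <- seg
  state$segments <- segs
  log <- logEvent(log, "intron_gain", branch, "gained",
                  list(target = "snorna", family = m$family,
                       insert_point = offs[i] + p,
                       arm = armInfo$arm, arm_length = armInfo$len,
                       intron_length = gained$len))
  list(state = state, log = log)
}

## ---- forced-event public wrappers ----------------------------------------

## locate the cluster intron hosting family `family` in an ancestor-like
## object's state
findFamilyIntron <- function(state, family) {
  idx <- clusterIntronIdx(state$segments)
  for (i in idx)
    if (identical(state$segments[[i]]$meta$family, family)) return(i)
  stop("no cluster intron hosts family ", family)
}

rerender <- function(anc, res, species = "ancestor") {
  out <- renderState(res$state, recordIdOf(species), species)
  anc$state <- res$state
  anc$genome <- out$genome
  anc$architecture <- out$architecture
  anc$snornas <- out$snornas
  anc$introns <- out$introns
  anc$eventRecord <- do.call(rbind, res$log)
  anc
}

#' Force a single evolutionary event on an ancestor genome
#'
#' These operators apply one mechanistic event to the genome returned by
#' \code{\link{buildAncestralCluster}} (or to the result of a previous
#' forced event) and return the modified object together with its event
#' record (\code{$eventRecord}) and re-rendered truth annotations. They are
#' the same operators the tree simulator applies stochastically.
#'
#' \code{applyExcisionInsertion} excises the full intron unit of a family
#' (donor GT through acceptor AG, snoRNA included), joins the flanking
#' exons, and re-inserts the unit into a background flank at least 500 nt
#' from the cluster, flanked by a planted target-site duplication (direct
#' repeat). \code{applyRecombination} fuses two distinct families' introns
#' into a chimeric intron whose snoRNA keeps box C of the 5' parent and
#' guide plus box D of the 3' parent. \code{applyDeletionLoss} deletes the
#' intron and snoRNA except a residual 5' stub. \code{applyDeintronization}
#' degrades the donor, branch-point and acceptor signals in place, leaving
#' the snoRNA exonic. \code{applyExonLoss} removes an internal exon,
#' placing its two neighbour introns in juxtaposition (a complex intron).
#' \code{applyIntronGain} inserts a new snoRNA-free intron into an exon (or
#' into a snoRNA between guide and box D) and plants a short inverted
#' repeat across the insertion junction.
#'
#' @param ancestor object from \code{\link{buildAncestralCluster}}
#' @param family snoRNA family whose intron is targeted
#' @param config the \code{SimulationConfig}
#' @param branch branch label recorded in the event log
#' @return the modified ancestor object (see
#'   \code{\link{buildAncestralCluster}}) with an \code{eventRecord}
#' @export
applyExcisionInsertion <- function(ancestor, family, config = ancestor$config,
                                   branch = "forced") {
  i <- findFamilyIntron(ancestor$state, family)
  res <- doExcisionInsertion(ancestor$state, i, config, branch, list())
  if (is.null(res))
    stop("simulation error: no insertion site far enough from the cluster")
  rerender(ancestor, res)
}

#' @rdname applyExcisionInsertion
#' @param familyA,familyB the 5' and 3' parent families to recombine
#' @export
applyRecombination <- function(ancestor, familyA, familyB,
                               config = ancestor$config, branch = "forced") {
  if (identical(familyA, familyB))
    stop("config error: recombination requires two distinct families")
  ia <- findFamilyIntron(ancestor$state, familyA)
  ib <- findFamilyIntron(ancestor$state, familyB)
  if (ia > ib) stop("familyA must lie 5' of familyB")
  res <- doRecombination(ancestor$state, ia, ib, config, branch, list())
  if (is.null(res))
    stop("families cannot be recombined: segments too short")
  rerender(ancestor, res)
}

#' @rdname applyExcisionInsertion
#' @export
applyDeletionLoss <- function(ancestor, family, config = ancestor$config,
                              branch = "forced") {
  i <- findFamilyIntron(ancestor$state, family)
  res <- doDeletionLoss(ancestor$state, i, config, branch, list())
  rerender(ancestor, res)
}

#' @rdname applyExcisionInsertion
#' @export
applyDeintronization <- function(ancestor, family, config = ancestor$config,
                                 branch = "forced") {
  i <- findFamilyIntron(ancestor$state, family)
  res <- doDeintronization(ancestor$state, i, config, branch, list())
  rerender(ancestor, res)
}

#' @rdname applyExcisionInsertion
#' @param exonIndex 1-based index among internal exons (between introns)
#' @export
applyExonLoss <- function(ancestor, exonIndex, config = ancestor$config,
                          branch = "forced") {
  runs <- internalExonRuns(ancestor$state$segments)
  if (exonIndex < 1L || exonIndex > length(runs))
    stop("exon loss targets internal exons only; have ", length(runs))
  res <- doExonLoss(ancestor$state, runs[[exonIndex]], config, branch, list())
  rerender(ancestor, res)
}

#' @rdname applyExcisionInsertion
#' @param target "exon" (with \code{exonIndex} counting all cluster exons)
#'   or a snoRNA family name (insertion between guide and box D)
#' @export
applyIntronGain <- function(ancestor, target = "exon", exonIndex = 1L,
                            config = ancestor$config, branch = "forced") {
  if (identical(target, "exon")) {
    ex <- which(vapply(ancestor$state$segments, function(s)
      s$kind == "exon" && s$inCluster && !s$frozen, logical(1L)))
    if (exonIndex < 1L || exonIndex > length(ex)) stop("no such exon")
    res <- doIntronGainExon(ancestor$state, ex[exonIndex], config, branch,
                            list())
    if (is.null(res)) stop("exon too short to accept an intron")
  } else {
    i <- findFamilyIntron(ancestor$state, target)
    res <- doIntronGainSnorna(ancestor$state, i, config, branch, list())
  }
  rerender(ancestor, res)
}

## ---- evolution along the tree ---------------------------------------------

## draw and apply this branch's events, then point mutations
evolveBranch <- function(state, branchLen, branch, config, log) {
  segs <- state$segments
  events <- list()   # list of list(priority, type, ids, payload)
  intr <- eligibleIntronIdx(segs)
  ids <- function(ix) vapply(segs[ix], `[[`, 0L, "id")
  for (i in intr) {
    if (runif(1L) < config@pDeletionLoss)
      events[[length(events) + 1L]] <- list(pri = 1L, type = "deletion_loss",
                                            ids = ids(i), i = i)
    if (runif(1L) < config@pExcisionInsertion)
      events[[length(events) + 1L]] <- list(pri = 3L, type = "excision_insertion",
                                            ids = ids(i), i = i)
    if (runif(1L) < config@pDeintronization)
      events[[length(events) + 1L]] <- list(pri = 4L, type = "deintronization",
                                            ids = ids(i), i = i)
    if (runif(1L) < config@pIntronGain)
      events[[length(events) + 1L]] <- list(pri = 5L, type = "intron_gain_sno",
                                            ids = ids(i), i = i)
  }
  ## adjacent eligible intron pairs (at most one exon run between, both
  ## non-chimeric hosts of distinct families)
  if (length(intr) > 1L) {
    for (k in seq_len(length(intr) - 1L)) {
      ia <- intr[k]; ib <- intr[k + 1L]
      between <- if (ib > ia + 1L) seq.int(ia + 1L, ib - 1L) else integer(0L)
      if (any(vapply(segs[between], function(s) s$kind != "exon", logical(1L))))
        next
      if (any(vapply(segs[between], `[[`, logical(1L), "frozen"))) next
      famA <- segs[[ia]]$meta$family; famB <- segs[[ib]]$meta$family
      if (is.null(famA) || is.null(famB) || identical(famA, famB)) next
      if (length(segs[[ia]]$meta$chimeric) || length(segs[[ib]]$meta$chimeric))
        next
      if (runif(1L) < config@pRecombination)
        events[[length(events) + 1L]] <- list(pri = 2L, type = "recombination",
                                              ids = ids(c(ia, ib, between)),
                                              ia = ia, ib = ib)
    }
  }
  exIdx <- which(vapply(segs, function(s)
    s$kind == "exon" && s$inCluster && !s$frozen, logical(1L)))
  for (i in exIdx)
    if (runif(1L) < config@pIntronGain)
      events[[length(events) + 1L]] <- list(pri = 5L, type = "intron_gain_exon",
                                            ids = ids(i), i = i)
  plainFamily <- function(seg) {
    f <- seg$meta$family
    !is.null(f) && !grepl("/", f, fixed = TRUE)
  }
  for (run in internalExonRuns(segs)) {
    if (any(vapply(segs[run], `[[`, logical(1L), "frozen"))) next
    ## only exons whose loss juxtaposes two snoRNA-family introns (the
    ## phenomenon scored comparatively) are eligible
    if (!plainFamily(segs[[min(run) - 1L]]) ||
        !plainFamily(segs[[max(run) + 1L]])) next
    if (runif(1L) < config@pExonLoss)
      events[[length(events) + 1L]] <- list(pri = 6L, type = "exon_loss",
                                            ids = ids(run), run = run)
  }
  ## resolve conflicts by fixed priority, at most one event per element
  if (length(events)) {
    ord <- order(vapply(events, `[[`, 0L, "pri"))
    used <- integer(0L)
    for (e in events[ord]) {
      if (any(e$ids %in% used)) next
      used <- c(used, e$ids)
      ## re-locate elements by id (indices shift as events are applied)
      segsNow <- state$segments
      locate <- function(id) {
        hit <- which(vapply(segsNow, function(s) identical(s$id, id),
                            logical(1L)))
        if (length(hit)) hit else NA_integer_
      }
      res <- switch(e$type,
        deletion_loss = {
          i <- locate(e$ids[1L]); if (is.na(i)) NULL
          else doDeletionLoss(state, i, config, branch, log)
        },
        recombination = {
          ia <- locate(e$ids[1L]); ib <- locate(e$ids[2L])
          if (is.na(ia) || is.na(ib)) NULL
          else doRecombination(state, ia, ib, config, branch, log)
        },
        excision_insertion = {
          i <- locate(e$ids[1L]); if (is.na(i)) NULL
          else doExcisionInsertion(state, i, config, branch, log)
        },
        deintronization = {
          i <- locate(e$ids[1L]); if (is.na(i)) NULL
          else doDeintronization(state, i, config, branch, log)
        },
        intron_gain_sno = {
          i <- locate(e$ids[1L]); if (is.na(i)) NULL
          else doIntronGainSnorna(state, i, config, branch, log)
        },
        intron_gain_exon = {
          i <- locate(e$ids[1L]); if (is.na(i)) NULL
          else doIntronGainExon(state, i, config, branch, log)
        },
        exon_loss = {
          run <- vapply(e$ids, locate, 0L)
          if (any(is.na(run))) NULL
          else doExonLoss(state, run, config, branch, log)
        })
      if (!is.null(res)) { state <- res$state; log <- res$log }
    }
  }
  if (!length(clusterIntronIdx(state$segments)))
    warning("cluster emptied of introns on branch ", branch)
  ## neutral point mutation outside protected positions
  p <- config@pointMutationRate * branchLen
  if (p > 0) {
    segs <- state$segments
    for (i in seq_along(segs)) {
      n <- segLen(segs[[i]])
      if (n == 0L) next
      prot <- if (config@protectMotifs) segs[[i]]$protect else integer(0L)
      pos <- setdiff(which(runif(n) < p), prot)
      if (length(pos))
        segs[[i]]$seq <- substitutePositions(segs[[i]]$seq, pos)
    }
    state$segments <- segs
  }
  list(state = state, log = log)
}

#' Evolve the ancestral cluster along the species tree
#'
#' Pre-order traversal from the root: on each branch every applicable
#' element independently suffers each event with its configured
#' probability (conflicts resolved by the fixed priority deletion >
#' recombination > excision-insertion > de-intronization > intron gain >
#' exon loss, at most one event per element per branch; an element changed
#' by an event is inert in its descendants), then point mutations are
#' applied outside protected motif positions. Branch lengths absent from
#' the tree are treated as 1.
#'
#' @param ancestor object from \code{\link{buildAncestralCluster}}
#' @param config a \code{SimulationConfig}
#' @return a \code{SimulationResult}
#' @export
evolveAlongTree <- function(ancestor, config = ancestor$config) {
  tree <- readSpeciesTreeText(config@tree)
  if (length(tree$tip.label) < 2L) stop("tree must have >= 2 leaves")
  set.seed(config@seed + 1000L)
  nTip <- length(tree$tip.label)
  labelOf <- function(node) if (node <= nTip) tree$tip.label[node]
                            else tree$node.label[node - nTip]
  edgeLen <- tree$edge.length %||% rep(1, nrow(tree$edge))
  root <- nTip + 1L
  states <- list(); states[[as.character(root)]] <- ancestor$state
  log <- list()
  leaves <- list()
  ## pre-order: parents always precede children in ape's default edge order
  ## after reorder(tree, "cladewise")
  tr <- ape::reorder.phylo(tree, "cladewise")
  el <- tr$edge.length %||% rep(1, nrow(tr$edge))
  for (r in seq_len(nrow(tr$edge))) {
    parent <- tr$edge[r, 1L]; child <- tr$edge[r, 2L]
    res <- evolveBranch(states[[as.character(parent)]], el[r],
                        labelOf(child), config, log)
    log <- res$log
    if (child <= nTip) leaves[[tree$tip.label[child]]] <- res$state
    else states[[as.character(child)]] <- res$state
  }
  genomes <- character(0L); annotations <- list(); architectures <- list()
  for (sp in tree$tip.label) {
    out <- renderState(leaves[[sp]], recordIdOf(sp), sp)
    genomes[sp] <- out$genome
    annotations[[sp]] <- list(snornas = out$snornas, introns = out$introns)
    architectures[[sp]] <- out$architecture
  }
  eventLog <- if (length(log)) do.call(rbind, log)
    else data.frame(kind = character(), branch = character(),
                    subject = character(), detail = character(),
                    stringsAsFactors = FALSE)
  new("SimulationResult", genomes = genomes, tree = tree,
      annotations = annotations, architectures = architectures,
      eventLog = eventLog, references = ancestor$references,
      rRNA = ancestor$rRNA, config = config)
}

#' Run a full simulation (ancestor + evolution) from a configuration
#'
#' @param config a \code{SimulationConfig}
#' @return a \code{SimulationResult}
#' @export
simulateEvolution <- function(config) {
  evolveAlongTree(buildAncestralCluster(config), config)
}

## ---- transcripts ----------------------------------------------------------

#' Simulate spliced transcripts from a cluster
#'
#' In \code{"stepwise"} mode every transcript's removed-intron set is a
#' 5'-contiguous prefix of the intron order (the empty set and the full set
#' included), sampled with \code{prefixWeights}; in \code{"violation"} mode
#' removed sets are sampled from all subsets and at least one transcript is
#' guaranteed to remove an intron while retaining a more-5' one.
#' Substitution errors are added at \code{errorRate} per site.
#'
#' @param genome named character vector holding the architecture's record
#' @param architecture a \code{ClusterArchitecture} with >= 1 intron
#' @param mode "stepwise" or "violation"
#' @param n number of transcripts
#' @param seed RNG seed
#' @param prefixWeights numeric weights over removed-prefix sizes 0..k
#'   (default: equal weight on each non-empty prefix, none on unspliced)
#' @param errorRate per-site substitution error rate
#' @return list with \code{transcripts} (named character vector) and
#'   \code{truth} (data.frame transcript_id, removed)
#' @export
simulateTranscripts <- function(genome, architecture,
                                mode = c("stepwise", "violation"),
                                n = 100L, seed = 1L, prefixWeights = NULL,
                                errorRate = 0) {
  mode <- match.arg(mode)
  if (n <= 0L) stop("n must be positive")
  el <- elements(architecture)
  iv <- el[el$kind == "intron", , drop = FALSE]
  k <- nrow(iv)
  if (k < 1L) stop("architecture has no introns")
  seq <- genome[[recordId(architecture)]]
  set.seed(seed)
  if (is.null(prefixWeights)) prefixWeights <- c(0, rep(1, k))
  stopifnot(length(prefixWeights) == k + 1L)
  span <- c(min(el$start), max(el$end))
  spliceOut <- function(removed) {
    keep <- character(0L)
    pos <- span[1L]
    for (j in seq_len(k)) {
      if (j %in% removed) {
        keep <- c(keep, subseq0(seq, pos, iv$start[j]))
        pos <- iv$end[j]
      }
    }
    paste0(paste(keep, collapse = ""), subseq0(seq, pos, span[2L]))
  }
  removedSets <- vector("list", n)
  if (mode == "stepwise") {
    m <- sample.int(k + 1L, n, replace = TRUE, prob = prefixWeights) - 1L
    for (t in seq_len(n)) removedSets[[t]] <- seq_len(m[t])
  } else {
    allSubsets <- lapply(seq_len(2L^k) - 1L, function(b)
      which(bitwAnd(b, 2L^(seq_len(k) - 1L)) > 0L))
    isPrefix <- vapply(allSubsets, function(s)
      length(s) == 0L || identical(s, seq_len(max(s))), logical(1L))
    pick <- sample.int(length(allSubsets), n, replace = TRUE)
    if (!any(!isPrefix[pick]))
      pick[1L] <- which(!isPrefix)[sample.int(sum(!isPrefix), 1L)]
    removedSets <- allSubsets[pick]
  }
  tx <- vapply(seq_len(n), function(t) {
    s <- spliceOut(removedSets[[t]])
    if (errorRate > 0) {
      pos <- which(runif(nchar(s)) < errorRate)
      if (length(pos)) s <- substitutePositions(s, pos)
    }
    s
  }, "")
  ids <- sprintf("tx%04d", seq_len(n))
  list(transcripts = setNames(tx, ids),
       truth = data.frame(transcript_id = ids,
                          removed = vapply(removedSets, paste, "",
                                           collapse = ","),
                          stringsAsFactors = FALSE))
}
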