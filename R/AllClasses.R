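#' @import methods
#' @importFrom stats runif rbinom setNames
#' @importFrom utils head tail as.roman
NULL

setOldClass("phylo")

#' SnoRNAAnnotation: a located box C/D snoRNA
#'
#' A box C/D snoRNA located on a genome record, with its box C and box D
#' motifs, the antisense guide element (the segment whose reverse complement
#' pairs with rRNA to direct 2'-O-ribose methylation), a family label
#' assigned against reference snoRNAs, and an optional chimeric split when
#' the snoRNA is a fusion of two parental families. All coordinates are
#' 0-based half-open on the forward strand of the named record.
#'
#' @slot recordId genome record identifier
#' @slot start,end snoRNA interval, 0-based half-open
#' @slot family family label (e.g. "snR78") or "novel"
#' @slot familyIdentity global-alignment identity against the best family
#'   reference, in \[0, 1\]
#' @slot boxCStart,boxCSeq box C position and sequence (consensus TGATGA)
#' @slot boxDStart,boxDSeq box D position and sequence (CTGA or ATGA)
#' @slot guideStart,guideEnd guide element interval; \code{NA} if no guide
#'   was found
#' @slot guideRRNAOffset 0-based offset of the matched rRNA window
#' @slot chimeric empty list, or \code{list(family5, family3, breakpoint)}
#'   where breakpoint is the 0-based position within the snoRNA at which the
#'   3' parent begins
#' @slot embeddedIntron empty list, or \code{list(start, end)} giving a
#'   gained intron inserted inside the snoRNA (between guide and box D)
#' @export
setClass("SnoRNAAnnotation",
  representation(recordId = "character", start = "integer", end = "integer",
                 family = "character", familyIdentity = "numeric",
                 boxCStart = "integer", boxCSeq = "character",
                 boxDStart = "integer", boxDSeq = "character",
                 guideStart = "integer", guideEnd = "integer",
                 guideRRNAOffset = "integer",
                 chimeric = "list", embeddedIntron = "list"),
  prototype(familyIdentity = NA_real_, guideStart = NA_integer_,
            guideEnd = NA_integer_, guideRRNAOffset = NA_integer_,
            chimeric = list(), embeddedIntron = list()))

setValidity("SnoRNAAnnotation", function(object) {
  msg <- character()
  if (object@end <= object@start) msg <- c(msg, "end must exceed start")
  if (object@boxCStart < object@start || object@boxCStart + nchar(object@boxCSeq) > object@end)
    msg <- c(msg, "box C outside snoRNA interval")
  if (object@boxDStart < object@start || object@boxDStart + nchar(object@boxDSeq) > object@end)
    msg <- c(msg, "box D outside snoRNA interval")
  if (object@boxDStart <= object@boxCStart)
    msg <- c(msg, "box C must precede box D")
  if (object@boxCStart - object@start > 10L)
    msg <- c(msg, "box C must lie within 10 nt of the 5' end")
  if (object@end - (object@boxDStart + nchar(object@boxDSeq)) > 10L)
    msg <- c(msg, "box D must lie within 10 nt of the 3' end")
  if (!is.na(object@guideStart)) {
    if (object@guideEnd <= object@guideStart)
      msg <- c(msg, "guide end must exceed guide start")
    lim <- if (length(object@embeddedIntron)) object@embeddedIntron$start
           else object@boxDStart
    if (object@guideEnd > lim)
      msg <- c(msg, "guide must lie 5' of box D")
  }
  if (length(object@chimeric)) {
    if (!all(c("family5", "family3", "breakpoint") %in% names(object@chimeric)))
      msg <- c(msg, "chimeric must carry family5, family3, breakpoint")
    else if (identical(object@chimeric$family5, object@chimeric$family3))
      msg <- c(msg, "chimeric families must differ")
  }
  if (length(msg)) msg else TRUE
})

#' IntronAnnotation: a located spliceosomal intron
#'
#' An intron delineated from canonical splice signals: a GT-initial donor,
#' a branch-point motif upstream of the acceptor, and an AG-terminal
#' acceptor. Coordinates are 0-based half-open.
#'
#' @slot recordId genome record identifier
#' @slot start,end intron interval, 0-based half-open
#' @slot donorSeq first nucleotides of the intron (scored against GTAAGT)
#' @slot branchStart,branchSeq branch-point motif position and sequence
#' @slot acceptorSeq last 2 nt of the intron
#' @slot snornaFamily family of the contained snoRNA, or \code{NA} for a
#'   snoRNA-free intron
#' @slot signalScore combined donor + branch + acceptor match score
#' @export
setClass("IntronAnnotation",
  representation(recordId = "character", start = "integer", end = "integer",
                 donorSeq = "character", branchStart = "integer",
                 branchSeq = "character", acceptorSeq = "character",
                 snornaFamily = "character", signalScore = "numeric"),
  prototype(snornaFamily = NA_character_, signalScore = NA_real_))

setValidity("IntronAnnotation", function(object) {
  msg <- character()
  if (object@end <= object@start) msg <- c(msg, "end must exceed start")
  if (substr(object@donorSeq, 1L, 2L) != "GT")
    msg <- c(msg, "canonical donor must start GT")
  if (object@acceptorSeq != "AG")
    msg <- c(msg, "canonical acceptor must be AG")
  if (!is.na(object@branchStart) &&
      (object@branchStart < object@start || object@branchStart >= object@end))
    msg <- c(msg, "branch point must lie within the intron")
  if (length(msg)) msg else TRUE
})

#' ClusterArchitecture: the exon/intron layout of one polycistronic cluster
#'
#' The ordered exon/intron tiling of one polycistronic snoRNA cluster in one
#' genome. Elements tile a contiguous region: each element's start equals
#' the previous element's end. Intron elements may carry the family of their
#' hosted snoRNA. Intron order indices run 1-based 5' to 3'.
#'
#' @slot clusterId cluster identifier
#' @slot recordId genome record identifier
#' @slot elements data.frame with columns kind ("exon"/"intron"), start,
#'   end (0-based half-open), family (NA for exons and snoRNA-free introns)
#' @export
setClass("ClusterArchitecture",
  representation(clusterId = "character", recordId = "character",
                 elements = "data.frame"))

setValidity("ClusterArchitecture", function(object) {
  el <- object@elements
  msg <- character()
  need <- c("kind", "start", "end", "family")
  if (!all(need %in% names(el))) return("elements must have kind/start/end/family")
  if (nrow(el)) {
    if (!all(el$kind %in% c("exon", "intron")))
      msg <- c(msg, "element kinds must be exon or intron")
    if (any(el$end <= el$start)) msg <- c(msg, "empty elements not allowed")
    if (nrow(el) > 1L && any(el$start[-1L] != el$end[-nrow(el)]))
      msg <- c(msg, "elements must tile contiguously (adjacent boundaries shared)")
  }
  if (length(msg)) msg else TRUE
})

#' PresenceAbsenceMatrix: intron orthology states across species
#'
#' Rows are intron orthology groups (keyed by snoRNA family, or a gained-
#' intron group id); columns are species. Cell states are one of
#' "intronic", "exonic", "absent", "relocated", "chimeric", "unknown".
#'
#' @slot states character matrix, rownames = groups, colnames = species
#' @slot evidence named list of per-cell evidence records
#' @export
setClass("PresenceAbsenceMatrix",
  representation(states = "matrix", evidence = "list"))

setValidity("PresenceAbsenceMatrix", function(object) {
  ok <- c("intronic", "exonic", "absent", "relocated", "chimeric", "unknown",
          "present")
  if (!all(object@states %in% ok))
    return(paste("invalid cell states:",
                 paste(setdiff(unique(c(object@states)), ok), collapse = ",")))
  if (anyDuplicated(rownames(object@states)))
    return("each orthology group keys at most one row")
  TRUE
})

#' EvolutionEvent: one mechanistically classified architectural change
#'
#' @slot kind one of deintronization, deletion_loss, excision_insertion,
#'   recombination, exon_loss, intron_gain
#' @slot branch tree edge on which the change is placed, named by its child
#'   node label
#' @slot subject snoRNA family, exon key ("exon:famA|famB"), or gained-
#'   intron group id
#' @slot evidenceType e.g. "stub_alignment", "relocated_locus",
#'   "degraded_signals", "chimera_split", "junction_repeats", "none"
#' @slot evidence typed evidence record (list)
#' @slot confidence "supported" (sequence-level evidence) or "inferred"
#'   (state change alone)
#' @export
setClass("EvolutionEvent",
  representation(kind = "character", branch = "character",
                 subject = "character", evidenceType = "character",
                 evidence = "list", confidence = "character"),
  prototype(evidenceType = "none", evidence = list(), confidence = "inferred"))

EVENT_KINDS <- c("deintronization", "deletion_loss", "excision_insertion",
                 "recombination", "exon_loss", "intron_gain")

setValidity("EvolutionEvent", function(object) {
  msg <- character()
  if (!object@kind %in% EVENT_KINDS)
    msg <- c(msg, paste("kind must be one of", paste(EVENT_KINDS, collapse = ", ")))
  if (!object@confidence %in% c("supported", "inferred"))
    msg <- c(msg, "confidence must be supported or inferred")
  if (length(msg)) msg else TRUE
})

#' JunctionRepeat: a short direct or inverted repeat at an insertion junction
#'
#' @slot kind "direct" or "inverted"
#' @slot armLength repeat arm length in nt
#' @slot arm1Start,arm1Seq first arm (exon/flank side), 0-based within the
#'   sequence it was searched in
#' @slot arm2Start,arm2Seq second arm (insert/intron side)
#' @slot mismatches number of mismatching positions between the arms (after
#'   reverse complement for inverted repeats)
#' @export
setClass("JunctionRepeat",
  representation(kind = "character", armLength = "integer",
                 arm1Start = "integer", arm1Seq = "character",
                 arm2Start = "integer", arm2Seq = "character",
                 mismatches = "integer"))

setValidity("JunctionRepeat", function(object) {
  msg <- character()
  if (!object@kind %in% c("direct", "inverted"))
    msg <- c(msg, "kind must be direct or inverted")
  if (nchar(object@arm1Seq) != object@armLength ||
      nchar(object@arm2Seq) != object@armLength)
    msg <- c(msg, "arm sequences must have length armLength")
  expected <- if (identical(object@kind, "direct")) object@arm2Seq
              else revcompChr(object@arm2Seq)
  if (countMismatches(object@arm1Seq, expected) != object@mismatches)
    msg <- c(msg, "mismatch count inconsistent with arm sequences")
  if (length(msg)) msg else TRUE
})

#' SplicedProduct: one transcript's removed/retained intron sets
#'
#' @slot transcriptId transcript identifier
#' @slot clusterId cluster identifier
#' @slot removed 1-based indices (5' to 3') of introns removed by splicing
#' @slot retained indices of introns retained
#' @slot mismatches alignment mismatches (substitutions + indel nt) of the
#'   best splicing hypothesis
#' @slot classification e.g. "I_removed", "I+II_removed", "all_removed",
#'   "unspliced", "other"
#' @export
setClass("SplicedProduct",
  representation(transcriptId = "character", clusterId = "character",
                 removed = "integer", retained = "integer",
                 mismatches = "integer", classification = "character"))

setValidity("SplicedProduct", function(object) {
  if (length(intersect(object@removed, object@retained)))
    return("removed and retained intron sets must be disjoint")
  TRUE
})

#' SimulationConfig: parameters of the synthetic-evolution simulator
#'
#' See \code{\link{simulationConfig}} for defaults and units.
#'
#' @slot seed integer RNG seed
#' @slot tree newick string of the rooted species tree
#' @slot nSnornaFamilies number of snoRNA families in the ancestral cluster
#' @slot familyNames family labels, 5' to 3'
#' @slot snornaLengthRange,intronLengthRange,exonLengthRange length ranges (nt)
#' @slot flankLength nt of background sequence either side of the cluster
#' @slot pointMutationRate substitutions per site per unit branch length
#' @slot pDeintronization,pDeletionLoss,pExcisionInsertion,pRecombination,pExonLoss,pIntronGain
#'   per-element per-branch event probabilities
#' @slot residualStubLengthRange nt of intron retained after deletion loss
#' @slot directRepeatLengthRange,invertedRepeatLengthRange planted repeat arm
#'   length ranges (nt)
#' @slot spliceDonor,spliceBranch,spliceAcceptor consensus splice signals
#' @slot protectMotifs protect boxes, guides and splice signals from point
#'   mutation
#' @slot rRNALength length of the generated rRNA decoy (nt)
#' @export
setClass("SimulationConfig",
  representation(seed = "integer", tree = "character",
                 nSnornaFamilies = "integer", familyNames = "character",
                 snornaLengthRange = "integer", intronLengthRange = "integer",
                 exonLengthRange = "integer", flankLength = "integer",
                 pointMutationRate = "numeric",
                 pDeintronization = "numeric", pDeletionLoss = "numeric",
                 pExcisionInsertion = "numeric", pRecombination = "numeric",
                 pExonLoss = "numeric", pIntronGain = "numeric",
                 residualStubLengthRange = "integer",
                 directRepeatLengthRange = "integer",
                 invertedRepeatLengthRange = "integer",
                 spliceDonor = "character", spliceBranch = "character",
                 spliceAcceptor = "character",
                 protectMotifs = "logical", rRNALength = "integer"))

setValidity("SimulationConfig", function(object) {
  msg <- character()
  for (nm in c("snornaLengthRange", "intronLengthRange", "exonLengthRange",
               "residualStubLengthRange", "directRepeatLengthRange",
               "invertedRepeatLengthRange")) {
    r <- slot(object, nm)
    if (length(r) != 2L || any(is.na(r)) || r[1L] > r[2L] || r[1L] < 0L)
      msg <- c(msg, paste0("'", nm, "' must be a range c(low, high), low <= high"))
  }
  probs <- c(object@pDeintronization, object@pDeletionLoss,
             object@pExcisionInsertion, object@pRecombination,
             object@pExonLoss, object@pIntronGain)
  if (any(is.na(probs)) || any(probs < 0) || any(probs > 1))
    msg <- c(msg, "event probabilities must lie in [0, 1]")
  if (is.na(object@pointMutationRate) || object@pointMutationRate < 0 ||
      object@pointMutationRate > 1)
    msg <- c(msg, "pointMutationRate must lie in [0, 1]")
  if (length(object@familyNames) != object@nSnornaFamilies)
    msg <- c(msg, "familyNames must have length nSnornaFamilies")
  if (substr(object@spliceDonor, 1L, 2L) != "GT")
    msg <- c(msg, "spliceDonor must start GT")
  if (substr(object@spliceAcceptor,
             nchar(object@spliceAcceptor) - 1L, nchar(object@spliceAcceptor)) != "AG")
    msg <- c(msg, "spliceAcceptor must end AG")
  ## the intron must be able to hold a snoRNA plus its signals
  need <- object@snornaLengthRange[1L] + nchar(object@spliceDonor) +
    nchar(object@spliceBranch) + nchar(object@spliceAcceptor) + 2L + 5L
  if (object@intronLengthRange[2L] < need)
    msg <- c(msg, paste0("intronLengthRange cannot fit a snoRNA plus splice ",
                         "signals (need at least ", need, " nt)"))
  if (length(msg)) msg else TRUE
})

#' SimulationResult: genomes, truth annotations and event log of one run
#'
#' @slot genomes named character vector of per-species genome sequences
#' @slot tree rooted species tree (ape phylo) with internal node labels
#' @slot annotations per-species list with components \code{snornas} and
#'   \code{introns} (lists of annotation objects) — the ground truth
#' @slot architectures per-species \code{ClusterArchitecture} ground truth
#' @slot eventLog data.frame of true events (kind, branch, subject, ...)
#' @slot references ancestral snoRNA reference sequences (named character)
#' @slot rRNA the rRNA decoy sequence the guides were drawn from
#' @slot config the \code{SimulationConfig} used
#' @export
setClass("SimulationResult",
  representation(genomes = "character", tree = "phylo",
                 annotations = "list", architectures = "list",
                 eventLog = "data.frame", references = "character",
                 rRNA = "character", config = "SimulationConfig"))
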