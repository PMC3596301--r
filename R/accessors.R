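## Constructors, accessors and show() methods for the core classes.

#' Construct a SnoRNAAnnotation
#'
#' @param recordId,start,end location (0-based half-open)
#' @param family,familyIdentity family assignment
#' @param boxCStart,boxCSeq,boxDStart,boxDSeq box motifs
#' @param guideStart,guideEnd,guideRRNAOffset guide element, NA if none
#' @param chimeric,embeddedIntron optional structures (lists)
#' @return a \code{SnoRNAAnnotation}
#' @export
SnoRNAAnnotation <- function(recordId, start, end, family = "novel",
                             familyIdentity = NA_real_,
                             boxCStart, boxCSeq, boxDStart, boxDSeq,
                             guideStart = NA_integer_, guideEnd = NA_integer_,
                             guideRRNAOffset = NA_integer_,
                             chimeric = list(), embeddedIntron = list()) {
  new("SnoRNAAnnotation", recordId = as.character(recordId),
      start = as.integer(start), end = as.integer(end),
      family = as.character(family), familyIdentity = as.numeric(familyIdentity),
      boxCStart = as.integer(boxCStart), boxCSeq = as.character(boxCSeq),
      boxDStart = as.integer(boxDStart), boxDSeq = as.character(boxDSeq),
      guideStart = as.integer(guideStart), guideEnd = as.integer(guideEnd),
      guideRRNAOffset = as.integer(guideRRNAOffset),
      chimeric = chimeric, embeddedIntron = embeddedIntron)
}

#' Construct an IntronAnnotation
#'
#' @param recordId,start,end location (0-based half-open)
#' @param donorSeq,branchStart,branchSeq,acceptorSeq splice signals
#' @param snornaFamily contained snoRNA family or NA
#' @param signalScore combined signal score
#' @return an \code{IntronAnnotation}
#' @export
IntronAnnotation <- function(recordId, start, end, donorSeq,
                             branchStart = NA_integer_, branchSeq = NA_character_,
                             acceptorSeq = "AG", snornaFamily = NA_character_,
                             signalScore = NA_real_) {
  new("IntronAnnotation", recordId = as.character(recordId),
      start = as.integer(start), end = as.integer(end),
      donorSeq = as.character(donorSeq), branchStart = as.integer(branchStart),
      branchSeq = as.character(branchSeq), acceptorSeq = as.character(acceptorSeq),
      snornaFamily = as.character(snornaFamily),
      signalScore = as.numeric(signalScore))
}

#' Construct a ClusterArchitecture
#'
#' @param clusterId,recordId identifiers
#' @param elements data.frame(kind, start, end, family)
#' @return a \code{ClusterArchitecture}
#' @export
ClusterArchitecture <- function(clusterId, recordId, elements) {
  elements$kind <- as.character(elements$kind)
  elements$start <- as.integer(elements$start)
  elements$end <- as.integer(elements$end)
  elements$family <- as.character(elements$family)
  rownames(elements) <- NULL
  new("ClusterArchitecture", clusterId = as.character(clusterId),
      recordId = as.character(recordId), elements = elements)
}

#' Construct an EvolutionEvent
#'
#' @param kind event mechanism
#' @param branch child-node label of the tree edge
#' @param subject affected family / exon key / gained-intron id
#' @param evidenceType,evidence,confidence evidence record
#' @return an \code{EvolutionEvent}
#' @export
EvolutionEvent <- function(kind, branch, subject, evidenceType = "none",
                           evidence = list(), confidence = "inferred") {
  new("EvolutionEvent", kind = kind, branch = branch, subject = subject,
      evidenceType = evidenceType, evidence = evidence,
      confidence = confidence)
}

## ---- generics -------------------------------------------------------------

#' @rdname accessors
#' @param x an annotation object
#' @export
setGeneric("featureStart", function(x) standardGeneric("featureStart"))
#' @rdname accessors
#' @export
setGeneric("featureEnd", function(x) standardGeneric("featureEnd"))
#' @rdname accessors
#' @export
setGeneric("recordId", function(x) standardGeneric("recordId"))
#' @rdname accessors
#' @export
setGeneric("snornaFamily", function(x) standardGeneric("snornaFamily"))
#' @rdname accessors
#' @export
setGeneric("elements", function(x) standardGeneric("elements"))
#' @rdname accessors
#' @export
setGeneric("eventKind", function(x) standardGeneric("eventKind"))
#' @rdname accessors
#' @export
setGeneric("eventBranch", function(x) standardGeneric("eventBranch"))
#' @rdname accessors
#' @export
setGeneric("eventSubject", function(x) standardGeneric("eventSubject"))
#' @rdname accessors
#' @export
setGeneric("cellStates", function(x) standardGeneric("cellStates"))
#' @rdname accessors
#' @export
setGeneric("removedIntrons", function(x) standardGeneric("removedIntrons"))
#' @rdname accessors
#' @export
setGeneric("retainedIntrons", function(x) standardGeneric("retainedIntrons"))

#' Accessors for snoEvol classes
#'
#' \code{featureStart}/\code{featureEnd} return 0-based half-open interval
#' bounds; \code{recordId} the genome record; \code{snornaFamily} the family
#' label; \code{elements} the tiled element table of an architecture;
#' \code{cellStates} the state matrix of a \code{PresenceAbsenceMatrix};
#' \code{eventKind}/\code{eventBranch}/\code{eventSubject} the fields of an
#' \code{EvolutionEvent}; \code{removedIntrons}/\code{retainedIntrons} the
#' intron index sets of a \code{SplicedProduct}.
#'
#' @name accessors
NULL

#' @rdname accessors
setMethod("featureStart", "SnoRNAAnnotation", function(x) x@start)
#' @rdname accessors
setMethod("featureEnd", "SnoRNAAnnotation", function(x) x@end)
#' @rdname accessors
setMethod("recordId", "SnoRNAAnnotation", function(x) x@recordId)
#' @rdname accessors
setMethod("snornaFamily", "SnoRNAAnnotation", function(x) x@family)
#' @rdname accessors
setMethod("featureStart", "IntronAnnotation", function(x) x@start)
#' @rdname accessors
setMethod("featureEnd", "IntronAnnotation", function(x) x@end)
#' @rdname accessors
setMethod("recordId", "IntronAnnotation", function(x) x@recordId)
#' @rdname accessors
setMethod("snornaFamily", "IntronAnnotation", function(x) x@snornaFamily)
#' @rdname accessors
setMethod("elements", "ClusterArchitecture", function(x) x@elements)
#' @rdname accessors
setMethod("recordId", "ClusterArchitecture", function(x) x@recordId)
#' @rdname accessors
setMethod("eventKind", "EvolutionEvent", function(x) x@kind)
#' @rdname accessors
setMethod("eventBranch", "EvolutionEvent", function(x) x@branch)
#' @rdname accessors
setMethod("eventSubject", "EvolutionEvent", function(x) x@subject)
#' @rdname accessors
setMethod("cellStates", "PresenceAbsenceMatrix", function(x) x@states)
#' @rdname accessors
setMethod("removedIntrons", "SplicedProduct", function(x) x@removed)
#' @rdname accessors
setMethod("retainedIntrons", "SplicedProduct", function(x) x@retained)

#' Intron order indices of an architecture
#'
#' Returns, for each intron element of the architecture, its 1-based order
#' index 5' to 3', named by hosted snoRNA family where present.
#'
#' @param x a \code{ClusterArchitecture}
#' @return named integer vector
#' @export
intronOrder <- function(x) {
  stopifnot(is(x, "ClusterArchitecture"))
  el <- x@elements
  idx <- which(el$kind == "intron")
  setNames(seq_along(idx), el$family[idx])
}

## ---- show methods ---------------------------------------------------------

setMethod("show", "SnoRNAAnnotation", function(object) {
  chim <- if (length(object@chimeric))
    sprintf(" chimeric(%s/%s@%d)", object@chimeric$family5,
            object@chimeric$family3, object@chimeric$breakpoint) else ""
  cat(sprintf("SnoRNAAnnotation %s [%d, %d) family=%s id=%.2f%s\n",
              object@recordId, object@start, object@end, object@family,
              object@familyIdentity, chim))
})

setMethod("show", "IntronAnnotation", function(object) {
  cat(sprintf("IntronAnnotation %s [%d, %d) donor=%s acceptor=%s snoRNA=%s score=%s\n",
              object@recordId, object@start, object@end, object@donorSeq,
              object@acceptorSeq, object@snornaFamily,
              format(object@signalScore)))
})

setMethod("show", "ClusterArchitecture", function(object) {
  el <- object@elements
  lab <- ifelse(el$kind == "intron",
                ifelse(is.na(el$family), "I", paste0("I(", el$family, ")")),
                "E")
  cat(sprintf("ClusterArchitecture %s on %s [%s]\n", object@clusterId,
              object@recordId, paste(lab, collapse = "-")))
})

setMethod("show", "PresenceAbsenceMatrix", function(object) {
  cat(sprintf("PresenceAbsenceMatrix: %d orthology groups x %d species\n",
              nrow(object@states), ncol(object@states)))
  print(object@states)
})

setMethod("show", "EvolutionEvent", function(object) {
  cat(sprintf("EvolutionEvent %s on branch %s subject=%s [%s, %s]\n",
              object@kind, object@branch, object@subject,
              object@evidenceType, object@confidence))
})

setMethod("show", "JunctionRepeat", function(object) {
  cat(sprintf("JunctionRepeat %s %dnt %s/%s mm=%d\n", object@kind,
              object@armLength, object@arm1Seq, object@arm2Seq,
              object@mismatches))
})

setMethod("show", "SplicedProduct", function(object) {
  cat(sprintf("SplicedProduct %s cluster=%s removed={%s} class=%s mm=%d\n",
              object@transcriptId, object@clusterId,
              paste(object@removed, collapse = ","),
              object@classification, object@mismatches))
})

setMethod("show", "SimulationConfig", function(object) {
  cat(sprintf(paste0("SimulationConfig: %d families, seed %d, mutation %.3g, ",
                     "event probs (deint %.3g, del %.3g, exc %.3g, rec %.3g, ",
                     "exl %.3g, gain %.3g)\n"),
              object@nSnornaFamilies, object@seed, object@pointMutationRate,
              object@pDeintronization, object@pDeletionLoss,
              object@pExcisionInsertion, object@pRecombination,
              object@pExonLoss, object@pIntronGain))
})

setMethod("show", "SimulationResult", function(object) {
  cat(sprintf("SimulationResult: %d species, %d true events\n",
              length(object@genomes), nrow(object@eventLog)))
})

#' Events as a data.frame
#'
#' @param events list of \code{EvolutionEvent}
#' @return data.frame with columns kind, branch, subject, evidence_type,
#'   confidence
#' @export
eventsAsDataFrame <- function(events) {
  if (!length(events))
    return(data.frame(kind = character(), branch = character(),
                      subject = character(), evidence_type = character(),
                      confidence = character(), stringsAsFactors = FALSE))
  data.frame(kind = vapply(events, eventKind, ""),
             branch = vapply(events, eventBranch, ""),
             subject = vapply(events, eventSubject, ""),
             evidence_type = vapply(events, function(e) e@evidenceType, ""),
             confidence = vapply(events, function(e) e@confidence, ""),
             stringsAsFactors = FALSE)
}
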