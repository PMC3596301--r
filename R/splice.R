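## splice_infer: resolve spliced transcripts against a cluster by
## exhaustive removed-subset hypothesis testing, tally product classes and
## test the stepwise 5'-to-3' splicing hypothesis for complex introns.

romanLabel <- function(removed, k) {
  if (length(removed) == 0L) return("unspliced")
  if (!identical(as.integer(removed), seq_len(max(removed))) ||
      max(removed) > k)
    return("other")
  if (length(removed) == k) return("all_removed")
  paste0(paste(as.character(as.roman(removed)), collapse = "+"), "_removed")
}

#' Resolve a spliced transcript against a cluster architecture
#'
#' Enumerates all 2^k removed-intron-subset hypotheses (k = number of
#' introns, k <= 12 enforced), constructs each predicted spliced sequence,
#' and compares it to the transcript by global alignment (unit scores,
#' affine gaps). The hypothesis with the fewest mismatches (substitutions
#' plus inserted/deleted nt) wins if its mismatch rate is at most
#' \code{maxMismatchRate}; ties prefer fewer removed introns, then the
#' lexicographically smallest index set. Returns \code{NULL} when no
#' hypothesis qualifies.
#'
#' @param transcript DNA string
#' @param genome named character vector containing the architecture's record
#' @param architecture a \code{ClusterArchitecture} with >= 1 intron
#' @param maxMismatchRate maximum tolerated mismatch rate
#' @param transcriptId id recorded on the product
#' @return a \code{SplicedProduct} or \code{NULL}
#' @export
resolveProduct <- function(transcript, genome, architecture,
                           maxMismatchRate = 0.03,
                           transcriptId = "transcript") {
  el <- elements(architecture)
  iv <- el[el$kind == "intron", , drop = FALSE]
  k <- nrow(iv)
  if (k < 1L) stop("architecture has no introns")
  if (k > 12L)
    stop("hypothesis space too large: ", k,
         " introns exceed the supported maximum of 12")
  seq <- genome[[recordId(architecture)]]
  span <- c(min(el$start), max(el$end))
  hypSeq <- function(removed) {
    keep <- character(0L); pos <- span[1L]
    for (j in removed) {
      keep <- c(keep, subseq0(seq, pos, iv$start[j]))
      pos <- iv$end[j]
    }
    paste0(paste(keep, collapse = ""), subseq0(seq, pos, span[2L]))
  }
  subsets <- lapply(seq_len(2L^k) - 1L, function(b)
    which(bitwAnd(b, 2L^(seq_len(k) - 1L)) > 0L))
  hyps <- vapply(subsets, hypSeq, "")
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1,
                                                  baseOnly = FALSE)
  aln <- Biostrings::pairwiseAlignment(Biostrings::DNAStringSet(hyps),
                                       Biostrings::DNAString(transcript),
                                       type = "global",
                                       substitutionMatrix = mat,
                                       gapOpening = 2, gapExtension = 1)
  alnLen <- nchar(as.character(Biostrings::pattern(aln)))
  mismatches <- alnLen - Biostrings::nmatch(aln)
  ## rank: fewest mismatches, then fewer removed introns, then smallest set
  sizes <- lengths(subsets)
  lexKey <- vapply(subsets, function(s) paste(sprintf("%02d", s),
                                              collapse = ","), "")
  ord <- order(mismatches, sizes, lexKey)
  best <- ord[1L]
  if (mismatches[best] / nchar(transcript) > maxMismatchRate) return(NULL)
  removed <- as.integer(subsets[[best]])
  new("SplicedProduct", transcriptId = transcriptId,
      clusterId = architecture@clusterId, removed = removed,
      retained = setdiff(seq_len(k), removed),
      mismatches = as.integer(mismatches[best]),
      classification = romanLabel(removed, k))
}

#' Resolve a batch of transcripts
#'
#' @param transcripts named character vector of transcript sequences
#' @param genome,architecture,maxMismatchRate see \code{\link{resolveProduct}}
#' @return list of \code{SplicedProduct} (unresolvable transcripts dropped)
#' @export
resolveProducts <- function(transcripts, genome, architecture,
                            maxMismatchRate = 0.03) {
  out <- list()
  for (i in seq_along(transcripts)) {
    p <- resolveProduct(transcripts[[i]], genome, architecture,
                        maxMismatchRate,
                        transcriptId = names(transcripts)[i] %||%
                          paste0("tx", i))
    if (!is.null(p)) out[[length(out) + 1L]] <- p
  }
  out
}

#' Tally spliced products per removed-set class
#'
#' Class labels follow the three-intron convention: "I_removed",
#' "I+II_removed", "all_removed", "unspliced" and "other" (the last for
#' any non-prefix removed set).
#'
#' @param products list of \code{SplicedProduct} from one cluster
#' @return named integer vector of class counts, including a "total"
#' @export
classifyProducts <- function(products) {
  if (length(products)) {
    cl <- vapply(products, function(p) p@clusterId, "")
    if (length(unique(cl)) > 1L)
      stop("products from mixed clusters: ", paste(unique(cl), collapse = ","))
  }
  labs <- vapply(products, function(p) p@classification, "")
  counts <- table(labs)
  out <- setNames(as.integer(counts), names(counts))
  c(out, total = length(products))
}

#' Test the stepwise 5'-to-3' splicing hypothesis
#'
#' Consistent if and only if every product's removed set is a 5'-contiguous
#' prefix of the intron order (the empty set and the full set allowed).
#' Otherwise violated, with every product that removes an intron while
#' retaining a more-5' intron listed.
#'
#' @param products list of \code{SplicedProduct}
#' @param intronOrder 5' to 3' intron indices (default: sorted union)
#' @return list(verdict = "consistent"/"violated", violations = list of
#'   offending products)
#' @export
testStepwise <- function(products, intronOrder = NULL) {
  viol <- list()
  for (p in products) {
    idx <- c(p@removed, p@retained)
    ord <- intronOrder %||% sort(idx)
    removedPos <- match(p@removed, ord)
    retainedPos <- match(p@retained, ord)
    if (length(removedPos) && length(retainedPos) &&
        min(retainedPos) < max(removedPos))
      viol[[length(viol) + 1L]] <- p
  }
  list(verdict = if (length(viol)) "violated" else "consistent",
       violations = viol)
}

#' Compatibility with the single-donor / alternative-acceptor model
#'
#' The alternative model (only intron I carries a functional donor, which
#' may splice to any intron's acceptor) predicts exactly the 5'-prefix
#' product classes, so the two models cannot be distinguished from product
#' classes alone: the flag is \code{TRUE} exactly when every non-empty
#' removed set is a 5' prefix. Purely annotational; it never changes the
#' stepwise verdict.
#'
#' @param products list of \code{SplicedProduct}
#' @param intronOrder 5' to 3' intron indices
#' @return logical flag: both models compatible with the observed classes
#' @export
noteAlternativeModel <- function(products, intronOrder = NULL) {
  testStepwise(products, intronOrder)$verdict == "consistent"
}
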