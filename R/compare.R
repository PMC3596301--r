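## compare_events: presence/absence matrix across species, mechanistic
## evidence gathering (residual stubs, relocated copies, chimeras, exon
## losses) and Fitch-parsimony placement of classified events on the tree.

## ---- tree helpers ---------------------------------------------------------

nodeLabelOf <- function(tree, node) {
  nTip <- length(tree$tip.label)
  if (node <= nTip) tree$tip.label[node] else tree$node.label[node - nTip]
}

leavesUnder <- function(tree, node) {
  nTip <- length(tree$tip.label)
  if (node <= nTip) return(tree$tip.label[node])
  kids <- tree$edge[tree$edge[, 1L] == node, 2L]
  unlist(lapply(kids, leavesUnder, tree = tree))
}

mrcaLabel <- function(tree, leaves) {
  if (length(leaves) == 1L) return(leaves)
  node <- ape::getMRCA(tree, leaves)
  nodeLabelOf(tree, node)
}

## branch labels of the maximal clades whose leaves all belong to `carriers`
maximalCarrierClades <- function(tree, carriers) {
  if (!length(carriers)) return(character(0L))
  nTip <- length(tree$tip.label)
  out <- character(0L)
  visit <- function(node) {
    lv <- leavesUnder(tree, node)
    if (all(lv %in% carriers)) {
      out <<- c(out, nodeLabelOf(tree, node))
      return()
    }
    if (node > nTip)
      for (kid in tree$edge[tree$edge[, 1L] == node, 2L]) visit(kid)
  }
  visit(nTip + 1L)
  out
}

#' Fitch small-parsimony ancestral states
#'
#' Unordered Fitch parsimony over an arbitrary state alphabet with support
#' for missing leaf data (\code{NA} = any state). The final (top-down) pass
#' assigns the root its prior state when that state is optimal, and
#' otherwise, like every ambiguous node, the first optimal state in
#' \code{preference} order.
#'
#' @param tree rooted ape \code{phylo} with node labels
#' @param leafStates named character vector (names = tip labels; NA allowed)
#' @param alphabet state alphabet
#' @param rootPrior preferred root state
#' @param preference tie-break order over states
#' @return list(nodeStates = named character vector over all node labels,
#'   changes = data.frame(branch, from, to) with branch = child label)
#' @export
fitchParsimony <- function(tree, leafStates, alphabet,
                           rootPrior = alphabet[1L],
                           preference = alphabet) {
  nTip <- length(tree$tip.label)
  nNode <- nTip + tree$Nnode
  sets <- vector("list", nNode)
  for (i in seq_len(nTip)) {
    s <- leafStates[[tree$tip.label[i]]]
    sets[[i]] <- if (is.na(s)) alphabet else s
  }
  childrenOf <- split(tree$edge[, 2L], tree$edge[, 1L])
  postorder <- rev(unique(ape::reorder.phylo(tree, "cladewise")$edge[, 1L]))
  for (node in postorder) {
    kids <- childrenOf[[as.character(node)]]
    inter <- Reduce(intersect, sets[kids])
    sets[[node]] <- if (length(inter)) inter
      else Reduce(union, sets[kids])
  }
  pickFrom <- function(set, want) {
    if (want %in% set) return(want)
    set[order(match(set, preference))][1L]
  }
  states <- character(nNode)
  root <- nTip + 1L
  states[root] <- pickFrom(sets[[root]], rootPrior)
  edges <- ape::reorder.phylo(tree, "cladewise")$edge
  changes <- list()
  for (r in seq_len(nrow(edges))) {
    parent <- edges[r, 1L]; child <- edges[r, 2L]
    states[child] <- pickFrom(sets[[child]], states[parent])
    if (states[child] != states[parent])
      changes[[length(changes) + 1L]] <-
        data.frame(branch = nodeLabelOf(tree, child),
                   from = states[parent], to = states[child],
                   stringsAsFactors = FALSE)
  }
  labels <- vapply(seq_len(nNode), nodeLabelOf, "", tree = tree)
  list(nodeStates = setNames(states, labels),
       changes = if (length(changes)) do.call(rbind, changes)
         else data.frame(branch = character(), from = character(),
                         to = character(), stringsAsFactors = FALSE))
}

## ---- presence/absence matrix ----------------------------------------------

#' Build the intron presence/absence matrix across species
#'
#' One row per snoRNA family (in reference order) plus one row per gained-
#' intron orthology group (snoRNA-free introns clustered across species by
#' global identity). Cells are "intronic", "exonic", "absent", "relocated",
#' "chimeric" or "unknown"; every non-absent cell is backed by an
#' annotation stored in the evidence slot.
#'
#' @param annots named list of per-species \code{\link{annotateGenome}}
#'   results
#' @param genomes named character vector of genome sequences
#' @param references named character vector of family references (the name
#'   order defines the canonical cluster order)
#' @param gainedIdentity single-linkage identity threshold for grouping
#'   gained introns across species
#' @return a \code{PresenceAbsenceMatrix}
#' @export
buildPresenceAbsenceMatrix <- function(annots, genomes, references,
                                       gainedIdentity = 0.8) {
  species <- names(annots)
  if (length(species) < 2L) stop("need >= 2 species")
  missing <- setdiff(species, names(genomes))
  if (length(missing))
    stop("species absent from genome set: ", paste(missing, collapse = ","))
  fams <- names(references)
  states <- matrix("absent", nrow = length(fams), ncol = length(species),
                   dimnames = list(fams, species))
  evidence <- list()
  gainedItems <- list()
  for (sp in species) {
    an <- annots[[sp]]
    if (is.null(an$architecture)) {
      states[, sp] <- "unknown"
      next
    }
    el <- elements(an$architecture)
    intronFams <- el$family[el$kind == "intron" & !is.na(el$family)]
    chimFams <- character(0L)
    for (sn in an$snornas) {
      if (length(sn@chimeric)) {
        chimFams <- c(chimFams, sn@chimeric$family5, sn@chimeric$family3)
        for (f in c(sn@chimeric$family5, sn@chimeric$family3))
          evidence[[paste(f, sp, sep = "|")]] <-
            list(chimera = sn@chimeric,
                 locus = list(species = sp, start = featureStart(sn),
                              end = featureEnd(sn)))
      }
    }
    relocFams <- character(0L)
    for (rl in an$relocated) {
      f <- snornaFamily(rl$snorna)
      if (f == "novel") next
      relocFams <- c(relocFams, f)
      iv <- if (!is.null(rl$intron))
        c(featureStart(rl$intron), featureEnd(rl$intron))
        else c(featureStart(rl$snorna), featureEnd(rl$snorna))
      evidence[[paste(f, sp, sep = "|")]] <-
        list(locus = list(species = sp, start = iv[1L], end = iv[2L],
                          identity = rl$snorna@familyIdentity))
    }
    for (f in fams) {
      states[f, sp] <-
        if (f %in% chimFams) "chimeric"
        else if (f %in% intronFams) "intronic"
        else if (f %in% an$exonicFamilies) "exonic"
        else if (f %in% relocFams) "relocated"
        else "absent"
    }
    ## gained snoRNA-free introns (top-level and embedded)
    for (ia in an$introns) {
      if (!is.na(snornaFamily(ia))) next
      gainedItems[[length(gainedItems) + 1L]] <-
        list(species = sp, start = featureStart(ia), end = featureEnd(ia),
             seq = subseq0(genomes[[sp]], featureStart(ia), featureEnd(ia)))
    }
  }
  ## cluster gained introns across species (single linkage); identity of
  ## the shorter sequence within the longer, so that a copy whose 3'
  ## boundary was called short still joins its orthologs
  if (length(gainedItems)) {
    n <- length(gainedItems)
    grp <- seq_len(n)
    if (n > 1L) {
      for (i in seq_len(n - 1L)) for (j in seq.int(i + 1L, n)) {
        if (grp[i] == grp[j]) next
        a <- gainedItems[[i]]$seq; b <- gainedItems[[j]]$seq
        if (nchar(a) > nchar(b)) { tmp <- a; a <- b; b <- tmp }
        if (segmentIdentities(a, b) >= gainedIdentity)
          grp[grp == grp[j]] <- grp[i]
      }
    }
    gid <- 0L
    for (g in unique(grp)) {
      gid <- gid + 1L
      row <- setNames(rep("absent", length(species)), species)
      rowName <- paste0("gained", gid)
      for (item in gainedItems[grp == g]) {
        row[item$species] <- "intronic"
        evidence[[paste(rowName, item$species, sep = "|")]] <-
          list(locus = list(species = item$species, start = item$start,
                            end = item$end))
      }
      states <- rbind(states, matrix(row, nrow = 1L,
                                     dimnames = list(rowName, species)))
    }
  }
  new("PresenceAbsenceMatrix", states = states, evidence = evidence)
}

## ---- loss evidence --------------------------------------------------------

#' Detect a residual intron stub at an exon-exon junction
#'
#' Scans the junction region for an ungapped match anchored to either end
#' of the reference intron: the intron's 5' end extended rightward from
#' each region offset, and its 3' end extended leftward. Evidence requires
#' a match of at least \code{minStub} nt with identity at least
#' \code{minIdentity}; the longest such match wins, then higher identity,
#' then the leftmost offset. Reports which intron end matched.
#'
#' @param junctionRegion DNA string spanning the exon-exon join
#' @param refIntron reference (intact orthologous) intron sequence
#' @param minStub minimum stub length (nt)
#' @param minIdentity minimum match identity
#' @return \code{NULL}, or list(end, offset, length, identity)
#' @export
detectResidualStub <- function(junctionRegion, refIntron, minStub = 8L,
                               minIdentity = 0.85) {
  nr <- nchar(junctionRegion)
  if (nr < minStub) return(NULL)
  qlen <- min(40L, nchar(refIntron))
  q5 <- substr(refIntron, 1L, qlen)
  q3 <- substr(refIntron, nchar(refIntron) - qlen + 1L, nchar(refIntron))
  best <- NULL
  consider <- function(end, offset, L, ident) {
    if (L < minStub || ident < minIdentity) return()
    if (is.null(best) || L > best$length ||
        (L == best$length && ident > best$identity + 1e-12) ||
        (L == best$length && abs(ident - best$identity) <= 1e-12 &&
         offset < best$offset))
      best <<- list(end = end, offset = offset, length = L, identity = ident)
  }
  rv <- strsplit(junctionRegion, "", fixed = TRUE)[[1L]]
  q5v <- strsplit(q5, "", fixed = TRUE)[[1L]]
  q3v <- strsplit(q3, "", fixed = TRUE)[[1L]]
  for (o in seq_len(max(0L, nr - minStub + 1L)) - 1L) {
    Lmax <- min(qlen, nr - o)
    if (Lmax < minStub) next
    mm <- cumsum(rv[(o + 1L):(o + Lmax)] != q5v[1L:Lmax])
    for (L in seq.int(Lmax, minStub))
      consider("5prime", o, L, (L - mm[L]) / L)
  }
  for (o in seq.int(minStub, nr)) {    # o = region end offset (1-based)
    Lmax <- min(qlen, o)
    if (Lmax < minStub) next
    mm <- cumsum(rev(rv[(o - Lmax + 1L):o]) != rev(q3v)[1L:Lmax])
    for (L in seq.int(Lmax, minStub))
      consider("3prime", o - L, L, (L - mm[L]) / L)
  }
  best
}

#' Search a genome for a relocated copy of a lost intron unit
#'
#' Best local alignment (unit scores, affine gaps) of the intron unit
#' against the genome outside the donor cluster span. A hit requires
#' identity at least \code{minIdentity} over at least \code{minCoverage}
#' of the unit.
#'
#' @param genomeSeq DNA string
#' @param unitSeq the lost intron unit (>= 40 nt)
#' @param exclude 0-based half-open interval to exclude (the cluster span)
#' @param minIdentity,minCoverage thresholds
#' @return \code{NULL}, or list(start, end, identity, coverage)
#' @export
searchRelocated <- function(genomeSeq, unitSeq, exclude = c(0L, 0L),
                            minIdentity = 0.7, minCoverage = 0.8) {
  if (nchar(unitSeq) < 40L) stop("lost unit must be >= 40 nt")
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1,
                                                  baseOnly = FALSE)
  parts <- list(c(0L, exclude[1L]), c(exclude[2L], nchar(genomeSeq)))
  best <- NULL
  for (part in parts) {
    if (part[2L] - part[1L] < 40L) next
    sub <- subseq0(genomeSeq, part[1L], part[2L])
    aln <- Biostrings::pairwiseAlignment(Biostrings::DNAString(unitSeq),
                                         Biostrings::DNAString(sub),
                                         type = "local",
                                         substitutionMatrix = mat,
                                         gapOpening = 2, gapExtension = 1)
    alnLen <- nchar(as.character(Biostrings::pattern(aln)))
    if (alnLen == 0L) next
    identity <- Biostrings::nmatch(aln) / alnLen
    pat <- Biostrings::pattern(aln)
    coverage <- (BiocGenerics::end(pat) - BiocGenerics::start(pat) + 1L) /
      nchar(unitSeq)
    subj <- Biostrings::subject(aln)
    hit <- list(start = as.integer(part[1L] + BiocGenerics::start(subj) - 1L),
                end = as.integer(part[1L] + BiocGenerics::end(subj)),
                identity = identity, coverage = coverage,
                score = BiocGenerics::score(aln))
    if (identity >= minIdentity && coverage >= minCoverage &&
        (is.null(best) || hit$score > best$score))
      best <- hit
  }
  if (is.null(best)) return(NULL)
  best$score <- NULL
  best
}

## Best ungapped placement of query inside subject (fewest mismatches);
## returns 0-based offset or NA. Used to locate a degraded ortholog of an
## intact intron.
bestDiagonalOffset <- function(query, subject) {
  nq <- nchar(query); ns <- nchar(subject)
  if (ns < nq) return(NA_integer_)
  qv <- strsplit(query, "", fixed = TRUE)[[1L]]
  sv <- strsplit(subject, "", fixed = TRUE)[[1L]]
  best <- NA_integer_; bestMM <- Inf
  for (o in 0:(ns - nq)) {
    mm <- sum(qv != sv[(o + 1L):(o + nq)])
    if (mm < bestMM) { bestMM <- mm; best <- o }
  }
  best
}

## The sequence relic of a degraded intron's splice signals in one species:
## the leaf nucleotides at the positions orthologous to the intact intron's
## donor (first 6), branch (7) and acceptor (last 2). Independent
## de-intronization events leave different relics; a shared event leaves
## the same relic in all descendants.
signalRelic <- function(leafRegion, unit, unitBranchRel) {
  off <- bestDiagonalOffset(unit, leafRegion)
  if (is.na(off)) return(NA_character_)
  take <- function(s, e) subseq0(leafRegion, off + s, off + e)
  paste0(take(0L, 6L),
         take(unitBranchRel, unitBranchRel + 7L),
         take(nchar(unit) - 2L, nchar(unit)))
}

## for each "absent" family cell, look for a relocated copy (upgrading the
## cell) and for a residual stub at the junction (stored as evidence); for
## each "exonic" cell, record the degraded-signal relic
gatherLossEvidence <- function(pam, annots, genomes, tree, references) {
  states <- pam@states
  fams <- names(references)
  species <- colnames(states)
  if (is.null(tree$edge.length))
    tree$edge.length <- rep(1, nrow(tree$edge))
  dist <- ape::cophenetic.phylo(tree)
  intronElement <- function(sp, fam) {
    arch <- annots[[sp]]$architecture
    if (is.null(arch)) return(NULL)
    el <- elements(arch)
    i <- which(el$kind == "intron" & !is.na(el$family) & el$family == fam)
    if (!length(i)) NULL else c(el$start[i[1L]], el$end[i[1L]])
  }
  for (f in fams) {
    absentIn <- species[states[f, ] == "absent"]
    if (!length(absentIn)) next
    donors <- species[states[f, ] == "intronic"]
    if (!length(donors)) next
    for (sp in absentIn) {
      donor <- donors[which.min(dist[sp, donors])]
      div <- intronElement(donor, f)
      if (is.null(div)) next
      unit <- subseq0(genomes[[donor]], div[1L], div[2L])
      arch <- annots[[sp]]$architecture
      if (is.null(arch)) next
      el <- elements(arch)
      span <- c(min(el$start), max(el$end))
      hit <- searchRelocated(genomes[[sp]], unit, exclude = span)
      key <- paste(f, sp, sep = "|")
      if (!is.null(hit)) {
        states[f, sp] <- "relocated"
        pam@evidence[[key]] <- list(locus = list(species = sp,
                                                 start = hit$start,
                                                 end = hit$end,
                                                 identity = hit$identity,
                                                 coverage = hit$coverage))
        next
      }
      ## junction region: between the nearest flanking intact reference
      ## introns in this species
      fi <- match(f, fams)
      leftIv <- NULL; rightIv <- NULL
      famL <- "."; famR <- "."
      for (j in rev(seq_len(fi - 1L))) {
        leftIv <- intronElement(sp, fams[j])
        if (!is.null(leftIv)) { famL <- fams[j]; break }
      }
      for (j in seq.int(fi + 1L, length.out = length(fams) - fi)) {
        rightIv <- intronElement(sp, fams[j])
        if (!is.null(rightIv)) { famR <- fams[j]; break }
      }
      lo <- if (!is.null(leftIv)) leftIv[2L] else span[1L]
      hi <- if (!is.null(rightIv)) rightIv[1L] else span[2L]
      if (hi <= lo) next
      ## exonic nt at the junction (detected introns in it excluded):
      ## orthologous junctions of one shared deletion have equal width,
      ## independent deletions almost always differ (their stubs do)
      exonNt <- hi - lo
      hadIntron <- FALSE
      for (ia in annots[[sp]]$introns) {
        s2 <- featureStart(ia); e2 <- featureEnd(ia)
        if (s2 >= lo && e2 <= hi) {
          exonNt <- exonNt - (e2 - s2)
          hadIntron <- TRUE
        }
      }
      ev <- pam@evidence[[key]] %||% list()
      ev$junctionExonNt <- exonNt
      ev$junctionHadIntron <- hadIntron
      ev$junctionFlanks <- paste(famL, famR, sep = "~")
      stub <- detectResidualStub(subseq0(genomes[[sp]], lo, hi), unit)
      if (!is.null(stub))
        ev$stub <- c(stub, list(species = sp, junction = c(lo, hi)))
      pam@evidence[[key]] <- ev
    }
  }
  ## refine relocated loci by local alignment against an intact ortholog
  ## unit, then record the upstream insertion-site flank: one shared
  ## excision-insertion leaves near-identical flanks in all descendants,
  ## independent insertions land in unrelated background
  for (f in fams) {
    relocIn <- species[states[f, ] == "relocated"]
    if (!length(relocIn)) next
    donorsF <- species[states[f, ] == "intronic"]
    for (sp in relocIn) {
      key <- paste(f, sp, sep = "|")
      ev <- pam@evidence[[key]] %||% list()
      if (length(donorsF)) {
        donor <- donorsF[which.min(dist[sp, donorsF])]
        div <- intronElement(donor, f)
        arch <- annots[[sp]]$architecture
        if (!is.null(div) && !is.null(arch)) {
          el <- elements(arch)
          hit <- searchRelocated(genomes[[sp]],
                                 subseq0(genomes[[donor]], div[1L], div[2L]),
                                 exclude = c(min(el$start), max(el$end)))
          if (!is.null(hit))
            ev$locus <- list(species = sp, start = hit$start, end = hit$end,
                             identity = hit$identity,
                             coverage = hit$coverage)
        }
      }
      if (!is.null(ev$locus))
        ev$relocFlanks <- subseq0(genomes[[sp]],
                                  max(0L, ev$locus$start - 40L),
                                  ev$locus$start)
      pam@evidence[[key]] <- ev
    }
  }
  ## degraded-signal relics for exonic cells (used to tell one shared
  ## de-intronization from independent ones)
  for (f in fams) {
    exonicIn <- species[states[f, ] == "exonic"]
    donors <- species[states[f, ] == "intronic"]
    if (length(exonicIn) < 2L || !length(donors)) next
    div <- intronElement(donors[1L], f)
    if (is.null(div)) next
    unit <- subseq0(genomes[[donors[1L]]], div[1L], div[2L])
    bRel <- NA_integer_
    for (ia in annots[[donors[1L]]]$introns)
      if (identical(snornaFamily(ia), f)) bRel <- ia@branchStart - div[1L]
    if (is.na(bRel)) next
    for (sp in exonicIn) {
      sn <- NULL
      for (s2 in annots[[sp]]$snornas)
        if (identical(snornaFamily(s2), f)) sn <- s2
      if (is.null(sn)) next
      lo <- max(0L, featureStart(sn) - 250L)
      hi <- min(nchar(genomes[[sp]]), featureEnd(sn) + 250L)
      relic <- signalRelic(subseq0(genomes[[sp]], lo, hi), unit, bRel)
      key <- paste(f, sp, sep = "|")
      ev <- pam@evidence[[key]] %||% list()
      ev$relic <- relic
      pam@evidence[[key]] <- ev
    }
  }
  pam@states <- states
  pam
}

#' Cross-species refinement of intronic calls by splice-site orthology
#'
#' Orthologous host introns keep their donor at the same offset from the
#' snoRNA (point substitution does not move positions). A species whose
#' donor offset disagrees with the offset shared by at least two other
#' species carries a spurious splice-signal triple (typically around a
#' de-intronized snoRNA); its call is demoted to exonic and the
#' architecture reassembled.
#'
#' @param annots named list of per-species \code{\link{annotateGenome}}
#'   results
#' @param genomes named character vector of genome sequences
#' @param references named character vector of family references
#' @return the refined annotation list
#' @export
refineAnnotations <- function(annots, genomes, references) {
  species <- names(annots)
  fams <- names(references)
  snoIv <- function(sp, fam, within) {
    for (sn in annots[[sp]]$snornas)
      if (identical(snornaFamily(sn), fam) &&
          featureStart(sn) >= within[1L] && featureEnd(sn) <= within[2L])
        return(c(featureStart(sn), featureEnd(sn)))
    NULL
  }
  for (f in fams) {
    offs <- list()
    for (sp in species) {
      arch <- annots[[sp]]$architecture
      if (is.null(arch)) next
      el <- elements(arch)
      i <- which(el$kind == "intron" & !is.na(el$family) & el$family == f)
      if (length(i) != 1L) next
      sv <- snoIv(sp, f, c(el$start[i], el$end[i]))
      if (is.null(sv)) next
      offs[[sp]] <- sv[1L] - el$start[i]
    }
    if (length(offs) < 3L) next
    tab <- table(unlist(offs))
    mode <- as.integer(names(tab)[which.max(tab)])
    if (max(tab) < 2L) next
    for (sp in names(offs)) {
      if (offs[[sp]] == mode || tab[[as.character(offs[[sp]])]] >= 2L) next
      ## demote: drop the intron call, mark the snoRNA exonic, reassemble
      an <- annots[[sp]]
      keep <- Filter(function(ia)
        is.na(snornaFamily(ia)) || snornaFamily(ia) != f, an$introns)
      an$introns <- keep
      an$exonicFamilies <- unique(c(an$exonicFamilies, f))
      el <- elements(an$architecture)
      span <- c(min(el$start), max(el$end))
      clusterIntrons <- Filter(function(ia)
        featureStart(ia) >= span[1L] - 400L &&
          featureEnd(ia) <= span[2L] + 400L, keep)
      clusterSno <- Filter(function(sn)
        featureStart(sn) >= span[1L] - 400L &&
          featureEnd(sn) <= span[2L] + 400L, an$snornas)
      if (length(clusterIntrons) || length(clusterSno))
        an$architecture <- assembleArchitecture(
          genomes[[sp]], clusterSno, clusterIntrons,
          clusterId = an$architecture@clusterId)
      annots[[sp]] <- an
    }
  }
  annots
}

## ---- event placement ------------------------------------------------------

#' Place classified evolution events on the species tree
#'
#' Per matrix row, Fitch small parsimony over the cell states (relocated
#' and chimeric collapse to absent; the root prior is intron-rich) assigns
#' state changes to branches; each change becomes an event whose kind is
#' chosen by the gathered evidence: absence with a relocated copy below the
#' branch is an excision-insertion (one event covering donor and target);
#' absence with a residual stub is a deletion loss (otherwise an inferred
#' deletion loss); intronic-to-exonic is a de-intronization; a chimera is a
#' recombination on the branch subtending all chimera-bearing leaves (the
#' parent families' own absence changes on that branch are absorbed); a
#' gained-intron row present only in a clade is an intron gain on the
#' clade's stem.
#'
#' @param pam a \code{PresenceAbsenceMatrix} (after evidence gathering)
#' @param tree rooted \code{phylo}; leaves must equal the matrix columns
#' @return list of \code{EvolutionEvent}
#' @export
placeEvents <- function(pam, tree) {
  states <- pam@states
  if (!setequal(colnames(states), tree$tip.label))
    stop("matrix columns must equal tree leaves")
  events <- list()
  ## recombination: cluster chimeric cells by parent-family pair and
  ## breakpoint (independent fusions of the same pair differ in
  ## breakpoint), then place one event on the stem of every maximal clade
  ## whose leaves all carry the fusion
  chimCells <- list()
  for (key in names(pam@evidence)) {
    ev <- pam@evidence[[key]]
    if (is.null(ev$chimera)) next
    parts <- strsplit(key, "|", fixed = TRUE)[[1L]]
    ck <- paste(ev$chimera$family5, ev$chimera$family3, parts[2L])
    chimCells[[ck]] <- list(species = parts[2L], chimera = ev$chimera,
                            evidence = ev)
  }
  if (length(chimCells)) {
    n <- length(chimCells)
    grp <- seq_len(n)
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (i >= j || grp[i] == grp[j]) next
      a <- chimCells[[i]]$chimera; b <- chimCells[[j]]$chimera
      if (identical(a$family5, b$family5) &&
          identical(a$family3, b$family3) &&
          abs(a$breakpoint - b$breakpoint) <= 5L)
        grp[grp == grp[j]] <- grp[i]
    }
    for (g in unique(grp)) {
      members <- chimCells[grp == g]
      leaves <- vapply(members, `[[`, "", "species")
      gk <- paste(members[[1L]]$chimera$family5,
                  members[[1L]]$chimera$family3, sep = "|")
      for (br in maximalCarrierClades(tree, leaves))
        events[[length(events) + 1L]] <- EvolutionEvent(
          kind = "recombination", branch = br, subject = gk,
          evidenceType = "chimera_split",
          evidence = members[[1L]]$evidence, confidence = "supported")
    }
  }
  descendantLeaves <- function(branch) {
    nTip <- length(tree$tip.label)
    if (branch %in% tree$tip.label) return(branch)
    node <- nTip + match(branch, tree$node.label)
    leavesUnder(tree, node)
  }
  gainedRows <- grep("^gained", rownames(states), value = TRUE)
  famRows <- setdiff(rownames(states), gainedRows)
  for (f in famRows) {
    raw <- states[f, ]
    ## excision-insertion: group relocated leaves by insertion-site flank
    ## concordance (independent insertions land in unrelated background),
    ## then one event per maximal clade wholly carrying each insertion
    reloc <- colnames(states)[raw == "relocated"]
    relocGroups <- list()
    if (length(reloc)) {
      fl <- vapply(reloc, function(sp)
        pam@evidence[[paste(f, sp, sep = "|")]]$relocFlanks %||%
          NA_character_, "")
      if (anyNA(fl) || length(reloc) == 1L) relocGroups <- list(reloc)
      else {
        grp <- seq_along(reloc)
        for (i in seq_along(reloc)) for (j in seq_along(reloc)) {
          if (i >= j || grp[i] == grp[j]) next
          if (globalIdentity(fl[i], fl[j]) >= 0.7)
            grp[grp == grp[j]] <- grp[i]
        }
        relocGroups <- unname(split(reloc, grp))
      }
    }
    for (g in relocGroups) for (br in maximalCarrierClades(tree, g))
      events[[length(events) + 1L]] <- EvolutionEvent(
        kind = "excision_insertion", branch = br, subject = f,
        evidenceType = "relocated_locus",
        evidence = pam@evidence[[paste(
          f, intersect(descendantLeaves(br), g)[1L], sep = "|")]] %||%
          list(),
        confidence = "supported")
    ## chimeric cells are explained by their recombination event and
    ## relocated cells by their excision-insertion; neither informs the
    ## family's own cluster state
    leafStates <- raw
    leafStates[leafStates %in% c("unknown", "chimeric", "relocated")] <- NA
    fit <- dolloReconstruction(tree, setNames(leafStates, colnames(states)),
                               order = c("intronic", "exonic", "absent"),
                               rootState = "intronic")
    ch <- fit$changes
    for (r in seq_len(nrow(ch))) {
      br <- ch$branch[r]
      below <- descendantLeaves(br)
      if (ch$to[r] == "absent") {
        ## convergent deletions on sibling branches leave junctions of
        ## different exonic width (their residual stubs differ); split
        ## discordant groups
        absLeaves <- below[raw[below] == "absent"]
        ## convergent deletions on sibling branches leave different
        ## residual stubs; when every leaf shows a stub, leaves whose stub
        ## lengths differ by more than the detection jitter are split
        stubLens <- vapply(absLeaves, function(sp) {
          st <- pam@evidence[[paste(f, sp, sep = "|")]]$stub
          if (is.null(st)) NA_integer_ else as.integer(st$length)
        }, 0L)
        groups <- list(absLeaves)
        if (length(absLeaves) >= 2L && !anyNA(stubLens)) {
          grp <- seq_along(absLeaves)
          for (i in seq_along(absLeaves)) for (j in seq_along(absLeaves)) {
            if (i >= j || grp[i] == grp[j]) next
            if (abs(stubLens[i] - stubLens[j]) <= 3L)
              grp[grp == grp[j]] <- grp[i]
          }
          groups <- unname(split(absLeaves, grp))
        }
        ## place on the stems of the clades actually exhibiting the loss:
        ## uninformative leaves (relocated/chimeric/unknown) never pull an
        ## event above its evidence
        emitAt <- lapply(groups, function(g) maximalCarrierClades(tree, g))
        for (gi in seq_along(groups)) {
          g <- groups[[gi]]
          stubKeys <- paste(f, g, sep = "|")
          stubs <- Filter(function(k) !is.null(pam@evidence[[k]]$stub),
                          stubKeys)
          for (br2 in emitAt[[gi]]) {
            if (length(stubs)) {
              events[[length(events) + 1L]] <- EvolutionEvent(
                kind = "deletion_loss", branch = br2, subject = f,
                evidenceType = "stub_alignment",
                evidence = pam@evidence[[stubs[[1L]]]],
                confidence = "supported")
            } else {
              events[[length(events) + 1L]] <- EvolutionEvent(
                kind = "deletion_loss", branch = br2, subject = f,
                confidence = "inferred")
            }
          }
        }
      } else if (ch$from[r] == "intronic" && ch$to[r] == "exonic") {
        ## convergent de-intronizations of the same family on sibling
        ## branches leave different signal relics; split discordant
        ## groups. Leaves that lost the family entirely further down are
        ## consistent with a prior exonic state and stay in the group.
        exLeaves <- below[raw[below] == "exonic"]
        deeperAbsent <- below[raw[below] == "absent"]
        groups <- list(c(exLeaves, deeperAbsent))
        relics <- vapply(exLeaves, function(sp)
          pam@evidence[[paste(f, sp, sep = "|")]]$relic %||% NA_character_,
          "")
        if (length(exLeaves) >= 2L && !length(deeperAbsent) &&
            !anyNA(relics) &&
            length(unique(nchar(relics))) == 1L) {
          ## threshold allows for post-event drift at the (now neutral)
          ## degraded positions; independent degradations differ at ~5-6
          ## of the 15 signal positions
          grp <- seq_along(exLeaves)
          for (i in seq_along(exLeaves)) for (j in seq_along(exLeaves)) {
            if (i >= j || grp[i] == grp[j]) next
            if (countMismatches(relics[i], relics[j]) <= 3L)
              grp[grp == grp[j]] <- grp[i]
          }
          groups <- unname(split(exLeaves, grp))
        }
        for (g in groups) for (br2 in maximalCarrierClades(tree, g))
          events[[length(events) + 1L]] <- EvolutionEvent(
            kind = "deintronization", branch = br2, subject = f,
            evidenceType = "degraded_signals",
            evidence = list(species = g), confidence = "supported")
      } else {
        events[[length(events) + 1L]] <- EvolutionEvent(
          kind = "deintronization", branch = br, subject = f,
          confidence = "inferred")
      }
    }
  }
  for (g in gainedRows) {
    ## a gained intron originates once: the gain sits on the stem of the
    ## smallest clade containing all carriers
    carriers <- colnames(states)[states[g, ] == "intronic"]
    if (!length(carriers)) next
    events[[length(events) + 1L]] <- EvolutionEvent(
      kind = "intron_gain", branch = mrcaLabel(tree, carriers), subject = g,
      evidenceType = "junction_repeats",
      evidence = pam@evidence[[paste(g, carriers[1L], sep = "|")]] %||%
        list(),
      confidence = "supported")
  }
  events
}

## Irreversible ("Dollo-style") ancestral reconstruction for characters
## whose transitions run one way along `order` (e.g. intronic -> exonic ->
## absent, never back). A node takes the strongest state (earliest in
## `order`) found among its informative descendant leaves; leaves with NA
## are uninformative; the root state is fixed by the model. Changes are
## edges whose informative child state differs from the parent state.
dolloReconstruction <- function(tree, leafStates, order, rootState,
                                subtreeRoot = NULL) {
  nTip <- length(tree$tip.label)
  nNode <- nTip + tree$Nnode
  val <- rep(NA_character_, nNode)
  for (i in seq_len(nTip)) val[i] <- leafStates[[tree$tip.label[i]]]
  childrenOf <- split(tree$edge[, 2L], tree$edge[, 1L])
  postorder <- rev(unique(ape::reorder.phylo(tree, "cladewise")$edge[, 1L]))
  for (node in postorder) {
    kids <- childrenOf[[as.character(node)]]
    states <- val[kids]
    states <- states[!is.na(states)]
    val[node] <- if (length(states)) order[min(match(states, order))]
                 else NA_character_
  }
  root <- subtreeRoot %||% (nTip + 1L)
  val[root] <- rootState
  edges <- ape::reorder.phylo(tree, "cladewise")$edge
  ## restrict to the subtree below `root`
  inSub <- rep(FALSE, nNode); inSub[root] <- TRUE
  changes <- list()
  for (r in seq_len(nrow(edges))) {
    parent <- edges[r, 1L]; child <- edges[r, 2L]
    if (!inSub[parent]) next
    inSub[child] <- TRUE
    if (is.na(val[child])) { val[child] <- val[parent]; next }
    if (val[child] != val[parent])
      changes[[length(changes) + 1L]] <-
        data.frame(branch = nodeLabelOf(tree, child),
                   from = val[parent], to = val[child],
                   stringsAsFactors = FALSE)
  }
  list(nodeStates = setNames(val, vapply(seq_len(nNode), nodeLabelOf, "",
                                         tree = tree)),
       changes = if (length(changes)) do.call(rbind, changes)
         else data.frame(branch = character(), from = character(),
                         to = character(), stringsAsFactors = FALSE))
}

#' Count exon-loss events across species
#'
#' For every internal exon between canonically adjacent snoRNA families
#' (reference order), species where both flanking introns are intact are
#' scored for exon presence (any exonic nt between the introns) or absence
#' (introns in juxtaposition); Fitch parsimony with an exon-present root
#' prior places each loss on a branch.
#'
#' @param annots named list of per-species \code{\link{annotateGenome}}
#'   results
#' @param tree rooted \code{phylo}
#' @param references named character vector (canonical family order)
#' @return list(count, events) where events is a list of
#'   \code{EvolutionEvent} of kind exon_loss
#' @export
countExonLoss <- function(annots, tree, references) {
  fams <- names(references)
  species <- names(annots)
  events <- list()
  ## per species, the reference families hosted by intact introns, in order
  famOrder <- lapply(species, function(sp) {
    arch <- annots[[sp]]$architecture
    if (is.null(arch)) return(character(0L))
    el <- elements(arch)
    el$family[el$kind == "intron" & !is.na(el$family) & el$family %in% fams]
  })
  names(famOrder) <- species
  ## candidate exon positions: ordered family pairs adjacent in >= 1 species
  pairs <- unique(do.call(rbind, lapply(species, function(sp) {
    fo <- famOrder[[sp]]
    if (length(fo) < 2L) return(NULL)
    data.frame(a = fo[-length(fo)], b = fo[-1L], stringsAsFactors = FALSE)
  })))
  nTip <- length(tree$tip.label)
  for (r in seq_len(nrow(pairs %||% data.frame()))) {
    fa <- pairs$a[r]; fb <- pairs$b[r]
    leafStates <- setNames(rep(NA_character_, length(species)), species)
    for (sp in species) {
      fo <- famOrder[[sp]]
      ia <- match(fa, fo); ib <- match(fb, fo)
      if (is.na(ia) || is.na(ib) || ib != ia + 1L) next   # not adjacent here
      arch <- annots[[sp]]$architecture
      el <- elements(arch)
      ea <- which(el$kind == "intron" & !is.na(el$family) & el$family == fa)
      eb <- which(el$kind == "intron" & !is.na(el$family) & el$family == fb)
      between <- el[seq.int(ea + 1L, length.out = eb - ea - 1L), ,
                    drop = FALSE]
      exonNt <- sum(between$end[between$kind == "exon"] -
                      between$start[between$kind == "exon"])
      leafStates[sp] <- if (exonNt > 0L) "present" else "absent"
    }
    informative <- names(leafStates)[!is.na(leafStates)]
    if (!length(informative)) next
    ## the exon position exists only where the pair is adjacent; root the
    ## reconstruction at the smallest clade containing those species, with
    ## the exon present at its origin
    subRoot <- if (length(informative) == 1L)
      match(informative, tree$tip.label)
      else ape::getMRCA(tree, informative)
    if (all(leafStates[informative] == "absent")) {
      ## lost everywhere the pair is visible: one loss on the stem
      events[[length(events) + 1L]] <- EvolutionEvent(
        kind = "exon_loss", branch = nodeLabelOf(tree, subRoot),
        subject = paste0("exon:", fa, "|", fb),
        evidenceType = "juxtaposed_introns", confidence = "supported")
      next
    }
    fit <- dolloReconstruction(tree, leafStates,
                               order = c("present", "absent"),
                               rootState = "present", subtreeRoot = subRoot)
    ch <- fit$changes
    for (q in seq_len(nrow(ch))) {
      if (!(ch$from[q] == "present" && ch$to[q] == "absent")) next
      events[[length(events) + 1L]] <- EvolutionEvent(
        kind = "exon_loss", branch = ch$branch[q],
        subject = paste0("exon:", fa, "|", fb),
        evidenceType = "juxtaposed_introns", confidence = "supported")
    }
  }
  list(count = length(events), events = events)
}

## ---- pipeline + evaluation ------------------------------------------------

#' Compare cluster architectures across species and classify events
#'
#' The full comparative pipeline: per-species scan and annotation (unless
#' precomputed annotations are supplied), presence/absence matrix, loss
#' evidence gathering (relocated copies, residual stubs), event placement,
#' exon-loss counting and junction-repeat annotation of insertion events.
#'
#' @param genomes named character vector of genome sequences (one record
#'   per species)
#' @param tree rooted \code{phylo}; tips must match \code{names(genomes)}
#' @param references named character vector of family reference sequences
#' @param rRNA rRNA decoy sequence
#' @param annots optional precomputed per-species annotation list
#' @return list(matrix, events, exonLossCount, annots)
#' @export
compareClusters <- function(genomes, tree, references, rRNA, annots = NULL) {
  if (is.null(annots)) {
    annots <- lapply(names(genomes), function(sp)
      annotateGenome(genomes[[sp]], recordIdOf(sp), references, rRNA))
    names(annots) <- names(genomes)
  }
  annots <- refineAnnotations(annots, genomes, references)
  pam <- buildPresenceAbsenceMatrix(annots, genomes, references)
  pam <- gatherLossEvidence(pam, annots, genomes, tree, references)
  events <- placeEvents(pam, tree)
  exl <- countExonLoss(annots, tree, references)
  events <- c(events, exl$events)
  events <- lapply(events, annotateEventJunctions, genomes = genomes)
  list(matrix = pam, events = events, exonLossCount = exl$count,
       annots = annots)
}

#' Precision and recall of event recovery against a simulator truth log
#'
#' Events are matched as multisets of (kind, branch) pairs.
#'
#' @param detected list of \code{EvolutionEvent} or a data.frame with kind
#'   and branch columns
#' @param truth the simulator \code{eventLog} data.frame
#' @return list(precision, recall, nDetected, nTruth, nMatched)
#' @export
evaluateEventRecovery <- function(detected, truth) {
  det <- if (is.data.frame(detected)) detected
    else eventsAsDataFrame(detected)
  dk <- paste(det$kind, det$branch)
  tk <- paste(truth$kind, truth$branch)
  matched <- 0L
  for (key in unique(c(dk, tk)))
    matched <- matched + min(sum(dk == key), sum(tk == key))
  list(precision = if (length(dk)) matched / length(dk) else 1,
       recall = if (length(tk)) matched / length(tk) else 1,
       nDetected = length(dk), nTruth = length(tk), nMatched = matched)
}
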