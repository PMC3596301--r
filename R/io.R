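## io_formats: FASTA / GFF3 / newick / TSV / JSON / YAML at the package
## boundary. Internally every interval is 0-based half-open; GFF3 is written
## 1-based inclusive and converted back on import.

#' Read a genome FASTA file
#'
#' Reads a FASTA file into a named character vector of uppercase DNA
#' sequences. Lowercase input is normalised to uppercase; sequences are
#' restricted to A, C, G, T, N (N is permitted in real assemblies and is
#' treated as a mismatch by all motif scanners).
#'
#' @param path FASTA file path
#' @return named character vector; names are record ids, values sequences
#' @export
readGenomeFasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  set <- tryCatch(Biostrings::readBStringSet(path),
                  error = function(e) stop("not a FASTA file: ", path))
  if (length(set) == 0L) stop("format error: empty FASTA file: ", path)
  ids <- sub("\\s.*$", "", names(set))
  dup <- ids[duplicated(ids)]
  if (length(dup))
    stop("format error: duplicate record id(s): ",
         paste(unique(dup), collapse = ", "))
  seqs <- toupper(as.character(set))
  bad <- grepl("[^ACGTN]", seqs)
  if (any(bad))
    stop("format error: invalid characters (gaps or non-ACGTN) in record(s): ",
         paste(ids[bad], collapse = ", "))
  setNames(seqs, ids)
}

#' Write sequences to FASTA
#'
#' @param seqs named character vector of sequences
#' @param path output path
#' @param width line wrap width
#' @return invisibly, \code{path}
#' @export
writeGenomeFasta <- function(seqs, path, width = 70L) {
  stopifnot(!is.null(names(seqs)), !anyDuplicated(names(seqs)))
  set <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(set, filepath = path, width = width)
  invisible(path)
}

#' Write snoRNA and intron annotations to GFF3
#'
#' Feature types are "snoRNA" and "intron". Internal 0-based half-open
#' intervals are converted to the 1-based inclusive GFF3 convention at the
#' file boundary. snoRNA attributes carry family, identity and (when set)
#' the chimeric split; intron attributes carry the hosted snoRNA family and
#' the intronic/exonic label of that snoRNA is emitted on the snoRNA
#' feature.
#'
#' @param snornas list of \code{SnoRNAAnnotation}
#' @param introns list of \code{IntronAnnotation}
#' @param path output path
#' @param genomes optional named character vector of genome sequences; when
#'   given, annotations are checked against record bounds
#' @return invisibly, \code{path}
#' @export
writeAnnotationsGFF3 <- function(snornas, introns, path, genomes = NULL) {
  rows <- list()
  intronic <- character(0L)
  for (ia in introns)
    if (!is.na(ia@snornaFamily)) intronic <- c(intronic, ia@snornaFamily)
  checkBounds <- function(rid, s, e) {
    if (!is.null(genomes)) {
      if (!rid %in% names(genomes))
        stop("annotation references unknown record: ", rid)
      if (s < 0L || e > nchar(genomes[[rid]]))
        stop("annotation outside record bounds on ", rid)
    }
  }
  for (a in snornas) {
    checkBounds(a@recordId, a@start, a@end)
    attrs <- c(sprintf("family=%s", a@family),
               sprintf("identity=%s", format(a@familyIdentity, digits = 6)),
               sprintf("label=%s", if (a@family %in% intronic) "intronic" else "exonic"),
               sprintf("box_c=%d;box_c_seq=%s", a@boxCStart + 1L, a@boxCSeq),
               sprintf("box_d=%d;box_d_seq=%s", a@boxDStart + 1L, a@boxDSeq))
    if (!is.na(a@guideStart))
      attrs <- c(attrs, sprintf("guide=%d-%d", a@guideStart + 1L, a@guideEnd))
    if (length(a@chimeric))
      attrs <- c(attrs, sprintf("chimeric=%s|%s|%d", a@chimeric$family5,
                                a@chimeric$family3, a@chimeric$breakpoint))
    rows[[length(rows) + 1L]] <-
      sprintf("%s\tsnoEvol\tsnoRNA\t%d\t%d\t.\t+\t.\t%s",
              a@recordId, a@start + 1L, a@end, paste(attrs, collapse = ";"))
  }
  for (a in introns) {
    checkBounds(a@recordId, a@start, a@end)
    attrs <- c(sprintf("snorna=%s", a@snornaFamily),
               sprintf("donor=%s", a@donorSeq),
               sprintf("acceptor=%s", a@acceptorSeq))
    if (!is.na(a@branchStart))
      attrs <- c(attrs, sprintf("branch=%d;branch_seq=%s",
                                a@branchStart + 1L, a@branchSeq))
    if (!is.na(a@signalScore))
      attrs <- c(attrs, sprintf("signal_score=%s",
                                format(a@signalScore, digits = 6)))
    rows[[length(rows) + 1L]] <-
      sprintf("%s\tsnoEvol\tintron\t%d\t%d\t.\t+\t.\t%s",
              a@recordId, a@start + 1L, a@end, paste(attrs, collapse = ";"))
  }
  lines <- unlist(rows, use.names = FALSE)
  if (length(lines)) {
    key <- do.call(rbind, strsplit(lines, "\t", fixed = TRUE))
    ord <- order(key[, 1L], as.integer(key[, 4L]), as.integer(key[, 5L]),
                 key[, 3L])
    lines <- lines[ord]
  }
  writeLines(c("##gff-version 3", lines), path)
  invisible(path)
}

#' Read annotations from a GFF3 file written by \code{writeAnnotationsGFF3}
#'
#' @param path GFF3 path
#' @return list with components \code{snornas} and \code{introns}
#' @export
readAnnotationsGFF3 <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  snornas <- list(); introns <- list()
  if (length(gr)) {
    md <- as.data.frame(gr)
    for (i in seq_len(nrow(md))) {
      rid <- as.character(md$seqnames[i])
      s0 <- md$start[i] - 1L; e0 <- md$end[i]
      if (md$type[i] == "snoRNA") {
        chim <- list()
        if (!is.null(md$chimeric) && !is.na(md$chimeric[i])) {
          p <- strsplit(md$chimeric[i], "|", fixed = TRUE)[[1L]]
          chim <- list(family5 = p[1L], family3 = p[2L],
                       breakpoint = as.integer(p[3L]))
        }
        g0 <- NA_integer_; g1 <- NA_integer_
        if (!is.null(md$guide) && !is.na(md$guide[i])) {
          p <- as.integer(strsplit(md$guide[i], "-", fixed = TRUE)[[1L]])
          g0 <- p[1L] - 1L; g1 <- p[2L]
        }
        snornas[[length(snornas) + 1L]] <- SnoRNAAnnotation(
          recordId = rid, start = s0, end = e0,
          family = md$family[i],
          familyIdentity = as.numeric(md$identity[i]),
          boxCStart = as.integer(md$box_c[i]) - 1L, boxCSeq = md$box_c_seq[i],
          boxDStart = as.integer(md$box_d[i]) - 1L, boxDSeq = md$box_d_seq[i],
          guideStart = g0, guideEnd = g1, chimeric = chim)
      } else if (md$type[i] == "intron") {
        bs <- NA_integer_; bseq <- NA_character_
        if (!is.null(md$branch) && !is.na(md$branch[i])) {
          bs <- as.integer(md$branch[i]) - 1L
          bseq <- md$branch_seq[i]
        }
        introns[[length(introns) + 1L]] <- IntronAnnotation(
          recordId = rid, start = s0, end = e0,
          donorSeq = md$donor[i], branchStart = bs, branchSeq = bseq,
          acceptorSeq = md$acceptor[i],
          snornaFamily = if (is.null(md$snorna)) NA_character_
                         else md$snorna[i],
          signalScore = if (is.null(md$signal_score)) NA_real_
                        else suppressWarnings(as.numeric(md$signal_score[i])))
      }
    }
  }
  list(snornas = snornas, introns = introns)
}

#' Read a rooted species tree in newick format
#'
#' Leaf labels must be unique; internal nodes without labels are assigned
#' stable labels n1, n2, ... in ape's node numbering order so that tree
#' edges can be named by their child node.
#'
#' @param path newick file path (single rooted tree)
#' @return an ape \code{phylo} with node labels
#' @export
readSpeciesTree <- function(path) {
  txt <- paste(readLines(path, warn = FALSE), collapse = "")
  readSpeciesTreeText(txt)
}

#' @rdname readSpeciesTree
#' @param text newick string
#' @export
readSpeciesTreeText <- function(text) {
  nopen <- lengths(regmatches(text, gregexpr("(", text, fixed = TRUE)))
  nclose <- lengths(regmatches(text, gregexpr(")", text, fixed = TRUE)))
  if (nopen != nclose)
    stop("newick parse error: unmatched parentheses")
  tree <- tryCatch(ape::read.tree(text = text),
                   error = function(e) stop("newick parse error: ",
                                            conditionMessage(e)))
  if (is.null(tree)) stop("newick parse error")
  if (anyDuplicated(tree$tip.label))
    stop("format error: duplicate leaf label(s): ",
         paste(unique(tree$tip.label[duplicated(tree$tip.label)]),
               collapse = ", "))
  if (is.null(tree$node.label) || any(tree$node.label == ""))
    tree$node.label <- paste0("n", seq_len(tree$Nnode))
  tree
}

#' Write a species tree to newick
#'
#' @param tree ape \code{phylo}
#' @param path output path
#' @return invisibly, \code{path}
#' @export
writeSpeciesTree <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' Write the presence/absence matrix to TSV
#'
#' @param pam a \code{PresenceAbsenceMatrix}
#' @param path output path
#' @return invisibly, \code{path}
#' @export
writeMatrixTSV <- function(pam, path) {
  df <- data.frame(group = rownames(pam@states), pam@states,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write classified events to TSV
#'
#' Columns: kind, branch, subject, evidence_type, evidence_detail,
#' confidence.
#'
#' @param events list of \code{EvolutionEvent}
#' @param path output path
#' @return invisibly, \code{path}
#' @export
writeEventsTSV <- function(events, path) {
  df <- eventsAsDataFrame(events)
  df$evidence_detail <- vapply(events, function(e) {
    if (!length(e@evidence)) return("")
    as.character(jsonlite::toJSON(e@evidence, auto_unbox = TRUE))
  }, "")
  df <- df[, c("kind", "branch", "subject", "evidence_type",
               "evidence_detail", "confidence")]
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write the simulator ground-truth event log to JSON
#'
#' @param eventLog the \code{eventLog} data.frame of a simulation result
#' @param path output path
#' @return invisibly, \code{path}
#' @export
writeEventLogJSON <- function(eventLog, path) {
  jsonlite::write_json(eventLog, path, auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(path)
}

#' Read a simulation configuration from YAML
#'
#' Any field of \code{\link{simulationConfig}} may be set in the YAML file;
#' unset fields keep their defaults.
#'
#' @param path YAML file path
#' @return a \code{SimulationConfig}
#' @export
readSimulationConfigYAML <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(simulationConfig, vals)
}

#' Write all outputs of a simulation run to a directory
#'
#' Emits one \code{<species>.fasta} and \code{<species>.truth.gff3} per
#' leaf, \code{tree.nwk}, \code{snorna_refs.fasta}, \code{rrna.fasta} and
#' \code{truth_events.json}.
#'
#' @param sim a \code{SimulationResult}
#' @param dir output directory (created if missing)
#' @return invisibly, \code{dir}
#' @export
writeSimulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (sp in names(sim@genomes)) {
    writeGenomeFasta(setNames(sim@genomes[[sp]], sp),
                     file.path(dir, paste0(sp, ".fasta")))
    ann <- sim@annotations[[sp]]
    writeAnnotationsGFF3(ann$snornas, ann$introns,
                         file.path(dir, paste0(sp, ".truth.gff3")))
  }
  writeSpeciesTree(sim@tree, file.path(dir, "tree.nwk"))
  writeGenomeFasta(sim@references, file.path(dir, "snorna_refs.fasta"))
  writeGenomeFasta(setNames(sim@rRNA, "rRNA_decoy"),
                   file.path(dir, "rrna.fasta"))
  writeEventLogJSON(sim@eventLog, file.path(dir, "truth_events.json"))
  invisible(dir)
}
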