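# File I/O for alignments (FASTA, NEXUS) and trees (Newick), built on ape.

#' @importFrom ape read.FASTA write.FASTA as.DNAbin read.nexus.data
#'   write.nexus.data read.tree write.tree dist.topo
NULL

alnToCharList <- function(aln) {
  m <- alignmentMatrix(aln)
  stats::setNames(lapply(seq_len(nrow(m)), function(i) m[i, ]),
                  rownames(m))
}

charListToAln <- function(x, file) {
  lens <- lengths(x)
  if (length(unique(lens)) != 1L)
    stop("unequal sequence lengths in ", file)
  m <- do.call(rbind, lapply(x, toupper))
  rownames(m) <- names(x)
  bad <- which(!m %in% NUC)
  if (length(bad))
    stop("non-ACGT character in ", file, " (sequence row ",
         ((bad[1] - 1) %% nrow(m)) + 1, ")")
  Alignment(m)
}

#' Read and write alignments
#'
#' FASTA and NEXUS (sequential or interleaved DATA block) readers/writers
#' with lossless round-tripping for simulated ACGT alignments.
#'
#' @param aln an \code{\link{Alignment}}.
#' @param file path.
#' @param interleaved write the NEXUS matrix interleaved.
#' @return \code{readFasta}/\code{readNexusAlignment} return an
#'   \code{Alignment}; the writers return \code{file} invisibly.
#' @name alignment-io
NULL

#' @rdname alignment-io
#' @export
writeFasta <- function(aln, file) {
  stopifnot(is(aln, "Alignment"))
  ape::write.FASTA(ape::as.DNAbin(alnToCharList(aln)), file)
  invisible(file)
}

#' @rdname alignment-io
#' @export
readFasta <- function(file) {
  if (!file.exists(file)) stop("no such file: ", file)
  x <- tryCatch(ape::read.FASTA(file),
                error = function(e) stop("failed to parse FASTA ", file,
                                         ": ", conditionMessage(e)))
  charListToAln(lapply(as.character(x), identity), file)
}

#' @rdname alignment-io
#' @export
writeNexusAlignment <- function(aln, file, interleaved = FALSE) {
  stopifnot(is(aln, "Alignment"))
  ape::write.nexus.data(alnToCharList(aln), file,
                        interleaved = interleaved)
  invisible(file)
}

#' @rdname alignment-io
#' @export
readNexusAlignment <- function(file) {
  if (!file.exists(file)) stop("no such file: ", file)
  x <- tryCatch(ape::read.nexus.data(file),
                error = function(e) stop("failed to parse NEXUS ", file,
                                         ": ", conditionMessage(e)))
  charListToAln(x, file)
}

#' Read and write trees in Newick format
#'
#' Thin wrappers over ape's Newick support; branch lengths are written with
#' 10 significant digits so round trips preserve them to well below 1e-9.
#'
#' @param tree a \code{phylo}.
#' @param file path.
#' @return \code{readNewick} returns a \code{phylo} (or \code{multiPhylo}
#'   when the file holds several trees); \code{writeNewick} returns
#'   \code{file} invisibly.
#' @name tree-io
NULL

#' @rdname tree-io
#' @export
writeNewick <- function(tree, file) {
  ape::write.tree(tree, file, digits = 10)
  invisible(file)
}

#' @rdname tree-io
#' @export
readNewick <- function(file) {
  if (!file.exists(file)) stop("no such file: ", file)
  tryCatch(ape::read.tree(file),
           error = function(e) stop("failed to parse Newick ", file, ": ",
                                    conditionMessage(e)))
}
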