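#' Molecular reference classes used throughout the pipeline
#'
#' The composition profile distinguishes small-RNA reads by the molecule
#' they derive from: mature miRNA, ribosomal, transfer and messenger RNA
#' breakdown products, retroelement transcripts and pri-miRNA precursors.
#' @export
REFERENCE_CLASSES <- c("miRNA", "rRNA", "tRNA", "mRNA",
                       "retroelement", "pri-miRNA", "genome")

#' Create a named reference set
#'
#' A reference set is a named collection of DNA sequences sharing one
#' molecular class label (e.g. all mature miRNAs, or all rRNA transcripts).
#'
#' @param sequences named character vector of A/C/G/T sequences.
#' @param class one of [REFERENCE_CLASSES].
#' @return an object of class `reference_set`.
#' @export
reference_set <- function(sequences, class) {
  class <- match.arg(class, REFERENCE_CLASSES)
  if (!length(sequences)) stop("reference set must contain at least one sequence")
  if (is.null(names(sequences)) || anyNA(names(sequences)) ||
      any(names(sequences) == "")) {
    stop("all reference sequences must be named")
  }
  if (anyDuplicated(names(sequences))) {
    stop("duplicated reference names in class ", class)
  }
  seqs <- setNames(toupper(as.character(sequences)), names(sequences))
  structure(
    list(sequences = seqs, names = names(seqs), class = class),
    class = "reference_set"
  )
}

#' @export
print.reference_set <- function(x, ...) {
  cat(sprintf("<reference_set> class %s: %d sequences, lengths %d-%d\n",
              x$class, length(x$sequences),
              min(nchar(x$sequences)), max(nchar(x$sequences))))
  invisible(x)
}

#' @export
length.reference_set <- function(x) length(x$sequences)

# Flatten one or more reference sets into a table (name, seq, class).
ref_table <- function(refs) {
  if (inherits(refs, "reference_set")) refs <- list(refs)
  rbindlist(lapply(refs, function(r) {
    stopifnot(inherits(r, "reference_set"))
    data.table(ref = r$names, seq = unname(r$sequences), class_ = r$class)
  }))
}

#' Write a reference set to FASTA
#'
#' @param refset a [reference_set()].
#' @param path output FASTA file.
#' @return `path`, invisibly.
#' @export
write_reference_fasta <- function(refset, path) {
  stopifnot(inherits(refset, "reference_set"))
  ss <- Biostrings::DNAStringSet(refset$sequences)
  names(ss) <- refset$names
  Biostrings::writeXStringSet(ss, filepath = path)
  invisible(path)
}

#' Read a reference set from FASTA
#'
#' @param path FASTA file.
#' @param class molecular class label for every sequence in the file.
#' @return a [reference_set()].
#' @export
read_reference_fasta <- function(path, class) {
  ss <- Biostrings::readDNAStringSet(path)
  seqs <- as.character(ss)
  # keep only the first whitespace-delimited token of the header
  names(seqs) <- sub("\\s.*$", "", names(ss))
  reference_set(seqs, class)
}
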