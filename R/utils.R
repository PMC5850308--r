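#' @importFrom data.table data.table setkey setorder rbindlist := .N .SD fwrite fread
#' @importFrom stats rbinom rlnorm rmultinom rnbinom rpois runif rnorm lm coef var sd cor setNames
#' @importFrom utils head
NULL

# silence R CMD check notes for data.table NSE columns
utils::globalVariables(c(
  ".", "frequency", "sequence", "lookup", "qid", "strand", "mm", "mut",
  "ref", "class_", "pos0", "reference_name", "position", "n_mismatches",
  "query_id", "score", "taxon", "bin", "family", "reference_class",
  "damage_consistent", "prio", "query_sequence", "reflen", "qseq",
  "mismatch_ref_pos", "maps_genome", "kept", "consistent", "exogenous",
  "endogenous", "id", "read_id", "n_damage", "damage_pos", "insert",
  "insert_len", "class", "call", "sample_id", "source_ref", "start", "n", "u"
))

DNA_BASES <- c("A", "C", "G", "T")

#' Reverse complement of DNA strings
#'
#' Vectorised reverse complement over A/C/G/T/N strings. Strings containing
#' characters outside that alphabet are passed through a character-level
#' complement (unknown characters unchanged), so they can never gain a match
#' they would not otherwise have.
#'
#' @param x character vector of sequences.
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  if (!length(x)) return(character(0))
  out <- character(length(x))
  ok <- grepl("^[ACGTN]*$", x)
  if (any(ok)) {
    out[ok] <- as.character(
      Biostrings::reverseComplement(Biostrings::DNAStringSet(x[ok]))
    )
  }
  if (any(!ok)) {
    comp <- chartr("ACGTNacgtn", "TGCANtgcan", x[!ok])
    out[!ok] <- vapply(
      strsplit(comp, "", fixed = TRUE),
      function(ch) paste(rev(ch), collapse = ""),
      character(1)
    )
  }
  out
}

# Deterministic sub-seed derivation: one master seed fans out to independent
# stage seeds. Kept below 2^31 - 1 so set.seed() always accepts it.
derive_seed <- function(seed, tag) {
  v <- utf8ToInt(tag)
  h <- sum(v * seq_along(v)) %% 2147483647
  as.integer((as.numeric(seed) %% 2147483647 * 48271 + h * 9973 + 1) %% 2147483647)
}

# Random DNA strings (uniform base composition).
rand_dna <- function(n, len) {
  if (length(len) == 1L) len <- rep.int(len, n)
  chars <- sample(DNA_BASES, sum(len), replace = TRUE)
  ends <- cumsum(len)
  starts <- ends - len + 1L
  vapply(seq_len(n), function(i) {
    paste(chars[starts[i]:ends[i]], collapse = "")
  }, character(1))
}

# Trapezoid integral of y over x (x strictly increasing).
trapz <- function(x, y) {
  n <- length(x)
  sum((y[-1] + y[-n]) * diff(x)) / 2
}
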