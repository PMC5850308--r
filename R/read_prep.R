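#' Trim the 3' adapter from reads
#'
#' Truncates each read at the leftmost position where a prefix of the
#' adapter matches exactly. The compared prefix length is the smaller of the
#' remaining read length and the full adapter length, and must be at least
#' `min_overlap`; reads with no such match are returned unchanged. The match
#' is exact (no mismatches): synthetic adapters are error-free and no
#' tolerance is specified for the original data.
#'
#' @param reads character vector of read sequences (may be empty strings).
#' @param adapter adapter sequence (non-empty).
#' @param min_overlap minimum adapter prefix length that counts as a match.
#' @return character vector of trimmed reads.
#' @export
trim_adapter <- function(reads, adapter, min_overlap = 5L) {
  adapter <- toupper(adapter)
  min_overlap <- as.integer(min_overlap)
  if (!nzchar(adapter)) stop("adapter must be non-empty")
  if (min_overlap < 1L) stop("min_overlap must be >= 1")
  if (!length(reads)) return(character(0))
  n <- nchar(reads)
  alen <- nchar(adapter)
  cut <- rep.int(NA_integer_, length(reads))
  if (max(n) >= min_overlap) {
    for (i in seq_len(max(n) - min_overlap + 1L)) {
      todo <- which(is.na(cut) & n - i + 1L >= min_overlap)
      if (!length(todo)) break
      L <- pmin(n[todo] - i + 1L, alen)
      hit <- substring(reads[todo], i, i + L - 1L) == substring(adapter, 1L, L)
      cut[todo[hit]] <- i
    }
  }
  ifelse(is.na(cut), reads, substr(reads, 1L, cut - 1L))
}

#' Size-parse trimmed reads into the small-RNA window
#'
#' Keeps reads whose trimmed length lies in `[min_len, max_len]` (default
#' 18-25 nt, the small regulatory RNA size range) and reports the size-passing
#' fraction.
#'
#' @param reads character vector of adapter-trimmed reads.
#' @param min_len,max_len inclusive size window.
#' @param sample_id optional sample label attached to the output.
#' @return list with `reads` (data.table: `sequence`, `sample_id`) and
#'   `report` (list: `total_reads`, `size_passing`, `srna_fraction`,
#'   `empty_input` flag; the fraction is reported as 0 with the flag set when
#'   the input is empty).
#' @export
parse_size <- function(reads, min_len = 18L, max_len = 25L, sample_id = NA_character_) {
  stopifnot(min_len >= 1L, max_len >= min_len)
  len <- nchar(reads)
  keep <- len >= min_len & len <= max_len
  total <- length(reads)
  list(
    reads = data.table(sequence = reads[keep], sample_id = sample_id),
    report = list(
      total_reads = total,
      size_passing = sum(keep),
      srna_fraction = if (total > 0L) sum(keep) / total else 0,
      empty_input = total == 0L
    )
  )
}

#' Collapse reads into unique sequences with frequencies
#'
#' Dereplication: one row per distinct sequence carrying the summed read
#' frequency. The operation is idempotent and conserves total frequency.
#'
#' @param reads character vector of sequences, or a data.frame/data.table
#'   with columns `sequence` and (optionally) `frequency`.
#' @return data.table with columns `sequence`, `frequency`, ordered by
#'   decreasing frequency then sequence.
#' @export
dereplicate <- function(reads) {
  if (is.character(reads)) {
    dt <- data.table(sequence = reads, frequency = 1L)
  } else {
    dt <- data.table::as.data.table(reads)
    if (!"sequence" %in% names(dt)) stop("input must have a 'sequence' column")
    if (!"frequency" %in% names(dt)) dt[, frequency := 1L]
  }
  out <- dt[, .(frequency = sum(frequency)), by = sequence]
  setorder(out, -frequency, sequence)
  out[]
}

#' Full read preparation: trim, size-parse, dereplicate
#'
#' The primary-data processing stage: adapter removal, parsing into 18-25 nt
#' small-RNA-sized sequences, and identification of sequence frequencies.
#'
#' @param raw character vector of raw read sequences.
#' @param adapter 3' adapter sequence.
#' @param min_overlap minimum adapter overlap for [trim_adapter()].
#' @param min_len,max_len size window for [parse_size()].
#' @param sample_id sample label.
#' @return list with `unique` (data.table: `sequence`, `frequency`) and
#'   `report` (`total_reads`, `adapter_trimmed`, `size_passing`,
#'   `srna_fraction`).
#' @export
prep_reads <- function(raw, adapter, min_overlap = 5L,
                       min_len = 18L, max_len = 25L,
                       sample_id = NA_character_) {
  trimmed <- trim_adapter(raw, adapter, min_overlap)
  parsed <- parse_size(trimmed, min_len, max_len, sample_id)
  list(
    unique = dereplicate(parsed$reads$sequence),
    report = c(list(sample_id = sample_id,
                    adapter_trimmed = sum(trimmed != raw)),
               parsed$report)
  )
}
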