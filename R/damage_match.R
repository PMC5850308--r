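#' Default class priority for resolving multi-class hits
#'
#' A read hitting several molecular classes is counted once, toward the most
#' specific class: miRNA > rRNA > tRNA > mRNA > retroelement > pri-miRNA >
#' genome.
#' @export
DEFAULT_CLASS_PRIORITY <- c("miRNA", "rRNA", "tRNA", "mRNA",
                            "retroelement", "pri-miRNA", "genome")

#' Build a substring index over reference sets
#'
#' Enumerates every forward-strand window of lengths `min_len..max_len` over
#' all references and keys them for constant-time exact lookup. Windows
#' containing characters outside A/C/G/T (e.g. N) are dropped: an ambiguous
#' base never matches. Queries are matched against this index directly
#' (exact) and, in ancient mode, through their deamination back-mutations,
#' so a seed-and-extend aligner is not needed at this scale.
#'
#' @param refs a [reference_set()] or list of them.
#' @param min_len,max_len query length window the index must serve.
#' @return an object of class `match_index`.
#' @export
build_match_index <- function(refs, min_len = 18L, max_len = 25L) {
  rt <- ref_table(refs)
  if (anyDuplicated(rt$ref)) stop("duplicated reference names across sets")
  pieces <- vector("list", nrow(rt) * (max_len - min_len + 1L))
  k <- 0L
  for (i in seq_len(nrow(rt))) {
    s <- rt$seq[i]
    L <- nchar(s)
    for (len in min_len:max_len) {
      if (L < len) next
      starts <- seq_len(L - len + 1L)
      k <- k + 1L
      pieces[[k]] <- data.table(
        seq = substring(s, starts, starts + len - 1L),
        ref = rt$ref[i], class_ = rt$class_[i],
        pos0 = starts - 1L
      )
    }
  }
  dt <- rbindlist(pieces[seq_len(k)])
  dt <- dt[grepl("^[ACGT]+$", seq)]
  setkey(dt, seq)
  structure(list(windows = dt, min_len = min_len, max_len = max_len,
                 reflen = setNames(nchar(rt$seq), rt$ref)),
            class = "match_index")
}

#' @export
print.match_index <- function(x, ...) {
  cat(sprintf("<match_index> %d windows (%d-%d nt) over %d references\n",
              nrow(x$windows), x$min_len, x$max_len, length(x$reflen)))
  invisible(x)
}

# Core matching engine over a character vector of queries. Returns one row
# per (query, reference window, strand) occurrence.
match_engine <- function(queries, index, mode = c("ancient", "modern")) {
  mode <- match.arg(mode)
  stopifnot(inherits(index, "match_index"))
  empty <- data.table(query_sequence = character(0),
                      reference_name = character(0),
                      reference_class = character(0), strand = character(0),
                      position = integer(0), n_mismatches = integer(0),
                      mismatch_ref_pos = integer(0),
                      damage_consistent = logical(0))
  if (!length(queries)) return(empty)
  len <- nchar(queries)
  if (any(len < index$min_len | len > index$max_len)) {
    stop("query length outside the indexed window [",
         index$min_len, ", ", index$max_len, "]")
  }
  uq <- unique(queries[grepl("^[ACGT]+$", queries)])
  if (!length(uq)) return(empty)

  lookups <- list(
    data.table(lookup = uq, qseq = uq, strand = "+", mm = 0L, mut = NA_integer_),
    data.table(lookup = revcomp(uq), qseq = uq, strand = "-", mm = 0L,
               mut = NA_integer_)
  )
  if (mode == "ancient") {
    # one C>T deamination in the frame of the strand the read derives from:
    # back-mutate each read T to C and look the variant up exactly
    tpos <- gregexpr("T", uq, fixed = TRUE)
    nvar <- vapply(tpos, function(p) if (p[1] == -1L) 0L else length(p),
                   integer(1))
    if (sum(nvar) > 0L) {
      qrep <- rep(uq, nvar)
      pos <- unlist(tpos[nvar > 0L], use.names = FALSE)
      v <- qrep
      substr(v, pos, pos) <- "C"
      lookups <- c(lookups, list(
        data.table(lookup = v, qseq = qrep, strand = "+", mm = 1L, mut = pos),
        data.table(lookup = revcomp(v), qseq = qrep, strand = "-", mm = 1L,
                   mut = pos)
      ))
    }
  }
  lk <- rbindlist(lookups)
  res <- index$windows[lk, on = c(seq = "lookup"), nomatch = NULL,
                       allow.cartesian = TRUE]
  if (!nrow(res)) return(empty)
  qlen <- nchar(res$qseq)
  res[, `:=`(
    query_sequence = qseq,
    reference_name = ref,
    reference_class = class_,
    position = pos0,
    n_mismatches = mm,
    mismatch_ref_pos = data.table::fifelse(
      mm == 0L, NA_integer_,
      data.table::fifelse(strand == "+", pos0 + mut - 1L, pos0 + qlen - mut)),
    damage_consistent = TRUE
  )]
  res <- res[, .(query_sequence, reference_name, reference_class, strand,
                 position, n_mismatches, mismatch_ref_pos, damage_consistent)]
  setorder(res, query_sequence, reference_name, position, strand, n_mismatches)
  res[]
}

#' Match one small-RNA query against references
#'
#' Modern mode reports all exact occurrences of the query or its reverse
#' complement. Ancient mode additionally reports occurrences with exactly one
#' mismatch, accepted only when it is deamination-consistent: on the + strand
#' the reference carries C where the query reads T; on the - strand the
#' forward reference carries G where the reverse-complemented query implies
#' A. In both cases the mismatch is C-to-T in the coordinate frame of the
#' strand the read derives from. Results are sorted by reference name,
#' position, strand. Queries containing N (or any non-A/C/G/T character)
#' yield no matches.
#'
#' @param query a single sequence of length within the indexed window.
#' @param references a [build_match_index()], or reference set(s) to index
#'   on the fly.
#' @param mode `"ancient"` or `"modern"`.
#' @return data.table of match results (possibly empty) with columns
#'   `query_sequence`, `reference_name`, `reference_class`, `strand`,
#'   `position` (0-based on the reference forward strand), `n_mismatches`,
#'   `mismatch_ref_pos`, `damage_consistent`.
#' @export
match_srna <- function(query, references, mode = c("ancient", "modern")) {
  stopifnot(length(query) == 1L)
  if (!inherits(references, "match_index")) {
    n <- nchar(query)
    references <- build_match_index(references, min_len = n, max_len = n)
  }
  match_engine(query, references, mode)
}

#' Pick a single class assignment from a set of match results
#'
#' Prefers 0-mismatch hits over 1-mismatch hits; among equals, the earliest
#' class in `class_priority`; remaining ties broken by the deterministic sort
#' order (reference name, position, strand).
#'
#' @param results match results for one query (from [match_srna()]).
#' @param class_priority ordered character vector of classes.
#' @return one-row data.table (`class`, `reference_name`, `strand`,
#'   `position`, `n_mismatches`), or `NULL` when unassigned.
#' @export
assign_best <- function(results, class_priority = DEFAULT_CLASS_PRIORITY) {
  if (is.null(results) || !nrow(results)) return(NULL)
  res <- data.table::as.data.table(results)
  res[, prio := match(reference_class, class_priority)]
  if (anyNA(res$prio)) {
    stop("match results contain classes absent from class_priority: ",
         paste(unique(res$reference_class[is.na(res$prio)]), collapse = ", "))
  }
  setorder(res, n_mismatches, prio, reference_name, position, strand)
  res[1L, .(class = reference_class, reference_name, strand, position,
            n_mismatches)]
}

#' Assign every unique sequence of a sample to a molecular class
#'
#' Bulk wrapper: matches all unique sequences and applies the
#' [assign_best()] rule to each. Sequences with no acceptable hit are kept
#' with class `"unassigned"`, so that frequency totals are conserved.
#'
#' @param unique_reads data.table with columns `sequence`, `frequency`
#'   (from [dereplicate()]).
#' @param index a [build_match_index()].
#' @param mode `"ancient"` or `"modern"`.
#' @param class_priority ordered class vector, see [assign_best()].
#' @return data.table: `sequence`, `frequency`, `class`, `reference_name`,
#'   `strand`, `position`, `n_mismatches`.
#' @export
assign_reads <- function(unique_reads, index, mode = c("ancient", "modern"),
                         class_priority = DEFAULT_CLASS_PRIORITY) {
  mode <- match.arg(mode)
  ur <- data.table::as.data.table(unique_reads)
  stopifnot(all(c("sequence", "frequency") %in% names(ur)))
  res <- match_engine(ur$sequence, index, mode)
  if (nrow(res)) {
    res[, prio := match(reference_class, class_priority)]
    if (anyNA(res$prio)) {
      stop("match results contain classes absent from class_priority: ",
           paste(unique(res$reference_class[is.na(res$prio)]), collapse = ", "))
    }
    setorder(res, query_sequence, n_mismatches, prio, reference_name,
             position, strand)
    best <- res[!duplicated(query_sequence),
                .(sequence = query_sequence, class = reference_class,
                  reference_name, strand, position, n_mismatches)]
  } else {
    best <- data.table(sequence = character(0), class = character(0),
                       reference_name = character(0), strand = character(0),
                       position = integer(0), n_mismatches = integer(0))
  }
  out <- best[ur, on = "sequence"]
  out[is.na(class), class := "unassigned"]
  setorder(out, -frequency, sequence)
  out[, .(sequence, frequency, class, reference_name, strand, position,
          n_mismatches)]
}
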