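#' RNA half-life from per-seed nucleic-acid masses
#'
#' `T1/2 = T * log(2) / log(V1 / V2)` (base-independent), where `T` is the
#' elapsed time in years, `V1` the modern per-seed RNA mass and `V2` the
#' ancient per-seed RNA mass (both in micrograms). Per-seed masses are used
#' because desiccation skews per-mass comparisons.
#'
#' @param T_elapsed elapsed time in years (> 0); vectorised, so a dating
#'   range such as `c(600, 900)` yields the corresponding half-life range.
#' @param v_modern modern RNA mass per seed (micrograms).
#' @param v_ancient ancient RNA mass per seed (micrograms); must be positive
#'   and smaller than `v_modern` for a finite positive half-life.
#' @return half-life in years (same length as `T_elapsed`).
#' @export
half_life <- function(T_elapsed, v_modern, v_ancient) {
  if (any(T_elapsed <= 0)) stop("elapsed time must be positive")
  if (v_modern <= 0 || v_ancient <= 0) stop("masses must be positive")
  if (v_modern <= v_ancient) {
    stop("modern mass must exceed ancient mass (no decay signal)")
  }
  T_elapsed * log(2) / log(v_modern / v_ancient)
}

#' Relative degradation rate of RNA versus DNA
#'
#' Ratio of half-lives: how many times faster RNA decays than DNA at the
#' same site (fold = DNA half-life / RNA half-life).
#'
#' @param dna_half_life DNA half-life in years (> 0).
#' @param rna_half_life RNA half-life in years (> 0); vectorised.
#' @return degradation fold (> 1 means RNA decays faster).
#' @export
degradation_fold <- function(dna_half_life, rna_half_life) {
  if (any(dna_half_life <= 0)) stop("DNA half-life must be positive")
  if (any(rna_half_life <= 0)) stop("RNA half-life must be positive")
  dna_half_life / rna_half_life
}

#' GC content of sequences
#'
#' Percentage of G+C bases. U is canonicalised to T before counting (RNA-
#' and DNA-alphabet forms of the same molecule score identically); N bases
#' are excluded from both numerator and denominator.
#'
#' @param sequences character vector over A/C/G/T/U/N (case-insensitive).
#' @return numeric vector of GC percentages in `[0, 100]`.
#' @export
gc_content <- function(sequences) {
  if (!length(sequences) || any(!nzchar(sequences))) {
    stop("sequences must be non-empty")
  }
  s <- chartr("U", "T", toupper(sequences))
  if (any(grepl("[^ACGTN]", s))) {
    stop("sequences must use the A/C/G/T/U/N alphabet")
  }
  gc <- nchar(gsub("[^GC]", "", s))
  informative <- nchar(gsub("N", "", s))
  if (any(informative == 0L)) stop("sequence contains no informative (non-N) bases")
  100 * gc / informative
}

# integer-exact 0.1%-bin index: bin k covers [k * 0.1, (k + 1) * 0.1)
gc_bin_index <- function(sequences) {
  s <- chartr("U", "T", toupper(sequences))
  gc <- nchar(gsub("[^GC]", "", s))
  informative <- nchar(gsub("N", "", s))
  as.integer((1000 * gc) %/% informative)
}

#' Sort sequences into 0.1% GC bins and locate each miRNA's GC bin
#'
#' Sequences are assigned to half-open GC bins `[k*0.1, (k+1)*0.1)` percent.
#' Because multiple sequence forms of each miRNA exist, the "GC location" of
#' a miRNA is the bin holding the plurality of its sequence frequency
#' (plurality rather than strict majority: with 1000 bins an absolute
#' majority is rare); ties break toward the lower bin.
#'
#' @param sequences character vector of sequences.
#' @param frequencies per-sequence frequencies (default 1).
#' @param ids optional per-sequence group label (e.g. miRNA family); GC
#'   locations are reported per group.
#' @return object of class `gc_bin_table`: `bins` (data.table `bin_lo`,
#'   `bin_hi`, `frequency` over occupied bins), `gc` (per-sequence GC
#'   percentages), and `gc_location` (named numeric, lower bin edge per
#'   group; a single unnamed location when `ids` is `NULL`).
#' @export
gc_binning <- function(sequences, frequencies = NULL, ids = NULL) {
  if (!length(sequences)) {
    return(structure(list(bins = data.table(bin_lo = numeric(0),
                                            bin_hi = numeric(0),
                                            frequency = numeric(0)),
                          gc = numeric(0), gc_location = numeric(0)),
                     class = "gc_bin_table"))
  }
  if (is.null(frequencies)) frequencies <- rep.int(1L, length(sequences))
  stopifnot(length(frequencies) == length(sequences))
  gc <- gc_content(sequences)
  k <- gc_bin_index(sequences)
  dt <- data.table(bin = k, frequency = as.numeric(frequencies),
                   id = if (is.null(ids)) "all" else as.character(ids))
  bins <- dt[, .(frequency = sum(frequency)), by = bin]
  setorder(bins, bin)
  loc <- dt[, .(frequency = sum(frequency)), by = .(id, bin)]
  setorder(loc, id, -frequency, bin) # tie -> lower bin
  loc <- loc[!duplicated(id)]
  gc_location <- setNames(loc$bin / 10, loc$id)
  if (is.null(ids)) gc_location <- unname(gc_location)
  structure(
    list(bins = bins[, .(bin_lo = bin / 10, bin_hi = (bin + 1) / 10, frequency)],
         gc = gc,
         gc_location = gc_location),
    class = "gc_bin_table"
  )
}

#' @export
print.gc_bin_table <- function(x, ...) {
  cat(sprintf("<gc_bin_table> %d sequences over %d occupied 0.1%% bins\n",
              length(x$gc), nrow(x$bins)))
  if (length(x$gc_location)) {
    cat("  GC location(s):",
        paste(sprintf("%s=%.1f%%",
                      if (is.null(names(x$gc_location))) seq_along(x$gc_location)
                      else names(x$gc_location),
                      x$gc_location), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Correlation between GC content and relative expression
#'
#' @param gc numeric vector of GC percentages (one per miRNA).
#' @param expression paired relative expression values.
#' @return list: `r_squared` (squared Pearson correlation), `n`,
#'   `degenerate` flag (`TRUE` with `NA` when either vector has zero
#'   variance).
#' @export
gc_expression_correlation <- function(gc, expression) {
  if (length(gc) != length(expression)) stop("gc and expression must be paired")
  if (length(gc) < 3L) stop("need at least 3 paired values")
  if (var(gc) == 0 || var(expression) == 0) {
    return(list(r_squared = NA_real_, n = length(gc), degenerate = TRUE))
  }
  list(r_squared = cor(gc, expression)^2, n = length(gc), degenerate = FALSE)
}
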