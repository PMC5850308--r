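PROFILE_CLASSES <- c("miRNA", "rRNA", "tRNA", "mRNA", "retroelement",
                     "pri-miRNA", "unassigned")

#' Build per-sample composition and miRNA-family expression profiles
#'
#' Aggregates class assignments into (i) a molecular-class composition
#' profile of the small-RNA-sized reads and (ii) a miRNA-family count table.
#' Counts aggregate read frequencies, not unique sequences (a unique-sequence
#' table is provided alongside as a secondary view).
#'
#' @param assignments named list, one [assign_reads()] table per sample.
#' @param family_map named character vector mapping each miRNA reference
#'   name to its family. Any miRNA-assigned reference missing from the map
#'   is an error naming the reference.
#' @param total_reads named numeric vector of total library read counts
#'   (before size filtering), one per sample; used as the normalization
#'   denominator downstream.
#' @return object of class `srna_profiles`: list with `composition`
#'   (data.table, one row per sample with per-class frequency-weighted
#'   counts and `total_srna`), `expression` (matrix families x samples,
#'   read-level counts), `expression_unique` (same shape, unique-sequence
#'   counts), `total_mirna`, `total_reads`.
#' @export
build_profiles <- function(assignments, family_map, total_reads) {
  stopifnot(is.list(assignments), length(assignments) >= 1L)
  samples <- names(assignments)
  if (is.null(samples) || any(samples == "")) {
    stop("assignments must be a named list of per-sample tables")
  }
  if (!all(samples %in% names(total_reads))) {
    stop("total_reads missing for sample(s): ",
         paste(setdiff(samples, names(total_reads)), collapse = ", "))
  }
  comp <- rbindlist(lapply(samples, function(s) {
    a <- data.table::as.data.table(assignments[[s]])
    counts <- setNames(rep(0, length(PROFILE_CLASSES)), PROFILE_CLASSES)
    if (nrow(a)) {
      agg <- a[, .(n = sum(frequency)), by = class]
      bad <- setdiff(agg$class, PROFILE_CLASSES)
      if (length(bad)) stop("unknown class label(s): ", paste(bad, collapse = ", "))
      counts[agg$class] <- agg$n
    }
    data.table::as.data.table(c(list(sample_id = s), as.list(counts),
                                list(total_srna = sum(counts))))
  }))

  families <- sort(unique(unname(family_map)))
  expr <- matrix(0, nrow = length(families), ncol = length(samples),
                 dimnames = list(families, samples))
  expr_u <- expr
  for (s in samples) {
    a <- data.table::as.data.table(assignments[[s]])
    mi <- a[class == "miRNA"]
    if (!nrow(mi)) next
    missing <- setdiff(unique(mi$reference_name), names(family_map))
    if (length(missing)) {
      stop("miRNA reference(s) lacking a family mapping: ",
           paste(missing, collapse = ", "))
    }
    mi[, family := family_map[reference_name]]
    agg <- mi[, .(n = sum(frequency), u = .N), by = family]
    expr[agg$family, s] <- agg$n
    expr_u[agg$family, s] <- agg$u
  }
  structure(
    list(composition = comp[],
         expression = expr,
         expression_unique = expr_u,
         total_mirna = colSums(expr),
         total_reads = total_reads[samples]),
    class = "srna_profiles"
  )
}

#' @export
print.srna_profiles <- function(x, ...) {
  cat(sprintf("<srna_profiles> %d samples, %d miRNA families\n",
              nrow(x$composition), nrow(x$expression)))
  fr <- x$composition$rRNA / pmax(x$composition$total_srna, 1)
  cat(sprintf("  rRNA fraction of sRNA-sized reads: %.1f%% - %.1f%%\n",
              100 * min(fr), 100 * max(fr)))
  cat(sprintf("  total miRNA reads per sample: %s\n",
              paste(x$total_mirna, collapse = ", ")))
  invisible(x)
}

#' Retroelement transcript proportions
#'
#' Two views of retroelement activity: the retroelement share of all
#' small-RNA-sized reads, and the share relative to messenger RNA only
#' (retro / (mRNA + retro)), excluding rRNA and tRNA from the denominator
#' since neither is messenger RNA and responsive rRNA expression cannot be
#' assumed to reflect stress.
#'
#' @param composition one row of the composition table from
#'   [build_profiles()] (or any list with `retroelement`, `mRNA`,
#'   `total_srna` entries).
#' @return named numeric: `retro_vs_all`, `retro_vs_mrna`. A zero denominator
#'   yields `NA` for the affected proportion.
#' @export
retro_proportions <- function(composition) {
  retro <- as.numeric(composition[["retroelement"]])
  mrna <- as.numeric(composition[["mRNA"]])
  total <- as.numeric(composition[["total_srna"]])
  c(retro_vs_all = if (total > 0) retro / total else NA_real_,
    retro_vs_mrna = if (mrna + retro > 0) retro / (mrna + retro) else NA_real_)
}

#' Mean and standard deviation of per-sample frequencies
#'
#' @param counts non-empty numeric vector (one count per sample).
#' @param sd_type `"population"` (divisor n, default) or `"sample"`
#'   (divisor n-1).
#' @return named numeric: `mean`, `sd`.
#' @export
mean_frequency <- function(counts, sd_type = c("population", "sample")) {
  sd_type <- match.arg(sd_type)
  if (!length(counts)) stop("counts must be non-empty")
  m <- mean(counts)
  n <- length(counts)
  s2 <- if (n > 1L) sum((counts - m)^2) / (if (sd_type == "population") n else n - 1L)
        else 0
  c(mean = m, sd = sqrt(s2))
}

#' Target-transcript fragment counts with cross-platform correction
#'
#' Counts reads assigned to the GAMYB/PCF5/PCF6 target transcripts per
#' sample. Control-side correction is the arithmetic mean of matching
#' fragments across all control samples; the modern/ancient sequencing-depth
#' correction factor is an explicit user input (it cannot be derived from
#' library totals alone) and divides the ancient counts.
#'
#' @param assignments named list of [assign_reads()] tables.
#' @param mrna_refs the mRNA [reference_set()] containing the targets.
#' @param targets character vector of target reference names.
#' @param ancient_id name of the ancient sample within `assignments`
#'   (`NULL` if none).
#' @param correction_factor depth correction dividing the ancient counts.
#' @return list with `counts` (matrix targets x samples), `control_mean`
#'   (per-target arithmetic mean over controls), `ancient_corrected`
#'   (per-target ancient counts divided by `correction_factor`, or `NULL`).
#' @export
target_fragment_counts <- function(assignments, mrna_refs,
                                   targets = c("GAMYB", "PCF5", "PCF6"),
                                   ancient_id = NULL,
                                   correction_factor = 1) {
  missing <- setdiff(targets, mrna_refs$names)
  if (length(missing)) {
    stop("target reference(s) missing from the mRNA set: ",
         paste(missing, collapse = ", "))
  }
  if (correction_factor <= 0) stop("correction_factor must be positive")
  samples <- names(assignments)
  counts <- matrix(0, nrow = length(targets), ncol = length(samples),
                   dimnames = list(targets, samples))
  for (s in samples) {
    a <- data.table::as.data.table(assignments[[s]])
    hit <- a[class == "mRNA" & reference_name %in% targets,
             .(n = sum(frequency)), by = reference_name]
    if (nrow(hit)) counts[hit$reference_name, s] <- hit$n
  }
  controls <- setdiff(samples, ancient_id)
  control_mean <- if (length(controls)) rowMeans(counts[, controls, drop = FALSE])
                  else NULL
  ancient_corrected <- if (!is.null(ancient_id) && ancient_id %in% samples) {
    counts[, ancient_id] / correction_factor
  } else NULL
  list(counts = counts, control_mean = control_mean,
       ancient_corrected = ancient_corrected,
       correction_factor = correction_factor)
}
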