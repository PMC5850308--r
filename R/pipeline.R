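#' Run the full synthetic-study pipeline
#'
#' Orchestrates every stage end to end on synthetic data: reference and
#' library simulation, read preparation, damage-aware matching (one
#' deamination-consistent mismatch allowed for the ancient library, exact
#' matches only for the controls), class/expression profiling, retroelement
#' proportions, simplified Phylogenetic Intersect Analysis, normalization
#' and extended-Poisson differential assessment, and half-life/GC analysis.
#' A stage failure aborts with the failing stage named.
#'
#' @param config a [sim_config()]; its seed drives every stage
#'   deterministically.
#' @param decay list of half-life inputs: `T_elapsed` (years, may be a
#'   range), `v_modern` and `v_ancient` (micrograms RNA per seed),
#'   `dna_half_life` (years) for the degradation-fold comparison. The
#'   defaults are the archaeological barley measurements (600-900 years BP,
#'   65.2 vs 4.45 ug per seed, DNA half-life 350 years).
#' @param pia list of PIA-simulation options: `n_reads`, `endo_prop`,
#'   `tie_rate`, `offlineage_rate`, `subsample`.
#' @param correction_factor explicit modern/ancient depth correction for the
#'   target-transcript (GAMYB/PCF) stage.
#' @param level central likelihood-interval coverage for differential calls.
#' @param verbose print per-stage progress with counts in and out.
#' @return object of class `paleo_report`; see [report_json()] for the
#'   machine-readable form.
#' @export
run_pipeline <- function(config = sim_config(),
                         decay = list(T_elapsed = c(600, 900),
                                      v_modern = 65.2, v_ancient = 4.45,
                                      dna_half_life = 350),
                         pia = list(n_reads = 2000L, endo_prop = 0.9,
                                    tie_rate = 0.05, offlineage_rate = 0.15,
                                    subsample = NULL),
                         correction_factor = 1,
                         level = 0.95,
                         verbose = FALSE) {
  stopifnot(inherits(config, "sim_config"))
  say <- function(...) if (verbose) message(sprintf(...))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  refs <- stage("simulate", {
    say("simulate: building references (%d miRNA families)",
        config$n_mirna_families)
    make_references(config)
  })
  libs <- stage("simulate", {
    out <- c(list(ancient = simulate_library(config, refs, "ancient", 1L)),
             lapply(seq_len(config$n_controls), function(i) {
               simulate_library(config, refs, "modern", i)
             }))
    names(out) <- c("ancient", sprintf("control%02d", seq_len(config$n_controls)))
    say("simulate: %d libraries, %d reads total", length(out),
        sum(vapply(out, function(l) nrow(l$reads), numeric(1))))
    out
  })

  preps <- stage("prep", {
    lapply(libs, function(l) {
      prep_reads(l$reads$read, config$adapter_seq,
                 sample_id = l$meta$sample_id)
    })
  })
  say("prep: sRNA fractions %s",
      paste(sprintf("%.2f", vapply(preps, function(p) p$report$srna_fraction,
                                   numeric(1))), collapse = " "))

  index <- stage("match", {
    build_match_index(refs[c("mirna", "rrna", "trna", "mrna", "retro",
                             "pri_mirna")])
  })
  assignments <- stage("match", {
    out <- lapply(names(preps), function(s) {
      mode <- if (s == "ancient") "ancient" else "modern"
      assign_reads(preps[[s]]$unique, index, mode)
    })
    names(out) <- names(preps)
    out
  })
  say("match: done (%d index windows)", nrow(index$windows))

  total_reads <- vapply(libs, function(l) l$meta$n_reads, numeric(1))
  profiles <- stage("classify", {
    build_profiles(assignments, attr(refs, "family_map"), total_reads)
  })
  control_ids <- setdiff(names(libs), "ancient")
  retro <- stage("classify", {
    comp <- profiles$composition
    per_sample <- lapply(seq_len(nrow(comp)), function(i) retro_proportions(comp[i]))
    names(per_sample) <- comp$sample_id
    ctrl_all <- vapply(per_sample[control_ids], `[[`, numeric(1), "retro_vs_all")
    ctrl_mrna <- vapply(per_sample[control_ids], `[[`, numeric(1), "retro_vs_mrna")
    list(ancient = per_sample$ancient,
         control_mean = c(retro_vs_all = mean(ctrl_all),
                          retro_vs_mrna = mean(ctrl_mrna)),
         control_retro_frequency = mean_frequency(
           profiles$composition[sample_id %in% control_ids]$retroelement))
  })
  targets <- stage("classify", {
    target_fragment_counts(assignments, refs$mrna, ancient_id = "ancient",
                           correction_factor = correction_factor)
  })

  pia_res <- stage("pia", {
    sim <- simulate_pia(refs, n_reads = pia$n_reads, endo_prop = pia$endo_prop,
                        tie_rate = pia$tie_rate,
                        offlineage_rate = pia$offlineage_rate,
                        seed = derive_seed(config$seed, "pia-stage"))
    endogenous_content(sim$queries, sim$hits, sim$taxonomy, refs["genome"],
                       mode = "ancient", subsample = pia$subsample,
                       seed = config$seed)
  })
  say("pia: endogenous %.1f%%, accuracy %.1f%%",
      100 * pia_res$endogenous_proportion, 100 * pia_res$accuracy)

  stats_res <- stage("stats", {
    ctrl_expr <- profiles$expression[, control_ids, drop = FALSE]
    norm <- normalize_controls(ctrl_expr, total_reads)
    adj <- adjust_ancient(profiles$expression[, "ancient"], norm$constants)
    r_hat <- estimate_r(norm$normalized)
    de <- differential_expression(norm$normalized, adj$adjusted, r = r_hat,
                                  level = level)
    reg_all <- profile_regression(rowMeans(norm$normalized), adj$adjusted)
    planted <- intersect(names(config$planted_effects),
                         rownames(norm$normalized))
    keep <- setdiff(rownames(norm$normalized), planted)
    reg_base <- profile_regression(rowMeans(norm$normalized[keep, , drop = FALSE]),
                                   adj$adjusted[keep])
    list(constants = norm$constants, normalized = norm$normalized,
         adjusted = adj$adjusted, adjustment_ratio = adj$adjustment_ratio,
         r = r_hat, differential = de,
         regression_all = reg_all, regression_baseline = reg_base)
  })
  say("stats: adjustment ratio %.3f, r = %.2f; calls: %s",
      stats_res$adjustment_ratio, stats_res$r,
      paste(stats_res$differential$table[call != "indistinguishable",
                                         paste(family, call)], collapse = ", "))

  decay_res <- stage("decay_gc", {
    t12 <- half_life(decay$T_elapsed, decay$v_modern, decay$v_ancient)
    fold <- degradation_fold(decay$dna_half_life, t12)
    # GC of miRNA-matching sequences, weighted by read frequency
    gc_of <- function(s) {
      a <- assignments[[s]]
      mi <- a[class == "miRNA"]
      if (!nrow(mi)) return(NULL)
      gc_binning(mi$sequence, mi$frequency, ids = mi$reference_name)
    }
    gc_anc <- gc_of("ancient")
    gc_ctrl <- {
      mi <- rbindlist(lapply(assignments[control_ids],
                             function(a) a[class == "miRNA"]))
      gc_binning(mi$sequence, mi$frequency, ids = mi$reference_name)
    }
    # GC vs relative expression across families
    fam_gc <- gc_content(refs$mirna$sequences)
    names(fam_gc) <- refs$mirna$names
    fams <- rownames(stats_res$normalized)
    corr_modern <- gc_expression_correlation(fam_gc[fams],
                                             rowMeans(stats_res$normalized))
    corr_ancient <- gc_expression_correlation(fam_gc[fams],
                                              stats_res$adjusted[fams])
    list(half_life = setNames(t12, paste0("T", decay$T_elapsed)),
         degradation_fold = setNames(fold, paste0("T", decay$T_elapsed)),
         gc_location_ancient = if (is.null(gc_anc)) NULL else gc_anc$gc_location,
         gc_location_modern = gc_ctrl$gc_location,
         mean_gc_ancient = weighted_mean_gc(gc_anc),
         mean_gc_modern = weighted_mean_gc(gc_ctrl),
         gc_expression_r2 = c(ancient = corr_ancient$r_squared,
                              modern = corr_modern$r_squared))
  })

  report <- structure(
    list(config = config,
         prep = lapply(preps, `[[`, "report"),
         composition = profiles$composition,
         expression = profiles$expression,
         total_mirna = profiles$total_mirna,
         retro = retro,
         targets = targets,
         pia = list(endogenous_proportion = pia_res$endogenous_proportion,
                    accuracy = pia_res$accuracy,
                    n_reads = pia_res$n_reads),
         stats = stats_res,
         decay = decay_res,
         truth = list(
           planted_effects = config$planted_effects,
           family_weights = attr(refs, "family_weights"),
           fractions = lapply(libs, function(l) l$meta$fractions))),
    class = "paleo_report"
  )
  report
}

# frequency-weighted mean GC from the binned table (bin midpoints)
weighted_mean_gc <- function(g) {
  if (is.null(g) || !length(g$gc)) return(NA_real_)
  sum(g$bins$frequency * (g$bins$bin_lo + 0.05)) / sum(g$bins$frequency)
}

#' @export
print.paleo_report <- function(x, ...) {
  cat("== ancient small-RNA pipeline report ==\n")
  cat(sprintf("seed %d; %d controls; ancient %d reads\n",
              x$config$seed, x$config$n_controls, x$config$reads_ancient))
  anc <- x$prep$ancient
  ctrl_fr <- vapply(x$prep[names(x$prep) != "ancient"],
                    function(p) p$srna_fraction, numeric(1))
  cat(sprintf("sRNA-size fraction: ancient %.1f%%, controls mean %.1f%%\n",
              100 * anc$srna_fraction, 100 * mean(ctrl_fr)))
  comp <- x$composition
  rr <- comp$rRNA / pmax(comp$total_srna, 1)
  cat(sprintf("rRNA share of sRNA reads: ancient %.1f%%, controls mean %.1f%%\n",
              100 * rr[comp$sample_id == "ancient"],
              100 * mean(rr[comp$sample_id != "ancient"])))
  cat(sprintf("retroelements: ancient %.2f%% of sRNA (%.2f%% of mRNA); controls %.2f%% / %.2f%%\n",
              100 * x$retro$ancient[["retro_vs_all"]],
              100 * x$retro$ancient[["retro_vs_mrna"]],
              100 * x$retro$control_mean[["retro_vs_all"]],
              100 * x$retro$control_mean[["retro_vs_mrna"]]))
  cat(sprintf("endogenous content (PIA lower bound): %.1f%% (accuracy %.1f%%)\n",
              100 * x$pia$endogenous_proportion, 100 * x$pia$accuracy))
  cat(sprintf("normalization: mean ratio %.5g, adjustment ratio %.2f, r = %.2f\n",
              x$stats$constants$mean_ratio, x$stats$adjustment_ratio, x$stats$r))
  print(x$stats$differential)
  hl <- x$decay$half_life
  cat(sprintf("RNA half-life: %s years; degradation fold vs DNA: %s\n",
              paste(round(hl), collapse = "-"),
              paste(sprintf("%.1f", sort(x$decay$degradation_fold)),
                    collapse = "-")))
  invisible(x)
}

#' Serialize a pipeline report to JSON
#'
#' Deterministic machine-readable form of the run report: the exact
#' configuration used, per-stage summaries and all headline quantities.
#' Identical config and seed produce byte-identical JSON.
#'
#' @param report a `paleo_report` from [run_pipeline()].
#' @param path optional output file; when `NULL` the JSON string is
#'   returned.
#' @return the JSON string, invisibly when written to `path`.
#' @export
report_json <- function(report, path = NULL) {
  stopifnot(inherits(report, "paleo_report"))
  de <- report$stats$differential
  out <- list(
    config = unclass(report$config),
    prep = report$prep,
    composition = report$composition,
    total_mirna = as.list(report$total_mirna),
    retro = list(ancient = as.list(report$retro$ancient),
                 control_mean = as.list(report$retro$control_mean),
                 control_retro_frequency = as.list(report$retro$control_retro_frequency)),
    target_fragments = list(counts = as.data.frame(report$targets$counts),
                            control_mean = as.list(report$targets$control_mean),
                            ancient_corrected = as.list(report$targets$ancient_corrected)),
    pia = report$pia,
    stats = list(mean_ratio = report$stats$constants$mean_ratio,
                 mean_adjusted_total = report$stats$constants$mean_adjusted_total,
                 adjustment_ratio = report$stats$adjustment_ratio,
                 r = report$stats$r,
                 calls = de$table,
                 regression_all = report$stats$regression_all,
                 regression_baseline = report$stats$regression_baseline),
    decay = report$decay
  )
  js <- jsonlite::toJSON(out, auto_unbox = TRUE, digits = NA, null = "null",
                         dataframe = "rows")
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(as.character(js)))
  }
  as.character(js)
}
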