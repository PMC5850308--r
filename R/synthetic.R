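#' Simulation configuration for synthetic archaeological small-RNA libraries
#'
#' Defines the statistical structure of the synthetic study: one deeply
#' sequenced ancient (singleplex) library and a panel of multiplexed modern
#' control libraries. Class fractions follow the archaeological barley
#' setting: about 59% of ancient reads fall in the 18-25 nt small-RNA window
#' against 17% in the controls; the ancient small-RNA fraction is dominated
#' by ribosomal breakdown products (71% vs 23%); retroelement-derived reads
#' are a fraction of a percent (0.24% ancient, 1.12% modern); ancient reads
#' carry strand-polarised C-to-T deamination; and three miRNA families carry
#' planted fold-changes in the ancient sample (two up, one down) on an
#' otherwise shared baseline.
#'
#' @param seed master seed; every downstream stage derives its own seed from
#'   it, so an identical config yields byte-identical outputs.
#' @param n_mirna_families number of mature miRNA families (>= 4 so that the
#'   three planted-effect families leave at least one baseline family).
#' @param n_controls number of modern control libraries.
#' @param reads_per_control reads per modern library.
#' @param reads_ancient reads in the ancient library.
#' @param srna_fraction_ancient,srna_fraction_modern probability that a read's
#'   insert falls in the 18-25 nt small-RNA window.
#' @param rrna_fraction_ancient,rrna_fraction_modern rRNA share of the
#'   small-RNA-sized reads.
#' @param retro_fraction_ancient,retro_fraction_modern retroelement share of
#'   the small-RNA-sized reads.
#' @param mirna_share miRNA share of the small-RNA-sized reads. Chosen so that
#'   per-sample miRNA totals land at the count scale the statistics operate on
#'   (hundreds to ~2000 reads per library) at desk-scale read budgets.
#' @param deamination_rate per-C probability of a C-to-T substitution on the
#'   sequenced strand of ancient reads.
#' @param overdispersion_r variance-to-mean ratio of family counts (>= 1;
#'   1 recovers the Poisson).
#' @param planted_effects named numeric vector of fold-changes applied to the
#'   ancient sample only; names must be miRNA family names.
#' @param fraction_cv relative standard deviation of class fractions across
#'   control libraries (biological/technical variability between accessions).
#' @param adapter_seq 3' sequencing adapter appended to every insert.
#' @param read_length sequencer read length; inserts plus adapter are
#'   truncated to this many bases.
#' @return a list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_mirna_families = 24L,
                       n_controls = 19L,
                       reads_per_control = 40000L,
                       reads_ancient = 60000L,
                       srna_fraction_ancient = 0.59,
                       srna_fraction_modern = 0.17,
                       rrna_fraction_ancient = 0.71,
                       rrna_fraction_modern = 0.23,
                       retro_fraction_ancient = 0.0024,
                       retro_fraction_modern = 0.0112,
                       mirna_share = 0.05,
                       deamination_rate = 0.05,
                       overdispersion_r = 2,
                       planted_effects = c(miR159 = 4, miR319 = 4, miR396 = 0.1),
                       fraction_cv = 0.10,
                       adapter_seq = "TGGAATTCTCGGGTGCCAAGG",
                       read_length = 50L) {
  cfg <- list(
    seed = as.integer(seed),
    n_mirna_families = as.integer(n_mirna_families),
    n_controls = as.integer(n_controls),
    reads_per_control = as.integer(reads_per_control),
    reads_ancient = as.integer(reads_ancient),
    srna_fraction_ancient = srna_fraction_ancient,
    srna_fraction_modern = srna_fraction_modern,
    rrna_fraction_ancient = rrna_fraction_ancient,
    rrna_fraction_modern = rrna_fraction_modern,
    retro_fraction_ancient = retro_fraction_ancient,
    retro_fraction_modern = retro_fraction_modern,
    mirna_share = mirna_share,
    deamination_rate = deamination_rate,
    overdispersion_r = overdispersion_r,
    planted_effects = planted_effects,
    fraction_cv = fraction_cv,
    adapter_seq = toupper(adapter_seq),
    read_length = as.integer(read_length)
  )
  props <- unlist(cfg[c("srna_fraction_ancient", "srna_fraction_modern",
                        "rrna_fraction_ancient", "rrna_fraction_modern",
                        "retro_fraction_ancient", "retro_fraction_modern",
                        "mirna_share", "deamination_rate")])
  if (any(props < 0 | props > 1)) stop("all proportions must lie in [0, 1]")
  for (kind in c("ancient", "modern")) {
    tot <- cfg[[paste0("rrna_fraction_", kind)]] +
      cfg[[paste0("retro_fraction_", kind)]] + cfg$mirna_share
    if (tot > 1) stop("class fractions for ", kind, " sample sum to > 1")
  }
  if (cfg$overdispersion_r < 1) stop("overdispersion_r must be >= 1")
  if (cfg$n_mirna_families < 4L) {
    stop("n_mirna_families must be >= 4 (three planted-effect families plus baseline)")
  }
  if (cfg$reads_per_control <= 0L || cfg$reads_ancient <= 0L) {
    stop("read budgets must be positive")
  }
  if (is.null(names(cfg$planted_effects)) || any(cfg$planted_effects <= 0)) {
    stop("planted_effects must be a named vector of positive fold-changes")
  }
  if (!grepl("^[ACGT]+$", cfg$adapter_seq)) stop("adapter_seq must be A/C/G/T")
  class(cfg) <- "sim_config"
  cfg
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  cat(sprintf("  seed %d; %d miRNA families; ancient %d reads; %d controls x %d reads\n",
              x$seed, x$n_mirna_families, x$reads_ancient,
              x$n_controls, x$reads_per_control))
  cat(sprintf("  sRNA fraction %.2f/%.2f, rRNA %.2f/%.2f (ancient/modern)\n",
              x$srna_fraction_ancient, x$srna_fraction_modern,
              x$rrna_fraction_ancient, x$rrna_fraction_modern))
  cat(sprintf("  deamination %.3f per C site; overdispersion r = %.2f\n",
              x$deamination_rate, x$overdispersion_r))
  cat("  planted effects:",
      paste(sprintf("%s x%.2g", names(x$planted_effects), x$planted_effects),
            collapse = ", "), "\n")
  invisible(x)
}

# family names: planted families keep their configured names, baseline
# families are fam04, fam05, ...
family_names <- function(config) {
  planted <- names(config$planted_effects)
  n_rest <- config$n_mirna_families - length(planted)
  c(planted, sprintf("fam%02d", length(planted) + seq_len(n_rest)))
}

#' Generate the synthetic reference collection
#'
#' Builds every FASTA-writable reference set the pipeline matches against:
#' mature miRNAs (20-24 nt, one per family), rRNA/tRNA/mRNA transcripts
#' (100-2000 nt; the mRNA set contains the GAMYB, PCF5 and PCF6 target
#' transcripts), retroelement sequences, pri-miRNA contigs embedding each
#' mature miRNA between random flanks, and a toy genome concatenating all of
#' the above with random spacers. Construction guarantees that no mature
#' miRNA occurs inside a different family's pri-miRNA contig (either strand).
#'
#' Baseline family abundances are drawn once, log-normally, so that families
#' span roughly three orders of magnitude; the largest baseline shares are
#' assigned to the planted-effect families (ordered so the down-regulated
#' family is the most abundant), reflecting that the differentially expressed
#' conserved families in grain are among the most highly expressed.
#'
#' @param config a [sim_config()].
#' @return named list of [reference_set()] objects (`mirna`, `rrna`, `trna`,
#'   `mrna`, `retro`, `pri_mirna`, `genome`) with attributes `family_map`
#'   (mature reference name -> family) and `family_weights` (baseline
#'   relative abundances summing to 1).
#' @export
make_references <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(derive_seed(config$seed, "references"))
  fams <- family_names(config)
  n <- config$n_mirna_families

  # mature miRNAs, all distinct and none a substring of another
  repeat {
    mature <- rand_dna(n, sample(20:24, n, replace = TRUE))
    dup <- anyDuplicated(mature) > 0L
    nest <- FALSE
    for (i in seq_len(n)) {
      if (any(vapply(mature[-i], function(m) grepl(m, mature[i], fixed = TRUE),
                     logical(1)))) nest <- TRUE
    }
    if (!dup && !nest) break
  }
  names(mature) <- fams

  # heavy-tailed baseline abundances; planted families take the top shares,
  # the strongest down-regulated family the largest of all
  w <- rlnorm(n, meanlog = 0, sdlog = 1.6)
  w <- sort(w / sum(w), decreasing = TRUE)
  planted <- names(config$planted_effects)
  planted_order <- planted[order(config$planted_effects)]
  weights <- numeric(n)
  names(weights) <- fams
  weights[planted_order] <- w[seq_along(planted_order)]
  weights[setdiff(fams, planted_order)] <- w[-seq_along(planted_order)]

  long_set <- function(prefix, n_seq, len_range) {
    seqs <- rand_dna(n_seq, sample(len_range[1]:len_range[2], n_seq, replace = TRUE))
    names(seqs) <- sprintf("%s%02d", prefix, seq_len(n_seq))
    seqs
  }
  rrna <- long_set("rRNA", 4L, c(1400L, 2000L))
  trna <- long_set("tRNA", 8L, c(100L, 180L))
  mrna <- long_set("mRNA", 15L, c(500L, 2000L))
  names(mrna)[1:3] <- c("GAMYB", "PCF5", "PCF6")
  retro <- long_set("retro", 5L, c(1000L, 2000L))

  # pri-miRNA contigs: mature embedded between random flanks; reject any
  # contig containing another family's mature sequence on either strand
  pri <- character(n)
  pri_mature_at <- integer(n)
  for (i in seq_len(n)) {
    repeat {
      f5 <- rand_dna(1L, sample(60:120, 1L))
      f3 <- rand_dna(1L, sample(60:120, 1L))
      contig <- paste0(f5, mature[i], f3)
      others <- c(mature[-i], revcomp(mature[-i]))
      if (!any(vapply(others, grepl, logical(1), x = contig, fixed = TRUE))) {
        pri[i] <- contig
        pri_mature_at[i] <- nchar(f5) + 1L
        break
      }
    }
  }
  names(pri) <- paste0("pri-", fams)

  all_seqs <- c(mature, rrna, trna, mrna, retro, pri)
  spacers <- rand_dna(length(all_seqs) + 1L, sample(50:200, length(all_seqs) + 1L,
                                                    replace = TRUE))
  genome <- paste0(paste0(spacers[seq_along(all_seqs)], all_seqs, collapse = ""),
                   spacers[length(spacers)])

  refs <- list(
    mirna = reference_set(mature, "miRNA"),
    rrna = reference_set(rrna, "rRNA"),
    trna = reference_set(trna, "tRNA"),
    mrna = reference_set(mrna, "mRNA"),
    retro = reference_set(retro, "retroelement"),
    pri_mirna = reference_set(pri, "pri-miRNA"),
    genome = reference_set(c(genome = genome), "genome")
  )
  attr(refs, "family_map") <- setNames(fams, fams)
  attr(refs, "family_weights") <- weights
  attr(refs, "pri_mature_at") <- setNames(pri_mature_at, names(pri))
  refs
}

# negative-binomial draw parameterised by mean and variance r * mean;
# r = 1 degenerates to Poisson
rnbinom_mv <- function(n, mean, r) {
  mean <- rep_len(mean, n)
  out <- integer(n)
  pos <- mean > 0
  if (!any(pos)) return(out)
  if (r <= 1 + 1e-12) {
    out[pos] <- rpois(sum(pos), mean[pos])
  } else {
    out[pos] <- rnbinom(sum(pos), size = mean[pos] / (r - 1), mu = mean[pos])
  }
  out
}

# draw fragment windows from a set of long references (length-weighted),
# returning insert sequences plus provenance
draw_fragments <- function(n_frag, seqs, lens) {
  if (n_frag == 0L) {
    return(data.table(source_ref = character(0), strand = character(0),
                      start = integer(0), insert = character(0)))
  }
  reflen <- nchar(seqs)
  idx <- sample.int(length(seqs), n_frag, replace = TRUE, prob = reflen)
  flen <- lens
  start <- floor(runif(n_frag) * (reflen[idx] - flen + 1)) + 1L
  ins <- substring(seqs[idx], start, start + flen - 1L)
  strand <- ifelse(runif(n_frag) < 0.5, "+", "-")
  neg <- strand == "-"
  if (any(neg)) ins[neg] <- revcomp(ins[neg])
  data.table(source_ref = names(seqs)[idx], strand = strand,
             start = as.integer(start), insert = ins)
}

#' Simulate one sequencing library
#'
#' Draws reads class-by-class under the configured composition, plants the
#' configured fold-changes in the ancient sample, applies strand-polarised
#' C-to-T deamination to ancient reads, appends the 3' adapter and truncates
#' to the read length. Control-library class fractions are jittered sample by
#' sample (relative sd `fraction_cv`); the single ancient library uses the
#' configured fractions exactly.
#'
#' miRNA reads are the mature sequences, drawn family-wise with mean
#' `mirna_share * n_sRNA * weight_f` (times the planted fold-change in the
#' ancient sample) and variance `r` times the mean. Long-RNA classes (rRNA,
#' tRNA, mRNA, retroelement, pri-miRNA) emit random 18-25 nt breakdown
#' fragments from either strand; pri-miRNA fragments falling entirely inside
#' the mature region are resampled, since such reads are the mature miRNA
#' itself. Out-of-window reads (inserts of 15-17 or 26-45 nt) fill the
#' remainder of the budget.
#'
#' @param config a [sim_config()].
#' @param refs references from [make_references()].
#' @param sample_kind `"ancient"` or `"modern"`.
#' @param sample_index control index in `1:n_controls` (must be 1 for the
#'   ancient library).
#' @return list of class `sim_library` with elements `reads` (data.table:
#'   `read_id`, `read`, `quality`), `truth` (per-read class, family, source
#'   reference, strand, start, insert length, damage positions) and `meta`
#'   (sample id, realised class fractions, true family means).
#' @export
simulate_library <- function(config, refs, sample_kind = c("ancient", "modern"),
                             sample_index = 1L) {
  stopifnot(inherits(config, "sim_config"))
  sample_kind <- match.arg(sample_kind)
  sample_index <- as.integer(sample_index)
  n_lib <- if (sample_kind == "ancient") 1L else config$n_controls
  if (sample_index < 1L || sample_index > n_lib) {
    stop("sample_index out of range for ", sample_kind, " (1..", n_lib, ")")
  }
  sample_id <- if (sample_kind == "ancient") "ancient" else
    sprintf("control%02d", sample_index)
  set.seed(derive_seed(config$seed, paste0("library-", sample_id)))

  n_reads <- if (sample_kind == "ancient") config$reads_ancient else
    config$reads_per_control
  srna_f <- config[[paste0("srna_fraction_", sample_kind)]]
  rrna_f <- config[[paste0("rrna_fraction_", sample_kind)]]
  retro_f <- config[[paste0("retro_fraction_", sample_kind)]]
  if (sample_kind == "modern" && config$fraction_cv > 0) {
    jit <- pmin(pmax(rnorm(3, 1, config$fraction_cv), 0.5), 1.5)
    srna_f <- min(srna_f * jit[1], 0.95)
    rrna_f <- min(rrna_f * jit[2], 1 - config$mirna_share - retro_f - 0.05)
    retro_f <- min(retro_f * jit[3], 0.2)
  }

  n_in <- rbinom(1L, n_reads, srna_f)
  n_out <- n_reads - n_in

  # family-wise miRNA counts
  fams <- family_names(config)
  weights <- attr(refs, "family_weights")[fams]
  fold <- setNames(rep(1, length(fams)), fams)
  if (sample_kind == "ancient") {
    fold[names(config$planted_effects)] <- config$planted_effects
  }
  mu <- config$mirna_share * n_in * weights * fold
  n_fam <- rnbinom_mv(length(fams), mu, config$overdispersion_r)
  names(n_fam) <- fams
  if (sum(n_fam) > n_in) { # degenerate budget; thin proportionally
    n_fam <- floor(n_fam * n_in / sum(n_fam))
  }
  n_mir <- sum(n_fam)

  # remaining small-RNA-sized reads: rRNA / retro / (mRNA, tRNA, pri-miRNA)
  rest <- n_in - n_mir
  remainder <- max(0, 1 - rrna_f - retro_f - config$mirna_share)
  p_rest <- c(rRNA = rrna_f, retroelement = retro_f,
              mRNA = remainder * 0.60, tRNA = remainder * 0.25,
              `pri-miRNA` = remainder * 0.15)
  n_rest <- drop(rmultinom(1L, rest, p_rest))
  names(n_rest) <- names(p_rest)

  mirna_seqs <- refs$mirna$sequences
  long_pool <- list(
    rRNA = refs$rrna$sequences,
    tRNA = refs$trna$sequences,
    mRNA = refs$mrna$sequences,
    retroelement = refs$retro$sequences,
    `pri-miRNA` = refs$pri_mirna$sequences
  )

  parts <- list()
  if (n_mir > 0L) {
    fam_rep <- rep(fams, n_fam)
    parts$mirna <- data.table(
      class = "miRNA", family = fam_rep, source_ref = fam_rep,
      strand = "+", start = 1L, insert = unname(mirna_seqs[fam_rep])
    )
  }
  pri_at <- attr(refs, "pri_mature_at")
  mature_len <- nchar(mirna_seqs)
  for (cl in names(n_rest)) {
    k <- n_rest[[cl]]
    if (k == 0L) next
    fr <- draw_fragments(k, long_pool[[cl]], sample(18:25, k, replace = TRUE))
    if (cl == "pri-miRNA") {
      # resample fragments wholly inside the mature region
      repeat {
        fam_of <- sub("^pri-", "", fr$source_ref)
        m_start <- pri_at[fr$source_ref]
        m_end <- m_start + mature_len[fam_of] - 1L
        flen <- nchar(fr$insert)
        inside <- fr$start >= m_start & (fr$start + flen - 1L) <= m_end
        if (!any(inside)) break
        fr[which(inside), c("source_ref", "strand", "start", "insert") :=
             draw_fragments(sum(inside), long_pool[[cl]],
                            sample(18:25, sum(inside), replace = TRUE))]
      }
    }
    parts[[cl]] <- data.table(class = cl, family = NA_character_,
                              source_ref = fr$source_ref, strand = fr$strand,
                              start = fr$start, insert = fr$insert)
  }
  if (n_out > 0L) {
    out_lens <- sample(c(15:17, 26:45), n_out, replace = TRUE,
                       prob = c(rep(0.1 / 3, 3), rep(0.9 / 20, 20)))
    out_cls <- sample(names(p_rest), n_out, replace = TRUE,
                      prob = p_rest / sum(p_rest))
    for (cl in unique(out_cls)) {
      sel <- out_cls == cl
      fr <- draw_fragments(sum(sel), long_pool[[cl]], out_lens[sel])
      parts[[paste0("out_", cl)]] <- data.table(
        class = paste0("oversize_", cl), family = NA_character_,
        source_ref = fr$source_ref, strand = fr$strand, start = fr$start,
        insert = fr$insert
      )
    }
  }
  truth <- rbindlist(parts)
  truth <- truth[sample.int(nrow(truth)), ]
  truth[, read_id := sprintf("%s_r%07d", sample_id, seq_len(.N))]

  # strand-polarised deamination: C -> T in the frame of the sequenced strand
  truth[, n_damage := 0L]
  truth[, damage_pos := ""]
  if (sample_kind == "ancient" && config$deamination_rate > 0) {
    chars <- strsplit(truth$insert, "", fixed = TRUE)
    lens <- lengths(chars)
    flat <- unlist(chars, use.names = FALSE)
    c_sites <- which(flat == "C")
    hit <- c_sites[runif(length(c_sites)) < config$deamination_rate]
    if (length(hit)) {
      flat[hit] <- "T"
      read_of <- findInterval(hit - 1L, cumsum(lens)) + 1L
      offset <- hit - c(0L, cumsum(lens))[read_of]
      dmg <- split(offset, read_of)
      ids <- as.integer(names(dmg))
      truth$n_damage[ids] <- lengths(dmg)
      truth$damage_pos[ids] <- vapply(dmg, paste, character(1), collapse = ",")
      ends <- cumsum(lens)
      truth[, insert := substring(paste(flat, collapse = ""),
                                  ends - lens + 1L, ends)]
    }
  }

  truth[, insert_len := nchar(insert)]
  read <- substr(paste0(truth$insert, config$adapter_seq), 1L, config$read_length)
  reads <- data.table(read_id = truth$read_id, read = read,
                      quality = strrep("I", nchar(read)))
  structure(
    list(reads = reads,
         truth = truth[, .(read_id, class, family, source_ref, strand, start,
                           insert_len, n_damage, damage_pos, insert)],
         meta = list(sample_id = sample_id, sample_kind = sample_kind,
                     n_reads = n_reads,
                     fractions = c(srna = srna_f, rrna = rrna_f, retro = retro_f,
                                   mirna_share = config$mirna_share),
                     family_mean = mu)),
    class = "sim_library"
  )
}

#' @export
print.sim_library <- function(x, ...) {
  cat(sprintf("<sim_library> %s: %d reads (%d small-RNA-sized inserts)\n",
              x$meta$sample_id, nrow(x$reads),
              sum(x$truth$insert_len >= 18 & x$truth$insert_len <= 25)))
  invisible(x)
}

#' Write a simulated library to FASTQ and its truth table to TSV
#'
#' @param lib a `sim_library` from [simulate_library()].
#' @param fastq_path output FASTQ path (4-line records, Phred+33).
#' @param truth_path optional output TSV path for the truth table.
#' @return `fastq_path`, invisibly.
#' @export
write_library <- function(lib, fastq_path, truth_path = NULL) {
  stopifnot(inherits(lib, "sim_library"))
  rec <- rbind(paste0("@", lib$reads$read_id), lib$reads$read, "+",
               lib$reads$quality)
  writeLines(as.vector(rec), fastq_path)
  if (!is.null(truth_path)) fwrite(lib$truth, truth_path, sep = "\t")
  invisible(fastq_path)
}

#' Read a FASTQ file into a named character vector
#'
#' @param path FASTQ file (4-line records).
#' @return named character vector of read sequences.
#' @export
read_fastq <- function(path) {
  ss <- Biostrings::readDNAStringSet(path, format = "fastq")
  seqs <- as.character(ss)
  names(seqs) <- sub("\\s.*$", "", names(ss))
  seqs
}

#' Toy taxonomy for the phylogenetic intersect stage
#'
#' A small rooted taxonomy with a grass clade (barley, wheat), a fungal
#' clade and a metazoan outgroup, targeted at barley.
#'
#' @return a [taxonomy()] object with target `Hordeum_vulgare`.
#' @export
toy_taxonomy <- function() {
  parents <- c(
    Eukaryota = "root",
    Viridiplantae = "Eukaryota",
    Poaceae = "Viridiplantae",
    Hordeum_vulgare = "Poaceae",
    Triticum_aestivum = "Poaceae",
    Fungi = "Eukaryota",
    Aspergillus = "Fungi",
    Penicillium = "Fungi",
    Metazoa = "Eukaryota",
    Homo_sapiens = "Metazoa"
  )
  taxonomy(parents, target = "Hordeum_vulgare")
}

#' Simulate PIA input: queries, redundancy frequencies and BLAST-like hit lists
#'
#' Emulates the metagenomic screening stage on a mixture of endogenous reads
#' (true genome fragments) and exogenous contamination (random sequences).
#' Endogenous reads usually receive a (barley, wheat) hit pair whose intersect
#' is the grass clade on the target lineage; a configurable fraction instead
#' receives tied top scores (discarded downstream) or an off-lineage hit pair,
#' emulating ultrashort conserved sequences that resolve poorly.
#'
#' @param refs references from [make_references()] (provides the genome).
#' @param n_reads number of unique query sequences.
#' @param endo_prop true endogenous proportion of the mixture.
#' @param tie_rate probability that a query's top two hits share a score.
#' @param offlineage_rate probability that an endogenous query nevertheless
#'   hits an off-lineage clade.
#' @param seed integer seed.
#' @return list with `queries` (sequence, frequency), `hits` (query_id, taxon,
#'   score), `taxonomy`, and `truth` (per-query endogenous flag).
#' @export
simulate_pia <- function(refs, n_reads = 2000L, endo_prop = 0.9,
                         tie_rate = 0.05, offlineage_rate = 0.15, seed = 1L) {
  set.seed(derive_seed(seed, "pia"))
  n_endo <- rbinom(1L, n_reads, endo_prop)
  n_exo <- n_reads - n_endo
  genome <- refs$genome$sequences
  endo <- draw_fragments(n_endo, genome, sample(18:25, n_endo, replace = TRUE))
  exo_seq <- rand_dna(n_exo, sample(18:25, n_exo, replace = TRUE))
  queries <- data.table(
    query_id = sprintf("q%05d", seq_len(n_reads)),
    sequence = c(endo$insert, exo_seq),
    frequency = 1L + rpois(n_reads, 2),
    endogenous = rep(c(TRUE, FALSE), c(n_endo, n_exo))
  )
  queries <- queries[sample.int(.N)]

  on_pair <- c("Hordeum_vulgare", "Triticum_aestivum")
  off_pair <- c("Aspergillus", "Penicillium")
  hit_rows <- lapply(seq_len(nrow(queries)), function(i) {
    endo_i <- queries$endogenous[i]
    pair <- if (endo_i && runif(1) >= offlineage_rate) on_pair else off_pair
    s1 <- 90 + sample(0:20, 1L)
    s2 <- if (runif(1) < tie_rate) s1 else s1 - sample(2:10, 1L)
    data.table(query_id = queries$query_id[i], taxon = pair, score = c(s1, s2))
  })
  list(queries = queries[, .(query_id, sequence, frequency)],
       hits = rbindlist(hit_rows),
       taxonomy = toy_taxonomy(),
       truth = queries[, .(query_id, endogenous)])
}
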