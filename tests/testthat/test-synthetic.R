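test_that("sim_config validates its preconditions", {
  expect_s3_class(sim_config(), "sim_config")
  expect_error(sim_config(n_mirna_families = 3), "n_mirna_families")
  expect_error(sim_config(reads_per_control = 0), "read budgets")
  expect_error(sim_config(reads_ancient = 0), "read budgets")
  expect_error(sim_config(overdispersion_r = 0.5), "overdispersion_r")
  expect_error(sim_config(srna_fraction_ancient = 1.2), "proportions")
  expect_error(sim_config(deamination_rate = -0.1), "proportions")
  expect_error(sim_config(rrna_fraction_ancient = 0.97), "sum to > 1")
  expect_error(sim_config(planted_effects = c(4, 4, 0.1)), "named")
  expect_error(sim_config(adapter_seq = "ACGU"), "adapter_seq")
})

test_that("make_references embeds each mature in exactly one pri-miRNA", {
  cfg <- sim_config(seed = 1, n_mirna_families = 10)
  refs <- make_references(cfg)
  mature <- refs$mirna$sequences
  pri <- refs$pri_mirna$sequences
  expect_length(mature, 10L)
  expect_true(all(nchar(mature) >= 20 & nchar(mature) <= 24))
  for (f in names(mature)) {
    n_hits <- sum(vapply(pri, grepl, logical(1), pattern = mature[[f]],
                         fixed = TRUE))
    expect_equal(n_hits, 1L)
    expect_true(grepl(mature[[f]], pri[[paste0("pri-", f)]], fixed = TRUE))
    # not present in any other family's contig on either strand
    others <- pri[names(pri) != paste0("pri-", f)]
    expect_false(any(vapply(others, grepl, logical(1),
                            pattern = revcomp(mature[[f]]), fixed = TRUE)))
  }
  # transcript length ranges
  for (set_name in c("rrna", "trna", "mrna")) {
    L <- nchar(refs[[set_name]]$sequences)
    expect_true(all(L >= 100 & L <= 2000))
  }
  # baseline weights are a distribution over the families
  w <- attr(refs, "family_weights")
  expect_equal(sum(w), 1)
  expect_true(all(w > 0))
})

test_that("identical seed gives byte-identical FASTA and FASTQ output", {
  cfg <- sim_config(seed = 42, n_mirna_families = 10)
  r1 <- make_references(cfg)
  r2 <- make_references(cfg)
  f1 <- tempfile(fileext = ".fa"); f2 <- tempfile(fileext = ".fa")
  write_reference_fasta(r1$pri_mirna, f1)
  write_reference_fasta(r2$pri_mirna, f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))

  cfg2 <- tiny_config(seed = 5)
  refs <- make_references(cfg2)
  l1 <- simulate_library(cfg2, refs, "modern", 1L)
  l2 <- simulate_library(cfg2, refs, "modern", 1L)
  expect_identical(l1$reads, l2$reads)
  expect_identical(l1$truth, l2$truth)
  q1 <- tempfile(fileext = ".fastq"); q2 <- tempfile(fileext = ".fastq")
  write_library(l1, q1); write_library(l2, q2)
  expect_identical(readBin(q1, "raw", file.size(q1)),
                   readBin(q2, "raw", file.size(q2)))
  # round trip preserves the reads
  back <- read_fastq(q1)
  expect_identical(unname(back), l1$reads$read)
  # different sample index gives a different library
  expect_false(identical(simulate_library(cfg2, refs, "modern", 2L)$reads,
                         l1$reads))
  unlink(c(f1, f2, q1, q2))
})

test_that("simulate_library validates sample kind and index", {
  cfg <- tiny_config()
  refs <- tiny_refs(cfg)
  expect_error(simulate_library(cfg, refs, "medieval"), "arg")
  expect_error(simulate_library(cfg, refs, "ancient", 2L), "out of range")
  expect_error(simulate_library(cfg, refs, "modern", 99L), "out of range")
})

test_that("with deamination_rate=0 every read is an exact source substring", {
  cfg <- tiny_config(seed = 21, deamination_rate = 0)
  refs <- tiny_refs(cfg)
  lib <- simulate_library(cfg, refs, "ancient", 1L)
  all_refs <- c(refs$mirna$sequences, refs$rrna$sequences, refs$trna$sequences,
                refs$mrna$sequences, refs$retro$sequences,
                refs$pri_mirna$sequences)
  tr <- lib$truth
  src <- all_refs[tr$source_ref]
  probe <- ifelse(tr$strand == "+", tr$insert, revcomp(tr$insert))
  ok <- mapply(grepl, pattern = probe, x = src, MoreArgs = list(fixed = TRUE))
  expect_true(all(ok))
  expect_true(all(tr$n_damage == 0L))
  # every emitted read appears exactly once in the truth table
  expect_identical(sort(tr$read_id), sort(lib$reads$read_id))
  expect_equal(anyDuplicated(tr$read_id), 0L)
})

test_that("ancient C-to-T rate matches deamination_rate", {
  cfg <- tiny_config(seed = 33, reads_ancient = 8000L, deamination_rate = 0.05)
  refs <- tiny_refs(cfg)
  lib <- simulate_library(cfg, refs, "ancient", 1L)
  tr <- lib$truth
  n_c_after <- nchar(gsub("[^C]", "", tr$insert))
  n_sites <- sum(n_c_after) + sum(tr$n_damage) # C sites before damage
  rate <- sum(tr$n_damage) / n_sites
  se <- sqrt(0.05 * 0.95 / n_sites)
  expect_lt(abs(rate - 0.05), 4 * se)
  # recorded damage positions carry T where the source had C
  dmg <- tr[n_damage > 0L][1:50]
  pos1 <- as.integer(sub(",.*$", "", dmg$damage_pos))
  expect_true(all(substr(dmg$insert, pos1, pos1) == "T"))
})

test_that("modern small-RNA-sized fraction follows the configured binomial", {
  cfg <- tiny_config(seed = 8, reads_per_control = 6000L, fraction_cv = 0)
  refs <- tiny_refs(cfg)
  lib <- simulate_library(cfg, refs, "modern", 3L)
  p <- cfg$srna_fraction_modern
  obs <- mean(lib$truth$insert_len >= 18 & lib$truth$insert_len <= 25)
  expect_lt(abs(obs - p), 3 * sqrt(p * (1 - p) / nrow(lib$truth)))
})

test_that("planted fold-changes are recovered from generated counts", {
  # symmetric design: same read budget and sRNA fraction in both arms, so
  # the ancient/control count ratio estimates the planted fold directly
  base <- tiny_config(seed = 101, reads_ancient = 3000L,
                      reads_per_control = 3000L,
                      srna_fraction_modern = 0.59, fraction_cv = 0,
                      deamination_rate = 0)
  refs <- tiny_refs(base)
  count_fam <- function(lib, fam) sum(lib$truth$family %in% fam)
  anc <- ctrl <- matrix(0, nrow = 50, ncol = 2,
                        dimnames = list(NULL, c("miR159", "miR396")))
  for (s in seq_len(50)) {
    cfg <- tiny_config(seed = 1000L + s, reads_ancient = 3000L,
                       reads_per_control = 3000L,
                       srna_fraction_modern = 0.59, fraction_cv = 0,
                       deamination_rate = 0)
    la <- simulate_library(cfg, refs, "ancient", 1L)
    lm <- simulate_library(cfg, refs, "modern", 1L)
    for (f in colnames(anc)) {
      anc[s, f] <- count_fam(la, f)
      ctrl[s, f] <- count_fam(lm, f)
    }
  }
  up_ratio <- mean(anc[, "miR159"]) / mean(ctrl[, "miR159"])
  down_ratio <- mean(anc[, "miR396"]) / mean(ctrl[, "miR396"])
  expect_lt(abs(up_ratio - 4) / 4, 0.2)
  expect_lt(abs(down_ratio - 0.1) / 0.1, 0.25)
})

test_that("count variance/mean across replicate controls matches r", {
  r_true <- 2
  cfg <- sim_config(seed = 61, n_mirna_families = 8L, n_controls = 32L,
                    reads_per_control = 4000L, fraction_cv = 0,
                    overdispersion_r = r_true)
  refs <- make_references(cfg)
  fams <- names(refs$mirna$sequences)
  counts <- sapply(seq_len(32L), function(i) {
    tr <- simulate_library(cfg, refs, "modern", i)$truth
    vapply(fams, function(f) sum(tr$family %in% f), numeric(1))
  })
  m <- rowMeans(counts)
  v <- apply(counts, 1, var)
  keep <- m >= 5 # variance/mean is too noisy for near-empty families
  r_hat <- mean(v[keep] / m[keep])
  expect_lt(abs(r_hat - r_true), 0.6)
})

test_that("simulate_pia produces a consistent mixture with hit lists", {
  cfg <- tiny_config()
  refs <- tiny_refs(cfg)
  p <- simulate_pia(refs, n_reads = 400L, endo_prop = 0.9, tie_rate = 0.05,
                    offlineage_rate = 0.1, seed = 3L)
  expect_equal(nrow(p$queries), 400L)
  expect_equal(sort(unique(p$hits$query_id)), sort(p$queries$query_id))
  expect_equal(nrow(p$hits), 800L) # two hits per query
  obs <- mean(p$truth$endogenous)
  expect_lt(abs(obs - 0.9), 3 * sqrt(0.9 * 0.1 / 400))
  # endogenous queries are genome substrings on one strand or the other
  g <- refs$genome$sequences[[1]]
  endo_seq <- p$queries[p$truth[endogenous == TRUE], on = "query_id"]$sequence
  ok <- vapply(endo_seq, function(s) {
    grepl(s, g, fixed = TRUE) || grepl(revcomp(s), g, fixed = TRUE)
  }, logical(1))
  expect_true(all(ok))
})
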