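# Independent oracles used across the suite. These deliberately share no
# code with the package internals: the matcher oracle is a per-character
# scan over every offset and strand, and the LCA oracle intersects explicit
# ancestor sets.

comp_char <- function(ch) chartr("ACGT", "TGCA", ch)

# Exhaustive scan over every reference window and strand, applying the
# deamination rule per character. refs: data.frame(name, seq, class).
brute_force_match <- function(query, refs, mode = c("ancient", "modern")) {
  mode <- match.arg(mode)
  qc <- strsplit(query, "")[[1]]
  n <- length(qc)
  rows <- list()
  k <- 0L
  if (all(qc %in% c("A", "C", "G", "T"))) {
    for (i in seq_len(nrow(refs))) {
      rseq <- strsplit(refs$seq[i], "")[[1]]
      L <- length(rseq)
      if (L < n) next
      for (off in 0:(L - n)) {
        w <- rseq[(off + 1):(off + n)]
        # + strand: read frame equals the forward window
        mm <- which(w != qc)
        if (length(mm) == 0L ||
            (mode == "ancient" && length(mm) == 1L &&
             w[mm] == "C" && qc[mm] == "T")) {
          k <- k + 1L
          rows[[k]] <- data.frame(reference_name = refs$name[i],
                                  strand = "+", position = off,
                                  n_mismatches = length(mm))
        }
        # - strand: read frame is the reverse complement of the window
        rw <- rev(comp_char(w))
        mm <- which(rw != qc)
        if (length(mm) == 0L ||
            (mode == "ancient" && length(mm) == 1L &&
             rw[mm] == "C" && qc[mm] == "T")) {
          k <- k + 1L
          rows[[k]] <- data.frame(reference_name = refs$name[i],
                                  strand = "-", position = off,
                                  n_mismatches = length(mm))
        }
      }
    }
  }
  if (k == 0L) {
    return(data.frame(reference_name = character(0), strand = character(0),
                      position = integer(0), n_mismatches = integer(0)))
  }
  out <- do.call(rbind, rows)
  out[order(out$reference_name, out$position, out$strand), , drop = FALSE]
}

# canonical comparable form of a match table
match_key <- function(df) {
  if (!nrow(df)) return(character(0))
  sort(paste(df$reference_name, df$strand, df$position, df$n_mismatches))
}

# LCA by explicit ancestor-set intersection (deepest shared ancestor)
oracle_lca <- function(parents, root, a, b) {
  chain <- function(x) {
    p <- x
    while (x != root) {
      x <- parents[[x]]
      p <- c(p, x)
    }
    p
  }
  ca <- chain(a)
  cb <- chain(b)
  common <- intersect(ca, cb)
  # chains are ordered node -> root, so the first common entry is deepest
  ca[ca %in% common][1]
}

# small, fast simulation config for unit tests
tiny_config <- function(seed = 11L, ...) {
  args <- list(seed = seed, n_mirna_families = 8L, n_controls = 4L,
               reads_per_control = 3000L, reads_ancient = 5000L)
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(sim_config, args)
}

# memoised tiny reference collection shared across tests
tiny_refs_cache <- new.env(parent = emptyenv())
tiny_refs <- function(cfg = tiny_config()) {
  key <- paste0("s", cfg$seed, "f", cfg$n_mirna_families)
  if (is.null(tiny_refs_cache[[key]])) {
    tiny_refs_cache[[key]] <- make_references(cfg)
  }
  tiny_refs_cache[[key]]
}

random_dna <- function(n, len) {
  len <- rep_len(len, n)
  vapply(seq_len(n), function(i) {
    paste(sample(c("A", "C", "G", "T"), len[i], replace = TRUE), collapse = "")
  }, character(1))
}
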