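#' Construct a taxonomy from a parent map
#'
#' @param parents named character vector mapping each non-root node to its
#'   parent; the root is the unique node appearing as a parent but never as
#'   a child (or mapped to `NA`).
#' @param target name of the focal taxon (e.g. the species the sample is
#'   assumed to derive from); must be present in the taxonomy.
#' @return object of class `taxonomy` with the parent map, root, target,
#'   and the target lineage (path from root to target).
#' @export
taxonomy <- function(parents, target) {
  parents <- parents[!is.na(parents)]
  children <- names(parents)
  if (is.null(children) || any(children == "")) {
    stop("parents must be a named vector (child -> parent)")
  }
  roots <- setdiff(unique(parents), children)
  if (length(roots) != 1L) {
    stop("taxonomy must have a single root; found: ",
         paste(roots, collapse = ", "))
  }
  nodes <- union(children, parents)
  # reachability: walking up from every node must terminate at the root
  for (nd in children) {
    seen <- character(0)
    cur <- nd
    while (cur != roots) {
      if (cur %in% seen) stop("cycle in taxonomy at node ", cur)
      seen <- c(seen, cur)
      if (!cur %in% children) stop("node ", cur, " not reachable from root")
      cur <- parents[[cur]]
    }
  }
  if (!target %in% nodes) stop("target taxon '", target, "' not in taxonomy")
  obj <- structure(list(parents = parents, root = roots, target = target,
                        nodes = nodes),
                   class = "taxonomy")
  obj$target_lineage <- ancestors_of(obj, target) # root ... target, inclusive
  obj
}

# path from root down to (and including) node
ancestors_of <- function(tax, node) {
  path <- node
  cur <- node
  while (cur != tax$root) {
    cur <- tax$parents[[cur]]
    path <- c(cur, path)
  }
  path
}

#' @export
print.taxonomy <- function(x, ...) {
  cat(sprintf("<taxonomy> %d nodes, root '%s', target '%s' (depth %d)\n",
              length(x$nodes), x$root, x$target,
              length(x$target_lineage) - 1L))
  invisible(x)
}

#' Read a taxonomy from a two-column parent-map TSV
#'
#' @param path TSV with columns `child`, `parent` (header optional with
#'   those names).
#' @param target focal taxon, see [taxonomy()].
#' @return a [taxonomy()].
#' @export
taxonomy_from_tsv <- function(path, target) {
  dt <- fread(path, header = "auto")
  if (!all(c("child", "parent") %in% names(dt))) {
    data.table::setnames(dt, seq_len(2L), c("child", "parent"))
  }
  taxonomy(setNames(as.character(dt$parent), as.character(dt$child)), target)
}

#' Read a taxonomy from a newick tree
#'
#' Internal node labels become taxonomy nodes; unlabelled internal nodes
#' receive synthetic `node<k>` labels.
#'
#' @param path newick file readable by [ape::read.tree()].
#' @param target focal taxon, see [taxonomy()].
#' @return a [taxonomy()].
#' @export
taxonomy_from_newick <- function(path, target) {
  tr <- ape::read.tree(path)
  nlab <- tr$node.label
  if (is.null(nlab)) nlab <- rep("", tr$Nnode)
  nlab[nlab == ""] <- sprintf("node%d", which(nlab == ""))
  labels <- c(tr$tip.label, nlab)
  parents <- setNames(labels[tr$edge[, 1L]], labels[tr$edge[, 2L]])
  taxonomy(parents, target)
}

#' Tie filter on a BLAST-like hit list
#'
#' A read whose second-best hit scores identically to its best hit carries
#' no discriminating signal and is discarded. Single-hit lists are kept;
#' empty lists are discarded (no evidence).
#'
#' @param scores numeric vector of hit scores, or a data.frame with a
#'   `score` column. Sorted to non-increasing order internally.
#' @return `TRUE` (keep) or `FALSE` (discard).
#' @export
filter_ties <- function(scores) {
  if (is.data.frame(scores)) scores <- scores[["score"]]
  if (!length(scores)) return(FALSE)
  if (length(scores) == 1L) return(TRUE)
  s <- sort(scores, decreasing = TRUE)
  s[2L] < s[1L]
}

#' Classification intersect of a hit list
#'
#' The lowest common ancestor (LCA) of the taxa of the top two hits; a
#' single-hit list intersects at that hit's taxon. The intersect is
#' "unknowable" (returned as `NA`) when a hit taxon is absent from the
#' taxonomy or when the LCA is the root: reads unresolvable from a basal
#' level carry no assignable signal.
#'
#' @param hits data.frame with columns `taxon`, `score` (sorted internally),
#'   or a character vector of taxa already in score order.
#' @param tax a [taxonomy()].
#' @return the intersect node name, or `NA_character_` if unknowable.
#' @export
intersect_node <- function(hits, tax) {
  if (is.data.frame(hits)) {
    hits <- hits[order(-hits[["score"]]), ]
    taxa <- as.character(hits[["taxon"]])
  } else {
    taxa <- as.character(hits)
  }
  if (!length(taxa)) return(NA_character_)
  top <- utils::head(taxa, 2L)
  if (!all(top %in% tax$nodes)) return(NA_character_)
  if (length(top) == 1L) {
    node <- top
  } else {
    a1 <- ancestors_of(tax, top[1L])
    a2 <- ancestors_of(tax, top[2L])
    k <- max(which(a1[seq_len(min(length(a1), length(a2)))] ==
                     a2[seq_len(min(length(a1), length(a2)))]))
    node <- a1[k]
  }
  if (node == tax$root) return(NA_character_)
  node
}

#' Estimate endogenous read content (simplified Phylogenetic Intersect Analysis)
#'
#' For each unique read: (i) the tie filter and classification intersect are
#' applied to its hit list; the read is "target-consistent" when the
#' intersect is a node on the lineage leading to the target taxon; (ii) the
#' read is remapped to the genome with the damage-aware matcher. A read is
#' called exogenous when it neither maps to the genome nor is
#' target-consistent. Redundancy frequencies weight every read, and the
#' endogenous proportion is reported as the lower bound
#' `1 - exogenous / total`. PIA accuracy is the frequency-weighted fraction
#' of genome-mapping reads whose intersect lies on the target lineage.
#'
#' @param queries data.table with `query_id`, `sequence`, `frequency`.
#' @param hits data.table with `query_id`, `taxon`, `score`.
#' @param tax a [taxonomy()].
#' @param genome_index [build_match_index()] over the genome (or a genome
#'   [reference_set()] to index on the fly).
#' @param mode matching mode for the genome remapping (default `"ancient"`).
#' @param subsample optional number of unique reads to analyse; a seeded
#'   random subsample emulates screening a fixed-size batch of redundant
#'   sequences.
#' @param seed seed for the subsample draw.
#' @return object of class `pia_result`: list with `endogenous_proportion`,
#'   `accuracy`, `n_reads`, `total_frequency`, and the per-read table.
#' @export
endogenous_content <- function(queries, hits, tax, genome_index,
                               mode = c("ancient", "modern"),
                               subsample = NULL, seed = 1L) {
  mode <- match.arg(mode)
  q <- data.table::as.data.table(queries)
  if (!nrow(q)) stop("empty query input")
  stopifnot(all(c("query_id", "sequence", "frequency") %in% names(q)))
  if (!inherits(genome_index, "match_index")) {
    genome_index <- build_match_index(genome_index)
  }
  if (!is.null(subsample) && subsample < nrow(q)) {
    set.seed(derive_seed(seed, "pia-subsample"))
    q <- q[sample.int(nrow(q), subsample)]
  }
  h <- data.table::as.data.table(hits)
  hl <- split(h[query_id %in% q$query_id], by = "query_id")

  mapped <- unique(match_engine(q$sequence, genome_index, mode)$query_sequence)
  q[, maps_genome := sequence %in% mapped]
  q[, kept := vapply(query_id, function(id) {
    x <- hl[[id]]
    !is.null(x) && filter_ties(x$score)
  }, logical(1))]
  q[, intersect := NA_character_]
  q[kept == TRUE,
    intersect := vapply(query_id, function(id) intersect_node(hl[[id]], tax),
                        character(1))]
  q[, consistent := kept & !is.na(intersect) &
      intersect %in% tax$target_lineage]
  q[, exogenous := !maps_genome & !consistent]

  total <- sum(q$frequency)
  exo <- sum(q$frequency[q$exogenous])
  acc_den <- sum(q$frequency[q$maps_genome])
  acc <- if (acc_den > 0) sum(q$frequency[q$maps_genome & q$consistent]) / acc_den
         else NA_real_
  structure(
    list(endogenous_proportion = 1 - exo / total,
         accuracy = acc,
         n_reads = nrow(q),
         total_frequency = total,
         reads = q[]),
    class = "pia_result"
  )
}

#' @export
print.pia_result <- function(x, ...) {
  cat(sprintf(
    "<pia_result> %d unique reads (total frequency %d)\n  endogenous content (lower bound): %.1f%%\n  intersect accuracy on genome-mapping reads: %s\n",
    x$n_reads, x$total_frequency, 100 * x$endogenous_proportion,
    if (is.na(x$accuracy)) "NA" else sprintf("%.1f%%", 100 * x$accuracy)))
  invisible(x)
}
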