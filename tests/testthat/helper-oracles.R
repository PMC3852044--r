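# Independent oracles used across the suite. Each one deliberately avoids
# the code path it checks.

# Exhaustive hypergeometric upper tail: enumerate every size-n draw from a
# population of N items of which the first K are successes. Feasible for
# N <= ~22.
enum_hyper_upper <- function(k, n, K, N) {
  draws <- utils::combn(N, n)
  succ <- colSums(draws <= K)
  mean(succ >= k)
}

# Brute-force per-query best hit: literal argmax loop over the rules
# (bit score desc, e-value asc, subject id asc) applied after the cutoff.
brute_best_hits <- function(hits, cutoff) {
  hits <- hits[hits$e_value <= cutoff, , drop = FALSE]
  out <- list()
  for (q in sort(unique(hits$query_id))) {
    rows <- hits[hits$query_id == q, , drop = FALSE]
    best <- rows[1, ]
    for (i in seq_len(nrow(rows))[-1]) {
      r <- rows[i, ]
      better <- r$bit_score > best$bit_score ||
        (r$bit_score == best$bit_score && r$e_value < best$e_value) ||
        (r$bit_score == best$bit_score && r$e_value == best$e_value &&
           r$subject_id < best$subject_id)
      if (better) best <- r
    }
    out[[q]] <- best
  }
  do.call(rbind, out)
}

# Exhaustive affine-gap local alignment score by recursion over all
# alignments of all substring pairs. Exponential; only for tiny strings.
brute_local_score <- function(a, b, mat, open, ext) {
  av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
  n <- length(av); m <- length(bv)
  best <- 0
  # state: positions consumed (i, j), last move (0 start, 1 diag, 2 gap in
  # b consuming a, 3 gap in a consuming b), running score
  rec <- function(i, j, last, sc) {
    if (sc > best) best <<- sc
    if (i < n && j < m)
      rec(i + 1L, j + 1L, 1L, sc + mat[av[i + 1L], bv[j + 1L]])
    if (i < n)
      rec(i + 1L, j, 2L, sc - (if (last == 2L) ext else open + ext))
    if (j < m)
      rec(i, j + 1L, 3L, sc - (if (last == 3L) ext else open + ext))
  }
  for (i0 in 0:(n - 1L)) for (j0 in 0:(m - 1L)) rec(i0, j0, 0L, 0)
  best
}

# Exhaustive simple-path enumeration source -> target via igraph; affected
# flags recomputed directly from node gene sets.
oracle_affected_paths <- function(graph, phenotype_node, missing_genes) {
  ig <- igraph::graph_from_data_frame(
    graph$edges, directed = TRUE,
    vertices = data.frame(name = graph$nodes$node_id))
  reach <- names(igraph::subcomponent(ig, phenotype_node, mode = "in"))
  sub <- igraph::induced_subgraph(ig, reach)
  indeg <- igraph::degree(sub, mode = "in")
  sources <- setdiff(names(indeg)[indeg == 0], phenotype_node)
  lesioned <- vapply(seq_len(nrow(graph$nodes)), function(i) {
    g <- graph$nodes$gene_ids[[i]]
    length(g) > 0 && any(g %in% missing_genes)
  }, logical(1))
  lesioned_ids <- graph$nodes$node_id[lesioned &
    !(graph$nodes$node_id %in% graph$phenotype_nodes)]
  n_tot <- 0L; n_aff <- 0L
  for (s in sources) {
    ps <- igraph::all_simple_paths(sub, from = s, to = phenotype_node,
                                   mode = "out")
    for (p in ps) {
      n_tot <- n_tot + 1L
      if (any(names(p) %in% lesioned_ids)) n_aff <- n_aff + 1L
    }
  }
  c(n_affected = n_aff, n_total = n_tot)
}

# Random pathway-graph DAG for property tests.
random_dag_graph <- function(n_nodes, gene_pool, edge_p = 0.3) {
  ids <- sprintf("v%02d", seq_len(n_nodes))
  gene_sets <- lapply(seq_len(n_nodes - 1L), function(i)
    sample(gene_pool, sample(1:2, 1L)))
  gene_sets[[n_nodes]] <- character()  # phenotype sink
  edges <- list()
  for (i in seq_len(n_nodes - 1L)) for (j in (i + 1L):n_nodes)
    if (stats::runif(1) < edge_p)
      edges[[length(edges) + 1L]] <- c(ids[i], ids[j])
  if (!length(edges)) edges[[1]] <- c(ids[1], ids[n_nodes])
  em <- do.call(rbind, edges)
  nodes <- data.frame(node_id = ids, label = ids, stringsAsFactors = FALSE)
  nodes$gene_ids <- gene_sets
  pathway_graph("pwtest", nodes,
                data.frame(source = em[, 1], target = em[, 2],
                           stringsAsFactors = FALSE),
                ids[n_nodes])
}

# Alignment with one subject-side gap run of `run_len` columns and a
# mismatch percentage of exactly `mismatch_pct` (denominator = alignment
# length), used for threshold-sharpness grids.
make_indel_pair <- function(run_len, mismatch_pct, flank = 200L) {
  L <- 2L * flank + run_len
  n_mis <- round(mismatch_pct / 100 * L)
  stopifnot(n_mis <= flank)
  a <- strsplit(strrep("A", L), "")[[1]]
  b <- a
  if (n_mis > 0) b[seq_len(n_mis)] <- "C"
  b[(flank + 1L):(flank + run_len)] <- "-"
  aligned_pair("ga", "gb", paste(a, collapse = ""),
               paste(b, collapse = ""))
}

# One codon per amino acid (standard code) for planting protein segments
# in synthetic contigs.
CODON_OF <- c(A = "GCT", C = "TGT", D = "GAT", E = "GAA", F = "TTT",
              G = "GGT", H = "CAT", I = "ATT", K = "AAA", L = "CTG",
              M = "ATG", N = "AAT", P = "CCT", Q = "CAA", R = "CGT",
              S = "TCT", T = "ACT", V = "GTT", W = "TGG", Y = "TAT")

back_translate <- function(segment)
  paste(CODON_OF[strsplit(segment, "")[[1]]], collapse = "")

random_aa <- function(n) paste(sample(names(CODON_OF), n, replace = TRUE),
                               collapse = "")

random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                       replace = TRUE), collapse = "")
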