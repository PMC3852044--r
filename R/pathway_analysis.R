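# Hypergeometric enrichment of lineage-missing genes per pathway, node-level
# status, and source-to-phenotype path-affectedness on pathway graphs.

#' Hypergeometric upper-tail probability
#'
#' `P(X >= k)` for `X ~ Hypergeometric(N, K, n)`: the chance of drawing at
#' least `k` annotated genes when `n` genes are drawn without replacement
#' from a background of `N` genes of which `K` are annotated. Computed as a
#' log-space sum of `choose(K, i) * choose(N - K, n - i) / choose(N, n)`,
#' exact for `N` well beyond 1e5. `k = 0` returns exactly 1.
#'
#' @param k observed count of annotated genes in the draw.
#' @param n draw size (pathway size).
#' @param K annotated genes in the background.
#' @param N background size.
#' @return probability in `[0, 1]`.
#' @export
hypergeometric_upper_tail <- function(k, n, K, N) {
  stopifnot(length(k) == 1L, length(n) == 1L, length(K) == 1L,
            length(N) == 1L)
  if (any(c(k, n, K, N) < 0) || n > N || K > N || k > min(n, K))
    stop("invalid hypergeometric parameters: need 0 <= k <= min(n, K), ",
         "n <= N, K <= N")
  if (k == 0) return(1)
  i <- k:min(n, K)
  logp <- lchoose(K, i) + lchoose(N - K, n - i) - lchoose(N, n)
  mx <- max(logp)
  p <- exp(mx) * sum(exp(logp - mx))
  min(max(p, 0), 1)
}

#' Pathway enrichment of missing genes
#'
#' For each pathway, tests whether the missing genes (class II: present in
#' species A, absent in B) are over-represented among its members. The
#' background defaults to all genes appearing in the membership table;
#' `K` is the missing genes within the background, `n` the pathway's
#' background genes, `k` the missing genes in the pathway. P-values come
#' from [hypergeometric_upper_tail()]; a Benjamini-Hochberg column is
#' emitted alongside as a convenience (the significance flag uses the raw
#' p-value, as in the published analysis).
#'
#' @param missing_genes character vector of missing (class II) gene ids.
#' @param membership data.frame with columns `gene_id`, `pathway_id`.
#' @param background character vector of background genes; default the
#'   distinct genes of `membership`.
#' @param p_max raw-p significance level (default 0.01, strict `<`).
#' @return data.frame with columns `pathway_id`, `k`, `n`, `K`, `N`,
#'   `p_value`, `p_bh`, `significant`, sorted by `p_value` then
#'   `pathway_id`.
#' @export
enrich_pathways <- function(missing_genes, membership, background = NULL,
                            p_max = 0.01) {
  if (is.null(background)) background <- unique(membership$gene_id)
  background <- unique(as.character(background))
  if (length(background) == 0L) stop("empty background gene set")
  missing_genes <- intersect(unique(as.character(missing_genes)), background)
  N <- length(background)
  K <- length(missing_genes)
  memb <- membership[membership$gene_id %in% background, , drop = FALSE]
  memb <- memb[!duplicated(paste(memb$gene_id, memb$pathway_id, sep = "\r")), ,
               drop = FALSE]
  pathways <- sort(unique(memb$pathway_id))
  rows <- lapply(pathways, function(pw) {
    genes <- memb$gene_id[memb$pathway_id == pw]
    n <- length(genes)
    k <- sum(genes %in% missing_genes)
    data.frame(pathway_id = pw, k = k, n = n, K = K, N = N,
               p_value = hypergeometric_upper_tail(k, n, K, N),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    return(data.frame(pathway_id = character(), k = integer(),
                      n = integer(), K = integer(), N = integer(),
                      p_value = numeric(), p_bh = numeric(),
                      significant = logical(), stringsAsFactors = FALSE))
  out$p_bh <- stats::p.adjust(out$p_value, method = "BH")
  out$significant <- out$p_value < p_max
  out <- out[order(out$p_value, out$pathway_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Node status under gene loss
#'
#' Labels every non-phenotype node of a pathway graph by how much of its
#' gene set is missing: `intact` (no gene missing), `partial` (some but not
#' all missing), `all_lost` (every gene missing, at least one gene).
#'
#' @param graph a [pathway_graph()].
#' @param missing_genes character vector of missing gene ids.
#' @return data.frame with columns `node_id`, `status`, `n_genes`,
#'   `n_missing`, in node order (phenotype nodes excluded).
#' @export
node_statuses <- function(graph, missing_genes) {
  stopifnot(inherits(graph, "pathway_graph"))
  keep <- !(graph$nodes$node_id %in% graph$phenotype_nodes)
  nodes <- graph$nodes[keep, , drop = FALSE]
  n_genes <- lengths(nodes$gene_ids)
  n_missing <- vapply(nodes$gene_ids, function(g)
    sum(g %in% missing_genes), 0L)
  status <- ifelse(n_missing == 0L, "intact",
            ifelse(n_missing == n_genes, "all_lost", "partial"))
  data.frame(node_id = nodes$node_id, status = status,
             n_genes = n_genes, n_missing = n_missing,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Node-level affectedness percentage
#'
#' The count and one-decimal percentage of non-phenotype nodes that contain
#' at least one missing gene (status `partial` or `all_lost`).
#'
#' @inheritParams node_statuses
#' @return list with `affected_nodes`, `total_nodes`, `percentage`.
#' @export
node_level_percentage <- function(graph, missing_genes) {
  st <- node_statuses(graph, missing_genes)
  affected <- sum(st$status != "intact")
  total <- nrow(st)
  list(affected_nodes = affected, total_nodes = total,
       percentage = if (total == 0L) 0 else percent_one_dp(affected, total))
}

# Adjacency list helpers on pathway_graph ----------------------------------

adjacency <- function(graph, reverse = FALSE) {
  ids <- graph$nodes$node_id
  adj <- stats::setNames(vector("list", length(ids)), ids)
  for (id in ids) adj[[id]] <- character()
  src <- if (reverse) graph$edges$target else graph$edges$source
  dst <- if (reverse) graph$edges$source else graph$edges$target
  for (i in seq_along(src)) adj[[src[i]]] <- c(adj[[src[i]]], dst[i])
  lapply(adj, unique)
}

reachable_to <- function(graph, target) {
  # nodes from which `target` is reachable (including target): BFS on
  # reversed edges
  radj <- adjacency(graph, reverse = TRUE)
  seen <- target
  frontier <- target
  while (length(frontier)) {
    nxt <- setdiff(unique(unlist(radj[frontier])), seen)
    seen <- c(seen, nxt)
    frontier <- nxt
  }
  seen
}

#' Source-to-phenotype path affectedness
#'
#' Restricts the graph to nodes from which `phenotype_node` is reachable,
#' takes every in-degree-0 node of that subgraph as a source, and
#' enumerates all simple directed paths (no repeated nodes, so cyclic maps
#' have a finite path set) from each source to the phenotype node. A path
#' is affected iff it contains at least one node whose status is `partial`
#' or `all_lost` under `missing_genes`. Enumeration aborts with an error
#' when more than `max_paths` paths are found.
#'
#' @param graph a [pathway_graph()].
#' @param phenotype_node node id of the phenotype sink.
#' @param missing_genes character vector of missing gene ids.
#' @param max_paths cap on the number of enumerated paths (default 10000).
#' @return list with `n_affected`, `n_total`, and `paths` (list of node-id
#'   vectors, affected flag as attribute "affected").
#' @export
affected_paths <- function(graph, phenotype_node, missing_genes,
                           max_paths = 10000L) {
  stopifnot(inherits(graph, "pathway_graph"))
  if (!phenotype_node %in% graph$nodes$node_id)
    stop("unknown phenotype node: ", phenotype_node)
  keep <- reachable_to(graph, phenotype_node)
  sub_edges <- graph$edges[graph$edges$source %in% keep &
                             graph$edges$target %in% keep, , drop = FALSE]
  indeg <- stats::setNames(integer(length(keep)), keep)
  for (t in sub_edges$target) indeg[[t]] <- indeg[[t]] + 1L
  sources <- names(indeg)[indeg == 0L]
  sources <- setdiff(sources, phenotype_node)
  st <- node_statuses(graph, missing_genes)
  lesioned <- st$node_id[st$status != "intact"]
  adj <- stats::setNames(vector("list", length(keep)), keep)
  for (id in keep) adj[[id]] <- character()
  for (i in seq_len(nrow(sub_edges)))
    adj[[sub_edges$source[i]]] <-
      c(adj[[sub_edges$source[i]]], sub_edges$target[i])
  paths <- list()
  walk <- function(node, trail) {
    if (node == phenotype_node) {
      if (length(paths) >= max_paths)
        stop("path enumeration exceeded max_paths = ", max_paths)
      p <- c(trail, node)
      attr(p, "affected") <- any(p %in% lesioned)
      paths[[length(paths) + 1L]] <<- p
      return(invisible())
    }
    for (nb in adj[[node]]) {
      if (nb %in% trail || nb == node) next
      walk(nb, c(trail, node))
    }
    invisible()
  }
  for (s in sort(sources)) walk(s, character())
  n_aff <- sum(vapply(paths, function(p) isTRUE(attr(p, "affected")),
                      logical(1)))
  list(n_affected = n_aff, n_total = length(paths), paths = paths)
}

#' Join missing genes against a curated annotation table
#'
#' Counts how many missing genes carry a phenotype flag and how many carry
#' an expression-change flag in a user-supplied annotation table, with
#' one-decimal percentages (e.g. 19 of 29 prints as 65.5).
#'
#' @param missing_genes character vector of gene ids.
#' @param annotation data.frame with columns `gene_id`, `phenotype_flag`,
#'   `expression_flag` (0/1); see [read_annotation_table()].
#' @return list with `n_genes`, `n_with_phenotype`, `pct_with_phenotype`,
#'   `n_with_expression_change`, `pct_with_expression_change`.
#' @export
annotate_missing_genes <- function(missing_genes, annotation) {
  missing_genes <- unique(as.character(missing_genes))
  n <- length(missing_genes)
  ann <- annotation[annotation$gene_id %in% missing_genes, , drop = FALSE]
  n_ph <- sum(ann$phenotype_flag == 1L)
  n_ex <- sum(ann$expression_flag == 1L)
  list(n_genes = n,
       n_with_phenotype = n_ph,
       pct_with_phenotype = if (n == 0L) 0 else percent_one_dp(n_ph, n),
       n_with_expression_change = n_ex,
       pct_with_expression_change = if (n == 0L) 0
                                    else percent_one_dp(n_ex, n))
}
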