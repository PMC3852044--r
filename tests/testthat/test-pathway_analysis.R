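# Hypergeometric tail, enrichment, node statuses, path affectedness,
# annotation joins.

test_that("hypergeometric_upper_tail: boundary cases and validation", {
  expect_identical(hypergeometric_upper_tail(0, 5, 3, 20), 1)
  expect_equal(hypergeometric_upper_tail(5, 5, 10, 10), 1)
  expect_error(hypergeometric_upper_tail(6, 5, 10, 20), "invalid")
  expect_error(hypergeometric_upper_tail(1, 5, 30, 20), "invalid")
})

test_that("upper tail equals exhaustive draw enumeration (N = 20 case and
           small grid)", {
  expect_equal(hypergeometric_upper_tail(3, 5, 6, 20),
               enum_hyper_upper(3, 5, 6, 20), tolerance = 1e-12)
  for (N in c(8L, 13L, 18L)) {
    for (K in c(2L, N %/% 2L)) {
      for (n in c(3L, N %/% 3L + 1L)) {
        for (k in 0:min(n, K)) {
          expect_equal(hypergeometric_upper_tail(k, n, K, N),
                       enum_hyper_upper(k, n, K, N), tolerance = 1e-12,
                       label = sprintf("P(X>=%d) N=%d K=%d n=%d", k, N, K, n))
        }
      }
    }
  }
})

test_that("upper tail is monotone non-increasing in k and matches the
           reference distribution for N <= 60", {
  set.seed(3)
  for (rep in 1:200) {
    N <- sample(2:60, 1); K <- sample(0:N, 1); n <- sample(1:N, 1)
    ks <- 0:min(n, K)
    p <- vapply(ks, hypergeometric_upper_tail, 0, n = n, K = K, N = N)
    expect_true(all(diff(p) <= 1e-15))
    ref <- stats::phyper(ks - 1, K, N - K, n, lower.tail = FALSE)
    expect_equal(p, ref, tolerance = 1e-12)
  }
})

test_that("enrich_pathways: trivial directions and row bookkeeping", {
  membership <- data.frame(
    gene_id = c(sprintf("g%02d", 1:40), sprintf("g%02d", 1:10)),
    pathway_id = c(rep("pwA", 40), rep("pwB", 10)),
    stringsAsFactors = FALSE)
  # missing set disjoint from pwB
  missing <- sprintf("g%02d", 31:40)
  rows <- enrich_pathways(missing, membership)
  b <- rows[rows$pathway_id == "pwB", ]
  expect_equal(b$k, 0L)
  expect_equal(b$p_value, 1)
  # all genes of a small pathway missing, background mostly intact
  rows2 <- enrich_pathways(sprintf("g%02d", 1:10), membership)
  b2 <- rows2[rows2$pathway_id == "pwB", ]
  expect_equal(b2$k, 10L)
  expect_lt(b2$p_value, 0.01)
  expect_true(b2$significant)
  expect_error(enrich_pathways("g1", membership, background = character()),
               "empty background")
})

test_that("planted enrichment signal is detected specifically", {
  # scaled replicate set of the full acceptance simulation (10 replicates
  # here; 100 in test-acceptance.R)
  set.seed(17)
  hits <- 0L
  for (rep in 1:10) {
    bg <- sprintf("g%04d", 1:1000)
    pws <- lapply(1:6, function(i) sample(bg, 30))
    names(pws) <- sprintf("pw%02d", 1:6)
    planted <- pws[[1]]
    missing <- union(sample(planted, 27),
                     sample(setdiff(bg, planted), 285 - 27))
    membership <- data.frame(
      gene_id = unlist(pws),
      pathway_id = rep(names(pws), times = lengths(pws)),
      stringsAsFactors = FALSE)
    rows <- enrich_pathways(missing, membership, background = bg)
    flagged <- rows$pathway_id[rows$significant]
    if (identical(flagged, "pw01")) hits <- hits + 1L
  }
  expect_gte(hits, 9L)
})

test_that("node_statuses follows the lost-gene rule and partitions nodes", {
  nodes <- data.frame(node_id = c("n1", "n2", "n3", "ph"),
                      label = c("n1", "n2", "n3", "ph"),
                      stringsAsFactors = FALSE)
  nodes$gene_ids <- list(c("g1", "g2"), c("g3", "g4"), "g5", character())
  g <- pathway_graph("pw", nodes,
                     data.frame(source = c("n1", "n2", "n3"),
                                target = c("n2", "ph", "ph")), "ph")
  st <- node_statuses(g, c("g1", "g3", "g4"))
  expect_equal(st$status, c("partial", "all_lost", "intact"))
  expect_equal(sum(table(st$status)), 3L)  # phenotype node excluded
  st0 <- node_statuses(g, character())
  expect_true(all(st0$status == "intact"))

  np <- node_level_percentage(g, c("g1", "g3", "g4"))
  expect_equal(np$affected_nodes, 2L)
  expect_equal(np$percentage, 66.7)
  expect_equal(node_level_percentage(g, character())$percentage, 0)
})

test_that("node-level percentage matches the generator's lost-node ledger", {
  ds <- generate_dataset(sim_config(n_shared_genes = 30, n_a_only = 10,
                                    n_b_only = 5, n_indel_pairs = 0,
                                    seed = 23))
  g <- ds$world$pathways$graph
  truth_missing <- ds$truth$node_missing
  np <- node_level_percentage(g, ds$truth$missing_genes)
  ph <- g$phenotype_nodes
  non_ph <- setdiff(names(truth_missing), ph)
  expect_equal(np$affected_nodes,
               sum(lengths(truth_missing[non_ph]) > 0))
  expect_equal(np$total_nodes, length(non_ph))
})

test_that("affected_paths: chain, diamond, and path cap", {
  mk <- function(node_genes, edges, ph) {
    nodes <- data.frame(node_id = names(node_genes),
                        label = names(node_genes), stringsAsFactors = FALSE)
    nodes$gene_ids <- unname(node_genes)
    pathway_graph("pw", nodes,
                  data.frame(source = edges[, 1], target = edges[, 2],
                             stringsAsFactors = FALSE), ph)
  }
  chain <- mk(list(S = "g1", X = "g2", P = character()),
              rbind(c("S", "X"), c("X", "P")), "P")
  res <- affected_paths(chain, "P", missing_genes = "g2")
  expect_equal(c(res$n_affected, res$n_total), c(1L, 1L))

  diamond <- mk(list(S = "g1", X = "g2", Y = "g3", P = character()),
                rbind(c("S", "X"), c("S", "Y"), c("X", "P"), c("Y", "P")),
                "P")
  res <- affected_paths(diamond, "P", missing_genes = "g2")
  expect_equal(c(res$n_affected, res$n_total), c(1L, 2L))
  expect_error(affected_paths(diamond, "P", "g2", max_paths = 1L),
               "max_paths")
  expect_error(affected_paths(diamond, "ZZ", "g2"), "unknown phenotype")
})

test_that("affected_paths equals the exhaustive DFS oracle on random DAGs
           and is monotone in the missing set", {
  skip_if_not_installed("igraph")
  set.seed(41)
  pool <- sprintf("g%02d", 1:12)
  for (rep in 1:60) {
    g <- random_dag_graph(sample(4:12, 1), pool)
    ph <- g$phenotype_nodes
    m1 <- sample(pool, sample(0:6, 1))
    m2 <- union(m1, sample(pool, sample(0:6, 1)))  # grown missing set
    r1 <- affected_paths(g, ph, m1)
    want <- oracle_affected_paths(g, ph, m1)
    expect_equal(c(r1$n_affected, r1$n_total), unname(want))
    r2 <- affected_paths(g, ph, m2)
    expect_gte(r2$n_affected, r1$n_affected)
    expect_lte(r1$n_affected, r1$n_total)
  }
})

test_that("annotate_missing_genes reproduces the published join arithmetic", {
  genes <- sprintf("g%02d", 1:29)
  ann <- data.frame(gene_id = genes,
                    phenotype_flag = c(rep(1L, 19), rep(0L, 10)),
                    expression_flag = 0L, stringsAsFactors = FALSE)
  res <- annotate_missing_genes(genes, ann)
  expect_equal(res$n_with_phenotype, 19L)
  expect_equal(res$pct_with_phenotype, 65.5)

  genes19 <- sprintf("g%02d", 1:19)
  ann19 <- data.frame(gene_id = genes19,
                      phenotype_flag = c(rep(1L, 7), rep(0L, 12)),
                      expression_flag = 1L, stringsAsFactors = FALSE)
  res19 <- annotate_missing_genes(genes19, ann19)
  expect_equal(res19$pct_with_phenotype, 36.8)

  empty <- annotate_missing_genes(genes, ann[0, ])
  expect_equal(empty$n_with_phenotype, 0L)
  expect_equal(empty$pct_with_phenotype, 0)
})
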