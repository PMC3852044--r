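# Representative selection, best hits, RBH, classification, local aligner.

mk_hits <- function(...) {
  rows <- list(...)
  do.call(rbind, lapply(rows, function(r)
    data.frame(query_id = r[[1]], subject_id = r[[2]],
               pct_identity = 90, aln_length = 100L, mismatches = 10L,
               gap_opens = 0L, q_start = 1L, q_end = 100L, s_start = 1L,
               s_end = 100L, e_value = as.numeric(r[[3]]),
               bit_score = as.numeric(r[[4]]), stringsAsFactors = FALSE)))
}

prot <- function(pid, gene, seq, pe = NA_integer_)
  data.frame(protein_id = pid, gene_id = gene, species = "A",
             sequence = seq, pe_rank = pe, stringsAsFactors = FALSE)

test_that("select_representative: PE dominates, then length, then id", {
  g <- rbind(prot("p1", "g", strrep("A", 300), 1L),
             prot("p2", "g", strrep("A", 500), 2L))
  expect_equal(select_representative(g)$protein_id, "p1")

  g <- rbind(prot("p1", "g", strrep("A", 300), 1L),
             prot("p2", "g", strrep("A", 500), 1L))
  expect_equal(select_representative(g)$protein_id, "p2")

  g <- rbind(prot("pZ", "g", strrep("A", 300), 1L),
             prot("pA", "g", strrep("A", 300), 1L))
  expect_equal(select_representative(g)$protein_id, "pA")

  # absent PE sorts after any numeric rank
  g <- rbind(prot("p1", "g", strrep("A", 900)),
             prot("p2", "g", strrep("A", 100), 5L))
  expect_equal(select_representative(g)$protein_id, "p2")

  expect_error(select_representative(prot("p", "g", "MKV")[0, ]), "empty")
})

test_that("best_hits: dominance, inclusive cutoff boundary", {
  h <- mk_hits(list("q1", "s1", 1e-20, 90), list("q1", "s2", 1e-10, 60))
  expect_equal(best_hits(h)$subject_id, "s1")

  h <- mk_hits(list("q1", "s1", 1e-3, 50))
  expect_equal(nrow(best_hits(h, cutoff = 1e-6)), 0L)

  # the boundary e = 1e-6 itself is kept (<=)
  h <- mk_hits(list("q1", "s1", 1e-6, 50))
  expect_equal(best_hits(h, cutoff = 1e-6)$subject_id, "s1")
})

test_that("best_hits equals the brute-force argmax oracle on random tables", {
  set.seed(42)
  qs <- sprintf("q%02d", 1:20)
  ss <- sprintf("s%02d", 1:15)
  hits <- data.frame(
    query_id = sample(qs, 200, replace = TRUE),
    subject_id = sample(ss, 200, replace = TRUE),
    pct_identity = 90, aln_length = 100L, mismatches = 10L, gap_opens = 0L,
    q_start = 1L, q_end = 100L, s_start = 1L, s_end = 100L,
    e_value = 10^-sample(0:30, 200, replace = TRUE),
    bit_score = sample(seq(30, 80, by = 5), 200, replace = TRUE),
    stringsAsFactors = FALSE)
  got <- best_hits(hits, cutoff = 1e-6)
  want <- brute_best_hits(hits, cutoff = 1e-6)
  expect_equal(got$query_id, want$query_id)
  expect_equal(got$subject_id, want$subject_id)
})

test_that("reciprocal_best_hits: mutuality and symmetry", {
  fwd <- mk_hits(list("a1", "b1", 1e-30, 100), list("a2", "b2", 1e-30, 100))
  rev <- mk_hits(list("b1", "a1", 1e-30, 100), list("b2", "a9", 1e-30, 100))
  fb <- best_hits(fwd); rb <- best_hits(rev)
  expect_equal(reciprocal_best_hits(fb, rb)$gene_a, "a1")
  # asymmetry excluded
  expect_false("a2" %in% reciprocal_best_hits(fb, rb)$gene_a)
  # swapping species mirrors the pair set
  mirrored <- reciprocal_best_hits(rb, fb)
  expect_equal(mirrored$gene_a, "b1")
  expect_equal(mirrored$gene_b, "a1")
})

test_that("classify_genes: conservation, idempotence, validation", {
  pairs <- data.frame(gene_a = c("a1", "a2"), gene_b = c("b1", "b2"),
                      stringsAsFactors = FALSE)
  part <- classify_genes(c("a1", "a2", "a3"), c("b1", "b2", "b3", "b4"),
                         pairs)
  expect_equal(nrow(part$class_1), 2L)
  expect_equal(part$class_2, "a3")
  expect_equal(part$class_3, c("b3", "b4"))
  # conservation identities
  expect_equal(nrow(part$class_1) + length(part$class_2), 3L)
  expect_equal(nrow(part$class_1) + length(part$class_3), 4L)
  # no pairs: everything lineage-specific
  part0 <- classify_genes(c("a1", "a2"), "b1", NULL)
  expect_equal(part0$class_2, c("a1", "a2"))
  expect_equal(part0$class_3, "b1")
  # idempotence: reclassifying the partitioned sets is a fixed point
  part2 <- classify_genes(c(part$class_1$gene_a, part$class_2),
                          c(part$class_1$gene_b, part$class_3),
                          part$class_1)
  expect_equal(part2$class_1, part$class_1)
  expect_equal(part2$class_2, part$class_2)
  expect_equal(part2$class_3, part$class_3)
  expect_error(classify_genes("a1", "b1",
                              data.frame(gene_a = "aX", gene_b = "b1")),
               "unknown gene")
})

test_that("partition conservation holds on random inputs", {
  set.seed(7)
  for (rep in 1:20) {
    na <- sample(5:40, 1); nb <- sample(5:40, 1)
    ga <- sprintf("a%02d", 1:na); gb <- sprintf("b%02d", 1:nb)
    k <- sample(0:min(na, nb), 1)
    pairs <- data.frame(gene_a = sample(ga, k), gene_b = sample(gb, k),
                        stringsAsFactors = FALSE)
    part <- classify_genes(ga, gb, pairs)
    expect_equal(nrow(part$class_1) + length(part$class_2), na)
    expect_equal(nrow(part$class_1) + length(part$class_3), nb)
    expect_length(intersect(part$class_1$gene_a, part$class_2), 0)
    expect_length(intersect(part$class_1$gene_b, part$class_3), 0)
  }
})

test_that("local_align: self-alignment and swap invariance", {
  al <- local_align("MKV", "MKV")
  expect_equal(al$hit$pct_identity, 100)
  expect_equal(al$hit$mismatches, 0L)
  expect_equal(al$hit$gap_opens, 0L)

  set.seed(31)
  for (rep in 1:10) {
    a <- random_aa(sample(20:60, 1)); b <- random_aa(sample(20:60, 1))
    s1 <- tryCatch(local_align(a, b)$score, error = function(e) NA)
    s2 <- tryCatch(local_align(b, a)$score, error = function(e) NA)
    expect_equal(s1, s2)
  }
  expect_error(local_align("MK1", "MKV"), "illegal character")
})

test_that("local_align score equals the exhaustive path-enumeration oracle
           on tiny instances", {
  mat <- orthogain:::blosum62()
  set.seed(99)
  for (rep in 1:12) {
    a <- random_aa(5); b <- random_aa(5)
    want <- brute_local_score(a, b, mat, open = 11, ext = 1)
    if (want <= 0) next
    expect_equal(local_align(a, b)$score, want,
                 label = paste("score for", a, "vs", b))
  }
})

test_that("local_align agrees with the Biostrings aligner on random pairs", {
  mat <- orthogain:::blosum62()
  set.seed(123)
  for (rep in 1:20) {
    a <- random_aa(sample(15:80, 1)); b <- random_aa(sample(15:80, 1))
    ref <- Biostrings::pairwiseAlignment(
      Biostrings::AAString(a), Biostrings::AAString(b), type = "local",
      substitutionMatrix = mat, gapOpening = 11, gapExtension = 1)
    refscore <- Biostrings::score(ref)
    if (refscore <= 0) next
    expect_equal(local_align(a, b)$score, refscore)
  }
})

test_that("local_align reproduces planted gap runs", {
  ds <- generate_dataset(sim_config(n_shared_genes = 12, n_a_only = 2,
                                    n_b_only = 2, n_indel_pairs = 4,
                                    indel_length_range = c(30L, 35L),
                                    seed = 17))
  tr <- ds$truth
  for (i in seq_len(nrow(tr$indels))) {
    ev <- tr$indels[i, ]
    sa <- ds$world$world$seq_a[[ev$gene_a]]
    sb <- ds$world$world$seq_b[[ev$gene_b]]
    prof <- gap_profile(local_align(sa, sb)$pair)
    big <- prof$runs[prof$runs$length > 25, ]
    expect_equal(nrow(big), 1L)
    expect_equal(big$length, ev$length)
  }
})

test_that("simulator tables without noise reproduce the truth pair set", {
  ds <- generate_dataset(sim_config(n_shared_genes = 40, n_a_only = 10,
                                    n_b_only = 10, n_indel_pairs = 3,
                                    seed = 29))
  tabs <- simulate_alignment_table(ds$truth)
  pairs <- reciprocal_best_hits(best_hits(tabs$forward),
                                best_hits(tabs$reverse))
  expect_equal(pairs[c("gene_a", "gene_b")], ds$truth$ortholog_pairs)
})
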