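# Gap profiling, candidate thresholds, polarity, domain overlap, six-frame
# verification.

test_that("gap_profile: hand-checkable cases and column accounting", {
  p <- aligned_pair("a", "b", "ACDEF", "ACDEF")
  prof <- gap_profile(p)
  expect_equal(nrow(prof$runs), 0L)
  expect_equal(prof$mismatch_count, 0L)
  expect_equal(prof$identity_pct, 100)

  p <- aligned_pair("a", "b", "ACD---KL", "ACDQWEKL")
  prof <- gap_profile(p)
  expect_equal(nrow(prof$runs), 1L)
  expect_equal(prof$runs$side, "query")
  expect_equal(prof$runs$column_start, 4L)
  expect_equal(prof$runs$length, 3L)

  expect_error(aligned_pair("a", "b", "A-C", "A-C"), "both sides")
})

test_that("column accounting holds for generated alignments", {
  ds <- generate_dataset(sim_config(n_shared_genes = 40, n_a_only = 5,
                                    n_b_only = 5, n_indel_pairs = 8,
                                    seed = 37))
  for (pair in ds$world$world$alns) {
    prof <- gap_profile(pair)
    expect_equal(prof$total_gap_columns + prof$mismatch_count +
                   round(prof$identity_pct / 100 * prof$aln_length),
                 prof$aln_length)
  }
  # planted run lengths recovered exactly from the true alignments
  tr <- ds$truth$indels
  for (i in seq_len(nrow(tr))) {
    prof <- gap_profile(ds$world$world$alns[[tr$gene_a[i]]])
    expect_equal(max(prof$runs$length), tr$length[i])
  }
})

test_that("threshold sharpness: strict > 25 and strict < 10", {
  cfg <- threshold_config()
  # run 26, mismatch 5% -> kept
  ev <- select_candidates(make_indel_pair(26L, 5), cfg)
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$length, 26L)
  # run 25 -> excluded
  expect_equal(nrow(select_candidates(make_indel_pair(25L, 5), cfg)), 0L)
  # mismatch exactly 10% -> excluded
  p <- make_indel_pair(40L, 10)
  expect_equal(gap_profile(p)$mismatch_pct, 10)
  expect_equal(nrow(select_candidates(p, cfg)), 0L)
  # mismatch 9.9%-ish below 10 -> exactly one event
  p <- make_indel_pair(26L, 9.8)
  expect_lt(gap_profile(p)$mismatch_pct, 10)
  expect_equal(nrow(select_candidates(p, cfg)), 1L)
})

test_that("polarity and coordinates: gap side determines the carrier", {
  # subject-side gap: segment retained by A = deletion in B
  p <- make_indel_pair(30L, 0)
  ev <- select_candidates(p)
  expect_equal(ev$polarity, "deletion_in_b")
  expect_equal(ev$start, 201L)
  expect_equal(ev$end, 230L)
  expect_equal(ev$end - ev$start + 1L, ev$length)
  # swapping the two sequences flips polarity and preserves length
  sw <- aligned_pair("gb", "ga", p$subject_aln, p$query_aln)
  ev2 <- select_candidates(sw)
  expect_equal(ev2$polarity, "insertion_in_b")
  expect_equal(ev2$length, ev$length)
  expect_equal(ev2$start, ev$start)
})

test_that("total-gap mode gates on summed gap columns", {
  # two runs of 15: total 30 > 25, max run 15
  a <- paste0(strrep("A", 50), strrep("A", 15), strrep("A", 50),
              strrep("A", 15), strrep("A", 50))
  b <- paste0(strrep("A", 50), strrep("-", 15), strrep("A", 50),
              strrep("-", 15), strrep("A", 50))
  p <- aligned_pair("ga", "gb", a, b)
  expect_equal(nrow(select_candidates(p, gap_mode = "run")), 0L)
  # in total mode the pair qualifies, but only runs > 25 become events;
  # none here
  expect_equal(nrow(select_candidates(p, gap_mode = "total")), 0L)
  # one 20-run plus one 26-run: total mode reports the 26-run event
  b2 <- paste0(strrep("A", 50), strrep("-", 20), strrep("A", 50),
               strrep("-", 26), strrep("A", 34))
  a2 <- strrep("A", 180)
  p2 <- aligned_pair("ga", "gb", a2, b2)
  expect_equal(nrow(select_candidates(p2, gap_mode = "run")), 1L)
  expect_equal(select_candidates(p2, gap_mode = "total")$length, 26L)
})

test_that("domain_overlap equals the brute-force interval oracle", {
  expect_equal(domain_overlap(
    list(start = 100L, end = 130L),
    data.frame(protein_id = "p", domain_id = "D1", start = 120L,
               end = 200L)), "D1")
  expect_equal(domain_overlap(
    list(start = 100L, end = 130L),
    data.frame(protein_id = "p", domain_id = "D1", start = 131L,
               end = 200L)), character())
  set.seed(53)
  for (rep in 1:50) {
    ev <- sort(sample(1:300, 2)); names(ev) <- NULL
    doms <- data.frame(domain_id = sprintf("D%02d", 1:8),
                       start = sample(1:250, 8), stringsAsFactors = FALSE)
    doms$end <- doms$start + sample(0:80, 8)
    got <- domain_overlap(list(start = ev[1], end = ev[2]), doms)
    want <- character()
    for (i in 1:8)
      if (max(ev[1], doms$start[i]) <= min(ev[2], doms$end[i]))
        want <- c(want, doms$domain_id[i])
    expect_equal(got, sort(unique(want)))
  }
})

test_that("six-frame verification finds planted segments on both strands", {
  set.seed(61)
  segment <- random_aa(30)
  dna <- back_translate(segment)
  contig <- paste0(random_dna(301), dna, random_dna(200))
  res <- verify_segment_absence(segment, contig)
  expect_equal(res$verdict, "present")
  expect_equal(res$frame, "+2")  # 301-nt lead-in puts it in frame +2
  expect_gte(res$identity_pct, 90)
  # coordinates locate the planted segment in the translated frame
  expect_equal(res$aa_start, 301 %/% 3 + 1L)

  # reverse-complement embedding is found on a negative frame
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(contig)))
  res_rc <- verify_segment_absence(segment, rc)
  expect_equal(res_rc$verdict, "present")
  expect_true(startsWith(res_rc$frame, "-"))

  # negative control: random contig
  res_neg <- verify_segment_absence(segment, random_dna(9999))
  expect_equal(res_neg$verdict, "absent")
  expect_error(verify_segment_absence("SHORT", contig), "at least 10")
  expect_error(verify_segment_absence(segment, "ACGTU"), "illegal")
})

test_that("random-contig hits at 90% identity are negligible", {
  # empirical negative-control rate over seeded replicates
  set.seed(67)
  false_present <- 0L
  for (rep in 1:10) {
    seg <- random_aa(30)
    if (verify_segment_absence(seg, random_dna(5000))$verdict == "present")
      false_present <- false_present + 1L
  }
  expect_equal(false_present, 0L)
})

test_that("scan_indels recovers planted events with domain context", {
  td <- withr::local_tempdir()
  ds <- generate_dataset(sim_config(n_shared_genes = 25, n_a_only = 5,
                                    n_b_only = 5, n_indel_pairs = 6,
                                    fraction_indels_in_domains = 1,
                                    seed = 43), td)
  orth <- run_orthology(td)
  events <- scan_indels(orth$partition, orth$rep_a, orth$rep_b,
                        read_domain_table(file.path(td, "domains_a.tsv")),
                        read_domain_table(file.path(td, "domains_b.tsv")))
  tr <- ds$truth$indels
  expect_equal(nrow(events), nrow(tr))
  expect_equal(sort(paste(events$gene_a, events$polarity, events$length)),
               sort(paste(tr$gene_a, tr$polarity, tr$length)))
  # every planted event sits inside a domain here
  expect_true(all(nzchar(events$domains)))
})
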