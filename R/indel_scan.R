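# Large-indel screen on class-I ortholog alignments: gap profiling,
# threshold filtering, domain overlap, and six-frame genome verification.

#' Gap profile of an explicit alignment
#'
#' Scans an [aligned_pair()] column by column. A gap run is a maximal block
#' of `-` on one side; a mismatch is a column with two differing residues.
#' The mismatch percentage uses the full alignment length as denominator,
#' so identities + mismatches + gap columns always sum to the alignment
#' length.
#'
#' @param pair an `aligned_pair`.
#' @return list with `runs` (data.frame `side` ("query"/"subject"),
#'   `column_start`, `length`), `total_gap_columns`, `mismatch_count`,
#'   `mismatch_pct`, `identity_pct`, `aln_length`.
#' @export
gap_profile <- function(pair) {
  stopifnot(inherits(pair, "aligned_pair"))
  qa <- strsplit(pair$query_aln, "")[[1]]
  sa <- strsplit(pair$subject_aln, "")[[1]]
  if (any(qa == "-" & sa == "-"))
    stop("column gapped on both sides")
  L <- length(qa)
  gap_q <- qa == "-"   # gap on query side (residues present in subject)
  gap_s <- sa == "-"
  run_table <- function(gaps, side) {
    if (!any(gaps))
      return(data.frame(side = character(), column_start = integer(),
                        length = integer(), stringsAsFactors = FALSE))
    r <- rle(gaps)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    keep <- r$values
    data.frame(side = side, column_start = starts[keep],
               length = r$lengths[keep], stringsAsFactors = FALSE)
  }
  runs <- rbind(run_table(gap_q, "query"), run_table(gap_s, "subject"))
  runs <- runs[order(runs$column_start), , drop = FALSE]
  rownames(runs) <- NULL
  resid <- !gap_q & !gap_s
  mism <- sum(resid & qa != sa)
  ident <- sum(resid & qa == sa)
  list(runs = runs,
       total_gap_columns = sum(gap_q) + sum(gap_s),
       mismatch_count = mism,
       mismatch_pct = mism / L * 100,
       identity_pct = ident / L * 100,
       aln_length = L)
}

# Map an alignment column to the 1-based coordinate on the ungapped
# sequence of the non-gapped side of a run.
ungapped_coord <- function(aln_chars, offset, column) {
  offset + sum(aln_chars[seq_len(column - 1L)] != "-")
}

#' Select large-indel candidates
#'
#' Applies the published filter to gap profiles: a pair qualifies when its
#' maximal single gap-run length exceeds `indel_gap_min` (strictly, default
#' > 25 columns) AND its mismatch percentage is strictly below
#' `indel_mismatch_pct_max` (default < 10). One event is emitted per
#' qualifying run (each run longer than the bound). Polarity is relative to
#' the subject species B: a gap on B's side means the segment was lost in B
#' (`deletion_in_b`); a gap on A's side means extra sequence in B
#' (`insertion_in_b`). Coordinates are 1-based inclusive on the ungapped
#' sequence that retains the segment.
#'
#' With `gap_mode = "total"` the pair-level filter uses the summed gap
#' columns instead of the maximal run (sensitivity analysis; events are
#' still per-run and only runs longer than the bound are reported).
#'
#' @param pairs list of `aligned_pair` objects (query = species A,
#'   subject = species B).
#' @param config a [threshold_config()].
#' @param gap_mode `"run"` (default) or `"total"`.
#' @return data.frame of indel events: `gene_a`, `gene_b`, `polarity`,
#'   `start`, `end`, `length`, `mismatch_pct`.
#' @export
select_candidates <- function(pairs, config = threshold_config(),
                              gap_mode = c("run", "total")) {
  gap_mode <- match.arg(gap_mode)
  if (inherits(pairs, "aligned_pair")) pairs <- list(pairs)
  out <- list()
  for (pair in pairs) {
    prof <- gap_profile(pair)
    if (prof$mismatch_pct >= config$indel_mismatch_pct_max) next
    gate <- if (gap_mode == "run") {
      nrow(prof$runs) > 0L && max(prof$runs$length) > config$indel_gap_min
    } else {
      prof$total_gap_columns > config$indel_gap_min
    }
    if (!gate) next
    qa <- strsplit(pair$query_aln, "")[[1]]
    sa <- strsplit(pair$subject_aln, "")[[1]]
    runs <- prof$runs[prof$runs$length > config$indel_gap_min, , drop = FALSE]
    for (k in seq_len(nrow(runs))) {
      side <- runs$side[k]; col <- runs$column_start[k]; len <- runs$length[k]
      if (side == "subject") {
        # gap on B's side: segment retained by A
        polarity <- "deletion_in_b"
        start <- ungapped_coord(qa, pair$q_offset, col)
      } else {
        # gap on A's side: segment present only in B
        polarity <- "insertion_in_b"
        start <- ungapped_coord(sa, pair$s_offset, col)
      }
      out[[length(out) + 1L]] <- data.frame(
        gene_a = pair$query_id, gene_b = pair$subject_id,
        polarity = polarity, start = start, end = start + len - 1L,
        length = len, mismatch_pct = prof$mismatch_pct,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(gene_a = character(), gene_b = character(),
                      polarity = character(), start = integer(),
                      end = integer(), length = integer(),
                      mismatch_pct = numeric(), stringsAsFactors = FALSE))
  ev <- do.call(rbind, out)
  ev <- ev[order(ev$gene_a, ev$start), , drop = FALSE]
  rownames(ev) <- NULL
  ev
}

#' Domains overlapping an indel event
#'
#' Reports the domain ids whose `[start, end]` interval intersects the
#' event's `[start, end]` by at least one residue (adjacent intervals do
#' not overlap). Coordinates on both sides are 1-based inclusive on the
#' segment-bearing protein.
#'
#' @param event one-row data.frame (or list) with `start`, `end`.
#' @param domains data.frame with columns `domain_id`, `start`, `end`
#'   (annotations of the protein that carries the segment).
#' @return character vector of overlapping `domain_id`s (sorted, unique).
#' @export
domain_overlap <- function(event, domains) {
  if (is.null(domains) || nrow(domains) == 0L) return(character())
  hit <- domains$start <= event$end & domains$end >= event$start
  sort(unique(domains$domain_id[hit]))
}

# ---------------------------------------------------------------------------
# Six-frame genome verification

GENETIC_CODE_TABLE <- NULL  # standard code comes from Biostrings

#' Six-frame translation of a nucleotide sequence
#'
#' Frames +1/+2/+3 are offsets 0/1/2 on the forward strand; -1/-2/-3 the
#' same offsets on the reverse complement. Sequences are trimmed to whole
#' codons; the standard genetic code is used, stop codons become `*` and
#' fuzzy codons `X`.
#'
#' @param genome_seq nucleotide string (A/C/G/T/N, case-insensitive).
#' @return named character vector of six protein strings
#'   (`+1`,`+2`,`+3`,`-1`,`-2`,`-3`).
#' @export
six_frame_translate <- function(genome_seq) {
  genome_seq <- toupper(genome_seq)
  if (grepl("[^ACGTN]", genome_seq))
    stop("illegal nucleotide character in genome sequence")
  fwd <- Biostrings::DNAString(genome_seq)
  rev <- Biostrings::reverseComplement(fwd)
  frames <- character(6)
  names(frames) <- c("+1", "+2", "+3", "-1", "-2", "-3")
  for (off in 0:2) {
    for (strand in c("+", "-")) {
      s <- if (strand == "+") fwd else rev
      len <- length(s) - off
      len <- len - (len %% 3L)
      frames[paste0(strand, off + 1L)] <- if (len >= 3L)
        as.character(Biostrings::translate(
          Biostrings::subseq(s, start = off + 1L, width = len),
          if.fuzzy.codon = "X", no.init.codon = TRUE))
      else ""
    }
  }
  frames
}

#' Verify absence of a protein segment from a genome
#'
#' Desk-scale stand-in for a translated genome search: the segment is
#' locally aligned against all six translated frames of `genome_seq`
#' (stops treated as X so alignments cannot cross them favourably). The
#' segment is called `present` iff the best frame alignment reaches
#' `min_identity` percent identity and covers at least `min_coverage` of
#' the segment; otherwise `absent`.
#'
#' @param segment amino-acid string, length >= 10.
#' @param genome_seq nucleotide string.
#' @param min_identity percent identity threshold (default 90).
#' @param min_coverage fraction of the segment that must be aligned
#'   (default 0.8).
#' @param scoring aligner parameters, see [align_scoring()].
#' @return list with `verdict` ("present"/"absent"), and for present calls
#'   `frame`, `aa_start`, `aa_end` (coordinates in the translated frame),
#'   `identity_pct`, `coverage`.
#' @export
verify_segment_absence <- function(segment, genome_seq, min_identity = 90,
                                   min_coverage = 0.8,
                                   scoring = align_scoring()) {
  if (nchar(segment) < 10L) stop("segment must be at least 10 residues")
  frames <- six_frame_translate(genome_seq)
  best <- NULL
  for (fr in names(frames)) {
    prot <- chartr("*", "X", frames[[fr]])
    if (nchar(prot) < 4L) next
    al <- tryCatch(local_align(segment, prot, query_id = "segment",
                               subject_id = fr, scoring = scoring),
                   error = function(e) NULL)
    if (is.null(al)) next
    cov <- (al$hit$q_end - al$hit$q_start + 1) / nchar(segment)
    cand <- list(frame = fr, identity_pct = al$hit$pct_identity,
                 coverage = cov, aa_start = al$hit$s_start,
                 aa_end = al$hit$s_end, score = al$score)
    if (is.null(best) || cand$score > best$score) best <- cand
  }
  if (!is.null(best) && best$identity_pct >= min_identity &&
      best$coverage >= min_coverage) {
    c(list(verdict = "present"), best[c("frame", "aa_start", "aa_end",
                                        "identity_pct", "coverage")])
  } else {
    list(verdict = "absent")
  }
}

#' Run the indel screen over ortholog pairs
#'
#' Aligns every class-I pair with the built-in aligner (or accepts
#' precomputed `aligned_pair`s), applies [select_candidates()], and
#' attaches overlapping domains of the segment-bearing protein.
#'
#' @param partition a `class_partition` (only `class_1` is used).
#' @param proteome_a,proteome_b representative protein data.frames keyed by
#'   `gene_id`.
#' @param domains_a,domains_b domain tables ([read_domain_table()]) for
#'   each species, or `NULL`.
#' @param config a [threshold_config()].
#' @param aligned optional named list of precomputed `aligned_pair`s keyed
#'   by `gene_a` (bypasses the aligner).
#' @param gap_mode passed to [select_candidates()].
#' @return indel-event data.frame with an extra `domains` column
#'   (comma-separated ids).
#' @export
scan_indels <- function(partition, proteome_a, proteome_b,
                        domains_a = NULL, domains_b = NULL,
                        config = threshold_config(), aligned = NULL,
                        gap_mode = "run") {
  stopifnot(inherits(partition, "class_partition"))
  seq_a <- stats::setNames(proteome_a$sequence, proteome_a$gene_id)
  seq_b <- stats::setNames(proteome_b$sequence, proteome_b$gene_id)
  prot_a <- stats::setNames(proteome_a$protein_id, proteome_a$gene_id)
  prot_b <- stats::setNames(proteome_b$protein_id, proteome_b$gene_id)
  pairs <- list()
  for (i in seq_len(nrow(partition$class_1))) {
    ga <- partition$class_1$gene_a[i]; gb <- partition$class_1$gene_b[i]
    if (!is.null(aligned) && !is.null(aligned[[ga]])) {
      pairs[[length(pairs) + 1L]] <- aligned[[ga]]
    } else {
      al <- tryCatch(local_align(seq_a[[ga]], seq_b[[gb]],
                                 query_id = ga, subject_id = gb),
                     error = function(e) NULL)
      if (!is.null(al)) pairs[[length(pairs) + 1L]] <- al$pair
    }
  }
  events <- select_candidates(pairs, config, gap_mode = gap_mode)
  if (nrow(events) == 0L) {
    events$domains <- character()
    return(events)
  }
  events$domains <- vapply(seq_len(nrow(events)), function(i) {
    ev <- events[i, ]
    if (ev$polarity == "deletion_in_b") {
      doms <- if (is.null(domains_a)) NULL
              else domains_a[domains_a$protein_id == prot_a[[ev$gene_a]], ,
                             drop = FALSE]
    } else {
      doms <- if (is.null(domains_b)) NULL
              else domains_b[domains_b$protein_id == prot_b[[ev$gene_b]], ,
                             drop = FALSE]
    }
    paste(domain_overlap(ev, doms), collapse = ",")
  }, "")
  events
}
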