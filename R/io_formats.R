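# Readers/writers for every external format the pipeline touches, plus the
# threshold configuration shared by all stages.

AA_LETTERS <- c("A","C","D","E","F","G","H","I","K","L","M","N","P","Q","R",
                "S","T","V","W","Y","X")

#' Analysis thresholds
#'
#' Bundles the cutoffs used across the pipeline. Defaults are the published
#' operating points of the rat vs naked mole-rat comparison this package
#' re-implements: orthology hits at E-value <= 1e-6, family assignment at
#' E-value <= 1e-5, indel candidates at single gap-run length > 25 with
#' mismatch percentage < 10 (both strict), pathway enrichment at p < 0.01.
#'
#' @param ortholog_evalue_max inclusive E-value ceiling for orthology hits.
#' @param family_evalue_max inclusive E-value ceiling for family assignment.
#' @param indel_gap_min exclusive lower bound on gap-run length (columns).
#' @param indel_mismatch_pct_max exclusive upper bound on mismatch percentage.
#' @param enrichment_p_max exclusive significance level for enrichment.
#' @return an object of class `threshold_config`.
#' @export
threshold_config <- function(ortholog_evalue_max = 1e-6,
                             family_evalue_max = 1e-5,
                             indel_gap_min = 25L,
                             indel_mismatch_pct_max = 10,
                             enrichment_p_max = 0.01) {
  stopifnot(ortholog_evalue_max > 0, family_evalue_max > 0,
            indel_gap_min > 0, indel_mismatch_pct_max > 0,
            enrichment_p_max > 0)
  structure(list(ortholog_evalue_max = ortholog_evalue_max,
                 family_evalue_max = family_evalue_max,
                 indel_gap_min = as.integer(indel_gap_min),
                 indel_mismatch_pct_max = indel_mismatch_pct_max,
                 enrichment_p_max = enrichment_p_max),
            class = "threshold_config")
}

#' Read a key=value configuration file into a threshold_config
#'
#' Lines are `key = value`; blank lines and lines starting with `#` are
#' ignored. Unknown keys raise an error.
#'
#' @param path file to read.
#' @param base configuration to override (default [threshold_config()]).
#' @return a `threshold_config`.
#' @export
read_threshold_config <- function(path, base = threshold_config()) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  vals <- unclass(base)
  for (ln in lines) {
    kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
    if (length(kv) != 2L)
      stop("malformed config line: '", ln, "'")
    key <- trimws(kv[1]); val <- as.numeric(trimws(kv[2]))
    if (!key %in% names(vals))
      stop("unknown configuration key: '", key, "'")
    if (is.na(val)) stop("non-numeric value for key '", key, "'")
    vals[[key]] <- val
  }
  do.call(threshold_config, vals)
}

# ---------------------------------------------------------------------------
# FASTA proteomes
#
# Header dialect: ">protein_id gene=GENE pe=N" with both tokens optional.
# gene defaults to the protein id; pe (protein-existence rank, smaller =
# stronger evidence) defaults to NA.

parse_fasta_header <- function(header, record_no) {
  toks <- strsplit(trimws(header), "[ \t]+")[[1]]
  if (length(toks) == 0L || !nzchar(toks[1]))
    stop("malformed FASTA header at record ", record_no, ": empty id")
  pid <- toks[1]
  gene <- pid
  pe <- NA_integer_
  for (tok in toks[-1]) {
    if (startsWith(tok, "gene=")) {
      gene <- sub("^gene=", "", tok)
      if (!nzchar(gene))
        stop("malformed FASTA header at record ", record_no,
             " ('", header, "'): empty gene token")
    } else if (startsWith(tok, "pe=")) {
      pe_chr <- sub("^pe=", "", tok)
      pe <- suppressWarnings(as.integer(pe_chr))
      if (is.na(pe) || pe < 1L)
        stop("malformed FASTA header at record ", record_no,
             " ('", header, "'): pe must be an integer >= 1, got '",
             pe_chr, "'")
    }
    # unrecognised tokens are free-text description and ignored
  }
  list(protein_id = pid, gene_id = gene, pe_rank = pe)
}

#' Read a proteome FASTA file
#'
#' Headers follow the dialect `>protein_id gene=GENE pe=N` (both tokens
#' optional; `gene` defaults to the protein id, `pe` to `NA`). Sequences are
#' uppercased and a trailing stop (`*`) is stripped.
#'
#' @param path FASTA file.
#' @param species species label attached to every record.
#' @return data.frame with columns `protein_id`, `gene_id`, `species`,
#'   `sequence`, `pe_rank`, one row per FASTA record in file order.
#' @export
read_fasta <- function(path, species = NA_character_) {
  # parsed line by line (not via readAAStringSet) so that dialect
  # violations are reported with their line number instead of being
  # silently dropped by the permissive AA alphabet
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  hdr_at <- which(startsWith(lines, ">"))
  if (length(hdr_at) == 0L) {
    if (any(nzchar(trimws(lines))))
      stop("not a FASTA file (no '>' header): ", path)
    return(data.frame(protein_id = character(), gene_id = character(),
                      species = character(), sequence = character(),
                      pe_rank = integer(), stringsAsFactors = FALSE))
  }
  if (any(nzchar(trimws(lines[seq_len(hdr_at[1] - 1L)]))))
    stop("sequence data before first FASTA header at line 1")
  bounds <- c(hdr_at, length(lines) + 1L)
  legal <- paste0("[^", paste(AA_LETTERS, collapse = ""), "]")
  recs <- lapply(seq_along(hdr_at), function(i) {
    ln <- hdr_at[i]
    meta <- tryCatch(parse_fasta_header(sub("^>", "", lines[ln]), i),
                     error = function(e)
                       stop(conditionMessage(e), " (line ", ln, ")",
                            call. = FALSE))
    body <- if (bounds[i + 1L] - 1L >= ln + 1L)
      lines[seq(ln + 1L, bounds[i + 1L] - 1L)] else character()
    sq <- toupper(paste(trimws(body), collapse = ""))
    sq <- sub("\\*$", "", sq)
    if (!nzchar(sq))
      stop("empty sequence for record '", meta$protein_id, "' (line ",
           ln, ")", call. = FALSE)
    bad <- regmatches(sq, regexpr(legal, sq))
    if (length(bad))
      stop("illegal residue character '", bad,
           "' in record '", meta$protein_id, "' (header at line ", ln,
           ")", call. = FALSE)
    data.frame(protein_id = meta$protein_id, gene_id = meta$gene_id,
               species = species, sequence = sq, pe_rank = meta$pe_rank,
               stringsAsFactors = FALSE)
  })
  rec <- do.call(rbind, recs)
  if (anyDuplicated(rec$protein_id))
    stop("duplicate protein_id in ", path, ": ",
         paste(unique(rec$protein_id[duplicated(rec$protein_id)]),
               collapse = ", "))
  rownames(rec) <- NULL
  rec
}

#' Write a proteome FASTA file
#'
#' Inverse of [read_fasta()]: emits `>protein_id gene=GENE pe=N` headers,
#' omitting the `pe` token when the rank is `NA`.
#'
#' @param records data.frame as returned by [read_fasta()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path) {
  stopifnot(all(c("protein_id", "gene_id", "sequence") %in% names(records)))
  pe <- if ("pe_rank" %in% names(records)) records$pe_rank
        else rep(NA_integer_, nrow(records))
  hdr <- paste0(records$protein_id, " gene=", records$gene_id,
                ifelse(is.na(pe), "", paste0(" pe=", pe)))
  ss <- Biostrings::AAStringSet(records$sequence)
  names(ss) <- hdr
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}

# ---------------------------------------------------------------------------
# 12-column tabular alignment (outfmt-6 convention)

ALN_COLS <- c("query_id", "subject_id", "pct_identity", "aln_length",
              "mismatches", "gap_opens", "q_start", "q_end",
              "s_start", "s_end", "e_value", "bit_score")
ALN_NUMERIC <- ALN_COLS[3:12]

#' Read a 12-column tabular alignment file
#'
#' Standard tab-separated pairwise-alignment rows in the order query,
#' subject, identity, length, mismatches, gap opens, qstart, qend, sstart,
#' send, evalue, bitscore. Scientific-notation E-values are accepted; row
#' order is preserved.
#'
#' @param path TSV file (no header; lines starting with `#` are skipped).
#' @return data.frame with columns `r ALN_COLS`.
#' @export
read_tabular_alignment <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  keep <- nzchar(lines) & !startsWith(lines, "#")
  lines <- lines[keep]
  if (length(lines) == 0L) return(empty_alignment_table())
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != 12L))
    stop("expected 12 tab-separated columns, got ", nf[nf != 12L][1],
         " at row ", which(nf != 12L)[1])
  m <- matrix(unlist(fields), ncol = 12L, byrow = TRUE)
  hits <- data.frame(query_id = m[, 1], subject_id = m[, 2],
                     stringsAsFactors = FALSE)
  for (j in 3:12) {
    v <- suppressWarnings(as.numeric(m[, j]))
    if (anyNA(v))
      stop("non-numeric value '", m[which(is.na(v))[1], j],
           "' in column ", j, " at row ", which(is.na(v))[1])
    hits[[ALN_COLS[j]]] <- v
  }
  for (cc in c("aln_length", "mismatches", "gap_opens",
               "q_start", "q_end", "s_start", "s_end"))
    hits[[cc]] <- as.integer(hits[[cc]])
  validate_alignment_table(hits)
  hits
}

empty_alignment_table <- function() {
  df <- data.frame(query_id = character(), subject_id = character(),
                   stringsAsFactors = FALSE)
  for (cc in ALN_NUMERIC) df[[cc]] <- numeric()
  for (cc in c("aln_length", "mismatches", "gap_opens",
               "q_start", "q_end", "s_start", "s_end"))
    df[[cc]] <- integer()
  df[ALN_COLS]
}

validate_alignment_table <- function(hits) {
  if (nrow(hits) == 0L) return(invisible(hits))
  if (any(hits$q_start > hits$q_end) || any(hits$s_start > hits$s_end))
    stop("alignment coordinates must satisfy start <= end")
  if (any(hits$e_value < 0)) stop("negative e_value in alignment table")
  invisible(hits)
}

#' Write a 12-column tabular alignment file
#' @param hits data.frame as returned by [read_tabular_alignment()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_tabular_alignment <- function(hits, path) {
  stopifnot(all(ALN_COLS %in% names(hits)))
  out <- hits[ALN_COLS]
  out$e_value <- format_evalue(out$e_value)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

format_evalue <- function(e) {
  # outfmt-6 style: small values in scientific notation, zero as 0.0
  vapply(e, function(x) {
    if (x == 0) "0.0"
    else if (x < 1e-3) sprintf("%.2e", x)
    else sprintf("%.3g", x)
  }, "")
}

# ---------------------------------------------------------------------------
# Generic header-line TSV tables (single '#'-prefixed header)

read_tsv_table <- function(path, expected_cols, numeric_cols = character()) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0L || !startsWith(lines[1], "#"))
    stop("expected a '#'-prefixed header line in ", path)
  hdr <- strsplit(sub("^#", "", lines[1]), "\t", fixed = TRUE)[[1]]
  if (!identical(hdr, expected_cols))
    stop("unexpected columns in ", path, ": got [",
         paste(hdr, collapse = ", "), "], expected [",
         paste(expected_cols, collapse = ", "), "]")
  body <- lines[-1]
  body <- body[nzchar(body)]
  if (length(body) == 0L) {
    df <- as.data.frame(stats::setNames(
      replicate(length(expected_cols), character(), simplify = FALSE),
      expected_cols), stringsAsFactors = FALSE)
  } else {
    fields <- strsplit(body, "\t", fixed = TRUE)
    nf <- lengths(fields)
    if (any(nf != length(expected_cols)))
      stop("wrong column count at data row ", which(nf != length(expected_cols))[1],
           " of ", path)
    m <- matrix(unlist(fields), ncol = length(expected_cols), byrow = TRUE)
    df <- as.data.frame(m, stringsAsFactors = FALSE)
    names(df) <- expected_cols
  }
  for (cc in numeric_cols) {
    v <- suppressWarnings(as.numeric(df[[cc]]))
    if (anyNA(v) && nrow(df) > 0L)
      stop("non-numeric value in column '", cc, "' of ", path)
    df[[cc]] <- v
  }
  df
}

write_tsv_table <- function(df, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("#", paste(names(df), collapse = "\t")), con)
  if (nrow(df) > 0L)
    utils::write.table(df, con, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Family, domain, membership and annotation tables
#'
#' Thin TSV readers/writers (UTF-8, tab-separated, one `#`-prefixed header
#' line) for the pipeline's side tables:
#' * family table: `protein_id, family_id, e_value, bit_score`
#' * domain table: `protein_id, domain_id, start, end` (1-based inclusive)
#' * pathway membership: `gene_id, pathway_id`
#' * annotation table: `gene_id, phenotype_flag, expression_flag` (0/1)
#'
#' @param path file to read or write.
#' @param df data.frame to write.
#' @return the readers return a data.frame; the writers return `path`
#'   invisibly.
#' @name side_tables
NULL

#' @rdname side_tables
#' @export
read_family_table <- function(path)
  read_tsv_table(path, c("protein_id", "family_id", "e_value", "bit_score"),
                 numeric_cols = c("e_value", "bit_score"))

#' @rdname side_tables
#' @export
write_family_table <- function(df, path) write_tsv_table(df, path)

#' @rdname side_tables
#' @export
read_domain_table <- function(path) {
  df <- read_tsv_table(path, c("protein_id", "domain_id", "start", "end"),
                       numeric_cols = c("start", "end"))
  df$start <- as.integer(df$start); df$end <- as.integer(df$end)
  if (nrow(df) > 0L && any(df$start < 1L | df$start > df$end))
    stop("domain intervals must satisfy 1 <= start <= end")
  df
}

#' @rdname side_tables
#' @export
write_domain_table <- function(df, path) write_tsv_table(df, path)

#' @rdname side_tables
#' @export
read_membership_table <- function(path)
  read_tsv_table(path, c("gene_id", "pathway_id"))

#' @rdname side_tables
#' @export
write_membership_table <- function(df, path) write_tsv_table(df, path)

#' @rdname side_tables
#' @export
read_annotation_table <- function(path) {
  df <- read_tsv_table(path, c("gene_id", "phenotype_flag", "expression_flag"),
                       numeric_cols = c("phenotype_flag", "expression_flag"))
  df$phenotype_flag <- as.integer(df$phenotype_flag)
  df$expression_flag <- as.integer(df$expression_flag)
  df
}

#' @rdname side_tables
#' @export
write_annotation_table <- function(df, path) write_tsv_table(df, path)

# ---------------------------------------------------------------------------
# Pathway graphs (purpose-built JSON dialect)

#' Construct a pathway graph
#'
#' A pathway graph is a directed graph of nodes (curated modules holding one
#' or several functionally similar genes) with designated phenotype sink
#' nodes. Gene sets may be empty only for phenotype nodes.
#'
#' @param pathway_id identifier string.
#' @param nodes data.frame with columns `node_id`, `label`, and a list
#'   column `gene_ids` (character vectors).
#' @param edges data.frame with columns `source`, `target` (node ids).
#' @param phenotype_nodes character vector of node ids.
#' @return object of class `pathway_graph`.
#' @export
pathway_graph <- function(pathway_id, nodes, edges, phenotype_nodes) {
  stopifnot(is.character(pathway_id), length(pathway_id) == 1L)
  if (anyDuplicated(nodes$node_id))
    stop("duplicate node_id: ",
         paste(unique(nodes$node_id[duplicated(nodes$node_id)]),
               collapse = ", "))
  unknown <- setdiff(c(edges$source, edges$target), nodes$node_id)
  if (length(unknown))
    stop("edge references unknown node(s): ",
         paste(unknown, collapse = ", "))
  missing_ph <- setdiff(phenotype_nodes, nodes$node_id)
  if (length(missing_ph))
    stop("phenotype node(s) not among nodes: ",
         paste(missing_ph, collapse = ", "))
  n_genes <- lengths(nodes$gene_ids)
  bad <- n_genes == 0L & !(nodes$node_id %in% phenotype_nodes)
  if (any(bad))
    stop("non-phenotype node(s) with empty gene set: ",
         paste(nodes$node_id[bad], collapse = ", "))
  structure(list(pathway_id = pathway_id,
                 nodes = nodes,
                 edges = edges,
                 phenotype_nodes = as.character(phenotype_nodes)),
            class = "pathway_graph")
}

#' @export
print.pathway_graph <- function(x, ...) {
  cat("pathway_graph '", x$pathway_id, "': ", nrow(x$nodes), " nodes, ",
      nrow(x$edges), " edges, ", length(x$phenotype_nodes),
      " phenotype node(s)\n", sep = "")
  invisible(x)
}

#' Read a pathway graph from JSON
#'
#' The JSON dialect is an object with fields `pathway_id`, `nodes` (array of
#' `{node_id, label, gene_ids}`), `edges` (array of `{source, target}`), and
#' `phenotype_nodes` (array of node ids). Validation matches
#' [pathway_graph()].
#'
#' @param path JSON file.
#' @return a `pathway_graph`.
#' @export
read_pathway_graph <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  obj <- jsonlite::fromJSON(path, simplifyDataFrame = FALSE)
  for (fld in c("pathway_id", "nodes", "edges", "phenotype_nodes"))
    if (is.null(obj[[fld]]) && fld != "phenotype_nodes")
      stop("pathway graph JSON missing field '", fld, "'")
  nodes <- data.frame(
    node_id = vapply(obj$nodes, `[[`, "", "node_id"),
    label = vapply(obj$nodes, function(n)
      if (is.null(n$label)) n$node_id else n$label, ""),
    stringsAsFactors = FALSE)
  nodes$gene_ids <- lapply(obj$nodes, function(n)
    as.character(unlist(n$gene_ids)))
  if (length(obj$edges)) {
    edges <- data.frame(
      source = vapply(obj$edges, `[[`, "", "source"),
      target = vapply(obj$edges, `[[`, "", "target"),
      stringsAsFactors = FALSE)
  } else {
    edges <- data.frame(source = character(), target = character(),
                        stringsAsFactors = FALSE)
  }
  pathway_graph(obj$pathway_id, nodes, edges,
                as.character(unlist(obj$phenotype_nodes)))
}

#' Write a pathway graph to JSON
#' @param graph a `pathway_graph`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_pathway_graph <- function(graph, path) {
  stopifnot(inherits(graph, "pathway_graph"))
  obj <- list(
    pathway_id = graph$pathway_id,
    nodes = lapply(seq_len(nrow(graph$nodes)), function(i)
      list(node_id = graph$nodes$node_id[i],
           label = graph$nodes$label[i],
           gene_ids = as.list(graph$nodes$gene_ids[[i]]))),
    edges = lapply(seq_len(nrow(graph$edges)), function(i)
      list(source = graph$edges$source[i],
           target = graph$edges$target[i])),
    phenotype_nodes = as.list(graph$phenotype_nodes))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}

# ---------------------------------------------------------------------------
# Aligned pairs (explicit gapped alignments)

#' Construct an aligned pair
#'
#' An explicit pairwise alignment: two equal-length gapped strings over the
#' amino-acid alphabet plus `-`, with 1-based start offsets of the aligned
#' region in each ungapped sequence. No column may be gapped on both sides.
#'
#' @param query_id,subject_id identifier strings.
#' @param query_aln,subject_aln equal-length gapped strings.
#' @param q_offset,s_offset 1-based start coordinates of the aligned region.
#' @return object of class `aligned_pair`.
#' @export
aligned_pair <- function(query_id, subject_id, query_aln, subject_aln,
                         q_offset = 1L, s_offset = 1L) {
  if (nchar(query_aln) != nchar(subject_aln))
    stop("aligned strings must have equal length")
  if (nchar(query_aln) == 0L) stop("empty alignment")
  qa <- strsplit(query_aln, "")[[1]]
  sa <- strsplit(subject_aln, "")[[1]]
  if (any(qa == "-" & sa == "-"))
    stop("column gapped on both sides at column ",
         which(qa == "-" & sa == "-")[1])
  structure(list(query_id = query_id, subject_id = subject_id,
                 query_aln = query_aln, subject_aln = subject_aln,
                 q_offset = as.integer(q_offset),
                 s_offset = as.integer(s_offset)),
            class = "aligned_pair")
}

#' @export
print.aligned_pair <- function(x, ...) {
  cat("aligned_pair ", x$query_id, " vs ", x$subject_id, " (",
      nchar(x$query_aln), " columns)\n", sep = "")
  invisible(x)
}

#' One-decimal percentage
#'
#' The summary formatter used throughout the reports: `k / n * 100`
#' rounded to two decimals and then to one (e.g. 15408 of 20835 prints as
#' 73.9). The two-stage rounding reproduces the reporting convention of
#' the comparative analyses this package follows: a percentage computed at
#' two decimals and displayed at one, under IEEE double rounding
#' (73.952 -> 73.95 -> 73.9, while 71.489 -> 71.49 -> 71.5; a single
#' round-to-one would print 74.0 for the former).
#'
#' @param k numerator count.
#' @param n denominator count.
#' @return numeric percentage at one decimal.
#' @export
percent_one_dp <- function(k, n) {
  stopifnot(n > 0)
  p2 <- round(k / n * 100, 2)
  # exact .X5 halves round down (73.95 -> 73.9), everything else to nearest
  floor(p2 * 10 + 0.5 - 1e-9) / 10
}
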