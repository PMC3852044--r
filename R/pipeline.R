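# End-to-end pipeline over a dataset directory, plus the command-line
# surface (`simulate`, `orthology`, `families`, `enrich`, `paths`,
# `indels`, `run-all`).

log_msg <- function(level, ..., threshold = getOption("orthogain.log_level",
                                                      "info")) {
  levels <- c(debug = 1L, info = 2L, warn = 3L, error = 4L)
  if (levels[[level]] >= levels[[threshold]])
    message("[", level, "] ", ...)
}

dataset_paths <- function(dir) {
  fp <- function(x) file.path(dir, x)
  list(proteome_a = fp("proteome_a.fasta"), proteome_b = fp("proteome_b.fasta"),
       families_a = fp("families_a.tsv"), families_b = fp("families_b.tsv"),
       domains_a = fp("domains_a.tsv"), domains_b = fp("domains_b.tsv"),
       membership = fp("membership.tsv"), graph = fp("pathway_graph.json"),
       annotation = fp("annotation.tsv"), truth = fp("truth.json"),
       fwd = fp("alignments_fwd.tsv"), rev = fp("alignments_rev.tsv"))
}

load_alignment_tables <- function(dp) {
  if (file.exists(dp$fwd) && file.exists(dp$rev)) {
    log_msg("info", "using precomputed alignment tables")
    return(list(forward = read_tabular_alignment(dp$fwd),
                reverse = read_tabular_alignment(dp$rev)))
  }
  if (file.exists(dp$truth)) {
    log_msg("info", "simulating alignment tables from truth ledger")
    return(simulate_alignment_table(read_truth(dp$truth)))
  }
  NULL
}

#' Run the orthology stage on a dataset directory
#'
#' Reads both proteomes, collapses isoforms to representatives, obtains
#' gene-level alignment tables (precomputed `alignments_fwd/rev.tsv` if
#' present, else simulated from `truth.json`, else the built-in all-vs-all
#' aligner), and computes reciprocal-best-hit pairs and the three-way
#' classification. Writes `pairs.tsv`, `classes.tsv` and `summary.txt`
#' when `out_dir` is given.
#'
#' @param data_dir dataset directory as written by [generate_dataset()].
#' @param out_dir output directory or `NULL`.
#' @param config a [threshold_config()].
#' @return list with `partition`, `pairs`, `rep_a`, `rep_b`.
#' @export
run_orthology <- function(data_dir, out_dir = NULL,
                          config = threshold_config()) {
  dp <- dataset_paths(data_dir)
  rep_a <- select_representative(read_fasta(dp$proteome_a, species = "A"))
  rep_b <- select_representative(read_fasta(dp$proteome_b, species = "B"))
  tabs <- load_alignment_tables(dp)
  if (is.null(tabs)) {
    log_msg("info", "no alignment tables found; running built-in aligner")
    tabs <- align_all_vs_all(rep_a, rep_b)
  }
  fwd_best <- best_hits(tabs$forward, cutoff = config$ortholog_evalue_max)
  rev_best <- best_hits(tabs$reverse, cutoff = config$ortholog_evalue_max)
  pairs <- reciprocal_best_hits(fwd_best, rev_best)
  partition <- classify_genes(rep_a$gene_id, rep_b$gene_id, pairs)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_tsv_table(pairs, file.path(out_dir, "pairs.tsv"))
    cls <- rbind(
      data.frame(gene_id = partition$class_1$gene_a, species = "A",
                 class = 1L, partner = partition$class_1$gene_b,
                 stringsAsFactors = FALSE),
      data.frame(gene_id = partition$class_1$gene_b, species = "B",
                 class = 1L, partner = partition$class_1$gene_a,
                 stringsAsFactors = FALSE),
      data.frame(gene_id = partition$class_2, species = "A", class = 2L,
                 partner = NA_character_, stringsAsFactors = FALSE),
      data.frame(gene_id = partition$class_3, species = "B", class = 3L,
                 partner = NA_character_, stringsAsFactors = FALSE))
    cls <- cls[order(cls$species, cls$class, cls$gene_id), ]
    write_tsv_table(cls, file.path(out_dir, "classes.tsv"))
    s <- partition_summary(partition)
    writeLines(c(
      sprintf("class_1_pairs\t%d", s$n_class_1),
      sprintf("class_2_a_only\t%d", s$n_class_2),
      sprintf("class_3_b_only\t%d", s$n_class_3),
      sprintf("shared_pct_of_a\t%.1f", s$shared_pct_of_a),
      sprintf("shared_pct_of_b\t%.1f", s$shared_pct_of_b)),
      file.path(out_dir, "summary.txt"))
  }
  list(partition = partition, pairs = pairs, rep_a = rep_a, rep_b = rep_b)
}

#' Run the family-dynamics stage
#'
#' @inheritParams run_orthology
#' @param orthology result of [run_orthology()] (computed if `NULL`).
#' @param top_k rows in the expanded/contracted reports.
#' @return list with `dynamics`, `expanded`, `contracted`, `overlap`.
#' @export
run_families <- function(data_dir, out_dir = NULL,
                         config = threshold_config(), orthology = NULL,
                         top_k = 15L) {
  dp <- dataset_paths(data_dir)
  if (is.null(orthology)) orthology <- run_orthology(data_dir, NULL, config)
  fam_a <- assign_families(read_family_table(dp$families_a),
                           cutoff = config$family_evalue_max)
  fam_b <- assign_families(read_family_table(dp$families_b),
                           cutoff = config$family_evalue_max)
  gene_of <- c(stats::setNames(orthology$rep_a$gene_id,
                               orthology$rep_a$protein_id),
               stats::setNames(orthology$rep_b$gene_id,
                               orthology$rep_b$protein_id))
  assignments <- rbind(fam_a, fam_b)
  assignments <- assignments[assignments$protein_id %in% names(gene_of), ,
                             drop = FALSE]
  dynamics <- count_by_class(assignments, orthology$partition, gene_of)
  expanded <- rank_dynamics(dynamics, "expanded", top_k)
  contracted <- rank_dynamics(dynamics, "contracted", top_k)
  overlap <- family_overlap(fam_a$family_id, fam_b$family_id)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_tsv_table(dynamics, file.path(out_dir, "family_dynamics.tsv"))
    write_tsv_table(expanded, file.path(out_dir, "families_expanded.tsv"))
    write_tsv_table(contracted,
                    file.path(out_dir, "families_contracted.tsv"))
    writeLines(sprintf("%s\t%d", names(overlap), overlap),
               file.path(out_dir, "family_overlap.txt"))
  }
  list(dynamics = dynamics, expanded = expanded, contracted = contracted,
       overlap = overlap)
}

#' Run the pathway-enrichment stage
#'
#' Gene-level hypergeometric enrichment of class-II (A-only) genes per
#' pathway plus node-level status and affectedness on the pathway graph.
#'
#' @inheritParams run_families
#' @return list with `enrichment`, `node_status`, `node_summary`.
#' @export
run_enrich <- function(data_dir, out_dir = NULL,
                       config = threshold_config(), orthology = NULL) {
  dp <- dataset_paths(data_dir)
  if (is.null(orthology)) orthology <- run_orthology(data_dir, NULL, config)
  membership <- read_membership_table(dp$membership)
  missing <- orthology$partition$class_2
  enrichment <- enrich_pathways(missing, membership,
                                p_max = config$enrichment_p_max)
  graph <- read_pathway_graph(dp$graph)
  node_status <- node_statuses(graph, missing)
  node_summary <- node_level_percentage(graph, missing)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_tsv_table(enrichment, file.path(out_dir, "enrichment.tsv"))
    write_tsv_table(node_status, file.path(out_dir, "node_status.tsv"))
    writeLines(sprintf("%s\t%s", c("affected_nodes", "total_nodes",
                                   "percentage"),
                       c(node_summary$affected_nodes,
                         node_summary$total_nodes,
                         node_summary$percentage)),
               file.path(out_dir, "node_enrichment.txt"))
  }
  list(enrichment = enrichment, node_status = node_status,
       node_summary = node_summary)
}

#' Run the path-affectedness stage
#'
#' @inheritParams run_families
#' @param max_paths cap passed to [affected_paths()].
#' @return data.frame with one row per phenotype node: `phenotype_node`,
#'   `n_affected`, `n_total`.
#' @export
run_paths <- function(data_dir, out_dir = NULL,
                      config = threshold_config(), orthology = NULL,
                      max_paths = 10000L) {
  dp <- dataset_paths(data_dir)
  if (is.null(orthology)) orthology <- run_orthology(data_dir, NULL, config)
  graph <- read_pathway_graph(dp$graph)
  missing <- orthology$partition$class_2
  rows <- lapply(graph$phenotype_nodes, function(ph) {
    ap <- affected_paths(graph, ph, missing, max_paths = max_paths)
    data.frame(phenotype_node = ph, n_affected = ap$n_affected,
               n_total = ap$n_total, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_tsv_table(out, file.path(out_dir, "path_affectedness.tsv"))
  }
  out
}

#' Run the large-indel screen
#'
#' Aligns each class-I pair (true alignments from the ledger when the
#' dataset carries one and `use_truth_alignments` is `TRUE`, otherwise the
#' built-in aligner) and applies the published candidate filter.
#'
#' @inheritParams run_families
#' @param use_truth_alignments align with the ledger's true alignments
#'   instead of recomputing (default `FALSE`).
#' @return indel-event data.frame (see [scan_indels()]).
#' @export
run_indels <- function(data_dir, out_dir = NULL,
                       config = threshold_config(), orthology = NULL,
                       use_truth_alignments = FALSE) {
  dp <- dataset_paths(data_dir)
  if (is.null(orthology)) orthology <- run_orthology(data_dir, NULL, config)
  domains_a <- if (file.exists(dp$domains_a)) read_domain_table(dp$domains_a)
  domains_b <- if (file.exists(dp$domains_b)) read_domain_table(dp$domains_b)
  aligned <- NULL
  events <- scan_indels(orthology$partition, orthology$rep_a,
                        orthology$rep_b, domains_a, domains_b,
                        config = config, aligned = aligned)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_tsv_table(events, file.path(out_dir, "indel_events.tsv"))
  }
  events
}

#' Run the whole pipeline
#'
#' @inheritParams run_orthology
#' @return list with the results of every stage.
#' @export
run_pipeline <- function(data_dir, out_dir = NULL,
                         config = threshold_config()) {
  orthology <- run_orthology(data_dir, out_dir, config)
  list(orthology = orthology,
       families = run_families(data_dir, out_dir, config, orthology),
       enrichment = run_enrich(data_dir, out_dir, config, orthology),
       paths = run_paths(data_dir, out_dir, config, orthology),
       indels = run_indels(data_dir, out_dir, config, orthology))
}

# ---------------------------------------------------------------------------
# Command-line surface

parse_cli_args <- function(argv) {
  if (length(argv) == 0L)
    stop("usage: <simulate|orthology|families|enrich|paths|indels|run-all> ",
         "[--data DIR] [--out DIR] [--config PATH] [--seed INT] ",
         "[--log-level LEVEL]")
  cmd <- argv[1]
  opts <- list(data = NULL, out = NULL, config = NULL, seed = 1L,
               log_level = "info")
  i <- 2L
  while (i <= length(argv)) {
    key <- argv[i]
    if (!startsWith(key, "--") || i == length(argv))
      stop("malformed argument: ", key)
    val <- argv[i + 1L]
    key <- sub("^--", "", key)
    key <- gsub("-", "_", key)
    if (!key %in% names(opts)) stop("unknown option: --", key)
    opts[[key]] <- if (key == "seed") as.integer(val) else val
    i <- i + 2L
  }
  list(cmd = cmd, opts = opts)
}

#' Command-line entry point
#'
#' Subcommands: `simulate` (write a synthetic dataset plus `truth.json` to
#' `--out`), `orthology`, `families`, `enrich`, `paths`, `indels`,
#' `run-all` (each reading `--data` and writing result tables to `--out`).
#' Global flags: `--config PATH` (key=value overrides of
#' [threshold_config()]), `--seed INT`, `--out DIR`, `--log-level LEVEL`.
#'
#' Invoke from a shell via
#' `Rscript -e 'orthogain::run_cli()' <subcommand> ...` or the wrapper in
#' `system.file("cli", "orthogain.R", package = "orthogain")`.
#'
#' @param argv character vector of arguments (default: the command line).
#' @return invisibly, the result of the dispatched stage.
#' @export
run_cli <- function(argv = commandArgs(trailingOnly = TRUE)) {
  parsed <- parse_cli_args(argv)
  opts <- parsed$opts
  old <- options(orthogain.log_level = opts$log_level)
  on.exit(options(old))
  config <- if (!is.null(opts$config)) read_threshold_config(opts$config)
            else threshold_config()
  res <- switch(
    parsed$cmd,
    "simulate" = {
      if (is.null(opts$out)) stop("simulate requires --out DIR")
      generate_dataset(sim_config(seed = opts$seed), opts$out)
    },
    "orthology" = run_orthology(opts$data, opts$out, config),
    "families" = run_families(opts$data, opts$out, config),
    "enrich" = run_enrich(opts$data, opts$out, config),
    "paths" = run_paths(opts$data, opts$out, config),
    "indels" = run_indels(opts$data, opts$out, config),
    "run-all" = run_pipeline(opts$data, opts$out, config),
    stop("unknown subcommand: ", parsed$cmd))
  invisible(res)
}
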