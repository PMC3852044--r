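# Synthetic paired-proteome generator with a ground-truth ledger: planted
# orthologs, lineage-specific genes, family expansions/contractions, >25-aa
# indels inside/outside domains, and a pathway graph with lost nodes.

AA20 <- setdiff(AA_LETTERS, "X")

# Named-substream scheme: one global integer seed plus a component name
# yields an independent, stable seed, so adding a new output never perturbs
# existing ones. Kept well below 2^31.
substream_seed <- function(seed, name) {
  h <- 0
  for (b in utf8ToInt(name)) h <- (h * 31 + b) %% 99991L
  (abs(as.integer(seed)) %% 21473L) * 99991L + h
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Simulation configuration
#'
#' The stated world for the synthetic two-proteome dataset. Defaults model
#' a desk-scale version of a rodent-vs-rodent comparison: 100 shared
#' ortholog pairs diverged by 5% per-residue substitutions, 30 A-only and
#' 20 B-only genes, 10 shared pairs carrying one planted contiguous indel
#' of 30-40 residues (half inside annotated domains), 20 protein families
#' with lineage-specific expansions/contractions, 6 pathways of 30 genes
#' with one 12-node pathway graph, and 20% of genes carrying 2-3 isoforms.
#'
#' @param n_shared_genes number of shared ortholog pairs.
#' @param n_a_only,n_b_only lineage-specific gene counts.
#' @param mean_protein_length mean representative length (lengths are drawn
#'   uniformly within +/-30%).
#' @param substitution_rate per-residue substitution probability applied to
#'   the B copy of each shared gene.
#' @param n_families number of protein families.
#' @param n_indel_pairs shared pairs carrying one planted indel each.
#' @param indel_length_range integer range of planted indel lengths; the
#'   minimum must exceed 25 so planted events are recoverable under the
#'   published filter.
#' @param fraction_indels_in_domains probability that a planted indel falls
#'   inside an annotated domain.
#' @param n_pathways,genes_per_pathway pathway membership shape.
#' @param nodes_per_graph,n_phenotype_nodes pathway-graph shape (graph is
#'   built for the first pathway).
#' @param isoform_fraction fraction of genes with 2-3 isoforms (extra
#'   isoforms are truncations with weaker protein-existence ranks).
#' @param seed global integer seed driving named substreams per component.
#' @return object of class `sim_config`.
#' @export
sim_config <- function(n_shared_genes = 100L, n_a_only = 30L,
                       n_b_only = 20L, mean_protein_length = 300L,
                       substitution_rate = 0.05, n_families = 20L,
                       n_indel_pairs = 10L, indel_length_range = c(30L, 40L),
                       fraction_indels_in_domains = 0.5,
                       n_pathways = 6L, genes_per_pathway = 30L,
                       nodes_per_graph = 12L, n_phenotype_nodes = 1L,
                       isoform_fraction = 0.2, seed = 1L) {
  stopifnot(n_shared_genes >= 0, n_a_only >= 0, n_b_only >= 0,
            mean_protein_length >= 50,
            substitution_rate >= 0, substitution_rate <= 1,
            fraction_indels_in_domains >= 0,
            fraction_indels_in_domains <= 1,
            isoform_fraction >= 0, isoform_fraction <= 1)
  if (n_indel_pairs > n_shared_genes)
    stop("n_indel_pairs (", n_indel_pairs,
         ") exceeds n_shared_genes (", n_shared_genes, ")")
  if (min(indel_length_range) <= 25)
    stop("indel_length_range minimum must exceed 25 (published filter)")
  structure(list(n_shared_genes = as.integer(n_shared_genes),
                 n_a_only = as.integer(n_a_only),
                 n_b_only = as.integer(n_b_only),
                 mean_protein_length = as.integer(mean_protein_length),
                 substitution_rate = substitution_rate,
                 n_families = as.integer(n_families),
                 n_indel_pairs = as.integer(n_indel_pairs),
                 indel_length_range = as.integer(indel_length_range),
                 fraction_indels_in_domains = fraction_indels_in_domains,
                 n_pathways = as.integer(n_pathways),
                 genes_per_pathway = as.integer(genes_per_pathway),
                 nodes_per_graph = as.integer(nodes_per_graph),
                 n_phenotype_nodes = as.integer(n_phenotype_nodes),
                 isoform_fraction = isoform_fraction,
                 seed = as.integer(seed)),
            class = "sim_config")
}

random_protein <- function(len) paste(sample(AA20, len, replace = TRUE),
                                      collapse = "")

# size-safe sampling: never falls into sample()'s scalar-as-range reading
resample <- function(x, size) x[sample.int(length(x), size)]

mutate_protein <- function(seq, rate) {
  if (rate <= 0) return(list(seq = seq, n_subs = 0L, positions = integer()))
  chars <- strsplit(seq, "")[[1]]
  hit <- which(stats::runif(length(chars)) < rate)
  for (i in hit)
    chars[i] <- sample(setdiff(AA20, chars[i]), 1L)
  list(seq = paste(chars, collapse = ""), n_subs = length(hit),
       positions = hit)
}

# Build the in-memory world: sequences, true alignments, indels, families,
# domains, pathways, isoforms.
build_world <- function(config) {
  cfg <- config
  pad <- function(i, p) sprintf("%s%03d", p, i)
  shared_a <- vapply(seq_len(cfg$n_shared_genes), pad, "", p = "As")
  shared_b <- vapply(seq_len(cfg$n_shared_genes), pad, "", p = "Bs")
  a_only <- vapply(seq_len(cfg$n_a_only), pad, "", p = "Au")
  b_only <- vapply(seq_len(cfg$n_b_only), pad, "", p = "Bu")

  # --- sequences + planted indels ---------------------------------------
  world <- with_seed(substream_seed(cfg$seed, "sequences"), {
    lens <- pmax(130L, as.integer(round(stats::runif(
      cfg$n_shared_genes, 0.7, 1.3) * cfg$mean_protein_length)))
    seq_a <- vapply(lens, random_protein, "")
    mut <- lapply(seq_a, mutate_protein, rate = cfg$substitution_rate)
    seq_b <- vapply(mut, `[[`, "", "seq")
    n_subs <- vapply(mut, `[[`, 0L, "n_subs")
    idx_indel <- if (cfg$n_indel_pairs > 0)
      sort(sample(cfg$n_shared_genes, cfg$n_indel_pairs)) else integer()
    indels <- list()
    alns <- vector("list", cfg$n_shared_genes)
    for (i in seq_len(cfg$n_shared_genes)) {
      la <- nchar(seq_a[i])
      if (i %in% idx_indel) {
        len <- resample(seq(cfg$indel_length_range[1],
                            cfg$indel_length_range[2]), 1L)
        polarity <- if (length(indels) %% 2L == 0L) "deletion_in_b"
                    else "insertion_in_b"
        start <- resample(seq(41L, la - 40L - len), 1L)
        if (polarity == "deletion_in_b") {
          # remove segment start..start+len-1 (A coordinates) from B
          sb <- seq_b[i]
          seq_b[i] <- paste0(substr(sb, 1L, start - 1L),
                             substr(sb, start + len, la))
          qa <- seq_a[i]
          sa <- paste0(substr(seq_b[i], 1L, start - 1L),
                       strrep("-", len),
                       substr(seq_b[i], start, nchar(seq_b[i])))
          coord_start <- start
        } else {
          # insert a fresh segment into B at position start
          segment <- random_protein(len)
          sb <- seq_b[i]
          seq_b[i] <- paste0(substr(sb, 1L, start - 1L), segment,
                             substr(sb, start, la))
          qa <- paste0(substr(seq_a[i], 1L, start - 1L),
                       strrep("-", len),
                       substr(seq_a[i], start, la))
          sa <- seq_b[i]
          coord_start <- start  # B coordinates: segment occupies start..
        }
        alns[[i]] <- aligned_pair(shared_a[i], shared_b[i], qa, sa)
        indels[[length(indels) + 1L]] <- data.frame(
          gene_a = shared_a[i], gene_b = shared_b[i], polarity = polarity,
          start = coord_start, end = coord_start + len - 1L, length = len,
          mismatch_pct = n_subs[i] / nchar(alns[[i]]$query_aln) * 100,
          stringsAsFactors = FALSE)
      } else {
        alns[[i]] <- aligned_pair(shared_a[i], shared_b[i],
                                  seq_a[i], seq_b[i])
      }
    }
    lens_a_only <- pmax(130L, as.integer(round(stats::runif(
      cfg$n_a_only, 0.7, 1.3) * cfg$mean_protein_length)))
    lens_b_only <- pmax(130L, as.integer(round(stats::runif(
      cfg$n_b_only, 0.7, 1.3) * cfg$mean_protein_length)))
    list(seq_a = seq_a, seq_b = seq_b, n_subs = n_subs, alns = alns,
         indels = if (length(indels)) do.call(rbind, indels)
                  else data.frame(),
         seq_a_only = vapply(lens_a_only, random_protein, ""),
         seq_b_only = vapply(lens_b_only, random_protein, ""))
  })
  names(world$seq_a) <- shared_a
  names(world$seq_b) <- shared_b
  names(world$alns) <- shared_a
  names(world$seq_a_only) <- a_only
  names(world$seq_b_only) <- b_only

  # --- families ----------------------------------------------------------
  fams <- with_seed(substream_seed(cfg$seed, "families"), {
    fam_ids <- sprintf("FAM%03d", seq_len(cfg$n_families))
    rows <- list()
    shared_pool <- seq_len(cfg$n_shared_genes)
    a_pool <- seq_len(cfg$n_a_only)
    b_pool <- seq_len(cfg$n_b_only)
    for (f in seq_len(cfg$n_families)) {
      n_sh <- min(length(shared_pool), sample(0:2, 1L))
      sh <- if (n_sh > 0) resample(shared_pool, n_sh) else integer()
      shared_pool <- setdiff(shared_pool, sh)
      # expansion/contraction: rotate among B-expanded, A-expanded, flat
      a_extra <- b_extra <- 0L
      if (f %% 3L == 1L) b_extra <- min(length(b_pool), sample(1:3, 1L))
      if (f %% 3L == 2L) a_extra <- min(length(a_pool), sample(1:3, 1L))
      ae <- if (a_extra > 0) resample(a_pool, a_extra) else integer()
      be <- if (b_extra > 0) resample(b_pool, b_extra) else integer()
      a_pool <- setdiff(a_pool, ae); b_pool <- setdiff(b_pool, be)
      add <- function(gene, species)
        rows[[length(rows) + 1L]] <<- data.frame(
          gene_id = gene, species = species, family_id = fam_ids[f],
          stringsAsFactors = FALSE)
      for (i in sh) { add(shared_a[i], "A"); add(shared_b[i], "B") }
      for (i in ae) add(a_only[i], "A")
      for (i in be) add(b_only[i], "B")
    }
    if (length(rows)) do.call(rbind, rows) else
      data.frame(gene_id = character(), species = character(),
                 family_id = character(), stringsAsFactors = FALSE)
  })

  # --- domains ------------------------------------------------------------
  seqlen_of <- c(nchar(world$seq_a), nchar(world$seq_b),
                 nchar(world$seq_a_only), nchar(world$seq_b_only))
  domains <- with_seed(substream_seed(cfg$seed, "domains"), {
    rows <- list()
    dom_counter <- 0L
    add_domain <- function(gene, start, end, in_indel = FALSE) {
      dom_counter <<- dom_counter + 1L
      rows[[length(rows) + 1L]] <<- data.frame(
        gene_id = gene, domain_id = sprintf("DOM%04d", dom_counter),
        start = as.integer(start), end = as.integer(end),
        stringsAsFactors = FALSE)
    }
    in_dom <- logical(0)
    if (nrow(world$indels)) {
      in_dom <- stats::runif(nrow(world$indels)) <
        cfg$fraction_indels_in_domains
      for (k in seq_len(nrow(world$indels))) {
        ev <- world$indels[k, ]
        carrier <- if (ev$polarity == "deletion_in_b") ev$gene_a else
          ev$gene_b
        carrier_len <- seqlen_of[[carrier]]
        if (in_dom[k]) {
          # domain straddling the planted segment
          start <- max(1L, ev$start - 10L)
          end <- min(carrier_len, ev$end + 10L)
          add_domain(carrier, start, end)
        } else if (ev$start > 45L) {
          # domain well before the segment (no overlap)
          add_domain(carrier, 5L, min(35L, ev$start - 2L))
        }
      }
    }
    # background domains on a third of the remaining genes, placed in the
    # first 100 residues (planted segments start at >= 41 but indel
    # carriers are excluded so overlap bookkeeping stays exact)
    carriers <- if (nrow(world$indels))
      ifelse(world$indels$polarity == "deletion_in_b",
             world$indels$gene_a, world$indels$gene_b) else character()
    others <- setdiff(names(seqlen_of), carriers)
    for (g in sample(others, ceiling(length(others) / 3))) {
      start <- sample(1:20, 1L)
      add_domain(g, start, min(seqlen_of[[g]], start + sample(29:79, 1L)))
    }
    list(table = do.call(rbind, rows), in_dom = in_dom)
  })
  if (nrow(world$indels)) world$indels$in_domain <- domains$in_dom

  # --- pathways (membership over species A; missing genes are A-only) ----
  pathways <- with_seed(substream_seed(cfg$seed, "pathways"), {
    universe_a <- c(shared_a, a_only)
    memb_rows <- list()
    pw_ids <- sprintf("pw%02d", seq_len(cfg$n_pathways))
    for (p in seq_along(pw_ids)) {
      n_g <- min(cfg$genes_per_pathway, length(universe_a))
      genes <- sample(universe_a, n_g)
      memb_rows[[p]] <- data.frame(gene_id = genes, pathway_id = pw_ids[p],
                                   stringsAsFactors = FALSE)
    }
    memb <- do.call(rbind, memb_rows)
    # graph for the first pathway: random DAG into phenotype sinks
    g1 <- memb$gene_id[memb$pathway_id == pw_ids[1]]
    n_nodes <- cfg$nodes_per_graph
    node_ids <- sprintf("n%02d", seq_len(n_nodes + cfg$n_phenotype_nodes))
    ph_nodes <- utils::tail(node_ids, cfg$n_phenotype_nodes)
    gene_sets <- vector("list", length(node_ids))
    pool <- g1
    for (i in seq_len(n_nodes)) {
      k <- min(length(pool), sample(1:3, 1L))
      if (k == 0L) { gene_sets[[i]] <- sample(g1, 1L) } else {
        gene_sets[[i]] <- sample(pool, k)
        pool <- setdiff(pool, gene_sets[[i]])
      }
    }
    for (i in seq_along(ph_nodes)) gene_sets[[n_nodes + i]] <- character()
    edges <- list()
    for (i in seq_len(n_nodes)) {
      for (j in seq_len(n_nodes)) {
        if (j <= i) next
        if (stats::runif(1) < 0.3)
          edges[[length(edges) + 1L]] <- c(node_ids[i], node_ids[j])
      }
    }
    em <- if (length(edges)) do.call(rbind, edges) else
      matrix(character(), ncol = 2)
    # every non-phenotype sink feeds a phenotype node
    sinks <- setdiff(node_ids[seq_len(n_nodes)], em[, 1])
    for (s in sinks)
      em <- rbind(em, c(s, sample(ph_nodes, 1L)))
    nodes <- data.frame(node_id = node_ids,
                        label = paste0("module_", node_ids),
                        stringsAsFactors = FALSE)
    nodes$gene_ids <- gene_sets
    graph <- pathway_graph(pw_ids[1], nodes,
                           data.frame(source = em[, 1], target = em[, 2],
                                      stringsAsFactors = FALSE),
                           ph_nodes)
    list(membership = memb[order(memb$pathway_id, memb$gene_id), ],
         graph = graph)
  })

  # --- annotation of A-only genes ----------------------------------------
  annotation <- with_seed(substream_seed(cfg$seed, "annotation"), {
    data.frame(gene_id = a_only,
               phenotype_flag = as.integer(stats::runif(cfg$n_a_only) < 0.5),
               expression_flag = as.integer(stats::runif(cfg$n_a_only) < 0.6),
               stringsAsFactors = FALSE)
  })

  # --- isoforms & protein records ----------------------------------------
  records <- with_seed(substream_seed(cfg$seed, "isoforms"), {
    make_records <- function(seqs, species) {
      rows <- list()
      for (g in names(seqs)) {
        sq <- seqs[[g]]
        n_iso <- if (stats::runif(1) < cfg$isoform_fraction)
          sample(2:3, 1L) else 1L
        rows[[length(rows) + 1L]] <- data.frame(
          protein_id = paste0(g, ".p1"), gene_id = g, species = species,
          sequence = sq, pe_rank = 1L, stringsAsFactors = FALSE)
        if (n_iso > 1L) {
          for (k in 2:n_iso) {
            frac <- stats::runif(1, 0.6, 0.9)
            rows[[length(rows) + 1L]] <- data.frame(
              protein_id = paste0(g, ".p", k), gene_id = g,
              species = species,
              sequence = substr(sq, 1L, max(30L, floor(nchar(sq) * frac))),
              pe_rank = sample(2:5, 1L), stringsAsFactors = FALSE)
          }
        }
      }
      do.call(rbind, rows)
    }
    list(a = make_records(c(world$seq_a, world$seq_a_only), "A"),
         b = make_records(c(world$seq_b, world$seq_b_only), "B"))
  })

  list(config = cfg,
       shared_a = shared_a, shared_b = shared_b,
       a_only = a_only, b_only = b_only,
       world = world, families = fams, domains = domains$table,
       pathways = pathways, annotation = annotation, records = records)
}

truth_from_world <- function(w) {
  cfg <- w$config
  gene_of <- function(rec) stats::setNames(rec$gene_id, rec$protein_id)
  rep_id <- function(genes) stats::setNames(paste0(genes, ".p1"), genes)
  fam <- w$families
  fam$protein_id <- paste0(fam$gene_id, ".p1")
  indels <- w$world$indels
  graph <- w$pathways$graph
  missing <- w$a_only
  node_missing <- lapply(seq_len(nrow(graph$nodes)), function(i)
    intersect(graph$nodes$gene_ids[[i]], missing))
  names(node_missing) <- graph$nodes$node_id
  structure(list(
    ortholog_pairs = data.frame(gene_a = w$shared_a, gene_b = w$shared_b,
                                stringsAsFactors = FALSE),
    class_2 = w$a_only, class_3 = w$b_only,
    genes_a = c(w$shared_a, w$a_only),
    genes_b = c(w$shared_b, w$b_only),
    representative_a = rep_id(c(w$shared_a, w$a_only)),
    representative_b = rep_id(c(w$shared_b, w$b_only)),
    families = fam[, c("protein_id", "gene_id", "species", "family_id")],
    shared_families = sort(unique(
      intersect(fam$family_id[fam$species == "A"],
                fam$family_id[fam$species == "B"]))),
    indels = indels,
    pair_stats = data.frame(
      gene_a = w$shared_a, gene_b = w$shared_b,
      n_subs = w$world$n_subs,
      aln_length = vapply(w$world$alns, function(p)
        nchar(p$query_aln), 0L),
      stringsAsFactors = FALSE),
    node_missing = node_missing,
    missing_genes = missing,
    seed = cfg$seed), class = "truth_ledger")
}

#' Generate a synthetic dataset
#'
#' Emits a self-contained dataset directory (two proteome FASTAs, family
#' tables, domain tables, pathway membership + graph, annotation table,
#' `truth.json`) and returns the ground-truth ledger. Identical
#' configurations yield byte-identical outputs; each component draws from a
#' named substream of the global seed.
#'
#' @param config a [sim_config()].
#' @param out_dir output directory (created if needed); `NULL` keeps
#'   everything in memory.
#' @return invisibly, a list with `truth` (class `truth_ledger`), `world`
#'   (in-memory records, sequences and true alignments), and `files`
#'   (named paths, when `out_dir` is given).
#' @export
generate_dataset <- function(config = sim_config(), out_dir = NULL) {
  stopifnot(inherits(config, "sim_config"))
  w <- build_world(config)
  truth <- truth_from_world(w)
  files <- NULL
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    fp <- function(x) file.path(out_dir, x)
    files <- c(proteome_a = fp("proteome_a.fasta"),
               proteome_b = fp("proteome_b.fasta"),
               families_a = fp("families_a.tsv"),
               families_b = fp("families_b.tsv"),
               domains_a = fp("domains_a.tsv"),
               domains_b = fp("domains_b.tsv"),
               membership = fp("membership.tsv"),
               graph = fp("pathway_graph.json"),
               annotation = fp("annotation.tsv"),
               truth = fp("truth.json"))
    write_fasta(w$records$a, files[["proteome_a"]])
    write_fasta(w$records$b, files[["proteome_b"]])
    fam_tables <- family_candidate_tables(w)
    write_family_table(fam_tables$a, files[["families_a"]])
    write_family_table(fam_tables$b, files[["families_b"]])
    dom <- w$domains
    dom$protein_id <- paste0(dom$gene_id, ".p1")
    dom <- dom[, c("protein_id", "domain_id", "start", "end")]
    is_a <- startsWith(dom$protein_id, "A")
    write_domain_table(dom[is_a, ], files[["domains_a"]])
    write_domain_table(dom[!is_a, ], files[["domains_b"]])
    write_membership_table(w$pathways$membership, files[["membership"]])
    write_pathway_graph(w$pathways$graph, files[["graph"]])
    write_annotation_table(w$annotation, files[["annotation"]])
    write_truth(truth, files[["truth"]])
  }
  invisible(list(truth = truth, world = w, files = files))
}

# Family candidate tables with planted decoys: the true family always has
# the smallest E-value; ~20% of assigned proteins carry a decoy candidate
# (half above the 1e-5 cutoff, half below but worse than the true hit).
family_candidate_tables <- function(w) {
  fam <- w$families
  fam$protein_id <- paste0(fam$gene_id, ".p1")
  all_fams <- sort(unique(fam$family_id))
  with_seed(substream_seed(w$config$seed, "family_tables"), {
    make <- function(species) {
      sub <- fam[fam$species == species, , drop = FALSE]
      if (nrow(sub) == 0L)
        return(data.frame(protein_id = character(), family_id = character(),
                          e_value = numeric(), bit_score = numeric(),
                          stringsAsFactors = FALSE))
      rows <- data.frame(protein_id = sub$protein_id,
                         family_id = sub$family_id,
                         e_value = 10^-stats::runif(nrow(sub), 10, 40),
                         bit_score = round(stats::runif(nrow(sub), 80, 400),
                                           1),
                         stringsAsFactors = FALSE)
      decoy_idx <- which(stats::runif(nrow(sub)) < 0.2)
      if (length(decoy_idx) && length(all_fams) > 1L) {
        decoys <- do.call(rbind, lapply(decoy_idx, function(i) {
          above <- stats::runif(1) < 0.5
          data.frame(protein_id = sub$protein_id[i],
                     family_id = sample(setdiff(all_fams,
                                                sub$family_id[i]), 1L),
                     e_value = if (above) 10^-stats::runif(1, 0, 4.5)
                               else 10^-stats::runif(1, 5.5, 9),
                     bit_score = round(stats::runif(1, 20, 70), 1),
                     stringsAsFactors = FALSE)
        }))
        rows <- rbind(rows, decoys)
      }
      rows[order(rows$protein_id, rows$e_value), ]
    }
    list(a = make("A"), b = make("B"))
  })
}

write_truth <- function(truth, path) {
  obj <- unclass(truth)
  obj$node_missing <- lapply(obj$node_missing, as.list)
  obj$representative_a <- as.list(obj$representative_a)
  obj$representative_b <- as.list(obj$representative_b)
  jsonlite::write_json(obj, path, auto_unbox = FALSE, pretty = TRUE,
                       digits = NA, dataframe = "columns")
  invisible(path)
}

#' Read a ground-truth ledger back from truth.json
#' @param path JSON file written by [generate_dataset()].
#' @return a `truth_ledger`.
#' @export
read_truth <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
  obj$node_missing <- lapply(obj$node_missing, function(x)
    as.character(unlist(x)))
  obj$representative_a <- unlist(obj$representative_a)
  obj$representative_b <- unlist(obj$representative_b)
  for (fld in c("ortholog_pairs", "families", "indels", "pair_stats"))
    obj[[fld]] <- as.data.frame(obj[[fld]], stringsAsFactors = FALSE)
  structure(obj, class = "truth_ledger")
}

#' Alignment-noise specification for [simulate_alignment_table()]
#'
#' @param n_spurious number of spurious cross-hits (non-ortholog pairs)
#'   added to each direction with E-values in `spurious_evalue_range`.
#' @param spurious_evalue_range E-value range of spurious hits (default
#'   above the 1e-6 orthology cutoff, so they are screened out).
#' @param asymmetric_fraction fraction of true pairs whose forward best hit
#'   is redirected to a decoy subject, breaking reciprocity for that pair
#'   only.
#' @return list of class `noise_spec`.
#' @export
noise_spec <- function(n_spurious = 0L,
                       spurious_evalue_range = c(1e-3, 1e-1),
                       asymmetric_fraction = 0) {
  stopifnot(n_spurious >= 0, asymmetric_fraction >= 0,
            asymmetric_fraction <= 1)
  structure(list(n_spurious = as.integer(n_spurious),
                 spurious_evalue_range = spurious_evalue_range,
                 asymmetric_fraction = asymmetric_fraction),
            class = "noise_spec")
}

#' Simulate forward and reverse alignment tables
#'
#' Emits 12-column hit tables (gene-level, representative proteins) in
#' which every true ortholog pair is the mutual best hit. E-values are a
#' documented monotone function of identity and alignment length (a pseudo
#' bit score `2 * identity_fraction * length`, E = `len^2 * 2^-bits`,
#' floored at 1e-180): they order hits correctly but are not
#' Karlin-Altschul statistics. Noise adds spurious weak cross-hits and/or
#' redirects the forward best hit of a fraction of pairs to a decoy.
#'
#' @param truth a `truth_ledger` from [generate_dataset()].
#' @param noise a [noise_spec()].
#' @return list with `forward` (A as query) and `reverse` (B as query)
#'   alignment tables keyed by gene id.
#' @export
simulate_alignment_table <- function(truth, noise = noise_spec()) {
  stopifnot(inherits(truth, "truth_ledger"))
  ps <- truth$pair_stats
  n <- nrow(ps)
  ident <- (ps$aln_length - ps$n_subs -
              (ps$aln_length - nchar_ungapped(truth, ps))) / ps$aln_length
  # identity fraction = identical columns / alignment length
  bits <- round(2 * ident * ps$aln_length, 1)
  evalue <- pmax(1e-180, ps$aln_length^2 * 2^(-bits))
  gap_cols <- ps$aln_length - nchar_ungapped(truth, ps)
  fwd <- data.frame(query_id = ps$gene_a, subject_id = ps$gene_b,
                    pct_identity = round(ident * 100, 2),
                    aln_length = ps$aln_length,
                    mismatches = ps$n_subs,
                    gap_opens = as.integer(gap_cols > 0L),
                    q_start = 1L, q_end = ps$aln_length,
                    s_start = 1L, s_end = ps$aln_length,
                    e_value = evalue, bit_score = bits,
                    stringsAsFactors = FALSE)
  rev <- fwd
  rev$query_id <- fwd$subject_id
  rev$subject_id <- fwd$query_id
  with_seed(substream_seed(truth$seed, "alignment_noise"), {
    if (noise$n_spurious > 0L && n > 1L) {
      mk_spurious <- function(queries, subjects, partner) {
        qi <- sample(queries, noise$n_spurious, replace = TRUE)
        si <- vapply(qi, function(q)
          sample(setdiff(subjects, partner[[q]]), 1L), "")
        data.frame(query_id = qi, subject_id = si,
                   pct_identity = round(stats::runif(noise$n_spurious,
                                                     20, 35), 2),
                   aln_length = 50L, mismatches = 30L, gap_opens = 2L,
                   q_start = 1L, q_end = 50L, s_start = 1L, s_end = 50L,
                   e_value = stats::runif(noise$n_spurious,
                                          noise$spurious_evalue_range[1],
                                          noise$spurious_evalue_range[2]),
                   bit_score = round(stats::runif(noise$n_spurious,
                                                  25, 40), 1),
                   stringsAsFactors = FALSE)
      }
      pa <- stats::setNames(as.list(ps$gene_b), ps$gene_a)
      pb <- stats::setNames(as.list(ps$gene_a), ps$gene_b)
      fwd <- rbind(fwd, mk_spurious(truth$genes_a, truth$genes_b, pa))
      rev <- rbind(rev, mk_spurious(truth$genes_b, truth$genes_a, pb))
    }
    broken <- character()
    if (noise$asymmetric_fraction > 0 && n > 1L) {
      n_break <- max(1L, round(noise$asymmetric_fraction * n))
      idx <- sample(n, n_break)
      broken <- ps$gene_a[idx]
      decoy_rows <- do.call(rbind, lapply(idx, function(i) {
        decoy <- sample(setdiff(ps$gene_b, ps$gene_b[i]), 1L)
        row <- fwd[i, ]
        row$subject_id <- decoy
        row$bit_score <- row$bit_score + 10
        row$e_value <- pmax(1e-180, row$e_value / 10)
        row
      }))
      fwd <- rbind(fwd, decoy_rows)
    }
    attr(fwd, "broken_pairs") <- broken
    list(forward = fwd, reverse = rev)
  })
}

nchar_ungapped <- function(truth, ps) {
  # identical-plus-mismatch columns per true alignment = min(len_a, len_b)
  # reconstructed from the ledger: aln_length - planted gap columns
  gaps <- integer(nrow(ps))
  if (!is.null(truth$indels) && nrow(truth$indels)) {
    m <- match(ps$gene_a, truth$indels$gene_a)
    gaps[!is.na(m)] <- truth$indels$length[m[!is.na(m)]]
  }
  ps$aln_length - gaps
}
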