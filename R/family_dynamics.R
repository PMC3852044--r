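# Protein-family assignment and expansion/contraction scoring between the
# two species' orthology classes.

#' Assign each protein to its single best family
#'
#' Candidates with `e_value > cutoff` are dropped (the cutoff itself is
#' kept); per protein the candidate with the smallest E-value wins, ties
#' broken by the highest bit score, then by lexicographic family id.
#' Proteins with no surviving candidate receive no assignment.
#'
#' @param candidates data.frame with columns `protein_id`, `family_id`,
#'   `e_value`, `bit_score` (several rows per protein allowed).
#' @param cutoff inclusive E-value ceiling (default 1e-5).
#' @return data.frame with one row per assigned protein.
#' @export
assign_families <- function(candidates, cutoff = 1e-5) {
  stopifnot(all(c("protein_id", "family_id", "e_value") %in%
                  names(candidates)))
  if (any(candidates$e_value < 0)) stop("negative e_value in candidates")
  if (!"bit_score" %in% names(candidates)) candidates$bit_score <- 0
  cand <- candidates[candidates$e_value <= cutoff, , drop = FALSE]
  if (nrow(cand) == 0L) {
    out <- cand
    rownames(out) <- NULL
    return(out)
  }
  ord <- order(cand$protein_id, cand$e_value, -cand$bit_score,
               cand$family_id)
  sorted <- cand[ord, , drop = FALSE]
  out <- sorted[!duplicated(sorted$protein_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Per-family gene counts by orthology class
#'
#' For each family, counts member genes falling in class I (shared), class
#' II (A-only) and class III (B-only), and the net change
#' `delta = class_3_count - class_2_count` (positive = expanded in species
#' B, negative = contracted). Counting is by gene after isoform collapsing;
#' a gene contributes to at most one family. Class-I membership is counted
#' on the species given by `class1_species` (default `"b"`), since a shared
#' pair appears once in published family tables.
#'
#' @param assignments family assignments ([assign_families()]) covering
#'   proteins of both species.
#' @param partition a `class_partition`.
#' @param gene_of named character vector mapping `protein_id` to `gene_id`.
#' @param class1_species `"b"` or `"a"`: which species' member of a shared
#'   pair is counted for the class-I column.
#' @return data.frame with columns `family_id`, `class_1_count`,
#'   `class_2_count`, `class_3_count`, `delta`, sorted by `family_id`.
#' @export
count_by_class <- function(assignments, partition, gene_of,
                           class1_species = c("b", "a")) {
  class1_species <- match.arg(class1_species)
  stopifnot(inherits(partition, "class_partition"))
  genes <- gene_of[assignments$protein_id]
  if (anyNA(genes))
    stop("protein(s) with unknown gene: ",
         paste(assignments$protein_id[is.na(genes)], collapse = ", "))
  class1_genes <- if (class1_species == "b") partition$class_1$gene_b
                  else partition$class_1$gene_a
  cls <- ifelse(genes %in% class1_genes, 1L,
         ifelse(genes %in% partition$class_2, 2L,
         ifelse(genes %in% partition$class_3, 3L, NA_integer_)))
  keep <- !is.na(cls)
  fam <- assignments$family_id[keep]
  cls <- cls[keep]
  gen <- genes[keep]
  # a gene contributes once per family
  dedup <- !duplicated(paste(fam, gen, sep = "\r"))
  fam <- fam[dedup]; cls <- cls[dedup]
  families <- sort(unique(fam))
  tab <- table(factor(fam, levels = families), factor(cls, levels = 1:3))
  out <- data.frame(family_id = families,
                    class_1_count = as.integer(tab[, 1]),
                    class_2_count = as.integer(tab[, 2]),
                    class_3_count = as.integer(tab[, 3]),
                    stringsAsFactors = FALSE)
  out$delta <- out$class_3_count - out$class_2_count
  rownames(out) <- NULL
  out
}

#' Rank families by expansion or contraction
#'
#' `"expanded"` sorts by `delta` descending (largest net gain in species B
#' first); `"contracted"` by `-delta` descending. Ties are broken by family
#' id; the result is truncated to `top_k` rows.
#'
#' @param rows output of [count_by_class()].
#' @param direction `"expanded"` or `"contracted"`.
#' @param top_k number of rows to keep (default 15).
#' @return reordered, truncated data.frame.
#' @export
rank_dynamics <- function(rows, direction = c("expanded", "contracted"),
                          top_k = 15L) {
  direction <- match.arg(direction)
  key <- if (direction == "expanded") -rows$delta else rows$delta
  ord <- order(key, rows$family_id)
  out <- rows[ord, , drop = FALSE]
  out <- utils::head(out, top_k)
  rownames(out) <- NULL
  out
}

#' Family-universe overlap between two species
#'
#' @param families_a,families_b character vectors of family ids present in
#'   each species.
#' @return named numeric vector `c(n_a, n_b, n_overlap)`.
#' @export
family_overlap <- function(families_a, families_b) {
  a <- unique(families_a); b <- unique(families_b)
  c(n_a = length(a), n_b = length(b),
    n_overlap = length(intersect(a, b)))
}
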