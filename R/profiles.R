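#' Gene-family relative-abundance matrix
#'
#' Converts a per-gene annotation table into a families x genomes matrix of
#' percent abundance: 100 * (genes of genome g annotated to family f) /
#' total_genes(g). Families absent from a genome are 0; column sums reach 100
#' exactly when the annotation table covers every gene of every genome.
#'
#' @param annotations `data.frame` with columns `genome_id`, `gene_id`,
#'   `family_id`.
#' @param genomes Genome table with `genome_id` and `total_genes` (> 0).
#' @param families Optional family universe defining the row set (useful when
#'   the annotation table is empty or a subset); default: families observed.
#' @return Numeric matrix, rows = families, columns = genomes, values in
#'   percent of total genes.
#' @export
family_abundance <- function(annotations, genomes, families = NULL) {
  check_columns(genomes, c("genome_id", "total_genes"), "genomes")
  check_columns(annotations, c("genome_id", "family_id"), "annotations")
  if (any(genomes$total_genes <= 0))
    stop_input("genome(s) with total_genes = 0: ",
               paste(genomes$genome_id[genomes$total_genes <= 0], collapse = ", "))
  orphan <- setdiff(unique(annotations$genome_id), genomes$genome_id)
  if (length(orphan))
    stop_input("annotations reference unknown genome_id(s): ",
               paste(orphan, collapse = ", "))
  families <- families %||% sort(unique(annotations$family_id))
  counts <- table(factor(annotations$family_id, levels = families),
                  factor(annotations$genome_id, levels = genomes$genome_id))
  m <- 100 * sweep(unclass(counts), 2, genomes$total_genes, "/")
  dimnames(m) <- list(families, genomes$genome_id)
  m
}

#' Rank gene families by mean relative abundance
#'
#' Families are ordered by mean percent abundance across genomes, descending,
#' ties broken by lexicographic family identifier; mirrors the "top 50 most
#' abundant" selection used for pangenome heatmaps.
#'
#' @param mat Abundance matrix from [family_abundance()].
#' @param n Number of families to return; capped at the family count.
#' @return Character vector of family identifiers, best first.
#' @export
select_top_families <- function(mat, n = 50) {
  n <- check_count(n, "n")
  if (!is.matrix(mat) || nrow(mat) == 0)
    stop_input("'mat' must be a non-empty abundance matrix")
  means <- rowMeans(mat)
  ord <- order(-means, rownames(mat))
  rownames(mat)[ord][seq_len(min(n, nrow(mat)))]
}

#' Row-wise Z-score transform
#'
#' Standardizes each family across genomes: Z = (x - mean) / sd with the
#' sample (n-1) standard deviation. Constant rows (including all-zero
#' families, common after subsetting) are mapped to all zeros rather than
#' NaN. Invariant under positive affine rescaling of a row.
#'
#' @param mat Abundance matrix (>= 2 columns).
#' @return Matrix of the same shape; each non-constant row has mean 0 and
#'   sample sd 1.
#' @export
zscore_transform <- function(mat) {
  if (!is.matrix(mat) || ncol(mat) < 2)
    stop_input("Z-scores need at least 2 genomes (sd undefined otherwise)")
  mu <- rowMeans(mat)
  s <- apply(mat, 1, sd)
  z <- (mat - mu) / ifelse(s > 0, s, 1)
  z[s == 0, ] <- 0
  z
}

#' Family-family Pearson correlation matrix
#'
#' Pearson r between family abundance profiles across genomes. Constant
#' families have no defined correlation; those entries are `NA`, never
#' imputed as zero.
#'
#' @param mat Abundance matrix (>= 3 columns).
#' @param families Families to correlate; default all rows.
#' @return Square symmetric matrix of Pearson r with unit diagonal (`NA`
#'   diagonal for constant families).
#' @export
family_correlation <- function(mat, families = NULL) {
  if (!is.matrix(mat) || ncol(mat) < 3)
    stop_input("correlations need at least 3 genomes")
  families <- families %||% rownames(mat)
  missing <- setdiff(families, rownames(mat))
  if (length(missing))
    stop_input("requested families absent from the matrix: ",
               paste(missing, collapse = ", "))
  x <- t(mat[families, , drop = FALSE])
  suppressWarnings(r <- cor(x, method = "pearson"))
  const <- apply(x, 2, sd) == 0
  r[const, ] <- NA_real_
  r[, const] <- NA_real_
  diag(r)[!const] <- 1
  r
}

#' Subgroup paralog-expansion scores
#'
#' For every (family, subgroup) pair, the ratio of the family's mean percent
#' abundance inside the subgroup to its mean abundance in all other genomes,
#' stabilized with a pseudocount: `(mean_in + eps) / (mean_out + eps)`. A
#' family planted in one subgroup and near-absent elsewhere scores highest
#' for that pair. The maximum raw copy count per subgroup is reported
#' alongside so users can apply copy-number cutoffs directly.
#'
#' @param mat Abundance matrix.
#' @param genomes Genome table with `genome_id`, `subgroup`; subgroups with
#'   zero genomes in the matrix are dropped with a warning.
#' @param pseudocount Abundance pseudocount eps (percent units).
#' @param annotations Optional annotation table to derive raw copy counts;
#'   when omitted `max_copies` is `NA`.
#' @return `data.frame` with `family`, `subgroup`, `score`, `mean_in`,
#'   `mean_out`, `max_copies`, sorted by decreasing score.
#' @export
expansion_scores <- function(mat, genomes, pseudocount = 0.01,
                             annotations = NULL) {
  check_columns(genomes, c("genome_id", "subgroup"), "genomes")
  pseudocount <- check_number(pseudocount, "pseudocount", min = 1e-12)
  all_subs <- unique(genomes$subgroup)
  genomes <- genomes[genomes$genome_id %in% colnames(mat), ]
  subs <- unique(genomes$subgroup)
  empty <- setdiff(all_subs, subs)
  if (length(empty))
    warning("subgroup(s) with zero genomes excluded: ",
            paste(empty, collapse = ", "))
  copies <- NULL
  if (!is.null(annotations)) {
    tab <- table(factor(annotations$family_id, levels = rownames(mat)),
                 annotations$genome_id)
    copies <- unclass(tab)
  }
  out <- lapply(subs, function(sg) {
    gin <- genomes$genome_id[genomes$subgroup == sg]
    gout <- genomes$genome_id[genomes$subgroup != sg]
    mean_in <- rowMeans(mat[, gin, drop = FALSE])
    mean_out <- if (length(gout)) rowMeans(mat[, gout, drop = FALSE])
                else rep(0, nrow(mat))
    mc <- if (!is.null(copies))
      apply(copies[, intersect(gin, colnames(copies)), drop = FALSE], 1, max)
    else NA_integer_
    data.frame(family = rownames(mat), subgroup = sg,
               score = (mean_in + pseudocount) / (mean_out + pseudocount),
               mean_in = mean_in, mean_out = mean_out, max_copies = mc,
               stringsAsFactors = FALSE, row.names = NULL)
  })
  out <- do.call(rbind, out)
  out[order(-out$score, out$family, out$subgroup), ]
}

#' Universal single-copy ortholog panel
#'
#' Returns the clusters present at copy number exactly 1 in every genome of
#' the input set — the defining property of a single-copy marker panel used
#' as a normalization denominator.
#'
#' @param membership `data.frame` with columns `genome_id`, `cluster_id`,
#'   `copies`. Clusters absent from a genome (no row, or `copies` 0) are
#'   excluded.
#' @return Character vector of cluster identifiers (possibly empty), sorted.
#' @export
single_copy_panel <- function(membership) {
  check_columns(membership, c("genome_id", "cluster_id", "copies"), "membership")
  genomes <- unique(membership$genome_id)
  n_gen <- length(genomes)
  if (!n_gen) return(character())
  ok <- membership$copies == 1
  per_cluster <- tapply(ok, membership$cluster_id, function(x) all(x) && length(x) == n_gen)
  # length(x) == n_gen only if every genome contributed exactly one row
  rows_per <- table(membership$cluster_id)
  keep <- names(per_cluster)[per_cluster & rows_per[names(per_cluster)] == n_gen]
  sort(keep)
}

#' Enzymes required to degrade a chirally complex compound
#'
#' A compound with n chiral centers has 2^n stereoisomers, so a degrader
#' lacking racemases needs one enzyme per stereoisomer: 2^n. If each center
#' can be racemized, one degradative enzyme plus one racemase per center
#' suffices: n + 1. With three centers this is 8 without racemization and 4
#' with it — the economy that makes racemase expansions an attractive
#' adaptation to chiral complexity in refractory dissolved organic matter.
#'
#' @param n_centers Number of chiral centers (>= 0).
#' @param racemization Is a racemase available per center?
#' @return Enzyme count (numeric; exact for n up to 52 without racemization).
#' @export
enzyme_requirement <- function(n_centers, racemization = FALSE) {
  if (!is.numeric(n_centers) || length(n_centers) != 1 || is.na(n_centers) ||
      n_centers < 0 || n_centers != round(n_centers))
    stop_input("'n_centers' must be a single non-negative integer")
  if (isTRUE(racemization)) n_centers + 1 else 2^n_centers
}
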