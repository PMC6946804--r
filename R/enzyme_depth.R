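# Single-copy-normalized enzyme-family abundance and depth correlations.

#' Enzyme-family abundance normalized by single-copy marker genes
#'
#' For each sample, divides the number of the focal taxon's genes annotated
#' to the family of interest by the total number of the taxon's genes
#' annotated to any single-copy marker cluster in the panel (gene
#' occurrences, not distinct clusters). The denominator proxies the taxon's
#' cell count in the sample, so the ratio reads as family copies per genome
#' equivalent. A zero denominator yields a missing value (with a warning),
#' never 0 or infinity.
#'
#' @param gene_table `data.frame` with `sample_id`, `gene_id`, `taxon`,
#'   `family_id`.
#' @param taxon Focal taxon label.
#' @param family Focal enzyme family label (e.g. "FMNO").
#' @param panel Non-empty character vector of single-copy cluster ids.
#' @param samples Optional sample table (`sample_id`, `depth_m`) to attach
#'   depths and include samples with no genes.
#' @return `data.frame` with `sample_id`, `depth` (NA if unknown), `family`,
#'   `value`.
#' @export
normalized_family_abundance <- function(gene_table, taxon, family, panel,
                                        samples = NULL) {
  if (!length(panel)) stop_input("'panel' must be non-empty")
  check_columns(gene_table, c("sample_id", "gene_id", "taxon", "family_id"),
                "gene_table")
  tg <- gene_table[gene_table$taxon == taxon, , drop = FALSE]
  ids <- if (!is.null(samples)) samples$sample_id else sort(unique(tg$sample_id))
  fam <- tapply(tg$family_id == family, factor(tg$sample_id, levels = ids), sum)
  scg <- tapply(tg$family_id %in% panel, factor(tg$sample_id, levels = ids), sum)
  fam[is.na(fam)] <- 0; scg[is.na(scg)] <- 0
  value <- ifelse(scg > 0, fam / scg, NA_real_)
  if (any(scg == 0))
    warning(sum(scg == 0), " sample(s) with zero single-copy marker genes; ",
            "value reported missing")
  depth <- if (!is.null(samples))
    samples$depth_m[match(ids, samples$sample_id)] else NA_real_
  data.frame(sample_id = ids, depth = depth, family = family,
             value = as.numeric(value), row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Pearson correlation of normalized abundance with depth
#'
#' Pairwise-complete Pearson r between value and depth, with a two-sided
#' p-value from the t transform on n - 2 degrees of freedom. Depth enters in
#' linear meters by default; `log_depth = TRUE` correlates against
#' log10(depth) instead.
#'
#' @param values `data.frame` with `value` and `depth` columns (e.g. from
#'   [normalized_family_abundance()]); rows with a missing value or depth are
#'   dropped, with a message stating how many.
#' @param log_depth Correlate against log10 depth?
#' @return `data.frame` with `r`, `p_value`, `n`. Zero-variance inputs give
#'   `r = NA` with a warning.
#' @export
depth_correlation <- function(values, log_depth = FALSE) {
  check_columns(values, c("value", "depth"), "values")
  ok <- !is.na(values$value) & !is.na(values$depth)
  dropped <- sum(!ok)
  if (dropped) message(dropped, " sample(s) dropped for missing value/depth")
  v <- values$value[ok]
  d <- values$depth[ok]
  if (log_depth) d <- log10(d)
  if (length(v) < 3)
    stop_input("need >= 3 non-missing (value, depth) pairs, got ", length(v))
  if (sd(v) == 0 || sd(d) == 0) {
    warning("zero variance: correlation undefined, reported missing")
    return(data.frame(r = NA_real_, p_value = NA_real_, n = length(v)))
  }
  ct <- cor.test(v, d, method = "pearson", alternative = "two.sided")
  data.frame(r = unname(ct$estimate), p_value = ct$p.value, n = length(v))
}

#' Per-genome family abundance vs depth of origin
#'
#' Correlates each genome's percent abundance of the focal family against the
#' depth the genome was recovered from — the genome-resolved complement of
#' the per-sample analysis, used to show that monooxygenase expansions sit in
#' deep-water genomes while enolase expansions sit in shallow ones.
#'
#' @param genomes Genome table with `genome_id`, `depth_origin`.
#' @param mat Abundance matrix from [family_abundance()].
#' @param family Family row to use.
#' @return As [depth_correlation()].
#' @export
per_genome_depth_correlation <- function(genomes, mat, family) {
  check_columns(genomes, c("genome_id", "depth_origin"), "genomes")
  if (!family %in% rownames(mat))
    stop_input("family '", family, "' not in the abundance matrix")
  g <- intersect(colnames(mat), genomes$genome_id)
  df <- data.frame(value = mat[family, g],
                   depth = genomes$depth_origin[match(g, genomes$genome_id)])
  depth_correlation(df)
}

#' Select samples by minimum taxon fraction
#'
#' Keeps samples whose relative abundance of the focal taxon is at least the
#' threshold (inclusive: exactly 1% passes a 1% cutoff), preserving input
#' order. Mirrors the miTAG-based screen used to pick metagenomes worth
#' assembling.
#'
#' @param fractions `data.frame` with `sample_id` and `fraction` in \[0, 1\].
#' @param min_fraction Inclusive threshold, default 0.01.
#' @return Character vector of retained sample ids.
#' @export
select_samples <- function(fractions, min_fraction = 0.01) {
  min_fraction <- check_number(min_fraction, "min_fraction", 0, 1)
  if (!nrow(fractions)) return(character())
  check_columns(fractions, c("sample_id", "fraction"), "fractions")
  if (any(fractions$fraction < 0 | fractions$fraction > 1))
    stop_input("'fraction' must lie in [0, 1]")
  fractions$sample_id[fractions$fraction >= min_fraction]
}
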