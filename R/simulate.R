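#' @useDynLib bathypan, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats cor cor.test pt rbinom rnbinom rnorm runif rmultinom sd
#' @importFrom utils read.table write.table
NULL

# Run expr with a locally seeded RNG, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  seed <- check_count(seed, "seed", min = 0L)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

#' Configuration for the pangenome simulator
#'
#' Describes a synthetic collection of genome bins grouped into subclades,
#' each genome carrying negative-binomial gene-family copy counts, with
#' selected (subgroup, family) pairs planted at an elevated copy mean to
#' emulate lineage-specific paralog expansions.
#'
#' @param n_subgroups Number of subclades.
#' @param genomes_per_subgroup Genomes simulated per subclade.
#' @param genes_per_genome Length-2 numeric `c(mean, dispersion)`: target mean
#'   total genes per genome and the negative-binomial size (dispersion)
#'   parameter shared by all family copy counts.
#' @param n_families Size of the gene-family universe.
#' @param expansions `data.frame` with columns `subgroup`, `family`,
#'   `copy_mean`: planted paralog expansions. May have zero rows.
#' @param depth_range Two-column matrix or data.frame (`min`, `max`), one row
#'   per subgroup, giving the depth band (m) genomes of that subgroup are
#'   drawn from. Default: contiguous bands spanning 0--4000 m.
#' @param subgroups Subgroup labels; default `SG1..SGn`.
#' @param families Family labels; default `FAM0001..`. Planted families must
#'   be members of this universe.
#' @param seed Integer seed; identical configs and seeds reproduce outputs
#'   exactly.
#' @return An object of class `pangenome_sim_config`.
#' @export
pangenome_sim_config <- function(n_subgroups = 5, genomes_per_subgroup = 20,
                                 genes_per_genome = c(2500, 5),
                                 n_families = 300,
                                 expansions = data.frame(subgroup = character(),
                                                         family = character(),
                                                         copy_mean = numeric()),
                                 depth_range = NULL,
                                 subgroups = NULL, families = NULL,
                                 seed = 1) {
  n_subgroups <- check_count(n_subgroups, "n_subgroups")
  genomes_per_subgroup <- check_count(genomes_per_subgroup, "genomes_per_subgroup")
  n_families <- check_count(n_families, "n_families")
  if (length(genes_per_genome) != 2 || any(genes_per_genome <= 0))
    stop_config("'genes_per_genome' must be c(mean, dispersion), both > 0")
  subgroups <- subgroups %||% paste0("SG", seq_len(n_subgroups))
  if (length(subgroups) != n_subgroups)
    stop_config("'subgroups' must have length n_subgroups")
  families <- families %||% sprintf("FAM%04d", seq_len(n_families))
  if (length(families) != n_families)
    stop_config("'families' must have length n_families")
  expansions <- as.data.frame(expansions)
  check_columns(expansions, c("subgroup", "family", "copy_mean"), "expansions")
  if (nrow(expansions)) {
    bad <- setdiff(expansions$family, families)
    if (length(bad))
      stop_config("planted family not in the family universe: ",
                  paste(bad, collapse = ", "))
    bad <- setdiff(expansions$subgroup, subgroups)
    if (length(bad))
      stop_config("planted subgroup not among subgroups: ",
                  paste(bad, collapse = ", "))
    if (any(expansions$copy_mean <= 0))
      stop_config("'expansions$copy_mean' must be > 0")
  }
  if (is.null(depth_range)) {
    edges <- seq(0, 4000, length.out = n_subgroups + 1)
    depth_range <- cbind(min = edges[-length(edges)], max = edges[-1])
  }
  depth_range <- as.matrix(depth_range)
  if (nrow(depth_range) != n_subgroups || ncol(depth_range) != 2 ||
      any(depth_range < 0) || any(depth_range[, 1] > depth_range[, 2]))
    stop_config("'depth_range' must be an n_subgroups x 2 matrix of non-negative min <= max depths")
  structure(list(n_subgroups = n_subgroups,
                 genomes_per_subgroup = genomes_per_subgroup,
                 genes_per_genome = as.numeric(genes_per_genome),
                 n_families = n_families, expansions = expansions,
                 depth_range = depth_range, subgroups = subgroups,
                 families = families, seed = check_count(seed, "seed", 0L)),
            class = "pangenome_sim_config")
}

#' Simulate a pangenome with planted paralog expansions
#'
#' Draws, for every genome, a copy count per gene family from a negative
#' binomial whose mean is the background mean (total genes / families) except
#' at planted (subgroup, family) pairs, where it equals the planted copy mean.
#' The over-dispersed count model mirrors the heavy-tailed paralog counts seen
#' in real genome bins, where a single genome can carry >100 copies of one
#' monooxygenase family.
#'
#' @param config A [pangenome_sim_config()].
#' @return A list with components:
#'   \describe{
#'     \item{genomes}{`data.frame`: `genome_id`, `subgroup`, `depth_origin`,
#'       `total_genes`, `completeness`, `redundancy`, `contamination`,
#'       `size_bp`, `station`.}
#'     \item{annotations}{`data.frame`: `genome_id`, `gene_id`, `family_id`,
#'       one row per gene.}
#'     \item{truth}{planted expansions, background copy mean, and the config.}
#'   }
#' @export
simulate_pangenome <- function(config) {
  if (!inherits(config, "pangenome_sim_config"))
    stop_config("'config' must be a pangenome_sim_config")
  with_seed(config$seed, {
    n_gen <- config$n_subgroups * config$genomes_per_subgroup
    subgroup <- rep(config$subgroups, each = config$genomes_per_subgroup)
    genome_id <- sprintf("GB%03d", seq_len(n_gen))
    idx <- rep(seq_len(config$n_subgroups), each = config$genomes_per_subgroup)
    depth_origin <- runif(n_gen, config$depth_range[idx, 1],
                          config$depth_range[idx, 2])
    background_mu <- config$genes_per_genome[1] / config$n_families
    size <- config$genes_per_genome[2]

    # per-genome mean vector over families: background except planted cells
    mu <- matrix(background_mu, nrow = config$n_families, ncol = n_gen,
                 dimnames = list(config$families, genome_id))
    if (nrow(config$expansions)) {
      for (i in seq_len(nrow(config$expansions))) {
        f <- config$expansions$family[i]
        g <- subgroup == config$expansions$subgroup[i]
        mu[f, g] <- config$expansions$copy_mean[i]
      }
    }
    copies <- matrix(rnbinom(length(mu), mu = mu, size = size),
                     nrow = nrow(mu), dimnames = dimnames(mu))
    total_genes <- colSums(copies)

    genomes <- data.frame(
      genome_id = genome_id, subgroup = subgroup,
      depth_origin = depth_origin, total_genes = total_genes,
      completeness = runif(n_gen, 70, 100),
      redundancy = runif(n_gen, 0, 1.0),
      contamination = runif(n_gen, 0, 4.5),
      size_bp = round(total_genes * runif(n_gen, 950, 1100)),
      station = sample(sprintf("ST%02d", 1:6), n_gen, replace = TRUE),
      stringsAsFactors = FALSE)

    nz <- which(copies > 0, arr.ind = TRUE)
    cnt <- copies[nz]
    annotations <- data.frame(
      genome_id = rep(genome_id[nz[, 2]], cnt),
      family_id = rep(config$families[nz[, 1]], cnt),
      stringsAsFactors = FALSE)
    # stable gene ids within genome
    annotations <- annotations[order(annotations$genome_id,
                                     annotations$family_id), ]
    annotations$gene_id <- paste0(annotations$genome_id, "_g",
                                  stats::ave(seq_len(nrow(annotations)),
                                             annotations$genome_id,
                                             FUN = seq_along))
    annotations <- annotations[, c("genome_id", "gene_id", "family_id")]
    rownames(annotations) <- NULL

    list(genomes = genomes, annotations = annotations,
         truth = list(expansions = config$expansions,
                      background_copy_mean = background_mu,
                      config = config))
  })
}

#' Configuration for the metagenome community simulator
#'
#' Each subgroup's relative abundance follows a Gaussian niche curve in depth
#' (`peak * exp(-(d - center)^2 / (2 width^2))`), the simplest unimodal shape
#' consistent with the depth-stratified recruitment maxima seen in ocean
#' transects.
#'
#' @param depth_grid Sample depths in meters (strictly positive); one sample
#'   per grid point.
#' @param niche_curves `data.frame` with columns `subgroup`, `center` (m),
#'   `width` (m), `peak` (relative abundance in \[0,1\]).
#' @param reads_per_sample,read_length Sequencing effort per sample.
#' @param identity_model Length-2 numeric `c(mean, sd)` of percent identity of
#'   simulated alignments, truncated to \[0,100\].
#' @param taxon Taxon label written to the gene-taxon table.
#' @param seed Integer seed.
#' @return An object of class `community_sim_config`.
#' @export
community_sim_config <- function(depth_grid = c(50, 100, 200, 400, 800, 1200,
                                                2000, 3000, 4000),
                                 niche_curves,
                                 reads_per_sample = 20000, read_length = 100,
                                 identity_model = c(92, 5),
                                 taxon = "SAR202", seed = 1) {
  if (!length(depth_grid) || any(depth_grid <= 0))
    stop_config("'depth_grid' must be non-empty and strictly positive")
  niche_curves <- as.data.frame(niche_curves)
  check_columns(niche_curves, c("subgroup", "center", "width", "peak"),
                "niche_curves")
  if (any(niche_curves$peak < 0 | niche_curves$peak > 1))
    stop_config("'niche_curves$peak' must lie in [0, 1]")
  if (any(niche_curves$width <= 0))
    stop_config("'niche_curves$width' must be > 0")
  structure(list(depth_grid = as.numeric(depth_grid),
                 n_samples = length(depth_grid),
                 niche_curves = niche_curves,
                 reads_per_sample = check_count(reads_per_sample, "reads_per_sample"),
                 read_length = check_count(read_length, "read_length"),
                 identity_model = as.numeric(identity_model),
                 taxon = as.character(taxon),
                 seed = check_count(seed, "seed", 0L)),
            class = "community_sim_config")
}

niche_weight <- function(curves, subgroup, depth) {
  i <- match(subgroup, curves$subgroup)
  w <- ifelse(is.na(i), 0,
              curves$peak[i] * exp(-(depth - curves$center[i])^2 /
                                     (2 * curves$width[i]^2)))
  w
}

#' Simulate depth-stratified metagenome samples against a genome set
#'
#' Allocates reads per sample to genomes by a multinomial whose cell
#' probabilities are the subgroup niche-curve abundance at the sample depth,
#' split evenly among the subgroup's genomes; remaining probability mass is
#' unaligned. Every emitted alignment spans `read_length` bases, so the sum
#' of aligned bases never exceeds the sample's total bases.
#'
#' @param config A [community_sim_config()].
#' @param genomes Genome table from [simulate_pangenome()] (needs `genome_id`,
#'   `subgroup`, `size_bp`).
#' @param annotations Optional annotation table; when supplied, a per-sample
#'   gene-taxon catalog is drawn from recruited genomes.
#' @param genes_per_sample Catalog size per sample when `annotations` given.
#' @return List with `samples` (`sample_id`, `station`, `depth_m`,
#'   `total_bases`), `alignments` (`sample_id`, `read_id`, `genome_id`,
#'   `pct_identity`, `aligned_bases`, `ref_start`, `ref_end`), `gene_taxon`
#'   (or NULL), and `truth` (niche curves and expected allocation weights).
#' @export
simulate_community <- function(config, genomes, annotations = NULL,
                               genes_per_sample = 1000) {
  if (!inherits(config, "community_sim_config"))
    stop_config("'config' must be a community_sim_config")
  if (!is.data.frame(genomes) || !nrow(genomes))
    stop_input("'genomes' table is empty")
  check_columns(genomes, c("genome_id", "subgroup", "size_bp"), "genomes")
  with_seed(config$seed, {
    n_s <- config$n_samples
    samples <- data.frame(
      sample_id = sprintf("SMP%03d", seq_len(n_s)),
      station = sprintf("ST%02d", seq_len(n_s)),
      depth_m = config$depth_grid,
      total_bases = config$reads_per_sample * config$read_length,
      stringsAsFactors = FALSE)

    per_sub <- table(genomes$subgroup)
    aln <- vector("list", n_s)
    gt <- vector("list", n_s)
    weights <- matrix(0, nrow(genomes), n_s,
                      dimnames = list(genomes$genome_id, samples$sample_id))
    for (s in seq_len(n_s)) {
      w_sub <- niche_weight(config$niche_curves, genomes$subgroup,
                            samples$depth_m[s])
      w <- w_sub / as.numeric(per_sub[genomes$subgroup])
      tot <- sum(w)
      if (tot > 1) w <- w / tot
      weights[, s] <- w
      probs <- c(w, max(0, 1 - sum(w)))
      counts <- rmultinom(1, config$reads_per_sample, probs)[, 1]
      reads <- counts[seq_len(nrow(genomes))]
      n_aln <- sum(reads)
      if (n_aln > 0) {
        gid <- rep(genomes$genome_id, reads)
        size <- rep(genomes$size_bp, reads)
        ident <- pmin(100, pmax(0, rnorm(n_aln, config$identity_model[1],
                                         config$identity_model[2])))
        start <- floor(runif(n_aln, 1, pmax(2, size - config$read_length + 1)))
        aln[[s]] <- data.frame(
          sample_id = samples$sample_id[s],
          read_id = sprintf("%s_r%06d", samples$sample_id[s], seq_len(n_aln)),
          genome_id = gid, pct_identity = ident,
          aligned_bases = config$read_length,
          ref_start = start, ref_end = start + config$read_length - 1,
          stringsAsFactors = FALSE)
      }
      if (!is.null(annotations) && n_aln > 0) {
        pool <- annotations[annotations$genome_id %in%
                              genomes$genome_id[reads > 0], ]
        if (nrow(pool)) {
          take <- pool[sample.int(nrow(pool), min(genes_per_sample, nrow(pool))), ]
          gt[[s]] <- data.frame(sample_id = samples$sample_id[s],
                                gene_id = take$gene_id, taxon = config$taxon,
                                family_id = take$family_id,
                                stringsAsFactors = FALSE)
        }
      }
    }
    alignments <- do.call(rbind, aln[!vapply(aln, is.null, TRUE)])
    if (is.null(alignments))
      alignments <- data.frame(sample_id = character(), read_id = character(),
                               genome_id = character(), pct_identity = numeric(),
                               aligned_bases = integer(), ref_start = integer(),
                               ref_end = integer())
    rownames(alignments) <- NULL
    gene_taxon <- if (is.null(annotations)) NULL else
      do.call(rbind, gt[!vapply(gt, is.null, TRUE)])
    list(samples = samples, alignments = alignments, gene_taxon = gene_taxon,
         truth = list(niche_curves = config$niche_curves, weights = weights,
                      config = config))
  })
}

#' Configuration for the FTICR-MS peak-list simulator
#'
#' @param n_base_formulas Number of base peaks per sample.
#' @param mz_range Length-2 numeric mass window (Da).
#' @param oxidation_prob Function of depth (m) returning the probability, in
#'   \[0,1\] and non-decreasing with depth, that a base peak carries a
#'   single-oxygen (+15.994915 Da) partner.
#' @param chain_length_max Maximum carbon-ladder length appended to each base
#'   peak in +12.000000 Da steps; ladder lengths are drawn once and shared by
#'   all samples, so the planted one-carbon pair count is depth-invariant.
#' @param noise_peaks Unrelated uniform peaks added per sample.
#' @param seed Integer seed.
#' @return An object of class `peaklist_sim_config`.
#' @export
peaklist_sim_config <- function(n_base_formulas = 300, mz_range = c(200, 700),
                                oxidation_prob = function(d) pmin(1, 0.05 + 0.20 * d / 4000),
                                chain_length_max = 3, noise_peaks = 100,
                                seed = 1) {
  if (!is.function(oxidation_prob))
    stop_config("'oxidation_prob' must be a function of depth")
  structure(list(n_base_formulas = check_count(n_base_formulas, "n_base_formulas"),
                 mz_range = as.numeric(mz_range),
                 oxidation_prob = oxidation_prob,
                 chain_length_max = check_count(chain_length_max,
                                                "chain_length_max", 0L),
                 noise_peaks = check_count(noise_peaks, "noise_peaks", 0L),
                 seed = check_count(seed, "seed", 0L)),
            class = "peaklist_sim_config")
}

MASS_O <- 15.994915  # monoisotopic oxygen, Da
MASS_C <- 12.000000  # monoisotopic carbon, Da

#' Simulate peak lists with a depth-increasing oxidation signal
#'
#' Each sample contains the shared base peaks, a carbon ladder (+12 Da steps)
#' of per-formula length fixed across samples, `round(p(depth) * n_base)`
#' single-oxygen partners (+15.994915 Da) on randomly chosen base peaks, and
#' uniform noise peaks. Because the planted one-carbon pair count is constant
#' and the planted one-oxygen pair count is a rounded monotone function of
#' depth, the truth-record O:C ratio is non-decreasing in depth by
#' construction.
#'
#' @param config A [peaklist_sim_config()].
#' @param depths Sample depths (m), non-empty.
#' @return List with `peaklists` (named list of sorted m/z vectors),
#'   `samples` (`sample_id`, `station`, `depth_m`), and `truth`
#'   (`data.frame`: per-sample planted `o_pairs`, `c_pairs`, `ratio`).
#' @export
simulate_peaklists <- function(config, depths) {
  if (!inherits(config, "peaklist_sim_config"))
    stop_config("'config' must be a peaklist_sim_config")
  if (!length(depths)) stop_input("'depths' must be non-empty")
  p <- config$oxidation_prob(as.numeric(depths))
  if (any(p < 0 | p > 1))
    stop_config("'oxidation_prob' must map depths into [0, 1]")
  if (is.unsorted(p[order(depths)]))
    stop_config("'oxidation_prob' must be non-decreasing with depth")
  with_seed(config$seed, {
    nb <- config$n_base_formulas
    base <- sort(runif(nb, config$mz_range[1], config$mz_range[2]))
    chain_len <- if (config$chain_length_max > 0)
      sample.int(config$chain_length_max + 1, nb, replace = TRUE) - 1L
    else rep(0L, nb)
    ladder <- unlist(lapply(seq_len(nb), function(i)
      if (chain_len[i] > 0) base[i] + MASS_C * seq_len(chain_len[i]) else numeric()))
    c_pairs <- sum(chain_len)  # adjacent +12 steps, same in every sample

    n_s <- length(depths)
    sample_id <- sprintf("PK%03d", seq_len(n_s))
    peaklists <- vector("list", n_s)
    names(peaklists) <- sample_id
    o_pairs <- integer(n_s)
    for (s in seq_len(n_s)) {
      n_ox <- round(p[s] * nb)
      ox_idx <- if (n_ox > 0) sample.int(nb, n_ox) else integer()
      noise <- runif(config$noise_peaks, config$mz_range[1],
                     config$mz_range[2] + 50)
      mz <- sort(c(base, ladder, base[ox_idx] + MASS_O, noise))
      # dedupe within 1e-6 Da
      keep <- c(TRUE, diff(mz) > 1e-6)
      peaklists[[s]] <- mz[keep]
      o_pairs[s] <- n_ox
    }
    truth <- data.frame(sample_id = sample_id, depth = as.numeric(depths),
                        o_pairs = o_pairs, c_pairs = c_pairs,
                        ratio = if (c_pairs > 0) o_pairs / c_pairs else NA_real_,
                        stringsAsFactors = FALSE)
    samples <- data.frame(sample_id = sample_id,
                          station = sprintf("ST%02d", seq_len(n_s)),
                          depth_m = as.numeric(depths),
                          stringsAsFactors = FALSE)
    list(peaklists = peaklists, samples = samples, truth = truth)
  })
}

#' Simulate a pair of sequences at a known divergence
#'
#' The second sequence is the first with independent per-site substitutions
#' at the stated rate; a substituted site always changes to a different base,
#' so divergence 1 forces a change at every position.
#'
#' @param length Sequence length (bases, >= 1).
#' @param divergence Per-site substitution probability in \[0, 1\].
#' @param seed Integer seed.
#' @return List with `seq_a`, `seq_b` (character), and `n_substitutions`
#'   (realized count).
#' @export
simulate_sequence_pair <- function(length, divergence, seed = 1) {
  length <- check_count(length, "length")
  if (!is.numeric(divergence) || length(divergence) != 1 ||
      is.na(divergence) || divergence < 0 || divergence > 1)
    stop_input("'divergence' must be in [0, 1]")
  with_seed(seed, {
    bases <- c("A", "C", "G", "T")
    a <- sample(bases, length, replace = TRUE)
    hit <- which(runif(length) < divergence)
    b <- a
    if (length(hit)) {
      # substitute with one of the three other bases, uniformly
      off <- sample.int(3, length(hit), replace = TRUE)
      b[hit] <- bases[(match(a[hit], bases) - 1L + off) %% 4L + 1L]
    }
    list(seq_a = paste(a, collapse = ""), seq_b = paste(b, collapse = ""),
         n_substitutions = length(hit))
  })
}

#' Simulate a per-sample gene survey with a planted linear depth trend
#'
#' Emits gene-taxon tables in which the ratio of a focal enzyme family's gene
#' count to the single-copy marker gene count rises linearly with sample
#' depth, with Gaussian noise scaled so the generating (population) Pearson
#' correlation between ratio and depth equals `target_r`. Used to validate
#' the normalized-abundance and depth-correlation machinery by parameter
#' recovery.
#'
#' @param n_samples Number of samples.
#' @param depth_range Sampling depth window (m).
#' @param taxon,family Labels for the focal taxon and enzyme family.
#' @param panel Single-copy marker cluster identifiers.
#' @param panel_genes Single-copy marker genes per sample (the denominator).
#' @param mean_ratio Mean family/marker ratio across the depth window.
#' @param target_r Generating Pearson correlation of ratio vs depth; 0 gives
#'   an independence null.
#' @param seed Integer seed.
#' @return List with `gene_table` (`sample_id`, `gene_id`, `taxon`,
#'   `family_id`), `samples` (`sample_id`, `depth_m`), and `truth`
#'   (generating r, per-sample true ratios).
#' @export
simulate_gene_survey <- function(n_samples = 100, depth_range = c(50, 4000),
                                 taxon = "SAR202", family = "FMNO",
                                 panel = sprintf("SCG%03d", 1:20),
                                 panel_genes = 300, mean_ratio = 0.15,
                                 target_r = 0.9, seed = 1) {
  n_samples <- check_count(n_samples, "n_samples", 3L)
  target_r <- check_number(target_r, "target_r", -1, 1)
  with_seed(seed, {
    depth <- runif(n_samples, depth_range[1], depth_range[2])
    # linear signal spanning [0.25, 1.75] * mean_ratio across the window
    slope <- 1.5 * mean_ratio / diff(range(depth_range))
    signal <- mean_ratio * 0.25 + slope * (depth - depth_range[1])
    if (abs(target_r) > 0 && abs(target_r) < 1) {
      sd_sig <- slope * sqrt(diff(range(depth_range))^2 / 12)  # uniform depth
      noise_sd <- sd_sig * sqrt(1 / target_r^2 - 1)
      ratio <- signal + rnorm(n_samples, 0, noise_sd)
    } else if (target_r == 0) {
      ratio <- mean_ratio + rnorm(n_samples, 0, mean_ratio / 3)
    } else {
      ratio <- signal
    }
    ratio <- pmax(ratio, 0)
    fam_count <- pmax(0L, as.integer(round(ratio * panel_genes)))

    rows <- vector("list", n_samples)
    sample_id <- sprintf("SV%03d", seq_len(n_samples))
    for (s in seq_len(n_samples)) {
      fam <- rep(family, fam_count[s])
      scg <- sample(panel, panel_genes, replace = TRUE)
      fams <- c(fam, scg)
      rows[[s]] <- data.frame(
        sample_id = sample_id[s],
        gene_id = sprintf("%s_g%05d", sample_id[s], seq_along(fams)),
        taxon = taxon, family_id = fams, stringsAsFactors = FALSE)
    }
    list(gene_table = do.call(rbind, rows),
         samples = data.frame(sample_id = sample_id, depth_m = depth,
                              stringsAsFactors = FALSE),
         truth = list(target_r = target_r, true_ratio = fam_count / panel_genes,
                      family = family, taxon = taxon, panel = panel))
  })
}
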