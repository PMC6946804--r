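test_that("pangenome simulation is deterministic under a fixed seed", {
  cfg <- pangenome_sim_config(n_subgroups = 2, genomes_per_subgroup = 4,
                              genes_per_genome = c(100, 5), n_families = 30,
                              seed = 42)
  a <- simulate_pangenome(cfg)
  b <- simulate_pangenome(cfg)
  expect_identical(a$genomes, b$genomes)
  expect_identical(a$annotations, b$annotations)
  c <- simulate_pangenome(pangenome_sim_config(
    n_subgroups = 2, genomes_per_subgroup = 4,
    genes_per_genome = c(100, 5), n_families = 30, seed = 43))
  expect_false(identical(a$annotations, c$annotations))
})

test_that("pangenome truth record reflects the planted expansions", {
  none <- simulate_pangenome(pangenome_sim_config(
    n_subgroups = 2, genomes_per_subgroup = 3,
    genes_per_genome = c(100, 5), n_families = 20, seed = 1))
  expect_equal(nrow(none$truth$expansions), 0)

  planted <- data.frame(subgroup = "SG1", family = "FAM0003", copy_mean = 15)
  sim <- simulate_pangenome(pangenome_sim_config(
    n_subgroups = 2, genomes_per_subgroup = 3,
    genes_per_genome = c(100, 5), n_families = 20,
    expansions = planted, seed = 1))
  expect_equal(sim$truth$expansions$family, "FAM0003")
  expect_equal(sim$truth$background_copy_mean, 100 / 20)
})

test_that("planted copy mean is recovered by the subgroup mean (Monte Carlo)", {
  # plant FMNO-like family at copy mean 100 against background 2;
  # 20 genomes/subgroup should put the subgroup mean within +/-15% of 100
  fams <- c("FMNO", sprintf("FAM%04d", 1:99))
  cfg <- pangenome_sim_config(
    n_subgroups = 2, genomes_per_subgroup = 20,
    genes_per_genome = c(200, 8), n_families = 100,
    families = fams, subgroups = c("IIIa", "I"),
    expansions = data.frame(subgroup = "IIIa", family = "FMNO",
                            copy_mean = 100),
    seed = 99)
  sim <- simulate_pangenome(cfg)
  ann <- sim$annotations
  in_sub <- sim$genomes$genome_id[sim$genomes$subgroup == "IIIa"]
  copies <- table(factor(ann$genome_id[ann$family_id == "FMNO"],
                         levels = in_sub))
  expect_gt(mean(copies), 85)
  expect_lt(mean(copies), 115)
})

test_that("config validation names the offending field", {
  expect_error(pangenome_sim_config(n_subgroups = 0), "n_subgroups")
  expect_error(pangenome_sim_config(
    expansions = data.frame(subgroup = "SG1", family = "NOPE", copy_mean = 5)),
    "family universe")
  expect_error(pangenome_sim_config(genes_per_genome = c(100, -1)),
               "genes_per_genome")
  expect_error(community_sim_config(depth_grid = c(-5, 10),
                                    niche_curves = default_niches()),
               "depth_grid")
  expect_error(community_sim_config(
    niche_curves = data.frame(subgroup = "SG1", center = 100, width = 10,
                              peak = 1.2)), "peak")
})

test_that("community reads follow the niche curves", {
  sim <- small_pangenome(seed = 3)
  # a subgroup with zero niche weight recruits nothing anywhere
  nc <- default_niches()
  nc$peak[nc$subgroup == "SG3"] <- 0
  com <- simulate_community(
    community_sim_config(niche_curves = nc, reads_per_sample = 5000,
                         seed = 11),
    sim$genomes)
  sg3 <- sim$genomes$genome_id[sim$genomes$subgroup == "SG3"]
  expect_false(any(com$alignments$genome_id %in% sg3))

  # per-sample aligned bases never exceed total bases (conservation)
  ab <- tapply(com$alignments$aligned_bases, com$alignments$sample_id, sum)
  tot <- com$samples$total_bases[match(names(ab), com$samples$sample_id)]
  expect_true(all(ab <= tot))
})

test_that("a full-abundance single genome recruits every base", {
  g <- data.frame(genome_id = "G1", subgroup = "SG1", size_bp = 1e6)
  cfg <- community_sim_config(
    depth_grid = 500,
    niche_curves = data.frame(subgroup = "SG1", center = 500, width = 100,
                              peak = 1),
    reads_per_sample = 1000, read_length = 150, seed = 4)
  com <- simulate_community(cfg, g)
  expect_equal(sum(com$alignments$aligned_bases), 1000 * 150)
})

test_that("Gaussian niche puts maximum recruitment at the depth nearest its center", {
  sim <- small_pangenome(seed = 5)
  grid <- c(50, 200, 400, 800, 1600, 3200)
  nc <- default_niches(centers = c(800, 800, 800))
  com <- simulate_community(
    community_sim_config(depth_grid = grid, niche_curves = nc,
                         reads_per_sample = 20000, seed = 12),
    sim$genomes)
  ab <- tapply(com$alignments$aligned_bases, com$alignments$sample_id, sum)
  best <- com$samples$depth_m[match(names(ab)[which.max(ab)],
                                    com$samples$sample_id)]
  expect_equal(best, 800)
})

test_that("empty genome table is rejected by the community simulator", {
  cfg <- community_sim_config(niche_curves = default_niches(), seed = 1)
  expect_error(simulate_community(cfg, data.frame()), "empty")
})

test_that("peak-list truth record tracks the oxidation model", {
  # zero oxidation probability everywhere -> zero planted O pairs
  cfg0 <- peaklist_sim_config(n_base_formulas = 50, noise_peaks = 10,
                              oxidation_prob = function(d) rep(0, length(d)),
                              seed = 2)
  pk0 <- simulate_peaklists(cfg0, c(100, 1000))
  expect_true(all(pk0$truth$o_pairs == 0))

  # single base peak, certain oxidation -> exactly one planted O pair
  cfg1 <- peaklist_sim_config(n_base_formulas = 1, chain_length_max = 0,
                              noise_peaks = 0,
                              oxidation_prob = function(d) rep(1, length(d)),
                              seed = 2)
  pk1 <- simulate_peaklists(cfg1, 500)
  expect_equal(pk1$truth$o_pairs, 1)
  expect_equal(length(pk1$peaklists[[1]]), 2)

  # monotone probability -> truth O:C ratio non-decreasing in depth
  pk <- simulate_peaklists(peaklist_sim_config(seed = 3),
                           c(4000, 100, 1000, 250, 2000))
  tr <- pk$truth[order(pk$truth$depth), ]
  expect_true(!is.unsorted(tr$ratio))

  # decreasing probability is rejected
  expect_error(
    simulate_peaklists(peaklist_sim_config(
      oxidation_prob = function(d) 1 - d / 5000, seed = 1), c(100, 1000)),
    "non-decreasing")
  expect_error(simulate_peaklists(peaklist_sim_config(seed = 1), numeric()),
               "non-empty")
})

test_that("sequence pairs realize the requested divergence", {
  same <- simulate_sequence_pair(500, 0, seed = 1)
  expect_identical(same$seq_a, same$seq_b)
  expect_equal(same$n_substitutions, 0)

  all_diff <- simulate_sequence_pair(500, 1, seed = 1)
  expect_equal(hamming(all_diff$seq_a, all_diff$seq_b), 500)

  expect_error(simulate_sequence_pair(100, 1.5), "divergence")

  # binomial tail: realized substitutions within 3 sd of n * p
  p <- 0.01; n <- 1e6
  sp <- simulate_sequence_pair(n, p, seed = 8)
  sd3 <- 3 * sqrt(n * p * (1 - p))
  expect_lt(abs(sp$n_substitutions - n * p), sd3)
  expect_equal(hamming(sp$seq_a, sp$seq_b), sp$n_substitutions)
})

test_that("gene survey plants the requested ratio-depth correlation", {
  sv <- simulate_gene_survey(n_samples = 80, target_r = 0.9, seed = 21)
  expect_setequal(unique(sv$gene_table$taxon), "SAR202")
  # the realized (truth) ratios correlate with depth near the target
  r_true <- cor(sv$truth$true_ratio, sv$samples$depth_m)
  expect_gt(r_true, 0.8)
  expect_lt(r_true, 0.97)
})
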