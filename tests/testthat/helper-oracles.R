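# Independent oracles used across tests: deliberately naive implementations
# kept separate from the package's code paths.

# two-pass Pearson correlation from the covariance/variance definitions
bf_pearson <- function(x, y) {
  mx <- sum(x) / length(x)
  my <- sum(y) / length(y)
  sum((x - mx) * (y - my)) /
    sqrt(sum((x - mx)^2) * sum((y - my)^2))
}

# naive all-pairs mass-difference counter (ppm tolerance on the heavier peak):
# materializes every ordered pair difference and counts matches directly
naive_pair_count <- function(mz, delta, tol_ppm) {
  mz <- sort(unique(mz))
  diffs <- outer(mz, mz, "-")          # diffs[i, j] = mz[i] - mz[j]
  tol <- tol_ppm * 1e-6 * mz           # relative to the heavier peak (row)
  match_ <- abs(diffs - delta) <= matrix(tol, length(mz), length(mz))
  sum(match_[lower.tri(match_)])       # i > j: heavier minus lighter
}

# hamming distance between two equal-length strings
hamming <- function(a, b) {
  sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
}

# small pangenome simulation shared by several tests: background copy mean 2,
# one family planted at mean 20 in SG2
small_pangenome <- function(seed = 1, planted = data.frame(
                              subgroup = "SG2", family = "FAM0010",
                              copy_mean = 20)) {
  simulate_pangenome(pangenome_sim_config(
    n_subgroups = 3, genomes_per_subgroup = 8,
    genes_per_genome = c(200, 5), n_families = 100,
    expansions = planted, seed = seed))
}

default_niches <- function(subgroups = paste0("SG", 1:3),
                           centers = c(200, 800, 3000)) {
  data.frame(subgroup = subgroups, center = centers,
             width = 500, peak = 0.2, stringsAsFactors = FALSE)
}
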