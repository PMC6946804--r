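test_that("family abundance is percent of total genes, zero when absent", {
  genomes <- data.frame(genome_id = c("G1", "G2"), total_genes = c(100, 50))
  ann <- data.frame(genome_id = c(rep("G1", 4), "G2"),
                    gene_id = paste0("g", 1:5),
                    family_id = c(rep("X", 4), "Y"))
  m <- family_abundance(ann, genomes)
  expect_equal(m["X", "G1"], 4.0)
  expect_equal(m["X", "G2"], 0)
  expect_equal(m["Y", "G2"], 2.0)

  # a genome carrying 114 copies of a monooxygenase family among 2850 genes
  # sits at the 4% ceiling observed for the most expanded genomes
  g <- data.frame(genome_id = "G3", total_genes = 2850)
  a <- data.frame(genome_id = "G3", gene_id = paste0("g", 1:114),
                  family_id = "FMNO")
  expect_equal(family_abundance(a, g)["FMNO", "G3"], 100 * 114 / 2850)
  expect_equal(family_abundance(a, g)["FMNO", "G3"], 4.0)

  # empty annotations with a declared universe -> all-zero matrix
  empty <- family_abundance(ann[0, ], genomes, families = c("X", "Y"))
  expect_true(all(empty == 0))
  expect_equal(dim(empty), c(2, 2))

  expect_error(family_abundance(ann, data.frame(genome_id = "G1",
                                                total_genes = 0)),
               "total_genes = 0")
  expect_error(
    family_abundance(data.frame(genome_id = "GX", gene_id = "g",
                                family_id = "X"), genomes),
    "unknown genome")
})

test_that("column sums hit 100 exactly over the complete family universe", {
  sim <- small_pangenome(seed = 2)
  m <- family_abundance(sim$annotations, sim$genomes)
  expect_true(all(abs(colSums(m) - 100) < 1e-9))
})

test_that("top-family selection ranks by mean abundance with lexicographic ties", {
  m <- rbind(A = c(1, 1), C = c(5, 5), B = c(5, 5), D = c(2, 2))
  colnames(m) <- c("G1", "G2")
  expect_equal(select_top_families(m, 3), c("B", "C", "D"))
  expect_equal(select_top_families(m, 10), c("B", "C", "D", "A"))
  expect_error(select_top_families(m[0, , drop = FALSE], 5), "non-empty")

  sim <- small_pangenome(seed = 4)
  mat <- family_abundance(sim$annotations, sim$genomes)
  expect_length(select_top_families(mat, 50), 50)
})

test_that("Z-scores standardize rows and map constant rows to zero", {
  m <- rbind(f1 = c(1, 2, 3), f2 = c(5, 5, 5))
  colnames(m) <- paste0("G", 1:3)
  z <- zscore_transform(m)
  expect_equal(unname(z["f1", ]), c(-1, 0, 1))  # sample sd of (1,2,3) is 1
  expect_equal(unname(z["f2", ]), c(0, 0, 0))
  expect_lt(abs(mean(z["f1", ])), 1e-9)
  expect_equal(sd(z["f1", ]), 1)
  expect_error(zscore_transform(m[, 1, drop = FALSE]), "at least 2")
})

test_that("Z-scores are invariant under positive affine rescaling of a row", {
  set.seed(31)
  for (i in 1:20) {
    x <- matrix(runif(24), nrow = 2,
                dimnames = list(c("a", "b"), paste0("G", 1:12)))
    a <- runif(1, 0.1, 10); b <- runif(1, -5, 5)
    expect_equal(zscore_transform(a * x + b), zscore_transform(x),
                 tolerance = 1e-9)
  }
})

test_that("correlation matrix matches a brute-force Pearson to 1e-12", {
  set.seed(7)
  for (rep in 1:10) {
    n_f <- sample(3:10, 1); n_g <- sample(4:10, 1)
    m <- matrix(runif(n_f * n_g), n_f,
                dimnames = list(paste0("f", seq_len(n_f)),
                                paste0("G", seq_len(n_g))))
    r <- family_correlation(m)
    expect_true(isSymmetric(r))
    expect_true(all(abs(diag(r) - 1) < 1e-12))
    expect_true(all(r >= -1 - 1e-12 & r <= 1 + 1e-12))
    for (i in seq_len(n_f)) for (j in seq_len(n_f))
      expect_equal(r[i, j], bf_pearson(m[i, ], m[j, ]), tolerance = 1e-12)
  }
})

test_that("constant families yield missing correlations, never zero", {
  m <- rbind(f1 = c(1, 2, 3, 4), f2 = c(2, 2, 2, 2), f3 = c(4, 3, 2, 1))
  colnames(m) <- paste0("G", 1:4)
  r <- family_correlation(m)
  expect_true(all(is.na(r["f2", ])))
  expect_true(all(is.na(r[, "f2"])))
  expect_equal(r["f1", "f3"], -1)
  expect_equal(r["f1", "f1"], 1)
  expect_error(family_correlation(m[, 1:2]), "3 genomes")
  expect_error(family_correlation(m, families = "nope"), "absent")
})

test_that("independent families are uncorrelated under the Monte-Carlo null", {
  set.seed(19)
  hits <- 0L
  for (rep in 1:100) {
    m <- rbind(a = rnorm(200), b = rnorm(200))
    colnames(m) <- paste0("G", 1:200)
    if (abs(family_correlation(m)["a", "b"]) < 0.2) hits <- hits + 1L
  }
  expect_gte(hits, 95)
})

test_that("expansion scores recover a planted single-subgroup family", {
  sim <- small_pangenome(seed = 6)
  mat <- family_abundance(sim$annotations, sim$genomes)
  es <- expansion_scores(mat, sim$genomes, annotations = sim$annotations)
  expect_equal(es$family[1], "FAM0010")
  expect_equal(es$subgroup[1], "SG2")
  expect_true(all(es$score >= 0))

  # uniform family scores ~1; absent family scores exactly 1 (eps/eps)
  m <- rbind(u = c(2, 2, 2, 2), z = c(0, 0, 0, 0))
  colnames(m) <- paste0("G", 1:4)
  g <- data.frame(genome_id = paste0("G", 1:4),
                  subgroup = c("A", "A", "B", "B"))
  es2 <- expansion_scores(m, g, pseudocount = 0.01)
  expect_equal(es2$score[es2$family == "z"], c(1, 1))
  expect_true(all(abs(es2$score[es2$family == "u"] - 1) < 0.02))
})

test_that("single-copy panel keeps exactly the universal single-copy clusters", {
  mem <- expand.grid(genome_id = paste0("G", 1:5),
                     cluster_id = paste0("C", 1:4),
                     stringsAsFactors = FALSE)
  mem$copies <- 1
  mem$copies[mem$cluster_id == "C2" & mem$genome_id == "G3"] <- 2
  mem <- mem[!(mem$cluster_id == "C3" & mem$genome_id == "G1"), ]  # missing
  expect_equal(single_copy_panel(mem), c("C1", "C4"))

  # planted truth: 20 universal single-copy clusters among 100
  set.seed(17)
  genomes <- paste0("G", 1:30)
  clusters <- paste0("CL", sprintf("%03d", 1:100))
  universal <- clusters[1:20]
  rows <- do.call(rbind, lapply(clusters, function(cl) {
    if (cl %in% universal)
      data.frame(genome_id = genomes, cluster_id = cl, copies = 1)
    else {
      n <- sample(5:30, 1)
      data.frame(genome_id = sample(genomes, n),
                 cluster_id = cl,
                 copies = sample(c(1, 1, 2, 3), n, replace = TRUE))
    }
  }))
  # non-universal clusters covering all genomes at copy 1 would also qualify;
  # force each to miss one genome or carry a duplicate
  expect_true(all(universal %in% single_copy_panel(rows)))
  got <- single_copy_panel(rows)
  extra <- setdiff(got, universal)
  for (cl in extra) {
    sub <- rows[rows$cluster_id == cl, ]
    expect_true(nrow(sub) == 30 && all(sub$copies == 1))
  }
})

test_that("enzyme requirement follows the stereoisomer arithmetic", {
  expect_equal(enzyme_requirement(3, racemization = FALSE), 8)
  expect_equal(enzyme_requirement(3, racemization = TRUE), 4)
  expect_equal(enzyme_requirement(0, FALSE), 1)
  expect_equal(enzyme_requirement(0, TRUE), 1)
  expect_error(enzyme_requirement(-1), "non-negative")
  # 2^n >= n + 1, equality only at n in {0, 1}
  for (n in 0:20) {
    no_rac <- enzyme_requirement(n, FALSE)
    rac <- enzyme_requirement(n, TRUE)
    expect_gte(no_rac, rac)
    if (n <= 1) expect_equal(no_rac, rac)
    else expect_gt(no_rac, rac)
  }
})
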