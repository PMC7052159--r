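small_cfg <- function(seed = 1, depth_mean = 9000, ...) {
  sim_config(seed = seed, n_species = 3, n_individuals = 4, n_otus = 100,
             n_trees = 3, raster_dim = c(8, 8), depth_mean = depth_mean,
             n_batches = 2, ...)
}

test_that("generators are deterministic under a fixed seed", {
  s1 <- simulate_assemblage(small_cfg(5))
  s2 <- simulate_assemblage(small_cfg(5))
  expect_identical(s1$counts$counts, s2$counts$counts)
  expect_identical(ape::write.tree(s1$trees), ape::write.tree(s2$trees))
  expect_identical(s1$truth$drer_true, s2$truth$drer_true)
  ## byte-identical emitted files
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_assemblage(s1, d1); write_assemblage(s2, d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     info = f)
  }
  s3 <- simulate_assemblage(small_cfg(6))
  expect_false(identical(s1$counts$counts, s3$counts$counts))
})

test_that("tree simulation and perturbation honour their contracts", {
  tr <- simulate_prey_tree(2, seed = 3)
  expect_equal(length(tr$tip.label), 2)
  expect_true(all(tr$edge.length > 0))
  expect_identical(ape::write.tree(simulate_prey_tree(100, seed = 9)),
                   ape::write.tree(simulate_prey_tree(100, seed = 9)))
  expect_equal(length(simulate_prey_tree(100, seed = 1)$tip.label), 100)
  expect_error(simulate_prey_tree(1), ">= 2")

  base <- simulate_prey_tree(20, seed = 4)
  ts0 <- perturb_tree_set(base, 5, sd = 0, seed = 1)
  expect_equal(length(ts0), 5)
  for (t in ts0) expect_equal(t$edge.length, base$edge.length)
  ts <- perturb_tree_set(base, 5, sd = 0.3, seed = 1)
  expect_false(identical(ts[[1]]$edge.length, ts[[2]]$edge.length))
  ## topology fixed: identical newick up to branch lengths
  expect_identical(ts[[1]]$tip.label, base$tip.label)
})

test_that("tau controls individual turnover in true diets", {
  set.seed(191)
  cfg0 <- small_cfg(7, tau = 0)
  tree <- simulate_prey_tree(cfg0$n_otus)
  d0 <- simulate_species_diets(cfg0, tree)
  P <- d0$profiles[[1]]
  res <- partition_diversity(P, q = 1)
  expect_equal(res$beta, 1, tolerance = 1e-9)
  expect_equal(res$turnover, 0, tolerance = 1e-9)
  ## high tau: individuals diverge, turnover grows
  set.seed(192)
  cfgH <- small_cfg(7, tau = 0.9)
  dH <- simulate_species_diets(cfgH, tree)
  resH <- partition_diversity(dH$profiles[[1]], q = 1)
  expect_gt(resH$turnover, 0.3)
  ## pool size bound enforced
  expect_error(sim_config(n_otus = 50, pool_size = 60), "exceeds")
})

test_that("dirichlet concentration raises evenness on average", {
  set.seed(201)
  even_of <- function(alpha) {
    mean(replicate(30, {
      base <- rgamma(30, shape = alpha)
      evenness_factor(base / sum(base))
    }))
  }
  e <- vapply(c(0.2, 1, 5), even_of, numeric(1))
  expect_true(all(diff(e) > 0))
})

test_that("read depths and dropout match configuration", {
  cfg <- sim_config(seed = 8, n_species = 3, n_individuals = 60, n_otus = 60,
                    primers = "Zeale", n_trees = 2, raster_dim = c(6, 6),
                    depth_mean = 15000, depth_dispersion = 8, dropout = 0.1,
                    low_depth_fraction = 0, artifact_otus_per_sample = 0,
                    low_noise_otus_per_sample = 0, contaminants_per_batch = 0,
                    pool_size = 20, dirichlet_alpha = 8, tau = 0,
                    n_batches = 1)
  set.seed(8)
  tree <- simulate_prey_tree(cfg$n_otus)
  diets <- simulate_species_diets(cfg, tree)
  reads <- simulate_reads(diets, cfg)
  nonblank <- !reads$counts$meta$is_blank
  depths <- colSums(apply(reads$counts$counts[, nonblank, ], c(1, 2), sum))
  expect_equal(length(depths), 180)  # 3 species x 60 individuals
  expect_lt(abs(mean(depths) - 15000) / 15000, 0.05)
  ## per-replicate dropout frequency among pool OTUs: with an even pool of
  ## 20 OTUs at ~5000 reads per replicate, multinomial zeros are negligible,
  ## so the observed zero rate estimates the dropout probability
  sp <- names(diets$profiles)[1]
  idx <- reads$counts$meta$species == sp
  pool <- diets$pools[[sp]]
  zero_rate <- mean(reads$counts$counts[pool, idx, ] == 0)
  expect_lt(abs(zero_rate - cfg$dropout), 0.02)
})

test_that("QC recovers true species richness at high depth", {
  ## deep sequencing, 10% dropout, contaminants planted: dR after the QC
  ## chain stays within 10% of the true prey-pool richness
  errs <- vapply(1:20, function(s) {
    cfg <- sim_config(seed = 300 + s, n_species = 2, n_individuals = 5,
                      n_otus = 150, primers = "Zeale", n_trees = 2,
                      raster_dim = c(6, 6), depth_mean = 50000,
                      dropout = 0.1, low_depth_fraction = 0,
                      pool_size = 40, dirichlet_alpha = 5, tau = 0.2,
                      n_batches = 1, contaminants_per_batch = 2)
    sim <- simulate_assemblage(cfg)
    qc <- qc_filter(sim$counts)
    prof <- to_profiles(qc, "abundance")
    rec <- species_metrics(prof)
    true_dR <- vapply(sim$truth$species_profiles,
                      function(p) hill_number(p, 0), numeric(1))
    max(abs(rec$metrics$dR - true_dR[rec$metrics$species]) /
          true_dR[rec$metrics$species])
  }, numeric(1))
  expect_lt(max(errs), 0.10)
})

test_that("planted nuisance structure is removed by QC, and only it", {
  sim <- simulate_assemblage(small_cfg(17, depth_mean = 20000))
  qc <- qc_filter(sim$counts)
  ## no contaminant OTU survives
  expect_length(intersect(rownames(qc$counts),
                          paste0("OTU_", sim$truth$contaminant_otus)), 0)
  ## shallow samples are gone
  expect_length(intersect(colnames(qc$counts), sim$truth$shallow_samples), 0)
  ## every surviving OTU belongs to some species' true prey pool
  pool_otus <- paste0("OTU_", sort(unique(unlist(sim$truth$pools))))
  expect_true(all(rownames(qc$counts) %in% pool_otus))
})

test_that("raster generator couples unevenness to homogeneity", {
  set.seed(211)
  r0 <- simulate_raster(c(10, 10), unevenness = 0)
  expect_equal(distribution_homogeneity(r0), 1)
  ## homogeneity decreases in expectation with unevenness
  h <- vapply(c(0.2, 1, 3), function(u) {
    mean(replicate(30, distribution_homogeneity(simulate_raster(c(10, 10), u))))
  }, numeric(1))
  expect_true(all(diff(h) < 0))
  ## same seed, same raster
  expect_identical(simulate_raster(c(9, 9), 1.5, seed = 2)$values,
                   simulate_raster(c(9, 9), 1.5, seed = 2)$values)
})

test_that("assemblage truth records the planted coupling", {
  s0 <- simulate_assemblage(small_cfg(23, coupling_slope = 0))
  expect_equal(s0$truth$coupling_slope, 0)
  sp <- simulate_assemblage(sim_config(seed = 29, n_species = 12,
    n_individuals = 3, n_otus = 150, n_trees = 3, raster_dim = c(10, 10),
    depth_mean = 9000, n_batches = 2, coupling_slope = 1.5,
    coupling_noise = 0.1))
  tau <- cor(rowMeans(sp$truth$drer_true), sp$truth$homogeneity_true,
             method = "kendall")
  expect_gt(tau, 0.3)
})

test_that("the full pipeline is reproducible end to end", {
  cfg <- small_cfg(31)
  r1 <- run_pipeline(simulate_assemblage(cfg))
  r2 <- run_pipeline(simulate_assemblage(cfg))
  expect_identical(as.data.frame(r1$contrasts), as.data.frame(r2$contrasts))
  expect_identical(r1$records$metrics, r2$records$metrics)
})
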