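#' Simulation configuration
#'
#' Collects every knob of the synthetic-data generator. Defaults emulate
#' the study design the package targets: 7 predator species sampled at
#' ~50 individuals each, triplicate PCRs under two primer sets, a sparse
#' OTU universe of 2000 prey taxa, 50 posterior-like prey trees, and one
#' habitat-suitability raster per species whose unevenness is linearly
#' coupled (on the log scale, with noise) to the species' true dietary
#' breadth dRER.
#'
#' @param seed integer seed; identical seeds give bit-identical output.
#' @param n_species number of predator species.
#' @param n_individuals individuals sampled per species.
#' @param n_replicates PCR replicates per individual per primer.
#' @param n_otus size of the prey OTU universe (and tree leaf count).
#' @param primers character vector of primer labels.
#' @param depth_mean,depth_dispersion negative-binomial read-depth model
#'   per sample (total across replicates): mean and size.
#' @param dropout per-replicate probability that a prey OTU fails to
#'   amplify in one PCR.
#' @param low_depth_fraction fraction of samples forced to shallow
#'   sequencing (mean \code{low_depth_mean}), destined for the depth filter.
#' @param low_depth_mean mean total depth of shallow samples.
#' @param n_batches number of wet-lab processing batches.
#' @param contaminants_per_batch contaminant OTUs planted per batch (they
#'   appear in the batch's extraction/library blanks and its samples).
#' @param contaminant_frac relative read abundance of each planted
#'   contaminant in affected samples.
#' @param artifact_otus_per_sample OTUs planted in exactly one replicate
#'   of a sample (removed by replicate concordance).
#' @param low_noise_otus_per_sample OTUs planted at ~1 read per replicate
#'   (below the 0.02\% filter at the default depth).
#' @param pool_size per-species prey-pool size; scalar or length
#'   \code{n_species} (graded richness by default).
#' @param dirichlet_alpha Dirichlet concentration of the species base
#'   profile; scalar or per species (graded evenness by default; larger =
#'   more even).
#' @param lambda_phylo phylogenetic clustering strength of the prey pool;
#'   0 = uniform leaf sampling, larger values concentrate the pool in few
#'   clades, lowering dietary regularity (graded by default).
#' @param tau individual turnover parameter in [0, 1): 0 = identical
#'   individuals, values near 1 give nearly disjoint individual diets.
#' @param n_trees number of perturbed posterior-like trees.
#' @param tree_sd lognormal sd of the branch-length perturbation.
#' @param primer_bias_sd lognormal sd of per-OTU primer detection bias.
#' @param raster_dim raster dimensions \code{c(nrow, ncol)}.
#' @param habitat_frac_range range of the per-species fraction of cells
#'   with any suitability (remaining cells are unsuitable, outside the
#'   potential range); drawn uniformly per species.
#' @param unevenness_base baseline lognormal sd of cell suitabilities.
#' @param coupling_slope linear coupling between the species'
#'   standardised true dRER and log raster unevenness (positive slope =
#'   broader diet, more homogeneous distribution).
#' @param coupling_noise sd of the noise on that coupling.
#' @return an object of class \code{sim_config} (a named list).
#' @export
sim_config <- function(seed = 1L,
                       n_species = 7L,
                       n_individuals = 50L,
                       n_replicates = 3L,
                       n_otus = 2000L,
                       primers = c("Zeale", "Epp"),
                       depth_mean = 20000,
                       depth_dispersion = 5,
                       dropout = 0.05,
                       low_depth_fraction = 0.05,
                       low_depth_mean = 3000,
                       n_batches = 4L,
                       contaminants_per_batch = 2L,
                       contaminant_frac = 0.005,
                       artifact_otus_per_sample = 2L,
                       low_noise_otus_per_sample = 2L,
                       pool_size = NULL,
                       dirichlet_alpha = NULL,
                       lambda_phylo = NULL,
                       tau = 0.4,
                       n_trees = 50L,
                       tree_sd = 0.05,
                       primer_bias_sd = 0.3,
                       raster_dim = c(50L, 50L),
                       habitat_frac_range = c(0.4, 0.95),
                       unevenness_base = 1,
                       coupling_slope = 0.8,
                       coupling_noise = 0.3) {
  if (is.null(pool_size)) {
    ## graded per-species richness: 4%..13% of the OTU universe
    pool_size <- round(seq(max(10, 0.04 * n_otus),
                           max(20, min(0.13 * n_otus, n_otus / 2)),
                           length.out = n_species))
  }
  pool_size <- rep_len(pool_size, n_species)
  if (any(pool_size > n_otus)) stop("prey-pool size exceeds the OTU universe")
  if (is.null(dirichlet_alpha)) {
    dirichlet_alpha <- seq(0.3, 1.5, length.out = n_species)
  }
  dirichlet_alpha <- rep_len(dirichlet_alpha, n_species)
  if (is.null(lambda_phylo)) lambda_phylo <- seq(0, 4, length.out = n_species)
  lambda_phylo <- rep_len(lambda_phylo, n_species)
  stopifnot(tau >= 0, tau < 1, dropout >= 0, dropout <= 1,
            low_depth_fraction >= 0, low_depth_fraction <= 1,
            n_species >= 1, n_individuals >= 1, n_replicates >= 1,
            n_otus >= 2, n_trees >= 1, tree_sd >= 0, unevenness_base >= 0)
  structure(as.list(environment()), class = "sim_config")
}

#' Simulate a prey phylogeny
#'
#' Random birth--death tree with positive branch lengths and leaves
#' labelled \code{OTU_1 .. OTU_n}; stands in for a Bayesian prey
#' phylogeny inferred from metabarcoding sequences.
#'
#' @param n_otus leaf count (>= 2).
#' @param seed optional integer seed; if \code{NULL} the current RNG
#'   stream is used.
#' @return an \code{ape} \code{phylo}.
#' @export
simulate_prey_tree <- function(n_otus, seed = NULL) {
  if (n_otus < 2L) stop("'n_otus' must be >= 2")
  if (!is.null(seed)) set.seed(seed)
  tree <- ape::rphylo(n_otus, birth = 1, death = 0)
  tree$tip.label <- paste0("OTU_", seq_len(n_otus))
  tree
}

#' Perturb a tree into a posterior-like tree set
#'
#' Produces \code{n_trees} copies of \code{tree} whose branch lengths are
#' multiplied by independent lognormal(0, sd) factors; topology is kept
#' fixed. Emulates the branch-length component of posterior tree
#' uncertainty, which is what drives dispersion of phylogenetic Hill
#' numbers across draws.
#'
#' @param tree a \code{phylo}.
#' @param n_trees number of draws.
#' @param sd lognormal sd (0 gives identical copies).
#' @param seed optional seed.
#' @return a \code{multiPhylo} of length \code{n_trees}.
#' @export
perturb_tree_set <- function(tree, n_trees, sd = 0.05, seed = NULL) {
  stopifnot(inherits(tree, "phylo"), sd >= 0, n_trees >= 1)
  if (!is.null(seed)) set.seed(seed)
  out <- lapply(seq_len(n_trees), function(i) {
    tr <- tree
    tr$edge.length <- tr$edge.length *
      stats::rlnorm(length(tr$edge.length), 0, sd)
    tr
  })
  class(out) <- "multiPhylo"
  out
}

## patristic distance from one tip to all tips, via parent pointers;
## avoids the O(n^2) full distance matrix
tip_distances <- function(tree, tip) {
  ntip <- length(tree$tip.label)
  nn <- ntip + tree$Nnode
  parent <- integer(nn)
  plen <- numeric(nn)
  parent[tree$edge[, 2L]] <- tree$edge[, 1L]
  plen[tree$edge[, 2L]] <- tree$edge.length
  depth <- numeric(nn)
  ## depths by walking each node up (memoised)
  known <- logical(nn)
  root <- ntip + 1L
  known[root] <- TRUE
  for (v in seq_len(nn)) {
    path <- integer(0)
    u <- v
    while (!known[u]) { path <- c(path, u); u <- parent[u] }
    for (w in rev(path)) { depth[w] <- depth[parent[w]] + plen[w]; known[w] <- TRUE }
  }
  ## seed's ancestor set with depths
  anc <- logical(nn)
  u <- tip
  while (u != root) { anc[u] <- TRUE; u <- parent[u] }
  anc[root] <- TRUE
  d <- numeric(ntip)
  for (t in seq_len(ntip)) {
    u <- t
    while (!anc[u]) u <- parent[u]
    d[t] <- depth[t] + depth[tip] - 2 * depth[u]
  }
  d
}

## draw a prey pool of given size with phylogenetic clustering lambda
sample_prey_pool <- function(tree, size, lambda) {
  ntip <- length(tree$tip.label)
  if (lambda <= 0) return(sort(sample.int(ntip, size)))
  seed_tip <- sample.int(ntip, 1L)
  d <- tip_distances(tree, seed_tip)
  w <- exp(-lambda * d / mean(d[d > 0]))
  sort(sample.int(ntip, size, prob = w))
}

#' Simulate true individual diet profiles for all species
#'
#' For each species: draw a prey pool from the tree leaves (uniformly at
#' clustering strength 0; concentrated in few clades as
#' \code{lambda_phylo} grows), draw a species base profile from a
#' symmetric Dirichlet (concentration controls evenness), then derive
#' individual profiles by gamma-perturbing the base with shape
#' \eqn{(1-\tau)/\tau}: at \eqn{\tau = 0} individuals are identical, as
#' \eqn{\tau \to 1} individual diets concentrate on nearly disjoint prey
#' subsets. Perturbed entries below \code{1e-6} (relative) are zeroed so
#' turnover also shows at the incidence level.
#'
#' @param config a \code{\link{sim_config}}.
#' @param tree the prey phylogeny (leaf labels OTU_*).
#' @return list with \code{profiles} (per species, an individuals-by-OTU
#'   matrix over the full OTU universe) and \code{pools} (per species,
#'   integer leaf indices).
#' @export
simulate_species_diets <- function(config, tree) {
  stopifnot(inherits(config, "sim_config"))
  n_otus <- config$n_otus
  otu_names <- tree$tip.label
  species <- species_codes(config$n_species)
  profiles <- list()
  pools <- list()
  for (s in seq_len(config$n_species)) {
    pool <- sample_prey_pool(tree, config$pool_size[s], config$lambda_phylo[s])
    base <- stats::rgamma(length(pool), shape = config$dirichlet_alpha[s])
    while (sum(base) <= 0) base <- stats::rgamma(length(pool), shape = config$dirichlet_alpha[s])
    base <- base / sum(base)
    P <- matrix(0, nrow = config$n_individuals, ncol = n_otus,
                dimnames = list(NULL, otu_names))
    for (i in seq_len(config$n_individuals)) {
      if (config$tau == 0) {
        p <- base
      } else {
        theta <- (1 - config$tau) / config$tau
        g <- stats::rgamma(length(pool), shape = theta, rate = theta)
        p <- base * g
        if (sum(p) <= 0) p <- base
        p <- p / sum(p)
        p[p < 1e-6] <- 0
        p <- p / sum(p)
      }
      P[i, pool] <- p
    }
    profiles[[species[s]]] <- P
    pools[[species[s]]] <- pool
  }
  list(profiles = profiles, pools = pools)
}

species_codes <- function(n) sprintf("SP%02d", seq_len(n))

#' Simulate replicated sequencing reads from true diet profiles
#'
#' Draws, for every individual, primer and PCR replicate, a multinomial
#' read vector from the individual's true profile modulated by a per-OTU
#' primer bias, with per-replicate amplification dropout. Planted
#' nuisance structure mirrors what the QC chain must remove: contaminant
#' OTUs present in each batch's extraction and library blanks and its
#' samples, single-replicate artifact OTUs, trace OTUs below the
#' relative-abundance threshold, and a fraction of under-sequenced
#' samples.
#'
#' @param diets result of \code{\link{simulate_species_diets}}.
#' @param config a \code{\link{sim_config}}.
#' @return list with \code{counts} (a
#'   \code{\link{replicate_count_table}} covering both primers and the
#'   blanks) and \code{planted} (contaminant/artifact bookkeeping).
#' @export
simulate_reads <- function(diets, config) {
  stopifnot(inherits(config, "sim_config"))
  n_otus <- config$n_otus
  otu_names <- colnames(diets$profiles[[1L]])
  species <- names(diets$profiles)
  R <- config$n_replicates
  pooled_otus <- sort(unique(unlist(diets$pools)))
  free_otus <- setdiff(seq_len(n_otus), pooled_otus)
  n_contam <- config$n_batches * config$contaminants_per_batch
  if (n_contam > 0) {
    contam_pool <- if (length(free_otus) >= n_contam) free_otus else seq_len(n_otus)
    contam_by_batch <- split(sample(contam_pool, n_contam),
                             rep(seq_len(config$n_batches),
                                 each = config$contaminants_per_batch))
  } else {
    contam_by_batch <- rep(list(integer(0)), config$n_batches)
  }

  ## sample bookkeeping
  ids <- character(0); meta_rows <- list()
  ind_tab <- expand.grid(ind = seq_len(config$n_individuals),
                         sp = seq_along(species), KEEP.OUT.ATTRS = FALSE)
  batch_of_ind <- rep_len(seq_len(config$n_batches), nrow(ind_tab))
  shallow <- stats::runif(nrow(ind_tab) * length(config$primers)) <
    config$low_depth_fraction

  ## primer-specific per-OTU detection bias
  bias <- lapply(config$primers, function(pr) {
    stats::rlnorm(n_otus, 0, config$primer_bias_sd)
  })
  names(bias) <- config$primers

  n_samp <- nrow(ind_tab) * length(config$primers) +
    config$n_batches * 3L * length(config$primers)
  counts <- array(0L, dim = c(n_otus, n_samp, R),
                  dimnames = list(otu_names, NULL, NULL))
  col <- 0L
  k <- 0L
  for (pr in config$primers) {
    for (j in seq_len(nrow(ind_tab))) {
      k <- k + 1L; col <- col + 1L
      sp <- species[ind_tab$sp[j]]
      id <- sprintf("%s_I%03d_%s", sp, ind_tab$ind[j], pr)
      ids[col] <- id
      meta_rows[[col]] <- data.frame(sample_id = id, species = sp,
                                     batch = batch_of_ind[j], primer = pr,
                                     is_blank = FALSE, blank_kind = "none")
      p0 <- diets$profiles[[sp]][ind_tab$ind[j], ] * bias[[pr]]
      p0 <- p0 / sum(p0)
      depth_mu <- if (shallow[k]) config$low_depth_mean else config$depth_mean
      contam <- contam_by_batch[[batch_of_ind[j]]]
      for (r in seq_len(R)) {
        p <- p0
        if (config$dropout > 0) {
          drop <- stats::runif(n_otus) < config$dropout
          p[drop] <- 0
          if (sum(p) <= 0) p <- p0
          p <- p / sum(p)
        }
        depth <- stats::rnbinom(1L, mu = depth_mu / R,
                                size = config$depth_dispersion)
        if (depth > 0) counts[, col, r] <- stats::rmultinom(1L, depth, p)[, 1L]
        ## planted contaminants: present in every replicate (survive
        ## concordance; only the blank filter can remove them)
        counts[contam, col, r] <- counts[contam, col, r] +
          stats::rpois(length(contam),
                       pmax(1, depth * config$contaminant_frac))
      }
      ## artifact (single-replicate) and trace OTUs, drawn disjointly
      n_art <- config$artifact_otus_per_sample
      n_tr <- if (shallow[k]) 0L else min(config$low_noise_otus_per_sample,
                                          max(0L, length(free_otus) - n_art))
      if (n_art + n_tr > 0) {
        noise_pool <- if (length(free_otus) >= n_art + n_tr) free_otus else seq_len(n_otus)
        picked <- sample(noise_pool, n_art + n_tr)
        if (n_art > 0) {
          art <- picked[seq_len(n_art)]
          rr <- sample.int(R, n_art, replace = TRUE)
          for (a in seq_along(art)) {
            counts[art[a], col, rr[a]] <- counts[art[a], col, rr[a]] +
              stats::rpois(1L, 20) + 1L
          }
        }
        if (n_tr > 0) {
          tr <- picked[n_art + seq_len(n_tr)]
          reps <- seq_len(min(2L, R))
          counts[tr, col, reps] <- counts[tr, col, reps] + 1L
        }
      }
    }
    ## blanks: extraction + library + pcr per batch
    for (b in seq_len(config$n_batches)) {
      for (bk in c("extraction", "library", "pcr")) {
        col <- col + 1L
        id <- sprintf("BLANK_%s_B%d_%s", bk, b, pr)
        ids[col] <- id
        meta_rows[[col]] <- data.frame(sample_id = id, species = "none",
                                       batch = b, primer = pr,
                                       is_blank = TRUE, blank_kind = bk)
        if (bk != "pcr") {
          contam <- contam_by_batch[[b]]
          for (r in seq_len(R)) {
            counts[contam, col, r] <- stats::rpois(length(contam), 150) + 1L
          }
        }
      }
    }
  }
  dimnames(counts)[[2L]] <- ids
  meta <- do.call(rbind, meta_rows)
  list(counts = replicate_count_table(counts, meta),
       planted = list(contaminants = contam_by_batch,
                      contaminant_otus = sort(unlist(contam_by_batch)),
                      shallow_samples = ids[seq_len(nrow(ind_tab) *
                        length(config$primers))][shallow]))
}

#' Simulate a habitat-suitability raster
#'
#' Cell suitabilities are drawn lognormal(0, unevenness) and rescaled by
#' the maximum into (0, 1]. At unevenness 0 every cell is equally
#' suitable, so distribution homogeneity is exactly 1; homogeneity falls
#' as unevenness grows.
#'
#' @param dim raster dimensions \code{c(nrow, ncol)} (a scalar gives a
#'   square raster).
#' @param unevenness lognormal sd (>= 0).
#' @param seed optional seed.
#' @param s_min minimum-suitability floor passed to
#'   \code{\link{suitability_raster}} (default 0 for simulated rasters:
#'   every cell is genuine model output).
#' @param habitat_frac fraction of cells with any suitability; the rest
#'   are set to 0 (outside the potential range under strict \code{> s_min}).
#' @export
simulate_raster <- function(dim = c(50L, 50L), unevenness = 1, seed = NULL,
                            s_min = 0, habitat_frac = 1) {
  if (unevenness < 0) stop("'unevenness' must be >= 0")
  if (habitat_frac <= 0 || habitat_frac > 1) stop("'habitat_frac' must lie in (0, 1]")
  if (!is.null(seed)) set.seed(seed)
  if (length(dim) == 1L) dim <- c(dim, dim)
  n <- prod(dim)
  v <- stats::rlnorm(n, 0, unevenness)
  v <- v / max(v)
  if (habitat_frac < 1) {
    v[sample.int(n, round(n * (1 - habitat_frac)))] <- 0
    if (all(v == 0)) v[1L] <- 1
  }
  m <- matrix(v, nrow = dim[1L], ncol = dim[2L])
  suitability_raster(m, s_min = s_min)
}

#' Simulate a complete study assemblage with known truth
#'
#' End-to-end generator: prey tree, perturbed tree set, species diets
#' with graded richness/evenness/regularity, replicated reads with
#' planted nuisance structure, behavioural trait profiles, and one
#' suitability raster per species whose unevenness is coupled to the
#' species' true dRER through \code{coupling_slope} (plus noise). The
#' coupling is imposed on the generating unevenness parameter, not on
#' realised homogeneity, so realised values inherit sampling noise —
#' the analogue of an observational design.
#'
#' @param config a \code{\link{sim_config}}.
#' @return list of class \code{sim_assemblage} with elements
#'   \code{config}, \code{tree}, \code{trees}, \code{counts}
#'   (\code{replicate_count_table}), \code{rasters} (named list),
#'   \code{traits} (data.frame of trait category counts) and
#'   \code{truth} (\code{SimulationTruth}-style list).
#' @export
simulate_assemblage <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  tree <- simulate_prey_tree(config$n_otus)
  trees <- perturb_tree_set(tree, config$n_trees, config$tree_sd)
  diets <- simulate_species_diets(config, tree)
  species <- names(diets$profiles)

  true_species_profile <- lapply(diets$profiles, function(P) {
    sp <- colMeans(P / rowSums(P))
    sp / sum(sp)
  })
  drer_true <- t(vapply(true_species_profile, function(p) {
    vapply(trees, function(tr) phylo_hill_number(p, tr, q = 1), numeric(1))
  }, numeric(config$n_trees)))
  rownames(drer_true) <- species
  drer_mean <- rowMeans(drer_true)

  z <- if (stats::sd(drer_mean) > 0) {
    (drer_mean - mean(drer_mean)) / stats::sd(drer_mean)
  } else rep(0, length(drer_mean))
  unevenness <- config$unevenness_base *
    exp(-config$coupling_slope * z +
          stats::rnorm(config$n_species, 0, config$coupling_noise))
  habitat_frac <- stats::runif(config$n_species,
                               config$habitat_frac_range[1L],
                               config$habitat_frac_range[2L])
  rasters <- lapply(seq_len(config$n_species), function(s) {
    simulate_raster(config$raster_dim, unevenness[s], s_min = 0,
                    habitat_frac = habitat_frac[s])
  })
  names(rasters) <- species

  reads <- simulate_reads(diets, config)

  traits <- do.call(rbind, lapply(species, function(sp) {
    data.frame(species = sp,
               t(c(hunting = stats::rmultinom(1L, 40, stats::rgamma(3, 1) + 0.05)[, 1L],
                   habitat = stats::rmultinom(1L, 40, stats::rgamma(4, 1) + 0.05)[, 1L],
                   roosting = stats::rmultinom(1L, 40, stats::rgamma(3, 1) + 0.05)[, 1L])))
  }))

  truth <- list(
    pools = diets$pools,
    species_profiles = true_species_profile,
    individual_profiles = diets$profiles,
    drer_true = drer_true,
    unevenness = stats::setNames(unevenness, species),
    homogeneity_true = vapply(rasters, distribution_homogeneity, numeric(1)),
    coupling_slope = config$coupling_slope,
    contaminants = reads$planted$contaminants,
    contaminant_otus = reads$planted$contaminant_otus,
    shallow_samples = reads$planted$shallow_samples)

  structure(list(config = config, tree = tree, trees = trees,
                 counts = reads$counts, rasters = rasters, traits = traits,
                 truth = truth),
            class = "sim_assemblage")
}

#' @export
print.sim_assemblage <- function(x, ...) {
  cat(sprintf("sim_assemblage: %d species x %d individuals, %d OTUs, %d trees, coupling slope %g\n",
              x$config$n_species, x$config$n_individuals, x$config$n_otus,
              x$config$n_trees, x$config$coupling_slope))
  invisible(x)
}

#' Write a simulated assemblage to disk
#'
#' Emits the file set a field pipeline would consume: long-format counts
#' TSV, metadata TSV, a multi-tree Newick file, one ASCII-grid raster per
#' species, a trait TSV and a JSON truth record.
#'
#' @param sim a \code{\link{simulate_assemblage}} result.
#' @param dir output directory (created if needed).
#' @return invisibly, the vector of files written.
#' @export
write_assemblage <- function(sim, dir) {
  stopifnot(inherits(sim, "sim_assemblage"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  f <- file.path(dir, "counts.tsv")
  write_counts_tsv(sim$counts, f); files <- c(files, f)
  f <- file.path(dir, "metadata.tsv")
  utils::write.table(sim$counts$meta, f, sep = "\t", quote = FALSE,
                     row.names = FALSE); files <- c(files, f)
  f <- file.path(dir, "trees.nwk")
  ape::write.tree(sim$trees, f); files <- c(files, f)
  for (sp in names(sim$rasters)) {
    f <- file.path(dir, paste0("raster_", sp, ".asc"))
    write_ascii_grid(sim$rasters[[sp]], f); files <- c(files, f)
  }
  f <- file.path(dir, "traits.tsv")
  utils::write.table(sim$traits, f, sep = "\t", quote = FALSE,
                     row.names = FALSE); files <- c(files, f)
  f <- file.path(dir, "truth.json")
  writeLines(jsonlite::toJSON(list(
    coupling_slope = sim$truth$coupling_slope,
    unevenness = as.list(sim$truth$unevenness),
    homogeneity_true = as.list(sim$truth$homogeneity_true),
    contaminant_otus = sim$truth$contaminant_otus,
    shallow_samples = sim$truth$shallow_samples,
    drer_true_mean = as.list(rowMeans(sim$truth$drer_true))),
    auto_unbox = TRUE, digits = NA), f)
  files <- c(files, f)
  invisible(files)
}
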