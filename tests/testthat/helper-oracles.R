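## Independent oracles used across the suite. These deliberately take a
## different computational route from the package implementation.

## random profile over S OTUs (named), optionally skewed
random_profile <- function(S, named = TRUE) {
  p <- stats::runif(S)^2
  p <- p / sum(p)
  if (named) names(p) <- paste0("OTU_", seq_len(S))
  p
}

## direct-formula Hill number, no shared code with hill_number()
direct_hill <- function(p, q) {
  p <- p[p > 0] / sum(p[p > 0])
  if (q == 1) return(exp(-sum(p * log(p))))
  sum(p^q)^(1 / (1 - q))
}

## naive phylogenetic Hill number: enumerate, for every edge, the tips
## descending it via root-to-tip node paths (ape::nodepath), then apply
## the branch-sum formulas directly. Independent of the postorder
## accumulation used by the implementation.
naive_phylo_hill <- function(p, tree, q) {
  p <- p[p > 0]
  if (length(p) < length(tree$tip.label)) tree <- ape::keep.tip(tree, names(p))
  p <- p / sum(p)
  ntip <- length(tree$tip.label)
  paths <- lapply(seq_len(ntip), function(t) ape::nodepath(tree, ntip + 1L, t))
  a <- numeric(nrow(tree$edge))
  for (e in seq_len(nrow(tree$edge))) {
    child <- tree$edge[e, 2L]
    below <- vapply(seq_len(ntip), function(t) child %in% paths[[t]], logical(1))
    a[e] <- sum(p[tree$tip.label[below]])
  }
  L <- tree$edge.length
  keep <- a > 0
  a <- a[keep]; L <- L[keep]
  Tbar <- sum(L * a)
  if (q == 1) exp(-sum((L / Tbar) * a * log(a))) else
    sum((L / Tbar) * a^q)^(1 / (1 - q))
}

## set-arithmetic alpha/gamma/beta at q = 0 for incidence-style profiles
brute_partition_q0 <- function(profiles) {
  supports <- apply(profiles > 0, 1L, which, simplify = FALSE)
  gamma <- length(unique(unlist(supports)))
  alpha <- mean(lengths(supports))
  list(alpha = alpha, gamma = gamma, beta = gamma / alpha)
}

## brute-force rarefaction by multivariate hypergeometric resampling
brute_rarefy <- function(counts, depth, draws = 10000) {
  pool <- rep.int(seq_along(counts), counts)
  mean(vapply(seq_len(draws), function(i) {
    length(unique(pool[sample.int(length(pool), depth)]))
  }, numeric(1)))
}

## tiny hand-assembled QC fixture with planted truth:
##  - OTU_A, OTU_B: genuine diet in samples S1..S3 (batch 1) and S4 (batch 2)
##  - OTU_C: contaminant, present in batch-1 extraction blank and batch-1 samples
##  - OTU_D: 1-of-3 replicate artifact in S1
##  - OTU_E: trace OTU at 1 read (0.01% of S1's ~10k total)
##  - S3: shallow sample, 4000 reads total
## expected survivors: OTU_A, OTU_B in S1, S2, S4
build_qc_fixture <- function() {
  otus <- c("OTU_A", "OTU_B", "OTU_C", "OTU_D", "OTU_E")
  samples <- c("S1", "S2", "S3", "S4", "BLK_ext_1", "BLK_lib_2")
  a <- array(0L, dim = c(5, 6, 3), dimnames = list(otus, samples, NULL))
  for (r in 1:3) {
    a["OTU_A", "S1", r] <- 2000L; a["OTU_B", "S1", r] <- 1400L
    a["OTU_A", "S2", r] <- 1800L; a["OTU_B", "S2", r] <- 1600L
    a["OTU_A", "S3", r] <- 800L;  a["OTU_B", "S3", r] <- 500L   # 3900+100 contam
    a["OTU_A", "S4", r] <- 2500L; a["OTU_B", "S4", r] <- 900L
    a["OTU_C", "S1", r] <- 50L; a["OTU_C", "S2", r] <- 40L
    a["OTU_C", "S3", r] <- 33L + r                              # shallow + contam
  }
  a["OTU_D", "S1", 2] <- 120L                  # single-replicate artifact
  a["OTU_E", "S1", 1:2] <- 1L                  # ~0.01% of S1 total
  a["OTU_C", "BLK_ext_1", 1:2] <- 300L         # batch-1 extraction blank
  ## batch-2 library blank left empty: nothing removed from batch 2
  meta <- data.frame(
    sample_id = samples,
    species = c("SPX", "SPX", "SPX", "SPY", "none", "none"),
    batch = c(1, 1, 1, 2, 1, 2),
    primer = "Zeale",
    is_blank = c(FALSE, FALSE, FALSE, FALSE, TRUE, TRUE),
    blank_kind = c("none", "none", "none", "none", "extraction", "library"))
  list(table = replicate_count_table(a, meta),
       truth_otus = c("OTU_A", "OTU_B"),
       truth_samples = c("S1", "S2", "S4"))
}
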