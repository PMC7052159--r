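make_simple_table <- function(counts_list, blanks = NULL) {
  ## counts_list: named list sample -> otu x replicate matrix
  otus <- rownames(counts_list[[1L]])
  R <- ncol(counts_list[[1L]])
  a <- array(0L, dim = c(length(otus), length(counts_list), R),
             dimnames = list(otus, names(counts_list), NULL))
  for (s in names(counts_list)) a[, s, ] <- counts_list[[s]]
  blanks <- blanks %||% character(0)
  meta <- data.frame(sample_id = names(counts_list), species = "SPX",
                     batch = 1, primer = "Zeale",
                     is_blank = names(counts_list) %in% blanks,
                     blank_kind = ifelse(names(counts_list) %in% blanks,
                                         "extraction", "none"))
  replicate_count_table(a, meta)
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("replicate concordance keeps 2-of-3 detections and zeroes the rest", {
  m <- rbind(OTU_1 = c(10, 0, 0), OTU_2 = c(10, 5, 0), OTU_3 = c(3, 2, 1))
  tab <- make_simple_table(list(S1 = m))
  out <- filter_replicate_concordance(tab, 2)
  expect_equal(as.vector(out$counts["OTU_1", "S1", ]), c(0, 0, 0))
  expect_equal(as.vector(out$counts["OTU_2", "S1", ]), c(10, 5, 0))
  expect_equal(as.vector(out$counts["OTU_3", "S1", ]), c(3, 2, 1))
  ## min_replicates = 1 is the identity on non-blank samples
  id <- filter_replicate_concordance(tab, 1)
  expect_equal(id$counts, tab$counts)
  expect_error(filter_replicate_concordance(tab, 4), "exceeds")
})

test_that("blank contaminant removal is batch-scoped and ignores PCR blanks", {
  otus <- c("OTU_X", "OTU_Y")
  a <- array(0L, dim = c(2, 5, 3), dimnames = list(otus,
             c("B1S1", "B2S1", "BLK1", "BLK2", "PCRB"), NULL))
  a["OTU_X", c("B1S1", "B2S1"), ] <- 100L
  a["OTU_Y", c("B1S1", "B2S1"), ] <- 50L
  a["OTU_X", "BLK1", 1] <- 10L           # extraction blank, batch 1
  a["OTU_Y", "PCRB", ] <- 30L            # pcr blank, batch 1: monitored only
  meta <- data.frame(sample_id = colnames(a),
                     species = c("SPX", "SPX", "none", "none", "none"),
                     batch = c(1, 2, 1, 2, 1), primer = "Zeale",
                     is_blank = c(FALSE, FALSE, TRUE, TRUE, TRUE),
                     blank_kind = c("none", "none", "extraction", "library", "pcr"))
  tab <- replicate_count_table(a, meta)
  out <- remove_blank_contaminants(tab)
  expect_equal(sum(out$counts["OTU_X", "B1S1", ]), 0)     # zeroed in batch 1
  expect_equal(sum(out$counts["OTU_X", "B2S1", ]), 300)   # batch 2 untouched
  expect_equal(sum(out$counts["OTU_Y", "B1S1", ]), 150)   # pcr blank not used
  expect_false(any(out$meta$is_blank))
  prov <- out$provenance[[1L]]
  expect_equal(prov$pcr_blank_otus, "OTU_Y")
  ## empty blanks: counts unchanged, blanks dropped
  tab2 <- make_simple_table(list(S1 = rbind(OTU_1 = c(5, 5, 5)),
                                 BK = rbind(OTU_1 = c(0, 0, 0))),
                            blanks = "BK")
  out2 <- remove_blank_contaminants(tab2)
  expect_equal(as.vector(out2$counts["OTU_1", "S1", ]), c(5, 5, 5))
  expect_equal(ncol(out2$counts), 1L)
})

test_that("collapse sums replicates and drops globally empty OTUs", {
  m <- rbind(OTU_1 = c(10, 5, 0), OTU_2 = c(0, 0, 0))
  out <- collapse_replicates(make_simple_table(list(S1 = m)))
  expect_equal(unname(out$counts["OTU_1", "S1"]), 15)
  expect_false("OTU_2" %in% rownames(out$counts))
})

test_that("depth filter is strict below the threshold", {
  m1 <- rbind(OTU_1 = c(2000, 2000, 999))   # 4999
  m2 <- rbind(OTU_1 = c(2000, 2000, 1000))  # 5000
  tab <- collapse_replicates(make_simple_table(list(S1 = m1, S2 = m2)))
  out <- filter_min_depth(tab, 5000)
  expect_equal(colnames(out$counts), "S2")
  expect_equal(ncol(filter_min_depth(tab, 0)$counts), 2L)
  expect_error(filter_min_depth(tab, 1e9), "every sample")
})

test_that("relative-abundance filter is strict below 0.02% and single-pass", {
  m <- rbind(OTU_1 = c(4000, 3000, 2997), OTU_2 = c(1, 0, 0), OTU_3 = c(1, 1, 0))
  tab <- collapse_replicates(make_simple_table(list(S1 = m)))  # total 10000
  out <- filter_rel_abundance(tab, 2e-4)
  expect_false("OTU_2" %in% rownames(out$counts))  # 1/10000 = 0.01% < 0.02%
  expect_true("OTU_3" %in% rownames(out$counts))   # 2/10000 = 0.02%, equality passes
  expect_equal(unname(out$counts["OTU_3", "S1"]), 2)
  id <- filter_rel_abundance(tab, 0)
  expect_equal(id$counts, tab$counts)
})

test_that("filters are idempotent and never increase reads or richness", {
  set.seed(61)
  sim <- simulate_assemblage(sim_config(seed = 61, n_species = 3,
    n_individuals = 4, n_otus = 120, n_trees = 2, raster_dim = c(8, 8),
    depth_mean = 9000, n_batches = 2))
  raw <- subset_samples(sim$counts, sim$counts$meta$primer == "Zeale")
  b <- remove_blank_contaminants(raw)
  c1 <- filter_replicate_concordance(b, 2)
  expect_equal(filter_replicate_concordance(c1, 2)$counts, c1$counts)
  col <- collapse_replicates(c1)
  d <- filter_min_depth(col, 5000)
  expect_equal(filter_min_depth(d, 5000)$counts, d$counts)
  r <- filter_rel_abundance(d, 2e-4)
  expect_equal(filter_rel_abundance(r, 2e-4)$counts, r$counts)
  ## monotonicity along the chain
  reads <- c(sum(b$counts), sum(c1$counts), sum(col$counts), sum(d$counts), sum(r$counts))
  expect_true(all(diff(reads) <= 0))
  rich <- c(sum(rowSums(c1$counts) > 0), nrow(col$counts), nrow(r$counts))
  expect_true(all(diff(rich) <= 0))
  ## provenance reproduces the applied order and parameters
  steps <- vapply(r$provenance, `[[`, character(1), "step")
  expect_equal(steps, c("blank_removal", "replicate_concordance",
                        "collapse_replicates", "min_depth", "rel_abundance"))
  expect_equal(r$provenance[[4L]]$min_reads, 5000)
  expect_equal(r$provenance[[5L]]$min_fraction, 2e-4)
})

test_that("the QC chain recovers exactly the planted truth on the fixture", {
  fx <- build_qc_fixture()
  out <- qc_filter(fx$table)
  expect_setequal(rownames(out$counts), fx$truth_otus)
  expect_setequal(colnames(out$counts), fx$truth_samples)
})

test_that("rarefaction expectation matches resampling and vegan", {
  ## single OTU: curve constant at 1
  cv <- rarefaction_curve(c(100), step = 10)
  expect_true(all(cv$richness == 1))
  ## full-depth expectation equals observed richness
  x <- c(50, 30, 10, 5, 5)
  cv <- rarefaction_curve(x, step = 25)
  expect_equal(cv$richness[nrow(cv)], 5)
  ## uniform 10 x 10 at depth 10: brute-force hypergeometric resampling
  set.seed(71)
  x <- rep(10, 10)
  exp_an <- rarefaction_curve(x, step = 10)$richness[1L]
  exp_mc <- brute_rarefy(x, 10, draws = 10000)
  expect_equal(exp_an, exp_mc, tolerance = 0.02)
  ## and the analytic value agrees with vegan's rarefy
  expect_equal(exp_an, as.numeric(suppressWarnings(vegan::rarefy(x, 10))),
               tolerance = 1e-8)
  expect_error(rarefaction_curve(x, step = 0), "step")
})

test_that("curvature index measures saturation", {
  flat <- data.frame(depth = 1:50, richness = rep(1, 50))
  expect_equal(curvature_index(flat), 1)
  line <- data.frame(depth = seq(0, 100, by = 10),
                     richness = seq(0, 20, by = 2))
  expect_equal(curvature_index(line), 0.5)
  ## concave rarefaction curves land in (0.5, 1]
  set.seed(81)
  for (i in 1:5) {
    x <- rpois(20, 50) + 1
    cv <- rarefaction_curve(x, step = 50)
    ci <- curvature_index(cv)
    expect_gt(ci, 0.5)
    expect_lte(ci, 1)
  }
})

test_that("profiles normalise abundance and incidence correctly", {
  m <- rbind(OTU_1 = c(10, 10, 10), OTU_2 = c(30, 20, 20))
  tab <- collapse_replicates(make_simple_table(list(S1 = m)))
  pa <- to_profiles(tab, "abundance")
  expect_equal(unname(pa$p["S1", ]), c(0.3, 0.7))
  pi <- to_profiles(tab, "incidence")
  expect_equal(unname(pi$p["S1", ]), c(0.5, 0.5))
  one <- collapse_replicates(make_simple_table(list(S1 = rbind(OTU_1 = c(5, 5, 5)))))
  expect_equal(unname(to_profiles(one, "abundance")$p[1, ]), 1)
  expect_equal(unname(to_profiles(one, "incidence")$p[1, ]), 1)
})

test_that("long-format TSV round-trips a replicate table", {
  fx <- build_qc_fixture()
  d <- withr::local_tempdir()
  write_counts_tsv(fx$table, file.path(d, "c.tsv"))
  write.table(fx$table$meta, file.path(d, "m.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  back <- read_count_table(file.path(d, "c.tsv"), file.path(d, "m.tsv"))
  common <- intersect(rownames(back$counts), rownames(fx$table$counts))
  expect_equal(back$counts[common, colnames(fx$table$counts), ],
               fx$table$counts[common, , ])
})
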