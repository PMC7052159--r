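test_that("fit_lm reproduces least squares exactly", {
  x <- c(1, 2, 3, 4, 5, 6, 7)
  r <- suppressWarnings(fit_lm(x, 2 * x))
  expect_equal(r$r2, 1)
  expect_equal(r$estimate, 2)
  expect_equal(unname(r$df), c(1, 5))
  ## textbook 5-point dataset against normal-equations arithmetic
  x <- c(1, 2, 3, 4, 5); y <- c(2, 1, 4, 3, 6)
  slope <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  r <- fit_lm(x, y)
  expect_equal(r$estimate, slope, tolerance = 1e-12)
  ssr <- sum((mean(y) + slope * (x - mean(x)) - mean(y))^2)
  sse <- sum((y - (mean(y) + slope * (x - mean(x))))^2)
  expect_equal(r$statistic, (ssr / 1) / (sse / 3), tolerance = 1e-10)
  expect_equal(r$r2, ssr / (ssr + sse), tolerance = 1e-12)
  ## independent noise: r2 near zero at large n
  set.seed(141)
  r <- fit_lm(rnorm(1000), rnorm(1000))
  expect_lt(r$r2, 0.01)
  expect_error(fit_lm(rep(1, 5), rnorm(5)), "zero variance")
  expect_error(fit_lm(1:2, 1:2), "3 species")
})

test_that("fit_lm r2 and p are invariant to affine rescaling of x", {
  set.seed(151)
  x <- rnorm(20); y <- x + rnorm(20)
  a <- fit_lm(x, y); b <- fit_lm(5 * x - 3, y)
  expect_equal(a$r2, b$r2, tolerance = 1e-12)
  expect_equal(a$p, b$p, tolerance = 1e-12)
})

test_that("fit_lmm falls back to species-mean OLS when variance is degenerate", {
  set.seed(164)
  n_sp <- 8; k <- 6
  x <- rnorm(n_sp)
  ## no species effect at all: random-intercept variance estimated at 0
  y <- as.vector(sapply(1:n_sp, function(s) 2 * x[s] + rnorm(k, 0, 1)))
  expect_warning(
    r <- fit_lmm(y, rep(x, each = k), rep(1:n_sp, each = k)),
    "singular")
  agg_y <- tapply(y, rep(1:n_sp, each = k), mean)
  ref <- fit_lm(x, as.numeric(agg_y))
  expect_equal(r$model, "LM")
  expect_equal(r$estimate, ref$estimate, tolerance = 1e-6)
})

test_that("fit_lmm recovers planted structure with sane r-squared", {
  set.seed(171)
  n_sp <- 12; k <- 10
  x <- rnorm(n_sp)
  y <- as.vector(sapply(1:n_sp, function(s) {
    1 + x[s] + rnorm(1, 0, 0.6) + rnorm(k, 0, 0.4)
  }))
  r <- fit_lmm(y, rep(x, each = k), rep(paste0("SP", 1:n_sp), each = k))
  expect_equal(r$model, "LMM")
  expect_equal(unname(r$df), n_sp - 2)
  expect_lt(abs(r$estimate - 1), 0.8)
  expect_gte(r$r2_conditional, r$r2_marginal)
  expect_true(r$r2_marginal >= 0 && r$r2_conditional <= 1)
  ## pure-noise predictor: marginal r2 collapses
  set.seed(181)
  r2m <- replicate(20, {
    xn <- rnorm(n_sp)
    yn <- as.vector(sapply(1:n_sp, function(s) rnorm(1, 0, 1) + rnorm(k, 0, 0.5)))
    fit <- tryCatch(suppressWarnings(
      fit_lmm(yn, rep(xn, each = k), rep(1:n_sp, each = k))),
      error = function(e) NULL)
    if (is.null(fit)) NA_real_ else if (fit$model == "LMM") fit$r2_marginal else 0
  })
  expect_lt(mean(r2m, na.rm = TRUE), 0.1)
})

test_that("primer averaging is per-metric and draw-wise", {
  mk <- function(dR, draws, primer) {
    species_records(data.frame(species = c("A", "B"), dR = dR),
                    matrix(draws, nrow = 2, byrow = TRUE,
                           dimnames = list(c("A", "B"), NULL)),
                    primer = primer)
  }
  z <- mk(c(10, 12), c(1, 2, 3, 4, 5, 6), "Zeale")
  e <- mk(c(20, 14), c(3, 4, 5, 6, 7, 8), "Epp")
  av <- average_primers(z, e)
  expect_equal(av$metrics$dR, c(15, 13))
  expect_equal(unname(av$drer_draws["A", ]), c(2, 3, 4))   # draw-wise mean
  expect_equal(av$metrics$dRER,
               unname(rowMeans(av$drer_draws)[av$metrics$species]))
  expect_true(all(av$metrics$averaged))
  ## identical inputs: identity
  same <- average_primers(z, z)
  expect_equal(same$metrics$dR, z$metrics$dR)
  expect_equal(same$drer_draws, z$drer_draws)
  ## mismatched draw counts error
  e_bad <- mk(c(20, 14), rep(1, 8), "Epp")
  e_bad$drer_draws <- matrix(1, 2, 4, dimnames = list(c("A", "B"), NULL))
  expect_error(average_primers(z, e_bad), "mismatched")
  ## species present in one primer only: passed through, flagged
  z2 <- species_records(data.frame(species = c("A", "B", "C"),
                                   dR = c(10, 12, 9)), primer = "Zeale")
  e2 <- species_records(data.frame(species = c("A", "B"), dR = c(20, 14)),
                        primer = "Epp")
  av2 <- average_primers(z2, e2)
  expect_equal(av2$metrics$dR[av2$metrics$species == "C"], 9)
  expect_false(av2$metrics$averaged[av2$metrics$species == "C"])
})

test_that("the contrast battery errors cleanly on too few species", {
  rec <- species_records(data.frame(species = "A", dR = 3, homogeneity = 0.5))
  expect_error(run_contrasts(rec), "3 species")
})

test_that("skipped contrasts are logged, not fatal", {
  rec <- species_records(data.frame(species = c("A", "B", "C", "D"),
                                    dR = c(3, 5, 4, 6),
                                    homogeneity = c(0.2, 0.5, 0.4, 0.7)))
  bat <- run_contrasts(rec)
  expect_true("dR_vs_homogeneity" %in% names(bat))
  expect_true(any(grepl("recognised", attr(bat, "skipped"))))
  df <- as.data.frame(bat)
  expect_true(all(c("contrast", "p", "r2") %in% names(df)))
})
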