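#' Linear model between two species-level metrics
#'
#' Ordinary least squares \code{y ~ x} for metrics with a single value per
#' species. Reports the slope, the overall F statistic with (1, n - 2)
#' degrees of freedom, the p value and r-squared.
#'
#' @param x,y numeric vectors, one value per species (n >= 3).
#' @param response,predictor optional labels carried into the result.
#' @return an object of class \code{association_result}.
#' @export
fit_lm <- function(x, y, response = "y", predictor = "x") {
  if (length(x) != length(y)) stop("'x' and 'y' must have equal length")
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3L) stop("need at least 3 species")
  if (stats::var(x) == 0) stop("zero variance in predictor '", predictor, "'")
  fit <- stats::lm(y ~ x)
  sm <- summary(fit)
  Fv <- sm$fstatistic
  association_result(
    model = "LM", response = response, predictor = predictor,
    estimate = unname(stats::coef(fit)[2L]),
    statistic = unname(Fv[1L]), stat_name = "F",
    df = unname(c(Fv[2L], Fv[3L])),
    p = unname(stats::pf(Fv[1L], Fv[2L], Fv[3L], lower.tail = FALSE)),
    r2 = sm$r.squared)
}

#' Linear mixed model for draw-replicated breadth values
#'
#' Used when a species-level metric carries multiple pseudoreplicated
#' measurements — here, one dietary-breadth value per posterior prey tree.
#' Fits a random-intercept model by REML,
#' \code{draw_value ~ x + (1 | species)}, where \code{x} is a
#' species-level covariate: the tree draws are the response and the
#' species random intercept absorbs the draw-to-draw correlation within
#' species (the covariate is constant within species, so placing the
#' draws on the predictor side would leave the slope confounded with the
#' random intercept).
#'
#' The p value comes from a likelihood-ratio test between the full and
#' intercept-only models, both refitted by maximum likelihood. The
#' fixed-effect t statistic is reported with \code{n_species - 2} degrees
#' of freedom. Marginal and conditional r-squared follow the
#' variance-partition definition: fixed-effect variance over total, and
#' fixed-plus-random over total. A singular fit (random-intercept
#' variance estimated at zero) falls back to an ordinary LM on the
#' species means, with a warning.
#'
#' @param y numeric vector of draw-level response values (e.g. dRER, one
#'   entry per species x tree draw).
#' @param x numeric vector, same length, of the species-level covariate
#'   (repeated across the draws of a species).
#' @param species factor/character vector, same length, giving the species
#'   of each draw.
#' @param response,predictor labels for the result.
#' @return an object of class \code{association_result} with
#'   \code{r2_marginal} and \code{r2_conditional}.
#' @export
fit_lmm <- function(y, x, species, response = "y", predictor = "x") {
  if (length(unique(c(length(y), length(x), length(species)))) != 1L) {
    stop("'y', 'x' and 'species' must have equal length")
  }
  species <- factor(species)
  n_sp <- nlevels(species)
  if (n_sp < 3L) stop("need at least 3 species")
  if (min(table(species)) < 2L) stop("need >= 2 draws per species")
  if (stats::var(x) == 0) stop("zero variance in predictor '", predictor, "'")
  dat <- data.frame(y = y, x = x, species = species)
  fit <- suppressMessages(lme4::lmer(y ~ x + (1 | species), data = dat, REML = TRUE))
  vc <- as.data.frame(lme4::VarCorr(fit))
  var_rand <- vc$vcov[vc$grp == "species"]
  var_resid <- vc$vcov[vc$grp == "Residual"]
  if (lme4::isSingular(fit, tol = 1e-5) || var_rand < 1e-12) {
    warning("singular mixed-model fit (zero random-intercept variance); ",
            "falling back to LM on species means")
    agg <- stats::aggregate(dat[c("y", "x")], list(species = dat$species), mean)
    return(fit_lm(agg$x, agg$y, response = response, predictor = predictor))
  }
  beta <- lme4::fixef(fit)
  pred_fixed <- beta[1L] + beta[2L] * dat$x
  var_fixed <- sum((pred_fixed - mean(pred_fixed))^2) / length(pred_fixed)
  denom <- var_fixed + var_rand + var_resid
  tval <- stats::coef(summary(fit))["x", "t value"]
  ## LR test, both models by ML
  full_ml <- suppressMessages(lme4::lmer(y ~ x + (1 | species), data = dat, REML = FALSE))
  null_ml <- suppressMessages(lme4::lmer(y ~ 1 + (1 | species), data = dat, REML = FALSE))
  lr <- 2 * (stats::logLik(full_ml) - stats::logLik(null_ml))
  p <- stats::pchisq(as.numeric(lr), df = 1L, lower.tail = FALSE)
  association_result(
    model = "LMM", response = response, predictor = predictor,
    estimate = unname(beta[2L]),
    statistic = unname(tval), stat_name = "t",
    df = n_sp - 2L, p = p,
    r2_marginal = var_fixed / denom,
    r2_conditional = (var_fixed + var_rand) / denom)
}

association_result <- function(model, response, predictor, estimate,
                               statistic, stat_name, df, p,
                               r2 = NA_real_, r2_marginal = NA_real_,
                               r2_conditional = NA_real_) {
  structure(list(model = model, response = response, predictor = predictor,
                 estimate = estimate, statistic = statistic,
                 stat_name = stat_name, df = df, p = p, r2 = r2,
                 r2_marginal = r2_marginal, r2_conditional = r2_conditional),
            class = "association_result")
}

#' @export
print.association_result <- function(x, ...) {
  cat(sprintf("%s: %s ~ %s\n", x$model, x$response, x$predictor))
  cat(sprintf("  estimate = %.4g, %s = %.3f (df %s), p = %.4g\n",
              x$estimate, x$stat_name, x$statistic,
              paste(round(x$df, 1), collapse = ", "), x$p))
  if (!is.na(x$r2)) cat(sprintf("  r2 = %.3f\n", x$r2))
  if (!is.na(x$r2_marginal)) {
    cat(sprintf("  r2 marginal = %.3f, conditional = %.3f\n",
                x$r2_marginal, x$r2_conditional))
  }
  invisible(x)
}

#' @export
as.data.frame.association_result <- function(x, ...) {
  data.frame(model = x$model, response = x$response, predictor = x$predictor,
             estimate = x$estimate, stat = x$statistic,
             stat_name = x$stat_name, df = paste(round(x$df, 2), collapse = ","),
             p = x$p, r2 = x$r2, r2_marginal = x$r2_marginal,
             r2_conditional = x$r2_conditional)
}

#' Per-species record set
#'
#' Bundles, for one primer dataset (or the primer average), the per-species
#' metric table and the matrix of dRER tree draws.
#'
#' @param metrics data.frame with one row per species; must contain a
#'   \code{species} column, plus any of \code{dR}, \code{dRE},
#'   \code{levins}, \code{alpha}, \code{turnover}, \code{hunting_breadth},
#'   \code{habitat_breadth}, \code{roosting_breadth},
#'   \code{potential_range_cells}, \code{recognised_range_area},
#'   \code{homogeneity}.
#' @param drer_draws numeric matrix, rows = species (rownames matching
#'   \code{metrics$species}), columns = tree draws; or \code{NULL}.
#' @param primer label of the primer dataset (e.g. "Zeale", "Epp",
#'   "averaged").
#' @export
species_records <- function(metrics, drer_draws = NULL, primer = "averaged") {
  metrics <- as.data.frame(metrics)
  if (!"species" %in% names(metrics)) stop("metrics needs a 'species' column")
  if (!is.null(drer_draws)) {
    drer_draws <- as.matrix(drer_draws)
    if (is.null(rownames(drer_draws))) rownames(drer_draws) <- metrics$species
    if (!setequal(rownames(drer_draws), metrics$species)) {
      stop("drer_draws rownames must match metrics$species")
    }
    drer_draws <- drer_draws[match(metrics$species, rownames(drer_draws)), ,
                             drop = FALSE]
    metrics$dRER <- rowMeans(drer_draws)
  }
  structure(list(metrics = metrics, drer_draws = drer_draws, primer = primer),
            class = "species_records")
}

#' @export
print.species_records <- function(x, ...) {
  cat(sprintf("species_records (%s): %d species, %s dRER draws\n",
              x$primer, nrow(x$metrics),
              if (is.null(x$drer_draws)) "no" else ncol(x$drer_draws)))
  invisible(x)
}

#' Average the two primer datasets
#'
#' Per-metric arithmetic mean of the Zeale- and Epp-derived values for each
#' species. dRER tree draws are averaged draw-wise (draw k with draw k),
#' preserving the dispersion across draws that the mixed models use. A
#' species present in only one input is passed through and flagged in the
#' \code{averaged} column.
#'
#' @param a,b \code{\link{species_records}} for the two primer datasets.
#' @return a \code{species_records} with \code{primer = "averaged"}.
#' @export
average_primers <- function(a, b) {
  stopifnot(inherits(a, "species_records"), inherits(b, "species_records"))
  sp_all <- union(a$metrics$species, b$metrics$species)
  num_cols <- union(names(a$metrics), names(b$metrics))
  num_cols <- setdiff(num_cols, "species")
  rows <- lapply(sp_all, function(sp) {
    ra <- a$metrics[a$metrics$species == sp, , drop = FALSE]
    rb <- b$metrics[b$metrics$species == sp, , drop = FALSE]
    vals <- sapply(num_cols, function(cl) {
      va <- if (nrow(ra) && cl %in% names(ra)) ra[[cl]] else NA_real_
      vb <- if (nrow(rb) && cl %in% names(rb)) rb[[cl]] else NA_real_
      mean(c(va, vb), na.rm = TRUE)
    })
    cbind(data.frame(species = sp), as.data.frame(as.list(vals)),
          data.frame(averaged = nrow(ra) > 0 && nrow(rb) > 0))
  })
  metrics <- do.call(rbind, rows)
  draws <- NULL
  if (!is.null(a$drer_draws) || !is.null(b$drer_draws)) {
    if (!is.null(a$drer_draws) && !is.null(b$drer_draws) &&
        ncol(a$drer_draws) != ncol(b$drer_draws)) {
      stop("mismatched dRER draw counts between primers: ",
           ncol(a$drer_draws), " vs ", ncol(b$drer_draws))
    }
    nd <- max(ncol(a$drer_draws %||% matrix(nrow = 0, ncol = 0)),
              ncol(b$drer_draws %||% matrix(nrow = 0, ncol = 0)))
    draws <- matrix(NA_real_, nrow = length(sp_all), ncol = nd,
                    dimnames = list(sp_all, NULL))
    for (sp in sp_all) {
      da <- if (!is.null(a$drer_draws) && sp %in% rownames(a$drer_draws)) {
        a$drer_draws[sp, ] } else NULL
      db <- if (!is.null(b$drer_draws) && sp %in% rownames(b$drer_draws)) {
        b$drer_draws[sp, ] } else NULL
      draws[sp, ] <- if (is.null(da)) db else if (is.null(db)) da else (da + db) / 2
    }
    metrics$dRER <- rowMeans(draws)[metrics$species]
  }
  species_records(metrics, draws, primer = "averaged")
}

#' Run the dietary-spatial contrast battery
#'
#' Executes the standard set of associations between dietary breadth,
#' turnover, trait breadths and spatial metrics: LMs for metrics with a
#' single value per species, LMMs (via \code{\link{fit_lmm}}) wherever
#' dRER's tree draws enter. Contrasts whose inputs are missing from the
#' record set are skipped with a log entry. The conventional significance
#' threshold is p = 0.05; no multiple-testing correction is applied.
#'
#' @param records a \code{\link{species_records}} object.
#' @return object of class \code{association_battery}: list of
#'   \code{association_result}s named by contrast, with a \code{skipped}
#'   attribute listing contrasts that could not run.
#' @export
run_contrasts <- function(records) {
  stopifnot(inherits(records, "species_records"))
  m <- records$metrics
  if (nrow(m) < 3L) stop("contrast battery requires at least 3 species")
  dr <- records$drer_draws
  res <- list()
  skipped <- character(0)

  has <- function(...) all(c(...) %in% names(m)) &&
    all(vapply(c(...), function(cl) sum(is.finite(m[[cl]])) >= 3L, logical(1)))

  run_lm <- function(name, xcol, ycol) {
    if (has(xcol, ycol)) {
      r <- tryCatch(fit_lm(m[[xcol]], m[[ycol]], response = ycol, predictor = xcol),
                    error = function(e) conditionMessage(e))
      if (is.character(r)) skipped <<- c(skipped, paste0(name, " (", r, ")"))
      else res[[name]] <<- r
    } else skipped <<- c(skipped, name)
  }
  run_lmm <- function(name, xcol) {
    if (!is.null(dr) && has(xcol)) {
      k <- ncol(dr)
      r <- tryCatch(suppressWarnings(fit_lmm(
        y = as.vector(t(dr)),
        x = rep(m[[xcol]][match(rownames(dr), m$species)], each = k),
        species = rep(rownames(dr), each = k),
        response = "dRER", predictor = xcol)),
        error = function(e) conditionMessage(e))
      if (is.character(r)) skipped <<- c(skipped, paste0(name, " (", r, ")"))
      else res[[name]] <<- r
    } else skipped <<- c(skipped, name)
  }

  run_lm("recognised_vs_potential_range", "potential_range_cells", "recognised_range_area")
  run_lm("homogeneity_vs_recognised_range", "recognised_range_area", "homogeneity")
  run_lmm("dRER_vs_recognised_range", "recognised_range_area")
  run_lm("dR_vs_homogeneity", "homogeneity", "dR")
  run_lmm("dRER_vs_homogeneity", "homogeneity")
  run_lm("alpha_vs_dRER", "dRER", "alpha")
  run_lm("turnover_vs_dRER", "dRER", "turnover")
  run_lm("turnover_vs_homogeneity", "homogeneity", "turnover")
  for (tr in c("hunting_breadth", "habitat_breadth", "roosting_breadth")) {
    run_lmm(paste0(tr, "_vs_dRER"), tr)
    run_lm(paste0(tr, "_vs_homogeneity"), "homogeneity", tr)
    run_lm(paste0(tr, "_vs_potential_range"), "potential_range_cells", tr)
  }
  structure(res, skipped = skipped, class = "association_battery")
}

#' @export
print.association_battery <- function(x, ...) {
  cat("Association battery:\n")
  for (nm in names(x)) {
    r <- x[[nm]]
    cat(sprintf("  %-34s %s %s = %7.3f  p = %.4g%s\n", nm, r$model,
                r$stat_name, r$statistic, r$p,
                if (r$p < 0.05) " *" else ""))
  }
  sk <- attr(x, "skipped")
  if (length(sk)) cat("  skipped:", paste(sk, collapse = ", "), "\n")
  invisible(x)
}

#' @export
as.data.frame.association_battery <- function(x, ...) {
  out <- do.call(rbind, lapply(x, as.data.frame))
  cbind(data.frame(contrast = names(x)), out, row.names = NULL)
}
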