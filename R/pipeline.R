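#' Run the full dietary-niche-breadth pipeline
#'
#' Drives the analysis end to end, per primer dataset: quality control of
#' the replicated count table (\code{\link{qc_filter}}), conversion to
#' diet profiles, species-level breadth metrics (dR, dRE, dRER across the
#' tree set, Levins' index), alpha diversity and Jaccard-type turnover
#' from the multiplicative partition, then spatial metrics from the
#' suitability rasters and trait-axis breadths; primer datasets are
#' averaged (\code{\link{average_primers}}) before the contrast battery
#' (\code{\link{run_contrasts}}) is fitted.
#'
#' @param counts a \code{\link{replicate_count_table}} covering all
#'   primers and blanks (e.g. \code{sim$counts}), or a
#'   \code{sim_assemblage}, in which case \code{trees}, \code{rasters}
#'   and \code{traits} are taken from it.
#' @param trees \code{multiPhylo} tree set for dRER.
#' @param rasters named list of \code{\link{suitability_raster}}s, one per
#'   species.
#' @param traits optional data.frame of trait category counts (column
#'   \code{species} plus columns prefixed \code{hunting}, \code{habitat},
#'   \code{roosting}).
#' @param recognised_range optional data.frame(species,
#'   recognised_range_area) from external cartography.
#' @param mode profile mode, \code{"abundance"} or \code{"incidence"}.
#' @param min_replicates,min_reads,min_fraction QC thresholds (see
#'   \code{\link{qc_filter}}).
#' @param q order of diversity for the partition stage (default 1).
#' @param pool species-profile pooling rule (see
#'   \code{\link{dietary_breadth}}).
#' @return list of class \code{nichebreadth_run}: \code{records} (primer
#'   averaged \code{\link{species_records}}), \code{records_by_primer},
#'   \code{contrasts} (\code{association_battery}), \code{qc} (filtered
#'   tables by primer) and \code{profiles} (by primer).
#' @export
run_pipeline <- function(counts, trees = NULL, rasters = NULL, traits = NULL,
                         recognised_range = NULL,
                         mode = c("abundance", "incidence"),
                         min_replicates = 2L, min_reads = 5000L,
                         min_fraction = 2e-4, q = 1,
                         pool = c("mean", "reads")) {
  mode <- match.arg(mode)
  pool <- match.arg(pool)
  if (inherits(counts, "sim_assemblage")) {
    sim <- counts
    counts <- sim$counts
    trees <- trees %||% sim$trees
    rasters <- rasters %||% sim$rasters
    traits <- traits %||% sim$traits
  }
  stopifnot(inherits(counts, "replicate_count_table"))

  spat <- if (!is.null(rasters)) spatial_metrics(rasters) else NULL
  trb <- if (!is.null(traits)) trait_breadths(traits) else NULL

  primers <- unique(counts$meta$primer)
  qc_by_primer <- list(); prof_by_primer <- list(); rec_by_primer <- list()
  for (pr in primers) {
    sub <- subset_samples(counts, counts$meta$primer == pr)
    qc <- qc_filter(sub, min_replicates = min_replicates,
                    min_reads = min_reads, min_fraction = min_fraction)
    prof <- to_profiles(qc, mode = mode)
    qc_by_primer[[pr]] <- qc
    prof_by_primer[[pr]] <- prof
    rec_by_primer[[pr]] <- species_metrics(prof, trees = trees, q = q,
                                           pool = pool, primer = pr)
  }
  records <- Reduce(average_primers, rec_by_primer)
  records <- merge_species_columns(records, spat)
  records <- merge_species_columns(records, trb)
  records <- merge_species_columns(records, recognised_range)
  contrasts <- run_contrasts(records)
  structure(list(records = records, records_by_primer = rec_by_primer,
                 contrasts = contrasts, qc = qc_by_primer,
                 profiles = prof_by_primer),
            class = "nichebreadth_run")
}

#' @export
print.nichebreadth_run <- function(x, ...) {
  cat(sprintf("nichebreadth_run: %d species, %d primer dataset(s)\n",
              nrow(x$records$metrics), length(x$records_by_primer)))
  print(x$contrasts)
  invisible(x)
}

#' Subset a replicated count table by sample
#'
#' @param raw a \code{\link{replicate_count_table}}.
#' @param keep logical or index vector over samples (metadata rows).
#' @export
subset_samples <- function(raw, keep) {
  stopifnot(inherits(raw, "replicate_count_table"))
  raw$counts <- raw$counts[, keep, , drop = FALSE]
  raw$meta <- raw$meta[keep, , drop = FALSE]
  rownames(raw$meta) <- NULL
  raw
}

#' Species-level breadth metrics from individual profiles
#'
#' Computes, for every species present in \code{profiles}, dR, dRE,
#' Levins' index and (given trees) the dRER tree draws, plus the alpha
#' component and Jaccard-type turnover of the multiplicative partition
#' across the species' individuals.
#'
#' @param profiles a \code{diet_profiles} object.
#' @param trees \code{multiPhylo} (or \code{NULL} to skip dRER).
#' @param q order of diversity for the partition.
#' @param pool pooling rule for the species profile.
#' @param primer label for the resulting record set.
#' @return a \code{\link{species_records}}.
#' @export
species_metrics <- function(profiles, trees = NULL, q = 1,
                            pool = "mean", primer = "unknown") {
  stopifnot(inherits(profiles, "diet_profiles"))
  species <- sort(unique(profiles$meta$species))
  rows <- list(); draw_rows <- list()
  for (sp in species) {
    P <- profiles$p[profiles$meta$species == sp, , drop = FALSE]
    n_ind <- nrow(P)
    spp <- species_profile(P, pool = pool)
    part <- if (n_ind >= 2L) partition_diversity(P, q = q) else NULL
    rows[[sp]] <- data.frame(
      species = sp, n_individuals = n_ind,
      dR = hill_number(spp, 0), dRE = hill_number(spp, 1),
      levins = levins_index(spp),
      alpha = alpha_diversity(P, q = q),
      turnover = if (is.null(part)) NA_real_ else part$turnover,
      beta = if (is.null(part)) NA_real_ else part$beta)
    if (!is.null(trees)) {
      draw_rows[[sp]] <- dietary_breadth(P, "dRER", trees = trees,
                                         pool = pool)$draws
    }
  }
  metrics <- do.call(rbind, rows)
  rownames(metrics) <- NULL
  draws <- if (length(draw_rows)) do.call(rbind, draw_rows) else NULL
  species_records(metrics, draws, primer = primer)
}

#' Trait-axis breadths per species
#'
#' Computes the effective number of categories used on each behavioural
#' axis (hunting, habitat, roosting) from a table of category counts.
#'
#' @param traits data.frame with a \code{species} column and numeric
#'   columns whose names start with \code{hunting}, \code{habitat} or
#'   \code{roosting}.
#' @return data.frame(species, hunting_breadth, habitat_breadth,
#'   roosting_breadth).
#' @export
trait_breadths <- function(traits) {
  axes <- c("hunting", "habitat", "roosting")
  out <- lapply(seq_len(nrow(traits)), function(i) {
    vals <- vapply(axes, function(ax) {
      cols <- grep(paste0("^", ax), names(traits), value = TRUE)
      if (!length(cols)) return(NA_real_)
      trait_breadth(as.numeric(traits[i, cols]))
    }, numeric(1))
    data.frame(species = traits$species[i],
               hunting_breadth = vals[["hunting"]],
               habitat_breadth = vals[["habitat"]],
               roosting_breadth = vals[["roosting"]])
  })
  do.call(rbind, out)
}

## left-join extra per-species columns into a species_records object
merge_species_columns <- function(records, extra) {
  if (is.null(extra)) return(records)
  extra <- as.data.frame(extra)
  m <- merge(records$metrics, extra, by = "species", all.x = TRUE, sort = FALSE)
  m <- m[match(records$metrics$species, m$species), , drop = FALSE]
  rownames(m) <- NULL
  records$metrics <- m
  records
}
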