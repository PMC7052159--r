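#' Replicated OTU count table
#'
#' Container for raw metabarcoding read counts indexed by OTU, sample and
#' PCR replicate, together with per-sample metadata. This is the input to
#' the quality-control chain: blank-based contaminant removal, replicate
#' concordance, replicate collapse, sequencing-depth filtering and the
#' per-sample relative-abundance filter.
#'
#' @param counts 3-d integer array \code{[otu, sample, replicate]} with
#'   dimnames on the first two margins; all values must be non-negative.
#' @param meta data.frame with one row per sample and columns
#'   \code{sample_id}, \code{species}, \code{batch}, \code{primer},
#'   \code{is_blank} (logical) and \code{blank_kind} (one of
#'   \code{"extraction"}, \code{"library"}, \code{"pcr"}, \code{"none"}).
#' @return an object of class \code{replicate_count_table}.
#' @export
replicate_count_table <- function(counts, meta) {
  if (length(dim(counts)) != 3L) stop("'counts' must be a 3-d array [otu, sample, replicate]")
  if (anyNA(counts) || any(counts < 0)) stop("counts must be non-negative and NA-free")
  if (is.null(dimnames(counts)[[1L]]) || is.null(dimnames(counts)[[2L]])) {
    stop("'counts' needs otu and sample dimnames")
  }
  meta <- as.data.frame(meta, stringsAsFactors = FALSE)
  need <- c("sample_id", "species", "batch", "primer", "is_blank", "blank_kind")
  miss <- setdiff(need, names(meta))
  if (length(miss)) stop("metadata is missing columns: ", paste(miss, collapse = ", "))
  absent <- setdiff(dimnames(counts)[[2L]], meta$sample_id)
  if (length(absent)) stop("samples without metadata: ", paste(absent, collapse = ", "))
  meta <- meta[match(dimnames(counts)[[2L]], meta$sample_id), , drop = FALSE]
  rownames(meta) <- NULL
  bad_blank <- meta$is_blank & meta$blank_kind == "none"
  if (any(bad_blank)) stop("blank samples must declare a blank_kind")
  structure(list(counts = counts, meta = meta, provenance = list()),
            class = "replicate_count_table")
}

#' @export
print.replicate_count_table <- function(x, ...) {
  d <- dim(x$counts)
  cat(sprintf("replicate_count_table: %d OTUs x %d samples x %d replicates (%d blanks)\n",
              d[1L], d[2L], d[3L], sum(x$meta$is_blank)))
  invisible(x)
}

#' Filtered (replicate-collapsed) count table
#'
#' OTU-by-sample matrix of read counts after replicate collapse, carrying
#' sample metadata and a provenance log of every filter applied with its
#' parameters.
#'
#' @param counts non-negative integer matrix \code{[otu, sample]}.
#' @param meta per-sample metadata (see
#'   \code{\link{replicate_count_table}}); blank rows must be absent.
#' @param provenance list of applied-filter records.
#' @export
filtered_count_table <- function(counts, meta, provenance = list()) {
  counts <- as.matrix(counts)
  if (anyNA(counts) || any(counts < 0)) stop("counts must be non-negative and NA-free")
  meta <- meta[match(colnames(counts), meta$sample_id), , drop = FALSE]
  rownames(meta) <- NULL
  if (any(meta$is_blank)) stop("blank samples must be removed before collapse")
  structure(list(counts = counts, meta = meta, provenance = provenance),
            class = "filtered_count_table")
}

#' @export
print.filtered_count_table <- function(x, ...) {
  cat(sprintf("filtered_count_table: %d OTUs x %d samples; filters applied: %s\n",
              nrow(x$counts), ncol(x$counts),
              if (length(x$provenance)) {
                paste(vapply(x$provenance, `[[`, character(1), "step"), collapse = " -> ")
              } else "none"))
  invisible(x)
}

log_step <- function(obj, step, ...) {
  obj$provenance <- c(obj$provenance, list(c(list(step = step), list(...))))
  obj
}

#' Replicate-concordance filter
#'
#' For every non-blank sample, an OTU is retained only if it was detected
#' (count > 0) in at least \code{min_replicates} of the sample's PCR
#' replicates; otherwise its counts are zeroed in all replicates of that
#' sample. OTUs seen in a single replicate are the classic signature of
#' PCR/sequencing artefacts. Blank samples are exempt: their content feeds
#' the contaminant filter and must not be pre-cleaned.
#'
#' @param raw a \code{\link{replicate_count_table}}.
#' @param min_replicates minimum number of replicates an OTU must appear
#'   in (default 2, the two-of-three rule for triplicate PCRs).
#' @return a \code{replicate_count_table} with discordant detections zeroed.
#' @export
filter_replicate_concordance <- function(raw, min_replicates = 2L) {
  stopifnot(inherits(raw, "replicate_count_table"))
  R <- dim(raw$counts)[3L]
  if (min_replicates < 1L) stop("'min_replicates' must be >= 1")
  if (min_replicates > R) {
    stop(sprintf("min_replicates = %d exceeds the %d replicates available (e.g. sample '%s')",
                 min_replicates, R, raw$meta$sample_id[1L]))
  }
  occ <- apply(raw$counts > 0, c(1L, 2L), sum)   # otu x sample detection count
  keep <- occ >= min_replicates
  nonblank <- !raw$meta$is_blank
  mask <- array(TRUE, dim = dim(raw$counts))
  for (r in seq_len(R)) mask[, nonblank, r] <- keep[, nonblank]
  raw$counts <- raw$counts * mask
  log_step(raw, "replicate_concordance", min_replicates = min_replicates)
}

#' Blank-based contaminant removal
#'
#' Within each processing batch, any OTU detected in an extraction or
#' library blank of that batch is treated as a contaminant and zeroed in
#' all non-blank samples of the same batch (other batches are untouched).
#' PCR blanks are reported in the provenance log but not used for removal.
#' All blank samples are dropped from the table afterwards.
#'
#' @param raw a \code{\link{replicate_count_table}}.
#' @return a \code{replicate_count_table} without blank samples.
#' @export
remove_blank_contaminants <- function(raw) {
  stopifnot(inherits(raw, "replicate_count_table"))
  meta <- raw$meta
  removal_blank <- meta$is_blank & meta$blank_kind %in% c("extraction", "library")
  pcr_blank <- meta$is_blank & meta$blank_kind == "pcr"
  removed <- list()
  for (b in unique(meta$batch[removal_blank])) {
    bl <- removal_blank & meta$batch == b
    contam <- rowSums(raw$counts[, bl, , drop = FALSE]) > 0
    if (any(contam)) {
      tgt <- !meta$is_blank & meta$batch == b
      raw$counts[contam, tgt, ] <- 0
      removed[[as.character(b)]] <- dimnames(raw$counts)[[1L]][contam]
    }
  }
  pcr_seen <- character(0)
  if (any(pcr_blank)) {
    pcr_seen <- dimnames(raw$counts)[[1L]][
      rowSums(raw$counts[, pcr_blank, , drop = FALSE]) > 0]
  }
  keep <- !meta$is_blank
  raw$counts <- raw$counts[, keep, , drop = FALSE]
  raw$meta <- meta[keep, , drop = FALSE]
  rownames(raw$meta) <- NULL
  log_step(raw, "blank_removal", contaminants_by_batch = removed,
           pcr_blank_otus = pcr_seen)
}

#' Collapse PCR replicates
#'
#' Sums read counts across replicates of each sample, producing the
#' OTU-by-sample table the depth and relative-abundance filters operate
#' on. Summing (rather than averaging) preserves integer total depth, so
#' the minimum-depth threshold keeps its literal read-count meaning.
#' OTU rows that are zero in every sample are dropped.
#'
#' @param filtered a \code{replicate_count_table}, normally after
#'   \code{\link{remove_blank_contaminants}} and
#'   \code{\link{filter_replicate_concordance}}.
#' @return a \code{\link{filtered_count_table}}.
#' @export
collapse_replicates <- function(filtered) {
  stopifnot(inherits(filtered, "replicate_count_table"))
  m <- apply(filtered$counts, c(1L, 2L), sum)
  m <- m[rowSums(m) > 0, , drop = FALSE]
  out <- filtered_count_table(m, filtered$meta, filtered$provenance)
  log_step(out, "collapse_replicates", rule = "sum")
}

#' Minimum sequencing-depth filter
#'
#' Removes samples whose total read count after collapse is strictly below
#' \code{min_reads}; a sample with exactly \code{min_reads} reads is
#' retained. Shallow samples carry unreliable, richness-biased profiles.
#'
#' @param table a \code{\link{filtered_count_table}}.
#' @param min_reads minimum total reads per sample (default 5000).
#' @export
filter_min_depth <- function(table, min_reads = 5000L) {
  stopifnot(inherits(table, "filtered_count_table"), min_reads >= 0)
  depth <- colSums(table$counts)
  keep <- depth >= min_reads
  if (!any(keep)) stop("depth filter removed every sample (min_reads = ", min_reads, ")")
  table$counts <- table$counts[, keep, drop = FALSE]
  table$meta <- table$meta[keep, , drop = FALSE]
  rownames(table$meta) <- NULL
  log_step(table, "min_depth", min_reads = min_reads,
           samples_removed = sum(!keep))
}

#' Per-sample relative-abundance filter
#'
#' Within each sample, zeroes OTU counts whose share of the sample total
#' is strictly below \code{min_fraction} (default 0.02%), the signature of
#' false positives from PCR and sequencing error. The comparison is a
#' single pass against the pre-filter sample totals; totals are not
#' re-normalised between removals. OTU rows left empty everywhere are
#' dropped.
#'
#' @param table a \code{\link{filtered_count_table}}.
#' @param min_fraction minimum within-sample relative abundance in [0, 1)
#'   (default \code{2e-4}).
#' @export
filter_rel_abundance <- function(table, min_fraction = 2e-4) {
  stopifnot(inherits(table, "filtered_count_table"))
  if (min_fraction < 0 || min_fraction >= 1) stop("'min_fraction' must lie in [0, 1)")
  totals <- colSums(table$counts)
  frac <- sweep(table$counts, 2L, pmax(totals, 1), "/")
  table$counts[frac < min_fraction] <- 0
  table$counts <- table$counts[rowSums(table$counts) > 0, , drop = FALSE]
  log_step(table, "rel_abundance", min_fraction = min_fraction)
}

#' Full quality-control chain
#'
#' Applies, in order: blank-based contaminant removal, replicate
#' concordance, replicate collapse, the minimum-depth filter and the
#' relative-abundance filter. The order is recorded in the provenance log
#' together with every parameter; it matters for the relative-abundance
#' threshold, which is evaluated against post-collapse sample totals.
#'
#' @param raw a \code{\link{replicate_count_table}}.
#' @param min_replicates replicate-concordance threshold (default 2).
#' @param min_reads depth threshold (default 5000).
#' @param min_fraction relative-abundance threshold (default \code{2e-4}).
#' @return a \code{\link{filtered_count_table}}.
#' @export
qc_filter <- function(raw, min_replicates = 2L, min_reads = 5000L,
                      min_fraction = 2e-4) {
  raw |>
    remove_blank_contaminants() |>
    filter_replicate_concordance(min_replicates = min_replicates) |>
    collapse_replicates() |>
    filter_min_depth(min_reads = min_reads) |>
    filter_rel_abundance(min_fraction = min_fraction)
}

#' Rarefaction curve of a sample
#'
#' Expected OTU richness at increasing sub-sampling depths. By default the
#' expectation is analytic (hypergeometric: the chance that at least one
#' of an OTU's reads enters a without-replacement subsample of size m);
#' with \code{draws > 0} it is estimated by Monte-Carlo resampling
#' instead.
#'
#' @param sample_counts integer vector of OTU read counts for one sample.
#' @param step depth increment between curve points (> 0).
#' @param draws number of resampling draws (0 = analytic).
#' @param seed optional seed for the resampling mode.
#' @return data.frame with columns \code{depth} and \code{richness},
#'   monotone non-decreasing in depth; the final point is the full sample
#'   depth with the observed richness.
#' @export
rarefaction_curve <- function(sample_counts, step = 100L, draws = 0L, seed = NULL) {
  if (step <= 0) stop("'step' must be a positive integer")
  x <- sample_counts[sample_counts > 0]
  N <- sum(x)
  if (N <= 0) stop("sample has no reads")
  depths <- unique(c(seq(min(step, N), N, by = step), N))
  if (draws > 0L) {
    if (!is.null(seed)) set.seed(seed)
    pool <- rep.int(seq_along(x), x)
    rich <- vapply(depths, function(m) {
      mean(vapply(seq_len(draws), function(i) {
        length(unique(pool[sample.int(N, m)]))
      }, numeric(1)))
    }, numeric(1))
  } else {
    rich <- vapply(depths, function(m) {
      ## E[S_m] = sum_i 1 - C(N - x_i, m) / C(N, m), via lchoose
      p_absent <- exp(lchoose(N - x, m) - lchoose(N, m))
      sum(1 - p_absent)
    }, numeric(1))
  }
  data.frame(depth = depths, richness = rich)
}

#' Curvature index of a rarefaction curve
#'
#' Saturation measure: the area under the rarefaction curve divided by the
#' area of the rectangle spanning the curve's depth range at its maximum
#' richness. A fully saturated (flat) curve scores 1; a straight line
#' rising from the origin scores 0.5; real concave curves fall in between,
#' approaching 1 as sequencing depth outruns richness. Samples with an
#' index below a chosen threshold (0.9 by convention here) are flagged as
#' potentially under-sequenced; flagging never removes a sample — the
#' hard rule is the minimum-depth filter.
#'
#' @param curve data.frame from \code{\link{rarefaction_curve}} (columns
#'   \code{depth}, \code{richness}), sorted by depth.
#' @return a fraction in (0, 1].
#' @export
curvature_index <- function(curve) {
  if (nrow(curve) < 2L) stop("curve needs at least two points")
  d <- curve$depth
  r <- curve$richness
  if (is.unsorted(d, strictly = TRUE)) stop("curve depths must be strictly increasing")
  if (is.unsorted(r)) stop("curve must be monotone non-decreasing")
  auc <- sum(diff(d) * (utils::head(r, -1L) + utils::tail(r, -1L)) / 2)
  rect <- (max(d) - min(d)) * max(r)
  if (rect <= 0) stop("degenerate curve: zero-area enclosing rectangle")
  auc / rect
}

#' Under-sequencing flags for all samples of a table
#'
#' Convenience wrapper computing the curvature index of every sample and
#' flagging those below \code{threshold}.
#'
#' @param table a \code{\link{filtered_count_table}}.
#' @param step rarefaction depth increment.
#' @param threshold curvature below which a sample is flagged (default 0.9).
#' @return data.frame(sample_id, depth, richness, curvature, flagged).
#' @export
sequencing_saturation <- function(table, step = 500L, threshold = 0.9) {
  stopifnot(inherits(table, "filtered_count_table"))
  out <- lapply(colnames(table$counts), function(s) {
    x <- table$counts[, s]
    cv <- curvature_index(rarefaction_curve(x, step = step))
    data.frame(sample_id = s, depth = sum(x), richness = sum(x > 0),
               curvature = cv, flagged = cv < threshold)
  })
  do.call(rbind, out)
}

#' Diet profiles from a filtered count table
#'
#' Converts filtered counts into per-individual diet profiles. In
#' abundance mode \eqn{p_i = count_i / total}; in incidence mode each
#' detected OTU receives \eqn{1/S_{obs}}, i.e. presence/absence normalised
#' to sum one, which makes incidence profiles valid inputs to every Hill
#' computation. Empty samples are excluded with a warning.
#'
#' @param table a \code{\link{filtered_count_table}}.
#' @param mode \code{"abundance"} or \code{"incidence"}.
#' @return object of class \code{diet_profiles}: list with \code{p}
#'   (matrix, rows = samples, each summing to 1), \code{meta}, \code{mode}
#'   and \code{level = "individual"}.
#' @export
to_profiles <- function(table, mode = c("abundance", "incidence")) {
  stopifnot(inherits(table, "filtered_count_table"))
  mode <- match.arg(mode)
  if (nrow(table$counts) == 0L || ncol(table$counts) == 0L) stop("table is empty")
  m <- t(table$counts)
  if (mode == "incidence") m <- (m > 0) * 1
  tot <- rowSums(m)
  keep <- tot > 0
  if (!all(keep)) {
    warning(sum(!keep), " empty sample(s) excluded from profiles")
    m <- m[keep, , drop = FALSE]
    tot <- tot[keep]
  }
  structure(list(p = m / tot,
                 meta = table$meta[keep, , drop = FALSE],
                 mode = mode, level = "individual"),
            class = "diet_profiles")
}

#' @export
print.diet_profiles <- function(x, ...) {
  cat(sprintf("diet_profiles: %d %s-level %s profiles over %d OTUs\n",
              nrow(x$p), x$level, x$mode, ncol(x$p)))
  invisible(x)
}
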