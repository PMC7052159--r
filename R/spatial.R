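#' Habitat-suitability raster
#'
#' A 2-d grid of environmental suitability values in [0, 1] with a nodata
#' mask and a per-species minimum-suitability floor \code{s_min}. Cells
#' strictly above \code{s_min} constitute the potential range; the same
#' gate feeds the homogeneity computation so that the order-0 point of the
#' breadth profile coincides with potential range size.
#'
#' @param values numeric matrix of suitabilities; \code{NA} marks nodata.
#' @param s_min minimum-suitability floor in [0, 1). If \code{NULL}
#'   (default) it falls back to the smallest strictly positive suitability
#'   present; the floor the species' distribution model estimated should
#'   be supplied whenever available.
#' @return an object of class \code{suitability_raster}.
#' @export
suitability_raster <- function(values, s_min = NULL) {
  values <- as.matrix(values)
  ok <- !is.na(values)
  if (!any(ok)) stop("raster is all nodata")
  if (any(values[ok] < 0 | values[ok] > 1)) stop("suitability values must lie in [0, 1]")
  if (is.null(s_min)) {
    pos <- values[ok & values > 0]
    s_min <- if (length(pos)) min(pos) else 0
  }
  if (s_min < 0 || s_min >= 1) stop("'s_min' must lie in [0, 1)")
  structure(list(values = values, s_min = s_min), class = "suitability_raster")
}

#' @export
print.suitability_raster <- function(x, ...) {
  cat(sprintf("suitability_raster: %d x %d cells (%d nodata), s_min = %g\n",
              nrow(x$values), ncol(x$values), sum(is.na(x$values)), x$s_min))
  invisible(x)
}

qualifying_cells <- function(raster) {
  v <- raster$values
  v[!is.na(v) & v > raster$s_min]
}

#' Potential range size
#'
#' Number of raster cells with suitability strictly above the species'
#' minimum-suitability floor. Cells are counted, not area-weighted; for
#' unprojected geographic grids spanning wide latitudes this conflates
#' cell count with area.
#'
#' @param raster a \code{\link{suitability_raster}}.
#' @return integer cell count.
#' @export
potential_range_size <- function(raster) {
  stopifnot(inherits(raster, "suitability_raster"))
  length(qualifying_cells(raster))
}

#' Distribution homogeneity
#'
#' The Hill-number evenness factor of the suitability distribution:
#' restrict to cells above \code{s_min}, normalise suitabilities to
#' \eqn{p_c = s_c / \sum s_c}, and divide the Hill number of order 1 by
#' the Hill number of order 0. Equals 1 when all qualifying cells are
#' equally suitable and approaches 0 as suitability concentrates in few
#' cells. Invariant to rescaling all suitabilities by a positive constant.
#'
#' @param raster a \code{\link{suitability_raster}}.
#' @return fraction in (0, 1].
#' @export
distribution_homogeneity <- function(raster) {
  stopifnot(inherits(raster, "suitability_raster"))
  s <- qualifying_cells(raster)
  if (length(s) == 0L) stop("no cells above s_min = ", raster$s_min)
  evenness_factor(s)
}

#' Spatial breadth profile over orders of diversity
#'
#' Hill numbers of the normalised cell-suitability distribution at each
#' order in \code{q_grid}: the "absolute spatial breadth", an effective
#' number of equally suitable cells. The relative breadth divides by the
#' qualifying cell count, so the q = 0 entry of the absolute profile is
#' the potential range size and the relative profile is 1 at q = 0.
#'
#' @param raster a \code{\link{suitability_raster}}.
#' @param q_grid numeric vector of orders (default \code{c(0, 1, 2)}).
#' @return data.frame(q, breadth, relative).
#' @export
breadth_profile <- function(raster, q_grid = c(0, 1, 2)) {
  stopifnot(inherits(raster, "suitability_raster"))
  s <- qualifying_cells(raster)
  if (length(s) == 0L) stop("no cells above s_min = ", raster$s_min)
  b <- vapply(q_grid, function(q) hill_number(s, q), numeric(1))
  data.frame(q = q_grid, breadth = b, relative = b / length(s))
}

#' Per-species spatial metrics table
#'
#' @param rasters named list of \code{\link{suitability_raster}} objects,
#'   one per species.
#' @return data.frame(species, cells_total, potential_range_cells,
#'   homogeneity, s_min).
#' @export
spatial_metrics <- function(rasters) {
  out <- lapply(names(rasters), function(sp) {
    r <- rasters[[sp]]
    data.frame(species = sp,
               cells_total = sum(!is.na(r$values)),
               potential_range_cells = potential_range_size(r),
               homogeneity = distribution_homogeneity(r),
               s_min = r$s_min)
  })
  do.call(rbind, out)
}

#' Read an ESRI ASCII grid
#'
#' Parses the plain-text ASCII grid dialect (ncols/nrows/xllcorner/
#' yllcorner/cellsize/NODATA_value header followed by rows of values) into
#' a \code{\link{suitability_raster}}. Nodata cells become \code{NA}.
#'
#' @param path file path.
#' @param s_min optional minimum-suitability floor (see
#'   \code{\link{suitability_raster}}).
#' @export
read_ascii_grid <- function(path, s_min = NULL) {
  lines <- readLines(path)
  hdr <- list()
  i <- 1L
  while (i <= length(lines) && grepl("^\\s*[A-Za-z_]+\\s", lines[i])) {
    kv <- strsplit(trimws(lines[i]), "\\s+")[[1L]]
    hdr[[tolower(kv[1L])]] <- as.numeric(kv[2L])
    i <- i + 1L
  }
  for (k in c("ncols", "nrows")) {
    if (is.null(hdr[[k]])) stop("ASCII grid header missing ", k)
  }
  vals <- scan(text = paste(lines[i:length(lines)], collapse = "\n"),
               quiet = TRUE)
  nr <- hdr$nrows; nc <- hdr$ncols
  if (length(vals) != nr * nc) {
    stop(sprintf("expected %d values, found %d", nr * nc, length(vals)))
  }
  m <- matrix(vals, nrow = nr, ncol = nc, byrow = TRUE)
  if (!is.null(hdr$nodata_value)) m[m == hdr$nodata_value] <- NA
  r <- suitability_raster(m, s_min = s_min)
  r$xllcorner <- hdr$xllcorner %||% 0
  r$yllcorner <- hdr$yllcorner %||% 0
  r$cellsize <- hdr$cellsize %||% 1
  r
}

#' Write a raster as an ESRI ASCII grid
#'
#' @param raster a \code{\link{suitability_raster}}.
#' @param path output file path.
#' @param nodata value standing in for \code{NA} cells (default -9999).
#' @export
write_ascii_grid <- function(raster, path, nodata = -9999) {
  stopifnot(inherits(raster, "suitability_raster"))
  m <- raster$values
  hdr <- c(sprintf("ncols %d", ncol(m)),
           sprintf("nrows %d", nrow(m)),
           sprintf("xllcorner %.6g", raster$xllcorner %||% 0),
           sprintf("yllcorner %.6g", raster$yllcorner %||% 0),
           sprintf("cellsize %.6g", raster$cellsize %||% 1),
           sprintf("NODATA_value %.6g", nodata))
  m[is.na(m)] <- nodata
  body <- apply(m, 1L, function(row) paste(format(row, digits = 17, trim = TRUE,
                                                  scientific = FALSE),
                                           collapse = " "))
  writeLines(c(hdr, body), path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
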