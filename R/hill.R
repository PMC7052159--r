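#' Hill number (effective number of OTUs) of a diet profile
#'
#' Computes the neutral Hill number of order \code{q} of a relative-abundance
#' (or relative-incidence) vector: \eqn{(\sum_i p_i^q)^{1/(1-q)}} for
#' \eqn{q \neq 1} and \eqn{\exp(-\sum_i p_i \log p_i)} at \eqn{q = 1}
#' (the continuous limit, handled analytically). Zero-abundance entries are
#' ignored; the vector is renormalised to sum to one, so raw counts are
#' accepted.
#'
#' In the dietary-breadth vocabulary used throughout the package, the Hill
#' number at \code{q = 0} is dR (richness), at \code{q = 1} it is dRE
#' (richness + evenness, the exponential of Shannon entropy) and at
#' \code{q = 2} it is the inverse Simpson concentration, identical to
#' Levins' index.
#'
#' @param p numeric vector of abundances or proportions; at least one entry
#'   must be positive and none may be negative.
#' @param q order of diversity, a single number \code{>= 0}. Larger \code{q}
#'   weighs abundant OTUs more heavily.
#' @return a single number \code{>= 1}: the effective number of equally
#'   abundant OTUs.
#' @examples
#' hill_number(c(0.5, 0.5), 1)      # 2: two equally common prey
#' hill_number(c(0.8, 0.1, 0.1), 0) # 3: richness ignores abundance
#' @export
hill_number <- function(p, q) {
  p <- validate_profile(p)
  if (length(q) != 1L || !is.finite(q)) stop("'q' must be a single finite number")
  if (q < 0) stop("order of diversity 'q' must be >= 0")
  ## uniform profiles return the support size exactly, at every order
  if (all(p == p[1L])) return(length(p))
  if (abs(q - 1) < 1e-9) {
    exp(-sum(p * log(p)))
  } else {
    sum(p^q)^(1 / (1 - q))
  }
}

## normalize and check a profile vector; drops zeros, keeps names
validate_profile <- function(p) {
  if (!is.numeric(p) || length(p) == 0L) stop("profile must be a non-empty numeric vector")
  if (anyNA(p)) stop("profile contains NA")
  if (any(p < 0)) stop("profile contains negative values")
  s <- sum(p)
  if (s <= 0) stop("profile has no positive entries")
  p <- p[p > 0]
  p / sum(p)
}

#' Phylogenetic Hill number (effective number of lineages)
#'
#' Computes the abundance-weighted phylogenetic Hill number of order
#' \code{q} of a diet profile on a rooted prey tree with branch lengths,
#' following the mean-phylogenetic-diversity formulation: with branch set
#' \eqn{B} of the tree pruned to the profile's support, branch abundance
#' \eqn{a_i} = sum of \eqn{p} over leaves descending branch \eqn{i}, and
#' mean depth \eqn{\bar T = \sum_{i \in B} L_i a_i},
#' \deqn{{}^qPD = \Big[\sum_{i \in B} (L_i/\bar T)\, a_i^q\Big]^{1/(1-q)}}
#' with the \eqn{q \to 1} limit \eqn{\exp(-\sum_i (L_i/\bar T) a_i \log a_i)}.
#' On a star tree with equal branch lengths this reduces to the neutral
#' \code{\link{hill_number}}; rescaling all branch lengths by a constant
#' leaves the value unchanged.
#'
#' @param p named numeric vector of abundances over OTUs; names must match
#'   tip labels of \code{tree}.
#' @param tree an \code{ape} \code{phylo} object whose tip labels cover the
#'   support of \code{p}.
#' @param q order of diversity \code{>= 0}.
#' @param prune prune the tree to the support of \code{p} before computing
#'   mean depth (default \code{TRUE}): diversity of the consumed assemblage,
#'   not of the reference tree.
#' @return effective number of equally abundant, equally distinct lineages.
#' @export
phylo_hill_number <- function(p, tree, q, prune = TRUE) {
  if (!inherits(tree, "phylo")) stop("'tree' must be an ape 'phylo' object")
  if (is.null(names(p))) stop("'p' must be named by OTU (tip label)")
  if (length(q) != 1L || !is.finite(q) || q < 0) stop("'q' must be a single number >= 0")
  p <- p[p > 0]
  missing <- setdiff(names(p), tree$tip.label)
  if (length(missing) > 0L) {
    stop("OTUs absent from the tree: ", paste(missing, collapse = ", "))
  }
  p <- p / sum(p)
  if (prune && length(p) < length(tree$tip.label)) {
    if (length(p) == 1L) return(1)
    tree <- ape::keep.tip(tree, names(p))
  }
  ab <- branch_abundances(tree, p)
  keep <- ab$a > 0 & ab$L > 0
  a <- ab$a[keep]
  L <- ab$L[keep]
  Tbar <- sum(L * a)
  if (!is.finite(Tbar) || Tbar <= 0) stop("degenerate tree: mean depth is zero")
  w <- L / Tbar
  if (abs(q - 1) < 1e-9) {
    exp(-sum(w * a * log(a)))
  } else {
    sum(w * a^q)^(1 / (1 - q))
  }
}

## abundance of each branch = sum of tip abundances descending it,
## via a single postorder sweep over the edge matrix
branch_abundances <- function(tree, p) {
  ntip <- length(tree$tip.label)
  tree <- ape::reorder.phylo(tree, "postorder")
  nn <- ntip + tree$Nnode
  node_ab <- numeric(nn)
  node_ab[seq_len(ntip)] <- p[tree$tip.label]
  ne <- nrow(tree$edge)
  for (e in seq_len(ne)) {
    child <- tree$edge[e, 2L]
    parent <- tree$edge[e, 1L]
    node_ab[parent] <- node_ab[parent] + node_ab[child]
  }
  list(a = node_ab[tree$edge[, 2L]], L = tree$edge.length)
}

#' Evenness factor of a profile
#'
#' Ratio of the Hill number of order 1 to the Hill number of order 0.
#' Equals 1 when the profile is uniform on its support and approaches 0 as
#' abundance concentrates on few OTUs. The same quantity, applied to the
#' normalised cell-suitability distribution of a raster, is the
#' distribution homogeneity of \code{\link{distribution_homogeneity}}.
#'
#' @inheritParams hill_number
#' @return a fraction in (0, 1].
#' @export
evenness_factor <- function(p) {
  hill_number(p, 1) / hill_number(p, 0)
}

#' Levins' index of niche breadth
#'
#' The reciprocal of the Simpson concentration, \eqn{1/\sum_i p_i^2},
#' identical to the Hill number of order 2. Included because it is the most
#' common breadth metric in the niche literature; it weighs dominant prey
#' heavily and ignores phylogenetic structure.
#'
#' @inheritParams hill_number
#' @export
levins_index <- function(p) {
  p <- validate_profile(p)
  1 / sum(p^2)
}

#' Breadth of a behavioural trait axis
#'
#' Effective number of trait categories used by a species (hunting mode,
#' habitat type, roost type), computed as the Hill number of order 1
#' (exponential Shannon diversity) of the normalised category profile.
#'
#' @param trait_profile numeric vector of counts or proportions over trait
#'   categories.
#' @export
trait_breadth <- function(trait_profile) {
  hill_number(trait_profile, 1)
}

#' Species-level dietary niche breadth with tree uncertainty
#'
#' Pools the individual diet profiles of one predator species into a
#' species-level profile and computes one of the breadth metrics:
#' \describe{
#'   \item{dR}{richness; neutral Hill number of order 0}
#'   \item{dRE}{richness + evenness; neutral Hill number of order 1}
#'   \item{dRER}{richness + evenness + regularity; phylogenetic Hill number
#'     of order 1, evaluated once per tree in \code{trees} so that the
#'     uncertainty of the prey phylogeny propagates into the estimate}
#' }
#' Pooling is, by default, the equal-weight arithmetic mean of the
#' individual relative-abundance (or incidence) vectors, renormalised;
#' this removes sequencing-depth differences between individuals. Read
#' pooling (summing counts before normalising) is available via
#' \code{pool = "reads"} when the rows of \code{profiles} are raw counts.
#'
#' @param profiles numeric matrix, one row per individual of the species,
#'   columns named by OTU; rows are profiles (or counts).
#' @param metric one of \code{"dR"}, \code{"dRE"}, \code{"dRER"}.
#' @param trees a \code{multiPhylo} set of prey trees; required for
#'   \code{"dRER"}, ignored otherwise.
#' @param pool \code{"mean"} (default) or \code{"reads"}.
#' @return an object of class \code{breadth_estimate}: list with
#'   \code{metric}, \code{mean}, \code{se} (standard error across tree
#'   draws, 0 for tree-free metrics), \code{draws} (per-tree values, for
#'   dRER) and \code{n_draws}.
#' @export
dietary_breadth <- function(profiles, metric = c("dR", "dRE", "dRER"),
                            trees = NULL, pool = c("mean", "reads")) {
  metric <- match.arg(metric)
  pool <- match.arg(pool)
  sp <- species_profile(profiles, pool = pool)
  if (metric == "dR") {
    out <- breadth_estimate(metric, mean = hill_number(sp, 0))
  } else if (metric == "dRE") {
    out <- breadth_estimate(metric, mean = hill_number(sp, 1))
  } else {
    if (is.null(trees)) stop("metric 'dRER' requires a tree set ('trees')")
    trees <- as_treeset(trees)
    vals <- vapply(trees, function(tr) phylo_hill_number(sp, tr, q = 1),
                   numeric(1))
    out <- breadth_estimate(metric, mean = mean(vals),
                            se = stats::sd(vals) / sqrt(length(vals)),
                            draws = vals)
  }
  out
}

#' Pool individual profiles into a species profile
#'
#' @param profiles matrix with one row per individual.
#' @param pool equal-weight mean of renormalised rows (\code{"mean"}) or
#'   column sums of raw counts (\code{"reads"}).
#' @return named numeric vector summing to one.
#' @export
species_profile <- function(profiles, pool = c("mean", "reads")) {
  pool <- match.arg(pool)
  profiles <- as_profile_matrix(profiles)
  if (pool == "mean") {
    rs <- rowSums(profiles)
    if (any(rs <= 0)) stop("every individual profile must have positive total")
    sp <- colMeans(profiles / rs)
  } else {
    sp <- colSums(profiles)
  }
  sp / sum(sp)
}

as_profile_matrix <- function(profiles) {
  if (is.numeric(profiles) && is.null(dim(profiles))) {
    profiles <- matrix(profiles, nrow = 1L,
                       dimnames = list(NULL, names(profiles)))
  }
  profiles <- as.matrix(profiles)
  if (is.null(colnames(profiles))) {
    colnames(profiles) <- paste0("OTU_", seq_len(ncol(profiles)))
  }
  if (anyNA(profiles) || any(profiles < 0)) stop("profiles must be non-negative and NA-free")
  profiles
}

breadth_estimate <- function(metric, mean, se = 0, draws = NULL) {
  stopifnot(mean >= 1 - 1e-9, se >= 0)
  structure(list(metric = metric, mean = mean, se = se, draws = draws,
                 n_draws = if (is.null(draws)) 0L else length(draws)),
            class = "breadth_estimate")
}

#' @export
print.breadth_estimate <- function(x, ...) {
  cat(sprintf("%s = %.4f", x$metric, x$mean))
  if (x$n_draws > 0L) {
    cat(sprintf(" (SE %.4f across %d tree draws)", x$se, x$n_draws))
  }
  cat("\n")
  invisible(x)
}

## coerce single tree / list / multiPhylo to a plain list of phylo
as_treeset <- function(trees) {
  if (inherits(trees, "phylo")) return(list(trees))
  if (inherits(trees, "multiPhylo")) return(unclass(trees))
  if (is.list(trees) && all(vapply(trees, inherits, logical(1), "phylo"))) {
    return(trees)
  }
  stop("'trees' must be a phylo, multiPhylo, or list of phylo objects")
}
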