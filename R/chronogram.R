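# Ultrametricization (penalized-likelihood rate smoothing, root scaled
# to 1), fixed-pairwise-clock age conversion, and least-squares clock-rate
# estimation from calibration nodes.

node_heights <- function(phy) {
  # height above the tips (assumes ultrametric); names = node numbers
  depth <- ape::node.depth.edgelength(phy)
  max(depth) - depth
}

is_ultrametric_strict <- function(phy, tol = 1e-9) {
  depth <- ape::node.depth.edgelength(phy)
  tips <- depth[seq_len(ape::Ntip(phy))]
  diff(range(tips)) <= tol * max(depth)
}

#' Ultrametricize a phylogram by penalized-likelihood smoothing
#'
#' Wraps Sanderson's penalized-likelihood method (as implemented by
#' `ape::chronopl`): branch substitution counts are modelled as Poisson and
#' rate changes between neighbouring branches are penalized by the smoothing
#' parameter `lambda`. The root height is normalized to exactly 1, the
#' convention used downstream by the GMYC stage.
#'
#' @param tree rooted, fully bifurcating `phylo` with positive branch
#'   lengths (collapse identical haplotypes first: zero-length branches must
#'   be resolved upstream).
#' @param lambda smoothing parameter (default 1); larger values force a
#'   more clock-like solution.
#' @param cv if `TRUE`, choose `lambda` from `10^(-2..2)` by the
#'   cross-validation score reported by the smoother.
#' @return list of class `mt_chronogram`: `tree` (ultrametric, root height
#'   1), `lambda`, `root_age = 1`, `ages = NULL` (see [apply_fixed_clock()]).
#' @export
ultrametricize <- function(tree, lambda = 1, cv = FALSE) {
  stopifnot(inherits(tree, "phylo"))
  if (!ape::is.rooted(tree)) stop("tree must be rooted")
  if (!ape::is.binary(tree))
    stop("tree must be fully bifurcating: resolve zero-length/polytomous ",
         "branches (collapse identical haplotypes) before smoothing")
  if (any(tree$edge.length <= 0))
    stop("all branch lengths must be strictly positive; collapse identical ",
         "haplotypes to remove zero-length branches")
  if (cv) {
    grid <- 10^seq(-2, 2, by = 1)
    fits <- lapply(grid, function(l)
      suppressWarnings(ape::chronopl(tree, lambda = l, age.min = 1, CV = TRUE)))
    scores <- vapply(fits, function(f) sum(attr(f, "D2")), numeric(1))
    best <- which.min(scores)
    chr <- fits[[best]]
    lambda <- grid[best]
  } else {
    chr <- suppressWarnings(ape::chronopl(tree, lambda = lambda, age.min = 1))
  }
  chr$edge.length <- chr$edge.length / max(ape::node.depth.edgelength(chr))
  structure(list(tree = chr, lambda = lambda, root_age = 1, ages = NULL,
                 rate = NULL),
            class = "mt_chronogram")
}

#' Wrap an already ultrametric tree as a chronogram
#'
#' @param tree ultrametric `phylo`.
#' @param normalize if `TRUE` (default) rescale so the root height is 1.
#' @return `mt_chronogram`.
#' @export
as_chronogram <- function(tree, normalize = TRUE) {
  stopifnot(inherits(tree, "phylo"))
  if (!is_ultrametric_strict(tree, tol = 1e-6))
    stop("tree is not ultrametric; use ultrametricize()")
  if (normalize)
    tree$edge.length <- tree$edge.length / max(ape::node.depth.edgelength(tree))
  structure(list(tree = tree, lambda = NA_real_, root_age = 1, ages = NULL,
                 rate = NULL),
            class = "mt_chronogram")
}

#' @export
print.mt_chronogram <- function(x, ...) {
  cat("mt_chronogram:", ape::Ntip(x$tree), "tips, root height",
      format(max(ape::node.depth.edgelength(x$tree))), "\n")
  if (!is.null(x$ages))
    cat(sprintf("Absolute ages attached (rate %.4g pairwise/MY); root age %.4g MY\n",
                x$rate, max(x$ages)))
  invisible(x)
}

#' Convert relative node heights to absolute ages under a fixed clock
#'
#' The clock is expressed as pairwise divergence per million years (two
#' lineages diverging from a node accumulate `rate` difference per MY), so
#' `age(node) = 2 * per-lineage depth / rate`. `root_divergence` states the
#' expected pairwise substitutions-per-site divergence spanned by the root,
#' translating the unit-height chronogram back to substitution units.
#'
#' @param chrono `mt_chronogram`.
#' @param root_divergence expected pairwise divergence (substitutions/site)
#'   at the root, e.g. the mean p-distance between the two basal clades.
#' @param rate pairwise divergence per million years (default 0.04: the
#'   mygalomorph 16S rate of 4 percent/MY).
#' @return `mt_chronogram` with `ages` (named by node number, in MY) and
#'   `rate` filled in.
#' @export
apply_fixed_clock <- function(chrono, root_divergence, rate = 0.04) {
  stopifnot(inherits(chrono, "mt_chronogram"), rate > 0,
            root_divergence >= 0)
  h <- node_heights(chrono$tree)          # relative, root = 1
  # per-lineage depth in subst/site = h * root_divergence/2;
  # pairwise divergence at a node = 2 * per-lineage depth
  ages <- h * root_divergence / rate
  chrono$ages <- ages
  chrono$rate <- rate
  chrono
}

#' Estimate a pairwise clock rate from calibration nodes
#'
#' Weighted least squares on calibrated node ages: minimizes
#' `sum(((2 * depth_subst / r - age) / sd)^2)` over the rate `r`, where
#' `depth_subst` is the per-lineage substitution depth of each calibrated
#' node. With `age = 2 d / r` linear in `1/r`, the optimum is closed-form;
#' a profile interval is reported from the curvature.
#'
#' @param chrono `mt_chronogram` (relative heights, root = 1).
#' @param root_divergence pairwise divergence (subst/site) at the root,
#'   giving substitution units.
#' @param calibrations data.frame with columns `node` (either an internal
#'   node number or a vector-valued list column `tips` of tip labels whose
#'   MRCA is calibrated), `age` (MY), `sd` (MY).
#' @return list: `rate` (pairwise per MY), `interval` (approx 95 percent),
#'   `per_node` data.frame of fitted ages.
#' @export
estimate_rate <- function(chrono, root_divergence, calibrations) {
  stopifnot(inherits(chrono, "mt_chronogram"), nrow(calibrations) >= 1)
  tr <- chrono$tree
  h <- node_heights(tr)
  ntip <- ape::Ntip(tr)
  nodes <- integer(nrow(calibrations))
  for (i in seq_len(nrow(calibrations))) {
    nd <- if (!is.null(calibrations$tips)) {
      ape::getMRCA(tr, calibrations$tips[[i]])
    } else calibrations$node[i]
    if (nd <= ntip) stop("calibration placed on a tip, not a clade")
    nodes[i] <- nd
  }
  d_pair <- h[nodes] * root_divergence     # pairwise divergence at node
  age <- calibrations$age
  sd <- if (!is.null(calibrations$sd)) calibrations$sd else rep(1, length(age))
  # age_hat = d_pair / r  =>  WLS in u = 1/r: min sum w (d u - age)^2
  w <- 1 / sd^2
  u <- sum(w * d_pair * age) / sum(w * d_pair^2)
  rate <- 1 / u
  # delta-method interval on r from curvature in u
  se_u <- sqrt(1 / sum(w * d_pair^2))
  lo <- 1 / (u + 1.96 * se_u)
  hi <- 1 / max(u - 1.96 * se_u, .Machine$double.eps)
  list(rate = rate, interval = c(lower = lo, upper = hi),
       per_node = data.frame(node = nodes, pairwise_divergence = d_pair,
                             calibration_age = age,
                             fitted_age = d_pair / rate))
}

#' Export a chronogram with ages as Newick and TSV
#'
#' @param chrono `mt_chronogram` (ages optional).
#' @param newick_path,tsv_path output file paths (either may be `NULL`).
#' @return invisible list of written paths.
#' @export
write_chronogram <- function(chrono, newick_path = NULL, tsv_path = NULL) {
  if (!is.null(newick_path)) ape::write.tree(chrono$tree, newick_path)
  if (!is.null(tsv_path)) {
    h <- node_heights(chrono$tree)
    df <- data.frame(node = seq_along(h), relative_height = h,
                     age_my = if (is.null(chrono$ages)) NA else chrono$ages)
    utils::write.table(df, tsv_path, sep = "\t", row.names = FALSE,
                       quote = FALSE)
  }
  invisible(list(newick = newick_path, tsv = tsv_path))
}
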