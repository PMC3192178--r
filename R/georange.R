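# Maximum-likelihood ancestral-location and dispersal estimation under a
# spatially explicit Brownian random walk on an ultrametric tree
# (PhyloMapper-style), with replicated smoothing starts and seeded
# hill-climbing restarts.

#' Project lat/lon to a local equirectangular plane (km)
#'
#' Degrees are not isotropic; before fitting, coordinates are projected
#' about the tip centroid: `x = (lon - lon0) * 111.32 * cos(lat0)`,
#' `y = (lat - lat0) * 110.57` km.
#'
#' @param lat,lon decimal degrees.
#' @param origin optional `c(lat0, lon0)`; defaults to the centroid.
#' @return list with `xy` (n x 2 matrix, km) and `origin`.
#' @export
project_coords <- function(lat, lon, origin = NULL) {
  if (is.null(origin)) origin <- c(mean(lat), mean(lon))
  x <- (lon - origin[2L]) * 111.32 * cos(origin[1L] * pi / 180)
  y <- (lat - origin[1L]) * 110.57
  list(xy = cbind(x = x, y = y), origin = origin)
}

unproject_coords <- function(xy, origin) {
  lon <- xy[2L] / (111.32 * cos(origin[1L] * pi / 180)) + origin[2L]
  lat <- xy[1L] / 110.57 + origin[1L]
  c(lat = lat, lon = lon)
}

#' Brownian pruning log-likelihood of tip coordinates
#'
#' Displacement along each branch is bivariate normal with mean zero and
#' variance `psi * branch length` per axis (axes independent). The
#' likelihood of the tip coordinates given the root location is computed by
#' Felsenstein's peeling on each axis.
#'
#' @param tree rooted `phylo` with branch lengths.
#' @param xy n x 2 matrix of tip coordinates, rows in `tree$tip.label` order
#'   (or named; names are matched).
#' @param root length-2 root coordinate.
#' @param psi dispersal variance per unit branch length per axis (> 0).
#' @return scalar log-likelihood.
#' @export
brownian_loglik <- function(tree, xy, root, psi) {
  stopifnot(inherits(tree, "phylo"), psi > 0)
  if (!is.null(rownames(xy))) xy <- xy[tree$tip.label, , drop = FALSE]
  bm_peel(bm_prepare(tree), xy, root, psi)
}

# Precompute the peeling traversal (children processed before parents).
bm_prepare <- function(tree) {
  n <- ape::Ntip(tree)
  children <- split(seq_len(nrow(tree$edge)), tree$edge[, 1L])
  inner <- as.integer(names(children))
  depth <- ape::node.depth.edgelength(tree)[inner]
  ord <- order(-depth)
  list(n = n, nn = n + tree$Nnode, edge = tree$edge,
       elen = tree$edge.length,
       nodes = inner[ord], children = children[ord])
}

bm_peel <- function(prep, xy, root, psi) {
  ll <- 0
  n <- prep$n
  for (axis in 1:2) {
    mu <- numeric(prep$nn)      # conditional mean per node
    vextra <- numeric(prep$nn)  # accumulated extra variance per node
    mu[seq_len(n)] <- xy[, axis]
    for (i in seq_along(prep$nodes)) {
      nd <- prep$nodes[i]
      es <- prep$children[[i]]
      kids <- prep$edge[es, 2L]
      vlen <- prep$elen[es] * psi + vextra[kids]
      if (length(kids) == 1L) {
        mu[nd] <- mu[kids]; vextra[nd] <- vlen
        next
      }
      # pairwise contrasts of the children
      m <- mu[kids[1L]]; v <- vlen[1L]
      for (j in 2L:length(kids)) {
        ll <- ll + stats::dnorm(mu[kids[j]], m, sqrt(v + vlen[j]), log = TRUE)
        newv <- 1 / (1 / v + 1 / vlen[j])
        m <- newv * (m / v + mu[kids[j]] / vlen[j])
        v <- newv
      }
      mu[nd] <- m; vextra[nd] <- v
    }
    rt <- n + 1L
    ll <- ll + stats::dnorm(mu[rt], root[axis], sqrt(vextra[rt]), log = TRUE)
  }
  ll
}

#' Fit root location and dispersal rate by ML
#'
#' Hill-climbing (Nelder-Mead over root x, root y, log psi) with seeded
#' random restarts ("optimization replicates"), optionally repeated over
#' several rate-smoothing starts when a non-ultrametric phylogram is given
#' ("smoothing replicates", re-smoothed with jittered penalized-likelihood
#' smoothing parameters). The best replicate is returned; all are retained.
#'
#' @param chrono `mt_chronogram`, ultrametric `phylo`, or a phylogram (which
#'   is then smoothed per replicate).
#' @param coords data.frame with `specimen_id`, `lat`, `lon` covering every
#'   tip, or an n x 2 `lat`/`lon` matrix with tip-label rownames.
#' @param smoothing_replicates number of smoothing starts (default 10; only
#'   meaningful for phylogram input, otherwise identical).
#' @param optim_replicates hill-climbing restarts per smoothing start
#'   (default 100).
#' @param seed integer seed.
#' @return list of class `mt_geofit`: `root` (lat/lon), `root_xy` (km
#'   plane), `psi` (km^2 per unit depth per axis), `logL`, `replicates`
#'   data.frame, `origin`.
#' @export
fit_dispersal <- function(chrono, coords, smoothing_replicates = 10,
                          optim_replicates = 100, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  tr0 <- if (inherits(chrono, "mt_chronogram")) chrono$tree else chrono
  stopifnot(inherits(tr0, "phylo"))
  if (is.data.frame(coords)) {
    rn <- coords$specimen_id
    coords <- as.matrix(coords[, c("lat", "lon")])
    rownames(coords) <- rn
  }
  missing_tips <- setdiff(tr0$tip.label, rownames(coords))
  if (length(missing_tips) > 0L)
    stop("tips without coordinates: ",
         paste(utils::head(missing_tips, 5), collapse = ", "))
  coords <- coords[tr0$tip.label, , drop = FALSE]
  proj <- project_coords(coords[, "lat"], coords[, "lon"])
  xy <- proj$xy
  rownames(xy) <- tr0$tip.label
  if (max(stats::dist(xy)) < 1e-9) {
    # degenerate: every tip at one point
    return(structure(list(
      root = unproject_coords(xy[1L, ], proj$origin), root_xy = xy[1L, ],
      psi = 0, logL = Inf, boundary = TRUE,
      replicates = data.frame(), origin = proj$origin),
      class = "mt_geofit"))
  }
  smooth_trees <- if (is_ultrametric_strict(tr0, tol = 1e-6)) {
    rep(list(tr0), smoothing_replicates)
  } else {
    lapply(seq_len(smoothing_replicates), function(i)
      ultrametricize(tr0, lambda = 10^stats::runif(1, -1, 1))$tree)
  }
  reps <- list()
  for (s in seq_along(smooth_trees)) {
    tr <- smooth_trees[[s]]
    prep <- bm_prepare(tr)
    xy_o <- xy[tr$tip.label, , drop = FALSE]
    rownames(xy_o) <- NULL
    depth <- max(ape::node.depth.edgelength(tr))
    span <- apply(xy, 2L, function(v) diff(range(v)))
    for (r in seq_len(optim_replicates)) {
      start <- c(stats::runif(1, min(xy[, 1L]), max(xy[, 1L])),
                 stats::runif(1, min(xy[, 2L]), max(xy[, 2L])),
                 log(mean(span^2) / depth * stats::runif(1, 0.1, 2)))
      fn <- function(par) {
        -bm_peel(prep, xy_o, par[1:2], exp(par[3L]))
      }
      fit <- tryCatch(
        stats::optim(start, fn, method = "Nelder-Mead",
                     control = list(maxit = 1000, reltol = 1e-10)),
        error = function(e) NULL)
      if (is.null(fit)) next
      reps[[length(reps) + 1L]] <- data.frame(
        smoothing = s, restart = r,
        x = fit$par[1L], y = fit$par[2L], psi = exp(fit$par[3L]),
        logL = -fit$value)
    }
  }
  repdf <- do.call(rbind, reps)
  best <- repdf[which.max(repdf$logL), ]
  root_xy <- c(best$x, best$y)
  structure(list(root = unproject_coords(root_xy, proj$origin),
                 root_xy = root_xy, psi = best$psi, logL = best$logL,
                 boundary = FALSE, replicates = repdf,
                 origin = proj$origin),
            class = "mt_geofit")
}

#' @export
print.mt_geofit <- function(x, ...) {
  cat(sprintf("mt_geofit: root %.4fN, %.4fW; psi = %.4g km^2/depth; L = %.5f\n",
              x$root["lat"], -x$root["lon"], x$psi, x$logL))
  invisible(x)
}

#' Consensus over replicated geographic fits
#'
#' Mean root location, bounding box of replicate optima, and likelihood
#' range; a disagreement flag is raised when replicate roots spread beyond
#' `radius_km`.
#'
#' @param fits list of `mt_geofit` on the same data (>= 2).
#' @param radius_km disagreement radius (default 200 km).
#' @return list with `mean_root` (lat/lon), `bbox`, `logL_range`,
#'   `disagreement`.
#' @export
replicate_consensus <- function(fits, radius_km = 200) {
  stopifnot(length(fits) >= 2L,
            all(vapply(fits, inherits, logical(1), "mt_geofit")))
  roots <- t(vapply(fits, function(f) f$root, numeric(2)))
  xys <- t(vapply(fits, function(f) f$root_xy, numeric(2)))
  ll <- vapply(fits, function(f) f$logL, numeric(1))
  ctr <- colMeans(xys)
  spread <- max(sqrt(rowSums((xys - matrix(ctr, nrow(xys), 2,
                                           byrow = TRUE))^2)))
  list(mean_root = colMeans(roots),
       bbox = apply(roots, 2L, range),
       logL_range = range(ll),
       logL_spread = diff(range(ll)),
       max_spread_km = spread,
       disagreement = spread > radius_km)
}

#' Export a geographic fit as a GeoJSON point and replicate TSV
#'
#' @param fit `mt_geofit`.
#' @param geojson_path,tsv_path output paths (either may be `NULL`).
#' @return invisible list of written paths.
#' @export
write_geofit <- function(fit, geojson_path = NULL, tsv_path = NULL) {
  stopifnot(inherits(fit, "mt_geofit"))
  if (!is.null(geojson_path)) {
    writeLines(sprintf(paste0(
      '{"type": "Feature", "geometry": {"type": "Point", ',
      '"coordinates": [%.6f, %.6f]}, "properties": ',
      '{"logL": %.6f, "psi_km2": %.6f}}'),
      fit$root["lon"], fit$root["lat"], fit$logL, fit$psi), geojson_path)
  }
  if (!is.null(tsv_path)) {
    utils::write.table(fit$replicates, tsv_path, sep = "\t",
                       row.names = FALSE, quote = FALSE)
  }
  invisible(list(geojson = geojson_path, tsv = tsv_path))
}
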