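# Generalized mixed Yule-coalescent species delimitation on ultrametric
# trees: null (single-process), single-threshold and multiple-threshold
# models, likelihood-ratio test, and 2-logL confidence sets.
#
# Interval likelihood: between successive branching events the total
# branching rate is b = lambda1 * k^p1 (speciation among the k species
# lineages) + lambda2 * sum_j [n_j (n_j - 1)]^p2 (coalescence within each
# cluster j with n_j lineages); an event-terminated interval of length x
# contributes b * exp(-b x), the final interval to the present contributes
# the survival term exp(-b x).

gmyc_tree <- function(x) {
  tr <- if (inherits(x, "mt_chronogram")) x$tree else x
  stopifnot(inherits(tr, "phylo"))
  if (ape::Ntip(tr) < 3L) stop("GMYC needs >= 3 tips")
  if (!ape::is.binary(tr)) stop("tree must be fully bifurcating")
  if (!is_ultrametric_strict(tr, tol = 1e-6))
    stop("tree must be ultrametric (see ultrametricize())")
  if (any(tr$edge.length <= 0))
    stop("zero-length branches: collapse identical haplotypes first")
  tr
}

# Precompute interval/edge structure shared by all GMYC fits.
gmyc_structure <- function(tr) {
  n <- ape::Ntip(tr)
  h <- node_heights(tr)
  h[seq_len(n)] <- 0                        # clamp tip heights exactly
  internal <- (n + 1L):(n + tr$Nnode)
  t_sorted <- sort(h[internal], decreasing = TRUE)
  bounds <- c(t_sorted, 0)                  # t_1 ... t_{n-1}, 0
  x <- -diff(bounds)                        # interval lengths, n-1 of them
  eps <- 1e-9 * max(h)
  hp <- h[tr$edge[, 1L]]
  hc <- h[tr$edge[, 2L]]
  nint <- length(x)
  # presence[i, e]: edge e exists throughout interval (bounds[i+1], bounds[i])
  presence <- matrix(FALSE, nint, nrow(tr$edge))
  for (i in seq_len(nint)) {
    presence[i, ] <- hp >= bounds[i] - eps & hc <= bounds[i + 1L] + eps
  }
  parent_of <- integer(n + tr$Nnode)
  parent_of[tr$edge[, 2L]] <- tr$edge[, 1L]
  # descendant lookups reused by every threshold evaluation
  desc_all <- phangorn::Descendants(tr, (n + 1L):(n + tr$Nnode), "all")
  desc_tips <- phangorn::Descendants(tr, (n + 1L):(n + tr$Nnode), "tips")
  list(tr = tr, n = n, h = h, t_sorted = t_sorted, x = x, eps = eps,
       hp = hp, hc = hc, presence = presence, parent_of = parent_of,
       desc_all = desc_all, desc_tips = desc_tips, root = n + 1L)
}

st_desc_all <- function(st, nd) {
  if (nd <= st$n) integer(0) else st$desc_all[[nd - st$n]]
}

st_desc_tips <- function(st, nd) {
  if (nd <= st$n) nd else st$desc_tips[[nd - st$n]]
}

pow0 <- function(v, p) {
  # v^p with the convention 0^p = 0 for all p (a vanished process
  # contributes no rate, even at p = 0)
  out <- v^p
  out[v == 0] <- 0
  out
}

# logL given per-interval Yule lineage counts k (vector) and cluster-size
# matrix N (intervals x clusters; may have 0 columns).
gmyc_loglik <- function(par, k, M, x) {
  lam1 <- exp(par[1L]); p1 <- par[2L]
  lam2 <- exp(par[3L]); p2 <- par[4L]
  b <- lam1 * pow0(k, p1)
  if (ncol(M) > 0L) b <- b + lam2 * rowSums(pow0(M, p2))
  nint <- length(x)
  ev <- seq_len(nint - 1L)
  if (any(b[ev] <= 0)) return(-Inf)
  sum(log(b[ev]) - b[ev] * x[ev]) - b[nint] * x[nint]
}

gmyc_optimize <- function(k, M, x, two_process = TRUE) {
  fn <- function(par) -gmyc_loglik(par, k, M, x)
  tscale <- sum(x)
  starts <- list(c(log(1 / tscale), 1, log(1 / tscale), 1),
                 c(log(5 / tscale), 0.5, log(5 / tscale), 1.5))
  if (!two_process)
    starts <- lapply(starts, function(s) { s[1L] <- -20; s[2L] <- 1; s })
  lower <- c(-25, 0, -25, 0)
  upper <- c(25, 2, 25, 2)
  best <- NULL
  for (s in starts) {
    fit <- tryCatch(
      stats::optim(s, fn, method = "L-BFGS-B", lower = lower, upper = upper,
                   control = list(maxit = 500)),
      error = function(e) NULL)
    if (!is.null(fit) && (is.null(best) || fit$value < best$value)) best <- fit
  }
  if (is.null(best)) stop("GMYC optimizer failed")
  list(par = best$par, logL = -best$value)
}

# Given a set of cluster-MRCA nodes, build (k, M, clusters, entities).
gmyc_counts <- function(st, mrcas) {
  coal_edge_cluster <- integer(nrow(st$tr$edge))   # 0 = Yule edge
  if (length(mrcas) > 0L) {
    # edges whose parent lies within a cluster subtree (MRCA included)
    node_cluster <- integer(st$n + st$tr$Nnode)
    for (j in seq_along(mrcas))
      node_cluster[c(mrcas[j], st_desc_all(st, mrcas[j]))] <- j
    coal_edge_cluster <- node_cluster[st$tr$edge[, 1L]]
  }
  yule <- coal_edge_cluster == 0L
  k <- rowSums(st$presence[, yule, drop = FALSE])
  M <- matrix(0, length(st$x), length(mrcas))
  for (j in seq_along(mrcas)) {
    nj <- rowSums(st$presence[, coal_edge_cluster == j, drop = FALSE])
    M[, j] <- nj * (nj - 1)
  }
  sizes <- vapply(mrcas, function(nd) length(st_desc_tips(st, nd)),
                  integer(1))
  clusters <- sum(sizes >= 2L)
  # entities = clusters + singleton lineages crossing into the Yule zone:
  # tips not inside any cluster subtree
  in_cluster_tips <- if (length(mrcas) > 0L)
    unique(unlist(lapply(mrcas, function(m) st_desc_tips(st, m))))
  else integer(0)
  singles <- st$n - length(in_cluster_tips)
  list(k = k, M = M, n_clusters = clusters,
       n_entities = clusters + singles, mrcas = mrcas)
}

# Cluster MRCAs induced by a height threshold T: nodes below T whose
# parent is at or above T (tips excluded: a crossing tip edge is a
# singleton entity, not a cluster MRCA).
threshold_mrcas <- function(st, T) {
  internal <- (st$n + 1L):(st$n + st$tr$Nnode)
  below <- internal[st$h[internal] < T - st$eps]
  below[vapply(below, function(nd) {
    p <- st$parent_of[nd]
    p == 0L || st$h[p] >= T - st$eps
  }, logical(1))]
}

#' Fit the GMYC null model (single branching process)
#'
#' The whole sample is treated as one process with rate
#' `lambda * [n_i (n_i - 1)]^p` over the ordered inter-node intervals.
#'
#' @param chrono `mt_chronogram` or ultrametric `phylo` (>= 3 tips, no
#'   zero-length internal branches).
#' @return `mt_gmyc` with `model = "null"`, fitted `lambda`, `p`, `logL`.
#' @export
fit_null <- function(chrono) {
  tr <- gmyc_tree(chrono)
  st <- gmyc_structure(tr)
  L <- (seq_along(st$x)) + 1L              # lineages per interval
  M <- matrix(L * (L - 1), ncol = 1L)
  k <- rep(0, length(st$x))
  opt <- gmyc_optimize(k, M, st$x, two_process = FALSE)
  structure(list(model = "null", tree = tr,
                 lambda = exp(opt$par[3L]), p = opt$par[4L],
                 logL = opt$logL, threshold = NA_real_,
                 n_clusters = 0L, n_entities = 1L),
            class = "mt_gmyc")
}

#' Fit the single-threshold GMYC model
#'
#' Every internal node height is tried as the speciation-to-coalescence
#' transition; at each candidate the four parameters (Yule rate/exponent,
#' coalescent rate/exponent) are re-optimized. Returns the best threshold
#' (ties broken toward the older one), the cluster/entity counts, and the
#' 2-logL confidence sets over thresholds.
#'
#' @param chrono `mt_chronogram` or ultrametric `phylo`.
#' @return `mt_gmyc` with `model = "single"`: `threshold`, `params`
#'   (lambda1, p1, lambda2, p2), `logL`, `n_clusters`, `n_entities`,
#'   `conf_clusters`, `conf_entities` (2-logL sets), `profile` data.frame,
#'   and `members` (tip labels per entity).
#' @export
fit_single_threshold <- function(chrono) {
  tr <- gmyc_tree(chrono)
  st <- gmyc_structure(tr)
  # first candidate sits above the root: the whole tree is one coalescent
  # cluster, which reproduces the null model and guarantees nesting
  cands <- c(max(st$t_sorted) * (1 + 1e-6), unique(st$t_sorted))
  prof <- data.frame(threshold = cands, logL = NA_real_,
                     n_clusters = NA_integer_, n_entities = NA_integer_)
  fits <- vector("list", length(cands))
  for (m in seq_along(cands)) {
    mr <- threshold_mrcas(st, cands[m])
    ct <- gmyc_counts(st, mr)
    opt <- gmyc_optimize(ct$k, ct$M, st$x)
    prof$logL[m] <- opt$logL
    prof$n_clusters[m] <- ct$n_clusters
    prof$n_entities[m] <- ct$n_entities
    fits[[m]] <- list(opt = opt, ct = ct)
  }
  best <- which.max(prof$logL)             # cands sorted old->young: first max
  keep <- prof$logL >= prof$logL[best] - 2
  bf <- fits[[best]]
  members <- entity_members(st, bf$ct$mrcas)
  structure(list(model = "single", tree = tr,
                 threshold = cands[best],
                 params = c(lambda1 = exp(bf$opt$par[1L]), p1 = bf$opt$par[2L],
                            lambda2 = exp(bf$opt$par[3L]), p2 = bf$opt$par[4L]),
                 logL = prof$logL[best],
                 n_clusters = prof$n_clusters[best],
                 n_entities = prof$n_entities[best],
                 conf_clusters = sort(unique(prof$n_clusters[keep])),
                 conf_entities = sort(unique(prof$n_entities[keep])),
                 profile = prof, members = members,
                 mrcas = bf$ct$mrcas),
            class = "mt_gmyc")
}

entity_members <- function(st, mrcas) {
  tips <- st$tr$tip.label
  out <- list()
  covered <- integer(0)
  for (m in mrcas) {
    tp <- st_desc_tips(st, m)
    out[[length(out) + 1L]] <- tips[tp]
    covered <- c(covered, tp)
  }
  for (tp in setdiff(seq_len(st$n), covered))
    out[[length(out) + 1L]] <- tips[tp]
  out
}

#' @export
print.mt_gmyc <- function(x, ...) {
  cat("GMYC", x$model, "model: logL =", format(x$logL, digits = 7))
  if (x$model != "null") {
    cat(",", x$n_clusters, "clusters,", x$n_entities, "entities")
    if (!is.null(x$conf_entities))
      cat(sprintf(" (2-logL CI: clusters %s, entities %s)",
                  paste(range(x$conf_clusters), collapse = "-"),
                  paste(range(x$conf_entities), collapse = "-")))
  }
  cat("\n")
  invisible(x)
}

#' Likelihood-ratio test of a GMYC model against the null
#'
#' `LR = 2 (logL_alt - logL_null)` referred to chi-square with df = 3
#' (four threshold-model parameters against two null parameters, the
#' threshold itself not counted; a documented convention).
#'
#' @param alt,null `mt_gmyc` fits on the same tree.
#' @param df degrees of freedom (default 3).
#' @return list with `statistic`, `df`, `p_value`.
#' @export
lr_test <- function(alt, null, df = 3) {
  stopifnot(inherits(alt, "mt_gmyc"), inherits(null, "mt_gmyc"))
  lr <- 2 * (alt$logL - null$logL)
  if (lr < -1e-4)
    stop("alternative logL below null logL: optimizer failure")
  lr <- max(lr, 0)
  list(statistic = lr, df = df,
       p_value = stats::pchisq(lr, df, lower.tail = FALSE))
}

#' Fit the multiple-threshold GMYC model
#'
#' Greedy refinement from the single-threshold optimum: the set of cluster
#' MRCAs is perturbed by split moves (replace a cluster MRCA by its internal
#' children) and merge/grow moves (replace a node's cluster descendants by
#' the node itself), accepting the best likelihood improvement until none
#' remains. This lets the speciation-coalescence transition vary across the
#' tree.
#'
#' @param chrono `mt_chronogram` or ultrametric `phylo`.
#' @param max_iter cap on greedy iterations.
#' @return `mt_gmyc` with `model = "multiple"`, `thresholds` (distinct local
#'   transition heights), cluster/entity counts and `members`.
#' @export
fit_multiple_threshold <- function(chrono, max_iter = 50L) {
  single <- fit_single_threshold(chrono)
  tr <- single$tree
  st <- gmyc_structure(tr)
  S <- single$mrcas
  eval_state <- function(S) {
    ct <- gmyc_counts(st, S)
    opt <- gmyc_optimize(ct$k, ct$M, st$x)
    list(ct = ct, opt = opt, logL = opt$logL)
  }
  cur <- eval_state(S)
  internal <- (st$n + 1L):(st$n + st$tr$Nnode)
  for (it in seq_len(max_iter)) {
    cand_states <- list()
    # split moves
    for (m in S) {
      kids <- st$tr$edge[st$tr$edge[, 1L] == m, 2L]
      repl <- kids[kids > st$n]
      cand_states[[length(cand_states) + 1L]] <-
        sort(unique(c(setdiff(S, m), repl)))
    }
    # merge/grow moves: any internal node not inside a current cluster
    inside <- if (length(S) > 0L)
      unique(unlist(lapply(S, function(m) c(m, st_desc_all(st, m)))))
    else integer(0)
    for (p in setdiff(internal, inside)) {
      desc <- st_desc_all(st, p)
      cand_states[[length(cand_states) + 1L]] <-
        sort(unique(c(setdiff(S, desc), p)))
    }
    cand_states <- unique(cand_states)
    best_new <- NULL
    for (cs in cand_states) {
      ev <- eval_state(cs)
      if (ev$logL > cur$logL + 1e-8 &&
          (is.null(best_new) || ev$logL > best_new$ev$logL))
        best_new <- list(S = cs, ev = ev)
    }
    if (is.null(best_new)) break
    S <- best_new$S
    cur <- best_new$ev
  }
  thr <- sort(unique(st$h[st$parent_of[S]]), decreasing = TRUE)
  structure(list(model = "multiple", tree = tr,
                 thresholds = thr,
                 params = c(lambda1 = exp(cur$opt$par[1L]),
                            p1 = cur$opt$par[2L],
                            lambda2 = exp(cur$opt$par[3L]),
                            p2 = cur$opt$par[4L]),
                 logL = cur$logL,
                 n_clusters = cur$ct$n_clusters,
                 n_entities = cur$ct$n_entities,
                 members = entity_members(st, S),
                 mrcas = S, single = single),
            class = "mt_gmyc")
}

#' Compare single- and multiple-threshold GMYC fits
#'
#' Chi-square on `2 * (logL_multiple - logL_single)` with df equal to the
#' difference in the number of local transition times.
#'
#' @param single,multiple `mt_gmyc` fits on the same tree.
#' @return list with `statistic`, `df`, `p_value`.
#' @export
compare_models <- function(single, multiple) {
  stopifnot(single$model == "single", multiple$model == "multiple")
  stat <- max(0, 2 * (multiple$logL - single$logL))
  df <- max(1L, length(multiple$thresholds) - 1L)
  list(statistic = stat, df = df,
       p_value = stats::pchisq(stat, df, lower.tail = FALSE))
}
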