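# Constant-size / exponential-growth coalescent simulator with
# infinite-sites mutations, used both for neutrality-test null
# distributions and by the synthetic-data generator.

#' Simulate coalescent genealogies and summary statistics
#'
#' Kingman coalescent for a sample of size `n` under constant population size
#' or exponential growth (rate `growth` per unit of scaled time, population
#' larger toward the present). Mutations are Poisson on branches with rate
#' `theta / 2` per unit scaled time (Hudson convention, `theta = 4 N mu` per
#' locus) under the infinite-sites model; alternatively exactly `S_fixed`
#' mutations are placed multinomially by branch length.
#'
#' @param n sample size.
#' @param reps number of replicates.
#' @param theta per-locus theta for Poisson mutations (ignored if `S_fixed`).
#' @param S_fixed place exactly this many mutations per replicate.
#' @param growth exponential growth rate (0 = constant size).
#' @param lstir optional precomputed log-Stirling matrix for `n`.
#' @return data.frame with per-replicate `S`, `k` (mean pairwise
#'   differences), `K` (haplotype count), `D`, `Fs`.
#' @export
sim_coalescent_stats <- function(n, reps, theta = NULL, S_fixed = NULL,
                                 growth = 0, lstir = NULL) {
  stopifnot(n >= 2L, !is.null(theta) || !is.null(S_fixed))
  if (is.null(lstir)) lstir <- log_stirling_matrix(n)
  out <- data.frame(S = integer(reps), k = numeric(reps), K = integer(reps),
                    D = numeric(reps), Fs = numeric(reps))
  npairs <- n * (n - 1) / 2
  for (r in seq_len(reps)) {
    iv <- coalescent_intervals(n, growth)
    # branch-time per lineage class: during interval with i lineages, each
    # of the i current lineages accrues iv$t[i]
    sizes <- iv$sizes       # list: tip-set size of each lineage per interval
    lens <- iv$lens         # per-interval per-lineage duration
    blen <- unlist(Map(function(sz, t) rep(t, length(sz)), sizes, lens))
    bsize <- unlist(sizes)
    total <- sum(blen)
    nmut <- if (!is.null(S_fixed)) S_fixed
      else stats::rpois(1L, theta / 2 * total)
    if (nmut == 0L) {
      out$S[r] <- 0L; out$k[r] <- 0; out$K[r] <- 1L
      out$D[r] <- NA_real_; out$Fs[r] <- Inf
      next
    }
    hit <- sample.int(length(blen), nmut, replace = TRUE, prob = blen)
    csize <- bsize[hit]
    k <- sum(csize * (n - csize)) / npairs
    # haplotype identity: per-tip set of mutations
    prof <- vector("list", n)
    branches <- unlist(iv$tipsets, recursive = FALSE)
    for (m in seq_len(nmut)) {
      for (tp in branches[[hit[m]]]) prof[[tp]] <- c(prof[[tp]], m)
    }
    key <- vapply(prof, function(p) paste(p, collapse = ","), "")
    K <- length(unique(key))
    out$S[r] <- nmut
    out$k[r] <- k
    out$K[r] <- K
    out$D[r] <- tajimas_d_from_stats(n, nmut, k)
    out$Fs[r] <- fus_fs_from_stats(n, k, K, lstir)
  }
  out
}

# Simulate one coalescent genealogy's interval structure.
# Returns, for each interval i (n, n-1, ..., 2 active lineages):
#   lens[i]  duration of the interval,
#   sizes[[i]] integer vector of subtended-tip counts per active lineage,
#   tipsets[[i]] list of tip index vectors per active lineage.
coalescent_intervals <- function(n, growth = 0) {
  act <- lapply(seq_len(n), function(i) i)
  lens <- numeric(n - 1L)
  sizes <- vector("list", n - 1L)
  tipsets <- vector("list", n - 1L)
  t <- 0
  for (step in seq_len(n - 1L)) {
    i <- n - step + 1L
    rate <- i * (i - 1) / 2
    E <- stats::rexp(1L)
    w <- if (growth == 0) E / rate
      else log(exp(growth * t) + growth * E / rate) / growth - t
    lens[step] <- w
    sizes[[step]] <- lengths(act)
    tipsets[[step]] <- act
    t <- t + w
    pick <- sample.int(i, 2L)
    merged <- c(act[[pick[1L]]], act[[pick[2L]]])
    act <- c(act[-pick], list(merged))
  }
  list(lens = lens, sizes = sizes, tipsets = tipsets)
}

#' Simulate a coalescent genealogy as a phylo tree
#'
#' Same process as [sim_coalescent_stats()] but returning the genealogy
#' itself (an ultrametric `phylo`), for feeding tree-based stages.
#'
#' @param n sample size.
#' @param growth exponential growth rate (0 = constant).
#' @param tip_labels optional tip names (default `t1..tn`).
#' @return ultrametric `phylo` with `n` tips.
#' @export
sim_coalescent_tree <- function(n, growth = 0, tip_labels = NULL) {
  stopifnot(n >= 2L)
  if (is.null(tip_labels)) tip_labels <- paste0("t", seq_len(n))
  # node ids: tips 1..n, internals n+1 .. 2n-1 (root = 2n-1 built last)
  act <- seq_len(n)
  heights <- numeric(2L * n - 1L)
  edge <- matrix(0L, 2L * (n - 1L), 2L)
  elen <- numeric(2L * (n - 1L))
  t <- 0
  nxt <- n + 1L
  erow <- 1L
  while (length(act) > 1L) {
    i <- length(act)
    rate <- i * (i - 1) / 2
    E <- stats::rexp(1L)
    w <- if (growth == 0) E / rate
      else log(exp(growth * t) + growth * E / rate) / growth - t
    t <- t + w
    pick <- sample.int(i, 2L)
    for (ch in act[pick]) {
      edge[erow, ] <- c(nxt, ch)
      elen[erow] <- t - heights[ch]
      erow <- erow + 1L
    }
    heights[nxt] <- t
    act <- c(act[-pick], nxt)
    nxt <- nxt + 1L
  }
  # renumber internals so root = n+1 (ape convention: root lowest internal)
  ninner <- n - 1L
  old_in <- (n + 1L):(2L * n - 1L)
  new_of <- integer(2L * n - 1L)
  new_of[seq_len(n)] <- seq_len(n)
  new_of[rev(old_in)] <- n + seq_len(ninner)   # built last = root
  edge2 <- matrix(new_of[edge], ncol = 2L)
  tr <- list(edge = edge2, edge.length = elen, Nnode = ninner,
             tip.label = tip_labels)
  class(tr) <- "phylo"
  ape::reorder.phylo(tr, "cladewise")
}
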