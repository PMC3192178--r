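tajima_constants <- function(n) {
  i <- seq_len(n - 1L)
  a1 <- sum(1 / i)
  a2 <- sum(1 / i^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  list(a1 = a1, a2 = a2, b1 = b1, b2 = b2, c1 = c1, c2 = c2,
       e1 = c1 / a1, e2 = c2 / (a1^2 + a2))
}

resolved_code <- function(align) {
  m <- align$matrix
  matrix(match(m, c("A", "C", "G", "T")), nrow = nrow(m),
         dimnames = dimnames(m))
}

#' Segregating sites and mean pairwise differences
#'
#' `S` counts columns with at least two distinct unambiguous states; `k` is
#' the mean number of pairwise mismatches over comparable (both-resolved)
#' sites, pairwise deletion.
#'
#' @param align [mt_alignment()].
#' @return list with `n`, `S`, `k`.
#' @export
seg_sites <- function(align) {
  code <- resolved_code(align)
  n <- nrow(code)
  S <- 0L
  for (j in seq_len(ncol(code))) {
    st <- code[, j]
    st <- st[!is.na(st)]
    if (length(st) >= 2L && length(unique(st)) >= 2L) S <- S + 1L
  }
  k <- 0
  np <- 0L
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    both <- !is.na(code[i, ]) & !is.na(code[j, ])
    k <- k + sum(code[i, both] != code[j, both])
    np <- np + 1L
  }
  list(n = n, S = S, k = k / np)
}

#' Nucleotide diversity with Nei's variance estimator
#'
#' Average pairwise uncorrected p-distance over all distinct sequence pairs
#' (pairwise deletion), with total standard deviation from Nei (1987,
#' eq. 10.7) combining sampling and stochastic variance.
#'
#' @param align [mt_alignment()] with >= 2 sequences.
#' @return list with `pi`, `sd`, `n`, `L` (columns).
#' @export
nucleotide_diversity <- function(align) {
  stopifnot(inherits(align, "mt_alignment"))
  n <- nrow(align$matrix)
  if (n < 2L) stop("nucleotide diversity needs >= 2 sequences")
  dm <- suppressWarnings(pdist_matrix(align))
  d <- dm$matrix[upper.tri(dm$matrix)]
  pi <- mean(d, na.rm = TRUE)
  L <- ncol(align$matrix)
  v <- (n + 1) / (3 * (n - 1) * L) * pi +
    2 * (n^2 + n + 3) / (9 * n * (n - 1)) * pi^2
  list(pi = pi, sd = sqrt(v), n = n, L = L)
}

#' Haplotype (gene) diversity with Nei's variance estimator
#'
#' `Hd = n(1 - sum f_i^2) / (n - 1)` over haplotype relative frequencies,
#' with the Nei (1987, eq. 8.12) sampling variance.
#'
#' @param haps [collapse_haplotypes()] result, or an integer vector of
#'   haplotype counts.
#' @return list with `Hd`, `sd`, `n`, `k` (number of haplotypes).
#' @export
haplotype_diversity <- function(haps) {
  counts <- if (inherits(haps, "mt_haplotypes")) haps$frequency else haps
  n <- sum(counts)
  if (n < 2L) stop("haplotype diversity needs >= 2 specimens")
  p <- counts / n
  s2 <- sum(p^2)
  Hd <- n * (1 - s2) / (n - 1)
  v <- 2 / (n * (n - 1)) *
    (2 * (n - 2) * (sum(p^3) - s2^2) + s2 - s2^2)
  list(Hd = Hd, sd = sqrt(max(v, 0)), n = n, k = length(counts))
}

#' Tajima's D
#'
#' Standardized difference between the pairwise-difference and
#' segregating-sites estimators of theta, with the Tajima (1989) constants.
#' Returns `NA` (flagged) when there are no segregating sites.
#'
#' @param align [mt_alignment()] or a list with `n`, `S`, `k` as returned by
#'   [seg_sites()].
#' @return scalar D (NA if S = 0).
#' @export
tajimas_d <- function(align) {
  st <- if (inherits(align, "mt_alignment")) seg_sites(align) else align
  tajimas_d_from_stats(st$n, st$S, st$k)
}

tajimas_d_from_stats <- function(n, S, k) {
  if (S < 1L) return(NA_real_)
  cst <- tajima_constants(n)
  (k - S / cst$a1) / sqrt(cst$e1 * S + cst$e2 * S * (S - 1))
}

log_stirling_matrix <- function(n) {
  # log unsigned Stirling numbers of the first kind, rows 1..n
  ls <- matrix(-Inf, n, n)
  ls[1L, 1L] <- 0
  if (n >= 2L) for (m in 2L:n) {
    for (k in seq_len(m)) {
      a <- if (k > 1L) ls[m - 1L, k - 1L] else -Inf
      b <- ls[m - 1L, k] + log(m - 1)
      ls[m, k] <- if (a == -Inf) b else if (b == -Inf) a
      else max(a, b) + log1p(exp(-abs(a - b)))
    }
  }
  ls
}

#' Fu's Fs
#'
#' `S' = P(K >= k_obs | theta, n)` from the Ewens sampling formula (unsigned
#' Stirling numbers of the first kind over the rising factorial, computed in
#' log space), with `Fs = ln(S' / (1 - S'))`. Theta defaults to the
#' pairwise-difference estimator of the sample. A monomorphic sample
#' (`k_obs = 1`) forces `S' = 1` and `Fs = +Inf` (flagged).
#'
#' @param align [mt_alignment()], or a list with `n`, `k` (mean pairwise
#'   differences) and `K` (observed haplotype count).
#' @param lstir optional precomputed [log] Stirling matrix for `n` (reused
#'   across simulation replicates).
#' @return scalar Fs (`Inf` when monomorphic, `NA` when theta = 0).
#' @export
fus_fs <- function(align, lstir = NULL) {
  if (inherits(align, "mt_alignment")) {
    st <- seg_sites(align)
    K <- length(collapse_haplotypes(align)$haplotype_id)
    n <- st$n; theta <- st$k
  } else {
    n <- align$n; theta <- align$k; K <- align$K
  }
  fus_fs_from_stats(n, theta, K, lstir)
}

fus_fs_from_stats <- function(n, theta, K, lstir = NULL) {
  if (K <= 1L) return(Inf)
  if (theta <= 0) return(NA_real_)
  if (is.null(lstir)) lstir <- log_stirling_matrix(n)
  lrise <- sum(log(theta + 0:(n - 1L)))
  lp <- lstir[n, seq_len(n)] + seq_len(n) * log(theta) - lrise
  mx <- max(lp)
  p <- exp(lp - mx)
  sp <- sum(p[K:n]) / sum(p)
  if (sp >= 1) return(Inf)
  if (sp <= 0) return(-Inf)
  log(sp / (1 - sp))
}

#' Neutrality test p-values by coalescent null simulation
#'
#' Simulates `reps` constant-size coalescent samples of size `n` conditioned
#' on the observed theta (pairwise estimator by default, or on the observed
#' number of segregating sites), computes D and Fs for each, and returns
#' one-tailed p-values toward negative values (the population-expansion
#' direction): `p = P(stat_sim <= stat_obs)`. Following the Arlequin
#' convention, Fs is customarily called significant at p < 0.02.
#'
#' @param align [mt_alignment()].
#' @param reps number of null replicates (default 10000).
#' @param seed integer seed.
#' @param condition `"theta_pi"` (default) or `"S"`.
#' @return list of class `mt_neutrality` with observed `D`, `Fs`, `p_D`,
#'   `p_Fs`, `reps`, and the simulated null statistics.
#' @export
neutrality_pvalues <- function(align, reps = 10000, seed = NULL,
                               condition = c("theta_pi", "S")) {
  condition <- match.arg(condition)
  if (reps < 100) warning("fewer than 100 replicates: p-values are crude")
  if (!is.null(seed)) set.seed(seed)
  st <- seg_sites(align)
  K_obs <- length(collapse_haplotypes(align)$haplotype_id)
  D_obs <- tajimas_d_from_stats(st$n, st$S, st$k)
  lstir <- log_stirling_matrix(st$n)
  Fs_obs <- fus_fs_from_stats(st$n, st$k, K_obs, lstir)
  sim <- sim_coalescent_stats(
    n = st$n, reps = reps,
    theta = if (condition == "theta_pi") st$k else NULL,
    S_fixed = if (condition == "S") st$S else NULL,
    lstir = lstir)
  p_D <- mean(sim$D[!is.na(sim$D)] <= D_obs)
  p_Fs <- mean(sim$Fs[is.finite(sim$Fs)] <= Fs_obs)
  structure(list(n = st$n, S = st$S, k = st$k, K = K_obs,
                 D = D_obs, Fs = Fs_obs, p_D = p_D, p_Fs = p_Fs,
                 reps = reps, null_D = sim$D, null_Fs = sim$Fs),
            class = "mt_neutrality")
}

#' @export
print.mt_neutrality <- function(x, ...) {
  cat(sprintf("n = %d, S = %d, k = %.3f, K = %d\n", x$n, x$S, x$k, x$K))
  cat(sprintf("Tajima's D = %.5f (p = %.4f)\n", x$D, x$p_D))
  cat(sprintf("Fu's Fs    = %.5f (p = %.4f)  [%d null replicates]\n",
              x$Fs, x$p_Fs, x$reps))
  invisible(x)
}

#' Table of diversity and neutrality statistics per group
#'
#' Convenience wrapper computing, for each group of specimens, the Table-3
#' style summary: n, S, pi +/- SD, haplotype count, Hd +/- SD, Tajima's D and
#' Fu's Fs with coalescent-null p-values.
#'
#' @param align [mt_alignment()].
#' @param groups named character vector (specimen id -> group) or data.frame
#'   with `specimen_id` and `group`/`species`.
#' @param reps,seed passed to [neutrality_pvalues()].
#' @return data.frame, one row per group.
#' @export
popgen_table <- function(align, groups, reps = 10000, seed = NULL) {
  if (is.data.frame(groups)) {
    gcol <- if ("group" %in% names(groups)) "group" else "species"
    groups <- stats::setNames(as.character(groups[[gcol]]),
                              groups$specimen_id)
  }
  labs <- sort(unique(groups[align$ids]))
  rows <- lapply(labs, function(lab) {
    ids <- align$ids[groups[align$ids] == lab]
    sub <- mt_alignment(ids, align$matrix[ids, , drop = FALSE],
                        align$partitions)
    nd <- nucleotide_diversity(sub)
    hp <- collapse_haplotypes(sub)
    hd <- haplotype_diversity(hp)
    nt <- neutrality_pvalues(sub, reps = reps, seed = seed)
    data.frame(group = lab, n = nd$n, S = nt$S,
               pi = nd$pi, pi_sd = nd$sd,
               haplotypes = hd$k, Hd = hd$Hd, Hd_sd = hd$sd,
               D = nt$D, p_D = nt$p_D, Fs = nt$Fs, p_Fs = nt$p_Fs,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
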