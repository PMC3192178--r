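# Independent brute-force oracles, deliberately coded from scratch and not
# sharing helpers with the package implementation.

make_align <- function(..., ids = NULL) {
  seqs <- c(...)
  if (is.null(ids)) ids <- paste0("s", seq_along(seqs))
  mt_alignment(ids, seqs)
}

random_align <- function(n, L, ambig_frac = 0) {
  bases <- c("A", "C", "G", "T")
  m <- matrix(sample(bases, n * L, replace = TRUE), n, L)
  # inject shared polymorphism so fixtures are not pure noise
  for (j in seq_len(L)) {
    if (stats::runif(1) < 0.6) m[, j] <- m[1L, j]
  }
  if (ambig_frac > 0) {
    idx <- sample(length(m), round(ambig_frac * length(m)))
    m[idx] <- sample(c("N", "-", "R", "Y"), length(idx), replace = TRUE)
  }
  mt_alignment(paste0("s", seq_len(n)), m)
}

# --- p-distance oracle: plain character loop --------------------------------
oracle_pdist <- function(align) {
  m <- align$matrix
  n <- nrow(m)
  out <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    mism <- 0L; comp <- 0L
    for (s in seq_len(ncol(m))) {
      a <- m[i, s]; b <- m[j, s]
      if (a %in% c("A", "C", "G", "T") && b %in% c("A", "C", "G", "T")) {
        comp <- comp + 1L
        if (a != b) mism <- mism + 1L
      }
    }
    out[i, j] <- if (comp == 0L) NA_real_ else mism / comp
  }
  out
}

# --- brute-force S and mean pairwise differences ----------------------------
oracle_seg <- function(align) {
  m <- align$matrix
  n <- nrow(m)
  acgt <- c("A", "C", "G", "T")
  S <- 0L
  for (s in seq_len(ncol(m))) {
    st <- m[, s]; st <- st[st %in% acgt]
    if (length(unique(st)) >= 2L) S <- S + 1L
  }
  tot <- 0
  cnt <- 0L
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    mism <- 0L
    for (s in seq_len(ncol(m))) {
      a <- m[i, s]; b <- m[j, s]
      if (a %in% acgt && b %in% acgt && a != b) mism <- mism + 1L
    }
    tot <- tot + mism
    cnt <- cnt + 1L
  }
  list(n = n, S = S, k = tot / cnt)
}

# --- Tajima's D oracle (straight from the 1989 constants) -------------------
oracle_tajima <- function(n, S, k) {
  if (S == 0L) return(NA_real_)
  a1 <- sum(1 / seq_len(n - 1))
  a2 <- sum(1 / seq_len(n - 1)^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n * n + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / (a1 * a1)
  e1 <- c1 / a1
  e2 <- c2 / (a1 * a1 + a2)
  (k - S / a1) / sqrt(e1 * S + e2 * S * (S - 1))
}

# --- Fu's Fs oracle: exact Ewens via rising-factorial polynomial ------------
# |s(n, k)| are the coefficients of x (x+1) ... (x+n-1).
oracle_stirling <- function(n) {
  coef <- 1
  for (m in 0:(n - 1)) coef <- c(0, coef) + c(coef * m, 0)  # times (x + m)
  coef[-1]                                                  # k = 1..n
}

oracle_fs <- function(n, theta, K) {
  if (K <= 1L) return(Inf)
  if (theta <= 0) return(NA_real_)
  st <- oracle_stirling(n)
  num <- st * theta^seq_len(n)
  p <- num / sum(num)           # sum_k |s(n,k)| theta^k = rising factorial
  sp <- sum(p[K:n])
  log(sp / (1 - sp))
}

# --- statistical-parsimony probability oracle -------------------------------
# Independent numeric path: JC expected substitutions found by root-solving,
# probabilities composed without logs.
oracle_parsprob <- function(j, m) {
  if (j == 0) return(1)
  d <- min(j / m, 0.74)
  f <- function(lam) 0.75 * (1 - exp(-4 * lam / 3)) - d
  lam <- stats::uniroot(f, c(1e-12, 50), tol = 1e-14)$root
  single <- lam * exp(-lam)
  diffp <- 0.75 * (1 - exp(-4 * lam / 3))
  (single / diffp)^j
}

# --- BFS shortest-path oracle on an igraph-free adjacency list -------------
oracle_bfs <- function(edges, from, nodes) {
  adj <- lapply(stats::setNames(vector("list", length(nodes)), nodes),
                function(x) character(0))
  for (r in seq_len(nrow(edges))) {
    a <- edges[r, 1]; b <- edges[r, 2]
    adj[[a]] <- c(adj[[a]], b)
    adj[[b]] <- c(adj[[b]], a)
  }
  dist <- stats::setNames(rep(Inf, length(nodes)), nodes)
  dist[from] <- 0
  queue <- from
  while (length(queue) > 0) {
    v <- queue[1]; queue <- queue[-1]
    for (w in adj[[v]]) {
      if (!is.finite(dist[w])) {
        dist[w] <- dist[v] + 1
        queue <- c(queue, w)
      }
    }
  }
  dist
}

# --- full-covariance Gaussian oracle for the Brownian tip likelihood --------
oracle_bm_loglik <- function(tree, xy, root, psi) {
  C <- ape::vcv(tree) * psi
  C <- C[tree$tip.label, tree$tip.label]
  xy <- xy[tree$tip.label, , drop = FALSE]
  n <- nrow(C)
  Ci <- solve(C)
  ld <- determinant(C, logarithm = TRUE)$modulus
  ll <- 0
  for (axis in 1:2) {
    z <- xy[, axis] - root[axis]
    ll <- ll - 0.5 * (n * log(2 * pi) + ld + drop(t(z) %*% Ci %*% z))
  }
  as.numeric(ll)
}

# --- tiny deterministic ultrametric trees -----------------------------------
balanced_tree <- function(heights = c(1, 0.3, 0.4)) {
  # ((t1:h2, t2:h2):(h1-h2), (t3:h3, t4:h3):(h1-h3));
  h1 <- heights[1]; h2 <- heights[2]; h3 <- heights[3]
  txt <- sprintf("((t1:%g,t2:%g):%g,(t3:%g,t4:%g):%g);",
                 h2, h2, h1 - h2, h3, h3, h1 - h3)
  ape::read.tree(text = txt)
}

caterpillar_species_tree <- function(k, tip_h = 0.03, first_split = 0.5,
                                     step = 0.25) {
  # k cherries (two tips each, distinct shallow heights) hanging from a
  # ladder of deep nodes
  cherry_h <- tip_h + 0.01 * (seq_len(k) - 1)
  cherry <- function(i) sprintf("(a%d:%g,b%d:%g)", i, cherry_h[i],
                                i, cherry_h[i])
  depths <- first_split + step * (seq_len(k - 1) - 1)  # cherry join heights
  txt <- cherry(1)
  h_cur <- cherry_h[1]
  for (i in 2:k) {
    h_new <- depths[i - 1]
    txt <- sprintf("(%s:%g,%s:%g)", txt, h_new - h_cur, cherry(i),
                   h_new - cherry_h[i])
    h_cur <- h_new
  }
  ape::read.tree(text = paste0(txt, ";"))
}
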