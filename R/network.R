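# Statistical-parsimony haplotype networks in the TCS tradition:
# a 95% connection limit from a per-site single-hit probability, edges of
# one mutational step, inferred intermediates, and ancestral-haplotype
# scoring by frequency and connectedness.

#' Probability that j observed differences are all single-hit
#'
#' Under a Jukes-Cantor per-site substitution process with expected
#' divergence `d = j / m`, a site differs between two sequences with
#' probability `(3/4)(1 - exp(-4*lambda/3))` where `lambda` is the expected
#' substitutions per site, and carries exactly one substitution with
#' probability `lambda * exp(-lambda)`. The parsimony probability of a
#' j-step connection over `m` sites is the product over the j differing
#' sites of the conditional single-hit probability.
#'
#' @param j number of observed differences (mutational steps).
#' @param m sequence length (compared sites).
#' @return probability in (0, 1].
#' @export
parsimony_probability <- function(j, m) {
  stopifnot(j >= 0, m >= 1)
  if (j == 0) return(1)
  d <- min(j / m, 0.74)                      # keep JC inversion finite
  lam <- -0.75 * log(1 - 4 * d / 3)
  r <- (lam * exp(-lam)) / (0.75 * (1 - exp(-4 * lam / 3)))
  r^j
}

#' Statistical-parsimony connection limit
#'
#' Largest number of mutational steps `j` whose parsimony probability
#' ([parsimony_probability()]) still reaches the confidence level; haplotype
#' pairs farther apart than `j` steps are left unconnected (95 percent limit
#' by default).
#'
#' @param seq_length number of sites in the alignment.
#' @param confidence confidence level in (0, 1), default 0.95.
#' @return integer number of steps (>= 0).
#' @export
connection_limit <- function(seq_length, confidence = 0.95) {
  stopifnot(seq_length >= 1, confidence > 0, confidence < 1)
  j <- 0L
  while (parsimony_probability(j + 1L, seq_length) >= confidence) j <- j + 1L
  j
}

hamming_resolved <- function(align) {
  code <- resolved_code(align)
  n <- nrow(code)
  d <- matrix(0L, n, n, dimnames = list(align$ids, align$ids))
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    both <- !is.na(code[i, ]) & !is.na(code[j, ])
    d[i, j] <- d[j, i] <- sum(code[i, both] != code[j, both])
  }
  d
}

#' Build a statistical-parsimony haplotype network
#'
#' Observed haplotypes are connected in increasing order of mutational
#' distance (Hamming distance over mutually resolved sites): a pair at
#' distance `d <= j` is linked through `d - 1` inferred intermediate nodes
#' whenever the pair is not yet connected at that distance, and all equally
#' minimal alternative connections are retained (reticulation). Pairs beyond
#' the connection limit stay in separate components.
#'
#' @param haps [collapse_haplotypes()] result.
#' @param j connection limit in steps (see [connection_limit()]).
#' @return list of class `mt_network`: `graph` (igraph, vertex attributes
#'   `observed`, `frequency`), `j`, `distances` (observed-pair Hamming
#'   matrix), `components` (membership for observed haplotypes).
#' @export
build_network <- function(haps, j) {
  stopifnot(inherits(haps, "mt_haplotypes"), j >= 0)
  ids <- haps$haplotype_id
  dmat <- hamming_resolved(haps$alignment)
  dimnames(dmat) <- list(ids, ids)
  g <- igraph::make_empty_graph(n = length(ids), directed = FALSE)
  igraph::V(g)$name <- ids
  igraph::V(g)$observed <- TRUE
  igraph::V(g)$frequency <- haps$frequency
  inter <- 0L
  ut <- which(upper.tri(dmat), arr.ind = TRUE)
  ord <- order(dmat[ut])
  for (idx in seq_along(ord)) {
    a <- ut[ord[idx], 1L]; b <- ut[ord[idx], 2L]
    d <- dmat[a, b]
    if (d > j) break
    if (d == 0L) next
    sp <- suppressWarnings(
      igraph::distances(g, v = ids[a], to = ids[b], weights = NA))[1L, 1L]
    if (is.finite(sp) && sp <= d) next     # already connected as well
    # add chain of d-1 intermediates (keeps equally minimal alternatives)
    prev <- ids[a]
    if (d > 1L) for (s in seq_len(d - 1L)) {
      inter <- inter + 1L
      nm <- sprintf("i%03d", inter)
      g <- igraph::add_vertices(g, 1L, name = nm, observed = FALSE,
                                frequency = 0L)
      g <- igraph::add_edges(g, c(prev, nm))
      prev <- nm
    }
    g <- igraph::add_edges(g, c(prev, ids[b]))
  }
  comp <- igraph::components(g)$membership[ids]
  structure(list(graph = g, j = j, distances = dmat, components = comp),
            class = "mt_network")
}

#' @export
print.mt_network <- function(x, ...) {
  nobs <- sum(igraph::V(x$graph)$observed)
  cat("mt_network:", nobs, "observed haplotypes,",
      igraph::vcount(x$graph) - nobs, "inferred intermediates,",
      igraph::ecount(x$graph), "edges; limit", x$j, "steps;",
      max(x$components), "component(s)\n")
  invisible(x)
}

#' Identify the ancestral haplotype of a network component
#'
#' Scores each observed haplotype by equally weighted normalized frequency
#' and normalized degree (internal position / number of lineages branching
#' from it); the top scorer is reported as ancestral, ties reported jointly
#' in haplotype-id order. Derived (leaf) haplotypes are those attached by a
#' single connecting branch.
#'
#' @param net [build_network()] result.
#' @param component which component to score (default: largest).
#' @return list of class `mt_ancestor`: `ancestor` (co-winners), `scores`
#'   data.frame, `steps` (shortest-path steps from the first ancestor),
#'   `derived` (degree-1 observed haplotypes).
#' @export
ancestral_haplotype <- function(net, component = NULL) {
  stopifnot(inherits(net, "mt_network"))
  if (is.null(component)) {
    tab <- table(net$components)
    component <- as.integer(names(tab)[which.max(tab)])
  }
  ids <- names(net$components)[net$components == component]
  if (length(ids) < 2L) stop("component has fewer than 2 observed haplotypes")
  g <- net$graph
  deg <- igraph::degree(g, v = ids)
  freq <- igraph::V(g)$frequency[match(ids, igraph::V(g)$name)]
  score <- 0.5 * freq / max(freq) + 0.5 * deg / max(deg)
  ord <- order(-score, ids)
  best <- score[ord[1L]]
  winners <- sort(ids[score >= best - 1e-12])
  steps <- steps_from_ancestor(net, winners[1L], ids = ids)
  structure(list(
    ancestor = winners,
    scores = data.frame(haplotype = ids[ord], frequency = freq[ord],
                        degree = deg[ord], score = score[ord],
                        row.names = NULL, stringsAsFactors = FALSE),
    steps = steps,
    derived = ids[deg == 1L]
  ), class = "mt_ancestor")
}

#' Mutational steps of every haplotype from an ancestor
#'
#' Shortest-path length in the network (inferred intermediates count as
#' steps). Unreachable haplotypes are `Inf`.
#'
#' @param net [build_network()] result.
#' @param ancestor haplotype id.
#' @param ids haplotypes to report (default: all observed).
#' @return named numeric vector of steps.
#' @export
steps_from_ancestor <- function(net, ancestor, ids = NULL) {
  stopifnot(inherits(net, "mt_network"))
  if (is.null(ids)) ids <- names(net$components)
  if (!ancestor %in% igraph::V(net$graph)$name)
    stop("ancestor not in network: ", ancestor)
  d <- suppressWarnings(
    igraph::distances(net$graph, v = ancestor, to = ids, weights = NA))
  stats::setNames(as.numeric(d[1L, ]), ids)
}

#' Export a network as an edge list
#'
#' @param net [build_network()] result.
#' @param path optional TSV path; if `NULL` the data.frame is returned only.
#' @return data.frame with `from`, `to`.
#' @export
network_edgelist <- function(net, path = NULL) {
  el <- igraph::as_edgelist(net$graph)
  df <- data.frame(from = el[, 1L], to = el[, 2L], stringsAsFactors = FALSE)
  if (!is.null(path))
    utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  df
}

#' Export a network as GraphML or DOT
#'
#' @param net [build_network()] result.
#' @param path output path.
#' @param format `"graphml"` or `"dot"`.
#' @return invisible `path`.
#' @export
write_network <- function(net, path, format = c("graphml", "dot")) {
  format <- match.arg(format)
  # DOT has no boolean attribute type; igraph coerces and warns
  suppressWarnings(igraph::write_graph(net$graph, path, format = format))
  invisible(path)
}
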