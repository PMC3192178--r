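# Synthetic-data generator: coalescent genealogies embedded in a Yule
# species tree, two linked mitochondrial partitions simulated on the shared
# genealogy, Brownian tip geography, and study-like presets.

#' Simulation configuration
#'
#' Defaults emulate the study design this pipeline targets: 7 species, 120
#' specimens (42 in the focal expanded species, 13 in each of the others),
#' two linked mitochondrial partitions of 1165 + 886 bp on one genealogy,
#' within-species diversity around 1 percent (under 3), between-species
#' divergence of at least 8 percent (above the 6 percent gap), HKY
#' substitution, and geographically structured tips.
#'
#' @param seed integer seed.
#' @param k number of species.
#' @param birth_rate Yule speciation rate.
#' @param samples per-species sample sizes (recycled to `k`).
#' @param theta_site within-species per-site theta.
#' @param growth per-species exponential growth rate (0 = constant size).
#' @param min_between_divergence expected pairwise divergence at the
#'   shallowest species split (species tree rescaled to achieve it).
#' @param locus_lengths two partition lengths in bp.
#' @param kappa HKY transition/transversion rate ratio.
#' @param base_freq equilibrium base frequencies (A, C, G, T).
#' @param gamma_shape optional Gamma rate-heterogeneity shape (NULL = equal
#'   rates).
#' @param root_coords root latitude/longitude (decimal degrees).
#' @param psi Brownian dispersal variance (degrees^2 per unit tree depth).
#' @param missing_fraction fraction of specimens given truncated sequences.
#' @return `sim_config` list.
#' @export
sim_config <- function(seed = 1L, k = 7L, birth_rate = 1,
                       samples = c(42L, rep(13L, 6L)),
                       theta_site = 0.01, growth = 0,
                       min_between_divergence = 0.08,
                       locus_lengths = c(1165L, 886L),
                       kappa = 4, base_freq = c(0.264, 0.139, 0.198, 0.399),
                       gamma_shape = NULL,
                       root_coords = c(30.5, -100.5), psi = 4,
                       missing_fraction = 0.05) {
  samples <- rep_len(as.integer(samples), k)
  stopifnot(k >= 1L, all(samples >= 1L), birth_rate > 0, theta_site > 0,
            all(locus_lengths >= 1L), kappa > 0, psi >= 0,
            missing_fraction >= 0, missing_fraction < 1)
  structure(list(seed = as.integer(seed), k = as.integer(k),
                 birth_rate = birth_rate, samples = samples,
                 theta_site = theta_site, growth = growth,
                 min_between_divergence = min_between_divergence,
                 locus_lengths = as.integer(locus_lengths), kappa = kappa,
                 base_freq = base_freq / sum(base_freq),
                 gamma_shape = gamma_shape,
                 root_coords = root_coords, psi = psi,
                 missing_fraction = missing_fraction),
            class = "sim_config")
}

#' Named simulation presets
#'
#' `"paper"`: the 7-species, 120-specimen emulation of the study design,
#' with recent within-species expansion (star-like genealogies, negative
#' Tajima's D, shallow within-species divergence well under 3 percent).
#' `"expansion"`: one recently expanded species (42 specimens, strong
#' exponential growth, star-like genealogy, negative Tajima's D expected).
#' `"null"`: one constant-size species (no expansion signal expected).
#'
#' @param preset preset name.
#' @param seed integer seed.
#' @return `sim_config`.
#' @export
sim_preset <- function(preset = c("paper", "expansion", "null"), seed = 1L) {
  preset <- match.arg(preset)
  switch(preset,
    paper = sim_config(seed = seed, growth = 5),
    expansion = sim_config(seed = seed, k = 1L, samples = 42L,
                           theta_site = 0.02, growth = 20,
                           missing_fraction = 0),
    null = sim_config(seed = seed, k = 1L, samples = 42L,
                      theta_site = 0.005, growth = 0, missing_fraction = 0))
}

#' Simulate an ultrametric Yule species tree
#'
#' Pure-birth tree conditioned on `k` tips (branching waits exponential in
#' the number of extant lineages).
#'
#' @param k number of species (tips).
#' @param birth_rate speciation rate.
#' @return ultrametric `phylo` with tips `sp1..spk`; for `k = 1` a
#'   single-tip stub with a root edge of expected length `1/birth_rate`.
#' @export
simulate_species_tree <- function(k, birth_rate = 1) {
  labels <- paste0("sp", seq_len(k))
  if (k == 1L) {
    tr <- list(edge = matrix(c(2L, 1L), 1L, 2L),
               edge.length = stats::rexp(1L, birth_rate),
               Nnode = 1L, tip.label = labels)
    class(tr) <- "phylo"
    return(tr)
  }
  # forward pure birth: with i lineages the next split waits Exp(i * rate);
  # the tree is cut one (unobserved) waiting time after the k-th lineage
  # appears, so E[root age] = (H_k - 1) / birth_rate
  n <- k
  t <- 0
  nxt_int <- n + 1L
  # represent active lineages by provisional ids; internals n+1.., tips later
  act_ids <- nxt_int        # root lineage
  birth <- stats::setNames(0, nxt_int)
  kids <- list()
  nxt_int <- nxt_int + 1L
  while (length(act_ids) < k) {
    i <- length(act_ids)
    t <- t + stats::rexp(1L, i * birth_rate)
    sp <- sample.int(i, 1L)
    par <- act_ids[sp]
    c1 <- nxt_int; c2 <- nxt_int + 1L
    nxt_int <- nxt_int + 2L
    kids[[as.character(par)]] <- c(c1, c2)
    birth[as.character(c1)] <- t
    birth[as.character(c2)] <- t
    act_ids <- c(act_ids[-sp], c1, c2)
  }
  t_end <- t + stats::rexp(1L, k * birth_rate)
  # map: active lineages -> tips 1..k, others -> internal numbers
  id_map <- integer(0)
  for (j in seq_len(k)) id_map[as.character(act_ids[j])] <- j
  internals <- setdiff(names(kids), as.character(act_ids))
  # order internals by birth time so root (birth 0) gets n+1
  internals <- internals[order(birth[internals])]
  for (j in seq_along(internals))
    id_map[internals[j]] <- k + j
  edges <- list(); elens <- numeric(0)
  for (par in internals) {
    for (ch in kids[[par]]) {
      edges[[length(edges) + 1L]] <- c(id_map[par], id_map[as.character(ch)])
      ch_end <- if (as.character(ch) %in% internals)
        birth[as.character(kids[[as.character(ch)]][1L])] else t_end
      elens <- c(elens, ch_end - birth[as.character(ch)])
    }
  }
  tr <- list(edge = do.call(rbind, edges), edge.length = elens,
             Nnode = k - 1L, tip.label = labels)
  class(tr) <- "phylo"
  ape::reorder.phylo(tr, "cladewise")
}

#' Simulate a gene genealogy within a species tree
#'
#' Censored coalescent: each species' samples coalesce (constant size or
#' exponential growth, `theta`-scaled time = coalescent units) along its
#' terminal branch; surviving lineages merge at species-tree nodes and keep
#' coalescing in ancestral populations. A single genealogy is returned (the
#' two mitochondrial partitions are linked).
#'
#' @param species_tree ultrametric `phylo` (heights in coalescent units).
#' @param samples per-species sample sizes, in `species_tree$tip.label`
#'   order.
#' @param growth within-species exponential growth rate.
#' @return list: `tree` (ultrametric `phylo`, tips `<species>_<i>`),
#'   `species_of` (named character vector tip -> species).
#' @export
simulate_gene_genealogy <- function(species_tree, samples, growth = 0) {
  k <- ape::Ntip(species_tree)
  samples <- rep_len(as.integer(samples), k)
  h <- node_heights(species_tree)
  labels <- unlist(lapply(seq_len(k), function(s)
    paste0(species_tree$tip.label[s], "_", seq_len(samples[s]))))
  n <- sum(samples)
  species_of <- stats::setNames(rep(species_tree$tip.label, samples), labels)
  # lineage bookkeeping: global node ids, tips 1..n
  heights <- numeric(2L * n - 1L)
  edge <- matrix(0L, 0L, 2L)
  elen <- numeric(0)
  nxt <- n + 1L
  offs <- c(0L, cumsum(samples))
  # pools[[node of species tree]] = active lineage ids entering that branch
  pools <- vector("list", k + species_tree$Nnode)
  for (s in seq_len(k)) pools[[s]] <- (offs[s] + 1L):offs[s + 1L]
  coalesce_pool <- function(pool, t_start, t_end, growth) {
    # coalesce within [t_start, t_end] (t_end may be Inf for the root)
    t <- t_start
    while (length(pool) > 1L) {
      i <- length(pool)
      rate <- i * (i - 1) / 2
      E <- stats::rexp(1L)
      w <- if (growth == 0) E / rate
        else log(exp(growth * t) + growth * E / rate) / growth - t
      if (t + w > t_end) break
      t <- t + w
      pick <- sample.int(i, 2L)
      for (ch in pool[pick]) {
        edge <<- rbind(edge, c(nxt, ch))
        elen <<- c(elen, t - heights[ch])
      }
      heights[nxt] <<- t
      pool <- c(pool[-pick], nxt)
      nxt <<- nxt + 1L
    }
    pool
  }
  # process species-tree nodes from tips upward
  stn <- k + seq_len(species_tree$Nnode)
  parent_st <- integer(k + species_tree$Nnode)
  parent_st[species_tree$edge[, 2L]] <- species_tree$edge[, 1L]
  for (s in seq_len(k)) {
    # a lone species is one population: its (possibly growing) coalescent
    # runs to the MRCA rather than being censored at the stub branch
    t_end <- if (k == 1L) Inf else h[parent_st[s]]
    pools[[s]] <- coalesce_pool(pools[[s]], 0, t_end, growth)
  }
  for (nd in stn[order(h[stn])]) {
    kids <- species_tree$edge[species_tree$edge[, 1L] == nd, 2L]
    pool <- unlist(pools[kids])
    t_end <- if (parent_st[nd] == 0L) Inf else h[parent_st[nd]]
    pools[[nd]] <- coalesce_pool(pool, h[nd], t_end, 0)
  }
  root_pool <- pools[[stn[which.max(h[stn])]]]
  if (length(root_pool) != 1L) stop("genealogy failed to fully coalesce")
  total <- nxt - 1L
  # renumber internals to ape convention (root = n + 1, built last)
  new_of <- integer(total)
  new_of[seq_len(n)] <- seq_len(n)
  new_of[total:(n + 1L)] <- n + seq_len(total - n)
  edge2 <- matrix(new_of[edge], ncol = 2L)
  tr <- list(edge = edge2, edge.length = elen, Nnode = total - n,
             tip.label = labels)
  class(tr) <- "phylo"
  tr <- ape::reorder.phylo(tr, "cladewise")
  list(tree = tr, species_of = species_of)
}

#' Simulate two linked locus alignments along a genealogy
#'
#' Per-site HKY (optionally +Gamma) substitution with `phangorn::simSeq`
#' along the shared genealogy; branch lengths must already be in expected
#' substitutions per site. Optionally truncates a fraction of specimens at
#' one end of the first partition (emulating shorter reads).
#'
#' @param genealogy `phylo` in substitutions/site.
#' @param config `sim_config`.
#' @return list: `co1`, `nd1_16s` ([mt_alignment()] per partition),
#'   `concatenated` (with both partitions), `specimens` (data.frame).
#' @export
simulate_sequences <- function(genealogy, config) {
  bf <- config$base_freq
  # HKY rate matrix in phangorn's Q order (ac, ag, at, cg, ct, gt)
  Q <- c(1, config$kappa, 1, 1, config$kappa, 1)
  L <- sum(config$locus_lengths)
  sim_args <- list(genealogy, l = L, Q = Q, bf = bf, type = "DNA")
  if (!is.null(config$gamma_shape)) {
    # discrete-gamma site rates via per-site simulation in 4 rate classes
    rates <- phangorn::discrete.gamma(config$gamma_shape, 4)
    counts <- stats::rmultinom(1L, L, rep(0.25, 4))[, 1L]
    parts <- lapply(seq_len(4L), function(c4) {
      if (counts[c4] == 0L) return(NULL)
      as.character(phangorn::simSeq(genealogy, l = counts[c4], Q = Q,
                                    bf = bf, type = "DNA",
                                    rate = rates[c4]))
    })
    m <- do.call(cbind, parts[!vapply(parts, is.null, logical(1))])
  } else {
    m <- as.character(do.call(phangorn::simSeq, sim_args))
  }
  m <- toupper(m)
  rownames(m) <- genealogy$tip.label
  i1 <- seq_len(config$locus_lengths[1L])
  i2 <- config$locus_lengths[1L] + seq_len(config$locus_lengths[2L])
  m1 <- m[, i1, drop = FALSE]
  m2 <- m[, i2, drop = FALSE]
  if (config$missing_fraction > 0) {
    ntrunc <- round(config$missing_fraction * nrow(m))
    if (ntrunc > 0L) {
      who <- sample(seq_len(nrow(m)), ntrunc)
      for (w in who) {
        cut <- sample(20:120, 1L)
        m1[w, seq_len(cut)] <- "N"
      }
    }
  }
  ids <- genealogy$tip.label
  co1 <- mt_alignment(ids, m1, list(co1 = i1 - 0L))
  nd1 <- mt_alignment(ids, m2, list(nd1_16s = seq_len(length(i2))))
  concat <- concatenate(co1, nd1)
  list(co1 = co1, nd1_16s = nd1, concatenated = concat)
}

#' Simulate tip coordinates by Brownian dispersal on a genealogy
#'
#' Displacement along each branch is bivariate normal, mean zero, variance
#' `psi * branch length` per axis.
#'
#' @param genealogy `phylo`.
#' @param root_coords `c(lat, lon)`.
#' @param psi variance per unit branch length per axis (degrees^2).
#' @return data.frame with `specimen_id`, `lat`, `lon`.
#' @export
simulate_geography <- function(genealogy, root_coords, psi) {
  stopifnot(psi >= 0)
  n <- ape::Ntip(genealogy)
  nn <- n + genealogy$Nnode
  pos <- matrix(NA_real_, nn, 2L)
  pos[n + 1L, ] <- root_coords
  tr <- ape::reorder.phylo(genealogy, "cladewise")   # parents before children
  for (e in seq_len(nrow(tr$edge))) {
    p <- tr$edge[e, 1L]; c_ <- tr$edge[e, 2L]
    sdv <- sqrt(psi * tr$edge.length[e])
    pos[c_, ] <- pos[p, ] + stats::rnorm(2L, 0, sdv)
  }
  data.frame(specimen_id = tr$tip.label,
             lat = pos[seq_len(n), 1L], lon = pos[seq_len(n), 2L],
             stringsAsFactors = FALSE)
}

#' Generate a complete synthetic dataset
#'
#' Runs the full generator under one seed: Yule species tree (rescaled so
#' the shallowest species split yields the configured minimum between-species
#' divergence), censored coalescent genealogy, two linked sequence
#' partitions, Brownian tip geography, and a specimen table. Optionally
#' writes FASTA/CSV/Newick files (byte-identical for a fixed seed).
#'
#' @param config `sim_config`.
#' @param dir optional output directory; created if needed.
#' @return list of class `sim_dataset`: `co1`, `nd1_16s`, `concatenated`,
#'   `specimens` (specimen table with species, group, lat/lon),
#'   `species_tree`, `genealogy` (substitutions/site), `genealogy_coal`
#'   (coalescent units), `truth` (generating parameters), `files`.
#' @export
generate_dataset <- function(config = sim_config(), dir = NULL) {
  set.seed(config$seed)
  st <- simulate_species_tree(config$k, config$birth_rate)
  # species-tree time is in coalescent units (2N generations); rescale so
  # the shallowest split gives the target expected between-species
  # divergence: E[div] = theta_site * (t + 1) for split at time t
  if (config$k > 1L) {
    hts <- node_heights(st)
    inner <- (config$k + 1L):(config$k + st$Nnode)
    shallow <- min(hts[inner])
    # multiple hits depress observed p-distance below the substitution
    # load; invert Jukes-Cantor so the OBSERVED divergence hits the target
    d_subst <- -0.75 * log(1 - 4 * config$min_between_divergence / 3)
    target_t <- d_subst / config$theta_site - 1
    st$edge.length <- st$edge.length * target_t / shallow
  }
  gg <- simulate_gene_genealogy(st, config$samples, config$growth)
  gene_coal <- gg$tree
  gene_subst <- gene_coal
  gene_subst$edge.length <- gene_coal$edge.length * config$theta_site / 2
  seqs <- simulate_sequences(gene_subst, config)
  geo <- simulate_geography(gene_coal, config$root_coords,
                            config$psi / max(node_heights(gene_coal)))
  specimens <- data.frame(
    specimen_id = gene_coal$tip.label,
    species = gg$species_of[gene_coal$tip.label],
    stringsAsFactors = FALSE)
  specimens <- merge(specimens, geo, by = "specimen_id", sort = TRUE)
  specimens$group <- ifelse(specimens$lat >= stats::median(specimens$lat),
                            "northern", "southern")
  files <- NULL
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    f <- list(co1 = file.path(dir, "co1.fasta"),
              nd1_16s = file.path(dir, "nd1_16s.fasta"),
              specimens = file.path(dir, "specimens.csv"),
              species_tree = file.path(dir, "species_tree.nwk"),
              genealogy = file.path(dir, "genealogy.nwk"))
    write_alignment(seqs$co1, f$co1, "fasta")
    write_alignment(seqs$nd1_16s, f$nd1_16s, "fasta")
    utils::write.csv(specimens, f$specimens, row.names = FALSE)
    ape::write.tree(st, f$species_tree)
    ape::write.tree(gene_coal, f$genealogy)
    files <- f
  }
  structure(list(co1 = seqs$co1, nd1_16s = seqs$nd1_16s,
                 concatenated = seqs$concatenated, specimens = specimens,
                 species_tree = st, genealogy = gene_subst,
                 genealogy_coal = gene_coal,
                 truth = list(config = config,
                              species_of = gg$species_of,
                              root_coords = config$root_coords),
                 files = files),
            class = "sim_dataset")
}
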