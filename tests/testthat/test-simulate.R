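test_that("datasets are byte-identical under a fixed seed", {
  cfg <- sim_config(seed = 9, k = 2, samples = c(5, 4),
                    locus_lengths = c(80, 60))
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  ds1 <- generate_dataset(cfg, dir = d1)
  ds2 <- generate_dataset(cfg, dir = d2)
  for (f in names(ds1$files)) {
    expect_identical(readLines(ds1$files[[f]]), readLines(ds2$files[[f]]))
  }
  expect_identical(ds1$concatenated$matrix, ds2$concatenated$matrix)
})

test_that("Yule species trees match the forward pure-birth expectation", {
  set.seed(42)
  one <- simulate_species_tree(1, 1)
  expect_equal(ape::Ntip(one), 1L)
  expect_equal(nrow(one$edge), 1L)

  k <- 5; lam <- 2
  ages <- replicate(800, {
    tr <- simulate_species_tree(k, lam)
    max(ape::node.depth.edgelength(tr))
  })
  expected <- (sum(1 / seq_len(k)) - 1) / lam     # (H_k - 1) / lambda
  expect_equal(mean(ages), expected, tolerance = 0.05)
  # two-tip case: root age is the Exp(2 lambda) cut wait
  ages2 <- replicate(800, {
    tr <- simulate_species_tree(2, lam)
    max(ape::node.depth.edgelength(tr))
  })
  expect_equal(mean(ages2), 1 / (2 * lam), tolerance = 0.08)
})

test_that("gene genealogies respect the species tree and coalescent scaling", {
  # one species, n = 2: mean pairwise TMRCA is 1 (in 2N units)
  set.seed(8)
  st <- simulate_species_tree(1, 1)
  tm <- replicate(600, {
    g <- simulate_gene_genealogy(st, 2, growth = 0)
    max(ape::node.depth.edgelength(g$tree))
  })
  expect_equal(mean(tm), 1, tolerance = 0.12)

  # n = 1 per species: genealogy topology equals the species tree once
  # branches are long enough that ancestral lineage sorting is complete
  set.seed(10)
  st5 <- simulate_species_tree(5, 1)
  st5$edge.length <- st5$edge.length * 50
  g5 <- simulate_gene_genealogy(st5, rep(1, 5))
  gt <- g5$tree
  gt$tip.label <- sub("_1$", "", gt$tip.label)
  expect_equal(ape::dist.topo(ape::unroot(gt), ape::unroot(st5)), 0,
               ignore_attr = TRUE)
  # every tip is labelled with its species
  expect_true(all(g5$species_of == sub("_1$", "", names(g5$species_of))))
})

test_that("sequence simulation follows branch lengths and the HKY model", {
  set.seed(13)
  st <- simulate_species_tree(2, 1)
  g <- simulate_gene_genealogy(st, c(4, 4))
  # zero branch lengths: identical sequences
  g0 <- g$tree
  g0$edge.length[] <- 0
  cfg <- sim_config(seed = 13, k = 2, locus_lengths = c(50, 30))
  seqs <- simulate_sequences(g0, cfg)
  expect_equal(length(collapse_haplotypes(seqs$concatenated)$haplotype_id), 1L)

  # segregating sites close to the Watterson expectation theta * a1
  n <- 15; theta <- 6
  sim <- sim_coalescent_stats(n, reps = 400, theta = theta)
  a1 <- sum(1 / seq_len(n - 1))
  expect_equal(mean(sim$S), theta * a1, tolerance = 0.08)

  # transition/transversion ratio increases with kappa
  tstv <- function(kappa) {
    set.seed(99)
    cfgk <- sim_config(seed = 99, k = 1, samples = 6,
                       locus_lengths = c(400, 200), theta_site = 0.05,
                       kappa = kappa, missing_fraction = 0)
    ds <- generate_dataset(cfgk)
    m <- ds$concatenated$matrix
    ts <- 0; tv <- 0
    pur <- c("A", "G")
    for (i in 1:(nrow(m) - 1)) for (j in (i + 1):nrow(m)) {
      diffs <- which(m[i, ] != m[j, ])
      for (s in diffs) {
        same_class <- (m[i, s] %in% pur) == (m[j, s] %in% pur)
        if (same_class) ts <- ts + 1 else tv <- tv + 1
      }
    }
    ts / max(tv, 1)
  }
  expect_gt(tstv(8), tstv(1))
})

test_that("Brownian geography is seeded, centered and tree-structured", {
  set.seed(3)
  st <- simulate_species_tree(2, 1)
  g <- simulate_gene_genealogy(st, c(6, 6))$tree
  # psi = 0: every tip at the root
  geo0 <- simulate_geography(g, c(30, -100), 0)
  expect_true(all(geo0$lat == 30 & geo0$lon == -100))
  # variance grows with psi
  set.seed(4)
  geo1 <- simulate_geography(g, c(30, -100), 0.5)
  set.seed(4)
  geo2 <- simulate_geography(g, c(30, -100), 8)
  expect_gt(stats::var(geo2$lat), stats::var(geo1$lat))
  # siblings covary more than cross-species pairs, on average
  set.seed(6)
  covs <- replicate(200, {
    geo <- simulate_geography(g, c(0, 0), 1)
    sp <- sub("_.*", "", geo$specimen_id)
    d <- as.matrix(stats::dist(cbind(geo$lat, geo$lon)))
    same <- d[outer(sp, sp, "==") & upper.tri(d)]
    diff <- d[outer(sp, sp, "!=") & upper.tri(d)]
    mean(same) - mean(diff)
  })
  expect_lt(mean(covs), 0)
})

test_that("the expansion preset produces star-like negative-D samples", {
  hits <- 0L
  reps <- 20
  for (i in seq_len(reps)) {
    ds <- generate_dataset(sim_preset("expansion", seed = 1000 + i))
    D <- tajimas_d(ds$concatenated)
    if (!is.na(D) && D < 0) hits <- hits + 1L
  }
  expect_gte(hits / reps, 0.9)
})

test_that("the paper-emulation preset has the advertised shape", {
  ds <- generate_dataset(sim_preset("paper", seed = 5))
  expect_equal(ncol(ds$concatenated$matrix), 2051L)
  expect_equal(length(ds$concatenated$ids), 120L)
  expect_equal(length(unique(ds$specimens$species)), 7L)
  expect_equal(names(ds$concatenated$partitions), c("co1", "nd1_16s"))
  g <- stats::setNames(ds$specimens$species, ds$specimens$specimen_id)
  gs <- group_distance_summary(pdist_matrix(ds$concatenated), g)
  expect_gt(gs$min_between, 0.06)
  expect_lt(gs$max_within, 0.03)
})
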