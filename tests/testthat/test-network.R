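test_that("connection limit is monotone and matches the oracle", {
  for (m in c(50, 200, 886, 2051)) {
    for (j in c(1, 3, 8, 15)) {
      expect_equal(parsimony_probability(j, m), oracle_parsprob(j, m),
                   tolerance = 1e-8)
    }
  }
  # oracle-equivalent limit
  for (m in c(50, 2051)) {
    j_pkg <- connection_limit(m, 0.95)
    j_or <- 0
    while (oracle_parsprob(j_or + 1, m) >= 0.95) j_or <- j_or + 1
    expect_equal(j_pkg, j_or)
  }
  # monotone: stricter confidence, fewer steps; longer sequences, more steps
  expect_true(connection_limit(2051, 0.99) <= connection_limit(2051, 0.95))
  expect_true(connection_limit(2051, 0.95) <= connection_limit(2051, 0.90))
  expect_true(connection_limit(50, 0.95) < connection_limit(2051, 0.95))
})

test_that("network construction obeys the step limit and adds intermediates", {
  base <- strsplit(paste(rep("A", 40), collapse = ""), "")[[1]]
  seq_at <- function(pos) {
    v <- base; v[pos] <- "T"; paste(v, collapse = "")
  }
  # two haplotypes 1 step apart: one edge, no intermediates
  a <- make_align(seq_at(integer(0)), seq_at(1))
  h <- collapse_haplotypes(a)
  net <- build_network(h, j = 5)
  expect_equal(igraph::ecount(net$graph), 1L)
  expect_equal(igraph::vcount(net$graph), 2L)
  expect_equal(max(net$components), 1L)
  # j + 1 steps apart: two components
  b <- make_align(seq_at(integer(0)), seq_at(1:6))
  net2 <- build_network(collapse_haplotypes(b), j = 5)
  expect_equal(max(net2$components), 2L)
  expect_equal(igraph::ecount(net2$graph), 0L)
  # 3 steps apart within the limit: 2 intermediates materialized
  c3 <- make_align(seq_at(integer(0)), seq_at(1:3))
  net3 <- build_network(collapse_haplotypes(c3), j = 5)
  expect_equal(igraph::vcount(net3$graph), 4L)
  expect_equal(igraph::ecount(net3$graph), 3L)
  expect_true(all(igraph::degree(net3$graph)[
    !igraph::V(net3$graph)$observed] >= 2))
})

test_that("network path lengths equal Hamming distance and the BFS oracle", {
  set.seed(66)
  cfg <- sim_config(seed = 66, k = 1, samples = 12,
                    locus_lengths = c(150, 100), theta_site = 0.02,
                    missing_fraction = 0)
  ds <- generate_dataset(cfg)
  h <- collapse_haplotypes(ds$concatenated)
  j <- connection_limit(ncol(ds$concatenated$matrix))
  net <- build_network(h, j)
  ids <- h$haplotype_id
  gdist <- igraph::distances(net$graph, v = ids, to = ids, weights = NA)
  for (a in seq_along(ids)) for (b in seq_along(ids)) {
    if (a >= b) next
    hd <- net$distances[ids[a], ids[b]]
    if (is.finite(gdist[ids[a], ids[b]]) && hd <= j) {
      expect_equal(unname(gdist[ids[a], ids[b]]), unname(hd))
    }
  }
  # steps_from_ancestor equals an independent BFS
  anc <- ancestral_haplotype(net)
  el <- network_edgelist(net)
  allnodes <- igraph::V(net$graph)$name
  bfs <- oracle_bfs(as.matrix(el), anc$ancestor[1], allnodes)
  expect_equal(anc$steps[names(anc$steps) %in% names(bfs)],
               bfs[names(anc$steps)[names(anc$steps) %in% names(bfs)]])
  expect_equal(unname(anc$steps[anc$ancestor[1]]), 0)
})

test_that("ancestral haplotype scoring prefers frequent internal nodes", {
  # star: center seen 10 times, 4 tips once each, all 1 step from center
  base <- strsplit(paste(rep("A", 30), collapse = ""), "")[[1]]
  seq_at <- function(pos) { v <- base; v[pos] <- "T"; paste(v, collapse = "") }
  seqs <- c(rep(seq_at(integer(0)), 10),
            seq_at(1), seq_at(2), seq_at(3), seq_at(4))
  a <- mt_alignment(c(paste0("c", 1:10), paste0("tip", 1:4)), seqs)
  h <- collapse_haplotypes(a)
  net <- build_network(h, j = 5)
  anc <- ancestral_haplotype(net)
  center_h <- h$haplotype_id[h$frequency == 10]
  expect_equal(anc$ancestor, center_h)
  expect_setequal(anc$derived, setdiff(h$haplotype_id, center_h))

  # equal-frequency path: middle node wins on degree
  p <- make_align(seq_at(integer(0)), seq_at(1), seq_at(1:2))
  hp <- collapse_haplotypes(p)
  netp <- build_network(hp, j = 5)
  ancp <- ancestral_haplotype(netp)
  mid <- hp$haplotype_id[hp$representative == "s2"]
  expect_equal(ancp$ancestor, mid)
})

test_that("duplicates change frequencies, not topology", {
  set.seed(9)
  a <- random_align(8, 60)
  h1 <- collapse_haplotypes(a)
  a2 <- mt_alignment(c(a$ids, "dup1"), rbind(a$matrix, a$matrix[3, ]))
  h2 <- collapse_haplotypes(a2)
  j <- 10
  n1 <- build_network(h1, j)
  n2 <- build_network(h2, j)
  expect_equal(igraph::ecount(n1$graph), igraph::ecount(n2$graph))
  expect_equal(igraph::vcount(n1$graph), igraph::vcount(n2$graph))
  expect_equal(sum(h2$frequency), sum(h1$frequency) + 1L)
})

test_that("species separate into distinct components on emulated data", {
  cfg <- sim_config(seed = 404, k = 3, samples = c(8, 6, 6),
                    locus_lengths = c(700, 500), theta_site = 0.004,
                    min_between_divergence = 0.10, missing_fraction = 0)
  ds <- generate_dataset(cfg)
  h <- collapse_haplotypes(ds$concatenated)
  j <- connection_limit(ncol(ds$concatenated$matrix))
  net <- build_network(h, j)
  sp_of_hap <- ds$specimens$species[match(h$representative,
                                          ds$specimens$specimen_id)]
  # no component mixes species
  for (cc in unique(net$components)) {
    expect_equal(length(unique(sp_of_hap[net$components == cc])), 1L)
  }
  expect_gte(max(net$components), 3L)
})

test_that("network and distance exports write readable files", {
  a <- make_align("AAAA", "AAAT", "AATT")
  net <- build_network(collapse_haplotypes(a), j = 3)
  gml <- withr::local_tempfile(fileext = ".graphml")
  dot <- withr::local_tempfile(fileext = ".dot")
  write_network(net, gml, "graphml")
  write_network(net, dot, "dot")
  expect_true(file.size(gml) > 0 && file.size(dot) > 0)
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_pdist(pdist_matrix(a), tsv)
  expect_equal(nrow(utils::read.delim(tsv)), 3L)
  phy <- withr::local_tempfile(fileext = ".phy")
  write_pdist(pdist_matrix(a), phy, phylip = TRUE)
  expect_match(readLines(phy)[1], "3")
})
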