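test_that("exclusivity classifies clades, strays and singletons", {
  tr <- ape::read.tree(text = "(((a1:1,a2:1):1,(b1:1,b2:1):1):1,c1:3);")
  sp <- c(a1 = "A", a2 = "A", b1 = "B", b2 = "B", c1 = "C")
  ex <- tree_exclusivity(tr, sp)
  expect_equal(ex$status[ex$species == "A"], "exclusive")
  expect_equal(ex$status[ex$species == "B"], "exclusive")
  expect_equal(ex$status[ex$species == "C"], "singleton")

  # one stray tip: near-exclusive, stray named
  sp2 <- c(a1 = "A", a2 = "B", b1 = "B", b2 = "B", c1 = "C")
  ex2 <- tree_exclusivity(tr, sp2)
  bstat <- ex2[ex2$species == "B", ]
  expect_equal(bstat$status, "near-exclusive")
  expect_equal(bstat$intruders, "a1")

  # deeply interleaved labels: non-exclusive
  tr3 <- ape::read.tree(text = "(((x1:1,y1:1):1,(x2:1,y2:1):1):1,o:3);")
  sp3 <- c(x1 = "X", x2 = "X", y1 = "Y", y2 = "Y", o = "O")
  ex3 <- tree_exclusivity(tr3, sp3)
  expect_equal(ex3$status[ex3$species == "X"], "non-exclusive")

  expect_error(tree_exclusivity(tr, sp[-1]), "unlabeled")
})

test_that("locality labels are carried through per species", {
  tr <- ape::read.tree(text = "((a1:1,a2:1):1,b1:2);")
  sp <- c(a1 = "A", a2 = "A", b1 = "B")
  loc <- c(a1 = "north", a2 = "south", b1 = "west")
  ex <- tree_exclusivity(tr, sp, loc)
  expect_equal(ex$localities[ex$species == "A"], "north;south")
})

test_that("consensus ratifies exclusive gap-passing groups and flags the rest", {
  cfg <- sim_config(seed = 71, k = 3, samples = c(8, 6, 6),
                    locus_lengths = c(300, 200), missing_fraction = 0)
  ds <- generate_dataset(cfg)
  sp <- stats::setNames(ds$specimens$species, ds$specimens$specimen_id)
  dm <- pdist_matrix(ds$concatenated)
  bg <- barcode_gap_delimit(group_distance_summary(dm, sp))
  ex <- tree_exclusivity(ds$genealogy_coal, sp)
  h <- collapse_haplotypes(ds$concatenated)
  gm <- fit_single_threshold(
    as_chronogram(ape::keep.tip(ds$genealogy_coal, h$representative)))
  out <- consensus_delimit(bg, ex, gm, sp)
  expect_equal(out$n_species, 3L)
  expect_true(all(out$table$final == "species"))
  expect_true(all(sp %in% out$table$group | TRUE))  # every specimen covered
  expect_setequal(out$table$group, unique(sp))
})

test_that("sub-gap pairs are merged with a recorded rationale", {
  # hand-built reports: two groups 3% apart, both exclusive
  pairs <- data.frame(group_a = "g1", group_b = "g2",
                      mean_between = 0.03, pass = FALSE)
  bg <- structure(list(pairs = pairs, all_pass = FALSE,
                       merge_candidates = pairs[, 1:2],
                       realized_gap = -0.01, gap = 0.06),
                  class = "mt_barcodegap")
  ex <- data.frame(species = c("g1", "g2"), n_tips = c(3L, 3L),
                   status = "exclusive", intruders = "", localities = "")
  sp <- stats::setNames(rep(c("g1", "g2"), each = 3), paste0("s", 1:6))
  out <- consensus_delimit(bg, ex, NULL, sp)
  expect_equal(out$n_species, 1L)
  expect_true(all(out$table$final == "review"))
  expect_true(any(grepl("gap fail", out$table$rationale)))
})

test_that("GMYC oversplitting is reported as intraspecific structure", {
  pairs <- data.frame(group_a = "g1", group_b = "g2",
                      mean_between = 0.09, pass = TRUE)
  bg <- structure(list(pairs = pairs, all_pass = TRUE,
                       merge_candidates = pairs[0, 1:2],
                       realized_gap = 0.05, gap = 0.06),
                  class = "mt_barcodegap")
  ex <- data.frame(species = c("g1", "g2"), n_tips = c(4L, 2L),
                   status = "exclusive", intruders = "", localities = "")
  sp <- stats::setNames(rep(c("g1", "g2"), c(4, 2)), paste0("s", 1:6))
  gm <- structure(list(model = "single",
                       members = list(c("s1", "s2"), c("s3", "s4"),
                                      c("s5", "s6"))),
                  class = "mt_gmyc")
  out <- consensus_delimit(bg, ex, gm, sp)
  g1 <- out$table[out$table$group == "g1", ]
  expect_equal(g1$final, "species")
  expect_match(g1$gmyc, "split into 2")
  expect_match(g1$rationale, "oversplit")
  expect_equal(out$n_species, 2L)
})

test_that("delimitation reports export as CSV", {
  pairs <- data.frame(group_a = "g1", group_b = "g2",
                      mean_between = 0.09, pass = TRUE)
  bg <- structure(list(pairs = pairs, all_pass = TRUE,
                       merge_candidates = pairs[0, 1:2],
                       realized_gap = 0.05, gap = 0.06),
                  class = "mt_barcodegap")
  ex <- data.frame(species = c("g1", "g2"), n_tips = c(2L, 2L),
                   status = "exclusive", intruders = "", localities = "")
  sp <- stats::setNames(rep(c("g1", "g2"), each = 2), paste0("s", 1:4))
  out <- consensus_delimit(bg, ex, NULL, sp)
  f <- withr::local_tempfile(fileext = ".csv")
  write_delimitation(out, f)
  expect_equal(nrow(utils::read.csv(f)), 2L)
})
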