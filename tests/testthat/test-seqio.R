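test_that("FASTA reading, validation and round trips behave", {
  f <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">s1", "ACGTAC", ">s2", "ACGTAA"), f)
  a <- read_alignment(f, "fasta")
  expect_equal(dim(a), c(2L, 6L))
  expect_equal(a$ids, c("s1", "s2"))
  expect_equal(paste(a$matrix[2, ], collapse = ""), "ACGTAA")

  empty <- withr::local_tempfile(fileext = ".fasta")
  writeLines(character(0), empty)
  expect_error(read_alignment(empty, "fasta"), "no records")

  ragged <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">s1", "ACGT", ">s2", "ACGTAA"), ragged)
  expect_error(read_alignment(ragged, "fasta"), "ragged")

  expect_error(mt_alignment("s1", "ACXT"), "X")

  # round trip both formats
  b <- make_align("ACGT-CGT", "ACGTNCGA", "ACGTACGT")
  for (fmt in c("fasta", "nexus")) {
    tmp <- withr::local_tempfile(fileext = paste0(".", fmt))
    write_alignment(b, tmp, fmt)
    b2 <- read_alignment(tmp, fmt)
    expect_equal(b2$matrix, b$matrix, ignore_attr = TRUE)
    expect_equal(b2$ids, b$ids)
  }
})

test_that("interleaved and sequential NEXUS give the same matrix", {
  seqs <- c(s1 = "ACGTACGTAC", s2 = "ACGTTCGTAA", s3 = "AGGTACGAAC")
  seq_file <- withr::local_tempfile(fileext = ".nex")
  writeLines(c(
    "#NEXUS", "BEGIN DATA;",
    "DIMENSIONS NTAX=3 NCHAR=10;",
    "FORMAT DATATYPE=DNA MISSING=N GAP=-;",
    "MATRIX",
    paste("s1", seqs[["s1"]]), paste("s2", seqs[["s2"]]),
    paste("s3", seqs[["s3"]]), ";", "END;"), seq_file)
  int_file <- withr::local_tempfile(fileext = ".nex")
  writeLines(c(
    "#NEXUS", "BEGIN DATA;",
    "DIMENSIONS NTAX=3 NCHAR=10;",
    "FORMAT DATATYPE=DNA MISSING=N GAP=- INTERLEAVE=YES;",
    "MATRIX",
    paste("s1", substr(seqs[["s1"]], 1, 5)),
    paste("s2", substr(seqs[["s2"]], 1, 5)),
    paste("s3", substr(seqs[["s3"]], 1, 5)),
    "",
    paste("s1", substr(seqs[["s1"]], 6, 10)),
    paste("s2", substr(seqs[["s2"]], 6, 10)),
    paste("s3", substr(seqs[["s3"]], 6, 10)),
    ";", "END;"), int_file)
  a_seq <- read_alignment(seq_file, "nexus")
  a_int <- read_alignment(int_file, "nexus")
  expect_equal(a_int$matrix, a_seq$matrix)
  # both match the literal sequences
  expect_equal(apply(a_seq$matrix, 1, paste, collapse = ""),
               seqs, ignore_attr = TRUE)
})

test_that("state canonicalization: ? and edge gaps become N, internal gap kept", {
  a <- make_align("--ACG-T?A--")
  expect_equal(paste(a$matrix[1, ], collapse = ""), "NNACG-TNANN")
})

test_that("concatenation joins on ids, pads missing loci, records partitions", {
  a <- mt_alignment(c("x", "y", "z"),
                    c("ACGTACGTAC", "ACGTTCGTAA", "AGGTACGAAC"),
                    list(co1 = 1:10))
  b <- mt_alignment(c("x", "y"), c("GGGTTT", "GGGTTA"),
                    list(nd1 = 1:6))
  ab <- concatenate(a, b)
  expect_equal(ncol(ab$matrix), 16L)
  expect_equal(names(ab$partitions), c("co1", "nd1"))
  expect_equal(ab$partitions$nd1, 11:16)
  # z lacks locus b: padded with missing
  expect_equal(paste(ab$matrix["z", 11:16], collapse = ""), "NNNNNN")
  # identity with an empty alignment
  empty <- mt_alignment(c("x", "y"), matrix("A", 2, 0)[, 0, drop = FALSE],
                        list(none = integer(0)))
  expect_identical(concatenate(a, empty), a)
  # disjoint ids fail
  c2 <- mt_alignment("w", "ACGTAC")
  expect_error(concatenate(a, c2), "shared")
})

test_that("haplotype collapse groups identical and compatible sequences", {
  a <- make_align(rep("ACGTACGT", 5))
  h <- collapse_haplotypes(a)
  expect_equal(length(h$haplotype_id), 1L)
  expect_equal(h$frequency, 5L)

  b <- make_align("ACGTACGT", "ACGTACGA")
  expect_equal(length(collapse_haplotypes(b)$haplotype_id), 2L)

  # truncated sequence joins its closest fully resolved match
  c3 <- make_align("ACGTACGT", "ACGTACGA", "NNGTACGT")
  h3 <- collapse_haplotypes(c3)
  expect_equal(length(h3$haplotype_id), 2L)
  grp <- h3$members[[which(vapply(h3$members, function(m) "s1" %in% m,
                                  logical(1)))]]
  expect_true("s3" %in% grp)

  # frequencies always sum to the specimen count; collapse is idempotent
  set.seed(101)
  for (rep in 1:5) {
    r <- random_align(8, 30, ambig_frac = 0.05)
    h <- collapse_haplotypes(r)
    expect_equal(sum(h$frequency), 8L)
    h2 <- collapse_haplotypes(h$alignment)
    expect_equal(length(h2$haplotype_id), length(h$haplotype_id))
    expect_true(all(h2$frequency == 1L))
  }
})

test_that("alignment summary matches brute-force per-column scans", {
  inv <- make_align("ACGT", "ACGT", "ACGT", "ACGT")
  s <- alignment_summary(inv)
  expect_equal(s$n_variable_sites, 0L)
  expect_equal(s$n_parsimony_informative, 0L)
  expect_equal(sum(s$base_frequencies), 1, tolerance = 1e-12)

  # variable but not informative (autapomorphy), then informative
  a <- make_align("AAAA", "AAAT", "AAAA", "AAAT")
  s2 <- alignment_summary(a)
  expect_equal(s2$n_variable_sites, 1L)
  expect_equal(s2$n_parsimony_informative, 1L)
  b <- make_align("AAAA", "AAAT", "AAAA")
  expect_equal(alignment_summary(b)$n_parsimony_informative, 0L)
  expect_equal(alignment_summary(b)$df, 6L)   # 3 (n - 1)

  set.seed(7)
  for (rep in 1:5) {
    r <- random_align(6, 20, ambig_frac = 0.05)
    s <- alignment_summary(r)
    # brute force
    acgt <- c("A", "C", "G", "T")
    nv <- 0L; ni <- 0L
    for (j in seq_len(ncol(r$matrix))) {
      col <- r$matrix[, j]; col <- col[col %in% acgt]
      tab <- table(col)
      if (length(tab) >= 2) {
        nv <- nv + 1L
        if (sum(tab >= 2) >= 2) ni <- ni + 1L
      }
    }
    expect_equal(s$n_variable_sites, nv)
    expect_equal(s$n_parsimony_informative, ni)
    expect_true(ni <= nv && nv <= ncol(r$matrix))
  }
  expect_error(alignment_summary(make_align("ACGT")), ">= 2")
})

test_that("specimen table reader validates ids and coordinates", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("specimen_id,species,lat,lon",
               "a,sp1,31.5,-98.4", "b,sp1,30.1,-101.7"), f)
  df <- read_specimen_table(f)
  expect_equal(nrow(df), 2L)
  bad <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("specimen_id,lat,lon", "a,99.0,-98.4"), bad)
  expect_error(read_specimen_table(bad), "latitude")
})
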