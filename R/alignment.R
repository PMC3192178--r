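IUPAC_AMBIG <- c("R", "Y", "S", "W", "K", "M", "B", "D", "H", "V")
VALID_STATES <- c("A", "C", "G", "T", "U", "N", "?", "-", IUPAC_AMBIG)

#' Aligned mtDNA character matrix
#'
#' Constructs the package's core alignment container: a specimens-by-columns
#' character matrix of nucleotide states (A/C/G/T, IUPAC ambiguity codes,
#' `-` gap, `N` missing) together with named locus partitions.
#'
#' States are uppercased and validated. `?` is canonicalized to `N`; runs of
#' `-` at either end of a row (truncated reads, not indels) are also turned
#' into `N`, while internal `-` is kept as gap.
#'
#' @param ids character vector of unique specimen identifiers.
#' @param matrix character matrix (rows = specimens) or a character vector of
#'   equal-length sequence strings.
#' @param partitions named list of integer column vectors tiling the columns
#'   without overlap; defaults to a single partition `locus1`.
#' @return An object of class `mt_alignment` with elements `ids`, `matrix`
#'   (dimnames set from `ids`), and `partitions`.
#' @export
mt_alignment <- function(ids, matrix, partitions = NULL) {
  if (is.character(matrix) && is.null(dim(matrix))) {
    lens <- nchar(matrix)
    if (length(unique(lens)) > 1L)
      stop("ragged rows: sequences have unequal lengths (",
           paste(unique(lens), collapse = ", "), ")")
    matrix <- do.call(rbind, strsplit(matrix, ""))
  }
  ids <- as.character(ids)
  if (anyDuplicated(ids)) stop("specimen ids must be unique")
  if (nrow(matrix) != length(ids)) stop("ids and matrix rows differ")
  matrix <- toupper(matrix)
  matrix[matrix == "U"] <- "T"
  bad <- setdiff(unique(as.vector(matrix)), VALID_STATES)
  if (length(bad) > 0L)
    stop("unknown character state(s): ", paste(sQuote(bad), collapse = ", "))
  matrix[matrix == "?"] <- "N"
  # leading/trailing gap runs are missing data, not indels
  for (r in seq_len(nrow(matrix))) {
    row <- matrix[r, ]
    nongap <- which(row != "-")
    if (length(nongap) == 0L) { matrix[r, ] <- "N"; next }
    if (nongap[1L] > 1L) matrix[r, seq_len(nongap[1L] - 1L)] <- "N"
    if (nongap[length(nongap)] < ncol(matrix))
      matrix[r, (nongap[length(nongap)] + 1L):ncol(matrix)] <- "N"
  }
  if (is.null(partitions)) partitions <- list(locus1 = seq_len(ncol(matrix)))
  partitions <- lapply(partitions, as.integer)
  cols <- sort(unlist(partitions, use.names = FALSE))
  if (!identical(cols, seq_len(ncol(matrix))))
    stop("partitions must tile the alignment columns exactly once")
  dimnames(matrix) <- list(ids, NULL)
  structure(list(ids = ids, matrix = matrix, partitions = partitions),
            class = "mt_alignment")
}

#' @export
print.mt_alignment <- function(x, ...) {
  cat("mt_alignment:", length(x$ids), "specimens x", ncol(x$matrix),
      "columns;", length(x$partitions), "partition(s):",
      paste(sprintf("%s[%d]", names(x$partitions),
                    lengths(x$partitions)), collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.mt_alignment <- function(x) dim(x$matrix)

#' Read an alignment from FASTA or NEXUS
#'
#' @param path file path.
#' @param format `"fasta"` or `"nexus"` (sequential and interleaved NEXUS
#'   both supported).
#' @return [mt_alignment()].
#' @export
read_alignment <- function(path, format = c("fasta", "nexus")) {
  format <- match.arg(tolower(format), c("fasta", "nexus"))
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "fasta") {
    recs <- suppressWarnings(ape::read.FASTA(path))
    if (length(recs) == 0L) stop("no records in ", path)
    chr <- lapply(as.character(recs), toupper)
    lens <- lengths(chr)
    if (length(unique(lens)) > 1L)
      stop("ragged rows: FASTA records have unequal lengths")
    mt_alignment(names(recs), do.call(rbind, chr))
  } else {
    recs <- ape::read.nexus.data(path)
    if (length(recs) == 0L) stop("no records in ", path)
    mt_alignment(names(recs), do.call(rbind, lapply(recs, toupper)))
  }
}

#' Write an alignment to FASTA or NEXUS
#'
#' @param align [mt_alignment()].
#' @param path output path.
#' @param format `"fasta"` or `"nexus"`.
#' @export
write_alignment <- function(align, path, format = c("fasta", "nexus")) {
  format <- match.arg(tolower(format), c("fasta", "nexus"))
  stopifnot(inherits(align, "mt_alignment"))
  if (format == "fasta") {
    lines <- character(0)
    for (i in seq_along(align$ids)) {
      lines <- c(lines, paste0(">", align$ids[i]),
                 paste(align$matrix[i, ], collapse = ""))
    }
    writeLines(lines, path)
  } else {
    seqs <- lapply(seq_along(align$ids), function(i) align$matrix[i, ])
    names(seqs) <- align$ids
    ape::write.nexus.data(seqs, path, interleaved = FALSE)
  }
  invisible(path)
}

#' Read a specimen metadata table
#'
#' CSV with required column `specimen_id`; recognised optional columns:
#' `species`, `group`, `locality`, `lat`, `lon`, `sex_stage`.
#'
#' @param path CSV path.
#' @return data.frame with validated coordinates.
#' @export
read_specimen_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!"specimen_id" %in% names(df))
    stop("specimen table must contain a 'specimen_id' column")
  df$specimen_id <- as.character(df$specimen_id)
  if (anyDuplicated(df$specimen_id)) stop("duplicate specimen_id values")
  if ("lat" %in% names(df)) {
    ok <- is.na(df$lat) | (df$lat >= -90 & df$lat <= 90)
    if (!all(ok)) stop("latitude out of [-90, 90]")
  }
  if ("lon" %in% names(df)) {
    ok <- is.na(df$lon) | (df$lon >= -180 & df$lon <= 180)
    if (!all(ok)) stop("longitude out of [-180, 180]")
  }
  df
}

#' Concatenate two locus alignments on shared specimen ids
#'
#' Specimens present in only one locus are retained with the other locus
#' filled with `N`; the per-locus column ranges are recorded as partitions.
#'
#' @param a,b [mt_alignment()] objects.
#' @return [mt_alignment()] with `ncol(a) + ncol(b)` columns.
#' @export
concatenate <- function(a, b) {
  stopifnot(inherits(a, "mt_alignment"), inherits(b, "mt_alignment"))
  if (ncol(b$matrix) == 0L) return(a)
  if (ncol(a$matrix) == 0L) return(b)
  shared <- intersect(a$ids, b$ids)
  if (length(shared) == 0L)
    stop("no shared specimen ids between the two alignments")
  ids <- union(a$ids, b$ids)
  na_ <- ncol(a$matrix); nb_ <- ncol(b$matrix)
  m <- matrix("N", nrow = length(ids), ncol = na_ + nb_,
              dimnames = list(ids, NULL))
  m[a$ids, seq_len(na_)] <- a$matrix
  m[b$ids, na_ + seq_len(nb_)] <- b$matrix
  parts <- c(
    stats::setNames(lapply(a$partitions, identity), names(a$partitions)),
    stats::setNames(lapply(b$partitions, function(p) p + na_),
                    names(b$partitions))
  )
  names(parts) <- make.unique(names(parts))
  mt_alignment(ids, m, parts)
}

is_resolved <- function(m) {
  m == "A" | m == "C" | m == "G" | m == "T"
}

#' Collapse specimens into unique haplotypes
#'
#' Two sequences belong to the same haplotype iff they agree at every column
#' where both carry an unambiguous, non-gap state. Sequences differing only
#' by missing/ambiguous states join the haplotype whose representative they
#' match with the fewest resolved differences (zero required), ties broken by
#' lowest specimen id. Representatives are assigned in order of decreasing
#' resolved-site count so truncated sequences join fuller ones.
#'
#' @param align [mt_alignment()].
#' @return `mt_haplotypes`: data.frame-like list with `haplotype_id`,
#'   `representative` (specimen id), `frequency`, `members` (list), and the
#'   representative sub-alignment in `$alignment`.
#' @export
collapse_haplotypes <- function(align) {
  stopifnot(inherits(align, "mt_alignment"))
  n <- length(align$ids)
  if (n == 0L) stop("empty alignment")
  res <- is_resolved(align$matrix)
  order_idx <- order(-rowSums(res), align$ids)
  rep_idx <- integer(0)        # representative row per haplotype
  members <- list()
  assign_of <- integer(n)
  for (i in order_idx) {
    hit <- 0L
    if (length(rep_idx) > 0L) {
      for (h in seq_along(rep_idx)) {
        r <- rep_idx[h]
        both <- res[i, ] & res[r, ]
        if (!any(align$matrix[i, both] != align$matrix[r, both])) {
          hit <- h
          break
        }
      }
    }
    if (hit == 0L) {
      rep_idx <- c(rep_idx, i)
      members[[length(rep_idx)]] <- i
      assign_of[i] <- length(rep_idx)
    } else {
      members[[hit]] <- c(members[[hit]], i)
      assign_of[i] <- hit
    }
  }
  k <- length(rep_idx)
  hap_ids <- sprintf("H%02d", seq_len(k))
  mem_ids <- lapply(members, function(ix) sort(align$ids[ix]))
  sub <- mt_alignment(align$ids[rep_idx],
                      align$matrix[rep_idx, , drop = FALSE],
                      align$partitions)
  structure(list(
    haplotype_id = hap_ids,
    representative = align$ids[rep_idx],
    frequency = lengths(mem_ids),
    members = mem_ids,
    assignment = stats::setNames(hap_ids[assign_of], align$ids),
    alignment = sub
  ), class = "mt_haplotypes")
}

#' @export
print.mt_haplotypes <- function(x, ...) {
  cat("mt_haplotypes:", length(x$haplotype_id), "haplotypes from",
      sum(x$frequency), "specimens; modal frequency", max(x$frequency), "\n")
  invisible(x)
}

#' Alignment summary statistics
#'
#' Variable sites (>= 2 unambiguous states observed), parsimony-informative
#' sites (>= 2 states each in >= 2 sequences), base frequencies over
#' unambiguous states, and a PAUP*-style chi-square test of base-frequency
#' homogeneity across sequences with df = 3(n - 1).
#'
#' @param align [mt_alignment()] with at least two sequences.
#' @return list with `n_variable_sites`, `n_parsimony_informative`,
#'   `base_frequencies`, `chisq`, `df`, `p_value`.
#' @export
alignment_summary <- function(align) {
  stopifnot(inherits(align, "mt_alignment"))
  m <- align$matrix
  if (nrow(m) < 2L) stop("alignment summary needs >= 2 sequences")
  res <- is_resolved(m)
  nvar <- 0L; ninf <- 0L
  for (j in seq_len(ncol(m))) {
    states <- m[res[, j], j]
    if (length(states) < 2L) next
    tab <- table(states)
    if (length(tab) >= 2L) {
      nvar <- nvar + 1L
      if (sum(tab >= 2L) >= 2L) ninf <- ninf + 1L
    }
  }
  counts <- t(apply(m, 1L, function(row) {
    c(A = sum(row == "A"), C = sum(row == "C"),
      G = sum(row == "G"), T = sum(row == "T"))
  }))
  tot <- colSums(counts)
  bf <- tot / sum(tot)
  # chi-square homogeneity across sequences (PAUP*-style, df = 3(n-1))
  rowtot <- rowSums(counts)
  expected <- outer(rowtot, bf)
  chisq <- sum((counts - expected)^2 / expected)
  df <- 3L * (nrow(m) - 1L)
  list(n_variable_sites = nvar,
       n_parsimony_informative = ninf,
       base_frequencies = bf,
       chisq = chisq, df = df,
       p_value = stats::pchisq(chisq, df, lower.tail = FALSE))
}

#' Neighbor-joining utility tree from an alignment
#'
#' Convenience wrapper used in tests and examples: NJ on uncorrected
#' p-distances (this package does not perform tree search; trees are inputs).
#'
#' @param align [mt_alignment()].
#' @param outgroup optional tip id to root on.
#' @return rooted `phylo`.
#' @export
nj_tree <- function(align, outgroup = NULL) {
  dm <- pdist_matrix(align)
  tr <- ape::nj(stats::as.dist(dm$matrix))
  if (!is.null(outgroup)) tr <- ape::root(tr, outgroup, resolve.root = TRUE)
  tr
}
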