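#' Uncorrected pairwise p-distance matrix
#'
#' For each pair of sequences the distance is the proportion of mismatches
#' over columns where both sequences carry an unambiguous non-gap state
#' (pairwise deletion). Pairs with zero comparable sites are returned as `NA`
#' and flagged.
#'
#' @param align [mt_alignment()] with >= 2 sequences.
#' @return list of class `mt_pdist`: `ids`, `matrix` (symmetric proportions,
#'   zero diagonal), `n_sites` (per-pair compared-site counts).
#' @export
pdist_matrix <- function(align) {
  stopifnot(inherits(align, "mt_alignment"))
  m <- align$matrix
  n <- nrow(m)
  if (n < 2L) stop("p-distances need >= 2 sequences")
  code <- matrix(match(m, c("A", "C", "G", "T")), nrow = n)
  d <- matrix(0, n, n, dimnames = list(align$ids, align$ids))
  cs <- matrix(0L, n, n, dimnames = list(align$ids, align$ids))
  for (i in seq_len(n - 1L)) {
    xi <- code[i, ]
    for (j in (i + 1L):n) {
      xj <- code[j, ]
      both <- !is.na(xi) & !is.na(xj)
      nc <- sum(both)
      cs[i, j] <- cs[j, i] <- nc
      if (nc == 0L) {
        d[i, j] <- d[j, i] <- NA_real_
        warning("no comparable sites between ", align$ids[i], " and ",
                align$ids[j])
      } else {
        dd <- sum(xi[both] != xj[both]) / nc
        d[i, j] <- d[j, i] <- dd
      }
    }
  }
  structure(list(ids = align$ids, matrix = d, n_sites = cs),
            class = "mt_pdist")
}

#' Group-wise p-distance summary
#'
#' Arithmetic means of pairwise distances within each group (over distinct
#' pairs) and between each group pair (over all cross pairs), as used for
#' barcode-gap assessment. Undefined (NA) pairs are dropped from means with a
#' warning. Within-group means of singleton groups are `NA` and flagged.
#'
#' @param dm [pdist_matrix()] result.
#' @param groups named character vector or data.frame (`specimen_id`,
#'   `species`/`group`) assigning every id in `dm` to exactly one group.
#' @param unique_sequences if `TRUE`, average over unique sequences instead
#'   of specimens: within each group, ids at distance zero from an earlier id
#'   are dropped before averaging, which makes the summary invariant to
#'   duplicated specimens. Default `FALSE` (specimen averaging).
#' @return list of class `mt_groupdist`: `groups`, `within` (named means, as
#'   proportions), `between` (symmetric matrix of means), `max_within`,
#'   `min_between`, `realized_gap`.
#' @export
group_distance_summary <- function(dm, groups, unique_sequences = FALSE) {
  stopifnot(inherits(dm, "mt_pdist"))
  if (is.data.frame(groups)) {
    gcol <- if ("species" %in% names(groups)) "species" else "group"
    groups <- stats::setNames(as.character(groups[[gcol]]),
                              groups$specimen_id)
  }
  missing_ids <- setdiff(dm$ids, names(groups))
  if (length(missing_ids) > 0L)
    stop("ids without group assignment: ",
         paste(utils::head(missing_ids, 5), collapse = ", "))
  g <- groups[dm$ids]
  keep <- rep(TRUE, length(dm$ids))
  if (unique_sequences) {
    for (i in seq_along(dm$ids)) {
      if (!keep[i]) next
      later <- which(seq_along(dm$ids) > i & g == g[i])
      dup <- later[!is.na(dm$matrix[i, later]) & dm$matrix[i, later] == 0]
      keep[dup] <- FALSE
    }
    dm <- structure(list(ids = dm$ids[keep],
                         matrix = dm$matrix[keep, keep, drop = FALSE],
                         n_sites = dm$n_sites[keep, keep, drop = FALSE]),
                    class = "mt_pdist")
    g <- g[keep]
  }
  labs <- sort(unique(g))
  k <- length(labs)
  within <- stats::setNames(rep(NA_real_, k), labs)
  between <- matrix(NA_real_, k, k, dimnames = list(labs, labs))
  for (a in seq_len(k)) {
    ia <- which(g == labs[a])
    if (length(ia) >= 2L) {
      sub <- dm$matrix[ia, ia][upper.tri(diag(length(ia)))]
      within[a] <- mean(sub, na.rm = TRUE)
    }
    for (b in seq_len(k)) {
      if (b <= a) next
      ib <- which(g == labs[b])
      cross <- dm$matrix[ia, ib, drop = FALSE]
      between[a, b] <- between[b, a] <- mean(cross, na.rm = TRUE)
    }
  }
  diag(between) <- 0
  mw <- suppressWarnings(max(within, na.rm = TRUE))
  if (!is.finite(mw)) mw <- NA_real_
  mb <- min(between[upper.tri(between)], na.rm = TRUE)
  structure(list(groups = labs, group_of = g, within = within,
                 between = between, max_within = mw, min_between = mb,
                 realized_gap = if (is.na(mw)) NA_real_ else mb - mw),
            class = "mt_groupdist")
}

#' @export
print.mt_groupdist <- function(x, ...) {
  cat("Between-group mean p-distances (%):\n")
  print(round(100 * x$between, 2))
  cat("Within-group means (%):",
      paste(sprintf("%s=%.2f", names(x$within), 100 * x$within),
            collapse = ", "), "\n")
  if (!is.na(x$realized_gap))
    cat(sprintf("Realized gap: %.2f%% (min between %.2f%% - max within %.2f%%)\n",
                100 * x$realized_gap, 100 * x$min_between, 100 * x$max_within))
  invisible(x)
}

#' Barcode-gap delimitation over group pairs
#'
#' A group pair passes when its mean between-group uncorrected p-distance
#' exceeds the gap threshold (default 6 percent, chosen in the source study
#' to exceed the greatest intraspecific distance). Failing pairs are listed
#' as merge candidates.
#'
#' @param summary [group_distance_summary()] result.
#' @param gap threshold as a proportion (default `0.06`).
#' @return list of class `mt_barcodegap`: `pairs` data.frame (`group_a`,
#'   `group_b`, `mean_between`, `pass`), `all_pass`, `merge_candidates`,
#'   `realized_gap`, `gap`.
#' @export
barcode_gap_delimit <- function(summary, gap = 0.06) {
  stopifnot(inherits(summary, "mt_groupdist"))
  labs <- summary$groups
  k <- length(labs)
  rows <- list()
  for (a in seq_len(k - 1L)) for (b in (a + 1L):k) {
    d <- summary$between[a, b]
    rows[[length(rows) + 1L]] <- data.frame(
      group_a = labs[a], group_b = labs[b], mean_between = d,
      pass = !is.na(d) && d > gap, stringsAsFactors = FALSE)
  }
  pairs <- do.call(rbind, rows)
  merge_candidates <- pairs[!pairs$pass, c("group_a", "group_b")]
  structure(list(pairs = pairs, all_pass = all(pairs$pass),
                 merge_candidates = merge_candidates,
                 realized_gap = summary$realized_gap, gap = gap),
            class = "mt_barcodegap")
}

#' @export
print.mt_barcodegap <- function(x, ...) {
  cat(sprintf("Barcode gap at %.1f%%: %d/%d group pairs pass\n",
              100 * x$gap, sum(x$pairs$pass), nrow(x$pairs)))
  if (nrow(x$merge_candidates) > 0L) {
    cat("Merge candidates:\n")
    print(x$merge_candidates)
  }
  invisible(x)
}

#' Export a distance matrix as TSV (optionally PHYLIP-style)
#'
#' @param dm [pdist_matrix()] result.
#' @param path output path.
#' @param phylip if `TRUE`, prepend the PHYLIP taxon-count header line.
#' @return invisible `path`.
#' @export
write_pdist <- function(dm, path, phylip = FALSE) {
  stopifnot(inherits(dm, "mt_pdist"))
  if (phylip) {
    con <- file(path, "w")
    writeLines(sprintf("%5d", length(dm$ids)), con)
    for (i in seq_along(dm$ids)) {
      writeLines(paste(c(formatC(dm$ids[i], width = -10),
                         sprintf("%.6f", dm$matrix[i, ])), collapse = " "),
                 con)
    }
    close(con)
  } else {
    utils::write.table(dm$matrix, path, sep = "\t", quote = FALSE,
                       col.names = NA)
  }
  invisible(path)
}
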