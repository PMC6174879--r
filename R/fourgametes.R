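#' Four-gamete compatibility of two sites
#'
#' Two biallelic sites are incompatible under the four-gamete test when all
#' four gametic combinations (00, 01, 10, 11) occur among the haplotypes:
#' under infinite-sites mutation this implies recombination between them.
#'
#' @param site_a,site_b 0/1 haplotype columns over the same haplotype rows.
#' @return \code{TRUE} if compatible (at most three gametes observed).
#' @export
four_gamete_compatible <- function(site_a, site_b) {
  stopifnot(length(site_a) == length(site_b))
  if (length(unique(site_a)) < 2 || length(unique(site_b)) < 2)
    stop("four_gamete_compatible requires polymorphic sites; pre-filter ",
         "monomorphic columns")
  if (max(site_a) > 1 || max(site_b) > 1)
    stop("four_gamete_compatible is defined for biallelic sites")
  length(unique(site_a * 2L + site_b)) < 4L
}

# Pairwise compatibility over the polymorphic columns of a haplotype block;
# monomorphic columns are vacuously compatible with everything.
incompatible_pairs <- function(haps) {
  S <- ncol(haps)
  if (S < 2) return(matrix(integer(0), 0, 2))
  poly <- vapply(seq_len(S), function(j) length(unique(haps[, j])) > 1, TRUE)
  out <- list()
  idx <- which(poly)
  if (length(idx) >= 2) {
    for (ai in seq_len(length(idx) - 1)) {
      for (bi in seq((ai + 1), length(idx))) {
        a <- idx[ai]; b <- idx[bi]
        if (!four_gamete_compatible(haps[, a], haps[, b]))
          out[[length(out) + 1L]] <- c(a, b)
      }
    }
  }
  if (length(out) == 0) matrix(integer(0), 0, 2) else do.call(rbind, out)
}

# Longest contiguous window of columns with no incompatible pair among the
# given rows; ties broken toward the smaller start. Returns c(start, end)
# (possibly a single column).
best_window <- function(haps, rows) {
  sub <- haps[rows, , drop = FALSE]
  S <- ncol(sub)
  bad <- incompatible_pairs(sub)
  if (nrow(bad) == 0) return(c(1L, S))
  best <- c(1L, 1L)
  for (i in seq_len(S)) {
    for (j in seq(i, S)) {
      ok <- !any(bad[, 1] >= i & bad[, 2] <= j)
      if (ok && (j - i + 1) > (best[2] - best[1] + 1)) best <- c(i, j)
    }
  }
  best
}

#' Resolve four-gamete incompatibilities within one locus
#'
#' In the style of recombination-filtering tools for isolation-with-
#' migration input: when a locus shows incompatible site pairs, either trim
#' to the largest contiguous compatible window of sites, remove up to
#' \code{k} individuals (both haplotypes), or both — choosing the action
#' that retains the most haplotype-sites (retained haplotype rows times
#' retained site columns). Individuals are removed only when this retains
#' strictly more haplotype-sites than trimming alone; removal ties are
#' broken by sample order and window ties by the smaller start position.
#' The output always passes a full compatibility re-scan.
#'
#' @param haps 0/1 haplotype matrix (2 rows per individual).
#' @param positions site positions (1-based within the locus).
#' @param k maximum number of individuals that may be removed (default 2).
#' @param samples optional sample names (one per individual); defaults to
#'   \code{ind1, ind2, ...}.
#' @param unit unit of removal: whole \code{"individual"}s (default, both
#'   haplotypes) or single \code{"haplotype"} rows.
#' @return A list with \code{haps}, \code{positions} (the retained block),
#'   \code{kept_rows}, \code{removed} (removed sample names or haplotype
#'   indices), \code{action} (\code{none}, \code{trimmed},
#'   \code{individuals_removed} or \code{both}), \code{window},
#'   \code{n_incompatible} and \code{retained_hap_sites}.
#' @export
filter_locus_fourgametes <- function(haps, positions, k = 2, samples = NULL,
                                     unit = c("individual", "haplotype")) {
  unit <- match.arg(unit)
  S <- ncol(haps)
  n_row <- nrow(haps)
  n_ind <- n_row / 2L
  if (is.null(samples)) samples <- paste0("ind", seq_len(n_ind))
  bad0 <- incompatible_pairs(haps)
  base <- list(haps = haps, positions = positions,
               kept_rows = seq_len(n_row), removed = character(0),
               action = "none", window = c(1L, max(1L, S)),
               n_incompatible = nrow(bad0),
               retained_hap_sites = n_row * S)
  if (S < 2 || nrow(bad0) == 0) return(base)

  units <- if (unit == "individual") seq_len(n_ind) else seq_len(n_row)
  rows_of_unit <- function(u) {
    if (unit == "individual") c(2L * u - 1L, 2L * u) else u
  }
  # candidate removal sets, smallest first (strict improvement required to
  # remove more)
  subsets <- list(integer(0))
  if (k >= 1) for (u in units) subsets[[length(subsets) + 1L]] <- u
  if (k >= 2 && length(units) >= 2) {
    cmb <- utils::combn(units, 2)
    for (cc in seq_len(ncol(cmb)))
      subsets[[length(subsets) + 1L]] <- cmb[, cc]
  }
  if (k > 2) {
    for (sz in 3:min(k, length(units) - 1)) {
      cmb <- utils::combn(units, sz)
      for (cc in seq_len(ncol(cmb)))
        subsets[[length(subsets) + 1L]] <- cmb[, cc]
    }
  }
  best <- NULL
  for (rm in subsets) {
    rows <- setdiff(seq_len(n_row), unlist(lapply(rm, rows_of_unit)))
    w <- best_window(haps, rows)
    retained <- length(rows) * (w[2] - w[1] + 1)
    if (is.null(best) || retained > best$retained) {
      best <- list(rm = rm, rows = rows, w = w, retained = retained)
    }
  }
  trimmed <- (best$w[2] - best$w[1] + 1) < S
  removed_any <- length(best$rm) > 0
  action <- if (trimmed && removed_any) "both"
            else if (removed_any) "individuals_removed"
            else "trimmed"
  cols <- seq(best$w[1], best$w[2])
  out_haps <- haps[best$rows, cols, drop = FALSE]
  # idempotence guard: the retained block must be fully compatible
  stopifnot(nrow(incompatible_pairs(out_haps)) == 0)
  removed <- if (unit == "individual") samples[best$rm]
             else as.character(best$rm)
  list(haps = out_haps, positions = positions[cols],
       kept_rows = best$rows, removed = removed, action = action,
       window = best$w, n_incompatible = nrow(bad0),
       retained_hap_sites = best$retained)
}

#' Four-gamete filtering across a locus_set
#'
#' Applies [filter_locus_fourgametes()] to every variable locus and returns
#' the filtered set together with a per-locus compatibility report.
#'
#' @param ls a [locus_set()].
#' @param k maximum individuals removable per locus.
#' @return A list with \code{locus_set} (filtered; loci keep their length
#'   and annotation) and \code{report} (one row per locus: action, number
#'   of incompatible pairs, retained window, removed samples).
#' @export
filter_fourgametes <- function(ls, k = 2) {
  reports <- vector("list", length(ls$loci))
  new_loci <- ls$loci
  for (i in seq_along(ls$loci)) {
    loc <- ls$loci[[i]]
    res <- filter_locus_fourgametes(loc$haps, loc$positions, k = k,
                                    samples = ls$popmap$sample)
    reports[[i]] <- data.frame(
      locus = loc$name, n_snps = ncol(loc$haps),
      n_incompatible = res$n_incompatible, action = res$action,
      window_start = res$window[1], window_end = res$window[2],
      removed = paste(res$removed, collapse = ","),
      retained_hap_sites = res$retained_hap_sites,
      stringsAsFactors = FALSE)
    if (res$action != "none") {
      loc$haps <- res$haps
      loc$positions <- res$positions
      loc$kept_rows <- res$kept_rows
      if (!is.null(loc$gq))
        loc$gq <- NULL  # sample set may have changed; qualities dropped
      new_loci[[i]] <- loc
    }
  }
  report <- do.call(rbind, reports)
  out <- ls
  out$loci <- new_loci
  list(locus_set = out, report = report)
}

#' Summarise a four-gamete compatibility report
#'
#' @param report the per-locus report from [filter_fourgametes()].
#' @return A list of counts: loci trimmed, loci with individuals removed,
#'   loci with both, total affected, and the proportion of loci affected.
#' @export
recombination_summary <- function(report) {
  trimmed <- sum(report$action %in% c("trimmed", "both"))
  removed <- sum(report$action %in% c("individuals_removed", "both"))
  both <- sum(report$action == "both")
  affected <- sum(report$action != "none")
  list(n_loci = nrow(report), n_trimmed = trimmed,
       n_individuals_removed = removed, n_both = both,
       n_affected = affected, proportion_affected = affected / nrow(report))
}
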