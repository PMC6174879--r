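#' Reduce a locus_set to one biallelic SNP per locus
#'
#' Preparation for joint-SFS demographic inference: excludes Z-flagged loci
#' (sex-linked loci have a different inheritance scalar), drops loci
#' containing a site with more than two alleles, and thins to one SNP per
#' locus. The order is Z-exclusion, then the biallelic filter, then
#' thinning; counts dropped at each step are recorded.
#'
#' @param ls a [locus_set()] with two populations and complete genotypes.
#' @param z_policy \code{"exclude"} (default) or \code{"keep"} Z-flagged
#'   loci.
#' @param thinning \code{"random"} (default; uses R's random stream) or
#'   \code{"first"} (lowest position, deterministic).
#' @return An object of class \code{snp_matrix}: a data frame with columns
#'   \code{locus}, \code{count1}, \code{count2} (alternate-allele haplotype
#'   counts per population, arbitrary orientation), with attributes
#'   \code{n1}, \code{n2} (haplotype sample sizes), \code{pops} and
#'   \code{dropped} (a named list of per-step drop counts).
#' @export
prepare_snp_matrix <- function(ls, z_policy = c("exclude", "keep"),
                               thinning = c("random", "first")) {
  z_policy <- match.arg(z_policy)
  thinning <- match.arg(thinning)
  pops <- population_names(ls)
  if (length(pops) != 2) stop("prepare_snp_matrix requires 2 populations")
  rows1 <- hap_rows_of_pop(ls, pops[1])
  rows2 <- hap_rows_of_pop(ls, pops[2])
  loci <- Filter(function(l) ncol(l$haps) > 0, ls$loci)
  n_start <- length(loci)
  if (z_policy == "exclude")
    loci <- Filter(function(l) l$chrom_class != "Z", loci)
  n_after_z <- length(loci)
  loci <- Filter(function(l) max(l$haps) <= 1, loci)
  n_after_biallelic <- length(loci)
  if (length(loci) == 0) stop("no loci left after filtering")
  out <- data.frame(locus = character(length(loci)),
                    count1 = integer(length(loci)),
                    count2 = integer(length(loci)),
                    stringsAsFactors = FALSE)
  for (i in seq_along(loci)) {
    loc <- loci[[i]]
    j <- if (thinning == "first") 1L
         else sample.int(ncol(loc$haps), 1L)
    out$locus[i] <- loc$name
    out$count1[i] <- sum(loc$haps[rows1, j])
    out$count2[i] <- sum(loc$haps[rows2, j])
  }
  structure(out, class = c("snp_matrix", "data.frame"),
            n1 = length(rows1), n2 = length(rows2), pops = pops,
            dropped = list(z_linked = n_start - n_after_z,
                           multiallelic = n_after_z - n_after_biallelic))
}

# Internal constructor.
new_joint_sfs <- function(mass, mask, folded, n1, n2) {
  structure(list(mass = mass, mask = mask, folded = folded,
                 n1 = n1, n2 = n2), class = "joint_sfs")
}

#' @export
print.joint_sfs <- function(x, ...) {
  cat("joint_sfs:", x$n1, "x", x$n2, "haplotypes,",
      if (x$folded) "folded," else "unfolded,",
      "unmasked mass =", sum(x$mass[!x$mask]), "\n")
  invisible(x)
}

# The standard mask: monomorphic corners, plus the redundant half-plane
# i + j > (n1+n2)/2 for folded spectra.
sfs_mask <- function(n1, n2, folded) {
  i <- matrix(0:n1, n1 + 1, n2 + 1)
  j <- matrix(0:n2, n1 + 1, n2 + 1, byrow = TRUE)
  mask <- matrix(FALSE, n1 + 1, n2 + 1)
  mask[1, 1] <- TRUE
  mask[n1 + 1, n2 + 1] <- TRUE
  if (folded) mask <- mask | (i + j > (n1 + n2) / 2)
  mask
}

# Fold an (n1+1) x (n2+1) grid of masses: mass at (i, j) maps to (i, j) when
# i + j < (n1+n2)/2, to the complement (n1-i, n2-j) when i + j > (n1+n2)/2,
# and half-and-half on the ambiguous diagonal (full mass when the cell is
# its own complement).
fold_grid <- function(mass, n1, n2) {
  out <- matrix(0, n1 + 1, n2 + 1)
  half <- (n1 + n2) / 2
  for (i in 0:n1) {
    for (j in 0:n2) {
      m <- mass[i + 1, j + 1]
      if (m == 0) next
      tot <- i + j
      if (tot < half) {
        out[i + 1, j + 1] <- out[i + 1, j + 1] + m
      } else if (tot > half) {
        out[n1 - i + 1, n2 - j + 1] <- out[n1 - i + 1, n2 - j + 1] + m
      } else if (i == n1 - i && j == n2 - j) {
        out[i + 1, j + 1] <- out[i + 1, j + 1] + m
      } else {
        out[i + 1, j + 1] <- out[i + 1, j + 1] + m / 2
        out[n1 - i + 1, n2 - j + 1] <- out[n1 - i + 1, n2 - j + 1] + m / 2
      }
    }
  }
  out
}

#' Build the folded joint site frequency spectrum
#'
#' Constructs the \code{(n1+1) x (n2+1)} folded joint SFS from per-locus
#' allele counts of arbitrary orientation, using the half-mass convention
#' for SNPs whose total count sits exactly at \eqn{(n_1+n_2)/2}. The two
#' monomorphic corners and the redundant half of the grid are masked;
#' unmasked mass sums to the number of SNPs.
#'
#' @param m a \code{snp_matrix} from [prepare_snp_matrix()].
#' @return A \code{joint_sfs} object.
#' @export
build_folded_joint_sfs <- function(m) {
  n1 <- attr(m, "n1"); n2 <- attr(m, "n2")
  if (any(m$count1 < 0 | m$count1 > n1 | m$count2 < 0 | m$count2 > n2))
    stop("allele counts outside [0, n]")
  tot <- m$count1 + m$count2
  if (any(tot == 0 | tot == n1 + n2))
    stop("snp_matrix contains sites monomorphic over the pooled sample")
  raw <- matrix(0, n1 + 1, n2 + 1)
  for (r in seq_len(nrow(m)))
    raw[m$count1[r] + 1, m$count2[r] + 1] <-
      raw[m$count1[r] + 1, m$count2[r] + 1] + 1
  new_joint_sfs(fold_grid(raw, n1, n2), sfs_mask(n1, n2, TRUE), TRUE, n1, n2)
}

#' Fold a joint SFS
#'
#' Applies the folding map to an existing spectrum (identity on spectra that
#' are already folded).
#'
#' @param sfs a \code{joint_sfs}.
#' @return A folded \code{joint_sfs}.
#' @export
fold_sfs <- function(sfs) {
  new_joint_sfs(fold_grid(sfs$mass, sfs$n1, sfs$n2),
                sfs_mask(sfs$n1, sfs$n2, TRUE), TRUE, sfs$n1, sfs$n2)
}

#' Block-jackknife replicates of the folded joint SFS
#'
#' Partitions loci into \code{n_reps} equal blocks at random and builds one
#' folded joint SFS per replicate, each leaving one block out (delete-m
#' jackknife over loci).
#'
#' Uses R's random stream; seed with [set.seed()].
#'
#' @param m a \code{snp_matrix}.
#' @param n_reps number of jackknife blocks (default 10).
#' @return A list with \code{replicates} (list of \code{joint_sfs}),
#'   \code{blocks} (block index per locus) and \code{block_m} (block
#'   sizes, the delete-m factors).
#' @export
jackknife_datasets <- function(m, n_reps = 10) {
  n_loci <- nrow(m)
  if (n_reps < 2) stop("n_reps must be >= 2")
  if (n_reps > n_loci) stop("more jackknife blocks than loci")
  blocks <- sample(rep(seq_len(n_reps), length.out = n_loci))
  reps <- lapply(seq_len(n_reps), function(r) {
    sub <- m[blocks != r, , drop = FALSE]
    attributes(sub)[c("n1", "n2", "pops")] <-
      attributes(m)[c("n1", "n2", "pops")]
    class(sub) <- class(m)
    build_folded_joint_sfs(sub)
  })
  list(replicates = reps, blocks = blocks,
       block_m = as.integer(table(blocks)))
}

#' Write / read the joint-SFS text dialect
#'
#' Three-line plain-text format: a header \code{"d1 d2 folded"} (grid
#' dimensions \code{n+1} per population and the folding state), a row-major
#' line of cell masses, and a row-major line of mask bits (1 = masked).
#' The round trip is bit-exact.
#'
#' @param sfs a \code{joint_sfs}.
#' @param path file path.
#' @return \code{write_sfs} returns \code{path} invisibly; \code{read_sfs}
#'   returns a \code{joint_sfs}.
#' @export
write_sfs <- function(sfs, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(paste(sfs$n1 + 1, sfs$n2 + 1,
                   if (sfs$folded) "folded" else "unfolded"),
             con, sep = "\n")
  # row-major: rows indexed by population-1 count
  writeLines(paste(sprintf("%.17g", as.vector(t(sfs$mass))), collapse = " "),
             con, sep = "\n")
  writeLines(paste(as.integer(as.vector(t(sfs$mask))), collapse = " "),
             con, sep = "\n")
  invisible(path)
}

#' @rdname write_sfs
#' @export
read_sfs <- function(path) {
  lines <- readLines(path)
  hdr <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  d1 <- as.integer(hdr[1]); d2 <- as.integer(hdr[2])
  folded <- identical(hdr[3], "folded")
  mass <- as.numeric(strsplit(trimws(lines[2]), "\\s+")[[1]])
  mask <- as.integer(strsplit(trimws(lines[3]), "\\s+")[[1]])
  stopifnot(length(mass) == d1 * d2, length(mask) == d1 * d2)
  new_joint_sfs(matrix(mass, d1, d2, byrow = TRUE),
                matrix(as.logical(mask), d1, d2, byrow = TRUE),
                folded, d1 - 1L, d2 - 1L)
}
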