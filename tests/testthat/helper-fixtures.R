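# Fixture builders and independent oracles shared across test files.

# A locus from a haplotype matrix (rows = haplotypes, 2 per individual).
make_locus <- function(haps, name = "locA", length_bp = 1000,
                       positions = seq_len(ncol(haps)),
                       chrom_class = "autosome") {
  list(name = name, length_bp = length_bp, chrom_class = chrom_class,
       positions = positions, haps = haps)
}

# A two-population locus_set; n1/n2 are diploid counts inferred from rows.
make_ls <- function(loci, n1, n2, invariant = NULL) {
  popmap <- data.frame(
    sample = c(paste0("a", seq_len(n1)), paste0("b", seq_len(n2))),
    population = rep(c("pop1", "pop2"), c(n1, n2)),
    stringsAsFactors = FALSE)
  locus_set(loci, popmap, invariant = invariant)
}

# Random biallelic locus over n_ind diploids (rows = 2*n_ind haplotypes).
random_locus <- function(n_ind, n_snps, name = "locR", p = 0.4) {
  repeat {
    haps <- matrix(rbinom(2 * n_ind * n_snps, 1, p), 2 * n_ind, n_snps)
    poly <- apply(haps, 2, function(x) length(unique(x)) > 1)
    if (all(poly)) return(make_locus(haps, name = name))
  }
}

# Independent exact HWE oracle: enumerate every genotype configuration
# (nAA, nAa, naa) with the observed allele counts, compute its conditional
# probability directly from binomial coefficients, and sum probabilities
# not exceeding the observed configuration's.
hwe_oracle <- function(n_AA, n_Aa, n_aa) {
  n <- n_AA + n_Aa + n_aa
  nA <- 2 * n_AA + n_Aa
  if (nA == 0 || nA == 2 * n) return(1)
  hets <- seq.int(0, n)
  probs <- vapply(hets, function(h) {
    aa2 <- nA - h
    if (aa2 < 0 || aa2 %% 2 != 0) return(0)
    AA <- aa2 / 2
    aa <- n - AA - h
    if (aa < 0) return(0)
    # P = n! 2^h / (AA! h! aa!)  /  C(2n, nA)
    exp(lgamma(n + 1) - lgamma(AA + 1) - lgamma(h + 1) - lgamma(aa + 1) +
          h * log(2) - (lgamma(2 * n + 1) - lgamma(nA + 1) -
                          lgamma(2 * n - nA + 1)))
  }, 0)
  p_obs <- probs[hets == n_Aa]
  sum(probs[probs <= p_obs + 1e-14])
}

# Independent transcription of the Weir & Cockerham (1984) estimator for
# one biallelic site, two populations of diploids, written from the
# variance-component definitions (not shared with the package internals).
wc_oracle_site <- function(geno1, geno2) {
  # geno1/geno2: vectors of dosages (0/1/2) per individual
  counts <- list(geno1, geno2)
  r <- 2
  ni <- vapply(counts, length, 0)
  pi_ <- vapply(counts, function(g) sum(g) / (2 * length(g)), 0)
  hi <- vapply(counts, function(g) mean(g == 1), 0)
  nbar <- mean(ni)
  C2 <- sum((ni - nbar)^2) / ((r) * nbar^2)  # not used; kept for clarity
  nc <- (sum(ni) - sum(ni^2) / sum(ni)) / (r - 1)
  pbar <- sum(ni * pi_) / sum(ni)
  ssq <- sum(ni * (pi_ - pbar)^2) / ((r - 1) * nbar)
  hbar <- sum(ni * hi) / sum(ni)
  a <- (nbar / nc) * (ssq - (1 / (nbar - 1)) *
                        (pbar * (1 - pbar) - ssq * (r - 1) / r - hbar / 4))
  b <- (nbar / (nbar - 1)) * (pbar * (1 - pbar) - ssq * (r - 1) / r -
                                hbar * (2 * nbar - 1) / (4 * nbar))
  cc <- hbar / 2
  c(a = a, b = b, c = cc)
}

# Brute-force four-gamete scan: explicit gamete-set construction.
brute_incompatible <- function(haps) {
  S <- ncol(haps)
  pairs <- list()
  if (S >= 2) {
    for (i in seq_len(S - 1)) for (j in seq((i + 1), S)) {
      a <- haps[, i]; b <- haps[, j]
      if (length(unique(a)) < 2 || length(unique(b)) < 2) next
      gam <- unique(paste0(a, b))
      if (all(c("00", "01", "10", "11") %in% gam))
        pairs[[length(pairs) + 1L]] <- c(i, j)
    }
  }
  pairs
}

# Exhaustive oracle for the four-gamete resolution objective: search every
# (individual subset of size <= k) x (contiguous window) combination and
# return the maximum retained haplotype-sites.
exhaustive_best_retained <- function(haps, k = 2) {
  n_row <- nrow(haps)
  n_ind <- n_row / 2
  S <- ncol(haps)
  best <- 0
  subsets <- list(integer(0))
  for (sz in seq_len(min(k, n_ind))) {
    cmb <- utils::combn(n_ind, sz)
    for (cc in seq_len(ncol(cmb))) subsets[[length(subsets) + 1]] <- cmb[, cc]
  }
  for (rm in subsets) {
    rows <- setdiff(seq_len(n_row), c(2 * rm - 1, 2 * rm))
    for (i in seq_len(S)) for (j in seq(i, S)) {
      sub <- haps[rows, i:j, drop = FALSE]
      if (length(brute_incompatible(sub)) == 0)
        best <- max(best, length(rows) * (j - i + 1))
    }
  }
  best
}

# Small default calibration matching two dated outgroup comparisons.
test_calibration <- function() {
  rate_calibration(
    data.frame(sites = c(1e6, 1e6),
               substitutions = c(1e6 * 6.83e-10 * 2 * 60.5e6,
                                 1e6 * 6.67e-10 * 2 * 53e6),
               tmrca_years = c(60.5e6, 53e6)),
    gen_time = 2.7)
}
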