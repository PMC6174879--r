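#' Nucleotide diversity (pi)
#'
#' Per-site nucleotide diversity: the sum over SNPs of the unbiased per-site
#' heterozygosity \eqn{(1 - \sum_a p_a^2) \, n/(n-1)} (which for a biallelic
#' site equals \eqn{2pq\,n/(n-1)}, the mean pairwise difference), divided by
#' the total surveyed length in bp. Invariant loci contribute length (the
#' denominator) but no variation, matching diversity computed from full
#' concatenated sequences.
#'
#' @param ls a [locus_set()].
#' @param scope \code{"all"} for the pooled sample, or a population name.
#' @param include_invariant include annotated invariant loci in the surveyed
#'   length (default TRUE).
#' @return A list with \code{pi}, \code{n_haplotypes}, \code{total_bp}.
#' @export
nucleotide_diversity <- function(ls, scope = "all", include_invariant = TRUE) {
  stopifnot(inherits(ls, "locus_set"), length(ls$loci) > 0)
  rows <- if (identical(scope, "all")) seq_len(2L * nrow(ls$popmap))
          else hap_rows_of_pop(ls, scope)
  if (length(rows) == 0) stop("no haplotypes in scope ", scope)
  total_bp <- total_surveyed_bp(ls, include_invariant)
  if (total_bp <= 0) stop("total surveyed length is zero")
  n <- length(rows)
  het_sum <- 0
  for (loc in ls$loci) {
    if (ncol(loc$haps) == 0) next
    sub <- loc$haps[rows, , drop = FALSE]
    for (j in seq_len(ncol(sub))) {
      p <- tabulate(sub[, j] + 1L) / n
      het_sum <- het_sum + (1 - sum(p^2)) * n / (n - 1)
    }
  }
  list(pi = het_sum / total_bp, n_haplotypes = n, total_bp = total_bp)
}

#' Between-population divergence (dxy and dA)
#'
#' \code{dxy} is the mean per-site difference over all between-population
#' haplotype pairs; \code{dA = dxy - (pi1 + pi2)/2} is the net divergence.
#' Computed as average pairwise differences per site (at shallow divergence
#' this is numerically indistinguishable from composite-likelihood
#' distances).
#'
#' @inheritParams nucleotide_diversity
#' @return A list with \code{dxy}, \code{dA}, \code{pi_by_pop},
#'   \code{pi_overall}, \code{total_bp}.
#' @export
divergence_stats <- function(ls, include_invariant = TRUE) {
  pops <- population_names(ls)
  if (length(pops) != 2) stop("divergence_stats requires exactly 2 populations")
  rows1 <- hap_rows_of_pop(ls, pops[1])
  rows2 <- hap_rows_of_pop(ls, pops[2])
  if (length(rows1) == 0 || length(rows2) == 0)
    stop("a population has zero samples")
  total_bp <- total_surveyed_bp(ls, include_invariant)
  dxy_sum <- 0
  for (loc in ls$loci) {
    if (ncol(loc$haps) == 0) next
    for (j in seq_len(ncol(loc$haps))) {
      a1 <- loc$haps[rows1, j]
      a2 <- loc$haps[rows2, j]
      # fraction of between-population pairs differing at this site
      tab1 <- tabulate(a1 + 1L, nbins = max(a1, a2) + 1L)
      tab2 <- tabulate(a2 + 1L, nbins = max(a1, a2) + 1L)
      same <- sum(tab1 * tab2)
      dxy_sum <- dxy_sum + 1 - same / (length(a1) * length(a2))
    }
  }
  pi1 <- nucleotide_diversity(ls, pops[1], include_invariant)$pi
  pi2 <- nucleotide_diversity(ls, pops[2], include_invariant)$pi
  dxy <- dxy_sum / total_bp
  list(dxy = dxy, dA = dxy - (pi1 + pi2) / 2,
       pi_by_pop = setNames(c(pi1, pi2), pops),
       pi_overall = nucleotide_diversity(ls, "all", include_invariant)$pi,
       total_bp = total_bp)
}

# Weir & Cockerham (1984) variance components (a, b, c) for one biallelic
# site over two populations, from diploid genotype data.
#   n_i: diploids per pop; p_i: allele frequency; h_i: observed het fraction
wc_components <- function(n, p, h) {
  r <- length(n)
  nbar <- mean(n)
  nc <- (r * nbar - sum(n^2) / (r * nbar)) / (r - 1)
  pbar <- sum(n * p) / (r * nbar)
  s2 <- sum(n * (p - pbar)^2) / ((r - 1) * nbar)
  hbar <- sum(n * h) / (r * nbar)
  a <- nbar / nc *
    (s2 - 1 / (nbar - 1) *
       (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4))
  b <- nbar / (nbar - 1) *
    (pbar * (1 - pbar) - (r - 1) / r * s2 - (2 * nbar - 1) / (4 * nbar) * hbar)
  c <- hbar / 2
  c(a = a, b = b, c = c)
}

#' Weir-Cockerham FST
#'
#' The Weir & Cockerham (1984) variance-components estimator of
#' differentiation for two populations of diploids, at SNP, locus, or
#' overall level. Locus and overall estimates are ratios of summed
#' components \eqn{\sum a / \sum (a + b + c)}. Monomorphic and
#' multi-allelic sites are excluded.
#'
#' @param ls a [locus_set()] with exactly two populations.
#' @param level \code{"snp"}, \code{"locus"} or \code{"overall"}.
#' @return For \code{"overall"}, a list with \code{fst} and the summed
#'   components; otherwise a data frame of per-item estimates plus the
#'   overall ratio-of-sums value as attribute \code{overall}.
#' @export
weir_cockerham_fst <- function(ls, level = c("overall", "snp", "locus")) {
  level <- match.arg(level)
  pops <- population_names(ls)
  if (length(pops) != 2) stop("weir_cockerham_fst requires 2 populations")
  dose <- dosage_matrix(ls)
  locus_of <- attr(dose, "locus")
  max_allele <- site_max_alleles(ls)
  pop_of <- ls$popmap$population
  n <- c(sum(pop_of == pops[1]), sum(pop_of == pops[2]))
  keep <- logical(ncol(dose))
  comp <- matrix(NA_real_, ncol(dose), 3,
                 dimnames = list(NULL, c("a", "b", "c")))
  for (j in seq_len(ncol(dose))) {
    if (max_allele[j] > 1) next  # multi-allelic sites excluded
    d <- dose[, j]
    p <- c(sum(d[pop_of == pops[1]]) / (2 * n[1]),
           sum(d[pop_of == pops[2]]) / (2 * n[2]))
    if (all(p == 0) || all(p == 1)) next  # monomorphic
    h <- c(mean(d[pop_of == pops[1]] == 1), mean(d[pop_of == pops[2]] == 1))
    comp[j, ] <- wc_components(n, p, h)
    keep[j] <- TRUE
  }
  if (!any(keep)) stop("all sites monomorphic; FST undefined")
  overall <- sum(comp[keep, "a"]) / sum(comp[keep, ])
  if (level == "overall")
    return(list(fst = overall, a = sum(comp[keep, "a"]),
                abc = sum(comp[keep, ]), n_sites = sum(keep)))
  if (level == "snp") {
    pos <- unlist(lapply(ls$loci, `[[`, "positions"), use.names = FALSE)
    out <- data.frame(locus = locus_of[keep], pos = pos[keep],
                      fst = comp[keep, "a"] / rowSums(comp[keep, , drop = FALSE]),
                      stringsAsFactors = FALSE)
  } else {
    sums <- rowsum(comp[keep, , drop = FALSE], locus_of[keep])
    out <- data.frame(locus = rownames(sums),
                      fst = sums[, "a"] / rowSums(sums),
                      stringsAsFactors = FALSE)
    rownames(out) <- NULL
  }
  attr(out, "overall") <- overall
  out
}

# Highest allele code per SNP column, in dosage_matrix column order.
site_max_alleles <- function(ls) {
  unlist(lapply(ls$loci, function(l) {
    if (ncol(l$haps) == 0) return(numeric(0))
    apply(l$haps, 2, max)
  }), use.names = FALSE)
}

# Pooled G statistic over per-SNP population x allele contingency tables.
g_statistic <- function(alt_counts, tot_counts) {
  # alt_counts, tot_counts: 2 x S matrices of alternate-allele and total
  # allele counts per population
  ref_counts <- tot_counts - alt_counts
  g <- 0
  for (j in seq_len(ncol(alt_counts))) {
    O <- rbind(c(alt_counts[1, j], ref_counts[1, j]),
               c(alt_counts[2, j], ref_counts[2, j]))
    E <- outer(rowSums(O), colSums(O)) / sum(O)
    nz <- O > 0
    g <- g + 2 * sum(O[nz] * log(O[nz] / E[nz]))
  }
  g
}

#' Permutation G-test of population differentiation
#'
#' Computes the log-likelihood-ratio (G) statistic pooled over per-SNP
#' allele-count contingency tables and compares it with its distribution
#' under random permutation of individuals across the two populations.
#' \eqn{p = (1 + \#\{G_{perm} \ge G_{obs}\}) / (n_{perm} + 1)}.
#'
#' Uses R's random stream; seed with [set.seed()].
#'
#' @param ls a [locus_set()] with two populations.
#' @param n_perm number of permutations (>= 100).
#' @return A list with \code{p_value}, \code{g_observed}, \code{n_perm}.
#' @export
permutation_differentiation_test <- function(ls, n_perm = 10000) {
  stopifnot(n_perm >= 100)
  pops <- population_names(ls)
  if (length(pops) != 2) stop("requires 2 populations")
  pop_of <- ls$popmap$population
  if (min(table(pop_of)) < 2) stop("need >= 2 individuals per population")
  dose <- dosage_matrix(ls)
  # biallelic sites only (dosage fully describes the genotype)
  dose <- dose[, site_max_alleles(ls) <= 1, drop = FALSE]
  if (ncol(dose) == 0) stop("no biallelic SNPs available")
  n_ind <- nrow(dose)
  stat <- function(labels) {
    alt <- rbind(colSums(dose[labels == pops[1], , drop = FALSE]),
                 colSums(dose[labels == pops[2], , drop = FALSE]))
    tot <- matrix(2 * c(sum(labels == pops[1]), sum(labels == pops[2])),
                  2, ncol(dose))
    g_statistic(alt, tot)
  }
  g_obs <- stat(pop_of)
  n_ge <- 0L
  for (r in seq_len(n_perm)) {
    if (stat(sample(pop_of)) >= g_obs - 1e-12) n_ge <- n_ge + 1L
  }
  list(p_value = (1 + n_ge) / (n_perm + 1), g_observed = g_obs,
       n_perm = n_perm)
}

#' Exact Hardy-Weinberg test for one biallelic SNP
#'
#' Exact conditional test: enumerates every heterozygote count compatible
#' with the observed allele counts, and sums the conditional probabilities
#' of all configurations no more probable than the observed one.
#' Monomorphic input returns \eqn{p = 1} by convention.
#'
#' @param n_AA,n_Aa,n_aa diploid genotype counts.
#' @return The exact p-value.
#' @export
hwe_exact_test <- function(n_AA, n_Aa, n_aa) {
  stopifnot(n_AA >= 0, n_Aa >= 0, n_aa >= 0)
  n <- n_AA + n_Aa + n_aa
  nA <- 2 * n_AA + n_Aa
  na <- 2 * n_aa + n_Aa
  if (nA == 0 || na == 0) return(1)  # monomorphic
  n_minor <- min(nA, na)
  hets <- seq(n_minor %% 2, n_minor, by = 2)
  # P(h | n, nA) up to a common constant: multinomial x 2^h
  logp <- vapply(hets, function(h) {
    aa <- (n_minor - h) / 2       # minor homozygotes
    AA <- n - aa - h
    h * log(2) - lgamma(AA + 1) - lgamma(h + 1) - lgamma(aa + 1)
  }, 0)
  prob <- exp(logp - max(logp))
  prob <- prob / sum(prob)
  p_obs <- prob[match(n_Aa, hets)]
  if (is.na(p_obs)) stop("heterozygote count incompatible with allele counts")
  min(1, sum(prob[prob <= p_obs * (1 + 1e-9)]))
}

#' Hardy-Weinberg tests across a locus_set
#'
#' Applies [hwe_exact_test()] to every biallelic SNP (populations pooled by
#' default) and flags loci with any SNP below the significance threshold.
#'
#' @param ls a [locus_set()].
#' @param per_population test within each population instead of pooling.
#' @param threshold per-SNP significance threshold for the out-of-HWE locus
#'   count (default 0.05, uncorrected).
#' @return A list with \code{snp_table} (locus, pos, p per SNP — per
#'   population if requested), \code{loci_out_of_hwe},
#'   \code{n_loci_in_hwe}, \code{n_loci_out}.
#' @export
hwe_test <- function(ls, per_population = FALSE, threshold = 0.05) {
  pops <- if (per_population) population_names(ls) else "pooled"
  rows_tab <- list()
  for (loc in ls$loci) {
    if (ncol(loc$haps) == 0) next
    for (j in seq_len(ncol(loc$haps))) {
      if (max(loc$haps[, j]) > 1) next  # biallelic only
      for (pp in pops) {
        idx <- if (identical(pp, "pooled")) seq_len(nrow(ls$popmap))
               else which(ls$popmap$population == pp)
        g <- loc$haps[2 * idx - 1, j] + loc$haps[2 * idx, j]
        p <- hwe_exact_test(sum(g == 0), sum(g == 1), sum(g == 2))
        rows_tab[[length(rows_tab) + 1L]] <-
          data.frame(locus = loc$name, pos = loc$positions[j],
                     population = pp, p = p, stringsAsFactors = FALSE)
      }
    }
  }
  tab <- do.call(rbind, rows_tab)
  out_loci <- unique(tab$locus[tab$p < threshold])
  tested <- unique(tab$locus)
  list(snp_table = tab, loci_out_of_hwe = out_loci,
       n_loci_in_hwe = length(tested) - length(out_loci),
       n_loci_out = length(out_loci))
}

#' Heterozygosity summary
#'
#' Observed (Ho) and unbiased expected (He) heterozygosity per SNP and per
#' population, per-locus means for the pooled sample, Bartlett's test of
#' homogeneity of variance between the per-locus Ho and He distributions,
#' a paired t-test of Ho against He across loci (both one- and two-tailed
#' p-values reported), and private ("unique") allele counts per population.
#'
#' @param ls a [locus_set()] with two populations.
#' @return A list; see Details in the package vignette.
#' @export
heterozygosity_summary <- function(ls) {
  stopifnot(length(ls$loci) >= 2)
  pops <- population_names(ls)
  pop_of <- ls$popmap$population
  ho_pop <- setNames(numeric(length(pops)), pops)
  he_pop <- setNames(numeric(length(pops)), pops)
  n_snp_pop <- setNames(numeric(length(pops)), pops)
  uniq <- setNames(numeric(length(pops)), pops)
  ho_locus <- he_locus <- numeric(0)
  n_all <- nrow(ls$popmap)
  for (loc in ls$loci) {
    if (ncol(loc$haps) == 0) next
    ho_l <- he_l <- numeric(0)
    for (j in seq_len(ncol(loc$haps))) {
      al <- loc$haps[, j]
      # pooled per-locus values
      g1 <- al[seq(1, length(al), 2)]
      g2 <- al[seq(2, length(al), 2)]
      ho_l <- c(ho_l, mean(g1 != g2))
      p <- tabulate(al + 1L) / length(al)
      he_l <- c(he_l, (1 - sum(p^2)) * (2 * n_all) / (2 * n_all - 1))
      # per-population values
      for (pp in pops) {
        idx <- which(pop_of == pp)
        a_pop <- al[sort(c(2 * idx - 1, 2 * idx))]
        gp1 <- al[2 * idx - 1]; gp2 <- al[2 * idx]
        ho_pop[pp] <- ho_pop[pp] + mean(gp1 != gp2)
        pv <- tabulate(a_pop + 1L) / length(a_pop)
        he_pop[pp] <- he_pop[pp] +
          (1 - sum(pv^2)) * length(a_pop) / (length(a_pop) - 1)
        n_snp_pop[pp] <- n_snp_pop[pp] + 1
      }
      # private alleles: present in one population, absent from the other
      alleles <- sort(unique(al))
      for (a in alleles) {
        in_pop <- vapply(pops, function(pp) {
          idx <- which(pop_of == pp)
          any(al[sort(c(2 * idx - 1, 2 * idx))] == a)
        }, TRUE)
        if (sum(in_pop) == 1) uniq[pops[in_pop]] <- uniq[pops[in_pop]] + 1
      }
    }
    ho_locus <- c(ho_locus, mean(ho_l))
    he_locus <- c(he_locus, mean(he_l))
  }
  bart <- bartlett.test(list(Ho = ho_locus, He = he_locus))
  tt <- tryCatch(t.test(ho_locus, he_locus, paired = TRUE),
                 error = function(e)  # constant differences: no variance
                   list(statistic = NA_real_, parameter = NA_real_,
                        p.value = NA_real_))
  t_stat <- unname(tt$statistic)
  df <- unname(tt$parameter)
  list(ho = ho_pop / n_snp_pop, he = he_pop / n_snp_pop,
       ho_by_locus = ho_locus, he_by_locus = he_locus,
       bartlett = list(statistic = unname(bart$statistic),
                       p = bart$p.value),
       paired_t = list(statistic = t_stat, df = df,
                       p_two_tailed = tt$p.value,
                       p_greater = pt_upper(t_stat, df),
                       p_less = 1 - pt_upper(t_stat, df)),
       unique_alleles = uniq)
}

pt_upper <- function(t, df) stats::pt(t, df, lower.tail = FALSE)

#' Population assignment by PCA + linear discriminant analysis
#'
#' DAPC-style assignment: centers the individual allele-dosage matrix,
#' projects onto the top principal components, fits a linear discriminant
#' between the two labelled populations, and reports per-individual
#' posterior membership probabilities and diagnosability (the fraction of
#' individuals whose highest-probability population matches their label).
#'
#' With few individuals and several retained components, posterior
#' probabilities evaluated on the training individuals are optimistic (the
#' discriminant can separate almost any labelling); \code{cv = "loo"}
#' instead predicts each individual from a PCA + LDA fit that excludes it,
#' which is calibrated under panmixia (about 50\% diagnosability) at the
#' cost of not reproducing the training-data posteriors that this style of
#' analysis conventionally reports.
#'
#' @param ls a [locus_set()] with two populations.
#' @param n_pcs number of principal components retained (default 4); must
#'   be smaller than the number of individuals.
#' @param cv \code{"none"} (default; posteriors on the training data, the
#'   conventional report) or \code{"loo"} (leave-one-out).
#' @return A list with \code{posterior} (individuals x populations),
#'   \code{assigned}, \code{diagnosability}, \code{n_pcs}.
#' @export
assign_individuals <- function(ls, n_pcs = 4, cv = c("none", "loo")) {
  cv <- match.arg(cv)
  dose <- dosage_matrix(ls)
  if (ncol(dose) < 1) stop("no SNPs available for assignment")
  n_ind <- nrow(dose)
  if (n_pcs >= n_ind)
    stop("n_pcs must be smaller than the number of individuals")
  grp <- factor(ls$popmap$population)
  project_fit <- function(train_idx, test_idx) {
    pc <- prcomp(dose[train_idx, , drop = FALSE], center = TRUE,
                 scale. = FALSE)
    k <- min(n_pcs, ncol(pc$x), length(train_idx) - 2L)
    tr <- pc$x[, seq_len(k), drop = FALSE]
    te <- stats::predict(pc, dose[test_idx, , drop = FALSE])[, seq_len(k),
                                                            drop = FALSE]
    fit <- MASS::lda(tr, grouping = grp[train_idx])
    stats::predict(fit, te)$posterior
  }
  all_idx <- seq_len(n_ind)
  if (cv == "none") {
    post <- project_fit(all_idx, all_idx)
  } else {
    post <- NULL
    for (i in all_idx) {
      p_i <- project_fit(setdiff(all_idx, i), i)
      if (is.null(post))
        post <- matrix(NA_real_, n_ind, ncol(p_i),
                       dimnames = list(NULL, colnames(p_i)))
      post[i, colnames(p_i)] <- p_i
    }
  }
  rownames(post) <- ls$popmap$sample
  assigned <- colnames(post)[max.col(post)]
  list(posterior = post,
       assigned = setNames(assigned, ls$popmap$sample),
       diagnosability = mean(assigned == as.character(grp)),
       n_pcs = min(n_pcs, n_ind - 1L))
}
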