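test_that("nucleotide diversity matches hand-computed pairwise
           differences", {
  # two identical haplotypes: pi = 0 (monomorphic columns never arise;
  # build a locus with zero SNPs)
  ls0 <- make_ls(list(make_locus(matrix(0L, 8, 0), length_bp = 500)), 2, 2)
  expect_equal(nucleotide_diversity(ls0)$pi, 0)
  # 4 haplotypes, one SNP at frequency 2/4, 1000 bp:
  # 4 differing pairs of 6 => (4/6)/1000
  haps <- matrix(c(0L, 0L, 1L, 1L), 4, 1)
  ls1 <- make_ls(list(make_locus(haps)), 1, 1)
  expect_equal(nucleotide_diversity(ls1)$pi, (4 / 6) / 1000)
  # invariant loci extend the denominator
  inv <- data.frame(name = "inv1", length_bp = 1000,
                    chrom_class = "autosome")
  ls2 <- make_ls(list(make_locus(haps)), 1, 1, invariant = inv)
  expect_equal(nucleotide_diversity(ls2)$pi, (4 / 6) / 2000)
  expect_equal(nucleotide_diversity(ls2, include_invariant = FALSE)$pi,
               (4 / 6) / 1000)
})

test_that("dxy and dA behave as between-population distances", {
  # populations that are copies of each other: dxy = pi (up to the
  # unbiasedness factor) and dA ~ 0
  set.seed(5)
  loc <- random_locus(4, 3)
  loc$haps <- rbind(loc$haps, loc$haps)  # pop2 = copy of pop1 (4 diploids)
  ls <- make_ls(list(loc), 4, 4)
  d <- divergence_stats(ls)
  expect_equal(d$dA, d$dxy - mean(d$pi_by_pop))  # arithmetic identity
  # dA is near zero up to the small-sample unbiasedness factor n/(n-1)
  expect_lt(abs(d$dA), d$dxy / 5)
  # fixed difference at one site, 100 bp: dxy = dA = 0.01
  haps <- matrix(c(0L, 0L, 0L, 0L, 1L, 1L, 1L, 1L), 8, 1)
  ls2 <- make_ls(list(make_locus(haps, length_bp = 100)), 2, 2)
  d2 <- divergence_stats(ls2)
  expect_equal(d2$dxy, 0.01)
  expect_equal(d2$dA, 0.01)
  expect_true(d2$dA <= d2$dxy)
})

test_that("Weir-Cockerham FST: fixed differences, null data, and the
           hand-transcribed oracle", {
  # populations fixed for alternative alleles, 4 diploids each -> FST = 1
  haps <- matrix(c(rep(0L, 8), rep(1L, 8)), 16, 1)
  ls <- make_ls(list(make_locus(haps)), 4, 4)
  expect_equal(weir_cockerham_fst(ls)$fst, 1)
  # identical allele frequency and genotype composition in both pops:
  # a-component zero => FST <= 0
  g <- c(0L, 0L, 0L, 1L)  # one het, rest ref hom
  haps2 <- matrix(c(g, g), 8, 1)
  ls2 <- make_ls(list(make_locus(haps2)), 2, 2)
  expect_lte(weir_cockerham_fst(ls2)$fst, 0)
  # worked 2+2 diploid case against the independent transcription
  # pop1 genotypes {0/0, 0/1}; pop2 {1/1, 1/1}
  haps3 <- matrix(c(0L, 0L, 0L, 1L, 1L, 1L, 1L, 1L), 8, 1)
  ls3 <- make_ls(list(make_locus(haps3)), 2, 2)
  comp <- wc_oracle_site(c(0, 1), c(2, 2))
  expect_equal(weir_cockerham_fst(ls3)$fst,
               unname(comp["a"] / sum(comp)), tolerance = 1e-12)
  # monomorphic-only input errors
  expect_error(weir_cockerham_fst(
    make_ls(list(make_locus(matrix(0L, 8, 0))), 2, 2)), "monomorphic")
})

test_that("overall FST is invariant to population label swap and equals
           the ratio of summed components", {
  set.seed(9)
  loci <- lapply(1:5, function(i) random_locus(4, 3, name = paste0("L", i)))
  ls <- make_ls(loci, 2, 2)
  f1 <- weir_cockerham_fst(ls, "overall")
  swapped <- ls
  swapped$popmap$population <- rev(ls$popmap$population)
  f2 <- weir_cockerham_fst(swapped, "overall")
  expect_equal(f1$fst, f2$fst, tolerance = 1e-12)
  # per-SNP components aggregate to the overall ratio of sums
  snp <- weir_cockerham_fst(ls, "snp")
  expect_equal(attr(snp, "overall"), f1$fst)
  loc <- weir_cockerham_fst(ls, "locus")
  expect_equal(attr(loc, "overall"), f1$fst)
})

test_that("FST increases stochastically with divergence time", {
  set.seed(77)
  fst_at <- function(T, seed) {
    cfg <- simulation_config(n_variable_loci_target = 120,
                             n_invariant_loci = 0,
                             model = "split_no_mig",
                             params = demographic_params(nu1 = 1, nu2 = 1,
                                                         T = T),
                             intralocus_recomb_fraction = 0,
                             z_fraction = 0, seed = seed)
    weir_cockerham_fst(generate_dataset(cfg)$locus_set)$fst
  }
  seeds <- sample.int(1e6, 20)
  deep <- vapply(seeds, function(s) fst_at(1.0, s), 0)
  shallow <- vapply(seeds + 1, function(s) fst_at(0.05, s), 0)
  expect_lt(wilcox.test(deep, shallow, alternative = "greater")$p.value,
            0.01)
})

test_that("permutation G-test separates differentiated populations and
           matches exhaustive enumeration", {
  # identical populations: p well above significance
  set.seed(13)
  loc <- random_locus(4, 4)
  loc$haps <- rbind(loc$haps[1:4, ], loc$haps[1:4, ])
  ls_same <- make_ls(list(loc), 2, 2)
  set.seed(1)
  expect_gte(permutation_differentiation_test(ls_same, 500)$p_value, 0.5)
  # 50 fixed SNPs over 8+8 diploids: p at the floor (with 4+4 diploids the
  # combinatorial floor 2/choose(8,4) is ~0.03, so use the larger sample)
  haps <- matrix(rep(c(rep(0L, 16), rep(1L, 16)), 50), 32, 50)
  ls_fix <- make_ls(list(make_locus(haps, positions = 1:50)), 8, 8)
  set.seed(2)
  expect_lte(permutation_differentiation_test(ls_fix, 1000)$p_value, 0.01)
  # exhaustive oracle at 3+3 individuals, 2 SNPs
  set.seed(33)
  loc2 <- random_locus(6, 2)
  ls6 <- make_ls(list(loc2), 3, 3)
  dose <- ls6$loci[[1]]$haps[seq(1, 11, 2), ] + ls6$loci[[1]]$haps[seq(2, 12, 2), ]
  g_of <- function(lab) {
    g <- 0
    for (j in 1:2) {
      alt <- c(sum(dose[lab == 1, j]), sum(dose[lab == 2, j]))
      O <- rbind(c(alt[1], 6 - alt[1]), c(alt[2], 6 - alt[2]))
      E <- outer(rowSums(O), colSums(O)) / sum(O)
      nz <- O > 0
      g <- g + 2 * sum(O[nz] * log(O[nz] / E[nz]))
    }
    g
  }
  obs <- g_of(rep(c(1, 2), each = 3))
  labelings <- utils::combn(6, 3)
  exact <- mean(apply(labelings, 2, function(idx) {
    lab <- rep(2, 6); lab[idx] <- 1
    g_of(lab) >= obs - 1e-12
  }))
  set.seed(3)
  mc <- permutation_differentiation_test(ls6, 4000)$p_value
  expect_lt(abs(mc - exact), 3 * sqrt(exact * (1 - exact) / 4000) + 1e-3)
})

test_that("permutation p-values are superuniform under panmixia", {
  set.seed(55)
  ps <- replicate(60, {
    cfg <- simulation_config(n_variable_loci_target = 40,
                             n_invariant_loci = 0, model = "neutral",
                             params = demographic_params(),
                             intralocus_recomb_fraction = 0,
                             z_fraction = 0, seed = sample.int(1e6, 1))
    ls <- generate_dataset(cfg)$locus_set
    permutation_differentiation_test(ls, 200)$p_value
  })
  expect_lte(mean(ps < 0.05), 0.12)
})

test_that("exact HWE test equals the enumeration oracle on all n <= 10
           configurations", {
  for (n in 1:10) {
    for (nA in 0:n) {
      for (h in seq.int(nA %% 2, min(nA, 2 * n - nA), by = 2)) {
        nAA <- (nA - h) / 2
        naa <- n - nAA - h
        expect_equal(hwe_exact_test(nAA, h, naa), hwe_oracle(nAA, h, naa),
                     tolerance = 1e-12,
                     info = sprintf("n=%d nA=%d het=%d", n, nA, h))
      }
    }
  }
  # monomorphic convention
  expect_equal(hwe_exact_test(7, 0, 0), 1)
  # all-heterozygote case against the oracle
  expect_equal(hwe_exact_test(0, 8, 0), hwe_oracle(0, 8, 0),
               tolerance = 1e-12)
})

test_that("hwe_test flags loci below the threshold", {
  # a locus with a strong heterozygote excess and a compliant locus
  bad <- make_locus(matrix(rep(c(0L, 1L), 8), 16, 1), name = "bad")
  # genotypes 0/0, 0/1, 0/1, 1/1 per population: exactly Hardy-Weinberg
  hw <- rep(c(0L, 0L, 0L, 1L, 0L, 1L, 1L, 1L), 2)
  ok <- make_locus(matrix(hw, 16, 1), name = "ok")
  ls <- make_ls(list(bad, ok), 4, 4)
  res <- hwe_test(ls)
  expect_true("bad" %in% res$loci_out_of_hwe)
  expect_false("ok" %in% res$loci_out_of_hwe)
  expect_equal(res$n_loci_in_hwe + res$n_loci_out, 2)
})

test_that("heterozygosity summary matches direct recomputation", {
  # all individuals heterozygous: Ho = 1, He = 0.5 * 2n/(2n-1)
  haps <- matrix(rep(c(0L, 1L), 8), 16, 1)
  ls <- make_ls(list(make_locus(haps), make_locus(haps, name = "locB")),
                4, 4)
  hs <- heterozygosity_summary(ls)
  expect_equal(unname(hs$ho), c(1, 1))
  expect_equal(unname(hs$he),
               rep(2 * 0.5 * 0.5 * 8 / 7, 2))  # per-pop n = 8 haplotypes
  # duplicate population: per-pop Ho and He identical across pops
  set.seed(21)
  loc <- random_locus(4, 5)
  loc$haps <- rbind(loc$haps[1:8, ], loc$haps[1:8, ])
  hs2 <- heterozygosity_summary(
    make_ls(list(loc, { l2 <- random_locus(4, 2, name = "locB")
                        l2$haps <- rbind(l2$haps[1:8, ], l2$haps[1:8, ]); l2 }),
            4, 4))
  expect_equal(unname(hs2$ho[1]), unname(hs2$ho[2]))
  expect_equal(unname(hs2$he[1]), unname(hs2$he[2]))
  expect_equal(unname(hs2$unique_alleles), c(0, 0))
  # spreadsheet-style recomputation on a small fixed matrix
  h3 <- matrix(c(0L, 1L, 0L, 0L, 1L, 1L, 0L, 1L), 8, 1)
  h3b <- matrix(c(0L, 0L, 0L, 1L, 1L, 1L, 1L, 1L), 8, 1)
  ls3 <- make_ls(list(make_locus(h3), make_locus(h3b, name = "locB")), 2, 2)
  hs3 <- heterozygosity_summary(ls3)
  # pop1 genotypes: 0/1, 0/0 -> Ho = 0.5; p = 1/4; He = 2pq * 4/3
  expect_equal(unname(hs3$ho["pop1"]), 0.5)
  expect_equal(unname(hs3$he["pop1"]), 2 * 0.25 * 0.75 * 4 / 3)
  # pop2: locA gives He = 2pq*4/3 with p = 3/4; locB is monomorphic in
  # pop2 (He = 0), so the mean across the two loci halves it
  expect_equal(unname(hs3$he["pop2"]), (2 * 0.25 * 0.75 * 4 / 3) / 2)
  # paired t reports both tails consistently
  expect_equal(hs3$paired_t$p_greater + hs3$paired_t$p_less, 1)
})

test_that("assignment reaches full diagnosability with fixed differences
           and finds no signal under panmixia", {
  # >= 10 fixed differences: perfect separation, posteriors ~ 1
  fixed <- matrix(rep(c(rep(0L, 8), rep(1L, 8)), 12), 16, 12)
  set.seed(31)
  noise <- random_locus(8, 6, name = "locN")
  ls <- make_ls(list(make_locus(fixed, positions = 1:12), noise), 4, 4)
  res <- assign_individuals(ls, n_pcs = 4)
  expect_equal(res$diagnosability, 1)
  expect_true(all(apply(res$posterior, 1, max) > 0.99))
  # overfitting guard
  expect_error(assign_individuals(ls, n_pcs = 8), "n_pcs")
  # panmictic data: leave-one-out assignment shows no predictive signal
  set.seed(41)
  diag_null <- replicate(8, {
    cfg <- simulation_config(n_variable_loci_target = 150,
                             n_invariant_loci = 0, model = "neutral",
                             params = demographic_params(),
                             intralocus_recomb_fraction = 0,
                             z_fraction = 0, seed = sample.int(1e6, 1))
    assign_individuals(generate_dataset(cfg)$locus_set, 4,
                       cv = "loo")$diagnosability
  })
  expect_lte(mean(diag_null), 0.5)
})
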