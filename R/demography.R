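#' Expected joint SFS by Monte-Carlo coalescent expectation
#'
#' Approximates the model's expected joint site frequency spectrum by
#' simulating genealogies under the structured coalescent and accumulating
#' each branch's length into the cell indexed by its descendant leaf counts
#' in the two populations. With infinite-sites mutation the expected SNP
#' mass per cell is \eqn{\theta/2} times the mean branch length, so the
#' returned grid is mean branch length divided by 2 and the overall
#' \eqn{\theta} scaling is applied downstream by
#' [composite_log_likelihood()]. The spectrum is folded by default.
#'
#' Uses R's random stream; fix the seed for a reproducible (and, within an
#' optimization, common-random-numbers) spectrum.
#'
#' @param model one of [DIVERGENCE_MODELS].
#' @param params a [demographic_params()].
#' @param n1,n2 haplotype sample sizes (\code{n2 = 0} for single-population
#'   spectra).
#' @param n_genealogies Monte-Carlo genealogy count (>= 1000).
#' @param fold return the folded spectrum (default TRUE).
#' @return A \code{joint_sfs} with attribute \code{n_genealogies}.
#' @export
expected_sfs <- function(model, params, n1, n2, n_genealogies = 20000,
                         fold = TRUE) {
  stopifnot(n_genealogies >= 1000)
  ka <- model_kernel_args(model, params)
  grid <- coal_branch_grid_cpp(as.integer(n_genealogies),
                               as.integer(n1), as.integer(n2),
                               ka$nu1, ka$nu2, ka$T, ka$m12, ka$m21,
                               ka$s1, ka$growth) / 2
  sfs <- if (fold)
    new_joint_sfs(fold_grid(grid, n1, n2), sfs_mask(n1, n2, TRUE),
                  TRUE, n1, n2)
  else
    new_joint_sfs(grid, sfs_mask(n1, n2, FALSE), FALSE, n1, n2)
  attr(sfs, "n_genealogies") <- n_genealogies
  sfs
}

#' Poisson composite log-likelihood of a data SFS given a model SFS
#'
#' Treats unmasked cells as independent Poisson counts with mean
#' \eqn{\hat\theta \times} model mass, where
#' \eqn{\hat\theta = \sum data / \sum model} over unmasked cells is the
#' Poisson-optimal scaling. Model cells equal to zero where the data are
#' positive are floored at \code{epsilon} (and counted in
#' \code{n_floored}).
#'
#' @param data,model \code{joint_sfs} objects of matching dimensions and
#'   masks.
#' @param epsilon floor for zero model cells (default 1e-12).
#' @return A list with \code{loglik}, \code{theta_hat}, \code{n_floored}.
#' @export
composite_log_likelihood <- function(data, model, epsilon = 1e-12) {
  stopifnot(identical(dim(data$mass), dim(model$mass)),
            identical(data$mask, model$mask))
  d <- data$mass[!data$mask]
  m <- model$mass[!model$mask]
  theta_hat <- sum(d) / sum(m)
  floored <- m <= 0 & d > 0
  m[m <= 0] <- epsilon
  mu <- theta_hat * m
  ll <- sum(-mu - lgamma(d + 1))
  pos <- d > 0
  ll <- ll + sum(d[pos] * log(mu[pos]))
  list(loglik = ll, theta_hat = theta_hat, n_floored = sum(floored))
}

# Default fitting bounds per free parameter.
default_bounds <- function(free) {
  lower <- c(nu1 = 1e-2, nu2 = 1e-2, T = 1e-2, m = 1e-3, m12 = 1e-3,
             m21 = 1e-3, s = 0.02)
  upper <- c(nu1 = 50, nu2 = 50, T = 10, m = 20, m12 = 20, m21 = 20,
             s = 0.98)
  list(lower = lower[free], upper = upper[free])
}

# Deterministic Monte-Carlo likelihood surface: reset the genealogy seed
# before every model-spectrum evaluation (common random numbers).
make_objective <- function(data, model, free, bounds, n_genealogies,
                           genealogy_seed) {
  n1 <- data$n1; n2 <- data$n2
  function(logx) {
    x <- exp(logx)
    names(x) <- free
    if (any(x < bounds$lower | x > bounds$upper)) return(1e10)
    params <- free_to_params(model, x)
    set.seed(genealogy_seed)
    msfs <- expected_sfs(model, params, n1, n2, n_genealogies,
                         fold = data$folded)
    -composite_log_likelihood(data, msfs)$loglik
  }
}

#' Fit a divergence model to a folded joint SFS
#'
#' Maximizes the Poisson composite likelihood over the model's free
#' parameters by Nelder-Mead in log-parameter space, from several perturbed
#' starting points. Within one fit the Monte-Carlo expected spectrum uses
#' common random numbers (a fixed genealogy seed), making the likelihood
#' surface deterministic. The fit is declared converged when the three best
#' starts agree within \code{loglik_tol} likelihood units (the
#' repeatability rule: a result is trusted once the same optimum is found
#' three times).
#'
#' @param data a folded \code{joint_sfs}.
#' @param model one of [DIVERGENCE_MODELS].
#' @param bounds optional list with named \code{lower}/\code{upper}
#'   vectors over the model's free parameters.
#' @param n_starts number of optimization starts (default 3).
#' @param n_genealogies genealogies per likelihood evaluation during
#'   optimization (default 20000).
#' @param final_n_genealogies genealogies for the final re-evaluation at
#'   the optimum (default 100000).
#' @param start optional named vector of starting values.
#' @param seed integer seed controlling starts and the common-random-number
#'   genealogy stream.
#' @param loglik_tol agreement tolerance for the convergence rule
#'   (default 0.5).
#' @param maxit Nelder-Mead iteration cap per start.
#' @return An object of class \code{fit_result}: model id, best \code{params},
#'   free-parameter vector, \code{theta_hat}, \code{loglik} (at
#'   \code{final_n_genealogies}), per-start table, \code{converged} flag,
#'   and the seeds used.
#' @export
fit_model <- function(data, model, bounds = NULL, n_starts = 3,
                      n_genealogies = 20000, final_n_genealogies = 100000,
                      start = NULL, seed = 1, loglik_tol = 0.5,
                      maxit = 500) {
  model <- match.arg(model, DIVERGENCE_MODELS)
  free <- model_free_params(model)
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()))
  genealogy_seed <- (as.integer(seed) * 7919L) %% 2147483399L + 1L

  if (length(free) == 0) {
    # the neutral model has no free parameters: evaluate directly
    set.seed(genealogy_seed)
    msfs <- expected_sfs(model, demographic_params(), data$n1, data$n2,
                         final_n_genealogies, fold = data$folded)
    cl <- composite_log_likelihood(data, msfs)
    return(structure(list(model = model, params = demographic_params(),
                          free = setNames(numeric(0), character(0)),
                          theta_hat = cl$theta_hat, loglik = cl$loglik,
                          starts = data.frame(start = 1, loglik = cl$loglik,
                                              convergence = 0L),
                          converged = TRUE, seed = seed,
                          n_genealogies = final_n_genealogies),
                     class = "fit_result"))
  }

  b <- default_bounds(free)
  if (!is.null(bounds)) {
    if (!is.null(bounds$lower)) b$lower[names(bounds$lower)] <- bounds$lower
    if (!is.null(bounds$upper)) b$upper[names(bounds$upper)] <- bounds$upper
  }
  stopifnot(all(b$lower > 0), all(is.finite(b$upper)), all(b$lower < b$upper))
  obj <- make_objective(data, model, free, b, n_genealogies, genealogy_seed)

  set.seed(seed)
  # coarse log-uniform probe of the bounded box, then polish the best
  # probes by Nelder-Mead (the (T, m) likelihood ridge defeats single-basin
  # perturbation starts)
  if (!is.null(start) && n_starts == 1) {
    # a trusted start (e.g. a jackknife refit from the full-data optimum):
    # no exploration needed
    start_pars <- list(log(start[free]))
  } else {
    # dense, cheap probing of the bounded box (a reduced genealogy count
    # is plenty for basin-finding), then a race of short runs
    n_probe <- max(25L * n_starts, 120L)
    obj_probe <- make_objective(data, model, free, b,
                                max(2000L, n_genealogies %/% 5L),
                                genealogy_seed)
    probes <- lapply(seq_len(n_probe), function(i)
      log(b$lower) + runif(length(free)) * (log(b$upper) - log(b$lower)))
    if (!is.null(start)) probes[[1]] <- log(start[free])
    probe_val <- vapply(probes, obj_probe, 0)
    n_race <- min(2L * n_starts, n_probe)
    raced <- lapply(probes[order(probe_val)[seq_len(n_race)]], function(s0)
      optim(s0, obj, method = "Nelder-Mead",
            control = list(maxit = 150, reltol = 1e-6)))
    race_val <- vapply(raced, `[[`, 0, "value")
    start_pars <- lapply(raced[order(race_val)[seq_len(n_starts)]],
                         `[[`, "par")
  }
  fits <- lapply(start_pars, function(s0) {
    f <- optim(s0, obj, method = "Nelder-Mead",
               control = list(maxit = maxit, reltol = 1e-8))
    # restart at the optimum: Nelder-Mead can report premature convergence
    optim(f$par, obj, method = "Nelder-Mead",
          control = list(maxit = maxit, reltol = 1e-8))
  })
  lls <- vapply(fits, function(f) -f$value, 0)
  ord <- order(lls, decreasing = TRUE)
  best <- fits[[ord[1]]]
  converged <- if (n_starts >= 3)
    (lls[ord[1]] - lls[ord[3]]) <= loglik_tol else fits[[ord[1]]]$convergence == 0

  # polish the winning start on a lower-noise surface
  if (final_n_genealogies > n_genealogies) {
    obj_final <- make_objective(data, model, free, b, final_n_genealogies,
                                genealogy_seed)
    best <- optim(best$par, obj_final, method = "Nelder-Mead",
                  control = list(maxit = max(200, maxit %/% 2),
                                 reltol = 1e-8))
  }
  best_free <- setNames(exp(best$par), free)

  params <- free_to_params(model, best_free)
  set.seed(genealogy_seed)
  msfs <- expected_sfs(model, params, data$n1, data$n2,
                       final_n_genealogies, fold = data$folded)
  cl <- composite_log_likelihood(data, msfs)
  structure(list(model = model, params = params, free = best_free,
                 theta_hat = cl$theta_hat, loglik = cl$loglik,
                 starts = data.frame(start = seq_len(n_starts),
                                     loglik = lls,
                                     convergence = vapply(fits, `[[`, 0L,
                                                          "convergence")),
                 converged = converged, seed = seed,
                 n_genealogies = n_genealogies),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat("fit_result:", x$model,
      "| log composite likelihood =", round(x$loglik, 2),
      "| theta_hat =", signif(x$theta_hat, 6),
      "| converged:", x$converged, "\n")
  if (length(x$free))
    print(round(x$free, 4))
  invisible(x)
}

#' Fit and rank several divergence models
#'
#' Fits each model to the same folded joint SFS and returns a table ranked
#' by maximum log composite likelihood. For fits that did not satisfy the
#' three-way agreement rule, the reported likelihood is the mean of the top
#' five per-start likelihoods (an unstable model's single best value is not
#' trustworthy), with the maximum retained in its own column.
#'
#' @param data a folded \code{joint_sfs}.
#' @param models character vector of model ids (default: all six).
#' @param ... passed to [fit_model()].
#' @return A list with \code{table} (ranked data frame) and \code{fits}
#'   (named list of \code{fit_result}s).
#' @export
compare_models <- function(data, models = DIVERGENCE_MODELS, ...) {
  stopifnot(length(models) >= 1)
  fits <- lapply(models, function(mm) fit_model(data, mm, ...))
  names(fits) <- models
  rows <- lapply(models, function(mm) {
    f <- fits[[mm]]
    top5 <- mean(sort(f$starts$loglik, decreasing = TRUE)[
      seq_len(min(5, nrow(f$starts)))])
    data.frame(model = mm, n_params = length(f$free),
               loglik = if (f$converged) f$loglik else top5,
               max_loglik = f$loglik, converged = f$converged,
               theta_hat = f$theta_hat, stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  tab <- tab[order(tab$loglik, decreasing = TRUE), ]
  rownames(tab) <- NULL
  list(table = tab, fits = fits)
}

#' Jackknife confidence intervals for fitted parameters
#'
#' Refits the model to each leave-one-block-out replicate spectrum,
#' starting from the full-data optimum, and forms delete-m jackknife
#' standard errors: \eqn{SE^2 = (g-1)/g \sum_r (\hat\theta_r - \bar\theta)^2}
#' over the \eqn{g} replicate estimates. 95\% intervals are the full-data
#' estimate \eqn{\pm 1.96\,SE}. Non-convergent replicate fits are excluded
#' and counted.
#'
#' @param replicates list of \code{joint_sfs} replicates (from
#'   [jackknife_datasets()]).
#' @param model model id.
#' @param full_fit the full-data \code{fit_result}.
#' @param n_genealogies genealogies per replicate likelihood evaluation.
#' @param maxit Nelder-Mead cap per replicate refit.
#' @param ... passed to [fit_model()].
#' @return A data frame with one row per parameter (including
#'   \code{theta}): estimate, se, lower, upper; attribute
#'   \code{n_excluded} counts dropped replicates.
#' @export
jackknife_ci <- function(replicates, model, full_fit,
                         n_genealogies = 20000, maxit = 200, ...) {
  stopifnot(length(replicates) >= 2)
  free <- model_free_params(model)
  ests <- list()
  n_excluded <- 0L
  for (r in seq_along(replicates)) {
    # one common genealogy seed across replicates: replicate-to-replicate
    # differences then reflect the data alone, not Monte-Carlo noise
    f <- fit_model(replicates[[r]], model, n_starts = 1,
                   start = full_fit$free, seed = full_fit$seed + 1000L,
                   n_genealogies = n_genealogies,
                   final_n_genealogies = n_genealogies, maxit = maxit, ...)
    if (length(free) > 0 && f$starts$convergence[1] != 0) {
      n_excluded <- n_excluded + 1L
      next
    }
    ests[[length(ests) + 1L]] <- c(f$free, theta = f$theta_hat)
  }
  if (length(ests) < 2) stop("fewer than two convergent jackknife replicates")
  em <- do.call(rbind, ests)
  g <- nrow(em)
  center <- colMeans(em)
  se <- sqrt((g - 1) / g * colSums(sweep(em, 2, center)^2))
  full <- c(full_fit$free, theta = full_fit$theta_hat)
  out <- data.frame(param = names(full), estimate = unname(full),
                    se = unname(se[names(full)]),
                    lower = unname(full - 1.96 * se[names(full)]),
                    upper = unname(full + 1.96 * se[names(full)]),
                    stringsAsFactors = FALSE)
  attr(out, "n_excluded") <- n_excluded
  attr(out, "replicate_estimates") <- em
  out
}
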