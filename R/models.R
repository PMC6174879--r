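#' Two-population divergence models
#'
#' The six demographic models supported throughout the package, in the
#' diffusion-unit convention: time in units of \eqn{2 N_{ref}} generations,
#' population sizes as ratios \eqn{\nu_i = N_i / N_{ref}}, and migration as
#' \eqn{m = 2 N_{ref} \times} (per-generation migration fraction).
#'
#' \describe{
#'   \item{neutral}{no divergence; a single panmictic population of size
#'     \eqn{N_{ref}} (the standard neutral model).}
#'   \item{split_mig}{the ancestral population splits at time \code{T} into
#'     two populations of constant sizes \code{nu1}, \code{nu2} exchanging
#'     migrants symmetrically at scaled rate \code{m12 = m21}.}
#'   \item{split_no_mig}{as \code{split_mig} with migration fixed at zero.}
#'   \item{im}{isolation-with-migration: the ancestral population splits
#'     into fractions \code{s} and \code{1 - s}, each changing size
#'     exponentially to \code{nu1}, \code{nu2} at the present, with
#'     independent migration rates \code{m12}, \code{m21}.}
#'   \item{im_no_mig}{as \code{im} with migration fixed at zero.}
#'   \item{split_bimig}{as \code{split_mig} but with independent
#'     \code{m12} and \code{m21} (asymmetric gene flow).}
#' }
#'
#' @format A character vector of model identifiers.
#' @export
DIVERGENCE_MODELS <- c("neutral", "split_mig", "split_no_mig",
                       "im", "im_no_mig", "split_bimig")

#' Demographic parameters in diffusion units
#'
#' Container for the parameters consumed by [simulate_genealogy()],
#' [expected_sfs()] and the model-fitting functions. Unused fields are fixed
#' by the model (e.g. migration rates are forced to zero by the no-migration
#' models).
#'
#' @param nu1,nu2 present-day population sizes as ratios to the ancestral
#'   reference size \eqn{N_{ref}}; must be positive.
#' @param T split time in units of \eqn{2 N_{ref}} generations; must be
#'   non-negative (zero collapses every model to the neutral one).
#' @param m12,m21 scaled migration rates (\eqn{2 N_{ref} \times} fraction per
#'   generation); must be non-negative.
#' @param s ancestral split fraction for the growth (\code{im}) models;
#'   strictly between 0 and 1.
#' @return An object of class \code{demographic_params} (a named list).
#' @export
demographic_params <- function(nu1 = 1, nu2 = 1, T = 0, m12 = 0, m21 = 0,
                               s = 0.5) {
  stopifnot(is.numeric(nu1), nu1 > 0, is.numeric(nu2), nu2 > 0,
            is.numeric(T), T >= 0, m12 >= 0, m21 >= 0, s > 0, s < 1)
  structure(list(nu1 = nu1, nu2 = nu2, T = T, m12 = m12, m21 = m21, s = s),
            class = "demographic_params")
}

# Resolve a model id + params into the arguments of the coalescent kernel,
# enforcing each model's constraints.
model_kernel_args <- function(model, params) {
  model <- match.arg(model, DIVERGENCE_MODELS)
  p <- params
  if (!inherits(p, "demographic_params"))
    p <- do.call(demographic_params, as.list(p))
  ka <- list(nu1 = p$nu1, nu2 = p$nu2, T = p$T, m12 = p$m12, m21 = p$m21,
             s1 = p$s, growth = FALSE)
  switch(model,
    neutral = {
      ka$T <- 0; ka$m12 <- 0; ka$m21 <- 0
      ka$nu1 <- 1; ka$nu2 <- 1
    },
    split_mig = {
      if (!isTRUE(all.equal(p$m12, p$m21)))
        stop("split_mig uses one symmetric migration rate; set m12 == m21 ",
             "or use model 'split_bimig'")
    },
    split_no_mig = {
      if (p$m12 != 0 || p$m21 != 0)
        stop("split_no_mig requires zero migration rates")
    },
    im = { ka$growth <- TRUE },
    im_no_mig = {
      if (p$m12 != 0 || p$m21 != 0)
        stop("im_no_mig requires zero migration rates")
      ka$growth <- TRUE
    },
    split_bimig = { }
  )
  ka
}

# Free parameters per model, in fitting order.
model_free_params <- function(model) {
  model <- match.arg(model, DIVERGENCE_MODELS)
  switch(model,
    neutral      = character(0),
    split_mig    = c("nu1", "nu2", "T", "m"),
    split_no_mig = c("nu1", "nu2", "T"),
    im           = c("s", "nu1", "nu2", "T", "m12", "m21"),
    im_no_mig    = c("s", "nu1", "nu2", "T"),
    split_bimig  = c("nu1", "nu2", "T", "m12", "m21"))
}

# Expand a named free-parameter vector into demographic_params.
free_to_params <- function(model, x) {
  x <- as.list(x)
  if (!is.null(x$m)) { x$m12 <- x$m; x$m21 <- x$m; x$m <- NULL }
  do.call(demographic_params, x)
}
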