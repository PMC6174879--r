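#' Configuration for the synthetic two-population dataset generator
#'
#' Defaults emulate the shape of a UCE population-genomics dataset for two
#' recently diverged bird populations: 2 populations x 4 diploids, ~2,600
#' variable loci of mean length ~1,154 bp, ~800 invariant loci, ~5% of loci
#' flagged as Z-linked, and a demographic truth of a split-with-migration
#' history at the fitted parameter values (nu1 = 3.52, nu2 = 5.95, T = 1.44,
#' m = 1.65). \code{theta_per_site} is calibrated so that this default
#' configuration yields about 3.6 SNPs per variable locus.
#'
#' @param samples_per_pop diploid individuals sampled per population.
#' @param n_variable_loci_target number of variable loci to generate.
#' @param n_invariant_loci number of invariant (annotation-only) loci.
#' @param locus_length_mean_bp,locus_length_sd_bp locus length distribution
#'   (normal, truncated below at 200 bp).
#' @param theta_per_site scaled mutation rate \eqn{4 N_{ref} \mu} per site.
#' @param model one of [DIVERGENCE_MODELS].
#' @param params a [demographic_params()] truth.
#' @param intralocus_recomb_fraction proportion of variable loci simulated as
#'   two linked genealogy blocks spliced at a uniform breakpoint (creating
#'   potential four-gamete violations).
#' @param z_fraction proportion of loci flagged as Z-linked.
#' @param seed integer seed; fixed seed gives byte-identical output.
#' @return An object of class \code{simulation_config}.
#' @export
simulation_config <- function(samples_per_pop = 4,
                              n_variable_loci_target = 2600,
                              n_invariant_loci = 800,
                              locus_length_mean_bp = 1153.6,
                              locus_length_sd_bp = 148,
                              theta_per_site = 3.0e-4,
                              model = "split_mig",
                              params = demographic_params(
                                nu1 = 3.52, nu2 = 5.95, T = 1.44,
                                m12 = 1.65, m21 = 1.65),
                              intralocus_recomb_fraction = 0.2,
                              z_fraction = 0.049,
                              seed = 1L) {
  stopifnot(samples_per_pop >= 1, n_variable_loci_target >= 1,
            n_invariant_loci >= 0, locus_length_mean_bp > 0,
            locus_length_sd_bp >= 0, theta_per_site > 0,
            intralocus_recomb_fraction >= 0, intralocus_recomb_fraction <= 1,
            z_fraction >= 0, z_fraction <= 1)
  model <- match.arg(model, DIVERGENCE_MODELS)
  structure(list(n_pops = 2L, samples_per_pop = as.integer(samples_per_pop),
                 n_variable_loci_target = as.integer(n_variable_loci_target),
                 n_invariant_loci = as.integer(n_invariant_loci),
                 locus_length_mean_bp = locus_length_mean_bp,
                 locus_length_sd_bp = locus_length_sd_bp,
                 theta_per_site = theta_per_site,
                 model = model, params = params,
                 intralocus_recomb_fraction = intralocus_recomb_fraction,
                 z_fraction = z_fraction, seed = as.integer(seed)),
            class = "simulation_config")
}

# Truncated-normal locus length (>= 200 bp), rounded to integer bp.
draw_locus_length <- function(cfg) {
  repeat {
    L <- round(rnorm(1, cfg$locus_length_mean_bp, cfg$locus_length_sd_bp))
    if (L >= 200) return(as.integer(L))
  }
}

# Distinct integer site positions within [lo, hi], sorted.
draw_positions <- function(n, lo, hi) {
  if (n == 0) return(integer(0))
  if (hi - lo + 1 < n) stop("locus too short for the mutation count drawn")
  sort(sample(seq.int(lo, hi), n))
}

#' Generate a synthetic multi-locus phased dataset
#'
#' Simulates variable loci under the configured divergence model until the
#' target count is reached (locus draws that receive no mutation are
#' discarded), flags loci as Z-linked at the configured rate, and emits the
#' configured number of invariant annotation-only loci. A configurable
#' fraction of loci is built from two genealogies spliced at a uniform
#' breakpoint, emulating intra-locus recombination; the remainder descend
#' from a single genealogy and therefore cannot violate the four-gamete
#' condition under infinite sites.
#'
#' @param cfg a [simulation_config()].
#' @return An object of class \code{synthetic_dataset}: a list with
#'   \code{locus_set} (the simulated [locus_set()]) and \code{truth}
#'   (the configuration, including the generating parameters).
#' @export
generate_dataset <- function(cfg) {
  stopifnot(inherits(cfg, "simulation_config"))
  set.seed(cfg$seed)
  ns <- cfg$samples_per_pop
  nh <- 2L * ns  # haplotypes per population
  samples <- c(paste0("pop1_ind", seq_len(ns)), paste0("pop2_ind", seq_len(ns)))
  popmap <- data.frame(sample = samples,
                       population = rep(c("pop1", "pop2"), each = ns),
                       stringsAsFactors = FALSE)
  loci <- vector("list", cfg$n_variable_loci_target)
  n_var <- 0L
  attempts <- 0L
  max_attempts <- 60L * cfg$n_variable_loci_target
  while (n_var < cfg$n_variable_loci_target) {
    attempts <- attempts + 1L
    if (attempts > max_attempts)
      stop("simulation produced too few variable loci; increase ",
           "theta_per_site or the locus length")
    L <- draw_locus_length(cfg)
    recomb <- runif(1) < cfg$intralocus_recomb_fraction
    if (recomb) {
      brk <- floor(runif(1, min = 1, max = L))  # block A = [1, brk]
      g1 <- simulate_genealogy(cfg$model, cfg$params, nh, nh)
      g2 <- simulate_genealogy(cfg$model, cfg$params, nh, nh)
      h1 <- sprinkle_mutations(g1, cfg$theta_per_site * brk)
      h2 <- sprinkle_mutations(g2, cfg$theta_per_site * (L - brk))
      pos <- c(draw_positions(ncol(h1), 1L, brk),
               draw_positions(ncol(h2), brk + 1L, L))
      haps <- cbind(h1, h2)
    } else {
      g <- simulate_genealogy(cfg$model, cfg$params, nh, nh)
      haps <- sprinkle_mutations(g, cfg$theta_per_site * L)
      pos <- draw_positions(ncol(haps), 1L, L)
    }
    if (ncol(haps) == 0L) next
    n_var <- n_var + 1L
    # genealogy leaves are ordered pop1 then pop2; rows must interleave
    # samples (two consecutive rows per diploid), which they already do
    # because leaves 2k-1, 2k are assigned to sample k within each pop.
    name <- sprintf("uce-%05d", n_var)
    gq <- matrix(pmin(99L, 10L + rpois(length(samples) * ncol(haps), 65)),
                 nrow = length(samples))
    loci[[n_var]] <- list(
      name = name, length_bp = L,
      chrom_class = if (runif(1) < cfg$z_fraction) "Z" else "autosome",
      positions = pos, haps = haps, gq = gq)
  }
  invariant <- NULL
  if (cfg$n_invariant_loci > 0) {
    invariant <- data.frame(
      name = sprintf("uce-inv-%05d", seq_len(cfg$n_invariant_loci)),
      length_bp = vapply(seq_len(cfg$n_invariant_loci),
                         function(i) draw_locus_length(cfg), 0L),
      chrom_class = ifelse(runif(cfg$n_invariant_loci) < cfg$z_fraction,
                           "Z", "autosome"),
      stringsAsFactors = FALSE)
  }
  structure(list(locus_set = locus_set(loci, popmap, invariant),
                 truth = cfg),
            class = "synthetic_dataset")
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat("synthetic_dataset under model", x$truth$model, "\n")
  print(x$locus_set)
  invisible(x)
}

#' @rdname generate_dataset
#' @param x a \code{synthetic_dataset}.
#' @param dir output directory for the VCF, popmap and annotation files.
#' @param prefix file-name prefix.
#' @export
write_dataset <- function(x, dir, prefix = "dataset") {
  stopifnot(inherits(x, "synthetic_dataset"))
  write_locus_set(x$locus_set, dir, prefix)
}
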