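#' Per-site substitution rate from outgroup divergence
#'
#' Divergence to a dated outgroup, annualized over the two branches:
#' \eqn{rate = (substitutions / sites) / (2 \times TMRCA)} per site per
#' year.
#'
#' @param substitutions total substitution count over the aligned bases.
#' @param sites total aligned length in bp (> 0).
#' @param tmrca_years time to the most recent common ancestor with the
#'   outgroup, in years (> 0).
#' @return Substitution rate per site per year.
#' @export
substitution_rate <- function(substitutions, sites, tmrca_years) {
  stopifnot(sites > 0, tmrca_years > 0, substitutions >= 0,
            substitutions <= sites)
  (substitutions / sites) / (2 * tmrca_years)
}

#' @rdname substitution_rate
#' @param rates one or more per-comparison rates to average (arithmetic
#'   mean), accounting for the uncertainty of any single outgroup
#'   calibration.
#' @export
average_rate <- function(rates) {
  stopifnot(length(rates) >= 1, all(rates >= 0))
  mean(rates)
}

#' Generation time from age at first breeding and adult survival
#'
#' \eqn{G = \alpha + s / (1 - s)}: the age at first breeding plus the
#' expected number of further breeding seasons given annual adult survival
#' \eqn{s}.
#'
#' @param alpha age at first breeding in years (>= 0).
#' @param s annual adult survival probability, in \eqn{[0, 1)}.
#' @return Generation time in years.
#' @export
generation_time <- function(alpha, s) {
  stopifnot(alpha >= 0, s >= 0)
  if (s >= 1) stop("annual survival must be < 1")
  alpha + s / (1 - s)
}

#' Substitution-rate calibration
#'
#' Bundles one or more outgroup comparisons into the calibration used for
#' unit conversion: per-comparison annual rates, their average, the
#' generation time, and the per-generation rate
#' \eqn{\mu_{gen} = rate \times G}.
#'
#' @param comparisons a data frame with columns \code{sites} (aligned bp),
#'   \code{substitutions} and \code{tmrca_years}, one row per outgroup.
#' @param gen_time generation time in years; alternatively supply
#'   \code{alpha} and \code{s} to compute it via [generation_time()].
#' @param alpha,s see [generation_time()].
#' @return An object of class \code{rate_calibration}.
#' @export
rate_calibration <- function(comparisons, gen_time = NULL, alpha = NULL,
                             s = NULL) {
  comparisons <- as.data.frame(comparisons)
  stopifnot(all(c("sites", "substitutions", "tmrca_years") %in%
                  names(comparisons)))
  if (is.null(gen_time)) gen_time <- generation_time(alpha, s)
  rates <- mapply(substitution_rate, comparisons$substitutions,
                  comparisons$sites, comparisons$tmrca_years)
  comparisons$rate_per_year <- rates
  structure(list(comparisons = comparisons,
                 rate_per_year = average_rate(rates),
                 gen_time = gen_time,
                 mu_per_generation = average_rate(rates) * gen_time),
            class = "rate_calibration")
}

# The monotone conversion maps from diffusion units to biological units.
conv_maps <- function(mu_gen, L, gen_time, nref) {
  list(
    theta = function(th) th / (4 * mu_gen * L),        # -> Nref individuals
    nu1 = function(nu) nu * nref,                      # -> N1 individuals
    nu2 = function(nu) nu * nref,                      # -> N2 individuals
    T = function(T) T * 2 * nref * gen_time            # -> years
  )
}

#' Convert fitted diffusion-unit parameters into biological units
#'
#' Translates \eqn{(\theta, \nu_1, \nu_2, T, m)} into individuals, years
#' and migrants per generation:
#' \deqn{N_{ref} = \theta / (4 \mu_{gen} L), \quad N_i = \nu_i N_{ref},}
#' \deqn{T_{years} = T \times 2 N_{ref} \times G, \quad
#'   migrants_i = m_i \nu_i / 2,}
#' where \eqn{\mu_{gen}} is the per-generation substitution rate and
#' \eqn{L} the adjusted surveyed sequence length in bp. Confidence-interval
#' endpoints, when supplied, are passed through the same (monotone) maps
#' with the other inputs held at their point estimates.
#'
#' @param theta fitted SFS scaling factor.
#' @param nu1,nu2 population size ratios.
#' @param T split time in \eqn{2 N_{ref}} generations.
#' @param m12,m21 scaled migration rates (supply the same value twice for
#'   the symmetric model).
#' @param cal a [rate_calibration()].
#' @param L adjusted surveyed sequence length in bp (> 0).
#' @param ci optional named list of \code{c(lower, upper)} diffusion-unit
#'   intervals for any of \code{theta, nu1, nu2, T, m12, m21}.
#' @return An object of class \code{bio_units}: a list with \code{nref},
#'   \code{n1}, \code{n2}, \code{t_years}, \code{migrants_1},
#'   \code{migrants_2}, \code{mu_per_generation}, \code{L}, and a
#'   Table-style data frame \code{table} (with CI columns when supplied).
#' @export
convert_parameters <- function(theta, nu1, nu2, T, m12, m21 = m12, cal, L,
                               ci = NULL) {
  stopifnot(theta > 0, nu1 > 0, nu2 > 0, T > 0, m12 >= 0, m21 >= 0, L > 0,
            inherits(cal, "rate_calibration"))
  mu_gen <- cal$mu_per_generation
  nref <- theta / (4 * mu_gen * L)
  maps <- conv_maps(mu_gen, L, cal$gen_time, nref)
  vals <- c(nu1 = maps$nu1(nu1), nu2 = maps$nu2(nu2), T = maps$T(T),
            m1 = m12 * nu1 / 2, m2 = m21 * nu2 / 2, theta = maps$theta(theta))
  diff_units <- c(nu1 = nu1, nu2 = nu2, T = T, m1 = m12, m2 = m21,
                  theta = theta)
  tab <- data.frame(parameter = names(vals),
                    diffusion_units = unname(diff_units),
                    biological_units = unname(vals),
                    unit = c("individuals pop1", "individuals pop2", "years",
                             "migrants/generation into pop1",
                             "migrants/generation into pop2",
                             "ancestral individuals (Nref)"),
                    stringsAsFactors = FALSE)
  if (!is.null(ci)) {
    lo <- hi <- rep(NA_real_, nrow(tab))
    names(lo) <- names(hi) <- tab$parameter
    map_ci <- list(nu1 = maps$nu1, nu2 = maps$nu2, T = maps$T,
                   m1 = function(m) m * nu1 / 2,
                   m2 = function(m) m * nu2 / 2, theta = maps$theta)
    ci_in <- ci
    names(ci_in)[names(ci_in) == "m12"] <- "m1"
    names(ci_in)[names(ci_in) == "m21"] <- "m2"
    for (p in names(ci_in)) {
      ends <- sort(map_ci[[p]](ci_in[[p]]))
      lo[p] <- ends[1]; hi[p] <- ends[2]
    }
    tab$ci_lower <- unname(lo)
    tab$ci_upper <- unname(hi)
  }
  structure(list(nref = unname(vals["theta"]), n1 = unname(vals["nu1"]),
                 n2 = unname(vals["nu2"]), t_years = unname(vals["T"]),
                 migrants_1 = unname(vals["m1"]),
                 migrants_2 = unname(vals["m2"]),
                 mu_per_generation = mu_gen, L = L, table = tab),
            class = "bio_units")
}

#' @export
print.bio_units <- function(x, ...) {
  cat("bio_units (L =", x$L, "bp, mu_gen =", signif(x$mu_per_generation, 4),
      "/site/generation):\n")
  print(x$table, digits = 6)
  invisible(x)
}

#' Deduplicate a tabular alignment hit table and total its substitutions
#'
#' Standard 12-column tabular alignment output (query, subject, identity,
#' alignment length, mismatches, gap opens, query/subject coordinates,
#' E-value, bit score), CSV or TSV auto-detected. Keeps the single best hit
#' per query locus (highest bit score; ties resolved to the first row) and
#' sums alignment lengths and mismatch counts over the retained rows —
#' mismatches being the per-row substitution field of the format.
#'
#' @param x path to a hit-table file, or a data frame with at least
#'   \code{query}, \code{length}, \code{mismatches}, \code{bitscore}.
#' @return A list with \code{sites} (total aligned bp),
#'   \code{substitutions}, \code{n_loci}, and the retained \code{hits}.
#' @export
dedupe_hit_table <- function(x) {
  cols <- c("query", "subject", "identity", "length", "mismatches",
            "gapopen", "qstart", "qend", "sstart", "send", "evalue",
            "bitscore")
  if (is.character(x) && length(x) == 1) {
    first <- readLines(x, n = 1)
    sep <- if (grepl("\t", first)) "\t" else ","
    x <- read.table(x, sep = sep, header = FALSE, stringsAsFactors = FALSE)
    if (ncol(x) != length(cols))
      stop("hit table must have the 12 standard columns; found ", ncol(x))
    names(x) <- cols
  }
  x <- as.data.frame(x)
  need <- c("query", "length", "mismatches", "bitscore")
  if (!all(need %in% names(x)))
    stop("hit table needs columns: ", paste(need, collapse = ", "))
  for (cc in c("length", "mismatches", "bitscore")) {
    v <- suppressWarnings(as.numeric(x[[cc]]))
    if (anyNA(v))
      stop("malformed hit-table row(s): ",
           paste(which(is.na(v)), collapse = ", "), " (column ", cc, ")")
    x[[cc]] <- v
  }
  keep <- unlist(lapply(split(seq_len(nrow(x)), x$query), function(idx) {
    idx[which.max(x$bitscore[idx])]
  }), use.names = FALSE)
  kept <- x[sort(keep), , drop = FALSE]
  list(sites = sum(kept$length), substitutions = sum(kept$mismatches),
       n_loci = nrow(kept), hits = kept)
}
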