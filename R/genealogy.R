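#' Simulate a genealogy under a two-population divergence model
#'
#' Draws one random gene genealogy for a sample of \code{n1 + n2} haplotypes
#' under the structured coalescent for the given model: within-population
#' pairwise coalescence at rate \eqn{1/\nu_i}, lineage migration backward in
#' time at rates \eqn{m_{12}/2} and \eqn{m_{21}/2} per lineage, and a merge of
#' all remaining lineages into the ancestral population (relative size 1) at
#' time \code{T}. Growth models rescale \eqn{\nu_i(t)} exponentially between
#' the ancestral split fractions and the present-day sizes.
#'
#' Uses R's random number stream; call [set.seed()] for reproducibility.
#'
#' @param model one of [DIVERGENCE_MODELS].
#' @param params a [demographic_params()] object.
#' @param n1,n2 numbers of sampled haplotypes per population (\code{n2} may
#'   be 0 for single-population samples).
#' @return An object of class \code{genealogy}: a list with \code{parent}
#'   (1-based parent index per node, \code{NA} at the root), \code{time}
#'   (node times in units of \eqn{2 N_{ref}} generations; leaves at 0),
#'   \code{leaf_pop} (1/2 per leaf) and \code{n_leaves}. Nodes
#'   \code{1..n_leaves} are leaves; internal nodes follow in coalescence
#'   order, the root last.
#' @export
simulate_genealogy <- function(model, params = demographic_params(),
                               n1, n2) {
  stopifnot(n1 >= 0, n2 >= 0, n1 + n2 >= 2)
  ka <- model_kernel_args(model, params)
  g <- coal_genealogy_cpp(as.integer(n1), as.integer(n2),
                          ka$nu1, ka$nu2, ka$T, ka$m12, ka$m21,
                          ka$s1, ka$growth)
  parent <- g$parent + 1L
  parent[parent == 0L] <- NA_integer_
  structure(list(parent = parent, time = g$time, leaf_pop = g$leaf_pop,
                 n_leaves = as.integer(n1 + n2)),
            class = "genealogy")
}

# Branch length above each node (NA at the root).
branch_lengths <- function(g) {
  bl <- g$time[g$parent] - g$time
  bl
}

# Logical matrix [node x leaf]: which leaves descend from each node
# (a leaf descends from itself).
descendant_leaves <- function(g) {
  n_nodes <- length(g$parent)
  n <- g$n_leaves
  below <- matrix(FALSE, n_nodes, n)
  below[cbind(seq_len(n), seq_len(n))] <- TRUE
  # children precede parents in node order (merge order)
  for (node in seq_len(n_nodes)) {
    p <- g$parent[node]
    if (!is.na(p)) below[p, ] <- below[p, ] | below[node, ]
  }
  below
}

total_branch_length <- function(g) {
  sum(branch_lengths(g), na.rm = TRUE)
}

#' Drop infinite-sites mutations onto a genealogy
#'
#' Places \eqn{Poisson(\theta_{locus}/2 \times L_{tree})} mutations on the
#' genealogy, each on a branch chosen with probability proportional to its
#' length. Every mutation creates one new biallelic site whose derived allele
#' is carried by exactly the leaves below the mutated branch (infinite-sites
#' model; recurrent mutation is ignored).
#'
#' @param g a \code{genealogy} from [simulate_genealogy()].
#' @param theta_locus scaled mutation rate \eqn{4 N_{ref} \mu L} for the
#'   whole locus; must be non-negative.
#' @return An integer 0/1 matrix with one row per haplotype (leaf) and one
#'   column per segregating site (possibly zero columns).
#' @export
sprinkle_mutations <- function(g, theta_locus) {
  stopifnot(inherits(g, "genealogy"), theta_locus >= 0)
  bl <- branch_lengths(g)
  bl[is.na(bl)] <- 0
  total <- sum(bl)
  n_mut <- rpois(1L, theta_locus / 2 * total)
  n <- g$n_leaves
  if (n_mut == 0L || total == 0)
    return(matrix(0L, n, 0))
  branches <- sample.int(length(bl), n_mut, replace = TRUE, prob = bl)
  below <- descendant_leaves(g)
  haps <- matrix(0L, n, n_mut)
  for (k in seq_len(n_mut)) haps[below[branches[k], ], k] <- 1L
  haps
}
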