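# Synthetic QSPkR data with planted informative descriptors.
#
# The generator reproduces the statistical structure the award/penalty
# fitness assumes: pharmacokinetic values fall into clusters (so a
# sizable fraction of compound pairs differ by less than epsilon after
# normalization), a few "informative" descriptors are monotone
# transforms of the PK value plus noise (so their pairwise distances
# track PK distances), and the remaining descriptors are uniform
# decoys carrying no signal.

#' Specification of a synthetic QSPkR dataset
#'
#' Defaults mirror the reference study's dimensions: 39 compounds by
#' 1,481 descriptors, with a clearance-like parameter on 1-50
#' mL/min/kg.
#'
#' @param n_compounds Number of compounds (default 39).
#' @param n_descriptors Number of descriptor columns (default 1481).
#' @param n_informative Number of planted informative descriptors
#'   (default 10; may be 0 for null data).
#' @param n_clusters Number of PK clusters (default 5).  Cluster
#'   centers are evenly spaced on the unit interval, so with the
#'   default epsilon of 0.1 same-cluster pairs fall in the award
#'   branch and cross-cluster pairs in the penalty branch.
#' @param cluster_spread Within-cluster standard deviation of the
#'   latent PK value, on the unit scale (default 0.02).
#' @param noise_sd Standard deviation of the noise added to
#'   informative descriptors, on the unit scale (default 0.05).
#' @param pk_range Range `c(min, max)` of the PK parameter in original
#'   units (default `c(1, 50)`, clearance-like).
#' @param pk_name,pk_unit Name and unit recorded for the PK parameter.
#' @param epsilon Normalized PK difference below which a compound pair
#'   counts as similar; used only for the reported pair fraction
#'   (default 0.1).
#' @param seed Optional integer seed.
#' @return A validated list of class `qspkr_synth_spec`.
#' @export
synthetic_spec <- function(n_compounds = 39L,
                           n_descriptors = 1481L,
                           n_informative = 10L,
                           n_clusters = 5L,
                           cluster_spread = 0.02,
                           noise_sd = 0.05,
                           pk_range = c(1, 50),
                           pk_name = "CL",
                           pk_unit = "mL/min/kg",
                           epsilon = 0.1,
                           seed = NULL) {
  spec <- list(n_compounds = as.integer(n_compounds),
               n_descriptors = as.integer(n_descriptors),
               n_informative = as.integer(n_informative),
               n_clusters = as.integer(n_clusters),
               cluster_spread = cluster_spread, noise_sd = noise_sd,
               pk_range = pk_range, pk_name = pk_name, pk_unit = pk_unit,
               epsilon = epsilon,
               seed = if (is.null(seed)) NULL else as.integer(seed))
  stopifnot(spec$n_compounds >= 3L, spec$n_descriptors >= 1L,
            spec$n_informative >= 0L,
            spec$n_informative <= spec$n_descriptors,
            spec$n_clusters >= 1L, spec$cluster_spread >= 0,
            spec$noise_sd >= 0, length(spec$pk_range) == 2L,
            spec$pk_range[2L] > spec$pk_range[1L],
            spec$epsilon > 0, spec$epsilon < 1)
  class(spec) <- "qspkr_synth_spec"
  spec
}

# monotone links applied to the latent PK value, cycled over the
# informative descriptors so the network stage sees non-linear shapes
synth_links <- list(
  identity = function(z) z,
  square = function(z) z^2,
  logistic = function(z) 1 / (1 + exp(-6 * (z - 0.5))))

#' Generate a synthetic dataset with known ground truth
#'
#' Draws clustered PK values, plants informative descriptors as noisy
#' monotone transforms of the PK value, fills the rest with uniform
#' decoys, and min-max normalizes everything via [minmax_normalize()].
#'
#' @param spec A [synthetic_spec()].
#' @return A list of class `qspkr_synth` with elements `data` (a
#'   `qspkr_dataset`), `truth` (list: `informative` indices, `links`,
#'   `latent` pre-noise PK values on the unit scale,
#'   `fraction_within_epsilon`), and `raw` (the un-normalized
#'   `qspkr_raw` descriptor and PK tables, e.g. for CSV export).
#' @export
generate_dataset <- function(spec = synthetic_spec()) {
  stopifnot(inherits(spec, "qspkr_synth_spec"))
  if (!is.null(spec$seed)) set.seed(spec$seed)
  n <- spec$n_compounds; D <- spec$n_descriptors
  centers <- if (spec$n_clusters == 1L) 0.5
             else seq(0.06, 0.94, length.out = spec$n_clusters)
  assignment <- sample(rep_len(seq_len(spec$n_clusters), n))
  latent <- centers[assignment] + stats::rnorm(n, 0, spec$cluster_spread)
  pk <- spec$pk_range[1L] + latent * diff(spec$pk_range)

  X <- matrix(stats::runif(n * D), n, D)
  informative <- if (spec$n_informative > 0L)
    sort(sample.int(D, spec$n_informative)) else integer(0)
  link_names <- character(0)
  for (m in seq_along(informative)) {
    ln <- names(synth_links)[(m - 1L) %% length(synth_links) + 1L]
    link_names <- c(link_names, ln)
    X[, informative[m]] <- synth_links[[ln]](latent) +
      stats::rnorm(n, 0, spec$noise_sd)
  }

  ids <- sprintf("compound_%02d", seq_len(n))
  raw_x <- new_qspkr_raw(ids, sprintf("desc_%04d", seq_len(D)), X)
  raw_pk <- new_qspkr_raw(ids, spec$pk_name, matrix(pk, ncol = 1L))
  attr(raw_pk, "unit") <- spec$pk_unit
  data <- minmax_normalize(raw_x, raw_pk)

  pr <- pair_index(data$dp, spec$epsilon)
  frac <- mean(pr$award)
  if (frac == 0)
    stop("no compound pair falls within epsilon after normalization; ",
         "increase cluster_spread/cluster sizes or reduce n_clusters")
  structure(list(data = data,
                 truth = list(informative = informative,
                              links = link_names,
                              latent = latent,
                              fraction_within_epsilon = frac),
                 raw = list(descriptors = raw_x, pk = raw_pk),
                 spec = spec),
            class = "qspkr_synth")
}

#' @export
print.qspkr_synth <- function(x, ...) {
  cat(sprintf(
    "<qspkr_synth> %d compounds x %d descriptors, %d informative, %.1f%% of pairs within epsilon\n",
    nrow(x$data$X), ncol(x$data$X), length(x$truth$informative),
    100 * x$truth$fraction_within_epsilon))
  invisible(x)
}

#' Full-scale synthetic benchmark dataset
#'
#' Convenience wrapper: [generate_dataset()] with the default
#' specification (39 compounds by 1,481 descriptors, 10 informative)
#' and the given seed.
#'
#' @param seed Integer seed.
#' @return A `qspkr_synth` list; see [generate_dataset()].
#' @export
synthetic_benchmark <- function(seed = 1L) {
  generate_dataset(synthetic_spec(seed = seed))
}
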