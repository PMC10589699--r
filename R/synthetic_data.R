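#' Configuration for synthetic paired-embedding worlds
#'
#' The generator emulates the statistical premise of cross-modal alignment:
#' two embedding systems over a shared vocabulary whose interconcept
#' similarity structures mirror each other up to controllable noise, plus an
#' acquisition table in which concepts with dense similarity neighborhoods
#' tend (controllably) to be acquired earlier.
#'
#' Concepts live in a latent space as a mixture of `n_clusters` Gaussians;
#' each modality observes the latents through an independent random
#' orthonormal map (distance-preserving, so at `alignment_noise = 0` the two
#' systems are exactly second-order isomorphic) plus iid Gaussian coordinate
#' noise of scale `alignment_noise`.
#'
#' @param n_concepts vocabulary size (>= 2).
#' @param dim_visual,dim_linguistic embedding dimensions (defaults 10 and 50,
#'   the usual sizes for scene-co-occurrence and GloVe-6B spaces).
#' @param latent_dim latent dimension; default `min(dim_visual, dim_linguistic)`.
#' @param n_clusters number of planted clusters.
#' @param cluster_spread within-cluster coordinate SD (sets the density scale).
#' @param cluster_sep SD of cluster centers around the origin.
#' @param alignment_noise sigma of modality-specific coordinate noise; 0
#'   yields perfectly mirrored systems.
#' @param noise_density_link gamma >= 0: per-concept noise scale is
#'   `alignment_noise * exp(-gamma * density)` (density standardized), so
#'   concepts in dense neighborhoods have more stable positions across
#'   modalities — the stability gradient that makes dense knowledge states
#'   better aligners. 0 gives homoscedastic noise.
#' @param density_bias beta >= 0: strength of the preference for dense
#'   concepts to enter the AoA subset and to be acquired early; 0 removes
#'   any density-acquisition link.
#' @param months month labels for the acquisition table.
#' @param n_aoa size of the AoA concept subset; default `round(n_concepts / 3)`
#'   (mirroring the roughly one-third AoA share of typical
#'   embedding-intersection vocabularies).
#' @param ramp_width width (months) of the logistic acquisition ramp.
#' @param seed integer seed.
#' @return A list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_concepts, n_clusters = 3,
                             dim_visual = 10, dim_linguistic = 50,
                             latent_dim = NULL,
                             cluster_spread = 1, cluster_sep = 3,
                             alignment_noise = 0, density_bias = 0,
                             noise_density_link = 0.5,
                             months = 16:24, n_aoa = NULL,
                             ramp_width = 1.5, seed = 1) {
  latent_dim <- latent_dim %||% min(dim_visual, dim_linguistic)
  n_aoa <- n_aoa %||% max(4L, round(n_concepts / 3))
  stopifnot(n_concepts >= 2, n_clusters >= 1, latent_dim <= min(dim_visual, dim_linguistic),
            alignment_noise >= 0, density_bias >= 0, noise_density_link >= 0,
            n_aoa <= n_concepts)
  if (n_clusters > n_concepts) stop("more clusters than concepts")
  structure(list(n_concepts = n_concepts, n_clusters = n_clusters,
                 dim_visual = dim_visual, dim_linguistic = dim_linguistic,
                 latent_dim = latent_dim, cluster_spread = cluster_spread,
                 cluster_sep = cluster_sep, alignment_noise = alignment_noise,
                 density_bias = density_bias,
                 noise_density_link = noise_density_link,
                 months = as.integer(months),
                 n_aoa = as.integer(n_aoa), ramp_width = ramp_width,
                 seed = as.integer(seed)),
            class = "synthetic_config")
}

# Random matrix with orthonormal columns (latent_dim of them) in dim rows.
random_orthonormal_map <- function(dim, latent_dim) {
  q <- qr.Q(qr(matrix(stats::rnorm(dim * latent_dim), dim, latent_dim)))
  q[, seq_len(latent_dim), drop = FALSE]
}

#' Generate a pair of mirrored embedding systems with planted clusters
#'
#' @param config a [synthetic_config()].
#' @param seed overrides `config$seed` when given.
#' @return A list: `pair` (a [intersect_systems()]-style `system_pair`) and
#'   `truth` with latent positions, cluster assignments and per-concept
#'   density scores (standardized negative mean distance to the nearest
#'   10 percent of latent neighbors).
#' @export
generate_paired_systems <- function(config, seed = NULL) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(seed %||% config$seed)
  n <- config$n_concepts
  concepts <- sprintf("c%03d", seq_len(n))
  centers <- matrix(stats::rnorm(config$n_clusters * config$latent_dim,
                                 sd = config$cluster_sep),
                    config$n_clusters, config$latent_dim)
  cl <- sort(rep_len(seq_len(config$n_clusters), n))
  latent <- centers[cl, , drop = FALSE] +
    matrix(stats::rnorm(n * config$latent_dim, sd = config$cluster_spread),
           n, config$latent_dim)

  dl <- as.matrix(stats::dist(latent))
  k <- max(2L, ceiling(0.1 * (n - 1)))
  density <- -apply(dl, 1, function(r) mean(sort(r[-which.min(r)])[seq_len(k)]))
  density <- as.numeric(scale(density))
  # stability gradient: dense concepts sit in lower-noise neighborhoods
  noise_sd <- config$alignment_noise * exp(-config$noise_density_link * density)

  make_sys <- function(dim, modality) {
    q <- random_orthonormal_map(dim, config$latent_dim)
    coords <- latent %*% t(q)
    if (config$alignment_noise > 0) {
      coords <- coords + matrix(stats::rnorm(n * dim, sd = noise_sd), n, dim)
    }
    embedding_system(coords, concepts, modality)
  }
  visual <- make_sys(config$dim_visual, "visual")
  linguistic <- make_sys(config$dim_linguistic, "linguistic")
  list(pair = intersect_systems(visual, linguistic),
       truth = list(latent = latent, clusters = cl, density = density,
                    concepts = concepts))
}

#' Generate a density-biased synthetic acquisition table
#'
#' Selects an AoA subset of the vocabulary and assigns each AoA concept an
#' acquisition-onset month. Both the subset membership and the onset order
#' are biased toward dense concepts with strength `density_bias` (log-odds
#' proportional to `density_bias * density`); `density_bias = 0` gives
#' density-independent, uniform acquisition. Cumulative monthly
#' probabilities follow a logistic ramp centered on each concept's onset, so
#' the table is monotone by construction.
#'
#' @param pair a `system_pair` (used for its vocabulary).
#' @param truth the `truth` element of [generate_paired_systems()].
#' @param config a [synthetic_config()].
#' @param seed overrides `config$seed + 1` when given.
#' @return A list: `table` (an [acquisition_table()] over the AoA subset)
#'   and `truth` extended with `aoa_concepts` and per-AoA-concept `onset`.
#' @export
generate_acquisition_table <- function(pair, truth, config, seed = NULL) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(seed %||% (config$seed + 1L))
  concepts <- pair$shared_concepts
  z <- truth$density[match(concepts, truth$concepts)]
  beta <- config$density_bias
  w <- exp(beta * z - max(beta * z))
  aoa <- sample(concepts, config$n_aoa, prob = w)
  # Gumbel-noised utilities: beta = 0 gives a uniformly random onset order.
  gumbel <- -log(-log(stats::runif(length(aoa))))
  util <- beta * z[match(aoa, concepts)] + gumbel
  onset_grid <- seq(min(config$months) - 1, max(config$months) + 2,
                    length.out = length(aoa))
  onset <- onset_grid[rank(-util, ties.method = "first")]
  probs <- t(vapply(onset, function(o) {
    stats::plogis((config$months - o) / config$ramp_width)
  }, numeric(length(config$months))))
  table <- acquisition_table(probs, aoa, config$months)
  truth$aoa_concepts <- aoa
  truth$onset <- stats::setNames(onset, aoa)
  list(table = table, truth = truth)
}

#' Generate a complete synthetic world
#'
#' Runs [generate_paired_systems()] and [generate_acquisition_table()] and
#' bundles the result with cached distance matrices via [build_world()].
#'
#' @param config a [synthetic_config()].
#' @param metric distance metric for the cached matrices.
#' @return An object of class `synthetic_world`: `world` (see
#'   [build_world()]), `truth`, `config`.
#' @export
generate_world <- function(config, metric = "euclidean") {
  sys <- generate_paired_systems(config)
  acq <- generate_acquisition_table(sys$pair, sys$truth, config)
  structure(list(world = build_world(sys$pair, acq$table, metric),
                 truth = acq$truth, config = config),
            class = "synthetic_world")
}

#' Registered deterministic test worlds
#'
#' Small, bitwise-stable fixtures used across the test suite:
#' \describe{
#'   \item{mirror10}{10 concepts, 2 clusters, zero alignment noise: the two
#'     systems are exactly second-order isomorphic, so forced choice is
#'     always correct.}
#'   \item{noisy30}{30 concepts, 3 clusters, moderate noise, mild density
#'     bias.}
#'   \item{planted60}{60 concepts, 4 clusters, moderate noise, strong
#'     density bias (beta = 5): AoA-subset concepts have dense neighborhoods
#'     and are acquired early.}
#' }
#'
#' @param name fixture name.
#' @return A `synthetic_world` (see [generate_world()]).
#' @export
make_fixture <- function(name = c("mirror10", "noisy30", "planted60")) {
  name <- match.arg(name)
  config <- switch(name,
    mirror10 = synthetic_config(10, n_clusters = 2, alignment_noise = 0,
                                density_bias = 0, n_aoa = 4, seed = 101),
    noisy30 = synthetic_config(30, n_clusters = 3, alignment_noise = 1.2,
                               density_bias = 2, n_aoa = 10, seed = 202),
    planted60 = synthetic_config(60, n_clusters = 4, alignment_noise = 2,
                                 density_bias = 5, noise_density_link = 1,
                                 n_aoa = 20, seed = 303)
  )
  generate_world(config)
}

#' Write a synthetic world to disk as plain-text files
#'
#' Emits the two embedding files (GloVe text dialect), the acquisition CSV
#' and a JSON file with the latent truth, into `dir`.
#'
#' @param sw a `synthetic_world`.
#' @param dir output directory (created if missing).
#' @return Invisibly, the named vector of written paths.
#' @export
write_world <- function(sw, dir) {
  stopifnot(inherits(sw, "synthetic_world"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(
    visual = file.path(dir, "visual_embeddings.txt"),
    linguistic = file.path(dir, "linguistic_embeddings.txt"),
    aoa = file.path(dir, "aoa_table.csv"),
    truth = file.path(dir, "truth.json")
  )
  write_embeddings(sw$world$pair$visual, paths["visual"])
  write_embeddings(sw$world$pair$linguistic, paths["linguistic"])
  write_acquisition_table(sw$world$table, paths["aoa"])
  jsonlite::write_json(
    list(clusters = sw$truth$clusters, density = sw$truth$density,
         concepts = sw$truth$concepts, aoa_concepts = sw$truth$aoa_concepts,
         onset = as.list(sw$truth$onset)),
    paths["truth"], auto_unbox = TRUE, digits = NA)
  invisible(paths)
}
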