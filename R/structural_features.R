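#' Build the semantic neighborhood graph of a system
#'
#' Nodes are concepts; an edge is kept only where the interconcept distance
#' is strictly below the given percentile (default 10th) of all
#' upper-triangle distances (linear-interpolation percentile). The graph may
#' be disconnected.
#'
#' @param dist a [pairwise_distances()] matrix.
#' @param percentile percentile in (0, 100).
#' @return An object of class `neighbor_graph`: `graph` (an
#'   \pkg{igraph} graph with concept-named vertices), `threshold`,
#'   `percentile`.
#' @export
build_neighbor_graph <- function(dist, percentile = 10) {
  stopifnot(percentile > 0, percentile < 100, nrow(dist) >= 2)
  d <- unclass(dist)
  ut <- upper_tri_vec(d)
  threshold <- unname(stats::quantile(ut, percentile / 100, type = 7))
  adj <- (d < threshold) * 1
  diag(adj) <- 0
  if (sum(adj) == 0) warning("neighbor graph has zero edges (all distances at or above threshold)")
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  structure(list(graph = g, threshold = threshold, percentile = percentile,
                 adjacency = adj),
            class = "neighbor_graph")
}

#' @export
print.neighbor_graph <- function(x, ...) {
  cat(sprintf("<neighbor_graph: %d nodes, %d edges, threshold %.4g (p%g)>\n",
              igraph::vcount(x$graph), igraph::ecount(x$graph),
              x$threshold, x$percentile))
  invisible(x)
}

# Per-world cache of everything the feature extractors need: distance
# matrices, neighbor-graph adjacency and full-system coordinate ranges for
# each configured modality. Feature computation inside generative training
# is hot, so everything downstream works on integer indices into this cache.
feature_cache <- function(world, percentile = 10,
                          modality = c("mean", "linguistic", "visual", "both")) {
  stopifnot(inherits(world, "world"))
  modality <- match.arg(modality)
  mods <- switch(modality, mean = c("visual", "linguistic"),
                 both = c("visual", "linguistic"), linguistic = "linguistic",
                 visual = "visual")
  d <- list(visual = unclass(world$dvis), linguistic = unclass(world$dlin))[mods]
  adj <- lapply(d, function(m) build_neighbor_graph(m, percentile)$adjacency)
  ranges <- lapply(mods, function(mo) {
    v <- world$pair[[mo]]$vectors
    apply(v, 2, range)
  })
  names(ranges) <- mods
  vecs <- lapply(mods, function(mo) world$pair[[mo]]$vectors)
  names(vecs) <- mods
  list(concepts = world$pair$shared_concepts, modality = modality, mods = mods,
       d = d, adj = adj, ranges = ranges, vectors = vecs,
       percentile = percentile)
}

state_feature_names <- c("degree_knowledge", "degree_full",
                         "mean_dist_knowledge", "coverage",
                         "min_dist_knowledge", "min_dist_full",
                         "skew_degree_knowledge")

# Adjusted Fisher-Pearson sample skewness; 0 for (near-)constant vectors.
sample_skewness <- function(x) {
  if (length(x) < 3 || stats::sd(x) == 0) return(0)
  e1071::skewness(x, type = 2)
}

# Core per-state computation over index vectors, one modality.
state_features_one <- function(cache, mod, idx) {
  d <- cache$d[[mod]]
  adj <- cache$adj[[mod]]
  sub_adj <- adj[idx, idx, drop = FALSE]
  sub_d <- d[idx, idx, drop = FALSE]
  diag(sub_d) <- Inf
  deg_know <- rowSums(sub_adj)
  deg_full <- rowSums(adj[idx, , drop = FALSE])
  dfull <- d[idx, , drop = FALSE]
  dfull[cbind(seq_along(idx), idx)] <- Inf
  rng_full <- cache$ranges[[mod]]
  span_full <- rng_full[2, ] - rng_full[1, ]
  keep <- span_full > 0
  if (!any(keep)) stop("all embedding dimensions have zero range")
  v <- cache$vectors[[mod]][idx, keep, drop = FALSE]
  span_state <- apply(v, 2, max) - apply(v, 2, min)
  c(degree_knowledge = mean(deg_know),
    degree_full = mean(deg_full),
    mean_dist_knowledge = mean(sub_d[is.finite(sub_d)]),
    coverage = mean(span_state / span_full[keep]),
    min_dist_knowledge = mean(apply(sub_d, 1, min)),
    min_dist_full = mean(apply(dfull, 1, min)),
    skew_degree_knowledge = sample_skewness(deg_know))
}

#' Structural features of a single concept
#'
#' Degree and distance features of one concept, computed with respect to the
#' full system and to the current knowledge state, per modality and averaged
#' across modalities by default. The neighbor-graph threshold is always the
#' full-system threshold; "knowledge" degrees count sub-threshold neighbors
#' that are state members.
#'
#' @param concept a concept label.
#' @param state character vector of knowledge-state concepts (nonempty for
#'   the `knowledge` features; may contain `concept`, which is excluded from
#'   its own reference set).
#' @param world a [build_world()] world.
#' @param percentile neighbor-graph percentile.
#' @param modality `"mean"` (average of visual and linguistic, the default),
#'   one modality, or `"both"` (suffixed features per modality).
#' @return Named numeric vector: `degree_full`, `degree_knowledge`,
#'   `min_dist_full`, `mean_dist_full`, `min_dist_knowledge`,
#'   `mean_dist_knowledge` (suffixed by modality when `modality = "both"`).
#' @export
concept_features <- function(concept, state, world, percentile = 10,
                             modality = "mean") {
  cache <- feature_cache(world, percentile, modality)
  ci <- match(concept, cache$concepts)
  if (is.na(ci)) stop("concept not in system: ", concept)
  ref <- setdiff(match(state, cache$concepts), ci)
  if (anyNA(ref)) stop("state concept outside shared vocabulary")
  if (length(ref) == 0) stop("undefined knowledge features: empty reference set")
  one <- function(mod) {
    d <- cache$d[[mod]]; adj <- cache$adj[[mod]]
    others <- setdiff(seq_along(cache$concepts), ci)
    c(degree_full = sum(adj[ci, ]),
      degree_knowledge = sum(adj[ci, ref]),
      min_dist_full = min(d[ci, others]),
      mean_dist_full = mean(d[ci, others]),
      min_dist_knowledge = min(d[ci, ref]),
      mean_dist_knowledge = mean(d[ci, ref]))
  }
  vals <- vapply(cache$mods, one, numeric(6))
  if (cache$modality == "both") {
    out <- as.numeric(vals)
    names(out) <- as.vector(outer(rownames(vals), colnames(vals), paste, sep = "_"))
    out
  } else {
    rowMeans(vals)
  }
}

#' Structural feature vector of a knowledge state
#'
#' Aggregates concept-level degree and distance features over the state
#' (means of concept-wise values), plus two whole-state features: the mean
#' dimension coverage (per-dimension coordinate range spanned by the state
#' divided by the full-system range, averaged over dimensions and
#' modalities) and the adjusted Fisher-Pearson skewness of the within-state
#' degree distribution.
#'
#' @param state character vector of concepts, length >= 3.
#' @param world a [build_world()] world.
#' @param percentile neighbor-graph percentile.
#' @param modality see [concept_features()].
#' @param cache optional precomputed internal cache (used by the trainers).
#' @return Named numeric vector of 7 features (14 when `modality = "both"`):
#'   `degree_knowledge`, `degree_full`, `mean_dist_knowledge`, `coverage`,
#'   `min_dist_knowledge`, `min_dist_full`, `skew_degree_knowledge`.
#' @export
state_features <- function(state, world, percentile = 10, modality = "mean",
                           cache = NULL) {
  cache <- cache %||% feature_cache(world, percentile, modality)
  idx <- match(state, cache$concepts)
  if (anyNA(idx)) stop("state concept outside shared vocabulary")
  if (length(idx) < 3) stop("state_features needs at least 3 concepts")
  vals <- vapply(cache$mods, function(mod) state_features_one(cache, mod, idx),
                 numeric(length(state_feature_names)))
  if (cache$modality == "both") {
    out <- as.numeric(vals)
    names(out) <- as.vector(outer(rownames(vals), colnames(vals), paste, sep = "_"))
    out
  } else {
    rowMeans(vals)
  }
}

#' Feature matrix for a set of knowledge-state samples
#'
#' @param states list of character vectors (knowledge states).
#' @param world a [build_world()] world.
#' @inheritParams state_features
#' @return Numeric matrix, one row per state.
#' @export
state_feature_matrix <- function(states, world, percentile = 10,
                                 modality = "mean") {
  cache <- feature_cache(world, percentile, modality)
  t(vapply(states, function(s) state_features(s, world, cache = cache),
           state_features(states[[1]], world, cache = cache) * 0))
}

min_max_fit <- function(x) list(min = apply(x, 2, min), max = apply(x, 2, max))
min_max_apply <- function(x, f) {
  span <- pmax(f$max - f$min, .Machine$double.eps)
  z <- sweep(sweep(x, 2, f$min), 2, span, "/")
  pmin(pmax(z, 0), 1)
}

glmnet_logistic <- function(x, y, lambda) {
  pad <- ncol(x) == 1
  if (pad) x <- cbind(x, `.pad` = 0)
  fit <- glmnet::glmnet(x, y, family = "binomial", alpha = 0,
                        lambda = lambda, maxit = 10000,
                        standardize = FALSE)
  beta <- as.numeric(fit$beta)
  names(beta) <- rownames(fit$beta)
  if (pad) beta <- beta[names(beta) != ".pad"]
  list(fit = fit, beta = beta, a0 = as.numeric(fit$a0),
       deviance = (1 - fit$dev.ratio) * fit$nulldev, pad = pad)
}

glmnet_predict <- function(model, x) {
  if (model$pad) x <- cbind(x, `.pad` = 0)
  as.numeric(stats::predict(model$fit, newx = x, type = "response"))
}

#' Classify knowledge states as AoA-like vs control
#'
#' Fits an L2-penalized logistic regression (ridge, max 10,000 iterations)
#' on min-max normalized features (normalization fitted on the training
#' split only), with recursive feature elimination: features are dropped one
#' at a time by smallest absolute coefficient, each feature-set size k is
#' scored by its training AIC (deviance + 2(k + 1)), and the AIC-minimizing
#' k is selected. Held-out metrics are reported for the selected model.
#'
#' @param features numeric matrix, one row per knowledge-state sample.
#' @param labels factor or character: `"aoa"` (positive class) or
#'   `"control"`.
#' @param train_frac training fraction (default 0.8).
#' @param lambda fixed ridge penalty.
#' @param seed split seed.
#' @return An object of class `classifier_report`: `selected_features`,
#'   `betas`, `intercept`, `k`, `accuracy`, `precision`, `recall`, `f1`,
#'   `aic_by_k` and the fitted `normalizer`.
#' @export
classify_states <- function(features, labels, train_frac = 0.8,
                            lambda = 1e-3, seed = 1) {
  features <- as.matrix(features)
  labels <- as.character(labels)
  stopifnot(nrow(features) == length(labels),
            all(labels %in% c("aoa", "control")))
  if (length(unique(labels)) < 2 || min(table(labels)) < 10) {
    stop("need at least 10 samples per class")
  }
  y <- as.integer(labels == "aoa")
  set.seed(as.integer(seed))
  n <- nrow(features)
  train <- sort(sample.int(n, max(2, floor(train_frac * n))))
  test <- setdiff(seq_len(n), train)
  if (length(unique(y[train])) < 2 || length(unique(y[test])) < 2) {
    stop("train/test split lost a class; supply more samples")
  }
  normalizer <- min_max_fit(features[train, , drop = FALSE])
  xtr <- min_max_apply(features[train, , drop = FALSE], normalizer)
  xte <- min_max_apply(features[test, , drop = FALSE], normalizer)

  active <- colnames(features) %||% paste0("f", seq_len(ncol(features)))
  colnames(xtr) <- colnames(xte) <- active
  path <- list()
  while (length(active) >= 1) {
    m <- glmnet_logistic(xtr[, active, drop = FALSE], y[train], lambda)
    k <- length(active)
    path[[as.character(k)]] <- list(features = active, model = m,
                                    aic = m$deviance + 2 * (k + 1))
    if (k == 1) break
    active <- active[-which.min(abs(m$beta))]
  }
  aic_by_k <- vapply(path, `[[`, numeric(1), "aic")
  best <- path[[which.min(aic_by_k)]]
  prob <- glmnet_predict(best$model, xte[, best$features, drop = FALSE])
  pred <- as.integer(prob >= 0.5)
  tp <- sum(pred == 1 & y[test] == 1); fp <- sum(pred == 1 & y[test] == 0)
  fn <- sum(pred == 0 & y[test] == 1)
  precision <- if (tp + fp > 0) tp / (tp + fp) else 0
  recall <- if (tp + fn > 0) tp / (tp + fn) else 0
  f1 <- if (precision + recall > 0) 2 * precision * recall / (precision + recall) else 0
  structure(list(selected_features = best$features, betas = best$model$beta,
                 intercept = best$model$a0, k = length(best$features),
                 accuracy = mean(pred == y[test]), precision = precision,
                 recall = recall, f1 = f1,
                 aic_by_k = aic_by_k, normalizer = normalizer),
            class = "classifier_report")
}

#' @export
print.classifier_report <- function(x, ...) {
  cat(sprintf("<classifier_report: k=%d, accuracy %.3f, precision %.3f, recall %.3f, f1 %.3f>\n",
              x$k, x$accuracy, x$precision, x$recall, x$f1))
  print(round(x$betas, 3))
  invisible(x)
}
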