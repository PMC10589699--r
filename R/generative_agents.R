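#' Configuration for generative structural agents
#'
#' Default hyperparameters: softmax temperature
#' 5e-2, 150 epochs, 5 restarts, Adam with learning rate 0.003
#' (AoA-Matched) or 0.01 (Task-Optimized), a 300-concept candidate set,
#' 59 held-out concepts each for the training and validation slates with
#' 750 probe pairs per slate, and 5,000 normalizer samples per month. For
#' vocabularies smaller than the 418-concept reference, the candidate,
#' held-out and slate sizes scale proportionally (`n` / 418, pairs by the
#' squared held-out ratio), with floors keeping them usable.
#'
#' @param kind `"aoa_matched"` (match bootstrapped acquisition
#'   probabilities) or `"task_optimized"` (minimize the soft alignment
#'   loss).
#' @param n_vocab vocabulary size of the world the agent will be trained on.
#' @param temperature softmax temperature T.
#' @param epochs,restarts training epochs and model restarts.
#' @param learning_rate Adam step size; default depends on `kind`.
#' @param n_candidates candidate-set size n_c.
#' @param n_heldout held-out concepts per slate (task kind).
#' @param pairs_per_slate probe pairs per slate (task kind).
#' @param n_norm_samples Monte-Carlo samples per month for loss
#'   normalization.
#' @param features structural features the internal model is defined over.
#' @param percentile neighbor-graph percentile for the features.
#' @param modality feature modality handling (see [state_features()]).
#' @param seed master seed.
#' @return A list of class `generative_config`.
#' @export
generative_config <- function(kind = c("aoa_matched", "task_optimized"),
                              n_vocab = 418,
                              temperature = 5e-2, epochs = 150, restarts = 5,
                              learning_rate = NULL,
                              n_candidates = NULL, n_heldout = NULL,
                              pairs_per_slate = NULL,
                              n_norm_samples = 5000,
                              features = state_feature_names,
                              percentile = 10, modality = "mean", seed = 1) {
  kind <- match.arg(kind)
  scale <- n_vocab / 418
  n_heldout <- n_heldout %||% max(4L, round(59 * scale))
  cap <- if (kind == "task_optimized") n_vocab - 2L * n_heldout else n_vocab
  n_candidates <- n_candidates %||% min(cap, max(10L, round(300 * scale)))
  # use every available pair when the held-out set offers fewer than the
  # reference 750, rather than subsampling and adding slate variance
  pairs_per_slate <- pairs_per_slate %||%
    min(choose(n_heldout, 2), 750L)
  learning_rate <- learning_rate %||% switch(kind, aoa_matched = 0.003,
                                             task_optimized = 0.01)
  stopifnot(temperature > 0, epochs >= 1, restarts >= 1,
            n_candidates + 2 * n_heldout <= n_vocab || kind == "aoa_matched",
            all(features %in% state_feature_names))
  structure(list(kind = kind, n_vocab = as.integer(n_vocab),
                 temperature = temperature, epochs = as.integer(epochs),
                 restarts = as.integer(restarts),
                 learning_rate = learning_rate,
                 n_candidates = as.integer(n_candidates),
                 n_heldout = as.integer(n_heldout),
                 pairs_per_slate = as.integer(pairs_per_slate),
                 n_norm_samples = as.integer(n_norm_samples),
                 features = features, percentile = percentile,
                 modality = modality, seed = as.integer(seed)),
            class = "generative_config")
}

# ---- fast augmented-state features ----------------------------------------

# Extend a feature cache with per-concept aggregates used by the hot path.
training_cache <- function(world, percentile = 10, modality = "mean") {
  cache <- feature_cache(world, percentile, modality)
  cache$degfull <- lapply(cache$adj, rowSums)
  cache$minfull <- lapply(cache$d, function(d) {
    dd <- d; diag(dd) <- Inf; apply(dd, 1, min)
  })
  cache
}

# Feature matrix A: row i = structural features of state + candidate i.
# Incremental vectorized computation; must agree with state_features() on
# the same augmented states (property-tested).
augmented_feature_matrix <- function(cache, state_idx, cand_idx) {
  s <- length(state_idx)
  stopifnot(s >= 2)
  nf <- length(state_feature_names)
  per_mod <- lapply(cache$mods, function(mod) {
    d <- cache$d[[mod]]; adj <- cache$adj[[mod]]
    degfull <- cache$degfull[[mod]]; minfull <- cache$minfull[[mod]]
    v <- cache$vectors[[mod]]
    sub_adj <- adj[state_idx, state_idx, drop = FALSE]
    sub_d <- d[state_idx, state_idx, drop = FALSE]
    diag(sub_d) <- Inf
    degS <- rowSums(sub_adj)
    minS <- apply(sub_d, 1, min)
    SD <- sum(sub_d[is.finite(sub_d)])
    ki <- as.numeric(adj[cand_idx, state_idx, drop = FALSE] %*% rep(1, s))
    dci <- d[cand_idx, state_idx, drop = FALSE]
    si <- rowSums(dci)
    rng <- cache$ranges[[mod]]
    span_full <- rng[2, ] - rng[1, ]
    keep <- span_full > 0
    vs <- v[state_idx, keep, drop = FALSE]
    maxS <- apply(vs, 2, max); minSv <- apply(vs, 2, min)
    vc <- v[cand_idx, keep, drop = FALSE]
    newmax <- t(pmax(t(vc), maxS))  # per-candidate dimension maxima
    newmin <- t(pmin(t(vc), minSv))
    coverage <- rowMeans(sweep(newmax - newmin, 2, span_full[keep], "/"))

    n_cand <- length(cand_idx)
    out <- matrix(0, n_cand, nf, dimnames = list(NULL, state_feature_names))
    out[, "degree_full"] <- (sum(degfull[state_idx]) + degfull[cand_idx]) / (s + 1)
    out[, "degree_knowledge"] <- (sum(degS) + 2 * ki) / (s + 1)
    out[, "mean_dist_knowledge"] <- (SD + 2 * si) / ((s + 1) * s)
    out[, "coverage"] <- coverage
    out[, "min_dist_full"] <- (sum(minfull[state_idx]) + minfull[cand_idx]) / (s + 1)
    for (r in seq_len(n_cand)) {
      drow <- dci[r, ]
      out[r, "min_dist_knowledge"] <- (sum(pmin(minS, drow)) + min(drow)) / (s + 1)
      out[r, "skew_degree_knowledge"] <-
        sample_skewness(c(degS + adj[state_idx, cand_idx[r]], ki[r]))
    }
    out
  })
  Reduce(`+`, per_mod) / length(per_mod)
}

#' Fit the min-max feature normalizer for a world
#'
#' The internal model lives in normalized feature space; the normalizer is
#' fitted once per world on the features of uniformly sampled random
#' knowledge states with sizes spanning the schedule, then frozen.
#'
#' @param world a [build_world()] world.
#' @param schedule a [month_schedule()].
#' @param n_states number of random states to sample.
#' @param percentile,modality feature settings.
#' @param seed integer seed.
#' @return A normalizer (list with `min` and `max` per feature).
#' @export
fit_feature_normalizer <- function(world, schedule, n_states = 200,
                                   percentile = 10, modality = "mean",
                                   seed = 1) {
  set.seed(as.integer(seed))
  vocab <- world$pair$shared_concepts
  sizes <- sample(pmax(3, schedule$N_m), n_states, replace = TRUE)
  states <- lapply(sizes, function(k) sample(vocab, min(k, length(vocab))))
  x <- state_feature_matrix(states, world, percentile, modality)
  min_max_fit(x)
}

# Normalize and subset an augmented feature matrix for the internal model.
model_feature_matrix <- function(A_raw, fnorm, features) {
  A <- min_max_apply(A_raw, fnorm)
  A[, features, drop = FALSE]
}

#' Generative scores of candidate concepts under an internal model
#'
#' For each candidate, the normalized structural features of the knowledge
#' state augmented with that candidate are compared against the model's
#' target values: `s = -|A - x_hat| %*% w`. Higher scores mean the
#' augmented state sits closer to the target under the feature weighting.
#'
#' @param candidates character vector of candidate concepts.
#' @param state current knowledge state (>= 2 concepts).
#' @param model an `internal_model` (see [train_agent()]).
#' @param world a [build_world()] world.
#' @return Named numeric score vector.
#' @export
generative_scores <- function(candidates, state, model, world) {
  stopifnot(inherits(model, "internal_model"))
  cache <- training_cache(world, model$percentile, model$modality)
  state_idx <- match(state, cache$concepts)
  cand_idx <- match(candidates, cache$concepts)
  if (anyNA(c(state_idx, cand_idx))) stop("concept outside shared vocabulary")
  A <- model_feature_matrix(
    augmented_feature_matrix(cache, state_idx, cand_idx),
    model$feature_normalizer, model$feature_names)
  s <- as.numeric(-abs(sweep(A, 2, model$x_hat)) %*% model$w)
  stats::setNames(s, candidates)
}

#' Softmax selection distribution over candidate scores
#'
#' Scores are standardized to zero mean and unit variance within the
#' candidate set (so the temperature is meaningful across worlds of
#' different scales) and passed through a temperature softmax. Constant
#' score vectors yield the uniform distribution.
#'
#' @param scores numeric score vector.
#' @param temperature softmax temperature T > 0.
#' @param standardize standardize scores before the softmax (the default);
#'   `FALSE` applies the softmax to raw scores divided by T.
#' @return Probability vector summing to 1.
#' @export
candidate_distribution <- function(scores, temperature = 5e-2,
                                   standardize = TRUE) {
  stopifnot(temperature > 0, all(is.finite(scores)))
  n <- length(scores)
  if (n == 1) return(stats::setNames(1, names(scores)))
  z <- scores
  if (standardize) {
    sdv <- stats::sd(scores)
    z <- if (sdv > 0) (scores - mean(scores)) / sdv else rep(0, n)
  }
  stats::setNames(softmax(z / temperature), names(scores))
}

# Forward pass from raw model parameters to the inclusion-probability vector
# p over the candidate set (1 for acquired concepts, softmax mass for the
# rest), keeping what the backward pass needs.
forward_inclusion <- function(x_hat, w, A, acquired, temperature) {
  dmat <- sweep(A, 2, x_hat)
  s <- as.numeric(-abs(dmat) %*% w)
  un <- which(!acquired)
  p <- rep(1, nrow(A))
  fw <- list(dmat = dmat, s = s, un = un, acquired = acquired,
             temperature = temperature, A = A)
  if (length(un) >= 2) {
    su <- s[un]
    m <- mean(su); sdv <- stats::sd(su)
    z <- if (sdv > 0) (su - m) / sdv else rep(0, length(su))
    q <- softmax(z / temperature)
    p[un] <- q
    fw <- c(fw, list(su = su, m = m, sdv = sdv, z = z, q = q))
  } else if (length(un) == 1) {
    p[un] <- 1
    fw$q <- 1
  }
  fw$p <- p
  fw
}

# Backward pass: gradient of a loss w.r.t. (x_hat, w) given dL/dp.
backward_inclusion <- function(fw, dL_dp, w) {
  k <- ncol(fw$dmat)
  ds <- rep(0, length(fw$s))
  un <- fw$un
  if (length(un) >= 2 && fw$sdv > 0) {
    gq <- dL_dp[un]
    q <- fw$q
    da <- q * (gq - sum(gq * q))       # a = z / T
    dz <- da / fw$temperature
    nu <- length(un)
    ds_u <- dz / fw$sdv - mean(dz) / fw$sdv -
      (fw$su - fw$m) / ((nu - 1) * fw$sdv^2) * sum(dz * fw$z)
    ds[un] <- ds_u
  }
  sgn <- sign(fw$dmat)
  grad_w <- as.numeric(-t(abs(fw$dmat)) %*% ds)
  grad_x <- w * as.numeric(t(sgn) %*% ds)
  list(x_hat = grad_x, w = grad_w)
}

# ---- losses ----------------------------------------------------------------

#' AoA-Matched loss: normalized MSE against a bootstrapped table
#'
#' Mean squared error between the model's per-concept inclusion
#' probabilities at a month and one bootstrapped acquisition distribution,
#' z-scored by the month's sampled loss distribution and shifted by the
#' z-score of the theoretical minimum MSE (0) so the loss is nonnegative.
#'
#' @param p_model numeric vector of inclusion probabilities (acquired
#'   concepts at 1), named by concept.
#' @param boot_probs bootstrap inclusion probabilities over the same
#'   concepts (same names, same order).
#' @param normalizer list with `mu` and `sigma` for the month; `NULL`
#'   returns the raw MSE.
#' @param grad also return the gradient with respect to `p_model`.
#' @return The scalar loss, or a list `value`/`raw`/`grad`.
#' @export
aoa_matched_loss <- function(p_model, boot_probs, normalizer = NULL,
                             grad = FALSE) {
  if (length(p_model) != length(boot_probs) ||
      (!is.null(names(p_model)) && !is.null(names(boot_probs)) &&
       !identical(names(p_model), names(boot_probs)))) {
    stop("concept-set mismatch between model probabilities and bootstrap")
  }
  n <- length(p_model)
  raw <- mean((p_model - boot_probs)^2)
  value <- if (is.null(normalizer)) raw else {
    (raw - normalizer$mu) / normalizer$sigma -
      (0 - normalizer$mu) / normalizer$sigma
  }
  if (!grad) return(value)
  scale <- if (is.null(normalizer)) 1 else 1 / normalizer$sigma
  list(value = value, raw = raw,
       grad = scale * 2 * (p_model - boot_probs) / n)
}

# Rank-transformed concatenated probe columns for one probe pair against a
# candidate set; ranks are recomputed per pair and treated as constants by
# the gradient (the loss is linear in the probability weights).
probe_rank_vectors <- function(cache, pair_idx, cand_idx) {
  dlin <- cache$d$linguistic
  dvis <- cache$d$visual
  if (is.null(dlin) || is.null(dvis)) {
    stop("soft alignment needs both modalities in the feature cache")
  }
  a <- pair_idx[1]; b <- pair_idx[2]
  list(
    lin = rank(c(dlin[a, cand_idx], dlin[b, cand_idx])),
    vis_correct = rank(c(dvis[a, cand_idx], dvis[b, cand_idx])),
    vis_incorrect = rank(c(dvis[b, cand_idx], dvis[a, cand_idx]))
  )
}

#' Soft alignment loss over a probe slate
#'
#' For each probe pair, probability-weighted Spearman-style alignment scores
#' are computed for the correct and the swapped mapping: the concatenated
#' probe distance columns are rank-transformed, then correlated with a
#' weighted Pearson estimator whose entry weights are the candidate
#' inclusion probabilities (the probe-vs-candidate block of the outer
#' product of the inclusion vector). The raw loss is the mean margin
#' `s_incorrect - s_correct` across pairs, bounded in \[-2, 2\]; it is
#' z-normalized by the month's sampled margin distribution and shifted by
#' the z-score of the theoretical floor -2, so the loss is nonnegative.
#'
#' @param p inclusion-probability vector over the candidate set.
#' @param slate two-column matrix of probe-pair indices (or labels) drawn
#'   from concepts outside the candidate set.
#' @param cand_idx integer indices of the candidate set in the cache.
#' @param cache a `training_cache` (internal; [build_world()] worlds are
#'   accepted and converted).
#' @param normalizer list with `mu` and `sigma`; `NULL` returns the raw
#'   mean margin.
#' @param grad also return the gradient with respect to `p`.
#' @return The scalar loss, or a list `value`/`raw`/`grad`.
#' @export
soft_alignment_loss <- function(p, slate, cand_idx, cache, normalizer = NULL,
                                grad = FALSE) {
  if (inherits(cache, "world")) {
    cache <- training_cache(cache)
  }
  slate <- as.matrix(slate)
  if (nrow(slate) == 0) stop("empty probe slate")
  if (is.character(slate)) {
    slate <- matrix(match(slate, cache$concepts), ncol = 2)
  }
  n_c <- length(cand_idx)
  stopifnot(length(p) == n_c)
  u <- c(p, p)
  margins <- numeric(nrow(slate))
  gsum <- rep(0, n_c)
  for (j in seq_len(nrow(slate))) {
    rv <- probe_rank_vectors(cache, slate[j, ], cand_idx)
    wc <- weighted_pearson(rv$lin, rv$vis_correct, u, grad = grad)
    wi <- weighted_pearson(rv$lin, rv$vis_incorrect, u, grad = grad)
    if (grad) {
      margins[j] <- wi$value - wc$value
      g <- wi$grad - wc$grad
      gsum <- gsum + g[seq_len(n_c)] + g[n_c + seq_len(n_c)]
    } else {
      margins[j] <- wi - wc
    }
  }
  raw <- mean(margins)
  value <- if (is.null(normalizer)) raw else {
    (raw - normalizer$mu) / normalizer$sigma -
      (-2 - normalizer$mu) / normalizer$sigma
  }
  if (!grad) return(value)
  scale <- if (is.null(normalizer)) 1 else 1 / normalizer$sigma
  list(value = value, raw = raw, grad = scale * gsum / nrow(slate))
}

# ---- normalizer calibration ------------------------------------------------

#' Calibrate monthwise loss normalizers
#'
#' Samples the raw loss distribution under random concept selection for
#' each month of the schedule and returns its mean and SD, which the
#' training losses use for z-scoring. For the `"aoa"` kind each sample is
#' the MSE between a pseudo inclusion vector (randomly selected acquired
#' concepts at probability 1, a uniform distribution across the rest of a
#' pseudo candidate set) and a random bootstrap table. For the `"task"`
#' kind each sample is the margin `s_incorrect - s_correct` for a random
#' probe pair against a pseudo candidate set weighted the same way.
#'
#' @param kind `"aoa"` or `"task"`.
#' @param schedule a [month_schedule()].
#' @param world a [build_world()] world.
#' @param config a [generative_config()].
#' @param boot a [bootstrap_distributions()] set (required for `"aoa"`).
#' @param n_samples Monte-Carlo samples per month (>= 100).
#' @param seed integer seed.
#' @return An object of class `month_normalizer`: data frame with `month`,
#'   `mu`, `sigma`, plus the `kind` attribute.
#' @export
calibrate_normalizers <- function(kind = c("aoa", "task"), schedule, world,
                                  config, boot = NULL,
                                  n_samples = NULL, seed = 1) {
  kind <- match.arg(kind)
  stopifnot(inherits(schedule, "month_schedule"), inherits(world, "world"))
  n_samples <- n_samples %||% config$n_norm_samples
  if (n_samples < 100) stop("need at least 100 normalizer samples")
  if (kind == "aoa" && is.null(boot)) stop("aoa normalizer needs a bootstrap set")
  set.seed(as.integer(seed))
  cache <- training_cache(world, config$percentile, config$modality)
  vocab <- world$pair$shared_concepts
  n_c <- min(config$n_candidates, length(vocab))
  heldout_free <- seq_along(vocab)
  rows <- lapply(seq_along(schedule$months), function(mi) {
    Nt <- schedule$N_m[mi]
    draws <- vapply(seq_len(n_samples), function(i) {
      cand <- sample(heldout_free, n_c)
      n_acq <- min(if (kind == "aoa") Nt else max(Nt - 1, 1), n_c - 1)
      acq <- seq_len(n_acq)  # cand is already a random permutation
      p <- rep(1 / (n_c - n_acq), n_c)
      p[acq] <- 1
      if (kind == "aoa") {
        b <- boot$dists[[sample(length(boot$dists), 1)]][, mi]
        target <- rep(0, n_c)
        hit <- match(vocab[cand], names(b))
        target[!is.na(hit)] <- b[hit[!is.na(hit)]]
        mean((p - target)^2)
      } else {
        outside <- setdiff(heldout_free, cand)
        pr <- sample(outside, 2)
        soft_alignment_loss(p, matrix(pr, 1), cand, cache)
      }
    }, numeric(1))
    data.frame(month = schedule$months[mi], mu = mean(draws),
               sigma = stats::sd(draws))
  })
  out <- do.call(rbind, rows)
  if (any(out$sigma == 0)) stop("degenerate world: zero loss variance in a month")
  structure(out, kind = kind, class = c("month_normalizer", "data.frame"))
}

month_norm <- function(normalizers, month) {
  i <- match(month, normalizers$month)
  if (is.na(i)) stop("no normalizer for month ", month)
  list(mu = normalizers$mu[i], sigma = normalizers$sigma[i])
}

# ---- Adam ------------------------------------------------------------------

adam_init <- function(par) list(m = par * 0, v = par * 0, t = 0)
adam_step <- function(par, grad, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1
  state$m <- beta1 * state$m + (1 - beta1) * grad
  state$v <- beta2 * state$v + (1 - beta2) * grad^2
  mhat <- state$m / (1 - beta1^state$t)
  vhat <- state$v / (1 - beta2^state$t)
  list(par = par - lr * mhat / (sqrt(vhat) + eps), state = state)
}

# ---- training --------------------------------------------------------------

# Candidate set for the current state: the acquired concepts plus a uniform
# refill to n_c from the eligible pool.
refill_candidates <- function(acquired_idx, pool_idx, n_c) {
  free <- setdiff(pool_idx, acquired_idx)
  n_fill <- min(n_c - length(acquired_idx), length(free))
  if (n_fill < 1) stop("candidate pool exhausted")
  c(acquired_idx, sample(free, n_fill))
}

# One pass over the schedule: sample a trajectory from the current model
# parameters, computing the loss (and gradient) at each month's end.
run_schedule <- function(x_hat, w, schedule, cache, fnorm, features, pool_idx,
                         n_c, temperature, month_loss, with_grad = TRUE,
                         lr = NULL, adam = NULL) {
  state_idx <- integer(0)
  total <- 0
  states <- vector("list", length(schedule$months))
  for (mi in seq_along(schedule$months)) {
    for (slot in seq_len(schedule$n_m[mi])) {
      cand <- refill_candidates(state_idx, pool_idx, n_c)
      un <- setdiff(cand, state_idx)
      if (length(state_idx) < 2) {
        pick <- if (length(un) == 1) un else sample(un, 1)
      } else {
        A <- model_feature_matrix(
          augmented_feature_matrix(cache, state_idx, cand), fnorm, features)
        fwd <- forward_inclusion(x_hat, w, A, cand %in% state_idx, temperature)
        q <- fwd$p[!(cand %in% state_idx)]
        pick <- if (length(un) == 1) un else sample(un, 1, prob = q / sum(q))
      }
      state_idx <- c(state_idx, pick)
    }
    states[[mi]] <- state_idx
    if (!is.null(month_loss) && length(state_idx) >= 2) {
      cand <- refill_candidates(state_idx, pool_idx, n_c)
      A <- model_feature_matrix(
        augmented_feature_matrix(cache, state_idx, cand), fnorm, features)
      fwd <- forward_inclusion(x_hat, w, A, cand %in% state_idx, temperature)
      L <- month_loss(mi, fwd$p, cand, grad = with_grad)
      if (with_grad) {
        if (!is.finite(L$value)) stop("non-finite loss")
        g <- backward_inclusion(fwd, L$grad, w)
        stx <- adam_step(x_hat, g$x_hat, adam$x, lr)
        x_hat <- stx$par; adam$x <- stx$state
        stw <- adam_step(w, g$w, adam$w, lr)
        w <- stw$par; adam$w <- stw$state
        total <- total + L$value
      } else {
        total <- total + L
      }
    }
  }
  list(x_hat = x_hat, w = w, adam = adam,
       loss = total / length(schedule$months), states = states)
}

#' Train a generative structural agent
#'
#' Learns the internal model (target feature values `x_hat` and weights
#' `w`) by gradient descent. Each epoch simulates the monthly schedule by
#' sampling concepts from the model's softmax selection distribution; at
#' each month's end the kind's loss is computed on the inclusion-probability
#' vector and backpropagated through the softmax with an Adam update. Of
#' `restarts` random initializations, the one with the lowest validation
#' loss averaged over the final 5 epochs is returned. Validation uses
#' held-out bootstrap tables (AoA-Matched) or probe slates drawn from a
#' disjoint validation segment of the non-candidate concepts, re-segmented
#' at every loss evaluation (Task-Optimized).
#'
#' @param config a [generative_config()].
#' @param world a [build_world()] world.
#' @param schedule a [month_schedule()]; defaults to [monthly_counts()] of
#'   the world's table.
#' @param boot a [bootstrap_distributions()] set (required for
#'   `"aoa_matched"`).
#' @param normalizers optional precomputed [calibrate_normalizers()] result.
#' @param feature_normalizer optional precomputed [fit_feature_normalizer()].
#' @return An object of class `internal_model`: `kind`, `feature_names`,
#'   `x_hat`, `w`, `history` (per restart x epoch train/validation loss),
#'   `best_restart`, plus the frozen `feature_normalizer`, `percentile`,
#'   `modality` and `temperature` needed for generation.
#' @export
train_agent <- function(config, world, schedule = NULL, boot = NULL,
                        normalizers = NULL, feature_normalizer = NULL) {
  stopifnot(inherits(config, "generative_config"), inherits(world, "world"))
  schedule <- schedule %||% monthly_counts(world$table)
  if (config$kind == "aoa_matched" && is.null(boot)) {
    stop("aoa_matched training needs a bootstrap set")
  }
  cache <- training_cache(world, config$percentile, config$modality)
  vocab <- world$pair$shared_concepts
  set.seed(config$seed)
  fnorm <- feature_normalizer %||%
    fit_feature_normalizer(world, schedule, percentile = config$percentile,
                           modality = config$modality, seed = config$seed)
  norm_kind <- if (config$kind == "aoa_matched") "aoa" else "task"
  normalizers <- normalizers %||%
    calibrate_normalizers(norm_kind, schedule, world, config, boot = boot,
                          n_samples = config$n_norm_samples,
                          seed = config$seed + 7L)

  pool_idx <- seq_along(vocab)
  n_c <- min(config$n_candidates, length(vocab))
  if (config$kind == "task_optimized" &&
      length(vocab) - n_c < 2 * config$n_heldout) {
    stop("vocabulary too small to hold out train and validation slates")
  }
  if (max(schedule$N_m) > n_c) stop("candidate set smaller than the schedule demands")

  sample_slate <- function(set_idx, k) {
    universe <- t(utils::combn(set_idx, 2))
    if (k >= nrow(universe)) return(universe)
    universe[sample.int(nrow(universe), k), , drop = FALSE]
  }
  make_loss <- function(split) {
    if (config$kind == "aoa_matched") {
      idx <- if (split == "train") boot$train_idx else boot$validation_idx
      function(mi, p, cand, grad = FALSE) {
        b <- boot$dists[[idx[sample(length(idx), 1)]]][, mi]
        target <- rep(0, length(cand))
        hit <- match(vocab[cand], names(b))
        target[!is.na(hit)] <- b[hit[!is.na(hit)]]
        aoa_matched_loss(p, target, month_norm(normalizers, schedule$months[mi]),
                         grad = grad)
      }
    } else {
      # The concepts outside the candidate set are re-segmented into
      # disjoint train and validation slates at every loss evaluation, so
      # over training every concept serves as a probe.
      function(mi, p, cand, grad = FALSE) {
        outside <- sample(setdiff(seq_along(vocab), cand))
        h <- config$n_heldout
        set_idx <- if (split == "train") outside[seq_len(h)] else
          outside[h + seq_len(min(h, length(outside) - h))]
        slate <- sample_slate(set_idx, config$pairs_per_slate)
        soft_alignment_loss(p, slate, cand, cache,
                            month_norm(normalizers, schedule$months[mi]),
                            grad = grad)
      }
    }
  }
  train_loss <- make_loss("train")
  valid_loss <- make_loss("validation")

  k <- length(config$features)
  restart_seeds <- spawn_seeds(config$seed + 29L, config$restarts)
  history <- list()
  models <- vector("list", config$restarts)
  val_scores <- rep(Inf, config$restarts)
  for (r in seq_len(config$restarts)) {
    set.seed(restart_seeds[r])
    x_hat <- stats::runif(k)
    w <- stats::runif(k, 0, 0.1)
    names(x_hat) <- names(w) <- config$features
    adam <- list(x = adam_init(x_hat), w = adam_init(w))
    val_by_epoch <- rep(NA_real_, config$epochs)
    ok <- TRUE
    for (e in seq_len(config$epochs)) {
      res <- tryCatch(
        run_schedule(x_hat, w, schedule, cache, fnorm, config$features,
                     pool_idx, n_c, config$temperature, train_loss,
                     with_grad = TRUE, lr = config$learning_rate, adam = adam),
        error = function(err) err)
      if (inherits(res, "error")) {
        warning("restart ", r, " aborted: ", conditionMessage(res))
        ok <- FALSE
        break
      }
      x_hat <- res$x_hat; w <- res$w; adam <- res$adam
      vres <- run_schedule(x_hat, w, schedule, cache, fnorm, config$features,
                           pool_idx, n_c, config$temperature, valid_loss,
                           with_grad = FALSE)
      val_by_epoch[e] <- vres$loss
      history[[length(history) + 1]] <- data.frame(
        restart = r, epoch = e, train_loss = res$loss, val_loss = vres$loss)
    }
    if (ok) {
      last <- utils::tail(stats::na.omit(val_by_epoch), 5)
      val_scores[r] <- mean(last)
      models[[r]] <- list(x_hat = x_hat, w = w)
    }
  }
  if (all(is.infinite(val_scores))) stop("all training restarts failed")
  best <- which.min(val_scores)
  structure(list(kind = config$kind, feature_names = config$features,
                 x_hat = models[[best]]$x_hat, w = models[[best]]$w,
                 best_restart = best, restart_scores = val_scores,
                 restart_models = models,
                 history = do.call(rbind, history),
                 feature_normalizer = fnorm,
                 percentile = config$percentile, modality = config$modality,
                 temperature = config$temperature, config = config),
            class = "internal_model")
}

#' @export
print.internal_model <- function(x, ...) {
  cat(sprintf("<internal_model (%s): best restart %d>\n", x$kind, x$best_restart))
  print(round(rbind(x_hat = x$x_hat, w = x$w), 3))
  invisible(x)
}

#' Save / load an internal model as JSON
#'
#' @param model an `internal_model`.
#' @param path JSON file path.
#' @return `write_internal_model` returns the path invisibly;
#'   `read_internal_model` the model.
#' @export
write_internal_model <- function(model, path) {
  stopifnot(inherits(model, "internal_model"))
  jsonlite::write_json(list(
    kind = model$kind, feature_names = model$feature_names,
    x_hat = as.list(model$x_hat), w = as.list(model$w),
    feature_normalizer = lapply(model$feature_normalizer, as.list),
    percentile = model$percentile, modality = model$modality,
    temperature = model$temperature), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_internal_model
#' @export
read_internal_model <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(kind = j$kind, feature_names = j$feature_names,
                 x_hat = stats::setNames(as.numeric(j$x_hat), names(j$x_hat)),
                 w = stats::setNames(as.numeric(j$w), names(j$w)),
                 feature_normalizer = lapply(j$feature_normalizer, unlist),
                 percentile = j$percentile, modality = j$modality,
                 temperature = j$temperature),
            class = "internal_model")
}

#' Generate a knowledge-state trajectory from a frozen internal model
#'
#' Concepts are sampled one at a time from the model's softmax selection
#' distribution over the candidate set (refilled to the configured size
#' after each acquisition) until each month's count is met. The first two
#' concepts are drawn uniformly, since structural features of an augmented
#' state need at least three members.
#'
#' @param model an `internal_model`.
#' @param schedule a [month_schedule()].
#' @param world a [build_world()] world.
#' @param seed optional seed (`NULL` uses the current RNG stream).
#' @param n_candidates candidate-set size; defaults to the training size.
#' @return A list of cumulative knowledge states, one per month.
#' @export
generate_sequence <- function(model, schedule, world, seed = NULL,
                              n_candidates = NULL) {
  stopifnot(inherits(model, "internal_model"), inherits(world, "world"))
  if (!is.null(seed)) set.seed(as.integer(seed))
  cache <- training_cache(world, model$percentile, model$modality)
  vocab <- world$pair$shared_concepts
  n_c <- min(n_candidates %||% model$config$n_candidates %||% 300,
             length(vocab))
  res <- run_schedule(model$x_hat, model$w, schedule, cache,
                      model$feature_normalizer, model$feature_names,
                      seq_along(vocab), n_c, model$temperature,
                      month_loss = NULL, with_grad = FALSE)
  states <- lapply(res$states, function(idx) vocab[idx])
  names(states) <- as.character(schedule$months)
  states
}
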