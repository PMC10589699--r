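test_that("generative scores equal the hand-computed weighted deviation from target", {
  sw <- cached_fixture("noisy30")
  w <- sw$world
  vocab <- w$pair$shared_concepts
  state <- vocab[1:4]
  cands <- vocab[5:10]
  sch <- monthly_counts(w$table)
  fnorm <- fit_feature_normalizer(w, sch, n_states = 40, seed = 2)
  feats <- alignsim:::state_feature_names
  model <- structure(list(
    kind = "task_optimized", feature_names = feats,
    x_hat = stats::setNames(seq(0.1, 0.7, by = 0.1), feats),
    w = stats::setNames(rep(c(0.5, -0.2), length.out = 7), feats),
    feature_normalizer = fnorm, percentile = 10, modality = "mean",
    temperature = 0.05), class = "internal_model")
  s <- generative_scores(cands, state, model, w)
  # hand arithmetic: -sum_j |A_ij - x_hat_j| * w_j on normalized features
  cache <- alignsim:::training_cache(w)
  A <- alignsim:::model_feature_matrix(
    alignsim:::augmented_feature_matrix(cache, match(state, vocab), match(cands, vocab)),
    fnorm, feats)
  manual <- sapply(seq_along(cands), function(i)
    -sum(abs(A[i, ] - model$x_hat) * model$w))
  expect_equal(unname(s), manual)

  # target hit with positive weights scores 0, the maximum
  model2 <- model
  model2$x_hat <- A[3, ]
  model2$w <- stats::setNames(rep(0.4, 7), feats)
  s2 <- generative_scores(cands, state, model2, w)
  expect_equal(unname(s2[3]), 0)
  expect_true(all(s2[-3] <= 0))

  # zero weights: all scores zero, uniform selection distribution
  model3 <- model
  model3$w[] <- 0
  s3 <- generative_scores(cands, state, model3, w)
  expect_true(all(s3 == 0))
  expect_equal(unname(candidate_distribution(s3)), rep(1 / 6, 6))
})

test_that("the softmax selection distribution behaves across temperatures", {
  expect_equal(unname(candidate_distribution(c(1, 1), 0.5)), c(0.5, 0.5))
  # closed form on raw (unstandardized) scores
  expect_equal(unname(candidate_distribution(c(1, 0), 0.5, standardize = FALSE)),
               c(stats::plogis(2), 1 - stats::plogis(2)))
  s <- c(3, 1, 2)
  hot <- candidate_distribution(s, 1e3)
  expect_equal(unname(hot), rep(1 / 3, 3), tolerance = 1e-2)
  cold <- candidate_distribution(s, 1e-3)
  expect_equal(unname(cold[1]), 1, tolerance = 1e-9)
  # invariance under adding a constant
  expect_equal(candidate_distribution(s + 17, 0.1), candidate_distribution(s, 0.1))
  expect_equal(sum(candidate_distribution(rnorm(9))), 1)
  # permutation equivariance
  perm <- c(2, 3, 1)
  expect_equal(unname(candidate_distribution(s[perm], 0.2)),
               unname(candidate_distribution(s, 0.2)[perm]))
})

test_that("the AoA-Matched loss matches hand arithmetic and z-shift algebra", {
  expect_equal(aoa_matched_loss(c(0.2, 0.8), c(0.2, 0.8),
                                list(mu = 0.3, sigma = 0.1)), 0)
  expect_equal(aoa_matched_loss(c(0.5, 0.5), c(0, 1)), 0.25)
  norm <- list(mu = 0.1, sigma = 0.05)
  res <- aoa_matched_loss(c(0.55, 0.45), c(0.1, 0), norm, grad = TRUE)
  expect_equal(res$raw, mean(c(0.45, 0.45)^2))
  expect_equal(aoa_matched_loss(c(0.3, 0.7), c(0.1, 0.5), norm),
               (0.04 - 0.1) / 0.05 - (0 - 0.1) / 0.05)  # = raw / sigma
  expect_error(aoa_matched_loss(c(a = 1), c(b = 1)), "mismatch")
})

test_that("the soft alignment margin is signed correctly, bounded, and z-shifted", {
  w <- cached_fixture("mirror10")$world
  cache <- alignsim:::training_cache(w)
  vocab <- w$pair$shared_concepts
  cand <- 1:6
  p <- rep(1, 6)  # fully concentrated on the knowledge state
  slate <- matrix(c(7, 8, 9, 10), 2, byrow = TRUE)
  raw <- soft_alignment_loss(p, slate, cand, cache)
  expect_lt(raw, 0)  # correct mapping wins on a mirrored world
  expect_gte(raw, -2)

  set.seed(12)
  for (i in 1:10) {
    pr <- runif(6)
    pr[1:3] <- 1
    r <- soft_alignment_loss(pr, slate, cand, cache, grad = TRUE)
    expect_gte(r$raw, -2)
    expect_lte(r$raw, 2)
    norm <- list(mu = -0.3, sigma = 0.2)
    expect_equal(soft_alignment_loss(pr, slate, cand, cache, norm),
                 (r$raw - norm$mu) / norm$sigma - (-2 - norm$mu) / norm$sigma)
  }
  expect_error(soft_alignment_loss(p, slate[0, , drop = FALSE], cand, cache),
               "empty")
})

test_that("backpropagated gradients match finite differences for both losses", {
  skip_if_not_installed("pracma")
  sw <- cached_fixture("noisy30")
  w <- sw$world
  cache <- alignsim:::training_cache(w)
  vocab <- w$pair$shared_concepts
  set.seed(3)
  state <- sample(vocab, 4)
  cand_idx <- match(c(state, sample(setdiff(vocab, state), 8)), vocab)
  acq <- cand_idx %in% match(state, vocab)
  sch <- monthly_counts(w$table)
  fnorm <- fit_feature_normalizer(w, sch, n_states = 40, seed = 4)
  A <- alignsim:::model_feature_matrix(
    alignsim:::augmented_feature_matrix(cache, match(state, vocab), cand_idx),
    fnorm, alignsim:::state_feature_names)
  k <- ncol(A)
  par0 <- c(runif(k), runif(k, 0, 0.1))
  target <- runif(length(cand_idx))
  norm_a <- list(mu = 0.05, sigma = 0.02)
  f_aoa <- function(par) {
    fw <- alignsim:::forward_inclusion(par[1:k], par[(k + 1):(2 * k)], A, acq, 0.05)
    aoa_matched_loss(fw$p, target, norm_a)
  }
  fw <- alignsim:::forward_inclusion(par0[1:k], par0[(k + 1):(2 * k)], A, acq, 0.05)
  La <- aoa_matched_loss(fw$p, target, norm_a, grad = TRUE)
  ga <- alignsim:::backward_inclusion(fw, La$grad, par0[(k + 1):(2 * k)])
  num_a <- pracma::grad(f_aoa, par0)
  expect_lte(max(abs(c(ga$x_hat, ga$w) - num_a)), 1e-4 * max(abs(num_a)) + 1e-8)

  outside <- setdiff(seq_along(vocab), cand_idx)
  slate <- t(replicate(6, sample(outside, 2)))
  norm_t <- list(mu = 0, sigma = 0.1)
  f_task <- function(par) {
    fw <- alignsim:::forward_inclusion(par[1:k], par[(k + 1):(2 * k)], A, acq, 0.05)
    soft_alignment_loss(fw$p, slate, cand_idx, cache, norm_t)
  }
  Lt <- soft_alignment_loss(fw$p, slate, cand_idx, cache, norm_t, grad = TRUE)
  gt <- alignsim:::backward_inclusion(fw, Lt$grad, par0[(k + 1):(2 * k)])
  num_t <- pracma::grad(f_task, par0)
  expect_lte(max(abs(c(gt$x_hat, gt$w) - num_t)), 1e-4 * max(abs(num_t)) + 1e-8)
})

test_that("normalizer calibration produces nonnegative losses and stable moments", {
  sw <- cached_fixture("noisy30")
  w <- sw$world
  sch <- monthly_counts(w$table)
  cfg <- generative_config("task_optimized", n_vocab = 30,
                           n_norm_samples = 150, seed = 5)
  nt <- calibrate_normalizers("task", sch, w, cfg, n_samples = 150, seed = 5)
  expect_true(all(nt$sigma > 0))
  # shift construction keeps every matching-month normalized loss >= 0
  cache <- alignsim:::training_cache(w)
  set.seed(6)
  for (i in 1:50) {
    cand <- sample(seq_along(w$pair$shared_concepts), cfg$n_candidates)
    p <- rep(1 / 10, cfg$n_candidates); p[1:5] <- 1
    pr <- sample(setdiff(seq_along(w$pair$shared_concepts), cand), 2)
    mi <- sample(nrow(nt), 1)
    val <- soft_alignment_loss(p, matrix(pr, 1), cand, cache,
                               list(mu = nt$mu[mi], sigma = nt$sigma[mi]))
    expect_gte(val, 0)
  }
  # doubling the sample budget moves the mean by less than 2 joint SEMs
  boot <- bootstrap_distributions(w$table, B = 6, seqs_per_boot = 10, seed = 7)
  na1 <- calibrate_normalizers("aoa", sch, w, cfg, boot = boot,
                               n_samples = 200, seed = 8)
  na2 <- calibrate_normalizers("aoa", sch, w, cfg, boot = boot,
                               n_samples = 400, seed = 9)
  sem <- na1$sigma / sqrt(200) + na2$sigma / sqrt(400)
  expect_true(all(abs(na1$mu - na2$mu) < 2.5 * sem + 1e-8))
})

test_that("a zero learning rate leaves the internal model at its initialization", {
  sw <- cached_fixture("noisy30")
  w <- sw$world
  sch <- monthly_counts(w$table)
  boot <- bootstrap_distributions(w$table, B = 4, seqs_per_boot = 5, seed = 11)
  cfg <- generative_config("aoa_matched", n_vocab = 30, epochs = 2, restarts = 1,
                           learning_rate = 0, n_norm_samples = 120, seed = 13)
  m <- train_agent(cfg, w, sch, boot = boot)
  rs <- alignsim:::spawn_seeds(cfg$seed + 29L, 1)
  set.seed(rs[1])
  x0 <- runif(7); w0 <- runif(7, 0, 0.1)
  expect_equal(unname(m$x_hat), x0)
  expect_equal(unname(m$w), w0)
})

test_that("frozen models generate reproducible schedules; zero-weight models sample uniformly", {
  sw <- cached_fixture("noisy30")
  w <- sw$world
  sch <- month_schedule(16:17, c(2L, 1L))
  feats <- alignsim:::state_feature_names
  fnorm <- fit_feature_normalizer(w, sch, n_states = 30, seed = 14)
  null_model <- structure(list(
    kind = "task_optimized", feature_names = feats,
    x_hat = stats::setNames(runif(7), feats),
    w = stats::setNames(rep(0, 7), feats),
    feature_normalizer = fnorm, percentile = 10, modality = "mean",
    temperature = 0.05,
    config = list(n_candidates = 6)), class = "internal_model")
  g1 <- generate_sequence(null_model, sch, w, seed = 15)
  g2 <- generate_sequence(null_model, sch, w, seed = 15)
  expect_identical(g1, g2)
  expect_equal(unname(lengths(g1)), sch$N_m)

  # zero weights: selection indistinguishable from uniform (chi-square)
  mini <- mirror_world(6, seed = 16)
  sch1 <- month_schedule(16L, 3L)
  set.seed(17)
  picks <- table(unlist(replicate(800, {
    generate_sequence(null_model, sch1, mini, n_candidates = 6)[[1]]
  })))
  expect_equal(length(picks), 6)
  expect_gt(stats::chisq.test(picks)$p.value, 0.001)
})

test_that("internal models round-trip through JSON", {
  feats <- alignsim:::state_feature_names
  m <- structure(list(
    kind = "aoa_matched", feature_names = feats,
    x_hat = stats::setNames(runif(7), feats),
    w = stats::setNames(runif(7), feats),
    feature_normalizer = list(min = stats::setNames(rep(0, 7), feats),
                              max = stats::setNames(rep(1, 7), feats)),
    percentile = 10, modality = "mean", temperature = 0.05),
    class = "internal_model")
  f <- withr::local_tempfile(fileext = ".json")
  write_internal_model(m, f)
  back <- read_internal_model(f)
  expect_equal(back$x_hat, m$x_hat)
  expect_equal(back$w, m$w)
  expect_equal(back$kind, m$kind)
})
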