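# Internal helpers shared across modules.

# Round half away from zero ("nearest whole number of concepts"; R's round()
# is banker's rounding, which would break reproducibility of cumulative counts).
round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

# Upper-triangle (i < j) entries of a square matrix, column-major order.
upper_tri_vec <- function(m) m[upper.tri(m)]

# Numerically safe softmax.
softmax <- function(x) {
  z <- exp(x - max(x))
  z / sum(z)
}

# Derive reproducible child seeds from a master seed without disturbing the
# caller's RNG stream more than one draw per child.
spawn_seeds <- function(seed, n) {
  stopifnot(is.numeric(seed), length(seed) == 1)
  old <- get0(".Random.seed", envir = globalenv(), ifnotfound = NULL)
  set.seed(as.integer(seed) %% .Machine$integer.max)
  s <- sample.int(.Machine$integer.max - 1L, n)
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  s
}

# Weighted Pearson correlation with nonnegative weights (not all zero).
# Returns the correlation; with `grad = TRUE` also the gradient with respect
# to the (unnormalized) weights, used by the soft alignment loss.
weighted_pearson <- function(x, y, w, grad = FALSE) {
  stopifnot(length(x) == length(y), length(x) == length(w), all(w >= 0))
  W <- sum(w)
  if (W <= 0) stop("weights sum to zero")
  u <- w / W
  mx <- sum(u * x)
  my <- sum(u * y)
  cx <- x - mx
  cy <- y - my
  vxy <- sum(u * cx * cy)
  vx <- sum(u * cx^2)
  vy <- sum(u * cy^2)
  if (vx <= .Machine$double.eps * max(x^2, 1) || vy <= .Machine$double.eps * max(y^2, 1)) {
    stop("weighted correlation undefined: a weighted vector is constant")
  }
  r <- vxy / sqrt(vx * vy)
  if (!grad) return(r)
  g <- (cx * cy / sqrt(vx * vy) - (r / 2) * (cx^2 / vx + cy^2 / vy)) / W
  list(value = r, grad = g)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
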