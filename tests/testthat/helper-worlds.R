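# Shared fixtures, built once per test run and cached.

.fixture_env <- new.env(parent = emptyenv())

cached_fixture <- function(name) {
  if (is.null(.fixture_env[[name]])) .fixture_env[[name]] <- make_fixture(name)
  .fixture_env[[name]]
}

# A pair of independent (unalignable) random systems over a shared vocabulary.
independent_world <- function(n = 30, seed = 7) {
  set.seed(seed)
  concepts <- sprintf("c%02d", seq_len(n))
  v <- embedding_system(matrix(stats::rnorm(n * 10), n, 10), concepts, "visual")
  l <- embedding_system(matrix(stats::rnorm(n * 50), n, 50), concepts, "linguistic")
  build_world(intersect_systems(v, l))
}

# Noiseless mirrored pair of given size (exact second-order isomorphism).
mirror_world <- function(n = 10, seed = 1) {
  cfg <- synthetic_config(n, n_clusters = 2, alignment_noise = 0,
                          density_bias = 0, n_aoa = max(4, round(n / 3)),
                          seed = seed)
  generate_world(cfg)$world
}

# Tiny deterministic acquisition table for schedule arithmetic tests.
toy_table <- function() {
  acquisition_table(rbind(c(0.5, 1.0), c(0.5, 1.0)), c("a", "b"), 16:17)
}

# Exhaustive inclusion probabilities for sequential without-replacement
# sampling from monthwise renormalized probabilities (the AoA rule), for
# tiny tables. Independent oracle used against simulation-based estimates.
enumerate_inclusion <- function(table, schedule) {
  concepts <- table$concepts
  n <- length(concepts)
  M <- length(schedule$months)
  incl <- matrix(0, n, M, dimnames = list(concepts, as.character(schedule$months)))
  recurse <- function(known, mi, slot, prob) {
    if (mi > M) return(invisible(NULL))
    if (slot > schedule$n_m[mi]) {
      incl[known, mi] <<- incl[known, mi] + prob
      recurse(known, mi + 1, 1, prob)
      return(invisible(NULL))
    }
    p <- suppressWarnings(
      acquisition_distribution(table, schedule$months[mi], known))
    for (cand in names(p)) {
      if (p[[cand]] > 0) {
        recurse(c(known, cand), mi, slot + 1, prob * p[[cand]])
      }
    }
    invisible(NULL)
  }
  recurse(character(0), 1, 1, 1)
  incl
}
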