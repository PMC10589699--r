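#' Alignment score between two systems under a candidate mapping
#'
#' The alignment score is the Spearman rank correlation (average-rank tie
#' handling) between the upper-triangle entries of the two systems' pairwise
#' distance matrices, after reordering the second matrix by the candidate
#' item mapping. A score of 1 means the two systems' interconcept distance
#' ranks mirror each other exactly under that mapping.
#'
#' @param dist_a,dist_b square distance matrices over the same number of
#'   items (n >= 3).
#' @param mapping integer permutation: item i of `dist_a` is mapped to item
#'   `mapping[i]` of `dist_b`. Default identity.
#' @return Spearman rho in \[-1, 1\].
#' @export
alignment_score <- function(dist_a, dist_b, mapping = seq_len(nrow(dist_a))) {
  dist_a <- unclass(dist_a); dist_b <- unclass(dist_b)
  n <- nrow(dist_a)
  if (n < 3) stop("alignment score needs at least 3 items")
  if (nrow(dist_b) != n) stop("distance matrices differ in size")
  if (length(mapping) != n || any(sort(mapping) != seq_len(n))) {
    stop("mapping must be a permutation of 1..n")
  }
  a <- upper_tri_vec(dist_a)
  b <- upper_tri_vec(dist_b[mapping, mapping])
  if (stats::sd(a) == 0 || stats::sd(b) == 0) {
    stop("undefined correlation: constant upper triangle")
  }
  stats::cor(a, b, method = "spearman")
}

# Distance columns from each probe item to every knowledge-state concept,
# concatenated in the given probe order.
probe_columns <- function(dmat, probes, state) {
  c(unclass(dmat)[probes[1], state], unclass(dmat)[probes[2], state])
}

#' Alignment score of one candidate probe mapping against a knowledge state
#'
#' For a two-alternative probe pair only the two probe items move between
#' the candidate mappings, so the comparison reduces to correlating the
#' concatenated probe distance columns: the distances from each probe word
#' to every known concept (linguistic system) against the distances from
#' each probe object to every known concept (visual system), with the
#' visual concatenation ordered by the candidate mapping.
#'
#' @param pair a [intersect_systems()] system pair, or a `world` built by
#'   [build_world()].
#' @param state character vector of known concepts (length >= 2).
#' @param probes character vector of two probe concept labels, neither in
#'   `state`.
#' @param candidate `"correct"` (probe word a to probe object a) or
#'   `"incorrect"` (the swapped mapping).
#' @param metric distance metric, passed to [pairwise_distances()] when
#'   `pair` carries no cached distances.
#' @return Spearman rho of the concatenated probe columns.
#' @export
probe_alignment_score <- function(pair, state, probes,
                                  candidate = c("correct", "incorrect"),
                                  metric = "euclidean") {
  candidate <- match.arg(candidate)
  w <- as_world(pair, metric)
  check_probes(w, state, probes)
  lin <- probe_columns(w$dlin, probes, state)
  vis_order <- if (candidate == "correct") probes else rev(probes)
  vis <- probe_columns(w$dvis, vis_order, state)
  if (stats::sd(lin) == 0 || stats::sd(vis) == 0) {
    stop("undefined correlation: constant probe-column vector")
  }
  stats::cor(lin, vis, method = "spearman")
}

check_probes <- function(world, state, probes) {
  if (length(state) < 2) stop("knowledge state must contain at least 2 concepts")
  if (length(probes) != 2 || probes[1] == probes[2]) stop("probes must be two distinct concepts")
  vocab <- world$pair$shared_concepts
  if (!all(c(state, probes) %in% vocab)) stop("state or probe concept outside shared vocabulary")
  if (any(probes %in% state)) stop("probe concept already in knowledge state")
  invisible(TRUE)
}

#' Two-alternative forced choice over a probe pair
#'
#' Scores both candidate mappings of the probe pair with
#' [probe_alignment_score()] and chooses the higher; exact ties (within
#' `tol`) are broken uniformly at random and flagged.
#'
#' @inheritParams probe_alignment_score
#' @param tol absolute tolerance within which the two scores count as tied.
#' @return A list of class `forced_choice_result`: `chosen_mapping`
#'   (`"correct"`/`"incorrect"`), `score_correct`, `score_incorrect`,
#'   `margin` (correct minus incorrect) and `tie_broken`.
#' @export
forced_choice <- function(pair, state, probes, metric = "euclidean",
                          tol = 1e-12) {
  sc <- probe_alignment_score(pair, state, probes, "correct", metric)
  si <- probe_alignment_score(pair, state, probes, "incorrect", metric)
  tie <- abs(sc - si) <= tol
  chosen <- if (tie) {
    if (stats::runif(1) < 0.5) "correct" else "incorrect"
  } else if (sc > si) "correct" else "incorrect"
  structure(list(chosen_mapping = chosen, score_correct = sc,
                 score_incorrect = si, margin = sc - si, tie_broken = tie),
            class = "forced_choice_result")
}

#' @export
print.forced_choice_result <- function(x, ...) {
  cat(sprintf("<forced_choice: %s (correct %.4f vs incorrect %.4f)%s>\n",
              x$chosen_mapping, x$score_correct, x$score_incorrect,
              if (x$tie_broken) " tie-broken" else ""))
  invisible(x)
}

#' Bundle a system pair with cached distance matrices and world metadata
#'
#' Most simulation and training functions consume a `world`: the system
#' pair, its two pairwise distance matrices (computed once), an optional
#' acquisition table restricted to the shared vocabulary, and the implied
#' AoA concept subset.
#'
#' @param pair an [intersect_systems()] result.
#' @param table optional [acquisition_table()]; rows outside the shared
#'   vocabulary are dropped.
#' @param metric distance metric for both systems.
#' @return An object of class `world`.
#' @export
build_world <- function(pair, table = NULL, metric = "euclidean") {
  stopifnot(inherits(pair, "system_pair"))
  if (!is.null(table)) {
    keep <- table$concepts %in% pair$shared_concepts
    if (!all(keep)) {
      table <- acquisition_table(table$probs[keep, , drop = FALSE],
                                 table$concepts[keep], table$months)
    }
  }
  structure(list(
    pair = pair,
    table = table,
    metric = metric,
    dvis = pairwise_distances(pair$visual, metric),
    dlin = pairwise_distances(pair$linguistic, metric),
    aoa_concepts = if (is.null(table)) character(0) else table$concepts
  ), class = "world")
}

# Accept either a system_pair or a prebuilt world where a pair is expected.
as_world <- function(pair, metric = "euclidean") {
  if (inherits(pair, "world")) pair else build_world(pair, metric = metric)
}

#' @export
print.world <- function(x, ...) {
  cat(sprintf("<world: %d concepts (%d AoA), metric=%s>\n",
              length(x$pair$shared_concepts), length(x$aoa_concepts), x$metric))
  invisible(x)
}
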