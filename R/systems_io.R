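#' Construct an embedding system
#'
#' An embedding system is one representational space: a set of named concepts,
#' each with a coordinate vector of common dimension D. Similarity relations
#' within a system (not the coordinates themselves) are what drive alignment.
#'
#' @param vectors numeric matrix, one row per concept, D columns.
#' @param concepts character vector of unique, nonempty concept labels.
#' @param modality label for the system, typically `"visual"` or `"linguistic"`.
#' @return An object of class `embedding_system` with fields `concepts`,
#'   `vectors` (row-named matrix), `modality` and `dim`.
#' @export
embedding_system <- function(vectors, concepts, modality = "linguistic") {
  vectors <- as.matrix(vectors)
  concepts <- as.character(concepts)
  if (length(concepts) == 0) stop("empty system: no concepts")
  if (nrow(vectors) != length(concepts)) {
    stop("concepts and vectors are not index-aligned")
  }
  if (anyDuplicated(concepts)) {
    stop("duplicate concept labels: ", paste(unique(concepts[duplicated(concepts)]), collapse = ", "))
  }
  if (any(!nzchar(concepts))) stop("empty concept label")
  if (any(!is.finite(vectors))) stop("non-finite embedding coordinate")
  rownames(vectors) <- concepts
  structure(
    list(modality = modality, concepts = concepts, vectors = vectors,
         dim = ncol(vectors)),
    class = "embedding_system"
  )
}

#' @export
print.embedding_system <- function(x, ...) {
  cat(sprintf("<embedding_system: %s, %d concepts, D=%d>\n",
              x$modality, length(x$concepts), x$dim))
  invisible(x)
}

#' Read embeddings in the GloVe text dialect
#'
#' One record per line: a token followed by D whitespace-separated decimal
#' coordinates. Lines must all have the same field count.
#'
#' @param path path to a UTF-8 text file.
#' @param modality label stored on the returned system.
#' @param lowercase lowercase tokens on read (WordBank items and GloVe-6B
#'   vocabularies are lowercase); duplicate tokens after lowercasing are an
#'   error.
#' @return An [embedding_system()].
#' @export
load_embeddings <- function(path, modality = "linguistic", lowercase = TRUE) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) stop("empty embedding file: ", path)
  fields <- strsplit(trimws(lines), "[[:space:]]+")
  counts <- lengths(fields)
  if (length(unique(counts)) != 1) {
    bad <- which(counts != counts[1])[1]
    stop(sprintf("ragged embedding file: line %d has %d fields, expected %d",
                 bad, counts[bad], counts[1]))
  }
  if (counts[1] < 2) stop("embedding lines need a token and at least one coordinate")
  tokens <- vapply(fields, `[[`, character(1), 1)
  if (lowercase) tokens <- tolower(tokens)
  coords <- t(vapply(fields, function(f) {
    v <- suppressWarnings(as.numeric(f[-1]))
    v
  }, numeric(counts[1] - 1)))
  if (counts[1] == 2) coords <- matrix(coords, ncol = 1)
  if (any(is.na(coords))) {
    bad <- which(apply(is.na(coords), 1, any))[1]
    stop(sprintf("non-numeric coordinate on line %d (token '%s')", bad, tokens[bad]))
  }
  embedding_system(coords, tokens, modality)
}

#' Write embeddings in the GloVe text dialect
#'
#' @param system an [embedding_system()].
#' @param path output file path.
#' @param digits significant digits for coordinates.
#' @export
write_embeddings <- function(system, path, digits = 12) {
  stopifnot(inherits(system, "embedding_system"))
  lines <- vapply(seq_along(system$concepts), function(i) {
    paste(c(system$concepts[i],
            formatC(system$vectors[i, ], digits = digits, format = "g")),
          collapse = " ")
  }, character(1))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Intersect a visual and a linguistic system on their shared vocabulary
#'
#' Restricts both systems to the concepts present in both, ordered by the
#' linguistic system's order so downstream sampling is reproducible.
#'
#' @param visual,linguistic [embedding_system()] objects.
#' @return An object of class `system_pair` with fields `visual`,
#'   `linguistic` (both restricted) and `shared_concepts`.
#' @export
intersect_systems <- function(visual, linguistic) {
  stopifnot(inherits(visual, "embedding_system"),
            inherits(linguistic, "embedding_system"))
  shared <- linguistic$concepts[linguistic$concepts %in% visual$concepts]
  if (length(shared) == 0) stop("empty intersection between systems")
  restrict <- function(sys) {
    embedding_system(sys$vectors[shared, , drop = FALSE], shared, sys$modality)
  }
  structure(
    list(visual = restrict(visual), linguistic = restrict(linguistic),
         shared_concepts = shared),
    class = "system_pair"
  )
}

#' @export
print.system_pair <- function(x, ...) {
  cat(sprintf("<system_pair: %d shared concepts (visual D=%d, linguistic D=%d)>\n",
              length(x$shared_concepts), x$visual$dim, x$linguistic$dim))
  invisible(x)
}

#' Pairwise interconcept distance matrix of a system
#'
#' @param system an [embedding_system()].
#' @param metric `"euclidean"` (L2 on raw coordinates, the default) or
#'   `"cosine"` (1 - cosine similarity).
#' @return An object of class `dist_matrix`: a symmetric zero-diagonal matrix
#'   with concept dimnames and a `metric` attribute.
#' @export
pairwise_distances <- function(system, metric = c("euclidean", "cosine")) {
  stopifnot(inherits(system, "embedding_system"))
  metric <- match.arg(metric)
  v <- system$vectors
  if (metric == "euclidean") {
    d <- as.matrix(stats::dist(v, method = "euclidean"))
  } else {
    nrm <- sqrt(rowSums(v^2))
    if (any(nrm == 0)) {
      stop("zero-norm vector under cosine metric: ",
           paste(system$concepts[nrm == 0], collapse = ", "))
    }
    sim <- (v %*% t(v)) / outer(nrm, nrm)
    d <- 1 - sim
    d[d < 0] <- 0  # clip fp noise
    diag(d) <- 0
  }
  dimnames(d) <- list(system$concepts, system$concepts)
  structure(d, metric = metric, class = c("dist_matrix", "matrix", "array"))
}
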