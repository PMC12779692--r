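#' Manhattan distance between descriptor vectors
#'
#' \deqn{d(x, y) = \sum_s |x_s - y_s|}
#' over the components of two equal-length descriptor vectors.
#'
#' @param x,y numeric vectors of equal length.
#' @return non-negative distance (dimensionless).
#' @export
manhattan_distance <- function(x, y) {
  stopifnot(is.numeric(x), is.numeric(y))
  if (length(x) != length(y))
    stop("descriptor vectors must have equal length")
  sum(abs(x - y))
}

#' Conformer-set container
#'
#' @param molecule_id identifier.
#' @param vectors numeric matrix, one row per conformer ordered by stability
#'   rank (most stable first), one column per descriptor component.
#' @return object of class `conformer_vectors`.
#' @export
conformer_vectors <- function(molecule_id, vectors) {
  vectors <- as.matrix(vectors)
  stopifnot(is.numeric(vectors), nrow(vectors) >= 1)
  structure(list(molecule_id = molecule_id, vectors = vectors),
            class = "conformer_vectors")
}

#' Molecule-level Manhattan similarity over conformer sets
#'
#' Computes the Manhattan distance between each rank-aligned conformer pair
#' (conformer i of x against conformer i of y, both lists truncated to the
#' shorter and to `n_conformers`) and aggregates by the minimum: the
#' best-matching conformer pair defines the molecule-level distance.
#'
#' @param x,y `conformer_vectors` objects with equal component counts.
#' @param n_conformers maximum conformers compared (default 18).
#' @return list with `distance` (the minimum), `per_conformer` (vector of
#'   aligned-pair distances) and `n_conformers_used`.
#' @export
conformer_distance <- function(x, y, n_conformers = 18) {
  stopifnot(inherits(x, "conformer_vectors"), inherits(y, "conformer_vectors"))
  if (ncol(x$vectors) != ncol(y$vectors))
    stop("descriptor vectors must have equal length")
  s <- min(nrow(x$vectors), nrow(y$vectors), n_conformers)
  d <- vapply(seq_len(s), function(i)
    manhattan_distance(x$vectors[i, ], y$vectors[i, ]), numeric(1))
  list(distance = min(d), per_conformer = d, n_conformers_used = s)
}

#' Symmetric molecule-by-molecule distance matrix
#'
#' @param sets list of `conformer_vectors`.
#' @param n_conformers passed to [conformer_distance()].
#' @return symmetric numeric matrix with molecule ids as dimnames.
#' @export
conformer_distance_matrix <- function(sets, n_conformers = 18) {
  n <- length(sets)
  ids <- vapply(sets, function(s) as.character(s$molecule_id), character(1))
  m <- matrix(0, n, n, dimnames = list(ids, ids))
  if (n > 1) {
    for (i in seq_len(n - 1)) for (j in seq(i + 1, n)) {
      m[i, j] <- m[j, i] <-
        conformer_distance(sets[[i]], sets[[j]], n_conformers)$distance
    }
  }
  m
}
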