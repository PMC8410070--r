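# Cross-dataset EC-subtype similarity: Jaccard coefficients over top-k
# marker sets, a classical (Torgerson) multidimensional-scaling embedding of
# the resulting dissimilarities, and congruent-marker intersections. Symbol
# comparison is case-normalized so atlases with different capitalization
# conventions can be compared directly.

#' Jaccard similarity of two gene sets
#'
#' @param a,b [gene_set()] / [marker_set()] objects or character vectors
#'   (nonempty).
#' @return `|a n b| / |a u b|`, computed on case-normalized symbols.
#' @export
jaccard <- function(a, b) {
  ga <- unique(toupper(genes_of(a)))
  gb <- unique(toupper(genes_of(b)))
  if (!length(ga) || !length(gb)) stop("gene sets must be nonempty")
  length(intersect(ga, gb)) / length(union(ga, gb))
}

#' Pairwise Jaccard matrix over marker sets
#'
#' @param sets named list of marker/gene sets; names are the
#'   dataset-qualified cluster labels (e.g. `"GBM.Co1"`, `"lung.tip"`) and
#'   must be unique.
#' @return List of class `similarity_matrix` with `J` (symmetric, unit
#'   diagonal, values in \[0, 1\]) and `labels`.
#' @export
jaccard_matrix <- function(sets) {
  if (length(sets) < 2) stop("need at least 2 sets")
  labels <- names(sets)
  if (is.null(labels) || any(!nzchar(labels)))
    labels <- vapply(sets, function(s)
      if (inherits(s, "marker_set")) s$cluster else genes_of(s)[1], character(1))
  if (anyDuplicated(labels))
    stop("duplicate qualified labels: ",
         fmt_list(unique(labels[duplicated(labels)])))
  n <- length(sets)
  J <- diag(1, n)
  dimnames(J) <- list(labels, labels)
  for (i in seq_len(n - 1))
    for (j in seq(i + 1, n))
      J[i, j] <- J[j, i] <- jaccard(sets[[i]], sets[[j]])
  structure(list(J = J, labels = labels), class = "similarity_matrix")
}

#' Classical multidimensional scaling of a similarity matrix
#'
#' Torgerson's procedure on the dissimilarity `d = 1 - J` (or
#' `sqrt(1 - J)`): square and double-center `-d^2/2`, eigendecompose, and
#' scale the top eigenvectors by the square roots of their (nonnegative-
#' clamped) eigenvalues. Negative eigenvalue mass — possible because
#' `1 - J` need not be Euclidean — is clamped to zero and reported. Axis
#' signs are fixed by making each axis's largest-magnitude loading
#' positive, so output files are reproducible across platforms.
#'
#' @param S a [jaccard_matrix()] result, or a symmetric dissimilarity
#'   matrix (used as `d` directly).
#' @param dims embedding dimensionality (default 2; must be < points).
#' @param transform similarity-to-distance transform when `S` is a
#'   similarity: `"one_minus"` (default) or `"sqrt_one_minus"`.
#' @return List of class `mds_embedding` with `coordinates` (points x
#'   dims), `eigenvalues` (descending, full spectrum), `stress` (relative
#'   error of the embedded distances), `clamped_mass` (total negative
#'   eigenvalue mass set to zero).
#' @export
classical_mds <- function(S, dims = 2,
                          transform = c("one_minus", "sqrt_one_minus")) {
  transform <- match.arg(transform)
  if (inherits(S, "similarity_matrix")) {
    d <- 1 - S$J
    if (transform == "sqrt_one_minus") d <- sqrt(d)
    labels <- S$labels
  } else {
    d <- as.matrix(S)
    labels <- rownames(d) %||% as.character(seq_len(nrow(d)))
  }
  n <- nrow(d)
  if (dims < 1) stop("dims must be >= 1")
  if (dims >= n) stop("dims (", dims, ") must be smaller than points (", n, ")")
  # double-center -d^2/2: subtracting row means, then column means of the
  # row-centered matrix, equals (I - 11'/n) B (I - 11'/n)
  B <- -0.5 * d^2
  B <- sweep(B, 1, rowMeans(B))
  B <- sweep(B, 2, colMeans(B))
  eig <- eigen((B + t(B)) / 2, symmetric = TRUE)
  lambda <- eig$values
  clamped <- sum(pmin(lambda, 0))
  lam_pos <- pmax(lambda[seq_len(dims)], 0)
  coords <- eig$vectors[, seq_len(dims), drop = FALSE] %*%
    diag(sqrt(lam_pos), dims)
  for (j in seq_len(dims)) {
    i_max <- which.max(abs(coords[, j]))
    if (coords[i_max, j] < 0) coords[, j] <- -coords[, j]
  }
  rownames(coords) <- labels
  colnames(coords) <- paste0("MDS", seq_len(dims))
  dhat <- as.matrix(dist(coords))
  stress <- if (sum(d^2) > 0) sqrt(sum((dhat - d)^2) / sum(d^2)) else 0
  structure(list(coordinates = coords, eigenvalues = lambda,
                 stress = stress, clamped_mass = abs(clamped)),
            class = "mds_embedding")
}

#' Congruent markers of two clusters
#'
#' Ordered intersection of two marker sets (order taken from the first
#' set's ranking), i.e. the genes reported as top markers in both atlases.
#'
#' @param a,b marker/gene sets or character vectors.
#' @return Character vector, possibly empty, in `a`'s order; matching is
#'   case-normalized but `a`'s original symbols are returned.
#' @export
congruent_markers <- function(a, b) {
  ga <- genes_of(a); gb <- toupper(genes_of(b))
  if (!length(ga) || !length(gb)) stop("marker sets must be nonempty")
  ga[toupper(ga) %in% gb]
}
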