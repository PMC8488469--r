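#' Fit an SVD projector on a descriptor matrix
#'
#' Centers the n x p descriptor matrix on its column means and keeps the
#' top-k right singular directions of the centered matrix (by default
#' k = 300 for the 400-d DHT descriptors, the noise-reduction step of the
#' pipeline). The basis is sign-canonicalised — the largest-magnitude
#' entry of each column is made positive — so fits are reproducible across
#' linear-algebra backends.
#'
#' @param X Numeric n x p matrix (rows = per-protein descriptors).
#' @param k Target dimension; silently capped at `min(n, p)` with a
#'   warning when larger.
#' @return An object of class `svd_projector` with fields `mean` (p),
#'   `basis` (p x k, orthonormal columns) and `explained` (k singular
#'   values, non-increasing).
#' @export
fit_projector <- function(X, k = 300L) {
  X <- as.matrix(X)
  if (!all(is.finite(X))) stop("descriptor matrix contains non-finite values")
  n <- nrow(X); p <- ncol(X)
  if (n < 1L) stop("need at least one descriptor row")
  k <- as.integer(k)
  if (is.na(k) || k < 1L) stop("k must be a positive integer")
  kmax <- min(n, p)
  if (k > kmax) {
    warning("k = ", k, " capped at min(n, p) = ", kmax)
    k <- kmax
  }
  mu <- colMeans(X)
  Xc <- sweep(X, 2L, mu)
  sv <- svd(Xc, nu = 0L, nv = k)
  basis <- sv$v
  # canonical signs: largest-|entry| of each direction is positive
  for (j in seq_len(ncol(basis))) {
    i <- which.max(abs(basis[, j]))
    if (basis[i, j] < 0) basis[, j] <- -basis[, j]
  }
  structure(list(mean = mu, basis = basis, explained = sv$d[seq_len(k)],
                 k = k, p = p),
            class = "svd_projector")
}

#' @export
print.svd_projector <- function(x, ...) {
  cat(sprintf("<svd_projector> %d -> %d (top singular value %.4g)\n",
              x$p, x$k, x$explained[1L]))
  invisible(x)
}

#' Project a descriptor onto the fitted SVD basis
#'
#' Computes `t(basis) %*% (d - mean)`: the centred descriptor's
#' coordinates in the top-k singular directions.
#'
#' @param projector An [fit_projector()] result.
#' @param d A single descriptor vector of length `projector$p`, or an
#'   n x p matrix of descriptors (rows are projected independently).
#' @return A length-k vector, or an n x k matrix for matrix input.
#' @export
project <- function(projector, d) {
  stopifnot(inherits(projector, "svd_projector"))
  if (is.matrix(d)) {
    if (ncol(d) != projector$p)
      stop("descriptor has ", ncol(d), " columns, expected ", projector$p)
    return(sweep(d, 2L, projector$mean) %*% projector$basis)
  }
  d <- as.numeric(d)
  if (length(d) != projector$p)
    stop("descriptor has length ", length(d), ", expected ", projector$p)
  as.numeric(crossprod(projector$basis, d - projector$mean))
}

#' Concatenate two reduced descriptors into a pair descriptor
#'
#' A protein pair is represented by the concatenation `[a; b]` of the two
#' reduced per-protein descriptors in the pair's listed order (600-d at
#' the default k = 300).
#'
#' @param a,b Reduced descriptors of equal length.
#' @return Numeric vector of length `2 * length(a)`.
#' @export
pair_descriptor <- function(a, b) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) != length(b))
    stop("reduced descriptors differ in length: ", length(a),
         " vs ", length(b))
  c(a, b)
}
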