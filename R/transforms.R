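# Frequency-domain weights for the discrete analytic signal of length n:
# h(0)=1, h(k)=2 for 0<k<n/2, h(n/2)=1 for even n, h(k)=0 above n/2.
analytic_weights <- function(n) {
  h <- numeric(n)
  h[1L] <- 1
  if (n %% 2L == 0L) {
    h[n / 2L + 1L] <- 1
    if (n > 2L) h[2:(n / 2L)] <- 2
  } else if (n > 1L) {
    h[2:((n + 1L) / 2L)] <- 2
  }
  h
}

#' 1-D discrete Hilbert transform (analytic signal)
#'
#' Computes the discrete-time analytic signal `x + i * H(x)` of a real
#' vector via the standard frequency-domain construction: forward DFT,
#' zeroing of negative-frequency coefficients (with the DC and, for even
#' lengths, Nyquist bins kept at unit weight and positive frequencies
#' doubled), inverse DFT. The real part of the result equals the input and
#' the spectrum of the result is one-sided.
#'
#' @param x Real input vector. A complex input has its imaginary part
#'   discarded with a warning.
#' @param n Transform length (default `length(x)`); `x` is zero-padded or
#'   truncated to `n`.
#' @return Complex vector of length `n`, the analytic signal.
#' @examples
#' t <- 0:15
#' a <- dht1(cos(2 * pi * t / 16))
#' max(abs(Im(a) - sin(2 * pi * t / 16)))  # quadrature pair, ~1e-16
#' @export
dht1 <- function(x, n = length(x)) {
  n <- as.integer(n)
  if (is.na(n) || n < 1L) stop("n must be a positive integer")
  if (is.complex(x)) {
    warning("dht1 ignores imaginary part of input")
    x <- Re(x)
  }
  x <- as.numeric(x)
  if (length(x) < n) x <- c(x, numeric(n - length(x)))
  if (length(x) > n) x <- x[seq_len(n)]
  X <- stats::fft(x)
  stats::fft(X * analytic_weights(n), inverse = TRUE) / n
}

#' 2-D discrete Hilbert transform of a condensed profile
#'
#' Computes the separable single-orthant 2-D discrete analytic signal of a
#' 20 x 20 real matrix: 2-D DFT, multiplication of coefficient (u, v) by
#' `h(u) * h(v)` with `h` the 1-D analytic-signal weights, inverse 2-D
#' DFT. Because the weight mask is a tensor product, this is exactly
#' equivalent to applying [dht1()] to every column and then to every row
#' of the result.
#'
#' @param M A 20 x 20 real matrix (a `condensed_matrix` or plain matrix).
#' @return A 20 x 20 complex matrix, the 2-D analytic signal.
#' @export
dht2 <- function(M) {
  M <- unclass(as.matrix(M))
  if (nrow(M) != 20L || ncol(M) != 20L)
    stop("dht2 expects a 20 x 20 matrix, got ", nrow(M), " x ", ncol(M))
  if (is.complex(M)) {
    warning("dht2 ignores imaginary part of input")
    M <- Re(M)
  }
  storage.mode(M) <- "double"
  h <- analytic_weights(20L)
  mask <- outer(h, h)
  X <- stats::fft(M)
  stats::fft(X * mask, inverse = TRUE) / length(M)
}

#' 400-dimensional local-energy descriptor via the 2-D DHT
#'
#' The per-protein feature vector: the element-wise local energy of the
#' 2-D analytic signal of the condensed profile, flattened row-major into
#' a 400-dimensional non-negative vector. Local energy is the modulus of
#' the complex analytic signal (or its square, if `energy = "squared"`).
#'
#' @param M A 20 x 20 condensed profile matrix.
#' @param energy `"modulus"` (default) or `"squared"`.
#' @return Numeric vector of length 400, class `protein_descriptor` with
#'   attribute `kind = "dht"`.
#' @export
dht_features <- function(M, energy = c("modulus", "squared")) {
  energy <- match.arg(energy)
  A <- dht2(M)
  e <- Mod(A)
  if (energy == "squared") e <- e^2
  descriptor(as.vector(t(e)), kind = "dht")
}

descriptor <- function(values, kind) {
  structure(as.numeric(values), kind = kind, class = "protein_descriptor")
}

# Orthonormal DCT-II basis matrix of size n.
dct_matrix <- function(n) {
  C <- sqrt(2 / n) * cos(outer(0:(n - 1), (2 * (0:(n - 1)) + 1) * pi / (2 * n)))
  C[1, ] <- C[1, ] / sqrt(2)
  C
}

#' Comparator feature descriptors: DCT, FFT, Haar DWT, auto-covariance
#'
#' Alternative feature extractors used to benchmark the DHT local-energy
#' descriptor:
#' \describe{
#'   \item{`dct`}{2-D orthonormal DCT-II coefficients of the 20 x 20
#'     matrix, row-major flatten; 400-d.}
#'   \item{`fft`}{Modulus of the 2-D DFT, row-major flatten; 400-d.}
#'   \item{`dwt`}{Single-level 2-D Haar decomposition; the four 10 x 10
#'     subbands (LL, LH, HL, HH) flattened row-major and concatenated;
#'     400-d.}
#'   \item{`ac`}{Column-wise auto-covariance of the *pre-condensation*
#'     U x 20 profile at lags 1..g:
#'     `AC(j, g) = sum_t (P[t,j] - mean_j) * (P[t+g,j] - mean_j) / (U - g)`;
#'     returned lag-major (20 values for lag 1, then lag 2, ...); 20*g-d.}
#' }
#'
#' @param M For `dct`, `fft`, `dwt`: a 20 x 20 condensed matrix. For
#'   `ac`: the U x 20 `ppi_profile` itself.
#' @param kind Which comparator to compute.
#' @param ac_lag Maximum auto-covariance lag g (default 5).
#' @return A `protein_descriptor` of the stated dimension.
#' @export
alt_features <- function(M, kind = c("dct", "fft", "dwt", "ac"),
                         ac_lag = 5L) {
  kind <- match.arg(kind)
  if (kind == "ac") {
    P <- unclass(as.matrix(M))
    if (ncol(P) != 20L) stop("ac expects a U x 20 profile")
    g <- as.integer(ac_lag)
    U <- nrow(P)
    if (U <= g)
      stop("auto-covariance needs more rows (U = ", U,
           ") than the lag (g = ", g, "); use a smaller ac_lag")
    mu <- colMeans(P)
    Pc <- sweep(P, 2L, mu)
    vals <- unlist(lapply(seq_len(g), function(l) {
      idx <- seq_len(U - l)
      colSums(Pc[idx, , drop = FALSE] * Pc[idx + l, , drop = FALSE]) / (U - l)
    }))
    return(descriptor(vals, kind = "ac"))
  }
  M <- unclass(as.matrix(M))
  if (nrow(M) != 20L || ncol(M) != 20L)
    stop(kind, " expects a 20 x 20 matrix")
  vals <- switch(kind,
    dct = {
      C <- dct_matrix(20L)
      as.vector(t(C %*% M %*% t(C)))
    },
    fft = as.vector(t(Mod(stats::fft(M)))),
    dwt = {
      odd <- seq(1L, 19L, by = 2L); even <- odd + 1L
      lo_r <- (M[odd, ] + M[even, ]) / sqrt(2)   # rows: low-pass
      hi_r <- (M[odd, ] - M[even, ]) / sqrt(2)   # rows: high-pass
      ll <- (lo_r[, odd] + lo_r[, even]) / sqrt(2)
      lh <- (lo_r[, odd] - lo_r[, even]) / sqrt(2)
      hl <- (hi_r[, odd] + hi_r[, even]) / sqrt(2)
      hh <- (hi_r[, odd] - hi_r[, even]) / sqrt(2)
      c(as.vector(t(ll)), as.vector(t(lh)),
        as.vector(t(hl)), as.vector(t(hh)))
    })
  descriptor(vals, kind = kind)
}
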