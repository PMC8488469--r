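# Shared fixture builders; everything is generated in code at test time.

# Bare numeric values of a profile, attributes stripped, for comparisons
# across sources (pssm vs synthetic vs smr).
profile_values <- function(p) {
  m <- as.matrix(p)
  array(as.numeric(m), dim = dim(m))
}

random_profile <- function(U = 30L, seed = 1L) {
  set.seed(seed)
  new_profile(matrix(round(rnorm(U * 20L, 0, 3)), U, 20L),
              source = "synthetic")
}

# Small but non-trivial synthetic dataset for pipeline-level unit tests.
tiny_dataset <- function(seed = 7L) {
  gen_dataset(synth_config(n_proteins = 24L, length_range = c(30L, 60L),
                           n_pos = 40L, n_neg = 40L,
                           signal_strength = 2, seed = seed))
}

# Fast classifier settings for pipeline-shape tests (not for accuracy).
fast_config <- function(...) {
  cfg <- default_config()
  cfg$dnn$epochs <- 15L
  cfg$dnn$hidden <- c(16L, 16L)
  cfg$svd$k <- 25L
  more <- list(...)
  for (nm in names(more)) cfg[[nm]] <- utils::modifyList(cfg[[nm]], more[[nm]])
  cfg
}

# 1-D analytic signal reference that keeps complex intermediates, used to
# verify the separable 2-D transform by sequential application.
analytic_1d_complex <- function(x) {
  n <- length(x)
  h <- dhtppi:::analytic_weights(n)
  stats::fft(stats::fft(x) * h, inverse = TRUE) / n
}

# Linearly separable two-blob toy problem.
blob_data <- function(n = 200L, seed = 42L) {
  set.seed(seed)
  half <- n %/% 2L
  X <- rbind(matrix(rnorm(half * 2L, mean = -2), ncol = 2L),
             matrix(rnorm((n - half) * 2L, mean = 2), ncol = 2L))
  y <- c(rep(0L, half), rep(1L, n - half))
  ord <- sample.int(n)
  list(X = X[ord, ], y = y[ord])
}
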