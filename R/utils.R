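# Internal helpers shared across modules.

# Counter-based sub-seed fan-out: subject/run-level reproducibility independent
# of the order in which subjects are generated. Multipliers kept small so the
# arithmetic stays exact in doubles; result always in [1, 2^31 - 2].
subseed <- function(seed, index, salt = 0L) {
  s <- (as.numeric(seed) %% 2147483629) * 69069 +
    as.numeric(index) * 30011 + as.numeric(salt) * 7919
  as.integer(s %% 2147483629) + 1L
}

# Unit-variance AR(1)-colored Gaussian noise, one column per series.
ar1_noise <- function(n, k, phi) {
  w <- matrix(stats::rnorm(n * k), n, k)
  if (phi == 0) return(w)
  x <- apply(w, 2, function(col) stats::filter(col, phi, method = "recursive"))
  matrix(x, n, k) * sqrt(1 - phi^2)
}

# Discrete cosine basis columns k (DCT-II on frame index), frequency of column
# k is k / (2 * n * tr) Hz.
dct_basis <- function(n, ks) {
  t <- seq_len(n) - 0.5
  vapply(ks, function(k) cos(pi * t * k / n), numeric(n))
}

dct_frequencies <- function(n, tr) seq_len(n - 1) / (2 * n * tr)

center_cols <- function(m) sweep(m, 2, colMeans(m), "-")

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(...) stop(sprintf(...), call. = FALSE)

# Fisher transform and inverse.
fisher_z <- function(r) atanh(r)
fisher_r <- function(z) tanh(z)

off_diag <- function(m) m[upper.tri(m)]
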