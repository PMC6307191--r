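# Small shared fixtures, built in code.

tiny_params <- function(...) {
  args <- list(n_frames_per_run = 200L, n_runs = 1L, seed = 42L)
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(sim_params, args)
}

tiny_geometry <- function(params = tiny_params()) {
  atlas <- build_symmetric_parcellation(params)
  list(params = params, atlas = atlas,
       masks = build_tissue_masks(params, atlas))
}

tiny_phenotype <- function(id = "sub-NT01", group = "NT", iq = 110) {
  list(subject_id = id, group = group, age_years = 11, sex = "M",
       iq_composite = iq)
}

# Brute-force censoring oracle: a frame is dropped iff it belongs to
# {t - 1, t} for any transition t with FD(t) > threshold.
censor_oracle <- function(fd, threshold = 0.2) {
  n <- length(fd)
  keep <- logical(n)
  for (f in seq_len(n))
    keep[f] <- !any(vapply(which(fd > threshold),
                           function(t) f %in% c(t - 1L, t), logical(1)))
  keep
}

# Brute-force 6-neighborhood erosion oracle.
erode_oracle <- function(mask) {
  d <- dim(mask)
  out <- array(FALSE, d)
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3])) {
    if (!mask[i, j, k]) next
    nb <- rbind(c(i - 1, j, k), c(i + 1, j, k), c(i, j - 1, k),
                c(i, j + 1, k), c(i, j, k - 1), c(i, j, k + 1))
    inside <- all(nb[, 1] >= 1 & nb[, 1] <= d[1] &
                  nb[, 2] >= 1 & nb[, 2] <= d[2] &
                  nb[, 3] >= 1 & nb[, 3] <= d[3])
    out[i, j, k] <- inside && all(mask[nb])
  }
  out
}

# Brute-force Benjamini-Hochberg step-up q values.
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- numeric(m)
  ps <- p[o]
  for (i in seq_len(m)) q_sorted[i] <- min(m * ps[i:m] / (i:m), 1)
  q <- numeric(m)
  q[o] <- q_sorted
  q
}

# Two columns with exact sample correlation r (Gram-Schmidt construction).
exact_corr_pair <- function(n, r, seed = 1L) {
  set.seed(seed)
  x <- stats::rnorm(n)
  e <- stats::rnorm(n)
  x <- (x - mean(x)) / stats::sd(x)
  e <- stats::residuals(stats::lm(e ~ x))
  e <- e / stats::sd(e)
  cbind(x = x, y = r * x + sqrt(1 - r^2) * e)
}
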