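# Independent oracles used to cross-check the implementation.

# Brute-force concordance AUC: fraction of active-decoy pairs in which the
# active scores lower (better), ties counted one half. Percent scale.
auc_paircount <- function(lib) {
  a <- lib$score[lib$label == "active"]
  d <- lib$score[lib$label == "decoy"]
  cmp <- outer(a, d, function(x, y) (x < y) + 0.5 * (x == y))
  100 * mean(cmp)
}

# Two-site exchange spectrum via the time domain: propagate the FID
# s(t) = 1' exp(G t) p with G = diag(2 pi i nu_j - R2_j) + K, then discrete
# Fourier transform onto the requested frequency grid. Independent of the
# frequency-domain matrix inversion used by simulate_lineshape().
lineshape_fft_oracle <- function(params, pb, grid, t_max = 2, n_t = 2^14) {
  kab <- if (pb >= 1) Inf else params$koff * pb / (1 - pb)
  kba <- params$koff
  G <- matrix(c(2i * pi * params$nu_apo - params$R2_apo - kab, kba,
                kab, 2i * pi * params$nu_holo - params$R2_holo - kba),
              2, 2, byrow = TRUE)
  p0 <- c(1 - pb, pb)
  eg <- eigen(G)
  coef <- solve(eg$vectors, p0)
  tt <- seq(0, t_max, length.out = n_t)
  modes <- colSums(eg$vectors) * coef     # s(t) = sum_k modes_k exp(lambda_k t)
  s <- sapply(eg$values, function(l) exp(l * tt)) %*% modes
  dt <- tt[2] - tt[1]
  vapply(grid, function(nu) {
    w <- rep(dt, n_t); w[1] <- dt / 2; w[n_t] <- dt / 2   # trapezoid
    Re(sum(w * s * exp(-2i * pi * nu * tt)))
  }, numeric(1))
}

# Random scored library with optional score ties (rounding).
random_library <- function(n_act, n_dec, round_digits = Inf) {
  sc <- stats::rnorm(n_act + n_dec)
  if (is.finite(round_digits)) sc <- round(sc, round_digits)
  scored_library(sprintf("c%04d", seq_len(n_act + n_dec)), sc,
                 rep(c("active", "decoy"), c(n_act, n_dec)))
}
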