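# Independent brute-force oracles used across test files.

# Pooled-variance two-sample t from the defining formulas.
brute_t_pooled <- function(a, b) {
  na <- length(a); nb <- length(b)
  sp2 <- ((na - 1) * var(a) + (nb - 1) * var(b)) / (na + nb - 2)
  t <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / na + 1 / nb))
  df <- na + nb - 2
  list(t = t, df = df, p = 2 * pt(-abs(t), df))
}

# Welch t with Satterthwaite df from the defining formulas.
brute_t_welch <- function(a, b) {
  na <- length(a); nb <- length(b)
  va <- var(a) / na; vb <- var(b) / nb
  t <- (mean(a) - mean(b)) / sqrt(va + vb)
  df <- (va + vb)^2 / (va^2 / (na - 1) + vb^2 / (nb - 1))
  list(t = t, df = df, p = 2 * pt(-abs(t), df))
}

# One-way ANOVA F from the sum-of-squares decomposition.
brute_anova_F <- function(groups) {
  y <- unlist(groups)
  k <- length(groups); n <- length(y)
  ssb <- sum(sapply(groups, function(v) length(v) * (mean(v) - mean(y))^2))
  ssw <- sum(sapply(groups, function(v) sum((v - mean(v))^2)))
  (ssb / (k - 1)) / (ssw / (n - k))
}

# Frame mean of a fine-grid curve by direct trapezoidal summation,
# independent of the package's cumulative-integral path.
brute_frame_mean <- function(times, values, t0, t1) {
  sel <- times >= t0 - 1e-12 & times <= t1 + 1e-12
  tt <- times[sel]; vv <- values[sel]
  sum(diff(tt) * (vv[-1] + vv[-length(vv)]) / 2) / (t1 - t0)
}

# Random positive semi-definite tensor (A A', scaled to diffusivity range).
random_psd_tensor <- function() {
  a <- matrix(rnorm(9), 3, 3)
  d <- (a %*% t(a)) * 1e-4
  cordquant_mat_to_6(d)
}

cordquant_mat_to_6 <- function(m) c(m[1, 1], m[2, 2], m[3, 3], m[1, 2], m[1, 3], m[2, 3])

cordquant_6_to_mat <- function(v) {
  matrix(c(v[1], v[4], v[5], v[4], v[2], v[6], v[5], v[6], v[3]), 3, 3)
}

# Random 3D rotation via QR of a Gaussian matrix (det forced to +1).
random_rotation <- function() {
  q <- qr.Q(qr(matrix(rnorm(9), 3, 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}
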