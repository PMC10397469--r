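# Truncated-normal helpers for the cohort generator. All take the parent
# (untruncated) mean/sd plus truncation bounds in data units; bounds may be
# +/-Inf.

.tn_moments <- function(mu, sigma, lo, hi) {
  a <- (lo - mu) / sigma
  b <- (hi - mu) / sigma
  Z <- pnorm(b) - pnorm(a)
  if (Z < 1e-10) {
    stop("truncation region carries almost no probability mass")
  }
  da <- dnorm(a)
  db <- dnorm(b)
  ta <- if (is.finite(a)) a * da else 0
  tb <- if (is.finite(b)) b * db else 0
  m <- mu + sigma * (da - db) / Z
  v <- sigma^2 * (1 + (ta - tb) / Z - ((da - db) / Z)^2)
  list(mean = m, var = max(v, 0), plo = pnorm(a), phi = pnorm(b), Z = Z)
}

# Quantile of the truncated normal at u in [0,1].
.tn_quantile <- function(u, mu, sigma, lo, hi) {
  plo <- pnorm(lo, mu, sigma)
  phi <- pnorm(hi, mu, sigma)
  p <- plo + u * (phi - plo)
  qnorm(pmin(pmax(p, 1e-14), 1 - 1e-14), mu, sigma)
}

# cov(z, q(Phi(z))) where z is standard normal and q the truncated-normal
# quantile: the covariance between a standard-normal copula coordinate and
# the truncated margin it drives. Computed by 1-D quadrature.
.tn_gamma <- function(mu, sigma, lo, hi) {
  f <- function(z) z * .tn_quantile(pnorm(z), mu, sigma, lo, hi) * dnorm(z)
  integrate(f, -8, 8, subdivisions = 400L, rel.tol = 1e-9)$value
}

# Truncation region (in anchor-change units) of a class for a
# change-threshold anchor definition.
.class_region <- function(anchor_def, class) {
  thr <- anchor_def$threshold
  s <- anchor_def$improvement_sign
  switch(class,
    improved = if (s > 0) c(thr, Inf) else c(-Inf, -thr),
    worsened = if (s > 0) c(-Inf, -thr) else c(thr, Inf),
    stable = c(-thr, thr),
    stop("unknown class '", class, "'")
  )
}
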