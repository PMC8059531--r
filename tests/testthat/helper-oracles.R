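# Independent oracles, deliberately written along different routes than
# the package implementation.

# Exact lower-tail binomial probability by direct summation of the pmf,
# with each term computed from log binomial coefficients.
binom_lower_tail_oracle <- function(k, n, p) {
  j <- 0:k
  sum(exp(lchoose(n, j) + j * log(p) + (n - j) * log1p(-p)))
}

# From-scratch least squares of y on x via the normal equations,
# returning slope, its standard error and the two-sided t-test p-value.
ols_oracle <- function(x, y) {
  X <- cbind(1, x)
  XtX <- t(X) %*% X
  beta <- solve(XtX, t(X) %*% y)
  res <- y - X %*% beta
  df <- length(y) - 2L
  s2 <- sum(res^2) / df
  covb <- s2 * solve(XtX)
  slope <- beta[2L]
  se <- sqrt(covb[2L, 2L])
  tval <- slope / se
  list(slope = slope, stderr = se, t_stat = tval,
       p_value = 2 * stats::pt(-abs(tval), df))
}

# Scalar ray-casting point-in-polygon (boundary treated as inside),
# looping edges one point at a time.
ray_cast_oracle <- function(px, py, ring) {
  if (any(ring[1L, ] != ring[nrow(ring), ])) ring <- rbind(ring, ring[1L, ])
  n <- nrow(ring)
  inside <- FALSE
  for (i in seq_len(n - 1L)) {
    x1 <- ring[i, 1L]; y1 <- ring[i, 2L]
    x2 <- ring[i + 1L, 1L]; y2 <- ring[i + 1L, 2L]
    # boundary
    if (abs((x2 - x1) * (py - y1) - (y2 - y1) * (px - x1)) < 1e-12 &&
        px >= min(x1, x2) - 1e-12 && px <= max(x1, x2) + 1e-12 &&
        py >= min(y1, y2) - 1e-12 && py <= max(y1, y2) + 1e-12)
      return(TRUE)
    if ((y1 > py) != (y2 > py)) {
      xint <- x1 + (py - y1) * (x2 - x1) / (y2 - y1)
      if (px < xint) inside <- !inside
    }
  }
  inside
}

# Repeated substitution to a fixpoint: the transitive closure of a
# synonym table applied to a vector of names.
substitute_to_fixpoint <- function(x, synonyms, max_iter = 100L) {
  for (i in seq_len(max_iter)) {
    idx <- match(x, names(synonyms))
    if (all(is.na(idx))) return(x)
    x[!is.na(idx)] <- unname(synonyms[idx[!is.na(idx)]])
  }
  stop("no fixpoint (cycle?)")
}
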