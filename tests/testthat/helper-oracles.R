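# Independent brute-force oracles used to cross-check the vectorised
# implementations. Deliberately written with plain loops and closed-form
# algebra, no calls into the code paths they verify.

# Type-7 quantile by hand (sorted-order interpolation)
oracle_quantile <- function(x, p) {
  x <- sort(x)
  n <- length(x)
  h <- (n - 1) * p + 1
  lo <- floor(h)
  hi <- ceiling(h)
  x[lo] + (h - lo) * (x[hi] - x[lo])
}

# Loop-based evaluation of the CompPASS statistics from first principles
oracle_compass <- function(X, P, percentile = 98) {
  k <- nrow(X)
  rows <- list()
  for (j in seq_len(ncol(X))) {
    col <- X[, j]
    m <- sum(col) / k
    s <- sqrt(sum((col - m)^2) / (k - 1))
    f <- sum(col > 0)
    omega <- if (m > 0) max(1, s / m) else 1
    for (i in seq_len(k)) {
      if (col[i] > 0) {
        wd <- sqrt(col[i] * ((k / f) * omega)^P[i, j])
        z <- if (s > 0) (col[i] - m) / s else 0
        rows[[length(rows) + 1]] <- data.frame(
          bait = rownames(X)[i], prey = colnames(X)[j],
          WD = wd, Z = z, stringsAsFactors = FALSE)
      }
    }
  }
  df <- do.call(rbind, rows)
  q <- oracle_quantile(df$WD[df$WD > 0], percentile / 100)
  df$NWD <- df$WD / q
  df[order(df$bait, df$prey), ]
}

# Random small stats table with the X>0 <=> p>=1 invariant
random_stats_table <- function(k, n_prey, n_rep = 2) {
  repeat {
    P <- matrix(sample(0:n_rep, k * n_prey, replace = TRUE,
                       prob = c(0.6, 0.2, 0.2)), k, n_prey)
    if (any(P > 0) && all(colSums(P) > 0)) break
  }
  X <- ifelse(P > 0, round(runif(k * n_prey, 0.5, 25), 3), 0)
  dimnames(X) <- list(sprintf("b%02d", seq_len(k)), sprintf("y%02d", seq_len(n_prey)))
  dimnames(P) <- dimnames(X)
  stats_table(X, P, "oracle")
}

# Exhaustive nearest-neighbour distance by double loop
oracle_nearest <- function(p, q) {
  out <- numeric(nrow(p))
  for (i in seq_len(nrow(p))) {
    best <- Inf
    for (j in seq_len(nrow(q))) {
      d <- sqrt((p[i, 1] - q[j, 1])^2 + (p[i, 2] - q[j, 2])^2)
      if (d < best) best <- d
    }
    out[i] <- best
  }
  out
}
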