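# Independent oracles used to cross-check the implementation. These are
# deliberately naive, direct translations of the definitions.

# Random count matrix with gene/sample names.
toy_counts <- function(g = 20, n = 5, mu = 50, size = 5, seed = 1) {
  withr::with_seed(seed, {
    m <- matrix(rnbinom(g * n, mu = mu, size = size), g, n)
    dimnames(m) <- list(sprintf("g%03d", seq_len(g)),
                        sprintf("s%02d", seq_len(n)))
    m
  })
}

# Simplified TMM, translated step by step from the trimmed-mean definition
# (same reference choice, same rank-based double trim, inverse-variance
# weights, product-1 standardization).
tmm_oracle <- function(m) {
  lib <- colSums(m)
  f75 <- apply(m, 2, stats::quantile, probs = 0.75) / lib
  ref <- which.min(abs(f75 - mean(f75)))
  f <- vapply(seq_len(ncol(m)), function(j) {
    obs <- m[, j]
    r <- m[, ref]
    keep <- obs > 0 & r > 0
    obs <- obs[keep]
    r <- r[keep]
    nO <- lib[j]
    nR <- lib[ref]
    logR <- log2((obs / nO) / (r / nR))
    absE <- (log2(obs / nO) + log2(r / nR)) / 2
    v <- (nO - obs) / (nO * obs) + (nR - r) / (nR * r)
    if (max(abs(logR)) < 1e-6) return(1)
    n <- length(logR)
    loL <- floor(n * 0.3) + 1
    hiL <- n + 1 - loL
    loS <- floor(n * 0.05) + 1
    hiS <- n + 1 - loS
    keep2 <- rank(logR) >= loL & rank(logR) <= hiL &
      rank(absE) >= loS & rank(absE) <= hiS
    fj <- 2^(sum(logR[keep2] / v[keep2]) / sum(1 / v[keep2]))
    if (!is.finite(fj)) 1 else fj
  }, numeric(1))
  f / exp(mean(log(f)))
}

# Median-of-ratios size factors, straight from the definition.
rle_oracle <- function(m) {
  pos <- apply(m > 0, 1, all)
  sub <- m[pos, , drop = FALSE]
  ref <- exp(rowMeans(log(sub)))
  f <- apply(sub, 2, function(col) median(col / ref))
  f / exp(mean(log(f)))
}

# Brute-force triple-loop DPI on an adjacency built from the threshold.
dpi_oracle <- function(A, threshold, eps = 0) {
  g <- nrow(A)
  adj <- A >= threshold & A > 0
  diag(adj) <- FALSE
  out <- adj
  for (i in seq_len(g - 1)) {
    for (j in seq.int(i + 1, g)) {
      if (!adj[i, j]) next
      for (k in seq_len(g)) {
        if (k == i || k == j) next
        if (adj[i, k] && adj[j, k] &&
            A[i, j] < min(A[i, k], A[j, k]) - eps) {
          out[i, j] <- out[j, i] <- FALSE
        }
      }
    }
  }
  sym <- rownames(A)
  sel <- which(upper.tri(out) & out, arr.ind = TRUE)
  sort(paste(pmin(sym[sel[, 1]], sym[sel[, 2]]),
             pmax(sym[sel[, 1]], sym[sel[, 2]])))
}

net_keys <- function(net) sort(paste(net$edges$from, net$edges$to))

# Random symmetric association matrix with zero diagonal.
random_assoc <- function(g) {
  A <- matrix(0, g, g)
  A[upper.tri(A)] <- runif(g * (g - 1) / 2)
  A <- A + t(A)
  dimnames(A) <- list(sprintf("n%02d", seq_len(g)),
                      sprintf("n%02d", seq_len(g)))
  A
}

# Plug-in entropy/MI from hard binning, for the B-spline k=1 special case.
plugin_mi <- function(bx, by, bins) {
  p <- table(factor(bx, 1:bins), factor(by, 1:bins)) / length(bx)
  px <- rowSums(p)
  py <- colSums(p)
  sum(p * log(p / outer(px, py)), na.rm = TRUE)
}

# Two vectors whose sample Pearson correlation is exactly r.
exact_corr_pair <- function(n, r, seed = 1) {
  withr::with_seed(seed, {
    x <- rnorm(n)
    e <- rnorm(n)
    e <- residuals(lm(e ~ x))
    x <- scale(x)[, 1]
    e <- scale(e)[, 1]
    list(x = x, y = r * x + sqrt(1 - r^2) * e)
  })
}
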