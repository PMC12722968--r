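# Independent oracles, coded straight from the definitions and kept free of
# the package's internal code paths.

# population SD
oracle_pop_sd <- function(x) sqrt(mean((x - mean(x))^2))

# entropy in bits from a probability vector
oracle_entropy <- function(p) {
  p <- p[p > 0]
  -sum(p * log2(p))
}

# equal-frequency binning written independently: one bin per value when few
# distinct values, else quantile breaks (type 7)
oracle_bins <- function(x, n_bins = 10) {
  ux <- sort(unique(x))
  if (length(ux) <= n_bins) return(match(x, ux))
  br <- unique(quantile(x, seq(0, 1, length.out = n_bins + 1), type = 7,
                        names = FALSE))
  as.integer(cut(x, br, include.lowest = TRUE))
}

# information gain by brute-force enumeration of the joint count table
oracle_ig <- function(x, y, n_bins = 10) {
  b <- oracle_bins(x, n_bins)
  hy <- oracle_entropy(table(y) / length(y))
  hcond <- 0
  for (lev in unique(b)) {
    idx <- b == lev
    hcond <- hcond + mean(idx) * oracle_entropy(table(y[idx]) / sum(idx))
  }
  hy - hcond
}

# pooled-SE standardized class-mean difference, direct per-class arithmetic
oracle_std_diff <- function(x, y) {
  x0 <- x[y == 0]; x1 <- x[y == 1]
  v0 <- mean((x0 - mean(x0))^2); v1 <- mean((x1 - mean(x1))^2)
  abs(mean(x1) - mean(x0)) / sqrt(v0 / length(x0) + v1 / length(x1))
}

# straight-line single-row evaluation of the fuzzy network
oracle_forward <- function(model, x) {
  R <- nrow(model$centers)
  w <- numeric(R)
  for (r in seq_len(R)) {
    mus <- exp(-(x - model$centers[r, ])^2 / (2 * model$widths[r, ]^2))
    w[r] <- prod(mus)
  }
  f <- vapply(seq_len(R),
              function(r) sum(model$p[r, ] * x) + model$q[r], 0)
  wbar <- w / sum(w)
  logits <- as.vector(model$V %*% (wbar * f)) + model$v0
  e <- exp(logits - max(logits))
  e / sum(e)
}

# finite-difference gradient of the network loss for one parameter group
fd_gradient <- function(model, X, y, name, eps = 1e-6) {
  g <- model[[name]] * 0
  for (i in seq_along(model[[name]])) {
    up <- model; up[[name]][i] <- up[[name]][i] + eps
    dn <- model; dn[[name]][i] <- dn[[name]][i] - eps
    g[i] <- (mfnn_loss(up, X, y) - mfnn_loss(dn, X, y)) / (2 * eps)
  }
  g
}

# a small randomly parameterized model for gradient checks
random_small_model <- function(seed = 42, n_rules = 2, d = 2) {
  set.seed(seed)
  X <- matrix(runif(10 * d), 10, d,
              dimnames = list(NULL, paste0("f", seq_len(d))))
  y <- rep(c(0L, 1L), 5)
  m <- pdfuzz:::mfnn_init(X, y, colnames(X), n_rules, 0.05, "product", seed)
  m$p[] <- rnorm(length(m$p), sd = 0.3)
  m$q <- rnorm(length(m$q), sd = 0.3)
  m$V[] <- rnorm(length(m$V), sd = 0.5)
  m$v0 <- rnorm(2, sd = 0.2)
  list(model = m, X = X, y = y)
}
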