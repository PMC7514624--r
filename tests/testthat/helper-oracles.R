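# Shared fixtures and independent brute-force oracles. The oracles
# materialize every set element-by-element with explicit loops and never
# call the package's neighborhood/entropy code paths.

# 4-sample, 3-attribute worked example (decision classes Y and N), consumed
# as printed, i.e. without re-normalization.
example_table <- function() {
  decision_table(data.frame(
    a = c(0.12, 0.21, 0.31, 0.61),
    b = c(0.41, 0.15, 0.11, 0.13),
    c = c(0.61, 0.14, 0.26, 0.23),
    d = c("Y", "Y", "N", "N")
  ))
}

# Random decision table on [0,1]^m with labels guaranteed to cover
# n_classes classes (when n >= n_classes).
random_table <- function(n, m, n_classes = 2, seed = 1) {
  withr::with_seed(seed, {
    df <- as.data.frame(matrix(runif(n * m), n, m))
    names(df) <- paste0("v", seq_len(m))
    lab <- c(seq_len(min(n_classes, n)), sample(n_classes, max(0, n - n_classes),
                                                replace = TRUE))
    df$cls <- paste0("k", sample(lab))
    decision_table(df, decision = "cls")
  })
}

# --- oracles ---------------------------------------------------------------

oracle_neighbors <- function(X, B, delta) {
  n <- nrow(X)
  out <- vector("list", n)
  for (i in seq_len(n)) {
    nb <- integer(0)
    for (j in seq_len(n)) {
      ss <- 0
      for (k in B) ss <- ss + (X[i, k] - X[j, k])^2
      if (sqrt(ss) <= delta) nb <- c(nb, j)
    }
    out[[i]] <- nb
  }
  out
}

# lower/upper approximation of an arbitrary target set of sample indices
oracle_approx <- function(neighbors, target) {
  n <- length(neighbors)
  lower <- integer(0)
  upper <- integer(0)
  for (i in seq_len(n)) {
    nb <- neighbors[[i]]
    if (all(nb %in% target)) lower <- c(lower, i)
    if (length(intersect(nb, target)) > 0) upper <- c(upper, i)
  }
  list(lower = lower, upper = upper)
}

oracle_positive_region <- function(X, y, B, delta) {
  neighbors <- if (length(B) == 0) rep(list(seq_len(nrow(X))), nrow(X)) else
    oracle_neighbors(X, B, delta)
  pos <- integer(0)
  for (lab in unique(y)) {
    pos <- union(pos, oracle_approx(neighbors, which(y == lab))$lower)
  }
  sort(pos)
}

oracle_joint_entropy <- function(X, y, B, delta) {
  n <- nrow(X)
  neighbors <- if (length(B) == 0) rep(list(seq_len(n)), n) else
    oracle_neighbors(X, B, delta)
  total <- 0
  for (i in seq_len(n)) {
    cls <- which(y == y[i])
    total <- total + log2(length(intersect(neighbors[[i]], cls)) / n)
  }
  -total / n
}

oracle_nrh <- function(X, y, B, delta) {
  n <- nrow(X)
  neighbors <- if (length(B) == 0) rep(list(seq_len(n)), n) else
    oracle_neighbors(X, B, delta)
  total <- 0
  for (lab in unique(y)) {
    dj <- which(y == lab)
    ap <- oracle_approx(neighbors, dj)
    gamma <- 1 - length(ap$lower) / length(ap$upper)
    inner <- 0
    for (i in dj) inner <- inner + log2(length(intersect(neighbors[[i]], dj)) / n)
    total <- total + log2(2 - gamma) * inner
  }
  -total / n
}

# context accessors used by oracle calls in tests
tbl_X <- function(dt) as.matrix(as.data.frame(dt)[setdiff(names(dt), attr(dt, "decision"))])
tbl_y <- function(dt) as.character(dt[[attr(dt, "decision")]])

# all non-empty subsets of 1..m as a list of integer vectors
all_subsets <- function(m) {
  out <- list()
  for (sz in seq_len(m)) out <- c(out, combn(m, sz, simplify = FALSE))
  out
}

# independent Fisher score recomputation, straight from the formula
oracle_fisher <- function(X, y, eps_var = 1e-12) {
  vapply(seq_len(ncol(X)), function(k) {
    mu <- mean(X[, k])
    num <- 0
    den <- 0
    for (lab in unique(y)) {
      v <- X[y == lab, k]
      num <- num + length(v) * (mean(v) - mu)^2
      den <- den + length(v) * mean((v - mean(v))^2)
    }
    num / (den + eps_var)
  }, numeric(1))
}
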