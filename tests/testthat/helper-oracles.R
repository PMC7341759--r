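# Independent oracles: direct-formula / enumeration / grid-search
# implementations kept deliberately separate from the package's code
# paths, used to pin down the statistical operations.

# Benjamini-Hochberg step-up, written out by hand.
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  r <- p[o] * m / seq_len(m)
  q <- pmin(rev(cummin(rev(r))), 1)
  out <- numeric(m)
  out[o] <- q
  out
}

# Paired t via direct formula with p from numeric t-density integration.
oracle_paired_t <- function(x, y) {
  d <- x - y
  n <- length(d)
  t <- mean(d) / (sd(d) / sqrt(n))
  p <- 2 * integrate(function(u) dt(u, n - 1), abs(t), Inf,
                     rel.tol = 1e-12)$value
  list(t_stat = t, p = p)
}

# Breslow partial log-likelihood for a single covariate.
oracle_breslow_loglik <- function(beta, x, time, status) {
  ll <- 0
  for (i in which(as.logical(status))) {
    risk <- which(time >= time[i])
    ll <- ll + beta * x[i] - log(sum(exp(beta * x[risk])))
  }
  ll
}

# Grid-search maximizer of the Breslow partial likelihood (coarse grid,
# then a fine grid around the coarse optimum).
oracle_cox_grid <- function(x, time, status, lo = -6, hi = 6) {
  coarse <- seq(lo, hi, by = 1e-3)
  ll <- vapply(coarse, oracle_breslow_loglik, 0, x = x, time = time,
               status = status)
  b0 <- coarse[which.max(ll)]
  fine <- seq(b0 - 2e-3, b0 + 2e-3, by = 1e-6)
  llf <- vapply(fine, oracle_breslow_loglik, 0, x = x, time = time,
                status = status)
  fine[which.max(llf)]
}

# Logistic log-likelihood scan: direct likelihood maximized from scratch.
oracle_logistic_scan <- function(x, y) {
  nll <- function(b) {
    eta <- b[1] + b[2] * x
    -sum(y * eta - log1p(exp(eta)))
  }
  fit <- optim(c(0, 0), nll, method = "BFGS",
               control = list(reltol = 1e-14, maxit = 500))
  fit$par[2]
}

# Union-find connected components over an edge list; returns a canonical
# sorted list of sorted member vectors.
oracle_components <- function(from, to) {
  nodes <- unique(c(from, to))
  parent <- setNames(nodes, nodes)
  find <- function(v) {
    while (parent[[v]] != v) {
      parent[[v]] <<- parent[[parent[[v]]]]
      v <- parent[[v]]
    }
    v
  }
  for (i in seq_along(from)) {
    a <- find(from[i]); b <- find(to[i])
    if (a != b) parent[[a]] <- b
  }
  roots <- vapply(nodes, find, "")
  comps <- lapply(split(nodes, roots), sort)
  comps[order(vapply(comps, `[[`, "", 1L))]
}

# Exhaustive hypergeometric tail: enumerate every n-subset of a universe
# of size N whose first K elements are the set.
oracle_hyper_enum <- function(k, K, n, N) {
  draws <- combn(N, n)
  mean(colSums(draws <= K) >= k)
}

# Naive quantile normalization for tie-free columns.
oracle_qn <- function(x) {
  m <- rowMeans(apply(x, 2, sort))
  out <- x
  for (j in seq_len(ncol(x))) out[order(x[, j]), j] <- m
  out
}
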