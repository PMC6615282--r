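# Independent numerical oracles. These must never call the production
# closed-form path they are used to check.

# Exact linear-system solution of the two-compartment infusion model via
# matrix exponentials, segment by segment (piecewise-constant input).
conc_expm_oracle <- function(p, regimen, times) {
  A <- matrix(c(-(p$cl + p$q) / p$v1, p$q / p$v2,
                p$q / p$v1, -p$q / p$v2),
              2, 2, byrow = TRUE)
  rate_at <- function(t) {
    r <- 0
    for (i in seq_len(nrow(regimen)))
      if (t >= regimen$start_h[i] && t < regimen$end_h[i])
        r <- r + regimen$rate[i]
    r
  }
  breaks <- sort(unique(c(0, regimen$start_h, regimen$end_h, times)))
  x <- c(0, 0)
  out <- numeric(length(times))
  for (k in seq_along(breaks)[-1]) {
    t0 <- breaks[k - 1]; t1 <- breaks[k]
    b <- c(rate_at(t0), 0)
    E <- as.matrix(Matrix::expm(A * (t1 - t0)))
    x <- drop(E %*% x + solve(A, (E - diag(2)) %*% b))
    hit <- which(abs(times - t1) < 1e-12)
    if (length(hit)) out[hit] <- x[1] / p$v1
  }
  out[abs(times) < 1e-12] <- 0
  out
}

# Marginal -2 log-likelihood by adaptive Gauss-Hermite quadrature over the
# active etas. Nodes/weights from the Golub-Welsch eigendecomposition of the
# Hermite Jacobi matrix (physicists' convention, weight exp(-x^2)).
gauss_hermite <- function(n) {
  J <- matrix(0, n, n)
  off <- sqrt(seq_len(n - 1) / 2)
  J[cbind(1:(n - 1), 2:n)] <- off
  J[cbind(2:n, 1:(n - 1))] <- off
  eg <- eigen(J, symmetric = TRUE)
  list(nodes = eg$values, weights = sqrt(pi) * eg$vectors[1, ]^2)
}

agq_ofv_oracle <- function(data, model, n_nodes = 64) {
  gh <- gauss_hermite(n_nodes)
  omega2 <- model$omega2[model$omega2 > 0]
  k <- length(omega2)
  stopifnot(k >= 1)
  grid <- as.matrix(expand.grid(rep(list(seq_len(n_nodes)), k)))
  logw <- rowSums(matrix(log(gh$weights[grid]), nrow(grid), k))
  znode <- matrix(gh$nodes[grid], nrow(grid), k)
  total <- 0
  for (ind in data$individuals) {
    y <- ind$dv
    n <- length(y)
    m2ll_cond <- function(eta_active) {
      eta <- c(0, 0)
      eta[which(model$omega2 > 0)] <- eta_active
      f <- predict_individual(model, ind, eta)
      # clamp far below any observable concentration but far above the
      # square-root underflow threshold
      f <- pmax(f, 1e-12)
      v <- model$sigma2 * f^2
      sum(log(2 * pi * v) + (y - f)^2 / v)
    }
    h <- function(eta_active)  # -2 log joint
      m2ll_cond(eta_active) + sum(eta_active^2 / omega2) +
        sum(log(2 * pi * omega2))
    # mode and curvature for the adaptive shift/scale
    opt <- optim(rep(0, k), h, method = "BFGS")
    mu <- opt$par
    H <- matrix(0, k, k)
    d <- 1e-4
    for (i in seq_len(k)) for (j in i:k) {
      ei <- ej <- rep(0, k); ei[i] <- d; ej[j] <- d
      H[i, j] <- H[j, i] <-
        (h(mu + ei + ej) - h(mu + ei - ej) - h(mu - ei + ej) +
           h(mu - ei - ej)) / (8 * d^2)  # Hessian of h/2
    }
    L <- t(chol(solve(H)))
    # integral of exp(-h/2): substitute eta = mu + sqrt(2) L z
    vals <- apply(znode, 1, function(z) {
      eta <- mu + sqrt(2) * drop(L %*% z)
      -h(eta) / 2 + sum(z^2)
    })
    log_int <- log(sum(exp(vals + logw - max(vals + logw)))) +
      max(vals + logw) + k / 2 * log(2) + sum(log(diag(L)))
    total <- total - 2 * log_int
  }
  total
}
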