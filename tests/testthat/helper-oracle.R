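# Independent oracles, written from scratch against the definitions rather
# than the package's code paths.

# squared Pearson correlation of two dosage vectors
oracle_r2 <- function(x, y) {
  if (sd(x) == 0 || sd(y) == 0) return(NA_real_)
  cor(x, y)^2
}

# brute-force GRM: explicit double loop over individuals and variants
oracle_grm <- function(X) {
  n <- nrow(X); m <- ncol(X)
  p <- colMeans(X) / 2
  G <- matrix(0, n, n)
  for (j in seq_len(n)) {
    for (k in seq_len(n)) {
      acc <- 0
      for (v in seq_len(m)) {
        acc <- acc + (X[j, v] - 2 * p[v]) * (X[k, v] - 2 * p[v]) /
          (2 * p[v] * (1 - p[v]))
      }
      G[j, k] <- acc / m
    }
  }
  G
}

# explicit restricted log-likelihood for V(theta) = sum_j theta_j M_j
oracle_reml_ll <- function(theta, y, X, Ms) {
  V <- Reduce(`+`, Map(`*`, theta, Ms))
  ev <- eigen(V, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 1e-10) return(-Inf)
  Vi <- solve(V)
  XtViX <- t(X) %*% Vi %*% X
  if (det(XtViX) <= 0) return(-Inf)
  P <- Vi - Vi %*% X %*% solve(XtViX) %*% t(X) %*% Vi
  as.numeric(-0.5 * (determinant(V)$modulus + determinant(XtViX)$modulus +
                       t(y) %*% P %*% y))
}

# direct numerical maximization of the restricted log-likelihood.
# var_idx parameters are optimized on the log scale; others (covariances)
# on the raw scale. Repeated Nelder-Mead restarts from the incumbent.
oracle_reml_opt <- function(y, X, Ms, init, var_idx, restarts = 4) {
  trans <- function(theta) {
    z <- theta
    z[var_idx] <- log(theta[var_idx])
    z
  }
  untrans <- function(z) {
    theta <- z
    theta[var_idx] <- exp(z[var_idx])
    theta
  }
  obj <- function(z) {
    ll <- oracle_reml_ll(untrans(z), y, X, Ms)
    if (!is.finite(ll)) 1e10 else -ll
  }
  z <- trans(init)
  best <- list(par = z, value = obj(z))
  for (r in seq_len(restarts)) {
    o <- optim(best$par, obj, method = "Nelder-Mead",
               control = list(maxit = 20000, reltol = 1e-14))
    if (o$value < best$value) best <- o else break
  }
  list(theta = untrans(best$par), ll = -best$value)
}

# assemble stacked-record bivariate structure matrices independently of the
# package: records are (trait-1 rows of ids1) then (trait-2 rows of ids2)
oracle_bi_structures <- function(G_list, ids1, ids2) {
  n1 <- length(ids1); n2 <- length(ids2); n <- n1 + n2
  out <- list()
  for (nm in names(G_list)) {
    G <- G_list[[nm]]
    M1 <- matrix(0, n, n); M1[1:n1, 1:n1] <- G[ids1, ids1]
    M2 <- matrix(0, n, n); M2[n1 + 1:n2, n1 + 1:n2] <- G[ids2, ids2]
    M12 <- matrix(0, n, n)
    M12[1:n1, n1 + 1:n2] <- G[ids1, ids2]
    M12[n1 + 1:n2, 1:n1] <- t(G[ids1, ids2])
    out[[paste0(nm, ":var1")]] <- M1
    out[[paste0(nm, ":var2")]] <- M2
    out[[paste0(nm, ":cov12")]] <- M12
  }
  R1 <- matrix(0, n, n); R1[1:n1, 1:n1] <- diag(n1)
  R2 <- matrix(0, n, n); R2[n1 + 1:n2, n1 + 1:n2] <- diag(n2)
  R12 <- matrix(0, n, n)
  shared <- outer(ids1, ids2, "==") * 1
  R12[1:n1, n1 + 1:n2] <- shared
  R12[n1 + 1:n2, 1:n1] <- t(shared)
  out[["residual:var1"]] <- R1
  out[["residual:var2"]] <- R2
  out[["residual:cov12"]] <- R12
  out
}
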