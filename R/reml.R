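#' Univariate REML with one or two genomic relationship matrices
#'
#' Fits \eqn{y = \mu 1 + \sum_k g_k + e} with \eqn{g_k \sim N(0, G_k
#' \sigma^2_k)} and \eqn{e \sim N(0, I \sigma^2_e)} by restricted maximum
#' likelihood: a short expectation-maximization warm-up followed by
#' average-information (AI) updates with step halving whenever a step would
#' decrease the restricted log-likelihood. One GRM gives the single-component
#' chip model; two GRMs the subset-plus-chip partitioning model. Standard
#' errors come from the inverse AI matrix at the optimum; the full inverse is
#' retained for delta-method statistics downstream.
#'
#' Variance components falling below `variance_floor` times the phenotypic
#' variance are pinned to that floor and flagged. Failure to reach `tolerance`
#' within `max_iterations` is reported through `converged = FALSE`, never as
#' an error, so batch runs over many subsets complete.
#'
#' @param phenotypes Tibble with `individual_id` and trait columns; missing
#'   trait values are dropped.
#' @param grms A `grm` object or named list of 1-2 `grm` objects. Every
#'   phenotyped individual must be present in every GRM.
#' @param trait Name of the trait column (default the first non-id column).
#' @param max_iterations,tolerance AI-REML iteration cap and relative
#'   log-likelihood change threshold.
#' @param variance_floor Lower bound for variance components, as a fraction
#'   of the phenotypic variance.
#' @return An object of class `uni_fit` with elements `components` (tibble:
#'   term, estimate, se, pinned), `vcov` (sampling covariance of the
#'   components), `loglik_trace`, `converged`, `n_iterations`, `n_records`.
#' @export
fit_univariate <- function(phenotypes, grms, trait = NULL,
                           max_iterations = 100, tolerance = 1e-8,
                           variance_floor = 1e-6) {
  grms <- as_grm_list(grms)
  trait <- trait %||% setdiff(names(phenotypes), "individual_id")[1]
  obs <- phenotypes[!is.na(phenotypes[[trait]]), ]
  check_grm_coverage(grms, obs$individual_id)
  if (nrow(obs) < 3) abort("fewer than 3 phenotype records")

  y <- obs[[trait]]
  ids <- obs$individual_id
  Mlist <- c(lapply(grms, function(g) g$matrix[ids, ids]),
             list(residual = diag(length(y))))
  names(Mlist) <- c(names(grms), "residual")
  vp <- var(y)
  k <- length(Mlist)
  init <- rep(vp / k, k)
  floor_vec <- rep(variance_floor * vp, k)
  X <- matrix(1, length(y), 1)

  res <- reml_engine(y, X, Mlist, init,
                     param_type = rep("var", k),
                     cov_pairs = list(),
                     floor_vec = floor_vec,
                     tol = tolerance, max_iter = max_iterations)

  comp <- tibble(term = names(Mlist),
                 estimate = unname(res$theta),
                 se = unname(res$se),
                 pinned = res$theta <= floor_vec + 1e-15)
  structure(list(components = comp, vcov = res$vcov,
                 loglik_trace = res$trace, converged = res$converged,
                 n_iterations = res$n_iter, n_records = length(y),
                 terms = names(grms), trait = trait,
                 phenotypic_variance = vp),
            class = "uni_fit")
}

#' Bivariate REML with one or two genomic relationship matrices
#'
#' Fits the two-trait mixed model by stacked-record REML: every observed
#' trait value is one record, so individuals missing one trait still
#' contribute to the other (per-trait sample sizes may differ). Each random
#' term carries a 2x2 trait (co)variance block; the residual covariance
#' applies only to individuals observed for both traits. With one GRM this is
#' the chip-only bivariate model; with two, the subset-plus-chip bivariate
#' partitioning model. Algorithm and reporting conventions follow
#' [fit_univariate()].
#'
#' During iteration each block's covariance is constrained so its implied
#' correlation stays within \eqn{\pm 0.9999}, keeping the phenotypic
#' covariance matrix invertible; estimates ending at that bound are flagged.
#'
#' @inheritParams fit_univariate
#' @param traits Length-2 character vector of trait column names.
#' @return An object of class `bi_fit` with `components` (tibble: term, trait
#'   in `"1"`, `"2"`, `"12"`, estimate, se, pinned, at_bound), `vcov`,
#'   `loglik_trace`, `converged`, `n_iterations`, `n_records` (named: trait1,
#'   trait2, both).
#' @export
fit_bivariate <- function(phenotypes, grms, traits = c("y1", "y2"),
                          max_iterations = 100, tolerance = 1e-8,
                          variance_floor = 1e-6) {
  stopifnot(length(traits) == 2)
  grms <- as_grm_list(grms)
  o1 <- phenotypes[!is.na(phenotypes[[traits[1]]]), ]
  o2 <- phenotypes[!is.na(phenotypes[[traits[2]]]), ]
  if (nrow(o1) < 3 || nrow(o2) < 3) abort("fewer than 3 records for a trait")
  both <- intersect(o1$individual_id, o2$individual_id)
  if (length(both) == 0) {
    abort("no individual observed for both traits; covariances unidentifiable")
  }
  check_grm_coverage(grms, union(o1$individual_id, o2$individual_id))

  n1 <- nrow(o1); n2 <- nrow(o2); n <- n1 + n2
  y <- c(o1[[traits[1]]], o2[[traits[2]]])
  X <- cbind(c(rep(1, n1), rep(0, n2)), c(rep(0, n1), rep(1, n2)))
  i1 <- seq_len(n1); i2 <- n1 + seq_len(n2)

  block <- function(B11, B12, B22) {
    M <- matrix(0, n, n)
    M[i1, i1] <- B11; M[i2, i2] <- B22
    M[i1, i2] <- B12; M[i2, i1] <- t(B12)
    M
  }
  zero12 <- matrix(0, n1, n2)
  Mlist <- list()
  for (k in seq_along(grms)) {
    G <- grms[[k]]$matrix
    g11 <- G[o1$individual_id, o1$individual_id]
    g22 <- G[o2$individual_id, o2$individual_id]
    g12 <- G[o1$individual_id, o2$individual_id, drop = FALSE]
    nm <- names(grms)[k]
    Mlist[[paste0(nm, ":var1")]] <- block(g11, zero12, matrix(0, n2, n2))
    Mlist[[paste0(nm, ":var2")]] <- block(matrix(0, n1, n1), zero12, g22)
    Mlist[[paste0(nm, ":cov12")]] <- block(matrix(0, n1, n1), g12,
                                           matrix(0, n2, n2))
  }
  E12 <- outer(o1$individual_id, o2$individual_id, "==") * 1
  Mlist[["residual:var1"]] <- block(diag(n1), zero12, matrix(0, n2, n2))
  Mlist[["residual:var2"]] <- block(matrix(0, n1, n1), zero12, diag(n2))
  Mlist[["residual:cov12"]] <- block(matrix(0, n1, n1), E12,
                                     matrix(0, n2, n2))

  terms <- c(names(grms), "residual")
  K <- length(terms)
  vp1 <- var(o1[[traits[1]]]); vp2 <- var(o2[[traits[2]]])
  cp <- cov(phenotypes[[traits[1]]][match(both, phenotypes$individual_id)],
            phenotypes[[traits[2]]][match(both, phenotypes$individual_id)])
  init <- numeric(3 * K)
  floor_vec <- rep(0, 3 * K)
  param_type <- rep(c("var", "var", "cov"), K)
  cov_pairs <- list()
  for (k in seq_len(K)) {
    j <- 3 * (k - 1)
    init[j + 1] <- vp1 / K; init[j + 2] <- vp2 / K; init[j + 3] <- cp / K
    floor_vec[j + 1] <- variance_floor * vp1
    floor_vec[j + 2] <- variance_floor * vp2
    cov_pairs[[length(cov_pairs) + 1]] <- c(j + 3, j + 1, j + 2)
  }

  res <- reml_engine(y, X, Mlist, init, param_type, cov_pairs, floor_vec,
                     tol = tolerance, max_iter = max_iterations)

  at_bound <- rep(FALSE, 3 * K)
  for (cp_idx in cov_pairs) {
    bound <- 0.9999 * sqrt(res$theta[cp_idx[2]] * res$theta[cp_idx[3]])
    at_bound[cp_idx[1]] <- abs(abs(res$theta[cp_idx[1]]) - bound) < 1e-12
  }
  comp <- tibble(term = rep(terms, each = 3),
                 trait = rep(c("1", "2", "12"), K),
                 estimate = unname(res$theta),
                 se = unname(res$se),
                 pinned = param_type == "var" & res$theta <= floor_vec + 1e-15,
                 at_bound = at_bound)
  structure(list(components = comp, vcov = res$vcov,
                 loglik_trace = res$trace, converged = res$converged,
                 n_iterations = res$n_iter,
                 n_records = c(trait1 = n1, trait2 = n2,
                               both = length(both)),
                 terms = names(grms), traits = traits),
            class = "bi_fit")
}

as_grm_list <- function(grms) {
  if (inherits(grms, "grm")) grms <- list(grms)
  stopifnot(length(grms) >= 1, length(grms) <= 2,
            all(vapply(grms, inherits, TRUE, "grm")))
  if (is.null(names(grms)) || any(!nzchar(names(grms)))) {
    names(grms) <- if (length(grms) == 1) "genomic" else c("set", "chip")
  }
  grms
}

check_grm_coverage <- function(grms, ids) {
  for (k in seq_along(grms)) {
    missing_ids <- setdiff(ids, grms[[k]]$individual_ids)
    if (length(missing_ids)) {
      abort(sprintf("GRM '%s' is missing %d phenotyped individual(s), e.g. %s",
                    names(grms)[k], length(missing_ids), missing_ids[1]))
    }
  }
}

# --- AI-REML engine ---------------------------------------------------------
#
# V(theta) = sum_j theta_j M_j, intercept-type fixed effects X profiled out.
# Three EM warm-up iterations on the variance parameters, then AI updates
# with step halving whenever a step would decrease the restricted
# log-likelihood. Covariance parameters are kept inside the PSD region of
# their 2x2 block via `cov_pairs` (index of cov, index of var1, index of var2).
reml_engine <- function(y, X, Mlist, init, param_type, cov_pairs, floor_vec,
                        tol = 1e-8, max_iter = 100, n_em = 3) {
  nP <- length(Mlist)
  n <- length(y)

  build_v <- function(theta) {
    V <- theta[1] * Mlist[[1]]
    for (j in seq_len(nP)[-1]) V <- V + theta[j] * Mlist[[j]]
    V
  }

  chol_ridge <- function(V) {
    ridge <- 0
    base <- mean(diag(V))
    repeat {
      ch <- tryCatch(chol(V + diag(ridge, n)), error = function(e) NULL)
      if (!is.null(ch)) return(ch)
      ridge <- if (ridge == 0) 1e-8 * base else ridge * 10
      if (ridge > 1e-2 * base) {
        abort("phenotypic covariance matrix V is singular; model unidentifiable at current parameter values")
      }
    }
  }

  # restricted log-likelihood only (cheap path for step halving)
  ll_only <- function(theta) {
    V <- build_v(theta)
    ch <- tryCatch(chol_ridge(V), error = function(e) NULL)
    if (is.null(ch)) return(-Inf)
    Viy <- backsolve(ch, forwardsolve(t(ch), y))
    ViX <- backsolve(ch, forwardsolve(t(ch), X))
    XtViX <- crossprod(X, ViX)
    chX <- tryCatch(chol(XtViX), error = function(e) NULL)
    if (is.null(chX)) return(-Inf)
    beta <- backsolve(chX, forwardsolve(t(chX), crossprod(ViX, y)))
    yPy <- sum(y * Viy) - sum(crossprod(ViX, y) * beta)
    -0.5 * (2 * sum(log(diag(ch))) + 2 * sum(log(diag(chX))) + yPy)
  }

  # full state: P matrix, Py, scores, AI
  eval_state <- function(theta) {
    V <- build_v(theta)
    ch <- chol_ridge(V)
    Vi <- chol2inv(ch)
    ViX <- Vi %*% X
    XtViX <- crossprod(X, ViX)
    XtViX_i <- solve(XtViX)
    P <- Vi - ViX %*% XtViX_i %*% t(ViX)
    Py <- P %*% y
    ll <- -0.5 * (2 * sum(log(diag(ch))) + determinant(XtViX)$modulus[1] +
                    sum(y * Py))
    MPy <- matrix(0, n, nP)
    trPM <- numeric(nP)
    score <- numeric(nP)
    for (j in seq_len(nP)) {
      MPy[, j] <- Mlist[[j]] %*% Py
      trPM[j] <- sum(P * Mlist[[j]])
      score[j] <- -0.5 * (trPM[j] - sum(Py * MPy[, j]))
    }
    PMPy <- P %*% MPy
    AI <- 0.5 * crossprod(MPy, PMPy)
    AI <- (AI + t(AI)) / 2
    list(ll = ll, score = score, AI = AI, trPM = trPM, MPy = MPy, Py = Py)
  }

  constrain <- function(theta) {
    theta[param_type == "var"] <- pmax(theta[param_type == "var"],
                                       floor_vec[param_type == "var"])
    for (cp in cov_pairs) {
      bound <- 0.9999 * sqrt(theta[cp[2]] * theta[cp[3]])
      theta[cp[1]] <- max(min(theta[cp[1]], bound), -bound)
    }
    theta
  }

  theta <- constrain(init)
  trace <- numeric(0)
  converged <- FALSE
  state <- eval_state(theta)
  it <- 0

  # halve along `delta` until the restricted log-likelihood strictly improves
  line_search <- function(theta, ll0, delta) {
    lambda <- 1
    for (h in 1:30) {
      cand <- constrain(theta + lambda * delta)
      ll_cand <- ll_only(cand)
      if (is.finite(ll_cand) && ll_cand > ll0) {
        return(list(theta = cand, ll = ll_cand))
      }
      lambda <- lambda / 2
    }
    NULL
  }

  # steepest-ascent fallback over the free parameters, scaled so the largest
  # move is ~10% of the current parameter magnitude. Covariances pushing
  # outward against their correlation bound are redirected along the curved
  # boundary: their score is chained onto the two variances through
  # d|cov_max|/d var.
  gradient_step <- function(theta, state, free) {
    g <- rep(0, nP)
    g[free] <- state$score[free]
    for (cp in cov_pairs) {
      ci <- cp[1]; v1 <- cp[2]; v2 <- cp[3]
      bound <- 0.9999 * sqrt(theta[v1] * theta[v2])
      if (bound > 0 && abs(theta[ci]) >= bound * (1 - 1e-9) &&
          g[ci] * sign(theta[ci]) > 0) {
        s <- sign(theta[ci])
        g[v1] <- g[v1] + g[ci] * s * 0.9999 * 0.5 * sqrt(theta[v2] / theta[v1])
        g[v2] <- g[v2] + g[ci] * s * 0.9999 * 0.5 * sqrt(theta[v1] / theta[v2])
        g[ci] <- 0
      }
    }
    if (max(abs(g)) == 0) return(NULL)
    step0 <- 0.1 * max(abs(theta), mean(diag(build_v(theta))) / n) / max(abs(g))
    line_search(theta, state$ll, g * step0)
  }

  while (it < max_iter) {
    it <- it + 1
    trace <- c(trace, state$ll)
    if (it <= n_em) {
      # EM update for variance parameters; covariances move in the AI phase
      new_theta <- theta
      for (j in which(param_type == "var")) {
        yPMPy <- sum(state$Py * state$MPy[, j])
        new_theta[j] <- theta[j] + theta[j]^2 * (yPMPy - state$trPM[j]) / n
      }
      theta <- constrain(new_theta)
      state <- eval_state(theta)
      next
    }
    # active set: parameters pinned at the variance floor whose score pushes
    # them further down stay fixed; the AI system is solved on the rest
    pinned_down <- param_type == "var" & theta <= floor_vec + 1e-15 &
      state$score < 0
    free <- which(!pinned_down)
    delta <- rep(0, nP)
    Af <- state$AI[free, free, drop = FALSE]
    delta[free] <- tryCatch(as.numeric(solve(Af, state$score[free])),
                            error = function(e)
                              as.numeric(MASS::ginv(Af) %*% state$score[free]))
    cand <- line_search(theta, state$ll, delta)
    if (is.null(cand)) cand <- gradient_step(theta, state, free)
    if (is.null(cand)) {
      # no ascent direction improves: constrained stationary point
      converged <- TRUE
      break
    }
    rel_change <- (cand$ll - state$ll) / max(1, abs(cand$ll))
    theta <- cand$theta
    state <- eval_state(theta)
    if (rel_change < tol) {
      # guard against boundary-clamped near-zero steps: only stop when a
      # plain gradient step cannot improve the likelihood either
      extra <- gradient_step(theta, state, free)
      if (is.null(extra) ||
          (extra$ll - state$ll) < tol * max(1, abs(extra$ll))) {
        converged <- TRUE
        trace <- c(trace, state$ll)
        break
      }
      theta <- extra$theta
      state <- eval_state(theta)
    }
  }

  vcov <- tryCatch(solve(state$AI), error = function(e) MASS::ginv(state$AI))
  vcov <- (vcov + t(vcov)) / 2
  se <- sqrt(pmax(diag(vcov), 0))
  names(theta) <- names(Mlist)
  dimnames(vcov) <- list(names(Mlist), names(Mlist))
  list(theta = theta, se = se, vcov = vcov, trace = trace,
       converged = converged, n_iter = it)
}

# --- methods ----------------------------------------------------------------

#' @export
print.uni_fit <- function(x, ...) {
  cat(sprintf("Univariate REML fit (%d records, %s)\n", x$n_records,
              if (x$converged) "converged" else "NOT converged"))
  print(as.data.frame(x$components), row.names = FALSE)
  invisible(x)
}

#' @export
print.bi_fit <- function(x, ...) {
  cat(sprintf("Bivariate REML fit (n1 = %d, n2 = %d, both = %d, %s)\n",
              x$n_records[["trait1"]], x$n_records[["trait2"]],
              x$n_records[["both"]],
              if (x$converged) "converged" else "NOT converged"))
  print(as.data.frame(x$components), row.names = FALSE)
  invisible(x)
}

#' Tidy a REML fit into a component table
#'
#' @param x A `uni_fit` or `bi_fit` object.
#' @param ... Unused.
#' @return A tibble with one row per (co)variance component.
#' @export
tidy.uni_fit <- function(x, ...) x$components

#' @rdname tidy.uni_fit
#' @export
tidy.bi_fit <- function(x, ...) x$components

#' One-row summary of a REML fit
#'
#' @param x A `uni_fit` or `bi_fit` object.
#' @param ... Unused.
#' @return A tibble with the final restricted log-likelihood, convergence
#'   state, iteration count and record count(s).
#' @export
glance.uni_fit <- function(x, ...) {
  tibble(logLik = x$loglik_trace[length(x$loglik_trace)],
         converged = x$converged, n_iterations = x$n_iterations,
         n_records = x$n_records)
}

#' @rdname glance.uni_fit
#' @export
glance.bi_fit <- function(x, ...) {
  tibble(logLik = x$loglik_trace[length(x$loglik_trace)],
         converged = x$converged, n_iterations = x$n_iterations,
         n_records_trait1 = x$n_records[["trait1"]],
         n_records_trait2 = x$n_records[["trait2"]],
         n_records_both = x$n_records[["both"]])
}
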