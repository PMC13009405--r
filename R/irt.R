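#' @name irt
#' @title Item-response models for checklist production data
#'
#' @description
#' One-, two- and three-parameter logistic models fitted by marginal maximum
#' likelihood (Bock-Aitkin EM) with fixed Gauss-Hermite quadrature over a
#' standard-normal latent trait. The identification convention fixes the
#' latent variance to 1 and lets the 1PL common slope be freely estimated,
#' so a k-item 1PL has k + 1 free parameters (k difficulties + 1 slope);
#' the 2PL has 2k and the 3PL 3k. The 3PL lower asymptote is stabilized by
#' a weak Beta(1, 9) penalty that vanishes at c = 0 (pseudo-Bayes), which
#' keeps plain-MML instability in check at modest sample sizes; this is
#' disclosed in the fit object (`c_prior`).
NULL

gh_nodes <- function(q) {
  gh <- pracma::gaussHermite(q)
  list(x = gh$x * sqrt(2), w = gh$w / sqrt(pi))
}

# item response function; a, b, c vectors of length k, theta vector of length Q
irf_matrix <- function(theta, a, b, c) {
  eta <- outer(a * -b, rep(1, length(theta))) + outer(a, theta)
  p <- c + (1 - c) * stats::plogis(eta)
  pmin(pmax(p, 1e-10), 1 - 1e-10)
}

marginal_loglik <- function(Y, P, w) {
  L <- Y %*% log(P) + (1 - Y) %*% log(1 - P)   # n x Q
  m <- apply(L, 1, max)
  post_un <- exp(L - m) * rep(w, each = nrow(L))
  list(ll = sum(m + log(rowSums(post_un))),
       post = post_un / rowSums(post_un))
}

#' Fit a 1PL/2PL/3PL model by marginal maximum likelihood
#'
#' EM algorithm: the E-step computes each person's posterior over the
#' quadrature nodes; the M-step maximizes the expected complete-data
#' log-likelihood per item by quasi-Newton steps with analytic gradients
#' (a generalized EM, so the marginal likelihood is non-decreasing across
#' iterations). 2PL fits warm-start from a 1PL solution and 3PL from 2PL,
#' which also guarantees the nested log-likelihood ordering.
#'
#' @param matrix an irt-ready [irt_matrix()] (>= 2 items, >= 2 persons, no
#'   degenerate columns).
#' @param model `"1PL"`, `"2PL"` or `"3PL"`.
#' @param quadrature_points number of Gauss-Hermite nodes (default 41).
#' @param max_iter maximum EM iterations.
#' @param tol EM stops when the marginal log-likelihood improves by less
#'   than `tol`.
#' @return object of class `irt_fit`: `model`, `items`, `difficulties`,
#'   `discriminations`, `guessing`, `slope` (1PL common slope, else NA),
#'   `log_likelihood`, `n_params`, `abilities` (EAP), `converged`,
#'   `ll_trace`, `n_persons`, `quadrature_points`, `c_prior`.
#' @export
fit_irt <- function(matrix, model = c("1PL", "2PL", "3PL"),
                    quadrature_points = 41, max_iter = 500, tol = 1e-6) {
  model <- match.arg(model)
  stopifnot(inherits(matrix, "irt_matrix"))
  Y <- matrix$data
  k <- ncol(Y); n <- nrow(Y)
  if (k < 2) stop_invalid("need at least 2 items")
  if (n < 2) stop_invalid("need at least 2 persons")
  cm <- colMeans(Y)
  if (any(cm == 0 | cm == 1))
    stop_invalid("degenerate (all-0/all-1) columns: ",
                 paste(matrix$items[cm == 0 | cm == 1], collapse = ", "),
                 "; drop them upstream with response_matrix(for_irt = TRUE)")
  gh <- gh_nodes(quadrature_points)

  if (model == "2PL") {
    init <- fit_irt(matrix, "1PL", quadrature_points, max_iter = 80, tol = 1e-4)
    a <- init$discriminations; b <- init$difficulties; cc <- rep(0, k)
  } else if (model == "3PL") {
    init <- fit_irt(matrix, "2PL", quadrature_points, max_iter = 120, tol = 1e-5)
    a <- init$discriminations; b <- init$difficulties; cc <- rep(1e-4, k)
  } else {
    a <- rep(1, k); b <- -stats::qlogis(cm); cc <- rep(0, k)
  }

  c_prior <- c(shape1 = 1, shape2 = 9)  # density maximal at c = 0
  ll_trace <- numeric(0)
  ll_old <- -Inf; converged <- FALSE
  post <- NULL
  for (iter in seq_len(max_iter)) {
    P <- irf_matrix(gh$x, a, b, cc)
    es <- marginal_loglik(Y, P, gh$w)
    ll <- es$ll
    ll_trace <- c(ll_trace, ll)
    if (is.finite(ll_old) && ll - ll_old < tol && iter > 2) {
      converged <- TRUE; post <- es$post; break
    }
    ll_old <- ll; post <- es$post
    nq <- colSums(post)                    # expected persons at node q
    rq <- crossprod(Y, post)               # k x Q expected correct
    if (model == "1PL") {
      upd <- mstep_1pl(a[1], b, rq, nq, gh$x)
      a <- rep(upd$a, k); b <- upd$b
    } else if (model == "2PL") {
      for (j in seq_len(k)) {
        upd <- mstep_item(c(log(a[j]), b[j]), rq[j, ], nq, gh$x, guessing = FALSE)
        a[j] <- upd[1]; b[j] <- upd[2]
      }
    } else {
      for (j in seq_len(k)) {
        upd <- mstep_item(c(log(a[j]), b[j], stats::qlogis(pmax(cc[j], 1e-6))),
                          rq[j, ], nq, gh$x, guessing = TRUE, c_prior = c_prior)
        a[j] <- upd[1]; b[j] <- upd[2]; cc[j] <- upd[3]
      }
    }
  }
  eap <- as.numeric(post %*% gh$x)
  n_params <- switch(model, "1PL" = k + 1L, "2PL" = 2L * k, "3PL" = 3L * k)
  structure(list(model = model, items = matrix$items,
                 difficulties = stats::setNames(b, matrix$items),
                 discriminations = stats::setNames(a, matrix$items),
                 guessing = stats::setNames(cc, matrix$items),
                 slope = if (model == "1PL") a[1] else NA_real_,
                 log_likelihood = ll_trace[length(ll_trace)],
                 n_params = n_params,
                 abilities = stats::setNames(eap, matrix$persons),
                 converged = converged, ll_trace = ll_trace,
                 n_persons = n, quadrature_points = quadrature_points,
                 c_prior = if (model == "3PL") c_prior else NULL),
            class = "irt_fit")
}

# common-slope M-step: coordinate ascent (Newton in each b_j, then in log a)
mstep_1pl <- function(a, b, rq, nq, x) {
  k <- nrow(rq)
  for (rep in 1:3) {
    for (j in seq_len(k)) {
      for (it in 1:5) {
        p <- stats::plogis(a * (x - b[j]))
        g <- -a * sum(rq[j, ] - nq * p)
        h <- -a^2 * sum(nq * p * (1 - p))
        step <- g / h
        b[j] <- b[j] - sign(step) * min(abs(step), 1)
        if (abs(g) < 1e-10) break
      }
    }
    la <- log(a)
    for (it in 1:5) {
      a <- exp(la)
      g <- 0; h <- 0
      for (j in seq_len(k)) {
        p <- stats::plogis(a * (x - b[j]))
        u <- a * (x - b[j])                       # d eta / d log a
        g <- g + sum((rq[j, ] - nq * p) * u)
        h <- h - sum(nq * p * (1 - p) * u^2)
      }
      if (h >= 0) h <- -1e-8
      step <- g / h
      la <- la - sign(step) * min(abs(step), 0.5)
      if (abs(g) < 1e-10) break
    }
    a <- exp(la)
  }
  list(a = a, b = b)
}

# per-item M-step for 2PL/3PL via BFGS with analytic gradient
mstep_item <- function(par, rj, nq, x, guessing, c_prior = NULL) {
  obj <- function(p) {
    a <- exp(p[1]); b <- p[2]
    cc <- if (guessing) stats::plogis(p[3]) else 0
    s <- stats::plogis(a * (x - b))
    pr <- pmin(pmax(cc + (1 - cc) * s, 1e-10), 1 - 1e-10)
    val <- sum(rj * log(pr) + (nq - rj) * log(1 - pr))
    if (guessing) val <- val + (c_prior[2] - 1) * log(1 - cc)
    -val
  }
  grad <- function(p) {
    a <- exp(p[1]); b <- p[2]
    cc <- if (guessing) stats::plogis(p[3]) else 0
    s <- stats::plogis(a * (x - b))
    pr <- pmin(pmax(cc + (1 - cc) * s, 1e-10), 1 - 1e-10)
    dldpr <- rj / pr - (nq - rj) / (1 - pr)
    dpr_deta <- (1 - cc) * s * (1 - s)
    geta <- dldpr * dpr_deta
    g <- c(sum(geta * a * (x - b)), sum(geta * -a))
    if (guessing) {
      dcc <- cc * (1 - cc)
      gc <- sum(dldpr * (1 - s)) * dcc - (c_prior[2] - 1) / (1 - cc) * dcc
      g <- c(g, gc)
    }
    -g
  }
  out <- stats::optim(par, obj, grad, method = "BFGS",
                      control = list(maxit = 25))
  a <- exp(out$par[1]); b <- out$par[2]
  cc <- if (guessing) stats::plogis(out$par[3]) else 0
  c(a, b, cc)
}

#' @export
print.irt_fit <- function(x, ...) {
  cat(sprintf("%s fit: %d items, %d persons, LL = %.3f, %d parameters%s\n",
              x$model, length(x$items), x$n_persons, x$log_likelihood,
              x$n_params, if (x$converged) "" else " (NOT converged)"))
  invisible(x)
}

#' Likelihood-ratio comparison of nested IRT fits
#'
#' `chi2 = 2 * (LL_larger - LL_smaller)` clamped at zero, on
#' `df = n_params(larger) - n_params(smaller)` degrees of freedom, with an
#' upper-tail chi-square p-value. For 17 items this gives df = 16 for
#' 1PL vs 2PL and df = 33 for 1PL vs 3PL.
#'
#' @param smaller,larger `irt_fit` objects on the same matrix, nested
#'   (1PL < 2PL < 3PL), with `larger` having more parameters.
#' @return list with `chi2`, `df`, `p`.
#' @export
compare_models <- function(smaller, larger) {
  stopifnot(inherits(smaller, "irt_fit"), inherits(larger, "irt_fit"))
  order <- c("1PL" = 1, "2PL" = 2, "3PL" = 3)
  if (!identical(smaller$items, larger$items) ||
      smaller$n_persons != larger$n_persons)
    stop_invalid("fits must come from the same response matrix")
  if (order[larger$model] <= order[smaller$model] ||
      larger$n_params <= smaller$n_params)
    stop_invalid("models must be nested with `larger` the bigger model")
  chi2 <- max(0, 2 * (larger$log_likelihood - smaller$log_likelihood))
  df <- larger$n_params - smaller$n_params
  list(chi2 = chi2, df = df,
       p = stats::pchisq(chi2, df, lower.tail = FALSE))
}

model_param_vector <- function(fit) {
  switch(fit$model,
         "1PL" = c(fit$slope, unname(fit$difficulties)),
         "2PL" = c(unname(fit$discriminations), unname(fit$difficulties)),
         "3PL" = c(unname(fit$discriminations), unname(fit$difficulties),
                   unname(fit$guessing)))
}

margins_from_params <- function(par, model, k, x, w, pairs) {
  if (model == "1PL") { a <- rep(par[1], k); b <- par[2:(k + 1)]; cc <- rep(0, k) }
  else if (model == "2PL") { a <- par[1:k]; b <- par[(k + 1):(2 * k)]; cc <- rep(0, k) }
  else { a <- par[1:k]; b <- par[(k + 1):(2 * k)]; cc <- par[(2 * k + 1):(3 * k)] }
  P <- irf_matrix(x, a, b, cc)
  uni <- as.numeric(P %*% w)
  biv <- vapply(seq_len(nrow(pairs)),
                function(r) sum(w * P[pairs[r, 1], ] * P[pairs[r, 2], ]),
                numeric(1))
  c(uni, biv)
}

#' Limited-information M2 goodness-of-fit statistic
#'
#' Tests whether the fitted model is consistent with the observed first-
#' and second-order response margins (univariate and bivariate proportions).
#' The statistic is the Maydeu-Olivares-Joe quadratic form
#' `M2 = N * e' C e` with `e` the margin residuals and
#' `C = Xi^-1 - Xi^-1 D (D' Xi^-1 D)^-1 D' Xi^-1`, where `Xi` is the
#' model-implied covariance of the margin indicators and `D` the Jacobian
#' of the model margins in the free parameters (computed by central
#' differences). Degrees of freedom are always reported analytically as
#' `k(k+1)/2 - n_params` (135 for a 17-item 1PL); when df <= 0 no p-value
#' is produced. A parametric-bootstrap calibration of the
#' margin-residual quadratic form is available as a fallback method.
#'
#' @param fit converged `irt_fit`.
#' @param matrix the [irt_matrix()] the fit was computed on.
#' @param method `"limited_information"` (default) or
#'   `"parametric_bootstrap"`.
#' @param n_boot bootstrap replicates for the fallback method.
#' @param seed seed for the bootstrap.
#' @return object of class `m2_result`: `statistic`, `df`, `p`, `method`.
#' @export
m2_statistic <- function(fit, matrix, method = c("limited_information",
                                                 "parametric_bootstrap"),
                         n_boot = 200, seed = 1) {
  method <- match.arg(method)
  stopifnot(inherits(fit, "irt_fit"), inherits(matrix, "irt_matrix"))
  if (!identical(fit$items, matrix$items))
    stop_invalid("fit and matrix item sets differ")
  Y <- matrix$data
  k <- ncol(Y); n <- nrow(Y)
  df <- as.integer(k * (k + 1) / 2 - fit$n_params)
  if (df <= 0) {
    return(structure(list(statistic = NA_real_, df = df, p = NA_real_,
                          method = method,
                          note = "df <= 0: margins cannot test this model"),
                     class = "m2_result"))
  }
  gh <- gh_nodes(fit$quadrature_points)
  pairs <- t(utils::combn(k, 2))
  sets <- c(lapply(seq_len(k), function(j) j),
            lapply(seq_len(nrow(pairs)), function(r) pairs[r, ]))
  s <- length(sets)
  par <- model_param_vector(fit)
  pi_hat <- margins_from_params(par, fit$model, k, gh$x, gh$w, pairs)
  p_obs <- c(colMeans(Y),
             vapply(seq_len(nrow(pairs)),
                    function(r) mean(Y[, pairs[r, 1]] * Y[, pairs[r, 2]]),
                    numeric(1)))
  e <- p_obs - pi_hat
  P <- irf_matrix(gh$x, fit$discriminations, fit$difficulties, fit$guessing)
  mu_of <- function(idx) {
    v <- P[idx[1], ]
    for (j in idx[-1]) v <- v * P[j, ]
    sum(gh$w * v)
  }
  Xi <- matrix(0, s, s)
  for (r in seq_len(s)) for (cidx in r:s) {
    m <- mu_of(unique(c(sets[[r]], sets[[cidx]])))
    Xi[r, cidx] <- Xi[cidx, r] <- m - pi_hat[r] * pi_hat[cidx]
  }
  stat <- if (method == "limited_information") {
    D <- vapply(seq_along(par), function(i) {
      h <- 1e-4 * (1 + abs(par[i]))
      pp <- par; pp[i] <- pp[i] + h
      pm <- par; pm[i] <- pm[i] - h
      (margins_from_params(pp, fit$model, k, gh$x, gh$w, pairs) -
         margins_from_params(pm, fit$model, k, gh$x, gh$w, pairs)) / (2 * h)
    }, numeric(s))
    Xii <- tryCatch(solve(Xi), error = function(err)
      solve(Xi + diag(1e-10, s)))
    XiD <- Xii %*% D
    Cmat <- Xii - XiD %*% solve(crossprod(D, XiD)) %*% t(XiD)
    as.numeric(n * t(e) %*% Cmat %*% e)
  } else {
    n * as.numeric(t(e) %*% solve(Xi + diag(1e-10, s)) %*% e)
  }
  p <- if (method == "limited_information") {
    stats::pchisq(stat, df, lower.tail = FALSE)
  } else {
    theta_sim <- NULL
    tb <- with_seed(seed, vapply(seq_len(n_boot), function(bidx) {
      Yb <- simulate_irt_responses(stats::rnorm(n), fit$difficulties,
                                   slope = fit$discriminations,
                                   guessing = fit$guessing,
                                   seed = child_seed(seed, bidx))
      mb <- tryCatch(irt_matrix(Yb, irt_ready = TRUE), error = function(err) NULL)
      if (is.null(mb)) return(NA_real_)
      fb <- fit_irt(mb, fit$model, fit$quadrature_points, max_iter = 200,
                    tol = 1e-5)
      pb <- margins_from_params(model_param_vector(fb), fit$model, k,
                                gh$x, gh$w, pairs)
      ob <- c(colMeans(Yb),
              vapply(seq_len(nrow(pairs)),
                     function(r) mean(Yb[, pairs[r, 1]] * Yb[, pairs[r, 2]]),
                     numeric(1)))
      eb <- ob - pb
      n * as.numeric(t(eb) %*% solve(Xi + diag(1e-10, s)) %*% eb)
    }, numeric(1)))
    tb <- tb[is.finite(tb)]
    (1 + sum(tb >= stat)) / (1 + length(tb))
  }
  structure(list(statistic = stat, df = df, p = p, method = method),
            class = "m2_result")
}

#' @export
print.m2_result <- function(x, ...) {
  if (is.na(x$p)) cat(sprintf("M2: df = %d, no p-value (%s)\n", x$df,
                              x$note %||% x$method))
  else cat(sprintf("M2(%d) = %.2f, p = %.4g [%s]\n", x$df, x$statistic,
                   x$p, x$method))
  invisible(x)
}

#' Item-person (Wright) map table
#'
#' Aligns item difficulties and person abilities on the shared latent
#' scale: items sorted by difficulty, persons binned at `bin_width`.
#'
#' @param fit converged `irt_fit`.
#' @param bin_width latent-scale bin width for person counts (default 0.5).
#' @return list with `items` (data.frame item_id/difficulty, ascending) and
#'   `persons` (data.frame ability_bin/person_count; bins are left edges).
#' @export
item_person_map <- function(fit, bin_width = 0.5) {
  stopifnot(inherits(fit, "irt_fit"))
  items <- data.frame(item_id = names(sort(fit$difficulties)),
                      difficulty = as.numeric(sort(fit$difficulties)),
                      stringsAsFactors = FALSE)
  bins <- floor(fit$abilities / bin_width) * bin_width
  tab <- table(bins)
  persons <- data.frame(ability_bin = as.numeric(names(tab)),
                        person_count = as.integer(tab))
  list(items = items, persons = persons)
}

#' Simulate dichotomous responses from a logistic IRT model
#'
#' Bernoulli draws with success probability
#' `c + (1 - c) * plogis(a * (theta - b))` per person-item pair. Used by the
#' synthetic-data generator, the bootstrap M2 method, and calibration
#' studies.
#'
#' @param theta person abilities.
#' @param difficulties item difficulties `b`.
#' @param slope common slope or per-item discriminations.
#' @param guessing per-item (or scalar) lower asymptotes.
#' @param seed integer seed.
#' @return persons x items binary matrix with item names from
#'   `difficulties`.
#' @export
simulate_irt_responses <- function(theta, difficulties, slope = 1,
                                   guessing = 0, seed = 1) {
  k <- length(difficulties)
  a <- rep_len(slope, k); cc <- rep_len(guessing, k)
  pr <- t(irf_matrix(theta, a, difficulties, cc))   # n x k
  Y <- with_seed(seed, matrix(stats::rbinom(length(pr), 1, pr), nrow = length(theta)))
  colnames(Y) <- names(difficulties) %||% paste0("item", seq_len(k))
  rownames(Y) <- paste0("p", seq_along(theta))
  Y
}
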