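## Gaussian-process surrogate for Bayesian hyperparameter optimization.
## Matern-5/2 kernel with a shared length scale on bounds-normalized
## coordinates; a small observation-noise jitter keeps the Cholesky
## factorization well conditioned when points nearly coincide.

matern52 <- function(X1, X2, lengthscale) {
  r2 <- outer(rowSums(X1^2), rowSums(X2^2), "+") - 2 * tcrossprod(X1, X2)
  r <- sqrt(pmax(r2, 0)) / lengthscale
  (1 + sqrt(5) * r + 5 * r^2 / 3) * exp(-sqrt(5) * r)
}

#' Fit a Gaussian-process regression surrogate
#'
#' Zero-mean GP on standardized responses with a Matern-5/2 kernel. Used as
#' the surrogate for the upper-confidence-bound acquisition; coordinates are
#' expected on the unit cube (normalize through the search bounds first).
#'
#' @param X n x d matrix of inputs in `[0, 1]^d`.
#' @param y Numeric response vector of length n.
#' @param lengthscale Kernel length scale on normalized coordinates
#'   (default 0.3).
#' @param noise Observation-noise variance relative to the (standardized)
#'   unit signal variance (default 1e-6).
#' @return A `gp_fit` object for [gp_posterior()].
#' @export
gp_fit <- function(X, y, lengthscale = 0.3, noise = 1e-6) {
  X <- as.matrix(X)
  stopifnot(nrow(X) == length(y))
  mu <- mean(y)
  sdy <- stats::sd(y)
  if (!is.finite(sdy) || sdy == 0) sdy <- 1
  ys <- (y - mu) / sdy
  K <- matern52(X, X, lengthscale) + diag(noise + 1e-10, nrow(X))
  L <- chol(K)
  alpha <- backsolve(L, forwardsolve(t(L), ys))
  structure(list(X = X, L = L, alpha = alpha, mu = mu, sdy = sdy,
                 lengthscale = lengthscale),
            class = "gp_fit")
}

#' Posterior mean and standard deviation of a fitted GP
#'
#' @param fit A `gp_fit`.
#' @param Xnew m x d matrix of query points on the same normalized scale.
#' @return List with vectors `mean` and `sd` of length m.
#' @export
gp_posterior <- function(fit, Xnew) {
  Xnew <- as.matrix(Xnew)
  Ks <- matern52(Xnew, fit$X, fit$lengthscale)
  mean_s <- drop(Ks %*% fit$alpha)
  V <- forwardsolve(t(fit$L), t(Ks))
  var_s <- pmax(1 - colSums(V^2), 0)
  list(mean = fit$mu + fit$sdy * mean_s,
       sd = fit$sdy * sqrt(var_s))
}

## normalize / denormalize points through the bounds box
normalize_point <- function(x, bounds)
  (x - bounds[1, ]) / pmax(bounds[2, ] - bounds[1, ], .Machine$double.eps)
denormalize_point <- function(u, bounds)
  bounds[1, ] + u * (bounds[2, ] - bounds[1, ])

#' Propose the next hyperparameter point by GP-UCB
#'
#' Fits a GP surrogate to the negated losses of the evaluation history and
#' returns the in-bounds point maximizing the upper confidence bound
#' `posterior mean + ucb_kappa * posterior sd`. The acquisition is maximized
#' by a seeded random candidate scan followed by L-BFGS-B polishing from the
#' best candidates. An empty history yields a uniform random in-bounds point.
#'
#' @param history List with `points` (n x d matrix, original scale) and
#'   `loss` (numeric vector); or NULL / zero rows for an empty history.
#' @param bounds 2 x d matrix (row 1 lower, row 2 upper), named columns.
#' @param ucb_kappa Exploration weight (default 2).
#' @param seed Integer seed for the candidate scan.
#' @param n_candidates Size of the random candidate scan (default 256).
#' @return Named numeric vector: the proposed point on the original scale.
#' @export
propose_ucb_point <- function(history, bounds, ucb_kappa = 2, seed = 1L,
                              n_candidates = 256L) {
  bounds <- as.matrix(bounds)
  d <- ncol(bounds)
  if (any(bounds[2, ] < bounds[1, ])) stop("invalid bounds: upper < lower")
  if (all(bounds[2, ] == bounds[1, ]))
    return(stats::setNames(bounds[1, ], colnames(bounds)))
  if (is.null(history) || length(history$loss) == 0) {
    u <- withr::with_seed(seed, stats::runif(d))
    return(stats::setNames(denormalize_point(u, bounds), colnames(bounds)))
  }
  U <- t(apply(as.matrix(history$points), 1, normalize_point, bounds))
  if (d == 1) U <- matrix(as.vector(U), ncol = 1)
  fit <- gp_fit(U, -history$loss)
  ucb <- function(u) {
    po <- gp_posterior(fit, matrix(u, ncol = d))
    po$mean + ucb_kappa * po$sd
  }
  withr::with_seed(seed, {
    cand <- matrix(stats::runif(n_candidates * d), ncol = d)
    cand <- rbind(cand, U)  # revisit observed points' neighborhoods
    acq <- {
      po <- gp_posterior(fit, cand)
      po$mean + ucb_kappa * po$sd
    }
    top <- order(acq, decreasing = TRUE)[seq_len(min(5, nrow(cand)))]
    best_u <- cand[top[1], ]
    best_a <- acq[top[1]]
    for (i in top) {
      opt <- stats::optim(cand[i, ], function(u) -ucb(u),
                          method = "L-BFGS-B", lower = rep(0, d),
                          upper = rep(1, d))
      if (-opt$value > best_a) {
        best_a <- -opt$value
        best_u <- opt$par
      }
    }
  })
  stats::setNames(denormalize_point(best_u, bounds), colnames(bounds))
}

#' Bayesian optimization of a scalar loss over a box
#'
#' Evaluates `n1` uniform random points, then any supplied probe points,
#' then `n2` sequential GP-UCB proposals; returns the argmin of the loss
#' over everything evaluated. This is the generic engine behind
#' [bayes_optimize()]; the objective is an arbitrary function of a named
#' point vector.
#'
#' @param objective Function(point named vector) -> scalar loss.
#' @param bounds 2 x d bounds matrix with named columns.
#' @param n1 Random initialization count (>= 1).
#' @param n2 Sequential acquisition count (>= 0).
#' @param ucb_kappa UCB exploration weight (default 2).
#' @param probe_points Optional list of named point vectors evaluated after
#'   the random stage (e.g. previous iterations' optima).
#' @param seed Integer seed.
#' @return List with `best_point`, `best_loss`, and `history`
#'   (`points` matrix + `loss` vector, in evaluation order).
#' @export
optimize_loss_ucb <- function(objective, bounds, n1 = 10L, n2 = 25L,
                              ucb_kappa = 2, probe_points = list(),
                              seed = 1L) {
  bounds <- as.matrix(bounds)
  stopifnot(n1 >= 1, n2 >= 0)
  d <- ncol(bounds)
  init <- withr::with_seed(seed, matrix(stats::runif(n1 * d), ncol = d))
  pts <- t(apply(init, 1, denormalize_point, bounds))
  if (d == 1) pts <- matrix(as.vector(pts), ncol = 1)
  colnames(pts) <- colnames(bounds)
  for (pp in probe_points)
    pts <- rbind(pts, pp[colnames(bounds)])
  loss <- apply(pts, 1, objective)
  for (j in seq_len(n2)) {
    nxt <- propose_ucb_point(list(points = pts, loss = loss), bounds,
                             ucb_kappa = ucb_kappa, seed = seed + 1009L * j)
    pts <- rbind(pts, nxt)
    loss <- c(loss, objective(nxt))
  }
  rownames(pts) <- NULL
  best <- which.min(loss)
  list(best_point = stats::setNames(pts[best, ], colnames(bounds)),
       best_loss = loss[best],
       history = list(points = pts, loss = loss))
}
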