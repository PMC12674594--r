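## Bayesian optimization of the electron-proton correlation admixture
## {b_epc, c_epc} against a dataset-RMSD objective: Latin hypercube
## presampling, a Matern-5/2 Gaussian process with marginal-likelihood
## hyperparameter fitting, and plain expected improvement maximised over a
## dense candidate grid (exact and reproducible on the 1-2D box).

#' Configuration of an admixture optimization
#'
#' Defaults follow the working protocol: 40 Latin-hypercube presamples plus
#' 20 acquisition points in 2-D, 10 + 3 in 1-D, bounds 0..1 per dimension.
#' In 1-D mode the free parameter is b_epc and the objective receives
#' (b_epc, 1 - b_epc).
#'
#' @param mode "1d" or "2d"
#' @param bounds 2-column matrix (lower, upper) per dimension
#' @param n_presample,n_acquisition sampling budget (defaults per mode)
#' @param seed random seed controlling the whole run
#' @return an `OptConfig`
#' @export
opt_config <- function(mode = c("1d", "2d"), bounds = NULL,
                       n_presample = NULL, n_acquisition = NULL, seed = 1L) {
  mode <- match.arg(mode)
  d <- if (mode == "1d") 1L else 2L
  if (is.null(bounds)) bounds <- matrix(rep(c(0, 1), each = d), ncol = 2)
  if (is.null(n_presample)) n_presample <- if (mode == "1d") 10L else 40L
  if (is.null(n_acquisition)) n_acquisition <- if (mode == "1d") 3L else 20L
  stopifnot(n_presample >= 2, n_acquisition >= 0,
            all(bounds[, 1] < bounds[, 2]), all(is.finite(bounds)))
  structure(list(mode = mode, dims = d, bounds = bounds,
                 n_presample = as.integer(n_presample),
                 n_acquisition = as.integer(n_acquisition),
                 seed = as.integer(seed)),
            class = "OptConfig")
}

#' Latin hypercube sample
#'
#' One point per equal-width stratum in every dimension; reproducible under a
#' fixed seed.
#'
#' @param n number of points
#' @param dims dimension
#' @param bounds 2-column matrix of (lower, upper) per dimension
#' @param seed integer seed
#' @return n x dims matrix
#' @export
latin_hypercube <- function(n, dims = 1L, bounds = NULL, seed = 1L) {
  if (n < 1) stop("n must be >= 1")
  if (is.null(bounds)) bounds <- matrix(rep(c(0, 1), each = dims), ncol = 2)
  set.seed(seed)
  u <- lhs::randomLHS(n, dims)
  lo <- bounds[, 1]; hi <- bounds[, 2]
  sweep(sweep(u, 2, hi - lo, `*`), 2, lo, `+`)
}

## ---------------------------------------------------------------------------
## Exact-inference Gaussian process with a Matern-5/2 kernel

matern52 <- function(X1, X2, ls, amp2) {
  d2 <- outer(rowSums(X1^2), rowSums(X2^2), `+`) - 2 * tcrossprod(X1, X2)
  r <- sqrt(pmax(d2, 0)) / ls
  amp2 * (1 + sqrt(5) * r + 5 * r^2 / 3) * exp(-sqrt(5) * r)
}

#' Fit a Matern-5/2 Gaussian process posterior
#'
#' Zero-noise interpolating GP (small jitter for numerical stability);
#' length-scale and amplitude fitted by marginal-likelihood maximization from
#' several deterministic restarts; constant prior mean set to the sample
#' mean.
#'
#' @param X matrix of training inputs (n x d)
#' @param y objective values
#' @param jitter diagonal nugget
#' @param n_restarts optimizer restarts
#' @return a `GPPosterior` with `$predict(Xnew)` returning mean and variance
#' @export
gp_posterior <- function(X, y, jitter = 1e-8, n_restarts = 5L) {
  X <- as.matrix(X)
  stopifnot(nrow(X) >= 2, all(is.finite(y)))
  mu0 <- mean(y)
  yc <- y - mu0
  span <- max(1e-3, max(dist(X)))
  nll <- function(th) {
    ls <- exp(th[1]); amp2 <- exp(th[2])
    K <- matern52(X, X, ls, amp2) + diag(jitter, nrow(X))
    L <- tryCatch(chol(K), error = function(e) NULL)
    if (is.null(L)) return(1e10)
    a <- backsolve(L, backsolve(L, yc, transpose = TRUE))
    as.numeric(0.5 * sum(yc * a) + sum(log(diag(L))))
  }
  starts <- expand.grid(ls = log(span * c(0.05, 0.2, 0.5, 1, 2))[seq_len(n_restarts)],
                        amp = log(max(stats::var(yc), 1e-8)))
  best <- NULL
  for (i in seq_len(nrow(starts))) {
    fit <- tryCatch(stats::optim(as.numeric(starts[i, ]), nll,
                                 method = "L-BFGS-B",
                                 lower = c(log(span * 1e-3), -30),
                                 upper = c(log(span * 10), 30)),
                    error = function(e) NULL)
    if (!is.null(fit) && (is.null(best) || fit$value < best$value)) best <- fit
  }
  th <- if (is.null(best)) c(log(span * 0.3), log(max(stats::var(yc), 1e-8))) else best$par
  ls <- exp(th[1]); amp2 <- exp(th[2])
  K <- matern52(X, X, ls, amp2) + diag(jitter, nrow(X))
  L <- tryCatch(chol(K), error = function(e) chol(K + diag(1e-6, nrow(X))))
  alpha <- backsolve(L, backsolve(L, yc, transpose = TRUE))
  structure(list(
    X = X, y = y, mu0 = mu0, ls = ls, amp2 = amp2, L = L, alpha = alpha,
    jitter = jitter,
    predict = function(Xnew) {
      Xnew <- as.matrix(Xnew)
      Ks <- matern52(Xnew, X, ls, amp2)
      mu <- mu0 + as.numeric(Ks %*% alpha)
      v <- backsolve(L, t(Ks), transpose = TRUE)
      var <- pmax(amp2 - colSums(v^2), 0)
      list(mean = mu, var = var)
    }), class = "GPPosterior")
}

#' Expected improvement for minimization
#'
#' `EI = (best - mu) Phi(z) + sd phi(z)` with `z = (best - mu)/sd`; in the
#' zero-variance limit it reduces to `max(best - mu, 0)`.
#'
#' @param mean,sd posterior mean and standard deviation at the candidates
#' @param best incumbent best (lowest) objective value
#' @return EI values (nonnegative)
#' @export
expected_improvement <- function(mean, sd, best) {
  ei <- pmax(best - mean, 0)
  pos <- sd > 1e-14
  if (any(pos)) {
    z <- (best[1] - mean[pos]) / sd[pos]
    ei[pos] <- (best - mean[pos]) * stats::pnorm(z) + sd[pos] * stats::dnorm(z)
  }
  pmax(ei, 0)
}

## dense candidate grid over the box
candidate_grid <- function(config) {
  if (config$dims == 1L) {
    matrix(seq(config$bounds[1, 1], config$bounds[1, 2], length.out = 2001),
           ncol = 1)
  } else {
    g1 <- seq(config$bounds[1, 1], config$bounds[1, 2], length.out = 201)
    g2 <- seq(config$bounds[2, 1], config$bounds[2, 2], length.out = 201)
    as.matrix(expand.grid(g1, g2))
  }
}

#' Bayesian optimization of the correlation admixture
#'
#' Runs the full presample + acquisition protocol against an arbitrary
#' objective.  The objective receives `(b_epc, c_epc)`; in 1-D mode the
#' sampled parameter is b_epc and `c_epc = 1 - b_epc`.  Objective values are
#' cached on parameter points rounded to 1e-6; failed evaluations are
#' recorded and skipped.
#'
#' @param objective function(b_epc, c_epc) -> scalar (e.g. dataset RMSD)
#' @param config an `OptConfig`
#' @param verbose print evaluations
#' @return an `OptResult`: evaluation history, best point and value, GP
#'   hyperparameters at termination, seed
#' @export
optimize_admixture <- function(objective, config = opt_config("1d"),
                               verbose = FALSE) {
  cache <- new.env(parent = emptyenv())
  n_eval <- 0L
  eval_pt <- function(x) {
    pt <- if (config$mode == "1d") c(x[1], 1 - x[1]) else c(x[1], x[2])
    key <- paste(round(pt, 6), collapse = ",")
    if (!is.null(cache[[key]])) return(cache[[key]])
    val <- tryCatch(objective(pt[1], pt[2]), error = function(e) NA_real_)
    n_eval <<- n_eval + 1L
    cache[[key]] <- val
    if (verbose) message(sprintf("eval %2d: b=%.4f c=%.4f -> %s", n_eval,
                                 pt[1], pt[2], format(val)))
    val
  }
  X <- latin_hypercube(config$n_presample, config$dims, config$bounds,
                       config$seed)
  y <- apply(X, 1, eval_pt)
  for (k in seq_len(config$n_acquisition)) {
    ok <- is.finite(y)
    if (sum(ok) < 2) stop("too many failed objective evaluations")
    gp <- gp_posterior(X[ok, , drop = FALSE], y[ok])
    cand <- candidate_grid(config)
    pr <- gp$predict(cand)
    ei <- expected_improvement(pr$mean, sqrt(pr$var), min(y[ok]))
    xnew <- cand[which.max(ei), , drop = FALSE]
    X <- rbind(X, xnew)
    y <- c(y, eval_pt(xnew))
  }
  ok <- is.finite(y)
  ib <- which(ok)[which.min(y[ok])]
  gp <- gp_posterior(X[ok, , drop = FALSE], y[ok])
  pts <- if (config$mode == "1d") cbind(b_epc = X[, 1], c_epc = 1 - X[, 1])
         else cbind(b_epc = X[, 1], c_epc = X[, 2])
  structure(list(
    points = pts, values = y, best_index = ib,
    best_point = pts[ib, ], best_value = y[ib],
    gp_hyperparameters = list(length_scale = gp$ls, amplitude2 = gp$amp2),
    n_evaluations = length(y), seed = config$seed, config = config),
    class = "OptResult")
}

#' @export
print.OptResult <- function(x, ...) {
  cat(sprintf("OptResult: %d evaluations; best b_epc = %.4f, c_epc = %.4f, objective = %.6g (seed %d)\n",
              x$n_evaluations, x$best_point[1], x$best_point[2],
              x$best_value, x$seed))
  invisible(x)
}
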