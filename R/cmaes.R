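#' Covariance matrix adaptation evolution strategy (CMA-ES)
#'
#' Compact implementation of the standard (mu/mu_w, lambda) CMA-ES with
#' cumulative step-size adaptation and rank-one/rank-mu covariance updates.
#' Box constraints are enforced by projecting sampled candidates onto the
#' bounds before evaluation. Seeded and fully reproducible; the best-so-far
#' error trajectory is non-increasing by construction (elitist bookkeeping,
#' not elitist selection).
#'
#' @param fn Objective function of a numeric vector; smaller is better.
#' @param x0 Initial mean.
#' @param sigma0 Initial step size (scalar, on the scale of `x0`), default
#'   0.3x the parameter scale.
#' @param lower,upper Bounds (recycled).
#' @param generations Number of generations (50-500 is typical).
#' @param popsize Lambda; default `4 + floor(3 log n)`.
#' @param seed RNG seed (restored on exit).
#' @return List with `par`, `value`, `trajectory` (best-so-far per
#'   generation), `generations`, `popsize`, `seed`.
#' @export
cma_es <- function(fn, x0, sigma0 = 0.3 * max(abs(x0), 1), lower = -Inf,
                   upper = Inf, generations = 200, popsize = NULL, seed = 1) {
  n <- length(x0)
  lower <- rep_len(lower, n); upper <- rep_len(upper, n)
  lambda <- if (is.null(popsize)) 4 + floor(3 * log(n)) else popsize
  mu <- floor(lambda / 2)
  w <- log(mu + 0.5) - log(seq_len(mu))
  w <- w / sum(w)
  mueff <- 1 / sum(w^2)
  cc <- (4 + mueff / n) / (n + 4 + 2 * mueff / n)
  cs <- (mueff + 2) / (n + mueff + 5)
  c1 <- 2 / ((n + 1.3)^2 + mueff)
  cmu <- min(1 - c1, 2 * (mueff - 2 + 1 / mueff) / ((n + 2)^2 + mueff))
  damps <- 1 + 2 * max(0, sqrt((mueff - 1) / (n + 1)) - 1) + cs
  chiN <- sqrt(n) * (1 - 1 / (4 * n) + 1 / (21 * n^2))

  old <- .Random.seed_exists()
  on.exit(restore_seed(old), add = TRUE)
  set.seed(seed)

  xmean <- as.numeric(x0)
  sigma <- sigma0
  pc <- ps <- numeric(n)
  C <- diag(n)
  best_val <- Inf; best_par <- xmean
  traj <- numeric(generations)

  for (g in seq_len(generations)) {
    eig <- eigen(C, symmetric = TRUE)
    D <- sqrt(pmax(eig$values, 1e-20))
    B <- eig$vectors
    arz <- matrix(stats::rnorm(n * lambda), n, lambda)
    ary <- B %*% (D * arz)
    arx <- xmean + sigma * ary
    arx <- pmin(pmax(arx, lower), upper)
    fit <- apply(arx, 2, fn)
    o <- order(fit)
    if (fit[o[1]] < best_val) { best_val <- fit[o[1]]; best_par <- arx[, o[1]] }
    traj[g] <- best_val

    sel <- o[seq_len(mu)]
    xold <- xmean
    xmean <- as.numeric(arx[, sel, drop = FALSE] %*% w)
    yw <- (xmean - xold) / sigma
    Cinv_half <- B %*% ((1 / D) * t(B))
    ps <- (1 - cs) * ps + sqrt(cs * (2 - cs) * mueff) * as.numeric(Cinv_half %*% yw)
    hsig <- sqrt(sum(ps^2)) / sqrt(1 - (1 - cs)^(2 * g)) / chiN < 1.4 + 2 / (n + 1)
    pc <- (1 - cc) * pc + hsig * sqrt(cc * (2 - cc) * mueff) * yw
    artmp <- (arx[, sel, drop = FALSE] - xold) / sigma
    C <- (1 - c1 - cmu) * C +
      c1 * (pc %o% pc + (1 - hsig) * cc * (2 - cc) * C) +
      cmu * artmp %*% (w * t(artmp))
    sigma <- sigma * exp((cs / damps) * (sqrt(sum(ps^2)) / chiN - 1))
    if (!is.finite(sigma) || sigma > 1e6 * sigma0) sigma <- sigma0
  }
  list(par = best_par, value = best_val, trajectory = traj,
       generations = generations, popsize = lambda, seed = seed)
}

#' Powell's direction-set minimizer
#'
#' Derivative-free minimization by successive line searches along an
#' updated direction set (Powell's method), with one-dimensional searches
#' by golden-section/parabolic interpolation ([stats::optimize()]) over an
#' adaptively scaled bracket.
#'
#' @param fn Objective function.
#' @param x0 Start point.
#' @param step Initial line-search half-width per coordinate (recycled).
#' @param tol Relative convergence tolerance on the objective.
#' @param maxit Maximum outer iterations.
#' @return List with `par`, `value`, `iterations`, `converged`.
#' @export
powell_minimize <- function(fn, x0, step = 1, tol = 1e-6, maxit = 50) {
  n <- length(x0)
  dirs <- diag(n) * rep_len(step, n)
  x <- as.numeric(x0)
  fx <- fn(x)
  converged <- FALSE
  for (it in seq_len(maxit)) {
    x_start <- x; f_start <- fx
    biggest_drop <- 0; biggest_i <- 1
    for (i in seq_len(n)) {
      d <- dirs[, i]
      ls <- stats::optimize(function(a) fn(x + a * d), interval = c(-2, 2),
                            tol = 1e-4)
      if (ls$objective < fx) {
        drop <- fx - ls$objective
        if (drop > biggest_drop) { biggest_drop <- drop; biggest_i <- i }
        x <- x + ls$minimum * d
        fx <- ls$objective
      }
    }
    # replace the direction of largest decrease with the net displacement
    net <- x - x_start
    if (sqrt(sum(net^2)) > 0) {
      ls <- stats::optimize(function(a) fn(x + a * net), interval = c(-1, 1),
                            tol = 1e-4)
      if (ls$objective < fx) { x <- x + ls$minimum * net; fx <- ls$objective }
      dirs[, biggest_i] <- net
    }
    if (2 * abs(f_start - fx) <= tol * (abs(f_start) + abs(fx) + 1e-12)) {
      converged <- TRUE
      break
    }
  }
  list(par = x, value = fx, iterations = it, converged = converged)
}
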