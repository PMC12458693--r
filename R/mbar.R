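#' Multistate Bennett acceptance ratio (MBAR)
#'
#' Solves the self-consistent multistate reweighting equations for the
#' relative reduced free energies of K thermodynamic states given samples
#' pooled from all of them:
#' \deqn{f_i = -\ln \sum_n \frac{\exp(-u_i(x_n))}{\sum_k N_k \exp(f_k - u_k(x_n))}}
#' iterated in log space until the free energies change by less than
#' \code{tol}.
#'
#' @param u_kn an N x K matrix of reduced potentials: row n holds
#'   \eqn{u_k(x_n)} for every state k
#' @param n_k samples drawn from each state (length K, sum N)
#' @param tol convergence tolerance on the free energies (default 1e-10,
#'   comfortably below the 1e-8 contract)
#' @param max_iter iteration cap; non-convergence warns and sets the
#'   \code{divergent} flag (poor window overlap)
#' @return list with reduced free energies \code{f} (first state = 0),
#'   \code{converged}, \code{divergent}, \code{n_iter}, and the weight
#'   matrix \code{w} (N x K, columns sum to 1)
#' @export
mbar <- function(u_kn, n_k, tol = 1e-10, max_iter = 100000) {
  u_kn <- as.matrix(u_kn)
  K <- ncol(u_kn)
  stopifnot(length(n_k) == K, sum(n_k) == nrow(u_kn), K >= 2)
  log_nk <- log(n_k)
  f <- numeric(K)
  converged <- FALSE
  it <- 0
  # a few self-consistent sweeps for stability, then Newton-Raphson on the
  # K-1 free differences (the extended-bridge-sampling objective is convex)
  while (it < max_iter) {
    it <- it + 1
    d <- row_logsumexp(sweep(-u_kn, 2, f + log_nk, "+"))
    fnew <- -apply(-u_kn - d, 2, logsumexp)
    fnew <- fnew - fnew[1]
    delta <- max(abs(fnew - f))
    f <- fnew
    if (delta < tol) { converged <- TRUE; break }
    if (it >= 10) break
  }
  while (!converged && it < max_iter) {
    it <- it + 1
    d <- row_logsumexp(sweep(-u_kn, 2, f + log_nk, "+"))
    Wn <- exp(sweep(-u_kn - d, 2, f, "+"))          # N x K, col sums ~ 1
    g <- n_k * colSums(Wn) - n_k                    # gradient
    WNW <- crossprod(Wn) * outer(n_k, n_k)          # N_i N_j sum_n W_ni W_nj
    H <- diag(n_k * colSums(Wn), K) - WNW
    step <- tryCatch(solve(H[-1, -1, drop = FALSE], -g[-1]),
                     error = function(e) NULL)
    if (is.null(step) || any(!is.finite(step))) {
      # fall back to a self-consistent sweep
      fnew <- -apply(-u_kn - d, 2, logsumexp)
      fnew <- fnew - fnew[1]
    } else {
      fnew <- f
      fnew[-1] <- f[-1] + pmin(pmax(step, -2), 2)   # damped step
    }
    delta <- max(abs(fnew - f))
    f <- fnew
    if (delta < tol) { converged <- TRUE; break }
  }
  d <- row_logsumexp(sweep(-u_kn, 2, f + log_nk, "+"))
  w <- exp(sweep(-u_kn - d, 2, f, "+"))
  # adjacent-window phase-space overlap (normalised weight cross-products);
  # effectively zero means the free-energy difference across that join is
  # unidentifiable and its uncertainty divergent
  ov <- vapply(seq_len(K - 1), function(k) {
    sum(w[, k] * w[, k + 1]) * nrow(u_kn) /
      sqrt(sum(w[, k]^2) * sum(w[, k + 1]^2) + 1e-300) /  nrow(u_kn)
  }, numeric(1))
  divergent <- !converged || any(!is.finite(f)) || any(ov < 1e-8)
  if (divergent)
    warning("MBAR windows have (near-)zero overlap or failed to converge; ",
            "the estimated uncertainty is divergent")
  list(f = f, converged = converged, divergent = divergent, n_iter = it,
       w = w, overlap = ov)
}

#' Free-energy difference of an alchemical leg by MBAR
#'
#' Estimates \eqn{\Delta G = [f(\lambda=1) - f(\lambda=0)]/\beta} from the
#' leg's reduced-potential samples.  Statistical uncertainty is estimated by
#' bootstrap over samples (resampled within each window); when the leg
#' carries independent repeats, the across-repeat standard deviation is also
#' reported.
#'
#' @param leg an \code{alchemical_leg} (from [run_alchemical_leg()]) or a
#'   list with \code{u_kn}, \code{n_k} and \code{beta}
#' @param n_boot bootstrap resamples for the uncertainty (default 30; 0
#'   skips it)
#' @param tol passed to [mbar()]
#' @return list with \code{dg} (kcal/mol), \code{se} (bootstrap),
#'   \code{f} (reduced free energies per window), \code{divergent}
#' @export
mbar_free_energy <- function(leg, n_boot = 30, tol = 1e-10) {
  beta <- leg$beta %||% leg$params$beta
  fit <- mbar(leg$u_kn, leg$n_k, tol = tol)
  K <- length(leg$n_k)
  dg <- (fit$f[K] - fit$f[1]) / beta
  se <- NA_real_
  if (n_boot > 0) {
    blocks <- rep(seq_len(K), leg$n_k)
    boots <- vapply(seq_len(n_boot), function(b) {
      idx <- unlist(lapply(seq_len(K), function(k) {
        rows <- which(blocks == k)
        sample(rows, length(rows), replace = TRUE)
      }))
      fb <- mbar(leg$u_kn[idx, , drop = FALSE], leg$n_k, tol = max(tol, 1e-8))$f
      (fb[K] - fb[1]) / beta
    }, numeric(1))
    se <- sd(boots)
  }
  list(dg = dg, se = se, f = fit$f, divergent = fit$divergent,
       n_iter = fit$n_iter)
}

#' Bennett acceptance ratio (two states)
#'
#' Independent two-state estimator used to cross-check MBAR: solves the
#' Bennett self-consistency equation by root finding.
#'
#' @param w_f forward reduced work values \eqn{u_1(x) - u_0(x)} for samples
#'   from state 0
#' @param w_r reverse reduced work values \eqn{u_0(x) - u_1(x)} for samples
#'   from state 1
#' @return reduced free-energy difference \eqn{f_1 - f_0}
#' @export
bar_free_energy <- function(w_f, w_r) {
  nf <- length(w_f); nr <- length(w_r)
  stopifnot(nf > 0, nr > 0)
  M <- log(nf / nr)
  g <- function(df) {
    sum(1 / (1 + exp(M + w_f - df))) - sum(1 / (1 + exp(-M + w_r + df)))
  }
  lo <- min(-abs(w_f), -abs(w_r)) - 50
  hi <- max(abs(w_f), abs(w_r)) + 50
  uniroot(g, c(lo, hi), tol = 1e-12)$root
}
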