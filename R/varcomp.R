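# Variance-component estimation for the sketched LMM.
#
# Model: y_s1 ~ N(X beta, sigma_g^2 * H_tau) with H_tau = K/m + tau * I,
# tau = sigma_e^2 / sigma_g^2, so h^2 = 1/(1 + tau). One symmetric
# eigendecomposition K = U Lambda U' makes H_tau diagonal in the rotated
# basis for every tau: d_i = lambda_i/m + tau. beta and sigma_g^2 are
# profiled out analytically, leaving a one-dimensional likelihood in
# theta = log tau that is maximized by Newton's method with analytic first
# and second derivatives, monotone step halving, and a golden-section
# safeguard.

#' Eigendecompose a (sketched) GRM
#'
#' Symmetric eigendecomposition with eigenvalues clipped below at zero
#' (small negative values arise only from floating point; the sketched GRM
#' is PSD by construction). The marker count `m` used to scale the GRM in
#' `H_tau = K/m + tau I` travels with the spectrum.
#'
#' @param K Symmetric `s1 x s1` matrix with finite entries.
#' @param markers Marker count `m` dividing `K` inside `H_tau`; default 1
#'   (i.e. `K` is used unscaled).
#' @return A `grm_spectrum`: `values` (non-increasing, >= 0), `vectors`
#'   (orthonormal), `markers`, `n_clipped`.
#' @export
eigendecompose <- function(K, markers = 1L) {
  K <- as.matrix(K)
  if (!all(is.finite(K))) stop("GRM contains non-finite entries")
  if (nrow(K) != ncol(K)) stop("GRM must be square")
  ee <- eigen((K + t(K)) / 2, symmetric = TRUE)
  n_clipped <- sum(ee$values < 0)
  if (n_clipped > 0L) {
    message(sprintf("eigendecompose: clipped %d negative eigenvalue(s) at 0 (min %.3e)",
                    n_clipped, min(ee$values)))
  }
  structure(
    list(values = pmax(ee$values, 0), vectors = ee$vectors,
         markers = as.numeric(markers), n_clipped = n_clipped),
    class = "grm_spectrum"
  )
}

# Rotate response and covariates into the eigenbasis once per fit.
.rotate <- function(spectrum, ys1, X) {
  U <- spectrum$vectors
  list(yt = drop(crossprod(U, ys1)),
       Xt = if (is.null(X) || ncol(as.matrix(X)) == 0L) NULL
            else crossprod(U, as.matrix(X)))
}

#' Profiled log-likelihood of the sketched LMM at a given tau
#'
#' Evaluates the Gaussian log-likelihood of `y_s1 ~ N(X beta, sigma_g^2
#' (K/m + tau I))` with `beta` and `sigma_g^2` replaced by their closed-form
#' maximizers, together with analytic first and second derivatives with
#' respect to `theta = log tau`. With `mode = "REML"` the restricted
#' likelihood is used: the variance divisor becomes `s1 - k` and the term
#' `-log det(X' H^-1 X) / 2` is added, which removes the downward bias the
#' fixed effects induce in the variance estimate.
#'
#' @param tau Positive variance ratio `sigma_e^2 / sigma_g^2`.
#' @param spectrum A [eigendecompose()] result (carries the marker scale).
#' @param ys1 Sketched response vector.
#' @param X Covariate matrix in sketched space (may be `NULL` for no fixed
#'   effects).
#' @param mode `"REML"` (default) or `"ML"`.
#' @return List with `value`, `grad`, `hess` (derivatives in `theta`),
#'   `beta`, `sigma_g2`, `tau`.
#' @export
profile_loglik <- function(tau, spectrum, ys1, X = NULL,
                           mode = c("REML", "ML")) {
  mode <- match.arg(mode)
  stopifnot(inherits(spectrum, "grm_spectrum"))
  if (!is.finite(tau) || tau <= 0) stop("`tau` must be positive and finite")
  rot <- .rotate(spectrum, ys1, X)
  .profile_loglik_rotated(tau, spectrum$values / spectrum$markers,
                          rot$yt, rot$Xt, mode)
}

# Core evaluation in the rotated basis. lam = lambda_i / m.
.profile_loglik_rotated <- function(tau, lam, yt, Xt, mode) {
  s1 <- length(yt)
  d <- lam + tau
  if (any(d <= 0)) stop("non-positive variance weight; tau trace invalid")
  w <- 1 / d
  wd <- -tau * w^2              # d w / d theta
  wdd <- -tau * w^2 + 2 * tau^2 * w^3

  k <- if (is.null(Xt)) 0L else ncol(Xt)
  if (k > 0L) {
    A <- crossprod(Xt, w * Xt)
    beta <- solve(A, crossprod(Xt, w * yt))
    r <- yt - drop(Xt %*% beta)
  } else {
    beta <- numeric(0)
    r <- yt
  }
  Q <- sum(w * r^2)
  if (Q <= 0) stop("degenerate residual sum of squares in profile likelihood")
  Qd <- sum(wd * r^2)
  if (k > 0L) {
    t1 <- crossprod(Xt, wd * r)            # k-vector
    Qdd <- sum(wdd * r^2) - 2 * sum(t1 * solve(A, t1))
  } else {
    Qdd <- sum(wdd * r^2)
  }

  logd_d <- sum(tau * w)
  logd_dd <- sum(tau * w - tau^2 * w^2)

  if (mode == "ML") {
    nn <- s1
    extra <- 0; extrad <- 0; extradd <- 0
  } else {
    nn <- s1 - k
    if (nn <= 0) stop("REML requires s1 > k")
    if (k > 0L) {
      Ainv <- solve(A)
      Adot <- crossprod(Xt, wd * Xt)
      Addot <- crossprod(Xt, wdd * Xt)
      extra <- determinant(A, logarithm = TRUE)$modulus[1L]
      M <- Ainv %*% Adot
      extrad <- sum(diag(M))
      extradd <- sum(diag(Ainv %*% Addot)) - sum(M * t(M))
    } else {
      extra <- 0; extrad <- 0; extradd <- 0
    }
  }

  sigma_g2 <- Q / nn
  value <- -0.5 * (nn * log(2 * pi * sigma_g2) + sum(log(d)) + extra + nn)
  grad <- -0.5 * (nn * Qd / Q + logd_d + extrad)
  hess <- -0.5 * (nn * (Qdd * Q - Qd^2) / Q^2 + logd_dd + extradd)
  list(value = value, grad = grad, hess = hess,
       beta = drop(beta), sigma_g2 = sigma_g2, tau = tau)
}

#' Fit variance components by Newton's method
#'
#' Maximizes the profiled (restricted) log-likelihood over
#' `theta = log tau` starting from `log(init_tau)`. Newton steps use the
#' analytic gradient and Hessian; a proposed step is halved until the
#' likelihood does not decrease, and `theta` is kept inside
#' `[log 1e-8, log 1e8]`. Convergence is declared when the accepted step or
#' the gradient falls below `tol`. If Newton fails to converge within
#' `max_iter` iterations, a golden-section search over
#' `theta in [log 1e-6, log 1e6]` provides the estimate and the fit is
#' flagged `converged = FALSE`.
#'
#' @param spectrum A [eigendecompose()] result.
#' @param ys1 Sketched response.
#' @param X Sketched covariate matrix (or `NULL`).
#' @param init_tau Initial variance ratio, default 1 (i.e. h^2 = 0.5).
#' @param tol Convergence tolerance on the step and gradient.
#' @param max_iter Maximum Newton iterations.
#' @param mode `"REML"` (default) or `"ML"`.
#' @return A `variance_components` object: `tau`, `sigma_g2`, `sigma_e2`,
#'   `h2 = 1/(1+tau)`, `beta`, `loglik`, `iterations`, `converged`, `mode`,
#'   and the iteration `trace`.
#' @export
fit_variance_components <- function(spectrum, ys1, X = NULL, init_tau = 1.0,
                                    tol = 1e-6, max_iter = 100L,
                                    mode = c("REML", "ML")) {
  mode <- match.arg(mode)
  stopifnot(inherits(spectrum, "grm_spectrum"))
  if (!is.finite(init_tau) || init_tau <= 0) stop("`init_tau` must be positive")
  rot <- .rotate(spectrum, ys1, X)
  lam <- spectrum$values / spectrum$markers
  pl <- function(theta) {
    f <- .profile_loglik_rotated(exp(theta), lam, rot$yt, rot$Xt, mode)
    if (!is.finite(f$value)) {
      stop("non-finite profile log-likelihood at tau = ", exp(theta),
           "; tau trace: ", paste(signif(exp(trace_theta), 4), collapse = ", "))
    }
    f
  }

  lo_th <- log(1e-8); hi_th <- log(1e8)
  theta <- min(max(log(init_tau), lo_th), hi_th)
  trace_theta <- theta
  f <- pl(theta)
  converged <- FALSE
  it <- 0L

  while (it < max_iter) {
    it <- it + 1L
    if (abs(f$grad) < tol) { converged <- TRUE; break }
    step <- if (is.finite(f$hess) && f$hess < 0) -f$grad / f$hess
            else sign(f$grad) # Hessian not negative: plain ascent step
    if (abs(step) > 10) step <- sign(step) * 10
    accepted <- FALSE
    for (h in 1:40) {
      cand_th <- min(max(theta + step, lo_th), hi_th)
      if (cand_th == theta) break
      cand <- pl(cand_th)
      if (is.finite(cand$value) && cand$value >= f$value - 1e-12) {
        accepted <- TRUE
        break
      }
      step <- step / 2
    }
    if (!accepted) break
    moved <- abs(cand_th - theta)
    theta <- cand_th
    f <- cand
    trace_theta <- c(trace_theta, theta)
    if (moved < tol) {
      # at a box boundary with the gradient pointing outward this is the
      # constrained maximizer; otherwise a genuinely small Newton step
      converged <- TRUE
      break
    }
  }

  if (!converged) {
    opt <- stats::optimize(function(th) pl(th)$value,
                           interval = c(log(1e-6), log(1e6)),
                           maximum = TRUE, tol = 1e-9)
    if (opt$objective > f$value) {
      theta <- opt$maximum
      f <- pl(theta)
      trace_theta <- c(trace_theta, theta)
    }
  }

  tau <- exp(theta)
  structure(
    list(tau = tau, sigma_g2 = f$sigma_g2, sigma_e2 = tau * f$sigma_g2,
         h2 = 1 / (1 + tau), beta = f$beta, loglik = f$value,
         iterations = it, converged = converged, mode = mode,
         trace = exp(trace_theta)),
    class = "variance_components"
  )
}

#' @export
print.variance_components <- function(x, ...) {
  cat(sprintf(
    "variance components (%s): tau = %.6g, sigma_g2 = %.6g, sigma_e2 = %.6g\n",
    x$mode, x$tau, x$sigma_g2, x$sigma_e2))
  cat(sprintf("  h2 = %.4f, loglik = %.6f, iterations = %d, converged = %s\n",
              x$h2, x$loglik, x$iterations, x$converged))
  invisible(x)
}

#' Write a variance-component fit report
#'
#' @param vc A `variance_components` object.
#' @param path Output text file.
#' @return `path`, invisibly.
#' @export
write_fit_report <- function(vc, path) {
  lines <- c(
    sprintf("mode\t%s", vc$mode),
    sprintf("tau\t%.10g", vc$tau),
    sprintf("sigma_g2\t%.10g", vc$sigma_g2),
    sprintf("sigma_e2\t%.10g", vc$sigma_e2),
    sprintf("h2\t%.10g", vc$h2),
    sprintf("loglik\t%.10g", vc$loglik),
    sprintf("iterations\t%d", vc$iterations),
    sprintf("converged\t%s", vc$converged))
  writeLines(lines, path)
  invisible(path)
}
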