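divergence_model <- function(X, a, b) 1 + a * (1 - b^X)

divergence_jacobian <- function(X, a, b) {
  # d/da = 1 - b^X ; d/db = -a X b^(X-1) (zero at X = 0)
  db <- ifelse(X == 0, 0, -a * X * b^(X - 1))
  cbind(a = 1 - b^X, b = db)
}

#' Fit the saturating lifespan-divergence curve Y = 1 + a(1 - b^X)
#'
#' Nonlinear least squares by Levenberg-Marquardt with b kept inside (0, 1).
#' The model passes through Y(0) = 1 exactly and saturates at 1 + a; a is the
#' asymptotic divergence increment and b the per-unit-time retention rate
#' (smaller b = faster approach to the asymptote). Standard errors come from
#' the Jacobian-based asymptotic covariance s^2 (J'J)^-1.
#'
#' @param series data.frame with columns X (time, >= 0), Y (divergence) and
#'   optionally sex.
#' @param sex optional filter applied to series$sex.
#' @param start optional c(a, b) start values; defaults a0 = max(Y) - 1,
#'   b0 = 0.5.
#' @param maxit iteration cap (default 200).
#' @return list of class `divergence_fit`: a, b, se_a, se_b, rss, sigma2, df,
#'   n, converged, iterations, sex.
#' @export
fit_divergence_curve <- function(series, sex = NULL, start = NULL, maxit = 200L) {
  df_ <- as.data.frame(series)
  if (!is.null(sex)) df_ <- df_[df_$sex == sex, , drop = FALSE]
  X <- df_$X; Y <- df_$Y
  if (length(X) < 3) stop("need at least 3 observations to fit 2 parameters")
  if (any(X < 0)) stop("X (time) must be >= 0")
  if (any(!is.finite(Y))) stop("Y must be finite")
  lo <- 1e-8; hi <- 1 - 1e-8
  if (is.null(start)) start <- c(max(max(Y) - 1, 0.1), 0.5)
  a <- start[1]; b <- min(max(start[2], lo), hi)
  sse <- sum((Y - divergence_model(X, a, b))^2)
  lambda <- 1e-3; converged <- FALSE; it <- 0L
  while (it < maxit) {
    it <- it + 1L
    r <- Y - divergence_model(X, a, b)
    J <- divergence_jacobian(X, a, b)
    JtJ <- crossprod(J)
    g <- crossprod(J, r)
    step_ok <- FALSE
    for (try in 1:30) {
      A <- JtJ + lambda * diag(diag(JtJ) + 1e-12)
      delta <- tryCatch(solve(A, g), error = function(e) NULL)
      if (is.null(delta)) { lambda <- lambda * 10; next }
      a_new <- unname(a + delta[1])
      b_new <- unname(min(max(b + delta[2], lo), hi))
      sse_new <- sum((Y - divergence_model(X, a_new, b_new))^2)
      if (is.finite(sse_new) && sse_new <= sse) {
        step_ok <- TRUE
        lambda <- max(lambda / 10, 1e-12)
        break
      }
      lambda <- lambda * 10
    }
    if (!step_ok) { converged <- TRUE; break }  # no descent direction left
    improvement <- sse - sse_new
    a <- a_new; b <- b_new; sse <- sse_new
    if (improvement < 1e-14 * (sse + 1e-14)) { converged <- TRUE; break }
  }
  if (!converged)
    stop(sprintf(paste0("divergence-curve fit did not converge after %d ",
                        "iterations (a = %.4g, b = %.4g, SSE = %.4g)"),
                 maxit, a, b, sse))
  n <- length(X); dof <- n - 2L
  J <- divergence_jacobian(X, a, b)
  sigma2 <- if (dof > 0) sse / dof else 0
  cov <- tryCatch(sigma2 * solve(crossprod(J)), error = function(e) {
    matrix(NA_real_, 2, 2)
  })
  se <- unname(sqrt(pmax(diag(cov), 0)))
  structure(list(a = unname(a), b = unname(b), se_a = se[1], se_b = se[2],
                 rss = sse, sigma2 = sigma2, df = dof, n = n,
                 converged = converged, iterations = it,
                 sex = if (is.null(sex)) NA_character_ else sex),
            class = "divergence_fit")
}

#' @export
print.divergence_fit <- function(x, ...) {
  cat(sprintf("Y = 1 + a(1 - b^X)%s: a = %.4f (SE %.4f), b = %.4f (SE %.4f), n = %d\n",
              if (is.na(x$sex)) "" else paste0(" [", x$sex, "]"),
              x$a, x$se_a, x$b, x$se_b, x$n))
  invisible(x)
}

#' Compare divergence-curve parameters between the sexes
#'
#' Welch-type t statistic per parameter, t = (theta_F - theta_M) /
#' sqrt(SE_F^2 + SE_M^2), with Welch-Satterthwaite degrees of freedom built
#' from the two fits' residual dfs and a two-sided p.
#'
#' @param fit_F,fit_M `divergence_fit`s for females and males.
#' @return list(t_a, p_a, t_b, p_b, df_a, df_b).
#' @export
compare_parameters <- function(fit_F, fit_M) {
  stopifnot(inherits(fit_F, "divergence_fit"), inherits(fit_M, "divergence_fit"))
  if (!fit_F$converged || !fit_M$converged) stop("both fits must have converged")
  welch_df <- function(sF, sM) {
    if (sF^2 + sM^2 < 1e-24)  # numerically zero SEs from a perfect fit
      stop("zero standard errors (perfect fits): compare parameters exactly instead")
    (sF^2 + sM^2)^2 /
      (sF^4 / max(fit_F$df, 1) + sM^4 / max(fit_M$df, 1))
  }
  comp <- function(thF, thM, sF, sM) {
    df <- welch_df(sF, sM)
    t <- (thF - thM) / sqrt(sF^2 + sM^2)
    list(t = t, df = df, p = 2 * stats::pt(-abs(t), df = df))
  }
  ca <- comp(fit_F$a, fit_M$a, fit_F$se_a, fit_M$se_a)
  cb <- comp(fit_F$b, fit_M$b, fit_F$se_b, fit_M$se_b)
  list(t_a = ca$t, p_a = ca$p, df_a = ca$df,
       t_b = cb$t, p_b = cb$p, df_b = cb$df)
}

#' Simulate a lifespan-divergence time series
#'
#' Gaussian noise around the saturating model, one series per sex.
#'
#' @param params named list like list(F = c(a =, b =), M = c(a =, b =)).
#' @param X time points (shared across sexes).
#' @param noise_sd residual sd.
#' @param seed RNG seed.
#' @return data.frame with columns X, Y, sex.
#' @export
simulate_divergence_series <- function(params, X = 0:19, noise_sd = 0.05, seed = 1) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  do.call(rbind, lapply(names(params), function(sx) {
    p <- params[[sx]]
    data.frame(X = X,
               Y = divergence_model(X, p[["a"]], p[["b"]]) +
                 stats::rnorm(length(X), 0, noise_sd),
               sex = sx, stringsAsFactors = FALSE)
  }))
}
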