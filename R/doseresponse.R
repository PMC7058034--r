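#' Per-concentration dose--response table of classified colonies
#'
#' Aggregates labeled colony records by concentration: total colonies,
#' GFP+ counts and fraction, sectored counts and fraction.  Output rows are
#' sorted by concentration; the result is invariant to the input order.
#'
#' @param records Colony records with `concentration_mM`, `phenotype` and
#'   `sectored` columns.
#' @return Data frame with columns `concentration_mM`, `n`, `n_gfp_pos`,
#'   `frac_gfp_pos`, `n_sectored`, `frac_sectored`.
#' @export
dose_response <- function(records) {
  stopifnot(all(c("concentration_mM", "phenotype", "sectored") %in%
                  names(records)))
  if (nrow(records) == 0L) {
    warning("no colony records; empty dose-response table")
    return(data.frame(concentration_mM = numeric(0), n = integer(0),
                      n_gfp_pos = integer(0), frac_gfp_pos = numeric(0),
                      n_sectored = integer(0), frac_sectored = numeric(0)))
  }
  sp <- split(records, records$concentration_mM)
  out <- do.call(rbind, lapply(sp, function(g) {
    data.frame(concentration_mM = g$concentration_mM[1],
               n = nrow(g),
               n_gfp_pos = sum(g$phenotype == "GFP+"),
               frac_gfp_pos = mean(g$phenotype == "GFP+"),
               n_sectored = sum(g$sectored),
               frac_sectored = mean(g$sectored))
  }))
  out <- out[order(out$concentration_mM), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Axis transforms available to the curve fits.  The steep-step and
# exponential-decline parameterizations are reported on the transformed
# axis, so the transform used is always carried in the result.
axis_transform <- function(name = c("identity", "log10", "negate")) {
  name <- match.arg(name)
  f <- switch(name, identity = function(x) x, log10 = function(x) log10(x),
              negate = function(x) -x)
  attr(f, "name") <- name
  f
}

#' Fit a steep step function to the GFP+ dose--response
#'
#' Least-squares fit of `y = a - a / (1 + exp(-k * (t(x) + b)))` with the
#' steepness `k` held fixed (default 100): a plateau of height `a` at low
#' concentration dropping to 0 beyond `-b` on the transformed axis.  For
#' fixed `b` the model is linear in `a`, so the fit profiles `a` out and
#' searches `b` on a fine grid followed by local refinement; this is robust
#' where generic gradient optimization stalls on the near-flat objective
#' produced by a very steep step.
#'
#' Standard errors come from the Jacobian at the optimum,
#' `se = sqrt(diag(RSS/(n-p) * solve(t(J) %*% J)))`, and p-values from
#' two-sided t-tests of each parameter against 0 with `n - p` degrees of
#' freedom.  With a steep step the derivative with respect to `b` is
#' numerically zero unless a data point falls on the transition, so `se_b`
#' may be reported as `Inf`.
#'
#' @param points Data frame with `concentration_mM` and `frac_gfp_pos`
#'   (e.g. from [dose_response()]), or `x`/`y` columns.
#' @param k Fixed steepness (per transformed-axis unit).
#' @param transform Axis transform: `"identity"`, `"log10"` or `"negate"`.
#' @return An object of class `step_fit`: list with `a`, `b`, `k`, `se_a`,
#'   `se_b`, `p_a`, `p_b`, `rss`, `n`, `transform`, `fitted`.
#' @export
fit_step <- function(points, k = 100, transform = "identity") {
  tf <- axis_transform(transform)
  xy <- extract_xy(points, yname = "frac_gfp_pos")
  x <- tf(xy$x); y <- xy$y
  n <- length(x)
  if (n < 4L) stop("need at least 4 points to fit the step function")
  g <- function(b) 1 / (1 + exp(pmin(700, k * (x + b))))
  a_of_b <- function(b) {
    gv <- g(b); s <- sum(gv^2)
    if (s < 1e-300) 0 else sum(gv * y) / s
  }
  obj <- function(b) { gv <- g(b); a <- a_of_b(b); sum((y - a * gv)^2) }
  bs <- seq(-max(x) - 1, -min(x) + 1, length.out = 4001L)
  vals <- vapply(bs, obj, 0)
  b0 <- bs[which.min(vals)]
  op <- stats::optimize(obj, c(b0 - 2 * diff(range(bs)) / 4000,
                               b0 + 2 * diff(range(bs)) / 4000),
                        tol = 1e-10)
  b <- op$minimum
  a <- a_of_b(b)
  gv <- g(b)
  fitted <- a * gv
  rss <- sum((y - fitted)^2)
  # Jacobian of a*g(b) wrt (a, b)
  eg <- exp(pmin(700, k * (x + b)))
  dgdb <- -k * eg / (1 + eg)^2
  J <- cbind(a = gv, b = a * dgdb)
  se <- param_se(J, rss, n)
  est <- c(a = a, b = b)
  tt <- est / se
  pv <- 2 * stats::pt(-abs(tt), df = max(n - 2L, 1L))
  structure(list(a = a, b = b, k = k, se_a = unname(se["a"]),
                 se_b = unname(se["b"]), p_a = unname(pv["a"]),
                 p_b = unname(pv["b"]), rss = rss, n = n,
                 transform = attr(tf, "name"), fitted = fitted),
            class = "step_fit")
}

#' Predict from a step-function fit
#'
#' @param object A `step_fit`.
#' @param x Concentrations (original axis units).
#' @param ... Unused.
#' @export
predict.step_fit <- function(object, x, ...) {
  t <- axis_transform(object$transform)(x)
  object$a - object$a / (1 + exp(pmin(700, -object$k * (t + object$b))))
}

#' @export
print.step_fit <- function(x, ...) {
  cat(sprintf(
    "step fit y = a - a/(1 + exp(-%g (t(x) + b))), transform = %s\n",
    x$k, x$transform))
  cat(sprintf("  a = %.4f +/- %.4f (p = %.3g)\n", x$a, x$se_a, x$p_a))
  cat(sprintf("  b = %.4f +/- %.4g (p = %.3g)\n", x$b, x$se_b, x$p_b))
  cat(sprintf("  RSS = %.4g on %d points\n", x$rss, x$n))
  invisible(x)
}

#' Fit an exponential decline to the switching (sector) fractions
#'
#' Least-squares fit of `y = exp(-a * (t(x) - b))` to the per-concentration
#' sectored-colony fractions.  Starting values come from a log-linear
#' regression on the positive fractions; the fit is refined by
#' Levenberg--Marquardt least squares.  Standard errors and p-values are
#' computed as in [fit_step()].  A constant-`y` input is returned as the
#' flat limit `a = 0` (with `b` undefined).
#'
#' @param points Data frame with `concentration_mM` and `frac_sectored`
#'   (e.g. from [dose_response()]), or `x`/`y` columns.
#' @param transform Axis transform: `"identity"`, `"log10"` or `"negate"`.
#' @return An object of class `exp_fit`: list with `a`, `b`, `se_a`,
#'   `se_b`, `p_a`, `p_b`, `rss`, `n`, `transform`, `fitted`, `converged`.
#' @export
fit_switch_decline <- function(points, transform = "identity") {
  tf <- axis_transform(transform)
  xy <- extract_xy(points, yname = "frac_sectored")
  x <- tf(xy$x); y <- xy$y
  n <- length(x)
  if (n < 3L) stop("need at least 3 points to fit the decline")
  if (diff(range(x)) <= 0) stop("points must have positive x-spread")
  if (all(y <= 0)) stop("no decline to fit: all fractions are zero")
  if (stats::sd(y) < 1e-12) {
    # flat limit: a -> 0 with a*b -> log(y); b is not identified
    return(structure(list(a = 0, b = NA_real_, se_a = NA_real_,
                          se_b = NA_real_, p_a = NA_real_, p_b = NA_real_,
                          rss = 0, n = n, transform = attr(tf, "name"),
                          fitted = y, converged = TRUE),
                     class = "exp_fit"))
  }
  pos <- y > 0
  start <- if (sum(pos) >= 2L) {
    co <- unname(stats::coef(stats::lm(log(y[pos]) ~ x[pos])))
    a0 <- max(-co[2], 1e-3)
    list(a = a0, b = co[1] / a0)
  } else list(a = 1, b = unname(x[which.max(y)]))
  dat <- data.frame(x = x, y = y)
  fit <- tryCatch(
    minpack.lm::nlsLM(y ~ exp(-a * (x - b)), data = dat, start = start,
                      control = minpack.lm::nls.lm.control(maxiter = 500)),
    error = function(e) NULL)
  if (is.null(fit)) {
    # multi-start fallback over decay rates
    best <- NULL
    for (a0 in c(0.1, 0.5, 1, 2, 5)) {
      f <- tryCatch(
        minpack.lm::nlsLM(y ~ exp(-a * (x - b)), data = dat,
                          start = list(a = a0, b = stats::median(x)),
                          control = minpack.lm::nls.lm.control(maxiter = 500)),
        error = function(e) NULL)
      if (!is.null(f) &&
          (is.null(best) || stats::deviance(f) < stats::deviance(best))) {
        best <- f
      }
    }
    fit <- best
  }
  if (is.null(fit)) {
    stop("exponential fit failed to converge from all starting values; ",
         "x-range: ", paste(signif(range(x), 3), collapse = " to "),
         ", y-range: ", paste(signif(range(y), 3), collapse = " to "))
  }
  co <- summary(fit)$coefficients
  structure(list(a = unname(co["a", "Estimate"]),
                 b = unname(co["b", "Estimate"]),
                 se_a = unname(co["a", "Std. Error"]),
                 se_b = unname(co["b", "Std. Error"]),
                 p_a = unname(co["a", "Pr(>|t|)"]),
                 p_b = unname(co["b", "Pr(>|t|)"]),
                 rss = stats::deviance(fit), n = n,
                 transform = attr(tf, "name"),
                 fitted = stats::fitted(fit), converged = TRUE),
            class = "exp_fit")
}

#' @export
print.exp_fit <- function(x, ...) {
  cat(sprintf("exponential fit y = exp(-a (t(x) - b)), transform = %s\n",
              x$transform))
  cat(sprintf("  a = %.4f +/- %.4g (p = %.3g)\n", x$a, x$se_a, x$p_a))
  cat(sprintf("  b = %.4f +/- %.4g (p = %.3g)\n", x$b, x$se_b, x$p_b))
  invisible(x)
}

# Accept either a dose-response data frame or plain x/y columns.
extract_xy <- function(points, yname) {
  if (is.data.frame(points)) {
    xcol <- if ("concentration_mM" %in% names(points)) "concentration_mM"
            else "x"
    ycol <- if (yname %in% names(points)) yname else "y"
    if (!xcol %in% names(points) || !ycol %in% names(points)) {
      stop("points must contain columns (concentration_mM, ", yname,
           ") or (x, y)")
    }
    list(x = as.numeric(points[[xcol]]), y = as.numeric(points[[ycol]]))
  } else {
    stop("points must be a data frame")
  }
}

# Parameter standard errors from the Jacobian: RSS/(n-p) * (J'J)^-1.
# A singular J'J (e.g. a steep step with no point on the transition) gives
# Inf for the unidentified parameter rather than failing.
param_se <- function(J, rss, n) {
  p <- ncol(J)
  df <- max(n - p, 1L)
  JtJ <- crossprod(J)
  V <- tryCatch(solve(JtJ) * rss / df, error = function(e) NULL)
  if (is.null(V) || any(!is.finite(diag(V))) || any(diag(V) < 0)) {
    se <- rep(Inf, p)
    ok <- diag(JtJ) > 1e-12
    if (any(ok)) {
      Vok <- tryCatch(solve(JtJ[ok, ok, drop = FALSE]) * rss / df,
                      error = function(e) NULL)
      if (!is.null(Vok)) se[ok] <- sqrt(pmax(diag(Vok), 0))
    }
  } else {
    se <- sqrt(pmax(diag(V), 0))
  }
  names(se) <- colnames(J)
  se
}
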