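#' Growth-model families
#'
#' The five candidate families used to describe the change of a brain
#' measurement with gestational age \code{t} (days post-conception):
#' \describe{
#'   \item{linear}{\eqn{V(t) = m t + b}, parameters \code{(m, b)}.}
#'   \item{quadratic}{\eqn{V(t) = c0 + c1 t + c2 t^2}, parameters
#'     \code{(c0, c1, c2)}.}
#'   \item{logistic3}{\eqn{V(t) = A / (1 + \exp(-Rg (t - tmid)))}, parameters
#'     \code{(A, Rg, tmid)}: asymptote, maximal-rate parameter, inflection age.}
#'   \item{logistic4}{\eqn{V(t) = (A - B)/(1 + \exp(-Rg (t - tmid))) + B},
#'     parameters \code{(A, B, Rg, tmid)}; equals \code{B} at \eqn{t = 0}.}
#'   \item{gompertz}{\eqn{V(t) = a \exp(-b \exp(-c t))}, parameters
#'     \code{(a, b, c)}.}
#' }
#'
#' @return Character vector of the family names.
#' @export
growth_families <- function() {
  names(.growth_family_table)
}

.growth_family_table <- list(
  linear    = list(n_params = 2L, par_names = c("m", "b")),
  quadratic = list(n_params = 3L, par_names = c("c0", "c1", "c2")),
  logistic3 = list(n_params = 3L, par_names = c("A", "Rg", "tmid")),
  logistic4 = list(n_params = 4L, par_names = c("A", "B", "Rg", "tmid")),
  gompertz  = list(n_params = 3L, par_names = c("a", "b", "c"))
)

.family_info <- function(family) {
  info <- .growth_family_table[[family]]
  if (is.null(info)) {
    stop("unknown growth-model family: ", family, call. = FALSE)
  }
  info
}

#' Evaluate a growth model
#'
#' @param family One of \code{growth_families()}.
#' @param params Numeric parameter vector in the family's canonical order
#'   (see \code{\link{growth_families}}).
#' @param t Ages in days post-conception; vectorized.
#' @return \eqn{V(t)} in the units of the measurement.
#' @examples
#' eval_growth_model("logistic3", c(A = 48.5, Rg = 0.0566, tmid = 113), 113)
#' @export
eval_growth_model <- function(family, params, t) {
  info <- .family_info(family)
  params <- unname(as.numeric(params))
  if (length(params) != info$n_params) {
    stop(sprintf("family '%s' takes %d parameters, got %d",
                 family, info$n_params, length(params)), call. = FALSE)
  }
  if (!all(is.finite(params))) {
    stop("non-finite model parameters", call. = FALSE)
  }
  switch(family,
    linear    = params[1] * t + params[2],
    quadratic = params[1] + params[2] * t + params[3] * t^2,
    logistic3 = params[1] / (1 + exp(-params[2] * (t - params[3]))),
    logistic4 = (params[1] - params[2]) /
                  (1 + exp(-params[3] * (t - params[4]))) + params[2],
    gompertz  = params[1] * exp(-params[2] * exp(-params[3] * t))
  )
}

# Deterministic, data-driven starting values and box bounds per family.
# Free-parameter subset handled by the caller.
.growth_start_bounds <- function(family, ages, values) {
  vmax <- max(values)
  vmin <- min(values)
  vabs <- max(abs(values), 1e-8)
  tspan <- max(diff(range(ages)), 1e-8)
  A0 <- 1.1 * max(vmax, 1e-8)
  Rg0 <- min(max(4 * (vmax - vmin) / (tspan * A0), 1e-4), 1)
  above <- ages[values > vmax / 2]
  tmid0 <- if (length(above)) min(above) else stats::median(ages)
  tmid0 <- min(max(tmid0, 0), 400)
  switch(family,
    linear = list(
      start = c(m = (vmax - vmin) / tspan, b = vmin),
      lower = c(-Inf, -Inf), upper = c(Inf, Inf)),
    quadratic = list(
      start = c(c0 = vmin, c1 = 0, c2 = 0),
      lower = rep(-Inf, 3), upper = rep(Inf, 3)),
    logistic3 = list(
      start = c(A = A0, Rg = Rg0, tmid = tmid0),
      lower = c(1e-8, 1e-8, 0),
      upper = c(10 * max(vabs, vmax), 1, 400)),
    logistic4 = list(
      start = c(A = A0, B = vmin, Rg = Rg0, tmid = tmid0),
      lower = c(1e-8, -10 * vabs, 1e-8, 0),
      upper = c(10 * max(vabs, vmax), 10 * vabs, 1, 400)),
    gompertz = {
      # moment-match a logistic3 guess: equal asymptote and maximal rate
      c0 <- min(max(Rg0 * exp(1) / 4, 1e-8), 1)
      list(
        start = c(a = A0, b = exp(min(c0 * tmid0, 50)), c = c0),
        lower = c(1e-8, 1e-8, 1e-8),
        upper = c(10 * max(vabs, vmax), exp(50), 1))
    }
  )
}

.growth_fit_result <- function(family, params, ages, values, n_free,
                               converged) {
  n <- length(values)
  rss <- if (converged) sum((values - eval_growth_model(family, params, ages))^2) else NA_real_
  if (converged) {
    k <- n_free + 1L  # free curve parameters + residual variance
    rss_c <- max(rss, .Machine$double.xmin)  # keep BIC finite on exact fits
    loglik <- -n / 2 * (log(2 * pi) + log(rss_c / n) + 1)
    bic <- n * log(rss_c / n) + k * log(n)
  } else {
    loglik <- NA_real_
    bic <- Inf
  }
  structure(list(
    family = family,
    params = params,
    rss = rss,
    loglik = loglik,
    bic = bic,
    n_obs = n,
    n_free = n_free,
    converged = converged
  ), class = "growth_fit")
}

#' @export
print.growth_fit <- function(x, ...) {
  cat("Growth-curve fit:", x$family,
      if (!x$converged) "(not converged)" else "", "\n")
  if (x$converged) {
    print(round(x$params, 6))
    cat(sprintf("n = %d, RSS = %.6g, BIC = %.4f\n", x$n_obs, x$rss, x$bic))
  }
  invisible(x)
}

#' Fit a growth curve by bounded nonlinear least squares
#'
#' Linear and quadratic families are solved exactly by ordinary least squares;
#' sigmoid families use Levenberg-Marquardt with box bounds and deterministic
#' data-driven starting values. The Gompertz start is moment-matched from the
#' logistic3 configuration (equal asymptote and maximal rate). Any parameter
#' may be pinned through \code{fixed}, which is how the percent-of-adult fits
#' constrain the asymptote to 100.
#'
#' The log-likelihood assumes i.i.d. Gaussian residuals with variance
#' \code{rss/n}; BIC is \code{n log(rss/n) + k log(n)} with \code{k} counting
#' the free curve parameters plus the residual variance.
#'
#' @param family One of \code{growth_families()}.
#' @param ages,values Numeric vectors of equal length (days; measurement units).
#' @param fixed Optional named list pinning parameters, e.g. \code{list(A = 100)}.
#' @return A \code{growth_fit}: family, full named parameter vector, rss,
#'   loglik, bic, n_obs, converged. Optimizer failure yields
#'   \code{converged = FALSE}, never an error.
#' @export
fit_growth_curve <- function(family, ages, values, fixed = NULL) {
  info <- .family_info(family)
  ages <- as.numeric(ages); values <- as.numeric(values)
  if (length(ages) != length(values)) {
    stop("ages and values must have equal length", call. = FALSE)
  }
  if (anyNA(ages) || anyNA(values) || !all(is.finite(c(ages, values)))) {
    stop("ages and values must be finite", call. = FALSE)
  }
  fixed <- as.list(fixed)
  if (length(fixed) && !all(names(fixed) %in% info$par_names)) {
    stop("fixed names must be parameters of family '", family, "'",
         call. = FALSE)
  }
  free_names <- setdiff(info$par_names, names(fixed))
  n_free <- length(free_names)
  if (length(values) < n_free) {
    stop("need at least ", n_free, " observations for family '",
         family, "'", call. = FALSE)
  }

  full_params <- function(free) {
    p <- numeric(info$n_params)
    names(p) <- info$par_names
    p[free_names] <- free
    if (length(fixed)) p[names(fixed)] <- unlist(fixed)
    p
  }

  sigmoid <- family %in% c("logistic3", "logistic4", "gompertz")
  # unidentifiable degenerate inputs: flat series for a sigmoid, or fewer
  # distinct ages than free parameters
  if ((sigmoid && stats::sd(values) == 0) ||
      length(unique(ages)) < n_free) {
    return(.growth_fit_result(family, full_params(rep(NA_real_, n_free)),
                              ages, values, n_free, converged = FALSE))
  }

  if (!sigmoid && length(fixed) == 0L) {
    X <- switch(family,
      linear = cbind(ages, 1),
      quadratic = cbind(1, ages, ages^2))
    beta <- tryCatch(qr.coef(qr(X), values), error = function(e) NULL)
    if (is.null(beta) || anyNA(beta)) {
      return(.growth_fit_result(family, full_params(rep(NA_real_, n_free)),
                                ages, values, n_free, converged = FALSE))
    }
    p <- full_params(as.numeric(beta))
    return(.growth_fit_result(family, p, ages, values, n_free, TRUE))
  }

  sb <- .growth_start_bounds(family, ages, values)
  idx <- match(free_names, info$par_names)
  start <- pmin(pmax(sb$start[idx], sb$lower[idx]), sb$upper[idx])
  resid_fn <- function(free) values - eval_growth_model(family, full_params(free), ages)
  fit <- tryCatch(
    minpack.lm::nls.lm(par = start, lower = sb$lower[idx],
                       upper = sb$upper[idx], fn = resid_fn,
                       control = minpack.lm::nls.lm.control(
                         maxiter = 200, ftol = 1e-12, ptol = 1e-12)),
    error = function(e) NULL)
  ok <- !is.null(fit) && fit$info %in% 1:4 && all(is.finite(fit$par))
  if (!ok) {
    return(.growth_fit_result(family, full_params(rep(NA_real_, n_free)),
                              ages, values, n_free, converged = FALSE))
  }
  .growth_fit_result(family, full_params(fit$par), ages, values, n_free, TRUE)
}

#' Select the growth-model family with the lowest BIC
#'
#' Fits every family in \code{families} and ranks converged fits by BIC.
#' Non-converged families are excluded from the ranking and carry
#' \code{BIC = Inf} in the table. BIC ties below 1e-6 resolve to the family
#' with fewer parameters.
#'
#' @param ages,values Numeric vectors; at least 6 observations.
#' @param families Families to try (default: all five).
#' @return A \code{growth_selection}: \code{fits} (named list of
#'   \code{growth_fit}), \code{winner}, \code{bic_table}.
#' @export
select_growth_model <- function(ages, values, families = growth_families()) {
  if (length(values) < 6L) {
    stop("model selection needs at least 6 observations", call. = FALSE)
  }
  fits <- lapply(families, function(f) fit_growth_curve(f, ages, values))
  names(fits) <- families
  bic <- vapply(fits, function(f) if (f$converged) f$bic else Inf, numeric(1))
  if (!any(is.finite(bic))) {
    stop("no growth-model family converged", call. = FALSE)
  }
  best <- min(bic)
  cand <- names(bic)[bic - best < 1e-6]
  if (length(cand) > 1L) {  # parsimony tie-break
    np <- vapply(cand, function(f) .family_info(f)$n_params, integer(1))
    cand <- cand[order(np)]
  }
  structure(list(fits = fits, winner = cand[1L], bic_table = bic),
            class = "growth_selection")
}

#' @export
print.growth_selection <- function(x, ...) {
  cat("Growth-model selection (winner:", x$winner, ")\n")
  print(round(sort(x$bic_table), 3))
  invisible(x)
}

#' Derived growth descriptors
#'
#' Converts fitted sigmoid parameters into the inflection age, the maximal
#' growth rate, and the asymptote. For logistic3 these are \code{tmid},
#' \code{A*Rg/4}, \code{A}; for logistic4 \code{tmid}, \code{(A-B)*Rg/4},
#' \code{A}; for Gompertz \code{ln(b)/c}, \code{a*c/e}, \code{a}.
#'
#' @param fit A converged \code{growth_fit} from a sigmoid family.
#' @return List with \code{t_mid} (days), \code{r_max} (units/day),
#'   \code{asymptote} (measurement units).
#' @export
derived_descriptors <- function(fit) {
  stopifnot(inherits(fit, "growth_fit"))
  if (!fit$family %in% c("logistic3", "logistic4", "gompertz")) {
    stop("derived descriptors are defined for sigmoid families only",
         call. = FALSE)
  }
  if (!fit$converged) stop("fit did not converge", call. = FALSE)
  p <- fit$params
  switch(fit$family,
    logistic3 = list(t_mid = unname(p["tmid"]),
                     r_max = unname(p["A"] * p["Rg"] / 4),
                     asymptote = unname(p["A"])),
    logistic4 = list(t_mid = unname(p["tmid"]),
                     r_max = unname((p["A"] - p["B"]) * p["Rg"] / 4),
                     asymptote = unname(p["A"])),
    gompertz  = list(t_mid = unname(log(p["b"]) / p["c"]),
                     r_max = unname(p["a"] * p["c"] / exp(1)),
                     asymptote = unname(p["a"]))
  )
}

#' Invert Gompertz descriptors back to curve parameters
#'
#' Given the asymptote \code{a}, maximal rate \code{r_max}, and inflection
#' \code{t_mid} of a Gompertz curve, recovers \code{c = r_max * e / a} and
#' \code{b = exp(c * t_mid)}.
#'
#' @param asymptote,r_max,t_mid Descriptor triple.
#' @return Named vector \code{(a, b, c)}.
#' @export
gompertz_from_descriptors <- function(asymptote, r_max, t_mid) {
  c_par <- r_max * exp(1) / asymptote
  c(a = asymptote, b = exp(c_par * t_mid), c = c_par)
}

#' Fit fetal volumes expressed as percent of the adult value
#'
#' Three-parameter logistic fit with the asymptote pinned at 100 percent of
#' the adult volume, leaving \code{Rg} and \code{tmid} free. The implied
#' maximal growth rate in percent/day is \code{100 * Rg / 4 = 25 * Rg}.
#'
#' @param ages Days post-conception.
#' @param percent_values Values on the 0-100 scale (overshoot above 100 is
#'   tolerated; a warning is issued if the mean of the latest age group
#'   exceeds 110).
#' @return A \code{growth_fit} (logistic3, \code{A} fixed at 100) with an
#'   additional element \code{r_max_percent_per_day}.
#' @export
fit_percent_of_adult <- function(ages, percent_values) {
  last_age <- max(ages)
  last_mean <- mean(percent_values[ages >= last_age - 3.5])
  if (is.finite(last_mean) && last_mean > 110) {
    warning("mean percent-of-adult in the latest age group exceeds 110",
            call. = FALSE)
  }
  fit <- fit_growth_curve("logistic3", ages, percent_values,
                          fixed = list(A = 100))
  fit$r_max_percent_per_day <-
    if (fit$converged) unname(25 * fit$params["Rg"]) else NA_real_
  fit
}
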