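#' Five-parameter log-logistic effect function
#'
#' Evaluates
#' \deqn{E(u) = c + \frac{d - c}{\left(1 + e^{b(\ln e - \ln u)}\right)^{f}}}
#' the five-parameter log-logistic model of the effect (immobile) fraction at
#' dose u. `c` is the background effect at dose 0 (the lower asymptote), `d`
#' the maximal effect, `e` the inflection dose, `b` the slope and `f` the
#' asymmetry; with `f = 1` the curve is symmetric on the log-dose axis and `e`
#' is the EC50. A positive `b` gives an effect that is nondecreasing in dose.
#' Dose 0 is handled on the asymptote, never through a log transform.
#'
#' @param dose Non-negative dose(s).
#' @param b,c,d,e,f Model parameters; `0 <= c <= d <= 1`, `e > 0`, `f > 0`.
#' @return Effect fraction(s) in `[c, d]`.
#' @examples
#' ll5_effect(100, b = 2, c = 0, d = 1, e = 100, f = 1) # 0.5
#' @export
ll5_effect <- function(dose, b, c, d, e, f) {
  if (any(dose < 0, na.rm = TRUE))
    ms_abort("`dose` must be non-negative.", "multistress_domain_error")
  out <- numeric(length(dose))
  zero <- dose == 0
  out[zero] <- if (b > 0) c else d
  u <- dose[!zero]
  z <- exp(b * (log(e) - log(u)))          # Inf-safe: (1 + Inf)^-f -> 0
  out[!zero] <- c + (d - c) / (1 + z)^f
  out
}

# internal: pool immobility counts by dose (fits are invariant to row order
# and to splitting a dose across replicate rows)
pool_doses <- function(data, dose_col = "clothianidin_conc") {
  dc <- if (dose_col %in% names(data)) dose_col
        else if ("dose" %in% names(data)) "dose"
        else ms_abort(paste0("no dose column `", dose_col, "` (or `dose`) in data."),
                      "multistress_schema_error")
  out <- dplyr::summarise(
    dplyr::group_by(data, dose = .data[[dc]]),
    n_exposed = sum(.data$n_exposed),
    n_immobile = sum(.data$n_immobile),
    .groups = "drop"
  )
  dplyr::arrange(out, .data$dose)
}

#' Fit a five-parameter log-logistic dose-response curve
#'
#' Fits [ll5_effect()] to immobility counts by binomial maximum likelihood:
#' the immobile count at each dose is modelled as Binomial(n_exposed, E(dose)).
#' With only a dozen animals per treatment the Gaussian approximation behind
#' least-squares on proportions is poor, so likelihood on the counts is the
#' default; `method = "ls"` provides a least-squares cross-check path.
#'
#' Counts are pooled by dose before fitting, so the fit is invariant to row
#' order and to how a dose's animals are split across replicate rows. The
#' control (dose 0) informs the lower asymptote directly. Optimisation uses
#' deterministic starting values from a logit-linear regression on
#' interpolated proportions, with a fixed ladder of perturbed starts on
#' non-convergence; there is no randomness anywhere in the fit, so refitting
#' the same table is bit-identical.
#'
#' @param data Data frame with one row per treatment (or replicate) holding
#'   the dose column, `n_exposed` and `n_immobile`.
#' @param dose_col Name of the dose column; `"clothianidin_conc"` by default,
#'   with `"dose"` accepted as a fallback.
#' @param method `"ml"` (binomial maximum likelihood, default) or `"ls"`
#'   (least squares on pooled proportions).
#' @return An object of class `ll5_fit`: parameters `par` (b, c, d, e, f),
#'   transformed-scale and natural-scale covariance matrices, `loglik`,
#'   `n_obs`, the pooled `data`, and convergence/boundary diagnostics.
#'   [tidy()] and [glance()] methods are provided.
#' @examples
#' tab <- data.frame(dose = c(0, 1, 10, 100, 1000),
#'                   n_exposed = 50,
#'                   n_immobile = c(1, 4, 13, 37, 49))
#' fit <- fit_ll5(tab)
#' ec_x(fit, 50)
#' @export
fit_ll5 <- function(data, dose_col = "clothianidin_conc",
                    method = c("ml", "ls")) {
  method <- match.arg(method)
  pooled <- pool_doses(data, dose_col)
  if (any(pooled$n_exposed <= 0))
    ms_abort("every dose needs at least one exposed individual.",
             "multistress_validation_error")
  if (nrow(pooled) < 5)
    ms_abort("need >= 5 distinct doses (including a control) to fit 5 parameters.",
             "multistress_validation_error")
  if (!any(pooled$dose == 0))
    ms_abort("a control (dose 0) treatment is required.",
             "multistress_validation_error")

  prop <- pooled$n_immobile / pooled$n_exposed
  if (all(prop %in% c(0, 1))) {
    if (length(unique(prop)) == 1)
      ms_abort("response is identical at every dose; no dose-response signal to fit.",
               "multistress_fit_error")
    ms_abort(paste0("all-or-nothing response at every dose (a step between ",
                    "adjacent doses); the slope is unbounded and a reduced ",
                    "model should be used."),
             "multistress_fit_error")
  }

  nll <- make_ll5_nll(pooled)
  start <- ll5_start(pooled)
  lower <- c(lb = -3, lc = -12, ld = -12,
             le = log(min(pooled$dose[pooled$dose > 0])) - 7, lf = -3)
  upper <- c(lb = 4, lc = 12, ld = 12,
             le = log(max(pooled$dose)) + 7, lf = 3)

  obj <- if (method == "ml") nll else make_ll5_ssq(pooled)
  fit <- NULL
  for (theta0 in start_ladder(start)) {
    theta0 <- pmin(pmax(theta0, lower + 1e-6), upper - 1e-6)
    cand <- tryCatch(
      optim(theta0, obj, method = "L-BFGS-B", lower = lower, upper = upper,
            control = list(maxit = 600, factr = 1e4)),
      error = function(e) NULL)
    if (!is.null(cand) && is.finite(cand$value) &&
        (is.null(fit) || cand$value < fit$value - 1e-10)) {
      cand$converged <- cand$convergence == 0
      if (is.null(fit) || cand$value < fit$value) fit <- cand
    }
    if (!is.null(fit) && fit$converged) break
  }
  if (is.null(fit))
    ms_abort("five-parameter log-logistic fit failed to converge from every start.",
             "multistress_fit_error")

  theta <- fit$par
  par <- ll5_untransform(theta)
  at_bound <- (theta <= lower + 1e-4) | (theta >= upper - 1e-4)

  # curvature on the transformed scale; near-flat directions (e.g. asymptotes
  # pinned at the boundary) get a capped generalized inverse so that delta-
  # method intervals stay finite and conservative
  H <- tryCatch(optimHess(theta, nll), error = function(e) NULL)
  vcov_t <- safe_inverse(H)
  J <- ll5_jacobian(theta)
  vcov_nat <- J %*% vcov_t %*% t(J)
  dimnames(vcov_nat) <- list(names(par), names(par))

  structure(list(
    par = par,
    tpar = theta,
    vcov = vcov_nat,
    vcov_tpar = vcov_t,
    loglik = -nll(theta),
    n_obs = sum(pooled$n_exposed),
    data = pooled,
    method = method,
    converged = isTRUE(fit$converged),
    at_boundary = at_bound,
    optimizer = list(value = fit$value, counts = fit$counts,
                     convergence = fit$convergence, message = fit$message)
  ), class = "ll5_fit")
}

# transformed scale: theta = (lb, lc, ld, le, lf)
#   b = exp(lb); c = plogis(lc) * d_free ... see ll5_untransform
ll5_untransform <- function(theta) {
  b <- exp(theta[["lb"]])
  d_top <- stats::plogis(theta[["ld"]])          # d in (0, 1)
  c_low <- d_top * stats::plogis(theta[["lc"]])  # c in (0, d)
  c(b = b, c = c_low, d = d_top,
    e = exp(theta[["le"]]), f = exp(theta[["lf"]]))
}

ll5_jacobian <- function(theta, h = 1e-5) {
  J <- matrix(0, 5, 5)
  for (j in 1:5) {
    tp <- tm <- theta
    tp[j] <- tp[j] + h; tm[j] <- tm[j] - h
    J[, j] <- (ll5_untransform(tp) - ll5_untransform(tm)) / (2 * h)
  }
  J
}

make_ll5_nll <- function(pooled) {
  dose <- pooled$dose; k <- pooled$n_immobile; n <- pooled$n_exposed
  function(theta) {
    p <- ll5_untransform(theta)
    pr <- ll5_effect(dose, p[["b"]], p[["c"]], p[["d"]], p[["e"]], p[["f"]])
    pr <- pmin(pmax(pr, 1e-12), 1 - 1e-12)
    -sum(dbinom(k, n, pr, log = TRUE))
  }
}

make_ll5_ssq <- function(pooled) {
  dose <- pooled$dose
  y <- pooled$n_immobile / pooled$n_exposed
  function(theta) {
    p <- ll5_untransform(theta)
    sum((y - ll5_effect(dose, p[["b"]], p[["c"]], p[["d"]], p[["e"]], p[["f"]]))^2)
  }
}

# deterministic starting values: empirical asymptotes, then a logit-linear
# regression of rescaled proportions on log dose
ll5_start <- function(pooled) {
  n <- pooled$n_exposed
  prop <- (pooled$n_immobile + 0.5) / (n + 1)
  c0 <- min(prop); d0 <- max(prop)
  c0 <- min(max(c0 - 0.01, 5e-4), 0.5)
  d0 <- max(min(d0 + 0.01, 1 - 5e-4), c0 + 0.05)
  pos <- pooled$dose > 0
  y <- pmin(pmax((prop[pos] - c0) / (d0 - c0), 0.02), 0.98)
  ld <- log(pooled$dose[pos])
  sl <- tryCatch(coef(lm(stats::qlogis(y) ~ ld)), error = function(e) c(0, 1))
  b0 <- sl[[2]]
  if (!is.finite(b0) || b0 < 0.1) b0 <- 1
  b0 <- min(b0, 20)
  e0 <- exp(-sl[[1]] / b0)
  rng <- range(pooled$dose[pos])
  if (!is.finite(e0) || e0 < rng[1] / 10 || e0 > rng[2] * 10)
    e0 <- exp(mean(log(rng)))
  c(lb = log(b0),
    lc = stats::qlogis(min(max(c0 / d0, 1e-3), 1 - 1e-3)),
    ld = stats::qlogis(d0),
    le = log(e0),
    lf = 0)
}

# fixed, deterministic ladder of perturbed starts (no RNG in fitting)
start_ladder <- function(start) {
  offs <- list(
    c(0, 0, 0, 0, 0),
    c(0, 0, 0, 0, 0.7), c(0, 0, 0, 0, -0.7),
    c(0.7, 0, 0, 0, 0), c(-0.7, 0, 0, 0, 0),
    c(0, 0, 0, 1, 0), c(0, 0, 0, -1, 0),
    c(0.5, -1, 1, 0.5, 0.5), c(-0.5, 1, -1, -0.5, -0.5)
  )
  lapply(offs, function(o) setNames(start + o, names(start)))
}

safe_inverse <- function(H, rel_eps = 1e-8) {
  if (is.null(H) || any(!is.finite(H))) return(matrix(NA_real_, 5, 5))
  eg <- eigen((H + t(H)) / 2, symmetric = TRUE)
  lam <- pmax(eg$values, max(abs(eg$values)) * rel_eps)
  eg$vectors %*% diag(1 / lam) %*% t(eg$vectors)
}

#' @export
print.ll5_fit <- function(x, ...) {
  cat("<ll5_fit> five-parameter log-logistic (binomial ",
      if (x$method == "ml") "ML" else "least squares", ")\n", sep = "")
  print(round(x$par, 5))
  cat(sprintf("logLik %.3f on %d animals across %d doses%s\n",
              x$loglik, x$n_obs, nrow(x$data),
              if (x$converged) "" else "  [did not converge]"))
  invisible(x)
}

#' @method tidy ll5_fit
#' @export
tidy.ll5_fit <- function(x, ...) {
  tibble::tibble(term = names(x$par),
                 estimate = unname(x$par),
                 std.error = sqrt(pmax(diag(x$vcov), 0)))
}

#' @method glance ll5_fit
#' @export
glance.ll5_fit <- function(x, ...) {
  tibble::tibble(logLik = x$loglik, df = 5L, nobs = x$n_obs,
                 n_doses = nrow(x$data), converged = x$converged,
                 method = x$method)
}

#' Evaluate the fitted effect at given doses
#'
#' Forward evaluation of a fitted curve; used by the null models and SAM.
#' Values lie in `[c, d]`, `effect_at(fit, 0)` equals the lower asymptote,
#' and the curve is nondecreasing in dose for positive slope.
#'
#' @param fit An `ll5_fit`.
#' @param dose Non-negative dose(s).
#' @return Effect fraction(s).
#' @export
effect_at <- function(fit, dose) {
  if (!inherits(fit, "ll5_fit"))
    ms_abort("`fit` must be an ll5_fit.", "multistress_domain_error")
  p <- fit$par
  ll5_effect(dose, p[["b"]], p[["c"]], p[["d"]], p[["e"]], p[["f"]])
}

#' ECx of a fitted dose-response curve
#'
#' Computes the dose producing x% effect with a confidence interval on the
#' log-dose scale. By default the "relative" ECx is returned: the dose at
#' which the effect, rescaled between the fitted asymptotes c and d, reaches
#' x%. `type = "absolute"` instead targets an absolute effect fraction of
#' x/100, which must lie inside (c, d).
#'
#' For the five-parameter log-logistic the relative ECx has the closed form
#' `ln ECx = ln e - ln((x/100)^(-1/f) - 1) / b`.
#'
#' Two interval methods are available. `"profile"` (default) inverts the
#' likelihood-ratio test along the profiled log-ECx axis; with binomial
#' counts of only a dozen animals per treatment the likelihood is markedly
#' asymmetric in log dose and the profile interval keeps close to nominal
#' coverage. `"delta"` is the classical delta-method (Wald) interval on the
#' log-dose scale from the curvature at the optimum; it is cheaper and
#' matches conventional dose-response software, but under-covers at very
#' small per-dose counts. The delta-method standard error is reported either
#' way.
#'
#' @param fit An `ll5_fit`.
#' @param x Effect level in percent, strictly between 0 and 100.
#' @param type `"relative"` (default) or `"absolute"`.
#' @param level Confidence level for the interval (default 0.95).
#' @param ci_method `"profile"` (default) or `"delta"`.
#' @return A one-row tibble: `level_x`, `dose`, `ci_low`, `ci_high`,
#'   `se_log_dose`, `type`, `ci_method`.
#' @export
ec_x <- function(fit, x, type = c("relative", "absolute"), level = 0.95,
                 ci_method = c("profile", "delta")) {
  type <- match.arg(type)
  ci_method <- match.arg(ci_method)
  if (!inherits(fit, "ll5_fit"))
    ms_abort("`fit` must be an ll5_fit.", "multistress_domain_error")
  if (!is.numeric(x) || length(x) != 1 || x <= 0 || x >= 100)
    ms_abort("`x` must lie strictly between 0 and 100.", "multistress_domain_error")

  log_dose_of <- function(theta) ll5_log_ecx(ll5_untransform(theta), x, type)
  ld <- log_dose_of(fit$tpar)
  if (!is.finite(ld))
    ms_abort(paste0("effect level ", x, "% is outside the achievable range of the fit."),
             "multistress_domain_error")

  g <- vapply(1:5, function(j) {
    h <- 1e-5
    tp <- tm <- fit$tpar
    tp[j] <- tp[j] + h; tm[j] <- tm[j] - h
    (log_dose_of(tp) - log_dose_of(tm)) / (2 * h)
  }, numeric(1))
  v <- drop(t(g) %*% fit$vcov_tpar %*% g)
  se <- if (is.finite(v) && v >= 0) sqrt(v) else NA_real_
  if (ci_method == "delta" || fit$method != "ml") {
    z <- qnorm(1 - (1 - level) / 2)
    lo <- exp(ld - z * se); hi <- exp(ld + z * se)
  } else {
    ci <- profile_ci_log_ecx(fit, x, type, level, ld, se)
    lo <- exp(ci[1]); hi <- exp(ci[2])
  }
  tibble::tibble(level_x = x,
                 dose = exp(ld),
                 ci_low = lo,
                 ci_high = hi,
                 se_log_dose = se,
                 type = type,
                 ci_method = if (fit$method == "ml") ci_method else "delta")
}

# profile the binomial likelihood along log ECx: for a fixed log-ECx value m
# the inflection log(e) is determined by the other four parameters, so the
# profile is a 4-parameter reoptimisation; interval bounds invert the
# likelihood-ratio test at the requested level
profile_ci_log_ecx <- function(fit, x, type, level, ld_hat, se) {
  thr <- stats::qchisq(level, 1) / 2
  nll4 <- make_ll5_nll(fit$data)
  theta_hat <- fit$tpar
  free <- c("lb", "lc", "ld", "lf")
  lower <- c(lb = -3, lc = -12, ld = -12, lf = -3)
  upper <- c(lb = 4, lc = 12, ld = 12, lf = 3)

  le_for <- function(th4, m) {
    par <- ll5_untransform(setNames(c(unname(th4[1:3]), 0, unname(th4[4])),
                                    c("lb", "lc", "ld", "le", "lf")))
    p <- if (type == "relative") x / 100
         else (x / 100 - par[["c"]]) / (par[["d"]] - par[["c"]])
    if (!is.finite(p) || p <= 0 || p >= 1) return(NA_real_)
    m + log(p^(-1 / par[["f"]]) - 1) / par[["b"]]
  }
  prof <- function(m, start4) {
    obj <- function(th4) {
      th4 <- setNames(unname(th4), free)
      le <- le_for(th4, m)
      if (!is.finite(le)) return(1e10)
      nll4(setNames(c(th4[1:3], le, th4[4]),
                    c("lb", "lc", "ld", "le", "lf")))
    }
    o <- tryCatch(optim(start4, obj, method = "L-BFGS-B",
                        lower = lower, upper = upper,
                        control = list(maxit = 300, factr = 1e6)),
                  error = function(e) NULL)
    if (is.null(o)) list(value = NA_real_, par = start4) else o
  }

  nll_min <- -fit$loglik
  step <- if (is.finite(se) && se > 0) max(0.25 * se, 0.02) else 0.2
  bound <- function(dir) {
    start4 <- theta_hat[free]
    m_prev <- ld_hat; d_prev <- 0
    for (i in 1:80) {
      m <- ld_hat + dir * step * i * (1 + 0.05 * i)
      o <- prof(m, start4)
      d <- o$value - nll_min
      if (!is.finite(d)) return(m_prev)
      start4 <- o$par
      if (d >= thr) {
        r <- tryCatch(uniroot(function(mm) prof(mm, start4)$value - nll_min - thr,
                              sort(c(m_prev, m)), tol = 1e-4)$root,
                      error = function(e) m)
        return(r)
      }
      m_prev <- m; d_prev <- d
    }
    dir * Inf + ld_hat * 0  # likelihood never excludes this side
  }
  c(bound(-1), bound(1))
}

# fast point estimate of the ECx dose (no interval); used by pipeline code
ec_x_dose <- function(fit, x, type = "relative") {
  ld <- ll5_log_ecx(fit$par, x, type)
  if (!is.finite(ld))
    ms_abort(paste0("effect level ", x, "% is outside the achievable range of the fit."),
             "multistress_domain_error")
  exp(ld)
}

ll5_log_ecx <- function(par, x, type) {
  b <- par[["b"]]; cc <- par[["c"]]; d <- par[["d"]]
  e <- par[["e"]]; f <- par[["f"]]
  p <- if (type == "relative") x / 100 else (x / 100 - cc) / (d - cc)
  if (!is.finite(p) || p <= 0 || p >= 1) return(NaN)
  log(e) - log(p^(-1 / f) - 1) / b
}
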