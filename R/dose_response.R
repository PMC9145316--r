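#' Convert a standard deviation to a standard error of the mean
#'
#' @param sd Standard deviation(s), >= 0.
#' @param n Group size(s), >= 1.
#' @return `sd / sqrt(n)`.
#' @export
sd_to_sem <- function(sd, n) {
  if (any(n < 1)) stop("group size n must be >= 1", call. = FALSE)
  if (any(sd < 0)) stop("sd must be non-negative", call. = FALSE)
  sd / sqrt(n)
}

#' @rdname sd_to_sem
#' @export
sem_to_sd <- function(sd, n) {
  if (any(n < 1)) stop("group size n must be >= 1", call. = FALSE)
  sd * sqrt(n)
}

#' Construct a continuous dose-response summary dataset
#'
#' Dose-group summary statistics for one compound and one continuous
#' endpoint, as reported in toxicity studies: dose, arithmetic group mean,
#' dispersion (SD or SEM) and group size. Responses are treated as
#' lognormal, so group means must be positive and a control group (dose 0)
#' must be present.
#'
#' @param compound Compound id.
#' @param endpoint Endpoint label (e.g. "white blood cell count").
#' @param dose Doses in ug/kg bw/d (>= 0, including 0).
#' @param mean Arithmetic group means (> 0).
#' @param dispersion SD or SEM per group.
#' @param dispersion_type `"SD"` or `"SEM"` (scalar or per group).
#' @param n Animals per group (integer >= 1).
#' @param direction `"decrease"` or `"increase"` (adverse direction).
#' @return A `dr_data` object (tibble plus metadata).
#' @export
dose_response_dataset <- function(compound, endpoint, dose, mean, dispersion,
                                  dispersion_type = "SD", n,
                                  direction = c("decrease", "increase")) {
  direction <- match.arg(direction)
  dispersion_type <- rep_len(dispersion_type, length(dose))
  stopifnot(length(mean) == length(dose), length(dispersion) == length(dose),
            length(n) == length(dose))
  if (!any(dose == 0)) stop("a control group (dose 0) is required", call. = FALSE)
  if (any(mean <= 0)) stop("group means must be positive (lognormal response)",
                           call. = FALSE)
  if (any(n < 1) || any(n != round(n))) {
    stop("group sizes must be integers >= 1", call. = FALSE)
  }
  if (!all(dispersion_type %in% c("SD", "SEM"))) {
    stop("dispersion_type must be 'SD' or 'SEM'", call. = FALSE)
  }
  tab <- tibble::tibble(
    dose = as.numeric(dose), mean = as.numeric(mean),
    dispersion = as.numeric(dispersion), dispersion_type = dispersion_type,
    n = as.integer(n)
  )
  structure(
    list(compound = compound, endpoint = endpoint, direction = direction,
         data = tab),
    class = "dr_data"
  )
}

#' @export
print.dr_data <- function(x, ...) {
  cat(sprintf("Dose-response data: %s, %s (%s), %d dose groups\n",
              x$compound, x$endpoint, x$direction, nrow(x$data)))
  print(x$data)
  invisible(x)
}

# Log-scale group summaries from arithmetic mean/SD assuming lognormal
# within-group responses: mu = log m - lv/2, lv = log(1 + (s/m)^2). The
# converted log variance is treated as the (n-1)-denominator sample
# variance of the log responses.
.prep_groups <- function(dr) {
  d <- dr$data
  sd <- ifelse(d$dispersion_type == "SEM", d$dispersion * sqrt(d$n),
               d$dispersion)
  cv2 <- (sd / d$mean)^2
  lv <- log(1 + cv2)
  tibble::tibble(
    dose = d$dose,
    ybar = log(d$mean) - lv / 2,
    s2 = lv,
    n = d$n
  )
}

.dr_families <- c("exp3", "exp4", "hill3", "hill4")

# Scaled response fraction g(u) in [0, 1): mean(x) = a * (1 + (c-1) g(b x))
.g_fun <- function(u, d, family) {
  if (startsWith(family, "exp")) 1 - exp(-u^d) else u^d / (1 + u^d)
}

.g_inv <- function(g, d, family) {
  if (startsWith(family, "exp")) (-log(1 - g))^(1 / d) else (g / (1 - g))^(1 / d)
}

# theta on transformed scale: (log b, raw c, [log d])
.theta_to_par <- function(theta, family, direction) {
  b <- exp(theta[1])
  c <- if (direction == "decrease") stats::plogis(theta[2]) else 1 + exp(theta[2])
  d <- if (family %in% c("exp4", "hill4")) exp(theta[3]) else 1
  list(b = b, c = c, d = d)
}

# shape contribution h(x) = log(1 + (c-1) g(b x)); profile log a and sigma2
.profile_loglik <- function(theta, groups, family, direction) {
  par <- .theta_to_par(theta, family, direction)
  penalty <- 0
  ld <- log(par$d)
  if (ld > log(8)) penalty <- penalty + 1e3 * (ld - log(8))^2
  if (ld < log(0.25)) penalty <- penalty + 1e3 * (ld - log(0.25))^2
  h <- log(1 + (par$c - 1) * .g_fun(par$b * groups$dose, par$d, family))
  if (any(!is.finite(h))) return(-1e10)
  N <- sum(groups$n)
  la <- sum(groups$n * (groups$ybar - h)) / N
  resid2 <- sum((groups$n - 1) * groups$s2 +
                  groups$n * (groups$ybar - la - h)^2)
  sigma2 <- resid2 / N
  if (sigma2 <= 0) sigma2 <- 1e-12
  ll <- -N / 2 * (log(2 * pi * sigma2) + 1)
  ll - penalty
}

.loglik_fixed_mu <- function(mu, groups) {
  N <- sum(groups$n)
  resid2 <- sum((groups$n - 1) * groups$s2 + groups$n * (groups$ybar - mu)^2)
  sigma2 <- resid2 / N
  if (sigma2 <= 0) sigma2 <- 1e-12
  -N / 2 * (log(2 * pi * sigma2) + 1)
}

.start_grid <- function(groups, family, direction) {
  max_dose <- max(groups$dose)
  b0 <- (1 / max_dose) * 10^seq(-1.5, 1.5, length.out = 5)
  y0 <- groups$ybar[groups$dose == 0][1]
  span <- if (direction == "decrease") {
    min(exp(min(groups$ybar) - y0), 0.95)
  } else {
    max(exp(max(groups$ybar) - y0), 1.05)
  }
  tc0 <- if (direction == "decrease") {
    stats::qlogis(pmin(pmax(c(span * 0.8, span * 0.3), 0.01), 0.98))
  } else {
    log(pmax(c((span - 1) * 1.2, (span - 1) * 3), 1e-3))
  }
  starts <- expand.grid(tb = log(b0), tc = tc0)
  if (family %in% c("exp4", "hill4")) starts$td <- 0
  starts
}

#' Fit one dose-response model family by maximum likelihood
#'
#' Fits a mean function with lognormal residuals to dose-group summary
#' statistics. Arithmetic means and SDs (or SEMs) are converted to
#' log-scale moments; the likelihood is the normal likelihood of the log
#' responses reconstructed from those summaries (up to a data-dependent
#' constant shared by all families), with the background level and the
#' residual variance profiled out. Families: `"exp3"`/`"exp4"`
#' (exponential, `a * (1 + (c-1)(1 - exp(-(b x)^d)))`), `"hill3"`/`"hill4"`
#' (Hill, `a * (1 + (c-1)(bx)^d / (1 + (bx)^d))`), `"null"` (constant) and
#' `"full"` (one mean per dose group). The 3-parameter variants fix the
#' shape exponent d at 1. Optimisation is derivative-free (Nelder-Mead)
#' from a grid of at least 10 starts spanning log-spaced potency values.
#'
#' @param dr A `dr_data` object.
#' @param family Model family name.
#' @return A `dr_fit`: list with `family`, `direction`, `par` (a, b, c, d),
#'   `sigma2`, `logLik`, `k` (parameter count incl. background and
#'   variance), `aic`, `converged`, and the prepared `groups`.
#' @export
fit_model <- function(dr, family = c("exp3", "exp4", "hill3", "hill4",
                                     "null", "full")) {
  family <- match.arg(family)
  groups <- .prep_groups(dr)
  if (family != "null" && nrow(groups) < 3) {
    stop("at least 3 dose groups are required for family '", family, "'",
         call. = FALSE)
  }
  .fit_groups(groups, family, dr$direction)
}

.fit_groups <- function(groups, family, direction, starts = NULL) {
  N <- sum(groups$n)
  G <- nrow(groups)

  if (family == "null") {
    la <- sum(groups$n * groups$ybar) / N
    ll <- .loglik_fixed_mu(la, groups)
    return(.dr_fit(family, direction, list(a = exp(la), b = NA, c = NA, d = NA),
                   groups, ll, k = 2, converged = TRUE))
  }
  if (family == "full") {
    resid2 <- sum((groups$n - 1) * groups$s2)
    sigma2 <- max(resid2 / N, 1e-12)
    ll <- -N / 2 * (log(2 * pi * sigma2) + 1)
    return(.dr_fit(family, direction,
                   list(a = exp(groups$ybar[groups$dose == 0][1]),
                        b = NA, c = NA, d = NA),
                   groups, ll, k = G + 1, converged = TRUE))
  }

  if (is.null(starts)) starts <- .start_grid(groups, family, direction)
  best <- NULL
  for (i in seq_len(nrow(starts))) {
    theta0 <- as.numeric(starts[i, ])
    opt <- stats::optim(
      theta0, function(th) -.profile_loglik(th, groups, family, direction),
      method = "Nelder-Mead",
      control = list(reltol = 1e-12, maxit = 3000)
    )
    if (is.null(best) || opt$value < best$value) best <- opt
  }
  theta <- best$par
  par <- .theta_to_par(theta, family, direction)
  h <- log(1 + (par$c - 1) * .g_fun(par$b * groups$dose, par$d, family))
  la <- sum(groups$n * (groups$ybar - h)) / N
  resid2 <- sum((groups$n - 1) * groups$s2 +
                  groups$n * (groups$ybar - la - h)^2)
  sigma2 <- max(resid2 / N, 1e-12)
  ll <- .profile_loglik(theta, groups, family, direction)
  k <- length(theta) + 2  # shape params + background + variance
  .dr_fit(family, direction,
          list(a = exp(la), b = par$b, c = par$c, d = par$d),
          groups, ll, k = k, converged = best$convergence == 0,
          sigma2 = sigma2, theta = theta)
}

.dr_fit <- function(family, direction, par, groups, logLik, k, converged,
                    sigma2 = NULL, theta = NULL) {
  if (is.null(sigma2)) {
    N <- sum(groups$n)
    mu <- if (family == "full") groups$ybar else log(par$a)
    resid2 <- sum((groups$n - 1) * groups$s2 + groups$n * (groups$ybar - mu)^2)
    sigma2 <- max(resid2 / N, 1e-12)
  }
  structure(
    list(family = family, direction = direction, par = par, sigma2 = sigma2,
         logLik = logLik, k = k, aic = 2 * k - 2 * logLik,
         converged = converged, groups = groups, theta = theta),
    class = "dr_fit"
  )
}

#' @export
print.dr_fit <- function(x, ...) {
  cat(sprintf("%s fit (%s): a=%.4g b=%.4g c=%.4g d=%.4g, lnL=%.3f, AIC=%.2f\n",
              x$family, x$direction, x$par$a, x$par$b, x$par$c, x$par$d,
              x$logLik, x$aic))
  invisible(x)
}

#' Fitted log-scale mean curve of a dose-response fit
#' @param fit A `dr_fit`.
#' @param dose Doses at which to evaluate.
#' @return Log-scale means.
#' @export
predict_logmean <- function(fit, dose) {
  if (fit$family %in% c("null", "full")) {
    if (fit$family == "null") return(rep(log(fit$par$a), length(dose)))
    idx <- match(dose, fit$groups$dose)
    return(fit$groups$ybar[idx])
  }
  log(fit$par$a) +
    log(1 + (fit$par$c - 1) * .g_fun(fit$par$b * dose, fit$par$d, fit$family))
}

#' Benchmark dose from a fitted model
#'
#' The benchmark dose (BMD) at benchmark response `bmr` is the dose at
#' which the fitted median response changes by a fraction `bmr` relative
#' to background: `mean(BMD) = mean(0) * (1 - bmr)` for a decrease,
#' `* (1 + bmr)` for an increase. For the exponential and Hill families
#' this inverts in closed form. When the fitted plateau never reaches the
#' benchmark response the BMD is unbounded: `Inf` is returned with
#' attribute `unbounded = TRUE` (also set when the BMD exceeds 10x the
#' largest tested dose).
#'
#' @param fit A `dr_fit` from [fit_model()].
#' @param bmr Benchmark response in (0, 1), e.g. 0.10.
#' @return The BMD in ug/kg bw/d (possibly `Inf`).
#' @export
bmd_from_model <- function(fit, bmr = 0.10) {
  stopifnot(bmr > 0, bmr < 1)
  if (fit$family %in% c("null", "full")) {
    out <- Inf
    attr(out, "unbounded") <- TRUE
    return(out)
  }
  target <- if (fit$direction == "decrease") {
    bmr / (1 - fit$par$c)
  } else {
    bmr / (fit$par$c - 1)
  }
  max_dose <- max(fit$groups$dose)
  if (!is.finite(target) || target <= 0 || target >= 1) {
    out <- Inf
    attr(out, "unbounded") <- TRUE
    return(out)
  }
  bmd <- .g_inv(target, fit$par$d, fit$family) / fit$par$b
  if (bmd > 10 * max_dose) attr(bmd, "unbounded") <- TRUE
  bmd
}

#' AIC weights across converged fits
#' @param fits List of `dr_fit` objects.
#' @return Named numeric weights summing to 1.
#' @export
aic_weights <- function(fits) {
  aics <- vapply(fits, function(f) f$aic, numeric(1))
  w <- exp(-(aics - min(aics)) / 2)
  stats::setNames(w / sum(w), vapply(fits, function(f) f$family, character(1)))
}

#' Model-averaged benchmark dose with bootstrap confidence interval
#'
#' Fits all requested families, weights them by AIC, and generates a
#' parametric bootstrap from the weighted-average fitted curve: per
#' replicate, group log-means are drawn from the averaged curve with the
#' averaged residual variance, group log-variances from the scaled
#' chi-squared sampling distribution, a family is sampled by its AIC
#' weight, re-fitted to the replicate data (warm-started at its original
#' estimate), and the replicate BMD recorded. The reported BMD is the
#' bootstrap median; BMDL and BMDU are the 5th and 95th bootstrap
#' percentiles (a two-sided 90% interval), so BMDL <= BMD <= BMDU by
#' construction.
#'
#' @param dr A `dr_data` object.
#' @param bmr Benchmark response (default 0.10).
#' @param families Families to average over.
#' @param B Bootstrap replicates (>= 200 for reportable intervals).
#' @param seed Integer seed.
#' @return A `bmd_result`: list with `bmr`, `bmd`, `bmdl`, `bmdu`,
#'   `method = "model_average"`, `weights`, `fits`, `B`, `seed`,
#'   `n_unbounded` (bootstrap replicates with unbounded BMD).
#' @export
model_average_bmd <- function(dr, bmr = 0.10,
                              families = c("exp3", "exp4", "hill3", "hill4"),
                              B = 1000, seed) {
  if (missing(seed)) stop("a seed is required", call. = FALSE)
  stopifnot(B >= 1)
  fits <- lapply(families, function(f) fit_model(dr, f))
  names(fits) <- families
  ok <- vapply(fits, function(f) isTRUE(f$converged), logical(1))
  if (!any(ok)) stop("no dose-response family converged", call. = FALSE)
  fits <- fits[ok]
  w <- aic_weights(fits)

  groups <- .prep_groups(dr)
  mu_avg <- as.numeric(
    Reduce(`+`, Map(function(f, wi) wi * predict_logmean(f, groups$dose),
                    fits, w))
  )
  sigma2_avg <- sum(w * vapply(fits, function(f) f$sigma2, numeric(1)))

  boots <- withr::with_seed(as.integer(seed), {
    fam_draw <- sample(names(w), B, replace = TRUE, prob = w)
    vapply(seq_len(B), function(r) {
      g <- groups
      g$ybar <- stats::rnorm(nrow(g), mu_avg, sqrt(sigma2_avg / g$n))
      g$s2 <- sigma2_avg * stats::rchisq(nrow(g), g$n - 1) / (g$n - 1)
      fam <- fam_draw[r]
      warm <- fits[[fam]]$theta
      starts <- rbind(warm, .start_grid(g, fam, dr$direction)[c(3, 8), ,
                                                             drop = FALSE])
      fit_r <- .fit_groups(g, fam, dr$direction, starts = as.data.frame(starts))
      as.numeric(bmd_from_model(fit_r, bmr))
    }, numeric(1))
  })

  qs <- stats::quantile(boots, c(0.05, 0.5, 0.95), names = FALSE, type = 7)
  structure(
    list(bmr = bmr, bmd = qs[2], bmdl = qs[1], bmdu = qs[3],
         method = "model_average", weights = w, fits = fits, B = B,
         seed = as.integer(seed), n_unbounded = sum(!is.finite(boots)),
         boots = boots),
    class = "bmd_result"
  )
}

#' @export
print.bmd_result <- function(x, ...) {
  cat(sprintf("BMD (BMR %.0f%%): %.4g [BMDL %.4g, BMDU %.4g] ug/kg bw/d (%s)\n",
              100 * x$bmr, x$bmd, x$bmdl, x$bmdu, x$method))
  invisible(x)
}

# Joint profile log-likelihood for the simultaneous fit: shared shape
# (b, c, [d]) and residual variance, per-compound background (profiled)
# and dose-scale rho (rho_ref = 1). theta = (tb, tc, [td], log rho_others).
.sim_loglik <- function(theta, group_list, family, direction, ref_idx) {
  n_shape <- if (family %in% c("exp4", "hill4")) 3 else 2
  par <- .theta_to_par(theta[seq_len(n_shape)], family, direction)
  penalty <- 0
  ld <- log(par$d)
  if (ld > log(8)) penalty <- penalty + 1e3 * (ld - log(8))^2
  if (ld < log(0.25)) penalty <- penalty + 1e3 * (ld - log(0.25))^2
  n_comp <- length(group_list)
  rho <- rep(1, n_comp)
  rho[-ref_idx] <- exp(theta[-seq_len(n_shape)])
  resid2 <- 0
  N <- 0
  for (i in seq_len(n_comp)) {
    g <- group_list[[i]]
    h <- log(1 + (par$c - 1) * .g_fun(par$b * rho[i] * g$dose, par$d, family))
    if (any(!is.finite(h))) return(-1e10)
    Ni <- sum(g$n)
    la <- sum(g$n * (g$ybar - h)) / Ni
    resid2 <- resid2 + sum((g$n - 1) * g$s2 + g$n * (g$ybar - la - h)^2)
    N <- N + Ni
  }
  sigma2 <- max(resid2 / N, 1e-12)
  -N / 2 * (log(2 * pi * sigma2) + 1) - penalty
}

.fit_sim_family <- function(group_list, family, direction, ref_idx,
                            starts = NULL) {
  n_comp <- length(group_list)
  n_shape <- if (family %in% c("exp4", "hill4")) 3 else 2
  if (is.null(starts)) {
    base <- .start_grid(group_list[[ref_idx]], family, direction)
    # initial dose-scale guesses from the ratio of dose ranges
    rho0 <- vapply(group_list, function(g) {
      max(group_list[[ref_idx]]$dose) / max(g$dose)
    }, numeric(1))[-ref_idx]
    starts <- cbind(base, matrix(rep(log(rho0), each = nrow(base)),
                                 nrow = nrow(base)))
  }
  best <- NULL
  for (i in seq_len(nrow(starts))) {
    theta0 <- as.numeric(starts[i, ])
    opt <- stats::optim(
      theta0,
      function(th) -.sim_loglik(th, group_list, family, direction, ref_idx),
      method = "Nelder-Mead",
      control = list(reltol = 1e-12, maxit = 5000)
    )
    if (is.null(best) || opt$value < best$value) best <- opt
  }
  theta <- best$par
  par <- .theta_to_par(theta[seq_len(n_shape)], family, direction)
  rho <- rep(1, n_comp)
  rho[-ref_idx] <- exp(theta[-seq_len(n_shape)])
  ll <- .sim_loglik(theta, group_list, family, direction, ref_idx)
  # shared shape + per-compound background + per-non-ref rho + variance
  k <- n_shape + n_comp + (n_comp - 1) + 1
  list(family = family, par = par, rho = rho, logLik = ll, k = k,
       aic = 2 * k - 2 * ll, converged = best$convergence == 0, theta = theta)
}

#' Simultaneous benchmark-dose analysis across compounds
#'
#' Joint maximum-likelihood fit of one mean-function family to several
#' dose-response datasets on the same endpoint, with compound-specific
#' background and potency (a dose-scale factor) but shared shape
#' parameters and residual variance — i.e. parallel curves on log-dose.
#' Under this constraint the relative potency factor RPF_i =
#' BMD_reference / BMD_i equals the dose-scale ratio and is identical for
#' every benchmark response. The best family by AIC is selected among the
#' candidates; per-compound benchmark doses at `bmr` are derived from the
#' joint fit, with optional parametric-bootstrap confidence intervals.
#' A parallelism diagnostic compares the joint fit with separate
#' per-compound fits of the same family: if the separate fits win by more
#' than 2 AIC units per extra parameter, a non-parallel warning is
#' recorded (the RPF is still reported, flagged).
#'
#' @param datasets List of `dr_data` objects with a common endpoint and
#'   direction, each including a control group.
#' @param reference Reference compound id (member of `datasets`).
#' @param bmr Benchmark response (default 0.10).
#' @param families Candidate families.
#' @param B Parametric-bootstrap replicates for per-compound BMD
#'   confidence intervals (0 to skip).
#' @param seed Seed, required when `B > 0`.
#' @return A `sim_fit`: list with `family`, `par`, `rpf` (an [rpf_set()]),
#'   `bmd` (tibble compound/bmd/bmdl/bmdu at `bmr`), `logLik`, `aic`,
#'   `parallel_ok`, `aic_margin`, `compounds`, `reference`.
#' @export
simultaneous_fit <- function(datasets, reference, bmr = 0.10,
                             families = c("exp3", "exp4", "hill3", "hill4"),
                             B = 0, seed = NULL) {
  stopifnot(length(datasets) >= 2)
  compounds <- vapply(datasets, function(d) d$compound, character(1))
  names(datasets) <- compounds
  if (!reference %in% compounds) {
    stop("reference compound '", reference, "' not among the datasets",
         call. = FALSE)
  }
  endpoints <- unique(vapply(datasets, function(d) d$endpoint, character(1)))
  directions <- unique(vapply(datasets, function(d) d$direction, character(1)))
  if (length(endpoints) > 1 || length(directions) > 1) {
    stop("datasets must share one endpoint and direction", call. = FALSE)
  }
  direction <- directions
  ref_idx <- match(reference, compounds)
  group_list <- lapply(datasets, .prep_groups)

  cand <- lapply(families, function(f) {
    .fit_sim_family(group_list, f, direction, ref_idx)
  })
  cand <- cand[vapply(cand, function(f) isTRUE(f$converged), logical(1))]
  if (!length(cand)) stop("no joint fit converged", call. = FALSE)
  best <- cand[[which.min(vapply(cand, function(f) f$aic, numeric(1)))]]

  # parallelism diagnostic: separate fits of the winning family
  sep <- lapply(group_list, function(g) .fit_groups(g, best$family, direction))
  aic_sep <- sum(vapply(sep, function(f) f$aic, numeric(1)))
  extra <- sum(vapply(sep, function(f) f$k, numeric(1))) - best$k
  margin <- best$aic - aic_sep
  parallel_ok <- margin <= 2 * extra
  if (!parallel_ok) {
    warning("parallelism questionable: joint fit worse than separate fits ",
            "by ", format(margin, digits = 3), " AIC units (threshold ",
            2 * extra, "); RPF reported with flag", call. = FALSE)
  }

  rho <- stats::setNames(best$rho, compounds)
  # BMD of the shared curve at the reference dose scale
  target <- if (direction == "decrease") {
    bmr / (1 - best$par$c)
  } else {
    bmr / (best$par$c - 1)
  }
  bmd_ref <- if (target > 0 && target < 1) {
    .g_inv(target, best$par$d, best$family) / best$par$b
  } else {
    Inf
  }
  bmd_tab <- tibble::tibble(
    compound = compounds,
    bmd = bmd_ref / rho,
    bmdl = NA_real_, bmdu = NA_real_
  )

  if (B > 0) {
    if (is.null(seed)) stop("a seed is required when B > 0", call. = FALSE)
    sigma2 <- .sim_sigma2(best, group_list, direction, ref_idx)
    boots <- withr::with_seed(as.integer(seed), {
      replicate(B, {
        gl <- group_list
        for (i in seq_along(gl)) {
          h <- log(1 + (best$par$c - 1) *
                     .g_fun(best$par$b * best$rho[i] * gl[[i]]$dose,
                            best$par$d, best$family))
          Ni <- sum(gl[[i]]$n)
          la <- sum(gl[[i]]$n * (group_list[[i]]$ybar - h)) / Ni
          gl[[i]]$ybar <- stats::rnorm(nrow(gl[[i]]), la + h,
                                       sqrt(sigma2 / gl[[i]]$n))
          gl[[i]]$s2 <- sigma2 * stats::rchisq(nrow(gl[[i]]),
                                               gl[[i]]$n - 1) /
            (gl[[i]]$n - 1)
        }
        refit <- .fit_sim_family(gl, best$family, direction, ref_idx,
                                 starts = rbind(data.frame(t(best$theta))))
        tr <- if (direction == "decrease") {
          bmr / (1 - refit$par$c)
        } else {
          bmr / (refit$par$c - 1)
        }
        br <- if (tr > 0 && tr < 1) {
          .g_inv(tr, refit$par$d, refit$family) / refit$par$b
        } else {
          Inf
        }
        br / refit$rho
      })
    })
    boots <- matrix(boots, nrow = length(compounds))
    bmd_tab$bmdl <- apply(boots, 1, stats::quantile, probs = 0.05,
                          names = FALSE, type = 7)
    bmd_tab$bmdu <- apply(boots, 1, stats::quantile, probs = 0.95,
                          names = FALSE, type = 7)
  }

  structure(
    list(
      family = best$family, par = best$par,
      rpf = rpf_set(reference, rho),
      bmd = bmd_tab, bmr = bmr, logLik = best$logLik, aic = best$aic,
      parallel_ok = parallel_ok, aic_margin = margin,
      compounds = compounds, reference = reference, theta = best$theta,
      group_list = group_list, direction = direction, ref_idx = ref_idx
    ),
    class = "sim_fit"
  )
}

.sim_sigma2 <- function(fit, group_list, direction, ref_idx) {
  resid2 <- 0
  N <- 0
  for (i in seq_along(group_list)) {
    g <- group_list[[i]]
    h <- log(1 + (fit$par$c - 1) *
               .g_fun(fit$par$b * fit$rho[i] * g$dose, fit$par$d, fit$family))
    Ni <- sum(g$n)
    la <- sum(g$n * (g$ybar - h)) / Ni
    resid2 <- resid2 + sum((g$n - 1) * g$s2 + g$n * (g$ybar - la - h)^2)
    N <- N + Ni
  }
  max(resid2 / N, 1e-12)
}

#' @export
print.sim_fit <- function(x, ...) {
  cat(sprintf("Simultaneous %s fit (%d compounds, reference %s)\n",
              x$family, length(x$compounds), x$reference))
  cat("RPFs:", paste(names(x$rpf$rpf), signif(x$rpf$rpf, 3),
                     sep = "=", collapse = ", "), "\n")
  if (!x$parallel_ok) cat("warning: parallelism questionable\n")
  print(x$bmd)
  invisible(x)
}

#' Recompute the RPF set of a simultaneous fit at another benchmark response
#'
#' Under the shared-shape (parallel-curve) constraint the RPF is the ratio
#' of dose-scale factors and does not depend on the benchmark response;
#' this helper recomputes it from per-compound BMDs at an arbitrary `bmr`
#' so that invariance can be asserted.
#'
#' @param fit A `sim_fit`.
#' @param bmr Benchmark response.
#' @return Named RPF vector (reference / compound BMD ratios).
#' @export
rpf_at_bmr <- function(fit, bmr) {
  target <- if (fit$direction == "decrease") {
    bmr / (1 - fit$par$c)
  } else {
    bmr / (fit$par$c - 1)
  }
  bmd_ref <- .g_inv(target, fit$par$d, fit$family) / fit$par$b
  bmds <- bmd_ref / fit$rpf$rpf[fit$compounds]
  stats::setNames(bmds[[match(fit$reference, fit$compounds)]] / bmds,
                  fit$compounds)
}

#' Select the reference compound with the most precise benchmark dose
#'
#' The compound whose BMD confidence interval is narrowest in ratio terms
#' (smallest BMDU/BMDL) carries the least uncertain reference point and is
#' preferred as the reference compound. Ties break lexicographically by
#' compound id.
#'
#' @param results Named list of `bmd_result` objects, or a data frame with
#'   columns `compound`, `bmdl`, `bmdu`.
#' @return The selected compound id.
#' @export
select_reference_compound <- function(results) {
  if (is.data.frame(results)) {
    tab <- tibble::tibble(compound = results$compound,
                          ratio = results$bmdu / results$bmdl)
  } else {
    stopifnot(length(results) >= 1)
    tab <- tibble::tibble(
      compound = names(results),
      ratio = vapply(results, function(r) r$bmdu / r$bmdl, numeric(1))
    )
  }
  tab <- tab[order(tab$ratio, tab$compound), ]
  tab$compound[1]
}
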