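#' Pool dwell times by assigned transition cluster
#'
#' Each transition record carries the dwell time of the state run that
#' preceded it; records are pooled by their maximum-responsibility
#' (from, to) cluster.  Truncated dwells never reach this stage (only
#' interior transitions become records).  Pairs with fewer than
#' \code{min_dwells} dwells are flagged "insufficient" and no fit is
#' attempted on them.
#'
#' @param records \code{transition_records}
#' @param model \code{tdp_cluster_model} used for assignment
#' @param min_dwells minimum dwells for a fittable distribution
#' @return named list ("i->j") of \code{dwell_dist} objects: sorted
#'   dwells, empirical CDF, from/to state, sufficiency flag
#' @export
collect_dwells <- function(records, model, min_dwells = 5) {
  a <- tdp_assign(model, records)
  out <- list()
  for (c in seq_along(model$from)) {
    d <- sort(records$dwell[a == c])
    key <- sprintf("%d->%d", model$from[c], model$to[c])
    out[[key]] <- structure(
      list(from = model$from[c], to = model$to[c], dwell = d,
           cdf = if (length(d)) seq_along(d) / length(d) else numeric(0),
           n = length(d), sufficient = length(d) >= min_dwells),
      class = "dwell_dist")
  }
  out
}

#' Exponential fit to an unbinned cumulative dwell-time distribution
#'
#' Nonlinear least squares of F(t) = 1 - A1 exp(-k1 t) - A2 exp(-k2 t)
#' (A2 = 0 for the mono-exponential) to the empirical CDF evaluated at the
#' sorted dwells with the midpoint plotting position (i - 1/2)/n, so no
#' binning choice enters.  Rates are initialized from
#' the empirical mean with a small grid of fallback starts on failure.
#' For reporting, components are ordered fast-first (k1 >= k2) and
#' A1 + A2 = 1 holds by construction.
#'
#' @param dist a \code{dwell_dist} or a numeric vector of dwell times
#' @param n_components 1 or 2
#' @return an \code{exp_fit}: A1, k1, A2, k2, rss, bic, n
#' @export
fit_dwell_cdf <- function(dist, n_components = 2) {
  t <- if (inherits(dist, "dwell_dist")) dist$dwell else sort(dist)
  n <- length(t)
  if (n < 5) stop("need >= 5 dwells")
  Fe <- (seq_len(n) - 0.5) / n
  km <- 1 / mean(t)
  dat <- data.frame(t = t, Fe = Fe)
  if (n_components == 1) {
    fit <- try_starts(dat, Fe ~ 1 - exp(-k1 * t),
                      list(list(k1 = km), list(k1 = 2 * km), list(k1 = km / 2)),
                      lower = c(k1 = 1e-9))
    co <- stats::coef(fit)
    out <- list(n_components = 1L, A1 = 1, k1 = unname(co["k1"]),
                A2 = 0, k2 = NA_real_)
    p <- 1
  } else if (n_components == 2) {
    starts <- list(list(A1 = 0.5, k1 = 2 * km, k2 = km / 2),
                   list(A1 = 0.3, k1 = 5 * km, k2 = km),
                   list(A1 = 0.7, k1 = 3 * km, k2 = km / 3),
                   list(A1 = 0.5, k1 = km, k2 = km))
    fit <- try_starts(dat, Fe ~ 1 - A1 * exp(-k1 * t) - (1 - A1) * exp(-k2 * t),
                      starts, lower = c(A1 = 0, k1 = 1e-9, k2 = 1e-9),
                      upper = c(A1 = 1, k1 = Inf, k2 = Inf))
    co <- stats::coef(fit)
    A1 <- unname(co["A1"]); k1 <- unname(co["k1"]); k2 <- unname(co["k2"])
    if (k1 < k2) { tmp <- k1; k1 <- k2; k2 <- tmp; A1 <- 1 - A1 }
    out <- list(n_components = 2L, A1 = A1, k1 = k1, A2 = 1 - A1, k2 = k2)
    p <- 3
  } else stop("n_components must be 1 or 2")
  rss <- sum(stats::residuals(fit)^2)
  out$rss <- rss
  out$bic <- n * log(max(rss, 1e-300) / n) + p * log(n)
  out$n <- n
  class(out) <- "exp_fit"
  out
}

# nlsLM over a list of starting values; first convergent fit wins.
try_starts <- function(dat, formula, starts, lower = NULL, upper = NULL) {
  last <- NULL
  for (s in starts) {
    fit <- tryCatch(
      minpack.lm::nlsLM(formula, data = dat, start = s, lower = lower,
                        upper = upper,
                        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) e)
    if (!inherits(fit, "error")) return(fit)
    last <- fit
  }
  stop("CDF fit failed to converge: ", conditionMessage(last))
}

#' Mono vs biexponential model choice for a dwell distribution
#'
#' Fits both models and picks the lower BIC (computed from the Gaussian
#' residual likelihood of the CDF fit); both fits are returned, matching
#' the practice of reporting mono and biexponential curves together.
#'
#' @param dist a \code{dwell_dist} or numeric dwells
#' @return list(mono, bi, chosen)
#' @export
fit_dwell <- function(dist) {
  mono <- fit_dwell_cdf(dist, 1)
  bi <- tryCatch(fit_dwell_cdf(dist, 2), error = function(e) NULL)
  chosen <- if (!is.null(bi) && bi$bic < mono$bic) bi else mono
  list(mono = mono, bi = bi, chosen = chosen)
}

#' Weighted-average rate constant of a biexponential fit
#'
#' k_av = 1 / (A1/k1 + A2/k2): each dwell-time component is weighted by
#' its amplitude on the timescale (not the rate) axis.  Equals k1 when
#' A2 = 0 or when k1 = k2, and is symmetric under component exchange.
#'
#' @param A1,k1,A2,k2 biexponential amplitudes (A1 + A2 = 1) and rates (1/s)
#' @return k_av (1/s)
#' @export
weighted_rate <- function(A1, k1, A2 = 0, k2 = NA) {
  if (abs(A1 + A2 - 1) > 1e-8) stop("amplitudes must sum to 1")
  if (k1 <= 0 || (A2 > 0 && (!is.finite(k2) || k2 <= 0)))
    stop("rates must be > 0")
  N <- if (A2 > 0) A2 / k2 else 0
  1 / (A1 / k1 + N)
}

#' Error propagation for the weighted-average rate
#'
#' Implements the printed propagation: DM = (A1/k1) sqrt((dA1/A1)^2 +
#' (dk1/k1)^2), DN likewise for the second component, and (mode "paper")
#' Dk_av = sqrt(DM^2 + DN^2) exactly as printed -- note this combination
#' carries units of time, not rate.  Mode "propagated" is a non-verbatim
#' alternative with rate units: Dk_av = k_av^2 sqrt(DM^2 + DN^2), the
#' first-order delta-method result for k_av = 1/(M + N).
#'
#' @param A1,k1,A2,k2 fit parameters (A1 + A2 = 1)
#' @param dA1,dk1,dA2,dk2 their standard deviations (e.g. bootstrap SDs)
#' @param mode "paper" (verbatim) or "propagated"
#' @return list(M, N, dM, dN, k_av, dk_av, mode)
#' @export
rate_error <- function(A1, k1, A2 = 0, k2 = NA, dA1 = 0, dk1 = 0,
                       dA2 = 0, dk2 = 0, mode = c("paper", "propagated")) {
  mode <- match.arg(mode)
  if (k1 <= 0) stop("k1 must be > 0")
  if (A1 <= 0 && (dA1 > 0 || dk1 > 0))
    stop("relative error undefined: A1 = 0 with nonzero uncertainty")
  M <- A1 / k1
  dM <- if (A1 > 0) M * sqrt((dA1 / A1)^2 + (dk1 / k1)^2) else 0
  if (A2 > 0) {
    if (!is.finite(k2) || k2 <= 0) stop("k2 must be > 0 when A2 > 0")
    N <- A2 / k2
    dN <- N * sqrt((dA2 / A2)^2 + (dk2 / k2)^2)
  } else {
    if (dA2 > 0 || dk2 > 0)
      stop("relative error undefined: A2 = 0 with nonzero uncertainty")
    N <- 0; dN <- 0
  }
  k_av <- 1 / (M + N)
  dk_av <- switch(mode,
                  paper = sqrt(dM^2 + dN^2),
                  propagated = k_av^2 * sqrt(dM^2 + dN^2))
  list(M = M, N = N, dM = dM, dN = dN, k_av = k_av, dk_av = dk_av,
       mode = mode)
}

#' Scale a dwell-time fit by its TDP cluster weight
#'
#' Converts the exit-rate estimate of a per-pair dwell fit into the rate
#' coefficient of that specific transition.  The dwell time before an
#' i -> j transition reflects the total exit rate of state i, so the
#' transition's own rate is the fitted k_av multiplied by the cluster
#' weight (the branching fraction of i -> j among exits from i); with
#' weight 1 the fit passes through unchanged, and rates of competing
#' exits scaled this way sum to the state's total exit rate.  Mode
#' "lifetime" instead multiplies the lifetime by the weight (the literal
#' reading of the source protocol), provided for comparison.
#'
#' @param fit an \code{exp_fit} (or a plain k_av value)
#' @param weight cluster weight in [0, 1]
#' @param mode "rate" (default) or "lifetime"
#' @return list(k_av, weight, k_scaled, lifetime_scaled, mode)
#' @export
scale_by_cluster_weight <- function(fit, weight, mode = c("rate", "lifetime")) {
  mode <- match.arg(mode)
  if (!is.finite(weight) || weight < 0 || weight > 1)
    stop("weight must lie in [0, 1]")
  k_av <- if (inherits(fit, "exp_fit"))
    weighted_rate(fit$A1, fit$k1, fit$A2, fit$k2) else as.numeric(fit)
  k_scaled <- switch(mode, rate = weight * k_av, lifetime = k_av / weight)
  list(k_av = k_av, weight = weight, k_scaled = k_scaled,
       lifetime_scaled = 1 / k_scaled, mode = mode)
}

#' Bootstrap standard deviations of dwell-fit parameters
#'
#' Resamples the dwell times with replacement \code{n_boot} times, refits,
#' and reports the per-parameter SD and 3 x SD.  Resampling is at the
#' dwell level (the bootstrapped-exponential-fitting convention); if more
#' than 20% of refits fail a warning is raised and SDs come from the
#' successful ones.
#'
#' @param dist a \code{dwell_dist} or numeric dwells
#' @param n_components 1 or 2
#' @param n_boot bootstrap samples
#' @param seed optional integer seed
#' @return list with \code{sd}, \code{sd3}, \code{n_fail}, \code{boots}
#'   (parameter matrix incl. k_av per resample)
#' @export
bootstrap_rates <- function(dist, n_components = 2, n_boot = 100,
                            seed = NULL) {
  t <- if (inherits(dist, "dwell_dist")) dist$dwell else sort(dist)
  if (!is.null(seed)) set.seed(seed)
  pars <- matrix(NA_real_, n_boot, 5,
                 dimnames = list(NULL, c("A1", "k1", "A2", "k2", "k_av")))
  for (b in seq_len(n_boot)) {
    tb <- sample(t, replace = TRUE)
    f <- tryCatch(fit_dwell_cdf(tb, n_components), error = function(e) NULL)
    if (is.null(f)) next
    pars[b, ] <- c(f$A1, f$k1, f$A2, f$k2,
                   weighted_rate(f$A1, f$k1, f$A2, f$k2))
  }
  ok <- stats::complete.cases(pars[, c("A1", "k1", "k_av")])
  n_fail <- n_boot - sum(ok)
  if (n_fail > 0.2 * n_boot)
    warning(sprintf("%d of %d bootstrap fits failed; SDs from the rest",
                    n_fail, n_boot))
  sds <- apply(pars[ok, , drop = FALSE], 2, stats::sd)
  if (n_components == 1) sds[c("A2", "k2")] <- 0
  list(sd = sds, sd3 = 3 * sds, n_fail = n_fail, boots = pars)
}
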