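#' Fit a Gaussian-emission hidden Markov model to a FRET trace
#'
#' Baum-Welch EM from \code{n_starts} randomized initializations (means at
#' quantiles of the data plus jitter), keeping the highest-likelihood
#' model.  Emissions are Gaussian on the efficiency axis, matching both
#' the idealization software this stage mirrors and the additive-noise
#' camera model of the simulator.  State variances are floored at
#' \code{var_floor} (in E^2) to prevent EM collapse on noiseless data; a
#' fit that hit the floor is flagged.  The returned model is canonicalized
#' by ascending mean.
#'
#' @param fret a \code{fret_trace} (or numeric vector of E values)
#' @param K number of states (>= 1)
#' @param n_starts randomized initializations
#' @param tol EM stops when the log-likelihood gain drops below this
#' @param max_iter maximum EM iterations per start
#' @param seed optional integer seed
#' @param var_floor minimum state variance (E^2 units)
#' @param shared_sd estimate one emission width shared by all states
#'   (default; the camera noise that sets the width is state-independent,
#'   and a shared width prevents surplus states from broadening into
#'   containers for frame-averaging artifacts) or one width per state
#' @return an \code{hmm_model}: K, mu, sd, trans, pi, loglik, n_params,
#'   n_obs, plus the per-iteration log-likelihood of the winning start
#' @export
fit_hmm <- function(fret, K, n_starts = 10, tol = 1e-6, max_iter = 1000,
                    seed = NULL, var_floor = 1e-4, shared_sd = TRUE) {
  obs <- fret_obs(fret)
  n <- length(obs)
  if (K < 1) stop("K must be >= 1")
  if (n < 5 * K) stop("insufficient frames: need >= ", 5 * K, ", have ", n)
  if (!is.null(seed)) set.seed(seed)
  n_params <- if (shared_sd) (K - 1) + K * (K - 1) + K + 1
              else (K - 1) + K * (K - 1) + 2 * K
  if (K == 1) {
    mod <- list(K = 1L, mu = mean(obs), sd = max(stats::sd(obs), sqrt(var_floor)),
                trans = matrix(1, 1, 1), pi = 1,
                loglik = sum(stats::dnorm(obs, mean(obs),
                             max(stats::sd(obs), sqrt(var_floor)), log = TRUE)),
                n_params = n_params, n_obs = n, ll_trace = NA_real_,
                converged = TRUE, floored = FALSE)
    class(mod) <- "hmm_model"
    return(mod)
  }
  sd0 <- max(stats::sd(obs), sqrt(var_floor))
  rng <- stats::quantile(obs, c(0.02, 0.98), names = FALSE)
  best <- NULL
  for (s in seq_len(n_starts)) {
    # alternate between occupancy-weighted (quantile) and range-spread
    # starts: sparsely populated extreme states are missed by quantile
    # seeding alone
    mu <- if (s %% 2 == 1)
      stats::quantile(obs, probs = seq_len(K) / (K + 1), names = FALSE) +
        stats::rnorm(K, 0, 0.02)
    else
      seq(rng[1], rng[2], length.out = K) + stats::rnorm(K, 0, 0.02)
    mu <- sort(mu)
    sds <- rep(max(sd0 / 2, sqrt(var_floor)), K)
    Tm <- matrix(0.1 / (K - 1), K, K); diag(Tm) <- 0.9
    pi0 <- rep(1 / K, K)
    fit <- baum_welch(obs, mu, sds, Tm, pi0, tol, max_iter, var_floor,
                      shared_sd)
    if (is.null(best) || fit$loglik > best$loglik) best <- fit
  }
  ord <- order(best$mu)
  mod <- list(K = as.integer(K), mu = best$mu[ord], sd = best$sd[ord],
              trans = best$trans[ord, ord, drop = FALSE], pi = best$pi[ord],
              loglik = best$loglik, n_params = n_params, n_obs = n,
              ll_trace = best$ll_trace, converged = best$converged,
              floored = best$floored)
  class(mod) <- "hmm_model"
  mod
}

# Baum-Welch EM (compiled); thin wrapper kept so the fit path has one
# R-level seam for tests.
baum_welch <- function(obs, mu, sds, Tm, pi0, tol, max_iter, var_floor,
                       shared_sd = TRUE) {
  f <- hmm_bw_cpp(obs, mu, sds, Tm, pi0, tol, max_iter, var_floor, shared_sd)
  f$mu <- as.numeric(f$mu); f$sd <- as.numeric(f$sd)
  f$pi <- as.numeric(f$pi)
  f
}

# Valid observations of a fret_trace restricted to its valid range.
fret_obs <- function(fret) {
  if (is.numeric(fret)) return(fret[is.finite(fret)])
  vr <- attr(fret, "valid_range")
  if (is.null(vr)) vr <- c(1L, nrow(fret))
  idx <- vr[1]:vr[2]
  obs <- fret$E[idx]
  obs[fret$valid[idx] & is.finite(obs)]
}

#' Most-probable state sequence (Viterbi decoding)
#'
#' Deterministic given the model and trace; ties between equally likely
#' predecessors are broken toward the lowest state index.
#'
#' With \code{refine_levels} (default) the reported level of each state
#' is re-estimated from the interior frames of its dwells (frames whose
#' neighbours share the state).  The first and last frame of a dwell can
#' straddle a transition and carry a time-averaged efficiency, so
#' excluding them removes the blur bias from the level estimate; states
#' without at least three interior frames keep the model mean.
#'
#' @param model an \code{hmm_model}
#' @param fret the \code{fret_trace} it was fitted on
#' @param refine_levels re-estimate levels from dwell-interior frames
#' @return an \code{idealized_path}: data frame (frame, state, level)
#' @export
viterbi_path <- function(model, fret, refine_levels = TRUE) {
  obs <- fret_obs(fret)
  st <- if (model$K == 1) rep(1L, length(obs))
        else hmm_viterbi_cpp(obs, model$mu, model$sd, model$trans, model$pi)
  mu <- model$mu
  if (refine_levels && length(obs) > 2) {
    n <- length(obs)
    interior <- c(FALSE, st[2:(n - 1)] == st[1:(n - 2)] &
                         st[2:(n - 1)] == st[3:n], FALSE)
    if (n > 2) {
      for (k in seq_len(model$K)) {
        sel <- interior & st == k
        if (sum(sel) >= 3) mu[k] <- mean(obs[sel])
      }
    }
  }
  structure(data.frame(frame = seq_along(obs), state = st,
                       level = mu[st]),
            trace_id = if (is.numeric(fret)) "trace" else attr(fret, "trace_id"),
            exposure = if (is.numeric(fret)) NA_real_ else attr(fret, "exposure"),
            K = model$K, mu = mu,
            class = c("idealized_path", "data.frame"))
}

#' Prune blur-broadened states from a fitted HMM
#'
#' Camera integration turns mid-frame transitions into frames whose
#' apparent efficiency lies between the flanking state levels.  When the
#' model order exceeds the number of states a trace visits, EM parks a
#' surplus state with a large emission width on these frame-averaging
#' artifacts.  The physical emission width is set by shot noise shared by
#' all states, so a state whose sigma exceeds \code{factor} times the
#' median sigma of the remaining states is removed (iteratively, broadest
#' first) and the trace is re-decoded with the reduced state set
#' (transition rows renormalized).
#'
#' @param model an \code{hmm_model}
#' @param factor width ratio above which a state is considered an
#'   artifact container
#' @return the pruned \code{hmm_model} (possibly unchanged)
#' @export
prune_broad_states <- function(model, factor = 1.5) {
  while (model$K > 2) {
    i <- which.max(model$sd)
    if (model$sd[i] <= factor * stats::median(model$sd[-i])) break
    keep <- setdiff(seq_len(model$K), i)
    Tm <- model$trans[keep, keep, drop = FALSE]
    Tm <- Tm / rowSums(Tm)
    pi0 <- model$pi[keep]
    if (sum(pi0) <= 0) pi0 <- rep(1 / length(keep), length(keep))
    model$mu <- model$mu[keep]
    model$sd <- model$sd[keep]
    model$trans <- Tm
    model$pi <- pi0 / sum(pi0)
    model$K <- length(keep)
    model$n_params <- (model$K - 1) + model$K * (model$K - 1) + 2 * model$K
  }
  model
}

#' Merge near-degenerate states of an idealized path
#'
#' When a trace visits fewer physical states than the model order, EM
#' parks surplus states on top of occupied levels; Viterbi then flickers
#' between the near-identical copies, creating spurious transitions with
#' E_before almost equal to E_after.  Levels closer than \code{tol} are
#' merged by single linkage (ascending sweep); merged states are
#' relabelled and their level becomes the frame-weighted mean of the
#' group.
#'
#' @param path an \code{idealized_path}
#' @param tol merge threshold on the E axis; should sit above the level
#'   estimation noise and below the smallest physical state separation
#' @return the path with merged states and updated levels
#' @export
merge_idealized_states <- function(path, tol = 0.06) {
  mu <- attr(path, "mu")
  K <- length(mu)
  if (K < 2) return(path)
  ord <- order(mu)
  grp <- integer(K); g <- 1L
  grp[ord[1]] <- 1L
  for (i in seq_len(K - 1)) {
    if (mu[ord[i + 1]] - mu[ord[i]] >= tol) g <- g + 1L
    grp[ord[i + 1]] <- g
  }
  if (max(grp) == K) return(path)
  counts <- tabulate(path$state, nbins = K)
  new_mu <- vapply(seq_len(max(grp)), function(gg) {
    sel <- grp == gg
    if (sum(counts[sel]) > 0) sum(mu[sel] * counts[sel]) / sum(counts[sel])
    else mean(mu[sel])
  }, 0)
  path$state <- grp[path$state]
  path$level <- new_mu[path$state]
  attr(path, "mu") <- new_mu
  attr(path, "K") <- max(grp)
  path
}

#' Select the number of HMM states by BIC
#'
#' BIC = -2 logL + n_params log(n_frames) with
#' n_params = (K - 1) + K(K - 1) + 2K.  Ties go to the smallest K.
#'
#' @param fret a \code{fret_trace}
#' @param k_range candidate state counts (within 1..10)
#' @param ... passed to \code{\link{fit_hmm}}
#' @return list with \code{model} (argmin-BIC fit), \code{bic} (named
#'   vector over K) and \code{models}
#' @export
select_k <- function(fret, k_range = 1:4, ...) {
  if (any(k_range < 1 | k_range > 10)) stop("k_range must lie within 1..10")
  models <- list(); bic <- rep(NA_real_, length(k_range))
  errs <- character(0)
  for (i in seq_along(k_range)) {
    K <- k_range[i]
    m <- tryCatch(fit_hmm(fret, K, ...), error = function(e) e)
    if (inherits(m, "error")) { errs <- c(errs, conditionMessage(m)); next }
    models[[as.character(K)]] <- m
    bic[i] <- -2 * m$loglik + m$n_params * log(m$n_obs)
  }
  names(bic) <- k_range
  if (all(is.na(bic)))
    stop("all HMM fits failed: ", paste(unique(errs), collapse = "; "))
  best <- k_range[which.min(bic)]   # which.min takes the first (smallest K) tie
  list(model = models[[as.character(best)]], bic = bic, models = models)
}

#' @export
print.hmm_model <- function(x, ...) {
  cat(sprintf("Gaussian HMM, K = %d, logL = %.2f (n = %d)\n",
              x$K, x$loglik, x$n_obs))
  cat("  means:", paste(sprintf("%.3f", x$mu), collapse = " "), "\n")
  cat("  sds:  ", paste(sprintf("%.3f", x$sd), collapse = " "), "\n")
  invisible(x)
}
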