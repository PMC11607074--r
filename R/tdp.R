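#' Extract transition records from idealized paths
#'
#' One record per state change, carrying the fitted level before and after
#' the change and the dwell time of the run preceding it.  The first and
#' last constant-state runs of every trace lack a complete dwell (they are
#' truncated by the observation window), so only interior transitions
#' produce records; a path with no transitions contributes nothing.
#'
#' Mid-frame transitions produce frames whose apparent efficiency is the
#' time-weighted average of the flanking states; decoded against a trace
#' that visits fewer levels than the model order, these frames accumulate
#' in a state of their own whose dwells are almost all a single frame.
#' A physical state, by contrast, dwells for many frames on average at
#' the rates considered here.  States whose mean run length falls below
#' \code{min_mean_run} frames are therefore treated as frame-averaging
#' artifacts and removed from that trace, each orphan frame joining the
#' preceding run -- which yields exactly the composite ("skipped")
#' transitions expected when intermediate dwells approach the frame
#' time.  Surviving states keep all their dwells, including one-frame
#' ones.
#'
#' @param paths list of \code{idealized_path} objects (or a single one)
#' @param exposure frame time (s); taken from the paths when present
#' @param min_mean_run per-trace threshold (frames) below which a state
#'   is discarded as a blur artifact; 0 disables
#' @return data frame of class \code{transition_records}: trace_id,
#'   from_state, to_state, e_before, e_after, dwell (s)
#' @export
extract_transitions <- function(paths, exposure = NULL, min_mean_run = 2) {
  if (inherits(paths, "idealized_path")) paths <- list(paths)
  recs <- lapply(paths, function(p) {
    dt <- attr(p, "exposure")
    if (is.null(dt) || is.na(dt)) dt <- exposure
    if (is.null(dt)) stop("exposure unknown; supply the exposure argument")
    s <- p$state
    if (min_mean_run > 0 && length(s) > 1) {
      r0 <- rle(s)
      meanrun <- tapply(r0$lengths, r0$values, mean)
      transient <- as.integer(names(meanrun))[meanrun < min_mean_run]
      if (length(transient)) {
        bad <- s %in% transient
        if (!all(bad)) {
          for (t in which(bad)) s[t] <- if (t > 1) s[t - 1] else s[min(which(!bad))]
        }
      }
    }
    p$state <- s
    r <- rle(p$state)
    m <- length(r$values)
    if (m < 3) return(NULL)
    i <- 2:(m - 1)          # interior runs only
    mu <- attr(p, "mu")
    data.frame(trace_id = attr(p, "trace_id"),
               from_state = r$values[i], to_state = r$values[i + 1],
               e_before = mu[r$values[i]], e_after = mu[r$values[i + 1]],
               dwell = r$lengths[i] * dt,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, recs)
  if (is.null(out))
    out <- data.frame(trace_id = character(0), from_state = integer(0),
                      to_state = integer(0), e_before = numeric(0),
                      e_after = numeric(0), dwell = numeric(0))
  rownames(out) <- NULL
  class(out) <- c("transition_records", "data.frame")
  out
}

#' Gaussian-convoluted transition density plot
#'
#' 2D histogram of (E_before, E_after) over the unit square, convolved
#' with an isotropic Gaussian kernel.  The kernel is discretely normalized
#' so the density integrates to the number of transitions; bandwidth 0
#' returns the raw histogram.  The grid is for display; model fitting
#' operates on the raw points (\code{\link{cluster_tdp}}).
#'
#' @param records \code{transition_records}
#' @param n_bins bins per axis (>= 10)
#' @param bandwidth kernel SD in E units
#' @return \code{tdp_grid}: list with bin centres and the density matrix
#' @export
build_tdp <- function(records, n_bins = 100, bandwidth = 0.02) {
  if (n_bins < 10) stop("n_bins must be >= 10")
  centers <- (seq_len(n_bins) - 0.5) / n_bins
  H <- matrix(0, n_bins, n_bins)
  if (nrow(records) == 0) {
    warning("no transition records; returning an empty grid")
  } else {
    bx <- pmin(n_bins, pmax(1, ceiling(records$e_before * n_bins)))
    by <- pmin(n_bins, pmax(1, ceiling(records$e_after * n_bins)))
    for (i in seq_along(bx)) H[bx[i], by[i]] <- H[bx[i], by[i]] + 1
  }
  if (bandwidth > 0 && nrow(records) > 0) {
    d <- outer(centers, centers, function(a, b)
      stats::dnorm(a - b, sd = bandwidth))
    d <- sweep(d, 2, colSums(d), "/")   # column-normalized: mass-preserving
    H <- d %*% H %*% t(d)
  }
  structure(list(x = centers, y = centers, density = H,
                 bandwidth = bandwidth, n = nrow(records)),
            class = "tdp_grid")
}

# Cluster index bookkeeping: ordered pairs (i, j), i != j, for K levels.
tdp_pairs <- function(K) {
  from <- integer(0); to <- integer(0)
  for (i in seq_len(K)) for (j in seq_len(K)) if (i != j) {
    from <- c(from, i); to <- c(to, j)
  }
  list(from = from, to = to)
}

#' Cluster a transition density plot with a constrained Gaussian mixture
#'
#' For each candidate K the raw (E_before, E_after) points are fit with a
#' mixture of K(K-1) isotropic 2D Gaussians whose centres are constrained
#' to the Cartesian pairs (E_i, E_j), i != j, of K shared state levels.
#' Free parameters: the K levels, the K(K-1) cluster weights and one
#' isotropic variance per cluster.  The best of \code{n_init} seeded EM
#' starts is kept, and the optimal state count K_opt minimizes
#' BIC = -2 logL + p log(n) with p = K + (K(K-1) - 1) + K(K-1); ties go to
#' the smallest K.  K = 1 is the no-transition null, scored as a single
#' broad isotropic component (p = 2).
#'
#' Each initialization is screened with a short EM run and the best
#' screening likelihood is polished to convergence (the standard
#' multi-start economy; with well-separated levels the winner is
#' identical to running every start to convergence).
#'
#' @param records \code{transition_records} (>= 10 rows)
#' @param k_range candidate numbers of FRET states (within 1..10)
#' @param n_init EM initializations per K
#' @param seed optional integer seed
#' @param max_iter,tol EM controls for the polishing run
#' @param n_short screening iterations per initialization
#' @param var_floor minimum cluster variance (E^2)
#' @return \code{tdp_cluster_model}: K_opt, sorted levels, weight matrix
#'   w[i, j], per-cluster SDs, per-K BIC table
#' @export
cluster_tdp <- function(records, k_range = 1:10, n_init = 30, seed = NULL,
                        max_iter = 300, tol = 1e-6, n_short = 25,
                        var_floor = 1e-4) {
  x <- cbind(records$e_before, records$e_after)
  n <- nrow(x)
  if (n < 10) stop("need >= 10 transition records")
  if (!is.null(seed)) set.seed(seed)
  pooled <- as.numeric(x)
  tab <- data.frame(K = k_range, loglik = NA_real_, p = NA_real_,
                    bic = NA_real_, note = "")
  fits <- list()
  for (r in seq_along(k_range)) {
    K <- k_range[r]
    if (K == 1) {
      mu <- mean(pooled)
      s2 <- max(mean((x[, 1] - mu)^2 + (x[, 2] - mu)^2) / 2, var_floor)
      ll <- sum(-log(2 * pi * s2) - ((x[, 1] - mu)^2 + (x[, 2] - mu)^2) / (2 * s2))
      tab$loglik[r] <- ll; tab$p[r] <- 2
      tab$bic[r] <- -2 * ll + 2 * log(n)
      fits[[as.character(K)]] <- list(levels = mu, w = 1, sigma2 = s2,
                                      from = 1L, to = 1L, loglik = ll)
      next
    }
    p <- K + (K * (K - 1) - 1) + K * (K - 1)
    if (n < p) { tab$note[r] <- "skipped: fewer records than parameters"; next }
    pr <- tdp_pairs(K)
    C <- length(pr$from)
    best <- NULL
    for (init in seq_len(n_init)) {
      lev0 <- sort(stats::quantile(pooled, probs = seq_len(K) / (K + 1),
                                   names = FALSE) + stats::rnorm(K, 0, 0.03))
      w0 <- rep(1 / C, C)
      s20 <- rep(max(stats::var(pooled) / 8, 4 * var_floor), C)
      f <- tdp_em_cpp(x, lev0, w0, s20, pr$from - 1L, pr$to - 1L,
                      n_short, tol, var_floor)
      if (is.null(best) || f$loglik > best$loglik) best <- f
    }
    best <- tdp_em_cpp(x, best$levels, best$w, best$sigma2,
                       pr$from - 1L, pr$to - 1L, max_iter, tol, var_floor)
    # canonicalize: sort levels ascending, remap cluster order
    ord <- order(best$levels)
    rank <- match(seq_len(K), ord)
    newfrom <- rank[pr$from]; newto <- rank[pr$to]
    key_old <- paste(newfrom, newto)
    key_new <- paste(pr$from, pr$to)
    perm <- match(key_new, key_old)
    fits[[as.character(K)]] <- list(levels = best$levels[ord],
                                    w = best$w[perm],
                                    sigma2 = best$sigma2[perm],
                                    from = pr$from, to = pr$to,
                                    loglik = best$loglik)
    tab$loglik[r] <- best$loglik; tab$p[r] <- p
    tab$bic[r] <- -2 * best$loglik + p * log(n)
  }
  if (all(is.na(tab$bic)))
    stop("all mixture fits failed or were skipped:\n",
         paste(sprintf("  K=%d %s", tab$K, tab$note), collapse = "\n"))
  kopt <- tab$K[which.min(tab$bic)]    # first minimum = smallest K on ties
  f <- fits[[as.character(kopt)]]
  W <- matrix(0, kopt, kopt)
  if (kopt > 1) W[cbind(f$from, f$to)] <- f$w
  structure(list(K = as.integer(kopt), levels = f$levels, weights = W,
                 w = f$w, sigma = sqrt(f$sigma2), from = f$from, to = f$to,
                 loglik = f$loglik,
                 bic = tab$bic[tab$K == kopt], bic_table = tab,
                 n = n, fits = fits),
            class = "tdp_cluster_model")
}

# Hard assignment of records to clusters by maximum responsibility.
tdp_assign <- function(model, records) {
  if (model$K == 1) return(rep(1L, nrow(records)))
  x <- cbind(records$e_before, records$e_after)
  r <- tdp_resp_cpp(x, model$levels, model$w, model$sigma^2,
                    model$from - 1L, model$to - 1L)
  max.col(r$resp, ties.method = "first")
}

#' Relative transition counts per ordered state pair
#'
#' Each record is assigned to its maximum-responsibility cluster; counts
#' are normalized to fractions of all transitions.
#'
#' @param model a \code{tdp_cluster_model}
#' @param records the \code{transition_records} it was fitted on
#' @return K x K matrix of fractions (row = from-state, column = to-state)
#' @export
transition_counts <- function(model, records) {
  K <- model$K
  out <- matrix(0, K, K)
  if (nrow(records) == 0) return(out)
  a <- tdp_assign(model, records)
  cnt <- tabulate(a, nbins = length(model$from))
  out[cbind(model$from, model$to)] <- cnt / sum(cnt)
  out
}

#' @export
print.tdp_cluster_model <- function(x, ...) {
  cat(sprintf("TDP cluster model: K_opt = %d (n = %d transitions)\n", x$K, x$n))
  cat("  levels:", paste(sprintf("%.3f", x$levels), collapse = " "), "\n")
  cat("  BIC by K:\n")
  print(x$bic_table[, c("K", "bic", "note")], row.names = FALSE)
  invisible(x)
}
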