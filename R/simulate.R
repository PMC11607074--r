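#' Exact stochastic simulation of a state path
#'
#' Gillespie realization of the kinetic scheme: waiting times are
#' exponential with rate equal to the sum of exit rates from the current
#' state, and the next state is drawn proportionally to the individual
#' rates.  A state with no exit rate yields a single segment to the end of
#' the observation window.
#'
#' @param scheme a \code{\link{kinetic_scheme}}
#' @param duration total simulated time (s)
#' @param initial_state starting state label; \code{NULL} draws it from the
#'   stationary distribution of the scheme
#' @param seed optional integer seed
#' @return a \code{continuous_path}: data frame of (state, t_entry, t_exit)
#'   segments covering [0, duration], with the duration as an attribute
#' @export
simulate_state_path <- function(scheme, duration, initial_state = NULL,
                                seed = NULL) {
  stopifnot(inherits(scheme, "kinetic_scheme"))
  if (duration <= 0) stop("duration must be > 0")
  if (!is.null(seed)) set.seed(seed)
  Q <- rate_matrix(scheme)
  states <- scheme$state_names
  if (is.null(initial_state)) {
    p <- stationary_distribution(scheme)
    initial_state <- sample(states, 1, prob = p)
  }
  if (!initial_state %in% states)
    stop("unknown initial state: ", initial_state)
  cur <- initial_state
  t <- 0
  st <- character(0); t0 <- numeric(0); t1 <- numeric(0)
  repeat {
    out <- Q[cur, ]
    out[cur] <- 0
    rtot <- sum(out)
    if (rtot <= 0) {            # absorbing: one segment to the end
      st <- c(st, cur); t0 <- c(t0, t); t1 <- c(t1, duration)
      break
    }
    dt <- stats::rexp(1, rtot)
    if (t + dt >= duration) {
      st <- c(st, cur); t0 <- c(t0, t); t1 <- c(t1, duration)
      break
    }
    st <- c(st, cur); t0 <- c(t0, t); t1 <- c(t1, t + dt)
    t <- t + dt
    cur <- sample(states, 1, prob = out)
  }
  structure(data.frame(state = st, t_entry = t0, t_exit = t1,
                       stringsAsFactors = FALSE),
            duration = duration, class = c("continuous_path", "data.frame"))
}

#' Render a state path as a camera-sampled intensity trace
#'
#' Frames of length \code{emission$exposure} integrate the path: the
#' apparent FRET level of a frame is the time-weighted mean of the state
#' levels of the segments overlapping it, which reproduces the
#' frame-blurring that makes fast intermediate dwells appear as skipped
#' states downstream.  Donor and acceptor photobleaching times are drawn
#' from independent exponential clocks; after acceptor bleach all intensity
#' reverts to the donor channel, and after donor bleach both channels fall
#' to background.  Bleached frames are retained (truncation is a filtering
#' decision, see \code{\link{filter_traces}}).
#'
#' @param path a \code{continuous_path}
#' @param emission an \code{\link{emission_model}}
#' @param seed optional integer seed
#' @param trace_id identifier stored with the trace
#' @return an \code{intensity_trace}: data frame (frame, time_s, donor,
#'   acceptor) with exposure, trace_id and true bleach times as attributes
#' @export
render_trace <- function(path, emission, seed = NULL, trace_id = "trace1") {
  stopifnot(inherits(path, "continuous_path"))
  if (!is.null(seed)) set.seed(seed)
  exposure <- emission$exposure
  duration <- attr(path, "duration")
  n_frames <- floor(duration / exposure + 1e-9)
  if (n_frames < 1) stop("path shorter than one frame")

  means <- emission$state_means
  lev <- means[path$state]
  lev[is.na(lev)] <- 0   # states absent from the emission model render dark
  # cumulative integral of E(t) at arbitrary times, evaluated on the
  # frame boundaries (exact time-weighted averaging)
  cum_at <- function(tt) {
    i <- findInterval(tt, path$t_entry)
    i[i < 1] <- 1
    base <- c(0, cumsum(lev * (path$t_exit - path$t_entry)))[i]
    base + lev[i] * pmax(0, tt - path$t_entry[i])
  }
  bounds <- (0:n_frames) * exposure
  ce <- cum_at(bounds)
  ebar <- diff(ce) / exposure

  t_a <- if (emission$acceptor_bleach_rate > 0)
    stats::rexp(1, emission$acceptor_bleach_rate) else Inf
  t_d <- if (emission$donor_bleach_rate > 0)
    stats::rexp(1, emission$donor_bleach_rate) else Inf
  # per-frame alive fractions
  f_d <- pmin(1, pmax(0, (t_d - bounds[-length(bounds)]) / exposure))
  f_both <- pmin(f_d, pmin(1, pmax(0, (min(t_a, t_d) - bounds[-length(bounds)]) / exposure)))

  g <- emission$gamma
  w_acc <- g * ebar / (g * ebar + (1 - ebar))
  w_acc[!is.finite(w_acc)] <- 0
  I <- emission$total_intensity
  ia <- I * w_acc * f_both
  id <- I * (1 - w_acc) * f_both + I * (f_d - f_both)
  if (emission$noise == "poisson") {
    ia <- stats::rpois(n_frames, ia)
    id <- stats::rpois(n_frames, id)
  } else {
    ia <- ia + stats::rnorm(n_frames, 0, emission$noise_sd)
    id <- id + stats::rnorm(n_frames, 0, emission$noise_sd)
  }
  ia_obs <- ia + emission$beta * id
  structure(data.frame(frame = seq_len(n_frames),
                       time_s = bounds[-length(bounds)],
                       donor = id, acceptor = ia_obs),
            exposure = exposure, trace_id = trace_id,
            bleach = c(acceptor = t_a, donor = t_d),
            class = c("intensity_trace", "data.frame"))
}

#' Generate a synthetic smFRET dataset with ground truth
#'
#' Draws independent state paths and renders them as intensity traces.
#' Per-trace seeds are derived from the master seed by a single
#' \code{sample.int} draw, so any trace can be regenerated in isolation.  A
#' configurable fraction of traces is replaced by donor-only (zero-FRET)
#' molecules, the nuisance population always present in TIRF fields.
#'
#' @param scheme a \code{\link{kinetic_scheme}}
#' @param emission an \code{\link{emission_model}}
#' @param n_traces number of traces (>= 1)
#' @param duration per-trace observation window (s); the default matches
#'   the ~25 s window of the TIRF movies
#' @param seed master seed
#' @param donor_only_frac fraction of donor-only traces
#' @param initial_state passed to \code{\link{simulate_state_path}}
#' @return list with elements \code{traces} (intensity traces),
#'   \code{paths} (ground-truth continuous paths), \code{donor_only}
#'   (logical), \code{scheme}, \code{emission}, \code{seeds}
#' @export
generate_dataset <- function(scheme, emission, n_traces, duration = 25,
                             seed = 1, donor_only_frac = 0,
                             initial_state = NULL) {
  if (n_traces < 1) stop("n_traces must be >= 1")
  set.seed(seed)
  seeds <- sample.int(.Machine$integer.max - 1, 2 * n_traces)
  is_dark <- stats::runif(n_traces) < donor_only_frac
  traces <- vector("list", n_traces)
  paths <- vector("list", n_traces)
  dark_emission <- emission
  dark_emission$state_means[] <- 0
  for (i in seq_len(n_traces)) {
    id <- sprintf("trace%03d", i)
    if (is_dark[i]) {
      p <- structure(data.frame(state = scheme$state_names[1], t_entry = 0,
                                t_exit = duration, stringsAsFactors = FALSE),
                     duration = duration,
                     class = c("continuous_path", "data.frame"))
      tr <- render_trace(p, dark_emission, seed = seeds[n_traces + i],
                         trace_id = id)
    } else {
      p <- simulate_state_path(scheme, duration, initial_state = initial_state,
                               seed = seeds[i])
      tr <- render_trace(p, emission, seed = seeds[n_traces + i],
                         trace_id = id)
    }
    traces[[i]] <- tr
    paths[[i]] <- p
  }
  names(traces) <- names(paths) <- vapply(traces, attr, "", "trace_id")
  list(traces = traces, paths = paths, donor_only = is_dark,
       scheme = scheme, emission = emission, seeds = seeds)
}
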