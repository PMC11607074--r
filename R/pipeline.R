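#' Configuration for a full analysis run
#'
#' Bundles the generator, filtering, idealization, clustering and
#' kinetics settings of one seeded end-to-end run.  Presets populate the
#' kinetic scheme and the state FRET levels; every stochastic stage
#' receives a seed derived from the master seed, so any stage can be
#' rerun in isolation and the whole report is regenerable from the
#' config alone.
#'
#' @param preset scheme/emission preset name ("sin37", "sin21",
#'   "sin37_mg", "tn3", or "custom" with scheme/emission supplied)
#' @param n_traces,duration dataset size (traces x seconds)
#' @param seed master seed
#' @param donor_only_frac zero-FRET nuisance fraction in the simulation
#' @param scheme,emission explicit objects (required for "custom")
#' @param criteria trace filter criteria (\code{\link{filter_criteria}})
#' @param hmm_mode "fixed" (always hmm_k states per trace, mirroring the
#'   4-state per-trace idealization, default) or "select" (per-trace BIC
#'   over 1..hmm_k)
#' @param hmm_k maximum (or fixed) number of HMM states per trace
#' @param hmm_n_starts EM starts per trace fit
#' @param merge_tol post-decoding merge threshold for near-degenerate
#'   states (\code{\link{merge_idealized_states}}); NULL disables
#' @param tdp_k_range,tdp_n_init TDP clustering controls
#' @param n_boot bootstrap samples for kinetic errors
#' @param min_dwells minimum dwells for a per-pair fit
#' @param do_kinetics run the dwell-time stage (disable for state-level
#'   only runs)
#' @export
run_config <- function(preset = "sin37", n_traces = 200, duration = 25,
                       seed = 1, donor_only_frac = 0.15,
                       scheme = NULL, emission = NULL,
                       criteria = filter_criteria(),
                       hmm_mode = c("fixed", "select"), hmm_k = 4,
                       hmm_n_starts = 10, merge_tol = 0.06,
                       tdp_k_range = 1:10, tdp_n_init = 30,
                       n_boot = 100, min_dwells = 5, do_kinetics = TRUE) {
  hmm_mode <- match.arg(hmm_mode)
  if (preset != "custom") {
    scheme <- scheme %||% scheme_preset(preset)
    emission <- emission %||% emission_preset(preset)
  } else if (is.null(scheme) || is.null(emission)) {
    stop("custom preset requires explicit scheme and emission")
  }
  base::structure(list(preset = preset, n_traces = n_traces,
                       duration = duration, seed = seed,
                       donor_only_frac = donor_only_frac, scheme = scheme,
                       emission = emission, criteria = criteria,
                       hmm_mode = hmm_mode, hmm_k = hmm_k,
                       hmm_n_starts = hmm_n_starts, merge_tol = merge_tol,
                       tdp_k_range = tdp_k_range, tdp_n_init = tdp_n_init,
                       n_boot = n_boot, min_dwells = min_dwells,
                       do_kinetics = do_kinetics),
                  class = "run_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the full idealization / clustering / kinetics pipeline
#'
#' simulate -> render -> filter -> FRET -> HMM idealization -> transition
#' extraction -> TDP mixture clustering -> dwell-time kinetics, fully
#' determined by the config and its master seed.  Stage seeds are drawn
#' up front from the master seed.  Stage record counts are logged with
#' \code{message()} so filtering is auditable.
#'
#' @param config a \code{\link{run_config}}
#' @param quiet suppress stage messages
#' @return a \code{run_report}: K_opt, state levels with SDs, transition
#'   fraction matrix, per-transition kinetics table, and all intermediates
#'   (dataset, idealized paths, records, cluster model)
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "run_config"))
  say <- function(...) if (!quiet) message(sprintf(...))
  set.seed(config$seed)
  stage_seed <- sample.int(.Machine$integer.max - 1, 8)

  ds <- generate_dataset(config$scheme, config$emission, config$n_traces,
                         config$duration, seed = stage_seed[1],
                         donor_only_frac = config$donor_only_frac)
  say("simulate: %d traces x %.0f s (%d donor-only)",
      config$n_traces, config$duration, sum(ds$donor_only))

  flt <- filter_traces(ds$traces, config$criteria)
  say("filter: kept %d, rejected %d", length(flt$kept), nrow(flt$rejected))
  if (length(flt$kept) == 0) stop("stage filter: no traces survived")

  frets <- lapply(flt$kept, compute_fret)

  set.seed(stage_seed[2])
  hmm_seeds <- sample.int(.Machine$integer.max - 1, length(frets))
  paths <- vector("list", length(frets))
  kept_idx <- logical(length(frets))
  for (i in seq_along(frets)) {
    m <- tryCatch({
      if (config$hmm_mode == "fixed")
        fit_hmm(frets[[i]], config$hmm_k, n_starts = config$hmm_n_starts,
                seed = hmm_seeds[i])
      else
        select_k(frets[[i]], k_range = seq_len(config$hmm_k),
                 n_starts = config$hmm_n_starts, seed = hmm_seeds[i])$model
    }, error = function(e) NULL)
    if (is.null(m)) next
    m <- prune_broad_states(m)
    vp <- viterbi_path(m, frets[[i]])
    if (!is.null(config$merge_tol))
      vp <- merge_idealized_states(vp, config$merge_tol)
    paths[[i]] <- vp
    kept_idx[i] <- TRUE
  }
  paths <- paths[kept_idx]
  say("idealize: %d traces idealized (%s mode)", length(paths),
      config$hmm_mode)
  if (length(paths) == 0) stop("stage idealize: no traces idealized")

  records <- extract_transitions(paths)
  say("transitions: %d interior records", nrow(records))
  if (nrow(records) < 10) {
    # static dataset: no transition structure to cluster
    say("tdp: skipped (%d records); reporting a single-state model",
        nrow(records))
    pooled <- unlist(lapply(frets, fret_obs))
    return(base::structure(list(
      K_opt = 1L, levels = mean(pooled), level_sd = stats::sd(pooled),
      state_names = "S1", fractions = matrix(0, 1, 1), kinetics = NULL,
      kinetics_skipped = "fewer than 10 transition records",
      cluster_model = NULL, records = records, paths = paths,
      filter = flt$rejected, dataset = ds, config = config,
      stage_seeds = stage_seed), class = "run_report"))
  }

  model <- cluster_tdp(records, k_range = config$tdp_k_range,
                       n_init = config$tdp_n_init, seed = stage_seed[3])
  say("tdp: K_opt = %d, levels %s", model$K,
      paste(sprintf("%.3f", model$levels), collapse = " "))

  fractions <- transition_counts(model, records)
  level_sd <- level_sds(model)

  kinetics <- NULL
  if (config$do_kinetics && model$K > 1) {
    kinetics <- kinetics_table(records, model, n_boot = config$n_boot,
                               min_dwells = config$min_dwells,
                               seed = stage_seed[4])
    say("kinetics: %d transition pairs fitted", nrow(kinetics))
  } else if (config$do_kinetics) {
    say("kinetics: skipped (single-state model, no transitions)")
  }

  state_names <- if (model$K == 4) c("lnr", "cnr", "cr", "lr")
                 else paste0("S", seq_len(model$K))
  base::structure(list(K_opt = model$K, levels = model$levels,
                       level_sd = level_sd, state_names = state_names,
                       fractions = fractions, kinetics = kinetics,
                       cluster_model = model, records = records,
                       paths = paths, filter = flt$rejected,
                       dataset = ds, config = config,
                       stage_seeds = stage_seed),
                  class = "run_report")
}

# Per-level SD: average cluster sigma over the clusters incident to the
# level (the "average Gaussian sample SD" convention).
level_sds <- function(model) {
  vapply(seq_len(model$K), function(k) {
    inc <- model$from == k | model$to == k
    if (!any(inc)) return(NA_real_)
    mean(model$sigma[inc])
  }, 0)
}

# Dwell-time kinetics for every sufficiently populated transition pair.
kinetics_table <- function(records, model, n_boot = 100, min_dwells = 5,
                           seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  dw <- collect_dwells(records, model, min_dwells = min_dwells)
  rows <- list()
  for (key in names(dw)) {
    d <- dw[[key]]
    if (!d$sufficient) next
    fits <- tryCatch(fit_dwell(d), error = function(e) NULL)
    if (is.null(fits)) next
    f <- fits$chosen
    nc <- f$n_components
    boot <- tryCatch(
      bootstrap_rates(d, n_components = nc, n_boot = n_boot),
      error = function(e) NULL)
    # branching fraction of this exit among all exits from the same state
    w_from <- sum(model$w[model$from == d$from])
    w_rel <- if (w_from > 0) model$w[model$from == d$from & model$to == d$to] / w_from else NA_real_
    k_av <- weighted_rate(f$A1, f$k1, f$A2, f$k2)
    err <- if (!is.null(boot)) {
      rate_error(f$A1, f$k1, f$A2, if (nc == 2) f$k2 else 1,
                 dA1 = boot$sd["A1"], dk1 = boot$sd["k1"],
                 dA2 = if (nc == 2) boot$sd["A2"] else 0,
                 dk2 = if (nc == 2) boot$sd["k2"] else 0)
    } else NULL
    rows[[key]] <- data.frame(
      from = d$from, to = d$to, n_dwells = d$n,
      n_components = nc, A1 = f$A1, k1 = f$k1, A2 = f$A2, k2 = f$k2,
      k_av = k_av, w_rel = w_rel, k_trans = w_rel * k_av,
      sd_k_av = if (!is.null(boot)) unname(boot$sd["k_av"]) else NA_real_,
      sd3_k_trans = if (!is.null(boot)) 3 * w_rel * unname(boot$sd["k_av"]) else NA_real_,
      dk_av_paper = if (!is.null(err)) err$dk_av else NA_real_,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  if (!is.null(out)) rownames(out) <- NULL
  out
}

#' Compare a run report against reference state levels and rates
#'
#' Computes absolute and SD-scaled deviations of the recovered levels and
#' transition rates from a reference table and flags rows outside
#' tolerance.  Key mismatches are listed, not fatal.
#'
#' State levels are flagged outside one reference SD (the reporting
#' convention for the cluster levels); rates outside three bootstrap
#' SDs.  A \code{tol_sd} column in the reference overrides either.
#'
#' @param report a \code{run_report}
#' @param reference data frame with columns type ("level" or "rate"),
#'   key (state name or "from->to" pair), value, optionally sd and
#'   tol_sd
#' @param tol_abs relative flag threshold used when sd is absent
#' @return data frame of deviations with a \code{pass} column
#' @export
compare_to_reference <- function(report, reference, tol_abs = 0.25) {
  rows <- list(); missing <- character(0)
  for (i in seq_len(nrow(reference))) {
    type <- reference$type[i]; key <- reference$key[i]
    got <- NA_real_
    if (type == "level") {
      j <- match(key, report$state_names)
      if (!is.na(j)) got <- report$levels[j]
    } else if (type == "rate" && !is.null(report$kinetics)) {
      pq <- strsplit(key, "->", fixed = TRUE)[[1]]
      j <- which(report$state_names[report$kinetics$from] == pq[1] &
                 report$state_names[report$kinetics$to] == pq[2])
      if (length(j) == 1) got <- report$kinetics$k_trans[j]
    }
    if (is.na(got)) { missing <- c(missing, key); next }
    ref <- reference$value[i]
    sd <- if ("sd" %in% names(reference)) reference$sd[i] else NA_real_
    tol_sd <- if ("tol_sd" %in% names(reference)) reference$tol_sd[i]
              else if (type == "level") 1 else 3
    dev <- got - ref
    dev_sd <- if (is.finite(sd) && sd > 0) dev / sd else NA_real_
    pass <- if (is.finite(dev_sd)) abs(dev_sd) <= tol_sd
            else abs(dev) <= tol_abs * abs(ref)
    rows[[length(rows) + 1]] <- data.frame(
      type = type, key = key, reference = ref, observed = got,
      deviation = dev, deviation_sd = dev_sd, pass = pass,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  if (length(missing)) attr(out, "missing_keys") <- missing
  out
}

#' @export
print.run_report <- function(x, ...) {
  cat(sprintf("Pipeline run (%s preset): K_opt = %d\n",
              x$config$preset, x$K_opt))
  cat("  levels:",
      paste(sprintf("%s=%.3f(%.3f)", x$state_names, x$levels, x$level_sd),
            collapse = " "), "\n")
  if (!is.null(x$kinetics)) {
    cat("  rates (k_trans, 1/s):\n")
    k <- x$kinetics
    for (i in seq_len(nrow(k)))
      cat(sprintf("    %s->%s  %.3f (n=%d)\n", x$state_names[k$from[i]],
                  x$state_names[k$to[i]], k$k_trans[i], k$n_dwells[i]))
  }
  invisible(x)
}
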