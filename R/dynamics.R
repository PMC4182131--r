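#' Starvation/restoration protocol
#'
#' External glucose is dropped from `glucose_high` to `glucose_low` at
#' `t_drop`, restored at `t_restore`, and the outcome is evaluated at
#' `t_eval` (all minutes).
#'
#' @param glucose_high mM (default 20)
#' @param glucose_low mM (default 0.1)
#' @param t_drop min (default 1)
#' @param t_restore min (default 10)
#' @param t_eval min (default 100)
#' @export
starvation_protocol <- function(glucose_high = 20, glucose_low = 0.1,
                                t_drop = 1, t_restore = 10, t_eval = 100) {
  stopifnot(0 < t_drop, t_drop < t_restore, t_restore < t_eval,
            glucose_low <= glucose_high)
  structure(list(glucose_high = glucose_high, glucose_low = glucose_low,
                 t_drop = t_drop, t_restore = t_restore, t_eval = t_eval),
            class = "starvation_protocol")
}

default_solver <- function() list(rtol = 1e-8, atol = 1e-9, maxsteps = 400000L)

# integrate one segment with constant fixed-species concentrations
integrate_segment <- function(model, par, y0, c_template, t0, t1, outtimes,
                              solver, relax_ftol = 0) {
  .ode_integrate(model$ptr, as.numeric(par), as.numeric(y0),
                 as.numeric(c_template), t0, t1, as.numeric(outtimes),
                 solver$rtol, solver$atol, hmax = max(t1 - t0, 1e-6),
                 maxsteps = solver$maxsteps, relax_ftol = relax_ftol)
}

#' Integrate the kinetic ODEs under a time-dependent glucose protocol
#'
#' Fixed species are protocol parameters; at each event time the clamped
#' value switches discontinuously and the stiff solver is restarted.
#'
#' @param model compiled model ([compile_model()])
#' @param par parameter vector of a state-consistent instance
#' @param state metabolic state providing initial (and fixed) concentrations
#' @param events data.frame(time, species, value) of clamp switches, or NULL
#' @param t_end end time (min)
#' @param times output grid (min); defaults to 200 points
#' @param solver list(rtol, atol, maxsteps)
#' @return object of class `trajectory`: `time`, concentration matrix
#'   (time x dynamic species), flux matrix, `status`
#' @export
integrate_timecourse <- function(model, par, state, events = NULL,
                                 t_end = 100, times = NULL,
                                 solver = default_solver()) {
  c_template <- full_conc(model, state)
  dyn <- which(!model$fixed)
  y <- c_template[dyn]
  if (is.null(times)) times <- seq(0, t_end, length.out = 200L)
  times <- sort(unique(c(times, t_end)))
  ev_times <- numeric(0)
  if (!is.null(events) && nrow(events)) {
    events <- events[order(events$time), , drop = FALSE]
    ev_times <- unique(events$time)
  }
  bounds <- sort(unique(c(0, ev_times, t_end)))
  out <- matrix(NA_real_, length(times), length(dyn),
                dimnames = list(NULL, model$met_ids[dyn]))
  if (any(times == 0)) out[times == 0, ] <- rep(y, each = sum(times == 0))
  status <- 0L
  for (k in seq_len(length(bounds) - 1L)) {
    t0 <- bounds[k]; t1 <- bounds[k + 1L]
    if (!is.null(events)) {
      for (i in which(events$time == t0)) {
        idx <- match(events$species[i], model$met_ids)
        if (is.na(idx) || !model$fixed[idx])
          stopf("event species '%s' is not a fixed species", events$species[i])
        c_template[idx] <- events$value[i]
      }
    }
    seg_out <- times[times > t0 & times <= t1]
    res <- integrate_segment(model, par, y, c_template, t0, t1, seg_out, solver)
    status <- max(status, res$status)
    if (length(seg_out))
      out[match(seg_out, times), ] <- t(res$states)
    y <- res$y
    if (status != 0L) break
  }
  conc <- out
  flux <- matrix(NA_real_, length(times), length(model$rxn_ids),
                 dimnames = list(NULL, model$rxn_ids))
  ctmp <- full_conc(model, state)
  if (status == 0L) {
    for (i in seq_along(times)) {
      ct <- ctmp
      # fixed values as of that time
      if (!is.null(events) && nrow(events)) {
        past <- events[events$time <= times[i], , drop = FALSE]
        if (nrow(past))
          ct[match(past$species, model$met_ids)] <- past$value
      }
      ct[dyn] <- conc[i, ]
      flux[i, ] <- model_rates(model, ct, par)
    }
  }
  structure(list(time = times, concentrations = conc, fluxes = flux,
                 status = status,
                 failed = status != 0L),
            class = "trajectory")
}

glucose_events <- function(protocol, species = "GLCx") {
  data.frame(time = c(protocol$t_drop, protocol$t_restore),
             species = species,
             value = c(protocol$glucose_low, protocol$glucose_high),
             stringsAsFactors = FALSE)
}

#' Classify recovery after a starvation protocol
#'
#' An instance has recovered when the relative L2 distance of the dynamic
#' concentration vector at `t_eval` to the reference state is at most
#' `tolerance` (default 0.05). The ATP-only relative distance is reported
#' alongside. NaN trajectories yield a `numerical_failure` outcome.
#'
#' @param trajectory a `trajectory` reaching `t_eval`
#' @param reference the reference [metabolic_state()]
#' @param network the network (for species ordering)
#' @param tolerance relative L2 tolerance
#' @param atp_id metabolite id of ATP (for trace summaries); NA to skip
#' @param starvation_window c(t_drop, t_restore) for the starvation-phase
#'   ATP mean, or NULL
#' @return object of class `recovery_outcome`
#' @export
classify_recovery <- function(trajectory, reference, network,
                              tolerance = 0.05, atp_id = "ATP",
                              starvation_window = NULL) {
  sp <- colnames(trajectory$concentrations)
  cref <- reference$concentrations[sp]
  last <- nrow(trajectory$concentrations)
  cend <- trajectory$concentrations[last, ]
  if (trajectory$failed || any(!is.finite(cend)))
    return(structure(list(recovered = FALSE, numerical_failure = TRUE,
                          collapsed = NA, distance = NA_real_,
                          atp_final = NA_real_, atp_distance = NA_real_,
                          atp_starvation_mean = NA_real_),
                     class = "recovery_outcome"))
  dist <- sqrt(sum((cend - cref)^2)) / sqrt(sum(cref^2))
  atp_final <- if (!is.na(atp_id) && atp_id %in% sp) cend[[atp_id]] else NA_real_
  atp_dist <- if (!is.na(atp_id) && atp_id %in% sp)
    abs(atp_final - cref[[atp_id]]) / cref[[atp_id]] else NA_real_
  atp_mean <- NA_real_
  if (!is.null(starvation_window) && !is.na(atp_id) && atp_id %in% sp) {
    sel <- trajectory$time >= starvation_window[1] &
      trajectory$time <= starvation_window[2]
    if (any(sel)) atp_mean <- mean(trajectory$concentrations[sel, atp_id])
  }
  cref_atp <- if (!is.na(atp_id) && atp_id %in% sp) cref[[atp_id]] else NA_real_
  structure(list(recovered = dist <= tolerance, numerical_failure = FALSE,
                 collapsed = is.finite(atp_final) && is.finite(cref_atp) &&
                   atp_final < 0.5 * cref_atp,
                 distance = dist, atp_final = atp_final,
                 atp_distance = atp_dist, atp_starvation_mean = atp_mean),
            class = "recovery_outcome")
}

#' Starvation experiment over a sampled ensemble
#'
#' Samples `config$n_samples` state-consistent instances, keeps the stable
#' ones, runs the starvation protocol on each and classifies recovery.
#' Numerical failures form their own category and are excluded from the
#' recovery denominator.
#'
#' @param network the network (regulation scenario already applied or
#'   selected via `config$include_regulation`)
#' @param state the metabolic state
#' @param config a [sampling_config()]
#' @param protocol a [starvation_protocol()]
#' @param glucose_id id of the clamped external glucose species
#' @param tolerance recovery tolerance (relative L2)
#' @param solver solver settings
#' @param keep_trajectories store full trajectories (memory-heavy)
#' @return object of class `starvation_result` with outcomes, counts and the
#'   recovered fraction (relative to stable, non-failed instances) with
#'   binomial CI
#' @export
run_starvation_experiment <- function(network, state, config,
                                      protocol = starvation_protocol(),
                                      glucose_id = "GLCx", tolerance = 0.05,
                                      solver = default_solver(),
                                      keep_trajectories = FALSE,
                                      times = NULL) {
  network <- strip_regulations(network, config$include_regulation)
  model <- compile_model(network)
  cons <- find_conservation_relations(network)
  events <- glucose_events(protocol, glucose_id)
  if (is.null(times))
    times <- sort(unique(c(seq(0, protocol$t_eval, length.out = 121L),
                           protocol$t_drop, protocol$t_restore)))
  n <- config$n_samples
  outcomes <- vector("list", n)
  trajs <- if (keep_trajectories) vector("list", n) else NULL
  counts <- c(sampled = n, rejected_sign = 0L, unstable = 0L,
              numerical_failure = 0L, evaluated = 0L)
  with_seed(derive_seed(config$seed, "starvation"), {
    seeds <- sample.int(2^31 - 2, n)
  })
  for (i in seq_len(n)) {
    ps <- with_seed(seeds[i], sample_parameter_set(model, state, config))
    if (ps$rejected) { counts["rejected_sign"] <- counts["rejected_sign"] + 1L; next }
    el <- compute_elasticities(model, state, ps$values)
    jr <- assemble_jacobian(cons, el$unscaled)
    if (!jr$stable) { counts["unstable"] <- counts["unstable"] + 1L; next }
    tr <- integrate_timecourse(model, ps$values, state, events,
                               t_end = protocol$t_eval, times = times,
                               solver = solver)
    oc <- classify_recovery(tr, state, network, tolerance,
                            starvation_window = c(protocol$t_drop,
                                                  protocol$t_restore))
    if (oc$numerical_failure) {
      counts["numerical_failure"] <- counts["numerical_failure"] + 1L
    } else {
      counts["evaluated"] <- counts["evaluated"] + 1L
    }
    outcomes[[i]] <- oc
    if (keep_trajectories) trajs[[i]] <- tr
  }
  done <- !vapply(outcomes, is.null, TRUE)
  oc <- outcomes[done]
  rec <- vapply(oc, function(o) isTRUE(o$recovered), TRUE)
  fail <- vapply(oc, function(o) isTRUE(o$numerical_failure), TRUE)
  n_eval <- sum(!fail)
  frac <- if (n_eval > 0) sum(rec) / n_eval else NA_real_
  structure(list(outcomes = oc, counts = counts,
                 recovered_fraction = frac,
                 recovered_se = binom_se(frac, n_eval),
                 atp_final = vapply(oc, function(o) o$atp_final %||% NA_real_, 0),
                 trajectories = if (keep_trajectories) trajs[done] else NULL,
                 instance_seeds = seeds,
                 protocol = protocol, config = config),
            class = "starvation_result")
}

#' @export
print.starvation_result <- function(x, ...) {
  cat(sprintf("<starvation_result: %d sampled, %d evaluated, recovered %.1f%% +/- %.1f%% (%d failures)>\n",
              x$counts[["sampled"]], x$counts[["evaluated"]],
              100 * x$recovered_fraction, 100 * x$recovered_se,
              x$counts[["numerical_failure"]]))
  invisible(x)
}

#' Recovery fraction as a function of starvation and recovery durations
#'
#' @inheritParams run_starvation_experiment
#' @param starvation_durations vector of starvation lengths (min)
#' @param recovery_durations vector of recovery lengths (min)
#' @return matrix of recovered fractions (starvation x recovery durations)
#' @export
recovery_surface <- function(network, state, config,
                             starvation_durations, recovery_durations,
                             glucose_high = 20, glucose_low = 0.1,
                             tolerance = 0.05, solver = default_solver()) {
  stopifnot(length(starvation_durations) > 0, length(recovery_durations) > 0)
  out <- matrix(NA_real_, length(starvation_durations),
                length(recovery_durations),
                dimnames = list(paste0("starve_", starvation_durations),
                                paste0("recover_", recovery_durations)))
  for (a in seq_along(starvation_durations)) {
    for (b in seq_along(recovery_durations)) {
      pr <- starvation_protocol(glucose_high, glucose_low, t_drop = 1,
                                t_restore = 1 + starvation_durations[a],
                                t_eval = 1 + starvation_durations[a] +
                                  recovery_durations[b])
      res <- run_starvation_experiment(network, state, config, pr,
                                       tolerance = tolerance, solver = solver)
      out[a, b] <- res$recovered_fraction
    }
  }
  out
}

#' Quasi-static glucose sweep: bistability and hysteresis detection
#'
#' External glucose is lowered along a logarithmic ladder from
#' `glucose_high` to `glucose_low` and raised back; at each rung the system
#' relaxes (integration until `||dc/dt||_inf < ftol` or `t_relax`). Sampled
#' instances may settle on a limit cycle rather than a fixed point
#' (glycolytic oscillations); such rungs are classified by the ATP average
#' over a trailing window of several cycle periods instead of an endpoint,
#' and flagged `oscillatory`. The instance is bistable when the down and up
#' branches disagree in (averaged) ATP by more than `branch_tol` (relative)
#' at any shared rung; a rung is indeterminate only on integration failure.
#'
#' @param model compiled model
#' @param par instance parameter vector
#' @param state reference state (starting point, fixed species)
#' @param n_rungs rungs per direction (default 30)
#' @param glucose_high,glucose_low ladder endpoints (mM)
#' @param t_relax relaxation horizon per rung (min)
#' @param t_avg trailing averaging window for oscillatory rungs (min)
#' @param ftol steady-state tolerance on `||dc/dt||_inf` (mM/min)
#' @param branch_tol relative ATP gap defining disagreement (default 0.01)
#' @param glucose_id,atp_id species ids
#' @param solver solver settings
#' @return object of class `hysteresis_scan`
#' @export
hysteresis_scan <- function(model, par, state, n_rungs = 30,
                            glucose_high = 20, glucose_low = 0.1,
                            t_relax = 60, t_avg = 20, ftol = 1e-4,
                            branch_tol = 0.01,
                            glucose_id = "GLCx", atp_id = "ATP",
                            solver = default_solver()) {
  ladder_down <- 10 ^ seq(log10(glucose_high), log10(glucose_low),
                          length.out = n_rungs)
  ladder_up <- rev(ladder_down)
  c_template <- full_conc(model, state)
  gi <- match(glucose_id, model$met_ids)
  dyn <- which(!model$fixed)
  ai <- match(atp_id, model$met_ids[dyn])
  relax_at <- function(y, glc) {
    ct <- c_template
    ct[gi] <- glc
    res <- integrate_segment(model, par, y, ct, 0, t_relax, numeric(0),
                             solver, relax_ftol = ftol)
    if (res$status != 0L)
      return(list(y = res$y, atp = NA_real_, ok = FALSE, oscillatory = FALSE))
    if (isTRUE(res$relaxed))
      return(list(y = res$y, atp = res$y[ai], lo = res$y[ai], hi = res$y[ai],
                  ok = TRUE, oscillatory = FALSE))
    # no fixed point reached: characterize the attractor (limit cycle) by
    # the mean and envelope of ATP over a trailing window
    tt <- seq(0, t_avg, length.out = 151L)[-1]
    r2 <- integrate_segment(model, par, res$y, ct, 0, t_avg, tt, solver)
    if (r2$status != 0L)
      return(list(y = r2$y, atp = NA_real_, lo = NA_real_, hi = NA_real_,
                  ok = FALSE, oscillatory = TRUE))
    trace <- r2$states[ai, ]
    list(y = r2$y, atp = mean(trace), lo = min(trace), hi = max(trace),
         ok = TRUE, oscillatory = TRUE)
  }
  y <- c_template[dyn]
  run_branch <- function(y, ladder) {
    atp <- lo <- hi <- numeric(length(ladder))
    ok <- osc <- logical(length(ladder))
    states <- matrix(NA_real_, length(ladder), length(dyn))
    for (k in seq_along(ladder)) {
      r <- relax_at(y, ladder[k])
      y <- r$y
      states[k, ] <- y
      atp[k] <- r$atp
      lo[k] <- r$lo
      hi[k] <- r$hi
      ok[k] <- r$ok
      osc[k] <- r$oscillatory
    }
    list(states = states, atp = atp, lo = lo, hi = hi, ok = ok,
         oscillatory = osc, y = y)
  }
  down <- run_branch(y, ladder_down)
  up <- run_branch(down$y, ladder_up)
  indeterminate <- !all(down$ok) || !all(up$ok)
  atp_down <- down$atp
  atp_up <- rev(up$atp)               # align to ladder_down ordering
  both_ok <- down$ok & rev(up$ok)
  gap <- abs(atp_down - atp_up) / pmax(abs(atp_down), 1e-9)
  gap[!both_ok] <- NA_real_           # only compare classified rung pairs
  # a rung disagrees only when the two attractors are distinct: the ATP
  # envelopes must be disjoint and the mean gap must clear both the
  # relative tolerance and an absolute floor (cycle-average noise guard)
  disjoint <- (down$lo > rev(up$hi)) | (rev(up$lo) > down$hi)
  sig <- disjoint & abs(atp_down - atp_up) >
    pmax(branch_tol * abs(atp_down), 0.05)
  sig[!both_ok] <- NA
  bistable <- any(sig, na.rm = TRUE)
  structure(list(ladder = ladder_down, atp_down = atp_down, atp_up = atp_up,
                 branch_gap = if (all(is.na(gap))) NA_real_ else
                   max(gap, na.rm = TRUE),
                 bistable = bistable,
                 indeterminate = indeterminate,
                 oscillatory = any(down$oscillatory) || any(up$oscillatory),
                 down_states = down$states, up_states = up$states),
            class = "hysteresis_scan")
}

#' @export
print.hysteresis_scan <- function(x, ...) {
  cat(sprintf("<hysteresis_scan: %s (max relative ATP branch gap %.3g%s)>\n",
              if (x$bistable) "bistable" else "monostable",
              x$branch_gap,
              if (x$indeterminate) ", INDETERMINATE rungs present" else ""))
  invisible(x)
}
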