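#' Reduced Jacobian and linear stability of a sampled instance
#'
#' Assembles the Jacobian on independent species, `J = N_R E L`, where `E`
#' holds the unscaled elasticities over dynamic species and `L`/`N_R` come
#' from the conservation analysis. An instance is stable when every
#' eigenvalue has real part below `-tol_eig`.
#'
#' @param conservation a `conservation_analysis` from
#'   [find_conservation_relations()]
#' @param elasticities unscaled elasticity matrix (reactions x species;
#'   extra columns for fixed species are ignored)
#' @param tol_eig stability margin; eigenvalues with real part in
#'   `[-tol_eig, 0]` count as unstable (reported via `marginal`)
#' @return object of class `jacobian_result`
#' @export
assemble_jacobian <- function(conservation, elasticities, tol_eig = 1e-9) {
  N_R <- conservation$reduced_stoichiometry
  L <- conservation$link_matrix
  dyn <- rownames(L)
  if (!all(dyn %in% colnames(elasticities)))
    stopf("elasticity matrix lacks columns for dynamic species")
  E <- elasticities[, dyn, drop = FALSE]
  J <- N_R %*% E %*% L
  ev <- eigen(J, only.values = TRUE)$values
  mx <- max(Re(ev))
  structure(list(jacobian = J, eigenvalues = ev, max_real_part = mx,
                 stable = mx < -tol_eig,
                 marginal = mx >= -tol_eig && mx <= 0),
            class = "jacobian_result")
}

#' Scaled flux and concentration control coefficients
#'
#' Implements the standard MCA matrix expressions: with unscaled
#' elasticities E, link matrix L and reduced stoichiometry N_R, the unscaled
#' concentration control matrix is \eqn{C^S = -L (N_R E L)^{-1} N_R} and the
#' unscaled flux control matrix \eqn{C^J = I + E C^S}. Scaling by the state
#' (`diag(J0)`, `diag(c0)`) yields coefficients obeying both summation
#' theorems: flux rows sum to 1, concentration rows to 0. Enzyme modulation
#' is proportional Vmax modulation, which for these rate laws equals a
#' proportional enzyme-level change.
#'
#' @param conservation conservation analysis of the network
#' @param elasticities unscaled elasticity matrix at the state
#' @param state the metabolic state (provides J0, c0)
#' @param network the network (orderings)
#' @return list(cj, cs) of scaled control matrices (flux x enzyme and
#'   species x enzyme)
#' @export
control_coefficients <- function(conservation, elasticities, state, network) {
  al <- align_state(network, state)
  dyn <- rownames(conservation$link_matrix)
  E <- elasticities[, dyn, drop = FALSE]
  N_R <- conservation$reduced_stoichiometry
  L <- conservation$link_matrix
  M <- N_R %*% E %*% L
  Minv <- tryCatch(solve(M), error = function(e) NULL)
  if (is.null(Minv)) stopf("reduced Jacobian is singular; instance skipped")
  CS <- -L %*% Minv %*% N_R
  CJ <- diag(nrow(E)) + E %*% CS
  J0 <- al$flux
  c0 <- al$conc[dyn]
  cj <- sweep(sweep(CJ, 1, J0, "/"), 2, J0, "*")
  cs <- sweep(sweep(CS, 1, c0, "/"), 2, J0, "*")
  dimnames(cj) <- list(rxn_ids(network), rxn_ids(network))
  dimnames(cs) <- list(dyn, rxn_ids(network))
  list(cj = cj, cs = cs)
}

#' Monte-Carlo ensemble of control coefficients
#'
#' Repeats state-consistent parameter sampling `config$n_samples` times;
#' for every stable instance the scaled control matrices are stored.
#' Sign-blocked rescaling rejections and unstable instances are counted,
#' never silently dropped.
#'
#' @param network a [metabolic_network()] (regulations already selected;
#'   see [strip_regulations()])
#' @param state the metabolic state
#' @param config a [sampling_config()]
#' @param keep_matrices store per-instance control matrices (set FALSE to
#'   save memory when only stability is of interest)
#' @return object of class `control_ensemble`
#' @export
sample_control_ensemble <- function(network, state, config,
                                    keep_matrices = TRUE) {
  network <- strip_regulations(network, config$include_regulation)
  model <- compile_model(network)
  cons <- find_conservation_relations(network)
  n <- config$n_samples
  counts <- c(sampled = n, rejected_sign = 0L, unstable = 0L, analyzed = 0L)
  cj <- if (keep_matrices) vector("list", n) else NULL
  cs <- if (keep_matrices) vector("list", n) else NULL
  stable <- logical(n)
  max_re <- numeric(n)
  with_seed(derive_seed(config$seed, "control"), {
    for (i in seq_len(n)) {
      ps <- sample_parameter_set(model, state, config)
      if (ps$rejected) {
        counts["rejected_sign"] <- counts["rejected_sign"] + 1L
        stable[i] <- NA
        max_re[i] <- NA
        next
      }
      el <- compute_elasticities(model, state, ps$values)
      jr <- assemble_jacobian(cons, el$unscaled)
      stable[i] <- jr$stable
      max_re[i] <- jr$max_real_part
      if (!jr$stable) {
        counts["unstable"] <- counts["unstable"] + 1L
        next
      }
      counts["analyzed"] <- counts["analyzed"] + 1L
      if (keep_matrices) {
        cc <- control_coefficients(cons, el$unscaled, state, network)
        cj[[i]] <- cc$cj
        cs[[i]] <- cc$cs
      }
    }
  })
  ok <- which(stable %in% TRUE)
  structure(list(network = network, state = state, config = config,
                 counts = counts, stable = stable, max_real_part = max_re,
                 cj = if (keep_matrices) cj[ok] else NULL,
                 cs = if (keep_matrices) cs[ok] else NULL,
                 conservation = cons),
            class = "control_ensemble")
}

#' @export
print.control_ensemble <- function(x, ...) {
  sf <- stability_filter(x)
  cat(sprintf("<control_ensemble: %d sampled, %d stable (%.1f%% +/- %.1f%%), %d sign-rejected>\n",
              x$counts[["sampled"]], sum(x$stable %in% TRUE),
              100 * sf$fraction, 100 * sf$se, x$counts[["rejected_sign"]]))
  invisible(x)
}

#' Stability filtering of an ensemble
#'
#' @param ensemble a `control_ensemble` (or logical vector of stability flags)
#' @return list(fraction, se, n_retained, n_tested); the fraction is over
#'   non-rejected instances and reported with its binomial standard error
#' @export
stability_filter <- function(ensemble) {
  stable <- if (inherits(ensemble, "control_ensemble")) ensemble$stable else ensemble
  tested <- sum(!is.na(stable))
  if (tested < 1) stopf("stability_filter: no instances")
  frac <- sum(stable, na.rm = TRUE) / tested
  list(fraction = frac, se = binom_se(frac, tested),
       n_retained = sum(stable, na.rm = TRUE), n_tested = tested)
}

#' Ensemble summary: distributions and sign profile of control coefficients
#'
#' For every (flux, enzyme) pair the distribution over stable instances is
#' summarised by a 51-bin histogram on \[-1, 1\] with two overflow bins,
#' the median and standard deviation of the raw values, and the fraction of
#' positive coefficients (the probabilistic sign profile).
#'
#' @param ensemble a `control_ensemble` with stored matrices
#' @param min_instances warn below this number of stable instances
#' @return object of class `control_summary` with arrays `median`, `sd`,
#'   `frac_positive` (flux x enzyme) and `histograms`
#' @export
ensemble_control_profile <- function(ensemble, min_instances = 100L) {
  if (!length(ensemble$cj)) stopf("empty ensemble: no stable instances stored")
  if (length(ensemble$cj) < min_instances)
    warning(sprintf("only %d stable instances (recommended >= %d)",
                    length(ensemble$cj), min_instances))
  arr <- simplify2array(ensemble$cj) # flux x enzyme x instance
  med <- apply(arr, c(1, 2), median)
  sdv <- apply(arr, c(1, 2), sd)
  fpos <- apply(arr, c(1, 2), function(z) mean(z > 0))
  breaks <- c(-2, seq(-1, 1, length.out = 52), 2)  # 51 bins + 2 overflow
  hists <- apply(arr, c(1, 2), function(z) {
    h <- hist(pmax(pmin(z, 1.5), -1.5), breaks = breaks, plot = FALSE)$counts
    h / length(z)
  })
  structure(list(median = med, sd = sdv, frac_positive = fpos,
                 histograms = hists, breaks = breaks,
                 n_instances = length(ensemble$cj)),
            class = "control_summary")
}

#' Distribution width versus displacement from equilibrium
#'
#' Pairs, per reaction, the displacement from equilibrium \eqn{\rho} of the
#' state with the average standard deviation of the control-coefficient
#' column of that enzyme across the ensemble, and reports the Spearman rank
#' correlation between \eqn{1-\rho} and the width (reactions close to
#' equilibrium have narrow, zero-centred control distributions).
#'
#' @param ensemble a `control_ensemble` with stored matrices
#' @param thermo a `thermo_report` for the same network/state
#' @return list(table, rank_correlation, degenerate)
#' @export
width_vs_disequilibrium <- function(ensemble, thermo) {
  if (nrow(thermo) < 3) stopf("need at least 3 reactions")
  if (length(ensemble$cj) < 2)
    return(list(table = NULL, rank_correlation = NA_real_, degenerate = TRUE))
  arr <- simplify2array(ensemble$cj)
  width <- apply(arr, 2, function(col) mean(apply(col, 1, sd)))
  tab <- data.frame(reaction_id = colnames(ensemble$cj[[1]]),
                    rho = thermo$rho[match(colnames(ensemble$cj[[1]]),
                                           thermo$reaction_id)],
                    avg_sd = width, stringsAsFactors = FALSE)
  rc <- suppressWarnings(cor(1 - tab$rho, tab$avg_sd, method = "spearman"))
  list(table = tab, rank_correlation = rc, degenerate = FALSE)
}
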