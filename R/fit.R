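#' Sampler control parameters
#'
#' Controls the Metropolis sampler used for simulation, Monte Carlo
#' maximum-likelihood estimation and goodness of fit. Counts are in
#' proposed dyad toggles. Defaults left `NULL` are resolved against the
#' network size at run time: with `nd = n(n-1)/2` dyads, `burn_in`
#' defaults to `10 * nd` and `thinning` to `nd`, so successive samples are
#' separated by one full sweep's worth of proposals and mixing effort grows
#' with the dyad count.
#'
#' @param burn_in proposals discarded before the first sample.
#' @param thinning proposals between retained samples.
#' @param n_samples number of retained samples.
#' @param proposal `"single_toggle"` (flip one uniform dyad) or
#'   `"tie_swap"` (delete a uniform tie, add a uniform non-tie; preserves
#'   the edge count exactly, as required under fixed-density conditioning).
#' @param seed integer seed for the sampler's random stream.
#' @return an object of class `sampler_control`.
#' @export
sampler_control <- function(burn_in = NULL, thinning = NULL, n_samples = 1000L,
                            proposal = c("single_toggle", "tie_swap"),
                            seed = NULL) {
  proposal <- match.arg(proposal)
  for (v in c(burn_in, thinning, n_samples)) {
    if (!is.null(v) && v < 0) stop("sampler counts must be nonnegative")
  }
  if (n_samples < 1) stop("n_samples must be positive")
  structure(list(burn_in = burn_in, thinning = thinning,
                 n_samples = as.integer(n_samples), proposal = proposal,
                 seed = seed),
            class = "sampler_control")
}

resolve_control <- function(control, n) {
  nd <- n * (n - 1) / 2
  control$burn_in <- control$burn_in %||% (10 * nd)
  control$thinning <- control$thinning %||% nd
  control
}

new_fit_result <- function(spec, theta, se, conv_t, method, seed,
                           n_simulations, estimable = NULL, converged = TRUE) {
  labels <- vapply(spec$terms, term_label, character(1))
  names(theta) <- names(se) <- labels
  if (!is.null(conv_t)) names(conv_t) <- labels
  estimable <- estimable %||% rep(TRUE, length(theta))
  significant <- ifelse(estimable, abs(theta) >= 2 * se, NA)
  structure(list(theta = theta, standard_errors = se,
                 convergence_t = conv_t, significant = significant,
                 method = method, spec = spec, seed = seed,
                 n_simulations = n_simulations, estimable = estimable,
                 converged = converged),
            class = "ergm_fit")
}

#' Maximum pseudo-likelihood estimation
#'
#' Fits the model by logistic regression of each dyad's state on its change
#' statistics, maximizing
#' `sum_{i<j} (x_ij * eta_ij - log(1 + exp(eta_ij)))` with
#' `eta_ij = theta . delta_ij`. The MPLE coincides with the maximum
#' likelihood estimate when the model's dyads are independent (edge,
#' activity, match/mismatch and dyadic-covariate terms only) and otherwise
#' serves as an initializer for [mcmcmle_fit()]. Standard errors come from
#' the curvature of the pseudo-likelihood and understate uncertainty for
#' dyad-dependent models.
#'
#' @param spec a [model_spec()].
#' @param net the observed binary `shared_patient_network`.
#' @param roster the matching `physician_roster`.
#' @param covs named list of dyadic covariate matrices.
#' @return an `ergm_fit`. Terms whose change statistics separate the tie
#'   variable perfectly are flagged non-estimable (with a warning) rather
#'   than silently diverging.
#' @export
mple_fit <- function(spec, net, roster, covs = NULL) {
  stopifnot(inherits(spec, "model_spec"),
            inherits(net, "shared_patient_network"))
  roster <- align_roster(net, roster)
  enc <- encode_terms(spec$terms, roster, covs, nrow(net$adjacency))
  des <- cpp_mple_design(net$adjacency, enc$code, enc$lambda, enc$avec,
                         enc$cmat, enc$role)
  df <- as.data.frame(des$X)
  names(df) <- paste0("t", seq_along(spec$terms))
  df$y <- des$y
  fml <- stats::as.formula(paste("y ~ 0 +",
                                 paste(names(df)[seq_along(spec$terms)],
                                       collapse = " + ")))
  fit <- suppressWarnings(glm(fml, family = binomial(), data = df))
  theta <- unname(coef(fit))
  se <- unname(sqrt(diag(vcov(fit))))
  # perfect separation shows up as runaway coefficients / curvature collapse
  estimable <- is.finite(theta) & is.finite(se) & abs(theta) < 15 & se < 50
  if (any(!estimable)) {
    bad <- vapply(spec$terms[!estimable], term_label, character(1))
    warning("non-estimable term(s) under the pseudo-likelihood ",
            "(perfect separation): ", paste(bad, collapse = ", "))
  }
  new_fit_result(spec, theta, se, NULL, "MPLE", seed = NA_integer_,
                 n_simulations = 0L, estimable = estimable)
}

#' Simulate networks from an ERGM
#'
#' Runs the Metropolis sampler at fixed parameters and returns thinned
#' sampled networks together with their statistic vectors.
#'
#' @inheritParams mple_fit
#' @param theta numeric parameter vector, one entry per term.
#' @param control a [sampler_control()].
#' @param start starting `shared_patient_network`; defaults to the empty
#'   graph over the roster for single-toggle proposals. Tie-swap chains
#'   require an explicit start that is neither empty nor complete (its edge
#'   count is preserved exactly).
#' @param return_networks set `FALSE` to skip materialising the sampled
#'   adjacency matrices (the statistics matrix is always returned).
#' @return a list of `shared_patient_network` objects (empty when
#'   `return_networks = FALSE`) with attributes `statistics` (matrix of
#'   sampled statistic vectors) and `acceptance_rate`.
#' @export
sample_networks <- function(spec, theta, roster, covs = NULL,
                            control = sampler_control(), start = NULL,
                            return_networks = TRUE) {
  stopifnot(inherits(spec, "model_spec"))
  if (!all(is.finite(theta))) stop("theta must be finite")
  if (length(theta) != length(spec$terms)) {
    stop("theta must have one entry per term")
  }
  n <- nrow(roster)
  if (spec$conditioning == "fixed_density") control$proposal <- "tie_swap"
  if (is.null(start)) {
    if (control$proposal == "tie_swap") {
      stop("tie_swap chains need an explicit start network")
    }
    start <- shared_patient_network(matrix(0L, n, n), "combined",
                                    roster$physician_id)
  }
  roster <- align_roster(start, roster)
  control <- resolve_control(control, n)
  if (!is.null(control$seed)) set.seed(control$seed)
  enc <- encode_terms(spec$terms, roster, covs, n)
  z0 <- statistics_vector(spec, start, roster, covs)
  res <- cpp_sample_ergm(start$adjacency, z0, theta, enc$code, enc$lambda,
                         enc$avec, enc$cmat, enc$role,
                         control$burn_in, control$thinning,
                         control$n_samples,
                         if (control$proposal == "tie_swap") 1L else 0L,
                         collect_nets = return_networks)
  nets <- list()
  if (return_networks) {
    nets <- lapply(res$nets, function(A) {
      shared_patient_network(A, start$channel, start$ids)
    })
  }
  stats <- res$stats
  colnames(stats) <- vapply(spec$terms, term_label, character(1))
  attr(nets, "statistics") <- stats
  attr(nets, "acceptance_rate") <- res$acc_rate
  nets
}

# Advance a chain by `steps` proposals; returns updated adjacency and z.
advance_chain <- function(A, z, theta, enc, steps, proposal) {
  res <- cpp_sample_ergm(A, z, theta, enc$code, enc$lambda, enc$avec,
                         enc$cmat, enc$role, steps, 0, 1L, proposal,
                         collect_nets = FALSE)
  list(A = res$final, z = drop(res$stats), edges = res$edges)
}

ridge_solve <- function(M) {
  p <- nrow(M)
  r <- tryCatch(rcond(M), error = function(e) 0)
  if (!is.finite(r) || r < 1e-10) {
    warning("statistic covariance is ill-conditioned; ridge regularization applied")
    M <- M + diag(1e-6 * max(mean(diag(M)), 1), p)
  }
  solve(M)
}

#' Monte Carlo maximum-likelihood estimation (Robbins-Monro)
#'
#' Solves the likelihood equation `E_theta z(Y) = z_obs` by stochastic
#' approximation in three phases: (1) a pilot simulation at the initial
#' parameters estimates the statistic covariance `D`; (2) Robbins-Monro
#' sub-phases iterate `theta <- theta - a_r D0^{-1} (z(Y_sim) - z_obs)`,
#' where `D0 = diag(D)` is the diagonal preconditioner (the usual
#' stochastic-approximation choice; the full inverse amplifies noise when
#' statistics are nearly collinear), with gain `a_r = gain0 / r` in
#' sub-phase `r` and sub-phase lengths doubling, each sub-phase ending with
#' Polyak averaging of its iterates; (3) a long
#' simulation at the final parameters yields per-term convergence t-ratios
#' `(mean_sim z_k - z_obs_k) / sd_sim z_k` and standard errors from the
#' inverse of the estimated statistic covariance (the Fisher information of
#' an exponential family). The fit is declared converged when every
#' `|t| <= t_tol`; otherwise phases 2-3 are repeated up to `max_rounds`
#' times, and a still-unconverged result is returned flagged, with a
#' warning.
#'
#' Under `fixed_density` conditioning all simulation uses tie-swap
#' proposals starting from the observed network, so every simulated network
#' has exactly the observed number of ties; the model must then exclude the
#' edge term, and initialization is at zero.
#'
#' @inheritParams mple_fit
#' @param control a [sampler_control()]; its `n_samples` sets the phase-1
#'   and phase-3 sample sizes.
#' @param init optional initial parameter vector; defaults to the MPLE
#'   (zeros under fixed-density conditioning or where the MPLE is
#'   non-estimable).
#' @param gain0 initial Robbins-Monro gain.
#' @param n_subphases number of sub-phases per round.
#' @param subphase_base iterations in the first sub-phase (doubling after).
#' @param t_tol convergence threshold on the per-term t-ratios.
#' @param max_rounds maximum estimation rounds before giving up.
#' @param max_step per-coordinate cap on a single Robbins-Monro update, a
#'   safeguard against overshooting into degeneracy.
#' @return an `ergm_fit` with convergence t-ratios and simulation-based
#'   standard errors.
#' @export
mcmcmle_fit <- function(spec, net, roster, covs = NULL,
                        control = sampler_control(), init = NULL,
                        gain0 = 0.1, n_subphases = 4L, subphase_base = 40L,
                        t_tol = 0.1, max_rounds = 4L, max_step = 0.5) {
  stopifnot(inherits(spec, "model_spec"),
            inherits(net, "shared_patient_network"))
  roster <- align_roster(net, roster)
  n <- nrow(net$adjacency)
  nd <- n * (n - 1) / 2
  p <- length(spec$terms)
  control <- resolve_control(control, n)
  if (!is.null(control$seed)) set.seed(control$seed)
  fixed <- spec$conditioning == "fixed_density"
  proposal <- if (fixed) 1L else if (control$proposal == "tie_swap") 1L else 0L
  m_obs <- sum(net$adjacency) / 2
  if (fixed && (m_obs == 0 || m_obs == nd)) {
    stop("fixed_density conditioning needs an observed network that is ",
         "neither empty nor complete")
  }

  if (is.null(init)) {
    if (fixed) {
      init <- numeric(p)
    } else {
      mp <- suppressWarnings(mple_fit(spec, net, roster, covs))
      init <- ifelse(mp$estimable, mp$theta, 0)
    }
  }
  theta <- as.numeric(init)
  enc <- encode_terms(spec$terms, roster, covs, n)
  z_obs <- unname(statistics_vector(spec, net, roster, covs))
  A <- net$adjacency
  z <- z_obs
  n_sim_total <- 0L

  simulate_phase <- function(theta, A, z, n_samples) {
    res <- cpp_sample_ergm(A, z, theta, enc$code, enc$lambda, enc$avec,
                           enc$cmat, enc$role, control$burn_in,
                           control$thinning, n_samples, proposal,
                           collect_nets = FALSE)
    res
  }

  # Phase 1: pilot covariance at the initial parameters.
  n1 <- max(50L, min(control$n_samples, 100L))
  pilot <- simulate_phase(theta, A, z, n1)
  n_sim_total <- n_sim_total + n1
  D <- var(pilot$stats)
  d_pre <- 1 / pmax(diag(D), 1e-8)
  A <- pilot$final
  z <- pilot$z_final

  converged <- FALSE
  t_ratio <- rep(NA_real_, p)
  se <- rep(NA_real_, p)
  degen_run <- 0L

  for (round in seq_len(max_rounds)) {
    # Phase 2: Robbins-Monro sub-phases.
    for (r in seq_len(n_subphases)) {
      a_r <- gain0 / r
      len <- subphase_base * 2^(r - 1)
      theta_sum <- numeric(p)
      for (it in seq_len(len)) {
        st <- advance_chain(A, z, theta, enc, control$thinning, proposal)
        A <- st$A; z <- st$z
        if (!fixed) {
          degen_run <- if (st$edges == 0L || st$edges == nd)
            degen_run + 1L else 0L
          if (degen_run >= 50L) {
            stop("degenerate simulation: sampled networks are persistently ",
                 if (st$edges == 0L) "empty" else "complete",
                 " at theta = (", paste(signif(theta, 3), collapse = ", "), ")")
          }
        }
        step <- a_r * d_pre * (z - z_obs)
        step <- pmin(pmax(step, -max_step), max_step)
        theta <- theta - step
        theta_sum <- theta_sum + theta
      }
      theta <- theta_sum / len  # Polyak average of the sub-phase
    }

    # Phase 3: convergence check and standard errors at the final theta.
    ph3 <- simulate_phase(theta, A, z, control$n_samples)
    n_sim_total <- n_sim_total + control$n_samples
    A <- ph3$final
    z <- ph3$z_final
    z_mean <- colMeans(ph3$stats)
    z_sd <- apply(ph3$stats, 2, sd)
    t_ratio <- ifelse(z_sd > 0, (z_mean - z_obs) / z_sd,
                      ifelse(z_mean == z_obs, 0, Inf))
    V <- var(ph3$stats)
    V_inv <- ridge_solve(V)
    se <- sqrt(pmax(diag(V_inv), 0))
    if (max(abs(t_ratio)) <= t_tol) {
      converged <- TRUE
      break
    }
    # refresh the preconditioner for the next round
    d_pre <- 1 / pmax(diag(V), 1e-8)
  }
  if (!converged) {
    warning("estimation did not reach |t| <= ", t_tol, " after ",
            max_rounds, " round(s); max |t| = ",
            signif(max(abs(t_ratio)), 3), ". Result flagged unconverged.")
  }
  new_fit_result(spec, theta, se, t_ratio, "MCMCMLE",
                 seed = control$seed %||% NA_integer_,
                 n_simulations = n_sim_total, converged = converged)
}

#' @export
print.ergm_fit <- function(x, ...) {
  cat(sprintf("ERGM fit (%s%s), %s\n", x$method,
              if (x$spec$conditioning == "fixed_density")
                ", fixed density" else "",
              if (isTRUE(x$converged)) "converged" else "NOT converged"))
  print(as.data.frame(x), digits = 4, row.names = FALSE)
  cat("* |estimate| >= 2 SE (significant at p <= 0.05, Wald convention)\n")
  invisible(x)
}

#' @export
as.data.frame.ergm_fit <- function(x, ...) {
  terms <- x$spec$terms
  data.frame(
    term = vapply(terms, function(t) t$name, character(1)),
    attribute = vapply(terms, function(t) t$attribute %||% "", character(1)),
    lambda = vapply(terms, function(t)
      if (t$name %in% ALT_TERMS) t$lambda else NA_real_, numeric(1)),
    estimate = unname(x$theta),
    SE = unname(x$standard_errors),
    t_ratio = if (is.null(x$convergence_t)) NA_real_ else
      unname(x$convergence_t),
    significant = ifelse(is.na(x$significant), "n.e.",
                         ifelse(x$significant, "*", "")),
    stringsAsFactors = FALSE)
}

#' Write a results table
#'
#' Mirrors the layout of published ERGM result tables: one row per term
#' with estimate, standard error, convergence t-ratio and a significance
#' star (`|estimate| >= 2 SE`).
#'
#' @param fit an `ergm_fit`.
#' @param path CSV output path.
#' @param channel optional channel label recorded in the table.
#' @return the results data frame, invisibly.
#' @export
write_fit_results <- function(fit, path, channel = NA_character_) {
  out <- as.data.frame(fit)
  out$channel <- channel
  write.csv(out, path, row.names = FALSE)
  invisible(out)
}
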