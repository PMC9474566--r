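#' Default auxiliary statistics for goodness of fit
#'
#' One entry per supported model configuration (attribute terms use the
#' GP role for activity and the medical specialty for match/mismatch; a
#' dyadic-covariate row is added for each supplied covariate), plus
#' structural summaries not tied to any single term: isolate count, total
#' triangle count, global clustering coefficient and the deciles of the
#' degree distribution.
#'
#' @param covs named list of dyadic covariate matrices (may be `NULL`).
#' @return named list of zero-argument statistic definitions used by
#'   [gof_report()]; term-based entries are [term_spec()] objects, the
#'   structural extras are functions of a network.
#' @keywords internal
default_auxiliary <- function(covs = NULL) {
  aux <- list(
    term_spec("edge"),
    term_spec("GGG_triad"), term_spec("GGS_triad"), term_spec("GSS_triad"),
    term_spec("GGG_chain"), term_spec("GGS_chain"), term_spec("SGS_chain"),
    term_spec("two_path"), term_spec("alt_two_paths"), term_spec("alt_stars"),
    term_spec("activity", attribute = "role"),
    term_spec("match", attribute = "specialty"),
    term_spec("mismatch", attribute = "specialty"))
  for (nm in names(covs %||% list())) {
    aux <- c(aux, list(term_spec("dyadic_cov", covariate = nm)))
  }
  aux
}

structural_stats <- function(net) {
  A <- net$adjacency
  deg <- rowSums(A)
  tri <- sum(diag(A %*% A %*% A)) / 6
  p2 <- sum(choose(deg, 2))
  c(isolates = sum(deg == 0),
    triangles = tri,
    clustering = if (p2 > 0) 3 * tri / p2 else 0,
    stats::setNames(as.numeric(quantile(deg, probs = seq(0.1, 0.9, 0.1),
                                        type = 1)),
                    paste0("degree_q", seq(10, 90, 10))))
}

#' Simulation-based goodness of fit
#'
#' Simulates networks at the fitted parameters (respecting the fit's
#' conditioning: fixed-density fits are re-simulated with tie-swap
#' proposals from the observed network, so every draw has the observed
#' number of ties) and compares auxiliary statistics of the simulations
#' with the observed network through t-ratios
#' `(observed - simulated mean) / simulated sd`. A row passes when
#' `|t| < 2`; a row with zero simulated spread but a discrepant observed
#' value is flagged degenerate and fails.
#'
#' @param fit a converged `ergm_fit` from [mcmcmle_fit()] (or [mple_fit()];
#'   pass `force = TRUE` to report on an unconverged fit).
#' @param net the observed binary `shared_patient_network` the model was
#'   fitted to.
#' @param roster the matching `physician_roster`.
#' @param covs named list of dyadic covariate matrices.
#' @param auxiliary list of [term_spec()] objects to use as auxiliary
#'   statistics; defaults to [default_auxiliary()] plus the structural
#'   summaries it documents.
#' @param control a [sampler_control()]; `n_samples` sets the number of
#'   GOF simulations (default 100).
#' @param force report even when the fit is flagged unconverged.
#' @return an object of class `gof_report`: a data frame with columns
#'   `statistic`, `observed`, `sim_mean`, `sim_sd`, `t_ratio`, `pass`,
#'   `degenerate`, with attributes `n_simulations` and `seed`.
#' @export
gof_report <- function(fit, net, roster, covs = NULL, auxiliary = NULL,
                       control = NULL, force = FALSE) {
  stopifnot(inherits(fit, "ergm_fit"),
            inherits(net, "shared_patient_network"))
  if (!isTRUE(fit$converged) && !force) {
    stop("fit is flagged unconverged; pass force = TRUE to report anyway")
  }
  roster <- align_roster(net, roster)
  n <- nrow(net$adjacency)
  control <- control %||% sampler_control(n_samples = 100L)
  control <- resolve_control(control, n)
  fixed <- fit$spec$conditioning == "fixed_density"
  if (fixed) control$proposal <- "tie_swap"
  if (!is.null(control$seed)) set.seed(control$seed)

  sims <- sample_networks(fit$spec, unname(fit$theta), roster, covs,
                          control = control, start = net,
                          return_networks = TRUE)

  aux_terms <- auxiliary %||% default_auxiliary(covs)
  term_names <- vapply(aux_terms, term_label, character(1))
  eval_aux <- function(network) {
    tvals <- vapply(aux_terms, global_statistic, numeric(1),
                    net = network, roster = roster, covs = covs)
    c(stats::setNames(tvals, term_names), structural_stats(network))
  }
  obs <- eval_aux(net)
  sim <- t(vapply(sims, eval_aux, numeric(length(obs))))

  mu <- colMeans(sim)
  s <- apply(sim, 2, sd)
  t_ratio <- ifelse(s > 0, (obs - mu) / s, ifelse(obs == mu, 0, NA_real_))
  degenerate <- s == 0 & obs != mu
  pass <- !degenerate & abs(ifelse(is.na(t_ratio), 0, t_ratio)) < 2
  out <- data.frame(statistic = names(obs), observed = unname(obs),
                    sim_mean = unname(mu), sim_sd = unname(s),
                    t_ratio = unname(t_ratio), pass = unname(pass),
                    degenerate = unname(degenerate),
                    stringsAsFactors = FALSE)
  attr(out, "n_simulations") <- control$n_samples
  attr(out, "seed") <- control$seed
  class(out) <- c("gof_report", "data.frame")
  out
}

#' @export
print.gof_report <- function(x, ...) {
  cat(sprintf("Goodness of fit (%d simulations): %d/%d statistics pass (|t| < 2)\n",
              attr(x, "n_simulations"), sum(x$pass), nrow(x)))
  df <- as.data.frame(x)
  df$flag <- ifelse(df$degenerate, "DEGENERATE", ifelse(df$pass, "", "FAIL"))
  print(df, digits = 3, row.names = FALSE)
  invisible(x)
}

#' Write a GOF report to CSV
#'
#' @param report a `gof_report`.
#' @param path CSV output path.
#' @return the report, invisibly.
#' @export
write_gof_report <- function(report, path) {
  write.csv(as.data.frame(report), path, row.names = FALSE)
  invisible(report)
}
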