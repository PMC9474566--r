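TERM_NAMES <- c("edge", "GGG_triad", "GGS_triad", "GSS_triad",
                "GGG_chain", "GGS_chain", "SGS_chain",
                "two_path", "alt_two_paths", "alt_stars",
                "activity", "match", "mismatch", "dyadic_cov")

ATTR_TERMS <- c("activity", "match", "mismatch")
ALT_TERMS <- c("alt_two_paths", "alt_stars")
ROLE_TERMS <- c("GGG_triad", "GGS_triad", "GSS_triad",
                "GGG_chain", "GGS_chain", "SGS_chain")

#' Declare a single ERGM term
#'
#' Supported configurations, all for undirected binary networks over the
#' GP/specialist role dichotomy (G = general practitioner, role 1; S =
#' medical specialist, role 0):
#'
#' * `edge` — number of ties.
#' * `GGG_triad`, `GGS_triad`, `GSS_triad` — closed triads (triangles) whose
#'   role multiset is \{G,G,G\}, \{G,G,S\}, \{G,S,S\}.
#' * `GGG_chain`, `GGS_chain`, `SGS_chain` — open triads: two-paths i--k--j
#'   with i,j not tied, whose center k is a GP and whose endpoint roles are
#'   \{G,G\}, \{G,S\}, \{S,S\} respectively.
#' * `two_path` — all center-based two-paths, `sum(choose(degree, 2))`
#'   (simple connectivity).
#' * `alt_two_paths` — geometrically weighted shared partners,
#'   `lambda * sum_{i<j} (1 - (1 - 1/lambda)^{L2_ij})` with `L2_ij` the
#'   number of common neighbours (multiple connectivity).
#' * `alt_stars` — alternating k-stars,
#'   `lambda^2 * sum_i ((1 - 1/lambda)^{d_i} - 1 + d_i/lambda)` (degree
#'   spread).
#' * `activity` — `sum_{i<j} x_ij (a_i + a_j)` for a binary roster
#'   attribute `a` (e.g. GP activity with `attribute = "role"`).
#' * `match` / `mismatch` — ties between actors with equal / unequal values
#'   of a categorical roster attribute (homophily / heterophily).
#' * `dyadic_cov` — `sum_{i<j} x_ij w_ij` for a symmetric dyadic covariate
#'   `w`, e.g. pairwise travel times in minutes.
#'
#' @param name term name, one of the above.
#' @param attribute roster column name; required for `activity`, `match`,
#'   `mismatch`, disallowed otherwise.
#' @param lambda damping constant of the alternating statistics (must
#'   exceed 1; default 2).
#' @param covariate for `dyadic_cov`: either the name of an entry in the
#'   `covs` list passed to downstream functions, or a matrix.
#' @return an object of class `term_spec`.
#' @export
term_spec <- function(name, attribute = NULL, lambda = 2, covariate = NULL) {
  name <- match.arg(name, TERM_NAMES)
  if (name %in% ATTR_TERMS) {
    if (is.null(attribute)) stop("term '", name, "' requires an attribute")
  } else if (!is.null(attribute)) {
    stop("term '", name, "' does not take an attribute")
  }
  if (name %in% ALT_TERMS && lambda <= 1) {
    stop("lambda must exceed 1")
  }
  if (name == "dyadic_cov") {
    if (is.null(covariate)) stop("dyadic_cov requires a covariate")
  } else if (!is.null(covariate)) {
    stop("term '", name, "' does not take a covariate")
  }
  structure(list(name = name, attribute = attribute,
                 lambda = lambda, covariate = covariate),
            class = "term_spec")
}

term_label <- function(term) {
  lab <- term$name
  if (!is.null(term$attribute)) lab <- paste0(lab, "(", term$attribute, ")")
  if (term$name == "dyadic_cov" && is.character(term$covariate)) {
    lab <- paste0(lab, "(", term$covariate, ")")
  }
  lab
}

#' Declare an ERGM
#'
#' @param terms list of [term_spec()] objects; `(name, attribute)` pairs
#'   must be unique.
#' @param conditioning `"free"` for unconditional estimation or
#'   `"fixed_density"` to condition on the observed number of ties (the
#'   sampler then uses tie-swap proposals and the model must not contain an
#'   `edge` term, whose statistic would be constant).
#' @return an object of class `model_spec`.
#' @export
#' @examples
#' spec <- model_spec(
#'   term_spec("edge"),
#'   term_spec("GGS_triad"),
#'   term_spec("activity", attribute = "role"),
#'   term_spec("dyadic_cov", covariate = "travel_time"))
model_spec <- function(..., terms = NULL, conditioning = c("free", "fixed_density")) {
  conditioning <- match.arg(conditioning)
  if (is.null(terms)) terms <- list(...)
  if (length(terms) == 0L) stop("model_spec needs at least one term")
  stopifnot(all(vapply(terms, inherits, logical(1), "term_spec")))
  keys <- vapply(terms, function(t)
    paste(t$name, t$attribute %||% "", sep = "\r"), character(1))
  if (anyDuplicated(keys)) stop("duplicate (name, attribute) term")
  if (conditioning == "fixed_density" &&
      any(vapply(terms, function(t) t$name, character(1)) == "edge")) {
    stop("fixed_density conditioning is incompatible with an edge term")
  }
  structure(list(terms = terms, conditioning = conditioning),
            class = "model_spec")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.model_spec <- function(x, ...) {
  cat("ERGM specification (", x$conditioning, ")\n", sep = "")
  for (t in x$terms) {
    extra <- if (t$name %in% ALT_TERMS) sprintf("  [lambda = %g]", t$lambda) else ""
    cat("  -", term_label(t), extra, "\n")
  }
  invisible(x)
}

# ---- internal helpers -----------------------------------------------------

align_roster <- function(net, roster) {
  validate_roster(roster)
  if (!identical(as.character(roster$physician_id), net$ids)) {
    ord <- match(net$ids, roster$physician_id)
    if (anyNA(ord)) stop("roster does not cover all network physicians")
    roster <- roster[ord, , drop = FALSE]
  }
  roster
}

resolve_cov <- function(term, covs, n) {
  w <- term$covariate
  if (is.character(w)) {
    if (is.null(covs) || is.null(covs[[w]])) {
      stop("dyadic covariate '", w, "' not found in covs")
    }
    w <- covs[[w]]
  }
  w <- as.matrix(w)
  if (!identical(dim(w), c(n, n))) stop("dyadic covariate has wrong dimension")
  if (max(abs(w - t(w))) > 1e-8) stop("dyadic covariate must be symmetric")
  w
}

term_attr_vector <- function(term, roster) {
  v <- roster[[term$attribute]]
  if (is.null(v)) stop("roster has no attribute column '", term$attribute, "'")
  v
}

# Count open two-paths by role pattern. Returns c(GGG, GGS, SGS) where the
# first letter block is the endpoint pattern and the center is always a GP.
open_chain_counts <- function(A, role) {
  n <- nrow(A)
  out <- c(GGG = 0, GGS = 0, SGS = 0)
  for (k in seq_len(n)) {
    if (role[k] != 1L) next
    nb <- which(A[k, ] == 1L)
    if (length(nb) < 2L) next
    open <- 1L - A[nb, nb, drop = FALSE]
    diag(open) <- 0L
    rsum <- outer(role[nb], role[nb], "+")
    up <- upper.tri(open)
    out["GGG"] <- out["GGG"] + sum(open[up][rsum[up] == 2L])
    out["GGS"] <- out["GGS"] + sum(open[up][rsum[up] == 1L])
    out["SGS"] <- out["SGS"] + sum(open[up][rsum[up] == 0L])
  }
  out
}

triangle_role_counts <- function(A, role) {
  g <- which(role == 1L)
  s <- which(role == 0L)
  tri <- function(M) if (nrow(M) < 3L) 0 else sum(diag(M %*% M %*% M)) / 6
  Agg <- A[g, g, drop = FALSE]
  Ass <- A[s, s, drop = FALSE]
  Ags <- A[g, s, drop = FALSE]
  ggs <- if (length(g) >= 2L && length(s) >= 1L)
    sum(Agg * tcrossprod(Ags)) / 2 else 0
  gss <- if (length(s) >= 2L && length(g) >= 1L)
    sum(Ass * tcrossprod(t(Ags))) / 2 else 0
  c(GGG = tri(Agg), GGS = ggs, GSS = gss, SSS = tri(Ass))
}

#' Global network statistic of a term
#'
#' Evaluates the term's statistic on a binary network. This is the quantity
#' whose observed value the Monte Carlo maximum-likelihood estimator matches
#' in expectation.
#'
#' @param term a [term_spec()].
#' @param net a binary `shared_patient_network`.
#' @param roster the matching `physician_roster` (used for roles and
#'   attribute terms; it is re-ordered to the network's ids if needed).
#' @param covs named list of dyadic covariate matrices, for `dyadic_cov`
#'   terms declared by name.
#' @return a single numeric value.
#' @export
global_statistic <- function(term, net, roster, covs = NULL) {
  stopifnot(inherits(term, "term_spec"),
            inherits(net, "shared_patient_network"))
  roster <- align_roster(net, roster)
  A <- net$adjacency
  n <- nrow(A)
  deg <- rowSums(A)
  role <- as.integer(roster$role)
  if (term$name %in% ROLE_TERMS &&
      (sum(role == 1L) == 0L || sum(role == 0L) == 0L)) {
    stop("role-attributed terms need at least one GP and one specialist")
  }
  lam <- term$lambda
  switch(term$name,
    edge = sum(A) / 2,
    GGG_triad = unname(triangle_role_counts(A, role)["GGG"]),
    GGS_triad = unname(triangle_role_counts(A, role)["GGS"]),
    GSS_triad = unname(triangle_role_counts(A, role)["GSS"]),
    GGG_chain = unname(open_chain_counts(A, role)["GGG"]),
    GGS_chain = unname(open_chain_counts(A, role)["GGS"]),
    SGS_chain = unname(open_chain_counts(A, role)["SGS"]),
    two_path = sum(choose(deg, 2)),
    alt_two_paths = {
      L2 <- A %*% A
      lam * sum((1 - (1 - 1 / lam)^L2[upper.tri(L2)]))
    },
    alt_stars = lam^2 * sum((1 - 1 / lam)^deg - 1 + deg / lam),
    activity = {
      a <- term_attr_vector(term, roster)
      if (!all(a %in% c(0, 1))) stop("activity attribute must be binary")
      sum(a * deg)
    },
    match = {
      cvals <- term_attr_vector(term, roster)
      eq <- outer(cvals, cvals, "==")
      sum(A[upper.tri(A)][eq[upper.tri(eq)]])
    },
    mismatch = {
      cvals <- term_attr_vector(term, roster)
      ne <- outer(cvals, cvals, "!=")
      sum(A[upper.tri(A)][ne[upper.tri(ne)]])
    },
    dyadic_cov = {
      w <- resolve_cov(term, covs, n)
      sum(A * w) / 2
    }
  )
}

#' Change statistic of a term at one dyad
#'
#' Returns the difference `g(x with x_ij = 1) - g(x with x_ij = 0)` for the
#' term's global statistic `g`, regardless of the dyad's current state.
#' Change statistics are the regressors of the pseudo-likelihood and drive
#' the Metropolis sampler's acceptance ratio.
#'
#' @inheritParams global_statistic
#' @param dyad unordered pair: integer vector of two distinct 1-based node
#'   indices, or two physician ids.
#' @return a single numeric value.
#' @export
change_statistic <- function(term, net, roster, dyad, covs = NULL) {
  stopifnot(inherits(term, "term_spec"),
            inherits(net, "shared_patient_network"))
  roster <- align_roster(net, roster)
  if (is.character(dyad)) dyad <- match(dyad, net$ids)
  dyad <- as.integer(dyad)
  if (length(dyad) != 2L || anyNA(dyad) ||
      any(dyad < 1L | dyad > nrow(net$adjacency))) {
    stop("dyad must be two valid node indices or ids")
  }
  if (dyad[1] == dyad[2]) stop("diagonal dyads are not toggleable")
  enc <- encode_terms(list(term), roster, covs, nrow(net$adjacency))
  drop(cpp_change_stats(net$adjacency, dyad[1] - 1L, dyad[2] - 1L,
                        enc$code, enc$lambda, enc$avec, enc$cmat, enc$role))
}

#' Vector of observed statistics for a model
#'
#' @param spec a [model_spec()].
#' @inheritParams global_statistic
#' @return named numeric vector, one entry per term in specification order.
#' @export
statistics_vector <- function(spec, net, roster, covs = NULL) {
  stopifnot(inherits(spec, "model_spec"))
  vals <- vapply(spec$terms, global_statistic, numeric(1),
                 net = net, roster = roster, covs = covs)
  names(vals) <- vapply(spec$terms, term_label, character(1))
  vals
}

# Encode a term list for the C++ kernels. Attribute terms carry an integer
# vector (binary for activity, category codes for match/mismatch); dyadic
# covariates carry their matrix; role is shared by all terms.
encode_terms <- function(terms, roster, covs, n) {
  p <- length(terms)
  code <- integer(p)
  lambda <- numeric(p)
  avec <- vector("list", p)
  cmat <- vector("list", p)
  for (k in seq_len(p)) {
    t <- terms[[k]]
    code[k] <- match(t$name, TERM_NAMES)
    lambda[k] <- t$lambda %||% 2
    avec[[k]] <- integer(0)
    cmat[[k]] <- matrix(0, 0, 0)
    if (t$name == "activity") {
      a <- term_attr_vector(t, roster)
      if (!all(a %in% c(0, 1))) stop("activity attribute must be binary")
      avec[[k]] <- as.integer(a)
    } else if (t$name %in% c("match", "mismatch")) {
      avec[[k]] <- as.integer(factor(term_attr_vector(t, roster)))
    } else if (t$name == "dyadic_cov") {
      cmat[[k]] <- resolve_cov(t, covs, n)
    }
  }
  list(code = code, lambda = lambda, avec = avec, cmat = cmat,
       role = as.integer(roster$role))
}

#' Write and read model specifications
#'
#' Round-trips a [model_spec()] through a YAML file. Matrix covariates are
#' not serialisable; declare `dyadic_cov` terms by covariate name for
#' file-based workflows.
#'
#' @param spec a `model_spec`.
#' @param path file path.
#' @return `read_model_spec()` the reconstructed `model_spec`;
#'   `write_model_spec()` its input, invisibly.
#' @export
write_model_spec <- function(spec, path) {
  stopifnot(inherits(spec, "model_spec"))
  terms <- lapply(spec$terms, function(t) {
    if (t$name == "dyadic_cov" && !is.character(t$covariate)) {
      stop("only name-referenced dyadic covariates can be serialised")
    }
    out <- list(name = t$name)
    if (!is.null(t$attribute)) out$attribute <- t$attribute
    if (t$name %in% ALT_TERMS) out$lambda <- t$lambda
    if (!is.null(t$covariate)) out$covariate <- t$covariate
    out
  })
  yaml::write_yaml(list(conditioning = spec$conditioning, terms = terms), path)
  invisible(spec)
}

#' @rdname write_model_spec
#' @export
read_model_spec <- function(path) {
  raw <- yaml::read_yaml(path)
  terms <- lapply(raw$terms, function(t) {
    term_spec(t$name, attribute = t$attribute,
              lambda = t$lambda %||% 2, covariate = t$covariate)
  })
  model_spec(terms = terms, conditioning = raw$conditioning)
}
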