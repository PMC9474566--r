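# Fixture builders and independent brute-force oracles. The oracles use
# plain triple loops over node triples / dyads and never call the package's
# statistic code, so they can stand as an independent check of it.

make_roster <- function(role, specialty = NULL, status = NULL,
                        practice = NULL, ids = NULL) {
  n <- length(role)
  ids <- ids %||% sprintf("p%02d", seq_len(n))
  as_physician_roster(data.frame(
    physician_id = ids,
    role = as.integer(role),
    status = status %||% rep("licensed", n),
    practice_form = practice %||% rep("single", n),
    specialty = specialty %||% rep(c("alpha", "beta"), length.out = n),
    x_km = seq_len(n), y_km = rep(0, n),
    stringsAsFactors = FALSE))
}

make_net <- function(A, ids = NULL) {
  n <- nrow(A)
  A <- matrix(as.integer(A), n, n)
  shared_patient_network(A, "combined", ids %||% sprintf("p%02d", seq_len(n)))
}

# symmetric 0/1 adjacency from an edge list given as rbind(c(i, j), ...)
adj_from_edges <- function(n, edges) {
  A <- matrix(0L, n, n)
  for (k in seq_len(nrow(edges))) {
    A[edges[k, 1], edges[k, 2]] <- A[edges[k, 2], edges[k, 1]] <- 1L
  }
  A
}

rand_adj <- function(n, p) {
  A <- matrix(0L, n, n)
  up <- upper.tri(A)
  A[up] <- rbinom(sum(up), 1, p)
  A[lower.tri(A)] <- t(A)[lower.tri(A)]
  A
}

rand_roster <- function(n, p_gp = 0.4) {
  role <- rbinom(n, 1, p_gp)
  # attributed-triad terms need both roles present
  if (sum(role) == 0) role[1] <- 1L
  if (sum(role) == n) role[1] <- 0L
  make_roster(role,
              specialty = sample(c("alpha", "beta", "gamma"), n, TRUE),
              status = sample(c("licensed", "employed", "authorized"), n, TRUE),
              practice = sample(c("single", "group", "ambulatory-center"), n, TRUE))
}

rand_sym_cov <- function(n) {
  W <- matrix(runif(n * n, 0, 10), n, n)
  W <- (W + t(W)) / 2
  diag(W) <- 0
  W
}

all_term_specs <- function(cov_name = "w") {
  list(term_spec("edge"),
       term_spec("GGG_triad"), term_spec("GGS_triad"), term_spec("GSS_triad"),
       term_spec("GGG_chain"), term_spec("GGS_chain"), term_spec("SGS_chain"),
       term_spec("two_path"), term_spec("alt_two_paths"), term_spec("alt_stars"),
       term_spec("activity", attribute = "role"),
       term_spec("match", attribute = "specialty"),
       term_spec("mismatch", attribute = "specialty"),
       term_spec("dyadic_cov", covariate = cov_name))
}

# ---- brute-force oracle ---------------------------------------------------

# triangle count with a given number of GPs among the three nodes
oracle_triangles_by_role <- function(A, role, n_gp) {
  n <- nrow(A)
  cnt <- 0L
  for (i in 1:(n - 2)) for (j in (i + 1):(n - 1)) for (k in (j + 1):n) {
    if (A[i, j] && A[i, k] && A[j, k] &&
        role[i] + role[j] + role[k] == n_gp) cnt <- cnt + 1L
  }
  cnt
}

# open two-paths i--k--j (x_ij = 0) with GP center and endpoint role sum
oracle_open_chains <- function(A, role, endpoint_sum) {
  n <- nrow(A)
  cnt <- 0L
  for (k in 1:n) {
    if (role[k] != 1) next
    for (i in 1:(n - 1)) for (j in (i + 1):n) {
      if (i == k || j == k) next
      if (A[i, k] && A[j, k] && !A[i, j] &&
          role[i] + role[j] == endpoint_sum) cnt <- cnt + 1L
    }
  }
  cnt
}

# all two-paths with GP center and endpoint role sum (open or closed)
oracle_all_twopaths <- function(A, role, endpoint_sum) {
  n <- nrow(A)
  cnt <- 0L
  for (k in 1:n) {
    if (role[k] != 1) next
    for (i in 1:(n - 1)) for (j in (i + 1):n) {
      if (i == k || j == k) next
      if (A[i, k] && A[j, k] && role[i] + role[j] == endpoint_sum)
        cnt <- cnt + 1L
    }
  }
  cnt
}

oracle_global <- function(name, A, role = NULL, attrs = NULL, lambda = 2,
                          W = NULL) {
  n <- nrow(A)
  deg <- rowSums(A)
  switch(name,
    edge = sum(A) / 2,
    GGG_triad = oracle_triangles_by_role(A, role, 3),
    GGS_triad = oracle_triangles_by_role(A, role, 2),
    GSS_triad = oracle_triangles_by_role(A, role, 1),
    GGG_chain = oracle_open_chains(A, role, 2),
    GGS_chain = oracle_open_chains(A, role, 1),
    SGS_chain = oracle_open_chains(A, role, 0),
    two_path = {
      cnt <- 0L
      for (k in 1:n) for (i in 1:n) for (j in 1:n) {
        if (i < j && i != k && j != k && A[i, k] && A[j, k]) cnt <- cnt + 1L
      }
      cnt
    },
    alt_two_paths = {
      s <- 0
      for (i in 1:(n - 1)) for (j in (i + 1):n) {
        L2 <- 0L
        for (k in 1:n) if (k != i && k != j && A[i, k] && A[j, k]) L2 <- L2 + 1L
        s <- s + (1 - (1 - 1 / lambda)^L2)
      }
      lambda * s
    },
    alt_stars = {
      s <- 0
      for (i in 1:n) s <- s + (1 - 1 / lambda)^deg[i] - 1 + deg[i] / lambda
      lambda^2 * s
    },
    activity = {
      s <- 0
      for (i in 1:(n - 1)) for (j in (i + 1):n)
        if (A[i, j]) s <- s + attrs[i] + attrs[j]
      s
    },
    match = {
      s <- 0L
      for (i in 1:(n - 1)) for (j in (i + 1):n)
        if (A[i, j] && attrs[i] == attrs[j]) s <- s + 1L
      s
    },
    mismatch = {
      s <- 0L
      for (i in 1:(n - 1)) for (j in (i + 1):n)
        if (A[i, j] && attrs[i] != attrs[j]) s <- s + 1L
      s
    },
    dyadic_cov = {
      s <- 0
      for (i in 1:(n - 1)) for (j in (i + 1):n) if (A[i, j]) s <- s + W[i, j]
      s
    },
    stop("unknown oracle term")
  )
}

oracle_args <- function(term, roster, W) {
  list(name = term$name,
       role = as.integer(roster$role),
       attrs = if (!is.null(term$attribute)) roster[[term$attribute]],
       lambda = term$lambda %||% 2,
       W = W)
}

oracle_value <- function(term, A, roster, W = NULL) {
  a <- oracle_args(term, roster, W)
  oracle_global(a$name, A, role = a$role, attrs = a$attrs,
                lambda = a$lambda, W = a$W)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Monte Carlo standard error of a chain mean via batch means, which stays
# honest under autocorrelation.
batch_mc_se <- function(x, n_batches = 20) {
  n <- length(x)
  bs <- floor(n / n_batches)
  means <- vapply(seq_len(n_batches),
                  function(b) mean(x[((b - 1) * bs + 1):(b * bs)]),
                  numeric(1))
  stats::sd(means) / sqrt(n_batches)
}
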