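test_that("edge-only MPLE equals logit of density", {
  set.seed(21)
  for (p in c(0.25, 0.5, 0.6)) {
    n <- 18
    A <- rand_adj(n, p)
    ros <- rand_roster(n)
    net <- make_net(A, ids = ros$physician_id)
    dens <- sum(A) / 2 / choose(n, 2)
    fit <- mple_fit(model_spec(term_spec("edge")), net, ros)
    expect_equal(unname(fit$theta), qlogis(dens), tolerance = 1e-6)
  }
  # the worked constant: an 8-node graph with 7 of its 28 dyads tied
  set.seed(4)
  repeat {
    B <- rand_adj(8, 0.25)
    if (sum(B) / 2 == 7) break
  }
  fit <- mple_fit(model_spec(term_spec("edge")),
                  make_net(B), make_roster(rep(c(1, 0), 4)))
  expect_equal(unname(fit$theta), log(0.25 / 0.75), tolerance = 1e-6)
  expect_equal(unname(fit$theta), -1.0986, tolerance = 1e-4)
})

test_that("MPLE matches an independent numerical pseudo-likelihood optimum", {
  set.seed(22)
  n <- 20
  ros <- rand_roster(n, p_gp = 0.35)
  A <- rand_adj(n, 0.3)
  net <- make_net(A, ids = ros$physician_id)
  spec <- model_spec(term_spec("edge"), term_spec("activity", attribute = "role"))
  fit <- mple_fit(spec, net, ros)

  # oracle: brute-force change statistics + generic optimizer
  X <- NULL; y <- NULL
  for (j in 2:n) for (i in 1:(j - 1)) {
    A1 <- A; A1[i, j] <- A1[j, i] <- 1L
    A0 <- A; A0[i, j] <- A0[j, i] <- 0L
    d_edge <- 1
    d_act <- ros$role[i] + ros$role[j]
    X <- rbind(X, c(d_edge, d_act))
    y <- c(y, A[i, j])
  }
  negpl <- function(th) {
    eta <- X %*% th
    -sum(y * eta - log1p(exp(eta)))
  }
  opt <- optim(c(0, 0), negpl, method = "BFGS",
               control = list(reltol = 1e-14, maxit = 1000))
  expect_equal(unname(fit$theta), opt$par, tolerance = 1e-6)
})

test_that("perfectly separable terms are flagged, not silently diverged", {
  # ties exist only between GPs: GP-activity separates perfectly
  n <- 8
  role <- c(1, 1, 1, 1, 0, 0, 0, 0)
  A <- matrix(0L, n, n)
  A[1:4, 1:4] <- 1L
  diag(A) <- 0L
  ros <- make_roster(role)
  net <- make_net(A, ids = ros$physician_id)
  spec <- model_spec(term_spec("edge"), term_spec("match", attribute = "grp"))
  ros$grp <- c(rep("a", 4), rep("b", 4))
  expect_warning(fit <- mple_fit(spec, net, ros), "non-estimable")
  expect_true(any(!fit$estimable))
  expect_true(any(is.na(fit$significant)))
})

test_that("single-toggle sampler reproduces Bernoulli densities", {
  set.seed(23)
  n <- 20
  ros <- rand_roster(n)
  nd <- choose(n, 2)
  spec <- model_spec(term_spec("edge"))
  for (target in c(0.5, 0.2)) {
    sims <- sample_networks(spec, qlogis(target), ros,
                            control = sampler_control(n_samples = 400, seed = 31),
                            return_networks = FALSE)
    st <- attr(sims, "statistics")[, 1]
    expect_lt(abs(mean(st / nd) - target), 3 * batch_mc_se(st / nd))
  }
})

test_that("tie-swap proposals preserve the edge count exactly", {
  set.seed(24)
  n <- 15
  ros <- rand_roster(n)
  A <- rand_adj(n, 0.3)
  net <- make_net(A, ids = ros$physician_id)
  m <- sum(A) / 2
  sims <- sample_networks(model_spec(term_spec("two_path"),
                                     conditioning = "fixed_density"),
                          0.05, ros,
                          control = sampler_control(n_samples = 60,
                                                    proposal = "tie_swap",
                                                    seed = 32),
                          start = net)
  counts <- vapply(sims, function(s) sum(s$adjacency) / 2, numeric(1))
  expect_true(all(counts == m))
  # and rejects degenerate starts
  expect_error(
    sample_networks(model_spec(term_spec("edge")), 0, ros,
                    control = sampler_control(proposal = "tie_swap", seed = 1),
                    start = make_net(matrix(0, n, n),
                                     ids = ros$physician_id)),
    "neither empty nor complete")
})

test_that("sampling is deterministic given a seed", {
  n <- 12
  ros <- rand_roster(n)
  spec <- model_spec(term_spec("edge"), term_spec("alt_stars"))
  ctl <- sampler_control(n_samples = 20, seed = 99)
  s1 <- sample_networks(spec, c(-1, 0.2), ros, control = ctl)
  s2 <- sample_networks(spec, c(-1, 0.2), ros, control = ctl)
  expect_identical(attr(s1, "statistics"), attr(s2, "statistics"))
  expect_identical(s1[[5]]$adjacency, s2[[5]]$adjacency)
})

test_that("edge-only MCMC MLE agrees with the closed form", {
  set.seed(25)
  n <- 18
  A <- rand_adj(n, 0.3)
  ros <- rand_roster(n)
  net <- make_net(A, ids = ros$physician_id)
  dens <- sum(A) / 2 / choose(n, 2)
  fit <- mcmcmle_fit(model_spec(term_spec("edge")), net, ros,
                     control = sampler_control(n_samples = 400, seed = 41))
  expect_true(fit$converged)
  expect_lt(abs(unname(fit$theta) - qlogis(dens)),
            3 * unname(fit$standard_errors))
  expect_lte(max(abs(fit$convergence_t)), 0.1)
})

test_that("MCMC MLE reproduces the MPLE on a dyad-independent model", {
  set.seed(26)
  n <- 22
  ros <- rand_roster(n, p_gp = 0.4)
  W <- rand_sym_cov(n)
  A <- rand_adj(n, 0.25)
  net <- make_net(A, ids = ros$physician_id)
  spec <- model_spec(term_spec("edge"),
                     term_spec("match", attribute = "specialty"),
                     term_spec("dyadic_cov", covariate = "w"))
  covs <- list(w = W)
  mp <- mple_fit(spec, net, ros, covs)
  ml <- mcmcmle_fit(spec, net, ros, covs,
                    control = sampler_control(n_samples = 600, seed = 51))
  expect_true(ml$converged)
  # MPLE = MLE for independent dyads; agreement within MC error
  expect_true(all(abs(mp$theta - ml$theta) <= 3 * ml$standard_errors))
})

test_that("fixed-density fits use tie swaps and skip the edge term", {
  set.seed(27)
  n <- 16
  ros <- rand_roster(n, p_gp = 0.4)
  A <- rand_adj(n, 0.3)
  net <- make_net(A, ids = ros$physician_id)
  spec <- model_spec(term_spec("activity", attribute = "role"),
                     conditioning = "fixed_density")
  fit <- mcmcmle_fit(spec, net, ros,
                     control = sampler_control(n_samples = 400, seed = 61))
  expect_true(fit$converged)
  expect_length(fit$theta, 1L)
  # estimating-equation property: simulated mean matches observed statistic
  sims <- sample_networks(spec, unname(fit$theta), ros,
                          control = sampler_control(n_samples = 200,
                                                    proposal = "tie_swap",
                                                    seed = 62),
                          start = net, return_networks = TRUE)
  counts <- vapply(sims, function(s) sum(s$adjacency) / 2, numeric(1))
  expect_true(all(counts == sum(A) / 2))
})

test_that("fit results print and export like a results table", {
  set.seed(28)
  n <- 14
  ros <- rand_roster(n)
  net <- make_net(rand_adj(n, 0.3), ids = ros$physician_id)
  fit <- mple_fit(model_spec(term_spec("edge"),
                             term_spec("activity", attribute = "role")),
                  net, ros)
  df <- as.data.frame(fit)
  expect_equal(df$term, c("edge", "activity"))
  expect_equal(df$attribute, c("", "role"))
  f <- tempfile(fileext = ".csv")
  out <- write_fit_results(fit, f, channel = "combined")
  expect_true(file.exists(f))
  expect_equal(read.csv(f)$channel, rep("combined", 2))
  expect_output(print(fit), "ERGM fit")
})
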