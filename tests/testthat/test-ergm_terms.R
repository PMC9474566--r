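test_that("term and model specification constraints are enforced", {
  expect_error(term_spec("activity"), "requires an attribute")
  expect_error(term_spec("edge", attribute = "role"), "does not take")
  expect_error(term_spec("alt_stars", lambda = 1), "exceed 1")
  expect_error(term_spec("dyadic_cov"), "covariate")
  expect_error(model_spec(term_spec("edge"), term_spec("edge")), "duplicate")
  expect_error(model_spec(term_spec("edge"), conditioning = "fixed_density"),
               "incompatible")
  # same name with different attributes is allowed
  spec <- model_spec(term_spec("match", attribute = "specialty"),
                     term_spec("match", attribute = "status"))
  expect_length(spec$terms, 2L)
})

test_that("closed and open triad statistics on hand-checked graphs", {
  # triangle with roles (G, G, S)
  tri <- make_net(adj_from_edges(3, rbind(c(1, 2), c(1, 3), c(2, 3))))
  ros <- make_roster(c(1, 1, 0))
  expect_equal(global_statistic(term_spec("GGS_triad"), tri, ros), 1)
  expect_equal(global_statistic(term_spec("GGG_triad"), tri, ros), 0)
  expect_equal(global_statistic(term_spec("GSS_triad"), tri, ros), 0)
  for (chain in c("GGG_chain", "GGS_chain", "SGS_chain")) {
    expect_equal(global_statistic(term_spec(chain), tri, ros), 0)
  }

  # path S - G - S with open ends
  path <- make_net(adj_from_edges(3, rbind(c(1, 2), c(2, 3))))
  ros2 <- make_roster(c(0, 1, 0))
  expect_equal(global_statistic(term_spec("SGS_chain"), path, ros2), 1)
  expect_equal(global_statistic(term_spec("two_path"), path, ros2), 1)
  expect_equal(global_statistic(term_spec("alt_two_paths"), path, ros2), 1)
})

test_that("alternating statistics take their closed-form values", {
  # star with center degree 3: lambda = 2 gives S2 - S3/lambda = 3 - 0.5
  star <- make_net(adj_from_edges(4, rbind(c(1, 2), c(1, 3), c(1, 4))))
  ros <- make_roster(c(1, 0, 0, 0))
  expect_equal(global_statistic(term_spec("alt_stars"), star, ros), 2.5)
  # 4-cycle: two dyads with L2 = 2 -> 2 * 2 * (1 - (1/2)^2) = 3
  cyc <- make_net(adj_from_edges(4, rbind(c(1, 2), c(2, 3), c(3, 4), c(4, 1))))
  expect_equal(global_statistic(term_spec("alt_two_paths"), cyc, ros), 3.0)
})

test_that("global statistics equal the brute-force oracle on random graphs", {
  set.seed(31)
  for (rep in 1:6) {
    n <- sample(8:14, 1)
    ros <- rand_roster(n)
    W <- rand_sym_cov(n)
    A <- rand_adj(n, runif(1, 0.15, 0.6))
    net <- make_net(A, ids = ros$physician_id)
    for (term in all_term_specs()) {
      expect_equal(
        global_statistic(term, net, ros, covs = list(w = W)),
        oracle_value(term, A, ros, W),
        tolerance = 1e-10, label = term$name)
    }
  }
})

test_that("change statistics equal brute-force global differences", {
  set.seed(77)
  terms <- all_term_specs()
  for (rep in 1:25) {
    n <- sample(7:12, 1)
    ros <- rand_roster(n)
    W <- rand_sym_cov(n)
    A <- rand_adj(n, runif(1, 0.1, 0.7))
    net <- make_net(A, ids = ros$physician_id)
    d <- sample(n, 2)
    A1 <- A; A1[d[1], d[2]] <- A1[d[2], d[1]] <- 1L
    A0 <- A; A0[d[1], d[2]] <- A0[d[2], d[1]] <- 0L
    for (term in terms) {
      brute <- oracle_value(term, A1, ros, W) - oracle_value(term, A0, ros, W)
      expect_equal(change_statistic(term, net, ros, d, covs = list(w = W)),
                   brute, tolerance = 1e-9, label = term$name)
    }
  }
  expect_error(change_statistic(terms[[1]], make_net(rand_adj(5, 0.5)),
                                rand_roster(5), c(2, 2)), "diagonal")
})

test_that("closing an open chain trades a chain for a triangle", {
  # G1 - G3 - G2 open; toggling {G1, G2} on closes it
  A <- adj_from_edges(3, rbind(c(1, 3), c(2, 3)))
  ros <- make_roster(c(1, 1, 1))
  net <- make_net(A)
  expect_equal(change_statistic(term_spec("GGG_triad"), net, ros, c(1, 2)), 1)
  expect_equal(change_statistic(term_spec("GGG_chain"), net, ros, c(1, 2)), -1)
  expect_equal(change_statistic(term_spec("edge"), net, ros, c(1, 2)), 1)
})

test_that("triangle role classes partition all triangles", {
  set.seed(13)
  for (rep in 1:10) {
    n <- 12
    ros <- rand_roster(n)
    A <- rand_adj(n, 0.4)
    net <- make_net(A, ids = ros$physician_id)
    total <- sum(diag(A %*% A %*% A)) / 6
    sss <- oracle_triangles_by_role(A, ros$role, 0)
    parts <- sum(
      global_statistic(term_spec("GGG_triad"), net, ros),
      global_statistic(term_spec("GGS_triad"), net, ros),
      global_statistic(term_spec("GSS_triad"), net, ros))
    expect_equal(parts + sss, total)
  }
})

test_that("open chains plus closed incidences give all two-paths per pattern", {
  set.seed(14)
  for (rep in 1:10) {
    n <- 11
    ros <- rand_roster(n)
    A <- rand_adj(n, 0.35)
    net <- make_net(A, ids = ros$physician_id)
    for (es in 0:2) {
      chain <- c("SGS_chain", "GGS_chain", "GGG_chain")[es + 1]
      open <- global_statistic(term_spec(chain), net, ros)
      all_tp <- oracle_all_twopaths(A, ros$role, es)
      # closed incidences counted by their own triple loop
      closed <- 0L
      role <- ros$role
      for (k in 1:n) {
        if (role[k] != 1) next
        for (i in 1:(n - 1)) for (j in (i + 1):n) {
          if (i == k || j == k) next
          if (A[i, k] && A[j, k] && A[i, j] &&
              role[i] + role[j] == es) closed <- closed + 1L
        }
      }
      expect_equal(open + closed, all_tp)
    }
  }
})

test_that("alt_stars approaches the two-path count as lambda grows", {
  set.seed(15)
  A <- rand_adj(15, 0.3)
  ros <- rand_roster(15)
  net <- make_net(A, ids = ros$physician_id)
  s2 <- global_statistic(term_spec("two_path"), net, ros)
  big <- global_statistic(term_spec("alt_stars", lambda = 1e6), net, ros)
  expect_equal(big, s2, tolerance = 1e-4)
})

test_that("statistics are invariant under node relabeling", {
  set.seed(16)
  n <- 12
  ros <- rand_roster(n)
  W <- rand_sym_cov(n)
  A <- rand_adj(n, 0.4)
  perm <- sample(n)
  ros_p <- as_physician_roster(ros[perm, ])
  net <- make_net(A, ids = ros$physician_id)
  net_p <- make_net(A[perm, perm], ids = ros_p$physician_id)
  for (term in all_term_specs()) {
    expect_equal(
      global_statistic(term, net_p, ros_p, covs = list(w = W[perm, perm])),
      global_statistic(term, net, ros, covs = list(w = W)),
      tolerance = 1e-10, label = term$name)
  }
})

test_that("statistics_vector keeps model order and zeroes on empty graphs", {
  ros <- make_roster(c(1, 1, 0, 0))
  empty <- make_net(matrix(0, 4, 4), ids = ros$physician_id)
  spec <- model_spec(term_spec("edge"), term_spec("GGS_triad"),
                     term_spec("two_path"), term_spec("alt_stars"))
  expect_equal(unname(statistics_vector(spec, empty, ros)), rep(0, 4))

  tri <- make_net(adj_from_edges(3, rbind(c(1, 2), c(1, 3), c(2, 3))))
  ros3 <- make_roster(c(1, 1, 0))
  spec2 <- model_spec(term_spec("edge"), term_spec("GGS_triad"))
  expect_equal(unname(statistics_vector(spec2, tri, ros3)), c(3, 1))
})

test_that("model specifications round-trip through YAML", {
  spec <- model_spec(
    term_spec("edge"),
    term_spec("GGS_triad"),
    term_spec("alt_stars", lambda = 3),
    term_spec("activity", attribute = "role"),
    term_spec("mismatch", attribute = "specialty"),
    term_spec("dyadic_cov", covariate = "travel_time"))
  f <- tempfile(fileext = ".yaml")
  write_model_spec(spec, f)
  back <- read_model_spec(f)
  expect_equal(back, spec)

  fixed <- model_spec(term_spec("two_path"), conditioning = "fixed_density")
  write_model_spec(fixed, f)
  expect_equal(read_model_spec(f)$conditioning, "fixed_density")
})

test_that("attribute terms demand a usable roster column", {
  ros <- make_roster(c(1, 0, 0))
  net <- make_net(rand_adj(3, 0.5), ids = ros$physician_id)
  expect_error(
    global_statistic(term_spec("match", attribute = "nope"), net, ros),
    "no attribute column")
  expect_error(
    global_statistic(term_spec("dyadic_cov", covariate = "w"), net, ros),
    "not found")
})
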