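test_that("Hill nonlinearities hit their half-maximum and step limits", {
  net <- net_cycle3()
  params <- c("γ[0]" = 1, "γ[1]" = 1, "γ[2]" = 1,
              "l[0][2]" = 0.5, "l[1][0]" = 0.5, "l[2][1]" = 0.5,
              "d[0][2]" = 1, "d[1][0]" = 1, "d[2][1]" = 1,
              "t[1][0]" = 1, "t[2][1]" = 1, "t[0][2]" = 1)
  sys <- hill_system(net, params, hill_n = 4)
  # H+ at x = theta is ell + delta / 2: node 0's rate at x2 = theta_{0,2}
  r <- hill_rhs(sys, c(1, 1, 1))
  expect_equal(r, rep(-1 + 0.5 + 0.5, 3))
  # large exponents approach the step values away from the threshold
  stiff <- hill_system(net, params, hill_n = 400)
  expect_equal(hill_rhs(stiff, c(0.5, 0.5, 0.5)),
               rep(-0.5 + 0.5, 3), tolerance = 1e-8)
  expect_equal(hill_rhs(stiff, c(2, 2, 2)), rep(-2 + 1.5, 3),
               tolerance = 1e-8)
})

test_that("analytic Jacobians agree with finite differences", {
  set.seed(42)
  nets <- list(net_top(),
               parse_network("x0 : (x1)(~x2)\nx1 : (x0)\nx2 : (~x0)"),
               parse_network("x0 : (~x1)(~x2)\nx1 : (x0)\nx2 : (x0)"))
  for (net in nets) {
    pg <- build_parameter_graph(net)
    v <- vapply(pg$sizes, function(s) sample.int(s, 1L), integer(1))
    par <- sample_parameters(pg, v, 1L, seed = 17)
    for (n in c(4, 30)) {
      sys <- hill_system(net, par[1L, ], hill_n = n)
      x <- stats::runif(3, 0.2, 3)
      J <- hill_jacobian(sys, x)
      Jfd <- vapply(1:3, function(j) {
        h <- 1e-6 * max(x[j], 1)
        e <- numeric(3); e[j] <- h
        (hill_rhs(sys, x + e) - hill_rhs(sys, x - e)) / (2 * h)
      }, numeric(3))
      expect_lt(max(abs(J - Jfd)) / max(abs(J)), 1e-5)
    }
  }
})

test_that("Newton finds equilibria and honors its failure contract", {
  # one node, no in-edges: dx/dt = -x + b has equilibrium x = b
  noin <- parse_network("x0 :")
  sys <- hill_system(noin,
                     list(gamma = 1, ell = matrix(NA, 1, 1),
                          delta = matrix(NA, 1, 1), theta = matrix(NA, 1, 1),
                          beta = 2.5),
                     hill_n = 4)
  expect_equal(find_equilibrium(sys, 0.1), 2.5, tolerance = 1e-8)
  expect_equal(find_equilibrium(sys, 40), 2.5, tolerance = 1e-8)
  expect_error(find_equilibrium(sys, -1), "positive")
  # capped iterations on a hopeless guess return NULL
  net <- net_top()
  sysn <- hill_system(net, switchgrade:::reference_continuation_params(),
                      hill_n = 4)
  expect_null(find_equilibrium(sysn, c(1e-9, 1e-9, 1e-9), maxit = 1L))
})

test_that("the reference continuation example yields a two-fold hysteresis curve", {
  net <- net_top()
  sys <- hill_system(net, switchgrade:::reference_continuation_params(),
                     hill_n = 4, s = 0)
  eq <- find_equilibrium(sys, c(0.5, 0.9, 0.2))
  expect_false(is.null(eq))
  cur <- continue_curve(sys, eq)
  expect_true(cur$complete)
  expect_equal(nrow(cur$folds), 2L)
  expect_true(all(cur$folds$x_out_before < cur$folds$x_out_after))
  # every accepted curve point satisfies the equilibrium equations
  res <- apply(cur$points, 1L, function(p) {
    sqrt(sum(hill_rhs(sys, p[2:4], s = p[1L])^2))
  })
  expect_lt(max(res), 1e-7)
  expect_true(as.logical(
    hysteretic_parameter_point(sys, "ascending", seed = 7)))
})

test_that("monotone systems have no folds and tiny increments no bistability", {
  # the three-cycle at its essential vertex but with near-constant
  # production cannot fold
  pg <- build_parameter_graph(net_cycle3())
  par <- sample_parameters(pg, c(1L, 2L, 2L), 1L, seed = 3)
  p <- unlist(par[1L, ])
  p[grepl("^d\\[", names(p))] <- 1e-4
  sys <- hill_system(net_cycle3(), p, hill_n = 4)
  eq <- find_equilibrium(sys, c(0.1, 0.1, 0.1))
  cur <- continue_curve(sys, eq)
  expect_true(cur$complete)
  expect_equal(nrow(cur$folds), 0L)
  expect_false(as.logical(hysteretic_parameter_point(sys, seed = 1)))
})

test_that("Monte-Carlo scoring is deterministic and audit-complete", {
  pg <- build_parameter_graph(net_cycle3())
  verts <- minimal_essential_vertices(pg)
  expect_equal(verts, list(c(1L, 2L, 2L)))
  mc0 <- monte_carlo_hysteresis_score(pg, verts, 0L, hill_n = 4)
  expect_true(is.na(mc0$score))
  expect_equal(nrow(mc0$records), 0L)
  mc1 <- monte_carlo_hysteresis_score(pg, verts, 6L, hill_n = 50, seed = 9)
  mc2 <- monte_carlo_hysteresis_score(pg, verts, 6L, hill_n = 50, seed = 9)
  expect_identical(mc1$records, mc2$records)
  expect_equal(nrow(mc1$records), 6L)
})

test_that("descending hysteresis never arises in an all-activator model", {
  pg <- build_parameter_graph(net_cycle3())
  verts <- minimal_essential_vertices(pg)
  mc <- monte_carlo_hysteresis_score(pg, verts, 8L, hill_n = 50, seed = 21,
                                     mode = "descending")
  expect_equal(mc$score, 0)
})
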