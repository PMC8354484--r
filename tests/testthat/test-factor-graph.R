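test_that("production value expressions follow the sum-then-multiply algebra", {
  pve <- production_value_exprs(net_top(), 1)  # activators x0 and x2
  expect_equal(pve$expr[pve$bits == "10"], "l[1][0] + d[1][0] + l[1][2]")
  expect_equal(pve$expr[pve$bits == "11"],
               "l[1][0] + d[1][0] + l[1][2] + d[1][2]")

  mixed <- parse_network("x0 : (x1)\nx1 : (x0)(~x2)\nx2 : (x1)")
  pve2 <- production_value_exprs(mixed, 1)
  expect_equal(pve2$expr[pve2$bits == "11"],
               "(l[1][0] + d[1][0]) * (l[1][2])")
  expect_equal(pve2$expr[pve2$bits == "00"],
               "(l[1][0]) * (l[1][2] + d[1][2])")

  noin <- parse_network("x0 :\nx1 : (x0)\nx2 : (x1)")
  expect_equal(production_value_exprs(noin, 0)$expr, "b[0]")
})

test_that("small factor graphs have the expected structure", {
  net <- net_cycle3()
  fg0 <- enumerate_factor_graph(net, 0)  # one in, one out
  expect_equal(fg0$n_vertices, 3L)
  expect_equal(sum(fg0$essential), 1L)
  # the essential vertex is the middle of the 3-path
  td <- tidy(fg0)
  expect_true(td$essential[td$size == 1L])
  expect_equal(nrow(cbind(fg0$adj_from, fg0$adj_to)), 2L)

  # two summed activators, one threshold: all 6 monotone sets realizable
  net2 <- parse_network("x0 : (x1 + x2)\nx1 : (x0)\nx2 : (x1)")
  fg2 <- enumerate_factor_graph(net2, 0)
  expect_equal(fg2$n_vertices, 6L)
  # essential: threshold crossed and both inputs relevant (AND- and OR-like)
  ess_sizes <- sort(fg2$sizes[fg2$essential])
  expect_equal(ess_sizes, c(1L, 3L))

  # one in, two out: 6 chains per class, 2 classes
  net3 <- parse_network("x0 : (x1)\nx1 : (x0)\nx2 : (x0)")
  fg3 <- enumerate_factor_graph(net3, 0)
  expect_equal(fg3$per_class, 6L)
  expect_equal(fg3$n_class, 2L)

  # no in-edges, one out-edge: constant production below or above
  noin <- parse_network("x0 :\nx1 : (x0)\nx2 : (x1)")
  fgn <- enumerate_factor_graph(noin, 0)
  expect_equal(fgn$n_vertices, 2L)
  expect_equal(sum(fgn$essential), 0L)
})

test_that("is_realizable rejects non-monotone chains and returns witnesses", {
  net <- net_cycle3()
  # both states above: the low-gamma region
  r <- is_realizable(net, 0, list(c(0, 1)))
  expect_equal(r$status, "realizable")
  w <- r$witness
  expect_true(all(unlist(w[c("ell", "delta", "theta")]) > 0))
  expect_true(w$gamma * w$theta < w$ell)
  # low state above but high state below the threshold: not monotone
  expect_equal(is_realizable(net, 0, list(c(0)))$status, "unrealizable")
  # middle region witness satisfies the defining double inequality
  m <- is_realizable(net, 0, list(c(1)))$witness
  expect_true(m$ell < m$gamma * m$theta)
  expect_true(m$gamma * m$theta < m$ell + m$delta)
})

test_that("nested chain and bound counting matches enumeration oracles", {
  expect_equal(chain_count_bound(1, 1), 3)
  expect_equal(chain_count_bound(2, 1), 6)
  expect_equal(chain_count_bound(1, 2), 6 * 2)
  # pairs of nested monotone sets: 6 over 2 input states, 20 over 4
  us1 <- switchgrade:::up_sets(1L, 1L)
  expect_equal(switchgrade:::count_nested_chains(us1, 2L), 6)
  us2 <- switchgrade:::up_sets(2L, c(1L, 1L))
  expect_equal(switchgrade:::count_nested_chains(us2, 2L), 20)
  # brute-force oracle for the chain DP on the 2-input lattice
  cnt <- 0L
  for (a in us2) for (b in us2) {
    if (bitwAnd(a, b) == b) cnt <- cnt + 1L
  }
  expect_equal(cnt, 20L)
})

test_that("gamma order has unique extremes and single-flip cover edges", {
  shapes <- list(net_cycle3(), net_top(),
                 parse_network("x0 : (x1)(~x2)\nx1 : (x0)\nx2 : (x0)"))
  for (net in shapes) {
    fg <- enumerate_factor_graph(net, 0)
    expect_equal(length(switchgrade:::fg_chain_index_min(fg)), 1L)
    expect_equal(length(switchgrade:::fg_chain_index_max(fg)), 1L)
    # every cover edge adds exactly one state at exactly one level
    for (e in seq_along(fg$cover_from)) {
      a <- fg$chains[fg$cover_from[e], ]
      b <- fg$chains[fg$cover_to[e], ]
      d <- mapply(function(x, y) sum(bitwAnd(bitwXor(x, y),
                                             bitwShiftL(1L, 0:15)) != 0L),
                  a, b)
      expect_equal(sum(d), 1L)
      expect_true(all(bitwAnd(a, b) == a))  # b contains a
    }
  }
})

test_that("the partition oracle covers and only covers enumerated regions", {
  # for each tested node shape: random positive draws always classify onto
  # an enumerated vertex, and every witness classifies back to itself
  shapes <- list(
    list(net = net_cycle3(), node = 0),                              # (1,1)
    list(net = parse_network("x0 : (x1 + x2)\nx1 : (x0)\nx2 : (x1)"),
         node = 0),                                                  # 2 act
    list(net = parse_network("x0 : (x1)(~x2)\nx1 : (x0)\nx2 : (x0)"),
         node = 0),                                                  # mixed
    list(net = parse_network("x0 : (~x1)(~x2)\nx1 : (x0)\nx2 : (x0)"),
         node = 0),                                                  # product
    list(net = parse_network("x0 : (x1)\nx1 : (x0)\nx2 : (x0)"),
         node = 0)                                                   # (1,2)
  )
  n_draws <- 2000L
  set.seed(99)
  for (sh in shapes) {
    fg <- enumerate_factor_graph(sh$net, sh$node)
    shape <- fg$shape
    hits <- vapply(seq_len(n_draws), function(i) {
      p <- random_node_params(shape)
      classify_node_parameters(fg, gamma = p$gamma, ell = p$ell,
                               delta = p$delta, theta = p$theta,
                               beta = p$beta)
    }, integer(1))
    expect_false(anyNA(hits))
    expect_true(all(hits >= 1L & hits <= fg$n_vertices))
    # witnesses hit their own region (thresholds mapped back to
    # ascending-target order)
    back <- vapply(seq_len(fg$n_vertices), function(id) {
      w <- switchgrade:::fg_witness(fg, id)
      ord <- switchgrade:::fg_order(fg, id)
      theta_bt <- numeric(shape$k); theta_bt[ord] <- w$theta
      classify_node_parameters(fg, gamma = w$gamma, ell = w$ell,
                               delta = w$delta, theta = theta_bt,
                               beta = w$beta)
    }, integer(1))
    expect_equal(back, seq_len(fg$n_vertices))
  }
})
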