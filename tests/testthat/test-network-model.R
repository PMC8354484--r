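test_that("the dialect parses the worked specifications", {
  net <- parse_network("x0:(x0+x1+x2)\nx1:(x0+x2)\nx2:(x0)")
  expect_equal(unname(net$coeffs),
               rbind(c(1L, 1L, 1L), c(1L, 0L, 1L), c(1L, 0L, 0L)))
  expect_equal(n_edges(net), 6L)

  one <- parse_network("x0:(x0)")
  expect_equal(unname(one$coeffs), matrix(1L, 1L, 1L))

  mixed <- parse_network("x0 : (x1)\nx1 : (x0)(~x2)\nx2 : (x1)")
  expect_equal(unname(mixed$coeffs[2L, ]), c(1L, 0L, -1L))

  # comments, blank lines, and empty right-hand sides
  net2 <- parse_network(c("# a comment", "", "a : (b)", "b :"))
  expect_equal(unname(net2$coeffs), rbind(c(0L, 1L), c(0L, 0L)))
})

test_that("parse errors name the offending line", {
  expect_error(parse_network("x0 : (x9)"), "line 1.*unknown node name")
  expect_error(parse_network("x0 : (x0)\nx0 : (x0)"), "line 2.*defined twice")
  expect_error(parse_network("x0 : x0"), "line 1.*malformed")
  expect_error(parse_network("x0 : (x0)(x0)"),
               "line 1")
  expect_error(parse_network("x0 : (x1)(x1)\nx1 : (x0)"),
               "more than one summed activator group")
})

test_that("serialization round-trips edge coefficients", {
  for (net in c(lapply(c("network1", "network6", "network12", "toy1d",
                         "selfrepressor"),
                       function(f) make_fixture(f)$network),
                random_networks(25, seed = 11))) {
    back <- parse_network(serialize_network(net))
    expect_identical(unname(back$coeffs), unname(net$coeffs))
  }
})

test_that("enumeration is a bijection with the documented counts", {
  all_nets <- enumerate_three_node_networks(include_trivial = TRUE,
                                            nine_edge = "keep_all")
  expect_equal(nrow(all_nets), 3^9)  # 19,683
  key <- do.call(paste, all_nets[, 2:10])
  expect_false(anyDuplicated(key) > 0)
  # canonical order: lexicographic row-major, -1 < 0 < 1
  expect_equal(unlist(all_nets[1L, 2:10], use.names = FALSE), rep(-1L, 9L))
  expect_equal(unlist(all_nets[nrow(all_nets), 2:10], use.names = FALSE),
               rep(1L, 9L))
  expect_equal(all_nets$id, seq_len(3^9))

  nontrivial <- enumerate_three_node_networks(include_trivial = FALSE,
                                              nine_edge = "keep_all")
  expect_equal(nrow(nontrivial), 14580L)
  expect_equal(sum(all_nets$trivial), 5103L)
  # closed form: free choice of 5 coefficients times the 21 zero-product
  # sign patterns of (a20, a21, a01, a10)
  grid4 <- expand.grid(p = -1:1, q = -1:1, r = -1:1, t = -1:1)
  n_pat <- sum(with(grid4, abs(p * q) + abs(p * r) + abs(q * t)) == 0)
  expect_equal(n_pat, 21L)
  expect_equal(sum(all_nets$trivial), n_pat * 3^5)

  scr <- enumerate_three_node_networks()
  expect_equal(nrow(scr), 14580L - 512L + 1L)  # one nine-edge survivor
  nine <- scr[scr$n_edges == 9L, ]
  expect_equal(nrow(nine), 1L)
  expect_true(all(nine[, 2:10] == 1L))
})

test_that("the trivial filter matches its defining products", {
  zero <- regulatory_network(matrix(0L, 3L, 3L))
  expect_true(is_trivial(zero))
  only01 <- regulatory_network(rbind(c(0L, 0L, 0L), c(1L, 0L, 0L),
                                     c(0L, 0L, 0L)))
  expect_true(is_trivial(only01))
  expect_false(is_trivial(net_top()))
  expect_false(is_trivial(net_cycle3()))
  expect_error(is_trivial(parse_network("x0:(x0)")), "3-node")
  # against the first-principles reachability definition
  for (net in random_networks(60, seed = 3)) {
    a <- net$coeffs
    reach02 <- a[3, 1] != 0L || (a[3, 2] != 0L && a[2, 1] != 0L)
    reach12 <- a[3, 2] != 0L || (a[3, 1] != 0L && a[1, 2] != 0L)
    expect_identical(is_trivial(net), !(reach02 && reach12))
  }
})

test_that("node consistency classifies out-edge sign patterns", {
  cons <- node_consistency(net_top())
  expect_true(all(cons$role == "activator-only"))
  mixed <- regulatory_network(rbind(c(0L, 1L, 0L), c(0L, 0L, 0L),
                                    c(0L, -1L, 1L)))
  roles <- node_consistency(mixed)$role
  expect_equal(roles[2L], "mixed")
  expect_equal(roles[1L], "no-out")
  expect_equal(roles[3L], "activator-only")
})
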