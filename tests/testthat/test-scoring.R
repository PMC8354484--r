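test_that("path counting matches brute-force enumeration", {
  nets <- list(net_cycle3(),
               parse_network("x0 : (x1 + x2)\nx1 : (x0)\nx2 : (x0)"),
               parse_network("x0 : (x1)\nx1 : (x0)\nx2 : (x0)"))
  for (net in nets) {
    fg <- enumerate_factor_graph(net, 0)
    for (kind in c("partial", "full")) {
      res <- enumerate_or_count_paths(fg, kind)
      oracle <- brute_force_paths(fg, kind)
      expect_equal(res$count, length(oracle))
      expect_equal(length(res$paths), length(oracle))
    }
  }
  # the 3-vertex path has exactly one partial path, also its full path
  fg1 <- enumerate_factor_graph(net_cycle3(), 0)
  expect_equal(enumerate_or_count_paths(fg1, "partial")$count, 1)
  expect_equal(enumerate_or_count_paths(fg1, "full")$count, 1)
  # a 2-vertex factor graph has no admissible path
  fgn <- enumerate_factor_graph(parse_network("x0 :\nx1 : (x0)\nx2 : (x1)"), 0)
  expect_equal(enumerate_or_count_paths(fgn, "partial")$count, 0)
  # 4-vertex linear chain (constant production vs three thresholds):
  # exactly 3 paths of at least three vertices
  net4 <- parse_network("x0 :\nx1 : (x0)\nx2 : (x0)\nx3 : (x0)")
  fg4 <- enumerate_factor_graph(net4, 0)
  expect_equal(fg4$per_class, 4L)
  expect_equal(enumerate_or_count_paths(fg4, "partial")$count, 3)
  expect_equal(enumerate_or_count_paths(fg4, "full")$count, 1)
})

test_that("the hysteresis predicate reads the stable-state sequence", {
  pg <- build_parameter_graph(net_cycle3())
  ess <- essential_subgraph(pg)
  fixed <- c(1L, ess$v1[1L], ess$v2[1L])
  expect_true(hysteresis_predicate(pg, 1:3, fixed, "ascending"))
  expect_false(hysteresis_predicate(pg, 1:3, fixed, "descending"))
  expect_true(hysteresis_predicate(pg, 1:3, fixed, "ascending",
                                   strict_ends = TRUE))
  # constant stable output along the path: no hysteresis either way
  off <- c(1L, 1L, ess$v2[1L])
  expect_false(hysteresis_predicate(pg, 1:3, off, "ascending"))
  expect_false(hysteresis_predicate(pg, 1:3, off, "descending"))
  expect_error(hysteresis_predicate(pg, 1:2, fixed), "at least 3")
})

test_that("the activating three-cycle scores 100 / 20 and is fragile", {
  pg <- build_parameter_graph(net_cycle3())
  ess <- hysteresis_score(pg, "ascending", "partial", "essential")
  expect_equal(ess$score, 100)
  per <- hysteresis_score(pg, "ascending", "partial", "perturbed")
  expect_equal(per$score, 20)
  expect_equal(per$denominator, 5)
  rc <- robustness_and_classification(ess, per)
  expect_equal(rc$robustness, 0.2)
  expect_equal(rc$label, "fragile")
  # strict endpooints reproduce the same classification
  ess_s <- hysteresis_score(pg, "ascending", "partial", "essential",
                            strict_ends = TRUE)
  expect_equal(ess_s$score, 100)
  # boundary arithmetic of the fragile label
  mk <- function(s) structure(list(score = s), class = "score_report")
  expect_equal(robustness_and_classification(mk(80), mk(60))$label, "robust")
  expect_equal(robustness_and_classification(mk(100), mk(50))$label, "fragile")
  expect_equal(robustness_and_classification(mk(0), mk(0))$label,
               "non-switching")
})

test_that("scores do not depend on the order of the parameter-vertex set", {
  # only node 0's paths and the content of the (v1, v2) set matter
  pg <- build_parameter_graph(net_cycle3())
  nb <- one_edge_neighborhood(pg, essential_subgraph(pg))
  shuffled <- nb[c(4L, 1L, 5L, 3L, 2L), ]
  s1 <- hysteresis_score(pg, parameter_set = nb)
  s2 <- hysteresis_score(pg, parameter_set = shuffled)
  expect_equal(s1$score, s2$score)
  expect_equal(s1$score, 20)
})

test_that("perturbation enlarges the denominator and cannot raise the score", {
  for (net in list(net_cycle3(), net_cascade())) {
    pg <- build_parameter_graph(net)
    ess <- hysteresis_score(pg, "ascending", "partial", "essential")
    per <- hysteresis_score(pg, "ascending", "partial", "perturbed")
    expect_gte(per$denominator, ess$denominator)
    expect_lte(per$score, ess$score)
  }
})

test_that("screening ranks deterministically and survives failures", {
  nets <- list(net_cycle3(),
               regulatory_network(matrix(0L, 3L, 3L)),  # trivial, no paths
               parse_network("x0 : (x1)\nx1 : (x0)\nx2 : (x0)"))
  tb <- screen(nets)
  expect_equal(nrow(tb), 3L)
  expect_equal(tb$hysteresis_score[1L], 100)
  expect_true(all(diff(ifelse(is.na(tb$hysteresis_score), -Inf,
                              tb$hysteresis_score)) <= 0))
  empty <- screen(list())
  expect_equal(nrow(empty), 0L)
  # every nontrivial all-activator 3-edge cycle scores 100% at essential
  # parameters (the rotations of the activating cycle)
  cyc <- list(net_cycle3(),
              parse_network("x0 : (x1)\nx1 : (x2)\nx2 : (x0)"))
  sc <- screen(cyc)
  expect_true(all(sc$hysteresis_score == 100))
})
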