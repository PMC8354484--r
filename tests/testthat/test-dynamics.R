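test_that("complex sizes follow the out-threshold counts", {
  pg1 <- build_parameter_graph(net_cycle3())
  expect_equal(nrow(build_complex(pg1, c(1L, 1L, 1L))$cells), 8L)  # 2x2x2
  pg6 <- build_parameter_graph(net_cascade())
  expect_equal(nrow(build_complex(pg6, c(1L, 1L, 1L))$cells), 16L)  # 4x2x2
  pg12 <- build_parameter_graph(net_top())
  expect_equal(nrow(build_complex(pg12, c(1L, 1L, 1L))$cells), 24L)  # 4x2x3
  # 1-node self-repressor: one threshold doubled into three cells
  pgsr <- build_parameter_graph(make_fixture("selfrepressor")$network)
  cx <- build_complex(pgsr, 2L)
  expect_equal(nrow(cx$cells), 3L)
  # collapse consistency: report coordinates use the true threshold count
  expect_equal(cx$nodes[[1L]]$report, c(0L, 0L, 1L))
})

test_that("wall labels recover the low-input flow of the activating cycle", {
  pg <- build_parameter_graph(net_cycle3())
  ess <- essential_subgraph(pg)
  # lowest input vertex: node 0's production always below its threshold,
  # so every axis-0 wall repels its lower side (flow points down)
  walls <- label_walls(pg, c(1L, ess$v1[1L], ess$v2[1L]))
  ax0 <- walls[walls$axis == 0L, ]
  expect_true(all(ax0$label_lower == "repelling"))
  expect_true(all(ax0$label_upper == "absorbing"))
  # a (1,1) node in its high-decay region decays through its threshold
  # from above everywhere, independently of the input state
  walls3 <- label_walls(pg, c(1L, 1L, 2L))
  ax1 <- walls3[walls3$axis == 1L, ]
  expect_true(all(ax1$label_upper == "absorbing"))
})

test_that("STGs of the activating cycle show the hysteresis sequence", {
  pg <- build_parameter_graph(net_cycle3())
  fps <- lapply(1:3, function(v0) build_stg(pg, c(v0, 2L, 2L))$fp$label)
  expect_equal(fps[[1L]], "FP(0, 0, 0)")
  expect_setequal(fps[[2L]], c("FP(0, 0, 0)", "FP(1, 1, 1)"))
  expect_equal(fps[[3L]], "FP(1, 1, 1)")

  # self-activator middle region: both sides of the threshold repel the
  # wall, giving two stable cells and no crossing edge
  pga <- build_parameter_graph(parse_network("x0 : (x0)"))
  stg <- build_stg(pga, 2L)
  expect_equal(sum(stg$self), 2L)
  expect_equal(nrow(stg$edges), 0L)
})

test_that("the self-repression refinement puts the stable state on the thin cell", {
  pgsr <- build_parameter_graph(make_fixture("selfrepressor")$network)
  # middle region: production above the threshold from below, below it
  # from above; the doubled walls carry opposite labels on their inner
  # sides and the thin middle cell is the unique attractor
  stg <- build_stg(pgsr, 2L)
  expect_equal(which(stg$self), 2L)
  expect_equal(stg$fp$label, "FP(0)")
  w <- stg$walls
  expect_equal(w$label_upper[w$pos == 1L], "repelling")
  expect_equal(w$label_lower[w$pos == 2L], "repelling")
  expect_equal(w$label_lower[w$pos == 1L], "absorbing")
  expect_equal(w$label_upper[w$pos == 2L], "absorbing")
})

test_that("Morse graphs condense the STG with consistent minimal nodes", {
  pg <- build_parameter_graph(net_cycle3())
  mg_mid <- morse_graph(build_stg(pg, c(2L, 2L, 2L)))
  expect_equal(sum(mg_mid$nodes$minimal), 2L)
  expect_setequal(mg_mid$nodes$fp[mg_mid$nodes$minimal],
                  c("FP(0, 0, 0)", "FP(1, 1, 1)"))
  mg_hi <- morse_graph(build_stg(pg, c(3L, 2L, 2L)))
  expect_equal(mg_hi$nodes$fp[mg_hi$nodes$minimal], "FP(1, 1, 1)")

  # a pure rotation: one recurrent cycle, no FP label
  pgr <- build_parameter_graph(
    parse_network("x0 : (~x1)\nx1 : (x0)"))
  # pick the essential vertex of both nodes: the repressilator-like loop
  ess2 <- essential_subgraph(pgr, c(0L, 1L))
  stg <- build_stg(pgr, c(ess2$v0[1L], ess2$v1[1L]))
  mg <- morse_graph(stg)
  expect_equal(nrow(mg$nodes), 1L)
  expect_true(is.na(mg$nodes$fp[1L]))
  expect_true(mg$nodes$minimal[1L])
  expect_equal(mg$nodes$n_cells[1L], 4L)
})

test_that("every wall is labeled on both sides at random parameter vertices", {
  set.seed(5)
  for (net in random_networks(6, seed = 21)) {
    if (is_trivial(net)) next
    pg <- build_parameter_graph(net)
    for (rep_ in 1:3) {
      v <- vapply(pg$sizes, function(s) sample.int(s, 1L), integer(1))
      walls <- label_walls(pg, v)
      expect_true(all(walls$label_lower %in% c("absorbing", "repelling")))
      expect_true(all(walls$label_upper %in% c("absorbing", "repelling")))
      mg <- morse_graph(build_stg(pg, v))
      expect_true(nrow(mg$nodes) >= 1L)
      expect_true(any(mg$nodes$minimal))
      # reachability order is acyclic: no mutual edges
      if (!is.null(mg$edges) && nrow(mg$edges)) {
        key <- paste(mg$edges[, 1L], mg$edges[, 2L])
        rev_ <- paste(mg$edges[, 2L], mg$edges[, 1L])
        expect_false(any(key %in% rev_))
      }
    }
  }
})
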