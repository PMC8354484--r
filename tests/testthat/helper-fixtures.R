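# shared helpers: fixtures, independent oracles, small utilities

net_cycle3 <- function() make_fixture("network1")$network
net_cascade <- function() make_fixture("network6")$network
net_top <- function() make_fixture("network12")$network

# evaluate the inequality strings of a parameter_region at named values —
# an oracle independent of the region construction (plain arithmetic on the
# substituted strings)
eval_region_inequalities <- function(region, values = region$witness,
                                     margin = 0) {
  vals <- values
  syms <- names(vals)
  syms <- syms[order(-nchar(syms))]
  ok <- vapply(region$inequalities, function(ineq) {
    for (s in syms) {
      ineq <- gsub(s, format(vals[[s]], digits = 17), ineq, fixed = TRUE)
    }
    sides <- strsplit(ineq, "<", fixed = TRUE)[[1L]]
    stopifnot(length(sides) == 2L)
    lhs <- eval(parse(text = sides[1L]), envir = baseenv())
    rhs <- eval(parse(text = sides[2L]), envir = baseenv())
    lhs < rhs - margin
  }, logical(1))
  all(ok)
}

# brute-force path enumeration oracle on a factor-graph class DAG:
# all monotone paths with >= min_vertices vertices (chain-index space)
brute_force_paths <- function(fg, kind = "partial", min_vertices = 3L) {
  C <- fg$per_class
  adj <- lapply(seq_len(C), function(v) fg$cover_to[fg$cover_from == v])
  starts <- if (kind == "full") fg_min <- which(rowSums(fg$chains != 0L) == 0L)
  else seq_len(C)
  ends <- if (kind == "full") {
    full <- 2L^fg$shape$n_states - 1L
    which(rowSums(fg$chains != full) == 0L)
  } else seq_len(C)
  out <- list()
  walk <- function(path) {
    v <- path[length(path)]
    if (length(path) >= min_vertices && v %in% ends) {
      out[[length(out) + 1L]] <<- path
    }
    for (w in adj[[v]]) walk(c(path, w))
  }
  for (s in starts) walk(s)
  out
}

# random positive node parameters for the partition oracle
random_node_params <- function(shape, sdlog = 1) {
  list(
    gamma = 1,
    ell = if (shape$m > 0L) stats::rlnorm(shape$m, -0.5, sdlog) else NULL,
    delta = if (shape$m > 0L) stats::rlnorm(shape$m, 0, sdlog) else NULL,
    theta = stats::rlnorm(shape$k, 0.5, sdlog),
    beta = if (shape$m == 0L) stats::rlnorm(1, 0, sdlog) else NULL
  )
}

# a small pool of random valid 3-node networks for property loops
# (in-degree capped at 2 so factor enumeration stays fast inside loops)
random_networks <- function(n, seed = 1L, max_in = 2L) {
  set.seed(seed)
  lapply(seq_len(n), function(i) {
    m <- matrix(sample(c(-1L, 0L, 1L), 9L, replace = TRUE), 3L, 3L)
    for (r in 1:3) {
      nz <- which(m[r, ] != 0L)
      if (length(nz) > max_in) {
        m[r, sample(nz, length(nz) - max_in)] <- 0L
      }
    }
    regulatory_network(m)
  })
}
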