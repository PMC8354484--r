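# The parameter graph: product of the per-node factor graphs.  A parameter
# vertex is one factor-graph vertex id per node; the combinatorial dynamics
# is constant on the open parameter region it indexes.

#' Build the parameter graph of a network
#'
#' Enumerates the factor graph of every node (see
#' [enumerate_factor_graph()]) and assembles the product structure.  The
#' vertex set is the Cartesian product of the factor vertex sets; an edge
#' changes exactly one coordinate along a factor-graph edge.  Vertices are
#' handled as coordinate vectors rather than materialized.
#'
#' @param net a [regulatory_network()].
#' @param eps strictness margin for region feasibility.
#' @return An object of class `parameter_graph` with elements `net`, `fgs`
#'   (list of factor graphs indexed by node + 1), `sizes`, and `n_vertices`.
#' @examples
#' pg <- build_parameter_graph(parse_network("x0 : (x2)\nx1 : (x0)\nx2 : (x1)"))
#' pg$n_vertices  # 27
#' @export
build_parameter_graph <- function(net, eps = 1e-6) {
  fgs <- lapply(seq_len(n_nodes(net)) - 1L, function(n) {
    enumerate_factor_graph(net, n, eps = eps)
  })
  sizes <- vapply(fgs, function(f) f$n_vertices, integer(1))
  structure(list(net = net, fgs = fgs, sizes = sizes,
                 n_vertices = prod(as.numeric(sizes)), eps = eps),
            class = "parameter_graph")
}

#' @export
print.parameter_graph <- function(x, ...) {
  cat("<parameter_graph> ", format(x$n_vertices, big.mark = ","),
      " vertices = ", paste(x$sizes, collapse = " x "), "\n", sep = "")
  invisible(x)
}

check_pvertex <- function(pg, vertex) {
  vertex <- as.integer(vertex)
  if (length(vertex) != length(pg$fgs) ||
      any(vertex < 1L | vertex > pg$sizes)) {
    stop("invalid parameter vertex", call. = FALSE)
  }
  vertex
}

#' Essential vertex combinations of selected nodes
#'
#' Restricts the listed nodes to their essential factor vertices (every
#' in-edge and out-edge dynamically relevant) and returns the coordinate
#' grid over those nodes.  Coordinates of unlisted nodes are unconstrained:
#' an empty `nodes` vector yields the neutral one-row, zero-column grid,
#' i.e. all parameter vertices.
#'
#' @param pg a [build_parameter_graph()] result.
#' @param nodes 0-based node indices to restrict (default `c(1, 2)`, the
#'   non-input nodes of a three-node switch).
#' @return A tibble with one column `v<node>` per listed node, one row per
#'   essential combination.
#' @export
essential_subgraph <- function(pg, nodes = c(1L, 2L)) {
  nodes <- as.integer(nodes)
  if (length(nodes) == 0L) return(tibble::as_tibble(data.frame(row.names = 1L)))
  cols <- lapply(nodes, function(n) fg_essential_ids(pg$fgs[[n + 1L]]))
  names(cols) <- paste0("v", nodes)
  grid <- rev(expand.grid(rev(cols), KEEP.OUT.ATTRS = FALSE))
  tibble::as_tibble(grid)
}

#' Closed one-edge neighborhood in the parameter graph
#'
#' Expands a vertex set over the listed nodes by all vertices at product
#' distance at most one, moving a single listed coordinate along one
#' factor-graph edge.  The result always contains the input set and the
#' operation is monotone in it.
#'
#' @param pg a [build_parameter_graph()] result.
#' @param vset tibble with columns `v<node>` for the listed nodes (as from
#'   [essential_subgraph()]).
#' @param nodes 0-based node indices whose coordinates may move; defaults to
#'   the columns of `vset`.
#' @return A tibble of the same shape, rows sorted and unique.
#' @export
one_edge_neighborhood <- function(pg, vset, nodes = NULL) {
  if (is.null(nodes)) {
    nodes <- as.integer(sub("^v", "", names(vset)))
  }
  if (nrow(vset) == 0L) return(vset)
  rows <- list(as.matrix(vset))
  for (j in seq_along(nodes)) {
    fg <- pg$fgs[[nodes[j] + 1L]]
    nbr <- rbind(cbind(fg$adj_from, fg$adj_to), cbind(fg$adj_to, fg$adj_from))
    for (r in seq_len(nrow(vset))) {
      hits <- nbr[nbr[, 1L] == vset[[j]][r], 2L]
      if (length(hits)) {
        block <- matrix(rep(as.integer(vset[r, , drop = TRUE]),
                            each = length(hits)),
                        nrow = length(hits))
        block[, j] <- hits
        rows[[length(rows) + 1L]] <- block
      }
    }
  }
  out <- unique(as.data.frame(do.call(rbind, rows)))
  names(out) <- names(vset)
  out <- out[do.call(order, out), , drop = FALSE]
  rownames(out) <- NULL
  tibble::as_tibble(out)
}

# symbol helpers for the inequality grammar
sym_gamma <- function(n) sprintf("γ[%d]", n)
sym_l <- function(n, m) sprintf("l[%d][%d]", n, m)
sym_d <- function(n, m) sprintf("d[%d][%d]", n, m)
sym_b <- function(n) sprintf("b[%d]", n)
sym_t <- function(m, n) {
  if (is.na(m)) sprintf("t[.][%d]", n) else sprintf("t[%d][%d]", m, n)
}

# per-node parameter names and witness values for one factor vertex
node_witness_params <- function(fg, id) {
  shape <- fg$shape
  n <- fg$node
  w <- fg_witness(fg, id)
  ord <- fg_order(fg, id)
  tg <- if (shape$placeholder) NA_integer_ else shape$targets[ord]
  nm <- c(sym_gamma(n),
          if (shape$m > 0L) sym_l(n, shape$sources),
          if (shape$m > 0L) sym_d(n, shape$sources),
          if (shape$m == 0L) sym_b(n),
          vapply(tg, sym_t, character(1), n = n))
  val <- c(w$gamma, w$ell, w$delta, w$beta, w$theta)
  names(val) <- nm
  val
}

#' Explicit inequalities and witness of a parameter region
#'
#' Emits the full conjunction of strict inequalities defining the open
#' region indexed by a parameter vertex: for every node, the threshold-order
#' inequalities, one comparison per (input state, threshold) pair between
#' the production value and the scaled threshold, and positivity of every
#' parameter.  Inequality strings use the grammar `lhs < rhs` with symbols
#' `γ[n]`, `l[n][m]`, `d[n][m]`, `t[m][n]`, `b[n]` (the placeholder
#' threshold of a node without out-edges prints as `t[.][n]`).
#'
#' @param pg a [build_parameter_graph()] result.
#' @param vertex integer vector: one factor-vertex id per node.
#' @return An object of class `parameter_region`: list with `vertex`,
#'   `inequalities` (character) and `witness` (named numeric, all entries
#'   strictly positive and satisfying every inequality).
#' @export
region_inequalities <- function(pg, vertex) {
  vertex <- check_pvertex(pg, vertex)
  ineqs <- character(0)
  witness <- numeric(0)
  for (n1 in seq_along(pg$fgs)) {
    fg <- pg$fgs[[n1]]
    n <- fg$node
    shape <- fg$shape
    id <- vertex[n1]
    ord <- fg_order(fg, id)
    masks <- fg_masks(fg, id)
    tg <- if (shape$placeholder) NA_integer_ else shape$targets[ord]
    tsyms <- vapply(tg, sym_t, character(1), n = n)
    scaled <- sprintf("%s * %s", sym_gamma(n), tsyms)
    # threshold order
    if (shape$k > 1L) {
      ineqs <- c(ineqs, sprintf("%s < %s", scaled[-shape$k], scaled[-1L]))
    }
    # binarization comparisons
    exprs <- production_value_exprs(pg$net, n)$expr
    for (i in seq_len(shape$k)) {
      above <- bitwAnd(masks[i], bitwShiftL(1L, 0:(shape$n_states - 1L))) != 0L
      ineqs <- c(ineqs,
                 sprintf("%s < %s", scaled[i], exprs[above]),
                 sprintf("%s < %s", exprs[!above], scaled[i]))
    }
    pars <- node_witness_params(fg, id)
    ineqs <- c(ineqs, sprintf("0 < %s", names(pars)))
    witness <- c(witness, pars)
  }
  structure(list(vertex = vertex, inequalities = ineqs, witness = witness),
            class = "parameter_region")
}

#' @export
print.parameter_region <- function(x, ...) {
  cat("<parameter_region> vertex (", paste(x$vertex, collapse = ", "),
      "): ", length(x$inequalities), " inequalities\n", sep = "")
  cat(" witness: ", paste(sprintf("%s = %.4g", names(x$witness), x$witness),
                          collapse = ", "), "\n", sep = "")
  invisible(x)
}

# run code with a private, restored RNG stream
with_seed <- function(seed, code) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# draw one jittered copy of a node's parameters that stays in its region
sample_node_params <- function(fg, id, sigma, max_rej) {
  w <- fg_witness(fg, id)
  shape <- fg$shape
  ord <- fg_order(fg, id)
  for (rej in seq_len(max_rej)) {
    ell <- w$ell * exp(stats::rnorm(length(w$ell), 0, sigma))
    delta <- w$delta * exp(stats::rnorm(length(w$delta), 0, sigma))
    theta <- w$theta * exp(stats::rnorm(length(w$theta), 0, sigma))
    beta <- if (is.null(w$beta)) NULL else w$beta * exp(stats::rnorm(1, 0, sigma))
    # classifier expects thresholds in ascending-target order
    theta_bt <- numeric(shape$k); theta_bt[ord] <- theta
    cls <- classify_node_parameters(fg, gamma = w$gamma, ell = ell,
                                    delta = delta, theta = theta_bt, beta = beta)
    if (!is.na(cls) && cls == id) {
      return(list(gamma = w$gamma, ell = ell, delta = delta, theta = theta,
                  beta = beta))
    }
  }
  stop("sampler failed after ", max_rej, " rejections for factor vertex ",
       id, " of node ", fg$node, call. = FALSE)
}

#' Sample numeric parameters from a region
#'
#' Draws strictly positive parameter vectors from the open region of a
#' parameter vertex: each node's witness is jittered log-normally and
#' rejection-checked against the exact region inequalities (classification
#' back onto the same factor vertex).  Decay rates stay at `gamma = 1`, the
#' scale the witnesses are normalized to.  Membership is guaranteed;
#' uniformity over the (unbounded) region is not.
#'
#' @param pg a [build_parameter_graph()] result.
#' @param vertex integer vector: one factor-vertex id per node.
#' @param count number of samples.
#' @param seed integer seed; the draw is deterministic given `seed`.
#' @param sigma log-normal jitter scale.
#' @param max_rej rejection cap per node and sample.
#' @return A tibble with `count` rows and one named column per parameter.
#' @export
sample_parameters <- function(pg, vertex, count, seed = 1L, sigma = 0.25,
                              max_rej = 10000L) {
  vertex <- check_pvertex(pg, vertex)
  names_ <- names(region_inequalities(pg, vertex)$witness)
  if (count == 0L) {
    out <- as.data.frame(matrix(numeric(0), 0L, length(names_)))
    names(out) <- names_
    return(tibble::as_tibble(out))
  }
  with_seed(seed, {
    rows <- lapply(seq_len(count), function(i) {
      unlist(lapply(seq_along(pg$fgs), function(n1) {
        p <- sample_node_params(pg$fgs[[n1]], vertex[n1], sigma, max_rej)
        node_params_vector(pg$fgs[[n1]], vertex[n1], p)
      }))
    })
    out <- as.data.frame(do.call(rbind, rows))
    names(out) <- names_
    tibble::as_tibble(out)
  })
}

node_params_vector <- function(fg, id, p) {
  c(p$gamma, p$ell, p$delta, p$beta, p$theta)
}

#' Classify a full numeric parameter vector onto a parameter vertex
#'
#' @param pg a [build_parameter_graph()] result.
#' @param params named numeric vector using the symbol grammar of
#'   [region_inequalities()] (as produced by [sample_parameters()]).
#' @return Integer vector of factor-vertex ids (one per node), or `NA`
#'   entries where classification fails.
#' @export
classify_parameters <- function(pg, params) {
  vapply(seq_along(pg$fgs), function(n1) {
    fg <- pg$fgs[[n1]]
    shape <- fg$shape
    n <- fg$node
    gamma <- params[[sym_gamma(n)]]
    ell <- if (shape$m > 0L) unname(params[sym_l(n, shape$sources)]) else NULL
    delta <- if (shape$m > 0L) unname(params[sym_d(n, shape$sources)]) else NULL
    beta <- if (shape$m == 0L) params[[sym_b(n)]] else NULL
    # thresholds in ascending-target order, whatever the vertex's class
    tg <- if (shape$placeholder) NA_integer_ else shape$targets
    theta <- unname(params[vapply(tg, sym_t, character(1), n = n)])
    classify_node_parameters(fg, gamma = gamma, ell = ell, delta = delta,
                             theta = theta, beta = beta)
  }, integer(1))
}
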