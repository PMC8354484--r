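# Hysteresis scoring over monotone signal paths.
#
# A change of the external input to node 0 traces a monotone path through
# one threshold-order class of PG(0), the input node's factor graph, while
# the other nodes' coordinates (v1, v2) stay fixed.  A path exhibits
# ascending hysteresis when the first vertex has a stable state with output
# coordinate 0, the last vertex one with output coordinate > 0, and some
# strictly intermediate vertex has both at once (bistability).  Scores
# aggregate over paths and over a set of (v1, v2) vertices.

# directed acyclic cover graph of one threshold-order class of a factor
# graph, in chain-index space (edges add one input state: low -> high
# production)
class_dag <- function(fg) {
  C <- fg$per_class
  inc <- vector("list", C)
  for (e in seq_along(fg$cover_from)) {
    t <- fg$cover_to[e]
    inc[[t]] <- c(inc[[t]], fg$cover_from[e])
  }
  list(C = C, incoming = inc, topo = order(fg$sizes))
}

# number of directed paths with >= 2 edges from an allowed start to an
# allowed end whose strictly interior vertices all lie in `allowed`
count_constrained_paths <- function(dag, start_ok, end_ok, allowed) {
  b <- numeric(dag$C)
  for (x in dag$topo) {
    ys <- dag$incoming[[x]]
    if (length(ys)) {
      b[x] <- sum(start_ok[ys] + allowed[ys] * b[ys])
    }
  }
  total <- 0
  for (x in which(end_ok)) {
    ys <- dag$incoming[[x]]
    if (length(ys)) total <- total + sum(allowed[ys] * b[ys])
  }
  total
}

#' Count (and optionally enumerate) monotone signal paths
#'
#' Counts the strictly monotone paths of at least three vertices in one
#' threshold-order class of a factor graph: `"partial"` paths may start and
#' end anywhere; `"full"` paths run from the class's unique minimal vertex
#' (all production values below all thresholds) to its unique maximal
#' vertex.  Counting is exact dynamic programming over the class's cover
#' DAG; paths are also enumerated when their number does not exceed `cap`.
#'
#' @param fg a factor graph (usually of the input node).
#' @param kind `"partial"` or `"full"`.
#' @param class threshold-order class (1 = thresholds ordered as the
#'   out-targets are listed).
#' @param cap enumeration cap; set to 0 to skip enumeration.
#' @return A list with `count` (double) and `paths` (list of integer
#'   vectors of vertex ids, or `NULL` when `count > cap`).
#' @export
enumerate_or_count_paths <- function(fg, kind = c("partial", "full"),
                                     class = 1L, cap = 10000L) {
  kind <- match.arg(kind)
  dag <- class_dag(fg)
  C <- dag$C
  if (kind == "full") {
    start_ok <- end_ok <- logical(C)
    start_ok[fg_chain_index_min(fg)] <- TRUE
    end_ok[fg_chain_index_max(fg)] <- TRUE
  } else {
    start_ok <- end_ok <- rep(TRUE, C)
  }
  count <- count_constrained_paths(dag, start_ok, end_ok, rep(TRUE, C))
  paths <- NULL
  if (cap > 0L && count <= cap) {
    out <- vector("list", 0L)
    walk <- function(path) {
      x <- path[length(path)]
      if (length(path) >= 3L && end_ok[x]) out[[length(out) + 1L]] <<- path
      for (e in which(fg$cover_from == x)) walk(c(path, fg$cover_to[e]))
    }
    for (s in which(start_ok)) walk(s)
    offset <- (class - 1L) * fg$per_class
    paths <- lapply(out, function(p) p + offset)
  }
  list(count = count, paths = paths)
}

fg_chain_index_min <- function(fg) which(rowSums(fg$chains != 0L) == 0L)
fg_chain_index_max <- function(fg) {
  full <- 2L^fg$shape$n_states - 1L
  which(rowSums(fg$chains != full) == 0L)
}

# stable-state flags of every class vertex of PG(0) at fixed (v1, v2, ...):
# low = an FP with output coordinate 0, high = one with output coordinate
# > 0
path_vertex_flags <- function(pg, fixed, class = 1L) {
  fg0 <- pg$fgs[[pg$net$input_node + 1L]]
  offset <- (class - 1L) * fg0$per_class
  n1 <- pg$net$input_node + 1L
  t(vapply(seq_len(fg0$per_class), function(i) {
    vertex <- fixed
    vertex[n1] <- offset + i
    oc <- stable_output_coords(pg, vertex)
    c(low = any(oc == 0L), high = any(oc > 0L))
  }, logical(2)))
}

#' Hysteresis predicate along one explicit path
#'
#' Evaluates the switching predicate for a single monotone path in PG(0)
#' at fixed coordinates of the remaining nodes.  Ascending mode requires a
#' stable state with output coordinate 0 at the first vertex, one with
#' output coordinate greater than 0 at the last vertex, and both
#' simultaneously at some strictly intermediate vertex; descending mode
#' mirrors the endpoint conditions.  `strict_ends` additionally forbids a
#' high stable state at the start and a low one at the end (monostable
#' endpoints).
#'
#' @param pg a [build_parameter_graph()] result.
#' @param path integer vector of at least three PG(0) vertex ids, strictly
#'   monotone along factor-graph edges.
#' @param fixed integer vector of factor ids, one per node (the input
#'   node's entry is overwritten by the path).
#' @param mode `"ascending"` or `"descending"`.
#' @param strict_ends require monostable endpoints.
#' @return Logical scalar.
#' @export
hysteresis_predicate <- function(pg, path, fixed,
                                 mode = c("ascending", "descending"),
                                 strict_ends = FALSE) {
  mode <- match.arg(mode)
  if (length(path) < 3L) stop("paths must have at least 3 vertices",
                              call. = FALSE)
  n1 <- pg$net$input_node + 1L
  flags <- t(vapply(path, function(v0) {
    vertex <- fixed
    vertex[n1] <- v0
    oc <- stable_output_coords(pg, vertex)
    c(low = any(oc == 0L), high = any(oc > 0L))
  }, logical(2)))
  lo <- flags[, "low"]; hi <- flags[, "high"]
  interior <- seq_along(path)[-c(1L, length(path))]
  if (mode == "ascending") {
    ok <- lo[1L] && hi[length(path)] && any(lo[interior] & hi[interior])
    if (strict_ends) ok <- ok && !hi[1L] && !lo[length(path)]
  } else {
    ok <- hi[1L] && lo[length(path)] && any(lo[interior] & hi[interior])
    if (strict_ends) ok <- ok && !lo[1L] && !hi[length(path)]
  }
  ok
}

# hysteretic path count at one fixed (v1, v2): inclusion-exclusion over the
# bistable-interior condition
hysteretic_path_count <- function(dag, flags, kind, fg0, mode, strict_ends) {
  lo <- flags[, "low"]; hi <- flags[, "high"]
  C <- dag$C
  if (mode == "ascending") {
    start_ok <- lo; end_ok <- hi
    if (strict_ends) { start_ok <- lo & !hi; end_ok <- hi & !lo }
  } else {
    start_ok <- hi; end_ok <- lo
    if (strict_ends) { start_ok <- hi & !lo; end_ok <- lo & !hi }
  }
  if (kind == "full") {
    smask <- emask <- logical(C)
    smask[fg_chain_index_min(fg0)] <- TRUE
    emask[fg_chain_index_max(fg0)] <- TRUE
    start_ok <- start_ok & smask
    end_ok <- end_ok & emask
  }
  with_bi <- count_constrained_paths(dag, start_ok, end_ok, rep(TRUE, C))
  without_bi <- count_constrained_paths(dag, start_ok, end_ok, !(lo & hi))
  with_bi - without_bi
}

#' Hysteresis score of a network
#'
#' Scores the prevalence of switch-like behaviour: the percentage of
#' (path, parameter-vertex) pairs that satisfy the hysteresis predicate,
#' where paths are the monotone paths of at least three vertices (or the
#' minimal-to-maximal full paths) in one threshold-order class of the input
#' node's factor graph, and parameter vertices range over a set of
#' coordinates for the non-input nodes: their essential combinations, the
#' closed one-edge neighborhood of those, or an explicit tibble.  Counting
#' is exact (dynamic programming with endpoint and bistable-interior
#' constraints); no path is enumerated.
#'
#' @param pg a [build_parameter_graph()] result (or a
#'   [regulatory_network()], for which one is built).
#' @param mode `"ascending"` or `"descending"`.
#' @param path_kind `"partial"` or `"full"`.
#' @param parameter_set `"essential"`, `"perturbed"` (closed one-edge
#'   neighborhood of essential), or a tibble of `v<node>` columns.
#' @param class threshold-order class of the input node's factor graph.
#' @param strict_ends require monostable path endpoints.
#' @return An object of class `score_report`; see [tidy.score_report()].
#' @examples
#' \donttest{
#' pg <- build_parameter_graph(parse_network("x0 : (x2)\nx1 : (x0)\nx2 : (x1)"))
#' hysteresis_score(pg)  # 100% on the activating three-cycle
#' }
#' @export
hysteresis_score <- function(pg, mode = c("ascending", "descending"),
                             path_kind = c("partial", "full"),
                             parameter_set = "essential",
                             class = 1L, strict_ends = FALSE) {
  mode <- match.arg(mode)
  path_kind <- match.arg(path_kind)
  if (inherits(pg, "regulatory_network")) pg <- build_parameter_graph(pg)
  net <- pg$net
  other_nodes <- setdiff(seq_len(n_nodes(net)) - 1L, net$input_node)
  pset <- parameter_set
  if (is.character(pset) && length(pset) == 1L) {
    ess <- essential_subgraph(pg, other_nodes)
    pset <- switch(pset,
                   essential = ess,
                   perturbed = one_edge_neighborhood(pg, ess, other_nodes),
                   stop("unknown parameter set ", dQuote(parameter_set),
                        call. = FALSE))
  }
  fg0 <- pg$fgs[[net$input_node + 1L]]
  dag <- class_dag(fg0)
  n_paths <- enumerate_or_count_paths(fg0, path_kind, class, cap = 0L)$count
  denom <- n_paths * nrow(pset)

  per_param <- numeric(nrow(pset))
  if (denom > 0) {
    pset_nodes <- as.integer(sub("^v", "", names(pset)))
    for (r in seq_len(nrow(pset))) {
      fixed <- rep(1L, n_nodes(net))
      fixed[pset_nodes + 1L] <- as.integer(pset[r, , drop = TRUE])
      flags <- path_vertex_flags(pg, fixed, class)
      per_param[r] <- hysteretic_path_count(dag, flags, path_kind, fg0,
                                            mode, strict_ends)
    }
  }
  numer <- sum(per_param)
  structure(list(
    network = serialize_network(net),
    mode = mode, path_kind = path_kind,
    parameter_set = if (is.character(parameter_set)) parameter_set else "explicit",
    class = class, strict_ends = strict_ends,
    n_paths = n_paths, n_param = nrow(pset),
    numerator = numer, denominator = denom,
    score = if (denom > 0) 100 * numer / denom else NA_real_,
    per_param = tibble::tibble(pset, hysteretic = per_param)
  ), class = "score_report")
}

#' @export
print.score_report <- function(x, ...) {
  cat("<score_report> ", x$mode, " hysteresis, ", x$path_kind, " paths, ",
      x$parameter_set, " parameters\n", sep = "")
  if (is.na(x$score)) {
    cat("  undefined (", x$n_paths, " paths x ", x$n_param,
        " parameter vertices)\n", sep = "")
  } else {
    cat(sprintf("  score %.4g%% (%s of %s path-parameter pairs)\n", x$score,
                format(x$numerator, big.mark = ","),
                format(x$denominator, big.mark = ",")))
  }
  invisible(x)
}

#' Robustness ratio and fragile/robust classification
#'
#' The robustness of a switch design is its perturbed hysteresis score
#' divided by its hysteresis score; designs at or below `0.5` are labeled
#' fragile (they lose most of their switching when one factor coordinate is
#' perturbed off the essential set), those above are robust.  A design with
#' zero (or undefined) essential score is labeled non-switching.
#'
#' @param report_essential,report_perturbed `score_report`s for the same
#'   network at essential and perturbed parameter sets.
#' @return A list with `robustness` (ratio or `NA`) and `label`.
#' @export
robustness_and_classification <- function(report_essential, report_perturbed) {
  se <- report_essential$score
  sp <- report_perturbed$score
  if (is.na(se) || se == 0) {
    return(list(robustness = NA_real_, label = "non-switching"))
  }
  r <- sp / se
  list(robustness = r, label = if (r <= 0.5) "fragile" else "robust")
}

#' Screen a collection of networks for hysteresis
#'
#' Runs [hysteresis_score()] at essential and perturbed parameter sets over
#' a collection of networks and returns the ranked table (descending
#' essential score, ties broken by the canonical network id).  Per-network
#' failures are recorded in the `error` column, not raised.
#'
#' @param networks a list of [regulatory_network()]s, or a tibble from
#'   [enumerate_three_node_networks()].
#' @param mode,path_kind,class,strict_ends passed to [hysteresis_score()].
#' @param eps feasibility margin for factor graphs.
#' @param progress print one line per network.
#' @return A tibble with one row per network: `network_id`, `spec`,
#'   `n_edges`, `consistent`, `hysteresis_score`, `perturbed_score`,
#'   `robustness`, `fragile`, `label`, the score denominators, and `error`.
#' @export
screen <- function(networks, mode = "ascending", path_kind = "partial",
                   class = 1L, strict_ends = FALSE, eps = 1e-6,
                   progress = FALSE) {
  if (is.data.frame(networks)) {
    ids <- networks$id
    nets <- lapply(seq_len(nrow(networks)), function(i) as_network(networks[i, ]))
  } else {
    nets <- networks
    ids <- seq_along(nets)
  }
  rows <- lapply(seq_along(nets), function(i) {
    net <- nets[[i]]
    base <- tibble::tibble(
      network_id = ids[i],
      spec = paste(serialize_network(net), collapse = "; "),
      n_edges = n_edges(net),
      consistent = all(node_consistency(net)$role != "mixed"),
      hysteresis_score = NA_real_, perturbed_score = NA_real_,
      robustness = NA_real_, fragile = NA, label = NA_character_,
      n_paths = NA_real_, n_param_essential = NA_real_,
      n_param_perturbed = NA_real_, error = NA_character_
    )
    res <- tryCatch({
      pg <- build_parameter_graph(net, eps = eps)
      ess <- hysteresis_score(pg, mode, path_kind, "essential", class,
                              strict_ends)
      per <- hysteresis_score(pg, mode, path_kind, "perturbed", class,
                              strict_ends)
      rc <- robustness_and_classification(ess, per)
      base$hysteresis_score <- ess$score
      base$perturbed_score <- per$score
      base$robustness <- rc$robustness
      base$fragile <- identical(rc$label, "fragile")
      base$label <- rc$label
      base$n_paths <- ess$n_paths
      base$n_param_essential <- ess$n_param
      base$n_param_perturbed <- per$n_param
      base
    }, error = function(e) {
      base$error <- conditionMessage(e)
      base
    })
    if (progress) {
      cat(sprintf("[%d/%d] id=%s score=%s\n", i, length(nets), ids[i],
                  format(res$hysteresis_score)))
    }
    res
  })
  if (length(rows) == 0L) {
    out <- tibble::tibble(
      network_id = integer(0), spec = character(0), n_edges = integer(0),
      consistent = logical(0), hysteresis_score = numeric(0),
      perturbed_score = numeric(0), robustness = numeric(0),
      fragile = logical(0), label = character(0), n_paths = numeric(0),
      n_param_essential = numeric(0), n_param_perturbed = numeric(0),
      error = character(0))
    class(out) <- c("switch_screen", class(out))
    return(out)
  }
  out <- do.call(rbind, rows)
  out <- out[order(-ifelse(is.na(out$hysteresis_score), -Inf,
                           out$hysteresis_score),
                   out$network_id), ]
  class(out) <- c("switch_screen", class(out))
  out
}
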