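# Combinatorial dynamics: cubical phase-space complex, wall labels, state
# transition graph (STG) and Morse graph at one parameter vertex.
#
# Phase space (0, Inf)^N is cut by the threshold hyperplanes x_n = theta_{m,n}
# into rectangular top cells.  On each wall (shared face of two adjacent
# cells) the sign of -gamma_n * theta + production value decides whether the
# wall absorbs or repels each side; those labels induce the STG.  A node
# with a repressing self-edge gets its self-threshold doubled (one extra
# thin cell) so that every wall keeps a consistent label; a node without
# out-edges gets a placeholder threshold.

#' Build the cubical phase-space complex at a parameter vertex
#'
#' @param pg a [build_parameter_graph()] result.
#' @param vertex integer vector: one factor-vertex id per node.
#' @return An object of class `cubical_complex`: per-node extents (with the
#'   doubled index for self-repressing nodes), the cell table, and the
#'   report-coordinate maps that collapse refined indices back to true
#'   threshold counts.
#' @export
build_complex <- function(pg, vertex) {
  vertex <- check_pvertex(pg, vertex)
  net <- pg$net
  N <- n_nodes(net)
  nodes <- vector("list", N)
  for (n1 in seq_len(N)) {
    n <- n1 - 1L
    fg <- pg$fgs[[n1]]
    shape <- fg$shape
    ord <- fg_order(fg, vertex[n1])
    selfrep <- !shape$placeholder && net$coeffs[n1, n1] == -1L
    E <- shape$k
    k <- if (selfrep) which(shape$targets[ord] == n) else NA_integer_
    ext <- E + as.integer(selfrep)
    truelev <- if (selfrep) {
      c(seq_len(k), k, if (k < E) (k + 1L):E)  # refined pos -> true level
    } else seq_len(E)
    report <- if (selfrep) {
      # cell coord 0..ext -> number of true thresholds strictly below
      vapply(0:ext, function(j) {
        if (j <= k - 1L) j else if (j == k) k - 1L else j - 1L
      }, integer(1))
    } else 0:ext
    nodes[[n1]] <- list(node = n, E = E, ext = ext, selfrep = selfrep, k = k,
                        order = ord, targets = shape$targets,
                        truelev = truelev, report = report,
                        masks = fg_masks(fg, vertex[n1]), shape = shape)
  }
  ext <- vapply(nodes, function(x) x$ext, integer(1))
  cells <- as.matrix(rev(expand.grid(rev(lapply(ext, function(e) 0:e)),
                                     KEEP.OUT.ATTRS = FALSE)))
  dimnames(cells) <- list(NULL, net$node_names)
  structure(list(net = net, vertex = vertex, nodes = nodes, ext = ext,
                 cells = cells),
            class = "cubical_complex")
}

#' @export
print.cubical_complex <- function(x, ...) {
  cat("<cubical_complex> ", nrow(x$cells), " cells (",
      paste(x$ext + 1L, collapse = " x "), ")\n", sep = "")
  invisible(x)
}

# refined position of threshold theta_{target, source} on the source axis
refined_threshold_pos <- function(cx, source, target) {
  info <- cx$nodes[[source + 1L]]
  q <- which(info$targets[info$order] == target)
  stopifnot(length(q) == 1L)
  if (info$selfrep && q > info$k) q + 1L else q
}

# input-state index of node n for every cell, with sliver coordinates of
# self-repressing nodes replaced by the cell just below the doubled
# threshold (valid: input states of other nodes agree on both sides)
cell_states <- function(cx, n) {
  info <- cx$nodes[[n + 1L]]
  shape <- info$shape
  st <- integer(nrow(cx$cells))
  if (shape$m == 0L) return(st)
  for (j in seq_len(shape$m)) {
    m <- shape$sources[j]
    minfo <- cx$nodes[[m + 1L]]
    coord <- cx$cells[, m + 1L]
    if (minfo$selfrep) coord <- ifelse(coord == minfo$k, minfo$k - 1L, coord)
    r <- refined_threshold_pos(cx, m, n)
    st <- st + bitwShiftL(as.integer(coord >= r), j - 1L)
  }
  st
}

# is the input state above threshold level q of node n's binarization?
state_above <- function(info, state, q) {
  bitwAnd(info$masks[q], bitwShiftL(1L, state)) != 0L
}

#' Label every interior wall at a parameter vertex
#'
#' For a wall on axis `n`, the side in a top cell `C` is `absorbing` when
#' the flow of `x_n` at the wall points out of `C` (the production value of
#' `C`'s input state lies beyond the wall's scaled threshold) and
#' `repelling` otherwise.  For the doubled self-repression threshold the
#' outer sides are labeled classically, the thin-cell side takes the
#' opposite label, and walls between thin cells inherit their labels from
#' the neighboring classical walls.  Boundary faces at `0` and infinity are
#' repelling (inward flow) and are not listed.
#'
#' @param pg a [build_parameter_graph()] result.
#' @param vertex integer vector: one factor-vertex id per node.
#' @return A tibble with columns `axis` (0-based node), `pos` (refined
#'   threshold position), `lower`, `upper` (cell row indices into the
#'   complex's cell table), `label_lower`, `label_upper`.
#' @export
label_walls <- function(pg, vertex) {
  cx <- build_complex(pg, vertex)
  wall_table(cx)
}

wall_table <- function(cx) {
  N <- length(cx$nodes)
  cells <- cx$cells
  strides <- c(rev(cumprod(rev(cx$ext + 1L)))[-1L], 1L)
  cell_index <- function(coords) 1L + as.integer(coords %*% strides)
  states <- lapply(seq_len(N) - 1L, function(n) cell_states(cx, n))
  out <- list()
  for (n1 in seq_len(N)) {
    info <- cx$nodes[[n1]]
    st <- states[[n1]]
    for (p in seq_len(info$ext)) {
      lo_rows <- which(cells[, n1] == p - 1L)
      hi_coords <- cells[lo_rows, , drop = FALSE]
      hi_coords[, n1] <- p
      hi_rows <- cell_index(hi_coords)
      q <- info$truelev[p]
      if (info$selfrep && p == info$k) {
        lab_lo <- ifelse(state_above(info, st[lo_rows], q),
                         "absorbing", "repelling")
        lab_hi <- ifelse(lab_lo == "absorbing", "repelling", "absorbing")
      } else if (info$selfrep && p == info$k + 1L) {
        lab_hi <- ifelse(state_above(info, st[hi_rows], q),
                         "repelling", "absorbing")
        lab_lo <- ifelse(lab_hi == "absorbing", "repelling", "absorbing")
      } else {
        lab_lo <- ifelse(state_above(info, st[lo_rows], q),
                         "absorbing", "repelling")
        lab_hi <- ifelse(state_above(info, st[hi_rows], q),
                         "repelling", "absorbing")
      }
      out[[length(out) + 1L]] <- data.frame(
        axis = info$node, pos = p, lower = lo_rows, upper = hi_rows,
        label_lower = lab_lo, label_upper = lab_hi,
        stringsAsFactors = FALSE)
    }
  }
  tibble::as_tibble(do.call(rbind, out))
}

#' State transition graph at a parameter vertex
#'
#' Builds the directed graph on top cells induced by the wall labels: a
#' wall absorbing with respect to one side and repelling with respect to
#' the other gives an edge out of the absorbing side; a wall repelling on
#' both sides gives no edge.  A cell whose walls all repel it (no outgoing
#' edge) carries a self-edge and is a stable state, labeled
#' `FP(i_0, ..., i_{N-1})` by its report coordinates.
#'
#' @param pg a [build_parameter_graph()] result.
#' @param vertex integer vector: one factor-vertex id per node.
#' @return An object of class `stg`: the complex, the wall table, an edge
#'   matrix (`from`, `to` cell rows), the self-edge flags, and the FP table.
#' @export
build_stg <- function(pg, vertex) {
  cx <- build_complex(pg, vertex)
  walls <- wall_table(cx)
  both_abs <- walls$label_lower == "absorbing" & walls$label_upper == "absorbing"
  if (any(both_abs)) {
    stop("wall absorbing from both sides outside the refined self-threshold; ",
         "the complex is inconsistent", call. = FALSE)
  }
  a1 <- walls$label_lower == "absorbing"
  a2 <- walls$label_upper == "absorbing"
  edges <- rbind(
    cbind(from = walls$lower[a1], to = walls$upper[a1]),
    cbind(from = walls$upper[a2], to = walls$lower[a2])
  )
  self <- !(seq_len(nrow(cx$cells)) %in% edges[, "from"])
  fp <- fp_table(cx, self)
  structure(list(complex = cx, walls = walls, edges = edges, self = self,
                 fp = fp),
            class = "stg")
}

fp_table <- function(cx, self) {
  rows <- which(self)
  rep_coords <- vapply(seq_along(cx$nodes), function(n1) {
    cx$nodes[[n1]]$report[cx$cells[rows, n1] + 1L]
  }, integer(length(rows)))
  rep_coords <- matrix(rep_coords, nrow = length(rows))
  tibble::tibble(
    cell = rows,
    label = apply(rep_coords, 1L, function(r) {
      sprintf("FP(%s)", paste(r, collapse = ", "))
    }),
    coords = lapply(seq_along(rows), function(i) rep_coords[i, ])
  )
}

#' @export
print.stg <- function(x, ...) {
  cat("<stg> ", nrow(x$complex$cells), " cells, ", nrow(x$edges),
      " edges, ", sum(x$self), " stable cells\n", sep = "")
  if (nrow(x$fp)) cat("  ", paste(x$fp$label, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Morse graph of a state transition graph
#'
#' Condenses the STG into its strongly connected components and keeps the
#' recurrent ones (components of more than one cell, or single cells with a
#' self-edge) as Morse nodes, ordered by reachability.  Minimal nodes —
#' those from which no other Morse node can be reached — are the attractors;
#' single-cell minimal nodes carry `FP` labels.
#'
#' @param stg a [build_stg()] result.
#' @return An object of class `morse_graph`: tibble of nodes (`id`,
#'   `n_cells`, `cells`, `fp`, `minimal`) and a reachability edge matrix.
#' @export
morse_graph <- function(stg) {
  n_cells <- nrow(stg$complex$cells)
  g <- igraph::graph_from_edgelist(
    rbind(stg$edges, cbind(which(stg$self), which(stg$self))),
    directed = TRUE)
  g <- igraph::add_vertices(g, max(0L, n_cells - igraph::vcount(g)))
  memb <- igraph::components(g, mode = "strong")$membership
  comp_size <- tabulate(memb)
  recurrent <- which(comp_size > 1L |
                       vapply(seq_along(comp_size), function(cmp) {
                         any(stg$self[memb == cmp])
                       }, logical(1)))
  # condensation DAG and reachability between recurrent components
  ce <- unique(cbind(memb[stg$edges[, 1L]], memb[stg$edges[, 2L]]))
  ce <- ce[ce[, 1L] != ce[, 2L], , drop = FALSE]
  n_comp <- length(comp_size)
  adj <- lapply(seq_len(n_comp), function(cmp) ce[ce[, 1L] == cmp, 2L])
  reach_from <- function(cmp) {
    seen <- logical(n_comp)
    stack <- adj[[cmp]]
    while (length(stack)) {
      v <- stack[[1L]]; stack <- stack[-1L]
      if (!seen[v]) { seen[v] <- TRUE; stack <- c(stack, adj[[v]]) }
    }
    which(seen)
  }
  edges <- do.call(rbind, lapply(recurrent, function(cmp) {
    down <- intersect(reach_from(cmp), recurrent)
    if (length(down)) cbind(from = cmp, to = down) else NULL
  }))
  minimal <- vapply(recurrent, function(cmp) {
    length(intersect(reach_from(cmp), recurrent)) == 0L
  }, logical(1))
  fp <- vapply(recurrent, function(cmp) {
    cells <- which(memb == cmp)
    if (length(cells) == 1L && stg$self[cells]) {
      stg$fp$label[match(cells, stg$fp$cell)]
    } else NA_character_
  }, character(1))
  nodes <- tibble::tibble(
    id = recurrent,
    n_cells = comp_size[recurrent],
    cells = lapply(recurrent, function(cmp) which(memb == cmp)),
    fp = fp,
    minimal = minimal
  )
  structure(list(nodes = nodes, edges = edges, membership = memb),
            class = "morse_graph")
}

#' @export
print.morse_graph <- function(x, ...) {
  cat("<morse_graph> ", nrow(x$nodes), " nodes, ",
      sum(x$nodes$minimal), " minimal\n", sep = "")
  lab <- ifelse(is.na(x$nodes$fp),
                paste0("cycle[", x$nodes$n_cells, "]"), x$nodes$fp)
  cat("  ", paste(ifelse(x$nodes$minimal, paste0("*", lab), lab),
                  collapse = ", "), "\n", sep = "")
  invisible(x)
}

# fast path for scoring: output-node report coordinates of the stable cells
# (terminal singleton components = cells with every wall repelling)
stable_output_coords <- function(pg, vertex) {
  stg <- build_stg(pg, vertex)
  rows <- which(stg$self)
  out1 <- pg$net$output_node + 1L
  stg$complex$nodes[[out1]]$report[stg$complex$cells[rows, out1] + 1L]
}
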