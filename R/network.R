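#' Annotated regulatory networks
#'
#' A regulatory network is a signed digraph on nodes `x0, x1, ...` with edge
#' coefficients `a_ij` describing the effect of source node `j` on target
#' node `i`: `+1` activation, `-1` repression, `0` no edge.  The interaction
#' algebra is fixed: activating inputs of a node are summed and the sum is
#' multiplied by one switching factor per repressing input.  By convention
#' node 0 receives the external input signal and node 2 (when present)
#' reports the output.
#'
#' @param coeffs integer matrix with entries in `{-1, 0, 1}`; rows index
#'   targets, columns sources (`coeffs[i, j]` is the effect of node `j - 1`
#'   on node `i - 1` in 0-based labels).
#' @param node_names optional character vector of node identifiers; defaults
#'   to `x0 ... x<N-1>`.
#' @param input_node,output_node 0-based indices of the signal-receiving and
#'   reporting nodes.  Defaults: 0 and `min(2, N - 1)`.
#' @return An object of class `regulatory_network`.
#' @examples
#' net <- regulatory_network(rbind(c(0, 0, 1), c(1, 0, 0), c(0, 1, 0)))
#' net
#' @export
regulatory_network <- function(coeffs, node_names = NULL,
                               input_node = 0L, output_node = NULL) {
  coeffs <- as.matrix(coeffs)
  storage.mode(coeffs) <- "integer"
  n <- nrow(coeffs)
  if (ncol(coeffs) != n) stop("`coeffs` must be a square matrix", call. = FALSE)
  if (!all(coeffs %in% c(-1L, 0L, 1L))) {
    stop("edge coefficients must be -1, 0 or +1", call. = FALSE)
  }
  if (is.null(node_names)) node_names <- paste0("x", seq_len(n) - 1L)
  if (length(node_names) != n || anyDuplicated(node_names)) {
    stop("`node_names` must be ", n, " distinct identifiers", call. = FALSE)
  }
  if (is.null(output_node)) output_node <- min(2L, n - 1L)
  input_node <- as.integer(input_node)
  output_node <- as.integer(output_node)
  stopifnot(input_node >= 0L, input_node < n, output_node >= 0L, output_node < n)
  dimnames(coeffs) <- list(node_names, node_names)
  structure(
    list(coeffs = coeffs, node_names = node_names,
         input_node = input_node, output_node = output_node),
    class = "regulatory_network"
  )
}

#' @export
print.regulatory_network <- function(x, ...) {
  cat("<regulatory_network> ", n_nodes(x), " nodes, ", n_edges(x), " edges\n",
      sep = "")
  cat(serialize_network(x), sep = "\n")
  invisible(x)
}

#' @export
format.regulatory_network <- function(x, ...) serialize_network(x)

n_nodes <- function(net) nrow(net$coeffs)
n_edges <- function(net) sum(net$coeffs != 0L)

#' In-edges of a node
#'
#' @param net a [regulatory_network()].
#' @param node 0-based node index.
#' @return Integer vector of 0-based source indices (ascending), with the
#'   edge sign as names-free attribute via `in_signs()`.
#' @keywords internal
in_sources <- function(net, node) {
  which(net$coeffs[node + 1L, ] != 0L) - 1L
}

in_signs <- function(net, node) {
  s <- net$coeffs[node + 1L, net$coeffs[node + 1L, ] != 0L]
  as.integer(s)
}

out_targets <- function(net, node) {
  which(net$coeffs[, node + 1L] != 0L) - 1L
}

#' Parse a network specification
#'
#' Reads the one-line-per-node text dialect: `name : (group)(group)...`.
#' Within a parenthesized group, `+`-separated node names are summed
#' activators; a group of the form `(~name)` contributes one multiplicative
#' repressor factor.  A node may have at most one summed activator group.
#' Blank lines and lines starting with `#` are ignored.  A node with no
#' in-edges is written `name :`.
#'
#' @param text character scalar (possibly multi-line) or character vector of
#'   lines.
#' @inheritParams regulatory_network
#' @return A [regulatory_network()].
#' @examples
#' parse_network("x0 : (x0 + x1 + x2)\nx1 : (x0 + x2)\nx2 : (x0)")
#' @export
parse_network <- function(text, input_node = 0L, output_node = NULL) {
  lines <- unlist(strsplit(paste(text, collapse = "\n"), "\n", fixed = TRUE))
  lines <- sub("#.*$", "", lines)
  keep <- nzchar(trimws(lines))
  raw <- lines[keep]
  lineno <- which(keep)
  if (length(raw) == 0L) stop("empty network specification", call. = FALSE)

  split1 <- regexpr(":", raw, fixed = TRUE)
  if (any(split1 < 0L)) {
    stop("line ", lineno[which(split1 < 0L)[1L]], ": expected `name : ...`",
         call. = FALSE)
  }
  names_ <- trimws(substr(raw, 1L, split1 - 1L))
  rhs <- trimws(substr(raw, split1 + 1L, nchar(raw)))
  if (any(!grepl("^[A-Za-z][A-Za-z0-9_.]*$", names_))) {
    bad <- which(!grepl("^[A-Za-z][A-Za-z0-9_.]*$", names_))[1L]
    stop("line ", lineno[bad], ": invalid node name ", dQuote(names_[bad]),
         call. = FALSE)
  }
  dup <- anyDuplicated(names_)
  if (dup) {
    stop("line ", lineno[dup], ": node ", dQuote(names_[dup]),
         " defined twice", call. = FALSE)
  }

  n <- length(names_)
  coeffs <- matrix(0L, n, n)
  for (i in seq_len(n)) {
    expr <- gsub("[[:space:]]", "", rhs[i])
    if (!nzchar(expr)) next
    if (!grepl("^(\\([^()]*\\))+$", expr)) {
      stop("line ", lineno[i], ": malformed expression ", dQuote(rhs[i]),
           call. = FALSE)
    }
    groups <- regmatches(expr, gregexpr("\\(([^()]*)\\)", expr))[[1L]]
    groups <- substr(groups, 2L, nchar(groups) - 1L)
    seen_act <- FALSE
    for (g in groups) {
      if (startsWith(g, "~")) {
        src <- match(substring(g, 2L), names_)
        if (is.na(src)) {
          stop("line ", lineno[i], ": unknown node name ",
               dQuote(substring(g, 2L)), call. = FALSE)
        }
        if (coeffs[i, src] != 0L) {
          stop("line ", lineno[i], ": duplicate edge from ",
               dQuote(names_[src]), call. = FALSE)
        }
        coeffs[i, src] <- -1L
      } else {
        if (seen_act) {
          stop("line ", lineno[i],
               ": more than one summed activator group", call. = FALSE)
        }
        seen_act <- TRUE
        if (!nzchar(g)) {
          stop("line ", lineno[i], ": empty group", call. = FALSE)
        }
        for (nm in strsplit(g, "+", fixed = TRUE)[[1L]]) {
          src <- match(nm, names_)
          if (is.na(src)) {
            stop("line ", lineno[i], ": unknown node name ", dQuote(nm),
                 call. = FALSE)
          }
          if (coeffs[i, src] != 0L) {
            stop("line ", lineno[i], ": duplicate edge from ", dQuote(nm),
                 call. = FALSE)
          }
          coeffs[i, src] <- 1L
        }
      }
    }
  }
  regulatory_network(coeffs, node_names = names_,
                     input_node = input_node, output_node = output_node)
}

#' Serialize a network to the text dialect
#'
#' Inverse of [parse_network()]: `parse_network(serialize_network(net))`
#' reproduces `net`'s edge coefficients.
#'
#' @param net a [regulatory_network()].
#' @return Character vector, one line per node.
#' @export
serialize_network <- function(net) {
  vapply(seq_len(n_nodes(net)) - 1L, function(i) {
    srcs <- in_sources(net, i)
    signs <- in_signs(net, i)
    act <- srcs[signs > 0L]
    rep_ <- srcs[signs < 0L]
    rhs <- ""
    if (length(act)) {
      rhs <- paste0("(", paste(net$node_names[act + 1L], collapse = " + "), ")")
    }
    if (length(rep_)) {
      rhs <- paste0(rhs, paste0("(~", net$node_names[rep_ + 1L], ")",
                                collapse = ""))
    }
    paste0(net$node_names[i + 1L], " : ", rhs)
  }, character(1))
}

#' Enumerate all three-node networks
#'
#' Generates the `3^9 = 19683` signed three-node digraphs in canonical
#' lexicographic order over the nine coefficients `(a00, a01, ..., a22)`
#' read row-major with `-1 < 0 < +1`.  The canonical index is stable and
#' internal to this package; it intentionally does not reproduce any
#' score-derived numbering.
#'
#' @param include_trivial keep networks for which [is_trivial()] is `TRUE`
#'   (no path from node 0 to node 2 or from node 1 to node 2).
#' @param nine_edge policy for the 512 fully-connected (nine-edge) networks:
#'   `"all_activator"` keeps only the network in which every edge activates
#'   (the default screening set), `"keep_all"` keeps all of them,
#'   `"drop_all"` drops all of them.
#' @return A tibble with one row per network: `id` (canonical index into the
#'   full 19683-network ordering), coefficient columns `a00 ... a22`
#'   (`a<target><source>`, 0-based), `n_edges`, and `trivial`.  Use
#'   [as_network()] to materialize a row.
#' @examples
#' nrow(enumerate_three_node_networks(include_trivial = TRUE,
#'                                    nine_edge = "keep_all"))
#' @export
enumerate_three_node_networks <- function(include_trivial = FALSE,
                                          nine_edge = c("all_activator",
                                                        "keep_all",
                                                        "drop_all")) {
  nine_edge <- match.arg(nine_edge)
  lev <- c(-1L, 0L, 1L)
  # a00 most significant: build right-to-left so column a22 varies fastest
  grid <- expand.grid(a22 = lev, a21 = lev, a20 = lev,
                      a12 = lev, a11 = lev, a10 = lev,
                      a02 = lev, a01 = lev, a00 = lev,
                      KEEP.OUT.ATTRS = FALSE)
  grid <- grid[, c("a00", "a01", "a02", "a10", "a11", "a12",
                   "a20", "a21", "a22")]
  grid$id <- seq_len(nrow(grid))
  grid$n_edges <- as.integer(rowSums(grid[, 1:9] != 0L))
  grid$trivial <- abs(grid$a20 * grid$a21) + abs(grid$a20 * grid$a01) +
    abs(grid$a21 * grid$a10) == 0L
  out <- grid
  if (!include_trivial) out <- out[!out$trivial, ]
  if (nine_edge != "keep_all") {
    nine <- out$n_edges == 9L
    keep <- !nine
    if (nine_edge == "all_activator") {
      keep <- keep | (nine & rowSums(out[, 1:9] == 1L) == 9L)
    }
    out <- out[keep, ]
  }
  tibble::as_tibble(out[, c("id", "a00", "a01", "a02", "a10", "a11", "a12",
                            "a20", "a21", "a22", "n_edges", "trivial")])
}

#' Materialize one enumerated network
#'
#' @param row a one-row data frame with columns `a00 ... a22` (as produced
#'   by [enumerate_three_node_networks()]), or a numeric vector of the nine
#'   coefficients in row-major order.
#' @return A [regulatory_network()].
#' @export
as_network <- function(row) {
  if (is.data.frame(row)) {
    stopifnot(nrow(row) == 1L)
    v <- as.integer(unlist(row[paste0("a", rep(0:2, each = 3), rep(0:2, 3))]))
  } else {
    v <- as.integer(row)
  }
  stopifnot(length(v) == 9L)
  regulatory_network(matrix(v, 3L, 3L, byrow = TRUE))
}

#' Trivial-network filter
#'
#' A three-node network is trivial when the output node cannot respond to
#' the input or to node 1, i.e. when `|a20*a21| + |a20*a01| + |a21*a10| = 0`
#' (no path from node 0 to node 2, or no path from node 1 to node 2).
#' Trivial networks are incapable of input-driven switching and are removed
#' from the screen.
#'
#' @param net a [regulatory_network()] with exactly 3 nodes.
#' @return Logical scalar.
#' @export
is_trivial <- function(net) {
  if (n_nodes(net) != 3L) {
    stop("the trivial-network filter is defined for 3-node networks",
         call. = FALSE)
  }
  a <- net$coeffs
  # a[i+1, j+1] = a_ij (target i, source j), 0-based labels
  abs(a[3, 1] * a[3, 2]) + abs(a[3, 1] * a[1, 2]) + abs(a[3, 2] * a[2, 1]) == 0L
}

#' Classify nodes by the signs of their out-edges
#'
#' A node is *consistent* when it acts only as an activator or only as a
#' repressor.  Consistency is a design constraint: it rules out components
#' that must both activate some targets and repress others.
#'
#' @param net a [regulatory_network()].
#' @return A tibble with columns `node` (0-based), `name`, and `role` in
#'   `{"activator-only", "repressor-only", "mixed", "no-out"}`.
#' @export
node_consistency <- function(net) {
  role <- vapply(seq_len(n_nodes(net)) - 1L, function(j) {
    s <- net$coeffs[, j + 1L]
    s <- s[s != 0L]
    if (length(s) == 0L) "no-out"
    else if (all(s > 0L)) "activator-only"
    else if (all(s < 0L)) "repressor-only"
    else "mixed"
  }, character(1))
  tibble::tibble(node = seq_len(n_nodes(net)) - 1L,
                 name = net$node_names, role = role)
}
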