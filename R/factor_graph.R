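# Factor graphs: the per-node decomposition of kinetic-parameter space.
#
# Each node n of a network carries a decay rate gamma_n, a low production
# rate ell_{n,m} and increment delta_{n,m} per in-edge m -> n, and one
# threshold theta_{k,n} per out-edge n -> k.  A factor-graph vertex is one
# realizable sign pattern of the comparisons "production value vs
# gamma * threshold": a threshold order plus a nested chain of input-state
# sets (the binarization chain).  Enumeration couples a combinatorial
# candidate generator (nested chains of polarity-adjusted up-sets) with an
# exact linear-feasibility decision in the pure-sum and pure-product cases
# and a seeded slack-maximization solve in the mixed case.

# ---- node shapes and input states -------------------------------------------

node_shape <- function(net, node) {
  srcs <- in_sources(net, node)
  signs <- in_signs(net, node)
  targets <- out_targets(net, node)
  placeholder <- length(targets) == 0L
  k <- if (placeholder) 1L else length(targets)
  m <- length(srcs)
  if (m > 4L || k > 4L) {
    stop("factor graphs support at most 4 in-edges and 4 out-edges per node",
         call. = FALSE)
  }
  list(node = node, m = m, sources = srcs, signs = signs,
       k = k, targets = if (placeholder) NA_integer_ else targets,
       placeholder = placeholder, n_states = 2L^m)
}

# bit matrix: n_states x m, entry = 1 iff in-edge j's source is above its
# threshold in that input state
state_bits <- function(m) {
  if (m == 0L) return(matrix(integer(0), 1L, 0L))
  s <- 0:(2L^m - 1L)
  vapply(seq_len(m), function(j) bitwAnd(bitwShiftR(s, j - 1L), 1L),
         integer(2L^m))
}

# production values for every input state given numeric per-node parameters
production_values <- function(shape, ell, delta, beta = NULL) {
  if (shape$m == 0L) return(beta)
  bits <- state_bits(shape$m)
  act <- shape$signs > 0L
  rep_ <- shape$signs < 0L
  sumpart <- if (any(act)) {
    sum(ell[act]) + as.vector(bits[, act, drop = FALSE] %*% delta[act])
  } else 1
  prodpart <- rep(1, shape$n_states)
  for (j in which(rep_)) {
    prodpart <- prodpart * ifelse(bits[, j] == 1L, ell[j], ell[j] + delta[j])
  }
  sumpart * prodpart
}

#' Symbolic production values of a node
#'
#' For every input state of a node (one bit per in-edge, set when the source
#' lies above its threshold) gives the production rate under the fixed
#' interaction algebra: activating inputs contribute `l[n][m]` (bit 0) or
#' `l[n][m] + d[n][m]` (bit 1) to a sum, and each repressing input
#' multiplies by `l[n][m] + d[n][m]` (bit 0) or `l[n][m]` (bit 1).  A node
#' with no in-edges produces the single constant `b[n]`.
#'
#' @param net a [regulatory_network()].
#' @param node 0-based node index.
#' @return A tibble with columns `state` (integer code), `bits` (character,
#'   one digit per in-edge, lowest-indexed source first), and `expr`
#'   (character expression in the grammar `l[n][m]`, `d[n][m]`, `b[n]`).
#' @export
production_value_exprs <- function(net, node) {
  shape <- node_shape(net, node)
  n <- node
  if (shape$m == 0L) {
    return(tibble::tibble(state = 0L, bits = "", expr = sprintf("b[%d]", n)))
  }
  bits <- state_bits(shape$m)
  exprs <- vapply(seq_len(shape$n_states), function(si) {
    act_terms <- character(0)
    rep_terms <- character(0)
    for (j in seq_len(shape$m)) {
      mm <- shape$sources[j]
      term <- if (bits[si, j] == 1L) {
        if (shape$signs[j] > 0L) sprintf("l[%d][%d] + d[%d][%d]", n, mm, n, mm)
        else sprintf("l[%d][%d]", n, mm)
      } else {
        if (shape$signs[j] > 0L) sprintf("l[%d][%d]", n, mm)
        else sprintf("l[%d][%d] + d[%d][%d]", n, mm, n, mm)
      }
      if (shape$signs[j] > 0L) act_terms <- c(act_terms, term)
      else rep_terms <- c(rep_terms, sprintf("(%s)", term))
    }
    sumpart <- if (length(act_terms)) paste(act_terms, collapse = " + ")
    else character(0)
    if (length(rep_terms) == 0L) return(sumpart)
    lhs <- if (length(sumpart)) sprintf("(%s)", sumpart) else character(0)
    paste(c(lhs, rep_terms), collapse = " * ")
  }, character(1))
  tibble::tibble(
    state = 0:(shape$n_states - 1L),
    bits = apply(bits, 1L, paste, collapse = ""),
    expr = exprs
  )
}

# ---- up-sets and chains ------------------------------------------------------

# enumerate the subsets of input states that are up-sets of the
# polarity-adjusted order (raising an activator input, or lowering a
# repressor input, never leaves the set).  Subsets are encoded as bitmasks
# over states.
up_sets <- function(m, signs) {
  ns <- 2L^m
  masks <- 0:(2L^ns - 1L)
  if (m == 0L) return(masks)  # {} and {state 0}
  # cover pairs in production-increasing direction
  lo <- integer(0); hi <- integer(0)
  for (s in 0:(ns - 1L)) {
    for (j in seq_len(m)) {
      bit <- bitwShiftL(1L, j - 1L)
      has <- bitwAnd(s, bit) != 0L
      up <- if (signs[j] > 0L && !has) bitwOr(s, bit)
      else if (signs[j] < 0L && has) bitwAnd(s, bitwNot(bit))
      else NA_integer_
      if (!is.na(up)) { lo <- c(lo, s); hi <- c(hi, up) }
    }
  }
  keep <- rep(TRUE, length(masks))
  for (p in seq_along(lo)) {
    keep <- keep & !(bitwAnd(masks, bitwShiftL(1L, lo[p])) != 0L &
                       bitwAnd(masks, bitwShiftL(1L, hi[p])) == 0L)
  }
  masks[keep]
}

# all nested k-tuples (B_1 >= B_2 >= ... >= B_k) of the given up-set masks,
# returned as an integer matrix with one row per chain
nested_chains <- function(usets, k) {
  contains <- outer(usets, usets,
                    function(a, b) bitwAnd(a, b) == b)  # a >= b
  grow <- function(chain_tail) {
    # chain_tail: indices chosen so far (level 1 .. l)
    if (length(chain_tail) == k) return(matrix(usets[chain_tail], 1L))
    last <- chain_tail[length(chain_tail)]
    next_idx <- which(contains[last, ])
    do.call(rbind, lapply(next_idx, function(i) grow(c(chain_tail, i))))
  }
  do.call(rbind, lapply(seq_along(usets), function(i) grow(i)))
}

count_nested_chains <- function(usets, k) {
  contains <- outer(usets, usets, function(a, b) bitwAnd(a, b) == b) * 1
  v <- rep(1, length(usets))
  for (i in seq_len(k - 1L)) v <- as.vector(contains %*% v)
  sum(v)
}

#' Maximal factor-graph size for given node degrees
#'
#' Counts, for a node with `n_in` in-edges and `n_out` out-edges, the
#' realizable nested `n_out`-chains of monotone input-state sets times the
#' `n_out!` threshold orders, maximized over the interaction sign patterns
#' (how many of the in-edges repress; with `signs` given, that one pattern
#' is counted).  The maximum over sign patterns is what bounds the
#' parameter-graph size of any network with the given degree sequence —
#' mixed sum-by-product logic admits more regions than pure-sum logic
#' (e.g. 756 vs 707 chains per class at three in- and out-edges).
#'
#' @param n_in,n_out in- and out-degree of the node (out-degree 0 uses the
#'   single placeholder threshold).
#' @param signs optional vector of in-edge signs; default maximizes over
#'   the number of repressors.
#' @return A double (counts overflow integers quickly).
#' @examples
#' chain_count_bound(1, 1)  # 3 regions
#' chain_count_bound(2, 1)  # 6 monotone sets
#' @export
chain_count_bound <- function(n_in, n_out, signs = NULL) {
  k <- max(1L, as.integer(n_out))
  sign_sets <- if (is.null(signs)) {
    lapply(0:n_in, function(r) {
      c(rep(1L, n_in - r), rep(-1L, r))
    })
  } else list(as.integer(signs))
  max(vapply(sign_sets, function(sg) {
    core <- factor_graph_core(sg, k, eps = 1e-6)
    nrow(core$chains) * factorial(k)
  }, numeric(1)))
}

#' @rdname chain_count_bound
#' @param net a [regulatory_network()].
#' @export
parameter_graph_bound <- function(net) {
  prod(vapply(seq_len(n_nodes(net)) - 1L, function(n) {
    chain_count_bound(length(in_sources(net, n)),
                      length(out_targets(net, n)),
                      signs = in_signs(net, n))
  }, numeric(1)))
}

# ---- realizability -----------------------------------------------------------

# rescale a witness so the largest scaled threshold sits at 3.0 (a
# biologically convenient scale commensurate with input signals of order
# one to four).  Regions are scale-invariant: production values and
# thresholds are multiplied by the same factor.
scale_witness <- function(w, signs) {
  lam <- 3 / max(w$gamma * w$theta)
  act <- signs > 0L; rep_ <- signs < 0L
  if (length(signs) == 0L) {
    w$beta <- w$beta * lam
  } else if (any(act)) {
    w$ell[act] <- w$ell[act] * lam
    w$delta[act] <- w$delta[act] * lam
  } else {
    f <- lam^(1 / sum(rep_))
    w$ell <- w$ell * f
    w$delta <- w$delta * f
  }
  w$theta <- w$theta * lam
  w
}

# decide whether a nested chain of up-sets is realizable by strictly
# positive parameters, and if so return a numeric witness.
# chain: integer vector of k state-set masks (level 1 .. k).
# Returns list(status = "realizable"|"unrealizable"|"undecided",
#              witness = list(gamma, ell, delta, theta, beta) or NULL)
realize_chain <- function(shape, chain, eps = 1e-6, n_starts = 20L,
                          rng_seed = 1L) {
  m <- shape$m; k <- shape$k; ns <- shape$n_states
  inB <- vapply(chain, function(msk) bitwAnd(msk, bitwShiftL(1L, 0:(ns - 1L))) != 0L,
                logical(ns))
  inB <- matrix(inB, nrow = ns)  # states x levels

  if (m == 0L) {
    # constant production beta: chain levels containing the single state
    # come first; put beta in the matching threshold gap
    j <- sum(inB[1L, ])
    theta <- seq_len(k)
    w <- list(gamma = 1, ell = numeric(0), delta = numeric(0),
              theta = theta, beta = j + 0.5)
    return(list(status = "realizable",
                witness = scale_witness(w, shape$signs)))
  }

  bits <- state_bits(m)
  act <- shape$signs > 0L; rep_ <- shape$signs < 0L
  A <- sum(act); R <- sum(rep_)

  if (R == 0L) {
    res <- realize_sum_lp(bits, inB, A, k, eps)
    if (is.null(res)) return(list(status = "unrealizable", witness = NULL))
    ell <- delta <- numeric(m)
    ell[act] <- res$c0 / A
    delta[act] <- res$d
    w <- list(gamma = 1, ell = ell, delta = delta, theta = res$t, beta = NULL)
    return(list(status = "realizable",
                witness = scale_witness(w, shape$signs)))
  }
  if (A == 0L) {
    res <- realize_prod_lp(bits, inB, R, k, eps)
    if (is.null(res)) return(list(status = "unrealizable", witness = NULL))
    ell <- delta <- numeric(m)
    ell[rep_] <- res$ell
    delta[rep_] <- res$delta
    w <- list(gamma = 1, ell = ell, delta = delta, theta = res$t, beta = NULL)
    return(list(status = "realizable",
                witness = scale_witness(w, shape$signs)))
  }
  realize_mixed(shape, bits, inB, eps = max(eps, 1e-5),
                n_starts = n_starts, rng_seed = rng_seed)
}

# slack-maximization LP for a pure-sum node.  Variables
# x = (c, d_1..d_A, t_1..t_k, mu) >= 0; all constraints as A x <= b.
# Homogeneous, so unit box rows only fix the scale.
realize_sum_lp <- function(bits, inB, A, k, eps) {
  abits <- bits[, seq_len(ncol(bits)), drop = FALSE]  # pure sum: all bits
  ns <- nrow(inB)
  nv <- 1L + A + k + 1L
  rows <- list(); rhs <- numeric(0)
  add <- function(r, b) { rows[[length(rows) + 1L]] <<- r; rhs[length(rhs) + 1L] <<- b }
  for (i in seq_len(k)) {
    for (s in seq_len(ns)) {
      r <- numeric(nv)
      r[1L] <- 1; r[1L + seq_len(A)] <- abits[s, ]
      r[1L + A + i] <- -1
      if (inB[s, i]) r <- -r   # value >= t_i + mu, else value <= t_i - mu
      r[nv] <- 1
      add(r, 0)
    }
  }
  for (i in seq_len(k - 1L)) {
    r <- numeric(nv); r[1L + A + i] <- 1; r[1L + A + i + 1L] <- -1; r[nv] <- 1
    add(r, 0)
  }
  for (j in c(1L, 1L + seq_len(A), 1L + A + 1L)) {
    r <- numeric(nv); r[j] <- -1; r[nv] <- 1
    add(r, 0)
  }
  for (j in seq_len(nv - 1L)) {  # box
    r <- numeric(nv); r[j] <- 1
    add(r, if (j > 1L + A) A + 2 else 1)
  }
  sol <- solve_slack_lp(do.call(rbind, rows), rhs, nv)
  if (is.null(sol) || sol[nv] < eps) return(NULL)
  list(c0 = sol[1L], d = sol[1L + seq_len(A)], t = sol[1L + A + seq_len(k)],
       mu = sol[nv])
}

# slack-maximization LP for a pure-product node, solved in log space.
# Variables are logs shifted by S = 3 so they are nonnegative:
# x = (u'_1..u'_R, v'_1..v'_R, tau'_1..tau'_k, mu), u = log(ell),
# v = log(ell + delta), tau = log(gamma * theta).
realize_prod_lp <- function(bits, inB, R, k, eps) {
  S <- 3; ns <- nrow(inB)
  nv <- 2L * R + k + 1L
  rows <- list(); rhs <- numeric(0)
  add <- function(r, b) { rows[[length(rows) + 1L]] <<- r; rhs[length(rhs) + 1L] <<- b }
  for (i in seq_len(k)) {
    for (s in seq_len(ns)) {
      sel <- numeric(nv)
      for (j in seq_len(R)) {
        if (bits[s, j] == 1L) sel[j] <- 1 else sel[R + j] <- 1
      }
      r <- numeric(nv)
      if (inB[s, i]) {        # log val >= tau_i + mu
        r <- -sel; r[2L * R + i] <- 1; r[nv] <- 1
        add(r, S - S * R)
      } else {                # log val <= tau_i - mu
        r <- sel; r[2L * R + i] <- -1; r[nv] <- 1
        add(r, S * R - S)
      }
    }
  }
  for (j in seq_len(R)) {     # v_j - u_j >= mu
    r <- numeric(nv); r[j] <- 1; r[R + j] <- -1; r[nv] <- 1
    add(r, 0)
  }
  for (i in seq_len(k - 1L)) {
    r <- numeric(nv); r[2L * R + i] <- 1; r[2L * R + i + 1L] <- -1; r[nv] <- 1
    add(r, 0)
  }
  for (j in seq_len(nv - 1L)) {  # box: logs within [-3, 3]
    r <- numeric(nv); r[j] <- 1
    add(r, 2 * S)
  }
  sol <- solve_slack_lp(do.call(rbind, rows), rhs, nv)
  if (is.null(sol) || sol[nv] < eps) return(NULL)
  u <- sol[seq_len(R)] - S
  v <- sol[R + seq_len(R)] - S
  tau <- sol[2L * R + seq_len(k)] - S
  list(ell = exp(u), delta = exp(v) - exp(u), t = exp(tau), mu = sol[nv])
}

# maximize mu = x[nv] subject to A x <= b, x >= 0, via a tiny-regularized
# quadratic program (Goldfarb-Idnani dual method; the system is always
# feasible at x = 0, and the ridge term distorts the LP optimum by far less
# than the acceptance margin)
solve_slack_lp <- function(A, b, nv, ridge = 1e-6) {
  dvec <- numeric(nv); dvec[nv] <- 1
  Amat <- t(rbind(-A, diag(nv)))
  bvec <- c(-b, numeric(nv))
  for (lam in c(ridge, 1e-4, 1e-2)) {
    res <- tryCatch(
      quadprog::solve.QP(diag(lam, nv), dvec, Amat, bvec),
      error = function(e) NULL
    )
    if (!is.null(res)) break
  }
  if (is.null(res)) return(NULL)
  x <- res$solution
  if (any(A %*% x > b + 1e-9) || any(x < -1e-9)) return(NULL)
  x
}

# seeded multi-start slack maximization for mixed sum-by-product nodes
realize_mixed <- function(shape, bits, inB, eps, n_starts, rng_seed) {
  act <- shape$signs > 0L; rep_ <- shape$signs < 0L
  A <- sum(act); R <- sum(rep_); k <- shape$k; ns <- shape$n_states
  np <- 1L + A + 2L * R + k
  idx_c <- 1L
  idx_d <- 1L + seq_len(A)
  idx_u <- 1L + A + seq_len(R)
  idx_v <- 1L + A + R + seq_len(R)
  idx_t <- 1L + A + 2L * R + seq_len(k)
  abits <- bits[, act, drop = FALSE]
  rbits <- bits[, rep_, drop = FALSE]
  sgn <- ifelse(inB, 1, -1)  # want sgn * (logval - logt) > 0

  minslack <- function(p) {
    lv <- log(exp(p[idx_c]) + as.vector(abits %*% exp(p[idx_d]))) +
      as.vector(rbits %*% p[idx_u] + (1 - rbits) %*% p[idx_v])
    s1 <- sgn * outer(lv, p[idx_t], `-`)
    s2 <- p[idx_v] - p[idx_u]
    s3 <- if (k > 1L) diff(p[idx_t]) else numeric(0)
    s4 <- 5 - abs(p)
    min(s1, s2, s3, s4)
  }
  best <- -Inf; best_p <- NULL
  set.seed(rng_seed)
  for (st in seq_len(n_starts)) {
    p0 <- stats::runif(np, -1, 1)
    opt <- stats::optim(p0, minslack, method = "Nelder-Mead",
                        control = list(fnscale = -1, maxit = 600,
                                       reltol = 1e-8))
    if (opt$value > best) { best <- opt$value; best_p <- opt$par }
    if (best >= 0.02) break  # comfortably feasible
  }
  if (best < 0.02 && best > -0.5) {
    # polish the incumbent before giving up
    opt <- stats::optim(best_p, minslack, method = "Nelder-Mead",
                        control = list(fnscale = -1, maxit = 3000,
                                       reltol = 1e-11))
    if (opt$value > best) { best <- opt$value; best_p <- opt$par }
  }
  if (best >= eps) {
    ell <- delta <- numeric(shape$m)
    ell[act] <- exp(best_p[idx_c]) / A
    delta[act] <- exp(best_p[idx_d])
    ell[rep_] <- exp(best_p[idx_u])
    delta[rep_] <- exp(best_p[idx_v]) - exp(best_p[idx_u])
    w <- list(gamma = 1, ell = ell, delta = delta,
              theta = exp(best_p[idx_t]), beta = NULL)
    list(status = "realizable", witness = scale_witness(w, shape$signs))
  } else {
    list(status = "undecided", witness = NULL)
  }
}

#' Decide realizability of one candidate region
#'
#' Tests whether a nested binarization chain, together with a threshold
#' order, bounds a nonempty open region of strictly positive parameters,
#' returning a numeric witness when it does.  Pure-sum and pure-product
#' nodes are decided exactly by linear feasibility (the product case after a
#' log transform); mixed sum-by-product nodes by seeded multi-start slack
#' maximization, which reports `"undecided"` when no feasible point is
#' found.
#'
#' @param net a [regulatory_network()].
#' @param node 0-based node index.
#' @param chain list (level 1..k) of integer vectors of input-state codes,
#'   nested and upward-closed in the polarity-adjusted state order.
#' @param eps strictness margin: every defining inequality must hold with
#'   relative slack at least `eps` at the witness.
#' @return A list with `status` (`"realizable"`, `"unrealizable"` or
#'   `"undecided"`) and `witness` (`gamma`, `ell`, `delta`, `theta`, `beta`)
#'   or `NULL`.
#' @export
is_realizable <- function(net, node, chain, eps = 1e-6) {
  shape <- node_shape(net, node)
  masks <- vapply(chain, function(states) {
    if (length(states) == 0L) 0L else sum(bitwShiftL(1L, as.integer(states)))
  }, integer(1))
  if (length(masks) != shape$k) {
    stop("chain must have one level per out-threshold (", shape$k, ")",
         call. = FALSE)
  }
  us <- up_sets(shape$m, shape$signs)
  if (!all(masks %in% us)) {
    return(list(status = "unrealizable", witness = NULL))
  }
  if (shape$k > 1L &&
      !all(vapply(seq_len(shape$k - 1L), function(i) {
        bitwAnd(masks[i], masks[i + 1L]) == masks[i + 1L]
      }, logical(1)))) {
    return(list(status = "unrealizable", witness = NULL))
  }
  realize_chain(shape, masks, eps = eps)
}

# ---- essentiality ------------------------------------------------------------

# (a) every threshold is crossed: each level is neither empty nor all states
# (b) every in-edge is relevant: flipping that bit moves some state across
#     some threshold
chain_essential <- function(masks, m, ns) {
  full <- 2L^ns - 1L
  if (any(masks == 0L) || any(masks == full)) return(FALSE)
  if (m == 0L) return(FALSE)
  for (j in seq_len(m)) {
    rel <- FALSE
    for (s in 0:(ns - 1L)) {
      s2 <- bitwXor(s, bitwShiftL(1L, j - 1L))
      for (msk in masks) {
        if ((bitwAnd(msk, bitwShiftL(1L, s)) != 0L) !=
            (bitwAnd(msk, bitwShiftL(1L, s2)) != 0L)) { rel <- TRUE; break }
      }
      if (rel) break
    }
    if (!rel) return(FALSE)
  }
  TRUE
}

# ---- factor graph construction ----------------------------------------------

.fg_cache <- new.env(parent = emptyenv())

# permutations of 1..k in lexicographic order (identity first)
perms_identity_first <- function(k) {
  if (k == 1L) return(matrix(1L, 1L, 1L))
  rec <- function(v) {
    if (length(v) == 1L) return(matrix(v, 1L, 1L))
    do.call(rbind, lapply(seq_along(v), function(i) {
      cbind(v[i], rec(v[-i]), deparse.level = 0)
    }))
  }
  rec(seq_len(k))
}

# core, shape-level enumeration shared between nodes of identical shape
factor_graph_core <- function(signs, k, eps, include_undecided = FALSE) {
  key <- paste(c(signs, "k", k, "e", format(eps), "u", include_undecided),
               collapse = "|")
  if (!is.null(.fg_cache[[key]])) return(.fg_cache[[key]])
  m <- length(signs); ns <- 2L^m
  shape <- list(node = NA_integer_, m = m, sources = seq_len(m) - 1L,
                signs = signs, k = k, targets = NA_integer_,
                placeholder = FALSE, n_states = ns)
  us <- up_sets(m, signs)
  cand <- nested_chains(us, k)
  status <- character(nrow(cand))
  witnesses <- vector("list", nrow(cand))
  for (i in seq_len(nrow(cand))) {
    r <- realize_chain(shape, cand[i, ], eps = eps, rng_seed = i)
    status[i] <- r$status
    witnesses[[i]] <- r$witness
  }
  keep <- status == "realizable" |
    (include_undecided & status == "undecided")
  chains <- cand[keep, , drop = FALSE]
  witnesses <- witnesses[keep]
  C <- nrow(chains)
  # within-class adjacency: chains differing by one state in one level,
  # both realizable
  chain_key <- apply(chains, 1L, paste, collapse = ",")
  lookup <- new.env(parent = emptyenv())
  for (i in seq_len(C)) lookup[[chain_key[i]]] <- i
  adj_from <- integer(0); adj_to <- integer(0)
  for (i in seq_len(C)) {
    for (lev in seq_len(k)) {
      for (s in 0:(ns - 1L)) {
        msk2 <- bitwXor(chains[i, lev], bitwShiftL(1L, s))
        if (msk2 < chains[i, lev]) next  # orient: add a state (dedupe)
        probe <- chains[i, ]; probe[lev] <- msk2
        jj <- lookup[[paste(probe, collapse = ",")]]
        if (!is.null(jj)) { adj_from <- c(adj_from, i); adj_to <- c(adj_to, jj) }
      }
    }
  }
  essential <- vapply(seq_len(C), function(i) {
    chain_essential(chains[i, ], m, ns)
  }, logical(1))
  sizes <- if (C > 0) {
    rowSums(matrix(vapply(as.vector(chains), function(msk) {
      sum(bitwAnd(msk, bitwShiftL(1L, 0:(ns - 1L))) != 0L)
    }, numeric(1)), nrow = C))
  } else numeric(0)
  out <- list(chains = chains, witnesses = witnesses, essential = essential,
              cover_from = adj_from, cover_to = adj_to, sizes = sizes,
              n_candidates = nrow(cand),
              n_undecided = sum(status == "undecided"))
  .fg_cache[[key]] <- out
  out
}

#' Enumerate the factor graph of one node
#'
#' Builds all realizable parameter regions of a node: every threshold order
#' (one class per permutation of the node's out-thresholds; a node without
#' out-edges gets a single placeholder threshold) combined with every
#' realizable nested binarization chain.  Vertices within a class are
#' adjacent when their chains differ by exactly one input state at exactly
#' one level; vertices in classes that differ by one adjacent transposition
#' are adjacent when their chains coincide and the two transposed levels
#' carry the same set.  The production partial order (`gamma` order) on a
#' class runs from the all-below region (minimal: every input state under
#' every threshold — low effective input) to the all-above region (maximal).
#'
#' @param net a [regulatory_network()].
#' @param node 0-based node index.
#' @param eps strictness margin for region feasibility.
#' @param include_undecided keep mixed-logic candidate regions whose
#'   numeric feasibility search was inconclusive (they carry no witness);
#'   by default they are excluded and only counted in `n_undecided`.
#' @return An object of class `factor_graph`: vertex table plus adjacency,
#'   oriented cover edges of the production order, witnesses, essential
#'   flags and class bookkeeping.
#' @examples
#' net <- parse_network("x0 : (x2)\nx1 : (x0)\nx2 : (x1)")
#' fg <- enumerate_factor_graph(net, 0)
#' fg$n_vertices   # 3 regions for a 1-in 1-out node
#' @export
enumerate_factor_graph <- function(net, node, eps = 1e-6,
                                   include_undecided = FALSE) {
  shape <- node_shape(net, node)
  core <- factor_graph_core(shape$signs, shape$k, eps, include_undecided)
  C <- nrow(core$chains)
  orders <- perms_identity_first(shape$k)
  n_class <- nrow(orders)
  V <- C * n_class
  vid <- function(class, i) (class - 1L) * C + i

  adj_from <- integer(0); adj_to <- integer(0)
  for (cl in seq_len(n_class)) {
    adj_from <- c(adj_from, vid(cl, core$cover_from))
    adj_to <- c(adj_to, vid(cl, core$cover_to))
  }
  # cross-class adjacency: adjacent transposition with equal sets at the
  # transposed levels
  if (n_class > 1L) {
    okey <- apply(orders, 1L, paste, collapse = ",")
    for (cl in seq_len(n_class)) {
      for (pos in seq_len(shape$k - 1L)) {
        o2 <- orders[cl, ]
        o2[c(pos, pos + 1L)] <- o2[c(pos + 1L, pos)]
        cl2 <- match(paste(o2, collapse = ","), okey)
        if (cl2 <= cl) next
        same <- which(core$chains[, pos] == core$chains[, pos + 1L])
        adj_from <- c(adj_from, vid(cl, same))
        adj_to <- c(adj_to, vid(cl2, same))
      }
    }
  }

  structure(list(
    node = node, shape = shape,
    chains = core$chains, witnesses = core$witnesses,
    essential = core$essential, sizes = core$sizes,
    orders = orders, n_class = n_class, per_class = C, n_vertices = V,
    adj_from = adj_from, adj_to = adj_to,
    cover_from = core$cover_from, cover_to = core$cover_to,
    n_undecided = core$n_undecided, eps = eps
  ), class = "factor_graph")
}

#' @export
print.factor_graph <- function(x, ...) {
  cat("<factor_graph> node ", x$node, ": ", x$n_vertices, " vertices (",
      x$per_class, " per class x ", x$n_class, " threshold orders), ",
      sum(x$essential) * x$n_class, " essential\n", sep = "")
  if (x$n_undecided > 0) {
    cat("  warning: ", x$n_undecided,
        " candidate regions undecided and excluded\n", sep = "")
  }
  invisible(x)
}

# vertex id decomposition
fg_class_of <- function(fg, id) ((id - 1L) %/% fg$per_class) + 1L
fg_chain_of <- function(fg, id) ((id - 1L) %% fg$per_class) + 1L

# chain masks (level -> state-set bitmask) of a vertex
fg_masks <- function(fg, id) fg$chains[fg_chain_of(fg, id), ]

fg_order <- function(fg, id) fg$orders[fg_class_of(fg, id), ]

fg_is_essential <- function(fg, id) fg$essential[fg_chain_of(fg, id)]

fg_witness <- function(fg, id) fg$witnesses[[fg_chain_of(fg, id)]]

# ids of the essential vertices (all classes)
fg_essential_ids <- function(fg) {
  base <- which(fg$essential)
  as.integer(outer(base, (seq_len(fg$n_class) - 1L) * fg$per_class, `+`))
}

# minimal (all-below) and maximal (all-above) vertex of one class
fg_min_vertex <- function(fg, class = 1L) {
  i <- which(rowSums(fg$chains != 0L) == 0L)
  stopifnot(length(i) == 1L)
  (class - 1L) * fg$per_class + i
}

fg_max_vertex <- function(fg, class = 1L) {
  full <- 2L^fg$shape$n_states - 1L
  i <- which(rowSums(fg$chains != full) == 0L)
  stopifnot(length(i) == 1L)
  (class - 1L) * fg$per_class + i
}

#' Classify numeric node parameters onto a factor-graph vertex
#'
#' Computes, for strictly positive parameter values, which enumerated
#' region they fall in: the threshold order is read off the sorted scaled
#' thresholds and each level's state set from the comparisons "production
#' value vs gamma * threshold".
#'
#' @param fg a [enumerate_factor_graph()] result.
#' @param gamma,ell,delta,theta,beta numeric parameters of the node
#'   (`ell`/`delta` ordered like the node's in-edges, ascending source
#'   index; `theta` named by 0-based target via position in ascending target
#'   order; `beta` only for a node without in-edges).
#' @return The vertex id, or `NA` if the point lies on a boundary or in an
#'   unenumerated region.
#' @export
classify_node_parameters <- function(fg, gamma = 1, ell = NULL, delta = NULL,
                                     theta, beta = NULL) {
  shape <- fg$shape
  vals <- production_values(shape, ell, delta, beta)
  scaled <- gamma * theta
  ord <- order(scaled)
  perm_row <- match(paste(ord, collapse = ","),
                    apply(fg$orders, 1L, paste, collapse = ","))
  if (is.na(perm_row)) return(NA_integer_)
  masks <- vapply(scaled[ord], function(tt) {
    above <- which(vals > tt) - 1L
    if (length(above) == 0L) 0L else sum(bitwShiftL(1L, above))
  }, integer(1))
  i <- match(paste(masks, collapse = ","),
             apply(fg$chains, 1L, paste, collapse = ","))
  if (is.na(i)) return(NA_integer_)
  (perm_row - 1L) * fg$per_class + i
}
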