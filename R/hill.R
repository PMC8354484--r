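# Hill-function ODE models and pseudo-arclength continuation.
#
# The smooth counterpart of the switching model replaces each step
# nonlinearity by a Hill function with shared exponent n:
#   increasing  H+(x) = ell + delta * x^n / (theta^n + x^n)
#   decreasing  H-(x) = ell + delta * theta^n / (theta^n + x^n)
# so node i obeys dx_i/dt = -gamma_i x_i + H_i(x) + [i = input] * s, with
# H_i built by the same sum-then-multiply algebra as the combinatorial
# production values.  Hysteresis of a parameter point is validated by
# continuing an equilibrium curve in the input s and counting saddle-node
# folds via the sign of the Jacobian determinant.

#' Construct a Hill ODE system from a network and parameters
#'
#' @param net a [regulatory_network()].
#' @param params named numeric vector in the symbol grammar of
#'   [region_inequalities()] (one row of [sample_parameters()] works), or a
#'   list with matrices `ell`, `delta`, `theta` (target x source), vectors
#'   `gamma` and `beta`.
#' @param hill_n shared Hill exponent.
#' @param s input signal added to the input node's rate.
#' @return An object of class `hill_system`.
#' @export
hill_system <- function(net, params, hill_n, s = 0) {
  N <- n_nodes(net)
  if (!is.list(params) || is.data.frame(params)) {
    params <- unlist(params)
    gamma <- ell <- delta <- theta <- NULL
    gam <- vapply(seq_len(N) - 1L, function(n) params[[sym_gamma(n)]],
                  numeric(1))
    ell <- delta <- theta <- matrix(NA_real_, N, N)
    beta <- rep(NA_real_, N)
    for (i in seq_len(N) - 1L) {
      srcs <- in_sources(net, i)
      if (length(srcs) == 0L) {
        beta[i + 1L] <- params[[sym_b(i)]]
        next
      }
      for (j in srcs) {
        ell[i + 1L, j + 1L] <- params[[sym_l(i, j)]]
        delta[i + 1L, j + 1L] <- params[[sym_d(i, j)]]
        theta[i + 1L, j + 1L] <- params[[sym_t(i, j)]]
      }
    }
    params <- list(gamma = gam, ell = ell, delta = delta, theta = theta,
                   beta = beta)
  }
  stopifnot(all(params$gamma > 0))
  nodes <- lapply(seq_len(N) - 1L, function(i) {
    srcs <- in_sources(net, i)
    signs <- in_signs(net, i)
    list(act = srcs[signs > 0L], rep = srcs[signs < 0L],
         ell = params$ell[i + 1L, , drop = TRUE],
         delta = params$delta[i + 1L, , drop = TRUE],
         theta = params$theta[i + 1L, , drop = TRUE],
         beta = params$beta[i + 1L])
  })
  structure(list(net = net, N = N, gamma = params$gamma, nodes = nodes,
                 hill_n = hill_n, s = s, params = params),
            class = "hill_system")
}

# stable Hill evaluations via the logistic of n * log(x / theta)
hill_p <- function(x, theta, n) stats::plogis(n * (log(x) - log(theta)))

#' Rate function and Jacobian of a Hill system
#'
#' @param sys a [hill_system()].
#' @param x strictly positive state vector.
#' @param s input signal (defaults to the system's).
#' @return `hill_rhs()` the rate vector; `hill_jacobian()` the N x N
#'   Jacobian of the rate with respect to `x`.
#' @export
hill_rhs <- function(sys, x, s = sys$s) {
  n <- sys$hill_n
  vapply(seq_len(sys$N), function(i1) {
    nd <- sys$nodes[[i1]]
    lam <- if (length(nd$act) + length(nd$rep) == 0L) {
      nd$beta
    } else {
      sumpart <- if (length(nd$act)) {
        sum(vapply(nd$act, function(j) {
          p <- hill_p(x[j + 1L], nd$theta[j + 1L], n)
          nd$ell[j + 1L] + nd$delta[j + 1L] * p
        }, numeric(1)))
      } else 1
      prodpart <- if (length(nd$rep)) {
        prod(vapply(nd$rep, function(j) {
          p <- hill_p(x[j + 1L], nd$theta[j + 1L], n)
          nd$ell[j + 1L] + nd$delta[j + 1L] * (1 - p)
        }, numeric(1)))
      } else 1
      sumpart * prodpart
    }
    -sys$gamma[i1] * x[i1] + lam +
      if (i1 == sys$net$input_node + 1L) s else 0
  }, numeric(1))
}

#' @rdname hill_rhs
#' @export
hill_jacobian <- function(sys, x) {
  n <- sys$hill_n
  J <- diag(-sys$gamma, sys$N)
  for (i1 in seq_len(sys$N)) {
    nd <- sys$nodes[[i1]]
    if (length(nd$act) + length(nd$rep) == 0L) next
    pvals <- numeric(sys$N)
    sumpart <- 1
    if (length(nd$act)) {
      sumpart <- sum(vapply(nd$act, function(j) {
        pvals[j + 1L] <<- hill_p(x[j + 1L], nd$theta[j + 1L], n)
        nd$ell[j + 1L] + nd$delta[j + 1L] * pvals[j + 1L]
      }, numeric(1)))
    }
    repfac <- vapply(nd$rep, function(j) {
      pvals[j + 1L] <<- hill_p(x[j + 1L], nd$theta[j + 1L], n)
      nd$ell[j + 1L] + nd$delta[j + 1L] * (1 - pvals[j + 1L])
    }, numeric(1))
    prodpart <- prod(repfac)
    for (j in nd$act) {
      p <- pvals[j + 1L]
      dH <- nd$delta[j + 1L] * n * p * (1 - p) / x[j + 1L]
      J[i1, j + 1L] <- J[i1, j + 1L] + dH * prodpart
    }
    for (jj in seq_along(nd$rep)) {
      j <- nd$rep[jj]
      p <- pvals[j + 1L]
      dH <- -nd$delta[j + 1L] * n * p * (1 - p) / x[j + 1L]
      other <- prod(repfac[-jj])
      J[i1, j + 1L] <- J[i1, j + 1L] + sumpart * dH * other
    }
  }
  J
}

#' Newton search for an equilibrium
#'
#' @param sys a [hill_system()].
#' @param guess strictly positive starting point.
#' @param tol residual norm tolerance.
#' @param maxit iteration cap.
#' @return The equilibrium (numeric vector) or `NULL` on non-convergence
#'   (including a singular Jacobian or an escape from the positive orthant).
#' @export
find_equilibrium <- function(sys, guess, tol = 1e-10, maxit = 100L) {
  x <- as.numeric(guess)
  if (any(x <= 0)) stop("guess must be strictly positive", call. = FALSE)
  for (it in seq_len(maxit)) {
    f <- hill_rhs(sys, x)
    if (sqrt(sum(f^2)) < tol) {
      return(if (all(x > 0)) x else NULL)
    }
    J <- hill_jacobian(sys, x)
    step <- tryCatch(solve(J, -f), error = function(e) NULL)
    if (is.null(step) || any(!is.finite(step))) return(NULL)
    x <- x + step
    if (any(!is.finite(x)) || any(x <= 0)) {
      x <- pmax(x, 1e-12)  # keep iterates in the open orthant
    }
  }
  NULL
}

# corrector: Newton on [F(x, s); tangent . (z - z_pred)] in z = (x, s)
pa_correct <- function(sys, z, tang, z_pred, tol = 1e-10, maxit = 25L) {
  N <- sys$N
  for (it in seq_len(maxit)) {
    f <- hill_rhs(sys, z[seq_len(N)], s = z[N + 1L])
    g <- sum(tang * (z - z_pred))
    if (sqrt(sum(f^2) + g^2) < tol) return(z)
    J <- hill_jacobian(sys, z[seq_len(N)])
    Fs <- numeric(N); Fs[sys$net$input_node + 1L] <- 1
    A <- rbind(cbind(J, Fs), tang)
    step <- tryCatch(solve(A, -c(f, g)), error = function(e) NULL)
    if (is.null(step) || any(!is.finite(step))) return(NULL)
    z <- z + step
    if (any(z[seq_len(N)] <= 0)) return(NULL)
  }
  NULL
}

pa_tangent <- function(sys, z, prev = NULL) {
  N <- sys$N
  J <- hill_jacobian(sys, z[seq_len(N)])
  Fs <- numeric(N); Fs[sys$net$input_node + 1L] <- 1
  A <- cbind(J, Fs)
  tang <- qr.Q(qr(t(A)), complete = TRUE)[, N + 1L]
  if (!is.null(prev) && sum(tang * prev) < 0) tang <- -tang
  tang
}

#' Pseudo-arclength continuation of an equilibrium curve
#'
#' Traces the equilibrium curve of a Hill system through the input range,
#' starting from an equilibrium at the lower end, with an adaptive
#' predictor-corrector scheme.  Saddle-node folds are detected by sign
#' changes of `det(J)` along the curve and refined by bisection in
#' arclength until the fold's `s` is bracketed to `1e-8`; the output
#' records the output-node values just before and after each fold.
#'
#' @param sys a [hill_system()].
#' @param start equilibrium at `s = s_range[1]`.
#' @param s_range continuation interval for the input (default `c(0, 4)`).
#' @param ds0,ds_min,ds_max initial/minimal/maximal arclength steps.
#' @param max_steps step budget.
#' @return An object of class `continuation_curve`: tibble `points`
#'   (`s`, one column per state, `det`), tibble `folds` (`s`, `x_out_before`,
#'   `x_out_after`), and flags `complete` (reached the upper end of
#'   `s_range`).
#' @export
continue_curve <- function(sys, start, s_range = c(0, 4), ds0 = 0.01,
                           ds_min = 1e-5, ds_max = 0.1, max_steps = 100000L) {
  N <- sys$N
  out1 <- sys$net$output_node + 1L
  z <- c(start, s_range[1L])
  tang <- pa_tangent(sys, z)
  if (tang[N + 1L] < 0) tang <- -tang  # head into increasing s
  pts <- matrix(NA_real_, 512L, N + 2L)
  npts <- 0L
  push <- function(z, d) {
    if (npts == nrow(pts)) pts <<- rbind(pts, matrix(NA_real_, nrow(pts), N + 2L))
    npts <<- npts + 1L
    pts[npts, ] <<- c(z[N + 1L], z[seq_len(N)], d)
  }
  detj <- function(z) det(hill_jacobian(sys, z[seq_len(N)]))
  push(z, detj(z))
  folds <- list()
  h <- ds0
  complete <- FALSE
  steps <- 0L
  while (steps < max_steps) {
    steps <- steps + 1L
    z_pred <- z + h * tang
    z_new <- pa_correct(sys, z_pred, tang, z_pred)
    if (is.null(z_new)) {
      h <- h / 2
      if (h < ds_min) break
      next
    }
    d_old <- pts[npts, N + 2L]
    d_new <- detj(z_new)
    if (sign(d_new) != sign(d_old) && d_old != 0) {
      folds[[length(folds) + 1L]] <- refine_fold(sys, z, tang, h, d_old,
                                                 out1, z_new)
    }
    push(z_new, d_new)
    tang <- pa_tangent(sys, z_new, prev = tang)
    z <- z_new
    if (z[N + 1L] > s_range[2L]) { complete <- TRUE; break }
    if (z[N + 1L] < s_range[1L] - 0.5) break
    h <- min(h * 1.3, ds_max)
  }
  pts <- pts[seq_len(npts), , drop = FALSE]
  colnames(pts) <- c("s", sys$net$node_names, "det")
  folds_tb <- if (length(folds)) {
    tibble::as_tibble(do.call(rbind, folds))
  } else {
    tibble::tibble(s = numeric(0), x_out_before = numeric(0),
                   x_out_after = numeric(0))
  }
  structure(list(points = tibble::as_tibble(as.data.frame(pts)),
                 folds = folds_tb, complete = complete, steps = steps),
            class = "continuation_curve")
}

# bisection in arclength between the last accepted point and the sign
# change; returns c(s_fold, x_out just before, just after)
refine_fold <- function(sys, z0, tang, h, d0, out1, z1) {
  lo <- 0; hi <- h
  z_lo <- z0; z_hi <- z1
  N <- sys$N
  while (abs(z_hi[N + 1L] - z_lo[N + 1L]) > 1e-8 && (hi - lo) > 1e-12) {
    mid <- (lo + hi) / 2
    z_pred <- z0 + mid * tang
    z_mid <- pa_correct(sys, z_pred, tang, z_pred)
    if (is.null(z_mid)) break
    if (sign(det(hill_jacobian(sys, z_mid[seq_len(N)]))) == sign(d0)) {
      lo <- mid; z_lo <- z_mid
    } else {
      hi <- mid; z_hi <- z_mid
    }
  }
  c(s = unname((z_lo[N + 1L] + z_hi[N + 1L]) / 2),
    x_out_before = unname(z0[out1]), x_out_after = unname(z1[out1]))
}

#' @export
print.continuation_curve <- function(x, ...) {
  cat("<continuation_curve> ", nrow(x$points), " points, ",
      nrow(x$folds), " folds, ",
      if (x$complete) "complete" else "incomplete", "\n", sep = "")
  invisible(x)
}

# thresholds applied to each variable (columns of theta), with the
# placeholder for nodes without out-edges falling back to the largest
# finite threshold so the sampling boxes stay defined
variable_thresholds <- function(sys) {
  lapply(seq_len(sys$N), function(j1) {
    th <- sys$params$theta[, j1]
    th <- th[!is.na(th)]
    if (length(th) == 0L) th <- 1
    th
  })
}

#' Hysteresis test of one sampled parameter point
#'
#' Implements the continuation-based decision procedure: sample a fixed
#' number of initial guesses in the low box `0 < x_j <= min theta_{*,j}`
#' (for descending mode the output coordinate is drawn from
#' `(max theta, 2 max theta]`), run Newton at `s = 0`, keep equilibria whose
#' output coordinate lies in the required band, continue each to `s = 4`,
#' and declare the point hysteretic when some curve reaches the upper end
#' with an even, nonzero number of saddle-node folds that all jump the
#' output coordinate in the mode's direction.  All failure paths (no
#' convergence, incomplete curves) yield `FALSE`.
#'
#' @param sys a [hill_system()] at `s = 0`.
#' @param mode `"ascending"` or `"descending"`.
#' @param guesses number of random initial guesses.
#' @param seed integer seed for the guesses.
#' @param s_max upper end of the continuation range.
#' @return Logical scalar, with attribute `curves` giving the number of
#'   continuations run.
#' @export
hysteretic_parameter_point <- function(sys, mode = c("ascending", "descending"),
                                       guesses = 10L, seed = 1L, s_max = 4) {
  mode <- match.arg(mode)
  thr <- variable_thresholds(sys)
  out1 <- sys$net$output_node + 1L
  with_seed(seed, {
    seen <- list()
    n_curves <- 0L
    for (g in seq_len(guesses)) {
      x0 <- vapply(seq_len(sys$N), function(j1) {
        stats::runif(1, 0, min(thr[[j1]]))
      }, numeric(1))
      if (mode == "descending") {
        x0[out1] <- stats::runif(1, max(thr[[out1]]), 2 * max(thr[[out1]]))
      }
      eq <- find_equilibrium(sys, x0)
      if (is.null(eq)) next
      band_ok <- if (mode == "ascending") {
        eq[out1] > 0 && eq[out1] <= min(thr[[out1]])
      } else {
        eq[out1] > max(thr[[out1]])
      }
      if (!band_ok) next
      key <- paste(round(eq, 8L), collapse = ",")
      if (!is.null(seen[[key]])) next
      seen[[key]] <- TRUE
      n_curves <- n_curves + 1L
      cur <- continue_curve(sys, eq, s_range = c(0, s_max))
      nf <- nrow(cur$folds)
      if (cur$complete && nf >= 2L && nf %% 2L == 0L) {
        jumps_ok <- if (mode == "ascending") {
          all(cur$folds$x_out_before < cur$folds$x_out_after)
        } else {
          all(cur$folds$x_out_before > cur$folds$x_out_after)
        }
        if (jumps_ok) return(structure(TRUE, curves = n_curves))
      }
    }
    structure(FALSE, curves = n_curves)
  })
}

#' Minimal-input essential parameter vertices
#'
#' The vertex set used for validating switch designs numerically: the
#' input node at the minimal (all-below) vertex of one threshold-order
#' class, crossed with the essential combinations of the remaining nodes.
#'
#' @param pg a [build_parameter_graph()] result.
#' @param class threshold-order class for the input node.
#' @return A list of full parameter-vertex vectors.
#' @export
minimal_essential_vertices <- function(pg, class = 1L) {
  net <- pg$net
  n1 <- net$input_node + 1L
  other <- setdiff(seq_len(n_nodes(net)) - 1L, net$input_node)
  ess <- essential_subgraph(pg, other)
  v0 <- fg_min_vertex(pg$fgs[[n1]], class)
  lapply(seq_len(nrow(ess)), function(r) {
    v <- integer(n_nodes(net))
    v[n1] <- v0
    v[other + 1L] <- as.integer(ess[r, , drop = TRUE])
    v
  })
}

#' Monte-Carlo Hill hysteresis frequency
#'
#' Samples numeric parameters from the given parameter vertices
#' (round-robin), tests each sampled point with
#' [hysteretic_parameter_point()], and reports the percentage of hysteretic
#' points.  Per-sample solver failures count as non-hysteretic and are
#' flagged in the records.
#'
#' @param pg a [build_parameter_graph()] result.
#' @param vertices list of full parameter-vertex vectors (e.g.
#'   [minimal_essential_vertices()]).
#' @param n_samples number of sampled parameter points.
#' @param hill_n Hill exponent.
#' @param seed integer seed; fixes the samples and the Newton guesses.
#' @param mode,guesses,s_max passed to [hysteretic_parameter_point()].
#' @return A list with `score` (percent, `NA` when `n_samples = 0`) and
#'   `records` (tibble: sample, vertex index, hysteretic, failed).
#' @export
monte_carlo_hysteresis_score <- function(pg, vertices, n_samples, hill_n,
                                         seed = 1L,
                                         mode = "ascending", guesses = 10L,
                                         s_max = 4) {
  if (n_samples == 0L) {
    return(list(score = NA_real_,
                records = tibble::tibble(sample = integer(0),
                                         vertex = integer(0),
                                         hysteretic = logical(0),
                                         failed = logical(0))))
  }
  recs <- lapply(seq_len(n_samples), function(i) {
    vi <- ((i - 1L) %% length(vertices)) + 1L
    res <- tryCatch({
      par <- sample_parameters(pg, vertices[[vi]], 1L, seed = seed + 13L * i)
      sys <- hill_system(pg$net, par[1L, ], hill_n = hill_n, s = 0)
      hy <- hysteretic_parameter_point(sys, mode = mode, guesses = guesses,
                                       seed = seed + 31L * i, s_max = s_max)
      c(as.logical(hy), FALSE)
    }, error = function(e) c(FALSE, TRUE))
    tibble::tibble(sample = i, vertex = vi, hysteretic = res[1L],
                   failed = res[2L])
  })
  records <- do.call(rbind, recs)
  list(score = 100 * mean(records$hysteretic), records = records)
}
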