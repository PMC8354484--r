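# broom-style tidiers and ggplot2 autoplot methods

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a score report
#'
#' @param x a `score_report` from [hysteresis_score()].
#' @param ... unused.
#' @return `tidy()`: one row per parameter vertex with its hysteretic path
#'   count and fraction; `glance()`: a one-row summary (mode, path kind,
#'   score, counts).
#' @method tidy score_report
#' @export
tidy.score_report <- function(x, ...) {
  out <- x$per_param
  out$fraction <- if (x$n_paths > 0) out$hysteretic / x$n_paths else NA_real_
  out
}

#' @rdname tidy.score_report
#' @method glance score_report
#' @export
glance.score_report <- function(x, ...) {
  tibble::tibble(
    mode = x$mode, path_kind = x$path_kind,
    parameter_set = x$parameter_set, class = x$class,
    strict_ends = x$strict_ends,
    n_paths = x$n_paths, n_param = x$n_param,
    numerator = x$numerator, denominator = x$denominator,
    score = x$score
  )
}

#' Tidy a factor graph
#'
#' @param x a `factor_graph`.
#' @param ... unused.
#' @return One row per vertex: id, class, threshold order, binarization
#'   chain (list of state-code vectors), total chain size, and the
#'   essential flag.
#' @method tidy factor_graph
#' @export
tidy.factor_graph <- function(x, ...) {
  ids <- seq_len(x$n_vertices)
  chains <- lapply(ids, function(id) {
    masks <- fg_masks(x, id)
    lapply(masks, function(msk) {
      which(bitwAnd(msk, bitwShiftL(1L, 0:(x$shape$n_states - 1L))) != 0L) - 1L
    })
  })
  tibble::tibble(
    id = ids,
    class = fg_class_of(x, ids),
    order = lapply(ids, function(id) fg_order(x, id)),
    chain = chains,
    size = x$sizes[fg_chain_of(x, ids)],
    essential = x$essential[fg_chain_of(x, ids)]
  )
}

#' @rdname tidy.factor_graph
#' @method glance factor_graph
#' @export
glance.factor_graph <- function(x, ...) {
  tibble::tibble(node = x$node, n_vertices = x$n_vertices,
                 per_class = x$per_class, n_class = x$n_class,
                 n_essential = sum(x$essential) * x$n_class,
                 n_undecided = x$n_undecided)
}

#' Tidy a Morse graph
#'
#' @param x a `morse_graph`.
#' @param ... unused.
#' @return One row per Morse node with its size, FP label and minimal flag.
#' @method tidy morse_graph
#' @export
tidy.morse_graph <- function(x, ...) x$nodes

#' Tidy a continuation curve
#'
#' @param x a `continuation_curve`.
#' @param ... unused.
#' @return `tidy()`: the accepted curve points; `glance()`: a one-row
#'   summary with the fold count and completion flag.
#' @method tidy continuation_curve
#' @export
tidy.continuation_curve <- function(x, ...) x$points

#' @rdname tidy.continuation_curve
#' @method glance continuation_curve
#' @export
glance.continuation_curve <- function(x, ...) {
  tibble::tibble(n_points = nrow(x$points), n_folds = nrow(x$folds),
                 complete = x$complete, steps = x$steps)
}

#' Plot a continuation curve
#'
#' Draws the equilibrium branch of the output variable against the input
#' signal, marking detected saddle-node folds.
#'
#' @param object a `continuation_curve`.
#' @param output name of the state column to plot (default: the last one).
#' @param ... unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.continuation_curve <- function(object, output = NULL, ...) {
  pts <- object$points
  if (is.null(output)) output <- names(pts)[ncol(pts) - 1L]
  p <- ggplot2::ggplot(pts, ggplot2::aes(x = .data$s, y = .data[[output]])) +
    ggplot2::geom_path() +
    ggplot2::labs(x = "input signal s", y = output,
                  title = "Equilibrium continuation")
  if (nrow(object$folds)) {
    p <- p + ggplot2::geom_vline(xintercept = object$folds$s,
                                 linetype = "dashed", colour = "red")
  }
  p
}

#' Plot a hysteresis screen
#'
#' Ranks networks by hysteresis score, with the perturbed score overlaid —
#' the visual summary of a screen run.
#'
#' @param object a tibble from [screen()].
#' @param ... unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.switch_screen <- function(object, ...) {
  df <- object[!is.na(object$hysteresis_score), ]
  df$rank <- seq_len(nrow(df))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$rank)) +
    ggplot2::geom_col(ggplot2::aes(y = .data$hysteresis_score),
                      fill = "steelblue", width = 0.8) +
    ggplot2::geom_point(ggplot2::aes(y = .data$perturbed_score),
                        colour = "red", size = 1) +
    ggplot2::labs(x = "rank", y = "hysteresis score (%)",
                  title = "Hysteresis screen (bars: essential, dots: perturbed)")
}
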