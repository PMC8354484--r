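# Built-in study networks.  The three-node designs are reconstructed from
# their defining algebraic descriptions: the activating three-cycle
# (network1), the all-activator six-edge design whose ODE form drives the
# continuation examples (network12), and network12 with the x2 -> x1 edge
# removed (network6), whose node 0 then carries three out-thresholds.

fixture_specs <- list(
  network1 = c("x0 : (x2)", "x1 : (x0)", "x2 : (x1)"),
  network6 = c("x0 : (x0 + x1 + x2)", "x1 : (x0)", "x2 : (x0)"),
  network12 = c("x0 : (x0 + x1 + x2)", "x1 : (x0 + x2)", "x2 : (x0)"),
  toy1d = "x0 :",
  selfrepressor = "x0 : (~x0)"
)

#' Built-in example networks with reference values
#'
#' Constructs one of the package's standard fixtures programmatically:
#' `network1` (activating 3-cycle, the minimal fragile switch),
#' `network6` (robust all-activator design with a tristable input cascade),
#' `network12` (the top-ranked consistent all-activator design),
#' `toy1d` (a single node with neither in- nor out-edges, exercising the
#' constant production and placeholder threshold), and `selfrepressor`
#' (a single self-repressing node, exercising the refined complex).
#' The `expected` entries are reference values for these designs that the
#' package's tests reproduce; each carries a note saying what it is.
#'
#' @param name fixture name.
#' @return A list with `name`, `network` (a [regulatory_network()]), and
#'   `expected` (named list of reference quantities with notes).
#' @examples
#' make_fixture("network1")$expected$parameter_graph_size
#' @export
make_fixture <- function(name) {
  if (!name %in% names(fixture_specs)) {
    stop("unknown fixture ", dQuote(name), "; available: ",
         paste(names(fixture_specs), collapse = ", "), call. = FALSE)
  }
  net <- parse_network(fixture_specs[[name]])
  expected <- switch(
    name,
    network1 = list(
      parameter_graph_size = 27,
      n_cells = 8,
      n_partial_paths = 1,
      hysteresis_score = 100,
      perturbed_score = 20,
      robustness = 0.2,
      label = "fragile",
      descending_score = 0,
      note = paste("3 regions per node; the unique essential (v1, v2)",
                   "vertex supports the unique monotone path's",
                   "low / bistable / high sequence")
    ),
    network6 = list(
      n_cells = 16,
      n_essential_param = 1,
      assured_fps = c("FP(0, 0, 0)", "FP(3, 1, 1)"),
      descending_score = 0,
      note = paste("node 0 has three out-thresholds (four input states);",
                   "bistability between the all-low and all-high cells",
                   "holds at every essential parameter vertex")
    ),
    network12 = list(
      n_edges = 6,
      n_cells = 24,
      full_path_score = 100,
      descending_score = 0,
      continuation_example = list(
        hill_n = 4, n_folds = 2,
        params = reference_continuation_params(),
        note = "reference parameter set of the bundled continuation example"
      ),
      note = "six-edge all-activator design; top-ranked robust switch"
    ),
    toy1d = list(
      n_factor_vertices = 2,
      n_cells = 2,
      note = "constant production vs the placeholder threshold"
    ),
    selfrepressor = list(
      n_factor_vertices = 3,
      n_cells = 3,
      note = "doubled self-threshold; the stable state sits on the thin cell"
    )
  )
  list(name = name, network = net, expected = expected)
}

# the reference continuation example for network12 (gamma = 1, summed low
# rates L_i split evenly across each node's activator group)
reference_continuation_params <- function() {
  L <- c(0.508736659464953, 0.823149364604282, 0.129562882298977)
  p <- c(1, 1, 1,
         L[1] / 3, L[1] / 3, L[1] / 3, L[2] / 2, L[2] / 2, L[3],
         1.172412555847297, 0.946904335902318, 0.077108238106769,
         2.862607698545040, 1.624416688203425, 4.947150771599252,
         2.742699202456864, 1.753260803421655, 0.724695975751957,
         3.176067131107269, 1.566020932246446, 3.406985767928092)
  names(p) <- c(sym_gamma(0), sym_gamma(1), sym_gamma(2),
                sym_l(0, 0), sym_l(0, 1), sym_l(0, 2),
                sym_l(1, 0), sym_l(1, 2), sym_l(2, 0),
                sym_d(0, 0), sym_d(0, 1), sym_d(0, 2),
                sym_d(1, 0), sym_d(1, 2), sym_d(2, 0),
                sym_t(0, 0), sym_t(0, 1), sym_t(0, 2),
                sym_t(1, 0), sym_t(1, 2), sym_t(2, 0))
  p
}
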