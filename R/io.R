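# Serialization: JSON for factor graphs and regions, DOT for STGs and
# Morse graphs, atomic CSV/JSON report writing.

#' Export a factor graph as JSON
#'
#' Vertices carry their id, threshold order (0-based out-targets, `null`
#' for the placeholder), binarization chain as state-code lists, essential
#' flag and numeric witness; the adjacency is an edge list.
#'
#' @param fg a `factor_graph`.
#' @param path optional file; when `NULL` the JSON string is returned.
#' @return The JSON string, invisibly when written to a file.
#' @export
export_factor_graph_json <- function(fg, path = NULL) {
  td <- tidy(fg)
  vertices <- lapply(seq_len(nrow(td)), function(i) {
    ord <- td$order[[i]]
    tg <- if (fg$shape$placeholder) NULL else fg$shape$targets[ord]
    w <- fg_witness(fg, td$id[i])
    list(id = td$id[i], class = td$class[i], threshold_order = tg,
         chain = td$chain[[i]], essential = td$essential[i],
         witness = w[!vapply(w, is.null, logical(1))])
  })
  x <- list(node = fg$node, n_vertices = fg$n_vertices,
            vertices = vertices,
            adjacency = cbind(fg$adj_from, fg$adj_to))
  json <- jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (is.null(path)) return(json)
  writeLines(json, path)
  invisible(json)
}

#' Export a parameter region as JSON
#'
#' @param region a `parameter_region` from [region_inequalities()].
#' @param path optional file.
#' @return The JSON string, invisibly when written to a file.
#' @export
export_region_json <- function(region, path = NULL) {
  x <- list(vertex = region$vertex, inequalities = region$inequalities,
            witness = as.list(region$witness))
  json <- jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (is.null(path)) return(json)
  writeLines(json, path)
  invisible(json)
}

#' Export an STG or Morse graph as DOT
#'
#' @param x a `stg` or `morse_graph`.
#' @param path optional file.
#' @return The DOT string, invisibly when written to a file.
#' @export
export_dot <- function(x, path = NULL) {
  lines <- if (inherits(x, "stg")) {
    cells <- apply(x$complex$cells, 1L, paste, collapse = ",")
    c("digraph stg {",
      sprintf("  n%d [label=\"(%s)\"%s];", seq_along(cells), cells,
              ifelse(x$self, " shape=doublecircle", "")),
      sprintf("  n%d -> n%d;", x$edges[, 1L], x$edges[, 2L]),
      "}")
  } else if (inherits(x, "morse_graph")) {
    lab <- ifelse(is.na(x$nodes$fp), paste0("cycle[", x$nodes$n_cells, "]"),
                  x$nodes$fp)
    c("digraph morse {",
      sprintf("  m%d [label=\"%s\"%s];", x$nodes$id, lab,
              ifelse(x$nodes$minimal, " peripheries=2", "")),
      if (!is.null(x$edges) && nrow(x$edges)) {
        sprintf("  m%d -> m%d;", x$edges[, "from"], x$edges[, "to"])
      },
      "}")
  } else {
    stop("export_dot() handles stg and morse_graph objects", call. = FALSE)
  }
  if (is.null(path)) return(paste(lines, collapse = "\n"))
  writeLines(lines, path)
  invisible(paste(lines, collapse = "\n"))
}

# write a file atomically: to a temp sibling, then rename
write_atomic <- function(writer, path) {
  tmp <- paste0(path, ".tmp", Sys.getpid())
  on.exit(if (file.exists(tmp)) unlink(tmp), add = TRUE)
  writer(tmp)
  if (!file.rename(tmp, path)) stop("cannot write ", path, call. = FALSE)
  invisible(path)
}

#' Write a results report with a provenance log
#'
#' Writes tabular results as CSV and/or structured results as JSON,
#' atomically (temp file plus rename), and appends a log line recording the
#' package version, seed and a hash of the configuration, so that runs are
#' auditable and byte-reproducible given the same config and seed.
#'
#' @param results a data frame (written as CSV) or list (written as JSON).
#' @param path output file; format chosen by extension (`.csv` or `.json`).
#' @param config optional named list recorded in the log (a `seed` entry is
#'   echoed explicitly).
#' @param log_path log file; default `<path>.log`.
#' @return `path`, invisibly.
#' @export
run_report <- function(results, path, config = list(),
                       log_path = paste0(path, ".log")) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "csv") {
    stopifnot(is.data.frame(results))
    write_atomic(function(p) {
      utils::write.csv(as.data.frame(results), p, row.names = FALSE)
    }, path)
  } else if (ext == "json") {
    write_atomic(function(p) {
      jsonlite::write_json(results, p, auto_unbox = TRUE, digits = NA,
                           pretty = TRUE)
    }, path)
  } else {
    stop("unsupported report extension ", dQuote(ext), call. = FALSE)
  }
  cfg_str <- paste(names(config), unlist(config), sep = "=", collapse = "|")
  cfg_int <- utf8ToInt(if (nzchar(cfg_str)) cfg_str else " ")
  cfg_hash <- sum(cfg_int * seq_along(cfg_int)) %% 1e9
  line <- sprintf("%s switchgrade=%s seed=%s config_hash=%09d file=%s",
                  format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
                  as.character(utils::packageVersion("switchgrade")),
                  if (is.null(config$seed)) "NA" else config$seed,
                  cfg_hash, basename(path))
  cat(line, "\n", file = log_path, append = TRUE)
  invisible(path)
}
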