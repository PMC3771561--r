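# One-call pipeline: graph -> SCCs -> covers -> characteristics -> fixed
# points -> stability.

#' Full circuit-breaking analysis of a model
#'
#' Convenience wrapper running the whole pipeline: interaction graph, SCC
#' decomposition, circuit covers, circuit-characteristics (per cyclic SCC,
#' under the first upstream fixed-point combination), assembled fixed points
#' and their stability report.
#'
#' @param model a `regmodel`.
#' @param overrides optional parameter overrides.
#' @param control see [cba_control()].
#' @param self_edges self-edge convention for [build_igraph()].
#' @param grid optional named list `list(lo=, hi=, n=)` overriding the
#'   characteristic grid (clipped to each leading variable's bounds).
#' @param seed seed for the interaction-graph sampling.
#' @return object of class `"cba_analysis"` with components `model`,
#'   `graph`, `scc`, `covers`, `characteristics`, `fixed_points`,
#'   `stability`.
#' @export
analyze_model <- function(model, overrides = NULL, control = cba_control(),
                          self_edges = "default", grid = NULL, seed = 1L) {
  graph <- build_igraph(model, seed = seed, self_edges = self_edges)
  scc <- scc_decompose(graph)
  covers <- lapply(scc$components, function(vs) scc_circuit_cover(graph, vs))
  fps <- assemble_fixed_points(model, graph, overrides = overrides,
                               control = control, keep_tangent = FALSE)
  stab <- stability_report(model, fps, graph, overrides = overrides)

  # characteristics per cyclic SCC under the first upstream combination
  chars <- list()
  u <- rep(NA_real_, model$n)
  for (k in seq_along(scc$components)) {
    cov <- covers[[k]]
    if (length(cov$cover)) {
      v1 <- cov$cover[1L]
      gr <- NULL
      if (!is.null(grid)) {
        lo <- max(grid$lo, model$bounds[v1, 1L])
        hi <- min(grid$hi, model$bounds[v1, 2L])
        gr <- seq(lo, hi, length.out = grid$n)
      }
      chars[[as.character(k)]] <-
        evaluate_characteristic(model, graph, cov, u, grid = gr,
                                overrides = overrides, control = control)
    }
    # continue downstream along the first fixed-point branch
    if (nrow(fps$points)) u[scc$components[[k]]] <-
        fps$points[1L, scc$components[[k]]]
  }
  structure(list(model = model, graph = graph, scc = scc, covers = covers,
                 characteristics = chars, fixed_points = fps,
                 stability = stab, overrides = overrides),
            class = "cba_analysis")
}

#' @export
print.cba_analysis <- function(x, ...) {
  cat("Circuit-breaking analysis of '", x$model$name, "'\n", sep = "")
  cat(" ", length(x$scc$components), "SCC(s);",
      sum(vapply(x$covers, function(cv) length(cv$circuits), integer(1L))),
      "elementary circuit(s)\n")
  print(x$fixed_points)
  if (nrow(x$fixed_points$points)) {
    cat("Stability:\n")
    print(x$stability)
  }
  invisible(x)
}
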