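# SCC condensation, elementary circuits, minimal circuit cover.

#' Strongly connected component decomposition
#'
#' Partitions the interaction graph into maximal strongly connected
#' components (SCCs) and numbers them along the hierarchical (topological)
#' order of the condensation graph, which is acyclic by construction.  Fixed
#' points of the full system can then be computed SCC by SCC, feeding each
#' component the fixed-point coordinates of its upstream components as
#' constant input.  Ties in the topological order are broken by the smallest
#' member vertex index, so the numbering is deterministic.
#'
#' @param graph an `interaction_graph`.
#' @return object of class `"scc_decomposition"`: `components` (list of
#'   integer vertex vectors, in hierarchical order) and `condensation_edges`
#'   (data.frame `from`/`to` of component indices).
#' @export
scc_decompose <- function(graph) {
  stopifnot(inherits(graph, "interaction_graph"))
  if (graph$n < 1L) stop("empty graph")
  g <- as_igraph_graph(graph)
  memb <- igraph::components(g, mode = "strong")$membership
  memb <- memb[order(as.integer(names(memb)))]
  comp_ids <- sort(unique(memb))
  comps <- lapply(comp_ids, function(cid) sort(unname(which(memb == cid))))
  K <- length(comps)
  which_comp <- integer(graph$n)
  for (k in seq_len(K)) which_comp[comps[[k]]] <- k

  # condensation edges (between distinct components)
  cf <- which_comp[graph$edges$from]
  ct <- which_comp[graph$edges$to]
  keep <- cf != ct
  ce <- unique(data.frame(from = cf[keep], to = ct[keep]))

  # Kahn topological order with deterministic tie-break: among ready
  # components pick the one whose smallest member vertex is smallest.
  indeg <- integer(K)
  for (r in seq_len(nrow(ce))) indeg[ce$to[r]] <- indeg[ce$to[r]] + 1L
  minv <- vapply(comps, min, integer(1L))
  order_k <- integer(0)
  ready <- which(indeg == 0L)
  remaining_ce <- ce
  while (length(ready)) {
    k <- ready[which.min(minv[ready])]
    order_k <- c(order_k, k)
    ready <- setdiff(ready, k)
    out <- which(remaining_ce$from == k)
    for (r in out) {
      t <- remaining_ce$to[r]
      indeg[t] <- indeg[t] - 1L
      if (indeg[t] == 0L) ready <- c(ready, t)
    }
    if (length(out)) remaining_ce <- remaining_ce[-out, , drop = FALSE]
  }
  stopifnot(length(order_k) == K)  # condensation is a DAG

  comps <- comps[order_k]
  relabel <- match(seq_len(K), order_k)
  ce2 <- data.frame(from = relabel[ce$from], to = relabel[ce$to])
  ce2 <- ce2[order(ce2$from, ce2$to), , drop = FALSE]
  rownames(ce2) <- NULL
  structure(list(components = comps, condensation_edges = ce2,
                 vars = graph$vars),
            class = "scc_decomposition")
}

#' @export
print.scc_decomposition <- function(x, ...) {
  cat("SCC decomposition:", length(x$components), "components\n")
  for (k in seq_along(x$components))
    cat(sprintf("  V%d = {%s}\n", k,
                paste(x$vars[x$components[[k]]], collapse = ", ")))
  invisible(x)
}

#' Enumerate all elementary circuits of a subgraph
#'
#' Johnson's algorithm over the induced subgraph; self-loops count as
#' length-1 circuits.  Each circuit is returned in canonical rotation
#' (smallest vertex first).  Enumeration stops after `cap` circuits, in which
#' case the result is flagged as truncated.
#'
#' @param graph an `interaction_graph`.
#' @param vertices vertex subset to induce on (default: all).
#' @param cap maximum number of circuits to return.
#' @return list with `circuits` (list of integer vectors in original vertex
#'   indices) and `truncated` flag.
#' @export
enumerate_elementary_circuits <- function(graph, vertices = NULL,
                                          cap = 10000L) {
  stopifnot(inherits(graph, "interaction_graph"))
  if (cap < 1L) stop("cap must be >= 1")
  if (is.null(vertices)) vertices <- seq_len(graph$n)
  vertices <- sort(vertices)
  adj <- adjacency_local(graph, vertices)
  k <- length(vertices)

  circuits <- list()
  truncated <- FALSE

  # self-loops first (length-1 circuits), then Johnson on the loop-free graph
  for (v in seq_len(k)) {
    if (v %in% adj[[v]]) circuits[[length(circuits) + 1L]] <- v
    adj[[v]] <- setdiff(adj[[v]], v)
  }

  blocked <- logical(k)
  Bsets <- vector("list", k)
  stack <- integer(0)

  unblock <- function(u) {
    blocked[u] <<- FALSE
    for (w in Bsets[[u]]) {
      Bsets[[u]] <<- setdiff(Bsets[[u]], w)
      if (blocked[w]) unblock(w)
    }
  }

  s <- 1L
  while (s <= k && !truncated) {
    # subgraph induced by vertices >= s
    sub_adj <- lapply(adj, function(a) a[a >= s])
    for (v in seq_len(k)) { blocked[v] <- FALSE; Bsets[[v]] <- integer(0) }
    circuit_fn <- function(v) {
      found <- FALSE
      stack <<- c(stack, v)
      blocked[v] <<- TRUE
      for (w in sub_adj[[v]]) {
        if (length(circuits) >= cap) { truncated <<- TRUE; break }
        if (w == s) {
          circuits[[length(circuits) + 1L]] <<- stack
          found <- TRUE
        } else if (!blocked[w]) {
          if (circuit_fn(w)) found <- TRUE
        }
      }
      if (found) {
        unblock(v)
      } else {
        for (w in sub_adj[[v]]) {
          if (!v %in% Bsets[[w]]) Bsets[[w]] <<- c(Bsets[[w]], v)
        }
      }
      stack <<- stack[-length(stack)]
      found
    }
    if (length(sub_adj[[s]])) circuit_fn(s)
    s <- s + 1L
  }

  circuits <- lapply(circuits, function(cc) vertices[cc])
  circuits <- lapply(circuits, canonical_rotation)
  list(circuits = circuits, truncated = truncated)
}

canonical_rotation <- function(circ) {
  if (length(circ) <= 1L) return(circ)
  i <- which.min(circ)
  if (i == 1L) circ else c(circ[i:length(circ)], circ[1:(i - 1L)])
}

#' Minimal circuit-covering vertex set
#'
#' Finds a minimum-cardinality set of vertices hitting every elementary
#' circuit ("breaking" all feedback).  The search is exact (branch and bound
#' over circuit vertices) when the number of candidate vertices is at most
#' `exhaustive_cap`; beyond that a greedy maximum-coverage heuristic is used
#' and the result is flagged as possibly non-minimal.  Among equal-size
#' covers the vertex contained in the most circuits is preferred, ties by
#' smallest index.
#'
#' @param circuits list of integer circuit vectors (possibly empty, for
#'   acyclic graphs) as returned by [enumerate_elementary_circuits()].
#' @param vertices vertex set of the (sub)graph the circuits live on.
#' @param exhaustive_cap maximum candidate-vertex count for the exact search.
#' @param truncated was circuit enumeration truncated? (propagated flag; a
#'   truncated circuit list can make the cover non-minimal).
#' @return object of class `"circuit_cover"` with fields `circuits`, `cover`
#'   (ordered: `v1` released last), `complement`, `release_order` (reverse of
#'   `cover`), `is_lvg`, `exact`, `truncated`.
#' @export
minimal_circuit_cover <- function(circuits, vertices,
                                  exhaustive_cap = 20L, truncated = FALSE) {
  vertices <- sort(vertices)
  if (!length(circuits)) {
    return(structure(list(circuits = circuits, cover = integer(0),
                          complement = vertices, release_order = integer(0),
                          is_lvg = FALSE, exact = TRUE, truncated = truncated,
                          vertices = vertices),
                     class = "circuit_cover"))
  }
  cand <- sort(unique(unlist(circuits)))
  counts <- table(factor(unlist(lapply(circuits, unique)), levels = cand))
  pref <- order(-as.integer(counts), cand)  # coverage desc, then index
  cand_o <- cand[pref]

  hit_all <- function(S) all(vapply(circuits, function(cc)
    any(cc %in% S), logical(1L)))

  cover <- NULL; exact <- TRUE
  if (length(cand) <= exhaustive_cap) {
    best <- cand_o  # trivial cover: all candidates
    # branch and bound: repeatedly branch on an uncovered circuit
    rec <- function(chosen, remaining) {
      if (length(chosen) >= length(best)) return()
      unc <- remaining[!vapply(remaining, function(ci)
        any(circuits[[ci]] %in% chosen), logical(1L))]
      if (!length(unc)) { best <<- chosen; return() }
      # branch on the uncovered circuit with fewest vertices
      sizes <- vapply(unc, function(ci) length(circuits[[ci]]), integer(1L))
      cc <- circuits[[unc[which.min(sizes)]]]
      for (v in cand_o[cand_o %in% cc]) rec(c(chosen, v), unc)
    }
    rec(integer(0), seq_along(circuits))
    cover <- best
  } else {
    exact <- FALSE
    remaining <- seq_along(circuits)
    cover <- integer(0)
    while (length(remaining)) {
      cnt <- table(factor(unlist(lapply(remaining, function(ci)
        unique(circuits[[ci]]))), levels = cand))
      v <- cand[order(-as.integer(cnt), cand)][1L]
      cover <- c(cover, v)
      remaining <- remaining[!vapply(remaining, function(ci)
        v %in% circuits[[ci]], logical(1L))]
    }
  }
  stopifnot(hit_all(cover))
  # order cover by preference: v1 (released last) first
  cover <- cover[order(match(cover, cand_o))]
  structure(list(circuits = circuits, cover = cover,
                 complement = setdiff(vertices, cover),
                 release_order = rev(cover),
                 is_lvg = length(cover) == 1L,
                 exact = exact, truncated = truncated,
                 vertices = vertices),
            class = "circuit_cover")
}

#' @export
print.circuit_cover <- function(x, ...) {
  cat("Circuit cover:", length(x$circuits), "elementary circuit(s), cover size",
      length(x$cover), if (x$is_lvg) "(leading vertex graph)", "\n")
  cat("  cover: {", paste(x$cover, collapse = ", "), "}\n")
  invisible(x)
}

#' Circuit analysis of one SCC (convenience wrapper)
#'
#' Enumerates elementary circuits of the SCC subgraph and computes its
#' minimal circuit-covering vertex set in one call.
#'
#' @param graph an `interaction_graph`.
#' @param vertices vertex set of one SCC.
#' @param cap circuit-enumeration cap.
#' @param exhaustive_cap exact-cover candidate cap.
#' @return a `circuit_cover`.
#' @export
scc_circuit_cover <- function(graph, vertices, cap = 10000L,
                              exhaustive_cap = 20L) {
  enum <- enumerate_elementary_circuits(graph, vertices, cap = cap)
  minimal_circuit_cover(enum$circuits, vertices,
                        exhaustive_cap = exhaustive_cap,
                        truncated = enum$truncated)
}

#' Leading-vertex-graph test
#'
#' An SCC is a leading vertex graph (LVG) when a single vertex lies on every
#' elementary circuit, i.e. the minimal circuit cover has exactly one
#' element.  For LVGs the circuit-characteristic is built in a single
#' circuit-closing step and a positive slope at one of its zeros is a
#' sufficient instability certificate.
#'
#' @param cover a `circuit_cover`.
#' @return list with `is_lvg` and `leading` (the leading vertex index, or
#'   `NA` when not an LVG).
#' @export
is_leading_vertex_graph <- function(cover) {
  stopifnot(inherits(cover, "circuit_cover"))
  list(is_lvg = cover$is_lvg,
       leading = if (cover$is_lvg) cover$cover[1L] else NA_integer_)
}

#' Acyclic evaluation order after circuit breaking
#'
#' Removes all edges pointing into the cover set ("breaking" every circuit)
#' and returns a topological evaluation order of the complement, treating the
#' cover variables as fixed inputs \eqn{\kappa}.  Errors if a cycle survives,
#' which would mean the cover is not a valid hitting set.
#'
#' @param graph an `interaction_graph`.
#' @param cover a `circuit_cover` for one SCC of `graph`.
#' @return integer vector: the complement vertices in dependency order.
#' @export
break_circuits <- function(graph, cover) {
  stopifnot(inherits(graph, "interaction_graph"),
            inherits(cover, "circuit_cover"))
  vs <- cover$vertices
  comp <- cover$complement
  if (!length(comp)) return(integer(0))
  # Kahn over the subgraph induced on the complement (edges from cover
  # vertices are external inputs and ignored)
  keep <- graph$edges$from %in% comp & graph$edges$to %in% comp &
    graph$edges$from != graph$edges$to
  ef <- graph$edges$from[keep]; et <- graph$edges$to[keep]
  indeg <- setNames(integer(length(comp)), comp)
  for (t in et) indeg[as.character(t)] <- indeg[as.character(t)] + 1L
  order_v <- integer(0)
  ready <- comp[indeg == 0L]
  while (length(ready)) {
    v <- min(ready)
    order_v <- c(order_v, v)
    ready <- setdiff(ready, v)
    out <- which(ef == v)
    for (r in out) {
      t <- et[r]
      indeg[as.character(t)] <- indeg[as.character(t)] - 1L
      if (indeg[as.character(t)] == 0L) ready <- c(ready, t)
    }
    if (length(out)) { ef <- ef[-out]; et <- et[-out] }
  }
  if (length(order_v) != length(comp))
    stop("internal error: breaking the cover left a residual cycle")
  order_v
}
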