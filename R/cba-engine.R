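# Circuit breaking, acyclic solving, circuit closing, characteristic and
# fixed-point assembly.

# --- one-dimensional root solving -----------------------------------------

# All roots of g on [lo, hi]: dense sign-change bracketing on n_scan
# subintervals, refined with uniroot; g must be vectorized over x.
scan_roots <- function(g, lo, hi, n_scan = 200L, tol_root = 1e-12) {
  xs <- seq(lo, hi, length.out = n_scan + 1L)
  ys <- g(xs)
  ok <- is.finite(ys)
  roots <- numeric(0)
  # exact hits on grid points
  hit <- which(ok & ys == 0)
  roots <- c(roots, xs[hit])
  for (i in seq_len(n_scan)) {
    if (!ok[i] || !ok[i + 1L]) next
    if (ys[i] == 0 || ys[i + 1L] == 0) next
    if (sign(ys[i]) != sign(ys[i + 1L])) {
      r <- uniroot(function(x) g(x)[1L], c(xs[i], xs[i + 1L]),
                   f.lower = ys[i], f.upper = ys[i + 1L],
                   tol = tol_root)$root
      roots <- c(roots, r)
    }
  }
  sort(unique(roots))
}

# Replace unset (NA) state slots by box midpoints for evaluation purposes.
# Any variable still NA at evaluation time has, by the interaction graph and
# the SCC ordering, no edge into the expressions being evaluated, i.e. the
# expression is constant in it over the box (e.g. a synthesis term whose
# prefactor parameter is zero), so any in-box value is equivalent.
fill_state <- function(model, state) {
  na <- is.na(state)
  if (any(na)) state[na] <- rowMeans(model$bounds)[na]
  state
}

# Solve f_p(x_p) = 0 for variable p with all other state components fixed.
# `state` is a full-length numeric vector (NA allowed in untouched slots).
# Closed form when the self-derivative is a state-independent constant d_p:
# f_p = r_p(x_{-p}) + d_p x_p  =>  x_p = -f_p(x_p = 0) / d_p.
solve_var <- function(model, state, p, penv, n_scan = 200L,
                      tol_root = 1e-12, bounds_tol = 1e-9) {
  lo <- model$bounds[p, 1L]; hi <- model$bounds[p, 2L]
  state <- fill_state(model, state)
  if (model$diag_struct_const[p]) {
    d <- diag_const_value(model, p, penv)
    if (abs(d) > 1e-300) {
      st <- as.list(state); st[[p]] <- 0
      r <- as.numeric(eval_expr_at(model, model$exprs[[p]], st, penv))
      x <- -r / d
      span <- hi - lo
      if (x >= lo - bounds_tol * span && x <= hi + bounds_tol * span)
        return(min(max(x, lo), hi))
      return(numeric(0))
    }
  }
  st <- as.list(state)
  g <- function(x) {
    st[[p]] <- x
    as.numeric(eval_expr_at(model, model$exprs[[p]], st, penv))
  }
  scan_roots(g, lo, hi, n_scan = n_scan, tol_root = tol_root)
}

# --- acyclic sub-problem (step 2d) ----------------------------------------

#' Solve the broken (acyclic) subproblem
#'
#' With all circuits broken — cover variables fixed at \eqn{\kappa} and
#' upstream coordinates fixed at `u` — the remaining variables can be solved
#' one at a time along the dependency order: each \eqn{f_p(x_p)=0} is a
#' one-dimensional root problem.  Variables in decay form are solved in
#' closed form; all others by dense sign-change bracketing over their bounds.
#' Multiple roots spawn branches (Cartesian continuation).
#'
#' @param model a `regmodel`.
#' @param order integer vector: evaluation order from [break_circuits()].
#' @param state full-length numeric state; cover variables set to their
#'   \eqn{\kappa} values, upstream variables to `u`, everything else may be
#'   `NA`.
#' @param overrides optional parameter overrides.
#' @param control solver control list, see [cba_control()].
#' @return list of completed states (one per branch; empty when some
#'   variable has no root inside its bounds).
#' @export
solve_acyclic <- function(model, order, state, overrides = NULL,
                          control = cba_control()) {
  penv <- param_env(model, overrides)
  solve_acyclic_env(model, order, state, penv, control)
}

solve_acyclic_env <- function(model, order, state, penv, control) {
  branches <- list(state)
  for (p in order) {
    nxt <- list()
    for (b in branches) {
      roots <- solve_var(model, b, p, penv, n_scan = control$n_scan,
                         tol_root = control$tol_root)
      for (r in roots) {
        b2 <- b; b2[p] <- r
        nxt[[length(nxt) + 1L]] <- b2
        if (length(nxt) > control$max_branches)
          stop("branch cap exceeded while solving the acyclic subproblem; ",
               "increase max_branches")
      }
    }
    branches <- nxt
    if (!length(branches)) break
  }
  branches
}

#' Solver control parameters
#'
#' @param n_scan subintervals for dense root bracketing per variable.
#' @param tol_root absolute tolerance of bracketed root refinement.
#' @param tol_zero tolerance on `|c|` at an accepted characteristic zero.
#' @param tol_tangent relative threshold (scaled by `max |c|` on the grid)
#'   below which a sign-preserving local minimum of `|c|` is reported as a
#'   tangency / bifurcation candidate.
#' @param tol_fp residual tolerance for assembled fixed points after polish.
#' @param tol_dedup relative tolerance for fixed-point deduplication.
#' @param max_branches cap on simultaneous solution branches.
#' @param n_grid default characteristic grid size.
#' @return a named list.
#' @export
cba_control <- function(n_scan = 200L, tol_root = 1e-12, tol_zero = 1e-8,
                        tol_tangent = 1e-4, tol_fp = 1e-8, tol_dedup = 1e-6,
                        max_branches = 16L, n_grid = 601L) {
  stopifnot(n_scan >= 2L, tol_root > 0, tol_zero > 0, tol_fp > 0,
            n_grid >= 3L)
  list(n_scan = as.integer(n_scan), tol_root = tol_root, tol_zero = tol_zero,
       tol_tangent = tol_tangent, tol_fp = tol_fp, tol_dedup = tol_dedup,
       max_branches = as.integer(max_branches), n_grid = as.integer(n_grid))
}

# --- circuit closing (step 2e) --------------------------------------------

# Solve the whole SCC interior given the leading value kappa1 (and any other
# already-fixed cover values).  `idx` indexes cover$cover: all cover vertices
# before `idx` are already set in `state`; vertices from `idx` on are
# released depth-first (v_m innermost) by solving the partial
# circuit-characteristic f_i(x_i, kappa, F(kappa)) = 0.  Returns the list of
# consistent completed states (branches).
solve_released <- function(model, cover, order, state, idx, penv, control) {
  m <- length(cover$cover)
  if (idx > m)
    return(solve_acyclic_env(model, order, state, penv, control))
  v <- cover$cover[idx]
  lo <- model$bounds[v, 1L]; hi <- model$bounds[v, 2L]

  # residuals (possibly several branches) of the partial characteristic at x
  resid_at <- function(x) {
    st <- state; st[v] <- x
    brs <- solve_released(model, cover, order, st, idx + 1L, penv, control)
    lapply(brs, function(b)
      list(c = as.numeric(eval_expr_at(model, model$exprs[[v]],
                                       as.list(fill_state(model, b)), penv)),
           state = b))
  }
  xs <- seq(lo, hi, length.out = control$n_scan + 1L)
  evals <- lapply(xs, resid_at)

  out <- list()
  push_root <- function(xa, xb, ya, yb, sa, sb) {
    # bisection with branch tracking by nearest downstream state
    ref <- sa
    for (it in 1:60) {
      xm <- (xa + xb) / 2
      em <- resid_at(xm)
      if (!length(em)) break
      dists <- vapply(em, function(z) sum((z$state - ref)^2, na.rm = TRUE),
                      numeric(1L))
      zm <- em[[which.min(dists)]]
      if (!is.finite(zm$c)) break
      if (abs(zm$c) < control$tol_root || (xb - xa) < 1e-14 * max(1, abs(xb))) {
        out[[length(out) + 1L]] <<- zm$state
        return(invisible())
      }
      if (sign(zm$c) == sign(ya)) { xa <- xm; ya <- zm$c } else { xb <- xm }
      ref <- zm$state
    }
    xm <- (xa + xb) / 2
    em <- resid_at(xm)
    if (length(em)) {
      dists <- vapply(em, function(z) sum((z$state - ref)^2, na.rm = TRUE),
                      numeric(1L))
      out[[length(out) + 1L]] <<- em[[which.min(dists)]]$state
    }
    invisible()
  }

  for (i in seq_len(control$n_scan)) {
    ea <- evals[[i]]; eb <- evals[[i + 1L]]
    if (!length(ea) || !length(eb)) next
    used_b <- logical(length(eb))
    for (za in ea) {
      # match each branch at x_i to the nearest branch at x_{i+1}
      dists <- vapply(eb, function(zb)
        sum((zb$state - za$state)^2, na.rm = TRUE), numeric(1L))
      dists[used_b] <- dists[used_b] + 0  # reuse allowed; greedy is enough
      jb <- which.min(dists)
      zb <- eb[[jb]]; used_b[jb] <- TRUE
      if (!is.finite(za$c) || !is.finite(zb$c)) next
      if (za$c == 0) { out[[length(out) + 1L]] <- za$state; next }
      if (sign(za$c) != sign(zb$c) && zb$c != 0)
        push_root(xs[i], xs[i + 1L], za$c, zb$c, za$state, zb$state)
    }
  }
  # endpoint exact zero at the last grid point
  for (zb in evals[[control$n_scan + 1L]])
    if (is.finite(zb$c) && zb$c == 0) out[[length(out) + 1L]] <- zb$state
  dedup_states(out, tol = 1e-9)
}

dedup_states <- function(states, tol = 1e-9) {
  if (length(states) <= 1L) return(states)
  keep <- list(states[[1L]])
  for (s in states[-1L]) {
    dup <- any(vapply(keep, function(k)
      max(abs(k - s) / pmax(1, abs(k)), na.rm = TRUE) < tol, logical(1L)))
    if (!dup) keep[[length(keep) + 1L]] <- s
  }
  keep
}

#' Close one circuit: solve a partial circuit-characteristic
#'
#' Releases one cover vertex \eqn{v_i}: with all cover vertices before it
#' still fixed at their \eqn{\kappa} values and all vertices after it (and
#' the complement) solved recursively, the implicit equation
#' \eqn{f_i(x_i, \kappa, F(\kappa)) = 0} is solved for \eqn{x_i} by dense
#' bracketing over its bounds.  The returned states are the zero set of the
#' partial circuit-characteristic with the downstream coordinates
#' \eqn{F(\kappa)} updated accordingly.
#'
#' @param model a `regmodel`.
#' @param graph the model's `interaction_graph`.
#' @param cover `circuit_cover` of the SCC.
#' @param state full-length state with upstream coordinates and the cover
#'   values that remain fixed (all cover vertices preceding `released`).
#' @param released index into `cover$cover` of the vertex to release
#'   (`length(cover$cover)` releases the innermost vertex first).
#' @param overrides,control see [solve_acyclic()].
#' @return list of completed states.
#' @export
close_circuit <- function(model, graph, cover, state, released,
                          overrides = NULL, control = cba_control()) {
  penv <- param_env(model, overrides)
  order <- break_circuits(graph, cover)
  solve_released(model, cover, order, state, released, penv, control)
}

# --- the circuit-characteristic (step 2e) ---------------------------------

#' Evaluate the circuit-characteristic of one SCC
#'
#' For each grid value \eqn{\kappa_1} of the leading variable the remaining
#' SCC variables are solved (acyclic subproblem plus iterative circuit
#' closing along the release order) and the characteristic
#' \eqn{c(\kappa_1) = f_1(\kappa_1, F(\kappa_1))} is evaluated.  Zeros of
#' `c` are fixed-point coordinates of the leading variable; multiple
#' downstream root selections appear as separate branches, matched across
#' grid points by nearest continuation.  Grid cells where some variable has
#' no root inside its bounds become holes (`NA`) in the branch.
#'
#' @param model a `regmodel`.
#' @param graph the model's `interaction_graph` (defaults to
#'   [build_igraph()]).
#' @param cover `circuit_cover` of the SCC (defaults to the cover of the
#'   SCC containing `leading`/the whole graph treated as one SCC).
#' @param u full-length numeric state carrying upstream fixed-point
#'   coordinates (`NA` for SCC members); defaults to all-`NA`.
#' @param grid numeric vector of \eqn{\kappa_1} values; defaults to
#'   `control$n_grid` points spanning the leading variable's bounds.
#' @param overrides optional parameter overrides.
#' @param control see [cba_control()].
#' @return object of class `"cba_characteristic"`: `grid`, `branches` (each
#'   with `values` and a state matrix), the `leading` vertex, and `cfun`, a
#'   function re-evaluating the characteristic at arbitrary \eqn{\kappa_1}.
#' @export
evaluate_characteristic <- function(model, graph = NULL, cover = NULL,
                                    u = NULL, grid = NULL, overrides = NULL,
                                    control = cba_control()) {
  stopifnot(inherits(model, "regmodel"))
  if (is.null(graph)) graph <- build_igraph(model)
  if (is.null(cover)) cover <- scc_circuit_cover(graph, seq_len(model$n))
  if (!length(cover$cover)) {
    if (length(cover$vertices) == 1L) {
      # degenerate case: a single circuit-free vertex; the characteristic is
      # just f_1 restricted to the line
      cover$cover <- cover$vertices
      cover$complement <- integer(0)
      cover$release_order <- cover$vertices
      cover$is_lvg <- FALSE
    } else {
      stop("SCC is acyclic: it has no circuit-characteristic")
    }
  }
  v1 <- cover$cover[1L]
  if (is.null(u)) u <- rep(NA_real_, model$n)
  if (is.null(grid))
    grid <- seq(model$bounds[v1, 1L], model$bounds[v1, 2L],
                length.out = control$n_grid)
  if (length(grid) < 3L) stop("characteristic grid needs at least 3 points")
  penv <- param_env(model, overrides)
  order <- break_circuits(graph, cover)
  m <- length(cover$cover)

  fast <- m == 1L && all(model$diag_struct_const[order]) &&
    all(vapply(order, function(p)
      abs(diag_const_value(model, p, penv)) > 1e-300, logical(1L)))

  if (fast) {
    # vectorized closed-form sweep over the whole grid in one pass
    st <- as.list(fill_state(model, u))
    st[[v1]] <- grid
    for (p in order) {
      d <- diag_const_value(model, p, penv)
      st[[p]] <- 0
      r <- as.numeric(eval_expr_at(model, model$exprs[[p]], st, penv))
      xp <- -r / d
      lo <- model$bounds[p, 1L]; hi <- model$bounds[p, 2L]
      span <- hi - lo
      xp[xp < lo - 1e-9 * span | xp > hi + 1e-9 * span] <- NA_real_
      st[[p]] <- xp
    }
    cvals <- as.numeric(eval_expr_at(model, model$exprs[[v1]], st, penv))
    smat <- matrix(NA_real_, length(grid), model$n,
                   dimnames = list(NULL, model$vars))
    solved <- unique(c(v1, order, which(!is.na(u))))
    for (j in solved)
      smat[, j] <- rep_len(st[[j]], length(grid))
    branches <- list(list(values = cvals, states = smat))
  } else {
    point_solve <- function(kappa) {
      st <- u; st[v1] <- kappa
      brs <- solve_released(model, cover, order, st, 2L, penv, control)
      lapply(brs, function(b)
        list(c = as.numeric(eval_expr_at(model, model$exprs[[v1]],
                                         as.list(b), penv)),
             state = b))
    }
    per_point <- lapply(grid, point_solve)
    branches <- track_branches(per_point, grid, model)
  }

  cfun <- function(kappa) {
    st <- u; st[v1] <- kappa
    brs <- solve_released(model, cover, order, st, 2L, penv, control)
    lapply(brs, function(b)
      list(c = as.numeric(eval_expr_at(model, model$exprs[[v1]],
                                       as.list(fill_state(model, b)), penv)),
           state = b))
  }

  structure(list(grid = grid, branches = branches, leading = v1,
                 cover = cover, u = u, vars = model$vars, cfun = cfun),
            class = "cba_characteristic")
}

# Assemble per-grid-point solution sets into branches by nearest-neighbor
# continuation of the downstream state.
track_branches <- function(per_point, grid, model) {
  ng <- length(grid)
  branches <- list()   # each: list(values, states, last_state, open)
  for (i in seq_len(ng)) {
    sols <- per_point[[i]]
    assigned <- rep(FALSE, length(sols))
    for (bi in seq_along(branches)) {
      br <- branches[[bi]]
      if (!br$open) next
      if (!length(sols)) { branches[[bi]]$open <- FALSE; next }
      d <- vapply(sols, function(z)
        sum((z$state - br$last_state)^2, na.rm = TRUE), numeric(1L))
      d[assigned] <- Inf
      j <- which.min(d)
      if (is.finite(d[j])) {
        assigned[j] <- TRUE
        branches[[bi]]$values[i] <- sols[[j]]$c
        branches[[bi]]$states[i, ] <- sols[[j]]$state
        branches[[bi]]$last_state <- sols[[j]]$state
      } else {
        branches[[bi]]$open <- FALSE
      }
    }
    for (j in which(!assigned)) {
      nb <- list(values = rep(NA_real_, ng),
                 states = matrix(NA_real_, ng, model$n,
                                 dimnames = list(NULL, model$vars)),
                 last_state = sols[[j]]$state, open = TRUE)
      nb$values[i] <- sols[[j]]$c
      nb$states[i, ] <- sols[[j]]$state
      branches[[length(branches) + 1L]] <- nb
    }
  }
  lapply(branches, function(b) list(values = b$values, states = b$states))
}

#' @export
print.cba_characteristic <- function(x, ...) {
  cat("Circuit-characteristic of leading variable", x$vars[x$leading],
      "on [", min(x$grid), ",", max(x$grid), "],", length(x$grid),
      "grid points,", length(x$branches), "branch(es)\n")
  invisible(x)
}

# --- zeros of the characteristic ------------------------------------------

#' Find zeros (and tangency candidates) of a circuit-characteristic
#'
#' Sign changes between adjacent grid points are refined by bisection on the
#' re-evaluated characteristic.  Local minima of `|c|` that come close to
#' zero without a sign change are reported as tangency candidates — the
#' signature of a saddle-node (fold) bifurcation, where the characteristic
#' touches the axis.  The slope at each zero is computed by central finite
#' differences on the refined curve.
#'
#' @param char a `cba_characteristic`.
#' @param control see [cba_control()].
#' @return data.frame with columns `kappa`, `value`, `slope`, `tangent`
#'   (logical), `branch`; one row per zero/tangency, plus attribute
#'   `"states"`: a list of the full downstream states at each zero.
#' @export
find_zeros <- function(char, control = cba_control()) {
  stopifnot(inherits(char, "cba_characteristic"))
  grid <- char$grid
  res <- data.frame(kappa = numeric(0), value = numeric(0),
                    slope = numeric(0), tangent = logical(0),
                    branch = integer(0))
  states <- list()
  span <- diff(range(grid))
  cmax <- max(vapply(char$branches, function(b)
    max(abs(b$values), na.rm = TRUE), numeric(1L)), 0)

  eval_branch <- function(kappa, ref_state) {
    sols <- char$cfun(kappa)
    if (!length(sols)) return(NULL)
    d <- vapply(sols, function(z)
      sum((z$state - ref_state)^2, na.rm = TRUE), numeric(1L))
    sols[[which.min(d)]]
  }

  for (bi in seq_along(char$branches)) {
    b <- char$branches[[bi]]
    y <- b$values
    ok <- is.finite(y)
    # refined sign-change zeros
    for (i in seq_len(length(grid) - 1L)) {
      if (!ok[i] || !ok[i + 1L]) next
      z <- NULL
      if (y[i] == 0) {
        if (i == 1L || !ok[i - 1L] || y[i - 1L] != 0)
          z <- list(kappa = grid[i], state = b$states[i, ], value = 0)
      } else if (y[i + 1L] != 0 && sign(y[i]) != sign(y[i + 1L])) {
        xa <- grid[i]; xb <- grid[i + 1L]; ya <- y[i]
        ref <- b$states[i, ]
        for (it in 1:60) {
          xm <- (xa + xb) / 2
          zm <- eval_branch(xm, ref)
          if (is.null(zm) || !is.finite(zm$c)) break
          # bisect down to x-resolution: an |c|-based exit would stop too
          # early when the characteristic spans many orders of magnitude
          if (zm$c == 0 || (xb - xa) < 1e-13 * max(1, abs(xb))) break
          if (sign(zm$c) == sign(ya)) { xa <- xm; ya <- zm$c } else xb <- xm
          ref <- zm$state
        }
        xm <- (xa + xb) / 2
        zm <- eval_branch(xm, ref)
        if (!is.null(zm))
          z <- list(kappa = xm, state = zm$state, value = zm$c)
      }
      if (!is.null(z)) {
        sl <- char_slope_fd(char, z$kappa, z$state, span)
        res <- rbind(res, data.frame(kappa = z$kappa, value = z$value,
                                     slope = sl, tangent = FALSE,
                                     branch = bi))
        states[[length(states) + 1L]] <- z$state
      }
    }
    # trailing exact zero at last grid point
    ng <- length(grid)
    if (ok[ng] && y[ng] == 0 && (!ok[ng - 1L] || y[ng - 1L] != 0)) {
      sl <- char_slope_fd(char, grid[ng], b$states[ng, ], span)
      res <- rbind(res, data.frame(kappa = grid[ng], value = 0,
                                   slope = sl, tangent = FALSE, branch = bi))
      states[[length(states) + 1L]] <- b$states[ng, ]
    }
    # tangency candidates: interior |c| minima without sign change
    ay <- abs(y)
    for (i in 2:(length(grid) - 1L)) {
      if (!ok[i - 1L] || !ok[i] || !ok[i + 1L]) next
      if (y[i] == 0) next
      if (sign(y[i - 1L]) != sign(y[i]) || sign(y[i]) != sign(y[i + 1L])) next
      if (ay[i] <= ay[i - 1L] && ay[i] <= ay[i + 1L] &&
          ay[i] < control$tol_tangent * max(1, cmax)) {
        opt <- optimize(function(k) {
          z <- eval_branch(k, b$states[i, ])
          if (is.null(z) || !is.finite(z$c)) Inf else abs(z$c)
        }, lower = grid[i - 1L], upper = grid[i + 1L],
        tol = 1e-10 * max(1, span))
        zk <- opt$minimum
        zz <- eval_branch(zk, b$states[i, ])
        if (!is.null(zz)) {
          res <- rbind(res, data.frame(kappa = zk, value = zz$c,
                                       slope = 0, tangent = TRUE,
                                       branch = bi))
          states[[length(states) + 1L]] <- zz$state
        }
      }
    }
  }
  o <- order(res$kappa)
  res <- res[o, , drop = FALSE]
  rownames(res) <- NULL
  attr(res, "states") <- states[o]
  res
}

# Central finite-difference slope of the characteristic at kappa, using the
# branch nearest to `state`.
char_slope_fd <- function(char, kappa, state, span) {
  h <- max(1e-7 * span, 1e-9)
  pick <- function(k) {
    sols <- char$cfun(k)
    if (!length(sols)) return(NA_real_)
    d <- vapply(sols, function(z)
      sum((z$state - state)^2, na.rm = TRUE), numeric(1L))
    sols[[which.min(d)]]$c
  }
  (pick(kappa + h) - pick(kappa - h)) / (2 * h)
}

# --- full-system fixed-point assembly (steps 1 + 2f) ----------------------

#' Compute all fixed points of a model via the circuit-breaking algorithm
#'
#' Traverses the SCCs of the interaction graph in hierarchical order.  For
#' every combination of upstream fixed-point coordinates `u`, the fixed
#' points of the current SCC are computed: acyclic components by direct
#' one-dimensional solving, cyclic components from the zeros of their
#' circuit-characteristic followed by back-substitution through the partial
#' characteristics.  Full states are Cartesian-combined across SCCs,
#' polished by damped Newton iteration on \eqn{f(x)=0}, checked against
#' their bounds and deduplicated.
#'
#' @param model a `regmodel`.
#' @param graph optional precomputed `interaction_graph`.
#' @param overrides optional parameter overrides.
#' @param control see [cba_control()].
#' @param keep_tangent also keep tangency-candidate zeros whose polished
#'   residual passes `tol_fp` (used at fold points).
#' @return object of class `"fixed_point_report"`: `points` (matrix, one row
#'   per fixed point), `residuals`, and `provenance` (per point, a
#'   data.frame of per-SCC zero records with the characteristic slope and
#'   LVG flag).
#' @export
assemble_fixed_points <- function(model, graph = NULL, overrides = NULL,
                                  control = cba_control(),
                                  keep_tangent = TRUE) {
  stopifnot(inherits(model, "regmodel"))
  if (is.null(graph)) graph <- build_igraph(model)
  scc <- scc_decompose(graph)
  penv <- param_env(model, overrides)

  prov0 <- data.frame(scc = integer(0), leading = integer(0),
                      kappa = numeric(0), slope = numeric(0),
                      is_lvg = logical(0), tangent = logical(0))
  partials <- list(list(state = rep(NA_real_, model$n), prov = prov0))

  for (k in seq_along(scc$components)) {
    vs <- scc$components[[k]]
    cover <- scc_circuit_cover(graph, vs)
    nxt <- list()
    for (part in partials) {
      u <- part$state
      if (!length(cover$cover)) {
        # acyclic component: direct sequential solve
        ord <- break_circuits(graph, cover)
        sols <- solve_acyclic_env(model, ord, u, penv, control)
        for (s in sols) {
          pr <- rbind(part$prov,
                      data.frame(scc = k, leading = NA_integer_,
                                 kappa = NA_real_, slope = NA_real_,
                                 is_lvg = FALSE, tangent = FALSE))
          nxt[[length(nxt) + 1L]] <- list(state = s, prov = pr)
        }
      } else {
        ch <- evaluate_characteristic(model, graph, cover, u,
                                      overrides = overrides,
                                      control = control)
        zs <- find_zeros(ch, control = control)
        sts <- attr(zs, "states")
        for (zi in seq_len(nrow(zs))) {
          if (zs$tangent[zi] && !keep_tangent) next
          s <- sts[[zi]]
          pr <- rbind(part$prov,
                      data.frame(scc = k, leading = ch$leading,
                                 kappa = zs$kappa[zi], slope = zs$slope[zi],
                                 is_lvg = cover$is_lvg,
                                 tangent = zs$tangent[zi]))
          nxt[[length(nxt) + 1L]] <- list(state = s, prov = pr)
        }
      }
    }
    partials <- nxt
    if (!length(partials)) break
  }

  # polish, validate, dedup
  pts <- list(); res <- numeric(0); prov <- list()
  for (part in partials) {
    x <- newton_polish(model, part$state, penv, control)
    if (is.null(x)) next
    r <- max(abs(eval_rhs_env(model, x, penv)))
    if (r > control$tol_fp) next
    span <- model$bounds[, 2L] - model$bounds[, 1L]
    if (any(x < model$bounds[, 1L] - 1e-6 * span |
            x > model$bounds[, 2L] + 1e-6 * span)) next
    dup <- FALSE
    for (q in seq_along(pts))
      if (max(abs(pts[[q]] - x) / pmax(1, abs(pts[[q]]))) < control$tol_dedup) {
        dup <- TRUE; break
      }
    if (dup) next
    pts[[length(pts) + 1L]] <- x
    res <- c(res, r)
    prov[[length(prov) + 1L]] <- part$prov
  }
  points <- if (length(pts)) do.call(rbind, pts) else
    matrix(numeric(0), 0L, model$n)
  colnames(points) <- model$vars
  structure(list(points = points, residuals = res, provenance = prov,
                 vars = model$vars, n_partials = length(partials)),
            class = "fixed_point_report")
}

eval_rhs_env <- function(model, x, penv) {
  xl <- as.list(as.numeric(x))
  vapply(seq_len(model$n), function(i)
    as.numeric(eval_expr_at(model, model$exprs[[i]], xl, penv)), numeric(1L))
}

# Damped Newton on f(x) = 0 with the analytic Jacobian; returns NULL on
# breakdown (singular Jacobian or non-finite iterates).
newton_polish <- function(model, x0, penv, control, max_iter = 60L) {
  x <- as.numeric(x0)
  if (any(!is.finite(x))) return(NULL)
  f <- eval_rhs_env(model, x, penv)
  for (it in seq_len(max_iter)) {
    nf <- max(abs(f))
    if (nf < 1e-13) break
    J <- tryCatch(eval_jacobian_env(model, x, penv), error = function(e) NULL)
    if (is.null(J)) return(NULL)
    step <- tryCatch(solve(J, -f), error = function(e) NULL)
    if (is.null(step) || any(!is.finite(step))) return(if (nf < control$tol_fp) x else NULL)
    s <- 1
    repeat {
      x2 <- x + s * step
      f2 <- tryCatch(eval_rhs_env(model, x2, penv), error = function(e) NULL)
      if (!is.null(f2) && all(is.finite(f2)) && max(abs(f2)) < nf) break
      s <- s / 2
      if (s < 1e-8) break
    }
    if (s < 1e-8) break
    x <- x2; f <- f2
  }
  if (any(!is.finite(x))) return(NULL)
  x
}

eval_jacobian_env <- function(model, x, penv) {
  xl <- as.list(as.numeric(x))
  J <- matrix(0, model$n, model$n)
  for (i in seq_len(model$n))
    for (j in seq_len(model$n))
      J[i, j] <- as.numeric(eval_expr_at(model, model$jac[[i, j]], xl, penv))
  J
}

#' @export
print.fixed_point_report <- function(x, ...) {
  cat("Fixed points found:", nrow(x$points), "\n")
  if (nrow(x$points)) {
    df <- as.data.frame(round(x$points, 4))
    df$residual <- signif(x$residuals, 3)
    print(df)
  }
  invisible(x)
}
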