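# Parameter sweeps, fold (saddle-node) localization via characteristic
# tangency, and Hopf detection along continued fixed-point branches.

apply_linkage <- function(model, parameter, value, linked = NULL) {
  ov <- setNames(value, parameter)
  if (!is.null(linked) && length(linked)) {
    env <- new.env(parent = baseenv())
    assign(parameter, value, envir = env)
    for (pn in names(model$params)) assign(pn, model$params[[pn]], envir = env)
    assign(parameter, value, envir = env)
    for (lk in linked) {
      parts <- strsplit(lk, "=", fixed = TRUE)[[1L]]
      if (length(parts) != 2L)
        stop("linkage must have the form NAME=EXPR: ", lk)
      nm <- trimws(parts[1L])
      if (!nm %in% names(model$params)) stop("unknown linked parameter: ", nm)
      val <- eval(str2lang(trimws(parts[2L])), envir = env)
      ov[nm] <- val
      assign(nm, val, envir = env)
    }
  }
  ov
}

#' Sweep a model parameter and track fixed-point branches
#'
#' Runs the full circuit-breaking fixed-point computation and eigenvalue
#' classification at every value of the sweep grid.  Fixed points at
#' adjacent parameter values are matched into branches by nearest relative
#' distance (with a jump threshold); unmatched points open new branches.
#' Other parameters can be linked to the swept one with expressions such as
#' `"eN=eM"`.
#'
#' @param model a `regmodel`.
#' @param parameter name of the swept parameter.
#' @param values numeric sweep grid (increasing).
#' @param linked optional character vector of linkages `"name=expr"`, where
#'   `expr` may use the swept parameter and the model parameters.
#' @param graph optional precomputed `interaction_graph`.
#' @param control see [cba_control()].
#' @param jump_tol relative distance above which points are not considered
#'   the same branch.
#' @return object of class `"bifurcation_scan"`: `table` (data.frame with
#'   `value`, `branch`, the state coordinates, `max_re`, `classification`,
#'   `n_points`), plus the sweep metadata.
#' @export
sweep_parameter <- function(model, parameter, values, linked = NULL,
                            graph = NULL, control = cba_control(),
                            jump_tol = 0.25) {
  stopifnot(inherits(model, "regmodel"))
  if (!parameter %in% names(model$params))
    stop("unknown parameter: ", parameter)
  values <- sort(as.numeric(values))
  if (is.null(graph)) graph <- build_igraph(model)

  rows <- list()
  branch_states <- list()   # branch id -> last state
  next_branch <- 1L
  for (v in values) {
    ov <- apply_linkage(model, parameter, v, linked)
    rep_v <- assemble_fixed_points(model, graph, overrides = ov,
                                   control = control, keep_tangent = FALSE)
    npts <- nrow(rep_v$points)
    ids <- integer(npts)
    used <- rep(FALSE, length(branch_states))
    for (i in seq_len(npts)) {
      x <- rep_v$points[i, ]
      if (length(branch_states)) {
        d <- vapply(branch_states, function(s)
          max(abs(s - x) / pmax(1, abs(s))), numeric(1L))
        d[used] <- Inf
        j <- which.min(d)
        if (is.finite(d[j]) && d[j] < jump_tol) {
          ids[i] <- j; used[j] <- TRUE
          branch_states[[j]] <- x
          next
        }
      }
      ids[i] <- next_branch
      branch_states[[next_branch]] <- x
      used <- c(used, TRUE)
      next_branch <- next_branch + 1L
    }
    for (i in seq_len(npts)) {
      x <- rep_v$points[i, ]
      cl <- classify_fixed_point(model, x, overrides = ov)
      row <- as.data.frame(t(x))
      row$value <- v; row$branch <- ids[i]
      row$max_re <- cl$max_re
      row$max_im_at_max_re <-
        max(abs(Im(cl$eigenvalues[Re(cl$eigenvalues) >=
                                    cl$max_re - cl$tol_eig])))
      row$classification <- cl$classification
      row$n_points <- npts
      rows[[length(rows) + 1L]] <- row
    }
    if (!npts) {
      row <- as.data.frame(t(setNames(rep(NA_real_, model$n), model$vars)))
      row$value <- v; row$branch <- NA_integer_
      row$max_re <- NA_real_; row$max_im_at_max_re <- NA_real_
      row$classification <- NA_character_; row$n_points <- 0L
      rows[[length(rows) + 1L]] <- row
    }
  }
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  structure(list(table = tab, parameter = parameter, values = values,
                 linked = linked, model = model, graph = graph,
                 control = control),
            class = "bifurcation_scan")
}

#' @export
print.bifurcation_scan <- function(x, ...) {
  cat("Parameter sweep of", x$parameter, "over [", min(x$values), ",",
      max(x$values), "],", length(x$values), "values;",
      max(c(x$table$branch, 0L), na.rm = TRUE), "branch(es)\n")
  invisible(x)
}

count_fps_at <- function(scan, value) {
  ov <- apply_linkage(scan$model, scan$parameter, value, scan$linked)
  rep_v <- assemble_fixed_points(scan$model, scan$graph, overrides = ov,
                                 control = scan$control,
                                 keep_tangent = FALSE)
  nrow(rep_v$points)
}

#' Locate saddle-node (fold) bifurcations
#'
#' A fold announces itself in the sweep as a change in the number of fixed
#' points between adjacent parameter values — the parameter at which the
#' circuit-characteristic touches the axis without crossing lies in
#' between.  Each such interval is refined by bisection on the fixed-point
#' count; at the refined fold the characteristic of the relevant SCC is
#' re-evaluated and its tangency candidate reported as the tangent fixed
#' point.
#'
#' @param scan a `bifurcation_scan`.
#' @param tol_param relative tolerance on the refined fold parameter.
#' @return list of events, each with `type = "saddle_node_candidate"`,
#'   `value` (fold parameter), `bracket`, `tangent_state` (state at the
#'   tangency, or `NULL`), `tangent_kappa`.
#' @export
locate_saddle_node <- function(scan, tol_param = 1e-4) {
  stopifnot(inherits(scan, "bifurcation_scan"))
  tab <- scan$table
  counts <- vapply(scan$values, function(v)
    tab$n_points[tab$value == v][1L], numeric(1L))
  events <- list()
  for (i in seq_len(length(scan$values) - 1L)) {
    if (is.na(counts[i]) || is.na(counts[i + 1L])) next
    if (counts[i] == counts[i + 1L]) next
    lo <- scan$values[i]; hi <- scan$values[i + 1L]
    clo <- counts[i]
    for (it in 1:40) {
      if ((hi - lo) <= tol_param * max(1, abs(hi))) break
      mid <- (lo + hi) / 2
      cm <- count_fps_at(scan, mid)
      if (cm == clo) lo <- mid else hi <- mid
    }
    fold <- (lo + hi) / 2
    # extract the tangency on the side of the bracket with fewer fixed
    # points, where the characteristic touches the axis without crossing
    side <- if (clo <= counts[i + 1L]) lo else hi
    tg <- fold_tangency(scan, side)
    events[[length(events) + 1L]] <-
      list(type = "saddle_node_candidate", value = fold,
           bracket = c(lo, hi),
           tangent_state = tg$state, tangent_kappa = tg$kappa,
           tangent_cmin = tg$cmin)
  }
  events
}

# At the fold parameter, find the tangency of the characteristic: scan all
# cyclic SCCs under each upstream combination and return the |c| minimum
# closest to zero that is not a transversal crossing of another branch.
fold_tangency <- function(scan, value) {
  model <- scan$model; graph <- scan$graph
  ov <- apply_linkage(model, scan$parameter, value, scan$linked)
  scc <- scc_decompose(graph)
  penv <- param_env(model, ov)
  control <- scan$control
  best <- list(state = NULL, kappa = NA_real_, cmin = Inf)
  partials <- list(rep(NA_real_, model$n))
  for (k in seq_along(scc$components)) {
    vs <- scc$components[[k]]
    cover <- scc_circuit_cover(graph, vs)
    nxt <- list()
    for (u in partials) {
      if (!length(cover$cover)) {
        ord <- break_circuits(graph, cover)
        for (s in solve_acyclic_env(model, ord, u, penv, control))
          nxt[[length(nxt) + 1L]] <- s
        next
      }
      ch <- evaluate_characteristic(model, graph, cover, u, overrides = ov,
                                    control = control)
      # tangency: global |c| minimum over sign-preserving runs
      loose <- control; loose$tol_tangent <- 0.2
      zs <- find_zeros(ch, control = loose)
      sts <- attr(zs, "states")
      for (zi in seq_len(nrow(zs))) {
        if (zs$tangent[zi] && abs(zs$value[zi]) < best$cmin) {
          best <- list(state = sts[[zi]], kappa = zs$kappa[zi],
                       cmin = abs(zs$value[zi]))
        }
        if (!zs$tangent[zi])
          nxt[[length(nxt) + 1L]] <- sts[[zi]]
      }
      if (is.null(best$state) && any(!zs$tangent)) {
        # just past the fold the pair has split into two transversal
        # crossings; the flattest zero stands in for the tangency
        zi <- which.min(abs(zs$slope) + ifelse(zs$tangent, Inf, 0))
        best <- list(state = sts[[zi]], kappa = zs$kappa[zi],
                     cmin = abs(zs$value[zi]))
      }
    }
    partials <- nxt
    if (!length(partials)) break
  }
  # complete the tangent state downstream (remaining SCCs) if one was found
  if (!is.null(best$state) && anyNA(best$state)) {
    st <- best$state
    for (k in seq_along(scc$components)) {
      vs <- scc$components[[k]]
      if (!anyNA(st[vs])) next
      cover <- scc_circuit_cover(graph, vs)
      if (!length(cover$cover)) {
        ord <- break_circuits(graph, cover)
        sols <- solve_acyclic_env(model, ord, st, penv, control)
        if (length(sols)) st <- sols[[1L]]
      }
    }
    best$state <- st
  }
  best
}

#' Detect Hopf bifurcation candidates along fixed-point branches
#'
#' Scans every branch of the sweep for sign changes of the largest
#' eigenvalue real part with nonzero imaginary part at the crossing — the
#' Hopf signature.  Each crossing is refined by bisection: the fixed point
#' is continued to the trial parameter by Newton iteration from the nearest
#' branch state and re-classified.  The number of characteristic zeros is
#' unchanged across a Hopf point: the characteristic itself is blind to it,
#' which is why eigenvalue continuation is required here.
#'
#' @param scan a `bifurcation_scan`.
#' @param tol_param relative tolerance on the refined Hopf parameter.
#' @param tol_im imaginary parts below this (relative to `max(1,|Re|)`) are
#'   treated as real crossings (not Hopf).
#' @return list of events, each with `type = "hopf_candidate"`, `value`,
#'   `bracket`, `branch`, `state` (continued fixed point at the crossing),
#'   `omega` (imaginary part at the crossing).
#' @export
detect_hopf <- function(scan, tol_param = 1e-4, tol_im = 1e-6) {
  stopifnot(inherits(scan, "bifurcation_scan"))
  model <- scan$model
  tab <- scan$table[!is.na(scan$table$branch), , drop = FALSE]
  events <- list()
  for (b in sort(unique(tab$branch))) {
    tb <- tab[tab$branch == b, , drop = FALSE]
    tb <- tb[order(tb$value), , drop = FALSE]
    if (nrow(tb) < 2L) next
    for (i in seq_len(nrow(tb) - 1L)) {
      r1 <- tb$max_re[i]; r2 <- tb$max_re[i + 1L]
      if (!is.finite(r1) || !is.finite(r2)) next
      if (sign(r1) == sign(r2) || r1 == 0 || r2 == 0) next
      lo <- tb$value[i]; hi <- tb$value[i + 1L]
      xlo <- as.numeric(tb[i, model$vars])
      slo <- sign(r1)
      omega <- NA_real_
      state_mid <- xlo
      for (it in 1:40) {
        if ((hi - lo) <= tol_param * max(1, abs(hi))) break
        mid <- (lo + hi) / 2
        ov <- apply_linkage(model, scan$parameter, mid, scan$linked)
        penv <- param_env(model, ov)
        x <- newton_polish(model, state_mid, penv, scan$control)
        if (is.null(x)) break
        cl <- classify_fixed_point(model, x, overrides = ov)
        state_mid <- x
        imax <- max(abs(Im(cl$eigenvalues[Re(cl$eigenvalues) >=
                                            cl$max_re - cl$tol_eig])))
        omega <- imax
        if (sign(cl$max_re) == slo) lo <- mid else hi <- mid
      }
      if (is.finite(omega) && omega > tol_im * max(1, abs(r1))) {
        events[[length(events) + 1L]] <-
          list(type = "hopf_candidate", value = (lo + hi) / 2,
               bracket = c(lo, hi), branch = b, state = state_mid,
               omega = omega)
      }
    }
  }
  events
}
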