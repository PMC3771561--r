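# Eigenvalue classification, determinant-ratio slope identity, and the
# leading-vertex-graph instability criterion.

#' Classify a fixed point by Jacobian eigenvalues
#'
#' Computes the eigenvalues of the analytic Jacobian at `x` and classifies
#' the fixed point by Hartman-Grobman: `unstable` when some eigenvalue has
#' real part above the tolerance, `asymptotically_stable` when all real
#' parts are below minus the tolerance, `marginal` otherwise (hyperbolicity
#' cannot be asserted; a bifurcation analysis is indicated).
#'
#' @param model a `regmodel`.
#' @param x fixed-point state (residual should be below `tol_fp`).
#' @param overrides optional parameter overrides.
#' @param tol_eig_rel relative eigenvalue tolerance (scaled by `max(1,
#'   ||J||_inf)`).
#' @return list with `eigenvalues` (complex), `classification`, `max_re`,
#'   `tol_eig`.
#' @export
classify_fixed_point <- function(model, x, overrides = NULL,
                                 tol_eig_rel = 1e-8) {
  J <- eval_jacobian(model, x, overrides)
  if (any(!is.finite(J))) stop("non-finite Jacobian at the fixed point")
  ev <- as.complex(eigen(J, only.values = TRUE)$values)
  tol <- tol_eig_rel * max(1, max(abs(J)))
  mre <- max(Re(ev))
  cls <- if (mre > tol) "unstable"
         else if (mre < -tol) "asymptotically_stable"
         else "marginal"
  list(eigenvalues = ev, classification = cls, max_re = mre, tol_eig = tol)
}

#' Determinant-ratio slope of the characteristic
#'
#' The slope of the circuit-characteristic at \eqn{(\kappa_1, F(\kappa_1))}
#' equals \eqn{\det J_f(x) / \det J_f^{V \setminus \{v_1\}}(x)}: the full
#' Jacobian determinant divided by the determinant of the Jacobian of the
#' subnetwork with the leading vertex removed.  For a fixed point of a
#' multi-SCC system the identity applies per SCC, with the upstream
#' coordinates frozen, so both determinants are taken over the SCC's
#' variables only.
#'
#' @param model a `regmodel`.
#' @param x state at which to evaluate (a point on the characteristic,
#'   typically a fixed point).
#' @param leading index of the leading vertex \eqn{v_1}.
#' @param scc_vars variables of the SCC (default: all variables).
#' @param overrides optional parameter overrides.
#' @return the slope value; `NA` with a warning when the reduced Jacobian is
#'   singular (the identity degenerates, typically at a bifurcation point).
#' @export
prop1_slope <- function(model, x, leading, scc_vars = NULL,
                        overrides = NULL) {
  J <- eval_jacobian(model, x, overrides)
  if (is.null(scc_vars)) scc_vars <- seq_len(model$n)
  stopifnot(leading %in% scc_vars)
  Js <- J[scc_vars, scc_vars, drop = FALSE]
  keep <- scc_vars != leading
  dr <- if (length(scc_vars) == 1L) 1 else det(Js[keep, keep, drop = FALSE])
  if (abs(dr) < 1e-300) {
    warning("reduced Jacobian is singular; slope identity inapplicable")
    return(NA_real_)
  }
  det(Js) / dr
}

#' Leading-vertex-graph instability criterion
#'
#' For an LVG, a positive slope of the circuit-characteristic at a zero is a
#' sufficient certificate that the corresponding fixed point is unstable.  A
#' negative slope carries no stability information (the verdict is
#' `inconclusive`, never "stable"), and the criterion does not apply to
#' SCCs whose minimal cover has more than one vertex.
#'
#' @param slope characteristic slope at the zero.
#' @param is_lvg is the SCC a leading vertex graph?
#' @param tol_slope slopes in `[-tol_slope, tol_slope]` are treated as
#'   tangent (no verdict).
#' @return one of `"unstable_by_slope"`, `"inconclusive"`,
#'   `"not_applicable"`.
#' @export
lvg_instability_test <- function(slope, is_lvg, tol_slope = 1e-6) {
  if (!isTRUE(is_lvg)) return("not_applicable")
  if (is.na(slope)) return("inconclusive")
  if (slope > tol_slope) "unstable_by_slope" else "inconclusive"
}

#' Sign structure of the reduced Jacobian determinant in an LVG
#'
#' In a leading vertex graph the subnetwork without the leading vertex is
#' acyclic, so the reduced Jacobian determinant equals the product of its
#' diagonal entries; with all self-derivatives negative (decay) its sign is
#' \eqn{(-1)^{n-1}}.  This function verifies both facts numerically.
#'
#' @param model a `regmodel`.
#' @param x evaluation state.
#' @param leading leading vertex index.
#' @param scc_vars SCC variable indices (default: all).
#' @param overrides optional parameter overrides.
#' @return list with `det` (reduced determinant), `diag_prod`, `sign`,
#'   `consistent` (determinant equals diagonal product to 1e-10 relative)
#'   and `diag_negative` (all diagonal entries `< 0`; when `FALSE` the
#'   instability proof's premise is violated and the LVG test should be
#'   reported inconclusive).
#' @export
reduced_determinant_sign <- function(model, x, leading, scc_vars = NULL,
                                     overrides = NULL) {
  J <- eval_jacobian(model, x, overrides)
  if (is.null(scc_vars)) scc_vars <- seq_len(model$n)
  keep <- scc_vars[scc_vars != leading]
  Jr <- J[keep, keep, drop = FALSE]
  d <- if (length(keep)) det(Jr) else 1
  dp <- if (length(keep)) prod(diag(Jr)) else 1
  list(det = d, diag_prod = dp,
       sign = sign(d),
       consistent = abs(d - dp) <= 1e-10 * max(1, abs(dp)),
       diag_negative = all(diag(Jr) < 0))
}

#' Full stability report for an assembled fixed-point set
#'
#' Combines eigenvalue classification, the determinant-ratio slope, and the
#' LVG verdict for every point of a [assemble_fixed_points()] report.  The
#' characteristic slope and LVG flag come from the per-SCC provenance
#' recorded during assembly; the LVG verdict refers to the (unique) cyclic
#' SCC a point's zero came from, and is `not_applicable` when no cyclic SCC
#' contributed or several did with conflicting verdicts resolved per SCC.
#'
#' @param model a `regmodel`.
#' @param report a `fixed_point_report`.
#' @param graph optional precomputed `interaction_graph` (rebuilt when
#'   missing; needed to delimit each SCC for the determinant ratio).
#' @param overrides optional parameter overrides.
#' @param tol_slope see [lvg_instability_test()].
#' @return data.frame with one row per fixed point: `classification`,
#'   `max_re`, per-SCC `char_slope`, `prop1_slope`, `lvg_verdict`; the
#'   eigenvalues are attached as attribute `"eigenvalues"` (list).
#' @export
stability_report <- function(model, report, graph = NULL, overrides = NULL,
                             tol_slope = 1e-6) {
  stopifnot(inherits(report, "fixed_point_report"))
  if (is.null(graph)) graph <- build_igraph(model)
  scc <- scc_decompose(graph)
  n <- nrow(report$points)
  out <- data.frame(classification = character(n), max_re = numeric(n),
                    char_slope = numeric(n), prop1_slope = numeric(n),
                    lvg_verdict = character(n), stringsAsFactors = FALSE)
  evs <- vector("list", n)
  for (i in seq_len(n)) {
    x <- report$points[i, ]
    cl <- classify_fixed_point(model, x, overrides)
    evs[[i]] <- cl$eigenvalues
    out$classification[i] <- cl$classification
    out$max_re[i] <- cl$max_re
    pr <- report$provenance[[i]]
    cyc <- pr[!is.na(pr$leading), , drop = FALSE]
    if (nrow(cyc)) {
      # the verdict of the last cyclic SCC (innermost feedback) is reported;
      # unstable_by_slope from any LVG SCC wins since it is a certificate
      slopes <- cyc$slope
      out$char_slope[i] <- slopes[nrow(cyc)]
      verdicts <- vapply(seq_len(nrow(cyc)), function(r)
        lvg_instability_test(cyc$slope[r], cyc$is_lvg[r], tol_slope),
        character(1L))
      out$lvg_verdict[i] <- if (any(verdicts == "unstable_by_slope"))
        "unstable_by_slope"
      else if (all(verdicts == "not_applicable")) "not_applicable"
      else "inconclusive"
      last <- nrow(cyc)
      out$prop1_slope[i] <- tryCatch(
        prop1_slope(model, x, cyc$leading[last],
                    scc_vars = scc$components[[cyc$scc[last]]],
                    overrides = overrides),
        warning = function(w) NA_real_)
    } else {
      out$char_slope[i] <- NA_real_
      out$prop1_slope[i] <- NA_real_
      out$lvg_verdict[i] <- "not_applicable"
    }
  }
  attr(out, "eigenvalues") <- evs
  out
}
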