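#' @importFrom stats D uniroot optimize runif setNames
#' @importFrom utils head tail combn packageVersion
NULL

# Function symbols allowed inside rate expressions.  The grammar is kept small
# on purpose: Hill-type kinetics, mass action and exponential terms are all
# expressible with it, and every expression stays differentiable by stats::D().
.cbnet_allowed_calls <- c("+", "-", "*", "/", "^", "(", "exp")

#' Construct a regulatory-network ODE model
#'
#' A regulatory model is a system \eqn{\dot x = f(x)} of autonomous first-order
#' ODEs over non-negative state variables (typically concentrations).  Each
#' rate expression \eqn{f_i} is given as an arithmetic string over the declared
#' variables and parameters; allowed operators are `+ - * / ^`, parentheses and
#' `exp()`.  Every variable carries a closed bound interval, interpreted as the
#' trapping region of the system: a box that trajectories eventually enter and
#' inside which all fixed points of interest are searched for.
#'
#' Symbolic partial derivatives of every rate with respect to every variable
#' are precomputed with [stats::D()] at construction time; they drive the
#' Jacobian, the interaction graph and the closed-form solution of variables
#' whose self-derivative is a state-independent (decay) constant.
#'
#' @param vars character vector of variable names (order defines the state
#'   vector).
#' @param rates character vector of rate expressions, one per variable.
#' @param params named numeric vector of parameter values (may be empty).
#' @param bounds numeric matrix with `length(vars)` rows and two columns
#'   `lo`, `hi`; `0 <= lo < hi`, finite.
#' @param name optional model name.
#' @param note optional free-text annotation (e.g. units).
#' @return an object of class `"regmodel"`.
#' @seealso [parse_model()], [eval_rhs()], [eval_jacobian()], [build_igraph()]
#' @export
regulatory_model <- function(vars, rates, params = numeric(0), bounds,
                             name = "model", note = NULL) {
  vars <- as.character(vars)
  n <- length(vars)
  if (n < 1L) stop("a model needs at least one variable")
  if (length(rates) != n) stop("need exactly one rate expression per variable")
  if (anyDuplicated(vars)) stop("duplicated variable name: ",
                                vars[duplicated(vars)][1L])
  if (length(params)) {
    if (is.null(names(params)) || any(!nzchar(names(params))))
      stop("parameters must be named")
    if (anyDuplicated(names(params)))
      stop("duplicated parameter name: ",
           names(params)[duplicated(names(params))][1L])
    if (any(names(params) %in% vars))
      stop("name used for both a variable and a parameter: ",
           intersect(names(params), vars)[1L])
  }
  bounds <- matrix(as.numeric(bounds), nrow = n, ncol = 2L,
                   dimnames = list(vars, c("lo", "hi")))
  if (any(!is.finite(bounds))) stop("bounds must be finite")
  bad <- which(bounds[, 1L] < 0 | bounds[, 1L] >= bounds[, 2L])
  if (length(bad))
    stop("invalid bounds for variable '", vars[bad[1L]],
         "': need 0 <= lo < hi")

  exprs <- vector("list", n)
  for (i in seq_len(n)) {
    e <- tryCatch(str2lang(rates[[i]]),
                  error = function(err)
                    stop("malformed rate expression for variable '", vars[i],
                         "': ", conditionMessage(err), call. = FALSE))
    check_expr_grammar(e, vars[i])
    syms <- all.vars(e)
    unknown <- setdiff(syms, c(vars, names(params)))
    if (length(unknown))
      stop("undeclared identifier '", unknown[1L],
           "' in rate expression for variable '", vars[i], "'")
    exprs[[i]] <- e
  }

  # symbolic Jacobian entries J[i][j] = d f_i / d x_j
  jac <- vector("list", n * n)
  dim(jac) <- c(n, n)
  for (i in seq_len(n))
    for (j in seq_len(n))
      jac[[i, j]] <- D(exprs[[i]], vars[j])

  # a variable is in decay form when d f_i / d x_i contains no state variable:
  # f_i = r_i(x_{-i}) - d_i x_i with constant d_i > 0 once parameters are fixed
  diag_struct_const <- vapply(seq_len(n), function(i)
    length(intersect(all.vars(jac[[i, i]]), vars)) == 0L, logical(1L))

  structure(list(
    name = name, note = note, vars = vars, n = n,
    rates = as.character(rates), exprs = exprs,
    params = params, bounds = bounds,
    jac = jac, diag_struct_const = diag_struct_const
  ), class = "regmodel")
}

check_expr_grammar <- function(e, var, top = TRUE) {
  if (is.numeric(e) || is.symbol(e)) return(invisible(TRUE))
  if (is.call(e)) {
    fn <- as.character(e[[1L]])
    if (!fn %in% .cbnet_allowed_calls)
      stop("malformed rate expression for variable '", var,
           "': function '", fn, "' is not part of the model grammar",
           call. = FALSE)
    for (k in seq_along(e)[-1L]) check_expr_grammar(e[[k]], var, FALSE)
    return(invisible(TRUE))
  }
  stop("malformed rate expression for variable '", var, "'", call. = FALSE)
}

#' Parse a model-description document
#'
#' The document is a small line-oriented text format:
#' \preformatted{
#'   # comment
#'   model  stem_cell
#'   note   dimensionless concentrations
#'   param  eN = 0.2
#'   var    x1 in [0, 6] : eN - x1
#' }
#' `param` lines declare parameters, `var` lines declare one state variable
#' with its bound interval (the trapping region used for root searches) and
#' its rate expression.  Declaration order defines the state vector.
#' Serialization with [format_model()] round-trips losslessly.
#'
#' @param text a character vector of lines, or a single string containing
#'   newlines.
#' @return a [regulatory_model()] object.
#' @export
parse_model <- function(text) {
  if (length(text) == 1L && grepl("\n", text, fixed = TRUE))
    text <- strsplit(text, "\n", fixed = TRUE)[[1L]]
  lines <- sub("#.*$", "", text)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) stop("empty model description")

  name <- "model"; note <- NULL
  params <- numeric(0)
  vars <- character(0); rates <- character(0); lo <- numeric(0); hi <- numeric(0)

  var_re <- "^var\\s+([A-Za-z][A-Za-z0-9_.]*)\\s+in\\s*\\[([^],]+),([^]]+)\\]\\s*:\\s*(.+)$"
  par_re <- "^param\\s+([A-Za-z][A-Za-z0-9_.]*)\\s*=\\s*(\\S+)\\s*$"

  for (ln in lines) {
    if (grepl("^model\\s+", ln)) {
      name <- trimws(sub("^model\\s+", "", ln))
    } else if (grepl("^note\\s+", ln)) {
      note <- trimws(sub("^note\\s+", "", ln))
    } else if (grepl(par_re, ln)) {
      pn <- sub(par_re, "\\1", ln)
      pv <- suppressWarnings(as.numeric(sub(par_re, "\\2", ln)))
      if (is.na(pv)) stop("non-numeric value for parameter '", pn, "'")
      params[pn] <- pv
    } else if (grepl("^var\\s+", ln)) {
      if (!grepl(var_re, ln))
        stop("malformed or incomplete var line (need 'var NAME in [lo, hi] : expr'): ", ln)
      vn <- sub(var_re, "\\1", ln)
      l <- suppressWarnings(as.numeric(trimws(sub(var_re, "\\2", ln))))
      h <- suppressWarnings(as.numeric(trimws(sub(var_re, "\\3", ln))))
      if (is.na(l) || is.na(h))
        stop("missing or non-numeric bounds for variable '", vn, "'")
      vars <- c(vars, vn); lo <- c(lo, l); hi <- c(hi, h)
      rates <- c(rates, trimws(sub(var_re, "\\4", ln)))
    } else {
      stop("unrecognized line in model description: ", ln)
    }
  }
  if (!length(vars)) stop("model description declares no variables")
  regulatory_model(vars, rates, params, cbind(lo, hi), name = name, note = note)
}

#' Read a model-description file
#' @param path file path.
#' @return a [regulatory_model()] object.
#' @export
read_model <- function(path) parse_model(readLines(path, warn = FALSE))

#' Serialize a model to its model-description format
#'
#' @param model a `regmodel`.
#' @return character vector of lines; `parse_model(format_model(m))`
#'   reconstructs an identical model.
#' @export
format_model <- function(model) {
  stopifnot(inherits(model, "regmodel"))
  out <- c(paste("model", model$name))
  if (!is.null(model$note)) out <- c(out, paste("note", model$note))
  for (pn in names(model$params))
    out <- c(out, sprintf("param %s = %s", pn,
                          format(model$params[[pn]], digits = 17)))
  for (i in seq_len(model$n))
    out <- c(out, sprintf("var %s in [%s, %s] : %s", model$vars[i],
                          format(model$bounds[i, 1L], digits = 17),
                          format(model$bounds[i, 2L], digits = 17),
                          model$rates[i]))
  out
}

#' Write a model-description file
#' @param model a `regmodel`.
#' @param path file path.
#' @export
write_model <- function(model, path) {
  writeLines(format_model(model), path)
  invisible(path)
}

#' @export
print.regmodel <- function(x, ...) {
  cat("Regulatory network model '", x$name, "': ", x$n, " variable",
      if (x$n != 1L) "s", ", ", length(x$params), " parameter",
      if (length(x$params) != 1L) "s", "\n", sep = "")
  for (i in seq_len(x$n))
    cat(sprintf("  %s' = %s   [%g, %g]\n", x$vars[i], x$rates[i],
                x$bounds[i, 1L], x$bounds[i, 2L]))
  if (length(x$params))
    cat("  params:", paste(names(x$params), x$params, sep = "=",
                           collapse = ", "), "\n")
  invisible(x)
}

# Evaluation environment holding parameter values (with optional overrides).
param_env <- function(model, overrides = NULL) {
  if (!is.null(overrides) && length(overrides)) {
    bad <- setdiff(names(overrides), names(model$params))
    if (length(bad)) stop("unknown parameter in overrides: ", bad[1L])
  }
  p <- model$params
  if (length(overrides)) p[names(overrides)] <- overrides
  e <- new.env(parent = baseenv())
  for (pn in names(p)) assign(pn, p[[pn]], envir = e)
  e
}

# Evaluate one precompiled expression at a state.  Components of `x` may be
# equal-length vectors, in which case the result is vectorized.
eval_expr_at <- function(model, expr, x, penv) {
  e <- new.env(parent = penv)
  for (i in seq_len(model$n)) assign(model$vars[i], x[[i]], envir = e)
  v <- eval(expr, envir = e)
  if (length(v) == 1L && is.numeric(x[[1L]]) && length(x[[1L]]) > 1L)
    v <- rep_len(v, length(x[[1L]]))
  v
}

#' Evaluate the right-hand side f(x)
#'
#' @param model a `regmodel`.
#' @param x numeric state vector of length `n` (order of `model$vars`).
#' @param overrides optional named numeric vector of parameter overrides.
#' @return numeric vector of rates \eqn{f(x;\theta)}.
#' @export
eval_rhs <- function(model, x, overrides = NULL) {
  stopifnot(inherits(model, "regmodel"))
  if (length(x) != model$n)
    stop("state vector has length ", length(x), ", expected ", model$n)
  penv <- param_env(model, overrides)
  xl <- as.list(as.numeric(x))
  out <- vapply(seq_len(model$n), function(i)
    as.numeric(eval_expr_at(model, model$exprs[[i]], xl, penv)), numeric(1L))
  if (any(!is.finite(out)))
    stop("non-finite rate for component ", which(!is.finite(out))[1L],
         " ('", model$vars[which(!is.finite(out))[1L]], "')")
  names(out) <- model$vars
  out
}

#' Evaluate the Jacobian matrix J[i,j] = df_i/dx_j
#'
#' Entries come from the symbolic derivatives precomputed at model
#' construction; [jacobian_fd()] provides an independent finite-difference
#' route for cross-checks.
#'
#' @inheritParams eval_rhs
#' @return `n x n` numeric matrix.
#' @export
eval_jacobian <- function(model, x, overrides = NULL) {
  stopifnot(inherits(model, "regmodel"))
  if (length(x) != model$n)
    stop("state vector has length ", length(x), ", expected ", model$n)
  penv <- param_env(model, overrides)
  xl <- as.list(as.numeric(x))
  J <- matrix(0, model$n, model$n, dimnames = list(model$vars, model$vars))
  for (i in seq_len(model$n))
    for (j in seq_len(model$n)) {
      v <- as.numeric(eval_expr_at(model, model$jac[[i, j]], xl, penv))
      if (!is.finite(v))
        stop("non-finite Jacobian entry (", i, ",", j, ")")
      J[i, j] <- v
    }
  J
}

#' Central finite-difference Jacobian
#'
#' Independent numerical route used to validate the symbolic Jacobian; step
#' size `h = max(1e-6, 1e-6 * |x_j|)` per column.
#'
#' @inheritParams eval_rhs
#' @return `n x n` numeric matrix.
#' @export
jacobian_fd <- function(model, x, overrides = NULL) {
  n <- model$n
  J <- matrix(0, n, n, dimnames = list(model$vars, model$vars))
  for (j in seq_len(n)) {
    h <- max(1e-6, 1e-6 * abs(x[j]))
    xp <- x; xp[j] <- x[j] + h
    xm <- x; xm[j] <- x[j] - h
    J[, j] <- (eval_rhs(model, xp, overrides) -
                 eval_rhs(model, xm, overrides)) / (2 * h)
  }
  J
}

# Numeric self-derivative constant d_i (only valid when diag_struct_const[i]);
# value of d f_i / d x_i, typically a negative decay rate.
diag_const_value <- function(model, i, penv) {
  as.numeric(eval(model$jac[[i, i]], envir = penv))
}

# Halton low-discrepancy sequence in [0,1]^dim, deterministic given `start`.
halton_seq <- function(n, dim, start = 1L) {
  primes <- c(2, 3, 5, 7, 11, 13, 17, 19, 23, 29, 31, 37, 41, 43, 47, 53)
  if (dim > length(primes)) stop("Halton sampler supports at most ",
                                 length(primes), " dimensions")
  idx <- start + seq_len(n) - 1L
  out <- matrix(0, n, dim)
  for (d in seq_len(dim)) {
    b <- primes[d]
    i <- idx; f <- 1; r <- numeric(n)
    while (any(i > 0)) {
      f <- f / b
      r <- r + f * (i %% b)
      i <- i %/% b
    }
    out[, d] <- r
  }
  out
}

#' Derive the interaction graph of a model
#'
#' The interaction graph (I-graph) `G(V,E)` has one vertex per state variable
#' and an edge `j -> i` whenever \eqn{\partial f_i/\partial x_j} is not
#' identically zero: the graph encodes which variables directly influence
#' which rates.  Presence and sign of edges are decided by evaluating the
#' symbolic partial derivatives on a low-discrepancy (Halton) sample of the
#' bounds box, so the graph is reproducible for a fixed `seed`.  An edge gets
#' a `+`/`-` sign label only when the sampled partial never changes sign.
#'
#' Self-edges need a convention because linear decay `- d x_i` gives every
#' variable a trivially negative self-derivative that generates no feedback:
#' \describe{
#'   \item{`"default"`}{a self-edge is added whenever the self-derivative is
#'     state-dependent (any self-regulation beyond a constant decay term),
#'     or a positive constant.  This convention makes saturable autoregulation
#'     (e.g. enzyme inhibition combined with saturable uptake) count as a
#'     length-1 circuit.}
#'   \item{`"strict"`}{a self-edge only when the sampled self-derivative is
#'     positive somewhere (positive autoregulation only).}
#' }
#'
#' @param model a `regmodel`.
#' @param n_samples number of sample states used for edge/sign detection.
#' @param seed integer seed for the low-discrepancy sample (start offset).
#' @param self_edges `"default"` or `"strict"` (see Details).
#' @param eps_edge numeric threshold below which a sampled partial counts as
#'   zero.
#' @param overrides optional parameter overrides.
#' @return object of class `"interaction_graph"`: vertex names plus an edge
#'   table with columns `from`, `to`, `sign`.
#' @export
build_igraph <- function(model, n_samples = 64L, seed = 1L,
                         self_edges = c("default", "strict"),
                         eps_edge = 1e-9, overrides = NULL) {
  stopifnot(inherits(model, "regmodel"))
  self_edges <- match.arg(self_edges)
  if (n_samples < 1L) stop("n_samples must be >= 1")
  if (any(model$bounds[, 2L] - model$bounds[, 1L] <= 0))
    stop("degenerate bounds")
  n <- model$n
  penv <- param_env(model, overrides)
  u <- halton_seq(n_samples, n, start = as.integer(seed))
  # sample states as list of vectors (vectorized expression evaluation)
  xs <- lapply(seq_len(n), function(j)
    model$bounds[j, 1L] + u[, j] * (model$bounds[j, 2L] - model$bounds[j, 1L]))

  from <- integer(0); to <- integer(0); sgn <- character(0)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      dexpr <- model$jac[[i, j]]
      if (identical(dexpr, 0)) next
      vals <- as.numeric(eval_expr_at(model, dexpr, xs, penv))
      if (length(vals) == 1L) vals <- rep(vals, n_samples)
      present <-
        if (i != j) {
          any(abs(vals) > eps_edge)
        } else if (self_edges == "strict") {
          any(vals > eps_edge)
        } else if (model$diag_struct_const[i]) {
          diag_const_value(model, i, penv) > eps_edge
        } else {
          any(abs(vals) > eps_edge)  # state-dependent self-regulation
        }
      if (!present) next
      s <- if (all(vals >= -eps_edge)) "+"
           else if (all(vals <= eps_edge)) "-"
           else "?"
      from <- c(from, j); to <- c(to, i); sgn <- c(sgn, s)
    }
  }
  structure(list(
    vars = model$vars, n = n,
    edges = data.frame(from = from, to = to, sign = sgn,
                       stringsAsFactors = FALSE),
    self_edges = from[from == to],
    mode = self_edges, n_samples = n_samples, seed = as.integer(seed)
  ), class = "interaction_graph")
}

#' @export
print.interaction_graph <- function(x, ...) {
  cat("Interaction graph:", x$n, "vertices,", nrow(x$edges), "edges\n")
  if (nrow(x$edges)) {
    lab <- sprintf("%s -%s-> %s", x$vars[x$edges$from], x$edges$sign,
                   x$vars[x$edges$to])
    cat(" ", paste(lab, collapse = ", "), "\n")
  }
  invisible(x)
}

# Convert to an igraph object (used for SCCs / DAG checks).
as_igraph_graph <- function(graph, vertices = NULL) {
  if (is.null(vertices)) vertices <- seq_len(graph$n)
  keep <- graph$edges$from %in% vertices & graph$edges$to %in% vertices
  el <- graph$edges[keep, c("from", "to"), drop = FALSE]
  igraph::graph_from_data_frame(
    el, directed = TRUE,
    vertices = data.frame(name = as.character(vertices)))
}

# Adjacency list over local indices 1..k for a vertex subset.
adjacency_local <- function(graph, vertices) {
  k <- length(vertices)
  pos <- match(seq_len(graph$n), vertices)
  adj <- vector("list", k)
  for (r in seq_len(nrow(graph$edges))) {
    f <- pos[graph$edges$from[r]]; t <- pos[graph$edges$to[r]]
    if (!is.na(f) && !is.na(t)) adj[[f]] <- c(adj[[f]], t)
  }
  lapply(adj, function(a) if (is.null(a)) integer(0) else sort(unique(a)))
}

#' Construct an interaction graph directly from an edge list
#'
#' Mostly useful for testing graph algorithms on arbitrary topologies
#' without an underlying ODE model.
#'
#' @param n number of vertices (named `v1..vn` unless `vars` given).
#' @param edges two-column matrix or data.frame of `from`, `to` vertex
#'   indices (may be empty).
#' @param vars optional vertex names.
#' @return an `interaction_graph`.
#' @export
interaction_graph <- function(n, edges = NULL, vars = NULL) {
  n <- as.integer(n)
  stopifnot(n >= 1L)
  if (is.null(vars)) vars <- paste0("v", seq_len(n))
  if (is.null(edges) || !NROW(edges)) {
    ed <- data.frame(from = integer(0), to = integer(0), sign = character(0))
  } else {
    edges <- as.matrix(edges)
    stopifnot(ncol(edges) == 2L, all(edges >= 1L), all(edges <= n))
    ed <- data.frame(from = as.integer(edges[, 1L]),
                     to = as.integer(edges[, 2L]),
                     sign = "?", stringsAsFactors = FALSE)
  }
  structure(list(vars = vars, n = n, edges = ed,
                 self_edges = ed$from[ed$from == ed$to],
                 mode = "manual", n_samples = 0L, seed = NA_integer_),
            class = "interaction_graph")
}

#' Propose trapping-region bounds for a decay-form model
#'
#' For variables written as \eqn{f_i = r_i(x) - d_i x_i} with constant decay
#' \eqn{d_i > 0}, any box with \eqn{hi_i \ge \max r_i / d_i} is positively
#' invariant in that coordinate.  Starting from the current bounds the upper
#' bounds are iterated as `hi_i <- max(r_i over box)/d_i` (sampled on a
#' low-discrepancy grid plus the box corners of the maximum) until they
#' stop growing, then inflated by a safety margin.
#'
#' @param model a `regmodel` with all variables in decay form.
#' @param n_samples sample count per iteration.
#' @param margin multiplicative safety margin on the proposed upper bounds.
#' @param max_iter iteration cap.
#' @return bounds matrix like `model$bounds`.
#' @export
propose_bounds <- function(model, n_samples = 256L, margin = 1.05,
                           max_iter = 25L) {
  stopifnot(inherits(model, "regmodel"))
  if (!all(model$diag_struct_const))
    stop("propose_bounds needs every variable in decay form")
  penv <- param_env(model)
  d <- vapply(seq_len(model$n), function(i)
    -diag_const_value(model, i, penv), numeric(1L))
  if (any(d <= 0)) stop("propose_bounds needs positive decay constants")
  b <- model$bounds
  for (it in seq_len(max_iter)) {
    u <- halton_seq(n_samples, model$n, start = 1L)
    xs <- lapply(seq_len(model$n), function(j)
      b[j, 1L] + c(u[, j], 0, 1) * (b[j, 2L] - b[j, 1L]))
    hi_new <- vapply(seq_len(model$n), function(i) {
      st <- xs; st[[i]] <- rep(0, length(xs[[1L]]))
      r <- as.numeric(eval_expr_at(model, model$exprs[[i]], st, penv))
      max(r) / d[i]
    }, numeric(1L))
    changed <- any(hi_new > b[, 2L] * (1 + 1e-9))
    b[, 2L] <- pmax(b[, 2L], hi_new)
    if (!changed) break
  }
  b[, 2L] <- b[, 2L] * margin
  b
}

#' Export an interaction graph as an edge-list table
#'
#' @param graph an `interaction_graph`.
#' @return data.frame with `source`, `target`, `sign` columns (variable
#'   names).
#' @export
igraph_edge_table <- function(graph) {
  data.frame(source = graph$vars[graph$edges$from],
             target = graph$vars[graph$edges$to],
             sign = graph$edges$sign, stringsAsFactors = FALSE)
}
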