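# Packaged network models and seeded random-model generators.

# Run `code` under a private RNG stream, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Hematopoietic stem-cell differentiation model
#'
#' Six-variable dimensionless model of the lineage choice between the
#' neutrophil and macrophage fates: the counter-acting suppressors Gfi-1
#' (`x2`) and Egr (`x3`) are activated by their transcription factors
#' C/EBPalpha (`x1`) and PU.1 (`x4`) and drive the lineage-specific
#' downstream genes Mac (`x5`) and Neut (`x6`).  Two interlocked positive
#' feedback circuits between `x2`, `x3`, `x4` produce bistability; the free
#' parameters are the rescaled synthesis rates `eN` (of C/EBPalpha) and
#' `eM` (maximal, of PU.1).
#'
#' @param e_N,e_M non-negative synthesis-rate parameters.
#' @return a `regmodel` with bounds `[0, 6]` per variable (the box contains
#'   the trapping region: every synthesis rate is below 6).
#' @export
stem_cell_model <- function(e_N = 0.2, e_M = 0.2) {
  stopifnot(e_N >= 0, e_M >= 0)
  parse_model(c(
    "model stem_cell",
    "note dimensionless concentrations (hematopoietic lineage choice)",
    sprintf("param eN = %.17g", e_N),
    sprintf("param eM = %.17g", e_M),
    "var x1 in [0, 6] : eN - x1",
    "var x2 in [0, 6] : 5*x1/(1 + x1) * 1/(1 + x3^4) - x2",
    "var x3 in [0, 6] : 5*x4/(1 + x4) * 1/(1 + x2^4) - x3",
    "var x4 in [0, 6] : eM/(1 + x2^4) - x4",
    "var x5 in [0, 6] : x1*x4/(1 + x1*x4) + 4*x3/(1 + x3) * 1/(1 + x2^4) - x5",
    "var x6 in [0, 6] : x1*x4/(1 + x1*x4) + 4*x2/(1 + x2) * 1/(1 + x3^4) - x6"))
}

#' Repressilator model
#'
#' The synthetic three-gene ring oscillator: mRNAs `m1, m2, m3` and proteins
#' `p1, p2, p3` of the repressors lacI, tetR and cI, each gene repressed by
#' the previous protein in the ring via
#' \eqn{r(p) = \alpha/(1+p^{n}) + \alpha_0}.  The protein equations are
#' \eqn{\dot p_i = \beta (m_i - p_i)}.  The trapping region follows from
#' \eqn{\alpha_0 \le r(p) \le \alpha + \alpha_0}; the bounds used are
#' `[0, alpha + alpha0]` so they stay non-degenerate for `alpha = 0`.
#'
#' @param alpha maximal repressible transcription rate.
#' @param alpha0 leaky transcription rate.
#' @param beta protein/mRNA decay-rate ratio.
#' @param n_hill Hill coefficient of repression.
#' @return a `regmodel` with variables `m1, p1, m2, p2, m3, p3`.
#' @export
repressilator_model <- function(alpha = 290, alpha0 = 10, beta = 1,
                                n_hill = 2) {
  stopifnot(alpha >= 0, alpha0 > 0, beta > 0, n_hill > 0)
  hi <- alpha + alpha0
  lines <- c(
    "model repressilator",
    "note dimensionless mRNA (m) and protein (p) concentrations",
    sprintf("param alpha = %.17g", alpha),
    sprintf("param alpha0 = %.17g", alpha0),
    sprintf("param beta = %.17g", beta),
    sprintf("param n_hill = %.17g", n_hill))
  rep_of <- c(3L, 1L, 2L)   # m_i is repressed by p_{rep_of[i]}
  for (i in 1:3) {
    lines <- c(lines,
      sprintf("var m%d in [0, %.17g] : alpha/(1 + p%d^n_hill) + alpha0 - m%d",
              i, hi, rep_of[i], i),
      sprintf("var p%d in [0, %.17g] : beta*(m%d - p%d)", i, hi, i, i))
  }
  parse_model(lines)
}

#' Tryptophan regulation model
#'
#' Four-variable model of tryptophan homeostasis in \emph{Escherichia coli}:
#' free operator sites (`x1`), mRNA (`x2`), enzyme (`x3`) and tryptophan
#' (`x4`).  Tryptophan feeds back on its own synthesis through three
#' mechanisms — operator binding, transcript attenuation and enzyme
#' inhibition — each modeled by a sigmoidally decreasing function
#' \eqn{C(x, K, m) = K^m/(K^m + x^m)}; uptake of tryptophan for protein
#' synthesis is the saturable term \eqn{g x_4/(x_4 + K_g)}.  `mu` is the
#' dilution rate due to cell growth and the natural bifurcation parameter.
#' Parameter defaults are the published set; concentrations in model units
#' (µM except the operator total `Ot`, printed in nM and used as printed),
#' time in minutes.
#'
#' @param ... named parameter overrides (e.g. `mu = 0.1`).
#' @return a `regmodel`.  Bounds are trapping-region estimates
#'   `x_i <= max(r_i)/d_i` evaluated at the smallest swept dilution rate,
#'   `x4` capped at 200 µM.
#' @export
tryptophan_model <- function(...) {
  defaults <- c(k1 = 50, Ot = 3.32, t1 = 3.53, m1 = 1.92, g1 = 0.5,
                mu = 0.01, k2 = 15, t2 = 0.04, m2 = 1.72, g2 = 15,
                k3 = 90, k4 = 59, t3 = 810, m3 = 1.2, g = 25, Kg = 0.2)
  ov <- c(...)
  if (length(ov)) {
    bad <- setdiff(names(ov), names(defaults))
    if (length(bad)) stop("unknown tryptophan parameter: ", bad[1L])
    defaults[names(ov)] <- ov
  }
  lines <- c(
    "model tryptophan",
    "note concentrations in model units, time in minutes",
    sprintf("param %s = %.17g", names(defaults), defaults),
    "var x1 in [0, 400] : k1*Ot * t1^m1/(t1^m1 + x4^m1) - (g1 + mu)*x1",
    "var x2 in [0, 400] : k2*x1 * t2^m2/(t2^m2 + x4^m2) - (g2 + mu)*x2",
    "var x3 in [0, 10000000] : k3*x2 - mu*x3",
    "var x4 in [0, 200] : k4 * t3^m3/(t3^m3 + x4^m3) * x3 - g*x4/(x4 + Kg) - mu*x4")
  parse_model(lines)
}

# one random Hill-type interaction term in variable `v` (activating or
# inhibiting), as an expression string
random_hill_term <- function(v, act = NULL) {
  a <- round(runif(1, 0.5, 2), 3)
  k <- round(runif(1, 0.3, 1.5), 3)
  if (is.null(act)) act <- runif(1) < 0.5
  if (act) sprintf("%.3f*%s^2/(%.3f + %s^2)", a, v, k^2, v)
  else sprintf("%.3f*%.3f/(%.3f + %s^2)", a, k^2, k^2, v)
}

#' Randomized proof-topology fixtures
#'
#' Regulatory models whose interaction graphs reproduce the two reference
#' topologies used to derive the determinant-ratio slope identity: a fully
#' connected three-vertex graph, and a four-vertex graph with dependence
#' structure `f1(x1,x3), f2(x1,x2,x4), f3(x1,x3,x4), f4(x2,x4)`.  Both need
#' two circuit-closing steps (their minimal cover has two vertices), so they
#' exercise the nested closing machinery; the slope identity must hold for
#' any smooth rates, so the rate laws are randomized sums of Hill terms
#' minus linear decay, fixed by `seed`.
#'
#' @param kind `"3vertex"` or `"4vertex"`.
#' @param seed integer seed fixing the random rate laws.
#' @return a `regmodel`.
#' @export
methods_fixture <- function(kind = c("3vertex", "4vertex"), seed = 1L) {
  kind <- match.arg(kind)
  deps <- if (kind == "3vertex")
    list(c(2L, 3L), c(1L, 3L), c(1L, 2L))
  else
    list(3L, c(1L, 4L), c(1L, 4L), 2L)
  n <- length(deps)
  with_seed(seed, {
    rates <- character(n); his <- numeric(n)
    for (i in seq_len(n)) {
      terms <- vapply(deps[[i]], function(j)
        random_hill_term(sprintf("x%d", j)), character(1L))
      d <- round(runif(1, 0.8, 1.5), 3)
      rates[i] <- paste(paste(terms, collapse = " + "),
                        sprintf("- %.3f*x%d", d, i))
      amax <- sum(as.numeric(sub("\\*.*$", "", terms)))
      his[i] <- ceiling(amax / d * 1.5 + 1)
    }
    parse_model(c(
      sprintf("model methods_%s", kind),
      sprintf("var x%d in [0, %g] : %s", seq_len(n), his, rates)))
  })
}

#' Random leading-vertex-graph model
#'
#' Generates a strongly connected regulatory model in which vertex `x1`
#' lies on every elementary circuit, by construction: the remaining
#' vertices are split into disjoint directed paths, each closed through
#' `x1`.  Removing `x1` leaves disjoint simple paths, hence no circuit
#' avoids it and the minimal cover is `{x1}` (an LVG).  Every edge is a
#' random signed Hill interaction, every variable has linear decay, so the
#' model is bounded by construction.  Same seed, same model (byte-identical
#' serialization).
#'
#' @param n_vars number of variables (`>= 2`).
#' @param seed integer seed.
#' @return a `regmodel`.
#' @export
random_lvg_model <- function(n_vars, seed = 1L) {
  stopifnot(n_vars >= 2L)
  with_seed(seed, {
    rest <- if (n_vars > 2L) sample(2:n_vars) else 2L
    n_paths <- sample(seq_len(min(3L, length(rest))), 1L)
    cuts <- sort(sample(seq_len(length(rest) - 1L),
                        min(n_paths - 1L, length(rest) - 1L)))
    paths <- split(rest, findInterval(seq_along(rest), cuts + 1L))
    in_edges <- vector("list", n_vars)   # in_edges[[i]]: sources feeding x_i
    for (pth in paths) {
      prev <- 1L
      for (v in pth) { in_edges[[v]] <- c(in_edges[[v]], prev); prev <- v }
      in_edges[[1L]] <- c(in_edges[[1L]], prev)
    }
    rates <- character(n_vars); his <- numeric(n_vars)
    for (i in seq_len(n_vars)) {
      terms <- vapply(in_edges[[i]], function(j)
        random_hill_term(sprintf("x%d", j)), character(1L))
      d <- round(runif(1, 0.8, 1.5), 3)
      rates[i] <- paste(paste(terms, collapse = " + "),
                        sprintf("- %.3f*x%d", d, i))
      amax <- sum(as.numeric(sub("\\*.*$", "", terms)))
      his[i] <- ceiling(amax / d * 1.5 + 1)
    }
    parse_model(c(
      sprintf("model random_lvg_%d_%d", n_vars, as.integer(seed)),
      sprintf("var x%d in [0, %g] : %s", seq_len(n_vars), his, rates)))
  })
}

#' Built-in model registry
#'
#' @param name one of `"stem_cell"`, `"repressilator"`, `"tryptophan"`,
#'   `"methods_3vertex"`, `"methods_4vertex"`, `"random_lvg"`.
#' @param ... arguments forwarded to the model constructor.
#' @return a `regmodel`.
#' @export
builtin_model <- function(name, ...) {
  switch(name,
         stem_cell = stem_cell_model(...),
         repressilator = repressilator_model(...),
         tryptophan = tryptophan_model(...),
         methods_3vertex = methods_fixture("3vertex", ...),
         methods_4vertex = methods_fixture("4vertex", ...),
         random_lvg = random_lvg_model(...),
         stop("unknown builtin model: ", name))
}

#' @rdname builtin_model
#' @export
list_builtin_models <- function() {
  c("stem_cell", "repressilator", "tryptophan",
    "methods_3vertex", "methods_4vertex", "random_lvg")
}
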