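# Model parsing, evaluation, Jacobians and interaction-graph derivation.

test_that("model parsing validates and round-trips", {
  m <- parse_model(c("model toy",
                     "param a = 1.5",
                     "var x1 in [0, 2] : a - x1"))
  expect_s3_class(m, "regmodel")
  expect_equal(m$vars, "x1")
  expect_equal(m$params, c(a = 1.5))
  m2 <- parse_model(format_model(m))
  expect_equal(format_model(m2), format_model(m))
  expect_equal(eval_rhs(m2, 0.5), eval_rhs(m, 0.5))

  # single linear-decay equation, empty parameter map
  m3 <- parse_model("var x1 in [0, 1] : -x1")
  expect_length(m3$params, 0)
  expect_equal(unname(eval_rhs(m3, 0.3)), -0.3)

  # richer model round-trips losslessly through a file
  sc <- stem_cell_model(0.2, 0.2)
  tf <- withr::local_tempfile(fileext = ".model")
  write_model(sc, tf)
  sc2 <- read_model(tf)
  expect_identical(format_model(sc2), format_model(sc))
  expect_equal(eval_rhs(sc2, rep(0.5, 6)), eval_rhs(sc, rep(0.5, 6)))
})

test_that("parser rejects bad documents with the offender named", {
  expect_error(parse_model("var x1 in [0, 1] : x1 ** y"), "y")
  expect_error(parse_model("var x1 in [0, 1] : log(x1)"), "log")
  expect_error(parse_model("var x1 in [2, 1] : -x1"), "x1")
  expect_error(parse_model("var x1 : -x1"), "var")
  expect_error(parse_model("param a = 1"), "no variables")
  expect_error(regulatory_model("x1", "-x1", bounds = cbind(0, Inf)), "finite")
})

test_that("eval_rhs reproduces printed fixed points of built-in models", {
  sc <- stem_cell_model(0.2, 0.2)
  # printed coordinates are rounded to 2 decimals, hence the loose residual
  expect_lt(max(abs(eval_rhs(sc, c(0.2, 0.81, 0.43, 0.14, 0.86, 1.75)))),
            5e-2)
  sc0 <- stem_cell_model(0, 0)
  expect_equal(unname(eval_rhs(sc0, rep(0, 6))), rep(0, 6))

  rp <- repressilator_model(alpha = 290, alpha0 = 10, beta = 1, n_hill = 2)
  expect_equal(unname(eval_rhs(rp, rep(12, 6))), rep(0, 6))
  # beta rescales only the protein equations, the fixed point is unchanged
  expect_equal(unname(eval_rhs(rp, rep(12, 6), overrides = c(beta = 7))),
               rep(0, 6))

  # the printed coordinates are 2-digit rounded and the tryptophan rates are
  # steep (k4*C3 ~ 58 multiplies x3), so print rounding alone leaves a
  # residual of up to ~0.3 in the x4 balance
  tr <- tryptophan_model()
  expect_lt(max(abs(eval_rhs(tr, c(4.71, 4.82e-5, 0.43, 31.82)))), 0.5)

  expect_error(eval_rhs(sc, c(1, 2)), "length")
  expect_error(eval_rhs(sc, rep(1, 6), overrides = c(zz = 1)), "zz")
})

test_that("symbolic Jacobian matches finite differences and known entries", {
  m1 <- parse_model("var x1 in [0, 1] : -x1")
  expect_equal(eval_jacobian(m1, 0.7), matrix(-1, 1, 1,
               dimnames = list("x1", "x1")))

  rp <- repressilator_model(alpha = 290, alpha0 = 10, beta = 1, n_hill = 2)
  J <- eval_jacobian(rp, rep(12, 6))
  expect_equal(J["m1", "p3"], -2 * 290 * 12 / (1 + 12^2)^2, tolerance = 1e-12)
  expect_equal(unname(abs(J["m1", "p3"])), 0.331, tolerance = 1e-3)

  m4 <- methods_fixture("4vertex", seed = 1)
  set.seed(1)
  for (k in 1:20) {
    x <- m4$bounds[, 1] + runif(4) * (m4$bounds[, 2] - m4$bounds[, 1])
    Js <- eval_jacobian(m4, x)
    Jn <- jacobian_fd(m4, x)
    expect_lt(max(abs(Js - Jn) / pmax(1, abs(Js))), 1e-4)
  }
})

test_that("interaction graphs reproduce the built-in topologies", {
  sc <- stem_cell_model(0.2, 0.2)
  g <- build_igraph(sc)
  ed <- igraph_edge_table(g)
  key <- paste(ed$source, ed$target)
  expect_setequal(key, c("x1 x2", "x3 x2", "x2 x3", "x4 x3", "x2 x4",
                         "x1 x5", "x2 x5", "x3 x5", "x4 x5",
                         "x1 x6", "x2 x6", "x3 x6", "x4 x6"))
  expect_length(g$self_edges, 0)

  rp <- repressilator_model()
  gr <- build_igraph(rp)
  er <- igraph_edge_table(gr)
  expect_equal(nrow(er), 6)
  expect_true(all(er$sign %in% c("+", "-")))  # all cross-edges signed
  expect_length(gr$self_edges, 0)

  tr <- tryptophan_model()
  gt <- build_igraph(tr)
  expect_equal(gt$self_edges, 4L)           # saturable self-regulation of trp
  gts <- build_igraph(tr, self_edges = "strict")
  expect_length(gts$self_edges, 0)          # strict mode: positive only

  # graphs are reproducible and deterministic
  expect_identical(build_igraph(sc, seed = 3L)$edges, build_igraph(sc, seed = 3L)$edges)
})

test_that("decay-form boundedness: rates non-positive at the top of the box", {
  # at the upper corner the synthesis terms are at most the decay flux;
  # equality occurs only on degenerate faces (repressilator: p = m)
  for (m in list(stem_cell_model(0.5, 0.5), repressilator_model(),
                 methods_fixture("3vertex", 2))) {
    expect_true(all(eval_rhs(m, m$bounds[, 2]) < 1e-9))
  }
})

test_that("propose_bounds returns a positively invariant box", {
  m <- parse_model(c("param a = 2",
                     "var x1 in [0, 0.1] : a - x1",
                     "var x2 in [0, 0.1] : 4*x1/(1 + x1) - 2*x2"))
  b <- propose_bounds(m)
  expect_gte(b["x1", 2], 2)               # max r1 / d1 = 2
  expect_gte(b["x2", 2], 1.3)             # ~ max r2 / d2 at the iterated box
  # vector field points inward on the upper faces
  for (i in 1:2) {
    x <- b[, 2]; x[i] <- b[i, 2]
    expect_lt(eval_rhs(m, x)[i], 0)
  }
})
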