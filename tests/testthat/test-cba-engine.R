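# Acyclic solving, circuit closing, characteristics, zeros and full
# fixed-point assembly.

test_that("solve_acyclic reproduces closed-form downstream coordinates", {
  sc <- stem_cell_model(0.2, 0.2)
  g <- build_igraph(sc)
  cov <- scc_circuit_cover(g, c(2L, 3L, 4L))
  ord <- break_circuits(g, cov)
  state <- c(0.2, 0.81, NA, NA, NA, NA)     # u = r1 = 0.2, kappa = 0.81
  sols <- solve_acyclic(sc, ord, state)
  expect_length(sols, 1)
  expect_equal(sols[[1]][4], 0.2 / (1 + 0.81^4), tolerance = 1e-12)
  expect_equal(sols[[1]][4], 0.14, tolerance = 1e-2)

  tr <- tryptophan_model()
  gt <- build_igraph(tr)
  covt <- scc_circuit_cover(gt, 1:4)
  ordt <- break_circuits(gt, covt)
  st <- c(NA, NA, NA, 31.82)
  solt <- solve_acyclic(tr, ordt, st)
  expect_length(solt, 1)
  expect_equal(solt[[1]][1], 4.71, tolerance = 0.01)

  # linear chain: x_p = u exactly
  ch <- parse_model(c("param u = 0.37",
                      "var x1 in [0, 1] : u - x1",
                      "var x2 in [0, 1] : x1 - x2"))
  gch <- build_igraph(ch)
  sch <- solve_acyclic(ch, 1:2, c(NA, NA))
  expect_equal(unname(sch[[1]]), c(0.37, 0.37), tolerance = 1e-14)
})

test_that("bracket scanning finds all roots of a scalar equation", {
  # monotone decreasing f with f(lo) > 0 > f(hi): exactly one root
  set.seed(42)
  for (k in 1:50) {
    a <- runif(1, 0.5, 3); h <- runif(1, 0.5, 2); d <- runif(1, 0.2, 2)
    m <- regulatory_model("x1", sprintf("%.17g - %.17g*x1^3 - %.17g*x1",
                                        a, h, d),
                          bounds = cbind(0, 5))
    sols <- solve_acyclic(m, 1L, NA_real_)
    expect_length(sols, 1)
    r <- sols[[1]][1]
    expect_lt(abs(a - h * r^3 - d * r), 1e-9)
  }
  # cubic-type rate with three roots spawns three branches
  m3 <- parse_model("var x1 in [0, 4] : 3*x1^2/(1 + x1^2) - 0.9*x1")
  sols3 <- solve_acyclic(m3, 1L, NA_real_)
  expect_length(sols3, 3)   # 0 and two positive roots
})

test_that("circuit-characteristics behave as documented on built-ins", {
  sc <- stem_cell_model(0.2, 0.2)
  g <- build_igraph(sc)
  s <- scc_decompose(g)
  cov <- scc_circuit_cover(g, s$components[[2]])
  u <- c(0.2, NA, NA, NA, NA, NA)
  ch <- evaluate_characteristic(sc, g, cov, u,
                                grid = seq(0, 3, length.out = 600))
  expect_length(ch$branches, 1)
  v <- ch$branches[[1]]$values
  expect_true(all(diff(v) < 0))             # monotonically decreasing
  expect_equal(sum(diff(sign(v)) != 0), 1)  # exactly one sign change

  # repressilator: c(kappa) = r(r(r(kappa))) - kappa, independent of beta
  rp <- repressilator_model(alpha = 290, alpha0 = 10, beta = 1, n_hill = 2)
  ch1 <- evaluate_characteristic(rp, overrides = c(beta = 0.1))
  ch2 <- evaluate_characteristic(rp, overrides = c(beta = 10))
  expect_lt(max(abs(ch1$branches[[1]]$values - ch2$branches[[1]]$values),
                na.rm = TRUE), 1e-12)
  r <- function(p) 290 / (1 + p^2) + 10
  expect_equal(ch1$branches[[1]]$values, r(r(r(ch1$grid))) - ch1$grid,
               tolerance = 1e-10)

  # tryptophan: strictly decreasing for all three dilution rates
  tr <- tryptophan_model()
  for (mu in c(0.01, 0.1, 0.2)) {
    cht <- evaluate_characteristic(tr, overrides = c(mu = mu))
    vt <- cht$branches[[1]]$values
    expect_true(all(diff(vt[is.finite(vt)]) < 0), info = paste("mu", mu))
  }
})

test_that("find_zeros locates printed fixed-point coordinates", {
  sc <- stem_cell_model(0.5, 0.5)
  g <- build_igraph(sc)
  s <- scc_decompose(g)
  cov <- scc_circuit_cover(g, s$components[[2]])
  ch <- evaluate_characteristic(sc, g, cov, c(0.5, NA, NA, NA, NA, NA))
  z <- find_zeros(ch)
  expect_equal(nrow(z), 3)
  expect_equal(z$kappa, c(0.20, 0.75, 1.66), tolerance = 0.01)
  expect_lt(max(abs(z$value)), 1e-7)
  expect_true(all(diff(z$kappa) > 0))
  expect_equal(sign(z$slope), c(-1, 1, -1))

  tr <- tryptophan_model()
  cht <- evaluate_characteristic(tr)
  zt <- find_zeros(cht)
  expect_equal(nrow(zt), 1)
  expect_equal(zt$kappa, 31.8, tolerance = 0.1)
})

test_that("tangency candidates are reported where c touches the axis", {
  # c(kappa) = (kappa - 1)^2: no crossing, one tangency near 1
  m <- parse_model("var x1 in [0, 2] : (x1 - 1)^2")
  ch <- evaluate_characteristic(m, grid = seq(0, 2, length.out = 600))
  z <- find_zeros(ch)
  expect_true(any(z$tangent))
  expect_equal(z$kappa[z$tangent][1], 1, tolerance = 1e-3)
  expect_false(any(!z$tangent))
})

test_that("degenerate single-variable characteristic equals the rate", {
  m <- parse_model(c("param mu = 0.4", "var x1 in [0, 1] : mu - x1"))
  ch <- evaluate_characteristic(m, grid = seq(0, 1, length.out = 101))
  expect_equal(ch$branches[[1]]$values, 0.4 - ch$grid, tolerance = 1e-14)
  z <- find_zeros(ch)
  expect_equal(z$kappa, 0.4, tolerance = 1e-9)
})

test_that("close_circuit solves partial characteristics on the 4-vertex fixture", {
  m4 <- methods_fixture("4vertex", seed = 1)
  g4 <- build_igraph(m4)
  cov4 <- scc_circuit_cover(g4, 1:4)
  expect_length(cov4$cover, 2)
  v1 <- cov4$cover[1]; v2 <- cov4$cover[2]
  kappa1 <- mean(m4$bounds[v1, ])
  st <- rep(NA_real_, 4); st[v1] <- kappa1
  sols <- close_circuit(m4, g4, cov4, st, released = 2L)
  expect_gt(length(sols), 0)
  for (b in sols) {
    # released vertex satisfies its implicit equation; downstream too
    f <- eval_rhs(m4, b)
    expect_lt(abs(f[v2]), 1e-8)
    expect_lt(max(abs(f[cov4$complement])), 1e-8)
  }
})

test_that("full assembly reproduces the stem-cell fixed points", {
  rep2 <- assemble_fixed_points(stem_cell_model(0.2, 0.2))
  expect_equal(nrow(rep2$points), 1)
  expect_equal(unname(rep2$points[1, 1:4]), c(0.2, 0.81, 0.43, 0.14),
               tolerance = 0.015)
  expect_lt(max(rep2$residuals), 1e-8)

  rep5 <- assemble_fixed_points(stem_cell_model(0.5, 0.5))
  expect_equal(nrow(rep5$points), 3)
  o <- order(rep5$points[, "x2"])
  expect_equal(unname(rep5$points[o, "x2"]), c(0.20, 0.75, 1.66),
               tolerance = 0.01)
  # provenance records the SCC-2 zero for every point
  for (pr in rep5$provenance) {
    expect_true(any(pr$scc == 2 & pr$is_lvg))
  }
})

test_that("CBA fixed points coincide with a multistart Newton oracle", {
  models <- list(stem_cell_model(0.5, 0.5),
                 repressilator_model(),
                 tryptophan_model())
  for (mi in seq_along(models)) {
    m <- models[[mi]]
    got <- assemble_fixed_points(m)
    want <- oracle_fixed_points(m, n_starts = 150L, seed = mi)
    expect_equal(nrow(got$points), nrow(want), info = paste("model", mi))
    got_o <- got$points[order(got$points[, 1], got$points[, 2]), , drop = FALSE]
    expect_equal(unname(got_o), unname(want), tolerance = 1e-6,
                 info = paste("model", mi))
  }
  for (seed in 1:10) {
    m <- random_lvg_model(2L + (seed %% 4L), seed = seed)
    got <- assemble_fixed_points(m)
    want <- oracle_fixed_points(m, n_starts = 100L, seed = seed)
    got_o <- got$points[order(got$points[, 1], got$points[, 2]), , drop = FALSE]
    expect_equal(nrow(got_o), nrow(want), info = paste("lvg seed", seed))
    expect_equal(unname(got_o), unname(want), tolerance = 1e-6,
                 info = paste("lvg seed", seed))
  }
})

test_that("zeros map to fixed points and back", {
  # every characteristic zero -> residual below tol; every oracle point ->
  # a zero of the SCC characteristic at its leading coordinate
  m <- stem_cell_model(0.5, 0.5)
  g <- build_igraph(m)
  s <- scc_decompose(g)
  cov <- scc_circuit_cover(g, s$components[[2]])
  ch <- evaluate_characteristic(m, g, cov, c(0.5, NA, NA, NA, NA, NA))
  z <- find_zeros(ch)
  sts <- attr(z, "states")
  for (i in seq_len(nrow(z))) {
    f <- eval_rhs(m, ifelse(is.na(sts[[i]]), 0, sts[[i]]))
    expect_lt(max(abs(f[2:4])), 1e-6)
  }
  want <- oracle_fixed_points(m, n_starts = 150L, seed = 5)
  for (i in seq_len(nrow(want)))
    expect_lt(min(abs(z$kappa - want[i, 2])), 1e-6)
})

test_that("zero locations are stable under grid refinement", {
  m <- stem_cell_model(0.5, 0.5)
  g <- build_igraph(m)
  s <- scc_decompose(g)
  cov <- scc_circuit_cover(g, s$components[[2]])
  u <- c(0.5, NA, NA, NA, NA, NA)
  z1 <- find_zeros(evaluate_characteristic(m, g, cov, u,
                                           grid = seq(0, 6, length.out = 601)))
  z2 <- find_zeros(evaluate_characteristic(m, g, cov, u,
                                           grid = seq(0, 6, length.out = 1201)))
  expect_equal(nrow(z1), nrow(z2))
  expect_lt(max(abs(z1$kappa - z2$kappa)), 1e-7)
})
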