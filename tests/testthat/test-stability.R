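# Eigenvalue classification, the determinant-ratio slope identity, and the
# LVG instability criterion.

test_that("eigenvalue classification matches known stability", {
  m1 <- parse_model("var x1 in [0, 1] : -x1")
  cl <- classify_fixed_point(m1, 0)
  expect_equal(cl$eigenvalues, as.complex(-1))
  expect_type(cl$eigenvalues, "complex")
  expect_equal(cl$classification, "asymptotically_stable")

  rep5 <- assemble_fixed_points(stem_cell_model(0.5, 0.5))
  o <- order(rep5$points[, "x2"])
  cls <- vapply(o, function(i)
    classify_fixed_point(stem_cell_model(0.5, 0.5),
                         rep5$points[i, ])$classification, character(1))
  expect_equal(cls, c("asymptotically_stable", "unstable",
                      "asymptotically_stable"))

  tr <- tryptophan_model()
  for (mu in c(0.01, 0.2)) {
    rp <- assemble_fixed_points(tr, overrides = c(mu = mu))
    expect_equal(classify_fixed_point(tr, rp$points[1, ],
                                      overrides = c(mu = mu))$classification,
                 "asymptotically_stable", info = paste("mu", mu))
  }
  rp1 <- assemble_fixed_points(tr, overrides = c(mu = 0.1))
  expect_equal(classify_fixed_point(tr, rp1$points[1, ],
                                    overrides = c(mu = 0.1))$classification,
               "unstable")
})

test_that("slope identity holds on the proof-topology fixtures", {
  # d c / d kappa_1 == det J / det J-without-v1, for any smooth rates and
  # any evaluation point on the characteristic (not only at zeros)
  for (seed in 1:10) {
    for (kind in c("3vertex", "4vertex")) {
      m <- methods_fixture(kind, seed = seed)
      g <- build_igraph(m)
      cov <- scc_circuit_cover(g, seq_len(m$n))
      expect_length(cov$cover, 2)   # not an LVG: two closing steps
      ch <- evaluate_characteristic(m, g, cov,
                                    control = cba_control(n_grid = 41))
      v1 <- ch$leading
      span <- diff(range(ch$grid))
      set.seed(1000 + seed)
      kappas <- runif(10, min(ch$grid) + 0.05 * span,
                      max(ch$grid) - 0.05 * span)
      for (k in kappas) {
        sols <- ch$cfun(k)
        if (!length(sols)) next
        st <- sols[[1]]$state
        fd <- cbnet:::char_slope_fd(ch, k, st, span)
        p1 <- prop1_slope(m, st, v1)
        expect_lt(abs(fd - p1) / max(1, abs(p1)), 1e-5,
                  label = sprintf("%s seed %d kappa %.3f: |fd-ratio|/max(1,|ratio|)",
                                  kind, seed, k))
      }
    }
  }
})

test_that("slope identity matches the refined slope at built-in zeros", {
  cases <- list(
    list(model = stem_cell_model(0.5, 0.5), u = c(0.5, NA, NA, NA, NA, NA),
         scc = c(2L, 3L, 4L)),
    list(model = tryptophan_model(), u = rep(NA_real_, 4), scc = 1:4))
  for (cs in cases) {
    g <- build_igraph(cs$model)
    cov <- scc_circuit_cover(g, cs$scc)
    ch <- evaluate_characteristic(cs$model, g, cov, cs$u)
    z <- find_zeros(ch)
    sts <- attr(z, "states")
    for (i in seq_len(nrow(z))) {
      if (z$tangent[i]) next
      st <- sts[[i]]
      st[is.na(st)] <- 0
      p1 <- prop1_slope(cs$model, st, cov$cover[1], scc_vars = cs$scc)
      expect_lt(abs(z$slope[i] - p1) / max(1, abs(p1)), 1e-5)
    }
  }
})

test_that("repressilator slope equals -1 + (dr/dp)^3, independent of beta", {
  rp <- repressilator_model(alpha = 290, alpha0 = 10, beta = 1, n_hill = 2)
  g <- build_igraph(rp)
  cov <- scc_circuit_cover(g, 1:6)
  x <- rep(12, 6)
  drdp <- -2 * 290 * 12 / (1 + 12^2)^2
  for (beta in c(0.1, 1, 10)) {
    p1 <- prop1_slope(rp, x, cov$cover[1], overrides = c(beta = beta))
    expect_equal(p1, -1 + drdp^3, tolerance = 1e-10,
                 info = paste("beta", beta))
  }
})

test_that("LVG verdicts certify instability and never claim stability", {
  sc <- stem_cell_model(0.5, 0.5)
  rep5 <- assemble_fixed_points(sc)
  st <- stability_report(sc, rep5)
  o <- order(rep5$points[, "x2"])
  expect_equal(st$lvg_verdict[o],
               c("inconclusive", "unstable_by_slope", "inconclusive"))
  expect_gt(st$char_slope[o][2], 0)
  expect_equal(st$classification[o][2], "unstable")

  # unstable tryptophan point has a negative slope: inconclusive, NOT stable
  tr <- tryptophan_model()
  rp1 <- assemble_fixed_points(tr, overrides = c(mu = 0.1))
  st1 <- stability_report(tr, rp1, overrides = c(mu = 0.1))
  expect_equal(st1$classification, "unstable")
  expect_lt(st1$char_slope, 0)
  expect_equal(st1$lvg_verdict, "inconclusive")

  expect_equal(lvg_instability_test(0.5, FALSE), "not_applicable")
  expect_equal(lvg_instability_test(-0.5, TRUE), "inconclusive")
  expect_equal(lvg_instability_test(0.5, TRUE), "unstable_by_slope")
})

test_that("positive-slope verdicts are always confirmed by eigenvalues", {
  models <- c(list(stem_cell_model(0.5, 0.5), stem_cell_model(0.4, 0.4),
                   tryptophan_model()),
              lapply(1:10, function(s) random_lvg_model(2L + (s %% 4L), s)))
  for (mi in seq_along(models)) {
    m <- models[[mi]]
    rp <- assemble_fixed_points(m)
    if (!nrow(rp$points)) next
    st <- stability_report(m, rp)
    for (i in seq_len(nrow(rp$points))) {
      if (st$lvg_verdict[i] == "unstable_by_slope")
        expect_equal(st$classification[i], "unstable",
                     info = sprintf("model %d point %d", mi, i))
    }
  }
})

test_that("reduced Jacobian of an LVG is triangular with negative diagonal", {
  tr <- tryptophan_model()
  rp <- assemble_fixed_points(tr)
  rd <- reduced_determinant_sign(tr, rp$points[1, ], leading = 4L)
  expect_true(rd$consistent)       # det equals the diagonal product
  expect_true(rd$diag_negative)
  expect_equal(rd$sign, (-1)^3)    # n - 1 = 3 decaying directions

  rpm <- repressilator_model(alpha = 290, alpha0 = 10, beta = 2, n_hill = 2)
  g <- build_igraph(rpm)
  cov <- scc_circuit_cover(g, 1:6)
  rd6 <- reduced_determinant_sign(rpm, rep(12, 6), leading = cov$cover[1])
  expect_true(rd6$consistent)
  expect_equal(rd6$det, -2^3, tolerance = 1e-10)  # -beta^3
  expect_equal(rd6$sign, (-1)^5)

  m2 <- parse_model(c("var x1 in [0, 1] : -x1",
                      "var x2 in [0, 1] : x1 - 2*x2",
                      "var x3 in [0, 1] : x2 - x3"))
  rd2 <- reduced_determinant_sign(m2, c(0, 0, 0), leading = 3L)
  expect_equal(rd2$det, 2)         # diag(-1, -2)
  expect_equal(rd2$sign, 1)
})

test_that("repressilator eigenvalues depend on beta, its characteristic does not", {
  # the characteristic is blind to beta while the spectrum is not: max Re
  # lambda climbs toward zero as beta shrinks, yet stays negative at the
  # printed parameter set, so the symmetric point stays linearly stable
  rp <- repressilator_model(alpha = 290, alpha0 = 10, beta = 1, n_hill = 2)
  x <- rep(12, 6)
  mres <- vapply(c(0.01, 0.1, 1, 10), function(b)
    classify_fixed_point(rp, x, overrides = c(beta = b))$max_re, numeric(1))
  expect_true(all(diff(mres) < 0))      # decreasing in beta
  expect_true(all(mres < 0))            # |dr/dp| < 1: stable for every beta
  expect_gt(mres[1], -0.02)             # and approaches 0 as beta -> 0
})
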