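test_that("bracket weights: closed-form special cases", {
  # p = 1 collapses to the classical AB2 pair (3, 1) at every lag
  for (m in c(0L, 1L, 7L, 200L)) {
    w <- ab_weight_pair(m, 0:m, 1)
    expect_equal(w$wA, rep(3, m + 1), tolerance = 1e-14)
    expect_equal(w$wB, rep(1, m + 1), tolerance = 1e-14)
  }
  # n = m: the (m-n)^p terms vanish, leaving (p + 2, 1)
  for (p in c(0.1, 0.5, 0.9, 1)) {
    w <- ab_weight_pair(13, 13, p)
    expect_identical(w$wA, p + 2)
    expect_identical(w$wB, 1)
  }
  # direct evaluation at (m = 1, n = 0, p = 0.5)
  w <- ab_weight_pair(1, 0, 0.5)
  expect_equal(w$wA, 3.5 * sqrt(2) - 4, tolerance = 1e-15)
  expect_equal(w$wB, 2^1.5 - 2.5, tolerance = 1e-15)
  expect_error(ab_weight_pair(2, 3, 0.5), "n <= m")
  expect_error(ab_weight_pair(2, 1, 1.5), "0 < p")
})

test_that("bracket weights are empirically positive over the tested grid", {
  for (p in seq(0.1, 1, by = 0.1)) {
    w <- ab_weight_pair(512, 0:512, p)
    expect_true(all(w$wA > 0))
    expect_true(all(w$wB > 0))
  }
})

test_that("fractal weights: q = 1 inert, power law elsewhere, regularized at 0", {
  expect_identical(fractal_factor(5, 0.1, 1), 1)
  expect_identical(fractal_factor(c(-1, 0, 3, 10), 0.05, 1), rep(1, 4))
  expect_equal(fractal_factor(4, 0.5, 0.5), 2^-0.5, tolerance = 1e-15)
  # first-panel mean of s^{q-1}: l^{q-1}/q for nodes 0 and -1
  expect_equal(fractal_factor(0, 0.1, 0.5), 0.1^-0.5 / 0.5, tolerance = 1e-15)
  expect_identical(fractal_factor(-1, 0.1, 0.5), fractal_factor(0, 0.1, 0.5))
  expect_error(fractal_factor(-2, 0.1, 0.5), ">= -1")
})

test_that("p = q = 1 reduces to the cumulative classical AB2", {
  y0 <- ad_initial_state()
  s1 <- solve_ff(ad_rhs_fn(), y0, step = 0.05, p = 1, q = 1, n_steps = 200,
                 warn_negative = FALSE)
  s2 <- classical_ab2(ad_rhs_fn(), y0, step = 0.05, n_steps = 200)
  expect_true(max_rel_dev(s1$states, s2$states) <= 1e-10)
})

test_that("classical AB2 sanity: zero field, exponential decay", {
  s <- classical_ab2(function(t, y) 0 * y, 7, step = 0.1, n_steps = 20)
  expect_identical(unname(s$states[, 1]), rep(7, 21))
  s <- classical_ab2(function(t, y) -y, 1, step = 0.01, horizon = 1)
  expect_lt(abs(endpoint(s) - exp(-1)), 1e-4)
})

test_that("constant forcing with q = 1 reproduces the power closed form", {
  for (p in c(0.3, 0.7, 1)) {
    s <- solve_ff(function(t, y) 2.5, 3, step = 0.1, p = p, q = 1,
                  n_steps = 60)
    exact <- 3 + 2.5 * s$time^p / gamma(p + 1)
    expect_true(max(abs(s$states[, 1] - exact) / abs(exact)) <= 1e-10)
  }
})

test_that("pair sums are conserved to 1e-12 relative across (p, q)", {
  y0 <- ad_initial_state()
  s0 <- unname(conserved_sums(y0))
  for (p in c(0.75, 1)) for (q in c(0.85, 1)) {
    tr <- solve_ff(ad_rhs_fn(), y0, step = 0.05, p = p, q = q,
                   n_steps = 100, warn_negative = FALSE)
    sums <- conserved_sums(tr$states)
    dev <- max(abs(t(t(sums) - s0)) / rep(s0, each = nrow(sums)))
    expect_lt(dev, 1e-12)
  }
})

test_that("the solver is linear in the initial state", {
  y0 <- ad_initial_state()
  a <- 3.25
  t1 <- solve_ff(ad_rhs_fn(), a * y0, step = 0.1, p = 0.8, q = 0.9,
                 n_steps = 50, warn_negative = FALSE)
  t2 <- solve_ff(ad_rhs_fn(), y0, step = 0.1, p = 0.8, q = 0.9,
                 n_steps = 50, warn_negative = FALSE)
  expect_equal(t1$states, a * t2$states, tolerance = 1e-13)
})

test_that("identical inputs give bit-identical output", {
  y0 <- ad_initial_state()
  a <- solve_ff(ad_rhs_fn(), y0, step = 0.05, p = 0.85, q = 0.75,
                n_steps = 80, warn_negative = FALSE)
  b <- solve_ff(ad_rhs_fn(), y0, step = 0.05, p = 0.85, q = 0.75,
                n_steps = 80, warn_negative = FALSE)
  expect_identical(a$states, b$states)
})

test_that("self-convergence at (0.9, 0.9): halving the step shrinks the error", {
  y0 <- ad_initial_state()
  ref <- fine_grid_reference(ad_rhs_fn(), y0, step = 0.02, p = 0.9, q = 0.9,
                             horizon = 2, l_ref = 0.0025)
  e <- vapply(c(0.02, 0.01), function(l) {
    tr <- solve_ff(ad_rhs_fn(), y0, step = l, p = 0.9, q = 0.9, horizon = 2,
                   warn_negative = FALSE)
    max(abs(endpoint(tr) - endpoint(ref)))
  }, numeric(1))
  expect_gte(e[1] / e[2], 1.8)
})

test_that("degenerate and invalid solver inputs", {
  y0 <- ad_initial_state()
  tr <- solve_ff(ad_rhs_fn(), y0, step = 0.05, p = 1, q = 1, n_steps = 0)
  expect_identical(nrow(tr$states), 1L)
  expect_identical(tr$states[1, ], y0)
  expect_error(solve_ff(ad_rhs_fn(), y0, step = 0.05, p = 0, q = 1,
                        n_steps = 10), "0 < p")
  expect_error(solve_ff(ad_rhs_fn(), y0, step = 0.05, p = 1, q = 1.2,
                        n_steps = 10), "0 < q")
  expect_error(solve_ff(ad_rhs_fn(), c(y0[-7], NA), step = 0.05, p = 1,
                        q = 1, n_steps = 10), "finite")
  # blow-up is reported with the step index
  expect_error(
    solve_ff(function(t, y) 1e300 * y, 1e300, step = 10, p = 1, q = 1,
             n_steps = 5, warn_negative = FALSE),
    "non-finite at step")
})

test_that("a negative excursion triggers exactly one warning", {
  expect_warning(
    solve_ff(function(t, y) -1, 0.1, step = 0.1, p = 1, q = 1, n_steps = 30),
    "negative")
})

test_that("trajectory methods: print, summary, as.data.frame", {
  tr <- solve_ff(ad_rhs_fn(), ad_initial_state(), step = 0.1, p = 1, q = 1,
                 n_steps = 10)
  expect_output(print(tr), "p = 1, q = 1")
  expect_output(print(summary(tr)), "component ranges")
  df <- as.data.frame(tr)
  expect_identical(colnames(df), c("time", "R", "Q", "Abeta", "Ip", "Ia",
                                   "S", "D"))
  expect_identical(nrow(df), 11L)
})
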