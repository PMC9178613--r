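test_that("model evaluation matches the closed-form segments", {
  p <- a30p_params()
  # plateau, then linear continuation, then added quadratic
  expect_equal(md_evaluate(p, p$T_fn0), p$A)
  expect_equal(md_evaluate(p, 0.85), p$A)
  expect_equal(md_evaluate(p, 0.9), p$A + p$B * (0.9 - p$T_fn1))
  expect_equal(md_evaluate(p, 0.959), 0.0348, tolerance = 1e-10)
  expect_equal(md_evaluate(p, 1), 0.12869, tolerance = 1e-10)
  expect_equal(md_evaluate(p, 0.5), 0)  # below onset
  e <- e46k_params()
  # ramp midpoint, jump at the plateau end, anchored value at T_fn2
  mid <- (e$T_fn_onset + e$T_fn0) / 2
  expect_equal(md_evaluate(e, mid), e$A / 2)
  expect_equal(md_evaluate(e, e$T_fn1) - md_evaluate(e, e$T_fn1 - 1e-12),
               e$delta, tolerance = 1e-9)
  expect_equal(md_evaluate(e, 0.959), 0.030, tolerance = 1e-12)
  expect_equal(md_evaluate(e, 1), 0.102, tolerance = 0.002 / 0.102)
})

test_that("the fitted curve is non-decreasing for non-negative amplitudes", {
  set.seed(101)
  grid <- seq(0.7, 1.0, length.out = 400)
  for (i in 1:25) {
    p <- random_std_params()
    expect_true(all(diff(md_evaluate(p, grid)) > -1e-12))
  }
  e <- e46k_params()
  expect_true(all(diff(md_evaluate(e, grid)) > -1e-12))
})

test_that("parameter invariants are enforced", {
  expect_error(md_params(A = 0.01, B = 0.2, C = 10, T_fn0 = 0.9,
                         T_fn1 = 0.85, T_fn2 = 0.95), "ordered")
  expect_error(md_params(A = -0.01, B = 0.2, C = 10, T_fn0 = 0.8,
                         T_fn1 = 0.85, T_fn2 = 0.95), ">= 0")
  expect_error(md_params(A = 0.01, B = 0.2, C = 10, T_fn0 = 0.8,
                         T_fn1 = 0.85, T_fn2 = 1.2), "ordered")
  expect_error(md_series(c(0.8, 0.8, 0.9, 1.0), rep(0, 4)), "increasing")
  expect_error(md_series(c(0.8, 0.9, 1.0), rep(0, 3)), "at least 4")
})

test_that("fitting noise-free model output recovers the generating
           parameters", {
  truth <- a30p_params()
  md <- gen_md(truth, grid = seq(0.80, 1.00, length.out = 40), sigma = 0)
  fit <- md_fit(md)
  expect_lt(fit$rss, 1e-18)
  expect_equal(fit$A, truth$A, tolerance = 1e-8)
  expect_equal(fit$B, truth$B, tolerance = 1e-6)
  expect_equal(fit$C, truth$C, tolerance = 1e-6)
  expect_equal(fit$T_fn1, truth$T_fn1, tolerance = 1e-6)
  expect_equal(fit$T_fn2, truth$T_fn2, tolerance = 1e-6)
  # T_fn0 is identifiable only up to the gap between adjacent grid points
  expect_lt(abs(fit$T_fn0 - truth$T_fn0), 0.006)
})

test_that("fitting noise-free extended output recovers the generating curve", {
  truth <- e46k_params()
  md <- gen_md(truth, grid = seq(0.76, 1.00, length.out = 60), sigma = 0)
  fit <- suppressWarnings(md_fit(md, "extended"))
  expect_lt(fit$rss, 1e-12)
  expect_lt(max(abs(md_evaluate(fit, md$T_fn) - md$n)), 1e-6)
  expect_equal(fit$B1, truth$B1, tolerance = 1e-3)
  expect_equal(fit$B2, truth$B2, tolerance = 1e-3)
  expect_equal(fit$T_fnx, truth$T_fnx, tolerance = 0.006)
})

test_that("fit errors on insufficient data and warns on clamped amplitudes", {
  md <- md_series(seq(0.8, 1, length.out = 6), rep(0.01, 6))
  expect_error(md_fit(md), "too few")
  # a decreasing tail forces a negative slope, which is clamped
  set.seed(7)
  tfn <- seq(0.8, 1, length.out = 30)
  n <- pmax(0.02 - 0.015 * pmax(tfn - 0.9, 0) +
              rnorm(30, sd = 1e-4), 0)
  md2 <- md_series(tfn, n)
  expect_warning(fit <- md_fit(md2), "clamped")
  expect_gte(fit$B, 0)
  expect_gte(fit$C, 0)
})

test_that("differential curves carry the analytic slopes", {
  p <- a30p_params()
  d <- md_differential(p, grid = seq(p$T_fn0, 1, by = 1e-3))
  val_at <- function(x) d$n[which.min(abs(d$T_fn - x))]
  expect_equal(val_at(0.85), 0)                      # plateau
  expect_equal(val_at(0.9), 0.24)                    # linear slope B
  expect_equal(d$n[length(d$n)], 0.24 + 2 * 50 * (1 - 0.959))  # 4.34
  expect_true(all(d$n >= 0))
})

test_that("the trapezoid integral of the differential equals the curve
           increment", {
  # deliberately off-grid breakpoints; grid refinement keeps trapezoid exact
  set.seed(202)
  for (i in 1:10) {
    p <- random_std_params()
    grid <- seq(p$T_fn0, 1, length.out = 10001)  # ~1e-4 spacing, ends at 1
    d <- md_differential(p, grid = grid)
    expect_equal(trapz(d$T_fn, d$n), md_evaluate(p, 1) - p$A,
                 tolerance = 1e-6)
  }
  e <- e46k_params()
  grid <- seq(e$T_fn0, 1, length.out = 10001)
  d1 <- md_differential(e, grid = grid)
  expect_equal(trapz(d1$T_fn, d1$n), md_evaluate(e, 1) - e$A,
               tolerance = 1e-6)
  d0 <- md_differential(e, grid = grid, spike = FALSE)
  expect_equal(trapz(d0$T_fn, d0$n), md_evaluate(e, 1) - e$A - e$delta,
               tolerance = 1e-6)
})

test_that("the extended-variant jump appears as a single-bin spike", {
  e <- e46k_params()
  d <- md_differential(e, grid = seq(e$T_fn0, 1, by = 1e-3))
  w <- attr(d, "spike_width")
  peak <- max(d$n[d$T_fn < e$T_fn2])
  expect_equal(peak, e$B1 + e$delta / w, tolerance = 1e-9)
})

test_that("melting diagrams are classified IDP-like vs globular-like", {
  expect_equal(as.character(md_classify(a30p_params())), "IDP-like")
  expect_equal(as.character(md_classify(e46k_params())), "IDP-like")
  flat <- md_params(A = 0.02, B = 0, C = 0,
                    T_fn0 = 0.80, T_fn1 = 0.95, T_fn2 = 0.99)
  expect_equal(as.character(md_classify(flat)), "globular-like")
  # classification from a raw series goes through the fit
  md <- gen_md(a30p_params(), seed = 5)
  expect_equal(as.character(md_classify(md)), "IDP-like")
})
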