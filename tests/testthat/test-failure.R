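test_that("failure classification applies strict thresholds per criterion", {
  thr <- failure_thresholds()
  z <- classify_failure(fake_measures(), thr)
  expect_false(any(z))
  ## uniform compressive state beyond -30%: only that criterion flags
  m <- fake_measures(e3 = -0.35)
  f <- classify_failure(m, thr)
  expect_true(all(f[, "compressive_strain"]))
  expect_false(any(f[, colnames(f) != "compressive_strain"]))
  ## boundary equality is not flagged (strict inequalities)
  onb <- fake_measures(e1 = 0.30, e3 = -0.30, shear = 0.32, fibril = 0.08,
                       sig1 = 7)
  expect_false(any(classify_failure(onb, thr)))
  ## random fields equal the elementwise brute-force comparison
  set.seed(8)
  r <- fake_measures(e1 = runif(50, 0, 0.6), e3 = -runif(50, 0, 0.6),
                     shear = runif(50, 0, 0.6), fibril = runif(50, 0, 0.2),
                     sig1 = runif(50, 0, 12), n = 50)
  f2 <- classify_failure(r, thr)
  expect_equal(unname(f2[, "tensile_stress"]), unname(r[, "sig1"] > 7))
  expect_equal(unname(f2[, "fibril_strain"]), unname(r[, "fibril"] > 0.08))
  expect_equal(unname(f2[, "tensile_strain"]), unname(r[, "e1"] > 0.30))
  expect_equal(unname(f2[, "compressive_strain"]), unname(r[, "e3"] < -0.30))
  expect_equal(unname(f2[, "shear_strain"]), unname(r[, "shear"] > 0.32))
  expect_error(classify_failure(r[, 1:3], thr), "missing")
})

test_that("each default limit is recovered by bisection on uniform states", {
  ## threshold-transition property: scaling a unit state, the flag switches
  ## exactly once, at the configured limit
  thr <- failure_thresholds()
  recover <- function(make_state) {
    lo <- 0; hi <- 20
    for (i in 1:60) {
      mid <- (lo + hi) / 2
      if (any(classify_failure(make_state(mid), thr))) hi <- mid else lo <- mid
    }
    (lo + hi) / 2
  }
  expect_equal(recover(function(s) fake_measures(e3 = -s)), 0.30,
               tolerance = 1e-6)
  expect_equal(recover(function(s) fake_measures(shear = s)), 0.32,
               tolerance = 1e-6)
  expect_equal(recover(function(s) fake_measures(sig1 = s)), 7,
               tolerance = 1e-6)
  expect_equal(recover(function(s) fake_measures(fibril = s)), 0.08,
               tolerance = 1e-6)
  expect_equal(recover(function(s) fake_measures(e1 = s)), 0.30,
               tolerance = 1e-6)
})

test_that("ROI extrema series honor set inclusion and the limit case", {
  fx <- indent_fix()
  st <- fx$states
  rim <- fx$comp$mesh$nodes[fx$comp$mesh$node_sets$surface[1:4], ]
  big <- roi_max_series(st, rim, radius_mm = 1e6)
  ## radius -> infinity equals the global extrema
  for (s in seq_along(st$times)) {
    m <- st$measures[[s]]
    expect_equal(big$e3[s], min(m[, "e3"]))
    expect_equal(big$shear[s], max(m[, "shear"]))
  }
  ## nested radii: inner extrema are bounded by the outer ones
  inner <- roi_max_series(st, rim, radius_mm = 2)
  outer <- roi_max_series(st, rim, radius_mm = 4)
  expect_true(all(inner$shear <= outer$shear + 1e-12))
  expect_true(all(inner$e3 >= outer$e3 - 1e-12))
  ## single evaluation point: the series is that point's trajectory
  one_pt <- st$qp_coords[17, , drop = FALSE]
  tiny <- roi_max_series(st, one_pt, radius_mm = 1e-6)
  traj <- vapply(seq_along(st$times), function(s) st$measures[[s]][17, "e3"],
                 numeric(1))
  expect_equal(tiny$e3, traj)
  expect_error(roi_max_series(st, rim + 1e4, radius_mm = 0.1), "empty ROI")
})

test_that("exceedance intervals interpolate crossings linearly", {
  s <- seq(0, 100, by = 10)
  expect_equal(nrow(exceedance_intervals(rep(0.1, 11), 0.3, s)), 0)
  full <- exceedance_intervals(rep(0.9, 11), 0.3, s)
  expect_equal(unname(full), cbind(0, 100), ignore_attr = TRUE)
  ## triangle wave crossing once up and once down: analytic endpoints
  tri <- c(0, 0.2, 0.4, 0.6, 0.8, 1.0, 0.8, 0.6, 0.4, 0.2, 0)
  iv <- exceedance_intervals(tri, 0.5, s)
  expect_equal(nrow(iv), 1)
  expect_equal(unname(iv[1, "start"]), 25, tolerance = 1e-10)
  expect_equal(unname(iv[1, "end"]), 75, tolerance = 1e-10)
  ## compressive criterion: exceed means fall below
  ivc <- exceedance_intervals(-tri, -0.5, s, direction = -1)
  expect_equal(unname(ivc), unname(iv), ignore_attr = TRUE)
  ## interval mass matches the integrated indicator within one sample spacing
  set.seed(3)
  w <- cumsum(rnorm(21)); sp <- seq(0, 100, by = 5)
  ivr <- exceedance_intervals(w, 0, sp)
  mass <- if (nrow(ivr)) sum(ivr[, 2] - ivr[, 1]) else 0
  ind <- sum((w > 0)[-1] * diff(sp))
  expect_lt(abs(mass - ind), 5 + 1e-9)
  expect_error(exceedance_intervals(tri, 0.5, rev(s)), "increasing")
})

test_that("scenario comparison reports null differences and exact scalings", {
  fx <- indent_fix()
  st <- fx$states
  ## identical histories: zero differences, fold change one where defined
  cmp <- compare_scenarios(st, st)
  for (d in cmp$differences) expect_lt(max(abs(d)), 1e-6)
  ## doubled history: fold change two everywhere defined
  st2 <- st
  st2$measures <- lapply(st$measures, function(m) {
    if (!is.null(m)) m[, ] <- 2 * m[, ]
    m
  })
  cmp2 <- compare_scenarios(st, st2)
  f <- cmp2$fold_changes[[length(cmp2$fold_changes)]]
  expect_equal(stats::median(f[is.finite(f)], na.rm = TRUE), 2,
               tolerance = 0.05)
  expect_error(compare_scenarios(st, within(unclass(st), times <- times + 1)),
               "time grids")
})
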