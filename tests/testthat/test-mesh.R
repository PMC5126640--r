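test_that("closed-form 3x3 eigenvalues match base eigen()", {
  v <- rand_sym6(200, sd = 0.3, seed = 7)
  expect_equal(cartimech:::eig3_sym(v), eigen_oracle(v), tolerance = 1e-9,
               ignore_attr = TRUE)
})

test_that("point location and interpolation reproduce trilinear fields", {
  comp <- flat_comp()
  mesh <- comp$mesh
  set.seed(2)
  pts <- cbind(runif(20, -4, 4), runif(20, -4, 4), runif(20, -1.6, -0.2))
  loc <- cartimech:::locate_points(mesh, pts)
  f <- function(p) 1 + 2 * p[, 1] - 3 * p[, 2] + 0.5 * p[, 3]
  vals <- cartimech:::interp_at(mesh, loc, matrix(f(mesh$nodes), ncol = 1))
  expect_equal(as.numeric(vals), f(pts), tolerance = 1e-9)
  expect_error(cartimech:::locate_points(mesh, rbind(c(50, 50, 50))),
               "outside")
})

test_that("boundary faces of a generated mesh tile its surface", {
  comp <- flat_comp()
  bf <- cartimech:::boundary_faces(comp$mesh)
  g <- attr(comp$mesh, "grid")
  expected <- 2 * g$nx * g$ny + 2 * g$nz * (g$nx + g$ny)
  expect_equal(nrow(bf), expected)
})

test_that("mesh writers emit parseable plain-text files", {
  comp <- flat_comp()
  tf <- tempfile(fileext = ".vtk")
  write_vtk(comp$mesh, tf, cell_data = list(mat = comp$mesh$material))
  lines <- readLines(tf)
  expect_true(any(grepl("^POINTS", lines)))
  expect_true(any(grepl("^CELLS", lines)))
  expect_true(any(grepl("thickness", lines)))
  ts <- tempfile(fileext = ".stl")
  write_stl(comp$intact_surface, ts)
  expect_true(any(grepl("^solid", readLines(ts, n = 1))))
})

test_that("logarithmic strain reduces to the small-strain tensor", {
  set.seed(4)
  g <- array(rnorm(9 * 10, sd = 1e-5), dim = c(3, 3, 10))
  El <- cartimech:::hencky_voigt(g)
  eps <- cartimech:::sym_voigt(g)
  expect_equal(El, eps, tolerance = 1e-4)
  ## and for a finite uniaxial stretch it gives log(lambda)
  g1 <- array(0, dim = c(3, 3, 1)); g1[3, 3, 1] <- 0.2
  expect_equal(cartimech:::hencky_voigt(g1)[1, 3], log(1.2), tolerance = 1e-12)
})
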