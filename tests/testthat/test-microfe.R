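test_that("element stiffness has the elasticity structure of a hex8 brick", {
  K <- element_stiffness(E = 1000, nu = 0.3, h = 0.0105)
  expect_equal(dim(K), c(24L, 24L))
  expect_equal(K, t(K))
  # exactly six rigid-body modes
  ev <- eigen(K, symmetric = TRUE, only.values = TRUE)$values
  expect_equal(sum(abs(ev) < max(ev) * 1e-10), 6L)
  expect_true(all(ev > -max(ev) * 1e-10))
  # linear in E and in h
  expect_equal(element_stiffness(2000, 0.3, 0.0105), 2 * K)
  expect_equal(element_stiffness(1000, 0.3, 0.021), 2 * K)
  # rigid translation produces no force
  tx <- rep(c(1, 0, 0), 8)
  expect_equal(max(abs(K %*% tx)), 0, tolerance = max(K) * 1e-12)
  expect_error(element_stiffness(-1, 0.3, 0.01), "E")
  expect_error(element_stiffness(1, 0.5, 0.01), "nu")
})

test_that("element stiffness passes the uniform-strain patch test", {
  E <- 5000; nu <- 0.3; h <- 0.0105
  K <- element_stiffness(E, nu, h)
  lambda <- E * nu / ((1 + nu) * (1 - 2 * nu)); mu <- E / (2 * (1 + nu))
  D <- matrix(0, 6, 6); D[1:3, 1:3] <- lambda
  diag(D)[1:3] <- lambda + 2 * mu; diag(D)[4:6] <- mu
  corners <- as.matrix(expand.grid(x = c(0, h), y = c(0, h), z = c(0, h)))
  # a few uniform strain states: uniaxial, volumetric, simple shear
  strains <- list(c(0.01, 0, 0, 0, 0, 0),
                  c(0.01, 0.01, 0.01, 0, 0, 0),
                  c(0, 0, 0, 0.02, 0, 0))
  for (eps in strains) {
    grad <- matrix(c(eps[1], eps[4] / 2, eps[6] / 2,
                     eps[4] / 2, eps[2], eps[5] / 2,
                     eps[6] / 2, eps[5] / 2, eps[3]), 3, 3)
    u <- as.vector(t(corners %*% grad))  # nodal displacements of the field
    energy <- 0.5 * drop(t(u) %*% K %*% u)
    exact <- 0.5 * drop(t(eps) %*% D %*% eps) * h^3
    expect_equal(energy, exact, tolerance = 1e-10)
  }
})

test_that("homogeneous block under roller support matches the closed form", {
  for (shape in list(c(4, 4, 4), c(6, 5, 9), c(16, 16, 16))) {
    blk <- make_homogeneous_block(shape, 500)
    mv <- build_material_volume(blk, cap = "none")
    sol <- solve_microfe(mv, bc_spec(bottom = "roller"))
    E <- 6.545 * 1000  # level 4 of the ladder, in MPa
    A <- prod(shape[1:2]) * 0.0105^2
    expect_equal(sol$f_resultant, E * 0.01 * A, tolerance = 1e-3)
    expect_equal(max(abs(sol$eff_strain - 1e4)) / 1e4, 0, tolerance = 1e-3)
  }
})

test_that("conjugate gradients reproduces a dense direct solve on tiny grids", {
  set.seed(11)
  for (shape in list(c(3, 3, 3), c(6, 6, 6))) {
    E_gpa <- array(exp(runif(prod(shape), log(0.003), log(20))), shape)
    mv <- raw_material_volume(E_gpa, voxel_size = 0.0105, nu = 0.3)
    sol <- solve_microfe(mv, bc_spec(), tol = 1e-10)
    bc <- dense_bcs(shape, 0.0105, 0.01)
    u_dense <- dense_solve(E_gpa * 1000, 0.3, 0.0105, bc$fixed, bc$u_fix)
    u_cg <- as.vector(t(sol$displacement))
    expect_lt(sqrt(sum((u_cg - u_dense)^2)) / sqrt(sum(u_dense^2)), 1e-8)
  }
})

test_that("solution scales linearly with the prescribed displacement", {
  ph <- make_osteotomy_phantom(phantom_spec(shape = c(16, 16, 20),
                                            cortex_radius = 5,
                                            cortex_thickness = 2,
                                            gap_width = 4, strut_radius = 1.2))
  mv <- build_material_volume(ph$volume)
  s1 <- solve_microfe(mv, bc_spec(delta = 0.01), tol = 1e-9)
  s2 <- solve_microfe(mv, bc_spec(delta = 0.02), tol = 1e-9)
  expect_equal(s2$f_resultant / s1$f_resultant, 2, tolerance = 1e-5)
  expect_equal(s2$eff_strain, 2 * s1$eff_strain, tolerance = 1e-4)

  s0 <- solve_microfe(mv, bc_spec(delta = 0))
  expect_equal(max(abs(s0$displacement)), 0)
  expect_equal(max(s0$eff_strain), 0)
  expect_equal(s0$f_resultant, 0)
})

test_that("reaction forces balance between top and bottom faces", {
  ph <- make_osteotomy_phantom(phantom_spec(shape = c(16, 16, 20),
                                            cortex_radius = 5,
                                            cortex_thickness = 2,
                                            gap_width = 4))
  mv <- build_material_volume(ph$volume)
  sol <- solve_microfe(mv, tol = 1e-9)
  expect_lt(abs(sol$f_top + sol$f_bottom) / sol$f_resultant, 1e-6)
})

test_that("a two-material serial stack follows the series-spring solution", {
  # soft layer on a stiff layer, near-zero Poisson ratio so the 1-D series
  # closed form is exact: sigma = delta * L / (L1/E1 + L2/E2)
  shape <- c(4, 4, 8)
  E_gpa <- array(2, shape); E_gpa[, , 5:8] <- 10
  mv <- raw_material_volume(E_gpa, voxel_size = 0.01, nu = 1e-9)
  sol <- solve_microfe(mv, bc_spec(bottom = "roller"), tol = 1e-10)
  L <- 8 * 0.01; dL <- 0.01 * L
  sigma <- dL / ((4 * 0.01) / 2000 + (4 * 0.01) / 10000)
  A <- 16 * 0.01^2
  expect_equal(sol$f_resultant, sigma * A, tolerance = 1e-6)
  # strains partition inversely to moduli, in microstrain
  expect_true(all(abs(sol$eff_strain[, , 1:4] / (sigma / 2000 * 1e6) - 1) < 1e-6))
  expect_true(all(abs(sol$eff_strain[, , 5:8] / (sigma / 10000 * 1e6) - 1) < 1e-6))
})

test_that("mechanically disconnected problems still solve but warn", {
  ph <- make_osteotomy_phantom(phantom_spec(shape = c(16, 16, 20),
                                            cortex_radius = 5,
                                            cortex_thickness = 2, gap_width = 4,
                                            strut_count = 0,
                                            bridge_fraction = 0))
  mv <- build_material_volume(ph$volume)
  expect_warning(sol <- solve_microfe(mv), "load path")
  expect_false(sol$connected)
  expect_gt(sol$f_resultant, 0)  # soft tissue still carries load
})

test_that("strain distributions follow the analysis mask exactly", {
  blk <- make_homogeneous_block(c(4, 4, 6), 500)
  mv <- build_material_volume(blk, cap = "none")
  sol <- solve_microfe(mv, bc_spec(bottom = "roller"), tol = 1e-10)
  full <- array(TRUE, c(4, 4, 6))
  dist <- effective_strain_field(sol, full)
  expect_length(dist$values, 96L)
  expect_lt(max(dist$values) - min(dist$values), 1e-3)

  half <- full; half[, , 1:3] <- FALSE
  expect_length(effective_strain_field(sol, half)$values, 48L)
  empty <- array(FALSE, c(4, 4, 6))
  expect_error(effective_strain_field(sol, empty), "empty")
  expect_error(effective_strain_field(sol, array(TRUE, c(2, 2, 2))), "shape")
})

test_that("boundary-condition specs validate their domain", {
  expect_error(bc_spec(delta = 0.2), "delta")
  expect_error(bc_spec(bottom = "nope"), "arg")
})
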