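small_spec <- function(...) {
  args <- list(shape = c(24, 24, 30), cortex_radius = 8, cortex_thickness = 3,
               gap_width = 6, strut_radius = 1.4)
  override <- list(...)
  args[names(override)] <- override
  do.call(phantom_spec, args)
}

test_that("homogeneous block is constant and validates its inputs", {
  blk <- make_homogeneous_block(c(4, 4, 4), 500, 0.0105)
  expect_equal(dim(blk), c(4L, 4L, 4L))
  expect_true(all(blk$values == 500))
  expect_error(make_homogeneous_block(c(4, 0, 4), 500), "extents")
  expect_error(make_homogeneous_block(c(4, 4, 4), -1), "density")
  expect_error(make_homogeneous_block(c(4, 4, 4), 500, voxel_size = 0),
               "positive")
})

test_that("phantom generation is deterministic in spec and seed", {
  a <- make_osteotomy_phantom(small_spec(seed = 5))
  b <- make_osteotomy_phantom(small_spec(seed = 5))
  expect_identical(a$volume$values, b$volume$values)
  expect_identical(a$masks, b$masks)
  c <- make_osteotomy_phantom(small_spec(seed = 6))
  expect_false(identical(a$volume$values, c$volume$values))
  # generation leaves the caller's RNG stream untouched
  set.seed(99); before <- runif(3)
  set.seed(99); invisible(make_osteotomy_phantom(small_spec()))
  expect_identical(runif(3), before)
})

test_that("tissue masks are disjoint and cover the grid", {
  ph <- make_osteotomy_phantom(small_spec())
  m <- ph$masks
  total <- m$cortex + m$callus + m$background
  expect_true(all(total == 1L))
})

test_that("the osteotomy gap empties the cortex and struts bridge it", {
  # no struts, no bridging: central gap slices hold no cortical bone
  ph0 <- make_osteotomy_phantom(small_spec(strut_count = 0,
                                           bridge_fraction = 0, gap_width = 8))
  gap_slices <- which(apply(ph0$masks$gap, 3, any))
  expect_length(gap_slices, 8L)
  expect_false(any(ph0$masks$cortex[, , gap_slices]))
  bone0 <- ph0$masks$cortex | ph0$masks$callus
  expect_false(reaches_top_26(bone0))

  # three struts make the bone mask 26-connected top to bottom
  ph3 <- make_osteotomy_phantom(small_spec(strut_count = 3,
                                           bridge_fraction = 0))
  bone3 <- ph3$masks$cortex | ph3$masks$callus
  expect_true(reaches_top_26(bone3))
})

test_that("invalid phantom geometry is rejected", {
  expect_error(phantom_spec(shape = c(24, 24, 0)), "extents")
  expect_error(small_spec(strut_radius = 9), "strut radius")
  expect_error(small_spec(gap_width = 40), "fit")
  expect_error(small_spec(callus_density = 300), "395")
  expect_error(small_spec(background_density = 500), "background")
  expect_error(small_spec(bridge_fraction = 1.2), "bridge_fraction")
})

test_that("phantom voxel size keeps the physical segment extent fixed", {
  expect_equal(phantom_spec()$voxel_size, 0.0105 * 300 / 48)
  expect_equal(phantom_spec(shape = c(300, 300, 210))$voxel_size, 0.0105)
})

test_that("healing series are monotone in bone voxel count by mode", {
  base <- small_spec(seed = 21)
  fser <- make_healing_series(healing_series_spec(base, mode = "formation"))
  fcount <- vapply(fser, function(p) sum(p$masks$cortex | p$masks$callus), 0)
  expect_length(fcount, 5L)
  expect_true(all(diff(fcount) >= 0))

  rser <- make_healing_series(
    healing_series_spec(small_spec(seed = 21, bridge_fraction = 0.7),
                        mode = "resorption"))
  rcount <- vapply(rser, function(p) sum(p$masks$cortex | p$masks$callus), 0)
  expect_true(all(diff(rcount) <= 0))

  # shared registration frame and identical noise field across weeks
  expect_identical(dim(fser[[1]]$volume), dim(fser[[5]]$volume))
  wk0 <- fser[[1]]; wk4 <- fser[[5]]
  bg_both <- wk0$masks$background & wk4$masks$background
  expect_identical(wk0$volume$values[bg_both], wk4$volume$values[bg_both])

  expect_error(healing_series_spec(base, n_time = 1), "2 time points")
  expect_error(healing_series_spec(base, mode = "resorption", thinning = 2),
               "consume")
})

test_that("formation thickens callus toward a contiguous bridging wall", {
  fser <- make_healing_series(
    healing_series_spec(small_spec(seed = 8), mode = "formation"))
  gap <- fser[[1]]$masks$gap
  fill <- vapply(fser, function(p) sum(p$masks$callus & gap), 0)
  expect_true(all(diff(fill) >= 0))
  expect_gt(fill[5], 2 * fill[1])
  # masks nest week over week
  for (t in 1:4) {
    expect_true(all(fser[[t]]$masks$callus <= fser[[t + 1]]$masks$callus))
  }
})

test_that("resorption raises strains under constant load week over week", {
  # small grids keep the five solves quick; the pattern mirrors a control
  # limb losing bone while the applied force stays fixed
  rser <- make_healing_series(
    healing_series_spec(phantom_spec(shape = c(32, 32, 40),
                                     cortex_radius = 10,
                                     cortex_thickness = 4,
                                     gap_width = 6, bridge_fraction = 0.7,
                                     seed = 31),
                        mode = "resorption", bridging_rate = 0.1))
  med10 <- vapply(rser, function(ph) {
    mv <- build_material_volume(ph$volume)
    sol <- solve_microfe(mv)
    d <- effective_strain_field(sol, bone_mask(mv))
    median_strain(d) * 10 / sol$f_resultant
  }, 0)
  expect_true(all(diff(med10) > 0))
})

test_that("overloaded-strut phantom honours its risk contract", {
  ov <- overloaded_fixture()
  expect_gt(ov$over_count, 50)
  mask <- bone_mask(ov$material)
  scaled <- ov$solution$eff_strain *
    (ov$reference_load / ov$solution$f_resultant)
  expect_equal(sum(scaled[mask] >= 10000), ov$over_count)
  # a tenth of the reference load is safe: strains scale linearly
  tenth <- ov$solution$eff_strain *
    (ov$reference_load / 10 / ov$solution$f_resultant)
  expect_equal(sum(tenth[mask] >= 10000), 0L)
  # deterministic regeneration
  ov2 <- make_overloaded_strut_phantom(reference_load = ov$reference_load)
  expect_identical(ov$volume$values, ov2$volume$values)
  expect_equal(ov2$over_count, ov$over_count)
})
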