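test_that("strain scaling is exactly linear in the applied force", {
  d <- strain_distribution(c(100, 200, 300), f_resultant = 10)
  expect_equal(scale_strains(d, 10)$values, d$values)
  expect_equal(scale_strains(d, 20)$values, 2 * d$values)
  expect_equal(scale_strains(d, 0)$values, c(0, 0, 0))
  # medians and quantiles transform with the same ratio
  set.seed(4)
  big <- strain_distribution(rlnorm(500, log(500), 0.4), f_resultant = 12)
  sc <- scale_strains(big, 30)
  expect_equal(median(sc$values), median(big$values) * 2.5)
  expect_equal(quantile(sc$values, 0.9), quantile(big$values, 0.9) * 2.5)
  # median 500 at 10 N reaches the 700 target at exactly 14 N
  d5 <- strain_distribution(c(400, 500, 600), f_resultant = 10)
  expect_equal(median(scale_strains(d5, 14)$values), 700)
  expect_error(strain_distribution(c(1, 2), f_resultant = -1), "f_resultant")
  expect_error(scale_strains(d, -3), "f_applied")
})

test_that("target construction pins the median at 700 microstrain", {
  set.seed(7)
  for (sample in list(rlnorm(1001, log(300), 0.6), runif(400, 10, 90),
                      c(1, 2, 3))) {
    tgt <- make_target(sample)
    expect_equal(median(tgt$values), 700)
  }
  # already-at-target samples are unchanged; the operation is idempotent
  at700 <- c(600, 700, 800)
  expect_equal(make_target(at700)$values, at700)
  tgt <- make_target(rlnorm(100, 5, 1))
  expect_equal(make_target(tgt)$values, tgt$values)
  expect_error(make_target(rep(0, 10)), "positive median")
  expect_error(make_target(numeric(0)), "empty")
})

test_that("KS statistic agrees with brute-force ECDF evaluation", {
  expect_equal(ks_statistic(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(ks_statistic(c(1, 2, 3), c(11, 12, 13)), 1)
  expect_equal(ks_statistic(c(1, 2), c(1, 3)), 0.5)
  # cross-check against the stats implementation on tie-free samples
  set.seed(9)
  for (i in 1:5) {
    a <- rnorm(40 + i); b <- rnorm(60, 0.3)
    expect_equal(ks_statistic(a, b),
                 unname(stats::ks.test(a, b)$statistic))
  }
  expect_error(ks_statistic(numeric(0), 1:3), "non-empty")
})

test_that("load matching recovers a known rescaling of the distribution", {
  set.seed(12)
  vals <- rlnorm(3000, log(480), 0.5)
  dist <- strain_distribution(vals, f_resultant = 10)
  target <- make_target(vals * 1.4, target_median = median(vals) * 1.4)
  plan <- match_load(dist, target)
  oracle <- grid_search_load(dist, target, 5, 25)
  expect_equal(plan$f_matched / dist$f_resultant, 1.4, tolerance = 0.01)
  expect_lt(plan$ks, 0.01)
  expect_lte(plan$ks, oracle$ks + 1e-12)
  expect_true(plan$converged)

  # target equal to the distribution itself: the fixed point is F_resultant
  self <- make_target(vals, target_median = median(vals))
  plan0 <- match_load(dist, self)
  expect_equal(plan0$f_matched, 10, tolerance = 0.01)
  expect_lt(plan0$ks, 0.001)
})

test_that("matching against an incompatible shape hits the oracle's D floor", {
  # a degenerate single-valued distribution cannot match a broad target at
  # any force; the best achievable D comes from the grid oracle
  dist <- strain_distribution(rep(500, 400), f_resultant = 10)
  set.seed(5)
  target <- default_target(n = 1000, seed = 5)
  plan <- match_load(dist, target)
  oracle <- grid_search_load(dist, target, 1, 40, n = 4000)
  expect_gte(plan$ks, oracle$ks - 1e-9)
  expect_gt(plan$ks, 0.3)  # far from a distributional match
})

test_that("the evaluated D values equal the grid oracle pointwise", {
  set.seed(2)
  vals <- rlnorm(800, log(600), 0.4)
  dist <- strain_distribution(vals, f_resultant = 8)
  target <- default_target(n = 500, seed = 3)
  plan <- match_load(dist, target)
  recomputed <- vapply(plan$trace$force, function(f) {
    ks_statistic(vals * f / 8, target$values)
  }, 0)
  expect_equal(plan$trace$ks, recomputed)
})

test_that("load menus rank by KS with force tie-breaking", {
  set.seed(13)
  vals <- rlnorm(2000, log(480), 0.5)
  dist <- strain_distribution(vals, f_resultant = 10)
  target <- make_target(vals * 1.4, target_median = median(vals) * 1.4)
  menu <- enumerate_loads(dist, target, c(8, 10, 12, 14))
  expect_equal(menu$force[1], 14)  # the 1.4 x 10 N rescaling wins
  expect_equal(menu$rank, 1:4)
  expect_true(all(diff(menu$ks) >= 0))

  single <- enumerate_loads(dist, target, 9)
  expect_equal(nrow(single), 1L)
  expect_equal(single$rank, 1L)

  # the matched optimum, inserted into a grid, ranks first
  plan <- match_load(dist, target)
  menu2 <- enumerate_loads(dist, target, c(5, plan$f_matched, 30))
  expect_equal(menu2$force[1], plan$f_matched)
  expect_error(enumerate_loads(dist, target, numeric(0)), "non-empty")
  expect_error(enumerate_loads(dist, target, c(2, -1)), "positive")
})

test_that("fracture guard walks down in fixed decrements until safe", {
  # engineered field: counts 200 @ 10 N, 120 @ 8 N, 60 @ 6 N, 30 @ 4 N
  # (value v is over threshold at force F iff v * F / 10 >= 10000)
  vals <- c(rep(10000, 80), rep(12600, 60), rep(16700, 30),
            rep(26000, 30), rep(100, 800))
  expect_equal(sum(vals >= 10000), 200)
  expect_equal(sum(vals * 0.8 >= 10000), 120)
  expect_equal(sum(vals * 0.6 >= 10000), 60)
  expect_equal(sum(vals * 0.4 >= 10000), 30)
  dist <- strain_distribution(vals, f_resultant = 10)
  plan <- new_plan_at(10)
  out <- fracture_guard(dist, plan)
  expect_equal(out$guard_trace$force, c(10, 8, 6, 4))
  expect_equal(out$guard_trace$count, c(200L, 120L, 60L, 30L))
  expect_equal(out$f_final, 4)
  expect_true(out$guard_ok)
  # successive trial loads differ by exactly the 2 N actuator step
  expect_equal(unique(diff(out$guard_trace$force)), -2)

  # an initially safe load is left untouched, trace length 1
  safe <- strain_distribution(rep(100, 1000), f_resultant = 10)
  out2 <- fracture_guard(safe, new_plan_at(10))
  expect_equal(nrow(out2$guard_trace), 1L)
  expect_equal(out2$f_final, 10)

  # unsatisfiable at any positive reachable force: flagged, not clamped
  hot <- strain_distribution(rep(1e6, 100), f_resultant = 10)
  out3 <- fracture_guard(hot, new_plan_at(10))
  expect_false(out3$guard_ok)
  expect_true(is.na(out3$f_final))
  # termination bound: at most ceil(F*/2) + 1 trials
  expect_lte(nrow(out3$guard_trace), ceiling(10 / 2) + 1)
})

test_that("guard counting uses an at-or-above threshold comparison", {
  vals <- c(rep(9999.999, 60), rep(10000, 60))
  dist <- strain_distribution(vals, f_resultant = 10)
  out <- fracture_guard(dist, new_plan_at(10))
  # exactly the 60 voxels at 10,000 count; they stay >= 50 until force drops
  expect_equal(out$guard_trace$count[1], 60L)
})

test_that("a full session on a homogeneous block is a fixed point", {
  # 0.5% compression keeps the uniform state clear of the risk threshold, so
  # matching the block's own distribution must return F_resultant untouched
  bc <- bc_spec(delta = 0.005, bottom = "roller")
  blk <- make_homogeneous_block(c(8, 8, 12), 500, voxel_size = 0.0105 * 300 / 48)
  mv <- build_material_volume(blk, cap = "none")
  sol <- solve_microfe(mv, bc)
  own <- effective_strain_field(sol, bone_mask(mv))
  target <- make_target(own$values, target_median = median(own$values))
  session <- rtfe_session(blk, target, bc = bc)
  expect_equal(session$plan$f_matched, session$dist_sim$f_resultant,
               tolerance = 0.01)
  g <- glance(session)
  expect_s3_class(g, "tbl_df")
  expect_equal(g$median_sim, 5000, tolerance = 1e-3)
  expect_equal(g$guard_steps, 0L)
  expect_equal(g$f_final, g$f_matched)
})

test_that("session glance and tidies expose the plan quantities", {
  ov <- overloaded_fixture()
  dist <- effective_strain_field(ov$solution, bone_mask(ov$material))
  target <- default_target(seed = 2)
  plan <- fracture_guard(dist, match_load(dist, target))
  td <- tidy(plan); gl <- glance(plan)
  expect_equal(nrow(td), nrow(plan$guard_trace))
  expect_equal(gl$f_final, plan$f_final)
  expect_lt(gl$f_final, gl$f_matched)  # the guard had to intervene
  # post-guard over-threshold count sits under the 50-voxel limit
  final_count <- sum(dist$values * gl$f_final / dist$f_applied >= 10000)
  expect_lt(final_count, 50)
})
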