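# small synthetic cohorts keep these tests fast; the full 36-stack,
# 64 x 64 x 8 pipeline is exercised in the acceptance suite

test_that("centre-of-mass alignment recovers known offsets to sub-voxel accuracy", {
  ss <- render_if_stacks(1, d = c(32, 32, 8), noise_sd = 0,
                         max_shift_vox = 0, max_angle_deg = 0,
                         max_log_scale = 0, deform_amplitude_vox = 0,
                         seed = 2)
  truth <- ss$truth
  ctr <- (dim(truth) + 1) / 2
  centered <- orient_and_center(truth)
  expect_lt(max(abs(sigold:::center_of_mass(centered) - ctr)), 0.5)
  # an already-centred stack barely moves: the residual translation is
  # sub-voxel and the pattern is preserved
  again <- orient_and_center(centered)
  expect_lt(max(abs(sigold:::center_of_mass(again) - ctr)), 0.5)
  expect_gt(similarity_score(again, centered), 0.95)
  # a known (dx, dy) offset is undone
  dx <- 3; dy <- -2
  shifted <- warp_stack(centered, sigold:::make_transform(t = c(-dx, -dy, 0)))
  recovered <- orient_and_center(shifted)
  com <- sigold:::center_of_mass(recovered)
  expect_lt(max(abs(com - ctr)), 0.5)
  # two translates of the same pattern coincide after centering
  shifted2 <- warp_stack(centered, sigold:::make_transform(t = c(2, 1, 0)))
  expect_gt(similarity_score(orient_and_center(shifted),
                             orient_and_center(shifted2)), 0.98)
  expect_error(orient_and_center(array(0, c(4, 4, 2))),
               class = "sigold_degenerate_error")
})

test_that("registering a stack to itself returns the identity at score 1", {
  ss <- render_if_stacks(1, d = c(32, 32, 8), seed = 4)
  r <- register(ss$stacks[[1]], ss$stacks[[1]], kind = "affine")
  expect_equal(r$score, 1)
  expect_equal(r$transform$A, diag(3))
  expect_equal(r$transform$t, c(0, 0, 0))
})

test_that("a known affine is recovered to sub-voxel composition error", {
  ss <- render_if_stacks(1, d = c(48, 48, 8), noise_sd = 0,
                         deform_amplitude_vox = 0, seed = 6)
  truth <- ss$truth
  tf_true <- ss$transforms[[1]]
  moving <- ss$stacks[[1]]           # = warp(truth, tf_true), noiseless
  r <- register(moving, truth, kind = "affine", maxit = 500,
                restarts = 5)
  expect_gt(r$score, 0.995)
  # T_true o T_rec must be near-identity wherever the pattern constrains
  # it (foreground voxels; empty corners carry no registration signal)
  d <- dim(truth)
  P <- sigold:::grid_coords(d)
  fg <- as.vector(truth) > 0.1 * max(truth)
  Q <- sigold:::transform_points(
    sigold:::transform_points(P, r$transform, d), tf_true, d)
  expect_lt(max(sqrt(rowSums((Q - P)^2))[fg]), 1)
})

test_that("the deformable stage never scores below affine alone", {
  ss <- render_if_stacks(2, d = c(32, 32, 8), deform_amplitude_vox = 1,
                         seed = 9)
  a <- register(ss$stacks[[1]], ss$truth, kind = "affine")
  ad <- register(ss$stacks[[1]], ss$truth, kind = "affdef")
  expect_gte(ad$score, a$score - 1e-9)
})

test_that("the stored transform explains each rendered stack", {
  ss <- render_if_stacks(2, d = c(32, 32, 8), noise_sd = 0.02, seed = 13)
  for (k in 1:2) {
    # forward: warping the truth with the stored transform reproduces the
    # stack up to the additive noise
    fwd <- warp_stack(ss$truth, ss$transforms[[k]])
    expect_gt(similarity_score(fwd, ss$stacks[[k]]), 0.95)
    # inverse: unwarping the stack recovers the truth pattern
    rec <- warp_stack_inverse(ss$stacks[[k]], ss$transforms[[k]])
    expect_gt(similarity_score(rec, ss$truth), 0.9)
  }
})

test_that("template building is a fixed point on identical stacks", {
  ss <- render_if_stacks(1, d = c(24, 24, 6), seed = 3)
  stacks <- list(a = ss$truth, b = ss$truth, c = ss$truth)
  tm <- build_template(stacks, k_keep = 2,
                       stages = c("affine", "affdef"))
  # every stage reproduces the common (centred) input exactly
  expect_equal(tm$template, orient_and_center(ss$truth))
  expect_true(all(abs(tm$history$score - 1) < 1e-12))
  expect_true(all(vapply(tm$transforms, function(tf) {
    all(tf$A == diag(3)) && all(tf$t == 0)
  }, logical(1))))
})

test_that("the template is invariant under input order at a fixed seed", {
  ss <- render_if_stacks(5, d = c(24, 24, 6), seed = 8)
  tm1 <- build_template(ss$stacks, k_keep = 3, stages = "affine",
                        maxit = 120)
  tm2 <- build_template(rev(ss$stacks), k_keep = 3, stages = "affine",
                        maxit = 120)
  expect_identical(tm1$template, tm2$template)
})

test_that("k_keep larger than the cohort is a parameter error", {
  ss <- render_if_stacks(2, d = c(16, 16, 4), seed = 1)
  expect_error(build_template(ss$stacks, k_keep = 5),
               class = "sigold_parameter_error")
})

test_that("averaging registered cohorts beats single noisy stacks against truth", {
  # noise-only cohorts (no deformation) make the comparison well-posed:
  # registration can exactly undo each stack's affine, so the template's
  # advantage is noise averaging
  wins <- 0
  for (sd in c(5, 11)) {
    ss <- render_if_stacks(8, d = c(40, 40, 8), seed = sd,
                           deform_amplitude_vox = 0, noise_sd = 0.1)
    tm <- build_template(ss$stacks, k_keep = 6,
                         stages = c("affine", "affine"), maxit = 200)
    t_score <- register(tm$template, ss$truth, kind = "affine")$score
    s_score <- max(vapply(ss$stacks, function(s) {
      register(s, ss$truth, kind = "affine")$score
    }, numeric(1)))
    wins <- wins + (t_score > s_score)
  }
  expect_gte(wins, 1)  # majority of the tested seeds
})

test_that("stacks round-trip through multi-page TIFF", {
  ss <- render_if_stacks(1, d = c(16, 16, 4), noise_sd = 0, seed = 5)
  arr <- ss$truth / max(ss$truth)
  path <- withr::local_tempfile(fileext = ".tif")
  write_stack_tiff(arr, path)
  back <- read_stack_tiff(path)
  expect_equal(dim(back), dim(arr))
  expect_equal(back, arr, tolerance = 1e-6)
})
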