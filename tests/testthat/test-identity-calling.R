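test_that("consistent labeling across paired grids confirms an identity", {
  cells <- data.frame(
    antibody = "PDF", run = rep(1:2, each = 2),
    layer = c(10, 11, 60, 61), neurite_id = "n1",
    count = c(2, 0, 3, 0))
  calls <- call_identities(tabulate_gold(cells))
  expect_equal(calls$tier, "confirmed")
  expect_equal(calls$n_runs_hit, 2)
  # single strong run, low total: candidate only
  cells$count <- c(2, 0, 0, 0)
  calls2 <- call_identities(tabulate_gold(cells))
  expect_equal(calls2$tier, "candidate")
  # single strong run but total >= 5: confirmed via the total rule
  cells$count <- c(2, 3, 0, 0)
  calls3 <- call_identities(tabulate_gold(cells))
  expect_equal(calls3$tier, "confirmed")
  # all-zero columns produce no call at all
  cells$count <- 0
  expect_equal(nrow(call_identities(tabulate_gold(cells))), 0)
})

test_that("a DCV-empty partner run yields a flagged candidate, not a miss", {
  cells <- data.frame(
    antibody = "FVa", run = rep(1:2, each = 3),
    layer = c(18:20, 69:71), neurite_id = "n5",
    count = c(2, 0, 0, 0, 0, 0))
  dcv <- tibble::tibble(neurite_id = "n5", section = c(18:20, 69:71),
                        dcv = c(2L, 1L, 3L, 0L, 0L, 0L))
  calls <- call_identities(tabulate_gold(cells), dcv = dcv)
  expect_equal(calls$tier, "candidate")
  expect_true(calls$dcv_absence_false_negative)
  # with a larger first-run total the same pattern is confirmed
  cells$count <- c(2, 2, 1, 0, 0, 0)
  calls2 <- call_identities(tabulate_gold(cells), dcv = dcv)
  expect_equal(calls2$tier, "confirmed")
  expect_true(calls2$dcv_absence_false_negative)
})

test_that("layers outside the design are an integrity error", {
  d <- design_paired_grids(n_sections = 200)
  cells <- data.frame(antibody = "PDF", run = 1, layer = 199,
                      neurite_id = "n1", count = 2)
  expect_error(call_identities(tabulate_gold(cells), design = d),
               class = "sigold_integrity_error")
})

test_that("coexpressing neurites are detected against ground truth", {
  cfg <- noiseless_config(n_neurites = 40, n_synapses = 0, seed = 8)
  ds <- generate_dataset(cfg)
  calls <- call_identities(ds$gold, ds$design)
  co <- detect_coexpression(calls)
  truth <- ds$neurites$id[lengths(ds$neurites$true_peptides) >= 2]
  expect_setequal(co$neurite_id, truth)
  if (nrow(co)) {
    for (k in seq_len(nrow(co))) {
      i <- match(co$neurite_id[k], ds$neurites$id)
      expect_setequal(co$labels[[k]], ds$neurites$true_peptides[[i]])
    }
  }
  # single-label calls alone yield nothing
  single <- dplyr::filter(calls, !neurite_id %in% co$neurite_id)
  expect_equal(nrow(detect_coexpression(single)), 0)
})

test_that("cross-reactive antibody groups are recovered from overlap", {
  # degenerate cases
  mk <- function(df) {
    structure(tibble::as_tibble(df), class = c("sigold_calls",
                                               class(tibble::tibble())))
  }
  same <- mk(data.frame(neurite_id = rep(c("a", "b"), 2),
                        antibody = rep(c("X", "Y"), each = 2),
                        tier = "confirmed"))
  expect_equal(flag_crossreactive_groups(same), list(c("X", "Y")))
  disjoint <- mk(data.frame(neurite_id = c("a", "b"),
                            antibody = c("X", "Y"), tier = "confirmed"))
  expect_equal(flag_crossreactive_groups(disjoint), list())
  # a seeded RFamide-like recognition block is recovered as one group
  block <- c("FMRFa", "LUQ", "RYa")
  cfg <- noiseless_config(
    n_neurites = 60, n_synapses = 0, seed = 12,
    crossreactivity = crossreactivity_matrix(groups = list(block),
                                             strength = 1))
  ds <- generate_dataset(cfg)
  calls <- call_identities(ds$gold, ds$design)
  groups <- flag_crossreactive_groups(calls, jaccard_min = 0.5)
  expect_true(list(sort(block)) %in% groups ||
                any(vapply(groups, function(g) all(block %in% g),
                           logical(1))))
})

test_that("group flagging is invariant under antibody relabeling", {
  mk <- function(ab) {
    structure(tibble::tibble(
      neurite_id = rep(c("a", "b", "c"), length(ab)),
      antibody = rep(ab, each = 3), tier = "confirmed"),
      class = c("sigold_calls", class(tibble::tibble())))
  }
  g1 <- flag_crossreactive_groups(mk(c("X", "Y", "Z")))
  g2 <- flag_crossreactive_groups(mk(c("Z", "X", "Y")))
  expect_equal(g1, g2)
})

test_that("bilateral symmetry scoring behaves at its extremes and under jitter", {
  mk_calls <- function(ids) {
    structure(tibble::tibble(neurite_id = ids, antibody = "PDF",
                             tier = "confirmed"),
              class = c("sigold_calls", class(tibble::tibble())))
  }
  geom <- tibble::tibble(id = c("L1", "R1", "L2", "R2"),
                         x = c(-4, 4, -7, 7), y = c(1, 1, -2, -2))
  expect_equal(bilateral_symmetry_score(mk_calls(geom$id), geom), 1)
  expect_equal(bilateral_symmetry_score(mk_calls(c("L1", "L2")), geom), 0)
  expect_error(bilateral_symmetry_score(mk_calls(geom$id), geom,
                                        midline_x = NA),
               class = "sigold_geometry_error")
  # invariance under y-translation and whole-dataset reflection
  s0 <- bilateral_symmetry_score(mk_calls(geom$id), geom)
  expect_equal(bilateral_symmetry_score(
    mk_calls(geom$id), dplyr::mutate(geom, y = y + 13)), s0)
  expect_equal(bilateral_symmetry_score(
    mk_calls(geom$id), dplyr::mutate(geom, x = -x)), s0)
  # mirrored layout with 0.3 um jitter at 1 um radius stays >= 0.9
  withr::with_seed(21, {
    n <- 40
    base <- tibble::tibble(x = runif(n, 1, 10), y = runif(n, -5, 5))
    jit <- tibble::tibble(
      id = c(paste0("L", 1:n), paste0("R", 1:n)),
      x = c(-base$x, base$x) + rnorm(2 * n, 0, 0.3),
      y = rep(base$y, 2) + rnorm(2 * n, 0, 0.3))
    expect_gte(bilateral_symmetry_score(mk_calls(jit$id), jit,
                                        radius_um = 1), 0.9)
  })
})

test_that("design evaluation is exact in the noiseless limit and needs replicates", {
  cfg <- noiseless_config(n_neurites = 30, n_synapses = 0, seed = 5)
  ev <- evaluate_design(cfg, n_replicates = 3, seed = 5)
  expect_equal(ev$precision, 1)
  expect_equal(ev$recall, 1)
  expect_error(evaluate_design(cfg, n_replicates = 1),
               class = "sigold_parameter_error")
})

test_that("skimpier designs lose recall at matched simulation parameters", {
  cfg <- sim_config(n_neurites = 120, n_synapses = 0,
                    enhancement_prob = 0.35, gold_per_dcv = 0.5)
  grid <- tibble::tibble(runs_per_antibody = c(1, 2),
                         sections_per_run = c(1, 5))
  ev <- evaluate_design(cfg, grid, n_replicates = 6, seed = 31)
  expect_lt(ev$recall[ev$sections_per_run == 1],
            ev$recall[ev$sections_per_run == 5])
  # background-free data keeps precision at 1 across designs
  cfg0 <- sim_config(n_neurites = 60, n_synapses = 0,
                     background_rate = 0)
  ev0 <- evaluate_design(cfg0, grid, n_replicates = 3, seed = 13)
  expect_true(all(ev0$precision == 1))
})
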