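test_that("tabulation conserves totals and rejects duplicate cells", {
  tab <- tabulate_gold(data.frame(antibody = "PDF", layer = 703,
                                  neurite_id = "n1", count = 7))
  expect_equal(gold_row_totals(tab)$total, 7)
  expect_equal(gold_col_totals(tab)$total, 7)
  expect_error(
    tabulate_gold(data.frame(antibody = "PDF", layer = c(703, 703),
                             neurite_id = "n1", count = c(1, 2))),
    class = "sigold_integrity_error")
  expect_error(
    tabulate_gold(data.frame(antibody = "PDF", layer = 703, count = 1)),
    class = "sigold_integrity_error")
})

test_that("grand total via rows equals grand total via columns", {
  withr::with_seed(5, {
    for (i in 1:5) {
      tab <- tabulate_gold(random_gold_cells())
      expect_equal(sum(gold_row_totals(tab)$total),
                   sum(gold_col_totals(tab)$total))
      expect_equal(sum(gold_row_totals(tab)$total), sum(tab$count))
    }
  })
})

test_that("the packaged PDF / nuchal-organ fixture matches its printed source", {
  tab <- load_table2_fixture()
  expect_equal(dplyr::n_distinct(tab$neurite_id), 35)
  expect_equal(sort(unique(tab$layer)), c(703L, 723L, 787L))
  col <- function(id) {
    dplyr::arrange(dplyr::filter(tab, neurite_id == id), layer)$count
  }
  expect_equal(col("l6"), c(0L, 3L, 10L))
  expect_equal(col("l1"), c(0L, 0L, 0L))
  expect_equal(col("r4"), c(0L, 0L, 7L))
  expect_equal(col("l13"), c(9L, 9L, 6L))
  # the run-on printed cell is flagged, not silently asserted
  expect_true("l14" %in% attr(tab, "ambiguous_neurons"))
})

test_that("candidate selection applies the >= 2 gold rule with witnesses", {
  tab <- tabulate_gold(data.frame(
    antibody = "FVa", layer = 0:2, neurite_id = "n1",
    count = c(0, 0, 1)))
  expect_equal(nrow(select_candidates(tab)), 0)
  fix <- load_table2_fixture()
  cand <- select_candidates(fix, min_gold = 2)
  expect_true(all(c("l13", "l6", "r4", "l2") %in% cand$neurite_id))
  expect_false(any(c("l1", "r2", "l3") %in% cand$neurite_id))
  l13 <- cand$witnesses[[match("l13", cand$neurite_id)]]
  expect_equal(sort(l13$layer), c(703L, 723L, 787L))
  expect_error(select_candidates(fix, min_gold = 0),
               class = "sigold_parameter_error")
})

test_that("candidate selection is monotone in the gold threshold", {
  withr::with_seed(9, {
    for (i in 1:5) {
      tab <- tabulate_gold(random_gold_cells(lambda = 2))
      sets <- lapply(1:3, function(m) {
        select_candidates(tab, min_gold = m)$neurite_id
      })
      expect_true(all(sets[[2]] %in% sets[[1]]))
      expect_true(all(sets[[3]] %in% sets[[2]]))
    }
  })
})

test_that("control transects sample per_step nearest unique profiles per step", {
  withr::with_seed(2, {
    pts <- tibble::tibble(id = paste0("n", 1:200),
                          x = runif(200, -18, 18), y = runif(200, -5, 5))
  })
  tr <- sample_control_transect(pts, step_um = 1, per_step = 2,
                                transect = rbind(c(-18, 0), c(18.5, 0)))
  expect_equal(nrow(tr), 2 * 36)
  expect_equal(anyDuplicated(tr$neurite_id), 0)
  expect_equal(nrow(sample_control_transect(pts, per_step = 0)), 0)
  # too few profiles: warn and truncate, never error
  few <- pts[1:3, ]
  expect_warning(
    short <- sample_control_transect(few, per_step = 2,
                                     transect = rbind(c(-18, 0),
                                                      c(18, 0))),
    "truncated")
  expect_equal(nrow(short), 3)
})

test_that("intensity shading is monotone with a reserved zero bin", {
  expect_equal(shade(tibble::tibble(count = c(0, 1, 3, 12)))$shade,
               c(0, 1, 2, 4))
  withr::with_seed(4, counts <- sort(sample(0:30, 20, replace = TRUE)))
  sh <- shade(tibble::tibble(count = counts))$shade
  expect_true(all(diff(sh) >= 0))
  expect_true(all(sh[counts == 0] == 0))
  expect_error(shade(tibble::tibble(count = 1), bins = c(2, 1)),
               class = "sigold_parameter_error")
})

test_that("gold labeling co-occurs with DCVs unless background is present", {
  # crafted violation
  tab <- tabulate_gold(data.frame(antibody = "FVa", layer = 0,
                                  neurite_id = "n1", count = 3))
  dcv <- tibble::tibble(neurite_id = "n1", section = 0L, dcv = 0L)
  cc <- dcv_cooccurrence_check(tab, dcv)
  expect_equal(nrow(cc$violations), 1)
  # missing coverage is an error naming the neurite
  expect_error(
    dcv_cooccurrence_check(tab, dplyr::mutate(dcv, section = 5L)),
    regexp = "n1", class = "sigold_coverage_error")
  # background-free synthetic data can have no violations
  ds <- generate_dataset(small_config(background_rate = 0))
  cc2 <- dcv_cooccurrence_check(ds$gold, ds$dcv)
  expect_equal(nrow(cc2$violations), 0)
})

test_that("a strong run with a DCV-empty partner run is flagged, not a violation", {
  # two runs of three sections ~50 apart: strong labeling in the first,
  # all-zero second run whose sections genuinely lack DCVs
  cells <- data.frame(
    antibody = "FVa", run = rep(1:2, each = 3),
    layer = c(18:20, 69:71), neurite_id = "n5",
    count = c(4, 3, 5, 0, 0, 0))
  tab <- tabulate_gold(cells)
  dcv <- tibble::tibble(neurite_id = "n5",
                        section = c(18:20, 69:71),
                        dcv = c(3L, 2L, 4L, 0L, 0L, 0L))
  cc <- dcv_cooccurrence_check(tab, dcv)
  expect_equal(nrow(cc$violations), 0)
  expect_equal(cc$dcv_absence_false_negatives$neurite_id, "n5")
  expect_equal(cc$dcv_absence_false_negatives$runs[[1]], 2L)
})
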