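#' Call molecular identities from a gold table
#'
#' Applies the rule-based identity assignment used for serial-multiplex
#' immunogold data. Per neurite x antibody:
#'
#' * **candidate** if any scored cell carries `>= min_gold` particles
#'   (the tracing-selection rule);
#' * **confirmed** if, in addition, the labeling is consistent: either
#'   `>= min_runs` distinct runs (grids) each contain a cell
#'   `>= min_gold`, or the total gold over all cells is `>= min_total`.
#'
#' Multi-label outcomes are retained: a neurite can be confirmed for
#' several antibodies (coexpression, or cross-reactive antibody groups).
#' When DCV tracks are supplied, candidates whose partner run is all-zero
#' but genuinely lacks DCVs are flagged `dcv_absence_false_negative`
#' rather than being held against the antibody.
#'
#' @param table A [gold_tbl][tabulate_gold].
#' @param design The [labeling design][design_paired_grids]; defaults to
#'   the table's own. Table layers must belong to the design.
#' @param dcv Optional DCV tracks (`neurite_id`, `section`, `dcv`) used for
#'   the false-negative flag.
#' @param min_gold Per-cell threshold (default 2).
#' @param min_runs Distinct strong runs required for confirmation
#'   (default 2).
#' @param min_total Alternative total-gold confirmation threshold
#'   (default 5).
#' @return A tibble of class `sigold_calls`: one row per (neurite,
#'   antibody) candidate with `tier`, evidence columns (`max_count`,
#'   `n_runs_hit`, `total_gold`, list-column `witness_layers`) and the
#'   `dcv_absence_false_negative` flag.
#' @export
#' @examples
#' calls <- call_identities(load_table2_fixture())
#' dplyr::filter(calls, tier == "confirmed")$neurite_id
call_identities <- function(table, design = attr(table, "design"),
                            dcv = NULL, min_gold = 2, min_runs = 2,
                            min_total = 5) {
  tab <- as_tibble(table)
  if (!is.null(design)) {
    sec <- design_sections(design)
    bad <- anti_join(distinct(tab, .data$antibody, .data$layer),
                     rename(sec, layer = "section"),
                     by = c("antibody", "layer"))
    if (nrow(bad)) {
      abort("table contains layers not present in the design",
            class = "sigold_integrity_error")
    }
  }
  calls <- tab |>
    group_by(.data$neurite_id, .data$antibody) |>
    summarise(
      max_count = max(.data$count),
      n_runs_hit = dplyr::n_distinct(.data$run[.data$count >= min_gold]),
      total_gold = sum(.data$count),
      witness_layers = list(.data$layer[.data$count >= min_gold]),
      .groups = "drop") |>
    filter(.data$max_count >= min_gold) |>
    mutate(tier = ifelse(.data$n_runs_hit >= min_runs |
                           .data$total_gold >= min_total,
                         "confirmed", "candidate"),
           .after = "antibody")
  calls$dcv_absence_false_negative <- FALSE
  if (!is.null(dcv) && nrow(calls)) {
    cc <- dcv_cooccurrence_check(table, dcv, strong_gold = min_gold)
    fns <- cc$dcv_absence_false_negatives
    key <- paste(calls$neurite_id, calls$antibody)
    calls$dcv_absence_false_negative <-
      key %in% paste(fns$neurite_id, fns$antibody)
  }
  structure(calls, class = c("sigold_calls", class(tibble())),
            min_gold = min_gold, min_runs = min_runs,
            min_total = min_total)
}

#' Detect neuropeptide coexpression
#'
#' Neurites confirmed for two or more antibodies (e.g. FVa + PDF
#' coexpression), grouped by their label set.
#'
#' @param calls A [sigold_calls][call_identities] tibble.
#' @return Tibble with one row per multi-label neurite: `neurite_id`,
#'   list-column `labels`, and the collapsed `label_set` string.
#' @export
detect_coexpression <- function(calls) {
  calls |>
    filter(.data$tier == "confirmed") |>
    group_by(.data$neurite_id) |>
    summarise(labels = list(sort(unique(.data$antibody))),
              .groups = "drop") |>
    filter(lengths(.data$labels) >= 2) |>
    mutate(label_set = purrr::map_chr(.data$labels, paste,
                                      collapse = "+")) |>
    arrange(.data$label_set, .data$neurite_id)
}

#' Flag groups of cross-reactive antibodies
#'
#' Antibodies whose confirmed-positive neurite sets overlap extensively
#' (Jaccard index `>= jaccard_min`) likely recognise overlapping epitopes
#' (e.g. an RFamide-like block). Builds an antibody graph with an edge per
#' high-overlap pair and returns its connected components of size >= 2.
#' Output is invariant under antibody relabeling/order.
#'
#' @param calls A [sigold_calls][call_identities] tibble.
#' @param jaccard_min Minimum Jaccard overlap to draw an edge
#'   (default 0.5).
#' @return List of character vectors, each one group of mutually
#'   overlapping antibodies (sorted; groups ordered by first member).
#' @export
flag_crossreactive_groups <- function(calls, jaccard_min = 0.5) {
  pos <- calls |>
    filter(.data$tier == "confirmed") |>
    distinct(.data$antibody, .data$neurite_id)
  abs <- sort(unique(pos$antibody))
  if (length(abs) < 2) return(list())
  sets <- split(pos$neurite_id, pos$antibody)[abs]
  pairs <- utils::combn(abs, 2)
  jac <- apply(pairs, 2, function(p) {
    a <- sets[[p[1]]]; b <- sets[[p[2]]]
    length(intersect(a, b)) / length(union(a, b))
  })
  keep <- jac >= jaccard_min
  g <- igraph::graph_from_data_frame(
    data.frame(from = pairs[1, keep], to = pairs[2, keep]),
    directed = FALSE, vertices = data.frame(name = abs))
  comp <- igraph::components(g)
  groups <- split(names(comp$membership), comp$membership)
  groups <- purrr::map(groups, sort)
  groups <- groups[lengths(groups) >= 2]
  groups <- unname(groups[order(purrr::map_chr(groups, 1))])
  groups
}

#' Bilateral symmetry of confirmed labeling
#'
#' Labeled peptidergic neuron populations in the ventral nerve cord occur
#' as left/right mirror pairs. The score is the fraction of confirmed
#' (neurite, label) positives whose mirror position about the midline lies
#' within `radius_um` of a *different* neurite confirmed for the same
#' label. It is invariant under global y-translation and under reflecting
#' the whole dataset.
#'
#' @param calls A [sigold_calls][call_identities] tibble.
#' @param geometry Cross-section centroids: a `sigold_dataset` or a tibble
#'   with `id`, `x`, `y` (um).
#' @param radius_um Match radius (default 1 um).
#' @param midline_x The midline plane (default `x = 0`); must be finite.
#' @return Score in \[0, 1\] (NA when there are no confirmed positives).
#' @export
bilateral_symmetry_score <- function(calls, geometry, radius_um = 1,
                                     midline_x = 0) {
  if (!is.numeric(midline_x) || length(midline_x) != 1 ||
      !is.finite(midline_x)) {
    abort("midline is undefined", class = "sigold_geometry_error")
  }
  pts <- if (inherits(geometry, "sigold_dataset")) geometry$neurites
         else as_tibble(geometry)
  pos <- filter(calls, .data$tier == "confirmed")
  if (nrow(pos) == 0) return(NA_real_)
  i <- match(pos$neurite_id, pts$id)
  if (anyNA(i)) {
    abort("geometry is missing confirmed neurites",
          class = "sigold_geometry_error")
  }
  px <- pts$x[i]; py <- pts$y[i]
  hit <- vapply(seq_len(nrow(pos)), function(k) {
    same <- pos$antibody == pos$antibody[k] &
      pos$neurite_id != pos$neurite_id[k]
    if (!any(same)) return(FALSE)
    mx <- 2 * midline_x - px[k]
    any(sqrt((px[same] - mx)^2 + (py[same] - py[k])^2) <= radius_um)
  }, logical(1))
  mean(hit)
}

# Score calls against simulator ground truth using the cognate map:
# an antibody's true-positive set is the neurites expressing a peptide it
# recognises at full strength (S = 1); partially recognised (0 < S < 1)
# hits are cross-reactive and count as neither TP nor FP.
score_calls <- function(calls, neurites, S) {
  conf <- filter(calls, .data$tier == "confirmed")
  cognate_of <- function(a) colnames(S)[S[a, ] == 1]
  partial_of <- function(a) colnames(S)[S[a, ] > 0 & S[a, ] < 1]
  pep <- stats::setNames(neurites$true_peptides, neurites$id)
  truth_pairs <- sum(vapply(rownames(S), function(a) {
    sum(vapply(pep, function(p) any(p %in% cognate_of(a)), logical(1)))
  }, numeric(1)))
  if (nrow(conf)) {
    kind <- vapply(seq_len(nrow(conf)), function(k) {
      a <- conf$antibody[k]
      p <- pep[[conf$neurite_id[k]]]
      if (any(p %in% cognate_of(a))) "tp"
      else if (any(p %in% partial_of(a))) "xr"
      else "fp"
    }, character(1))
  } else {
    kind <- character(0)
  }
  tp <- sum(kind == "tp"); fp <- sum(kind == "fp")
  precision <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  recall <- if (truth_pairs > 0) tp / truth_pairs else NA_real_
  f1 <- if (!is.na(precision) && !is.na(recall) && precision + recall > 0) {
    2 * precision * recall / (precision + recall)
  } else NA_real_
  tibble(tp = tp, fp = fp, n_crossreactive = sum(kind == "xr"),
         n_truth = truth_pairs, precision = precision, recall = recall,
         f1 = f1)
}

#' Power analysis of sparse labeling designs
#'
#' Simulates repeated experiments over a grid of labeling designs and
#' scores the confirmed identity calls against the generator's ground
#' truth (cognate map: see Details of [call_identities()]). Reports mean
#' precision, recall and F1 with Monte-Carlo standard errors, so designs
#' (runs per antibody, sections per run, run spacing) can be compared
#' before committing grids.
#'
#' @param config A [sim_config()] giving the base simulation conditions.
#' @param design_grid Tibble with any of the columns `runs_per_antibody`,
#'   `sections_per_run`, `run_spacing`; one simulated condition per row.
#'   Defaults to the single design in `config`.
#' @param n_replicates Simulated datasets per design (>= 2; SEs are
#'   undefined otherwise).
#' @param seed Root seed; replicate `r` of design `d` uses an independent
#'   child stream, identical across designs so comparisons are paired.
#' @param min_gold,min_runs,min_total Calling thresholds, passed to
#'   [call_identities()].
#' @return A `sigold_design_eval`: tibble with one row per design
#'   (parameters, mean and SE of precision/recall/F1, mean cross-reactive
#'   hits); attribute `replicates` holds the per-replicate scores.
#' @export
evaluate_design <- function(config, design_grid = NULL, n_replicates = 20,
                            seed = 1, min_gold = 2, min_runs = 2,
                            min_total = 5) {
  if (!is_count(n_replicates) || n_replicates < 2) {
    abort("`n_replicates` must be an integer >= 2",
          class = "sigold_parameter_error")
  }
  if (is.null(design_grid)) {
    design_grid <- tibble(runs_per_antibody = config$runs_per_antibody,
                          sections_per_run = config$sections_per_run,
                          run_spacing = config$run_spacing)
  }
  design_grid <- as_tibble(design_grid)
  reps <- purrr::map_dfr(seq_len(nrow(design_grid)), function(d) {
    cfg <- config
    for (f in intersect(names(design_grid),
                        c("runs_per_antibody", "sections_per_run",
                          "run_spacing"))) {
      cfg[[f]] <- as.integer(design_grid[[f]][d])
    }
    purrr::map_dfr(seq_len(n_replicates), function(r) {
      cfg$seed <- child_seed(seed, "rep", r)
      ds <- generate_dataset(validate_config(cfg))
      calls <- call_identities(ds$gold, ds$design, dcv = ds$dcv,
                               min_gold = min_gold, min_runs = min_runs,
                               min_total = min_total)
      bind_cols(design_grid[d, ], tibble(design = d, replicate = r),
                score_calls(calls, ds$neurites, cfg$crossreactivity))
    })
  })
  se <- function(x) stats::sd(x, na.rm = TRUE) / sqrt(sum(!is.na(x)))
  summ <- reps |>
    group_by(across(any_of(c("design", "runs_per_antibody",
                             "sections_per_run", "run_spacing")))) |>
    summarise(
      n_replicates = n(),
      precision_se = se(.data$precision),
      recall_se = se(.data$recall),
      f1_se = se(.data$f1),
      precision = mean(.data$precision, na.rm = TRUE),
      recall = mean(.data$recall, na.rm = TRUE),
      f1 = mean(.data$f1, na.rm = TRUE),
      crossreactive_hits = mean(.data$n_crossreactive),
      .groups = "drop") |>
    relocate("precision", "precision_se", "recall", "recall_se",
             "f1", "f1_se", .after = "n_replicates")
  structure(summ, class = c("sigold_design_eval", class(tibble())),
            replicates = reps, seed = seed)
}
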