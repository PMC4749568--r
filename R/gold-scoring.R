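#' Gold-count tables
#'
#' A `gold_tbl` is a tidy antibody x layer x neurite table of immunogold
#' counts: one row per scored cell, with columns `antibody`, `run` (the
#' grid, i.e. within-antibody run of consecutive sections), `layer`
#' (absolute 0-based section index) and `neurite_id`, `count`. Cells for
#' (neurite, layer) pairs where the neurite does not cross the layer are
#' absent rather than zero, and totals ignore absent cells.
#'
#' @param x For [tabulate_gold()]: a `sigold_dataset`, a `gold_tbl`, or a
#'   data frame of raw cells with at least `antibody`, `layer`,
#'   `neurite_id`, `count` (an optional `run` column defaults to one run
#'   per layer).
#' @param design Optional [design_paired_grids()]-style design used to
#'   order antibodies and attach run structure.
#' @param neurite_order Optional character vector fixing the column
#'   (neurite) order, e.g. by spatial position across the cross-section.
#' @return A `gold_tbl`.
#' @export
#' @examples
#' tab <- tabulate_gold(data.frame(
#'   antibody = "PDF", layer = c(1, 2), neurite_id = "n1", count = c(3, 0)))
#' gold_col_totals(tab)
tabulate_gold <- function(x, design = NULL, neurite_order = NULL) {
  if (inherits(x, "sigold_dataset")) {
    tab <- x$gold
    if (!is.null(neurite_order)) attr(tab, "neurite_order") <- neurite_order
    return(validate_gold_tbl(tab))
  }
  cells <- as_tibble(x)
  need <- c("antibody", "layer", "neurite_id", "count")
  if (!all(need %in% names(cells))) {
    abort(paste("gold cells need columns:", paste(need, collapse = ", ")),
          class = "sigold_integrity_error")
  }
  if (!"run" %in% names(cells)) {
    if (!is.null(design)) {
      sec <- design_sections(design)
      cells <- left_join(cells, rename(sec, layer = "section"),
                         by = c("antibody", "layer"))
      if (anyNA(cells$run)) {
        abort("table layers not covered by the design",
              class = "sigold_integrity_error")
      }
    } else {
      cells <- cells |>
        group_by(.data$antibody) |>
        mutate(run = match(.data$layer, sort(unique(.data$layer)))) |>
        ungroup()
    }
  }
  new_gold_tbl(cells[, c("antibody", "run", "layer", "neurite_id", "count")],
               design = design,
               neurite_order = neurite_order %||% unique(cells$neurite_id))
}

new_gold_tbl <- function(cells, design = NULL, neurite_order = NULL) {
  cells <- as_tibble(cells)
  cells$layer <- as.integer(cells$layer)
  cells$run <- as.integer(cells$run)
  cells$count <- as.integer(cells$count)
  ab_levels <- if (!is.null(design)) unique(design$antibody)
               else unique(cells$antibody)
  cells <- arrange(cells,
                   match(.data$antibody, ab_levels), .data$layer,
                   match(.data$neurite_id,
                         neurite_order %||% unique(cells$neurite_id)))
  validate_gold_tbl(structure(
    cells, class = c("gold_tbl", class(tibble())),
    design = design, neurite_order = neurite_order
  ))
}

validate_gold_tbl <- function(tab) {
  if (any(tab$count < 0)) {
    abort("gold counts must be non-negative",
          class = "sigold_integrity_error")
  }
  key <- paste(tab$antibody, tab$layer, tab$neurite_id)
  if (anyDuplicated(key)) {
    abort("duplicate (antibody, layer, neurite) cell",
          class = "sigold_integrity_error")
  }
  tab
}

#' @rdname tabulate_gold
#' @param table A `gold_tbl`.
#' @export
gold_row_totals <- function(table) {
  table |>
    group_by(.data$antibody, .data$layer) |>
    summarise(total = sum(.data$count), .groups = "drop")
}

#' @rdname tabulate_gold
#' @export
gold_col_totals <- function(table) {
  table |>
    group_by(.data$neurite_id) |>
    summarise(total = sum(.data$count), n_layers = n(), .groups = "drop")
}

#' @rdname tabulate_gold
#' @export
gold_antibody_totals <- function(table) {
  table |>
    group_by(.data$antibody) |>
    summarise(total = sum(.data$count),
              n_layers = dplyr::n_distinct(.data$layer), .groups = "drop")
}

#' @rdname tabulate_gold
#' @export
gold_matrix <- function(table) {
  wide <- table |>
    mutate(row = paste(.data$antibody, .data$layer, sep = ":")) |>
    select("row", "neurite_id", "count") |>
    tidyr::pivot_wider(names_from = "neurite_id", values_from = "count")
  m <- as.matrix(wide[, -1])
  rownames(m) <- wide$row
  ord <- attr(table, "neurite_order")
  if (!is.null(ord)) m <- m[, intersect(ord, colnames(m)), drop = FALSE]
  m
}

#' Select candidate neurites by the >= 2 gold rule
#'
#' A neurite is a candidate for an identity if any of its scored cells
#' carries at least `min_gold` gold particles in a single immunolabeled
#' section. Candidates are what get traced across the full series.
#'
#' @param table A [gold_tbl][tabulate_gold].
#' @param min_gold Minimum particles in a single cell (default 2).
#' @return Tibble with one row per candidate: `neurite_id`, `max_count`,
#'   `total`, and the list-column `witnesses` holding the witnessing
#'   (antibody, run, layer, count) cells.
#' @export
#' @examples
#' tab <- load_table2_fixture()
#' select_candidates(tab)$neurite_id
select_candidates <- function(table, min_gold = 2) {
  if (!is_count(min_gold) || min_gold < 1) {
    abort("`min_gold` must be an integer >= 1",
          class = "sigold_parameter_error")
  }
  table |>
    group_by(.data$neurite_id) |>
    summarise(
      max_count = max(.data$count),
      total = sum(.data$count),
      witnesses = list(filter(pick("antibody", "run", "layer", "count"),
                              .data$count >= min_gold)),
      .groups = "drop") |>
    filter(.data$max_count >= min_gold)
}

#' Sample control neurite profiles along a transect
#'
#' Emulates unbiased control sampling: a transect is walked across the
#' cross-section in `step_um` increments and at each step the `per_step`
#' nearest not-yet-sampled neurite profiles are taken as controls. The
#' default transect is the horizontal (coronal) chord through the median
#' `y` of the profile centroids, spanning their full `x` range.
#'
#' @param cross_section A `sigold_dataset` or a tibble of profile centroids
#'   with columns `id`, `x`, `y` (um).
#' @param step_um Sampling step along the transect (default 1 um).
#' @param per_step Profiles sampled per step (default 2).
#' @param transect Optional 2x2 matrix `rbind(start, end)` of um
#'   endpoints.
#' @return A tibble (`transect_sample`) with columns `step`, `neurite_id`,
#'   `dist_um`; attributes `transect`, `step_um`, `per_step`.
#' @export
sample_control_transect <- function(cross_section, step_um = 1,
                                    per_step = 2, transect = NULL) {
  pts <- if (inherits(cross_section, "sigold_dataset")) {
    cross_section$neurites
  } else {
    as_tibble(cross_section)
  }
  empty <- structure(
    tibble(step = integer(), neurite_id = character(), dist_um = numeric()),
    class = c("transect_sample", class(tibble())),
    transect = transect, step_um = step_um, per_step = per_step)
  if (nrow(pts) == 0 || per_step == 0) return(empty)
  if (is.null(transect)) {
    y0 <- stats::median(pts$y)
    transect <- rbind(c(min(pts$x), y0), c(max(pts$x), y0))
  }
  v <- transect[2, ] - transect[1, ]
  len <- sqrt(sum(v^2))
  n_steps <- floor(len / step_um)
  if (n_steps == 0) return(empty)
  u <- v / len
  pool <- pts
  out <- vector("list", n_steps)
  for (s in seq_len(n_steps)) {
    if (nrow(pool) == 0) break
    p <- transect[1, ] + (s - 1) * step_um * u
    k <- min(per_step, nrow(pool))
    if (k < per_step) {
      warn(sprintf("only %d profile(s) left at step %d; sample truncated",
                   k, s))
    }
    d <- sqrt((pool$x - p[1])^2 + (pool$y - p[2])^2)
    pick <- order(d)[seq_len(k)]
    out[[s]] <- tibble(step = s, neurite_id = pool$id[pick],
                       dist_um = d[pick])
    pool <- pool[-pick, ]
  }
  structure(bind_rows(out),
            class = c("transect_sample", class(tibble())),
            transect = transect, step_um = step_um, per_step = per_step)
}

#' Check that gold labeling co-occurs with dense-core vesicles
#'
#' Gold labeling reflects neuropeptide inside DCVs, so (absent background)
#' gold should only appear on sections where the neurite contains DCVs.
#' This check reports every scored cell with `count >= min_gold` but DCV
#' count 0 as a violation, and additionally flags "DCV-absence false
#' negatives": neurite x antibody combinations with strong labeling on one
#' run but an all-zero partner run whose sections genuinely lack DCVs (so
#' the missing signal is explained by vesicle absence, not by the
#' antibody).
#'
#' @param table A [gold_tbl][tabulate_gold].
#' @param dcv DCV tracks: tibble with `neurite_id`, `section`, `dcv`.
#' @param min_gold Count threshold defining a positive cell (default 1 for
#'   violations; the false-negative flag uses `strong_gold`).
#' @param strong_gold Threshold for "strong" labeling (default 2).
#' @return List of class `sigold_cooccurrence` with elements `violations`
#'   (tibble of offending cells), `cooccurrence_fraction` (fraction of
#'   gold-positive cells that have DCVs), and `dcv_absence_false_negatives`
#'   (tibble of flagged neurite x antibody runs).
#' @export
dcv_cooccurrence_check <- function(table, dcv, min_gold = 1,
                                   strong_gold = 2) {
  cells <- left_join(as_tibble(table),
                     rename(as_tibble(dcv), layer = "section"),
                     by = c("neurite_id", "layer"))
  if (anyNA(cells$dcv)) {
    missing <- unique(cells$neurite_id[is.na(cells$dcv)])
    abort(paste("no DCV coverage for neurite(s):",
                paste(missing, collapse = ", ")),
          class = "sigold_coverage_error")
  }
  pos <- filter(cells, .data$count >= min_gold)
  violations <- filter(pos, .data$dcv == 0)
  frac <- if (nrow(pos)) 1 - nrow(violations) / nrow(pos) else NA_real_
  runs <- cells |>
    group_by(.data$neurite_id, .data$antibody, .data$run) |>
    summarise(max_count = max(.data$count), any_dcv = any(.data$dcv > 0),
              .groups = "drop_last") |>
    summarise(
      strong = any(.data$max_count >= strong_gold),
      fn_runs = list(.data$run[.data$max_count == 0 & !.data$any_dcv]),
      .groups = "drop")
  fns <- runs |>
    filter(.data$strong, lengths(.data$fn_runs) > 0) |>
    select("neurite_id", "antibody", runs = "fn_runs")
  structure(list(violations = violations,
                 cooccurrence_fraction = frac,
                 dcv_absence_false_negatives = fns),
            class = "sigold_cooccurrence")
}

#' @export
print.sigold_cooccurrence <- function(x, ...) {
  cat(sprintf("<DCV co-occurrence: %d violation(s); fraction %s; %d DCV-absence false negative(s)>\n",
              nrow(x$violations),
              format(x$cooccurrence_fraction, digits = 3),
              nrow(x$dcv_absence_false_negatives)))
  invisible(x)
}

#' Ordinal intensity shading of gold counts
#'
#' Maps counts to ordinal intensity shades the way published gold tables
#' shade their cells. Shade 0 is reserved for count 0; the default edges
#' give bins \{0\}, \{1\}, \{2-4\}, \{5-9\}, \{>= 10\}.
#'
#' @param table A [gold_tbl][tabulate_gold] (or any tibble with `count`).
#' @param bins Strictly increasing lower bin edges (first edge must be 1).
#' @return The table with an added integer `shade` column, monotone in
#'   `count`.
#' @export
#' @examples
#' shade(tibble::tibble(count = c(0, 1, 3, 12)))$shade
shade <- function(table, bins = c(1, 2, 5, 10)) {
  if (any(diff(bins) <= 0) || bins[1] != 1) {
    abort("`bins` must be strictly increasing lower edges starting at 1",
          class = "sigold_parameter_error")
  }
  mutate(table, shade = findInterval(.data$count, bins))
}
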