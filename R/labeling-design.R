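#' Labeling designs: which sections get which antibody
#'
#' A labeling design assigns one antibody to each short run of consecutive
#' sections (the sections collected on one EM grid). Section indices are
#' 0-based and runs are half-open `[start, end)`. Two generator styles are
#' provided:
#'
#' * `design_paired_grids()` emulates a ventral-nerve-cord series in which
#'   each antibody is applied to two grids of 4-18 consecutive sections
#'   separated by a serial distance of approximately 50 sections.
#' * `design_whole_body()` emulates a whole-body series in which short runs
#'   of 1-6 "set-aside" sections are scattered over thousands of sections.
#'
#' @param antibodies Character vector of antibody names.
#' @param n_sections Total number of sections in the series.
#' @param sections_per_run Run length (sections per grid), 4-18 for
#'   paired-grids.
#' @param run_spacing Target serial distance between the start of an
#'   antibody's consecutive runs (paired-grids). If the antibody block is
#'   longer than the spacing the effective spacing is widened to keep runs
#'   disjoint.
#' @param runs_per_antibody Number of runs per antibody.
#' @return A `sigold_design`: a tibble with columns `antibody`, `run`
#'   (within-antibody run index), `start`, `end` (half-open, 0-based), plus
#'   attributes `style` and `n_sections`.
#' @export
#' @examples
#' d <- design_paired_grids(sigold_antibodies(), n_sections = 200)
#' labeled_section_fraction(d)
design_paired_grids <- function(antibodies = sigold_antibodies(),
                                n_sections = 200,
                                sections_per_run = 5,
                                run_spacing = 50,
                                runs_per_antibody = 2) {
  n_ab <- length(antibodies)
  block <- n_ab * sections_per_run
  spacing_eff <- max(run_spacing, block)
  rows <- tidyr::expand_grid(
    antibody = antibodies,
    run = seq_len(runs_per_antibody)
  )
  i <- match(rows$antibody, antibodies) - 1L
  rows$start <- as.integer(i * sections_per_run +
                             (rows$run - 1L) * spacing_eff)
  rows$end <- rows$start + as.integer(sections_per_run)
  if (max(rows$end) > n_sections) {
    abort(sprintf(
      "design needs %d sections but the series has only %d",
      max(rows$end), n_sections), class = "sigold_range_error")
  }
  new_labeling_design(rows, style = "paired-grids", n_sections = n_sections)
}

#' @rdname design_paired_grids
#' @param run_lengths Integer vector of run lengths (1-6 each); one run per
#'   entry, antibodies assigned cyclically. Defaults to `runs_per_antibody`
#'   runs of `sections_per_run` sections for each antibody.
#' @export
design_whole_body <- function(antibodies = sigold_antibodies(),
                              n_sections = 5056,
                              run_lengths = NULL,
                              runs_per_antibody = 2,
                              sections_per_run = 3) {
  if (is.null(run_lengths)) {
    run_lengths <- rep(sections_per_run, length(antibodies) * runs_per_antibody)
  }
  run_lengths <- as.integer(run_lengths)
  if (any(run_lengths < 1 | run_lengths > 6)) {
    abort("whole-body run lengths must be 1-6 sections",
          class = "sigold_config_error")
  }
  n_runs <- length(run_lengths)
  if (sum(run_lengths) + n_runs > n_sections) {
    abort("runs do not fit in the series", class = "sigold_range_error")
  }
  # spread run starts evenly along the series, keeping runs disjoint
  gap <- (n_sections - sum(run_lengths)) %/% n_runs
  starts <- cumsum(c(0L, run_lengths[-n_runs] + gap))
  ab <- rep(antibodies, length.out = n_runs)
  rows <- tibble(
    antibody = ab,
    start = as.integer(starts),
    end = as.integer(starts + run_lengths)
  ) |>
    arrange(.data$antibody, .data$start) |>
    mutate(run = as.integer(stats::ave(start, antibody,
                                       FUN = seq_along)),
           .after = "antibody")
  new_labeling_design(rows, style = "whole-body", n_sections = n_sections)
}

new_labeling_design <- function(rows, style, n_sections) {
  rows <- as_tibble(rows)[, c("antibody", "run", "start", "end")]
  rows <- arrange(rows, .data$start)
  if (any(rows$start < 0) || any(rows$end > n_sections)) {
    abort("design run outside [0, n_sections)", class = "sigold_range_error")
  }
  if (any(rows$end <= rows$start)) {
    abort("empty design run", class = "sigold_config_error")
  }
  if (nrow(rows) > 1 && any(rows$start[-1] < rows$end[-nrow(rows)])) {
    abort("design runs must be disjoint", class = "sigold_config_error")
  }
  structure(rows, class = c("sigold_design", class(rows)),
            style = style, n_sections = as.integer(n_sections))
}

#' @rdname design_paired_grids
#' @param design A `sigold_design`.
#' @export
labeled_sections <- function(design) {
  sum(design$end - design$start)
}

#' Fraction of the series that is immunolabeled
#'
#' @param design A `sigold_design`.
#' @param n_sections Series length; defaults to the design's own.
#' @return Fraction in \[0, 1\]: labeled sections / total sections.
#' @export
#' @examples
#' d <- design_whole_body(run_lengths = rep(3, 22), n_sections = 1000)
#' labeled_section_fraction(d)
labeled_section_fraction <- function(design,
                                     n_sections = attr(design, "n_sections")) {
  labeled_sections(design) / n_sections
}

# all labeled section indices (0-based), one row per (antibody, run, section)
design_sections <- function(design) {
  tidyr::unnest(
    mutate(as_tibble(design),
           section = purrr::map2(.data$start, .data$end - 1L, seq)),
    "section"
  ) |>
    mutate(section = as.integer(.data$section)) |>
    select("antibody", "run", "section")
}

#' @export
print.sigold_design <- function(x, ...) {
  cat(sprintf("<sigold_design: %s; %d runs over %d antibodies; %d/%d sections labeled>\n",
              attr(x, "style"), nrow(x), length(unique(x$antibody)),
              labeled_sections(x), attr(x, "n_sections")))
  NextMethod()
}
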