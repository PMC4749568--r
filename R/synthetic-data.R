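#' Sample vesicle diameters
#'
#' Draws vesicle diameters from a positive-truncated normal model. The
#' default parameters (mean 63 nm, SD 8.4 nm) describe dense-core vesicles
#' at peptidergic presynapses; clear synaptic vesicles at classical
#' synapses are smaller (default mean 35 nm, SD 5 nm in [sim_config()]).
#'
#' @param n Number of diameters to draw.
#' @param mean,sd Normal parameters in nm before truncation at 0.
#' @return Numeric vector of `n` positive diameters (nm).
#' @export
#' @examples
#' d <- sample_vesicle_diameters(100)
#' mean(d)
sample_vesicle_diameters <- function(n, mean = 63, sd = 8.4) {
  if (n == 0) return(numeric(0))
  d <- stats::rnorm(n, mean, sd)
  while (any(bad <- d <= 0)) {
    d[bad] <- stats::rnorm(sum(bad), mean, sd)
  }
  d
}

# Two-state (off = 0, on = 1) Markov chain over `n` sections.
# p_on = P(off -> on), p_off = P(on -> off); initial state drawn from the
# stationary distribution (all-off when p_on = 0).
markov_on_off <- function(n, p_on, p_off) {
  state <- integer(n)
  if (n == 0) return(state)
  pi_on <- if (p_on + p_off > 0) p_on / (p_on + p_off) else 0
  state[1] <- stats::rbinom(1, 1, pi_on)
  if (n > 1) {
    u <- stats::runif(n - 1)
    for (i in 2:n) {
      state[i] <- if (state[i - 1] == 1) as.integer(u[i - 1] >= p_off)
                  else as.integer(u[i - 1] < p_on)
    }
  }
  state
}

#' Simulate dense-core-vesicle occupancy along a neurite
#'
#' DCVs are non-uniformly ("burstily") distributed along neurites: runs of
#' sections rich in DCVs alternate with runs that completely lack them. The
#' model is a two-state Markov chain over sections (off/on) with Poisson
#' counts (mean `dcv_mean`) in the on state and count 0 in the off state.
#' Zero-run lengths are geometric with parameter `dcv_on_rate`; the
#' long-run mean count is `dcv_on_rate / (dcv_on_rate + dcv_off_rate) *
#' dcv_mean`.
#'
#' @param neurite A one-row neurite tibble (with `id`, `start_section`,
#'   `end_section`) or a single integer giving a section count.
#' @param config A [sim_config()].
#' @param seed Optional seed; if `NULL` the current RNG stream is used.
#' @return Tibble with columns `neurite_id`, `section`, `dcv`.
#' @export
#' @examples
#' trk <- sample_dcv_counts(100, sim_config(), seed = 1)
#' table(trk$dcv == 0)
sample_dcv_counts <- function(neurite, config, seed = NULL) {
  if (is.numeric(neurite) && length(neurite) == 1) {
    id <- "n1"
    sections <- seq_len(neurite) - 1L
  } else {
    stopifnot(nrow(neurite) == 1)
    id <- neurite$id
    sections <- seq(neurite$start_section, neurite$end_section - 1L)
  }
  if (length(sections) == 0) {
    abort("neurite path is empty", class = "sigold_config_error")
  }
  draw <- function() {
    on <- markov_on_off(length(sections), config$dcv_on_rate,
                        config$dcv_off_rate)
    counts <- integer(length(sections))
    counts[on == 1] <- stats::rpois(sum(on), config$dcv_mean)
    counts
  }
  counts <- if (is.null(seed)) draw() else with_seed(seed, draw())
  tibble(neurite_id = id, section = as.integer(sections),
         dcv = as.integer(counts))
}

#' Low-level gold-deposition law
#'
#' The count model behind [deposit_gold()]: on one labeled section, the
#' number of deposited gold particles on a neurite profile is Poisson with
#' rate `alpha * dcv * recognition + background_rate * area`, and each
#' deposited particle is silver-enhanced (hence countable) independently
#' with probability `enhancement_prob`. The observable count is therefore a
#' thinned Poisson with mean
#' `enhancement_prob * (alpha * dcv * recognition + background_rate * area)`.
#'
#' @param n Number of independent replicate sections to draw.
#' @param dcv DCV count on the section (vector recycled against `n`).
#' @param recognition Antibody recognition strength in \[0, 1\].
#' @param area Profile area in um^2 (for the background term).
#' @param alpha Expected gold per DCV at full recognition.
#' @param background_rate Background gold per um^2 per section.
#' @param enhancement_prob Silver-enhancement (detection) probability.
#' @return Integer vector of `n` observed gold counts.
#' @export
#' @examples
#' mean(sample_gold_counts(1e4, dcv = 3, alpha = 2, enhancement_prob = 0.5))
sample_gold_counts <- function(n, dcv, recognition = 1, area = 0,
                               alpha = 1, background_rate = 0,
                               enhancement_prob = 1) {
  rate <- alpha * dcv * recognition + background_rate * area
  raw <- stats::rpois(n, rate)
  as.integer(stats::rbinom(n, raw, enhancement_prob))
}

# Neurite population over the cross-section. Bilateral layouts produce
# mirror pairs about the midline x = 0 that share their ground-truth
# peptide content; per-pair child seeds keep draws stable when the
# population grows.
generate_neurites <- function(config) {
  n <- config$n_neurites
  root <- config$seed
  empty <- tibble(
    id = character(), side = character(), partner_id = character(),
    soma_section = integer(), x = numeric(), y = numeric(),
    area_um2 = numeric(), start_section = integer(),
    end_section = integer(), true_peptides = list()
  )
  if (n == 0) return(empty)

  draw_peptides <- function() {
    if (stats::runif(1) < config$peptidergic_frac) {
      p <- sample(config$antibody_panel, 1)
      if (stats::runif(1) < config$coexpression_prob &&
          length(config$antibody_panel) > 1) {
        p <- c(p, sample(setdiff(config$antibody_panel, p), 1))
      }
      p
    } else {
      character(0)
    }
  }

  if (config$bilateral) {
    n_pairs <- n %/% 2
    rows <- vector("list", n)
    for (k in seq_len(max(n_pairs, 0))) {
      rows[[2 * k - 1]] <- with_seed(child_seed(root, "neurite", k), {
        x <- -stats::runif(1, 0.5, 12)
        y <- stats::runif(1, -5, 5)
        a <- stats::rlnorm(1, log(0.3), 0.4)
        list(x = x, y = y, area = a, peptides = draw_peptides())
      })
    }
    out <- empty
    for (k in seq_len(n_pairs)) {
      b <- rows[[2 * k - 1]]
      idl <- sprintf("n%d", 2 * k - 1)
      idr <- sprintf("n%d", 2 * k)
      out <- bind_rows(out, tibble(
        id = c(idl, idr), side = c("left", "right"),
        partner_id = c(idr, idl), soma_section = NA_integer_,
        x = c(b$x, -b$x), y = b$y, area_um2 = b$area,
        start_section = 0L, end_section = config$n_sections,
        true_peptides = list(b$peptides, b$peptides)
      ))
    }
    if (n %% 2 == 1) {
      b <- with_seed(child_seed(root, "neurite", n_pairs + 1), {
        list(y = stats::runif(1, -5, 5),
             area = stats::rlnorm(1, log(0.3), 0.4),
             peptides = draw_peptides())
      })
      out <- bind_rows(out, tibble(
        id = sprintf("n%d", n), side = "medial", partner_id = NA_character_,
        soma_section = NA_integer_, x = 0, y = b$y, area_um2 = b$area,
        start_section = 0L, end_section = config$n_sections,
        true_peptides = list(b$peptides)
      ))
    }
    out
  } else {
    purrr::map_dfr(seq_len(n), function(k) {
      with_seed(child_seed(root, "neurite", k), {
        tibble(
          id = sprintf("n%d", k),
          side = sample(c("left", "right"), 1),
          partner_id = NA_character_, soma_section = NA_integer_,
          x = stats::runif(1, 0.5, 12) *
            ifelse(stats::runif(1) < 0.5, -1, 1),
          y = stats::runif(1, -5, 5),
          area_um2 = stats::rlnorm(1, log(0.3), 0.4),
          start_section = 0L, end_section = config$n_sections,
          true_peptides = list(draw_peptides())
        )
      })
    })
  }
}

# Per-section neurite path: reference centroid plus iid positional jitter.
generate_paths <- function(neurites, config) {
  if (nrow(neurites) == 0) {
    return(tibble(neurite_id = character(), section = integer(),
                  x = numeric(), y = numeric()))
  }
  purrr::map_dfr(seq_len(nrow(neurites)), function(i) {
    nr <- neurites[i, ]
    with_seed(child_seed(config$seed, "path", i), {
      sec <- seq(nr$start_section, nr$end_section - 1L)
      tibble(
        neurite_id = nr$id, section = as.integer(sec),
        x = nr$x + stats::rnorm(length(sec), 0, config$position_jitter_um),
        y = nr$y + stats::rnorm(length(sec), 0, config$position_jitter_um)
      )
    })
  })
}

# antibody recognition per neurite: max over expressed peptides of S[a, p]
recognition_table <- function(neurites, config) {
  S <- config$crossreactivity
  purrr::map_dfr(seq_len(nrow(neurites)), function(i) {
    pep <- intersect(neurites$true_peptides[[i]], colnames(S))
    rec <- if (length(pep)) apply(S[, pep, drop = FALSE], 1, max)
           else stats::setNames(rep(0, nrow(S)), rownames(S))
    tibble(neurite_id = neurites$id[i],
           antibody = rownames(S), recognition = unname(rec))
  })
}

#' Simulate immunogold deposition over a labeling design
#'
#' For every labeled section `s` (antibody `a`) and every neurite `i`
#' crossing it, the observed gold count follows the thinned-Poisson law of
#' [sample_gold_counts()] with DCV count `D(i, s)`, recognition
#' `max_p S[a, p]` over the neurite's expressed peptides, and an
#' area-proportional background. Sections outside the design are absent
#' from the result (not zero-filled): unlabeled sections carry no gold
#' information.
#'
#' @param dataset A `sigold_dataset` (needs `neurites` and `dcv`).
#' @param design A `sigold_design`; defaults to the dataset's own.
#' @param config A [sim_config()]; defaults to the dataset's own.
#' @param seed Optional seed.
#' @return A [gold_tbl] with one row per (antibody, run, layer, neurite)
#'   cell.
#' @export
deposit_gold <- function(dataset, design = dataset$design,
                         config = dataset$config, seed = NULL) {
  if (max(design$end) > config$n_sections) {
    abort("design references sections outside the stack",
          class = "sigold_range_error")
  }
  neurites <- dataset$neurites
  cells <- design_sections(design)
  if (nrow(neurites) == 0 || nrow(cells) == 0) {
    return(new_gold_tbl(
      tibble(antibody = character(), run = integer(), layer = integer(),
             neurite_id = character(), count = integer()),
      design = design, neurite_order = character()))
  }
  cells <- tidyr::crossing(
    cells,
    neurites |> select("id", "area_um2", "start_section", "end_section")
  ) |>
    filter(.data$section >= .data$start_section,
           .data$section < .data$end_section) |>
    rename(neurite_id = "id")
  missing_dcv <- setdiff(unique(cells$neurite_id),
                         unique(dataset$dcv$neurite_id))
  if (length(missing_dcv)) {
    abort(paste("no DCV track for neurite(s):",
                paste(missing_dcv, collapse = ", ")),
          class = "sigold_coverage_error")
  }
  cells <- cells |>
    left_join(dataset$dcv, by = c("neurite_id", "section")) |>
    left_join(recognition_table(neurites, config),
              by = c("neurite_id", "antibody"))
  draw <- function() {
    sample_gold_counts(
      nrow(cells), dcv = cells$dcv, recognition = cells$recognition,
      area = cells$area_um2, alpha = config$gold_per_dcv,
      background_rate = config$background_rate,
      enhancement_prob = config$enhancement_prob)
  }
  cells$count <- if (is.null(seed)) draw() else with_seed(seed, draw())
  ord <- neurites$id[order(neurites$x, neurites$y)]
  new_gold_tbl(
    cells |>
      transmute(.data$antibody, .data$run, layer = .data$section,
                .data$neurite_id, .data$count),
    design = design, neurite_order = ord)
}

#' Simulate synapse records with vesicle-diameter samples
#'
#' Peptidergic presynapses (originating from neurites that express at least
#' one neuropeptide) contain only dense-core vesicles and sample diameters
#' from the DCV model (default mean 63 nm, SD 8.4 nm); classical
#' presynapses sample from the smaller clear-vesicle model. The side of the
#' postsynaptic profile relative to the midline `x = 0` is recorded.
#'
#' @inheritParams deposit_gold
#' @param n Number of synapses; defaults to `config$n_synapses`.
#' @return Tibble with columns `id`, `pre_neurite_id`, `post_neurite_id`,
#'   `section_index`, `side_of_post`, `vesicle_class_truth`, and the
#'   list-column `vesicle_diameters_nm`.
#' @export
generate_synapses <- function(dataset, config = dataset$config,
                              seed = NULL, n = config$n_synapses) {
  empty <- tibble(
    id = character(), pre_neurite_id = character(),
    post_neurite_id = character(), section_index = integer(),
    side_of_post = character(), vesicle_class_truth = character(),
    vesicle_diameters_nm = list()
  )
  neurites <- dataset$neurites
  if (n == 0 || nrow(neurites) < 2) return(empty)
  draw <- function() {
    pep_ids <- neurites$id[lengths(neurites$true_peptides) > 0]
    n_pep <- if (length(pep_ids)) round(n * config$synapse_peptidergic_frac)
             else 0
    cls <- c(rep("peptidergic", n_pep), rep("classical", n - n_pep))
    pre <- character(n)
    if (n_pep > 0) pre[seq_len(n_pep)] <- sample(pep_ids, n_pep, replace = TRUE)
    nonpep <- setdiff(neurites$id, pep_ids)
    pool <- if (length(nonpep)) nonpep else neurites$id
    if (n - n_pep > 0) {
      pre[seq(n_pep + 1, n)] <- sample(pool, n - n_pep, replace = TRUE)
    }
    post <- vapply(pre, function(p) sample(setdiff(neurites$id, p), 1), "")
    post_x <- neurites$x[match(post, neurites$id)]
    diam <- lapply(cls, function(cl) {
      if (cl == "peptidergic") {
        sample_vesicle_diameters(config$vesicles_per_synapse,
                                 config$vesicle_diam_mean_nm,
                                 config$vesicle_diam_sd_nm)
      } else {
        sample_vesicle_diameters(config$vesicles_per_synapse,
                                 config$clear_diam_mean_nm,
                                 config$clear_diam_sd_nm)
      }
    })
    tibble(
      id = sprintf("s%d", seq_len(n)),
      pre_neurite_id = unname(pre), post_neurite_id = unname(post),
      section_index = sample.int(config$n_sections, n, replace = TRUE) - 1L,
      side_of_post = ifelse(post_x < 0, "left", "right"),
      vesicle_class_truth = cls,
      vesicle_diameters_nm = diam
    )
  }
  if (is.null(seed)) draw() else with_seed(seed, draw())
}

#' Generate a complete synthetic serial-section immunogold dataset
#'
#' Composes the generative models of the package into one reproducible
#' dataset: a bilaterally symmetric neurite population crossing a stack of
#' serial sections, bursty per-section DCV occupancy for peptidergic
#' neurites (all-zero tracks for the rest, which carry no DCVs), a sparse
#' labeling design, thinned-Poisson gold counts on the labeled sections,
#' and synapse records with vesicle-diameter samples. Everything is
#' reproducible from `config$seed`; each component draws from its own
#' child stream.
#'
#' @param config A [sim_config()].
#' @return A `sigold_dataset`: list with elements `config`, `neurites`,
#'   `paths`, `dcv`, `design`, `gold` (a [gold_tbl]) and `synapses`.
#' @export
#' @examples
#' ds <- generate_dataset(sim_config(n_neurites = 20, n_synapses = 10))
#' ds
generate_dataset <- function(config) {
  config <- validate_config(config)
  neurites <- generate_neurites(config)
  paths <- generate_paths(neurites, config)
  dcv <- if (nrow(neurites) == 0) {
    tibble(neurite_id = character(), section = integer(), dcv = integer())
  } else {
    purrr::map_dfr(seq_len(nrow(neurites)), function(i) {
      trk <- if (lengths(neurites$true_peptides)[i] > 0) {
        sample_dcv_counts(neurites[i, ], config,
                          seed = child_seed(config$seed, "dcv", i))
      } else {
        tibble(neurite_id = neurites$id[i],
               section = seq(neurites$start_section[i],
                             neurites$end_section[i] - 1L),
               dcv = 0L)
      }
      trk
    })
  }
  design <- if (config$design_style == "paired-grids") {
    design_paired_grids(config$antibody_panel, config$n_sections,
                        config$sections_per_run, config$run_spacing,
                        config$runs_per_antibody)
  } else {
    design_whole_body(config$antibody_panel, config$n_sections,
                      runs_per_antibody = config$runs_per_antibody,
                      sections_per_run = min(config$sections_per_run, 6L))
  }
  dataset <- structure(
    list(config = config, neurites = neurites, paths = paths, dcv = dcv,
         design = design, gold = NULL, synapses = NULL),
    class = "sigold_dataset"
  )
  dataset$gold <- deposit_gold(dataset, design, config,
                               seed = child_seed(config$seed, "gold"))
  dataset$synapses <- generate_synapses(dataset, config,
                                        seed = child_seed(config$seed,
                                                          "synapses"))
  dataset
}

#' @export
print.sigold_dataset <- function(x, ...) {
  cat("<sigold_dataset>\n")
  cat(sprintf("  %d neurites (%d peptidergic) over %d sections\n",
              nrow(x$neurites), sum(lengths(x$neurites$true_peptides) > 0),
              x$config$n_sections))
  cat(sprintf("  design: %s, %d labeled sections\n",
              attr(x$design, "style"), labeled_sections(x$design)))
  cat(sprintf("  gold cells: %d; synapses: %d\n",
              nrow(x$gold), nrow(x$synapses)))
  invisible(x)
}
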