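#' Packaged gold-count fixture: PDF labeling of nuchal-organ sensory
#' neurons
#'
#' Published gold-particle counts for the 35 nuchal-organ sensory neurons
#' (SNnuch; 20 right-side `r1`-`r20`, 15 left-side `l1`-`l15`) scored in
#' three whole-body sections labeled with the pigment-dispersing-factor
#' (PDF) antibody, at absolute layers 703, 723 and 787. One printed cell
#' (`l14`) is a run-on digit string whose split is ambiguous; it carries
#' an `ambiguous` annotation and should be excluded from exact
#' assertions.
#'
#' @param keep_ambiguous Include cells flagged ambiguous (default `TRUE`;
#'   they remain flagged via the `ambiguous_neurons` attribute).
#' @return A [gold_tbl][tabulate_gold] (antibody `"PDF"`, 3 layers x 35
#'   neurites) with attributes `ambiguous_neurons` and `notes`.
#' @export
#' @examples
#' tab <- load_table2_fixture()
#' dplyr::filter(tab, neurite_id == "l6")$count
load_table2_fixture <- function(keep_ambiguous = TRUE) {
  path <- system.file("extdata", "table2_pdf_gold_snnuch.csv",
                      package = "sigold", mustWork = TRUE)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  long <- raw |>
    tidyr::pivot_longer(dplyr::starts_with("layer_"),
                        names_to = "layer", names_prefix = "layer_",
                        values_to = "count") |>
    mutate(layer = as.integer(.data$layer), antibody = "PDF",
           run = match(.data$layer, sort(unique(.data$layer)))) |>
    rename(neurite_id = "neuron")
  if (!keep_ambiguous) long <- filter(long, !.data$ambiguous)
  tab <- new_gold_tbl(
    long[, c("antibody", "run", "layer", "neurite_id", "count")],
    neurite_order = raw$neuron)
  attr(tab, "ambiguous_neurons") <- raw$neuron[raw$ambiguous]
  attr(tab, "notes") <- stats::setNames(raw$note[raw$ambiguous],
                                        raw$neuron[raw$ambiguous])
  tab
}

#' Gold-table CSV input/output
#'
#' The on-disk format is the tidy long table (columns `antibody`, `run`,
#' `layer`, `neurite_id`, `count`); it round-trips losslessly.
#' [export_gold_matrix()] additionally writes the display-style wide
#' matrix with row and column totals appended.
#'
#' @param table A [gold_tbl][tabulate_gold].
#' @param path File path.
#' @return `read_gold_csv()` returns a `gold_tbl`.
#' @export
write_gold_csv <- function(table, path) {
  readr::write_csv(as_tibble(table), path)
  invisible(path)
}

#' @rdname write_gold_csv
#' @export
read_gold_csv <- function(path) {
  cells <- readr::read_csv(path, show_col_types = FALSE)
  new_gold_tbl(cells, neurite_order = unique(cells$neurite_id))
}

#' @rdname write_gold_csv
#' @export
export_gold_matrix <- function(table, path) {
  m <- gold_matrix(table)
  row_tot <- rowSums(m, na.rm = TRUE)
  col_tot <- colSums(m, na.rm = TRUE)
  out <- rbind(cbind(m, total = row_tot),
               total = c(col_tot, sum(col_tot)))
  utils::write.csv(out, path, na = "")
  invisible(path)
}

#' Serialise a synthetic dataset
#'
#' Writes one JSON document (config scalars, neurites, per-section paths,
#' DCV tracks, labeling design, synapses) plus the gold table as CSV.
#' Reading back yields an equivalent dataset; serialisation is
#' deterministic, so identical (config, seed) pairs produce byte-identical
#' files.
#'
#' @param dataset A `sigold_dataset`.
#' @param dir Output directory (created if needed).
#' @return `read_dataset()` returns a `sigold_dataset`-shaped list.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cfg <- unclass(dataset$config)
  cfg$crossreactivity <- as.data.frame(cfg$crossreactivity)
  doc <- list(
    config = cfg,
    neurites = dataset$neurites,
    paths = dataset$paths,
    dcv = dataset$dcv,
    design = list(style = attr(dataset$design, "style"),
                  n_sections = attr(dataset$design, "n_sections"),
                  runs = as_tibble(dataset$design)),
    synapses = dataset$synapses
  )
  jsonlite::write_json(doc, file.path(dir, "dataset.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  write_gold_csv(dataset$gold, file.path(dir, "gold.csv"))
  invisible(dir)
}

#' @rdname write_dataset
#' @export
read_dataset <- function(dir) {
  doc <- jsonlite::read_json(file.path(dir, "dataset.json"),
                             simplifyVector = TRUE)
  design <- new_labeling_design(as_tibble(doc$design$runs),
                                style = doc$design$style,
                                n_sections = doc$design$n_sections)
  gold <- read_gold_csv(file.path(dir, "gold.csv"))
  attr(gold, "design") <- design
  structure(list(config = doc$config,
                 neurites = as_tibble(doc$neurites),
                 paths = as_tibble(doc$paths),
                 dcv = as_tibble(doc$dcv),
                 design = design, gold = gold,
                 synapses = as_tibble(doc$synapses)),
            class = "sigold_dataset")
}

#' Identity calls export
#'
#' @param calls A [sigold_calls][call_identities] tibble.
#' @param path Output path (`.csv` or `.json`).
#' @return `path`, invisibly.
#' @export
write_calls <- function(calls, path) {
  flat <- as_tibble(calls) |>
    mutate(witness_layers = purrr::map_chr(
      .data$witness_layers, paste, collapse = ";"))
  if (grepl("\\.json$", path)) {
    jsonlite::write_json(flat, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  } else {
    readr::write_csv(flat, path)
  }
  invisible(path)
}

#' Read a simulation config from a YAML file
#'
#' Keys map 1:1 onto [sim_config()] arguments; unknown keys are rejected.
#' Cross-reactivity can be given as `crossreactive_groups` (a list of
#' antibody-name vectors) plus `crossreactive_strength`.
#'
#' @param path YAML file.
#' @param seed Optional seed overriding the file's.
#' @return A [sim_config()].
#' @export
read_sim_config <- function(path, seed = NULL) {
  y <- yaml::read_yaml(path)
  groups <- y$crossreactive_groups
  strength <- y$crossreactive_strength %||% 0.6
  y$crossreactive_groups <- NULL
  y$crossreactive_strength <- NULL
  known <- names(formals(sim_config))
  unknown <- setdiff(names(y), known)
  if (length(unknown)) {
    abort(paste("unknown config key(s):", paste(unknown, collapse = ", ")),
          class = "sigold_config_error")
  }
  if (!is.null(y$antibody_panel)) y$antibody_panel <- unlist(y$antibody_panel)
  if (!is.null(groups)) {
    y$crossreactivity <- crossreactivity_matrix(
      y$antibody_panel %||% sigold_antibodies(),
      groups = lapply(groups, unlist), strength = strength)
  }
  if (!is.null(seed)) y$seed <- seed
  do.call(sim_config, y)
}

# run manifest: config, seed, package/R versions (no timestamps, so
# repeated runs are byte-identical)
write_manifest <- function(dir, params, seed) {
  jsonlite::write_json(
    list(tool = "sigold",
         version = as.character(utils::packageVersion("sigold")),
         r_version = paste(R.version$major, R.version$minor, sep = "."),
         seed = seed, params = params),
    file.path(dir, "manifest.json"), auto_unbox = TRUE, pretty = TRUE)
  invisible(NULL)
}
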