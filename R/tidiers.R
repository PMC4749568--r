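#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy / glance methods
#'
#' Broom-style accessors for the package's result objects: `tidy()`
#' returns the per-unit tibble (per design, per call, per edge, per
#' registration), `glance()` a one-row summary.
#'
#' @param x A `sigold_design_eval`, `sigold_calls`, `sigold_circuit` or
#'   `sigold_template`.
#' @param ... Unused.
#' @name sigold-tidiers
NULL

#' @rdname sigold-tidiers
#' @export
tidy.sigold_design_eval <- function(x, ...) {
  as_tibble(unclass(x))
}

#' @rdname sigold-tidiers
#' @export
glance.sigold_design_eval <- function(x, ...) {
  tibble(n_designs = nrow(x),
         n_replicates = sum(x$n_replicates),
         best_f1 = max(x$f1, na.rm = TRUE),
         best_design = which.max(x$f1))
}

#' @rdname sigold-tidiers
#' @export
tidy.sigold_calls <- function(x, ...) {
  as_tibble(x) |>
    mutate(witness_layers = purrr::map_chr(.data$witness_layers, paste,
                                           collapse = ";"))
}

#' @rdname sigold-tidiers
#' @export
glance.sigold_calls <- function(x, ...) {
  tibble(n_calls = nrow(x),
         n_candidate = sum(x$tier == "candidate"),
         n_confirmed = sum(x$tier == "confirmed"),
         n_neurites = dplyr::n_distinct(x$neurite_id),
         n_coexpressing = nrow(detect_coexpression(x)),
         n_dcv_absence_flags = sum(x$dcv_absence_false_negative))
}

#' @rdname sigold-tidiers
#' @export
tidy.sigold_circuit <- function(x, ...) {
  x$edges
}

#' @rdname sigold-tidiers
#' @export
glance.sigold_circuit <- function(x, ...) {
  tibble(n_nodes = nrow(x$nodes), n_edges = nrow(x$edges),
         total_synapses = sum(x$edges$weight),
         max_edge_weight = if (nrow(x$edges)) max(x$edges$weight) else 0L)
}

#' @rdname sigold-tidiers
#' @export
tidy.sigold_template <- function(x, ...) {
  x$history
}

#' @rdname sigold-tidiers
#' @export
glance.sigold_template <- function(x, ...) {
  s <- x$history |>
    group_by(.data$stage) |>
    summarise(mean_kept_score = mean(.data$score[.data$kept]),
              .groups = "drop")
  out <- as_tibble(as.list(stats::setNames(
    s$mean_kept_score, paste0("stage", s$stage))))
  mutate(out, k_keep = x$k_keep, .before = 1)
}
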