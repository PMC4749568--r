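#' Attach identity calls to traced skeletons
#'
#' Copies confirmed identity labels from a calls table onto the matching
#' skeletons (by `neurite_id` == `neuron_id`). Calls without a matching
#' skeleton are reported, never dropped silently.
#'
#' @param skeletons List of [skeleton()]s.
#' @param calls A [sigold_calls][call_identities] tibble (only `confirmed`
#'   rows are attached).
#' @return List with `skeletons` (annotated) and `unmatched` (tibble of
#'   calls with no skeleton).
#' @export
attach_identities <- function(skeletons, calls) {
  ids <- vapply(skeletons, function(s) s$neuron_id, "")
  if (anyDuplicated(ids)) {
    abort(paste("ambiguous skeleton ids:",
                paste(unique(ids[duplicated(ids)]), collapse = ", ")),
          class = "sigold_mapping_error")
  }
  conf <- filter(as_tibble(calls), .data$tier == "confirmed")
  matched <- conf$neurite_id %in% ids
  for (k in which(matched)) {
    i <- match(conf$neurite_id[k], ids)
    skeletons[[i]]$annotations <-
      sort(unique(c(skeletons[[i]]$annotations, conf$antibody[k])))
  }
  list(skeletons = skeletons,
       unmatched = conf[!matched, c("neurite_id", "antibody")])
}

#' Build a synapse-count circuit graph
#'
#' Nodes are neurons or named groups of neurons; a directed edge carries
#' weight equal to the number of synaptic (pre, post) pairs between the
#' groups. Polyadic synapses contribute one pair per postsynaptic target.
#' A display width proportional to the square root of the synapse count is
#' attached to every edge. Regrouping never changes the total weight.
#'
#' @param skeletons List of [skeleton()]s (may be `NULL` to skip reference
#'   checks; nodes are then taken from the connectors and grouping).
#' @param connectors Tibble of synaptic pairs: one row per (pre, post)
#'   pair with columns `connector_id`, `pre_neuron`, `post_neuron`
#'   (optional `pre_node`, `post_node`, `section_index`).
#' @param grouping Named character vector mapping `neuron_id` to group
#'   name; unmapped neurons stay as singleton nodes under their own id.
#' @return A `sigold_circuit`: list with `edges` (tibble `pre`, `post`,
#'   `weight`, `width`), `nodes` (tibble `node`, `n_neurons`) and `graph`
#'   (a directed, weighted [igraph][igraph::graph_from_data_frame] graph).
#' @export
#' @examples
#' conn <- tibble::tibble(connector_id = 1:3, pre_neuron = "a",
#'                        post_neuron = "b")
#' build_graph(NULL, conn)$edges
build_graph <- function(skeletons, connectors, grouping = NULL) {
  conn <- as_tibble(connectors)
  stopifnot(all(c("pre_neuron", "post_neuron") %in% names(conn)))
  if (all(c("pre_node", "post_node") %in% names(conn)) &&
      nrow(conn) > 0 &&
      any(conn$pre_neuron == conn$post_neuron &
            conn$pre_node == conn$post_node, na.rm = TRUE)) {
    abort("a synapse cannot have the same node pre and post",
          class = "sigold_integrity_error")
  }
  known <- if (!is.null(skeletons)) {
    vapply(skeletons, function(s) s$neuron_id, "")
  } else {
    unique(c(conn$pre_neuron, conn$post_neuron, names(grouping)))
  }
  dangling <- setdiff(unique(c(conn$pre_neuron, conn$post_neuron)), known)
  if (length(dangling)) {
    abort(paste("connectors reference unknown neurons:",
                paste(dangling, collapse = ", ")),
          class = "sigold_integrity_error")
  }
  to_group <- function(id) {
    g <- unname(grouping[id])
    ifelse(is.na(g) | is.null(g), id, g)
  }
  if (is.null(grouping)) to_group <- identity
  edges <- conn |>
    mutate(pre = to_group(.data$pre_neuron),
           post = to_group(.data$post_neuron)) |>
    count(.data$pre, .data$post, name = "weight") |>
    mutate(width = sqrt(.data$weight)) |>
    arrange(.data$pre, .data$post)
  all_nodes <- sort(unique(c(edges$pre, edges$post, to_group(known))))
  members <- stats::setNames(to_group(known), known)
  nodes <- tibble(node = all_nodes,
                  n_neurons = vapply(all_nodes, function(g) {
                    max(1L, sum(members == g))
                  }, integer(1)))
  g <- igraph::graph_from_data_frame(
    edges[, c("pre", "post", "weight", "width")],
    directed = TRUE, vertices = nodes)
  structure(list(edges = edges, nodes = nodes, graph = g),
            class = "sigold_circuit", grouping = grouping)
}

#' @export
print.sigold_circuit <- function(x, ...) {
  cat(sprintf("<sigold_circuit: %d node(s), %d edge(s), %d synapse pair(s)>\n",
              nrow(x$nodes), nrow(x$edges), sum(x$edges$weight)))
  invisible(x)
}

#' In-degree spectrum of a source group
#'
#' How many synapses each target neuron (or group node) receives from a
#' given source group, plus the histogram over targets: how many targets
#' receive exactly k synapses. With sensory-organ sources this separates
#' strongly connected interneurons from the long tail of single-synapse
#' targets.
#'
#' @param circuit A [build_graph()] result.
#' @param source_group Node name, or group name under the circuit's
#'   grouping.
#' @return List with `per_target` (tibble `target`, `synapses`) and
#'   `histogram` (tibble `synapses`, `n_targets`).
#' @export
in_degree_spectrum <- function(circuit, source_group) {
  grouping <- attr(circuit, "grouping")
  sources <- circuit$nodes$node[circuit$nodes$node == source_group]
  if (length(sources) == 0 && !is.null(grouping)) {
    sources <- intersect(unique(names(grouping)[grouping == source_group]),
                         circuit$nodes$node)
  }
  if (length(sources) == 0) {
    abort(sprintf("unknown source group '%s'", source_group),
          class = "sigold_key_error")
  }
  per_target <- circuit$edges |>
    filter(.data$pre %in% sources) |>
    group_by(target = .data$post) |>
    summarise(synapses = sum(.data$weight), .groups = "drop") |>
    arrange(desc(.data$synapses))
  histogram <- per_target |>
    count(.data$synapses, name = "n_targets") |>
    arrange(.data$synapses)
  list(per_target = per_target, histogram = histogram)
}

#' Laterality of a neuron's synaptic output
#'
#' Classifies each outgoing synapse of a neuron as ipsilateral or
#' contralateral to its soma side (relative to the midline plane) and
#' returns the laterality index `n_ipsi / (n_ipsi + n_contra)`:
#' 1 for strictly ipsilateral output (photoreceptor-like), 0.5 for
#' balanced bilateral output. The index is invariant under reflecting all
#' coordinates.
#'
#' @param skel A [skeleton()]. The soma side is the sign of the soma
#'   node's x; if no soma node (SWC type 1) exists the root node is used
#'   with a warning.
#' @param connectors Synaptic pair tibble (see [build_graph()]); rows with
#'   `pre_neuron == skel$neuron_id` are this neuron's output. Post-target
#'   side comes from a `post_x` column if present, else from the post
#'   node's x in `skeletons`.
#' @param skeletons Optional list of skeletons for post-node lookup.
#' @param midline_x Midline plane (default 0).
#' @return List `n_ipsi`, `n_contra`, `index`.
#' @export
laterality_profile <- function(skel, connectors, skeletons = NULL,
                               midline_x = 0) {
  soma <- soma_node(skel)
  if (is.null(soma)) {
    warn(sprintf("neuron %s has no soma node; using the root",
                 skel$neuron_id))
    soma <- skel$nodes[skel$nodes$parent_id == -1, ][1, ]
  }
  soma_side <- sign(soma$x - midline_x)
  out <- filter(as_tibble(connectors),
                .data$pre_neuron == skel$neuron_id)
  if (nrow(out) == 0) {
    return(list(n_ipsi = 0L, n_contra = 0L, index = NA_real_))
  }
  post_x <- if ("post_x" %in% names(out)) {
    out$post_x
  } else {
    if (is.null(skeletons)) {
      abort("need `post_x` in connectors or `skeletons` for post positions",
            class = "sigold_integrity_error")
    }
    ids <- vapply(skeletons, function(s) s$neuron_id, "")
    vapply(seq_len(nrow(out)), function(k) {
      s <- skeletons[[match(out$post_neuron[k], ids)]]
      i <- if ("post_node" %in% names(out) && !is.na(out$post_node[k])) {
        match(out$post_node[k], s$nodes$node_id)
      } else 1L
      s$nodes$x[i]
    }, numeric(1))
  }
  side <- sign(post_x - midline_x)
  n_ipsi <- sum(side == soma_side)
  n_contra <- sum(side == -soma_side)
  list(n_ipsi = n_ipsi, n_contra = n_contra,
       index = n_ipsi / (n_ipsi + n_contra))
}

#' Classify a synapse by its vesicle diameters
#'
#' Dense-core vesicles at peptidergic synapses (~63 nm) are larger than
#' clear vesicles at classical neurotransmitter synapses (~35 nm). A
#' synapse is `peptidergic` if all sampled diameters are `>= cut_nm`,
#' `classical` if all are below, and `mixed` otherwise. The default cut,
#' 45 nm, sits midway between the two diameter models.
#'
#' @param vesicle_diameters_nm Positive diameters sampled at the
#'   presynapse.
#' @param cut_nm Classification threshold (default 45 nm).
#' @return One of `"peptidergic"`, `"classical"`, `"mixed"`.
#' @export
#' @examples
#' classify_synapse(c(58, 61, 70))
classify_synapse <- function(vesicle_diameters_nm, cut_nm = 45) {
  if (length(vesicle_diameters_nm) == 0) {
    abort("at least one vesicle diameter is required",
          class = "sigold_input_error")
  }
  big <- vesicle_diameters_nm >= cut_nm
  if (all(big)) "peptidergic" else if (!any(big)) "classical" else "mixed"
}

#' Export a circuit graph
#'
#' @param circuit A [build_graph()] result.
#' @param path Output file; format chosen by extension (`.graphml` or
#'   `.dot`/`.gv`).
#' @return `path`, invisibly.
#' @export
write_circuit <- function(circuit, path) {
  fmt <- if (grepl("\\.graphml$", path)) "graphml" else "dot"
  igraph::write_graph(circuit$graph, path, format = fmt)
  invisible(path)
}
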