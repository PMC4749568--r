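#' Neuron skeletons and SWC input/output
#'
#' A skeleton is the traced tree morphology of one neuron: a node table
#' with parent pointers, in um coordinates. [read_swc()] and [write_swc()]
#' use the standard 7-column SWC format (`id type x y z radius parent`,
#' `#` comments, parent of the root = -1, 1-based node ids).
#'
#' @param nodes Tibble with columns `node_id`, `type`, `x`, `y`, `z`,
#'   `radius`, `parent_id`.
#' @param neuron_id Identifier of the neuron.
#' @param annotations Character vector of identity labels.
#' @param group Optional group name (e.g. "SNnuch", "INarc", "PRC").
#' @return A `sigold_skeleton`.
#' @export
skeleton <- function(nodes, neuron_id, annotations = character(),
                     group = NA_character_) {
  nodes <- as_tibble(nodes)
  need <- c("node_id", "type", "x", "y", "z", "radius", "parent_id")
  stopifnot(all(need %in% names(nodes)))
  roots <- nodes$node_id[nodes$parent_id == -1]
  if (length(roots) != 1) {
    abort(sprintf("skeleton '%s' must have exactly one root, found %d",
                  neuron_id, length(roots)),
          class = "sigold_format_error")
  }
  nonroot <- nodes$parent_id != -1
  if (!all(nodes$parent_id[nonroot] %in% nodes$node_id)) {
    bad <- nodes$node_id[nonroot &
                           !(nodes$parent_id %in% nodes$node_id)][1]
    abort(sprintf("node %d references a missing parent", bad),
          class = "sigold_format_error")
  }
  # depth resolution doubles as the cycle check: a node whose depth never
  # resolves sits on a parent loop
  id_chr <- as.character(nodes$node_id)
  parent_chr <- as.character(nodes$parent_id)
  depth <- stats::setNames(rep(NA_integer_, nrow(nodes)), id_chr)
  depth[parent_chr == "-1"] <- 0L
  for (pass in seq_len(nrow(nodes))) {
    unresolved <- which(is.na(depth))
    if (!length(unresolved)) break
    depth[unresolved] <- unname(depth[parent_chr[unresolved]]) + 1L
  }
  if (anyNA(depth)) {
    bad <- as.integer(names(depth)[is.na(depth)][1])
    abort(sprintf("cyclic parent links involving node %d", bad),
          class = "sigold_format_error")
  }
  structure(list(neuron_id = neuron_id, nodes = nodes,
                 annotations = annotations, group = group,
                 depth = unname(depth[id_chr])),
            class = "sigold_skeleton")
}

#' @rdname skeleton
#' @param path File path.
#' @param neuron_id Neuron identifier; defaults to the file name without
#'   extension.
#' @export
read_swc <- function(path, neuron_id = NULL) {
  lines <- readLines(path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0) {
    abort("empty SWC file", class = "sigold_format_error")
  }
  m <- utils::read.table(text = lines, col.names = c(
    "node_id", "type", "x", "y", "z", "radius", "parent_id"))
  skeleton(as_tibble(m),
           neuron_id %||% sub("\\.[^.]*$", "", basename(path)))
}

#' @rdname skeleton
#' @param skel A `sigold_skeleton`.
#' @export
write_swc <- function(skel, path) {
  n <- skel$nodes
  writeLines(c(
    sprintf("# SWC export of neuron %s", skel$neuron_id),
    sprintf("%d %d %.6g %.6g %.6g %.6g %d",
            n$node_id, n$type, n$x, n$y, n$z, n$radius, n$parent_id)
  ), path)
  invisible(path)
}

#' @export
print.sigold_skeleton <- function(x, ...) {
  cat(sprintf("<sigold_skeleton %s: %d nodes, depth %d%s>\n",
              x$neuron_id, nrow(x$nodes), max(x$depth),
              if (length(x$annotations))
                paste0("; labels: ", paste(x$annotations, collapse = ", "))
              else ""))
  invisible(x)
}

# soma node (SWC type 1) if present, else the root (with a warning from
# callers that need a soma)
soma_node <- function(skel) {
  s <- skel$nodes[skel$nodes$type == 1, ]
  if (nrow(s) > 0) return(s[1, ])
  NULL
}
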