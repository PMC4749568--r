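# Small shared fixtures, all built in code.

# a compact but fully featured simulation configuration
small_config <- function(...) {
  args <- utils::modifyList(
    list(n_neurites = 30, n_sections = 200, n_synapses = 20, seed = 42L),
    list(...))
  do.call(sim_config, args)
}

# deterministic high-signal configuration: DCVs always present, full
# enhancement, no background — the noiseless limit of the gold law
noiseless_config <- function(...) {
  args <- utils::modifyList(
    list(dcv_on_rate = 1, dcv_off_rate = 0, dcv_mean = 6,
         gold_per_dcv = 3, background_rate = 0, enhancement_prob = 1),
    list(...))
  do.call(sim_config, args)
}

# a hand-built three-node chain skeleton: root soma at (x0, 0, 0), two
# child nodes stepping along +x
chain_skeleton <- function(id = "a", x0 = -2, step = 1) {
  skeleton(tibble::tibble(
    node_id = 1:3, type = c(1L, 0L, 0L),
    x = x0 + step * (0:2), y = 0, z = 0:2, radius = 0.2,
    parent_id = c(-1L, 1L, 2L)), neuron_id = id)
}

random_gold_cells <- function(n_ab = 3, n_layers = 2, n_neurites = 5,
                              lambda = 1.5) {
  tidyr::expand_grid(
    antibody = paste0("ab", seq_len(n_ab)),
    run = seq_len(n_layers),
    neurite_id = paste0("n", seq_len(n_neurites))) |>
    dplyr::mutate(layer = (match(antibody, unique(antibody)) - 1L) *
                    n_layers + run - 1L,
                  count = stats::rpois(dplyr::n(), lambda))
}
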