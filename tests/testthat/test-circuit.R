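test_that("identity calls are copied onto matching skeletons", {
  skels <- list(chain_skeleton("n1"), chain_skeleton("n2"))
  calls <- structure(tibble::tibble(
    neurite_id = c("n1", "n3"), antibody = c("PDF", "FVa"),
    tier = "confirmed"),
    class = c("sigold_calls", class(tibble::tibble())))
  res <- attach_identities(skels, calls)
  expect_equal(res$skeletons[[1]]$annotations, "PDF")
  expect_equal(res$skeletons[[2]]$annotations, character(0))
  expect_equal(res$unmatched$neurite_id, "n3")
  expect_error(attach_identities(list(chain_skeleton("a"),
                                      chain_skeleton("a")), calls),
               class = "sigold_mapping_error")
})

test_that("synthetic round-trip annotates exactly the confirmed neurites", {
  ds <- generate_dataset(noiseless_config(n_neurites = 20,
                                          n_synapses = 0, seed = 3))
  calls <- call_identities(ds$gold, ds$design)
  skels <- lapply(ds$neurites$id, chain_skeleton)
  res <- attach_identities(skels, calls)
  annotated <- vapply(res$skeletons,
                      function(s) length(s$annotations) > 0, logical(1))
  confirmed <- ds$neurites$id %in%
    calls$neurite_id[calls$tier == "confirmed"]
  expect_equal(annotated, confirmed)
})

test_that("circuit graphs count synaptic pairs with sqrt display widths", {
  conn <- tibble::tibble(connector_id = 1:3, pre_neuron = "A",
                         post_neuron = "B")
  g <- build_graph(NULL, conn)
  expect_equal(g$edges$weight, 3)
  expect_equal(g$edges$width, sqrt(3))
  # polyadic synapse: one pre, two posts in different groups
  poly <- tibble::tibble(connector_id = c(7, 7), pre_neuron = "A",
                         post_neuron = c("B", "C"))
  gp <- build_graph(NULL, poly,
                    grouping = c(A = "src", B = "g1", C = "g2"))
  expect_equal(sort(gp$edges$weight), c(1, 1))
  expect_equal(sum(gp$edges$weight), nrow(poly))
  # dangling references are rejected
  skels <- list(chain_skeleton("A"))
  expect_error(build_graph(skels, conn),
               class = "sigold_integrity_error")
})

test_that("total edge weight is conserved under arbitrary regrouping", {
  withr::with_seed(17, {
    for (i in 1:5) {
      neurons <- paste0("c", 1:8)
      n <- sample(10:40, 1)
      conn <- tibble::tibble(
        connector_id = seq_len(n),
        pre_neuron = sample(neurons, n, replace = TRUE),
        post_neuron = sample(neurons, n, replace = TRUE))
      g0 <- build_graph(NULL, conn)
      grouping <- stats::setNames(sample(c("p", "q", "r"), 8,
                                         replace = TRUE), neurons)
      g1 <- build_graph(NULL, conn, grouping)
      expect_equal(sum(g0$edges$weight), n)
      expect_equal(sum(g1$edges$weight), n)
    }
  })
})

test_that("in-degree spectra histogram per-target synapse counts", {
  conn <- tibble::tibble(
    connector_id = 1:26,
    pre_neuron = rep(paste0("sn", 1:4), length.out = 26),
    post_neuron = c("t1", "t2", rep("t3", 2), rep("t4", 22)))
  grouping <- stats::setNames(
    c(rep("SNnuch", 4), "t1", "t2", "t3", "t4"),
    c(paste0("sn", 1:4), paste0("t", 1:4)))
  g <- build_graph(NULL, conn, grouping)
  sp <- in_degree_spectrum(g, "SNnuch")
  expect_equal(sp$per_target$synapses[sp$per_target$target == "t4"], 22)
  hist <- stats::setNames(sp$histogram$n_targets, sp$histogram$synapses)
  expect_equal(hist[["1"]], 2)
  expect_equal(hist[["2"]], 1)
  expect_equal(hist[["22"]], 1)
  expect_equal(sum(sp$histogram$n_targets), nrow(sp$per_target))
  expect_error(in_degree_spectrum(g, "nope"), class = "sigold_key_error")
  # a group with no outgoing synapses yields an empty spectrum
  g2 <- build_graph(NULL, conn,
                    grouping = c(grouping, lonely = "isolated"))
  sp2 <- in_degree_spectrum(g2, "isolated")
  expect_equal(nrow(sp2$histogram), 0)
})

test_that("laterality index separates ipsilateral-only from bilateral output", {
  prc <- chain_skeleton("prc", x0 = -3)  # soma on the left
  mk_conn <- function(post_x) {
    tibble::tibble(connector_id = seq_along(post_x), pre_neuron = "prc",
                   post_neuron = "t", post_x = post_x)
  }
  expect_equal(laterality_profile(prc, mk_conn(c(-1, -2, -5)))$index, 1)
  expect_equal(laterality_profile(prc, mk_conn(c(-1, -2, 1, 2)))$index, 0.5)
  expect_equal(laterality_profile(prc, mk_conn(c(1, 2, 3)))$index, 0)
  # invariant under reflecting every coordinate
  refl <- chain_skeleton("prc", x0 = 3)
  expect_equal(laterality_profile(refl, mk_conn(c(1, 2, -5)))$index,
               laterality_profile(prc, mk_conn(c(-1, -2, 5)))$index)
  # no soma node: fall back to the root with a warning
  nosoma <- skeleton(tibble::tibble(
    node_id = 1:2, type = 0L, x = c(-1, 0), y = 0, z = 0:1,
    radius = 0.1, parent_id = c(-1L, 1L)), "ns")
  expect_warning(laterality_profile(nosoma, mk_conn(-1)), "soma")
})

test_that("vesicle-diameter classification matches the two-diameter model", {
  expect_equal(classify_synapse(c(58, 63, 71)), "peptidergic")
  expect_equal(classify_synapse(c(30, 35, 40)), "classical")
  expect_equal(classify_synapse(c(30, 60)), "mixed")
  expect_error(classify_synapse(numeric(0)), class = "sigold_input_error")
  # misclassification of single-vesicle synapses matches the normal tails
  cfg <- small_config(n_synapses = 400, vesicles_per_synapse = 1,
                      synapse_peptidergic_frac = 0.5, seed = 99)
  ds <- generate_dataset(cfg)
  syn <- ds$synapses
  pred <- vapply(syn$vesicle_diameters_nm, classify_synapse, "")
  pep <- syn$vesicle_class_truth == "peptidergic"
  mis_pep <- mean(pred[pep] != "peptidergic")
  mis_cls <- mean(pred[!pep] != "classical")
  p_pep <- pnorm(45, 63, 8.4)                 # P(DCV diameter < cut)
  p_cls <- 1 - pnorm(45, 35, 5)               # P(clear diameter >= cut)
  n_pep <- sum(pep); n_cls <- sum(!pep)
  expect_lt(abs(mis_pep - p_pep),
            3 * sqrt(p_pep * (1 - p_pep) / n_pep) + 1e-9)
  expect_lt(abs(mis_cls - p_cls),
            3 * sqrt(p_cls * (1 - p_cls) / n_cls) + 1e-9)
})
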