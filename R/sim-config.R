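#' Standard neuropeptide antibody panel
#'
#' The eleven amidated-neuropeptide antibodies routinely used for
#' serial-multiplex immunogold labeling of annelid larvae: FMRFamide,
#' RYamide, myoinhibitory peptide, RGWamide, proenkephalin, luqin,
#' allatotropin, pigment-dispersing factor, leucokinin, FVamide and
#' FVRIamide.
#'
#' @return Character vector of 11 antibody (and cognate proneuropeptide)
#'   abbreviations.
#' @export
#' @examples
#' sigold_antibodies()
sigold_antibodies <- function() {
  c("FMRFa", "RYa", "MIP", "RGWa", "PENK", "LUQ",
    "ATO", "PDF", "LEUC", "FVa", "FVRIa")
}

#' Antibody-by-peptide cross-reactivity matrix
#'
#' Builds the recognition matrix `S[a, p]` giving the relative strength with
#' which antibody `a` recognises peptide `p`. The diagonal (cognate epitope)
#' is always 1. Off-diagonal cross-reactivity can be introduced for groups of
#' antibodies that recognise overlapping epitopes, e.g. the RFamide-like
#' block (FMRFa, LUQ, RYa) that labels overlapping neurite sets.
#'
#' @param panel Character vector of antibody names; peptides are assumed to
#'   share these names (one cognate peptide per antibody).
#' @param groups Optional list of character vectors; within each group every
#'   antibody recognises every member peptide with strength `strength`.
#' @param strength Off-diagonal recognition strength in (0, 1).
#' @return A square numeric matrix with `dimnames = list(antibody, peptide)`.
#' @export
#' @examples
#' S <- crossreactivity_matrix(groups = list(c("FMRFa", "LUQ", "RYa")))
#' S["FMRFa", "RYa"]
crossreactivity_matrix <- function(panel = sigold_antibodies(),
                                   groups = NULL, strength = 0.6) {
  S <- diag(length(panel))
  dimnames(S) <- list(antibody = panel, peptide = panel)
  for (g in groups) {
    g <- intersect(g, panel)
    S[g, g][S[g, g] == 0] <- strength
  }
  S
}

#' Simulation configuration for serial-section immunogold experiments
#'
#' Collects every tunable of the synthetic-data generator: the geometry of
#' the serial-section stack, the neurite population, the dense-core-vesicle
#' (DCV) occupancy model, the gold-deposition law, the vesicle-diameter
#' models and the sparse labeling design.
#'
#' @param n_sections Number of serial sections in the series. The default,
#'   200, matches a typical ventral-nerve-cord series cut from the first
#'   trunk segment.
#' @param section_thickness_nm Physical section thickness in nm (default 40).
#' @param n_neurites Number of neurite profiles crossing the series.
#' @param antibody_panel Ordered character vector of antibody names.
#' @param crossreactivity Antibody x peptide recognition matrix `S` with unit
#'   diagonal; see [crossreactivity_matrix()].
#' @param dcv_on_rate,dcv_off_rate Per-section switch probabilities of the
#'   two-state (on/off) Markov chain governing DCV occupancy along a
#'   neurite: `dcv_on_rate` = P(off -> on), `dcv_off_rate` = P(on -> off).
#' @param dcv_mean Mean DCV count per section while the chain is "on"
#'   (counts are Poisson).
#' @param gold_per_dcv Expected gold particles deposited per DCV per labeled
#'   section at full recognition (the linear gain `alpha`).
#' @param background_rate Expected background gold per square micrometre of
#'   profile area per labeled section (`lambda_bg`). Small but nonzero by
#'   default so classifier specificity is testable; omitted-primary controls
#'   correspond to zeroing both this and the recognition term.
#' @param enhancement_prob Probability that a deposited ultra-small gold
#'   particle is silver-enhanced into a countable particle (`p_enh`); models
#'   the fact that unenhanced particles are invisible at scoring resolution.
#' @param vesicle_diam_mean_nm,vesicle_diam_sd_nm Dense-core vesicle
#'   diameter model (positive-truncated normal; defaults 63 and 8.4 nm).
#' @param clear_diam_mean_nm,clear_diam_sd_nm Clear (classical
#'   neurotransmitter) vesicle diameter model (defaults 35 and 5 nm).
#' @param peptidergic_frac Fraction of neurites that are peptidergic (carry
#'   DCVs and express at least one neuropeptide).
#' @param coexpression_prob Probability that a peptidergic neurite expresses
#'   a second neuropeptide (e.g. FVa + PDF coexpression).
#' @param bilateral If `TRUE`, neurites are generated as mirror pairs about
#'   the midline `x = 0`, emulating the bilateral symmetry of the ventral
#'   nerve cord.
#' @param position_jitter_um SD of per-section positional jitter of a
#'   neurite path about its reference centroid, in micrometres.
#' @param design_style `"paired-grids"` (each antibody on two runs of
#'   consecutive sections separated by ~50 sections) or `"whole-body"`
#'   (short 1-6 section runs scattered over the whole series).
#' @param runs_per_antibody,sections_per_run,run_spacing Labeling-design
#'   parameters; see [design_paired_grids()] and [design_whole_body()].
#' @param n_synapses Number of synapse records to generate.
#' @param synapse_peptidergic_frac Fraction of synapses whose presynapse is
#'   peptidergic (DCV-only), when peptidergic neurites exist.
#' @param vesicles_per_synapse Number of vesicle diameters sampled at each
#'   presynaptic site.
#' @param seed Root random seed; every component derives its own child
#'   stream from it.
#' @return An object of class `sigold_config` (a validated named list).
#' @export
#' @examples
#' cfg <- sim_config(n_neurites = 20, n_sections = 120)
#' cfg$dcv_mean
sim_config <- function(n_sections = 200,
                       section_thickness_nm = 40,
                       n_neurites = 200,
                       antibody_panel = sigold_antibodies(),
                       crossreactivity = NULL,
                       dcv_on_rate = 0.2,
                       dcv_off_rate = 0.1,
                       dcv_mean = 4,
                       gold_per_dcv = 1,
                       background_rate = 0.02,
                       enhancement_prob = 0.5,
                       vesicle_diam_mean_nm = 63,
                       vesicle_diam_sd_nm = 8.4,
                       clear_diam_mean_nm = 35,
                       clear_diam_sd_nm = 5,
                       peptidergic_frac = 0.3,
                       coexpression_prob = 0.05,
                       bilateral = TRUE,
                       position_jitter_um = 0.15,
                       design_style = c("paired-grids", "whole-body"),
                       runs_per_antibody = 2,
                       sections_per_run = 5,
                       run_spacing = 50,
                       n_synapses = 120,
                       synapse_peptidergic_frac = 0.5,
                       vesicles_per_synapse = 10,
                       seed = 1L) {
  design_style <- match.arg(design_style)
  if (is.null(crossreactivity)) {
    crossreactivity <- crossreactivity_matrix(antibody_panel)
  }
  cfg <- structure(
    list(
      n_sections = as.integer(n_sections),
      section_thickness_nm = section_thickness_nm,
      n_neurites = as.integer(n_neurites),
      antibody_panel = antibody_panel,
      crossreactivity = crossreactivity,
      dcv_on_rate = dcv_on_rate,
      dcv_off_rate = dcv_off_rate,
      dcv_mean = dcv_mean,
      gold_per_dcv = gold_per_dcv,
      background_rate = background_rate,
      enhancement_prob = enhancement_prob,
      vesicle_diam_mean_nm = vesicle_diam_mean_nm,
      vesicle_diam_sd_nm = vesicle_diam_sd_nm,
      clear_diam_mean_nm = clear_diam_mean_nm,
      clear_diam_sd_nm = clear_diam_sd_nm,
      peptidergic_frac = peptidergic_frac,
      coexpression_prob = coexpression_prob,
      bilateral = isTRUE(bilateral),
      position_jitter_um = position_jitter_um,
      design_style = design_style,
      runs_per_antibody = as.integer(runs_per_antibody),
      sections_per_run = as.integer(sections_per_run),
      run_spacing = as.integer(run_spacing),
      n_synapses = as.integer(n_synapses),
      synapse_peptidergic_frac = synapse_peptidergic_frac,
      vesicles_per_synapse = as.integer(vesicles_per_synapse),
      seed = as.integer(seed)
    ),
    class = "sigold_config"
  )
  validate_config(cfg)
}

validate_config <- function(cfg) {
  if (!is_count(cfg$n_sections) || cfg$n_sections < 1) {
    stop_field("n_sections", "must be an integer >= 1")
  }
  if (!is.numeric(cfg$section_thickness_nm) || cfg$section_thickness_nm <= 0) {
    stop_field("section_thickness_nm", "must be > 0")
  }
  if (!is_count(cfg$n_neurites)) {
    stop_field("n_neurites", "must be a non-negative integer")
  }
  if (!is.character(cfg$antibody_panel) || length(cfg$antibody_panel) < 1 ||
      anyDuplicated(cfg$antibody_panel)) {
    stop_field("antibody_panel", "must be distinct antibody names")
  }
  S <- cfg$crossreactivity
  if (!is.matrix(S) || !is.numeric(S) ||
      nrow(S) != length(cfg$antibody_panel) ||
      any(S < 0) || any(S > 1)) {
    stop_field("crossreactivity",
               "must be a numeric antibody x peptide matrix with values in [0, 1]")
  }
  if (!all(rownames(S) == cfg$antibody_panel)) {
    stop_field("crossreactivity", "row names must equal the antibody panel")
  }
  cognate <- intersect(cfg$antibody_panel, colnames(S))
  if (any(S[cbind(cognate, cognate)] != 1)) {
    stop_field("crossreactivity", "cognate (diagonal) recognition must be 1")
  }
  for (f in c("dcv_on_rate", "dcv_off_rate", "enhancement_prob",
              "peptidergic_frac", "coexpression_prob",
              "synapse_peptidergic_frac")) {
    if (!is_prob(cfg[[f]])) stop_field(f, "must be a probability in [0, 1]")
  }
  for (f in c("dcv_mean", "gold_per_dcv", "background_rate",
              "position_jitter_um")) {
    if (!is.numeric(cfg[[f]]) || length(cfg[[f]]) != 1 || cfg[[f]] < 0) {
      stop_field(f, "must be a non-negative number")
    }
  }
  for (f in c("vesicle_diam_mean_nm", "vesicle_diam_sd_nm",
              "clear_diam_mean_nm", "clear_diam_sd_nm")) {
    if (!is.numeric(cfg[[f]]) || cfg[[f]] <= 0) stop_field(f, "must be > 0")
  }
  if (cfg$runs_per_antibody < 1) stop_field("runs_per_antibody", "must be >= 1")
  if (cfg$sections_per_run < 1) stop_field("sections_per_run", "must be >= 1")
  if (!is_count(cfg$n_synapses)) {
    stop_field("n_synapses", "must be a non-negative integer")
  }
  if (cfg$vesicles_per_synapse < 1) {
    stop_field("vesicles_per_synapse", "must be >= 1")
  }
  cfg
}

#' @export
print.sigold_config <- function(x, ...) {
  cat("<sigold_config>\n")
  cat(sprintf("  sections: %d x %g nm; neurites: %d (%s)\n",
              x$n_sections, x$section_thickness_nm, x$n_neurites,
              if (x$bilateral) "bilateral" else "unpaired"))
  cat(sprintf("  antibodies: %s\n", paste(x$antibody_panel, collapse = ", ")))
  cat(sprintf("  DCV chain: on %.2f / off %.2f, mean %g per on-section\n",
              x$dcv_on_rate, x$dcv_off_rate, x$dcv_mean))
  cat(sprintf(
    "  gold law: alpha %g, bg %g /um^2, enhancement %.2f\n",
    x$gold_per_dcv, x$background_rate, x$enhancement_prob))
  cat(sprintf("  design: %s (%d run(s) x %d section(s), spacing ~%d)\n",
              x$design_style, x$runs_per_antibody, x$sections_per_run,
              x$run_spacing))
  invisible(x)
}
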