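#' Read a declarative plan configuration
#'
#' One YAML (or JSON) file fully describes a plan: the phantom geometry,
#' the beam set with its lattice parameters, the tissue-parameter table and
#' the evaluation settings (reference D98%, constraints). Scenarios that
#' differ only in geometry or prescription then differ only in their config
#' file. Requires the suggested yaml package (jsonlite for \code{.json}).
#'
#' Sections: \code{phantom} (fields of \code{\link{phantom_spec}}),
#' \code{beams} (\code{angles}, \code{entrance_peak_dose}, optional lattice
#' parameters, \code{dilation_px}), optional \code{tissue_table} (CSV path;
#' default the packaged registry), optional \code{evaluation}
#' (\code{reference_d98}, \code{constraints} list with structure/metric/
#' arg/threshold/comparator, or a \code{constraints_csv} path).
#'
#' @param path Config file path.
#' @return A list of class \code{mrt_plan_config} with elements
#'   \code{phantom_spec}, \code{beam_args}, \code{registry},
#'   \code{evaluation}.
#' @export
read_plan_config <- function(path) {
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    if (!requireNamespace("jsonlite", quietly = TRUE))
      stop("JSON configs need the jsonlite package")
    jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  } else {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("YAML configs need the yaml package")
    yaml::read_yaml(path)
  }
  if (is.null(cfg$phantom) || is.null(cfg$beams))
    stop("config needs 'phantom' and 'beams' sections")
  ph <- cfg$phantom
  spec <- phantom_spec(
    shape = as.integer(unlist(ph$shape)),
    spacing = as.numeric(unlist(ph$spacing)),
    body = ph$body,
    target = ph$target,
    oars = if (is.null(ph$oars)) list() else ph$oars,
    lung = ph$lung,
    air_density = if (is.null(ph$air_density)) 0.001 else ph$air_density,
    noise_sd = if (is.null(ph$noise_sd)) 0 else ph$noise_sd)
  if (is.null(cfg$beams$angles)) stop("beams section needs 'angles'")
  registry <- if (is.null(cfg$tissue_table)) read_tissue_table()
              else read_tissue_table(cfg$tissue_table)
  ev <- cfg$evaluation
  if (!is.null(ev$constraints_csv))
    ev$constraints <- read_constraints(ev$constraints_csv)
  else if (!is.null(ev$constraints))
    ev$constraints <- lapply(ev$constraints, function(cs)
      constraint_spec(cs$structure, cs$metric, cs$threshold,
                      arg = if (is.null(cs$arg)) NA else cs$arg,
                      comparator = if (is.null(cs$comparator)) "<" else cs$comparator))
  structure(list(phantom_spec = spec, beam_args = cfg$beams,
                 registry = registry, evaluation = ev),
            class = "mrt_plan_config")
}

#' Run a configured plan end to end
#'
#' Generates the phantom, arranges the conformal beams, simulates the
#' per-voxel histograms over the structures, optionally normalizes to the
#' configured reference PTV D98%, and evaluates DVHs and constraints on the
#' EQD2(EUD) map.
#'
#' @param config An \code{mrt_plan_config} from
#'   \code{\link{read_plan_config}}, or a path to one.
#' @param seed Seed for the phantom's optional noise term.
#' @param pitch_um Subvoxel sample pitch in um.
#' @return List with \code{phantom}, \code{sim}, \code{eud}, \code{eqd2}
#'   (\code{\link{voxel_grid}}s), \code{factor} (normalization factor or
#'   \code{NA}), \code{dvhs}, and \code{report} (or \code{NULL}).
#' @export
run_plan <- function(config, seed = 1L, pitch_um = 25) {
  if (is.character(config)) config <- read_plan_config(config)
  stopifnot(inherits(config, "mrt_plan_config"))
  ph <- generate_phantom(config$phantom_spec, seed = seed)
  ba <- config$beam_args
  tgt_label <- config$phantom_spec$target$label
  tgt <- ph$structures$masks[[tgt_label]]
  lattice <- ba[names(ba) %in% c("peak_width_um", "center_to_center_um",
                                 "valley_fraction", "effective_mu",
                                 "penumbra_sigma_um", "scatter_fraction")]
  beams <- do.call(arrange_beams, c(
    list(angles = as.numeric(unlist(ba$angles)), target = tgt,
         spacing = ph$structures$spacing, origin = ph$structures$origin,
         entrance_peak_dose = if (is.null(ba$entrance_peak_dose)) 1
                              else ba$entrance_peak_dose,
         dilation_px = if (is.null(ba$dilation_px)) 1L else as.integer(ba$dilation_px)),
    lattice))
  region <- Reduce(`|`, ph$structures$masks)
  sim <- simulate_plan(ph$density, beams, voxels = region, pitch_um = pitch_um)
  priority <- names(ph$structures$masks)
  factor <- NA_real_
  ev <- config$evaluation
  if (!is.null(ev$reference_d98)) {
    ans <- normalize_to_reference_d98(sim, ev$reference_d98, tgt,
                                      ph$structures, config$registry, priority)
    sim <- ans$sim
    factor <- ans$factor
  }
  emap <- eud_map(sim, ph$structures, config$registry, priority)
  qmap <- eqd2_map(emap, ph$structures, config$registry, priority)
  dvhs <- lapply(ph$structures$masks, function(m) dvh(qmap, m))
  report <- if (!is.null(ev$constraints))
    evaluate_constraints(qmap, ph$structures, ev$constraints)
  list(phantom = ph, sim = sim, eud = emap, eqd2 = qmap,
       factor = factor, dvhs = dvhs, report = report)
}
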