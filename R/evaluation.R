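#' Simulate per-voxel microscopic dose histograms for a plan
#'
#' Runs the analytic microbeam engine over the requested voxels and reduces
#' each voxel's 25 um in-plane sample sheet to its 35-bin dose histogram.
#' The result caches everything needed for EUD/EQD2 maps, DVHs and
#' normalization; because every sampled dose is linear in the global beam
#' weight, rescaling a plan (\code{\link{scale_plan}}) rescales the cached
#' histogram doses without re-running the engine.
#'
#' @param density_grid \code{\link{voxel_grid}} of densities relative to
#'   water.
#' @param beams List of \code{\link{beam_spec}}.
#' @param voxels Logical 3D array selecting the voxels to simulate
#'   (default: all). Unselected voxels carry zero dose.
#' @param pitch_um Subvoxel sample pitch in um.
#' @param n_bins Histogram bins per voxel.
#' @return An object of class \code{mrt_plan_dose}: list with
#'   \code{histograms} (per selected voxel), \code{voxel_idx} (linear
#'   indices), \code{dim}, \code{spacing}, \code{origin}, \code{beams},
#'   \code{weight_factor}.
#' @export
simulate_plan <- function(density_grid, beams, voxels = NULL,
                          pitch_um = 25, n_bins = 35L) {
  stopifnot(inherits(density_grid, "voxel_grid"))
  dims <- dim(density_grid$values)
  if (is.null(voxels)) voxels <- array(TRUE, dims)
  if (!identical(dim(voxels), dims)) stop("voxels mask must match the grid")
  idx <- which(voxels)
  hists <- vector("list", length(idx))
  for (i in seq_along(idx)) {
    vi <- arrayInd(idx[i], dims)[1, ]
    blk <- sample_subvoxel_doses(vi, beams, density_grid,
                                 pitch_um = pitch_um, collapse_z = TRUE)
    hists[i] <- list(if (all(blk$sample_doses == 0)) NULL else
      build_histogram(blk, n_bins))
  }
  structure(list(histograms = hists, voxel_idx = idx, dim = dims,
                 spacing = density_grid$spacing,
                 origin = density_grid$origin,
                 beams = beams, weight_factor = 1),
            class = "mrt_plan_dose")
}

#' @export
print.mrt_plan_dose <- function(x, ...) {
  cat(sprintf("<mrt_plan_dose> %d simulated voxels on %dx%dx%d grid, %d beams, weight factor %.4g\n",
              length(x$voxel_idx), x$dim[1], x$dim[2], x$dim[3],
              length(x$beams), x$weight_factor))
  invisible(x)
}

#' Rescale the beam weights of a simulated plan
#'
#' Multiplies every beam's entrance dose — and hence, by linearity, every
#' cached histogram dose — by \code{factor}.
#'
#' @param sim An \code{mrt_plan_dose} from \code{\link{simulate_plan}}.
#' @param factor Positive scalar.
#' @return The rescaled \code{mrt_plan_dose}.
#' @export
scale_plan <- function(sim, factor) {
  stopifnot(inherits(sim, "mrt_plan_dose"), is.finite(factor), factor > 0)
  sim$histograms <- lapply(sim$histograms, function(h) {
    if (is.null(h)) NULL else dose_histogram(h$bin_doses * factor, h$bin_weights)
  })
  sim$beams <- lapply(sim$beams, function(b) {
    b$entrance_peak_dose <- b$entrance_peak_dose * factor; b
  })
  sim$weight_factor <- sim$weight_factor * factor
  sim
}

## per-voxel tissue parameters for the simulated voxels, via contour priority
voxel_param_list <- function(sim, structures, registry, priority) {
  lapply(sim$voxel_idx, function(ix) {
    labs <- if (is.null(structures)) character(0) else voxel_labels(structures, ix)
    resolve_tissue_params(labs, registry, priority)
  })
}

#' Equivalent uniform dose map of a simulated plan
#'
#' Per voxel: tissue parameters resolved from the covering contours by
#' priority, then EUD from the cached 35-bin histogram. Voxels that were
#' not simulated (or received no dose) are 0.
#'
#' @param sim An \code{mrt_plan_dose}.
#' @param structures A \code{\link{structure_set}} or \code{NULL}.
#' @param registry Tissue-parameter registry
#'   (\code{\link{read_tissue_table}}).
#' @param priority Label priority, targets first; defaults to the order of
#'   structures in the set.
#' @return \code{\link{voxel_grid}} of EUD in Gy.
#' @export
eud_map <- function(sim, structures = NULL,
                    registry = list(default = default_tissue_params()),
                    priority = if (is.null(structures)) character(0) else names(structures$masks)) {
  stopifnot(inherits(sim, "mrt_plan_dose"))
  pars <- voxel_param_list(sim, structures, registry, priority)
  vals <- array(0, sim$dim)
  for (i in seq_along(sim$voxel_idx)) {
    h <- sim$histograms[[i]]
    if (!is.null(h))
      vals[sim$voxel_idx[i]] <- eud_from_histogram(h, pars[[i]])
  }
  voxel_grid(vals, sim$spacing, sim$origin)
}

#' Convert a dose map to EQD2
#'
#' Voxel-wise fractionation conversion with the voxel's own alpha/beta
#' (resolved from the covering contours by priority). For an MRT EUD map
#' the single-temporal-fraction rule applies: each voxel's whole EUD is its
#' fraction dose. For a clinical map supply either the number of fractions
#' (per-voxel fraction dose = voxel dose / n) or a fixed fraction dose.
#'
#' @param dose_map \code{\link{voxel_grid}}: MRT EUD map or clinical total
#'   dose map, Gy.
#' @param structures,registry,priority As in \code{\link{eud_map}}.
#' @param single_fraction If \code{TRUE} (MRT), use the voxel dose itself
#'   as the fraction dose.
#' @param fractions Number of fractions of the clinical plan.
#' @param fraction_dose Fixed clinical fraction dose in Gy (alternative to
#'   \code{fractions}).
#' @return \code{\link{voxel_grid}} of EQD2 in Gy.
#' @export
eqd2_map <- function(dose_map, structures = NULL,
                     registry = list(default = default_tissue_params()),
                     priority = if (is.null(structures)) character(0) else names(structures$masks),
                     single_fraction = TRUE, fractions = NULL,
                     fraction_dose = NULL) {
  stopifnot(inherits(dose_map, "voxel_grid"))
  if (!single_fraction && is.null(fractions) && is.null(fraction_dose))
    stop("clinical conversion needs a fraction scheme (fractions or fraction_dose)")
  vals <- dose_map$values
  out <- array(0, dim(vals))
  idx <- which(vals > 0)
  if (length(idx)) {
    ab <- vapply(idx, function(ix) {
      labs <- if (is.null(structures)) character(0) else voxel_labels(structures, ix)
      resolve_tissue_params(labs, registry, priority)$alpha_beta
    }, numeric(1))
    d <- vals[idx]
    fd <- if (single_fraction) d
          else if (!is.null(fraction_dose)) rep(fraction_dose, length(d))
          else d / fractions
    out[idx] <- eqd2(d, fd, ab)
  }
  voxel_grid(out, dose_map$spacing, dose_map$origin)
}

#' Cumulative dose-volume histogram of a structure
#'
#' The fraction of the structure volume receiving at least each dose level,
#' evaluated at every distinct voxel dose (plus 0): 100% at 0 Gy,
#' non-increasing, 0% beyond the maximum dose.
#'
#' @param dose_map \code{\link{voxel_grid}} of doses in Gy.
#' @param mask Logical 3D array: the structure (non-empty).
#' @return A data.frame of class \code{dvh_curve} with columns \code{dose}
#'   (Gy) and \code{volume_pct}.
#' @export
dvh <- function(dose_map, mask) {
  stopifnot(inherits(dose_map, "voxel_grid"))
  d <- dose_map$values[mask]
  if (length(d) == 0L) stop("empty structure")
  lev <- sort(unique(c(0, d)))
  vol <- vapply(lev, function(x) mean(d >= x) * 100, numeric(1))
  out <- data.frame(dose = c(lev, max(lev) * 1.0000001 + 1e-9),
                    volume_pct = c(vol, 0))
  class(out) <- c("dvh_curve", "data.frame")
  out
}

## Dose at cumulative (hottest-first) volume: sort doses descending and
## return the minimum dose of the hottest `volume` (same units as `vols`).
## Step convention: D(v) is the dose of the voxel in which the cumulative
## volume v falls; `interpolate` blends linearly between neighbouring voxel
## doses across each voxel's volume span instead.
dose_at_hot_volume <- function(doses, vols, volume, interpolate = FALSE) {
  o <- order(doses, decreasing = TRUE)
  d <- doses[o]; v <- cumsum(vols[o])
  total <- v[length(v)]
  if (volume <= 0) return(d[1])
  if (volume > total * (1 + 1e-9)) stop("requested volume exceeds structure volume")
  volume <- min(volume, total)
  i <- which(v >= volume * (1 - 1e-12))[1]
  if (!interpolate) return(d[i])
  v_lo <- if (i == 1L) 0 else v[i - 1L]
  d_lo <- if (i == 1L) d[1] else d[i - 1L]
  frac <- (volume - v_lo) / (v[i] - v_lo)
  d_lo + frac * (d[i] - d_lo)
}

#' Dose metric of a structure
#'
#' Evaluates the standard plan metrics on a dose map restricted to a
#' structure, under the hottest-volume convention: \code{D_x\%} is the
#' minimum dose received by the hottest x\% of the structure volume (so
#' D2\% is near-maximum, D98\% near-minimum), \code{D_cc} the minimum dose
#' of the hottest given absolute volume, \code{V_Gy} the percentage of the
#' volume at or above a dose, and \code{V_pct} the dose covering the given
#' volume percentage (identical to \code{D_x\%}).
#'
#' @param dose_map \code{\link{voxel_grid}} of doses in Gy.
#' @param mask Logical 3D array: the structure (non-empty).
#' @param metric One of \code{"Dmax"}, \code{"Dmean"}, \code{"Dpct"},
#'   \code{"Dcc"}, \code{"VGy"}, \code{"Vpct"}.
#' @param arg Metric argument: x for \code{Dpct}/\code{Vpct} (percent),
#'   volume in cm^3 for \code{Dcc}, dose in Gy for \code{VGy}.
#' @param interpolate Linear partial-voxel interpolation for \code{Dcc}
#'   (absolute-volume metrics are sensitive to voxel granularity).
#' @return Metric value: Gy for D-type metrics, percent for \code{VGy}.
#' @examples
#' g <- voxel_grid(array(1:100, c(100, 1, 1)), c(1, 1, 1))
#' m <- array(TRUE, c(100, 1, 1))
#' dose_metric(g, m, "Dpct", 98)  # 3 Gy
#' dose_metric(g, m, "Dpct", 2)   # 99 Gy
#' @export
dose_metric <- function(dose_map, mask, metric, arg = NULL,
                        interpolate = (metric == "Dcc")) {
  stopifnot(inherits(dose_map, "voxel_grid"))
  d <- dose_map$values[mask]
  if (length(d) == 0L) stop("empty structure")
  voxel_cc <- prod(dose_map$spacing) / 1000  # mm^3 -> cm^3
  switch(metric,
    Dmax = max(d),
    Dmean = mean(d),
    Dpct = ,
    Vpct = {
      if (is.null(arg) || arg <= 0 || arg > 100) stop("Dpct/Vpct needs x in (0, 100]")
      dose_at_hot_volume(d, rep(1, length(d)), arg / 100 * length(d),
                         interpolate = interpolate)
    },
    Dcc = {
      if (is.null(arg) || arg <= 0) stop("Dcc needs a volume in cm^3")
      dose_at_hot_volume(d, rep(voxel_cc, length(d)), arg,
                         interpolate = interpolate)
    },
    VGy = {
      if (is.null(arg) || arg < 0) stop("VGy needs a dose in Gy")
      mean(d >= arg) * 100
    },
    stop("unknown metric '", metric, "'"))
}

#' Normalize a plan to a reference D98% of the target
#'
#' Finds the single scalar beam-weight factor that makes the PTV D98% of
#' the plan's EQD2(EUD) map equal the reference (the clinical plan's PTV
#' D98%, in Gy EQD2). Matching is performed on the final EQD2(EUD) map —
#' the quantity plans are compared on — so the factor is found by a scalar
#' root solve; by linearity of the engine the candidate maps cost only a
#' histogram rescale each.
#'
#' @param sim An \code{mrt_plan_dose}.
#' @param reference_d98 Target PTV D98% in Gy (EQD2 scale), > 0.
#' @param target_mask Logical 3D array: the PTV.
#' @param structures,registry,priority As in \code{\link{eud_map}}.
#' @param tol Relative tolerance on the matched D98%.
#' @param max_factor Upper bracket for the weight factor search.
#' @return List with \code{sim} (the rescaled plan), \code{factor}, and
#'   \code{achieved_d98}.
#' @export
normalize_to_reference_d98 <- function(sim, reference_d98, target_mask,
                                       structures = NULL,
                                       registry = list(default = default_tissue_params()),
                                       priority = if (is.null(structures)) character(0) else names(structures$masks),
                                       tol = 1e-3, max_factor = 1e4) {
  stopifnot(inherits(sim, "mrt_plan_dose"), reference_d98 > 0)
  if (!any(target_mask)) stop("empty normalization target")
  d98_of <- function(s) {
    m <- eqd2_map(eud_map(scale_plan(sim, s), structures, registry, priority),
                  structures, registry, priority, single_fraction = TRUE)
    dose_metric(m, target_mask, "Dpct", 98)
  }
  f <- function(s) d98_of(s) - reference_d98
  f1 <- f(1)
  if (abs(f1) <= tol * reference_d98)
    return(list(sim = sim, factor = 1, achieved_d98 = f1 + reference_d98))
  lo <- 1; hi <- 1
  if (f1 < 0) {
    while (f(hi) < 0) {
      hi <- hi * 2
      if (hi > max_factor)
        stop("normalization did not bracket the reference within factor ", max_factor)
    }
  } else {
    while (f(lo) > 0) {
      lo <- lo / 2
      if (lo < 1 / max_factor)
        stop("normalization did not bracket the reference within factor 1/", max_factor)
    }
  }
  root <- stats::uniroot(f, c(lo, hi), tol = 1e-7 * hi)
  s <- root$root
  list(sim = scale_plan(sim, s), factor = s, achieved_d98 = d98_of(s))
}

#' Organ-at-risk constraint specification
#'
#' One dose constraint on one structure, on the EQD2 scale: a metric
#' (\code{Dmax}, \code{Dmean}, \code{Dpct}, \code{Dcc}, \code{VGy},
#' \code{Vpct}), its argument, a threshold with units and a comparator.
#'
#' @param structure Structure label.
#' @param metric Metric kind (see \code{\link{dose_metric}}).
#' @param threshold Threshold value (Gy for D-type and Vpct, percent for
#'   VGy).
#' @param arg Metric argument (see \code{\link{dose_metric}}).
#' @param comparator \code{"<"} or \code{"<="}.
#' @param units Unit string for reporting.
#' @return An object of class \code{constraint_spec}.
#' @export
constraint_spec <- function(structure, metric, threshold, arg = NA,
                            comparator = "<",
                            units = if (metric == "VGy") "%" else "Gy") {
  if (!metric %in% c("Dmax", "Dmean", "Dpct", "Dcc", "VGy", "Vpct"))
    stop("unknown metric kind '", metric, "'")
  if (!comparator %in% c("<", "<=")) stop("comparator must be '<' or '<='")
  structure(list(structure = structure, metric = metric, arg = arg,
                 threshold = threshold, comparator = comparator,
                 units = units),
            class = "constraint_spec")
}

#' Read an OAR constraint table from CSV
#'
#' Columns: \code{structure}, \code{metric}, \code{arg} (empty where
#' unused), \code{threshold}, \code{comparator}, optional \code{units}.
#'
#' @param path CSV file path.
#' @return List of \code{\link{constraint_spec}}.
#' @export
read_constraints <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("structure", "metric", "threshold", "comparator")
  if (!all(need %in% names(df)))
    stop("constraint table needs columns ", paste(need, collapse = ", "))
  lapply(seq_len(nrow(df)), function(i)
    constraint_spec(df$structure[i], df$metric[i], df$threshold[i],
                    arg = if ("arg" %in% names(df)) df$arg[i] else NA,
                    comparator = df$comparator[i]))
}

#' Check achieved dose metrics against constraints
#'
#' Builds the pass/fail table of a plan: one row per constraint with the
#' achieved value, the threshold and the violation flag (fail iff the
#' comparator is violated). Metrics must be on the EQD2 scale, matching
#' the scale constraints are stated on.
#'
#' @param constraints List of \code{\link{constraint_spec}}.
#' @param achieved Named numeric vector (names formatted as
#'   \code{"structure:metric"} or \code{"structure:metric:arg"}), or the
#'   result of \code{\link{plan_metrics}}.
#' @return A data.frame of class \code{constraint_report} with columns
#'   \code{structure}, \code{metric}, \code{arg}, \code{threshold},
#'   \code{achieved}, \code{units}, \code{pass}.
#' @examples
#' cs <- constraint_spec("brain_stem", "Dmax", 54)
#' constraint_report(list(cs), c("brain_stem:Dmax" = 51.49))  # pass
#' constraint_report(list(cs), c("brain_stem:Dmax" = 65.79))  # fail
#' @export
constraint_report <- function(constraints, achieved) {
  if (length(constraints) == 0L)
    return(structure(data.frame(structure = character(0), metric = character(0),
                                arg = numeric(0), threshold = numeric(0),
                                achieved = numeric(0), units = character(0),
                                pass = logical(0)),
                     class = c("constraint_report", "data.frame")))
  rows <- lapply(constraints, function(cs) {
    key <- constraint_key(cs)
    if (!key %in% names(achieved))
      stop("no achieved value for constraint '", key, "'")
    val <- unname(achieved[[key]])
    ok <- if (cs$comparator == "<") val < cs$threshold else val <= cs$threshold
    data.frame(structure = cs$structure, metric = cs$metric,
               arg = if (is.na(cs$arg)) NA_real_ else cs$arg,
               threshold = cs$threshold, achieved = val,
               units = cs$units, pass = ok)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("constraint_report", "data.frame")
  out
}

constraint_key <- function(cs) {
  if (is.na(cs$arg)) paste(cs$structure, cs$metric, sep = ":")
  else paste(cs$structure, cs$metric, cs$arg, sep = ":")
}

#' Compute the metrics a constraint table requires
#'
#' @param dose_map \code{\link{voxel_grid}} on the EQD2 scale.
#' @param structures A \code{\link{structure_set}}.
#' @param constraints List of \code{\link{constraint_spec}}.
#' @return Named numeric vector keyed as \code{constraint_report} expects.
#' @export
plan_metrics <- function(dose_map, structures, constraints) {
  vals <- vapply(constraints, function(cs) {
    if (!cs$structure %in% names(structures$masks))
      stop("structure '", cs$structure, "' not in the structure set")
    dose_metric(dose_map, structures$masks[[cs$structure]], cs$metric,
                arg = if (is.na(cs$arg)) NULL else cs$arg)
  }, numeric(1))
  names(vals) <- vapply(constraints, constraint_key, character(1))
  vals
}

#' Evaluate a plan's constraint table end to end
#'
#' @inheritParams plan_metrics
#' @return A \code{constraint_report} data.frame.
#' @export
evaluate_constraints <- function(dose_map, structures, constraints) {
  constraint_report(constraints, plan_metrics(dose_map, structures, constraints))
}
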