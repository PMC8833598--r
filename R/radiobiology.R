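#' Tissue radiobiology parameters
#'
#' Bundles the linear quadratic model (LQM) coefficients of one structure:
#' the linear coefficient \eqn{\alpha} (1/Gy), the quadratic coefficient
#' \eqn{\beta} (1/Gy^2) and their ratio \eqn{\alpha/\beta} (Gy). Any two of
#' the three determine the third; if all three are supplied they must be
#' mutually consistent.
#'
#' @param name Structure label (character scalar).
#' @param alpha LQM linear coefficient in 1/Gy (> 0).
#' @param beta LQM quadratic coefficient in 1/Gy^2 (> 0).
#' @param alpha_beta Ratio alpha/beta in Gy (> 0). Derived when missing.
#' @return An object of class \code{tissue_params} with fields \code{name},
#'   \code{alpha}, \code{beta}, \code{alpha_beta}.
#' @examples
#' tissue_params("brain_stem", alpha = 0.035, beta = 0.0167)
#' default_tissue_params()
#' @export
tissue_params <- function(name, alpha = NULL, beta = NULL, alpha_beta = NULL) {
  stopifnot(is.character(name), length(name) == 1L)
  n_given <- sum(!vapply(list(alpha, beta, alpha_beta), is.null, logical(1)))
  if (n_given < 2L)
    stop("supply at least two of alpha, beta, alpha_beta")
  if (is.null(alpha)) alpha <- alpha_beta * beta
  if (is.null(beta)) beta <- alpha / alpha_beta
  if (is.null(alpha_beta)) alpha_beta <- alpha / beta
  for (v in c(alpha = alpha, beta = beta, alpha_beta = alpha_beta))
    if (!is.finite(v) || v <= 0) stop("alpha, beta and alpha/beta must be finite and > 0")
  if (abs(alpha_beta - alpha / beta) > 1e-9 * max(1, alpha_beta))
    stop("inconsistent parameters: alpha_beta != alpha/beta for '", name, "'")
  structure(list(name = name, alpha = alpha, beta = beta,
                 alpha_beta = alpha / beta),
            class = "tissue_params")
}

#' @export
print.tissue_params <- function(x, ...) {
  cat(sprintf("<tissue_params> %s: alpha = %g /Gy, beta = %g /Gy^2, alpha/beta = %.4g Gy\n",
              x$name, x$alpha, x$beta, x$alpha_beta))
  invisible(x)
}

#' Default normal-tissue parameters
#'
#' The fallback LQM parameters assigned to voxels not covered by any
#' contour: alpha = 0.1 /Gy, beta = 0.05 /Gy^2 (alpha/beta = 2 Gy), the
#' conventional generic normal-tissue values.
#'
#' @return A \code{tissue_params} object named \code{"default"}.
#' @export
default_tissue_params <- function() {
  tissue_params("default", alpha = 0.1, beta = 0.05)
}

#' Per-voxel dose histogram
#'
#' A weighted histogram of the microscopic dose within one CT-scale voxel:
#' bin doses \eqn{D_i} (Gy, non-decreasing) and volume-fraction weights
#' \eqn{w_i} summing to 1. This is the object the survival-fraction and EUD
#' formulas consume; the canonical reduction uses 35 equal-count groups of
#' the sorted subvoxel doses (see \code{\link{build_histogram}}).
#'
#' @param bin_doses Numeric vector of mean group doses in Gy (non-negative,
#'   non-decreasing).
#' @param bin_weights Numeric vector of volume fractions (> 0, summing to 1).
#'   Defaults to equal weights.
#' @return An object of class \code{dose_histogram}.
#' @examples
#' dose_histogram(c(1, 3))              # two equal-volume compartments
#' @export
dose_histogram <- function(bin_doses,
                           bin_weights = rep(1 / length(bin_doses), length(bin_doses))) {
  bin_doses <- as.numeric(bin_doses)
  bin_weights <- as.numeric(bin_weights)
  if (length(bin_doses) == 0L) stop("histogram needs at least one bin")
  if (length(bin_doses) != length(bin_weights))
    stop("bin_doses and bin_weights differ in length")
  if (any(!is.finite(bin_doses)) || any(bin_doses < 0))
    stop("bin doses must be finite and non-negative")
  if (is.unsorted(bin_doses)) stop("bin doses must be non-decreasing")
  if (any(!is.finite(bin_weights)) || any(bin_weights <= 0))
    stop("bin weights must be finite and positive")
  if (abs(sum(bin_weights) - 1) > 1e-9)
    stop("bin weights must sum to 1 (off by ", format(sum(bin_weights) - 1), ")")
  structure(list(bin_doses = bin_doses, bin_weights = bin_weights,
                 n_bins = length(bin_doses)),
            class = "dose_histogram")
}

#' @export
print.dose_histogram <- function(x, ...) {
  cat(sprintf("<dose_histogram> %d bins, dose range [%.4g, %.4g] Gy, mean %.4g Gy\n",
              x$n_bins, min(x$bin_doses), max(x$bin_doses),
              sum(x$bin_doses * x$bin_weights)))
  invisible(x)
}

## log of the LQM survival sum, accumulated in log space so that bins with
## peak doses of hundreds of Gy underflow gracefully instead of poisoning
## the sum. Returns a finite value for any finite histogram.
log_survival_fraction <- function(hist, params) {
  stopifnot(inherits(hist, "dose_histogram"), inherits(params, "tissue_params"))
  d <- hist$bin_doses
  lt <- log(hist$bin_weights) - params$alpha * d - params$beta * d^2
  m <- max(lt)
  m + log(sum(exp(lt - m)))
}

#' Survival fraction of a heterogeneous dose distribution
#'
#' Evaluates the LQM clonogenic survival of a voxel from its dose histogram:
#' \deqn{SF = \sum_i w_i \exp(-\alpha D_i - \beta D_i^2).}
#' The sum is accumulated in log space, so extreme peak doses underflow to
#' their correct (negligible) contribution. If the total survival is smaller
#' than the smallest representable double, the returned value is 0 and a
#' warning of class \code{mrtdose_sf_underflow} is emitted;
#' \code{\link{eud_from_histogram}} is unaffected because it works with
#' \eqn{\ln SF} directly.
#'
#' @param hist A \code{\link{dose_histogram}}.
#' @param params A \code{\link{tissue_params}} object.
#' @return Survival fraction in (0, 1] (0 only on underflow, with a warning).
#' @examples
#' p <- default_tissue_params()
#' survival_fraction(dose_histogram(2), p)        # exp(-0.4)
#' survival_fraction(dose_histogram(c(1, 3)), p)  # ~0.6665
#' @export
survival_fraction <- function(hist, params) {
  sf <- exp(log_survival_fraction(hist, params))
  if (sf == 0)
    warning(warningCondition(
      "survival fraction underflowed to 0 in double precision; ln(SF) remains finite",
      class = "mrtdose_sf_underflow"))
  sf
}

#' Equivalent uniform dose of a dose histogram
#'
#' The homogeneous dose producing the same LQM cell survival as the
#' heterogeneous distribution described by \code{hist}: the positive root of
#' \eqn{\beta E^2 + \alpha E + \ln SF = 0},
#' \deqn{EUD = -\frac{\alpha}{2\beta} +
#'   \sqrt{\left(\frac{\alpha}{2\beta}\right)^2 - \frac{\ln SF}{\beta}}.}
#' For \eqn{\beta = 0} the quadratic degenerates and the linear limit
#' \eqn{EUD = -\ln SF / \alpha} is used.
#'
#' @inheritParams survival_fraction
#' @return EUD in Gy; always within \code{[min(D_i), max(D_i)]}.
#' @examples
#' p <- default_tissue_params()
#' eud_from_histogram(dose_histogram(rep(5, 35)), p)  # uniform dose: 5
#' eud_from_histogram(dose_histogram(c(1, 3)), p)     # ~2.019
#' @export
eud_from_histogram <- function(hist, params) {
  lsf <- log_survival_fraction(hist, params)
  a <- params$alpha
  b <- params$beta
  eud <- if (b == 0) -lsf / a else -a / (2 * b) + sqrt((a / (2 * b))^2 - lsf / b)
  # guard fp noise at the histogram's support boundary
  min(max(eud, min(hist$bin_doses)), max(hist$bin_doses))
}

#' Equivalent dose in 2 Gy fractions (EQD2)
#'
#' Converts a total dose delivered in fractions of size \code{fraction_dose}
#' to the isoeffective total dose delivered in 2 Gy fractions:
#' \deqn{EQD2 = D \frac{d + \alpha/\beta}{2\,\mathrm{Gy} + \alpha/\beta}.}
#' At \code{fraction_dose = 2} the conversion is the identity. Arguments are
#' recycled elementwise, so whole dose maps convert in one call.
#'
#' @param total_dose Total physical dose D in Gy (>= 0).
#' @param fraction_dose Dose per fraction d in Gy (> 0).
#' @param alpha_beta Tissue alpha/beta ratio in Gy (> 0).
#' @return EQD2 in Gy.
#' @examples
#' eqd2(37.5, 12.5, 10)  # 70.31 Gy: lung SBRT prescription
#' eqd2(20, 20, 3)       # 92 Gy: single-fraction radiosurgery
#' eqd2(60, 2, 2.096)    # 60 Gy: already at reference fractionation
#' @export
eqd2 <- function(total_dose, fraction_dose, alpha_beta) {
  if (any(!is.finite(total_dose)) || any(total_dose < 0))
    stop("total_dose must be finite and >= 0")
  if (any(!is.finite(fraction_dose)) || any(fraction_dose <= 0))
    stop("fraction_dose must be finite and > 0")
  if (any(!is.finite(alpha_beta)) || any(alpha_beta <= 0))
    stop("alpha_beta must be finite and > 0")
  total_dose * (fraction_dose + alpha_beta) / (2 + alpha_beta)
}

#' EQD2 of a single-fraction EUD
#'
#' MRT delivery is modelled as one temporal fraction, so the voxel's whole
#' EUD is its fraction dose: \code{eqd2(eud, eud, alpha_beta)}. An EUD of 0
#' maps to 0.
#'
#' @param eud EUD in Gy (>= 0). Vectorized.
#' @param alpha_beta Tissue alpha/beta ratio in Gy (> 0).
#' @return EQD2 in Gy.
#' @examples
#' eqd2_single_fraction(20, 3)  # 92 Gy
#' eqd2_single_fraction(2, 10)  # 2 Gy: d = 2 is the reference fractionation
#' @export
eqd2_single_fraction <- function(eud, alpha_beta) {
  if (any(!is.finite(eud)) || any(eud < 0))
    stop("eud must be finite and >= 0")
  out <- numeric(length(eud))
  pos <- eud > 0
  if (any(pos)) out[pos] <- eqd2(eud[pos], eud[pos], alpha_beta)
  if (!is.null(dim(eud))) dim(out) <- dim(eud)
  out
}

#' Read a tissue-parameter registry from CSV
#'
#' The file must have columns \code{name}, \code{alpha}, \code{beta} (an
#' optional \code{alpha_beta} column is checked for consistency). A
#' \code{"default"} row is appended with the generic normal-tissue values
#' unless the file provides one.
#'
#' @param path CSV file path. Defaults to the registry shipped with the
#'   package, transcribed from published LQM parameter compilations for the
#'   structures of the five reference treatment scenarios.
#' @return Named list of \code{\link{tissue_params}}, keyed by structure name.
#' @export
read_tissue_table <- function(path = system.file("extdata", "tissue_params.csv",
                                                 package = "mrtdose")) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("name", "alpha", "beta") %in% names(df)))
    stop("tissue table needs columns name, alpha, beta")
  reg <- lapply(seq_len(nrow(df)), function(i)
    tissue_params(df$name[i], alpha = df$alpha[i], beta = df$beta[i],
                  alpha_beta = if ("alpha_beta" %in% names(df)) df$alpha_beta[i]))
  names(reg) <- df$name
  if (!"default" %in% names(reg)) reg$default <- default_tissue_params()
  reg
}

#' Resolve the tissue parameters of a voxel
#'
#' A voxel covered by several contours takes the parameters of the
#' highest-priority label; a voxel covered by none takes the registry's
#' \code{"default"} normal-tissue row. By default targets should be listed
#' before organs at risk in \code{priority}, so that an OAR overlapping the
#' PTV is scored with target parameters inside the overlap.
#'
#' @param voxel_labels Character vector of structure labels covering the
#'   voxel (may be empty).
#' @param registry Named list of \code{\link{tissue_params}} (must contain a
#'   \code{"default"} entry).
#' @param priority Character vector of labels in decreasing priority.
#'   Defaults to the order in which labels appear in \code{voxel_labels}.
#' @return A \code{\link{tissue_params}} object.
#' @export
resolve_tissue_params <- function(voxel_labels, registry,
                                  priority = voxel_labels) {
  if (length(registry) == 0L) stop("empty tissue-parameter registry")
  if (!"default" %in% names(registry))
    stop("registry must contain a 'default' entry")
  hit <- priority[priority %in% voxel_labels & priority %in% names(registry)]
  if (length(hit) == 0L) return(registry$default)
  registry[[hit[[1L]]]]
}
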