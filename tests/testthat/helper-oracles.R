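# Independent oracles and fixture builders shared across the suite.
# These deliberately avoid the package's own computational paths.

# brute-force LQM survival: plain sum of exponential terms
sf_brute <- function(doses, weights, alpha, beta) {
  sum(weights * exp(-alpha * doses - beta * doses^2))
}

# EUD as the bisection root of beta*E^2 + alpha*E + ln(SF) = 0
eud_bisect <- function(lnsf, alpha, beta, hi = 2000, tol = 1e-9) {
  g <- function(E) beta * E^2 + alpha * E + lnsf
  lo <- 0
  if (g(lo) > 0) return(0)
  while (g(hi) < 0) hi <- hi * 2
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    if (g(mid) < 0) lo <- mid else hi <- mid
    if (hi - lo < tol) break
  }
  (lo + hi) / 2
}

# random valid histogram (weights renormalized to sum exactly 1)
random_histogram <- function(n_bins = NULL, max_dose = 600) {
  if (is.null(n_bins)) n_bins <- sample(1:35, 1)
  d <- sort(runif(n_bins, 0, max_dose))
  w <- runif(n_bins, 0.05, 1)
  w <- w / sum(w)
  w[n_bins] <- 1 - sum(w[-n_bins])
  dose_histogram(d, w)
}

# exhaustive-sort dose metrics on equal-volume voxels (step convention)
metric_sort_oracle <- function(doses, metric, arg = NULL, voxel_cc = 1) {
  s <- sort(doses, decreasing = TRUE)
  n <- length(s)
  switch(metric,
    Dmax = max(doses),
    Dmean = mean(doses),
    Dpct = s[ceiling(arg / 100 * n)],
    Dcc = s[which(cumsum(rep(voxel_cc, n)) >= arg - 1e-12)[1]],
    VGy = 100 * sum(doses >= arg) / n)
}

# small water phantom with an off-center target and one overlapping OAR,
# coarse enough for fast engine runs
tiny_phantom <- function() {
  spec <- phantom_spec(
    shape = c(16L, 16L, 3L), spacing = c(3, 3, 3),
    body = list(type = "cylinder", radius = 22, density = 1),
    target = list(label = "ptv_gbm_cavity", center = c(28, 21, 4.5),
                  diameter = 11, semiaxes = c(5.5, 5.5, 4)),
    oars = list(list(label = "brain_stem", center = c(23, 27, 4.5), diameter = 7)))
  generate_phantom(spec, seed = 1)
}

tiny_beams <- function(ph, angles = c(0, 90), entrance = 100, ...) {
  arrange_beams(angles, ph$structures$masks$ptv_gbm_cavity,
                ph$structures$spacing, ph$structures$origin,
                entrance_peak_dose = entrance, ...)
}
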