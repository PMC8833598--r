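#' Reduce subvoxel doses to an equal-count dose histogram
#'
#' Sorts the microscopic dose samples of one voxel in increasing order,
#' partitions them into \code{n_bins} contiguous groups of as-equal-as-
#' possible size, and records each group's mean dose and volume fraction.
#' When the sample count is not divisible by \code{n_bins}, the remainder is
#' distributed one extra sample per group starting from the lowest-dose
#' group, and the weights carry the true group sizes so that weight and mean
#' conservation are exact. With fewer samples than bins the reduction
#' degenerates to one singleton bin per sample.
#'
#' @param block A \code{\link{subvoxel_block}} or a bare numeric vector of
#'   dose samples in Gy.
#' @param n_bins Number of groups; 35 is the canonical CT-voxel reduction.
#' @return A \code{\link{dose_histogram}} with at most \code{n_bins} bins.
#' @examples
#' h <- build_histogram(c(rep(5, 300), rep(100, 50)))
#' h$bin_doses[c(1, 35)]   # 5 and 100
#' @export
build_histogram <- function(block, n_bins = 35L) {
  doses <- if (inherits(block, "subvoxel_block")) block$sample_doses else as.numeric(block)
  n <- length(doses)
  if (n == 0L) stop("block contains no dose samples")
  if (any(!is.finite(doses)) || any(doses < 0))
    stop("dose samples must be finite and non-negative")
  n_bins <- as.integer(n_bins)
  if (n_bins < 1L) stop("n_bins must be >= 1")
  doses <- sort(doses)
  k <- min(n_bins, n)
  base <- n %/% k
  rem <- n %% k
  sizes <- rep(base, k) + c(rep(1L, rem), rep(0L, k - rem))
  grp <- rep.int(seq_len(k), sizes)
  means <- as.numeric(vapply(split(doses, grp), mean, numeric(1)))
  w <- sizes / n
  # absorb the rounding residual (at most 1 ulp) so the weights total exactly 1
  if (k > 1L) w[k] <- 1 - sum(w[-k])
  dose_histogram(means, w)
}
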