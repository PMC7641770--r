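# Charge-ladder deconvolution of ESI spectra: a deterministic grid scorer
# that sums, for each candidate neutral mass, the interpolated spectrum
# intensity at every protonated charge state, then reports refined local
# maxima. A reproducible, testable alternative to maximum-entropy
# deconvolution, adequate for spectra with a few well-separated species.

#' Read a peak list from TSV
#'
#' Two columns (m/z, intensity); lines starting with \code{#} ignored.
#' @param path TSV file.
#' @return data.frame with columns \code{mz}, \code{intensity}, sorted by
#'   ascending \code{mz}.
#' @export
read_peaklist_tsv <- function(path) {
  df <- utils::read.delim(path, comment.char = "#", header = TRUE,
                          stringsAsFactors = FALSE)
  names(df)[1:2] <- c("mz", "intensity")
  .validate_peaklist(df)
}

#' Write a peak list to TSV
#' @param peaks data.frame with \code{mz}, \code{intensity}.
#' @param path Output file.
#' @return \code{path}, invisibly.
#' @export
write_peaklist_tsv <- function(peaks, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# ESI peak list; mz in Th (Da/charge), arbitrary intensity", con)
  utils::write.table(peaks, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

.validate_peaklist <- function(peaks) {
  stopifnot(is.data.frame(peaks), all(c("mz", "intensity") %in% names(peaks)))
  if (nrow(peaks) == 0L) stop("empty peak list")
  if (is.unsorted(peaks$mz, strictly = TRUE)) {
    peaks <- peaks[order(peaks$mz), , drop = FALSE]
    if (anyDuplicated(peaks$mz)) stop("duplicate m/z values in peak list")
  }
  if (any(peaks$intensity < 0)) stop("negative intensities in peak list")
  peaks
}

#' Deconvolute an ESI charge ladder to neutral masses
#'
#' For every candidate mass M on a grid over \code{mass_window}, scores
#' \eqn{S(M) = \sum_z I((M + z m_p)/z)} over charges \code{z_min..z_max}
#' whose m/z falls inside the instrument range, with \eqn{I} the linearly
#' interpolated peak-list intensity and \eqn{m_p} the proton mass
#' (positive mode, protonation only). Local maxima of S above a
#' noise-adaptive threshold are refined by parabolic interpolation.
#'
#' @param peaks data.frame (\code{mz}, \code{intensity}) or a peak-list
#'   TSV path.
#' @param z_min,z_max Charge-state range (default 5-30, \code{z_min >= 1}).
#' @param mass_window Length-2 numeric, lo < hi, neutral-mass search
#'   window in Da.
#' @param grid_step Mass grid step in Da (default 0.1).
#' @param mz_range Instrument m/z range (default 600-2000).
#' @param min_rel_score Local maxima below \code{min_rel_score * max(S)}
#'   and below the noise floor (median + 5 MAD of S) are discarded.
#' @param min_support Minimum fraction of the visible charge states that
#'   must carry intensity at the candidate mass (default 0.8). A real
#'   species produces a peak at essentially every charge state whose m/z
#'   is in range, whereas harmonic ghosts (masses at small rational
#'   multiples of a true mass, e.g. M/2 or 2M/3) align with only a
#'   subset of the ladder; this filter removes them.
#' @return data.frame with columns \code{mass} (refined, Da),
#'   \code{score}, and \code{support} (fraction of visible charge states
#'   with intensity), sorted by decreasing score.
#' @export
deconvolve_charge_ladder <- function(peaks, z_min = 5L, z_max = 30L,
                                     mass_window, grid_step = 0.1,
                                     mz_range = c(600, 2000),
                                     min_rel_score = 0.25,
                                     min_support = 0.8) {
  if (is.character(peaks)) peaks <- read_peaklist_tsv(peaks)
  peaks <- .validate_peaklist(peaks)
  stopifnot(z_min >= 1L, z_max >= z_min, grid_step > 0)
  if (length(mass_window) != 2L || mass_window[1] >= mass_window[2]) {
    stop("mass_window must be (lo, hi) with lo < hi")
  }
  grid <- seq(mass_window[1], mass_window[2], by = grid_step)
  score <- numeric(length(grid))
  for (z in seq.int(z_min, z_max)) {
    mz <- (grid + z * PROTON_MASS) / z
    inside <- mz >= mz_range[1] & mz <= mz_range[2]
    if (!any(inside)) next
    y <- stats::approx(peaks$mz, peaks$intensity, xout = mz[inside],
                       yleft = 0, yright = 0, ties = "ordered")$y
    score[inside] <- score[inside] + y
  }
  if (all(score == 0)) {
    return(data.frame(mass = numeric(0), score = numeric(0)))
  }
  noise_floor <- stats::median(score) + 5 * stats::mad(score)
  threshold <- max(noise_floor, min_rel_score * max(score))
  n <- length(score)
  is_peak <- rep(FALSE, n)
  if (n >= 3) {
    interior <- 2:(n - 1)
    is_peak[interior] <- score[interior] >= score[interior - 1] &
      score[interior] > score[interior + 1] &
      score[interior] >= threshold
  }
  idx <- which(is_peak)
  if (length(idx) == 0L) {
    return(data.frame(mass = numeric(0), score = numeric(0),
                      support = numeric(0)))
  }
  # parabolic vertex through the three grid points around each maximum
  refine <- vapply(idx, function(i) {
    y1 <- score[i - 1]; y2 <- score[i]; y3 <- score[i + 1]
    denom <- y1 - 2 * y2 + y3
    delta <- if (denom == 0) 0 else 0.5 * (y1 - y3) / denom
    delta <- max(-0.5, min(0.5, delta))
    grid[i] + delta * grid_step
  }, numeric(1))
  support <- vapply(refine, function(m) {
    mz <- (m + seq.int(z_min, z_max) * PROTON_MASS) / seq.int(z_min, z_max)
    vis <- mz >= mz_range[1] & mz <= mz_range[2]
    if (!any(vis)) return(0)
    y <- stats::approx(peaks$mz, peaks$intensity, xout = mz[vis],
                       yleft = 0, yright = 0, ties = "ordered")$y
    if (!any(y > 0)) return(0)
    mean(y >= 0.05 * stats::median(y[y > 0]))
  }, numeric(1))
  out <- data.frame(mass = refine, score = score[idx], support = support)
  out <- out[out$support >= min_support, , drop = FALSE]
  out <- out[order(-out$score), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write deconvoluted masses to TSV
#' @param masses data.frame with \code{mass}, \code{score}.
#' @param path Output file.
#' @return \code{path}, invisibly.
#' @export
write_masses_tsv <- function(masses, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# deconvoluted neutral masses (Da) with ladder scores", con)
  utils::write.table(masses, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
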