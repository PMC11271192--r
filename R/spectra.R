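# 1D urine spectra: synthesis, total-intensity normalization, and
# fixed-width binning into 290 buckets of 0.03 ppm over [0.5, 9.5] ppm
# with the water region (4.7, 5.0) excluded.

BIN_WIDTH <- 0.03
PPM_MIN <- 0.5
PPM_MAX <- 9.5
WATER_LO <- 4.7
WATER_HI <- 5.0

new_spectrum <- function(ppm, intensity) {
  if (length(ppm) == 0L) stop("spectrum axis is empty")
  if (length(ppm) != length(intensity)) {
    stop("ppm and intensity must have equal length")
  }
  d <- diff(ppm)
  if (!(all(d > 0) || all(d < 0))) stop("ppm grid must be strictly monotone")
  if (any(!is.finite(intensity))) stop("intensities must be finite")
  structure(list(ppm = as.numeric(ppm), intensity = as.numeric(intensity)),
            class = "nmr_spectrum")
}

#' @export
print.nmr_spectrum <- function(x, ...) {
  cat("1D NMR spectrum: ", length(x$ppm), " points, ",
      sprintf("%.3f..%.3f ppm", min(x$ppm), max(x$ppm)), "\n", sep = "")
  invisible(x)
}

#' Simulate a 1D urine spectrum as a sum of Gaussian peaks
#'
#' Each peak contributes `amplitude * exp(-(ppm - center)^2 / (2 width^2))`;
#' Gaussian white noise of standard deviation `noise_sd` is added and the
#' result clipped at zero (intensities are nonnegative). This emulates a
#' processed 1D spectrum only at the resolution the binning needs: no
#' J-coupling, lineshape or baseline artifacts are simulated.
#'
#' @param peaks data frame with columns `center` (ppm), `width` (ppm, > 0)
#'   and `amplitude`; zero rows give a flat spectrum.
#' @param axis strictly monotone ppm grid.
#' @param noise_sd nonnegative noise standard deviation.
#' @param seed integer seed.
#' @return An `nmr_spectrum`.
#' @export
generate_urine_spectrum <- function(peaks, axis, noise_sd = 0, seed = 1L) {
  if (length(axis) == 0L) stop("spectrum axis is empty")
  peaks <- as.data.frame(peaks)
  if (nrow(peaks) > 0L) {
    stopifnot(all(c("center", "width", "amplitude") %in% names(peaks)))
    if (any(peaks$width <= 0)) stop("peak widths must be > 0")
  }
  y <- rep(0, length(axis))
  for (i in seq_len(nrow(peaks))) {
    y <- y + peaks$amplitude[i] *
      exp(-(axis - peaks$center[i])^2 / (2 * peaks$width[i]^2))
  }
  if (noise_sd > 0) {
    y <- y + with_seed(seed, stats::rnorm(length(axis), sd = noise_sd))
  }
  new_spectrum(axis, pmax(y, 0))
}

# Bin edges for the two retained segments, shared by the bin table, the
# binning itself and the retained-region mask so boundary handling is
# bitwise consistent.
bin_edges <- function() {
  list(seq(PPM_MIN, WATER_LO, by = BIN_WIDTH),   # 141 edges, 140 bins
       seq(WATER_HI, PPM_MAX, by = BIN_WIDTH))   # 151 edges, 150 bins
}

retained_region <- function(ppm) {
  e <- bin_edges()
  (ppm >= e[[1L]][1L] & ppm < e[[1L]][length(e[[1L]])]) |
    (ppm >= e[[2L]][1L] & ppm <= e[[2L]][length(e[[2L]])])
}

#' Normalize a spectrum by total intensity
#'
#' Divides all intensities by the total intensity of the analysed region
#' ([0.5, 9.5] ppm minus the water window), so the retained intensities
#' sum to one. The water window is discarded from analysis and therefore
#' excluded from the total.
#'
#' @param spectrum an `nmr_spectrum`.
#' @return Normalized `nmr_spectrum`.
#' @export
normalize_total_intensity <- function(spectrum) {
  stopifnot(inherits(spectrum, "nmr_spectrum"))
  total <- sum(spectrum$intensity[retained_region(spectrum$ppm)])
  if (total <= 0) stop("total intensity over the retained region is zero")
  new_spectrum(spectrum$ppm, spectrum$intensity / total)
}

#' Bin definitions for the 290 fixed-width urine buckets
#'
#' Two contiguous segments of 0.03-ppm bins: 140 bins covering
#' [0.5, 4.7) and 150 bins covering [5.0, 9.5], excluding the water
#' region. Bins are half-open `[lo, hi)`; the final bin is closed so the
#' segments cover their ranges exhaustively. Each bin is named by its
#' center, which covers 0.015 ppm to either side.
#'
#' @return Tibble with columns `name`, `lo`, `hi`, `center`.
#' @export
bin_definitions <- function() {
  seg <- function(edges) {
    tibble::tibble(lo = edges[-length(edges)], hi = edges[-1L],
                   center = edges[-length(edges)] + BIN_WIDTH / 2)
  }
  e <- bin_edges()
  bins <- rbind(seg(e[[1L]]), seg(e[[2L]]))
  bins$name <- sprintf("bin_%.3f", bins$center)
  bins[, c("name", "lo", "hi", "center")]
}

#' Bin a spectrum into the 290 fixed-width buckets
#'
#' Each bin collects the summed intensity of the grid points whose ppm
#' falls in its half-open interval (final bin closed). The grid must
#' cover [0.5, 9.5] ppm. Summing all bins recovers the total intensity
#' of the retained region exactly.
#'
#' @param spectrum an `nmr_spectrum` covering [0.5, 9.5] ppm.
#' @return Object of class `bin_table`: tibble with `name`, `lo`, `hi`,
#'   `center`, `intensity`.
#' @export
bin_spectrum <- function(spectrum) {
  stopifnot(inherits(spectrum, "nmr_spectrum"))
  if (min(spectrum$ppm) > PPM_MIN || max(spectrum$ppm) < PPM_MAX) {
    stop(sprintf("spectrum grid [%.3f, %.3f] does not cover [%.1f, %.1f] ppm",
                 min(spectrum$ppm), max(spectrum$ppm), PPM_MIN, PPM_MAX))
  }
  bins <- bin_definitions()
  e <- bin_edges()
  seg_sums <- function(edges, closed_right) {
    k <- length(edges) - 1L
    idx <- findInterval(spectrum$ppm, edges,
                        rightmost.closed = closed_right)
    keep <- idx >= 1L & idx <= k
    vapply(seq_len(k), function(i) sum(spectrum$intensity[keep & idx == i]),
           numeric(1))
  }
  bins$intensity <- c(seg_sums(e[[1L]], FALSE), seg_sums(e[[2L]], TRUE))
  class(bins) <- c("bin_table", class(bins))
  bins
}

#' Normalize and bin a set of spectra into a wide bin matrix
#'
#' Convenience wrapper: each spectrum is total-intensity normalized,
#' binned, and the bin intensities collected into a samples x 290
#' matrix with bin names as columns.
#'
#' @param spectra named list of `nmr_spectrum` objects.
#' @return Numeric matrix (samples x bins).
#' @export
bin_spectra_matrix <- function(spectra) {
  stopifnot(is.list(spectra), length(spectra) > 0L)
  rows <- lapply(spectra, function(s) bin_spectrum(normalize_total_intensity(s))$intensity)
  m <- do.call(rbind, rows)
  colnames(m) <- bin_definitions()$name
  rownames(m) <- names(spectra)
  m
}
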