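#' Time-resolved difference-spectrum series
#'
#' Container for a wavelength x time-delay matrix of difference absorbances
#' (Delta OD), optionally carrying the individual repeat measurements the
#' matrix was averaged from.
#'
#' @param wavelengths numeric vector of wavelengths in nm, strictly increasing.
#' @param delays numeric vector of pump-probe delays in ms, strictly
#'   increasing, all >= 0.
#' @param D numeric matrix of difference absorbance, one row per wavelength
#'   and one column per delay.
#' @param repeats optional 3-d array (`length(wavelengths)` x `length(delays)`
#'   x n_repeats) of individual repeat matrices.
#' @return An object of class `"spectral_series"`.
#' @export
spectral_series <- function(wavelengths, delays, D, repeats = NULL) {
  wavelengths <- as.numeric(wavelengths)
  delays <- as.numeric(delays)
  D <- as.matrix(D)
  if (any(diff(wavelengths) <= 0)) stop("wavelengths must be strictly increasing")
  if (any(diff(delays) <= 0)) stop("delays must be strictly increasing")
  if (any(delays < 0)) stop("delays must be >= 0 ms")
  if (nrow(D) != length(wavelengths) || ncol(D) != length(delays))
    stop("D must be |wavelengths| x |delays|")
  if (!all(is.finite(D))) stop("D contains non-finite values")
  if (!is.null(repeats)) {
    repeats <- as.array(repeats)
    if (length(dim(repeats)) != 3 ||
        dim(repeats)[1] != length(wavelengths) ||
        dim(repeats)[2] != length(delays))
      stop("repeats must be a |wavelengths| x |delays| x n array")
    if (!all(is.finite(repeats))) stop("repeats contain non-finite values")
  }
  structure(list(wavelengths = wavelengths, delays = delays, D = D,
                 repeats = repeats),
            class = "spectral_series")
}

#' @export
print.spectral_series <- function(x, ...) {
  cat("Difference-spectrum series:", length(x$wavelengths), "wavelengths (",
      min(x$wavelengths), "-", max(x$wavelengths), "nm ) x",
      length(x$delays), "delays (", min(x$delays), "-", max(x$delays), "ms )\n")
  if (!is.null(x$repeats))
    cat("  carrying", dim(x$repeats)[3], "repeat measurements\n")
  cat("  Delta OD range:", signif(min(x$D), 3), "to", signif(max(x$D), 3), "\n")
  invisible(x)
}

#' Average repeat measurements with outlier rejection
#'
#' Repeats whose root-mean-square deviation from the element-wise median
#' matrix exceeds `rejection_k` times the median of all repeats' RMS
#' deviations are discarded; the remainder are averaged.
#'
#' @param repeats a `spectral_series` carrying a repeat stack, or a 3-d array
#'   of repeat matrices (wavelength x delay x repeat).
#' @param rejection_k positive multiplier on the median RMS deviation above
#'   which a repeat is rejected (default 3).
#' @param wavelengths,delays axes, required when `repeats` is a bare array.
#' @return A `spectral_series` whose `D` is the mean of the retained repeats,
#'   with attributes `n_retained` and `retained` (logical index).
#' @export
average_repeats <- function(repeats, rejection_k = 3,
                            wavelengths = NULL, delays = NULL) {
  if (inherits(repeats, "spectral_series")) {
    wavelengths <- repeats$wavelengths
    delays <- repeats$delays
    stack <- repeats$repeats
    if (is.null(stack)) stop("series carries no repeat stack")
  } else {
    stack <- as.array(repeats)
    if (is.null(wavelengths) || is.null(delays))
      stop("wavelengths and delays required with a bare repeat array")
  }
  if (rejection_k <= 0) stop("rejection_k must be positive")
  n <- dim(stack)[3]
  if (n < 2) stop("need at least 2 repeats")
  med <- apply(stack, c(1, 2), stats::median)
  rms_dev <- vapply(seq_len(n),
                    function(i) sqrt(mean((stack[, , i] - med)^2)),
                    numeric(1))
  cutoff <- rejection_k * stats::median(rms_dev)
  keep <- rms_dev <= cutoff
  if (!any(keep))
    stop(sprintf("all repeats rejected at threshold %.3g (k = %g)",
                 cutoff, rejection_k))
  Dbar <- apply(stack[, , keep, drop = FALSE], c(1, 2), mean)
  out <- spectral_series(wavelengths, delays, Dbar,
                         repeats = stack[, , keep, drop = FALSE])
  attr(out, "n_retained") <- sum(keep)
  attr(out, "retained") <- keep
  out
}

#' Truncated singular value decomposition of a spectral series
#'
#' @param x a `spectral_series` or numeric matrix.
#' @param rank number of leading components to keep.
#' @return list with `u` (left vectors), `d` (all singular values), `v`
#'   (right vectors); `u` and `v` are truncated to `rank` columns, `d` is
#'   returned in full so rank-gap diagnostics remain available.
#' @export
svd_truncate <- function(x, rank) {
  D <- if (inherits(x, "spectral_series")) x$D else as.matrix(x)
  if (!all(is.finite(D))) stop("matrix contains non-finite entries")
  rank <- as.integer(rank)
  if (rank < 1 || rank > min(dim(D))) stop("rank out of range")
  s <- svd(D)
  list(u = s$u[, seq_len(rank), drop = FALSE],
       d = s$d,
       v = s$v[, seq_len(rank), drop = FALSE])
}

#' Read / write a spectral series as CSV
#'
#' Format: first column the wavelength in nm, remaining columns one per
#' delay, header row giving the delays in ms, cells Delta OD.
#'
#' @param path file path.
#' @rdname spectra_io
#' @export
read_spectra <- function(path) {
  tab <- tryCatch(utils::read.csv(path, check.names = FALSE),
                  error = function(e) stop("malformed spectra file '", path,
                                           "': ", conditionMessage(e)))
  if (nrow(tab) == 0 || ncol(tab) < 2)
    stop("spectra file '", path, "' has no data (need wavelength column + >=1 delay column)")
  delays <- suppressWarnings(as.numeric(colnames(tab)[-1]))
  if (any(is.na(delays)))
    stop("spectra file '", path, "': header must give numeric delays in ms")
  spectral_series(tab[[1]], delays, as.matrix(tab[, -1, drop = FALSE]))
}

#' @param series a `spectral_series`.
#' @rdname spectra_io
#' @export
write_spectra <- function(series, path) {
  tab <- data.frame(wavelength_nm = series$wavelengths, series$D,
                    check.names = FALSE)
  colnames(tab) <- c("wavelength_nm", format(series$delays, trim = TRUE))
  utils::write.csv(tab, path, row.names = FALSE)
  invisible(path)
}
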