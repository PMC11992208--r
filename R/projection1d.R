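#' Project difference density onto the protein sequence
#'
#' Every grid point with `|value| >= threshold_sigma * sigma` lying within
#' `cutoff_A` of any model atom is assigned to exactly one residue — that of
#' its nearest atom, ties broken by the lowest atom serial (table order) —
#' and its `|value|` accumulated into the residue's positive or negative
#' amplitude according to sign. Above-threshold density farther than the
#' cutoff from every atom is dropped and its total reported, so
#' `sum(pos_amp + neg_amp) + dropped` conserves the above-threshold
#' amplitude exactly.
#'
#' @param map a [real_space_map()].
#' @param sites atom table with columns `chain`, `resid`, `atom`, `fx`, `fy`,
#'   `fz`; hydrogens should already be excluded.
#' @param threshold_sigma contour threshold in sigma units (default 3).
#' @param cutoff_A assignment radius in Angstrom (default 2).
#' @return object of class `"sequence_profile"`: data.frame with one row per
#'   residue in the model (`chain`, `resid`, `pos_amp`, `neg_amp`), with
#'   attributes `params` and `dropped_amplitude`.
#' @export
project_to_sequence <- function(map, sites, threshold_sigma = 3,
                                cutoff_A = 2) {
  stopifnot(threshold_sigma > 0, cutoff_A > 0)
  if (nrow(sites) == 0) stop("empty model")
  res_key <- paste(sites$chain, sites$resid)
  res_tab <- unique(data.frame(chain = sites$chain, resid = sites$resid,
                               stringsAsFactors = FALSE))
  prof <- data.frame(chain = res_tab$chain, resid = res_tab$resid,
                     pos_amp = 0, neg_amp = 0, stringsAsFactors = FALSE)
  dropped <- 0
  sel <- which(abs(map$values) >= threshold_sigma * map$sigma & map$sigma > 0)
  if (length(sel) > 0) {
    idx <- arrayInd(sel, map$dim)
    frac <- sweep(idx - 1, 2, map$dim, "/")
    vals <- as.numeric(map$values)[sel]
    at_frac <- as.matrix(sites[, c("fx", "fy", "fz")])
    dist <- .min_image_dist(map$cell, frac, at_frac)
    nearest <- apply(dist, 1, which.min)  # which.min takes the first = lowest serial on ties
    dmin <- dist[cbind(seq_along(nearest), nearest)]
    within <- dmin <= cutoff_A
    dropped <- sum(abs(vals[!within]))
    if (any(within)) {
      key <- paste(res_tab$chain, res_tab$resid)
      ri <- match(res_key[nearest[within]], key)
      v <- vals[within]
      pos <- tapply(abs(v) * (v > 0), ri, sum)
      neg <- tapply(abs(v) * (v < 0), ri, sum)
      prof$pos_amp[as.integer(names(pos))] <- as.numeric(pos)
      prof$neg_amp[as.integer(names(neg))] <- as.numeric(neg)
    }
  }
  structure(prof,
            params = list(threshold_sigma = threshold_sigma,
                          cutoff_A = cutoff_A),
            dropped_amplitude = dropped,
            class = c("sequence_profile", "data.frame"))
}

#' Pearson correlation between two sequence profiles
#'
#' Correlates the concatenated (positive, negative) amplitude vectors of two
#' profiles on identical residue axes — the statistic used to ask whether
#' difference-density distributions at different time points report the same
#' structural changes.
#'
#' @param p1,p2 `sequence_profile`s with identical residue axes.
#' @return Pearson r in `[-1, 1]`, or `NA` (undefined) for zero-variance
#'   input.
#' @export
profile_correlation <- function(p1, p2) {
  if (!identical(paste(p1$chain, p1$resid), paste(p2$chain, p2$resid)))
    stop("profiles are on different residue axes")
  v1 <- c(p1$pos_amp, p1$neg_amp)
  v2 <- c(p2$pos_amp, p2$neg_amp)
  if (stats::sd(v1) == 0 || stats::sd(v2) == 0) return(NA_real_)
  stats::cor(v1, v2)
}

#' Mean profile amplitude over a residue region
#'
#' Arithmetic mean of `pos_amp + neg_amp` over the inclusive residue range.
#'
#' @param profile a `sequence_profile`.
#' @param first,last inclusive residue-id range, or a one-row region
#'   data.frame with columns `first` and `last` as `first`.
#' @return mean amplitude.
#' @export
region_mean_amplitude <- function(profile, first, last = NULL) {
  if (is.data.frame(first)) {
    last <- first$last[1]; first <- first$first[1]
  }
  stopifnot(first <= last)
  sel <- profile$resid >= first & profile$resid <= last
  if (!any(sel)) stop("region does not intersect the profile")
  mean(profile$pos_amp[sel] + profile$neg_amp[sel])
}

#' Transmembrane helix boundaries of the NpSRII model
#'
#' Residue ranges of the seven transmembrane helices used to annotate
#' sequence-projected difference density.
#'
#' @return data.frame with `label`, `first`, `last` (inclusive).
#' @export
srii_helices <- function() {
  data.frame(label = c("A", "B", "C", "D", "E", "F", "G"),
             first = c(3, 33, 70, 94, 122, 153, 189),
             last = c(26, 56, 92, 118, 150, 181, 219),
             stringsAsFactors = FALSE)
}

#' Named NpSRII regions for time-course averaging of difference density
#'
#' The four regions whose mean difference-density amplitude is tracked over
#' time: the extracellular portion of helix C (Pro71-Pro81), the
#' extracellular portions of helices D/E (Val118-Tyr124), the cytoplasmic
#' portion of helix F plus the F/G loop (Gly143-Pro171), and the mid-portion
#' of helix G (Ile197-Leu213).
#'
#' @return data.frame with `label`, `first`, `last` (inclusive).
#' @export
srii_regions <- function() {
  data.frame(label = c("helixC_EC", "helixDE_EC", "helixF_FG", "helixG_mid"),
             first = c(71, 118, 143, 197),
             last = c(81, 124, 171, 213),
             stringsAsFactors = FALSE)
}

#' Read / write a sequence profile as CSV
#'
#' @param path file path.
#' @rdname profile_io
#' @export
read_profile <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("chain", "resid", "pos_amp", "neg_amp")
  if (!all(need %in% names(tab)))
    stop("profile file '", path, "' must have columns ",
         paste(need, collapse = ", "))
  structure(tab[, need], class = c("sequence_profile", "data.frame"))
}

#' @param profile a `sequence_profile`.
#' @rdname profile_io
#' @export
write_profile <- function(profile, path) {
  utils::write.csv(as.data.frame(profile)[, c("chain", "resid", "pos_amp",
                                              "neg_amp")],
                   path, row.names = FALSE)
  invisible(path)
}
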