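#' Real-space map on a periodic fractional grid
#'
#' @param cell unit cell (a, b, c, alpha, beta, gamma).
#' @param values 3-d numeric array of density values; axis i spans fractional
#'   coordinate `(0:(n_i-1))/n_i`.
#' @return object of class `"real_space_map"` with `sigma` the root mean
#'   square of the grid values (the map-normalisation unit).
#' @export
real_space_map <- function(cell, values) {
  .check_cell(cell)
  values <- as.array(values)
  if (length(dim(values)) != 3) stop("values must be a 3-d array")
  if (!all(is.finite(values))) stop("map values must be finite")
  structure(list(cell = as.numeric(cell), dim = dim(values), values = values,
                 sigma = sqrt(mean(values^2))),
            class = "real_space_map")
}

#' @export
print.real_space_map <- function(x, ...) {
  cat(sprintf("Real-space map: %d x %d x %d grid, sigma (rms) = %.4g\n",
              x$dim[1], x$dim[2], x$dim[3], x$sigma))
  invisible(x)
}

# grid dimensions giving spacing <= d_min/3 along each cell axis
.grid_for <- function(cell, d_min) {
  pmax(4L, as.integer(ceiling(3 * cell[1:3] / d_min)))
}

# canonical Friedel half-set selector: TRUE for the representative of each pair
.friedel_half <- function(hkl) {
  (hkl[, 1] > 0) |
    (hkl[, 1] == 0 & hkl[, 2] > 0) |
    (hkl[, 1] == 0 & hkl[, 2] == 0 & hkl[, 3] > 0)
}

# inverse Fourier synthesis of complex coefficients onto a periodic grid:
# rho(x) = (1/V) sum_h F(h) exp(-2 pi i h.x), with Friedel mates added so the
# synthesis is real. `hkl` must contain one representative per Friedel pair.
.fourier_synthesis <- function(cell, hkl, coeff, dim) {
  A <- array(0 + 0i, dim = dim)
  idx <- cbind(hkl[, 1] %% dim[1], hkl[, 2] %% dim[2], hkl[, 3] %% dim[3]) + 1L
  idxm <- cbind((-hkl[, 1]) %% dim[1], (-hkl[, 2]) %% dim[2],
                (-hkl[, 3]) %% dim[3]) + 1L
  for (i in seq_len(nrow(hkl))) {
    A[idx[i, 1], idx[i, 2], idx[i, 3]] <-
      A[idx[i, 1], idx[i, 2], idx[i, 3]] + coeff[i]
    A[idxm[i, 1], idxm[i, 2], idxm[i, 3]] <-
      A[idxm[i, 1], idxm[i, 2], idxm[i, 3]] + Conj(coeff[i])
  }
  # fft computes sum_n A[n] exp(-2 pi i k.n/N): with A[h] = F(h) this is
  # exactly sum_h F(h) exp(-2 pi i h.x) at x = k/N
  Re(stats::fft(A)) / cell_volume(cell)
}

#' Isomorphous difference Fourier map Fo(light) - Fo(dark)
#'
#' Scales the light amplitudes onto the dark set, forms difference
#' coefficients `(F_light - F_dark) exp(i phi_dark)` over the common indices,
#' and synthesises the real-space difference density by inverse FFT with
#' Friedel completion. The map is annotated with its rms `sigma`, the unit in
#' which difference features are conventionally contoured (+/- 3 sigma).
#'
#' @param light,dark `reflection_set`s of the two states.
#' @param phases `phase_set` of dark-model phases covering the common indices.
#' @param d_min optional high-resolution cutoff in Angstrom, applied
#'   symmetrically to both sets before scaling (default: use all common
#'   reflections).
#' @param grid optional grid dimensions (length-3 integer); default gives
#'   spacing `d_min/3`.
#' @param scale_mode amplitude scaling mode, see [scale_amplitudes()]; use
#'   `"none"` to skip scaling.
#' @return a [real_space_map()].
#' @export
compute_difference_map <- function(light, dark, phases, d_min = NULL,
                                   grid = NULL,
                                   scale_mode = c("global", "shells", "none")) {
  scale_mode <- match.arg(scale_mode)
  if (!is.null(d_min)) {
    keep_l <- d_spacing(light$cell, light$hkl) >= d_min
    light <- reflection_set(light$cell, light$hkl[keep_l, , drop = FALSE],
                            light$f[keep_l], light$sigf[keep_l])
    keep_d <- d_spacing(dark$cell, dark$hkl) >= d_min
    dark <- reflection_set(dark$cell, dark$hkl[keep_d, , drop = FALSE],
                           dark$f[keep_d], dark$sigf[keep_d])
  }
  if (scale_mode == "none") {
    key_l <- .hkl_key(light$hkl); key_d <- .hkl_key(dark$hkl)
    common <- intersect(key_l, key_d)
    if (length(common) == 0) stop("no common indices between the two sets")
    il <- match(common, key_l); id <- match(common, key_d)
    hkl <- light$hkl[il, , drop = FALSE]
    df <- light$f[il] - dark$f[id]
  } else {
    sc <- scale_amplitudes(light, dark, mode = scale_mode)
    hkl <- sc$light$hkl
    df <- sc$light$f - sc$dark$f
  }
  # drop F(000) and keep one representative per Friedel pair
  zero <- rowSums(abs(hkl)) == 0
  hkl <- hkl[!zero, , drop = FALSE]; df <- df[!zero]
  half <- .friedel_half(hkl)
  if (!all(half)) {
    # fold any -h representatives onto the canonical half (phases conjugate)
    key <- .hkl_key(hkl)
    key_m <- .hkl_key(-hkl)
    dup <- !half & key_m %in% key[half]
    hkl <- hkl[half | !dup, , drop = FALSE]
    df <- df[half | !dup]
    flip <- !.friedel_half(hkl)
    hkl[flip, ] <- -hkl[flip, , drop = FALSE]
  }
  key_p <- .hkl_key(phases$hkl)
  ip <- match(.hkl_key(hkl), key_p)
  if (anyNA(ip)) {
    # allow phases supplied for the Friedel mate: phi(-h) = -phi(h)
    im <- match(.hkl_key(-hkl), key_p)
    miss <- which(is.na(ip))
    ip[miss] <- im[miss]
    conj_sign <- rep(1, length(ip)); conj_sign[miss] <- -1
    if (anyNA(ip)) {
      i <- which(is.na(ip))[1]
      stop(sprintf("missing phase for retained reflection (%d %d %d)",
                   hkl[i, 1], hkl[i, 2], hkl[i, 3]))
    }
    phi <- conj_sign * phases$phi[ip]
  } else {
    phi <- phases$phi[ip]
  }
  if (is.null(grid)) {
    dm <- if (is.null(d_min)) min(d_spacing(light$cell, hkl)) else d_min
    grid <- .grid_for(light$cell, dm)
  }
  coeff <- df * exp(1i * phi * pi / 180)
  real_space_map(light$cell,
                 .fourier_synthesis(light$cell, hkl, coeff, as.integer(grid)))
}

# fractional coordinates of all grid points of a map (n x 3)
.grid_frac <- function(map) {
  d <- map$dim
  cbind(rep((0:(d[1] - 1)) / d[1], times = d[2] * d[3]),
        rep(rep((0:(d[2] - 1)) / d[2], each = d[1]), times = d[3]),
        rep((0:(d[3] - 1)) / d[3], each = d[1] * d[2]))
}

# minimum-image distances (Angstrom) from each row of frac_a to each row of
# frac_b; fractional differences wrapped to [-0.5, 0.5) before
# orthogonalization (exact for orthorhombic cells)
.min_image_dist <- function(cell, frac_a, frac_b) {
  O <- orthogonalization_matrix(cell)
  na <- nrow(frac_a); nb <- nrow(frac_b)
  out <- matrix(0, na, nb)
  for (j in seq_len(nb)) {
    d <- sweep(frac_a, 2, frac_b[j, ])
    d <- d - round(d)
    xyz <- d %*% t(O)
    out[, j] <- sqrt(rowSums(xyz^2))
  }
  out
}

#' Search a difference map for significant density features
#'
#' Finds grid-point local extrema with `|value| >= threshold_sigma * sigma`
#' (26-neighbour periodic comparison), merges same-sign extrema within
#' 1.5 Angstrom keeping the strongest, and assigns each feature to the
#' nearest atom of the model.
#'
#' @param map a `real_space_map`.
#' @param threshold_sigma contour threshold in sigma units (> 0; the
#'   conventional choice is 3.0).
#' @param sites atom table with columns `chain`, `resid`, `atom`, `fx`, `fy`,
#'   `fz` (fractional coordinates), e.g. from [crystal_sites()].
#' @return data.frame of features: fractional position, `value_sigma`
#'   (signed height in sigma units), nearest atom and its distance in
#'   Angstrom; sorted by `|value_sigma|` descending.
#' @export
peak_search <- function(map, threshold_sigma, sites) {
  stopifnot(threshold_sigma > 0)
  v <- map$values
  d <- map$dim
  if (map$sigma == 0) return(.empty_features())
  sh <- function(arr, s) {
    # periodic shift of a 3-d array by s = c(sx, sy, sz)
    i1 <- ((seq_len(d[1]) - 1 + s[1]) %% d[1]) + 1
    i2 <- ((seq_len(d[2]) - 1 + s[2]) %% d[2]) + 1
    i3 <- ((seq_len(d[3]) - 1 + s[3]) %% d[3]) + 1
    arr[i1, i2, i3]
  }
  is_max <- array(TRUE, d); is_min <- array(TRUE, d)
  for (sx in -1:1) for (sy in -1:1) for (sz in -1:1) {
    if (sx == 0 && sy == 0 && sz == 0) next
    nb <- sh(v, c(sx, sy, sz))
    is_max <- is_max & (v >= nb)
    is_min <- is_min & (v <= nb)
  }
  cand <- which((is_max | is_min) & abs(v) >= threshold_sigma * map$sigma)
  if (length(cand) == 0) return(.empty_features())
  idx <- arrayInd(cand, d)
  frac <- sweep(idx - 1, 2, d, "/")
  val <- v[cand]
  ord <- order(-abs(val))
  idx <- idx[ord, , drop = FALSE]; frac <- frac[ord, , drop = FALSE]
  val <- val[ord]
  # greedy same-sign merge within 1.5 A, strongest kept
  keep <- logical(length(val))
  kept_frac <- NULL
  for (i in seq_along(val)) {
    if (!is.null(kept_frac)) {
      dd <- .min_image_dist(map$cell, kept_frac, frac[i, , drop = FALSE])
      same <- sign(val[keep][seq_len(nrow(kept_frac))]) == sign(val[i])
      if (any(dd[same, 1] < 1.5)) next
    }
    keep[i] <- TRUE
    kept_frac <- rbind(kept_frac, frac[i, ])
  }
  frac <- frac[keep, , drop = FALSE]; val <- val[keep]
  at_frac <- as.matrix(sites[, c("fx", "fy", "fz")])
  dist <- .min_image_dist(map$cell, frac, at_frac)
  nearest <- apply(dist, 1, which.min)
  data.frame(fx = frac[, 1], fy = frac[, 2], fz = frac[, 3],
             value_sigma = val / map$sigma,
             chain = sites$chain[nearest],
             resid = sites$resid[nearest],
             atom = sites$atom[nearest],
             distance_A = dist[cbind(seq_along(nearest), nearest)],
             row.names = NULL)
}

.empty_features <- function() {
  data.frame(fx = numeric(0), fy = numeric(0), fz = numeric(0),
             value_sigma = numeric(0), chain = character(0),
             resid = integer(0), atom = character(0),
             distance_A = numeric(0))
}

#' Signed difference-density value at an atomic site
#'
#' The signed extremum (largest absolute value) of the map over all grid
#' points within `radius_A` of the given fractional position, reported in
#' sigma units — the convention in which light-induced density changes at
#' named atoms are quoted.
#'
#' @param map a `real_space_map`.
#' @param position fractional coordinate (length 3); wrapped into the cell.
#' @param radius_A search radius in Angstrom, at least one grid spacing.
#' @return signed value in sigma units (0 for an all-zero map).
#' @export
feature_at_site <- function(map, position, radius_A) {
  spacing <- max(map$cell[1:3] / map$dim)
  if (radius_A < spacing)
    stop(sprintf("radius (%.3g A) below grid spacing (%.3g A)", radius_A,
                 spacing))
  if (map$sigma == 0) return(0)
  frac <- .grid_frac(map)
  dd <- .min_image_dist(map$cell, frac,
                        matrix(as.numeric(position) %% 1, nrow = 1))
  sel <- which(dd[, 1] <= radius_A)
  vals <- as.numeric(map$values)[sel]
  vals[which.max(abs(vals))] / map$sigma
}
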