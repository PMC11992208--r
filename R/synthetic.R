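#' Generate a synthetic difference-spectrum series with known ground truth
#'
#' Builds M and O basis difference spectra as (intermediate Gaussian
#' absorption band minus ground-state Gaussian band), evolves them under the
#' sequential kinetic model, and adds Gaussian noise. The defaults emulate
#' the flash-photolysis measurements of the blue-light photosensor: ground
#' peak at 498 nm, blue-shifted M band (390 nm, deprotonated Schiff base),
#' red-shifted O band (530 nm), rate constants solved from the observed
#' 63 ms crossover / 240 ms half-decay (tau1 ~ 81 ms, tau2 ~ 220 ms), and
#' 45 repeats as in the spectroscopy protocol when `n_repeats` is raised.
#'
#' @param wavelengths wavelength axis, nm (default 330-700 in 2 nm steps).
#' @param delays delay axis, ms (default 30 delays spanning 0-500 ms).
#' @param k1,k2 sequential-model rates, 1/ms (defaults 1/81, 1/220).
#' @param ground_peak_nm,m_peak_nm,o_peak_nm band centres, nm.
#' @param band_width_nm Gaussian band sd, nm (same for all bands).
#' @param amp_m,amp_o peak intermediate-band absorbances relative to the
#'   ground band.
#' @param delta_od overall Delta OD scale (ground-band bleach depth at unit
#'   occupancy).
#' @param noise_sd Gaussian noise sd in Delta OD; overridden by `snr`.
#' @param snr if given, `noise_sd` is set to `rms(clean signal)/snr`.
#' @param n_repeats number of independent noisy repeats; `D` is their mean.
#' @param seed optional integer seed.
#' @return list with `series` (a [spectral_series()]) and `truth` (basis
#'   spectra `S_M`, `S_O`, the generating [photocycle_model()], traces, and
#'   `noise_sd`).
#' @export
make_spectral_series <- function(wavelengths = seq(330, 700, by = 2),
                                 delays = seq(0, 500, length.out = 30),
                                 k1 = 1 / 81, k2 = 1 / 220,
                                 ground_peak_nm = 498, m_peak_nm = 390,
                                 o_peak_nm = 530, band_width_nm = 28,
                                 amp_m = 0.8, amp_o = 1.1, delta_od = 0.05,
                                 noise_sd = 0, snr = NULL, n_repeats = 1,
                                 seed = NULL) {
  stopifnot(band_width_nm > 0, noise_sd >= 0, n_repeats >= 1)
  if (!is.null(seed)) set.seed(seed)
  band <- function(mu) exp(-(wavelengths - mu)^2 / (2 * band_width_nm^2))
  S_M <- delta_od * (amp_m * band(m_peak_nm) - band(ground_peak_nm))
  S_O <- delta_od * (amp_o * band(o_peak_nm) - band(ground_peak_nm))
  model <- photocycle_model(k1, k2)
  traces <- occupancies(model, delays)
  clean <- cbind(S_M, S_O) %*% t(traces)
  if (!is.null(snr)) noise_sd <- sqrt(mean(clean^2)) / snr
  reps <- array(rep(clean, n_repeats),
                dim = c(length(wavelengths), length(delays), n_repeats))
  if (noise_sd > 0)
    reps <- reps + array(stats::rnorm(length(reps), sd = noise_sd),
                         dim = dim(reps))
  D <- apply(reps, c(1, 2), mean)
  series <- spectral_series(wavelengths, delays, D,
                            repeats = if (n_repeats > 1) reps)
  list(series = series,
       truth = list(S_M = S_M, S_O = S_O, model = model, traces = traces,
                    noise_sd = noise_sd))
}

#' Toy crystal of Gaussian atoms in P1
#'
#' A minimal crystal whose electron density is a sum of isotropic Gaussians,
#' so that structure factors have an exact closed form and direct-summation
#' oracles are available for every map computation.
#'
#' @param cell unit cell (a, b, c, alpha, beta, gamma).
#' @param atoms data.frame with columns `chain`, `resid`, `atom`, `fx`,
#'   `fy`, `fz` (fractional coordinates), `width` (Gaussian sd, Angstrom)
#'   and `weight` (integrated density, e.g. electron count).
#' @param d_min nominal resolution, Angstrom.
#' @return object of class `"toy_crystal"`.
#' @export
toy_crystal <- function(cell, atoms, d_min = 2) {
  .check_cell(cell)
  need <- c("chain", "resid", "atom", "fx", "fy", "fz", "width", "weight")
  if (!all(need %in% names(atoms)))
    stop("atoms need columns ", paste(need, collapse = ", "))
  stopifnot(all(atoms$width > 0), all(is.finite(atoms$weight)), d_min > 0)
  structure(list(cell = as.numeric(cell), atoms = atoms, d_min = d_min),
            class = "toy_crystal")
}

#' @export
print.toy_crystal <- function(x, ...) {
  cat(sprintf("Toy crystal: %d Gaussian atoms, cell (%s), d_min %.2f A\n",
              nrow(x$atoms), paste(format(x$cell, digits = 4), collapse = ", "),
              x$d_min))
  invisible(x)
}

#' Atom site table of a toy crystal or atomic model
#'
#' Returns the `chain`/`resid`/`atom`/`fx`/`fy`/`fz` table consumed by
#' [peak_search()] and [project_to_sequence()]. For an [atomic_model()] the
#' orthogonal coordinates are converted to fractional with the supplied
#' cell; hydrogens are dropped.
#'
#' @param x a `toy_crystal` or `atomic_model`.
#' @param cell required for an `atomic_model`.
#' @return data.frame of sites.
#' @export
crystal_sites <- function(x, cell = NULL) {
  if (inherits(x, "toy_crystal"))
    return(x$atoms[, c("chain", "resid", "atom", "fx", "fy", "fz")])
  if (inherits(x, "atomic_model")) {
    if (is.null(cell)) stop("cell required to fractionalize an atomic model")
    m <- x[x$elt != "H", , drop = FALSE]
    frac <- as.matrix(m[, c("x", "y", "z")]) %*%
      t(solve(orthogonalization_matrix(cell)))
    return(data.frame(chain = m$chain, resid = m$resid, atom = m$atom,
                      fx = frac[, 1] %% 1, fy = frac[, 2] %% 1,
                      fz = frac[, 3] %% 1, stringsAsFactors = FALSE))
  }
  stop("unsupported object")
}

#' Structure factors of a toy crystal by direct summation
#'
#' Exact transform of the Gaussian-atom density:
#' `F(h) = sum_j w_j exp(-2 pi^2 width_j^2 |s|^2) exp(2 pi i h.x_j)` with
#' `|s| = 1/d` the reciprocal-vector length. One representative per Friedel
#' pair is returned (F(000) excluded).
#'
#' @param toy a [toy_crystal()].
#' @param d_min resolution cutoff, Angstrom (default the crystal's `d_min`).
#' @return list with `reflections` (a [reflection_set()]) and `phases`
#'   (a [phase_set()], degrees in `[-180, 180)`).
#' @export
structure_factors_direct <- function(toy, d_min = toy$d_min) {
  cell <- toy$cell
  hmax <- ceiling(cell[1:3] / d_min)
  g <- expand.grid(h = -hmax[1]:hmax[1], k = -hmax[2]:hmax[2],
                   l = -hmax[3]:hmax[3])
  hkl <- as.matrix(g)
  hkl <- hkl[.friedel_half(hkl), , drop = FALSE]
  d <- d_spacing(cell, hkl)
  hkl <- hkl[d >= d_min, , drop = FALSE]
  F <- .direct_structure_factors(toy, hkl)
  list(reflections = reflection_set(cell, hkl, Mod(F)),
       phases = phase_set(hkl, Arg(F) * 180 / pi))
}

# complex F(h) of a toy crystal for given index rows
.direct_structure_factors <- function(toy, hkl) {
  s2 <- 1 / d_spacing(toy$cell, hkl)^2
  Fc <- rep(0 + 0i, nrow(hkl))
  for (j in seq_len(nrow(toy$atoms))) {
    a <- toy$atoms[j, ]
    ph <- 2 * pi * (hkl[, 1] * a$fx + hkl[, 2] * a$fy + hkl[, 3] * a$fz)
    Fc <- Fc + a$weight * exp(-2 * pi^2 * a$width^2 * s2) *
      complex(modulus = 1, argument = ph)
  }
  Fc
}

#' Real-space Gaussian density of a toy crystal on a grid
#'
#' Direct-space oracle for the Fourier synthesis: sums the periodic images
#' (+/- 1 cell) of each normalised Gaussian atom on the fractional grid.
#'
#' @param toy a [toy_crystal()].
#' @param grid grid dimensions (length-3 integer).
#' @return a [real_space_map()].
#' @export
density_direct <- function(toy, grid) {
  grid <- as.integer(grid)
  O <- orthogonalization_matrix(toy$cell)
  fr <- .grid_frac(list(dim = grid))
  rho <- numeric(nrow(fr))
  shifts <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  for (j in seq_len(nrow(toy$atoms))) {
    a <- toy$atoms[j, ]
    for (s in seq_len(nrow(shifts))) {
      d <- sweep(fr, 2, c(a$fx, a$fy, a$fz) + shifts[s, ])
      xyz <- d %*% t(O)
      r2 <- rowSums(xyz^2)
      rho <- rho + a$weight * (2 * pi * a$width^2)^(-1.5) *
        exp(-r2 / (2 * a$width^2))
    }
  }
  real_space_map(toy$cell, array(rho, dim = grid))
}

#' Perturb a toy crystal
#'
#' Emulates light-state structural changes: removing an atom (e.g. a water
#' that disorders), shifting an atom, or scaling its occupancy-like weight.
#' The input crystal is untouched.
#'
#' @param toy a [toy_crystal()].
#' @param action one of `"delete_atom"`, `"shift_atom"`, `"scale_weight"`.
#' @param atom index (row) of the atom acted on.
#' @param shift_frac fractional-coordinate shift (length 3) for
#'   `"shift_atom"`.
#' @param factor weight multiplier for `"scale_weight"`.
#' @return a new `toy_crystal`.
#' @export
perturb_crystal <- function(toy, action = c("delete_atom", "shift_atom",
                                            "scale_weight"),
                            atom = 1, shift_frac = c(0, 0, 0), factor = 1) {
  action <- match.arg(action)
  atoms <- toy$atoms
  stopifnot(atom >= 1, atom <= nrow(atoms))
  if (action == "delete_atom") {
    atoms <- atoms[-atom, , drop = FALSE]
  } else if (action == "shift_atom") {
    atoms[atom, c("fx", "fy", "fz")] <-
      (unlist(atoms[atom, c("fx", "fy", "fz")]) + shift_frac) %% 1
  } else {
    atoms$weight[atom] <- atoms$weight[atom] * factor
  }
  toy_crystal(toy$cell, atoms, toy$d_min)
}

#' Redundant noisy amplitude observations from a reflection set
#'
#' Replicates every amplitude `n_per_index` times with additive Gaussian
#' noise, emulating the per-image measurements that bootstrap resampling
#' operates on.
#'
#' @param reflections a [reflection_set()].
#' @param n_per_index observations per index (>= 1).
#' @param noise_sd observation noise sd (amplitude units).
#' @param seed optional integer seed.
#' @return data.frame of class `"observation_set"` with columns `h`, `k`,
#'   `l`, `f` (repeated rows per index) and attribute `cell`.
#' @export
make_observations <- function(reflections, n_per_index, noise_sd = 0,
                              seed = NULL) {
  stopifnot(n_per_index >= 1, noise_sd >= 0)
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(reflections$hkl)
  obs <- data.frame(
    h = rep(reflections$hkl[, 1], each = n_per_index),
    k = rep(reflections$hkl[, 2], each = n_per_index),
    l = rep(reflections$hkl[, 3], each = n_per_index),
    f = rep(reflections$f, each = n_per_index) +
      stats::rnorm(n * n_per_index, sd = noise_sd))
  obs$f <- pmax(obs$f, 0)
  structure(obs, cell = reflections$cell,
            class = c("observation_set", "data.frame"))
}

#' Read / write observation sets as whitespace text (h k l F, repeated lines)
#'
#' @param path file path.
#' @param cell unit cell to attach on reading.
#' @rdname obs_io
#' @export
read_observations <- function(path, cell) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) stop("empty observation file '", path, "'")
  parts <- strsplit(trimws(lines), "\\s+")
  bad <- which(lengths(parts) != 4)
  if (length(bad))
    stop("malformed observation file '", path, "' at line ", bad[1])
  m <- do.call(rbind, lapply(parts, as.numeric))
  if (any(is.na(m)))
    stop("malformed observation file '", path, "': non-numeric field")
  structure(data.frame(h = as.integer(m[, 1]), k = as.integer(m[, 2]),
                       l = as.integer(m[, 3]), f = m[, 4]),
            cell = cell, class = c("observation_set", "data.frame"))
}

#' @param obs an `observation_set`.
#' @rdname obs_io
#' @export
write_observations <- function(obs, path) {
  utils::write.table(data.frame(obs$h, obs$k, obs$l, signif(obs$f, 9)),
                     path, row.names = FALSE, col.names = FALSE, quote = FALSE)
  invisible(path)
}
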