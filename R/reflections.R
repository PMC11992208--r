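#' Unit-cell geometry helpers
#'
#' @param cell numeric vector (a, b, c, alpha, beta, gamma) in Angstrom and
#'   degrees.
#' @return `cell_volume`: volume in A^3; `orthogonalization_matrix`: 3x3
#'   matrix mapping fractional to orthogonal Angstrom coordinates (PDB
#'   convention); `d_spacing`: resolution in Angstrom per reflection.
#' @rdname cell_geometry
#' @export
cell_volume <- function(cell) {
  .check_cell(cell)
  ca <- cos(cell[4] * pi / 180); cb <- cos(cell[5] * pi / 180)
  cg <- cos(cell[6] * pi / 180)
  cell[1] * cell[2] * cell[3] *
    sqrt(1 - ca^2 - cb^2 - cg^2 + 2 * ca * cb * cg)
}

.check_cell <- function(cell) {
  if (length(cell) != 6 || any(!is.finite(cell)) || any(cell[1:3] <= 0) ||
      any(cell[4:6] <= 0) || any(cell[4:6] >= 180))
    stop("cell must be (a, b, c, alpha, beta, gamma) with positive lengths and angles in (0, 180)")
  invisible(cell)
}

#' @rdname cell_geometry
#' @export
orthogonalization_matrix <- function(cell) {
  .check_cell(cell)
  a <- cell[1]; b <- cell[2]; c3 <- cell[3]
  al <- cell[4] * pi / 180; be <- cell[5] * pi / 180; ga <- cell[6] * pi / 180
  v <- cell_volume(cell)
  matrix(c(a, b * cos(ga), c3 * cos(be),
           0, b * sin(ga), c3 * (cos(al) - cos(be) * cos(ga)) / sin(ga),
           0, 0, v / (a * b * sin(ga))),
         nrow = 3, byrow = TRUE)
}

#' @param hkl integer matrix (n x 3) of Miller indices.
#' @rdname cell_geometry
#' @export
d_spacing <- function(cell, hkl) {
  .check_cell(cell)
  hkl <- matrix(as.numeric(hkl), ncol = 3)
  # reciprocal metric tensor from the inverse orthogonalization matrix
  Oinv <- solve(orthogonalization_matrix(cell))
  s <- hkl %*% Oinv           # reciprocal-space vectors, 1/A
  1 / sqrt(rowSums(s^2))
}

#' Reflection amplitude set
#'
#' @param cell unit cell (a, b, c, alpha, beta, gamma), Angstrom / degrees.
#' @param hkl integer matrix (n x 3) of Miller indices, unique rows.
#' @param f structure-factor amplitudes, >= 0.
#' @param sigf optional amplitude sigmas.
#' @return object of class `"reflection_set"`.
#' @export
reflection_set <- function(cell, hkl, f, sigf = NULL) {
  .check_cell(cell)
  hkl <- matrix(as.integer(round(hkl)), ncol = 3)
  if (anyDuplicated(hkl)) stop("duplicate Miller indices")
  f <- as.numeric(f)
  if (length(f) != nrow(hkl)) stop("one amplitude per index required")
  if (any(!is.finite(f)) || any(f < 0)) stop("amplitudes must be finite and >= 0")
  if (!is.null(sigf)) {
    sigf <- as.numeric(sigf)
    if (length(sigf) != nrow(hkl)) stop("one sigma per index required")
  }
  structure(list(cell = as.numeric(cell), hkl = hkl, f = f, sigf = sigf),
            class = "reflection_set")
}

#' @export
print.reflection_set <- function(x, ...) {
  d <- d_spacing(x$cell, x$hkl)
  cat(sprintf("Reflection set: %d reflections, %.2f - %.2f A, cell (%s)\n",
              nrow(x$hkl), max(d), min(d),
              paste(format(x$cell, digits = 4), collapse = ", ")))
  invisible(x)
}

#' Model-phase set
#'
#' @param hkl integer matrix (n x 3) of Miller indices.
#' @param phi phases in degrees; wrapped into `[-180, 180)`.
#' @return object of class `"phase_set"`.
#' @export
phase_set <- function(hkl, phi) {
  hkl <- matrix(as.integer(round(hkl)), ncol = 3)
  phi <- as.numeric(phi)
  if (length(phi) != nrow(hkl)) stop("one phase per index required")
  phi <- ((phi + 180) %% 360) - 180
  structure(list(hkl = hkl, phi = phi), class = "phase_set")
}

.hkl_key <- function(hkl) paste(hkl[, 1], hkl[, 2], hkl[, 3])

#' Scale one amplitude set onto another
#'
#' Least-squares scaling of the light amplitudes onto the dark set over
#' their common indices: globally (one factor k minimising
#' `sum((F_dark - k F_light)^2)`) or per resolution shell.
#'
#' @param light,dark `reflection_set`s sharing a cell.
#' @param mode `"global"` or `"shells"`.
#' @param n_shells number of equal-count resolution shells for
#'   `mode = "shells"` (default 20).
#' @return list with `light` (scaled, restricted to common indices), `dark`
#'   (restricted), `k` (scale factor(s)) and `residual` (sum of squared
#'   scaled differences).
#' @export
scale_amplitudes <- function(light, dark, mode = c("global", "shells"),
                             n_shells = 20) {
  mode <- match.arg(mode)
  key_l <- .hkl_key(light$hkl); key_d <- .hkl_key(dark$hkl)
  common <- intersect(key_l, key_d)
  if (length(common) == 0) stop("no common indices between the two sets")
  il <- match(common, key_l); id <- match(common, key_d)
  hkl <- light$hkl[il, , drop = FALSE]
  fl <- light$f[il]; fd <- dark$f[id]
  if (mode == "global") {
    k <- sum(fd * fl) / sum(fl^2)
    ks <- rep(k, length(fl))
  } else {
    d <- d_spacing(light$cell, hkl)
    shell <- cut(rank(-d, ties.method = "first"),
                 breaks = seq(0, length(d), length.out = n_shells + 1),
                 labels = FALSE, include.lowest = TRUE)
    k <- vapply(split(seq_along(fl), shell), function(i) {
      sum(fd[i] * fl[i]) / sum(fl[i]^2)
    }, numeric(1))
    ks <- k[shell]
  }
  list(light = reflection_set(light$cell, hkl, fl * ks,
                              if (!is.null(light$sigf)) light$sigf[il] * ks),
       dark = reflection_set(dark$cell, hkl, fd,
                             if (!is.null(dark$sigf)) dark$sigf[id]),
       k = k,
       residual = sum((fd - fl * ks)^2))
}

#' Read / write reflection amplitudes as whitespace text (h k l F [sigF])
#'
#' @param path file path.
#' @param cell unit cell to attach to the set on reading.
#' @rdname hkl_io
#' @export
read_hkl <- function(path, cell) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) stop("empty reflection file '", path, "'")
  parts <- strsplit(trimws(lines), "\\s+")
  nf <- lengths(parts)
  bad <- which(nf < 4 | nf > 5)
  if (length(bad))
    stop("malformed reflection file '", path, "' at line ", bad[1],
         ": expected 'h k l F [sigF]'")
  vals <- suppressWarnings(lapply(parts, as.numeric))
  badnum <- which(vapply(vals, function(v) any(is.na(v)), logical(1)))
  if (length(badnum))
    stop("malformed reflection file '", path, "' at line ", badnum[1],
         ": non-numeric field")
  m <- do.call(rbind, lapply(vals, function(v) c(v, NA)[1:5]))
  reflection_set(cell, m[, 1:3], m[, 4],
                 if (all(!is.na(m[, 5]))) m[, 5] else NULL)
}

#' @param refl a `reflection_set`.
#' @rdname hkl_io
#' @export
write_hkl <- function(refl, path) {
  tab <- cbind(refl$hkl, signif(refl$f, 9))
  if (!is.null(refl$sigf)) tab <- cbind(tab, signif(refl$sigf, 9))
  utils::write.table(tab, path, row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Read / write model phases as whitespace text (h k l phi)
#'
#' @param path file path.
#' @rdname phase_io
#' @export
read_phases <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) stop("empty phase file '", path, "'")
  parts <- strsplit(trimws(lines), "\\s+")
  bad <- which(lengths(parts) != 4)
  if (length(bad))
    stop("malformed phase file '", path, "' at line ", bad[1],
         ": expected 'h k l phi'")
  m <- do.call(rbind, lapply(parts, as.numeric))
  if (any(is.na(m)))
    stop("malformed phase file '", path, "': non-numeric field")
  phase_set(m[, 1:3], m[, 4])
}

#' @param phases a `phase_set`.
#' @rdname phase_io
#' @export
write_phases <- function(phases, path) {
  utils::write.table(cbind(phases$hkl, signif(phases$phi, 9)), path,
                     row.names = FALSE, col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Filter dataset cell records against a target crystal form
#'
#' Keeps records whose six lattice parameters all lie within tolerance of
#' the target: relative tolerance on axis lengths, absolute on angles.
#' Serial-crystallography datasets often contain several crystal forms;
#' imposing the cell of the well-diffracting form selects its images.
#'
#' @param records data.frame with columns `a, b, c, alpha, beta, gamma`.
#' @param target length-6 target cell.
#' @param tol_length relative tolerance on a, b, c (default 0.015).
#' @param tol_angle_deg absolute tolerance on angles in degrees (default 1.5).
#' @return list with `kept`, `rejected` (data.frames) and counts.
#' @export
filter_by_cell <- function(records, target, tol_length = 0.015,
                           tol_angle_deg = 1.5) {
  stopifnot(tol_length >= 0, tol_angle_deg >= 0)
  .check_cell(target)
  need <- c("a", "b", "c", "alpha", "beta", "gamma")
  if (!all(need %in% names(records))) stop("records need columns ", paste(need, collapse = ", "))
  ok <- abs(records$a - target[1]) <= tol_length * target[1] &
        abs(records$b - target[2]) <= tol_length * target[2] &
        abs(records$c - target[3]) <= tol_length * target[3] &
        abs(records$alpha - target[4]) <= tol_angle_deg &
        abs(records$beta - target[5]) <= tol_angle_deg &
        abs(records$gamma - target[6]) <= tol_angle_deg
  list(kept = records[ok, , drop = FALSE],
       rejected = records[!ok, , drop = FALSE],
       n_kept = sum(ok), n_rejected = sum(!ok))
}
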