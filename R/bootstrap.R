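#' Bootstrap errors of difference-density features
#'
#' For each bootstrap replicate the individual amplitude observations are
#' resampled with replacement within each Miller index, merged by unweighted
#' mean into light and dark amplitude sets, a sigma-normalised difference
#' map is computed, and the signed density at every requested site is
#' recorded. The per-site standard deviation across replicates is the error
#' estimate attached to reported feature heights.
#'
#' @param light_obs,dark_obs `observation_set`s (columns `h`, `k`, `l`, `f`,
#'   repeated rows per index, attribute `cell`).
#' @param phases a [phase_set()] of dark-model phases.
#' @param sites matrix or data.frame of fractional positions (`fx`, `fy`,
#'   `fz`), one row per feature site.
#' @param n_boot number of bootstrap replicates (default 100).
#' @param seed integer seed making the resampling reproducible.
#' @param radius_A site search radius passed to [feature_at_site()].
#' @param d_min,grid,scale_mode passed to [compute_difference_map()].
#' @return list with `std` (per-site standard deviation, sigma units),
#'   `mean` (per-site mean), and `replicates` (n_boot x n_sites matrix).
#' @export
bootstrap_feature_errors <- function(light_obs, dark_obs, phases, sites,
                                     n_boot = 100, seed = 1, radius_A = 1.5,
                                     d_min = NULL, grid = NULL,
                                     scale_mode = "global") {
  stopifnot(n_boot >= 2)
  cell <- attr(light_obs, "cell")
  if (is.null(cell)) stop("light observations carry no cell")
  key_l <- paste(light_obs$h, light_obs$k, light_obs$l)
  key_d <- paste(dark_obs$h, dark_obs$k, dark_obs$l)
  only <- union(setdiff(key_l, key_d), setdiff(key_d, key_l))
  if (length(only) > 0)
    stop("index present in only one state: ", only[1])
  # sort within each index so the estimate depends only on the multiset of
  # observations, not their file order
  gl <- lapply(split(light_obs$f, key_l), sort)
  gd <- lapply(split(dark_obs$f, key_d), sort)
  gd <- gd[names(gl)]
  hkl <- do.call(rbind, lapply(strsplit(names(gl), " "), as.numeric))
  sites <- as.matrix(as.data.frame(sites)[, c("fx", "fy", "fz")])
  set.seed(seed)
  reps <- matrix(NA_real_, n_boot, nrow(sites))
  for (b in seq_len(n_boot)) {
    fl <- vapply(gl, function(v) mean(v[sample.int(length(v), replace = TRUE)]),
                 numeric(1))
    fd <- vapply(gd, function(v) mean(v[sample.int(length(v), replace = TRUE)]),
                 numeric(1))
    light <- reflection_set(cell, hkl, pmax(fl, 0))
    dark <- reflection_set(cell, hkl, pmax(fd, 0))
    map <- compute_difference_map(light, dark, phases, d_min = d_min,
                                  grid = grid, scale_mode = scale_mode)
    for (s in seq_len(nrow(sites)))
      reps[b, s] <- if (map$sigma == 0) 0 else
        feature_at_site(map, sites[s, ], radius_A)
  }
  list(std = apply(reps, 2, stats::sd),
       mean = colMeans(reps),
       replicates = reps)
}

#' Bootstrap errors of light-dark coordinate separations
#'
#' Given ensembles of refined models from bootstrap-resampled light and dark
#' data (replicates paired by index), computes for every residue the Calpha
#' separation within each replicate pair, and returns the mean separation
#' with its standard deviation over replicates — the coordinate error bars
#' attached to per-residue displacement profiles.
#'
#' @param light_ensemble,dark_ensemble lists of `atomic_model`s of equal
#'   length (>= 2) and equal topology.
#' @return data.frame with `chain`, `resid`, `mean_separation`, `std`
#'   (both Angstrom).
#' @export
coordinate_separation_errors <- function(light_ensemble, dark_ensemble) {
  n <- length(light_ensemble)
  if (n != length(dark_ensemble)) stop("ensembles must pair by replicate index")
  if (n < 2) stop("need at least 2 replicate pairs")
  seps <- NULL
  ref <- NULL
  for (i in seq_len(n)) {
    m <- .matched_ca(dark_ensemble[[i]], light_ensemble[[i]])
    key <- paste(m$chain, m$resid)
    if (is.null(ref)) {
      ref <- list(key = key, chain = m$chain, resid = m$resid)
      seps <- matrix(NA_real_, n, length(key))
    } else if (!identical(key, ref$key)) {
      stop("topology mismatch between replicate ", i, " and replicate 1")
    }
    seps[i, ] <- sqrt(rowSums((m$b - m$a)^2))
  }
  data.frame(chain = ref$chain, resid = ref$resid,
             mean_separation = colMeans(seps),
             std = apply(seps, 2, stats::sd),
             stringsAsFactors = FALSE)
}
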