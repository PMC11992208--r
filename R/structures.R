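#' Atomic model table
#'
#' Flat atom table used for displacement analysis: one row per atom with
#' chain, residue id/name, atom name, element, alternate-conformer tag
#' (`""` when absent), orthogonal Angstrom coordinates, occupancy and
#' B-factor.
#'
#' @param df data.frame with columns `chain`, `resid`, `resname`, `atom`,
#'   `elt`, `alt`, `x`, `y`, `z`, `occ`, `b` (missing optional columns are
#'   filled with defaults).
#' @return object of class `"atomic_model"` (a data.frame).
#' @export
atomic_model <- function(df) {
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  if (!all(c("chain", "resid", "atom", "x", "y", "z") %in% names(df)))
    stop("need at least chain, resid, atom, x, y, z")
  if (is.null(df$resname)) df$resname <- "ALA"
  if (is.null(df$elt)) df$elt <- substr(df$atom, 1, 1)
  if (is.null(df$alt)) df$alt <- ""
  df$alt[is.na(df$alt)] <- ""
  if (is.null(df$occ)) df$occ <- 1
  if (is.null(df$b)) df$b <- 20
  if (!all(is.finite(c(df$x, df$y, df$z)))) stop("non-finite coordinates")
  if (any(df$occ < 0 | df$occ > 1)) stop("occupancies must lie in [0, 1]")
  class(df) <- c("atomic_model", "data.frame")
  df
}

#' Read / write atomic models in PDB format (via bio3d)
#'
#' @param path file path.
#' @rdname model_io
#' @export
read_model <- function(path) {
  pdb <- bio3d::read.pdb(path, rm.alt = FALSE, verbose = FALSE)
  a <- pdb$atom
  atomic_model(data.frame(chain = a$chain, resid = a$resno,
                          resname = a$resid, atom = a$elety,
                          elt = ifelse(is.na(a$elesy) | a$elesy == "",
                                       substr(trimws(a$elety), 1, 1), a$elesy),
                          alt = ifelse(is.na(a$alt), "", a$alt),
                          x = a$x, y = a$y, z = a$z,
                          occ = a$o, b = a$b, stringsAsFactors = FALSE))
}

#' @param model an `atomic_model`.
#' @rdname model_io
#' @export
write_model <- function(model, path) {
  xyz <- as.numeric(t(as.matrix(model[, c("x", "y", "z")])))
  bio3d::write.pdb(file = path, xyz = xyz,
                   type = rep("ATOM", nrow(model)),
                   resno = model$resid, resid = model$resname,
                   eleno = seq_len(nrow(model)), elety = model$atom,
                   chain = model$chain,
                   alt = ifelse(model$alt == "", "", model$alt),
                   o = model$occ, b = model$b,
                   elesy = model$elt)
  invisible(path)
}

# Kabsch least-squares rigid superposition of two matched coordinate sets
# (n x 3); returns proper rotation R and translation t with b ~ a %*% R + t
.kabsch <- function(a, b) {
  ca <- colMeans(a); cb <- colMeans(b)
  A <- sweep(a, 2, ca); B <- sweep(b, 2, cb)
  s <- svd(crossprod(A, B))
  d <- sign(det(s$u %*% t(s$v)))
  R <- s$u %*% diag(c(1, 1, d)) %*% t(s$v)
  list(rotation = R, translation = cb - as.numeric(ca %*% R))
}

# matched CA coordinate pairs between two models (by chain + residue id)
.matched_ca <- function(model_a, model_b, selection = NULL) {
  ca_a <- model_a[trimws(model_a$atom) == "CA", , drop = FALSE]
  ca_b <- model_b[trimws(model_b$atom) == "CA", , drop = FALSE]
  if (!is.null(selection)) {
    ca_a <- ca_a[ca_a$resid %in% selection, , drop = FALSE]
    ca_b <- ca_b[ca_b$resid %in% selection, , drop = FALSE]
  }
  # one CA per residue: prefer the first (lowest alt tag by table order)
  ca_a <- ca_a[!duplicated(paste(ca_a$chain, ca_a$resid)), , drop = FALSE]
  ca_b <- ca_b[!duplicated(paste(ca_b$chain, ca_b$resid)), , drop = FALSE]
  key_a <- paste(ca_a$chain, ca_a$resid)
  key_b <- paste(ca_b$chain, ca_b$resid)
  common <- intersect(key_a, key_b)
  ia <- match(common, key_a); ib <- match(common, key_b)
  list(a = as.matrix(ca_a[ia, c("x", "y", "z")]),
       b = as.matrix(ca_b[ib, c("x", "y", "z")]),
       chain = ca_a$chain[ia], resid = ca_a$resid[ia],
       n_unmatched = (length(key_a) - length(common)) +
         (length(key_b) - length(common)))
}

#' Rigid Calpha superposition and RMSD between two models
#'
#' Least-squares (Kabsch) superposition of model B onto model A over their
#' matched Calpha atoms (matched by chain and residue id), with a proper
#' rotation enforced, and the post-fit RMSD.
#'
#' @param model_a,model_b `atomic_model`s.
#' @param selection optional vector of residue ids to restrict the match.
#' @return list with `rotation` (3x3), `translation` (length 3), `rmsd`
#'   (Angstrom), `n` (matched pairs), `n_unmatched`.
#' @export
superpose_ca <- function(model_a, model_b, selection = NULL) {
  m <- .matched_ca(model_a, model_b, selection)
  if (nrow(m$a) < 3) stop("fewer than 3 matched Calpha pairs")
  cen <- sweep(m$a, 2, colMeans(m$a))
  if (svd(cen)$d[2] < 1e-8 * max(svd(cen)$d))
    warning("matched Calpha set is (nearly) collinear; rotation is degenerate")
  k <- .kabsch(m$b, m$a)   # move b onto a
  moved <- m$b %*% k$rotation
  moved <- sweep(moved, 2, k$translation, "+")
  list(rotation = k$rotation, translation = k$translation,
       rmsd = sqrt(mean(rowSums((moved - m$a)^2))),
       n = nrow(m$a), n_unmatched = m$n_unmatched)
}

#' Split a multi-conformer model into dark and light submodels
#'
#' Atoms carrying the dark tag or no alternate-conformer tag form the dark
#' submodel; atoms with the light tag or no tag the light submodel — the
#' structure produced by partial-occupancy refinement, where the resting
#' conformation is one conformer and the photoactivated state the other.
#'
#' @param model an `atomic_model` with alternate conformers.
#' @param tag_dark,tag_light conformer tags (defaults `"A"`, `"B"`).
#' @return list with `dark` and `light` `atomic_model`s.
#' @export
conformer_split <- function(model, tag_dark = "A", tag_light = "B") {
  tags <- unique(model$alt[model$alt != ""])
  if (length(tags) > 0 && !any(c(tag_dark, tag_light) %in% tags))
    stop("neither conformer tag present in the model")
  dark <- model[model$alt %in% c("", tag_dark), , drop = FALSE]
  light <- model[model$alt %in% c("", tag_light), , drop = FALSE]
  list(dark = atomic_model(dark), light = atomic_model(light))
}

#' Per-residue Calpha displacement between paired dark/light models
#'
#' `|Calpha_light - Calpha_dark|` per matched residue, optionally after a
#' global Kabsch superposition of the light model onto the dark model.
#' Within one refined entry the two conformers share a crystal frame, so
#' no superposition is the natural default; set `superpose = TRUE` when
#' comparing separately refined entries.
#'
#' @param dark,light `atomic_model`s.
#' @param superpose logical; superpose light onto dark on all matched
#'   Calpha first (default FALSE).
#' @return object of class `"displacement_profile"`: data.frame with
#'   `chain`, `resid`, `displacement` (Angstrom).
#' @export
per_residue_displacement <- function(dark, light, superpose = FALSE) {
  m <- .matched_ca(dark, light)
  if (nrow(m$a) == 0) stop("no matched Calpha pairs")
  b <- m$b
  if (superpose) {
    k <- .kabsch(b, m$a)
    b <- sweep(b %*% k$rotation, 2, k$translation, "+")
  }
  structure(data.frame(chain = m$chain, resid = m$resid,
                       displacement = sqrt(rowSums((b - m$a)^2)),
                       stringsAsFactors = FALSE),
            n_unmatched = m$n_unmatched,
            class = c("displacement_profile", "data.frame"))
}

#' Mean Calpha displacement over a residue range
#'
#' Arithmetic mean of the per-residue displacements over the inclusive
#' range — the statistic by which helix movements (e.g. the outward tilt of
#' helix F) are quantified and compared between proteins.
#'
#' @param profile a `displacement_profile`.
#' @param first,last inclusive residue-id range.
#' @return mean displacement in Angstrom.
#' @export
region_mean_displacement <- function(profile, first, last) {
  stopifnot(first <= last)
  sel <- profile$resid >= first & profile$resid <= last
  if (!any(sel)) stop("range does not intersect the profile")
  mean(profile$displacement[sel])
}
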