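# shared toy fixtures, built in code at test time

# four-Gaussian-atom P1 crystal; atom 4 plays the part of a water that
# disorders on illumination
toy4 <- function(d_min = 1.5) {
  atoms <- data.frame(chain = "A", resid = 1:4,
                      atom = c("CA", "CA", "O", "O"),
                      fx = c(0.10, 0.50, 0.75, 0.30),
                      fy = c(0.20, 0.60, 0.25, 0.80),
                      fz = c(0.30, 0.40, 0.70, 0.15),
                      width = c(1.2, 1.2, 1.0, 1.0),
                      weight = c(12, 12, 8, 8),
                      stringsAsFactors = FALSE)
  toy_crystal(c(16, 14, 12, 90, 90, 90), atoms, d_min = d_min)
}

# smaller crystal for bootstrap loops
toy_small <- function() {
  atoms <- data.frame(chain = "A", resid = 1:2, atom = c("CA", "O"),
                      fx = c(0.25, 0.7), fy = c(0.3, 0.6), fz = c(0.4, 0.2),
                      width = c(1.1, 0.9), weight = c(10, 8),
                      stringsAsFactors = FALSE)
  toy_crystal(c(10, 10, 10, 90, 90, 90), atoms, d_min = 2)
}

# extended CA-trace model with n residues
ca_model <- function(n = 20, seed = 11) {
  set.seed(seed)
  atomic_model(data.frame(chain = "A", resid = seq_len(n), atom = "CA",
                          resname = "ALA", elt = "C",
                          x = cumsum(rnorm(n, 1.5, 0.3)),
                          y = cumsum(rnorm(n, 0.5, 0.3)),
                          z = cumsum(rnorm(n, 0.8, 0.3)),
                          stringsAsFactors = FALSE))
}

# apply a rigid rotation + translation to an atomic model
rigid_move <- function(model, angle = 0.4, axis = 3, shift = c(3, -2, 5)) {
  cs <- cos(angle); sn <- sin(angle)
  R <- diag(3)
  ij <- setdiff(1:3, axis)
  R[ij[1], ij[1]] <- cs; R[ij[2], ij[2]] <- cs
  R[ij[1], ij[2]] <- -sn; R[ij[2], ij[1]] <- sn
  xyz <- as.matrix(model[, c("x", "y", "z")]) %*% R
  model$x <- xyz[, 1] + shift[1]
  model$y <- xyz[, 2] + shift[2]
  model$z <- xyz[, 3] + shift[3]
  atomic_model(model)
}

# brute-force Fourier synthesis oracle: independent direct summation of
# rho(x) = (1/V) sum_h [F e^(-2 pi i h.x) + conj] over the half-set
direct_synthesis_oracle <- function(cell, hkl, coeff, frac) {
  v <- cell_volume(cell)
  vapply(seq_len(nrow(frac)), function(i) {
    ph <- -2 * pi * (hkl %*% frac[i, ])
    sum(Re(coeff * complex(modulus = 1, argument = as.numeric(ph)))) * 2 / v
  }, numeric(1))
}
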