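#' Sequential two-intermediate photocycle model
#'
#' The irreversible chain M -> O -> ground with rate constants `k1` (M decay
#' into O) and `k2` (O decay back to the resting state), starting from a unit
#' photoexcited population entirely in M at t = 0:
#' \deqn{c_M(t) = e^{-k_1 t}}
#' \deqn{c_O(t) = \frac{k_1}{k_2 - k_1}\left(e^{-k_1 t} - e^{-k_2 t}\right)}
#' with the analytic limit \eqn{c_O(t) = k t e^{-k t}} when `k1 == k2`
#' (|k1 - k2| < 1e-9 k1).
#'
#' @param k1 rate of the M -> O step, 1/ms, > 0.
#' @param k2 rate of the O -> ground step, 1/ms, >= 0 (0 means O never decays).
#' @return An object of class `"photocycle_model"`.
#' @export
photocycle_model <- function(k1, k2) {
  if (!is.finite(k1) || k1 <= 0) stop("k1 must be > 0")
  if (!is.finite(k2) || k2 < 0) stop("k2 must be >= 0")
  structure(list(k1 = k1, k2 = k2), class = "photocycle_model")
}

#' @export
print.photocycle_model <- function(x, ...) {
  cat(sprintf("Sequential M -> O -> ground model: k1 = %.5g /ms (tau1 = %.4g ms), k2 = %.5g /ms (tau2 = %s ms)\n",
              x$k1, 1 / x$k1, x$k2,
              if (x$k2 > 0) format(1 / x$k2, digits = 4) else "Inf"))
  invisible(x)
}

#' Intermediate occupancies of the sequential model
#'
#' @param model a `photocycle_model`.
#' @param t numeric vector of times in ms.
#' @return matrix with columns `M` and `O`, one row per time.
#' @export
occupancies <- function(model, t) {
  k1 <- model$k1; k2 <- model$k2
  cM <- exp(-k1 * t)
  if (abs(k1 - k2) < 1e-9 * k1) {
    cO <- k1 * t * exp(-k1 * t)
  } else {
    cO <- k1 / (k2 - k1) * (exp(-k1 * t) - exp(-k2 * t))
  }
  cbind(M = cM, O = cO)
}

# locate the smallest root of f in (0, t_max] by sign-change scan on a log
# grid followed by uniroot at 1e-6 ms tolerance; NA if no sign change
.first_root <- function(f, t_max, n_scan = 4000) {
  ts <- exp(seq(log(t_max) - log(1e8), log(t_max), length.out = n_scan))
  fv <- vapply(ts, f, numeric(1))
  s <- which(fv[-1] * fv[-length(fv)] <= 0 & is.finite(fv[-1]))
  if (length(s) == 0) return(NA_real_)
  i <- s[1]
  if (fv[i] == 0) return(ts[i])
  stats::uniroot(f, c(ts[i], ts[i + 1]), tol = 1e-6)$root
}

#' Crossover time of the M and O populations
#'
#' Smallest t > 0 with c_M(t) = c_O(t), located by bracketing and bisection
#' to 1e-6 ms. Returns `NA` when the populations never cross within
#' `100 * max(1/k1, 1/k2)`.
#'
#' @param model a `photocycle_model` (or a `photocycle_fit`, whose model is
#'   used).
#' @return crossover time in ms, or `NA_real_`.
#' @export
crossover_time <- function(model) {
  if (inherits(model, "photocycle_fit")) model <- model$model
  k1 <- model$k1; k2 <- model$k2
  t_max <- 100 * max(1 / k1, if (k2 > 0) 1 / k2 else 1 / k1)
  f <- function(t) {
    co <- occupancies(model, t)
    co[, "M"] - co[, "O"]
  }
  .first_root(f, t_max)
}

#' Half-decay time of the total photoexcited population
#'
#' Time at which c_M(t) + c_O(t) has fallen to 0.5, i.e. half the initial
#' photoexcited population remains in either intermediate. Returns `NA`
#' when `k2 = 0` (the total is conserved at 1).
#'
#' @inheritParams crossover_time
#' @return half-decay time in ms, or `NA_real_`.
#' @export
half_decay_time <- function(model) {
  if (inherits(model, "photocycle_fit")) model <- model$model
  k1 <- model$k1; k2 <- model$k2
  if (k2 == 0) return(NA_real_)
  t_max <- 100 * max(1 / k1, 1 / k2)
  f <- function(t) sum(occupancies(model, t)) - 0.5
  .first_root(f, t_max)
}

#' Solve sequential-model rates from a crossover and half-decay time
#'
#' Numerically inverts the two timing observables of the sequential model:
#' finds (k1, k2) such that the M/O crossover occurs at `crossover_ms` and
#' the combined M+O population halves at `half_decay_ms`. Nested
#' root-finding: for each trial k1, k2 is solved from the half-decay
#' condition (monotone in k2), then k1 from the crossover condition.
#'
#' @param crossover_ms target crossover time in ms.
#' @param half_decay_ms target half-decay time in ms (> crossover is typical).
#' @return a `photocycle_model`.
#' @export
solve_rates_from_times <- function(crossover_ms, half_decay_ms) {
  stopifnot(crossover_ms > 0, half_decay_ms > 0)
  k2_for_k1 <- function(k1) {
    g <- function(k2) {
      half_decay_time(photocycle_model(k1, k2)) - half_decay_ms
    }
    stats::uniroot(g, lower = 1e-8, upper = 10 * k1, tol = 1e-12,
                   extendInt = "downX")$root
  }
  h <- function(k1) {
    k2 <- k2_for_k1(k1)
    crossover_time(photocycle_model(k1, k2)) - crossover_ms
  }
  # the fastest possible half-decay at given k1 is ln2/k1 (k2 -> Inf), so
  # only k1 above ln2/half_decay can satisfy the half-decay condition; the
  # crossover may be undefined (no crossing) near that edge, so bracket h by
  # a scan over a log grid of k1 before bisecting
  k1s <- exp(seq(log(1.02 * log(2) / half_decay_ms),
                 log(50 / crossover_ms), length.out = 200))
  hv <- vapply(k1s, function(k) tryCatch(h(k), error = function(e) NA_real_),
               numeric(1))
  ok <- which(!is.na(hv))
  sc <- ok[which(hv[ok[-length(ok)]] * hv[ok[-1]] <= 0)]
  if (length(sc) == 0)
    stop("no sequential model reproduces the requested crossover and half-decay times")
  i <- sc[1]; j <- ok[which(ok == i) + 1]
  k1 <- stats::uniroot(h, c(k1s[i], k1s[j]), tol = 1e-10)$root
  photocycle_model(k1, k2_for_k1(k1))
}
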