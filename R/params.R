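#' Wound-model parameters
#'
#' Construct and validate the parameter set of the radially symmetric
#' wound-healing model. Defaults are the values used throughout the
#' experiments: a circular wound of radius 3 mm discretized into 100
#' cell-centered mesh cells of width 0.03 mm, with treatment decisions
#' taken every 1/3 day.
#'
#' The five state variables are debris `a`, pro-inflammatory (M1)
#' macrophages `m1`, pro-repair (M2) macrophages `m2`, temporary tissue `c`
#' and new tissue `n`, each a radial profile on the mesh. The control input
#' accelerates M1 to M2 polarization only.
#'
#' @param R wound radius (mm).
#' @param n_cells number of mesh cells.
#' @param L cell width (mm); must satisfy `n_cells * L == R`.
#' @param beta debris-driven M1 recruitment rate (1/day).
#' @param rho maximal polarization rate (1/day).
#' @param kappa polarization half-saturation constant (dimensionless).
#' @param q Hill exponent of the polarization term.
#' @param gamma1,gamma2 M1 and M2 decay rates (1/day).
#' @param mu temporary-tissue decay rate (1/day).
#' @param D_m macrophage diffusion coefficient (mm^2/day).
#' @param D_n new-tissue diffusion coefficient (mm^2/day).
#' @param alpha_n logistic regrowth rate of new tissue (1/day).
#' @param sigma healed-tissue threshold in (0,1); a cell counts as healed
#'   once `n >= sigma`.
#' @param T_decision control decision interval (day); doses are held
#'   constant (zero-order hold) over each interval.
#' @param k_wound steepness (1/mm) of the initial new-tissue margin seed
#'   `n(r,0) = sigma * exp(-k_wound * (R - r))`; the default is calibrated
#'   so the untreated wound heals in 13.83 days.
#'
#' @return an object of class `wound_params` (a named list) with an
#'   additional element `r`, the cell-center radii `(i - 1/2) * L`.
#' @export
#' @examples
#' p <- wound_params()
#' p$R; length(p$r)
wound_params <- function(R = 3, n_cells = 100L, L = R / n_cells,
                         beta = 1, rho = 0.1, kappa = 0.05, q = 5,
                         gamma1 = 0.1, gamma2 = 0.1, mu = 0.2,
                         D_m = 0.32, D_n = 3e-4, alpha_n = 1.8,
                         sigma = 0.95, T_decision = 1 / 3,
                         k_wound = 9.97) {
  p <- list(R = R, n_cells = as.integer(n_cells), L = L, beta = beta,
            rho = rho, kappa = kappa, q = q, gamma1 = gamma1,
            gamma2 = gamma2, mu = mu, D_m = D_m, D_n = D_n,
            alpha_n = alpha_n, sigma = sigma, T_decision = T_decision,
            k_wound = k_wound)
  num <- vapply(p, is.numeric, logical(1))
  if (!all(num)) stop("all wound parameters must be numeric")
  if (any(unlist(p) < 0)) stop("all wound parameters must be nonnegative")
  if (abs(p$n_cells * p$L - p$R) > 1e-9)
    stop("mesh must cover the wound exactly: n_cells * L must equal R")
  if (p$sigma <= 0 || p$sigma >= 1) stop("sigma must lie in (0, 1)")
  if (p$q < 1) stop("Hill exponent q must be >= 1")
  if (p$n_cells < 3L) stop("mesh needs at least 3 cells")
  p$r <- (seq_len(p$n_cells) - 0.5) * p$L
  structure(p, class = "wound_params")
}

#' @export
print.wound_params <- function(x, ...) {
  cat("Wound model parameters\n")
  cat(sprintf("  mesh: R = %g mm, %d cells of width %g mm\n",
              x$R, x$n_cells, x$L))
  cat(sprintf("  rates: beta=%g rho=%g kappa=%g q=%g gamma1=%g gamma2=%g mu=%g\n",
              x$beta, x$rho, x$kappa, x$q, x$gamma1, x$gamma2, x$mu))
  cat(sprintf("  diffusion: D_m=%g D_n=%g mm^2/day; alpha_n=%g\n",
              x$D_m, x$D_n, x$alpha_n))
  cat(sprintf("  sigma=%g, T_decision=%g day, k_wound=%g /mm\n",
              x$sigma, x$T_decision, x$k_wound))
  invisible(x)
}

# flatten/unflatten between a wound state (list of 5 profiles) and the
# 5*n_cells vector ordered (a, m1, m2, c, n)
state_fields <- c("a", "m1", "m2", "c", "n")

#' Flatten a wound state into a vector
#'
#' @param state list with profiles `a`, `m1`, `m2`, `c`, `n`.
#' @return numeric vector of length `5 * n_cells`, blocks ordered
#'   (a, m1, m2, c, n).
#' @export
flatten_state <- function(state) {
  unlist(state[state_fields], use.names = FALSE)
}

#' Rebuild a wound state from a flattened vector
#'
#' @param x numeric vector of length `5 * n_cells`.
#' @return list with the five named profiles.
#' @export
unflatten_state <- function(x) {
  nc <- length(x) / 5L
  if (nc != round(nc)) stop("flattened state length must be a multiple of 5")
  s <- split(x, rep(seq_len(5), each = nc))
  names(s) <- state_fields
  s
}
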