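#' LQR configuration for the stage model
#'
#' Cost weights and target for linear-quadratic regulation of the learned
#' stage dynamics `dz/dt = A z + W u`. The default target is full
#' maturation `z_goal = (0, 0, 0, 1)` -- the absorbing healed stage (its
#' column of `A` is zero) -- with unit state cost and cheap control
#' (`Rcost = 1e-2 I`), which yields an aggressive healing reference.
#'
#' @param Q 4 x 4 positive-semidefinite state-cost matrix.
#' @param r_cost scalar actuation cost; the cost matrix is `r_cost * I_du`.
#' @param z_goal target stage distribution (on the simplex).
#' @param condition_limit availability threshold on the conditioning of the
#'   Riccati solution; larger is more permissive.
#' @return an `lqr_config` list.
#' @export
lqr_config <- function(Q = diag(4), r_cost = 1e-2,
                       z_goal = c(0, 0, 0, 1), condition_limit = 1e8) {
  if (any(abs(Q - t(Q)) > 1e-12) || any(eigen(Q, TRUE, TRUE)$values < -1e-12))
    stop("Q must be symmetric positive semidefinite")
  if (r_cost <= 0) stop("r_cost must be positive")
  if (abs(sum(z_goal) - 1) > 1e-6 || any(z_goal < 0))
    stop("z_goal must lie on the 4-simplex")
  list(Q = Q, r_cost = r_cost, z_goal = z_goal,
       condition_limit = condition_limit)
}

# continuous algebraic Riccati equation A'P + PA - P B R^-1 B' P + Q = 0,
# solved by the stable invariant subspace of the Hamiltonian matrix.
solve_care <- function(A, B, Q, R) {
  n <- nrow(A)
  Rinv <- solve(R)
  H <- rbind(cbind(A, -B %*% Rinv %*% t(B)),
             cbind(-Q, -t(A)))
  eg <- eigen(H)
  stab <- which(Re(eg$values) < 0)
  if (length(stab) != n) stop("Hamiltonian has no n-dimensional stable subspace")
  U <- eg$vectors[, stab, drop = FALSE]
  U1 <- U[seq_len(n), , drop = FALSE]
  U2 <- U[n + seq_len(n), , drop = FALSE]
  kap <- kappa(U1, exact = TRUE)
  P <- Re(U2 %*% solve(U1))
  P <- (P + t(P)) / 2
  list(P = P, K = Rinv %*% t(B) %*% P, condition = kap)
}

# simplex-tangent reduction: with z_goal = e4 (absorbing healed stage) the
# error coordinates are d = z[1:3] - z_goal[1:3]; their dynamics
# d' = A3 d + W3 u are self-contained because the fourth column of A is 0.
reduce_model <- function(A, W, cfg) {
  M <- rbind(diag(3), -1)                       # d -> e = z - z_goal lift
  list(A3 = A[1:3, 1:3], W3 = W[1:3, , drop = FALSE],
       Q3 = t(M) %*% cfg$Q %*% M)
}

#' Solve the LQR problem on the learned stage model
#'
#' Computes the optimal state-feedback gain `u = -K (z - z_goal)` for the
#' learned linear model by solving the continuous algebraic Riccati
#' equation on the 3-dimensional simplex-tangent reduction (the stage
#' probabilities are conserved in total, so the full 4-state model has a
#' structural zero eigenvalue and is not stabilizable in raw coordinates;
#' eliminating the absorbing healed stage removes it).
#'
#' @param model a `deep_mapper` (uses its rates and coupling matrix `W`),
#'   or a list with elements `A` (4 x 4) and `W` (4 x du).
#' @param cfg an [lqr_config()].
#' @return list with the gain `K` (du x 4, zero column for the healed
#'   stage), Riccati solution `P`, closed-loop eigenvalues `eig_cl` of the
#'   reduced system, and `condition`.
#' @export
solve_lqr <- function(model, cfg = lqr_config()) {
  AW <- model_matrices(model)
  if (!all(is.finite(AW$A)) || !all(is.finite(AW$W)))
    stop("model matrices must be finite")
  red <- reduce_model(AW$A, AW$W, cfg)
  du <- ncol(AW$W)
  sol <- solve_care(red$A3, red$W3, red$Q3, cfg$r_cost * diag(du))
  K <- cbind(sol$K, 0)                           # no feedback from Pm
  eig_cl <- eigen(red$A3 - red$W3 %*% sol$K, only.values = TRUE)$values
  list(K = K, P = sol$P, eig_cl = eig_cl, condition = sol$condition)
}

model_matrices <- function(model) {
  if (inherits(model, "deep_mapper")) {
    k <- mapper_rates(model)
    list(A = build_A(k[1L], k[2L], k[3L]), W = model$Win)
  } else list(A = model$A, W = model$W)
}

#' Is the LQR reference available?
#'
#' The linear reference is usable only when the Riccati solve succeeds and
#' its conditioning stays below the configured limit; during early
#' training the learned model can be degenerate or ill-conditioned, in
#' which case the tracking reward falls back to its penalty branch.
#'
#' @inheritParams solve_lqr
#' @return `TRUE` or `FALSE` (never throws).
#' @export
reference_available <- function(model, cfg = lqr_config()) {
  out <- tryCatch(solve_lqr(model, cfg), error = function(e) NULL)
  !is.null(out) && all(is.finite(out$K)) &&
    out$condition <= cfg$condition_limit &&
    all(Re(out$eig_cl) < 0)
}

#' One step of the optimal linear reference
#'
#' Applies the clipped LQR law `u* = clip(-K (z - z_goal), 0, 1)` and
#' advances the learned linear model `dz/dt = A z + W u*` over one decision
#' interval, renormalizing the result onto the probability simplex (the
#' learned coupling `W` need not conserve total probability).
#'
#' @param z current stage distribution.
#' @param K LQR gain from [solve_lqr()].
#' @param model mapper or `list(A, W)` (as in [solve_lqr()]).
#' @param cfg an [lqr_config()].
#' @param T_decision decision interval (day).
#' @return list with `u_star` (continuous dose vector in `[0,1]`) and
#'   `z_next` (stage distribution after the interval).
#' @export
optimal_reference <- function(z, K, model, cfg = lqr_config(),
                              T_decision = 1 / 3) {
  AW <- model_matrices(model)
  u_star <- pmin(pmax(-drop(K %*% (z - cfg$z_goal)), 0), 1)
  drive <- drop(AW$W %*% u_star)
  sol <- deSolve::lsoda(z, c(0, T_decision),
                        function(t, y, p) list(drop(AW$A %*% y) + drive),
                        NULL, rtol = 1e-8, atol = 1e-10)
  z_next <- pmax(unname(sol[nrow(sol), -1L]), 0)
  list(u_star = u_star, z_next = z_next / sum(z_next))
}

#' Decode a linear reference state
#'
#' Maps a reference stage distribution through the decoder to the target
#' nonlinear wound state used by the tracking reward.
#'
#' @param z_star reference stage distribution (on the simplex).
#' @param mapper a trained `deep_mapper`.
#' @return decoded (scaled) state vector.
#' @export
decode_reference <- function(z_star, mapper) decode_state(z_star, mapper)
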