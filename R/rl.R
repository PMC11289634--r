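#' Epsilon-greedy exploration schedule
#'
#' Multiplicative decay with a floor: `eps <- max(eps_min, nu * eps)`.
#'
#' @param eps0 initial exploration rate (close to 1).
#' @param eps_min floor.
#' @param nu decay factor in (0, 1).
#' @return an `epsilon_schedule` list with the `current` rate.
#' @export
epsilon_schedule <- function(eps0 = 0.99, eps_min = 0.01, nu = 0.99) {
  if (nu <= 0 || nu >= 1) stop("nu must lie in (0, 1)")
  if (eps_min > eps0) stop("eps_min must not exceed eps0")
  list(eps0 = eps0, eps_min = eps_min, nu = nu, current = eps0)
}

#' Advance the exploration schedule one step
#'
#' @param sched an [epsilon_schedule()].
#' @return the schedule with `current` decayed to
#'   `max(eps_min, nu * current)`.
#' @export
epsilon_next <- function(sched) {
  sched$current <- max(sched$eps_min, sched$nu * sched$current)
  sched
}

#' Reference-tracking reward
#'
#' `exp(-||x_ref - x_next||_2) - 1`, in `(-1, 0]`, when a decoded LQR
#' reference exists; exactly `-2` when the reference is unavailable, which
#' penalizes the agent for operating in regimes where the learned linear
#' model cannot produce a target.
#'
#' @param x_next realized (scaled) state after the step.
#' @param x_ref decoded reference state, or `NULL` when unavailable.
#' @return scalar reward.
#' @export
reward_tracking <- function(x_next, x_ref) {
  if (is.null(x_ref)) return(-2)
  if (length(x_ref) != length(x_next)) stop("state dimension mismatch")
  exp(-sqrt(sum((x_ref - x_next)^2))) - 1
}

#' Unhealed-time reward
#'
#' `-1` while the wound is open (innermost new tissue at or below the
#' healed threshold), `0` once healed. Minimizing the discounted sum of
#' this reward directly minimizes healing time.
#'
#' @param state wound state (list of profiles) or new-tissue profile.
#' @param sigma healed threshold.
#' @return `-1` or `0`.
#' @export
reward_naive <- function(state, sigma = 0.95) {
  n <- if (is.list(state)) state$n else state
  if (n[1L] <= sigma) -1 else 0
}

#' Initialize the Q-network
#'
#' Four fully connected layers with ReLU activations over the flattened
#' (scaled) wound state. The action space of per-region dose levels is
#' factorized: the head emits one score row per mesh region over the 11
#' dose levels \{0, 0.1, ..., 1\}, and the value of a joint action is the
#' sum of the chosen per-region scores.
#'
#' @param dx input dimension (`5 * n_cells`).
#' @param n_regions number of independently dosed regions (mesh cells).
#' @param hidden widths of the three hidden layers.
#' @return a `q_network`.
#' @export
q_network <- function(dx, n_regions, hidden = c(128L, 64L, 64L)) {
  net <- mlp_init(c(dx, hidden, n_regions * 11L))
  structure(list(net = net, dx = dx, n_regions = as.integer(n_regions)),
            class = "q_network")
}

# raw per-region action scores (logits), one row per region, 11 columns
q_logits <- function(x, qp) {
  X <- if (is.matrix(x)) x else matrix(x, nrow = 1L)
  if (ncol(X) != qp$dx) stop("state dimension mismatch")
  mlp_forward(qp$net, X, head = "linear")$Z
}

#' Per-region action-score table
#'
#' Softmax-normalized per-region scores of each dose level: each row is an
#' 11-way distribution over the levels for one mesh region.
#'
#' @param x flattened (scaled) state.
#' @param qp a [q_network()].
#' @return `n_regions x 11` matrix, rows summing to 1.
#' @export
q_scores <- function(x, qp) {
  logits <- matrix(q_logits(x, qp), qp$n_regions, 11L, byrow = TRUE)
  row_softmax(logits)
}

dose_levels <- seq(0, 1, by = 0.1)

#' Select a dose action
#'
#' Epsilon-greedy over the factorized action grid: with probability
#' `epsilon`, each region's dose level is drawn uniformly from its
#' admissible levels; otherwise each region takes the admissible level
#' with the highest score, ties broken toward the lower dose.
#'
#' @param x flattened (scaled) state.
#' @param qp a [q_network()].
#' @param epsilon exploration probability in `[0, 1]`.
#' @param admissible logical `n_regions x 11` matrix of allowed levels
#'   (default all); a row with no `TRUE` entry is an error.
#' @return list with `u` (dose vector), `levels` (integer level indices
#'   1..11) and `explored` flag.
#' @export
select_action <- function(x, qp, epsilon = 0,
                          admissible = NULL) {
  nr <- qp$n_regions
  if (is.null(admissible)) admissible <- matrix(TRUE, nr, 11L)
  if (any(rowSums(admissible) == 0L)) stop("constraint admits no action")
  explored <- stats::runif(1) < epsilon
  if (explored) {
    lev <- vapply(seq_len(nr), function(i) {
      ok <- which(admissible[i, ])
      ok[sample.int(length(ok), 1L)]
    }, 0L)
  } else {
    sc <- matrix(q_logits(x, qp), nr, 11L, byrow = TRUE)
    sc[!admissible] <- -Inf
    lev <- max.col(sc, ties.method = "first")   # first = lowest dose level
  }
  list(u = dose_levels[lev], levels = lev, explored = explored)
}

#' Admissible-dose constraint
#'
#' Regions whose tissue has already healed (`n >= sigma`) are restricted
#' to zero dose; all levels are admissible elsewhere.
#'
#' @param state wound state (list of profiles).
#' @param sigma healed threshold.
#' @return logical `n_regions x 11` matrix.
#' @export
admissible_actions <- function(state, sigma = 0.95) {
  healed <- state$n >= sigma
  adm <- matrix(TRUE, length(healed), 11L)
  adm[healed, -1L] <- FALSE
  adm
}

# joint Q-value of chosen levels = sum over regions of the chosen logits
q_value <- function(logits_row, levels, nr) {
  sum(logits_row[(seq_len(nr) - 1L) * 11L + levels])
}

# factorized greedy value = sum over regions of the per-region max
q_max <- function(logits_row, nr, admissible = NULL) {
  m <- matrix(logits_row, nr, 11L, byrow = TRUE)
  if (!is.null(admissible)) m[!admissible] <- -Inf
  sum(apply(m, 1L, max))
}

#' Bellman residual of a transition
#'
#' `r + gamma * max_u' Q(x', u') - Q(x, u)` with the factorized value
#' aggregation (sum of per-region scores); the bootstrap term is dropped
#' for terminal transitions.
#'
#' @param tr transition: list with `x`, `levels` (chosen level indices),
#'   `r`, `x_next`, `terminal`, and optionally `adm_next` (admissible-level
#'   mask at the next state, used in the bootstrap max).
#' @param qp a [q_network()].
#' @param gamma discount factor.
#' @param target_qp optional target network for the bootstrap term
#'   (defaults to `qp`).
#' @return scalar residual.
#' @export
bellman_residual <- function(tr, qp, gamma = 0.995, target_qp = qp) {
  nr <- qp$n_regions
  qx <- q_value(drop(q_logits(tr$x, qp)), tr$levels, nr)
  boot <- if (isTRUE(tr$terminal)) 0 else
    gamma * q_max(drop(q_logits(tr$x_next, target_qp)), nr,
                  admissible = tr$adm_next)
  tr$r + boot - qx
}

#' Replay buffer
#'
#' Bounded FIFO store of transitions with uniform minibatch sampling.
#'
#' @param capacity maximum number of stored transitions.
#' @return a `replay_buffer` environment.
#' @export
replay_buffer <- function(capacity = 1e5) {
  env <- new.env(parent = emptyenv())
  env$data <- vector("list", capacity)
  env$capacity <- as.integer(capacity)
  env$n <- 0L
  env$head <- 0L
  class(env) <- "replay_buffer"
  env
}

#' @rdname replay_buffer
#' @param buf a `replay_buffer`.
#' @param tr transition to store.
#' @export
buffer_add <- function(buf, tr) {
  buf$head <- buf$head %% buf$capacity + 1L
  buf$data[[buf$head]] <- tr
  buf$n <- min(buf$n + 1L, buf$capacity)
  invisible(buf)
}

#' @rdname replay_buffer
#' @param size minibatch size (capped at the buffer content).
#' @export
buffer_sample <- function(buf, size) {
  idx <- sample.int(buf$n, min(size, buf$n))
  buf$data[idx]
}

#' One DQN update step
#'
#' Adam step on the mean squared Bellman residual over a minibatch, with
#' the bootstrap target computed from a frozen target network.
#'
#' @param batch list of transitions (see [bellman_residual()]).
#' @param qp a [q_network()].
#' @param opt Adam state from a previous call, or `NULL` to initialize.
#' @param gamma discount factor.
#' @param lr learning rate.
#' @param target_qp frozen target copy of the network.
#' @return list with updated `qp`, `opt`, and the batch `loss`.
#' @export
dqn_update <- function(batch, qp, opt = NULL, gamma = 0.995, lr = 1e-3,
                       target_qp = qp) {
  B <- length(batch)
  if (!B) stop("batch must be nonempty")
  nr <- qp$n_regions
  X <- do.call(rbind, lapply(batch, `[[`, "x"))
  Xn <- do.call(rbind, lapply(batch, `[[`, "x_next"))
  fw <- mlp_forward(qp$net, X, head = "linear")
  ln <- mlp_forward(target_qp$net, Xn, head = "linear")$Z
  idx <- do.call(rbind, lapply(batch, function(tr)
    (seq_len(nr) - 1L) * 11L + tr$levels))
  qx <- vapply(seq_len(B), function(i) sum(fw$Z[i, idx[i, ]]), 0)
  boot <- vapply(seq_len(B), function(i)
    if (isTRUE(batch[[i]]$terminal)) 0 else
      q_max(ln[i, ], nr, admissible = batch[[i]]$adm_next), 0)
  target <- vapply(batch, `[[`, 0, "r") + gamma * boot
  resid <- target - qx
  if (!all(is.finite(resid))) stop("training failure: non-finite Bellman loss")
  dZ <- matrix(0, B, ncol(fw$Z))
  for (i in seq_len(B)) dZ[i, idx[i, ]] <- -2 * resid[i] / B
  grads <- mlp_backward(qp$net, fw, dZ)
  if (is.null(opt)) opt <- adam_init(grads)
  st <- adam_step(qp$net$layers, grads, opt, lr = lr)
  qp$net$layers <- st$params
  list(qp = qp, opt = st$state, loss = mean(resid^2))
}
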