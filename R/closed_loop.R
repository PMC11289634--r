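#' Closed-loop run configuration
#'
#' Master configuration of the adaptive closed-loop training: wound model,
#' mapper pretraining and refinement, LQR weights, DQN hyperparameters and
#' outer-loop termination.
#'
#' @param params a [wound_params()].
#' @param mapper_cfg a [mapper_config()] for the pretraining stage on the
#'   untreated wound.
#' @param refine_cfg a [mapper_config()] for online refinement (warm
#'   start; typically few epochs).
#' @param lqr a [lqr_config()].
#' @param reward reward mode: `"tracking"` (decoded LQR reference) or
#'   `"naive"` (unhealed-time indicator).
#' @param gamma discount factor.
#' @param eps0,eps_min,nu exploration schedule (see [epsilon_schedule()]).
#' @param episodes_per_iter episodes collected per outer iteration.
#' @param max_iter maximum outer iterations.
#' @param tol relative parameter-distance termination tolerance.
#' @param horizon episode horizon (day).
#' @param q_hidden Q-network hidden widths.
#' @param q_lr Q-network learning rate.
#' @param batch_size replay minibatch size.
#' @param target_sync target-network sync period (updates).
#' @param replay_capacity replay-buffer capacity.
#' @param dataset_copies,dataset_noise augmentation of the pretraining
#'   dataset (see [mapper_dataset()]).
#' @param mapper_pool_max cap on pooled online mapper samples.
#' @param seed master seed; fixes simulator sampling, network
#'   initialization, exploration and replay.
#' @return a `run_config` list.
#' @export
run_config <- function(params = wound_params(),
                       mapper_cfg = mapper_config(),
                       refine_cfg = mapper_config(epochs = 150L, n_runs = 1L,
                                                  pred_weight = 0),
                       lqr = lqr_config(),
                       reward = c("tracking", "naive"),
                       gamma = 0.995, eps0 = 0.99, eps_min = 0.01, nu = 0.99,
                       episodes_per_iter = 25L, max_iter = 4L, tol = 1e-4,
                       horizon = 20, q_hidden = c(128L, 64L, 64L),
                       q_lr = 1e-3, batch_size = 64L, target_sync = 200L,
                       replay_capacity = 1e5, dataset_copies = 25L,
                       dataset_noise = 0.1, mapper_pool_max = 4000L,
                       seed = 1L) {
  if (max_iter < 1L) stop("max_iter must be >= 1")
  list(params = params, mapper_cfg = mapper_cfg, refine_cfg = refine_cfg,
       lqr = lqr, reward = match.arg(reward), gamma = gamma, eps0 = eps0,
       eps_min = eps_min, nu = nu,
       episodes_per_iter = as.integer(episodes_per_iter),
       max_iter = as.integer(max_iter), tol = tol, horizon = horizon,
       q_hidden = as.integer(q_hidden), q_lr = q_lr,
       batch_size = as.integer(batch_size),
       target_sync = as.integer(target_sync),
       replay_capacity = replay_capacity,
       dataset_copies = as.integer(dataset_copies),
       dataset_noise = dataset_noise,
       mapper_pool_max = as.integer(mapper_pool_max),
       seed = as.integer(seed))
}

# scale a flattened raw state into mapper feature units
scale_state <- function(xflat, scales, nc) {
  xflat / scales[rep(seq_len(5L), each = nc)]
}

# advance the wound one decision interval under a fixed dose profile
step_wound <- function(y, u, p, dt) {
  deriv <- function(t, yy, parms) {
    s <- unflatten_state(pmax(yy, 0))
    list(unlist(wound_rhs(s, u, p), use.names = FALSE))
  }
  sol <- deSolve::lsoda(y, c(0, dt), deriv, NULL, rtol = 1e-6, atol = 1e-8)
  pmax(sol[2L, -1L], 0)
}

#' A frozen greedy dosing policy backed by a Q-network
#'
#' @param qp a [q_network()].
#' @param scales per-variable feature scales used when the network was
#'   trained.
#' @param sigma healed threshold for the admissible-dose constraint.
#' @return a `dqn_policy`; callable as `function(t, state)` so it can be
#'   passed to [simulate_wound()] or [evaluate_policy()].
#' @export
dqn_policy <- function(qp, scales, sigma = 0.95) {
  f <- function(t, state) {
    x <- scale_state(flatten_state(state), scales, qp$n_regions)
    select_action(x, qp, epsilon = 0,
                  admissible = admissible_actions(state, sigma))$u
  }
  class(f) <- c("dqn_policy", "function")
  attr(f, "qp") <- qp
  attr(f, "scales") <- scales
  f
}

#' Adaptive closed-loop training
#'
#' Joint online training of the stage mapper and the DQN dosing agent
#' against the wound simulator. A pretraining stage learns the
#' encoder/decoder and stage rates from the untreated wound; the outer
#' loop then alternates (i) episode collection under an epsilon-greedy
#' policy with rewards from the decoded LQR reference (or the naive
#' unhealed-time reward), (ii) mapper refinement on the pooled
#' (pretraining + collected) data, which learns the input coupling `W`,
#' and (iii) DQN replay updates. The loop stops when successive parameter
#' vectors are closer than `tol` in relative Euclidean norm or after
#' `max_iter` iterations; mapper parameters are Polyak--Ruppert averaged
#' within each refinement.
#'
#' @param cfg a [run_config()].
#' @param pretrained optionally a pretrained mapper fit (as returned by
#'   [train_mapper()]) with its `dataset`, to skip the pretraining stage.
#' @param verbose print per-iteration progress.
#' @return list with `mapper`, `qp` (Q-network), `policy` (frozen greedy
#'   [dqn_policy()]), `lqr` (gain etc.), `dataset` scales and `history`
#'   (per-episode return, healing time, epsilon; per-iteration parameter
#'   distances and rates).
#' @export
run_training <- function(cfg = run_config(), pretrained = NULL,
                         verbose = FALSE) {
  p <- cfg$params
  nc <- p$n_cells
  set.seed(cfg$seed)
  # --- stage 1: pretrain the mapper on the untreated wound
  if (is.null(pretrained)) {
    traj0 <- simulate_wound(horizon = cfg$horizon, p = p, record_deriv = TRUE)
    ds <- mapper_dataset(traj0, sample_interval = 0.5,
                         copies = cfg$dataset_copies,
                         noise_halfwidth = cfg$dataset_noise,
                         seed = cfg$seed)
    fit <- train_mapper(ds, cfg$mapper_cfg)
  } else {
    ds <- pretrained$dataset
    fit <- pretrained
  }
  mapper <- fit$mapper
  scales <- ds$scales
  # pooled online samples for refinement
  pool <- list(X = ds$X, Xd = ds$Xd, U = ds$U, t = ds$t)
  set.seed(cfg$seed + 1L)
  qp <- q_network(5L * nc, nc, hidden = cfg$q_hidden)
  target_qp <- qp
  opt <- NULL
  buf <- replay_buffer(cfg$replay_capacity)
  sched <- epsilon_schedule(cfg$eps0, cfg$eps_min, cfg$nu)
  n_updates <- 0L
  ep_hist <- data.frame()
  iter_hist <- list()
  flat_params <- function() c(unlist(tree_flatten(qp$net$layers)),
                              unlist(tree_flatten(mapper$enc$layers)),
                              unlist(tree_flatten(mapper$dec$layers)),
                              mapper$s, as.vector(mapper$Win))
  prev <- flat_params()
  for (iter in seq_len(cfg$max_iter)) {
    lq <- tryCatch(solve_lqr(mapper, cfg$lqr), error = function(e) NULL)
    avail <- !is.null(lq) && reference_available(mapper, cfg$lqr)
    for (ep in seq_len(cfg$episodes_per_iter)) {
      y <- flatten_state(initial_wound(p))
      ret <- 0; t <- 0; steps <- 0L
      new_X <- list(); new_Xd <- list(); new_U <- list(); new_t <- c()
      repeat {
        state <- unflatten_state(y)
        x_sc <- scale_state(y, scales, nc)
        act <- select_action(x_sc, qp, epsilon = sched$current,
                             admissible = admissible_actions(state, p$sigma))
        u <- act$u
        # record a mapper sample at the decision knot
        dx <- unlist(wound_rhs(state, u, p), use.names = FALSE)
        new_X[[length(new_X) + 1L]] <- x_sc
        new_Xd[[length(new_Xd) + 1L]] <- scale_state(dx, scales, nc)
        new_U[[length(new_U) + 1L]] <- u
        new_t <- c(new_t, t)
        # reference for the tracking reward
        x_ref <- NULL
        if (cfg$reward == "tracking" && avail) {
          z <- encode_state(x_sc, mapper)
          ref <- optimal_reference(z, lq$K, mapper, cfg$lqr, p$T_decision)
          x_ref <- decode_reference(ref$z_next, mapper)
        }
        y_next <- step_wound(y, u, p, p$T_decision)
        t <- t + p$T_decision
        steps <- steps + 1L
        state_next <- unflatten_state(y_next)
        healed <- wound_size(state_next, p$sigma, p) == 0
        terminal <- healed || t >= cfg$horizon - 1e-9
        x_next_sc <- scale_state(y_next, scales, nc)
        r <- if (cfg$reward == "tracking") {
          if (avail) reward_tracking(x_next_sc, x_ref) else -2
        } else reward_naive(state_next, p$sigma)
        ret <- ret + r
        buffer_add(buf, list(x = x_sc, levels = act$levels, r = r,
                             x_next = x_next_sc, terminal = healed,
                             adm_next = admissible_actions(state_next,
                                                           p$sigma)))
        if (buf$n >= cfg$batch_size) {
          up <- dqn_update(buffer_sample(buf, cfg$batch_size), qp, opt,
                           gamma = cfg$gamma, lr = cfg$q_lr,
                           target_qp = target_qp)
          qp <- up$qp; opt <- up$opt
          n_updates <- n_updates + 1L
          if (n_updates %% cfg$target_sync == 0L) target_qp <- qp
        }
        sched <- epsilon_next(sched)
        y <- y_next
        if (terminal) break
      }
      ep_hist <- rbind(ep_hist, data.frame(
        iter = iter, episode = nrow(ep_hist) + 1L, steps = steps,
        return = ret, healed = healed, epsilon = sched$current))
      pool$X <- rbind(pool$X, do.call(rbind, new_X))
      pool$Xd <- rbind(pool$Xd, do.call(rbind, new_Xd))
      pool$U <- rbind(pool$U, do.call(rbind, new_U))
      pool$t <- c(pool$t, new_t)
      if (nrow(pool$X) > cfg$mapper_pool_max) {
        keep <- c(seq_len(nrow(ds$X)),                    # keep pretraining data
                  seq(nrow(ds$X) + 1L, nrow(pool$X)))
        keep <- utils::tail(keep, cfg$mapper_pool_max)
        pool$X <- pool$X[keep, , drop = FALSE]
        pool$Xd <- pool$Xd[keep, , drop = FALSE]
        pool$U <- pool$U[keep, , drop = FALSE]
        pool$t <- pool$t[keep]
      }
    }
    # --- mapper refinement on pooled data (learns W from treated samples)
    pd <- structure(list(X = pool$X, Xd = pool$Xd, U = pool$U, t = pool$t,
                         scales = scales,
                         provenance = list(n_base = length(pool$t),
                                           copies = 1L)),
                    class = "mapper_dataset")
    rf_cfg <- cfg$refine_cfg
    rf_cfg$seed <- cfg$seed + 100L + iter
    rfit <- train_mapper(pd, rf_cfg, warm_start = mapper)
    mapper <- rfit$mapper
    cur <- flat_params()
    dist <- sqrt(sum((cur - prev)^2)) / max(sqrt(sum(prev^2)), 1e-12)
    iter_hist[[iter]] <- list(iter = iter, param_distance = dist,
                              rates = mapper_rates(mapper),
                              reference_available = avail)
    if (verbose)
      message(sprintf(
        "iter %d: eps=%.3f dist=%.2e rates=(%.3f, %.3f, %.3f) ref=%s",
        iter, sched$current, dist, mapper_rates(mapper)[1],
        mapper_rates(mapper)[2], mapper_rates(mapper)[3], avail))
    prev <- cur
    if (dist < cfg$tol) break
  }
  lq <- tryCatch(solve_lqr(mapper, cfg$lqr), error = function(e) NULL)
  list(mapper = mapper, qp = qp,
       policy = dqn_policy(qp, scales, p$sigma),
       lqr = lq, scales = scales,
       history = list(episodes = ep_hist, iterations = iter_hist),
       config = cfg)
}

#' Evaluate a frozen dosing policy
#'
#' Deterministic rollout (no exploration) of a policy from the fresh
#' injury state, recording the wound-size series, healing time and the
#' spatially summed cumulative actuation.
#'
#' @param policy `function(t, state) -> dose vector` (e.g. a
#'   [dqn_policy()]), or `NULL` for the untreated baseline.
#' @param p a [wound_params()].
#' @param horizon rollout length (day).
#' @param name label used in comparison tables.
#' @return an `evaluation_report` entry: list with `name`, `tau`, `t`,
#'   `wound_size`, `dose` (per-step spatial sum) and `cumulative_dose`
#'   (dose-day units, nondecreasing).
#' @export
evaluate_policy <- function(policy = NULL, p = wound_params(), horizon = 20,
                            name = if (is.null(policy)) "untreated" else "policy") {
  traj <- simulate_wound(controller = policy, horizon = horizon, p = p)
  s <- wound_size_series(traj)
  dose <- rowSums(traj$u)
  dt <- diff(traj$t)
  cum <- c(0, cumsum(dose[-length(dose)] * dt))
  structure(list(name = name, tau = healing_time(traj), t = traj$t,
                 wound_size = s, dose = dose, cumulative_dose = cum,
                 params = p),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("Policy '%s': healing time %s, total dose %.1f dose-days\n",
              x$name,
              if (is.na(x$tau)) "not reached" else sprintf("%.2f days", x$tau),
              max(x$cumulative_dose)))
  invisible(x)
}

#' Compare evaluated policies
#'
#' Healing times and percent reductions relative to a baseline,
#' `100 * (1 - tau / tau_baseline)`. Fixed external reference healing
#' times (e.g. a published brute-force-search policy) can be injected as
#' display-only rows.
#'
#' @param reports list of [evaluate_policy()] entries.
#' @param baseline name of the baseline entry.
#' @param extra optional named numeric vector of external healing times
#'   (days) to include for display.
#' @return data.frame with `policy`, `tau`, `reduction_vs_baseline` (%).
#' @export
compare_policies <- function(reports, baseline = "untreated", extra = NULL) {
  taus <- vapply(reports, `[[`, 0, "tau")
  names(taus) <- vapply(reports, `[[`, "", "name")
  if (!baseline %in% names(taus)) stop("baseline report missing")
  if (is.na(taus[baseline]))
    stop("undefined reduction: baseline did not heal within the horizon")
  taus <- c(taus, extra)
  data.frame(policy = names(taus), tau = unname(taus),
             reduction_vs_baseline =
               unname(100 * (1 - taus / taus[baseline])))
}

#' Dose-safety profile of an evaluated policy
#'
#' Total administered dose during the early window after injury (when
#' dosing is biologically risky) and after the wound has healed (when any
#' dose is waste).
#'
#' @param report an [evaluate_policy()] entry.
#' @param early_window length of the early phase (day).
#' @return list with `early_dose` and `post_healing_dose` (dose-day) and
#'   `total_dose`.
#' @export
safety_profile <- function(report, early_window = 2) {
  t <- report$t
  dt <- c(diff(t), 0)
  early <- sum(report$dose[t < early_window] * dt[t < early_window])
  post <- if (is.na(report$tau)) 0 else
    sum(report$dose[t >= report$tau] * dt[t >= report$tau])
  list(early_dose = early, post_healing_dose = post,
       total_dose = max(report$cumulative_dose))
}

# configuration fingerprint: md5 of a canonical JSON rendering
config_hash <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(jsonlite::toJSON(x, auto_unbox = TRUE, digits = 10), f)
  unname(tools::md5sum(f))
}

#' Export an evaluation report
#'
#' Writes the time series of each policy as CSV and a JSON summary
#' (healing times, reductions, safety profile, seed and config hash).
#' `read_report` re-imports the summary and series.
#'
#' @param reports list of [evaluate_policy()] entries.
#' @param dir output directory (created if needed).
#' @param baseline baseline name for reductions.
#' @param seed seed to record.
#' @return invisibly, the paths written.
#' @export
export_report <- function(reports, dir, baseline = "untreated", seed = NA) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character()
  for (rep in reports) {
    f <- file.path(dir, paste0("series_", rep$name, ".csv"))
    utils::write.csv(
      format(data.frame(t = rep$t, wound_size = rep$wound_size,
                        dose = rep$dose,
                        cumulative_dose = rep$cumulative_dose),
             digits = 17, trim = TRUE),
      f, row.names = FALSE, quote = FALSE)
    paths <- c(paths, f)
  }
  cmp <- compare_policies(reports, baseline)
  summary <- list(
    healing_times = stats::setNames(as.list(cmp$tau), cmp$policy),
    reductions_pct = stats::setNames(as.list(cmp$reduction_vs_baseline),
                                     cmp$policy),
    safety = lapply(stats::setNames(reports,
                                    vapply(reports, `[[`, "", "name")),
                    safety_profile),
    seed = seed,
    config_hash = config_hash(reports[[1L]]$params[
      setdiff(names(reports[[1L]]$params), "r")]))
  jf <- file.path(dir, "summary.json")
  jsonlite::write_json(summary, jf, auto_unbox = TRUE, digits = NA)
  invisible(c(paths, jf))
}
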