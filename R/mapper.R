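#' Structured stage-transition matrix
#'
#' Generator of the four-stage healing chain haemostasis -> inflammation ->
#' proliferation -> maturation. Column sums are zero, so total stage
#' probability is conserved under `dz/dt = A z`; the maturation column is
#' zero (healed is absorbing):
#' \deqn{A = \begin{pmatrix} -k_h & 0 & 0 & 0 \\ k_h & -k_i & 0 & 0 \\
#'   0 & k_i & -k_p & 0 \\ 0 & 0 & k_p & 0 \end{pmatrix}}
#'
#' @param kh,ki,kp nonnegative stage-transition rates (1/day).
#' @return a 4 x 4 matrix.
#' @export
#' @examples
#' build_A(0.495, 0.247, 0.068)
build_A <- function(kh, ki, kp) {
  if (kh < 0 || ki < 0 || kp < 0) stop("transition rates must be nonnegative")
  matrix(c(-kh,  0,   0, 0,
            kh, -ki,  0, 0,
            0,   ki, -kp, 0,
            0,   0,   kp, 0), 4L, 4L, byrow = TRUE)
}

stage_names <- c("Ph", "Pi", "Pp", "Pm")

# internal constructor for the full mapper parameter set
mapper_init <- function(dx, du, hidden = c(64L, 32L), rate_init_range = c(-1, 1),
                        coupling = c("W", "jacobian")) {
  coupling <- match.arg(coupling)
  enc <- mlp_init(c(dx, hidden, 4L))
  dec <- mlp_init(c(4L, rev(hidden), dx))
  s <- stats::runif(3L, rate_init_range[1L], rate_init_range[2L])
  Win <- matrix(0, 4L, du)
  structure(list(enc = enc, dec = dec, s = s, Win = Win,
                 dx = dx, du = du, coupling = coupling),
            class = "deep_mapper")
}

#' @export
print.deep_mapper <- function(x, ...) {
  k <- mapper_rates(x)
  cat(sprintf("DeepMapper: %d -> %s -> 4 (softmax), coupling = %s\n",
              x$dx, paste(x$enc$dims[-c(1, length(x$enc$dims))],
                          collapse = " -> "), x$coupling))
  cat(sprintf("  rates: kh=%.4f ki=%.4f kp=%.4f\n", k[1], k[2], k[3]))
  invisible(x)
}

#' Stage-transition rates of a mapper
#'
#' The rates are stored through a softplus transform so nonnegativity (and
#' hence the generator structure of [build_A()]) holds by construction.
#'
#' @param mapper a `deep_mapper`.
#' @return named vector `c(kh, ki, kp)`.
#' @export
mapper_rates <- function(mapper) {
  stats::setNames(softplus(mapper$s), c("kh", "ki", "kp"))
}

#' Encode wound states into stage probabilities
#'
#' Runs the encoder network (three fully connected layers, ReLU hidden,
#' softmax output), mapping each flattened, scaled wound state to the
#' 4-simplex of healing-stage probabilities (Ph, Pi, Pp, Pm).
#'
#' @param x a state vector of length `dx`, or a batch matrix (rows =
#'   states).
#' @param mapper a `deep_mapper`.
#' @return stage-probability vector (or matrix with one row per state).
#' @export
encode_state <- function(x, mapper) {
  X <- if (is.matrix(x)) x else matrix(x, nrow = 1L)
  if (ncol(X) != mapper$dx) stop("state dimension mismatch")
  Z <- mlp_forward(mapper$enc, X, head = "softmax")$Z
  colnames(Z) <- stage_names
  if (is.matrix(x)) Z else drop(Z)
}

#' Decode stage probabilities into wound states
#'
#' Runs the decoder network (mirror of the encoder with a sigmoid output
#' head), mapping a stage-probability vector back to an estimate of the
#' flattened, scaled wound state. Inputs must lie on the probability
#' simplex.
#'
#' @param z stage-probability vector (or matrix of rows).
#' @param mapper a `deep_mapper`.
#' @param tol tolerance for the simplex check.
#' @return decoded state vector (or matrix), componentwise in (0, 1).
#' @export
decode_state <- function(z, mapper, tol = 1e-6) {
  Z <- if (is.matrix(z)) z else matrix(z, nrow = 1L)
  if (ncol(Z) != 4L) stop("stage vector must have 4 components")
  if (any(abs(rowSums(Z) - 1) > tol) || any(Z < -tol))
    stop("stage probabilities must lie on the 4-simplex")
  X <- mlp_forward(mapper$dec, Z, head = "sigmoid")$Z
  if (is.matrix(z)) X else drop(X)
}

#' Exact encoder Jacobian
#'
#' Analytic derivative of [encode_state()] at `x` (4 x dx), assembled from
#' the layer weights, the ReLU activation pattern and the softmax Jacobian
#' -- not a finite-difference approximation. Because the output sums to
#' one, every column of the Jacobian sums to zero.
#'
#' @param x a state vector of length `dx`.
#' @param mapper a `deep_mapper`.
#' @return a `4 x dx` matrix.
#' @export
encoder_jacobian <- function(x, mapper) {
  if (length(x) != mapper$dx) stop("state dimension mismatch")
  fw <- mlp_forward(mapper$enc, matrix(x, nrow = 1L), head = "softmax")
  z <- drop(fw$Z)
  L <- length(mapper$enc$layers)
  J <- diag(z) - tcrossprod(z)                  # softmax Jacobian
  for (l in rev(seq_len(L))) {
    J <- J %*% t(mapper$enc$layers[[l]]$W)
    if (l > 1L) J <- J * rep(drop(fw$cache$mask[[l - 1L]]), each = 4L)
  }
  J
}

# control tangent in state space for the jacobian coupling mode:
# d xdot / du direction = (0, -u*m1, +u*m1, 0, 0), in scaled units
control_tangent <- function(X, U, scales) {
  nc <- ncol(U)
  m1 <- X[, nc + seq_len(nc), drop = FALSE] * scales[2L]
  V <- matrix(0, nrow(X), ncol(X))
  V[, nc + seq_len(nc)] <- -U * m1 / scales[2L]
  V[, 2L * nc + seq_len(nc)] <- U * m1 / scales[3L]
  V
}

# batched forward pass of the consistency residual, rows = samples.
# W mode:        R = J(x) dxdt - (A z + W u)
# jacobian mode: R = J(x) dxdt - (A z + J(x) B u) = J(x)(dxdt - B u) - A z,
# so the control term folds into the tangent and shares one forward pass.
consistency_forward <- function(X, Xd, U, mapper, scales = rep(1, 5L)) {
  k <- softplus(mapper$s)
  A <- build_A(k[1L], k[2L], k[3L])
  have_u <- !is.null(U) && any(U != 0)
  if (have_u && mapper$coupling == "jacobian")
    Xd <- Xd - control_tangent(X, U, scales)
  fw <- mlp_forward(mapper$enc, X, Xd, head = "softmax")
  drive <- fw$Z %*% t(A)
  if (have_u && mapper$coupling == "W")
    drive <- drive + U %*% t(mapper$Win)
  list(R = fw$TZ - drive, fw = fw, A = A, k = k)
}

#' Jacobian-consistency loss
#'
#' Mean squared norm of the linear-model residual
#' `J(x) dx/dt - (A z + W u)` over a batch: the extent to which the
#' encoded trajectory fails to follow the structured linear stage dynamics.
#' The encoder Jacobian-vector product is computed by exact forward-mode
#' differentiation.
#'
#' @param data a `mapper_dataset` (or slice).
#' @param mapper a `deep_mapper`.
#' @return nonnegative scalar.
#' @export
consistency_loss <- function(data, mapper) {
  if (!nrow(data$X)) stop("invalid dataset: empty batch")
  if (is.null(data$Xd)) stop("invalid dataset: state derivatives missing")
  cf <- consistency_forward(data$X, data$Xd, data$U, mapper,
                            scales = data$scales %||% rep(1, 5L))
  mean(rowSums(cf$R^2))
}

#' Reconstruction loss
#'
#' Mean squared error of the decoder/encoder round trip
#' `x - decode(encode(x))` over a batch.
#'
#' @inheritParams consistency_loss
#' @return nonnegative scalar.
#' @export
reconstruction_loss <- function(data, mapper) {
  if (!nrow(data$X)) stop("invalid dataset: empty batch")
  Z <- mlp_forward(mapper$enc, data$X, head = "softmax")$Z
  Xhat <- mlp_forward(mapper$dec, Z, head = "sigmoid")$Z
  mean(rowSums((data$X - Xhat)^2))
}

#' Total training loss
#'
#' `consistency_loss + alpha * reconstruction_loss`; the decoder term rules
#' out the degenerate all-zero solution that trivially minimizes the
#' consistency term alone.
#'
#' @inheritParams consistency_loss
#' @param alpha nonnegative decoder-loss weight.
#' @return scalar.
#' @export
total_loss <- function(data, mapper, alpha = 1) {
  if (alpha < 0) stop("alpha must be nonnegative")
  consistency_loss(data, mapper) +
    if (alpha > 0) alpha * reconstruction_loss(data, mapper) else 0
}

# gradients of (consistency + alpha * reconstruction) w.r.t. all mapper
# parameters, averaged over the batch
mapper_gradients <- function(X, Xd, U, mapper, alpha,
                             scales = rep(1, 5L), anchor = NULL) {
  B <- nrow(X)
  cf <- consistency_forward(X, Xd, U, mapper, scales = scales)
  G <- 2 / B * cf$R
  # encoder grads through both primal (via -A z) and tangent paths
  dZ <- -G %*% cf$A
  genc <- mlp_backward(mapper$enc, cf$fw, dZ, dTZ = G)
  # structured-rate grads: dL/dA = -G^T Z, folded through the chain pattern
  GA <- -crossprod(G, cf$fw$Z)
  gk <- c(-GA[1L, 1L] + GA[2L, 1L],
          -GA[2L, 2L] + GA[3L, 2L],
          -GA[3L, 3L] + GA[4L, 3L])
  gs <- gk * stats::plogis(mapper$s)            # softplus chain rule
  gW <- matrix(0, 4L, mapper$du)
  if (!is.null(U) && any(U != 0) && mapper$coupling == "W")
    gW <- -crossprod(G, U)
  # initial-stage anchor: encode(x at t=0) should be e1 (haemostasis)
  if (!is.null(anchor) && anchor$weight > 0 && length(anchor$rows)) {
    fa <- mlp_forward(mapper$enc, X[anchor$rows, , drop = FALSE],
                      head = "softmax")
    dZa <- 2 * anchor$weight / length(anchor$rows) *
      sweep(fa$Z, 2L, c(1, 0, 0, 0), "-")
    genc <- tree_map(`+`, genc, mlp_backward(mapper$enc, fa, dZa))
  }
  # decoder (and encoder-through-decoder) grads
  gdec <- tree_map(function(x) x * 0, mapper$dec$layers)
  if (alpha > 0) {
    fe <- mlp_forward(mapper$enc, X, head = "softmax")
    fd <- mlp_forward(mapper$dec, fe$Z, head = "sigmoid")
    dXhat <- -2 / B * alpha * (X - fd$Z)
    gdec <- mlp_backward(mapper$dec, fd, dXhat)
    # back through the decoder input into the encoder
    dZrec <- dXhat * fd$Z * (1 - fd$Z)
    for (l in rev(seq_along(mapper$dec$layers))) {
      if (l < length(mapper$dec$layers)) dZrec <- dZrec * fd$cache$mask[[l]]
      dZrec <- tcrossprod(dZrec, mapper$dec$layers[[l]]$W)
    }
    genc2 <- mlp_backward(mapper$enc, fe, dZrec)
    genc <- tree_map(`+`, genc, genc2)
  }
  list(enc = genc, dec = gdec, s = gs, Win = gW)
}

# differentiable surrogate of expm(A * dt): (I + dt/m A)^m
expm_poly <- function(A, dt, m = 16L) {
  M <- diag(4L) + (dt / m) * A
  P <- diag(4L)
  pows <- vector("list", m + 1L)          # pows[[j]] = M^(j-1)
  pows[[1L]] <- diag(4L)
  for (j in seq_len(m)) pows[[j + 1L]] <- pows[[j]] %*% M
  list(P = pows[[m + 1L]], M = M, pows = pows, m = m, dt = dt)
}

# gradient of scalar loss w.r.t. A given dL/dP through the power product
expm_poly_backward <- function(ep, dP) {
  dM <- matrix(0, 4L, 4L)
  for (j in 0:(ep$m - 1L))                # d(M^m)/dM product rule
    dM <- dM + t(ep$pows[[j + 1L]]) %*% dP %*% t(ep$pows[[ep$m - j]])
  (ep$dt / ep$m) * dM
}

# linear-prediction term over one or more horizons:
# || enc(x_{t+L dt}) - (e^{A L dt} z_t + L dt W u) ||^2, residuals scaled
# by 1/(L dt) so every horizon contributes on a common rate scale
pred_gradients <- function(data, mapper, weight, lags = c(1L, 4L, 12L)) {
  k <- softplus(mapper$s)
  A <- build_A(k[1L], k[2L], k[3L])
  nb <- data$provenance$n_base %||% max(data$pair_dst)
  genc <- NULL; gk <- numeric(3L)
  gW <- matrix(0, 4L, mapper$du)
  loss <- 0
  for (lag in lags[lags < nb]) {
    src <- seq_len(nb - lag)
    dst <- src + lag
    N <- length(src)
    h <- lag * data$dt
    ep <- expm_poly(A, h)
    fs <- mlp_forward(mapper$enc, data$X[src, , drop = FALSE],
                      head = "softmax")
    fd <- mlp_forward(mapper$enc, data$X[dst, , drop = FALSE],
                      head = "softmax")
    Us <- data$U[src, , drop = FALSE]
    have_u <- any(Us != 0) && mapper$coupling == "W"
    pred <- fs$Z %*% t(ep$P)
    if (have_u) pred <- pred + h * Us %*% t(mapper$Win)
    q <- fd$Z - pred
    w <- weight / h^2                       # per-unit-time residual scale
    loss <- loss + w * mean(rowSums(q^2))
    c1 <- 2 * w / N
    genc_lag <- tree_map(`+`,
                         mlp_backward(mapper$enc, fd, c1 * q),
                         mlp_backward(mapper$enc, fs, -c1 * q %*% ep$P))
    genc <- if (is.null(genc)) genc_lag else tree_map(`+`, genc, genc_lag)
    GA <- expm_poly_backward(ep, -c1 * crossprod(q, fs$Z))
    gk <- gk + c(-GA[1L, 1L] + GA[2L, 1L],
                 -GA[2L, 2L] + GA[3L, 2L],
                 -GA[3L, 3L] + GA[4L, 3L])
    if (have_u) gW <- gW - c1 * h * crossprod(q, Us)
  }
  list(enc = genc, s = gk * stats::plogis(mapper$s), Win = gW, loss = loss)
}

#' Build a training dataset from a trajectory
#'
#' Subsamples a simulated trajectory at `sample_interval`, flattens states
#' and their time derivatives, rescales each of the five variable blocks
#' into `[0, 1]` by its trajectory maximum (the decoder output head is a
#' sigmoid, so features must be unit-scaled; derivatives share the same
#' factors), and optionally augments the samples with i.i.d. uniform noise
#' on the scaled features: each base point is replicated `copies` times and
#' noise from `[-noise_halfwidth, noise_halfwidth]` is added to the state
#' (the recorded derivative is carried over from the base point).
#'
#' @param traj a `wound_trajectory` simulated with `record_deriv = TRUE`.
#' @param sample_interval spacing (day) of base points along the
#'   trajectory.
#' @param copies replicates per base point (>= 1; 1 = no augmentation).
#' @param noise_halfwidth half-width of the uniform feature noise.
#' @param seed RNG seed for the noise draws.
#' @return a `mapper_dataset`: list with scaled `X`, `Xd`, `U` matrices,
#'   `scales` (per-variable factors), `t` (base times per sample) and
#'   provenance.
#' @export
mapper_dataset <- function(traj, sample_interval = 0.5, copies = 1L,
                           noise_halfwidth = 0.1, seed = 1L) {
  if (!length(traj$t)) stop("invalid input: empty trajectory")
  if (copies < 1L) stop("copies must be >= 1")
  if (noise_halfwidth < 0) stop("noise_halfwidth must be nonnegative")
  if (is.null(traj$dxdt))
    stop("trajectory must carry state derivatives (record_deriv = TRUE)")
  keep <- which(abs((traj$t / sample_interval) -
                      round(traj$t / sample_interval)) < 1e-6)
  spacing <- diff(traj$t[keep])
  if (!length(spacing) || any(abs(spacing - sample_interval) > 1e-6))
    stop("trajectory does not contain samples at the requested interval; ",
         "simulate with a matching dt_record")
  nc <- traj$params$n_cells
  blocks <- rep(seq_len(5L), each = nc)
  scales <- vapply(seq_len(5L), function(v)
    max(traj$x[keep, blocks == v], 1), 0)
  sc <- scales[blocks]
  X0 <- sweep(traj$x[keep, , drop = FALSE], 2L, sc, "/")
  Xd0 <- sweep(traj$dxdt[keep, , drop = FALSE], 2L, sc, "/")
  U0 <- traj$u[keep, , drop = FALSE]
  nb <- length(keep)
  idx <- rep(seq_len(nb), times = copies)
  X <- X0[idx, , drop = FALSE]
  if (copies > 1L || noise_halfwidth > 0) {
    set.seed(seed)
    noise <- matrix(stats::runif(length(X), -noise_halfwidth,
                                 noise_halfwidth), nrow(X), ncol(X))
    if (copies >= 1L) noise[seq_along(keep), ] <- 0  # keep the clean base copy
    X <- X + noise
  }
  # consecutive clean base rows, used by the one-step linear-prediction term
  structure(list(X = X, Xd = Xd0[idx, , drop = FALSE],
                 U = U0[idx, , drop = FALSE], scales = scales,
                 t = traj$t[keep][idx],
                 pair_src = seq_len(nb - 1L), pair_dst = seq_len(nb - 1L) + 1L,
                 dt = stats::median(spacing),
                 provenance = list(sample_interval = sample_interval,
                                   copies = copies,
                                   noise_halfwidth = noise_halfwidth,
                                   seed = seed,
                                   n_base = nb)),
            class = "mapper_dataset")
}

#' @export
print.mapper_dataset <- function(x, ...) {
  cat(sprintf(
    "Mapper dataset: %d samples (%d base points x %d copies), dx = %d\n",
    nrow(x$X), x$provenance$n_base, x$provenance$copies, ncol(x$X)))
  invisible(x)
}

dataset_slice <- function(data, i) {
  out <- data
  out$X <- data$X[i, , drop = FALSE]
  out$Xd <- data$Xd[i, , drop = FALSE]
  out$U <- data$U[i, , drop = FALSE]
  out$t <- data$t[i]
  out
}

#' Linear-model fit quality along a trajectory
#'
#' Ratio of the mean consistency-residual norm
#' `||J(x) dx/dt - (A z + W u)||` to the mean norm of the encoded
#' derivative `||J(x) dx/dt||` over a dataset: 0 means the encoded
#' trajectory follows the learned linear stage dynamics exactly.
#'
#' @param data a `mapper_dataset` (typically the clean base rows).
#' @param mapper a trained `deep_mapper`.
#' @return nonnegative scalar ratio.
#' @export
linear_fit_ratio <- function(data, mapper) {
  cf <- consistency_forward(data$X, data$Xd, data$U, mapper,
                            scales = data$scales %||% rep(1, 5L))
  mean(sqrt(rowSums(cf$R^2))) / mean(sqrt(rowSums(cf$fw$TZ^2)))
}

#' Per-variable reconstruction error
#'
#' Mean squared error of `decode(encode(x))` against `x`, split by the
#' five wound variables (in scaled feature units).
#'
#' @inheritParams linear_fit_ratio
#' @return named numeric vector of per-variable MSEs.
#' @export
reconstruction_mse <- function(data, mapper) {
  Z <- encode_state(data$X, mapper)
  Xhat <- decode_state(Z, mapper)
  nc <- ncol(data$X) / 5L
  vapply(stats::setNames(1:5, c("a", "m1", "m2", "c", "n")), function(v)
    mean((data$X[, (v - 1L) * nc + seq_len(nc)] -
            Xhat[, (v - 1L) * nc + seq_len(nc)])^2), 0)
}

#' Polyak--Ruppert average of parameter iterates
#'
#' Arithmetic mean of the iterates with index beyond the burn-in fraction:
#' with `N` iterates and burn-in `b`, averages iterates `floor(b*N)+1 .. N`.
#' Iterates may be numerics or (nested) lists of numerics, averaged
#' elementwise.
#'
#' @param iterates list of parameter snapshots, in order.
#' @param burn_in_fraction fraction of early iterates to discard, in
#'   `[0, 1)`.
#' @return the averaged parameters (same shape as one iterate).
#' @export
#' @examples
#' polyak_average(as.list(1:5), 0.8)  # mean of the last 20%: 4.5
polyak_average <- function(iterates, burn_in_fraction = 0.8) {
  N <- length(iterates)
  if (burn_in_fraction < 0 || burn_in_fraction >= 1)
    stop("invalid config: burn_in_fraction must lie in [0, 1)")
  keep <- max(1L, floor(burn_in_fraction * N)):N   # indices >= N0
  if (!length(keep)) stop("invalid config: burn-in leaves no iterates")
  acc <- iterates[[keep[1L]]]
  for (i in keep[-1L]) acc <- tree_map(`+`, acc, iterates[[i]])
  tree_map(function(x) x / length(keep), acc)
}

#' Mapper training configuration
#'
#' @param alpha decoder-loss weight (>= 0).
#' @param lr Adam learning rate at the first epoch.
#' @param lr_final learning rate at the last epoch (geometric decay across
#'   epochs; set equal to `lr` for a constant rate).
#' @param epochs training epochs per run.
#' @param batch_size minibatch size; batches of at least the dataset size
#'   mean full-batch training.
#' @param burn_in_fraction Polyak--Ruppert burn-in (fraction of epochs
#'   discarded before averaging).
#' @param n_runs independent restarts (fresh Kaiming init each).
#' @param hidden hidden-layer widths of the encoder (decoder mirrored).
#' @param coupling input-coupling mode: learned constant matrix `"W"`
#'   (default) or the state-dependent `"jacobian"` form `J(x) B u`.
#' @param pred_weight weight of the one-step linear-prediction term
#'   `||encode(x(t+dt)) - exp(A dt) encode(x(t))||^2` over consecutive
#'   samples; it ties the latent trajectory to the stage dynamics at the
#'   data's own timescale and prevents the encoder from degenerately
#'   flattening the consistency residual (0 disables).
#' @param anchor_weight weight of the initial-stage anchor term
#'   `||encode(x(0)) - (1,0,0,0)||^2`, which pins the fresh wound to the
#'   haemostasis stage and makes the stage assignment of the learned
#'   representation unique (0 disables).
#' @param chart_epochs supervised warm-start epochs fitting the encoder to
#'   the biological stage chart (normalized variable-block means under the
#'   standard stage semantics) before the main objective; selects the
#'   canonical stage labeling among the many latent charts that fit the
#'   dynamics equally well (0 disables).
#' @param seed master seed.
#' @return a `mapper_config` list.
#' @export
mapper_config <- function(alpha = 1, lr = 2e-3, lr_final = lr / 5,
                          epochs = 2000L,
                          batch_size = 256L, burn_in_fraction = 0.8,
                          n_runs = 5L, hidden = c(64L, 32L),
                          coupling = c("W", "jacobian"),
                          anchor_weight = 1, pred_weight = 10,
                          chart_epochs = 300L, seed = 1L) {
  if (alpha < 0) stop("alpha must be nonnegative")
  if (burn_in_fraction < 0 || burn_in_fraction >= 1)
    stop("burn_in_fraction must lie in [0, 1)")
  list(alpha = alpha, lr = lr, lr_final = lr_final,
       epochs = as.integer(epochs),
       batch_size = as.integer(batch_size),
       burn_in_fraction = burn_in_fraction, n_runs = as.integer(n_runs),
       hidden = as.integer(hidden), coupling = match.arg(coupling),
       anchor_weight = anchor_weight, pred_weight = pred_weight,
       chart_epochs = as.integer(chart_epochs), seed = as.integer(seed))
}

# biological stage chart: surrogate stage probabilities from the scaled
# variable blocks under the standard stage semantics (haemostasis ~ debris,
# inflammation ~ M1, proliferation ~ repair tissue, maturation ~ new
# tissue); used only to initialize the encoder in its canonical basin
stage_chart <- function(X) {
  nc <- ncol(X) / 5L
  bm <- vapply(1:5, function(v)
    rowMeans(X[, (v - 1L) * nc + seq_len(nc), drop = FALSE]), numeric(nrow(X)))
  v <- cbind(bm[, 1L], bm[, 2L], (bm[, 3L] + bm[, 4L]) / 2, bm[, 5L]) + 1e-6
  v / rowSums(v)
}

# supervised warm start of the encoder toward the stage chart
chart_pretrain <- function(enc, X, epochs, lr = 3e-3) {
  P <- stage_chart(X)
  opt <- NULL
  for (ep in seq_len(epochs)) {
    fw <- mlp_forward(enc, X, head = "softmax")
    g <- mlp_backward(enc, fw, 2 * (fw$Z - P) / nrow(X))
    if (is.null(opt)) opt <- adam_init(g)
    st <- adam_step(enc$layers, g, opt, lr = lr)
    enc$layers <- st$params; opt <- st$state
  }
  enc
}

# one training run; returns the Polyak-averaged mapper plus history
train_mapper_once <- function(data, cfg, seed, mapper = NULL) {
  set.seed(seed)
  N <- nrow(data$X)
  if (is.null(mapper)) {
    mapper <- mapper_init(ncol(data$X), ncol(data$U), hidden = cfg$hidden,
                          coupling = cfg$coupling)
    if ((cfg$chart_epochs %||% 0) > 0)
      mapper$enc <- chart_pretrain(mapper$enc, data$X, cfg$chart_epochs)
  }
  params <- mapper[c("enc", "dec", "s", "Win")]
  params$enc <- params$enc$layers
  params$dec <- params$dec$layers
  opt <- adam_init(params)
  loss_hist <- numeric(cfg$epochs)
  rate_hist <- matrix(NA_real_, cfg$epochs, 3L,
                      dimnames = list(NULL, c("kh", "ki", "kp")))
  burn <- floor(cfg$burn_in_fraction * cfg$epochs)
  avg <- NULL; n_avg <- 0L
  lr_final <- cfg$lr_final %||% cfg$lr
  decay <- if (cfg$epochs > 1L && cfg$lr > 0 && lr_final > 0)
    (lr_final / cfg$lr)^(1 / (cfg$epochs - 1L)) else 1
  for (ep in seq_len(cfg$epochs)) {
    lr_ep <- cfg$lr * decay^(ep - 1L)
    ord <- if (cfg$batch_size >= N) list(seq_len(N)) else
      split(sample.int(N), ceiling(seq_len(N) / cfg$batch_size))
    for (b in ord) {
      mapper$enc$layers <- params$enc
      mapper$dec$layers <- params$dec
      mapper$s <- params$s
      mapper$Win <- params$Win
      anchor <- if ((cfg$anchor_weight %||% 0) > 0) {
        # clean t = 0 rows only: the anchor pins the exact initial state,
        # not its noise-augmented neighbourhood
        nb <- data$provenance$n_base %||% nrow(data$X)
        rows <- which(abs(data$t[b]) < 1e-9 & b <= nb)
        list(weight = cfg$anchor_weight, rows = rows)
      }
      g <- mapper_gradients(data$X[b, , drop = FALSE],
                            data$Xd[b, , drop = FALSE],
                            data$U[b, , drop = FALSE], mapper, cfg$alpha,
                            scales = data$scales %||% rep(1, 5L),
                            anchor = anchor)
      if ((cfg$pred_weight %||% 0) > 0 && length(data$pair_src %||% c())) {
        pg <- pred_gradients(data, mapper, cfg$pred_weight)
        g$enc <- tree_map(`+`, g$enc, pg$enc)
        g$s <- g$s + pg$s
        g$Win <- g$Win + pg$Win
      }
      st <- adam_step(params, g[c("enc", "dec", "s", "Win")], opt,
                      lr = lr_ep)
      params <- st$params; opt <- st$state
    }
    mapper$enc$layers <- params$enc
    mapper$dec$layers <- params$dec
    mapper$s <- params$s
    mapper$Win <- params$Win
    loss_hist[ep] <- total_loss(data, mapper, cfg$alpha)
    if (!is.finite(loss_hist[ep]))
      stop("training failure: loss diverged at epoch ", ep)
    rate_hist[ep, ] <- softplus(params$s)
    if (ep >= max(1L, burn)) {             # running Polyak-Ruppert mean
      avg <- if (is.null(avg)) params else tree_map(`+`, avg, params)
      n_avg <- n_avg + 1L
    }
  }
  avg <- tree_map(function(x) x / n_avg, avg)
  mapper$enc$layers <- avg$enc
  mapper$dec$layers <- avg$dec
  mapper$s <- avg$s
  mapper$Win <- avg$Win
  list(mapper = mapper, loss = loss_hist, rates = rate_hist,
       rates_polyak = stats::setNames(softplus(avg$s), c("kh", "ki", "kp")))
}

#' Train the DeepMapper
#'
#' Minimizes the Jacobian-consistency plus reconstruction objective with
#' Adam over `n_runs` independent Kaiming-initialized restarts. Within each
#' run, parameters are Polyak--Ruppert averaged over the post-burn-in
#' epochs; across runs, the stage-transition rates are additionally
#' averaged (`rates_run_mean`), which is the headline estimate of
#' (kh, ki, kp). The returned mapper is the run with the lowest final
#' total loss (its encoder/decoder/rates are mutually consistent).
#'
#' @param data a `mapper_dataset`.
#' @param cfg a [mapper_config()].
#' @param warm_start optionally a `deep_mapper` to refine instead of a
#'   fresh initialization (forces `n_runs = 1`).
#' @return list with elements `mapper` (Polyak-averaged `deep_mapper`),
#'   `rates_run_mean`, `rates_per_run`, and `history` (per-epoch loss and
#'   rate traces per run). Final loss never exceeds the initial loss.
#' @export
train_mapper <- function(data, cfg = mapper_config(), warm_start = NULL) {
  if (!nrow(data$X)) stop("invalid dataset: no samples")
  n_runs <- if (is.null(warm_start)) cfg$n_runs else 1L
  runs <- lapply(seq_len(n_runs), function(k)
    train_mapper_once(data, cfg, seed = cfg$seed + 1000L * (k - 1L),
                      mapper = warm_start))
  final <- vapply(runs, function(r) r$loss[length(r$loss)], 0)
  best <- which.min(final)
  per_run <- t(vapply(runs, `[[`, numeric(3L), "rates_polyak"))
  list(mapper = runs[[best]]$mapper,
       rates_run_mean = colMeans(per_run),
       rates_per_run = per_run,
       history = lapply(runs, function(r) r[c("loss", "rates")]),
       best_run = best)
}
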