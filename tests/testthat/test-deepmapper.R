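test_that("build_A has the conserved chain structure", {
  A <- build_A(0.495, 0.247, 0.068)
  expect_equal(colSums(A), rep(0, 4))
  expect_equal(A[1, 1], -0.495)
  expect_equal(A[2, 1], 0.495)
  expect_equal(A[3, 2], 0.247)
  expect_equal(A[4, 3], 0.068)
  expect_equal(A[, 4], rep(0, 4))                    # healed is absorbing
  expect_identical(build_A(0, 0, 0), matrix(0, 4, 4))
  expect_error(build_A(-0.1, 0, 0), "nonnegative")
  # conservation holds for any rates under the continuous dynamics
  set.seed(1)
  for (i in 1:20) {
    A <- do.call(build_A, as.list(runif(3, 0, 2)))
    expect_equal(colSums(A), rep(0, 4))
  }
})

test_that("stage dynamics conserve total probability", {
  A <- build_A(0.7, 0.3, 0.1)
  z0 <- c(1, 0, 0, 0)
  sol <- deSolve::lsoda(z0, seq(0, 20, 0.5),
                        function(t, z, p) list(drop(A %*% z)), NULL,
                        rtol = 1e-10, atol = 1e-12)
  expect_lt(max(abs(rowSums(sol[, -1]) - 1)), 1e-8)
  expect_true(all(sol[, -1] > -1e-10))
})

test_that("encoder output lives on the simplex and is deterministic", {
  m <- random_mapper()
  set.seed(3)
  X <- matrix(runif(200 * m$dx), 200)
  Z <- encode_state(X, m)
  expect_lt(max(abs(rowSums(Z) - 1)), 1e-9)
  expect_true(all(Z > 0 & Z < 1))
  expect_identical(encode_state(X[1, ], m), encode_state(X[1, ], m))
  expect_error(encode_state(runif(3), m), "dimension")
})

test_that("decoder output lies in (0,1) and enforces the simplex domain", {
  m <- random_mapper()
  z <- c(0.4, 0.3, 0.2, 0.1)
  x <- decode_state(z, m)
  expect_true(all(x > 0 & x < 1))
  expect_length(x, m$dx)
  expect_error(decode_state(c(0.9, 0.9, 0.1, 0.1), m), "simplex")
  expect_identical(decode_reference(z, m), decode_state(z, m))
})

test_that("encoder Jacobian matches central finite differences", {
  for (seed in 1:5) {
    m <- random_mapper(seed = seed)
    set.seed(seed + 100)
    x <- runif(m$dx)
    J <- encoder_jacobian(x, m)
    expect_equal(dim(J), c(4L, m$dx))
    expect_lt(max(abs(colSums(J))), 1e-12)            # simplex constraint
    h <- 1e-5
    Jfd <- vapply(seq_len(m$dx), function(i) {
      xp <- x; xp[i] <- x[i] + h
      xm <- x; xm[i] <- x[i] - h
      (encode_state(xp, m) - encode_state(xm, m)) / (2 * h)
    }, numeric(4))
    expect_lt(max(abs(J - Jfd)), 1e-4)
  }
})

test_that("zeroed output layer gives a zero Jacobian", {
  m <- random_mapper()
  m$enc$layers[[3]]$W[] <- 0
  expect_equal(encoder_jacobian(runif(m$dx), m), matrix(0, 4, m$dx))
})

test_that("consistency loss vanishes on exactly consistent data", {
  # hand-built example: encoder reduced to softmax of a linear map
  m <- random_mapper(dx = 6L, du = 2L)
  for (l in 1:2) {                 # make hidden layers the identity-ish map
    m$enc$layers[[l]]$W <- diag(1, nrow(m$enc$layers[[l]]$W),
                                ncol(m$enc$layers[[l]]$W))
    m$enc$layers[[l]]$b[] <- 1     # keep ReLU strictly active
  }
  set.seed(4)
  x <- runif(6)
  z <- encode_state(x, m)
  J <- encoder_jacobian(x, m)
  k <- mapper_rates(m)
  A <- build_A(k[1], k[2], k[3])
  u <- runif(2)
  target <- drop(A %*% z) + drop(m$Win %*% u)
  # construct xd with J xd = target exactly (rows of J sum to 0, as does
  # the target, so solving on three rows solves all four)
  J3 <- J[1:3, , drop = FALSE]
  xd <- drop(t(J3) %*% solve(J3 %*% t(J3), target[1:3]))
  batch <- structure(list(X = matrix(x, 1), Xd = matrix(xd, 1),
                          U = matrix(u, 1), scales = rep(1, 5)),
                     class = "mapper_dataset")
  expect_lt(consistency_loss(batch, m), 1e-16)
})

test_that("all-zero encoder head with zero model is the degenerate minimum", {
  m <- random_mapper()
  m$enc$layers[[3]]$W[] <- 0
  m$enc$layers[[3]]$b[] <- 0
  m$s[] <- -50                            # rates ~ 0
  m$Win[] <- 0
  b <- random_batch()
  b$U[] <- 0
  expect_lt(consistency_loss(b, m), 1e-12)
  expect_gt(reconstruction_loss(b, m), 0) # ... which the decoder term penalizes
})

test_that("consistency loss matches a hand-computed residual norm", {
  m <- random_mapper(dx = 4L, du = 1L, hidden = c(3L, 3L), seed = 7)
  b <- random_batch(dx = 4L, du = 1L, n = 3L, seed = 8)
  # independent evaluation from exported primitives
  k <- mapper_rates(m)
  A <- build_A(k[1], k[2], k[3])
  res <- vapply(1:3, function(i) {
    J <- encoder_jacobian(b$X[i, ], m)
    z <- encode_state(b$X[i, ], m)
    r <- drop(J %*% b$Xd[i, ]) - (drop(A %*% z) + drop(m$Win %*% b$U[i, ]))
    sum(r^2)
  }, 0)
  expect_equal(consistency_loss(b, m), mean(res), tolerance = 1e-12)
})

test_that("reconstruction and total losses satisfy their identities", {
  m <- random_mapper()
  b <- random_batch()
  lc <- consistency_loss(b, m)
  lr <- reconstruction_loss(b, m)
  expect_gte(lr, 0)
  expect_equal(total_loss(b, m, alpha = 0), lc)
  expect_equal(total_loss(b, m, alpha = 1), lc + lr)
  expect_equal(total_loss(b, m, alpha = 2.5), lc + 2.5 * lr)
  expect_error(total_loss(b, m, alpha = -1), "nonnegative")
  # single-coordinate perturbation: loss is delta^2
  Z <- encode_state(b$X, m)
  Xhat <- decode_state(Z, m)
  delta <- b$X - Xhat
  expect_equal(lr, mean(rowSums(delta^2)))
})

test_that("mapper gradients agree with finite differences", {
  m <- random_mapper()
  b <- random_batch()
  g <- woundloop:::mapper_gradients(b$X, b$Xd, b$U, m, alpha = 0.7)
  loss_at <- function(m2) total_loss(b, m2, 0.7)
  h <- 1e-6
  # transition-rate parameters
  for (i in 1:3) {
    mp <- m; mp$s[i] <- m$s[i] + h
    mm <- m; mm$s[i] <- m$s[i] - h
    expect_equal(g$s[i], (loss_at(mp) - loss_at(mm)) / (2 * h),
                 tolerance = 1e-4)
  }
  # a weight from each network
  mp <- m; mp$enc$layers[[1]]$W[1, 1] <- m$enc$layers[[1]]$W[1, 1] + h
  mm <- m; mm$enc$layers[[1]]$W[1, 1] <- m$enc$layers[[1]]$W[1, 1] - h
  expect_equal(g$enc[[1]]$W[1, 1], (loss_at(mp) - loss_at(mm)) / (2 * h),
               tolerance = 1e-4)
  mp <- m; mp$dec$layers[[2]]$W[2, 1] <- m$dec$layers[[2]]$W[2, 1] + h
  mm <- m; mm$dec$layers[[2]]$W[2, 1] <- m$dec$layers[[2]]$W[2, 1] - h
  expect_equal(g$dec[[2]]$W[2, 1], (loss_at(mp) - loss_at(mm)) / (2 * h),
               tolerance = 1e-4)
  mp <- m; mp$Win[2, 1] <- m$Win[2, 1] + h
  mm <- m; mm$Win[2, 1] <- m$Win[2, 1] - h
  expect_equal(g$Win[2, 1], (loss_at(mp) - loss_at(mm)) / (2 * h),
               tolerance = 1e-4)
})

test_that("one-step prediction gradients agree with finite differences", {
  m <- random_mapper(dx = 8L, du = 2L, hidden = c(5L, 4L), seed = 3)
  set.seed(30)
  data <- list(X = matrix(runif(9 * 8), 9), U = matrix(runif(18), 9),
               pair_src = 1:6, pair_dst = 4:9, dt = 0.5)
  g <- woundloop:::pred_gradients(data, m, weight = 3)
  ploss <- function(m2) woundloop:::pred_gradients(data, m2, 3)$loss
  h <- 1e-6
  for (i in 1:3) {
    mp <- m; mp$s[i] <- m$s[i] + h
    mm <- m; mm$s[i] <- m$s[i] - h
    expect_equal(g$s[i], (ploss(mp) - ploss(mm)) / (2 * h), tolerance = 1e-4)
  }
  i <- which.max(abs(g$enc[[1]]$W))
  mp <- m; mp$enc$layers[[1]]$W[i] <- m$enc$layers[[1]]$W[i] + h
  mm <- m; mm$enc$layers[[1]]$W[i] <- m$enc$layers[[1]]$W[i] - h
  expect_equal(g$enc[[1]]$W[i], (ploss(mp) - ploss(mm)) / (2 * h),
               tolerance = 1e-4)
})

test_that("polyak averaging implements the burn-in mean", {
  expect_equal(polyak_average(as.list(1:5), 0.8), 4.5)  # mean of last 20%
  expect_equal(polyak_average(list(7), 0), 7)
  expect_equal(polyak_average(rep(list(3.3), 10), 0.5), 3.3)
  # elementwise over parameter trees; N0 = 0.5 * 4 = 2, so mean of 2..4
  it <- lapply(1:4, function(i) list(a = matrix(i, 2, 2), b = c(i, -i)))
  avg <- polyak_average(it, 0.5)
  expect_equal(avg$a, matrix(3, 2, 2))
  expect_equal(avg$b, c(3, -3))
  expect_error(polyak_average(as.list(1:5), 1), "burn_in")
})

test_that("augmentation multiplies and perturbs samples reproducibly", {
  tr <- untreated_traj(n_cells = 10L, dt_record = 0.5)
  d1 <- mapper_dataset(tr, sample_interval = 0.5, copies = 5L,
                       noise_halfwidth = 0.1, seed = 3)
  expect_equal(nrow(d1$X), 41L * 5L)
  expect_equal(d1$provenance$n_base, 41L)
  d2 <- mapper_dataset(tr, sample_interval = 0.5, copies = 5L,
                       noise_halfwidth = 0.1, seed = 3)
  expect_identical(d1$X, d2$X)                    # seeded reproducibility
  d0 <- mapper_dataset(tr, sample_interval = 0.5, copies = 3L,
                       noise_halfwidth = 0, seed = 3)
  expect_equal(d0$X[42:82, ], d0$X[1:41, ])       # zero noise: exact copies
  # derivatives carried from the base point
  expect_equal(d1$Xd[42:82, ], d1$Xd[1:41, ])
  # noise bounded by the half-width
  expect_lt(max(abs(d1$X[42:205, ] - d1$X[rep(1:41, 4), ])), 0.1 + 1e-12)
  expect_error(mapper_dataset(tr, copies = 0L), "copies")
})

test_that("feature scaling puts all variable blocks in the unit range", {
  tr <- untreated_traj()
  ds <- mapper_dataset(tr, sample_interval = 0.5, copies = 1L,
                       noise_halfwidth = 0)
  expect_true(all(ds$X <= 1 + 1e-9))
  expect_true(all(ds$scales >= 1))
  expect_equal(ncol(ds$X), 5L * 25L)
})

test_that("a short training run reduces the loss and is reproducible", {
  tr <- untreated_traj(n_cells = 10L, dt_record = 0.5)
  ds <- mapper_dataset(tr, sample_interval = 0.5, copies = 3L,
                       noise_halfwidth = 0.1, seed = 5)
  cfg <- mapper_config(epochs = 30L, n_runs = 1L, hidden = c(8L, 6L),
                       batch_size = 1000L, lr = 3e-3, seed = 9)
  f1 <- train_mapper(ds, cfg)
  f2 <- train_mapper(ds, cfg)
  expect_lt(f1$history[[1]]$loss[30], f1$history[[1]]$loss[1])
  expect_identical(f1$rates_run_mean, f2$rates_run_mean)  # same seed
  expect_identical(f1$mapper$enc$layers, f2$mapper$enc$layers)
  expect_s3_class(f1$mapper, "deep_mapper")
})

test_that("a zero-learning-rate epoch leaves parameters at initialization", {
  tr <- untreated_traj(n_cells = 10L, dt_record = 0.5)
  ds <- mapper_dataset(tr, sample_interval = 0.5, copies = 2L,
                       noise_halfwidth = 0.05, seed = 5)
  cfg <- mapper_config(epochs = 1L, n_runs = 1L, hidden = c(8L, 6L),
                       lr = 0, burn_in_fraction = 0, chart_epochs = 0L,
                       seed = 31)
  fit <- train_mapper(ds, cfg)
  set.seed(31)
  ref <- woundloop:::mapper_init(ncol(ds$X), ncol(ds$U), hidden = c(8L, 6L))
  expect_equal(fit$mapper$enc$layers, ref$enc$layers, tolerance = 1e-12)
  expect_equal(fit$mapper$s, ref$s, tolerance = 1e-12)
})
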