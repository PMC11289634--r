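# Minimal fully connected network machinery: Kaiming-uniform init, ReLU
# hidden layers, softmax / sigmoid output heads, reverse-mode gradients and
# a forward-mode tangent path (needed for the Jacobian-vector products of
# the consistency objective), plus an Adam optimizer over parameter trees.
# Batches are row-major: X is B x d_in, layer weights W are d_in x d_out.

kaiming_uniform <- function(fan_in, fan_out) {
  b <- sqrt(6 / fan_in)
  matrix(stats::runif(fan_in * fan_out, -b, b), fan_in, fan_out)
}

#' Initialize a fully connected network
#'
#' Weights drawn by the Kaiming uniform rule (bound `sqrt(6/fan_in)`),
#' biases zero. Hidden activations are ReLU; the output head is chosen at
#' forward time.
#'
#' @param dims integer vector of layer sizes, input first.
#' @return list of `W`/`b` pairs (`mlp` object).
#' @keywords internal
mlp_init <- function(dims) {
  layers <- lapply(seq_len(length(dims) - 1L), function(l)
    list(W = kaiming_uniform(dims[l], dims[l + 1L]),
         b = numeric(dims[l + 1L])))
  structure(list(layers = layers, dims = dims), class = "mlp")
}

row_softmax <- function(A) {
  E <- exp(A - apply(A, 1L, max))
  E / rowSums(E)
}

# Forward pass with optional tangent propagation.
# X: B x d_in primal batch; Xd: B x d_in tangent batch (or NULL).
# head: "softmax", "sigmoid" or "linear".
# Returns Z (B x d_out), TZ (tangent of Z), and the cache for backward.
mlp_forward <- function(net, X, Xd = NULL, head = "linear") {
  L <- length(net$layers)
  P <- X; Tn <- Xd
  cache <- list(P = vector("list", L + 1L), Tm = vector("list", L + 1L),
                mask = vector("list", L))
  cache$P[[1L]] <- P; cache$Tm[1L] <- list(Tn)
  for (l in seq_len(L)) {
    W <- net$layers[[l]]$W; b <- net$layers[[l]]$b
    A <- sweep(P %*% W, 2L, b, "+")
    Tp <- if (!is.null(Tn)) Tn %*% W
    if (l < L) {                      # ReLU hidden layer
      mask <- A > 0
      P <- A * mask
      if (!is.null(Tp)) Tn <- Tp * mask
      cache$mask[[l]] <- mask
    } else {
      P <- A; Tn <- Tp
    }
    cache$P[[l + 1L]] <- P; cache$Tm[l + 1L] <- list(Tn)
  }
  out <- switch(head,
    linear  = list(Z = P, TZ = Tn),
    sigmoid = {
      Z <- 1 / (1 + exp(-P))
      list(Z = Z, TZ = if (!is.null(Tn)) Tn * Z * (1 - Z))
    },
    softmax = {
      Z <- row_softmax(P)
      list(Z = Z,
           TZ = if (!is.null(Tn)) Z * (Tn - rowSums(Z * Tn)))
    },
    stop("unknown head"))
  out$cache <- cache
  out$head <- head
  out
}

# Reverse pass through mlp_forward. dZ / dTZ are gradients w.r.t. the head
# outputs (dTZ may be NULL when no tangent path was run). Head nonlinearity
# gradients are folded in here; for the softmax tangent path the exact
# second-order softmax terms are included.
mlp_backward <- function(net, fw, dZ, dTZ = NULL) {
  L <- length(net$layers)
  cache <- fw$cache
  Z <- fw$Z; TZ <- fw$TZ
  # gradients w.r.t. pre-head primal (dA) and tangent (dT)
  if (fw$head == "linear") {
    dA <- dZ; dT <- dTZ
  } else if (fw$head == "sigmoid") {
    sg <- Z * (1 - Z)
    dA <- dZ * sg
    dT <- NULL
    if (!is.null(dTZ)) {
      Tpre <- cache$Tm[[L + 1L]]
      dA <- dA + dTZ * Tpre * sg * (1 - 2 * Z)   # d(sg)/dA term
      dT <- dTZ * sg
    }
  } else { # softmax: Z = softmax(A), TZ = Z*(T - sum(Z*T))
    dV <- dZ                                   # dL/dZ accumulated
    dT <- NULL
    if (!is.null(dTZ)) {
      Tpre <- cache$Tm[[L + 1L]]
      s <- rowSums(Z * Tpre)
      gz <- rowSums(dTZ * Z)
      # dL/dT_k = Z_k (dTZ_k - sum_j dTZ_j Z_j)
      dT <- Z * (dTZ - gz)
      # dL/dZ_k += dTZ_k (T_k - s) - gz * T_k
      dV <- dV + dTZ * (Tpre - s) - gz * Tpre
    }
    dA <- Z * (dV - rowSums(dV * Z))           # softmax Jacobian transpose
  }
  grads <- vector("list", L)
  dP <- dA
  for (l in rev(seq_len(L))) {
    if (l < L) {                               # undo ReLU
      dP <- dP * cache$mask[[l]]
      if (!is.null(dT)) dT <- dT * cache$mask[[l]]
    }
    Pin <- cache$P[[l]]; Tin <- cache$Tm[[l]]
    gW <- crossprod(Pin, dP)
    if (!is.null(dT) && !is.null(Tin)) gW <- gW + crossprod(Tin, dT)
    grads[[l]] <- list(W = gW, b = colSums(dP))
    W <- net$layers[[l]]$W
    dP <- tcrossprod(dP, W)
    if (!is.null(dT)) dT <- tcrossprod(dT, W)
  }
  grads
}

# ---- parameter-tree utilities (lists of numeric arrays, arbitrarily nested)

tree_map <- function(f, ...) {
  trees <- list(...)
  if (is.list(trees[[1L]]))
    return(stats::setNames(
      lapply(seq_along(trees[[1L]]),
             function(i) do.call(tree_map, c(list(f), lapply(trees, `[[`, i)))),
      names(trees[[1L]])))
  do.call(f, trees)
}

tree_flatten <- function(tree) {
  if (!is.list(tree)) return(list(tree))
  do.call(c, lapply(tree, tree_flatten))
}

tree_norm <- function(tree) sqrt(sum(vapply(tree_flatten(tree),
                                            function(x) sum(x^2), 0)))

adam_init <- function(params) {
  list(m = tree_map(function(x) x * 0, params),
       v = tree_map(function(x) x * 0, params),
       t = 0L)
}

adam_step <- function(params, grads, state, lr = 1e-3,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  state$m <- tree_map(function(m, g) beta1 * m + (1 - beta1) * g,
                      state$m, grads)
  state$v <- tree_map(function(v, g) beta2 * v + (1 - beta2) * g^2,
                      state$v, grads)
  c1 <- 1 - beta1^state$t; c2 <- 1 - beta2^state$t
  params <- tree_map(function(p, m, v) p - lr * (m / c1) / (sqrt(v / c2) + eps),
                     params, state$m, state$v)
  list(params = params, state = state)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

softplus <- function(x) ifelse(x > 30, x, log1p(exp(x)))
softplus_inv <- function(y) ifelse(y > 30, y, log(expm1(y)))
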