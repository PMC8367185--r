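# Dueling Q-network: a fully connected network (two hidden layers with
# batch normalization and leaky-ReLU) whose last hidden layer feeds two
# streams, a scalar state value V(s) and per-action advantages A(s,a),
# recombined as Q(s,a) = V(s) + A(s,a) - mean_a A(s,a). Forward,
# backward and the Adam update are written in base R matrix code.

BN_EPS <- 1e-5
BN_MOMENTUM <- 0.1
LEAKY_SLOPE <- 0.01

# column-broadcast helpers: `v` is a length-ncol vector
bsub <- function(M, v) M - rep(v, each = nrow(M))
bmul <- function(M, v) M * rep(v, each = nrow(M))
badd <- function(M, v) M + rep(v, each = nrow(M))

#' Initialize a dueling Q-network
#'
#' @param input_width state dimension (49 for the default feature scheme).
#' @param arity number of actions (output width).
#' @param hidden widths of the two hidden layers.
#' @param dueling use the value/advantage decomposition (default TRUE).
#' @param seed integer seed for weight initialization.
#' @return Object of class `t2d_qmodel`.
#' @export
qnet_init <- function(input_width, arity, hidden = c(64L, 32L),
                      dueling = TRUE, seed = 1L) {
  stopifnot(length(hidden) == 2L, input_width > 0L, arity > 0L)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  he <- function(fan_in, fan_out) {
    matrix(stats::rnorm(fan_in * fan_out, 0, sqrt(2 / fan_in)),
           fan_in, fan_out)
  }
  params <- list(
    W1 = he(input_width, hidden[1]),
    g1 = rep(1, hidden[1]), b1 = rep(0, hidden[1]),
    W2 = he(hidden[1], hidden[2]),
    g2 = rep(1, hidden[2]), b2 = rep(0, hidden[2]),
    Wv = he(hidden[2], 1L) * 0.1, bv = 0,
    Wa = he(hidden[2], arity) * 0.1, ba = rep(0, arity)
  )
  structure(list(
    spec = list(input_width = as.integer(input_width),
                arity = as.integer(arity), hidden = as.integer(hidden),
                dueling = isTRUE(dueling)),
    params = params,
    running = list(m1 = rep(0, hidden[1]), v1 = rep(1, hidden[1]),
                   m2 = rep(0, hidden[2]), v2 = rep(1, hidden[2]))
  ), class = "t2d_qmodel")
}

#' @export
print.t2d_qmodel <- function(x, ...) {
  cat("<t2d_qmodel>", x$spec$input_width, "->",
      paste(x$spec$hidden, collapse = "/"), "->", x$spec$arity,
      if (x$spec$dueling) "(dueling)" else "", "\n")
  invisible(x)
}

leaky <- function(x) ifelse(x > 0, x, LEAKY_SLOPE * x)

# Forward pass. training=TRUE uses batch statistics in the BN layers;
# update_running additionally refreshes the running statistics used in
# evaluation mode. Returns Q and (if keep_cache) the activations needed
# for the backward pass.
qnet_forward <- function(model, X, training = FALSE, update_running = FALSE,
                         keep_cache = FALSE) {
  p <- model$params
  if (ncol(X) != model$spec$input_width) {
    stop("state width ", ncol(X), " does not match network input width ",
         model$spec$input_width, call. = FALSE)
  }
  n <- nrow(X)
  bn <- function(Z, g, b, rm, rv) {
    if (training && n > 1L) {
      mu <- colMeans(Z)
      va <- colMeans(Z * Z) - mu^2
    } else {
      mu <- rm; va <- rv
    }
    sd_ <- sqrt(va + BN_EPS)
    xh <- bmul(bsub(Z, mu), 1 / sd_)
    list(out = badd(bmul(xh, g), b), xh = xh, sd = sd_, mu = mu, va = va)
  }
  Z1 <- X %*% p$W1
  l1 <- bn(Z1, p$g1, p$b1, model$running$m1, model$running$v1)
  A1 <- leaky(l1$out)
  Z2 <- A1 %*% p$W2
  l2 <- bn(Z2, p$g2, p$b2, model$running$m2, model$running$v2)
  A2 <- leaky(l2$out)
  if (model$spec$dueling) {
    V <- A2 %*% p$Wv + p$bv
    Adv <- badd(A2 %*% p$Wa, p$ba)
    Q <- Adv - rowMeans(Adv) + as.vector(V)
  } else {
    Q <- badd(A2 %*% p$Wa, p$ba)
    V <- NULL; Adv <- NULL
  }
  out <- list(Q = Q)
  if (update_running && training && n > 1L) {
    out$running <- list(
      m1 = (1 - BN_MOMENTUM) * model$running$m1 + BN_MOMENTUM * l1$mu,
      v1 = (1 - BN_MOMENTUM) * model$running$v1 + BN_MOMENTUM * l1$va,
      m2 = (1 - BN_MOMENTUM) * model$running$m2 + BN_MOMENTUM * l2$mu,
      v2 = (1 - BN_MOMENTUM) * model$running$v2 + BN_MOMENTUM * l2$va)
  }
  if (keep_cache) {
    out$cache <- list(X = X, H1 = l1$out, xh1 = l1$xh, sd1 = l1$sd, A1 = A1,
                      H2 = l2$out, xh2 = l2$xh, sd2 = l2$sd, A2 = A2,
                      Adv = Adv, n = n)
  }
  out
}

#' Action values of a batch of states
#'
#' Evaluation-mode forward pass (frozen batch-normalization statistics):
#' deterministic given the model parameters.
#'
#' @param model a `t2d_qmodel`, or a list of them (a snapshot ensemble),
#'   whose Q-values are averaged.
#' @param states numeric matrix, one state per row (or a single vector).
#' @return Matrix `nrow(states) x arity` of Q-values.
#' @export
q_values <- function(model, states) {
  if (is.null(dim(states))) states <- matrix(states, nrow = 1L)
  if (!inherits(model, "t2d_qmodel") && is.list(model)) {
    qs <- lapply(model, function(m)
      qnet_forward(m, states, training = FALSE)$Q)
    return(Reduce(`+`, qs) / length(qs))
  }
  qnet_forward(model, states, training = FALSE)$Q
}

# Backward pass: dQsa is the per-sample gradient of the loss w.r.t.
# Q(s, a_taken); `actions` are 0-based. Returns gradients for all params.
qnet_backward <- function(model, cache, actions, dQsa) {
  p <- model$params
  n <- cache$n
  K <- model$spec$arity
  if (model$spec$dueling) {
    dAdv <- matrix(-1 / K, n, K) * dQsa
    dAdv[cbind(seq_len(n), actions + 1L)] <-
      dAdv[cbind(seq_len(n), actions + 1L)] + dQsa
    dV <- matrix(dQsa, ncol = 1L)
    dWv <- crossprod(cache$A2, dV); dbv <- sum(dV)
    dWa <- crossprod(cache$A2, dAdv); dba <- colSums(dAdv)
    dA2 <- dAdv %*% t(p$Wa) + dV %*% t(p$Wv)
  } else {
    dAdv <- matrix(0, n, K)
    dAdv[cbind(seq_len(n), actions + 1L)] <- dQsa
    dWv <- p$Wv * 0; dbv <- 0
    dWa <- crossprod(cache$A2, dAdv); dba <- colSums(dAdv)
    dA2 <- dAdv %*% t(p$Wa)
  }
  bn_back <- function(dH, xh, sd_, g) {
    dgamma <- colSums(dH * xh)
    dbeta <- colSums(dH)
    dxh <- bmul(dH, g)
    s1 <- colSums(dxh)
    s2 <- colSums(dxh * xh)
    dZ <- bmul(dxh - badd(bmul(xh, s2 / n), s1 / n), 1 / sd_)
    list(dZ = dZ, dgamma = dgamma, dbeta = dbeta)
  }
  dH2 <- dA2 * ifelse(cache$H2 > 0, 1, LEAKY_SLOPE)
  b2 <- bn_back(dH2, cache$xh2, cache$sd2, p$g2)
  dW2 <- crossprod(cache$A1, b2$dZ)
  dA1 <- b2$dZ %*% t(p$W2)
  dH1 <- dA1 * ifelse(cache$H1 > 0, 1, LEAKY_SLOPE)
  b1 <- bn_back(dH1, cache$xh1, cache$sd1, p$g1)
  dW1 <- crossprod(cache$X, b1$dZ)
  list(W1 = dW1, g1 = b1$dgamma, b1 = b1$dbeta,
       W2 = dW2, g2 = b2$dgamma, b2 = b2$dbeta,
       Wv = dWv, bv = dbv, Wa = dWa, ba = dba)
}

adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = 0L)
}

adam_step <- function(params, grads, state, lr = 1e-3,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (k in names(params)) {
    state$m[[k]] <- beta1 * state$m[[k]] + (1 - beta1) * grads[[k]]
    state$v[[k]] <- beta2 * state$v[[k]] + (1 - beta2) * grads[[k]]^2
    params[[k]] <- params[[k]] -
      lr * (state$m[[k]] / bc1) / (sqrt(state$v[[k]] / bc2) + eps)
  }
  list(params = params, state = state)
}

clip_global_norm <- function(grads, max_norm) {
  total <- sqrt(sum(vapply(grads, function(g) sum(g^2), numeric(1))))
  if (is.finite(total) && total > max_norm) {
    grads <- lapply(grads, function(g) g * (max_norm / total))
  }
  grads
}

#' Recompute exact batch-normalization inference statistics
#'
#' Replaces the running mean/variance of both batch-normalization layers
#' by the exact statistics of the given states under the current
#' parameters, so evaluation-mode forward passes see the same
#' normalization the data imply (the momentum-averaged running statistics
#' lag the parameters they were collected under).
#'
#' @param model a `t2d_qmodel`.
#' @param states matrix of states (typically the full training set).
#' @return The model with refreshed running statistics.
#' @export
qnet_calibrate_bn <- function(model, states) {
  p <- model$params
  Z1 <- states %*% p$W1
  m1 <- colMeans(Z1)
  v1 <- colMeans(Z1 * Z1) - m1^2
  H1 <- badd(bmul(bmul(bsub(Z1, m1), 1 / sqrt(v1 + BN_EPS)), p$g1), p$b1)
  Z2 <- leaky(H1) %*% p$W2
  m2 <- colMeans(Z2)
  v2 <- colMeans(Z2 * Z2) - m2^2
  model$running <- list(m1 = m1, v1 = v1, m2 = m2, v2 = v2)
  model
}

#' Soft (Polyak) update of the target network
#'
#' Every parameter of the target network is moved toward the evaluation
#' network: `theta' <- tau * theta + (1 - tau) * theta'`. Running
#' batch-normalization statistics are blended the same way.
#'
#' @param target,eval_model `t2d_qmodel`s with identical specs.
#' @param tau update rate in (0, 1]; `tau = 1` copies the evaluation
#'   network, `tau = 0` leaves the target unchanged.
#' @return The updated target model.
#' @export
soft_update <- function(target, eval_model, tau) {
  stopifnot(identical(target$spec, eval_model$spec))
  for (k in names(target$params)) {
    if (!identical(dim(target$params[[k]]), dim(eval_model$params[[k]]))) {
      stop("parameter shape mismatch for ", k, call. = FALSE)
    }
    target$params[[k]] <- tau * eval_model$params[[k]] +
      (1 - tau) * target$params[[k]]
  }
  for (k in names(target$running)) {
    target$running[[k]] <- tau * eval_model$running[[k]] +
      (1 - tau) * target$running[[k]]
  }
  target
}
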