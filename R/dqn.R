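# Offline dueling double-DQN training: TD targets, regularized loss,
# prioritized experience replay and the training loop. The replay buffer
# is the full fixed set of training transitions (retrospective data; no
# environment interaction and no exploration).

#' Training configuration
#'
#' Defaults follow the reference settings: discount 0.9, soft-update rate
#' 0.01, learning rate 0.001, batch size 256, up to 100,000 iterations,
#' Q-magnitude regularization threshold `r_reg = 4` with weight
#' `lambda = 0.5`. Prioritized-replay exponents `alpha` (priority) and
#' `beta` (importance correction) default to 0.6/0.4 with priority floor
#' 1e-3.
#'
#' @param gamma discount factor in [0, 1].
#' @param tau soft target-update rate in (0, 1].
#' @param lr Adam learning rate.
#' @param batch_size minibatch size.
#' @param max_iter number of training iterations.
#' @param r_reg regularization threshold on |Q|.
#' @param lambda regularization weight (0 disables the penalty).
#' @param alpha,beta,priority_eps prioritized-replay hyperparameters.
#' @param clip_norm global gradient-norm clip.
#' @param block_size iterations per checkpoint block; the parameters with
#'   the best block-mean loss are kept.
#' @param patience number of consecutive blocks without improvement of the
#'   block-mean loss before training stops early (`Inf` disables).
#' @param seed integer seed controlling initialization and sampling.
#' @return List of class `t2d_dqn_config`.
#' @export
dqn_config <- function(gamma = 0.9, tau = 0.01, lr = 1e-3, batch_size = 256L,
                       max_iter = 100000L, r_reg = 4, lambda = 0.5,
                       alpha = 0.6, beta = 0.4, priority_eps = 1e-3,
                       clip_norm = 10, block_size = 500L, patience = 8L,
                       seed = 1L) {
  stopifnot(gamma >= 0, gamma <= 1, tau > 0, tau <= 1, lr > 0,
            batch_size > 0, max_iter > 0, lambda >= 0, r_reg > 0,
            alpha >= 0, beta >= 0, priority_eps > 0, block_size > 0,
            patience > 0)
  structure(list(gamma = gamma, tau = tau, lr = lr,
                 batch_size = as.integer(batch_size),
                 max_iter = as.integer(max_iter), r_reg = r_reg,
                 lambda = lambda, alpha = alpha, beta = beta,
                 priority_eps = priority_eps, clip_norm = clip_norm,
                 block_size = as.integer(block_size), patience = patience,
                 seed = as.integer(seed)),
            class = "t2d_dqn_config")
}

#' Double-DQN temporal-difference targets
#'
#' Terminal samples get `Q' = r`; otherwise
#' `Q' = r + gamma * Q_target(s', argmax_a Q_eval(s', a))`: the action is
#' chosen by the evaluation network, its value read from the target
#' network.
#'
#' @param batch list with `reward`, `next_state` (matrix) and `terminal`.
#' @param eval_model,target_model `t2d_qmodel`s sharing one spec.
#' @param gamma discount factor.
#' @param training use batch statistics in the batch-normalization layers
#'   (the training loop does, so that target and prediction passes see the
#'   same normalization); the default evaluation mode is deterministic.
#' @return Numeric vector of per-sample targets.
#' @export
td_target <- function(batch, eval_model, target_model, gamma,
                      training = FALSE) {
  stopifnot(identical(eval_model$spec, target_model$spec))
  out <- batch$reward
  live <- which(!batch$terminal)
  if (length(live) && gamma > 0) {
    ns <- batch$next_state[live, , drop = FALSE]
    qe <- qnet_forward(eval_model, ns, training = training)$Q
    a_star <- max.col(qe, ties.method = "first")
    qt <- qnet_forward(target_model, ns, training = training)$Q
    out[live] <- out[live] + gamma * qt[cbind(seq_along(live), a_star)]
  }
  out
}

#' Regularized temporal-difference loss
#'
#' Weighted mean of squared TD error plus a magnitude penalty
#' `lambda * max(|Q| - r_reg, 0)` discouraging action values beyond the
#' largest attainable reward. Also returns the per-sample TD errors used
#' to refresh replay priorities.
#'
#' @param q_pred predicted Q(s, a) per sample.
#' @param q_target TD targets per sample.
#' @param weights importance weights (default 1).
#' @param lambda,r_reg regularization weight and threshold.
#' @return List with `loss` (scalar) and `td_error` (vector).
#' @export
dqn_loss <- function(q_pred, q_target, weights = rep(1, length(q_pred)),
                     lambda = 0.5, r_reg = 4) {
  stopifnot(length(q_pred) == length(q_target),
            length(weights) == length(q_pred))
  if (any(!is.finite(q_pred)) || any(!is.finite(q_target))) {
    stop("non-finite inputs to loss", call. = FALSE)
  }
  td <- q_target - q_pred
  per <- td^2 + lambda * pmax(abs(q_pred) - r_reg, 0)
  list(loss = mean(weights * per), td_error = td)
}

#' Build a prioritized replay buffer from transitions
#'
#' Offline buffer: built once over the fixed training set. Initial
#' priorities are uniform (1); they are refreshed with `|TD error| +
#' priority_eps` as samples are trained on.
#'
#' @param transitions a `t2d_transitions` object or a compatible list.
#' @param alpha,beta,priority_eps see [dqn_config()].
#' @return Object of class `t2d_replay_buffer`.
#' @export
replay_buffer <- function(transitions, alpha = 0.6, beta = 0.4,
                          priority_eps = 1e-3) {
  n <- length(transitions$reward)
  if (n == 0L) stop("empty transition set", call. = FALSE)
  structure(list(transitions = transitions, n = n,
                 priority = rep(1, n), alpha = alpha, beta = beta,
                 priority_eps = priority_eps),
            class = "t2d_replay_buffer")
}

#' Sample a prioritized minibatch
#'
#' Item i is drawn (with replacement) with probability
#' `priority_i^alpha / sum_j priority_j^alpha`; importance weights are
#' `(N * P(i))^-beta`, normalized by their maximum.
#'
#' @param buffer a [replay_buffer()].
#' @param batch_size number of samples.
#' @param replace sample with replacement (default TRUE).
#' @return List with `index` and `weight`.
#' @export
replay_sample <- function(buffer, batch_size, replace = TRUE) {
  if (!replace && batch_size > buffer$n) {
    stop("batch size exceeds buffer size without replacement", call. = FALSE)
  }
  p <- buffer$priority^buffer$alpha
  p <- p / sum(p)
  idx <- sample.int(buffer$n, batch_size, replace = replace, prob = p)
  w <- (buffer$n * p[idx])^(-buffer$beta)
  list(index = idx, weight = w / max(w))
}

#' Train a dueling double-DQN on fixed transitions
#'
#' Each iteration: sample a prioritized minibatch, compute double-DQN TD
#' targets, take one Adam step on the regularized weighted loss, refresh
#' the sampled items' priorities with their new absolute TD errors, and
#' soft-update the target network. Deterministic given `config$seed`.
#'
#' Training runs for at most `config$max_iter` iterations with
#' block-loss checkpointing: the parameters achieving the lowest
#' block-mean loss are retained, and training stops early once the block
#' loss has not improved for `config$patience` consecutive blocks (offline
#' Q-learning on a fixed buffer can degrade after its optimum; the
#' checkpoint guards against that).
#'
#' @param transitions `t2d_transitions` (all `action < arity`).
#' @param config a [dqn_config()].
#' @param arity action-space arity; defaults to `transitions$arity`.
#' @param hidden hidden-layer widths.
#' @param verbose print a summary every 1000 iterations.
#' @return List of class `t2d_dqn_fit`: `model` (evaluation network),
#'   `target`, `loss_history`, `td_history` (mean |TD| per iteration),
#'   `config`.
#' @export
train_dqn <- function(transitions, config = dqn_config(),
                      arity = NULL, hidden = c(64L, 32L), verbose = FALSE) {
  arity <- as.integer(arity %||% transitions$arity)
  n <- length(transitions$reward)
  if (n == 0L) stop("no transitions to train on", call. = FALSE)
  if (any(transitions$action < 0L | transitions$action >= arity)) {
    stop("action index out of range of the action space", call. = FALSE)
  }
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(config$seed)
  input_width <- ncol(transitions$state)
  eval_model <- qnet_init(input_width, arity, hidden,
                          seed = config$seed)
  target_model <- eval_model
  adam <- adam_init(eval_model$params)
  buffer <- replay_buffer(transitions, config$alpha, config$beta,
                          config$priority_eps)
  bs <- config$batch_size
  loss_history <- numeric(config$max_iter)
  td_history <- numeric(config$max_iter)
  best <- list(loss = Inf, params = eval_model$params,
               running = eval_model$running,
               target_params = target_model$params,
               target_running = target_model$running, iter = 0L)
  # up to three lowest-loss block snapshots form an inference ensemble
  snaps <- list()
  stale_blocks <- 0L
  n_iter <- config$max_iter
  for (it in seq_len(config$max_iter)) {
    smp <- replay_sample(buffer, bs)
    idx <- smp$index
    batch <- list(state = transitions$state[idx, , drop = FALSE],
                  action = transitions$action[idx],
                  reward = transitions$reward[idx],
                  next_state = transitions$next_state[idx, , drop = FALSE],
                  terminal = transitions$terminal[idx])
    qt <- td_target(batch, eval_model, target_model, config$gamma,
                    training = TRUE)
    fwd <- qnet_forward(eval_model, batch$state, training = TRUE,
                        update_running = TRUE, keep_cache = TRUE)
    if (!is.null(fwd$running)) eval_model$running <- fwd$running
    q_sa <- fwd$Q[cbind(seq_along(idx), batch$action + 1L)]
    l <- dqn_loss(q_sa, qt, smp$weight, config$lambda, config$r_reg)
    if (!is.finite(l$loss)) {
      stop("training diverged at iteration ", it, " (non-finite loss)",
           call. = FALSE)
    }
    # gradient of the weighted per-sample loss w.r.t. Q(s,a)
    dQsa <- (smp$weight / length(idx)) *
      (-2 * l$td_error +
         config$lambda * sign(q_sa) * (abs(q_sa) > config$r_reg))
    grads <- qnet_backward(eval_model, fwd$cache, batch$action, dQsa)
    grads <- clip_global_norm(grads, config$clip_norm)
    step <- adam_step(eval_model$params, grads, adam, lr = config$lr)
    eval_model$params <- step$params
    adam <- step$state
    buffer$priority[idx] <- abs(l$td_error) + config$priority_eps
    target_model <- soft_update(target_model, eval_model, config$tau)
    loss_history[it] <- l$loss
    td_history[it] <- mean(abs(l$td_error))
    if (it %% config$block_size == 0L) {
      block_loss <- mean(loss_history[(it - config$block_size + 1L):it])
      if (length(snaps) < 3L ||
          block_loss < max(vapply(snaps, `[[`, numeric(1), "loss"))) {
        snaps[[length(snaps) + 1L]] <- list(loss = block_loss,
                                            params = eval_model$params,
                                            running = eval_model$running)
        if (length(snaps) > 3L) {
          snaps[[which.max(vapply(snaps, `[[`, numeric(1), "loss"))]] <- NULL
        }
      }
      if (block_loss < best$loss) {
        best <- list(loss = block_loss, params = eval_model$params,
                     running = eval_model$running,
                     target_params = target_model$params,
                     target_running = target_model$running, iter = it)
        stale_blocks <- 0L
      } else {
        stale_blocks <- stale_blocks + 1L
        if (stale_blocks >= config$patience) {
          n_iter <- it
          break
        }
      }
    }
    if (verbose && it %% 1000L == 0L) {
      message(sprintf("iter %6d  loss %.4f  mean|TD| %.4f", it,
                      mean(loss_history[(it - 999L):it]),
                      mean(td_history[(it - 999L):it])))
    }
  }
  eval_model$params <- best$params
  eval_model$running <- best$running
  target_model$params <- best$target_params
  target_model$running <- best$target_running
  # exact inference statistics for the restored parameters
  eval_model <- qnet_calibrate_bn(eval_model, transitions$state)
  target_model <- qnet_calibrate_bn(target_model, transitions$state)
  ensemble <- lapply(snaps, function(s) {
    m <- eval_model
    m$params <- s$params
    m$running <- s$running
    qnet_calibrate_bn(m, transitions$state)
  })
  structure(list(model = eval_model, target = target_model,
                 ensemble = ensemble,
                 loss_history = loss_history[seq_len(n_iter)],
                 td_history = td_history[seq_len(n_iter)],
                 buffer_priority = buffer$priority,
                 best_iter = best$iter, config = config),
            class = "t2d_dqn_fit")
}

#' Train an ensemble of independently initialized Q-networks
#'
#' Trains `n_networks` dueling double-DQNs on the same transitions with
#' different initialization/sampling seeds (derived from `config$seed`)
#' and returns their models as an ensemble whose Q-values are averaged by
#' [q_values()]. Averaging independently trained value estimates reduces
#' the ranking noise of a single offline fit.
#'
#' @inheritParams train_dqn
#' @param n_networks ensemble size.
#' @return List of class `t2d_dqn_ensemble`: `models` (list of
#'   `t2d_qmodel`), `fits` (the individual `t2d_dqn_fit`s).
#' @export
train_dqn_ensemble <- function(transitions, config = dqn_config(),
                               n_networks = 3L, arity = NULL,
                               hidden = c(64L, 32L), verbose = FALSE) {
  fits <- lapply(seq_len(n_networks), function(k) {
    cfg_k <- config
    cfg_k$seed <- config$seed + (k - 1L) * 1000L
    train_dqn(transitions, cfg_k, arity = arity, hidden = hidden,
              verbose = verbose)
  })
  structure(list(models = lapply(fits, `[[`, "model"), fits = fits,
                 config = config), class = "t2d_dqn_ensemble")
}

#' @export
print.t2d_dqn_ensemble <- function(x, ...) {
  cat("<t2d_dqn_ensemble>", length(x$models), "networks; best iterations:",
      vapply(x$fits, `[[`, integer(1), "best_iter"), "\n")
  invisible(x)
}

#' @export
print.t2d_dqn_fit <- function(x, ...) {
  n <- length(x$loss_history)
  tail_mean <- mean(x$loss_history[max(1, n - 99):n])
  cat("<t2d_dqn_fit>", n, "iterations; final loss (last 100 mean)",
      signif(tail_mean, 4), "\n")
  invisible(x)
}
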