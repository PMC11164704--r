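# Deterministic-policy-gradient actor-critic (DDPG) learner in plain matrix
# algebra: two fully connected hidden layers of 200 rectified units in both
# actor and critic, tanh-bounded actions, replay buffer, target networks
# with Polyak averaging, and Adam updates. Written row-major: inputs are
# n x d matrices, weights d_in x d_out.

relu <- function(x) pmax(x, 0)

# He-style initialisation for a dense layer.
init_layer <- function(d_in, d_out) {
  list(W = matrix(stats::rnorm(d_in * d_out, 0, sqrt(2 / d_in)), d_in, d_out),
       b = rep(0, d_out))
}

init_net <- function(d_in, hidden, d_out) {
  dims <- c(d_in, hidden, d_out)
  lapply(seq_len(length(dims) - 1L),
         function(i) init_layer(dims[i], dims[i + 1]))
}

zeros_like <- function(net) {
  lapply(net, function(l) list(W = l$W * 0, b = l$b * 0))
}

#' Create a DDPG soaring agent
#'
#' Actor and critic networks with two hidden layers of `hidden` rectified
#' (non-negative) units each; the actor output is tanh-bounded and scaled to
#' the action limits (+/-15 deg bank change, +/-10 deg angle-of-attack
#' change). Training state (replay buffer, target networks, Adam moments)
#' lives inside the returned object.
#'
#' @param obs_dim Observation dimension, `6 * (buffer + 1)`.
#' @param hidden Hidden-layer widths. Default `c(200, 200)`.
#' @param action_scale Per-action output scaling, degrees.
#' @param lr_actor,lr_critic Adam learning rates.
#' @param discount Reward discount factor.
#' @param tau Polyak averaging rate for the target networks.
#' @param batch_size Minibatch size for updates.
#' @param buffer_size Replay-buffer capacity (transitions).
#' @param noise_sd Exploration noise sd in normalized action units.
#' @param reward_scale Factor applied to rewards inside the critic update
#'   (the environment's rewards are reported unscaled).
#' @param warmup Number of transitions collected before updates start.
#' @param train_every Environment steps between gradient updates.
#' @param seed Integer seed for weight initialization.
#' @return An object of class `ddpg_agent` (an R environment).
#' @export
ddpg_agent <- function(obs_dim, hidden = c(200, 200),
                       action_scale = c(15, 10),
                       lr_actor = 1e-3, lr_critic = 1e-3,
                       discount = 0.99, tau = 0.005,
                       batch_size = 64, buffer_size = 100000,
                       noise_sd = 0.1, reward_scale = 0.01,
                       warmup = 500, train_every = 1, seed = NULL) {
  a <- new.env(parent = emptyenv())
  if (!is.null(seed)) set.seed(seed)
  a$obs_dim <- obs_dim
  a$act_dim <- length(action_scale)
  a$hidden <- hidden
  a$action_scale <- action_scale
  a$actor <- init_net(obs_dim, hidden, a$act_dim)
  a$critic <- init_net(obs_dim + a$act_dim, hidden, 1L)
  a$actor_target <- a$actor
  a$critic_target <- a$critic
  a$m_actor <- zeros_like(a$actor); a$v_actor <- zeros_like(a$actor)
  a$m_critic <- zeros_like(a$critic); a$v_critic <- zeros_like(a$critic)
  a$adam_t <- 0L
  a$hp <- list(lr_actor = lr_actor, lr_critic = lr_critic,
               discount = discount, tau = tau, batch_size = batch_size,
               buffer_size = buffer_size, noise_sd = noise_sd,
               reward_scale = reward_scale, warmup = warmup,
               train_every = train_every)
  a$buf <- new_replay_buffer(buffer_size, obs_dim, a$act_dim)
  a$sim_time <- 0 # cumulative simulated seconds seen in training
  class(a) <- c("ddpg_agent", "environment")
  a
}

#' @export
print.ddpg_agent <- function(x, ...) {
  cat(sprintf("<ddpg_agent> obs %d -> hidden %s -> actions %d; %.3g simulated s\n",
              x$obs_dim, paste(x$hidden, collapse = "x"), x$act_dim, x$sim_time))
  invisible(x)
}

# Forward pass through a rectified 2-hidden-layer net. Returns hidden
# activations and the linear output (pre-squash).
net_forward <- function(net, X) {
  H1 <- relu(sweep(X %*% net[[1]]$W, 2, net[[1]]$b, `+`))
  H2 <- relu(sweep(H1 %*% net[[2]]$W, 2, net[[2]]$b, `+`))
  Z <- sweep(H2 %*% net[[3]]$W, 2, net[[3]]$b, `+`)
  list(H1 = H1, H2 = H2, Z = Z)
}

# Actor forward: normalized actions in [-1, 1]^act_dim.
actor_forward <- function(agent, X, target = FALSE) {
  net <- if (target) agent$actor_target else agent$actor
  f <- net_forward(net, X)
  f$A <- tanh(f$Z)
  f
}

critic_forward <- function(agent, X, A, target = FALSE) {
  net <- if (target) agent$critic_target else agent$critic
  net_forward(net, cbind(X, A))
}

#' Deterministic policy of an agent
#'
#' @param agent A [ddpg_agent()] object.
#' @return A function mapping an observation vector to an action
#'   `c(d_sigma, d_alpha)` in degrees (no exploration noise).
#' @export
agent_policy <- function(agent) {
  force(agent)
  function(obs) {
    a <- actor_forward(agent, matrix(obs, 1))$A
    as.numeric(a) * agent$action_scale
  }
}

# Backprop through net given upstream gradient dZ at the linear output.
# Returns gradients per layer and the gradient w.r.t. the input.
net_backward <- function(net, X, f, dZ) {
  g3 <- list(W = crossprod(f$H2, dZ), b = colSums(dZ))
  dH2 <- (dZ %*% t(net[[3]]$W)) * (f$H2 > 0)
  g2 <- list(W = crossprod(f$H1, dH2), b = colSums(dH2))
  dH1 <- (dH2 %*% t(net[[2]]$W)) * (f$H1 > 0)
  g1 <- list(W = crossprod(X, dH1), b = colSums(dH1))
  dX <- dH1 %*% t(net[[1]]$W)
  list(grads = list(g1, g2, g3), dX = dX)
}

adam_update <- function(net, grads, m, v, lr, t,
                        beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  for (i in seq_along(net)) {
    for (p in c("W", "b")) {
      g <- grads[[i]][[p]]
      m[[i]][[p]] <- beta1 * m[[i]][[p]] + (1 - beta1) * g
      v[[i]][[p]] <- beta2 * v[[i]][[p]] + (1 - beta2) * g^2
      mhat <- m[[i]][[p]] / (1 - beta1^t)
      vhat <- v[[i]][[p]] / (1 - beta2^t)
      net[[i]][[p]] <- net[[i]][[p]] - lr * mhat / (sqrt(vhat) + eps)
    }
  }
  list(net = net, m = m, v = v)
}

polyak <- function(target, net, tau) {
  for (i in seq_along(net)) {
    target[[i]]$W <- (1 - tau) * target[[i]]$W + tau * net[[i]]$W
    target[[i]]$b <- (1 - tau) * target[[i]]$b + tau * net[[i]]$b
  }
  target
}

# Cyclic replay buffer as a closure: `<<-` row-writes into the locally bound
# matrices stay in place (no copy), which matters at one write per control
# step.
new_replay_buffer <- function(cap, obs_dim, act_dim) {
  S <- matrix(0, cap, obs_dim); A <- matrix(0, cap, act_dim)
  R <- numeric(cap); S2 <- matrix(0, cap, obs_dim); D <- numeric(cap)
  n <- 0L; pos <- 0L
  add <- function(s, act, r, s2, done) {
    i <- pos %% cap + 1L
    S[i, ] <<- s; A[i, ] <<- act; R[i] <<- r; S2[i, ] <<- s2; D[i] <<- done
    pos <<- pos + 1L
    n <<- min(n + 1L, cap)
    invisible(NULL)
  }
  sample_batch <- function(batch) {
    idx <- sample.int(n, batch)
    list(S = S[idx, , drop = FALSE], A = A[idx, , drop = FALSE],
         R = R[idx], S2 = S2[idx, , drop = FALSE], D = D[idx])
  }
  list(add = add, sample_batch = sample_batch,
       size = function() n, writes = function() pos)
}

buffer_add <- function(agent, s, act, r, s2, done) {
  agent$buf$add(s, act, r, s2, done)
  invisible(agent)
}

# One DDPG gradient step on a sampled minibatch.
ddpg_update <- function(agent) {
  hp <- agent$hp
  if (agent$buf$size() < max(hp$batch_size, hp$warmup)) return(invisible(agent))
  bt <- agent$buf$sample_batch(hp$batch_size)
  S <- bt$S; A <- bt$A; R <- bt$R * hp$reward_scale
  S2 <- bt$S2; Dn <- bt$D
  nb <- hp$batch_size
  agent$adam_t <- agent$adam_t + 1L

  # critic: TD target from the target networks
  A2 <- actor_forward(agent, S2, target = TRUE)$A
  Q2 <- critic_forward(agent, S2, A2, target = TRUE)$Z
  y <- R + hp$discount * (1 - Dn) * as.numeric(Q2)
  fc <- critic_forward(agent, S, A)
  dZ <- 2 * (fc$Z - y) / nb
  bc <- net_backward(agent$critic, cbind(S, A), fc, dZ)
  up <- adam_update(agent$critic, bc$grads, agent$m_critic, agent$v_critic,
                    hp$lr_critic, agent$adam_t)
  agent$critic <- up$net; agent$m_critic <- up$m; agent$v_critic <- up$v

  # actor: ascend mean Q(s, pi(s))
  fa <- actor_forward(agent, S)
  fq <- critic_forward(agent, S, fa$A)
  dZq <- matrix(-1 / nb, nb, 1) # minimize -mean(Q)
  bq <- net_backward(agent$critic, cbind(S, fa$A), fq, dZq)
  dA <- bq$dX[, agent$obs_dim + seq_len(agent$act_dim), drop = FALSE]
  dZ3 <- dA * (1 - fa$A^2) # through tanh
  ba <- net_backward(agent$actor, S, fa, dZ3)
  up <- adam_update(agent$actor, ba$grads, agent$m_actor, agent$v_actor,
                    hp$lr_actor, agent$adam_t)
  agent$actor <- up$net; agent$m_actor <- up$m; agent$v_actor <- up$v

  agent$actor_target <- polyak(agent$actor_target, agent$actor, hp$tau)
  agent$critic_target <- polyak(agent$critic_target, agent$critic, hp$tau)
  invisible(agent)
}

#' Snapshot an agent's weights (checkpoint)
#'
#' @param agent A [ddpg_agent()] object.
#' @return A plain list checkpoint (weights, targets, configuration,
#'   cumulative simulated time). Restore with [load_checkpoint()].
#' @export
agent_checkpoint <- function(agent) {
  list(obs_dim = agent$obs_dim, act_dim = agent$act_dim,
       hidden = agent$hidden, action_scale = agent$action_scale,
       actor = agent$actor, critic = agent$critic,
       actor_target = agent$actor_target, critic_target = agent$critic_target,
       hp = agent$hp, sim_time = agent$sim_time)
}

#' Restore an agent from a checkpoint
#'
#' @param ckpt A checkpoint list from [agent_checkpoint()], or a path to an
#'   RDS file containing one.
#' @return A [ddpg_agent()] object with restored weights (fresh optimizer
#'   moments and an empty replay buffer).
#' @export
load_checkpoint <- function(ckpt) {
  if (is.character(ckpt)) ckpt <- readRDS(ckpt)
  a <- ddpg_agent(ckpt$obs_dim, hidden = ckpt$hidden,
                  action_scale = ckpt$action_scale)
  a$hp <- ckpt$hp
  a$actor <- ckpt$actor; a$critic <- ckpt$critic
  a$actor_target <- ckpt$actor_target; a$critic_target <- ckpt$critic_target
  a$sim_time <- ckpt$sim_time
  a
}

#' Save a checkpoint to disk
#'
#' @param agent A [ddpg_agent()] object (or a checkpoint list).
#' @param path Output RDS path.
#' @export
save_checkpoint <- function(agent, path) {
  ckpt <- if (inherits(agent, "ddpg_agent")) agent_checkpoint(agent) else agent
  saveRDS(ckpt, path)
  invisible(path)
}
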