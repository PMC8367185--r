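# Tabular-MDP helpers: deterministic toy environments encoded one-hot,
# and an exact value-iteration oracle.

# deterministic tabular MDP given reward and next-state tables; states are
# one-hot encoded
make_mdp_transitions <- function(R, NS, n = 400L, seed = 1L,
                                 terminal_frac = 0) {
  ns <- nrow(R); na <- ncol(R)
  enc <- function(s) {
    m <- matrix(0, length(s), ns)
    m[cbind(seq_along(s), s)] <- 1
    m
  }
  set.seed(seed)
  s <- sample(ns, n, replace = TRUE)
  a <- sample(na, n, replace = TRUE)
  list(state = enc(s), action = as.integer(a - 1L),
       reward = R[cbind(s, a)], next_state = enc(NS[cbind(s, a)]),
       terminal = rep(FALSE, n), arity = as.integer(na), enc = enc)
}

value_iteration <- function(R, NS, gamma, tol = 1e-12) {
  Q <- R * 0
  repeat {
    V <- apply(Q, 1, max)
    Qn <- R + gamma * matrix(V[NS], nrow(R), ncol(R))
    if (max(abs(Qn - Q)) < tol) return(Qn)
    Q <- Qn
  }
}

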