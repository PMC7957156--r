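# Independent continuous-time Markov chain simulator used as a
# Monte-Carlo oracle: plain jump-chain stepping, no matrix exponentials.

sim_ctmc_state_at <- function(q, t, n_paths, start = 1L,
                              max_steps = 1000L) {
  n <- nrow(q)
  states <- rep(as.integer(start), n_paths)
  clock <- numeric(n_paths)
  alive <- rep(TRUE, n_paths)
  for (step in seq_len(max_steps)) {
    act <- which(alive)
    if (!length(act)) break
    for (s in unique(states[act])) {
      idx <- act[states[act] == s]
      rates <- pmax(q[s, ], 0)
      rates[s] <- 0
      total <- sum(rates)
      if (total <= 0) { alive[idx] <- FALSE; next }
      soj <- stats::rexp(length(idx), total)
      done <- clock[idx] + soj > t
      alive[idx[done]] <- FALSE
      move <- idx[!done]
      if (length(move)) {
        clock[move] <- clock[move] + soj[!done]
        states[move] <- sample.int(n, length(move), replace = TRUE,
                                   prob = rates)
      }
    }
  }
  states
}

# random generator matrix with the five-state progressive structure
random_phase_q <- function() {
  rates <- stats::runif(6, 0.05, 1.5)
  q <- matrix(0, 5, 5)
  q[phase_transitions()] <- rates
  diag(q) <- -rowSums(q)
  q
}
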