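# Independent reaction-network oracle: assembles the mass-action RHS from an
# explicit list of (rate, stoichiometry) reaction tuples, term by term,
# without reference to the closed-form equations in the package. Species
# order: (T, M, C1..CN); the cytosolic Drp1 balance is scaled by gamma at
# the end (compartment correction).
oracle_rhs <- function(state, params) {
  N <- params$N_max; ell <- params$ell
  Tc <- state[[1]]; M <- state[[2]]; C <- state[3:(N + 2)]
  nsp <- N + 2
  iT <- 1; iM <- 2; iC <- function(i) i + 2
  reactions <- list()
  add <- function(rate, ...) {
    st <- numeric(nsp)
    ch <- list(...)
    for (k in seq(1, length(ch), by = 2)) st[ch[[k]]] <- st[ch[[k]]] + ch[[k + 1]]
    reactions[[length(reactions) + 1]] <<- list(rate = rate, st = st)
  }
  # T + M <-> C1
  add(params$k1 * Tc * M, iT, -1, iM, -1, iC(1), +1)
  add(params$k_m1 * C[1], iT, +1, iM, +1, iC(1), -1)
  # elongation Ci + C1 -> C(i+1); i = 1 consumes two C1
  add(params$k_plus * C[1] * C[1], iC(1), -2, iC(2), +1)
  for (i in 2:(N - 1))
    add(params$k_plus * C[i] * C[1], iC(i), -1, iC(1), -1, iC(i + 1), +1)
  # shrinkage Ci -> C(i-1) + C1; i = 2 yields two C1
  add(params$k_minus * C[2], iC(2), -1, iC(1), +2)
  for (i in 3:N)
    add(params$k_minus * C[i], iC(i), -1, iC(i - 1), +1, iC(1), +1)
  # fission above the threshold returns i units of T and M to the pools
  for (i in seq_len(N))
    if (i > ell) add(params$a * C[i], iC(i), -1, iT, +i, iM, +i)
  d <- Reduce(`+`, lapply(reactions, function(r) r$rate * r$st))
  d[iT] <- params$gamma * d[iT]
  d
}

# random strictly positive state for property tests
random_state <- function(N, scale = 1) {
  stats::runif(N + 2, 1e-4, 2) * scale
}

# random positive parameter set: Table-style baseline jittered by
# log-uniform multipliers in [1/2, 2]
random_fission_params <- function() {
  m <- exp(stats::runif(8, log(0.5), log(2)))
  fission_params(k1 = 1 * m[1], k_m1 = 0.02 * m[2], k_plus = 5 * m[3],
                 k_minus = 0.1 * m[4], a = 5 * m[5], gamma = 0.1 * m[6],
                 T_total = 20 * m[7], M_total = 15 * m[8])
}

# minimal hand-built trajectory (for quadrature / classifier edge cases)
fake_trajectory <- function(times, tfr, params = fission_params()) {
  N <- params$N_max
  states <- matrix(0, length(times), N + 2,
                   dimnames = list(NULL, c("T", "M", paste0("C", 1:N))))
  states[, 1] <- params$T_total; states[, 2] <- params$M_total
  # put the whole TFR into C_N so states and tfr stay consistent
  states[, N + 2] <- tfr / params$a
  states[, 2] <- states[, 2] - N * states[, N + 2]
  structure(list(times = times, states = states, tfr = tfr,
                 cumtf = cumsum(c(0, diff(times) *
                                    (utils::head(tfr, -1) + tfr[-1]) / 2)),
                 params = params, system = "dimensional",
                 solver = list(), conservation_drift = 0),
            class = "fission_trajectory")
}
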