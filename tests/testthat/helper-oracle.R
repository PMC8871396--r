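# independent reference integrator for toy networks, built on deSolve
oracle_relax <- function(net, init, t_max = 25, silenced = integer(0)) {
  n <- length(net$areas)
  p <- net$params
  rhs <- function(t, y, parms) {
    m <- matrix(y, nrow = n)  # columns SA SB SC rA rB rC
    m[silenced, ] <- 0
    SA <- m[, 1]; SB <- m[, 2]; SC <- m[, 3]
    rA <- m[, 4]; rB <- m[, 5]; rC <- m[, 6]
    InA <- net$G * as.numeric(net$W_EE %*% SA)
    InB <- net$G * as.numeric(net$W_EE %*% SB)
    InC <- net$G * net$Z * as.numeric(net$W_EI %*% (SA + SB))
    IA <- net$Js * SA + p$J_c * SB + p$J_EI * SC + p$I0_A + InA
    IB <- p$J_c * SA + net$Js * SB + p$J_EI * SC + p$I0_B + InB
    IC <- net$JIE * (SA + SB) + p$J_II * SC + p$I0_C + InC
    d <- cbind(-SA / p$tau_N + p$gamma * (1 - SA) * rA,
               -SB / p$tau_N + p$gamma * (1 - SB) * rB,
               -SC / p$tau_G + p$gamma_I * rC,
               (phi_excitatory(IA, p) - rA) / p$tau_r,
               (phi_excitatory(IB, p) - rB) / p$tau_r,
               (phi_inhibitory(IC, p) - rC) / p$tau_r)
    d[silenced, ] <- 0
    list(as.numeric(d))
  }
  y0 <- as.numeric(init[, 1:6])
  out <- deSolve::ode(y0, c(0, t_max), rhs, NULL, method = "lsoda")
  matrix(out[2, -1], nrow = n,
         dimnames = list(net$areas, colnames(init)[1:6]))
}

oracle_census <- function(net, threshold, seed_value = 0.3) {
  n <- length(net$areas)
  pats <- character(0)
  for (k in seq_len(2^n - 1)) {
    subset <- which(bitwAnd(k, 2^(seq_len(n) - 1)) > 0)
    st <- net$spont
    st[subset, "S_A"] <- seed_value
    fin <- oracle_relax(net, st)
    act <- fin[, "r_A"] > threshold | fin[, "r_B"] > threshold
    if (any(act)) pats <- c(pats, paste(as.integer(act), collapse = ""))
  }
  sort(unique(pats))
}

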