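# Shared fixtures and independent oracles.

# Brute-force expected reward by enumerating every state path of the chain,
# weighting by path probability, and applying the half-cycle correction and
# discounting path-wise. Independent of the matrix algebra in accumulate().
brute_force_accumulate <- function(matrix, costs, utilities, config) {
  P <- as.matrix(matrix)
  T <- config$horizon
  disc <- discount_factor(0:(T - 1), config)
  cvec <- c(costs$drug + costs$tests + costs$ae, costs$subsequent, 0)
  uvec <- c(utilities$pfs, utilities$pd, 0) * config$cycle_length / 12
  paths <- as.matrix(expand.grid(rep(list(1:3), T)))
  cost <- 0; qaly <- 0
  for (i in seq_len(nrow(paths))) {
    s <- c(1L, paths[i, ])
    prob <- prod(P[cbind(s[-length(s)], s[-1])])
    if (prob == 0) next
    for (t in seq_len(T)) {
      occ <- if (config$half_cycle_correction) {
        o <- numeric(3); o[s[t]] <- o[s[t]] + 0.5; o[s[t + 1]] <- o[s[t + 1]] + 0.5
        o
      } else {
        o <- numeric(3); o[s[t]] <- 1; o
      }
      cost <- cost + prob * disc[t] * sum(occ * cvec)
      qaly <- qaly + prob * disc[t] * sum(occ * uvec)
    }
  }
  list(cost = cost, qaly = qaly)
}

random_matrix <- function() {
  r1 <- stats::runif(3); r1 <- r1 / sum(r1)
  r2 <- stats::runif(2); r2 <- r2 / sum(r2)
  transition_matrix(r1[1], r1[2], r1[3], r2[1], r2[2])
}

# random matrix with all five probabilities inside [lo, hi], the regime in
# which calibration is identifiable
random_interior_matrix <- function(lo = 0.02, hi = 0.98) {
  repeat {
    stay_pfs <- stats::runif(1, lo, hi)
    share <- stats::runif(1)
    exit <- 1 - stay_pfs
    p <- c(stay_pfs, exit * (1 - share), exit * share)
    stay_pd <- stats::runif(1, lo, hi)
    if (all(c(p, stay_pd, 1 - stay_pd) >= lo & c(p, stay_pd, 1 - stay_pd) <= hi))
      return(transition_matrix(p[1], p[2], p[3], stay_pd, 1 - stay_pd))
  }
}

toy_costs <- function(drug = 100, tests = 0, ae = 0, subsequent = 0)
  cost_inputs(drug, tests, ae, subsequent)

max_param_diff <- function(m1, m2)
  max(abs(unlist(m1[names(m1)]) - unlist(m2[names(m2)])))
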