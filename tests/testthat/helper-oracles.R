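# Independent oracles, deliberately written as naive enumerations so they
# share no code path with the package implementations they check.

# Tie-aware probability-of-superiority effect by double-loop pair counting.
oracle_mw_effect <- function(control, treated) {
  wins <- 0
  for (c_i in control) {
    for (t_j in treated) {
      if (t_j > c_i) wins <- wins + 1 else if (t_j == c_i) wins <- wins + 0.5
    }
  }
  wins / (length(control) * length(treated)) - 0.5
}

# Exact two-sided signed-rank p by enumerating all 2^n sign assignments of
# the (zero-dropped, midranked) differences.
oracle_signed_rank_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  vs <- vapply(0:(2^n - 1), function(mask) {
    pos <- as.logical(bitwAnd(mask, 2^(0:(n - 1))))
    sum(r[pos])
  }, numeric(1))
  p_le <- mean(vs <= v_obs + 1e-9)
  p_ge <- mean(vs >= v_obs - 1e-9)
  min(1, 2 * min(p_le, p_ge))
}

# Medcouple by direct enumeration of the kernel over all straddling pairs,
# with the sign kernel for median ties.
oracle_medcouple <- function(x) {
  x <- sort(x)
  m <- median(x)
  tied <- which(x == m)
  k <- length(tied)
  vals <- c()
  for (i in which(x <= m)) {
    for (j in which(x >= m)) {
      if (x[i] == m && x[j] == m) {
        vals <- c(vals, sign(match(i, tied) + match(j, tied) - 1 - k))
      } else {
        vals <- c(vals, ((x[j] - m) - (m - x[i])) / (x[j] - x[i]))
      }
    }
  }
  median(vals)
}

# A small ready-made study reused by several tests (moderate size, coupled
# clonality so the headline pattern is present).
small_study <- function(seed = 11) {
  simulate_study(n_species = 12, pots_per_cell = 5, seed = seed,
                 missing_rate = 0)
}

strip_latent <- function(pots) dplyr::select(pots, !dplyr::starts_with("."))
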