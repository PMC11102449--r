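# Independent oracles used by the test suite.

# Smallest positive integer z with 1 - z^(-l) >= u, by direct scanning.
scan_levy_oracle <- function(u, l, z_max = 500000L) {
  for (z in seq_len(z_max)) {
    if (1 - z^(-l) >= u) return(z)
  }
  stop("scan oracle exceeded z_max")
}

# Draw-for-draw R mirror of the compiled engine for the tumor-only scenario
# (no immune agents, no doses, parameters chosen so that neither oxygen nor
# adenosine enters any decision: r_Ht = 0, r_At = 0). Consumes R's global RNG
# exactly as the engine does: a Fisher-Yates shuffle of the alive agents in
# creation order, then per tumor cell one division draw (only when an empty
# Moore neighbor exists) and one daughter-placement draw (only on success).
# Returns the logical tumor occupancy after n_steps.
tumor_only_mirror <- function(state, params, n_steps) {
  N <- state$N
  dr <- c(-1L, -1L, -1L, 0L, 0L, 1L, 1L, 1L)
  dc <- c(-1L, 0L, 1L, -1L, 1L, -1L, 0L, 1L)
  stopifnot(params$r_Ht == 0, params$r_At == 0)
  p_div <- params$P_tumor
  init <- which(state$kind == 1L)  # column-major = engine creation order
  ar <- (init - 1L) %% N + 1L
  ac <- (init - 1L) %/% N + 1L
  grid <- matrix(0L, N, N)
  grid[cbind(ar, ac)] <- seq_along(ar)
  for (t in seq_len(n_steps)) {
    ord <- seq_along(ar)  # all agents alive (nothing kills tumor here)
    n <- length(ord)
    if (n > 1) {
      for (i in n:2) {
        j <- min(floor(runif(1) * i) + 1L, i)
        tmp <- ord[i]; ord[i] <- ord[j]; ord[j] <- tmp
      }
    }
    for (ai in ord) {
      r <- ar[ai]; cc <- ac[ai]
      k <- 0L; er <- integer(8); ec <- integer(8)
      for (d in 1:8) {
        nr <- r + dr[d]; nc <- cc + dc[d]
        if (nr >= 1L && nr <= N && nc >= 1L && nc <= N &&
            grid[nr, nc] == 0L) {
          k <- k + 1L; er[k] <- nr; ec[k] <- nc
        }
      }
      if (k == 0L) next
      if (runif(1) < p_div) {
        j <- min(floor(runif(1) * k) + 1L, k)
        ar <- c(ar, er[j]); ac <- c(ac, ec[j])
        grid[er[j], ec[j]] <- length(ar)
      }
    }
  }
  grid != 0L
}
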