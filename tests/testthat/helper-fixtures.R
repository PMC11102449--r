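# Shared fixtures: all built in code at test time.

# Small-grid parameter set for fast engine tests; immune counts scaled with
# grid area so densities match the full-scale defaults.
small_params <- function(N = 30, ...) {
  p <- default_parameters()
  scale <- (N / p$N)^2
  p$N <- as.integer(N)
  p$N_T <- as.integer(round(p$N_T * scale))
  p$N_D <- as.integer(round(p$N_D * scale))
  p$V_DC <- as.integer(max(1, round(p$V_DC * scale)))
  dots <- list(...)
  p[names(dots)] <- dots
  validate_parameters(p)
  p
}

# A bare simulation state with chosen occupancy, uniform oxygen and zero
# humoral levels; kind_sites is a list mapping code -> matrix/vector of sites.
make_state <- function(params, tumor_sites = NULL, dc_in = NULL,
                       dc_ac = NULL, t_in = NULL, treg = NULL, eff = NULL,
                       U = NULL) {
  N <- params$N
  lat <- new_lattice(N)
  put <- function(lat, sites, code) {
    if (is.null(sites)) return(lat)
    sites <- matrix(sites, ncol = 2)
    for (i in seq_len(nrow(sites))) lat$kind[sites[i, 1], sites[i, 2]] <- code
    lat
  }
  lat <- put(lat, tumor_sites, 1L)
  lat <- put(lat, dc_in, 2L)
  lat <- put(lat, dc_ac, 3L)
  lat <- put(lat, t_in, 4L)
  lat <- put(lat, treg, 5L)
  lat <- put(lat, eff, 6L)
  if (is.null(U)) U <- matrix(params$U_boundary, N, N)
  state <- c(unclass(lat), list(
    U = U, Ad = 0, px = 0, s_raw = 0,
    s_buf = numeric(params$M), s_pos = 1L, S_t = 0, t = 0L
  ))
  class(state) <- "tme_state"
  state
}

# Advance a state through the compiled engine without a protocol.
engine_steps <- function(state, params, n_steps, record_every = 1L) {
  hypadsim:::cpp_simulate(state, params,
                          integer(0), numeric(0), integer(0), numeric(0),
                          integer(0), integer(0),
                          as.integer(n_steps), as.integer(record_every))
}
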