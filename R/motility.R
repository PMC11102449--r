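#' Sample a Levy-walk run length
#'
#' Inverts the discrete power-law run-length distribution
#' `F(z) = 1 - z^(-l)`, `z = 1, 2, ...`: the returned `z` is the smallest
#' positive integer with `1 - z^(-l) >= u`, i.e. `ceiling((1 - u)^(-1/l))`.
#' The pmf is `P(Z = z) = (z - 1)^(-l) - z^(-l)` for `z >= 2`, with `z = 1`
#' only on the boundary draw `u = 0`.
#'
#' @param u Uniform(0, 1) draw(s); must satisfy `0 <= u < 1`.
#' @param l Walk exponent, `> 1`.
#' @return Integer vector of run lengths, same length as `u`.
#' @export
#' @examples
#' sample_levy_run_length(c(0, 0.5, 0.9), l = 1.15)
sample_levy_run_length <- function(u, l) {
  if (l <= 1) stop("walk exponent 'l' must exceed 1")
  if (any(!is.finite(u)) || any(u < 0) || any(u >= 1)) {
    stop("'u' must lie in [0, 1)")
  }
  z <- ceiling((1 - u)^(-1 / l))
  z <- pmax(z, 1)
  # guard floating-point rounding at integer boundaries of the inverse CDF
  down <- z > 1 & (1 - (z - 1)^(-l)) >= u
  z[down] <- z[down] - 1
  up <- (1 - z^(-l)) < u
  z[up] <- z[up] + 1
  as.integer(z)
}

#' One Levy-walk step for a single agent
#'
#' Implements the persistent power-law walk of inactive immune cells. If no
#' run is in progress (`steps == 0`), a fresh run length `z` is drawn from
#' [sample_levy_run_length()] and a direction is drawn uniformly among the
#' currently empty Moore neighbors; the agent moves there and keeps the
#' direction for `z - 1` further steps. If no neighbor is empty the draw is
#' deferred to the next step. With a run in progress, the agent attempts one
#' move along the stored direction: a move onto an occupied site fails (the
#' agent waits), a move out of the grid fails and mirrors the stored direction
#' (a bounce off the boundary vessel wall); in both cases the remaining run
#' length still decrements.
#'
#' @param lattice A `"tme_lattice"` (or simulation state).
#' @param site `(row, col)` of the agent.
#' @param params Model parameters (uses the walk exponent `l`).
#' @return The updated lattice.
#' @export
levy_step <- function(lattice, site, params) {
  site <- .check_site(lattice, site)
  r <- site[1]; cc <- site[2]
  if (lattice$kind[r, cc] == 0L) stop("no agent at site")
  if (lattice$steps[r, cc] == 0L) {
    emp <- empty_moore_neighbors(lattice, site)
    ne <- nrow(emp)
    if (ne == 0L) return(lattice)
    z <- sample_levy_run_length(runif(1), params$l)
    j <- min(floor(runif(1) * ne) + 1, ne)
    to <- emp[j, ]
    d <- which(.moore_dr == to[1] - r & .moore_dc == to[2] - cc) - 1L
    lattice <- .move_agent(lattice, site, to)
    lattice$dir[to[1], to[2]] <- d
    lattice$steps[to[1], to[2]] <- z - 1L
  } else {
    d <- lattice$dir[r, cc]
    tr <- r + .moore_dr[d + 1]
    tc <- cc + .moore_dc[d + 1]
    lattice$steps[r, cc] <- lattice$steps[r, cc] - 1L
    if (tr < 1L || tr > lattice$N || tc < 1L || tc > lattice$N) {
      lattice$dir[r, cc] <- 7L - d
    } else if (lattice$kind[tr, tc] == 0L) {
      lattice <- .move_agent(lattice, site, c(tr, tc))
    }
    # occupied target: wait in place this step
  }
  lattice
}

#' One Brownian step for a single agent
#'
#' Activated immune cells move by Brownian motion: one of the eight Moore
#' directions is drawn with equal probability; the move is executed only when
#' the chosen site is inside the grid and empty, otherwise the agent stays
#' put this step.
#'
#' @inheritParams levy_step
#' @return The updated lattice.
#' @export
brownian_step <- function(lattice, site, params) {
  site <- .check_site(lattice, site)
  if (lattice$kind[site[1], site[2]] == 0L) stop("no agent at site")
  d <- min(floor(runif(1) * 8), 7)
  tr <- site[1] + .moore_dr[d + 1]
  tc <- site[2] + .moore_dc[d + 1]
  if (tr >= 1L && tr <= lattice$N && tc >= 1L && tc <= lattice$N &&
      lattice$kind[tr, tc] == 0L) {
    lattice <- .move_agent(lattice, site, c(tr, tc))
  }
  lattice
}
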