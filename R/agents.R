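#' Tumor division step
#'
#' Applies the rim-only stochastic division rule to every tumor cell, in a
#' uniformly shuffled order. A tumor cell with at least one empty Moore
#' neighbor divides with probability [tumor_rate()] evaluated at the oxygen
#' of its own site and the current global adenosine level; the daughter is
#' placed uniformly at random among the empty neighbors while the mother
#' stays in place. Fully enclosed cells cannot divide, so only the tumor rim
#' proliferates. Daughters placed earlier in the sweep occupy sites and can
#' block later divisions, exactly as in the compiled engine.
#'
#' @param lattice A `"tme_lattice"` (or simulation state).
#' @param U Oxygen concentration matrix.
#' @param Ad Global adenosine level.
#' @param params Model parameters.
#' @return The updated lattice.
#' @export
tumor_division_step <- function(lattice, U, Ad, params) {
  sites <- which(lattice$kind == 1L)
  if (length(sites) == 0L) return(lattice)
  ord <- sample.int(length(sites))
  n <- lattice$N
  for (s in sites[ord]) {
    rc <- c((s - 1L) %% n + 1L, (s - 1L) %/% n + 1L)
    emp <- empty_moore_neighbors(lattice, rc)
    ne <- nrow(emp)
    if (ne == 0L) next
    p <- tumor_rate(U[s], Ad, params)
    if (runif(1) < p) {
      j <- min(floor(runif(1) * ne) + 1, ne)
      lattice$kind[emp[j, 1], emp[j, 2]] <- 1L
    }
  }
  lattice
}

#' DC activation step
#'
#' Every inactive DC with at least one tumor cell in its Moore neighborhood
#' becomes an active (antigen-loaded) DC with probability `D_act`; its
#' motility switches from Levy walk to Brownian motion (any stored run is
#' discarded).
#'
#' @inheritParams tumor_division_step
#' @return The updated lattice.
#' @export
dc_activation_step <- function(lattice, params) {
  nbt <- .neighbor_count(lattice$kind == 1L)
  cand <- which(lattice$kind == 2L & nbt > 0L)
  if (length(cand) == 0L) return(lattice)
  act <- cand[runif(length(cand)) < params$D_act]
  lattice$kind[act] <- 3L
  lattice$dir[act] <- -1L
  lattice$steps[act] <- 0L
  lattice
}

#' T-cell activation and fate step
#'
#' Every inactive T cell adjacent to at least one active DC activates with
#' probability `C_act`. Upon activation, one adjacent active DC is chosen
#' uniformly as the activator and the cell polarizes to a Treg with
#' probability [treg_rate()] evaluated at the oxygen of the activating DC's
#' site (tolerogenic conditioning of the DC), otherwise it becomes an
#' effector cell. Activated cells switch to Brownian motion. One active DC
#' may activate several T cells in the same step.
#'
#' @inheritParams tumor_division_step
#' @return The updated lattice.
#' @export
t_activation_step <- function(lattice, U, Ad, params) {
  nbd <- .neighbor_count(lattice$kind == 3L)
  cand <- which(lattice$kind == 4L & nbd > 0L)
  if (length(cand) == 0L) return(lattice)
  act <- cand[runif(length(cand)) < params$C_act]
  n <- lattice$N
  for (s in act) {
    rc <- c((s - 1L) %% n + 1L, (s - 1L) %/% n + 1L)
    nb <- moore_neighbors(lattice, rc)
    dcs <- nb[lattice$kind[nb] == 3L, , drop = FALSE]
    j <- min(floor(runif(1) * nrow(dcs)) + 1, nrow(dcs))
    p <- treg_rate(U[dcs[j, 1], dcs[j, 2]], Ad, params)
    lattice$kind[s] <- if (runif(1) < p) 5L else 6L
    lattice$dir[s] <- -1L
    lattice$steps[s] <- 0L
  }
  lattice
}

#' Effector killing step
#'
#' Every effector cell with at least one tumor cell in its Moore neighborhood
#' selects one of them uniformly at random and removes it with probability
#' [cytotoxicity_rate()] evaluated at the oxygen of the effector's site; the
#' vacated site becomes empty. The effector survives and can kill again in
#' later steps (serial killing); at most one kill per effector per step.
#' Effectors are processed in a uniformly shuffled order.
#'
#' @inheritParams tumor_division_step
#' @return A list with elements `lattice` (updated) and `kills` (count).
#' @export
effector_kill_step <- function(lattice, U, Ad, params) {
  sites <- which(lattice$kind == 6L)
  kills <- 0L
  if (length(sites) == 0L) return(list(lattice = lattice, kills = kills))
  ord <- sample.int(length(sites))
  n <- lattice$N
  for (s in sites[ord]) {
    rc <- c((s - 1L) %% n + 1L, (s - 1L) %/% n + 1L)
    nb <- moore_neighbors(lattice, rc)
    tum <- nb[lattice$kind[nb] == 1L, , drop = FALSE]
    nt <- nrow(tum)
    if (nt == 0L) next
    j <- min(floor(runif(1) * nt) + 1, nt)
    p <- cytotoxicity_rate(U[s], Ad, params)
    if (runif(1) < p) {
      lattice$kind[tum[j, 1], tum[j, 2]] <- 0L
      lattice$dir[tum[j, 1], tum[j, 2]] <- -1L
      lattice$steps[tum[j, 1], tum[j, 2]] <- 0L
      kills <- kills + 1L
    }
  }
  list(lattice = lattice, kills = kills)
}

#' DC inactivation step
#'
#' Every active DC with at least one Treg in its Moore neighborhood reverts
#' to the inactive state with probability `D_inact` (contact-mediated
#' suppression). A deactivated DC resumes Levy-walk motility with a fresh run
#' and can be re-activated later by tumor contact. Each active DC adjacent to
#' a Treg rolls independently, so one Treg can suppress several DCs in one
#' step.
#'
#' @inheritParams tumor_division_step
#' @return The updated lattice.
#' @export
dc_inactivation_step <- function(lattice, params) {
  nbr <- .neighbor_count(lattice$kind == 5L)
  cand <- which(lattice$kind == 3L & nbr > 0L)
  if (length(cand) == 0L) return(lattice)
  deact <- cand[runif(length(cand)) < params$D_inact]
  lattice$kind[deact] <- 2L
  lattice$dir[deact] <- -1L
  lattice$steps[deact] <- 0L
  lattice
}
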