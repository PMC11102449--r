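# Moore-neighborhood offsets in the package's canonical order.
# Direction index d (0-based, 0..7) maps to row offset .moore_dr[d + 1]
# and column offset .moore_dc[d + 1]; the mirrored direction is 7 - d.
.moore_dr <- c(-1L, -1L, -1L, 0L, 0L, 1L, 1L, 1L)
.moore_dc <- c(-1L, 0L, 1L, -1L, 1L, -1L, 0L, 1L)

#' Agent type codes
#'
#' Integer codes used in the lattice occupancy matrix: 0 = empty, 1 = tumor,
#' 2 = inactive DC, 3 = active DC, 4 = inactive T cell, 5 = Treg,
#' 6 = effector cell. A site holds at most one agent.
#'
#' @return Named integer vector of codes.
#' @export
agent_codes <- function() {
  c(empty = 0L, tumor = 1L, dc_inactive = 2L, dc_active = 3L,
    t_inactive = 4L, treg = 5L, effector = 6L)
}

#' Create an empty lattice
#'
#' The lattice stores, per site, the occupying agent type (`kind`, see
#' [agent_codes()]) and the motility state of the occupant: the current Levy
#' direction (`dir`, 0..7 or -1 when no run is in progress) and the remaining
#' steps of the current Levy run (`steps`). Agents in Brownian mode carry
#' `steps = 0`.
#'
#' @param N Side length (sites).
#' @return A list of class `"tme_lattice"` with elements `N`, `kind`, `dir`
#'   and `steps` (all matrices except `N`).
#' @export
new_lattice <- function(N) {
  N <- as.integer(N)
  if (N < 3) stop("lattice side must be at least 3")
  structure(
    list(
      N = N,
      kind = matrix(0L, N, N),
      dir = matrix(-1L, N, N),
      steps = matrix(0L, N, N)
    ),
    class = "tme_lattice"
  )
}

.check_site <- function(lattice, site) {
  if (length(site) != 2 || any(!is.finite(site))) {
    stop("site must be a (row, col) pair")
  }
  site <- as.integer(site)
  if (any(site < 1L) || any(site > lattice$N)) {
    stop("site (", site[1], ", ", site[2], ") is outside the ",
         lattice$N, " x ", lattice$N, " grid")
  }
  site
}

#' Moore neighbors of a site
#'
#' Returns the in-grid Moore neighbors (up to 8) of a lattice site, in the
#' package's canonical direction order. There is no wrap-around: corner sites
#' have 3 neighbors and edge sites 5.
#'
#' @param lattice A `"tme_lattice"` (or any list with element `N`).
#' @param site Integer `(row, col)`, 1-based.
#' @return Integer matrix with columns `row`, `col` and one row per neighbor.
#' @export
moore_neighbors <- function(lattice, site) {
  site <- .check_site(lattice, site)
  r <- site[1] + .moore_dr
  c <- site[2] + .moore_dc
  keep <- r >= 1L & r <= lattice$N & c >= 1L & c <= lattice$N
  cbind(row = r[keep], col = c[keep])
}

#' Empty Moore neighbors of a site
#'
#' The subset of [moore_neighbors()] whose sites are unoccupied; these are the
#' candidate positions for tumor daughters and for fresh Levy directions.
#'
#' @inheritParams moore_neighbors
#' @return Integer matrix with columns `row`, `col` (possibly 0 rows).
#' @export
empty_moore_neighbors <- function(lattice, site) {
  nb <- moore_neighbors(lattice, site)
  nb[lattice$kind[nb] == 0L, , drop = FALSE]
}

#' Audit lattice occupancy
#'
#' Recomputes the per-type occupancy counts from the occupancy matrix and
#' checks the structural invariants of the representation: type codes in
#' 0..6, directions in -1..7, non-negative remaining run lengths, and zero
#' remaining run length for activated (Brownian) agents. Because occupancy is
#' a single matrix, single occupancy per site holds by construction; the audit
#' guards against corrupted motility bookkeeping.
#'
#' @param lattice A `"tme_lattice"` or simulation state containing `kind`,
#'   `dir`, `steps`.
#' @return Named integer vector of counts per agent type.
#' @export
audit_lattice <- function(lattice) {
  k <- lattice$kind
  if (any(!(k %in% 0:6))) stop("audit failed: invalid agent code on lattice")
  if (any(!(lattice$dir %in% -1:7))) stop("audit failed: invalid direction")
  if (any(lattice$steps < 0L)) stop("audit failed: negative run length")
  brown <- k %in% c(1L, 3L, 5L, 6L)
  if (any(lattice$steps[brown] != 0L)) {
    stop("audit failed: Brownian/stationary agent with remaining Levy steps")
  }
  if (any(lattice$dir[k == 0L] != -1L) || any(lattice$steps[k == 0L] != 0L)) {
    stop("audit failed: motility state on an empty site")
  }
  codes <- agent_codes()
  counts <- vapply(codes, function(code) sum(k == code), integer(1))
  names(counts) <- names(codes)
  counts
}

# Move an agent between sites, carrying its motility state.
.move_agent <- function(lattice, from, to) {
  lattice$kind[to[1], to[2]] <- lattice$kind[from[1], from[2]]
  lattice$dir[to[1], to[2]] <- lattice$dir[from[1], from[2]]
  lattice$steps[to[1], to[2]] <- lattice$steps[from[1], from[2]]
  lattice$kind[from[1], from[2]] <- 0L
  lattice$dir[from[1], from[2]] <- -1L
  lattice$steps[from[1], from[2]] <- 0L
  lattice
}

# Count, for every site, how many Moore neighbors satisfy a logical mask.
# Used by the vectorized per-rule updates.
.neighbor_count <- function(mask) {
  n <- nrow(mask)
  out <- matrix(0L, n, n)
  for (d in seq_len(8)) {
    dr <- .moore_dr[d]; dc <- .moore_dc[d]
    ri <- max(1L, 1L - dr):min(n, n - dr)
    ci <- max(1L, 1L - dc):min(n, n - dc)
    out[ri, ci] <- out[ri, ci] + mask[ri + dr, ci + dc]
  }
  out
}
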