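#' Create an oxygen field
#'
#' Initial condition for the oxygen reaction-diffusion scheme: zero
#' concentration everywhere inside the grid, with the boundary sites held at
#' the fixed vessel concentration `U_boundary` (Dirichlet boundary).
#'
#' @param N Grid side length (divisible by 3).
#' @param U_boundary Boundary oxygen concentration (mMol).
#' @return An `N x N` numeric matrix.
#' @export
new_oxygen_field <- function(N, U_boundary = 0.8) {
  U <- matrix(0, N, N)
  U[1, ] <- U_boundary
  U[N, ] <- U_boundary
  U[, 1] <- U_boundary
  U[, N] <- U_boundary
  U
}

#' Average concentration of a 3x3 block
#'
#' The grid is partitioned into non-overlapping 3x3 blocks anchored at site
#' (1, 1); valid block centers are the sites whose row and column are
#' congruent to 2 modulo 3. Returns the arithmetic mean of the block's nine
#' sites.
#'
#' @param U Concentration matrix.
#' @param center `(row, col)` of a block center.
#' @return Scalar mean concentration.
#' @export
block_average <- function(U, center) {
  center <- as.integer(center)
  n <- nrow(U)
  if (length(center) != 2 || any(center < 2) || any(center > n - 1) ||
      any(center %% 3 != 2)) {
    stop("center (", center[1], ", ", center[2],
         ") is not a 3x3 block center of the fixed partition")
  }
  mean(U[(center[1] - 1):(center[1] + 1), (center[2] - 1):(center[2] + 1)])
}

# Block means of an N x N matrix -> (N/3) x (N/3) matrix.
.block_means <- function(M) {
  b <- nrow(M) %/% 3L
  g <- rep(seq_len(b), each = 3)
  t(rowsum(t(rowsum(M, g, reorder = FALSE)), g, reorder = FALSE)) / 9
}

# Truncated Moore(+self) mean over a coarse matrix: mean of the up-to-9
# entries of the 3x3 neighborhood that fall inside the matrix.
.moore_block_mean <- function(V) {
  b <- nrow(V)
  S <- matrix(0, b, b)
  C <- matrix(0, b, b)
  for (dr in -1:1) {
    for (dc in -1:1) {
      ri <- max(1L, 1L - dr):min(b, b - dr)
      ci <- max(1L, 1L - dc):min(b, b - dc)
      S[ri, ci] <- S[ri, ci] + V[ri + dr, ci + dc]
      C[ri, ci] <- C[ri, ci] + 1
    }
  }
  S / C
}

#' One oxygen diffusion step
#'
#' Advances the block-discretized reaction-diffusion scheme by one time step.
#' The grid is partitioned into fixed non-overlapping 3x3 blocks; each block
#' carries its mean concentration `V`. The updated block value is
#' `alpha * A + (1 - alpha) * V - f_bar * (tumor fraction of the block)
#' + k * px`, where `A` is the mean of `V` over the block's (truncated) 3x3
#' neighborhood of blocks -- the diffusive mixing term -- and the tumor
#' consumption `f_bar` is weighted by the fraction of the block's nine sites
#' occupied by tumor. The updated value is redistributed to all nine sites of
#' the block, negative values are clamped to zero, and the Dirichlet boundary
#' is re-imposed at `U_boundary`. The hypoxia-inhibitor source `k * px` is
#' spatially uniform (the drug is modeled as well mixed).
#'
#' With no tumor and `px = 0` the scheme relaxes monotonically to the uniform
#' boundary value, on which it is exactly idempotent.
#'
#' @param U Concentration matrix (side divisible by 3).
#' @param tumor_mask Logical or 0/1 matrix of tumor-occupied sites.
#' @param px Current hypoxia-inhibitor concentration (scalar).
#' @param params Model parameters (`alpha`, `f_bar`, `k`, `U_boundary`).
#' @return The updated concentration matrix.
#' @export
diffuse_step <- function(U, tumor_mask, px, params) {
  n <- nrow(U)
  if (n %% 3L != 0L) stop("grid side must be divisible by 3")
  V <- .block_means(U)
  TF <- .block_means(tumor_mask * 1)
  A <- .moore_block_mean(V)
  newV <- params$alpha * A + (1 - params$alpha) * V -
    params$f_bar * TF + params$k * px
  newV[newV < 0] <- 0
  idx <- rep(seq_len(n %/% 3L), each = 3)
  Unew <- newV[idx, idx, drop = FALSE]
  dimnames(Unew) <- NULL
  Unew[1, ] <- params$U_boundary
  Unew[n, ] <- params$U_boundary
  Unew[, 1] <- params$U_boundary
  Unew[, n] <- params$U_boundary
  Unew
}

#' Hypoxia level at a site
#'
#' Hypoxia is modeled as inversely proportional to the local oxygen
#' concentration: `1 / (U + c)`, with the small offset `c > 0` preventing
#' division by zero in anoxic sites.
#'
#' @param U Concentration matrix (or a scalar concentration).
#' @param site `(row, col)`; ignored when `U` is scalar.
#' @param c Denominator offset (> 0).
#' @return Hypoxia level.
#' @export
hypoxia_at <- function(U, site = NULL, c = 0.01) {
  if (c <= 0) stop("'c' must be positive")
  u <- if (is.matrix(U)) U[site[1], site[2]] else U
  1 / (u + c)
}

#' Write an oxygen-field snapshot
#'
#' Dumps a concentration grid as a plain-text CSV matrix together with a JSON
#' sidecar recording the simulated day and units, for later inspection of the
#' spatial oxygen/hypoxia pattern around the tumor.
#'
#' @param U Concentration matrix.
#' @param path Output CSV path; the sidecar is written to `<path>.json`.
#' @param day Simulated day of the snapshot.
#' @return `path`, invisibly.
#' @export
write_field_snapshot <- function(U, path, day = NA_real_) {
  utils::write.table(U, path, sep = ",", row.names = FALSE, col.names = FALSE)
  sidecar <- sprintf(
    '{"day": %s, "units": "mMol", "rows": %d, "cols": %d}',
    ifelse(is.na(day), "null", format(day)), nrow(U), ncol(U)
  )
  writeLines(sidecar, paste0(path, ".json"))
  invisible(path)
}
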