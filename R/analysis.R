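#' Coefficient of determination
#'
#' `R^2 = 1 - SS_res / SS_tot` between a simulated series and a reference
#' series at matched time points. Values below zero (a fit worse than the
#' reference mean) are returned as computed and flagged with a warning.
#' `R^2` is invariant to applying a common affine rescaling to both series.
#'
#' @param sim Simulated series.
#' @param ref Reference series (same length, nonzero variance).
#' @return The coefficient of determination.
#' @export
#' @examples
#' rsq(c(1, 2, 4), c(1, 2, 3))  # 0.5
rsq <- function(sim, ref) {
  if (length(sim) != length(ref)) stop("series must have equal length")
  ss_tot <- sum((ref - mean(ref))^2)
  if (ss_tot == 0) stop("reference series is constant (SS_tot = 0)")
  out <- 1 - sum((ref - sim)^2) / ss_tot
  if (out < 0) {
    warning("negative R-squared (", signif(out, 4),
            "): model fits worse than the reference mean")
  }
  out
}

#' Partial rank correlation coefficients
#'
#' PRCC between each column of a design matrix and a response: all variables
#' are rank-transformed, then for each input the linear effects of the other
#' inputs are regressed out of both the input and the response, and the
#' Pearson correlation of the two residual vectors is returned. PRCC is the
#' standard global-sensitivity statistic for monotone input-output
#' relationships under Latin-hypercube sampling.
#'
#' @param X Numeric matrix, one column per input parameter.
#' @param y Numeric response vector.
#' @return Named numeric vector of PRCC values in \[-1, 1\].
#' @export
prcc <- function(X, y) {
  X <- as.matrix(X)
  if (nrow(X) != length(y)) stop("nrow(X) must equal length(y)")
  if (any(apply(X, 2, sd) == 0)) {
    stop("degenerate sampling: an input column is constant")
  }
  R <- apply(X, 2, rank)
  ry <- rank(y)
  out <- vapply(seq_len(ncol(X)), function(j) {
    Z <- cbind(1, R[, -j, drop = FALSE])
    rx <- stats::lm.fit(Z, R[, j])$residuals
    rr <- stats::lm.fit(Z, ry)$residuals
    if (sd(rx) == 0 || sd(rr) == 0) return(0)
    cor(rx, rr)
  }, numeric(1))
  names(out) <- colnames(X)
  out
}

#' Latin-hypercube global sensitivity analysis
#'
#' Samples the named parameters jointly and uniformly within
#' `+/- rel_range` of their defaults using a Latin hypercube, evaluates a
#' scalar model response for each sample (by default the tumor volume
#' averaged over an untreated run, averaged over
#' `replicates_per_sample` stochastic replicates), and ranks the parameters
#' by the absolute partial rank correlation coefficient between parameter
#' and response.
#'
#' @param params Base parameter set; defaults are the sampling centers.
#' @param param_names Character vector of parameters to perturb.
#' @param n_samples Number of hypercube samples (>= 10 per parameter).
#' @param rel_range Relative half-range of the uniform sampling (> 0;
#'   default 0.5, i.e. +/- 50%).
#' @param seed Integer seed for sampling and the per-sample simulations.
#' @param replicates_per_sample Stochastic replicates averaged per sample.
#' @param horizon_days Horizon of the per-sample simulations.
#' @param response Optional function `(params, seed) -> scalar` replacing the
#'   default untreated-tumor-volume response; used to plug in other outputs
#'   or analytic test harnesses.
#' @return A data.frame with columns `parameter`, `prcc` and `rank`
#'   (1 = largest `|prcc|`), ordered by rank; class `"tme_sensitivity"`.
#' @export
global_sensitivity <- function(params = default_parameters(), param_names,
                               n_samples, rel_range = 0.5, seed = 1,
                               replicates_per_sample = 3, horizon_days = 18,
                               response = NULL) {
  k <- length(param_names)
  if (n_samples < 10 * k) {
    stop("'n_samples' must be at least 10 per parameter (>= ", 10 * k, ")")
  }
  if (rel_range <= 0) stop("degenerate sampling: 'rel_range' must be > 0")
  bad <- setdiff(param_names, names(params))
  if (length(bad)) stop("unknown parameter(s): ", paste(bad, collapse = ", "))
  centers <- vapply(param_names, function(nm) params[[nm]], 0)
  if (any(centers == 0)) {
    stop("cannot sample +/- a relative range around a zero default: ",
         paste(param_names[centers == 0], collapse = ", "))
  }
  set.seed(seed)
  L <- lhs::randomLHS(n_samples, k)
  X <- sweep(sweep(L * 2 - 1, 2, centers * rel_range, `*`), 2, centers, `+`)
  colnames(X) <- param_names
  if (is.null(response)) {
    response <- function(p, s) {
      vols <- vapply(seq_len(replicates_per_sample), function(rep) {
        tr <- run_simulation(p, protocol = NULL, seed = s + rep,
                             horizon_days = horizon_days)$trajectory
        mean(tr$volume_mm3)
      }, 0)
      mean(vols)
    }
  }
  y <- vapply(seq_len(n_samples), function(i) {
    p <- params
    for (j in seq_len(k)) p[[param_names[j]]] <- X[i, j]
    response(p, seed + i * 101L)
  }, 0)
  pr <- prcc(X, y)
  out <- data.frame(parameter = param_names, prcc = unname(pr))
  out$rank <- rank(-abs(out$prcc), ties.method = "first")
  out <- out[order(out$rank), ]
  rownames(out) <- NULL
  class(out) <- c("tme_sensitivity", "data.frame")
  out
}

# The seven model outputs screened in the identifiability analysis, derived
# from a daily-resampled trajectory.
.identifiability_outputs <- function(tr, params) {
  list(
    tumor_volume = tr$volume_mm3,
    adenosine = tr$adenosine,
    hypoxia = 1 / (tr$mean_oxygen + params$c),
    cytotoxicity = tr$cytotoxicity,
    effector = tr$n_effector,
    treg = tr$n_treg,
    dc = tr$n_dc_active
  )
}

#' Pairwise identifiability screening
#'
#' Computes, for every named parameter, the central finite-difference
#' sensitivity trajectory of each model output (tumor volume, adenosine,
#' hypoxia, ambient cytotoxicity, effector, Treg and active-DC counts at
#' daily resolution, averaged over `replicates` runs with common random
#' numbers for the +/- perturbations), then the Pearson correlation between
#' the sensitivity trajectories of every parameter pair, per output. A pair
#' is flagged non-identifiable when `|correlation| >= threshold` for *every*
#' output -- its two parameters move all observable outputs along collinear
#' directions and cannot be determined separately from such data. Parameters
#' whose sensitivity is identically zero in all outputs are reported inert
#' and excluded from pair correlations with a warning.
#'
#' @param params Base parameter set.
#' @param param_names Parameters to screen.
#' @param delta Relative finite-difference step (> 0; default 0.1).
#' @param seed Integer seed.
#' @param replicates Replicates averaged per perturbed run.
#' @param horizon_days Horizon of the runs.
#' @param protocol Protocol under which sensitivities are computed (default
#'   untreated).
#' @param threshold Collinearity threshold (default 0.9).
#' @param simulator Optional function `(params, seed) -> named list of output
#'   series` replacing the model run; used for analytic test harnesses.
#' @return A list of class `"tme_identifiability"`: `min_abs_cor` (symmetric
#'   matrix with unit diagonal: the minimum over outputs of the absolute
#'   pairwise correlation -- the quantity compared with the threshold),
#'   `per_output` (3D array parameter x parameter x output), `flagged`
#'   (data.frame of non-identifiable pairs), `inert` (character vector).
#' @export
identifiability <- function(params = default_parameters(), param_names,
                            delta = 0.1, seed = 1, replicates = 2,
                            horizon_days = 18, protocol = NULL,
                            threshold = 0.9, simulator = NULL) {
  if (delta <= 0) stop("'delta' must be positive")
  bad <- setdiff(param_names, names(params))
  if (length(bad)) stop("unknown parameter(s): ", paste(bad, collapse = ", "))
  if (is.null(simulator)) {
    spd <- steps_per_day(params)
    simulator <- function(p, s) {
      acc <- NULL
      for (rep in seq_len(replicates)) {
        tr <- run_simulation(p, protocol = protocol, seed = s + rep,
                             horizon_days = horizon_days)$trajectory
        tr <- tr[tr$step %% spd == 0, , drop = FALSE]
        outs <- .identifiability_outputs(tr, params)
        if (is.null(acc)) acc <- outs
        else acc <- Map(`+`, acc, outs)
      }
      lapply(acc, function(x) x / replicates)
    }
  }
  k <- length(param_names)
  sens <- vector("list", k)
  names(sens) <- param_names
  for (j in seq_len(k)) {
    nm <- param_names[j]
    p0 <- params[[nm]]
    if (p0 == 0) stop("cannot perturb zero-valued parameter '", nm, "'")
    up <- params; up[[nm]] <- p0 * (1 + delta)
    dn <- params; dn[[nm]] <- p0 * (1 - delta)
    # common random numbers: same seed for + and - perturbations
    o_up <- simulator(up, seed)
    o_dn <- simulator(dn, seed)
    sens[[j]] <- Map(function(a, b) (a - b) / (2 * delta * p0), o_up, o_dn)
  }
  out_names <- names(sens[[1]])
  inert <- param_names[vapply(sens, function(sj) {
    all(vapply(sj, function(x) {
      x <- x[is.finite(x)]
      length(x) == 0 || sd(x) == 0
    }, TRUE))
  }, TRUE)]
  if (length(inert)) {
    warning("inert parameter(s) excluded from pair correlations: ",
            paste(inert, collapse = ", "))
  }
  per_output <- array(NA_real_, dim = c(k, k, length(out_names)),
                      dimnames = list(param_names, param_names, out_names))
  for (o in seq_along(out_names)) {
    for (i in seq_len(k)) {
      per_output[i, i, o] <- 1
      for (j in seq_len(k)) {
        if (j <= i) next
        if (param_names[i] %in% inert || param_names[j] %in% inert) next
        xi <- sens[[i]][[o]]
        xj <- sens[[j]][[o]]
        ok <- is.finite(xi) & is.finite(xj)
        cc <- if (sum(ok) > 2 && sd(xi[ok]) > 0 && sd(xj[ok]) > 0) {
          cor(xi[ok], xj[ok])
        } else NA_real_
        per_output[i, j, o] <- cc
        per_output[j, i, o] <- cc
      }
    }
  }
  min_abs <- apply(abs(per_output), c(1, 2), function(v) {
    if (all(is.na(v))) NA_real_ else min(v, na.rm = TRUE)
  })
  diag(min_abs) <- 1
  flagged <- data.frame(param1 = character(0), param2 = character(0),
                        min_abs_cor = numeric(0))
  for (i in seq_len(k)) {
    for (j in seq_len(k)) {
      if (j <= i) next
      m <- min_abs[i, j]
      if (!is.na(m) && m >= threshold) {
        flagged <- rbind(flagged, data.frame(
          param1 = param_names[i], param2 = param_names[j], min_abs_cor = m))
      }
    }
  }
  structure(list(min_abs_cor = min_abs, per_output = per_output,
                 flagged = flagged, inert = inert, threshold = threshold),
            class = "tme_identifiability")
}

#' @export
print.tme_identifiability <- function(x, ...) {
  k <- nrow(x$min_abs_cor)
  cat("Identifiability screening of", k, "parameters (threshold",
      x$threshold, ")\n")
  if (nrow(x$flagged) == 0) {
    cat("  no non-identifiable pair: every pair decorrelates in at least one output\n")
  } else {
    cat("  non-identifiable pairs:\n")
    print(x$flagged)
  }
  if (length(x$inert)) cat("  inert parameters:", paste(x$inert, collapse = ", "), "\n")
  invisible(x)
}

#' Synthetic reference tumor-growth curve
#'
#' Generates a smooth logistic tumor-volume curve for goodness-of-fit
#' demonstrations. This is a synthetic stand-in for an empirical caliper
#' time series (which would be supplied as a day/volume table); it is not
#' derived from any measured data.
#'
#' @param days Numeric vector of days.
#' @param v_final Volume reached at the last day (mm^3).
#' @param midpoint Day of the inflection.
#' @param steepness Logistic growth steepness (per day).
#' @return Numeric vector of volumes (mm^3).
#' @export
synthetic_reference_curve <- function(days, v_final = 400, midpoint = 12,
                                      steepness = 0.45) {
  raw <- 1 / (1 + exp(-steepness * (days - midpoint)))
  raw <- raw - raw[1]
  v_final * raw / raw[length(raw)]
}
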