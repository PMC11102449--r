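#' Default model parameters
#'
#' Returns the calibrated parameter set of the tumor-immune model: the
#' humoral rates (adenosine production/elimination, vaccine pharmacokinetics),
#' the hypoxia/adenosine modulation coefficients, the per-step agent-rule
#' probabilities, the lattice geometry and the unit conversions. All rates are
#' expressed per time step (one step = `dt_minutes` minutes) and are used
#' directly as per-step Bernoulli probabilities or forward-Euler increments.
#'
#' Fields:
#' \describe{
#'   \item{gamma}{adenosine inhibition by the (filtered) adenosine-inhibitor
#'     drug, per step.}
#'   \item{a}{strength of hypoxia-driven adenosine production; enters as
#'     `a / (U + c)`.}
#'   \item{r}{adenosine elimination rate per step.}
#'   \item{beta}{basal adenosine production per step.}
#'   \item{r_At, r_Ht}{adenosine and hypoxia effects on tumor proliferation.}
#'   \item{r_Ar, r_Hr}{adenosine and hypoxia effects on Treg polarization.}
#'   \item{r_Ae, r_He}{adenosine and hypoxia penalties on effector
#'     cytotoxicity.}
#'   \item{lambda_s, eta}{elimination rates of the adenosine inhibitor (siRNA)
#'     and hypoxia inhibitor (Px-478).}
#'   \item{k}{oxygen added per step per unit of hypoxia-inhibitor
#'     concentration.}
#'   \item{D_act, C_act, D_inact}{DC activation by tumor contact, T-cell
#'     activation by active DCs, DC deactivation by Tregs.}
#'   \item{mu, P_Treg, P_tumor}{base cytotoxicity, Treg polarization and tumor
#'     division probabilities.}
#'   \item{f_bar}{oxygen consumed per tumor site per step (mMol).}
#'   \item{c}{offset preventing division by zero in the hypoxia term
#'     `1 / (U + c)`.}
#'   \item{l}{Levy-walk exponent.}
#'   \item{N_T, N_D, V_DC}{initial inactive T-cell and DC counts and the DC
#'     vaccine bolus size.}
#'   \item{M}{moving-average window (steps) of the drug adhesion filter.}
#'   \item{N, chi}{grid side length (sites, divisible by 3) and site spacing
#'     in micrometers.}
#'   \item{dt_minutes}{minutes per simulation step.}
#'   \item{alpha}{oxygen diffusion mixing coefficient, in (0, 1).}
#'   \item{U_boundary}{Dirichlet boundary oxygen concentration (mMol),
#'     representing vessels at the grid edge.}
#'   \item{dose_px, dose_s}{bolus magnitudes of the hypoxia- and
#'     adenosine-inhibitor vaccines.}
#'   \item{volume_factor, site_area_mm2}{2D-to-3D volume conversion: tumor
#'     volume (mm^3) = sites x `site_area_mm2` x `volume_factor`.}
#' }
#'
#' @return A validated list of class `"tme_params"`.
#' @seealso [read_parameters()], [write_parameters()]
#' @export
#' @examples
#' p <- default_parameters()
#' p$P_tumor
default_parameters <- function() {
  p <- list(
    gamma = 0.000038,
    a = 0.9412,
    r = 0.07,
    beta = 12,
    r_At = 0.000025,
    r_Ht = 0.0021,
    r_Ar = 0.0015,
    r_Hr = 0.0047,
    lambda_s = 0.002,
    D_act = 0.003,
    C_act = 0.24,
    mu = 0.45,
    r_Ae = 0.001,
    r_He = 0.014,
    D_inact = 0.01,
    eta = 0.014,
    k = 0.00004,
    P_Treg = 0.3,
    P_tumor = 0.001,
    f_bar = 0.0023,
    c = 0.01,
    l = 1.15,
    N_T = 750,
    N_D = 100,
    V_DC = 70,
    M = 800,
    N = 210,
    chi = 10,
    dt_minutes = 2,
    alpha = 0.5,
    U_boundary = 0.8,
    dose_px = 40,
    dose_s = 4200,
    volume_factor = 2200,
    site_area_mm2 = 1e-4
  )
  class(p) <- "tme_params"
  validate_parameters(p)
}

#' Validate a parameter set
#'
#' Checks that every field is present, that all agent-rule probabilities are
#' in \[0, 1\], that `alpha` is in (0, 1), that the Levy exponent exceeds 1,
#' and that the grid side is at least 9 and divisible by 3 (the oxygen scheme
#' partitions the grid into 3x3 blocks).
#'
#' @param params A list of model parameters (see [default_parameters()]).
#' @return `params`, invisibly with class `"tme_params"`, or an error.
#' @export
validate_parameters <- function(params) {
  required <- names(default_parameter_list())
  missing <- setdiff(required, names(params))
  if (length(missing) > 0) {
    stop("missing parameter(s): ", paste(missing, collapse = ", "))
  }
  unknown <- setdiff(names(params), required)
  if (length(unknown) > 0) {
    stop("unknown parameter(s): ", paste(unknown, collapse = ", "))
  }
  probs <- c("D_act", "C_act", "D_inact", "mu", "P_Treg", "P_tumor")
  for (nm in probs) {
    v <- params[[nm]]
    if (!is.numeric(v) || v < 0 || v > 1) {
      stop("parameter '", nm, "' must be a probability in [0, 1]")
    }
  }
  if (params$alpha <= 0 || params$alpha >= 1) stop("'alpha' must lie in (0, 1)")
  if (params$l <= 1) stop("Levy exponent 'l' must exceed 1")
  if (params$M < 1) stop("moving-average window 'M' must be >= 1")
  if (params$N < 9 || params$N %% 3 != 0) {
    stop("grid side 'N' must be >= 9 and divisible by 3")
  }
  if (params$c <= 0) stop("'c' must be positive")
  if (params$dt_minutes <= 0) stop("'dt_minutes' must be positive")
  nonneg <- c(
    "gamma", "a", "r", "beta", "r_At", "r_Ht", "r_Ar", "r_Hr", "lambda_s",
    "r_Ae", "r_He", "eta", "k", "f_bar", "N_T", "N_D", "V_DC", "U_boundary",
    "dose_px", "dose_s", "volume_factor", "site_area_mm2"
  )
  for (nm in nonneg) {
    if (!is.numeric(params[[nm]]) || params[[nm]] < 0) {
      stop("parameter '", nm, "' must be non-negative")
    }
  }
  class(params) <- "tme_params"
  invisible(params)
}

# Unclassed default list; single source of truth for the field set.
default_parameter_list <- function() {
  p <- default_parameters_raw
  p
}

# Stored as a plain list so validate_parameters() and default_parameters()
# cannot disagree about the field set.
default_parameters_raw <- local({
  list(
    gamma = 0.000038, a = 0.9412, r = 0.07, beta = 12, r_At = 0.000025,
    r_Ht = 0.0021, r_Ar = 0.0015, r_Hr = 0.0047, lambda_s = 0.002,
    D_act = 0.003, C_act = 0.24, mu = 0.45, r_Ae = 0.001, r_He = 0.014,
    D_inact = 0.01, eta = 0.014, k = 0.00004, P_Treg = 0.3, P_tumor = 0.001,
    f_bar = 0.0023, c = 0.01, l = 1.15, N_T = 750, N_D = 100, V_DC = 70,
    M = 800, N = 210, chi = 10, dt_minutes = 2, alpha = 0.5, U_boundary = 0.8,
    dose_px = 40, dose_s = 4200, volume_factor = 2200, site_area_mm2 = 1e-4
  )
})

#' Read a parameter file
#'
#' Reads a flat key-value YAML file and overlays it on the defaults. Unknown
#' keys are rejected; omitted keys keep their default values.
#'
#' @param path Path to a YAML file.
#' @return A validated `"tme_params"` list.
#' @export
read_parameters <- function(path) {
  # keep YAML-1.1 boolean-like keys such as "N" as literal strings
  keep <- function(x) x
  vals <- yaml::read_yaml(path, handlers = list("bool#yes" = keep,
                                                "bool#no" = keep))
  if (!is.list(vals)) stop("parameter file must be a flat key: value mapping")
  p <- default_parameter_list()
  unknown <- setdiff(names(vals), names(p))
  if (length(unknown) > 0) {
    stop("unknown parameter(s) in '", path, "': ",
         paste(unknown, collapse = ", "))
  }
  p[names(vals)] <- vals
  class(p) <- "tme_params"
  validate_parameters(p)
  p
}

#' Write a parameter file
#'
#' Serializes a parameter set to flat YAML with enough precision that reading
#' it back reproduces every value bit-identically.
#'
#' @param params A `"tme_params"` list.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_parameters <- function(params, path) {
  validate_parameters(params)
  yaml::write_yaml(unclass(params), path, precision = 17)
  invisible(path)
}

#' Simulation steps per day
#'
#' @param params A `"tme_params"` list.
#' @return Integer number of steps in one simulated day (720 at the default
#'   2-minute step).
#' @export
steps_per_day <- function(params) {
  as.integer(round(24 * 60 / params$dt_minutes))
}

#' @export
print.tme_params <- function(x, ...) {
  cat("Tumor-immune model parameters (", length(x), " fields)\n", sep = "")
  cat("  grid: ", x$N, " x ", x$N, " sites (", x$chi, " um spacing), dt = ",
      x$dt_minutes, " min\n", sep = "")
  cat("  initial cells: 1 tumor, ", x$N_D, " inactive DC, ", x$N_T,
      " inactive T\n", sep = "")
  cat("  adenosine: beta = ", x$beta, ", a = ", x$a, ", r = ", x$r,
      ", gamma = ", x$gamma, "\n", sep = "")
  cat("  base probabilities: P_tumor = ", x$P_tumor, ", P_Treg = ", x$P_Treg,
      ", mu = ", x$mu, "\n", sep = "")
  invisible(x)
}
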