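.group_names <- c(
  "Untreated", "Px-478", "siRNA", "DC",
  "Px-478+DC", "siRNA+DC", "siRNA+Px-478", "siRNA+Px-478+DC"
)

.px_days_default <- c(6, 8, 10, 13, 15)
.s_days_default <- c(6, 9, 12, 15)
.dc_day_default <- 7

new_protocol <- function(px_days = integer(0), s_days = integer(0),
                         dc_events = data.frame(day = integer(0),
                                                count = integer(0)),
                         px_dose_scale = 1, s_dose_scale = 1,
                         name = "custom") {
  p <- structure(
    list(px_days = as.integer(px_days), s_days = as.integer(s_days),
         dc_events = dc_events, px_dose_scale = px_dose_scale,
         s_dose_scale = s_dose_scale, name = name),
    class = "tme_protocol"
  )
  validate_protocol(p)
  p
}

#' Validate a treatment protocol
#'
#' Checks dose days are within the simulation horizon, dose scales are
#' positive and DC cell counts non-negative.
#'
#' @param protocol A `"tme_protocol"` object.
#' @param horizon_days Latest allowed injection day (default 18).
#' @return `protocol`, invisibly, or an error.
#' @export
validate_protocol <- function(protocol, horizon_days = 18) {
  days <- c(protocol$px_days, protocol$s_days, protocol$dc_events$day)
  if (length(days) > 0 && (any(days < 0) || any(days > horizon_days))) {
    stop("injection days must lie in [0, ", horizon_days, "]")
  }
  if (protocol$px_dose_scale <= 0 || protocol$s_dose_scale <= 0) {
    stop("dose scales must be positive")
  }
  if (any(protocol$dc_events$count < 0)) stop("DC cell counts must be >= 0")
  invisible(protocol)
}

#' Treatment protocol of an experimental group
#'
#' Returns the vaccination schedule of one of the eight experimental groups:
#' the hypoxia inhibitor (Px-478) on days 6, 8, 10, 13 and 15; the adenosine
#' inhibitor (siRNA) on days 6, 9, 12 and 15; and the DC vaccine (`V_DC`
#' active DCs, 70 by default) on day 7 -- each included or not according to
#' the group name. Dose scales are 1 (the calibrated bolus magnitudes).
#'
#' @param name One of `"Untreated"`, `"Px-478"`, `"siRNA"`, `"DC"`,
#'   `"Px-478+DC"`, `"siRNA+DC"`, `"siRNA+Px-478"`, `"siRNA+Px-478+DC"`.
#' @param params Model parameters (supplies the DC bolus size `V_DC`).
#' @return A `"tme_protocol"` object.
#' @export
#' @examples
#' group_protocol("siRNA+Px-478+DC")
group_protocol <- function(name, params = default_parameters()) {
  if (!name %in% .group_names) {
    stop("unknown group '", name, "'; valid groups: ",
         paste(.group_names, collapse = ", "))
  }
  has_px <- name %in% c("Px-478", "Px-478+DC", "siRNA+Px-478",
                        "siRNA+Px-478+DC")
  has_s <- name %in% c("siRNA", "siRNA+DC", "siRNA+Px-478",
                       "siRNA+Px-478+DC")
  has_dc <- name %in% c("DC", "Px-478+DC", "siRNA+DC", "siRNA+Px-478+DC")
  new_protocol(
    px_days = if (has_px) .px_days_default else integer(0),
    s_days = if (has_s) .s_days_default else integer(0),
    dc_events = if (has_dc) {
      data.frame(day = .dc_day_default, count = as.integer(params$V_DC))
    } else {
      data.frame(day = integer(0), count = integer(0))
    },
    name = name
  )
}

#' Modify a treatment protocol
#'
#' Produces dose/timing variants of a base protocol; unspecified components
#' are left untouched. Supported modifications:
#' \describe{
#'   \item{dc_day}{move the (single) DC injection to this day.}
#'   \item{dc_scale}{multiply every DC injection's cell count (rounded to the
#'     nearest integer).}
#'   \item{dc_times, dc_interval}{replace the DC schedule by `dc_times`
#'     injections starting at the first DC day (day 7 if the base had none),
#'     spaced `dc_interval` days; each injection uses the (scaled) base cell
#'     count.}
#'   \item{px_every, s_every}{replace the Px-478 / siRNA schedule by
#'     every-`k`-days dosing from day 6 through day 17.}
#'   \item{px_scale, s_scale}{multiply the bolus magnitudes.}
#'   \item{alternate}{`"px"` or `"s"`: daily alternation of the two
#'     inhibitors from day 6 through day 17, starting with the named drug.}
#' }
#'
#' @param base A `"tme_protocol"` object.
#' @param dc_day,dc_scale,dc_times,dc_interval,px_every,s_every,px_scale,s_scale,alternate
#'   See Details; `NULL` leaves the component unchanged.
#' @return The modified `"tme_protocol"`.
#' @export
#' @examples
#' base <- group_protocol("siRNA+Px-478+DC")
#' variant_protocol(base, dc_day = 6)
#' variant_protocol(base, s_every = 1)
variant_protocol <- function(base, dc_day = NULL, dc_scale = NULL,
                             dc_times = NULL, dc_interval = 1,
                             px_every = NULL, s_every = NULL,
                             px_scale = NULL, s_scale = NULL,
                             alternate = NULL) {
  p <- base
  if (!is.null(dc_scale)) {
    if (dc_scale < 0) stop("'dc_scale' must be non-negative")
    p$dc_events$count <- as.integer(round(p$dc_events$count * dc_scale))
  }
  if (!is.null(dc_day)) {
    count <- if (nrow(p$dc_events) > 0) p$dc_events$count[1] else 70L
    p$dc_events <- data.frame(day = as.integer(dc_day), count = count)
  }
  if (!is.null(dc_times)) {
    start <- if (nrow(p$dc_events) > 0) p$dc_events$day[1] else 7L
    count <- if (nrow(p$dc_events) > 0) p$dc_events$count[1] else 70L
    days <- start + dc_interval * (seq_len(dc_times) - 1L)
    p$dc_events <- data.frame(day = as.integer(days),
                              count = rep(as.integer(count), dc_times))
  }
  if (!is.null(px_every)) p$px_days <- as.integer(seq(6, 17, by = px_every))
  if (!is.null(s_every)) p$s_days <- as.integer(seq(6, 17, by = s_every))
  if (!is.null(px_scale)) {
    if (px_scale <= 0) stop("'px_scale' must be positive")
    p$px_dose_scale <- base$px_dose_scale * px_scale
  }
  if (!is.null(s_scale)) {
    if (s_scale <= 0) stop("'s_scale' must be positive")
    p$s_dose_scale <- base$s_dose_scale * s_scale
  }
  if (!is.null(alternate)) {
    alternate <- match.arg(alternate, c("px", "s"))
    first <- seq(6, 17, by = 2)
    second <- seq(7, 17, by = 2)
    if (alternate == "px") {
      p$px_days <- as.integer(first); p$s_days <- as.integer(second)
    } else {
      p$s_days <- as.integer(first); p$px_days <- as.integer(second)
    }
  }
  p$name <- paste0(base$name, " (variant)")
  validate_protocol(p)
  p
}

#' Expand a protocol into per-step dose events
#'
#' Maps injection days to 0-based step indices (day `d` doses at the first
#' step of that day, step `d * steps_per_day`) and applies the dose scales to
#' the bolus magnitudes. The inverse mapping (steps back to days) is exact,
#' so the expansion is lossless.
#'
#' @param protocol A `"tme_protocol"` or `NULL` (no treatment).
#' @param params Model parameters.
#' @return A list with integer step vectors `px_steps`, `s_steps`,
#'   `dc_steps`, numeric `px_amounts`, `s_amounts` and integer `dc_counts`.
#' @export
protocol_steps <- function(protocol, params) {
  spd <- steps_per_day(params)
  if (is.null(protocol)) {
    return(list(px_steps = integer(0), px_amounts = numeric(0),
                s_steps = integer(0), s_amounts = numeric(0),
                dc_steps = integer(0), dc_counts = integer(0)))
  }
  validate_protocol(protocol)
  list(
    px_steps = as.integer(protocol$px_days * spd),
    px_amounts = rep(params$dose_px * protocol$px_dose_scale,
                     length(protocol$px_days)),
    s_steps = as.integer(protocol$s_days * spd),
    s_amounts = rep(params$dose_s * protocol$s_dose_scale,
                    length(protocol$s_days)),
    dc_steps = as.integer(protocol$dc_events$day * spd),
    dc_counts = as.integer(protocol$dc_events$count)
  )
}

#' Inject a DC vaccine bolus
#'
#' Places `count` active DCs uniformly at random on distinct empty lattice
#' sites (the vaccine is administered systemically, not locally). If fewer
#' empty sites exist than requested, all empties are filled and a warning is
#' issued.
#'
#' @param lattice A `"tme_lattice"` (or simulation state).
#' @param count Number of active DCs to place (>= 0).
#' @return The updated lattice.
#' @export
inject_dc_vaccine <- function(lattice, count) {
  count <- as.integer(count)
  if (count < 0) stop("'count' must be >= 0")
  if (count == 0L) return(lattice)
  emp <- which(lattice$kind == 0L)
  if (length(emp) < count) {
    warning("only ", length(emp), " empty sites available for ", count,
            " injected DCs; filling all empties")
    count <- length(emp)
  }
  pick <- if (length(emp) == 1L) emp else sample(emp, count)
  lattice$kind[pick] <- 3L
  lattice$dir[pick] <- -1L
  lattice$steps[pick] <- 0L
  lattice
}

#' Read a treatment protocol from a file
#'
#' Reads a flat YAML protocol description with keys `px_days`, `s_days`,
#' `dc_days`, `dc_counts`, `px_dose_scale`, `s_dose_scale` and `name` (all
#' optional; omitted components are empty/unit). Unknown keys are rejected.
#'
#' @param path Path to a YAML file.
#' @return A `"tme_protocol"` object.
#' @seealso [write_protocol()], [group_protocol()]
#' @export
read_protocol <- function(path) {
  keep <- function(x) x
  vals <- yaml::read_yaml(path, handlers = list("bool#yes" = keep,
                                                "bool#no" = keep))
  allowed <- c("px_days", "s_days", "dc_days", "dc_counts",
               "px_dose_scale", "s_dose_scale", "name")
  unknown <- setdiff(names(vals), allowed)
  if (length(unknown) > 0) {
    stop("unknown protocol key(s) in '", path, "': ",
         paste(unknown, collapse = ", "))
  }
  dc_days <- as.integer(vals$dc_days %||% integer(0))
  dc_counts <- as.integer(vals$dc_counts %||% rep(70L, length(dc_days)))
  if (length(dc_counts) != length(dc_days)) {
    stop("'dc_days' and 'dc_counts' must have equal length")
  }
  new_protocol(
    px_days = vals$px_days %||% integer(0),
    s_days = vals$s_days %||% integer(0),
    dc_events = data.frame(day = dc_days, count = dc_counts),
    px_dose_scale = vals$px_dose_scale %||% 1,
    s_dose_scale = vals$s_dose_scale %||% 1,
    name = vals$name %||% "custom"
  )
}

#' Write a treatment protocol to a file
#'
#' @param protocol A `"tme_protocol"` object.
#' @param path Output YAML path.
#' @return `path`, invisibly.
#' @export
write_protocol <- function(protocol, path) {
  validate_protocol(protocol)
  yaml::write_yaml(list(
    name = protocol$name,
    px_days = protocol$px_days,
    s_days = protocol$s_days,
    dc_days = protocol$dc_events$day,
    dc_counts = protocol$dc_events$count,
    px_dose_scale = protocol$px_dose_scale,
    s_dose_scale = protocol$s_dose_scale
  ), path, precision = 17)
  invisible(path)
}

#' @export
print.tme_protocol <- function(x, ...) {
  cat("Treatment protocol:", x$name, "\n")
  cat("  Px-478 days: ", if (length(x$px_days)) paste(x$px_days, collapse = ", ")
      else "none", " (dose scale ", x$px_dose_scale, ")\n", sep = "")
  cat("  siRNA days:  ", if (length(x$s_days)) paste(x$s_days, collapse = ", ")
      else "none", " (dose scale ", x$s_dose_scale, ")\n", sep = "")
  if (nrow(x$dc_events) > 0) {
    cat("  DC events:   ", paste(sprintf("day %d (%d cells)", x$dc_events$day,
                                         x$dc_events$count), collapse = ", "),
        "\n", sep = "")
  } else cat("  DC events:   none\n")
  invisible(x)
}
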