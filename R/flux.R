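#' Core incubation geometry
#'
#' Geometry of a sealed sediment core incubation: inner diameter of the
#' core tube, volume of overlying water, and the volume withdrawn at each
#' sampling point (the lid is depressed as samples are drawn, so by
#' default the effective volume is taken as constant).
#'
#' @param inner_diameter core inner diameter in metres (default 0.10).
#' @param water_volume overlying-water volume in litres (default 3.8).
#' @param sample_withdrawal litres removed per sampling point (default 0).
#' @return An object of class \code{core_geometry}.
#' @export
core_geometry <- function(inner_diameter = 0.10, water_volume = 3.8,
                          sample_withdrawal = 0) {
  if (inner_diameter <= 0 || water_volume <= 0 || sample_withdrawal < 0) {
    stop("core geometry requires positive diameter and volume and non-negative withdrawal")
  }
  structure(list(inner_diameter = inner_diameter,
                 water_volume = water_volume,
                 sample_withdrawal = sample_withdrawal,
                 area = pi * (inner_diameter / 2)^2),
            class = "core_geometry")
}

#' @export
print.core_geometry <- function(x, ...) {
  cat(sprintf("Core geometry: ID %.3f m (area %.5f m^2), %.2f L overlying water, %.3f L withdrawn per sample\n",
              x$inner_diameter, x$area, x$water_volume, x$sample_withdrawal))
  invisible(x)
}

#' Convert an overlying-water concentration to an areal pool
#'
#' pool (mmol m^-2) = concentration (umol L^-1) x effective volume (L) /
#' 1000 / core area (m^2). When samples are withdrawn without
#' replacement, the effective volume at the i-th sampling point is the
#' initial volume minus the i - 1 prior withdrawals.
#'
#' @param conc_uM concentration in micromolar.
#' @param geometry a [core_geometry()].
#' @param timepoint_index 1-based sampling index (used only when
#'   \code{sample_withdrawal > 0}).
#' @return Areal pool in mmol m^-2.
#' @examples
#' areal_pool(1, core_geometry())  # 0.48383 mmol m^-2
#' @export
areal_pool <- function(conc_uM, geometry = core_geometry(),
                       timepoint_index = 1L) {
  stopifnot(inherits(geometry, "core_geometry"), all(conc_uM >= 0),
            all(timepoint_index >= 1))
  vol <- geometry$water_volume -
    geometry$sample_withdrawal * (timepoint_index - 1)
  if (any(vol <= 0)) stop("effective volume exhausted by withdrawals")
  conc_uM * vol / 1000 / geometry$area
}

#' Per-core linear flux from a solute time series
#'
#' Ordinary least-squares slope of the areal pool against time in days.
#' The sign convention is production positive, consumption negative;
#' [consumption_rate()] negates the slope for solutes reported as
#' consumed (e.g. oxygen).
#'
#' @param time_h sampling times in hours (strictly increasing, >= 3).
#' @param conc_uM concentrations in micromolar, same length.
#' @param geometry a [core_geometry()].
#' @return A list with \code{slope} and \code{intercept} (mmol m^-2 d^-1
#'   and mmol m^-2), \code{se} (slope standard error), and \code{n}.
#' @export
linear_rate <- function(time_h, conc_uM, geometry = core_geometry()) {
  stopifnot(length(time_h) == length(conc_uM))
  if (length(time_h) < 3) {
    stop("at least 3 timepoints are required to estimate a rate")
  }
  if (any(diff(time_h) <= 0)) stop("times must be strictly increasing")
  pool <- areal_pool(conc_uM, geometry, seq_along(time_h))
  t_d <- time_h / 24
  fit <- stats::lm(pool ~ t_d)
  # noiseless series are legitimate inputs; silence the perfect-fit note
  sm <- suppressWarnings(summary(fit))$coefficients
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       se = unname(sm[2, 2]),
       n = length(time_h))
}

#' @rdname linear_rate
#' @export
consumption_rate <- function(time_h, conc_uM, geometry = core_geometry()) {
  r <- linear_rate(time_h, conc_uM, geometry)
  r$slope <- -r$slope
  r$intercept <- NULL
  r
}

#' Per-core slopes for every core x solute in a water-chemistry table
#'
#' @param water a water-chemistry data frame with columns \code{core_id},
#'   \code{solute}, \code{time_h}, \code{conc_uM} (see
#'   [read_water_chemistry()]).
#' @param geometry a [core_geometry()].
#' @return Data frame with one row per core x solute: \code{core_id},
#'   \code{solute}, \code{slope}, \code{se}.
#' @export
per_core_rates <- function(water, geometry = core_geometry()) {
  stopifnot(all(c("core_id", "solute", "time_h", "conc_uM") %in% names(water)))
  pieces <- split(water, list(water$core_id, water$solute), drop = TRUE)
  out <- lapply(pieces, function(d) {
    d <- d[order(d$time_h), ]
    r <- linear_rate(d$time_h, d$conc_uM, geometry)
    data.frame(core_id = d$core_id[1], solute = d$solute[1],
               slope = r$slope, se = r$se, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out[order(out$solute, out$core_id), ]
}

#' Treatment-level mean and standard error of per-core rates
#'
#' Across-replicate summaries: mean and SE = sd / sqrt(n) over the
#' replicate cores of each treatment. A treatment with a single core gets
#' \code{NA} for the SE.
#'
#' @param rates data frame with columns \code{core_id} and \code{slope}
#'   (e.g. one solute's rows from [per_core_rates()]).
#' @param design design table with columns \code{core_id},
#'   \code{treatment}.
#' @return Data frame with \code{treatment}, \code{mean}, \code{se},
#'   \code{n}.
#' @export
summarize_rates <- function(rates, design) {
  stopifnot(all(c("core_id", "slope") %in% names(rates)),
            all(c("core_id", "treatment") %in% names(design)))
  m <- merge(rates, design[, c("core_id", "treatment")], by = "core_id")
  if (nrow(m) < nrow(rates)) {
    stop("some cores in the rate table are missing from the design")
  }
  grp <- split(m$slope, m$treatment)
  if (any(lengths(grp) == 0)) stop("empty treatment group")
  out <- data.frame(
    treatment = names(grp),
    mean = unname(vapply(grp, mean, numeric(1))),
    se = unname(vapply(grp, function(x) {
      if (length(x) < 2) NA_real_ else stats::sd(x) / sqrt(length(x))
    }, numeric(1))),
    n = unname(lengths(grp)),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out
}
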