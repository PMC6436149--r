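# Conductance-based quantities: centrifuge (Cavitron) PLC series, specific
# conductivity of branch segments, native embolism, root-system conductance.

#' Build a PLC series from a centrifuge conductance series
#'
#' Percentage loss of conductivity relative to the first (maximum)
#' measurement: `PLC_i = 100 * (1 - k_i / k_1)`. The first measurement
#' (typically at -0.25 MPa) defines the 100%-conductivity reference even
#' if native embolism exists; native embolism is a separate diagnostic
#' ([native_plc()]).
#'
#' @param pressure Target xylem pressures, MPa (<= 0), ordered from least
#'   to most negative.
#' @param k Hydraulic conductances (>= 0), same length; `k[1]` must be > 0.
#' @return A data.frame `pressure_mpa`, `percent` suitable for
#'   [fit_sigmoid()]. Conductances exceeding the reference give negative
#'   PLC, which is retained but flagged with a message.
#' @examples
#' cavitron_plc_series(c(-0.25, -1, -3, -6), c(4, 4, 2, 0))
#' @export
cavitron_plc_series <- function(pressure, k) {
  check_numeric(pressure, "pressure", nonpos = TRUE)
  check_numeric(k, "k", nonneg = TRUE)
  if (length(pressure) != length(k)) {
    stop("`pressure` and `k` must have equal length", call. = FALSE)
  }
  if (is.unsorted(rev(pressure), strictly = FALSE)) {
    stop("`pressure` must be ordered from least to most negative", call. = FALSE)
  }
  if (k[1L] == 0) {
    stop("first (reference) conductance is zero; PLC undefined", call. = FALSE)
  }
  plc <- 100 * (1 - k / k[1L])
  if (any(plc < 0)) {
    message(sum(plc < 0), " measurement(s) exceed the reference conductance ",
            "(negative PLC retained)")
  }
  data.frame(pressure_mpa = pressure, percent = plc)
}

#' Specific hydraulic conductivity of a stem segment
#'
#' `k_s = k * length / xylem_area`. With the default input unit
#' kg s^-1 MPa^-1 and water density 1 g cm^-3, conductance is converted to
#' cm^3 s^-1 MPa^-1 (x 1000) so that `k_s` comes out in cm^2 s^-1 MPa^-1.
#'
#' @param k Hydraulic conductance (>= 0).
#' @param length_cm Sample length, cm (> 0).
#' @param xylem_area_cm2 Xylem cross-sectional area, cm^2 (> 0).
#' @param input_unit `"kg_s_mpa"` (default; converted via water density
#'   1 g cm^-3) or `"cm3_s_mpa"` (used as is).
#' @return Specific conductivity, cm^2 s^-1 MPa^-1.
#' @examples
#' specific_conductivity(1e-4, length_cm = 8, xylem_area_cm2 = 0.1)  # 8.0
#' @export
specific_conductivity <- function(k, length_cm, xylem_area_cm2,
                                  input_unit = c("kg_s_mpa", "cm3_s_mpa")) {
  input_unit <- match.arg(input_unit)
  check_numeric(k, "k", nonneg = TRUE)
  check_numeric(length_cm, "length_cm", positive = TRUE)
  check_numeric(xylem_area_cm2, "xylem_area_cm2", positive = TRUE)
  k_vol <- if (input_unit == "kg_s_mpa") k * 1000 else k  # kg -> cm^3 of water
  k_vol * length_cm / xylem_area_cm2
}

#' Native (or preparation-artefact) embolism from pre/post-flush conductance
#'
#' `100 * (1 - k_initial / k_flushed)`, floored at 0 with a warning when
#' the flushed conductance is lower than the initial one (measurement
#' noise, not negative embolism).
#'
#' @param k_initial Conductance before flushing (>= 0).
#' @param k_flushed Conductance after high-pressure flushing (> 0).
#' @return Native PLC, percent in \[0, 100\].
#' @export
native_plc <- function(k_initial, k_flushed) {
  check_numeric(k_initial, "k_initial", nonneg = TRUE)
  check_numeric(k_flushed, "k_flushed", nonneg = TRUE)
  if (any(k_flushed == 0)) {
    stop("flushed conductance is zero; native PLC undefined", call. = FALSE)
  }
  plc <- 100 * (1 - k_initial / k_flushed)
  if (any(plc < 0)) {
    warning("initial conductance exceeds flushed conductance; native PLC ",
            "floored at 0", call. = FALSE)
    plc <- pmax(plc, 0)
  }
  plc
}

#' Aggregate transient root-conductance measurements
#'
#' Mean and standard error of the 3-5 transient conductance readings taken
#' on one root system.
#'
#' @param transients Numeric vector of conductances (kg s^-1 MPa^-1,
#'   >= 0). Fewer than 3 or more than 5 values trigger a warning (the
#'   standard protocol takes 3-5) but are still aggregated.
#' @return List with `mean`, `se`, `n`.
#' @examples
#' root_conductance(c(4e-6, 5e-6, 6e-6))
#' @export
root_conductance <- function(transients) {
  check_numeric(transients, "transients", nonneg = TRUE)
  n <- length(transients)
  if (n < 3L || n > 5L) {
    warning("expected 3-5 transient measurements, got ", n, call. = FALSE)
  }
  list(mean = mean(transients), se = if (n >= 2L) se_of(transients) else 0,
       n = n)
}
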