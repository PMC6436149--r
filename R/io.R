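# CSV readers/writers with itemized validation. Dialect: comma-separated,
# UTF-8, dot decimal, mandatory header row. Pressures must be negative MPa
# at parse time (auto_negate flips sign-inverted input).

read_csv_checked <- function(path, required, numeric_cols, optional = character(0)) {
  if (!file.exists(path)) stop("input file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, encoding = "UTF-8")
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop("file ", path, ": missing required column(s) ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  for (col in intersect(c(required, optional), numeric_cols)) {
    if (!col %in% names(df)) next
    v <- df[[col]]
    if (!is.numeric(v)) {
      bad <- which(is.na(suppressWarnings(as.numeric(v))) & !is.na(v))
      stop("file ", path, ", column ", col, ": non-numeric value at row ",
           if (length(bad)) bad[1L] else "?", call. = FALSE)
    }
    if (any(!is.finite(v))) {
      stop("file ", path, ", column ", col, ": non-finite value at row ",
           which(!is.finite(v))[1L], call. = FALSE)
    }
  }
  df
}

check_pressure_col <- function(df, col, path, auto_negate = FALSE) {
  if (auto_negate) df[[col]] <- -abs(df[[col]])
  bad <- which(df[[col]] > 0)
  if (length(bad)) {
    stop("file ", path, ", column ", col, ", row ", bad[1L],
         ": positive pressure; pressures are negative MPa ",
         "(set auto_negate = TRUE to flip sign-inverted data)", call. = FALSE)
  }
  df
}

#' Read a (pressure, percent) response series CSV
#'
#' Columns `pressure_mpa`, `percent`, optional `series_id` (long format,
#' several series per file).
#'
#' @param path CSV file path.
#' @param auto_negate Negate positive pressures instead of erroring.
#' @return data.frame with validated columns.
#' @export
read_response_csv <- function(path, auto_negate = FALSE) {
  df <- read_csv_checked(path, c("pressure_mpa", "percent"),
                         c("pressure_mpa", "percent"))
  check_pressure_col(df, "pressure_mpa", path, auto_negate)
}

#' Read a pressure-volume leaf CSV
#'
#' Either raw masses (`tw_g`, `fw_g`, `dw_g`, `psi_mpa`; WSD computed via
#' [compute_wsd()]) or precomputed (`wsd`, `psi_mpa`). Optional `leaf_id`.
#'
#' @inheritParams read_response_csv
#' @return data.frame with columns `wsd`, `psi_mpa` (plus `leaf_id` when
#'   present).
#' @export
read_pv_csv <- function(path, auto_negate = FALSE) {
  if (!file.exists(path)) stop("input file not found: ", path, call. = FALSE)
  peek <- names(utils::read.csv(path, nrows = 1L))
  if (all(c("tw_g", "fw_g", "dw_g", "psi_mpa") %in% peek)) {
    df <- read_csv_checked(path, c("tw_g", "fw_g", "dw_g", "psi_mpa"),
                           c("tw_g", "fw_g", "dw_g", "psi_mpa"))
    df <- check_pressure_col(df, "psi_mpa", path, auto_negate)
    df$wsd <- compute_wsd(df$tw_g, df$fw_g, df$dw_g)
  } else {
    df <- read_csv_checked(path, c("wsd", "psi_mpa"), c("wsd", "psi_mpa"))
    df <- check_pressure_col(df, "psi_mpa", path, auto_negate)
  }
  df
}

#' Read a conductance series CSV (`pressure_mpa`, `k`)
#' @inheritParams read_response_csv
#' @return data.frame with validated columns.
#' @export
read_flow_csv <- function(path, auto_negate = FALSE) {
  df <- read_csv_checked(path, c("pressure_mpa", "k"), c("pressure_mpa", "k"))
  check_pressure_col(df, "pressure_mpa", path, auto_negate)
}

#' Read a conduit CSV (`sample_id` plus `diameter_um` or `lumen_area_um2`)
#'
#' Lumen areas are converted to circular-equivalent diameters.
#'
#' @param path CSV file path.
#' @return data.frame `sample_id`, `diameter_um`.
#' @export
read_conduit_csv <- function(path) {
  if (!file.exists(path)) stop("input file not found: ", path, call. = FALSE)
  peek <- names(utils::read.csv(path, nrows = 1L))
  if ("diameter_um" %in% peek) {
    df <- read_csv_checked(path, c("sample_id", "diameter_um"), "diameter_um")
  } else {
    df <- read_csv_checked(path, c("sample_id", "lumen_area_um2"),
                           "lumen_area_um2")
    df$diameter_um <- diameter_from_area(df$lumen_area_um2)
  }
  df[, c("sample_id", "diameter_um")]
}

#' Read a wall-pair CSV (`sample_id`, `t_um`, `b_um`)
#' @param path CSV file path.
#' @return data.frame with validated columns.
#' @export
read_wall_csv <- function(path) {
  read_csv_checked(path, c("sample_id", "t_um", "b_um"), c("t_um", "b_um"))
}

#' Read a gas-exchange course CSV (`tree_id`, `time`, `gs_mmol`, `psi_mpa`)
#' @inheritParams read_response_csv
#' @return data.frame with validated columns.
#' @export
read_gas_exchange_csv <- function(path, auto_negate = FALSE) {
  df <- read_csv_checked(path, c("tree_id", "time", "gs_mmol", "psi_mpa"),
                         c("gs_mmol", "psi_mpa"))
  check_pressure_col(df, "psi_mpa", path, auto_negate)
}

#' Write a data.frame as the package's CSV dialect
#' @param df data.frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_traits_csv <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}
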