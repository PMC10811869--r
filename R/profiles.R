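# Required columns of the long profile format, in canonical order.
profile_columns <- function() {
  c("experiment", "treatment", "block", "plot", "time",
    "depth_top_cm", "depth_bottom_cm", "bd_g_cm3", "c_g_kg")
}

#' Validate a long table of layered soil measurements
#'
#' A profile set is a long data frame with one row per plot x sampling time x
#' depth increment, carrying bulk density (g cm-3) and organic-carbon
#' concentration (g C kg-1). Validation enforces the profile invariants:
#' increments are contiguous half-open intervals \code{[top, bottom)} starting
#' at 0 cm, bulk density is positive, concentration non-negative, and no
#' (plot, time, increment) row is duplicated.
#'
#' @param df data frame with columns \code{experiment, treatment, block, plot,
#'   time, depth_top_cm, depth_bottom_cm, bd_g_cm3, c_g_kg}.
#' @param time_map optional named character vector mapping the values found in
#'   the \code{time} column to the canonical labels \code{"t0"} and
#'   \code{"t1"}, e.g. \code{c("1993" = "t0", "2012" = "t1")}.
#' @return the validated data frame, sorted by plot, time and depth, with
#'   class \code{profile_set}.
#' @export
as_profile_set <- function(df, time_map = NULL) {
  df <- as.data.frame(df)
  missing_cols <- setdiff(profile_columns(), names(df))
  if (length(missing_cols) > 0) {
    stop("profile table is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  df <- df[, profile_columns()]
  for (col in c("depth_top_cm", "depth_bottom_cm", "bd_g_cm3", "c_g_kg")) {
    v <- df[[col]]
    if (!is.numeric(v)) {
      v <- suppressWarnings(as.numeric(as.character(v)))
      if (anyNA(v)) stop("column '", col, "' is not numeric", call. = FALSE)
      df[[col]] <- v
    }
    if (anyNA(df[[col]])) {
      stop("column '", col, "' contains missing values", call. = FALSE)
    }
  }
  for (col in c("experiment", "treatment", "block", "plot", "time")) {
    df[[col]] <- as.character(df[[col]])
  }
  if (!is.null(time_map)) {
    unknown <- setdiff(unique(df$time), names(time_map))
    if (length(unknown) > 0) {
      stop("time label(s) not covered by time_map: ",
           paste(unknown, collapse = ", "), call. = FALSE)
    }
    df$time <- unname(time_map[df$time])
  }
  if (any(df$bd_g_cm3 <= 0)) {
    stop("bulk density must be > 0 g cm-3", call. = FALSE)
  }
  if (any(df$c_g_kg < 0)) {
    stop("carbon concentration must be >= 0 g C kg-1", call. = FALSE)
  }
  if (any(df$depth_top_cm < 0) || any(df$depth_bottom_cm <= df$depth_top_cm)) {
    stop("depth increments must satisfy 0 <= top < bottom", call. = FALSE)
  }
  key <- interaction(df$experiment, df$treatment, df$plot, df$time, drop = TRUE)
  df <- df[order(key, df$depth_top_cm), , drop = FALSE]
  rownames(df) <- NULL
  key <- interaction(df$experiment, df$treatment, df$plot, df$time, drop = TRUE)
  for (k in levels(key)) {
    sub <- df[key == k, , drop = FALSE]
    if (anyDuplicated(sub$depth_top_cm)) {
      stop("duplicate depth increment for plot ", sub$plot[1], " at time ",
           sub$time[1], call. = FALSE)
    }
    if (sub$depth_top_cm[1] != 0) {
      stop("profile for plot ", sub$plot[1], " at time ", sub$time[1],
           " does not start at 0 cm", call. = FALSE)
    }
    n <- nrow(sub)
    if (n > 1) {
      gaps <- which(sub$depth_bottom_cm[-n] != sub$depth_top_cm[-1])
      if (length(gaps) > 0) {
        i <- gaps[1]
        stop("non-contiguous increments for plot ", sub$plot[1], " at time ",
             sub$time[1], ": gap/overlap between ", sub$depth_bottom_cm[i],
             " and ", sub$depth_top_cm[i + 1], " cm", call. = FALSE)
      }
    }
  }
  class(df) <- c("profile_set", "data.frame")
  df
}

#' Read a profile set from a CSV file
#'
#' @param path path to a comma-delimited file with the columns documented in
#'   [as_profile_set()].
#' @inheritParams as_profile_set
#' @return a validated \code{profile_set}.
#' @export
read_profiles <- function(path, time_map = NULL) {
  df <- data.table::fread(path, data.table = FALSE)
  as_profile_set(df, time_map = time_map)
}

# Split a profile set into per-(experiment, treatment, block, plot, time)
# profiles, each sorted by depth.
split_profiles <- function(profiles) {
  key <- interaction(profiles$experiment, profiles$treatment, profiles$plot,
                     profiles$time, drop = TRUE, sep = "\r")
  split(as.data.frame(profiles), key)
}

#' Remap layer values onto a new set of depth increments
#'
#' Intensive layer quantities (bulk density, carbon concentration) measured on
#' one contiguous increment grid are transferred to another by overlap-weighted
#' averaging: each target value is the thickness-weighted mean of the source
#' values over the overlapping centimetres. This generalises the two-adjacent-
#' increment weighted average used when a baseline campaign's sampling depths
#' must be harmonised with a later campaign's grid. Stocks (extensive) are
#' never remapped directly; recompute them from remapped intensive fields.
#'
#' @param profile data frame for a single plot/time with columns
#'   \code{depth_top_cm}, \code{depth_bottom_cm} and the fields to remap.
#' @param targets data frame with columns \code{depth_top_cm},
#'   \code{depth_bottom_cm}; must be contiguous and lie within the span of the
#'   source increments.
#' @param fields character vector of column names to remap
#'   (default bulk density and concentration, intersected with what exists).
#' @return a data frame on the target grid; any identifier columns of
#'   \code{profile} are carried over.
#' @export
remap_increments <- function(profile, targets,
                             fields = c("bd_g_cm3", "c_g_kg")) {
  profile <- as.data.frame(profile)
  targets <- as.data.frame(targets)
  fields <- intersect(fields, names(profile))
  if (length(fields) == 0) stop("no remappable fields present", call. = FALSE)
  profile <- profile[order(profile$depth_top_cm), , drop = FALSE]
  targets <- targets[order(targets$depth_top_cm), , drop = FALSE]
  stop_bad <- function(msg) stop(msg, call. = FALSE)
  n <- nrow(profile)
  if (n > 1 && any(profile$depth_bottom_cm[-n] != profile$depth_top_cm[-1])) {
    stop_bad("source increments are not contiguous")
  }
  m <- nrow(targets)
  if (m > 1 && any(targets$depth_bottom_cm[-m] != targets$depth_top_cm[-1])) {
    stop_bad("target increments are not contiguous")
  }
  if (min(targets$depth_top_cm) < min(profile$depth_top_cm)) {
    stop_bad("target grid starts above the shallowest source increment")
  }
  if (max(targets$depth_bottom_cm) > max(profile$depth_bottom_cm)) {
    stop_bad(sprintf(
      "target grid extends to %g cm but source increments stop at %g cm",
      max(targets$depth_bottom_cm), max(profile$depth_bottom_cm)))
  }
  out <- targets[, c("depth_top_cm", "depth_bottom_cm"), drop = FALSE]
  id_cols <- setdiff(names(profile),
                     c("depth_top_cm", "depth_bottom_cm", fields))
  for (col in id_cols) {
    if (length(unique(profile[[col]])) == 1) out[[col]] <- profile[[col]][1]
  }
  for (f in fields) {
    vals <- numeric(m)
    for (j in seq_len(m)) {
      ov <- pmax(0, pmin(profile$depth_bottom_cm, out$depth_bottom_cm[j]) -
                    pmax(profile$depth_top_cm, out$depth_top_cm[j]))
      vals[j] <- sum(ov * profile[[f]]) / sum(ov)
    }
    out[[f]] <- vals
  }
  ord <- c("depth_top_cm", "depth_bottom_cm")
  out[, c(setdiff(names(out), c(ord, fields)), ord, fields), drop = FALSE]
}

#' Write a result table to CSV
#'
#' Comma-delimited, UTF-8, "." decimal separator, header row, stable column
#' order, and floats written with enough digits to round-trip exactly.
#'
#' @param rows non-empty data frame.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
write_table <- function(rows, path) {
  rows <- as.data.frame(rows)
  if (nrow(rows) == 0) stop("refusing to write an empty table", call. = FALSE)
  for (col in names(rows)) {
    if (is.double(rows[[col]])) {
      # 17 significant digits round-trip any double exactly
      rows[[col]] <- sprintf("%.17g", rows[[col]])
    }
  }
  data.table::fwrite(rows, path)
  invisible(path)
}

#' Read back a table written by [write_table()]
#'
#' @param path file path.
#' @return a data frame.
#' @export
read_table <- function(path) {
  data.table::fread(path, data.table = FALSE)
}
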