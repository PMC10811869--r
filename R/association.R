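#' SOC stock carried by bulk-density-driven soil-mass change
#'
#' For one plot, the stock lost or gained in the top of the profile through
#' bulk-density change alone: the soil mass difference implied by the change
#' in bulk density from t0 to t1 in each increment down to \code{depth_limit},
#' valued at the t1 carbon concentration. In Mg C ha-1:
#' \code{sum over layers of (rho_t1 - rho_t0) * d * 100 * c_t1 / 1000}.
#'
#' @param t0_layers,t1_layers data frames for the same plot at the two times,
#'   with columns \code{depth_top_cm, depth_bottom_cm, bd_g_cm3, c_g_kg} on
#'   matching increments covering 0 to \code{depth_limit} cm.
#' @param depth_limit depth to accumulate to (default 30 cm; a layer counts
#'   when its bottom is at or above the limit).
#' @return Mg C ha-1 (negative when bulk density declined).
#' @export
bd_stock_delta <- function(t0_layers, t1_layers, depth_limit = 30) {
  t0_layers <- t0_layers[order(t0_layers$depth_top_cm), , drop = FALSE]
  t1_layers <- t1_layers[order(t1_layers$depth_top_cm), , drop = FALSE]
  keep0 <- t0_layers$depth_bottom_cm <= depth_limit
  keep1 <- t1_layers$depth_bottom_cm <= depth_limit
  a <- t0_layers[keep0, , drop = FALSE]
  b <- t1_layers[keep1, , drop = FALSE]
  if (nrow(a) == 0 || nrow(a) != nrow(b) ||
      any(a$depth_top_cm != b$depth_top_cm) ||
      any(a$depth_bottom_cm != b$depth_bottom_cm) ||
      max(a$depth_bottom_cm) != depth_limit) {
    stop("profiles must share increments covering 0-", depth_limit, " cm",
         call. = FALSE)
  }
  d <- a$depth_bottom_cm - a$depth_top_cm
  sum((b$bd_g_cm3 - a$bd_g_cm3) * d * 100 * b$c_g_kg / 1000)
}

#' Per-plot association records: BD-driven stock delta vs FD-ESM gap
#'
#' Builds, for every plot present at both times, the pair of quantities whose
#' correlation measures how much of the fixed-depth error is explained by
#' bulk-density change: the BD-driven stock delta ([bd_stock_delta()]) and the
#' gap between the t1 FD and t1 ESM stocks accumulated over the same surface
#' layers. With the default orientation (\code{FD - ESM}) both quantities are
#' negative under surface loosening and positive under compaction.
#'
#' @inheritParams reference_masses
#' @param stocks a stock table from [stocks_pipeline()]; computed on the fly
#'   when \code{NULL}.
#' @param depth_limit surface depth to accumulate over (default 30 cm).
#' @param esm_method ESM engine used for the gap (default spline).
#' @param orientation \code{"fd_minus_esm"} (default) or \code{"esm_minus_fd"}.
#' @param extrapolate passed to [stocks_pipeline()] when stocks are computed
#'   here.
#' @param t1_label label of the later sampling time.
#' @return data frame with columns \code{treatment, plot,
#'   bd_stock_delta_MgC_ha, fd_esm_gap_MgC_ha}.
#' @export
association_records <- function(profiles, stocks = NULL, depth_limit = 30,
                                esm_method = "ESM_spline",
                                orientation = c("fd_minus_esm",
                                                "esm_minus_fd"),
                                extrapolate = FALSE,
                                t0_label = "t0", t1_label = "t1") {
  orientation <- match.arg(orientation)
  if (is.null(stocks)) {
    stocks <- stocks_pipeline(profiles, methods = c("FD", esm_method),
                              extrapolate = extrapolate, t0_label = t0_label)
  }
  df <- as.data.frame(profiles)
  s1 <- stocks[stocks$time == t1_label &
                 stocks$layer_bottom_cm <= depth_limit, , drop = FALSE]
  plots <- unique(df[, c("treatment", "plot")])
  recs <- lapply(seq_len(nrow(plots)), function(i) {
    tr <- plots$treatment[i]; pl <- plots$plot[i]
    p0 <- df[df$treatment == tr & df$plot == pl & df$time == t0_label, ]
    p1 <- df[df$treatment == tr & df$plot == pl & df$time == t1_label, ]
    if (nrow(p0) == 0 || nrow(p1) == 0) return(NULL)
    delta <- bd_stock_delta(p0, p1, depth_limit = depth_limit)
    fd <- sum(s1$stock_MgC_ha[s1$plot == pl & s1$treatment == tr &
                                s1$method == "FD"])
    esm <- sum(s1$stock_MgC_ha[s1$plot == pl & s1$treatment == tr &
                                 s1$method == esm_method])
    gap <- if (orientation == "fd_minus_esm") fd - esm else esm - fd
    data.frame(treatment = tr, plot = pl,
               bd_stock_delta_MgC_ha = delta, fd_esm_gap_MgC_ha = gap)
  })
  out <- do.call(rbind, recs)
  rownames(out) <- NULL
  out
}

#' Pearson correlation of the association records
#'
#' @param records data frame from [association_records()].
#' @return Pearson r between the BD-driven stock delta and the FD-ESM gap.
#' @export
association_r <- function(records) {
  if (nrow(records) < 3) stop("need >= 3 records", call. = FALSE)
  x <- records$bd_stock_delta_MgC_ha
  y <- records$fd_esm_gap_MgC_ha
  if (stats::var(x) == 0 || stats::var(y) == 0) {
    stop("correlation undefined: a variable has zero variance", call. = FALSE)
  }
  stats::cor(x, y)
}
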