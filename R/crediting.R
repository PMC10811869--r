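#' Convert a carbon stock to CO2 equivalents
#'
#' 1 Mg C corresponds to 44/12 t CO2e (molecular over atomic mass).
#'
#' @param mgc_ha Mg C ha-1.
#' @return t CO2e ha-1.
#' @export
mgc_to_tco2e <- function(mgc_ha) {
  mgc_ha * 44 / 12
}

#' Lower confidence limit on the difference between means
#'
#' The empirical-sampling crediting rule: the lower bound of the two-sided
#' \code{conf} confidence interval on \code{mean(t1) - mean(t0)} under Welch
#' assumptions. At the default \code{conf = 0.50} this is the one-sided 75%
#' lower bound, so issuing credits on it prevents over-crediting 75 percent
#' of the time.
#'
#' @param x0 replicate stocks at the initial sampling, Mg C ha-1.
#' @param x1 replicate stocks at the later sampling, Mg C ha-1.
#' @param conf two-sided confidence level (default 0.50).
#' @return LCL in Mg C ha-1.
#' @export
lcl_difference_between_means <- function(x0, x1, conf = 0.50) {
  if (length(x0) < 2 || length(x1) < 2) {
    stop("each sampling time needs >= 2 replicates", call. = FALSE)
  }
  w <- welch_components(x0, x1)
  if (w$se == 0) stop("degenerate: zero variance in both groups", call. = FALSE)
  w$diff - stats::qt(1 - (1 - conf) / 2, w$df) * w$se
}

#' Lower confidence limit on a mean of paired differences
#'
#' Alternative crediting rule: the lower bound of the two-sided \code{conf}
#' confidence interval on the mean of per-plot differences (one-sample t).
#'
#' @param diffs per-plot stock differences (t1 - t0), Mg C ha-1.
#' @param conf two-sided confidence level (default 0.90).
#' @return LCL in Mg C ha-1 (equal to the mean when all differences agree).
#' @export
lcl_mean_difference <- function(diffs, conf = 0.90) {
  n <- length(diffs)
  if (n < 2) stop("need >= 2 paired differences", call. = FALSE)
  s <- stats::sd(diffs)
  if (s == 0) return(mean(diffs))
  mean(diffs) - stats::qt(1 - (1 - conf) / 2, n - 1) * s / sqrt(n)
}

#' Whole credits issued for a field
#'
#' One credit is one t CO2e. Credits are the per-hectare LCL scaled to the
#' field area, truncated to a whole number, never negative.
#'
#' @param lcl_tco2e_ha lower confidence limit, t CO2e ha-1.
#' @param area_ha field area, ha (> 0).
#' @return integer number of credits, >= 0.
#' @export
issue_credits <- function(lcl_tco2e_ha, area_ha) {
  if (any(area_ha <= 0)) stop("area must be > 0 ha", call. = FALSE)
  as.integer(pmax(0, floor(lcl_tco2e_ha * area_ha)))
}

#' Bulk-density equivalence check per treatment and layer
#'
#' Flags treatment x layer combinations whose mean bulk density moved by more
#' than \code{threshold} (default 5 percent) between the two sampling times;
#' fixed-depth stocks for flagged combinations need an equivalent-mass
#' correction before crediting.
#'
#' @inheritParams reference_masses
#' @param threshold relative change that triggers the flag (default 0.05).
#' @param t1_label label of the later sampling time.
#' @return data frame with columns \code{treatment, layer_top_cm,
#'   layer_bottom_cm, mean_bd_t0, mean_bd_t1, rel_change, flagged}.
#' @export
bd_equivalence_check <- function(profiles, threshold = 0.05,
                                 t0_label = "t0", t1_label = "t1") {
  df <- as.data.frame(profiles)
  grp <- split(df, list(df$treatment, df$depth_top_cm), drop = TRUE)
  out <- do.call(rbind, lapply(grp, function(sub) {
    b0 <- mean(sub$bd_g_cm3[sub$time == t0_label])
    b1 <- mean(sub$bd_g_cm3[sub$time == t1_label])
    rel <- abs(b1 - b0) / b0
    data.frame(treatment = sub$treatment[1],
               layer_top_cm = sub$depth_top_cm[1],
               layer_bottom_cm = sub$depth_bottom_cm[1],
               mean_bd_t0 = b0, mean_bd_t1 = b1,
               rel_change = rel, flagged = rel > threshold)
  }))
  out <- out[order(out$treatment, out$layer_top_cm), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Per-plot stock vectors for one treatment/method, by layer or aggregated to
# a cumulative surface depth.
credit_stock_values <- function(stocks, treatment, method, time_label,
                                top, bottom, aggregate = FALSE) {
  sub <- stocks[stocks$treatment == treatment & stocks$method == method &
                  stocks$time == time_label, , drop = FALSE]
  if (aggregate) {
    sub <- sub[sub$layer_bottom_cm <= bottom, , drop = FALSE]
  } else {
    sub <- sub[sub$layer_top_cm == top & sub$layer_bottom_cm == bottom, ,
               drop = FALSE]
  }
  tapply(sub$stock_MgC_ha, sub$plot, sum)
}

#' Crediting table per treatment, layer and accounting method
#'
#' For every treatment x ESM depth x accounting method, computes the
#' lower-confidence-limit stock change under the chosen crediting rule,
#' converts it to t CO2e ha-1 and issues whole credits for a field of
#' \code{area_ha}. Cumulative surface aggregates (0-30 and 0-60 cm) are
#' appended when the layer grid supports them. Fixed-depth rows whose layer
#' failed the bulk-density equivalence check carry a note recommending ESM.
#'
#' @param stocks a stock table from [stocks_pipeline()].
#' @param profiles optional profile set used for the bulk-density equivalence
#'   check; skipped when \code{NULL}.
#' @param area_ha field area (default 50 ha).
#' @param confidence two-sided level for the LCL (default 0.50 for the
#'   difference-between-means rule, 0.90 is conventional for mean_difference).
#' @param method crediting rule: \code{"difference_between_means"} (two-sample
#'   Welch) or \code{"mean_difference"} (paired one-sample).
#' @param stock_methods accounting methods to credit (default spline ESM and
#'   FD).
#' @param cumulative also credit 0-30 and 0-60 cm aggregates (default TRUE).
#' @param crediting_years reporting metadata echoed into the table.
#' @inheritParams reference_masses
#' @param t1_label label of the later sampling time.
#' @return data frame with columns \code{treatment, layer_top_cm,
#'   layer_bottom_cm, stock_method, mean_diff_MgC_ha, lcl_MgC_ha,
#'   lcl_tCO2e_ha, credits, crediting_years, bd_flag, over_credit_note}.
#' @export
credit_table <- function(stocks, profiles = NULL, area_ha = 50,
                         confidence = 0.50,
                         method = c("difference_between_means",
                                    "mean_difference"),
                         stock_methods = c("ESM_spline", "FD"),
                         cumulative = TRUE, crediting_years = 20,
                         t0_label = "t0", t1_label = "t1") {
  method <- match.arg(method)
  bd_flags <- if (!is.null(profiles)) {
    bd_equivalence_check(profiles, t0_label = t0_label, t1_label = t1_label)
  }
  layers <- unique(stocks[stocks$method %in% stock_methods,
                          c("treatment", "layer_top_cm", "layer_bottom_cm")])
  rows <- list()
  add_row <- function(treatment, top, bottom, sm, aggregate) {
    x0 <- credit_stock_values(stocks, treatment, sm, t0_label, top, bottom,
                              aggregate)
    x1 <- credit_stock_values(stocks, treatment, sm, t1_label, top, bottom,
                              aggregate)
    if (length(x0) < 2 || length(x1) < 2) return(NULL)
    lcl <- if (method == "difference_between_means") {
      if (stats::var(x0) == 0 && stats::var(x1) == 0) {
        mean(x1) - mean(x0)  # SE -> 0 limit of the Welch bound
      } else {
        lcl_difference_between_means(x0, x1, conf = confidence)
      }
    } else {
      common <- intersect(names(x0), names(x1))
      lcl_mean_difference(x1[common] - x0[common], conf = confidence)
    }
    flagged <- FALSE
    if (!is.null(bd_flags)) {
      f <- bd_flags[bd_flags$treatment == treatment &
                      bd_flags$layer_top_cm >= top &
                      bd_flags$layer_bottom_cm <= bottom, , drop = FALSE]
      flagged <- nrow(f) > 0 && any(f$flagged)
    }
    note <- if (flagged && sm == "FD") {
      "bulk density changed > 5%: FD credits unreliable, use ESM"
    } else {
      ""
    }
    data.frame(treatment = treatment, layer_top_cm = top,
               layer_bottom_cm = bottom, stock_method = sm,
               mean_diff_MgC_ha = mean(x1) - mean(x0),
               lcl_MgC_ha = lcl,
               lcl_tCO2e_ha = mgc_to_tco2e(lcl),
               credits = issue_credits(mgc_to_tco2e(lcl), area_ha),
               crediting_years = crediting_years,
               bd_flag = flagged, over_credit_note = note)
  }
  for (i in seq_len(nrow(layers))) {
    for (sm in stock_methods) {
      rows[[length(rows) + 1]] <- add_row(layers$treatment[i],
                                          layers$layer_top_cm[i],
                                          layers$layer_bottom_cm[i],
                                          sm, aggregate = FALSE)
    }
  }
  if (cumulative) {
    for (tr in unique(layers$treatment)) {
      bots <- layers$layer_bottom_cm[layers$treatment == tr]
      for (lim in intersect(c(30, 60), bots)) {
        for (sm in stock_methods) {
          rows[[length(rows) + 1]] <- add_row(tr, 0, lim, sm,
                                              aggregate = TRUE)
        }
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
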