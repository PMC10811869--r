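#' Hedges' g standardized mean difference
#'
#' Effect size for the difference between two groups: the difference in means
#' in units of the pooled (Bessel-corrected) standard deviation, shrunk by the
#' small-sample factor \code{J = 1 - 3 / (4 (n0 + n1 - 2) - 1)}. Positive when
#' the second group's mean is larger.
#'
#' @param x0,x1 numeric vectors of replicate values (each of length >= 2).
#' @return Hedges' g.
#' @export
hedges_g <- function(x0, x1) {
  n0 <- length(x0); n1 <- length(x1)
  if (n0 < 2 || n1 < 2) stop("each group needs >= 2 values", call. = FALSE)
  sp2 <- ((n0 - 1) * stats::var(x0) + (n1 - 1) * stats::var(x1)) /
    (n0 + n1 - 2)
  if (sp2 <= 0) stop("pooled standard deviation is zero", call. = FALSE)
  J <- 1 - 3 / (4 * (n0 + n1 - 2) - 1)
  J * (mean(x1) - mean(x0)) / sqrt(sp2)
}

# Closed-form Welch two-sample machinery shared by change_stat and the
# crediting LCL.
welch_components <- function(x0, x1) {
  n0 <- length(x0); n1 <- length(x1)
  v0 <- stats::var(x0); v1 <- stats::var(x1)
  se2 <- v0 / n0 + v1 / n1
  df <- se2^2 / ((v0 / n0)^2 / (n0 - 1) + (v1 / n1)^2 / (n1 - 1))
  list(n0 = n0, n1 = n1, mean0 = mean(x0), mean1 = mean(x1),
       diff = mean(x1) - mean(x0), se = sqrt(se2), df = df)
}

#' Change statistics between two sampling times
#'
#' Welch (unequal-variance) two-sample comparison of replicate values at t1
#' versus t0: mean change, confidence interval at \code{conf}, t statistic,
#' Welch degrees of freedom, p value, Hedges' g (pooled SD, even though the
#' test is Welch) and percent change relative to the t0 mean.
#'
#' @param x0 replicate values at the initial sampling time.
#' @param x1 replicate values at the later sampling time.
#' @param conf two-sided confidence level (default 0.95).
#' @return one-row data frame with columns \code{n0, n1, mean_t0, mean_t1,
#'   mean_change, ci_low, ci_high, t_stat, df, p_value, hedges_g,
#'   percent_change}.
#' @export
change_stat <- function(x0, x1, conf = 0.95) {
  if (length(x0) < 2 || length(x1) < 2) {
    stop("each sampling time needs >= 2 replicate values", call. = FALSE)
  }
  v0 <- stats::var(x0); v1 <- stats::var(x1)
  if (v0 == 0 && v1 == 0) {
    if (mean(x0) != mean(x1)) {
      stop("degenerate: zero variance in both groups with unequal means",
           call. = FALSE)
    }
    return(data.frame(n0 = length(x0), n1 = length(x1),
                      mean_t0 = mean(x0), mean_t1 = mean(x1),
                      mean_change = 0, ci_low = 0, ci_high = 0,
                      t_stat = 0, df = length(x0) + length(x1) - 2,
                      p_value = 1, hedges_g = 0,
                      percent_change = 0))
  }
  tt <- stats::t.test(x1, x0, conf.level = conf)
  g <- hedges_g(x0, x1)
  m0 <- mean(x0)
  data.frame(n0 = length(x0), n1 = length(x1),
             mean_t0 = m0, mean_t1 = mean(x1),
             mean_change = mean(x1) - m0,
             ci_low = tt$conf.int[1], ci_high = tt$conf.int[2],
             t_stat = unname(tt$statistic), df = unname(tt$parameter),
             p_value = tt$p.value, hedges_g = g,
             percent_change = if (m0 != 0) 100 * (mean(x1) - m0) / m0 else NA_real_)
}

#' Contrast between ESM and FD stock-change estimates
#'
#' The per-plot stock changes estimated under ESM and FD accounting are
#' compared; the mean difference \code{ESM - FD} is the error attributable to
#' the fixed-depth method when ESM is taken as correct. Either an unpaired
#' Welch t test (default) or a paired t test over plots.
#'
#' @param esm_changes per-plot stock changes (t1 - t0) under ESM, Mg C ha-1.
#' @param fd_changes per-plot stock changes under FD, Mg C ha-1.
#' @param paired pair by plot (vectors must align) instead of Welch.
#' @param conf two-sided confidence level (default 0.95).
#' @return one-row data frame with \code{mean_esm_change, mean_fd_change,
#'   diff, ci_low, ci_high, t_stat, df, p_value, hedges_g}.
#' @export
method_contrast <- function(esm_changes, fd_changes, paired = FALSE,
                            conf = 0.95) {
  if (paired && length(esm_changes) != length(fd_changes)) {
    stop("paired contrast needs equal-length change vectors", call. = FALSE)
  }
  d <- mean(esm_changes) - mean(fd_changes)
  if (stats::var(esm_changes) == 0 && stats::var(fd_changes) == 0) {
    if (d != 0) stop("degenerate: zero variance with unequal means",
                     call. = FALSE)
    return(data.frame(mean_esm_change = mean(esm_changes),
                      mean_fd_change = mean(fd_changes), diff = 0,
                      ci_low = 0, ci_high = 0, t_stat = 0,
                      df = length(esm_changes) + length(fd_changes) - 2,
                      p_value = 1, hedges_g = 0))
  }
  tt <- if (paired) {
    stats::t.test(esm_changes, fd_changes, paired = TRUE, conf.level = conf)
  } else {
    stats::t.test(esm_changes, fd_changes, conf.level = conf)
  }
  data.frame(mean_esm_change = mean(esm_changes),
             mean_fd_change = mean(fd_changes),
             diff = d,
             ci_low = tt$conf.int[1], ci_high = tt$conf.int[2],
             t_stat = unname(tt$statistic), df = unname(tt$parameter),
             p_value = tt$p.value,
             hedges_g = hedges_g(fd_changes, esm_changes))
}

#' Replicates needed to detect a relative change
#'
#' Smallest per-group sample size for a two-sided two-sample t test to detect
#' a mean shift of \code{rel_change} times the baseline against replicate
#' noise of \code{cv} times the baseline, at significance \code{alpha} and the
#' requested power. Solved by iterating the noncentral-t power condition.
#'
#' @param cv coefficient of variation of replicate values (> 0).
#' @param rel_change detectable relative change, in (0, 1).
#' @param alpha two-sided significance level (default 0.05).
#' @param power target power (default 0.8).
#' @param n_max search cap (default 1e6).
#' @return smallest integer n per group (>= 2).
#' @export
required_sample_size <- function(cv, rel_change, alpha = 0.05, power = 0.8,
                                 n_max = 1e6) {
  if (rel_change == 0) stop("a zero change is undetectable", call. = FALSE)
  stopifnot(cv > 0, rel_change > 0, rel_change < 1,
            alpha > 0, alpha < 1, power > 0, power < 1)
  for (n in 2:n_max) {
    df <- 2 * (n - 1)
    tcrit <- stats::qt(1 - alpha / 2, df)
    ncp <- rel_change / (cv * sqrt(2 / n))
    pw <- 1 - stats::pt(tcrit, df, ncp = ncp) +
      stats::pt(-tcrit, df, ncp = ncp)
    if (pw >= power) return(n)
  }
  stop("no n <= n_max achieves the requested power", call. = FALSE)
}

# Per-plot change values (t1 - t0) for one numeric column, matched by plot.
plot_changes <- function(df, value_col, t0_label = "t0", t1_label = "t1") {
  w0 <- df[df$time == t0_label, , drop = FALSE]
  w1 <- df[df$time == t1_label, , drop = FALSE]
  common <- intersect(w0$plot, w1$plot)
  v0 <- w0[[value_col]][match(common, w0$plot)]
  v1 <- w1[[value_col]][match(common, w1$plot)]
  data.frame(plot = common, change = v1 - v0)
}

#' Per-treatment, per-layer change statistics for an intensive variable
#'
#' Applies [change_stat()] to each treatment x depth increment of a profile
#' set, for bulk density or carbon concentration.
#'
#' @inheritParams reference_masses
#' @param variable \code{"bd_g_cm3"} or \code{"c_g_kg"}.
#' @param conf confidence level.
#' @param t1_label value of \code{time} identifying the later sampling.
#' @return data frame: treatment, layer bounds, variable, and the
#'   [change_stat()] columns.
#' @export
profile_change_table <- function(profiles, variable = c("bd_g_cm3", "c_g_kg"),
                                 conf = 0.95, t0_label = "t0",
                                 t1_label = "t1") {
  variable <- match.arg(variable)
  df <- as.data.frame(profiles)
  grp <- split(df, list(df$treatment, df$depth_top_cm), drop = TRUE)
  out <- do.call(rbind, lapply(grp, function(sub) {
    x0 <- sub[[variable]][sub$time == t0_label]
    x1 <- sub[[variable]][sub$time == t1_label]
    cbind(data.frame(treatment = sub$treatment[1],
                     layer_top_cm = sub$depth_top_cm[1],
                     layer_bottom_cm = sub$depth_bottom_cm[1],
                     variable = variable),
          change_stat(x0, x1, conf = conf))
  }))
  out <- out[order(out$treatment, out$layer_top_cm), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Per-treatment, per-layer stock change statistics
#'
#' Applies [change_stat()] to the per-plot layer stocks of one accounting
#' method in a stock table produced by [stocks_pipeline()].
#'
#' @param stocks a stock table.
#' @param method one of \code{"FD", "ESM_classical", "ESM_spline"}.
#' @inheritParams profile_change_table
#' @return data frame of change statistics per treatment x ESM depth.
#' @export
stock_change_table <- function(stocks, method = "ESM_spline", conf = 0.95,
                               t0_label = "t0", t1_label = "t1") {
  df <- stocks[stocks$method == method, , drop = FALSE]
  if (nrow(df) == 0) stop("no rows for method '", method, "'", call. = FALSE)
  grp <- split(df, list(df$treatment, df$layer_top_cm), drop = TRUE)
  out <- do.call(rbind, lapply(grp, function(sub) {
    x0 <- sub$stock_MgC_ha[sub$time == t0_label]
    x1 <- sub$stock_MgC_ha[sub$time == t1_label]
    cbind(data.frame(treatment = sub$treatment[1],
                     layer_top_cm = sub$layer_top_cm[1],
                     layer_bottom_cm = sub$layer_bottom_cm[1],
                     method = method),
          change_stat(x0, x1, conf = conf))
  }))
  out <- out[order(out$treatment, out$layer_top_cm), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' ESM-versus-FD contrast table
#'
#' For each treatment x ESM depth, forms the per-plot stock changes under the
#' chosen ESM engine and under FD, and reports the [method_contrast()]
#' statistics on \code{ESM - FD}.
#'
#' @inheritParams stock_change_table
#' @param esm_method which ESM engine to contrast against FD.
#' @param paired use a paired t test over plots.
#' @return data frame: treatment, esm_depth bounds, and the
#'   [method_contrast()] columns.
#' @export
contrast_table <- function(stocks, esm_method = "ESM_spline", paired = FALSE,
                           conf = 0.95, t0_label = "t0", t1_label = "t1") {
  esm <- stocks[stocks$method == esm_method, , drop = FALSE]
  fd <- stocks[stocks$method == "FD", , drop = FALSE]
  grp <- split(esm, list(esm$treatment, esm$layer_top_cm), drop = TRUE)
  out <- do.call(rbind, lapply(grp, function(sub) {
    fsub <- fd[fd$treatment == sub$treatment[1] &
                 fd$layer_top_cm == sub$layer_top_cm[1], , drop = FALSE]
    ce <- plot_changes(sub, "stock_MgC_ha", t0_label, t1_label)
    cf <- plot_changes(fsub, "stock_MgC_ha", t0_label, t1_label)
    cf <- cf[match(ce$plot, cf$plot), , drop = FALSE]
    cbind(data.frame(treatment = sub$treatment[1],
                     layer_top_cm = sub$layer_top_cm[1],
                     layer_bottom_cm = sub$layer_bottom_cm[1]),
          method_contrast(ce$change, cf$change, paired = paired, conf = conf))
  }))
  out <- out[order(out$treatment, out$layer_top_cm), , drop = FALSE]
  rownames(out) <- NULL
  out
}
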