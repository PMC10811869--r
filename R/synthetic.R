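#' Layer means of an exponentially decaying concentration profile
#'
#' Carbon concentration in many cultivated profiles decays roughly
#' exponentially with depth. Given a surface-layer mean and a depth scale,
#' returns the exact layer means of \code{c(z) = A exp(-z / z_scale)} over
#' each increment, scaled so the first layer's mean equals
#' \code{c_surface}.
#'
#' @param c_surface mean concentration of the first increment, g C kg-1.
#' @param z_scale e-folding depth, cm.
#' @param grid data frame with \code{depth_top_cm, depth_bottom_cm}.
#' @return numeric vector of layer-mean concentrations.
#' @export
conc_decay_profile <- function(c_surface, z_scale, grid) {
  d <- grid$depth_bottom_cm - grid$depth_top_cm
  raw <- z_scale * (exp(-grid$depth_top_cm / z_scale) -
                      exp(-grid$depth_bottom_cm / z_scale)) / d
  raw * c_surface / raw[1]
}

#' Scenario configuration for the synthetic profile generator
#'
#' Describes one treatment of a two-time-point sampling campaign: the
#' increment grid, the t0 mean bulk-density and concentration profiles, the
#' per-layer relative changes applied at t1, and the per-layer replicate
#' noise. Bulk density must be non-decreasing with depth; concentration
#' decays with depth.
#'
#' @param treatment treatment label.
#' @param n number of replicate plots (>= 2).
#' @param grid data frame with \code{depth_top_cm, depth_bottom_cm},
#'   contiguous from 0.
#' @param bd_t0 t0 mean bulk density per layer, g cm-3.
#' @param conc_t0 t0 mean carbon concentration per layer, g C kg-1.
#' @param bd_change_rel relative bulk-density change per layer at t1
#'   (e.g. -0.16 for a 16 percent decrease).
#' @param conc_change_rel relative concentration change per layer at t1.
#' @param bd_noise_sd replicate noise SD per layer for bulk density at t0,
#'   g cm-3. Long-term trials start from a deliberately uniform baseline, so
#'   this is typically smaller than the t1 dispersion.
#' @param conc_noise_sd replicate noise SD per layer for concentration at t0,
#'   g C kg-1.
#' @param bd_noise_sd_t1,conc_noise_sd_t1 noise SDs applied on top of the
#'   systematic change at t1 (default: same as t0). Two decades of
#'   plot-specific management response usually disperse plots well beyond
#'   the baseline spread, so presets use larger values here.
#' @param experiment experiment label.
#' @param n_blocks blocks to cycle replicates through (default 3).
#' @param compaction optional per-layer mass multipliers for a
#'   mass-preserving compaction scenario; when supplied, t1 is derived from
#'   each replicate's t0 column by compacting soil mass into shallower
#'   increments with the mass-ordered concentration unchanged, and
#'   \code{bd_change_rel}/\code{conc_change_rel} are ignored.
#' @return a validated \code{scenario_config} list.
#' @export
scenario_config <- function(treatment, n, grid, bd_t0, conc_t0,
                            bd_change_rel = rep(0, nrow(grid)),
                            conc_change_rel = rep(0, nrow(grid)),
                            bd_noise_sd = rep(0, nrow(grid)),
                            conc_noise_sd = rep(0, nrow(grid)),
                            bd_noise_sd_t1 = bd_noise_sd,
                            conc_noise_sd_t1 = conc_noise_sd,
                            experiment = "synthetic", n_blocks = 3,
                            compaction = NULL) {
  grid <- as.data.frame(grid)[, c("depth_top_cm", "depth_bottom_cm")]
  J <- nrow(grid)
  if (grid$depth_top_cm[1] != 0 ||
      (J > 1 && any(grid$depth_bottom_cm[-J] != grid$depth_top_cm[-1]))) {
    stop("grid must be contiguous from 0 cm", call. = FALSE)
  }
  if (n < 2) stop("need n >= 2 replicates", call. = FALSE)
  lens <- vapply(list(bd_t0, conc_t0, bd_change_rel, conc_change_rel,
                      bd_noise_sd, conc_noise_sd, bd_noise_sd_t1,
                      conc_noise_sd_t1), length, integer(1))
  if (any(lens != J)) stop("per-layer fields must match the grid", call. = FALSE)
  if (any(bd_t0 <= 0)) stop("mean bulk density must be > 0", call. = FALSE)
  if (any(conc_t0 < 0)) stop("mean concentration must be >= 0", call. = FALSE)
  if (any(diff(bd_t0) < 0)) {
    stop("t0 bulk density must be non-decreasing with depth", call. = FALSE)
  }
  if (any(c(bd_noise_sd, conc_noise_sd, bd_noise_sd_t1,
            conc_noise_sd_t1) < 0)) {
    stop("noise SDs must be >= 0", call. = FALSE)
  }
  if (any(bd_t0 * (1 + bd_change_rel) <= 0)) {
    stop("bulk-density change drives the mean negative", call. = FALSE)
  }
  if (!is.null(compaction) &&
      (length(compaction) != J || any(compaction < 1))) {
    stop("compaction multipliers must be >= 1, one per layer", call. = FALSE)
  }
  structure(list(treatment = treatment, n = n, grid = grid, bd_t0 = bd_t0,
                 conc_t0 = conc_t0, bd_change_rel = bd_change_rel,
                 conc_change_rel = conc_change_rel,
                 bd_noise_sd = bd_noise_sd, conc_noise_sd = conc_noise_sd,
                 bd_noise_sd_t1 = bd_noise_sd_t1,
                 conc_noise_sd_t1 = conc_noise_sd_t1,
                 experiment = experiment, n_blocks = n_blocks,
                 compaction = compaction),
            class = "scenario_config")
}

# Draw truncated-at-zero Gaussian layer values by resampling violations.
draw_positive <- function(mu, sd, lower = 0) {
  x <- stats::rnorm(length(mu), mu, sd)
  for (it in 1:100) {
    bad <- x < lower
    if (!any(bad)) return(x)
    x[bad] <- stats::rnorm(sum(bad), mu[bad], sd[bad])
  }
  pmax(x, lower)
}

# t1 column of a mass-preserving compaction: soil mass per increment grows by
# the configured multipliers; the concentration as a function of cumulative
# mass is unchanged, extended below the sampled column with the deepest
# concentration.
compact_column <- function(bd0, conc0, d, mult) {
  mass0 <- bd0 * d * 100
  cum0 <- cumsum(mass0)
  cums0 <- cumsum(mass0 * conc0 / 1000)
  s0 <- function(m) {
    inside <- m <= cum0[length(cum0)]
    out <- numeric(length(m))
    out[inside] <- stats::approx(c(0, cum0), c(0, cums0), xout = m[inside])$y
    if (any(!inside)) {
      out[!inside] <- cums0[length(cums0)] +
        (m[!inside] - cum0[length(cum0)]) * conc0[length(conc0)] / 1000
    }
    out
  }
  bd1 <- bd0 * mult
  cum1 <- cumsum(bd1 * d * 100)
  stock1 <- diff(c(0, s0(cum1)))
  conc1 <- stock1 / (bd1 * d * 100) * 1000
  list(bd = bd1, conc = conc1)
}

#' Generate a synthetic two-time-point profile set
#'
#' For each replicate plot, t0 layer values are the configured means plus
#' independent Gaussian noise (negative draws resampled); t1 values are the
#' replicate's t0 values times (1 + relative change) plus noise. Compaction
#' scenarios instead derive t1 deterministically from each replicate's t0
#' column (see [scenario_config()]). Deterministic given \code{seed}.
#'
#' @param config a \code{scenario_config} or a list of them (treatments of
#'   one experiment, generated under a single random stream).
#' @param seed integer seed; \code{NULL} leaves the RNG state alone.
#' @return a validated \code{profile_set} with times \code{"t0"}/\code{"t1"}.
#' @export
generate_profiles <- function(config, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  configs <- if (inherits(config, "scenario_config")) list(config) else config
  rows <- list()
  for (cfg in configs) {
    if (!inherits(cfg, "scenario_config")) {
      stop("config must be a scenario_config or list of them", call. = FALSE)
    }
    d <- cfg$grid$depth_bottom_cm - cfg$grid$depth_top_cm
    for (i in seq_len(cfg$n)) {
      bd0 <- draw_positive(cfg$bd_t0, cfg$bd_noise_sd, lower = 1e-6)
      conc0 <- draw_positive(cfg$conc_t0, cfg$conc_noise_sd, lower = 0)
      if (!is.null(cfg$compaction)) {
        t1 <- compact_column(bd0, conc0, d, cfg$compaction)
        bd1 <- t1$bd; conc1 <- t1$conc
      } else {
        bd1 <- draw_positive(bd0 * (1 + cfg$bd_change_rel),
                             cfg$bd_noise_sd_t1, lower = 1e-6)
        conc1 <- draw_positive(conc0 * (1 + cfg$conc_change_rel),
                               cfg$conc_noise_sd_t1, lower = 0)
      }
      plot_id <- paste0(cfg$treatment, "-", i)
      block <- paste0("B", ((i - 1) %% cfg$n_blocks) + 1)
      for (tm in c("t0", "t1")) {
        rows[[length(rows) + 1]] <- data.frame(
          experiment = cfg$experiment, treatment = cfg$treatment,
          block = block, plot = plot_id, time = tm,
          depth_top_cm = cfg$grid$depth_top_cm,
          depth_bottom_cm = cfg$grid$depth_bottom_cm,
          bd_g_cm3 = if (tm == "t0") bd0 else bd1,
          c_g_kg = if (tm == "t0") conc0 else conc1)
      }
    }
  }
  as_profile_set(do.call(rbind, rows))
}

century_grid <- function() {
  data.frame(depth_top_cm = c(0, 15, 30, 60, 100),
             depth_bottom_cm = c(15, 30, 60, 100, 200))
}

wicst_grid <- function() {
  data.frame(depth_top_cm = c(0, 15, 30, 60),
             depth_bottom_cm = c(15, 30, 60, 90))
}

#' Preset scenario configurations
#'
#' Four scenarios spanning the regimes the pipeline must handle:
#' \describe{
#'   \item{century_maize_like}{n = 6, five increments to 200 cm; surface
#'     bulk density falls 16 percent while surface concentration rises 41
#'     percent (organic-amendment regime: loosening plus enrichment), so FD
#'     understates the stock gain.}
#'   \item{century_wheat_like}{n = 6; surface bulk density falls ~15 percent
#'     with only a small concentration rise.}
#'   \item{wicst_like}{n = 12, four increments to 90 cm on a carbon-rich
#'     Mollisol; surface bulk density rises 19 percent while concentration
#'     falls (no-till compaction regime), so FD can report a gain where ESM
#'     shows a loss.}
#'   \item{compaction_null}{n = 6; a mass-preserving redistribution of each
#'     t0 column into shallower increments: true ESM change is zero by
#'     construction while FD registers a gain.}
#' }
#'
#' @param name preset name.
#' @return a \code{scenario_config}.
#' @export
preset <- function(name = c("century_maize_like", "century_wheat_like",
                            "wicst_like", "compaction_null")) {
  name <- match.arg(name)
  cg <- century_grid()
  century_bd <- c(1.44, 1.50, 1.53, 1.58, 1.62)
  century_conc <- conc_decay_profile(9.8, 80, cg)
  century_bd_sd0 <- c(0.04, 0.04, 0.05, 0.06, 0.07)
  century_bd_sd1 <- c(0.09, 0.09, 0.10, 0.10, 0.11)
  century_conc_sd0 <- c(0.45, 0.45, 0.50, 0.40, 0.30)
  century_conc_sd1 <- c(1.05, 1.00, 1.00, 0.75, 0.50)
  switch(name,
    century_maize_like = scenario_config(
      treatment = "OMT_like", n = 6, grid = cg,
      bd_t0 = century_bd, conc_t0 = century_conc,
      bd_change_rel = c(-0.16, -0.11, -0.05, -0.01, 0),
      conc_change_rel = c(0.41, 0.22, 0.03, 0.006, 0),
      bd_noise_sd = century_bd_sd0, conc_noise_sd = century_conc_sd0,
      bd_noise_sd_t1 = century_bd_sd1, conc_noise_sd_t1 = century_conc_sd1,
      experiment = "century_like"),
    century_wheat_like = scenario_config(
      treatment = "RW_WCC_like", n = 6, grid = cg,
      bd_t0 = century_bd, conc_t0 = century_conc,
      bd_change_rel = c(-0.15, -0.11, 0.03, 0, 0),
      conc_change_rel = c(0.05, 0.01, -0.01, 0, 0),
      bd_noise_sd = century_bd_sd0, conc_noise_sd = century_conc_sd0,
      bd_noise_sd_t1 = century_bd_sd1, conc_noise_sd_t1 = century_conc_sd1,
      experiment = "century_like"),
    wicst_like = scenario_config(
      treatment = "MS_like", n = 12, grid = wicst_grid(),
      bd_t0 = c(1.10, 1.27, 1.40, 1.48),
      conc_t0 = conc_decay_profile(25, 40, wicst_grid()),
      bd_change_rel = c(0.19, 0.055, 0, 0),
      conc_change_rel = c(-0.08, -0.03, -0.01, 0),
      bd_noise_sd = c(0.04, 0.04, 0.04, 0.04),
      conc_noise_sd = c(1.2, 1.0, 0.8, 0.6),
      bd_noise_sd_t1 = c(0.10, 0.07, 0.06, 0.06),
      conc_noise_sd_t1 = c(2.2, 1.8, 1.3, 0.9),
      experiment = "wicst_like", n_blocks = 4),
    compaction_null = scenario_config(
      treatment = "compaction_null", n = 6, grid = cg,
      bd_t0 = century_bd, conc_t0 = century_conc,
      bd_noise_sd = century_bd_sd0, conc_noise_sd = century_conc_sd0,
      compaction = c(1.15, 1.08, 1.03, 1.0, 1.0),
      experiment = "century_like"))
}

#' The three maize-system scenarios as one experiment
#'
#' Configurations mimicking the three maize systems of a loosening-plus-
#' enrichment trial (conventional: large bulk-density drop, small
#' concentration rise; cover-cropped: moderate drop, moderate rise; organic:
#' large drop, large rise), 6 replicates each, for pooled-association
#' analyses over 18 plots.
#'
#' @return list of three \code{scenario_config}s.
#' @export
century_maize_systems <- function() {
  cg <- century_grid()
  base <- preset("century_maize_like")
  cmt <- scenario_config(
    treatment = "CMT_like", n = 6, grid = cg,
    bd_t0 = base$bd_t0, conc_t0 = base$conc_t0,
    bd_change_rel = c(-0.19, -0.11, -0.03, 0, 0),
    conc_change_rel = c(0.03, 0.01, -0.02, -0.01, 0),
    bd_noise_sd = base$bd_noise_sd, conc_noise_sd = base$conc_noise_sd,
    bd_noise_sd_t1 = base$bd_noise_sd_t1,
    conc_noise_sd_t1 = base$conc_noise_sd_t1,
    experiment = "century_like")
  wcc <- scenario_config(
    treatment = "CMT_WCC_like", n = 6, grid = cg,
    bd_t0 = base$bd_t0, conc_t0 = base$conc_t0,
    bd_change_rel = c(-0.13, -0.11, -0.12, -0.01, 0),
    conc_change_rel = c(0.21, 0.05, -0.02, -0.01, 0),
    bd_noise_sd = base$bd_noise_sd, conc_noise_sd = base$conc_noise_sd,
    bd_noise_sd_t1 = base$bd_noise_sd_t1,
    conc_noise_sd_t1 = base$conc_noise_sd_t1,
    experiment = "century_like")
  list(cmt, wcc, base)
}
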