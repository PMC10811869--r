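# Shared fixtures and independent oracles.

# Long-format rows for one plot/time.
make_profile_df <- function(top, bottom, bd, conc, plot = "p1", time = "t0",
                            treatment = "T", experiment = "E", block = "B1") {
  data.frame(experiment = experiment, treatment = treatment, block = block,
             plot = plot, time = time, depth_top_cm = top,
             depth_bottom_cm = bottom, bd_g_cm3 = bd, c_g_kg = conc)
}

# A two-plot, two-time profile set on a fixed grid; change applied
# multiplicatively to plot values at t1.
make_profile_set <- function(n_plots = 2, bd = c(1.2, 1.4, 1.5),
                             conc = c(10, 6, 3),
                             bd_mult = 1, conc_mult = 1,
                             top = c(0, 15, 30), bottom = c(15, 30, 60),
                             jitter = 0, seed = 1) {
  set.seed(seed)
  rows <- list()
  for (i in seq_len(n_plots)) {
    b0 <- bd + stats::rnorm(length(bd), 0, jitter)
    c0 <- conc + stats::rnorm(length(conc), 0, jitter)
    rows[[length(rows) + 1]] <- make_profile_df(top, bottom, b0, c0,
                                                plot = paste0("p", i))
    rows[[length(rows) + 1]] <- make_profile_df(top, bottom, b0 * bd_mult,
                                                c0 * conc_mult,
                                                plot = paste0("p", i),
                                                time = "t1")
  }
  as_profile_set(do.call(rbind, rows))
}

# Brute-force cumulative-coordinate oracle: discretise the profile into
# `step`-cm sublayers (constant properties within a source layer) and read
# the cumulative stock at a query mass off the fine cumulative curves.
fine_cum_stock <- function(top, bottom, bd, conc, query_mass, step = 0.1) {
  edges <- seq(0, max(bottom), by = step)
  mids <- edges[-1] - step / 2
  idx <- findInterval(mids, top)
  m <- bd[idx] * step * 100
  s <- m * conc[idx] / 1000
  stats::approx(c(0, cumsum(m)), c(0, cumsum(s)), xout = query_mass)$y
}

# A random profile with smooth underlying fields: bulk density saturating
# towards depth, concentration decaying exponentially to a floor. Returns the
# layer means a lab would report plus the continuous functions.
random_smooth_profile <- function(top = c(0, 15, 30, 60),
                                  bottom = c(15, 30, 60, 100)) {
  zs <- runif(1, 40, 90); A <- 8 + runif(1, 0, 8); cf <- runif(1, 0.3, 1.5)
  b0 <- runif(1, 1.0, 1.3); b1 <- b0 + runif(1, 0.1, 0.4)
  zb <- runif(1, 20, 60)
  cfun <- function(z) A * exp(-z / zs) + cf
  bfun <- function(z) b1 - (b1 - b0) * exp(-z / zb)
  layer_mean <- function(f, a, b) stats::integrate(f, a, b)$value / (b - a)
  list(top = top, bottom = bottom,
       bd = mapply(layer_mean, a = top, b = bottom, MoreArgs = list(f = bfun)),
       conc = mapply(layer_mean, a = top, b = bottom,
                     MoreArgs = list(f = cfun)),
       cfun = cfun, bfun = bfun)
}

# Fine-discretisation oracle over the continuous fields.
fine_cum_stock_cont <- function(bfun, cfun, max_depth, query_mass,
                                step = 0.05) {
  edges <- seq(0, max_depth, by = step)
  mids <- edges[-1] - step / 2
  m <- bfun(mids) * step * 100
  s <- m * cfun(mids) / 1000
  stats::approx(c(0, cumsum(m)), c(0, cumsum(s)), xout = query_mass)$y
}

# Closed-form Welch two-sample statistics, written out from the formulas.
welch_hand <- function(x0, x1, conf = 0.95) {
  n0 <- length(x0); n1 <- length(x1)
  v0 <- var(x0); v1 <- var(x1)
  se <- sqrt(v0 / n0 + v1 / n1)
  df <- se^4 / ((v0 / n0)^2 / (n0 - 1) + (v1 / n1)^2 / (n1 - 1))
  diff <- mean(x1) - mean(x0)
  tcrit <- qt(1 - (1 - conf) / 2, df)
  list(diff = diff, se = se, df = df, t = diff / se,
       ci = c(diff - tcrit * se, diff + tcrit * se),
       p = 2 * pt(-abs(diff / se), df))
}

# Deterministic mass-preserving compaction of a single column: multiply layer
# masses by `mult` and carry the t0 mass-ordered concentration (extended at
# depth with the deepest value) into the new increments.
compact_oracle <- function(top, bottom, bd, conc, mult) {
  d <- bottom - top
  m0 <- bd * d * 100
  cum0 <- cumsum(m0)
  cums0 <- cumsum(m0 * conc / 1000)
  s0 <- function(m) {
    ifelse(m <= cum0[length(cum0)],
           stats::approx(c(0, cum0), c(0, cums0), xout = m)$y,
           cums0[length(cums0)] +
             (m - cum0[length(cum0)]) * conc[length(conc)] / 1000)
  }
  bd1 <- bd * mult
  cum1 <- cumsum(bd1 * d * 100)
  stock1 <- diff(c(0, s0(cum1)))
  list(bd = bd1, conc = stock1 / (bd1 * d * 100) * 1000)
}
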