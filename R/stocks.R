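#' Soil mass of a layer
#'
#' Converts bulk density and layer thickness to areal soil mass:
#' \code{M = rho * d * 100} with \code{rho} in g cm-3 and \code{d} in cm gives
#' Mg ha-1 (1 g cm-3 over 1 cm depth is 100 Mg ha-1).
#'
#' @param bd_g_cm3 bulk density, g cm-3.
#' @param thickness_cm layer thickness, cm.
#' @return soil mass, Mg ha-1.
#' @export
soil_mass <- function(bd_g_cm3, thickness_cm) {
  bd_g_cm3 * thickness_cm * 100
}

#' Fixed-depth SOC stock of a layer
#'
#' The fixed-depth (FD) stock multiplies carbon concentration, bulk density and
#' layer thickness: \code{S = c * rho * d * 0.1} Mg C ha-1 with \code{c} in
#' g C kg-1, equivalently soil mass times \code{c / 1000}.
#'
#' @param c_g_kg carbon concentration, g C kg-1.
#' @inheritParams soil_mass
#' @return SOC stock, Mg C ha-1.
#' @export
fd_stock <- function(c_g_kg, bd_g_cm3, thickness_cm) {
  c_g_kg * bd_g_cm3 * thickness_cm * 0.1
}

#' Reference soil masses per treatment and layer
#'
#' The reference mass that defines the equivalent-soil-mass (ESM) coordinate
#' system for a treatment is the soil mass of each initial (t0) fixed-depth
#' increment averaged across that treatment's replicate plots. Reference
#' masses are taken from t0 and shared by both sampling times and all
#' replicates; ESM layers inherit the t0 increment boundaries as their
#' "ESM depth" labels.
#'
#' @param profiles a \code{profile_set} (see [as_profile_set()]).
#' @param t0_label value of the \code{time} column identifying the initial
#'   sampling (default \code{"t0"}).
#' @return data frame with columns \code{treatment, layer_index, layer_top_cm,
#'   layer_bottom_cm, ref_mass_Mg_ha, cum_ref_mass_Mg_ha}.
#' @export
reference_masses <- function(profiles, t0_label = "t0") {
  t0 <- as.data.frame(profiles)[profiles$time == t0_label, , drop = FALSE]
  if (nrow(t0) == 0) stop("no profiles at t0 label '", t0_label, "'",
                          call. = FALSE)
  out <- lapply(split(t0, t0$treatment), function(sub) {
    grids <- split(sub, sub$plot)
    g0 <- grids[[1]][order(grids[[1]]$depth_top_cm), ]
    for (g in grids) {
      g <- g[order(g$depth_top_cm), ]
      if (nrow(g) != nrow(g0) ||
          any(g$depth_top_cm != g0$depth_top_cm) ||
          any(g$depth_bottom_cm != g0$depth_bottom_cm)) {
        stop("t0 replicates of treatment ", sub$treatment[1],
             " do not share an increment grid", call. = FALSE)
      }
    }
    masses <- vapply(grids, function(g) {
      g <- g[order(g$depth_top_cm), ]
      soil_mass(g$bd_g_cm3, g$depth_bottom_cm - g$depth_top_cm)
    }, numeric(nrow(g0)))
    ref <- if (is.matrix(masses)) rowMeans(masses) else mean(masses)
    data.frame(treatment = sub$treatment[1],
               layer_index = seq_len(nrow(g0)),
               layer_top_cm = g0$depth_top_cm,
               layer_bottom_cm = g0$depth_bottom_cm,
               ref_mass_Mg_ha = ref,
               cum_ref_mass_Mg_ha = cumsum(ref))
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

# Cumulative-coordinate knots of one profile: cumulative soil mass vs
# cumulative FD stock, with the origin prepended.
profile_knots <- function(profile) {
  profile <- profile[order(profile$depth_top_cm), , drop = FALSE]
  d <- profile$depth_bottom_cm - profile$depth_top_cm
  mass <- soil_mass(profile$bd_g_cm3, d)
  stock <- fd_stock(profile$c_g_kg, profile$bd_g_cm3, d)
  list(mass = mass, stock = stock,
       cum_mass = cumsum(mass), cum_stock = cumsum(stock),
       conc = profile$c_g_kg)
}

#' Spline-ESM cumulative stock at query masses
#'
#' Fits a natural cubic spline (second derivative zero at the ends) through
#' the cumulative-coordinate knots (0, 0), (cumulative soil mass, cumulative
#' FD stock) of a sampled profile and evaluates it at the requested cumulative
#' reference masses. Evaluation at a knot reproduces the knot exactly.
#'
#' @param cum_mass cumulative sampled soil mass at each layer bottom, Mg ha-1
#'   (strictly increasing, origin excluded).
#' @param cum_stock cumulative FD stock at each layer bottom, Mg C ha-1.
#' @param query_mass cumulative reference masses to interpolate at, Mg ha-1.
#' @param extrapolate if \code{FALSE} (default) a query beyond the sampled
#'   mass is an error reporting the shortfall; if \code{TRUE} the last spline
#'   segment is extended linearly and the result flagged.
#' @return list with \code{cum_stock} at the queries and logical
#'   \code{extrapolated} per query.
#' @export
esm_spline_cum <- function(cum_mass, cum_stock, query_mass,
                           extrapolate = FALSE) {
  if (length(cum_mass) < 2) {
    stop("spline ESM needs at least 2 sampled layers", call. = FALSE)
  }
  beyond <- query_mass > max(cum_mass) * (1 + 1e-12)
  if (any(beyond) && !extrapolate) {
    shortfall <- max(query_mass) - max(cum_mass)
    stop(sprintf(paste0(
      "deepest cumulative reference mass exceeds sampled cumulative mass ",
      "by %.3f Mg ha-1; sample deeper or set extrapolate = TRUE"), shortfall),
      call. = FALSE)
  }
  f <- stats::splinefun(c(0, cum_mass), c(0, cum_stock), method = "natural")
  list(cum_stock = f(query_mass), extrapolated = beyond)
}

#' Classical-ESM cumulative stock at reference masses
#'
#' The classical equivalent-soil-mass correction processes layers top-down,
#' comparing the sampled cumulative mass at each layer bottom with the
#' cumulative reference mass of the corresponding ESM layer. A surplus
#' (sampled more soil than the reference) removes the surplus mass valued at
#' that layer's concentration; a deficit borrows the missing mass from the
#' next deeper layer, valued at the deeper layer's concentration.
#'
#' A deficit at the deepest layer has no layer to borrow from and is an error
#' unless \code{extrapolate = TRUE}, in which case the missing mass is valued
#' at the deepest layer's concentration and the layer flagged.
#'
#' @inheritParams esm_spline_cum
#' @param conc layer carbon concentrations, g C kg-1, aligned with
#'   \code{cum_mass}.
#' @param ref_cum_mass cumulative reference masses, one per ESM layer; must be
#'   aligned one-to-one with the sampled layers.
#' @return list with \code{cum_stock} (cumulative ESM stock at each
#'   cumulative reference mass, Mg C ha-1) and logical \code{extrapolated}
#'   per layer.
#' @export
esm_classical_cum <- function(cum_mass, cum_stock, conc, ref_cum_mass,
                              extrapolate = FALSE) {
  J <- length(ref_cum_mass)
  if (length(cum_mass) != J) {
    stop("classical ESM requires one sampled layer per ESM layer", call. = FALSE)
  }
  out <- numeric(J)
  extr <- rep(FALSE, J)
  for (j in seq_len(J)) {
    delta <- cum_mass[j] - ref_cum_mass[j]
    if (delta >= 0) {
      out[j] <- cum_stock[j] - delta * conc[j] / 1000
    } else {
      if (j == J) {
        if (!extrapolate) {
          stop(sprintf(paste0(
            "mass deficit of %.3f Mg ha-1 at the deepest layer with no ",
            "layer below to borrow from; sample deeper or set ",
            "extrapolate = TRUE"), -delta), call. = FALSE)
        }
        out[j] <- cum_stock[j] - delta * conc[j] / 1000
        extr[j] <- TRUE
      } else {
        out[j] <- cum_stock[j] - delta * conc[j + 1] / 1000
      }
    }
  }
  list(cum_stock = out, extrapolated = extr)
}

# Stock rows for one profile and one method.
profile_stock_rows <- function(profile, method, refs = NULL,
                               extrapolate = FALSE) {
  profile <- profile[order(profile$depth_top_cm), , drop = FALSE]
  kn <- profile_knots(profile)
  id <- profile[1, c("experiment", "treatment", "block", "plot", "time"),
                drop = FALSE]
  rownames(id) <- NULL
  if (method == "FD") {
    return(cbind(id,
      data.frame(layer_top_cm = profile$depth_top_cm,
                 layer_bottom_cm = profile$depth_bottom_cm,
                 method = "FD",
                 soil_mass_Mg_ha = kn$mass,
                 stock_MgC_ha = kn$stock,
                 cum_mass_Mg_ha = kn$cum_mass,
                 cum_stock_MgC_ha = kn$cum_stock,
                 extrapolated_flag = FALSE)))
  }
  if (is.null(refs)) stop("ESM methods need a reference-mass table",
                          call. = FALSE)
  r <- refs[refs$treatment == id$treatment, , drop = FALSE]
  if (nrow(r) == 0) {
    stop("no reference masses for treatment ", id$treatment, call. = FALSE)
  }
  r <- r[order(r$layer_index), , drop = FALSE]
  extr <- rep(FALSE, nrow(r))
  if (method == "ESM_spline") {
    sp <- esm_spline_cum(kn$cum_mass, kn$cum_stock, r$cum_ref_mass_Mg_ha,
                         extrapolate = extrapolate)
    cum <- sp$cum_stock
    extr <- sp$extrapolated
  } else if (method == "ESM_classical") {
    cl <- esm_classical_cum(kn$cum_mass, kn$cum_stock, kn$conc,
                            r$cum_ref_mass_Mg_ha, extrapolate = extrapolate)
    cum <- cl$cum_stock
    extr <- cl$extrapolated
  } else {
    stop("unknown stock method '", method, "'", call. = FALSE)
  }
  layer_stock <- diff(c(0, cum))
  if (any(layer_stock < 0) && all(profile$c_g_kg >= 0)) {
    warning("negative interpolated layer stock (spline overshoot) for plot ",
            id$plot, " at time ", id$time, "; reported as-is", call. = FALSE)
  }
  cbind(id,
    data.frame(layer_top_cm = r$layer_top_cm,
               layer_bottom_cm = r$layer_bottom_cm,
               method = method,
               soil_mass_Mg_ha = r$ref_mass_Mg_ha,
               stock_MgC_ha = layer_stock,
               cum_mass_Mg_ha = r$cum_ref_mass_Mg_ha,
               cum_stock_MgC_ha = cum,
               extrapolated_flag = extr))
}

#' Compute FD and ESM stocks for every profile
#'
#' Runs the fixed-depth, classical-ESM and spline-ESM stock engines over all
#' plots and times of a profile set. ESM rows are labelled with the "ESM
#' depth" intervals: the t0 fixed-depth boundaries whose reference masses the
#' ESM layers represent.
#'
#' @inheritParams reference_masses
#' @param refs optional reference-mass table (e.g. a published one); defaults
#'   to [reference_masses()] computed from the t0 profiles.
#' @param methods subset of \code{c("FD", "ESM_classical", "ESM_spline")}.
#' @param extrapolate passed to [esm_spline_cum()].
#' @return a stock table: one row per plot x time x layer x method with
#'   columns \code{experiment, treatment, block, plot, time, layer_top_cm,
#'   layer_bottom_cm, method, soil_mass_Mg_ha, stock_MgC_ha, cum_mass_Mg_ha,
#'   cum_stock_MgC_ha, extrapolated_flag}.
#' @export
stocks_pipeline <- function(profiles, refs = NULL,
                            methods = c("FD", "ESM_classical", "ESM_spline"),
                            extrapolate = FALSE, t0_label = "t0") {
  methods <- match.arg(methods, c("FD", "ESM_classical", "ESM_spline"),
                       several.ok = TRUE)
  if (is.null(refs) && any(methods != "FD")) {
    refs <- reference_masses(profiles, t0_label = t0_label)
  }
  parts <- split_profiles(profiles)
  out <- do.call(rbind, unlist(lapply(parts, function(p) {
    lapply(methods, function(m) {
      profile_stock_rows(p, m, refs = refs, extrapolate = extrapolate)
    })
  }), recursive = FALSE))
  rownames(out) <- NULL
  out
}
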