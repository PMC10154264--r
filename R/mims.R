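#' Construct a MIMS chamber gas trace
#'
#' Annotated time series of dissolved O2 and CO2-isotopologue concentrations
#' from a closed, stirred, pH-buffered chamber, with dark/light segment labels
#' and chamber metadata. Concentrations are micromolar, time in seconds.
#'
#' @param time strictly increasing numeric vector, seconds.
#' @param o2 dissolved O2, micromolar.
#' @param co2_45,co2_47,co2_49 CO2 isotopologue concentrations, micromolar
#'   (m/z 45 = 13C16O16O, 47 = 13C16O18O, 49 = 13C18O18O).
#' @param segment character vector of segment labels (e.g. `"dark1"`,
#'   `"light1"`); any label containing `"light"` is treated as illuminated.
#' @param cell_density cells per cubic metre of chamber volume (0 for
#'   cell-free traces).
#' @param chamber_volume_mL chamber volume, millilitres (metadata only; rates
#'   are computed per cell via `cell_density`).
#' @param conditions a [seawater_conditions()] object.
#' @return Object of class `"mims_trace"`: a data.frame with attributes
#'   `cell_density`, `chamber_volume_mL`, `conditions`.
#' @export
mims_trace <- function(time, o2, co2_45, co2_47 = 0 * time, co2_49 = 0 * time,
                       segment, cell_density, chamber_volume_mL = 8,
                       conditions) {
  stopifnot(is.numeric(time), length(time) >= 2)
  if (any(diff(time) <= 0)) stop("time must be strictly increasing")
  n <- length(time)
  stopifnot(length(o2) == n, length(co2_45) == n, length(co2_47) == n,
            length(co2_49) == n, length(segment) == n)
  if (min(o2, co2_45, co2_47, co2_49) < -1e-9)
    stop("negative concentrations in trace")
  stopifnot(inherits(conditions, "seawater_conditions"),
            is.numeric(cell_density), cell_density >= 0)
  df <- data.frame(time_s = time, o2_uM = o2, co2_45_uM = co2_45,
                   co2_47_uM = co2_47, co2_49_uM = co2_49,
                   segment = as.character(segment),
                   stringsAsFactors = FALSE)
  structure(df, cell_density = cell_density,
            chamber_volume_mL = chamber_volume_mL,
            conditions = conditions,
            class = c("mims_trace", "data.frame"))
}

#' @export
print.mims_trace <- function(x, ...) {
  segs <- rle(x$segment)$values
  cat(sprintf("MIMS trace: %d samples over %.0f s; segments: %s\n",
              nrow(x), diff(range(x$time_s)), paste(segs, collapse = " -> ")))
  cat(sprintf("  cell density %.3g cells/m^3, chamber %.1f mL, %.1f degC\n",
              attr(x, "cell_density"), attr(x, "chamber_volume_mL"),
              attr(x, "conditions")$temperature_C))
  invisible(x)
}

#' @export
plot.mims_trace <- function(x, ...) {
  graphics::par(mfrow = c(2, 1), mar = c(4, 4, 1, 1))
  graphics::plot(x$time_s, x$o2_uM, type = "l", xlab = "time (s)",
                 ylab = "O2 (uM)", ...)
  dark <- grepl("dark", x$segment)
  graphics::points(x$time_s[dark], x$o2_uM[dark], pch = ".", col = "grey40")
  tot <- x$co2_45_uM + x$co2_47_uM + x$co2_49_uM
  graphics::plot(x$time_s, tot, type = "l", xlab = "time (s)",
                 ylab = "total CO2 (uM)")
  invisible(x)
}

#' Read / write a MIMS trace as delimited text
#'
#' Tab-delimited UTF-8 with mandatory header
#' `time_s o2_uM co2_45_uM co2_47_uM co2_49_uM segment`; chamber metadata is
#' carried in `#`-prefixed key=value comment lines.
#'
#' @param trace a `"mims_trace"`.
#' @param path file path.
#' @return `read_mims_trace` returns a `"mims_trace"`;
#'   `write_mims_trace` returns `path` invisibly.
#' @export
write_mims_trace <- function(trace, path) {
  cond <- attr(trace, "conditions")
  hdr <- c(sprintf("# cell_density=%.10g", attr(trace, "cell_density")),
           sprintf("# chamber_volume_mL=%.10g", attr(trace, "chamber_volume_mL")),
           sprintf("# temperature_C=%.10g", cond$temperature_C),
           sprintf("# salinity=%.10g", cond$salinity),
           sprintf("# pH=%.10g", cond$pH))
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(hdr, con)
  utils::write.table(as.data.frame(trace), con, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' @rdname write_mims_trace
#' @export
read_mims_trace <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  meta_lines <- grep("^#", lines, value = TRUE)
  kv <- do.call(rbind, strsplit(sub("^#\\s*", "", meta_lines), "="))
  meta <- stats::setNames(as.numeric(kv[, 2]), kv[, 1])
  df <- utils::read.delim(textConnection(grep("^#", lines, value = TRUE,
                                              invert = TRUE)),
                          stringsAsFactors = FALSE)
  mims_trace(df$time_s, df$o2_uM, df$co2_45_uM, df$co2_47_uM, df$co2_49_uM,
             df$segment, cell_density = meta[["cell_density"]],
             chamber_volume_mL = meta[["chamber_volume_mL"]],
             conditions = seawater_conditions(meta[["temperature_C"]],
                                              meta[["salinity"]],
                                              meta[["pH"]]))
}

#' Per-cell rate from a trace segment
#'
#' Linear-regression slope of a gas channel over the quasi-steady tail of a
#' segment, converted to a per-cell molar rate. Positive = evolution into the
#' chamber, negative = consumption.
#'
#' @param trace a `"mims_trace"`.
#' @param segment segment label present in the trace.
#' @param channel one of `"o2"`, `"co2"` (total CO2), `"co2_45"`, `"co2_47"`,
#'   `"co2_49"`.
#' @param tail_fraction fraction of the segment (from its end) used as the
#'   quasi-steady fitting window; default 0.6.
#' @return list with `rate` (mol cell^-1 s^-1), `se` (standard error, same
#'   unit), `slope_uM_s`, `n`.
#' @export
segment_rate <- function(trace, segment, channel = "o2", tail_fraction = 0.6) {
  stopifnot(inherits(trace, "mims_trace"))
  idx <- which(trace$segment == segment)
  if (!length(idx)) stop("segment not found: ", segment)
  keep <- idx[idx >= idx[1] + floor((1 - tail_fraction) * length(idx))]
  if (length(keep) < 5) stop("fewer than 5 samples in the fitted window")
  dens <- attr(trace, "cell_density")
  if (dens <= 0) stop("cell density must be positive for per-cell rates")
  y <- switch(channel,
              o2 = trace$o2_uM,
              co2 = trace$co2_45_uM + trace$co2_47_uM + trace$co2_49_uM,
              co2_45 = trace$co2_45_uM,
              co2_47 = trace$co2_47_uM,
              co2_49 = trace$co2_49_uM,
              stop("unknown channel: ", channel))[keep]
  t <- trace$time_s[keep]
  fit <- stats::lm.fit(cbind(1, t), y)
  slope <- fit$coefficients[2]
  rss <- sum(fit$residuals^2)
  se_slope <- if (length(t) > 2)
    sqrt(rss / (length(t) - 2) / sum((t - mean(t))^2)) else NA_real_
  # uM/s -> mol m^-3 s^-1 is *1e-3; per cell divide by density (cells m^-3)
  conv <- 1e-3 / dens
  list(rate = unname(slope * conv), se = unname(se_slope * conv),
       slope_uM_s = unname(slope), n = length(t))
}

#' Daily net O2 evolution
#'
#' Day-integrated net O2 rate over a 16 h light : 8 h dark cycle, i.e.
#' `(2/3) * p_light + (1/3) * r_dark`.
#'
#' @param p_light net O2 evolution in the light, mol cell^-1 s^-1 (>= 0
#'   expected).
#' @param r_dark dark respiration, mol cell^-1 s^-1 (<= 0 expected,
#'   consumption negative).
#' @return mol O2 cell^-1 s^-1 averaged over the diel cycle.
#' @export
daily_net_o2 <- function(p_light, r_dark) {
  if (r_dark > 0 || p_light < 0)
    warning("expected r_dark <= 0 <= p_light; check sign conventions")
  (2 / 3) * p_light + (1 / 3) * r_dark
}

#' Partition inorganic-carbon uptake into CO2 and HCO3- components
#'
#' At light quasi-steady state (extracellular carbonic anhydrase inhibited),
#' cellular CO2 uptake is the observed chamber CO2 drawdown corrected for net
#' uncatalyzed chemical CO2 production `kr*[HCO3-] - kf*[CO2]`:
#' `u_co2 = (kr*B - kf*C - dC/dt) / density`. Total inorganic-carbon uptake is
#' set equal to net O2 evolution (photosynthetic quotient `pq`, default 1),
#' and `u_hco3 = total - u_co2`.
#'
#' @param trace a `"mims_trace"` containing a light segment.
#' @param carb a `"carb_system"` at the trace temperature.
#' @param dic_mM DIC loaded into the chamber (mM) at the reference time;
#'   required for the HCO3- bookkeeping below.
#' @param segment light segment label; default the first segment containing
#'   `"light"`.
#' @param pq photosynthetic quotient (mol O2 per mol C), default 1.
#' @param tail_fraction quasi-steady window, as in [segment_rate()].
#' @param t_ref time (s) at which the chamber held `dic_mM` (default: first
#'   sample of the trace). Bulk HCO3- at later times is reconstructed as
#'   DIC bookkeeping: carbon fixed since `t_ref` is read off the O2 channel
#'   (photosynthetic quotient `pq`), CO3(2-) is treated as a spectator at
#'   the clamped pH, and the measured CO2 is subtracted.
#' @return list with `u_co2`, `u_hco3` (mol cell^-1 s^-1), `co2_fraction`,
#'   `total_c_uptake`, `net_o2`, `bulk_co2_uM`, `bulk_hco3_uM`, and `flag`
#'   (character, non-empty when u_hco3 is negative beyond tolerance).
#' @export
partition_ci_uptake <- function(trace, carb, dic_mM, segment = NULL, pq = 1,
                                tail_fraction = 0.6, t_ref = NULL) {
  stopifnot(inherits(trace, "mims_trace"), inherits(carb, "carb_system"),
            is.numeric(dic_mM), dic_mM > 0)
  if (is.null(segment)) {
    segment <- grep("light", unique(trace$segment), value = TRUE)[1]
    if (is.na(segment)) stop("no light segment in trace")
  }
  dens <- attr(trace, "cell_density")
  net_o2 <- segment_rate(trace, segment, "o2", tail_fraction)$rate
  co2_sr <- segment_rate(trace, segment, "co2", tail_fraction)
  idx <- which(trace$segment == segment)
  keep <- idx[idx >= idx[1] + floor((1 - tail_fraction) * length(idx))]
  co2_t <- (trace$co2_45_uM + trace$co2_47_uM + trace$co2_49_uM)[keep]
  co2_uM <- mean(co2_t)
  # bulk HCO3- bookkeeping: HCO3(t) = [CO2 + HCO3 at t_ref] - C fixed - CO2(t)
  sp <- speciate_dic(dic_mM, carb)
  i_ref <- if (is.null(t_ref)) 1L else which.min(abs(trace$time_s - t_ref))
  o2_ref <- trace$o2_uM[i_ref]
  fixed_uM <- (trace$o2_uM[keep] - o2_ref) / pq
  hco3_t <- (sp[["co2"]] + sp[["hco3"]]) * 1e3 - fixed_uM - co2_t
  hco3_uM <- mean(hco3_t)
  if (hco3_uM <= 0) stop("DIC bookkeeping gives non-positive bulk HCO3-")
  # chemical source in mol m^-3 s^-1; concentrations uM -> *1e-3
  chem <- mean(carb$kr * hco3_t - carb$kf * co2_t) * 1e-3
  dCdt <- co2_sr$slope_uM_s * 1e-3
  u_co2 <- (chem - dCdt) / dens
  total <- net_o2 / pq
  u_hco3 <- total - u_co2
  flag <- ""
  if (u_hco3 < -0.05 * abs(total)) {
    flag <- "u_hco3 negative beyond tolerance: model/measurement inconsistency"
    warning(flag)
  }
  frac <- if (total != 0) u_co2 / total else NA_real_
  list(u_co2 = u_co2, u_hco3 = u_hco3, co2_fraction = frac,
       total_c_uptake = total, net_o2 = net_o2, bulk_co2_uM = co2_uM,
       bulk_hco3_uM = hco3_uM, flag = flag)
}

#' Cytosolic CO2 concentration from bulk CO2 and CO2 uptake
#'
#' Steady-state diffusive balance across the cell boundary:
#' `[CO2]cyt = [CO2]bulk - u_co2 / fc`, with `fc` the CO2 mass-transfer
#' coefficient of the cell (m^3 cell^-1 s^-1).
#'
#' @param co2_bulk bulk CO2, micromolar.
#' @param u_co2 cellular CO2 uptake, mol cell^-1 s^-1.
#' @param fc CO2 mass-transfer coefficient, m^3 cell^-1 s^-1 (> 0).
#' @return list with `co2_cyt_uM` and `flag` (non-empty if the estimate is
#'   negative, indicating inconsistent inputs; the value is not clipped).
#' @export
cytosolic_co2 <- function(co2_bulk, u_co2, fc) {
  if (fc <= 0) stop("fc must be positive")
  val <- co2_bulk - (u_co2 / fc) * 1e3   # mol/m^3 -> uM
  flag <- ""
  if (val < 0) {
    flag <- "negative cytosolic CO2: inputs inconsistent (u_co2/fc exceeds bulk)"
    warning(flag)
  }
  list(co2_cyt_uM = val, flag = flag)
}

#' Gross O2 evolution from net light rate and dark respiration
#'
#' `gross = net_light - r_dark` (respiration is negative, so gross =
#' net + |respiration|), assuming light respiration equals dark respiration.
#'
#' @param p_light net light O2 evolution, mol cell^-1 s^-1.
#' @param r_dark dark respiration (negative), mol cell^-1 s^-1.
#' @return gross O2 evolution, mol cell^-1 s^-1.
#' @export
gross_o2 <- function(p_light, r_dark) p_light - r_dark
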