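# High-throughput plate-reader kinetics: trace assembly from the two-CSV
# input convention, sliding-window initial-rate extraction, replicate
# statistics, and dose-response / reversibility classification.

#' Read a screening plate from raw + descriptor CSVs
#'
#' The raw CSV holds a `time_s` column plus one column per well; the
#' descriptor CSV annotates each well with columns `well, variant, metal,
#' conc_uM, edta, replicate, blank`. Wells present in the raw table but
#' missing from the descriptor are skipped with a warning; a descriptor
#' row referencing a missing raw well, or a duplicated well id, is an
#' error.
#'
#' @param raw_path path to the raw kinetics CSV.
#' @param descriptor_path path to the descriptor CSV.
#' @return a `plate_traces` list; each element has `$well` (descriptor
#'   row as a one-row data.frame), `$times` (s) and `$signal`.
#' @export
read_plate_csvs <- function(raw_path, descriptor_path) {
  raw <- utils::read.csv(raw_path, check.names = FALSE)
  if (!"time_s" %in% names(raw)) {
    stop("raw CSV must have a 'time_s' column")
  }
  desc <- utils::read.csv(descriptor_path, stringsAsFactors = FALSE)
  need <- c("well", "variant", "metal", "conc_uM", "edta", "replicate", "blank")
  miss <- setdiff(need, names(desc))
  if (length(miss)) {
    stop("descriptor CSV missing column(s): ", paste(miss, collapse = ", "))
  }
  if (anyDuplicated(desc$well)) {
    stop("duplicate well id(s) in descriptor: ",
         paste(unique(desc$well[duplicated(desc$well)]), collapse = ", "))
  }
  raw_wells <- setdiff(names(raw), "time_s")
  absent <- setdiff(desc$well, raw_wells)
  if (length(absent)) {
    stop("descriptor references well(s) missing from raw data: ",
         paste(absent, collapse = ", "))
  }
  orphan <- setdiff(raw_wells, desc$well)
  if (length(orphan)) {
    warning("skipping ", length(orphan), " undescribed well(s): ",
            paste(orphan, collapse = ", "))
  }
  traces <- lapply(seq_len(nrow(desc)), function(i) {
    w <- desc$well[i]
    structure(list(well = desc[i, , drop = FALSE],
                   times = raw$time_s, signal = raw[[w]]),
              class = "kinetic_trace")
  })
  structure(traces, class = "plate_traces")
}

#' Maximum slope of a kinetic trace by sliding-window regression
#'
#' Fits an ordinary-least-squares line over every contiguous window of
#' `window_size` timepoints and returns the maximum slope (ties: earliest
#' window). Non-finite points are dropped pairwise first; trailing points
#' at or above `saturation_ceiling` (detector saturation) are trimmed
#' before windowing.
#'
#' @param times numeric vector, seconds, strictly increasing.
#' @param signal numeric vector, same length (AU or RLU). Alternatively
#'   pass a `kinetic_trace` as `times` and leave `signal` missing.
#' @param window_size number of timepoints per regression window.
#' @param saturation_ceiling signal ceiling; `Inf` disables trimming.
#' @return list with `max_slope` (signal units per second),
#'   `window_start_time` (s) and `window_index`.
#' @export
sliding_window_max_slope <- function(times, signal = NULL, window_size = 5,
                                     saturation_ceiling = 3.5) {
  if (inherits(times, "kinetic_trace")) {
    signal <- times$signal
    times <- times$times
  }
  stopifnot(length(times) == length(signal), window_size >= 2)
  ok <- is.finite(times) & is.finite(signal)
  times <- times[ok]; signal <- signal[ok]
  # trim the saturated tail only (plateau at the detector ceiling)
  if (is.finite(saturation_ceiling)) {
    n <- length(signal)
    while (n > 0 && signal[n] >= saturation_ceiling) n <- n - 1
    times <- times[seq_len(n)]; signal <- signal[seq_len(n)]
  }
  n <- length(times)
  if (n < window_size) {
    stop("trace too short: ", n, " usable point(s), window needs ",
         window_size)
  }
  w <- window_size
  nw <- n - w + 1
  # rolling OLS slope via cumulative sums
  cx <- cumsum(c(0, times)); cy <- cumsum(c(0, signal))
  cxx <- cumsum(c(0, times^2)); cxy <- cumsum(c(0, times * signal))
  i0 <- seq_len(nw); i1 <- i0 + w
  sx <- cx[i1] - cx[i0]; sy <- cy[i1] - cy[i0]
  sxx <- cxx[i1] - cxx[i0]; sxy <- cxy[i1] - cxy[i0]
  slope <- (w * sxy - sx * sy) / (w * sxx - sx^2)
  k <- which.max(slope)  # earliest on ties
  list(max_slope = slope[k], window_start_time = times[k], window_index = k)
}

#' Extract per-well maximum slopes for a whole plate
#'
#' @param traces a `plate_traces` list from [read_plate_csvs()].
#' @param window_size sliding-window length (timepoints).
#' @param saturation_ceiling see [sliding_window_max_slope()].
#' @param blank_correct subtract the mean max-slope of blank wells from
#'   every well (off by default).
#' @return data.frame with the descriptor columns plus `slope` (per
#'   second), `slope_per_min`, and `window_start_time`.
#' @export
plate_rates <- function(traces, window_size = 5, saturation_ceiling = 3.5,
                        blank_correct = FALSE) {
  stopifnot(inherits(traces, "plate_traces"))
  rows <- lapply(traces, function(tr) {
    r <- sliding_window_max_slope(tr$times, tr$signal, window_size,
                                  saturation_ceiling)
    cbind(tr$well, slope = r$max_slope,
          window_start_time = r$window_start_time)
  })
  out <- do.call(rbind, rows)
  if (blank_correct) {
    bl <- out$slope[out$blank == 1]
    if (!length(bl)) stop("blank_correct = TRUE but the plate has no blank wells")
    out$slope <- out$slope - mean(bl)
  }
  out$slope_per_min <- out$slope * 60
  rownames(out) <- NULL
  out
}

#' Replicate statistics per reaction condition
#'
#' Averages per-well maximum slopes over replicates of each condition
#' (variant x metal x concentration x EDTA status), reporting the mean,
#' the sample standard deviation (n-1 denominator; 0 for a single
#' replicate) and the replicate count. Blank wells are excluded.
#'
#' @param rates data.frame from [plate_rates()].
#' @return data.frame with variant, metal, conc_uM, edta,
#'   mean_slope (per s), mean_slope_per_min, sd_slope, n_replicates.
#' @export
aggregate_condition <- function(rates) {
  stopifnot(is.data.frame(rates), nrow(rates) >= 1)
  rates <- rates[rates$blank != 1, , drop = FALSE]
  if (!nrow(rates)) stop("no non-blank wells to aggregate")
  key <- interaction(rates$variant, rates$metal, rates$conc_uM, rates$edta,
                     drop = TRUE, lex.order = TRUE)
  agg <- lapply(split(rates, key), function(g) {
    data.frame(variant = g$variant[1], metal = g$metal[1],
               conc_uM = g$conc_uM[1], edta = g$edta[1],
               mean_slope = mean(g$slope),
               sd_slope = if (nrow(g) > 1) stats::sd(g$slope) else 0,
               n_replicates = nrow(g), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, agg)
  out$mean_slope_per_min <- out$mean_slope * 60
  out <- out[order(out$variant, out$metal, out$edta, out$conc_uM), ]
  rownames(out) <- NULL
  out
}

#' Classify one variant's metal dose-response
#'
#' Rules: `inactive` when the apo (0 metal, no EDTA) rate falls below the
#' activity floor; otherwise `inhibited` when the rate at the highest
#' metal concentration is below 50% of the apo rate, `activated` when it
#' exceeds 150% of the apo rate, else `unresponsive`. The activity floor
#' is `floor_fraction` of `reference_rate` (e.g. a wild-type apo rate)
#' when one is supplied, otherwise the absolute floor.
#'
#' @param agg aggregated conditions from [aggregate_condition()].
#' @param variant,metal condition selectors.
#' @param reference_rate optional wild-type apo rate (same units as
#'   `mean_slope`).
#' @param floor_fraction activity floor as a fraction of the reference.
#' @param absolute_floor activity floor (per-second slope units) used when
#'   no reference is given.
#' @return a `dose_response` list: variant, metal, conc (uM grid),
#'   rate (mean slopes), normalized (rate/apo rate), classification,
#'   fold_change_low_high (apo / highest-concentration rate).
#' @export
classify_dose_response <- function(agg, variant, metal,
                                   reference_rate = NULL,
                                   floor_fraction = 0.05,
                                   absolute_floor = 1e-6) {
  g <- agg[agg$variant == variant & agg$metal == metal & agg$edta == 0, ,
           drop = FALSE]
  g <- g[order(g$conc_uM), , drop = FALSE]
  if (!any(g$conc_uM == 0)) {
    stop("no apo (conc 0) condition for variant '", variant, "' with metal '",
         metal, "'")
  }
  if (nrow(g) < 2) stop("need at least two concentrations to classify")
  apo <- g$mean_slope[g$conc_uM == 0][1]
  top <- g$mean_slope[which.max(g$conc_uM)]
  floorv <- if (!is.null(reference_rate)) floor_fraction * reference_rate
            else absolute_floor
  if (apo < floorv) {
    cls <- "inactive"
    normalized <- rep(NA_real_, nrow(g))
    fold <- NA_real_
  } else {
    ratio <- top / apo
    cls <- if (ratio < 0.5) "inhibited"
           else if (ratio > 1.5) "activated"
           else "unresponsive"
    normalized <- g$mean_slope / apo
    fold <- apo / top
  }
  structure(list(variant = variant, metal = metal, conc = g$conc_uM,
                 rate = g$mean_slope, normalized = normalized,
                 classification = cls, fold_change_low_high = fold),
            class = "dose_response")
}

#' Classify every variant x metal combination on a plate
#'
#' @param agg aggregated conditions from [aggregate_condition()].
#' @param reference_variant variant whose apo rate sets the activity
#'   floor (optional).
#' @inheritParams classify_dose_response
#' @return data.frame with variant, metal, classification,
#'   fold_change_low_high.
#' @export
classify_plate <- function(agg, reference_variant = NULL,
                           floor_fraction = 0.05, absolute_floor = 1e-6) {
  ref <- NULL
  if (!is.null(reference_variant)) {
    r <- agg[agg$variant == reference_variant & agg$conc_uM == 0 &
             agg$edta == 0, , drop = FALSE]
    if (!nrow(r)) stop("reference variant '", reference_variant,
                       "' has no apo condition")
    ref <- mean(r$mean_slope)
  }
  combos <- unique(agg[agg$edta == 0, c("variant", "metal")])
  rows <- lapply(seq_len(nrow(combos)), function(i) {
    dr <- classify_dose_response(agg, combos$variant[i], combos$metal[i],
                                 reference_rate = ref,
                                 floor_fraction = floor_fraction,
                                 absolute_floor = absolute_floor)
    data.frame(variant = dr$variant, metal = dr$metal,
               classification = dr$classification,
               fold_change_low_high = dr$fold_change_low_high,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' @export
print.dose_response <- function(x, ...) {
  cat(sprintf("Dose-response %s + %s: %s\n", x$variant, x$metal,
              x$classification))
  print(data.frame(conc_uM = x$conc, rate = x$rate,
                   normalized = x$normalized))
  invisible(x)
}

#' Fractional recovery of activity after chelator addition
#'
#' Measures reversibility of metal-dependent inhibition: 1 when EDTA fully
#' restores the apo rate, 0 when the post-EDTA rate equals the
#' metal-bound rate (irreversible, Fe(II)-like). When the metal-bound and
#' apo rates are indistinguishable (a non-responder) recovery is undefined
#' and flagged.
#'
#' @param rate_metal mean rate with metal.
#' @param rate_after_edta mean rate after subsequent EDTA treatment.
#' @param rate_apo mean apo rate.
#' @param tol relative tolerance for declaring apo and metal rates equal.
#' @return list with `recovery`, `after_over_apo`, and `defined` flag.
#' @export
reversibility_recovery <- function(rate_metal, rate_after_edta, rate_apo,
                                   tol = 1e-6) {
  denom <- rate_apo - rate_metal
  if (abs(denom) <= tol * max(abs(rate_apo), abs(rate_metal), tol)) {
    return(list(recovery = NA_real_,
                after_over_apo = rate_after_edta / rate_apo,
                defined = FALSE))
  }
  list(recovery = (rate_after_edta - rate_metal) / denom,
       after_over_apo = rate_after_edta / rate_apo,
       defined = TRUE)
}
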