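# End-to-end orchestration: run the pH and optical methods over time
# series, compare them at a reference time, and summarize a concentration
# sweep.

#' pH time series over the sebum layer
#'
#' A validated data frame of pH readings above the sebum column, sampled
#' at strictly increasing times (the reference protocol records one
#' reading per minute for four hours).
#'
#' @param time_min Times in minutes, strictly increasing.
#' @param ph pH readings, each in (0, 14), same length as `time_min`.
#' @param concentration_label Optional label, e.g. `"0.5%"`.
#' @param replicate_id Optional replicate identifier.
#' @return A data frame of class `ph_series` with columns `time_min`, `ph`.
#' @export
ph_series <- function(time_min, ph, concentration_label = NA_character_,
                      replicate_id = NA_character_) {
  stopifnot(is.numeric(time_min), is.numeric(ph))
  if (length(time_min) != length(ph))
    stop("time_min and ph must have the same length")
  if (length(time_min) == 0L) stop("empty pH series")
  if (any(diff(time_min) <= 0)) stop("times must be strictly increasing")
  if (any(!is.finite(ph)) || any(ph <= 0) || any(ph >= 14))
    stop("pH values must lie in (0, 14)")
  structure(data.frame(time_min = time_min, ph = ph),
            class = c("ph_series", "data.frame"),
            concentration_label = concentration_label,
            replicate_id = replicate_id)
}

#' Set of replicate layer-height time series
#'
#' Replicated optical measurements for one concentration: each replicate
#' is a data frame with columns `time_min`, `h_penetration_mm`,
#' `h_increase_mm` on a common time grid.
#'
#' @param replicates List of replicate data frames (>= 1); identical
#'   `time_min` grids required.
#' @param concentration_label Optional label.
#' @return An object of class `height_series_set`.
#' @export
height_series_set <- function(replicates,
                              concentration_label = NA_character_) {
  stopifnot(is.list(replicates), length(replicates) >= 1L)
  need <- c("time_min", "h_penetration_mm", "h_increase_mm")
  for (r in replicates) {
    if (!all(need %in% names(r)))
      stop("each replicate needs columns: ", paste(need, collapse = ", "))
    if (any(r$h_penetration_mm < 0) || any(r$h_increase_mm < 0))
      stop("heights must be non-negative")
  }
  t0 <- replicates[[1]]$time_min
  for (r in replicates[-1])
    if (!isTRUE(all.equal(r$time_min, t0)))
      stop("replicate time grids differ")
  structure(list(replicates = replicates,
                 concentration_label = concentration_label),
            class = "height_series_set")
}

#' Volume time series
#'
#' The common output currency of both quantification methods: per-time
#' volumes in mm^3. pH-method series carry `reacted_mm3` (+ `sd_mm3`);
#' optical series carry `v_penetrated_mm3`, `v_increased_mm3` and their
#' SDs across replicates.
#'
#' @param df Data frame with a `time_min` column and the volume columns
#'   for the given method.
#' @param method `"ph"` or `"optical"`.
#' @param concentration_label Optional label.
#' @return A data frame of class `volume_series` with a `method`
#'   attribute.
#' @export
volume_series <- function(df, method = c("ph", "optical"),
                          concentration_label = NA_character_) {
  method <- match.arg(method)
  stopifnot(is.data.frame(df), "time_min" %in% names(df))
  vol_cols <- if (method == "ph") "reacted_mm3" else
    c("v_penetrated_mm3", "v_increased_mm3")
  if (!all(vol_cols %in% names(df)))
    stop("missing volume columns: ",
         paste(setdiff(vol_cols, names(df)), collapse = ", "))
  for (cl in vol_cols)
    if (any(df[[cl]] < 0, na.rm = TRUE))
      stop("volumes must be non-negative (column ", cl, ")")
  structure(df, class = c("volume_series", "data.frame"),
            method = method, concentration_label = concentration_label)
}

#' Reacted sebum volume series from a pH series (pH method)
#'
#' Applies the stoichiometric chain [ph_to_reacted_volume()] to every time
#' point, using the pH at the first time point as the unreacted baseline
#' (the measured starting state, rather than the nominal prepared
#' concentration). The `sd_mm3` column propagates the pH-meter accuracy:
#' the chain is evaluated at `ph +/- ph_accuracy` and half the spread is
#' reported, which is how a replicate-free pH run still carries an
#' uncertainty.
#'
#' @param series A [ph_series()].
#' @param amine An [alcoholamine_spec()].
#' @param Vr Solution volume, dm^3 (default 0.003).
#' @param sebum A [sebum_composition()].
#' @param direction,policy Passed to [ph_to_reacted_volume()].
#' @param ph_accuracy Instrument accuracy in pH units (default 0.01).
#' @return A [volume_series()] with columns `time_min`, `reacted_mm3`,
#'   `sd_mm3`; the value at the first time point is exactly 0.
#' @export
run_ph_method <- function(series, amine = alcoholamine_spec(), Vr = 0.003,
                          sebum = sebum_composition(),
                          direction = c("physical", "as_printed"),
                          policy = c("clamp", "raw"),
                          ph_accuracy = 0.01) {
  stopifnot(inherits(series, "ph_series"))
  direction <- match.arg(direction)
  policy <- match.arg(policy)
  ph0 <- series$ph[1]
  v <- ph_to_reacted_volume(ph0, series$ph, amine, Vr, sebum,
                            direction = direction, policy = policy)
  # device-accuracy propagation: lower pH reading -> larger apparent volume
  v_lo <- ph_to_reacted_volume(ph0, pmax(series$ph - ph_accuracy, 1e-6),
                               amine, Vr, sebum,
                               direction = direction, policy = policy)
  v_hi <- ph_to_reacted_volume(ph0, pmin(series$ph + ph_accuracy, 13.999),
                               amine, Vr, sebum,
                               direction = direction, policy = policy)
  df <- data.frame(time_min = series$time_min,
                   reacted_mm3 = as.numeric(v),
                   sd_mm3 = abs(as.numeric(v_lo) - as.numeric(v_hi)) / 2)
  out <- volume_series(df, "ph",
                       attr(series, "concentration_label"))
  attr(out, "clamped") <- attr(v, "clamped")
  out
}

#' Penetrated and increased volume series from replicate heights
#' (optical method)
#'
#' Converts each replicate's layer heights to cylinder volumes and
#' aggregates across replicates as mean +/- sample SD (n - 1 denominator;
#' SD is `NA` for a single replicate).
#'
#' @param heights A [height_series_set()].
#' @param geometry A [tube_geometry()].
#' @return A [volume_series()] with columns `time_min`,
#'   `v_penetrated_mm3`, `sd_penetrated_mm3`, `v_increased_mm3`,
#'   `sd_increased_mm3`.
#' @export
run_optical_method <- function(heights, geometry = tube_geometry()) {
  stopifnot(inherits(heights, "height_series_set"))
  reps <- heights$replicates
  pen <- sapply(reps, function(r) cylinder_volume(r$h_penetration_mm, geometry))
  inc <- sapply(reps, function(r) cylinder_volume(r$h_increase_mm, geometry))
  pen <- matrix(pen, ncol = length(reps))
  inc <- matrix(inc, ncol = length(reps))
  sd_or_na <- function(m) {
    if (ncol(m) < 2L) rep(NA_real_, nrow(m)) else apply(m, 1, stats::sd)
  }
  df <- data.frame(time_min = reps[[1]]$time_min,
                   v_penetrated_mm3 = rowMeans(pen),
                   sd_penetrated_mm3 = sd_or_na(pen),
                   v_increased_mm3 = rowMeans(inc),
                   sd_increased_mm3 = sd_or_na(inc))
  volume_series(df, "optical", heights$concentration_label)
}

#' Compare the optical and pH methods at a reference time
#'
#' Looks up the optical penetrated volume and the pH-derived reacted
#' volume at `at_time` and reports their difference (optical minus
#' pH-derived). A negative difference — the pH method inferring more
#' consumed amine than the optically visible etching can account for —
#' is flagged as evidence of a rigid product plug at the interface.
#'
#' @param optical An optical [volume_series()].
#' @param ph_based A pH-method [volume_series()].
#' @param at_time Reference time in minutes (default 216).
#' @return An object of class `method_comparison`: list with
#'   `concentration_label`, `time_min`, `optical_mm3`, `ph_mm3`,
#'   `difference_mm3`, `plug_flag`.
#' @export
compare_methods <- function(optical, ph_based, at_time = 216) {
  stopifnot(inherits(optical, "volume_series"),
            inherits(ph_based, "volume_series"))
  if (attr(optical, "method") != "optical" ||
      attr(ph_based, "method") != "ph")
    stop("expected an optical series and a pH-method series, in that order")
  i_o <- match(at_time, optical$time_min)
  i_p <- match(at_time, ph_based$time_min)
  if (is.na(i_o) || is.na(i_p))
    stop("reference time ", at_time, " min not covered by both series")
  o <- optical$v_penetrated_mm3[i_o]
  p <- ph_based$reacted_mm3[i_p]
  structure(list(concentration_label = attr(optical, "concentration_label"),
                 time_min = at_time,
                 optical_mm3 = o,
                 ph_mm3 = p,
                 difference_mm3 = o - p,
                 plug_flag = (o - p) < 0),
            class = "method_comparison")
}

#' @export
print.method_comparison <- function(x, ...) {
  cat(sprintf(
    "Method comparison (%s) at %g min: optical %.2f mm^3, pH-derived %.2f mm^3, difference %.2f mm^3%s\n",
    ifelse(is.na(x$concentration_label), "-", x$concentration_label),
    x$time_min, x$optical_mm3, x$ph_mm3, x$difference_mm3,
    if (x$plug_flag) " [plug]" else ""))
  invisible(x)
}

#' Summarize a concentration sweep
#'
#' Collates per-concentration comparisons and optical volume series into a
#' ranking of concentrations by final penetrated volume. Concentrations
#' whose comparison carries a plug flag are excluded from the favourable
#' ranking (`rank = NA`). A depletion indicator marks series whose
#' penetrated volume plateaus before the end of observation (growth over
#' the final tenth of the observation window below `plateau_tol` of the
#' final volume), the signature of the amine running out at low
#' concentrations.
#'
#' @param comparisons List of [compare_methods()] results, one per
#'   concentration.
#' @param volumes List of optical [volume_series()], same order.
#' @param plateau_tol Relative growth threshold for the plateau indicator
#'   (default 0.01).
#' @return A data frame with one row per concentration: label, final
#'   penetrated volume, `depleted`, `plug`, and `rank` (1 = largest final
#'   penetrated volume among plug-free concentrations).
#' @export
concentration_sweep_summary <- function(comparisons, volumes,
                                        plateau_tol = 0.01) {
  stopifnot(is.list(comparisons), is.list(volumes),
            length(comparisons) == length(volumes))
  n <- length(comparisons)
  lab <- vapply(comparisons, function(x) {
    if (is.na(x$concentration_label)) "" else x$concentration_label
  }, character(1))
  final_v <- vapply(volumes, function(v) {
    v$v_penetrated_mm3[nrow(v)]
  }, numeric(1))
  plug <- vapply(comparisons, function(x) isTRUE(x$plug_flag), logical(1))
  depleted <- vapply(volumes, function(v) {
    if (nrow(v) < 3L) return(FALSE)
    t_end <- v$time_min[nrow(v)]
    t_win <- t_end - 0.1 * (t_end - v$time_min[1])
    i <- max(which(v$time_min <= t_win))
    vf <- v$v_penetrated_mm3[nrow(v)]
    vf > 0 && (vf - v$v_penetrated_mm3[i]) / vf < plateau_tol
  }, logical(1))
  rank_v <- rep(NA_integer_, n)
  ok <- !plug
  rank_v[ok] <- rank(-final_v[ok], ties.method = "first")
  data.frame(concentration_label = lab,
             final_penetrated_mm3 = final_v,
             depleted = depleted,
             plug = plug,
             rank = rank_v)
}

#' Turbidity time series
#'
#' Apparent absorbance (850 nm) of the solution above the sebum layer,
#' driven by suspended reacted-sebum particles.
#'
#' @param time_h Times in hours, strictly increasing.
#' @param absorbance Non-negative absorbance values.
#' @param concentration_pct Numeric concentration, % w/w (used for
#'   cross-series ordering checks).
#' @return A data frame of class `turbidity_series`.
#' @export
turbidity_series <- function(time_h, absorbance, concentration_pct) {
  stopifnot(is.numeric(time_h), is.numeric(absorbance),
            length(time_h) == length(absorbance))
  if (any(diff(time_h) <= 0)) stop("times must be strictly increasing")
  if (any(!is.finite(absorbance)) || any(absorbance < 0))
    stop("absorbance must be non-negative")
  structure(data.frame(time_h = time_h, absorbance = absorbance),
            class = c("turbidity_series", "data.frame"),
            concentration_pct = concentration_pct)
}

#' Check the expected turbidity trends
#'
#' Verifies the two monotonicities that characterize the suspension of
#' reacted sebum particles: within each concentration the turbidity is
#' non-decreasing in time, and at each common time point the turbidity is
#' non-increasing as the amine concentration increases (thicker, denser
#' product layers hold the particles back). Violations are reported, not
#' raised.
#'
#' @param series_list List of [turbidity_series()] on a common time grid.
#' @return A list of class `turbidity_trend_report` with elements `ok`
#'   (logical) and `violations` (data frame: `type`,
#'   `concentration_pct`, `time_h`).
#' @export
turbidity_trend_check <- function(series_list) {
  stopifnot(is.list(series_list), length(series_list) >= 1L)
  grid <- series_list[[1]]$time_h
  for (s in series_list[-1])
    if (!isTRUE(all.equal(s$time_h, grid)))
      stop("turbidity series must share a common time grid")
  conc <- vapply(series_list, function(s) attr(s, "concentration_pct"),
                 numeric(1))
  ord <- order(conc)
  viol <- data.frame(type = character(0), concentration_pct = numeric(0),
                     time_h = numeric(0))
  for (s in series_list) {
    bad <- which(diff(s$absorbance) < 0)
    if (length(bad))
      viol <- rbind(viol, data.frame(
        type = "not_increasing_in_time",
        concentration_pct = attr(s, "concentration_pct"),
        time_h = s$time_h[bad + 1L]))
  }
  if (length(series_list) >= 2L) {
    a <- sapply(series_list[ord], function(s) s$absorbance)
    a <- matrix(a, ncol = length(series_list))
    for (i in seq_along(grid)) {
      bad <- which(diff(a[i, ]) > 0)
      if (length(bad))
        viol <- rbind(viol, data.frame(
          type = "not_decreasing_in_concentration",
          concentration_pct = conc[ord][bad + 1L],
          time_h = grid[i]))
    }
  }
  structure(list(ok = nrow(viol) == 0L, violations = viol),
            class = "turbidity_trend_report")
}

#' @export
print.turbidity_trend_report <- function(x, ...) {
  if (x$ok) cat("Turbidity trends: OK (no violations)\n")
  else {
    cat("Turbidity trends:", nrow(x$violations), "violation(s)\n")
    print(x$violations)
  }
  invisible(x)
}
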