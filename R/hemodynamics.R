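#' Percent change relative to baseline
#'
#' @param value measured value(s).
#' @param baseline_value the baseline value (non-zero).
#' @return `(value / baseline_value - 1) * 100`, in percent.
#' @export
relative_change <- function(value, baseline_value) {
  if (any(baseline_value == 0)) stop("baseline must be non-zero")
  (value / baseline_value - 1) * 100
}

#' Arteriole-venule flow-conservation fit
#'
#' In a closed vascular bed the volumetric flow entering through arterioles
#' equals the flow leaving through venules, so their relative flow changes
#' over time should be correlated. This fits venule percent flow change on
#' arteriole percent flow change by ordinary least squares and reports the
#' squared Pearson correlation.
#'
#' @param arteriole_dq numeric vector of arteriole flow changes (%).
#' @param venule_dq paired venule flow changes (%), same length >= 3.
#' @return list `slope`, `intercept`, `r_squared`, `n`.
#' @export
flow_conservation_fit <- function(arteriole_dq, venule_dq) {
  if (length(arteriole_dq) != length(venule_dq)) {
    stop("series must be paired (equal length)")
  }
  if (length(arteriole_dq) < 3) stop("need at least 3 paired points")
  if (stats::sd(arteriole_dq) == 0) {
    stop("zero-variance predictor: conservation fit undefined")
  }
  fit <- stats::lm(venule_dq ~ arteriole_dq)
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       r_squared = stats::cor(arteriole_dq, venule_dq)^2,
       n = length(arteriole_dq))
}

#' Percent change of the V/D-squared ratio across timepoints
#'
#' Since flow is proportional to `V * D^2`, the ratio `V / D^2` separates
#' the two independently measured contributions to a flow change: positive
#' changes mean the flow change is velocity-dominated (arteriole-like
#' behaviour), negative changes mean diameter-dominated (venule-like).
#'
#' @param velocity_mm_s per-timepoint velocities, baseline first.
#' @param diameter_um per-timepoint diameters, baseline first.
#' @return percent change of `V/D^2` relative to baseline, one per
#'   timepoint (0 at baseline by construction).
#' @export
v_over_d2_ratio <- function(velocity_mm_s, diameter_um) {
  if (length(velocity_mm_s) != length(diameter_um)) {
    stop("velocity and diameter series must align")
  }
  if (any(diameter_um <= 0)) stop("diameters must be positive")
  ratio <- velocity_mm_s / diameter_um^2
  relative_change(ratio, ratio[1])
}

#' Per-timepoint cohort summary (mean, SD, n)
#'
#' Arithmetic mean and sample standard deviation (n-1 denominator) of one
#' metric at each timepoint across a cohort of vessels or cells; `sd` is
#' `NA` where n = 1.
#'
#' @param data data.frame with columns `timepoint` and the metric.
#' @param metric name of the metric column.
#' @param timepoint_levels optional ordering of timepoint labels (default:
#'   order of first appearance).
#' @return data.frame `timepoint, n, mean, sd`.
#' @export
summarize_cohort <- function(data, metric,
                             timepoint_levels = unique(data$timepoint)) {
  if (!metric %in% names(data)) stop("no column '", metric, "'")
  if (nrow(data) == 0) stop("need at least one observation")
  tp <- factor(data$timepoint, levels = timepoint_levels)
  vals <- split(data[[metric]], tp)
  out <- data.frame(
    timepoint = timepoint_levels,
    n = vapply(vals, length, integer(1)),
    mean = vapply(vals, function(v) mean(v), numeric(1)),
    sd = vapply(vals, function(v) if (length(v) > 1) stats::sd(v) else
      NA_real_, numeric(1))
  )
  rownames(out) <- NULL
  out
}

#' Build longitudinal relative-change series from vessel measurements
#'
#' Given a table of per-vessel, per-timepoint measurements (as produced by
#' [vessel_measurement()]), computes for every vessel the percent change of
#' velocity, diameter and flow relative to its own baseline (the first
#' timepoint level), plus the `V/D^2` ratio change.
#'
#' @param measurements data.frame with `vessel_id, vessel_type, timepoint,
#'   velocity_mm_s, diameter_um, flow_nl_s`.
#' @param timepoint_levels ordered timepoint labels; the first is baseline.
#' @return data.frame adding `dv_pct, dd_pct, dq_pct, v_over_d2_pct`.
#' @export
longitudinal_changes <- function(measurements,
                                 timepoint_levels =
                                   unique(measurements$timepoint)) {
  out <- lapply(split(measurements, measurements$vessel_id), function(m) {
    m <- m[match(timepoint_levels, m$timepoint), ]
    if (anyNA(m$vessel_id)) {
      stop("vessel ", m$vessel_id[!is.na(m$vessel_id)][1],
           " is missing a timepoint (baseline must be present)")
    }
    m$dv_pct <- relative_change(m$velocity_mm_s, m$velocity_mm_s[1])
    m$dd_pct <- relative_change(m$diameter_um, m$diameter_um[1])
    m$dq_pct <- relative_change(m$flow_nl_s, m$flow_nl_s[1])
    m$v_over_d2_pct <- v_over_d2_ratio(m$velocity_mm_s, m$diameter_um)
    m
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Friedman test across timepoints for a cohort metric
#'
#' Repeated-measures rank test of whether a metric changes across
#' timepoints, each vessel (or mouse) serving as its own block. Delegated
#' to [stats::friedman.test()]; reported alongside the descriptive
#' summaries.
#'
#' @param data data.frame with `vessel_id`, `timepoint` and the metric.
#' @param metric metric column name.
#' @return the `htest` object from [stats::friedman.test()].
#' @export
cohort_friedman_test <- function(data, metric) {
  stats::friedman.test(data[[metric]],
                       groups = factor(data$timepoint,
                                       levels = unique(data$timepoint)),
                       blocks = factor(data$vessel_id))
}

#' Simulate a flow-conserving arteriole/venule cohort
#'
#' Generates paired arteriole and venule flow series over ordered
#' timepoints under exact conservation: in each replicate (vascular bed)
#' both vessels share the same true flow change at every timepoint, drawn
#' per replicate around a cohort-level time course; measured flows then get
#' independent multiplicative noise. The default time course follows an
#' inflammation-like rise and resolution (baseline, then roughly +30%,
#' +67%, +20%, +5% with between-replicate spread), and the default
#' measurement noise is 5% per flow reading.
#'
#' @param n_replicates number of arteriole/venule pairs (default 6).
#' @param timepoints ordered labels (default baseline, 6h, 24h, 72h, 10d).
#' @param mean_dq_pct cohort-mean true flow change (%) per timepoint.
#' @param sd_dq_pct between-replicate SD (%) of the true change.
#' @param noise_frac multiplicative measurement noise SD (default 0.05).
#' @param rng_seed integer seed.
#' @return list `arteriole_dq`, `venule_dq` (n_replicates x n_timepoints
#'   matrices of measured percent flow changes), `true_dq` (the shared true
#'   changes), `timepoints`.
#' @export
simulate_conserved_cohort <- function(n_replicates = 6,
                                      timepoints = c("baseline", "6h",
                                                     "24h", "72h", "10d"),
                                      mean_dq_pct = c(0, 30, 67, 20, 5),
                                      sd_dq_pct = 25,
                                      noise_frac = 0.05, rng_seed = 1L) {
  stopifnot(length(mean_dq_pct) == length(timepoints))
  with_seed(rng_seed, {
    nt <- length(timepoints)
    true_dq <- matrix(0, n_replicates, nt)
    for (j in 2:nt) {
      true_dq[, j] <- stats::rnorm(n_replicates, mean_dq_pct[j], sd_dq_pct)
    }
    measure <- function() {
      # measured flow = true flow x lognormal-ish noise, at every timepoint
      # including baseline; changes recomputed against the noisy baseline
      q_true <- 1 + true_dq / 100
      noise <- matrix(1 + stats::rnorm(n_replicates * nt, 0, noise_frac),
                      n_replicates, nt)
      q_meas <- q_true * noise
      (q_meas / q_meas[, 1] - 1) * 100
    }
    list(arteriole_dq = measure(), venule_dq = measure(),
         true_dq = true_dq, timepoints = timepoints)
  })
}
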