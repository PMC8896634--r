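## Residency windows and propensity-shift metrics.
##
## A residency window is one amino acid's tenure at one site: accepted at
## substitution i, replaced at substitution j, so the resident-propensity
## series covers states i .. j-1 (length T_res = j - i, time in jump-chain
## substitutions anywhere in the protein). M_SLR is the least-squares slope
## of the series against substitution index; M_AMI is its mean minus its
## value at acceptance.

#' Construct a residency window
#'
#' @param site Site index.
#' @param aa Resident amino acid (one-letter code).
#' @param i,j Acceptance and replacement substitution indices (j = i + T_res).
#' @param series Propensity series over states i .. j-1 (length j - i).
#' @param complete Whether the residue was both accepted and replaced within
#'   the simulation.
#' @return An object of class `residency_window`.
#' @export
residency_window <- function(site, aa, i, j, series, complete = TRUE) {
  stopifnot(j - i >= 1, length(series) == j - i)
  structure(list(site = site, aa = aa, i = i, j = j, T_res = j - i,
                 series = as.numeric(series), complete = complete),
            class = "residency_window")
}

#' @export
print.residency_window <- function(x, ...) {
  cat(sprintf("residency_window: site %d, %s, steps %d..%d (T_res = %d%s)\n",
              x$site, x$aa, x$i, x$j, x$T_res,
              if (x$complete) "" else ", partial"))
  invisible(x)
}

#' Extract residency windows from a trajectory
#'
#' One window per (site, tenure) episode. A window is complete when the
#' amino acid was accepted after the start of the recorded trajectory and
#' replaced before its end; truncated episodes are excluded unless
#' `complete_only = FALSE`.
#'
#' @param traj A [simulate_trajectory()] record.
#' @param min_residency Minimum T_res in substitutions (default 10).
#' @param complete_only Keep only complete windows (default TRUE).
#' @return List of [residency_window()]s.
#' @export
extract_windows <- function(traj, min_residency = 10L, complete_only = TRUE) {
  n <- traj$n
  aa <- aa_alphabet()
  out <- vector("list", 64L)
  k <- 0L
  for (h in seq_len(traj$L)) {
    r <- traj$resident_aa[, h]
    runs <- rle(r)
    ends <- cumsum(runs$lengths)          # state index + 1 (rows are 0-based)
    starts <- ends - runs$lengths + 1L
    for (e in seq_along(runs$lengths)) {
      s_state <- starts[e] - 1L           # first state of the tenure
      e_state <- ends[e] - 1L             # last state of the tenure
      T_res <- e_state - s_state + 1L
      complete <- s_state > 0L && e_state < n
      if (T_res < min_residency) next
      if (complete_only && !complete) next
      k <- k + 1L
      if (k > length(out)) out <- c(out, vector("list", length(out)))
      out[[k]] <- residency_window(
        site = h, aa = aa[runs$values[e]],
        i = s_state, j = e_state + 1L,
        series = traj$resident_prop[(s_state:e_state) + 1L, h],
        complete = complete)
    }
  }
  out[seq_len(k)]
}

#' Slope-of-linear-regression shift metric
#'
#' Ordinary least-squares slope of the propensity series against
#' substitution index, in propensity per substitution.
#'
#' @param window A [residency_window()] (or plain numeric series).
#' @return Slope; requires at least 2 points.
#' @export
m_slr <- function(window) {
  y <- if (inherits(window, "residency_window")) window$series else window
  T_res <- length(y)
  if (T_res < 2) stop("M_SLR needs a residency of at least 2 substitutions")
  x <- seq_len(T_res)
  xc <- x - mean(x)
  sum(xc * (y - mean(y))) / sum(xc^2)
}

#' Average-minus-initial shift metric
#'
#' Mean of the propensity series during residency (acceptance step
#' included) minus the propensity at acceptance.
#'
#' @inheritParams m_slr
#' @return Dimensionless propensity difference.
#' @export
m_ami <- function(window) {
  y <- if (inherits(window, "residency_window")) window$series else window
  mean(y) - y[1]
}

#' Half-window rate of propensity change
#'
#' Computes the chosen metric on the first and second halves of the window
#' (for odd T_res the first half gets the extra point) and returns
#' (|M2| - |M1|) / T_res: positive when the change concentrates late,
#' negative when it concentrates early.
#'
#' @inheritParams m_slr
#' @param metric `"slr"` or `"ami"`.
#' @return Rate of change; NA (with a warning-free pass-through) for
#'   T_res < 4, where half-metrics are undefined.
#' @export
half_window_rate <- function(window, metric = c("slr", "ami")) {
  metric <- match.arg(metric)
  y <- if (inherits(window, "residency_window")) window$series else window
  T_res <- length(y)
  if (T_res < 4) return(NA_real_)
  cut <- ceiling(T_res / 2)
  fn <- if (metric == "slr") m_slr else m_ami
  (abs(fn(y[(cut + 1):T_res])) - abs(fn(y[1:cut]))) / T_res
}

#' Lag-k autocorrelation of a propensity series
#'
#' Pearson correlation of the series against itself shifted by `lag`.
#'
#' @param series Numeric vector.
#' @param lag Positive lag (default 1).
#' @return Correlation, or NA for zero-variance or too-short series.
#' @export
propensity_autocorrelation <- function(series, lag = 1L) {
  n <- length(series)
  if (n <= lag + 1) return(NA_real_)
  x <- series[1:(n - lag)]
  y <- series[(lag + 1):n]
  degenerate <- function(v) {
    diff(range(v)) <= 1e-12 * max(abs(v), .Machine$double.xmin)
  }
  if (degenerate(x) || degenerate(y)) return(NA_real_)
  stats::cor(x, y)
}

#' Lag-k autocorrelation of propensity changes
#'
#' First differences the series, then applies
#' [propensity_autocorrelation()]. Negative values mean increases tend to
#' be followed by decreases (and vice versa).
#'
#' @inheritParams propensity_autocorrelation
#' @export
change_autocorrelation <- function(series, lag = 1L) {
  if (length(series) <= lag + 2) return(NA_real_)
  propensity_autocorrelation(diff(series), lag = lag)
}

#' Metric table for a list of windows
#'
#' @param windows List of [residency_window()]s.
#' @return Data frame: site, aa, i, j, T_res, complete, m_slr, m_ami,
#'   rate_slr, rate_ami.
#' @export
window_metrics <- function(windows) {
  if (length(windows) == 0) {
    return(data.frame(site = integer(0), aa = character(0), i = integer(0),
                      j = integer(0), T_res = integer(0),
                      complete = logical(0), m_slr = numeric(0),
                      m_ami = numeric(0), rate_slr = numeric(0),
                      rate_ami = numeric(0)))
  }
  data.frame(
    site = vapply(windows, function(w) as.numeric(w$site), numeric(1)),
    aa = vapply(windows, `[[`, character(1), "aa"),
    i = vapply(windows, `[[`, numeric(1), "i"),
    j = vapply(windows, `[[`, numeric(1), "j"),
    T_res = vapply(windows, `[[`, numeric(1), "T_res"),
    complete = vapply(windows, `[[`, logical(1), "complete"),
    m_slr = vapply(windows, function(w)
      if (w$T_res >= 2) m_slr(w) else NA_real_, numeric(1)),
    m_ami = vapply(windows, m_ami, numeric(1)),
    rate_slr = vapply(windows, half_window_rate, numeric(1), metric = "slr"),
    rate_ami = vapply(windows, half_window_rate, numeric(1), metric = "ami"))
}

#' Summarize propensity shifts over a set of windows
#'
#' Percent negative under each metric (a metric exactly 0 counts as
#' non-negative and is also reported separately), medians and counts.
#'
#' @param windows List of [residency_window()]s, or a [window_metrics()]
#'   data frame.
#' @return One-row data frame.
#' @export
summarize_shifts <- function(windows) {
  met <- if (is.data.frame(windows)) windows else window_metrics(windows)
  if (nrow(met) == 0) stop("no windows to summarize")
  pct <- function(x) 100 * mean(x, na.rm = TRUE)
  data.frame(
    n_windows = nrow(met),
    pct_neg_slr = pct(met$m_slr < 0),
    pct_neg_ami = pct(met$m_ami < 0),
    pct_zero_slr = pct(met$m_slr == 0),
    pct_zero_ami = pct(met$m_ami == 0),
    median_slr = stats::median(met$m_slr, na.rm = TRUE),
    median_ami = stats::median(met$m_ami, na.rm = TRUE),
    median_T_res = stats::median(met$T_res))
}

#' Site-averaged lag-1 autocorrelations of a trajectory
#'
#' For each site, the lag-1 autocorrelation of the resident amino acid's
#' propensity series and of its first differences, pooled over tenure
#' segments within the site (a resident's series is only defined while it
#' is resident; pairs never straddle a replacement), then averaged over
#' sites. Under the `"substitution"` clock the series is read at every
#' recorded state; under the `"nonsynonymous"` clock only states following
#' an amino-acid-changing substitution are kept. Propensity *changes* are
#' zero at every site for a synonymous step (the protein is unchanged), so
#' the change autocorrelation is conventionally read on the nonsynonymous
#' clock, where each step actually perturbs the landscapes.
#'
#' @param traj A [simulate_trajectory()] record.
#' @param clock `"substitution"` (all recorded states) or `"nonsynonymous"`.
#' @return List with `propensity_R1` and `change_R1`.
#' @export
trajectory_autocorrelations <- function(traj,
                                        clock = c("substitution",
                                                  "nonsynonymous")) {
  clock <- match.arg(clock)
  keep <- if (clock == "nonsynonymous" && traj$n > 0) {
    c(TRUE, !traj$steps$synonymous)
  } else {
    rep(TRUE, traj$n + 1L)
  }
  site_ac <- function(h, differences) {
    p <- traj$resident_prop[keep, h]
    r <- traj$resident_aa[keep, h]
    runs <- rle(r)
    ends <- cumsum(runs$lengths)
    starts <- ends - runs$lengths + 1L
    xs <- ys <- numeric(0)
    for (e in seq_along(ends)) {
      s <- p[starts[e]:ends[e]]
      if (differences) s <- diff(s)
      if (length(s) >= 2) {
        xs <- c(xs, s[-length(s)])
        ys <- c(ys, s[-1])
      }
    }
    if (length(xs) < 3 || stats::sd(xs) == 0 || stats::sd(ys) == 0) {
      return(NA_real_)
    }
    stats::cor(xs, ys)
  }
  r1 <- vapply(seq_len(traj$L), site_ac, numeric(1), differences = FALSE)
  d1 <- vapply(seq_len(traj$L), site_ac, numeric(1), differences = TRUE)
  list(propensity_R1 = mean(r1, na.rm = TRUE),
       change_R1 = mean(d1, na.rm = TRUE))
}

#' Pooled within-window lag-1 autocorrelation
#'
#' Pearson correlation over all consecutive pairs of resident-propensity
#' values inside each window, pooled across windows. This is the
#' level-series persistence the autocorrelated null model reproduces.
#'
#' @param windows List of [residency_window()]s.
#' @return Scalar correlation.
#' @export
pooled_window_autocorrelation <- function(windows) {
  .pooled_lag1(lapply(windows, `[[`, "series"))
}

#' Write windows and summaries as TSV
#'
#' @param windows List of windows or metric table.
#' @param path Output TSV path.
#' @export
write_window_metrics <- function(windows, path) {
  met <- if (is.data.frame(windows)) windows else window_metrics(windows)
  utils::write.table(met, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
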