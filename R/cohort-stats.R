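#' Heatmap table of coagulation-factor concentration changes
#'
#' For each factor and each time period, computes the per-patient change
#' Delta = concentration(period end) - concentration(period start) and
#' averages it over patients grouped by the concentration bin at the start
#' of the period. Positive cells for low starting bins and negative cells
#' for high starting bins indicate equilibration toward homeostasis.
#'
#' @param cohort Long-format data frame with columns `patient_id`,
#'   `outcome`, `time_h` and the eight factor columns (% activity).
#' @param bin_edges Strictly increasing bin edges for the starting
#'   concentration; default 20%-wide bins from 0 to 200 with the last bin
#'   open-ended.
#' @param periods List of `c(start, end)` hour pairs.
#' @return Data frame of class `delta_heatmap` with one row per
#'   factor/period/bin: `mean_delta` (NA when no patient has both endpoints
#'   in that cell) and `n` (patients contributing).
#' @export
delta_heatmap <- function(cohort,
                          bin_edges = c(seq(0, 200, by = 20), Inf),
                          periods = list(c(0, 6), c(6, 12), c(12, 24))) {
  stopifnot(is.data.frame(cohort),
            all(c("patient_id", "time_h", FACTOR_NAMES) %in% names(cohort)))
  if (any(diff(bin_edges) <= 0))
    stop("bin_edges must be strictly increasing", call. = FALSE)
  labs <- paste0("[", head(bin_edges, -1), ",",
                 ifelse(is.finite(bin_edges[-1]), bin_edges[-1], "Inf"), ")")
  out <- list()
  for (per in periods) {
    a <- cohort[cohort$time_h == per[1], c("patient_id", FACTOR_NAMES)]
    b <- cohort[cohort$time_h == per[2], c("patient_id", FACTOR_NAMES)]
    mrg <- merge(a, b, by = "patient_id", suffixes = c("_start", "_end"))
    plab <- sprintf("%g-%gh", per[1], per[2])
    for (f in FACTOR_NAMES) {
      start <- mrg[[paste0(f, "_start")]]
      end <- mrg[[paste0(f, "_end")]]
      ok <- !is.na(start) & !is.na(end)
      bin <- cut(start[ok], breaks = bin_edges, labels = labs, right = FALSE)
      delta <- end[ok] - start[ok]
      mean_d <- tapply(delta, bin, mean)
      nn <- tapply(delta, bin, length)
      nn[is.na(nn)] <- 0
      out[[length(out) + 1L]] <- data.frame(
        period = plab, factor = f, bin = labs,
        mean_delta = as.numeric(mean_d[labs]),
        n = as.integer(nn[labs]),
        stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  class(res) <- c("delta_heatmap", "data.frame")
  res
}

#' Significance tier of a p-value
#'
#' The conventional reporting scheme: `"ns"` for p > 0.05, `"*"` for
#' p <= 0.05, `"**"` for p <= 0.01, `"***"` for p <= 0.001.
#'
#' @param p Numeric p-value(s) in `[0, 1]`.
#' @return Character tier(s).
#' @export
significance_tier <- function(p) {
  stopifnot(all(p >= 0 & p <= 1))
  ifelse(p > 0.05, "ns",
         ifelse(p <= 0.001, "***",
                ifelse(p <= 0.01, "**", "*")))
}

#' Welch's two-sample t-test for unequal variances
#'
#' The unpaired, unequal-variance t statistic
#' \deqn{t = (\mu_x - \mu_y) / \sqrt{S_x^2/n + S_y^2/m}}
#' with Welch-Satterthwaite degrees of freedom and a two-sided p-value, used
#' to contrast concentration changes between deceased and surviving patient
#' groups. Two zero-variance samples with equal means give t = 0, p = 1.
#'
#' @param x,y Numeric samples, each of size >= 2.
#' @return An `htest`-like list of class `c("welch_test", "htest")` with
#'   `statistic` (t), `parameter` (df), `p.value` and the significance
#'   `tier` per [significance_tier()].
#' @export
welch_test <- function(x, y) {
  x <- as.numeric(x)
  y <- as.numeric(y)
  if (length(x) < 2 || length(y) < 2)
    stop("each sample needs at least 2 observations", call. = FALSE)
  n <- length(x)
  m <- length(y)
  mx <- mean(x)
  my <- mean(y)
  sex <- stats::var(x) / n
  sey <- stats::var(y) / m
  se2 <- sex + sey
  if (se2 == 0) {
    t <- if (mx == my) 0 else sign(mx - my) * Inf
    df <- n + m - 2
    p <- if (mx == my) 1 else 0
  } else {
    t <- (mx - my) / sqrt(se2)
    df <- se2^2 / (sex^2 / (n - 1) + sey^2 / (m - 1))
    p <- 2 * pt(-abs(t), df)
  }
  structure(list(statistic = c(t = t), parameter = c(df = df), p.value = p,
                 tier = significance_tier(p),
                 estimate = c(mean_x = mx, mean_y = my),
                 method = "Welch two-sample t-test (unequal variances)",
                 data.name = paste(deparse1(substitute(x)), "vs",
                                   deparse1(substitute(y)))),
            class = c("welch_test", "htest"))
}

#' Per-group convergence summary of coagulation-factor trajectories
#'
#' Mean and SD of each factor at each timepoint, per outcome group, plus a
#' flag for whether the group mean at the final timepoint lies inside the
#' normal band. Survivor cohorts equilibrate inside 60-140% activity;
#' deceased cohorts converge with at least one factor outside it.
#'
#' @inheritParams delta_heatmap
#' @param band Normal concentration band, % activity.
#' @return List of class `convergence_summary`: `summary` (outcome, time_h,
#'   factor, mean, sd, n) and `final_in_band` (outcome, factor, final mean,
#'   logical `in_band`).
#' @export
convergence_summary <- function(cohort, band = NORMAL_BAND) {
  stopifnot(is.data.frame(cohort),
            all(c("patient_id", "outcome", "time_h", FACTOR_NAMES) %in%
                  names(cohort)))
  rows <- list()
  for (g in split(cohort, cohort[c("time_h", "outcome")], drop = TRUE)) {
    for (f in FACTOR_NAMES) {
      v <- g[[f]][!is.na(g[[f]])]
      rows[[length(rows) + 1L]] <- data.frame(
        outcome = g$outcome[1], time_h = g$time_h[1], factor = f,
        mean = mean(v), sd = if (length(v) > 1) sd(v) else 0,
        n = length(v), stringsAsFactors = FALSE)
    }
  }
  summ <- do.call(rbind, rows)
  summ <- summ[order(summ$outcome, summ$time_h, match(summ$factor,
                                                      FACTOR_NAMES)), ]
  rownames(summ) <- NULL
  fin <- do.call(rbind, lapply(split(summ, summ$outcome), function(g) {
    last <- g[g$time_h == max(g$time_h), ]
    data.frame(outcome = last$outcome, factor = last$factor,
               final_mean = last$mean,
               in_band = last$mean >= band[1] & last$mean <= band[2],
               stringsAsFactors = FALSE)
  }))
  rownames(fin) <- NULL
  structure(list(summary = summ, final_in_band = fin, band = band),
            class = "convergence_summary")
}

#' @export
print.convergence_summary <- function(x, ...) {
  cat("Coagulation-factor convergence summary:\n")
  print(x$final_in_band)
  invisible(x)
}
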