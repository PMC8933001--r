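#' Construct a rank series
#'
#' A rank series maps signed SOP ranks (0 = the first divider, SOP0;
#' anterior negative, posterior positive) to division times relative to
#' SOP0, with the metric rank `rank * spacing_um` in µm.
#'
#' @param rank Integer vector of consecutive ranks including 0.
#' @param time_min Division times relative to SOP0 (minutes; 0 at rank 0).
#' @param spacing_um Mean inter-SOP distance (µm, > 0).
#' @param row_key Optional identifying list/character (notum, row, side).
#' @return A tibble of class `rank_series` with columns `rank`,
#'   `metric_rank_um`, `time_min` and attributes `spacing_um`, `row_key`.
#' @export
new_rank_series <- function(rank, time_min, spacing_um, row_key = NULL) {
  rank <- as.integer(rank)
  stopifnot(length(rank) == length(time_min), spacing_um > 0)
  if (!any(rank == 0L)) stop("rank 0 (SOP0) is required", call. = FALSE)
  if (!isTRUE(all.equal(sort(rank), seq(min(rank), max(rank)))))
    stop("ranks must be consecutive integers", call. = FALSE)
  if (any(abs(time_min[rank == 0L]) > 1e-12, na.rm = TRUE))
    stop("time at rank 0 must be 0", call. = FALSE)
  ord <- order(rank)
  out <- tibble::tibble(rank = rank[ord],
                        metric_rank_um = rank[ord] * spacing_um,
                        time_min = time_min[ord])
  structure(out, spacing_um = spacing_um, row_key = row_key,
            class = c("rank_series", class(tibble::tibble())))
}

#' Identify SOP0, the first divider of a row
#'
#' Returns the record with the minimal division time; ties are broken by
#' the most anterior (smallest) position, then lexicographically by
#' notum/row ids, so the choice is deterministic and order-invariant.
#'
#' @param row_records Data frame of SOP records from one row (>= 2 rows).
#' @return A single-row tibble, the SOP0 record.
#' @export
identify_sop0 <- function(row_records) {
  d <- tibble::as_tibble(row_records)
  if (nrow(d) < 2L)
    stop("a row needs >= 2 records to define a wave", call. = FALSE)
  ord <- order(d$division_time_min, d$position_um,
               d$notum_id, d$row_id)
  d[ord[1L], ]
}

#' Assign signed ranks and relative times around SOP0
#'
#' Records are sorted by antero-posterior position; the rank is the signed
#' ordinal offset from SOP0 (anterior negative) and the metric rank is the
#' rank times the row's mean inter-SOP distance. Times are rebased so SOP0
#' divides at 0.
#'
#' @param row_records Data frame of SOP records from one row.
#' @param sop0 The SOP0 record (default: [identify_sop0()] of
#'   `row_records`). Must be one of `row_records`.
#' @param spacing Either `"observed_mean"` (mean of consecutive position
#'   gaps) or a fixed numeric spacing in µm (e.g. 30 for the control
#'   genotype's printed mean inter-SOP distance).
#' @return A [new_rank_series()] tibble.
#' @export
assign_ranks <- function(row_records, sop0 = identify_sop0(row_records),
                         spacing = "observed_mean") {
  d <- tibble::as_tibble(row_records)
  if (nrow(d) < 2L)
    stop("a row needs >= 2 records", call. = FALSE)
  if (anyDuplicated(d$position_um))
    stop("duplicate positions: rank ordering is ambiguous", call. = FALSE)
  i0 <- which(d$position_um == sop0$position_um[1L] &
                d$division_time_min == sop0$division_time_min[1L])
  if (length(i0) != 1L)
    stop("`sop0` must match exactly one record", call. = FALSE)
  ord <- order(d$position_um)
  d <- d[ord, ]
  i0 <- which(ord == i0)
  spacing_um <- if (identical(spacing, "observed_mean")) {
    mean(diff(d$position_um))
  } else {
    stopifnot(is.numeric(spacing), length(spacing) == 1L, spacing > 0)
    as.numeric(spacing)
  }
  new_rank_series(rank = seq_len(nrow(d)) - i0,
                  time_min = d$division_time_min - d$division_time_min[i0],
                  spacing_um = spacing_um,
                  row_key = list(notum_id = d$notum_id[i0],
                                 row_id = d$row_id[i0],
                                 side = d$side[i0]))
}

#' Aggregate rank series across nota
#'
#' Per rank, the mean and SEM (sample SD / sqrt(n)) of relative division
#' times over the series that contain that rank. The metric rank reported
#' per rank is the rank times the mean spacing of the contributing series.
#'
#' @param series_list A non-empty list of [new_rank_series()] objects
#'   sharing a spacing convention.
#' @return A tibble of class `aggregate_series` with columns `rank`,
#'   `metric_rank_um`, `mean_time_min`, `sem_time_min` (`NA` where only one
#'   series contributes), `n_rows`.
#' @export
aggregate_series <- function(series_list) {
  if (length(series_list) == 0L)
    stop("need at least one rank series", call. = FALSE)
  stopifnot(all(vapply(series_list, inherits, logical(1), "rank_series")))
  long <- do.call(rbind, lapply(seq_along(series_list), function(i) {
    s <- series_list[[i]]
    data.frame(series = i, rank = s$rank, time = s$time_min,
               spacing = attr(s, "spacing_um"))
  }))
  long <- long[is.finite(long$time), , drop = FALSE]
  ranks <- sort(unique(long$rank))
  agg <- lapply(ranks, function(rk) {
    x <- long[long$rank == rk, ]
    n <- nrow(x)
    tibble::tibble(rank = rk,
                   metric_rank_um = rk * mean(x$spacing),
                   mean_time_min = mean(x$time),
                   sem_time_min = if (n > 1L) sd(x$time) / sqrt(n) else NA_real_,
                   n_rows = n)
  })
  out <- do.call(rbind, agg)
  structure(out, class = c("aggregate_series", class(tibble::tibble())))
}

#' Linear regression of division time on metric rank for one wave arm
#'
#' Ordinary least squares of relative time (min) on metric rank (µm)
#' restricted to ranks <= 0 (anterior) or >= 0 (posterior). Rank 0 — the
#' shared origin of both arms — is included in both fits. The anterior
#' slope is negative for a normal centrifugal wave.
#'
#' @param series A [new_rank_series()] or [aggregate_series()] object.
#' @param side `"anterior"` or `"posterior"`.
#' @return An object of class `wave_regression`: list with `side`,
#'   `slope_min_per_um`, `intercept_min`, `r_squared` (`NA` when undefined:
#'   fewer than 3 points or no time variance), `n_points`.
#' @export
fit_wave_regression <- function(series, side = c("posterior", "anterior")) {
  side <- match.arg(side)
  x <- series$metric_rank_um
  y <- if ("mean_time_min" %in% names(series)) series$mean_time_min
       else series$time_min
  keep <- is.finite(x) & is.finite(y) &
    (if (side == "anterior") series$rank <= 0L else series$rank >= 0L)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 2L)
    stop(sprintf("need >= 2 points on the %s side (have %d)",
                 side, length(x)), call. = FALSE)
  fit <- lm(y ~ x)
  r2 <- if (length(x) >= 3L && sd(y) > 0) {
    1 - sum(residuals(fit)^2) / sum((y - mean(y))^2)
  } else NA_real_
  structure(list(side = side,
                 slope_min_per_um = unname(coef(fit)[2L]),
                 intercept_min = unname(coef(fit)[1L]),
                 r_squared = r2,
                 n_points = length(x)),
            class = "wave_regression")
}

#' @export
print.wave_regression <- function(x, ...) {
  cat(sprintf("<wave_regression %s> slope = %.4g min/um, intercept = %.4g min, R2 = %s, n = %d\n",
              x$side, x$slope_min_per_um, x$intercept_min,
              ifelse(is.na(x$r_squared), "NA", sprintf("%.3f", x$r_squared)),
              x$n_points))
  invisible(x)
}

#' Wave rate: mean absolute inverse slope
#'
#' The rate of the mitotic wave is the mean over regressions of
#' `|1 / slope|` in µm/min — higher means more synchronous divisions.
#' Slopes whose magnitude is below `zero_tol` (perfectly synchronous arms,
#' where the inverse diverges) are excluded from the mean with a warning;
#' the count of exclusions is attached as attribute `n_excluded`.
#'
#' @param regressions A list of [fit_wave_regression()] results (or a
#'   single one).
#' @param zero_tol Slopes with `|slope| < zero_tol` (min/µm) are excluded.
#' @return The wave rate (µm/min) with attribute `n_excluded`; `NaN` if
#'   every slope was excluded.
#' @export
wave_rate <- function(regressions, zero_tol = 1e-6) {
  if (inherits(regressions, "wave_regression"))
    regressions <- list(regressions)
  stopifnot(length(regressions) > 0L,
            all(vapply(regressions, inherits, logical(1), "wave_regression")))
  slopes <- vapply(regressions, function(r) r$slope_min_per_um, numeric(1))
  zero <- abs(slopes) < zero_tol
  if (any(zero))
    warning(sprintf("%d regression(s) with |slope| < %g excluded from the rate (infinite inverse)",
                    sum(zero), zero_tol), call. = FALSE)
  rate <- mean(abs(1 / slopes[!zero]))
  structure(rate, n_excluded = sum(zero))
}
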