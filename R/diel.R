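## Diel activity profiles, circular uniformity testing, nocturnal activity.

#' Meteorological season of a date
#'
#' Winter is Dec-Feb (the definition used by the survival covariate);
#' the remaining seasons follow the same three-month convention:
#' spring Mar-May, summer Jun-Aug, fall Sep-Nov.
#'
#' @param date a `Date` (or coercible) vector.
#' @return character vector in `{WINTER, SPRING, SUMMER, FALL}`.
#' @export
assign_season <- function(date) {
  m <- as.integer(format(as.Date(date), "%m"))
  c("WINTER", "WINTER", "SPRING", "SPRING", "SPRING", "SUMMER", "SUMMER",
    "SUMMER", "FALL", "FALL", "FALL", "WINTER")[m]
}

seconds_of_day <- function(ts) {
  as.numeric(ts) - as.numeric(as.POSIXct(format(ts, "%Y-%m-%d"), tz = "UTC"))
}

#' Map clock times to angles on the 24-h circle
#'
#' @param ts POSIXct timestamps (or numeric seconds of day).
#' @return angles in radians, `2*pi*t/86400`.
#' @export
clock_to_angle <- function(ts) {
  s <- if (inherits(ts, "POSIXct")) seconds_of_day(ts) else as.numeric(ts)
  2 * pi * s / 86400
}

#' Seasonal diel activity profile
#'
#' Builds the mean (+/- SE) number of visits per clock hour across the
#' days of one season.  Every calendar day of the season inside the span
#' of the supplied visits counts, including zero-visit days, so
#' `sum(hourly_mean) * n_days` returns the season's total visit count.
#' The activity span is reported two ways: the mean over days of the daily
#' first/last visit clock time, and the overall extremes.
#'
#' @param visits visit table (start timestamps are used).
#' @param season one of `"WINTER","SPRING","SUMMER","FALL"`, or `NULL`
#'   for all seasons pooled.
#' @param roster optional roster for `group_filter`.
#' @param group_filter optional named list matched against roster columns,
#'   e.g. `list(sex = "F", species = "ANNA")`.
#' @return an object of class `"diel_profile"`: `season`, `hourly_mean`,
#'   `hourly_se` (24 values each), `n_visits`, `n_days`, `peak_hour`
#'   (earliest argmax), `first_visit_clock`/`last_visit_clock` (mean daily,
#'   seconds of day), `first_visit_extreme`/`last_visit_extreme`.
#' @export
diel_profile <- function(visits, season = NULL, roster = NULL,
                         group_filter = NULL) {
  v <- visits
  if (!is.null(group_filter)) {
    stopifnot(!is.null(roster))
    keep <- rep(TRUE, nrow(roster))
    for (nm in names(group_filter))
      keep <- keep & roster[[nm]] %in% group_filter[[nm]]
    v <- v[v$tag_id %in% roster$tag_id[keep], , drop = FALSE]
  }
  dates <- as.Date(v$start)
  if (!is.null(season)) {
    v <- v[assign_season(dates) == season, , drop = FALSE]
    dates <- as.Date(v$start)
  }
  if (!nrow(v)) {
    return(structure(list(season = season, hourly_mean = rep(0, 24),
                          hourly_se = rep(NA_real_, 24), n_visits = 0L,
                          n_days = 0L, peak_hour = NA_integer_,
                          first_visit_clock = NA_real_,
                          last_visit_clock = NA_real_,
                          first_visit_extreme = NA_real_,
                          last_visit_extreme = NA_real_, empty = TRUE),
                     class = "diel_profile"))
  }
  all_days <- seq(min(dates), max(dates), by = "day")
  if (!is.null(season)) all_days <- all_days[assign_season(all_days) == season]
  hr <- floor(seconds_of_day(v$start) / 3600)
  counts <- table(factor(as.character(dates), levels = as.character(all_days)),
                  factor(hr, levels = 0:23))
  counts <- matrix(as.integer(counts), nrow = length(all_days), ncol = 24)
  n_days <- length(all_days)
  hm <- colMeans(counts)
  hse <- apply(counts, 2, sd) / sqrt(n_days)
  sod <- seconds_of_day(v$start)
  daily_first <- tapply(sod, as.character(dates), min)
  daily_last <- tapply(sod, as.character(dates), max)
  structure(list(season = season, hourly_mean = hm, hourly_se = hse,
                 n_visits = nrow(v), n_days = n_days,
                 peak_hour = which.max(hm) - 1L,
                 first_visit_clock = mean(daily_first),
                 last_visit_clock = mean(daily_last),
                 first_visit_extreme = min(sod),
                 last_visit_extreme = max(sod), empty = FALSE),
            class = "diel_profile")
}

#' @export
print.diel_profile <- function(x, ...) {
  cat("Diel profile", if (!is.null(x$season)) paste0("(", x$season, ")"),
      "-", x$n_visits, "visits over", x$n_days, "days\n")
  if (!x$empty)
    cat(sprintf("  peak hour %02d:00; mean daily activity %s to %s\n",
                x$peak_hour, fmt_clock(x$first_visit_clock),
                fmt_clock(x$last_visit_clock)))
  invisible(x)
}

fmt_clock <- function(s) sprintf("%02d:%02d", floor(s / 3600) %% 24,
                                 floor((s %% 3600) / 60))

#' Rayleigh test of circular uniformity
#'
#' Tests whether angles on the circle (here: visit clock times mapped via
#' [clock_to_angle()]) are uniformly distributed.  The statistic is the
#' mean resultant length `Rbar = |sum(exp(i*theta))|/n`, `Z = n*Rbar^2`,
#' with the standard large-sample series approximation for the p-value
#' `p = exp(-Z) * [1 + (2Z - Z^2)/(4n) - (24Z - 132Z^2 + 76Z^3 - 9Z^4)/(288n^2)]`,
#' clamped to `(0, 1]`.
#'
#' @param angles_radians numeric vector of angles (n >= 2).
#' @return list of class `"rayleigh_test"` with `n`, `Rbar`, `Z`, `p`.
#' @export
rayleigh_test <- function(angles_radians) {
  n <- length(angles_radians)
  if (n < 2L) stop("Rayleigh test needs at least 2 angles", call. = FALSE)
  C <- sum(cos(angles_radians)); S <- sum(sin(angles_radians))
  Rbar <- sqrt(C^2 + S^2) / n
  Z <- n * Rbar^2
  p <- exp(-Z) * (1 + (2 * Z - Z^2) / (4 * n) -
                  (24 * Z - 132 * Z^2 + 76 * Z^3 - 9 * Z^4) / (288 * n^2))
  p <- min(max(p, .Machine$double.xmin), 1)
  structure(list(n = n, Rbar = Rbar, Z = Z, p = p),
            class = "rayleigh_test")
}

#' @export
print.rayleigh_test <- function(x, ...) {
  cat(sprintf("Rayleigh test: n = %d, Rbar = %.4f, Z = %.3f, p = %.4g\n",
              x$n, x$Rbar, x$Z, x$p))
  invisible(x)
}

#' Nocturnal feeder activity
#'
#' Flags visits whose start clock time falls in the night window, by
#' default 22:00-04:00 (i.e. `[22:00, 24:00) U [00:00, 04:00]`, the upper
#' bound inclusive at exactly 04:00:00), and summarizes the night-active
#' birds.
#'
#' @param visits visit table.
#' @param window `c(start_hour, end_hour)` wrapping midnight; default
#'   `c(22, 4)`.
#' @return a `data.frame` per night-active bird: `tag_id`,
#'   `n_night_visits`, `stations` (comma-joined), `dates` (comma-joined).
#' @export
night_activity <- function(visits, window = c(22, 4)) {
  s <- seconds_of_day(visits$start)
  lo <- window[1] * 3600; hi <- window[2] * 3600
  night <- s >= lo | s <= hi
  v <- visits[night, , drop = FALSE]
  if (!nrow(v))
    return(data.frame(tag_id = character(), n_night_visits = integer(),
                      stations = character(), dates = character()))
  tags <- sort(unique(v$tag_id))
  do.call(rbind, lapply(tags, function(tg) {
    vi <- v[v$tag_id == tg, , drop = FALSE]
    data.frame(tag_id = tg, n_night_visits = nrow(vi),
               stations = paste(sort(unique(vi$station_id)), collapse = ","),
               dates = paste(sort(unique(as.character(as.Date(vi$start)))),
                             collapse = ","),
               stringsAsFactors = FALSE)
  }))
}
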