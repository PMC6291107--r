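## Visit segmentation and per-bird visitation metrics.

#' Segment detection streams into feeder visits
#'
#' A visit is a maximal run of one bird's detections at one station in
#' which every gap between consecutive reads is at most `gap_max_s`
#' seconds.  The rule is inclusive: with the default of 11 s and a 10-s
#' reader duty cycle, consecutive reads of a bird sitting at the feeder
#' (10-11 s apart) merge into one visit, while a gap of 12 s or more
#' splits visits.  Visit duration is last read minus first read, so a
#' single-read visit has duration 0 and is called *transient*
#' (duration < 10 s, below the duty cycle's resolution).
#'
#' Exact duplicate reads (same tag, station and second) collapse to one
#' detection.  Detections at different stations never merge.
#'
#' @param detections detection table (any order; sorted internally).
#' @param gap_max_s maximal within-visit gap in seconds (> 0 unless 0 is
#'   given deliberately to make every read its own visit).
#' @return a `data.frame` of visits: `tag_id`, `station_id`, `site_id`,
#'   `start`, `end`, `duration_s`, `n_detections`, `transient`.
#' @export
segment_visits <- function(detections, gap_max_s = 11) {
  stopifnot(gap_max_s >= 0)
  if (!nrow(detections)) {
    return(data.frame(tag_id = character(), station_id = character(),
                      site_id = character(),
                      start = as.POSIXct(character(), tz = "UTC"),
                      end = as.POSIXct(character(), tz = "UTC"),
                      duration_s = integer(), n_detections = integer(),
                      transient = logical(), stringsAsFactors = FALSE))
  }
  o <- order(detections$tag_id, detections$station_id, detections$timestamp)
  d <- detections[o, , drop = FALSE]
  key <- paste(d$tag_id, d$station_id, sep = "\r")
  dupl <- duplicated(paste(key, as.numeric(d$timestamp)))
  d <- d[!dupl, , drop = FALSE]; key <- key[!dupl]
  tt <- as.numeric(d$timestamp)
  new_grp <- c(TRUE, key[-1L] != key[-length(key)] |
                     diff(tt) > gap_max_s)
  vid <- cumsum(new_grp)
  first <- !duplicated(vid)
  last <- !duplicated(vid, fromLast = TRUE)
  start <- d$timestamp[first]
  end <- d$timestamp[last]
  dur <- as.integer(round(as.numeric(end) - as.numeric(start)))
  data.frame(tag_id = d$tag_id[first], station_id = d$station_id[first],
             site_id = d$site_id[first], start = start, end = end,
             duration_s = dur,
             n_detections = as.integer(tabulate(vid)),
             transient = dur < 10, stringsAsFactors = FALSE)
}

#' Per-bird visitation summaries
#'
#' For every detected bird: visit counts, transient-visit counts, mean and
#' total visit duration, the observation span (first to last detection),
#' the proportion of that span spent at feeders, distinct days detected,
#' latency from tagging to first detection, and the observation period
#' (tagging to last detection).  Transient visits contribute 0 s to the
#' mean and total duration.  A bird whose whole record is a single read
#' has span 0; its `proportion_time` is defined as 0 and flagged via
#' `span_zero`.
#'
#' Birds in the roster never seen are excluded; their tags are attached as
#' `attr(x, "not_returned")`.
#'
#' @param visits visit table from [segment_visits()].
#' @param roster roster table from [read_roster()].
#' @return a `data.frame`, one row per detected bird.
#' @export
summarize_birds <- function(visits, roster) {
  v <- visits[visits$tag_id %in% roster$tag_id, , drop = FALSE]
  tags <- sort(unique(v$tag_id))
  rows <- lapply(tags, function(tg) {
    vi <- v[v$tag_id == tg, , drop = FALSE]
    span <- as.numeric(max(vi$end)) - as.numeric(min(vi$start))
    total <- sum(vi$duration_s)
    tagd <- roster$tag_date[roster$tag_id == tg]
    data.frame(tag_id = tg,
               n_visits = nrow(vi),
               n_transient = sum(vi$transient),
               mean_duration_s = mean(vi$duration_s),
               median_duration_s = stats::median(vi$duration_s),
               total_time_s = total,
               observation_span_s = span,
               proportion_time = if (span > 0) total / span else 0,
               span_zero = span == 0,
               days_detected = length(unique(as.Date(vi$start))),
               latency_days = as.numeric(min(as.Date(vi$start)) - tagd),
               observation_period_days =
                 as.numeric(max(as.Date(vi$end)) - tagd),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) out <- data.frame(tag_id = character())
  attr(out, "not_returned") <- setdiff(roster$tag_id, tags)
  out
}

#' Rank feeders per bird (primary / secondary / tertiary)
#'
#' Orders each bird's stations by descending visit count (ties broken
#' lexicographically by `station_id`) and labels ranks 1-3 as primary,
#' secondary and tertiary feeders.  Percentages are of the bird's total
#' visits and sum to 100 across its stations.
#'
#' @param visits visit table.
#' @return a `data.frame` with `tag_id`, `station_id`, `n_visits`,
#'   `pct_visits`, `rank`, `role`.
#' @seealso [primary_feeder_tally()] for site-level counts of primary
#'   feeder holders.
#' @export
rank_feeders <- function(visits) {
  if (!nrow(visits))
    return(data.frame(tag_id = character(), station_id = character(),
                      n_visits = integer(), pct_visits = numeric(),
                      rank = integer(), role = character()))
  tab <- aggregate(list(n_visits = rep(1L, nrow(visits))),
                   by = list(tag_id = visits$tag_id,
                             station_id = visits$station_id), FUN = sum)
  tab <- tab[order(tab$tag_id, -tab$n_visits, tab$station_id), , drop = FALSE]
  rk <- stats::ave(tab$n_visits, tab$tag_id, FUN = seq_along)
  tot <- stats::ave(tab$n_visits, tab$tag_id, FUN = sum)
  roles <- c("primary", "secondary", "tertiary")
  out <- data.frame(tag_id = tab$tag_id, station_id = tab$station_id,
                    n_visits = tab$n_visits,
                    pct_visits = 100 * tab$n_visits / tot,
                    rank = as.integer(rk),
                    role = ifelse(rk <= 3, roles[rk], NA_character_),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' How many birds hold each station as their primary feeder
#'
#' @param ranking output of [rank_feeders()].
#' @return a `data.frame` `station_id`, `n_primary_birds`, descending.
#' @export
primary_feeder_tally <- function(ranking) {
  p <- ranking[ranking$rank == 1L, , drop = FALSE]
  tab <- sort(table(p$station_id), decreasing = TRUE)
  data.frame(station_id = names(tab), n_primary_birds = as.integer(tab),
             stringsAsFactors = FALSE)
}

#' Cross-site movement of tagged birds
#'
#' Percentage of each bird's visits per site, and whether the bird is a
#' "mover" (any visit at a site other than its tagging site).
#'
#' @param visits visit table.
#' @param roster roster (supplies `tag_site`).
#' @return a `data.frame` `tag_id`, `site_id`, `n_visits`, `pct_visits`,
#'   `tag_site`, `mover` (bird-level flag, repeated on each row).
#' @export
site_movement <- function(visits, roster) {
  v <- visits[visits$tag_id %in% roster$tag_id, , drop = FALSE]
  if (!nrow(v))
    return(data.frame(tag_id = character(), site_id = character(),
                      n_visits = integer(), pct_visits = numeric(),
                      tag_site = character(), mover = logical()))
  tab <- aggregate(list(n_visits = rep(1L, nrow(v))),
                   by = list(tag_id = v$tag_id, site_id = v$site_id),
                   FUN = sum)
  tot <- stats::ave(tab$n_visits, tab$tag_id, FUN = sum)
  tab$pct_visits <- 100 * tab$n_visits / tot
  tab$tag_site <- roster$tag_site[match(tab$tag_id, roster$tag_id)]
  away <- tab$site_id != tab$tag_site
  tab$mover <- tab$tag_id %in% tab$tag_id[away]
  tab[order(tab$tag_id, -tab$pct_visits), , drop = FALSE]
}

#' Kruskal-Wallis rank test across groups
#'
#' Thin wrapper around [stats::kruskal.test()] (tie-corrected H statistic,
#' chi-square reference with k-1 df) with the argument/return contract
#' used by the visitation comparisons.
#'
#' @param values_by_group a named list of numeric vectors, one per group;
#'   at least two groups, none empty.
#' @return list with `H`, `df`, `p`.
#' @export
kruskal_wallis <- function(values_by_group) {
  if (length(values_by_group) < 2L)
    stop("need at least two groups", call. = FALSE)
  if (any(!lengths(values_by_group)))
    stop("empty group in Kruskal-Wallis input", call. = FALSE)
  kt <- kruskal.test(values_by_group)
  list(H = unname(kt$statistic), df = unname(kt$parameter),
       p = kt$p.value)
}

#' Two-sided Fisher's exact test for a 2x2 table
#'
#' Wrapper around [stats::fisher.test()]: the two-sided p-value sums
#' hypergeometric probabilities of all tables (fixed margins) no more
#' probable than the observed one.
#'
#' @param table 2x2 matrix of non-negative integer counts.
#' @return list with `odds_ratio` (conditional MLE) and `p_two_sided`.
#' @export
fisher_exact_2x2 <- function(table) {
  table <- as.matrix(table)
  if (!all(dim(table) == c(2L, 2L)))
    stop("need a 2x2 table", call. = FALSE)
  if (any(table < 0)) stop("negative entries in 2x2 table", call. = FALSE)
  ft <- fisher.test(table)
  list(odds_ratio = unname(ft$estimate), p_two_sided = ft$p.value)
}
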