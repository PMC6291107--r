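## Reading, validating and normalizing RFID detection logs and bird rosters.

#' Describe the column layout of a detection log
#'
#' RFID transceiver exports differ between vendors; a dialect maps the
#' columns of a particular export to the fields perchwatch needs.  The
#' default dialect is the layout written by [write_detection_log()] and by
#' the synthetic-colony simulator.
#'
#' @param datetime,tag_id,antenna_id,station_id,site_id column names in the
#'   source file.  `station_id` and `site_id` may be `NA`: a missing station
#'   column means each antenna is its own station, a missing site column
#'   puts everything at site `"site0"`.
#' @param ts_format `strptime()` format for the timestamp column.
#' @return a named list of class `"detection_dialect"`.
#' @export
detection_dialect <- function(datetime = "datetime", tag_id = "tag_id",
                              antenna_id = "antenna_id",
                              station_id = "station_id", site_id = "site_id",
                              ts_format = "%Y-%m-%d %H:%M:%S") {
  structure(list(datetime = datetime, tag_id = tag_id,
                 antenna_id = antenna_id, station_id = station_id,
                 site_id = site_id, ts_format = ts_format),
            class = "detection_dialect")
}

# Timestamps are deliberately parsed as timezone-naive local clock time
# (stored as UTC so no DST rule can shift wall-clock hours): the diel
# analyses need the clock hour the bird experienced, not an absolute epoch.
parse_local <- function(x, format = "%Y-%m-%d %H:%M:%S") {
  as.POSIXct(x, format = format, tz = "UTC")
}

#' Read a detection log
#'
#' Reads a CSV of timestamped tag reads into the normalized detection
#' table used throughout the package: one row per read with columns
#' `tag_id`, `timestamp` (POSIXct, local clock), `antenna_id`,
#' `station_id`, `site_id`, in stable input order.
#'
#' @param source path to a CSV file with a header row.
#' @param dialect a [detection_dialect()] naming the columns.
#' @return a `data.frame` of detections.
#' @export
read_detection_log <- function(source, dialect = detection_dialect()) {
  raw <- read.csv(source, colClasses = "character", check.names = FALSE)
  need <- c(datetime = dialect$datetime, tag_id = dialect$tag_id,
            antenna_id = dialect$antenna_id)
  missing_cols <- need[!need %in% names(raw)]
  if (length(missing_cols))
    stop("detection log is missing mandatory column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  ts <- parse_local(raw[[dialect$datetime]], dialect$ts_format)
  if (nrow(raw) && anyNA(ts)) {
    bad <- which(is.na(ts))[1L]
    stop(sprintf("unparseable timestamp %s at data row %d",
                 dQuote(raw[[dialect$datetime]][bad]), bad), call. = FALSE)
  }
  station <- if (!is.na(dialect$station_id) && dialect$station_id %in% names(raw))
    raw[[dialect$station_id]] else raw[[dialect$antenna_id]]
  site <- if (!is.na(dialect$site_id) && dialect$site_id %in% names(raw))
    raw[[dialect$site_id]] else rep("site0", nrow(raw))
  det <- data.frame(tag_id = raw[[dialect$tag_id]],
                    timestamp = ts,
                    antenna_id = raw[[dialect$antenna_id]],
                    station_id = station, site_id = site,
                    stringsAsFactors = FALSE)
  if (any(!nzchar(det$tag_id)))
    stop("empty tag_id at data row ", which(!nzchar(det$tag_id))[1L],
         call. = FALSE)
  det
}

#' Write a detection log
#'
#' Inverse of [read_detection_log()]: `read_detection_log(write_detection_log(d))`
#' reproduces `d` field for field.
#'
#' @param detections detection table.
#' @param path output CSV path.
#' @param dialect column layout to write.
#' @return `path`, invisibly.
#' @export
write_detection_log <- function(detections, path,
                                dialect = detection_dialect()) {
  out <- data.frame(format(detections$timestamp, dialect$ts_format),
                    detections$tag_id, detections$antenna_id,
                    detections$station_id, detections$site_id,
                    stringsAsFactors = FALSE)
  names(out) <- c(dialect$datetime, dialect$tag_id, dialect$antenna_id,
                  dialect$station_id, dialect$site_id)
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

species_levels <- c("ANNA", "ALLEN")
sex_levels <- c("F", "M", "UNKNOWN")
age_levels <- c("AHY", "HY", "UNKNOWN")

normalize_enum <- function(x, what) {
  key <- toupper(trimws(x))
  key[is.na(key) | key == "" | key %in% c("U", "UNK", "UNKNOWN", "NA")] <- "UNKNOWN"
  out <- switch(what,
    species = {
      v <- rep(NA_character_, length(key))
      v[grepl("ANNA", key)] <- "ANNA"
      v[grepl("ALLEN", key)] <- "ALLEN"
      v
    },
    sex = {
      v <- rep(NA_character_, length(key))
      v[key %in% c("F", "FEMALE")] <- "F"
      v[key %in% c("M", "MALE")] <- "M"
      v[key == "UNKNOWN"] <- "UNKNOWN"
      v
    },
    age = {
      v <- rep(NA_character_, length(key))
      v[key %in% c("AHY", "ADULT") | grepl("AFTER", key)] <- "AHY"
      v[key %in% c("HY", "HATCH YEAR", "HATCH-YEAR", "HATCHYEAR")] <- "HY"
      v[key == "UNKNOWN"] <- "UNKNOWN"
      v
    })
  if (anyNA(out))
    stop("unrecognized ", what, " value: ",
         dQuote(x[is.na(out)][1L]), call. = FALSE)
  out
}

#' Read a bird roster
#'
#' Reads the tagging roster (one row per PIT-tagged bird) and normalizes
#' the categorical fields: species to `ANNA`/`ALLEN`, sex to `F`/`M`/
#' `UNKNOWN`, age class to `AHY`/`HY`/`UNKNOWN`.  Unknowns are preserved,
#' never imputed.
#'
#' @param source path to a CSV with columns `tag_id`, `band_id`, `species`,
#'   `sex`, `age`, `tag_date` (ISO date), `tag_site`.
#' @return a `data.frame`, one row per bird.
#' @export
read_roster <- function(source) {
  raw <- read.csv(source, colClasses = "character", check.names = FALSE)
  need <- c("tag_id", "band_id", "species", "sex", "age", "tag_date", "tag_site")
  if (length(miss <- setdiff(need, names(raw))))
    stop("roster is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(raw$tag_id))
    stop("duplicate tag_id in roster: ",
         raw$tag_id[duplicated(raw$tag_id)][1L], call. = FALSE)
  data.frame(tag_id = raw$tag_id, band_id = raw$band_id,
             species = normalize_enum(raw$species, "species"),
             sex = normalize_enum(raw$sex, "sex"),
             age = normalize_enum(raw$age, "age"),
             tag_date = as.Date(raw$tag_date),
             tag_site = raw$tag_site, stringsAsFactors = FALSE)
}

#' Validate a detection log against a roster
#'
#' Report-only quality checks.  Detections from tags absent from the
#' roster are flagged but retained (they remain useful for antenna
#' diagnostics); downstream per-bird analyses drop them by joining on the
#' roster.
#'
#' @param detections detection table.
#' @param roster roster table.
#' @return a list of class `"validation_report"` with `unknown_tags`,
#'   `pre_tagging_detections`, `duplicate_rows` (rows minus distinct rows),
#'   and `per_site_counts`.
#' @export
validate_detections <- function(detections, roster) {
  unknown <- sort(unique(detections$tag_id[!detections$tag_id %in% roster$tag_id]))
  tagd <- roster$tag_date[match(detections$tag_id, roster$tag_id)]
  pre <- sum(!is.na(tagd) & as.Date(detections$timestamp) < tagd)
  key <- paste(detections$tag_id, detections$timestamp,
               detections$antenna_id, sep = "\r")
  dup <- nrow(detections) - length(unique(key))
  per_site <- table(detections$site_id)
  structure(list(unknown_tags = unknown,
                 pre_tagging_detections = pre,
                 duplicate_rows = dup,
                 per_site_counts = as.list(per_site)),
            class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat("Detection-log validation report\n")
  cat("  unknown tags:          ", length(x$unknown_tags), "\n")
  cat("  pre-tagging detections:", x$pre_tagging_detections, "\n")
  cat("  duplicate rows:        ", x$duplicate_rows, "\n")
  for (s in names(x$per_site_counts))
    cat(sprintf("  %-10s %d detections\n", s, x$per_site_counts[[s]]))
  invisible(x)
}

#' Resolve multi-antenna stations to a single detection stream
#'
#' Stations with a double antenna (side + top) record the same bird on two
#' transceivers.  `side_only` keeps side-antenna reads (the convention
#' adopted after comparing the two antennas; top reads are discarded);
#' `merge_dedup` pools both antennas of a station and collapses same-tag
#' reads that fall within 1 s of each other into one.
#'
#' @param detections detection table.
#' @param policy `"side_only"` or `"merge_dedup"`.
#' @param roles named character vector mapping `antenna_id` to one of
#'   `"side"`, `"top"`, `"single"`.  Antennas absent from `roles` are an
#'   error.
#' @return the filtered/merged detection table.
#' @export
select_antenna <- function(detections, policy = c("side_only", "merge_dedup"),
                           roles) {
  policy <- match.arg(policy)
  r <- roles[detections$antenna_id]
  if (anyNA(r) || any(!r %in% c("side", "top", "single")))
    stop("unknown antenna role for antenna(s): ",
         paste(unique(detections$antenna_id[is.na(r) |
               !r %in% c("side", "top", "single")]), collapse = ", "),
         call. = FALSE)
  if (policy == "side_only")
    return(detections[r %in% c("side", "single"), , drop = FALSE])
  # merge_dedup: within (tag, station), keep a read only if it is > 1 s
  # after the previously kept read
  o <- order(detections$tag_id, detections$station_id, detections$timestamp)
  d <- detections[o, , drop = FALSE]
  grp <- paste(d$tag_id, d$station_id, sep = "\r")
  keep <- logical(nrow(d))
  last_t <- -Inf; last_g <- ""
  tt <- as.numeric(d$timestamp)
  for (i in seq_len(nrow(d))) {
    if (grp[i] != last_g || tt[i] - last_t > 1) {
      keep[i] <- TRUE; last_t <- tt[i]; last_g <- grp[i]
    }
  }
  out <- d[keep, , drop = FALSE]
  out[order(out$timestamp, out$tag_id), , drop = FALSE]
}

#' Compare the two antennas of a double-antenna station
#'
#' Computes, per antenna, the number of raw detections, the number of
#' visits (each antenna's stream segmented independently with
#' [segment_visits()]), the set of unique tags, and an aligned daily
#' detection series for plotting.
#'
#' @param detections detection table.
#' @param station_id station with exactly two antennas.
#' @param gap_max_s gap rule passed to [segment_visits()].
#' @return a list with one element per antenna plus `daily`, a data.frame
#'   `date x antenna` of daily detection counts.
#' @export
compare_antennas <- function(detections, station_id, gap_max_s = 11) {
  d <- detections[detections$station_id == station_id, , drop = FALSE]
  ants <- sort(unique(d$antenna_id))
  if (length(ants) != 2L)
    stop("station ", station_id, " has ", length(ants),
         " antenna(s); need exactly 2", call. = FALSE)
  per <- lapply(ants, function(a) {
    da <- d[d$antenna_id == a, , drop = FALSE]
    list(antenna_id = a,
         n_detections = nrow(da),
         n_visits = nrow(segment_visits(da, gap_max_s = gap_max_s)),
         unique_tags = sort(unique(da$tag_id)))
  })
  names(per) <- ants
  days <- sort(unique(as.Date(d$timestamp)))
  daily <- data.frame(date = days)
  for (a in ants)
    daily[[a]] <- as.integer(table(factor(
      as.Date(d$timestamp[d$antenna_id == a]), levels = as.character(days))))
  c(per, list(daily = daily))
}
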