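# Fixture builders and independent oracles shared across test files.

T0 <- as.POSIXct("2017-03-01 08:00:00", tz = "UTC")

make_detections <- function(offsets_s, tag = "A", station = "S1",
                            site = "site1", antenna = NULL, t0 = T0) {
  data.frame(tag_id = tag, timestamp = t0 + offsets_s,
             antenna_id = if (is.null(antenna)) paste0(station, "-side")
                          else antenna,
             station_id = station, site_id = site,
             stringsAsFactors = FALSE)
}

make_visits <- function(starts_s, ends_s, tags, station = "S1",
                        site = "site1", t0 = T0) {
  data.frame(tag_id = tags, station_id = station, site_id = site,
             start = t0 + starts_s, end = t0 + ends_s,
             duration_s = as.integer(ends_s - starts_s),
             n_detections = pmax(1L, as.integer((ends_s - starts_s) %/% 10) + 1L),
             transient = (ends_s - starts_s) < 10,
             stringsAsFactors = FALSE)
}

make_roster <- function(tags, species = "ANNA", sex = "M", age = "AHY",
                        tag_date = as.Date("2017-01-01"), site = "site1") {
  data.frame(tag_id = tags, band_id = paste0("B", tags),
             species = rep_len(species, length(tags)),
             sex = rep_len(sex, length(tags)),
             age = rep_len(age, length(tags)),
             tag_date = rep_len(tag_date, length(tags)),
             tag_site = rep_len(site, length(tags)),
             stringsAsFactors = FALSE)
}

# --- visit segmentation oracle: naive linear scan over sorted gaps -------
oracle_segment <- function(offsets_s, gap_max_s = 11) {
  t <- sort(unique(offsets_s))
  groups <- list(); cur <- t[1]
  for (x in t[-1]) {
    if (x - cur[length(cur)] <= gap_max_s) cur <- c(cur, x)
    else { groups[[length(groups) + 1]] <- cur; cur <- x }
  }
  groups[[length(groups) + 1]] <- cur
  data.frame(duration = vapply(groups, function(g) max(g) - min(g),
                               numeric(1)),
             n = lengths(groups))
}

# --- betweenness oracle: exhaustive simple-path enumeration (n <= 8) -----
# For every unordered pair (s,t), enumerate ALL simple paths via recursion,
# keep the shortest ones, and credit each interior node with
# (#shortest paths through it) / (#shortest paths).
oracle_betweenness <- function(edges, nodes) {
  n <- length(nodes)
  adj <- matrix(FALSE, n, n, dimnames = list(nodes, nodes))
  for (i in seq_len(nrow(edges))) {
    adj[edges$bird_a[i], edges$bird_b[i]] <- TRUE
    adj[edges$bird_b[i], edges$bird_a[i]] <- TRUE
  }
  score <- setNames(numeric(n), nodes)
  all_paths <- function(cur, target, visited) {
    if (cur == target) return(list(visited))
    out <- list()
    for (nx in nodes[adj[cur, ]]) {
      if (!nx %in% visited)
        out <- c(out, all_paths(nx, target, c(visited, nx)))
    }
    out
  }
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    paths <- all_paths(nodes[i], nodes[j], nodes[i])
    if (!length(paths)) next
    len <- min(lengths(paths))
    sp <- paths[lengths(paths) == len]
    for (p in sp) {
      interior <- setdiff(p, c(nodes[i], nodes[j]))
      score[interior] <- score[interior] + 1 / length(sp)
    }
  }
  denom <- if (n > 2) (n - 1) * (n - 2) / 2 else 1
  score / denom
}

# --- CJS single-history oracle: enumerate latent alive trajectories ------
# P(h | released at f) summed over all alive/dead paths; phi, p scalars.
oracle_cjs_prob <- function(h, phi, p) {
  T <- length(h); f <- which(h == 1)[1]
  if (f == T) return(1)
  total <- 0
  # d = last occasion alive (from f to T); after d the bird is dead
  for (d in f:T) {
    pr <- phi^(d - f) * (if (d < T) (1 - phi) else 1)
    obs <- 1
    for (t in (f + 1):T) {
      if (t > d) { if (h[t] == 1) { obs <- 0; break } }
      else obs <- obs * (if (h[t] == 1) p else 1 - p)
    }
    if (f + 1 > T) obs <- 1
    total <- total + pr * obs
  }
  total
}
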