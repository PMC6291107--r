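## Pairwise interaction detection, contact-network inference, centralities,
## node-label permutation regression.

#' Detect pairwise interactions between visits at a feeder
#'
#' Two different birds' visits at the same station interact when either
#' (a) their co-mingling (interval overlap) exceeds `long_overlap_s`
#' seconds - a LONG interaction - or (b) the gap from the end of the
#' earlier visit to the start of the later one is strictly less than
#' `transient_gap_s` seconds - a TRANSIENT interaction (this includes
#' negative gaps, i.e. overlaps too short to qualify as LONG).  A gap of
#' exactly `transient_gap_s` is no interaction.  All qualifying pairs are
#' emitted, not only time-adjacent ones: one long visit can interact with
#' several partners.
#'
#' @param visits visit table (one or more stations; pairs are only formed
#'   within a station).
#' @param long_overlap_s LONG threshold (strict `>`), default 11 s.
#' @param transient_gap_s TRANSIENT gap threshold (strict `<`), default 11 s.
#' @return a `data.frame`: `bird_a`, `bird_b` (canonical `a < b`),
#'   `station_id`, `kind` (`"LONG"`/`"TRANSIENT"`), `overlap_s`, `gap_s`,
#'   `t_ref` (start of the later visit).
#' @export
detect_interactions <- function(visits, long_overlap_s = 11,
                                transient_gap_s = 11) {
  empty <- data.frame(bird_a = character(), bird_b = character(),
                      station_id = character(), kind = character(),
                      overlap_s = numeric(), gap_s = numeric(),
                      t_ref = as.POSIXct(character(), tz = "UTC"),
                      stringsAsFactors = FALSE)
  if (!nrow(visits)) return(empty)
  out <- list()
  for (st in unique(visits$station_id)) {
    v <- visits[visits$station_id == st, , drop = FALSE]
    v <- v[order(as.numeric(v$start), v$tag_id), , drop = FALSE]
    s <- as.numeric(v$start); e <- as.numeric(v$end)
    n <- nrow(v)
    for (i in seq_len(n)) {
      j <- i + 1L
      # sorted by start, so once start_j - end_i >= gap threshold and
      # there is no overlap, no later j can qualify with i as "earlier"
      while (j <= n && s[j] - e[i] < transient_gap_s) {
        if (v$tag_id[j] != v$tag_id[i]) {
          ov <- max(0, min(e[i], e[j]) - s[j])
          gap <- s[j] - e[i]
          kind <- if (ov > long_overlap_s) "LONG" else "TRANSIENT"
          pr <- sort(c(v$tag_id[i], v$tag_id[j]))
          out[[length(out) + 1L]] <- data.frame(
            bird_a = pr[1L], bird_b = pr[2L], station_id = st,
            kind = kind, overlap_s = ov, gap_s = gap,
            t_ref = v$start[j], stringsAsFactors = FALSE)
        }
        j <- j + 1L
      }
    }
  }
  if (!length(out)) return(empty)
  res <- do.call(rbind, out)
  res[order(res$t_ref, res$bird_a, res$bird_b), , drop = FALSE]
}

#' Build the weighted contact network from interactions
#'
#' Birds with at least one interaction become nodes; an undirected edge
#' connects each interacting pair, weighted by the summed co-mingling time
#' (`weight_s = sum(overlap_s)`; transient interactions contribute 0 s but
#' still create/keep the edge) with the interaction count alongside.
#'
#' @param interactions output of [detect_interactions()].
#' @param roster optional roster supplying node attributes (species, sex,
#'   age).
#' @return list of class `"contact_network"`: `nodes` (data.frame),
#'   `edges` (data.frame `bird_a, bird_b, weight_s, n_interactions`).
#' @export
build_network <- function(interactions, roster = NULL) {
  if (!nrow(interactions)) {
    net <- list(nodes = data.frame(tag_id = character()),
                edges = data.frame(bird_a = character(),
                                   bird_b = character(),
                                   weight_s = numeric(),
                                   n_interactions = integer()))
    return(structure(net, class = "contact_network"))
  }
  key <- paste(interactions$bird_a, interactions$bird_b, sep = "\r")
  agg <- aggregate(list(weight_s = interactions$overlap_s,
                        n_interactions = rep(1L, nrow(interactions))),
                   by = list(key = key), FUN = sum)
  pr <- do.call(rbind, strsplit(agg$key, "\r", fixed = TRUE))
  edges <- data.frame(bird_a = pr[, 1L], bird_b = pr[, 2L],
                      weight_s = agg$weight_s,
                      n_interactions = as.integer(agg$n_interactions),
                      stringsAsFactors = FALSE)
  edges <- edges[order(edges$bird_a, edges$bird_b), , drop = FALSE]
  tags <- sort(unique(c(edges$bird_a, edges$bird_b)))
  nodes <- data.frame(tag_id = tags, stringsAsFactors = FALSE)
  if (!is.null(roster)) {
    i <- match(tags, roster$tag_id)
    nodes$species <- roster$species[i]
    nodes$sex <- roster$sex[i]
    nodes$age <- roster$age[i]
  }
  structure(list(nodes = nodes, edges = edges), class = "contact_network")
}

#' @export
print.contact_network <- function(x, ...) {
  cat("Contact network:", nrow(x$nodes), "birds,", nrow(x$edges),
      "edges, total co-mingling", sum(x$edges$weight_s), "s\n")
  invisible(x)
}

#' Convert a contact network to an igraph graph
#'
#' @param network a `"contact_network"`.
#' @return an undirected [igraph::graph] with node attributes and edge
#'   attributes `weight_s`, `n_interactions`.
#' @export
as_igraph <- function(network) {
  igraph::graph_from_data_frame(
    d = network$edges, directed = FALSE,
    vertices = network$nodes)
}

#' Node centralities of the contact network
#'
#' Degree = number of distinct interaction partners.  Betweenness = the
#' fraction of unweighted shortest paths between other node pairs passing
#' through the node, normalized by `(n-1)(n-2)/2`; pairs in different
#' components contribute nothing.  (A weighted variant, distance
#' `1/weight_s` with zero-weight edges at distance 1, is available via
#' `weighted = TRUE`.)
#'
#' @param network a `"contact_network"`.
#' @param weighted use inverse-weight distances for betweenness.
#' @return a `data.frame` `tag_id`, `degree`, `betweenness`.
#' @export
centralities <- function(network, weighted = FALSE) {
  g <- as_igraph(network)
  n <- igraph::vcount(g)
  if (!n) return(data.frame(tag_id = character(), degree = integer(),
                            betweenness = numeric()))
  deg <- igraph::degree(g)
  w <- if (weighted) {
    ws <- igraph::E(g)$weight_s
    1 / ifelse(ws > 0, ws, 1)
  } else NULL
  btw_raw <- igraph::betweenness(g, directed = FALSE, weights = w)
  denom <- if (n > 2) (n - 1) * (n - 2) / 2 else 1
  data.frame(tag_id = igraph::V(g)$name, degree = as.integer(deg),
             betweenness = btw_raw / denom,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Connected components of the contact network
#'
#' @param network a `"contact_network"`.
#' @return list of character vectors of tag ids, largest component first.
#' @export
network_components <- function(network) {
  if (!nrow(network$nodes)) return(list())
  g <- as_igraph(network)
  cm <- igraph::components(g)
  comps <- split(igraph::V(g)$name, cm$membership)
  comps <- lapply(comps, sort)
  names(comps) <- NULL
  comps[order(-lengths(comps))]
}

#' Node-label permutation regression of centrality on attributes
#'
#' Fits an ordinary least-squares regression of each centrality measure on
#' node attributes (dummy-coded), then re-fits after jointly permuting the
#' attribute rows across nodes `n_perm` times, keeping the network (and
#' hence the centralities) fixed.  Two-sided permutation p-values use the
#' add-one estimator `p = (1 + #{|b*| >= |b_obs|}) / (1 + n_perm)`, which
#' can never return 0.
#'
#' @param centrality_table output of [centralities()] (or any data.frame
#'   with `tag_id` plus numeric response columns).
#' @param attributes data.frame with `tag_id` and the predictor columns.
#' @param predictors character vector of attribute columns, default
#'   `c("sex", "age")`.
#' @param n_perm number of permutations (default 10000).
#' @param seed RNG seed; recorded in the result.
#' @param unknown `"exclude"` drops nodes with `UNKNOWN` in a predictor;
#'   `"level"` keeps UNKNOWN as its own factor level.
#' @return a `data.frame` of class `"permutation_glm"`: `response`,
#'   `term`, `beta_observed`, `p_perm`, `n_permutations`, `seed`.
#'   Predictors constant across nodes yield `NA` coefficients (undefined,
#'   not 0).
#' @export
permutation_glm <- function(centrality_table, attributes,
                            predictors = c("sex", "age"),
                            n_perm = 10000, seed = 1,
                            unknown = c("exclude", "level")) {
  unknown <- match.arg(unknown)
  stopifnot(n_perm >= 1)
  dat <- merge(centrality_table, attributes, by = "tag_id")
  responses <- setdiff(names(centrality_table), "tag_id")
  responses <- responses[vapply(dat[responses], is.numeric, logical(1))]
  if (unknown == "exclude") {
    for (p in predictors) dat <- dat[dat[[p]] != "UNKNOWN", , drop = FALSE]
  }
  usable <- predictors[vapply(predictors,
                              function(p) length(unique(dat[[p]])) > 1L,
                              logical(1))]
  dropped <- setdiff(predictors, usable)
  res <- list()
  if (length(usable)) {
    for (p in usable) dat[[p]] <- factor(dat[[p]])
    form <- stats::as.formula(paste("~", paste(usable, collapse = " + ")))
    X <- model.matrix(form, dat)
    set.seed(seed)
    perms <- replicate(n_perm, sample.int(nrow(dat)))
    for (resp in responses) {
      y <- dat[[resp]]
      b_obs <- lm.fit(X, y)$coefficients[-1L]
      exceed <- numeric(length(b_obs))
      for (k in seq_len(n_perm)) {
        Xp <- X[perms[, k], , drop = FALSE]
        b_star <- lm.fit(Xp, y)$coefficients[-1L]
        exceed <- exceed + (abs(b_star) >= abs(b_obs) - 1e-12)
      }
      res[[length(res) + 1L]] <- data.frame(
        response = resp, term = names(b_obs), beta_observed = unname(b_obs),
        p_perm = unname((1 + exceed) / (1 + n_perm)),
        n_permutations = n_perm, seed = seed, stringsAsFactors = FALSE)
    }
  }
  for (p in dropped) {
    for (resp in responses)
      res[[length(res) + 1L]] <- data.frame(
        response = resp, term = p, beta_observed = NA_real_,
        p_perm = NA_real_, n_permutations = n_perm, seed = seed,
        stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, res)
  class(out) <- c("permutation_glm", class(out))
  rownames(out) <- NULL
  out
}
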