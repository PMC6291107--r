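test_that("interaction detection classifies the threshold geometry", {
  pair <- function(a_int, b_int) {
    v <- make_visits(c(a_int[1], b_int[1]), c(a_int[2], b_int[2]),
                     c("A", "B"))
    detect_interactions(v)
  }
  # overlap 15 > 11 -> LONG
  r <- pair(c(0, 30), c(10, 25))
  expect_equal(r$kind, "LONG"); expect_equal(r$overlap_s, 15)
  # gap 10 < 11 -> TRANSIENT, overlap 0
  r <- pair(c(0, 30), c(40, 45))
  expect_equal(r$kind, "TRANSIENT"); expect_equal(r$overlap_s, 0)
  expect_equal(r$gap_s, 10)
  # gap exactly 11 -> no interaction
  expect_equal(nrow(pair(c(0, 30), c(41, 45))), 0L)
  # far apart -> none
  expect_equal(nrow(pair(c(0, 5), c(100, 110))), 0L)
  # nested overlap 5 (> 0 but <= 11) -> TRANSIENT via negative gap
  r <- pair(c(0, 30), c(20, 25))
  expect_equal(r$kind, "TRANSIENT"); expect_equal(r$overlap_s, 5)
  expect_equal(r$gap_s, -10)
  # same bird never interacts with itself; different stations never pair
  self <- make_visits(c(0, 20), c(5, 25), c("A", "A"))
  expect_equal(nrow(detect_interactions(self)), 0L)
  cross <- rbind(make_visits(0, 30, "A", station = "S1"),
                 make_visits(5, 25, "B", station = "S2"))
  expect_equal(nrow(detect_interactions(cross)), 0L)
})

test_that("one long visit can interact with several partners", {
  v <- make_visits(c(0, 5, 20, 100), c(200, 30, 40, 130),
                   c("A", "B", "C", "D"))
  r <- detect_interactions(v)
  partners <- unique(c(r$bird_a, r$bird_b))
  expect_setequal(partners, c("A", "B", "C", "D"))
  # A overlaps B, C and D by > 11 s; B-C overlap 10 s is TRANSIENT
  expect_equal(sum(r$kind == "LONG"), 3L)
  expect_equal(sum(r$kind == "TRANSIENT"), 1L)
})

test_that("interaction detection is order-symmetric and canonical", {
  set.seed(77)
  for (rep in 1:10) {
    n <- 30
    st <- sort(sample.int(2000, n))
    v <- make_visits(st, st + sample(c(0, 0, 0, 20, 40), n, TRUE),
                     sample(LETTERS[1:6], n, TRUE))
    r1 <- detect_interactions(v)
    r2 <- detect_interactions(v[sample.int(n), , drop = FALSE])
    key <- function(r) sort(paste(r$bird_a, r$bird_b, r$kind, r$overlap_s,
                                  r$gap_s, r$t_ref))
    expect_equal(key(r1), key(r2))
    expect_true(all(r1$bird_a < r1$bird_b))
  }
})

test_that("network construction aggregates pair weights", {
  v <- make_visits(c(0, 100, 200), c(0, 100, 200), "A")
  tr <- data.frame(bird_a = "A", bird_b = "B", station_id = "S1",
                   kind = "TRANSIENT", overlap_s = 0, gap_s = 5,
                   t_ref = T0, stringsAsFactors = FALSE)
  net <- build_network(rbind(tr, tr, tr))
  expect_equal(net$edges$n_interactions, 3L)
  expect_equal(net$edges$weight_s, 0)
  tr2 <- tr; tr2$kind <- "LONG"
  tr2$overlap_s <- 15
  tr3 <- tr2; tr3$overlap_s <- 20
  net2 <- build_network(rbind(tr2, tr3))
  expect_equal(net2$edges$weight_s, 35)
  empty <- build_network(detect_interactions(v[0, ]))
  expect_equal(nrow(empty$nodes), 0L)
  expect_equal(length(network_components(empty)), 0L)
})

test_that("degree sum equals twice the edge count on random networks", {
  set.seed(123)
  for (rep in 1:10) {
    n <- 60
    st <- sort(sample.int(4000, n))
    v <- make_visits(st, st + sample(c(0, 0, 15, 40), n, TRUE),
                     sample(sprintf("B%02d", 1:12), n, TRUE),
                     station = sample(c("S1", "S2"), n, TRUE))
    net <- build_network(detect_interactions(v))
    if (!nrow(net$edges)) next
    cent <- centralities(net)
    expect_equal(sum(cent$degree), 2L * nrow(net$edges))
    expect_true(all(cent$degree <= nrow(net$nodes) - 1L))
    expect_true(all(cent$betweenness >= 0 & cent$betweenness <= 1))
  }
})

test_that("centralities match exhaustive path enumeration on small graphs", {
  mk_net <- function(edges) {
    structure(list(nodes = data.frame(
      tag_id = sort(unique(c(edges$bird_a, edges$bird_b))),
      stringsAsFactors = FALSE), edges = edges),
      class = "contact_network")
  }
  ed <- function(...) {
    m <- matrix(c(...), ncol = 2, byrow = TRUE)
    data.frame(bird_a = m[, 1], bird_b = m[, 2], weight_s = 1,
               n_interactions = 1L, stringsAsFactors = FALSE)
  }
  # star: center has betweenness 1, leaves 0
  star <- mk_net(ed("c", "l1", "c", "l2", "c", "l3", "c", "l4"))
  cs <- centralities(star)
  expect_equal(cs$degree[cs$tag_id == "c"], 4L)
  expect_equal(cs$betweenness[cs$tag_id == "c"], 1)
  expect_true(all(cs$betweenness[cs$tag_id != "c"] == 0))
  # complete graph K4: all betweenness 0
  k4 <- mk_net(ed("a", "b", "a", "c", "a", "d", "b", "c", "b", "d",
                  "c", "d"))
  expect_true(all(centralities(k4)$betweenness == 0))
  # path a-b-c: b carries the single a<->c geodesic
  path <- mk_net(ed("a", "b", "b", "c"))
  cp <- centralities(path)
  expect_equal(cp$betweenness[cp$tag_id == "b"], 1)
  # random graphs vs the exhaustive simple-path oracle
  set.seed(9)
  for (rep in 1:8) {
    nodes <- letters[1:sample(4:8, 1)]
    pairs <- t(combn(nodes, 2))
    keep <- runif(nrow(pairs)) < 0.45
    if (!any(keep)) next
    edges <- data.frame(bird_a = pairs[keep, 1], bird_b = pairs[keep, 2],
                        weight_s = 1, n_interactions = 1L,
                        stringsAsFactors = FALSE)
    net <- mk_net(edges)
    got <- centralities(net)
    want <- oracle_betweenness(edges, net$nodes$tag_id)
    expect_equal(got$betweenness, unname(want[got$tag_id]),
                 tolerance = 1e-12)
  }
})

test_that("components split disjoint groups, largest first", {
  ed <- data.frame(bird_a = c("a", "b", "a", "x", "y", "x", "p"),
                   bird_b = c("b", "c", "c", "y", "z", "z", "q"),
                   weight_s = 1, n_interactions = 1L,
                   stringsAsFactors = FALSE)
  net <- structure(list(nodes = data.frame(
    tag_id = c("a", "b", "c", "x", "y", "z", "p", "q")), edges = ed),
    class = "contact_network")
  comps <- network_components(net)
  expect_equal(lengths(comps), c(3L, 3L, 2L))
  expect_true(list(c("p", "q")) %in% comps)
})

test_that("a 3-site colony yields site-separated communities", {
  cfg <- colony_config(
    n_birds = list(ANNA = c(F_AHY = 15, M_AHY = 15)),
    start = "2017-06-01", end = "2017-06-30",
    visit_rate = 25, p_detect = c(AHY = 1, HY = 1, UNKNOWN = 1),
    phi_monthly = 1, night_frac = 0, follower_pairs = 6)
  roster <- simulate_roster(cfg, 37)
  v <- simulate_visits(roster, cfg, 37)
  net <- build_network(detect_interactions(segment_visits(
    render_detections(v, cfg, 37))), roster)
  expect_gt(nrow(net$edges), 0)
  site_of <- setNames(roster$tag_site, roster$tag_id)
  # no bird visits outside its tagging site, so every edge is intra-site
  expect_true(all(site_of[net$edges$bird_a] == site_of[net$edges$bird_b]))
  comp_sites <- unique(vapply(network_components(net),
                              function(cp) unname(site_of[cp[1]]),
                              character(1)))
  expect_setequal(unique(site_of[net$nodes$tag_id]), comp_sites)
})

test_that("follower pairs create known LONG interactions", {
  cfg <- colony_config(
    n_birds = list(ANNA = c(M_AHY = 10)),
    sites = list(site2 = c("A4", "A5")),
    start = "2017-06-01", end = "2017-06-20",
    visit_rate = 10, p_detect = c(AHY = 1, HY = 1, UNKNOWN = 1),
    phi_monthly = 1, night_frac = 0, follower_pairs = 3)
  roster <- simulate_roster(cfg, 41)
  v <- simulate_visits(roster, cfg, 41)
  fp <- attr(v, "follower_pairs")
  ints <- detect_interactions(segment_visits(render_detections(v, cfg, 41)))
  long <- ints[ints$kind == "LONG", ]
  for (k in seq_len(nrow(fp))) {
    pr <- sort(c(fp$leader[k], fp$follower[k]))
    expect_true(any(long$bird_a == pr[1] & long$bird_b == pr[2]))
  }
})

test_that("permutation regression: nulls, determinism and exact enumeration", {
  attrs <- data.frame(tag_id = letters[1:6],
                      sex = c("F", "F", "F", "M", "M", "M"),
                      age = "AHY", stringsAsFactors = FALSE)
  cent <- data.frame(tag_id = letters[1:6], degree = rep(3, 6))
  # constant response -> beta 0, p 1; constant predictor -> NA not 0
  r <- permutation_glm(cent, attrs, n_perm = 50, seed = 3)
  expect_equal(r$beta_observed[r$term == "sexM"], 0)
  expect_equal(r$p_perm[r$term == "sexM"], 1)
  expect_true(is.na(r$beta_observed[r$term == "age"]))
  # reproducible under a fixed seed; p bounded below by 1/(n_perm+1)
  cent2 <- data.frame(tag_id = letters[1:6], degree = c(5, 4, 4, 1, 2, 1))
  r1 <- permutation_glm(cent2, attrs, n_perm = 300, seed = 11)
  r2 <- permutation_glm(cent2, attrs, n_perm = 300, seed = 11)
  expect_identical(r1, r2)
  expect_gte(min(r1$p_perm, na.rm = TRUE), 1 / 301)
  # exact enumeration over all 6! label orders vs sampled permutations
  y <- cent2$degree
  X <- model.matrix(~sex, attrs)
  b_obs <- lm.fit(X, y)$coefficients[2]
  perms <- as.matrix(expand.grid(rep(list(1:6), 6)))
  perms <- perms[apply(perms, 1, function(r) length(unique(r)) == 6), ]
  b_all <- apply(perms, 1, function(ix)
    lm.fit(X[ix, , drop = FALSE], y)$coefficients[2])
  p_exact <- mean(abs(b_all) >= abs(b_obs) - 1e-12)
  r3 <- permutation_glm(cent2, attrs, predictors = "sex", n_perm = 4000,
                        seed = 19)
  expect_lt(abs(r3$p_perm - p_exact), 0.02)
})

test_that("permutation regression holds its size under the null", {
  set.seed(55)
  rej <- replicate(300, {
    n <- 20
    cent <- data.frame(tag_id = sprintf("b%02d", 1:n),
                       degree = rpois(n, 6))
    attrs <- data.frame(tag_id = cent$tag_id,
                        sex = sample(c("F", "M"), n, TRUE),
                        stringsAsFactors = FALSE)
    r <- permutation_glm(cent, attrs, predictors = "sex", n_perm = 199,
                         seed = sample.int(1e6, 1))
    r$p_perm <= 0.05
  })
  ci <- qbinom(c(0.005, 0.995), 300, 0.05) / 300
  expect_gte(mean(rej), ci[1])
  expect_lte(mean(rej), ci[2])
})
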