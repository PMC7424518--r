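edges_of <- function(net) chronnet_edges(net)

test_that("the chronological link rule produces the expected directed weights", {
  # consecutive pairs, h = 1
  net <- build_chronnet(c(1, 2, 1, 2, 3), 1:5, directed = TRUE)
  expect_equal(edges_of(net),
               canonical_edges(data.frame(from = c("1", "2", "2"),
                                          to = c("2", "1", "3"),
                                          weight = c(2, 1, 1))))
  expect_equal(sum(edges_of(net)$weight), 5 - 1)   # T - 1 pairs

  # consecutive same-cell events become self-loops
  loops <- build_chronnet(c(4, 4, 4), 1:3, directed = TRUE)
  expect_equal(edges_of(loops),
               data.frame(from = "4", to = "4", weight = 2))
  none <- build_chronnet(c(4, 4, 4), 1:3, directed = TRUE, self_loops = FALSE)
  expect_equal(nrow(edges_of(none)), 0L)

  # window h = 2 links every lag 1..2
  w2 <- build_chronnet(c(1, 2, 3), 1:3, h = 2, directed = TRUE)
  expect_equal(edges_of(w2),
               canonical_edges(data.frame(from = c("1", "1", "2"),
                                          to = c("2", "3", "3"),
                                          weight = c(1, 1, 1))))
  # exact-lag alternative links only lag h
  e2 <- build_chronnet(c(1, 2, 3), 1:3, h = 2, directed = TRUE,
                       mode = "exact")
  expect_equal(edges_of(e2), data.frame(from = "1", to = "3", weight = 1))

  # spatial cutoff suppresses distant consecutive events
  far <- build_chronnet(c(1, 2), 1:2, coords = rbind(c(0, 0), c(5, 0)),
                        d_max = 1, directed = TRUE)
  expect_equal(nrow(edges_of(far)), 0L)
  near <- build_chronnet(c(1, 2), 1:2, coords = rbind(c(0, 0), c(5, 0)),
                         d_max = 5, directed = TRUE)
  expect_equal(edges_of(near)$weight, 1)           # boundary: d <= d_max links

  expect_error(build_chronnet(c(1, 2), c(2, 1)), "sorted")
  expect_error(build_chronnet(c(1, 2), 1:3), "aligned")
  expect_error(build_chronnet(c(1, 2), 1:2, h = 0), "h must be")
})

test_that("parallel events link all combinations of different cells across consecutive stamps", {
  # {A, B} at t = 1, {B, C} at t = 2 -> A->B, A->C, B->C but no B->B
  net <- build_chronnet(c(1, 2, 2, 3), c(1, 1, 2, 2), directed = TRUE)
  expect_equal(edges_of(net),
               canonical_edges(data.frame(from = c("1", "1", "2"),
                                          to = c("2", "3", "3"),
                                          weight = c(1, 1, 1))))
  # the flag restores same-cell counting across parallel groups
  withloop <- build_chronnet(c(1, 2, 2, 3), c(1, 1, 2, 2), directed = TRUE,
                             parallel_self_loops = TRUE)
  expect_true(any(edges_of(withloop)$from == "2" &
                    edges_of(withloop)$to == "2"))

  # duplicate events of one cell in a stamp count once (node combinations)
  dup <- build_chronnet(c(1, 1, 2), c(1, 1, 2), directed = TRUE)
  expect_equal(edges_of(dup), data.frame(from = "1", to = "2", weight = 1))

  # all-distinct timestamps reduce to singleton groups / consecutive pairs
  expect_equal(group_parallel(1:4), list(1L, 2L, 3L, 4L))
  expect_equal(group_parallel(c(1, 1, 2, 3, 3, 3)),
               list(1:2, 3L, 4:6))
  expect_error(group_parallel(c(2, 1)), "sorted")

  # singleton same-cell consecutive groups self-loop under the plain rule
  # but not under the parallel combination rule unless flagged
  plain <- build_chronnet(c(7, 7), c(1, 2), directed = TRUE)
  expect_equal(edges_of(plain)$weight, 1)
  par_ctx <- build_chronnet(c(7, 5, 7), c(1, 1, 2), directed = TRUE)
  expect_false(any(edges_of(par_ctx)$from == "7" &
                     edges_of(par_ctx)$to == "7"))
})

test_that("undirected aggregation sums reciprocal weights and conserves total weight", {
  net <- build_chronnet(c(1, 2, 1, 2, 3), 1:5, directed = TRUE)
  und <- to_undirected(net)
  e <- edges_of(und)
  expect_equal(e[e$from == "1" & e$to == "2", "weight"], 3)   # 2 + 1
  expect_false(igraph::is_directed(und))
  expect_equal(to_undirected(und), und)   # idempotent

  for (s in 1:5) {
    r <- random_chronnet(s, T_events = 80, parallel = TRUE, directed = TRUE)
    d <- edges_of(r$net)
    u <- edges_of(to_undirected(r$net))
    expect_equal(sum(u$weight), sum(d$weight))  # conservation incl. loops
    expect_equal(u, undirected_edges(d))        # independent aggregation
  }
})

test_that("pruning removes weights <= tau, keeps nodes, and nests", {
  net <- build_chronnet(c(1, 2, 1, 2, 1, 2, 3, 1, 3), 1:9)  # A-B:5, B-C:1, A-C:2
  p2 <- prune_chronnet(net, 2)
  expect_equal(edges_of(p2)$weight, 5)
  expect_equal(igraph::vcount(p2), 3L)            # isolated nodes retained
  expect_equal(chronnet_config(p2)$tau, 2)
  expect_equal(chronnet_config(p2)$isolated_nodes, 1)
  expect_equal(edges_of(prune_chronnet(net, 0)), edges_of(net))  # identity
  expect_error(prune_chronnet(net, -1), "tau")

  # nesting: edge set at larger tau is a subset, density non-increasing
  for (s in 1:5) {
    r <- random_chronnet(s + 20, T_events = 150, n_cells = 6)
    taus <- c(0, 1, 2, 4, 8)
    sets <- lapply(taus, function(tt) {
      e <- edges_of(prune_chronnet(r$net, tt)); paste(e$from, e$to)
    })
    dens <- sapply(taus, function(tt) net_density(prune_chronnet(r$net, tt)))
    for (i in seq_along(taus)[-1]) {
      expect_true(all(sets[[i]] %in% sets[[i - 1]]))
    }
    expect_true(all(diff(dens) <= 0))
  }
})

test_that("construction matches a brute-force pair enumerator on random inputs", {
  cases <- expand.grid(seed = 1:4, h = c(1, 2, 3), parallel = c(FALSE, TRUE))
  for (i in seq_len(nrow(cases))) {
    cs <- cases[i, ]
    set.seed(cs$seed * 100 + cs$h)
    T_ev <- sample(50:200, 1)
    cells <- sample.int(7, T_ev, replace = TRUE)
    times <- if (cs$parallel) {
      sort(sample.int(ceiling(T_ev / 3), T_ev, replace = TRUE))
    } else seq_len(T_ev)
    net <- build_chronnet(cells, times, h = cs$h, directed = TRUE)
    expect_equal(edges_of(net),
                 brute_chronnet(cells, times, h = cs$h),
                 info = sprintf("seed %d h %d parallel %s",
                                cs$seed, cs$h, cs$parallel))
  }
  # with a distance cutoff
  set.seed(99)
  cells <- sample.int(5, 60, replace = TRUE)
  coords <- cbind(runif(60, 0, 10), runif(60, 0, 10))
  net <- build_chronnet(cells, 1:60, coords = coords, d_max = 4,
                        directed = TRUE)
  expect_equal(edges_of(net),
               brute_chronnet(cells, 1:60, coords = coords, d_max = 4))
})

test_that("total weight follows the window-size conservation law", {
  # distinct timestamps, self-loops on, no cutoff: sum_w = sum_g max(0, T-g)
  for (s in 1:4) {
    set.seed(s)
    T_ev <- sample(c(3, 10, 57), 1)
    cells <- sample.int(4, T_ev, replace = TRUE)
    for (h in c(1, 2, 5, T_ev + 2)) {
      net <- build_chronnet(cells, seq_len(T_ev), h = h, directed = TRUE)
      expect_equal(sum(edges_of(net)$weight),
                   sum(pmax(0, T_ev - seq_len(h))))
    }
  }
})

test_that("construction time grows roughly linearly in the number of events", {
  t_of <- function(T_ev) {
    set.seed(1)
    cells <- sample.int(50, T_ev, replace = TRUE)
    system.time(build_chronnet(cells, seq_len(T_ev)))[["elapsed"]]
  }
  small <- t_of(20000); large <- t_of(80000)
  # trend check, deliberately generous: 4x the events in far less than
  # quadratic time
  expect_lt(large, max(16 * small, 0.5))
})

test_that("snapshots partition time with no cross-window links", {
  cells <- c(1, 2, 1, 2, 3, 4, 3, 4, 3, 4)
  times <- 1:10
  # one window covering everything reproduces the static chronnet
  one <- build_snapshots(cells, times, delta_t = 10)
  expect_length(one, 1L)
  expect_equal(edges_of(one[[1]]), edges_of(build_chronnet(cells, times)))

  # two windows of 5 events each: 2 * (5 - 1) linked pairs total
  two <- build_snapshots(cells, times, delta_t = 5)
  expect_length(two, 2L)
  expect_equal(sum(sapply(two, function(n) sum(edges_of(n)$weight))), 8)
  # events 6..10 only in the second window
  expect_setequal(igraph::V(two[[2]])$name, c("3", "4"))

  # empty windows are preserved in sequence
  gap <- build_snapshots(c(1, 1, 2, 2), c(1, 2, 11, 12), delta_t = 4)
  expect_length(gap, 3L)
  expect_equal(igraph::vcount(gap[[2]]), 0L)
  expect_equal(attr(gap, "window_starts"), c(1, 5, 9))
  expect_error(build_snapshots(cells, times, delta_t = 0), "delta_t")
})

test_that("chronnets serialize to edge list + GraphML + config and back", {
  net <- prune_chronnet(build_chronnet(c(1, 2, 1, 2, 3, 1), 1:6), 1)
  base <- file.path(withr::local_tempdir(), "net")
  write_chronnet(net, base)
  expect_true(file.exists(paste0(base, "_edges.csv")))
  expect_true(file.exists(paste0(base, ".graphml")))
  back <- read_chronnet(base)
  expect_equal(edges_of(back), edges_of(net))
  expect_setequal(igraph::V(back)$name, igraph::V(net)$name)  # isolated kept
  expect_equal(chronnet_config(back)$tau, 1)
  # the GraphML is readable by igraph itself
  gm <- igraph::read_graph(paste0(base, ".graphml"), format = "graphml")
  expect_equal(igraph::ecount(gm), igraph::ecount(net))
})

test_that("great-circle distances gate lonlat links in kilometres", {
  # ~111 km apart (1 degree of latitude)
  tab <- event_table(c(0, 0), c(0, 1), 1:2, coordinate_system = "lonlat")
  cells <- c(1L, 2L)
  blocked <- build_chronnet(cells, tab$t, coords = cbind(tab$x, tab$y),
                            d_max = 100, metric = "greatcircle",
                            directed = TRUE)
  linked <- build_chronnet(cells, tab$t, coords = cbind(tab$x, tab$y),
                           d_max = 120, metric = "greatcircle",
                           directed = TRUE)
  expect_equal(nrow(edges_of(blocked)), 0L)
  expect_equal(nrow(edges_of(linked)), 1L)
})
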