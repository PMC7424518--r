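# Independent oracles and fixture builders used across the suite.
# Everything here deliberately re-derives results by brute force / first
# principles, never by calling the code paths under test.

# Brute-force chronnet construction: explicit loops over timestamp groups,
# cross products enumerated pair by pair. Returns a canonical data.frame
# (from, to, weight) of the *directed* multigraph aggregation.
brute_chronnet <- function(cells, times, h = 1, self_loops = TRUE,
                           parallel_self_loops = FALSE, coords = NULL,
                           d_max = NULL, mode = c("window", "exact")) {
  mode <- match.arg(mode)
  stopifnot(!is.unsorted(times))
  uts <- unique(times)
  groups <- lapply(uts, function(u) which(times == u))
  G <- length(groups)
  acc <- new.env()
  add <- function(i, j) {
    key <- paste(i, j)
    acc[[key]] <- (acc[[key]] %||0% 0) + 1
  }
  lags <- if (mode == "exact") h else seq_len(h)
  for (L in lags) {
    if (L >= G + 1) next
    for (g in seq_len(max(G - L, 0))) {
      A <- groups[[g]]; B <- groups[[g + L]]
      # distinct cells per group, first event as representative
      Ar <- A[!duplicated(cells[A])]
      Br <- B[!duplicated(cells[B])]
      for (a in Ar) for (b in Br) {
        same <- cells[a] == cells[b]
        singleton <- length(Ar) == 1 && length(Br) == 1
        if (same && !(self_loops && (singleton || parallel_self_loops))) next
        if (!is.null(d_max)) {
          d <- sqrt(sum((coords[a, ] - coords[b, ])^2))
          if (d > d_max) next
        }
        add(cells[a], cells[b])
      }
    }
  }
  keys <- ls(acc)
  if (!length(keys)) {
    return(data.frame(from = character(), to = character(),
                      weight = numeric()))
  }
  parts <- strsplit(keys, " ", fixed = TRUE)
  out <- data.frame(from = vapply(parts, `[`, "", 1),
                    to = vapply(parts, `[`, "", 2),
                    weight = vapply(keys, function(k) acc[[k]], 0))
  canonical_edges(out)
}

`%||0%` <- function(a, b) if (is.null(a)) b else a

# Canonical sorted edge table for set comparison
canonical_edges <- function(df) {
  df <- df[order(df$from, df$to), , drop = FALSE]
  rownames(df) <- NULL
  df
}

chronnet_edges <- function(net) {
  canonical_edges(igraph::as_data_frame(net, what = "edges"))
}

# Undirected canonicalization: unordered pair key
undirected_edges <- function(df) {
  a <- pmin(df$from, df$to); b <- pmax(df$from, df$to)
  agg <- stats::aggregate(weight ~ from + to,
                          data = data.frame(from = a, to = b,
                                            weight = df$weight),
                          FUN = sum)
  canonical_edges(agg)
}

# All-pairs shortest hop distances by Floyd-Warshall on an adjacency matrix
fw_distances <- function(adj) {
  n <- nrow(adj)
  d <- ifelse(adj > 0, 1, Inf)
  diag(d) <- 0
  for (k in seq_len(n)) d <- pmin(d, outer(d[, k], d[k, ], `+`))
  d
}

# Exhaustive betweenness: count shortest paths through each node by the
# d(j,i) + d(i,k) == d(j,k) decomposition with path counts from DP.
brute_betweenness <- function(adj) {
  n <- nrow(adj)
  d <- fw_distances(adj)
  nsp <- matrix(0, n, n)
  for (j in seq_len(n)) {
    nsp[j, j] <- 1
    for (dist in seq_len(n)) {
      at <- which(d[j, ] == dist)
      for (k in at) {
        pred <- which(adj[, k] > 0 & d[j, ] == dist - 1)
        nsp[j, k] <- sum(nsp[j, pred])
      }
    }
  }
  bw <- numeric(n)
  for (i in seq_len(n)) {
    for (j in seq_len(n - 1)) for (k in (j + 1):n) {
      if (j == i || k == i || !is.finite(d[j, k])) next
      if (d[j, i] + d[i, k] == d[j, k]) {
        bw[i] <- bw[i] + nsp[j, i] * nsp[i, k] / nsp[j, k]
      }
    }
  }
  bw
}

# Exhaustive global transitivity: triad census over all node triples
brute_transitivity <- function(adj) {
  n <- nrow(adj)
  tri <- 0; triples <- 0
  for (i in seq_len(n - 2)) for (j in (i + 1):(n - 1)) for (k in (j + 1):n) {
    e <- adj[i, j] > 0; f <- adj[j, k] > 0; g <- adj[i, k] > 0
    ne <- e + f + g
    if (ne == 3) { tri <- tri + 1; triples <- triples + 3 }
    if (ne == 2) triples <- triples + 1
  }
  3 * tri / triples
}

# Discrete power-law sample via exact inverse CDF (zeta normalization
# truncated at kmax, negligible mass beyond for gamma > 2)
rzeta <- function(n, gamma, kmax = 1e6) {
  p <- (seq_len(kmax))^(-gamma)
  cdf <- cumsum(p) / sum(p)
  findInterval(stats::runif(n), cdf) + 1L
}

# Random small chronnet for property tests
random_chronnet <- function(seed, T_events = 60, n_cells = 8, h = 1,
                            parallel = FALSE, ...) {
  set.seed(seed)
  cells <- sample.int(n_cells, T_events, replace = TRUE)
  times <- if (parallel) sort(sample.int(ceiling(T_events / 2), T_events,
                                         replace = TRUE))
           else seq_len(T_events)
  list(cells = cells, times = times,
       net = build_chronnet(cells, times, h = h, ...))
}

# Synthetic MCD14ML-style fire-record fixture (whitespace-delimited).
# Entirely fabricated records for testing the reader and pipeline.
write_modis_fixture <- function(path, n_per_region = 60, seed = 1) {
  set.seed(seed)
  # two fire regions active in alternating months of 2010, plus a
  # persistent static source (type 2) acting as an outlier cell
  months <- sprintf("2010%02d", 1:6)
  rows <- list()
  for (m in seq_along(months)) {
    active <- if (m %% 2 == 1) c(lat = -10, lon = -55) else c(lat = 5, lon = 20)
    k <- n_per_region
    rows[[m]] <- data.frame(
      YYYYMMDD = paste0(months[m], sprintf("%02d", sample(1:28, k, TRUE))),
      HHMM = sprintf("%02d%02d", sample(0:23, k, TRUE), sample(0:59, k, TRUE)),
      sat = "T",
      lat = round(active["lat"] + runif(k, -2, 2), 3),
      lon = round(active["lon"] + runif(k, -2, 2), 3),
      T21 = 330, T31 = 300, sample = 500, FRP = 25,
      conf = sample(60:100, k, TRUE),
      type = 0L)
  }
  static <- data.frame(
    YYYYMMDD = paste0(sample(months, 30, TRUE),
                      sprintf("%02d", sample(1:28, 30, TRUE))),
    HHMM = sprintf("%02d%02d", sample(0:23, 30, TRUE), sample(0:59, 30, TRUE)),
    sat = "A", lat = round(40 + runif(30, -0.1, 0.1), 3),
    lon = round(15 + runif(30, -0.1, 0.1), 3),
    T21 = 350, T31 = 300, sample = 500, FRP = 80,
    conf = sample(80:100, 30, TRUE), type = 2L)
  all <- do.call(rbind, c(rows, list(static)))
  write.table(all, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
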