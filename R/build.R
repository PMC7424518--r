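#' Build a chronnet from a cell-assigned event sequence
#'
#' The chronnet construction rule: given events sorted in time and mapped to
#' grid cells, a directed link is laid from the cell of event `e_a` to the
#' cell of event `e_(a+g)` for every lag `1 <= g <= h` (sequence window `h`),
#' and the weight `w_ij` of a link counts how many consecutive event pairs it
#' represents. Self-loops (`i = j`) count consecutive events inside one cell.
#' An optional spatial cutoff `d_max` suppresses links between events farther
#' apart than `d_max`; strong links therefore represent recurrent consecutive
#' events between two cells.
#'
#' Events sharing a timestamp ("parallel" events) are handled by grouping:
#' the lag is taken over successive *distinct timestamps present in the
#' data*, and every distinct cell with an event at one timestamp is linked to
#' every *different* cell with an event at the next (the full combination,
#' same-cell pairs excluded; see `parallel_self_loops` to allow them). When
#' all timestamps are distinct this reduces exactly to the consecutive-pair
#' rule. Each distinct cell pair contributes weight 1 per group pair.
#'
#' @param cells Integer cell ids aligned with `times` (e.g. a `cell_series`
#'   from [assign_cells()] or [load_cell_assignment()]).
#' @param times Per-event timestamps, non-decreasing.
#' @param coords Optional two-column matrix/data.frame of per-event
#'   coordinates; required when `d_max` is set.
#' @param h Sequence window size (>= 1). With `mode = "window"` (default)
#'   every lag `1..h` links; with `mode = "exact"` only lag `h` does.
#' @param d_max Optional maximum distance between two events for them to be
#'   linked (same units as `coords` for planar data, kilometres for lonlat).
#'   `NULL` (default) disables the cutoff.
#' @param metric `"planar"` (Euclidean) or `"greatcircle"` (haversine, km).
#' @param directed Keep the directed graph (`TRUE`) or aggregate reciprocal
#'   links into undirected weights (`FALSE`, the default used throughout the
#'   package's analyses; see [to_undirected()]).
#' @param self_loops Count consecutive same-cell events as self-loops
#'   (default `TRUE`).
#' @param parallel_self_loops Also count same-cell pairs across parallel
#'   (multi-event) timestamp groups (default `FALSE`: the combination rule
#'   links only different cells).
#' @param mode See `h`.
#' @return A `chronnet`: an [igraph][igraph::igraph-package] graph whose
#'   vertex names are cell ids, with an edge attribute `weight` and a graph
#'   attribute `config` recording the construction parameters (including the
#'   pruning threshold `tau`, 0 until [prune_chronnet()] is applied).
#' @examples
#' net <- build_chronnet(cells = c(1, 2, 1, 2, 3), times = 1:5)
#' igraph::E(net)$weight
#' @export
build_chronnet <- function(cells, times, coords = NULL, h = 1, d_max = NULL,
                           metric = c("planar", "greatcircle"),
                           directed = FALSE, self_loops = TRUE,
                           parallel_self_loops = FALSE,
                           mode = c("window", "exact")) {
  metric <- match.arg(metric)
  mode <- match.arg(mode)
  h <- as.integer(h)
  if (h < 1L) stop("h must be >= 1")
  if (!is.null(d_max)) {
    if (d_max <= 0) stop("d_max must be positive")
    if (is.null(coords)) stop("coords are required when d_max is set")
  }
  n <- length(cells)
  if (length(times) != n) stop("cells and times must be aligned (equal length)")
  if (!is.null(coords)) {
    coords <- as.matrix(coords)[, 1:2, drop = FALSE]
    if (nrow(coords) != n) stop("coords must be aligned with cells and times")
  }
  if (is.unsorted(times)) stop("times must be sorted non-decreasingly; see sort_events()")

  cfg <- list(h = h, d_max = d_max, metric = metric, directed = directed,
              self_loops = self_loops, parallel_self_loops = parallel_self_loops,
              mode = mode, tau = 0)

  node_ids <- sort(unique(as.integer(cells)))
  if (n == 0L) return(empty_chronnet(cfg))

  ci <- match(as.integer(cells), node_ids)       # 1-based node index per event
  grp <- cumsum(c(TRUE, diff(times) != 0))       # timestamp-group per event
  G <- grp[n]

  # one occurrence per (group, cell): the combination rule links *nodes*
  occ <- !duplicated(cbind(grp, ci))
  gu <- grp[occ]; cu <- ci[occ]; ev <- which(occ) # representative event idx
  cnt <- tabulate(gu, nbins = G)                  # occurrences per group
  starts <- cumsum(c(1L, cnt))[seq_len(G)]        # block start per group in gu/cu

  lags <- if (mode == "exact") h else seq_len(min(h, max(G - 1L, 0L)))
  from_all <- integer(0); to_all <- integer(0)
  for (L in lags) {
    if (L >= G) next
    sel <- which(gu <= G - L)
    pc <- cnt[gu[sel] + L]
    from_pos <- rep.int(sel, pc)
    to_pos <- sequence(pc, from = starts[gu[sel] + L])
    same <- cu[from_pos] == cu[to_pos]
    if (any(same)) {
      # same-cell pairs: allowed under the plain consecutive rule (both
      # groups singleton) when self_loops is on; across parallel groups only
      # when parallel_self_loops is also on
      singleton <- cnt[gu[from_pos]] == 1L & cnt[gu[to_pos]] == 1L
      drop <- same & !(self_loops & (singleton | parallel_self_loops))
      if (any(drop)) { from_pos <- from_pos[!drop]; to_pos <- to_pos[!drop] }
    }
    if (!is.null(d_max) && length(from_pos)) {
      d <- event_distance(coords[ev[from_pos], , drop = FALSE],
                          coords[ev[to_pos], , drop = FALSE], metric)
      keep <- d <= d_max
      from_pos <- from_pos[keep]; to_pos <- to_pos[keep]
    }
    from_all <- c(from_all, cu[from_pos])
    to_all <- c(to_all, cu[to_pos])
  }

  net <- edges_to_chronnet(from_all, to_all, node_ids, cfg)
  if (!directed) net <- to_undirected(net) else net
}

# Pairwise (aligned) distance between event coordinate rows
event_distance <- function(a, b, metric) {
  if (metric == "planar") {
    sqrt((a[, 1] - b[, 1])^2 + (a[, 2] - b[, 2])^2)
  } else {
    geosphere::distHaversine(a, b) / 1000   # km; columns are (lon, lat)
  }
}

# Aggregate directed node-index pairs into a weighted igraph chronnet
edges_to_chronnet <- function(from, to, node_ids, cfg) {
  K <- length(node_ids)
  if (length(from)) {
    key <- (from - 1) * K + to
    agg <- sort_key_counts(key)
    e_from <- (agg$key - 1) %/% K + 1
    e_to <- (agg$key - 1) %% K + 1
    edges <- data.frame(from = as.character(node_ids[e_from]),
                        to = as.character(node_ids[e_to]),
                        weight = agg$count)
  } else {
    edges <- data.frame(from = character(), to = character(),
                        weight = numeric())
  }
  g <- igraph::graph_from_data_frame(
    edges, directed = TRUE,
    vertices = data.frame(name = as.character(node_ids)))
  as_chronnet(g, cfg)
}

sort_key_counts <- function(key) {
  key <- sort(key)
  r <- rle(key)
  list(key = r$values, count = r$lengths)
}

empty_chronnet <- function(cfg) {
  g <- igraph::make_empty_graph(0, directed = isTRUE(cfg$directed))
  g <- igraph::set_vertex_attr(g, "name", value = character(0))
  igraph::E(g)$weight <- numeric(0)
  as_chronnet(g, cfg)
}

as_chronnet <- function(g, cfg) {
  g <- igraph::set_graph_attr(g, "config", cfg)
  class(g) <- unique(c("chronnet", class(g)))
  g
}

#' @rdname build_chronnet
#' @param net A `chronnet`.
#' @export
chronnet_config <- function(net) igraph::graph_attr(net, "config")

#' @rdname build_chronnet
#' @param x A `chronnet`.
#' @param ... Unused.
#' @export
print.chronnet <- function(x, ...) {
  cfg <- chronnet_config(x)
  cat(sprintf("chronnet: %d nodes, %d links (%s, h = %d%s, tau = %g)\n",
              igraph::vcount(x), igraph::ecount(x),
              if (igraph::is_directed(x)) "directed" else "undirected",
              cfg$h,
              if (is.null(cfg$d_max)) "" else sprintf(", d_max = %g", cfg$d_max),
              cfg$tau))
  invisible(x)
}

#' Build a chronnet straight from an event table
#'
#' Convenience wrapper: sorts the events, assigns them to `grid` (unless a
#' precomputed `cells` series is given) and calls [build_chronnet()].
#'
#' @param table An `event_table`.
#' @param grid A `rect_grid`; ignored when `cells` is supplied.
#' @param cells Optional precomputed `cell_series` aligned with the *sorted*
#'   table.
#' @param ... Passed to [build_chronnet()].
#' @return A `chronnet`.
#' @export
chronnet_from_events <- function(table, grid = NULL, cells = NULL, ...) {
  table <- sort_events(table)
  if (is.null(cells)) {
    if (is.null(grid)) stop("supply either a grid or a precomputed cell series")
    cells <- assign_cells(table, grid)
  }
  metric <- if (coordinate_system(table) == "lonlat") "greatcircle" else "planar"
  build_chronnet(cells, table$t, coords = cbind(table$x, table$y),
                 metric = metric, ...)
}

#' Group events by identical timestamp
#'
#' Returns the maximal runs of equal timestamps as a list of event-index
#' vectors, in time order. This is the grouping [build_chronnet()] uses to
#' treat parallel (same-timestamp) events.
#'
#' @param times Sorted per-event timestamps.
#' @return A list of integer vectors of event indices.
#' @examples
#' group_parallel(c(1, 1, 2, 3, 3, 3))
#' @export
group_parallel <- function(times) {
  if (is.unsorted(times)) stop("times must be sorted")
  if (!length(times)) return(list())
  grp <- cumsum(c(TRUE, diff(times) != 0))
  unname(split(seq_along(times), grp))
}

#' Aggregate a directed chronnet into its undirected form
#'
#' In the undirected chronnet a link weight is the total number of
#' consecutive-event pairs between two cells regardless of order:
#' `w_ij + w_ji`. Self-loops are carried over unchanged. This is the default
#' analysis object for every measure in the package.
#'
#' @param net A `chronnet` (directed or already undirected, in which case it
#'   is returned as is).
#' @return An undirected `chronnet`.
#' @export
to_undirected <- function(net) {
  if (!igraph::is_directed(net)) return(net)
  cfg <- chronnet_config(net)
  e <- igraph::as_data_frame(net, what = "edges")
  v <- igraph::as_data_frame(net, what = "vertices")
  if (nrow(e)) {
    a <- pmin(e$from, e$to); b <- pmax(e$from, e$to)
    key <- paste(a, b, sep = "\r")
    w <- rowsum(e$weight, group = key)
    parts <- strsplit(rownames(w), "\r", fixed = TRUE)
    e <- data.frame(from = vapply(parts, `[`, "", 1L),
                    to = vapply(parts, `[`, "", 2L),
                    weight = as.numeric(w))
  }
  g <- igraph::graph_from_data_frame(e, directed = FALSE, vertices = v)
  cfg$directed <- FALSE
  as_chronnet(g, cfg)
}

#' Prune weak links from a chronnet
#'
#' Removes every link whose weight is less than or equal to `tau`. Weak
#' links stand for sporadic consecutive co-occurrences (often noise or bad
#' records); pruning keeps only recurrent patterns. Nodes isolated by the
#' pruning are retained — they still identify grid cells — and their count is
#' recorded in the configuration.
#'
#' @param net A `chronnet`.
#' @param tau Non-negative weight threshold; links with `weight <= tau` are
#'   dropped (`tau = 0` is the identity, since construction weights are
#'   >= 1).
#' @return The pruned `chronnet`, with `tau` and the number of isolated
#'   nodes recorded in its config.
#' @export
prune_chronnet <- function(net, tau) {
  if (tau < 0) stop("tau must be >= 0")
  cfg <- chronnet_config(net)
  g <- igraph::delete_edges(net, igraph::E(net)[igraph::E(net)$weight <= tau])
  cfg$tau <- tau
  cfg$isolated_nodes <- sum(igraph::degree(g, loops = FALSE) == 0)
  as_chronnet(g, cfg)
}

#' Build a sequence of chronnet snapshots
#'
#' Splits the event stream into consecutive non-overlapping windows of
#' temporal length `delta_t` (anchored at the first timestamp) and builds an
#' independent chronnet per window; no links cross window boundaries. A
#' `delta_t` covering the whole record reproduces the single static chronnet.
#' Windows without events yield empty chronnets, kept in sequence.
#'
#' @inheritParams build_chronnet
#' @param delta_t Window length in timestamp units (> 0).
#' @param ... Passed to [build_chronnet()].
#' @return A list of `chronnet` objects, one per window, with attribute
#'   `"window_starts"` giving each window's start time.
#' @export
build_snapshots <- function(cells, times, coords = NULL, delta_t, ...) {
  if (delta_t <= 0) stop("delta_t must be positive")
  if (!length(times)) return(structure(list(), window_starts = numeric()))
  if (is.unsorted(times)) stop("times must be sorted non-decreasingly")
  t0 <- times[1L]
  span <- times[length(times)] - t0
  nwin <- max(1L, as.integer(ceiling(span / delta_t)))
  win <- pmin(floor((times - t0) / delta_t), nwin - 1L)
  out <- vector("list", nwin)
  for (k in seq_len(nwin)) {
    idx <- which(win == k - 1L)
    out[[k]] <- build_chronnet(cells[idx], times[idx],
                               coords = if (is.null(coords)) NULL
                                        else coords[idx, , drop = FALSE],
                               ...)
  }
  structure(out, window_starts = t0 + (seq_len(nwin) - 1L) * delta_t)
}

#' Write / read a chronnet
#'
#' `write_chronnet()` serializes a chronnet as three sibling files:
#' `<base>_edges.csv` (columns `from,to,weight`; self-loops have
#' `from == to`), `<base>.graphml` (via igraph), and `<base>_config.json`
#' (construction provenance plus the full node list, so isolated nodes
#' survive the round trip). `read_chronnet()` reads them back.
#'
#' @param net A `chronnet`.
#' @param base Path prefix (no extension).
#' @return `write_chronnet()`: `base`, invisibly. `read_chronnet()`: a
#'   `chronnet`.
#' @export
write_chronnet <- function(net, base) {
  e <- igraph::as_data_frame(net, what = "edges")
  utils::write.csv(e, paste0(base, "_edges.csv"), row.names = FALSE,
                   quote = FALSE)
  cfg <- chronnet_config(net)
  g <- igraph::delete_graph_attr(net, "config")  # graphml wants flat attrs
  igraph::write_graph(g, paste0(base, ".graphml"), format = "graphml")
  jsonlite::write_json(
    list(config = cfg, directed = igraph::is_directed(net),
         nodes = igraph::V(net)$name),
    paste0(base, "_config.json"), auto_unbox = TRUE, null = "null",
    digits = NA)
  invisible(base)
}

#' @rdname write_chronnet
#' @export
read_chronnet <- function(base) {
  meta <- jsonlite::read_json(paste0(base, "_config.json"),
                              simplifyVector = TRUE)
  e <- utils::read.csv(paste0(base, "_edges.csv"),
                       colClasses = c("character", "character", "numeric"))
  g <- igraph::graph_from_data_frame(
    e, directed = isTRUE(meta$directed),
    vertices = data.frame(name = as.character(meta$nodes)))
  cfg <- meta$config
  if (!is.null(cfg$d_max) && !length(cfg$d_max)) cfg$d_max <- NULL
  as_chronnet(g, cfg)
}
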