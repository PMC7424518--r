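#' Detect communities in a chronnet
#'
#' Communities — groups of densely interconnected cells — represent regions
#' whose events occur consecutively within the same period. Two weighted
#' methods are offered: agglomerative modularity optimization
#' (`"fast_greedy"`), which yields a full merge dendrogram plus the
#' best-modularity flat cut; and `"label_propagation"`, which yields a flat
#' partition and, being order-dependent, is run `restarts` times from the
#' given seed with the maximum-modularity run reported.
#'
#' @param net An undirected `chronnet` (a directed one is aggregated
#'   first). Self-loops are ignored for community detection.
#' @param method `"fast_greedy"` or `"label_propagation"`.
#' @param seed Integer seed making label propagation reproducible.
#' @param restarts Label-propagation restarts (default 10).
#' @return A `partition`: list with `membership` (named integer vector,
#'   community ids contiguous from 1), `modularity`, `method`, `k` (number
#'   of communities), and (fast greedy only) the igraph `communities`
#'   object as `dendrogram`.
#' @examples
#' net <- build_chronnet(rep(c(1, 2, 1, 3, 7, 8, 7, 9), 5), 1:40)
#' detect_communities(net)$k
#' @export
detect_communities <- function(net,
                               method = c("fast_greedy", "label_propagation"),
                               seed = NULL, restarts = 10L) {
  method <- match.arg(method)
  net <- to_undirected(net)
  if (igraph::vcount(net) == 0L) stop("community detection on an empty graph")
  g <- igraph::simplify(net, remove.loops = TRUE, remove.multiple = FALSE)
  w <- igraph::E(g)$weight
  if (method == "fast_greedy") {
    cm <- igraph::cluster_fast_greedy(g, weights = w)
    # best-modularity cut, ties broken toward the coarsest partition (a
    # uniform complete graph is one community, not an arbitrary split)
    mods <- cm$modularity
    idx <- max(which(mods >= max(mods) - 1e-12))
    k_best <- igraph::vcount(g) - idx + 1L
    m <- igraph::cut_at(cm, no = k_best)
    names(m) <- igraph::V(g)$name
    part <- list(membership = normalize_membership(m),
                 modularity = max(mods),
                 method = method,
                 dendrogram = cm)
  } else {
    if (!is.null(seed)) set.seed(seed)
    best <- NULL; best_q <- -Inf
    for (r in seq_len(max(1L, restarts))) {
      cm <- igraph::cluster_label_prop(g, weights = w)
      q <- igraph::modularity(g, igraph::membership(cm), weights = w)
      if (q > best_q) { best_q <- q; best <- cm }
    }
    part <- list(membership = normalize_membership(igraph::membership(best)),
                 modularity = best_q,
                 method = method)
  }
  part$k <- length(unique(part$membership))
  structure(part, class = "partition")
}

# relabel community ids to 1..k in order of first appearance
normalize_membership <- function(m) {
  ids <- as.integer(factor(as.integer(m), levels = unique(as.integer(m))))
  stats::setNames(ids, names(m))
}

#' @export
print.partition <- function(x, ...) {
  cat(sprintf("partition: %d communities over %d nodes (%s, modularity %.3f)\n",
              x$k, length(x$membership), x$method, x$modularity))
  invisible(x)
}

#' Cut a community dendrogram at k communities
#'
#' The agglomerative merge tree permits clustering the cells — and through
#' them the events — into any chosen number of regions, not only the
#' best-modularity one.
#'
#' @param partition A `partition` from
#'   `detect_communities(method = "fast_greedy")`.
#' @param k Number of communities, `1 <= k <=` number of nodes.
#' @return A flat `partition` with exactly `k` communities (no dendrogram).
#' @export
cut_dendrogram <- function(partition, k) {
  if (is.null(partition$dendrogram)) {
    stop("partition has no dendrogram; use method = 'fast_greedy'")
  }
  n <- length(partition$membership)
  if (k < 1L || k > n) stop("k must be between 1 and the number of nodes")
  m <- igraph::cut_at(partition$dendrogram, no = k)
  names(m) <- names(partition$membership)
  structure(list(membership = normalize_membership(m),
                 modularity = NA_real_,
                 method = paste0(partition$method, "_cut"),
                 k = k),
            class = "partition")
}

#' Cluster events through node communities
#'
#' Every event inherits the community of the cell it occurred in, giving the
#' time-ordered label sequence `C = {c_1, ..., c_T}` that underlies event
#' clustering and change-point detection.
#'
#' @param cells A `cell_series` aligned with the sorted event table.
#' @param partition A `partition` labelling every cell appearing in `cells`.
#' @return An integer vector of class `label_sequence` (community per event,
#'   in time order).
#' @export
cluster_events <- function(cells, partition) {
  m <- partition$membership
  lab <- m[as.character(as.integer(cells))]
  if (anyNA(lab)) {
    missing <- unique(as.integer(cells)[is.na(lab)])
    stop("cells without a community label: ",
         paste(utils::head(missing, 10L), collapse = ", "))
  }
  structure(as.integer(lab), names = NULL, class = "label_sequence")
}

#' @export
print.label_sequence <- function(x, ...) {
  cat(sprintf("label_sequence: %d events, %d distinct labels\n",
              length(x), length(unique(unclass(x)))))
  invisible(x)
}

#' Correct isolated labels in an event label sequence
#'
#' The correction function over a window radius `delta` (odd): an element
#' `c_t` is replaced iff the window
#' `{c_(t-delta), ..., c_(t-1), c_(t+1), ..., c_(t+delta)}` — taken from the
#' *original* sequence, excluding `c_t` itself — contains exactly one unique
#' value, in which case `c_t` becomes that value. All positions are
#' evaluated against the original sequence and corrected simultaneously, so
#' the result does not depend on sweep order. Boundary positions without a
#' full window are left unchanged. The function never invents a label absent
#' from a position's window and never touches positions whose window is
#' mixed — genuine regime changes survive, isolated mislabels do not.
#'
#' @param seq A `label_sequence` (or plain integer vector).
#' @param delta Odd positive window radius (default 1: immediate
#'   neighbours).
#' @return The corrected sequence, same class as the input.
#' @examples
#' smooth_labels(c(1, 1, 1, 2, 1, 1, 1), delta = 3)
#' @export
smooth_labels <- function(seq, delta = 1L) {
  delta <- as.integer(delta)
  if (delta < 1L || delta %% 2L == 0L) stop("delta must be an odd integer >= 1")
  x <- as.integer(seq)
  n <- length(x)
  if (n <= 2L * delta) return(seq)
  out <- x
  interior <- (delta + 1L):(n - delta)
  offs <- c(-(delta:1), 1:delta)
  win <- vapply(offs, function(o) x[interior + o], integer(length(interior)))
  if (is.null(dim(win))) win <- matrix(win, nrow = 1L)
  uniform <- rowSums(win != win[, 1L]) == 0L
  out[interior[uniform]] <- win[uniform, 1L]
  if (inherits(seq, "label_sequence")) class(out) <- "label_sequence"
  out
}

#' Change points of a label sequence
#'
#' A time index `t` (1-based, `t >= 2`) is a change point when
#' `c_t != c_(t-1)`: the events moved to a different community, i.e. the
#' active region changed. Typically applied after [smooth_labels()] so
#' isolated outliers do not masquerade as changes.
#'
#' @param seq A `label_sequence` (or integer vector).
#' @return Integer vector of change-point indices (empty when length < 2).
#' @examples
#' change_points(c(1, 1, 2, 2, 3))
#' @export
change_points <- function(seq) {
  x <- as.integer(seq)
  if (length(x) < 2L) return(integer(0))
  which(x[-1L] != x[-length(x)]) + 1L
}

#' Outlier cells by degree or strength
#'
#' Cells with uncommonly long or intense activity become high-degree /
#' high-strength nodes; the top fraction of either statistic flags them.
#' Ties are broken deterministically by node id.
#'
#' @param net A `chronnet`.
#' @param by `"degree"` or `"strength"`.
#' @param top_fraction Fraction of nodes to flag, in (0, 1).
#' @return Character vector of node names (cell ids), highest statistic
#'   first.
#' @export
outlier_nodes <- function(net, by = c("degree", "strength"),
                          top_fraction = 0.02) {
  by <- match.arg(by)
  if (top_fraction <= 0 || top_fraction >= 1) {
    stop("top_fraction must be in (0, 1)")
  }
  stat <- if (by == "degree") degrees(net) else strengths(net)
  k <- ceiling(top_fraction * length(stat))
  ord <- order(-stat, suppressWarnings(as.numeric(names(stat))), names(stat))
  names(stat)[ord][seq_len(k)]
}

#' Adjusted Rand index between two labelings
#'
#' Chance-corrected agreement between two partitions of the same items: 1
#' for identical partitions (up to relabeling), about 0 for independent
#' ones. Used to score event clusterings against planted or external
#' labels.
#'
#' @param a,b Label vectors of equal length.
#' @return The ARI, in `[-1, 1]`.
#' @export
adjusted_rand_index <- function(a, b) {
  if (length(a) != length(b)) stop("label vectors must have equal length")
  mclust::adjustedRandIndex(a, b)
}
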