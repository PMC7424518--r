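#' Node degrees and strengths of a chronnet
#'
#' The degree `k_i` counts the distinct other cells whose events occurred
#' consecutively with cell `i` (self-loops excluded). The strength
#' `s_i = sum_j w_ij` sums the incident link weights and is a proxy for the
#' number of events at the cell; the sum runs over `j = i` too, so self-loop
#' weights are included by default (once), switchable off.
#'
#' @param net A `chronnet` (undirected; a directed net is aggregated first).
#' @param self_loops Include self-loop weights in strengths (default `TRUE`).
#' @return A named numeric vector over nodes.
#' @examples
#' net <- build_chronnet(c(1, 2, 1, 2, 3), 1:5)
#' degrees(net)
#' strengths(net)
#' @export
degrees <- function(net) {
  net <- to_undirected(net)
  igraph::degree(igraph::simplify(net, remove.loops = TRUE,
                                  remove.multiple = FALSE))
}

#' @rdname degrees
#' @export
strengths <- function(net, self_loops = TRUE) {
  net <- to_undirected(net)
  e <- igraph::as_data_frame(net, what = "edges")
  s <- stats::setNames(numeric(igraph::vcount(net)), igraph::V(net)$name)
  if (nrow(e)) {
    loop <- e$from == e$to
    inc <- rowsum(c(e$weight[!loop], e$weight[!loop]),
                  group = c(e$from[!loop], e$to[!loop]))
    s[rownames(inc)] <- s[rownames(inc)] + as.numeric(inc)
    if (self_loops && any(loop)) {
      lw <- rowsum(e$weight[loop], group = e$from[loop])
      s[rownames(lw)] <- s[rownames(lw)] + as.numeric(lw)
    }
  }
  s
}

#' Degree and strength distributions
#'
#' The degree distribution is the fraction of nodes with each degree `k` —
#' the probability `P(k)` of drawing a node of degree `k` at random. It
#' summarizes how spatially spread the events were: uniform event generation
#' gives a light-tailed, bell-shaped distribution, while strongly skewed
#' generation yields heavy tails with hub cells. The strength distribution
#' is the analogue over link weights.
#'
#' @inheritParams degrees
#' @return A data.frame with columns `value` (degree or strength) and
#'   `fraction` (summing to 1).
#' @export
degree_distribution <- function(net) {
  value_distribution(degrees(net))
}

#' @rdname degree_distribution
#' @export
strength_distribution <- function(net, self_loops = TRUE) {
  value_distribution(strengths(net, self_loops = self_loops))
}

value_distribution <- function(v) {
  if (!length(v)) stop("distribution of an empty node set")
  tab <- table(v)
  data.frame(value = as.numeric(names(tab)),
             fraction = as.numeric(tab) / length(v))
}

#' Fit a discrete power law to positive counts
#'
#' Maximum-likelihood fit of `P(k) ~ k^-gamma` for `k >= k_min`, with the
#' lower cutoff `k_min` selected by minimizing the Kolmogorov-Smirnov
#' distance between the fitted model and the empirical tail (Clauset-style,
#' via igraph's `plfit` implementation). A heavy-tailed fit alone does not
#' establish scale-freeness; use [tail_fit_comparison()] to weigh it against
#' a log-normal alternative.
#'
#' @param values Positive counts (e.g. degrees or strengths); at least ~50
#'   recommended for a stable cutoff.
#' @param k_min Optional fixed lower cutoff; `NULL` (default) selects it by
#'   KS minimization.
#' @return A list with `gamma` (exponent), `k_min`, and `ks` (KS distance of
#'   the fit on the tail).
#' @export
fit_discrete_powerlaw <- function(values, k_min = NULL) {
  values <- values[values > 0]
  if (length(unique(values)) < 2L) {
    stop("degenerate input: need at least two distinct positive values")
  }
  f <- igraph::fit_power_law(round(values), xmin = k_min,
                             implementation = "plfit")
  list(gamma = f$alpha, k_min = f$xmin, ks = f$KS.stat)
}

#' Fit a log-normal to positive values
#'
#' Maximum likelihood on the log scale, optionally restricted to values at
#' or above a lower cutoff (to fit a distribution tail).
#'
#' @param values Positive values.
#' @param k_min Optional lower cutoff; only `values >= k_min` enter the fit.
#' @return A list with `mu` and `sigma` (MLE, i.e. `sigma` uses the `1/n`
#'   denominator) and `n` (values used).
#' @export
fit_lognormal <- function(values, k_min = NULL) {
  values <- values[values > 0]
  if (!is.null(k_min)) values <- values[values >= k_min]
  if (length(unique(values)) < 2L) {
    stop("degenerate input: need at least two distinct positive values")
  }
  lv <- log(values)
  mu <- mean(lv)
  sigma <- sqrt(mean((lv - mu)^2))
  list(mu = mu, sigma = sigma, n = length(values))
}

#' Compare power-law and log-normal fits on a distribution tail
#'
#' Fits both families to `values >= k_min` (cutoff from the power-law fit
#' unless given) and reports each family's KS distance to the empirical tail
#' distribution; the smaller KS indicates the better-matching family. This
#' deliberately stops short of a formal likelihood-ratio test: it ranks the
#' two candidate shapes, nothing more.
#'
#' @inheritParams fit_discrete_powerlaw
#' @return A list with elements `powerlaw` (from [fit_discrete_powerlaw()]),
#'   `lognormal` (from [fit_lognormal()] plus its `ks`), `k_min`, and
#'   `preferred` (`"powerlaw"` or `"lognormal"`).
#' @export
tail_fit_comparison <- function(values, k_min = NULL) {
  pl <- fit_discrete_powerlaw(values, k_min = k_min)
  k_min <- pl$k_min
  tail_vals <- sort(values[values >= k_min])
  # conditional (left-truncated at k_min) log-normal MLE, so both families
  # model the same tail; started from the plain log-moment estimates
  start <- fit_lognormal(tail_vals)
  nll <- function(par) {
    if (par[2] <= 0) return(Inf)
    -sum(stats::dlnorm(tail_vals, par[1], par[2], log = TRUE)) +
      length(tail_vals) *
        log(pmax(1 - stats::plnorm(k_min, par[1], par[2]), 1e-300))
  }
  opt <- stats::optim(c(start$mu, start$sigma), nll, method = "Nelder-Mead")
  ln <- list(mu = opt$par[1], sigma = opt$par[2], n = length(tail_vals))
  # KS of the conditional log-normal against the empirical tail
  ecdf_hi <- seq_along(tail_vals) / length(tail_vals)
  ecdf_lo <- (seq_along(tail_vals) - 1) / length(tail_vals)
  p_lo <- stats::plnorm(k_min, ln$mu, ln$sigma)
  theo <- (stats::plnorm(tail_vals, ln$mu, ln$sigma) - p_lo) /
    max(1 - p_lo, 1e-300)
  ln$ks <- max(abs(theo - ecdf_hi), abs(theo - ecdf_lo))
  if (!is.finite(ln$ks)) ln$ks <- Inf   # degenerate truncated fit
  list(powerlaw = pl, lognormal = ln, k_min = k_min,
       preferred = if (pl$ks <= ln$ks) "powerlaw" else "lognormal")
}

#' Node centrality in a chronnet
#'
#' Degree centrality is the degree itself: relevant cells are those whose
#' events co-occurred with many other cells. Betweenness counts, over all
#' node pairs, the fraction of shortest paths traversing a node — in
#' chronnets it flags cells bridging communities. Closeness is the inverse
#' of the summed shortest-path distances from a node — cells whose events
#' reach every other cell in few consecutive steps. With
#' `use_weights = TRUE`, link weights are mapped to distances as `1/w`
#' before shortest paths, so strong (recurrent) links act as short temporal
#' distances.
#'
#' Closeness on a disconnected graph is computed per connected component;
#' the result carries a `"component"` attribute labelling each node's
#' component.
#'
#' @param net A `chronnet`.
#' @param kind `"degree"`, `"betweenness"` or `"closeness"`.
#' @param use_weights Use `1/weight` distances for path-based centralities
#'   (default `FALSE`: hop counts).
#' @return A named numeric vector of scores.
#' @export
centrality <- function(net, kind = c("degree", "betweenness", "closeness"),
                       use_weights = FALSE) {
  kind <- match.arg(kind)
  net <- to_undirected(net)
  g <- igraph::simplify(net, remove.loops = TRUE, remove.multiple = FALSE)
  wts <- if (use_weights) 1 / igraph::E(g)$weight else NA
  switch(kind,
    degree = igraph::degree(g),
    betweenness = igraph::betweenness(g, weights = wts, directed = FALSE),
    closeness = {
      comp <- igraph::components(g)
      sc <- numeric(igraph::vcount(g))
      names(sc) <- igraph::V(g)$name
      for (cid in seq_len(comp$no)) {
        vs <- which(comp$membership == cid)
        if (length(vs) == 1L) { sc[vs] <- NA_real_; next }
        sub <- igraph::induced_subgraph(g, vs)
        swts <- if (use_weights) 1 / igraph::E(sub)$weight else NA
        d <- igraph::distances(sub, weights = swts)
        sc[vs] <- 1 / rowSums(d)
      }
      attr(sc, "component") <- stats::setNames(comp$membership,
                                               igraph::V(g)$name)
      sc
    })
}

#' Global transitivity of a chronnet
#'
#' The proportion of connected triples closed into triangles
#' (`3 * triangles / connected triples`). A triangle in a chronnet is a
#' recurrent cyclic activation pattern between three cells; events at random
#' positions give transitivity near zero. Self-loops are ignored.
#'
#' @param net A `chronnet`.
#' @return A fraction in `[0, 1]` (`NaN` on a graph with no connected
#'   triple).
#' @export
net_transitivity <- function(net) {
  net <- to_undirected(net)
  g <- igraph::simplify(net, remove.loops = TRUE, remove.multiple = FALSE)
  igraph::transitivity(g, type = "global")
}

#' Shortest-path statistics of a chronnet
#'
#' The shortest path between two cells is the minimum chain of consecutive
#' historical events separating them; its network average and maximum
#' (diameter) summarize how quickly activity cascades can connect any two
#' cells. Computed as unweighted hop counts by default, on the largest
#' connected component (with the coverage of that component reported), since
#' pruning may disconnect a chronnet.
#'
#' @param net A `chronnet`.
#' @param use_weights Use `1/weight` distances instead of hop counts.
#' @return A list: `mean_path` (average shortest path), `diameter`,
#'   `component_sizes` (decreasing), `coverage` (fraction of nodes in the
#'   largest component).
#' @export
path_stats <- function(net, use_weights = FALSE) {
  net <- to_undirected(net)
  g <- igraph::simplify(net, remove.loops = TRUE, remove.multiple = FALSE)
  if (igraph::vcount(g) == 0L) stop("path statistics of an empty graph")
  comp <- igraph::components(g)
  sizes <- sort(comp$csize, decreasing = TRUE)
  big <- which(comp$membership == which.max(comp$csize))
  sub <- igraph::induced_subgraph(g, big)
  wts <- if (use_weights) 1 / igraph::E(sub)$weight else NA
  if (igraph::vcount(sub) < 2L) {
    return(list(mean_path = NA_real_, diameter = NA_real_,
                component_sizes = sizes,
                coverage = sizes[1] / igraph::vcount(g)))
  }
  d <- igraph::distances(sub, weights = wts)
  ut <- d[upper.tri(d)]
  list(mean_path = mean(ut), diameter = max(ut),
       component_sizes = sizes,
       coverage = sizes[1] / igraph::vcount(g))
}

#' Edge density of a chronnet
#'
#' Fraction of realizable node pairs that carry a link:
#' `|E| / (n (n - 1) / 2)` on the undirected graph, self-loops excluded.
#' Pruning can only decrease it.
#'
#' @param net A `chronnet` with at least 2 nodes.
#' @return A fraction in `[0, 1]`.
#' @export
net_density <- function(net) {
  net <- to_undirected(net)
  g <- igraph::simplify(net, remove.loops = TRUE, remove.multiple = FALSE)
  n <- igraph::vcount(g)
  if (n < 2L) stop("edge density needs at least 2 nodes")
  igraph::ecount(g) / (n * (n - 1) / 2)
}

#' Summarize a chronnet
#'
#' One-stop characterization: node counts, density, mean degree, degree and
#' strength vectors and distributions, transitivity, path statistics and the
#' tail-fit comparison for the degree distribution (when it has enough
#' distinct values to fit).
#'
#' @param net A `chronnet`.
#' @param fit_tails Attempt power-law/log-normal tail fits of degrees and
#'   strengths (default `TRUE`; skipped silently when degenerate).
#' @return A list of class `chronnet_summary`.
#' @export
chronnet_summary <- function(net, fit_tails = TRUE) {
  net <- to_undirected(net)
  k <- degrees(net); s <- strengths(net)
  out <- list(
    n_nodes = igraph::vcount(net),
    n_links = igraph::ecount(net),
    density = if (igraph::vcount(net) >= 2L) net_density(net) else NA_real_,
    mean_degree = mean(k),
    degrees = k, strengths = s,
    degree_distribution = degree_distribution(net),
    strength_distribution = strength_distribution(net),
    transitivity = net_transitivity(net),
    paths = path_stats(net))
  if (fit_tails) {
    out$degree_fit <- try_tail_fit(k)
    out$strength_fit <- try_tail_fit(s)
  }
  structure(out, class = "chronnet_summary")
}

try_tail_fit <- function(v) {
  tryCatch(tail_fit_comparison(v), error = function(e) NULL)
}

#' @export
print.chronnet_summary <- function(x, ...) {
  cat(sprintf("chronnet summary: %d nodes, %d links, density %.4f\n",
              x$n_nodes, x$n_links, x$density))
  cat(sprintf("  mean degree %.2f, transitivity %.3f\n",
              x$mean_degree, x$transitivity))
  cat(sprintf("  largest component: %.0f%% of nodes, <l> = %.2f, diameter %g\n",
              100 * x$paths$coverage, x$paths$mean_path, x$paths$diameter))
  if (!is.null(x$degree_fit)) {
    cat(sprintf("  degree tail: gamma = %.2f (k_min = %g), preferred fit: %s\n",
                x$degree_fit$powerlaw$gamma, x$degree_fit$k_min,
                x$degree_fit$preferred))
  }
  invisible(x)
}
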