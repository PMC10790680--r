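# Gene-gene interaction network: median-score edge filter, topological
# importance (degree, betweenness, harmonic closeness, rank sum), and
# selection of the top candidate pair.

#' Filter a weighted edge list at the median combined score
#'
#' Canonicalizes the edge list to an undirected simple graph (self-loops
#' dropped; duplicate node pairs collapsed keeping the highest score) and
#' retains only edges whose score is strictly greater than the median of
#' all scores. Nodes isolated by the filter are dropped; if every score
#' equals the median the result is an empty graph.
#'
#' @param edges data.frame with columns `node1`, `node2`, `combined_score`.
#' @return an [igraph::graph] with edge attribute `score`.
#' @export
filter_edges_by_median <- function(edges) {
  stopifnot(is.data.frame(edges),
            all(c("node1", "node2", "combined_score") %in% names(edges)))
  if (nrow(edges) == 0L) stop("empty edge list", call. = FALSE)
  a <- as.character(edges$node1); b <- as.character(edges$node2)
  s <- as.numeric(edges$combined_score)
  keep <- a != b
  a <- a[keep]; b <- b[keep]; s <- s[keep]
  if (!length(a)) stop("edge list contains only self-loops", call. = FALSE)
  lo <- pmin(a, b); hi <- pmax(a, b)
  key <- paste(lo, hi, sep = "\r")
  s <- tapply(s, key, max)
  lo <- sub("\r.*$", "", names(s)); hi <- sub("^.*\r", "", names(s))
  med <- stats::median(s)
  sel <- s > med
  g <- igraph::graph_from_data_frame(
    data.frame(from = lo[sel], to = hi[sel], score = as.numeric(s[sel]),
               stringsAsFactors = FALSE),
    directed = FALSE)
  g
}

#' Topological importance of every network node
#'
#' Unweighted degree, shortest-path betweenness normalized by
#' (n-1)(n-2)/2, and harmonic closeness (mean of 1/d over all other
#' nodes, with 1/Inf = 0, i.e. disconnected-safe), plus `rank_sum`: the
#' sum of the three descending-order ranks (average ranks on ties) —
#' smaller means more important.
#'
#' @param network an [igraph::graph], e.g. from [filter_edges_by_median()].
#' @return data.frame: `gene_id`, `degree`, `betweenness`, `closeness`,
#'   `rank_sum`.
#' @export
compute_topology <- function(network) {
  stopifnot(inherits(network, "igraph"))
  n <- igraph::vcount(network)
  if (n == 0L) stop("empty network", call. = FALSE)
  deg <- igraph::degree(network)
  btw <- if (n > 2L) igraph::betweenness(network, normalized = TRUE)
         else stats::setNames(rep(0, n), names(deg))
  clo <- igraph::harmonic_centrality(network, normalized = TRUE)
  rk <- function(x) rank(-x, ties.method = "average")
  data.frame(gene_id = igraph::V(network)$name,
             degree = unname(deg),
             betweenness = unname(btw),
             closeness = unname(clo),
             rank_sum = unname(rk(deg) + rk(btw) + rk(clo)),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Rank candidate pairs and flag the top pair
#'
#' Candidates are sorted by `mean_abs_r` descending; ties are broken by
#' the smaller combined `rank_sum` of the two members in the network
#' topology (pairs with a member absent from the network rank last within
#' a tie), then lexicographically by pair id.
#'
#' @param candidates data.frame with `lnc_id`, `mrna_id`, `mean_abs_r`
#'   (e.g. from [intersect_targets()]).
#' @param topology data.frame from [compute_topology()].
#' @return `candidates` with added `combined_rank_sum`, `rank` and `top`
#'   (logical; TRUE on the first row only), sorted by rank.
#' @export
select_top_pair <- function(candidates, topology) {
  if (is.null(candidates) || nrow(candidates) == 0L)
    stop("no candidate pairs to rank", call. = FALSE)
  rs <- stats::setNames(topology$rank_sum, topology$gene_id)
  look <- function(id) ifelse(id %in% names(rs), rs[id], Inf)
  combined <- unname(look(candidates$lnc_id) + look(candidates$mrna_id))
  pair_id <- paste(candidates$lnc_id, candidates$mrna_id, sep = "|")
  ord <- order(-candidates$mean_abs_r, combined, pair_id)
  out <- candidates[ord, , drop = FALSE]
  out$combined_rank_sum <- combined[ord]
  out$rank <- seq_len(nrow(out))
  out$top <- out$rank == 1L
  rownames(out) <- NULL
  out
}
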