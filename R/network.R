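#' Score-descending covering prefix of the DCV logratio network
#'
#' Sorts all logratios by descending DCV score (ratio name as the stable
#' tie-break) and retains the shortest prefix whose edges touch every taxon;
#' if that prefix is not a single connected component, further logratios are
#' appended in score order until it is.  The result is the weighted logratio
#' network handed to [maximum_spanning_tree()].
#'
#' @param scores a [dcv_scores()] object covering all `d(d-1)/2` ratios.
#' @return an object of class `logratio_network`: list with `edges`
#'   (data.frame `num`, `den`, `weight`, `ratio`, directed numerator ->
#'   denominator), `taxa`, and `q = nrow(edges)`.
#' @export
covering_prefix_network <- function(scores) {
  stopifnot(inherits(scores, "dcv_scores"))
  ratios <- scores$ratios
  taxa <- sort(unique(c(ratios$num, ratios$den)))
  d <- length(taxa)
  p <- nrow(ratios)
  if (p != d * (d - 1) / 2)
    stop("scores must cover all ", d * (d - 1) / 2, " pairwise logratios of ",
         d, " taxa (got ", p, ")")
  ord <- order(-scores$scores, names(scores$scores))

  num_i <- match(ratios$num, taxa)
  den_i <- match(ratios$den, taxa)
  parent <- uf_new(d)
  n_comp <- d
  seen <- logical(d)
  n_seen <- 0L
  q <- 0L
  for (e in ord) {
    q <- q + 1L
    for (v in c(num_i[e], den_i[e])) {
      if (!seen[v]) { seen[v] <- TRUE; n_seen <- n_seen + 1L }
    }
    ra <- uf_find(parent, num_i[e]); rb <- uf_find(parent, den_i[e])
    if (ra != rb) { parent[ra] <- rb; n_comp <- n_comp - 1L }
    if (n_seen == d && n_comp == 1L) break
  }
  keep <- ord[seq_len(q)]
  edges <- data.frame(num = ratios$num[keep], den = ratios$den[keep],
                      weight = unname(scores$scores[keep]),
                      ratio = names(scores$scores)[keep],
                      stringsAsFactors = FALSE)
  new_logratio_network(edges, taxa)
}

new_logratio_network <- function(edges, taxa) {
  if (any(edges$num == edges$den)) stop("self-loop logratio")
  key <- paste(pmin(edges$num, edges$den), pmax(edges$num, edges$den))
  if (anyDuplicated(key)) stop("duplicate taxon pair in edge set")
  if (any(!is.finite(edges$weight))) stop("edge weights must be finite")
  structure(list(edges = edges, taxa = taxa, q = nrow(edges)),
            class = "logratio_network")
}

#' Maximum spanning tree of a logratio network
#'
#' Extracts the spanning tree of maximal total DCV weight from a connected
#' logratio network via Kruskal's algorithm with a union-find, processing
#' edges in descending weight order with the lexicographically smaller ratio
#' name breaking ties, so repeated runs return an identical tree.  The tree's
#' `d - 1` logratios form a linearly independent, full-rank basis of the
#' logratio space.
#'
#' @param G a [covering_prefix_network()] result (or any `logratio_network`).
#' @return an object of class `spanning_tree`: list with `edges` (num, den,
#'   weight, ratio), `taxa`, and `total_weight`.
#' @export
maximum_spanning_tree <- function(G) {
  stopifnot(inherits(G, "logratio_network"))
  edges <- G$edges[order(-G$edges$weight, G$edges$ratio), , drop = FALSE]
  d <- length(G$taxa)
  parent <- uf_new(d)
  num_i <- match(edges$num, G$taxa)
  den_i <- match(edges$den, G$taxa)
  pick <- logical(nrow(edges))
  n_pick <- 0L
  for (e in seq_len(nrow(edges))) {
    ra <- uf_find(parent, num_i[e]); rb <- uf_find(parent, den_i[e])
    if (ra != rb) {
      parent[ra] <- rb
      pick[e] <- TRUE
      n_pick <- n_pick + 1L
      if (n_pick == d - 1L) break
    }
  }
  if (n_pick != d - 1L)
    stop("network is disconnected: spanning tree would need ", d - 1L,
         " edges, found ", n_pick)
  edges <- edges[pick, , drop = FALSE]
  rownames(edges) <- NULL
  structure(list(edges = edges, taxa = G$taxa,
                 total_weight = sum(edges$weight)),
            class = "spanning_tree")
}

#' Global clustering coefficient of a logratio network
#'
#' `3 * triangles / connected triples` on the undirected projection; a
#' logratio subset whose network contains a closed triangle (clustering
#' coefficient > 0) is linearly dependent, whereas trees and forests score
#' exactly 0.  Returns 0 when the graph has no connected triples.
#'
#' @param x a `logratio_network`, `spanning_tree`, selection result, or an
#'   edge data.frame with `num`/`den` columns.
#' @return a number in `[0, 1]`.
#' @export
global_clustering_coefficient <- function(x) {
  edges <- edge_table(x)
  if (nrow(edges) == 0L) return(0)
  taxa <- sort(unique(c(edges$num, edges$den)))
  d <- length(taxa)
  A <- matrix(0L, d, d, dimnames = list(taxa, taxa))
  A[cbind(match(edges$num, taxa), match(edges$den, taxa))] <- 1L
  A <- pmax(A, t(A))
  deg <- rowSums(A)
  triples <- sum(deg * (deg - 1)) / 2
  if (triples == 0) return(0)
  triangles <- sum(diag(A %*% A %*% A)) / 6
  3 * triangles / triples
}

edge_table <- function(x) {
  if (is.data.frame(x)) x else
    if (inherits(x, c("logratio_network", "spanning_tree"))) x$edges else
      if (!is.null(x$signature) && is.data.frame(x$signature)) x$signature else
        stop("cannot extract an edge table from ", paste(class(x), collapse = "/"))
}

#' Convert a logratio network to an igraph object
#'
#' Directed edges point from the numerator to the denominator taxon; edge
#' weights are DCV scores.
#'
#' @param x a `logratio_network` or `spanning_tree`.
#' @return an `igraph` graph.
#' @export
as_igraph <- function(x) {
  edges <- edge_table(x)
  taxa <- if (!is.null(x$taxa)) x$taxa else sort(unique(c(edges$num, edges$den)))
  igraph::graph_from_data_frame(
    edges[, c("num", "den", "weight")], directed = TRUE,
    vertices = data.frame(name = taxa))
}

#' Write a logratio network to disk
#'
#' `write_edge_list()` emits a TSV with numerator, denominator, and weight;
#' `write_graphml()` emits GraphML for external visualization tools.
#'
#' @param x a `logratio_network` or `spanning_tree`.
#' @param path output file path.
#' @return the input, invisibly.
#' @export
write_edge_list <- function(x, path) {
  edges <- edge_table(x)
  write.table(edges[, c("num", "den", "weight")], path,
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(x)
}

#' @rdname write_edge_list
#' @export
write_graphml <- function(x, path) {
  igraph::write_graph(as_igraph(x), path, format = "graphml")
  invisible(x)
}

#' @export
print.logratio_network <- function(x, ...) {
  cat("logratio_network:", length(x$taxa), "taxa,", x$q, "logratio edges\n")
  invisible(x)
}

#' @export
print.spanning_tree <- function(x, ...) {
  cat("spanning_tree:", length(x$taxa), "taxa,", nrow(x$edges),
      "edges, total weight", round(x$total_weight, 4), "\n")
  invisible(x)
}
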