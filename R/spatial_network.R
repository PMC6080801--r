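#' Spatially embedded ductal network
#'
#' A `spatial_network` is the common substrate of every analysis in this
#' package: a set of labeled nodes with 3D coordinates, undirected edges
#' with positive lengths, and one designated root (exit) node where the
#' ductal system drains. Planar samples simply carry `z = 0`.
#'
#' Node IDs are arbitrary positive integers (as produced by digitization);
#' internally nodes are stored in a dense order and edges refer to that
#' order. The ID-to-index mapping is kept in `node_id` so files round-trip.
#'
#' @param nodes data.frame with columns `id`, `x`, `y`, `z` (one row per
#'   node; `z` may be omitted and defaults to 0).
#' @param edges data.frame with columns `source`, `target` and optionally
#'   `length`. Edges are undirected and deduplicated order-insensitively.
#'   Missing lengths are filled with the Euclidean distance between the
#'   endpoint coordinates.
#' @param root_id integer ID of the exit node. Defaults to the smallest
#'   node ID.
#' @param name optional sample label.
#'
#' @return An object of class `spatial_network`: a list with elements
#'   `node_id` (integer vector), `pos` (n x 3 matrix), `edges` (m x 2
#'   matrix of node *indices*, each row sorted), `length` (numeric vector
#'   of edge lengths), `root` (node index of the exit), `name`.
#' @export
spatial_network <- function(nodes, edges, root_id = NULL, name = "") {
  stopifnot(is.data.frame(nodes), is.data.frame(edges))
  if (!all(c("id", "x", "y") %in% names(nodes)))
    stop("nodes table must have columns id, x, y (and optionally z)")
  if (is.null(nodes$z)) nodes$z <- 0
  if (!all(c("source", "target") %in% names(edges)))
    stop("edges table must have columns source, target (and optionally length)")

  id <- as.integer(nodes$id)
  if (anyDuplicated(id))
    stop("duplicate node ID: ", paste(unique(id[duplicated(id)]), collapse = ", "))
  pos <- cbind(x = as.numeric(nodes$x), y = as.numeric(nodes$y),
               z = as.numeric(nodes$z))

  if (is.null(root_id)) root_id <- min(id)
  root <- match(as.integer(root_id), id)
  if (is.na(root)) stop("root node ", root_id, " not present in node table")

  m <- nrow(edges)
  ei <- match(as.integer(edges$source), id)
  ej <- match(as.integer(edges$target), id)
  bad <- which(is.na(ei) | is.na(ej))
  if (length(bad)) {
    b <- bad[1L]
    miss <- c(edges$source[b], edges$target[b])
    miss <- miss[is.na(match(as.integer(miss), id))]
    stop("edge (", edges$source[b], ",", edges$target[b],
         ") references unknown node ", paste(miss, collapse = ","))
  }
  if (any(ei == ej))
    stop("self-edge on node ", id[ei[which(ei == ej)[1L]]], " is not allowed")

  em <- cbind(pmin(ei, ej), pmax(ei, ej))
  len <- if (!is.null(edges$length)) as.numeric(edges$length) else rep(NA_real_, m)
  # fill missing lengths from coordinates; stored lengths win (ducts curve)
  need <- is.na(len)
  if (any(need)) {
    d <- sqrt(rowSums((pos[em[need, 1L], , drop = FALSE] -
                       pos[em[need, 2L], , drop = FALSE])^2))
    len[need] <- d
  }
  if (any(len <= 0))
    stop("edge lengths must be positive; offending edge row ",
         which(len <= 0)[1L])

  key <- paste(em[, 1L], em[, 2L])
  keep <- !duplicated(key)
  em <- em[keep, , drop = FALSE]
  len <- len[keep]

  structure(list(node_id = id, pos = pos, edges = em, length = len,
                 root = root, name = name),
            class = "spatial_network")
}

#' @export
print.spatial_network <- function(x, ...) {
  cat("<spatial_network", if (nzchar(x$name)) paste0(" '", x$name, "'"), ">\n",
      sep = "")
  cat("  nodes: ", n_nodes(x), "  edges: ", n_edges(x),
      "  root id: ", x$node_id[x$root], "\n", sep = "")
  cat("  total length: ", format(total_length(x)), "\n", sep = "")
  invisible(x)
}

#' Number of nodes / edges
#' @param net a `spatial_network`
#' @return integer count
#' @export
n_nodes <- function(net) length(net$node_id)

#' @rdname n_nodes
#' @export
n_edges <- function(net) nrow(net$edges)

#' Total duct length of a network
#'
#' Sum of all edge lengths (L_tot): half the sum of the weighted adjacency
#' matrix.
#' @param net a `spatial_network`
#' @return numeric scalar
#' @export
total_length <- function(net) sum(net$length)

#' Convert to an igraph object
#'
#' Vertices are named by node ID, edge `weight` carries the duct length,
#' vertex attributes x/y/z carry coordinates. Used internally for shortest
#' paths, connectivity, and bridge detection.
#' @param net a `spatial_network`
#' @return an igraph graph
#' @export
as_igraph <- function(net) {
  g <- igraph::make_empty_graph(n = n_nodes(net), directed = FALSE)
  g <- igraph::set_vertex_attr(g, "name", value = as.character(net$node_id))
  g <- igraph::set_vertex_attr(g, "x", value = net$pos[, 1L])
  g <- igraph::set_vertex_attr(g, "y", value = net$pos[, 2L])
  g <- igraph::set_vertex_attr(g, "z", value = net$pos[, 3L])
  if (n_edges(net) > 0) {
    g <- igraph::add_edges(g, t(net$edges), attr = list(weight = net$length))
  }
  g
}

#' Is the network connected?
#' @param net a `spatial_network`
#' @return logical
#' @export
is_connected_net <- function(net) {
  n_nodes(net) <= 1L || igraph::is_connected(as_igraph(net))
}

#' Node degrees
#' @param net a `spatial_network`
#' @return integer vector of degrees in node storage order
#' @export
node_degrees <- function(net) {
  tabulate(c(net$edges[, 1L], net$edges[, 2L]), nbins = n_nodes(net))
}

#' Read a digitized network from a nodes/edges table pair
#'
#' The expected layout mirrors digitized duct skeleton exports: one table
#' of node IDs and positions, one of node connectivity (and, optionally,
#' measured duct lengths, which win over straight-line recomputation
#' because digitized ducts are curved).
#'
#' @param nodes_table path to a CSV with columns `id,x,y,z`
#' @param edges_table path to a CSV with columns `source,target[,length]`
#' @param root_id integer ID of the exit node (default: smallest ID)
#' @param name sample label (default: file stem of `nodes_table`)
#' @return a validated [spatial_network()]
#' @export
read_network <- function(nodes_table, edges_table, root_id = NULL, name = NULL) {
  nodes <- utils::read.csv(nodes_table)
  edges <- utils::read.csv(edges_table)
  if (is.null(name))
    name <- sub("_nodes$", "", sub("\\.[^.]*$", "", basename(nodes_table)))
  spatial_network(nodes, edges, root_id = root_id, name = name)
}

#' Write a network as a nodes/edges CSV pair
#'
#' Inverse of [read_network()]: `read_network(write_network(net, ...))`
#' reproduces the network exactly (up to node ordering).
#'
#' @param net a `spatial_network`
#' @param nodes_table,edges_table output CSV paths
#' @return invisibly, the two paths
#' @export
write_network <- function(net, nodes_table, edges_table) {
  nd <- data.frame(id = net$node_id, x = net$pos[, 1L], y = net$pos[, 2L],
                   z = net$pos[, 3L])
  ed <- data.frame(source = net$node_id[net$edges[, 1L]],
                   target = net$node_id[net$edges[, 2L]],
                   length = net$length)
  utils::write.csv(nd, nodes_table, row.names = FALSE)
  utils::write.csv(ed, edges_table, row.names = FALSE)
  invisible(c(nodes_table, edges_table))
}

#' Binary and weighted adjacency matrices
#'
#' Returns the N x N binary adjacency matrix A (`A[i,j] = 1` iff i and j
#' are linked; zero diagonal, symmetric) and the weighted adjacency
#' `Aw[i,j] = A[i,j] * d(i,j)` with d the stored duct length. Rows and
#' columns are in node storage order and named by node ID.
#'
#' @param net a `spatial_network`
#' @return list with dense matrices `A` and `Aw`
#' @export
to_adjacency <- function(net) {
  n <- n_nodes(net)
  A <- matrix(0, n, n, dimnames = list(net$node_id, net$node_id))
  Aw <- A
  if (n_edges(net) > 0) {
    i <- net$edges[, 1L]; j <- net$edges[, 2L]
    A[cbind(i, j)] <- 1; A[cbind(j, i)] <- 1
    Aw[cbind(i, j)] <- net$length; Aw[cbind(j, i)] <- net$length
  }
  list(A = A, Aw = Aw)
}

#' Contract chains of degree-2 nodes
#'
#' Digitized skeletons place nodes only at terminal ends and duct
#' intersections; a degree-2 node merely marks the continuation of a duct.
#' This replaces each maximal chain of non-root degree-2 nodes by a single
#' edge whose length is the sum of the chain's edge lengths, so total
#' length and the cycle-space dimension E - N + 1 are preserved exactly.
#' The root is never contracted.
#'
#' @param net a connected `spatial_network`
#' @return a `spatial_network` in which no non-root node has degree 2
#' @export
contract_degree2 <- function(net) {
  repeat {
    deg <- node_degrees(net)
    cand <- which(deg == 2L & seq_len(n_nodes(net)) != net$root)
    if (!length(cand)) return(net)
    v <- cand[1L]
    inc <- which(net$edges[, 1L] == v | net$edges[, 2L] == v)
    e1 <- net$edges[inc[1L], ]; e2 <- net$edges[inc[2L], ]
    a <- if (e1[1L] == v) e1[2L] else e1[1L]
    b <- if (e2[1L] == v) e2[2L] else e2[1L]
    if (a == b && a == v)
      stop("cannot contract: cycle composed entirely of degree-2 nodes ",
           "through node ", net$node_id[v])
    newlen <- sum(net$length[inc])
    if (a == b) {
      # contracting would create a self-loop a-a: the chain closes a cycle
      stop("cannot contract node ", net$node_id[v],
           ": contraction would create a self-loop at node ", net$node_id[a])
    }
    keep <- setdiff(seq_len(n_edges(net)), inc)
    edges <- net$edges[keep, , drop = FALSE]
    len <- net$length[keep]
    # merge with an existing a-b edge would create a multi-edge; since the
    # representation is simple, such a merge collapses a 2-path + edge
    # triangle -- refuse, it would drop length
    dup <- which(edges[, 1L] == min(a, b) & edges[, 2L] == max(a, b))
    if (length(dup))
      stop("cannot contract node ", net$node_id[v],
           ": a parallel duct between nodes ", net$node_id[a], " and ",
           net$node_id[b], " already exists")
    edges <- rbind(edges, c(min(a, b), max(a, b)))
    len <- c(len, newlen)
    # drop node v, reindex
    keepv <- setdiff(seq_len(n_nodes(net)), v)
    remap <- integer(n_nodes(net)); remap[keepv] <- seq_along(keepv)
    net <- structure(list(node_id = net$node_id[keepv],
                          pos = net$pos[keepv, , drop = FALSE],
                          edges = matrix(remap[edges], ncol = 2L),
                          length = len,
                          root = remap[net$root],
                          name = net$name),
                     class = "spatial_network")
  }
}

# internal: build a spatial_network from index-based parts without
# revalidating via data.frames (used by generators and pruning)
new_spatial_network <- function(node_id, pos, edges, length, root, name = "") {
  if (nrow(edges)) {
    edges <- cbind(pmin(edges[, 1L], edges[, 2L]),
                   pmax(edges[, 1L], edges[, 2L]))
  }
  structure(list(node_id = as.integer(node_id), pos = pos,
                 edges = edges, length = as.numeric(length),
                 root = as.integer(root), name = name),
            class = "spatial_network")
}

# internal: copy of net with a subset of edges kept
subset_edges <- function(net, keep) {
  new_spatial_network(net$node_id, net$pos,
                      net$edges[keep, , drop = FALSE], net$length[keep],
                      net$root, net$name)
}
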