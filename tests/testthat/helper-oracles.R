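# Independent oracles used to validate the package's computations.
# These deliberately use brute force / third-party routes, never the
# package's own code paths.

# count simple cycles of length k by exhaustive enumeration:
# for every k-subset of vertices, count Hamiltonian cycles of the subset
# (each found twice, once per direction)
brute_cycle_count <- function(A, k) {
  n <- nrow(A)
  if (n < k) return(0L)
  total <- 0L
  for (sub in utils::combn(n, k, simplify = FALSE)) {
    first <- sub[1L]
    rest <- sub[-1L]
    perms <- all_perms(rest)
    for (p in perms) {
      cyc <- c(first, p)
      ok <- TRUE
      for (i in seq_len(k)) {
        a <- cyc[i]; b <- cyc[if (i == k) 1L else i + 1L]
        if (A[a, b] == 0) { ok <- FALSE; break }
      }
      if (ok) total <- total + 1L
    }
  }
  total %/% 2L
}

all_perms <- function(v) {
  if (length(v) <= 1L) return(list(v))
  out <- list()
  for (i in seq_along(v))
    for (p in all_perms(v[-i])) out[[length(out) + 1L]] <- c(v[i], p)
  out
}

# random connected simple graph as a spatial_network (positions random 3D)
random_connected_net <- function(n, p = 0.35, seed = 1L) {
  set.seed(seed)
  repeat {
    g <- igraph::sample_gnp(n, p)
    if (igraph::is_connected(g)) break
  }
  el <- igraph::as_edgelist(g, names = FALSE)
  pos <- matrix(stats::runif(3 * n, 0, 10), ncol = 3)
  spatial_network(
    data.frame(id = 1:n, x = pos[, 1], y = pos[, 2], z = pos[, 3]),
    data.frame(source = el[, 1], target = el[, 2]),
    root_id = 1L)
}

# 20x20 unit grid graph (4-neighbor), rooted at a corner
grid_net <- function(side = 20L) {
  idx <- function(r, c) (r - 1L) * side + c
  pos <- expand.grid(c = seq_len(side), r = seq_len(side))
  edges <- list()
  for (r in seq_len(side)) for (c in seq_len(side)) {
    if (c < side) edges[[length(edges) + 1L]] <- c(idx(r, c), idx(r, c + 1L))
    if (r < side) edges[[length(edges) + 1L]] <- c(idx(r, c), idx(r + 1L, c))
  }
  em <- do.call(rbind, edges)
  spatial_network(
    data.frame(id = seq_len(side^2), x = pos$c, y = pos$r, z = 0),
    data.frame(source = em[, 1], target = em[, 2]),
    root_id = 1L)
}

# unit chain of n nodes rooted at one end
chain_net <- function(n) {
  spatial_network(data.frame(id = 1:n, x = 0:(n - 1), y = 0, z = 0),
                  data.frame(source = 1:(n - 1), target = 2:n),
                  root_id = 1L)
}

# a 4-cycle with a pendant terminal hanging off node 3, rooted at node 1:
# fluid enters at node 5, drains at 1; the two cycle paths 1-2-3 and
# 1-4-3 carry equal flux, so the first pruned edge is on the cycle
square_with_terminal <- function() {
  spatial_network(
    data.frame(id = 1:5, x = c(0, 1, 1, 0, 2), y = c(0, 0, 1, 1, 1), z = 0),
    data.frame(source = c(1, 2, 3, 4, 3), target = c(2, 3, 4, 1, 5)),
    root_id = 1L)
}

# split every edge at its midpoint (all new nodes have degree 2)
subdivide_once <- function(net) {
  pos <- net$pos
  ids <- net$node_id
  src <- integer(0); tgt <- integer(0); len <- numeric(0)
  next_id <- max(ids) + 1L
  for (e in seq_len(n_edges(net))) {
    a <- net$edges[e, 1L]; b <- net$edges[e, 2L]
    mid <- (pos[a, ] + pos[b, ]) / 2
    pos <- rbind(pos, mid)
    ids <- c(ids, next_id)
    src <- c(src, net$node_id[a], next_id)
    tgt <- c(tgt, next_id, net$node_id[b])
    len <- c(len, net$length[e] / 2, net$length[e] / 2)
    next_id <- next_id + 1L
  }
  spatial_network(
    data.frame(id = ids, x = pos[, 1], y = pos[, 2], z = pos[, 3]),
    data.frame(source = src, target = tgt, length = len),
    root_id = net$node_id[net$root])
}
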