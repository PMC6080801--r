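#' Degree distribution of a network
#'
#' Tally of node degrees. A node of degree 1 is a terminal end (an acinar
#' tip in a ductal tree); degree-2 nodes are normally absent from
#' digitized skeletons (see [contract_degree2()]).
#'
#' @param net a `spatial_network`
#' @return named integer vector: names are degrees, values are node counts;
#'   counts sum to the number of nodes.
#' @export
degree_distribution <- function(net) {
  deg <- node_degrees(net)
  tab <- table(deg)
  out <- as.integer(tab)
  names(out) <- names(tab)
  out
}

#' Count triangles, squares, and pentagons by adjacency traces
#'
#' Counts simple cycles of length 3, 4, and 5 ("polygonal features") from
#' powers of the binary adjacency matrix A, correcting the closed-walk
#' traces for degenerate walks:
#' \deqn{n(C_3) = tr(A^3)/6}
#' \deqn{n(C_4) = [tr(A^4) - 4\sum_i \binom{d_i}{2} - 2E]/8}
#' \deqn{n(C_5) = [tr(A^5) - 5\sum_i A^3_{ii}(d_i - 2) - 30\,n(C_3)]/10}
#' where \eqn{d_i} is the degree of node i. The second term of the square
#' count is the binomial coefficient choose(d, 2) (the only reading that
#' yields exactly 1 square on a 4-cycle).
#'
#' @param net a `spatial_network` (simple, undirected)
#' @return integer vector `c(triangles=, squares=, pentagons=)`
#' @export
count_polygons <- function(net) {
  A <- to_adjacency(net)$A
  deg <- rowSums(A)
  E <- n_edges(net)
  A2 <- A %*% A
  A3 <- A2 %*% A
  tr3 <- sum(diag(A3))
  tr4 <- sum(A2 * A2)          # tr(A^4) = sum of squared entries of A^2
  tr5 <- sum(diag(A3 %*% A2))
  n3 <- tr3 / 6
  n4 <- (tr4 - 4 * sum(choose(deg, 2)) - 2 * E) / 8
  n5 <- (tr5 - 5 * sum(diag(A3) * (deg - 2)) - 30 * n3) / 10
  out <- round(c(triangles = n3, squares = n4, pentagons = n5))
  storage.mode(out) <- "integer"
  out
}

#' Average clustering coefficient
#'
#' Mean over all nodes of the local clustering coefficient
#' (triangles through the node divided by choose(degree, 2)); nodes of
#' degree < 2 contribute 0.
#'
#' @param net a `spatial_network`
#' @return numeric in \[0, 1\]
#' @export
mean_clustering <- function(net) {
  if (n_edges(net) == 0) return(0)
  g <- as_igraph(net)
  igraph::transitivity(g, type = "localaverage", isolates = "zero")
}

#' Euclidean minimum spanning tree of the node cloud
#'
#' The MST of the complete graph on the node positions with Euclidean
#' edge weights: the cheapest possible network spanning the same nodes.
#' It is the reference for both [network_cost()] and
#' [network_performance()]. For clouds above `complete_max` nodes the MST
#' is built on the k-nearest-neighbor graph (k = 15) with a connectivity
#' fallback that joins components by their closest node pair.
#'
#' @param net a `spatial_network` (only positions and IDs are used)
#' @param complete_max largest N for which the complete graph is used
#' @return a `spatial_network` that is a tree (E = N - 1) on the same
#'   nodes, same root; edge lengths are Euclidean distances.
#' @export
euclidean_mst <- function(net, complete_max = 2000L) {
  n <- n_nodes(net)
  if (n <= 1L) return(subset_edges(net, integer(0)))
  if (n <= complete_max) {
    D <- as.matrix(stats::dist(net$pos))
    # lexicographic edge order gives deterministic tie-breaking
    idx <- which(upper.tri(D), arr.ind = TRUE)
    ord <- order(idx[, 1L], idx[, 2L])
    idx <- idx[ord, , drop = FALSE]
    w <- D[idx]
    g <- igraph::make_empty_graph(n, directed = FALSE)
    g <- igraph::add_edges(g, t(idx), attr = list(weight = w))
  } else {
    g <- knn_graph(net$pos, k = 15L)
  }
  t0 <- igraph::mst(g, weights = igraph::E(g)$weight)
  em <- igraph::as_edgelist(t0, names = FALSE)
  storage.mode(em) <- "integer"
  len <- sqrt(rowSums((net$pos[em[, 1L], , drop = FALSE] -
                       net$pos[em[, 2L], , drop = FALSE])^2))
  new_spatial_network(net$node_id, net$pos, em, len, net$root,
                      paste0(net$name, "_mst"))
}

# internal: symmetric kNN graph with components stitched by nearest pairs
knn_graph <- function(pos, k = 15L) {
  n <- nrow(pos)
  D <- as.matrix(stats::dist(pos))
  el <- matrix(0L, 0L, 2L); w <- numeric(0)
  for (i in seq_len(n)) {
    nb <- order(D[i, ])[2:(k + 1L)]
    el <- rbind(el, cbind(i, nb))
    w <- c(w, D[i, nb])
  }
  s <- el[, 1L] > el[, 2L]
  el[s, ] <- el[s, 2:1]
  key <- paste(el[, 1L], el[, 2L])
  keep <- !duplicated(key)
  el <- el[keep, , drop = FALSE]; w <- w[keep]
  g <- igraph::make_empty_graph(n, directed = FALSE)
  g <- igraph::add_edges(g, t(el), attr = list(weight = w))
  comp <- igraph::components(g)
  while (comp$no > 1L) {
    a <- which(comp$membership == 1L)
    b <- which(comp$membership != 1L)
    sub <- D[a, b, drop = FALSE]
    hit <- which(sub == min(sub), arr.ind = TRUE)[1L, ]
    g <- igraph::add_edges(g, c(a[hit[1L]], b[hit[2L]]),
                           attr = list(weight = min(sub)))
    comp <- igraph::components(g)
  }
  g
}

#' Network cost
#'
#' Total duct length divided by the total length of the Euclidean minimum
#' spanning tree on the same nodes: C = L_tot / L_tot^MST. Always >= 1 for
#' a connected spanning network; the excess over 1 measures redundancy.
#'
#' @param net a connected `spatial_network`
#' @return numeric >= 1 (up to ties in the MST)
#' @export
network_cost <- function(net) {
  if (!is_connected_net(net)) stop("cost is defined for connected networks only")
  total_length(net) / total_length(euclidean_mst(net))
}

#' Network performance
#'
#' Mean shortest-path distance between node pairs along the network,
#' divided by the same quantity on the Euclidean MST:
#' P = \eqn{\langle l \rangle / \langle l_{MST} \rangle}. The mean runs
#' over all ordered pairs, self-pairs included (1/N^2 normalization).
#' P < 1 means redundant links shorten transport paths relative to the
#' cheapest tree.
#'
#' @param net a connected `spatial_network`
#' @return numeric > 0
#' @export
network_performance <- function(net) {
  if (!is_connected_net(net))
    stop("performance is defined for connected networks only")
  mean_pair_dist(net) / mean_pair_dist(euclidean_mst(net))
}

# internal: 1/N^2 sum of weighted shortest-path distances over ordered pairs
mean_pair_dist <- function(net) {
  g <- as_igraph(net)
  d <- igraph::distances(g, weights = igraph::E(g)$weight)
  mean(d)
}

#' Mean distances to the root and between all nodes
#'
#' \eqn{\langle D_{root} \rangle = (1/N) \sum_i l(i, root)} — how far, on
#' average, a node lies from the exit along the ducts — and
#' \eqn{\langle D \rangle = (1/N^2) \sum_{ij} l(i,j)}, the mean distance
#' between all ordered node pairs (self-pairs contribute 0). Their ratio
#' approaches 1 as a network reorganizes around its exit.
#'
#' @param net a connected, rooted `spatial_network`
#' @return list with `mean_dist_root`, `mean_pairwise_dist`, `root_ratio`
#' @export
mean_distances <- function(net) {
  if (!is_connected_net(net))
    stop("distances are defined for connected networks only")
  g <- as_igraph(net)
  d <- igraph::distances(g, weights = igraph::E(g)$weight)
  droot <- mean(d[net$root, ])
  dall <- mean(d)
  list(mean_dist_root = droot, mean_pairwise_dist = dall,
       root_ratio = droot / dall)
}

#' Network dimension
#'
#' The scaling exponent of the cumulative node count within network
#' distance r of a node: for each sampled node, nodes are ranked by
#' weighted shortest-path distance, a straight line is fitted to
#' log(count) against log(r) over a window, and the mean slope across
#' sampled nodes is returned. Planar duct meshes give values near 2;
#' pruned trees drift toward lower values.
#'
#' The default window keeps radii at which the cumulative count lies
#' between `count_min` nodes and N/2, avoiding small-count noise near the
#' seed node and saturation at the network boundary.
#'
#' @param net a connected `spatial_network`, ideally N >= 50
#' @param count_min smallest cumulative count entering the fit
#' @param count_max_frac largest cumulative count entering the fit, as a
#'   fraction of N
#' @param max_sample_nodes nodes are all used when N <= this, otherwise a
#'   seeded random subset of this size
#' @param sample_seed seed for the node subsample
#' @return list with `dimension` (mean slope), `per_node` (slope per
#'   sampled node, NA where the window held < 3 points), `n_sampled`
#' @export
network_dimension <- function(net, count_min = 5, count_max_frac = 0.5,
                              max_sample_nodes = 500L, sample_seed = 1L) {
  if (!is_connected_net(net))
    stop("dimension is defined for connected networks only")
  n <- n_nodes(net)
  g <- as_igraph(net)
  nodes <- seq_len(n)
  if (n > max_sample_nodes) {
    rng <- local({ set.seed(sample_seed); sample(nodes, max_sample_nodes) })
    nodes <- sort(rng)
  }
  d <- igraph::distances(g, v = nodes, weights = igraph::E(g)$weight)
  cmax <- count_max_frac * n
  slopes <- vapply(seq_along(nodes), function(i) {
    r <- sort(d[i, ])
    # cumulative histogram over distinct radii. On graphs with discrete
    # distance values (lattices) a radius value r stands for the whole
    # continuum shell (r - h/2, r + h/2], h being the radius resolution;
    # fitting shell-midpoint counts against shell-upper-edge radii
    # removes the half-shell discretization bias that otherwise pulls
    # the slope well below the continuum dimension. For continuous
    # distance spectra h is negligible and the correction vanishes.
    cnt <- seq_along(r)
    last <- !duplicated(r, fromLast = TRUE)
    n_at <- cnt[last]
    shell <- diff(c(0L, n_at))
    k_mid <- n_at - shell / 2
    rr <- r[last]
    h <- stats::median(diff(rr))
    ok <- rr > 0 & n_at >= count_min & n_at <= cmax
    if (sum(ok) < 3) return(NA_real_)
    stats::coef(stats::lm(log(k_mid[ok]) ~ log(rr[ok] + h / 2)))[[2L]]
  }, numeric(1))
  if (all(is.na(slopes)))
    stop("dimension fit failed for every sampled node (window too narrow)")
  list(dimension = mean(slopes, na.rm = TRUE), per_node = slopes,
       n_sampled = length(nodes))
}

#' Degree-preserving randomization
#'
#' Rewires the network by double-edge swaps — (a,b),(c,d) becomes
#' (a,d),(c,b) — rejecting any swap that would create a self-loop or
#' multi-edge or disconnect the graph, so the degree sequence and
#' connectivity are preserved exactly. Node positions are untouched and
#' edge lengths are recomputed as Euclidean distances between the new
#' endpoints. Used to build randomized counterparts of digitized networks.
#'
#' @param net a connected `spatial_network`
#' @param n_swaps number of attempted swaps (default 10 E)
#' @param seed RNG seed
#' @return a `spatial_network` with attribute `"swaps_done"` counting
#'   accepted swaps; a warning is raised if none could be performed.
#' @export
randomize_degree_preserving <- function(net, n_swaps = 10L * n_edges(net),
                                        seed = 1L) {
  set.seed(seed)
  edges <- net$edges
  m <- nrow(edges)
  done <- 0L
  if (m >= 2L) {
    ekey <- function(e) paste(pmin(e[, 1L], e[, 2L]), pmax(e[, 1L], e[, 2L]))
    present <- new.env(hash = TRUE)
    for (k in ekey(edges)) assign(k, TRUE, envir = present)
    for (s in seq_len(n_swaps)) {
      pick <- sample.int(m, 2L)
      e1 <- edges[pick[1L], ]; e2 <- edges[pick[2L], ]
      if (stats::runif(1) < 0.5) e2 <- rev(e2)
      na1 <- c(e1[1L], e2[2L]); na2 <- c(e2[1L], e1[2L])
      if (na1[1L] == na1[2L] || na2[1L] == na2[2L]) next
      k1 <- paste(min(na1), max(na1)); k2 <- paste(min(na2), max(na2))
      if (k1 == k2) next
      if (exists(k1, envir = present) || exists(k2, envir = present)) next
      cand <- edges
      cand[pick[1L], ] <- c(min(na1), max(na1))
      cand[pick[2L], ] <- c(min(na2), max(na2))
      gc_ <- igraph::make_empty_graph(n_nodes(net), directed = FALSE)
      gc_ <- igraph::add_edges(gc_, t(cand))
      if (!igraph::is_connected(gc_)) next
      rm(list = ekey(edges[pick, , drop = FALSE]), envir = present)
      edges <- cand
      for (k in c(k1, k2)) assign(k, TRUE, envir = present)
      done <- done + 1L
    }
  }
  if (done == 0L && m >= 2L)
    warning("no valid degree-preserving swap found in ", n_swaps, " attempts")
  len <- sqrt(rowSums((net$pos[edges[, 1L], , drop = FALSE] -
                       net$pos[edges[, 2L], , drop = FALSE])^2))
  out <- new_spatial_network(net$node_id, net$pos, edges, len, net$root,
                             paste0(net$name, "_rand"))
  attr(out, "swaps_done") <- done
  out
}

#' Full per-network statistic vector
#'
#' Computes every summary statistic used to characterize a developmental
#' stage: node/edge counts, total length, mean degree, clustering,
#' polygon counts, cost, performance, distances to the root, and network
#' dimension.
#'
#' @param net a connected, rooted `spatial_network`
#' @param dimension compute the (comparatively expensive) network
#'   dimension? Skipped networks get NA.
#' @return one-row data.frame with columns `name, n_nodes, n_edges,
#'   total_length, mean_degree, mean_clustering, n_triangles, n_squares,
#'   n_pentagons, cost, performance, mean_dist_root, mean_pairwise_dist,
#'   root_ratio, dimension`
#' @export
summarize_network <- function(net, dimension = TRUE) {
  poly <- count_polygons(net)
  mst <- euclidean_mst(net)
  md <- mean_distances(net)
  dim_ <- if (dimension) network_dimension(net)$dimension else NA_real_
  data.frame(
    name = if (nzchar(net$name)) net$name else NA_character_,
    n_nodes = n_nodes(net),
    n_edges = n_edges(net),
    total_length = total_length(net),
    mean_degree = 2 * n_edges(net) / n_nodes(net),
    mean_clustering = mean_clustering(net),
    n_triangles = poly[["triangles"]],
    n_squares = poly[["squares"]],
    n_pentagons = poly[["pentagons"]],
    cost = total_length(net) / total_length(mst),
    performance = mean_pair_dist(net) / mean_pair_dist(mst),
    mean_dist_root = md$mean_dist_root,
    mean_pairwise_dist = md$mean_pairwise_dist,
    root_ratio = md$root_ratio,
    dimension = dim_,
    stringsAsFactors = FALSE
  )
}

#' Compare two groups of network summaries measure by measure
#'
#' Classic equal-variance two-sample two-tailed t tests on each numeric
#' summary column, with a Bonferroni-adjusted significance threshold
#' alpha / (number of measures). Groups with zero variance and equal
#' means get p = 1 by convention.
#'
#' @param summaries_a,summaries_b data.frames of [summarize_network()]
#'   rows (>= 2 rows each)
#' @param alpha family significance level (default 0.05)
#' @param var_equal use the pooled-variance t test (default TRUE)
#' @return data.frame with one row per measure: `measure, mean_a, mean_b,
#'   sem_a, sem_b, t, p, bonferroni_alpha, significant`
#' @export
compare_groups <- function(summaries_a, summaries_b, alpha = 0.05,
                           var_equal = TRUE) {
  stopifnot(nrow(summaries_a) >= 2, nrow(summaries_b) >= 2)
  meas <- intersect(names(summaries_a), names(summaries_b))
  meas <- meas[vapply(summaries_a[meas], is.numeric, logical(1))]
  meas <- setdiff(meas, c("n_nodes", "n_edges"))
  meas <- c(intersect(c("n_nodes", "n_edges"), names(summaries_a)), meas)
  m <- length(meas)
  sem <- function(x) stats::sd(x) / sqrt(length(x))
  rows <- lapply(meas, function(v) {
    a <- summaries_a[[v]]; b <- summaries_b[[v]]
    a <- a[!is.na(a)]; b <- b[!is.na(b)]
    if (stats::sd(a) == 0 && stats::sd(b) == 0) {
      tt <- list(statistic = if (mean(a) == mean(b)) 0 else Inf,
                 p.value = if (mean(a) == mean(b)) 1 else 0)
    } else {
      ht <- stats::t.test(a, b, var.equal = var_equal)
      tt <- list(statistic = unname(ht$statistic), p.value = ht$p.value)
    }
    data.frame(measure = v, mean_a = mean(a), mean_b = mean(b),
               sem_a = sem(a), sem_b = sem(b),
               t = tt$statistic, p = tt$p.value,
               bonferroni_alpha = alpha / m,
               significant = tt$p.value < alpha / m,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
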