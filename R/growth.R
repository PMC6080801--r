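#' Parameters of the stochastic network creation model
#'
#' Bundles the knobs of the plexus growth model: new lumen nodes appear
#' near the existing network and link to `M + 1` of their nearest
#' neighbors, where `M ~ Poisson(lambda)` sets the amount of redundant
#' linking and `delta` widens the candidate pool of the `M + 1 + delta`
#' closest nodes, loosening spatial specificity.
#'
#' @param lambda mean of the Poisson number of extra links per new node
#'   (best-fit value for the early plexus: 0.25)
#' @param delta candidate-pool slack (best fit: 1)
#' @param n_target final node count (default 320, a typical early plexus)
#' @param init `"two_nodes"` (two nodes a unit apart, one edge) or
#'   `"l_system"` (a small random binary tree, see [random_lsystem()])
#' @param l_system_size initial node count when `init = "l_system"`
#' @param retry_budget maximum rejected placement proposals per node
#' @return a list of class `growth_params`
#' @export
growth_params <- function(lambda = 0.25, delta = 1L, n_target = 320L,
                          init = c("two_nodes", "l_system"),
                          l_system_size = 4L, retry_budget = 1e5) {
  init <- match.arg(init)
  stopifnot(lambda >= 0, delta >= 0, n_target >= 2)
  structure(list(lambda = lambda, delta = as.integer(delta),
                 n_target = as.integer(n_target), init = init,
                 l_system_size = as.integer(l_system_size),
                 retry_budget = retry_budget),
            class = "growth_params")
}

#' Propose a position for a new lumen node
#'
#' Samples a point uniformly in the ball of radius
#' `r_max = max(d_com) + 0.5` around the center of mass of the existing
#' nodes (`d_com` are the node-to-center distances), and accepts it with
#' probability \eqn{\prod_i (1 - e^{-d_i})} where \eqn{d_i} is the
#' distance from the proposal to node i — so proposals on top of existing
#' lumens are rejected and acceptance saturates away from the network.
#' Sampling repeats until acceptance. Distances are in lumen-spacing
#' units: the acceptance kernel itself sets the length scale.
#'
#' @param net non-empty `spatial_network`
#' @param retry_budget error out after this many rejections (degenerate
#'   geometry guard)
#' @return accepted 3D point (numeric length 3)
#' @export
propose_node_position <- function(net, retry_budget = 1e5) {
  pos <- net$pos
  com <- colMeans(pos)
  d_com <- sqrt(colSums((t(pos) - com)^2))
  r_max <- max(d_com) + 0.5
  for (tries in seq_len(retry_budget)) {
    dir <- stats::rnorm(3)
    dir <- dir / sqrt(sum(dir^2))
    r <- r_max * stats::runif(1)^(1 / 3)
    p <- com + r * dir
    d <- sqrt(colSums((t(pos) - p)^2))
    p_acc <- prod(1 - exp(-d))
    if (stats::runif(1) < p_acc) return(p)
  }
  stop("no proposal accepted after ", retry_budget,
       " tries: degenerate geometry (nodes too densely packed?)")
}

#' Attach a new node to the network
#'
#' Draws `M ~ Poisson(lambda)` and links the new node to `M + 1` distinct
#' targets chosen uniformly without replacement from the `M + 1 + delta`
#' nearest existing nodes. Both the link count and the pool are capped at
#' the current network size, so small networks are handled gracefully.
#' Link lengths are Euclidean.
#'
#' @param net non-empty `spatial_network`
#' @param point 3D position of the new node (already accepted)
#' @param lambda,delta model parameters (see [growth_params()])
#' @return the enlarged `spatial_network`; the new node gets
#'   `max(node_id) + 1`.
#' @export
attach_node <- function(net, point, lambda, delta) {
  n <- n_nodes(net)
  M <- stats::rpois(1L, lambda)
  k <- min(M + 1L, n)                 # links to form
  pool_n <- min(M + 1L + delta, n)    # candidate pool
  d <- sqrt(colSums((t(net$pos) - point)^2))
  pool <- order(d)[seq_len(pool_n)]
  targets <- if (pool_n == k) pool else pool[sample.int(pool_n, k)]
  new_id <- max(net$node_id) + 1L
  edges <- rbind(net$edges, cbind(targets, n + 1L))
  len <- c(net$length, d[targets])
  new_spatial_network(c(net$node_id, new_id), rbind(net$pos, point),
                      edges, len, net$root, net$name)
}

#' Random binary (dichotomic) L-system tree
#'
#' A small spatially embedded binary tree used as an alternative
#' initialization of the growth model, emulating stereotyped early
#' branching: starting from a single node, each tip spawns two children
#' at unit distance in independent uniformly random 3D directions until
#' `n_init` nodes exist.
#'
#' @param n_init number of nodes (>= 2)
#' @return a `spatial_network` tree (E = N - 1) rooted at the first node
#' @export
random_lsystem <- function(n_init) {
  stopifnot(n_init >= 2)
  pos <- matrix(0, nrow = 1, ncol = 3)
  edges <- matrix(0L, 0L, 2L)
  tips <- 1L
  while (nrow(pos) < n_init) {
    new_tips <- integer(0)
    for (t in tips) {
      for (child in 1:2) {
        if (nrow(pos) >= n_init) break
        dir <- stats::rnorm(3)
        dir <- dir / sqrt(sum(dir^2))
        pos <- rbind(pos, pos[t, ] + dir)
        edges <- rbind(edges, c(t, nrow(pos)))
        new_tips <- c(new_tips, nrow(pos))
      }
    }
    tips <- new_tips
  }
  len <- sqrt(rowSums((pos[edges[, 1L], , drop = FALSE] -
                       pos[edges[, 2L], , drop = FALSE])^2))
  new_spatial_network(seq_len(nrow(pos)), pos, edges, len, 1L, "lsystem")
}

#' Grow a plexus network by redundant lumen linking
#'
#' Iterates [propose_node_position()] and [attach_node()] from the chosen
#' initialization until `n_target` nodes exist. With `lambda = 0` and
#' `delta = 0` every new node forms exactly one link to its nearest
#' neighbor and the result is a tree; at the plexus best fit
#' (`lambda = 0.25`, `delta = 1`) the network is loop-rich, with short
#' polygons as observed in the early embryonic duct mesh. The root (exit)
#' is the first initial node. Fully reproducible from `seed`: per added
#' node the generator consumes, in order, the placement proposals
#' (direction, radius, acceptance draw), the Poisson draw M, and the
#' candidate-pool sample.
#'
#' @param params a [growth_params()] list
#' @param seed integer RNG seed
#' @return a connected `spatial_network` with `n_target` nodes
#' @export
grow_network <- function(params = growth_params(), seed = 1L) {
  set.seed(seed)
  net <- switch(params$init,
    two_nodes = new_spatial_network(
      1:2, rbind(c(0, 0, 0), c(1, 0, 0)),
      matrix(c(1L, 2L), 1L), 1, 1L,
      sprintf("plexus_l%g_d%d_s%d", params$lambda, params$delta, seed)),
    l_system = {
      x <- random_lsystem(params$l_system_size)
      x$name <- sprintf("plexus_ls%d_l%g_d%d_s%d", params$l_system_size,
                        params$lambda, params$delta, seed)
      x
    })
  if (params$n_target < n_nodes(net))
    stop("n_target smaller than the initial network")
  while (n_nodes(net) < params$n_target) {
    p <- propose_node_position(net, params$retry_budget)
    net <- attach_node(net, p, params$lambda, params$delta)
  }
  net
}
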