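#' Combinatorial graph Laplacian
#'
#' L = D - A with D the diagonal degree matrix and A the binary adjacency
#' matrix: rows sum to zero and L is positive semidefinite. Duct lengths
#' do not enter (diffusion is per link, not per unit length), matching
#' the unweighted operator used throughout the pruning model.
#'
#' @param net a `spatial_network`
#' @return a sparse symmetric [Matrix::Matrix] of size N x N
#' @export
network_laplacian <- function(net) {
  n <- n_nodes(net)
  deg <- node_degrees(net)
  i <- c(seq_len(n), net$edges[, 1L], net$edges[, 2L])
  j <- c(seq_len(n), net$edges[, 2L], net$edges[, 1L])
  x <- c(deg, rep(-1, 2L * n_edges(net)))
  Matrix::sparseMatrix(i = i, j = j, x = x, dims = c(n, n),
                       dimnames = list(net$node_id, net$node_id))
}

#' Numerical configuration of the diffusion solver
#'
#' @param diffusion_coeff diffusion coefficient C (> 0)
#' @param dt forward-Euler time step; default `1 / (2 * max_degree + 1)`,
#'   chosen at solve time, which satisfies the stability bound
#'   `C * dt < 1 / (2 * max_degree)`
#' @param tol steady state is declared when the summed absolute
#'   concentration change per step drops below this; default `1e-10 * N`,
#'   chosen at solve time
#' @param max_steps Euler iteration cap
#' @param source_mode `"terminals_only"`: fluid enters at every terminal
#'   end (degree-1 node other than the root), whose concentration is
#'   clamped at 1, and drains at the root, clamped at 0.
#'   `"all_nodes"`: every non-root node injects one unit of fluid per
#'   step (ductal secretion everywhere); only the root is clamped at 0.
#' @return list of class `diffusion_config`
#' @export
diffusion_config <- function(diffusion_coeff = 1, dt = NULL, tol = NULL,
                             max_steps = 1e7,
                             source_mode = c("terminals_only", "all_nodes")) {
  source_mode <- match.arg(source_mode)
  stopifnot(diffusion_coeff > 0, is.null(dt) || dt > 0,
            is.null(tol) || tol > 0)
  structure(list(diffusion_coeff = diffusion_coeff, dt = dt, tol = tol,
                 max_steps = max_steps, source_mode = source_mode),
            class = "diffusion_config")
}

#' Steady-state concentrations and per-link fluxes
#'
#' Solves the diffusion model on the network: concentration phi evolves by
#' `phi(t + dt) = phi(t) - C L phi(t) dt` with boundary values re-imposed
#' each step (terminals at 1, root at 0 in `terminals_only` mode; in
#' `all_nodes` mode a unit source is added at every non-root node per
#' step with only the root clamped). At steady state the flux carried by
#' the link (i, j) is `Q(i,j) = C * (phi_i - phi_j)`.
#'
#' The production path (`method = "direct"`) solves the clamped linear
#' system exactly with a sparse factorization; the forward-Euler
#' iteration is retained as `method = "euler"` and converges to the same
#' fixed point (used as a cross-check).
#'
#' @param net connected, rooted `spatial_network`
#' @param config a [diffusion_config()]
#' @param method `"direct"` (default) or `"euler"`
#' @return list of class `flux_state`: `phi` (per-node concentration),
#'   `flux` (data.frame `u, v, flux, magnitude` with u, v node indices of
#'   each edge, `flux = C * (phi_u - phi_v)` signed), plus the config.
#' @export
solve_steady_state <- function(net, config = diffusion_config(),
                               method = c("direct", "euler")) {
  method <- match.arg(method)
  if (!is_connected_net(net)) stop("diffusion requires a connected network")
  n <- n_nodes(net)
  deg <- node_degrees(net)
  C <- config$diffusion_coeff
  dt <- if (is.null(config$dt)) 1 / (2 * max(deg) + 1) else config$dt
  if (C * dt >= 1 / (2 * max(deg)))
    stop("unstable time step: need C * dt < 1 / (2 * max_degree) (have ",
         signif(C * dt, 3), " vs ", signif(1 / (2 * max(deg)), 3), ")")
  tol <- if (is.null(config$tol)) 1e-10 * n else config$tol
  L <- network_laplacian(net)
  root <- net$root
  terminals <- setdiff(which(deg == 1L), root)
  if (config$source_mode == "terminals_only" && length(terminals) == 0L)
    stop("terminals_only mode needs at least one degree-1 node besides the root")

  if (config$source_mode == "terminals_only") {
    clamped <- c(root, terminals)
    phi_b <- c(0, rep(1, length(terminals)))
    free <- setdiff(seq_len(n), clamped)
    phi <- numeric(n)
    phi[clamped] <- phi_b
    if (length(free)) {
      if (method == "direct") {
        rhs <- -L[free, clamped, drop = FALSE] %*% phi_b
        phi[free] <- as.numeric(Matrix::solve(L[free, free, drop = FALSE], rhs))
      } else {
        phi[free] <- mean(phi_b)
        phi <- euler_iterate(L, phi, clamped, phi_b, source = NULL,
                             C, dt, tol, config$max_steps)
      }
    }
  } else {
    s <- rep(1, n); s[root] <- 0
    free <- setdiff(seq_len(n), root)
    phi <- numeric(n)
    if (method == "direct") {
      # fixed point of phi <- phi - C L phi dt + s  (root clamped at 0)
      rhs <- s[free] / (C * dt)
      phi[free] <- as.numeric(Matrix::solve(L[free, free, drop = FALSE], rhs))
    } else {
      phi <- euler_iterate(L, phi, clamped = root, phi_b = 0, source = s,
                           C, dt, tol, config$max_steps)
    }
  }

  u <- net$edges[, 1L]; v <- net$edges[, 2L]
  q <- C * (phi[u] - phi[v])
  structure(list(phi = phi,
                 flux = data.frame(u = u, v = v, flux = q,
                                   magnitude = abs(q)),
                 config = config, method = method),
            class = "flux_state")
}

# internal: forward-Euler iteration with re-clamping (and optional source)
euler_iterate <- function(L, phi, clamped, phi_b, source, C, dt, tol,
                          max_steps) {
  for (step in seq_len(max_steps)) {
    phi_new <- phi - C * dt * as.numeric(L %*% phi)
    if (!is.null(source)) phi_new <- phi_new + source
    phi_new[clamped] <- phi_b
    delta <- sum(abs(phi_new - phi))
    phi <- phi_new
    if (delta < tol) return(phi)
  }
  stop("no steady state within ", max_steps, " Euler steps (residual ",
       signif(delta, 3), " > tol ", signif(tol, 3), ")")
}

#' Redundant (removable) links
#'
#' A link is redundant if its removal does not fragment the network —
#' i.e. it is not a bridge. Only redundant links are eligible for
#' pruning; in a connected network their number equals the cycle-space
#' dimension E - N + 1.
#'
#' @param net a connected `spatial_network`
#' @return integer vector of edge row indices into `net$edges`
#' @export
redundant_edges <- function(net) {
  g <- as_igraph(net)
  setdiff(seq_len(n_edges(net)), igraph::bridges(g))
}

#' Prune a plexus to a tree by removing lowest-flux redundant links
#'
#' Repeats: solve the steady-state diffusion, sort links by flux
#' magnitude, remove the lowest-flux link whose removal does not fragment
#' the network, re-solve — until no removable link remains, i.e. the
#' network is a spanning tree. Ties in flux are broken lexicographically
#' by sorted node-ID pair. Each removal is recorded with its flux and its
#' shortest-path distance to the root (from the removed link's closer
#' endpoint, measured on the network before that removal), which lets one
#' trace whether pruning proceeds from the periphery toward the exit.
#'
#' @param net connected, rooted `spatial_network`
#' @param config a [diffusion_config()]
#' @return list with `tree` (the pruned `spatial_network`) and `trace`
#'   (data.frame `event, u, v, flux, dist_to_root` with u, v node IDs)
#' @export
prune_by_flux <- function(net, config = diffusion_config()) {
  cur <- net
  ev <- list()
  k <- 0L
  repeat {
    red <- redundant_edges(cur)
    if (!length(red)) break
    fs <- solve_steady_state(cur, config)
    mag <- fs$flux$magnitude[red]
    id_u <- cur$node_id[cur$edges[red, 1L]]
    id_v <- cur$node_id[cur$edges[red, 2L]]
    ord <- order(mag, pmin(id_u, id_v), pmax(id_u, id_v))
    pick <- red[ord[1L]]
    k <- k + 1L
    ev[[k]] <- data.frame(
      event = k,
      u = cur$node_id[cur$edges[pick, 1L]],
      v = cur$node_id[cur$edges[pick, 2L]],
      flux = fs$flux$magnitude[pick],
      dist_to_root = edge_root_distance(cur, pick))
    cur <- subset_edges(cur, setdiff(seq_len(n_edges(cur)), pick))
  }
  trace <- if (k) do.call(rbind, ev) else
    data.frame(event = integer(0), u = integer(0), v = integer(0),
               flux = numeric(0), dist_to_root = numeric(0))
  list(tree = cur, trace = trace)
}

#' Prune a plexus to a tree by removing random redundant links
#'
#' Baseline for [prune_by_flux()]: at each step one redundant link is
#' removed uniformly at random, until the network is a spanning tree.
#'
#' @param net connected `spatial_network`
#' @param seed RNG seed
#' @return list with `tree` and `trace` (as in [prune_by_flux()], flux
#'   column all NA)
#' @export
prune_random <- function(net, seed = 1L) {
  set.seed(seed)
  cur <- net
  ev <- list()
  k <- 0L
  repeat {
    red <- redundant_edges(cur)
    if (!length(red)) break
    pick <- red[sample.int(length(red), 1L)]
    k <- k + 1L
    ev[[k]] <- data.frame(
      event = k,
      u = cur$node_id[cur$edges[pick, 1L]],
      v = cur$node_id[cur$edges[pick, 2L]],
      flux = NA_real_,
      dist_to_root = edge_root_distance(cur, pick))
    cur <- subset_edges(cur, setdiff(seq_len(n_edges(cur)), pick))
  }
  trace <- if (k) do.call(rbind, ev) else
    data.frame(event = integer(0), u = integer(0), v = integer(0),
               flux = numeric(0), dist_to_root = numeric(0))
  list(tree = cur, trace = trace)
}

# internal: weighted shortest-path distance from an edge's closer
# endpoint to the root, on the current network
edge_root_distance <- function(net, edge_row) {
  g <- as_igraph(net)
  d <- igraph::distances(g, v = net$root, weights = igraph::E(g)$weight)
  min(d[1L, net$edges[edge_row, ]])
}
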