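#' Named small fixture networks
#'
#' Exactly constructed small networks with documented coordinates, used
#' throughout the test suite as hand-checkable oracles: `triangle`
#' (unit-ish equilateral), `cycle4` / `square_perimeter` (unit square),
#' `cycle5` (regular pentagon), `k4` (complete graph on 4 points),
#' `path10` (unit chain of 10 nodes), `star6` (hub plus 5 unit spokes),
#' `subdivided_square` (unit square with every side split in half, 8
#' nodes), and `binary_tree_2` .. `binary_tree_4` (balanced binary trees
#' of depth 2-4, unit edges). Roots default to node 1.
#'
#' @return named list of `spatial_network` objects
#' @export
make_fixtures <- function() {
  net <- function(pos, edges, name, len = NULL) {
    nd <- data.frame(id = seq_len(nrow(pos)), x = pos[, 1], y = pos[, 2],
                     z = if (ncol(pos) >= 3) pos[, 3] else 0)
    ed <- data.frame(source = edges[, 1], target = edges[, 2])
    if (!is.null(len)) ed$length <- len
    spatial_network(nd, ed, root_id = 1L, name = name)
  }
  poly_pos <- function(k) cbind(cos(2 * pi * (0:(k - 1)) / k),
                                sin(2 * pi * (0:(k - 1)) / k), 0)
  cyc <- function(k) cbind(1:k, c(2:k, 1))
  sq <- rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(0, 1, 0))

  # balanced binary tree of given depth, drawn layer by layer, unit edges
  btree <- function(depth) {
    n <- 2^(depth + 1) - 1
    lvl <- floor(log2(seq_len(n)))
    x <- vapply(seq_len(n), function(i) {
      k <- i - 2^lvl[i]                       # position within the level
      (k + 0.5) / 2^lvl[i]
    }, numeric(1))
    pos <- cbind(x, -lvl, 0)
    edges <- cbind(2:n, floor((2:n) / 2))
    net(pos, edges, sprintf("binary_tree_%d", depth), len = rep(1, n - 1))
  }

  list(
    triangle = net(poly_pos(3), cyc(3), "triangle"),
    cycle4 = net(poly_pos(4), cyc(4), "cycle4"),
    cycle5 = net(poly_pos(5), cyc(5), "cycle5"),
    k4 = net(sq, rbind(cyc(4), c(1, 3), c(2, 4)), "k4"),
    path10 = net(cbind(0:9, 0, 0), cbind(1:9, 2:10), "path10"),
    star6 = net(rbind(c(0, 0, 0), poly_pos(5)), cbind(1, 2:6), "star6",
                len = rep(1, 5)),
    square_perimeter = net(sq, cyc(4), "square_perimeter"),
    subdivided_square = net(
      rbind(c(0, 0, 0), c(.5, 0, 0), c(1, 0, 0), c(1, .5, 0),
            c(1, 1, 0), c(.5, 1, 0), c(0, 1, 0), c(0, .5, 0)),
      cbind(1:8, c(2:8, 1)), "subdivided_square"),
    binary_tree_2 = btree(2),
    binary_tree_3 = btree(3),
    binary_tree_4 = btree(4)
  )
}

#' Jittered, diluted triangular-lattice mesh
#'
#' A planar loop-rich control network that is independent of the growth
#' model: a roughly square patch of a unit triangular lattice, positions
#' jittered by Gaussian noise, then a fraction of the (currently
#' non-bridge) edges removed uniformly at random so connectivity is never
#' broken. The root is the bottom-left boundary node. Emulates the
#' planar, loop-rich geometry of an early duct plexus with dimension
#' close to 2.
#'
#' @param n_nodes target node count (>= 16); the patch is the smallest
#'   near-square lattice holding at least this many nodes, truncated to
#'   exactly `n_nodes`
#' @param noise positional jitter sd, in lattice units
#' @param dilution fraction of edges to (attempt to) remove; bridges are
#'   protected, so the realized fraction can be smaller
#' @param seed RNG seed
#' @return a connected `spatial_network`
#' @export
make_lattice_mesh <- function(n_nodes = 100L, noise = 0, dilution = 0,
                              seed = 1L) {
  stopifnot(n_nodes >= 16, dilution >= 0, dilution <= 1, noise >= 0)
  set.seed(seed)
  ncol_ <- ceiling(sqrt(n_nodes))
  nrow_ <- ceiling(n_nodes / ncol_)
  pts <- expand.grid(col = seq_len(ncol_), row = seq_len(nrow_))
  pts <- pts[order(pts$row, pts$col), ]
  pts <- pts[seq_len(n_nodes), ]
  x <- pts$col + ifelse(pts$row %% 2 == 0, 0.5, 0)
  y <- pts$row * sqrt(3) / 2
  pos <- cbind(x, y, 0)
  if (noise > 0) pos[, 1:2] <- pos[, 1:2] + stats::rnorm(2 * n_nodes, 0, noise)
  # connect pairs at (pre-jitter) lattice distance ~1
  x0 <- pts$col + ifelse(pts$row %% 2 == 0, 0.5, 0)
  y0 <- pts$row * sqrt(3) / 2
  D0 <- as.matrix(stats::dist(cbind(x0, y0)))
  idx <- which(upper.tri(D0) & abs(D0 - 1) < 1e-9, arr.ind = TRUE)
  net <- new_spatial_network(
    seq_len(n_nodes), pos, idx,
    sqrt(rowSums((pos[idx[, 1L], , drop = FALSE] -
                  pos[idx[, 2L], , drop = FALSE])^2)),
    root = 1L,
    name = sprintf("lattice_n%d_s%d", n_nodes, seed))
  if (!is_connected_net(net))
    stop("lattice patch is disconnected; increase n_nodes")
  if (dilution > 0) {
    target <- round(dilution * n_edges(net))
    removed <- 0L
    while (removed < target) {
      red <- redundant_edges(net)
      if (!length(red)) break
      pick <- red[sample.int(length(red), 1L)]
      net <- subset_edges(net, setdiff(seq_len(n_edges(net)), pick))
      removed <- removed + 1L
    }
  }
  net
}

#' Plexus-stage synthetic network
#'
#' The early-plexus stand-in: wraps [grow_network()] at the best-fit
#' creation parameters (`lambda = 0.25`, `delta = 1`, 320 nodes), which
#' reproduce the loop statistics of the embryonic duct mesh.
#'
#' @param n_nodes final node count (default 320)
#' @param seed RNG seed
#' @param lambda,delta growth parameters (defaults are the best fit)
#' @return a connected, rooted `spatial_network`
#' @export
make_plexus <- function(n_nodes = 320L, seed = 1L, lambda = 0.25,
                        delta = 1L) {
  grow_network(growth_params(lambda = lambda, delta = delta,
                             n_target = n_nodes), seed = seed)
}

#' Tree-stage synthetic network
#'
#' A treelike (near-mature) stand-in: a plexus grown at the best-fit
#' parameters and then pruned to a spanning tree by flux.
#'
#' @param n_nodes node count (default 320)
#' @param seed RNG seed
#' @return a `spatial_network` tree
#' @export
make_tree <- function(n_nodes = 320L, seed = 1L) {
  px <- make_plexus(n_nodes = n_nodes, seed = seed)
  out <- prune_by_flux(px)$tree
  out$name <- sprintf("tree_n%d_s%d", n_nodes, seed)
  out
}

#' Write a set of synthetic samples as nodes/edges CSV pairs
#'
#' Generates one network per config and writes it in the [read_network()]
#' layout (`<name>_nodes.csv`, `<name>_edges.csv`) plus a
#' `manifest.csv` recording generator, parameters, and seed, so the set
#' is reproducible and every sample round-trips through [read_network()].
#'
#' @param out_dir output directory (created if missing)
#' @param configs list of config lists, each with `generator` (one of
#'   `"fixture"`, `"lattice_mesh"`, `"plexus"`, `"tree"`), `name`, and
#'   the generator's parameters (`fixture_name` for fixtures; `n_nodes`,
#'   `noise`, `dilution`, `seed` as applicable)
#' @return data.frame manifest (also written to `out_dir/manifest.csv`)
#' @export
emit_sample_set <- function(out_dir, configs) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  rows <- lapply(configs, function(cf) {
    gen <- match.arg(cf$generator,
                     c("fixture", "lattice_mesh", "plexus", "tree"))
    net <- switch(gen,
      fixture = make_fixtures()[[cf$fixture_name]],
      lattice_mesh = make_lattice_mesh(cf$n_nodes %||% 100L,
                                       cf$noise %||% 0,
                                       cf$dilution %||% 0,
                                       cf$seed %||% 1L),
      plexus = make_plexus(cf$n_nodes %||% 320L, cf$seed %||% 1L),
      tree = make_tree(cf$n_nodes %||% 320L, cf$seed %||% 1L))
    if (is.null(net)) stop("unknown fixture name: ", cf$fixture_name)
    nm <- cf$name %||% net$name
    nf <- file.path(out_dir, paste0(nm, "_nodes.csv"))
    ef <- file.path(out_dir, paste0(nm, "_edges.csv"))
    write_network(net, nf, ef)
    data.frame(name = nm, generator = gen,
               n_nodes = n_nodes(net), n_edges = n_edges(net),
               root_id = net$node_id[net$root],
               seed = cf$seed %||% NA_integer_,
               nodes_file = basename(nf), edges_file = basename(ef),
               stringsAsFactors = FALSE)
  })
  manifest <- do.call(rbind, rows)
  utils::write.csv(manifest, file.path(out_dir, "manifest.csv"),
                   row.names = FALSE)
  manifest
}

`%||%` <- function(a, b) if (is.null(a)) b else a
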