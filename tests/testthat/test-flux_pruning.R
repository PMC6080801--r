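test_that("Laplacian is D - A with zero row sums", {
  two <- spatial_network(data.frame(id = 1:2, x = 0:1, y = 0, z = 0),
                         data.frame(source = 1, target = 2))
  L <- as.matrix(network_laplacian(two))
  expect_equal(unname(L), rbind(c(1, -1), c(-1, 1)))
  fx <- make_fixtures()
  L <- as.matrix(network_laplacian(fx$triangle))
  expect_equal(unname(diag(L)), rep(2, 3))
  expect_equal(unname(rowSums(L)), rep(0, 3))
  # matches an independent D - A recomputation on a random graph
  net <- random_connected_net(12, seed = 21)
  A <- to_adjacency(net)$A
  expect_equal(unname(as.matrix(network_laplacian(net))),
               unname(diag(rowSums(A)) - A))
})

test_that("steady state on a chain is harmonic interpolation", {
  ch <- chain_net(3)   # root - interior - terminal
  fs <- solve_steady_state(ch)
  expect_equal(fs$phi, c(0, 0.5, 1))
  expect_equal(fs$flux$magnitude, c(0.5, 0.5))
})

test_that("Euler iteration and the direct clamped solve agree", {
  nets <- list(chain_net(5), square_with_terminal(),
               make_plexus(n_nodes = 40, seed = 6),
               make_plexus(n_nodes = 60, seed = 7))
  for (net in nets) {
    for (mode in c("terminals_only", "all_nodes")) {
      # tighten the Euler stopping rule so the iterate lands within the
      # comparison tolerance of the shared fixed point
      cfg <- diffusion_config(source_mode = mode, tol = 1e-13)
      a <- solve_steady_state(net, cfg, method = "direct")
      b <- solve_steady_state(net, cfg, method = "euler")
      expect_lt(max(abs(a$phi - b$phi)), 1e-8)
    }
  }
  # unstable step rejected before iterating
  expect_error(solve_steady_state(chain_net(4), diffusion_config(dt = 2)),
               "unstable")
})

test_that("net flux at interior nodes vanishes at steady state", {
  for (s in 1:10) {
    px <- make_plexus(n_nodes = 60, seed = 400 + s)
    cfg <- diffusion_config()
    fs <- solve_steady_state(px, cfg)
    deg <- node_degrees(px)
    interior <- setdiff(which(deg > 1), px$root)
    net_in <- numeric(n_nodes(px))
    for (e in seq_len(nrow(fs$flux))) {
      net_in[fs$flux$u[e]] <- net_in[fs$flux$u[e]] - fs$flux$flux[e]
      net_in[fs$flux$v[e]] <- net_in[fs$flux$v[e]] + fs$flux$flux[e]
    }
    tol <- 1e-10 * n_nodes(px)
    expect_lt(max(abs(net_in[interior])), 10 * tol)
  }
})

test_that("flux is invariant to node relabeling and rigid motion", {
  px <- make_plexus(n_nodes = 50, seed = 17)
  fs <- solve_steady_state(px)
  # translate + rotate coordinates: lengths never enter the Laplacian
  th <- 0.7
  R <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  moved <- px
  moved$pos <- sweep(px$pos %*% t(R), 2, c(5, -3, 2), `+`)
  expect_identical(solve_steady_state(moved)$flux$magnitude,
                   fs$flux$magnitude)
  # relabel nodes (reverse order): per-edge magnitudes identical
  perm <- rev(seq_len(n_nodes(px)))
  nd <- data.frame(id = perm, x = px$pos[, 1], y = px$pos[, 2],
                   z = px$pos[, 3])
  ed <- data.frame(source = perm[px$edges[, 1]], target = perm[px$edges[, 2]],
                   length = px$length)
  rel <- spatial_network(nd, ed, root_id = perm[px$root])
  fs2 <- solve_steady_state(rel)
  key1 <- paste(pmin(px$node_id[px$edges[, 1]], px$node_id[px$edges[, 2]]),
                pmax(px$node_id[px$edges[, 1]], px$node_id[px$edges[, 2]]))
  key2 <- paste(pmin(rel$node_id[rel$edges[, 1]], rel$node_id[rel$edges[, 2]]),
                pmax(rel$node_id[rel$edges[, 1]], rel$node_id[rel$edges[, 2]]))
  expect_equal(fs2$flux$magnitude[match(paste(pmin(perm[px$edges[, 1]], perm[px$edges[, 2]]),
                                              pmax(perm[px$edges[, 1]], perm[px$edges[, 2]])), key2)],
               fs$flux$magnitude)
})

test_that("redundant edges are exactly the non-bridges", {
  fx <- make_fixtures()
  expect_length(redundant_edges(fx$binary_tree_3), 0)
  expect_length(redundant_edges(fx$cycle4), 4)
  for (s in 1:8) {
    net <- random_connected_net(sample(6:12, 1), seed = 600 + s)
    got <- sort(redundant_edges(net))
    # removal oracle: drop each edge, test connectivity
    ref <- which(vapply(seq_len(n_edges(net)), function(e) {
      g <- igraph::make_empty_graph(n_nodes(net), directed = FALSE)
      g <- igraph::add_edges(g, t(net$edges[-e, , drop = FALSE]))
      igraph::is_connected(g)
    }, logical(1)))
    expect_equal(got, ref)
    # non-bridge count bounds the cycle-space dimension from above
    expect_gte(length(got), n_edges(net) - n_nodes(net) + 1L)
  }
})

test_that("flux pruning removes the far cycle edge first and yields a tree", {
  net <- square_with_terminal()
  out <- prune_by_flux(net)
  expect_equal(n_edges(out$tree), n_nodes(out$tree) - 1L)
  expect_equal(sum(count_polygons(out$tree)), 0L)
  expect_equal(nrow(out$trace), 1L)
  # by symmetry both cycle branches carry flux 0.5; the tie is broken
  # lexicographically among the equal-flux cycle edges -> edge (1,2)
  expect_equal(c(out$trace$u, out$trace$v), c(1, 2))
  # the pendant edge (3,5) carries all inflow and is never pruned
  expect_true(any(out$tree$edges[, 1] == 3 & out$tree$edges[, 2] == 5))

  # tree input returned unchanged with empty trace
  tr <- make_fixtures()$binary_tree_3
  out2 <- prune_by_flux(tr)
  expect_identical(out2$tree$edges, tr$edges)
  expect_equal(nrow(out2$trace), 0L)
})

test_that("both pruning modes end in spanning trees with cycle-dim removals", {
  for (s in 1:5) {
    px <- make_plexus(n_nodes = 70, seed = 200 + s)
    cyc <- n_edges(px) - n_nodes(px) + 1L
    f <- prune_by_flux(px)
    r <- prune_random(px, seed = s)
    for (out in list(f, r)) {
      expect_equal(n_edges(out$tree), n_nodes(px) - 1L)
      expect_true(is_connected_net(out$tree))
      expect_equal(nrow(out$trace), cyc)
      expect_equal(sum(count_polygons(out$tree)), 0L)
    }
  }
})

test_that("random pruning removes each redundant edge uniformly", {
  fx <- make_fixtures()
  n_trial <- 2000
  first <- vapply(seq_len(n_trial), function(s)
    paste(prune_random(fx$cycle4, seed = s)$trace[1, c("u", "v")],
          collapse = "-"), character(1))
  freq <- table(first) / n_trial
  expect_length(freq, 4)
  for (f in freq)
    expect_equal(unname(f), 0.25, tolerance = 4 * sqrt(0.25 * 0.75 / n_trial) / 0.25)
})

test_that("flux pruning proceeds from the periphery toward the exit", {
  rhos <- vapply(1:8, function(s) {
    px <- make_plexus(n_nodes = 100, seed = 300 + s)
    tr <- prune_by_flux(px)$trace
    cor(tr$event, tr$dist_to_root, method = "spearman")
  }, numeric(1))
  expect_lt(median(rhos), 0)
})
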