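fx <- make_fixtures()

test_that("degree distribution tallies match an independent recount", {
  expect_equal(degree_distribution(fx$triangle), c("2" = 3L))
  expect_equal(degree_distribution(fx$star6), c("1" = 5L, "5" = 1L))
  px <- make_plexus(n_nodes = 120, seed = 11)
  dd <- degree_distribution(px)
  expect_equal(sum(dd), n_nodes(px))
  # independent tally straight from the edge list
  cnt <- table(factor(c(px$edges[, 1], px$edges[, 2]), levels = 1:n_nodes(px)))
  expect_equal(dd, table(as.integer(cnt))[names(dd)], ignore_attr = TRUE)
  expect_equal(sum(as.integer(names(dd)) * dd) / n_nodes(px),
               2 * n_edges(px) / n_nodes(px))
})

test_that("trace-formula polygon counts equal brute-force enumeration", {
  expect_equal(unname(count_polygons(fx$triangle)), c(1L, 0L, 0L))
  expect_equal(unname(count_polygons(fx$cycle4)), c(0L, 1L, 0L))
  expect_equal(unname(count_polygons(fx$cycle5)), c(0L, 0L, 1L))
  expect_equal(unname(count_polygons(fx$k4)), c(4L, 3L, 0L))
  # tr(A^3) = 24 on K4 -> 24/6 = 4 triangles
  A <- to_adjacency(fx$k4)$A
  expect_equal(sum(diag(A %*% A %*% A)), 24)

  for (s in 1:12) {
    n <- sample(5:12, 1)
    net <- random_connected_net(n, p = 0.4, seed = 100 + s)
    A <- to_adjacency(net)$A
    expect_equal(unname(count_polygons(net)),
                 c(brute_cycle_count(A, 3), brute_cycle_count(A, 4),
                   brute_cycle_count(A, 5)),
                 label = paste("graph seed", 100 + s))
  }
})

test_that("mean clustering matches per-node hand computation", {
  expect_equal(mean_clustering(fx$triangle), 1)
  expect_equal(mean_clustering(fx$star6), 0)
  # K4 minus one edge: two nodes of degree 3 with 1 triangle out of 3
  # pairs (1/3... no: degree 2 nodes have C = 1); hand value:
  # deg-3 nodes: 2 triangles? K4 minus edge {1,2}: triangles = {1,3,4},{2,3,4}
  # node 1: k=2, pairs {3,4} linked -> C=1; node 2 likewise 1;
  # nodes 3,4: k=3, of 3 pairs 2 linked -> 2/3. mean = (1+1+2/3+2/3)/4 = 5/6
  k4m <- spatial_network(
    data.frame(id = 1:4, x = c(0, 1, 1, 0), y = c(0, 0, 1, 1), z = 0),
    data.frame(source = c(1, 2, 3, 1, 2), target = c(3, 3, 4, 4, 4)))
  expect_equal(mean_clustering(k4m), 5 / 6)
})

test_that("euclidean MST is minimal and matches an independent solver", {
  # unit square corners: MST = any 3 sides, length 3
  expect_equal(total_length(euclidean_mst(fx$square_perimeter)), 3)
  # collinear points: chain
  expect_equal(total_length(euclidean_mst(chain_net(3))), 2)
  # 30 random points: total equals vegan::spantree on the distance matrix
  set.seed(9)
  pts <- matrix(runif(90, 0, 5), ncol = 3)
  net <- spatial_network(
    data.frame(id = 1:30, x = pts[, 1], y = pts[, 2], z = pts[, 3]),
    data.frame(source = 1:29, target = 2:30))
  mst <- euclidean_mst(net)
  expect_equal(n_edges(mst), 29L)
  expect_true(is_connected_net(mst))
  skip_if_not_installed("vegan")
  expect_equal(total_length(mst), sum(vegan::spantree(dist(pts))$dist),
               tolerance = 1e-12)
})

test_that("cost and performance against hand-computed references", {
  # a tree is its own-cost minimizer
  expect_equal(network_cost(euclidean_mst(fx$square_perimeter)), 1)
  expect_equal(network_performance(euclidean_mst(fx$square_perimeter)), 1)
  # unit-square perimeter: cost 4/3; performance 1/1.25 = 0.8
  expect_equal(network_cost(fx$square_perimeter), 4 / 3)
  expect_equal(network_performance(fx$square_perimeter), 0.8)
  expect_error(network_cost(spatial_network(
    data.frame(id = 1:4, x = c(0, 1, 5, 6), y = 0, z = 0),
    data.frame(source = c(1, 3), target = c(2, 4)))), "connected")
  # cost >= 1 on random loop-rich inputs
  for (s in 1:5) {
    net <- make_lattice_mesh(36, noise = 0.1, dilution = 0.2, seed = s)
    expect_gte(network_cost(net), 1)
  }
})

test_that("mean distances follow the printed normalizations", {
  # unit chain of 3 rooted at an end: Droot = (0+1+2)/3; D = 8/9
  md <- mean_distances(chain_net(3))
  expect_equal(md$mean_dist_root, 1)
  expect_equal(md$mean_pairwise_dist, 8 / 9)
  expect_equal(md$root_ratio, 9 / 8)
  # star rooted at hub: Droot = 5/6 (root's own 0 included)
  md <- mean_distances(fx$star6)
  expect_equal(md$mean_dist_root, 5 / 6)
  # identity root_ratio * mean_pairwise = mean_dist_root
  px <- make_plexus(n_nodes = 80, seed = 2)
  md <- mean_distances(px)
  expect_equal(md$root_ratio * md$mean_pairwise_dist, md$mean_dist_root)
})

test_that("removing a non-bridge edge cannot raise polygon counts nor lower mean distance", {
  px <- make_plexus(n_nodes = 60, seed = 8)
  p0 <- sum(count_polygons(px))
  d0 <- mean_distances(px)$mean_pairwise_dist
  red <- redundant_edges(px)
  for (e in red[seq_len(min(5, length(red)))]) {
    cut <- ductnet:::subset_edges(px, setdiff(seq_len(n_edges(px)), e))
    expect_lte(sum(count_polygons(cut)), p0)
    expect_gte(mean_distances(cut)$mean_pairwise_dist, d0 - 1e-12)
  }
})

test_that("network dimension recovers the analytic limits", {
  expect_equal(network_dimension(chain_net(200))$dimension, 1,
               tolerance = 0.15)
  expect_equal(network_dimension(grid_net(20))$dimension, 2,
               tolerance = 0.2)
  # too-narrow window errors
  expect_error(network_dimension(chain_net(200), count_min = 99,
                                 count_max_frac = 0.5), "window|failed")
})

test_that("degree-preserving randomization keeps degrees and connectivity", {
  tri <- fx$triangle
  expect_warning(r <- randomize_degree_preserving(tri, seed = 1), "swap")
  expect_equal(r$edges, tri$edges)
  for (s in 1:10) {
    net <- make_lattice_mesh(49, noise = 0.05, dilution = 0.15, seed = s)
    r <- randomize_degree_preserving(net, n_swaps = 3L * n_edges(net),
                                     seed = s + 50)
    expect_equal(sort(node_degrees(r)), sort(node_degrees(net)))
    expect_true(is_connected_net(r))
    # lengths recomputed from positions
    expect_equal(r$length,
                 sqrt(rowSums((r$pos[r$edges[, 1], ] - r$pos[r$edges[, 2], ])^2)))
  }
  # randomization scrambles the geometric loop structure of a mesh
  net <- make_lattice_mesh(100, noise = 0.05, dilution = 0.1, seed = 3)
  p_orig <- sum(count_polygons(net))
  p_rand <- vapply(1:25, function(s)
    sum(count_polygons(randomize_degree_preserving(net, seed = s))),
    numeric(1))
  sem <- sd(p_rand) / sqrt(length(p_rand))
  expect_gt(abs(mean(p_rand) - p_orig), sem)
})

test_that("summarize_network agrees field by field with direct recomputation", {
  px <- make_plexus(n_nodes = 70, seed = 13)
  s <- summarize_network(px)
  expect_equal(s$n_nodes, 70L)
  expect_equal(s$mean_degree, 2 * n_edges(px) / 70)
  expect_equal(s$total_length, sum(px$length))
  expect_equal(s$cost, network_cost(px))
  expect_equal(s$performance, network_performance(px))
  expect_equal(s$root_ratio, s$mean_dist_root / s$mean_pairwise_dist)
  expect_equal(s$dimension, network_dimension(px)$dimension)
  expect_equal(c(s$n_triangles, s$n_squares, s$n_pentagons),
               unname(as.integer(count_polygons(px))))
  # MST summary: cost = performance = 1, no polygons
  sm <- summarize_network(euclidean_mst(px), dimension = FALSE)
  expect_equal(sm$cost, 1)
  expect_equal(sm$performance, 1)
  expect_equal(sm$n_triangles + sm$n_squares + sm$n_pentagons, 0L)
})

test_that("group comparison applies pooled t tests with Bonferroni", {
  set.seed(4)
  mk <- function(mu) data.frame(cost = rnorm(20, mu, 0.1),
                                performance = rnorm(20, 1, 0.1))
  same <- compare_groups(mk(1.5), mk(1.5), alpha = 0.05)
  expect_true(all(same$p > 0.001))
  diff_ <- compare_groups(mk(0), mk(1), alpha = 0.05)
  expect_true(diff_$significant[diff_$measure == "cost"])
  expect_equal(unique(diff_$bonferroni_alpha), 0.05 / nrow(diff_))
  # 11 measures -> alpha/11
  a <- as.data.frame(matrix(rnorm(22 * 2), nrow = 2))
  names(a) <- paste0("m", 1:22)[1:22]
  a <- a[, 1:11]
  cc <- compare_groups(rbind(a, a + 0.1), rbind(a, a - 0.1), alpha = 0.05)
  expect_equal(unique(cc$bonferroni_alpha), 0.05 / 11, tolerance = 1e-12)
  # zero variance in both groups with equal means -> p = 1
  z <- data.frame(cost = c(1, 1, 1))
  expect_equal(compare_groups(z, z)$p, 1)
  # matches stats::t.test directly
  g1 <- mk(0.2); g2 <- mk(0.4)
  out <- compare_groups(g1, g2)
  ref <- t.test(g1$cost, g2$cost, var.equal = TRUE)
  expect_equal(out$p[out$measure == "cost"], ref$p.value)
  expect_equal(out$t[out$measure == "cost"], unname(ref$statistic))
})
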