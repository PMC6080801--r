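#' Parameters of the flux-diameter adaptation law
#'
#' A duct's wall experiences shear stress tau from the laminar fluid flow
#' it carries; its diameter adapts by
#' \deqn{\partial d/\partial t = K [\tau(t) - \tau_{desired}]\, d(t)}
#' so every duct converges to a common target shear stress. With
#' Poiseuille's relation \eqn{d^3 = 32 \eta Q / (\pi \tau)} this drives
#' each diameter to the cube root of the flux it carries.
#'
#' @param adaptation_constant K > 0, rate of diameter adaptation
#' @param tau_desired target wall shear stress (> 0), arbitrary units
#' @param viscosity fluid viscosity eta (> 0), arbitrary units
#' @param dt_ode explicit-Euler step of the ODE integrator
#' @param tol_ode convergence threshold on the max relative diameter
#'   change per step
#' @param max_steps_ode integration cap
#' @return list of class `adaptation_params`
#' @export
adaptation_params <- function(adaptation_constant = 0.1, tau_desired = 1,
                              viscosity = 1, dt_ode = 0.01, tol_ode = 1e-10,
                              max_steps_ode = 1e6) {
  stopifnot(adaptation_constant > 0, tau_desired > 0, viscosity > 0,
            dt_ode > 0, tol_ode > 0)
  structure(list(adaptation_constant = adaptation_constant,
                 tau_desired = tau_desired, viscosity = viscosity,
                 dt_ode = dt_ode, tol_ode = tol_ode,
                 max_steps_ode = max_steps_ode),
            class = "adaptation_params")
}

#' Drained basin of every duct in a rooted tree
#'
#' For each edge of a rooted tree, the number of nodes and the total duct
#' length in the subtree on the far side from the root — the basin the
#' duct drains. With uniform secretion (one unit per node) the basin node
#' count is exactly the steady-state flow the duct carries, which links
#' the pruned tree to the diameter adaptation law without re-solving
#' diffusion.
#'
#' @param tree a `spatial_network` that is a tree (E = N - 1, connected)
#' @return data.frame with one row per edge: `u, v` (node IDs, `u` on the
#'   root side), `length`, `basin_nodes`, `basin_length`
#' @export
drained_basin <- function(tree) {
  n <- n_nodes(tree)
  if (n_edges(tree) != n - 1L || !is_connected_net(tree))
    stop("drained_basin needs a tree; prune cyclic networks first ",
         "(see prune_by_flux)")
  g <- as_igraph(tree)
  # orient edges away from the root via BFS parents
  bfs <- igraph::bfs(g, root = tree$root, father = TRUE, order = TRUE)
  father <- as.integer(bfs$father)
  order_ <- as.integer(bfs$order)
  # subtree accumulation in reverse BFS order
  basin_n <- rep(1L, n)
  basin_len <- numeric(n)        # duct length strictly below node + its stem? no:
  # basin_len[v] = total edge length in the subtree rooted at v (edges below v)
  edge_len <- numeric(n)         # length of the stem edge (father[v], v)
  for (e in seq_len(n_edges(tree))) {
    a <- tree$edges[e, 1L]; b <- tree$edges[e, 2L]
    child <- if (!is.na(father[b]) && father[b] == a) b
             else if (!is.na(father[a]) && father[a] == b) a
             else stop("edge (", tree$node_id[a], ",", tree$node_id[b],
                       ") is not part of the BFS tree; input is not a tree")
    edge_len[child] <- tree$length[e]
  }
  for (v in rev(order_)) {
    f <- father[v]
    if (is.na(f)) next
    basin_n[f] <- basin_n[f] + basin_n[v]
    basin_len[f] <- basin_len[f] + basin_len[v] + edge_len[v]
  }
  child <- setdiff(order_, tree$root)
  data.frame(u = tree$node_id[father[child]],
             v = tree$node_id[child],
             length = edge_len[child],
             basin_nodes = basin_n[child],
             basin_length = basin_len[child] + edge_len[child])
}

#' Steady-state duct diameter under Poiseuille flow
#'
#' The fixed point of the shear-stress adaptation ODE:
#' \eqn{d = (32 \eta Q / (\pi \tau_{desired}))^{1/3}}, i.e. diameter
#' proportional to the cube root of the flux. `Q = 0` gives `d = 0` (the
#' duct disappears).
#'
#' @param Q per-duct flux (>= 0)
#' @param params an [adaptation_params()]
#' @return per-duct diameter, same length as `Q`
#' @export
steady_diameter <- function(Q, params = adaptation_params()) {
  if (any(Q < 0)) stop("flux must be non-negative")
  (32 * params$viscosity * Q / (pi * params$tau_desired))^(1 / 3)
}

#' Integrate the shear-stress adaptation ODE
#'
#' Explicit-Euler integration of
#' \eqn{\partial d/\partial t = K[\tau - \tau_{desired}] d} with
#' \eqn{\tau = 32 \eta Q / (\pi d^3)} from Poiseuille's law, each duct
#' carrying its fixed flux `Q`. From any positive start the trajectory
#' converges monotonically to [steady_diameter()].
#'
#' @param Q per-duct flux (> 0)
#' @param params an [adaptation_params()]
#' @param d0 initial diameters (> 0), recycled to `length(Q)`
#' @return list: `diameter` (final), `trajectory` (steps x ducts matrix,
#'   thinned to at most 1000 rows), `steps`
#' @export
simulate_adaptation_ode <- function(Q, params = adaptation_params(), d0 = 1) {
  stopifnot(all(Q > 0), all(d0 > 0))
  d <- rep_len(d0, length(Q))
  K <- params$adaptation_constant
  traj <- list(d)
  for (step in seq_len(params$max_steps_ode)) {
    tau <- 32 * params$viscosity * Q / (pi * d^3)
    d_new <- d + params$dt_ode * K * (tau - params$tau_desired) * d
    if (any(d_new <= 0))
      stop("diameter reached <= 0 during integration: decrease dt_ode")
    rel <- max(abs(d_new - d) / d)
    d <- d_new
    traj[[length(traj) + 1L]] <- d
    if (rel < params$tol_ode) break
  }
  if (rel >= params$tol_ode)
    stop("adaptation ODE did not converge within max_steps_ode")
  tr <- do.call(rbind, traj)
  if (nrow(tr) > 1000L)
    tr <- tr[unique(round(seq(1L, nrow(tr), length.out = 1000L))), ,
             drop = FALSE]
  list(diameter = d, trajectory = tr, steps = step)
}

#' Two parallel ducts competing for a fixed total flow
#'
#' Companion dynamics to [simulate_adaptation_ode()]: two ducts of equal
#' length connect the same two nodes and share a constant total flow,
#' split in proportion to their Poiseuille conductances (d^4). Under the
#' shear-stress adaptation law this configuration is unstable: from any
#' asymmetric start one duct loses flow and vanishes while the other
#' attains the steady diameter for the full flow — the mechanism by which
#' redundant ducts are eliminated.
#'
#' @param Q_total constant total flow through the pair (> 0)
#' @param params an [adaptation_params()]
#' @param d0 length-2 vector of initial diameters
#' @param vanish_frac a duct is declared vanished when its diameter falls
#'   below this fraction of the steady diameter for `Q_total`
#' @return list: `diameter` (final pair), `winner` (1 or 2),
#'   `steps`
#' @export
simulate_parallel_ducts <- function(Q_total, params = adaptation_params(),
                                    d0 = c(1, 1.1), vanish_frac = 1e-3) {
  stopifnot(Q_total > 0, length(d0) == 2L, all(d0 > 0))
  d <- d0
  K <- params$adaptation_constant
  d_ss <- steady_diameter(Q_total, params)
  for (step in seq_len(params$max_steps_ode)) {
    g4 <- d^4
    Q <- Q_total * g4 / sum(g4)
    tau <- ifelse(d > 0, 32 * params$viscosity * Q / (pi * d^3), 0)
    d <- pmax(d + params$dt_ode * K * (tau - params$tau_desired) * d, 0)
    if (min(d) < vanish_frac * d_ss &&
        abs(max(d) - d_ss) < 1e-6 * d_ss) break
  }
  list(diameter = d, winner = which.max(d), steps = step)
}

#' Fit a power law between drained basin and duct diameter
#'
#' Ordinary least squares on log(basin) against log(diameter); the slope
#' is the power-law exponent (3 when the basin is proportional to the
#' cube of the diameter, as laminar Poiseuille drainage predicts).
#' Non-positive values are dropped with a message.
#'
#' @param basin per-duct drained-basin measure (node count or upstream
#'   length)
#' @param diameter per-duct diameter
#' @return list: `exponent`, `intercept` (log-log), `r_squared`,
#'   `n_used`, `n_dropped`
#' @export
fit_powerlaw <- function(basin, diameter) {
  stopifnot(length(basin) == length(diameter))
  ok <- basin > 0 & diameter > 0 & is.finite(basin) & is.finite(diameter)
  if (sum(!ok))
    message("fit_powerlaw: dropped ", sum(!ok), " non-positive value(s)")
  if (sum(ok) < 3) stop("fewer than 3 usable (basin, diameter) pairs")
  y <- log(basin[ok])
  fit <- stats::lm(y ~ log(diameter[ok]))
  rss <- sum(stats::residuals(fit)^2)
  tss <- sum((y - mean(y))^2)
  list(exponent = unname(stats::coef(fit)[2L]),
       intercept = unname(stats::coef(fit)[1L]),
       r_squared = if (tss > 0) 1 - rss / tss else NA_real_,
       n_used = sum(ok), n_dropped = sum(!ok))
}
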