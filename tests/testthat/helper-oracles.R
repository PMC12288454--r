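# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths for the quantity they check.

# exhaustive suboptimal-path enumeration: every simple source->sink path via
# igraph::all_simple_paths, filtered at L_opt + delta
oracle_suboptimal_paths <- function(net, sources, sinks, delta) {
  g <- igraph::graph_from_data_frame(
    data.frame(from = as.character(net$edges$i),
               to = as.character(net$edges$j)),
    directed = FALSE,
    vertices = data.frame(name = as.character(net$nodes$id)))
  igraph::E(g)$weight <- net$edges$weight
  wlook <- new.env(parent = emptyenv())
  for (e in seq_len(nrow(net$edges))) {
    key <- paste(sort(c(net$edges$i[e], net$edges$j[e])), collapse = "-")
    assign(key, net$edges$weight[e], envir = wlook)
  }
  path_weight <- function(p) {
    s <- 0
    for (k in seq_len(length(p) - 1))
      s <- s + get(paste(sort(c(p[k], p[k + 1])), collapse = "-"),
                   envir = wlook)
    s
  }
  d <- igraph::distances(g, v = as.character(sources),
                         to = as.character(sinks),
                         weights = igraph::E(g)$weight)
  L_opt <- min(d)
  all_paths <- list()
  for (s in sources) {
    ps <- igraph::all_simple_paths(g, from = as.character(s),
                                   to = as.character(sinks))
    for (p in ps) {
      ids <- as.integer(names(p))
      all_paths[[length(all_paths) + 1L]] <-
        list(nodes = ids, weight = path_weight(ids))
    }
  }
  keep <- vapply(all_paths, function(p) p$weight <= L_opt + delta + 1e-9,
                 logical(1))
  list(paths = all_paths[keep], L_opt = L_opt)
}

# canonical string form of a path set, for set equality
path_set_key <- function(paths) {
  sort(vapply(paths, paste, "", collapse = "-"))
}

# random connected weighted graph as a DynamicalNetwork-shaped object
random_connected_net <- function(n, p = 0.3, seed = 1) {
  set.seed(seed)
  repeat {
    pairs <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
    keep <- stats::runif(nrow(pairs)) < p
    # always keep a spanning path so connectivity is likely
    edges <- rbind(cbind(1:(n - 1), 2:n), pairs[keep, , drop = FALSE])
    edges <- unique(edges)
    g <- igraph::graph_from_edgelist(edges, directed = FALSE)
    if (igraph::vcount(g) == n && igraph::is_connected(g)) break
  }
  w <- stats::runif(nrow(edges), 0.1, 2)
  structure(list(
    nodes = data.frame(id = seq_len(n), chain = "A", resid = seq_len(n),
                       domain_label = "x", stringsAsFactors = FALSE),
    edges = data.frame(i = edges[, 1], j = edges[, 2], weight = w,
                       occupancy = 1, c = exp(-w))),
    class = "DynamicalNetwork")
}

# grid-search oracle for binding fits: SSE minimum over a log-spaced K grid
# (and an n grid for the Hill model); returns the grid optimum and the grid
# spacing in log units
oracle_grid_binding <- function(x, y, model, protein_total = NULL,
                                k_range = NULL, n_k = 60, n_n = 25) {
  k_range <- k_range %||% c(min(x[x > 0]) / 4, max(x) * 4)
  k_grid <- exp(seq(log(k_range[1]), log(k_range[2]), length.out = n_k))
  if (model == "hill") {
    n_grid <- seq(0.5, 4, length.out = n_n)
    sse <- outer(k_grid, n_grid, Vectorize(function(K, n)
      sum((y - x^n / (K^n + x^n))^2)))
    best <- arrayInd(which.min(sse), dim(sse))
    list(K = k_grid[best[1]], n = n_grid[best[2]],
         log_step = diff(log(k_grid))[1])
  } else {
    sse <- vapply(k_grid, function(K)
      sum((y - allosterik::isotherm_model(protein_total, x, K))^2),
      numeric(1))
    list(K = k_grid[which.min(sse)], n = NA_real_,
         log_step = diff(log(k_grid))[1])
  }
}

# brute-force rigid superposition: minimum RMSD over a refined grid of
# z-y-z Euler rotations, centroids aligned
oracle_min_rmsd <- function(P, Q, levels = 4, n_grid = 12) {
  rot <- function(a, b, c) {
    Rz <- function(t) matrix(c(cos(t), sin(t), 0, -sin(t), cos(t), 0, 0, 0, 1), 3)
    Ry <- function(t) matrix(c(cos(t), 0, -sin(t), 0, 1, 0, sin(t), 0, cos(t)), 3)
    Rz(a) %*% Ry(b) %*% Rz(c)
  }
  Pc <- sweep(P, 2, colMeans(P))
  Qc <- sweep(Q, 2, colMeans(Q))
  center <- c(pi, pi / 2, pi)
  width <- c(2 * pi, pi, 2 * pi)
  best <- Inf
  for (lv in seq_len(levels)) {
    grids <- lapply(1:3, function(i)
      seq(center[i] - width[i] / 2, center[i] + width[i] / 2,
          length.out = n_grid))
    for (a in grids[[1]]) for (b in grids[[2]]) for (c in grids[[3]]) {
      R <- rot(a, b, c)
      r <- sqrt(mean(rowSums((Pc %*% t(R) - Qc)^2)))
      if (r < best) {
        best <- r
        center_new <- c(a, b, c)
      }
    }
    center <- center_new
    width <- width * 2.5 / n_grid
  }
  best
}

# small hand-built trajectory
make_traj <- function(coord_list, chain = "A") {
  n <- nrow(coord_list[[1]])
  atoms <- data.frame(serial = seq_len(n), atom_name = "CA",
                      residue_index = seq_len(n), residue_name = "ALA",
                      chain_id = chain, stringsAsFactors = FALSE)
  coords <- array(0, c(length(coord_list), n, 3))
  for (f in seq_along(coord_list)) coords[f, , ] <- coord_list[[f]]
  new_trajectory(atoms, coords)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# DBD x EO mean |C| of a correlation matrix given the residue domain labels
dbd_eo_block_mean <- function(C, labels) {
  dbd <- which(labels == "DBD")
  eo <- which(labels == "EO")
  mean(abs(C[dbd, eo]))
}
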