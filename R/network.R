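#' Build a correlation-weighted dynamical network
#'
#' Residues are nodes; an edge joins residues i and j when (a) their C-alpha
#' atoms are within `contact_cutoff` in at least `o_min` of frames, (b) they
#' are not sequence neighbours within a chain (unless `exclude_bonded =
#' FALSE`), and (c) `|C_ij| >= c_min`. Edge weights follow the standard
#' dynamical-network convention `w_ij = -ln|C_ij|` (natural log), so strong
#' correlation means short communication distance.
#'
#' @param traj a superposed [Trajectory] sharing residue ordering with `cm`.
#' @param cm a [dcc()] result on the same residues.
#' @param contact_cutoff C-alpha contact distance, Angstrom (default 8.0 —
#'   the heavy-atom 4.5 A criterion has no meaning on C-alpha-only models).
#' @param o_min minimum contact occupancy (fraction of frames, default 0.75).
#' @param c_min minimum `|C|` for an edge (default 0.01; avoids infinite
#'   weights).
#' @param exclude_bonded drop |i-j| == 1 pairs within a chain (default TRUE).
#' @return object of class `DynamicalNetwork`: list with `nodes` (id, chain,
#'   resid, domain_label) and `edges` (i, j, weight, occupancy, c).
#' @export
build_network <- function(traj, cm, contact_cutoff = 8.0, o_min = 0.75,
                          c_min = 0.01, exclude_bonded = TRUE) {
  assert_that(inherits(cm, "CorrelationMatrix"), "cm must be a CorrelationMatrix")
  n <- nrow(cm$C)
  assert_that(n_atoms(traj) == n,
              "trajectory and correlation matrix residue counts differ")
  nf <- n_frames(traj)
  occ <- matrix(0, n, n)
  for (f in seq_len(nf)) {
    d <- as.matrix(stats::dist(frame_coords(traj, f)))
    occ <- occ + (d <= contact_cutoff)
  }
  occ <- occ / nf
  pairs <- which(upper.tri(occ), arr.ind = TRUE)
  keep <- occ[pairs] >= o_min & abs(cm$C[pairs]) >= c_min
  if (exclude_bonded) {
    same_chain <- cm$residues$chain[pairs[, 1]] == cm$residues$chain[pairs[, 2]]
    adjacent <- abs(cm$residues$resid[pairs[, 1]] -
                    cm$residues$resid[pairs[, 2]]) == 1
    keep <- keep & !(same_chain & adjacent)
  }
  pairs <- pairs[keep, , drop = FALSE]
  if (nrow(pairs) == 0)
    stop("degenerate network: no residue pair satisfies the contact and ",
         "correlation thresholds", call. = FALSE)
  cvals <- cm$C[pairs]
  edges <- data.frame(i = pairs[, 1], j = pairs[, 2],
                      weight = -log(pmin(abs(cvals), 1)),
                      occupancy = occ[pairs], c = cvals)
  nodes <- data.frame(id = seq_len(n), chain = cm$residues$chain,
                      resid = cm$residues$resid,
                      domain_label = cm$residues$domain_label,
                      stringsAsFactors = FALSE)
  structure(list(nodes = nodes, edges = edges), class = "DynamicalNetwork")
}

#' @export
print.DynamicalNetwork <- function(x, ...) {
  cat("DynamicalNetwork:", nrow(x$nodes), "nodes,", nrow(x$edges), "edges\n")
  invisible(x)
}

# igraph view of a DynamicalNetwork; vertex names are node ids as characters
as_igraph <- function(net) {
  g <- igraph::graph_from_data_frame(
    data.frame(from = as.character(net$edges$i), to = as.character(net$edges$j)),
    directed = FALSE,
    vertices = data.frame(name = as.character(net$nodes$id)))
  igraph::E(g)$weight <- net$edges$weight
  g
}

#' Divisive community detection (Girvan-Newman)
#'
#' Repeatedly removes the edge of highest weighted edge betweenness (edge
#' weights treated as distances, floored at 1e-6) and scores every partition
#' level by weighted modularity Q computed on the *original* graph with edge
#' affinities `1/max(w, 1e-6)`. Returns the level maximizing Q. Betweenness
#' ties are broken deterministically by lexicographic (i, j) node order.
#'
#' @param net a [build_network()] result.
#' @return object of class `CommunityPartition`: `membership` (integer per
#'   node id), `n_communities`, `modularity`.
#' @export
detect_communities <- function(net) {
  assert_that(inherits(net, "DynamicalNetwork"),
              "net must be a DynamicalNetwork")
  w_floor <- pmax(net$edges$weight, 1e-6)
  affinity <- 1 / w_floor
  g0 <- as_igraph(net)
  igraph::E(g0)$affinity <- affinity
  g <- g0
  igraph::E(g)$dist <- w_floor
  score <- function(graph) {
    memb <- igraph::components(graph)$membership
    memb <- memb[as.character(net$nodes$id)]
    list(memb = memb,
         q = igraph::modularity(g0, memb, weights = igraph::E(g0)$affinity))
  }
  best <- score(g)
  n_comp <- max(best$memb)
  while (igraph::ecount(g) > 0) {
    eb <- igraph::edge_betweenness(g, weights = igraph::E(g)$dist)
    top <- which(eb == max(eb))
    if (length(top) > 1) {
      ends <- igraph::ends(g, igraph::E(g)[top])
      a <- as.integer(ends[, 1]); b <- as.integer(ends[, 2])
      key_i <- pmin(a, b); key_j <- pmax(a, b)
      top <- top[order(key_i, key_j)][1]
    }
    g <- igraph::delete_edges(g, igraph::E(g)[top])
    comp <- igraph::components(g)$no
    if (comp > n_comp) {
      n_comp <- comp
      cand <- score(g)
      if (cand$q > best$q + 1e-12) best <- cand
    }
  }
  memb <- best$memb
  # relabel communities 1..k in order of first appearance
  memb <- as.integer(factor(memb, levels = unique(memb)))
  names(memb) <- as.character(net$nodes$id)
  structure(list(membership = memb, n_communities = max(memb),
                 modularity = best$q),
            class = "CommunityPartition")
}

#' @export
print.CommunityPartition <- function(x, ...) {
  cat("CommunityPartition:", x$n_communities, "communities, Q =",
      round(x$modularity, 4), "\n")
  invisible(x)
}

#' Enumerate optimal and suboptimal communication paths
#'
#' Finds every simple path from any source to any sink whose total weight is
#' within `delta` of the globally optimal source-sink weight `L_opt`
#' (Dijkstra). Enumeration is depth-first branch-and-bound: a partial path
#' is pruned when its weight plus the exact remaining shortest distance to
#' the nearest sink exceeds `L_opt + delta`. Results are capped at
#' `max_paths` with an explicit truncation flag, never silently.
#'
#' @param net a [build_network()] result.
#' @param sources,sinks node ids; defaults are all DBD-labelled residues
#'   (sources) and all EO-labelled residues (sinks), aggregated over both
#'   monomers. `representative = TRUE` keeps only the central residue of
#'   each domain per chain.
#' @param delta suboptimality tolerance in weight units; default
#'   `0.2 * L_opt`.
#' @param max_paths safety cap (default 100000).
#' @param representative single-representative source/sink mode.
#' @return object of class `PathEnsemble`: `paths` (list of node-id integer
#'   vectors, weight-sorted), `weights`, `L_opt`, `delta`, `truncated`,
#'   `histogram` (breaks with origin at `L_opt`, width `(max - L_opt)/20`,
#'   and counts).
#' @export
suboptimal_paths <- function(net, sources = NULL, sinks = NULL, delta = NULL,
                             max_paths = 100000L, representative = FALSE) {
  assert_that(inherits(net, "DynamicalNetwork"),
              "net must be a DynamicalNetwork")
  pick <- function(label) {
    idx <- which(net$nodes$domain_label %in% label)
    if (!representative) return(net$nodes$id[idx])
    unname(vapply(split(net$nodes$id[idx], net$nodes$chain[idx]),
                  function(v) v[ceiling(length(v) / 2)], integer(1)))
  }
  sources <- sources %||% pick("DBD")
  sinks <- sinks %||% pick("EO")
  assert_that(length(sources) > 0 && length(sinks) > 0,
              "sources and sinks must be non-empty")
  assert_that(length(intersect(sources, sinks)) == 0,
              "sources and sinks must be disjoint")
  if (!is.null(delta)) assert_that(delta >= 0, "delta must be >= 0")

  g <- as_igraph(net)
  dmat <- igraph::distances(g, v = as.character(net$nodes$id),
                            to = as.character(sinks),
                            weights = igraph::E(g)$weight)
  d_sink <- apply(dmat, 1, min)
  names(d_sink) <- net$nodes$id
  L_opt <- min(d_sink[as.character(sources)])
  if (!is.finite(L_opt))
    stop("no path: no source is connected to any sink", call. = FALSE)
  delta <- delta %||% (0.2 * L_opt)
  bound <- L_opt + delta + 1e-9

  n <- nrow(net$nodes)
  adj <- vector("list", n)
  for (e in seq_len(nrow(net$edges))) {
    i <- net$edges$i[e]; j <- net$edges$j[e]; w <- net$edges$weight[e]
    adj[[i]] <- rbind(adj[[i]], c(j, w))
    adj[[j]] <- rbind(adj[[j]], c(i, w))
  }
  ds <- unname(d_sink[as.character(seq_len(n))])
  # visit promising neighbours first: cheaper pruning, near-sorted output
  for (v in seq_len(n)) if (!is.null(adj[[v]])) {
    ord <- order(adj[[v]][, 2] + ds[adj[[v]][, 1]])
    adj[[v]] <- adj[[v]][ord, , drop = FALSE]
  }
  is_sink <- rep(FALSE, n); is_sink[sinks] <- TRUE

  env <- new.env(parent = emptyenv())
  env$paths <- vector("list", 1024L)
  env$weights <- numeric(1024L)
  env$np <- 0L
  env$truncated <- FALSE
  visited <- rep(FALSE, n)
  path <- integer(n)

  record <- function(depth, wsum) {
    if (env$np >= max_paths) {
      env$truncated <- TRUE
      return(FALSE)
    }
    env$np <- env$np + 1L
    if (env$np > length(env$paths)) {
      env$paths <- c(env$paths, vector("list", length(env$paths)))
      env$weights <- c(env$weights, numeric(length(env$weights)))
    }
    env$paths[[env$np]] <- path[seq_len(depth)]
    env$weights[env$np] <- wsum
    TRUE
  }

  dfs <- function(v, depth, wsum) {
    if (env$truncated) return(invisible(NULL))
    path[depth] <<- v
    visited[v] <<- TRUE
    if (is_sink[v]) {
      if (!record(depth, wsum)) {
        visited[v] <<- FALSE
        return(invisible(NULL))
      }
    }
    nb <- adj[[v]]
    if (!is.null(nb)) {
      for (r in seq_len(nrow(nb))) {
        u <- nb[r, 1]
        if (visited[u]) next
        w2 <- wsum + nb[r, 2]
        if (w2 + ds[u] > bound) next
        dfs(u, depth + 1L, w2)
        if (env$truncated) break
      }
    }
    visited[v] <<- FALSE
    invisible(NULL)
  }

  for (s in sources) {
    if (!is.finite(ds[s]) || ds[s] > bound) next
    dfs(s, 1L, 0)
    if (env$truncated) break
  }

  np <- env$np
  weights <- env$weights[seq_len(np)]
  paths <- env$paths[seq_len(np)]
  ord <- order(weights)
  weights <- weights[ord]
  paths <- paths[ord]

  wmax <- if (np > 0) max(weights) else L_opt
  if (wmax > L_opt) {
    breaks <- L_opt + (0:20) * (wmax - L_opt) / 20
    counts <- graphics::hist(weights, breaks = breaks, plot = FALSE,
                             include.lowest = TRUE, right = TRUE)$counts
  } else {
    breaks <- c(L_opt, L_opt)
    counts <- np
  }
  structure(
    list(paths = paths, weights = weights, L_opt = L_opt, delta = delta,
         truncated = env$truncated, sources = sources, sinks = sinks,
         histogram = list(breaks = breaks, counts = counts)),
    class = "PathEnsemble"
  )
}

#' @export
print.PathEnsemble <- function(x, ...) {
  cat("PathEnsemble:", length(x$paths), "paths, L_opt =",
      round(x$L_opt, 4), ", delta =", round(x$delta, 4),
      if (x$truncated) "(TRUNCATED at cap)" else "", "\n")
  invisible(x)
}

#' Compare path ensembles across states and variants
#'
#' Summarizes each ensemble (path count, optimal weight, mean and median
#' path length) and classifies every ordered pair as right-/left-shifted by
#' the difference of median path lengths: positive beyond `tol` means the
#' second ensemble's communication paths are longer (delayed signalling),
#' negative means shorter (faster communication). States are ranked by path
#' count.
#'
#' @param ensembles named list of [suboptimal_paths()] results (>= 2).
#' @param tol median-difference tolerance for calling a shift.
#' @return list with `summary`, `pairwise` and `ranking` data.frames.
#' @export
path_statistics <- function(ensembles, tol = 1e-6) {
  assert_that(is.list(ensembles) && length(ensembles) >= 2,
              "need at least two ensembles")
  assert_that(!is.null(names(ensembles)) && all(nzchar(names(ensembles))),
              "ensembles must be named")
  summ <- do.call(rbind, lapply(names(ensembles), function(nm) {
    e <- ensembles[[nm]]
    data.frame(name = nm, n_paths = length(e$paths), L_opt = e$L_opt,
               mean_length = if (length(e$weights)) mean(e$weights) else NA_real_,
               median_length = if (length(e$weights)) stats::median(e$weights) else NA_real_,
               truncated = e$truncated, stringsAsFactors = FALSE)
  }))
  nm <- summ$name
  pairs <- expand.grid(a = nm, b = nm, stringsAsFactors = FALSE)
  pairs <- pairs[pairs$a != pairs$b, ]
  pairs$median_diff <- summ$median_length[match(pairs$b, nm)] -
    summ$median_length[match(pairs$a, nm)]
  pairs$shift <- ifelse(pairs$median_diff > tol, "right",
                        ifelse(pairs$median_diff < -tol, "left", "none"))
  ranking <- summ[order(-summ$n_paths, summ$name), c("name", "n_paths")]
  ranking$rank <- seq_len(nrow(ranking))
  list(summary = summ, pairwise = pairs, ranking = ranking)
}

#' Write network and path outputs
#'
#' `write_network_tsv` writes the edge list (i, j, weight, occupancy, c);
#' `write_network_graphml` exports via igraph; `write_paths_tsv` writes
#' (rank, weight, node id sequence).
#'
#' @param net a [build_network()] result.
#' @param path output file.
#' @export
write_network_tsv <- function(net, path) {
  utils::write.table(net$edges, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' @rdname write_network_tsv
#' @export
write_network_graphml <- function(net, path) {
  g <- as_igraph(net)
  igraph::E(g)$occupancy <- net$edges$occupancy
  igraph::E(g)$c <- net$edges$c
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}

#' @rdname write_network_tsv
#' @param ensemble a [suboptimal_paths()] result.
#' @export
write_paths_tsv <- function(ensemble, path) {
  df <- data.frame(rank = seq_along(ensemble$paths),
                   weight = ensemble$weights,
                   nodes = vapply(ensemble$paths, paste, "", collapse = "-"))
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
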