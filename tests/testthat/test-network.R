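# dynamical network construction, community detection, suboptimal paths

make_net <- function(edges, n = max(c(edges$i, edges$j)), labels = "x") {
  structure(list(
    nodes = data.frame(id = seq_len(n), chain = "A", resid = seq_len(n),
                       domain_label = rep_len(labels, n),
                       stringsAsFactors = FALSE),
    edges = edges), class = "DynamicalNetwork")
}

test_that("network edges obey the contact-occupancy and weight conventions", {
  # 2-state toy: residues 1-2 always 4 A apart and co-moving (|C| = 1);
  # residue 3 swings between 7 and 12 A from residue 2, so their contact
  # occupancy is exactly 0.5 at an 8 A cutoff
  frame <- function(y3, dy) rbind(c(0, dy, 0), c(4, dy, 0), c(4, y3, 0))
  tr <- make_traj(list(frame(7, 0.5), frame(12, -0.5),
                       frame(7, 0.5), frame(12, -0.5)))
  cm <- dcc(tr)
  expect_equal(cm$C[1, 2], 1, tolerance = 1e-12)
  expect_equal(cm$C[2, 3], -1, tolerance = 1e-12)
  has_edge <- function(net, i, j)
    any((net$edges$i == i & net$edges$j == j) |
        (net$edges$i == j & net$edges$j == i))
  strict <- build_network(tr, cm, contact_cutoff = 8, o_min = 0.75,
                          c_min = 0.01, exclude_bonded = FALSE)
  expect_true(has_edge(strict, 1, 2))
  expect_false(has_edge(strict, 2, 3))   # 50% occupancy < 75%
  expect_false(has_edge(strict, 1, 3))   # 50% occupancy < 75%
  loose <- build_network(tr, cm, contact_cutoff = 8, o_min = 0.5,
                         c_min = 0.01, exclude_bonded = FALSE)
  expect_true(has_edge(loose, 2, 3))
  # w = -ln|C|, checked against the stored correlation; |C| = 1 gives w = 0
  expect_equal(loose$edges$weight, -log(pmin(abs(loose$edges$c), 1)),
               tolerance = 1e-12)
  expect_equal(loose$edges$weight[loose$edges$i == 1 & loose$edges$j == 2], 0)
  expect_equal(-log(0.5), 0.6931472, tolerance = 1e-6)
  # degenerate thresholds give an explicit error
  expect_error(build_network(tr, cm, contact_cutoff = 1), "degenerate network")
})

test_that("Girvan-Newman splits two cliques across their bridge", {
  clique <- function(off) t(utils::combn(off + 1:4, 2))
  ee <- rbind(clique(0), clique(4), c(4, 5))
  net <- make_net(data.frame(i = ee[, 1], j = ee[, 2], weight = 1,
                             occupancy = 1, c = exp(-1)))
  cp <- detect_communities(net)
  expect_equal(cp$n_communities, 2)
  m <- cp$membership
  expect_equal(length(unique(m[as.character(1:4)])), 1)
  expect_equal(length(unique(m[as.character(5:8)])), 1)
  expect_false(m[["4"]] == m[["5"]])
  # the returned partition's modularity is at least that of the planted one
  g <- igraph::graph_from_data_frame(
    data.frame(from = ee[, 1], to = ee[, 2]), directed = FALSE,
    vertices = data.frame(name = 1:8))
  planted_q <- igraph::modularity(g, rep(1:2, each = 4))
  expect_gte(cp$modularity, planted_q - 1e-9)

  # a uniform complete graph has no community structure
  k5 <- t(utils::combn(1:5, 2))
  net5 <- make_net(data.frame(i = k5[, 1], j = k5[, 2], weight = 1,
                              occupancy = 1, c = exp(-1)))
  cp5 <- detect_communities(net5)
  expect_equal(cp5$n_communities, 1)

  # partition covers all nodes
  expect_setequal(names(cp$membership), as.character(1:8))
})

test_that("community memberships are invariant to node relabeling", {
  net <- random_connected_net(10, p = 0.35, seed = 4)
  cp1 <- detect_communities(net)
  # reverse node order (ids and all edge endpoints remapped)
  perm <- rev(seq_len(10))
  net2 <- net
  net2$edges$i <- perm[net$edges$i]
  net2$edges$j <- perm[net$edges$j]
  cp2 <- detect_communities(net2)
  m1 <- cp1$membership[as.character(1:10)]
  m2 <- cp2$membership[as.character(perm[1:10])]
  # same partition up to a bijection of community ids
  expect_equal(length(unique(paste(m1, m2))),
               length(unique(m1)))
  expect_equal(cp1$n_communities, cp2$n_communities)
})

test_that("suboptimal paths reproduce the worked diamond example", {
  edges <- data.frame(i = c(1, 2, 1, 3, 1), j = c(2, 4, 3, 4, 4),
                      weight = c(1, 1, 1.5, 1, 3), occupancy = 1,
                      c = exp(-c(1, 1, 1.5, 1, 3)))
  net <- make_net(edges)
  e0 <- suboptimal_paths(net, sources = 1, sinks = 4, delta = 0)
  expect_equal(length(e0$paths), 1)
  expect_equal(e0$paths[[1]], c(1L, 2L, 4L))
  expect_equal(e0$L_opt, 2)
  e05 <- suboptimal_paths(net, sources = 1, sinks = 4, delta = 0.5)
  expect_equal(length(e05$paths), 2)
  expect_equal(e05$weights, c(2, 2.5))
  e1 <- suboptimal_paths(net, sources = 1, sinks = 4, delta = 1)
  expect_equal(length(e1$paths), 3)

  # single edge source-sink
  single <- make_net(data.frame(i = 1, j = 2, weight = 0.4, occupancy = 1,
                                c = exp(-0.4)))
  es <- suboptimal_paths(single, sources = 1, sinks = 2, delta = 100)
  expect_equal(length(es$paths), 1)

  # disconnected query errors
  two <- make_net(data.frame(i = 1, j = 2, weight = 1, occupancy = 1,
                             c = exp(-1)), n = 3)
  expect_error(suboptimal_paths(two, sources = 1, sinks = 3), "no path")
  expect_error(suboptimal_paths(net, sources = 1, sinks = 1), "disjoint")
})

test_that("path enumeration matches exhaustive search on random graphs", {
  for (seed in 1:12) {
    n <- sample(5:10, 1)
    net <- random_connected_net(n, p = 0.35, seed = seed)
    sources <- 1L
    sinks <- c(n - 1L, n)
    for (delta_kind in c("zero", "frac", "all")) {
      probe <- suboptimal_paths(net, sources, sinks, delta = 0)
      delta <- switch(delta_kind, zero = 0, frac = 0.4 * probe$L_opt,
                      all = 1e6)
      mine <- suboptimal_paths(net, sources, sinks, delta = delta)
      oracle <- oracle_suboptimal_paths(net, sources, sinks, delta)
      expect_equal(mine$L_opt, oracle$L_opt, tolerance = 1e-9)
      expect_identical(path_set_key(mine$paths),
                       path_set_key(lapply(oracle$paths, `[[`, "nodes")))
      # stored weights re-sum correctly
      for (k in seq_along(mine$paths)) {
        p <- mine$paths[[k]]
        w <- 0
        for (s in seq_len(length(p) - 1)) {
          hit <- which((net$edges$i == p[s] & net$edges$j == p[s + 1]) |
                       (net$edges$j == p[s] & net$edges$i == p[s + 1]))
          w <- w + net$edges$weight[hit]
        }
        expect_equal(w, mine$weights[k], tolerance = 1e-9)
      }
    }
  }
})

test_that("path counts grow with delta and the cap is flagged, not silent", {
  net <- random_connected_net(9, p = 0.5, seed = 3)
  counts <- vapply(c(0, 0.3, 0.8, 2), function(d)
    length(suboptimal_paths(net, 1, 9, delta = d)$paths), numeric(1))
  expect_true(all(diff(counts) >= 0))

  capped <- suboptimal_paths(net, 1, 9, delta = 1e6, max_paths = 3)
  expect_true(capped$truncated)
  expect_lte(length(capped$paths), 3)
  full <- suboptimal_paths(net, 1, 9, delta = 1e6, max_paths = 1e5)
  expect_false(full$truncated)
})

test_that("path statistics classify shifted ensembles and rank by count", {
  edges <- data.frame(i = c(1, 2, 1, 3), j = c(2, 4, 3, 4),
                      weight = c(1, 1, 1.1, 1.1), occupancy = 1,
                      c = exp(-1))
  net_a <- make_net(edges)
  e_a <- suboptimal_paths(net_a, 1, 4, delta = 1)
  edges_b <- edges
  edges_b$weight <- edges_b$weight + 0.5
  e_b <- suboptimal_paths(make_net(edges_b), 1, 4, delta = 1)
  st <- path_statistics(list(A = e_a, B = e_b, A2 = e_a))
  pw <- st$pairwise
  expect_equal(pw$shift[pw$a == "A" & pw$b == "B"], "right")
  expect_equal(pw$shift[pw$a == "B" & pw$b == "A"], "left")
  expect_equal(pw$shift[pw$a == "A" & pw$b == "A2"], "none")
  expect_equal(st$summary$n_paths[st$summary$name == "A"],
               st$summary$n_paths[st$summary$name == "A2"])
  expect_equal(nrow(st$ranking), 3)
})
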