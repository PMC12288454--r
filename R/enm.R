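#' Specification of an elastic-network Gaussian trajectory
#'
#' The synthetic stand-in for an MD production run. An anisotropic elastic
#' network (Hookean springs between all C-alpha pairs within
#' `contact_cutoff`, plus any planted `extra_couplings`) defines a 3N x 3N
#' Hessian; C-alpha displacements are drawn from the zero-mean multivariate
#' normal whose covariance is `temperature_scale` times the Hessian
#' pseudo-inverse (rigid-body modes removed). Because the second moments are
#' known exactly, every downstream statistic (RMSF, DCC, PCA eigenvalues)
#' has an analytic oracle.
#'
#' @param spec a [toy_dimer_spec()].
#' @param contact_cutoff spring cutoff between C-alpha beads, Angstrom.
#' @param spring_constant uniform network spring constant (energy/A^2 in
#'   reduced units).
#' @param extra_couplings NULL or data.frame (res_i, res_j, k) of planted
#'   springs; residue indices are global (1..2n over chains A then B).
#' @param n_frames number of frames to sample (>= 10).
#' @param temperature_scale variance scale (A^2); 0 freezes the structure.
#' @param state_label one of "APO", "E", "D", "ED".
#' @param seed integer RNG seed; sampling is bit-reproducible.
#' @return object of class `ENMTrajectorySpec`.
#' @export
enm_trajectory_spec <- function(spec,
                                contact_cutoff = 7,
                                spring_constant = 1,
                                extra_couplings = NULL,
                                n_frames = 1000L,
                                temperature_scale = 1,
                                state_label = c("APO", "E", "D", "ED"),
                                seed = 1L) {
  assert_that(inherits(spec, "ToyDimerSpec"), "spec must be a ToyDimerSpec")
  assert_that(contact_cutoff > 0, "contact_cutoff must be > 0")
  assert_that(spring_constant > 0, "spring_constant must be > 0")
  assert_that(n_frames >= 10, "n_frames must be >= 10")
  assert_that(temperature_scale >= 0, "temperature_scale must be >= 0")
  state_label <- match.arg(state_label)
  if (!is.null(extra_couplings)) {
    assert_that(all(c("res_i", "res_j", "k") %in% names(extra_couplings)),
                "extra_couplings needs columns res_i, res_j, k")
    n_tot <- 2L * spec$residues_per_monomer
    assert_that(all(extra_couplings$res_i >= 1 & extra_couplings$res_i <= n_tot &
                    extra_couplings$res_j >= 1 & extra_couplings$res_j <= n_tot),
                "extra_couplings residue indices out of range")
    assert_that(all(extra_couplings$res_i != extra_couplings$res_j),
                "extra_couplings must join distinct residues")
    assert_that(all(extra_couplings$k > 0), "planted spring constants must be > 0")
  }
  structure(
    list(spec = spec, contact_cutoff = contact_cutoff,
         spring_constant = spring_constant, extra_couplings = extra_couplings,
         n_frames = as.integer(n_frames), temperature_scale = temperature_scale,
         state_label = state_label, seed = as.integer(seed)),
    class = "ENMTrajectorySpec"
  )
}

# anisotropic-network Hessian: off-diagonal 3x3 block for a spring (i, j) is
# -k/d^2 * (r_ij r_ij^T); diagonal blocks make rows sum to zero.
enm_hessian <- function(coords, contact_cutoff, spring_constant,
                        extra_couplings = NULL) {
  n <- nrow(coords)
  d <- as.matrix(stats::dist(coords))
  contact <- d <= contact_cutoff & upper.tri(d)
  pairs <- which(contact, arr.ind = TRUE)
  kvec <- rep(spring_constant, nrow(pairs))
  if (!is.null(extra_couplings) && nrow(extra_couplings) > 0) {
    ij <- cbind(pmin(extra_couplings$res_i, extra_couplings$res_j),
                pmax(extra_couplings$res_i, extra_couplings$res_j))
    pairs <- rbind(unname(pairs), unname(ij))
    kvec <- c(kvec, extra_couplings$k)
  }
  # connectivity check before building blocks
  g <- igraph::graph_from_edgelist(pairs, directed = FALSE)
  g <- igraph::add_vertices(g, max(0, n - igraph::vcount(g)))
  comp <- igraph::components(g)
  if (comp$no > 1) {
    main <- which.max(comp$csize)
    isolated <- which(comp$membership != main)
    stop("degenerate elastic network: residues not connected to the main ",
         "component: ", paste(isolated, collapse = ", "), call. = FALSE)
  }
  H <- matrix(0, 3 * n, 3 * n)
  for (e in seq_len(nrow(pairs))) {
    i <- pairs[e, 1]; j <- pairs[e, 2]
    rij <- coords[j, ] - coords[i, ]
    d2 <- sum(rij^2)
    blk <- -(kvec[e] / d2) * tcrossprod(rij)
    ii <- (3 * i - 2):(3 * i); jj <- (3 * j - 2):(3 * j)
    H[ii, jj] <- H[ii, jj] + blk
    H[jj, ii] <- H[jj, ii] + blk
    H[ii, ii] <- H[ii, ii] - blk
    H[jj, jj] <- H[jj, jj] - blk
  }
  H
}

# pseudo-inverse covariance: drop modes with eigenvalue < tol * max eigenvalue
# (the six rigid-body modes of a connected 3D network)
enm_covariance <- function(H, temperature_scale, tol = 1e-8) {
  eig <- eigen(H, symmetric = TRUE)
  lam <- eig$values
  zero <- lam < tol * max(lam)
  n_zero <- sum(zero)
  if (n_zero != 6)
    stop("degenerate elastic network: expected 6 zero modes, found ", n_zero,
         call. = FALSE)
  keep <- !zero
  V <- eig$vectors[, keep, drop = FALSE]
  lam_k <- lam[keep]
  cov <- temperature_scale * (V %*% (t(V) / lam_k))
  list(cov = (cov + t(cov)) / 2, modes = V, lambda = lam_k)
}

#' Sample a Gaussian elastic-network trajectory
#'
#' @param espec an [enm_trajectory_spec()].
#' @return list with elements `trajectory` (a [Trajectory]), `covariance`
#'   (the exact 3N x 3N displacement covariance used for sampling, Angstrom^2),
#'   `structure` (the reference [generate_toy_dimer()] model) and `spec`.
#' @export
sample_enm_trajectory <- function(espec) {
  assert_that(inherits(espec, "ENMTrajectorySpec"),
              "espec must be an ENMTrajectorySpec")
  ref <- generate_toy_dimer(espec$spec)
  n <- nrow(ref$coords)
  H <- enm_hessian(ref$coords, espec$contact_cutoff, espec$spring_constant,
                   espec$extra_couplings)
  cv <- enm_covariance(H, espec$temperature_scale)
  nf <- espec$n_frames
  coords <- array(0, dim = c(nf, n, 3))
  if (espec$temperature_scale > 0) {
    set.seed(espec$seed)
    m <- ncol(cv$modes)
    z <- matrix(stats::rnorm(nf * m), nf, m)
    scale <- sqrt(espec$temperature_scale / cv$lambda)
    disp <- z %*% (t(cv$modes) * scale)  # nf x 3n
  } else {
    disp <- matrix(0, nf, 3 * n)
  }
  base <- as.vector(t(ref$coords))      # x1 y1 z1 x2 ...
  for (f in seq_len(nf))
    coords[f, , ] <- matrix(base + disp[f, ], ncol = 3, byrow = TRUE)
  traj <- new_trajectory(ref$atoms, coords)
  list(trajectory = traj, covariance = cv$cov, structure = ref, spec = espec)
}

#' Residue cross-correlations implied by a displacement covariance
#'
#' Collapses a 3N x 3N Cartesian covariance to the n x n matrix of
#' normalized residue displacement correlations
#' `tr(Cov_ij) / sqrt(tr(Cov_ii) tr(Cov_jj))` — the analytic counterpart of
#' the trajectory-derived dynamic cross-correlation map, used as its oracle.
#'
#' @param covariance 3N x 3N matrix.
#' @return n x n correlation matrix.
#' @export
dcc_from_covariance <- function(covariance) {
  n3 <- nrow(covariance)
  assert_that(n3 %% 3 == 0, "covariance dimension must be a multiple of 3")
  n <- n3 %/% 3
  num <- matrix(0, n, n)
  for (a in 1:3) {
    idx <- seq(a, n3, by = 3)
    num <- num + covariance[idx, idx]
  }
  v <- diag(num)
  num / sqrt(outer(v, v))
}

# central `size` residues of a domain within one chain, as global atom indices
domain_center_patch <- function(structure, chain, domain, size) {
  idx <- which(structure$atoms$chain_id == chain &
               structure$atoms$domain_label == domain)
  size <- min(size, length(idx))
  mid <- ceiling(length(idx) / 2)
  lo <- max(1L, mid - (size - 1L) %/% 2L)
  idx[lo:min(length(idx), lo + size - 1L)]
}

#' Default per-state planted couplings
#'
#' Encodes, as planted springs, how each ligand constrains the dimer. The
#' effector (E) rigidifies the dimer core: springs between all pairs of the
#' central `pocket_size` residues of the two EO domains (the binding pockets
#' sit at the oligomerization interface). Operator DNA (D) clamps the two
#' DNA-binding domains together: springs between the central `clamp_size`
#' residues of each DBD, emulating both recognition helices engaging one
#' operator duplex. ED engages both sets; APO carries no planted springs.
#' Constraining these third bodies is what raises coherent DBD-EO co-motion
#' in the sampled trajectories: in a mode-projected Gaussian network, a
#' spring placed directly between two domains suppresses exactly the hinge
#' modes that correlate them, so ligand couplings act at the ligand sites.
#'
#' @param structure a [generate_toy_dimer()] model.
#' @param state one of "APO", "E", "D", "ED".
#' @param effector_k,dna_k spring constants of the planted springs.
#' @param pocket_size,clamp_size residues per monomer anchoring each spring
#'   set.
#' @return data.frame (res_i, res_j, k), possibly empty.
#' @export
state_couplings <- function(structure, state = c("APO", "E", "D", "ED"),
                            effector_k = 5, dna_k = 5, pocket_size = 7L,
                            clamp_size = 2L) {
  state <- match.arg(state)
  pocket_a <- domain_center_patch(structure, "A", "EO", pocket_size)
  pocket_b <- domain_center_patch(structure, "B", "EO", pocket_size)
  clamp_a <- domain_center_patch(structure, "A", "DBD", clamp_size)
  clamp_b <- domain_center_patch(structure, "B", "DBD", clamp_size)
  eff <- expand.grid(res_i = pocket_a, res_j = pocket_b,
                     KEEP.OUT.ATTRS = FALSE)
  eff$k <- effector_k
  dna <- expand.grid(res_i = clamp_a, res_j = clamp_b, KEEP.OUT.ATTRS = FALSE)
  dna$k <- dna_k
  switch(state,
         APO = eff[0, ],
         E = eff,
         D = dna,
         ED = rbind(eff, dna))
}

#' Generate the four-state trajectory suite for one variant
#'
#' Produces exactly four trajectories (APO, E-bound, D-bound, ED-bound) from
#' a single base specification, differing only in their planted couplings
#' per [state_couplings()] and in a deterministic per-state sub-seed.
#' Variant effects are modelled as scale factors on the planted springs:
#' a variant with a blunted effector response engages the effector springs
#' weakly (`effector_scale < 1`), one with weakened operator binding
#' engages the DNA clamp weakly (`dna_scale < 1`).
#'
#' @param base an [enm_trajectory_spec()] (its `extra_couplings` are kept and
#'   the per-state springs appended; its `state_label` is overridden).
#' @param effector_scale,dna_scale multipliers on the planted spring
#'   constants (> 0, or 0 to remove that spring class).
#' @param effector_k,dna_k base spring constants, see [state_couplings()].
#' @return named list APO/E/D/ED of [sample_enm_trajectory()] results.
#' @export
generate_state_suite <- function(base, effector_scale = 1, dna_scale = 1,
                                 effector_k = 5, dna_k = 5) {
  assert_that(inherits(base, "ENMTrajectorySpec"),
              "base must be an ENMTrajectorySpec")
  ref <- generate_toy_dimer(base$spec)
  states <- c("APO", "E", "D", "ED")
  out <- vector("list", 4L)
  names(out) <- states
  for (s in seq_along(states)) {
    planted <- state_couplings(ref, states[s],
                               effector_k = effector_k * effector_scale,
                               dna_k = dna_k * dna_scale)
    planted <- planted[planted$k > 0, , drop = FALSE]
    espec <- base
    espec$state_label <- states[s]
    espec$extra_couplings <- rbind(base$extra_couplings, planted)
    if (!is.null(espec$extra_couplings) && nrow(espec$extra_couplings) == 0)
      espec$extra_couplings <- NULL
    espec$seed <- derive_seed(base$seed, s - 1L)
    out[[s]] <- sample_enm_trajectory(espec)
  }
  out
}
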