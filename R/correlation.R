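#' Dynamic cross-correlation map
#'
#' Computes the matrix of normalized displacement correlations between
#' C-alpha atoms over a superposed trajectory,
#' `C_ij = <dr_i . dr_j> / sqrt(<|dr_i|^2> <|dr_j|^2>)` with
#' `dr_i = r_i - <r_i>` (full 3D dot products per atom, not per coordinate).
#' Atoms with zero positional variance get `C_ii = 1` and zero off-diagonals
#' by convention, and are flagged.
#'
#' @param traj a superposed [Trajectory].
#' @param selection integer atom indices (default: all).
#' @return object of class `CorrelationMatrix`: list with `residues`
#'   (chain, resid, domain_label), `C` (n x n), and `zero_variance` (integer
#'   indices, possibly empty).
#' @export
dcc <- function(traj, selection = NULL) {
  assert_that(inherits(traj, "Trajectory"), "traj must be a Trajectory")
  if (n_frames(traj) < 2)
    stop("insufficient frames: dynamic cross-correlation needs >= 2 frames",
         call. = FALSE)
  sel <- selection %||% seq_len(n_atoms(traj))
  nf <- n_frames(traj)
  num <- 0
  for (a in 1:3) {
    D <- traj$coords[, sel, a, drop = TRUE]
    if (is.null(dim(D))) D <- matrix(D, ncol = length(sel))
    D <- sweep(D, 2, colMeans(D))
    num <- num + crossprod(D) / nf
  }
  v <- diag(num)
  zero <- which(v < .Machine$double.eps * max(v, 1))
  v_safe <- v
  v_safe[zero] <- 1
  C <- num / sqrt(outer(v_safe, v_safe))
  if (length(zero)) {
    C[zero, ] <- 0
    C[, zero] <- 0
  }
  diag(C) <- 1
  C <- (C + t(C)) / 2
  structure(
    list(residues = data.frame(chain = traj$atoms$chain_id[sel],
                               resid = traj$atoms$residue_index[sel],
                               domain_label = traj$atoms$domain_label[sel],
                               stringsAsFactors = FALSE),
         C = C, zero_variance = zero),
    class = "CorrelationMatrix"
  )
}

#' @export
print.CorrelationMatrix <- function(x, ...) {
  cat("CorrelationMatrix:", nrow(x$C), "residues\n")
  invisible(x)
}

#' Inter-domain coupling summary
#'
#' Mean and maximum absolute correlation over every domain-pair block of the
#' map (diagonal entries excluded), split by monomer scope: all residue
#' pairs, pairs within the same chain, and pairs across chains. The
#' DBD x EO blocks quantify how strongly effector-site motions couple to the
#' DNA-binding domain — the allosteric signal the planted-spring fixtures
#' are designed to carry.
#'
#' @param cm a [dcc()] result.
#' @param domains character vector of per-residue labels; defaults to the
#'   `domain_label` column captured from the trajectory.
#' @return data.frame (domain_a, domain_b, scope, mean_abs_c, max_abs_c,
#'   n_pairs).
#' @export
interdomain_coupling <- function(cm, domains = NULL) {
  assert_that(inherits(cm, "CorrelationMatrix"), "cm must be a CorrelationMatrix")
  domains <- domains %||% cm$residues$domain_label
  bad <- which(is.na(domains) | domains == "")
  if (length(bad))
    stop("unlabeled residues: ",
         paste(utils::head(bad, 10), collapse = ", "),
         if (length(bad) > 10) " ..." else "", call. = FALSE)
  absC <- abs(cm$C)
  chain <- cm$residues$chain
  labs <- sort(unique(domains))
  rows <- list()
  for (a in seq_along(labs)) for (b in a:length(labs)) {
    ia <- which(domains == labs[a]); ib <- which(domains == labs[b])
    block <- absC[ia, ib, drop = FALSE]
    same <- outer(chain[ia], chain[ib], "==")
    selfpair <- outer(ia, ib, "==")
    for (scope in c("all", "intra_monomer", "inter_monomer")) {
      keep <- switch(scope, all = !selfpair,
                     intra_monomer = same & !selfpair,
                     inter_monomer = !same)
      vals <- block[keep]
      rows[[length(rows) + 1L]] <- data.frame(
        domain_a = labs[a], domain_b = labs[b], scope = scope,
        mean_abs_c = if (length(vals)) mean(vals) else NA_real_,
        max_abs_c = if (length(vals)) max(vals) else NA_real_,
        n_pairs = length(vals), stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Essential dynamics (PCA of the coordinate covariance)
#'
#' Eigendecomposition of the 3N x 3N covariance of superposed coordinates.
#' Eigenvector signs are fixed by convention (the largest-magnitude
#' component of each mode is made positive) so that downstream displacement
#' fields are reproducible.
#'
#' @param traj a superposed [Trajectory].
#' @param k number of modes to retain (projections and mode vectors).
#' @param selection integer atom indices (default: all).
#' @return object of class `EssentialModes`: `eigenvalues` (all 3N,
#'   descending, Angstrom^2), `modes` (3N x k orthonormal), `projections`
#'   (n_frames x k), `mean_structure` (n x 3), `atoms`.
#' @export
essential_dynamics <- function(traj, k = 5L, selection = NULL) {
  assert_that(inherits(traj, "Trajectory"), "traj must be a Trajectory")
  sel <- selection %||% seq_len(n_atoms(traj))
  n3 <- 3L * length(sel)
  assert_that(k >= 1 && k <= n3, "k must be between 1 and 3 * n_atoms")
  nf <- n_frames(traj)
  assert_that(nf >= k + 1, "need at least k + 1 frames")
  X <- matrix(0, nf, n3)
  for (f in seq_len(nf))
    X[f, ] <- as.vector(t(frame_coords(traj, f)[sel, , drop = FALSE]))
  mu <- colMeans(X)
  Xc <- sweep(X, 2, mu)
  cv <- crossprod(Xc) / (nf - 1)
  eig <- eigen(cv, symmetric = TRUE)
  values <- pmax(eig$values, 0)
  modes <- eig$vectors[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    m <- modes[, j]
    if (m[which.max(abs(m))] < 0) modes[, j] <- -m
  }
  structure(
    list(eigenvalues = values, modes = modes,
         projections = Xc %*% modes,
         mean_structure = matrix(mu, ncol = 3, byrow = TRUE),
         atoms = traj$atoms[sel, , drop = FALSE]),
    class = "EssentialModes"
  )
}

#' Per-residue displacement field along a principal component
#'
#' The "porcupine" view of a mode: each residue's 3-vector of mode
#' components scaled by the projection range (max - min) observed along that
#' mode, i.e. the collective displacement spanned by the trajectory.
#' Residues whose displacement magnitude falls below `cutoff` are masked,
#' mirroring the 3.5 A arrow cutoff convention of PC1 motion figures.
#'
#' @param modes an [essential_dynamics()] result.
#' @param mode_index which mode (1 = largest eigenvalue).
#' @param cutoff magnitude cutoff in Angstrom (default 3.5).
#' @param scale optional explicit scale overriding the projection range.
#' @return object of class `PorcupineField`: data.frame (chain, resid, dx,
#'   dy, dz, magnitude, kept).
#' @export
porcupine <- function(modes, mode_index = 1L, cutoff = 3.5, scale = NULL) {
  assert_that(inherits(modes, "EssentialModes"), "modes must be EssentialModes")
  assert_that(mode_index >= 1 && mode_index <= ncol(modes$modes),
              "mode_index out of range")
  v <- matrix(modes$modes[, mode_index], ncol = 3, byrow = TRUE)
  pr <- modes$projections[, mode_index]
  amp <- scale %||% (max(pr) - min(pr))
  disp <- v * amp
  mag <- sqrt(rowSums(disp^2))
  out <- data.frame(chain = modes$atoms$chain_id,
                    resid = modes$atoms$residue_index,
                    dx = disp[, 1], dy = disp[, 2], dz = disp[, 3],
                    magnitude = mag, kept = mag >= cutoff,
                    stringsAsFactors = FALSE)
  class(out) <- c("PorcupineField", class(out))
  attr(out, "cutoff") <- cutoff
  attr(out, "scale") <- amp
  out
}

#' Write a correlation matrix as TSV
#'
#' @param cm a [dcc()] result.
#' @param path output file.
#' @param long if TRUE, long form (chain_i, resid_i, chain_j, resid_j, c)
#'   instead of an n x n matrix.
#' @export
write_correlation_tsv <- function(cm, path, long = FALSE) {
  if (!long) {
    utils::write.table(cm$C, path, sep = "\t", row.names = FALSE,
                       col.names = FALSE)
  } else {
    n <- nrow(cm$C)
    idx <- which(upper.tri(cm$C, diag = TRUE), arr.ind = TRUE)
    df <- data.frame(chain_i = cm$residues$chain[idx[, 1]],
                     resid_i = cm$residues$resid[idx[, 1]],
                     chain_j = cm$residues$chain[idx[, 2]],
                     resid_j = cm$residues$resid[idx[, 2]],
                     c = cm$C[idx])
    utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}
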