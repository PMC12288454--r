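# synthetic-data generators: toy dimer geometry, ENM sampling, sequence
# panels, assay curves

test_that("toy dimer construction honours the domain map and bead geometry", {
  dm <- data.frame(label = c("DBD", "linker", "EO"),
                   start = c(1, 7, 10), end = c(6, 9, 20))
  ref <- generate_toy_dimer(toy_dimer_spec(20, domain_map = dm))
  expect_equal(nrow(ref$atoms), 40)
  expect_equal(nrow(ref$coords), 40)
  expect_equal(sum(ref$atoms$domain_label == "DBD"), 12)
  expect_equal(sum(ref$atoms$domain_label == "linker"), 6)
  expect_setequal(unique(ref$atoms$chain_id), c("A", "B"))

  # consecutive bead distances within each chain sit at C-alpha spacing
  for (ch in c("A", "B")) {
    xyz <- ref$coords[ref$atoms$chain_id == ch, ]
    d <- sqrt(rowSums(diff(xyz)^2))
    expect_true(all(d >= 3.7 & d <= 3.9))
  }

  # full-length default: 229 per monomer, 458 residues over two chains
  big <- generate_toy_dimer(toy_dimer_spec(229))
  expect_equal(nrow(big$atoms), 458)
  expect_equal(as.vector(table(big$atoms$chain_id)[c("A", "B")]),
               c(229L, 229L))
})

test_that("overlapping or gappy domain maps are rejected", {
  expect_error(toy_dimer_spec(20, domain_map = data.frame(
    label = c("DBD", "linker", "EO"), start = c(1, 5, 10),
    end = c(6, 9, 20))), "overlap")
  expect_error(toy_dimer_spec(20, domain_map = data.frame(
    label = c("DBD", "linker", "EO"), start = c(1, 8, 10),
    end = c(6, 9, 20))), "cover")
})

test_that("ENM sampling is seed-reproducible and respects the frozen limit", {
  ds <- toy_dimer_spec(12, domain_map = data.frame(
    label = c("DBD", "linker", "EO"), start = c(1, 5, 7), end = c(4, 6, 12)))
  es <- enm_trajectory_spec(ds, contact_cutoff = 9, n_frames = 50, seed = 42)
  r1 <- sample_enm_trajectory(es)
  r2 <- sample_enm_trajectory(es)
  expect_identical(r1$trajectory$coords, r2$trajectory$coords)

  frozen <- sample_enm_trajectory(
    enm_trajectory_spec(ds, contact_cutoff = 9, n_frames = 20,
                        temperature_scale = 0, seed = 1))
  ref <- generate_toy_dimer(ds)
  for (f in 1:20)
    expect_equal(matrix(frozen$trajectory$coords[f, , ], ncol = 3),
                 ref$coords, tolerance = 1e-12)
  prof <- rmsd_rmsf(frozen$trajectory, ref)
  expect_true(all(prof$rmsf$rmsf == 0))
})

test_that("a degenerate elastic network is reported, naming the culprits", {
  ds <- toy_dimer_spec(20)
  # below the bond length no springs exist at all: every residue isolated
  expect_error(sample_enm_trajectory(enm_trajectory_spec(ds, contact_cutoff = 3.5,
                                                         n_frames = 10)),
               "not connected")
  # short cutoffs can also leave free torsion axes (> 6 zero modes)
  expect_error(sample_enm_trajectory(enm_trajectory_spec(ds, contact_cutoff = 4,
                                                         n_frames = 10)),
               "zero modes|not connected")
})

test_that("planted couplings alter the analytic correlation structure", {
  ds <- toy_dimer_spec(20)
  base <- enm_trajectory_spec(ds, n_frames = 10, seed = 1)
  c_apo <- dcc_from_covariance(sample_enm_trajectory(base)$covariance)
  # an operator clamp between the two DBDs raises mean DBD x EO coupling
  clamp <- state_couplings(generate_toy_dimer(ds), "D")
  with_clamp <- enm_trajectory_spec(ds, n_frames = 10, seed = 1,
                                    extra_couplings = clamp)
  c_d <- dcc_from_covariance(sample_enm_trajectory(with_clamp)$covariance)
  labels <- generate_toy_dimer(ds)$atoms$domain_label
  expect_gt(dbd_eo_block_mean(c_d, labels), dbd_eo_block_mean(c_apo, labels))
  # and strictly changes the endpoint correlation of a directly planted pair
  pair <- enm_trajectory_spec(ds, n_frames = 10, seed = 1,
                              extra_couplings = data.frame(res_i = 4,
                                                           res_j = 15, k = 5))
  c_p <- dcc_from_covariance(sample_enm_trajectory(pair)$covariance)
  expect_false(isTRUE(all.equal(c_p[4, 15], c_apo[4, 15])))
})

test_that("empirical covariance converges to the analytic covariance", {
  ds <- toy_dimer_spec(12, domain_map = data.frame(
    label = c("DBD", "linker", "EO"), start = c(1, 5, 7), end = c(4, 6, 12)))
  err <- vapply(c(500, 5000), function(nf) {
    r <- sample_enm_trajectory(enm_trajectory_spec(ds, contact_cutoff = 9,
                                                   n_frames = nf, seed = 3))
    nfr <- dim(r$trajectory$coords)[1]
    X <- t(vapply(seq_len(nfr), function(f)
      as.vector(t(matrix(r$trajectory$coords[f, , ], ncol = 3))),
      numeric(3 * 24)))
    Xc <- sweep(X, 2, colMeans(X))
    emp <- crossprod(Xc) / nfr
    max(abs(emp - r$covariance))
  }, numeric(1))
  expect_lt(err[2], err[1])
})

test_that("the four-state suite enumerates exactly the ligand states", {
  ds <- toy_dimer_spec(20)
  base <- enm_trajectory_spec(ds, n_frames = 10, seed = 5)
  suite <- generate_state_suite(base)
  expect_named(suite, c("APO", "E", "D", "ED"))
  expect_identical(vapply(suite, function(s) s$spec$state_label, ""),
                   c(APO = "APO", E = "E", D = "D", ED = "ED"))
  expect_equal(nrow(state_couplings(generate_toy_dimer(ds), "APO")), 0)
})

test_that("sequence panels plant exactly the specified substitutions", {
  # 1 variant, 1 carrier among 3 sequences: one record differs at one position
  ps <- panel_spec(reference_length = 30,
                   planted_variants = data.frame(position = 10, ref = "A",
                                                 alt = "V", n_carriers = 1),
                   total_sequences = 3, seed = 7)
  gp <- generate_sequence_panel(ps)
  diffs <- vapply(gp$sequences, function(s)
    sum(strsplit(s, "")[[1]] != strsplit(gp$reference, "")[[1]]), integer(1))
  expect_equal(sort(unname(diffs)), c(0L, 0L, 1L))
  carrier <- names(which(diffs == 1))
  expect_equal(gp$truth$seq_id, carrier)
  expect_equal(substr(gp$sequences[[carrier]], 10, 10), "V")

  # zero planted variants: everything identical to the reference
  none <- generate_sequence_panel(panel_spec(reference_length = 25,
                                             planted_variants = NULL,
                                             total_sequences = 5, seed = 2))
  expect_true(all(none$sequences == none$reference))
  expect_equal(nrow(none$truth), 0)
})

test_that("the packaged census panel carries 12 substitutions in 42 isolates", {
  gp <- generate_sequence_panel(panel_spec(seed = 11))
  expect_equal(length(gp$sequences), 340)
  expect_true(all(nchar(gp$sequences) == 229))
  expect_equal(nrow(gp$truth), 42)
  expect_equal(length(unique(paste(gp$truth$position, gp$truth$alt))), 12)
  # truth table consistency: re-diffing every record reproduces it exactly
  refv <- strsplit(gp$reference, "")[[1]]
  rediff <- do.call(rbind, lapply(names(gp$sequences), function(id) {
    sv <- strsplit(gp$sequences[[id]], "")[[1]]
    at <- which(sv != refv)
    if (!length(at)) return(NULL)
    data.frame(seq_id = id, position = at, ref = refv[at], alt = sv[at])
  }))
  truth <- gp$truth[order(gp$truth$seq_id), c("seq_id", "position", "ref", "alt")]
  rediff <- rediff[order(rediff$seq_id), ]
  rownames(truth) <- rownames(rediff) <- NULL
  expect_equal(rediff, truth)
})

test_that("conflicting planted reference residues are rejected", {
  expect_error(panel_spec(planted_variants = data.frame(
    position = c(10, 10), ref = c("A", "G"), alt = c("V", "W"),
    n_carriers = c(1, 1))), "conflicting ref_aa")
})

test_that("curve generation reproduces model truth and noise deterministically", {
  # noiseless Hill curve sits exactly on the model
  cs <- curve_spec("hill", list(K_D = 494, n = 1),
                   x_values = seq(50, 1600, by = 150), noise_cv = 0)
  cd <- generate_curve(cs)
  expect_equal(cd$y, hill_model(cd$x, 494, 1), tolerance = 1e-12)

  # growth curve doubles every 1.62 h inside the exponential window
  gs <- curve_spec("growth_lag_exp",
                   list(od0 = 0.03, lag_h = 0, doubling_h = 1.62,
                        plateau = 1e6),
                   x_values = c(0.5, 1.62, 2.4, 3.24, 4.86, 6, 8, 10),
                   noise_cv = 0)
  gd <- generate_curve(gs)
  ratio <- gd$y[gd$x == 3.24] / gd$y[gd$x == 1.62]
  expect_equal(ratio, 2, tolerance = 1e-9)

  # same seed, same noise draws
  n1 <- generate_curve(curve_spec("hill", list(K_D = 100, n = 2),
                                  x_values = 1:10 * 20, noise_cv = 0.05,
                                  seed = 9))
  n2 <- generate_curve(curve_spec("hill", list(K_D = 100, n = 2),
                                  x_values = 1:10 * 20, noise_cv = 0.05,
                                  seed = 9))
  expect_identical(n1$y, n2$y)
})
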