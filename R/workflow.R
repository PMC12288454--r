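#' Study design: variants x ligand states
#'
#' @param variants character vector of variant names (e.g. "WT", "R71C",
#'   "A152E").
#' @param states subset of the four ligand states APO, E, D, ED.
#' @return object of class `StudyDesign`.
#' @export
study_design <- function(variants, states = c("APO", "E", "D", "ED")) {
  assert_that(length(variants) >= 1, "need at least one variant")
  bad <- setdiff(states, c("APO", "E", "D", "ED"))
  if (length(bad))
    stop("unknown state label(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  assert_that(length(states) >= 1, "need at least one state")
  structure(list(variants = variants, states = states), class = "StudyDesign")
}

#' Enumerate the simulation systems of a design
#'
#' Cartesian product of variants and states in deterministic order (states
#' cycle within each variant). Two variants across the four ligand states
#' give the eight-system study layout.
#'
#' @param design a [study_design()].
#' @return data.frame (variant, state), one row per system.
#' @export
enumerate_systems <- function(design) {
  assert_that(inherits(design, "StudyDesign"), "design must be a StudyDesign")
  out <- expand.grid(state = design$states, variant = design$variants,
                     stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE)
  out <- out[, c("variant", "state")]
  rownames(out) <- NULL
  out
}

# per-variant planted-spring scale factors used by the dynamics pipeline;
# fixtures, not measurements: the linker variant blunts the DBD-EO relay,
# the EO variant blunts operator engagement
default_variant_profiles <- function() {
  list(WT    = list(effector_scale = 1,    dna_scale = 1),
       R71C  = list(effector_scale = 0.25, dna_scale = 1),
       A152E = list(effector_scale = 1,    dna_scale = 0.25))
}

#' Run an end-to-end pipeline
#'
#' Executes one of three run kinds from a config (an R list, or a path to a
#' YAML/JSON file):
#' \describe{
#'   \item{dynamics}{synthetic four-state trajectory suites per variant ->
#'     superposition -> DCC -> inter-domain coupling -> dynamical network ->
#'     suboptimal paths -> cross-state comparison report.}
#'   \item{scan}{sequence panel (generated, or FASTA paths) -> length filter
#'     -> variant census report.}
#'   \item{curves}{synthetic or CSV assay curves -> binding/growth fits.}
#' }
#' Every stochastic stage receives an explicit seed derived from
#' `config$seed`. All intermediates are written under `out_dir` together
#' with a JSON manifest (package version, config echo, per-file MD5 hashes)
#' and a human-readable summary; rerunning the same config reproduces all
#' outputs bit-identically.
#'
#' @param config list or YAML/JSON path. Required fields: `kind`
#'   ("dynamics", "scan" or "curves"), `seed`, plus kind-specific settings
#'   (see the package vignette).
#' @param out_dir output directory; defaults to `config$out_dir`.
#' @return (invisibly) list with `manifest` and the per-stage results.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  if (is.character(config) && length(config) == 1) {
    assert_that(file.exists(config), paste("config file not found:", config))
    config <- if (grepl("\\.json$", config)) jsonlite::read_json(config,
                                                                 simplifyVector = TRUE)
              else yaml::read_yaml(config)
  }
  assert_that(is.list(config), "config must be a list or a YAML/JSON path")
  assert_that(!is.null(config$kind), "config$kind is required")
  assert_that(!is.null(config$seed), "config$seed is required")
  out_dir <- out_dir %||% config$out_dir
  assert_that(!is.null(out_dir), "an output directory is required")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
  }
  results <- switch(config$kind,
                    dynamics = run_dynamics_pipeline(config, out_dir, stage),
                    scan = run_scan_pipeline(config, out_dir, stage),
                    curves = run_curves_pipeline(config, out_dir, stage),
                    stop("unknown run kind: ", config$kind, call. = FALSE))

  files <- setdiff(list.files(out_dir, recursive = TRUE),
                   c("manifest.json", "summary.txt"))
  manifest <- list(
    package = "allosterik",
    version = as.character(utils::packageVersion("allosterik")),
    kind = config$kind,
    seed = config$seed,
    config = config,
    outputs = lapply(files, function(f) list(
      path = f, md5 = unname(tools::md5sum(file.path(out_dir, f)))))
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  writeLines(c(sprintf("allosterik %s run: %s (seed %s)",
                       manifest$version, config$kind, config$seed),
               sprintf("outputs: %d files under %s", length(files), out_dir),
               results$summary_lines),
             file.path(out_dir, "summary.txt"))
  invisible(list(manifest = manifest, results = results$value))
}

run_dynamics_pipeline <- function(config, out_dir, stage) {
  npm <- config$residues_per_monomer %||% 20L
  nf <- config$n_frames %||% 1000L
  variants <- config$variants %||% c("WT", "R71C")
  profiles <- default_variant_profiles()
  dspec <- stage("dimer", toy_dimer_spec(npm))
  ensembles <- list()
  coupling_rows <- list()
  summary_lines <- character(0)
  for (v in seq_along(variants)) {
    vn <- variants[[v]]
    prof <- profiles[[vn]] %||% profiles$WT
    base <- enm_trajectory_spec(dspec, n_frames = nf,
                                seed = derive_seed(config$seed, 100L * v))
    suite <- stage(paste0("suite:", vn), do.call(generate_state_suite,
                                                 c(list(base = base), prof)))
    for (st in names(suite)) {
      sys_name <- paste(vn, st, sep = ".")
      run <- suite[[st]]
      traj <- stage(paste0("superpose:", sys_name),
                    superpose(run$trajectory, run$structure))
      cm <- stage(paste0("dcc:", sys_name), dcc(traj))
      write_correlation_tsv(cm, file.path(out_dir,
                                          paste0("dcc_", sys_name, ".tsv")))
      cpl <- interdomain_coupling(cm)
      cpl$system <- sys_name
      coupling_rows[[sys_name]] <- cpl
      net <- stage(paste0("network:", sys_name), build_network(traj, cm))
      write_network_tsv(net, file.path(out_dir,
                                       paste0("edges_", sys_name, ".tsv")))
      ens <- stage(paste0("paths:", sys_name),
                   suboptimal_paths(net, max_paths = config$max_paths %||% 100000L))
      write_paths_tsv(ens, file.path(out_dir,
                                     paste0("paths_", sys_name, ".tsv")))
      ensembles[[sys_name]] <- ens
      summary_lines <- c(summary_lines,
                         sprintf("%s: %d paths, L_opt %.3f", sys_name,
                                 length(ens$paths), ens$L_opt))
    }
  }
  stats <- stage("compare", path_statistics(ensembles))
  utils::write.table(do.call(rbind, coupling_rows),
                     file.path(out_dir, "interdomain_coupling.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  jsonlite::write_json(stats, file.path(out_dir, "path_statistics.json"),
                       auto_unbox = TRUE, dataframe = "rows", digits = NA)
  list(value = list(ensembles = ensembles, statistics = stats),
       summary_lines = summary_lines)
}

run_scan_pipeline <- function(config, out_dir, stage) {
  if (!is.null(config$panel_fasta)) {
    panel <- stage("read-panel", as_sequence_set(config$panel_fasta))
    reference <- stage("read-reference",
                       as_sequence_set(config$reference_fasta)[[1]])
  } else {
    ps <- panel_spec(seed = derive_seed(config$seed, 0L))
    gp <- stage("generate-panel", generate_sequence_panel(ps))
    write_panel_fasta(gp, file.path(out_dir, "panel"))
    panel <- gp$sequences
    reference <- gp$reference
  }
  flt <- stage("length-filter",
               length_filter(panel, config$required_length %||% nchar(reference)))
  report <- stage("tabulate", tabulate_panel(flt$kept, reference))
  report$n_length_filtered <- length(flt$kept)
  write_variant_report(report,
                       tsv_path = file.path(out_dir, "variants.tsv"),
                       json_path = file.path(out_dir, "variants.json"))
  list(value = report,
       summary_lines = sprintf(
         "scan: %d unique variants, %d carriers / %d sequences (DBD %d, linker %d, EO %d)",
         nrow(report$unique_variants), report$n_carrier_sequences,
         report$n_sequences_scanned, report$per_domain_counts[["DBD"]],
         report$per_domain_counts[["linker"]], report$per_domain_counts[["EO"]]))
}

run_curves_pipeline <- function(config, out_dir, stage) {
  assert_that(!is.null(config$curves), "config$curves is required")
  fits <- list()
  summary_lines <- character(0)
  for (k in seq_along(config$curves)) {
    cc <- config$curves[[k]]
    nm <- cc$name %||% paste0("curve", k)
    curve <- if (!is.null(cc$csv)) {
      stage(paste0("read:", nm), read_curve_csv(cc$csv))
    } else {
      cs <- curve_spec(cc$model, cc$true_params, unlist(cc$x_values),
                       noise_cv = cc$noise_cv %||% 0.05,
                       seed = derive_seed(config$seed, k))
      gc <- stage(paste0("generate:", nm), generate_curve(cs))
      write_curve_csv(gc, file.path(out_dir, paste0(nm, ".csv")))
      gc
    }
    fit_model <- cc$fit %||% cc$model
    fit <- stage(paste0("fit:", nm), switch(
      fit_model,
      hill = fit_binding(curve, "hill"),
      isotherm_1to1 = fit_binding(curve, "isotherm_1to1",
                                  protein_total = cc$protein_total %||%
                                    cc$true_params$protein_total),
      growth_lag_exp = fit_growth(curve),
      stop("unknown curve model: ", fit_model)))
    fits[[nm]] <- fit
    summary_lines <- c(summary_lines, paste0(
      nm, ": ", if (inherits(fit, "BindingFit"))
        sprintf("K_D %.4g (fit %s)", fit$K_D, fit$model)
      else sprintf("doubling %.3f h, lag %.2f h", fit$doubling_time,
                   fit$lag_time)))
  }
  flat <- lapply(fits, function(f) f[setdiff(names(f), "fit")])
  jsonlite::write_json(flat, file.path(out_dir, "fits.json"),
                       auto_unbox = TRUE, digits = NA)
  list(value = fits, summary_lines = summary_lines)
}
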