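#' The catalogued DgoR substitution census
#'
#' The twelve unique amino acid substitutions observed in DgoR across a
#' reference panel of 340 sequenced natural E. coli isolates, carried by 42
#' isolates in total. Named carriers are known for four substitutions (P24L:
#' 2 isolates; R71C: 2; P92L: 1; A152E: 2); the remaining 35 carriers are
#' distributed over the other eight substitutions as a packaged fixture —
#' only the total is established, so the per-variant split for those eight
#' is a simulation default, not biology.
#'
#' @return data.frame (variant, position, ref, alt, n_carriers) summing to
#'   42 carriers.
#' @export
dgor_variant_census <- function() {
  df <- data.frame(
    variant = c("L3F", "K15R", "H19Q", "P24L", "R71C", "P92L", "A128S",
                "A152E", "T180S", "A186V", "S220C", "T222I"),
    position = c(3L, 15L, 19L, 24L, 71L, 92L, 128L, 152L, 180L, 186L, 220L, 222L),
    ref = c("L", "K", "H", "P", "R", "P", "A", "A", "T", "A", "S", "T"),
    alt = c("F", "R", "Q", "L", "C", "L", "S", "E", "S", "V", "C", "I"),
    n_carriers = c(5L, 5L, 4L, 2L, 2L, 1L, 5L, 2L, 4L, 4L, 4L, 4L),
    stringsAsFactors = FALSE
  )
  stopifnot(sum(df$n_carriers) == 42L)
  df
}

#' Specification of a synthetic isolate sequence panel
#'
#' @param reference_length protein length in residues (default 229, the DgoR
#'   monomer).
#' @param planted_variants data.frame (position, ref, alt, n_carriers);
#'   default: the packaged twelve-substitution census.
#' @param total_sequences panel size (default 340 isolates).
#' @param seed integer RNG seed.
#' @return object of class `PanelSpec`.
#' @export
panel_spec <- function(reference_length = 229L,
                       planted_variants = dgor_variant_census(),
                       total_sequences = 340L,
                       seed = 101L) {
  pv <- planted_variants
  if (is.null(pv)) pv <- dgor_variant_census()[0, ]
  if (nrow(pv) > 0) {
    assert_that(all(c("position", "ref", "alt", "n_carriers") %in% names(pv)),
                "planted_variants needs columns position, ref, alt, n_carriers")
    assert_that(all(pv$position >= 1 & pv$position <= reference_length),
                "planted positions must lie within the reference")
    assert_that(all(pv$ref != pv$alt), "ref_aa must differ from alt_aa")
    assert_that(all(pv$ref %in% AA20) && all(pv$alt %in% AA20),
                "ref and alt must be canonical amino acids")
    assert_that(sum(pv$n_carriers) <= total_sequences,
                "carrier counts exceed total_sequences")
    byp <- split(pv$ref, pv$position)
    conflict <- names(byp)[vapply(byp, function(r) length(unique(r)) > 1,
                                  logical(1))]
    if (length(conflict))
      stop("conflicting ref_aa at planted position(s): ",
           paste(conflict, collapse = ", "), call. = FALSE)
  }
  structure(list(reference_length = as.integer(reference_length),
                 planted_variants = pv,
                 total_sequences = as.integer(total_sequences),
                 seed = as.integer(seed)),
            class = "PanelSpec")
}

#' Generate a synthetic isolate sequence panel
#'
#' Builds a seeded random reference protein carrying the stated reference
#' residue at every planted position, then plants each substitution into a
#' disjoint, randomly chosen carrier set. Carrier identities are recorded in
#' a truth table so that downstream variant calls can be verified exactly.
#'
#' @param pspec a [panel_spec()].
#' @return object of class `SequencePanel`: list with `reference` (character
#'   string), `sequences` (named character vector of `total_sequences`
#'   records), `truth` (data.frame seq_id, variant, position, ref, alt) and
#'   `spec`.
#' @export
generate_sequence_panel <- function(pspec) {
  assert_that(inherits(pspec, "PanelSpec"), "pspec must be a PanelSpec")
  set.seed(pspec$seed)
  L <- pspec$reference_length
  ref <- sample(AA20, L, replace = TRUE)
  pv <- pspec$planted_variants
  if (nrow(pv) > 0) ref[pv$position] <- pv$ref
  n <- pspec$total_sequences
  ids <- sprintf("iso_%04d", seq_len(n))
  seqs <- matrix(rep(ref, n), nrow = n, byrow = TRUE)
  truth <- data.frame(seq_id = character(0), variant = character(0),
                      position = integer(0), ref = character(0),
                      alt = character(0), stringsAsFactors = FALSE)
  if (nrow(pv) > 0 && sum(pv$n_carriers) > 0) {
    carriers <- sample(n, sum(pv$n_carriers))
    at <- 0L
    for (k in seq_len(nrow(pv))) {
      if (pv$n_carriers[k] == 0) next
      idx <- carriers[(at + 1L):(at + pv$n_carriers[k])]
      at <- at + pv$n_carriers[k]
      seqs[idx, pv$position[k]] <- pv$alt[k]
      variant <- if (!is.null(pv$variant)) pv$variant[k]
                 else paste0(pv$ref[k], pv$position[k], pv$alt[k])
      truth <- rbind(truth, data.frame(
        seq_id = ids[idx], variant = variant, position = pv$position[k],
        ref = pv$ref[k], alt = pv$alt[k], stringsAsFactors = FALSE))
    }
  }
  sequences <- apply(seqs, 1, paste, collapse = "")
  names(sequences) <- ids
  truth <- truth[order(truth$position, truth$alt, truth$seq_id), ]
  rownames(truth) <- NULL
  structure(list(reference = paste(ref, collapse = ""), sequences = sequences,
                 truth = truth, spec = pspec),
            class = "SequencePanel")
}

#' @export
print.SequencePanel <- function(x, ...) {
  cat("SequencePanel:", length(x$sequences), "sequences of length",
      nchar(x$reference), "|", nrow(x$truth), "planted carrier records\n")
  invisible(x)
}

#' Write a sequence panel to FASTA (plus JSON truth table)
#'
#' @param panel a [generate_sequence_panel()] result.
#' @param dir output directory (created if needed).
#' @return named list of written paths.
#' @export
write_panel_fasta <- function(panel, dir) {
  assert_that(inherits(panel, "SequencePanel"), "panel must be a SequencePanel")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list(panel = file.path(dir, "panel.fasta"),
                reference = file.path(dir, "reference.fasta"),
                truth = file.path(dir, "truth.json"))
  Biostrings::writeXStringSet(Biostrings::AAStringSet(panel$sequences),
                              paths$panel, width = 60)
  Biostrings::writeXStringSet(
    Biostrings::AAStringSet(c(reference = panel$reference)),
    paths$reference, width = 60)
  jsonlite::write_json(panel$truth, paths$truth, dataframe = "rows")
  paths
}
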