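#' Classify a residue position into its domain
#'
#' @param position 1-based position(s) in the reference.
#' @param domain_map data.frame (label, start, end); default: the packaged
#'   DgoR map (DBD 1-63, linker 64-79, EO 80-229).
#' @return character vector of domain labels.
#' @export
classify_domain <- function(position, domain_map = default_domain_map()) {
  dm <- domain_map
  out <- character(length(position))
  for (k in seq_along(position)) {
    hit <- which(dm$start <= position[k] & dm$end >= position[k])
    if (length(hit) != 1)
      stop("position ", position[k], " is outside the domain map (1..",
           max(dm$end), ")", call. = FALSE)
    out[k] <- dm$label[hit]
  }
  out
}

# coerce FASTA path / AAStringSet / named character to named character
as_sequence_set <- function(panel) {
  if (is.character(panel) && length(panel) == 1 &&
      (file.exists(panel) ||
       grepl("\\.(fa|fasta|faa)$", panel, ignore.case = TRUE))) {
    assert_that(file.exists(panel), paste("FASTA file not found:", panel))
    ss <- Biostrings::readAAStringSet(panel)
    out <- as.character(ss)
    names(out) <- sub("\\s.*$", "", names(ss))
    return(out)
  }
  if (methods::is(panel, "XStringSet")) {
    out <- as.character(panel)
    return(out)
  }
  if (inherits(panel, "SequencePanel")) return(panel$sequences)
  assert_that(is.character(panel), "panel must be sequences or a FASTA path")
  if (is.null(names(panel))) names(panel) <- sprintf("seq_%04d", seq_along(panel))
  panel
}

#' Exact-length filter for a homolog panel
#'
#' Keeps only records of exactly `required_length` residues (the census
#' procedure analyzed homologs of the full 229-aa repressor length).
#' Records containing non-amino-acid characters are dropped with a
#' per-record warning.
#'
#' @param panel FASTA path, `AAStringSet`, [generate_sequence_panel()] result
#'   or named character vector.
#' @param required_length integer (default 229).
#' @return list with `kept` (named character vector) and `dropped`
#'   (data.frame id, length, reason).
#' @export
length_filter <- function(panel, required_length = 229L) {
  seqs <- as_sequence_set(panel)
  if (length(seqs) == 0)
    return(list(kept = character(0),
                dropped = data.frame(id = character(0), length = integer(0),
                                     reason = character(0))))
  valid <- vapply(strsplit(toupper(seqs), ""),
                  function(ch) all(ch %in% AA20), logical(1))
  for (id in names(seqs)[!valid])
    warning("record ", id, " contains non-amino-acid characters; dropped",
            call. = FALSE)
  len_ok <- nchar(seqs) == required_length
  keep <- valid & len_ok
  reason <- ifelse(!valid, "non-amino-acid characters",
                   paste0("length ", nchar(seqs), " != ", required_length))
  list(kept = seqs[keep],
       dropped = data.frame(id = names(seqs)[!keep],
                            length = nchar(seqs)[!keep],
                            reason = reason[!keep],
                            stringsAsFactors = FALSE))
}

blosum62 <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      e <- new.env()
      utils::data("BLOSUM62", package = "Biostrings", envir = e)
      cache <<- e$BLOSUM62
    }
    cache
  }
})

#' Call amino acid substitutions against a reference
#'
#' Globally aligns one homolog to the reference (Needleman-Wunsch, BLOSUM62,
#' gap opening 10 / extension 0.5) and reports substitutions at columns
#' where both residues are aligned and differ, in reference coordinates.
#' Indels are reported separately — they are not substitutions. Alignments
#' below 50% identity are flagged with a low-homology warning.
#'
#' @param seq homolog sequence (character string).
#' @param reference reference sequence (character string).
#' @return list with `substitutions` (data.frame position, ref, alt),
#'   `indels` (data.frame type, ref_position, length), `identity` (percent)
#'   and `low_homology` (logical).
#' @export
call_substitutions <- function(seq, reference) {
  assert_that(nchar(seq) > 0 && nchar(reference) > 0,
              "sequences must be non-empty")
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(seq), Biostrings::AAString(reference),
    type = "global", substitutionMatrix = blosum62(),
    gapOpening = 10, gapExtension = 0.5)
  p <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
  s <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
  refpos <- cumsum(s != "-")
  subst_idx <- which(p != "-" & s != "-" & p != s)
  substitutions <- data.frame(position = refpos[subst_idx],
                              ref = s[subst_idx], alt = p[subst_idx],
                              stringsAsFactors = FALSE)
  indels <- data.frame(type = character(0), ref_position = integer(0),
                       length = integer(0), stringsAsFactors = FALSE)
  gap <- p == "-" | s == "-"
  if (any(gap)) {
    runs <- rle(gap)
    ends <- cumsum(runs$lengths)
    starts <- ends - runs$lengths + 1L
    for (r in which(runs$values)) {
      type <- if (s[starts[r]] == "-") "insertion" else "deletion"
      indels <- rbind(indels, data.frame(
        type = type,
        ref_position = max(refpos[starts[r]], 1L),
        length = runs$lengths[r], stringsAsFactors = FALSE))
    }
  }
  identity <- Biostrings::pid(aln)
  low <- identity < 50
  if (low)
    warning("low-homology alignment: ", round(identity, 1), "% identity",
            call. = FALSE)
  list(substitutions = substitutions, indels = indels,
       identity = identity, low_homology = low)
}

#' Tabulate unique variants in a homolog panel
#'
#' Scans every record against the reference with [call_substitutions()],
#' de-duplicates by (position, ref, alt), attaches carrier lists and domain
#' labels, and reports per-domain counts. Ordering is deterministic
#' (position, then alt residue), so the report is invariant to panel record
#' order.
#'
#' @param panel length-filtered panel (named character vector, or anything
#'   [length_filter()] accepts — then filtered here with `required_length =
#'   nchar(reference)` disabled; pass pre-filtered data for strict census
#'   semantics).
#' @param reference reference sequence (character string).
#' @param domain_map data.frame (label, start, end).
#' @return object of class `VariantPanelReport`: `n_sequences_scanned`,
#'   `n_length_filtered`, `unique_variants` (data.frame variant, position,
#'   ref, alt, domain, n_carriers, carrier_ids), `per_domain_counts`
#'   (named integer), `n_carrier_sequences`, `indel_records`.
#' @export
tabulate_panel <- function(panel, reference,
                           domain_map = default_domain_map(nchar(reference))) {
  seqs <- as_sequence_set(panel)
  validate_domain_map(domain_map, nchar(reference))
  calls <- list()
  indel_records <- data.frame(seq_id = character(0), type = character(0),
                              ref_position = integer(0), length = integer(0),
                              stringsAsFactors = FALSE)
  carrier_ids <- character(0)
  for (id in names(seqs)) {
    res <- call_substitutions(seqs[[id]], reference)
    if (nrow(res$substitutions) > 0) {
      carrier_ids <- c(carrier_ids, id)
      for (r in seq_len(nrow(res$substitutions))) {
        key <- paste(res$substitutions$position[r], res$substitutions$ref[r],
                     res$substitutions$alt[r], sep = ":")
        calls[[key]] <- c(calls[[key]], id)
      }
    }
    if (nrow(res$indels) > 0)
      indel_records <- rbind(indel_records,
                             cbind(seq_id = id, res$indels))
  }
  if (length(calls)) {
    parts <- strsplit(names(calls), ":", fixed = TRUE)
    uv <- data.frame(
      position = vapply(parts, function(p) as.integer(p[1]), integer(1)),
      ref = vapply(parts, `[[`, "", 2),
      alt = vapply(parts, `[[`, "", 3),
      stringsAsFactors = FALSE)
    uv$variant <- paste0(uv$ref, uv$position, uv$alt)
    uv$domain <- classify_domain(uv$position, domain_map)
    uv$n_carriers <- vapply(calls, length, integer(1))
    ord <- order(uv$position, uv$alt)
    uv <- uv[ord, c("variant", "position", "ref", "alt", "domain", "n_carriers")]
    uv$carrier_ids <- lapply(calls[ord], sort)
    rownames(uv) <- NULL
  } else {
    uv <- data.frame(variant = character(0), position = integer(0),
                     ref = character(0), alt = character(0),
                     domain = character(0), n_carriers = integer(0),
                     stringsAsFactors = FALSE)
    uv$carrier_ids <- list()
  }
  per_domain <- vapply(c("DBD", "linker", "EO"),
                       function(d) sum(uv$domain == d), integer(1))
  structure(
    list(n_sequences_scanned = length(seqs),
         n_length_filtered = length(seqs),
         unique_variants = uv,
         per_domain_counts = per_domain,
         n_carrier_sequences = length(unique(carrier_ids)),
         indel_records = indel_records),
    class = "VariantPanelReport"
  )
}

#' @export
print.VariantPanelReport <- function(x, ...) {
  cat("VariantPanelReport:", nrow(x$unique_variants), "unique variants in",
      x$n_carrier_sequences, "carriers /", x$n_sequences_scanned,
      "sequences\n")
  cat("  per domain:",
      paste(names(x$per_domain_counts), x$per_domain_counts,
            sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' Write a variant panel report
#'
#' @param report a [tabulate_panel()] result.
#' @param tsv_path,json_path output paths (NULL to skip either).
#' @export
write_variant_report <- function(report, tsv_path = NULL, json_path = NULL) {
  uv <- report$unique_variants
  flat <- uv
  flat$carrier_ids <- vapply(uv$carrier_ids, paste, "", collapse = ",")
  if (!is.null(tsv_path))
    utils::write.table(flat, tsv_path, sep = "\t", row.names = FALSE,
                       quote = FALSE)
  if (!is.null(json_path))
    jsonlite::write_json(
      list(n_sequences_scanned = report$n_sequences_scanned,
           n_carrier_sequences = report$n_carrier_sequences,
           per_domain_counts = as.list(report$per_domain_counts),
           unique_variants = flat),
      json_path, auto_unbox = TRUE, dataframe = "rows")
  invisible(NULL)
}
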