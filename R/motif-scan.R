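# Scanning static structures for alpha-strand motifs: windows of residues
# whose quadrant labels alternate (alpha_R/alpha_L), optionally constrained
# to a residue-name sequence such as Thr-Gly-Val.

.parse_pattern <- function(pattern) {
  if (length(pattern) == 1L && !pattern[1L] %in% .STRAND_LABELS) {
    # compact form, e.g. "RLR"
    letters1 <- strsplit(toupper(pattern), "")[[1L]]
    if (!all(letters1 %in% c("R", "L"))) {
      stop("pattern must use labels alpha_R/alpha_L or letters R/L")
    }
    pattern <- ifelse(letters1 == "R", "alpha_R", "alpha_L")
  }
  stopifnot(all(pattern %in% .STRAND_LABELS), length(pattern) >= 3L)
  if (any(pattern[-1L] == pattern[-length(pattern)])) {
    stop("an alpha-strand pattern must strictly alternate alpha_R/alpha_L")
  }
  pattern
}

#' Scan a structure for alpha-strand motifs
#'
#' Slides a window over every chain of a (single-model) structure and reports
#' each window whose conformation labels equal the requested alternating
#' pattern and, when a sequence constraint is given, whose residue names
#' match it. Windows never span residue-numbering gaps; overlapping hits are
#' all reported. Alternate locations resolve to the highest-occupancy
#' conformer (first on tie).
#'
#' @param frame an `md_frame` (e.g. `get_frame(read_multimodel_pdb(f), 0)`).
#' @param pattern label pattern: a character vector of `alpha_R`/`alpha_L`
#'   or a compact string such as `"RLR"` (default).
#' @param sequence optional residue-name constraint, e.g.
#'   `c("THR", "GLY", "VAL")`; same length as the pattern.
#' @param chains chains to scan (default: all chains in the frame).
#' @param structure_id identifier copied into the hit table.
#' @return data frame with one row per hit: `structure_id`, `chain`,
#'   `start_residue`, `length`, `residues` (names joined by "-"), `pattern`,
#'   and list-columns `phi`, `psi` holding the window's dihedrals.
#' @export
scan_structure <- function(frame, pattern = "RLR", sequence = NULL,
                           chains = NULL, structure_id = NA_character_) {
  stopifnot(inherits(frame, "md_frame"))
  pattern <- .parse_pattern(pattern)
  m <- length(pattern)
  if (!is.null(sequence)) {
    sequence <- toupper(sequence)
    stopifnot(length(sequence) == m)
  }
  if (is.null(chains)) chains <- unique(frame$atoms$chain)
  hits <- list()
  for (ch in chains) {
    pp <- suppressWarnings(assign_phi_psi(frame, chain = ch))
    n <- nrow(pp)
    if (n < m) next
    lab <- classify_conformation(pp$phi, pp$psi)
    for (s in seq_len(n - m + 1L)) {
      w <- s:(s + m - 1L)
      if (!all(lab[w] == pattern)) next
      if (!all(diff(pp$resseq[w]) == 1L)) next
      if (!is.null(sequence) && !all(toupper(pp$resname[w]) == sequence)) next
      hit <- data.frame(structure_id = structure_id, chain = ch,
                        start_residue = pp$resseq[s], length = m,
                        residues = paste(pp$resname[w], collapse = "-"),
                        pattern = .pattern_string(lab[w]))
      hit$phi <- list(pp$phi[w])
      hit$psi <- list(pp$psi[w])
      hits[[length(hits) + 1L]] <- hit
    }
  }
  if (!length(hits)) return(.empty_hits())
  out <- do.call(rbind, hits)
  rownames(out) <- NULL
  out
}

.empty_hits <- function() {
  out <- data.frame(structure_id = character(), chain = character(),
                    start_residue = integer(), length = integer(),
                    residues = character(), pattern = character())
  out$phi <- list()
  out$psi <- list()
  out
}

#' Scan a directory of structure files for alpha-strand motifs
#'
#' Applies [scan_structure()] to the first model of every matching file.
#' Files that fail to parse are skipped and reported, not fatal.
#'
#' @param dir directory containing structure files.
#' @param pattern,sequence passed to [scan_structure()].
#' @param file_pattern regular expression selecting files (default
#'   PDB-style extensions).
#' @param chains passed to [scan_structure()].
#' @return list with `n_files`, `n_structures_with_hits`,
#'   `total_occurrences`, `hits` (combined hit table) and `failed`
#'   (character vector of unparseable files).
#' @export
scan_directory <- function(dir, pattern = "RLR", sequence = NULL,
                           file_pattern = "\\.(pdb|ent)$", chains = NULL) {
  files <- sort(list.files(dir, pattern = file_pattern, full.names = TRUE))
  hits <- list()
  failed <- character()
  for (f in files) {
    res <- tryCatch({
      traj <- read_multimodel_pdb(f)
      scan_structure(get_frame(traj, 0L), pattern = pattern,
                     sequence = sequence, chains = chains,
                     structure_id = basename(f))
    }, error = function(e) e)
    if (inherits(res, "error")) {
      warning(sprintf("skipping '%s': %s", basename(f), conditionMessage(res)))
      failed <- c(failed, basename(f))
    } else if (nrow(res)) {
      hits[[length(hits) + 1L]] <- res
    }
  }
  hits <- if (length(hits)) do.call(rbind, hits) else .empty_hits()
  list(n_files = length(files),
       n_structures_with_hits = length(unique(hits$structure_id)),
       total_occurrences = nrow(hits),
       hits = hits, failed = failed)
}
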