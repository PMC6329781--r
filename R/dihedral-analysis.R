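# Backbone phi/psi assignment, quadrant classification into alpha_R/alpha_L,
# alpha-strand detection, occupancy and Ramachandran time series.
#
# Conformation labels: "alpha_R" for phi and psi both in (-180, 0),
# "alpha_L" for both in (0, 180), "other" for every other defined pair
# (boundaries at 0 and +/-180 included, since the quadrant rule uses strict
# inequalities), "undefined" where a dihedral cannot be computed (chain
# termini, missing backbone atoms).

.LABEL_LEVELS <- c("alpha_R", "alpha_L", "other", "undefined")
.STRAND_LABELS <- c("alpha_R", "alpha_L")

#' Classify a (phi, psi) pair into helical quadrants
#'
#' Implements the quadrant rule used for alpha-strand bookkeeping: a residue
#' is `alpha_R` when -180 < phi < 0 and -180 < psi < 0, `alpha_L` when
#' 0 < phi < 180 and 0 < psi < 180, `other` for any other defined pair
#' (including values exactly on a quadrant boundary), and `undefined` when
#' either angle is `NA`.
#'
#' @param phi,psi numeric vectors of angles in degrees, range (-180, 180].
#' @return character vector of labels, same length as the inputs.
#' @examples
#' classify_conformation(c(-60, 57, -120, 0), c(-45, 47, 130, 50))
#' @export
classify_conformation <- function(phi, psi) {
  stopifnot(length(phi) == length(psi))
  out <- rep("other", length(phi))
  out[phi > -180 & phi < 0 & psi > -180 & psi < 0] <- "alpha_R"
  out[phi > 0 & phi < 180 & psi > 0 & psi < 180] <- "alpha_L"
  out[is.na(phi) | is.na(psi)] <- "undefined"
  out
}

# Build backbone atom indices for one chain of an atom table. Residues are
# those carrying a CA atom; the preceding residue's C (which may belong to an
# ACE cap) supplies the fourth atom of phi, the following residue's N the
# fourth atom of psi. Alternate locations resolve to the highest occupancy
# (first on tie). Numbering gaps break phi/psi across the gap.
.backbone_index <- function(atoms, chain = "A") {
  a <- atoms[atoms$chain == chain, , drop = FALSE]
  a$row <- as.integer(rownames(a))
  if (!nrow(a)) {
    return(list(resseq = integer(), resname = character(),
                iN = integer(), iCA = integer(), iC = integer(),
                iCprev = integer(), iNnext = integer()))
  }
  bb <- a[a$name %in% c("N", "CA", "C"), , drop = FALSE]
  if (nrow(bb)) {
    ord <- order(bb$resseq, bb$name, -bb$occ)
    bb <- bb[ord, , drop = FALSE]
    bb <- bb[!duplicated(bb[, c("resseq", "name")]), , drop = FALSE]
  }
  pick <- function(res, nm) {
    i <- bb$row[bb$resseq == res & bb$name == nm]
    if (length(i)) i[1L] else NA_integer_
  }
  resseq <- sort(unique(bb$resseq[bb$name == "CA"]))
  resname <- vapply(resseq, function(r) a$resname[a$resseq == r][1L], character(1L))
  iN <- vapply(resseq, pick, integer(1L), nm = "N")
  iCA <- vapply(resseq, pick, integer(1L), nm = "CA")
  iC <- vapply(resseq, pick, integer(1L), nm = "C")
  iCprev <- vapply(resseq - 1L, pick, integer(1L), nm = "C")
  iNnext <- vapply(resseq + 1L, pick, integer(1L), nm = "N")
  list(resseq = resseq, resname = resname, iN = iN, iCA = iCA, iC = iC,
       iCprev = iCprev, iNnext = iNnext)
}

.phi_psi_from_xyz <- function(xyz, idx) {
  n <- length(idx$resseq)
  phi <- rep(NA_real_, n)
  psi <- rep(NA_real_, n)
  ok_core <- !is.na(idx$iN) & !is.na(idx$iCA) & !is.na(idx$iC)
  okp <- ok_core & !is.na(idx$iCprev)
  if (any(okp)) {
    phi[okp] <- .dihedral_raw(xyz[idx$iCprev[okp], , drop = FALSE],
                              xyz[idx$iN[okp], , drop = FALSE],
                              xyz[idx$iCA[okp], , drop = FALSE],
                              xyz[idx$iC[okp], , drop = FALSE])
  }
  oks <- ok_core & !is.na(idx$iNnext)
  if (any(oks)) {
    psi[oks] <- .dihedral_raw(xyz[idx$iN[oks], , drop = FALSE],
                              xyz[idx$iCA[oks], , drop = FALSE],
                              xyz[idx$iC[oks], , drop = FALSE],
                              xyz[idx$iNnext[oks], , drop = FALSE])
  }
  list(phi = phi, psi = psi)
}

#' Backbone phi/psi angles for one frame
#'
#' phi is the C(i-1)-N-CA-C torsion and psi the N-CA-C-N(i+1) torsion. phi is
#' undefined for the first residue of a chain unless a capping group (e.g. an
#' ACE acetyl cap) supplies the preceding carbonyl carbon; psi is undefined
#' for the last residue. Residues missing a backbone atom get `NA` angles
#' with a warning rather than an error.
#'
#' @param frame an `md_frame`.
#' @param chain chain identifier (default "A").
#' @return data frame with columns `resseq`, `resname`, `phi`, `psi`.
#' @export
assign_phi_psi <- function(frame, chain = "A") {
  stopifnot(inherits(frame, "md_frame"))
  atoms <- frame$atoms
  rownames(atoms) <- seq_len(nrow(atoms))
  idx <- .backbone_index(atoms, chain)
  if (!length(idx$resseq)) {
    return(data.frame(resseq = integer(), resname = character(),
                      phi = numeric(), psi = numeric()))
  }
  incomplete <- is.na(idx$iN) | is.na(idx$iCA) | is.na(idx$iC)
  if (any(incomplete)) {
    warning(sprintf("residue(s) %s missing backbone atoms; dihedrals undefined",
                    paste(idx$resseq[incomplete], collapse = ", ")))
  }
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  pp <- .phi_psi_from_xyz(xyz, idx)
  data.frame(resseq = idx$resseq, resname = idx$resname,
             phi = pp$phi, psi = pp$psi)
}

#' Per-residue phi/psi matrices for a whole trajectory
#'
#' @param traj a `trajectory`.
#' @param chain chain identifier.
#' @return list with `resseq`, `resname`, and `phi`, `psi` matrices
#'   (residues x frames; columns are frames 0 .. n-1).
#' @export
trajectory_dihedrals <- function(traj, chain = "A") {
  stopifnot(inherits(traj, "trajectory"))
  atoms <- traj$atoms
  rownames(atoms) <- seq_len(nrow(atoms))
  idx <- .backbone_index(atoms, chain)
  nfr <- n_frames(traj)
  nres <- length(idx$resseq)
  phi <- matrix(NA_real_, nres, nfr)
  psi <- matrix(NA_real_, nres, nfr)
  for (f in seq_len(nfr)) {
    xyz <- traj$coords[, , f, drop = FALSE]
    dim(xyz) <- dim(traj$coords)[1:2]
    pp <- .phi_psi_from_xyz(xyz, idx)
    phi[, f] <- pp$phi
    psi[, f] <- pp$psi
  }
  rownames(phi) <- rownames(psi) <- idx$resseq
  list(resseq = idx$resseq, resname = idx$resname, phi = phi, psi = psi)
}

#' Per-residue conformation labels over a trajectory
#'
#' @inheritParams trajectory_dihedrals
#' @return character matrix (residues x frames) of labels with residue
#'   numbers as row names; columns correspond to frames 0 .. n-1.
#' @export
conformation_labels <- function(traj, chain = "A") {
  dh <- trajectory_dihedrals(traj, chain)
  lab <- matrix(classify_conformation(as.vector(dh$phi), as.vector(dh$psi)),
                nrow = nrow(dh$phi), dimnames = dimnames(dh$phi))
  lab
}

.pattern_string <- function(labels) {
  paste(ifelse(labels == "alpha_R", "R", "L"), collapse = "")
}

#' Detect alpha-strand segments in a label sequence
#'
#' An alpha-strand is a maximal run of at least `min_length` consecutive
#' residues whose labels strictly alternate between `alpha_R` and `alpha_L`
#' (alpha_R-alpha_L-alpha_R or alpha_L-alpha_R-alpha_L and longer). A
#' repeated identical label, any `other`/`undefined` residue, or a residue
#' numbering gap breaks a run.
#'
#' @param labels character vector of conformation labels ordered by residue.
#' @param resseq residue numbers aligned with `labels` (default consecutive
#'   from 1).
#' @param frame 0-based frame index recorded in the output (default `NA`).
#' @param min_length minimum segment length (default 3).
#' @return data frame with columns `frame`, `start_residue`, `length`,
#'   `pattern` (e.g. `"RLR"`), one row per maximal segment.
#' @export
detect_strands <- function(labels, resseq = seq_along(labels), frame = NA_integer_,
                           min_length = 3L) {
  stopifnot(length(labels) == length(resseq), min_length >= 2L)
  n <- length(labels)
  empty <- data.frame(frame = integer(), start_residue = integer(),
                      length = integer(), pattern = character())
  if (n < min_length) return(empty)
  ok <- labels %in% .STRAND_LABELS
  alt <- ok[-n] & ok[-1L] & labels[-n] != labels[-1L] &
    resseq[-1L] == resseq[-n] + 1L
  r <- rle(alt)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & r$lengths + 1L >= min_length
  if (!any(keep)) return(empty)
  segs <- lapply(which(keep), function(k) {
    s <- starts[k]
    len <- r$lengths[k] + 1L
    data.frame(frame = frame, start_residue = resseq[s], length = len,
               pattern = .pattern_string(labels[s:(s + len - 1L)]))
  })
  out <- do.call(rbind, segs)
  rownames(out) <- NULL
  out
}

#' Per-frame alpha-strand presence over a residue region
#'
#' A frame is counted as "present" when one detected alpha-strand segment
#' simultaneously covers every residue of the region (not when the residues
#' are individually in a helical quadrant at different times).
#'
#' @param traj a `trajectory`.
#' @param region integer vector of consecutive residue numbers, e.g. `72:74`.
#' @param chain chain identifier.
#' @param min_length minimum strand length passed to [detect_strands()].
#' @param labels optionally, a precomputed label matrix from
#'   [conformation_labels()] (rows named by residue number); when supplied
#'   `traj` is only used for the frame interval.
#' @return a `strand_series`: list with `region`, `present` (logical, one per
#'   frame), `segments` (data frame of all detected segments in all frames),
#'   `n_frames`, `frame_interval_ps`, `min_length`.
#' @export
strand_presence <- function(traj, region, chain = "A", min_length = 3L,
                            labels = NULL) {
  if (is.null(labels)) {
    stopifnot(inherits(traj, "trajectory"))
    labels <- conformation_labels(traj, chain)
  }
  resseq <- as.integer(rownames(labels))
  if (!all(region %in% resseq)) {
    stop(sprintf("region residue(s) %s not present in chain %s",
                 paste(setdiff(region, resseq), collapse = ", "), chain))
  }
  nfr <- ncol(labels)
  region <- sort(region)
  present <- logical(nfr)
  seg_list <- vector("list", nfr)
  for (f in seq_len(nfr)) {
    segs <- detect_strands(labels[, f], resseq = resseq, frame = f - 1L,
                           min_length = min_length)
    seg_list[[f]] <- segs
    if (nrow(segs)) {
      covers <- segs$start_residue <= min(region) &
        segs$start_residue + segs$length - 1L >= max(region)
      present[f] <- any(covers)
    }
  }
  structure(list(region = region, present = present,
                 segments = do.call(rbind, seg_list), n_frames = nfr,
                 frame_interval_ps = if (inherits(traj, "trajectory"))
                   traj$frame_interval_ps else 10,
                 min_length = min_length),
            class = "strand_series")
}

#' Occupancy and first-appearance time of an alpha-strand region
#'
#' Occupancy is the percentage of all frames (including frames with undefined
#' dihedrals, which count as absent) in which the region is covered by an
#' alpha-strand; the first-appearance time is the 0-based index of the first
#' such frame times the saving interval.
#'
#' @param series a `strand_series` from [strand_presence()].
#' @return an `occupancy_result`: list with `region`, `occupancy_percent`,
#'   `n_frames`, `n_present`, `first_appearance_ps` (`NA` when the strand
#'   never appears).
#' @export
occupancy <- function(series) {
  stopifnot(inherits(series, "strand_series"))
  nfr <- series$n_frames
  if (nfr < 1L) stop("occupancy is undefined for a zero-frame series")
  np <- sum(series$present)
  first <- if (np > 0L) {
    (which(series$present)[1L] - 1L) * series$frame_interval_ps
  } else {
    NA_real_
  }
  structure(list(region = series$region,
                 occupancy_percent = 100 * np / nfr,
                 n_frames = nfr, n_present = np,
                 first_appearance_ps = first),
            class = "occupancy_result")
}

#' @export
print.occupancy_result <- function(x, ...) {
  cat(sprintf("alpha-strand occupancy, region %d-%d\n",
              min(x$region), max(x$region)))
  cat(sprintf("  occupancy: %.2f%% (%d of %d frames)\n",
              x$occupancy_percent, x$n_present, x$n_frames))
  if (is.na(x$first_appearance_ps)) {
    cat("  first appearance: never\n")
  } else {
    cat(sprintf("  first appearance: %g ps\n", x$first_appearance_ps))
  }
  invisible(x)
}

#' @export
print.strand_series <- function(x, ...) {
  cat(sprintf("alpha-strand presence, region %d-%d: %d of %d frames\n",
              min(x$region), max(x$region), sum(x$present), x$n_frames))
  invisible(x)
}

#' Ramachandran time series for a residue region
#'
#' Tabulates phi, psi and the conformation label of each region residue in
#' every frame (for transition plots), and summarizes per residue the label
#' at the start of the run, the set of visited labels, and the first frame at
#' which the label changed from its initial value.
#'
#' @inheritParams strand_presence
#' @return a `ramachandran_series`: list with `table` (data frame: `residue`,
#'   `frame`, `time_ps`, `phi`, `psi`, `label`) and `summary` (data frame:
#'   `residue`, `initial_label`, `visited`, `first_change_frame`).
#' @export
ramachandran_series <- function(traj, region, chain = "A") {
  stopifnot(inherits(traj, "trajectory"))
  dh <- trajectory_dihedrals(traj, chain)
  if (!all(region %in% dh$resseq)) {
    stop(sprintf("region residue(s) %s not present in chain %s",
                 paste(setdiff(region, dh$resseq), collapse = ", "), chain))
  }
  ri <- match(sort(region), dh$resseq)
  nfr <- ncol(dh$phi)
  frames <- 0:(nfr - 1L)
  tab <- data.frame(
    residue = rep(dh$resseq[ri], each = nfr),
    frame = rep(frames, times = length(ri)),
    time_ps = rep(frames * traj$frame_interval_ps, times = length(ri)),
    phi = as.vector(t(dh$phi[ri, , drop = FALSE])),
    psi = as.vector(t(dh$psi[ri, , drop = FALSE]))
  )
  tab$label <- classify_conformation(tab$phi, tab$psi)
  summ <- do.call(rbind, lapply(ri, function(i) {
    lab <- classify_conformation(dh$phi[i, ], dh$psi[i, ])
    ini <- lab[1L]
    chg <- which(lab != ini)
    data.frame(residue = dh$resseq[i], initial_label = ini,
               visited = paste(sort(unique(lab)), collapse = ","),
               first_change_frame = if (length(chg)) chg[1L] - 1L else NA_integer_)
  }))
  structure(list(table = tab, summary = summ), class = "ramachandran_series")
}

#' @export
print.ramachandran_series <- function(x, ...) {
  cat(sprintf("Ramachandran series: %d residue(s), %d frame(s)\n",
              nrow(x$summary), max(x$table$frame) + 1L))
  print(x$summary)
  invisible(x)
}
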