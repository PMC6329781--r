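# Peptide-plane flip detection and snapshot superposition.
#
# A flip of the peptide plane carrying residue i moves that residue between
# the alpha_R and alpha_L quadrants between consecutive frames. Events are
# defined on the label series (the same bookkeeping that defines the
# alpha-strand); the carbonyl-vector rotation between the two frames can be
# attached separately as a descriptive quantity.

#' Detect peptide-plane flip events in a label series
#'
#' One event is recorded whenever a residue's conformation label changes
#' between `alpha_R` and `alpha_L` across consecutive frames (direction
#' `"R_to_L"` or `"L_to_R"`). With `gap = 1` a single intervening
#' `other`/`undefined` frame is tolerated; with the default `gap = 0` the
#' change must happen between adjacent frames.
#'
#' @param labels character matrix (residues x frames) from
#'   [conformation_labels()], or a character vector for a single residue.
#' @param resseq residue numbers; defaults to the matrix row names.
#' @param gap number of intervening non-helical frames tolerated (0 or 1).
#' @return data frame with columns `residue`, `frame_from`, `frame_to`
#'   (0-based frame indices) and `direction`.
#' @export
detect_flips <- function(labels, resseq = NULL, gap = 0L) {
  stopifnot(gap %in% c(0L, 1L))
  if (!is.matrix(labels)) labels <- matrix(labels, nrow = 1L)
  if (is.null(resseq)) {
    resseq <- if (!is.null(rownames(labels))) as.integer(rownames(labels))
              else seq_len(nrow(labels))
  }
  stopifnot(length(resseq) == nrow(labels))
  out <- lapply(seq_len(nrow(labels)), function(i) {
    lab <- labels[i, ]
    hel <- which(lab %in% .STRAND_LABELS)
    if (length(hel) < 2L) return(NULL)
    from <- hel[-length(hel)]
    to <- hel[-1L]
    ev <- lab[from] != lab[to] & (to - from) <= gap + 1L
    if (!any(ev)) return(NULL)
    data.frame(residue = resseq[i],
               frame_from = from[ev] - 1L,
               frame_to = to[ev] - 1L,
               direction = ifelse(lab[from[ev]] == "alpha_R",
                                  "R_to_L", "L_to_R"))
  })
  out <- do.call(rbind, out)
  if (is.null(out)) {
    out <- data.frame(residue = integer(), frame_from = integer(),
                      frame_to = integer(), direction = character())
  }
  rownames(out) <- NULL
  out
}

#' Angle between carbonyl C=O vectors of a residue in two frames
#'
#' Descriptive companion to [detect_flips()]: the rotation of the carbonyl
#' bond vector of residue `resseq` between two frames, in degrees.
#'
#' @param frame_a,frame_b `md_frame` objects sharing one topology.
#' @param resseq residue number.
#' @param chain chain identifier.
#' @return angle in degrees in `[0, 180]`.
#' @export
carbonyl_rotation <- function(frame_a, frame_b, resseq, chain = "A") {
  co_vec <- function(fr) {
    at <- fr$atoms[fr$atoms$chain == chain & fr$atoms$resseq == resseq, ]
    ci <- which(at$name == "C")[1L]
    oi <- which(at$name == "O")[1L]
    if (is.na(ci) || is.na(oi)) {
      stop(sprintf("residue %d lacks C or O atoms", resseq))
    }
    v <- as.numeric(at[oi, c("x", "y", "z")]) - as.numeric(at[ci, c("x", "y", "z")])
    v / sqrt(sum(v^2))
  }
  va <- co_vec(frame_a); vb <- co_vec(frame_b)
  acos(pmin(1, pmax(-1, sum(va * vb)))) * 180 / pi
}

#' Superpose two frames on an atom selection
#'
#' Convenience wrapper around [superpose()] selecting paired atoms from two
#' frames of one trajectory.
#'
#' @param frame_fixed,frame_mobile `md_frame` objects with identical atom
#'   ordering.
#' @param idx integer atom indices (rows of the atom table) to fit on.
#' @return a `superposition` object.
#' @export
superpose_frames <- function(frame_fixed, frame_mobile, idx) {
  superpose(.frame_xyz(frame_fixed, idx), .frame_xyz(frame_mobile, idx))
}

#' First alpha-strand frame superposed onto the initial conformation
#'
#' Retrieves the first frame of the trajectory and the first frame in which
#' the region forms an alpha-strand, superposes the latter onto the former on
#' the region's backbone N/CA/C atoms, and optionally writes the pair as a
#' two-model PDB file for visual comparison of the flipped peptide plane.
#'
#' @param traj a `trajectory`.
#' @param series a `strand_series` for the region of interest (with at least
#'   one present frame).
#' @param chain chain identifier.
#' @param path optional output path for a 2-model PDB (initial conformation
#'   first, superposed strand conformation second).
#' @return list with `initial` (frame 0), `strand` (the first strand frame,
#'   all atoms rigid-body fitted onto the initial frame), `frame_index`
#'   (0-based), `time_ps` and `superposition`.
#' @export
first_strand_snapshot <- function(traj, series, chain = "A", path = NULL) {
  stopifnot(inherits(traj, "trajectory"), inherits(series, "strand_series"))
  if (!any(series$present)) {
    stop("the region never forms an alpha-strand in this trajectory")
  }
  k <- which(series$present)[1L] - 1L
  f0 <- get_frame(traj, 0L)
  fk <- get_frame(traj, k)
  sel <- which(f0$atoms$chain == chain &
                 f0$atoms$resseq %in% series$region &
                 f0$atoms$name %in% c("N", "CA", "C"))
  if (length(sel) < 3L) stop("region backbone selection has fewer than 3 atoms")
  sup <- superpose_frames(f0, fk, sel)
  moved <- apply_superposition(sup, .frame_xyz(fk))
  fk$atoms$x <- moved[, 1L]; fk$atoms$y <- moved[, 2L]; fk$atoms$z <- moved[, 3L]
  if (!is.null(path)) {
    coords <- array(NA_real_, c(nrow(f0$atoms), 3L, 2L))
    coords[, , 1L] <- .frame_xyz(f0)
    coords[, , 2L] <- moved
    pair <- .new_trajectory(traj$atoms, coords, box = traj$box,
                            frame_interval_ps = traj$frame_interval_ps)
    write_multimodel_pdb(pair, path)
  }
  list(initial = f0, strand = fk, frame_index = k,
       time_ps = k * traj$frame_interval_ps, superposition = sup)
}
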