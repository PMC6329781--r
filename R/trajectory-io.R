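# Reading/writing multi-model PDB trajectories and frame-level selections.
#
# A `trajectory` holds one topology (atom table) plus a coordinate array
# [n_atoms x 3 x n_frames]. Frames are numbered from 0 so that
# time_ps = frame * frame_interval_ps, with the first saved frame at t = 0.

.WATER_RESNAMES <- c("HOH", "SOL", "TIP3", "TIP", "WAT")
.ION_RESNAMES <- c("NA", "CL", "SOD", "CLA", "K", "POT", "MG", "ZN",
                   "CA2", "NA+", "CL-")

#' System condition metadata
#'
#' Descriptive metadata for a simulated system (no effect on any computation):
#' a label such as "system 2", the simulation temperature, the pH class and
#' the sequence variant.
#'
#' @param label free-text system label.
#' @param temperature_K simulation temperature in Kelvin (> 0).
#' @param ph_class `"neutral"` or `"low"`.
#' @param variant sequence variant, e.g. `"WT"`, `"A30P"`.
#' @return a list of class `system_condition`.
#' @export
system_condition <- function(label = "unnamed", temperature_K = 300,
                             ph_class = c("neutral", "low"), variant = "WT") {
  ph_class <- match.arg(ph_class)
  stopifnot(is.numeric(temperature_K), temperature_K > 0)
  structure(list(label = label, temperature_K = temperature_K,
                 ph_class = ph_class, variant = variant),
            class = "system_condition")
}

.new_trajectory <- function(atoms, coords, box = NULL, frame_interval_ps = 10,
                            condition = NULL) {
  stopifnot(is.data.frame(atoms), length(dim(coords)) == 3L,
            dim(coords)[1L] == nrow(atoms), dim(coords)[2L] == 3L)
  if (!is.numeric(frame_interval_ps) || frame_interval_ps <= 0) {
    stop("'frame_interval_ps' must be a positive number")
  }
  structure(list(atoms = atoms, coords = coords, box = box,
                 frame_interval_ps = frame_interval_ps,
                 condition = condition),
            class = "trajectory")
}

#' Number of frames in a trajectory
#' @param traj a `trajectory`.
#' @return integer frame count.
#' @export
n_frames <- function(traj) {
  stopifnot(inherits(traj, "trajectory"))
  dim(traj$coords)[3L]
}

# Diagnostic re-scan used only when the fast reader fails: locates the first
# malformed ATOM/HETATM record (reported by line number) or an inconsistent
# per-model atom count.
.diagnose_pdb <- function(path, original = NULL) {
  lines <- readLines(path, warn = FALSE)
  rec <- substr(lines, 1L, 6L)
  is_atom <- rec %in% c("ATOM  ", "HETATM")
  at <- which(is_atom)
  if (length(at)) {
    short <- nchar(lines[at]) < 54L
    if (any(short)) {
      stop(sprintf("malformed ATOM record at line %d of '%s': line too short",
                   at[which(short)[1L]], path))
    }
    coords <- suppressWarnings(cbind(
      as.numeric(substr(lines[at], 31L, 38L)),
      as.numeric(substr(lines[at], 39L, 46L)),
      as.numeric(substr(lines[at], 47L, 54L))))
    bad <- which(!stats::complete.cases(coords))
    if (length(bad)) {
      stop(sprintf("malformed ATOM record at line %d of '%s': non-numeric coordinates",
                   at[bad[1L]], path))
    }
  }
  model_starts <- which(substr(lines, 1L, 5L) == "MODEL")
  if (length(model_starts) > 1L) {
    counts <- vapply(seq_along(model_starts), function(i) {
      from <- model_starts[i]
      to <- if (i < length(model_starts)) model_starts[i + 1L] - 1L else length(lines)
      sum(is_atom[from:to])
    }, integer(1L))
    if (length(unique(counts)) > 1L) {
      stop(sprintf(
        "topology error in '%s': models have inconsistent atom counts (%s)",
        path, paste(unique(counts), collapse = ", ")))
    }
  }
  if (!is.null(original)) stop(original)
  invisible(TRUE)
}

.read_cryst1 <- function(path) {
  head <- readLines(path, n = 200L, warn = FALSE)
  cl <- head[substr(head, 1L, 6L) == "CRYST1"]
  if (!length(cl)) return(NULL)
  box <- suppressWarnings(as.numeric(c(substr(cl[1L], 7L, 15L),
                                       substr(cl[1L], 16L, 24L),
                                       substr(cl[1L], 25L, 33L))))
  if (anyNA(box) || any(box <= 0)) NULL else box
}

#' Read a multi-model PDB file as a trajectory
#'
#' Each MODEL/ENDMDL block becomes one frame; a file without MODEL records is
#' read as a single-frame trajectory. Atom order, names and residue numbering
#' are preserved exactly as printed. The saving interval is not stored in PDB
#' files and is supplied by the caller (default 10 ps, the usual interval for
#' coordinates saved during production runs).
#'
#' @param path path to a PDB file.
#' @param frame_interval_ps time between saved frames, picoseconds.
#' @param condition optional [system_condition()] metadata.
#' @return a `trajectory`: list with `atoms` (data frame: `serial`, `name`,
#'   `resname`, `chain`, `resseq`, `occ`, `element`), `coords`
#'   (n_atoms x 3 x n_frames array, Angstrom), `box` (length-3 vector or
#'   NULL), `frame_interval_ps`, `condition`.
#' @export
read_multimodel_pdb <- function(path, frame_interval_ps = 10, condition = NULL) {
  if (!file.exists(path)) stop(sprintf("file '%s' does not exist", path))
  pdb <- tryCatch(
    suppressWarnings(bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)),
    error = function(e) .diagnose_pdb(path, original = e)
  )
  xyz <- pdb$xyz
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1L)
  if (anyNA(xyz)) .diagnose_pdb(path)
  nat <- nrow(pdb$atom)
  if (ncol(xyz) != 3L * nat) .diagnose_pdb(path)
  nfr <- nrow(xyz)
  coords <- aperm(array(t(xyz), dim = c(3L, nat, nfr)), c(2L, 1L, 3L))
  element <- pdb$atom$elesy
  no_el <- is.na(element) | element == ""
  element[no_el] <- substr(gsub("[^A-Za-z].*", "", pdb$atom$elety[no_el]), 1L, 1L)
  atoms <- data.frame(
    serial = pdb$atom$eleno,
    name = trimws(pdb$atom$elety),
    resname = trimws(pdb$atom$resid),
    chain = ifelse(is.na(pdb$atom$chain), " ", pdb$atom$chain),
    resseq = pdb$atom$resno,
    occ = ifelse(is.na(pdb$atom$o), 1, pdb$atom$o),
    element = trimws(element),
    stringsAsFactors = FALSE
  )
  .new_trajectory(atoms, coords, box = .read_cryst1(path),
                  frame_interval_ps = frame_interval_ps, condition = condition)
}

.format_atom_lines <- function(atoms, xyz) {
  nm <- atoms$name
  name_field <- ifelse(nchar(nm) >= 4L, sprintf("%-4s", substr(nm, 1L, 4L)),
                       sprintf(" %-3s", nm))
  sprintf("ATOM  %5d %s %3.3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          atoms$serial %% 100000L, name_field,
          atoms$resname, substr(atoms$chain, 1L, 1L),
          atoms$resseq, xyz[, 1L], xyz[, 2L], xyz[, 3L],
          atoms$occ, 0, atoms$element)
}

#' Write a trajectory as a multi-model PDB file
#'
#' One MODEL/ENDMDL pair per frame, coordinates at the standard 3-decimal PDB
#' precision; a CRYST1 record is emitted when the trajectory carries a box.
#'
#' @param traj a `trajectory` (non-empty).
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_multimodel_pdb <- function(traj, path) {
  stopifnot(inherits(traj, "trajectory"))
  nfr <- n_frames(traj)
  if (is.null(nfr) || nfr < 1L || nrow(traj$atoms) < 1L) {
    stop("cannot write an empty trajectory")
  }
  con <- file(path, open = "wt")
  on.exit(close(con))
  if (!is.null(traj$box)) {
    writeLines(sprintf("CRYST1%9.3f%9.3f%9.3f%7.2f%7.2f%7.2f P 1           1",
                       traj$box[1L], traj$box[2L], traj$box[3L], 90, 90, 90), con)
  }
  for (f in seq_len(nfr)) {
    writeLines(sprintf("MODEL     %4d", f), con)
    writeLines(.format_atom_lines(traj$atoms, traj$coords[, , f, drop = FALSE][, , 1L]), con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

#' Extract a single frame from a trajectory
#'
#' @param traj a `trajectory`.
#' @param frame 0-based frame (model) index; frame `f` is at
#'   `f * frame_interval_ps` picoseconds.
#' @return an `md_frame`: list with `atoms` (the topology table plus `x`,
#'   `y`, `z` columns), `box`, `model_index` and `time_ps`.
#' @export
get_frame <- function(traj, frame = 0L) {
  stopifnot(inherits(traj, "trajectory"))
  nfr <- n_frames(traj)
  if (frame < 0L || frame >= nfr) {
    stop(sprintf("frame %d out of range [0, %d]", frame, nfr - 1L))
  }
  atoms <- traj$atoms
  xyz <- traj$coords[, , frame + 1L, drop = FALSE][, , 1L, drop = FALSE]
  dim(xyz) <- dim(traj$coords)[1:2]
  atoms$x <- xyz[, 1L]; atoms$y <- xyz[, 2L]; atoms$z <- xyz[, 3L]
  structure(list(atoms = atoms, box = traj$box, model_index = frame,
                 time_ps = frame * traj$frame_interval_ps),
            class = "md_frame")
}

.frame_xyz <- function(frame, idx = NULL) {
  a <- frame$atoms
  if (!is.null(idx)) a <- a[idx, , drop = FALSE]
  as.matrix(a[, c("x", "y", "z")])
}

#' Select atoms of given residues
#'
#' @param frame an `md_frame`.
#' @param resseq integer vector of residue numbers (PDB numbering, as printed
#'   in the file).
#' @param chain chain identifier (default "A").
#' @return the matching rows of the frame's atom table, original order
#'   preserved (possibly zero rows).
#' @export
select_residues <- function(frame, resseq, chain = "A") {
  stopifnot(inherits(frame, "md_frame"))
  frame$atoms[frame$atoms$chain == chain & frame$atoms$resseq %in% resseq, ,
              drop = FALSE]
}

#' Split a frame into protein, waters and ions
#'
#' Waters are recognized by residue name and regrouped into one row per
#' molecule with the three site positions; a water with a missing hydrogen is
#' an error because the TIP3P pair energy needs all three sites.
#'
#' @param frame an `md_frame`.
#' @param water_resnames residue names treated as water.
#' @param ion_resnames residue names treated as monatomic ions.
#' @return list with `protein` (atom table), `waters` (a `water_set` data
#'   frame: `residue_seq`, `ox`, `oy`, `oz`, `h1x` ... `h2z`), and `ions`
#'   (atom table).
#' @export
split_protein_water <- function(frame, water_resnames = .WATER_RESNAMES,
                                ion_resnames = .ION_RESNAMES) {
  stopifnot(inherits(frame, "md_frame"))
  a <- frame$atoms
  is_w <- a$resname %in% water_resnames
  is_i <- !is_w & a$resname %in% ion_resnames
  wat <- a[is_w, , drop = FALSE]
  waters <- if (nrow(wat)) {
    key <- paste(wat$chain, wat$resseq)
    groups <- split(seq_len(nrow(wat)), factor(key, levels = unique(key)))
    rows <- lapply(groups, function(ii) {
      sub <- wat[ii, , drop = FALSE]
      is_o <- sub$element == "O" | grepl("^O", sub$name)
      is_h <- sub$element == "H" | grepl("^H", sub$name)
      if (sum(is_o) != 1L || sum(is_h) != 2L) {
        stop(sprintf(
          "water residue %s %d has %d oxygen(s) and %d hydrogen(s); need exactly 1 and 2",
          sub$resname[1L], sub$resseq[1L], sum(is_o), sum(is_h)))
      }
      o <- sub[is_o, c("x", "y", "z")]
      h <- sub[is_h, c("x", "y", "z")]
      data.frame(residue_seq = sub$resseq[1L],
                 ox = o[1, 1], oy = o[1, 2], oz = o[1, 3],
                 h1x = h[1, 1], h1y = h[1, 2], h1z = h[1, 3],
                 h2x = h[2, 1], h2y = h[2, 2], h2z = h[2, 3])
    })
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
  } else {
    data.frame(residue_seq = integer(), ox = numeric(), oy = numeric(),
               oz = numeric(), h1x = numeric(), h1y = numeric(),
               h1z = numeric(), h2x = numeric(), h2y = numeric(),
               h2z = numeric())
  }
  list(protein = a[!is_w & !is_i, , drop = FALSE],
       waters = waters,
       ions = a[is_i, , drop = FALSE])
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("MD trajectory: %d atoms, %d frame(s), %.4g ps between frames\n",
              nrow(x$atoms), n_frames(x), x$frame_interval_ps))
  if (!is.null(x$box)) {
    cat(sprintf("  box: %.2f x %.2f x %.2f Angstrom\n",
                x$box[1L], x$box[2L], x$box[3L]))
  }
  if (!is.null(x$condition)) {
    cat(sprintf("  condition: %s (%s, %g K, %s pH)\n", x$condition$label,
                x$condition$variant, x$condition$temperature_K,
                x$condition$ph_class))
  }
  invisible(x)
}

#' @export
print.md_frame <- function(x, ...) {
  cat(sprintf("Frame %d (t = %.4g ps): %d atoms\n",
              x$model_index, x$time_ps, nrow(x$atoms)))
  invisible(x)
}
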