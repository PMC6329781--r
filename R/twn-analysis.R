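# Topological water network (TWN) analysis: TIP3P water-water pair energies,
# the hydrogen-bond graph at a pair-energy criterion, counts of
# three-membered water rings (triangles) near selected residues, and the
# strand / non-strand stratified summary table.
#
# The pair energy of waters a and b is the nine Coulomb site-site terms plus
# one oxygen-oxygen Lennard-Jones term:
#   v(a,b) = sum_i sum_j k q_i q_j / r_ij + A / r_oo^12 - C / r_oo^6
# with the rigid TIP3P parameters A = 582,000 kcal A^12/mol,
# C = 595 kcal A^6/mol, q_O = -0.834 e, q_H = +0.417 e. Two waters are
# hydrogen-bonded when v(a,b) <= -2.25 kcal/mol (the minimum of the
# pair-energy distribution of liquid water).

#' TIP3P pair-energy parameters
#'
#' @param A oxygen-oxygen repulsion coefficient, kcal A^12 / mol.
#' @param C oxygen-oxygen attraction coefficient, kcal A^6 / mol.
#' @param q_O,q_H site charges, elementary charge units (must sum to zero
#'   over one molecule: q_O + 2 q_H = 0).
#' @param coulomb_constant conversion factor e^2 -> kcal A / mol
#'   (332.0636; the pair-energy equation is written in e^2/r units and the
#'   constant is exposed here).
#' @param hbond_energy_cutoff hydrogen-bond criterion, kcal/mol; a pair is
#'   bonded when its energy is less than or equal to this value.
#' @return a list of class `tip3p_parameters`.
#' @export
tip3p_parameters <- function(A = 582000, C = 595, q_O = -0.834, q_H = 0.417,
                             coulomb_constant = 332.0636,
                             hbond_energy_cutoff = -2.25) {
  if (abs(q_O + 2 * q_H) > 1e-9) {
    stop("charges must sum to zero over one water molecule (q_O + 2 q_H = 0)")
  }
  structure(list(A = A, C = C, q_O = q_O, q_H = q_H,
                 coulomb_constant = coulomb_constant,
                 hbond_energy_cutoff = hbond_energy_cutoff),
            class = "tip3p_parameters")
}

.water_sites <- function(w) {
  # one water -> 3 x 3 matrix of site coordinates (O, H1, H2)
  if (is.data.frame(w)) w <- as.numeric(w[1L, c("ox", "oy", "oz", "h1x", "h1y",
                                                "h1z", "h2x", "h2y", "h2z")])
  matrix(w, nrow = 3L, byrow = TRUE)
}

.water_matrix <- function(waters) {
  as.matrix(waters[, c("ox", "oy", "oz", "h1x", "h1y", "h1z",
                       "h2x", "h2y", "h2z")])
}

#' TIP3P water-water pair interaction energy
#'
#' @param a,b one water each: either a single row of a `water_set` data frame
#'   (see [split_protein_water()]) or a numeric length-9 vector
#'   (O, H1, H2 coordinates).
#' @param params a [tip3p_parameters()] object.
#' @return energy in kcal/mol (symmetric in `a` and `b`).
#' @export
pair_energy <- function(a, b, params = tip3p_parameters()) {
  sa <- .water_sites(a)
  sb <- .water_sites(b)
  q <- c(params$q_O, params$q_H, params$q_H)
  d <- sqrt(outer(rowSums(sa^2), rowSums(sb^2), "+") - 2 * sa %*% t(sb))
  if (any(!is.finite(d)) || any(d < 1e-9)) {
    stop("coincident sites: pair energy is singular")
  }
  e_coul <- params$coulomb_constant * sum(outer(q, q) / d)
  roo <- d[1L, 1L]
  e_coul + params$A / roo^12 - params$C / roo^6
}

# Vectorized pair energies for index pairs (i, j) into a water matrix.
# When `box` is given, molecule j is shifted by the minimum-image offset of
# the O-O displacement (the molecule is moved rigidly, never split).
.pair_energies <- function(wm, i, j, params, box = NULL) {
  a <- wm[i, , drop = FALSE]
  b <- wm[j, , drop = FALSE]
  if (!is.null(box)) {
    dO <- b[, 1:3, drop = FALSE] - a[, 1:3, drop = FALSE]
    shift <- -round(sweep(dO, 2L, box, "/")) %*% diag(box)
    b <- b + cbind(shift, shift, shift)
  }
  q <- c(params$q_O, params$q_H, params$q_H)
  e <- numeric(nrow(a))
  for (si in 1:3) {
    for (sj in 1:3) {
      dx <- a[, 3 * si - 2] - b[, 3 * sj - 2]
      dy <- a[, 3 * si - 1] - b[, 3 * sj - 1]
      dz <- a[, 3 * si] - b[, 3 * sj]
      r <- sqrt(dx * dx + dy * dy + dz * dz)
      e <- e + params$coulomb_constant * q[si] * q[sj] / r
    }
  }
  dx <- a[, 1] - b[, 1]; dy <- a[, 2] - b[, 2]; dz <- a[, 3] - b[, 3]
  roo2 <- dx * dx + dy * dy + dz * dz
  e + params$A / roo2^6 - params$C / roo2^3
}

# Minimum-image O-O distances for all pairs i < j; returns list(i, j, d).
.oo_pairs <- function(O, box = NULL, within = Inf) {
  n <- nrow(O)
  if (n < 2L) return(list(i = integer(), j = integer(), d = numeric()))
  ij <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  i <- ij[, 1L]; j <- ij[, 2L]
  d <- O[i, , drop = FALSE] - O[j, , drop = FALSE]
  if (!is.null(box)) d <- d - round(sweep(d, 2L, box, "/")) %*% diag(box)
  dist <- sqrt(rowSums(d * d))
  keep <- dist <= within
  list(i = i[keep], j = j[keep], d = dist[keep])
}

#' Build the water hydrogen-bond graph
#'
#' Nodes are waters; an edge joins every pair whose TIP3P pair energy is at
#' or below the hydrogen-bond criterion. Pairs whose O-O distance exceeds
#' `prefilter_oo` are skipped without evaluating the energy; this is a pure
#' optimization (at 6 A separation no orientation reaches the -2.25 kcal/mol
#' criterion, which the test suite validates empirically), and
#' `prefilter_oo = Inf` disables it.
#'
#' @param waters a `water_set` data frame (one row per water).
#' @param params a [tip3p_parameters()] object.
#' @param prefilter_oo O-O distance prefilter in Angstrom (default 6).
#' @param box optional length-3 periodic box (Angstrom); minimum-image
#'   convention is applied to both the prefilter and the energies.
#' @return an `igraph` undirected simple graph whose vertices are the rows of
#'   `waters` and whose edges carry a `pair_energy` attribute (kcal/mol).
#' @export
build_hbond_graph <- function(waters, params = tip3p_parameters(),
                              prefilter_oo = 6, box = NULL) {
  n <- nrow(waters)
  g <- igraph::make_empty_graph(n = n, directed = FALSE)
  if (n < 2L) return(g)
  wm <- .water_matrix(waters)
  cand <- .oo_pairs(wm[, 1:3, drop = FALSE], box = box, within = prefilter_oo)
  if (!length(cand$i)) return(g)
  e <- .pair_energies(wm, cand$i, cand$j, params, box = box)
  keep <- e <= params$hbond_energy_cutoff
  if (any(keep)) {
    g <- igraph::add_edges(g, rbind(cand$i[keep], cand$j[keep]))
    igraph::E(g)$pair_energy <- e[keep]
  }
  g
}

#' Count three-membered water rings
#'
#' The number of triangles (3-cycles) in a hydrogen-bond graph.
#'
#' @param graph an `igraph` graph from [build_hbond_graph()].
#' @return nonnegative integer triangle count.
#' @export
count_three_rings <- function(graph) {
  as.integer(sum(igraph::count_triangles(graph)) / 3L)
}

.residue_center <- function(frame, residue_seq, chain = NULL,
                            center = c("calpha", "heavy")) {
  center <- match.arg(center)
  a <- frame$atoms
  sel <- a$resseq == residue_seq & !(a$resname %in% .WATER_RESNAMES)
  if (!is.null(chain)) sel <- sel & a$chain == chain
  a <- a[sel, , drop = FALSE]
  if (!nrow(a)) stop(sprintf("residue %d not present in frame", residue_seq))
  if (center == "calpha") {
    ca <- a[a$name == "CA", , drop = FALSE]
    if (!nrow(ca)) stop(sprintf("residue %d lacks a CA atom", residue_seq))
    as.matrix(ca[1L, c("x", "y", "z")])
  } else {
    h <- a[a$element != "H", , drop = FALSE]
    as.matrix(h[, c("x", "y", "z")])
  }
}

.min_dist_to_centers <- function(O, centers, box = NULL) {
  # distance from each O row to the nearest center row
  out <- rep(Inf, nrow(O))
  for (k in seq_len(nrow(centers))) {
    d <- sweep(O, 2L, as.numeric(centers[k, ]))
    if (!is.null(box)) d <- d - round(sweep(d, 2L, box, "/")) %*% diag(box)
    out <- pmin(out, sqrt(rowSums(d * d)))
  }
  out
}

#' Count water rings within a radius of a residue
#'
#' Selects the waters whose oxygen lies within `radius` of the residue
#' center and counts the three-membered rings among them. The default
#' follows the select-then-count reading: waters inside the sphere are
#' selected first and rings are counted among the selected waters only
#' (equivalently, triangles of the induced subgraph, i.e. all three oxygens
#' inside the sphere). `membership = "any"` instead counts rings of the
#' global graph with at least one member inside the sphere, for sensitivity
#' analysis of boundary-straddling rings.
#'
#' @param frame an `md_frame` containing the residue.
#' @param waters a `water_set` for the same frame.
#' @param residue_seq residue number defining the sphere center.
#' @param radius sphere radius in Angstrom (15 and 20 are the conventional
#'   choices).
#' @param params a [tip3p_parameters()] object.
#' @param graph optionally a precomputed [build_hbond_graph()] result for
#'   `waters` (built on the fly when `NULL`).
#' @param chain optional chain restriction for the residue lookup.
#' @param center `"calpha"` (sphere centered on the residue's C-alpha, the
#'   default) or `"heavy"` (within `radius` of any heavy atom of the
#'   residue).
#' @param membership `"all"` (all three oxygens inside, default) or `"any"`.
#' @param prefilter_oo,box passed to [build_hbond_graph()] when the graph is
#'   built here; `box` also applies minimum-image to water-residue distances.
#' @return nonnegative integer ring count.
#' @export
rings_near_residue <- function(frame, waters, residue_seq, radius,
                               params = tip3p_parameters(), graph = NULL,
                               chain = NULL, center = c("calpha", "heavy"),
                               membership = c("all", "any"),
                               prefilter_oo = 6, box = NULL) {
  membership <- match.arg(membership)
  centers <- .residue_center(frame, residue_seq, chain = chain,
                             center = match.arg(center))
  O <- .water_matrix(waters)[, 1:3, drop = FALSE]
  sel <- which(.min_dist_to_centers(O, centers, box = box) <= radius)
  if (is.null(graph)) {
    graph <- build_hbond_graph(waters, params, prefilter_oo = prefilter_oo,
                               box = box)
  }
  if (membership == "all") {
    if (length(sel) < 3L) return(0L)
    count_three_rings(igraph::induced_subgraph(graph, sel))
  } else {
    tri <- igraph::triangles(graph)
    if (!length(tri)) return(0L)
    tri <- matrix(as.integer(tri), ncol = 3L, byrow = TRUE)
    sum(tri[, 1L] %in% sel | tri[, 2L] %in% sel | tri[, 3L] %in% sel)
  }
}

#' Stratified summary of per-frame ring counts
#'
#' Aggregates a long table of per-frame, per-residue, per-radius ring counts
#' into per-residue means and their totals, stratified into strand and
#' non-strand frames. A stratum with zero frames is reported with `NA`
#' means (empty), not zero.
#'
#' @param counts data frame with columns `frame`, `residue_seq`, `radius`,
#'   `ring_count`, `strand_frame` (logical).
#' @return a `twn_table`: list with `per_residue` (data frame: `radius`,
#'   `stratum`, `residue_seq`, `mean_rings`, `n_frames`) and `totals` (data
#'   frame: `radius`, `stratum`, `total_rings`, `n_frames`), where each total
#'   is the sum of that stratum's per-residue means.
#' @export
summarize_ring_counts <- function(counts) {
  need <- c("frame", "residue_seq", "radius", "ring_count", "strand_frame")
  stopifnot(all(need %in% names(counts)))
  counts$stratum <- ifelse(counts$strand_frame, "strand", "non_strand")
  radii <- sort(unique(counts$radius))
  residues <- sort(unique(counts$residue_seq))
  strata <- c("non_strand", "strand")
  per <- expand.grid(radius = radii, stratum = strata, residue_seq = residues,
                     stringsAsFactors = FALSE)
  per$mean_rings <- NA_real_
  per$n_frames <- 0L
  for (r in seq_len(nrow(per))) {
    sub <- counts[counts$radius == per$radius[r] &
                    counts$stratum == per$stratum[r] &
                    counts$residue_seq == per$residue_seq[r], ]
    per$n_frames[r] <- length(unique(sub$frame))
    if (nrow(sub)) per$mean_rings[r] <- mean(sub$ring_count)
  }
  tot <- expand.grid(radius = radii, stratum = strata, stringsAsFactors = FALSE)
  tot$total_rings <- NA_real_
  tot$n_frames <- 0L
  for (r in seq_len(nrow(tot))) {
    sub <- per[per$radius == tot$radius[r] & per$stratum == tot$stratum[r], ]
    tot$n_frames[r] <- max(sub$n_frames)
    if (all(!is.na(sub$mean_rings))) tot$total_rings[r] <- sum(sub$mean_rings)
  }
  structure(list(per_residue = per, totals = tot, counts = counts),
            class = "twn_table")
}

#' Topological water network summary over a trajectory
#'
#' For every frame, splits off the solvent, builds the hydrogen-bond graph,
#' counts the three-membered rings within each radius of each residue, and
#' aggregates the counts stratified by whether the frame shows the
#' alpha-strand (per the supplied presence series).
#'
#' @param traj a `trajectory` whose frames contain waters.
#' @param series a `strand_series` aligned to `traj` (or a logical vector,
#'   one entry per frame).
#' @param residues residue numbers around which rings are counted.
#' @param radii vector of sphere radii in Angstrom (default `c(15, 20)`).
#' @param params a [tip3p_parameters()] object.
#' @param chain chain of the target residues.
#' @inheritParams rings_near_residue
#' @param use_box apply minimum-image convention when the trajectory has a
#'   periodic box (default TRUE).
#' @return a `twn_table` (see [summarize_ring_counts()]).
#' @export
twn_summary <- function(traj, series, residues, radii = c(15, 20),
                        params = tip3p_parameters(), chain = "A",
                        center = "calpha", membership = "all",
                        prefilter_oo = 6, use_box = TRUE) {
  stopifnot(inherits(traj, "trajectory"))
  present <- if (inherits(series, "strand_series")) series$present else series
  nfr <- n_frames(traj)
  stopifnot(length(present) == nfr)
  box <- if (use_box) traj$box else NULL
  rows <- vector("list", nfr)
  for (f in seq_len(nfr)) {
    fr <- get_frame(traj, f - 1L)
    sw <- split_protein_water(fr)
    g <- build_hbond_graph(sw$waters, params, prefilter_oo = prefilter_oo,
                           box = box)
    grid <- expand.grid(residue_seq = residues, radius = radii)
    grid$ring_count <- mapply(function(res, rad) {
      rings_near_residue(fr, sw$waters, res, rad, params = params, graph = g,
                         chain = chain, center = center,
                         membership = membership, box = box)
    }, grid$residue_seq, grid$radius)
    grid$frame <- f - 1L
    grid$strand_frame <- present[f]
    rows[[f]] <- grid
  }
  summarize_ring_counts(do.call(rbind, rows))
}

#' @export
print.twn_table <- function(x, digits = 2, ...) {
  cat("Three-membered water-ring summary (means per stratum)\n")
  for (rad in unique(x$per_residue$radius)) {
    for (st in unique(x$per_residue$stratum)) {
      sub <- x$per_residue[x$per_residue$radius == rad &
                             x$per_residue$stratum == st, ]
      tot <- x$totals[x$totals$radius == rad & x$totals$stratum == st, ]
      if (!tot$n_frames) {
        cat(sprintf("  %2g A  %-10s  (no frames)\n", rad, st))
      } else {
        cat(sprintf("  %2g A  %-10s  %s | total %s  (n=%d)\n", rad, st,
                    paste(sprintf(paste0("%.", digits, "f"), sub$mean_rings),
                          collapse = " "),
                    sprintf(paste0("%.", digits, "f"), tot$total_rings),
                    tot$n_frames))
      }
    }
  }
  invisible(x)
}
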