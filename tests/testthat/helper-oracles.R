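# Independent oracles and fixture builders. Every oracle here deliberately
# uses a different algorithm from the implementation it checks: explicit
# loops and enumeration instead of vectorized run-length or graph-library
# code.

# --- alpha-strand brute force -----------------------------------------------
# Grows an alternating window from every start position and keeps the
# maximal ones; independent of the rle-based detector.
oracle_strands <- function(labels, resseq = seq_along(labels), min_length = 3L) {
  n <- length(labels)
  helical <- labels %in% c("alpha_R", "alpha_L")
  pair_ok <- function(i) {
    helical[i] && helical[i + 1L] && labels[i] != labels[i + 1L] &&
      resseq[i + 1L] == resseq[i] + 1L
  }
  out <- NULL
  for (s in seq_len(n)) {
    if (s > 1L && pair_ok(s - 1L)) next   # not maximal: extends left
    e <- s
    while (e < n && pair_ok(e)) e <- e + 1L
    if (e - s + 1L >= min_length) {
      out <- rbind(out, data.frame(
        start_residue = resseq[s], length = e - s + 1L,
        pattern = paste(ifelse(labels[s:e] == "alpha_R", "R", "L"),
                        collapse = "")))
    }
  }
  if (is.null(out)) {
    out <- data.frame(start_residue = integer(), length = integer(),
                      pattern = character())
  }
  out
}

random_labels <- function(n, p_helical = 0.5) {
  sample(c("alpha_R", "alpha_L", "other", "undefined"), n, replace = TRUE,
         prob = c(p_helical / 2, p_helical / 2, 1 - p_helical - 0.05, 0.05))
}

# --- TIP3P term-by-term oracle ----------------------------------------------
# Literal transcription of the pair-energy equation: nine explicit Coulomb
# terms plus one oxygen-oxygen Lennard-Jones term.
oracle_pair_energy <- function(a, b, params = tip3p_parameters()) {
  if (is.data.frame(a)) a <- as.numeric(a[1, c("ox", "oy", "oz", "h1x", "h1y",
                                               "h1z", "h2x", "h2y", "h2z")])
  if (is.data.frame(b)) b <- as.numeric(b[1, c("ox", "oy", "oz", "h1x", "h1y",
                                               "h1z", "h2x", "h2y", "h2z")])
  sa <- matrix(a, nrow = 3, byrow = TRUE)
  sb <- matrix(b, nrow = 3, byrow = TRUE)
  q <- c(params$q_O, params$q_H, params$q_H)
  e <- 0
  for (i in 1:3) {
    for (j in 1:3) {
      r <- sqrt(sum((sa[i, ] - sb[j, ])^2))
      e <- e + params$coulomb_constant * q[i] * q[j] / r
    }
  }
  roo <- sqrt(sum((sa[1, ] - sb[1, ])^2))
  e + params$A / roo^12 - params$C / roo^6
}

# Random water: position plus random rigid orientation of a TIP3P monomer.
random_water <- function(center = runif(3, 0, 20)) {
  rot <- qr.Q(qr(matrix(rnorm(9), 3)))
  if (det(rot) < 0) rot[, 1] <- -rot[, 1]
  oh <- 0.9572
  a2 <- 104.52 * pi / 180
  h1 <- center + as.numeric(rot %*% c(oh, 0, 0))
  h2 <- center + as.numeric(rot %*% (oh * c(cos(a2), sin(a2), 0)))
  data.frame(residue_seq = 1L, ox = center[1], oy = center[2], oz = center[3],
             h1x = h1[1], h1y = h1[2], h1z = h1[3],
             h2x = h2[1], h2y = h2[2], h2z = h2[3])
}

random_water_set <- function(n, box = c(20, 20, 20)) {
  rows <- lapply(seq_len(n), function(i) {
    w <- random_water(runif(3, 0, box))
    w$residue_seq <- i
    w
  })
  do.call(rbind, rows)
}

# Ideal linear TIP3P dimer: donor O-H aimed at the acceptor oxygen, the
# acceptor's hydrogens symmetric about the O-O axis pointing away.
ideal_dimer <- function(roo = 2.75) {
  oh <- 0.9572
  a2 <- 104.52 * pi / 180
  half <- a2 / 2
  donor <- data.frame(residue_seq = 1L, ox = 0, oy = 0, oz = 0,
                      h1x = oh, h1y = 0, h1z = 0,
                      h2x = oh * cos(a2), h2y = oh * sin(a2), h2z = 0)
  acceptor <- data.frame(residue_seq = 2L, ox = roo, oy = 0, oz = 0,
                         h1x = roo + oh * cos(half), h1y = oh * sin(half), h1z = 0,
                         h2x = roo + oh * cos(half), h2y = -oh * sin(half), h2z = 0)
  rbind(donor, acceptor)
}

# --- triangle brute force ---------------------------------------------------
# Enumerates all C(n, 3) vertex triples against the adjacency matrix.
oracle_triangles <- function(graph) {
  n <- igraph::vcount(graph)
  if (n < 3) return(0L)
  adj <- as.matrix(igraph::as_adjacency_matrix(graph)) > 0
  trip <- utils::combn(n, 3)
  sum(adj[cbind(trip[1, ], trip[2, ])] &
        adj[cbind(trip[2, ], trip[3, ])] &
        adj[cbind(trip[1, ], trip[3, ])])
}

random_graph <- function(n, p = 0.15) {
  g <- igraph::make_empty_graph(n = n, directed = FALSE)
  pairs <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  keep <- runif(nrow(pairs)) < p
  if (any(keep)) {
    g <- igraph::add_edges(g, rbind(pairs[keep, 1], pairs[keep, 2]))
  }
  g
}

# --- small structural fixtures ----------------------------------------------
# A backbone whose region residues carry an alpha-strand and whose flanks
# are beta-like.
strand_host_frame <- function(flank = 2L, region_names = c("THR", "GLY", "VAL"),
                              resseq_start = 1L) {
  phis <- c(rep(-120, flank), -60, 60, -60, rep(-120, flank))
  psis <- c(rep(130, flank), -45, 45, -45, rep(130, flank))
  nm <- c(rep("ALA", flank), region_names, rep("ALA", flank))
  build_backbone(phis, psis, resnames = nm, resseq_start = resseq_start)
}

# Frame -> single-frame trajectory (for writer tests).
frame_as_trajectory <- function(frame, frame_interval_ps = 10) {
  xyz <- as.matrix(frame$atoms[, c("x", "y", "z")])
  coords <- array(xyz, c(nrow(xyz), 3, 1))
  alphastrand:::.new_trajectory(
    frame$atoms[, setdiff(names(frame$atoms), c("x", "y", "z"))],
    coords, frame_interval_ps = frame_interval_ps)
}
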