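test_that("pair energy matches the term-by-term oracle and its limits", {
  params <- tip3p_parameters()
  # long-range: all terms decay, |v| below 0.01 kcal/mol at 100 A
  far <- rbind(random_water(c(0, 0, 0)), random_water(c(100, 0, 0)))
  expect_lt(abs(pair_energy(far[1, ], far[2, ])), 0.01)
  # coincident sites are singular
  w <- random_water(c(0, 0, 0))
  expect_error(pair_energy(w, w), "singular|coincident")
  # random geometries against the literal equation
  set.seed(12)
  for (i in 1:50) {
    a <- random_water(runif(3, 0, 10))
    b <- random_water(runif(3, 0, 10) + c(3, 0, 0))
    expect_equal(pair_energy(a, b, params), oracle_pair_energy(a, b, params),
                 tolerance = 1e-12)
    # symmetry
    expect_equal(pair_energy(a, b, params), pair_energy(b, a, params),
                 tolerance = 1e-12)
  }
})

test_that("an ideal linear hydrogen-bonded dimer satisfies the criterion", {
  d <- ideal_dimer(2.75)
  e <- pair_energy(d[1, ], d[2, ])
  expect_lte(e, -2.25)
  expect_equal(e, oracle_pair_energy(d[1, ], d[2, ]), tolerance = 1e-12)
})

test_that("pair energy is invariant under a common rigid transform", {
  set.seed(14)
  a <- random_water(c(1, 2, 3))
  b <- random_water(c(4, 2, 3))
  e0 <- pair_energy(a, b)
  Q <- qr.Q(qr(matrix(rnorm(9), 3)))
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  shift <- c(-7, 3, 12)
  move <- function(w) {
    m <- matrix(as.numeric(w[1, -1]), 3, byrow = TRUE) %*% t(Q) +
      rep(shift, each = 3)
    out <- w
    out[1, -1] <- as.vector(t(m))
    out
  }
  expect_equal(pair_energy(move(a), move(b)), e0, tolerance = 1e-9)
})

test_that("the hydrogen-bond graph applies the energy criterion exactly", {
  params <- tip3p_parameters()
  # two far waters: no edge
  far <- rbind(random_water(c(0, 0, 0)), random_water(c(50, 0, 0)))
  far$residue_seq <- 1:2
  expect_equal(igraph::ecount(build_hbond_graph(far, params)), 0)
  # planted trimer: exactly 3 edges, 1 triangle
  tri <- water_trimer(c(5, 5, 5), params = params)
  g <- build_hbond_graph(tri, params)
  expect_equal(igraph::ecount(g), 3)
  expect_equal(count_three_rings(g), 1)
  expect_true(all(igraph::E(g)$pair_energy <= params$hbond_energy_cutoff))
  # edge present exactly when the energy is at or below the cutoff:
  # stretch the ideal dimer through the criterion
  for (roo in seq(2.6, 4.5, by = 0.1)) {
    d <- ideal_dimer(roo)
    e <- pair_energy(d[1, ], d[2, ])
    has_edge <- igraph::ecount(build_hbond_graph(d, params)) == 1
    expect_identical(has_edge, e <= params$hbond_energy_cutoff)
  }
})

test_that("the O-O prefilter never changes the graph", {
  set.seed(16)
  for (i in 1:20) {
    w <- random_water_set(30, box = c(18, 18, 18))
    g_pre <- build_hbond_graph(w, prefilter_oo = 6)
    g_all <- build_hbond_graph(w, prefilter_oo = Inf)
    expect_identical(igraph::as_edgelist(g_pre), igraph::as_edgelist(g_all))
  }
})

test_that("triangle counting equals brute-force triple enumeration", {
  expect_equal(count_three_rings(igraph::make_full_graph(3)), 1)
  expect_equal(count_three_rings(igraph::make_full_graph(4)), 4)
  expect_equal(count_three_rings(igraph::make_ring(4)), 0)
  set.seed(18)
  for (i in 1:40) {
    g <- random_graph(sample(3:40, 1), p = runif(1, 0.05, 0.4))
    expect_equal(count_three_rings(g), oracle_triangles(g))
  }
})

test_that("ring counting near a residue respects the sphere and its modes", {
  fr <- build_backbone(rep(-60, 5), rep(-45, 5))
  ca <- as.numeric(fr$atoms[fr$atoms$resseq == 3 & fr$atoms$name == "CA",
                            c("x", "y", "z")])
  box <- water_box_spec(n_background = 0,
                        trimer_centers = rbind(ca + c(5, 0, 0)),
                        box = c(60, 60, 60), seed = 20)
  w <- generate_water_box(box)
  expect_equal(rings_near_residue(fr, w, 3, 15), 1)
  expect_equal(rings_near_residue(fr, w, 3, 3), 0)
  expect_error(rings_near_residue(fr, w, 99, 15), "not present")
  # residue without CA
  fr_noca <- fr
  fr_noca$atoms <- fr_noca$atoms[!(fr_noca$atoms$resseq == 3 &
                                     fr_noca$atoms$name == "CA"), ]
  expect_error(rings_near_residue(fr_noca, w, 3, 15), "CA")
  # planted in/out counts, cross-checked against restricted brute force
  centers <- rbind(ca + c(6, 0, 0), ca + c(0, 8, 0), ca + c(0, 0, 18),
                   ca + c(0, -18, 0))
  w2 <- generate_water_box(water_box_spec(n_background = 0,
                                          trimer_centers = centers,
                                          box = c(80, 80, 80), seed = 21))
  g2 <- build_hbond_graph(w2)
  expect_equal(rings_near_residue(fr, w2, 3, 15, graph = g2), 2)
  expect_equal(rings_near_residue(fr, w2, 3, 20, graph = g2), 4)
  O <- as.matrix(w2[, c("ox", "oy", "oz")])
  inside <- which(sqrt(colSums((t(O) - ca)^2)) <= 15)
  expect_equal(rings_near_residue(fr, w2, 3, 15, graph = g2),
               oracle_triangles(igraph::induced_subgraph(g2, inside)))
  # monotone in the radius
  for (rad in c(5, 10, 15, 20, 30)) {
    expect_lte(rings_near_residue(fr, w2, 3, rad, graph = g2),
               rings_near_residue(fr, w2, 3, rad + 5, graph = g2))
  }
  # "any"-membership counts boundary-straddling rings too
  expect_gte(rings_near_residue(fr, w2, 3, 15, graph = g2, membership = "any"),
             rings_near_residue(fr, w2, 3, 15, graph = g2))
})

test_that("stratified summary means, totals and empty strata behave as defined", {
  # single-frame trajectory with one trimer near each of 3 residues
  fr <- build_backbone(rep(-60, 6), rep(-45, 6), resseq_start = 1)
  ca3 <- as.numeric(fr$atoms[fr$atoms$resseq == 3 & fr$atoms$name == "CA",
                             c("x", "y", "z")])
  # three well-separated trimers, all within 15 A of every region residue
  centers <- rbind(ca3 + c(8, 0, 0), ca3 + c(-8, 0, 0), ca3 + c(0, 8, 0))
  w <- generate_water_box(water_box_spec(n_background = 0,
                                         trimer_centers = centers,
                                         box = c(80, 80, 80), seed = 23))
  tr <- generate_trajectory(
    synthetic_trajectory_spec(n_residues = 6, n_frames = 1, region = 2:4,
                              episodes = list(c(0, 0))), waters = w)$trajectory
  tw <- twn_summary(tr, series = c(TRUE), residues = 2:4, radii = 20)
  strand_rows <- tw$per_residue[tw$per_residue$stratum == "strand", ]
  expect_equal(strand_rows$mean_rings, c(3, 3, 3))  # all trimers within 20 A
  expect_equal(tw$totals$total_rings[tw$totals$stratum == "strand"], 9)
  # the non-strand stratum has no frames: reported empty, not zero
  ns <- tw$totals[tw$totals$stratum == "non_strand", ]
  expect_equal(ns$n_frames, 0)
  expect_true(is.na(ns$total_rings))
})

test_that("summary totals always equal the sum of per-residue means", {
  set.seed(25)
  counts <- expand.grid(frame = 0:19, residue_seq = 72:75, radius = c(15, 20))
  counts$ring_count <- rpois(nrow(counts), 8)
  counts$strand_frame <- counts$frame %in% 5:9
  tw <- summarize_ring_counts(counts)
  for (r in seq_len(nrow(tw$totals))) {
    sub <- tw$per_residue[tw$per_residue$radius == tw$totals$radius[r] &
                            tw$per_residue$stratum == tw$totals$stratum[r], ]
    expect_equal(tw$totals$total_rings[r], sum(sub$mean_rings), tolerance = 1e-12)
  }
})
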