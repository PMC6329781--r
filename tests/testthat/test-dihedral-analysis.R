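test_that("torsion angles follow the standard convention", {
  # planar cis -> 0, planar trans -> 180
  expect_equal(dihedral_angle(c(1, 1, 0), c(1, 0, 0), c(-1, 0, 0), c(-1, 1, 0)), 0)
  expect_equal(dihedral_angle(c(1, 1, 0), c(1, 0, 0), c(-1, 0, 0), c(-1, -1, 0)), 180)
  # collinear points have no torsion
  expect_error(dihedral_angle(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0), c(3, 1, 0)),
               "collinear|undefined")
  # output range is (-180, 180]
  set.seed(42)
  for (i in 1:20) {
    p <- matrix(rnorm(12), 4)
    a <- dihedral_angle(p[1, ], p[2, ], p[3, ], p[4, ])
    expect_true(a > -180 && a <= 180)
  }
})

test_that("phi/psi agree with an independent torsion implementation", {
  spec <- synthetic_trajectory_spec(n_residues = 8, n_frames = 1, region = 3:5,
                                    episodes = list(c(0, 0)), spread_deg = 8,
                                    seed = 7)
  tr <- generate_trajectory(spec)$trajectory
  path <- withr::local_tempfile(fileext = ".pdb")
  write_multimodel_pdb(tr, path)
  ref <- bio3d::torsion.pdb(bio3d::read.pdb(path))
  ours <- assign_phi_psi(get_frame(read_multimodel_pdb(path), 0))
  expect_equal(ours$phi[-1], ref$phi[-1], tolerance = 1e-4)
  expect_equal(ours$psi[-8], ref$psi[-8], tolerance = 1e-4)
})

test_that("quadrant classification matches the strict-inequality rule", {
  expect_identical(classify_conformation(-60, -45), "alpha_R")
  expect_identical(classify_conformation(57, 47), "alpha_L")
  expect_identical(classify_conformation(-120, 130), "other")   # beta region
  expect_identical(classify_conformation(0, 50), "other")        # boundary
  expect_identical(classify_conformation(50, 180), "other")      # boundary
  expect_identical(classify_conformation(NA, 50), "undefined")
  # partition property: exactly one label for any defined pair
  set.seed(1)
  phi <- runif(500, -180, 180); psi <- runif(500, -180, 180)
  lab <- classify_conformation(phi, psi)
  expect_true(all(lab %in% c("alpha_R", "alpha_L", "other")))
  # label invariant under within-quadrant perturbation
  lab2 <- classify_conformation(sign(phi) * pmin(abs(phi) * 0.5, 179),
                                sign(psi) * pmin(abs(psi) * 0.5, 179))
  expect_identical(lab2[lab != "other"], lab[lab != "other"])
})

test_that("chain termini have undefined dihedrals and ACE caps define phi of residue 1", {
  fr <- build_backbone(c(-60, 60, -60), c(-45, 45, -45))
  pp <- assign_phi_psi(fr)
  expect_equal(nrow(pp), 3)
  expect_true(is.na(pp$phi[1]) && is.na(pp$psi[3]))
  expect_false(anyNA(c(pp$phi[2], pp$psi[2])))

  # acetylated N-terminus: convert residue 1 into an ACE cap (CH3-C=O)
  fr4 <- build_backbone(c(-60, -70, 65, -60), c(-45, -40, 40, -45))
  atoms <- fr4$atoms
  cap <- atoms$resseq == 1
  atoms$resname[cap] <- "ACE"
  atoms$name[cap & atoms$name == "CA"] <- "CH3"
  atoms <- atoms[!(cap & atoms$name == "N"), ]
  fr_ace <- structure(list(atoms = atoms, box = NULL, model_index = 0L,
                           time_ps = 0), class = "md_frame")
  pp_ace <- assign_phi_psi(fr_ace)
  expect_equal(pp_ace$resseq, 2:4)     # the cap itself is not a residue
  expect_false(is.na(pp_ace$phi[1]))   # phi defined through the cap's C
  # verify against a direct four-atom torsion
  x <- function(res, nm) {
    as.numeric(atoms[atoms$resseq == res & atoms$name == nm, c("x", "y", "z")])
  }
  direct <- dihedral_angle(x(1, "C"), x(2, "N"), x(2, "CA"), x(2, "C"))
  expect_equal(pp_ace$phi[1], direct, tolerance = 1e-10)
})

test_that("missing backbone atoms yield a warning and undefined labels, not an error", {
  fr <- strand_host_frame()
  fr$atoms <- fr$atoms[!(fr$atoms$resseq == 4 & fr$atoms$name == "N"), ]
  expect_warning(pp <- assign_phi_psi(fr), "missing backbone")
  expect_true(is.na(pp$phi[pp$resseq == 4]))
})

test_that("strand detection matches the named patterns and breaks correctly", {
  R <- "alpha_R"; L <- "alpha_L"; O <- "other"
  s1 <- detect_strands(c(R, L, R))
  expect_equal(s1$length, 3)
  expect_equal(s1$pattern, "RLR")
  s2 <- detect_strands(c(R, L, R, L))
  expect_equal(nrow(s2), 1)
  expect_equal(s2$length, 4)
  expect_equal(nrow(detect_strands(c(R, R, L))), 0)       # repeat breaks alternation
  s3 <- detect_strands(c(R, O, L, R, L))
  expect_equal(s3$start_residue, 3)
  expect_equal(s3$length, 3)
  # numbering gap breaks a window
  s4 <- detect_strands(c(R, L, R), resseq = c(1, 2, 5))
  expect_equal(nrow(s4), 0)
})

test_that("strand detection equals the brute-force alternating-window oracle", {
  set.seed(99)
  for (i in 1:200) {
    lab <- random_labels(sample(3:40, 1))
    got <- detect_strands(lab)
    want <- oracle_strands(lab)
    expect_equal(got[, c("start_residue", "length", "pattern")], want,
                 ignore_attr = TRUE)
  }
})

test_that("longer minimum lengths select a subset of segments by span", {
  set.seed(5)
  for (i in 1:50) {
    lab <- random_labels(30, p_helical = 0.7)
    s3 <- detect_strands(lab, min_length = 3)
    s4 <- detect_strands(lab, min_length = 4)
    span <- function(d) paste(d$start_residue, d$start_residue + d$length - 1)
    expect_true(all(span(s4) %in% span(s3)))
    expect_true(all(s4$length >= 4))
  }
})

test_that("region presence requires the whole region in one alternating segment", {
  spec <- synthetic_trajectory_spec(n_residues = 12, n_frames = 40,
                                    region = 5:7,
                                    episodes = list(c(3, 9), c(20, 24)),
                                    seed = 21)
  g <- generate_trajectory(spec)
  sp <- strand_presence(g$trajectory, 5:7)
  expect_identical(sp$present, g$truth$present)
  expect_error(strand_presence(g$trajectory, 50:52), "not present")
})

test_that("occupancy and first-appearance arithmetic follow the frame/time mapping", {
  mk_series <- function(present, interval = 10) {
    structure(list(region = 72:74, present = present,
                   segments = NULL, n_frames = length(present),
                   frame_interval_ps = interval, min_length = 3L),
              class = "strand_series")
  }
  all_true <- occupancy(mk_series(rep(TRUE, 50)))
  expect_equal(all_true$occupancy_percent, 100)
  expect_equal(all_true$first_appearance_ps, 0)
  late <- occupancy(mk_series(c(rep(FALSE, 207), rep(TRUE, 93))))
  expect_equal(late$first_appearance_ps, 2070)
  never <- occupancy(mk_series(rep(FALSE, 10)))
  expect_true(is.na(never$first_appearance_ps))
  expect_equal(never$occupancy_percent, 0)
})

test_that("ramachandran series reports the schema, initial labels and transitions", {
  spec <- synthetic_trajectory_spec(n_residues = 8, n_frames = 30, region = 3:5,
                                    episodes = list(c(10, 19)), seed = 3)
  g <- generate_trajectory(spec)
  rs <- ramachandran_series(g$trajectory, 3:5)
  expect_named(rs$table, c("residue", "frame", "time_ps", "phi", "psi", "label"))
  expect_equal(nrow(rs$table), 3 * 30)
  expect_equal(unique(rs$table$time_ps), (0:29) * 10)
  # residue 4 starts beta-ish ("other") and visits alpha_L during the episode
  r4 <- rs$summary[rs$summary$residue == 4, ]
  expect_true(grepl("alpha_L", r4$visited))
  # a single-frame trajectory gives one row per region residue
  g1 <- generate_trajectory(synthetic_trajectory_spec(
    n_residues = 8, n_frames = 1, region = 3:5, episodes = list(c(0, 0))))
  expect_equal(nrow(ramachandran_series(g1$trajectory, 3:5)$table), 3)
})

test_that("first-transition frames recover the planted episode onset", {
  spec <- synthetic_trajectory_spec(n_residues = 10, n_frames = 60,
                                    region = 4:6, episodes = list(c(25, 40)),
                                    seed = 13,
                                    transition_matrix = diag(4))  # frozen background
  g <- generate_trajectory(spec)
  rs <- ramachandran_series(g$trajectory, 4:6)
  r5 <- rs$summary[rs$summary$residue == 5, ]
  expect_equal(r5$first_change_frame, 25)
  expect_identical(sort(strsplit(r5$visited, ",")[[1]]),
                   c("alpha_L", "other"))
})
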