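rot_z_90 <- matrix(c(0, -1, 0, 1, 0, 0, 0, 0, 1), 3, byrow = TRUE)

random_cloud <- function(n) matrix(rnorm(3 * n, sd = 5), ncol = 3)

test_that("Kabsch superposition is exact on self and rigid copies", {
  set.seed(81)
  X <- random_cloud(10)
  self <- kabsch_superpose(X, X)
  expect_equal(self$rmsd, 0, tolerance = 1e-9)
  expect_equal(self$rotation, diag(3), tolerance = 1e-9)

  moved <- sweep(X %*% t(rot_z_90), 2, c(5, -3, 2), `+`)
  sup <- kabsch_superpose(X, moved)
  expect_equal(sup$rmsd, 0, tolerance = 1e-9)
  # recovered transform inverts the applied one
  expect_equal(sup$rotation %*% rot_z_90, diag(3), tolerance = 1e-9)
  expect_equal(apply_superposition(sup, moved), X, tolerance = 1e-9)
  expect_equal(det(sup$rotation), 1, tolerance = 1e-9)
})

test_that("Kabsch RMSD matches the quaternion-method oracle", {
  set.seed(82)
  for (i in 1:20) {
    A <- random_cloud(6)
    B <- random_cloud(6)
    sup <- kabsch_superpose(A, B)
    expect_equal(sup$rmsd, quaternion_superpose_rmsd(A, B),
                 tolerance = 1e-9)
    expect_equal(det(sup$rotation), 1, tolerance = 1e-9)
  }
})

test_that("RMSD is invariant under rigid transforms of the mobile set", {
  set.seed(83)
  A <- random_cloud(8)
  B <- random_cloud(8)
  base <- kabsch_superpose(A, B)$rmsd
  for (i in 1:5) {
    q <- rnorm(4); q <- q / sqrt(sum(q^2))
    R <- matrix(c(
      1 - 2 * (q[3]^2 + q[4]^2), 2 * (q[2] * q[3] - q[1] * q[4]),
      2 * (q[2] * q[4] + q[1] * q[3]),
      2 * (q[2] * q[3] + q[1] * q[4]), 1 - 2 * (q[2]^2 + q[4]^2),
      2 * (q[3] * q[4] - q[1] * q[2]),
      2 * (q[2] * q[4] - q[1] * q[3]), 2 * (q[3] * q[4] + q[1] * q[2]),
      1 - 2 * (q[2]^2 + q[3]^2)), 3, byrow = TRUE)
    Bt <- sweep(B %*% t(R), 2, runif(3, -20, 20), `+`)
    expect_equal(kabsch_superpose(A, Bt)$rmsd, base, tolerance = 1e-9)
  }
  expect_error(kabsch_superpose(A[1:2, ], B[1:2, ]), "at least 3")
  line <- cbind(1:5, 0, 0)
  expect_error(kabsch_superpose(line + rnorm(15, sd = 1e-14), line),
               "degenerate")
})

test_that("probe displacement reads out a planted local shift", {
  toys <- make_toy_structures(seed = 7, shift = 1.3, probe_res = 8)
  align <- list(resno = setdiff(1:12, 8), elety = "CA")
  probe <- list(resno = 8, elety = "CA")
  d <- ca_displacement(toys$model_a, toys$model_b, align,
                       probe_a = probe)
  expect_equal(as.numeric(d), 1.3, tolerance = 1e-6)

  # identical structures -> zero displacement
  d0 <- ca_displacement(toys$model_a, toys$model_a, align,
                        probe_a = probe)
  expect_equal(as.numeric(d0), 0, tolerance = 1e-9)

  expect_error(ca_displacement(toys$model_a, toys$model_b,
                               list(resno = 99), probe_a = probe),
               "no atoms")
  expect_error(ca_displacement(toys$model_a, toys$model_b, align,
                               probe_a = list(resno = 1:2)),
               "exactly one atom")
})

# Minimal phospho-serine / lysine fixture mimicking the pS8-K604 pairing.
saltbridge_model <- function(d_nz_o1p = 3.4) {
  structure_model(data.frame(
    chain = c("A", "A", "B", "B", "B"),
    resno = c(604L, 604L, 8L, 8L, 8L),
    resid = c("LYS", "LYS", "SEP", "SEP", "SEP"),
    elety = c("NZ", "CE", "O1P", "O2P", "CA"),
    elesy = c("N", "C", "O", "O", "C"),
    x = c(0, 0.5, d_nz_o1p, d_nz_o1p + 6, 10),
    y = 0, z = 0, stringsAsFactors = FALSE))
}

test_that("salt-bridge census pairs charged groups within the cutoff", {
  m <- saltbridge_model(3.4)
  cen <- contact_census(m, list(chain = "A"), list(chain = "B"),
                        mode = "saltbridge")
  expect_equal(attr(cen, "count"), 1)
  expect_equal(cen$atom_a, "NZ")
  expect_equal(cen$atom_b, "O1P")
  expect_equal(cen$distance, 3.4, tolerance = 1e-9)
  # symmetric in the two selections
  rev <- contact_census(m, list(chain = "B"), list(chain = "A"),
                        mode = "saltbridge")
  expect_equal(attr(rev, "count"), 1)
  # beyond the cutoff -> empty
  far <- saltbridge_model(5)
  expect_equal(attr(contact_census(far, list(chain = "A"),
                                   list(chain = "B"), cutoff = 4,
                                   mode = "saltbridge"), "count"), 0)
  expect_error(contact_census(m, list(chain = "Z"), list(chain = "B"),
                              mode = "saltbridge"), "empty")
})

test_that("heavy-atom H-bond census equals the all-pairs oracle", {
  set.seed(85)
  for (i in 1:5) {
    n <- 12
    atoms <- data.frame(
      chain = rep(c("A", "B"), each = n),
      resno = rep(seq_len(n), 2),
      resid = "GLY",
      elety = rep(c("N", "O"), n),
      elesy = rep(c("N", "O"), n),
      x = runif(2 * n, 0, 8), y = runif(2 * n, 0, 8),
      z = runif(2 * n, 0, 8), stringsAsFactors = FALSE)
    m <- structure_model(atoms)
    cen <- contact_census(m, list(chain = "A"), list(chain = "B"),
                          cutoff = 3.5, mode = "hbond_heavy")
    a <- as.matrix(atoms[atoms$chain == "A", c("x", "y", "z")])
    b <- as.matrix(atoms[atoms$chain == "B", c("x", "y", "z")])
    expect_equal(attr(cen, "count"), brute_pairs_within(a, b, 3.5))
  }
})

test_that("conservation colours follow the red-to-white ramp", {
  expect_equal(conservation_colour(100)$hex, "#FF0000")
  expect_equal(conservation_colour(95)$hex, "#FF0000")
  mid <- conservation_colour(92.5)           # midpoint of the ramp
  expect_equal(mid$g, 128L)
  expect_equal(mid$g, mid$b)
  expect_equal(conservation_colour(90)$hex, "#FFFFFF")
  expect_equal(conservation_colour(50)$hex, "#FFFFFF")
  # monotone: less identity is never redder
  ramp <- conservation_colour(seq(100, 80, by = -0.5))
  expect_true(all(diff(ramp$g) >= 0))
  expect_error(conservation_colour(101), "0, 100")
})

test_that("conservation maps into the B-factor channel", {
  toys <- make_toy_structures(seed = 9)
  ident <- data.frame(residue_number = 1:12,
                      identity_pct = seq(100, 45, length.out = 12))
  res <- conservation_to_structure(toys$model_a, ident)
  expect_equal(res$model$b, ident$identity_pct)
  expect_equal(nrow(res$colours), 12)
  bad <- data.frame(residue_number = 1, identity_pct = 150)
  expect_error(conservation_to_structure(toys$model_a, bad), "0, 100")
})

test_that("structure models survive a PDB round-trip", {
  toys <- make_toy_structures(seed = 10)
  f <- tempfile(fileext = ".pdb")
  write_structure(toys$model_a, f)
  back <- read_structure(f)
  expect_equal(nrow(back), nrow(toys$model_a))
  expect_equal(back$x, toys$model_a$x, tolerance = 1e-3)
  expect_equal(back$resno, toys$model_a$resno)
  expect_equal(back$elety, toys$model_a$elety)
})
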