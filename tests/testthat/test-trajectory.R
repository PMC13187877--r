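test_that("Kabsch superposition recovers exact rigid transforms", {
  set.seed(1)
  ref <- matrix(rnorm(30), 10, 3)
  fit0 <- kabsch_superpose(ref, ref)
  expect_equal(fit0$rmsd, 0, tolerance = 1e-12)
  expect_equal(fit0$rotation, diag(3), tolerance = 1e-10)

  th <- 1.1
  R <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  mob <- ref %*% t(R) + matrix(c(3, -1, 2), 10, 3, byrow = TRUE)
  fit <- kabsch_superpose(mob, ref)
  expect_lt(fit$rmsd, 1e-8)
  expect_equal(det(fit$rotation), 1, tolerance = 1e-10)

  # RMSD invariant under a common rigid transform of both sets
  both <- kabsch_superpose(mob + 5, ref %*% t(R) + 5)
  set.seed(2)
  mob2 <- ref + matrix(rnorm(30, sd = 0.3), 10, 3)
  r1 <- kabsch_superpose(mob2, ref)$rmsd
  r2 <- kabsch_superpose(mob2 %*% t(R) + 7, ref %*% t(R) + 7)$rmsd
  expect_equal(r1, r2, tolerance = 1e-9)

  # collinear sets are rejected
  line <- cbind(1:5, 0, 0)
  expect_error(kabsch_superpose(line + 0.0, line), "collinear")
})

test_that("perturbing one point matches a grid-search over rotations", {
  # 4 points; push one along a direction orthogonal to every centred
  # coordinate axis change, then compare with brute-force minimisation over
  # a fine rotation grid
  base <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0))
  mob <- base
  delta <- 0.2
  mob[1, 3] <- mob[1, 3] + delta
  fit <- kabsch_superpose(mob, base)
  # brute force: rotations about x, y, z on a fine grid after centering
  ctr <- function(x) sweep(x, 2, colMeans(x))
  A <- ctr(mob); B <- ctr(base)
  best <- Inf
  for (ax in seq(-0.3, 0.3, by = 0.0025)) for (ay in seq(-0.2, 0.2, by = 0.0025)) {
    Rx <- rbind(c(1, 0, 0), c(0, cos(ax), -sin(ax)), c(0, sin(ax), cos(ax)))
    Ry <- rbind(c(cos(ay), 0, sin(ay)), c(0, 1, 0), c(-sin(ay), 0, cos(ay)))
    rmsd <- sqrt(mean(rowSums((A %*% t(Ry %*% Rx) - B)^2)))
    best <- min(best, rmsd)
  }
  expect_equal(fit$rmsd, best, tolerance = 1e-3)
})

test_that("RMSD series handles references, equilibration and T-scaling", {
  s <- make_structure(synthetic_spec(10, "ideal_helix"))
  fit <- nma(s, enm_model(12, 1), do_minimize = FALSE)
  # identical frames: all-zero series
  flat <- trajectory(matrix(rep(as.vector(t(coords(s))), 5), 5, byrow = TRUE), s)
  rs <- rmsd_series(flat)
  expect_equal(rs$values, rep(0, 5), tolerance = 1e-12)

  # equilibration bookkeeping: a 10-frame window drops exactly 10 values
  tr <- simulate_harmonic_trajectory(fit, 300, 50, seed = 2)
  r10 <- rmsd_series(tr, equilibration = 10)
  expect_equal(r10$n_excluded, 10L)
  expect_equal(r10$mean, mean(r10$values[11:50]))

  # amplitude scales as sqrt(T): T vs 4T gives ratio 2
  t1 <- simulate_harmonic_trajectory(fit, 100, 3000, seed = 3)
  t4 <- simulate_harmonic_trajectory(fit, 400, 3000, seed = 3)
  m1 <- rmsd_series(t1, equilibration = 0)$mean
  m4 <- rmsd_series(t4, equilibration = 0)$mean
  expect_equal(m4 / m1, 2, tolerance = 0.1)
  expect_error(rmsd_series(tr, reference_frame = 99), "frame")
})

test_that("RMSF profile matches the analytic harmonic covariance", {
  s <- make_structure(synthetic_spec(12, "ideal_helix"))
  fit <- nma(s, enm_model(12, 1), do_minimize = FALSE)
  Tk <- 300
  tr <- simulate_harmonic_trajectory(fit, Tk, 20000, seed = 11)
  prof <- rmsf_per_residue(tr)
  nzi <- setdiff(seq_along(fit$omega), fit$zero_idx)
  lam <- fit$omega[nzi]^2 / 418.4
  kbt <- 1.987204259e-3 * Tk
  pred <- vapply(1:12, function(i) {
    rows <- (3 * i - 2):(3 * i)
    sqrt(sum(kbt / lam * colSums(fit$vectors[rows, nzi, drop = FALSE]^2)) /
           masses(s)[i])
  }, numeric(1))
  expect_lt(max(abs(as.numeric(prof$values) - pred) / pred), 0.05)

  # identical frames: zero profile
  flat <- trajectory(matrix(rep(as.vector(t(coords(s))), 12), 12, byrow = TRUE), s)
  expect_equal(max(rmsf_per_residue(flat)$values), 0, tolerance = 1e-12)

  # a rigid rotation applied to every frame leaves the profile unchanged
  th <- 0.5
  R <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  tr2 <- tr
  short <- tr$frames[1:200, , drop = FALSE]
  rot <- t(apply(short, 1, function(fr) as.vector(t(matrix(fr, 12, 3, byrow = TRUE) %*% t(R)))))
  p1 <- rmsf_per_residue(trajectory(short, s))
  p2 <- rmsf_per_residue(trajectory(rot, s))
  expect_equal(as.numeric(p1$values), as.numeric(p2$values), tolerance = 1e-6)
})

test_that("trajectory readers round-trip multi-model PDB and frame tables", {
  s <- make_structure(synthetic_spec(6, "extended_chain"))
  fit <- nma(s, enm_model(12, 1), do_minimize = FALSE)
  tr <- simulate_harmonic_trajectory(fit, 200, 4, seed = 5)
  p <- withr::local_tempfile(fileext = ".pdb")
  lines <- c()
  for (k in 1:4) {
    tmp <- s
    tmp$atoms[, c("x", "y", "z")] <- matrix(tr$frames[k, ], 6, 3, byrow = TRUE)
    tf <- tempfile(); write_pdb(tmp, tf)
    body <- readLines(tf)
    body <- body[!grepl("^(TITLE|END)", body)]
    lines <- c(lines, sprintf("MODEL %8d", k), body, "ENDMDL")
    unlink(tf)
  }
  writeLines(c(lines, "END"), p)
  back <- read_trajectory_pdb(p)
  expect_equal(nrow(back$frames), 4L)
  expect_equal(back$frames, round(tr$frames, 3), tolerance = 1e-9,
               ignore_attr = TRUE)

  p2 <- withr::local_tempfile(fileext = ".txt")
  write.table(tr$frames, p2, row.names = FALSE, col.names = FALSE)
  back2 <- read_trajectory_table(p2, s)
  expect_equal(back2$frames, tr$frames, tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("salt bridges are detected within cutoff and deduplicated", {
  asp <- toy_asp(1)
  lys <- data.frame(name = c("N", "CA", "NZ"), element = c("N", "C", "N"),
                    resname = "LYS", resseq = 2, chain = "A", icode = "",
                    x = c(6, 7, 7.8), y = c(2.3, 2.3, 2.3), z = 0)
  s <- protein_structure(rbind(asp, lys))
  # OD1 at (4.4, 2.3, 0): NZ at (7.8, 2.3, 0) -> 3.4 A
  sb <- detect_salt_bridges(s)
  expect_equal(nrow(sb), 1L)
  expect_equal(sb$distance, 3.4, tolerance = 1e-9)

  lys_far <- lys; lys_far$x <- lys_far$x + 1.2
  expect_equal(nrow(detect_salt_bridges(protein_structure(rbind(asp, lys_far)))), 0L)

  # two ASP within reach of one LYS: two deduplicated pairs
  asp2 <- toy_asp(3, shift = c(6.8, 4.6, 0))
  asp2[, c("x")] <- rev(11.2 - (asp2$x - 6.8)) + 6.8  # mirror roughly toward NZ
  s3 <- protein_structure(rbind(asp, lys,
    within(toy_asp(3, shift = c(3.5, 0.1, 0)), {})))
  sb3 <- detect_salt_bridges(s3)
  expect_equal(nrow(sb3), 2L)
  expect_equal(anyDuplicated(paste(sb3$acid_ordinal, sb3$base_ordinal)), 0L)
})

test_that("hydrogen-bond counting applies both distance and angle gates", {
  mk <- function(bend = 180, dist = 2.9) {
    # donor N at origin, H along +x, acceptor O at `dist` from N, angle
    # N-H-O set by `bend`
    h <- c(1, 0, 0)
    ang <- bend * pi / 180
    o <- h + (dist - 1) * c(cos(pi - ang), sin(pi - ang), 0)
    # a spacer residue keeps donor and acceptor non-adjacent in ordinal
    protein_structure(data.frame(
      name = c("N", "H", "CA", "CA", "O"),
      element = c("N", "H", "C", "C", "O"),
      resname = "ALA", resseq = c(1, 1, 1, 3, 5), chain = "A", icode = "",
      x = c(0, h[1], 0.5, 30, o[1]), y = c(0, h[2], 1.2, 30, o[2]),
      z = c(0, 0, 0, 30, 0)))
  }
  expect_equal(as.integer(count_hbonds(mk(180))), 1L)
  expect_equal(as.integer(count_hbonds(mk(90))), 0L)    # angle gate
  expect_equal(as.integer(count_hbonds(mk(180, 4.2))), 0L)  # distance gate
  # region restriction: counting within 79..128 of a backbone helix
  s <- make_backbone_helix(128)
  cnt <- count_hbonds(s, region = c(79, 128))
  expect_equal(as.integer(cnt), 50L - 4L)
  expect_error(count_hbonds(s, region = c(50, 10)), "region")
})
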