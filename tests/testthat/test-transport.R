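# mode set + hessian for a small disordered chain, shared by several blocks
local_chain_modes <- function(n = 24, seed = 2) {
  set.seed(seed)
  s <- protein_structure(data.frame(
    name = "CA", element = "C", resname = "ALA", resseq = seq_len(n),
    chain = "A", x = 3.8 * (seq_len(n) - 1), y = 0, z = 0,
    mass = runif(n, 0.8, 1.2)))
  h <- build_hessian(s, spring_model(chain_springs(n)), warn_unminimized = FALSE)
  list(h = h, m = normal_modes(h), s = s)
}

test_that("diffusivity is zero without resonant partners and NA at zero modes", {
  # diatomic: a single internal mode has nobody to exchange energy with
  s <- chain_structure(2)
  h <- build_hessian(s, spring_model(chain_springs(2)), warn_unminimized = FALSE)
  m <- normal_modes(h)
  D <- mode_diffusivity(m, h, broadening = 5, dims = 1, stability_check = FALSE)
  expect_true(all(is.na(D$D[m$zero_idx])))
  expect_equal(D$D[!is.na(D$D)], 0)
  expect_error(mode_diffusivity(m, h, broadening = -1), "broadening")
})

test_that("perfect chain diffusivity grows as the broadening shrinks", {
  # harmonic-crystal (ballistic) divergence: with the broadening well above
  # the level spacing, D scales like 1/eta, so narrowing eta inflates D
  n <- 64
  s <- chain_structure(n)
  h <- build_hessian(s, spring_model(chain_springs(n)), warn_unminimized = FALSE)
  m <- normal_modes(h)
  D0 <- mode_diffusivity(m, h, dims = 1, stability_check = FALSE)
  ok <- which(!is.na(D0$D))
  spacing <- median(diff(sort(m$frequencies[ok])))
  d_wide <- mode_diffusivity(m, h, broadening = 8 * spacing, dims = 1,
                             stability_check = FALSE)$D[ok]
  d_narrow <- mode_diffusivity(m, h, broadening = 4 * spacing, dims = 1,
                               stability_check = FALSE)$D[ok]
  mid <- m$frequencies[ok] > quantile(m$frequencies[ok], 0.3) &
         m$frequencies[ok] < quantile(m$frequencies[ok], 0.9)
  expect_gt(median((d_narrow / d_wide)[mid]), 1.5)
  # and the per-mode flag reports the non-convergence
  D <- mode_diffusivity(m, h, dims = 1)
  expect_true(any(!D$stable[ok][mid]))
})

test_that("wave-packet oracle conserves energy and resolves locality", {
  cm <- local_chain_modes(32, seed = 4)
  w_mid <- wavepacket_oracle(cm$h, 16, t_max = 1.0, dims = 1)
  expect_lt(attr(w_mid, "energy_drift"), 1e-6)
  w_end <- wavepacket_oracle(cm$h, 2, t_max = 1.0, dims = 1)
  expect_lt(attr(w_end, "energy_drift"), 1e-6)
  # early-time spread differs between end and middle excitation
  expect_false(isTRUE(all.equal(attr(w_mid, "msd")[10], attr(w_end, "msd")[10])))
  expect_error(wavepacket_oracle(cm$h, 16, t_max = -1), "t_max")
})

test_that("stronger disorder transports energy more slowly", {
  build <- function(lo, hi, seed) {
    set.seed(seed)
    n <- 48
    s <- protein_structure(data.frame(
      name = "CA", element = "C", resname = "ALA", resseq = seq_len(n),
      chain = "A", x = 3.8 * (seq_len(n) - 1), y = 0, z = 0,
      mass = runif(n, lo, hi)))
    build_hessian(s, spring_model(chain_springs(n)), warn_unminimized = FALSE)
  }
  d_strong <- mean(vapply(1:3, function(sd.) {
    as.numeric(wavepacket_oracle(build(0.5, 2.0, sd.), 24, 0.8, dims = 1))
  }, numeric(1)))
  d_weak <- mean(vapply(1:3, function(sd.) {
    as.numeric(wavepacket_oracle(build(0.9, 1.1, sd.), 24, 0.8, dims = 1))
  }, numeric(1)))
  expect_lt(d_strong, d_weak)
})

test_that("band averaging selects nearest modes with low-frequency ties", {
  cm <- local_chain_modes(24)
  D <- mode_diffusivity(cm$m, cm$h, dims = 1, stability_check = FALSE)
  ok <- which(!is.na(D$D))
  # constant field: every band average equals the constant
  Dc <- D; Dc$D[ok] <- 7.5
  ba <- band_average(Dc, cm$m, band_spec(c(10, 40, 80), 5))
  expect_equal(ba$value, rep(7.5, 3))
  # synthetic D = frequency: band mean equals mean of the 10 nearest,
  # recomputed by direct sort
  Df <- D; Df$D[ok] <- cm$m$frequencies[ok]
  ba2 <- band_average(Df, cm$m, band_spec(100, 10))
  fr <- cm$m$frequencies[ok]
  want <- mean(fr[order(abs(fr - 100), fr)][1:10])
  expect_equal(ba2$value, want)
  # spectrum with exactly as many modes as the band: all centres identical
  cm2 <- local_chain_modes(11)
  D2 <- mode_diffusivity(cm2$m, cm2$h, dims = 1, stability_check = FALSE)
  ba3 <- band_average(D2, cm2$m, band_spec(c(5, 50, 500), 10))
  expect_equal(ba3$value[1], ba3$value[2])
  expect_equal(ba3$value[2], ba3$value[3])
})

test_that("thermal averaging applies classical and Bose weights correctly", {
  bv <- data.frame(center = c(50, 100, 150, 200, 300, 400), value = 3)
  expect_equal(thermal_average(bv, 300), 3)        # uniform weights
  expect_equal(thermal_average(bv, 500), 3)        # any T, equal values
  # amplitude scaling: linear in T
  m300 <- thermal_average(bv, 300, amplitude_scaling = TRUE)
  m340 <- thermal_average(bv, 340, amplitude_scaling = TRUE)
  expect_equal(m340 / m300, 340 / 300)
  # Bose weights follow the occupation ratio closed form
  bv2 <- data.frame(center = c(50, 400), value = c(1, 1))
  w50 <- 1 / expm1(1.43877688 * 50 / 300)
  w400 <- 1 / expm1(1.43877688 * 400 / 300)
  got <- thermal_average(data.frame(center = c(50, 400), value = c(1, 0)),
                         300, weights = "bose")
  expect_equal(got, w50 / (w50 + w400), tolerance = 1e-9)
  expect_error(thermal_average(bv, -3), "temperature")
})

test_that("communication maps are symmetric, non-negative and complete", {
  s <- make_structure(synthetic_spec(30, "ideal_helix"))
  fit <- nma(s, enm_model(12, 1), do_minimize = FALSE)
  D <- mode_diffusivity(fit, stability_check = FALSE)
  band <- scale_band_centers(fit)
  for (Tk in c(300, 340)) {
    mp <- communication_map(fit, D, s, band, temperature = Tk)
    expect_equal(mp$matrix, t(mp$matrix))
    expect_true(all(mp$matrix >= 0))
    # decomposition completeness: grand sum equals the thermally averaged
    # band mean of mode diffusivity
    want <- thermal_average(band_average(D, fit, band), Tk)
    expect_equal(sum(mp$matrix), want, tolerance = 1e-6)
  }
})

test_that("non-interacting sub-networks have zero cross-block coupling", {
  # two helices far apart: springs never bridge them under the cutoff
  a <- make_structure(synthetic_spec(12, "ideal_helix"))
  b_atoms <- a$atoms
  b_atoms$x <- b_atoms$x + 200
  b_atoms$resseq <- b_atoms$resseq + 12L
  s <- protein_structure(rbind(a$atoms[setdiff(names(a$atoms), "res_ord")],
                               b_atoms[setdiff(names(b_atoms), "res_ord")]))
  sp <- rbind(vedmap:::.enm_springs(coords(a), 12, 1),
              within(vedmap:::.enm_springs(coords(a), 12, 1),
                     {i <- i + 12L; j <- j + 12L}))
  h <- build_hessian(s, spring_model(sp), warn_unminimized = FALSE)
  m <- suppressWarnings(normal_modes(h))
  D <- mode_diffusivity(m, h, stability_check = FALSE)
  mp <- communication_map(m, D, s, band_spec(c(5, 10), 6), temperature = 300)
  off <- mp$matrix[1:12, 13:24]
  expect_lt(max(abs(off)), 1e-10 * max(mp$matrix))
})

test_that("difference maps subtract elementwise and antisymmetrise", {
  s <- make_structure(synthetic_spec(20, "ideal_helix"))
  fit <- nma(s, enm_model(12, 1), do_minimize = FALSE)
  D <- mode_diffusivity(fit, stability_check = FALSE)
  band <- scale_band_centers(fit)
  m300 <- communication_map(fit, D, s, band, 300, amplitude_scaling = TRUE)
  m340 <- communication_map(fit, D, s, band, 340, amplitude_scaling = TRUE)
  self <- difference_map(m300, m300)
  expect_equal(max(abs(self$matrix)), 0)
  d1 <- difference_map(m340, m300)
  d2 <- difference_map(m300, m340)
  expect_equal(d1$matrix, -d2$matrix)
  expect_equal(d1$temperature, c(340, 300))
  # classical amplitude scaling: difference = (340/300 - 1) * map300
  expect_equal(d1$matrix, (340 / 300 - 1) * m300$matrix, tolerance = 1e-12)
})

test_that("colour classification reproduces the printed bands at boundaries", {
  expect_equal(as.character(classify_ved(1.05e7)), "red")
  expect_equal(as.character(classify_ved(9.5e6)), "orange")
  expect_equal(as.character(classify_ved(8.5e6)), "blue")
  expect_equal(as.character(classify_ved(5e6)), "below_range")
  # boundary conventions: 1e7 is orange (upper bound inclusive), 9e6 orange,
  # 8e6 blue, just above 1e7 red
  expect_equal(as.character(classify_ved(c(1e7, 9e6, 8e6, 1e7 + 1))),
               c("orange", "orange", "blue", "red"))
  expect_equal(as.character(classify_ved(8.9999e6)), "blue")
  expect_error(classify_ved(-1), "negative")
})

test_that("top_residues filters, sorts and breaks ties by ordinal", {
  prof <- structure(c(A1 = 5e6, A2 = 1.2e7, A3 = 9.5e6, A4 = 9.5e6),
                    class = "VEDProfile")
  names(prof) <- c("A1", "A2", "A3", "A4")
  tr <- top_residues(prof)
  expect_equal(tr$label, c("A2", "A3", "A4"))
  expect_equal(as.character(tr$class), c("red", "orange", "orange"))
  empty <- top_residues(structure(rep(1e6, 4), class = "VEDProfile",
                                  names = paste0("A", 1:4)))
  expect_equal(nrow(empty), 0L)
  one <- top_residues(structure(c(A1 = 1.2e7, A2 = 1e3), class = "VEDProfile",
                                names = c("A1", "A2")))
  expect_equal(nrow(one), 1L)
  expect_equal(as.character(one$class), "red")
})

test_that("mode diffusivity varies smoothly under broadening changes", {
  cm <- local_chain_modes(64, seed = 8)
  D1 <- mode_diffusivity(cm$m, cm$h, dims = 1, stability_check = FALSE)
  eta <- D1$eta_cm1[!is.na(D1$eta_cm1)]
  D2 <- mode_diffusivity(cm$m, cm$h, broadening = 2 * median(eta), dims = 1,
                         stability_check = FALSE)
  ok <- which(!is.na(D1$D) & D1$D > 0 & D2$D > 0)
  mid <- ok[cm$m$frequencies[ok] > quantile(cm$m$frequencies[ok], 0.3) &
            cm$m$frequencies[ok] < quantile(cm$m$frequencies[ok], 0.9)]
  ratio <- pmax(D1$D[mid] / D2$D[mid], D2$D[mid] / D1$D[mid])
  expect_lt(max(ratio), 10)
})

test_that("phospho model couples its site and partner more strongly", {
  ok <- 0
  for (seed in 1:5) {
    pair <- make_homolog_pair(64, 6, 2, seed = seed, link_region = c(40, 64))
    ps <- attr(pair, "phospho_site"); pp <- attr(pair, "phospho_partner")
    maps <- lapply(pair, function(mdl) {
      fit <- nma(mdl$structure,
                 enm_with_links(mdl$structure, mdl$crosslinks, 12, 1),
                 do_minimize = FALSE)
      D <- mode_diffusivity(fit, stability_check = FALSE)
      communication_map(fit, D, mdl$structure, scale_band_centers(fit),
                        temperature = 300)
    })
    if (maps$A$matrix[ps + 1, pp + 1] > maps$B$matrix[ps + 1, pp + 1] &&
        ved_profile(maps$A)[ps + 1] > ved_profile(maps$B)[ps + 1])
      ok <- ok + 1
  }
  expect_gte(ok, 4)
})
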