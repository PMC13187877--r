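test_that("free chain spectrum matches the analytic dispersion", {
  # omega_j = 2 sqrt(k/m) sin(j pi / 2N), j = 0..N-1
  for (N in c(3, 12, 50)) {
    s <- chain_structure(N)
    h <- build_hessian(s, spring_model(chain_springs(N)),
                       warn_unminimized = FALSE)
    m <- normal_modes(h)
    got <- sort(m$omega[m$omega > 0])
    want <- 2 * sin((1:(N - 1)) * pi / (2 * N)) *
      vedmap_constants$FREQ_PS1
    expect_lt(max(abs(got - want) / want), 1e-8)
  }
  # N = 3 unit chain: frequencies proportional to {0, 1, sqrt(3)}
  s <- chain_structure(3)
  m <- normal_modes(build_hessian(s, spring_model(chain_springs(3)),
                                  warn_unminimized = FALSE))
  nz <- sort(m$omega[m$omega > 0])
  expect_equal(nz[2] / nz[1], sqrt(3), tolerance = 1e-10)
})

test_that("3-D non-collinear networks have exactly 6 zero modes", {
  for (spec in list(synthetic_spec(10, "ideal_helix"),
                    synthetic_spec(27, "lattice"),
                    synthetic_spec(40, "ideal_helix"))) {
    s <- make_structure(spec)
    m <- nma(s, enm_model(12, 1), do_minimize = FALSE)
    expect_equal(m$n_zero_modes, 6L)
    V <- m$vectors
    expect_lt(max(abs(crossprod(V) - diag(ncol(V)))), 1e-6)
  }
})

test_that("analytic Hessian matches central differences on random networks", {
  worst <- 0
  for (seed in 1:20) {
    net <- random_network(8, seed, minimum = (seed %% 2 == 0))
    mod <- spring_model(net$springs)
    h <- build_hessian(net$structure, mod, warn_unminimized = FALSE)
    x0 <- coords(net$structure)
    n <- nrow(x0)
    eps <- 1e-5
    g <- function(x) as.vector(t(spring_gradient(mod, x)))
    Hfd <- matrix(0, 3 * n, 3 * n)
    for (a in seq_len(3 * n)) {
      xp <- x0; xp[ceiling(a / 3), ((a - 1) %% 3) + 1] <- xp[ceiling(a / 3), ((a - 1) %% 3) + 1] + eps
      xm <- x0; xm[ceiling(a / 3), ((a - 1) %% 3) + 1] <- xm[ceiling(a / 3), ((a - 1) %% 3) + 1] - eps
      Hfd[a, ] <- (g(xp) - g(xm)) / (2 * eps)
    }
    sw <- sqrt(rep(masses(net$structure), each = 3))
    Hfd <- Hfd / tcrossprod(sw) * 418.4
    worst <- max(worst, max(abs(Hfd - h$matrix)) / max(abs(h$matrix)))
  }
  expect_lt(worst, 1e-5)
})

test_that("Hessian obeys the translational sum rule and reconstruction", {
  net <- random_network(10, 3)
  h <- build_hessian(net$structure, spring_model(net$springs),
                     warn_unminimized = FALSE)
  sw <- sqrt(rep(masses(net$structure), each = 3))
  expect_lt(max(abs(h$matrix %*% sw)), 1e-8)
  m <- normal_modes(h)
  lam <- (m$omega)^2
  rec <- m$vectors %*% (lam * t(m$vectors))
  expect_lt(max(abs(rec - h$matrix)), 1e-8 * max(abs(h$matrix)))
})

test_that("spectrum is invariant under rigid rotation and translation", {
  s <- make_structure(synthetic_spec(15, "ideal_helix"))
  m1 <- nma(s, enm_model(12, 1), do_minimize = FALSE)
  th <- 0.7
  R <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  s2 <- s
  s2$atoms[, c("x", "y", "z")] <- coords(s) %*% t(R) +
    matrix(c(5, -3, 11), 15, 3, byrow = TRUE)
  m2 <- nma(s2, enm_model(12, 1), do_minimize = FALSE)
  expect_equal(m1$omega, m2$omega, tolerance = 1e-8)
})

test_that("normal_modes rejects saddle-point structures", {
  # a spring held far from its rest length has unstable transverse modes
  s <- chain_structure(2, spacing = 5)
  sp <- data.frame(i = 1, j = 2, k = 1, r0 = 8)
  h <- build_hessian(s, spring_model(sp), warn_unminimized = FALSE)
  expect_error(normal_modes(h), "unstable")
  # diatomic: non-zero eigenvalue 2k/m
  sp2 <- data.frame(i = 1, j = 2, k = 1, r0 = 5)
  m <- normal_modes(build_hessian(s, spring_model(sp2), warn_unminimized = FALSE))
  expect_equal(max(m$omega)^2 / 418.4, 2, tolerance = 1e-10)
})

test_that("minimisation reaches analytic minima and audits energy", {
  # two beads, one spring r0 = 3.8, started at 5.0
  s <- chain_structure(2, spacing = 5.0)
  mod <- spring_model(data.frame(i = 1, j = 2, k = 1, r0 = 3.8))
  out <- minimize(s, mod)
  d <- sqrt(sum(diff(coords(out$structure))^2))
  expect_equal(d, 3.8, tolerance = 1e-4)
  expect_true(out$report$converged)

  # already at a minimum: zero productive steps
  s0 <- make_structure(synthetic_spec(8, "ideal_helix"))
  out0 <- minimize(s0, enm_model(12, 1))
  expect_true(out0$report$converged)
  expect_equal(out0$report$stages$steps[1], 0L)
  expect_equal(max(abs(coords(out0$structure) - coords(s0))), 0)

  # perturbed chain: energy must not increase
  set.seed(5)
  s1 <- make_structure(synthetic_spec(10, "ideal_helix"))
  mod1 <- spring_model(vedmap:::model_springs(enm_model(12, 1), coords(s1)))
  s1p <- s1
  s1p$atoms[, c("x", "y", "z")] <- coords(s1) + matrix(rnorm(30, sd = 0.3), 10, 3)
  e0 <- spring_energy(mod1, coords(s1p))
  out1 <- minimize(s1p, mod1)
  e1 <- spring_energy(mod1, coords(out1$structure))
  expect_lte(e1, e0)
  expect_lt(e1, 1e-6)
})

test_that("heat capacity has the right limits and is monotone in T", {
  s <- make_structure(synthetic_spec(9, "ideal_helix"))
  m <- nma(s, enm_model(12, 1), do_minimize = FALSE)
  hi <- heat_capacity(m, 1e8)
  expect_equal(as.numeric(hi) / attr(hi, "classical"), 1, tolerance = 1e-3)
  expect_lt(heat_capacity(m, 1e-3), 1e-12)
  temps <- c(1, 5, 20, 80, 200, 300, 500, 1000)
  cvs <- vapply(temps, function(Tk) as.numeric(heat_capacity(m, Tk)), numeric(1))
  expect_true(all(diff(cvs) > 0))
  expect_error(heat_capacity(m, 0), "temperature")

  # single mode: closed-form Einstein heat capacity evaluated independently
  s2 <- chain_structure(2)
  m2 <- normal_modes(build_hessian(s2, spring_model(chain_springs(2)),
                                   warn_unminimized = FALSE))
  nu <- max(m2$frequencies)
  x <- 1.43877688 * nu / 300
  einstein <- 1.987204259e-3 * x^2 * exp(x) / (exp(x) - 1)^2
  expect_equal(as.numeric(heat_capacity(m2, 300)), einstein, tolerance = 5e-3)
})
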