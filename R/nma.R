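# Mass-weighted Hessians, normal modes and harmonic thermodynamics.
# The Hessian is stored in ps^-2 (angular frequency squared); eigenvalue
# lambda gives omega = sqrt(lambda) ps^-1 and wavenumber omega * 5.30884 cm^-1.

.OMEGA_TO_CM1 <- 1 / (2 * pi * 2.99792458e-2)  # 5.30884 cm^-1 per angular ps^-1

#' Analytic mass-weighted Hessian of a spring network
#'
#' Second derivatives of the harmonic spring energy at the supplied
#' coordinates, weighted by 1/sqrt(m_i m_j) and converted to ps^-2. For a
#' spring with rest length r0 at current length d the 3x3 pair block is
#' k\[rr^T + (1 - r0/d)(I - rr^T)\] with r the unit bond vector; at an exact
#' minimum (d = r0, the elastic-network case) this reduces to the classic
#' -k rr^T off-diagonal block.
#'
#' @param structure a [protein_structure()]
#' @param model a `PotentialModel`
#' @param warn_unminimized warn when the gradient at the input coordinates is
#'   appreciable (the Hessian is then not a vibrational one)
#' @return object of class `Hessian`: `matrix` (3N x 3N, ps^-2), `masses`,
#'   `xyz` (reference coordinates), `springs`
#' @export
build_hessian <- function(structure, model, warn_unminimized = TRUE) {
  xyz <- coords(structure)
  m <- masses(structure)
  n <- nrow(xyz)
  sp <- model_springs(model, xyz)
  if (warn_unminimized) {
    g <- spring_gradient(spring_model(sp), xyz)
    if (max(abs(g)) > 1e-4)
      warning("structure does not look minimised under this model (max |grad| = ",
              format(max(abs(g)), digits = 3), " kcal/mol/A)")
  }
  H <- matrix(0, 3 * n, 3 * n)
  I3 <- diag(3)
  for (s in seq_len(nrow(sp))) {
    i <- sp$i[s]; j <- sp$j[s]
    dv <- xyz[i, ] - xyz[j, ]
    d <- sqrt(sum(dv^2))
    u <- dv / d
    blk <- sp$k[s] * (tcrossprod(u) + (1 - sp$r0[s] / d) * (I3 - tcrossprod(u)))
    ii <- (3 * i - 2):(3 * i); jj <- (3 * j - 2):(3 * j)
    H[ii, ii] <- H[ii, ii] + blk
    H[jj, jj] <- H[jj, jj] + blk
    H[ii, jj] <- H[ii, jj] - blk
    H[jj, ii] <- H[jj, ii] - blk
  }
  invm <- rep(1 / sqrt(m), each = 3)
  H <- H * tcrossprod(invm) * vedmap_constants$KCAL_A2_TO_KJ_NM2
  H <- (H + t(H)) / 2
  structure(list(matrix = H, masses = m, xyz = xyz, springs = sp),
            class = "Hessian")
}

#' @export
print.Hessian <- function(x, ...) {
  cat(sprintf("<Hessian: %d atoms, %d springs, ps^-2>\n",
              length(x$masses), nrow(x$springs)))
  invisible(x)
}

#' Normal modes of a mass-weighted Hessian
#'
#' Symmetric eigendecomposition with frequencies in ascending order. Zero
#' (rigid-body) modes are those with |lambda| below `zero_tol` times the
#' spectral maximum; an eigenvalue more negative than that tolerance means
#' the structure is not at a minimum and is an error. Eigenvector signs follow
#' the convention that the first component exceeding 1e-6 in magnitude is
#' positive.
#'
#' @param hessian a [build_hessian()] result
#' @param zero_tol relative zero-mode threshold, default 1e-8
#' @return object of class `nma`: `frequencies` (cm^-1, ascending, zero modes
#'   first as 0), `omega` (angular ps^-1), `vectors` (orthonormal columns,
#'   mass-weighted), `n_zero_modes`, `zero_idx`, `masses`, `xyz`
#' @export
normal_modes <- function(hessian, zero_tol = 1e-8) {
  ev <- eigen(hessian$matrix, symmetric = TRUE)
  lambda <- rev(ev$values)
  V <- ev$vectors[, rev(seq_along(ev$values)), drop = FALSE]
  thr <- zero_tol * max(abs(lambda))
  if (any(lambda < -thr))
    stop(sum(lambda < -thr),
         " unstable (negative-eigenvalue) mode(s): structure is not at a minimum")
  zero <- abs(lambda) <= thr
  lambda[zero] <- 0
  # stable ordering: zero modes first, then ascending frequency
  ord <- order(lambda)
  lambda <- lambda[ord]; V <- V[, ord, drop = FALSE]
  for (a in seq_len(ncol(V))) {
    lead <- which(abs(V[, a]) > 1e-6)[1]
    if (!is.na(lead) && V[lead, a] < 0) V[, a] <- -V[, a]
  }
  omega <- sqrt(pmax(lambda, 0))
  structure(list(frequencies = omega * .OMEGA_TO_CM1, omega = omega,
                 vectors = V, n_zero_modes = sum(zero),
                 zero_idx = which(lambda == 0), masses = hessian$masses,
                 xyz = hessian$xyz),
            class = "nma")
}

#' Fit normal modes to a structure (minimise, build Hessian, decompose)
#'
#' The one-call interface: relaxes the structure under the model (optional),
#' builds the analytic mass-weighted Hessian and eigendecomposes it.
#'
#' @param structure a [protein_structure()]
#' @param model a `PotentialModel`, default [enm_model()]
#' @param do_minimize run [minimize()] first? default `TRUE`. An `enm` model
#'   is already at its minimum by construction, so minimisation exits
#'   immediately in that case.
#' @param schedule minimisation schedule, see [default_min_schedule()]
#' @param zero_tol passed to [normal_modes()]
#' @return an object of class `nma` (see [normal_modes()]); the relaxed
#'   structure and minimisation report are attached as `$structure` and
#'   `$min_report`
#' @export
nma <- function(structure, model = enm_model(), do_minimize = TRUE,
                schedule = default_min_schedule(), zero_tol = 1e-8) {
  rep <- NULL
  if (do_minimize) {
    mz <- minimize(structure, model, schedule)
    structure <- mz$structure
    rep <- mz$report
  }
  h <- build_hessian(structure, model, warn_unminimized = !do_minimize)
  modes <- normal_modes(h, zero_tol = zero_tol)
  modes$structure <- structure
  modes$hessian <- h
  modes$min_report <- rep
  modes
}

#' @export
print.nma <- function(x, ...) {
  nz <- x$frequencies[x$frequencies > 0]
  cat(sprintf("<nma: %d atoms, %d modes (%d zero); frequencies %.2f..%.2f cm^-1>\n",
              length(x$masses), length(x$frequencies), x$n_zero_modes,
              if (length(nz)) min(nz) else NA, if (length(nz)) max(nz) else NA))
  invisible(x)
}

.nonzero_idx <- function(modes)
  setdiff(seq_along(modes$frequencies), modes$zero_idx)

#' @export
summary.nma <- function(object, temperature = 300, ...) {
  nz <- object$frequencies[.nonzero_idx(object)]
  cv <- heat_capacity(object, temperature)
  out <- list(n_atoms = length(object$masses),
              n_modes = length(object$frequencies),
              n_zero_modes = object$n_zero_modes,
              freq_range = range(nz), temperature = temperature,
              cv = cv)
  class(out) <- "summary.nma"
  out
}

#' @export
print.summary.nma <- function(x, ...) {
  cat(sprintf(paste0(
    "Normal-mode model: %d atoms, %d modes (%d rigid-body)\n",
    "Non-zero frequencies: %.3f .. %.3f cm^-1\n",
    "Heat capacity at %g K: %.6g kcal/mol/K (classical limit %.6g)\n"),
    x$n_atoms, x$n_modes, x$n_zero_modes, x$freq_range[1], x$freq_range[2],
    x$temperature, x$cv, attr(x$cv, "classical")))
  invisible(x)
}

#' @export
plot.nma <- function(x, ...) {
  f <- x$frequencies[.nonzero_idx(x)]
  graphics::hist(f, breaks = 30, main = "Vibrational spectrum",
                 xlab = expression(nu ~ (cm^-1)), ...)
  invisible(x)
}

#' Quantum harmonic heat capacity of a mode set
#'
#' Cv = kB * sum over non-zero modes of x^2 e^x / (e^x - 1)^2 with
#' x = h c nu / (kB T). The classical (Dulong-Petit) limit, (number of
#' non-zero modes) * kB, is attached as attribute `"classical"`.
#'
#' @param modes an `nma` object
#' @param temperature temperature, K (> 0)
#' @return heat capacity, kcal mol^-1 K^-1
#' @export
heat_capacity <- function(modes, temperature) {
  if (temperature <= 0) stop("temperature must be > 0")
  nu <- modes$frequencies[.nonzero_idx(modes)]
  x <- vedmap_constants$CM1_K * nu / temperature
  term <- ifelse(x < 1e-8, 1,
                 ifelse(x > 500, 0, x^2 * exp(x) / (expm1(x))^2))
  cv <- vedmap_constants$KB_KCAL * sum(term)
  attr(cv, "classical") <- vedmap_constants$KB_KCAL * length(nu)
  cv
}
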