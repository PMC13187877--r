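# Vibrational energy transport: Allen-Feldman mode diffusivity from harmonic
# heat-flux matrix elements, frequency-band averaging, thermal averaging,
# residue-residue communication maps, and an independent wave-packet oracle.

#' Frequency-band specification
#'
#' @param centers band centres, cm^-1, positive and ascending (default the
#'   low-frequency set 50, 100, 150, 200, 300, 400)
#' @param modes_per_band modes averaged per band (default 10)
#' @return object of class `BandSpec`
#' @export
band_spec <- function(centers = c(50, 100, 150, 200, 300, 400),
                      modes_per_band = 10L) {
  stopifnot(all(centers > 0), !is.unsorted(centers, strictly = TRUE),
            modes_per_band >= 1L)
  structure(list(centers = centers, modes_per_band = as.integer(modes_per_band)),
            class = "BandSpec")
}

#' Place band centres at their relative spectral position
#'
#' The standard reporting bands (50..400 cm^-1) address an all-atom
#' vibrational spectrum, which extends to roughly 4000 cm^-1; they select its
#' low-frequency collective end. A residue-level elastic network's spectrum
#' tops out near 40-80 cm^-1, so using those centres verbatim would collapse
#' every band onto the same few highest modes. This helper maps the centres
#' onto the same relative position of the model's own spectrum:
#' `centers / reference_max * max(frequency)`.
#'
#' @param modes an `nma` object
#' @param centers nominal band centres, cm^-1
#' @param modes_per_band modes per band
#' @param reference_max spectral ceiling the nominal centres refer to, cm^-1
#'   (default 4000, the all-atom range)
#' @return a [band_spec()] with rescaled centres
#' @export
scale_band_centers <- function(modes, centers = c(50, 100, 150, 200, 300, 400),
                               modes_per_band = 10L, reference_max = 4000) {
  fmax <- max(modes$frequencies)
  band_spec(centers / reference_max * fmax, modes_per_band)
}

#' Allen-Feldman mode diffusivity
#'
#' For each non-zero mode alpha,
#' \deqn{D_\alpha = \frac{\pi}{d\,\omega_\alpha^2}\sum_{\beta\neq\alpha}
#'   |S_{\alpha\beta}|^2\, g_\eta(\omega_\alpha-\omega_\beta)}
#' with the harmonic heat-flux matrix elements
#' \deqn{S_{\alpha\beta} = \frac{\omega_\alpha+\omega_\beta}
#'   {4\sqrt{\omega_\alpha\omega_\beta}} \sum_{i,j} (r_i - r_j)\,
#'   e_{\alpha,i}^{\mathsf T}\,\Phi_{ij}\, e_{\beta,j}}
#' built from the mass-weighted force-constant blocks \eqn{\Phi_{ij}} and the
#' inter-atom displacement vectors, and \eqn{g_\eta} a unit-area Gaussian of
#' width eta. `d` is the transport dimensionality (3 for a 3-D network; the
#' isotropic flux average). Zero (rigid-body) modes carry `NA` and are
#' excluded from both sums. A stability flag per mode records whether D moves
#' by less than a factor of 1.5 when the broadening is doubled; for a
#' perfectly ordered chain the diffusivity scales like 1/eta (the ballistic
#' harmonic-crystal divergence) and such modes are flagged unconverged
#' rather than silently returned.
#'
#' @param modes an `nma` object
#' @param hessian the matching `Hessian` (default `modes$hessian`)
#' @param broadening Gaussian width eta in cm^-1 (scalar), or `NULL` for the
#'   default 3x the local mean mode spacing around each mode
#' @param dims transport dimensionality d (default 3)
#' @param stability_check also evaluate at 2x eta and flag unstable modes
#' @return object of class `ModeDiffusivity`: `D` (A^2/ps, `NA` at zero
#'   modes), `frequencies` (cm^-1), `eta_cm1` (per mode), `stable`, `dims`
#' @export
mode_diffusivity <- function(modes, hessian = modes$hessian, broadening = NULL,
                             dims = 3, stability_check = TRUE) {
  if (is.null(hessian)) stop("no hessian supplied or attached to modes")
  if (!is.null(broadening) && any(broadening <= 0))
    stop("broadening must be positive")
  nz <- .nonzero_idx(modes)
  if (length(nz) < 1L) stop("no non-zero modes")
  E <- modes$vectors[, nz, drop = FALSE]
  omega <- modes$omega[nz]
  if (nrow(E) != nrow(hessian$matrix))
    stop("modes and hessian have mismatched dimensions")
  S2 <- .heatflux_sq(hessian, E, omega)
  eta <- .broadening_omega(omega, broadening)
  G <- .gauss_kernel(omega, eta)
  D_nz <- (pi / (dims * omega^2)) * rowSums(S2 * G)
  stable <- rep(TRUE, length(nz))
  if (stability_check) {
    D2 <- (pi / (dims * omega^2)) * rowSums(S2 * .gauss_kernel(omega, 2 * eta))
    r <- ifelse(D_nz > 0 & D2 > 0, pmax(D_nz / D2, D2 / D_nz), 1)
    stable <- r < 1.5
  }
  D <- rep(NA_real_, length(modes$omega))
  D[nz] <- D_nz
  st <- rep(NA, length(modes$omega)); st[nz] <- stable
  structure(list(D = D, frequencies = modes$frequencies,
                 eta_cm1 = {e <- rep(NA_real_, length(modes$omega))
                            e[nz] <- eta * .OMEGA_TO_CM1; e},
                 stable = st, dims = dims, zero_idx = modes$zero_idx),
            class = "ModeDiffusivity")
}

#' @export
print.ModeDiffusivity <- function(x, ...) {
  d <- x$D[!is.na(x$D)]
  cat(sprintf("<ModeDiffusivity: %d modes (%d zero excluded); D %.3g..%.3g A^2/ps>\n",
              length(x$D), length(x$zero_idx), min(d), max(d)))
  invisible(x)
}

# squared heat-flux matrix elements |S_ab|^2 for the non-zero-mode block
.heatflux_sq <- function(hessian, E, omega) {
  H <- hessian$matrix
  xyz <- hessian$xyz
  K <- length(omega)
  f <- outer(omega, omega, function(a, b) (a + b) / (4 * sqrt(a * b)))
  S2 <- matrix(0, K, K)
  for (c in 1:3) {
    rc <- rep(xyz[, c], each = 3)
    Ac <- H * outer(rc, rc, `-`)
    Tc <- crossprod(E, Ac %*% E)
    S2 <- S2 + (f * Tc)^2
  }
  diag(S2) <- 0
  S2
}

# per-mode broadening in angular ps^-1
.broadening_omega <- function(omega, broadening) {
  if (!is.null(broadening)) {
    return(rep(broadening / .OMEGA_TO_CM1, length(omega)))
  }
  K <- length(omega)
  vapply(seq_len(K), function(a) {
    lo <- max(1L, a - 5L); hi <- min(K, a + 5L)
    sp <- (omega[hi] - omega[lo]) / max(1L, hi - lo)
    3 * max(sp, 1e-12)
  }, numeric(1))
}

# row-wise unit-area Gaussian kernel, zero diagonal
.gauss_kernel <- function(omega, eta) {
  dd <- outer(omega, omega, `-`)
  G <- exp(-dd^2 / (2 * eta^2)) / (eta * sqrt(2 * pi))
  diag(G) <- 0
  G
}

#' Wave-packet diffusivity oracle
#'
#' Independent brute-force estimate of vibrational energy diffusivity:
#' propagates exact harmonic dynamics from a kinetic-energy excitation
#' localised at `source_atom`, assigns site energies (kinetic plus half of
#' each connected spring's harmonic energy), and fits the slope of the
#' mean-square energy displacement about the initial energy centroid;
#' D = slope / (2 d). Rigid-body components of the excitation are projected
#' out. With `freq_window` the excitation is band-passed: only modes inside
#' the window (cm^-1) are excited, which makes the estimate comparable to a
#' band-restricted mode-diffusivity average.
#'
#' @param hessian a `Hessian` (small system; the full eigenproblem is solved)
#' @param source_atom 1-based atom index of the excitation
#' @param t_max propagation time, ps (> 0); should cover several vibration
#'   periods but stay below the boundary-reflection time
#' @param dims transport dimensionality d (1 for a chain)
#' @param n_times number of sample times
#' @param fit_window fraction of `t_max` over which the linear fit runs
#' @param freq_window optional c(lo, hi) band-pass, cm^-1
#' @return diffusivity estimate, A^2/ps, with attributes `energy_drift`
#'   (max relative deviation of total energy), `times`, `msd`
#' @export
wavepacket_oracle <- function(hessian, source_atom, t_max, dims = 3,
                              n_times = 200L, fit_window = c(0.1, 0.9),
                              freq_window = NULL) {
  if (t_max <= 0) stop("t_max must be positive")
  modes <- normal_modes(hessian)
  nz <- .nonzero_idx(modes)
  E <- modes$vectors[, nz, drop = FALSE]
  omega <- modes$omega[nz]
  n <- length(hessian$masses)
  p0 <- numeric(3 * n)
  p0[(3 * source_atom - 2):(3 * source_atom)] <- 1 / sqrt(3)
  b <- drop(crossprod(E, p0))
  if (!is.null(freq_window)) {
    keep <- modes$frequencies[nz] >= freq_window[1] &
            modes$frequencies[nz] <= freq_window[2]
    if (!any(keep)) stop("no modes inside freq_window")
    b[!keep] <- 0
  }
  sp <- hessian$springs
  xyz <- hessian$xyz
  sqm <- sqrt(rep(hessian$masses, each = 3))
  uhat <- (xyz[sp$i, , drop = FALSE] - xyz[sp$j, , drop = FALSE])
  dlen <- sqrt(rowSums(uhat^2)); uhat <- uhat / dlen
  times <- seq(0, t_max, length.out = n_times)
  site_E <- matrix(0, n, n_times)
  for (k in seq_len(n_times)) {
    t <- times[k]
    q <- (b / omega) * sin(omega * t)
    qdot <- b * cos(omega * t)
    u_mw <- drop(E %*% q)        # mass-weighted displacements
    v_mw <- drop(E %*% qdot)
    ke <- 0.5 * rowSums(matrix(v_mw^2, n, 3, byrow = TRUE))
    u <- matrix(u_mw / sqm, n, 3, byrow = TRUE)  # cartesian displacement
    du <- u[sp$i, , drop = FALSE] - u[sp$j, , drop = FALSE]
    # harmonic pair energy: projection on the bond direction plus the
    # transverse r0/d term of the pair block
    para <- rowSums(du * uhat)
    perp2 <- rowSums(du^2) - para^2
    # pair energy in amu A^2 ps^-2, the same units as the mass-weighted
    # kinetic term (k converted kcal/mol/A^2 -> amu ps^-2 per A^2)
    e_s <- 0.5 * sp$k * vedmap_constants$KCAL_A2_TO_KJ_NM2 *
      (para^2 + (1 - sp$r0 / dlen) * perp2)
    pe <- numeric(n)
    tmp <- rowsum(c(e_s / 2, e_s / 2), c(sp$i, sp$j))
    pe[as.integer(rownames(tmp))] <- tmp[, 1]
    site_E[, k] <- ke + pe
  }
  tot <- colSums(site_E)
  drift <- max(abs(tot - tot[1])) / tot[1]
  cent0 <- colSums(xyz * site_E[, 1]) / tot[1]
  r2 <- rowSums((xyz - matrix(cent0, n, 3, byrow = TRUE))^2)
  msd <- colSums(site_E * r2) / tot
  sel <- times >= fit_window[1] * t_max & times <= fit_window[2] * t_max
  slope <- stats::coef(stats::lm(msd[sel] ~ times[sel]))[2]
  D <- unname(slope) / (2 * dims)
  attr(D, "energy_drift") <- drift
  attr(D, "times") <- times
  attr(D, "msd") <- msd
  D
}

#' Average mode diffusivity over frequency bands
#'
#' For each band centre the `modes_per_band` non-zero modes nearest in
#' frequency are averaged (ties broken toward lower frequency). A
#' Gaussian-weighted window is available via `window = "gaussian"`.
#'
#' @param D a [mode_diffusivity()] result
#' @param modes the matching `nma` object
#' @param band a [band_spec()]
#' @param window `"nearest"` (default) or `"gaussian"`
#' @param gaussian_width width of the Gaussian window, cm^-1 (default 25)
#' @return data.frame with `center`, `value`, `n_modes`; the per-band mode
#'   memberships (indices into the mode set) are attached as attribute
#'   `"members"` for audit
#' @export
band_average <- function(D, modes, band = band_spec(),
                         window = c("nearest", "gaussian"),
                         gaussian_width = 25) {
  window <- match.arg(window)
  ok <- which(!is.na(D$D))
  if (!length(ok)) stop("empty spectrum: no finite mode diffusivities")
  if (length(ok) < band$modes_per_band)
    stop("fewer non-zero modes (", length(ok), ") than modes_per_band")
  freq <- modes$frequencies[ok]
  members <- list()
  vals <- numeric(length(band$centers))
  for (b in seq_along(band$centers)) {
    ctr <- band$centers[b]
    if (window == "nearest") {
      ord <- order(abs(freq - ctr), freq)
      sel <- ord[seq_len(band$modes_per_band)]
      vals[b] <- mean(D$D[ok[sel]])
      members[[b]] <- sort(ok[sel])
    } else {
      w <- exp(-(freq - ctr)^2 / (2 * gaussian_width^2))
      w <- w / sum(w)
      vals[b] <- sum(w * D$D[ok])
      members[[b]] <- ok
    }
  }
  out <- data.frame(center = band$centers, value = vals,
                    n_modes = vapply(members, length, integer(1)))
  attr(out, "members") <- members
  out
}

#' Thermally averaged scalar from per-band values
#'
#' Classical (equipartition) weighting gives every band the same weight - the
#' plain band mean - optionally scaled by T/`T_ref` when the classical
#' amplitude convention is enabled (mode energy kB T). Quantum weighting uses
#' normalised Bose occupations of the band centres at T.
#'
#' @param band_values data.frame from [band_average()] (or numeric vector)
#' @param temperature K (> 0)
#' @param band a [band_spec()] (needed for Bose weights when `band_values`
#'   is a bare vector)
#' @param weights `"classical"` or `"bose"`
#' @param amplitude_scaling multiply by temperature / `T_ref`? default FALSE
#' @param T_ref reference temperature for amplitude scaling, K
#' @return scalar thermally averaged value
#' @export
thermal_average <- function(band_values, temperature, band = band_spec(),
                            weights = c("classical", "bose"),
                            amplitude_scaling = FALSE, T_ref = 300) {
  if (temperature <= 0) stop("temperature must be > 0")
  weights <- match.arg(weights)
  if (is.data.frame(band_values)) {
    v <- band_values$value
    centers <- band_values$center
  } else {
    v <- band_values
    centers <- band$centers
  }
  w <- .band_weights(centers, temperature, weights)
  out <- sum(w * v)
  if (amplitude_scaling) out <- out * temperature / T_ref
  out
}

.band_weights <- function(centers, temperature, weights) {
  if (weights == "classical") {
    rep(1 / length(centers), length(centers))
  } else {
    x <- vedmap_constants$CM1_K * centers / temperature
    occ <- 1 / expm1(x)
    occ / sum(occ)
  }
}

#' Residue-residue communication map
#'
#' Projects band-averaged, thermally averaged mode diffusivity onto residue
#' pairs through mode participations: with \eqn{P_{\alpha I} = \sum_{i \in I}
#' |e_{\alpha,i}|^2}, the entry for residues (I, J) is
#' \deqn{M_{IJ} = \sum_b w_b \frac{1}{n_b} \sum_{\alpha \in b}
#'   D_\alpha P_{\alpha I} P_{\alpha J}.}
#' The map is symmetric and non-negative by construction, its diagonal holds
#' the residue-local value, and because participations sum to one per mode
#' the grand sum over all residue pairs equals the thermally averaged total
#' diffusivity exactly (decomposition completeness).
#'
#' @param modes an `nma` object
#' @param D a [mode_diffusivity()] result
#' @param structure the matching [protein_structure()]
#' @param band a [band_spec()]
#' @param temperature K
#' @param weights,amplitude_scaling,T_ref see [thermal_average()]
#' @return object of class `CommunicationMap`: `matrix` (R x R, A^2/ps),
#'   `temperature`, `band`, `labels` (residue labels), `weights`
#' @export
communication_map <- function(modes, D, structure, band = band_spec(),
                              temperature = 300,
                              weights = c("classical", "bose"),
                              amplitude_scaling = FALSE, T_ref = 300) {
  weights <- match.arg(weights)
  a <- structure$atoms
  if (3 * nrow(a) != nrow(modes$vectors))
    stop("structure and modes have mismatched dimensions")
  R <- structure$n_residues
  ba <- band_average(D, modes, band)
  members <- attr(ba, "members")
  wb <- .band_weights(band$centers, temperature, weights)
  amp <- if (amplitude_scaling) temperature / T_ref else 1
  M <- matrix(0, R, R)
  # participation of each residue in each needed mode
  need <- sort(unique(unlist(members)))
  E2 <- modes$vectors[, need, drop = FALSE]^2
  P <- rowsum(E2, rep(a$res_ord + 1L, each = 3))  # R x |need|
  for (b in seq_along(members)) {
    cols <- match(members[[b]], need)
    Db <- D$D[members[[b]]]
    Pb <- P[, cols, drop = FALSE]
    M <- M + (wb[b] / length(cols)) * (Pb %*% (Db * t(Pb)))
  }
  M <- amp * (M + t(M)) / 2
  rt <- residue_table(structure)
  labels <- sprintf("%s%d%s", rt$chain, rt$resseq, rt$icode)
  structure(list(matrix = M, temperature = temperature, band = band,
                 labels = labels, weights = weights,
                 amplitude_scaling = amplitude_scaling, T_ref = T_ref),
            class = "CommunicationMap")
}

#' @export
print.CommunicationMap <- function(x, ...) {
  cat(sprintf("<CommunicationMap: %d residues, T = %s K, total %.4g A^2/ps>\n",
              nrow(x$matrix), paste(x$temperature, collapse = "-"),
              sum(x$matrix)))
  invisible(x)
}

#' @export
plot.CommunicationMap <- function(x, ...) {
  R <- nrow(x$matrix)
  graphics::image(1:R, 1:R, x$matrix, xlab = "residue", ylab = "residue",
                  main = sprintf("Communication map, T = %s K",
                                 paste(x$temperature, collapse = "-")), ...)
  invisible(x)
}

#' Temperature-difference communication map
#'
#' Elementwise `map_hi - map_lo`; both temperatures are recorded in the
#' result's metadata.
#'
#' @param map_hi,map_lo `CommunicationMap`s over the same residues and band
#' @return a `CommunicationMap` whose matrix is the difference (entries may
#'   be of either sign)
#' @export
difference_map <- function(map_hi, map_lo) {
  if (!identical(map_hi$labels, map_lo$labels))
    stop("residue labels differ between maps")
  if (!identical(map_hi$band, map_lo$band))
    stop("band specifications differ between maps")
  out <- map_hi
  out$matrix <- map_hi$matrix - map_lo$matrix
  out$temperature <- c(map_hi$temperature, map_lo$temperature)
  out
}

#' Per-residue vibrational energy diffusivity profile
#'
#' Row sums of a communication map: the total energy-transport coupling each
#' residue participates in at the map's temperature and band.
#'
#' @param map a `CommunicationMap`
#' @return object of class `VEDProfile`: numeric vector named by residue
#'   label, with the temperature as attribute
#' @export
ved_profile <- function(map) {
  v <- rowSums(map$matrix)
  names(v) <- map$labels
  structure(v, temperature = map$temperature, class = "VEDProfile")
}

#' Classify a diffusivity value on the reporting colour scale
#'
#' Colour bands on the printed reporting scale: red above 1e7, orange from
#' 9e6 to 1e7 (both endpoints included), blue from 8e6 (included) up to but
#' not including 9e6, and `below_range` otherwise.
#'
#' @param value non-negative value(s) on the reporting scale
#' @param thresholds named vector `c(blue = 8e6, orange = 9e6, red = 1e7)`
#' @return factor with levels below_range, blue, orange, red
#' @export
classify_ved <- function(value, thresholds = c(blue = 8e6, orange = 9e6, red = 1e7)) {
  if (any(value < 0)) stop("negative diffusivity value")
  cls <- ifelse(value > thresholds[["red"]], "red",
         ifelse(value >= thresholds[["orange"]], "orange",
         ifelse(value >= thresholds[["blue"]], "blue", "below_range")))
  factor(cls, levels = c("below_range", "blue", "orange", "red"))
}

#' Highly vibrationally active residues
#'
#' Residues whose profile value reaches at least the lowest colour band,
#' sorted by decreasing value (ties broken by residue ordinal).
#'
#' @param profile a [ved_profile()]
#' @param thresholds see [classify_ved()]
#' @return data.frame with `ordinal` (0-based), `label`, `value`, `class`;
#'   zero rows when nothing reaches the lowest band
#' @export
top_residues <- function(profile, thresholds = c(blue = 8e6, orange = 9e6, red = 1e7)) {
  v <- as.numeric(profile)
  cls <- classify_ved(v, thresholds)
  keep <- cls != "below_range"
  out <- data.frame(ordinal = which(keep) - 1L,
                    label = names(profile)[keep],
                    value = v[keep], class = cls[keep],
                    stringsAsFactors = FALSE)
  out <- out[order(-out$value, out$ordinal), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Cross-validate mode diffusivity against the wave-packet oracle
#'
#' Builds a mass-disordered harmonic chain (masses uniform in `mass_range`,
#' nearest-neighbour springs), band-averages the Allen-Feldman diffusivity
#' around the median non-zero frequency, and compares it with wave-packet
#' estimates launched from `sources`. The wave-packet propagation time is
#' capped at `time_factor` times the boundary-reflection time (source-to-end
#' distance over the chain's sound speed, taken from the top of its
#' spectrum): beyond that the mean-square energy displacement saturates at
#' the chain ends and no longer measures bulk transport.
#'
#' @param n_beads chain length (default 64)
#' @param seed integer seed for the mass draw
#' @param mass_range uniform mass bounds, amu
#' @param spacing bead spacing, A
#' @param k spring constant, kcal mol^-1 A^-2
#' @param modes_per_band modes in the comparison band
#' @param sources wave-packet source beads (averaged)
#' @param time_factor fraction of the boundary-reflection time propagated
#' @return list with `af` (band-averaged Allen-Feldman D, A^2/ps),
#'   `wavepacket` (mean oracle D), `ratio`, `band_window` (cm^-1),
#'   `energy_drift` (worst oracle run)
#' @export
transport_crosscheck <- function(n_beads = 64L, seed = 1L,
                                 mass_range = c(0.8, 1.2), spacing = 3.8,
                                 k = 1, modes_per_band = 10L,
                                 sources = NULL, time_factor = 0.7) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  mass <- stats::runif(n_beads, mass_range[1], mass_range[2])
  s <- protein_structure(data.frame(
    name = "CA", element = "C", resname = "ALA", resseq = seq_len(n_beads),
    chain = "A", x = spacing * (seq_len(n_beads) - 1L), y = 0, z = 0,
    mass = mass))
  sp <- data.frame(i = seq_len(n_beads - 1L), j = 2:n_beads, k = k,
                   r0 = spacing)
  h <- build_hessian(s, spring_model(sp), warn_unminimized = FALSE)
  m <- normal_modes(h)
  D <- mode_diffusivity(m, h, dims = 1)
  nzf <- m$frequencies[!is.na(D$D)]
  ba <- band_average(D, m, band_spec(stats::median(nzf), modes_per_band))
  fw <- range(m$frequencies[attr(ba, "members")[[1]]])
  cmax <- spacing * max(m$omega) / 2   # sound speed, A/ps
  if (is.null(sources))
    sources <- round(n_beads / 2) + c(-4L, 0L, 4L)
  drift <- 0
  wps <- vapply(sources, function(src) {
    t_bound <- min(src - 1L, n_beads - src) * spacing / cmax
    w <- wavepacket_oracle(h, src, time_factor * t_bound, dims = 1,
                           freq_window = fw, fit_window = c(0.15, 1.0))
    drift <<- max(drift, attr(w, "energy_drift"))
    as.numeric(w)
  }, numeric(1))
  list(af = ba$value, wavepacket = mean(wps), ratio = ba$value / mean(wps),
       band_window = fw, energy_drift = drift)
}

#' Rescale colour thresholds to a profile's own scale
#'
#' The printed colour scale belongs to all-atom maps; synthetic bead maps
#' live on a different numeric scale. This maps the three colour thresholds
#' onto quantiles of the supplied profile (by default blue at the 90th
#' percentile and the band widths preserved proportionally).
#'
#' @param profile a [ved_profile()]
#' @param prob quantile at which the lowest (blue) threshold is placed
#' @return named thresholds vector usable with [classify_ved()]
#' @export
rescale_thresholds <- function(profile, prob = 0.9) {
  q <- stats::quantile(as.numeric(profile), prob, names = FALSE)
  top <- max(as.numeric(profile))
  step <- (top - q) / 3
  c(blue = q, orange = q + step, red = q + 2 * step)
}
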