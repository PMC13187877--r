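# Trajectories and stability metrics: harmonic-equilibrium sampling, RMSD
# with Kabsch superposition, per-residue RMSF, salt-bridge detection and
# geometric hydrogen-bond counting.

#' Construct a trajectory
#'
#' @param frames F x 3N matrix of coordinates (A), one frame per row, atom
#'   triples in structure order
#' @param structure the [protein_structure()] the frames belong to
#' @param times frame times, ps (default 0, 1, ...)
#' @return object of class `Trajectory`
#' @export
trajectory <- function(frames, structure, times = seq_len(nrow(frames)) - 1) {
  frames <- as.matrix(frames)
  if (nrow(frames) < 2L) stop("a trajectory needs at least 2 frames")
  if (ncol(frames) != 3L * nrow(structure$atoms))
    stop("frame width does not match structure atom count")
  structure(list(frames = frames, times = times, structure = structure),
            class = "Trajectory")
}

#' @export
print.Trajectory <- function(x, ...) {
  cat(sprintf("<Trajectory: %d frames x %d atoms>\n",
              nrow(x$frames), ncol(x$frames) / 3))
  invisible(x)
}

#' Sample a harmonic-equilibrium trajectory from a normal-mode model
#'
#' Frames are drawn independently from the classical harmonic equilibrium
#' distribution: each non-zero mode amplitude is Gaussian with variance
#' kB T / omega^2 in mass-weighted coordinates (rigid-body modes are not
#' excited). Frame 1 is the reference geometry. Frames carry no time
#' correlation; the sampling targets fluctuation statistics, not kinetics.
#'
#' @param modes an `nma` object
#' @param temperature K (> 0)
#' @param n_frames number of frames (>= 2)
#' @param seed integer seed; fully determines the trajectory
#' @return a [trajectory()]
#' @export
simulate_harmonic_trajectory <- function(modes, temperature, n_frames, seed = 1L) {
  if (temperature <= 0) stop("temperature must be > 0")
  if (n_frames < 2L) stop("n_frames must be >= 2")
  nz <- .nonzero_idx(modes)
  E <- modes$vectors[, nz, drop = FALSE]
  # eigenvalues in internal kcal/mol/A^2/amu units so that kB T / lambda is
  # a squared amplitude in A^2 amu
  lambda <- modes$omega[nz]^2 / vedmap_constants$KCAL_A2_TO_KJ_NM2
  sdev <- sqrt(vedmap_constants$KB_KCAL * temperature / lambda)
  n <- length(modes$masses)
  ref <- as.vector(t(modes$xyz))
  sqm <- sqrt(rep(modes$masses, each = 3))
  frames <- matrix(0, n_frames, 3 * n)
  frames[1, ] <- ref
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  z <- matrix(stats::rnorm((n_frames - 1L) * length(nz)), n_frames - 1L)
  disp <- (z %*% (sdev * t(E)))           # mass-weighted displacements
  frames[-1, ] <- sweep(disp, 2, sqm, "/") + rep(ref, each = n_frames - 1L)
  trajectory(frames, modes$structure %||% .structure_from_modes(modes))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.structure_from_modes <- function(modes) {
  n <- length(modes$masses)
  protein_structure(data.frame(
    serial = seq_len(n), name = "CA", element = "C", resname = "ALA",
    resseq = seq_len(n), chain = "A", icode = "",
    x = modes$xyz[, 1], y = modes$xyz[, 2], z = modes$xyz[, 3],
    mass = modes$masses, charge = 0))
}

#' @export
simulate.nma <- function(object, nsim = 100, seed = 1L, temperature = 300, ...) {
  simulate_harmonic_trajectory(object, temperature, nsim, seed)
}

#' Read a multi-model PDB file as a trajectory
#'
#' @param path file path; every MODEL must contain the same atoms
#' @param ... passed to [read_pdb()] filtering (applied per model)
#' @return a [trajectory()]; times are model indices (ps)
#' @export
read_trajectory_pdb <- function(path, ...) {
  lines <- readLines(path, warn = FALSE)
  starts <- grep("^MODEL", lines)
  if (!length(starts)) stop("no MODEL records in ", path, "; not a trajectory")
  ends <- grep("^ENDMDL", lines)
  if (length(ends) < length(starts)) ends <- c(ends, length(lines))
  tmp <- tempfile(fileext = ".pdb")
  on.exit(unlink(tmp))
  frames <- NULL
  structure1 <- NULL
  for (k in seq_along(starts)) {
    writeLines(lines[(starts[k] + 1L):(ends[k] - 1L)], tmp)
    s <- read_pdb(tmp, ...)
    if (is.null(structure1)) {
      structure1 <- s
      frames <- matrix(0, length(starts), 3L * nrow(s$atoms))
    } else if (nrow(s$atoms) != nrow(structure1$atoms)) {
      stop("model ", k, " has a different atom count")
    }
    frames[k, ] <- as.vector(t(coords(s)))
  }
  trajectory(frames, structure1)
}

#' Read a plain-text frame table as a trajectory
#'
#' @param path whitespace-delimited file, one frame per row, 3N columns
#'   (x1 y1 z1 x2 ...)
#' @param structure the matching [protein_structure()]
#' @return a [trajectory()]
#' @export
read_trajectory_table <- function(path, structure) {
  m <- as.matrix(utils::read.table(path, header = FALSE))
  trajectory(unname(m), structure)
}

#' Optimal rigid superposition (Kabsch)
#'
#' Least-squares rigid-body fit of `mobile` onto `reference`, optionally
#' weighted (typically by mass). The rotation is proper (det = +1).
#'
#' @param mobile,reference N x 3 coordinate matrices, N >= 3 non-collinear
#' @param weights optional per-point weights
#' @return list with `rotation` (3 x 3), `translation` (length 3; the fit is
#'   `mobile %*% t(rotation)` + translation), `rmsd` (weighted, A)
#' @export
kabsch_superpose <- function(mobile, reference, weights = NULL) {
  n <- nrow(mobile)
  if (n < 3L || nrow(reference) != n) stop("need matching N >= 3 point sets")
  w <- if (is.null(weights)) rep(1, n) else weights
  w <- w / sum(w)
  cm <- colSums(mobile * w); cr <- colSums(reference * w)
  A <- sweep(mobile, 2, cm); B <- sweep(reference, 2, cr)
  sv0 <- svd(B * sqrt(w))
  if (sv0$d[2] < 1e-8 * max(sv0$d[1], 1e-300))
    stop("degenerate (collinear) point set: superposition is ill-defined")
  H <- crossprod(A * w, B)
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  U <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)   # rotation: fit = A %*% t(U)
  fit <- A %*% t(U)
  rmsd <- sqrt(sum(w * rowSums((fit - B)^2)))
  list(rotation = U, translation = cr - drop(U %*% cm), rmsd = rmsd)
}

#' Per-frame RMSD of a trajectory
#'
#' RMSD of every frame from a reference frame after optimal superposition.
#' The summary mean and SD exclude a leading equilibration window.
#'
#' @param traj a [trajectory()]
#' @param reference_frame frame index used as reference (default 1)
#' @param selection optional atom indices used for both fit and RMSD
#' @param equilibration leading frames excluded from the summary: a fraction
#'   of the trajectory when < 1, else a frame count (default 0.1)
#' @param mass_weighted weight the fit and RMSD by atom mass (default TRUE)
#' @return object of class `FluctuationSummary`: `values` (per frame, A),
#'   `times`, `mean`, `sd`, `n_excluded`
#' @export
rmsd_series <- function(traj, reference_frame = 1L, selection = NULL,
                        equilibration = 0.1, mass_weighted = TRUE) {
  F <- nrow(traj$frames)
  if (reference_frame < 1L || reference_frame > F)
    stop("bad reference frame index")
  n <- ncol(traj$frames) / 3
  sel <- if (is.null(selection)) seq_len(n) else selection
  if (!length(sel)) stop("empty selection")
  w <- if (mass_weighted) masses(traj$structure)[sel] else NULL
  ref <- matrix(traj$frames[reference_frame, ], n, 3, byrow = TRUE)[sel, , drop = FALSE]
  vals <- vapply(seq_len(F), function(k) {
    xk <- matrix(traj$frames[k, ], n, 3, byrow = TRUE)[sel, , drop = FALSE]
    kabsch_superpose(xk, ref, w)$rmsd
  }, numeric(1))
  nex <- if (equilibration < 1) as.integer(round(equilibration * F)) else
    as.integer(equilibration)
  nex <- min(nex, F - 1L)
  keep <- vals[seq.int(nex + 1L, F)]
  structure(list(values = vals, times = traj$times, mean = mean(keep),
                 sd = stats::sd(keep), n_excluded = nex),
            class = "FluctuationSummary")
}

#' @export
print.FluctuationSummary <- function(x, ...) {
  cat(sprintf("<FluctuationSummary: %d values, mean %.3f +/- %.3f A%s>\n",
              length(x$values), x$mean, x$sd,
              if (!is.null(x$n_excluded) && x$n_excluded > 0)
                sprintf(" (%d equilibration values excluded)", x$n_excluded)
              else ""))
  invisible(x)
}

#' Per-residue RMSF of a trajectory
#'
#' Superposes every frame onto the mean structure (two fixed-point
#' iterations of fit-then-average), then reports the mass-weighted root
#' mean-square fluctuation of each residue about its mean position.
#'
#' @param traj a [trajectory()] with at least 10 frames
#' @param selection optional atom indices
#' @return a `FluctuationSummary` whose `values` is the per-residue profile
#'   (A) named by residue label; `mean`/`sd` summarise the profile
#' @export
rmsf_per_residue <- function(traj, selection = NULL) {
  F <- nrow(traj$frames)
  if (F < 10L) stop("need >= 10 frames for an RMSF profile")
  n <- ncol(traj$frames) / 3
  sel <- if (is.null(selection)) seq_len(n) else selection
  if (!length(sel)) stop("empty selection")
  m <- masses(traj$structure)[sel]
  X <- array(0, c(F, length(sel), 3))
  for (k in seq_len(F))
    X[k, , ] <- matrix(traj$frames[k, ], n, 3, byrow = TRUE)[sel, , drop = FALSE]
  mean_x <- X[1, , ]
  for (iter in 1:2) {
    for (k in seq_len(F)) {
      fit <- kabsch_superpose(X[k, , ], mean_x, m)
      X[k, , ] <- X[k, , ] %*% t(fit$rotation) +
        matrix(fit$translation, length(sel), 3, byrow = TRUE)
    }
    mean_x <- apply(X, c(2, 3), mean)
  }
  msf_atom <- rowMeans(vapply(seq_len(F), function(k)
    rowSums((X[k, , ] - mean_x)^2), numeric(length(sel))))
  ord <- traj$structure$atoms$res_ord[sel]
  wsum <- rowsum(m * msf_atom, ord)
  msum <- rowsum(m, ord)
  prof <- sqrt(wsum[, 1] / msum[, 1])
  rt <- residue_table(traj$structure)
  names(prof) <- sprintf("%s%d%s", rt$chain, rt$resseq, rt$icode)[
    match(as.integer(rownames(wsum)), rt$ordinal)]
  structure(list(values = prof, times = NULL, mean = mean(prof),
                 sd = stats::sd(prof), n_excluded = 0L),
            class = "FluctuationSummary")
}

# residue ordinal bounds from a region spec: c(lo, hi) residue numbers
# (single chain) or list(first, last) residue keys
.region_bounds <- function(structure, region) {
  if (is.null(region)) return(c(0L, structure$n_residues - 1L))
  if (is.list(region) && inherits(region[[1]], "residue_key")) {
    c(.res_ordinal(structure, region[[1]]), .res_ordinal(structure, region[[2]]))
  } else {
    rt <- residue_table(structure)
    c(rt$ordinal[match(region[1], rt$resseq)],
      rt$ordinal[match(region[2], rt$resseq)])
  }
}

#' Detect salt bridges
#'
#' Residue pairs where an acidic side-chain oxygen (ASP OD1/OD2, GLU
#' OE1/OE2) lies within `cutoff` of a basic side-chain nitrogen (LYS NZ,
#' ARG NH1/NH2/NE, HIS ND1/NE2). Each residue pair is reported once with its
#' minimum O-N distance.
#'
#' @param structure a [protein_structure()] with side-chain atoms
#' @param cutoff distance cutoff, A (default 4.0)
#' @return data.frame with `acid`, `base` (residue labels), `acid_ordinal`,
#'   `base_ordinal`, `distance`; zero rows when none found
#' @export
detect_salt_bridges <- function(structure, cutoff = 4.0) {
  a <- structure$atoms
  acid <- which((a$resname == "ASP" & a$name %in% c("OD1", "OD2")) |
                (a$resname == "GLU" & a$name %in% c("OE1", "OE2")))
  base <- which((a$resname == "LYS" & a$name == "NZ") |
                (a$resname == "ARG" & a$name %in% c("NH1", "NH2", "NE")) |
                (a$resname == "HIS" & a$name %in% c("ND1", "NE2")))
  empty <- data.frame(acid = character(), base = character(),
                      acid_ordinal = integer(), base_ordinal = integer(),
                      distance = numeric(), stringsAsFactors = FALSE)
  if (!length(acid) || !length(base)) return(empty)
  xyz <- coords(structure)
  rt <- residue_table(structure)
  lab <- sprintf("%s%d%s", rt$chain, rt$resseq, rt$icode)
  out <- list()
  for (i in acid) for (j in base) {
    d <- sqrt(sum((xyz[i, ] - xyz[j, ])^2))
    if (d <= cutoff) {
      key <- paste(a$res_ord[i], a$res_ord[j])
      if (is.null(out[[key]]) || d < out[[key]]$distance)
        out[[key]] <- data.frame(
          acid = lab[a$res_ord[i] + 1L], base = lab[a$res_ord[j] + 1L],
          acid_ordinal = a$res_ord[i], base_ordinal = a$res_ord[j],
          distance = d, stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) return(empty)
  res <- do.call(rbind, out)
  res <- res[order(res$acid_ordinal, res$base_ordinal), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Count hydrogen bonds in a residue region
#'
#' Geometric criterion: donor nitrogen with a covalently attached hydrogen
#' (same residue, N-H < 1.2 A), acceptor oxygen, donor-acceptor distance
#' <= `dist_cutoff` and donor-H-acceptor angle >= `angle_cutoff`. Pairs in
#' the same or adjacent residues are excluded (covalent neighbourhood).
#'
#' @param structure a [protein_structure()] with hydrogens
#' @param region residue interval: `c(lo, hi)` residue numbers or
#'   `list(first, last)` of [residue_key()]s; `NULL` for the whole structure
#' @param dist_cutoff donor-acceptor distance cutoff, A (default 3.5)
#' @param angle_cutoff donor-H-acceptor angle cutoff, degrees (default 120)
#' @return integer count with the donor/acceptor pair table attached as
#'   attribute `"pairs"`
#' @export
count_hbonds <- function(structure, region = NULL, dist_cutoff = 3.5,
                         angle_cutoff = 120) {
  b <- .region_bounds(structure, region)
  if (anyNA(b) || b[1] > b[2]) stop("empty or invalid region")
  a <- structure$atoms
  inreg <- a$res_ord >= b[1] & a$res_ord <= b[2]
  xyz <- coords(structure)
  don <- which(inreg & a$element == "N")
  hyd <- which(a$element == "H")
  acc <- which(inreg & a$element == "O")
  pairs <- list()
  for (dn in don) {
    hh <- hyd[a$res_ord[hyd] == a$res_ord[dn]]
    if (!length(hh)) next
    hd <- sqrt(rowSums((xyz[hh, , drop = FALSE] -
                        matrix(xyz[dn, ], length(hh), 3, byrow = TRUE))^2))
    hh <- hh[hd < 1.2]
    for (h in hh) for (ac in acc) {
      if (abs(a$res_ord[ac] - a$res_ord[dn]) < 2L) next
      dda <- sqrt(sum((xyz[ac, ] - xyz[dn, ])^2))
      if (dda > dist_cutoff) next
      v1 <- xyz[dn, ] - xyz[h, ]; v2 <- xyz[ac, ] - xyz[h, ]
      ang <- acos(pmin(1, pmax(-1, sum(v1 * v2) /
                   sqrt(sum(v1^2) * sum(v2^2))))) * 180 / pi
      if (ang >= angle_cutoff)
        pairs[[length(pairs) + 1L]] <- data.frame(
          donor_res = a$res_ord[dn], acceptor_res = a$res_ord[ac],
          donor = a$name[dn], acceptor = a$name[ac],
          distance = dda, angle = ang)
    }
  }
  tab <- if (length(pairs)) do.call(rbind, pairs) else
    data.frame(donor_res = integer(), acceptor_res = integer(),
               donor = character(), acceptor = character(),
               distance = numeric(), angle = numeric())
  structure(nrow(tab), pairs = tab)
}
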