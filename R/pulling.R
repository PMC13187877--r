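# Constant-velocity pulling of coarse-grained bead-spring models with
# breakable cross-links. Units follow the molecular-simulation convention:
# nm, ps, amu, kJ/mol; spring constants kJ mol^-1 nm^-2, forces
# kJ mol^-1 nm^-1.

#' Build a coarse-grained bead-spring model
#'
#' One bead per residue, backbone springs between consecutive beads of the
#' same chain, breakable cross-link springs from a table. The default pull
#' groups are all-but-last bead (the main body) and the last bead (the
#' pulling handle).
#'
#' @param structure a bead-per-residue [protein_structure()] (coordinates A,
#'   converted to nm internally)
#' @param crosslinks optional table as from [sample_crosslinks()]: `i`, `j`
#'   (1-based bead indices), `k_spring` (kJ mol^-1 nm^-2), `r0` (nm),
#'   `rupture_extension` (nm)
#' @param k_backbone backbone spring constant, kJ mol^-1 nm^-2; default 10x
#'   the stiffest cross-link (or 15000 with no cross-links) so that unfolding
#'   proceeds by link rupture rather than backbone stretching
#' @param group_a,group_b optional pull-group bead indices
#' @return object of class `CGModel`
#' @export
build_cg_model <- function(structure, crosslinks = NULL, k_backbone = NULL,
                           group_a = NULL, group_b = NULL) {
  xyz <- coords(structure) / 10   # A -> nm
  n <- nrow(xyz)
  if (n < 2L) stop("need at least 2 beads")
  if (!is.null(crosslinks) && nrow(crosslinks) &&
      (max(crosslinks$i, crosslinks$j) > n || min(crosslinks$i, crosslinks$j) < 1))
    stop("cross-link references a missing bead")
  if (is.null(k_backbone))
    k_backbone <- if (!is.null(crosslinks) && nrow(crosslinks))
      10 * max(crosslinks$k_spring) else 15000
  ch <- structure$atoms$chain
  bi <- which(ch[-n] == ch[-1])
  bonds <- data.frame(i = bi, j = bi + 1L, k = k_backbone,
                      r0 = sqrt(rowSums((xyz[bi, , drop = FALSE] -
                                         xyz[bi + 1L, , drop = FALSE])^2)))
  # connectivity over backbone + cross-links
  edges <- rbind(cbind(bonds$i, bonds$j),
                 if (!is.null(crosslinks) && nrow(crosslinks))
                   cbind(crosslinks$i, crosslinks$j))
  comp <- seq_len(n)
  repeat {
    changed <- FALSE
    for (e in seq_len(nrow(edges))) {
      a <- comp[edges[e, 1]]; b <- comp[edges[e, 2]]
      if (a != b) {
        comp[comp == max(a, b)] <- min(a, b)
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  if (length(unique(comp)) > 1L)
    stop("bond graph is disconnected (", length(unique(comp)), " components)")
  if (is.null(group_b)) group_b <- n
  if (is.null(group_a)) group_a <- setdiff(seq_len(n), group_b)
  if (!length(group_a) || !length(group_b) || length(intersect(group_a, group_b)))
    stop("pull groups must be disjoint and non-empty")
  structure(list(xyz = xyz, mass = masses(structure),
                 bonds = bonds,
                 crosslinks = if (is.null(crosslinks))
                   data.frame(i = integer(), j = integer(), k_spring = numeric(),
                              r0 = numeric(), rupture_extension = numeric())
                 else crosslinks,
                 group_a = group_a, group_b = group_b),
            class = "CGModel")
}

#' @export
print.CGModel <- function(x, ...) {
  cat(sprintf("<CGModel: %d beads, %d backbone bonds, %d cross-links>\n",
              nrow(x$xyz), nrow(x$bonds), nrow(x$crosslinks)))
  invisible(x)
}

#' Constant-velocity pulling protocol
#'
#' Defaults follow the standard umbrella-pulling setup: restraint stiffness
#' 1500 kJ mol^-1 nm^-2 between the two group centres of mass, pull rate
#' 0.01 nm ps^-1 along z, 2 fs time step, samples recorded every 1 ps.
#'
#' @param spring_constant restraint stiffness, kJ mol^-1 nm^-2
#' @param pull_rate nm ps^-1 (0 allowed for equilibrium runs, then give
#'   `max_time`)
#' @param temperature K (0 switches thermal noise off)
#' @param timestep fs
#' @param record_interval ps
#' @param axis pulling direction (normalised internally)
#' @param friction Langevin friction, ps^-1 (0 disables the thermostat:
#'   plain velocity-Verlet dynamics)
#' @param max_extension_factor run ends when the group separation reaches
#'   this multiple of its initial value (default 3)
#' @param rupture_grace once every cross-link has ruptured, keep integrating
#'   for this long (ps) to record the force decay, then stop; the remaining
#'   pull would only stretch the intact backbone
#' @param max_time optional wall of simulated time, ps
#' @param seed integer seed
#' @return object of class `PullProtocol`
#' @export
pull_protocol <- function(spring_constant = 1500, pull_rate = 0.01,
                          temperature = 300, timestep = 2,
                          record_interval = 1, axis = c(0, 0, 1),
                          friction = 1, max_extension_factor = 3,
                          rupture_grace = 50, max_time = NULL, seed = 1L) {
  stopifnot(spring_constant > 0, pull_rate >= 0, temperature >= 0,
            timestep > 0, record_interval > 0, max_extension_factor > 1)
  if (pull_rate == 0 && is.null(max_time))
    stop("pull_rate = 0 needs an explicit max_time")
  structure(list(spring_constant = spring_constant, pull_rate = pull_rate,
                 temperature = temperature, timestep = timestep,
                 record_interval = record_interval,
                 axis = axis / sqrt(sum(axis^2)), friction = friction,
                 max_extension_factor = max_extension_factor,
                 rupture_grace = rupture_grace,
                 max_time = max_time, seed = as.integer(seed)),
            class = "PullProtocol")
}

#' Run a constant-velocity pull
#'
#' Langevin (BAOAB) dynamics at the protocol temperature with a harmonic
#' restraint coupling the axis-projected centre-of-mass separation of the two
#' pull groups to a virtual point moving at the pull rate. Cross-links are
#' removed permanently when stretched beyond `r0 + rupture_extension`; each
#' removal is logged as a rupture event. The run ends at the configured
#' maximum extension (or `max_time`).
#'
#' @param model a [build_cg_model()]
#' @param protocol a [pull_protocol()]
#' @return list with `profile` (a `ForceProfile`: time ps, separation nm,
#'   force kJ mol^-1 nm^-1, total energy kJ/mol), `events` (logged link
#'   breakages: time, force, i, j), `model` (final state, broken links
#'   dropped)
#' @export
run_pull <- function(model, protocol) {
  dt <- protocol$timestep / 1000  # fs -> ps
  xi0 <- .initial_separation(model, protocol$axis)
  max_xi <- protocol$max_extension_factor * xi0
  # the restraint lags the moving target by force/spring_constant, so budget
  # twice the nominal travel time; the extension and all-links-ruptured
  # checks stop the run early
  t_needed <- if (protocol$pull_rate > 0)
    2 * (max_xi - xi0) / protocol$pull_rate else Inf
  if (!is.null(protocol$max_time)) t_needed <- min(t_needed, protocol$max_time)
  max_steps <- as.integer(ceiling(t_needed / dt))
  record_every <- max(1L, as.integer(round(protocol$record_interval / dt)))
  xl <- model$crosslinks
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(protocol$seed)
  res <- pull_cpp(model$xyz, model$mass,
                  model$bonds$i, model$bonds$j, model$bonds$k, model$bonds$r0,
                  xl$i, xl$j, xl$k_spring, xl$r0, xl$rupture_extension,
                  model$group_a, model$group_b,
                  protocol$spring_constant, protocol$pull_rate,
                  protocol$temperature, dt, protocol$friction,
                  record_every, max_steps, protocol$axis, max_xi,
                  10L, protocol$rupture_grace)
  if (res$blown)
    stop("integrator blow-up (non-finite coordinates); last stable time ",
         format(res$last_time, digits = 6), " ps")
  profile <- structure(list(
    time = res$time, separation = res$separation, force = res$force,
    energy = res$energy, protocol = protocol, xi0 = res$xi0),
    class = "ForceProfile")
  events <- data.frame(time = res$event_time, force = res$event_force,
                       i = res$event_i, j = res$event_j)
  final <- model
  final$xyz <- res$final_pos
  final$crosslinks <- xl[res$alive, , drop = FALSE]
  list(profile = profile, events = events, model = final)
}

.initial_separation <- function(model, axis) {
  comA <- colSums(model$xyz[model$group_a, , drop = FALSE] *
                  model$mass[model$group_a]) / sum(model$mass[model$group_a])
  comB <- colSums(model$xyz[model$group_b, , drop = FALSE] *
                  model$mass[model$group_b]) / sum(model$mass[model$group_b])
  sum((comB - comA) * axis)
}

#' @export
print.ForceProfile <- function(x, ...) {
  cat(sprintf("<ForceProfile: %d samples over %.1f ps; max force %.1f kJ/mol/nm>\n",
              length(x$time), max(x$time), max(x$force)))
  invisible(x)
}

#' @export
plot.ForceProfile <- function(x, ...) {
  graphics::plot(x$time, x$force, type = "l", xlab = "time (ps)",
                 ylab = "force (kJ/mol/nm)", ...)
  invisible(x)
}

#' Maximum recorded pulling force
#'
#' With `smooth = 0` (default) this is the maximum raw recorded spring
#' force. For rupture analysis a small running-mean window (`smooth` in
#' sample counts, i.e. ps at the default 1 ps recording interval) suppresses
#' the thermal noise of the instantaneous restraint force so the peak
#' reflects the rupture event rather than a noise extreme.
#'
#' @param profile a `ForceProfile`
#' @param smooth running-mean window in samples (0 = raw)
#' @return the maximum force (kJ mol^-1 nm^-1) with its time (ps) as
#'   attribute `"time"`
#' @export
max_force <- function(profile, smooth = 0) {
  if (!length(profile$force)) stop("empty force profile")
  f <- profile$force
  if (smooth > 1) {
    f <- as.numeric(stats::filter(f, rep(1 / smooth, smooth), sides = 2))
  }
  i <- which.max(ifelse(is.na(f), -Inf, f))
  structure(f[i], time = profile$time[i])
}

#' Detect rupture events in a force profile
#'
#' Flags samples where the (lightly smoothed) force drops by at least
#' `drop_fraction` of the preceding local maximum within a trailing window.
#' Peaks below `min_peak_frac` of the profile's overall maximum are ignored:
#' the thermal noise of the restraint force produces relative drops
#' everywhere in the low-force regime, while rupture shows up as a distinct
#' peak on the loading envelope. When integrator-logged link breakages are
#' supplied they are merged in (drop-detected events within `window` of a
#' logged breakage are reported once, with the link identity attached).
#'
#' @param profile a `ForceProfile`
#' @param drop_fraction minimum relative drop (default 0.2)
#' @param window trailing window, ps
#' @param smooth running-mean window in samples applied before detection
#'   (default 11; 1 = raw)
#' @param min_peak_frac minimum peak height as a fraction of the profile
#'   maximum (default 0.25)
#' @param logged_events optional event table from [run_pull()]
#' @return data.frame of events: `time`, `force` (preceding local maximum),
#'   `i`, `j` (NA when not matched to a logged breakage), time-ordered
#' @export
detect_ruptures <- function(profile, drop_fraction = 0.2, window = 20,
                            smooth = 11, min_peak_frac = 0.25,
                            logged_events = NULL) {
  tt <- profile$time; ff <- profile$force
  if (length(ff) < 2L) stop("profile too short")
  if (smooth > 1 && length(ff) > smooth) {
    sm <- as.numeric(stats::filter(ff, rep(1 / smooth, smooth), sides = 2))
    ff <- ifelse(is.na(sm), ff, sm)
  }
  floor_force <- min_peak_frac * max(ff)
  dt <- stats::median(diff(tt))
  w <- max(2L, as.integer(round(window / dt)))
  events <- list()
  k <- 1L
  while (k < length(ff)) {
    # local max over the trailing window, then look for the drop
    hi <- min(length(ff), k + w)
    seg <- ff[k:hi]
    pk <- which.max(seg)
    peak_val <- seg[pk]; peak_idx <- k + pk - 1L
    rest <- ff[peak_idx:hi]
    drop_idx <- which(rest <= peak_val * (1 - drop_fraction))
    if (length(drop_idx) && peak_val >= floor_force) {
      events[[length(events) + 1L]] <-
        data.frame(time = tt[peak_idx], force = peak_val,
                   i = NA_integer_, j = NA_integer_)
      k <- peak_idx + drop_idx[1]
    } else {
      k <- k + max(1L, pk)
    }
  }
  out <- if (length(events)) do.call(rbind, events) else
    data.frame(time = numeric(), force = numeric(),
               i = integer(), j = integer())
  if (!is.null(logged_events) && nrow(logged_events)) {
    for (r in seq_len(nrow(out))) {
      hit <- which(abs(logged_events$time - out$time[r]) <= window)
      if (length(hit)) {
        out$i[r] <- logged_events$i[hit[1]]
        out$j[r] <- logged_events$j[hit[1]]
      }
    }
    # logged breakages not caught by the force detector are appended
    for (r in seq_len(nrow(logged_events))) {
      if (!any(abs(out$time - logged_events$time[r]) <= window &
               (out$i == logged_events$i[r] | is.na(out$i))))
        out <- rbind(out, data.frame(time = logged_events$time[r],
                                     force = logged_events$force[r],
                                     i = logged_events$i[r],
                                     j = logged_events$j[r]))
    }
  }
  out <- out[order(out$time), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Export a force profile as TSV
#'
#' @param profile a `ForceProfile`
#' @param path destination file
#' @export
write_force_profile <- function(profile, path) {
  df <- data.frame(time_ps = profile$time,
                   com_separation_nm = profile$separation,
                   force_kJ_mol_nm = profile$force)
  utils::write.table(format(df, digits = 10, trim = TRUE, scientific = FALSE),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
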