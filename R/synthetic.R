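# Synthetic structures with known statistical properties: ideal geometries,
# homolog pairs differing only by a phospho-like modification and cross-link
# count, and harmonic-equilibrium trajectories. Everything is a pure function
# of its arguments and seed.

#' Specification for a synthetic bead structure
#'
#' @param n_residues number of residues (one C-alpha bead each), >= 2
#' @param geometry one of `"ideal_helix"` (rise 1.5 A, 100 degree twist,
#'   radius 2.3 A), `"extended_chain"` (3.8 A spacing on a line) or
#'   `"lattice"` (snaked cubic grid, 3.8 A spacing)
#' @param crosslink_count number of cross-links to sample (endpoints at least
#'   3 residues apart)
#' @param phospho_site optional 0-based residue ordinal for a phospho-like
#'   bead (extra mass 79 amu)
#' @param seed integer seed; fully determines the output
#' @return a list of class `synthetic_spec`
#' @export
synthetic_spec <- function(n_residues, geometry = "ideal_helix",
                           crosslink_count = 0L, phospho_site = NULL,
                           seed = 1L) {
  if (n_residues < 2L) stop("n_residues must be >= 2")
  if (!geometry %in% c("ideal_helix", "extended_chain", "lattice"))
    stop("unknown geometry tag: ", geometry)
  structure(list(n_residues = as.integer(n_residues), geometry = geometry,
                 crosslink_count = as.integer(crosslink_count),
                 phospho_site = phospho_site, seed = as.integer(seed)),
            class = "synthetic_spec")
}

.bead_positions <- function(n, geometry) {
  i <- seq_len(n) - 1L
  switch(geometry,
    ideal_helix = {
      th <- i * 100 * pi / 180
      cbind(2.3 * cos(th), 2.3 * sin(th), 1.5 * i)
    },
    extended_chain = cbind(3.8 * i, 0, 0),
    lattice = {
      m <- ceiling(n^(1 / 3))
      iz <- i %/% (m * m); rem <- i %% (m * m)
      iy <- rem %/% m; ix <- rem %% m
      # snake so consecutive beads stay 3.8 A apart
      ix <- ifelse(iy %% 2L == 1L, m - 1L - ix, ix)
      iy <- ifelse(iz %% 2L == 1L, m - 1L - iy, iy)
      cbind(3.8 * ix, 3.8 * iy, 3.8 * iz)
    },
    stop("unknown geometry tag: ", geometry))
}

#' Build a synthetic C-alpha bead structure
#'
#' One bead per residue; bead mass defaults to 110 amu (the mean amino-acid
#' residue mass) so that bead-spring frequencies fall in a protein-like range.
#' A `phospho_site` bead carries 79 amu extra (the PO3 group mass) and the
#' residue name `PAS`.
#'
#' @param spec a [synthetic_spec()]
#' @param bead_mass mass per bead, amu
#' @return a [protein_structure()]; if `crosslink_count > 0` the sampled
#'   cross-link table (see [sample_crosslinks()]) is attached as attribute
#'   `"crosslinks"`
#' @export
make_structure <- function(spec, bead_mass = 110) {
  n <- spec$n_residues
  xyz <- .bead_positions(n, spec$geometry)
  mass <- rep(bead_mass, n)
  resname <- rep("ALA", n)
  if (!is.null(spec$phospho_site)) {
    ps <- spec$phospho_site + 1L
    stopifnot(ps >= 1L, ps <= n)
    mass[ps] <- mass[ps] + 79
    resname[ps] <- "PAS"
  }
  s <- protein_structure(data.frame(
    serial = seq_len(n), name = "CA", element = "C", resname = resname,
    resseq = seq_len(n), chain = "A", icode = "", x = xyz[, 1], y = xyz[, 2],
    z = xyz[, 3], mass = mass, charge = 0, stringsAsFactors = FALSE),
    title = sprintf("synthetic %s n=%d seed=%d", spec$geometry, n, spec$seed))
  if (spec$crosslink_count > 0L) {
    attr(s, "crosslinks") <- sample_crosslinks(
      n, spec$crosslink_count, seed = spec$seed, coords = xyz)
  }
  s
}

#' Sample cross-links between beads
#'
#' Chooses `count` distinct bead pairs uniformly (seeded) among pairs with
#' ordinal separation >= `min_sep` inside `region`, preferring spatially
#' close pairs (within `max_dist` Angstrom when coordinates are supplied) so
#' that links are physically plausible. Rest lengths are set to the native
#' pair distance.
#'
#' @param n_residues chain length
#' @param count number of links
#' @param region inclusive 1-based residue bounds, default whole chain
#' @param min_sep minimum ordinal separation, default 3
#' @param seed integer seed
#' @param coords optional n x 3 bead coordinates (A) used for rest lengths
#' @param k_spring spring constant, kJ mol^-1 nm^-2
#' @param rupture_extension extension beyond rest length at which the link
#'   breaks, nm
#' @param max_dist largest native distance (A) eligible when `coords` given
#' @return data.frame with columns `i`, `j` (1-based bead indices),
#'   `k_spring`, `r0` (nm), `rupture_extension` (nm)
#' @export
sample_crosslinks <- function(n_residues, count, region = c(1L, n_residues),
                              min_sep = 3L, seed = 1L, coords = NULL,
                              k_spring = 5000, rupture_extension = 0.3,
                              max_dist = 12) {
  lo <- region[1]; hi <- region[2]
  pairs <- expand.grid(i = lo:hi, j = lo:hi)
  pairs <- pairs[pairs$j - pairs$i >= min_sep, , drop = FALSE]
  if (!is.null(coords)) {
    d <- sqrt(rowSums((coords[pairs$i, , drop = FALSE] -
                       coords[pairs$j, , drop = FALSE])^2))
    ok <- d <= max_dist
    if (sum(ok) >= count) { pairs <- pairs[ok, , drop = FALSE]; d <- d[ok] }
  }
  if (nrow(pairs) < count)
    stop("only ", nrow(pairs), " eligible pairs for ", count, " cross-links")
  pick <- local({
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
    sample.int(nrow(pairs), count)
  })
  sel <- pairs[pick, , drop = FALSE]
  r0 <- if (!is.null(coords)) {
    sqrt(rowSums((coords[sel$i, , drop = FALSE] -
                  coords[sel$j, , drop = FALSE])^2)) / 10  # A -> nm
  } else rep(0.5, count)
  out <- data.frame(i = sel$i, j = sel$j, k_spring = k_spring, r0 = r0,
                    rupture_extension = rupture_extension)
  out[order(out$i, out$j), , drop = FALSE]
}

#' Write / read a plain-text cross-link table
#'
#' @param links data.frame as returned by [sample_crosslinks()]
#' @param path file path
#' @return `read_crosslinks` returns the data.frame
#' @export
write_crosslinks <- function(links, path) {
  utils::write.table(format(links, digits = 10), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_crosslinks
#' @export
read_crosslinks <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t")
}

#' Generate a homologous structure pair differing by a phospho modification
#'
#' Emulates a pair of structurally identical proteins whose C-terminal halves
#' differ in the number of stabilising cross-links (standing in for hydrogen
#' bonds), and of which only one carries a phospho-like modification: model A
#' has `strong_links` cross-links in residues `link_region`, an extra bead
#' mass of 79 amu at `phospho_site`, and one extra hydrogen-bond-class
#' spring from the phospho site to the bead `partner_offset` ordinals
#' downstream (the aspartate-55/aspartate-62 style core contact, stiff
#' relative to the elastic-network background). Model B has the first
#' `weak_links` of A's cross-links and no modification. Backbone coordinates
#' of A and B are identical, so downstream maps are directly comparable.
#'
#' @param n_residues chain length, default 128
#' @param strong_links,weak_links cross-link counts (strong > weak >= 0)
#' @param seed integer seed
#' @param phospho_site 0-based ordinal of the modified residue; the default
#'   (`NULL`) is residue 55 for the 128-residue reference length and the
#'   same proportional position otherwise
#' @param partner_offset ordinal offset to the contact partner (default 7,
#'   the 55-to-62 spacing)
#' @param link_region 1-based residue bounds for the cross-links; default
#'   residues 79..n for the reference length (the C-terminal region), the
#'   same proportional position otherwise
#' @param k_link,k_phospho cross-link and phospho-contact spring constants,
#'   kJ mol^-1 nm^-2
#' @return list with elements `A` and `B`, each a list of `structure` (a
#'   [protein_structure()]) and `crosslinks` (table as in
#'   [sample_crosslinks()]); attributes `phospho_site` and `phospho_partner`
#'   give the 0-based ordinals of the modified pair
#' @export
make_homolog_pair <- function(n_residues = 128L, strong_links = 9L,
                              weak_links = 2L, seed = 1L,
                              phospho_site = NULL, partner_offset = 7L,
                              link_region = NULL,
                              k_link = 5000, k_phospho = 5000) {
  if (!(strong_links > weak_links && weak_links >= 0L))
    stop("need strong_links > weak_links >= 0")
  if (is.null(phospho_site))
    phospho_site <- as.integer(round(54 / 128 * n_residues))
  if (is.null(link_region))
    link_region <- c(as.integer(round(79 / 128 * n_residues)), n_residues)
  xyz <- .bead_positions(n_residues, "ideal_helix")
  links_a <- sample_crosslinks(n_residues, strong_links, region = link_region,
                               seed = seed, coords = xyz, k_spring = k_link)
  links_b <- links_a[seq_len(weak_links), , drop = FALSE]
  sa <- make_structure(synthetic_spec(n_residues, "ideal_helix",
                                      phospho_site = phospho_site, seed = seed))
  sb <- make_structure(synthetic_spec(n_residues, "ideal_helix", seed = seed))
  partner <- phospho_site + partner_offset
  if (partner >= n_residues) stop("phospho partner beyond chain end")
  pr0 <- sqrt(sum((xyz[phospho_site + 1L, ] - xyz[partner + 1L, ])^2)) / 10
  plink <- data.frame(i = phospho_site + 1L, j = partner + 1L,
                      k_spring = k_phospho, r0 = pr0, rupture_extension = 0.3)
  out <- list(A = list(structure = sa, crosslinks = rbind(plink, links_a)),
              B = list(structure = sb, crosslinks = links_b))
  attr(out, "phospho_site") <- phospho_site
  attr(out, "phospho_partner") <- partner
  out
}

#' Synthetic full-backbone helix with ideal hydrogen-bond geometry
#'
#' Builds an N/H/CA/C/O backbone around the ideal C-alpha helix so that every
#' residue i donates exactly one hydrogen bond to the carbonyl oxygen of
#' residue i-4 (donor-acceptor distance about 3.4 A, linear N-H...O). Used to
#' exercise geometric hydrogen-bond counting on a structure whose bond count
#' is known by construction.
#'
#' @param n_residues number of residues (>= 6)
#' @return a [protein_structure()]
#' @export
make_backbone_helix <- function(n_residues) {
  stopifnot(n_residues >= 6L)
  ca_ext <- .bead_positions(n_residues + 4L, "ideal_helix")
  ca <- ca_ext[seq_len(n_residues), , drop = FALSE]
  # ideal i -> i+4 direction from the helix parametrisation (virtual beads
  # beyond the chain end keep the trailing donors on-geometry)
  d <- ca_ext[5:(n_residues + 4L), , drop = FALSE] - ca
  d <- d / sqrt(rowSums(d^2))
  rows <- vector("list", n_residues)
  for (i in seq_len(n_residues)) {
    Ni <- ca[i, ] - 1.4 * d[i, ]
    Oi <- ca[i, ] + 1.4 * d[i, ]
    Ci <- ca[i, ] + 0.7 * d[i, ]
    Hi <- if (i > 4L) {
      acc <- ca[i - 4L, ] + 1.4 * d[i - 4L, ]
      u <- acc - Ni
      Ni + u / sqrt(sum(u^2))
    } else Ni - 1.0 * d[i, ]
    rows[[i]] <- data.frame(
      name = c("N", "H", "CA", "C", "O"),
      element = c("N", "H", "C", "C", "O"),
      resname = "ALA", resseq = i, chain = "A", icode = "",
      x = c(Ni[1], Hi[1], ca[i, 1], Ci[1], Oi[1]),
      y = c(Ni[2], Hi[2], ca[i, 2], Ci[2], Oi[2]),
      z = c(Ni[3], Hi[3], ca[i, 3], Ci[3], Oi[3]),
      stringsAsFactors = FALSE)
  }
  protein_structure(do.call(rbind, rows),
                    title = sprintf("synthetic backbone helix n=%d", n_residues))
}
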