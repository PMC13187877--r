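# Harmonic potential models: an elastic network (all pairs within a distance
# cutoff) or an explicit pairwise spring list. Energies in kcal/mol, lengths
# in Angstrom, spring constants in kcal mol^-1 A^-2.

#' Elastic-network potential model
#'
#' Springs connect every atom pair within `cutoff` Angstrom; rest lengths are
#' the pair distances in the reference structure, so the reference is an
#' exact energy minimum.
#'
#' @param cutoff distance cutoff, Angstrom (default 12)
#' @param k uniform spring constant, kcal mol^-1 A^-2 (default 1)
#' @return a `PotentialModel`
#' @export
enm_model <- function(cutoff = 12, k = 1) {
  stopifnot(cutoff > 0, k > 0)
  structure(list(kind = "enm", cutoff = cutoff, k = k),
            class = "PotentialModel")
}

#' Explicit pairwise-spring potential model
#'
#' @param springs data.frame with columns `i`, `j` (1-based atom indices),
#'   `k` (kcal mol^-1 A^-2) and `r0` (A)
#' @return a `PotentialModel`
#' @export
spring_model <- function(springs) {
  stopifnot(all(c("i", "j", "k", "r0") %in% names(springs)),
            all(springs$k > 0), all(springs$i != springs$j))
  structure(list(kind = "pairwise_springs", springs = springs),
            class = "PotentialModel")
}

#' Elastic network augmented with explicit cross-links
#'
#' Combines the uniform-cutoff elastic network of a structure with the
#' cross-link table of [sample_crosslinks()] (units converted from
#' kJ mol^-1 nm^-2 / nm to kcal mol^-1 A^-2 / A). Cross-link springs add on
#' top of any elastic-network spring connecting the same pair.
#'
#' @param structure a [protein_structure()] (bead-per-residue)
#' @param crosslinks cross-link table (`i`, `j`, `k_spring`, `r0`)
#' @param cutoff elastic-network cutoff, A
#' @param k elastic-network spring constant, kcal mol^-1 A^-2
#' @return a `PotentialModel` of kind `pairwise_springs`
#' @export
enm_with_links <- function(structure, crosslinks, cutoff = 12, k = 1) {
  base <- .enm_springs(coords(structure), cutoff, k)
  if (!is.null(crosslinks) && nrow(crosslinks)) {
    extra <- data.frame(i = crosslinks$i, j = crosslinks$j,
                        k = crosslinks$k_spring / vedmap_constants$KCAL_A2_TO_KJ_NM2,
                        r0 = crosslinks$r0 * 10)
    base <- rbind(base, extra)
  }
  spring_model(base)
}

# enumerate ENM springs for a coordinate set
.enm_springs <- function(xyz, cutoff, k) {
  d <- as.matrix(stats::dist(xyz))
  sel <- which(upper.tri(d) & d <= cutoff & d > 1e-6, arr.ind = TRUE)
  if (!nrow(sel)) stop("no springs under cutoff ", cutoff)
  deg <- tabulate(c(sel[, 1], sel[, 2]), nbins = nrow(xyz))
  if (any(deg == 0))
    stop("atom(s) with zero neighbours under enm cutoff: ",
         paste(which(deg == 0), collapse = ", "))
  data.frame(i = sel[, 1], j = sel[, 2], k = k, r0 = d[sel])
}

# resolve a model to its spring list for given coordinates
model_springs <- function(model, xyz) {
  if (model$kind == "enm") .enm_springs(xyz, model$cutoff, model$k)
  else model$springs
}

#' Potential energy and gradient of a spring network
#'
#' @param model a `PotentialModel`
#' @param xyz N x 3 coordinates, A; for an `enm` model the springs are fixed
#'   from `ref_xyz` (default `xyz` itself)
#' @param ref_xyz reference coordinates defining enm connectivity
#' @return `spring_energy`: scalar kcal/mol. `spring_gradient`: N x 3 matrix
#'   kcal mol^-1 A^-1.
#' @export
spring_energy <- function(model, xyz, ref_xyz = xyz) {
  sp <- model_springs(model, ref_xyz)
  dv <- xyz[sp$i, , drop = FALSE] - xyz[sp$j, , drop = FALSE]
  d <- sqrt(rowSums(dv^2))
  sum(0.5 * sp$k * (d - sp$r0)^2)
}

#' @rdname spring_energy
#' @export
spring_gradient <- function(model, xyz, ref_xyz = xyz) {
  sp <- model_springs(model, ref_xyz)
  dv <- xyz[sp$i, , drop = FALSE] - xyz[sp$j, , drop = FALSE]
  d <- sqrt(rowSums(dv^2))
  fac <- sp$k * (d - sp$r0) / pmax(d, 1e-12)
  g <- matrix(0, nrow(xyz), 3)
  idx <- c(sp$i, sp$j)
  for (c in 1:3) {
    gc <- fac * dv[, c]
    tmp <- rowsum(c(gc, -gc), idx)
    g[as.integer(rownames(tmp)), c] <- tmp[, 1]
  }
  g
}
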