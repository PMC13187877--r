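# Small structures built in code, shared across test files.

# a one-residue alanine backbone fragment as PDB text
ala_pdb_lines <- function() {
  c("ATOM      1  N   ALA A   1       0.000   0.000   0.000  1.00  0.00           N",
    "ATOM      2  CA  ALA A   1       1.458   0.000   0.000  1.00  0.00           C",
    "ATOM      3  C   ALA A   1       2.009   1.420   0.000  1.00  0.00           C")
}

write_ala_pdb <- function(path, extra = character()) {
  writeLines(c(ala_pdb_lines(), extra, "END"), path)
  path
}

# toy aspartate with a full side chain (idealised geometry, not stereochemical)
toy_asp <- function(resseq = 1, chain = "A", shift = c(0, 0, 0)) {
  df <- data.frame(
    name = c("N", "CA", "CB", "CG", "OD1", "OD2"),
    element = c("N", "C", "C", "C", "O", "O"),
    resname = "ASP", resseq = resseq, chain = chain, icode = "",
    x = c(0.0, 1.5, 2.2, 3.7, 4.4, 4.3),
    y = c(0.0, 0.0, 1.3, 1.3, 2.3, 0.2),
    z = 0,
    stringsAsFactors = FALSE)
  df$x <- df$x + shift[1]; df$y <- df$y + shift[2]; df$z <- df$z + shift[3]
  df
}

# free 1-D chain of point masses on the x axis with nearest-neighbour springs
chain_structure <- function(n, mass = 1, spacing = 3.8) {
  protein_structure(data.frame(
    name = "CA", element = "C", resname = "ALA", resseq = seq_len(n),
    chain = "A", x = spacing * (seq_len(n) - 1), y = 0, z = 0,
    mass = rep(mass, length.out = n)))
}

chain_springs <- function(n, k = 1, spacing = 3.8) {
  data.frame(i = seq_len(n - 1), j = 2:n, k = k, r0 = spacing)
}

# random well-connected 3-D spring network (positions are its rest state only
# when r0 is set to the current distances)
random_network <- function(n, seed, minimum = TRUE) {
  set.seed(seed)
  xyz <- matrix(stats::rnorm(3 * n, sd = 3), n, 3)
  s <- protein_structure(data.frame(
    name = "CA", element = "C", resname = "ALA", resseq = seq_len(n),
    chain = "A", x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
    mass = stats::runif(n, 1, 3)))
  d <- as.matrix(stats::dist(xyz))
  sel <- which(upper.tri(d), arr.ind = TRUE)
  sp <- data.frame(i = sel[, 1], j = sel[, 2],
                   k = stats::runif(nrow(sel), 0.5, 2), r0 = d[upper.tri(d)])
  if (!minimum) sp$r0 <- sp$r0 * stats::runif(nrow(sp), 0.8, 1.2)
  list(structure = s, springs = sp)
}
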