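# ProteinStructure: an ordered atom table plus residue bookkeeping.
# Atoms live in a data.frame (serial, name, element, resname, resseq, chain,
# icode, x, y, z, mass, charge); residues are addressed either by author
# numbering (chain, resseq, icode) or by a contiguous 0-based ordinal.

#' Construct a residue key
#'
#' A residue key addresses a residue by PDB author numbering: chain identifier,
#' residue sequence number and (optional) insertion code. Keys are totally
#' ordered by (chain, seq, insertion code).
#'
#' @param chain single-character chain identifier
#' @param resseq integer residue sequence number
#' @param icode insertion code, default `""`
#' @return an object of class `residue_key`
#' @export
residue_key <- function(chain, resseq, icode = "") {
  stopifnot(is.character(chain), nchar(chain) == 1L, length(resseq) == 1L)
  structure(list(chain = chain, resseq = as.integer(resseq), icode = icode),
            class = "residue_key")
}

#' @export
format.residue_key <- function(x, ...) {
  sprintf("%s/%d%s", x$chain, x$resseq, x$icode)
}

#' @export
print.residue_key <- function(x, ...) {
  cat("<residue ", format(x), ">\n", sep = "")
  invisible(x)
}

# canonical string used for ordering and lookup
.key_string <- function(chain, resseq, icode) {
  sprintf("%s|%09d|%s", chain, as.integer(resseq), icode)
}

#' Construct a protein structure from an atom table
#'
#' @param atoms data.frame with columns `serial`, `name`, `element`,
#'   `resname`, `resseq`, `chain`, `icode`, `x`, `y`, `z`, `mass`, `charge`.
#'   Missing `element` entries are inferred from the first alphabetic
#'   character of the atom name; missing `mass` is filled from the element;
#'   missing `charge` defaults to 0.
#' @param title free-text title
#' @return object of class `ProteinStructure`: the atom table plus a residue
#'   index mapping each (chain, resseq, icode) to a contiguous 0-based ordinal
#'   in order of first appearance.
#' @export
protein_structure <- function(atoms, title = "") {
  atoms <- as.data.frame(atoms, stringsAsFactors = FALSE)
  need <- c("name", "resname", "resseq", "chain", "x", "y", "z")
  miss <- setdiff(need, names(atoms))
  if (length(miss)) stop("atom table lacks columns: ", paste(miss, collapse = ", "))
  n <- nrow(atoms)
  if (n < 1L) stop("structure has zero atoms")
  if (is.null(atoms$serial)) atoms$serial <- seq_len(n)
  if (is.null(atoms$icode)) atoms$icode <- ""
  atoms$icode[is.na(atoms$icode)] <- ""
  if (is.null(atoms$element) || anyNA(atoms$element) || any(atoms$element == "")) {
    guess <- .element_from_name(atoms$name)
    if (is.null(atoms$element)) atoms$element <- guess
    fix <- is.na(atoms$element) | atoms$element == ""
    atoms$element[fix] <- guess[fix]
  }
  if (is.null(atoms$mass)) atoms$mass <- element_mass(atoms$element)
  if (anyNA(atoms$mass)) {
    i <- is.na(atoms$mass)
    atoms$mass[i] <- element_mass(atoms$element[i])
  }
  if (is.null(atoms$charge)) atoms$charge <- 0
  atoms$charge[is.na(atoms$charge)] <- 0
  if (!all(is.finite(as.matrix(atoms[, c("x", "y", "z")]))))
    stop("non-finite coordinates in atom table")
  if (any(atoms$mass <= 0)) stop("non-positive atom mass")
  ks <- .key_string(atoms$chain, atoms$resseq, atoms$icode)
  dup <- duplicated(paste(ks, atoms$name, sep = "@"))
  if (any(dup))
    stop("duplicate atom identity (chain, resseq, icode, name): ",
         paste(atoms$name[dup][1], ks[dup][1]))
  ord <- match(ks, unique(ks)) - 1L  # 0-based, order of first appearance
  atoms$res_ord <- ord
  structure(list(atoms = atoms, title = title,
                 n_residues = max(ord) + 1L),
            class = "ProteinStructure")
}

.element_from_name <- function(name) {
  vapply(name, function(nm) {
    ch <- regmatches(nm, regexpr("[A-Za-z]", nm))
    if (!length(ch)) stop("cannot infer element from atom name '", nm, "'")
    toupper(ch)
  }, character(1), USE.NAMES = FALSE)
}

#' @export
print.ProteinStructure <- function(x, ...) {
  cat(sprintf("<ProteinStructure: %d atoms, %d residues%s>\n",
              nrow(x$atoms), x$n_residues,
              if (nzchar(x$title)) paste0(", '", x$title, "'") else ""))
  invisible(x)
}

#' Coordinates of a structure as an N x 3 matrix
#' @param structure a `ProteinStructure`
#' @return numeric matrix, Angstrom
#' @export
coords <- function(structure) {
  m <- as.matrix(structure$atoms[, c("x", "y", "z")])
  dimnames(m) <- NULL
  m
}

#' Atom masses of a structure
#' @param structure a `ProteinStructure`
#' @return numeric vector, amu
#' @export
masses <- function(structure) structure$atoms$mass

#' Residue keys of a structure in ordinal order
#' @param structure a `ProteinStructure`
#' @return data.frame with chain, resseq, icode, resname, ordinal (0-based)
#' @export
residue_table <- function(structure) {
  a <- structure$atoms
  first <- !duplicated(a$res_ord)
  data.frame(chain = a$chain[first], resseq = a$resseq[first],
             icode = a$icode[first], resname = a$resname[first],
             ordinal = a$res_ord[first], stringsAsFactors = FALSE)
}

# ordinal (0-based) of a residue_key, or NA
.res_ordinal <- function(structure, key) {
  a <- structure$atoms
  hit <- a$chain == key$chain & a$resseq == key$resseq & a$icode == key$icode
  if (!any(hit)) return(NA_integer_)
  a$res_ord[which(hit)[1]]
}

#' Read a protein structure from a PDB file
#'
#' Interprets ATOM/HETATM/TER/MODEL/ENDMDL records of a fixed-column (v3.3)
#' PDB file. Only the first MODEL of a multi-model file is read (use
#' [read_trajectory_pdb()] for trajectories). Alternate locations other than
#' `' '` or `'A'` are dropped. Masses are assigned from the element column,
#' falling back to the first alphabetic character of the atom name.
#'
#' @param path file path
#' @param keep_waters keep residues named HOH/WAT? default `FALSE`
#' @param chain_filter optional character vector of chain ids to retain
#' @return a [protein_structure()]
#' @export
read_pdb <- function(path, keep_waters = FALSE, chain_filter = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  rec <- substr(lines, 1, 6)
  in_model1 <- TRUE
  keep <- logical(length(lines))
  for (i in seq_along(lines)) {
    r <- rec[i]
    if (startsWith(r, "MODEL")) {
      # a second MODEL record ends reading
      if (!in_model1) break
    } else if (startsWith(r, "ENDMDL")) {
      in_model1 <- FALSE
    } else if ((r == "ATOM  " || r == "HETATM") && in_model1) {
      keep[i] <- TRUE
    }
  }
  idx <- which(keep)
  if (!length(idx)) stop("no ATOM/HETATM records in ", path)
  ln <- lines[idx]
  fld <- function(a, b) substr(ln, a, b)
  xs <- suppressWarnings(as.numeric(fld(31, 38)))
  ys <- suppressWarnings(as.numeric(fld(39, 46)))
  zs <- suppressWarnings(as.numeric(fld(47, 54)))
  bad <- which(is.na(xs) | is.na(ys) | is.na(zs))
  if (length(bad))
    stop("malformed coordinate fields at line ", idx[bad[1]], " of ", path)
  altloc <- fld(17, 17)
  name <- trimws(fld(13, 16))
  resname <- trimws(fld(18, 20))
  chain <- fld(22, 22)
  resseq <- suppressWarnings(as.integer(fld(23, 26)))
  if (anyNA(resseq))
    stop("malformed residue number at line ", idx[which(is.na(resseq))[1]], " of ", path)
  icode <- trimws(fld(27, 27))
  element <- trimws(fld(77, 78))
  serial <- suppressWarnings(as.integer(fld(7, 11)))
  sel <- altloc %in% c(" ", "A", "")
  if (!keep_waters) sel <- sel & !(resname %in% c("HOH", "WAT"))
  if (!is.null(chain_filter)) sel <- sel & chain %in% chain_filter
  if (!any(sel)) stop("zero atoms after filtering in ", path)
  atoms <- data.frame(serial = serial[sel], name = name[sel],
                      element = element[sel], resname = resname[sel],
                      resseq = resseq[sel], chain = chain[sel],
                      icode = icode[sel], x = xs[sel], y = ys[sel], z = zs[sel],
                      stringsAsFactors = FALSE)
  atoms$element[atoms$element == ""] <- NA_character_
  protein_structure(atoms, title = basename(path))
}

# one fixed-column ATOM/HETATM line
.pdb_atom_line <- function(serial, name, resname, chain, resseq, icode,
                           x, y, z, element, het = FALSE) {
  # atom names of 1-3 chars start in column 14 unless 4 chars
  nm <- if (nchar(name) >= 4L) substr(name, 1, 4) else sprintf(" %-3s", name)
  sprintf("%-6s%5d %-4s %-3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          if (het) "HETATM" else "ATOM", serial %% 100000L, nm, resname, chain,
          resseq %% 10000L, ifelse(nzchar(icode), icode, " "),
          x, y, z, 1.00, 0.00, substr(element, 1, 2))
}

#' Write a protein structure to a PDB file
#'
#' Coordinates are written with 3 decimals (the PDB fixed-column precision);
#' a round trip through [read_pdb()] reproduces atom names, numbering and
#' coordinates to that precision.
#'
#' @param structure a `ProteinStructure`
#' @param path destination file
#' @export
write_pdb <- function(structure, path) {
  a <- structure$atoms
  std <- c(
    "ALA","ARG","ASN","ASP","CYS","GLN","GLU","GLY","HIS","ILE","LEU","LYS",
    "MET","PHE","PRO","SER","THR","TRP","TYR","VAL")
  lines <- character(nrow(a) + 2L)
  lines[1] <- sprintf("TITLE     %s", structure$title)
  for (i in seq_len(nrow(a))) {
    lines[i + 1L] <- .pdb_atom_line(a$serial[i], a$name[i], a$resname[i],
                                    a$chain[i], a$resseq[i], a$icode[i],
                                    a$x[i], a$y[i], a$z[i], a$element[i],
                                    het = !(a$resname[i] %in% std))
  }
  lines[length(lines)] <- "END"
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(lines, con)
  invisible(path)
}

#' Attach a phosphoryl group to an aspartate-like residue
#'
#' Models the covalent PO3(2-) modification of an aspartate side chain: a
#' phosphorus atom is bonded to one carboxylate oxygen (bridge P-O 1.6 A) and
#' three terminal oxygens are placed at ideal tetrahedral geometry (P-O
#' 1.5 A). The added charge of -2 is spread uniformly over the three terminal
#' oxygens. The residue is renamed to the phospho variant label; all other
#' residues are untouched.
#'
#' @param structure a `ProteinStructure`
#' @param target a [residue_key()] addressing the acceptor residue
#' @param acceptor_resnames residue names accepted as patchable, default `"ASP"`
#' @param patched_label residue name given to the modified residue
#' @return a new `ProteinStructure` with four atoms appended to the target
#' @export
apply_phospho_patch <- function(structure, target,
                                acceptor_resnames = "ASP",
                                patched_label = "PAS") {
  a <- structure$atoms
  ord <- .res_ordinal(structure, target)
  if (is.na(ord)) stop("target residue ", format(target), " not found")
  ri <- which(a$res_ord == ord)
  rn <- a$resname[ri[1]]
  if (rn == patched_label || any(a$element[ri] == "P"))
    stop("residue ", format(target), " is already phosphorylated")
  if (!rn %in% acceptor_resnames)
    stop("residue ", format(target), " is ", rn, ", not an accepted acceptor")
  onames <- intersect(c("OD1", "OD2", "OE1", "OE2"), a$name[ri])
  if (!length(onames))
    stop("residue ", format(target), " lacks a side-chain carboxylate oxygen")
  oi <- ri[match(onames[1], a$name[ri])]
  o_pos <- as.numeric(a[oi, c("x", "y", "z")])
  # direction away from the carboxylate carbon (CG/CD), else residue centroid
  ci <- ri[match(c("CG", "CD"), a$name[ri])]
  ci <- ci[!is.na(ci)]
  anchor <- if (length(ci)) as.numeric(a[ci[1], c("x", "y", "z")]) else
    colMeans(a[ri, c("x", "y", "z")])
  u <- o_pos - anchor
  nu <- sqrt(sum(u^2))
  u <- if (nu > 1e-8) u / nu else c(0, 0, 1)
  p_pos <- o_pos + 1.6 * u
  # orthonormal frame around u for the three terminal oxygens
  ref <- if (abs(u[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  v <- ref - sum(ref * u) * u; v <- v / sqrt(sum(v^2))
  w <- c(u[2] * v[3] - u[3] * v[2], u[3] * v[1] - u[1] * v[3],
         u[1] * v[2] - u[2] * v[1])
  tet <- 109.471 * pi / 180
  # terminal P-O directions at the tetrahedral angle from the O-P bridge bond
  newo <- t(vapply(c(0, 2 * pi / 3, 4 * pi / 3), function(phi) {
    d <- cos(pi - tet) * u + sin(pi - tet) * (cos(phi) * v + sin(phi) * w)
    p_pos + 1.5 * d
  }, numeric(3)))
  add <- data.frame(
    serial = max(a$serial) + 1:4,
    name = c("P", "O1P", "O2P", "O3P"),
    element = c("P", "O", "O", "O"),
    resname = patched_label,
    resseq = a$resseq[ri[1]], chain = a$chain[ri[1]], icode = a$icode[ri[1]],
    x = c(p_pos[1], newo[, 1]), y = c(p_pos[2], newo[, 2]),
    z = c(p_pos[3], newo[, 3]),
    mass = element_mass(c("P", "O", "O", "O")),
    charge = c(0, -2 / 3, -2 / 3, -2 / 3),
    stringsAsFactors = FALSE)
  a$resname[ri] <- patched_label
  # insert the new atoms directly after the target residue to keep residue
  # atoms contiguous
  last <- ri[length(ri)]
  out <- rbind(a[seq_len(last), setdiff(names(a), "res_ord")],
               add,
               if (last < nrow(a)) a[(last + 1):nrow(a), setdiff(names(a), "res_ord")])
  protein_structure(out, title = structure$title)
}

#' Extract a contiguous residue interval
#'
#' Returns the substructure spanning the closed residue interval
#' `[first, last]` in residue order; ordinals are renumbered from 0.
#'
#' @param structure a `ProteinStructure`
#' @param first,last [residue_key()]s bounding the selection (inclusive)
#' @return a `ProteinStructure`
#' @export
select_region <- function(structure, first, last) {
  o1 <- .res_ordinal(structure, first)
  o2 <- .res_ordinal(structure, last)
  if (is.na(o1)) stop("residue ", format(first), " not found")
  if (is.na(o2)) stop("residue ", format(last), " not found")
  if (o1 > o2) stop("first residue is after last in residue order")
  a <- structure$atoms
  sel <- a$res_ord >= o1 & a$res_ord <= o2
  if (!any(sel)) stop("empty selection")
  protein_structure(a[sel, setdiff(names(a), "res_ord")],
                    title = structure$title)
}
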