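# Protein-protein interface analysis from atomic coordinates: contact
# census at a distance cutoff, hydrogen-bond detection by donor/acceptor
# geometry, per-residue contact shares, and buried solvent-accessible
# surface area by Shrake-Rupley sphere-point quadrature.

# Bondi van der Waals radii (A) for the elements found in protein/peptide
# crystal structures; calcium/sodium/magnesium ionic-vdW values included so
# metal sites do not abort an area calculation.
VDW_RADII <- c(H = 1.20, C = 1.70, N = 1.55, O = 1.52, S = 1.80,
               P = 1.80, SE = 1.90, F = 1.47, CL = 1.75, BR = 1.85,
               I = 1.98, "NA" = 2.27, K = 2.75, MG = 1.73, CA = 2.31,
               ZN = 1.39, MN = 1.73, FE = 1.70)

WATER_RESNAMES <- c("HOH", "WAT", "H2O", "DOD")
ION_RESNAMES <- c("CA", "NA", "K", "MG", "ZN", "CL", "MN", "FE", "SO4", "PO4")

#' Structure container for interface analysis
#'
#' @param atoms Data frame with columns `chain`, `resno` (integer),
#'   `insert` (insertion code, "" if none), `resid` (residue name),
#'   `elety` (atom name), `elesy` (element symbol), `x`, `y`, `z` (A),
#'   `o` (occupancy), `b` (B-factor), `is_water`, `is_ion` (logical).
#' @return Object of class `xtal_structure`.
#' @export
xtal_structure <- function(atoms) {
  need <- c("chain", "resno", "insert", "resid", "elety", "elesy",
            "x", "y", "z", "o", "b", "is_water", "is_ion")
  if (!all(need %in% names(atoms)))
    stop("atoms table needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  if (any(!is.finite(atoms$x) | !is.finite(atoms$y) | !is.finite(atoms$z)))
    stop("all coordinates must be finite", call. = FALSE)
  key <- paste(atoms$chain, atoms$resno, atoms$insert, atoms$elety)
  if (anyDuplicated(key))
    stop("duplicate (chain, residue, atom) keys in structure", call. = FALSE)
  structure(list(atoms = atoms), class = "xtal_structure")
}

#' @export
print.xtal_structure <- function(x, ...) {
  a <- x$atoms
  cat(sprintf("Structure: %d atoms, chains %s (%d waters, %d ions)\n",
              nrow(a), paste(sort(unique(a$chain)), collapse = ","),
              sum(a$is_water), sum(a$is_ion)))
  invisible(x)
}

#' Read a PDB-format coordinate file
#'
#' Parses ATOM/HETATM records (via bio3d), keeping residue numbering and
#' insertion codes verbatim.  For alternate locations only the
#' highest-occupancy altloc of each atom is kept.  Waters and common ions
#' are flagged, not removed.
#'
#' @param path Path to a PDB file.
#' @return An [xtal_structure()].
#' @export
read_structure <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  pdb <- bio3d::read.pdb(path, verbose = FALSE)
  a <- pdb$atom
  a$insert[is.na(a$insert)] <- ""
  a$alt[is.na(a$alt)] <- ""
  # keep highest-occupancy altloc per (chain, resno, insert, atom name)
  if (any(a$alt != "")) {
    key <- paste(a$chain, a$resno, a$insert, a$elety)
    ord <- order(key, -a$o)
    a <- a[ord, ]
    a <- a[!duplicated(paste(a$chain, a$resno, a$insert, a$elety)), ]
    a <- a[order(as.numeric(rownames(a))), ]
  }
  elesy <- toupper(trimws(a$elesy))
  miss <- is.na(elesy) | elesy == ""
  if (any(miss))  # infer element from the first letter(s) of the atom name
    elesy[miss] <- toupper(substr(gsub("[0-9]", "", a$elety[miss]), 1L, 1L))
  atoms <- data.frame(
    chain = a$chain, resno = a$resno, insert = a$insert, resid = a$resid,
    elety = a$elety, elesy = elesy, x = a$x, y = a$y, z = a$z,
    o = ifelse(is.na(a$o), 1, a$o), b = ifelse(is.na(a$b), 0, a$b),
    is_water = a$resid %in% WATER_RESNAMES,
    is_ion = a$resid %in% ION_RESNAMES,
    stringsAsFactors = FALSE)
  xtal_structure(atoms)
}

#' Write a structure to a PDB-format file
#'
#' @param struct An [xtal_structure()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_structure <- function(struct, path) {
  stopifnot(inherits(struct, "xtal_structure"))
  a <- struct$atoms
  bio3d::write.pdb(file = path, xyz = as.numeric(t(a[, c("x", "y", "z")])),
                   type = ifelse(a$is_water | a$is_ion, "HETATM", "ATOM"),
                   resno = a$resno, resid = a$resid, chain = a$chain,
                   insert = ifelse(a$insert == "", NA, a$insert),
                   elety = a$elety, o = a$o, b = a$b,
                   elesy = a$elesy)
  invisible(path)
}

# resolve a selection (list with optional `chain`, `resno` vectors) to an
# atom index vector
.select_atoms <- function(struct, sel, heavy_only = TRUE,
                          exclude_water = TRUE, exclude_ions = TRUE) {
  a <- struct$atoms
  idx <- rep(TRUE, nrow(a))
  if (!is.null(sel$chain)) idx <- idx & a$chain %in% sel$chain
  if (!is.null(sel$resno)) idx <- idx & a$resno %in% sel$resno
  if (heavy_only) idx <- idx & a$elesy != "H"
  if (exclude_water) idx <- idx & !a$is_water
  if (exclude_ions) idx <- idx & !a$is_ion
  which(idx)
}

.cross_dist <- function(xyz_a, xyz_b) {
  # |a - b| for all pairs; rows of the result index xyz_a
  d2 <- outer(rowSums(xyz_a^2), rowSums(xyz_b^2), "+") -
    2 * xyz_a %*% t(xyz_b)
  sqrt(pmax(d2, 0))
}

#' Count inter-selection atomic contacts
#'
#' All atom pairs with one atom in selection A, one in selection B, and
#' distance <= `cutoff`.  By default only heavy (non-hydrogen) atoms are
#' considered and waters and ions are excluded; all toggles are exposed
#' because deposited-structure contact censuses rarely state their
#' conventions.
#'
#' @param struct An [xtal_structure()].
#' @param sel_a,sel_b Selections: lists with optional `chain` and `resno`
#'   components.  Must select disjoint atom sets.
#' @param cutoff Distance cutoff in A (default 4.2).
#' @param heavy_only Drop hydrogens (default TRUE).
#' @param exclude_water,exclude_ions Drop waters/ions (default TRUE).
#' @return Object of class `contact_set`: data frame `pairs` (atom indices,
#'   chains, residues, atom names, distance), `n_contacts`, `cutoff`, and
#'   the selections used.
#' @export
count_contacts <- function(struct, sel_a, sel_b, cutoff = 4.2,
                           heavy_only = TRUE, exclude_water = TRUE,
                           exclude_ions = TRUE) {
  stopifnot(inherits(struct, "xtal_structure"))
  ia <- .select_atoms(struct, sel_a, heavy_only, exclude_water, exclude_ions)
  ib <- .select_atoms(struct, sel_b, heavy_only, exclude_water, exclude_ions)
  if (length(ia) == 0L || length(ib) == 0L)
    stop("empty atom selection", call. = FALSE)
  if (length(intersect(ia, ib)))
    stop("selections A and B must be disjoint", call. = FALSE)
  a <- struct$atoms
  d <- .cross_dist(as.matrix(a[ia, c("x", "y", "z")]),
                   as.matrix(a[ib, c("x", "y", "z")]))
  hit <- which(d <= cutoff, arr.ind = TRUE)
  pairs <- data.frame(
    atom_a = ia[hit[, 1L]], atom_b = ib[hit[, 2L]],
    chain_a = a$chain[ia[hit[, 1L]]], resno_a = a$resno[ia[hit[, 1L]]],
    elety_a = a$elety[ia[hit[, 1L]]],
    chain_b = a$chain[ib[hit[, 2L]]], resno_b = a$resno[ib[hit[, 2L]]],
    elety_b = a$elety[ib[hit[, 2L]]],
    distance = d[hit], stringsAsFactors = FALSE)
  structure(
    list(pairs = pairs, n_contacts = nrow(pairs), cutoff = cutoff,
         sel_a = sel_a, sel_b = sel_b),
    class = "contact_set"
  )
}

#' @export
print.contact_set <- function(x, ...) {
  cat(sprintf("%d inter-selection contacts at %.2f A cutoff\n",
              x$n_contacts, x$cutoff))
  invisible(x)
}

# donor and acceptor heavy atoms of the standard amino acids (N/O chemistry
# only); backbone N donates, backbone O/OXT accepts.
.HB_DONORS <- list(
  backbone = "N",
  ARG = c("NE", "NH1", "NH2"), ASN = "ND2", GLN = "NE2",
  HIS = c("ND1", "NE2"), LYS = "NZ", SER = "OG", THR = "OG1",
  TRP = "NE1", TYR = "OH", CYS = "SG")
.HB_ACCEPTORS <- list(
  backbone = c("O", "OXT"),
  ASN = "OD1", ASP = c("OD1", "OD2"), GLN = "OE1",
  GLU = c("OE1", "OE2"), HIS = c("ND1", "NE2"), MET = "SD",
  SER = "OG", THR = "OG1", TYR = "OH")

.polar_atoms <- function(atoms, idx, table) {
  sub <- atoms[idx, ]
  hit <- sub$elety %in% table$backbone
  for (res in setdiff(names(table), "backbone"))
    hit <- hit | (sub$resid == res & sub$elety %in% table[[res]])
  idx[hit]
}

#' Detect hydrogen bonds across an interface
#'
#' Direct H-bonds are donor-acceptor heavy-atom pairs (N/O/S chemistry per
#' a residue dictionary) within `d_max`.  The donor-H-acceptor angle test
#' is applied only when explicit hydrogens are present (crystal structures
#' at typical resolution lack them).  Optionally also reports
#' water-mediated bonds: a water oxygen within `d_max` of a polar atom on
#' each side.
#'
#' @param struct An [xtal_structure()].
#' @param sel_a,sel_b Selections as in [count_contacts()].
#' @param d_max Donor-acceptor distance cutoff (A, default 3.5).
#' @param angle_min Minimum D-H-A angle in degrees (default 120), used only
#'   with explicit hydrogens.
#' @param water_mediated Also search for water bridges (default FALSE).
#' @return List with `direct` (data frame of donor/acceptor pairs),
#'   `n_hbonds`, and if requested `water_mediated` (data frame of bridges)
#'   and `n_water_mediated`.
#' @export
detect_hbonds <- function(struct, sel_a, sel_b, d_max = 3.5,
                          angle_min = 120, water_mediated = FALSE) {
  stopifnot(inherits(struct, "xtal_structure"))
  a <- struct$atoms
  ia <- .select_atoms(struct, sel_a, heavy_only = TRUE)
  ib <- .select_atoms(struct, sel_b, heavy_only = TRUE)

  known <- a$is_water | a$resid %in%
    c(names(.HB_DONORS), names(.HB_ACCEPTORS), "ALA", "GLY", "ILE", "LEU",
      "PHE", "PRO", "VAL", "MET", "CYS", "ASP", "GLU", "ARG", "LYS", "SER",
      "THR", "ASN", "GLN", "HIS", "TRP", "TYR")
  unknown <- unique(a$resid[!known & !a$is_ion])
  if (length(unknown))
    warning("unknown residue(s) skipped in H-bond typing: ",
            paste(unknown, collapse = ", "))

  one_way <- function(don_side, acc_side) {
    don <- .polar_atoms(a, don_side, .HB_DONORS)
    acc <- .polar_atoms(a, acc_side, .HB_ACCEPTORS)
    if (!length(don) || !length(acc)) return(NULL)
    d <- .cross_dist(as.matrix(a[don, c("x", "y", "z")]),
                     as.matrix(a[acc, c("x", "y", "z")]))
    hit <- which(d <= d_max, arr.ind = TRUE)
    if (!nrow(hit)) return(NULL)
    data.frame(donor = don[hit[, 1L]], acceptor = acc[hit[, 2L]],
               distance = d[hit])
  }
  direct <- rbind(one_way(ia, ib), one_way(ib, ia))
  if (is.null(direct)) direct <- data.frame(donor = integer(0),
                                            acceptor = integer(0),
                                            distance = numeric(0))
  # the same N...O pair found in both directions counts once
  direct <- direct[!duplicated(t(apply(direct[, 1:2, drop = FALSE], 1L, sort))), ]

  # explicit-hydrogen angle filter
  hyd <- which(a$elesy == "H")
  if (length(hyd) && nrow(direct)) {
    keep <- vapply(seq_len(nrow(direct)), function(i) {
      dn <- direct$donor[i]; ac <- direct$acceptor[i]
      # hydrogens covalently attached to the donor (within 1.3 A)
      hd <- hyd[a$chain[hyd] == a$chain[dn] & a$resno[hyd] == a$resno[dn]]
      if (!length(hd)) return(TRUE)
      dist_dh <- sqrt((a$x[hd] - a$x[dn])^2 + (a$y[hd] - a$y[dn])^2 +
                        (a$z[hd] - a$z[dn])^2)
      hd <- hd[dist_dh < 1.3]
      if (!length(hd)) return(TRUE)
      ang <- vapply(hd, function(h) {
        v1 <- c(a$x[dn] - a$x[h], a$y[dn] - a$y[h], a$z[dn] - a$z[h])
        v2 <- c(a$x[ac] - a$x[h], a$y[ac] - a$y[h], a$z[ac] - a$z[h])
        acos(sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2))) * 180 / pi
      }, numeric(1))
      any(ang >= angle_min)
    }, logical(1))
    direct <- direct[keep, ]
  }

  out <- list(direct = direct, n_hbonds = nrow(direct))

  if (water_mediated) {
    wat <- which(a$is_water & a$elesy == "O")
    pol_a <- c(.polar_atoms(a, ia, .HB_DONORS), .polar_atoms(a, ia, .HB_ACCEPTORS))
    pol_b <- c(.polar_atoms(a, ib, .HB_DONORS), .polar_atoms(a, ib, .HB_ACCEPTORS))
    bridges <- NULL
    if (length(wat) && length(pol_a) && length(pol_b)) {
      dwa <- .cross_dist(as.matrix(a[wat, c("x", "y", "z"), drop = FALSE]),
                         as.matrix(a[pol_a, c("x", "y", "z"), drop = FALSE]))
      dwb <- .cross_dist(as.matrix(a[wat, c("x", "y", "z"), drop = FALSE]),
                         as.matrix(a[pol_b, c("x", "y", "z"), drop = FALSE]))
      for (w in seq_along(wat)) {
        na_ <- which(dwa[w, ] <= d_max)
        nb_ <- which(dwb[w, ] <= d_max)
        if (length(na_) && length(nb_))
          bridges <- rbind(bridges, data.frame(
            water = wat[w], atom_a = pol_a[na_[1L]], atom_b = pol_b[nb_[1L]],
            d_a = dwa[w, na_[1L]], d_b = dwb[w, nb_[1L]]))
      }
    }
    if (is.null(bridges)) bridges <- data.frame(water = integer(0),
                                                atom_a = integer(0),
                                                atom_b = integer(0),
                                                d_a = numeric(0),
                                                d_b = numeric(0))
    out$water_mediated <- bridges
    out$n_water_mediated <- nrow(bridges)
  }
  out
}

# deterministic unit sphere quadrature: golden-spiral point set
.sphere_points <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

# Shrake-Rupley SASA (A^2) of the atoms in `idx`, in the context of the
# same atom set (no external occluders)
.sasa <- function(atoms, idx, probe = 1.4, n_points = 960) {
  elems <- atoms$elesy[idx]
  radii <- unname(VDW_RADII[elems])
  if (anyNA(radii)) {
    bad <- unique(elems[is.na(radii)])
    stop("no van der Waals radius for element(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  radii <- radii + probe
  xyz <- as.matrix(atoms[idx, c("x", "y", "z")])
  pts <- .sphere_points(n_points)
  n <- length(idx)
  # neighbour lists limited by the largest possible overlap distance
  d <- .cross_dist(xyz, xyz)
  rmax <- max(radii)
  total <- 0
  for (i in seq_len(n)) {
    nb <- which(d[i, ] < radii[i] + rmax & seq_len(n) != i)
    nb <- nb[d[i, nb] < radii[i] + radii[nb]]
    surf <- xyz[rep(i, n_points), , drop = FALSE] + pts * radii[i]
    if (length(nb)) {
      occl <- rep(FALSE, n_points)
      for (j in nb) {
        dj2 <- (surf[, 1L] - xyz[j, 1L])^2 + (surf[, 2L] - xyz[j, 2L])^2 +
          (surf[, 3L] - xyz[j, 3L])^2
        occl <- occl | dj2 < radii[j]^2
        if (all(occl)) break
      }
      frac <- mean(!occl)
    } else frac <- 1
    total <- total + frac * 4 * pi * radii[i]^2
  }
  total
}

#' Solvent-accessible surface area of a selection
#'
#' Shrake-Rupley quadrature SASA (A^2) of the selected heavy atoms, with no
#' occlusion from atoms outside the selection.
#'
#' @param struct An [xtal_structure()].
#' @param sel Selection as in [count_contacts()]; default all non-water,
#'   non-ion heavy atoms.
#' @param probe Probe radius (A, default 1.4).
#' @param n_points Quadrature points per atom (default 960).
#' @return SASA in A^2.
#' @export
sasa <- function(struct, sel = list(), probe = 1.4, n_points = 960) {
  stopifnot(inherits(struct, "xtal_structure"))
  idx <- .select_atoms(struct, sel)
  if (!length(idx)) stop("empty atom selection", call. = FALSE)
  .sasa(struct$atoms, idx, probe, n_points)
}

#' Buried solvent-accessible surface area of an interface
#'
#' Shrake-Rupley sphere-point quadrature of the solvent-accessible surface
#' area (SASA) of each selection alone and of the complex;
#' `buried = (SASA_A + SASA_B - SASA_AB) / 2`.  Waters and ions are
#' excluded; hydrogens are excluded (united-atom convention of the Bondi
#' radii used).
#'
#' @param struct An [xtal_structure()].
#' @param sel_a,sel_b Selections as in [count_contacts()].
#' @param probe Probe radius (A, default 1.4).
#' @param n_points Quadrature points per atom (default 960).
#' @return Buried area in A^2 (single number), with attributes `sasa_a`,
#'   `sasa_b`, `sasa_ab`.
#' @export
buried_area <- function(struct, sel_a, sel_b, probe = 1.4, n_points = 960) {
  stopifnot(inherits(struct, "xtal_structure"))
  ia <- .select_atoms(struct, sel_a)
  ib <- .select_atoms(struct, sel_b)
  if (!length(ia) || !length(ib)) stop("empty atom selection", call. = FALSE)
  a <- struct$atoms
  s_a <- .sasa(a, ia, probe, n_points)
  s_b <- .sasa(a, ib, probe, n_points)
  s_ab <- .sasa(a, c(ia, ib), probe, n_points)
  out <- (s_a + s_b - s_ab) / 2
  attr(out, "sasa_a") <- s_a
  attr(out, "sasa_b") <- s_b
  attr(out, "sasa_ab") <- s_ab
  out
}

#' Fraction of interface contacts involving a residue subset
#'
#' Share of contacts in a [count_contacts()] census that have at least one
#' atom in the given residues.
#'
#' @param contacts A `contact_set`.
#' @param residues Data frame with columns `chain` and `resno` naming the
#'   subset.
#' @return Fraction in [0, 1] (0 when the census is empty).
#' @export
contact_share <- function(contacts, residues) {
  stopifnot(inherits(contacts, "contact_set"))
  p <- contacts$pairs
  if (nrow(p) == 0L) return(0)
  key <- function(chain, resno) paste(chain, resno)
  sub <- key(residues$chain, residues$resno)
  hit <- key(p$chain_a, p$resno_a) %in% sub | key(p$chain_b, p$resno_b) %in% sub
  mean(hit)
}
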