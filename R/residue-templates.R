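#' @include AllClasses.R AllGenerics.R utils-geometry.R
NULL

BACKBONE_NAMES <- c("N", "CA", "C", "O", "OXT")

## Idealised side-chain internal coordinates. Each row places one heavy
## atom D from reference atoms A-B-C (C bonded to D) with the given bond
## length (Angstrom), angle B-C-D (degrees) and dihedral A-B-C-D =
## chi[chi] + offset (chi = 0 means a fixed dihedral). Rings are built as
## open chains with planar geometry, which closes hexagons exactly and
## five-rings approximately; side chains are idealised, not minimised.
sc_row <- function(name, elesy, A, B, C, bond, angle, chi, offset) {
  data.frame(name = name, elesy = elesy, A = A, B = B, C = C,
             bond = bond, angle = angle, chi = chi, offset = offset,
             stringsAsFactors = FALSE)
}

CB_ROW <- sc_row("CB", "C", "C", "N", "CA", 1.53, 110.5, 0L, 122.6)

SC_TEMPLATES <- list(
  GLY = NULL,
  ALA = CB_ROW,
  SER = rbind(CB_ROW, sc_row("OG",  "O", "N", "CA", "CB", 1.42, 110.8, 1L, 0)),
  CYS = rbind(CB_ROW, sc_row("SG",  "S", "N", "CA", "CB", 1.81, 113.8, 1L, 0)),
  THR = rbind(CB_ROW,
              sc_row("OG1", "O", "N", "CA", "CB", 1.43, 109.6, 1L, 0),
              sc_row("CG2", "C", "N", "CA", "CB", 1.52, 110.5, 1L, -120)),
  VAL = rbind(CB_ROW,
              sc_row("CG1", "C", "N", "CA", "CB", 1.52, 110.8, 1L, 0),
              sc_row("CG2", "C", "N", "CA", "CB", 1.52, 110.8, 1L, 122)),
  ILE = rbind(CB_ROW,
              sc_row("CG1", "C", "N", "CA", "CB", 1.53, 110.4, 1L, 0),
              sc_row("CG2", "C", "N", "CA", "CB", 1.52, 110.5, 1L, -122),
              sc_row("CD1", "C", "CA", "CB", "CG1", 1.52, 113.8, 2L, 0)),
  LEU = rbind(CB_ROW,
              sc_row("CG",  "C", "N", "CA", "CB", 1.53, 116.3, 1L, 0),
              sc_row("CD1", "C", "CA", "CB", "CG", 1.52, 110.7, 2L, 0),
              sc_row("CD2", "C", "CA", "CB", "CG", 1.52, 110.7, 2L, 122)),
  MET = rbind(CB_ROW,
              sc_row("CG", "C", "N", "CA", "CB", 1.52, 114.1, 1L, 0),
              sc_row("SD", "S", "CA", "CB", "CG", 1.81, 112.7, 2L, 0),
              sc_row("CE", "C", "CB", "CG", "SD", 1.79, 100.8, 3L, 0)),
  PRO = rbind(CB_ROW,
              sc_row("CG", "C", "N", "CA", "CB", 1.50, 104.5, 0L, 30),
              sc_row("CD", "C", "CA", "CB", "CG", 1.51, 105.5, 0L, -35)),
  PHE = rbind(CB_ROW,
              sc_row("CG",  "C", "N", "CA", "CB", 1.51, 113.8, 1L, 0),
              sc_row("CD1", "C", "CA", "CB", "CG", 1.39, 120.0, 2L, 0),
              sc_row("CD2", "C", "CA", "CB", "CG", 1.39, 120.0, 2L, 180),
              sc_row("CE1", "C", "CB", "CG", "CD1", 1.39, 120.0, 0L, 180),
              sc_row("CE2", "C", "CB", "CG", "CD2", 1.39, 120.0, 0L, 180),
              sc_row("CZ",  "C", "CG", "CD1", "CE1", 1.39, 120.0, 0L, 0)),
  TYR = rbind(CB_ROW,
              sc_row("CG",  "C", "N", "CA", "CB", 1.51, 113.8, 1L, 0),
              sc_row("CD1", "C", "CA", "CB", "CG", 1.39, 120.0, 2L, 0),
              sc_row("CD2", "C", "CA", "CB", "CG", 1.39, 120.0, 2L, 180),
              sc_row("CE1", "C", "CB", "CG", "CD1", 1.39, 120.0, 0L, 180),
              sc_row("CE2", "C", "CB", "CG", "CD2", 1.39, 120.0, 0L, 180),
              sc_row("CZ",  "C", "CG", "CD1", "CE1", 1.39, 120.0, 0L, 0),
              sc_row("OH",  "O", "CD1", "CE1", "CZ", 1.38, 120.0, 0L, 180)),
  TRP = rbind(CB_ROW,
              sc_row("CG",  "C", "N", "CA", "CB", 1.50, 113.6, 1L, 0),
              sc_row("CD1", "C", "CA", "CB", "CG", 1.37, 126.9, 2L, 0),
              sc_row("CD2", "C", "CA", "CB", "CG", 1.43, 126.7, 2L, 180),
              sc_row("NE1", "N", "CB", "CG", "CD1", 1.38, 110.2, 0L, 180),
              sc_row("CE2", "C", "CB", "CG", "CD2", 1.41, 107.2, 0L, 180),
              sc_row("CE3", "C", "NE1", "CE2", "CD2", 1.40, 122.4, 0L, 180),
              sc_row("CZ2", "C", "CG", "CD2", "CE2", 1.40, 122.4, 0L, 180),
              sc_row("CZ3", "C", "CE2", "CD2", "CE3", 1.39, 118.6, 0L, 0),
              sc_row("CH2", "C", "CD2", "CE2", "CZ2", 1.37, 117.5, 0L, 0)),
  ASP = rbind(CB_ROW,
              sc_row("CG",  "C", "N", "CA", "CB", 1.52, 112.6, 1L, 0),
              sc_row("OD1", "O", "CA", "CB", "CG", 1.25, 118.4, 2L, 0),
              sc_row("OD2", "O", "CA", "CB", "CG", 1.25, 118.4, 2L, 180)),
  ASN = rbind(CB_ROW,
              sc_row("CG",  "C", "N", "CA", "CB", 1.52, 112.6, 1L, 0),
              sc_row("OD1", "O", "CA", "CB", "CG", 1.23, 120.8, 2L, 0),
              sc_row("ND2", "N", "CA", "CB", "CG", 1.33, 116.4, 2L, 180)),
  GLU = rbind(CB_ROW,
              sc_row("CG",  "C", "N", "CA", "CB", 1.52, 114.1, 1L, 0),
              sc_row("CD",  "C", "CA", "CB", "CG", 1.52, 112.6, 2L, 0),
              sc_row("OE1", "O", "CB", "CG", "CD", 1.25, 118.4, 3L, 0),
              sc_row("OE2", "O", "CB", "CG", "CD", 1.25, 118.4, 3L, 180)),
  GLN = rbind(CB_ROW,
              sc_row("CG",  "C", "N", "CA", "CB", 1.52, 114.1, 1L, 0),
              sc_row("CD",  "C", "CA", "CB", "CG", 1.52, 112.6, 2L, 0),
              sc_row("OE1", "O", "CB", "CG", "CD", 1.23, 120.8, 3L, 0),
              sc_row("NE2", "N", "CB", "CG", "CD", 1.33, 116.4, 3L, 180)),
  LYS = rbind(CB_ROW,
              sc_row("CG", "C", "N", "CA", "CB", 1.52, 114.1, 1L, 0),
              sc_row("CD", "C", "CA", "CB", "CG", 1.52, 111.3, 2L, 0),
              sc_row("CE", "C", "CB", "CG", "CD", 1.52, 111.3, 3L, 0),
              sc_row("NZ", "N", "CG", "CD", "CE", 1.49, 111.9, 4L, 0)),
  ARG = rbind(CB_ROW,
              sc_row("CG",  "C", "N", "CA", "CB", 1.52, 114.1, 1L, 0),
              sc_row("CD",  "C", "CA", "CB", "CG", 1.52, 111.3, 2L, 0),
              sc_row("NE",  "N", "CB", "CG", "CD", 1.46, 112.0, 3L, 0),
              sc_row("CZ",  "C", "CG", "CD", "NE", 1.33, 124.2, 4L, 0),
              sc_row("NH1", "N", "CD", "NE", "CZ", 1.33, 120.0, 0L, 0),
              sc_row("NH2", "N", "CD", "NE", "CZ", 1.33, 120.0, 0L, 180)),
  HIS = rbind(CB_ROW,
              sc_row("CG",  "C", "N", "CA", "CB", 1.49, 113.8, 1L, 0),
              sc_row("ND1", "N", "CA", "CB", "CG", 1.38, 122.7, 2L, 0),
              sc_row("CD2", "C", "CA", "CB", "CG", 1.36, 129.1, 2L, 180),
              sc_row("CE1", "C", "CB", "CG", "ND1", 1.32, 109.3, 0L, 180),
              sc_row("NE2", "N", "CB", "CG", "CD2", 1.37, 107.2, 0L, 180))
)

## number of sampled chi angles per residue type
n_chi <- function(resname) {
  t <- SC_TEMPLATES[[resname]]
  if (is.null(t)) 0L else max(t$chi)
}

#' Backbone-independent rotamer library
#'
#' Discrete side-chain rotamers built from canonical staggered chi values
#' (-65, 65, 180 degrees; aromatic chi2 at +/-90) with multiplicative
#' prior weights favouring trans and gauche-minus, normalised per residue
#' type. The prior enters the packing energy as `-log(weight)`.
#'
#' @return Named list; each element has a `chis` matrix (rotamers x chi
#'   slots) and a normalised `weights` vector.
#' @export
rotamerLibrary <- function() {
  lib <- list()
  for (res in AA3) {
    nc <- n_chi(res)
    if (nc == 0L) {
      lib[[res]] <- list(chis = matrix(0, 1L, 0L), weights = 1)
      next
    }
    vals <- vector("list", nc)
    wts <- vector("list", nc)
    for (k in seq_len(nc)) {
      if (k == 2L && res %in% c("PHE", "TYR", "TRP", "HIS")) {
        vals[[k]] <- c(90, -90); wts[[k]] <- c(0.5, 0.5)
      } else {
        vals[[k]] <- c(-65, 65, 180); wts[[k]] <- c(0.4, 0.2, 0.4)
      }
    }
    grid <- as.matrix(expand.grid(vals, KEEP.OUT.ATTRS = FALSE))
    w <- apply(as.matrix(expand.grid(wts, KEEP.OUT.ATTRS = FALSE)), 1L, prod)
    dimnames(grid) <- NULL
    lib[[res]] <- list(chis = grid, weights = w / sum(w))
  }
  lib
}

## build side-chain heavy atoms for one residue from its backbone N/CA/C
## positions; returns data.frame(elety, elesy, x, y, z)
build_side_chain <- function(N, CA, C, resname, chi = numeric(0)) {
  t <- SC_TEMPLATES[[resname]]
  if (is.null(resname) || !resname %in% names(SC_TEMPLATES))
    stop("no side-chain template for residue ", resname)
  if (is.null(t))
    return(data.frame(elety = character(0), elesy = character(0),
                      x = numeric(0), y = numeric(0), z = numeric(0)))
  pos <- list(N = N, CA = CA, C = C)
  xyz <- matrix(NA_real_, nrow(t), 3L)
  for (i in seq_len(nrow(t))) {
    ci <- t$chi[i]
    if (ci > length(chi))
      stop(resname, " needs chi", ci, " but only ", length(chi),
           " supplied")
    dih <- t$offset[i] + if (ci > 0L) chi[ci] else 0
    p <- place_atom(pos[[t$A[i]]], pos[[t$B[i]]], pos[[t$C[i]]],
                    t$bond[i], t$angle[i], dih)
    pos[[t$name[i]]] <- p
    xyz[i, ] <- p
  }
  data.frame(elety = t$name, elesy = t$elesy, x = xyz[, 1L],
             y = xyz[, 2L], z = xyz[, 3L], stringsAsFactors = FALSE)
}

## replace the side chain of one residue with `to` built at chi angles;
## backbone atoms (and their coordinates) are untouched bitwise
swap_side_chain <- function(structure, chain, resno, to, chi = numeric(0)) {
  a <- atomData(structure)
  in_res <- a$chain == chain & a$resno == resno
  if (!any(in_res)) stop("no residue ", chain, resno, " in structure")
  bb <- in_res & a$elety %in% BACKBONE_NAMES
  need <- c("N", "CA", "C")
  have <- a$elety[bb]
  if (!all(need %in% have))
    stop("residue ", chain, resno, " lacks backbone atoms required ",
         "for side-chain construction")
  get <- function(nm) {
    i <- which(in_res & a$elety == nm)[1L]
    c(a$x[i], a$y[i], a$z[i])
  }
  sc <- build_side_chain(get("N"), get("CA"), get("C"), to, chi)
  a$resid[in_res] <- to
  keep <- !(in_res & !a$elety %in% BACKBONE_NAMES)
  last_bb <- max(which(bb))
  newrows <- if (nrow(sc) > 0L)
    data.frame(chain = chain, resno = resno, resid = to,
               elety = sc$elety, elesy = sc$elesy,
               x = sc$x, y = sc$y, z = sc$z, b = 0,
               stringsAsFactors = FALSE)
  else NULL
  pre <- a[keep & seq_len(nrow(a)) <= last_bb, , drop = FALSE]
  post <- a[keep & seq_len(nrow(a)) > last_bb, , drop = FALSE]
  structure_(rbind(pre, newrows, post), label = structure@label)
}
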