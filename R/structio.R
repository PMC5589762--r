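#' @include AllClasses.R AllGenerics.R selectors.R
NULL

#' Construct a Structure from an atom table
#'
#' @param atoms data.frame with columns `chain`, `resno`, `resid`, `elety`,
#'   `elesy`, `x`, `y`, `z` and optionally `b` (defaults to 0).
#' @param label optional label.
#' @return A validated [Structure-class].
#' @export
structure_ <- function(atoms, label = "") {
  if (is.null(atoms$b)) atoms$b <- 0
  atoms <- atoms[, ATOM_COLS]
  rownames(atoms) <- NULL
  new("Structure", atoms = atoms, label = as.character(label))
}

#' Construct an Ensemble from a list of structures
#'
#' @param structures list of [Structure-class] objects sharing one topology.
#' @param annotations optional data.frame, one row per member.
#' @return A validated [Ensemble-class].
#' @export
ensemble <- function(structures, annotations = NULL) {
  if (is(structures, "Structure")) structures <- list(structures)
  if (is.null(annotations))
    annotations <- data.frame(row.names = seq_along(structures))
  new("Ensemble", members = structures, annotations = annotations)
}

## light sanity scan of a PDB file: returns per-model identity strings and
## flags malformed ATOM/HETATM records with their line number (the actual
## record parsing is done by bio3d)
scan_pdb_models <- function(path) {
  lines <- readLines(path, warn = FALSE)
  rec <- substr(lines, 1L, 6L)
  is_atom <- rec %in% c("ATOM  ", "HETATM")
  bad <- which(is_atom & (nchar(lines) < 54L |
    is.na(suppressWarnings(as.numeric(substr(lines, 31L, 38L)))) |
    is.na(suppressWarnings(as.numeric(substr(lines, 39L, 46L)))) |
    is.na(suppressWarnings(as.numeric(substr(lines, 47L, 54L))))))
  if (length(bad) > 0L)
    stop("malformed ATOM record at line ", bad[1L], " of ", path)
  model_starts <- which(startsWith(lines, "MODEL"))
  if (length(model_starts) == 0L) {
    ids <- list(paste(substr(lines[is_atom], 13L, 27L)))
  } else {
    model_ends <- which(startsWith(lines, "ENDMDL"))
    if (length(model_ends) != length(model_starts))
      stop("unbalanced MODEL/ENDMDL blocks in ", path)
    ids <- lapply(seq_along(model_starts), function(i) {
      idx <- seq(model_starts[i] + 1L, model_ends[i] - 1L)
      idx <- idx[is_atom[idx]]
      substr(lines[idx], 13L, 27L)
    })
  }
  ids
}

#' Read a (multi-model) PDB file into an Ensemble
#'
#' Each MODEL block becomes one ensemble member; a single-model file yields
#' a one-member ensemble. Chains, author residue numbering and element
#' symbols are preserved; when the element column is blank the element is
#' inferred from the leading character of the atom name. For alternate
#' locations the highest-occupancy conformer is kept (ties resolved to
#' altloc `A`).
#'
#' @param path path to a PDB file.
#' @param dialect input dialect; only `"pdb"` is supported.
#' @param keepHydrogens keep hydrogen atoms (default `TRUE`).
#' @return An [Ensemble-class].
#' @examples
#' f <- tempfile(fileext = ".pdb")
#' s <- makeToyComplex(toySpec(coreLength = 8, chaperoneLength = 6))
#' writeStructureModels(ensemble(list(s, s)), f)
#' e <- readStructureModels(f)
#' nMembers(e)
#' @export
readStructureModels <- function(path, dialect = c("pdb"),
                                keepHydrogens = TRUE) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("no such file: ", path)
  ids <- scan_pdb_models(path)
  n0 <- length(ids[[1L]])
  for (i in seq_along(ids)) {
    if (length(ids[[i]]) != n0 || any(ids[[i]] != ids[[1L]]))
      stop("inconsistent topology: MODEL ", i,
           " does not match MODEL 1 in ", path)
  }
  pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  a <- pdb$atom
  elesy <- a$elesy
  blank <- is.na(elesy) | !nzchar(trimws(elesy))
  elesy[blank] <- element_from_name(a$elety[blank])
  elesy <- trimws(elesy)
  chain <- a$chain
  chain[is.na(chain)] <- " "
  nmod <- nrow(pdb$xyz)
  keep <- rep(TRUE, nrow(a))
  ## altloc: highest occupancy, ties to 'A'
  if (any(!is.na(a$alt))) {
    key <- paste(chain, a$resno, a$elety)
    occ <- ifelse(is.na(a$o), 1, a$o)
    pref <- occ - ifelse(is.na(a$alt) | a$alt == "A", 0, 1e-6)
    best <- tapply(seq_len(nrow(a)), key, function(ii) ii[which.max(pref[ii])])
    keep <- seq_len(nrow(a)) %in% unlist(best)
  }
  if (!keepHydrogens) keep <- keep & !is_hydrogen(elesy)
  idx <- which(keep)
  base <- data.frame(chain = chain[idx], resno = a$resno[idx],
                     resid = a$resid[idx], elety = a$elety[idx],
                     elesy = elesy[idx], x = 0, y = 0, z = 0,
                     b = ifelse(is.na(a$b[idx]), 0, a$b[idx]),
                     stringsAsFactors = FALSE)
  xi <- 3L * (idx - 1L) + 1L
  structures <- lapply(seq_len(nmod), function(m) {
    v <- pdb$xyz[m, ]
    base$x <- v[xi]; base$y <- v[xi + 1L]; base$z <- v[xi + 2L]
    structure_(base, label = sprintf("%s#%d", basename(path), m))
  })
  ensemble(structures)
}

#' Write an Ensemble as a multi-model PDB file
#'
#' One MODEL/ENDMDL block per member. The B-factor column can be loaded
#' with arbitrary per-atom values (e.g. average interface contact counts
#' for surface heat maps).
#'
#' @param ens an [Ensemble-class] or a single [Structure-class].
#' @param path output file path.
#' @param bfactorSource optional named numeric vector keyed by
#'   `"chain|resno|atomname"`; named atoms get that B-factor, all others
#'   keep their stored value. A key matching no atom is an error.
#' @return `path`, invisibly.
#' @export
writeStructureModels <- function(ens, path, bfactorSource = NULL) {
  if (is(ens, "Structure")) ens <- ensemble(ens)
  stopifnot(is(ens, "Ensemble"))
  a <- atomData(members(ens)[[1L]])
  b <- a$b
  if (!is.null(bfactorSource)) {
    keys <- atomKeys(members(ens)[[1L]])
    hit <- match(names(bfactorSource), keys)
    if (anyNA(hit))
      stop("bfactorSource names atoms absent from the structure: ",
           paste(names(bfactorSource)[is.na(hit)][1:min(3, sum(is.na(hit)))],
                 collapse = ", "))
    b[hit] <- unname(bfactorSource)
  }
  xyz <- do.call(rbind, lapply(members(ens), function(s) {
    m <- coords(s)
    as.vector(t(m))
  }))
  bio3d::write.pdb(file = path, xyz = xyz, resno = a$resno, resid = a$resid,
                   chain = a$chain, elety = a$elety, elesy = a$elesy,
                   b = b, o = rep(1, nrow(a)))
  invisible(path)
}

#' Superpose one structure onto another
#'
#' Rigid-body least-squares fit of `mobile` onto `reference` over the
#' atoms named by `selector`; the optimal rotation/translation is applied
#' to *all* atoms of `mobile`.
#'
#' @param mobile,reference [Structure-class] objects.
#' @param selector an [AtomSelector-class]; must resolve to the same
#'   number (>= 3) of non-collinear atoms on both structures.
#' @return list with `structure` (transformed mobile) and `rmsd`
#'   (Angstrom, over the selection).
#' @examples
#' s <- makeToyComplex(toySpec(coreLength = 8, chaperoneLength = 6))
#' fit <- superpose(s, s, atomSelector(atomNames = "CA"))
#' fit$rmsd  # 0
#' @export
superpose <- function(mobile, reference, selector = atomSelector()) {
  im <- resolveSelection(mobile, selector)
  ir <- resolveSelection(reference, selector)
  if (length(im) != length(ir))
    stop("selector resolves to ", length(im), " atoms on mobile but ",
         length(ir), " on reference")
  if (length(im) < 3L) stop("superposition needs at least 3 selected atoms")
  xm <- coords(mobile)[im, , drop = FALSE]
  xr <- coords(reference)[ir, , drop = FALSE]
  for (m in list(xm, xr)) {
    sv <- svd(scale(m, scale = FALSE))$d
    if (sv[2L] < 1e-8 * max(sv[1L], 1))
      stop("degenerate (collinear) selection; cannot superpose")
  }
  fitted <- bio3d::fit.xyz(fixed = as.vector(t(xr)),
                           mobile = as.vector(t(coords(mobile))),
                           fixed.inds = seq_len(3L * length(ir)),
                           mobile.inds = bio3d::atom2xyz(im))
  out <- mobile
  coords(out) <- matrix(fitted, ncol = 3L, byrow = TRUE)
  d <- coords(out)[im, , drop = FALSE] - xr
  list(structure = out, rmsd = sqrt(mean(rowSums(d * d))))
}
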