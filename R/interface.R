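#' @include AllClasses.R AllGenerics.R selectors.R structio.R
NULL

#' Count heavy-atom contacts across an interface
#'
#' A contact is a pair of non-hydrogen atoms, one from each group, within
#' `cutoff` Angstrom (inclusive). Intra-group pairs are never counted.
#'
#' @param structure a [Structure-class].
#' @param groupA,groupB disjoint [AtomSelector-class] groups.
#' @param cutoff contact distance, Angstrom (default 6.0).
#' @return List with `perResidueA`, `perResidueB` (data.frames: chain,
#'   resno, resid, contacts) and `total` (number of qualifying pairs).
#' @export
countContacts <- function(structure, groupA, groupB, cutoff = 6.0) {
  ia <- resolveSelection(structure, groupA)
  ib <- resolveSelection(structure, groupB)
  if (length(intersect(ia, ib)) > 0L)
    stop("contact groups overlap (", length(intersect(ia, ib)),
         " shared atoms)")
  a <- atomData(structure)
  ia <- ia[!is_hydrogen(a$elesy[ia])]
  ib <- ib[!is_hydrogen(a$elesy[ib])]
  xyz <- coords(structure)
  per_res <- function(idx) {
    u <- !duplicated(paste(a$chain[idx], a$resno[idx]))
    data.frame(chain = a$chain[idx][u], resno = a$resno[idx][u],
               resid = a$resid[idx][u], contacts = rep(0, sum(u)),
               stringsAsFactors = FALSE)
  }
  resA <- per_res(ia)
  resB <- per_res(ib)
  if (length(ia) == 0L || length(ib) == 0L)
    return(list(perResidueA = resA, perResidueB = resB, total = 0L))
  D <- cross_dist(xyz[ia, , drop = FALSE], xyz[ib, , drop = FALSE])
  hit <- which(D <= cutoff, arr.ind = TRUE)
  total <- nrow(hit)
  if (total > 0L) {
    keyA <- paste(a$chain[ia], a$resno[ia])
    keyB <- paste(a$chain[ib], a$resno[ib])
    cntA <- table(keyA[hit[, 1L]])
    cntB <- table(keyB[hit[, 2L]])
    mA <- match(paste(resA$chain, resA$resno), names(cntA))
    mB <- match(paste(resB$chain, resB$resno), names(cntB))
    resA$contacts <- ifelse(is.na(mA), 0, as.numeric(cntA)[mA])
    resB$contacts <- ifelse(is.na(mB), 0, as.numeric(cntB)[mB])
  }
  list(perResidueA = resA, perResidueB = resB, total = total)
}

#' Ensemble-averaged per-residue interface contacts
#'
#' Averages [countContacts()] per-residue counts over all ensemble
#' members. Hydrogens are excluded throughout; the result does not depend
#' on member order.
#'
#' @param ens an [Ensemble-class].
#' @param groupA,groupB disjoint [AtomSelector-class] groups (A is
#'   conventionally the histone dimer, B the chaperone).
#' @param cutoff contact distance, Angstrom.
#' @return An [InterfaceProfile-class].
#' @export
averageContacts <- function(ens, groupA, groupB, cutoff = 6.0) {
  mem <- members(ens)
  first <- countContacts(mem[[1L]], groupA, groupB, cutoff)
  prof <- rbind(cbind(side = "A", first$perResidueA),
                cbind(side = "B", first$perResidueB))
  acc <- prof$contacts
  totals <- numeric(length(mem))
  totals[1L] <- first$total
  if (length(mem) > 1L) {
    for (m in seq(2L, length(mem))) {
      cc <- countContacts(mem[[m]], groupA, groupB, cutoff)
      acc <- acc + c(cc$perResidueA$contacts, cc$perResidueB$contacts)
      totals[m] <- cc$total
    }
  }
  prof$contacts <- NULL
  prof$avgContacts <- acc / length(mem)
  names(prof)[names(prof) == "side"] <- "side"
  new("InterfaceProfile", profile = prof, totalsPerMember = totals,
      cutoff = cutoff)
}

#' Shrake-Rupley solvent-accessible surface area
#'
#' Classic sphere-point SASA: each heavy atom is expanded by the probe
#' radius and sampled with a deterministic golden-spiral point set; the
#' accessible fraction of points gives the atom's SASA. Hydrogens are
#' ignored (assigned zero area).
#'
#' @param structure a [Structure-class].
#' @param radii named per-element radii, Angstrom (default C 1.7, N 1.55,
#'   O 1.52, S 1.8, P 1.8).
#' @param probe probe radius, Angstrom (default 1.4, water).
#' @param points number of sphere sample points (default 960).
#' @return A [SasaResult-class].
#' @examples
#' ## one carbon: SASA ~ 4*pi*(1.7+1.4)^2
#' s <- structure_(data.frame(chain = "A", resno = 1, resid = "UNK",
#'                            elety = "C", elesy = "C",
#'                            x = 0, y = 0, z = 0))
#' sum(computeSasa(s)@perAtom)
#' @export
computeSasa <- function(structure, radii = ELEMENT_RADII, probe = 1.4,
                        points = 960L) {
  a <- atomData(structure)
  heavy <- which(!is_hydrogen(a$elesy))
  el <- toupper(a$elesy[heavy])
  miss <- setdiff(unique(el), names(radii))
  if (length(miss) > 0L)
    stop("no radius for element(s): ", paste(miss, collapse = ", "))
  rad <- unname(radii[el]) + probe
  xyz <- coords(structure)[heavy, , drop = FALSE]
  sphere <- golden_spiral_points(points)
  n <- length(heavy)
  area <- numeric(nrow(a))
  for (k in seq_len(n)) {
    d2 <- row_dist2(xyz, xyz[k, ])
    nb <- which(d2 < (rad + rad[k])^2 & seq_len(n) != k)
    pts <- sweep(sphere * rad[k], 2L, xyz[k, ], "+")
    acc <- rep(TRUE, points)
    for (j in nb) {
      if (!any(acc)) break
      acc[acc] <- row_dist2(pts[acc, , drop = FALSE], xyz[j, ]) > rad[j]^2
    }
    area[heavy[k]] <- 4 * pi * rad[k]^2 * sum(acc) / points
  }
  per_chain <- tapply(area, a$chain, sum)
  new("SasaResult", perAtom = area,
      perChain = stats::setNames(as.numeric(per_chain), names(per_chain)),
      probe = probe, points = as.integer(points))
}

#' Buried solvent-accessible surface area of a two-group complex
#'
#' `SASA(A alone) + SASA(B alone) - SASA(complex)`, where A and B are
#' disjoint chain sets covering the whole structure. Symmetric in A and B.
#'
#' @param structure a [Structure-class].
#' @param chainsA,chainsB character vectors partitioning the chains.
#' @param radii,probe,points SASA parameters, see [computeSasa()].
#' @return Buried area in square Angstrom.
#' @export
buriedSasa <- function(structure, chainsA, chainsB,
                       radii = ELEMENT_RADII, probe = 1.4, points = 960L) {
  ch <- chainIds(structure)
  if (length(intersect(chainsA, chainsB)) > 0L)
    stop("chain partitions overlap")
  if (!setequal(c(chainsA, chainsB), ch))
    stop("partition must cover exactly the chains: ",
         paste(ch, collapse = ", "))
  a <- atomData(structure)
  sub <- function(chains)
    structure_(a[a$chain %in% chains, , drop = FALSE])
  sA <- sum(computeSasa(sub(chainsA), radii, probe, points)@perAtom)
  sB <- sum(computeSasa(sub(chainsB), radii, probe, points)@perAtom)
  sAB <- sum(computeSasa(structure, radii, probe, points)@perAtom)
  sA + sB - sAB
}

#' Ensemble buried surface area, mean and spread
#'
#' Per-member [buriedSasa()] aggregated as mean and standard deviation
#' (the spread statistic is the SD across members, labelled explicitly).
#'
#' @param ens an [Ensemble-class].
#' @inheritParams buriedSasa
#' @return Named numeric: `mean`, `sd`, `n`.
#' @export
ensembleBuriedSasa <- function(ens, chainsA, chainsB,
                               radii = ELEMENT_RADII, probe = 1.4,
                               points = 960L) {
  v <- vapply(members(ens), buriedSasa, numeric(1), chainsA = chainsA,
              chainsB = chainsB, radii = radii, probe = probe,
              points = points)
  c(mean = mean(v), sd = if (length(v) > 1L) stats::sd(v) else 0,
    n = length(v))
}

#' Export an interface-contact heat map
#'
#' Writes a PDB whose B-factor column carries each residue's average
#' interface contact count (0 for residues outside the profile), plus a
#' TSV table (chain, resno, resid, avg_contacts).
#'
#' @param structure a [Structure-class] (e.g. a centroid).
#' @param profile an [InterfaceProfile-class].
#' @param path output PDB path; the TSV is written alongside with
#'   extension `.tsv`.
#' @return Named character vector of the two paths, invisibly.
#' @export
exportHeatmap <- function(structure, profile, path) {
  a <- atomData(structure)
  p <- profile@profile
  key <- paste(a$chain, a$resno)
  hit <- match(key, paste(p$chain, p$resno))
  b <- ifelse(is.na(hit), 0, p$avgContacts[hit])
  s <- structure
  s@atoms$b <- b
  writeStructureModels(ensemble(s), path)
  tsv <- sub("\\.pdb$", ".tsv", path)
  if (tsv == path) tsv <- paste0(path, ".tsv")
  utils::write.table(
    data.frame(chain = p$chain, resno = p$resno, resid = p$resid,
               avg_contacts = p$avgContacts),
    tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(pdb = path, tsv = tsv))
}
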