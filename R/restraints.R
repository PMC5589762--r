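#' @include AllClasses.R AllGenerics.R selectors.R structio.R
NULL

empty_restraints <- function() {
  data.frame(chain_a = character(0), resno_a = integer(0),
             atom_a = character(0), chain_b = character(0),
             resno_b = integer(0), atom_b = character(0),
             upper = numeric(0), remapped_a = logical(0),
             remapped_b = logical(0), padded = logical(0),
             interface = logical(0), stringsAsFactors = FALSE)
}

restraint_set <- function(df, provenance = "") {
  base <- empty_restraints()
  for (col in c("remapped_a", "remapped_b", "padded"))
    if (is.null(df[[col]])) df[[col]] <- FALSE
  df <- df[, names(base)]
  rownames(df) <- NULL
  new("RestraintSet", restraints = df, provenance = provenance)
}

## map restraint endpoints to atom indices on a topology; NA-free or error
resolveRestraints <- function(set, topology) {
  r <- restraints(set)
  keys <- atomKeys(topology)
  ia <- match(paste(r$chain_a, r$resno_a, r$atom_a, sep = "|"), keys)
  ib <- match(paste(r$chain_b, r$resno_b, r$atom_b, sep = "|"), keys)
  bad <- which(is.na(ia) | is.na(ib))
  if (length(bad) > 0L) {
    i <- bad[1L]
    miss <- if (is.na(ia[i]))
      paste(r$chain_a[i], r$resno_a[i], r$atom_a[i]) else
      paste(r$chain_b[i], r$resno_b[i], r$atom_b[i])
    stop("restraint ", i, " names an atom absent from the topology: ", miss)
  }
  cbind(ia, ib)
}

#' Parse a plain-text NOE distance-restraint table
#'
#' The dialect is one restraint per line, whitespace-separated:
#' `chain resno atomname chain resno atomname upper_bound`, with `#`
#' comments. Atoms must resolve on the supplied topology. The `interface`
#' flag is set for restraints joining the chaperone chain to any other
#' chain.
#'
#' @param path path to the restraint table.
#' @param topology a [Structure-class] the atom names resolve against.
#' @param chaperoneChain chain id of the chaperone (default `"C"`).
#' @return A [RestraintSet-class] in file order.
#' @export
parseRestraints <- function(path, topology, chaperoneChain = "C") {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  keep <- which(nzchar(trimws(lines)))
  rows <- lapply(keep, function(i) {
    tok <- strsplit(trimws(lines[i]), "[[:space:]]+")[[1L]]
    if (length(tok) != 7L)
      stop("line ", i, ": expected 7 fields, got ", length(tok))
    up <- suppressWarnings(as.numeric(tok[7L]))
    if (is.na(up) || up <= 0)
      stop("line ", i, ": bad upper bound ", sQuote(tok[7L]))
    data.frame(chain_a = tok[1L], resno_a = as.integer(tok[2L]),
               atom_a = tok[3L], chain_b = tok[4L],
               resno_b = as.integer(tok[5L]), atom_b = tok[6L],
               upper = up, stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  if (is.null(df)) df <- empty_restraints()
  df$interface <- (df$chain_a == chaperoneChain) != (df$chain_b == chaperoneChain)
  set <- restraint_set(df, provenance = basename(path))
  resolveRestraints(set, topology)  # errors if anything is unresolvable
  set
}

#' Import X-PLOR style `assign` NOE statements
#'
#' Secondary reader for restraint lists in the X-PLOR/CNS dialect
#' `assign (segid A and resid 70 and name HD1)(segid C and resid 9 and
#' name HA) d dminus dplus`; the upper bound is taken as `d + dplus`.
#'
#' @inheritParams parseRestraints
#' @return A [RestraintSet-class].
#' @export
parseXplorRestraints <- function(path, topology, chaperoneChain = "C") {
  if (!file.exists(path)) stop("no such file: ", path)
  txt <- paste(readLines(path, warn = FALSE), collapse = " ")
  stmts <- regmatches(txt, gregexpr(
    "assign[[:space:]]*\\([^)]*\\)[[:space:]]*\\([^)]*\\)[[:space:]]*[0-9.]+[[:space:]]+[0-9.]+[[:space:]]+[0-9.]+",
    txt, ignore.case = TRUE))[[1L]]
  if (length(stmts) == 0L) stop("no assign statements found in ", path)
  parse_sel <- function(s) {
    seg <- regmatches(s, regexpr("(segid|chain)[[:space:]]+[A-Za-z0-9]+", s,
                                 ignore.case = TRUE))
    res <- regmatches(s, regexpr("resid[[:space:]]+[0-9]+", s,
                                 ignore.case = TRUE))
    nam <- regmatches(s, regexpr("name[[:space:]]+[A-Za-z0-9'#*]+", s,
                                 ignore.case = TRUE))
    if (!length(seg) || !length(res) || !length(nam))
      stop("cannot parse selection: ", s)
    c(chain = sub(".*[[:space:]]", "", seg),
      resno = sub(".*[[:space:]]", "", res),
      atom = sub(".*[[:space:]]", "", nam))
  }
  rows <- lapply(stmts, function(st) {
    sels <- regmatches(st, gregexpr("\\([^)]*\\)", st))[[1L]]
    nums <- as.numeric(strsplit(trimws(sub(".*\\)", "", st)),
                                "[[:space:]]+")[[1L]])
    a <- parse_sel(sels[1L]); b <- parse_sel(sels[2L])
    data.frame(chain_a = a[["chain"]], resno_a = as.integer(a[["resno"]]),
               atom_a = a[["atom"]], chain_b = b[["chain"]],
               resno_b = as.integer(b[["resno"]]), atom_b = b[["atom"]],
               upper = nums[1L] + nums[3L], stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  df$interface <- (df$chain_a == chaperoneChain) != (df$chain_b == chaperoneChain)
  set <- restraint_set(df, provenance = basename(path))
  resolveRestraints(set, topology)
  set
}

## find the heavy-atom parent of a hydrogen within its residue; returns a
## row index into `res_atoms` or NA
hydrogen_parent <- function(hname, res_atoms) {
  rem <- sub("^[0-9]*H", "", hname)  # strip leading digit + H (e.g. 1HB)
  if (rem == hname) return(NA_integer_)
  if (rem == "" || rem == "N") {     # backbone amide H / HN
    i <- which(res_atoms$elety == "N")
    return(if (length(i)) i[1L] else NA_integer_)
  }
  cand <- rem
  while (nchar(cand) > 0L) {
    for (el in c("C", "N", "O", "S")) {
      i <- which(res_atoms$elety == paste0(el, cand))
      if (length(i)) return(i[1L])
    }
    cand <- substr(cand, 1L, nchar(cand) - 1L)
  }
  NA_integer_
}

#' Remap aliphatic-proton restraint endpoints to their bonded carbons
#'
#' For force fields without explicit carbon-bound hydrogens, every
#' restraint endpoint naming a hydrogen bonded to a carbon is replaced by
#' that carbon, and the upper bound grows by 1 Angstrom per remapped
#' endpoint to absorb the extra bond length. Hydrogens bonded to N, O or S
#' (polar hydrogens) are left untouched. Methyl/methylene protons that
#' collapse onto the same carbon can make restraints coincide; duplicated
#' atom pairs are merged into a single restraint carrying the loosest
#' bound.
#'
#' @param set a [RestraintSet-class] whose endpoints resolve on `topology`
#'   (hydrogens may be named even if absent from the topology, as long as
#'   their residue is present).
#' @param topology a [Structure-class] providing residue compositions.
#' @return A [RestraintSet-class] with remap flags set.
#' @examples
#' ## a 4.0-A methyl-proton restraint becomes a 5.0-A carbon restraint
#' @export
remapAliphatic <- function(set, topology) {
  r <- restraints(set)
  if (nrow(r) == 0L) return(set)
  a <- atomData(topology)
  remap_end <- function(chain, resno, atom) {
    res_atoms <- a[a$chain == chain & a$resno == resno, , drop = FALSE]
    if (nrow(res_atoms) == 0L)
      stop("restraint names residue ", chain, resno,
           " absent from the topology")
    if (!grepl("^[0-9]*H", atom))
      return(list(atom = atom, remapped = FALSE))
    ip <- hydrogen_parent(atom, res_atoms)
    if (is.na(ip))
      stop("no parent heavy atom found for hydrogen ", atom,
           " in residue ", chain, resno)
    parent <- res_atoms[ip, ]
    if (toupper(parent$elesy) == "C")
      list(atom = parent$elety, remapped = TRUE)
    else
      list(atom = atom, remapped = FALSE)  # polar hydrogen: untouched
  }
  for (i in seq_len(nrow(r))) {
    ea <- remap_end(r$chain_a[i], r$resno_a[i], r$atom_a[i])
    eb <- remap_end(r$chain_b[i], r$resno_b[i], r$atom_b[i])
    r$atom_a[i] <- ea$atom; r$remapped_a[i] <- ea$remapped
    r$atom_b[i] <- eb$atom; r$remapped_b[i] <- eb$remapped
    r$upper[i] <- r$upper[i] + 1.0 * (ea$remapped + eb$remapped)
  }
  ## collapse duplicates born from methyl/methylene ambiguity: loosest bound
  ka <- paste(r$chain_a, r$resno_a, r$atom_a, sep = "|")
  kb <- paste(r$chain_b, r$resno_b, r$atom_b, sep = "|")
  key <- ifelse(ka < kb, paste(ka, kb), paste(kb, ka))
  if (anyDuplicated(key)) {
    keep <- !duplicated(key)
    upper_max <- tapply(r$upper, key, max)
    padded_any <- tapply(r$padded, key, any)
    r <- r[keep, , drop = FALSE]
    kkey <- key[keep]
    r$upper <- as.numeric(upper_max[kkey])
    r$padded <- as.logical(padded_any[kkey])
  }
  restraint_set(r, provenance = set@provenance)
}

#' Pad all restraint upper bounds
#'
#' Adds a uniform margin (default 1 Angstrom, absorbing the standard
#' deviation of the NOE signal) to every upper bound. Padding is additive:
#' padding by `a` then `b` equals padding once by `a + b`.
#'
#' @param set a [RestraintSet-class].
#' @param pad margin in Angstrom, >= 0.
#' @return A [RestraintSet-class] with the `padded` flag set (when
#'   `pad > 0`).
#' @export
padRestraints <- function(set, pad = 1.0) {
  stopifnot(pad >= 0)
  r <- restraints(set)
  r$upper <- r$upper + pad
  if (pad > 0) r$padded <- TRUE
  restraint_set(r, provenance = set@provenance)
}

## observed distances for every restraint in one structure
restraint_distances <- function(structure, set, idx = NULL) {
  if (is.null(idx)) idx <- resolveRestraints(set, structure)
  xyz <- coords(structure)
  d <- xyz[idx[, 1L], , drop = FALSE] - xyz[idx[, 2L], , drop = FALSE]
  sqrt(rowSums(d * d))
}

#' Per-restraint violations of one structure
#'
#' The violation of a restraint is `max(0, r_observed - upper_bound)`:
#' only distances above the experimental upper bound count.
#'
#' @param structure a [Structure-class].
#' @param set a [RestraintSet-class].
#' @return Numeric vector of violations (Angstrom), one per restraint.
#' @export
structureViolation <- function(structure, set) {
  r <- restraint_distances(structure, set)
  pmax(0, r - restraints(set)$upper)
}

#' r^-6 average of a distance sample
#'
#' The NOE signal scales as `r^-6`, so the effective distance of an
#' ensemble is `(mean(r^-6))^(-1/6)`. Lies between `min(r)` and `max(r)`
#' and never exceeds the arithmetic mean (power-mean inequality).
#'
#' @param r positive numeric vector of distances (Angstrom).
#' @return The r^-6-averaged effective distance.
#' @examples
#' r6AverageDistance(c(4, 8))  # 4.478...
#' @export
r6AverageDistance <- function(r) {
  if (any(r <= 0)) stop("distances must be positive for r^-6 averaging")
  mean(r^(-6))^(-1 / 6)
}

#' Ensemble-averaged effective distances of restraints
#'
#' For each restraint, computes the per-member distances across the
#' ensemble and collapses them with [r6AverageDistance()].
#'
#' @param ens an [Ensemble-class].
#' @param set a [RestraintSet-class].
#' @return Numeric vector of effective distances, one per restraint.
#' @export
ensembleEffectiveDistance <- function(ens, set) {
  idx <- resolveRestraints(set, members(ens)[[1L]])
  D <- vapply(members(ens), restraint_distances, numeric(nrow(idx)),
              set = set, idx = idx)
  D <- matrix(D, nrow = nrow(idx))
  if (any(D <= 0))
    stop("coincident restraint atoms (r = 0) in at least one member")
  apply(D, 1L, r6AverageDistance)
}

#' Mean ensemble violation under r^-6 averaging
#'
#' Mean over the selected restraints of
#' `max(0, effective_distance - upper_bound)`, where the effective
#' distance is the r^-6 ensemble average.
#'
#' @param ens an [Ensemble-class].
#' @param set a [RestraintSet-class].
#' @param subset `"all"` or `"interface"` (restraints spanning the
#'   chaperone and a histone chain).
#' @return Mean violation in Angstrom.
#' @export
meanEnsembleViolation <- function(ens, set, subset = c("all", "interface")) {
  subset <- match.arg(subset)
  r <- restraints(set)
  keep <- if (subset == "interface") which(r$interface) else seq_len(nrow(r))
  if (length(keep) == 0L)
    stop("no restraints selected by subset ", sQuote(subset))
  eff <- ensembleEffectiveDistance(ens, set)
  mean(pmax(0, eff[keep] - r$upper[keep]))
}

#' Construct a two-well restraint potential
#'
#' @param lowerEdge inner well edge, Angstrom (default 1.8, hard-contact
#'   distance).
#' @param innerStep penalty for `r < lowerEdge` (default equals
#'   `outerStep`).
#' @param outerStep step height at the upper bound; beyond the bound the
#'   penalty is `outerStep * (1 + (r - upper))`, a step plus linear ramp.
#' @return A [TwoWellPotential-class].
#' @export
twoWellPotential <- function(lowerEdge = 1.8, outerStep = 1,
                             innerStep = outerStep) {
  new("TwoWellPotential", lowerEdge = lowerEdge, innerStep = innerStep,
      outerStep = outerStep)
}

#' Two-well restraint energy of a structure
#'
#' Sums, over all restraints, zero inside the well
#' (`lowerEdge <= r <= upper`), `innerStep` below the well, and
#' `outerStep * (1 + (r - upper))` above it. The linear outer ramp gives
#' Monte Carlo moves a restoring signal while keeping the stepped two-well
#' topology.
#'
#' @param structure a [Structure-class].
#' @param set a [RestraintSet-class].
#' @param potential a [TwoWellPotential-class].
#' @return Scalar energy.
#' @export
restraintEnergy <- function(structure, set, potential = twoWellPotential()) {
  r <- restraint_distances(structure, set)
  upper <- restraints(set)$upper
  e <- numeric(length(r))
  e[r < potential@lowerEdge] <- potential@innerStep
  over <- r > upper
  e[over] <- potential@outerStep * (1 + (r[over] - upper[over]))
  sum(e)
}

#' Build a harmonic tether from a reference structure
#'
#' @param reference a [Structure-class] providing reference coordinates.
#' @param selector an [AtomSelector-class] naming the tethered atoms
#'   (e.g. histone backbone).
#' @param k spring constant, kcal/mol/atom at 1 Angstrom displacement
#'   (default 0.4).
#' @return A [HarmonicTether-class].
#' @export
harmonicTether <- function(reference, selector, k = 0.4) {
  idx <- resolveSelection(reference, selector)
  if (length(idx) == 0L) stop("tether selector resolves to no atoms")
  ref <- coords(reference)[idx, , drop = FALSE]
  rownames(ref) <- atomKeys(reference)[idx]
  new("HarmonicTether", selector = selector, ref = ref, k = k)
}

#' Harmonic tether energy of a structure
#'
#' `sum over tethered atoms of k * |x - x_ref|^2`; `k` is read as the
#' energy of one atom displaced by 1 Angstrom.
#'
#' @param structure a [Structure-class].
#' @param tether a [HarmonicTether-class].
#' @return Scalar energy.
#' @export
tetherEnergy <- function(structure, tether) {
  idx <- resolveSelection(structure, tether@selector)
  keys <- atomKeys(structure)[idx]
  hit <- match(keys, rownames(tether@ref))
  if (anyNA(hit))
    stop("tether selection includes atoms without reference coordinates")
  d <- coords(structure)[idx, , drop = FALSE] -
    tether@ref[hit, , drop = FALSE]
  tether@k * sum(d * d)
}
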