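#' @import methods
NULL

ATOM_COLS <- c("chain", "resno", "resid", "elety", "elesy",
               "x", "y", "z", "b")

#' Structure: one atomic conformation
#'
#' A `Structure` holds the ordered atom records of a single conformation:
#' chain identifier, residue number and name, atom name, element symbol,
#' Cartesian coordinates in Angstrom, and a B-factor slot used for
#' annotation export. Atom order is file order and is preserved by all
#' operations.
#'
#' @slot atoms data.frame with columns `chain`, `resno`, `resid`, `elety`
#'   (atom name), `elesy` (element symbol), `x`, `y`, `z`, `b`.
#' @slot label character scalar naming the conformation.
#' @export
setClass("Structure",
  representation(atoms = "data.frame", label = "character"),
  prototype(label = "")
)

setValidity("Structure", function(object) {
  a <- object@atoms
  if (!all(ATOM_COLS %in% names(a)))
    return(paste("atoms must have columns:", paste(ATOM_COLS, collapse = ", ")))
  if (nrow(a) < 1L) return("Structure must contain at least one atom")
  if (any(!nzchar(a$elesy) | is.na(a$elesy)))
    return("every atom needs a non-empty element symbol")
  if (any(!is.finite(a$x) | !is.finite(a$y) | !is.finite(a$z)))
    return("all coordinates must be finite")
  if (any(!nzchar(a$chain) | is.na(a$chain)))
    return("all chain identifiers must be non-empty")
  key <- paste(a$chain, a$resno, a$elety)
  if (anyDuplicated(key))
    return("(chain, resno, atom name) must be unique within a Structure")
  TRUE
})

#' Ensemble: an ordered collection of conformations with shared topology
#'
#' All members share the same atoms in the same order; per-member scalar
#' annotations (energies, violations, replica ids, ...) live in a
#' data.frame with one row per member.
#'
#' @slot members list of [Structure-class] objects with identical topology.
#' @slot annotations data.frame with `length(members)` rows (possibly zero
#'   columns).
#' @export
setClass("Ensemble",
  representation(members = "list", annotations = "data.frame")
)

setValidity("Ensemble", function(object) {
  if (length(object@members) < 1L) return("Ensemble must have at least one member")
  if (!all(vapply(object@members, is, logical(1), "Structure")))
    return("all members must be Structure objects")
  key0 <- atomKeys(object@members[[1L]])
  for (i in seq_along(object@members)) {
    ki <- atomKeys(object@members[[i]])
    if (length(ki) != length(key0) || any(ki != key0))
      return(sprintf("member %d does not share the topology of member 1", i))
  }
  if (nrow(object@annotations) != 0L &&
      nrow(object@annotations) != length(object@members))
    return("annotations must have one row per member")
  TRUE
})

#' AtomSelector: a declarative, order-preserving atom subset
#'
#' Resolves to a deterministic ordered subset of the atoms of a
#' [Structure-class] (file order). Empty filter slots mean "no constraint".
#'
#' @slot chains character vector of chain ids (empty = any chain).
#' @slot resnoMin,resnoMax numeric residue-number range (inclusive).
#' @slot atomNames character vector of atom names (empty = any atom).
#' @slot heavyOnly logical; if `TRUE` keep only non-hydrogen atoms.
#' @export
setClass("AtomSelector",
  representation(chains = "character", resnoMin = "numeric",
                 resnoMax = "numeric", atomNames = "character",
                 heavyOnly = "logical"),
  prototype(chains = character(0), resnoMin = -Inf, resnoMax = Inf,
            atomNames = character(0), heavyOnly = FALSE)
)

#' RestraintSet: ordered NOE distance upper bounds
#'
#' Each restraint names two atoms by (chain, residue number, atom name) and
#' an upper distance bound in Angstrom. Provenance flags record whether an
#' endpoint was remapped from an aliphatic proton to its bonded carbon and
#' whether the bound has been padded. The `interface` flag marks restraints
#' spanning the chaperone chain and a histone chain.
#'
#' @slot restraints data.frame with columns `chain_a`, `resno_a`, `atom_a`,
#'   `chain_b`, `resno_b`, `atom_b`, `upper`, `remapped_a`, `remapped_b`,
#'   `padded`, `interface`.
#' @slot provenance character scalar describing the origin of the list.
#' @export
setClass("RestraintSet",
  representation(restraints = "data.frame", provenance = "character"),
  prototype(provenance = "")
)

RESTRAINT_COLS <- c("chain_a", "resno_a", "atom_a",
                    "chain_b", "resno_b", "atom_b",
                    "upper", "remapped_a", "remapped_b", "padded", "interface")

setValidity("RestraintSet", function(object) {
  r <- object@restraints
  if (!all(RESTRAINT_COLS %in% names(r)))
    return(paste("restraints must have columns:",
                 paste(RESTRAINT_COLS, collapse = ", ")))
  if (nrow(r) > 0L) {
    if (any(r$upper <= 0)) return("all upper bounds must be positive")
    same <- r$chain_a == r$chain_b & r$resno_a == r$resno_b &
      r$atom_a == r$atom_b
    if (any(same)) return("a restraint cannot join an atom to itself")
  }
  TRUE
})

#' TwoWellPotential: stepwise NOE restraint potential
#'
#' Distance potential with a flat favourable well between `lowerEdge` and
#' the restraint's upper bound, a step of height `innerStep` below
#' `lowerEdge`, and a step plus linear ramp (slope `outerStep` per
#' Angstrom) above the upper bound, so Monte Carlo moves feel a restoring
#' signal towards the allowed well.
#'
#' @slot lowerEdge numeric, Angstrom; default 1.8 (van der Waals contact).
#' @slot innerStep,outerStep numeric, energy units; both >= 0.
#' @export
setClass("TwoWellPotential",
  representation(lowerEdge = "numeric", innerStep = "numeric",
                 outerStep = "numeric"),
  prototype(lowerEdge = 1.8, innerStep = 1, outerStep = 1)
)

setValidity("TwoWellPotential", function(object) {
  if (object@lowerEdge <= 0) return("lowerEdge must be positive")
  if (object@innerStep < 0 || object@outerStep < 0)
    return("potential steps must be non-negative")
  TRUE
})

#' HarmonicTether: harmonic positional restraint to reference coordinates
#'
#' Tethers a selection of atoms to reference coordinates with energy
#' `k * |x - x_ref|^2` per atom, i.e. `k` is the energy of a 1 Angstrom
#' displacement. Default spring constant 0.4 kcal/mol/atom.
#'
#' @slot selector an [AtomSelector-class] resolving the tethered atoms.
#' @slot ref numeric matrix (n x 3) of reference coordinates, rownames are
#'   `chain|resno|atomname` keys.
#' @slot k numeric spring constant, kcal/mol/atom at 1 Angstrom.
#' @export
setClass("HarmonicTether",
  representation(selector = "AtomSelector", ref = "matrix", k = "numeric"),
  prototype(k = 0.4)
)

setValidity("HarmonicTether", function(object) {
  if (object@k < 0) return("spring constant must be non-negative")
  if (ncol(object@ref) != 3L) return("ref must be an n x 3 matrix")
  if (is.null(rownames(object@ref))) return("ref must have atom-key rownames")
  TRUE
})

#' SamplerConfig: replica-exchange Monte Carlo run parameters
#'
#' The default temperature ladder is the 16-value reduced-unit ladder
#' 0.480 ... 0.767 commonly used for all-atom replica-exchange runs of
#' this system (roughly 240-383 K). Move weights mix torsion pivots and
#' crankshaft rotations on the flexible chaperone chain with single-atom
#' jiggles on any atom.
#'
#' @slot temperatures strictly increasing numeric ladder (reduced units).
#' @slot stepsPerReplica integer number of MC steps per replica.
#' @slot snapshotInterval,swapInterval integers >= 1.
#' @slot moveWeights named numeric (`pivot`, `crankshaft`, `jiggle`),
#'   summing to 1.
#' @slot maxDisplacement numeric, Angstrom, for jiggle moves.
#' @slot maxRotation numeric, degrees, for pivot/crankshaft moves.
#' @slot moveChain character chain id receiving torsion moves.
#' @slot seed integer RNG seed; each replica gets stream `seed + replica`.
#' @slot traceEvery integer; if > 0, record the full coordinate vector of
#'   the coldest replica every `traceEvery` steps (small systems only).
#' @slot metadata list of free-form annotations (e.g. nominal time step,
#'   aggregate sampling of the physical protocol being emulated).
#' @export
setClass("SamplerConfig",
  representation(temperatures = "numeric", stepsPerReplica = "integer",
                 snapshotInterval = "integer", swapInterval = "integer",
                 moveWeights = "numeric", maxDisplacement = "numeric",
                 maxRotation = "numeric", moveChain = "character",
                 seed = "integer", traceEvery = "integer",
                 metadata = "list")
)

setValidity("SamplerConfig", function(object) {
  tt <- object@temperatures
  if (length(tt) < 1L || any(diff(tt) <= 0))
    return("temperatures must be strictly increasing")
  if (any(tt <= 0)) return("temperatures must be positive")
  if (object@stepsPerReplica < 1L) return("stepsPerReplica must be >= 1")
  if (object@snapshotInterval < 1L || object@swapInterval < 1L)
    return("intervals must be >= 1")
  w <- object@moveWeights
  if (!all(c("pivot", "crankshaft", "jiggle") %in% names(w)))
    return("moveWeights needs pivot, crankshaft and jiggle entries")
  if (any(w < 0) || abs(sum(w) - 1) > 1e-9)
    return("moveWeights must be non-negative and sum to 1")
  TRUE
})

#' SamplingRun: output of a replica-exchange run
#'
#' @slot ensemble an [Ensemble-class] of snapshots with per-snapshot
#'   annotations (replica, temperature, step, energy decomposition).
#' @slot swapLog data.frame (step, replica_i, replica_j, accepted).
#' @slot trace numeric matrix of flattened coldest-replica coordinates
#'   (zero rows when tracing is off).
#' @slot config the [SamplerConfig-class] used.
#' @export
setClass("SamplingRun",
  representation(ensemble = "Ensemble", swapLog = "data.frame",
                 trace = "matrix", config = "SamplerConfig")
)

#' FilterSpec: ensemble refinement criteria
#'
#' Members are kept if they survive, in order, every energy-percentile
#' criterion (lowest `energyPercentileKeep` percent by each named
#' annotation) and then the per-structure mean-violation ceiling.
#'
#' @slot energyKeys character vector of annotation names filtered on.
#' @slot energyPercentileKeep numeric in (0, 100].
#' @slot violationMax numeric, Angstrom; ceiling on per-structure mean
#'   restraint violation (`Inf` disables).
#' @export
setClass("FilterSpec",
  representation(energyKeys = "character", energyPercentileKeep = "numeric",
                 violationMax = "numeric"),
  prototype(energyKeys = character(0), energyPercentileKeep = 50,
            violationMax = 0.5)
)

setValidity("FilterSpec", function(object) {
  if (object@energyPercentileKeep <= 0 || object@energyPercentileKeep > 100)
    return("energyPercentileKeep must be in (0, 100]")
  if (object@violationMax < 0) return("violationMax must be >= 0")
  TRUE
})

#' CentroidReport: k-medoids clustering of an ensemble
#'
#' @slot centroids integer member indices of the k medoids.
#' @slot clusters integer cluster assignment per member (values in 1..k).
#' @slot objective numeric summed within-cluster RMSD to medoids.
#' @slot rmsdSummary numeric summary (min/median/max) of the pairwise
#'   RMSD matrix used.
#' @export
setClass("CentroidReport",
  representation(centroids = "integer", clusters = "integer",
                 objective = "numeric", rmsdSummary = "numeric")
)

#' InterfaceProfile: ensemble-averaged per-residue interface contacts
#'
#' @slot profile data.frame (side, chain, resno, resid, avgContacts).
#' @slot totalsPerMember numeric vector of total cross-group contact pairs
#'   per ensemble member.
#' @slot cutoff numeric contact cutoff in Angstrom.
#' @export
setClass("InterfaceProfile",
  representation(profile = "data.frame", totalsPerMember = "numeric",
                 cutoff = "numeric")
)

#' SasaResult: Shrake-Rupley solvent-accessible surface area
#'
#' @slot perAtom numeric per-atom SASA in square Angstrom (hydrogens get 0).
#' @slot perChain named numeric per-chain totals.
#' @slot probe numeric probe radius, Angstrom.
#' @slot points integer number of sphere sample points.
#' @export
setClass("SasaResult",
  representation(perAtom = "numeric", perChain = "numeric",
                 probe = "numeric", points = "integer")
)

#' Mutation: one point substitution
#'
#' The screen never mutates to proline, cysteine or the native residue.
#'
#' @slot chain character chain id.
#' @slot resno integer residue number.
#' @slot from,to 3-letter residue codes.
#' @export
setClass("Mutation",
  representation(chain = "character", resno = "integer",
                 from = "character", to = "character")
)

setValidity("Mutation", function(object) {
  if (!object@from %in% AA3) return(paste("unknown residue:", object@from))
  if (!object@to %in% AA3) return(paste("unknown residue:", object@to))
  if (object@to %in% c("PRO", "CYS"))
    return("mutations to proline or cysteine are excluded")
  if (object@to == object@from)
    return("mutation must change the residue type")
  TRUE
})

#' DdgRecord: binding stability change of one mutation
#'
#' Per-run free energies of the four repacking arms (mutant/wild-type in
#' the full complex and in the histone dimer alone) plus the aggregate
#' mean and standard error. Positive ddG = destabilizing.
#'
#' @slot mutation a [Mutation-class].
#' @slot runs data.frame (centroid, run, dG_complex_mut, dG_dimer_mut,
#'   dG_complex_wt, dG_dimer_wt, ddg).
#' @slot ddgMean,ddgSem numeric aggregate over all runs x centroids
#'   (surrogate energy units).
#' @slot nRuns integer total number of runs pooled.
#' @export
setClass("DdgRecord",
  representation(mutation = "Mutation", runs = "data.frame",
                 ddgMean = "numeric", ddgSem = "numeric", nRuns = "integer")
)

setValidity("DdgRecord", function(object) {
  if (object@nRuns < 1L) return("nRuns must be >= 1")
  if (object@ddgSem < 0) return("ddgSem must be >= 0")
  TRUE
})
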