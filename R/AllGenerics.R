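#' @include AllClasses.R
NULL

#' Accessors for structures, ensembles and restraint sets
#'
#' `atomData()` returns the atom table of a [Structure-class];
#' `coords()` returns (and `coords<-` replaces) its n x 3 coordinate
#' matrix; `nAtoms()` and `chainIds()` summarise it. `members()`,
#' `nMembers()` and `annotations()` access the parts of an
#' [Ensemble-class]; `restraints()` returns the restraint table of a
#' [RestraintSet-class].
#'
#' @param x a `Structure`, `Ensemble` or `RestraintSet`.
#' @param value replacement value.
#' @return The accessed component (see details above).
#' @name accessors
#' @aliases atomData coords coords<- nAtoms chainIds members nMembers
#'   annotations annotations<- restraints
#' @examples
#' s <- makeToyComplex(toySpec(coreLength = 8, chaperoneLength = 6))
#' nAtoms(s)
#' chainIds(s)
#' head(atomData(s))
NULL

#' @rdname accessors
#' @export
setGeneric("atomData", function(x) standardGeneric("atomData"))
#' @rdname accessors
#' @export
setGeneric("coords", function(x) standardGeneric("coords"))
#' @rdname accessors
#' @export
setGeneric("coords<-", function(x, value) standardGeneric("coords<-"))
#' @rdname accessors
#' @export
setGeneric("nAtoms", function(x) standardGeneric("nAtoms"))
#' @rdname accessors
#' @export
setGeneric("chainIds", function(x) standardGeneric("chainIds"))
#' @rdname accessors
#' @export
setGeneric("members", function(x) standardGeneric("members"))
#' @rdname accessors
#' @export
setGeneric("nMembers", function(x) standardGeneric("nMembers"))
#' @rdname accessors
#' @export
setGeneric("annotations", function(x) standardGeneric("annotations"))
#' @rdname accessors
#' @export
setGeneric("annotations<-", function(x, value) standardGeneric("annotations<-"))
#' @rdname accessors
#' @export
setGeneric("restraints", function(x) standardGeneric("restraints"))

#' @rdname accessors
setMethod("atomData", "Structure", function(x) x@atoms)

#' @rdname accessors
setMethod("coords", "Structure", function(x) {
  m <- as.matrix(x@atoms[, c("x", "y", "z")])
  dimnames(m) <- NULL
  m
})

#' @rdname accessors
setMethod("coords<-", "Structure", function(x, value) {
  stopifnot(is.matrix(value), ncol(value) == 3L,
            nrow(value) == nrow(x@atoms))
  x@atoms$x <- value[, 1L]
  x@atoms$y <- value[, 2L]
  x@atoms$z <- value[, 3L]
  x
})

#' @rdname accessors
setMethod("nAtoms", "Structure", function(x) nrow(x@atoms))

#' @rdname accessors
setMethod("chainIds", "Structure", function(x) unique(x@atoms$chain))

#' @rdname accessors
setMethod("members", "Ensemble", function(x) x@members)

#' @rdname accessors
setMethod("nMembers", "Ensemble", function(x) length(x@members))

#' @rdname accessors
setMethod("annotations", "Ensemble", function(x) x@annotations)

#' @rdname accessors
setMethod("annotations<-", "Ensemble", function(x, value) {
  stopifnot(is.data.frame(value),
            nrow(value) == length(x@members) || nrow(value) == 0L)
  x@annotations <- value
  x
})

#' @rdname accessors
setMethod("restraints", "RestraintSet", function(x) x@restraints)

## internal: unique atom identity keys, file order
atomKeys <- function(structure) {
  a <- if (is(structure, "Structure")) structure@atoms else structure
  paste(a$chain, a$resno, a$elety, sep = "|")
}

setMethod("show", "Structure", function(object) {
  a <- object@atoms
  cat("Structure ",
      if (nzchar(object@label)) paste0("'", object@label, "'") else "",
      "\n  ", nrow(a), " atoms, ", length(unique(a$chain)), " chain(s): ",
      paste(unique(a$chain), collapse = ", "), "\n", sep = "")
  for (ch in unique(a$chain)) {
    r <- range(a$resno[a$chain == ch])
    cat("    chain ", ch, ": residues ", r[1L], "-", r[2L], "\n", sep = "")
  }
})

setMethod("show", "Ensemble", function(object) {
  cat("Ensemble of ", length(object@members), " member(s), ",
      nrow(object@members[[1L]]@atoms), " atoms each\n", sep = "")
  if (ncol(object@annotations) > 0L)
    cat("  annotations: ", paste(names(object@annotations), collapse = ", "),
        "\n", sep = "")
})

setMethod("show", "RestraintSet", function(object) {
  r <- object@restraints
  cat("RestraintSet with ", nrow(r), " restraint(s)",
      if (nzchar(object@provenance)) paste0(" [", object@provenance, "]"),
      "\n", sep = "")
  if (nrow(r) > 0L)
    cat("  interface: ", sum(r$interface), ", padded: ", sum(r$padded),
        ", remapped endpoints: ", sum(r$remapped_a) + sum(r$remapped_b),
        "\n  upper bounds: ", sprintf("%.2f-%.2f", min(r$upper), max(r$upper)),
        " Angstrom\n", sep = "")
})

setMethod("show", "InterfaceProfile", function(object) {
  cat("InterfaceProfile over ", length(object@totalsPerMember),
      " member(s), cutoff ", object@cutoff, " Angstrom\n",
      "  residues: ", nrow(object@profile),
      ", mean total contacts: ",
      sprintf("%.1f", mean(object@totalsPerMember)), "\n", sep = "")
})

setMethod("show", "DdgRecord", function(object) {
  m <- object@mutation
  cat(sprintf("%s%d %s->%s  ddG = %.3f +/- %.3f (n = %d)\n",
              m@chain, m@resno, m@from, m@to,
              object@ddgMean, object@ddgSem, object@nRuns))
})

setMethod("show", "SamplingRun", function(object) {
  cat("SamplingRun: ", nMembers(object@ensemble), " snapshots, ",
      length(object@config@temperatures), " replicas, ",
      object@config@stepsPerReplica, " steps/replica\n",
      "  swap acceptance: ",
      if (nrow(object@swapLog)) sprintf("%.2f", mean(object@swapLog$accepted))
      else "NA", "\n", sep = "")
})
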