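#' @include AllClasses.R AllGenerics.R structio.R restraints.R
NULL

#' Build an ensemble refinement specification
#'
#' @param energyKeys annotation names filtered on, in order (e.g.
#'   `c("energy")`; any named per-member annotation can stand in for an
#'   externally computed potential).
#' @param energyPercentileKeep keep the lowest this-percent members by
#'   each energy criterion, applied sequentially.
#' @param violationMax ceiling on per-structure mean restraint violation,
#'   Angstrom (`Inf` disables). Default 0.5.
#' @return A [FilterSpec-class].
#' @export
filterSpec <- function(energyKeys = "energy", energyPercentileKeep = 50,
                       violationMax = 0.5) {
  new("FilterSpec", energyKeys = as.character(energyKeys),
      energyPercentileKeep = energyPercentileKeep,
      violationMax = violationMax)
}

#' Per-structure mean restraint violation of every ensemble member
#'
#' The plain (per-snapshot) average of per-restraint violations; this is
#' the per-member filtering statistic, distinct from the r^-6
#' ensemble-averaged violation used to report a final ensemble.
#'
#' @param ens an [Ensemble-class].
#' @param set a [RestraintSet-class].
#' @return Numeric vector, one mean violation per member.
#' @export
perMemberMeanViolation <- function(ens, set) {
  vapply(members(ens), function(s) mean(structureViolation(s, set)),
         numeric(1))
}

#' Filter an ensemble by energy percentiles and restraint violation
#'
#' Members are removed, sequentially, by each energy criterion (keep the
#' lowest `energyPercentileKeep` percent by that annotation) and then by
#' the per-structure mean-violation ceiling. Original member order is
#' preserved.
#'
#' @param ens an [Ensemble-class] carrying the annotations named in
#'   `spec@energyKeys`.
#' @param set a [RestraintSet-class] (used when `violationMax` is finite).
#' @param spec a [FilterSpec-class].
#' @return List with `ensemble` (refined), `kept` (original indices) and
#'   `report` (data.frame of members removed per criterion).
#' @export
filterEnsemble <- function(ens, set = NULL, spec = filterSpec()) {
  n <- nMembers(ens)
  ann <- annotations(ens)
  alive <- rep(TRUE, n)
  report <- list()
  for (key in spec@energyKeys) {
    if (!key %in% names(ann))
      stop("ensemble lacks required annotation ", sQuote(key))
    e <- ann[[key]]
    cut <- stats::quantile(e[alive], spec@energyPercentileKeep / 100,
                           names = FALSE, type = 7)
    drop <- alive & e > cut
    report[[length(report) + 1L]] <-
      data.frame(criterion = paste0("energy:", key), removed = sum(drop))
    alive <- alive & !drop
  }
  if (is.finite(spec@violationMax)) {
    if (is.null(set)) stop("violation filtering needs a restraint set")
    v <- perMemberMeanViolation(ens, set)
    drop <- alive & v > spec@violationMax
    report[[length(report) + 1L]] <-
      data.frame(criterion = "violation", removed = sum(drop))
    alive <- alive & !drop
  }
  if (!any(alive)) {
    rep_df <- do.call(rbind, report)
    stop("all members removed by filtering (",
         paste(sprintf("%s: %d", rep_df$criterion, rep_df$removed),
               collapse = ", "), ")")
  }
  kept <- which(alive)
  refined <- ensemble(members(ens)[kept],
                      annotations = ann[kept, , drop = FALSE])
  list(ensemble = refined, kept = kept,
       report = do.call(rbind, report))
}

#' Pairwise superposed-RMSD matrix of an ensemble
#'
#' Entry (i, j) is the RMSD of member i on member j after least-squares
#' superposition over `selector`. Symmetric with a zero diagonal.
#'
#' @param ens an [Ensemble-class] with >= 2 members.
#' @param selector an [AtomSelector-class].
#' @return Symmetric numeric matrix (Angstrom).
#' @export
pairwiseRmsdMatrix <- function(ens, selector = atomSelector()) {
  n <- nMembers(ens)
  if (n < 2L) stop("need at least 2 members")
  if (length(resolveSelection(members(ens)[[1L]], selector)) == 0L)
    stop("selector resolves to no atoms")
  m <- matrix(0, n, n)
  mem <- members(ens)
  for (i in seq_len(n - 1L)) {
    for (j in seq(i + 1L, n)) {
      r <- superpose(mem[[i]], mem[[j]], selector)$rmsd
      m[i, j] <- r
      m[j, i] <- r
    }
  }
  m
}

#' Extract centroid structures by k-medoids
#'
#' Partitioning-around-medoids (build + swap) on a pairwise RMSD matrix;
#' each centroid is the member minimising the summed RMSD within its
#' cluster. Deterministic for a given matrix (the PAM build phase needs no
#' random initialisation; the seed argument is kept for interface
#' stability).
#'
#' @param rmsdMatrix symmetric dissimilarity matrix from
#'   [pairwiseRmsdMatrix()].
#' @param k number of centroids (default 6).
#' @param seed unused by PAM; retained for call-site compatibility.
#' @return A [CentroidReport-class].
#' @export
extractCentroids <- function(rmsdMatrix, k = 6L, seed = 1L) {
  n <- nrow(rmsdMatrix)
  if (k > n) stop("k (", k, ") exceeds the number of members (", n, ")")
  if (k == n) {
    return(new("CentroidReport", centroids = seq_len(n),
               clusters = seq_len(n), objective = 0,
               rmsdSummary = stats::quantile(rmsdMatrix[upper.tri(rmsdMatrix)],
                                             c(0, 0.5, 1), names = FALSE)))
  }
  fit <- cluster::pam(stats::as.dist(rmsdMatrix), k = k, diss = TRUE)
  medoids <- as.integer(fit$id.med)
  clusters <- as.integer(fit$clustering)
  obj <- sum(rmsdMatrix[cbind(seq_len(n), medoids[clusters])])
  ut <- rmsdMatrix[upper.tri(rmsdMatrix)]
  new("CentroidReport", centroids = medoids, clusters = clusters,
      objective = obj,
      rmsdSummary = if (length(ut)) stats::quantile(ut, c(0, 0.5, 1),
                                                    names = FALSE)
      else c(0, 0, 0))
}
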