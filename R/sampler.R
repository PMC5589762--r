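#' @include AllClasses.R AllGenerics.R restraints.R
NULL

## 16-replica reduced-unit temperature ladder (roughly 240-383 K)
DEFAULT_T_LADDER <- c(0.480, 0.495, 0.512, 0.528, 0.546, 0.563, 0.581,
                      0.600, 0.619, 0.638, 0.658, 0.679, 0.700, 0.722,
                      0.744, 0.767)

#' Build a replica-exchange sampler configuration
#'
#' @param temperatures strictly increasing reduced-unit ladder; default is
#'   the 16-value ladder 0.480 ... 0.767.
#' @param stepsPerReplica MC steps per replica.
#' @param snapshotInterval record a snapshot from every replica each this
#'   many steps.
#' @param swapInterval attempt nearest-neighbour exchanges each this many
#'   steps, alternating even/odd pairs.
#' @param moveWeights named weights for `pivot`, `crankshaft` and `jiggle`
#'   moves; must sum to 1.
#' @param maxDisplacement jiggle half-width, Angstrom.
#' @param maxRotation pivot/crankshaft half-width, degrees.
#' @param moveChain chain id of the flexible (chaperone) chain; all moves
#'   act on this chain, the remaining chains are held rigid under their
#'   tether.
#' @param seed integer; replica `i` draws from an RNG stream seeded
#'   `seed + i`, so changing the replica count does not reshuffle streams.
#' @param traceEvery if > 0, record the flattened coordinates of the
#'   coldest replica every `traceEvery` steps (intended for very small
#'   systems, e.g. single-particle checks).
#' @param metadata free-form list; the nominal physical protocol being
#'   emulated (50 fs time unit, ~8 us aggregate sampling) can be recorded
#'   here but is not used by the sampler.
#' @return A [SamplerConfig-class].
#' @export
samplerConfig <- function(temperatures = DEFAULT_T_LADDER,
                          stepsPerReplica = 2000L,
                          snapshotInterval = 100L,
                          swapInterval = 20L,
                          moveWeights = c(pivot = 0.4, crankshaft = 0.2,
                                          jiggle = 0.4),
                          maxDisplacement = 0.3,
                          maxRotation = 20,
                          moveChain = "C",
                          seed = 1L,
                          traceEvery = 0L,
                          metadata = list(time_unit_fs = 50)) {
  new("SamplerConfig", temperatures = as.numeric(temperatures),
      stepsPerReplica = as.integer(stepsPerReplica),
      snapshotInterval = as.integer(snapshotInterval),
      swapInterval = as.integer(swapInterval),
      moveWeights = moveWeights,
      maxDisplacement = as.numeric(maxDisplacement),
      maxRotation = as.numeric(maxRotation),
      moveChain = as.character(moveChain), seed = as.integer(seed),
      traceEvery = as.integer(traceEvery), metadata = metadata)
}

## soft-sphere pair context: heavy-atom pairs not excluded (exclusions:
## same residue, or sequence-adjacent residues on the same chain)
ev_pairs <- function(a, radii = ELEMENT_RADII) {
  heavy <- which(!is_hydrogen(a$elesy))
  el <- toupper(a$elesy[heavy])
  miss <- setdiff(unique(el), names(radii))
  if (length(miss) > 0L)
    stop("no excluded-volume radius for element(s): ",
         paste(miss, collapse = ", "))
  rad <- unname(radii[el])
  np <- length(heavy)
  if (np < 2L)
    return(list(i = integer(0), j = integer(0), sigma = numeric(0),
                heavy = heavy))
  cmb <- t(combn(np, 2L))
  i <- cmb[, 1L]; j <- cmb[, 2L]
  same_chain <- a$chain[heavy[i]] == a$chain[heavy[j]]
  near_seq <- same_chain & abs(a$resno[heavy[i]] - a$resno[heavy[j]]) <= 1L
  keep <- !near_seq
  list(i = heavy[i[keep]], j = heavy[j[keep]],
       sigma = rad[i[keep]] + rad[j[keep]], heavy = heavy)
}

ev_energy_from_coords <- function(xyz, pairs) {
  if (length(pairs$i) == 0L) return(0)
  d <- sqrt(row_dist2_pairs(xyz, pairs$i, pairs$j))
  over <- d < pairs$sigma
  if (!any(over)) return(0)
  sum((pairs$sigma[over] - d[over])^2)
}

row_dist2_pairs <- function(xyz, i, j) {
  (xyz[i, 1L] - xyz[j, 1L])^2 + (xyz[i, 2L] - xyz[j, 2L])^2 +
    (xyz[i, 3L] - xyz[j, 3L])^2
}

#' Total surrogate energy decomposition of a structure
#'
#' Sum of the two-well restraint energy, the harmonic tether energy and a
#' soft-sphere excluded-volume term `sum((sigma_ij - r)^2)` over
#' non-bonded heavy-atom pairs closer than `sigma_ij` (the sum of the two
#' element radii; pairs within one residue or between sequence-adjacent
#' residues are excluded). This stands in for a full molecular-mechanics
#' force field: it scores restraint satisfaction and steric feasibility,
#' not detailed energetics.
#'
#' @param structure a [Structure-class].
#' @param set optional [RestraintSet-class].
#' @param potential a [TwoWellPotential-class].
#' @param tethers list of [HarmonicTether-class] objects (or a single one).
#' @param radii named element radii, Angstrom.
#' @return Named numeric: `restraint`, `tether`, `excluded`, `total`.
#' @export
totalEnergy <- function(structure, set = NULL,
                        potential = twoWellPotential(),
                        tethers = list(), radii = ELEMENT_RADII) {
  if (is(tethers, "HarmonicTether")) tethers <- list(tethers)
  er <- if (!is.null(set) && nrow(restraints(set)) > 0L)
    restraintEnergy(structure, set, potential) else 0
  et <- if (length(tethers))
    sum(vapply(tethers, tetherEnergy, numeric(1), structure = structure))
  else 0
  pairs <- ev_pairs(atomData(structure), radii)
  ev <- ev_energy_from_coords(coords(structure), pairs)
  c(restraint = er, tether = et, excluded = ev, total = er + et + ev)
}

#' Metropolis acceptance
#'
#' Accepts with probability `min(1, exp(-deltaE / temperature))`.
#'
#' @param deltaE proposed energy change.
#' @param temperature reduced-unit temperature, > 0.
#' @param u optional uniform(0,1) draw; defaults to `runif(1)`.
#' @return Logical.
#' @export
metropolisAccept <- function(deltaE, temperature, u = stats::runif(1)) {
  stopifnot(temperature > 0)
  deltaE <= 0 || u < exp(-deltaE / temperature)
}

#' Replica-exchange swap acceptance probability
#'
#' For configurations with energies `eI`, `eJ` at temperatures `tI < tJ`,
#' the exchange is accepted with probability
#' `min(1, exp((1/tI - 1/tJ) * (eI - eJ)))`, which preserves detailed
#' balance of the product ensemble.
#'
#' @param eI,eJ energies of the two replicas.
#' @param tI,tJ their temperatures.
#' @return Probability in `[0, 1]`.
#' @export
swapAcceptProb <- function(eI, eJ, tI, tJ) {
  min(1, exp((1 / tI - 1 / tJ) * (eI - eJ)))
}

#' Attempt a replica exchange
#'
#' @inheritParams swapAcceptProb
#' @param u optional uniform(0,1) draw.
#' @return Logical: whether the exchange is accepted.
#' @export
attemptSwap <- function(eI, eJ, tI, tJ, u = stats::runif(1)) {
  u < swapAcceptProb(eI, eJ, tI, tJ)
}

## indices moved by a phi/psi pivot at residue `r` of the move chain
pivot_move_set <- function(a, chainId, r, which = c("phi", "psi")) {
  which <- match.arg(which)
  on_chain <- a$chain == chainId
  if (which == "phi")
    which(on_chain & (a$resno > r | (a$resno == r & a$elety != "N")))
  else
    which(on_chain & (a$resno > r | (a$resno == r & a$elety == "O")))
}

#' Run replica-exchange Metropolis Monte Carlo sampling
#'
#' Samples conformations of the flexible chaperone chain under the
#' two-well restraint potential, harmonic tethers and a soft-sphere
#' excluded-volume term. Moves are torsion pivots about phi/psi axes of
#' the chaperone chain (bond geometry preserving), local crankshaft
#' rotations between two chaperone CA atoms, and single-atom jiggles; all
#' other chains are held rigid. Nearest-neighbour exchanges alternate
#' even/odd pairs every `swapInterval` steps. The run is bit-reproducible
#' for a fixed seed and configuration.
#'
#' @param initial a [Structure-class] starting conformation.
#' @param set optional [RestraintSet-class].
#' @param tethers list of [HarmonicTether-class] objects.
#' @param config a [SamplerConfig-class].
#' @param potential a [TwoWellPotential-class].
#' @param radii named element radii for excluded volume.
#' @return A [SamplingRun-class]: snapshot ensemble (annotated with
#'   replica, temperature, step and energy decomposition), swap log, and
#'   optional coordinate trace of the coldest replica.
#' @export
runSampling <- function(initial, set = NULL, tethers = list(),
                        config = samplerConfig(),
                        potential = twoWellPotential(),
                        radii = ELEMENT_RADII) {
  stopifnot(is(initial, "Structure"))
  validObject(config)
  if (all(config@moveWeights == 0)) stop("all move weights are zero")
  if (is(tethers, "HarmonicTether")) tethers <- list(tethers)
  a <- atomData(initial)
  nrep <- length(config@temperatures)
  temps <- config@temperatures

  movable <- which(a$chain == config@moveChain)
  if (length(movable) == 0L)
    stop("move chain ", sQuote(config@moveChain), " has no atoms")
  mov_res <- sort(unique(a$resno[movable]))

  ## restraint context
  has_restraints <- !is.null(set) && nrow(restraints(set)) > 0L
  if (has_restraints) {
    ridx <- resolveRestraints(set, initial)
    rupper <- restraints(set)$upper
  }
  ## tether context: split into constant (rigid chains) and movable parts
  tether_ctx <- lapply(tethers, function(th) {
    idx <- resolveSelection(initial, th@selector)
    keys <- atomKeys(initial)[idx]
    hit <- match(keys, rownames(th@ref))
    if (anyNA(hit))
      stop("tether selection includes atoms without reference coordinates")
    mv <- idx %in% movable
    list(idx = idx[mv], ref = th@ref[hit[mv], , drop = FALSE], k = th@k)
  })
  ## excluded-volume pairs: only pairs touching a movable atom vary
  pairs_all <- ev_pairs(a, radii)
  varies <- pairs_all$i %in% movable | pairs_all$j %in% movable
  pairs_var <- list(i = pairs_all$i[varies], j = pairs_all$j[varies],
                    sigma = pairs_all$sigma[varies])
  pairs_const <- list(i = pairs_all$i[!varies], j = pairs_all$j[!varies],
                      sigma = pairs_all$sigma[!varies])
  xyz0 <- coords(initial)
  e_const_ev <- ev_energy_from_coords(xyz0, pairs_const)
  e_const_tether <- sum(vapply(tethers, tetherEnergy, numeric(1),
                               structure = initial)) -
    sum(vapply(tether_ctx, function(tc) {
      d <- xyz0[tc$idx, , drop = FALSE] - tc$ref
      tc$k * sum(d * d)
    }, numeric(1)))

  low <- potential@lowerEdge
  inner <- potential@innerStep
  outer <- potential@outerStep

  e_var <- function(xyz) {
    er <- 0
    if (has_restraints) {
      d <- sqrt(row_dist2_pairs(xyz, ridx[, 1L], ridx[, 2L]))
      er <- sum(inner * (d < low)) +
        sum(outer * (1 + (d - rupper))[d > rupper])
    }
    et <- 0
    for (tc in tether_ctx) {
      dd <- xyz[tc$idx, , drop = FALSE] - tc$ref
      et <- et + tc$k * sum(dd * dd)
    }
    ev <- ev_energy_from_coords(xyz, pairs_var)
    c(restraint = er, tether = et, excluded = ev)
  }

  ## per-replica state
  reps <- vector("list", nrep)
  rng <- vector("list", nrep)
  e0 <- e_var(xyz0)
  for (i in seq_len(nrep)) {
    reps[[i]] <- list(xyz = xyz0, e = e0)
    set.seed(config@seed + i)
    rng[[i]] <- .GlobalEnv$.Random.seed
  }
  set.seed(config@seed)
  rng_swap <- .GlobalEnv$.Random.seed

  wts <- cumsum(config@moveWeights[c("pivot", "crankshaft", "jiggle")])
  max_disp <- config@maxDisplacement
  max_rot <- config@maxRotation * pi / 180
  snap_int <- config@snapshotInterval
  n_snap_per_rep <- config@stepsPerReplica %/% snap_int
  snaps <- vector("list", n_snap_per_rep * nrep)
  snap_meta <- vector("list", n_snap_per_rep * nrep)
  snap_n <- 0L
  do_trace <- config@traceEvery > 0L
  if (do_trace) {
    ntr <- config@stepsPerReplica %/% config@traceEvery
    trace <- matrix(NA_real_, ntr, 3L * nrow(xyz0))
    tr_n <- 0L
  } else trace <- matrix(numeric(0), 0L, 0L)

  propose <- function(xyz) {
    u <- stats::runif(1)
    if (u < wts[1L] && length(mov_res) >= 1L) {
      r <- mov_res[sample.int(length(mov_res), 1L)]
      kind <- if (stats::runif(1) < 0.5) "phi" else "psi"
      idx <- pivot_move_set(a, config@moveChain, r, kind)
      ax_from <- if (kind == "phi") "N" else "CA"
      ax_to <- if (kind == "phi") "CA" else "C"
      i1 <- which(a$chain == config@moveChain & a$resno == r &
                    a$elety == ax_from)
      i2 <- which(a$chain == config@moveChain & a$resno == r &
                    a$elety == ax_to)
      if (length(i1) != 1L || length(i2) != 1L || length(idx) == 0L)
        return(NULL)
      axis <- xyz[i2, ] - xyz[i1, ]
      if (vnorm(axis) < 1e-9) return(NULL)
      th <- stats::runif(1, -max_rot, max_rot)
      new_xyz <- xyz
      new_xyz[idx, ] <- rotate_about_axis(xyz[idx, , drop = FALSE],
                                          xyz[i1, ], axis, th)
      new_xyz
    } else if (u < wts[2L] && length(mov_res) >= 3L) {
      gap <- sample(2:3, 1L)
      pick <- mov_res[mov_res + gap <= max(mov_res)]
      if (length(pick) == 0L) return(NULL)
      r1 <- pick[sample.int(length(pick), 1L)]
      r2 <- r1 + gap
      i1 <- which(a$chain == config@moveChain & a$resno == r1 &
                    a$elety == "CA")
      i2 <- which(a$chain == config@moveChain & a$resno == r2 &
                    a$elety == "CA")
      if (length(i1) != 1L || length(i2) != 1L) return(NULL)
      idx <- which(a$chain == config@moveChain &
                     ((a$resno > r1 & a$resno < r2) |
                        (a$resno == r1 & a$elety %in% c("C", "O")) |
                        (a$resno == r2 & a$elety == "N")))
      if (length(idx) == 0L) return(NULL)
      axis <- xyz[i2, ] - xyz[i1, ]
      if (vnorm(axis) < 1e-9) return(NULL)
      th <- stats::runif(1, -max_rot, max_rot)
      new_xyz <- xyz
      new_xyz[idx, ] <- rotate_about_axis(xyz[idx, , drop = FALSE],
                                          xyz[i1, ], axis, th)
      new_xyz
    } else {
      i <- movable[sample.int(length(movable), 1L)]
      new_xyz <- xyz
      new_xyz[i, ] <- xyz[i, ] + stats::runif(3L, -max_disp, max_disp)
      new_xyz
    }
  }

  swap_log <- list()
  n_seg <- ceiling(config@stepsPerReplica / config@swapInterval)
  step_done <- 0L
  for (seg in seq_len(n_seg)) {
    seg_steps <- min(config@swapInterval, config@stepsPerReplica - step_done)
    for (ri in seq_len(nrep)) {
      .GlobalEnv$.Random.seed <- rng[[ri]]
      st <- reps[[ri]]
      Tcur <- temps[ri]
      for (s in seq_len(seg_steps)) {
        new_xyz <- propose(st$xyz)
        if (!is.null(new_xyz)) {
          e_new <- e_var(new_xyz)
          if (metropolisAccept(sum(e_new) - sum(st$e), Tcur)) {
            st$xyz <- new_xyz
            st$e <- e_new
          }
        }
        gstep <- step_done + s
        if (gstep %% snap_int == 0L) {
          snap_n <- snap_n + 1L
          snaps[[snap_n]] <- st$xyz
          snap_meta[[snap_n]] <- c(replica = ri, temperature = Tcur,
                                   step = gstep,
                                   restraint = unname(st$e["restraint"]),
                                   tether = unname(st$e["tether"]) +
                                     e_const_tether,
                                   excluded = unname(st$e["excluded"]) +
                                     e_const_ev)
        }
        if (do_trace && ri == 1L && gstep %% config@traceEvery == 0L) {
          tr_n <- tr_n + 1L
          trace[tr_n, ] <- as.vector(t(st$xyz))
        }
      }
      reps[[ri]] <- st
      rng[[ri]] <- .GlobalEnv$.Random.seed
    }
    step_done <- step_done + seg_steps
    ## alternating even/odd nearest-neighbour exchanges
    .GlobalEnv$.Random.seed <- rng_swap
    first <- if (seg %% 2L == 1L) 1L else 2L
    ii <- if (first <= nrep - 1L) seq(first, nrep - 1L, by = 2L)
    else integer(0)
    for (i in ii) {
      ei <- sum(reps[[i]]$e)
      ej <- sum(reps[[i + 1L]]$e)
      acc <- attemptSwap(ei, ej, temps[i], temps[i + 1L])
      if (acc) {
        tmp <- reps[[i]]
        reps[[i]] <- reps[[i + 1L]]
        reps[[i + 1L]] <- tmp
      }
      swap_log[[length(swap_log) + 1L]] <-
        data.frame(step = step_done, replica_i = i, replica_j = i + 1L,
                   accepted = acc)
    }
    rng_swap <- .GlobalEnv$.Random.seed
  }

  meta <- do.call(rbind, snap_meta[seq_len(snap_n)])
  structures <- lapply(seq_len(snap_n), function(k) {
    s <- initial
    coords(s) <- snaps[[k]]
    s@label <- sprintf("snapshot %d", k)
    s
  })
  ann <- as.data.frame(meta)
  ann$energy <- ann$restraint + ann$tether + ann$excluded
  ens <- ensemble(structures, annotations = ann)
  sl <- if (length(swap_log)) do.call(rbind, swap_log) else
    data.frame(step = integer(0), replica_i = integer(0),
               replica_j = integer(0), accepted = logical(0))
  new("SamplingRun", ensemble = ens, swapLog = sl,
      trace = if (do_trace) trace[seq_len(tr_n), , drop = FALSE] else trace,
      config = config)
}
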