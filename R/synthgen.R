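#' @include AllClasses.R AllGenerics.R residue-templates.R restraints.R interface.R
NULL

#' Specification for a toy chaperone-histone complex
#'
#' The toy emulates the geometry of an extended chaperone peptide wrapped
#' around a compact two-chain core: chains A and B are coiled compact
#' chains side by side, chain C is an extended strand following a circular
#' arc around them at a controlled clearance, covering `wrapFraction` of
#' the core circumference (default two thirds, the lasso-like arrangement
#' seen for this class of chaperone).
#'
#' @param coreLength residues per core chain (>= 3).
#' @param chaperoneLength residues of the wrapped chain; `NULL` derives
#'   the longest chain that fits the requested wrap at ~3.8 Angstrom
#'   residue spacing.
#' @param wrapFraction fraction of the core circumference covered,
#'   in (0, 1].
#' @param contactSpacing radial clearance between the chaperone backbone
#'   and the outermost core heavy atom, Angstrom.
#' @param seed integer; a small seeded coordinate jitter (0.02 Angstrom)
#'   makes distinct seeds distinguishable while preserving the geometry.
#' @return List of class parameters used by [makeToyComplex()].
#' @export
toySpec <- function(coreLength = 16L, chaperoneLength = NULL,
                    wrapFraction = 2 / 3, contactSpacing = 4.2,
                    seed = 1L) {
  stopifnot(coreLength >= 3L, wrapFraction > 0, wrapFraction <= 1,
            contactSpacing > 0)
  if (!is.null(chaperoneLength)) stopifnot(chaperoneLength >= 3L)
  list(coreLength = as.integer(coreLength),
       chaperoneLength = if (is.null(chaperoneLength)) NULL
       else as.integer(chaperoneLength),
       wrapFraction = wrapFraction, contactSpacing = contactSpacing,
       seed = as.integer(seed))
}

## zig-zag all-atom backbone along a CA path with outward normals; side
## chains built from idealised templates, choosing among a few uniform
## chi sets per residue so the reference conformation stays clash-free
build_chain_on_path <- function(P, U, chainId, sequence, resnoStart = 1L,
                                context = NULL) {
  n <- nrow(P)
  stopifnot(length(sequence) == n)
  frames <- vector("list", n)
  bb_rows <- vector("list", n)
  for (i in seq_len(n)) {
    t <- if (i == 1L) P[2L, ] - P[1L, ] else if (i == n)
      P[n, ] - P[n - 1L, ] else P[i + 1L, ] - P[i - 1L, ]
    t <- unit(t)
    u <- unit(U[i, ] - sum(U[i, ] * t) * t)
    v <- cross3(t, u)
    ca <- P[i, ]
    N <- ca - 1.30 * t + 0.55 * v
    C <- ca + 1.30 * t + 0.55 * v
    O <- place_atom(N, ca, C, 1.23, 120.5, 150)
    frames[[i]] <- list(N = N, CA = ca, C = C, u = u)
    bb_rows[[i]] <- data.frame(
      chain = chainId, resno = resnoStart + i - 1L, resid = sequence[i],
      elety = c("N", "CA", "C", "O"), elesy = c("N", "C", "C", "O"),
      x = c(N[1L], ca[1L], C[1L], O[1L]),
      y = c(N[2L], ca[2L], C[2L], O[2L]),
      z = c(N[3L], ca[3L], C[3L], O[3L]),
      b = 0, stringsAsFactors = FALSE)
  }
  bb_all <- do.call(rbind, bb_rows)
  sc_rows <- vector("list", n)
  for (i in seq_len(n)) {
    res <- sequence[i]
    fr <- frames[[i]]
    build_sc <- function(chi) {
      sc <- build_side_chain(fr$N, fr$CA, fr$C, res, chi = chi)
      if (nrow(sc) == 0L) return(sc)
      ## orient outward: if CB falls inward of the path normal, mirror
      ## through the plane normal to u (bond lengths exact; chirality is
      ## cosmetic for the toy)
      cb <- c(sc$x[1L], sc$y[1L], sc$z[1L])
      if (sum((cb - fr$CA) * fr$u) < 0) {
        for (k in seq_len(nrow(sc))) {
          p <- c(sc$x[k], sc$y[k], sc$z[k])
          p <- p - 2 * sum((p - fr$CA) * fr$u) * fr$u
          sc$x[k] <- p[1L]; sc$y[k] <- p[2L]; sc$z[k] <- p[3L]
        }
      }
      sc
    }
    ## obstacles: non-adjacent backbone of this chain, earlier side
    ## chains (non-adjacent), and any context atoms from other chains
    resno_i <- resnoStart + i - 1L
    obst <- bb_all[abs(bb_all$resno - resno_i) > 1L, c("x", "y", "z")]
    prior <- do.call(rbind, sc_rows[seq_len(max(i - 2L, 0L))])
    if (!is.null(prior)) obst <- rbind(obst, prior[, c("x", "y", "z")])
    if (!is.null(context)) obst <- rbind(obst, context[, c("x", "y", "z")])
    nc <- n_chi(res)
    if (nc == 0L) {
      sc <- build_sc(numeric(0))
    } else {
      ## candidate chi sets: vary the first two torsions over staggered
      ## values, keep deeper torsions extended
      base <- c(180, -65, 65)
      cands <- if (nc == 1L) lapply(base, identity) else
        lapply(seq_len(9L), function(k) {
          c(base[(k - 1L) %% 3L + 1L], base[(k - 1L) %/% 3L + 1L],
            rep(180, max(nc - 2L, 0L)))[seq_len(nc)]
        })
      best <- NULL; best_d <- -Inf
      for (chi in cands) {
        cand <- build_sc(chi)
        dmin <- if (nrow(obst) == 0L) Inf else
          min(cross_dist(cbind(cand$x, cand$y, cand$z), as.matrix(obst)))
        if (dmin > best_d) { best <- cand; best_d <- dmin }
        if (dmin >= 3.45) break
      }
      sc <- best
    }
    if (nrow(sc) > 0L)
      sc_rows[[i]] <- data.frame(
        chain = chainId, resno = resno_i, resid = res,
        elety = sc$elety, elesy = sc$elesy, x = sc$x, y = sc$y, z = sc$z,
        b = 0, stringsAsFactors = FALSE)
  }
  out <- vector("list", n)
  for (i in seq_len(n)) out[[i]] <- rbind(bb_rows[[i]], sc_rows[[i]])
  do.call(rbind, out)
}

## coiled CA path for a core chain: radius 2.3, ~100 degrees and 1.5 A
## rise per residue (3.8 A consecutive-CA spacing); the two core chains
## stack coaxially so the assembled core is a compact cylinder
core_path <- function(n, z0, phase0 = 0) {
  i <- seq_len(n) - 1L
  th <- phase0 + i * 100 * pi / 180
  P <- cbind(2.3 * cos(th), 2.3 * sin(th), z0 + 1.5 * i)
  U <- cbind(cos(th), sin(th), 0)
  list(P = P, U = U)
}

## deterministic toy sequences: compact core mostly alanine with a few
## small polar/hydrophobic residues, chaperone mixing charged residues
toy_sequences <- function(nCore, nChap) {
  core <- rep("ALA", nCore)
  core[seq_len(nCore) %% 4L == 3L] <- "SER"
  core[seq_len(nCore) %% 5L == 4L] <- "VAL"
  chap <- rep(c("ALA", "ARG", "SER", "GLU", "LEU"), length.out = nChap)
  list(A = core, B = rev(core), C = chap)
}

## clash check: no heavy-atom pair below `limit`, excluding pairs within
## one residue or between sequence-adjacent residues of a chain
min_nonlocal_distance <- function(a) {
  heavy <- which(!is_hydrogen(a$elesy))
  xyz <- as.matrix(a[heavy, c("x", "y", "z")])
  cmb <- t(combn(length(heavy), 2L))
  i <- cmb[, 1L]; j <- cmb[, 2L]
  near <- a$chain[heavy[i]] == a$chain[heavy[j]] &
    abs(a$resno[heavy[i]] - a$resno[heavy[j]]) <= 1L
  d <- sqrt((xyz[i, 1L] - xyz[j, 1L])^2 + (xyz[i, 2L] - xyz[j, 2L])^2 +
              (xyz[i, 3L] - xyz[j, 3L])^2)
  min(d[!near])
}

#' Generate a toy chaperone-histone complex
#'
#' Builds an all-heavy-atom reference conformation: two compact coiled
#' core chains (A, B) and an extended chain (C) wrapped around them on a
#' circular arc at the requested clearance. Reproducible under
#' `spec$seed`; fails if the requested wrap geometry would break the
#' ~3.8 Angstrom residue spacing of the wrapped chain or produce
#' heavy-atom clashes (< 2.4 Angstrom, non-local pairs).
#'
#' @param spec a [toySpec()] list.
#' @param arcPhase optional angular offset (radians) of the wrap arc,
#'   used to aim the arc at a particular core residue.
#' @param arcZ optional height of the wrap arc (defaults to the junction
#'   between the two stacked core chains).
#' @return A [Structure-class] with chains A, B and C.
#' @export
makeToyComplex <- function(spec = toySpec(), arcPhase = NULL, arcZ = NULL) {
  nA <- spec$coreLength
  gap <- 4.5
  cpA <- core_path(nA, 0)
  cpB <- core_path(nA, 1.5 * (nA - 1L) + gap,
                   phase0 = nA * 100 * pi / 180)
  seqs <- toy_sequences(nA, 1L)
  coreA <- build_chain_on_path(cpA$P, cpA$U, "A", seqs$A)
  coreB <- build_chain_on_path(cpB$P, cpB$U, "B", seqs$B, context = coreA)
  core <- rbind(coreA, coreB)
  z_mid <- if (is.null(arcZ)) 1.5 * (nA - 1L) + gap / 2 else arcZ
  ## radius such that a ring at height z_mid clears the core by exactly
  ## the requested contact spacing (worst case: angularly aligned atom)
  rho <- sqrt(core$x^2 + core$y^2)
  dz <- core$z - z_mid
  ring_clearance <- function(R) min(sqrt((R - rho)^2 + dz^2))
  R <- stats::uniroot(function(R) ring_clearance(R) - spec$contactSpacing,
                      interval = c(max(rho), max(rho) + 30))$root
  span <- spec$wrapFraction * 2 * pi
  rise <- 0.5  # gentle helical rise keeps a near-full lasso from closing
  nC <- if (is.null(spec$chaperoneLength))
    max(3L, floor(span * R / 3.8) + 1L) else spec$chaperoneLength
  dth <- if (nC > 1L) span / (nC - 1L) else 0
  arc_sp <- sqrt((R * dth)^2 + rise^2)
  if (arc_sp < 3.0 || arc_sp > 4.2)
    stop("infeasible wrap geometry: residue spacing on the arc would be ",
         sprintf("%.2f", arc_sp), " Angstrom (need 3.0-4.2); adjust ",
         "chaperoneLength or wrapFraction")
  phase <- if (is.null(arcPhase)) pi / 2 else arcPhase
  th <- phase - dth * (nC - 1L) / 2 + dth * (seq_len(nC) - 1L)
  zc <- z_mid + rise * (seq_len(nC) - (nC + 1L) / 2)
  P <- cbind(R * cos(th), R * sin(th), zc)
  U <- cbind(cos(th), sin(th), 0)
  chap <- build_chain_on_path(P, U, "C", toy_sequences(1L, nC)$C,
                              context = core)
  a <- rbind(core, chap)
  set.seed(spec$seed)
  jit <- matrix(stats::rnorm(3L * nrow(a), sd = 0.02), ncol = 3L)
  a$x <- a$x + jit[, 1L]; a$y <- a$y + jit[, 2L]; a$z <- a$z + jit[, 3L]
  dmin <- min_nonlocal_distance(a)
  if (dmin < 2.4)
    stop("generated reference has a heavy-atom clash (",
         sprintf("%.2f", dmin), " Angstrom); loosen contactSpacing")
  structure_(a, label = sprintf("toy complex (seed %d)", spec$seed))
}

#' Derive ground-truth restraints from a reference structure
#'
#' Picks, for each chaperone residue, the closest cross-chain heavy-atom
#' pairs with reference distance <= 5 Angstrom and sets each upper bound
#' to the reference distance plus `slack`, so the reference conformation
#' violates nothing by construction.
#'
#' @param structure the reference [Structure-class].
#' @param nPerResidue maximum restraints kept per chaperone residue.
#' @param slack bound margin above the reference distance, Angstrom.
#' @param chaperoneChain chaperone chain id.
#' @param maxRef only pairs closer than this in the reference qualify
#'   (default 5 Angstrom).
#' @return A [RestraintSet-class] (all restraints are interface
#'   restraints).
#' @export
deriveTrueRestraints <- function(structure, nPerResidue = 2L, slack = 0.5,
                                 chaperoneChain = "C", maxRef = 5.0) {
  a <- atomData(structure)
  heavy <- !is_hydrogen(a$elesy)
  ic <- which(heavy & a$chain == chaperoneChain)
  ih <- which(heavy & a$chain != chaperoneChain)
  if (length(ic) == 0L || length(ih) == 0L)
    stop("structure lacks a chaperone/core partition")
  xyz <- coords(structure)
  D <- cross_dist(xyz[ic, , drop = FALSE], xyz[ih, , drop = FALSE])
  rows <- list()
  for (res in unique(a$resno[ic])) {
    ri <- which(a$resno[ic] == res)
    cand <- which(D[ri, , drop = FALSE] <= maxRef, arr.ind = TRUE)
    if (nrow(cand) == 0L) next
    dvals <- D[ri, , drop = FALSE][cand]
    ord <- order(dvals)[seq_len(min(nPerResidue, nrow(cand)))]
    for (k in ord) {
      i1 <- ic[ri[cand[k, 1L]]]
      i2 <- ih[cand[k, 2L]]
      rows[[length(rows) + 1L]] <- data.frame(
        chain_a = a$chain[i1], resno_a = a$resno[i1], atom_a = a$elety[i1],
        chain_b = a$chain[i2], resno_b = a$resno[i2], atom_b = a$elety[i2],
        upper = dvals[k] + slack, stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0L)
    stop("no cross-chain heavy-atom pairs within ", maxRef,
         " Angstrom; no interface to restrain")
  df <- do.call(rbind, rows)
  df$interface <- TRUE
  restraint_set(df, provenance = "synthetic ground truth")
}

#' Specification for graded decoy ensembles
#'
#' @param sigmas Gaussian perturbation levels, Angstrom (per coordinate).
#' @param membersPerLevel decoys per level.
#' @param seed RNG seed.
#' @return Parameter list for [makeDecoyEnsemble()].
#' @export
decoySpec <- function(sigmas = c(0.25, 1.0, 3.0), membersPerLevel = 10L,
                      seed = 1L) {
  stopifnot(all(sigmas >= 0), membersPerLevel >= 1L)
  list(sigmas = sigmas, membersPerLevel = as.integer(membersPerLevel),
       seed = as.integer(seed))
}

#' Generate a graded decoy ensemble
#'
#' Perturbs the chaperone-chain coordinates with zero-mean Gaussian noise
#' at each level in `spec$sigmas` (the core chains stay untouched); the
#' per-member ground-truth level is recorded in the `sigma` annotation.
#'
#' @param structure reference [Structure-class].
#' @param spec a [decoySpec()] list.
#' @param chaperoneChain chain receiving the perturbation.
#' @return An [Ensemble-class] with a `sigma` annotation column.
#' @export
makeDecoyEnsemble <- function(structure, spec = decoySpec(),
                              chaperoneChain = "C") {
  set.seed(spec$seed)
  a <- atomData(structure)
  idx <- which(a$chain == chaperoneChain)
  mems <- list()
  sig <- numeric(0)
  for (s in spec$sigmas) {
    for (m in seq_len(spec$membersPerLevel)) {
      x <- coords(structure)
      if (s > 0)
        x[idx, ] <- x[idx, ] +
          matrix(stats::rnorm(3L * length(idx), sd = s), ncol = 3L)
      st <- structure
      coords(st) <- x
      st@label <- sprintf("decoy sigma=%.2f #%d", s, m)
      mems[[length(mems) + 1L]] <- st
      sig <- c(sig, s)
    }
  }
  ensemble(mems, annotations = data.frame(sigma = sig))
}

#' Build a mutation benchmark with planted effect signs
#'
#' Constructs a toy complex with (a) a small interface residue whose
#' enlargement must clash with the wrapped chaperone (expected
#' destabilising, ddG > 0) and (b) a solvent-exposed residue far from
#' the chaperone (expected |ddG| near 0), plus jittered centroid copies.
#'
#' @param seed RNG seed.
#' @param nCentroids number of jittered centroid copies (default 3).
#' @return List: `centroids` ([Ensemble-class]), `clashSite` and
#'   `distalSite` (data.frames with chain/resno/from), `mutations` (list
#'   of [Mutation-class] with an `expected_sign` attribute: `+1` clash,
#'   `0` distal control).
#' @export
makeDdgBenchmark <- function(seed = 1L, nCentroids = 3L) {
  spec <- toySpec(coreLength = 20L, contactSpacing = 3.8, seed = seed)
  ref0 <- makeToyComplex(spec)
  a0 <- atomData(ref0)
  ## aim the wrap arc at the topmost alanine of chain A so its outward CB
  ## direction points squarely at the chaperone
  candA <- which(a0$chain == "A" & a0$elety == "CB" & a0$resid == "ALA")
  site_cb <- candA[which.max(a0$z[candA])]
  phase <- atan2(a0$y[site_cb], a0$x[site_cb])
  site_ca <- which(a0$chain == "A" & a0$resno == a0$resno[site_cb] &
                     a0$elety == "CA")
  ref <- makeToyComplex(spec, arcPhase = phase, arcZ = a0$z[site_ca] + 2.0)
  a <- atomData(ref)
  clash_resno <- a0$resno[site_cb]
  ## distal control: chain A residue with no chaperone atom nearby
  chap <- which(a$chain == "C" & !is_hydrogen(a$elesy))
  xyzC <- coords(ref)[chap, , drop = FALSE]
  resA <- unique(a$resno[a$chain == "A"])
  mind <- vapply(resA, function(r) {
    ii <- which(a$chain == "A" & a$resno == r & !is_hydrogen(a$elesy))
    min(cross_dist(coords(ref)[ii, , drop = FALSE], xyzC))
  }, numeric(1))
  distal_resno <- resA[which.max(mind)]
  from_of <- function(r) a$resid[a$chain == "A" & a$resno == r][1L]
  set.seed(seed + 1L)
  cents <- lapply(seq_len(nCentroids), function(k) {
    s <- ref
    x <- coords(s)
    coords(s) <- x + matrix(stats::rnorm(length(x), sd = 0.1),
                            ncol = 3L)
    s@label <- sprintf("benchmark centroid %d", k)
    s
  })
  muts <- list(
    mutation("A", clash_resno, from_of(clash_resno), "TRP"),
    mutation("A", distal_resno, from_of(distal_resno), "TRP"))
  attr(muts[[1L]], "expected_sign") <- 1
  attr(muts[[2L]], "expected_sign") <- 0
  list(centroids = ensemble(cents),
       clashSite = data.frame(chain = "A", resno = clash_resno,
                              from = from_of(clash_resno)),
       distalSite = data.frame(chain = "A", resno = distal_resno,
                               from = from_of(distal_resno)),
       mutations = muts)
}
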