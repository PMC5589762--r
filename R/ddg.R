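#' @include AllClasses.R AllGenerics.R residue-templates.R sampler.R
NULL

## unit-charge assignment on charged side-chain groups
atom_charge <- function(resid, elety) {
  q <- numeric(length(resid))
  q[resid == "LYS" & elety == "NZ"] <- 1
  q[resid == "ARG" & elety %in% c("NH1", "NH2")] <- 0.5
  q[resid == "ASP" & elety %in% c("OD1", "OD2")] <- -0.5
  q[resid == "GLU" & elety %in% c("OE1", "OE2")] <- -0.5
  q
}

#' Construct a mutation
#'
#' @param chain chain id.
#' @param resno residue number.
#' @param from,to 3-letter residue codes; `to` may not be proline,
#'   cysteine or the native residue.
#' @return A validated [Mutation-class].
#' @export
mutation <- function(chain, resno, from, to) {
  new("Mutation", chain = as.character(chain), resno = as.integer(resno),
      from = toupper(from), to = toupper(to))
}

#' Enumerate point mutations at interface sites
#'
#' At every site, every standard amino acid except proline, cysteine and
#' the native residue is a candidate: 17 mutations at a typical site.
#' Output order is by site, then alphabetical by target 3-letter code.
#'
#' @param sites data.frame with columns `chain`, `resno`, `from`
#'   (3-letter native codes).
#' @return List of [Mutation-class] objects.
#' @examples
#' length(enumerateMutations(
#'   data.frame(chain = "A", resno = 5, from = "ARG")))  # 17
#' @export
enumerateMutations <- function(sites) {
  stopifnot(all(c("chain", "resno", "from") %in% names(sites)))
  out <- list()
  for (i in seq_len(nrow(sites))) {
    from <- toupper(sites$from[i])
    if (!from %in% AA3) stop("non-standard residue: ", from)
    targets <- setdiff(AA3, c("PRO", "CYS", from))  # AA3 is alphabetical
    for (to in targets)
      out[[length(out) + 1L]] <-
        mutation(sites$chain[i], sites$resno[i], from, to)
  }
  out
}

#' Annealing schedule for rotamer repacking
#'
#' @param tStart,tEnd start/end temperatures (surrogate units), geometric
#'   interpolation.
#' @param sweeps number of sweeps (one proposed rotamer change per shell
#'   residue per sweep).
#' @return List with a `temperatures` vector of per-sweep temperatures.
#' @export
annealSchedule <- function(tStart = 5, tEnd = 0.1, sweeps = 200L) {
  stopifnot(tStart > 0, tEnd > 0, sweeps >= 1L)
  list(temperatures = tStart * (tEnd / tStart)^(seq_len(sweeps) / sweeps),
       sweeps = as.integer(sweeps))
}

## --- repacking machinery ---------------------------------------------
## The packing energy is a documented surrogate: soft-sphere repulsion
## (w_rep * (sigma - r)^2 below sigma = sum of element radii),
## distance-dependent-dielectric Coulomb (332 * q_i q_j / (4 r^2), 10 A
## cutoff) with unit charges on charged groups, and a rotamer prior
## -log(weight). It scores steric feasibility and coarse electrostatics,
## not calibrated free energies; outputs are comparable only within this
## package.
REPACK_PARS <- list(w_rep = 10, coul_k = 332 / 4, coul_cut = 10,
                    w_prior = 0.5)

## static context for repacking one site within one structure
repack_context <- function(structure, chain, resno, shell = 8,
                           radii = ELEMENT_RADII) {
  a <- atomData(structure)
  site <- which(a$chain == chain & a$resno == resno)
  if (length(site) == 0L)
    stop("no residue ", chain, resno, " in structure")
  site_xyz <- as.matrix(a[site, c("x", "y", "z")])
  ## residues with >=1 sampled chi whose heavy atoms come within `shell`
  res_key <- paste(a$chain, a$resno)
  heavy <- !is_hydrogen(a$elesy)
  d2min <- rep(Inf, nrow(a))
  for (k in seq_len(nrow(site_xyz)))
    d2min <- pmin(d2min, row_dist2(as.matrix(a[, c("x", "y", "z")]),
                                   site_xyz[k, ]))
  near_res <- unique(res_key[heavy & d2min <= shell^2])
  shell_df <- unique(data.frame(key = near_res, stringsAsFactors = FALSE))
  shell_res <- do.call(rbind, lapply(shell_df$key, function(k) {
    i <- which(res_key == k)[1L]
    data.frame(chain = a$chain[i], resno = a$resno[i],
               resid = a$resid[i], stringsAsFactors = FALSE)
  }))
  rotatable <- vapply(shell_res$resid, function(r)
    r %in% names(SC_TEMPLATES), logical(1))
  nchis <- vapply(shell_res$resid, n_chi, integer(1))
  is_site <- shell_res$chain == chain & shell_res$resno == resno
  shell_res <- shell_res[rotatable & (nchis >= 1L | is_site), , drop = FALSE]
  if (!any(shell_res$chain == chain & shell_res$resno == resno))
    shell_res <- rbind(shell_res,
                       data.frame(chain = chain, resno = resno,
                                  resid = a$resid[site[1L]]))
  rownames(shell_res) <- NULL
  ## backbone anchors per shell residue
  anchors <- lapply(seq_len(nrow(shell_res)), function(i) {
    ii <- which(a$chain == shell_res$chain[i] &
                  a$resno == shell_res$resno[i])
    g <- function(nm) {
      j <- ii[a$elety[ii] == nm]
      if (length(j) != 1L)
        stop("residue ", shell_res$chain[i], shell_res$resno[i],
             " lacks backbone atom ", nm)
      c(a$x[j], a$y[j], a$z[j])
    }
    list(N = g("N"), CA = g("CA"), C = g("C"))
  })
  ## background = everything except side chains of shell residues
  in_shell_sc <- res_key %in% paste(shell_res$chain, shell_res$resno) &
    !a$elety %in% BACKBONE_NAMES
  bg <- a[!in_shell_sc & heavy, , drop = FALSE]
  list(shell = shell_res, anchors = anchors,
       bg = list(xyz = as.matrix(bg[, c("x", "y", "z")]),
                 rad = unname(radii[toupper(bg$elesy)]),
                 q = atom_charge(bg$resid, bg$elety),
                 chain = bg$chain, resno = bg$resno,
                 backbone = bg$elety %in% BACKBONE_NAMES),
       radii = radii)
}

## side-chain heavy atoms of shell residue i at given chis (resid may be
## overridden, e.g. the mutant target at the site)
ctx_side_chain <- function(ctx, i, resid, chi) {
  an <- ctx$anchors[[i]]
  sc <- build_side_chain(an$N, an$CA, an$C, resid, chi)
  if (nrow(sc) == 0L)
    return(list(xyz = matrix(numeric(0), 0L, 3L), rad = numeric(0),
                q = numeric(0)))
  list(xyz = cbind(sc$x, sc$y, sc$z),
       rad = unname(ctx$radii[toupper(sc$elesy)]),
       q = atom_charge(rep(resid, nrow(sc)), sc$elety))
}

## pair energy between an atom set and another (vdW repulsion + Coulomb)
pair_energy <- function(A, B, exclude = NULL) {
  if (nrow(A$xyz) == 0L || nrow(B$xyz) == 0L) return(0)
  D <- cross_dist(A$xyz, B$xyz)
  if (!is.null(exclude)) D[, exclude] <- Inf
  S <- outer(A$rad, B$rad, "+")
  over <- D < S
  e <- if (any(over)) REPACK_PARS$w_rep * sum((S[over] - D[over])^2) else 0
  qq <- outer(A$q, B$q)
  hasq <- qq != 0 & D < REPACK_PARS$coul_cut
  if (any(hasq))
    e <- e + REPACK_PARS$coul_k * sum(qq[hasq] / D[hasq]^2)
  e
}

## energy of shell residue i's side chain against the fixed background
## (own residue and sequence-adjacent backbone excluded)
env_energy <- function(ctx, i, sc) {
  if (nrow(sc$xyz) == 0L) return(0)
  ch <- ctx$shell$chain[i]; rn <- ctx$shell$resno[i]
  bg <- ctx$bg
  excl <- (bg$chain == ch & bg$resno == rn) |
    (bg$chain == ch & abs(bg$resno - rn) == 1L & bg$backbone)
  pair_energy(sc, bg, exclude = which(excl))
}

## simulated-annealing rotamer repack; returns final packing energy (and,
## optionally, the final rotamer state). `target` overrides the residue
## type at the site row (mutant arm); NULL repacks the native type
## (wild-type arm).
repack_run <- function(ctx, site_i, target = NULL, library = rotamerLibrary(),
                       schedule = annealSchedule(), seed = 1L,
                       return_state = FALSE, memo = new.env()) {
  set.seed(seed)
  n <- nrow(ctx$shell)
  types <- ctx$shell$resid
  if (!is.null(target)) types[site_i] <- target
  rots <- lapply(types, function(tp) library[[tp]])
  ## rotamer geometry and environment energy are deterministic given the
  ## fixed backbone: memoise both per (residue, type, rotamer); the memo
  ## can be shared across runs on the same context
  get_sc <- function(i, r) {
    key <- paste0("s", i, ":", types[i], ":", r)
    v <- memo[[key]]
    if (is.null(v)) {
      v <- ctx_side_chain(ctx, i, types[i], rots[[i]]$chis[r, ])
      memo[[key]] <- v
    }
    v
  }
  get_env <- function(i, r) {
    key <- paste0("e", i, ":", types[i], ":", r)
    v <- memo[[key]]
    if (is.null(v)) {
      v <- env_energy(ctx, i, get_sc(i, r))
      memo[[key]] <- v
    }
    v
  }
  cur <- integer(n)
  sc <- vector("list", n)
  e_env <- numeric(n)
  prior <- numeric(n)
  for (i in seq_len(n)) {
    cur[i] <- which.max(rots[[i]]$weights)
    sc[[i]] <- get_sc(i, cur[i])
    e_env[i] <- get_env(i, cur[i])
    prior[i] <- -REPACK_PARS$w_prior * log(rots[[i]]$weights[cur[i]])
  }
  ## pairwise side-chain interaction matrix, updated row/column-wise
  M <- matrix(0, n, n)
  for (i in seq_len(max(n - 1L, 0L))) for (j in seq(i + 1L, n)) {
    if (j > n) break
    M[i, j] <- M[j, i] <- pair_energy(sc[[i]], sc[[j]])
  }
  sampleable <- which(vapply(rots, function(r) nrow(r$chis) > 1L, logical(1)))
  if (length(sampleable) > 0L) {
    for (Tm in schedule$temperatures) {
      for (k in seq_along(sampleable)) {
        i <- sampleable[sample.int(length(sampleable), 1L)]
        prop <- sample.int(nrow(rots[[i]]$chis), 1L)
        if (prop == cur[i]) next
        sci <- get_sc(i, prop)
        env_new <- get_env(i, prop)
        row_new <- numeric(n)
        for (j in seq_len(n)) if (j != i)
          row_new[j] <- pair_energy(sci, sc[[j]])
        prior_new <- -REPACK_PARS$w_prior * log(rots[[i]]$weights[prop])
        dE <- (env_new + sum(row_new) + prior_new) -
          (e_env[i] + sum(M[i, ]) + prior[i])
        if (metropolisAccept(dE, Tm)) {
          cur[i] <- prop; sc[[i]] <- sci
          e_env[i] <- env_new; prior[i] <- prior_new
          M[i, ] <- row_new; M[, i] <- row_new
        }
      }
    }
  }
  energy <- sum(e_env) + sum(prior) + sum(M) / 2
  if (!return_state) return(energy)
  list(energy = energy, assignment = cur, types = types,
       chis = lapply(seq_len(n), function(i) rots[[i]]$chis[cur[i], ]))
}

#' Mutate a residue and repack the neighbourhood
#'
#' Replaces the site's side chain with the target residue built from
#' idealised internal coordinates, then repacks all rotatable side chains
#' within `shell` Angstrom by simulated-annealing rotamer Monte Carlo
#' under the surrogate packing energy. Backbone coordinates are never
#' touched.
#'
#' @param structure a [Structure-class].
#' @param mut a [Mutation-class], or `NULL` for a wild-type repack-only
#'   pass at the site given by `chain`/`resno`.
#' @param chain,resno site of a wild-type repack (ignored when `mut` is
#'   given).
#' @param library rotamer library, see [rotamerLibrary()].
#' @param schedule annealing schedule, see [annealSchedule()].
#' @param seed RNG seed.
#' @param shell repack radius around the site, Angstrom (default 8).
#' @return List with `structure` (repacked; backbone identical to input)
#'   and `energy` (final packing energy, surrogate units).
#' @export
mutateAndRepack <- function(structure, mut = NULL, chain = NULL,
                            resno = NULL, library = rotamerLibrary(),
                            schedule = annealSchedule(), seed = 1L,
                            shell = 8) {
  if (!is.null(mut)) {
    validObject(mut)
    chain <- mut@chain; resno <- mut@resno
    a <- atomData(structure)
    i <- which(a$chain == chain & a$resno == resno)
    if (length(i) == 0L) stop("no residue ", chain, resno, " in structure")
    native <- a$resid[i[1L]]
    if (native != mut@from)
      stop("site ", chain, resno, " is ", native, ", not ", mut@from)
  }
  ctx <- repack_context(structure, chain, resno, shell = shell)
  site_i <- which(ctx$shell$chain == chain & ctx$shell$resno == resno)
  target <- if (is.null(mut)) NULL else mut@to
  st <- repack_run(ctx, site_i, target = target, library = library,
                   schedule = schedule, seed = seed, return_state = TRUE)
  ## realise the repacked shell in the returned structure
  out <- structure
  for (i in seq_len(nrow(ctx$shell)))
    out <- swap_side_chain(out, ctx$shell$chain[i], ctx$shell$resno[i],
                           st$types[i], st$chis[[i]])
  list(structure = out, energy = st$energy)
}

#' Binding stability change of one mutation
#'
#' For each centroid and run, repacks four arms under the surrogate
#' packing energy: mutant and wild type, each in the full complex and in
#' the histone dimer with the chaperone chain deleted. Each run's value is
#' `(dG_complex_mut - dG_dimer_mut) - (dG_complex_wt - dG_dimer_wt)`;
#' positive values are destabilising. Mutant and wild-type arms share RNG
#' seeds pairwise, so a wild-type "mutation" cancels exactly.
#'
#' @param centroids an [Ensemble-class] (or list of structures) of
#'   centroid conformations.
#' @param mut a [Mutation-class] on a histone chain, or `NULL` for a
#'   wild-type control at `chain`/`resno`.
#' @param chaperoneChain chain id deleted to form the unbound dimer.
#' @param nRuns repack runs per centroid (production screens typically
#'   use hundreds; desk-scale default 20).
#' @param seed master seed; run-level seeds derive deterministically.
#' @param chain,resno site for a wild-type control when `mut` is `NULL`.
#' @param library,schedule,shell see [mutateAndRepack()].
#' @param pairSeeds share RNG seeds between the mutant and wild-type arm
#'   of each run (default `TRUE`; set `FALSE` to measure the unpaired
#'   repack noise floor, e.g. from wild-type replicates).
#' @return A [DdgRecord-class].
#' @export
ddgOfMutation <- function(centroids, mut, chaperoneChain = "C",
                          nRuns = 20L, seed = 1L, chain = NULL,
                          resno = NULL, library = rotamerLibrary(),
                          schedule = annealSchedule(), shell = 8,
                          pairSeeds = TRUE) {
  mem <- if (is(centroids, "Ensemble")) members(centroids) else centroids
  if (!is.null(mut)) {
    validObject(mut)
    if (mut@chain == chaperoneChain)
      stop("the screen mutates the histone side only; site is on the ",
           "chaperone chain ", sQuote(chaperoneChain))
    chain <- mut@chain; resno <- mut@resno
  }
  if (is.null(chain) || is.null(resno))
    stop("a site (chain, resno) is required for a wild-type control")
  rows <- list()
  for (ci in seq_along(mem)) {
    cx <- mem[[ci]]
    a <- atomData(cx)
    dimer <- structure_(a[a$chain != chaperoneChain, , drop = FALSE],
                        label = paste0(cx@label, " dimer"))
    ctx_c <- repack_context(cx, chain, resno, shell = shell)
    ctx_d <- repack_context(dimer, chain, resno, shell = shell)
    site_c <- which(ctx_c$shell$chain == chain & ctx_c$shell$resno == resno)
    site_d <- which(ctx_d$shell$chain == chain & ctx_d$shell$resno == resno)
    target <- if (is.null(mut)) NULL else mut@to
    memo_c <- new.env(); memo_d <- new.env()
    for (r in seq_len(nRuns)) {
      s1 <- (seed + 7919L * ci + 104729L * r) %% 2147483629L
      s2 <- (s1 + 1299709L) %% 2147483629L
      s1w <- if (pairSeeds) s1 else (s1 + 15485863L) %% 2147483629L
      s2w <- if (pairSeeds) s2 else (s2 + 15485863L) %% 2147483629L
      gcm <- repack_run(ctx_c, site_c, target, library, schedule, seed = s1,
                        memo = memo_c)
      gcw <- repack_run(ctx_c, site_c, NULL, library, schedule, seed = s1w,
                        memo = memo_c)
      gdm <- repack_run(ctx_d, site_d, target, library, schedule, seed = s2,
                        memo = memo_d)
      gdw <- repack_run(ctx_d, site_d, NULL, library, schedule, seed = s2w,
                        memo = memo_d)
      rows[[length(rows) + 1L]] <-
        data.frame(centroid = ci, run = r, dG_complex_mut = gcm,
                   dG_dimer_mut = gdm, dG_complex_wt = gcw,
                   dG_dimer_wt = gdw,
                   ddg = (gcm - gdm) - (gcw - gdw))
    }
  }
  runs <- do.call(rbind, rows)
  m <- if (is.null(mut)) {
    a1 <- atomData(mem[[1L]])
    nat <- a1$resid[a1$chain == chain & a1$resno == resno][1L]
    other <- setdiff(AA3, c("PRO", "CYS", nat))[1L]
    mutation(chain, resno, nat, other)  # placeholder identity for controls
  } else mut
  new("DdgRecord", mutation = m, runs = runs,
      ddgMean = mean(runs$ddg),
      ddgSem = if (nrow(runs) > 1L)
        stats::sd(runs$ddg) / sqrt(nrow(runs)) else 0,
      nRuns = nrow(runs))
}

#' Screen all mutations at interface sites
#'
#' Enumerates every allowed substitution at the supplied histone-side
#' sites (or at residues exceeding an average-contact threshold in an
#' [InterfaceProfile-class]) and computes a [ddgOfMutation()] record for
#' each. Deterministic under `seed`; rows sorted by descending mean ddG.
#'
#' @param centroids an [Ensemble-class] of centroid structures.
#' @param sites data.frame (`chain`, `resno`, `from`), or `NULL` to derive
#'   from `profile`.
#' @param profile optional [InterfaceProfile-class]; sites are side-A
#'   residues with `avgContacts > contactThreshold`.
#' @param contactThreshold threshold on average contacts (default 0).
#' @param chaperoneChain chaperone chain id.
#' @param nRuns,seed,library,schedule,shell see [ddgOfMutation()].
#' @return List with `table` (data.frame, sorted by descending
#'   `ddg_mean`) and `records` (list of [DdgRecord-class]).
#' @export
screenInterface <- function(centroids, sites = NULL, profile = NULL,
                            contactThreshold = 0, chaperoneChain = "C",
                            nRuns = 20L, seed = 1L,
                            library = rotamerLibrary(),
                            schedule = annealSchedule(), shell = 8) {
  if (is.null(sites)) {
    if (is.null(profile)) stop("supply sites or an InterfaceProfile")
    p <- profile@profile
    p <- p[p$side == "A" & p$avgContacts > contactThreshold, , drop = FALSE]
    sites <- data.frame(chain = p$chain, resno = p$resno, from = p$resid,
                        stringsAsFactors = FALSE)
  }
  if (nrow(sites) == 0L) stop("empty interface site set")
  muts <- enumerateMutations(sites)
  records <- lapply(muts, function(m)
    ddgOfMutation(centroids, m, chaperoneChain = chaperoneChain,
                  nRuns = nRuns, seed = seed, library = library,
                  schedule = schedule, shell = shell))
  tab <- do.call(rbind, lapply(records, function(r) {
    m <- r@mutation
    data.frame(mutation = sprintf("%s%d%s>%s", m@chain, m@resno, m@from,
                                  m@to),
               chain = m@chain, resno = m@resno, from = m@from, to = m@to,
               ddg_mean = r@ddgMean, ddg_sem = r@ddgSem, n_runs = r@nRuns,
               stringsAsFactors = FALSE)
  }))
  ord <- order(-tab$ddg_mean)
  list(table = tab[ord, , drop = FALSE], records = records[ord])
}
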