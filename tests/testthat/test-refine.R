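## mixed ensemble with ground-truth labels: near-native vs scrambled
labelled_mix <- function(n_each = 15L, seed = 5L) {
  fx <- toy_fixture()
  dec <- makeDecoyEnsemble(fx$structure,
                           decoySpec(sigmas = c(0.25, 3.0),
                                     membersPerLevel = n_each, seed = seed))
  ann <- annotations(dec)
  ann$energy <- vapply(members(dec), restraintEnergy, numeric(1),
                       set = fx$restraints)
  annotations(dec) <- ann
  dec
}

test_that("filtering respects percentiles, ceilings and order", {
  mix <- labelled_mix()
  ## keep-everything spec is the identity
  all_kept <- filterEnsemble(mix, toy_fixture()$restraints,
                             filterSpec(energyKeys = character(0),
                                        violationMax = Inf))
  expect_equal(all_kept$kept, seq_len(nMembers(mix)))
  ## explicit energies 1..10, keep lowest 50%
  fx <- toy_fixture()
  ten <- ensemble(members(mix)[1:10],
                  annotations = data.frame(energy = 1:10))
  half <- filterEnsemble(ten, spec = filterSpec(violationMax = Inf,
                                                energyPercentileKeep = 50))
  expect_equal(half$kept, 1:5)
  ## order preserved, counts reported
  res <- filterEnsemble(mix, fx$restraints, filterSpec())
  expect_true(all(diff(res$kept) > 0))
  expect_equal(sum(res$report$removed),
               nMembers(mix) - nMembers(res$ensemble))
  ## every member removed is an error with diagnostics
  expect_error(filterEnsemble(ten, fx$restraints,
                              filterSpec(energyPercentileKeep = 10,
                                         violationMax = 0)),
               "all members removed")
  ## missing annotation is an error
  expect_error(filterEnsemble(ensemble(members(mix)[1:3]), fx$restraints,
                              filterSpec()),
               "lacks required annotation")
})

test_that("near-native members survive filtering, scrambled decoys do not", {
  mix <- labelled_mix()
  fx <- toy_fixture()
  res <- filterEnsemble(mix, fx$restraints, filterSpec())
  sig <- annotations(mix)$sigma[res$kept]
  n_each <- sum(annotations(mix)$sigma == 0.25)
  expect_gte(sum(sig == 0.25) / n_each, 0.9)
  expect_lte(sum(sig == 3.0) / n_each, 0.1)
  ## per-member mean violation can only drop on average
  expect_lt(mean(perMemberMeanViolation(res$ensemble, fx$restraints)),
            mean(perMemberMeanViolation(mix, fx$restraints)))
  ## r^-6 ensemble violation of the refined set never exceeds the
  ## unfiltered one
  expect_lte(meanEnsembleViolation(res$ensemble, fx$restraints),
             meanEnsembleViolation(mix, fx$restraints) + 1e-12)
})

test_that("tightening a filter never grows the refined ensemble", {
  mix <- labelled_mix()
  fx <- toy_fixture()
  sizes_v <- vapply(c(Inf, 1.0, 0.5, 0.2), function(vm)
    nMembers(filterEnsemble(mix, fx$restraints,
                            filterSpec(energyKeys = character(0),
                                       violationMax = vm))$ensemble),
    numeric(1))
  expect_true(all(diff(sizes_v) <= 0))
  sizes_e <- vapply(c(100, 80, 50, 30), function(p)
    nMembers(filterEnsemble(mix, fx$restraints,
                            filterSpec(energyPercentileKeep = p,
                                       violationMax = Inf))$ensemble),
    numeric(1))
  expect_true(all(diff(sizes_e) <= 0))
})

test_that("pairwise RMSD matrices agree with the one-pair fit", {
  fx <- toy_fixture()
  dec <- makeDecoyEnsemble(fx$structure,
                           decoySpec(sigmas = c(0, 0.5, 1.5),
                                     membersPerLevel = 2L, seed = 8))
  sel <- atomSelector(chains = "C", atomNames = "backbone")
  M <- pairwiseRmsdMatrix(dec, sel)
  expect_equal(M, t(M))
  expect_equal(diag(M), rep(0, nMembers(dec)))
  ## the two sigma-0 members are identical: off-diagonal zero
  expect_equal(M[1, 2], 0, tolerance = 1e-9)
  ## entries match independent pair superpositions
  for (pair in list(c(1, 3), c(2, 6), c(4, 5))) {
    r <- superpose(members(dec)[[pair[1]]], members(dec)[[pair[2]]],
                   sel)$rmsd
    expect_equal(M[pair[1], pair[2]], r, tolerance = 1e-9)
  }
  expect_error(pairwiseRmsdMatrix(ensemble(members(dec)[1]), sel),
               "at least 2")
})

test_that("k-medoids extracts true basin representatives", {
  fx <- toy_fixture()
  ## two tight basins: jitter around the reference and around one fixed
  ## far-perturbed conformation
  anchor2 <- members(makeDecoyEnsemble(
    fx$structure, decoySpec(sigmas = 6, membersPerLevel = 1,
                            seed = 99)))[[1L]]
  jit <- function(s, seed) members(makeDecoyEnsemble(
    s, decoySpec(sigmas = 0.15, membersPerLevel = 1, seed = seed)))[[1L]]
  mem <- c(lapply(1:5, function(i) jit(fx$structure, i)),
           lapply(6:10, function(i) jit(anchor2, i)))
  ens <- ensemble(mem)
  sel <- atomSelector(chains = "C", atomNames = "backbone")
  M <- pairwiseRmsdMatrix(ens, sel)
  rep2 <- extractCentroids(M, k = 2)
  expect_equal(rep2@clusters[1:5], rep(rep2@clusters[1], 5))
  expect_equal(rep2@clusters[6:10], rep(rep2@clusters[6], 5))
  expect_false(rep2@clusters[1] == rep2@clusters[6])
  ## k = n: everyone is their own centroid
  repn <- extractCentroids(M, k = 10)
  expect_equal(sort(repn@centroids), 1:10)
  ## k = 1: medoid matches exhaustive scan
  rep1 <- extractCentroids(M, k = 1)
  expect_equal(rep1@centroids, which.min(rowSums(M)))
  expect_error(extractCentroids(M, k = 11), "exceeds")
  ## PAM objective beats random medoids
  obj_random <- replicate(100, {
    med <- sample(10, 2)
    sum(apply(M[, med, drop = FALSE], 1, min))
  })
  expect_lte(rep2@objective, min(obj_random) + 1e-9)
})
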