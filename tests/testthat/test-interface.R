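selA <- function() atomSelector(chains = c("A", "B"))
selB <- function() atomSelector(chains = "C")

test_that("contact counting is inclusive at the cutoff and cross-group only", {
  mk <- function(d) tiny_structure(rbind(c(0, 0, 0), c(d, 0, 0)),
                                   chain = c("A", "C"))
  expect_equal(countContacts(mk(5.99), selA(), selB())$total, 1L)
  expect_equal(countContacts(mk(6.00), selA(), selB())$total, 1L)
  expect_equal(countContacts(mk(6.01), selA(), selB())$total, 0L)
  ## hydrogens never count
  sh <- tiny_structure(rbind(c(0, 0, 0), c(3, 0, 0)), chain = c("A", "C"),
                       elesy = c("C", "H"))
  expect_equal(countContacts(sh, selA(), selB())$total, 0L)
  ## overlapping groups are a contract violation
  fx <- toy_fixture()
  expect_error(countContacts(fx$structure, atomSelector(chains = "A"),
                             atomSelector(chains = c("A", "C"))),
               "overlap")
})

test_that("contact counts match a brute-force all-pairs oracle", {
  set.seed(17)
  for (rep in 1:20) {
    nA <- 22L; nB <- 18L
    xyzA <- matrix(runif(3 * nA, 0, 14), ncol = 3)
    xyzB <- matrix(runif(3 * nB, 0, 14), ncol = 3)
    s <- tiny_structure(rbind(xyzA, xyzB),
                        chain = c(rep("A", nA), rep("C", nB)))
    got <- countContacts(s, selA(), selB())
    want <- brute_contacts(xyzA, xyzB, 6.0)
    expect_equal(got$total, want$total)
    expect_equal(got$perResidueA$contacts, as.numeric(want$perA))
    expect_equal(got$perResidueB$contacts, as.numeric(want$perB))
    ## side sums both equal the total
    expect_equal(sum(got$perResidueA$contacts), got$total)
    expect_equal(sum(got$perResidueB$contacts), got$total)
  }
})

test_that("contacts are invariant under rigid motion of the whole complex", {
  fx <- toy_fixture()
  base <- countContacts(fx$structure, selA(), selB())
  th <- 1.1; ax <- c(0, 1, 1) / sqrt(2)
  K <- matrix(c(0, -ax[3], ax[2], ax[3], 0, -ax[1], -ax[2], ax[1], 0),
              3, 3, byrow = TRUE)
  R <- diag(3) * cos(th) + sin(th) * K + (1 - cos(th)) * (ax %o% ax)
  s2 <- fx$structure
  coords(s2) <- coords(fx$structure) %*% t(R) +
    matrix(c(-4, 8, 1), nAtoms(fx$structure), 3, byrow = TRUE)
  moved <- countContacts(s2, selA(), selB())
  expect_equal(moved$total, base$total)
  expect_equal(moved$perResidueA$contacts, base$perResidueA$contacts)
})

test_that("ensemble contact profiles average per residue", {
  fx <- toy_fixture()
  one <- averageContacts(ensemble(fx$structure), selA(), selB())
  cc <- countContacts(fx$structure, selA(), selB())
  expect_equal(one@profile$avgContacts,
               c(cc$perResidueA$contacts, cc$perResidueB$contacts))
  ## two members average; order of members is irrelevant
  dec <- makeDecoyEnsemble(fx$structure,
                           decoySpec(sigmas = c(0, 1), membersPerLevel = 1,
                                     seed = 2))
  p12 <- averageContacts(dec, selA(), selB())
  p21 <- averageContacts(ensemble(rev(members(dec))), selA(), selB())
  expect_equal(p12@profile$avgContacts, p21@profile$avgContacts)
  m1 <- countContacts(members(dec)[[1]], selA(), selB())
  m2 <- countContacts(members(dec)[[2]], selA(), selB())
  expect_equal(p12@profile$avgContacts[1:nrow(m1$perResidueA)],
               (m1$perResidueA$contacts + m2$perResidueA$contacts) / 2)
})

test_that("Shrake-Rupley SASA reproduces sphere analytics", {
  one <- tiny_structure(matrix(0, 1, 3))
  got <- sum(computeSasa(one)@perAtom)
  want <- 4 * pi * (1.7 + 1.4)^2
  expect_lt(abs(got - want) / want, 0.01)
  ## far-separated atoms are additive
  two_far <- tiny_structure(rbind(c(0, 0, 0), c(50, 0, 0)))
  expect_lt(abs(sum(computeSasa(two_far)@perAtom) - 2 * want) / (2 * want),
            0.01)
  ## two fused carbons match the closed-form two-sphere area
  for (d in c(1.5, 2.4, 3.3)) {
    fused <- tiny_structure(rbind(c(0, 0, 0), c(d, 0, 0)))
    got <- sum(computeSasa(fused)@perAtom)
    want2 <- two_sphere_area(3.1, 3.1, d)
    expect_lt(abs(got - want2) / want2, 0.01)
  }
  ## unknown elements are refused by name
  odd <- tiny_structure(matrix(0, 1, 3), elesy = "X")
  expect_error(computeSasa(odd), "no radius for element")
  ## deterministic for fixed point count
  fx <- toy_fixture()
  expect_identical(computeSasa(fx$structure, points = 240L)@perAtom,
                   computeSasa(fx$structure, points = 240L)@perAtom)
})

test_that("buried SASA is symmetric, zero for separated chains, and matches
          an independent random-point estimate", {
  ## separated chains bury nothing
  apart <- tiny_structure(rbind(c(0, 0, 0), c(40, 0, 0)),
                          chain = c("A", "C"))
  expect_equal(buriedSasa(apart, "A", "C"), 0, tolerance = 1e-9)
  fx <- toy_fixture()
  b1 <- buriedSasa(fx$structure, c("A", "B"), "C", points = 480L)
  b2 <- buriedSasa(fx$structure, "C", c("A", "B"), points = 480L)
  expect_gt(b1, 0)
  expect_equal(b1, b2)
  expect_error(buriedSasa(fx$structure, "A", "C"), "partition")
  ## independent estimate: Monte Carlo point sampling instead of the
  ## deterministic spiral
  mc_sasa <- function(structure, npts = 2000L, seed = 123) {
    set.seed(seed)
    a <- atomData(structure)
    xyz <- coords(structure)
    rad <- c(C = 1.7, N = 1.55, O = 1.52, S = 1.8)[toupper(a$elesy)] + 1.4
    tot <- 0
    for (i in seq_len(nrow(a))) {
      v <- matrix(rnorm(3 * npts), ncol = 3)
      v <- v / sqrt(rowSums(v^2))
      pts <- sweep(v * rad[i], 2, xyz[i, ], "+")
      acc <- rep(TRUE, npts)
      for (j in seq_len(nrow(a))[-i]) {
        d2 <- (pts[, 1] - xyz[j, 1])^2 + (pts[, 2] - xyz[j, 2])^2 +
          (pts[, 3] - xyz[j, 3])^2
        acc <- acc & d2 > rad[j]^2
      }
      tot <- tot + 4 * pi * rad[i]^2 * mean(acc)
    }
    tot
  }
  a <- atomData(fx$structure)
  small <- structure_(a[a$resno <= 6 & abs(a$z -
    mean(a$z[a$chain == "C"])) < 12, ])
  got <- sum(computeSasa(small)@perAtom)
  want <- mc_sasa(small)
  expect_lt(abs(got - want) / want, 0.03)
})

test_that("ensemble buried area reports mean and SD across members", {
  fx <- toy_fixture()
  dec <- makeDecoyEnsemble(fx$structure,
                           decoySpec(sigmas = c(0, 0.5),
                                     membersPerLevel = 2L, seed = 4))
  v <- ensembleBuriedSasa(dec, c("A", "B"), "C", points = 240L)
  expect_equal(unname(v["n"]), 4)
  expect_gt(unname(v["mean"]), 0)
  expect_gte(unname(v["sd"]), 0)
})

test_that("heat-map export writes per-residue B-factors and a TSV", {
  fx <- toy_fixture()
  prof <- averageContacts(ensemble(fx$structure), selA(), selB())
  f <- withr::local_tempfile(fileext = ".pdb")
  paths <- exportHeatmap(fx$structure, prof, f)
  back <- members(readStructureModels(paths[["pdb"]]))[[1L]]
  a <- atomData(back)
  p <- prof@profile
  for (k in sample(nrow(p), 5)) {
    rows <- a$chain == p$chain[k] & a$resno == p$resno[k]
    expect_equal(unique(round(a$b[rows], 2)),
                 round(p$avgContacts[k], 2))
  }
  tsv <- utils::read.delim(paths[["tsv"]])
  expect_equal(nrow(tsv), nrow(p))
  ## empty profile: all B-factors zero
  empty <- methods::new("InterfaceProfile",
                        profile = p[0L, ], totalsPerMember = 0,
                        cutoff = 6)
  f2 <- withr::local_tempfile(fileext = ".pdb")
  exportHeatmap(fx$structure, empty, f2)
  b <- atomData(members(readStructureModels(f2))[[1L]])$b
  expect_true(all(b == 0))
})
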