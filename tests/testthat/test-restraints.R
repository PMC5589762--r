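## topology fixture with explicit hydrogens for the remapping rules
h_topology <- function() {
  row <- function(chain, resno, resid, elety, elesy, x)
    data.frame(chain = chain, resno = resno, resid = resid, elety = elety,
               elesy = elesy, x = x, y = 0, z = 0, b = 0,
               stringsAsFactors = FALSE)
  structure_(rbind(
    row("C", 70, "LEU", "N", "N", 0), row("C", 70, "LEU", "H", "H", -0.5),
    row("C", 70, "LEU", "CA", "C", 1.5), row("C", 70, "LEU", "CB", "C", 2.5),
    row("C", 70, "LEU", "CG", "C", 3.5), row("C", 70, "LEU", "CD1", "C", 4.5),
    row("C", 70, "LEU", "HD11", "H", 5.0), row("C", 70, "LEU", "HD12", "H", 5.1),
    row("B", 40, "TYR", "CZ", "C", 10), row("B", 40, "TYR", "OH", "O", 11),
    row("B", 40, "VAL", "CG1", "C", 14), row("B", 40, "VAL", "HG11", "H", 14.5),
    row("A", 5, "SER", "CB", "C", 19), row("A", 5, "SER", "OG", "O", 20),
    row("A", 5, "SER", "HG", "H", 20.5)))
}

test_that("restraint tables parse in order with interface flags", {
  topo <- h_topology()
  f <- withr::local_tempfile()
  writeLines(c("# comment",
               "C 70 CD1 B 40 CZ 4.0",
               "C 70 CB  A 5  CB 5.5",
               "A 5  OG  B 40 CZ 3.5",
               "C 70 CA  B 40 OH 4.5",
               "C 70 N   A 5  CB 6.0"), f)
  set <- parseRestraints(f, topo)
  r <- restraints(set)
  expect_equal(nrow(r), 5L)
  expect_equal(r$atom_a, c("CD1", "CB", "OG", "CA", "N"))
  expect_equal(r$interface, c(TRUE, TRUE, FALSE, TRUE, TRUE))
  f2 <- withr::local_tempfile()
  writeLines("C 70 XX B 40 CZ 4.0", f2)
  expect_error(parseRestraints(f2, topo), "absent from the topology")
  f3 <- withr::local_tempfile()
  writeLines("C 70 CD1 B 40 CZ", f3)
  expect_error(parseRestraints(f3, topo), "expected 7 fields")
})

test_that("X-PLOR assign statements import with d + dplus upper bounds", {
  topo <- h_topology()
  f <- withr::local_tempfile()
  writeLines(c(
    "assign (segid C and resid 70 and name HD11)",
    "       (segid B and resid 40 and name CZ)  3.0 1.2 1.0",
    "assign (segid A and resid 5 and name OG)(segid C and resid 70 and name CB) 4.0 2.0 0.5"),
    f)
  set <- parseXplorRestraints(f, topo)
  r <- restraints(set)
  expect_equal(r$upper, c(4.0, 4.5))
  expect_equal(r$interface, c(TRUE, TRUE))
})

test_that("aliphatic protons remap to bonded carbons with +1 A per endpoint", {
  topo <- h_topology()
  mk <- function(aa, ra, na, ab, rb, nb, up) {
    f <- tempfile()
    writeLines(paste(aa, ra, na, ab, rb, nb, up), f)
    parseRestraints(f, topo)
  }
  ## methyl proton -> CD1, bound 4.0 -> 5.0
  r1 <- restraints(remapAliphatic(mk("C", 70, "HD11", "B", 40, "CZ", 4.0),
                                  topo))
  expect_equal(r1$atom_a, "CD1")
  expect_equal(r1$upper, 5.0)
  expect_true(r1$remapped_a); expect_false(r1$remapped_b)
  ## both endpoints aliphatic -> +2 A total
  r2 <- restraints(remapAliphatic(mk("C", 70, "HD11", "B", 40, "HG11", 4.0),
                                  topo))
  expect_equal(c(r2$atom_a, r2$atom_b), c("CD1", "CG1"))
  expect_equal(r2$upper, 6.0)
  ## backbone amide and hydroxyl protons are polar: untouched
  r3 <- restraints(remapAliphatic(mk("C", 70, "H", "B", 40, "CZ", 3.5), topo))
  expect_equal(r3$atom_a, "H")
  expect_equal(r3$upper, 3.5)
  r4 <- restraints(remapAliphatic(mk("A", 5, "HG", "B", 40, "CZ", 3.5), topo))
  expect_equal(r4$atom_a, "HG")
  ## methyl ambiguity: HD11 and HD12 collapse to one CD1 restraint with
  ## the loosest bound
  f <- withr::local_tempfile()
  writeLines(c("C 70 HD11 B 40 CZ 4.0", "C 70 HD12 B 40 CZ 4.6"), f)
  r5 <- restraints(remapAliphatic(parseRestraints(f, topo), topo))
  expect_equal(nrow(r5), 1L)
  expect_equal(r5$upper, 5.6)
})

test_that("padding is uniform, flagged and additive", {
  topo <- h_topology()
  f <- withr::local_tempfile()
  writeLines(c("C 70 CD1 B 40 CZ 4.0", "C 70 CB A 5 CB 5.5"), f)
  set <- parseRestraints(f, topo)
  p <- padRestraints(set, 1.0)
  expect_equal(restraints(p)$upper, c(5.0, 6.5))
  expect_true(all(restraints(p)$padded))
  expect_equal(restraints(padRestraints(set, 0))$upper,
               restraints(set)$upper)
  expect_equal(restraints(padRestraints(padRestraints(set, 0.4), 0.6))$upper,
               restraints(padRestraints(set, 1.0))$upper)
  ## composed with remapping: single aliphatic endpoint 4.0 -> 6.0 total
  f2 <- withr::local_tempfile()
  writeLines("C 70 HD11 B 40 CZ 4.0", f2)
  both <- padRestraints(remapAliphatic(parseRestraints(f2, topo), topo), 1.0)
  expect_equal(restraints(both)$upper, 6.0)
})

test_that("violations are one-sided distances above the bound", {
  mkpair <- function(d, upper) {
    s <- tiny_structure(rbind(c(0, 0, 0), c(d, 0, 0)), chain = c("C", "A"))
    f <- tempfile()
    writeLines(sprintf("C 1 C1 A 2 C2 %f", upper), f)
    list(s = s, set = parseRestraints(f, s))
  }
  x <- mkpair(5.0, 6.0)
  expect_equal(structureViolation(x$s, x$set), 0)
  x <- mkpair(7.25, 6.0)
  expect_equal(structureViolation(x$s, x$set), 1.25)
  x <- mkpair(6.0, 6.0)
  expect_equal(structureViolation(x$s, x$set), 0)
})

test_that("r^-6 averaging reproduces closed forms and its bounds", {
  expect_equal(r6AverageDistance(4), 4)
  expect_equal(r6AverageDistance(c(4, 8)), ((4^-6 + 8^-6) / 2)^(-1 / 6),
               tolerance = 1e-12)
  expect_equal(r6AverageDistance(rep(3.3, 7)), 3.3)
  expect_error(r6AverageDistance(c(4, 0)), "positive")
  set.seed(11)
  for (k in 1:200) {
    r <- runif(sample(2:20, 1), 1, 12)
    eff <- r6AverageDistance(r)
    expect_lte(eff, mean(r) + 1e-12)
    expect_gte(eff, min(r) - 1e-12)
    expect_lte(eff, max(r) + 1e-12)
  }
})

restraint_set_empty <- function() {
  fx <- toy_fixture()
  r <- restraints(fx$restraints)[0L, ]
  methods::new("RestraintSet", restraints = r, provenance = "empty")
}

test_that("ensemble effective distances and mean violations behave", {
  ## two members with pair distances 4 and 8
  mk <- function(d) tiny_structure(rbind(c(0, 0, 0), c(d, 0, 0)),
                                   chain = c("C", "A"))
  f <- withr::local_tempfile()
  writeLines("C 1 C1 A 2 C2 4.0", f)
  set <- parseRestraints(f, mk(4))
  ens <- ensemble(list(mk(4), mk(8)))
  expect_equal(ensembleEffectiveDistance(ens, set),
               ((4^-6 + 8^-6) / 2)^(-1 / 6), tolerance = 1e-9)
  ## coincident atoms are a singularity
  expect_error(ensembleEffectiveDistance(ensemble(list(mk(0.0))), set),
               class = "error")
  ## reference toy with its own restraints: zero violation
  fx <- toy_fixture()
  ens1 <- ensemble(list(fx$structure))
  expect_equal(meanEnsembleViolation(ens1, fx$restraints), 0)
  expect_equal(meanEnsembleViolation(ens1, fx$restraints, "interface"), 0)
  ## arithmetic mean over restraints: violations 0.2 and 0.0 average 0.1
  s2 <- tiny_structure(rbind(c(0, 0, 0), c(4.2, 0, 0), c(0, 3, 0),
                             c(3.5, 3, 0)), chain = c("C", "A", "C", "A"))
  f2 <- withr::local_tempfile()
  writeLines(c("C 1 C1 A 2 C2 4.0", "C 3 C3 A 4 C4 4.0"), f2)
  set2 <- parseRestraints(f2, s2)
  expect_equal(meanEnsembleViolation(ensemble(list(s2)), set2), 0.1,
               tolerance = 1e-9)
  ## padding can only lower the ensemble violation
  fx_dec <- makeDecoyEnsemble(toy_fixture()$structure,
                              decoySpec(sigmas = 1.2, membersPerLevel = 6,
                                        seed = 3))
  v_raw <- meanEnsembleViolation(fx_dec, fx$restraints)
  v_pad <- meanEnsembleViolation(fx_dec, padRestraints(fx$restraints, 1))
  expect_lte(v_pad, v_raw)
  ## decoy ensembles violate more at larger perturbation; the r^-6
  ## average forgives mild perturbations entirely (the shortest distances
  ## dominate), so the strict ordering is tested across well-separated
  ## noise levels
  for (sd in 1:5) {
    d1 <- makeDecoyEnsemble(fx$structure,
                            decoySpec(sigmas = 0.5, membersPerLevel = 8,
                                      seed = sd))
    d2 <- makeDecoyEnsemble(fx$structure,
                            decoySpec(sigmas = 3.0, membersPerLevel = 8,
                                      seed = sd))
    expect_lt(meanEnsembleViolation(d1, fx$restraints),
              meanEnsembleViolation(d2, fx$restraints))
  }
  expect_error(meanEnsembleViolation(ens1, restraint_set_empty()),
               class = "error")
})

test_that("two-well restraint energy has a flat well and linear outer ramp", {
  mkpair <- function(d, upper = 6) {
    s <- tiny_structure(rbind(c(0, 0, 0), c(d, 0, 0)), chain = c("C", "A"))
    f <- tempfile()
    writeLines(sprintf("C 1 C1 A 2 C2 %f", upper), f)
    list(s = s, set = parseRestraints(f, s))
  }
  pot <- twoWellPotential(outerStep = 1)
  x <- mkpair(5.0)
  expect_equal(restraintEnergy(x$s, x$set, pot), 0)
  x <- mkpair(7.0)  # upper + 1 with unit outer step -> 2
  expect_equal(restraintEnergy(x$s, x$set, pot), 2.0)
  x <- mkpair(1.0)  # inside the hard inner edge
  expect_equal(restraintEnergy(x$s, x$set, pot), pot@innerStep)
  ## monotone beyond the bound
  es <- vapply(seq(6.0, 12, by = 0.25),
               function(d) restraintEnergy(mkpair(d)$s, mkpair(d)$set, pot),
               numeric(1))
  expect_true(all(diff(es) >= 0))
  ## zero energy iff zero violation and no penetration
  fx <- toy_fixture()
  expect_equal(restraintEnergy(fx$structure, fx$restraints, pot), 0)
  expect_equal(sum(structureViolation(fx$structure, fx$restraints)), 0)
})

test_that("harmonic tethers score squared displacement with k per Angstrom^2", {
  s <- tiny_structure(rbind(c(0, 0, 0), c(5, 0, 0)), chain = c("A", "A"))
  th <- harmonicTether(s, atomSelector(chains = "A"), k = 0.4)
  expect_equal(tetherEnergy(s, th), 0)
  s1 <- s; coords(s1) <- coords(s) + rbind(c(1, 0, 0), c(0, 0, 0))
  expect_equal(tetherEnergy(s1, th), 0.4)
  s2 <- s; coords(s2) <- coords(s) + rbind(c(2, 0, 0), c(0, 0, 0))
  expect_equal(tetherEnergy(s2, th), 4 * tetherEnergy(s1, th))
})
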