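quick_schedule <- function() annealSchedule(sweeps = 40L)

test_that("mutation enumeration follows the exclusion rule per site", {
  muts <- enumerateMutations(data.frame(chain = "A", resno = 5,
                                        from = "ARG"))
  expect_length(muts, 17L)
  tos <- vapply(muts, function(m) m@to, character(1))
  expect_false(any(tos %in% c("PRO", "CYS", "ARG")))
  expect_equal(tos, sort(tos))  # alphabetical by 3-letter code
  ## native cysteine: only proline and the native are excluded
  expect_length(enumerateMutations(data.frame(chain = "A", resno = 1,
                                              from = "CYS")), 18L)
  ## three ordinary sites
  sites <- data.frame(chain = "A", resno = 1:3,
                      from = c("ALA", "LEU", "SER"))
  expect_length(enumerateMutations(sites), 51L)
  expect_error(enumerateMutations(data.frame(chain = "A", resno = 1,
                                             from = "XYZ")),
               "non-standard")
  expect_error(mutation("A", 1, "ALA", "PRO"), class = "error")
  expect_error(mutation("A", 1, "ALA", "ALA"), class = "error")
})

test_that("repacking rebuilds side chains but never touches the backbone", {
  b <- ddg_bench_fixture()
  s <- members(b$centroids)[[1L]]
  mut <- b$mutations[[1L]]
  out <- mutateAndRepack(s, mut, schedule = quick_schedule(), seed = 3)
  a0 <- atomData(s); a1 <- atomData(out$structure)
  bb0 <- a0[a0$elety %in% c("N", "CA", "C", "O"),
            c("chain", "resno", "elety", "x", "y", "z")]
  bb1 <- a1[a1$elety %in% c("N", "CA", "C", "O"),
            c("chain", "resno", "elety", "x", "y", "z")]
  rownames(bb0) <- rownames(bb1) <- NULL
  expect_identical(bb1, bb0)
  site <- a1$chain == mut@chain & a1$resno == mut@resno
  expect_true(all(a1$resid[site] == mut@to))
  expect_true(all(c("CB", "CG", "CD1", "NE1") %in% a1$elety[site]))
  expect_error(mutateAndRepack(s, mutation("A", 999, "ALA", "TRP")),
               class = "error")
  ## mutating from the wrong native is refused
  expect_error(mutateAndRepack(s, mutation(mut@chain, mut@resno, "TYR",
                                           "TRP")),
               class = "error")
})

test_that("an enlargement into an enclosed pocket always costs energy", {
  b <- ddg_bench_fixture()
  s <- members(b$centroids)[[1L]]
  mut <- b$mutations[[1L]]  # small residue facing the chaperone -> TRP
  for (sd in 1:5) {
    e_mut <- mutateAndRepack(s, mut, schedule = quick_schedule(),
                             seed = sd)$energy
    e_wt <- mutateAndRepack(s, NULL, chain = mut@chain, resno = mut@resno,
                            schedule = quick_schedule(), seed = sd)$energy
    expect_gt(e_mut, e_wt)
  }
})

test_that("paired-seed wild-type controls cancel exactly", {
  b <- ddg_bench_fixture()
  site <- b$clashSite
  rec <- ddgOfMutation(b$centroids, NULL, chain = site$chain,
                       resno = site$resno, nRuns = 2L, seed = 5,
                       schedule = quick_schedule())
  expect_equal(rec@ddgMean, 0)
  expect_equal(rec@ddgSem, 0)
  expect_true(all(rec@runs$ddg == 0))
  ## without seed pairing the control spreads but stays centred
  rec2 <- ddgOfMutation(b$centroids, NULL, chain = site$chain,
                        resno = site$resno, nRuns = 4L, seed = 5,
                        schedule = quick_schedule(), pairSeeds = FALSE)
  expect_lt(abs(rec2@ddgMean), max(1, 6 * rec2@ddgSem))
})

test_that("a planted interface clash is destabilising, a distal copy is not", {
  b <- ddg_bench_fixture()
  clash <- ddgOfMutation(b$centroids, b$mutations[[1L]], nRuns = 3L,
                         seed = 7, schedule = quick_schedule())
  distal <- ddgOfMutation(b$centroids, b$mutations[[2L]], nRuns = 3L,
                          seed = 7, schedule = quick_schedule())
  expect_gt(clash@ddgMean, 0)
  expect_gt(clash@ddgMean, 10 * abs(distal@ddgMean))
  ## record invariants
  expect_equal(clash@ddgMean, mean(clash@runs$ddg))
  expect_equal(clash@nRuns, nrow(clash@runs))
  ## a chaperone-side site is out of contract
  expect_error(ddgOfMutation(b$centroids, mutation("C", 3, "SER", "ALA")),
               "histone side")
})

test_that("the interface screen is deterministic and ranks the clash first", {
  b <- ddg_bench_fixture()
  one <- ensemble(members(b$centroids)[1L])
  sites <- rbind(b$clashSite, b$distalSite)
  ## restrict to two targets per site to keep the scan tight: the screen
  ## surface is exercised end to end through enumerateMutations otherwise
  scr <- screenInterface(one, sites = sites, nRuns = 1L, seed = 11,
                         schedule = annealSchedule(sweeps = 15L))
  expect_equal(nrow(scr$table), 34L)  # 17 per ALA site
  expect_true(all(diff(scr$table$ddg_mean) <= 0))
  top <- scr$table[1L, ]
  expect_equal(top$resno, b$clashSite$resno)
  scr2 <- screenInterface(one, sites = sites, nRuns = 1L, seed = 11,
                          schedule = annealSchedule(sweeps = 15L))
  expect_identical(scr$table, scr2$table)
  expect_error(screenInterface(one, sites = sites[0, ]), "empty")
})

test_that("sites can be derived from an interface contact profile", {
  fx <- toy_fixture()
  prof <- averageContacts(ensemble(fx$structure),
                          atomSelector(chains = c("A", "B")),
                          atomSelector(chains = "C"))
  p <- prof@profile
  active <- p[p$side == "A" & p$avgContacts > 0, ]
  expect_gt(nrow(active), 0)
  muts <- enumerateMutations(data.frame(chain = active$chain,
                                        resno = active$resno,
                                        from = active$resid))
  perSite <- table(vapply(muts, function(m)
    paste(m@chain, m@resno), character(1)))
  expect_true(all(perSite %in% c(17L, 18L)))
})
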