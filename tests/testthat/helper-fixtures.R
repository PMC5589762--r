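## Shared fixtures and independent oracles. The toy complex is cached per
## session because several test files reuse it unchanged.

.fixture_env <- new.env()

toy_fixture <- function() {
  if (is.null(.fixture_env$toy)) {
    s <- makeToyComplex()
    .fixture_env$toy <- list(structure = s,
                             restraints = deriveTrueRestraints(s))
  }
  .fixture_env$toy
}

ddg_bench_fixture <- function() {
  if (is.null(.fixture_env$bench))
    .fixture_env$bench <- makeDdgBenchmark(seed = 1)
  .fixture_env$bench
}

## minimal hand-built structure: n atoms at given coordinates, one
## residue per atom unless resno given
tiny_structure <- function(xyz, chain = "A", elesy = "C",
                           resno = seq_len(nrow(xyz)), elety = NULL) {
  n <- nrow(xyz)
  if (length(chain) == 1L) chain <- rep(chain, n)
  if (length(elesy) == 1L) elesy <- rep(elesy, n)
  if (is.null(elety)) elety <- paste0(elesy, seq_len(n))
  structure_(data.frame(chain = chain, resno = resno, resid = "UNK",
                        elety = elety, elesy = elesy,
                        x = xyz[, 1], y = xyz[, 2], z = xyz[, 3], b = 0,
                        stringsAsFactors = FALSE))
}

## independent rigid-fit oracle (Kabsch via SVD, written without the
## package's superposition path)
kabsch_rmsd <- function(mobile, fixed) {
  cm <- colMeans(mobile); cf <- colMeans(fixed)
  A <- sweep(mobile, 2, cm); B <- sweep(fixed, 2, cf)
  s <- svd(t(A) %*% B)
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  fitted <- A %*% t(R)
  sqrt(mean(rowSums((fitted - B)^2)))
}

## brute-force all-pairs contact count, plain double loop
brute_contacts <- function(xyzA, xyzB, cutoff) {
  total <- 0L
  perA <- integer(nrow(xyzA)); perB <- integer(nrow(xyzB))
  for (i in seq_len(nrow(xyzA))) for (j in seq_len(nrow(xyzB))) {
    d <- sqrt(sum((xyzA[i, ] - xyzB[j, ])^2))
    if (d <= cutoff) {
      total <- total + 1L
      perA[i] <- perA[i] + 1L
      perB[j] <- perB[j] + 1L
    }
  }
  list(total = total, perA = perA, perB = perB)
}

## closed-form total SASA of two intersecting spheres with expanded radii
## R1, R2 at centre distance d (cap areas removed analytically)
two_sphere_area <- function(R1, R2, d) {
  if (d >= R1 + R2) return(4 * pi * (R1^2 + R2^2))
  h1 <- (R2^2 - (d - R1)^2) / (2 * d)
  h2 <- (R1^2 - (d - R2)^2) / (2 * d)
  4 * pi * (R1^2 + R2^2) - 2 * pi * (R1 * h1 + R2 * h2)
}
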