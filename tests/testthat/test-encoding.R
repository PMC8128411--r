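test_that("allele frequencies are per-marker call proportions", {
  g <- line_genotypes(matrix(c(1, 1, 1, 1, 1, 0, 0, 0), 4, 2,
                             dimnames = list(paste0("L", 1:4), c("m1", "m2"))),
                      "g")
  p <- compute_allele_freqs(g)
  expect_equal(as.numeric(p), c(1, 0.25))

  set.seed(7)
  big <- toy_panel(200, 50, "g")
  counted <- apply(big$calls, 2, function(x) sum(x == 1) / length(x))
  expect_equal(as.numeric(compute_allele_freqs(big)), as.numeric(counted))

  empty <- line_genotypes(matrix(numeric(), 0, 2,
                                 dimnames = list(character(0),
                                                 c("m1", "m2"))), "g")
  expect_error(compute_allele_freqs(empty), "empty group")
})

test_that("centered coding has exact zero column sums and two-valued columns", {
  set.seed(8)
  g <- toy_panel(40, 25, "g")
  p <- compute_allele_freqs(g)
  Z <- center_line_genotypes(g, p)
  expect_lt(max(abs(colSums(Z))), 1e-12)
  for (j in sample(ncol(Z), 5)) {
    expect_true(all(Z[, j] %in% c(1 - p[j], -p[j])))
  }
  # p = 0 leaves the column unchanged
  g0 <- line_genotypes(matrix(0, 3, 1, dimnames = list(paste0("L", 1:3), "m1")),
                       "g")
  expect_equal(unname(center_line_genotypes(g0, 0)[, 1]), c(0, 0, 0))
  expect_error(center_line_genotypes(g, p[-1]), "length")
})

test_that("parent incidence maps one line per hybrid and counts repeats", {
  ped <- hybrid_pedigree(c("H1", "H2", "H3"), c("D1", "D1", "D2"),
                         c("F1", "F2", "F1"))
  T1 <- build_parent_incidence(ped, c("D1", "D2"), 1)
  expect_equal(unname(rowSums(T1)), c(1, 1, 1))
  expect_equal(unname(T1[, "D1"]), c(1, 1, 0))
  # T'T diagonal counts hybrids per line (independent tabulation)
  counts <- table(factor(ped$parent1, levels = c("D1", "D2")))
  expect_equal(unname(diag(crossprod(T1))), as.numeric(counts))
  expect_error(build_parent_incidence(ped, "D1", 1), "unknown group-1 parent")
})

test_that("dominance incidence matches the printed genotype-class table", {
  # M1=1, M2=0 at p1=p2=0.5: w = 2*q1*p2 = 0.5
  mk <- function(call, id, group) {
    line_genotypes(matrix(call, 1, 1, dimnames = list(id, "m1")), group)
  }
  Z1 <- center_line_genotypes(mk(1, "D1", "g1"), 0.5)
  Z2 <- center_line_genotypes(mk(0, "F1", "g2"), 0.5)
  ped <- hybrid_pedigree("H1", "D1", "F1")
  expect_equal(unname(build_dominance_incidence(Z1, Z2, ped)[1, 1]), 0.5)

  # M1=1, M2=1 at p1=0.3, p2=0.6: w = -2*q1*q2 = -0.56
  Z1 <- center_line_genotypes(mk(1, "D1", "g1"), 0.3)
  Z2 <- center_line_genotypes(mk(1, "F1", "g2"), 0.6)
  expect_equal(unname(build_dominance_incidence(Z1, Z2, ped)[1, 1]), -0.56)

  # monomorphic group-1 marker gives an all-zero column
  st <- toy_study(seed = 12)
  calls <- st$g1$calls; calls[, 3] <- 1
  g1 <- line_genotypes(calls, "dent")
  W <- build_dominance_incidence(center_line_genotypes(g1),
                                 center_line_genotypes(st$g2), st$ped)
  expect_true(all(W[, 3] == 0))

  # permuting hybrids permutes rows identically
  perm <- sample(nrow(st$ped))
  ped2 <- hybrid_pedigree(st$ped$hybrid[perm], st$ped$parent1[perm],
                          st$ped$parent2[perm])
  W0 <- build_dominance_incidence(center_line_genotypes(st$g1),
                                  center_line_genotypes(st$g2), st$ped)
  W2 <- build_dominance_incidence(center_line_genotypes(st$g1),
                                  center_line_genotypes(st$g2), ped2)
  expect_equal(unname(W2), unname(W0[perm, ]))
})

test_that("hybrid genotypes are parental sums with partitioned class freqs", {
  st <- toy_study(seed = 3)
  hg <- derive_hybrid_genotypes(st$g1, st$g2, st$ped)
  i <- 5
  expect_equal(unname(hg$counts[i, ]),
               unname(st$g1$calls[st$ped$parent1[i], ] +
                      st$g2$calls[st$ped$parent2[i], ]))
  expect_equal(unname(hg$pBB + hg$pBb + hg$pbb), rep(1, ncol(hg$counts)))
  expect_true(all(hg$counts %in% 0:2))
})

test_that("NOIA codings follow the three-branch formulas and HWE reduction", {
  # complete factorial with equal group frequencies puts hybrids in exact HWE
  set.seed(21)
  calls1 <- matrix(0, 5, 3, dimnames = list(paste0("D", 1:5),
                                            paste0("m", 1:3)))
  calls1[1:2, ] <- 1                       # p1 = 0.4 at every marker
  calls2 <- matrix(0, 5, 3, dimnames = list(paste0("F", 1:5),
                                            paste0("m", 1:3)))
  calls2[1:2, ] <- 1                       # p2 = 0.4
  g1 <- line_genotypes(calls1, "g1"); g2 <- line_genotypes(calls2, "g2")
  ped <- complete_factorial(g1, g2)
  hg <- derive_hybrid_genotypes(g1, g2, ped)
  nc <- noia_codings(hg)
  p <- 0.4; q <- 0.6
  # Ha is the centered allele count
  expect_equal(unname(nc$Ha), unname(hg$counts) - 2 * p)
  # Hd reduces to the classical HWE dominance coding
  expected <- matrix(0, nrow(hg$counts), ncol(hg$counts))
  expected[hg$counts == 2] <- -2 * q^2
  expected[hg$counts == 1] <- 2 * p * q
  expected[hg$counts == 0] <- -2 * p^2
  expect_equal(unname(nc$Hd), expected)

  # all-heterozygous marker: degenerate class structure, zero Hd column
  calls1[, 2] <- 1; calls2[, 2] <- 0
  hg2 <- derive_hybrid_genotypes(line_genotypes(calls1, "g1"),
                                 line_genotypes(calls2, "g2"), ped)
  nc2 <- noia_codings(hg2)
  expect_true(all(nc2$Hd[, 2] == 0))
  # symmetric case: Ha of a heterozygote at pk = 0.5 is 0
  expect_true(all(nc2$Ha[, 2] == 0))
})

test_that("single-locus incidence codes are orthogonal in the ideal population", {
  set.seed(31)
  for (rep in 1:25) {
    L <- random_locus()
    cl <- hybridGP:::locus_classes(L)
    w <- -2 * cl$z1 * cl$z2
    wm <- function(x) sum(cl$freq * x)
    expect_lt(abs(wm(cl$z1)), 1e-14)
    expect_lt(abs(wm(cl$z2)), 1e-14)
    expect_lt(abs(wm(w)), 1e-14)
    expect_lt(abs(wm(cl$z1 * cl$z2)), 1e-14)
    expect_lt(abs(wm(cl$z1 * w)), 1e-14)
    expect_lt(abs(wm(cl$z2 * w)), 1e-14)
  }
})
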