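test_that("additive kinship matches the hand-evaluated two-line example", {
  g <- line_genotypes(matrix(c(1, 0), 2, 1,
                             dimnames = list(c("L1", "L2"), "m1")), "g")
  GA <- additive_kinship(center_line_genotypes(g))
  expect_equal(km(GA), matrix(c(1, -1, -1, 1), 2))
  expect_equal(attr(GA, "scale_constant"), 0.25)
})

test_that("additive kinship with observed freqs has mean diag 1, mean 0", {
  set.seed(15)
  g <- toy_panel(30, 120, "g")
  GA <- additive_kinship(center_line_genotypes(g))
  expect_equal(mean(diag(GA)), 1, tolerance = 1e-12)
  expect_lt(abs(mean(GA)), 1e-12)
  s <- kinship_summary(GA)
  expect_equal(s$mean_diag, 1, tolerance = 1e-12)
  expect_gt(s$min_eigenvalue, -1e-8 * s$max_eigenvalue)

  gfix <- line_genotypes(matrix(1, 3, 2, dimnames = list(paste0("L", 1:3),
                                                         c("m1", "m2"))), "g")
  expect_error(additive_kinship(center_line_genotypes(gfix)), "fixed")
})

test_that("VanRaden method-1 on 0/2 coding equals exactly twice GA", {
  g <- line_genotypes(matrix(c(1, 0), 2, 1,
                             dimnames = list(c("L1", "L2"), "m1")), "g")
  expect_equal(km(vanraden1_kinship(g)),
               matrix(c(2, -2, -2, 2), 2))

  set.seed(16)
  big <- toy_panel(30, 200, "g")
  GA <- additive_kinship(center_line_genotypes(big))
  GVR <- vanraden1_kinship(big)
  expect_lt(max(abs(unclass(GVR) - 2 * unclass(GA))), 1e-12)
  # the coancestry scaling GVR1/2 recovers GA exactly
  expect_equal(km(GVR) / 2, km(GA), tolerance = 1e-14)
})

test_that("dominance kinship reproduces the 2x2 factorial example", {
  g1 <- line_genotypes(matrix(c(1, 0), 2, 1,
                              dimnames = list(c("D1", "D2"), "m1")), "g1")
  g2 <- line_genotypes(matrix(c(1, 0), 2, 1,
                              dimnames = list(c("F1", "F2"), "m1")), "g2")
  ped <- complete_factorial(g1, g2)
  W <- build_dominance_incidence(center_line_genotypes(g1),
                                 center_line_genotypes(g2), ped)
  D <- dominance_kinship(W, 0.5, 0.5)
  sgn <- c(1, -1, -1, 1)  # hybrids ordered D1F1, D2F1, D1F2, D2F2
  expect_equal(unname(W[, 1]), -0.5 * sgn)
  expect_equal(km(D), outer(sgn, sgn))
  expect_equal(attr(D, "scale_constant"), 0.25)

  # complete factorial: mean diagonal exactly 1
  st <- toy_study(n1 = 8, n2 = 6, m = 60, seed = 17)
  W2 <- build_dominance_incidence(center_line_genotypes(st$g1),
                                  center_line_genotypes(st$g2), st$ped)
  D2 <- dominance_kinship(W2, compute_allele_freqs(st$g1),
                          compute_allele_freqs(st$g2))
  expect_equal(mean(diag(D2)), 1, tolerance = 1e-12)
  s <- kinship_summary(D2)
  expect_gt(s$min_eigenvalue, -1e-8 * s$max_eigenvalue)
})

test_that("within-group epistatic matrix obeys the Hadamard identity", {
  GA <- kinship_matrix(matrix(c(1, -1, -1, 1), 2), "GA1", "lines1", 1)
  GAA <- epistatic_within(GA)
  expect_equal(km(GAA), matrix(1, 2, 2))

  # explicit Kronecker pair coding vs Hadamard square, <=5 lines x 4 markers
  set.seed(18)
  g <- toy_panel(5, 4, "g")
  Z <- center_line_genotypes(g)
  Z11 <- t(apply(Z, 1, function(z) kronecker(z, z)))
  expect_lt(max(abs(tcrossprod(Z11) - tcrossprod(Z) * tcrossprod(Z))), 1e-12)

  GAbig <- additive_kinship(Z)
  expect_equal(mean(diag(epistatic_within(GAbig))), 1, tolerance = 1e-14)
})

test_that("across-group epistatic matrix equals the per-pair parental product", {
  st <- toy_study(n1 = 5, n2 = 4, m = 40, seed = 19)
  set.seed(20)
  keep <- sample(nrow(st$ped), 10)
  ped <- hybrid_pedigree(st$ped$hybrid[keep], st$ped$parent1[keep],
                         st$ped$parent2[keep])
  GA1 <- additive_kinship(center_line_genotypes(st$g1), name = "GA1")
  GA2 <- additive_kinship(center_line_genotypes(st$g2), name = "GA2",
                          level = "lines2")
  T1 <- build_parent_incidence(ped, rownames(st$g1$calls), 1)
  T2 <- build_parent_incidence(ped, rownames(st$g2$calls), 2)
  GAA12 <- epistatic_across(GA1, GA2, T1, T2)
  # loop oracle on the unscaled entries
  raw <- matrix(NA_real_, 10, 10)
  for (i in 1:10) for (j in 1:10)
    raw[i, j] <- GA1[ped$parent1[i], ped$parent1[j]] *
      GA2[ped$parent2[i], ped$parent2[j]]
  expect_equal(km(GAA12), raw / (sum(diag(raw)) / 10),
               tolerance = 1e-14)
  expect_equal(mean(diag(GAA12)), 1, tolerance = 1e-12)
  # hybrids sharing both parents: unscaled entry is the diagonal product
  expect_equal(raw[1, 1], GA1[ped$parent1[1], ped$parent1[1]] *
                 GA2[ped$parent2[1], ped$parent2[1]])
})

test_that("dominance-involving epistatic matrices match loop oracles", {
  st <- toy_study(n1 = 4, n2 = 3, m = 50, seed = 22)
  p1 <- compute_allele_freqs(st$g1); p2 <- compute_allele_freqs(st$g2)
  Z1 <- center_line_genotypes(st$g1); Z2 <- center_line_genotypes(st$g2)
  W <- build_dominance_incidence(Z1, Z2, st$ped)
  D <- dominance_kinship(W, p1, p2)
  GA1 <- additive_kinship(Z1)
  T1 <- build_parent_incidence(st$ped, rownames(st$g1$calls), 1)
  GA1D <- epistatic_with_dominance(D, GA1, T1, "GA1D")
  n <- nrow(st$ped)
  raw <- matrix(NA_real_, n, n)
  for (i in 1:n) for (j in 1:n)
    raw[i, j] <- GA1[st$ped$parent1[i], st$ped$parent1[j]] * D[i, j]
  expect_equal(km(GA1D), raw / (sum(diag(raw)) / n),
               tolerance = 1e-12)
  expect_equal(mean(diag(GA1D)), 1, tolerance = 1e-12)

  # GDD of the all-+-1/-1 2x2-factorial D is the all-ones matrix
  sgn <- c(1, -1, -1, 1)
  D4 <- kinship_matrix(outer(sgn, sgn), "D", "hybrids", 1)
  expect_equal(km(epistatic_with_dominance(D4)),
               matrix(1, 4, 4))
})

test_that("G-model matrices are trace-scaled and DH reduces under HWE", {
  # complete factorial with equal group frequencies -> hybrids in HWE
  calls1 <- matrix(0, 5, 4, dimnames = list(paste0("D", 1:5),
                                            paste0("m", 1:4)))
  calls2 <- matrix(0, 5, 4, dimnames = list(paste0("F", 1:5),
                                            paste0("m", 1:4)))
  set.seed(23)
  for (j in 1:4) { k <- sample(1:4, 1); calls1[seq_len(k), j] <- 1
                   calls2[seq_len(k), j] <- 1 }
  g1 <- line_genotypes(calls1, "g1"); g2 <- line_genotypes(calls2, "g2")
  ped <- complete_factorial(g1, g2)
  hg <- derive_hybrid_genotypes(g1, g2, ped)
  gm <- gmodel_kinships(noia_codings(hg))
  for (K in gm) expect_equal(mean(diag(K)), 1, tolerance = 1e-12)
  # DH proportional to the classical HWE dominance relationship
  p <- hg$pk; q <- 1 - p
  Hd_hwe <- matrix(0, nrow(hg$counts), ncol(hg$counts))
  for (j in seq_along(p)) {
    Hd_hwe[hg$counts[, j] == 2, j] <- -2 * q[j]^2
    Hd_hwe[hg$counts[, j] == 1, j] <- 2 * p[j] * q[j]
    Hd_hwe[hg$counts[, j] == 0, j] <- -2 * p[j]^2
  }
  DH_hwe <- tcrossprod(Hd_hwe)
  ratio <- unclass(gm$DH)[DH_hwe != 0] / DH_hwe[DH_hwe != 0]
  expect_lt(diff(range(ratio)), 1e-10)
  # GAAH is the trace-rescaled elementwise square of GAH
  M <- km(gm$GAH)^2
  expect_equal(km(gm$GAAH), M / (sum(diag(M)) / nrow(M)),
               tolerance = 1e-14)
})

test_that("duplicating every marker leaves all kinship matrices unchanged", {
  st <- toy_study(n1 = 6, n2 = 5, m = 40, seed = 25)
  dup <- function(g) {
    calls <- cbind(g$calls, g$calls)
    colnames(calls) <- c(colnames(g$calls),
                         paste0(colnames(g$calls), "_b"))
    line_genotypes(calls, g$group)
  }
  g1d <- dup(st$g1); g2d <- dup(st$g2)
  GA <- additive_kinship(center_line_genotypes(st$g1))
  GAd <- additive_kinship(center_line_genotypes(g1d))
  expect_equal(km(GAd), km(GA), tolerance = 1e-12,
               ignore_attr = TRUE)
  W <- build_dominance_incidence(center_line_genotypes(st$g1),
                                 center_line_genotypes(st$g2), st$ped)
  Wd <- build_dominance_incidence(center_line_genotypes(g1d),
                                  center_line_genotypes(g2d), st$ped)
  D <- dominance_kinship(W, compute_allele_freqs(st$g1),
                         compute_allele_freqs(st$g2))
  Dd <- dominance_kinship(Wd, compute_allele_freqs(g1d),
                          compute_allele_freqs(g2d))
  expect_equal(km(Dd), km(D), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(km(epistatic_within(GAd)), km(epistatic_within(GA)),
               tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("kinship summary of the identity has mean_all 1/n", {
  s <- kinship_summary(diag(4))
  expect_equal(s$mean_diag, 1)
  expect_equal(s$mean_all, 1 / 4)
})

test_that("D entries regress on GAA12 entries with slope near 1", {
  # complete factorial: GAA12 approximates D (finite-genome estimator)
  slopes <- sapply(1:3, function(s) {
    st <- toy_study(n1 = 10, n2 = 8, m = 500, seed = 300 + s)
    p1 <- compute_allele_freqs(st$g1); p2 <- compute_allele_freqs(st$g2)
    Z1 <- center_line_genotypes(st$g1); Z2 <- center_line_genotypes(st$g2)
    W <- build_dominance_incidence(Z1, Z2, st$ped)
    D <- dominance_kinship(W, p1, p2)
    GA1 <- additive_kinship(Z1, p1, "GA1", "lines1")
    GA2 <- additive_kinship(Z2, p2, "GA2", "lines2")
    T1 <- build_parent_incidence(st$ped, rownames(st$g1$calls), 1)
    T2 <- build_parent_incidence(st$ped, rownames(st$g2$calls), 2)
    GAA12 <- epistatic_across(GA1, GA2, T1, T2)
    lo <- lower.tri(D)
    stats::coef(stats::lm(D[lo] ~ unclass(GAA12)[lo]))[2]
  })
  expect_true(all(slopes > 0.8 & slopes < 1.2))
})
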