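#' Configuration for the synthetic two-group hybrid study generator
#'
#' Defaults emulate the structure of a published Dent x Flint maize
#' study: 123 and 86 inbred lines, an incomplete factorial of 1,254
#' hybrids, and variance components matching that study's estimates under
#' the fullest origin-specific model (additive 19.06/10.61, dominance
#' 2.3, within-group additive-by-additive 5.41/5.57, across-group 3.24,
#' residual genetic 3.8/4.56, residual 13.67, in squared trait units).
#' The default marker panel is 5,000 loci in linkage equilibrium, a
#' desk-scale stand-in for a 35k SNP chip: under LE the relationship
#' matrices and variance bookkeeping are governed by the sums of pq over
#' markers, which the rescaling of drawn effects fixes exactly at any
#' panel size.  Founder frequencies are Beta-distributed per group and
#' truncated away from fixation.
#'
#' @param n1,n2 line counts per group.
#' @param nsnp marker panel size.
#' @param n_hybrids hybrid count for the incomplete design.
#' @param design `"incomplete"` or `"complete"` factorial.
#' @param beta1,beta2 `c(alpha, beta)` of the founder-frequency Beta law
#'   per group (different laws make the groups diverge).
#' @param freq_bounds truncation interval for founder frequencies.
#' @param effect_mode `"statistical"` (draw substitution/dominance/
#'   epistatic deviations directly) or `"functional"` (draw functional
#'   a1, a2, d per locus and derive the statistical effects through the
#'   single-locus theory).
#' @param variances named vector of target variance components among
#'   `A1, A2, D, AA11, AA22, AA12, r1, r2, e`.
#' @param n_pairs epistatic pairs drawn per within/across-group class.
#' @param mu trait intercept (default 100, a realistic grain-yield entry
#'   mean in q/ha).
#' @param seed RNG seed.
#' @return object of class `sim_config`.
#' @export
sim_config <- function(n1 = 123, n2 = 86, nsnp = 5000, n_hybrids = 1254,
                       design = c("incomplete", "complete"),
                       beta1 = c(2, 2), beta2 = c(2, 2),
                       freq_bounds = c(0.05, 0.95),
                       effect_mode = c("statistical", "functional"),
                       variances = c(A1 = 19.06, A2 = 10.61, D = 2.3,
                                     AA11 = 5.41, AA22 = 5.57, AA12 = 3.24,
                                     r1 = 3.8, r2 = 4.56, e = 13.67),
                       n_pairs = 500, mu = 100, seed = NULL) {
  design <- match.arg(design)
  effect_mode <- match.arg(effect_mode)
  if (any(variances < 0)) stop("variance targets must be >= 0")
  structure(list(n1 = n1, n2 = n2, nsnp = nsnp, n_hybrids = n_hybrids,
                 design = design, beta1 = beta1, beta2 = beta2,
                 freq_bounds = freq_bounds, effect_mode = effect_mode,
                 variances = variances, n_pairs = n_pairs, mu = mu,
                 seed = seed),
            class = "sim_config")
}

#' Simulate two diverged panels of inbred lines
#'
#' Per group, marker frequencies are drawn from the group's Beta law
#' (truncated to `freq_bounds`) and line calls are independent
#' Bernoulli(p) homozygote indicators per marker: linkage equilibrium by
#' construction, matching the standing assumption of the relationship
#' theory.
#'
#' @param cfg a [sim_config].
#' @return list with `g1`, `g2` ([line_genotypes]) and the founder
#'   frequencies `p1_founder`, `p2_founder`.
#' @export
simulate_lines <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  draw_group <- function(n, beta_par, prefix) {
    p <- stats::rbeta(cfg$nsnp, beta_par[1L], beta_par[2L])
    p <- pmin(pmax(p, cfg$freq_bounds[1L]), cfg$freq_bounds[2L])
    calls <- matrix(stats::rbinom(n * cfg$nsnp, 1L, rep(p, each = n)),
                    nrow = n, ncol = cfg$nsnp,
                    dimnames = list(paste0(prefix, seq_len(n)),
                                    paste0("m", seq_len(cfg$nsnp))))
    list(p = p, g = line_genotypes(calls, prefix))
  }
  a <- draw_group(cfg$n1, cfg$beta1, "D")
  b <- draw_group(cfg$n2, cfg$beta2, "F")
  list(g1 = a$g, g2 = b$g, p1_founder = a$p, p2_founder = b$p)
}

#' Simulate a factorial hybrid pedigree
#'
#' Complete mode crosses every group-1 line with every group-2 line.
#' Incomplete mode samples `n_hybrids` crosses uniformly without
#' replacement, resampling (up to a cap) until every line appears in at
#' least one hybrid, emulating an incomplete factorial in which all
#' parents are represented.
#'
#' @param cfg a [sim_config].
#' @param g1,g2 the simulated [line_genotypes].
#' @param max_retries resampling cap for the coverage requirement.
#' @return a [hybrid_pedigree].
#' @export
simulate_pedigree <- function(cfg, g1, g2, max_retries = 100) {
  l1 <- rownames(g1$calls); l2 <- rownames(g2$calls)
  all_crosses <- expand.grid(parent1 = l1, parent2 = l2,
                             stringsAsFactors = FALSE)
  if (cfg$design == "complete" || cfg$n_hybrids >= nrow(all_crosses)) {
    if (cfg$design == "incomplete" && cfg$n_hybrids > nrow(all_crosses))
      stop("n_hybrids exceeds the ", nrow(all_crosses),
           " possible crosses")
    sel <- all_crosses
  } else {
    for (try in seq_len(max_retries)) {
      idx <- sample.int(nrow(all_crosses), cfg$n_hybrids)
      sel <- all_crosses[idx, ]
      if (all(l1 %in% sel$parent1) && all(l2 %in% sel$parent2)) break
      if (try == max_retries)
        stop("could not cover every line in ", max_retries,
             " pedigree draws; increase n_hybrids")
    }
  }
  hybrid_pedigree(paste0("H", seq_len(nrow(sel))), sel$parent1, sel$parent2)
}

#' Simulate genetic effects and hybrid phenotypes with known components
#'
#' Builds the origin-specific codings for the simulated study and draws
#' marker effects so that the realized analytic variance of every genetic
#' class equals its target exactly.  In `"statistical"` mode the
#' substitution effects alpha1/alpha2, dominance effects d and epistatic
#' deviations are drawn i.i.d. normal per marker (or marker pair) and
#' each class is rescaled once so that the analytic sums over markers --
#' `sum(p1 q1 alpha1^2)`, `sum(p2 q2 alpha2^2)`,
#' `sum(4 p1 q1 p2 q2 d^2)`, and `sum(pq pq aa^2)` over drawn pairs --
#' hit the targets, with observed within-group frequencies.  In
#' `"functional"` mode, functional effects a1, a2, d are drawn per locus
#' and converted to statistical effects through the single-locus theory
#' before the same rescaling.  Residual genetic line effects and the
#' residual are drawn normal at their target variances (not rescaled).
#'
#' @param cfg a [sim_config].
#' @param g1,g2 simulated [line_genotypes].
#' @param ped a [hybrid_pedigree] over the study hybrids.
#' @return list with `pheno` (hybrid entry-mean table) and `truth`
#'   (realized variance components, drawn effects, per-hybrid genetic
#'   values).
#' @export
simulate_effects_and_phenotypes <- function(cfg, g1, g2, ped) {
  stopifnot(inherits(cfg, "sim_config"))
  v <- cfg$variances
  tgt <- function(nm) if (nm %in% names(v)) v[[nm]] else 0
  p1 <- compute_allele_freqs(g1); q1 <- 1 - p1
  p2 <- compute_allele_freqs(g2); q2 <- 1 - p2
  Z1 <- center_line_genotypes(g1, p1)
  Z2 <- center_line_genotypes(g2, p2)
  i1 <- match(ped$parent1, rownames(g1$calls))
  i2 <- match(ped$parent2, rownames(g2$calls))
  n <- nrow(ped)
  nsnp <- ncol(g1$calls)

  rescale <- function(eff, weights, target, what) {
    realized <- sum(weights * eff^2)
    if (target == 0) return(eff * 0)
    if (realized == 0)
      stop("cannot realize ", what, " variance: all weights are zero")
    eff * sqrt(target / realized)
  }

  if (cfg$effect_mode == "statistical") {
    alpha1 <- stats::rnorm(nsnp)
    alpha2 <- stats::rnorm(nsnp)
    dd <- stats::rnorm(nsnp)
  } else {
    a1 <- stats::rnorm(nsnp); a2 <- stats::rnorm(nsnp)
    dd <- stats::rnorm(nsnp)
    alpha1 <- a1 + (q2 - p2) * dd     # substitution effects from theory
    alpha2 <- a2 + (q1 - p1) * dd
  }
  alpha1 <- rescale(alpha1, p1 * q1, tgt("A1"), "A1")
  alpha2 <- rescale(alpha2, p2 * q2, tgt("A2"), "A2")
  dd <- rescale(dd, 4 * p1 * q1 * p2 * q2, tgt("D"), "D")

  gA1_line <- as.numeric(Z1 %*% alpha1)
  gA2_line <- as.numeric(Z2 %*% alpha2)
  W <- build_dominance_incidence(Z1, Z2, ped)
  gD <- as.numeric(W %*% dd)

  draw_pairs <- function() {
    ks <- sample.int(nsnp, cfg$n_pairs, replace = TRUE)
    ms <- sample.int(nsnp, cfg$n_pairs, replace = TRUE)
    clash <- ks == ms
    while (any(clash)) {
      ms[clash] <- sample.int(nsnp, sum(clash), replace = TRUE)
      clash <- ks == ms
    }
    cbind(ks, ms)
  }
  gAA11_line <- numeric(nrow(g1$calls)); gAA22_line <- numeric(nrow(g2$calls))
  gAA12 <- numeric(n)
  aa11 <- aa22 <- aa12 <- NULL
  pr11 <- pr22 <- pr12 <- NULL
  if (tgt("AA11") > 0) {
    pr11 <- draw_pairs()
    aa11 <- rescale(stats::rnorm(cfg$n_pairs),
                    (p1 * q1)[pr11[, 1L]] * (p1 * q1)[pr11[, 2L]],
                    tgt("AA11"), "AA11")
    gAA11_line <- as.numeric((Z1[, pr11[, 1L], drop = FALSE] *
                              Z1[, pr11[, 2L], drop = FALSE]) %*% aa11)
  }
  if (tgt("AA22") > 0) {
    pr22 <- draw_pairs()
    aa22 <- rescale(stats::rnorm(cfg$n_pairs),
                    (p2 * q2)[pr22[, 1L]] * (p2 * q2)[pr22[, 2L]],
                    tgt("AA22"), "AA22")
    gAA22_line <- as.numeric((Z2[, pr22[, 1L], drop = FALSE] *
                              Z2[, pr22[, 2L], drop = FALSE]) %*% aa22)
  }
  if (tgt("AA12") > 0) {
    pr12 <- draw_pairs()
    aa12 <- rescale(stats::rnorm(cfg$n_pairs),
                    (p1 * q1)[pr12[, 1L]] * (p2 * q2)[pr12[, 2L]],
                    tgt("AA12"), "AA12")
    gAA12 <- as.numeric((Z1[i1, pr12[, 1L], drop = FALSE] *
                         Z2[i2, pr12[, 2L], drop = FALSE]) %*% aa12)
  }
  r1 <- stats::rnorm(nrow(g1$calls), 0, sqrt(tgt("r1")))
  r2 <- stats::rnorm(nrow(g2$calls), 0, sqrt(tgt("r2")))
  e <- stats::rnorm(n, 0, sqrt(tgt("e")))

  genetic <- gA1_line[i1] + gA2_line[i2] + gD +
    gAA11_line[i1] + gAA22_line[i2] + gAA12 + r1[i1] + r2[i2]
  y <- cfg$mu + genetic + e

  realized <- c(A1 = sum(p1 * q1 * alpha1^2),
                A2 = sum(p2 * q2 * alpha2^2),
                D = sum(4 * p1 * q1 * p2 * q2 * dd^2),
                AA11 = if (is.null(aa11)) 0 else
                  sum((p1 * q1)[pr11[, 1L]] * (p1 * q1)[pr11[, 2L]] *
                      aa11^2),
                AA22 = if (is.null(aa22)) 0 else
                  sum((p2 * q2)[pr22[, 1L]] * (p2 * q2)[pr22[, 2L]] *
                      aa22^2),
                AA12 = if (is.null(aa12)) 0 else
                  sum((p1 * q1)[pr12[, 1L]] * (p2 * q2)[pr12[, 2L]] *
                      aa12^2),
                r1 = tgt("r1"), r2 = tgt("r2"), e = tgt("e"))

  list(pheno = data.frame(hybrid = ped$hybrid, value = y,
                          stringsAsFactors = FALSE),
       truth = list(realized = realized, mu = cfg$mu,
                    alpha1 = alpha1, alpha2 = alpha2, d = dd,
                    pairs11 = pr11, pairs22 = pr22, pairs12 = pr12,
                    aa11 = aa11, aa22 = aa22, aa12 = aa12,
                    r1 = r1, r2 = r2,
                    genetic_values = setNames(genetic, ped$hybrid)))
}

#' Simulate a complete synthetic hybrid study
#'
#' Convenience wrapper chaining [simulate_lines()],
#' [simulate_pedigree()] and [simulate_effects_and_phenotypes()].
#'
#' @param cfg a [sim_config].
#' @return list with `g1`, `g2`, `ped`, `pheno`, `truth` and the founder
#'   frequencies.
#' @export
simulate_study <- function(cfg) {
  lines <- simulate_lines(cfg)
  ped <- simulate_pedigree(cfg, lines$g1, lines$g2)
  ep <- simulate_effects_and_phenotypes(cfg, lines$g1, lines$g2, ped)
  c(lines, list(ped = ped), ep)
}
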