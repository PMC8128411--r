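#' Single-locus functional parameters
#'
#' A biallelic locus with origin-specific alleles: B1/b1 segregate in
#' heterotic group 1 at frequency p1, B2/b2 in group 2 at p2.  The
#' genotypic values of the four hybrid classes are `G(B1B2) = a1 + a2`,
#' `G(B1b2) = a1 + d`, `G(b1B2) = a2 + d`, `G(b1b2) = 0`: a1 and a2 are
#' functional additive effects of the group-specific B alleles, d the
#' functional dominance value of both heterozygotes.
#'
#' @param a1,a2 functional additive effects.
#' @param d functional dominance effect.
#' @param p1,p2 B-allele frequencies in groups 1 and 2 (in \[0, 1\];
#'   boundary values give degenerate, zero-variance components).
#' @return object of class `locus_spec`.
#' @export
locus_spec <- function(a1, a2, d, p1, p2) {
  stopifnot(is.finite(a1), is.finite(a2), is.finite(d),
            p1 >= 0, p1 <= 1, p2 >= 0, p2 <= 1)
  structure(list(a1 = a1, a2 = a2, d = d, p1 = p1, p2 = p2),
            class = "locus_spec")
}

# genotypic values and ideal-population class frequencies, in the fixed
# class order B1B2, B1b2, b1B2, b1b2
locus_classes <- function(L) {
  q1 <- 1 - L$p1; q2 <- 1 - L$p2
  list(G = c(L$a1 + L$a2, L$a1 + L$d, L$a2 + L$d, 0),
       freq = c(L$p1 * L$p2, L$p1 * q2, q1 * L$p2, q1 * q2),
       z1 = c(q1, q1, -L$p1, -L$p1),
       z2 = c(q2, -L$p2, q2, -L$p2))
}

#' Orthogonal decomposition of a single hybrid locus
#'
#' Enumerates the four hybrid genotype classes of an ideal (random-mating
#' across groups) hybrid population and decomposes the genotypic value
#' into the population mean, two statistical gamete additive effects and a
#' dominance deviation.  Closed forms:
#' `E(G) = p1 a1 + p2 a2 + (p1 q2 + q1 p2) d`;
#' substitution effects `alpha1 = a1 + (q2 - p2) d`,
#' `alpha2 = a2 + (q1 - p1) d`;
#' gamete values `gA1 in {q1 alpha1, -p1 alpha1}` (B1, b1) and analogously
#' for group 2; dominance deviations
#' `gD = {-2 q1 q2, 2 q1 p2, 2 p1 q2, -2 p1 p2} * d` per class;
#' variances `varA1 = p1 q1 alpha1^2`, `varA2 = p2 q2 alpha2^2`,
#' `varD = 4 p1 q1 p2 q2 d^2`.  The components are orthogonal, so they sum
#' to the total genotypic variance exactly.
#'
#' @param L a [locus_spec].
#' @return list of class `locus_decomposition` with the population mean,
#'   average allele effects, substitution effects, per-class gamete and
#'   dominance values, and the variance partition.
#' @export
decompose_locus <- function(L) {
  stopifnot(inherits(L, "locus_spec"))
  q1 <- 1 - L$p1; q2 <- 1 - L$p2
  cl <- locus_classes(L)
  mean_G <- sum(cl$freq * cl$G)
  alpha1 <- L$a1 + (q2 - L$p2) * L$d
  alpha2 <- L$a2 + (q1 - L$p1) * L$d
  out <- list(
    mean = mean_G,
    alpha_B1 = q1 * alpha1, alpha_b1 = -L$p1 * alpha1,
    alpha_B2 = q2 * alpha2, alpha_b2 = -L$p2 * alpha2,
    alpha1 = alpha1, alpha2 = alpha2,
    gA1 = c(B1 = q1 * alpha1, b1 = -L$p1 * alpha1),
    gA2 = c(B2 = q2 * alpha2, b2 = -L$p2 * alpha2),
    gD = c(B1B2 = -2 * q1 * q2, B1b2 = 2 * q1 * L$p2,
           b1B2 = 2 * L$p1 * q2, b1b2 = -2 * L$p1 * L$p2) * L$d,
    varA1 = L$p1 * q1 * alpha1^2,
    varA2 = L$p2 * q2 * alpha2^2,
    varD = 4 * L$p1 * q1 * L$p2 * q2 * L$d^2,
    varTotal = sum(cl$freq * cl$G^2) - mean_G^2,
    class_freq = cl$freq)
  class(out) <- "locus_decomposition"
  out
}

#' Cross-check the three routes to the substitution effect
#'
#' The substitution effect of group 1 can be obtained (i) from the closed
#' form `a1 + (q2 - p2) d`, (ii) as the frequency-weighted value change of
#' substituting b1 by B1 across the partner gametes,
#' `p2 [(a1+a2) - (a2+d)] + q2 [(a1+d) - 0]`, and (iii) as the difference
#' of average allele effects `alphaB1 - alphab1`.  All three must agree to
#' machine precision (and analogously for group 2).
#'
#' @param L a [locus_spec].
#' @return list with `ok` (logical), the per-route values and the maximum
#'   absolute discrepancy.
#' @export
verify_substitution_definition <- function(L) {
  stopifnot(inherits(L, "locus_spec"))
  q1 <- 1 - L$p1; q2 <- 1 - L$p2
  dec <- decompose_locus(L)
  routes1 <- c(closed = dec$alpha1,
               substitution = L$p2 * ((L$a1 + L$a2) - (L$a2 + L$d)) +
                 q2 * ((L$a1 + L$d) - 0),
               avg_effect_diff = dec$alpha_B1 - dec$alpha_b1)
  routes2 <- c(closed = dec$alpha2,
               substitution = L$p1 * ((L$a1 + L$a2) - (L$a1 + L$d)) +
                 q1 * ((L$a2 + L$d) - 0),
               avg_effect_diff = dec$alpha_B2 - dec$alpha_b2)
  disc <- max(abs(routes1 - routes1[1L]), abs(routes2 - routes2[1L]))
  list(ok = disc < 1e-12, alpha1_routes = routes1, alpha2_routes = routes2,
       max_discrepancy = disc)
}

#' Dominance deviations by subtraction
#'
#' Independent route to the dominance deviations: for each hybrid genotype
#' class, subtract the population mean and both statistical gamete
#' additive effects from the genotypic value,
#' `gD = G - E(G) - gA1 - gA2`.  This must reproduce the closed-form table
#' `{-2 q1 q2, 2 q1 p2, 2 p1 q2, -2 p1 p2} * d` exactly.
#'
#' @param L a [locus_spec].
#' @return named vector of the four class deviations (B1B2, B1b2, b1B2,
#'   b1b2).
#' @export
dominance_deviation_by_subtraction <- function(L) {
  stopifnot(inherits(L, "locus_spec"))
  dec <- decompose_locus(L)
  cl <- locus_classes(L)
  gA1_class <- dec$gA1[c(1, 1, 2, 2)]   # gamete 1 is B1, B1, b1, b1
  gA2_class <- dec$gA2[c(1, 2, 1, 2)]   # gamete 2 is B2, b2, B2, b2
  out <- cl$G - dec$mean - gA1_class - gA2_class
  names(out) <- c("B1B2", "B1b2", "b1B2", "b1b2")
  out
}

#' Exact two-locus enumeration with epistasis
#'
#' Enumerates all 16 two-locus hybrid genotype classes (4 group-1 gametes
#' x 4 group-2 gametes, product frequencies, i.e. linkage equilibrium) for
#' two loci k and m.  The genetic value of a class is the sum of the two
#' single-locus statistical models plus optional second-order epistatic
#' deviations built from Kronecker products of the single-locus codes:
#' within-group-1 `z1(k)*z1(m)*aa11`, within-group-2 `z2(k)*z2(m)*aa22`,
#' and across-group `z1(k)*z2(m)*aa12`.  Closed-form component variances
#' (e.g. `p1k q1k p1m q1m aa11^2` for the within-group-1 term) are
#' returned next to the enumerated ones; orthogonality makes all
#' cross-covariances vanish and the components sum to the enumerated total
#' exactly.
#'
#' @param Lk,Lm [locus_spec] objects for the two loci.
#' @param aa11,aa22,aa12 epistatic interaction deviations (default 0).
#' @return list with per-component variances (enumerated and closed-form),
#'   the total, the maximum absolute cross-covariance between component
#'   codes, and the component means.
#' @export
two_locus_epistatic_enumeration <- function(Lk, Lm, aa11 = 0, aa22 = 0,
                                            aa12 = 0) {
  stopifnot(inherits(Lk, "locus_spec"), inherits(Lm, "locus_spec"))
  ck <- locus_classes(Lk); cm <- locus_classes(Lm)
  dk <- decompose_locus(Lk); dm <- decompose_locus(Lm)
  # index every combination of the 4 classes at k with the 4 at m
  ik <- rep(1:4, each = 4L); im <- rep(1:4, times = 4L)
  freq <- ck$freq[ik] * cm$freq[im]
  comp <- cbind(
    A1 = ck$z1[ik] * dk$alpha1 + cm$z1[im] * dm$alpha1,
    A2 = ck$z2[ik] * dk$alpha2 + cm$z2[im] * dm$alpha2,
    D  = dk$gD[ik] + dm$gD[im],
    AA11 = ck$z1[ik] * cm$z1[im] * aa11,
    AA22 = ck$z2[ik] * cm$z2[im] * aa22,
    AA12 = ck$z1[ik] * cm$z2[im] * aa12)
  wmean <- function(x) sum(freq * x)
  wvar <- function(x) wmean(x^2) - wmean(x)^2
  wcov <- function(x, y) wmean(x * y) - wmean(x) * wmean(y)
  total_value <- rowSums(comp)
  vars <- apply(comp, 2L, wvar)
  pq <- function(p) p * (1 - p)
  closed <- c(
    A1 = dk$varA1 + dm$varA1, A2 = dk$varA2 + dm$varA2,
    D = dk$varD + dm$varD,
    AA11 = pq(Lk$p1) * pq(Lm$p1) * aa11^2,
    AA22 = pq(Lk$p2) * pq(Lm$p2) * aa22^2,
    AA12 = pq(Lk$p1) * pq(Lm$p2) * aa12^2)
  cross <- 0
  for (i in 1:5) for (j in (i + 1):6)
    cross <- max(cross, abs(wcov(comp[, i], comp[, j])))
  list(variances = vars, closed_form = closed,
       total = wvar(total_value), sum_components = sum(vars),
       max_cross_covariance = cross,
       component_means = apply(comp, 2L, wmean))
}

#' Aggregate variance components into GCA/SCA and the genotypic total
#'
#' Ignoring third- and higher-order epistasis, the genotypic variance is
#' the sum of the orthogonal components
#' `A1 + A2 + D + AA11 + AA22 + AA12 (+ A1D + A2D + DD)`.  The breeding
#' aggregates are `GCA1 = A1 + AA11 (+ r1)`, `GCA2 = A2 + AA22 (+ r2)` and
#' `SCA = D + AA12 (+ A1D + A2D + DD)`, where the "residual genetic" line
#' variances r capture unmodelled higher-order within-group epistasis.
#'
#' @param components named numeric vector or list; recognized names are
#'   `A1, A2, D, AA11, AA22, AA12, A1D, A2D, DD, r1, r2`.  Missing
#'   components count as 0.
#' @return list with `total` (genotypic variance, r terms included),
#'   `GCA1`, `GCA2`, `SCA`.
#' @export
genotypic_variance_partition <- function(components) {
  comp <- unlist(components)
  if (any(comp < 0)) stop("negative variance component supplied")
  g <- function(nm) if (nm %in% names(comp)) comp[[nm]] else 0
  gca1 <- g("A1") + g("AA11") + g("r1")
  gca2 <- g("A2") + g("AA22") + g("r2")
  sca  <- g("D") + g("AA12") + g("A1D") + g("A2D") + g("DD")
  list(total = gca1 + gca2 + sca, GCA1 = gca1, GCA2 = gca2, SCA = sca)
}
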