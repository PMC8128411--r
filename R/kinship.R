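#' Construct a kinship_matrix object
#'
#' Thin wrapper storing the matrix together with its name, the level it
#' indexes (`"lines1"`, `"lines2"` or `"hybrids"`) and the scaling constant
#' (denominator) used to build it.
#'
#' @param values symmetric numeric matrix with ids as dimnames.
#' @param name matrix name, e.g. `"GA1"`, `"D"`, `"GAA12"`.
#' @param level one of `"lines1"`, `"lines2"`, `"hybrids"`.
#' @param scale_constant the denominator applied to the cross-product.
#' @return matrix of class `kinship_matrix`.
#' @export
kinship_matrix <- function(values, name, level, scale_constant) {
  if (!all(is.finite(values))) stop("non-finite entries in ", name)
  structure(values, class = c("kinship_matrix", "matrix", "array"),
            kinship_name = name, level = level,
            scale_constant = scale_constant)
}

#' @export
print.kinship_matrix <- function(x, ...) {
  cat("kinship_matrix '", attr(x, "kinship_name"), "' (", nrow(x), " x ",
      ncol(x), ", level ", attr(x, "level"), ", scale constant ",
      format(attr(x, "scale_constant")), ")\n", sep = "")
  invisible(x)
}

#' Additive genomic relationship matrix of a line panel
#'
#' `G = Z Z' / sum(p*q)` over markers, with Z the centered coding of the
#' group.  With observed frequencies the mean diagonal is exactly 1 and
#' the mean over all entries exactly 0, so a variance component attached
#' to G is interpretable as the additive genetic variance of the fully
#' inbred line population's gametes.
#'
#' @param Z centered coding from [center_line_genotypes()].
#' @param p allele frequencies used for the denominator; defaults to the
#'   frequencies stored on `Z`.
#' @param name matrix name (`"GA1"` or `"GA2"`).
#' @param level level label (`"lines1"` or `"lines2"`).
#' @return a [kinship_matrix].
#' @export
additive_kinship <- function(Z, p = attr(Z, "freqs"), name = "GA1",
                             level = "lines1") {
  if (is.null(p)) stop("no allele frequencies supplied or stored on Z")
  denom <- sum(p * (1 - p))
  if (denom <= 0) stop("all markers fixed: sum(p*q) = 0")
  kinship_matrix(tcrossprod(Z) / denom, name, level, denom)
}

#' VanRaden method-1 relationship matrix from 0/2-coded lines
#'
#' Codes the pure lines as 0/2 copies of B, centers by `2p` and divides by
#' `2 * sum(p*q)`.  For fully inbred lines this equals exactly twice the
#' additive matrix of [additive_kinship()]; the factor 2 reflects the
#' choice of an outbred rather than fully inbred reference population for
#' the additive variance.
#'
#' @param g a [line_genotypes] object (0/1 indicator calls).
#' @param p allele frequencies (default observed).
#' @param name,level as in [additive_kinship()].
#' @return a [kinship_matrix] named `"GVR1"` by default.
#' @export
vanraden1_kinship <- function(g, p = compute_allele_freqs(g),
                              name = "GVR1", level = "lines1") {
  denom <- 2 * sum(p * (1 - p))
  if (denom <= 0) stop("all markers fixed: sum(p*q) = 0")
  Zstar <- sweep(2 * g$calls, 2L, 2 * as.numeric(p), "-")
  kinship_matrix(tcrossprod(Zstar) / denom, name, level, denom)
}

#' Dominance relationship matrix across hybrids
#'
#' `D = W W' / sum(4 p1 q1 p2 q2)` over markers, with W the dominance
#' incidence coding.  Under a complete factorial with observed
#' within-group frequencies the mean diagonal is exactly 1.
#'
#' @param W dominance coding from [build_dominance_incidence()].
#' @param p1,p2 within-group allele frequencies.
#' @return a [kinship_matrix] named `"D"` at hybrid level.
#' @export
dominance_kinship <- function(W, p1, p2) {
  denom <- sum(4 * p1 * (1 - p1) * p2 * (1 - p2))
  if (denom <= 0)
    stop("no marker segregates in both groups: dominance denominator is 0")
  kinship_matrix(tcrossprod(W) / denom, "D", "hybrids", denom)
}

scale_trace <- function(M, name, level) {
  n <- nrow(M)
  sc <- sum(diag(M)) / n
  if (sc <= 0) stop("zero trace: cannot scale ", name)
  kinship_matrix(M / sc, name, level, sc)
}

#' Within-group additive-by-additive epistatic relationship matrix
#'
#' The Kronecker pair coding has the Gram-matrix identity
#' `Z11 Z11' = (Z Z') o (Z Z')` (Hadamard square), so the matrix is built
#' as `(GA o GA) / (tr(GA o GA)/n)`, giving a mean diagonal of exactly 1.
#'
#' @param GA additive [kinship_matrix] of the group.
#' @param name `"GAA11"` or `"GAA22"`.
#' @return a [kinship_matrix] at line level.
#' @export
epistatic_within <- function(GA, name = "GAA11") {
  M <- unclass(GA) * unclass(GA)
  scale_trace(M, name, attr(GA, "level"))
}

#' Across-group additive-by-additive epistatic relationship matrix
#'
#' Entry (i, j) is the product of the two parental additive relationships,
#' `GA1[parent1_i, parent1_j] * GA2[parent2_i, parent2_j]`, i.e.
#' `(T1 GA1 T1') o (T2 GA2 T2')`, scaled to an average diagonal of 1.
#'
#' @param GA1,GA2 additive matrices of the two groups.
#' @param T1,T2 parent-incidence matrices ([build_parent_incidence()]).
#' @return a [kinship_matrix] named `"GAA12"` at hybrid level.
#' @export
epistatic_across <- function(GA1, GA2, T1, T2) {
  M1 <- T1 %*% unclass(GA1) %*% t(T1)
  M2 <- T2 %*% unclass(GA2) %*% t(T2)
  K <- scale_trace(M1 * M2, "GAA12", "hybrids")
  dimnames(K) <- list(rownames(T1), rownames(T1))
  K
}

#' Epistatic relationship matrices involving dominance
#'
#' Additive-by-dominance (`(T GA T') o D`) and dominance-by-dominance
#' (`D o D`) hybrid-level matrices, each scaled by its trace over n.
#' These are constructible for completeness; their variance components are
#' hard to estimate in practice and they are not part of the stock model
#' codes.
#'
#' @param D dominance [kinship_matrix] (hybrid level).
#' @param GA optional additive matrix of one group, with its `T`; if
#'   omitted, the dominance-by-dominance matrix `GDD` is returned.
#' @param T parent-incidence matrix matching `GA`.
#' @param name output name (`"GA1D"`, `"GA2D"` or `"GDD"`).
#' @return a [kinship_matrix] at hybrid level.
#' @export
epistatic_with_dominance <- function(D, GA = NULL, T = NULL, name = "GDD") {
  if (is.null(GA)) {
    M <- unclass(D) * unclass(D)
  } else {
    if (is.null(T)) stop("supply the parent-incidence matrix T with GA")
    M <- (T %*% unclass(GA) %*% t(T)) * unclass(D)
  }
  K <- scale_trace(M, name, "hybrids")
  dimnames(K) <- dimnames(D)
  K
}

#' G-model relationship matrices from NOIA codings
#'
#' `GAH = Ha Ha' / (tr(Ha Ha')/n)` (VanRaden-style but with a trace
#' denominator that accounts for the hybrids' lack of HWE), `DH` the same
#' from Hd, and `GAAH` the trace-scaled Hadamard square of GAH.
#'
#' @param noia codings from [noia_codings()].
#' @return list of three [kinship_matrix] objects `GAH`, `DH`, `GAAH`.
#' @export
gmodel_kinships <- function(noia) {
  GAH <- scale_trace(tcrossprod(noia$Ha), "GAH", "hybrids")
  DH  <- scale_trace(tcrossprod(noia$Hd), "DH", "hybrids")
  GAAH <- scale_trace(unclass(GAH) * unclass(GAH), "GAAH", "hybrids")
  list(GAH = GAH, DH = DH, GAAH = GAAH)
}

#' Summary statistics of a relationship matrix
#'
#' @param K a matrix.
#' @return list with `mean_diag`, `mean_all`, `min_eigenvalue`,
#'   `max_eigenvalue` and `offdiag_range`.
#' @export
kinship_summary <- function(K) {
  if (!all(is.finite(K))) stop("non-finite entries")
  ev <- eigen((unclass(K) + t(unclass(K))) / 2, symmetric = TRUE,
              only.values = TRUE)$values
  off <- K[row(K) != col(K)]
  list(mean_diag = mean(diag(K)), mean_all = mean(K),
       min_eigenvalue = min(ev), max_eigenvalue = max(ev),
       offdiag_range = if (length(off)) range(off) else c(NA_real_, NA_real_))
}
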