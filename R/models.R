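#' Model codes for hybrid genomic evaluation
#'
#' Expands a model code into its set of random terms.  GCA-model codes
#' define marker effects "according to origin" with line-level additive
#' and within-group epistatic terms mapped to hybrids through the parent
#' incidence matrices; G-model codes define effects uniquely at the
#' hybrid level via the NOIA codings.
#'
#' Stock codes and their terms:
#' \describe{
#'   \item{`GCA:A`}{A1, A2}
#'   \item{`GCA:AD`}{A1, A2, D}
#'   \item{`GCA:AAA12`}{A1, A2, AA12}
#'   \item{`GCA:ADAA12`}{A1, A2, D, AA12}
#'   \item{`GCA:ADAA11AA22AA12`}{A1, A2, D, AA11, AA22, AA12}
#'   \item{`G:A`}{AH}
#'   \item{`G:ADH`}{AH, DH}
#'   \item{`G:AAAH`}{AH, AAH}
#'   \item{`G:ADHAAH`}{AH, DH, AAH}
#' }
#' Every GCA code optionally adds the "residual genetic" line terms r1 and
#' r2 (identity covariance at line level), estimable because lines repeat
#' across hybrids; the G-model has one record per hybrid, so r terms are
#' not available there.  The dominance-involving epistatic terms A1D, A2D
#' and DD can be added explicitly via `extra` but are not part of any
#' stock code (their variances are poorly estimable in practice).
#'
#' @param code one of the stock codes above (punctuation in the epistasis
#'   suffix, as in `"GCA:AAA(1,2)"`, is tolerated).
#' @param with_r add residual genetic line terms (GCA-model only).
#' @param extra character vector of extra hybrid-level terms among
#'   `"A1D"`, `"A2D"`, `"DD"`.
#' @return object of class `hybrid_model` with fields `code`, `type`
#'   (`"GCA"` or `"G"`), `terms`, `with_r`.
#' @export
hybrid_model <- function(code, with_r = TRUE, extra = character()) {
  norm <- gsub("[(),]", "", toupper(code))
  menu <- list(
    "GCA:A" = c("A1", "A2"),
    "GCA:AD" = c("A1", "A2", "D"),
    "GCA:AAA12" = c("A1", "A2", "AA12"),
    "GCA:ADAA12" = c("A1", "A2", "D", "AA12"),
    "GCA:ADAA11AA22AA12" = c("A1", "A2", "D", "AA11", "AA22", "AA12"),
    "G:A" = "AH",
    "G:ADH" = c("AH", "DH"),
    "G:AAAH" = c("AH", "AAH"),
    "G:ADHAAH" = c("AH", "DH", "AAH"))
  if (!norm %in% names(menu))
    stop("unknown model code '", code, "'; available: ",
         paste(names(menu), collapse = ", "))
  type <- if (startsWith(norm, "GCA")) "GCA" else "G"
  terms <- menu[[norm]]
  if (length(extra)) {
    stopifnot(all(extra %in% c("A1D", "A2D", "DD")))
    if (type == "G") stop("A1D/A2D/DD terms belong to the GCA-model")
    terms <- c(terms, extra)
  }
  if (with_r && type == "G")
    stop("residual genetic r terms are not estimable in the G-model ",
         "(one record per hybrid); use with_r = FALSE")
  if (with_r) terms <- c(terms, "r1", "r2")
  structure(list(code = norm, type = type, terms = terms, with_r = with_r),
            class = "hybrid_model")
}

#' @export
print.hybrid_model <- function(x, ...) {
  cat("hybrid_model ", x$code, if (x$with_r) " + r" else "",
      ": terms ", paste(x$terms, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Eigendecomposed design matrix for one random term
#'
#' A random term with line- or hybrid-level covariance K and mapping T
#' contributes a hybrid-level covariance `T K T'`.  This function
#' eigendecomposes that (ridge-stabilized) covariance and returns
#' `B = U Gamma^(1/2)` over the retained eigenpairs, so that
#' `B B' = T K T'` up to the dropped-eigenvalue mass and the ridge.  The
#' columns of B are orthogonal, which lets the Gibbs sampler draw each
#' term's ridge-regression coefficients jointly from a diagonal-precision
#' normal.  The term's variance component stays on the kinship scale
#' because the design absorbs `Gamma^(1/2)`.
#'
#' @param K covariance matrix of the term (a [kinship_matrix] or identity;
#'   pass `NULL` for identity when `T` is given, as for r terms).
#' @param T optional hybrid x unit incidence matrix; `NULL` means the term
#'   is already at hybrid level.
#' @param tol relative eigenvalue drop tolerance (default 1e-10 of the
#'   largest eigenvalue).
#' @param ridge stabilizer added to the retained eigenvalues (never to
#'   stored kinship matrices).
#' @return matrix B (hybrids x retained dimensions) with attributes
#'   `dropped_mass` (sum of dropped eigenvalues) and `eigenvalues`.
#' @export
eigen_design <- function(K = NULL, T = NULL, tol = 1e-10, ridge = 1e-8) {
  if (is.null(K) && is.null(T)) stop("supply K and/or T")
  C <- if (is.null(T)) {
    unclass(K)
  } else if (is.null(K)) {
    tcrossprod(T)
  } else {
    T %*% unclass(K) %*% t(T)
  }
  C <- (C + t(C)) / 2
  e <- eigen(C, symmetric = TRUE)
  keep <- e$values > tol * max(e$values)
  if (!any(keep)) stop("all eigenvalues dropped; term covariance is null")
  # ridge stabilizes the retained spectrum only; dropped (numerically
  # null or negative) directions stay dropped
  B <- e$vectors[, keep, drop = FALSE] %*%
    diag(sqrt(e$values[keep] + ridge), sum(keep))
  rownames(B) <- if (!is.null(T)) rownames(T) else rownames(K)
  attr(B, "dropped_mass") <- sum(e$values[!keep])
  attr(B, "eigenvalues") <- e$values[keep]
  B
}

#' Build all eigen-designs for a model over the full hybrid set
#'
#' Computes the codings and relationship matrices required by the model's
#' terms and returns one eigen-design per term, with rows for every hybrid
#' in the pedigree (train and predict alike), so downstream fits can
#' subset training rows and predictions always have design rows.
#'
#' @param g1,g2 [line_genotypes] of the two groups (shared marker panel).
#' @param ped a [hybrid_pedigree] naming every hybrid of the study.
#' @param model a [hybrid_model].
#' @param tol,ridge passed to [eigen_design()].
#' @return object of class `hybrid_designs`: list with `designs` (named
#'   list of B matrices), `kinships` (the constructed relationship
#'   matrices), `ped`, `model`.
#' @export
build_designs <- function(g1, g2, ped, model, tol = 1e-10, ridge = 1e-8) {
  stopifnot(inherits(model, "hybrid_model"))
  validate_study(g1, g2, ped)
  terms <- model$terms
  kin <- list()
  designs <- list()

  need <- function(...) any(c(...) %in% terms)
  p1 <- compute_allele_freqs(g1)
  p2 <- compute_allele_freqs(g2)
  T1 <- build_parent_incidence(ped, rownames(g1$calls), 1)
  T2 <- build_parent_incidence(ped, rownames(g2$calls), 2)

  if (need("A1", "A2", "D", "AA11", "AA22", "AA12", "A1D", "A2D", "DD")) {
    Z1 <- center_line_genotypes(g1, p1)
    Z2 <- center_line_genotypes(g2, p2)
    GA1 <- additive_kinship(Z1, p1, "GA1", "lines1")
    GA2 <- additive_kinship(Z2, p2, "GA2", "lines2")
    kin$GA1 <- GA1; kin$GA2 <- GA2
    if (need("D", "A1D", "A2D", "DD")) {
      W <- build_dominance_incidence(Z1, Z2, ped)
      kin$D <- dominance_kinship(W, p1, p2)
    }
    if (need("AA11")) kin$GAA11 <- epistatic_within(GA1, "GAA11")
    if (need("AA22")) kin$GAA22 <- epistatic_within(GA2, "GAA22")
    if (need("AA12")) kin$GAA12 <- epistatic_across(GA1, GA2, T1, T2)
    if (need("A1D"))
      kin$GA1D <- epistatic_with_dominance(kin$D, GA1, T1, "GA1D")
    if (need("A2D"))
      kin$GA2D <- epistatic_with_dominance(kin$D, GA2, T2, "GA2D")
    if (need("DD")) kin$GDD <- epistatic_with_dominance(kin$D, name = "GDD")
  }
  if (need("AH", "DH", "AAH")) {
    hg <- derive_hybrid_genotypes(g1, g2, ped)
    gm <- gmodel_kinships(noia_codings(hg))
    kin$GAH <- gm$GAH; kin$DH <- gm$DH; kin$GAAH <- gm$GAAH
  }

  for (tm in terms) {
    designs[[tm]] <- switch(tm,
      A1 = eigen_design(kin$GA1, T1, tol, ridge),
      A2 = eigen_design(kin$GA2, T2, tol, ridge),
      D = eigen_design(kin$D, NULL, tol, ridge),
      AA11 = eigen_design(kin$GAA11, T1, tol, ridge),
      AA22 = eigen_design(kin$GAA22, T2, tol, ridge),
      AA12 = eigen_design(kin$GAA12, NULL, tol, ridge),
      A1D = eigen_design(kin$GA1D, NULL, tol, ridge),
      A2D = eigen_design(kin$GA2D, NULL, tol, ridge),
      DD = eigen_design(kin$GDD, NULL, tol, ridge),
      r1 = eigen_design(NULL, T1, tol, ridge),
      r2 = eigen_design(NULL, T2, tol, ridge),
      AH = eigen_design(kin$GAH, NULL, tol, ridge),
      DH = eigen_design(kin$DH, NULL, tol, ridge),
      AAH = eigen_design(kin$GAAH, NULL, tol, ridge),
      stop("no design rule for term ", tm))
  }
  structure(list(designs = designs, kinships = kin, ped = ped,
                 model = model),
            class = "hybrid_designs")
}

#' @export
print.hybrid_designs <- function(x, ...) {
  cat("hybrid_designs for", x$model$code, "over", nrow(x$ped), "hybrids\n")
  for (nm in names(x$designs))
    cat("  ", nm, ": ", ncol(x$designs[[nm]]), " dimensions\n", sep = "")
  invisible(x)
}
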