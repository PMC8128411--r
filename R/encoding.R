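#' Observed allele frequencies of a line panel
#'
#' The frequency of the counted allele B at each marker is the column mean
#' of the homozygote-indicator calls (each inbred line contributes one
#' gamete type).
#'
#' @param g a [line_genotypes] object.
#' @return numeric vector of frequencies, named by marker id, with the
#'   group label as attribute `group`.
#' @export
compute_allele_freqs <- function(g) {
  stopifnot(inherits(g, "line_genotypes"))
  if (nrow(g$calls) == 0L) stop("empty group '", g$group, "'")
  p <- colMeans(g$calls)
  attr(p, "group") <- g$group
  p
}

#' Centered additive line coding Z
#'
#' Subtracts the allele frequency from the indicator calls, column by
#' column: `Z = M - 1 p'`.  With observed frequencies every column of Z
#' sums to zero exactly, and the entries at each marker are `q = 1 - p`
#' (carriers of B) or `-p` (carriers of b).
#'
#' @param g a [line_genotypes] object.
#' @param p allele frequencies; defaults to the observed frequencies
#'   [compute_allele_freqs()].  Supplying reference frequencies waives the
#'   zero-column-sum property.
#' @return matrix lines x markers, with attribute `freqs`.
#' @export
center_line_genotypes <- function(g, p = compute_allele_freqs(g)) {
  stopifnot(inherits(g, "line_genotypes"))
  if (length(p) != ncol(g$calls))
    stop("frequency vector length does not match marker panel")
  Z <- sweep(g$calls, 2L, as.numeric(p), "-")
  attr(Z, "freqs") <- as.numeric(p)
  attr(Z, "group") <- g$group
  Z
}

#' Parent-incidence matrix T
#'
#' A 0/1 matrix of hybrids x lines with a single 1 per row, linking each
#' hybrid to its parent in the requested group.  `T %*% v` maps line-level
#' effects `v` to hybrids.
#'
#' @param ped a [hybrid_pedigree].
#' @param line_ids ordered line ids of the group panel (the matrix columns).
#' @param group which parent, `1` or `2`.
#' @return 0/1 matrix with hybrid ids as rownames, line ids as colnames.
#' @export
build_parent_incidence <- function(ped, line_ids, group = 1) {
  stopifnot(inherits(ped, "hybrid_pedigree"), group %in% c(1, 2))
  parent <- if (group == 1) ped$parent1 else ped$parent2
  unknown <- setdiff(parent, line_ids)
  if (length(unknown)) {
    h <- ped$hybrid[match(unknown[1L], parent)]
    stop("hybrid '", h, "' has unknown group-", group,
         " parent '", unknown[1L], "'")
  }
  T <- matrix(0, nrow(ped), length(line_ids),
              dimnames = list(ped$hybrid, line_ids))
  T[cbind(seq_len(nrow(ped)), match(parent, line_ids))] <- 1
  T
}

#' Hybrid dominance incidence coding W
#'
#' For each hybrid and marker, `w = -2 * z1 * z2` where z1 and z2 are the
#' centered codes of its two parental gametes.  Per genotype class this
#' takes the values -2*q1*q2 (B1B2), 2*q1*p2 (B1b2), 2*p1*q2 (b1B2) and
#' -2*p1*p2 (b1b2).  A marker monomorphic in either group yields a zero
#' column.
#'
#' @param Z1,Z2 centered codings from [center_line_genotypes()].
#' @param ped a [hybrid_pedigree].
#' @return matrix hybrids x markers.
#' @export
build_dominance_incidence <- function(Z1, Z2, ped) {
  stopifnot(inherits(ped, "hybrid_pedigree"))
  if (ncol(Z1) != ncol(Z2)) stop("marker panels differ between groups")
  i1 <- match(ped$parent1, rownames(Z1))
  i2 <- match(ped$parent2, rownames(Z2))
  if (anyNA(i1) || anyNA(i2)) stop("pedigree parent missing from coding rows")
  W <- -2 * Z1[i1, , drop = FALSE] * Z2[i2, , drop = FALSE]
  rownames(W) <- ped$hybrid
  W
}

#' Derive hybrid genotypes from parental lines
#'
#' The B-allele count of a hybrid at a marker is the sum of its two
#' parental indicators (0, 1 or 2).  Genotype-class frequencies and the
#' hybrid-set B frequency are computed over the realized hybrid set, with
#' no Hardy-Weinberg assumption.
#'
#' @param g1,g2 [line_genotypes] of the two groups (shared marker panel).
#' @param ped a [hybrid_pedigree].
#' @return list with `counts` (hybrids x markers, 0/1/2), per-marker class
#'   frequencies `pBB`, `pBb`, `pbb`, and the hybrid B frequency `pk`.
#' @export
derive_hybrid_genotypes <- function(g1, g2, ped) {
  stopifnot(inherits(g1, "line_genotypes"), inherits(g2, "line_genotypes"),
            inherits(ped, "hybrid_pedigree"))
  if (!identical(colnames(g1$calls), colnames(g2$calls)))
    stop("marker panels differ between groups")
  i1 <- match(ped$parent1, rownames(g1$calls))
  i2 <- match(ped$parent2, rownames(g2$calls))
  if (anyNA(i1) || anyNA(i2)) stop("pedigree parent missing from panel")
  counts <- g1$calls[i1, , drop = FALSE] + g2$calls[i2, , drop = FALSE]
  rownames(counts) <- ped$hybrid
  pBB <- colMeans(counts == 2)
  pBb <- colMeans(counts == 1)
  pbb <- colMeans(counts == 0)
  list(counts = counts, pBB = pBB, pBb = pBb, pbb = pbb,
       pk = colMeans(counts) / 2)
}

#' NOIA hybrid-level additive and dominance codings
#'
#' Builds the orthogonal hybrid-level codings that define the G-model.
#' The additive coding Ha takes values `2 - 2pk`, `1 - 2pk`, `-2pk` for
#' genotypes BB, Bb, bb, with `pk` the B frequency in the hybrid set.  The
#' dominance coding Hd is the natural-and-orthogonal (NOIA) coding, valid
#' without Hardy-Weinberg equilibrium:
#' \deqn{hd_{BB} = -2 p_{Bb} p_{bb} / s, \quad
#'       hd_{Bb} = 4 p_{BB} p_{bb} / s, \quad
#'       hd_{bb} = -2 p_{BB} p_{Bb} / s}
#' with \eqn{s = p_{BB} + p_{bb} - (p_{BB} - p_{bb})^2}.  Markers where the
#' hybrid set lacks the class structure needed by the coding (s = 0, e.g.
#' every hybrid heterozygous) get a zero Hd column, which contributes no
#' covariance while preserving panel alignment.  In a hybrid set that
#' happens to be in HWE, Hd reduces to the classical coding
#' \{-2q^2, 2pq, -2p^2\}.
#'
#' @param hg hybrid genotypes from [derive_hybrid_genotypes()].
#' @return list with matrices `Ha` and `Hd` (hybrids x markers).
#' @export
noia_codings <- function(hg) {
  counts <- hg$counts
  pk <- hg$pk
  Ha <- sweep(counts, 2L, 2 * pk, "-")
  s <- hg$pBB + hg$pbb - (hg$pBB - hg$pbb)^2
  hdBB <- ifelse(s > 0, -2 * hg$pBb * hg$pbb / s, 0)
  hdBb <- ifelse(s > 0,  4 * hg$pBB * hg$pbb / s, 0)
  hdbb <- ifelse(s > 0, -2 * hg$pBB * hg$pBb / s, 0)
  Hd <- matrix(0, nrow(counts), ncol(counts), dimnames = dimnames(counts))
  for (val in 0:2) {
    idx <- counts == val
    row_code <- switch(as.character(val), "0" = hdbb, "1" = hdBb, "2" = hdBB)
    Hd[idx] <- rep(row_code, each = nrow(counts))[idx]
  }
  list(Ha = Ha, Hd = Hd)
}
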