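#' Line genotype container
#'
#' Holds the homozygote-indicator genotype matrix of one heterotic group of
#' fully inbred lines.  Calls are coded 1 for lines homozygous for the
#' counted allele (B) and 0 for the alternative homozygote (b); inbred lines
#' carry no heterozygous calls.
#'
#' @param calls numeric matrix, lines x markers, entries in \{0, 1\}, with
#'   line ids as rownames and marker ids as colnames.
#' @param group group label, e.g. `"dent"` or `1`.
#' @param counted_allele optional character vector (one per marker) recording
#'   which allele the 1-call counts (for VCF input, the ALT allele).
#' @return an object of class `line_genotypes`.
#' @export
line_genotypes <- function(calls, group, counted_allele = NULL) {
  calls <- as.matrix(calls)
  if ((nrow(calls) > 0L && is.null(rownames(calls))) ||
      is.null(colnames(calls)))
    stop("calls must carry line ids as rownames and marker ids as colnames")
  if (anyDuplicated(rownames(calls)))
    stop("duplicate line ids in group '", group, "'")
  if (anyDuplicated(colnames(calls)))
    stop("duplicate marker ids in group '", group, "'")
  if (anyNA(calls))
    stop("missing genotype calls in group '", group,
         "' (load with impute_missing = TRUE to allow)")
  if (!all(calls %in% c(0, 1)))
    stop("genotype calls must be 0 or 1 (homozygote indicators)")
  storage.mode(calls) <- "double"
  structure(list(calls = calls, group = group,
                 counted_allele = counted_allele),
            class = "line_genotypes")
}

#' @export
print.line_genotypes <- function(x, ...) {
  cat("line_genotypes: group '", x$group, "', ",
      nrow(x$calls), " lines x ", ncol(x$calls), " markers\n", sep = "")
  invisible(x)
}

#' @export
dim.line_genotypes <- function(x) dim(x$calls)

#' Hybrid pedigree container
#'
#' Maps each single-cross hybrid to its parent line in each heterotic group.
#'
#' @param hybrid,parent1,parent2 character vectors of equal length.
#' @return an object of class `hybrid_pedigree` (a data frame).
#' @export
hybrid_pedigree <- function(hybrid, parent1, parent2) {
  hybrid  <- as.character(hybrid)
  parent1 <- as.character(parent1)
  parent2 <- as.character(parent2)
  if (length(hybrid) == 0L) stop("no hybrids")
  if (anyDuplicated(hybrid)) stop("duplicate hybrid ids")
  if (anyNA(hybrid) || anyNA(parent1) || anyNA(parent2) ||
      any(parent1 == "") || any(parent2 == ""))
    stop("every hybrid needs both parents")
  structure(data.frame(hybrid = hybrid, parent1 = parent1,
                       parent2 = parent2, stringsAsFactors = FALSE),
            class = c("hybrid_pedigree", "data.frame"))
}

#' Read pure-line genotypes from CSV or VCF
#'
#' The CSV dialect has a header row of marker ids, the line id in the first
#' column and 0/1 homozygote-indicator calls in the body.  VCF input (read
#' with \pkg{vcfR}) is accepted for inbred lines only: every genotype call
#' must be homozygous; `1/1` becomes call 1 (the ALT allele is counted) and
#' `0/0` becomes 0.
#'
#' @param path file path.
#' @param group group label attached to the result.
#' @param format `"csv"` or `"vcf"`.
#' @param impute_missing if `TRUE`, missing calls are imputed per marker to
#'   the major allele (the rounded per-marker mean call); the default is to
#'   fail on any missing call, since silent imputation distorts the
#'   sum-of-pq scalings downstream.
#' @return a [line_genotypes] object.
#' @export
read_line_genotypes <- function(path, group, format = c("csv", "vcf"),
                                impute_missing = FALSE) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "csv") {
    tab <- utils::read.csv(path, check.names = FALSE,
                           stringsAsFactors = FALSE)
    if (ncol(tab) < 2L) stop("genotype CSV needs a line-id column and markers")
    ids <- as.character(tab[[1L]])
    calls <- as.matrix(tab[, -1L, drop = FALSE])
    storage.mode(calls) <- "double"
    rownames(calls) <- ids
    calls <- impute_or_fail(calls, group, impute_missing)
    bad <- which(!(calls %in% c(0, 1)))
    if (length(bad))
      stop("non-0/1 genotype call at line '",
           rownames(calls)[row(calls)[bad[1L]]], "', marker '",
           colnames(calls)[col(calls)[bad[1L]]], "'")
    line_genotypes(calls, group)
  } else {
    read_vcf_lines(path, group, impute_missing)
  }
}

read_vcf_lines <- function(path, group, impute_missing) {
  if (!requireNamespace("vcfR", quietly = TRUE))
    stop("VCF input requires the vcfR package")
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  marker_ids <- rownames(gt)
  if (is.null(marker_ids) || anyNA(marker_ids))
    marker_ids <- paste0(v@fix[, "CHROM"], "_", v@fix[, "POS"])
  line_ids <- colnames(gt)
  core <- gsub("\\|", "/", gt)
  calls <- matrix(NA_real_, nrow = nrow(gt), ncol = ncol(gt))
  calls[core %in% c("0/0", "0")] <- 0
  calls[core %in% c("1/1", "1")] <- 1
  het <- which(!is.na(core) & !(core %in% c("0/0", "1/1", "0", "1")))
  if (length(het)) {
    i <- het[1L]
    stop("heterozygous or unsupported call '", core[i], "' for line '",
         line_ids[col(core)[i]], "' at marker '", marker_ids[row(core)[i]],
         "': inbred-line VCF input must be homozygous")
  }
  calls <- t(calls)                       # lines x markers
  rownames(calls) <- line_ids
  colnames(calls) <- marker_ids
  calls <- impute_or_fail(calls, group, impute_missing)
  line_genotypes(calls, group, counted_allele = unname(v@fix[, "ALT"]))
}

impute_or_fail <- function(calls, group, impute_missing) {
  if (!anyNA(calls)) return(calls)
  if (!impute_missing) {
    i <- which(is.na(calls))[1L]
    stop("missing genotype call at line '", rownames(calls)[row(calls)[i]],
         "', marker '", colnames(calls)[col(calls)[i]], "' in group '",
         group, "'; set impute_missing = TRUE to impute to the major allele")
  }
  for (j in seq_len(ncol(calls))) {
    miss <- is.na(calls[, j])
    if (any(miss)) {
      m <- mean(calls[!miss, j])
      if (is.nan(m)) m <- 0               # fully missing marker
      calls[miss, j] <- round(m)
    }
  }
  calls
}

#' Read a hybrid pedigree table
#'
#' Expects a header and three columns: hybrid id, group-1 parent, group-2
#' parent.  Referential integrity against genotype panels is checked later
#' by [validate_study()].
#'
#' @param path file path (CSV or whitespace/tab separated).
#' @return a [hybrid_pedigree] object.
#' @export
read_pedigree <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- utils::read.table(path, header = TRUE, sep = "",
                           stringsAsFactors = FALSE,
                           colClasses = "character", fill = TRUE)
  if (nrow(tab) == 0L && file.size(path) > 0L) {
    # maybe comma separated
    tab <- utils::read.csv(path, stringsAsFactors = FALSE,
                           colClasses = "character")
  } else if (ncol(tab) == 1L) {
    tab <- utils::read.csv(path, stringsAsFactors = FALSE,
                           colClasses = "character")
  }
  if (nrow(tab) == 0L) stop("no hybrids in pedigree file ", path)
  if (ncol(tab) < 3L) stop("pedigree needs columns hybrid, parent1, parent2")
  hybrid_pedigree(tab[[1L]], tab[[2L]], tab[[3L]])
}

#' Read hybrid entry-mean phenotypes
#'
#' One record per hybrid: hybrid id in the first column, the trait entry
#' mean in the second; further columns are carried along as covariates.
#'
#' @param path file path (CSV).
#' @return data frame with columns `hybrid`, `value`, then any covariates.
#' @export
read_phenotypes <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (ncol(tab) < 2L) stop("phenotype file needs hybrid id and value columns")
  names(tab)[1:2] <- c("hybrid", "value")
  tab$hybrid <- as.character(tab$hybrid)
  if (anyDuplicated(tab$hybrid))
    stop("duplicate hybrid id in phenotypes (entry means expected)")
  if (!is.numeric(tab$value) || anyNA(tab$value))
    stop("phenotype values must be numeric and non-missing")
  tab
}

#' Validate a study's cross-references
#'
#' Checks that the two genotype panels share an identically ordered marker
#' panel and that every pedigree parent exists in its group's panel.
#'
#' @param g1,g2 [line_genotypes] for groups 1 and 2.
#' @param ped a [hybrid_pedigree].
#' @param pheno optional phenotype table ([read_phenotypes]).
#' @param reconcile_markers if `TRUE`, the two panels are intersected and
#'   reordered to a common marker set instead of failing (off by default).
#' @return invisibly, a list with the (possibly reconciled) `g1` and `g2`.
#' @export
validate_study <- function(g1, g2, ped, pheno = NULL,
                           reconcile_markers = FALSE) {
  m1 <- colnames(g1$calls); m2 <- colnames(g2$calls)
  if (!identical(m1, m2)) {
    if (!reconcile_markers)
      stop("marker panels differ between groups (",
           length(m1), " vs ", length(m2),
           " markers); set reconcile_markers = TRUE to intersect")
    common <- intersect(m1, m2)
    if (length(common) == 0L) stop("no shared markers between groups")
    g1 <- line_genotypes(g1$calls[, common, drop = FALSE], g1$group)
    g2 <- line_genotypes(g2$calls[, common, drop = FALSE], g2$group)
  }
  miss1 <- setdiff(ped$parent1, rownames(g1$calls))
  if (length(miss1))
    stop("pedigree parent(s) not in group-1 panel: ",
         paste(utils::head(miss1, 5L), collapse = ", "))
  miss2 <- setdiff(ped$parent2, rownames(g2$calls))
  if (length(miss2))
    stop("pedigree parent(s) not in group-2 panel: ",
         paste(utils::head(miss2, 5L), collapse = ", "))
  if (!is.null(pheno)) {
    missh <- setdiff(pheno$hybrid, ped$hybrid)
    if (length(missh))
      stop("phenotyped hybrid(s) not in pedigree: ",
           paste(utils::head(missh, 5L), collapse = ", "))
  }
  invisible(list(g1 = g1, g2 = g2))
}

#' Write a relationship matrix to disk
#'
#' Two plain-text formats: `"csv"` writes a dense matrix with the ids as
#' header row and first column; `"triplet"` writes one `id1 id2 value` row
#' per upper-triangle entry under a `#id1 id2 value` header.  Both store
#' values with full double precision so that [read_kinship()] round-trips
#' bit-exactly.
#'
#' @param K a matrix (typically a `kinship_matrix`, see [additive_kinship()]).
#' @param path output file.
#' @param format `"csv"` or `"triplet"`.
#' @export
write_kinship <- function(K, path, format = c("csv", "triplet")) {
  format <- match.arg(format)
  if (!all(is.finite(K))) stop("non-finite entries in kinship matrix")
  ids <- rownames(K)
  if (is.null(ids)) ids <- as.character(seq_len(nrow(K)))
  if (format == "csv") {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(paste(c("id", ids), collapse = ","), con)
    for (i in seq_len(nrow(K)))
      writeLines(paste(c(ids[i], sprintf("%.17g", K[i, ])), collapse = ","),
                 con)
  } else {
    iu <- which(upper.tri(K, diag = TRUE), arr.ind = TRUE)
    lines <- c("#id1 id2 value",
               sprintf("%s %s %.17g", ids[iu[, 1L]], ids[iu[, 2L]],
                       K[iu]))
    writeLines(lines, path)
  }
  invisible(path)
}

#' Read a relationship matrix written by [write_kinship()]
#'
#' @param path input file.
#' @param format `"csv"` or `"triplet"`.
#' @return a numeric matrix with ids as dimnames.
#' @export
read_kinship <- function(path, format = c("csv", "triplet")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "csv") {
    tab <- utils::read.csv(path, check.names = FALSE,
                           stringsAsFactors = FALSE)
    K <- as.matrix(tab[, -1L, drop = FALSE])
    storage.mode(K) <- "double"
    rownames(K) <- as.character(tab[[1L]])
    K
  } else {
    tab <- utils::read.table(path, header = FALSE, skip = 1L,
                             col.names = c("id1", "id2", "value"),
                             colClasses = c("character", "character",
                                            "numeric"))
    ids <- unique(c(tab$id1, tab$id2))
    K <- matrix(0, length(ids), length(ids), dimnames = list(ids, ids))
    K[cbind(tab$id1, tab$id2)] <- tab$value
    K[cbind(tab$id2, tab$id1)] <- tab$value
    K
  }
}
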