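#' One T2/T1/T0 cross-validation split
#'
#' Samples `nD` group-1 and `nF` group-2 parent lines, draws `n_train`
#' training hybrids uniformly from the hybrids whose two parents are both
#' sampled (resampling the lines up to `max_retries` times if that pool
#' is too small), and labels every remaining hybrid by how many of its
#' parents appear among the training hybrids' parents: T2 (both), T1
#' (exactly one) or T0 (neither).
#'
#' @param ped a [hybrid_pedigree].
#' @param n_train training-set size.
#' @param nD,nF numbers of group-1 and group-2 lines sampled.
#' @param seed optional RNG seed for a reproducible split.
#' @param max_retries line-resampling cap before giving up.
#' @return list of class `cv_split` with `train` (hybrid ids), `labels`
#'   (named T2/T1/T0 factor over the remaining hybrids) and `seed`.
#' @export
make_cv_split <- function(ped, n_train = 300, nD = 90, nF = 53,
                          seed = NULL, max_retries = 50) {
  stopifnot(inherits(ped, "hybrid_pedigree"))
  if (!is.null(seed)) set.seed(seed)
  lines1 <- unique(ped$parent1); lines2 <- unique(ped$parent2)
  if (nD > length(lines1) || nF > length(lines2))
    stop("fewer lines available than requested for sampling")
  pool_size <- 0L
  for (try in seq_len(max_retries)) {
    s1 <- sample(lines1, nD)
    s2 <- sample(lines2, nF)
    pool <- ped$hybrid[ped$parent1 %in% s1 & ped$parent2 %in% s2]
    pool_size <- max(pool_size, length(pool))
    if (length(pool) >= n_train) break
    if (try == max_retries)
      stop("could not assemble ", n_train, " training hybrids from ",
           nD, " x ", nF, " sampled lines after ", max_retries,
           " tries (largest pool: ", pool_size, ")")
  }
  train <- sample(pool, n_train)
  rest <- setdiff(ped$hybrid, train)
  tp1 <- unique(ped$parent1[ped$hybrid %in% train])
  tp2 <- unique(ped$parent2[ped$hybrid %in% train])
  ri <- match(rest, ped$hybrid)
  n_parents <- (ped$parent1[ri] %in% tp1) + (ped$parent2[ri] %in% tp2)
  labels <- factor(c("T0", "T1", "T2")[n_parents + 1L],
                   levels = c("T2", "T1", "T0"))
  names(labels) <- rest
  structure(list(train = train, labels = labels, seed = seed),
            class = "cv_split")
}

#' Predictive ability of a set of predictions
#'
#' Pearson correlation of predicted and observed values, divided by the
#' broad-sense heritability (`divisor = "h2"`, the default), by its
#' square root, or left undivided.
#'
#' @param pred,obs numeric vectors of equal length (>= 3 pairs).
#' @param H2 broad-sense heritability in (0, 1].
#' @param divisor `"h2"`, `"sqrt_h2"` or `"none"`.
#' @return a single number, or `NA` if either vector has zero variance.
#' @export
predictive_ability <- function(pred, obs, H2 = 1,
                               divisor = c("h2", "sqrt_h2", "none")) {
  divisor <- match.arg(divisor)
  stopifnot(length(pred) == length(obs), H2 > 0, H2 <= 1)
  if (length(pred) < 3L) return(NA_real_)
  if (stats::sd(pred) == 0 || stats::sd(obs) == 0) return(NA_real_)
  r <- stats::cor(pred, obs)
  switch(divisor, h2 = r / H2, sqrt_h2 = r / sqrt(H2), none = r)
}

#' Run the T2/T1/T0 cross-validation protocol
#'
#' For each replicate: draw a split ([make_cv_split()]), fit the model on
#' the training hybrids, predict all remaining hybrids and compute the
#' predictive ability separately per T2/T1/T0 class.  All randomness is
#' driven by per-replicate seeds derived from `seed`, so different model
#' codes evaluated with the same `seed` see identical splits (paired
#' comparison).  The heritability used as divisor is taken from a
#' full-data fit of the most complete GCA-model unless supplied.
#'
#' @param g1,g2 [line_genotypes] of the two groups.
#' @param ped a [hybrid_pedigree] over all study hybrids.
#' @param pheno phenotype table ([read_phenotypes()]).
#' @param model a [hybrid_model] to evaluate.
#' @param reps number of replicates.
#' @param chain a [chain_config] for the per-replicate fits.
#' @param n_train,nD,nF split parameters ([make_cv_split()]).
#' @param seed master seed for the split/chain streams.
#' @param divisor passed to [predictive_ability()].
#' @param H2 heritability divisor; if `NULL`, estimated once by fitting
#'   `GCA:ADAA11AA22AA12` with r terms on the full data with `chain`.
#' @param designs optional precomputed `hybrid_designs` for `model`
#'   (avoids rebuilding kinships every call).
#' @return object of class `cv_result`: per-class mean and SD of
#'   predictive ability over replicates, the per-replicate table, `H2`
#'   and the divisor mode.
#' @export
run_cv <- function(g1, g2, ped, pheno, model, reps = 100,
                   chain = chain_config(), n_train = 300, nD = 90, nF = 53,
                   seed = 1, divisor = c("h2", "sqrt_h2", "none"),
                   H2 = NULL, designs = NULL) {
  divisor <- match.arg(divisor)
  stopifnot(inherits(model, "hybrid_model"))
  set.seed(seed)
  rep_seeds <- sample.int(.Machine$integer.max, reps)
  if (is.null(H2)) {
    full <- hybrid_model("GCA:ADAA11AA22AA12", with_r = TRUE)
    dfull <- build_designs(g1, g2, ped, full)
    cfull <- chain; cfull$seed <- rep_seeds[1L] %% 100000L + 1L
    H2 <- summarize_fit(gibbs_fit(pheno, dfull, cfull))$H2
  }
  if (is.null(designs)) designs <- build_designs(g1, g2, ped, model)
  res <- data.frame(replicate = integer(), class = character(),
                    ability = numeric(), n = integer())
  for (r in seq_len(reps)) {
    split <- make_cv_split(ped, n_train, nD, nF, seed = rep_seeds[r])
    tr_ph <- pheno[pheno$hybrid %in% split$train, , drop = FALSE]
    ch <- chain; ch$seed <- rep_seeds[r] + 1L
    fit <- tryCatch(gibbs_fit(tr_ph, designs, ch),
                    error = function(e)
                      stop("replicate ", r, ": ", conditionMessage(e)))
    test_ids <- intersect(names(split$labels), pheno$hybrid)
    pred <- predict_hybrids(fit, test_ids)
    obs <- pheno$value[match(test_ids, pheno$hybrid)]
    cls <- split$labels[test_ids]
    for (lv in levels(cls)) {
      sel <- cls == lv
      ab <- if (sum(sel) >= 3L)
        predictive_ability(pred[sel], obs[sel], H2, divisor) else NA_real_
      res <- rbind(res, data.frame(replicate = r, class = lv,
                                   ability = ab, n = sum(sel)))
    }
  }
  agg <- do.call(rbind, lapply(c("T2", "T1", "T0"), function(lv) {
    x <- res$ability[res$class == lv]
    data.frame(class = lv, mean = mean(x, na.rm = TRUE),
               sd = if (sum(!is.na(x)) > 1L) stats::sd(x, na.rm = TRUE)
                    else NA_real_,
               n_replicates = sum(!is.na(x)))
  }))
  structure(list(summary = agg, replicates = res, H2 = H2,
                 divisor = divisor, model = model$code, reps = reps),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat("cv_result:", x$model, "-", x$reps, "replicates, divisor",
      x$divisor, sprintf("(H2 = %.3f)\n", x$H2))
  print(x$summary, row.names = FALSE)
  invisible(x)
}
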