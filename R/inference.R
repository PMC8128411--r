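#' MCMC chain configuration
#'
#' Defaults follow common practice for these models: 60,000 iterations,
#' the first 30,000 discarded as burn-in and the rest thinned by 10, so
#' 3,000 samples are kept per run.  Variance priors are scaled inverse
#' chi-square with `df0` degrees of freedom; prior scales follow the
#' standard Bayesian-ridge-regression default: a fraction `R2` of the
#' phenotypic variance is split equally across the genetic terms (each
#' term's prior mode is `R2 * var(y) / n_terms`) and the residual prior
#' mode is `(1 - R2) * var(y)`.  Explicit scales can be supplied instead.
#'
#' @param n_iter total Gibbs iterations.
#' @param burn_in iterations discarded.
#' @param thin keep every `thin`-th post-burn-in iteration.
#' @param seed RNG seed for reproducible chains (`NULL` leaves the RNG
#'   state alone).
#' @param df0 prior degrees of freedom for every variance.
#' @param R2 prior guess of the phenotypic-variance fraction explained by
#'   all genetic terms together.
#' @param scales optional named vector of prior scales per term (plus
#'   `"e"` for the residual), overriding the default.
#' @return object of class `chain_config`.
#' @export
chain_config <- function(n_iter = 60000, burn_in = 30000, thin = 10,
                         seed = NULL, df0 = 5, R2 = 0.5, scales = NULL) {
  stopifnot(n_iter > burn_in, thin >= 1, df0 > 0, R2 > 0, R2 < 1)
  structure(list(n_iter = as.integer(n_iter), burn_in = as.integer(burn_in),
                 thin = as.integer(thin), seed = seed, df0 = df0, R2 = R2,
                 scales = scales),
            class = "chain_config")
}

#' Gibbs sampler for the hybrid variance-component models
#'
#' Fits `y = 1 mu + sum_t B_t u_t + e` with `u_t ~ N(0, I sigma2_t)` and
#' `e ~ N(0, I sigma2_e)`, where each `B_t` is the eigen-design of one
#' random term ([build_designs()]), so `B_t u_t` has covariance
#' `T K T' sigma2_t` on the kinship scale.  Updates are standard
#' conjugate draws: flat prior on the intercept, a joint multivariate
#' normal block per term (diagonalized once per fit through the
#' eigendecomposition of the observed design's cross-product), and scaled
#' inverse chi-square draws for every variance.
#'
#' @param pheno phenotype table with columns `hybrid` and `value`
#'   ([read_phenotypes()]), or a named numeric vector.  Hybrids absent
#'   from the table are treated as prediction targets.
#' @param designs a `hybrid_designs` object covering all study hybrids.
#' @param chain a [chain_config].
#' @param fix_variances optional named vector clamping variances (term
#'   names and/or `"e"`); clamped variances are not updated, which turns
#'   the sampler into a draw from the effect posteriors at known
#'   variances (BLUP regime).
#' @return object of class `hgp_fit` with the variance samples, intercept
#'   and deviance samples, posterior-mean coefficients per term, and
#'   bookkeeping needed by [summarize_fit()] and [predict_hybrids()].
#' @export
gibbs_fit <- function(pheno, designs, chain = chain_config(),
                      fix_variances = NULL) {
  stopifnot(inherits(designs, "hybrid_designs"),
            inherits(chain, "chain_config"))
  if (is.numeric(pheno) && !is.null(names(pheno)))
    pheno <- data.frame(hybrid = names(pheno), value = as.numeric(pheno))
  if (!all(c("hybrid", "value") %in% names(pheno)))
    stop("pheno needs 'hybrid' and 'value' columns")
  if (!all(is.finite(pheno$value))) stop("non-finite phenotype values")
  all_ids <- designs$ped$hybrid
  unmapped <- setdiff(pheno$hybrid, all_ids)
  if (length(unmapped))
    stop("phenotyped hybrid(s) without design rows: ",
         paste(utils::head(unmapped, 5L), collapse = ", "))
  obs <- match(pheno$hybrid, all_ids)
  y <- pheno$value
  n <- length(y)
  terms <- names(designs$designs)
  nt <- length(terms)

  if (!is.null(chain$seed)) set.seed(chain$seed)

  # observed-row designs and their diagonalizations
  Bo <- lapply(designs$designs, function(B) B[obs, , drop = FALSE])
  Qs <- vector("list", nt); Ss <- vector("list", nt)
  for (t in seq_len(nt)) {
    ct <- crossprod(Bo[[t]])
    e <- eigen((ct + t(ct)) / 2, symmetric = TRUE)
    Qs[[t]] <- e$vectors
    Ss[[t]] <- pmax(e$values, 0)
  }

  # priors: genetic terms split a fraction R2 of var(y) equally, the
  # residual prior mode is the remaining fraction
  df0 <- chain$df0
  vy <- stats::var(y)
  mode_t <- chain$R2 * vy / nt
  mode_e <- (1 - chain$R2) * vy
  S0 <- setNames(c(rep(mode_t, nt), mode_e) * (df0 + 2) / df0,
                 c(terms, "e"))
  if (!is.null(chain$scales)) S0[names(chain$scales)] <- chain$scales

  fixed <- rep(FALSE, nt + 1); names(fixed) <- c(terms, "e")
  v <- setNames(rep(vy / (nt + 1), nt + 1), c(terms, "e"))
  if (!is.null(fix_variances)) {
    bad <- setdiff(names(fix_variances), names(v))
    if (length(bad)) stop("unknown term(s) in fix_variances: ",
                          paste(bad, collapse = ", "))
    v[names(fix_variances)] <- fix_variances
    fixed[names(fix_variances)] <- TRUE
  }

  u <- lapply(Bo, function(B) numeric(ncol(B)))
  mu <- mean(y)
  e_res <- y - mu

  n_saved <- (chain$n_iter - chain$burn_in) %/% chain$thin
  var_samples <- matrix(NA_real_, n_saved, nt + 1,
                        dimnames = list(NULL, c(terms, "e")))
  mu_samples <- numeric(n_saved)
  dev_samples <- numeric(n_saved)
  u_mean <- lapply(Bo, function(B) numeric(ncol(B)))
  saved <- 0L

  for (it in seq_len(chain$n_iter)) {
    # intercept (flat prior)
    e_res <- e_res + mu
    mu <- stats::rnorm(1L, mean(e_res), sqrt(v[["e"]] / n))
    e_res <- e_res - mu
    # one joint block draw per term
    for (t in seq_len(nt)) {
      B <- Bo[[t]]
      e_res <- e_res + B %*% u[[t]]
      rhs <- crossprod(Qs[[t]], crossprod(B, e_res)) / v[["e"]]
      cvar <- 1 / (Ss[[t]] / v[["e"]] + 1 / v[[t]])
      w <- rhs * cvar + sqrt(cvar) * stats::rnorm(length(cvar))
      u[[t]] <- as.numeric(Qs[[t]] %*% w)
      e_res <- e_res - B %*% u[[t]]
      if (!fixed[[t]]) {
        k <- length(u[[t]])
        v[[t]] <- (sum(u[[t]]^2) + df0 * S0[[t]]) /
          stats::rchisq(1L, df0 + k)
      }
    }
    if (!fixed[["e"]])
      v[["e"]] <- (sum(e_res^2) + df0 * S0[["e"]]) /
        stats::rchisq(1L, df0 + n)
    if (it > chain$burn_in && (it - chain$burn_in) %% chain$thin == 0L) {
      saved <- saved + 1L
      var_samples[saved, ] <- v
      mu_samples[saved] <- mu
      dev_samples[saved] <- n * log(2 * pi * v[["e"]]) +
        sum(e_res^2) / v[["e"]]
      for (t in seq_len(nt)) u_mean[[t]] <- u_mean[[t]] + u[[t]]
    }
  }
  u_mean <- lapply(u_mean, function(x) x / saved)
  structure(list(var_samples = var_samples, mu_samples = mu_samples,
                 dev_samples = dev_samples, coef_means = u_mean,
                 terms = terms, designs = designs, obs = obs, y = y,
                 pheno_ids = pheno$hybrid, chain = chain,
                 fixed = fixed),
            class = "hgp_fit")
}

#' @export
print.hgp_fit <- function(x, ...) {
  cat("hgp_fit:", x$designs$model$code, "on", length(x$y), "hybrids,",
      nrow(x$var_samples), "posterior samples\n")
  pm <- colMeans(x$var_samples)
  for (nm in names(pm))
    cat(sprintf("  sigma2_%-5s %8.3f\n", nm, pm[[nm]]))
  invisible(x)
}

#' Posterior summary of a fitted model
#'
#' Posterior means and SDs of every variance component, the genomic
#' broad-sense heritability `H2 = sum(genetic variances incl. r) /
#' (same + sigma2_e)` computed per sample, the GCA/SCA aggregate
#' variances (`GCA1 = A1 + AA11 + r1`, `GCA2 = A2 + AA22 + r2`,
#' `SCA = D + AA12 (+ A1D + A2D + DD)`; GCA-model only), and the deviance
#' information criterion `DIC = mean(D) + pD` with
#' `pD = mean(D) - D(at posterior means)` under the conditional Gaussian
#' deviance given the sampled effects.
#'
#' @param fit an `hgp_fit`.
#' @return object of class `hgp_summary`: list with `variances` (mean/sd
#'   table), `H2`, `H2_sd`, `DIC`, `pD`, `aggregates`, `mu`.
#' @export
summarize_fit <- function(fit) {
  stopifnot(inherits(fit, "hgp_fit"))
  vs <- fit$var_samples
  gen <- setdiff(colnames(vs), "e")
  h2_samples <- rowSums(vs[, gen, drop = FALSE]) / rowSums(vs)
  # deviance at posterior means of mu and effects, with posterior-mean
  # residual variance
  e_hat <- fit$y - mean(fit$mu_samples)
  for (t in seq_along(fit$terms)) {
    B <- fit$designs$designs[[t]][fit$obs, , drop = FALSE]
    e_hat <- e_hat - B %*% fit$coef_means[[t]]
  }
  ve_hat <- mean(vs[, "e"])
  n <- length(fit$y)
  d_hat <- n * log(2 * pi * ve_hat) + sum(e_hat^2) / ve_hat
  d_bar <- mean(fit$dev_samples)
  pD <- d_bar - d_hat
  pm <- colMeans(vs)
  agg <- if (fit$designs$model$type == "GCA") {
    comp <- setNames(as.list(pm[gen]), gen)
    genotypic_variance_partition(comp)
  } else NULL
  structure(list(
    variances = data.frame(term = colnames(vs), mean = pm,
                           sd = apply(vs, 2L, stats::sd),
                           row.names = NULL),
    H2 = mean(h2_samples), H2_sd = stats::sd(h2_samples),
    DIC = d_bar + pD, pD = pD, Dbar = d_bar,
    aggregates = agg, mu = mean(fit$mu_samples),
    model = fit$designs$model$code,
    note = paste("H2 numerator includes every fitted genetic term",
                 "(r terms included); DIC uses the conditional Gaussian",
                 "deviance given sampled effects")),
    class = "hgp_summary")
}

#' @export
print.hgp_summary <- function(x, ...) {
  cat("Model", x$model, "\n")
  cat(sprintf("  mu     %8.3f\n", x$mu))
  for (i in seq_len(nrow(x$variances)))
    cat(sprintf("  sigma2_%-5s %8.3f (%.3f)\n", x$variances$term[i],
                x$variances$mean[i], x$variances$sd[i]))
  cat(sprintf("  H2  %.3f (%.3f)   DIC %.2f (pD %.1f)\n",
              x$H2, x$H2_sd, x$DIC, x$pD))
  if (!is.null(x$aggregates))
    cat(sprintf("  GCA1 %.3f  GCA2 %.3f  SCA %.3f\n",
                x$aggregates$GCA1, x$aggregates$GCA2, x$aggregates$SCA))
  invisible(x)
}

#' Predicted total genetic values of hybrids
#'
#' `prediction = mu_hat + sum_t B_t(full rows) u_t_hat` over the fitted
#' terms, using posterior-mean coefficients.  Hybrids never phenotyped
#' (including T0 hybrids, whose parents carry no phenotype) still receive
#' informative predictions through the marker-based relationships
#' embedded in the designs.
#'
#' @param fit an `hgp_fit`.
#' @param hybrids hybrid ids to predict (default: every hybrid in the
#'   design pedigree).
#' @return named numeric vector of predictions.
#' @export
predict_hybrids <- function(fit, hybrids = NULL) {
  stopifnot(inherits(fit, "hgp_fit"))
  all_ids <- fit$designs$ped$hybrid
  if (is.null(hybrids)) hybrids <- all_ids
  idx <- match(hybrids, all_ids)
  if (anyNA(idx))
    stop("hybrid(s) absent from designs: ",
         paste(utils::head(hybrids[is.na(idx)], 5L), collapse = ", "))
  pred <- rep(mean(fit$mu_samples), length(idx))
  for (t in seq_along(fit$terms)) {
    B <- fit$designs$designs[[t]][idx, , drop = FALSE]
    pred <- pred + as.numeric(B %*% fit$coef_means[[t]])
  }
  names(pred) <- hybrids
  pred
}
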