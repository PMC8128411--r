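# small in-code fixtures shared across test files

# plain numeric matrix view of a kinship_matrix (drops all attributes)
km <- function(K) matrix(as.numeric(K), nrow(K))

# random 0/1 inbred panel with at least one segregating marker
toy_panel <- function(n, m, group = "G", seed = NULL, prefix = "L") {
  if (!is.null(seed)) set.seed(seed)
  repeat {
    calls <- matrix(rbinom(n * m, 1L, runif(m, 0.2, 0.8)[rep(1:m, each = n)]),
                    nrow = n,
                    dimnames = list(paste0(prefix, seq_len(n)),
                                    paste0("m", seq_len(m))))
    p <- colMeans(calls)
    if (sum(p * (1 - p)) > 0) break
  }
  line_genotypes(calls, group)
}

# complete factorial pedigree over two panels
complete_factorial <- function(g1, g2) {
  cr <- expand.grid(parent1 = rownames(g1$calls),
                    parent2 = rownames(g2$calls),
                    stringsAsFactors = FALSE)
  hybrid_pedigree(paste0("H", seq_len(nrow(cr))), cr$parent1, cr$parent2)
}

# random locus_spec with interior frequencies
random_locus <- function() {
  locus_spec(a1 = rnorm(1), a2 = rnorm(1), d = rnorm(1),
             p1 = runif(1, 0.05, 0.95), p2 = runif(1, 0.05, 0.95))
}

# tiny two-group study bundle used by io/encoding/kinship tests
toy_study <- function(n1 = 6, n2 = 4, m = 30, seed = 99) {
  set.seed(seed)
  g1 <- toy_panel(n1, m, "dent", prefix = "D")
  g2 <- toy_panel(n2, m, "flint", prefix = "F")
  list(g1 = g1, g2 = g2, ped = complete_factorial(g1, g2))
}
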