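# Small fixture builders shared across test files.

# bare labeled matrix with hand-set values
tiny_em <- function(values, labels = NULL) {
  rownames(values) <- paste0("g", seq_len(nrow(values)))
  colnames(values) <- paste0("s", seq_len(ncol(values)))
  expression_matrix(values, labels = labels)
}

# two-class Gaussian matrix with a given per-gene tumor shift (first
# n_signal genes), already strictly positive; bypasses the generator for
# tests that need full control of the distribution
shifted_em <- function(n_genes = 30, n_tumor = 30, n_normal = 10,
                       n_signal = 3, shift = 3, seed = 1) {
  withr::with_seed(seed, {
    v <- matrix(abs(rnorm(n_genes * (n_tumor + n_normal))) + 0.1,
                nrow = n_genes)
    v[seq_len(n_signal), seq_len(n_tumor)] <-
      v[seq_len(n_signal), seq_len(n_tumor)] + shift
    dimnames(v) <- list(sprintf("g%03d", seq_len(n_genes)),
                        c(sprintf("t%03d", seq_len(n_tumor)),
                          sprintf("n%03d", seq_len(n_normal))))
    expression_matrix(v, labels = c(rep("tumor", n_tumor),
                                    rep("normal", n_normal)))
  })
}

quiet <- function(code) {
  withr::with_options(list(treeDEG.verbose = FALSE), code)
}
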