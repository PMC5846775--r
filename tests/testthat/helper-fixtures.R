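# Small fixtures built in code, shared across test files.

# A compact proteome matching the generator's error model, for tests that
# need a quick normalization rather than the full-size study emulation.
smallProteome <- function(seed = 1, nProteins = 150, nDifferential = 15,
                          nProteases = 8, ...) {
  simulateProteome(synthProteomeConfig(nProteins = nProteins,
                                       nDifferential = nDifferential,
                                       nProteases = nProteases,
                                       seed = seed, ...))
}

# Two well-separated classes in a given number of features.
separatedClasses <- function(n1 = 10, n2 = 10, p = 3, gap = 10, seed = 1) {
  set.seed(seed)
  x <- rbind(matrix(rnorm(n1 * p), n1, p),
             matrix(rnorm(n2 * p, mean = gap), n2, p))
  colnames(x) <- paste0("f", seq_len(p))
  list(x = x, labels = factor(rep(c("a", "b"), c(n1, n2))))
}
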