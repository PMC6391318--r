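# independent brute-force oracle for the exact HWE test: probability of
# each genotype configuration with the observed allele counts, from
# multinomial ordered-assignment counting
hwe_brute_force_p <- function(g) {
  n <- sum(g)
  n_ref <- 2 * g[1] + g[2]
  configs <- list()
  for (het in 0:n) {
    hom_ref <- (n_ref - het) / 2
    hom_alt <- n - hom_ref - het
    if (hom_ref < 0 || hom_alt < 0 || hom_ref != round(hom_ref)) next
    configs[[length(configs) + 1]] <- c(hom_ref, het, hom_alt)
  }
  ways <- vapply(configs, function(cf) {
    exp(lgamma(n + 1) - sum(lgamma(cf + 1)) + cf[2] * log(2))
  }, 0)
  probs <- ways / sum(ways)
  obs <- which(vapply(configs, function(cf) all(cf == g), TRUE))
  sum(probs[probs <= probs[obs] * (1 + 1e-7)])
}
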