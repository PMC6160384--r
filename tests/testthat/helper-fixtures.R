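# Shared small fixtures, built once per test run.

ref5 <- build_reference(5, seed = 1)
ref20 <- build_reference(20, seed = 1)

# profiles-table constructor for screen-level unit tests
make_profiles <- function(ids, canonical, i5, i3, i53, i3e) {
  tot <- canonical + i5 + i3 + i53 + i3e
  data.frame(
    mirna_id = ids, precursor_id = sub("-[53]p$", "", ids), arm = "5p",
    annotated = TRUE, total_count = tot, canonical = canonical,
    isomir_5p = i5, isomir_3p = i3, isomir_53p = i53, isomir_3e = i3e,
    top_variant_count = canonical, stringsAsFactors = FALSE)
}

# independent textbook chi-square on a 2 x k table
chi2_oracle <- function(m) {
  E <- outer(rowSums(m), colSums(m)) / sum(m)
  sum((m - E)^2 / E)
}

# independent log-gamma hypergeometric upper tail (direct summation)
hyper_oracle <- function(x, n, K, N) {
  ks <- x:min(n, K)
  sum(exp(lchoose(K, ks) + lchoose(N - K, n - ks) - lchoose(N, n)))
}
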