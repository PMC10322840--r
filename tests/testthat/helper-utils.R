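collapse_chars <- function(x) paste(x, collapse = "")

sample_aa <- function(n, seed, alphabet = strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]) {
  withr::with_seed(seed, sample(alphabet, n, replace = TRUE))
}

# shared fixtures (templates are deterministic, build once per test run)
braf <- braf_reference()
pl_ksr3 <- ksr3_reference("Pl")
sk_ksr3 <- ksr3_reference("Sk")
nv_ksr3 <- ksr3_reference("Nv")
pl_ksr1 <- ksr1_reference()
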