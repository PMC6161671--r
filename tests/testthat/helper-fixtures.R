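# Small fixtures built in code, shared across test files.

# 3 genes x 2 samples Ct matrix with a reference row
tiny_ct <- function() {
  ct <- rbind(G1 = c(25, 24), G2 = c(20, 26), REF = c(20, 20))
  colnames(ct) <- c("S1", "S2")
  ct_matrix(ct, "REF")
}

# two-latent-factor gene expression simulator used by the factor-model
# tests: genes load 0.9 on their own factor, Gaussian noise on top
simulate_two_factor <- function(n = 200, genes_per_factor = 15,
                                loading = 0.9, noise_sd = 0.3,
                                n_factors = 2, seed = 1) {
  set.seed(seed)
  f <- matrix(rnorm(n * n_factors), n, n_factors)
  per <- rep(seq_len(n_factors), each = genes_per_factor)
  x <- loading * t(f[, per]) +
    rnorm(genes_per_factor * n_factors * n, 0, noise_sd)
  dimnames(x) <- list(
    paste0("G", seq_len(n_factors * genes_per_factor)),
    paste0("S", seq_len(n)))
  # x is on the reflected scale; store as raw delta-Ct
  structure(list(dct = -x, reflected = FALSE, reference_gene = "REF"),
            class = "dct_matrix")
}

# the published confusion matrices, reconstructed from printed
# sensitivity/specificity and the 19/86 progression split
youden_confusion <- function() c(tp = 18, fp = 34, fn = 1, tn = 52)
rulein_confusion <- function() c(tp = 13, fp = 17, fn = 6, tn = 69)
ultrasound_confusion <- function() c(tp = 7, fp = 14, fn = 13, tn = 83)

# small synthetic cohort scaled down for fast end-to-end tests
small_cohort_config <- function(seed = 1) {
  cohort_config(n_at_risk = 60L, n_hc = 20L, n_sle = 20L,
                progression_rate = 0.2, missing_fraction = 0.1,
                m = 3L, seed = seed)
}
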