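# small in-code fixtures shared across test files

# 2 samples x 3 sites matrix with known values
tiny_matrix <- function() {
  m <- matrix(c(0.1, 0.2, 0.3, 0.4, 0.5, 0.6), nrow = 2, byrow = TRUE,
              dimnames = list(c("s1", "s2"), c("cg1", "cg2", "cg3")))
  methyl_matrix(m)
}

tiny_metadata <- function() {
  data.frame(sample_id = c("s1", "s2"), tissue = c("brain", "brain"),
             status = c(0L, 1L), stringsAsFactors = FALSE)
}

# one-tissue cohort whose group medians at one site are exactly (hm, dm):
# three healthy and three disease samples, medians are the middle values
summary_fixture <- function(healthy, disease, site = "cgX",
                            tissue = "brain") {
  n <- length(healthy) + length(disease)
  m <- matrix(c(healthy, disease), ncol = 1,
              dimnames = list(sprintf("s%02d", seq_len(n)), site))
  md <- data.frame(sample_id = rownames(m), tissue = tissue,
                   status = rep(c(0L, 1L), c(length(healthy),
                                             length(disease))),
                   stringsAsFactors = FALSE)
  list(m = methyl_matrix(m), md = md)
}

# cohort of one tissue where the first n_signal sites are shifted by `shift`
# in disease samples: a linearly separable diagnosis problem
separable_cohort <- function(n_per_class = 100, n_sites = 400,
                             n_signal = 40, shift = 0.3, seed = 5) {
  cfg <- cohort_config(tissues = "brain",
                       n_healthy_per_tissue = n_per_class,
                       n_disease_per_tissue = n_per_class,
                       n_sites = n_sites,
                       n_tissue_specific = n_signal,
                       n_disease_specific_per_tissue = n_signal,
                       tissue_shift = 0, disease_shift = shift,
                       seed = seed)
  generate_cohort(cfg)
}

# brute-force pairwise-concordance AUC (ties count one half): the
# independent oracle for roc_auc
auc_bruteforce <- function(truth, scores) {
  pos <- scores[truth == 1]
  neg <- scores[truth == 0]
  s <- 0
  for (p in pos) for (q in neg)
    s <- s + if (p > q) 1 else if (p == q) 0.5 else 0
  s / (length(pos) * length(neg))
}
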