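# Small in-code fixtures shared across the suite.

random_beta_matrix <- function(n_probes = 6, n_samples = 4, seed = 1,
                               missing = 0) {
  withr::with_seed(seed, {
    m <- matrix(runif(n_probes * n_samples), n_probes, n_samples,
                dimnames = list(sprintf("cg%05d", seq_len(n_probes)),
                                sprintf("s%03d", seq_len(n_samples))))
    if (missing > 0) m[sample(length(m), missing)] <- NA_real_
    beta_matrix(m)
  })
}

random_clock <- function(n_cpgs = 5, seed = 2) {
  withr::with_seed(seed, {
    ids <- sprintf("cg%05d", sample.int(99999, n_cpgs))
    ga_clock(intercept = runif(1, 250, 300),
             coefficients = stats::setNames(rnorm(n_cpgs, 0, 20), ids),
             training_medians = stats::setNames(runif(n_cpgs), ids))
  })
}

# One fresh-transfer ART record with internally consistent dates.
art_record <- function(embryo_state = "fresh",
                       birth = as.Date("2010-09-23"),
                       retrieval = as.Date("2010-01-01"),
                       insertion = retrieval + 2,
                       freeze = as.Date(NA)) {
  list(sample_id = "a1", art = TRUE, procedure = "IVF",
       embryo_state = embryo_state, birth_date = birth,
       egg_retrieval_date = retrieval, embryo_insertion_date = insertion,
       freeze_date = freeze, ga_ultrasound_days = 280L)
}

# Lasso objective on the original data scale.
lasso_objective <- function(X, y, intercept, coefs, lambda) {
  eta <- intercept + as.numeric(X[, names(coefs), drop = FALSE] %*% coefs)
  mean((y - eta)^2) / 2 + lambda * sum(abs(coefs))
}
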