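# Shared fixture builders. All randomness is locally seeded so tests are
# order-independent.

rand_matrix <- function(n, m, seed) {
  set.seed(seed)
  expression_matrix(matrix(stats::rlnorm(n * m, meanlog = 6), n, m),
                    feature_ids = sprintf("f%03d", seq_len(n)),
                    sample_ids = sprintf("s%03d", seq_len(m)))
}

rand_norm_matrix <- function(n, m, seed) normalize_samples(rand_matrix(n, m, seed))

balanced_annot <- function(sample_ids, labels = c("A", "B")) {
  m <- length(sample_ids)
  sample_annotation(sample_ids, rep(labels, length.out = m))
}

# independent step-up BH oracle: literal definition, O(m^2)-free but written
# without cummin so it shares no code path with the implementation
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- numeric(m)
  for (k in seq_len(m)) {
    q[k] <- min(1, min(p[o[k:m]] * m / (k:m)))
  }
  out <- numeric(m)
  out[o] <- q
  out
}

# pairwise Mann-Whitney AUC oracle with ties counted 1/2
auc_oracle <- function(scores, pos) {
  sp <- scores[pos]; sn <- scores[!pos]
  cmp <- outer(sp, sn, function(a, b) (a > b) + 0.5 * (a == b))
  mean(cmp)
}

# small cohort for fast end-to-end tests
small_cohort <- function(seed, ...) {
  args <- utils::modifyList(
    list(n_features = 400L, n_class1 = 15L, n_class2 = 15L,
         n_informative = 10L, effect_size = 3.0, noise_sd = 1.0,
         seed = seed),
    list(...))
  do.call(generate_two_class_cohort, args)
}

prep_cohort <- function(cohort) {
  normalize_samples(log_transform(cohort$matrix))
}
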