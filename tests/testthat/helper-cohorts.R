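# Small cohort fixtures shared across test files.

small_spec <- function(seed = 1, ...) {
  args <- utils::modifyList(
    list(n_case_subjects = 12, n_control_subjects = 8,
         reps_per_subject = 3,
         block_sizes = c(a = 6, b = 6, c = 4),
         informative_count = 4, effect_size = 1.5,
         within_block_corr = 0.3, subject_sd = 0.5, noise_sd = 1,
         gender = TRUE, seed = seed),
    list(...))
  do.call(cohort_spec, args)
}

small_cohort <- function(seed = 1, ...) generate_cohort(small_spec(seed, ...))

# tiny transformer settings used wherever a network must actually train
tiny_model_args <- function(...) {
  utils::modifyList(list(embed_dim = 8, n_encoders = 2, n_heads = 1,
                         rho = 2, head_hidden = 16, dropout_p = 0.1),
                    list(...))
}

# six-row two-subject hand table
toy_table <- function() {
  as_dysphonia_tbl(
    data.frame(id = rep(c("s1", "s2"), each = 3),
               class = rep(c(1, 0), each = 3),
               f1 = c(1, 2, 3, 4, 5, 6),
               f2 = c(0.5, 0.1, 0.9, 0.2, 0.8, 0.4),
               f3 = rep(5, 6),
               f4 = c(10, 11, 9, 12, 8, 10)),
    subject_col = "id", label_col = "class")
}
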