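#' Specify a synthetic dysphonia cohort
#'
#' The generator emulates the structure of multi-recording Parkinson's
#' voice studies: each subject contributes several recordings of a
#' sustained phonation, cases outnumber controls roughly 3:1, features
#' come in correlated blocks by measure category (baseline acoustics,
#' MFCCs, wavelet, TQWT, vocal-fold measures), a subset of features carry
#' a class signal, and repeated recordings of one subject are correlated
#' through a subject-level random effect.
#'
#' @param n_case_subjects Number of case (PD) subjects.
#' @param n_control_subjects Number of control subjects.
#' @param reps_per_subject Recordings per subject.
#' @param block_sizes Named integer vector of feature-block sizes; names
#'   are category tags. Defaults sum to 753 features.
#' @param informative_count How many features (the first ones, spread over
#'   the leading blocks) receive a class-mean shift.
#' @param effect_size Mean shift on informative features for cases, in
#'   units of the marginal feature standard deviation.
#' @param within_block_corr Equicorrelation of features inside one block,
#'   in `[0, 1)`.
#' @param subject_sd Standard deviation of the per-subject random effect
#'   shared by all of a subject's recordings (drives intraclass
#'   correlation across repetitions).
#' @param noise_sd Residual per-recording noise standard deviation.
#' @param gender Add an uninformative per-subject gender column?
#' @param seed Integer seed; generation is deterministic given the spec.
#' @return A `vt_cohort_spec` list.
#' @export
cohort_spec <- function(n_case_subjects = 188, n_control_subjects = 64,
                        reps_per_subject = 3,
                        block_sizes = c(baseline = 21, mfcc = 84,
                                        wavelet = 182, tqwt = 432,
                                        vocal_fold = 22, other = 12),
                        informative_count = 20, effect_size = 2,
                        within_block_corr = 0.3, subject_sd = 0.5,
                        noise_sd = 1, gender = TRUE, seed = 1) {
  spec <- list(n_case_subjects = n_case_subjects,
               n_control_subjects = n_control_subjects,
               reps_per_subject = reps_per_subject,
               block_sizes = block_sizes,
               informative_count = informative_count,
               effect_size = effect_size,
               within_block_corr = within_block_corr,
               subject_sd = subject_sd, noise_sd = noise_sd,
               gender = gender, seed = seed)
  validate_cohort_spec(spec)
  structure(spec, class = "vt_cohort_spec")
}

validate_cohort_spec <- function(spec) {
  with(spec, {
    stopifnot(n_case_subjects >= 1, n_control_subjects >= 1,
              reps_per_subject >= 1, all(block_sizes >= 1),
              within_block_corr >= 0, within_block_corr < 1,
              informative_count >= 0,
              informative_count <= sum(block_sizes),
              subject_sd >= 0, noise_sd >= 0)
  })
  invisible(spec)
}

cohort_feature_names <- function(spec) {
  tags <- names(spec$block_sizes)
  if (is.null(tags)) tags <- paste0("block", seq_along(spec$block_sizes))
  unlist(lapply(seq_along(spec$block_sizes), function(b) {
    sprintf("%s_%03d", tags[b], seq_len(spec$block_sizes[b]))
  }), use.names = FALSE)
}

#' Generate a synthetic dysphonia cohort
#'
#' Each feature value is the sum of a block-wise equicorrelated standard
#' Gaussian (correlation `within_block_corr` inside a block), the
#' subject's scalar random effect `~ N(0, subject_sd^2)`, and recording
#' noise `~ N(0, noise_sd^2)`. Informative features additionally shift by
#' `effect_size` marginal standard deviations for cases. Cases are labeled
#' 1, controls 0.
#'
#' @param spec A `vt_cohort_spec` from [cohort_spec()].
#' @return A `dysphonia_tbl` with
#'   `(n_case_subjects + n_control_subjects) * reps_per_subject` rows.
#' @export
generate_cohort <- function(spec) {
  validate_cohort_spec(spec)
  n_subj <- spec$n_case_subjects + spec$n_control_subjects
  m <- n_subj * spec$reps_per_subject
  n_feat <- sum(spec$block_sizes)
  rho <- spec$within_block_corr

  withr::with_seed(spec$seed, {
    subj_label <- c(rep(1L, spec$n_case_subjects),
                    rep(0L, spec$n_control_subjects))
    subj_id <- sprintf("S%03d", seq_len(n_subj))
    u <- stats::rnorm(n_subj, 0, spec$subject_sd)

    # equicorrelated block: sqrt(rho) * shared factor + sqrt(1-rho) * own
    x <- matrix(0, m, n_feat)
    col0 <- 0L
    for (b in seq_along(spec$block_sizes)) {
      p <- spec$block_sizes[b]
      shared <- stats::rnorm(m)
      own <- matrix(stats::rnorm(m * p), m, p)
      x[, col0 + seq_len(p)] <- sqrt(rho) * shared + sqrt(1 - rho) * own
      col0 <- col0 + p
    }
    rep_idx <- rep(seq_len(n_subj), each = spec$reps_per_subject)
    x <- x + u[rep_idx] + matrix(stats::rnorm(m * n_feat, 0, spec$noise_sd),
                                 m, n_feat)

    marg_sd <- sqrt(1 + spec$subject_sd^2 + spec$noise_sd^2)
    label <- subj_label[rep_idx]
    if (spec$informative_count > 0) {
      shift <- spec$effect_size * marg_sd
      inf <- seq_len(spec$informative_count)
      x[label == 1L, inf] <- x[label == 1L, inf] + shift
    }

    colnames(x) <- cohort_feature_names(spec)
    df <- tibble::tibble(subject_id = subj_id[rep_idx], label = label)
    if (isTRUE(spec$gender)) {
      g <- sample(c("M", "F"), n_subj, replace = TRUE)
      df$gender <- g[rep_idx]
    }
    df <- dplyr::bind_cols(df, tibble::as_tibble(x))
    as_dysphonia_tbl(df, subject_col = "subject_id", label_col = "label",
                     gender_col = if (isTRUE(spec$gender)) "gender")
  })
}

#' Ground-truth informative feature names of a cohort spec
#'
#' For selector-recovery tests: returns the names of the features that
#' [generate_cohort()] shifts between classes.
#'
#' @param spec A `vt_cohort_spec`.
#' @return Character vector of length `informative_count`.
#' @export
oracle_informative_features <- function(spec) {
  validate_cohort_spec(spec)
  utils::head(cohort_feature_names(spec), spec$informative_count)
}
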