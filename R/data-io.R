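#' Build a dysphonia table from a data frame
#'
#' A dysphonia table is a tibble with one row per voice recording: a
#' `subject_id` column, a binary `label` column (1 = Parkinson's disease,
#' the positive and majority class; 0 = healthy), an optional `gender`
#' column, and any number of continuous feature columns. All recordings of
#' one subject must carry the same label.
#'
#' @param df A data frame or tibble.
#' @param subject_col Name of the subject-identifier column.
#' @param label_col Name of the binary class column.
#' @param gender_col Name of the gender column, or `NULL` if absent.
#' @param na_policy What to do with rows containing missing or non-numeric
#'   feature values: `"reject"` (drop the row, the default) or `"error"`.
#' @return A `dysphonia_tbl`: a tibble with columns `subject_id`, `label`,
#'   optionally `gender`, then the feature columns in their original order.
#' @export
as_dysphonia_tbl <- function(df, subject_col = "id", label_col = "class",
                             gender_col = NULL,
                             na_policy = c("reject", "error")) {
  na_policy <- match.arg(na_policy)
  stopifnot(is.data.frame(df))
  if (!subject_col %in% names(df)) {
    stop("subject column '", subject_col, "' not found", call. = FALSE)
  }
  if (!label_col %in% names(df)) {
    stop("label column '", label_col, "' not found", call. = FALSE)
  }
  meta_cols <- c(subject_col, label_col, gender_col)
  feat_cols <- setdiff(names(df), meta_cols)
  if (length(feat_cols) == 0L) stop("no feature columns", call. = FALSE)

  out <- tibble::tibble(
    subject_id = as.character(df[[subject_col]]),
    label = as.integer(df[[label_col]])
  )
  if (!is.null(gender_col)) out$gender <- as.character(df[[gender_col]])
  feats <- df[feat_cols]
  feats[] <- lapply(feats, function(x) suppressWarnings(as.numeric(x)))
  out <- dplyr::bind_cols(out, feats)

  bad <- !stats::complete.cases(feats) | is.na(out$label)
  if (any(bad)) {
    if (na_policy == "error") {
      stop(sum(bad), " row(s) with missing or non-numeric values", call. = FALSE)
    }
    warning(sum(bad), " row(s) rejected (missing or non-numeric values)",
            call. = FALSE)
    out <- out[!bad, , drop = FALSE]
  }
  if (!all(out$label %in% c(0L, 1L))) {
    stop("label must be binary 0/1", call. = FALSE)
  }
  lab_per_subj <- tapply(out$label, out$subject_id, function(l) length(unique(l)))
  if (any(lab_per_subj > 1L)) {
    stop("subject(s) with inconsistent labels: ",
         paste(names(lab_per_subj)[lab_per_subj > 1L], collapse = ", "),
         call. = FALSE)
  }
  structure(out, class = c("dysphonia_tbl", class(tibble::as_tibble(out))))
}

#' Read a dysphonia CSV file
#'
#' Expects a header row; the subject-id and label columns are named by the
#' caller (matching the UCI Parkinson's speech file layout, where `id` and
#' `class` bracket 753 feature columns), every remaining column is treated
#' as a continuous feature.
#'
#' @inheritParams as_dysphonia_tbl
#' @param path Path to a CSV file (UTF-8, "." decimal separator).
#' @return A `dysphonia_tbl`.
#' @export
read_dysphonia_csv <- function(path, subject_col = "id", label_col = "class",
                               gender_col = NULL,
                               na_policy = c("reject", "error")) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  as_dysphonia_tbl(df, subject_col = subject_col, label_col = label_col,
                   gender_col = gender_col, na_policy = na_policy)
}

#' Feature column names of a dysphonia table
#' @param data A `dysphonia_tbl`.
#' @param include_gender Treat a `gender` column as a feature too?
#' @return Character vector of feature names, in table order.
#' @export
feature_names <- function(data, include_gender = FALSE) {
  drop <- c("subject_id", "label", if (!include_gender) "gender")
  setdiff(names(data), drop)
}

#' Extract the feature matrix of a dysphonia table
#' @inheritParams feature_names
#' @return Numeric matrix, m samples by n features.
#' @export
feature_matrix <- function(data, include_gender = FALSE) {
  fn <- feature_names(data, include_gender = include_gender)
  x <- data[fn]
  if ("gender" %in% fn) {
    # gender enters as an indicator so tree/linear rankers can score it
    x$gender <- as.numeric(factor(x$gender)) - 1
  }
  as.matrix(x)
}

#' Fit per-feature standardization parameters
#'
#' Computes the mean mu_j and standard deviation sigma_j of every feature
#' column over the given rows, for the z-score transform
#' chi_ij = (x_ij - mu_j) / sigma_j.
#'
#' @param data A `dysphonia_tbl`.
#' @param rows Integer row indices to fit on (default: all rows). Use a
#'   training fold's rows for leakage-safe per-fold standardization.
#' @param convention `"population"` (divide by m, the default — idempotent
#'   on the fitted rows) or `"sample"` (divide by m - 1).
#' @return A `vt_standardizer`: tibble with columns `feature`, `mu`,
#'   `sigma`, carrying the fit convention and row scope as attributes.
#' @export
fit_standardizer <- function(data, rows = NULL,
                             convention = c("population", "sample")) {
  convention <- match.arg(convention)
  x <- feature_matrix(data)
  if (is.null(rows)) rows <- seq_len(nrow(x))
  if (length(rows) == 0L) stop("empty row subset", call. = FALSE)
  xs <- x[rows, , drop = FALSE]
  mu <- colMeans(xs)
  ss <- colMeans(sweep(xs, 2, mu)^2)
  if (convention == "sample" && nrow(xs) > 1L) {
    ss <- ss * nrow(xs) / (nrow(xs) - 1L)
  }
  out <- tibble::tibble(feature = colnames(x), mu = unname(mu),
                        sigma = unname(sqrt(ss)))
  structure(out,
            class = c("vt_standardizer", class(out)),
            convention = convention,
            fit_rows = if (length(rows) == nrow(x)) "all" else "subset")
}

#' Apply a fitted standardizer to a dysphonia table
#'
#' Zero-variance features (sigma_j = 0) are mapped to 0 with a warning
#' rather than dividing by zero.
#'
#' @param data A `dysphonia_tbl`.
#' @param params A `vt_standardizer` from [fit_standardizer()].
#' @return The table with feature columns standardized.
#' @export
apply_standardizer <- function(data, params) {
  fn <- feature_names(data)
  if (!identical(sort(params$feature), sort(fn))) {
    stop("standardizer features do not match the table", call. = FALSE)
  }
  p <- params[match(fn, params$feature), ]
  zero <- p$sigma == 0
  if (any(zero)) {
    warning("zero-variance feature(s) set to 0: ",
            paste(p$feature[zero], collapse = ", "), call. = FALSE)
  }
  sigma <- ifelse(zero, 1, p$sigma)
  x <- as.matrix(data[fn])
  x <- sweep(sweep(x, 2, p$mu), 2, sigma, "/")
  x[, zero] <- 0
  data[fn] <- as.data.frame(x)
  data
}

#' Subject-grouped stratified k-fold plan
#'
#' Every subject's recordings land in exactly one fold, so no subject ever
#' spans a training and a test set. Stratification is at subject level:
#' within each class, subjects are shuffled with the seed and dealt
#' round-robin to folds, so per-fold class proportions (counted in
#' subjects) differ from the global proportion by at most one subject.
#'
#' @param data A `dysphonia_tbl`.
#' @param k Number of folds (>= 2).
#' @param seed Integer seed controlling the shuffle.
#' @return A `vt_fold_plan`: tibble with columns `subject_id`, `label`,
#'   `fold`, plus `k` and `seed` attributes.
#' @export
make_grouped_stratified_folds <- function(data, k = 10, seed = 1) {
  stopifnot(k >= 2)
  subj <- dplyr::distinct(tibble::as_tibble(data)[c("subject_id", "label")])
  n_by_class <- table(subj$label)
  if (length(n_by_class) < 2L) stop("need both classes", call. = FALSE)
  if (any(n_by_class < k)) {
    stop("each class needs at least k = ", k, " subjects (have ",
         paste(n_by_class, collapse = "/"), ")", call. = FALSE)
  }
  plan <- withr::with_seed(seed, {
    dplyr::bind_rows(lapply(split(subj, subj$label), function(s) {
      s <- s[sample.int(nrow(s)), , drop = FALSE]
      s$fold <- rep_len(seq_len(k), nrow(s))
      s
    }))
  })
  plan <- dplyr::arrange(plan, .data$subject_id)
  structure(plan, class = c("vt_fold_plan", class(plan)), k = k, seed = seed)
}

#' Row indices of one fold's train/test split
#' @param data A `dysphonia_tbl`.
#' @param plan A `vt_fold_plan`.
#' @param fold Fold index in `1:k`.
#' @return List with integer vectors `train` and `test`.
#' @export
fold_rows <- function(data, plan, fold) {
  k <- attr(plan, "k")
  stopifnot(fold >= 1, fold <= k)
  test_subj <- plan$subject_id[plan$fold == fold]
  test <- which(data$subject_id %in% test_subj)
  list(train = setdiff(seq_len(nrow(data)), test), test = test)
}
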