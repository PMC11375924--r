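#' Construct a pairwise linear-fit model
#'
#' The normative model behind the desynchronization index: one straight line
#' per unordered VOI pair, in the canonical orientation with the
#' lower-indexed VOI (by the model's VOI list order) on the abscissa and the
#' higher-indexed VOI on the ordinate. Used directly by tests and as the
#' return type of [fit_pair_models()].
#'
#' @param vois Character vector of VOI ids (defines the canonical order).
#' @param slope,intercept Numeric matrices (`length(vois)` square); only the
#'   upper triangle (`i < j`: response `vois[j]` on abscissa `vois[i]`) is
#'   used.
#' @param n_rep Number of bootstrap resamples behind the fit (0 for an
#'   analytic model).
#' @param training_cohort Label of the cohort the fits were trained on.
#' @param seed Seed used for the bootstrap.
#' @return An object of class `pairwise_fit_model`.
#' @export
pairwise_fit_model <- function(vois, slope, intercept, n_rep = 0L,
                               training_cohort = NA_character_,
                               seed = NA_integer_) {
  p <- length(vois)
  stopifnot(is.matrix(slope), is.matrix(intercept),
            all(dim(slope) == p), all(dim(intercept) == p))
  ut <- upper.tri(slope)
  if (any(!is.finite(slope[ut])) || any(!is.finite(intercept[ut]))) {
    msync_abort("non-finite slope/intercept in pair model",
                class = "microsync_validation_error")
  }
  dimnames(slope) <- dimnames(intercept) <- list(vois, vois)
  structure(
    list(vois = vois, slope = slope, intercept = intercept,
         n_rep = as.integer(n_rep), training_cohort = training_cohort,
         seed = seed),
    class = "pairwise_fit_model"
  )
}

#' @export
print.pairwise_fit_model <- function(x, ...) {
  cat(sprintf("<pairwise_fit_model> %d VOIs (%d pairs), %d bootstrap resamples, trained on %s\n",
              length(x$vois), choose(length(x$vois), 2), x$n_rep,
              x$training_cohort))
  invisible(x)
}

#' Train normative pairwise linear fits on a reference cohort
#'
#' For every unordered VOI pair, fits an ordinary least-squares line of the
#' higher-indexed VOI on the lower-indexed VOI within each bootstrap resample
#' of the training subjects; the model slope and intercept are the means over
#' valid resamples (mean of the bootstrap fits). Resamples in which the
#' abscissa VOI has zero variance leave the fit undefined and are excluded;
#' a pair degenerate in more than half of the resamples raises an error
#' naming the pair.
#'
#' @param train Training [uptake_table()] (>= 3 subjects), typically SUVR.
#' @param voi_subset Optional VOI ids to restrict to (order defines the
#'   canonical pair orientation); default: all table VOIs in table order.
#' @param n_rep Number of bootstrap resamples (10000 in the reference
#'   analysis).
#' @param seed Integer seed.
#' @param identity_resample If `TRUE`, uses the identity resample in every
#'   replicate; with `n_rep = 1` the model equals the plain OLS fit.
#' @return A [pairwise_fit_model()].
#' @export
fit_pair_models <- function(train, voi_subset = NULL, n_rep = 10000,
                            seed = 1L, identity_resample = FALSE) {
  stopifnot(inherits(train, "uptake_table"))
  if (!is.null(voi_subset)) {
    train <- subset_vois(train, voi_subset)
  }
  X <- train$values
  n <- nrow(X)
  p <- ncol(X)
  if (n < 3) {
    msync_abort("training requires at least 3 subjects",
                class = "microsync_validation_error")
  }
  idx <- if (identity_resample) {
    matrix(rep(seq_len(n), each = n_rep), nrow = n_rep)
  } else {
    bootstrap_resample(n, n_rep, seed)
  }
  m_sum <- matrix(0, p, p)
  b_sum <- matrix(0, p, p)
  cnt <- matrix(0L, p, p)
  for (k in seq_len(n_rep)) {
    Xk <- X[idx[k, ], , drop = FALSE]
    C <- stats::cov(Xk)
    v <- diag(C)
    mu <- colMeans(Xk)
    M <- C / v                       # M[i, j] = slope of VOI j on VOI i
    B <- matrix(mu, p, p, byrow = TRUE) - M * mu
    valid <- matrix(v > 0, p, p)     # abscissa variance per row i
    good <- valid & is.finite(M) & is.finite(B)
    m_sum[good] <- m_sum[good] + M[good]
    b_sum[good] <- b_sum[good] + B[good]
    cnt[good] <- cnt[good] + 1L
  }
  frac_invalid <- 1 - cnt / n_rep
  ut <- which(upper.tri(cnt), arr.ind = TRUE)
  bad <- frac_invalid[upper.tri(cnt)] > 0.5
  if (any(bad)) {
    i <- ut[which(bad)[1], ]
    msync_abort("pair (", train$vois[i[1]], ", ", train$vois[i[2]],
                ") degenerate in > 50% of resamples",
                class = "microsync_degenerate_error")
  }
  slope <- m_sum / cnt
  intercept <- b_sum / cnt
  n_excluded <- sum((n_rep - cnt)[upper.tri(cnt)])
  if (n_excluded > 0) {
    msync_log("fit_pair_models: excluded ", n_excluded,
              " zero-variance pair-resamples")
  }
  pairwise_fit_model(train$vois, slope, intercept, n_rep = n_rep,
                     training_cohort = attr(train, "cohort") %||% NA_character_,
                     seed = if (identity_resample) NA_integer_ else as.integer(seed))
}

#' Perpendicular distance from a point to a line
#'
#' Orthogonal point-to-line distance from `(x0, y0)` to `y = m x + b`:
#' `|m x0 - y0 + b| / sqrt(m^2 + 1)`. Vectorized over all arguments.
#'
#' @param x0,y0 Point coordinates.
#' @param m,b Line slope and intercept.
#' @return Non-negative distance(s).
#' @export
perpendicular_distance <- function(x0, y0, m, b) {
  abs(m * x0 - y0 + b) / sqrt(m^2 + 1)
}

#' Desynchronization index of one subject
#'
#' For each unordered VOI pair, the perpendicular distance from the subject's
#' pair of uptake values to the pair's normative line is computed once (from
#' the canonical fit) and credited to both member VOIs. The desynchronization
#' index of VOI `i` is the sum of the distances of the `N - 1` pairs
#' containing `i`. It is expressed in the units of the uptake values (SUVR).
#'
#' @param subject_row Named numeric vector of uptake values covering all
#'   model VOIs.
#' @param model A [pairwise_fit_model()].
#' @return Named numeric vector of per-VOI index values (all >= 0).
#' @export
desynchronization_index <- function(subject_row, model) {
  stopifnot(inherits(model, "pairwise_fit_model"))
  if (is.null(names(subject_row))) {
    if (length(subject_row) != length(model$vois)) {
      msync_abort("unnamed subject row must match the model VOI count",
                  class = "microsync_validation_error")
    }
    names(subject_row) <- model$vois
  }
  missing <- setdiff(model$vois, names(subject_row))
  if (length(missing) > 0) {
    msync_abort("subject row missing VOI(s): ",
                paste(missing, collapse = ", "),
                class = "microsync_validation_error")
  }
  x <- subject_row[model$vois]
  p <- length(x)
  ut <- upper.tri(model$slope)
  D <- matrix(NA_real_, p, p)
  Xi <- matrix(x, p, p)              # abscissa value x_i in row i
  Xj <- matrix(x, p, p, byrow = TRUE) # ordinate value x_j in column j
  D[ut] <- perpendicular_distance(Xi[ut], Xj[ut],
                                  model$slope[ut], model$intercept[ut])
  di <- rowSums(D, na.rm = TRUE) + colSums(D, na.rm = TRUE)
  stats::setNames(di, model$vois)
}

#' Score all subjects of a table against a normative model
#'
#' @param table An [uptake_table()] whose VOIs cover the model VOIs.
#' @param model A [pairwise_fit_model()].
#' @param reference_mode Provenance tag, `"external_train"` (default) or
#'   `"leave_one_out"`.
#' @return A `di_table`: fields `subjects`, `vois`, `values`
#'   (subjects x VOIs matrix of index values) and `reference_mode`.
#' @export
score_subjects <- function(table, model, reference_mode = "external_train") {
  stopifnot(inherits(table, "uptake_table"))
  vals <- t(apply(table$values, 1, desynchronization_index, model = model))
  colnames(vals) <- model$vois
  di_table(vals, reference_mode = reference_mode)
}

#' Construct a desynchronization-index table
#'
#' @param values Numeric matrix (subjects x VOIs) of non-negative index
#'   values with dimnames.
#' @param reference_mode `"external_train"` or `"leave_one_out"`.
#' @return An object of class `di_table`.
#' @export
di_table <- function(values, reference_mode = c("external_train", "leave_one_out")) {
  reference_mode <- match.arg(reference_mode)
  stopifnot(is.matrix(values), !is.null(rownames(values)), !is.null(colnames(values)))
  if (any(!is.finite(values) | values < 0)) {
    msync_abort("index values must be finite and non-negative",
                class = "microsync_validation_error")
  }
  structure(
    list(subjects = rownames(values), vois = colnames(values),
         values = values, reference_mode = reference_mode),
    class = "di_table"
  )
}

#' @export
print.di_table <- function(x, ...) {
  cat(sprintf("<di_table> %d subjects x %d VOIs (reference mode: %s)\n",
              length(x$subjects), length(x$vois), x$reference_mode))
  invisible(x)
}

#' Combine desynchronization-index tables by row
#'
#' @param ... `di_table` objects over identical VOI lists.
#' @param reference_mode Tag for the combined table; defaults to
#'   `"external_train"` when the inputs disagree.
#' @return A `di_table` holding all subjects.
#' @export
rbind_di <- function(..., reference_mode = NULL) {
  tabs <- list(...)
  stopifnot(length(tabs) >= 1, all(vapply(tabs, inherits, logical(1), "di_table")))
  vois <- tabs[[1]]$vois
  vals <- do.call(rbind, lapply(tabs, function(t) t$values[, vois, drop = FALSE]))
  modes <- unique(vapply(tabs, `[[`, character(1), "reference_mode"))
  di_table(vals, reference_mode = reference_mode %||%
             if (length(modes) == 1) modes else "external_train")
}

#' Leave-one-out scoring of a reference cohort
#'
#' Scores each subject of the reference cohort with normative fits trained on
#' the remaining subjects, yielding an unbiased within-cohort index
#' distribution. Fold `k` trains [fit_pair_models()] on `n - 1` subjects with
#' a fold-specific seed derived from `seed` and scores the left-out subject.
#'
#' @param reference An [uptake_table()] with >= 4 subjects.
#' @param voi_subset Optional VOI subset passed to [fit_pair_models()].
#' @param n_rep Bootstrap resamples per fold.
#' @param seed Integer base seed (fold `k` uses `seed + k`).
#' @return A `di_table` with `reference_mode = "leave_one_out"` and one row
#'   per reference subject.
#' @export
loo_reference_di <- function(reference, voi_subset = NULL, n_rep = 10000,
                             seed = 1L) {
  stopifnot(inherits(reference, "uptake_table"))
  n <- length(reference$subjects)
  if (n < 4) {
    msync_abort("leave-one-out referencing requires >= 4 subjects",
                class = "microsync_validation_error")
  }
  if (!is.null(voi_subset)) {
    reference <- subset_vois(reference, voi_subset)
  }
  rows <- vector("list", n)
  for (k in seq_len(n)) {
    train <- uptake_table(reference$values[-k, , drop = FALSE],
                          normalization = reference$normalization)
    model <- fit_pair_models(train, n_rep = n_rep, seed = seed + k)
    rows[[k]] <- desynchronization_index(reference$values[k, ], model)
  }
  vals <- do.call(rbind, rows)
  rownames(vals) <- reference$subjects
  di_table(vals, reference_mode = "leave_one_out")
}
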