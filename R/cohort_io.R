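#' Construct a validated uptake table
#'
#' An uptake table holds mean regional tracer uptake for a set of subjects:
#' one row per subject, one column per volume of interest (VOI). Values are
#' strictly positive; raw tables carry arbitrary activity units, normalized
#' tables are unitless uptake ratios (SUVR).
#'
#' @param values Numeric matrix (subjects x VOIs) with row names holding
#'   subject identifiers and column names holding VOI identifiers.
#' @param normalization One of `"raw"`, `"global_mean"`, `"myocardium"`,
#'   `"best_reference"`; records how the table was scaled.
#' @return An object of class `uptake_table` with fields `subjects`, `vois`,
#'   `values` and `normalization`.
#' @export
uptake_table <- function(values,
                         normalization = c("raw", "global_mean",
                                           "myocardium", "best_reference")) {
  normalization <- match.arg(normalization)
  if (!is.matrix(values) || !is.numeric(values)) {
    msync_abort("`values` must be a numeric matrix", class = "microsync_format_error")
  }
  subjects <- rownames(values)
  vois <- colnames(values)
  if (is.null(subjects) || is.null(vois)) {
    msync_abort("`values` must carry subject row names and VOI column names",
                class = "microsync_format_error")
  }
  if (anyDuplicated(subjects)) {
    msync_abort("duplicated subject identifier: ",
                paste(unique(subjects[duplicated(subjects)]), collapse = ", "),
                class = "microsync_format_error")
  }
  if (anyDuplicated(vois)) {
    msync_abort("duplicated VOI identifier: ",
                paste(unique(vois[duplicated(vois)]), collapse = ", "),
                class = "microsync_format_error")
  }
  bad <- which(!is.finite(values) | values <= 0, arr.ind = TRUE)
  if (nrow(bad) > 0) {
    msync_abort("non-positive or non-finite uptake for subject '",
                subjects[bad[1, 1]], "', VOI '", vois[bad[1, 2]], "'",
                class = "microsync_validation_error")
  }
  structure(
    list(subjects = subjects, vois = vois, values = values,
         normalization = normalization),
    class = "uptake_table"
  )
}

#' @export
print.uptake_table <- function(x, ...) {
  cat(sprintf("<uptake_table> %d subjects x %d VOIs (normalization: %s)\n",
              length(x$subjects), length(x$vois), x$normalization))
  invisible(x)
}

#' @export
dim.uptake_table <- function(x) dim(x$values)

#' Read an uptake table from delimited text
#'
#' Expects a wide table: first column `subject_id`, remaining columns one per
#' VOI. Comma-delimited by default; tab accepted via `sep`.
#'
#' @param path Path to the file.
#' @param sep Field separator, `","` (default) or `"\t"`.
#' @param normalization Normalization tag to attach (files do not carry it).
#' @return An [uptake_table()].
#' @export
read_uptake_table <- function(path, sep = ",", normalization = "raw") {
  if (!file.exists(path)) {
    msync_abort("uptake table not found: ", path, class = "microsync_io_error")
  }
  header <- strsplit(readLines(path, n = 1), sep, fixed = TRUE)[[1]]
  if (anyDuplicated(header[-1])) {
    msync_abort("duplicated VOI column in header: ",
                paste(unique(header[-1][duplicated(header[-1])]), collapse = ", "),
                class = "microsync_format_error")
  }
  df <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                          stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  if (ncol(df) < 2 || names(df)[1] != "subject_id") {
    msync_abort("first column must be `subject_id`, followed by VOI columns",
                class = "microsync_format_error")
  }
  vois <- names(df)[-1]
  for (v in vois) {
    if (!is.numeric(df[[v]])) {
      msync_abort("non-numeric uptake in VOI column '", v, "'",
                  class = "microsync_validation_error")
    }
  }
  values <- as.matrix(df[, -1, drop = FALSE])
  rownames(values) <- as.character(df$subject_id)
  uptake_table(values, normalization = normalization)
}

#' Write an uptake table to delimited text
#'
#' Inverse of [read_uptake_table()]: round-tripping preserves values to full
#' precision (numbers are serialized with 17 significant digits).
#'
#' @param table An [uptake_table()].
#' @param path Output path.
#' @param sep Field separator.
#' @return `path`, invisibly.
#' @export
write_uptake_table <- function(table, path, sep = ",") {
  stopifnot(inherits(table, "uptake_table"))
  df <- data.frame(subject_id = table$subjects, check.names = FALSE,
                   stringsAsFactors = FALSE)
  for (j in seq_along(table$vois)) {
    df[[table$vois[j]]] <- format(table$values[, j], digits = 17,
                                  scientific = TRUE, trim = TRUE)
  }
  utils::write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' Construct or read atlas metadata
#'
#' Atlas metadata maps each VOI to a compartment label (mouse scheme:
#' `cortical` / `subcortical`; human scheme: `parietal` / `temporal` /
#' `motor_sensory`) and a hemisphere (`L`, `R` or `bilateral`). Compartment
#' labels drive the classification of significant connections.
#'
#' @param voi_id Character vector of unique VOI identifiers.
#' @param compartment Character vector of compartment labels.
#' @param hemisphere Character vector in `{"L","R","bilateral"}`.
#' @return A `data.frame` of class `atlas_metadata`.
#' @export
atlas_metadata <- function(voi_id, compartment, hemisphere = "bilateral") {
  if (anyDuplicated(voi_id)) {
    msync_abort("duplicated VOI in atlas: ",
                paste(unique(voi_id[duplicated(voi_id)]), collapse = ", "),
                class = "microsync_format_error")
  }
  hemisphere <- rep_len(hemisphere, length(voi_id))
  if (!all(hemisphere %in% c("L", "R", "bilateral"))) {
    msync_abort("hemisphere must be one of L, R, bilateral",
                class = "microsync_validation_error")
  }
  out <- data.frame(voi_id = as.character(voi_id),
                    compartment = as.character(compartment),
                    hemisphere = hemisphere,
                    stringsAsFactors = FALSE)
  class(out) <- c("atlas_metadata", "data.frame")
  out
}

#' @rdname atlas_metadata
#' @param path Path to a CSV with columns `voi_id`, `compartment`,
#'   `hemisphere`.
#' @param sep Field separator.
#' @export
read_atlas <- function(path, sep = ",") {
  if (!file.exists(path)) {
    msync_abort("atlas file not found: ", path, class = "microsync_io_error")
  }
  df <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                          stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  need <- c("voi_id", "compartment", "hemisphere")
  if (!all(need %in% names(df))) {
    msync_abort("atlas file must have columns: ", paste(need, collapse = ", "),
                class = "microsync_format_error")
  }
  atlas_metadata(df$voi_id, df$compartment, df$hemisphere)
}

#' @rdname atlas_metadata
#' @param atlas An `atlas_metadata` object to write.
#' @export
write_atlas <- function(atlas, path, sep = ",") {
  utils::write.table(atlas, path, sep = sep, row.names = FALSE, quote = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' Construct or read a cohort manifest
#'
#' The manifest assigns each subject to exactly one cohort, names the cohort's
#' reference cohort (empty/`NA` for cohorts scored by leave-one-out against
#' themselves), and carries per-subject covariates such as cognition scores
#' or TSPO binding status (`HAB`/`MAB`/`LAB`).
#'
#' @param subject_id,cohort Character vectors (one entry per subject).
#' @param reference_cohort Character vector or `NA`.
#' @param ... Further covariate columns (recycled to length).
#' @return A `data.frame` of class `cohort_manifest`.
#' @export
cohort_manifest <- function(subject_id, cohort, reference_cohort = NA_character_, ...) {
  if (anyDuplicated(subject_id)) {
    msync_abort("each subject must be assigned exactly one cohort; duplicated: ",
                paste(unique(subject_id[duplicated(subject_id)]), collapse = ", "),
                class = "microsync_format_error")
  }
  out <- data.frame(subject_id = as.character(subject_id),
                    cohort = as.character(cohort),
                    reference_cohort = as.character(reference_cohort),
                    stringsAsFactors = FALSE)
  extra <- list(...)
  for (nm in names(extra)) out[[nm]] <- rep_len(extra[[nm]], nrow(out))
  check_reference_acyclic(out)
  class(out) <- c("cohort_manifest", "data.frame")
  out
}

# The cohort -> reference-cohort map must not contain cycles (a cohort may
# reference itself, which means leave-one-out referencing).
check_reference_acyclic <- function(manifest) {
  map <- unique(manifest[, c("cohort", "reference_cohort")])
  map <- map[!is.na(map$reference_cohort) & map$reference_cohort != "" &
               map$reference_cohort != map$cohort, , drop = FALSE]
  ref_of <- stats::setNames(map$reference_cohort, map$cohort)
  for (start in names(ref_of)) {
    seen <- character()
    cur <- start
    while (cur %in% names(ref_of)) {
      if (cur %in% seen) {
        msync_abort("cyclic reference-cohort mapping involving '", cur, "'",
                    class = "microsync_validation_error")
      }
      seen <- c(seen, cur)
      cur <- ref_of[[cur]]
    }
  }
  invisible(TRUE)
}

#' @rdname cohort_manifest
#' @param path Path to a CSV with columns `subject_id`, `cohort`,
#'   `reference_cohort` plus arbitrary covariate columns.
#' @param sep Field separator.
#' @export
read_manifest <- function(path, sep = ",") {
  if (!file.exists(path)) {
    msync_abort("manifest file not found: ", path, class = "microsync_io_error")
  }
  df <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                          stringsAsFactors = FALSE, fileEncoding = "UTF-8",
                          na.strings = c("NA", ""))
  need <- c("subject_id", "cohort", "reference_cohort")
  if (!all(need %in% names(df))) {
    msync_abort("manifest must have columns: ", paste(need, collapse = ", "),
                class = "microsync_format_error")
  }
  extra <- df[, setdiff(names(df), need), drop = FALSE]
  do.call(cohort_manifest,
          c(list(subject_id = df$subject_id, cohort = df$cohort,
                 reference_cohort = df$reference_cohort),
            as.list(extra)))
}

#' @rdname cohort_manifest
#' @param manifest A `cohort_manifest` to write.
#' @export
write_manifest <- function(manifest, path, sep = ",") {
  utils::write.table(manifest, path, sep = sep, row.names = FALSE,
                     quote = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Filter subjects of an uptake table by a manifest rule
#'
#' Applies an inclusion rule to the manifest rows of the table's subjects and
#' returns the table restricted to subjects satisfying it. The canonical use
#' is the a-priori exclusion of low-affinity binders
#' (`rule = "tspo_binding != 'LAB'"`).
#'
#' @param table An [uptake_table()].
#' @param manifest A [cohort_manifest()] covering every table subject.
#' @param rule Either a one-sided predicate as a character expression
#'   evaluated in the manifest columns (e.g. `"cohort == 'CTRL'"`), or a
#'   function taking the manifest `data.frame` and returning a logical
#'   vector.
#' @return The filtered [uptake_table()]; the number of excluded subjects is
#'   logged.
#' @export
filter_subjects <- function(table, manifest, rule) {
  stopifnot(inherits(table, "uptake_table"))
  missing <- setdiff(table$subjects, manifest$subject_id)
  if (length(missing) > 0) {
    msync_abort("subject(s) absent from manifest: ",
                paste(missing, collapse = ", "),
                class = "microsync_validation_error")
  }
  rows <- manifest[match(table$subjects, manifest$subject_id), , drop = FALSE]
  keep <- if (is.function(rule)) {
    rule(rows)
  } else if (is.character(rule) && length(rule) == 1L) {
    eval(parse(text = rule), envir = rows, enclos = parent.frame())
  } else {
    msync_abort("`rule` must be a character expression or a function")
  }
  keep <- as.logical(keep)
  if (length(keep) != length(table$subjects) || anyNA(keep)) {
    msync_abort("rule must yield one non-missing logical per subject",
                class = "microsync_validation_error")
  }
  if (!any(keep)) {
    msync_abort("rule excludes all subjects; downstream stages require n >= 2",
                class = "microsync_validation_error")
  }
  msync_log("filter_subjects: excluded ", sum(!keep), " of ",
            length(keep), " subjects")
  uptake_table(table$values[keep, , drop = FALSE],
               normalization = table$normalization)
}

#' Restrict an uptake table to a VOI subset
#'
#' @param table An [uptake_table()].
#' @param vois Character vector of VOI ids to keep (order preserved as given).
#' @return The restricted [uptake_table()].
#' @export
subset_vois <- function(table, vois) {
  stopifnot(inherits(table, "uptake_table"))
  missing <- setdiff(vois, table$vois)
  if (length(missing) > 0) {
    msync_abort("VOI(s) absent from table: ", paste(missing, collapse = ", "),
                class = "microsync_validation_error")
  }
  uptake_table(table$values[, vois, drop = FALSE],
               normalization = table$normalization)
}

#' Restrict an uptake table to the subjects of one cohort
#'
#' @param table An [uptake_table()].
#' @param manifest A [cohort_manifest()].
#' @param cohort Cohort label to keep.
#' @return The restricted [uptake_table()].
#' @export
cohort_table <- function(table, manifest, cohort) {
  filter_subjects(table, manifest,
                  function(df) df$cohort == cohort)
}
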