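MODALITIES <- c("SC_raw", "SC_trans", "FC", "mFCSC")

#' Construct a connectome
#'
#' A connectome holds one subject's square symmetric region-by-region matrix
#' for one modality: raw structural connectivity (`SC_raw`, e.g. a
#' SIFT2-weighted streamline sum), power-law-transformed structural
#' connectivity (`SC_trans`), functional connectivity (`FC`, a time-course
#' correlation), or the FC-SC mismatch (`mFCSC`, where excluded entries are
#' `NaN`).
#'
#' @param matrix square numeric matrix; must be symmetric within `tol`.
#'   It is symmetrised as `(M + t(M)) / 2` and the diagonal is zeroed
#'   (`NaN` for `mFCSC`).
#' @param modality one of `"SC_raw"`, `"SC_trans"`, `"FC"`, `"mFCSC"`.
#' @param subject_id subject identifier string.
#' @param tol absolute asymmetry tolerance; asymmetry above it is rejected.
#' @return An object of class `connectome`.
#' @export
connectome <- function(matrix, modality, subject_id = "",
                       tol = 1e-8) {
  modality <- match.arg(modality, MODALITIES)
  if (!is_square_matrix(matrix))
    abort_validation("connectome matrix must be a square numeric matrix")
  asym <- max_asymmetry(matrix)
  if (asym > tol)
    abort_validation(
      "matrix asymmetry %.3g exceeds tolerance %.3g (modality %s)",
      asym, tol, modality)
  m <- matrix
  if (modality != "mFCSC") {
    m <- (m + t(m)) / 2
    diag(m) <- 0
    if (modality == "SC_raw" && any(m < 0))
      abort_validation("SC_raw entries must be nonnegative (min %.4g)",
                       min(m))
  } else {
    # mFCSC matrices carry NaN outside the analysis mask; symmetrise only
    # where both triangles are defined.
    both <- is.finite(m) & is.finite(t(m))
    m[both] <- ((m + t(m)) / 2)[both]
    diag(m) <- NaN
  }
  dimnames(m) <- NULL
  structure(list(subject_id = as.character(subject_id),
                 modality = modality, matrix = m),
            class = "connectome")
}

#' @export
print.connectome <- function(x, ...) {
  cat(sprintf("connectome '%s' [%s], %d x %d\n",
              x$subject_id, x$modality, nrow(x$matrix), ncol(x$matrix)))
  invisible(x)
}

#' Read a connectome matrix from a dense text file
#'
#' Accepts whitespace- or comma-delimited dense square matrices, the dialect
#' written by MRtrix's `tck2connectome` among others. With `labels = TRUE`
#' the file is instead a labelled CSV whose first row and column carry region
#' labels in parcellation order.
#'
#' @param path path to the matrix file.
#' @param parcellation a [parcellation()]; the matrix dimension must match.
#' @param modality connectome modality, see [connectome()].
#' @param subject_id subject identifier; defaults to the file name without
#'   extension.
#' @param labels logical; labelled-CSV dialect with header row and label
#'   column.
#' @param tol asymmetry tolerance passed to [connectome()].
#' @return A [connectome()].
#' @export
read_connectome <- function(path, parcellation, modality,
                            subject_id = NULL, labels = FALSE,
                            tol = 1e-8) {
  stopifnot(inherits(parcellation, "parcellation"))
  if (!file.exists(path))
    abort_validation("connectome file not found: %s", path)
  if (is.null(subject_id))
    subject_id <- sub("\\.[^.]*$", "", basename(path))
  if (labels) {
    tab <- utils::read.csv(path, row.names = 1, check.names = FALSE)
    m <- as.matrix(tab)
    if (!identical(colnames(m), parcellation$label))
      abort_validation("labelled connectome columns do not match parcellation")
  } else {
    first <- readLines(path, n = 1L)
    sep <- if (grepl(",", first, fixed = TRUE)) "," else ""
    tab <- utils::read.table(path, sep = sep, header = FALSE,
                             colClasses = "numeric",
                             na.strings = c("nan", "NaN", "NA"))
    m <- as.matrix(tab)
  }
  storage.mode(m) <- "double"
  m[is.na(m) & !is.nan(m)] <- NaN
  n <- n_regions(parcellation)
  if (nrow(m) != n || ncol(m) != n)
    abort_validation("connectome is %d x %d but parcellation has %d regions",
                     nrow(m), ncol(m), n)
  connectome(m, modality, subject_id, tol = tol)
}

#' Write a connectome as a dense CSV matrix
#'
#' Undefined (excluded) entries are written as the token `nan`. The written
#' file round-trips through [read_connectome()] to within 1e-12 relative
#' error.
#'
#' @param connectome a [connectome()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_connectome <- function(connectome, path) {
  stopifnot(inherits(connectome, "connectome"))
  if (!nzchar(path))
    abort_validation("empty output path")
  m <- connectome$matrix
  txt <- vapply(seq_len(nrow(m)), function(i) {
    row <- sprintf("%.17g", m[i, ])
    row[is.nan(m[i, ])] <- "nan"
    paste(row, collapse = ",")
  }, character(1))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(txt, con)
  invisible(path)
}

#' Element-wise group average of connectomes
#'
#' The arithmetic mean of the subjects' matrices, zeros included; written
#' \eqn{\langle\cdot\rangle}. Group-averaged connectomes are what the
#' power-law transform is fitted on and what the edge-exclusion step uses,
#' so that the same transform and the same exclusions apply to every subject.
#'
#' @param connectomes non-empty list of [connectome()]s sharing modality and
#'   dimension.
#' @return A [connectome()] with `subject_id = "group"`.
#' @export
group_average <- function(connectomes) {
  if (length(connectomes) == 0L)
    abort_validation("cannot average an empty list of connectomes")
  stopifnot(all(vapply(connectomes, inherits, logical(1), "connectome")))
  modality <- unique(vapply(connectomes, function(x) x$modality, character(1)))
  if (length(modality) != 1L)
    abort_validation("mixed modalities in group average: %s",
                     paste(modality, collapse = ", "))
  dims <- unique(vapply(connectomes, function(x) nrow(x$matrix), integer(1)))
  if (length(dims) != 1L)
    abort_validation("connectomes of different dimensions")
  s <- Reduce(`+`, lapply(connectomes, function(x) x$matrix))
  connectome(s / length(connectomes), modality, "group", tol = Inf)
}

#' Assemble a cohort of matched SC/FC connectomes
#'
#' @param parcellation a [parcellation()].
#' @param subjects list of `list(sc = <SC_raw connectome>, fc = <FC
#'   connectome>)`, one per subject, with matching `subject_id`s.
#' @return An object of class `cohort`.
#' @export
cohort <- function(parcellation, subjects) {
  stopifnot(inherits(parcellation, "parcellation"))
  n <- n_regions(parcellation)
  for (s in subjects) {
    if (!inherits(s$sc, "connectome") || !inherits(s$fc, "connectome"))
      abort_validation("each subject needs an 'sc' and an 'fc' connectome")
    if (s$sc$modality != "SC_raw" || s$fc$modality != "FC")
      abort_validation("subject %s: expected modalities SC_raw and FC",
                       s$sc$subject_id)
    if (s$sc$subject_id != s$fc$subject_id)
      abort_validation("subject id mismatch: '%s' vs '%s'",
                       s$sc$subject_id, s$fc$subject_id)
    if (nrow(s$sc$matrix) != n || nrow(s$fc$matrix) != n)
      abort_validation("subject %s: matrix dimension does not match parcellation",
                       s$sc$subject_id)
  }
  ids <- vapply(subjects, function(s) s$sc$subject_id, character(1))
  if (anyDuplicated(ids))
    abort_validation("duplicated subject ids")
  structure(list(parcellation = parcellation, subjects = subjects),
            class = "cohort")
}

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf("cohort: %d subjects, %d regions\n",
              length(x$subjects), n_regions(x$parcellation)))
  invisible(x)
}

#' Read a cohort from SC and FC directories
#'
#' Subjects are matched by file name (without extension) across the two
#' directories; every subject must have exactly one SC and one FC matrix.
#'
#' @param sc_dir directory of raw SC matrices, one file per subject.
#' @param fc_dir directory of FC matrices, one file per subject.
#' @param parcellation a [parcellation()] or path to a parcellation CSV.
#' @param labels labelled-CSV dialect flag, see [read_connectome()].
#' @return A [cohort()].
#' @export
read_cohort <- function(sc_dir, fc_dir, parcellation, labels = FALSE) {
  if (is.character(parcellation))
    parcellation <- read_parcellation(parcellation)
  sc_files <- sort(list.files(sc_dir, full.names = TRUE))
  fc_files <- sort(list.files(fc_dir, full.names = TRUE))
  strip <- function(p) sub("\\.[^.]*$", "", basename(p))
  sc_ids <- strip(sc_files)
  fc_ids <- strip(fc_files)
  odd <- c(setdiff(sc_ids, fc_ids), setdiff(fc_ids, sc_ids))
  if (length(odd) > 0L)
    abort_validation("unmatched subject(s) across SC/FC directories: %s",
                     paste(odd, collapse = ", "))
  if (length(sc_ids) == 0L)
    abort_validation("no connectome files found in %s", sc_dir)
  subjects <- lapply(seq_along(sc_files), function(i) {
    list(sc = read_connectome(sc_files[i], parcellation, "SC_raw",
                              labels = labels),
         fc = read_connectome(fc_files[match(sc_ids[i], fc_ids)],
                              parcellation, "FC", labels = labels))
  })
  cohort(parcellation, subjects)
}
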