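#' Read a 3D NIfTI volume
#'
#' Reads a single-frame NIfTI-1 image (.nii or .nii.gz) into a
#' [scalar_volume()]. The sform/qform affine is preserved exactly and values
#' are not rescaled or cast; NaNs (e.g. outside an analysis mask) pass
#' through untouched.
#'
#' @param path Path to a NIfTI file.
#' @return A [scalar_volume()].
#' @seealso [write_volume()]
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) {
    stop("file not found: ", path, call. = FALSE)
  }
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) == 4L && d[4] == 1L) {
    img <- img[, , , 1L]
    d <- d[1:3]
  } else if (length(d) != 3L) {
    stop("expected 3D volume, got ", length(d), "D image: ", path, call. = FALSE)
  }
  aff <- RNifti::xform(img)
  aff <- matrix(as.numeric(aff), 4L, 4L)
  grid <- volume_grid(d, affine = aff)
  scalar_volume(array(as.numeric(img), dim = d), grid)
}

#' Write a 3D NIfTI volume
#'
#' Writes a [scalar_volume()] as double-precision NIfTI so that a
#' write-then-read round trip is bit-preserving for the values; the affine is
#' preserved to the NIfTI-1 header's own float32 precision (exactly, for
#' entries representable in single precision).
#'
#' @param vol A [scalar_volume()].
#' @param path Output path (.nii or .nii.gz).
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path) {
  stopifnot(inherits(vol, "scalar_volume"))
  img <- RNifti::asNifti(vol$values, datatype = "double")
  img <- RNifti::`sform<-`(img, structure(vol$grid$affine, code = 2L))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Cognitive test score ranges and control-group calibration
#'
#' Score maxima for the MMSE and the CASI total plus its nine subdomains,
#' together with the control-group mean and SD each synthetic score is
#' calibrated to. Used for cohort validation and by the synthetic generator.
#'
#' @return A tibble with columns `test`, `max`, `ctl_mean`, `ctl_sd`.
#' @export
cognitive_score_info <- function() {
  tibble::tribble(
    ~test,                ~max, ~ctl_mean, ~ctl_sd,
    "mmse",                30,     28.01,    1.80,
    "casi_total",         100,     92.41,    5.21,
    "mental_manipulation", 10,      8.98,    1.36,
    "attention",            8,      7.50,    0.68,
    "orientation",         18,     17.61,    1.03,
    "long_term_memory",    10,      9.89,    0.46,
    "short_term_memory",   12,     10.86,    1.38,
    "abstract_thinking",   12,     10.12,    1.68,
    "drawing_ability",     10,      9.63,    1.14,
    "verbal_fluency",      10,      8.08,    1.83,
    "language",            10,      9.75,    0.48
  )
}

#' Read and validate a cohort table
#'
#' Reads a delimited cohort table (TSV or CSV, header required) with one row
#' per subject. Required columns: `id`, `group` (levels `YOAD`/`CTL`), `age`,
#' `education`, `sex`, `etiv`. Cognitive score columns matching
#' [cognitive_score_info()] are validated against their maxima. Rows with
#' missing required fields are kept but flagged (`complete = FALSE`) for
#' listwise deletion downstream; the count is reported as a message.
#'
#' @param path Path to a TSV/CSV file.
#' @return A tibble, one row per subject, with a logical `complete` column.
#' @export
read_cohort <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  delim <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  tab <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                           progress = FALSE)
  validate_cohort(tab)
}

#' @rdname read_cohort
#' @param tab A data frame holding the cohort table.
#' @export
validate_cohort <- function(tab) {
  tab <- tibble::as_tibble(tab)
  required <- c("id", "group", "age", "education", "sex", "etiv")
  missing_cols <- setdiff(required, names(tab))
  if (length(missing_cols) > 0) {
    stop("cohort table missing columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(tab$id)) {
    stop("duplicated subject ids: ",
         paste(unique(tab$id[duplicated(tab$id)]), collapse = ", "),
         call. = FALSE)
  }
  bad_group <- setdiff(unique(as.character(tab$group)), c("YOAD", "CTL"))
  if (length(bad_group) > 0) {
    stop("unknown group labels: ", paste(bad_group, collapse = ", "),
         call. = FALSE)
  }
  info <- cognitive_score_info()
  for (k in seq_len(nrow(info))) {
    col <- info$test[k]
    if (col %in% names(tab)) {
      v <- tab[[col]]
      bad <- which(is.finite(v) & (v < 0 | v > info$max[k]))
      if (length(bad) > 0) {
        stop(sprintf("%s scores outside [0, %g] for ids: %s", col, info$max[k],
                     paste(tab$id[bad], collapse = ", ")), call. = FALSE)
      }
    }
  }
  tab$complete <- stats::complete.cases(tab[required])
  n_inc <- sum(!tab$complete)
  if (n_inc > 0) {
    message(n_inc, " subject(s) with missing required fields flagged for ",
            "listwise deletion")
  }
  tab
}
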