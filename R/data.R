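#' Construct a validated long-format longitudinal trial dataset
#'
#' A `longitudinal_data` object is a long-format data frame with one row per
#' visit, holding a current two-arm trial and/or a historical control arm.
#' Required columns are `subject` (character), `study` (`"current"` or
#' `"historical"`), `arm` (`"treatment"` or `"control"`), `time` (numeric,
#' non-negative) and `y` (numeric outcome). Any further columns are treated
#' as baseline covariates.
#'
#' Validation enforces the design assumptions of the constrained longitudinal
#' data analysis (cLDA) model with one historical control arm: every
#' historical record is a control record; each subject belongs to exactly one
#' (study, arm) pair; every subject has at least one visit; outcomes and
#' times are finite; and no subject has two records at the same time.
#' Missing visits are simply absent rows (likelihood-based handling); no
#' imputation is performed.
#'
#' @param df data frame with the columns described above.
#' @param time_unit character scalar naming the unit of `time` (metadata only).
#' @return A `longitudinal_data` object: the input data frame with subjects
#'   ordered lexicographically and records sorted by time within subject.
#' @examples
#' df <- data.frame(subject = "s1", study = "current", arm = "treatment",
#'                  time = c(0, 0.5, 1), y = c(2.1, 2.4, 3.0))
#' d <- longitudinal_data(df)
#' nrow(d)
#' @export
longitudinal_data <- function(df, time_unit = "study-time") {
  stopifnot(is.data.frame(df))
  req <- c("subject", "study", "arm", "time", "y")
  missing_cols <- setdiff(req, names(df))
  if (length(missing_cols) > 0L) {
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "))
  }
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  df$subject <- as.character(df$subject)
  df$study <- as.character(df$study)
  df$arm <- as.character(df$arm)
  df$time <- as.numeric(df$time)
  df$y <- as.numeric(df$y)

  if (!all(df$study %in% c("current", "historical"))) {
    stop("'study' must be 'current' or 'historical'")
  }
  if (!all(df$arm %in% c("treatment", "control"))) {
    stop("'arm' must be 'treatment' or 'control'")
  }
  if (any(df$study == "historical" & df$arm == "treatment")) {
    stop("historical records must all be control-arm records")
  }
  if (!all(is.finite(df$time)) || !all(is.finite(df$y))) {
    stop("times and outcomes must be finite")
  }
  if (any(df$time < 0)) stop("times must be non-negative")

  grp <- unique(df[, c("subject", "study", "arm")])
  if (anyDuplicated(grp$subject)) {
    stop("each subject must appear in exactly one (study, arm) pair")
  }
  key <- paste(df$subject, df$time, sep = "\r")
  if (anyDuplicated(key)) {
    stop("duplicated (subject, time) record")
  }

  ord <- order(df$subject, df$time, method = "radix")
  df <- df[ord, , drop = FALSE]
  rownames(df) <- NULL
  structure(df, class = c("longitudinal_data", "data.frame"),
            time_unit = time_unit)
}

#' @export
print.longitudinal_data <- function(x, ...) {
  ns <- table(unique(data.frame(s = x$subject,
                                g = paste(x$study, x$arm)))$g)
  cat("Longitudinal trial data:", nrow(x), "records,",
      length(unique(x$subject)), "subjects\n")
  for (g in names(ns)) cat("  ", g, ":", ns[[g]], "subjects\n")
  cat("  time range:", min(x$time), "-", max(x$time),
      paste0("(", attr(x, "time_unit"), ")"), "\n")
  covs <- covariate_names(x)
  if (length(covs)) cat("  covariates:", paste(covs, collapse = ", "), "\n")
  invisible(x)
}

#' Names of covariate columns in a longitudinal dataset
#' @param data a `longitudinal_data` object (or plain data frame).
#' @return character vector of non-required column names.
#' @export
covariate_names <- function(data) {
  setdiff(names(data), c("subject", "study", "arm", "time", "y"))
}

#' Subset a longitudinal dataset by study
#' @param data a `longitudinal_data` object.
#' @param study `"current"` or `"historical"`.
#' @return a `longitudinal_data` object (possibly with zero rows).
#' @export
study_subset <- function(data, study = c("current", "historical")) {
  study <- match.arg(study)
  out <- data[data$study == study, , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = class(data), time_unit = attr(data, "time_unit"))
}

#' Read a long-format trial CSV
#'
#' Reads a comma-separated, UTF-8, headered file with the canonical columns
#' `subject, study, arm, time, y` (extra columns become covariates) and
#' validates it via [longitudinal_data()]. Non-canonical column names can be
#' remapped with `col_map`.
#'
#' @param path path to a CSV file.
#' @param col_map optional named character vector mapping canonical names to
#'   the names used in the file, e.g. `c(y = "outcome")`.
#' @param time_unit passed to [longitudinal_data()].
#' @return a `longitudinal_data` object.
#' @export
read_long_csv <- function(path, col_map = NULL, time_unit = "study-time") {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        fileEncoding = "UTF-8", check.names = FALSE)
  if (!is.null(col_map)) {
    for (canon in names(col_map)) {
      j <- match(col_map[[canon]], names(df))
      if (is.na(j)) stop("col_map names a column not in the file: ",
                         col_map[[canon]])
      names(df)[j] <- canon
    }
  }
  longitudinal_data(df, time_unit = time_unit)
}

#' Write a long-format trial CSV
#'
#' Inverse of [read_long_csv()]: writes the canonical columns (and any
#' covariates) so that reading the file back yields an equal dataset.
#'
#' @param data a `longitudinal_data` object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_long_csv <- function(data, path) {
  utils::write.csv(as.data.frame(data), path, row.names = FALSE,
                   quote = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Build cLDA design matrices for one study
#'
#' Constructs, per subject, the fixed-effects design matrix `X` with columns
#' `(intercept, covariates..., time, treatment:time)` and the random-effects
#' design `Z` with columns `(intercept, time)` (configurable subset). Under
#' the cLDA constraint there is no treatment main effect: randomised arms
#' share the baseline mean and treatment enters only through the
#' treatment-by-time interaction, whose column is identically zero for
#' control subjects. The historical model has no treatment term at all, so
#' `for_study = "historical"` omits the interaction column.
#'
#' Records are sorted by time within subject, so the design is invariant to
#' the input row order.
#'
#' @param data a `longitudinal_data` object.
#' @param covariates character vector of covariate columns to include, in the
#'   order they should appear in `X`.
#' @param for_study which study's subjects to build designs for.
#' @param z_cols random-effects columns, a subset of
#'   `c("intercept", "time")`.
#' @return an object of class `design_matrices`: a list with one element per
#'   subject, each a list with `X`, `Z`, `y`, `subject`, `arm`; attributes
#'   `x_cols` and `z_cols` give the column layout.
#' @export
build_design <- function(data, covariates = character(),
                         for_study = c("current", "historical"),
                         z_cols = c("intercept", "time")) {
  for_study <- match.arg(for_study)
  z_cols <- match.arg(z_cols, c("intercept", "time"), several.ok = TRUE)
  d <- study_subset(data, for_study)
  if (nrow(d) == 0L) stop("no records for study '", for_study, "'")
  bad <- setdiff(covariates, names(d))
  if (length(bad)) stop("unknown covariate column(s): ",
                        paste(bad, collapse = ", "))
  for (cv in covariates) {
    if (anyNA(d[[cv]])) stop("missing value in covariate '", cv,
                             "' (no imputation is performed)")
    if (!is.numeric(d[[cv]])) stop("covariate '", cv, "' must be numeric")
  }
  has_trt <- for_study == "current"
  x_cols <- c("intercept", covariates, "time", if (has_trt) "trt_time")
  subjects <- unique(d$subject)  # already lexicographic
  out <- lapply(subjects, function(s) {
    rows <- d[d$subject == s, , drop = FALSE]
    m <- nrow(rows)
    trt <- as.numeric(rows$arm[1L] == "treatment")
    X <- cbind(1, if (length(covariates))
      as.matrix(rows[, covariates, drop = FALSE]), rows$time,
      if (has_trt) trt * rows$time)
    colnames(X) <- x_cols
    Z <- cbind(if ("intercept" %in% z_cols) rep(1, m),
               if ("time" %in% z_cols) rows$time)
    colnames(Z) <- z_cols
    list(X = X, Z = Z, y = rows$y, subject = s, arm = rows$arm[1L])
  })
  structure(out, class = "design_matrices", x_cols = x_cols, z_cols = z_cols,
            study = for_study)
}

#' @export
print.design_matrices <- function(x, ...) {
  cat("cLDA design matrices:", length(x), "subjects (study:",
      attr(x, "study"), ")\n")
  cat("  X columns:", paste(attr(x, "x_cols"), collapse = ", "), "\n")
  cat("  Z columns:", paste(attr(x, "z_cols"), collapse = ", "), "\n")
  invisible(x)
}

# Group subjects by identical (times, Z) pattern and stack their design rows.
# The marginal covariance V = Z G Z' + sigma^2 I is shared within a group, so
# the sampler factorises it once per group.  Returns a list of groups, each
# with stacked X (n*m x p), stacked y (n*m), Z (m x q), n, m.
make_groups <- function(design) {
  pat <- vapply(design, function(s)
    paste(c(dim(s$X), signif(s$Z, 12)), collapse = ","), "")
  split_idx <- split(seq_along(design), pat)
  lapply(unname(split_idx), function(idx) {
    Xs <- do.call(rbind, lapply(design[idx], `[[`, "X"))
    ys <- unlist(lapply(design[idx], `[[`, "y"), use.names = FALSE)
    list(X = unname(Xs), y = ys, Z = unname(design[[idx[1L]]]$Z),
         n = length(idx), m = length(design[[idx[1L]]]$y))
  })
}
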