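#' Variable metadata for a survey column
#'
#' A variable spec records how one survey column is to be interpreted:
#' its short label, measurement kind, analysis role, and admissible levels
#' for non-continuous kinds.
#'
#' @param name Short label, e.g. `"AD"`, `"Depre"`, `"PCS"`.
#' @param kind One of `"binary"`, `"continuous"`, `"ordinal"`.
#' @param role One of `"shc"` (secondary health condition item),
#'   `"outcome"`, `"covariate"`.
#' @param levels Integer vector of admissible values for binary/ordinal
#'   variables (ignored for continuous). Binary variables must use `0:1`;
#'   ordinal levels must be consecutive integers.
#' @return A one-row data frame with columns `name`, `kind`, `role` and a
#'   list-column `levels`.
#' @export
variable_spec <- function(name, kind = c("binary", "continuous", "ordinal"),
                          role = c("shc", "outcome", "covariate"),
                          levels = if (kind == "binary") 0:1 else NULL) {
  kind <- match.arg(kind)
  role <- match.arg(role)
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  if (role == "shc" && kind != "binary")
    stop("SHC item '", name, "' must be binary", call. = FALSE)
  if (kind == "binary") {
    if (!identical(as.integer(levels), 0:1))
      stop("binary variable '", name, "' must have levels {0, 1}", call. = FALSE)
  }
  if (kind == "ordinal") {
    lv <- as.integer(levels)
    if (length(lv) < 2L || any(diff(lv) != 1L))
      stop("ordinal levels of '", name, "' must be consecutive integers",
           call. = FALSE)
  }
  out <- data.frame(name = name, kind = kind, role = role,
                    stringsAsFactors = FALSE)
  out$levels <- list(if (kind == "continuous") NULL else as.integer(levels))
  out
}

#' Combine variable specs into a metadata table
#'
#' @param ... One-row data frames from [variable_spec()], or complete spec
#'   data frames to be row-bound.
#' @return A spec data frame with unique names.
#' @export
survey_specs <- function(...) {
  out <- do.call(rbind, list(...))
  if (anyDuplicated(out$name))
    stop("duplicate variable names in specs: ",
         paste(unique(out$name[duplicated(out$name)]), collapse = ", "),
         call. = FALSE)
  rownames(out) <- NULL
  out
}

#' Read variable metadata from a JSON or YAML file
#'
#' The file holds an array of objects with fields `name`, `kind`, `role`
#' and optional `levels`.
#'
#' @param path File path ending in `.json`, `.yaml` or `.yml`.
#' @return A spec data frame as from [survey_specs()].
#' @export
read_variable_specs <- function(path) {
  ext <- tolower(tools::file_ext(path))
  raw <- if (ext == "json") {
    jsonlite::fromJSON(path, simplifyDataFrame = FALSE)
  } else if (ext %in% c("yaml", "yml")) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("the 'yaml' package is required to read YAML specs", call. = FALSE)
    yaml::read_yaml(path)
  } else stop("unsupported spec file extension: ", ext, call. = FALSE)
  rows <- lapply(raw, function(v) {
    variable_spec(v$name, v$kind, v$role,
                  levels = if (!is.null(v$levels)) unlist(v$levels)
                           else if (identical(v$kind, "binary")) 0:1 else NULL)
  })
  do.call(survey_specs, rows)
}

#' Code a raw SHC response to 0/1
#'
#' Survey respondents report each secondary health condition as present,
#' absent, or "do not know"; a "do not know" answer is coded as not having
#' the condition. Already-numeric 0/1 input passes through unchanged.
#'
#' @param x Vector of tokens among `"present"`, `"absent"`, `"do_not_know"`,
#'   `NA`, or numeric 0/1.
#' @return Integer vector of 0/1 with `NA` preserved.
#' @export
code_shc <- function(x) {
  if (is.numeric(x) || is.logical(x)) {
    v <- as.integer(x)
    bad <- !is.na(v) & !(v %in% c(0L, 1L))
    if (any(bad))
      stop("non-binary numeric SHC value(s): ",
           paste(unique(v[bad]), collapse = ", "), call. = FALSE)
    return(v)
  }
  x <- as.character(x)
  map <- c(present = 1L, absent = 0L, do_not_know = 0L)
  out <- rep(NA_integer_, length(x))
  known <- x %in% names(map)
  miss <- is.na(x) | x == "" | x == "missing"
  if (any(!known & !miss))
    stop("unrecognized SHC response token(s): ",
         paste(unique(x[!known & !miss]), collapse = ", "), call. = FALSE)
  out[known] <- unname(map[x[known]])
  out
}

#' Dichotomize an ordinal satisfaction / quality-of-life rating
#'
#' The life-satisfaction item (1 = very dissatisfied ... 6 = very satisfied)
#' is coded satisfied (1) for ratings 5-6 and not satisfied (0) for 1-4.
#' The 5-point overall quality-of-life item (1 = poor ... 5 = good) is coded
#' good (1) at or above `qol_cut` (default 4).
#'
#' @param value Integer rating(s).
#' @param scale `"lisat6"` or `"qol5"`.
#' @param qol_cut First rating counted as satisfied on the 5-point scale.
#' @return Integer 0/1 with `NA` preserved.
#' @export
dichotomize_outcome <- function(value, scale = c("lisat6", "qol5"),
                                qol_cut = 4L) {
  scale <- match.arg(scale)
  rng <- if (scale == "lisat6") c(1L, 6L) else c(1L, 5L)
  cut <- if (scale == "lisat6") 5L else as.integer(qol_cut)
  v <- as.integer(value)
  bad <- !is.na(v) & (v < rng[1] | v > rng[2])
  if (any(bad))
    stop("rating(s) out of range [", rng[1], ", ", rng[2], "] for scale ",
         scale, ": ", paste(unique(v[bad]), collapse = ", "), call. = FALSE)
  ifelse(is.na(v), NA_integer_, as.integer(v >= cut))
}

#' Construct a coded survey dataset
#'
#' @param values Data frame of coded participant-by-variable values. A column
#'   `id`, if present, must hold unique participant identifiers.
#' @param specs Spec data frame from [survey_specs()]; every spec name must
#'   match a column of `values`.
#' @param cohort_label Free-text cohort tag (e.g. `"TSCI"`, `"NTSCI"`).
#' @return An object of class `survey_dataset`: a list with elements
#'   `values`, `specs`, `cohort_label`.
#' @export
survey_dataset <- function(values, specs, cohort_label = "cohort") {
  stopifnot(is.data.frame(values), is.data.frame(specs))
  missing_cols <- setdiff(specs$name, names(values))
  if (length(missing_cols))
    stop("columns declared in specs but absent from data: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  if ("id" %in% names(values) && anyDuplicated(values$id))
    stop("duplicate participant identifiers", call. = FALSE)
  for (i in seq_len(nrow(specs))) {
    nm <- specs$name[i]
    v <- values[[nm]]
    if (specs$kind[i] == "binary") {
      if (!all(is.na(v) | v %in% c(0, 1)))
        stop("binary column '", nm, "' contains values other than 0/1/NA",
             call. = FALSE)
    } else if (specs$kind[i] == "ordinal") {
      lv <- specs$levels[[i]]
      if (!all(is.na(v) | v %in% lv))
        stop("ordinal column '", nm, "' contains out-of-level values",
             call. = FALSE)
    } else if (!is.numeric(v)) {
      stop("continuous column '", nm, "' is not numeric", call. = FALSE)
    }
  }
  structure(list(values = values, specs = specs,
                 cohort_label = cohort_label),
            class = "survey_dataset")
}

#' @export
print.survey_dataset <- function(x, ...) {
  cat("<survey_dataset> cohort:", x$cohort_label, "-", nrow(x$values),
      "participants,", nrow(x$specs), "declared variables\n")
  cat("  roles:", paste(sprintf("%s=%d", names(table(x$specs$role)),
                                table(x$specs$role)), collapse = ", "), "\n")
  invisible(x)
}

#' Names of SHC items in a dataset
#' @param dataset A `survey_dataset`.
#' @return Character vector of item names with role `"shc"`.
#' @export
shc_names <- function(dataset) dataset$specs$name[dataset$specs$role == "shc"]

#' Define a multimorbidity index over a set of SHC items
#'
#' @param item_names Ordered character vector of SHC names, length 1-30,
#'   no duplicates.
#' @return An object of class `mmi_definition`.
#' @export
mmi_definition <- function(item_names) {
  item_names <- as.character(item_names)
  if (anyDuplicated(item_names))
    stop("duplicate items in index definition", call. = FALSE)
  if (length(item_names) < 1L || length(item_names) > 30L)
    stop("index must contain between 1 and 30 items", call. = FALSE)
  structure(list(item_names = item_names), class = "mmi_definition")
}

#' @export
print.mmi_definition <- function(x, ...) {
  cat("<mmi_definition> MMI-", length(x$item_names), ": ",
      paste(x$item_names, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Score a multimorbidity index
#'
#' The index score is the per-participant sum of the coded 0/1 items; a
#' participant with any missing item gets a missing score.
#'
#' @param dataset A `survey_dataset` with coded SHC columns.
#' @param index An [mmi_definition()] whose items all appear in the dataset.
#' @return Integer vector of scores in `[0, length(index$item_names)]`.
#' @export
score_mmi <- function(dataset, index) {
  stopifnot(inherits(dataset, "survey_dataset"),
            inherits(index, "mmi_definition"))
  unknown <- setdiff(index$item_names,
                     dataset$specs$name[dataset$specs$role == "shc"])
  if (length(unknown))
    stop("index items not found among SHC variables: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  m <- as.matrix(dataset$values[, index$item_names, drop = FALSE])
  out <- rowSums(m)
  as.integer(out)
}

#' Load and code a cohort from a delimited text file
#'
#' Reads a CSV with a header row, checks it against the declared variable
#' specs, applies the SHC coding rule (token or 0/1 input), and returns a
#' coded [survey_dataset()]. Columns present in the file but not declared
#' are dropped with a warning; declared columns missing from the file are an
#' error.
#'
#' @param path CSV file path.
#' @param specs Spec data frame from [survey_specs()] or
#'   [read_variable_specs()].
#' @param cohort_label Cohort tag stored on the dataset.
#' @return A `survey_dataset`.
#' @export
load_cohort <- function(path, specs, cohort_label = "cohort") {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         na.strings = c("NA", ""))
  missing_cols <- setdiff(specs$name, names(raw))
  if (length(missing_cols))
    stop("declared column(s) missing from file: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  extra <- setdiff(names(raw), c(specs$name, "id"))
  if (length(extra)) {
    warning("ignoring undeclared column(s): ", paste(extra, collapse = ", "),
            call. = FALSE)
    raw <- raw[, setdiff(names(raw), extra), drop = FALSE]
  }
  for (i in seq_len(nrow(specs))) {
    nm <- specs$name[i]
    if (specs$role[i] == "shc") {
      raw[[nm]] <- code_shc(raw[[nm]])
    } else if (specs$kind[i] != "binary" || is.character(raw[[nm]])) {
      v <- suppressWarnings(as.numeric(raw[[nm]]))
      bad <- which(is.na(v) & !is.na(raw[[nm]]))
      if (length(bad))
        stop("non-numeric value in column '", nm, "' at row ", bad[1],
             call. = FALSE)
      raw[[nm]] <- v
    }
  }
  survey_dataset(raw, specs, cohort_label)
}

#' Write a coded cohort to CSV with a JSON provenance sidecar
#'
#' @param dataset A `survey_dataset`.
#' @param path Output CSV path; the sidecar is written to `paste0(path,
#'   ".meta.json")`.
#' @return Invisibly, the CSV path.
#' @export
write_cohort <- function(dataset, path) {
  utils::write.csv(dataset$values, path, row.names = FALSE, na = "NA")
  meta <- list(cohort_label = dataset$cohort_label,
               n = nrow(dataset$values),
               variables = lapply(seq_len(nrow(dataset$specs)), function(i)
                 list(name = dataset$specs$name[i],
                      kind = dataset$specs$kind[i],
                      role = dataset$specs$role[i],
                      levels = dataset$specs$levels[[i]])),
               coding = list(shc = "present/do_not_know/absent -> 1/0/0",
                             lisat6 = "1-4 -> 0, 5-6 -> 1",
                             qol5 = "below cut -> 0, at/above cut -> 1"))
  jsonlite::write_json(meta, paste0(path, ".meta.json"), auto_unbox = TRUE,
                       null = "null")
  invisible(path)
}
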