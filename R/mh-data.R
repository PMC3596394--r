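#' Assemble subject-level data for symmetrical odds-ratio analysis
#'
#' Validates two 0/1 outcome columns and builds the covariate design matrix
#' shared by all fitting routines. Categorical covariates (factor or
#' character columns) are expanded to reference-cell indicator columns;
#' continuous covariates are passed through unchanged unless `standardize`
#' is set. Rows with a missing value in any selected column are dropped
#' (complete-case analysis) and the dropped count is recorded.
#'
#' @param data A data frame with one row per subject.
#' @param x,y Names of the two dichotomous columns. Values must be exactly
#'   0 or 1 (numeric, integer, logical, or the strings "0"/"1").
#' @param z Character vector of covariate column names (may be empty: the
#'   unadjusted, crude-odds-ratio limit).
#' @param reference Optional named list mapping a categorical covariate name
#'   to the level used as the reference cell. Defaults to the first factor
#'   level (alphabetical for character columns).
#' @param standardize If `TRUE`, centre and scale continuous covariates.
#'   The odds-ratio estimators are invariant to affine covariate rescaling
#'   at the optimum; the default keeps coefficients on their raw scale.
#' @param quiet Suppress the message reporting dropped rows.
#'
#' @return An object of class `mh_data`: a list with elements `x`, `y`
#'   (integer 0/1 vectors), `z` (numeric n-by-m design matrix),
#'   `covariate_names`, `n`, `m`, `n_dropped`, and `raw` (a tibble of the
#'   selected columns before coding, used for stratification and display).
#'
#' @examples
#' d <- data.frame(x = c(0, 1, 0, 1), y = c(0, 0, 1, 1), age = c(20, 30, 40, 50))
#' md <- mh_data(d, "x", "y", "age")
#' md$n
#' @export
mh_data <- function(data, x, y, z = character(), reference = NULL,
                    standardize = FALSE, quiet = FALSE) {
  if (!is.data.frame(data)) abort("`data` must be a data frame.")
  cols <- c(x, y, z)
  missing_cols <- setdiff(cols, names(data))
  if (length(missing_cols) > 0) {
    abort(paste0("Column(s) not found: ", paste(missing_cols, collapse = ", ")))
  }
  if (anyDuplicated(cols)) abort("x, y and z columns must be distinct.")

  sel <- tibble::as_tibble(data[cols])
  keep <- complete.cases(sel)
  n_dropped <- sum(!keep)
  sel <- sel[keep, , drop = FALSE]
  if (nrow(sel) == 0L) abort("No complete cases remain after filtering.")
  if (n_dropped > 0 && !quiet) {
    inform(paste0("Dropped ", n_dropped, " row(s) with missing values."))
  }

  xv <- check_binary(sel[[x]], x)
  yv <- check_binary(sel[[y]], y)

  zmat <- build_design(sel[z], reference = reference, standardize = standardize)

  structure(
    list(
      x = xv, y = yv, z = zmat,
      covariate_names = colnames(zmat),
      n = length(xv), m = ncol(zmat),
      n_dropped = n_dropped,
      x_name = x, y_name = y, z_names = z,
      raw = sel
    ),
    class = "mh_data"
  )
}

# coerce a column to strict 0/1 integer, reporting offending rows
check_binary <- function(v, name) {
  if (is.logical(v)) v <- as.integer(v)
  if (is.factor(v)) v <- as.character(v)
  if (is.character(v)) {
    ok <- v %in% c("0", "1")
    if (!all(ok)) {
      abort(paste0("Column `", name, "` must be coded 0/1; offending row(s): ",
                   paste(head(which(!ok), 5), collapse = ", ")))
    }
    v <- as.integer(v)
  }
  if (!is.numeric(v)) abort(paste0("Column `", name, "` must be coded 0/1."))
  bad <- which(!(v %in% c(0, 1)))
  if (length(bad) > 0) {
    abort(paste0("Column `", name, "` must be coded 0/1; offending row(s): ",
                 paste(head(bad, 5), collapse = ", "),
                 " (value ", v[bad[1]], ")"))
  }
  as.integer(v)
}

# reference-cell coding of a covariate tibble into a numeric design matrix
build_design <- function(zdf, reference = NULL, standardize = FALSE) {
  if (ncol(zdf) == 0L) {
    return(matrix(numeric(0), nrow = nrow(zdf), ncol = 0))
  }
  zdf <- as.data.frame(zdf)
  for (nm in names(zdf)) {
    col <- zdf[[nm]]
    if (is.character(col) || is.logical(col)) col <- factor(col)
    if (is.factor(col)) {
      ref <- reference[[nm]]
      if (!is.null(ref)) {
        if (!ref %in% levels(col)) {
          abort(paste0("Reference level '", ref, "' not found in `", nm, "`."))
        }
        col <- stats::relevel(col, ref = ref)
      }
      if (nlevels(droplevels(col)) < 2L) {
        abort(paste0("Categorical covariate `", nm, "` has fewer than 2 levels."))
      }
      col <- droplevels(col)
    } else if (standardize) {
      col <- as.numeric(scale(col))
    }
    zdf[[nm]] <- col
  }
  mm <- model.matrix(~ ., data = zdf)
  zmat <- mm[, -1L, drop = FALSE]
  rownames(zmat) <- NULL
  if (anyDuplicated(colnames(zmat))) abort("Design matrix column labels are not unique.")
  zmat
}

# rebuild an mh_data from components (internal, used by bootstrap/simulation)
mh_data_from_parts <- function(x, y, z, template = NULL) {
  structure(
    list(
      x = as.integer(x), y = as.integer(y), z = z,
      covariate_names = colnames(z),
      n = length(x), m = ncol(z),
      n_dropped = 0L,
      x_name = template$x_name %||% "x",
      y_name = template$y_name %||% "y",
      z_names = template$z_names %||% colnames(z),
      raw = NULL
    ),
    class = "mh_data"
  )
}

#' Read subject-level data from a delimited text file
#'
#' Thin wrapper around [readr::read_delim()] followed by [mh_data()]. The
#' delimiter is auto-detected from the file extension (`.tsv`/`.txt` are
#' tab-delimited, anything else comma-delimited) unless given explicitly.
#'
#' @inheritParams mh_data
#' @param path Path to a delimited text file with a header row.
#' @param delim Field delimiter; `NULL` (default) auto-detects.
#' @return An `mh_data` object.
#' @export
read_mh_data <- function(path, x, y, z = character(), delim = NULL,
                         reference = NULL, standardize = FALSE, quiet = FALSE) {
  if (is.null(delim)) {
    delim <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
  }
  df <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                          progress = FALSE)
  mh_data(df, x = x, y = y, z = z, reference = reference,
          standardize = standardize, quiet = quiet)
}

#' @export
print.mh_data <- function(x, ...) {
  cat("<mh_data> ", x$n, " subjects, ", x$m, " design column(s)",
      if (x$n_dropped > 0) paste0(" (", x$n_dropped, " rows dropped)"), "\n",
      sep = "")
  cat("  x: ", x$x_name, "  y: ", x$y_name, "\n", sep = "")
  if (x$m > 0) cat("  z: ", paste(x$covariate_names, collapse = ", "), "\n", sep = "")
  tab <- marginal_table(x)
  cat("  marginal 2x2 (n00, n01, n10, n11): ",
      paste(tab, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' @method as_tibble mh_data
#' @export
as_tibble.mh_data <- function(x, ...) {
  out <- tibble::tibble(x = x$x, y = x$y)
  names(out) <- c(x$x_name, x$y_name)
  if (x$m > 0) out <- dplyr::bind_cols(out, tibble::as_tibble(x$z))
  out
}

# marginal (x, y) cell counts in the order n00, n01, n10, n11
marginal_table <- function(data) {
  idx <- 2L * data$x + data$y   # 0..3 maps to 00,01,10,11
  counts <- tabulate(idx + 1L, nbins = 4L)
  setNames(counts, c("n00", "n01", "n10", "n11"))
}

#' Stratify subjects on a categorical covariate
#'
#' Builds one 2-by-2 table of (x, y) counts per observed level of a
#' stratification variable, the input to the classical Mantel-Haenszel
#' estimator. Levels with zero margins are retained; they contribute zero
#' to the Mantel-Haenszel sums.
#'
#' @param data An `mh_data` object, or a data frame.
#' @param strata Name of the stratification column. For an `mh_data` object
#'   this must be one of the originally selected covariate columns.
#' @param x,y Outcome column names; only used when `data` is a plain data
#'   frame.
#' @return A tibble of class `mh_strata` with one row per stratum and
#'   columns `stratum`, `n00`, `n01`, `n10`, `n11`, `n`.
#' @export
mh_stratify <- function(data, strata, x = "x", y = "y") {
  if (inherits(data, "mh_data")) {
    if (is.null(data$raw)) abort("This mh_data object carries no raw columns.")
    if (!strata %in% names(data$raw)) {
      abort(paste0("`", strata, "` is not a selected column of this dataset."))
    }
    df <- tibble::tibble(x = data$x, y = data$y, s = data$raw[[strata]])
  } else {
    df <- tibble::tibble(x = check_binary(data[[x]], x),
                         y = check_binary(data[[y]], y),
                         s = data[[strata]])
  }
  out <- df |>
    dplyr::mutate(cell = paste0("n", .data$x, .data$y)) |>
    dplyr::count(.data$s, .data$cell) |>
    tidyr::pivot_wider(names_from = "cell", values_from = "n",
                       values_fill = 0L) |>
    dplyr::rename(stratum = "s")
  for (cell in c("n00", "n01", "n10", "n11")) {
    if (!cell %in% names(out)) out[[cell]] <- 0L
  }
  out <- out |>
    dplyr::select("stratum", "n00", "n01", "n10", "n11") |>
    dplyr::mutate(n = .data$n00 + .data$n01 + .data$n10 + .data$n11) |>
    dplyr::arrange(.data$stratum)
  class(out) <- c("mh_strata", class(out))
  out
}
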