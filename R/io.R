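#' Read a gene-expression dataset from ARFF or CSV
#'
#' ARFF files (dense dialect, numeric attributes with a nominal class) are
#' read with the last nominal attribute as the class unless `class_col`
#' names one; sparse ARFF rows are rejected. CSV files hold one instance
#' per row with a header of gene identifiers and a designated label column
#' (default `class`). Missing values are rejected with their locations, as
#' are non-numeric gene columns and single-class files.
#'
#' @param path Path to the file.
#' @param format `"auto"` (by extension), `"arff"` or `"csv"`.
#' @param class_col Name of the class attribute/column; `NULL` picks the
#'   last nominal ARFF attribute (for CSV, defaults to `"class"`).
#' @return A tibble of numeric gene columns plus a `class` factor column.
#' @export
read_dataset <- function(path, format = c("auto", "arff", "csv"),
                         class_col = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) abort(sprintf("File not found: %s", path))
  if (format == "auto") {
    format <- if (grepl("\\.arff$", path, ignore.case = TRUE)) "arff" else "csv"
  }
  if (format == "arff") {
    first_data <- FALSE
    for (ln in readLines(path, warn = FALSE)) {
      if (grepl("^\\s*@data", ln, ignore.case = TRUE)) first_data <- TRUE
      else if (first_data && grepl("^\\s*\\{", ln)) {
        abort("Sparse ARFF is not supported; supply a dense file.")
      }
    }
    df <- foreign::read.arff(path)
    nominal <- names(df)[vapply(df, is.factor, logical(1))]
    cls <- class_col %||% {
      if (length(nominal) == 0) abort("ARFF file has no nominal class attribute.")
      nominal[length(nominal)]
    }
  } else {
    df <- as.data.frame(readr::read_csv(path, show_col_types = FALSE,
                                        progress = FALSE))
    cls <- class_col %||% "class"
  }
  if (!cls %in% names(df)) {
    abort(sprintf("Class column `%s` not found.", cls))
  }
  na_cells <- which(is.na(as.matrix(df)), arr.ind = TRUE)
  if (nrow(na_cells) > 0) {
    loc <- apply(utils::head(na_cells, 5), 1, function(rc) {
      sprintf("row %d, column %s", rc[1], names(df)[rc[2]])
    })
    abort(sprintf("%d missing value(s), e.g. %s.",
                  nrow(na_cells), paste(loc, collapse = "; ")))
  }
  y <- droplevels(as.factor(df[[cls]]))
  if (nlevels(y) < 2) abort("Dataset has a single class.")
  genes <- df[setdiff(names(df), cls)]
  not_num <- names(genes)[!vapply(genes, is.numeric, logical(1))]
  if (length(not_num) > 0) {
    abort(sprintf("Non-numeric gene columns: %s.",
                  paste(utils::head(not_num, 5), collapse = ", ")))
  }
  if (ncol(genes) > 0 && is.null(names(genes))) {
    names(genes) <- sprintf("g%04d", seq_len(ncol(genes)))
  }
  out <- as_tibble(genes)
  out$class <- y
  out
}

#' Write a gene-expression dataset to ARFF or CSV
#'
#' ARFF output is dense, with real-typed gene attributes and the class as
#' the final nominal attribute; identical data always produce identical
#' bytes.
#'
#' @param data Data frame of gene columns plus the class column.
#' @param path Output path.
#' @param format `"auto"` (by extension), `"arff"` or `"csv"`.
#' @param class_col Name of the class column in `data`.
#' @return The path, invisibly.
#' @export
write_dataset <- function(data, path, format = c("auto", "arff", "csv"),
                          class_col = "class") {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.arff$", path, ignore.case = TRUE)) "arff" else "csv"
  }
  ds <- split_dataset(data, class_col) # validates
  df <- as.data.frame(data)
  # class last, as the conventional final nominal attribute
  df <- df[c(setdiff(names(df), class_col), class_col)]
  df[[class_col]] <- as.factor(df[[class_col]])
  if (format == "arff") {
    foreign::write.arff(df, path, relation = "expression")
  } else {
    readr::write_csv(df, path, progress = FALSE)
  }
  invisible(path)
}

#' Write / read a plain-text gene list
#'
#' One gene identifier per line; the interchange format for selected masks.
#'
#' @param genes Character vector of gene ids.
#' @param path File path.
#' @return `write_gene_list()` the path invisibly; `read_gene_list()` a
#'   character vector.
#' @export
write_gene_list <- function(genes, path) {
  writeLines(as.character(genes), path)
  invisible(path)
}

#' @rdname write_gene_list
#' @export
read_gene_list <- function(path) {
  out <- readLines(path, warn = FALSE)
  out[nzchar(out)]
}

#' Write / read a run configuration
#'
#' Serializes the optimizer, fitness and classifier settings of a run to
#' YAML so the exact configuration travels next to its results and
#' round-trips losslessly.
#'
#' @param config Named list (e.g. `list(epo = epo_config(), ...)`).
#' @param path File path (`.yaml`/`.yml` or `.json`).
#' @return `write_run_config()` the path invisibly; `read_run_config()` the
#'   named list.
#' @export
write_run_config <- function(config, path) {
  strip <- function(x) {
    if (is.list(x)) {
      x <- lapply(x, strip)
      attributes(x) <- list(names = names(x))
    }
    x
  }
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(strip(config), path, auto_unbox = TRUE, null = "null")
  } else {
    yaml::write_yaml(strip(config), path)
  }
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
}
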