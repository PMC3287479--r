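#' Individual-by-trait tables
#'
#' A `trait_table` holds one row per individual: an opaque unique id, a set
#' of traits (continuous, or nominal with unordered categories), and optional
#' covariate columns (e.g. sex, recruitment area) that are carried along but
#' never mined as traits.
#'
#' @param ids character vector of unique individual ids.
#' @param traits data.frame of trait columns (numeric, or character/factor
#'   for nominal traits), one row per individual.
#' @param covariates optional data.frame of covariate columns, same row
#'   order as `traits`.
#' @return An object of class `trait_table`.
#' @export
trait_table <- function(ids, traits, covariates = NULL) {
  ids <- as.character(ids)
  if (anyDuplicated(ids)) {
    stop2("duplicate individual_id: ",
          paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  traits <- as.data.frame(traits, stringsAsFactors = FALSE)
  if (ncol(traits) < 1L) stop2("a trait_table needs at least one trait")
  if (nrow(traits) != length(ids)) stop2("ids and traits disagree on N")
  if (!is.null(covariates)) {
    covariates <- as.data.frame(covariates, stringsAsFactors = FALSE)
    if (nrow(covariates) != length(ids)) stop2("covariates disagree on N")
  }
  structure(
    list(ids = ids, traits = traits, covariates = covariates),
    class = "trait_table"
  )
}

#' @export
print.trait_table <- function(x, ...) {
  cat(sprintf("<trait_table> %d individuals x %d traits", nrow(x$traits),
              ncol(x$traits)))
  if (!is.null(x$covariates)) {
    cat(sprintf(" (+%d covariates)", ncol(x$covariates)))
  }
  cat("\n  traits:", paste(trait_names(x), collapse = ", "), "\n")
  invisible(x)
}

#' @rdname trait_table
#' @param x a `trait_table`.
#' @export
trait_names <- function(x) names(x$traits)

#' @rdname trait_table
#' @export
n_individuals <- function(x) length(x$ids)

#' Read a trait table from TSV
#'
#' The file must be tab-delimited with a header row; the first column is the
#' individual id, the remaining columns are traits or covariates. Columns
#' whose non-missing values are all numeric are treated as continuous;
#' any other column must be declared in `nominal` or `covariate_cols`,
#' otherwise the offending cell is reported as an error.
#'
#' @param path path to a TSV file.
#' @param missing_marker string that encodes a missing value (default "NA").
#' @param nominal character vector of column names to treat as nominal
#'   traits (categories passed through as-is).
#' @param covariate_cols column names to set aside as covariates.
#' @return a [trait_table()].
#' @export
read_trait_table <- function(path, missing_marker = "NA",
                             nominal = character(),
                             covariate_cols = character()) {
  if (!file.exists(path)) stop2("no such file: ", path)
  raw <- utils::read.delim(path, colClasses = "character",
                           check.names = FALSE, na.strings = NULL)
  if (ncol(raw) < 2L) stop2("expected an id column plus >=1 trait column")
  ids <- raw[[1L]]
  body <- raw[-1L]
  is_cov <- names(body) %in% covariate_cols
  parse_col <- function(col, name) {
    miss <- col == missing_marker
    if (name %in% nominal) {
      col[miss] <- NA_character_
      return(col)
    }
    num <- suppressWarnings(as.numeric(col))
    bad <- which(!miss & is.na(num))
    if (length(bad)) {
      stop2(sprintf("non-numeric value '%s' in continuous column '%s', row %d",
                    col[bad[1L]], name, bad[1L]))
    }
    num[miss] <- NA_real_
    num
  }
  traits <- body[!is_cov]
  traits[] <- Map(parse_col, traits, names(traits))
  covs <- if (any(is_cov)) body[is_cov] else NULL
  tt <- trait_table(ids, traits, covs)
  message(sprintf("read %d individuals x %d traits from %s",
                  n_individuals(tt), length(trait_names(tt)), path))
  tt
}

#' Remove individuals with any missing trait value
#'
#' Mirrors the cohort cleaning step in which every individual missing at
#' least one trait is dropped before mining.
#'
#' @param table a [trait_table()].
#' @return the filtered `trait_table`; the number removed is reported.
#' @export
filter_complete <- function(table) {
  stopifnot(inherits(table, "trait_table"))
  miss <- Reduce(`|`, lapply(table$traits, is.na))
  keep <- !miss
  if (!any(keep)) stop2("all individuals have missing trait values")
  removed <- sum(!keep)
  message(sprintf("removed %d individuals with missing trait values", removed))
  out <- trait_table(table$ids[keep], table$traits[keep, , drop = FALSE],
                     if (!is.null(table$covariates))
                       table$covariates[keep, , drop = FALSE])
  attr(out, "n_removed") <- removed
  out
}

#' Drop named traits from a table
#'
#' @param table a [trait_table()].
#' @param names trait names to remove; all must be present.
#' @return the `trait_table` without those traits, column order preserved.
#' @export
drop_traits <- function(table, names) {
  stopifnot(inherits(table, "trait_table"))
  unknown <- setdiff(names, trait_names(table))
  if (length(unknown)) {
    stop2("unknown trait(s): ", paste(unknown, collapse = ", "))
  }
  keep <- setdiff(trait_names(table), names)
  if (!length(keep)) stop2("dropping all traits leaves an empty table")
  trait_table(table$ids, table$traits[keep], table$covariates)
}
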