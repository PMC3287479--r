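#' Quantile discretization schemes
#'
#' Traits are turned into ordered levels 1..n_levels ("TG5" = top fifth of
#' triglycerides) by cutting at empirical quantiles. Cut points use the
#' inverse-ECDF (type 1) quantile so that, for all-distinct values, level
#' occupancies differ from N/n_levels by at most one individual. Values
#' exactly equal to a cut point fall in the lower level; this tie rule is
#' deterministic and independent of row order. Nominal traits keep one item
#' per observed category.
#'
#' @param table a [trait_table()].
#' @param n_levels number of ordered levels per continuous trait (default 5,
#'   giving the quintile vocabulary).
#' @return a `disc_scheme`: per-trait cut points (continuous) or category
#'   levels (nominal), plus `n_levels` and the method tag.
#' @export
fit_quantile_scheme <- function(table, n_levels = 5L) {
  stopifnot(inherits(table, "trait_table"))
  n_levels <- as.integer(n_levels)
  if (n_levels < 2L) stop2("n_levels must be >= 2")
  cuts <- lapply(trait_names(table), function(nm) {
    x <- table$traits[[nm]]
    if (!is.numeric(x)) {
      lev <- sort(unique(x[!is.na(x)]))
      if (!length(lev)) stop2("trait '", nm, "' has no observed categories")
      return(list(type = "categorical", levels = lev))
    }
    x <- x[!is.na(x)]
    if (length(unique(x)) < n_levels) {
      stop2("trait '", nm, "' has fewer than ", n_levels,
            " distinct values (constant or near-constant)")
    }
    cp <- unname(stats::quantile(x, probs = seq_len(n_levels - 1L) / n_levels,
                                 type = 1, names = FALSE))
    if (any(diff(cp) <= 0)) {
      stop2("trait '", nm, "' yields non-increasing quantile cuts; ",
            "too many ties for ", n_levels, " levels")
    }
    list(type = "quantile", cuts = cp)
  })
  names(cuts) <- trait_names(table)
  structure(list(n_levels = n_levels, traits = cuts, method = "quantile"),
            class = "disc_scheme")
}

#' Build a fixed-cut scheme
#'
#' Alternative to [fit_quantile_scheme()] for clinically motivated cut
#' points (e.g. LDL-C at 100/130/160/190 mg/dl).
#'
#' @param cuts named list; each element a strictly increasing numeric vector
#'   of cut points for one trait.
#' @param n_levels number of levels implied (must equal length(cuts)+1 for
#'   every trait).
#' @export
fixed_scheme <- function(cuts, n_levels = NULL) {
  n_levels <- as.integer(n_levels %||% (length(cuts[[1L]]) + 1L))
  traits <- lapply(names(cuts), function(nm) {
    cp <- cuts[[nm]]
    if (any(diff(cp) <= 0)) stop2("cuts for '", nm, "' not strictly increasing")
    if (length(cp) != n_levels - 1L) {
      stop2("trait '", nm, "' needs ", n_levels - 1L, " cut points")
    }
    list(type = "fixed", cuts = unname(cp))
  })
  names(traits) <- names(cuts)
  structure(list(n_levels = n_levels, traits = traits, method = "fixed"),
            class = "disc_scheme")
}

#' @export
print.disc_scheme <- function(x, ...) {
  cat(sprintf("<disc_scheme> %s, %d levels, %d traits\n", x$method,
              x$n_levels, length(x$traits)))
  invisible(x)
}

# level of value v given cuts c1<...<ck: 1 + #(cuts < v); ties -> lower level
value_level <- function(v, cuts) 1L + findInterval(v, cuts, left.open = TRUE)

#' Itemize a trait table
#'
#' Each individual becomes a transaction of items "<TRAIT><level>". Missing
#' trait values contribute no item, so a transaction holds exactly one item
#' per non-missing trait.
#'
#' @param table a [trait_table()].
#' @param scheme a scheme from [fit_quantile_scheme()] or [fixed_scheme()]
#'   fitted on a compatible trait set.
#' @return an `itemized` object: `transactions` (list of character vectors),
#'   `items` (vocabulary), `ids`.
#' @export
itemize <- function(table, scheme) {
  stopifnot(inherits(table, "trait_table"), inherits(scheme, "disc_scheme"))
  missing_traits <- setdiff(trait_names(table), names(scheme$traits))
  if (length(missing_traits)) {
    stop2("scheme lacks trait(s): ", paste(missing_traits, collapse = ", "))
  }
  n <- n_individuals(table)
  per_trait <- lapply(trait_names(table), function(nm) {
    sc <- scheme$traits[[nm]]
    x <- table$traits[[nm]]
    if (sc$type == "categorical") {
      lev <- match(as.character(x), sc$levels)
      if (any(!is.na(x) & is.na(lev))) {
        stop2("trait '", nm, "' has categories unseen by the scheme")
      }
    } else {
      lev <- value_level(x, sc$cuts)
      lev[is.na(x)] <- NA_integer_
    }
    ifelse(is.na(lev), NA_character_, paste0(nm, lev))
  })
  item_mat <- do.call(cbind, per_trait)
  transactions <- apply(item_mat, 1L, function(r) r[!is.na(r)],
                        simplify = FALSE)
  vocab <- sort(unique(unlist(transactions)))
  itemized(transactions, ids = table$ids, items = vocab)
}

#' Construct an itemized transaction set
#'
#' @param transactions list of character vectors (one per individual); no
#'   duplicate items within a transaction.
#' @param ids optional individual ids.
#' @param items optional vocabulary (defaults to union of transactions).
#' @export
itemized <- function(transactions, ids = NULL, items = NULL) {
  if (any(vapply(transactions, anyDuplicated, 0L) > 0L)) {
    stop2("a transaction contains duplicate items")
  }
  items <- items %||% sort(unique(unlist(transactions)))
  structure(
    list(transactions = transactions,
         ids = ids %||% as.character(seq_along(transactions)),
         items = items),
    class = "itemized"
  )
}

#' @export
print.itemized <- function(x, ...) {
  cat(sprintf("<itemized> %d transactions, %d items\n",
              length(x$transactions), length(x$items)))
  invisible(x)
}

#' Transaction text and scheme YAML round-trips
#'
#' Transactions serialize as one line per individual of space-separated item
#' tokens (the common input dialect of generic itemset miners); ids are not
#' kept. Schemes serialize as YAML.
#'
#' @param x an `itemized` object (or a `disc_scheme` for the scheme pair).
#' @param path output/input file path.
#' @name transaction_io
#' @export
write_transactions <- function(x, path) {
  stopifnot(inherits(x, "itemized"))
  writeLines(vapply(x$transactions, paste, "", collapse = " "), path)
  invisible(path)
}

#' @rdname transaction_io
#' @export
read_transactions <- function(path) {
  lines <- readLines(path)
  itemized(lapply(strsplit(lines, " ", fixed = TRUE),
                  function(t) t[nzchar(t)]))
}

#' @rdname transaction_io
#' @export
write_scheme <- function(x, path) {
  stopifnot(inherits(x, "disc_scheme"))
  yaml::write_yaml(unclass(x), path, precision = 15L)
  invisible(path)
}

#' @rdname transaction_io
#' @export
read_scheme <- function(path) {
  x <- yaml::read_yaml(path)
  x$n_levels <- as.integer(x$n_levels)
  structure(x, class = "disc_scheme")
}
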