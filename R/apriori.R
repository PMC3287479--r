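#' APRIORI frequent itemset mining
#'
#' Level-wise search exploiting downward closure of support: every
#' (k-1)-subset of a frequent k-itemset must itself be frequent, so
#' candidate k-sets are generated by joining frequent (k-1)-sets sharing
#' their first k-2 items (in canonical lexicographic order) and pruned
#' before counting. Support is kept as an exact transaction count
#' internally; the `support` column is count/N.
#'
#' @param data an `itemized` transaction set (see [itemize()]).
#' @param min_sup minimum support as a fraction in (0, 1].
#' @param max_len largest itemset size to mine (default 5: rule bodies of
#'   up to four items plus a single-item head).
#' @return an `itemset_set`: data.frame with columns `items`
#'   (";"-joined, canonically ordered), `size`, `count`, `support`;
#'   attribute `n_transactions`.
#' @export
apriori <- function(data, min_sup = 0.01, max_len = 5L) {
  stopifnot(inherits(data, "itemized"))
  if (!length(data$transactions)) stop2("empty transaction database")
  if (min_sup <= 0 || min_sup > 1) stop2("min_sup must be in (0, 1]")
  max_len <- as.integer(max_len)
  if (max_len < 1L) stop2("max_len must be >= 1")

  vocab <- sort(data$items)
  n <- length(data$transactions)
  # transaction-by-item incidence matrix; vocabularies here are small
  # (<= traits x levels) so a dense logical matrix is the right tool
  mat <- matrix(FALSE, n, length(vocab), dimnames = list(NULL, vocab))
  for (i in seq_len(n)) {
    mat[i, match(data$transactions[[i]], vocab)] <- TRUE
  }
  min_count <- ceiling(min_sup * n - 1e-9)

  counts <- colSums(mat)
  keep <- counts >= min_count
  frequent <- list()
  if (any(keep)) {
    frequent[[1L]] <- list(sets = as.list(vocab[keep]),
                           counts = unname(counts[keep]))
  }
  k <- 1L
  while (k < max_len && length(frequent) == k && length(frequent[[k]]$sets) > 1L) {
    prev <- frequent[[k]]$sets
    prev_keys <- vapply(prev, paste, "", collapse = ";")
    cand <- list()
    # join step: pairs agreeing on the first k-1 items
    prefixes <- vapply(prev, function(s) paste(s[-length(s)], collapse = ";"), "")
    for (grp in split(seq_along(prev), prefixes)) {
      if (length(grp) < 2L) next
      lasts <- vapply(prev[grp], function(s) s[length(s)], "")
      ord <- order(lasts)
      grp <- grp[ord]; lasts <- lasts[ord]
      for (a in seq_len(length(grp) - 1L)) {
        for (b in (a + 1L):length(grp)) {
          cand[[length(cand) + 1L]] <- c(prev[[grp[a]]], lasts[b])
        }
      }
    }
    if (!length(cand)) break
    # prune step: all k-subsets of a candidate must be frequent
    ok <- vapply(cand, function(s) {
      all(vapply(seq_along(s), function(d)
        paste(s[-d], collapse = ";") %in% prev_keys, TRUE))
    }, TRUE)
    cand <- cand[ok]
    if (!length(cand)) break
    cnt <- vapply(cand, function(s) {
      sum(rowSums(mat[, s, drop = FALSE]) == length(s))
    }, 0)
    keep <- cnt >= min_count
    if (!any(keep)) break
    k <- k + 1L
    frequent[[k]] <- list(sets = cand[keep], counts = unname(cnt[keep]))
  }

  sets <- unlist(lapply(frequent, `[[`, "sets"), recursive = FALSE)
  cnts <- unlist(lapply(frequent, `[[`, "counts"))
  out <- data.frame(
    items = vapply(sets, paste, "", collapse = ";"),
    size = vapply(sets, length, 0L),
    count = as.integer(cnts %||% integer()),
    support = (cnts %||% numeric()) / n,
    stringsAsFactors = FALSE
  )
  out <- out[order(out$size, out$items), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, n_transactions = n, class = c("itemset_set", "data.frame"))
}

#' Generate association rules from frequent itemsets
#'
#' For every frequent itemset Z of size >= 2 and every item y of Z
#' (optionally restricted to a head whitelist), the rule Z\\{y} -> y is
#' emitted when its confidence s(Z)/s(Z\\{y}) reaches `min_conf`. Heads are
#' single items: the mined patterns describe which trait levels predict one
#' trait of interest. All metrics come from the stored supports; nothing is
#' recounted.
#'
#' @param frequent an `itemset_set` from [apriori()] (closed under subsets).
#' @param min_conf minimum confidence in \[0, 1\].
#' @param heads optional character vector restricting rule heads.
#' @return a `rule_set`: data.frame with columns `body` (";"-joined),
#'   `head`, `support`, `confidence`, `lift`.
#' @export
generate_rules <- function(frequent, min_conf = 0.10, heads = NULL) {
  stopifnot(inherits(frequent, "itemset_set"))
  supp <- stats::setNames(frequent$support, frequent$items)
  rows <- list()
  big <- frequent[frequent$size >= 2L, , drop = FALSE]
  for (i in seq_len(nrow(big))) {
    z <- strsplit(big$items[i], ";", fixed = TRUE)[[1L]]
    s_z <- big$support[i]
    for (y in z) {
      if (!is.null(heads) && !(y %in% heads)) next
      body <- setdiff(z, y)
      key <- paste(body, collapse = ";")
      s_body <- supp[key]
      s_head <- supp[y]
      if (is.na(s_body) || is.na(s_head)) {
        stop2("missing subset support for {", key, "} or {", y,
              "}: frequent set is not closed under subsets")
      }
      conf <- s_z / s_body
      if (conf >= min_conf - 1e-12) {
        rows[[length(rows) + 1L]] <- data.frame(
          body = key, head = y, support = s_z, confidence = conf,
          lift = conf / s_head, stringsAsFactors = FALSE)
      }
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(body = character(), head = character(), support = numeric(),
               confidence = numeric(), lift = numeric())
  out <- out[order(out$head, out$body), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("rule_set", "data.frame"))
}

#' Rule-form constraints
#'
#' A constraint of the style "TG5 must appear in the rule (either side) and
#' confidence >= 0.7, lift >= 1, support >= 0.025". All clauses are optional;
#' an empty constraint keeps everything.
#'
#' @param item required item (NULL for none).
#' @param side where the item must appear: "body", "head" or "either".
#' @param min_sup,min_conf,min_lift metric thresholds.
#' @param max_body_size largest admissible body.
#' @export
rule_constraint <- function(item = NULL, side = c("either", "body", "head"),
                            min_sup = 0, min_conf = 0, min_lift = 0,
                            max_body_size = Inf) {
  side <- match.arg(side)
  if (min_sup < 0 || min_sup > 1 || min_conf < 0 || min_conf > 1) {
    stop2("support/confidence thresholds must lie in [0, 1]")
  }
  if (min_lift < 0) stop2("min_lift must be >= 0")
  structure(list(item = item, side = side, min_sup = min_sup,
                 min_conf = min_conf, min_lift = min_lift,
                 max_body_size = max_body_size),
            class = "rule_constraint")
}

#' Filter rules by a constraint
#'
#' Pure predicate evaluation over stored metrics; nothing is recomputed.
#'
#' @param rules a `rule_set`.
#' @param constraint a [rule_constraint()].
#' @return the surviving `rule_set`, order preserved.
#' @export
filter_rules <- function(rules, constraint) {
  stopifnot(inherits(rules, "rule_set"), inherits(constraint, "rule_constraint"))
  if (!nrow(rules)) return(rules)
  bodies <- strsplit(rules$body, ";", fixed = TRUE)
  keep <- rules$support >= constraint$min_sup &
    rules$confidence >= constraint$min_conf &
    rules$lift >= constraint$min_lift &
    lengths(bodies) <= constraint$max_body_size
  if (!is.null(constraint$item)) {
    in_body <- vapply(bodies, function(b) constraint$item %in% b, TRUE)
    in_head <- rules$head == constraint$item
    keep <- keep & switch(constraint$side,
                          body = in_body, head = in_head,
                          either = in_body | in_head)
  }
  out <- rules[keep, , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("rule_set", "data.frame"))
}

#' Rule CSV round-trip
#'
#' Columns: rule_id, body (";"-joined items), head, support, confidence,
#' lift. Metrics are written at full precision so read(write(x)) == x.
#'
#' @param rules a `rule_set`.
#' @param path CSV path.
#' @name rule_io
#' @export
write_rules <- function(rules, path) {
  stopifnot(inherits(rules, "rule_set"))
  df <- data.frame(rule_id = seq_len(nrow(rules)),
                   body = rules$body, head = rules$head,
                   support = format(rules$support, digits = 17,
                                    scientific = FALSE, trim = TRUE),
                   confidence = format(rules$confidence, digits = 17,
                                       scientific = FALSE, trim = TRUE),
                   lift = format(rules$lift, digits = 17,
                                 scientific = FALSE, trim = TRUE))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname rule_io
#' @export
read_rules <- function(path) {
  lines <- readLines(path)
  if (!length(lines)) stop2("empty rule file: ", path)
  header <- strsplit(lines[1L], ",", fixed = TRUE)[[1L]]
  want <- c("rule_id", "body", "head", "support", "confidence", "lift")
  if (!identical(header, want)) stop2("malformed rule CSV header in ", path)
  parse_row <- function(i) {
    f <- strsplit(lines[i], ",", fixed = TRUE)[[1L]]
    if (length(f) != 6L) stop2("malformed rule row at line ", i, " of ", path)
    nums <- suppressWarnings(as.numeric(f[4:6]))
    if (anyNA(nums)) stop2("non-numeric metric at line ", i, " of ", path)
    data.frame(body = f[2L], head = f[3L], support = nums[1L],
               confidence = nums[2L], lift = nums[3L],
               stringsAsFactors = FALSE)
  }
  out <- if (length(lines) > 1L) {
    do.call(rbind, lapply(2:length(lines), parse_row))
  } else {
    data.frame(body = character(), head = character(), support = numeric(),
               confidence = numeric(), lift = numeric())
  }
  rownames(out) <- NULL
  structure(out, class = c("rule_set", "data.frame"))
}
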