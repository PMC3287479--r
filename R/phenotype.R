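#' Phenotype predicates and case/control definitions
#'
#' A predicate constrains one trait: a threshold comparison (">=" / "<=",
#' e.g. LDL >= 130 mg/dl) or membership in a set of discretized levels
#' ("in", e.g. the top quintile). A phenotype definition names a case
#' conjunction and a control conjunction; individuals satisfying neither
#' are excluded, which is what makes multivariate designs much smaller
#' than the cohort.
#'
#' @param trait trait name.
#' @param op one of ">=", "<=", "in".
#' @param value finite numeric threshold, or (for "in") a non-empty integer
#'   set of levels.
#' @export
phenotype_predicate <- function(trait, op = c(">=", "<=", "in"), value) {
  op <- match.arg(op)
  if (op == "in") {
    if (!length(value)) stop2("level set must be non-empty")
  } else if (!is.finite(value)) {
    stop2("threshold for ", trait, " must be finite")
  }
  structure(list(trait = trait, op = op, value = value),
            class = "phenotype_predicate")
}

#' @rdname phenotype_predicate
#' @param name definition name (e.g. "highLDLhighTG").
#' @param case,control lists of predicates, interpreted as conjunctions.
#' @export
phenotype_definition <- function(name, case, control) {
  stopifnot(all(vapply(case, inherits, TRUE, "phenotype_predicate")),
            all(vapply(control, inherits, TRUE, "phenotype_predicate")))
  structure(list(name = name, case = case, control = control),
            class = "phenotype_definition")
}

#' @export
print.phenotype_definition <- function(x, ...) {
  fmt <- function(p) if (p$op == "in") {
    sprintf("%s in {%s}", p$trait, paste(p$value, collapse = ","))
  } else sprintf("%s %s %s", p$trait, p$op, p$value)
  cat(sprintf("<phenotype_definition> %s\n  case:    %s\n  control: %s\n",
              x$name,
              paste(vapply(x$case, fmt, ""), collapse = " AND "),
              paste(vapply(x$control, fmt, ""), collapse = " AND ")))
  invisible(x)
}

#' Derive a case/control definition from mined rules
#'
#' The mined rules justify pairing two traits; the definition itself is
#' their extreme levels: cases are the conjunction of each trait's top
#' mined level, controls the conjunction of the bottom levels. Clinical
#' overrides replace the quintile memberships with guideline thresholds
#' (e.g. case LDL >= 130 & TG >= 180; control LDL <= 100 & TG <= 100).
#'
#' @param rules a `rule_set` that mentions extreme levels of both traits.
#' @param traits character(2): the two trait names (trait_i, trait_j).
#' @param overrides optional list with elements `case` and `control`, each
#'   a named numeric vector of thresholds per trait.
#' @param n_levels number of discretization levels (default 5).
#' @return a [phenotype_definition()].
#' @export
derive_definition <- function(rules, traits, overrides = NULL, n_levels = 5L) {
  stopifnot(inherits(rules, "rule_set"), length(traits) == 2L)
  all_items <- unique(c(unlist(strsplit(rules$body, ";", fixed = TRUE)),
                        rules$head))
  mk <- function(trait, side) {
    lev <- suppressWarnings(as.integer(sub(paste0("^", trait), "",
      grep(paste0("^", trait, "[0-9]+$"), all_items, value = TRUE))))
    if (!length(lev)) stop2("trait '", trait, "' absent from rule set")
    ov <- overrides[[side]]
    if (!is.null(ov) && trait %in% names(ov)) {
      return(phenotype_predicate(trait, if (side == "case") ">=" else "<=",
                                 ov[[trait]]))
    }
    phenotype_predicate(trait, "in",
                        if (side == "case") max(lev) else 1L)
  }
  phenotype_definition(
    name = paste0("high", traits[1L], "high", traits[2L]),
    case = lapply(traits, mk, side = "case"),
    control = lapply(traits, mk, side = "control")
  )
}

#' Project a bivariate definition onto one trait
#'
#' Gives the single-trait designs used for the companion genome scans
#' (e.g. highLDL: case LDL >= 130, control LDL <= 100).
#'
#' @param defn a [phenotype_definition()].
#' @param trait which trait to keep.
#' @export
project_definition <- function(defn, trait) {
  pick <- function(preds) Filter(function(p) p$trait == trait, preds)
  case <- pick(defn$case); control <- pick(defn$control)
  if (!length(case) || !length(control)) {
    stop2("trait '", trait, "' not in definition '", defn$name, "'")
  }
  phenotype_definition(paste0("high", trait), case, control)
}

eval_predicate <- function(pred, table, scheme = NULL) {
  x <- table$traits[[pred$trait]]
  if (is.null(x)) stop2("trait '", pred$trait, "' missing from table")
  if (pred$op == "in") {
    if (is.null(scheme)) {
      stop2("level predicate on '", pred$trait, "' needs a disc_scheme")
    }
    lev <- value_level(x, scheme$traits[[pred$trait]]$cuts)
    out <- lev %in% pred$value
  } else {
    out <- if (pred$op == ">=") x >= pred$value else x <= pred$value
  }
  out & !is.na(x)
}

#' Assign case/control status
#'
#' An individual is a case iff every case predicate holds, a control iff
#' every control predicate holds, and excluded otherwise. The definition
#' must be empirically exclusive: any individual satisfying both
#' conjunctions is an error.
#'
#' @param table a [trait_table()].
#' @param defn a [phenotype_definition()].
#' @param scheme required when the definition uses level predicates.
#' @return a `cc_assignment`: data.frame(id, status) with status in
#'   case/control/excluded, covariates attached, plus count attributes.
#' @export
assign_phenotype <- function(table, defn, scheme = NULL) {
  stopifnot(inherits(table, "trait_table"),
            inherits(defn, "phenotype_definition"))
  is_case <- Reduce(`&`, lapply(defn$case, eval_predicate, table, scheme))
  is_ctrl <- Reduce(`&`, lapply(defn$control, eval_predicate, table, scheme))
  both <- which(is_case & is_ctrl)
  if (length(both)) {
    stop2("case and control predicates overlap at individual '",
          table$ids[both[1L]], "'")
  }
  status <- ifelse(is_case, "case", ifelse(is_ctrl, "control", "excluded"))
  if (!any(is_case)) stop2("definition '", defn$name, "' yields zero cases")
  if (!any(is_ctrl)) stop2("definition '", defn$name, "' yields zero controls")
  out <- data.frame(id = table$ids, status = status, stringsAsFactors = FALSE)
  if (!is.null(table$covariates)) out <- cbind(out, table$covariates)
  structure(out, phenotype = defn$name,
            counts = c(case = sum(is_case), control = sum(is_ctrl),
                       excluded = sum(status == "excluded")),
            class = c("cc_assignment", "data.frame"))
}

#' Stratified descriptive summary
#'
#' Per status x covariate-level stratum: n, mean and SD of each requested
#' trait. Strata of one individual report SD = 0 with `degenerate = TRUE`;
#' empty strata report n = 0 and no statistics.
#'
#' @param assignment a `cc_assignment`.
#' @param table the matching [trait_table()].
#' @param covariates covariate column names to stratify on (each considered
#'   separately, as in a descriptive cohort table).
#' @param traits trait names to summarize (default all numeric traits).
#' @return long data.frame: status, covariate, stratum, trait, n, mean, sd,
#'   degenerate.
#' @export
summarize_assignment <- function(assignment, table, covariates,
                                 traits = NULL) {
  stopifnot(inherits(assignment, "cc_assignment"))
  missing_cov <- setdiff(covariates, names(assignment))
  if (length(missing_cov)) {
    stop2("covariate(s) not in assignment: ",
          paste(missing_cov, collapse = ", "))
  }
  traits <- traits %||%
    trait_names(table)[vapply(table$traits, is.numeric, TRUE)]
  ix <- match(assignment$id, table$ids)
  rows <- list()
  for (st in c("control", "case")) {
    in_st <- assignment$status == st
    for (cv in covariates) {
      for (lev in sort(unique(assignment[[cv]]))) {
        sel <- in_st & assignment[[cv]] == lev
        for (tr in traits) {
          v <- table$traits[[tr]][ix[sel]]
          v <- v[!is.na(v)]
          n <- length(v)
          rows[[length(rows) + 1L]] <- data.frame(
            status = st, covariate = cv, stratum = as.character(lev),
            trait = tr, n = n,
            mean = if (n) mean(v) else NA_real_,
            sd = if (n > 1L) stats::sd(v) else if (n == 1L) 0 else NA_real_,
            degenerate = n == 1L, stringsAsFactors = FALSE)
        }
      }
    }
  }
  do.call(rbind, rows)
}

#' @rdname summarize_assignment
#' @param summary output of `summarize_assignment`.
#' @param path TSV output path.
#' @export
write_summary <- function(summary, path) {
  utils::write.table(summary, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Sex-by-status test of independence
#'
#' 2x2 chi-square of case/control status against sex, reported both with
#' the Yates continuity correction (sum of (|O-E|-0.5)^2/E, the value such
#' cohort tables usually print) and without.
#'
#' @param x either a 2x2 count matrix (rows = status, cols = sex) or a
#'   `cc_assignment` with a sex covariate.
#' @param sex_col covariate column holding sex when `x` is an assignment.
#' @return list with `statistic` (corrected), `uncorrected`, `df`,
#'   `p.value`, `p.uncorrected` and the observed table.
#' @export
sex_by_status_test <- function(x, sex_col = "SEX") {
  if (inherits(x, "cc_assignment")) {
    if (!sex_col %in% names(x)) stop2("no covariate column '", sex_col, "'")
    kept <- x[x$status %in% c("case", "control"), ]
    x <- table(kept$status, kept[[sex_col]])
  }
  x <- as.matrix(x)
  if (!all(dim(x) == 2L)) stop2("need a 2x2 table (both sexes, both statuses)")
  if (any(rowSums(x) == 0) || any(colSums(x) == 0)) {
    stop2("zero marginal in the 2x2 table")
  }
  n <- sum(x)
  e <- outer(rowSums(x), colSums(x)) / n
  raw <- sum((x - e)^2 / e)
  adj <- abs(x - e) - 0.5
  adj[adj < 0] <- 0  # correction never overshoots
  corrected <- sum(adj^2 / e)
  list(statistic = corrected,
       uncorrected = raw,
       df = 1L,
       p.value = stats::pchisq(corrected, 1L, lower.tail = FALSE),
       p.uncorrected = stats::pchisq(raw, 1L, lower.tail = FALSE),
       observed = x)
}

#' Write a PLINK-compatible phenotype file
#'
#' Columns FID IID PHENO with 2 = case, 1 = control, -9 = excluded.
#'
#' @param assignment a `cc_assignment`.
#' @param path output path.
#' @export
write_phenotype_file <- function(assignment, path) {
  stopifnot(inherits(assignment, "cc_assignment"))
  code <- c(case = 2L, control = 1L, excluded = -9L)[assignment$status]
  utils::write.table(
    data.frame(FID = assignment$id, IID = assignment$id, PHENO = code),
    path, sep = " ", row.names = FALSE, col.names = FALSE, quote = FALSE)
  invisible(path)
}
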