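#' Allelic case-control test
#'
#' The 1-df chi-square on the 2x2 table of allele counts (cases vs controls,
#' allele1 vs allele2), without continuity correction — the basic allelic
#' test of a PLINK case/control workflow. The odds ratio is (a*d)/(b*c),
#' oriented on allele1, with the Haldane-Anscombe 0.5 added to every cell
#' only when some cell is zero (and only for the OR, never the chi-square).
#' A zero marginal yields chi2 = 0, p = 1 and an undefined (NA) OR.
#'
#' All four arguments are vectorized.
#'
#' @param a,b allele1 and allele2 counts in cases.
#' @param d,c_ allele2 and allele1 counts in controls (`c_` = allele1).
#' @return data.frame with columns chi2, p, OR, or_undefined.
#' @export
allelic_test <- function(a, b, c_, d) {
  a <- as.numeric(a); b <- as.numeric(b); c_ <- as.numeric(c_); d <- as.numeric(d)
  n <- a + b + c_ + d
  if (any(n <= 0)) stop2("allelic_test needs a positive total count")
  r1 <- a + b; r2 <- c_ + d; c1 <- a + c_; c2 <- b + d
  zero_marg <- r1 == 0 | r2 == 0 | c1 == 0 | c2 == 0
  chi2 <- ifelse(zero_marg, 0, n * (a * d - b * c_)^2 /
                   pmax(r1 * r2 * c1 * c2, .Machine$double.xmin))
  p <- ifelse(zero_marg, 1, stats::pchisq(chi2, 1L, lower.tail = FALSE))
  any_zero <- a == 0 | b == 0 | c_ == 0 | d == 0
  aa <- a + 0.5 * any_zero; bb <- b + 0.5 * any_zero
  cc <- c_ + 0.5 * any_zero; dd <- d + 0.5 * any_zero
  or <- ifelse(zero_marg, NA_real_, (aa * dd) / (bb * cc))
  data.frame(chi2 = chi2, p = p, OR = or, or_undefined = zero_marg)
}

#' Genome-wide case-control scan
#'
#' One allelic test per variant over the individuals assigned case or
#' control; excluded individuals and missing genotypes contribute nothing.
#' Results come back sorted by (chr, position).
#'
#' @param gm a [genotype_matrix()].
#' @param assignment a `cc_assignment` (see [assign_phenotype()]).
#' @return an `assoc_result` data.frame: snp_id, chr, pos, allele1, allele2,
#'   f_case, f_control, maf, the four allele counts, chi2, p, OR.
#' @export
genome_scan <- function(gm, assignment) {
  stopifnot(inherits(gm, "genotype_matrix"),
            inherits(assignment, "cc_assignment"))
  st <- assignment$status[match(gm$ids, assignment$id)]
  case_rows <- which(!is.na(st) & st == "case")
  ctrl_rows <- which(!is.na(st) & st == "control")
  if (!length(case_rows) && !length(ctrl_rows)) {
    stop2("no overlap between genotype sample ids and the assignment")
  }
  if (!length(case_rows) || !length(ctrl_rows)) {
    stop2("need at least one case and one control among genotyped samples")
  }
  count_side <- function(rows) {
    sub <- gm$geno[rows, , drop = FALSE]
    nonmiss <- colSums(!is.na(sub))
    a1 <- colSums(sub, na.rm = TRUE)
    list(a1 = a1, a2 = 2 * nonmiss - a1)
  }
  cs <- count_side(case_rows)
  ct <- count_side(ctrl_rows)
  tst <- allelic_test(cs$a1, cs$a2, ct$a1, ct$a2)
  tot1 <- cs$a1 + ct$a1; tot <- cs$a1 + cs$a2 + ct$a1 + ct$a2
  out <- data.frame(
    snp_id = gm$map$snp_id, chr = gm$map$chr, pos = gm$map$pos,
    allele1 = gm$map$allele1, allele2 = gm$map$allele2,
    f_case = ifelse(cs$a1 + cs$a2 > 0, cs$a1 / (cs$a1 + cs$a2), NA_real_),
    f_control = ifelse(ct$a1 + ct$a2 > 0, ct$a1 / (ct$a1 + ct$a2), NA_real_),
    maf = ifelse(tot > 0, pmin(tot1 / tot, 1 - tot1 / tot), NA_real_),
    n_case_a1 = cs$a1, n_case_a2 = cs$a2,
    n_control_a1 = ct$a1, n_control_a2 = ct$a2,
    chi2 = tst$chi2, p = tst$p, OR = tst$OR,
    stringsAsFactors = FALSE
  )
  out <- out[order(out$chr, out$pos), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, n_case = length(case_rows), n_control = length(ctrl_rows),
            class = c("assoc_result", "data.frame"))
}

#' Stratified replication scans
#'
#' Re-runs the scan independently within each level of a covariate (e.g.
#' recruitment area or sex), then on the union of usable strata. Strata
#' with fewer than two cases or two controls are skipped with a warning.
#'
#' @param gm a [genotype_matrix()].
#' @param assignment a `cc_assignment` carrying the covariate.
#' @param strata covariate column name.
#' @param snps optional snp_id whitelist to restrict the scans (the usual
#'   replication design: only the discovery survivors are re-tested).
#' @return named list of `assoc_result`s, one per stratum, plus
#'   `"combined"`.
#' @export
replicate_stratified <- function(gm, assignment, strata, snps = NULL) {
  stopifnot(inherits(assignment, "cc_assignment"))
  if (!strata %in% names(assignment)) {
    stop2("unknown stratum covariate: ", strata)
  }
  if (!is.null(snps)) {
    keep <- gm$map$snp_id %in% snps
    gm <- genotype_matrix(gm$map[keep, , drop = FALSE],
                          gm$geno[, keep, drop = FALSE], gm$ids)
  }
  out <- list()
  used <- character()
  for (lev in sort(unique(assignment[[strata]]))) {
    sub <- assignment[assignment[[strata]] == lev, , drop = FALSE]
    cls <- c("cc_assignment", "data.frame")
    class(sub) <- cls
    n_case <- sum(sub$status == "case")
    n_ctrl <- sum(sub$status == "control")
    if (n_case < 2L || n_ctrl < 2L) {
      warning(sprintf("stratum '%s' skipped: %d cases, %d controls",
                      lev, n_case, n_ctrl))
      next
    }
    out[[as.character(lev)]] <- genome_scan(gm, sub)
    used <- c(used, as.character(lev))
  }
  if (length(used)) {
    comb <- assignment[assignment[[strata]] %in% used, , drop = FALSE]
    class(comb) <- c("cc_assignment", "data.frame")
    out[["combined"]] <- genome_scan(gm, comb)
  }
  out
}

#' Export scan results for Manhattan plotting
#'
#' TSV with columns chr, pos, snp, p, neglog10_p, ordered by (chr, pos).
#'
#' @param results an `assoc_result` (or empty data.frame).
#' @param path output path.
#' @export
export_manhattan <- function(results, path) {
  df <- data.frame(chr = results$chr, pos = results$pos,
                   snp = results$snp_id, p = results$p,
                   neglog10_p = -log10(pmax(results$p, 1e-300)))
  df <- df[order(df$chr, df$pos), , drop = FALSE]
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
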