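#' mOR: log10 ratio of single-trait to multivariate p-values
#'
#' `mOR = log10(p_single) - log10(p_multi)`. A value of 1 means the SNP's
#' association evidence is ten times stronger (in p-value terms) for the
#' multivariate phenotype than for the single trait — the pruning boundary
#' below which a SNP is considered to act on the single trait. Exactly
#' equal p-values give mOR = 0; the statistic chains additively,
#' mor(p1,p3) = mor(p1,p2) + mor(p2,p3). p-values that underflowed to 0
#' are floored at 1e-300 before taking logs.
#'
#' @param p_multi p-value from the multivariate-phenotype scan, in (0, 1].
#' @param p_single p-value from the single-trait scan, in (0, 1].
#' @return numeric, log10(p_single / p_multi). Vectorized.
#' @export
compute_mor <- function(p_multi, p_single) {
  if (any(p_multi < 0 | p_single < 0, na.rm = TRUE)) {
    stop2("p-values must be non-negative")
  }
  if (any(p_multi > 1 | p_single > 1, na.rm = TRUE)) {
    stop2("p-values must be <= 1")
  }
  log10(pmax(p_single, 1e-300)) - log10(pmax(p_multi, 1e-300))
}

#' Join three scans into an mOR table
#'
#' One record per SNP common to the multivariate scan and both single-trait
#' scans; SNPs absent from any scan are dropped with a warning.
#'
#' @param multi,single_i,single_j `assoc_result`s from [genome_scan()].
#' @return data.frame: snp_id, chr, pos, p_multi, OR, p_single_i,
#'   p_single_j, mor_i, mor_j.
#' @export
mor_table <- function(multi, single_i, single_j) {
  common <- Reduce(intersect, list(multi$snp_id, single_i$snp_id,
                                   single_j$snp_id))
  dropped <- length(unique(c(multi$snp_id, single_i$snp_id,
                             single_j$snp_id))) - length(common)
  if (!length(common)) stop2("no SNPs shared by the three scans")
  if (dropped > 0L) {
    warning(sprintf("%d SNP(s) missing from at least one scan were dropped",
                    dropped))
  }
  m <- multi[match(common, multi$snp_id), ]
  si <- single_i[match(common, single_i$snp_id), ]
  sj <- single_j[match(common, single_j$snp_id), ]
  out <- data.frame(
    snp_id = common, chr = m$chr, pos = m$pos,
    p_multi = m$p, OR = m$OR,
    p_single_i = si$p, p_single_j = sj$p,
    mor_i = compute_mor(m$p, si$p),
    mor_j = compute_mor(m$p, sj$p),
    stringsAsFactors = FALSE
  )
  out <- out[order(out$chr, out$pos), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Pairwise LD as squared dosage correlation
#'
#' Squared Pearson correlation of allele1 dosages over individuals
#' non-missing at both variants. Monomorphic variants in the
#' pairwise-complete subset give NA (treated as no LD by the clumper).
#'
#' @param gm a [genotype_matrix()].
#' @param snp_a,snp_b snp_ids.
#' @return r-squared in \[0, 1\], or NA when undefined.
#' @export
pairwise_r2 <- function(gm, snp_a, snp_b) {
  ia <- match(snp_a, gm$map$snp_id); ib <- match(snp_b, gm$map$snp_id)
  if (is.na(ia) || is.na(ib)) stop2("unknown snp_id in pairwise_r2")
  x <- gm$geno[, ia]; y <- gm$geno[, ib]
  ok <- !is.na(x) & !is.na(y)
  if (sum(ok) < 2L) stop2("fewer than 2 pairwise-complete individuals")
  x <- x[ok]; y <- y[ok]
  if (stats::var(x) == 0 || stats::var(y) == 0) return(NA_real_)
  stats::cor(x, y)^2
}

#' Clumping parameters
#'
#' Defaults follow the common PLINK clumping setup: index SNPs at
#' p <= 1e-5, clumped SNPs at p <= 1e-4, r2 >= 0.5 within 250 kb.
#'
#' @param p_index index-SNP p-value ceiling.
#' @param p_clumped clumped-SNP p-value ceiling (>= p_index).
#' @param r2_threshold minimum dosage r2 to join a clump.
#' @param window_kb physical window around the index, in kb.
#' @export
clump_spec <- function(p_index = 1e-5, p_clumped = 1e-4,
                       r2_threshold = 0.5, window_kb = 250L) {
  if (!(p_index > 0 && p_index <= p_clumped && p_clumped <= 1)) {
    stop2("need 0 < p_index <= p_clumped <= 1")
  }
  if (!(r2_threshold > 0 && r2_threshold <= 1)) {
    stop2("need 0 < r2_threshold <= 1")
  }
  structure(list(p_index = p_index, p_clumped = p_clumped,
                 r2_threshold = r2_threshold,
                 window_kb = as.integer(window_kb)),
            class = "clump_spec")
}

#' Greedy LD clumping
#'
#' SNPs with p <= p_index are visited in ascending p order (ties broken by
#' chromosome then position); each still-unclaimed one becomes an index and
#' claims every unclaimed SNP with p <= p_clumped on the same chromosome,
#' within the window, and with r2 >= the threshold. The outcome is
#' independent of input row order.
#'
#' @param results an `assoc_result` (needs snp_id, chr, pos, p).
#' @param gm the matching [genotype_matrix()] for r2.
#' @param spec a [clump_spec()].
#' @return data.frame: snp_id, chr, pos, p, clump_id (index snp_id, NA if
#'   in no clump), is_index, r2_to_index.
#' @export
greedy_clump <- function(results, gm, spec = clump_spec()) {
  stopifnot(inherits(spec, "clump_spec"))
  df <- data.frame(snp_id = results$snp_id, chr = results$chr,
                   pos = results$pos, p = results$p,
                   stringsAsFactors = FALSE)
  df <- df[order(df$chr, df$pos), , drop = FALSE]
  n <- nrow(df)
  clump_id <- rep(NA_character_, n)
  r2_to_index <- rep(NA_real_, n)
  is_index <- rep(FALSE, n)
  claimed <- rep(FALSE, n)
  cand <- which(df$p <= spec$p_index)
  cand <- cand[order(df$p[cand], df$chr[cand], df$pos[cand])]
  win <- spec$window_kb * 1000
  for (i in cand) {
    if (claimed[i]) next
    claimed[i] <- TRUE; is_index[i] <- TRUE
    clump_id[i] <- df$snp_id[i]; r2_to_index[i] <- 1
    near <- which(!claimed & df$chr == df$chr[i] &
                    abs(df$pos - df$pos[i]) <= win &
                    df$p <= spec$p_clumped)
    for (j in near) {
      r2 <- pairwise_r2(gm, df$snp_id[i], df$snp_id[j])
      if (!is.na(r2) && r2 >= spec$r2_threshold) {
        claimed[j] <- TRUE
        clump_id[j] <- df$snp_id[i]
        r2_to_index[j] <- r2
      }
    }
  }
  df$clump_id <- clump_id
  df$is_index <- is_index
  df$r2_to_index <- r2_to_index
  rownames(df) <- NULL
  df
}

#' Prune SNPs down to candidate pleiotropic loci
#'
#' Applies the three filters to the joined mOR/clump table:
#' (1) multivariate-scan p <= `p_multi_max`;
#' (2) mOR >= `mor_min` against *both* single traits (the intersection of
#'     the two single-trait-filtered sets);
#' (3) an LD-support condition with two selectable readings of the
#'     clumping rule: `"index_or_clumped"` (default) keeps SNPs belonging
#'     to a clump — i.e. the SNP is an index at p <= p_index or is claimed
#'     by one while itself meeting p <= p_clumped; `"index_only"` keeps
#'     index SNPs alone.
#'
#' Every input SNP is labelled with the first condition that removed it
#' ("p_multi", "mor", "clump") or "pass".
#'
#' @param mor output of [mor_table()].
#' @param clumps output of [greedy_clump()] on the multivariate scan.
#' @param p_multi_max condition (1) threshold (default 5e-4).
#' @param mor_min condition (2) threshold (default 1).
#' @param clump_rule condition (3) reading.
#' @return a `pruned_set`: the mOR table with clump columns,
#'   `filter_status`, and logical `survives`.
#' @export
prune_snps <- function(mor, clumps, p_multi_max = 5e-4, mor_min = 1,
                       clump_rule = c("index_or_clumped", "index_only")) {
  clump_rule <- match.arg(clump_rule)
  ix <- match(mor$snp_id, clumps$snp_id)
  if (anyNA(ix)) stop2("mOR table and clump table disagree on SNPs")
  df <- mor
  df$clump_id <- clumps$clump_id[ix]
  df$is_index <- clumps$is_index[ix]
  df$r2_to_index <- clumps$r2_to_index[ix]
  pass1 <- df$p_multi <= p_multi_max
  pass2 <- df$mor_i >= mor_min & df$mor_j >= mor_min
  pass3 <- if (clump_rule == "index_only") df$is_index else !is.na(df$clump_id)
  df$filter_status <- ifelse(!pass1, "p_multi",
                       ifelse(!pass2, "mor",
                        ifelse(!pass3, "clump", "pass")))
  df$survives <- df$filter_status == "pass"
  structure(df, thresholds = list(p_multi_max = p_multi_max,
                                  mor_min = mor_min,
                                  clump_rule = clump_rule),
            class = c("pruned_set", "data.frame"))
}

#' Write the pruning audit trail
#'
#' TSV mirroring the hit-table layout: SNP, chr, pos, p_multi, OR, mOR for
#' each single trait, r2 to the clump index, clump id, filter status.
#'
#' @param pruned a `pruned_set`.
#' @param path output path.
#' @export
write_pruned <- function(pruned, path) {
  utils::write.table(as.data.frame(pruned), path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}
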