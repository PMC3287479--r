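#' Simulation specification
#'
#' States the synthetic world used to exercise the pipeline: cohort size,
#' SNP panel with MAF range and optional LD blocks, planted per-allele
#' effects on one or both of two lipid-like traits, the correlation of the
#' trait noise, and a missingness rate. All randomness flows from `seed`.
#'
#' Planted effects are given in units of the trait's base SD ("beta per
#' allele in trait SD units"); the traits are then placed on clinically
#' plausible scales (defaults LDL ~ N(115, 30) and TG ~ N(160, 70) before
#' effects) so that guideline thresholds such as LDL >= 130 / TG >= 180
#' partition the cohort realistically.
#'
#' @param n_individuals cohort size.
#' @param n_snps panel size.
#' @param maf_range MAF drawn uniformly from this interval (must lie in
#'   (0, 0.5\]).
#' @param effects data.frame(snp, target, beta): `snp` is the variant index,
#'   `target` one of "i", "j", "both".
#' @param rho correlation of the two traits' Gaussian noise.
#' @param trait_scales list of two c(mean, sd) vectors, named by trait.
#' @param missing_rate fraction of trait cells set missing at random.
#' @param ld_blocks data.frame(start, end, r2): variant index ranges that
#'   share a founder haplotype with within-block pairwise dosage r2 near
#'   `r2`.
#' @param seed mandatory integer seed.
#' @export
sim_spec <- function(n_individuals, n_snps,
                     maf_range = c(0.1, 0.5),
                     effects = data.frame(snp = integer(),
                                          target = character(),
                                          beta = numeric()),
                     rho = 0.3,
                     trait_scales = list(LDL = c(115, 30), TG = c(160, 70)),
                     missing_rate = 0,
                     ld_blocks = NULL,
                     seed) {
  if (missing(seed)) stop2("sim_spec requires an explicit seed")
  if (maf_range[1L] <= 0 || maf_range[2L] > 0.5) {
    stop2("maf_range must lie in (0, 0.5]")
  }
  if (abs(rho) > 1) stop2("rho must be a correlation")
  if (!is.null(ld_blocks)) {
    if (any(ld_blocks$r2 <= 0 | ld_blocks$r2 > 1)) {
      stop2("infeasible within-block r2 target (need 0 < r2 <= 1)")
    }
    if (any(ld_blocks$end > n_snps | ld_blocks$start < 1)) {
      stop2("ld block outside the SNP panel")
    }
  }
  if (nrow(effects) && any(effects$snp < 1 | effects$snp > n_snps)) {
    stop2("planted effect references a SNP outside the panel")
  }
  structure(list(n_individuals = as.integer(n_individuals),
                 n_snps = as.integer(n_snps), maf_range = maf_range,
                 effects = effects, rho = rho, trait_scales = trait_scales,
                 missing_rate = missing_rate, ld_blocks = ld_blocks,
                 seed = as.integer(seed)),
            class = "sim_spec")
}

# ground-truth label per SNP from the planted effects
truth_labels <- function(spec) {
  lab <- rep("null", spec$n_snps)
  if (nrow(spec$effects)) {
    lab[spec$effects$snp[spec$effects$target == "i"]] <- "single_i"
    lab[spec$effects$snp[spec$effects$target == "j"]] <- "single_j"
    lab[spec$effects$snp[spec$effects$target == "both"]] <- "pleiotropic"
  }
  lab
}

#' Simulate genotypes under Hardy-Weinberg with optional LD blocks
#'
#' Independent SNPs are drawn Binomial(2, maf). Within an LD block all
#' sites share the first site's MAF and each haplotype allele copies a
#' block-founder allele with probability `r2^(1/4)` (else an independent
#' draw), which makes the expected pairwise dosage correlation between two
#' block members `sqrt(r2)`, i.e. pairwise r2 near the target.
#'
#' @param spec a [sim_spec()].
#' @return list(gm = [genotype_matrix()], truth = data.frame with per-SNP
#'   label, nominal and realized allele1 frequency).
#' @export
simulate_genotypes <- function(spec) {
  stopifnot(inherits(spec, "sim_spec"))
  set.seed(spec$seed)
  n <- spec$n_individuals; m <- spec$n_snps
  maf <- stats::runif(m, spec$maf_range[1L], spec$maf_range[2L])
  in_block <- rep(FALSE, m)
  if (!is.null(spec$ld_blocks)) {
    for (b in seq_len(nrow(spec$ld_blocks))) {
      idx <- spec$ld_blocks$start[b]:spec$ld_blocks$end[b]
      in_block[idx] <- TRUE
      maf[idx] <- maf[idx[1L]]
    }
  }
  geno <- matrix(stats::rbinom(n * m, 2L, rep(maf, each = n)), n, m)
  if (!is.null(spec$ld_blocks)) {
    for (b in seq_len(nrow(spec$ld_blocks))) {
      idx <- spec$ld_blocks$start[b]:spec$ld_blocks$end[b]
      p <- maf[idx[1L]]
      phi <- spec$ld_blocks$r2[b]^(1 / 4)
      founder <- matrix(stats::rbinom(2L * n, 1L, p), n, 2L)
      for (s in idx) {
        copy <- matrix(stats::rbinom(2L * n, 1L, phi) == 1L, n, 2L)
        fresh <- matrix(stats::rbinom(2L * n, 1L, p), n, 2L)
        hap <- ifelse(copy, founder, fresh)
        geno[, s] <- hap[, 1L] + hap[, 2L]
      }
    }
  }
  # spread variants along chromosomes, blocks kept physically contiguous
  chr <- ((seq_len(m) - 1L) %/% max(1L, ceiling(m / 22L))) + 1L
  pos <- integer(m)
  for (cc in unique(chr)) {
    k <- sum(chr == cc)
    pos[chr == cc] <- seq(1e5L, by = 20000L, length.out = k)
  }
  map <- data.frame(snp_id = sprintf("snp%05d", seq_len(m)), chr = chr,
                    pos = pos, allele1 = "A", allele2 = "G",
                    stringsAsFactors = FALSE)
  gm <- genotype_matrix(map, geno, sprintf("ind%05d", seq_len(n)))
  truth <- data.frame(snp_id = map$snp_id, label = truth_labels(spec),
                      maf_nominal = maf,
                      freq_realized = colMeans(geno) / 2,
                      stringsAsFactors = FALSE)
  list(gm = gm, truth = truth)
}

#' Simulate correlated traits with planted additive SNP effects
#'
#' trait_k = mean_k + sd_k * (noise_k + sum over planted SNPs targeting k
#' of beta * centered dosage). The two noise vectors are standard Gaussian
#' with correlation rho. Dosages are centered at their realized mean so
#' planted effects shift individuals, not the cohort location. Sex and
#' area covariates are attached (independent of the traits).
#'
#' @param gm a [genotype_matrix()] from [simulate_genotypes()].
#' @param spec the same [sim_spec()].
#' @return a [trait_table()] with the two scaled traits and SEX/AREA
#'   covariates; realized genetic values kept in attribute "genetic".
#' @export
simulate_traits <- function(gm, spec) {
  stopifnot(inherits(gm, "genotype_matrix"), inherits(spec, "sim_spec"))
  bad <- setdiff(spec$effects$snp, seq_len(ncol(gm$geno)))
  if (length(bad)) stop2("effects reference missing SNPs")
  set.seed(spec$seed + 1L)
  n <- nrow(gm$geno)
  z1 <- stats::rnorm(n)
  z2 <- spec$rho * z1 + sqrt(1 - spec$rho^2) * stats::rnorm(n)
  g_i <- g_j <- numeric(n)
  if (nrow(spec$effects)) {
    for (r in seq_len(nrow(spec$effects))) {
      d <- gm$geno[, spec$effects$snp[r]]
      d <- d - mean(d)
      if (spec$effects$target[r] %in% c("i", "both")) {
        g_i <- g_i + spec$effects$beta[r] * d
      }
      if (spec$effects$target[r] %in% c("j", "both")) {
        g_j <- g_j + spec$effects$beta[r] * d
      }
    }
  }
  nms <- names(spec$trait_scales)
  sc_i <- spec$trait_scales[[1L]]; sc_j <- spec$trait_scales[[2L]]
  traits <- data.frame(sc_i[1L] + sc_i[2L] * (z1 + g_i),
                       sc_j[1L] + sc_j[2L] * (z2 + g_j))
  names(traits) <- nms
  if (spec$missing_rate > 0) {
    for (k in seq_along(traits)) {
      hit <- stats::runif(n) < spec$missing_rate
      traits[[k]][hit] <- NA_real_
    }
  }
  covs <- data.frame(SEX = sample(1:2, n, replace = TRUE),
                     AREA = sample(c("Ansung", "Ansan"), n, replace = TRUE),
                     stringsAsFactors = FALSE)
  out <- trait_table(gm$ids, traits, covs)
  attr(out, "genetic") <- data.frame(g_i = g_i, g_j = g_j)
  out
}

#' Simulate transaction databases with planted itemsets
#'
#' The vocabulary is parsed into trait groups by stripping trailing level
#' digits; each transaction independently expresses each trait with
#' probability `background_rate`, choosing one level uniformly (so the
#' one-level-per-trait invariant holds). Each planted itemset is switched
#' on in a transaction with a probability adjusted so its *empirical*
#' support matches the target despite background co-occurrence.
#'
#' @param n number of transactions.
#' @param vocabulary item vocabulary, e.g. c("TG1".."TG5", "LDL1"..).
#' @param planted list of list(items=, support=) entries.
#' @param seed integer seed.
#' @param background_rate per-trait expression probability.
#' @return an `itemized` transaction set.
#' @export
simulate_transactions <- function(n, vocabulary, planted = list(),
                                  seed, background_rate = 0.4) {
  if (missing(seed)) stop2("simulate_transactions requires a seed")
  set.seed(seed)
  trait_of <- sub("[0-9]+$", "", vocabulary)
  groups <- split(vocabulary, trait_of)
  for (pl in planted) {
    if (pl$support <= 0 || pl$support >= 1) {
      stop2("planted support must be in (0, 1)")
    }
    if (!all(pl$items %in% vocabulary)) {
      stop2("planted itemset uses items outside the vocabulary")
    }
  }
  # background probability that one transaction contains a given item
  item_bg <- function(it) background_rate / length(groups[[trait_of[match(it, vocabulary)]]])
  tx <- vector("list", n)
  base <- lapply(seq_len(n), function(i) {
    picked <- vapply(groups, function(g) {
      if (stats::runif(1) < background_rate) sample(g, 1L) else NA_character_
    }, "")
    picked[!is.na(picked)]
  })
  for (pl in planted) {
    p_bg_joint <- prod(vapply(pl$items, item_bg, 0))
    s_adj <- (pl$support - p_bg_joint) / (1 - p_bg_joint)
    if (s_adj < 0) {
      stop2("target support ", pl$support,
            " below background co-occurrence; infeasible")
    }
    on <- stats::runif(n) < s_adj
    for (i in which(on)) {
      keep <- base[[i]][!(sub("[0-9]+$", "", base[[i]]) %in%
                            sub("[0-9]+$", "", pl$items))]
      base[[i]] <- c(keep, pl$items)
    }
  }
  itemized(lapply(base, function(t) sort(unique(t))), items = sort(vocabulary))
}

#' Write simulation truth labels
#'
#' @param truth the truth data.frame from [simulate_genotypes()].
#' @param path TSV path.
#' @export
write_truth <- function(truth, path) {
  utils::write.table(truth, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}
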