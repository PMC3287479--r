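# Independent oracles used to check the mining and clumping implementations.
# These deliberately share no code with the package: brute-force enumeration
# and straight transcription of the definitions.

# Exhaustive frequent-itemset enumeration over the full power set.
brute_apriori <- function(tx, min_sup, max_len = Inf) {
  vocab <- sort(unique(unlist(tx$transactions)))
  n <- length(tx$transactions)
  mat <- matrix(FALSE, n, length(vocab), dimnames = list(NULL, vocab))
  for (i in seq_len(n)) mat[i, match(tx$transactions[[i]], vocab)] <- TRUE
  min_count <- ceiling(min_sup * n - 1e-9)
  rows <- list()
  for (k in seq_len(min(length(vocab), max_len))) {
    sets <- utils::combn(vocab, k, simplify = FALSE)
    for (s in sets) {
      cnt <- sum(rowSums(mat[, s, drop = FALSE]) == k)
      if (cnt >= min_count) {
        rows[[length(rows) + 1L]] <- data.frame(
          items = paste(s, collapse = ";"), size = k, count = cnt,
          support = cnt / n, stringsAsFactors = FALSE)
      }
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(items = character(), size = integer(), count = integer(),
               support = numeric())
  out <- out[order(out$size, out$items), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Rules straight from the definition, using brute-force supports.
brute_rules <- function(tx, min_sup, min_conf, max_len = Inf) {
  freq <- brute_apriori(tx, min_sup, max_len)
  supp <- stats::setNames(freq$support, freq$items)
  rows <- list()
  for (i in which(freq$size >= 2L)) {
    z <- strsplit(freq$items[i], ";", fixed = TRUE)[[1L]]
    for (y in z) {
      body <- paste(setdiff(z, y), collapse = ";")
      conf <- freq$support[i] / supp[[body]]
      if (conf >= min_conf - 1e-12) {
        rows[[length(rows) + 1L]] <- data.frame(
          body = body, head = y, support = freq$support[i],
          confidence = conf, lift = conf / supp[[y]],
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(body = character(), head = character(), support = numeric(),
               confidence = numeric(), lift = numeric())
  out <- out[order(out$head, out$body), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Random transaction database over single-letter items.
random_transactions <- function(n_items, n_tx, p = 0.3) {
  vocab <- LETTERS[seq_len(n_items)]
  tx <- lapply(seq_len(n_tx), function(i) vocab[stats::runif(n_items) < p])
  itemized(tx, items = vocab)
}

# Random rule set with consistent-looking metrics (for filtering/IO tests).
random_rule_set <- function(n, vocab = paste0(rep(LETTERS[1:8], each = 5),
                                              1:5)) {
  rows <- lapply(seq_len(n), function(i) {
    k <- sample(1:4, 1L)
    its <- sample(vocab, k + 1L)
    s_head <- stats::runif(1, 0.05, 0.5)
    conf <- stats::runif(1, 0.1, 1)
    data.frame(body = paste(sort(its[-1L]), collapse = ";"), head = its[1L],
               support = stats::runif(1, 0.001, 0.2), confidence = conf,
               lift = conf / s_head, stringsAsFactors = FALSE)
  })
  structure(do.call(rbind, rows), class = c("rule_set", "data.frame"))
}

# Independent transcription of the greedy clumping rule, working from a
# precomputed full r2 matrix.
brute_clump <- function(df, r2mat, p_index, p_clumped, r2_threshold,
                        window_kb) {
  ord <- order(df$chr, df$pos)
  df <- df[ord, , drop = FALSE]
  r2mat <- r2mat[ord, ord, drop = FALSE]
  n <- nrow(df)
  clump_id <- rep(NA_character_, n); claimed <- rep(FALSE, n)
  is_index <- rep(FALSE, n)
  cand <- order(df$p, df$chr, df$pos)
  cand <- cand[df$p[cand] <= p_index]
  for (i in cand) {
    if (claimed[i]) next
    claimed[i] <- TRUE; is_index[i] <- TRUE; clump_id[i] <- df$snp_id[i]
    for (j in seq_len(n)) {
      if (claimed[j] || df$p[j] > p_clumped) next
      if (df$chr[j] != df$chr[i]) next
      if (abs(df$pos[j] - df$pos[i]) > window_kb * 1000) next
      if (is.na(r2mat[i, j]) || r2mat[i, j] < r2_threshold) next
      claimed[j] <- TRUE; clump_id[j] <- df$snp_id[i]
    }
  }
  data.frame(snp_id = df$snp_id, clump_id = clump_id, is_index = is_index,
             stringsAsFactors = FALSE)
}

# Build a genotype_matrix directly from a dosage matrix.
make_gm <- function(geno, chr = NULL, pos = NULL, ids = NULL) {
  m <- ncol(geno)
  genotype_matrix(
    data.frame(snp_id = sprintf("s%03d", seq_len(m)),
               chr = chr %||% rep(1L, m),
               pos = pos %||% seq(1e5L, by = 1000L, length.out = m),
               allele1 = "A", allele2 = "G", stringsAsFactors = FALSE),
    geno, ids %||% sprintf("i%04d", seq_len(nrow(geno))))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Case/control assignment built directly (bypassing trait thresholds).
make_assignment <- function(ids, status, covariates = NULL) {
  out <- data.frame(id = ids, status = status, stringsAsFactors = FALSE)
  if (!is.null(covariates)) out <- cbind(out, covariates)
  structure(out, class = c("cc_assignment", "data.frame"))
}

# Two-locus haplotype simulation at stated allele freqs and D', plus the
# analytic r2 it should produce.
simulate_dprime_pair <- function(n, p1, p2, dprime) {
  dmax <- if (dprime >= 0) min(p1 * (1 - p2), (1 - p1) * p2) else
    min(p1 * p2, (1 - p1) * (1 - p2))
  D <- dprime * dmax
  h <- c(p1 * p2 + D, p1 * (1 - p2) - D, (1 - p1) * p2 - D,
         (1 - p1) * (1 - p2) + D)
  stopifnot(all(h >= -1e-12))
  draw <- function(k) {
    idx <- sample.int(4L, k, replace = TRUE, prob = pmax(h, 0))
    cbind(a = as.integer(idx %in% c(1L, 2L)), b = as.integer(idx %in% c(1L, 3L)))
  }
  h1 <- draw(n); h2 <- draw(n)
  list(geno = cbind(h1[, "a"] + h2[, "a"], h1[, "b"] + h2[, "b"]),
       r2_analytic = D^2 / (p1 * (1 - p1) * p2 * (1 - p2)))
}
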