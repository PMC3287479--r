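test_that("compute_mor: boundary, identity, log arithmetic, additivity", {
  expect_identical(compute_mor(1e-4, 1e-3), 1)
  expect_equal(compute_mor(0.02, 0.02), 0)
  expect_equal(compute_mor(1e-6, 1e-2), 4)
  expect_error(compute_mor(-1e-4, 1e-3), "non-negative")
  expect_error(compute_mor(1e-4, 1.3), "<= 1")
  # underflowed p-values are floored, not infinite
  expect_true(is.finite(compute_mor(0, 1e-3)))

  # additivity in the log ratio
  set.seed(71)
  p <- sort(runif(3, 1e-8, 1))
  expect_equal(compute_mor(p[1], p[3]),
               compute_mor(p[1], p[2]) + compute_mor(p[2], p[3]),
               tolerance = 1e-12)
})

mk_scan <- function(snp, p, chr = 1L, pos = NULL, OR = 1.5) {
  data.frame(snp_id = snp, chr = chr,
             pos = pos %||% seq(1e5, by = 1e4, length.out = length(snp)),
             p = p, OR = OR, stringsAsFactors = FALSE)
}

test_that("mor_table joins scans, warns on partial overlap", {
  m <- mk_scan(c("s1", "s2", "s3"), c(1e-5, 1e-4, 1e-3))
  si <- mk_scan(c("s1", "s2"), c(1e-3, 1e-3))
  sj <- mk_scan(c("s1", "s2", "s4"), c(1e-2, 1e-4, 0.5))
  expect_warning(tab <- mor_table(m, si, sj), "dropped")
  expect_equal(nrow(tab), 2L)
  expect_equal(tab$mor_i, log10(c(1e-3, 1e-3)) - log10(c(1e-5, 1e-4)))

  # identical scans give all-zero mor
  tab0 <- mor_table(m, m, m)
  expect_true(all(tab0$mor_i == 0) && all(tab0$mor_j == 0))

  expect_error(mor_table(m, mk_scan("zz", 0.5), sj), "no SNPs shared")

  # random scans equal row-wise recomputation
  set.seed(72)
  snps <- sprintf("r%02d", 1:30)
  a <- mk_scan(snps, runif(30)); b <- mk_scan(snps, runif(30))
  cc <- mk_scan(snps, runif(30))
  tab2 <- mor_table(a, b, cc)
  for (k in sample(30, 5)) {
    id <- tab2$snp_id[k]
    expect_equal(tab2$mor_i[k],
                 log10(b$p[b$snp_id == id]) - log10(a$p[a$snp_id == id]))
  }
})

test_that("pairwise_r2: perfect LD, anticorrelation, undefined cases", {
  g <- make_gm(cbind(c(0L, 1L, 2L, 0L), c(0L, 1L, 2L, 0L),
                     c(2L, 1L, 0L, 2L), c(1L, 1L, 1L, 1L)))
  expect_equal(pairwise_r2(g, "s001", "s002"), 1)
  expect_equal(pairwise_r2(g, "s001", "s003"), 1)  # anticorrelation squares to 1
  expect_true(is.na(pairwise_r2(g, "s001", "s004")))  # monomorphic
  expect_error(pairwise_r2(g, "s001", "zz"), "unknown snp")

  gna <- make_gm(cbind(c(0L, NA, 2L, NA), c(NA, 1L, NA, 0L)))
  expect_error(pairwise_r2(gna, "s001", "s002"), "fewer than 2")
})

test_that("dosage r2 recovers the two-locus closed form at n = 2000", {
  # a single r2-hat at n = 2000 has Monte-Carlo SD ~ 0.019, on par with the
  # 0.02 tolerance, so the accuracy check averages 10 replicated
  # measurements of the stated size (SE ~ 0.006)
  set.seed(73)
  cases <- list(c(0.3, 0.4, 0.8), c(0.2, 0.2, 1.0), c(0.45, 0.35, 0.5))
  for (cs in cases) {
    r2s <- replicate(10, {
      sim <- simulate_dprime_pair(2000, cs[1], cs[2], cs[3])
      pairwise_r2(make_gm(sim$geno), "s001", "s002")
    })
    analytic <- simulate_dprime_pair(2, cs[1], cs[2], cs[3])$r2_analytic
    expect_true(abs(mean(r2s) - analytic) <= 0.02)
  }
})

test_that("greedy_clump merges by p, window, and r2 threshold", {
  # strongly correlated dosages 10 kb apart: one clump led by the smaller p
  set.seed(74)
  x <- rbinom(500, 2, 0.3)
  y <- ifelse(runif(500) < 0.95, x, rbinom(500, 2, 0.3))
  gm <- make_gm(cbind(x, y), pos = c(100000L, 110000L))
  res <- mk_scan(c("s001", "s002"), c(1e-6, 1e-5), pos = c(100000L, 110000L))
  cl <- greedy_clump(res, gm, clump_spec())
  expect_true(cl$is_index[cl$snp_id == "s001"])
  expect_equal(cl$clump_id, c("s001", "s001"))
  expect_gte(cl$r2_to_index[2], 0.5)

  # no LD: two singleton clumps
  z <- rbinom(500, 2, 0.3)
  gm2 <- make_gm(cbind(x, z), pos = c(100000L, 110000L))
  cl2 <- greedy_clump(res, gm2, clump_spec())
  expect_true(all(cl2$is_index))

  # outside the window: no claiming even in perfect LD
  far <- c(100000L, 100000L + 251000L)
  gm3 <- make_gm(cbind(x, x), pos = far)
  res3 <- mk_scan(c("s001", "s002"), c(1e-6, 1e-5), pos = far)
  cl3 <- greedy_clump(res3, gm3, clump_spec())
  expect_true(all(cl3$is_index))

  # a SNP above p_clumped is never claimed, above p_index never indexes
  res4 <- mk_scan(c("s001", "s002"), c(1e-6, 5e-4), pos = c(100000L, 110000L))
  cl4 <- greedy_clump(res4, gm, clump_spec())
  expect_true(is.na(cl4$clump_id[cl4$snp_id == "s002"]))
})

test_that("greedy_clump matches the brute-force reference on block LD", {
  set.seed(75)
  for (rep in 1:10) {
    spec <- sim_spec(n_individuals = 300, n_snps = 30,
                     ld_blocks = data.frame(start = c(3, 15),
                                            end = c(8, 20),
                                            r2 = c(0.9, 0.8)),
                     seed = 7500 + rep)
    gm <- simulate_genotypes(spec)$gm
    p <- 10^(-runif(30, 0, 7))
    res <- data.frame(snp_id = gm$map$snp_id, chr = gm$map$chr,
                      pos = gm$map$pos, p = p)
    spec_c <- clump_spec(1e-3, 1e-2, 0.4, 100L)
    got <- greedy_clump(res, gm, spec_c)
    r2m <- matrix(NA_real_, 30, 30)
    for (i in 1:29) for (j in (i + 1):30) {
      r2m[i, j] <- r2m[j, i] <- pairwise_r2(gm, gm$map$snp_id[i],
                                            gm$map$snp_id[j])
    }
    want <- brute_clump(res, r2m, 1e-3, 1e-2, 0.4, 100L)
    expect_equal(got$clump_id, want$clump_id)
    expect_equal(got$is_index, want$is_index)
    # order invariance of the input rows
    got2 <- greedy_clump(res[sample(30), ], gm, spec_c)
    expect_equal(got2$clump_id, got$clump_id)
  }
})

test_that("clump_spec validates its thresholds", {
  expect_error(clump_spec(1e-3, 1e-4), "p_index <= p_clumped")
  expect_error(clump_spec(r2_threshold = 0), "r2_threshold")
})

mk_mor <- function(snp, p_multi, mor_i, mor_j, chr = 1L, pos = NULL) {
  data.frame(snp_id = snp, chr = chr,
             pos = pos %||% seq(1e5, by = 1e4, length.out = length(snp)),
             p_multi = p_multi, OR = 1.4,
             p_single_i = 10^(log10(p_multi) + mor_i),
             p_single_j = 10^(log10(p_multi) + mor_j),
             mor_i = mor_i, mor_j = mor_j, stringsAsFactors = FALSE)
}

mk_clumps <- function(snp, clump_id, is_index) {
  data.frame(snp_id = snp, chr = 1L, pos = seq_along(snp),
             p = 1e-6, clump_id = clump_id, is_index = is_index,
             r2_to_index = ifelse(is_index, 1, 0.8),
             stringsAsFactors = FALSE)
}

test_that("prune_snps applies the three conditions with an audit trail", {
  mor <- mk_mor(c("hit", "failP", "failM"),
                p_multi = c(6.2e-5, 7.3e-4, 1e-5),
                mor_i = c(3.25, 2.21, 2.0),
                mor_j = c(1.58, 0.04, 0.5))
  cl <- mk_clumps(mor$snp_id, clump_id = mor$snp_id,
                  is_index = c(TRUE, TRUE, TRUE))
  out <- prune_snps(mor, cl)
  expect_equal(out$filter_status,
               c("pass", "p_multi", "mor"))
  expect_equal(out$snp_id[out$survives], "hit")

  # clump condition: unclumped SNPs removed under the default reading,
  # clumped non-index SNPs kept; index_only drops them
  mor2 <- mk_mor(c("idx", "member", "lone"), rep(1e-5, 3), 2, 2)
  cl2 <- mk_clumps(c("idx", "member", "lone"),
                   clump_id = c("idx", "idx", NA),
                   is_index = c(TRUE, FALSE, FALSE))
  out2 <- prune_snps(mor2, cl2)
  expect_equal(out2$filter_status, c("pass", "pass", "clump"))
  out3 <- prune_snps(mor2, cl2, clump_rule = "index_only")
  expect_equal(out3$snp_id[out3$survives], "idx")
})

test_that("prune_snps is monotone in its thresholds", {
  set.seed(76)
  n <- 50
  mor <- mk_mor(sprintf("m%02d", 1:n), 10^(-runif(n, 2, 6)),
                runif(n, -1, 4), runif(n, -1, 4))
  cl <- mk_clumps(mor$snp_id, clump_id = ifelse(runif(n) < 0.7,
                                                mor$snp_id, NA),
                  is_index = runif(n) < 0.5)
  base <- prune_snps(mor, cl, p_multi_max = 5e-4, mor_min = 1)
  relaxed <- prune_snps(mor, cl, p_multi_max = 5e-3, mor_min = 0.5)
  expect_true(all(base$snp_id[base$survives] %in%
                    relaxed$snp_id[relaxed$survives]))
})
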