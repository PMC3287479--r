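mk_rules <- function(df) structure(df, class = c("rule_set", "data.frame"))

lipid_rules <- mk_rules(data.frame(
  body = c("TCHL5;LDL5", "TG5;LDL1"), head = c("TG5", "NONHDL5"),
  support = .02, confidence = .8, lift = 3))

test_that("derive_definition builds the clinical bivariate design", {
  ov <- list(case = c(LDL = 130, TG = 180), control = c(LDL = 100, TG = 100))
  defn <- derive_definition(lipid_rules, c("LDL", "TG"), overrides = ov)
  expect_equal(defn$name, "highLDLhighTG")
  expect_equal(vapply(defn$case, `[[`, "", "op"), c(">=", ">="))
  expect_equal(vapply(defn$case, `[[`, 0, "value"), c(130, 180))
  expect_equal(vapply(defn$control, `[[`, "", "op"), c("<=", "<="))
  expect_equal(vapply(defn$control, `[[`, 0, "value"), c(100, 100))

  # no overrides: quintile-level memberships (top level vs level 1)
  defn2 <- derive_definition(lipid_rules, c("LDL", "TG"))
  expect_equal(vapply(defn2$case, `[[`, "", "op"), c("in", "in"))
  expect_equal(vapply(defn2$case, function(p) p$value, 0L), c(5L, 5L))
  expect_equal(vapply(defn2$control, function(p) p$value, 0L), c(1L, 1L))

  expect_error(derive_definition(lipid_rules, c("HDL", "TG")), "absent")

  # single-trait projections give the univariate designs
  hl <- project_definition(defn, "LDL")
  expect_equal(length(hl$case), 1L)
  expect_equal(hl$case[[1]]$value, 130)
  expect_equal(hl$control[[1]]$value, 100)
})

test_that("assign_phenotype partitions individuals by predicate logic", {
  tt <- trait_table(c("a", "b", "c"),
                    data.frame(LDL = c(150, 90, 110), TG = c(200, 80, 80)))
  defn <- phenotype_definition(
    "highLDLhighTG",
    list(phenotype_predicate("LDL", ">=", 130),
         phenotype_predicate("TG", ">=", 180)),
    list(phenotype_predicate("LDL", "<=", 100),
         phenotype_predicate("TG", "<=", 100)))
  asg <- assign_phenotype(tt, defn)
  expect_equal(asg$status, c("case", "control", "excluded"))
  expect_equal(sum(attr(asg, "counts")), 3L)
  # idempotent partition: rerun gives identical assignment
  expect_identical(assign_phenotype(tt, defn)$status, asg$status)

  overlap <- phenotype_definition(
    "bad", list(phenotype_predicate("LDL", ">=", 100)),
    list(phenotype_predicate("LDL", "<=", 120)))
  expect_error(assign_phenotype(tt, overlap), "overlap.*'c'")
})

test_that("assignment counts match a brute-force scan on simulated traits", {
  spec <- sim_spec(n_individuals = 2000, n_snps = 5, seed = 301)
  sg <- simulate_genotypes(spec)
  tt <- simulate_traits(sg$gm, spec)
  defn <- phenotype_definition(
    "highLDLhighTG",
    list(phenotype_predicate("LDL", ">=", 130),
         phenotype_predicate("TG", ">=", 180)),
    list(phenotype_predicate("LDL", "<=", 100),
         phenotype_predicate("TG", "<=", 100)))
  asg <- assign_phenotype(tt, defn)
  want_case <- sum(tt$traits$LDL >= 130 & tt$traits$TG >= 180)
  want_ctrl <- sum(tt$traits$LDL <= 100 & tt$traits$TG <= 100)
  expect_equal(unname(attr(asg, "counts")["case"]), want_case)
  expect_equal(unname(attr(asg, "counts")["control"]), want_ctrl)

  # containment: multivariate cases within each single-trait design's cases
  asg_i <- assign_phenotype(tt, project_definition(defn, "LDL"))
  asg_j <- assign_phenotype(tt, project_definition(defn, "TG"))
  multi_cases <- asg$id[asg$status == "case"]
  expect_true(all(multi_cases %in% asg_i$id[asg_i$status == "case"]))
  expect_true(all(multi_cases %in% asg_j$id[asg_j$status == "case"]))
  multi_ctrl <- asg$id[asg$status == "control"]
  expect_true(all(multi_ctrl %in% asg_i$id[asg_i$status == "control"]))
  expect_true(all(multi_ctrl %in% asg_j$id[asg_j$status == "control"]))
})

test_that("level-set predicates assign through a discretization scheme", {
  tt <- trait_table(letters[1:10], data.frame(LDL = 1:10, TG = 10:1))
  sch <- fit_quantile_scheme(tt, 5L)
  defn <- phenotype_definition(
    "hiLDL", list(phenotype_predicate("LDL", "in", 5L)),
    list(phenotype_predicate("LDL", "in", 1L)))
  asg <- assign_phenotype(tt, defn, scheme = sch)
  expect_equal(sum(asg$status == "case"), 2L)
  expect_equal(sum(asg$status == "control"), 2L)
  expect_error(assign_phenotype(tt, defn), "needs a disc_scheme")
})

test_that("summarize_assignment reports stratified mean/SD with degenerate flags", {
  tt <- trait_table(c("a", "b", "c", "d"),
                    data.frame(LDL = c(80, 82, 150, 90)),
                    covariates = data.frame(AREA = c("X", "X", "X", "Y")))
  asg <- make_assignment(tt$ids, c("control", "control", "case", "control"),
                         data.frame(AREA = c("X", "X", "X", "Y")))
  sm <- summarize_assignment(asg, tt, "AREA")
  cx <- sm[sm$status == "control" & sm$stratum == "X", ]
  expect_equal(cx$n, 2L)
  expect_equal(cx$mean, 81)
  expect_equal(cx$sd, sqrt(2))
  cy <- sm[sm$status == "control" & sm$stratum == "Y", ]
  expect_equal(cy$sd, 0)
  expect_true(cy$degenerate)
  ey <- sm[sm$status == "case" & sm$stratum == "Y", ]
  expect_equal(ey$n, 0L)
  expect_true(is.na(ey$mean))
  expect_error(summarize_assignment(asg, tt, "SEX"), "not in assignment")

  # recompute oracle on a simulated cohort
  spec <- sim_spec(n_individuals = 500, n_snps = 2, seed = 88)
  tt2 <- simulate_traits(simulate_genotypes(spec)$gm, spec)
  asg2 <- make_assignment(tt2$ids,
                          sample(c("case", "control"), 500, replace = TRUE),
                          tt2$covariates)
  sm2 <- summarize_assignment(asg2, tt2, "SEX", traits = "LDL")
  row <- sm2[sm2$status == "case" & sm2$stratum == "1", ]
  sel <- asg2$status == "case" & asg2$SEX == 1
  expect_equal(row$mean, mean(tt2$traits$LDL[sel]))
  expect_equal(row$sd, sd(tt2$traits$LDL[sel]))
})

test_that("sex_by_status_test matches the textbook corrected formula", {
  # balanced table: statistic exactly 0, and scale invariant at independence
  expect_equal(sex_by_status_test(matrix(10, 2, 2))$statistic, 0)
  expect_equal(sex_by_status_test(matrix(20, 2, 2))$statistic, 0)

  expect_error(sex_by_status_test(matrix(c(0, 0, 5, 5), 2, 2)), "marginal")

  set.seed(61)
  for (i in 1:20) {
    m <- matrix(rpois(4, 50) + 1, 2, 2)
    got <- sex_by_status_test(m)
    ref <- suppressWarnings(chisq.test(m, correct = TRUE))
    ref0 <- suppressWarnings(chisq.test(m, correct = FALSE))
    expect_equal(got$statistic, unname(ref$statistic), tolerance = 1e-12)
    expect_equal(got$uncorrected, unname(ref0$statistic), tolerance = 1e-12)
    expect_equal(got$p.value, ref$p.value, tolerance = 1e-12)
  }

  # assignment interface with a sex covariate
  asg <- make_assignment(1:40, rep(c("case", "control"), each = 20),
                         data.frame(SEX = rep(c(1, 2, 1, 2), c(15, 5, 5, 15))))
  got <- sex_by_status_test(asg)
  expect_equal(got$observed["case", "1"], 15)
  expect_equal(got$df, 1L)
})

test_that("phenotype files use PLINK case/control coding", {
  asg <- make_assignment(c("a", "b", "c"), c("case", "control", "excluded"))
  f <- tempfile()
  write_phenotype_file(asg, f)
  got <- read.table(f)
  expect_equal(got$V3, c(2L, 1L, -9L))
})
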