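# The end-to-end recovery world: 5,000 SNPs in 8,000 individuals; 20
# pleiotropic SNPs (beta = 0.25 SD on both traits), 10 + 10 single-trait
# SNPs, 4,960 nulls. The bivariate phenotype uses the clinical lipid
# thresholds (case LDL >= 130 & TG >= 180; control LDL <= 100 & TG <= 100)
# and pruning runs at the published thresholds (p_multi <= 5e-4, both
# mOR >= 1, clump support at p_index 1e-5 / p_clumped 1e-4).
recovery_effects <- function() {
  data.frame(
    snp = c(seq(120L, by = 240L, length.out = 20L),
            seq(200L, by = 480L, length.out = 10L),
            seq(440L, by = 480L, length.out = 10L)),
    target = rep(c("both", "i", "j"), c(20L, 10L, 10L)),
    beta = 0.25)
}

recovery_definition <- function() {
  phenotype_definition(
    "highLDLhighTG",
    list(phenotype_predicate("LDL", ">=", 130),
         phenotype_predicate("TG", ">=", 180)),
    list(phenotype_predicate("LDL", "<=", 100),
         phenotype_predicate("TG", "<=", 100)))
}

recovery_run <- function(seed) {
  spec <- sim_spec(n_individuals = 8000L, n_snps = 5000L,
                   effects = recovery_effects(), seed = seed)
  sg <- simulate_genotypes(spec)
  tt <- simulate_traits(sg$gm, spec)
  defn <- recovery_definition()
  asg <- assign_phenotype(tt, defn)
  asg_i <- assign_phenotype(tt, project_definition(defn, "LDL"))
  asg_j <- assign_phenotype(tt, project_definition(defn, "TG"))
  multi <- genome_scan(sg$gm, asg)
  si <- genome_scan(sg$gm, asg_i)
  sj <- genome_scan(sg$gm, asg_j)
  mor <- mor_table(multi, si, sj)
  cl <- greedy_clump(multi, sg$gm, clump_spec())
  pruned <- prune_snps(mor, cl, p_multi_max = 5e-4, mor_min = 1)
  surv <- pruned$snp_id[pruned$survives]
  lab <- sg$truth$label[match(surv, sg$truth$snp_id)]
  ple_ids <- sg$truth$snp_id[sg$truth$label == "pleiotropic"]
  list(sensitivity = mean(ple_ids %in% surv),
       n_survivors = length(surv),
       n_true = sum(lab == "pleiotropic"),
       n_single = sum(lab %in% c("single_i", "single_j")),
       n_null = sum(lab == "null"))
}
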