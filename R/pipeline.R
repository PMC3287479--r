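#' Pipeline configuration
#'
#' Read a YAML config describing file paths, mining parameters, rule
#' constraints, the phenotype definition and pruning thresholds, merged
#' over defaults and validated. See the package vignette for the full key
#' reference.
#'
#' @param path YAML file path.
#' @param overrides optional named list merged on top (exposed mostly for
#'   tests and the CLI).
#' @return a validated `pipeline_config` list.
#' @export
read_config <- function(path = NULL, overrides = list()) {
  defaults <- list(
    traits = NULL, ped = NULL, map = NULL, out_dir = ".",
    missing_marker = "NA",
    drop_traits = character(),
    n_levels = 5L,
    mining = list(min_sup = 0.01, min_conf = 0.10, max_len = 5L),
    interestingness = list(min_conf = 0.5, min_lift = 1),
    constraints = list(),
    phenotype = NULL,   # list(traits=c(i,j), case=..., control=...)
    thresholds = list(p_multi_max = 5e-4, mor_min = 1,
                      p_index = 1e-5, p_clumped = 1e-4,
                      r2_threshold = 0.5, window_kb = 250L,
                      clump_rule = "index_or_clumped"),
    seed = 1L
  )
  user <- if (!is.null(path)) yaml::read_yaml(path) else list()
  merge2 <- function(base, new) {
    for (k in names(new)) {
      base[[k]] <- if (is.list(base[[k]]) && is.list(new[[k]])) {
        merge2(base[[k]], new[[k]])
      } else new[[k]]
    }
    base
  }
  cfg <- merge2(merge2(defaults, user), overrides)
  th <- cfg$thresholds
  if (th$p_multi_max <= 0 || th$p_multi_max > 1) {
    stop2("p_multi_max out of range")
  }
  clump_spec(th$p_index, th$p_clumped, th$r2_threshold, th$window_kb)
  structure(cfg, class = "pipeline_config")
}

stage <- function(label, expr) {
  tryCatch(expr, error = function(e) {
    stop2("[", label, "] ", conditionMessage(e))
  })
}

#' Run the mining stage
#'
#' Chains trait loading, missing-value filtering, trait dropping, quintile
#' discretization, APRIORI mining, rule generation, the interestingness
#' pass (lift/confidence), any rule-form constraints, and the trait graph.
#' Counts at each stage of the funnel are logged. Outputs (rules CSV,
#' GraphML + edge list, scheme YAML) are stamped with the config hash and
#' seed, so identical configs give byte-identical files.
#'
#' @param config a `pipeline_config` from [read_config()].
#' @param table optional in-memory [trait_table()] (else `config$traits`
#'   is read).
#' @return list with the rule set, graph, scheme and output paths.
#' @export
run_mine <- function(config, table = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  tt <- stage("load", {
    if (!is.null(table)) table else {
      if (is.null(config$traits)) stop2("no trait table given")
      read_trait_table(config$traits, config$missing_marker)
    }
  })
  tt <- stage("filter_missing", filter_complete(tt))
  if (length(config$drop_traits)) {
    tt <- stage("drop_traits", drop_traits(tt, config$drop_traits))
  }
  scheme <- stage("discretize", fit_quantile_scheme(tt, config$n_levels))
  tx <- stage("itemize", itemize(tt, scheme))
  freq <- stage("apriori",
                apriori(tx, config$mining$min_sup, config$mining$max_len))
  rules <- stage("rules", generate_rules(freq, config$mining$min_conf))
  message(sprintf("mined %d rules at min_sup=%g min_conf=%g",
                  nrow(rules), config$mining$min_sup, config$mining$min_conf))
  interesting <- filter_rules(rules, rule_constraint(
    min_conf = config$interestingness$min_conf,
    min_lift = config$interestingness$min_lift))
  message(sprintf("%d rules retained by lift >= %g and confidence >= %g",
                  nrow(interesting), config$interestingness$min_lift,
                  config$interestingness$min_conf))
  for (cs in config$constraints) {
    interesting <- filter_rules(interesting, do.call(rule_constraint, cs))
    message(sprintf("%d rules after constraint on %s", nrow(interesting),
                    cs$item %||% "<metrics>"))
  }
  hdr <- provenance_header(unclass(config), config$seed)
  paths <- list(rules = file.path(config$out_dir, "rules.csv"),
                graphml = file.path(config$out_dir, "trait_graph.graphml"),
                edgelist = file.path(config$out_dir, "trait_graph.tsv"),
                scheme = file.path(config$out_dir, "scheme.yaml"))
  writeLines(hdr, paths$rules)
  tmp <- tempfile(); write_rules(interesting, tmp)
  file.append(paths$rules, tmp); unlink(tmp)
  graph <- NULL
  if (nrow(interesting)) {
    graph <- build_trait_graph(interesting)
    export_graph(graph, paths$graphml, "graphml")
    writeLines(hdr, paths$edgelist)
    tmp <- tempfile(); export_graph(graph, tmp, "edgelist")
    file.append(paths$edgelist, tmp); unlink(tmp)
  }
  write_scheme(scheme, paths$scheme)
  list(rules = interesting, graph = graph, scheme = scheme,
       table = tt, paths = paths)
}

config_definition <- function(config) {
  ph <- config$phenotype
  if (is.null(ph)) stop2("config lacks a phenotype block")
  mk <- function(side) {
    lapply(ph[[side]], function(p)
      phenotype_predicate(p$trait, p$op, unlist(p$value)))
  }
  phenotype_definition(ph$name %||% "multivariate", mk("case"), mk("control"))
}

#' Run the GWAS + pruning stage
#'
#' Assigns case/control status for the multivariate phenotype and its two
#' single-trait projections, runs the three allelic genome scans, computes
#' the mOR table, clumps the multivariate scan, prunes, and writes the
#' audit trail plus Manhattan export.
#'
#' @param config a `pipeline_config` with a `phenotype` block naming the
#'   two traits and their case/control predicates.
#' @param table optional in-memory [trait_table()].
#' @param gm optional in-memory [genotype_matrix()].
#' @return list with the three scans, assignments, mor table, clumps,
#'   pruned set and output paths.
#' @export
run_gwas <- function(config, table = NULL, gm = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  tt <- stage("load_traits", {
    if (!is.null(table)) table else
      read_trait_table(config$traits, config$missing_marker)
  })
  gm <- stage("load_genotypes", {
    if (!is.null(gm)) gm else {
      if (is.null(config$ped)) stop2("no genotypes given")
      read_ped_map(config$ped, config$map)
    }
  })
  defn <- stage("phenotype", config_definition(config))
  traits2 <- vapply(defn$case, `[[`, "", "trait")
  asg <- stage("assign", assign_phenotype(tt, defn))
  message(sprintf("phenotype %s: %d cases, %d controls, %d excluded",
                  defn$name, attr(asg, "counts")[["case"]],
                  attr(asg, "counts")[["control"]],
                  attr(asg, "counts")[["excluded"]]))
  asg_i <- stage("assign_i",
                 assign_phenotype(tt, project_definition(defn, traits2[1L])))
  asg_j <- stage("assign_j",
                 assign_phenotype(tt, project_definition(defn, traits2[2L])))
  scan_multi <- stage("scan_multi", genome_scan(gm, asg))
  scan_i <- stage("scan_i", genome_scan(gm, asg_i))
  scan_j <- stage("scan_j", genome_scan(gm, asg_j))
  mor <- stage("mor", mor_table(scan_multi, scan_i, scan_j))
  th <- config$thresholds
  cl <- stage("clump", greedy_clump(scan_multi, gm,
                clump_spec(th$p_index, th$p_clumped, th$r2_threshold,
                           th$window_kb)))
  pruned <- stage("prune", prune_snps(mor, cl, th$p_multi_max, th$mor_min,
                                      th$clump_rule))
  tab <- table(pruned$filter_status)
  message(paste(sprintf("%s: %d", names(tab), tab), collapse = ", "))
  if (!any(pruned$survives)) {
    warning("no SNPs survive the pruning thresholds")
  }
  hdr <- provenance_header(unclass(config), config$seed)
  paths <- list(pruned = file.path(config$out_dir, "pruned.tsv"),
                manhattan = file.path(config$out_dir, "manhattan.tsv"))
  writeLines(hdr, paths$pruned)
  tmp <- tempfile(); write_pruned(pruned, tmp)
  file.append(paths$pruned, tmp); unlink(tmp)
  writeLines(hdr, paths$manhattan)
  tmp <- tempfile(); export_manhattan(scan_multi, tmp)
  file.append(paths$manhattan, tmp); unlink(tmp)
  list(assignment = asg, assignment_i = asg_i, assignment_j = asg_j,
       scans = list(multi = scan_multi, single_i = scan_i,
                    single_j = scan_j),
       mor = mor, clumps = cl, pruned = pruned, paths = paths)
}

#' Run the in-silico replication stage
#'
#' Re-tests the pruning survivors within each level of a covariate stratum
#' (recruitment area, sex) for the multivariate phenotype and both single
#' traits, writing a wide per-SNP table of stratum p-values.
#'
#' @param config a `pipeline_config`.
#' @param gwas output of [run_gwas()].
#' @param gm the [genotype_matrix()] used for the scans.
#' @param strata covariate column name (e.g. "AREA" or "SEX").
#' @return list(table = wide data.frame, path = output TSV).
#' @export
run_replicate <- function(config, gwas, gm, strata) {
  stopifnot(inherits(config, "pipeline_config"))
  survivors <- gwas$pruned$snp_id[gwas$pruned$survives]
  hdr <- provenance_header(unclass(config), config$seed)
  path <- file.path(config$out_dir, sprintf("replication_%s.tsv", strata))
  if (!length(survivors)) {
    writeLines(c(hdr, "snp_id"), path)
    return(list(table = data.frame(snp_id = character()), path = path))
  }
  designs <- list(multi = gwas$assignment, single_i = gwas$assignment_i,
                  single_j = gwas$assignment_j)
  wide <- data.frame(snp_id = survivors, stringsAsFactors = FALSE)
  for (dn in names(designs)) {
    res <- stage(paste0("replicate_", dn),
                 replicate_stratified(gm, designs[[dn]], strata,
                                      snps = survivors))
    for (lev in names(res)) {
      col <- res[[lev]]$p[match(survivors, res[[lev]]$snp_id)]
      wide[[paste(dn, lev, sep = "_")]] <- col
    }
  }
  writeLines(hdr, path)
  tmp <- tempfile()
  utils::write.table(wide, tmp, sep = "\t", row.names = FALSE, quote = FALSE)
  file.append(path, tmp); unlink(tmp)
  list(table = wide, path = path)
}
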