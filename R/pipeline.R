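#' Write a synthetic cohort to disk
#'
#' Emits the genotype panel as a PLINK binary trio and a phased VCF, the
#' cohort and feeder-visit tables as TSV, and a JSON manifest recording
#' the full generator configuration, under one output directory.
#'
#' @param geno phased [geno_matrix].
#' @param cohort,visits data.frames from the generator.
#' @param config the [sim_config] used.
#' @param dir output directory (created if needed).
#' @return named list of written paths, invisibly.
#' @export
write_sim_cohort <- function(geno, cohort, visits, config, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list(
    plink = file.path(dir, "genotypes"),
    vcf = file.path(dir, "genotypes.vcf"),
    cohort = file.path(dir, "cohort.tsv"),
    visits = file.path(dir, "visits.tsv"),
    manifest = file.path(dir, "manifest.json")
  )
  write_plink(geno, paths$plink)
  write_phased_vcf(geno, paths$vcf)
  data.table::fwrite(cohort, paths$cohort, sep = "\t")
  data.table::fwrite(visits, paths$visits, sep = "\t")
  jsonlite::write_json(unclass(config), paths$manifest, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(paths)
}

#' Run the full two-layer analysis pipeline
#'
#' Orchestrates the complete desk-scale study on a seeded synthetic
#' cohort: genotype and phenotype simulation, feeder-trait derivation,
#' marker QC, genomic relationship matrices, the social genetic effects
#' REML fit, deregression of direct and social EBVs, single-locus
#' mixed-model GWAS on each deregressed response, Gabriel haplotype-block
#' detection, the haplotype-allele GWAS, tiered hit tables,
#' direct-vs-social overlap sets, and plot-ready exports. Every stage's
#' output lands in `out_dir`; a manifest records the configuration so a
#' rerun reproduces all outputs bit for bit.
#'
#' @param config a [sim_config], or a path to a manifest.json written by
#'   a previous run.
#' @param out_dir output directory.
#' @param hap_freq_min haplotype-allele frequency filter.
#' @return invisible list with the main in-memory objects (`fit`,
#'   `debv`, `assoc_dge`, `assoc_sge`, `hap_dge`, `hap_sge`, `blocks`,
#'   `overlap`, `qc_report`, `paths`).
#' @export
run_pipeline <- function(config, out_dir, hap_freq_min = 0.01) {
  if (is.character(config)) {
    cfg <- jsonlite::read_json(config, simplifyVector = TRUE)
    cfg$seed <- as.integer(cfg$seed)
    config <- do.call(sim_config, cfg)
  }
  stopifnot(inherits(config, "sim_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(out_dir, "pipeline.log")
  logline <- function(fmt, ...) {
    cat(sprintf(paste0(fmt, "\n"), ...), file = log_path, append = TRUE)
  }
  cat(sprintf("sgegwas pipeline, package %s, seed %d\n",
              as.character(utils::packageVersion("sgegwas")), config$seed),
      file = log_path)

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stopf("pipeline stage '%s' failed: %s", name, conditionMessage(e))
    })
  }

  # --- simulate -----------------------------------------------------------
  geno <- stage("simulate-genotypes", sim_genotypes(config))
  sim <- stage("simulate-phenotypes",
               sim_effects_and_phenotypes(geno, config))
  visits <- stage("simulate-feeder", sim_feeder_records(sim$cohort, config))
  paths <- write_sim_cohort(geno, sim$cohort, visits, config, out_dir)
  logline("simulated %d individuals x %d markers", nrow(geno$dosage),
          ncol(geno$dosage))

  # --- derived traits -----------------------------------------------------
  derived <- stage("derive-traits", derive_traits(sim$cohort, visits))
  data.table::fwrite(derived, file.path(out_dir, "derived_traits.tsv"),
                     sep = "\t")

  # --- QC and relationship matrices --------------------------------------
  qc <- stage("marker-qc", qc_markers(geno, maf_min = config$maf_min / 2))
  write_qc_report(qc$report, file.path(out_dir, "qc_report.tsv"))
  logline("QC retained %d of %d markers", qc$report$n_retained,
          qc$report$n_input)
  G <- stage("grm", grm_centered(qc$geno))
  K <- grm_centered(qc$geno, method = "scaled")

  # --- social model and deregression -------------------------------------
  design <- stage("design", build_design(sim$cohort, sim$traits, "y"))
  fit <- stage("reml", reml_fit_social(design, K))
  capture <- utils::capture.output(print(fit))
  writeLines(capture, file.path(out_dir, "reml_fit.txt"))
  debv <- stage("deregress", deregressed_ebv_table(fit, trait = "y"))
  data.table::fwrite(debv, file.path(out_dir, "deregressed_ebv.tsv"),
                     sep = "\t")

  # --- single-locus GWAS per effect type ----------------------------------
  thr <- bonferroni_thresholds(ncol(qc$geno$dosage))
  scan_one <- function(effect) {
    tab <- debv[debv$effect == effect & debv$usable, ]
    idx <- match(tab$id, qc$geno$samples)
    null <- fit_mlm_null(tab$debv, G[idx, idx, drop = FALSE])
    assoc <- wald_scan(qc$geno$dosage[idx, , drop = FALSE], null,
                       map = qc$geno$map)
    list(null = null, assoc = assoc, idx = idx,
         lambda = genomic_lambda(assoc$p))
  }
  dge <- stage("gwas-dge", scan_one("DGE"))
  sge <- stage("gwas-sge", scan_one("SGE"))
  logline("genomic lambda: DGE %.3f, SGE %.3f", dge$lambda, sge$lambda)
  for (nm in c("dge", "sge")) {
    res <- get(nm)
    data.table::fwrite(res$assoc,
                       file.path(out_dir, sprintf("assoc_snp_%s.tsv", nm)),
                       sep = "\t")
    data.table::fwrite(manhattan_table(res$assoc),
                       file.path(out_dir, sprintf("manhattan_snp_%s.tsv", nm)),
                       sep = "\t")
  }

  # --- haplotype layer ----------------------------------------------------
  blocks <- stage("blocks", gabriel_blocks(qc$geno))
  write_blocks(blocks, file.path(out_dir, "blocks.tsv"))
  logline("%d haplotype blocks", length(blocks))
  hap_scan <- function(scan) {
    g <- geno_subset(qc$geno, samples = scan$idx)
    hap_gwas(blocks, g, scan$null, allele_freq_min = hap_freq_min)
  }
  hap_dge <- stage("hap-gwas-dge", hap_scan(dge))
  hap_sge <- stage("hap-gwas-sge", hap_scan(sge))
  data.table::fwrite(hap_dge$assoc, file.path(out_dir, "assoc_hap_dge.tsv"),
                     sep = "\t")
  data.table::fwrite(hap_sge$assoc, file.path(out_dir, "assoc_hap_sge.tsv"),
                     sep = "\t")

  # --- reporting ----------------------------------------------------------
  hits_dge <- significant_hits(dge$assoc, thr)
  hits_sge <- significant_hits(sge$assoc, thr)
  data.table::fwrite(hits_dge, file.path(out_dir, "hits_snp_dge.tsv"),
                     sep = "\t")
  data.table::fwrite(hits_sge, file.path(out_dir, "hits_snp_sge.tsv"),
                     sep = "\t")
  ov <- overlap_hits(hits_dge, hits_sge)
  data.table::fwrite(ov$common, file.path(out_dir, "hits_common.tsv"),
                     sep = "\t")
  regions <- if (nrow(hits_dge)) {
    do.call(rbind, lapply(seq_len(nrow(hits_dge)), function(r) {
      q <- qtl_region(hits_dge$chr[r], hits_dge$pos[r], hits_dge$id[r])
      data.frame(chr = q$chr, lower = q$lower, upper = q$upper,
                 anchor = q$anchor_id, display = q$display)
    }))
  } else {
    data.frame(chr = character(0), lower = numeric(0), upper = numeric(0),
               anchor = character(0), display = character(0))
  }
  data.table::fwrite(regions, file.path(out_dir, "qtl_regions_dge.tsv"),
                     sep = "\t")
  logline("hits: %d DGE, %d SGE, %d common", nrow(hits_dge),
          nrow(hits_sge), nrow(ov$common))

  invisible(list(fit = fit, debv = debv, assoc_dge = dge$assoc,
                 assoc_sge = sge$assoc, hap_dge = hap_dge,
                 hap_sge = hap_sge, blocks = blocks, overlap = ov,
                 qc_report = qc$report, thresholds = thr,
                 lambda = c(DGE = dge$lambda, SGE = sge$lambda),
                 paths = paths, out_dir = out_dir))
}
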