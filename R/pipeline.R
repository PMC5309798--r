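#' Run the full CNV dosage-sensitivity pipeline
#'
#' Orchestrates the end-to-end analysis on either simulated data or
#' tables read from disk:
#' \enumerate{
#'   \item benign CNVs kept as full calls, split by type; pathogenic
#'     CNVs merged into typed CNVRs and refined into coverage peak
#'     regions;
#'   \item dosage-class assignment of every gene (Class B / P / X /
#'     BL_PG / BG_PL) and the solitary Class P gene calls;
#'   \item conservation scoring of ancestral genes across the species
#'     panel, summarized by class (quartiles, Fligner-Killeen scale
#'     test, conserved-by-class chi-squared);
#'   \item the CNV location-randomization test for developmental-gene
#'     containment by pathogenic CNVs (skipped when `n_reps = 0`);
#'   \item the enrichment battery across classes and the
#'     hypergeometric term enrichment of solitary genes against the
#'     pathogenic-CNVR gene background.
#' }
#'
#' @param sim_config A [simulation_config()] to generate inputs, or
#'   `NULL` when `cnv_path`/`gene_path`/`orthology_path` are given.
#' @param cnv_path,gene_path,orthology_path Input table paths (used
#'   when `sim_config` is `NULL`); the CNV table is read with the
#'   `dbvar_tsv` dialect.
#' @param build A [genome_build()]; defaults to [grch37_autosomes()]
#'   for file input and to the simulated build otherwise.
#' @param n_reps Randomization replicates (0 skips the stage).
#' @param seed Master seed; stage seeds are derived from it.
#' @param out_dir Optional output directory; when given, BED/TSV
#'   reports and a `manifest.txt` echoing every tunable are written.
#' @return List with elements `cnvs`, `genes`, `regions` (per-scope
#'   CNVR tables), `peaks`, `assignments`, `solitary`,
#'   `solitary_summary`, `conservation`, `conservation_by_class`,
#'   `randomization`, `battery`, `term_enrichment`, `fractions`
#'   (genome fractions and overlap accounting) and `manifest`.
#' @export
run_pipeline <- function(sim_config = NULL, cnv_path = NULL,
                         gene_path = NULL, orthology_path = NULL,
                         build = NULL, n_reps = 1000, seed = 1,
                         out_dir = NULL) {
  if (is.null(sim_config) &&
      (is.null(cnv_path) || is.null(gene_path) || is.null(orthology_path)))
    stop("provide either sim_config or all three input paths")
  if (!is.null(sim_config)) {
    sim <- simulate_genome(sim_config, seed = seed)
    build <- sim$build
    genes <- sim$genes
    profiles <- simulate_orthology(genes, sim_config, seed = seed + 1)
    cnvs <- simulate_cnvs(genes, build, sim_config, seed = seed + 2)
  } else {
    if (is.null(build)) build <- grch37_autosomes()
    cnvs <- read_cnv_table(cnv_path, "dbvar_tsv", build)
    genes <- read_gene_table(gene_path)
    profiles <- read_orthology_table(orthology_path)
  }

  benign <- cnvs[cnvs$interpretation == "benign", , drop = FALSE]
  path <- cnvs[cnvs$interpretation == "pathogenic", , drop = FALSE]

  regions <- list(
    benign_grouped = merge_cnvrs(benign, "grouped"),
    path_grouped = merge_cnvrs(path, "grouped"),
    path_gain = merge_cnvrs(path, "gain_only"),
    path_loss = merge_cnvrs(path, "loss_only"))
  peaks <- list(
    path_grouped = find_peaks(regions$path_grouped, path),
    path_gain = find_peaks(regions$path_gain, path),
    path_loss = find_peaks(regions$path_loss, path))

  assignments <- assign_classes(
    genes,
    benign[benign$type == "gain", , drop = FALSE],
    benign[benign$type == "loss", , drop = FALSE],
    peaks$path_gain, peaks$path_loss)

  typed_peaks <- rbind(peaks$path_gain, peaks$path_loss)
  solitary <- find_solitary(typed_peaks, assignments, genes)
  sol_sum <- solitary_summary(solitary)

  ancestral <- genes$gene_id[genes$ancestral %in% TRUE]
  cons <- summarize_profiles(profiles[profiles$unit_id %in% ancestral, ,
                                      drop = FALSE])
  cons_by_class <- conservation_by_class(cons, assignments)

  randomization <- NULL
  if (n_reps > 0 && nrow(path) > 0)
    randomization <- permutation_test(
      stat_frac_with_flagged_gene(genes, "developmental"),
      path, build, n_reps = n_reps, seed = seed + 3)

  battery <- enrichment_battery(assignments, genes)

  path_cnvr_genes <- genes$gene_id[
    intersect_genes(genes, regions$path_grouped)]
  term_map <- list(
    developmental = genes$gene_id[genes$developmental %in% TRUE],
    complex_member = genes$gene_id[genes$complex_member %in% TRUE],
    ohnologue = genes$gene_id[genes$ohnologue %in% TRUE],
    omim_disease = genes$gene_id[genes$omim_disease %in% TRUE])
  term_enrichment <- NULL
  sol_in_bg <- intersect(sol_sum$solitary_genes, path_cnvr_genes)
  if (length(sol_in_bg) > 0 && length(path_cnvr_genes) > 1)
    term_enrichment <- hypergeom_enrichment(sol_in_bg, path_cnvr_genes,
                                            term_map)

  fractions <- list(
    genome_fraction_pathogenic = genome_fraction(path, build),
    genome_fraction_benign = genome_fraction(benign, build),
    genome_fraction_path_peaks = genome_fraction(peaks$path_grouped, build),
    benign_overlapped_by_pathogenic =
      if (nrow(benign)) region_overlap(benign, path) else NULL,
    benign_overlapped_by_path_peaks =
      if (nrow(benign)) region_overlap(benign, peaks$path_grouped) else NULL)

  manifest <- c(
    package_version = as.character(utils::packageVersion("dosagescope")),
    build = build$name,
    seed = seed,
    n_reps = n_reps,
    n_cnvs = nrow(cnvs),
    n_genes = nrow(genes),
    min_cnv_length_bp = 50,
    max_cnv_chrom_fraction = 0.1,
    simulated = !is.null(sim_config))

  result <- list(build = build, cnvs = cnvs, genes = genes,
                 regions = regions, peaks = peaks,
                 assignments = assignments, solitary = solitary,
                 solitary_summary = sol_sum, conservation = cons,
                 conservation_by_class = cons_by_class,
                 randomization = randomization, battery = battery,
                 term_enrichment = term_enrichment,
                 fractions = fractions, manifest = manifest)
  if (!is.null(out_dir)) write_pipeline_outputs(result, out_dir)
  result
}

#' Write pipeline reports to a directory
#'
#' Emits BED files of CNVRs and peaks (score column = coverage
#' depth), the per-gene class table, the per-gene conservation
#' table, the solitary-region table, the enrichment tables and a
#' plain-text manifest echoing seed and thresholds.
#'
#' @param result A [run_pipeline()] result.
#' @param out_dir Output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_pipeline_outputs <- function(result, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  fp <- function(...) file.path(out_dir, ...)
  for (nm in names(result$regions)) {
    r <- result$regions[[nm]]
    write_bed(data.frame(chrom = r$chrom, start = r$start, end = r$end,
                         name = r$region_id, score = r$n_members),
              fp(paste0("cnvr_", nm, ".bed")))
  }
  for (nm in names(result$peaks)) {
    p <- result$peaks[[nm]]
    write_bed(data.frame(chrom = p$chrom, start = p$start, end = p$end,
                         name = p$peak_id, score = p$depth),
              fp(paste0("peaks_", nm, ".bed")))
  }
  utils::write.table(result$assignments, fp("gene_classes.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(result$conservation, fp("conservation.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  sol <- result$solitary
  sol$class_p_gene_ids <- vapply(sol$class_p_gene_ids, paste,
                                 character(1), collapse = ",")
  utils::write.table(sol, fp("solitary.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(result$battery$flag_tests, fp("enrichment_flags.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(result$battery$median_tests))
    utils::write.table(result$battery$median_tests,
                       fp("enrichment_medians.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(result$term_enrichment))
    utils::write.table(result$term_enrichment, fp("term_enrichment.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  manifest <- result$manifest
  if (is.null(result$randomization))
    manifest <- c(manifest, randomization = "skipped (n_reps = 0)")
  else
    manifest <- c(manifest,
                  randomization_z = result$randomization$z,
                  randomization_p_empirical =
                    result$randomization$p_empirical)
  writeLines(paste(names(manifest), unname(manifest), sep = "="),
             fp("manifest.txt"))
  invisible(out_dir)
}
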