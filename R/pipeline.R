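#' Run the full allele-specific screen end to end
#'
#' Executes the stages in order: heterozygote validation from bisulfite
#' allele support, allele counting under the quality filter, ASM, ASHM
#' (with HWE QC) and ASE/ASP calling, clustering of significant ASHM sites
#' with driver identification, and proximity enrichment of the call sets
#' against the annotation tracks relative to the high-coverage background.
#' Every stage logs its in/out counts; every output TSV carries a comment
#' header naming the package version, seed, and resolved thresholds. The
#' run is deterministic: identical inputs and thresholds give byte-identical
#' outputs.
#'
#' @param input_dir Directory of fixture files (see [write_fixtures()]).
#' @param output_dir Directory for result TSVs (created if absent).
#' @param thresholds A [pipeline_thresholds()] object.
#' @param seed Seed recorded in output headers (the pipeline itself is
#'   deterministic; the seed documents the provenance of the inputs).
#' @return Invisibly, a list with `sites`, `counts`, `asm`, `ashm`,
#'   `per_modification`, `ase`, `clusters`, `enrichment`, `background`.
#' @export
run_pipeline <- function(input_dir, output_dir,
                         thresholds = pipeline_thresholds(),
                         seed = NA) {
  stopifnot(inherits(thresholds, "pipeline_thresholds"))
  ds <- read_dataset(input_dir)
  ok <- dir.exists(output_dir) || dir.create(output_dir, recursive = TRUE,
                                             showWarnings = FALSE)
  if (!ok) stop("I/O error: cannot create ", output_dir, call. = FALSE)

  header <- c(
    paste0("ashmscreen ", as.character(packageVersion("ashmscreen"))),
    paste0("seed: ", seed),
    paste0("thresholds: ",
           paste(names(thresholds), vapply(thresholds, function(x)
             paste(format(x), collapse = ","), character(1)),
             sep = "=", collapse = " "))
  )
  out <- function(x, f) write_tsv(x, file.path(output_dir, f), header)

  # -- stage: validate-hets ------------------------------------------------
  stage <- function(...) message("[", ..., "]")
  stage("validate-hets: ", nrow(ds$sites), " candidate sites")
  methyl_obs <- extract_methylation_observations(
    ds$bis_obs, ds$sites, ds$known_polymorphisms,
    min_base_quality = thresholds$min_base_quality)
  support <- bisulfite_allele_support(methyl_obs, ds$sites)
  sites <- filter_het_sites(ds$sites, support,
                            p_min = thresholds$p_het_min,
                            min_reads_per_allele =
                              thresholds$min_bis_reads_per_allele)
  validated <- sites[validated == TRUE]
  stage("validate-hets: ", nrow(validated), " validated")
  out(sites, "validated_sites.tsv")

  # -- stage: count-alleles ------------------------------------------------
  counts <- count_alleles(ds$chip_reads, validated,
                          min_base_quality = thresholds$min_base_quality,
                          datasets = unique(ds$chip_reads$dataset_id))
  background <- select_background_sites(
    counts, min_total_coverage = thresholds$min_chip_coverage)
  stage("count-alleles: ", length(unique(counts$site_id)),
        " covered sites, ", length(background), " at >= ",
        thresholds$min_chip_coverage, "x")

  # -- stage: call-asm -----------------------------------------------------
  asm <- call_asm(methyl_obs[site_id %chin% validated$site_id],
                  asm_alpha = thresholds$asm_alpha)
  asm <- annotate_adjacent_polymorphism(
    asm, ds$sites, max_distance = thresholds$adjacency_bp,
    p_min = thresholds$p_het_min)
  stage("call-asm: ", nrow(asm), " tested, ", sum(asm$significant),
        " significant at ", format(thresholds$asm_alpha))
  out(asm, "asm_calls.tsv")

  # -- stage: call-ashm ----------------------------------------------------
  ashm_res <- call_ashm(counts, validated,
                        ashm_alpha = thresholds$ashm_alpha,
                        min_total_coverage = thresholds$min_chip_coverage)
  ashm <- apply_qc(ashm_res$calls, ds$population,
                   hwe_alpha = thresholds$hwe_alpha,
                   ashm_alpha = thresholds$ashm_alpha)
  out(ashm, "ashm_calls.tsv")
  out(ashm_res$per_modification, "ashm_per_modification.tsv")

  # -- stage: call-ase -----------------------------------------------------
  ase <- call_ase(ds$expression, validated,
                  ase_alpha = thresholds$ase_alpha)
  stage("call-ase: ", nrow(ase), " tested, ", sum(ase$significant),
        " significant at ", format(thresholds$ase_alpha))
  out(ase, "ase_calls.tsv")

  # -- stage: cluster ------------------------------------------------------
  sig_ids <- ashm[significant == TRUE, site_id]
  clusters <- NULL
  if (length(sig_ids) >= 2) {
    profiles <- build_imbalance_profiles(ashm_res$per_modification,
                                         site_ids = sig_ids)
    dend <- cluster_sites(profiles)
    clusters <- choose_cut_and_drivers(dend, profiles)
    out(data.table(site_id = names(clusters$labels),
                   cluster = as.integer(clusters$labels)),
        "clusters.tsv")
    out(clusters$drivers, "drivers.tsv")
    writeLines(serialize_dendrogram(dend),
               file.path(output_dir, "dendrogram.txt"))
    stage("cluster: ", clusters$n_clusters, " cluster(s) over ",
          length(sig_ids), " significant sites")
  } else {
    stage("cluster: skipped (", length(sig_ids), " significant sites)")
  }

  # -- stage: enrich -------------------------------------------------------
  site_pos <- ds$sites[, .(site_id, chrom, pos)]
  bg_sites <- site_pos[site_id %chin% background]
  fg_sets <- list(
    ashm = site_pos[site_id %chin% intersect(sig_ids, background)],
    asm = unique(asm[significant == TRUE, .(chrom, pos = query_pos)])
  )
  enr <- list()
  for (set_name in names(fg_sets)) {
    fg <- fg_sets[[set_name]]
    if (nrow(fg) == 0) next
    for (tr in unique(ds$annotations$track)) {
      targets <- ds$annotations[track == tr]
      for (w in thresholds$windows) {
        f <- proximity_fraction(fg, targets, w)
        b <- proximity_fraction(bg_sites, targets, w)
        if (b$total == 0) next
        row <- enrichment_test(f$count_in, f$total, b$count_in, b$total,
                               window = w)
        row[, `:=`(call_set = set_name, track = tr)]
        enr[[length(enr) + 1L]] <- row
      }
    }
  }
  enrichment <- if (length(enr)) rbindlist(enr) else data.table(
    window = numeric(0), fg_in = integer(0), fg_total = integer(0),
    bg_in = integer(0), bg_total = integer(0), fg_prop = numeric(0),
    bg_prop = numeric(0), fold = numeric(0), p_value = numeric(0),
    test = character(0), call_set = character(0), track = character(0))
  out(enrichment, "enrichment.tsv")
  stage("enrich: ", nrow(enrichment), " comparisons")

  invisible(list(sites = sites, counts = counts, asm = asm, ashm = ashm,
                 per_modification = ashm_res$per_modification, ase = ase,
                 clusters = clusters, enrichment = enrichment,
                 background = background))
}
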