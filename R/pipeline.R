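#' Pipeline run configuration
#'
#' Exactly one of `simulation` (a [simulation_config]) or the four input
#' paths (`vcf`, `ped`, `bed`, `annotations`) must be given.
#'
#' @param vcf,ped,bed,annotations input file paths (file mode).
#' @param simulation a [simulation_config] (simulation mode).
#' @param proband_id proband individual id; in simulation mode defaults to
#'   the simulated proband, in file mode to the first affected member with
#'   two recorded parents.
#' @param family_id family to analyse when the PED holds several
#'   (default: first).
#' @param pass_only,permissive_parents,allowed_chroms see [apply_filters()].
#' @param chrom_style see [normalize_chrom()].
#' @param outdir output directory for stage artifacts and the JSON report.
#' @return object of class `run_config`.
#' @export
run_config <- function(vcf = NULL, ped = NULL, bed = NULL, annotations = NULL,
                       simulation = NULL, proband_id = NULL, family_id = NULL,
                       pass_only = FALSE, permissive_parents = FALSE,
                       allowed_chroms = NULL, chrom_style = "verbatim",
                       outdir = tempfile("trioscan_run")) {
  paths <- list(vcf = vcf, ped = ped, bed = bed, annotations = annotations)
  have_paths <- !vapply(paths, is.null, logical(1))
  if (is.null(simulation) && !all(have_paths)) {
    stop_with("trioscan_validation_error",
              "either a simulation block or all four input paths are required")
  }
  if (!is.null(simulation) && any(have_paths)) {
    stop_with("trioscan_validation_error",
              "simulation block and input paths are mutually exclusive")
  }
  if (!is.null(simulation)) stopifnot(inherits(simulation, "simulation_config"))
  structure(list(paths = paths, simulation = simulation,
                 proband_id = proband_id, family_id = family_id,
                 pass_only = pass_only, permissive_parents = permissive_parents,
                 allowed_chroms = allowed_chroms, chrom_style = chrom_style,
                 outdir = outdir),
            class = "run_config")
}

pick_proband <- function(ped) {
  m <- ped$members
  ok <- m$phenotype == "affected" & !is.na(m$father_id) & !is.na(m$mother_id)
  if (!any(ok)) {
    stop_with("trioscan_validation_error",
              "no affected member with two recorded parents in family '%s'",
              ped$family_id)
  }
  m$individual_id[which(ok)[1]]
}

stage <- function(name, expr) {
  message(sprintf("[%s] start", name))
  tryCatch(expr, error = function(e) {
    stop_with("trioscan_stage_error", "stage '%s' failed: %s",
              name, conditionMessage(e))
  })
}

#' Run the full candidate-discovery pipeline
#'
#' Orchestrates input acquisition (simulation or files), trio recessive
#' filtering, impact triage with gene aggregation, and per-candidate
#' segregation evaluation against the full pedigree. Stage artifacts
#' (`candidates.vcf`, `candidates.tsv`, `gene_report.tsv`, `report.json`)
#' are written under the configured output directory.
#'
#' Segregation is evaluated for every surviving SNV/indel: the candidate's
#' genotypes across all pedigree members are tested for consistency with
#' the recessive model, so candidates contradicted by a sibling genotype
#' are flagged even when the trio pattern alone admitted them.
#'
#' @param config a [run_config].
#' @return the run report (list), invisibly identical to what is written
#'   as `report.json` (timestamp aside): record counts per stage, tier
#'   tallies, the gene table, per-candidate segregation decisions, and a
#'   provenance block (package version, seed, full configuration).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  if (!dir.exists(config$outdir)) {
    dir.create(config$outdir, recursive = TRUE)
  }

  sim <- NULL
  if (!is.null(config$simulation)) {
    sim <- stage("simulate", simulate_family(config$simulation))
    ped <- sim$pedigree
    records <- sim$records
    annotations <- sim$annotations
    gene_map <- sim$config$gene_map
    write_fixture(sim, file.path(config$outdir, "fixture"))
  } else {
    peds <- stage("read", read_ped(config$paths$ped))
    ped <- if (is.null(config$family_id)) peds[[1]] else peds[[config$family_id]]
    if (is.null(ped)) {
      stop_with("trioscan_lookup_error", "family '%s' not in PED", config$family_id)
    }
    records <- stage("read", read_vcf(config$paths$vcf,
                                      sample_ids = ped$members$individual_id))
    annotations <- stage("read", read_consequences(config$paths$annotations))
    gene_map <- stage("read", read_gene_bed(config$paths$bed))
  }

  proband_id <- config$proband_id
  if (is.null(proband_id)) {
    proband_id <- if (!is.null(sim)) "proband" else pick_proband(ped)
  }
  trio_members <- extract_trio(ped, proband_id)
  trio <- trio_assignment(trio_members$father$individual_id,
                          trio_members$mother$individual_id,
                          proband_id)

  candidates <- stage("filter", apply_filters(
    records, trio, pass_only = config$pass_only,
    permissive_parents = config$permissive_parents,
    allowed_chroms = config$allowed_chroms))
  all_samples <- ped$members$individual_id
  if (length(candidates$snv) + length(candidates$cnv) > 0) {
    write_vcf(c(candidates$snv, candidates$cnv),
              file.path(config$outdir, "candidates.vcf"),
              sample_ids = all_samples)
  }
  surv <- data.frame(
    key = vapply(c(candidates$snv, candidates$cnv), variant_key, character(1)),
    class = vapply(c(candidates$snv, candidates$cnv),
                   function(r) r$variant_class, character(1)),
    stringsAsFactors = FALSE)
  utils::write.table(surv, file.path(config$outdir, "candidates.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  report_genes <- stage("triage", aggregate_by_gene(
    candidates, annotations, gene_map, chrom_style = config$chrom_style))
  write_gene_report(report_genes, file.path(config$outdir, "gene_report.tsv"))

  segregation <- stage("segregate", lapply(candidates$snv, function(rec) {
    verdict <- check_recessive_segregation(
      ped, rec$genotypes[intersect(names(rec$genotypes), all_samples)])
    list(variant = variant_key(rec), status = verdict$status,
         n_informative = verdict$n_informative,
         n_violations = nrow(verdict$violations))
  }))

  report <- list(
    counts = c(report_genes["tally"], candidates$counts),
    n_genes = nrow(report_genes$genes),
    genes = report_genes$genes,
    cnv_genes = report_genes$cnv$genes,
    unannotated = report_genes$unannotated,
    segregation = segregation,
    truth = if (!is.null(sim)) sim$truth[c("causal_snv", "causal_gene",
                                           "causal_cnv", "causal_cnv_gene")],
    provenance = list(
      tool = "trioscan",
      version = as.character(utils::packageVersion("trioscan")),
      seed = if (!is.null(config$simulation)) config$simulation$seed,
      proband_id = proband_id,
      family_id = ped$family_id,
      config = serialize_config(config)
    ),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  jsonlite::write_json(report, file.path(config$outdir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  invisible(report)
}

# Flatten a run_config into plain lists for the provenance block; the full
# configuration is recorded verbatim so a run is exactly repeatable.
serialize_config <- function(config) {
  sim <- config$simulation
  list(
    paths = config$paths,
    simulation = if (!is.null(sim)) {
      c(unclass(sim)[setdiff(names(sim), "gene_map")],
        list(n_genes = nrow(sim$gene_map)))
    },
    proband_id = config$proband_id,
    family_id = config$family_id,
    pass_only = config$pass_only,
    permissive_parents = config$permissive_parents,
    allowed_chroms = config$allowed_chroms,
    chrom_style = config$chrom_style
  )
}
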