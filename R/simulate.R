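# Weighted consequence vocabularies for background SNVs. Genic terms are
# mostly modifier/low with a minority of moderate/high so triage tallies
# are nontrivial; all terms are SNV-compatible.
.GENIC_TERMS <- c(
  intron_variant = 0.45, synonymous_variant = 0.17, missense_variant = 0.20,
  splice_region_variant = 0.05, `3_prime_UTR_variant` = 0.06,
  `5_prime_UTR_variant` = 0.03, stop_gained = 0.025,
  splice_donor_variant = 0.01, stop_lost = 0.005
)
.INTERGENIC_TERMS <- c(
  intergenic_variant = 0.6, upstream_gene_variant = 0.2,
  downstream_gene_variant = 0.2
)

#' Default gene map for simulations
#'
#' Twenty 100-kb genes, ten per chromosome on `chr1` and `chr2`, spaced
#' 1 Mb apart, in BED (0-based half-open) coordinates.
#'
#' @return data.frame with columns `chrom`, `start`, `end`, `gene_id`.
#' @export
default_gene_map <- function() {
  l <- rep(1:10, 2)
  data.frame(
    chrom = rep(c("chr1", "chr2"), each = 10),
    start = as.integer(400000 + (l - 1) * 1000000),
    end = as.integer(500000 + (l - 1) * 1000000),
    gene_id = sprintf("gene%02d", 1:20),
    stringsAsFactors = FALSE
  )
}

#' Simulation configuration
#'
#' Defines the family and genome that [simulate_family()] generates: a
#' nuclear family of two carrier parents and `n_offspring` children,
#' genome-wide unlinked biallelic background SNVs in Hardy-Weinberg
#' proportions among founders, one fully penetrant recessive causal SNV
#' (both parents forced heterozygous), background copy-number deletions
#' segregating as per-haplotype alleles, and one recessive causal deletion
#' (parents copy number 1, proband 0).
#'
#' @param seed integer seed; the whole simulation is reproducible from it.
#' @param n_background_snvs number of background biallelic SNV sites.
#' @param founder_alt_freq alternate-allele frequency used to draw founder
#'   genotypes; scalar or per-site vector of length `n_background_snvs`.
#' @param n_offspring number of children (the first is the proband).
#' @param n_cnv_background number of background CNV deletion loci.
#' @param genotyping_error_rate probability that an observed SNV genotype
#'   call is replaced by a uniformly chosen different call; the error-free
#'   truth is retained in the simulation's `truth` element.
#' @param gene_map gene intervals (BED semantics); see [default_gene_map()].
#' @param causal_site list with `chrom`, `pos`, `gene_id`; must fall inside
#'   the named gene's interval.
#' @param causal_cnv list with `chrom`, `start` (1-based), `end`
#'   (inclusive), `gene_id`; must overlap the named gene.
#' @param causal_consequence consequence term annotated on the causal SNV.
#' @param cnv_del_freq per-haplotype deletion frequency at background CNV
#'   loci.
#' @param penetrance probability that a homozygous-alternate offspring is
#'   affected (default 1: fully penetrant).
#' @return object of class `simulation_config`.
#' @export
simulation_config <- function(seed = 1L,
                              n_background_snvs = 2000L,
                              founder_alt_freq = 0.3,
                              n_offspring = 4L,
                              n_cnv_background = 20L,
                              genotyping_error_rate = 0,
                              gene_map = default_gene_map(),
                              causal_site = list(chrom = "chr1", pos = 4450000L,
                                                 gene_id = "gene05"),
                              causal_cnv = list(chrom = "chr2", start = 4430001L,
                                                end = 4470000L,
                                                gene_id = "gene15"),
                              causal_consequence = "stop_gained",
                              cnv_del_freq = 0.2,
                              penetrance = 1) {
  stopifnot(n_background_snvs >= 0, n_offspring >= 1, n_cnv_background >= 0,
            all(founder_alt_freq >= 0 & founder_alt_freq <= 1),
            length(founder_alt_freq) %in% c(1L, n_background_snvs),
            genotyping_error_rate >= 0, genotyping_error_rate <= 1,
            cnv_del_freq >= 0, cnv_del_freq <= 1,
            penetrance >= 0, penetrance <= 1)
  g <- gene_map[gene_map$gene_id == causal_site$gene_id, ]
  if (nrow(g) != 1 || g$chrom != causal_site$chrom ||
      causal_site$pos <= g$start || causal_site$pos > g$end) {
    stop_with("trioscan_validation_error",
              "causal_site must fall inside its gene_map interval")
  }
  gc <- gene_map[gene_map$gene_id == causal_cnv$gene_id, ]
  if (nrow(gc) != 1 || gc$chrom != causal_cnv$chrom ||
      causal_cnv$end <= gc$start || causal_cnv$start > gc$end) {
    stop_with("trioscan_validation_error",
              "causal_cnv must overlap its gene_map interval")
  }
  structure(list(seed = as.integer(seed),
                 n_background_snvs = as.integer(n_background_snvs),
                 founder_alt_freq = founder_alt_freq,
                 n_offspring = as.integer(n_offspring),
                 n_cnv_background = as.integer(n_cnv_background),
                 genotyping_error_rate = genotyping_error_rate,
                 gene_map = gene_map, causal_site = causal_site,
                 causal_cnv = causal_cnv,
                 causal_consequence = causal_consequence,
                 cnv_del_freq = cnv_del_freq, penetrance = penetrance),
            class = "simulation_config")
}

.CODE_TO_CALL <- c("hom_ref", "het", "hom_alt")

# Offspring genotype codes from parental codes: one transmitted allele per
# parent per site, independent sites (no linkage).
transmit <- function(father_code, mother_code) {
  n <- length(father_code)
  stats::rbinom(n, 1, father_code / 2) + stats::rbinom(n, 1, mother_code / 2)
}

#' Simulate a nuclear family with a planted recessive causal variant
#'
#' Generates the family structure the pipeline is designed for: two
#' founder parents, forced heterozygous at the causal SNV and carrying one
#' deleted haplotype at the causal CNV, plus `n_offspring` children drawn
#' by Mendelian transmission at every (unlinked) site. The family is
#' ascertained through its proband: the first offspring is conditioned to
#' inherit the alternate allele from each parent at the causal SNV and the
#' deleted haplotype from each parent at the causal CNV, so an affected
#' proband with the full recessive trio pattern always exists. All other
#' offspring and all background sites segregate freely. Phenotype is
#' affected iff homozygous-alternate at the causal SNV and a penetrance
#' draw succeeds.
#'
#' @param config a [simulation_config].
#' @return list of class `family_simulation`: `pedigree` ([pedigree]),
#'   `records` (list of [variant_record], sorted by chrom/pos, SNVs then
#'   CNVs per position), `annotations` (consequence table), `truth` (list:
#'   causal keys and gene ids, affected ids, error-free calls at corrupted
#'   sites) and `config`.
#' @export
simulate_family <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  if (exists(".Random.seed", envir = globalenv())) {
    old_seed <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old_seed, envir = globalenv()))
  }
  set.seed(config$seed)

  n_off <- config$n_offspring
  kids <- c("proband", if (n_off > 1) paste0("sib", seq_len(n_off - 1)))
  indiv <- c("father", "mother", kids)
  chroms <- unique(config$gene_map$chrom)
  chrom_len <- vapply(chroms, function(ch)
    max(config$gene_map$end[config$gene_map$chrom == ch]) + 1000000L, numeric(1))

  ## --- SNV sites ---------------------------------------------------------
  n_bg <- config$n_background_snvs
  site_chrom <- sample(chroms, n_bg, replace = TRUE)
  site_pos <- vapply(site_chrom, function(ch) sample.int(chrom_len[[ch]], 1),
                     numeric(1))
  dup <- duplicated(paste(site_chrom, site_pos)) |
    (site_chrom == config$causal_site$chrom & site_pos == config$causal_site$pos)
  while (any(dup)) {
    site_pos[dup] <- vapply(site_chrom[dup],
                            function(ch) sample.int(chrom_len[[ch]], 1), numeric(1))
    dup <- duplicated(paste(site_chrom, site_pos)) |
      (site_chrom == config$causal_site$chrom & site_pos == config$causal_site$pos)
  }
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, n_bg + 1L, replace = TRUE)
  alt <- vapply(ref, function(b) sample(setdiff(bases, b), 1), character(1),
                USE.NAMES = FALSE)
  site_chrom <- c(site_chrom, config$causal_site$chrom)
  site_pos <- c(site_pos, config$causal_site$pos)
  n_sites <- n_bg + 1L
  causal_idx <- n_sites
  is_causal <- seq_len(n_sites) == causal_idx

  p <- rep_len(config$founder_alt_freq, n_bg)
  codes <- matrix(0L, nrow = length(indiv), ncol = n_sites,
                  dimnames = list(indiv, NULL))
  codes["father", ] <- c(stats::rbinom(n_bg, 2, p), 1L)
  codes["mother", ] <- c(stats::rbinom(n_bg, 2, p), 1L)
  for (k in kids) {
    codes[k, ] <- transmit(codes["father", ], codes["mother", ])
  }
  codes["proband", causal_idx] <- 2L  # ascertainment: alt from each het parent

  affected <- vapply(kids, function(k) {
    codes[k, causal_idx] == 2L && stats::runif(1) < config$penetrance
  }, logical(1))

  ## --- observed calls with genotyping error ------------------------------
  true_calls <- matrix(.CODE_TO_CALL[codes + 1L], nrow = nrow(codes),
                       dimnames = dimnames(codes))
  obs_calls <- true_calls
  err <- config$genotyping_error_rate
  corrupted <- NULL
  if (err > 0) {
    flip <- matrix(stats::runif(length(obs_calls)) < err, nrow = nrow(obs_calls))
    idx <- which(flip, arr.ind = TRUE)
    if (nrow(idx) > 0) {
      all_calls <- c("hom_ref", "het", "hom_alt", "missing")
      obs_calls[idx] <- vapply(seq_len(nrow(idx)), function(j) {
        sample(setdiff(all_calls, true_calls[idx[j, 1], idx[j, 2]]), 1)
      }, character(1))
      corrupted <- data.frame(
        site = idx[, 2], individual = indiv[idx[, 1]],
        true_call = true_calls[idx], observed_call = obs_calls[idx],
        stringsAsFactors = FALSE)
    }
  }

  ## --- CNV loci -----------------------------------------------------------
  n_cnv <- config$n_cnv_background
  cnv_chrom <- sample(chroms, n_cnv, replace = TRUE)
  cnv_start <- vapply(cnv_chrom, function(ch)
    sample.int(chrom_len[[ch]] - 60000L, 1), numeric(1))
  cnv_width <- sample(5000:50000, n_cnv, replace = TRUE)
  cnv_chrom <- c(cnv_chrom, config$causal_cnv$chrom)
  cnv_start <- c(cnv_start, config$causal_cnv$start)
  cnv_end <- c(cnv_start[seq_len(n_cnv)] + cnv_width - 1L, config$causal_cnv$end)
  n_cnv_all <- n_cnv + 1L
  # deletion dosage (number of deleted haplotypes) per individual per locus
  del <- matrix(0L, nrow = length(indiv), ncol = n_cnv_all,
                dimnames = list(indiv, NULL))
  del["father", ] <- c(stats::rbinom(n_cnv, 2, config$cnv_del_freq), 1L)
  del["mother", ] <- c(stats::rbinom(n_cnv, 2, config$cnv_del_freq), 1L)
  for (k in kids) {
    del[k, ] <- transmit(del["father", ], del["mother", ])
  }
  del["proband", n_cnv_all] <- 2L  # ascertainment at the causal deletion
  cn <- 2L - del

  ## --- pedigree -----------------------------------------------------------
  sexes <- c("male", "female",
             sample(c("male", "female"), n_off, replace = TRUE))
  ped <- pedigree("F1", data.frame(
    individual_id = indiv,
    father_id = c(NA, NA, rep("father", n_off)),
    mother_id = c(NA, NA, rep("mother", n_off)),
    sex = sexes,
    phenotype = c("unaffected", "unaffected",
                  ifelse(affected, "affected", "unaffected")),
    stringsAsFactors = FALSE
  ))

  ## --- records, sorted by genome position ---------------------------------
  snv_ord <- order(site_chrom, site_pos)
  snv_records <- lapply(snv_ord, function(i) {
    variant_record(site_chrom[i], site_pos[i], ref[i], alt[i], "snv",
                   genotypes = stats::setNames(obs_calls[, i], indiv))
  })
  cnv_ord <- order(cnv_chrom, cnv_start)
  cnv_records <- lapply(cnv_ord, function(i) {
    variant_record(cnv_chrom[i], cnv_start[i], "N", "<DEL>", "cnv_deletion",
                   copy_numbers = stats::setNames(cn[, i], indiv),
                   end = cnv_end[i])
  })
  records <- c(snv_records, cnv_records)

  ## --- annotations ---------------------------------------------------------
  gm <- config$gene_map
  ann_gene <- character(n_sites)
  ann_term <- character(n_sites)
  for (i in seq_len(n_sites)) {
    if (is_causal[i]) {
      ann_gene[i] <- config$causal_site$gene_id
      ann_term[i] <- config$causal_consequence
      next
    }
    on_chrom <- gm[gm$chrom == site_chrom[i], ]
    inside <- site_pos[i] > on_chrom$start & site_pos[i] <= on_chrom$end
    if (any(inside)) {
      ann_gene[i] <- on_chrom$gene_id[which(inside)[1]]
      ann_term[i] <- sample(names(.GENIC_TERMS), 1, prob = .GENIC_TERMS)
    } else {
      mid <- (on_chrom$start + on_chrom$end) / 2
      ann_gene[i] <- on_chrom$gene_id[which.min(abs(mid - site_pos[i]))]
      ann_term[i] <- sample(names(.INTERGENIC_TERMS), 1,
                            prob = .INTERGENIC_TERMS)
    }
  }
  annotations <- data.frame(
    chrom = site_chrom[snv_ord], pos = as.integer(site_pos[snv_ord]),
    ref = ref[snv_ord], alt = alt[snv_ord], gene_id = ann_gene[snv_ord],
    consequence = ann_term[snv_ord], stringsAsFactors = FALSE)
  annotations$consequence_terms <- strsplit(annotations$consequence, ",")

  causal_snv_key <- paste(config$causal_site$chrom, config$causal_site$pos,
                          ref[causal_idx], alt[causal_idx], sep = ":")
  causal_cnv_key <- paste0(config$causal_cnv$chrom, ":",
                           config$causal_cnv$start, "-",
                           config$causal_cnv$end, ":DEL")
  if (!is.null(corrupted)) {
    corrupted$variant_key <- paste(site_chrom[corrupted$site],
                                   site_pos[corrupted$site],
                                   ref[corrupted$site], alt[corrupted$site],
                                   sep = ":")
    corrupted$site <- NULL
  }
  truth <- list(
    causal_snv = causal_snv_key,
    causal_gene = config$causal_site$gene_id,
    causal_cnv = causal_cnv_key,
    causal_cnv_gene = config$causal_cnv$gene_id,
    affected = kids[affected],
    causal_true_calls = as.list(stats::setNames(true_calls[, causal_idx], indiv)),
    corrupted_calls = corrupted
  )
  structure(list(pedigree = ped, records = records, annotations = annotations,
                 truth = truth, config = config),
            class = "family_simulation")
}

#' @export
print.family_simulation <- function(x, ...) {
  cat(sprintf(
    "<family_simulation> seed %d: %d members (%d affected), %d records\n",
    x$config$seed, nrow(x$pedigree$members),
    sum(x$pedigree$members$phenotype == "affected"), length(x$records)))
  invisible(x)
}

#' Write a simulated family as a file fixture
#'
#' Writes `family.vcf`, `family.ped`, `genes.bed`, `consequences.tsv` and
#' `truth.json` under `outdir`. Outputs carry no timestamps, so reruns of
#' the same seed are byte-identical.
#'
#' @param sim a `family_simulation` from [simulate_family()].
#' @param outdir output directory (created if absent).
#' @return named character vector of the five paths, invisibly.
#' @export
write_fixture <- function(sim, outdir) {
  stopifnot(inherits(sim, "family_simulation"))
  if (!dir.exists(outdir)) {
    ok <- dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop_with("trioscan_io_error", "cannot create directory %s", outdir)
  }
  paths <- c(
    vcf = file.path(outdir, "family.vcf"),
    ped = file.path(outdir, "family.ped"),
    bed = file.path(outdir, "genes.bed"),
    consequences = file.path(outdir, "consequences.tsv"),
    truth = file.path(outdir, "truth.json")
  )
  write_vcf(sim$records, paths[["vcf"]],
            sample_ids = sim$pedigree$members$individual_id)
  write_ped(sim$pedigree, paths[["ped"]])
  write_gene_bed(sim$config$gene_map, paths[["bed"]])
  write_consequences(sim$annotations, paths[["consequences"]])
  jsonlite::write_json(sim$truth, paths[["truth"]], auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, null = "null")
  invisible(paths)
}
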