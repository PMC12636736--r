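test_that("simulation_config validates probabilities, counts and causal placement", {
  expect_s3_class(simulation_config(), "simulation_config")
  expect_error(simulation_config(founder_alt_freq = 1.5))
  expect_error(simulation_config(n_offspring = 0))
  expect_error(simulation_config(genotyping_error_rate = -0.1))
  # causal site outside its gene interval
  expect_error(
    simulation_config(causal_site = list(chrom = "chr1", pos = 10L,
                                         gene_id = "gene05")),
    class = "trioscan_validation_error")
  expect_error(
    simulation_config(causal_cnv = list(chrom = "chr1", start = 1L, end = 2L,
                                        gene_id = "gene15")),
    class = "trioscan_validation_error")
})

test_that("affected offspring are exactly the causal-site homozygotes at full penetrance", {
  sim <- small_sim(5)
  causal <- Filter(function(r) trioscan:::variant_key(r) == sim$truth$causal_snv,
                   sim$records)[[1]]
  m <- sim$pedigree$members
  kids <- m$individual_id[!is.na(m$father_id)]
  for (k in kids) {
    expect_equal(m$phenotype[m$individual_id == k] == "affected",
                 unname(causal$genotypes[k] == "hom_alt"), info = k)
  }
  # parents are forced heterozygous carriers
  expect_equal(unname(causal$genotypes[c("father", "mother")]),
               c("het", "het"))
  expect_equal(m$phenotype[is.na(m$father_id)],
               c("unaffected", "unaffected"))
  # the ascertained proband is always affected
  expect_true("proband" %in% sim$truth$affected)
})

test_that("the same seed reproduces byte-identical fixture files", {
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  p1 <- write_fixture(small_sim(77), d1)
  p2 <- write_fixture(small_sim(77), d2)
  expect_setequal(names(p1), c("vcf", "ped", "bed", "consequences", "truth"))
  for (nm in names(p1)) {
    expect_identical(readLines(p1[[nm]]), readLines(p2[[nm]]), info = nm)
  }
  # rerunning into the same directory overwrites identically
  p3 <- write_fixture(small_sim(77), d1)
  expect_identical(readLines(p3[["vcf"]]), readLines(p2[["vcf"]]))
  # and a different seed differs
  d3 <- withr::local_tempdir()
  p4 <- write_fixture(small_sim(78), d3)
  expect_false(identical(readLines(p4[["vcf"]]), readLines(p2[["vcf"]])))
})

test_that("fixture files parse back into the simulated structures", {
  sim <- small_sim(13)
  d <- withr::local_tempdir()
  p <- write_fixture(sim, d)
  expect_identical(read_ped(p[["ped"]])[["F1"]], sim$pedigree)
  expect_identical(read_vcf(p[["vcf"]]), sim$records)
  truth <- jsonlite::read_json(p[["truth"]])
  expect_equal(truth$causal_snv, sim$truth$causal_snv)
  # VCF sample count is 2 parents + n_offspring
  hdr <- grep("^#CHROM", readLines(p[["vcf"]]), value = TRUE)
  expect_length(strsplit(hdr, "\t")[[1]], 9 + 2 + sim$config$n_offspring)
})

test_that("zero background sites leave only the causal SNV and CNV records", {
  sim <- simulate_family(simulation_config(seed = 2, n_background_snvs = 0L,
                                           n_cnv_background = 0L))
  keys <- vapply(sim$records, trioscan:::variant_key, character(1))
  expect_setequal(keys, c(sim$truth$causal_snv, sim$truth$causal_cnv))
})

test_that("error-free offspring genotypes are Mendelian-consistent at every site", {
  sim <- small_sim(19, n_snv = 400L)
  m <- sim$pedigree$members
  kids <- m$individual_id[!is.na(m$father_id)]
  for (r in Filter(function(r) r$variant_class == "snv", sim$records)) {
    f <- call_to_code(r$genotypes[["father"]])
    mo <- call_to_code(r$genotypes[["mother"]])
    for (k in kids) {
      expect_true(mendel_consistent(f, mo, call_to_code(r$genotypes[[k]])),
                  info = trioscan:::variant_key(r))
    }
  }
  # CNV copy numbers likewise: deletion dosage is transmitted per haplotype
  for (r in Filter(function(r) r$variant_class == "cnv_deletion", sim$records)) {
    f <- 2L - r$copy_numbers[["father"]]
    mo <- 2L - r$copy_numbers[["mother"]]
    for (k in kids) {
      expect_true(mendel_consistent(f, mo, 2L - r$copy_numbers[[k]]),
                  info = trioscan:::variant_key(r))
    }
  }
})

test_that("genotyping errors corrupt observations but truth is preserved", {
  sim <- small_sim(3, n_snv = 800L, genotyping_error_rate = 0.05)
  corrupted <- sim$truth$corrupted_calls
  expect_gt(nrow(corrupted), 0)
  expect_true(all(corrupted$true_call != corrupted$observed_call))
  # observed records reflect the corruption
  keys <- vapply(sim$records, trioscan:::variant_key, character(1))
  for (i in seq_len(min(nrow(corrupted), 20))) {
    rec <- sim$records[[match(corrupted$variant_key[i], keys)]]
    expect_equal(unname(rec$genotypes[corrupted$individual[i]]),
                 corrupted$observed_call[i])
  }
  # error rate is approximately honoured (binomial 4-sigma band)
  n_cells <- (sim$config$n_background_snvs + 1L) * 6L
  expect_lt(abs(nrow(corrupted) / n_cells - 0.05),
            4 * sqrt(0.05 * 0.95 / n_cells))
})

test_that("founder genotypes follow Hardy-Weinberg proportions (chi-square GOF)", {
  sim <- simulate_family(simulation_config(seed = 8, n_background_snvs = 10000L,
                                           founder_alt_freq = 0.5,
                                           n_cnv_background = 0L))
  snvs <- Filter(function(r) r$variant_class == "snv", sim$records)
  keys <- vapply(snvs, trioscan:::variant_key, character(1))
  bg <- snvs[keys != sim$truth$causal_snv]
  father <- vapply(bg, function(r) r$genotypes[["father"]], character(1))
  counts <- table(factor(father, levels = CALLS))
  p <- stats::chisq.test(counts, p = c(0.25, 0.5, 0.25))$p.value
  expect_gt(p, 0.01)
})

test_that("annotations cover every SNV site with non-empty known-vocabulary terms", {
  sim <- small_sim(29, n_snv = 300L)
  snv_keys <- vapply(Filter(function(r) r$variant_class == "snv", sim$records),
                     trioscan:::variant_key, character(1))
  ann_keys <- paste(sim$annotations$chrom, sim$annotations$pos,
                    sim$annotations$ref, sim$annotations$alt, sep = ":")
  expect_setequal(ann_keys, snv_keys)
  expect_true(all(lengths(sim$annotations$consequence_terms) >= 1))
  expect_true(all(unlist(sim$annotations$consequence_terms) %in%
                    impact_table()$term))
  # the causal annotation is the configured high-impact term in the truth gene
  i <- match(sim$truth$causal_snv, ann_keys)
  expect_equal(sim$annotations$gene_id[i], sim$truth$causal_gene)
  expect_equal(sim$annotations$consequence[i], "stop_gained")
})
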