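test_that("the confirmed family pattern is consistent with six informative members", {
  v <- check_recessive_segregation(family1_pedigree(), family1_calls())
  expect_equal(v$status, "consistent")
  expect_equal(v$n_informative, 6L)
  expect_equal(nrow(v$violations), 0)
})

test_that("an affected heterozygote makes the family inconsistent and is named", {
  calls <- family1_calls()
  calls[["sib1"]] <- "het"
  v <- check_recessive_segregation(family1_pedigree(), calls)
  expect_equal(v$status, "inconsistent")
  expect_true("sib1" %in% v$violations$individual_id)
  # an unaffected hom-alt individual is also a violation
  calls2 <- family1_calls()
  calls2[["sib3"]] <- "hom_alt"
  v2 <- check_recessive_segregation(family1_pedigree(), calls2)
  expect_equal(v2$status, "inconsistent")
  expect_true("sib3" %in% v2$violations$individual_id)
  # an obligate-carrier parent homozygous reference violates carrier logic
  calls3 <- family1_calls()
  calls3[["father"]] <- "hom_ref"
  v3 <- check_recessive_segregation(family1_pedigree(), calls3)
  expect_true("father" %in% v3$violations$individual_id)
})

test_that("all calls missing is inconclusive; unknown individuals raise a key error", {
  ped <- family1_pedigree()
  v <- check_recessive_segregation(ped, c(father = "missing", proband = "missing"))
  expect_equal(v$status, "inconclusive")
  expect_equal(v$n_informative, 0L)
  expect_error(check_recessive_segregation(ped, c(stranger = "het")),
               class = "trioscan_key_error")
})

test_that("verdicts equal the rule-by-rule reference over all 4^6 call assignments", {
  ped <- family1_pedigree()
  ids <- ped$members$individual_id
  grid <- expand.grid(rep(list(CALLS_M), 6), stringsAsFactors = FALSE)
  expect_equal(nrow(grid), 4096)
  for (i in seq_len(nrow(grid))) {
    calls <- stats::setNames(unlist(grid[i, ]), ids)
    got <- check_recessive_segregation(ped, calls)
    ref <- reference_segregation(ped, calls)
    expect_equal(got$status, ref$status, info = paste(calls, collapse = ","))
    expect_setequal(got$violations$individual_id, ref$violators)
    expect_equal(got$n_informative, ref$n_informative)
  }
})

test_that("adding a missing-call entry never changes a verdict", {
  ped <- family1_pedigree()
  set.seed(31)
  for (i in 1:40) {
    ids <- sample(ped$members$individual_id, 4)
    calls <- stats::setNames(sample(CALLS, 4, replace = TRUE), ids)
    base <- check_recessive_segregation(ped, calls)
    extra_id <- setdiff(ped$members$individual_id, ids)[1]
    augmented <- check_recessive_segregation(
      ped, c(calls, stats::setNames("missing", extra_id)))
    expect_equal(augmented$status, base$status)
    expect_equal(augmented$n_informative, base$n_informative)
  }
})

family2_inconsistent <- function() {
  # minimal independent family contradicting the model: an affected
  # offspring heterozygous at the candidate site
  ped <- pedigree("F2", data.frame(
    individual_id = c("f2_father", "f2_mother", "f2_affected"),
    father_id = c(NA, NA, "f2_father"),
    mother_id = c(NA, NA, "f2_mother"),
    sex = c("male", "female", "male"),
    phenotype = c("unaffected", "unaffected", "affected"),
    stringsAsFactors = FALSE))
  list(ped = ped,
       calls = c(f2_father = "het", f2_mother = "hom_ref", f2_affected = "het"))
}

test_that("one inconsistent family excludes a candidate despite a consistent one", {
  f2 <- family2_inconsistent()
  dec <- evaluate_candidate(list(family1_pedigree(), f2$ped),
                            list(family1_calls(), f2$calls))
  expect_equal(dec$decision, "excluded")
  expect_equal(dec$verdicts[["F1"]]$status, "consistent")
  expect_equal(dec$verdicts[["F2"]]$status, "inconsistent")
})

test_that("support requires all-consistent families and an informativeness floor", {
  ped <- family1_pedigree()
  # two consistent families with >= 3 informative calls each
  dec <- evaluate_candidate(list(ped, ped),
                            list(family1_calls(), family1_calls()))
  expect_equal(dec$decision, "supported")
  # single family, all missing -> inconclusive
  blank <- stats::setNames(rep("missing", 6), ped$members$individual_id)
  expect_equal(evaluate_candidate(list(ped), list(blank))$decision,
               "inconclusive")
  # consistent but under-informative -> inconclusive
  thin <- c(proband = "hom_alt")
  expect_equal(evaluate_candidate(list(ped), list(thin))$decision,
               "inconclusive")
  expect_error(evaluate_candidate(list(), list()),
               class = "trioscan_validation_error")
})

test_that("evaluate_candidate is order-invariant in its family list", {
  f2 <- family2_inconsistent()
  d1 <- evaluate_candidate(list(family1_pedigree(), f2$ped),
                           list(family1_calls(), f2$calls))
  d2 <- evaluate_candidate(list(f2$ped, family1_pedigree()),
                           list(f2$calls, family1_calls()))
  expect_equal(d1$decision, d2$decision)
  expect_equal(d1$verdicts[["F2"]], d2$verdicts[["F2"]])
})

test_that("genotype tables round-trip through TSV", {
  tab <- data.frame(individual_id = names(family1_calls()),
                    call = unname(family1_calls()),
                    stringsAsFactors = FALSE)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_genotype_table(tab, path)
  expect_identical(read_genotype_table(path), tab)
  v <- check_recessive_segregation(family1_pedigree(),
                                   read_genotype_table(path))
  expect_equal(v$status, "consistent")
})
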