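test_that("classify_impact maps terms through the bundled table with a max rule", {
  expect_equal(classify_impact("stop_gained"), "high")
  expect_equal(classify_impact(c("missense_variant", "intron_variant")),
               "moderate")
  expect_equal(classify_impact("synonymous_variant"), "low")
  expect_equal(classify_impact("intergenic_variant"), "modifier")
  expect_equal(classify_impact(c("transcript_ablation", "missense_variant")),
               "high")
  expect_warning(res <- classify_impact("made_up_term"), "unknown")
  expect_equal(res, "modifier")
  expect_error(classify_impact(character(0)), class = "trioscan_validation_error")
})

test_that("classify_impact is monotone: adding a term never lowers the tier", {
  levels <- c("modifier", "low", "moderate", "high")
  terms <- impact_table()$term
  set.seed(5)
  for (i in 1:50) {
    base <- sample(terms, sample(1:3, 1))
    extra <- sample(terms, 1)
    r1 <- match(classify_impact(base), levels)
    r2 <- match(classify_impact(c(base, extra)), levels)
    expect_gte(r2, r1)
  }
})

test_that("genes_overlapping honours half-open BED semantics at boundaries", {
  gm <- data.frame(chrom = "chr1", start = 150L, end = 300L, gene_id = "G",
                   stringsAsFactors = FALSE)
  # deletion chr1:100-200 (1-based inclusive) overlaps [150, 300)
  expect_equal(genes_overlapping(cnv_rec(c(1, 1, 0), pos = 100, end = 200), gm),
               "G")
  # deletion ending at the base before the gene starts: abutment, no overlap
  expect_equal(genes_overlapping(cnv_rec(c(1, 1, 0), pos = 100, end = 150), gm),
               character(0))
  # first overlapping base
  expect_equal(genes_overlapping(cnv_rec(c(1, 1, 0), pos = 100, end = 151), gm),
               "G")
  expect_warning(
    out <- genes_overlapping(cnv_rec(c(1, 1, 0), chrom = "chr9"), gm),
    "no genes")
  expect_equal(out, character(0))
})

test_that("genes_overlapping equals the brute-force all-pairs scan on random instances", {
  set.seed(99)
  for (rep in 1:4) {
    gm <- data.frame(
      chrom = sample(c("chr1", "chr2"), 50, replace = TRUE),
      start = sample.int(100000, 50),
      gene_id = sprintf("g%02d", 1:50),
      stringsAsFactors = FALSE)
    gm$end <- gm$start + sample.int(5000, 50)
    for (i in 1:50) {
      pos <- sample.int(100000, 1)
      cnv <- cnv_rec(c(1, 1, 0), chrom = sample(c("chr1", "chr2"), 1),
                     pos = pos, end = pos + sample.int(8000, 1))
      expect_identical(genes_overlapping(cnv, gm), brute_force_overlap(cnv, gm))
    }
  }
})

toy_annotations <- function() {
  data.frame(
    chrom = c("chr1", "chr1", "chr1"),
    pos = c(100L, 300L, 300L),
    ref = c("A", "C", "C"), alt = c("T", "G", "G"),
    gene_id = c("geneA", "geneA", "geneB"),
    consequence = c("missense_variant", "synonymous_variant",
                    "intron_variant"),
    consequence_terms = I(list("missense_variant", "synonymous_variant",
                               "intron_variant")),
    stringsAsFactors = FALSE)
}

test_that("aggregate_by_gene hand-counted toy: max impact, tally, multi-gene bookkeeping", {
  cand <- structure(list(
    snv = list(snv_rec("het", "het", "hom_alt", pos = 100, ref = "A", alt = "T"),
               snv_rec("het", "het", "hom_alt", pos = 300, ref = "C", alt = "G")),
    cnv = list(),
    counts = list()), class = "candidate_set")
  rep <- aggregate_by_gene(cand, toy_annotations(), default_gene_map())
  # geneA holds both variants (moderate, low); geneB the shared one (modifier)
  expect_equal(rep$genes$gene_id, c("geneA", "geneB"))
  expect_equal(rep$genes$max_impact, c("moderate", "modifier"))
  expect_equal(rep$genes$n_variants, c(2L, 1L))
  # the two-gene variant counts once in the tally, at its max over genes (low)
  expect_equal(unname(rep$tally[c("high", "moderate", "low", "modifier")]),
               c(0L, 1L, 1L, 0L))
  expect_equal(sum(rep$tally), 2)
})

test_that("aggregate_by_gene reports unannotated variants and empty inputs", {
  cand <- structure(list(
    snv = list(snv_rec("het", "het", "hom_alt", pos = 999)),
    cnv = list(), counts = list()), class = "candidate_set")
  rep <- aggregate_by_gene(cand, toy_annotations(), default_gene_map())
  expect_equal(rep$unannotated, "chr1:999:A:T")
  expect_equal(sum(rep$tally), 0)
  empty <- structure(list(snv = list(), cnv = list(), counts = list()),
                     class = "candidate_set")
  rep0 <- aggregate_by_gene(empty, toy_annotations(), default_gene_map())
  expect_equal(nrow(rep0$genes), 0)
  expect_equal(sum(rep0$tally), 0)
})

test_that("CNV survivors enter gene candidates as high impact, tallied distinctly", {
  gm <- default_gene_map()
  cand <- structure(list(
    snv = list(),
    cnv = list(cnv_rec(c(1, 1, 0), chrom = "chr1", pos = 450000, end = 460000)),
    counts = list()), class = "candidate_set")
  rep <- aggregate_by_gene(cand, toy_annotations()[0, ], gm)
  expect_equal(rep$genes$gene_id, "gene01")
  expect_equal(rep$genes$max_impact, "high")
  expect_equal(sum(rep$tally), 0)  # SNV tier tally untouched
  expect_equal(rep$cnv$n, 1)
  expect_equal(rep$cnv$genes, "gene01")
})

test_that("tier tally partitions the distinct annotated SNV survivors", {
  sim <- small_sim(23, n_snv = 500L)
  cand <- suppressMessages(apply_filters(sim$records, std_trio()))
  rep <- aggregate_by_gene(cand, sim$annotations, sim$config$gene_map)
  expect_equal(sum(rep$tally),
               length(cand$snv) - length(rep$unannotated))
  # planted causal gene is present at high impact
  expect_true(sim$truth$causal_gene %in% rep$genes$gene_id)
  expect_equal(
    rep$genes$max_impact[rep$genes$gene_id == sim$truth$causal_gene], "high")
})
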