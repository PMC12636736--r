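# Shared fixtures and independent reference (oracle) implementations.
# Oracles are deliberately written as literal, unoptimized restatements of
# the rules, sharing no code with the package internals they check.

CALLS <- c("hom_ref", "het", "hom_alt")
CALLS_M <- c(CALLS, "missing")

# Family-1-shaped pedigree: carrier parents, proband + affected sib,
# two unaffected sibs.
family1_pedigree <- function() {
  pedigree("F1", data.frame(
    individual_id = c("father", "mother", "proband", "sib1", "sib2", "sib3"),
    father_id = c(NA, NA, "father", "father", "father", "father"),
    mother_id = c(NA, NA, "mother", "mother", "mother", "mother"),
    sex = c("male", "female", "male", "female", "male", "female"),
    phenotype = c("unaffected", "unaffected", "affected", "affected",
                  "unaffected", "unaffected"),
    stringsAsFactors = FALSE
  ))
}

# The Sanger-confirmed segregation pattern: het parents, hom-alt affected
# offspring, one carrier and one wildtype unaffected sibling.
family1_calls <- function() {
  c(father = "het", mother = "het", proband = "hom_alt",
    sib1 = "hom_alt", sib2 = "het", sib3 = "hom_ref")
}

snv_rec <- function(f, m, p, chrom = "chr1", pos = 100, ref = "A", alt = "T",
                    filter = "PASS") {
  variant_record(chrom, pos, ref, alt, "snv",
                 genotypes = c(father = f, mother = m, proband = p),
                 filter = filter)
}

cnv_rec <- function(cn, class = "cnv_deletion", chrom = "chr1", pos = 100,
                    end = 200) {
  variant_record(chrom, pos, "N",
                 if (class == "cnv_deletion") "<DEL>" else "<DUP>", class,
                 copy_numbers = c(father = cn[1], mother = cn[2],
                                  proband = cn[3]),
                 end = end)
}

std_trio <- function() trio_assignment("father", "mother", "proband")

# Random mixed record sets over a father/mother/proband sample trio.
random_records <- function(n, seed) {
  set.seed(seed)
  lapply(seq_len(n), function(i) {
    chrom <- sample(c("chr1", "chr2", "chrX"), 1)
    if (stats::runif(1) < 0.25) {
      cnv_rec(sample(0:3, 3, replace = TRUE),
              class = sample(c("cnv_deletion", "cnv_duplication"), 1),
              chrom = chrom, pos = i * 1000, end = i * 1000 + 500)
    } else {
      g <- sample(CALLS_M, 3, replace = TRUE, prob = c(0.35, 0.3, 0.3, 0.05))
      snv_rec(g[1], g[2], g[3], chrom = chrom, pos = i * 100)
    }
  })
}

# Literal restatement of the two extraction rules over a record list;
# returns the indices of surviving records (autosomes only).
naive_filter_reference <- function(records) {
  which(vapply(records, function(r) {
    chrom <- sub("^chr", "", r$chrom)
    if (chrom %in% c("X", "Y", "M", "MT")) return(FALSE)
    if (!is.null(r$copy_numbers)) {
      if (r$variant_class != "cnv_deletion") return(FALSE)
      cn <- r$copy_numbers
      !anyNA(cn[c("father", "mother", "proband")]) &&
        cn[["father"]] == 1 && cn[["mother"]] == 1 && cn[["proband"]] == 0
    } else {
      g <- r$genotypes
      identical(g[["father"]], "het") && identical(g[["mother"]], "het") &&
        identical(g[["proband"]], "hom_alt")
    }
  }, logical(1)))
}

# Rule-by-rule reference evaluator for recessive segregation. Checks each
# rule independently and tallies violating individuals, rather than
# intersecting allowed-call sets as the implementation does.
reference_segregation <- function(ped, calls) {
  m <- ped$members
  get_call <- function(id) {
    if (id %in% names(calls)) calls[[id]] else "missing"
  }
  affected <- m$individual_id[m$phenotype == "affected"]
  parents_of_affected <- character(0)
  for (a in affected) {
    r <- m[m$individual_id == a, ]
    parents_of_affected <- c(parents_of_affected, r$father_id, r$mother_id)
  }
  parents_of_affected <- unique(parents_of_affected[!is.na(parents_of_affected)])
  violators <- character(0)
  informative <- character(0)
  for (i in seq_len(nrow(m))) {
    id <- m$individual_id[i]
    obs <- get_call(id)
    if (obs == "missing") next
    pheno <- m$phenotype[i]
    any_rule <- FALSE
    bad <- FALSE
    if (pheno == "affected") {
      any_rule <- TRUE
      if (obs != "hom_alt") bad <- TRUE
    }
    if (pheno == "unaffected") {
      any_rule <- TRUE
      if (obs == "hom_alt") bad <- TRUE
    }
    if (id %in% parents_of_affected) {
      any_rule <- TRUE
      if (obs == "hom_ref") bad <- TRUE
    }
    if (any_rule) informative <- c(informative, id)
    if (bad) violators <- c(violators, id)
  }
  status <- if (length(violators) > 0) {
    "inconsistent"
  } else if (length(informative) > 0) {
    "consistent"
  } else {
    "inconclusive"
  }
  list(status = status, violators = violators,
       n_informative = length(informative))
}

# All-pairs interval overlap scan: 1-based inclusive CNV span against
# 0-based half-open genes.
brute_force_overlap <- function(cnv, gene_map) {
  hits <- character(0)
  for (i in seq_len(nrow(gene_map))) {
    if (gene_map$chrom[i] != cnv$chrom) next
    lo <- cnv$pos - 1  # 0-based half-open CNV span [lo, hi)
    hi <- cnv$end
    if (lo < gene_map$end[i] && gene_map$start[i] < hi) {
      hits <- c(hits, gene_map$gene_id[i])
    }
  }
  gm <- gene_map[gene_map$gene_id %in% hits, ]
  gm <- gm[order(gm$chrom, gm$start, gm$gene_id), ]
  unique(gm$gene_id)
}

# Exhaustive Mendelian consistency: child genotype code is possible iff
# some combination of one transmitted allele per parent produces it.
mendel_consistent <- function(father_code, mother_code, child_code) {
  f_alleles <- unique(c(as.integer(father_code >= 1), as.integer(father_code == 2)))
  m_alleles <- unique(c(as.integer(mother_code >= 1), as.integer(mother_code == 2)))
  child_code %in% outer(f_alleles, m_alleles, `+`)
}

call_to_code <- function(call) match(call, CALLS) - 1L

small_sim <- function(seed, n_snv = 300L, n_cnv = 10L, ...) {
  simulate_family(simulation_config(seed = seed, n_background_snvs = n_snv,
                                    n_cnv_background = n_cnv, ...))
}
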