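# Frozen Sequence Ontology consequence-term -> impact map (VEP taxonomy),
# bundled so tier counts are reproducible offline.
.SO_IMPACT <- c(
  transcript_ablation = "high",
  splice_acceptor_variant = "high",
  splice_donor_variant = "high",
  stop_gained = "high",
  frameshift_variant = "high",
  stop_lost = "high",
  start_lost = "high",
  transcript_amplification = "high",
  feature_elongation = "high",
  feature_truncation = "high",
  inframe_insertion = "moderate",
  inframe_deletion = "moderate",
  missense_variant = "moderate",
  protein_altering_variant = "moderate",
  splice_donor_5th_base_variant = "low",
  splice_region_variant = "low",
  splice_donor_region_variant = "low",
  splice_polypyrimidine_tract_variant = "low",
  incomplete_terminal_codon_variant = "low",
  start_retained_variant = "low",
  stop_retained_variant = "low",
  synonymous_variant = "low",
  coding_sequence_variant = "modifier",
  mature_miRNA_variant = "modifier",
  `5_prime_UTR_variant` = "modifier",
  `3_prime_UTR_variant` = "modifier",
  non_coding_transcript_exon_variant = "modifier",
  intron_variant = "modifier",
  NMD_transcript_variant = "modifier",
  non_coding_transcript_variant = "modifier",
  upstream_gene_variant = "modifier",
  downstream_gene_variant = "modifier",
  TFBS_ablation = "modifier",
  TFBS_amplification = "modifier",
  TF_binding_site_variant = "modifier",
  regulatory_region_ablation = "modifier",
  regulatory_region_amplification = "modifier",
  regulatory_region_variant = "modifier",
  intergenic_variant = "modifier",
  sequence_variant = "modifier"
)

.IMPACT_LEVELS <- c("modifier", "low", "moderate", "high")

#' Bundled consequence-term impact table
#'
#' @return data.frame with columns `term` and `impact` giving the frozen
#'   Sequence Ontology term to impact-tier mapping used by
#'   [classify_impact()].
#' @export
impact_table <- function() {
  data.frame(term = names(.SO_IMPACT), impact = unname(.SO_IMPACT),
             stringsAsFactors = FALSE)
}

impact_rank <- function(impact) match(impact, .IMPACT_LEVELS)

#' Classify the impact tier of a consequence-term set
#'
#' Each Sequence Ontology term maps to one of the four VEP impact tiers
#' (high > moderate > low > modifier); a variant's tier is the maximum over
#' its terms. Terms absent from the bundled table fall back to modifier
#' with a warning, so unexpected annotations never silently promote a
#' variant.
#'
#' @param terms non-empty character vector of consequence terms.
#' @return single string: `"high"`, `"moderate"`, `"low"` or `"modifier"`.
#' @examples
#' classify_impact("stop_gained")                          # "high"
#' classify_impact(c("missense_variant", "intron_variant")) # "moderate"
#' @export
classify_impact <- function(terms) {
  if (length(terms) == 0) {
    stop_with("trioscan_validation_error", "empty consequence-term set")
  }
  imp <- .SO_IMPACT[terms]
  if (anyNA(imp)) {
    warning(sprintf("unknown consequence term(s) treated as modifier: %s",
                    paste(unique(terms[is.na(imp)]), collapse = ", ")))
    imp[is.na(imp)] <- "modifier"
  }
  .IMPACT_LEVELS[max(impact_rank(imp))]
}

#' Read a gene map from a BED file
#'
#' Standard BED semantics: 0-based half-open intervals, columns chrom,
#' start, end, name (gene id).
#'
#' @param path path to a BED file (no header).
#' @return data.frame with columns `chrom`, `start`, `end`, `gene_id`.
#' @export
read_gene_bed <- function(path) {
  df <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 4) {
    stop_with("trioscan_schema_error", "gene BED needs >= 4 columns")
  }
  df <- df[, 1:4]
  names(df) <- c("chrom", "start", "end", "gene_id")
  df$start <- as.integer(df$start)
  df$end <- as.integer(df$end)
  df
}

#' @rdname read_gene_bed
#' @param gene_map data.frame with columns `chrom`, `start`, `end`, `gene_id`.
#' @export
write_gene_bed <- function(gene_map, path) {
  utils::write.table(gene_map[, c("chrom", "start", "end", "gene_id")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' Genes overlapping a CNV record
#'
#' Intersects the CNV's 1-based inclusive span with a 0-based half-open
#' gene map; any overlap of at least one base counts. Returns gene ids
#' ordered by (chrom, start, gene_id). A chromosome with no genes after
#' name normalization yields an empty set with a warning.
#'
#' @param cnv a CNV [variant_record].
#' @param gene_map data.frame as from [read_gene_bed()].
#' @param chrom_style chromosome-name normalization applied to both sides;
#'   see [normalize_chrom()].
#' @return character vector of gene ids.
#' @export
genes_overlapping <- function(cnv, gene_map, chrom_style = "verbatim") {
  stopifnot(cnv$variant_class %in% c("cnv_deletion", "cnv_duplication"))
  gm <- gene_map[normalize_chrom(gene_map$chrom, chrom_style) ==
                   normalize_chrom(cnv$chrom, chrom_style), , drop = FALSE]
  if (nrow(gm) == 0) {
    warning(sprintf("no genes on chromosome '%s' after normalization", cnv$chrom))
    return(character(0))
  }
  hits <- IRanges::findOverlaps(
    IRanges::IRanges(start = cnv$pos, end = cnv$end),
    IRanges::IRanges(start = gm$start + 1L, end = gm$end)
  )
  gm <- gm[S4Vectors::subjectHits(hits), , drop = FALSE]
  gm <- gm[order(gm$chrom, gm$start, gm$gene_id), , drop = FALSE]
  unique(gm$gene_id)
}

#' Aggregate surviving variants into gene-level candidates
#'
#' SNV/indel survivors are joined to their consequence annotations; a
#' variant annotated against k genes contributes to k gene candidates but
#' exactly once to the impact-tier tally, at the maximum impact over all
#' its annotations. CNV survivors are assigned to the genes they overlap
#' and enter gene candidates as high impact (a homozygous deletion ablates
#' the transcript); they are tallied separately from the SNV tiers.
#' Unannotated SNVs are reported, not dropped silently.
#'
#' @param candidates a `candidate_set` from [apply_filters()].
#' @param annotations data.frame from [read_consequences()].
#' @param gene_map data.frame from [read_gene_bed()].
#' @param chrom_style see [normalize_chrom()].
#' @return list of class `gene_report` with elements `genes` (data.frame:
#'   `gene_id`, `max_impact`, `n_variants`, `variant_keys`, sorted by
#'   impact descending then gene id), `tally` (named counts over the four
#'   tiers, SNV/indel variants only), `unannotated` (variant keys) and
#'   `cnv` (list: `n`, `genes`).
#' @export
aggregate_by_gene <- function(candidates, annotations, gene_map,
                              chrom_style = "verbatim") {
  ann_key <- paste(annotations$chrom, annotations$pos, annotations$ref,
                   annotations$alt, sep = ":")
  gene_vars <- list()   # gene_id -> data.frame(key, impact)
  add_gene_variant <- function(gene, key, impact) {
    gene_vars[[gene]] <<- rbind(gene_vars[[gene]],
      data.frame(key = key, impact = impact, stringsAsFactors = FALSE))
  }
  tally <- stats::setNames(integer(4), rev(.IMPACT_LEVELS))
  unannotated <- character(0)
  for (rec in candidates$snv) {
    key <- variant_key(rec)
    rows <- which(ann_key == key)
    if (length(rows) == 0) {
      unannotated <- c(unannotated, key)
      next
    }
    per_gene <- vapply(rows, function(i)
      classify_impact(annotations$consequence_terms[[i]]), character(1))
    tier <- .IMPACT_LEVELS[max(impact_rank(per_gene))]
    tally[tier] <- tally[tier] + 1L
    for (j in seq_along(rows)) {
      add_gene_variant(annotations$gene_id[rows[j]], key, per_gene[j])
    }
  }
  cnv_genes <- character(0)
  for (rec in candidates$cnv) {
    key <- variant_key(rec)
    genes <- genes_overlapping(rec, gene_map, chrom_style)
    cnv_genes <- union(cnv_genes, genes)
    for (g in genes) add_gene_variant(g, key, "high")
  }
  genes <- if (length(gene_vars) == 0) {
    data.frame(gene_id = character(0), max_impact = character(0),
               n_variants = integer(0), variant_keys = character(0),
               stringsAsFactors = FALSE)
  } else {
    do.call(rbind, lapply(names(gene_vars), function(g) {
      v <- gene_vars[[g]]
      data.frame(
        gene_id = g,
        max_impact = .IMPACT_LEVELS[max(impact_rank(v$impact))],
        n_variants = length(unique(v$key)),
        variant_keys = paste(unique(v$key), collapse = ","),
        stringsAsFactors = FALSE
      )
    }))
  }
  genes <- genes[order(-impact_rank(genes$max_impact), genes$gene_id), ,
                 drop = FALSE]
  rownames(genes) <- NULL
  structure(list(genes = genes, tally = tally, unannotated = unannotated,
                 cnv = list(n = length(candidates$cnv), genes = cnv_genes)),
            class = "gene_report")
}

#' @export
print.gene_report <- function(x, ...) {
  cat(sprintf(
    "<gene_report> %d genes; tiers high=%d moderate=%d low=%d modifier=%d; %d CNV\n",
    nrow(x$genes), x$tally[["high"]], x$tally[["moderate"]], x$tally[["low"]],
    x$tally[["modifier"]], x$cnv$n))
  invisible(x)
}

#' Write a gene-level candidate report as TSV
#'
#' @param report a `gene_report` from [aggregate_by_gene()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gene_report <- function(report, path) {
  utils::write.table(report$genes, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
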