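#' Assign VCF samples to trio roles
#'
#' @param father_sample,mother_sample,proband_sample distinct sample ids.
#' @return object of class `trio_assignment`.
#' @export
trio_assignment <- function(father_sample, mother_sample, proband_sample) {
  ids <- c(father_sample, mother_sample, proband_sample)
  stopifnot(is.character(ids), length(ids) == 3, all(nzchar(ids)))
  if (anyDuplicated(ids)) {
    stop_with("trioscan_validation_error", "trio sample ids must be distinct")
  }
  structure(list(father_sample = father_sample, mother_sample = mother_sample,
                 proband_sample = proband_sample), class = "trio_assignment")
}

trio_calls <- function(record, trio) {
  ids <- c(trio$father_sample, trio$mother_sample, trio$proband_sample)
  if (!all(ids %in% names(record$genotypes))) {
    stop_with("trioscan_assignment_error",
              "trio sample(s) absent from record %s: %s", variant_key(record),
              paste(setdiff(ids, names(record$genotypes)), collapse = ", "))
  }
  record$genotypes[ids]
}

#' Recessive trio filter for SNV/indel records
#'
#' The core extraction rule: both parents heterozygous (0/1) and the
#' proband homozygous for the alternate allele (1/1). Any missing genotype
#' fails. With `permissive_parents = TRUE` the parental requirement relaxes
#' to carrying at least one alternate allele (het or hom-alt), which admits
#' recessive-compatible but non-canonical parental configurations.
#'
#' @param record a SNV/indel [variant_record].
#' @param trio a [trio_assignment]; all three samples must be genotyped in
#'   the record.
#' @param permissive_parents logical; default `FALSE` (strict het x het).
#' @return `TRUE` iff the record matches the recessive trio pattern.
#' @export
recessive_snv_pass <- function(record, trio, permissive_parents = FALSE) {
  stopifnot(record$variant_class %in% c("snv", "indel"))
  g <- trio_calls(record, trio)
  if (any(g == "missing")) return(FALSE)
  parent_ok <- if (permissive_parents) {
    all(g[1:2] %in% c("het", "hom_alt"))
  } else {
    all(g[1:2] == "het")
  }
  parent_ok && g[[3]] == "hom_alt"
}

#' Recessive trio filter for CNV records
#'
#' Only deletions are considered, with copy number 1 in both parents
#' (heterozygous deletion carriers) and 0 in the proband (homozygous
#' deletion). A missing copy number fails quietly rather than erroring.
#'
#' @param record a CNV [variant_record].
#' @inheritParams recessive_snv_pass
#' @return `TRUE` iff the record is a deletion with trio copy numbers
#'   (1, 1, 0).
#' @export
recessive_cnv_pass <- function(record, trio) {
  stopifnot(record$variant_class %in% c("cnv_deletion", "cnv_duplication"))
  if (record$variant_class != "cnv_deletion") return(FALSE)
  ids <- c(trio$father_sample, trio$mother_sample, trio$proband_sample)
  if (!all(ids %in% names(record$copy_numbers))) {
    stop_with("trioscan_assignment_error",
              "trio sample(s) absent from record %s: %s", variant_key(record),
              paste(setdiff(ids, names(record$copy_numbers)), collapse = ", "))
  }
  cn <- record$copy_numbers[ids]
  if (anyNA(cn)) {
    message(sprintf("record %s: missing copy number, excluded", variant_key(record)))
    return(FALSE)
  }
  cn[[1]] == 1L && cn[[2]] == 1L && cn[[3]] == 0L
}

#' Apply the recessive trio filters to a record stream
#'
#' Runs [recessive_snv_pass()] on SNV/indel records and
#' [recessive_cnv_pass()] on CNV records, in input order. Sex-chromosome
#' and mitochondrial records are dropped before testing (the inheritance
#' model is autosomal); pass `allowed_chroms` to override.
#'
#' @param records list of [variant_record]s.
#' @param trio a [trio_assignment].
#' @param pass_only logical; if `TRUE`, only records whose FILTER field is
#'   `PASS` or `.` are considered.
#' @param permissive_parents see [recessive_snv_pass()].
#' @param allowed_chroms optional chromosome allow-list; default admits all
#'   autosomes.
#' @return object of class `candidate_set`: list with `snv` and `cnv`
#'   (surviving records, order preserved) and `counts` (records examined
#'   and passed per class).
#' @export
apply_filters <- function(records, trio, pass_only = FALSE,
                          permissive_parents = FALSE, allowed_chroms = NULL) {
  is_cnv <- vapply(records, function(r)
    r$variant_class %in% c("cnv_deletion", "cnv_duplication"), logical(1))
  keep <- vapply(records, function(r) {
    if (!is.null(allowed_chroms)) r$chrom %in% allowed_chroms else is_autosome(r$chrom)
  }, logical(1))
  if (pass_only) {
    keep <- keep & vapply(records, function(r) r$filter %in% c("PASS", "."), logical(1))
  }
  pass <- logical(length(records))
  for (i in seq_along(records)) {
    if (!keep[i]) next
    pass[i] <- if (is_cnv[i]) {
      recessive_cnv_pass(records[[i]], trio)
    } else {
      recessive_snv_pass(records[[i]], trio, permissive_parents)
    }
  }
  out <- structure(list(
    snv = records[pass & !is_cnv],
    cnv = records[pass & is_cnv],
    counts = list(
      n_input = length(records),
      n_snv_examined = sum(keep & !is_cnv),
      n_cnv_examined = sum(keep & is_cnv),
      n_snv_pass = sum(pass & !is_cnv),
      n_cnv_pass = sum(pass & is_cnv)
    )
  ), class = "candidate_set")
  message(sprintf("[filter] SNV/indel: %d/%d pass; CNV: %d/%d pass",
                  out$counts$n_snv_pass, out$counts$n_snv_examined,
                  out$counts$n_cnv_pass, out$counts$n_cnv_examined))
  out
}

#' @export
print.candidate_set <- function(x, ...) {
  cat(sprintf("<candidate_set> %d SNV/indel + %d CNV survivors (of %d records)\n",
              length(x$snv), length(x$cnv), x$counts$n_input))
  invisible(x)
}
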