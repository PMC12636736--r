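#' Parse a VCF genotype string
#'
#' Biallelic diploid calls only: `"0/0"` is homozygous reference, `"0/1"`
#' and `"1/0"` heterozygous, `"1/1"` homozygous alternate. Phased
#' separators (`|`) set the phase flag but never change the call. Any
#' allele given as `.` (including one-sided calls like `"./1"`) yields a
#' missing call. Allele indices above 1 indicate a multiallelic leak and
#' raise an error; sites must be split to biallelic first (see
#' [read_vcf()]).
#'
#' @param gt_string a single genotype field string, e.g. `"0/1"`.
#' @return list of class `genotype` with elements `call` (one of
#'   `"hom_ref"`, `"het"`, `"hom_alt"`, `"missing"`) and `phased` (logical).
#' @examples
#' parse_genotype("0/1")$call   # "het"
#' parse_genotype("1|1")$phased # TRUE
#' @export
parse_genotype <- function(gt_string) {
  stopifnot(is.character(gt_string), length(gt_string) == 1)
  phased <- grepl("|", gt_string, fixed = TRUE)
  if (gt_string == ".") {
    return(structure(list(call = "missing", phased = FALSE), class = "genotype"))
  }
  alleles <- strsplit(gt_string, "[/|]")[[1]]
  if (length(alleles) != 2 || !all(grepl("^(\\.|[0-9]+)$", alleles))) {
    stop_with("trioscan_parse_error", "malformed genotype '%s'", gt_string)
  }
  if (any(alleles %in% as.character(2:9)) ||
      any(suppressWarnings(as.integer(alleles[alleles != "."])) > 1)) {
    stop_with("trioscan_multiallelic_error",
              "genotype '%s' carries an allele index > 1; split the site to biallelic first",
              gt_string)
  }
  call <- if (any(alleles == ".")) {
    "missing"
  } else {
    c("hom_ref", "het", "hom_alt")[sum(as.integer(alleles)) + 1]
  }
  structure(list(call = call, phased = phased), class = "genotype")
}

#' @export
print.genotype <- function(x, ...) {
  cat(sprintf("<genotype> %s%s\n", x$call, if (x$phased) " (phased)" else ""))
  invisible(x)
}

#' Construct a variant record
#'
#' SNV/indel records carry one biallelic genotype call per sample; CNV
#' records carry one non-negative integer copy number per sample plus an
#' inclusive `end` coordinate. Coordinates are 1-based (VCF convention).
#'
#' @param chrom chromosome name.
#' @param pos 1-based position.
#' @param ref,alt allele strings; `alt` is `"<DEL>"`/`"<DUP>"` for CNVs.
#' @param variant_class one of `"snv"`, `"indel"`, `"cnv_deletion"`,
#'   `"cnv_duplication"`.
#' @param genotypes named character vector of calls (non-CNV records).
#' @param copy_numbers named integer vector of copy numbers (CNV records);
#'   `NA` allowed for missing values.
#' @param end 1-based inclusive end (CNV records), `end >= pos`.
#' @param filter VCF FILTER field (default `"PASS"`).
#' @return object of class `variant_record`.
#' @export
variant_record <- function(chrom, pos, ref, alt, variant_class,
                           genotypes = NULL, copy_numbers = NULL,
                           end = NULL, filter = "PASS") {
  stopifnot(variant_class %in% c("snv", "indel", "cnv_deletion", "cnv_duplication"))
  pos <- as.integer(pos)
  if (variant_class %in% c("cnv_deletion", "cnv_duplication")) {
    if (is.null(copy_numbers) || is.null(names(copy_numbers))) {
      stop_with("trioscan_validation_error", "CNV record needs named copy_numbers")
    }
    end <- as.integer(end)
    if (is.null(end) || is.na(end) || end < pos) {
      stop_with("trioscan_validation_error", "CNV record needs end >= pos")
    }
    cn <- as.integer(copy_numbers)
    names(cn) <- names(copy_numbers)
    if (any(!is.na(cn) & cn < 0)) {
      stop_with("trioscan_validation_error", "copy numbers must be non-negative")
    }
    genotypes <- NULL
    copy_numbers <- cn
  } else {
    if (is.null(genotypes) || is.null(names(genotypes))) {
      stop_with("trioscan_validation_error", "genotype record needs named genotypes")
    }
    stopifnot(all(genotypes %in% c("hom_ref", "het", "hom_alt", "missing")))
    if (variant_class == "snv" && !(nchar(ref) == 1 && nchar(alt) == 1 && ref != alt)) {
      stop_with("trioscan_validation_error",
                "snv requires single differing ref/alt bases, got %s>%s", ref, alt)
    }
    end <- NULL
    copy_numbers <- NULL
  }
  structure(list(chrom = chrom, pos = pos, ref = ref, alt = alt,
                 variant_class = variant_class, genotypes = genotypes,
                 copy_numbers = copy_numbers, end = end, filter = filter),
            class = "variant_record")
}

#' @export
print.variant_record <- function(x, ...) {
  cat(sprintf("<variant_record> %s [%s]\n", variant_key(x), x$variant_class))
  invisible(x)
}

# Split one multiallelic genotype token against alt index k: allele 0 -> 0,
# allele k -> 1, any other alt (or *) -> whole call missing.
recode_gt_against_alt <- function(token, k) {
  if (token %in% c(".", "./.", ".|.")) return("missing")
  alleles <- strsplit(token, "[/|]")[[1]]
  if (length(alleles) != 2) {
    stop_with("trioscan_parse_error", "malformed genotype '%s'", token)
  }
  if (any(alleles == ".")) return("missing")
  a <- as.integer(alleles)
  if (any(is.na(a))) stop_with("trioscan_parse_error", "malformed genotype '%s'", token)
  if (any(a != 0 & a != k)) return("missing")
  c("hom_ref", "het", "hom_alt")[sum(a == k) + 1]
}

info_field <- function(info, key) {
  m <- regmatches(info, regexec(paste0("(?:^|;)", key, "=([^;]+)"), info))[[1]]
  if (length(m) < 2) NA_character_ else m[2]
}

format_field <- function(format, values, key) {
  keys <- strsplit(format, ":", fixed = TRUE)[[1]]
  i <- match(key, keys)
  if (is.na(i)) return(rep(NA_character_, length(values)))
  vapply(strsplit(values, ":", fixed = TRUE), function(v) {
    if (length(v) >= i) v[i] else NA_character_
  }, character(1))
}

#' Read variant records from a VCF file
#'
#' Parses a VCF 4.x file (plain or gzipped) into a list of
#' [variant_record] objects in file order. Multiallelic sites are split
#' into one biallelic record per alternate allele, with genotypes recoded
#' against that allele; a genotype carrying any other alternate allele
#' becomes missing in the split record. Lines with a symbolic `<DEL>` or
#' `<DUP>` alternate and a per-sample `CN` FORMAT field become CNV records;
#' their `end` is taken from the INFO `END` key (required).
#'
#' @param path path to a VCF file.
#' @param sample_ids optional character vector of expected samples; an
#'   error is raised if any is absent from the header.
#' @return list of [variant_record]s (possibly empty).
#' @seealso [write_vcf()]
#' @export
read_vcf <- function(path, sample_ids = NULL) {
  if (!file.exists(path)) {
    stop_with("trioscan_io_error", "VCF file not found: %s", path)
  }
  con <- if (grepl("\\.gz$", path)) gzfile(path) else file(path)
  n_body <- sum(!startsWith(readLines(con, warn = FALSE), "#"))
  if (n_body == 0) {
    # vcfR rejects record-free files; an empty stream is a valid input here
    hdr <- readLines(path, warn = FALSE)
    chrom_line <- grep("^#CHROM", hdr, value = TRUE)
    if (length(chrom_line) == 1 && !is.null(sample_ids)) {
      samples <- strsplit(chrom_line, "\t", fixed = TRUE)[[1]][-(1:9)]
      if (!all(sample_ids %in% samples)) {
        stop_with("trioscan_header_error", "samples absent from VCF header: %s",
                  paste(setdiff(sample_ids, samples), collapse = ", "))
      }
    }
    return(list())
  }
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- v@fix
  gt <- v@gt
  samples <- colnames(gt)[-1]
  if (!is.null(sample_ids) && !all(sample_ids %in% samples)) {
    stop_with("trioscan_header_error", "samples absent from VCF header: %s",
              paste(setdiff(sample_ids, samples), collapse = ", "))
  }
  records <- vector("list", 2L * nrow(fix))
  n <- 0L
  for (i in seq_len(nrow(fix))) {
    chrom <- unname(fix[i, "CHROM"]); pos <- as.integer(fix[i, "POS"])
    ref <- unname(fix[i, "REF"]); alt <- unname(fix[i, "ALT"])
    filt <- unname(fix[i, "FILTER"])
    if (is.na(filt)) filt <- "."
    fmt <- gt[i, 1]
    vals <- gt[i, -1]
    if (alt %in% c("<DEL>", "<DUP>")) {
      end <- info_field(fix[i, "INFO"], "END")
      if (is.na(end)) {
        stop_with("trioscan_format_error",
                  "symbolic record %s:%d lacks INFO END", chrom, pos)
      }
      cn_raw <- format_field(fmt, vals, "CN")
      if (all(is.na(cn_raw))) {
        stop_with("trioscan_format_error",
                  "symbolic record %s:%d lacks FORMAT CN", chrom, pos)
      }
      cn <- suppressWarnings(as.integer(cn_raw))
      names(cn) <- samples
      n <- n + 1L
      records[[n]] <- variant_record(
        chrom, pos, ref, alt,
        if (alt == "<DEL>") "cnv_deletion" else "cnv_duplication",
        copy_numbers = cn, end = as.integer(end), filter = filt
      )
    } else {
      alts <- strsplit(alt, ",", fixed = TRUE)[[1]]
      gts <- format_field(fmt, vals, "GT")
      gts[is.na(gts)] <- "."
      for (k in seq_along(alts)) {
        if (alts[k] == "*") next
        calls <- vapply(gts, recode_gt_against_alt, character(1), k = k)
        names(calls) <- samples
        cls <- if (nchar(ref) == 1 && nchar(alts[k]) == 1) "snv" else "indel"
        n <- n + 1L
        records[[n]] <- variant_record(chrom, pos, ref, alts[k], cls,
                                       genotypes = calls, filter = filt)
      }
    }
  }
  records[seq_len(n)]
}

.CALL_TO_GT <- c(hom_ref = "0/0", het = "0/1", hom_alt = "1/1", missing = "./.")

vcf_header <- function(sample_ids) {
  c("##fileformat=VCFv4.2",
    "##INFO=<ID=END,Number=1,Type=Integer,Description=\"End position of the variant\">",
    "##INFO=<ID=SVTYPE,Number=1,Type=String,Description=\"Type of structural variant\">",
    "##ALT=<ID=DEL,Description=\"Deletion\">",
    "##ALT=<ID=DUP,Description=\"Duplication\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=CN,Number=1,Type=Integer,Description=\"Copy number\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", sample_ids), collapse = "\t"))
}

#' Write variant records to a VCF file
#'
#' Emits a minimal VCF 4.2 file. Genotype records are written unphased
#' (`0/1` style); CNV records are written with a symbolic alternate allele,
#' `INFO END`/`SVTYPE` and a per-sample `CN` FORMAT field. A write-read
#' round trip through [read_vcf()] reproduces the records.
#'
#' @param records list of [variant_record]s.
#' @param path output path.
#' @param sample_ids sample column order; defaults to the sample names of
#'   the first record.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(records, path, sample_ids = NULL) {
  if (is.null(sample_ids)) {
    if (length(records) == 0) {
      stop_with("trioscan_validation_error",
                "sample_ids required to write an empty VCF")
    }
    r1 <- records[[1]]
    sample_ids <- names(if (is.null(r1$genotypes)) r1$copy_numbers else r1$genotypes)
  }
  lines <- vapply(records, function(r) {
    if (r$variant_class %in% c("cnv_deletion", "cnv_duplication")) {
      sv <- if (r$variant_class == "cnv_deletion") "DEL" else "DUP"
      cn <- r$copy_numbers[sample_ids]
      paste(c(r$chrom, r$pos, ".", r$ref, paste0("<", sv, ">"), ".", r$filter,
              sprintf("END=%d;SVTYPE=%s", r$end, sv), "CN",
              ifelse(is.na(cn), ".", as.character(cn))), collapse = "\t")
    } else {
      paste(c(r$chrom, r$pos, ".", r$ref, r$alt, ".", r$filter, ".", "GT",
              unname(.CALL_TO_GT[r$genotypes[sample_ids]])), collapse = "\t")
    }
  }, character(1))
  writeLines(c(vcf_header(sample_ids), lines), path)
  invisible(path)
}

#' Read VEP-style consequence annotations
#'
#' Tab-separated table with columns `chrom`, `pos`, `ref`, `alt`,
#' `gene_id`, `consequence` (comma-separated Sequence Ontology terms).
#' One row per (variant, gene) pair; unknown terms are kept verbatim.
#'
#' @param path path to the TSV file.
#' @return data.frame with the key columns, the raw `consequence` string
#'   and a `consequence_terms` list column of term vectors.
#' @export
read_consequences <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = c(pos = "integer"))
  needed <- c("chrom", "pos", "ref", "alt", "gene_id", "consequence")
  if (!all(needed %in% names(df))) {
    stop_with("trioscan_schema_error", "annotation table missing columns: %s",
              paste(setdiff(needed, names(df)), collapse = ", "))
  }
  df <- df[, needed]
  df$consequence <- as.character(df$consequence)
  df$consequence_terms <- strsplit(df$consequence, ",", fixed = TRUE)
  if (any(lengths(df$consequence_terms) == 0)) {
    stop_with("trioscan_validation_error", "annotation with empty consequence terms")
  }
  df
}

#' @rdname read_consequences
#' @param annotations data.frame as returned by [read_consequences()].
#' @export
write_consequences <- function(annotations, path) {
  df <- annotations[, c("chrom", "pos", "ref", "alt", "gene_id", "consequence")]
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
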