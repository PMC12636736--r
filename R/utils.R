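#' Round half away from zero
#'
#' Commercial rounding used for reported percentages: ties go away from zero
#' rather than to the even digit as in [base::round()].
#'
#' @param x numeric vector.
#' @param digits integer; decimal places to keep.
#' @return numeric vector rounded to `digits` places.
#' @keywords internal
round_half_away <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

#' Normalize chromosome names
#'
#' Harmonizes the "chr1" vs "1" dialects. The default keeps names verbatim;
#' `style = "strip"` removes a leading "chr", `style = "add"` prepends it
#' where absent.
#'
#' @param chrom character vector of chromosome names.
#' @param style one of "verbatim", "strip", "add".
#' @return character vector of normalized names.
#' @export
normalize_chrom <- function(chrom, style = c("verbatim", "strip", "add")) {
  style <- match.arg(style)
  switch(style,
    verbatim = chrom,
    strip = sub("^chr", "", chrom),
    add = ifelse(grepl("^chr", chrom), chrom, paste0("chr", chrom))
  )
}

# Autosome test: anything not X/Y/M/MT after stripping a "chr" prefix.
is_autosome <- function(chrom) {
  !(toupper(sub("^chr", "", chrom)) %in% c("X", "Y", "M", "MT"))
}

# Canonical string key for a variant record.
variant_key <- function(rec) {
  if (rec$variant_class %in% c("cnv_deletion", "cnv_duplication")) {
    type <- if (rec$variant_class == "cnv_deletion") "DEL" else "DUP"
    paste0(rec$chrom, ":", rec$pos, "-", rec$end, ":", type)
  } else {
    paste(rec$chrom, rec$pos, rec$ref, rec$alt, sep = ":")
  }
}

stop_with <- function(class, fmt, ...) {
  stop(structure(
    class = c(class, "trioscan_error", "error", "condition"),
    list(message = sprintf(fmt, ...), call = sys.call(-1))
  ))
}
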