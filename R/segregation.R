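#' Check autosomal recessive segregation in one family
#'
#' Evaluates, for every pedigree member with a non-missing genotype call,
#' the recessive-model rules: affected individuals must be homozygous for
#' the alternate allele; unaffected individuals must not be; and a parent
#' of any affected member is an obligate carrier and must carry at least
#' one alternate allele (het or hom-alt), regardless of the parent's own
#' phenotype. Individuals with unknown phenotype contribute no
#' phenotype-based rule. Members with missing calls (or absent from the
#' table) are uninformative but can still make their parents obligate
#' carriers through their phenotype.
#'
#' @param ped a [pedigree].
#' @param calls named character vector (or two-column data.frame
#'   `individual_id`, `call`) mapping member ids to genotype calls
#'   (`"hom_ref"`, `"het"`, `"hom_alt"`, `"missing"`). Every id must be a
#'   pedigree member; members absent from `calls` count as missing.
#' @return list of class `segregation_verdict`: `status` (`"consistent"`,
#'   `"inconsistent"` or `"inconclusive"`), `violations` (data.frame with
#'   `individual_id`, `observed`, `allowed`), and `n_informative` (count of
#'   individuals with a non-missing call subject to at least one rule).
#'   Consistent requires zero violations and at least one informative
#'   individual; a family where no rule could be evaluated is inconclusive.
#' @export
check_recessive_segregation <- function(ped, calls) {
  if (is.data.frame(calls)) {
    calls <- stats::setNames(calls$call, calls$individual_id)
  }
  m <- ped$members
  unknown <- setdiff(names(calls), m$individual_id)
  if (length(unknown) > 0) {
    stop_with("trioscan_key_error",
              "individual(s) not in family '%s': %s", ped$family_id,
              paste(unknown, collapse = ", "))
  }
  stopifnot(all(calls %in% c("hom_ref", "het", "hom_alt", "missing")))
  affected_ids <- m$individual_id[m$phenotype == "affected"]
  obligate <- unique(stats::na.omit(c(
    m$father_id[m$individual_id %in% affected_ids],
    m$mother_id[m$individual_id %in% affected_ids]
  )))
  violations <- data.frame(individual_id = character(0),
                           observed = character(0), allowed = character(0),
                           stringsAsFactors = FALSE)
  n_informative <- 0L
  for (i in seq_len(nrow(m))) {
    id <- m$individual_id[i]
    obs <- if (id %in% names(calls)) calls[[id]] else "missing"
    if (obs == "missing") next
    allowed <- c("hom_ref", "het", "hom_alt")
    ruled <- FALSE
    if (m$phenotype[i] == "affected") {
      allowed <- intersect(allowed, "hom_alt"); ruled <- TRUE
    } else if (m$phenotype[i] == "unaffected") {
      allowed <- setdiff(allowed, "hom_alt"); ruled <- TRUE
    }
    if (id %in% obligate) {
      allowed <- intersect(allowed, c("het", "hom_alt")); ruled <- TRUE
    }
    if (!ruled) next
    n_informative <- n_informative + 1L
    if (!(obs %in% allowed)) {
      violations <- rbind(violations, data.frame(
        individual_id = id, observed = obs,
        allowed = paste(allowed, collapse = ","), stringsAsFactors = FALSE))
    }
  }
  status <- if (nrow(violations) > 0) {
    "inconsistent"
  } else if (n_informative >= 1L) {
    "consistent"
  } else {
    "inconclusive"
  }
  structure(list(status = status, violations = violations,
                 n_informative = n_informative),
            class = "segregation_verdict")
}

#' @export
print.segregation_verdict <- function(x, ...) {
  cat(sprintf("<segregation_verdict> %s (%d informative, %d violation%s)\n",
              x$status, x$n_informative, nrow(x$violations),
              if (nrow(x$violations) == 1) "" else "s"))
  invisible(x)
}

#' Evaluate a candidate variant across multiple families
#'
#' Exclusion is decisive: one family whose genotypes contradict the
#' recessive model excludes the candidate. Support is provisional: it
#' requires every evaluated family to be consistent and at least one
#' family with three or more informative genotypes. Anything else is
#' inconclusive (e.g. a family whose calls were all missing).
#'
#' @param peds list of [pedigree] objects.
#' @param tables list of call tables (as accepted by
#'   [check_recessive_segregation()]), parallel to `peds`.
#' @return list of class `candidate_decision`: `decision` (`"supported"`,
#'   `"excluded"` or `"inconclusive"`) and `verdicts` (per-family
#'   `segregation_verdict`s, named by family id).
#' @export
evaluate_candidate <- function(peds, tables) {
  if (length(peds) == 0) {
    stop_with("trioscan_validation_error", "at least one family required")
  }
  stopifnot(length(peds) == length(tables))
  verdicts <- Map(check_recessive_segregation, peds, tables)
  names(verdicts) <- vapply(peds, function(p) p$family_id, character(1))
  statuses <- vapply(verdicts, function(v) v$status, character(1))
  informative <- vapply(verdicts, function(v) v$n_informative, integer(1))
  decision <- if (any(statuses == "inconsistent")) {
    "excluded"
  } else if (all(statuses == "consistent") && any(informative >= 3L)) {
    "supported"
  } else {
    "inconclusive"
  }
  structure(list(decision = decision, verdicts = verdicts),
            class = "candidate_decision")
}

#' @export
print.candidate_decision <- function(x, ...) {
  cat(sprintf("<candidate_decision> %s (%d famil%s)\n", x$decision,
              length(x$verdicts), if (length(x$verdicts) == 1) "y" else "ies"))
  invisible(x)
}

#' Read or write a per-family genotype call table
#'
#' Two-column TSV (`individual_id`, `call`) holding Sanger-style genotype
#' calls for one variant in one family.
#'
#' @param path path to the TSV file.
#' @return data.frame with columns `individual_id` and `call`.
#' @export
read_genotype_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("individual_id", "call") %in% names(df))) {
    stop_with("trioscan_schema_error",
              "genotype table needs columns individual_id, call")
  }
  df[, c("individual_id", "call")]
}

#' @rdname read_genotype_table
#' @param table data.frame with columns `individual_id` and `call`.
#' @export
write_genotype_table <- function(table, path) {
  utils::write.table(table[, c("individual_id", "call")], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
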