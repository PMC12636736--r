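#' Pedigree objects
#'
#' A pedigree is a family identifier plus an ordered member table. Parent
#' links must point at members of the same pedigree (or be `NA` for
#' founders), must not form cycles, and at least one founder must exist.
#'
#' @param family_id single character family identifier.
#' @param members data.frame with columns `individual_id`, `father_id`,
#'   `mother_id` (`NA` for none), `sex` (`"male"`, `"female"`, `"unknown"`)
#'   and `phenotype` (`"affected"`, `"unaffected"`, `"unknown"`).
#' @return an object of class `pedigree`.
#' @examples
#' ped <- pedigree("F1", data.frame(
#'   individual_id = c("dad", "mom", "kid"),
#'   father_id = c(NA, NA, "dad"), mother_id = c(NA, NA, "mom"),
#'   sex = c("male", "female", "male"),
#'   phenotype = c("unaffected", "unaffected", "affected")
#' ))
#' @export
pedigree <- function(family_id, members) {
  stopifnot(is.character(family_id), length(family_id) == 1, nzchar(family_id))
  members <- as.data.frame(members, stringsAsFactors = FALSE)
  needed <- c("individual_id", "father_id", "mother_id", "sex", "phenotype")
  if (!all(needed %in% names(members))) {
    stop_with("trioscan_validation_error", "pedigree members need columns: %s",
              paste(setdiff(needed, names(members)), collapse = ", "))
  }
  members <- members[, needed]
  ids <- members$individual_id
  if (any(!nzchar(ids) | is.na(ids))) {
    stop_with("trioscan_validation_error", "empty individual id in family '%s'", family_id)
  }
  if (anyDuplicated(ids)) {
    stop_with("trioscan_validation_error",
              "duplicate individual id '%s' in family '%s'",
              ids[duplicated(ids)][1], family_id)
  }
  for (col in c("father_id", "mother_id")) {
    bad <- !is.na(members[[col]]) & !(members[[col]] %in% ids)
    if (any(bad)) {
      stop_with("trioscan_validation_error",
                "%s '%s' of '%s' is not a member of family '%s'",
                col, members[[col]][bad][1], ids[bad][1], family_id)
    }
  }
  stopifnot(all(members$sex %in% c("male", "female", "unknown")),
            all(members$phenotype %in% c("affected", "unaffected", "unknown")))
  founders <- is.na(members$father_id) & is.na(members$mother_id)
  if (!any(founders)) {
    stop_with("trioscan_validation_error", "family '%s' has no founder", family_id)
  }
  # cycle check: repeatedly peel individuals whose recorded parents are peeled
  remaining <- ids
  repeat {
    peelable <- vapply(remaining, function(id) {
      r <- members[match(id, ids), ]
      ok <- function(p) is.na(p) || !(p %in% remaining)
      ok(r$father_id) && ok(r$mother_id)
    }, logical(1))
    if (!any(peelable)) {
      stop_with("trioscan_validation_error",
                "parent links in family '%s' contain a cycle", family_id)
    }
    remaining <- remaining[!peelable]
    if (length(remaining) == 0) break
  }
  structure(list(family_id = family_id, members = members), class = "pedigree")
}

#' @export
print.pedigree <- function(x, ...) {
  cat(sprintf("<pedigree> family %s: %d members (%d affected, %d founders)\n",
              x$family_id, nrow(x$members),
              sum(x$members$phenotype == "affected"),
              sum(is.na(x$members$father_id) & is.na(x$members$mother_id))))
  invisible(x)
}

.SEX_FROM_CODE <- c("1" = "male", "2" = "female")
.SEX_TO_CODE <- c(male = "1", female = "2", unknown = "0")
.PHENO_TO_CODE <- c(affected = "2", unaffected = "1", unknown = "0")

#' Read pedigrees from a PED (linkage format) file
#'
#' Parses the common 6-column dialect: family id, individual id, father id,
#' mother id, sex (1 = male, 2 = female, other = unknown) and phenotype
#' (2 = affected, 1 = unaffected, 0 or -9 = unknown). Parent id "0" means no
#' recorded parent. Fields may be separated by tabs or spaces; extra columns
#' are ignored with a warning.
#'
#' @param path path to a PED file.
#' @return named list of [pedigree] objects, one per family id, in order of
#'   first appearance. An empty file yields an empty list.
#' @seealso [write_ped()]
#' @export
read_ped <- function(path) {
  if (!file.exists(path)) {
    stop_with("trioscan_io_error", "PED file not found: %s", path)
  }
  lines <- readLines(path, warn = FALSE)
  keep <- nzchar(trimws(lines))
  lines <- lines[keep]
  if (length(lines) == 0) return(list())
  lineno <- which(keep)
  fields <- strsplit(trimws(lines), "[ \t]+")
  ncols <- lengths(fields)
  if (any(ncols < 6)) {
    i <- which(ncols < 6)[1]
    stop_with("trioscan_parse_error",
              "PED line %d has %d fields; 6 required", lineno[i], ncols[i])
  }
  if (any(ncols > 6)) {
    warning(sprintf("PED file %s: columns beyond 6 ignored", path))
  }
  m <- do.call(rbind, lapply(fields, `[`, 1:6))
  df <- data.frame(
    family_id = m[, 1],
    individual_id = m[, 2],
    father_id = ifelse(m[, 3] == "0", NA_character_, m[, 3]),
    mother_id = ifelse(m[, 4] == "0", NA_character_, m[, 4]),
    sex = unname(ifelse(m[, 5] %in% names(.SEX_FROM_CODE),
                        .SEX_FROM_CODE[m[, 5]], "unknown")),
    phenotype = ifelse(m[, 6] == "2", "affected",
                ifelse(m[, 6] == "1", "unaffected",
                ifelse(m[, 6] %in% c("0", "-9"), "unknown", NA))),
    stringsAsFactors = FALSE
  )
  if (anyNA(df$phenotype)) {
    i <- which(is.na(df$phenotype))[1]
    stop_with("trioscan_parse_error",
              "PED line %d: unrecognized phenotype code '%s'", lineno[i], m[i, 6])
  }
  fams <- unique(df$family_id)
  out <- lapply(fams, function(f) {
    pedigree(f, df[df$family_id == f, -1])
  })
  names(out) <- fams
  out
}

#' Write pedigrees to a PED file
#'
#' Tab-delimited 6-column linkage format; inverse of [read_ped()].
#'
#' @param peds a [pedigree] or list of pedigrees.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_ped <- function(peds, path) {
  if (inherits(peds, "pedigree")) peds <- list(peds)
  rows <- unlist(lapply(peds, function(p) {
    m <- p$members
    paste(p$family_id, m$individual_id,
          ifelse(is.na(m$father_id), "0", m$father_id),
          ifelse(is.na(m$mother_id), "0", m$mother_id),
          .SEX_TO_CODE[m$sex], .PHENO_TO_CODE[m$phenotype],
          sep = "\t")
  }), use.names = FALSE)
  writeLines(rows, path)
  invisible(path)
}

ped_member <- function(ped, id) {
  i <- match(id, ped$members$individual_id)
  if (is.na(i)) {
    stop_with("trioscan_lookup_error",
              "individual '%s' not in family '%s'", id, ped$family_id)
  }
  as.list(ped$members[i, ])
}

#' Extract a father-mother-proband trio
#'
#' @param ped a [pedigree].
#' @param proband_id individual id of the proband; both parents must be
#'   recorded and present in the pedigree.
#' @return list with elements `father`, `mother`, `proband`, each a one-row
#'   list of member fields.
#' @export
extract_trio <- function(ped, proband_id) {
  pb <- ped_member(ped, proband_id)
  if (is.na(pb$father_id) || is.na(pb$mother_id)) {
    stop_with("trioscan_trio_error",
              "trio undefined: '%s' lacks two recorded parents", proband_id)
  }
  list(father = ped_member(ped, pb$father_id),
       mother = ped_member(ped, pb$mother_id),
       proband = pb)
}

#' Full siblings of an individual
#'
#' Members sharing both recorded parents with the individual, excluding the
#' individual itself. Founders and half-siblings yield no entries.
#'
#' @inheritParams extract_trio
#' @param individual_id member whose siblings are sought.
#' @return data.frame of sibling member rows (possibly empty).
#' @export
siblings_of <- function(ped, individual_id) {
  self <- ped_member(ped, individual_id)
  m <- ped$members
  if (is.na(self$father_id) || is.na(self$mother_id)) {
    return(m[0, ])
  }
  sib <- !is.na(m$father_id) & !is.na(m$mother_id) &
    m$father_id == self$father_id & m$mother_id == self$mother_id &
    m$individual_id != individual_id
  m[sib, ]
}
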