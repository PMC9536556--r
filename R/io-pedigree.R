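#' Read a PED-like pedigree file
#'
#' Tab-delimited pedigree text in the usual PLINK order
#' `family_id, id, father_id, mother_id, sex, phenotype`, with an optional
#' seventh column carrying a monozygotic-twin group label (`mz_group`).
#' Sex is coded 1 = male, 2 = female, 0 = unknown; the phenotype column is
#' interpreted as affected when equal to 2 (1/0/-9 = unaffected). `0` marks
#' an unknown (founder) parent; empty, `0` or `.` in the twin column means
#' no twin group.
#'
#' @param path path to the pedigree file (no header line).
#' @return a data.frame of class `pedigree_table` with columns `id`,
#'   `family_id`, `father_id`, `mother_id`, `sex`
#'   (`male`/`female`/`unknown`), `affected` (logical), `mz_group`
#'   (`NA` when not a twin) and `founder` (logical; both parents unknown).
#' @export
read_pedigree <- function(path) {
  raw <- read.delim(path, header = FALSE, stringsAsFactors = FALSE,
                    colClasses = "character", comment.char = "#")
  if (ncol(raw) < 6) {
    stop("pedigree file must have >= 6 tab-delimited columns, found ", ncol(raw))
  }
  ped <- data.frame(
    id = raw[[2]], family_id = raw[[1]],
    father_id = raw[[3]], mother_id = raw[[4]],
    sex = c(`0` = "unknown", `1` = "male", `2` = "female")[raw[[5]]],
    affected = raw[[6]] == "2",
    mz_group = if (ncol(raw) >= 7) raw[[7]] else NA_character_,
    stringsAsFactors = FALSE
  )
  ped$mz_group[ped$mz_group %in% c("", "0", ".")] <- NA_character_
  if (anyNA(ped$sex)) stop("invalid sex code in pedigree (expect 0/1/2)")
  ped$founder <- ped$father_id == "0" & ped$mother_id == "0"
  validate_pedigree(ped)
  class(ped) <- c("pedigree_table", "data.frame")
  ped
}

#' Validate pedigree structure
#'
#' Checks that parent references resolve within the family (or are the `0`
#' founder marker) and that members of a monozygotic-twin group share both
#' parents and sex. Called by [read_pedigree()]; exported so programmatically
#' built pedigrees can be checked too.
#'
#' @param ped a pedigree data.frame as returned by [read_pedigree()].
#' @return `ped`, invisibly; errors on violation.
#' @export
validate_pedigree <- function(ped) {
  if (anyDuplicated(ped$id)) {
    stop("duplicate individual id(s): ",
         paste(unique(ped$id[duplicated(ped$id)]), collapse = ", "))
  }
  for (fam in unique(ped$family_id)) {
    fp <- ped[ped$family_id == fam, ]
    for (col in c("father_id", "mother_id")) {
      bad <- setdiff(fp[[col]], c("0", fp$id))
      if (length(bad)) {
        stop("unknown parent id(s) in family ", fam, ": ",
             paste(bad, collapse = ", "))
      }
    }
  }
  for (grp in unique(ped$mz_group[!is.na(ped$mz_group)])) {
    tw <- ped[!is.na(ped$mz_group) & ped$mz_group == grp, ]
    if (length(unique(tw$father_id)) > 1 || length(unique(tw$mother_id)) > 1) {
      stop("monozygotic twin group '", grp, "' members have different parents")
    }
    if (length(unique(tw$sex)) > 1) {
      stop("monozygotic twin group '", grp, "' members have different sexes")
    }
  }
  invisible(ped)
}

#' Write a pedigree table in PED-like format
#'
#' Inverse of [read_pedigree()] (field-by-field round trip).
#'
#' @param ped a pedigree data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_pedigree <- function(ped, path) {
  sex <- c(unknown = "0", male = "1", female = "2")[ped$sex]
  out <- cbind(ped$family_id, ped$id, ped$father_id, ped$mother_id, sex,
               ifelse(ped$affected, "2", "1"),
               ifelse(is.na(ped$mz_group), "0", ped$mz_group))
  writeLines(apply(out, 1, paste, collapse = "\t"), path)
  invisible(path)
}
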