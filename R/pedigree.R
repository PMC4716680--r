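#' Construct a pedigree table
#'
#' A pedigree is a data frame with one row per individual. Affection status
#' is "yes"/"no"/"unknown"; `married_in` is derived, never supplied: an
#' individual with no recorded parents who co-parents a child with another
#' pedigree member entered the family by marriage and, when unaffected,
#' carries no disease haplotype -- the property the phase filter exploits.
#'
#' @param fam family identifier(s)
#' @param id individual identifiers (unique)
#' @param father,mother parental identifiers, `NA` if unknown/absent
#' @param sex "male"/"female"/"unknown" (or 1/2/0 PED codes)
#' @param affected "yes"/"no"/"unknown"
#' @param genotyped logical: was a DNA sample available
#' @return a data frame of class `pedigree` with a derived `married_in`
#'   column
#' @export
pedigree <- function(fam, id, father, mother, sex, affected, genotyped = TRUE) {
  n <- length(id)
  sex <- as.character(sex)
  sex[sex == "1"] <- "male"
  sex[sex == "2"] <- "female"
  sex[sex %in% c("0", "-9")] <- "unknown"
  ped <- data.frame(
    fam = rep_len(as.character(fam), n),
    id = as.character(id),
    father = as.character(father),
    mother = as.character(mother),
    sex = sex,
    affected = as.character(affected),
    genotyped = rep_len(as.logical(genotyped), n),
    stringsAsFactors = FALSE
  )
  ped$father[ped$father %in% c("0", "")] <- NA_character_
  ped$mother[ped$mother %in% c("0", "")] <- NA_character_
  if (anyDuplicated(ped$id)) stop("duplicate individual ids in pedigree")
  if (!all(ped$affected %in% c("yes", "no", "unknown"))) {
    stop("affected must be yes/no/unknown")
  }
  for (col in c("father", "mother")) {
    dangling <- setdiff(stats::na.omit(ped[[col]]), ped$id)
    if (length(dangling) > 0) {
      stop("pedigree ", col, " id(s) not present as individuals: ",
           paste(dangling, collapse = ", "))
    }
  }
  check_pedigree_acyclic(ped)
  parents <- unique(c(stats::na.omit(ped$father), stats::na.omit(ped$mother)))
  ped$married_in <- is.na(ped$father) & is.na(ped$mother) &
    ped$id %in% parents & has_coparent(ped)
  class(ped) <- c("pedigree", "data.frame")
  ped
}

has_coparent <- function(ped) {
  vapply(ped$id, function(i) {
    kids <- ped$father %in% i | ped$mother %in% i
    any(kids & !is.na(ped$father) & !is.na(ped$mother))
  }, TRUE)
}

check_pedigree_acyclic <- function(ped) {
  # depth-first walk up the parent graph; a revisit on the current path is
  # a cycle (an individual who is their own ancestor)
  parent_of <- function(i) {
    r <- ped[ped$id == i, ]
    stats::na.omit(c(r$father, r$mother))
  }
  state <- new.env(parent = emptyenv())
  visit <- function(i, path) {
    if (i %in% path) stop("pedigree parent graph contains a cycle at ", i)
    if (!is.null(state[[i]])) return(invisible())
    for (p in parent_of(i)) visit(p, c(path, i))
    state[[i]] <- TRUE
  }
  for (i in ped$id) visit(i, character())
  invisible(ped)
}

#' Read a PED file
#'
#' Standard 6-column PED dialect (family, id, father, mother, sex,
#' phenotype) with an optional 7th column flagging whether the individual
#' was genotyped (1/0; absent means all genotyped). Phenotype 2 = affected,
#' 1 = unaffected, 0 or -9 = unknown.
#'
#' @param path PED file path
#' @return a [pedigree()]
#' @export
read_ped <- function(path) {
  tab <- utils::read.table(path, header = FALSE, stringsAsFactors = FALSE,
                           colClasses = "character")
  if (ncol(tab) < 6) stop("PED file must have at least 6 columns")
  pheno <- tab[[6]]
  affected <- ifelse(pheno == "2", "yes",
                     ifelse(pheno == "1", "no", "unknown"))
  genotyped <- if (ncol(tab) >= 7) tab[[7]] == "1" else TRUE
  pedigree(fam = tab[[1]], id = tab[[2]], father = tab[[3]],
           mother = tab[[4]], sex = tab[[5]], affected = affected,
           genotyped = genotyped)
}

#' Write a pedigree as a PED file
#'
#' Emits the 7-column dialect read by [read_ped()].
#'
#' @param ped a [pedigree()]
#' @param path output path
#' @export
write_ped <- function(ped, path) {
  sex_code <- c(male = "1", female = "2", unknown = "0")[ped$sex]
  pheno <- c(yes = "2", no = "1", unknown = "0")[ped$affected]
  lines <- sprintf("%s\t%s\t%s\t%s\t%s\t%s\t%d",
                   ped$fam, ped$id,
                   ifelse(is.na(ped$father), "0", ped$father),
                   ifelse(is.na(ped$mother), "0", ped$mother),
                   sex_code, pheno, as.integer(ped$genotyped))
  writeLines(lines, path)
  invisible(path)
}

affected_ids <- function(ped, genotyped_only = TRUE) {
  sel <- ped$affected == "yes"
  if (genotyped_only) sel <- sel & ped$genotyped
  ped$id[sel]
}

unaffected_ids <- function(ped, genotyped_only = TRUE) {
  sel <- ped$affected == "no"
  if (genotyped_only) sel <- sel & ped$genotyped
  ped$id[sel]
}
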