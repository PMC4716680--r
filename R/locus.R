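#' Read a marker genotype table
#'
#' TSV with columns `marker`, `chrom`, `pos`, then one column per sample
#' holding unordered allele pairs written `a/b`. Microsatellite and SNP
#' markers are treated identically as multi-allelic markers.
#'
#' @param path TSV path
#' @return data frame sorted by position
#' @export
read_markers <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE, check.names = FALSE)
  stopifnot(all(c("marker", "chrom", "pos") %in% names(tab)))
  tab <- tab[order(tab$pos), , drop = FALSE]
  if (any(duplicated(tab$pos))) stop("marker positions must be strictly increasing")
  rownames(tab) <- NULL
  tab
}

#' Write a marker genotype table
#' @param markers data frame as produced by [read_markers()]
#' @param path output path
#' @export
write_markers <- function(markers, path) {
  utils::write.table(markers, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

marker_alleles <- function(gt) strsplit(gt, "/", fixed = TRUE)[[1]]

#' Infer the shared disease haplotype across affected individuals
#'
#' For each marker the candidate disease allele is the allele compatible
#' with carriage by every affected individual; where the affected's parents
#' are genotyped, an allele the transmitting (affected) parent does not
#' carry is removed from the candidates. Markers where several candidates
#' remain are flagged uninformative and contribute no breakpoint evidence;
#' markers where no allele is shared by all affecteds mark obligate
#' recombination.
#'
#' @param markers marker genotype table ([read_markers()] layout); sample
#'   columns must include all genotyped affecteds
#' @param ped a [pedigree()]
#' @return list with `assignments` (data frame marker/pos/status/
#'   disease_allele) and `carries` (logical matrix affected x marker;
#'   does this affected carry the candidate disease allele)
#' @export
infer_disease_haplotype <- function(markers, ped) {
  affecteds <- intersect(affected_ids(ped), names(markers))
  if (length(affecteds) < 2) stop("need at least two genotyped affecteds")
  n <- nrow(markers)
  status <- character(n)
  allele <- rep(NA_character_, n)
  carries <- matrix(NA, nrow = length(affecteds), ncol = n,
                    dimnames = list(affecteds, markers$marker))
  for (j in seq_len(n)) {
    sets <- lapply(affecteds, function(s) marker_alleles(markers[[s]][j]))
    names(sets) <- affecteds
    shared <- Reduce(intersect, sets)
    if (length(shared) == 0) {
      status[j] <- "recombinant"
      # most widely carried allele stands in as the disease allele so that
      # the individuals lacking it can be reported as the recombinants
      all_alleles <- unlist(sets)
      tab <- sort(table(all_alleles), decreasing = TRUE)
      allele[j] <- names(tab)[1]
    } else {
      cand <- shared
      if (length(cand) > 1) {
        cand <- Filter(function(a) {
          transmissible_by_all(a, affecteds, markers, ped, j)
        }, cand)
        if (length(cand) == 0) cand <- shared  # over-pruned; stay ambiguous
      }
      if (length(cand) == 1) {
        status[j] <- "shared"
        allele[j] <- cand
      } else {
        status[j] <- "uninformative"
      }
    }
    carries[, j] <- vapply(affecteds, function(s) allele[j] %in% sets[[s]], TRUE)
  }
  if (all(status == "recombinant")) {
    stop("no shared haplotype: every marker has an empty shared-allele set")
  }
  list(assignments = data.frame(marker = markers$marker, pos = markers$pos,
                                status = status, disease_allele = allele,
                                stringsAsFactors = FALSE),
       carries = carries)
}

# can allele `a` have been transmitted to every affected whose parents are
# both genotyped? the affected parent must carry it (full penetrance: the
# disease haplotype travels through the affected lineage)
transmissible_by_all <- function(a, affecteds, markers, ped, j) {
  for (s in affecteds) {
    row <- ped[ped$id == s, ]
    if (nrow(row) == 0 || is.na(row$father) || is.na(row$mother)) next
    parents <- ped[ped$id %in% c(row$father, row$mother), ]
    aff_parent <- parents$id[parents$affected == "yes"]
    if (length(aff_parent) != 1 || !aff_parent %in% names(markers)) next
    if (!a %in% marker_alleles(markers[[aff_parent]][j])) return(FALSE)
  }
  TRUE
}

#' Refine the disease interval from haplotype sharing
#'
#' Finds the maximal contiguous run of markers uninterrupted by obligate
#' recombination and reports the closed interval spanned by the outermost
#' shared markers of that run (uninformative markers inside the run neither
#' extend nor break it). With no recombinant marker the refined interval is
#' the full span of shared evidence. Deterministic: ties between runs go to
#' the run with more shared markers, then the wider, then the leftmost.
#'
#' @param haplotype result of [infer_disease_haplotype()]
#' @param chrom chromosome of the markers
#' @return list of class `shared_haplotype_result`: `interval`, per-affected
#'   `breakpoint_evidence`, `markers_informative`
#' @export
refine_interval <- function(haplotype, chrom = "chr20") {
  a <- haplotype$assignments
  if (!any(a$status == "shared")) stop("zero shared markers; cannot refine")
  # segment markers into runs separated by recombinant markers
  run_id <- cumsum(a$status == "recombinant")
  best <- NULL
  for (r in unique(run_id[a$status != "recombinant"])) {
    idx <- which(run_id == r & a$status != "recombinant")
    sh <- idx[a$status[idx] == "shared"]
    if (length(sh) == 0) next
    cand <- list(first = min(sh), last = max(sh), n_shared = length(sh),
                 width = a$pos[max(sh)] - a$pos[min(sh)])
    if (is.null(best) || cand$n_shared > best$n_shared ||
        (cand$n_shared == best$n_shared && cand$width > best$width)) {
      best <- cand
    }
  }
  refined <- interval(chrom, a$pos[best$first], a$pos[best$last])
  evidence <- breakpoint_evidence(haplotype, best)
  structure(list(interval = refined,
                 breakpoint_evidence = evidence,
                 markers_informative = sum(a$status == "shared")),
            class = "shared_haplotype_result")
}

breakpoint_evidence <- function(haplotype, best) {
  a <- haplotype$assignments
  rec <- which(a$status == "recombinant")
  left <- rec[rec < best$first]
  right <- rec[rec > best$last]
  ev <- list()
  for (j in c(if (length(left)) max(left), if (length(right)) min(right))) {
    lost <- rownames(haplotype$carries)[!haplotype$carries[, j]]
    ev[[a$marker[j]]] <- list(marker = a$marker[j], pos = a$pos[j],
                              recombinant_individuals = lost)
  }
  ev
}

#' @export
print.shared_haplotype_result <- function(x, ...) {
  cat("Refined disease interval: ")
  print(x$interval)
  cat(sprintf("Informative shared markers: %d\n", x$markers_informative))
  for (ev in x$breakpoint_evidence) {
    cat(sprintf("  obligate recombination at %s (%s): %s\n", ev$marker,
                format(ev$pos, big.mark = ","),
                paste(ev$recombinant_individuals, collapse = ", ")))
  }
  invisible(x)
}
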