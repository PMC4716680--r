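#' Configuration for the variant filter cascade
#'
#' Captures every tunable of the prioritization stage. The frequency filter
#' applies only to `maf_panels`; further panels may be carried for
#' annotation (`annotation_panels`) without influencing filtering, because
#' reference panels differ enough in ancestry composition that a single
#' union rule over all of them discards true rare founder variants.
#'
#' @param locus [interval()] restricting the search space (the linked locus)
#' @param required_het samples that must be heterozygous carriers (the
#'   affected, dominantly inherited genotype pattern)
#' @param excluded_carrier samples that must not carry the alternate allele
#'   (unaffected relatives / control genomes)
#' @param maf_threshold fail a variant whose frequency exceeds this in any
#'   `maf_panels` member (default 0.005)
#' @param maf_panels panels the threshold applies to (default 1000G + ExAC)
#' @param annotation_panels panels reported but never filtered on
#' @param phase_parent optional married-in unaffected parent whose carried
#'   alleles phase a child's variants onto the unaffected haplotype
#' @param exonic_only apply a consequence filter after the genotype filters
#' @param consequence_keep annotation classes kept in exonic mode
#'   (default "missense", i.e. rare non-synonymous coding)
#' @param deep_intronic_distance bp threshold for deep-intronic calls
#' @return list of class `cascade_config`
#' @export
cascade_config <- function(locus, required_het, excluded_carrier = character(),
                           maf_threshold = 0.005,
                           maf_panels = c("1000G", "ExAC"),
                           annotation_panels = c("UK10K", "GoNL", "UCL"),
                           phase_parent = NULL, exonic_only = FALSE,
                           consequence_keep = "missense",
                           deep_intronic_distance = 100) {
  stopifnot(inherits(locus, "interval"),
            maf_threshold > 0, maf_threshold < 1,
            length(required_het) >= 1)
  if (length(intersect(required_het, excluded_carrier)) > 0) {
    stop("required_het and excluded_carrier overlap")
  }
  structure(list(locus = locus, required_het = required_het,
                 excluded_carrier = excluded_carrier,
                 maf_threshold = maf_threshold, maf_panels = maf_panels,
                 annotation_panels = annotation_panels,
                 phase_parent = phase_parent, exonic_only = exonic_only,
                 consequence_keep = consequence_keep,
                 deep_intronic_distance = deep_intronic_distance),
            class = "cascade_config")
}

#' Allele frequency of a variant in one reference panel
#'
#' @param variant one-row `variant_table`
#' @param panel panel name
#' @return allele_count / allele_number, or `NA` when the variant was not
#'   identified in that panel
#' @export
compute_maf <- function(variant, panel) {
  ac <- variant[[paste0("ac_", panel)]]
  an <- variant[[paste0("an_", panel)]]
  if (is.null(ac) || is.null(an) || is.na(ac) || is.na(an)) return(NA_real_)
  if (an == 0) stop("allele_number is zero for panel ", panel)
  ac / an
}

#' Reference-panel frequency filter
#'
#' Fails iff the variant's frequency exceeds the threshold in at least one
#' of the configured filter panels; "not identified" always passes.
#'
#' @param variant one-row `variant_table`
#' @param config a [cascade_config()]
#' @return list(pass, detail)
#' @export
maf_filter <- function(variant, config) {
  for (p in config$maf_panels) {
    maf <- compute_maf(variant, p)
    if (!is.na(maf) && maf > config$maf_threshold) {
      return(list(pass = FALSE,
                  detail = sprintf("MAF %.4g in %s exceeds %.3g", maf, p,
                                   config$maf_threshold)))
    }
  }
  list(pass = TRUE, detail = "rare or not identified in all filter panels")
}

#' Dominant-model genotype pattern filter
#'
#' Passes iff every required sample is heterozygous (strictly: hom-alt fails
#' the dominant model) and no excluded sample carries the alternate allele.
#' A missing call in an excluded sample passes with a warning rather than
#' silently discarding a candidate on a no-call.
#'
#' @param key variant key
#' @param genotypes a [genotype_table()]
#' @param config a [cascade_config()]
#' @return list(pass, detail)
#' @export
genotype_pattern_filter <- function(key, genotypes, config) {
  samples <- gt_samples(genotypes)
  absent <- setdiff(config$required_het, samples)
  if (length(absent) > 0) {
    stop("required sample(s) not present in genotype data: ",
         paste(absent, collapse = ", "))
  }
  for (s in config$required_het) {
    call <- gt_call(genotypes, s, key)
    if (call != "het") {
      return(list(pass = FALSE,
                  detail = sprintf("%s is %s, not het", s, call)))
    }
  }
  for (s in config$excluded_carrier) {
    call <- gt_call(genotypes, s, key)
    if (call %in% c("het", "hom_alt")) {
      return(list(pass = FALSE,
                  detail = sprintf("carried by excluded sample %s (%s)", s, call)))
    }
    if (call == "missing") {
      warning("no call for excluded sample ", s, " at ", key,
              "; treated as non-carrier")
    }
  }
  list(pass = TRUE, detail = "het in all required, absent in excluded")
}

#' Phase filter against a married-in unaffected parent
#'
#' Under full penetrance a married-in unaffected parent carries no disease
#' haplotype; any variant they carry must sit on the child's unaffected
#' haplotype and is removed. An ungenotyped parent cannot phase the variant,
#' which then passes with a warning.
#'
#' @param key variant key
#' @param genotypes a [genotype_table()]
#' @param parent sample id of the married-in unaffected parent
#' @param pedigree optional [pedigree()]; when given, the parent must be
#'   flagged married-in and unaffected
#' @return list(pass, detail)
#' @export
phase_filter_married_in <- function(key, genotypes, parent, pedigree = NULL) {
  if (!is.null(pedigree)) {
    row <- pedigree[pedigree$id == parent, ]
    if (nrow(row) == 0) stop("phase parent ", parent, " not in pedigree")
    if (!row$married_in || row$affected != "no") {
      stop("phase parent ", parent, " must be married-in and unaffected")
    }
  }
  call <- gt_call(genotypes, parent, key)
  if (call %in% c("het", "hom_alt")) {
    return(list(pass = FALSE,
                detail = sprintf("on unaffected haplotype: carried by %s (%s)",
                                 parent, call)))
  }
  if (call == "missing") {
    warning("phase parent ", parent, " not genotyped at ", key,
            "; variant cannot be phased and is kept")
    return(list(pass = TRUE, detail = "parent not genotyped; unphased, kept"))
  }
  list(pass = TRUE, detail = sprintf("absent in married-in parent %s", parent))
}

#' Run the full filter cascade
#'
#' Applies, in the order locus -> frequency -> genotype pattern ->
#' \[phase\] -> \[consequence\], every configured filter to every variant.
#' Filters are independent predicates, so the survivor set does not depend
#' on their order; the order only shapes the per-stage counters. Every
#' variant receives a complete filter trace, and
#' survivors + failures = input.
#'
#' @param variants a [variant_table()]
#' @param genotypes a [genotype_table()]
#' @param pedigree optional [pedigree()] (validates the phase parent)
#' @param config a [cascade_config()]
#' @param models list of [transcript_model()], required in exonic mode
#' @param quiet suppress per-stage counter messages
#' @return list with `survivors` (sorted by position), `trace` (data frame
#'   key/filter/outcome/detail) and `counts` (per-stage survivor counts)
#' @export
run_cascade <- function(variants, genotypes, pedigree = NULL, config,
                        models = NULL, quiet = TRUE) {
  stopifnot(inherits(config, "cascade_config"))
  if (config$exonic_only && is.null(models)) {
    stop("exonic mode requires transcript models")
  }
  keys <- variant_key(variants)
  filters <- list(
    locus = function(i) {
      inside <- variants$chrom[i] == config$locus$chrom &&
        interval_contains(config$locus, variants$pos[i], nchar(variants$ref[i]))
      list(pass = inside,
           detail = if (inside) "inside locus" else "outside locus")
    },
    frequency = function(i) maf_filter(variants[i, ], config),
    genotype_pattern = function(i) {
      genotype_pattern_filter(keys[[i]], genotypes, config)
    }
  )
  if (!is.null(config$phase_parent)) {
    filters$phase_married_in <- function(i) {
      phase_filter_married_in(keys[[i]], genotypes, config$phase_parent,
                              pedigree)
    }
  }
  if (config$exonic_only) {
    filters$consequence <- function(i) {
      ann <- annotate_variant(variants[i, ], models,
                              config$deep_intronic_distance)
      list(pass = ann$class %in% config$consequence_keep,
           detail = sprintf("class %s", ann$class))
    }
  }

  trace <- list()
  pass_mat <- matrix(NA, nrow = nrow(variants), ncol = length(filters),
                     dimnames = list(NULL, names(filters)))
  withCallingHandlers({
    for (f in names(filters)) {
      for (i in seq_len(nrow(variants))) {
        res <- filters[[f]](i)
        pass_mat[i, f] <- res$pass
        trace[[length(trace) + 1]] <- data.frame(
          key = keys[[i]], filter = f,
          outcome = if (res$pass) "pass" else "fail",
          detail = res$detail, stringsAsFactors = FALSE)
      }
    }
  }, warning = function(w) {
    if (!quiet) message("cascade note: ", conditionMessage(w))
    invokeRestart("muffleWarning")
  })

  surviving <- rowSums(!pass_mat) == 0
  counts <- integer(length(filters))
  names(counts) <- names(filters)
  alive <- rep(TRUE, nrow(variants))
  for (f in names(filters)) {
    alive <- alive & pass_mat[, f]
    counts[[f]] <- sum(alive)
    if (!quiet) message(sprintf("after %-18s %d variants remain", f, sum(alive)))
  }
  survivors <- variants[surviving, , drop = FALSE]
  survivors <- survivors[order(survivors$pos), , drop = FALSE]
  rownames(survivors) <- NULL
  attr(survivors, "panels") <- variant_panels(variants)
  class(survivors) <- class(variants)
  list(survivors = survivors,
       trace = do.call(rbind, trace),
       counts = counts)
}

#' Variants overlapping regulatory intervals
#'
#' Returns the subset of variants whose reference span intersects (closed
#' intervals, terminal bases included) at least one regulatory feature.
#'
#' @param variants a [variant_table()]
#' @param regulatory list of [interval()] (e.g. read from a BED of
#'   regulatory features)
#' @return the overlapping subset of `variants`
#' @export
regulatory_overlap <- function(variants, regulatory) {
  if (length(regulatory) == 0 || nrow(variants) == 0) {
    return(variants[integer(0), , drop = FALSE])
  }
  vr <- GenomicRanges::GRanges(
    seqnames = variants$chrom,
    ranges = IRanges::IRanges(start = variants$pos,
                              end = variants$pos + nchar(variants$ref) - 1))
  hits <- GenomicRanges::findOverlaps(vr, as_granges(regulatory))
  out <- variants[sort(unique(S4Vectors::queryHits(hits))), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Segregation counts for one variant over a genotyped cohort
#'
#' Counts carriers and non-carriers among genotyped pedigree members with
#' known affection status. The variant "fully segregates" when no affected
#' non-carrier and no unaffected carrier exists.
#'
#' @param key variant key
#' @param genotypes a [genotype_table()]
#' @param pedigree a [pedigree()] with `genotyped` flags set
#' @return list with `counts` (named: affected_carrier,
#'   affected_noncarrier, unaffected_carrier, unaffected_noncarrier) and
#'   `fully_segregates`
#' @export
segregation_count <- function(key, genotypes, pedigree) {
  members <- pedigree[pedigree$genotyped & pedigree$affected != "unknown", ]
  carrier <- vapply(members$id, function(s) {
    gt_call(genotypes, s, key) %in% c("het", "hom_alt")
  }, TRUE)
  affected <- members$affected == "yes"
  counts <- c(affected_carrier = sum(affected & carrier),
              affected_noncarrier = sum(affected & !carrier),
              unaffected_carrier = sum(!affected & carrier),
              unaffected_noncarrier = sum(!affected & !carrier))
  list(counts = counts,
       fully_segregates = counts[["affected_noncarrier"]] == 0 &&
         counts[["unaffected_carrier"]] == 0)
}
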