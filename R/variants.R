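#' Construct a variant table
#'
#' One row per chromosome/position/ref/alt record (multi-allelic sites are
#' decomposed upstream). Per-panel allele counts travel as paired columns
#' `ac_<panel>` / `an_<panel>`; `NA` in both means the variant was not
#' identified in that panel ("NI"), which downstream frequency filters treat
#' as passing.
#'
#' @param chrom,pos,ref,alt vectors describing each record (pos is the
#'   1-based position of the first reference base)
#' @param id optional identifiers (e.g. dbSNP), `NA` when absent
#' @param panel_counts optional named list: panel name -> two-column matrix
#'   or data frame / list with elements `ac` and `an`
#' @return data frame of class `variant_table` with attribute `panels`
#' @export
variant_table <- function(chrom, pos, ref, alt, id = NA_character_,
                          panel_counts = list()) {
  n <- length(pos)
  ref <- toupper(as.character(ref))
  alt <- toupper(as.character(alt))
  if (!all(is_dna(ref)) || !all(is_dna(alt))) {
    stop("ref and alt must be non-empty strings over A/C/G/T")
  }
  if (any(ref == alt)) stop("ref and alt must differ")
  vt <- data.frame(chrom = rep_len(as.character(chrom), n),
                   pos = as.numeric(pos), ref = ref, alt = alt,
                   id = rep_len(as.character(id), n),
                   stringsAsFactors = FALSE)
  panels <- names(panel_counts)
  for (p in panels) {
    ac <- as.numeric(panel_counts[[p]]$ac)
    an <- as.numeric(panel_counts[[p]]$an)
    bad <- !is.na(ac) & !is.na(an) & (ac < 0 | an <= 0 | ac > an)
    if (any(bad)) {
      stop("invalid allele counts for panel ", p,
           ": need 0 <= ac <= an, an > 0")
    }
    vt[[paste0("ac_", p)]] <- ac
    vt[[paste0("an_", p)]] <- an
  }
  attr(vt, "panels") <- panels
  class(vt) <- c("variant_table", "data.frame")
  vt
}

#' Canonical variant key
#' @param vt a `variant_table` (or data frame with chrom/pos/ref/alt)
#' @return character vector `chrom:pos:ref:alt`
#' @export
variant_key <- function(vt) {
  sprintf("%s:%s:%s:%s", vt$chrom, format(vt$pos, scientific = FALSE,
                                          trim = TRUE), vt$ref, vt$alt)
}

variant_panels <- function(vt) {
  p <- attr(vt, "panels")
  if (!is.null(p)) return(p)
  sub("^ac_", "", grep("^ac_", names(vt), value = TRUE))
}

#' Width of the reference span of each variant
#' @param vt a `variant_table`
#' @return integer vector, `nchar(ref)`
#' @export
ref_span_width <- function(vt) nchar(vt$ref)

#' Genomic span duplicated by a VCF-style tandem duplication
#'
#' Duplications are stored VCF-style as an anchor base plus the inserted
#' copy (`ref = A`, `alt = A<dup>`); the duplicated genomic span is the
#' `nchar(alt) - 1` reference bases immediately following the anchor.
#'
#' @param variant one-row `variant_table` (or list with chrom/pos/ref/alt)
#' @return an [interval()] covering the duplicated reference bases
#' @export
duplication_span <- function(variant) {
  if (nchar(variant$alt) <= nchar(variant$ref) ||
      substr(variant$alt, 1, nchar(variant$ref)) != variant$ref) {
    stop("variant is not an anchored insertion/duplication")
  }
  ins <- nchar(variant$alt) - nchar(variant$ref)
  interval(variant$chrom, variant$pos + 1, variant$pos + ins)
}

#' Construct a genotype call table
#'
#' Long-format calls: one row per (sample, variant key), call one of
#' hom_ref / het / hom_alt / missing.
#'
#' @param sample,key,call equal-length vectors
#' @return data frame of class `genotype_table`
#' @export
genotype_table <- function(sample, key, call) {
  stopifnot(all(call %in% c("hom_ref", "het", "hom_alt", "missing")))
  gt <- data.frame(sample = as.character(sample), key = as.character(key),
                   call = as.character(call), stringsAsFactors = FALSE)
  if (anyDuplicated(gt[c("sample", "key")])) {
    stop("duplicate (sample, variant) genotype entries")
  }
  class(gt) <- c("genotype_table", "data.frame")
  gt
}

#' Look up a genotype call
#' @param gt a `genotype_table`
#' @param sample sample id
#' @param key variant key
#' @param absent value returned when no entry exists (default "missing")
#' @return the call string
#' @export
gt_call <- function(gt, sample, key, absent = "missing") {
  hit <- gt$call[gt$sample == sample & gt$key == key]
  if (length(hit) == 0) absent else hit[[1]]
}

gt_samples <- function(gt) unique(gt$sample)

#' Read a multi-sample VCF
#'
#' Parses a VCF 4.x file via vcfR. Multi-allelic records are decomposed into
#' one variant per ALT allele (per-allele INFO counts are split
#' accordingly); genotypes become hom_ref / het / hom_alt / missing calls
#' against each decomposed allele. Per-panel allele counts are read from
#' INFO keys `AC_<panel>` / `AN_<panel>` for the panels named in `panels` --
#' the key naming is configuration, not convention.
#'
#' @param path VCF path
#' @param panels character vector of panel names to extract from INFO
#' @return list with elements `variants` (a [variant_table()]) and
#'   `genotypes` (a [genotype_table()])
#' @export
read_vcf <- function(path, panels = character()) {
  validate_vcf_lines(path)
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf, getINFO = TRUE)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  gt_mat <- if (ncol(vcf@gt) > 1) vcfR::extract.gt(vcf, element = "GT") else NULL
  if (!is.null(gt_mat) && is.null(dim(gt_mat))) {
    gt_mat <- matrix(gt_mat, nrow = 1, dimnames = list(NULL, names(gt_mat)))
  }
  info <- fix[, "INFO"]

  rows <- list(); calls <- list()
  for (r in seq_len(nrow(fix))) {
    alts <- strsplit(fix[r, "ALT"], ",", fixed = TRUE)[[1]]
    kv <- parse_info(info[[r]])
    for (a in seq_along(alts)) {
      rec <- list(chrom = fix[r, "CHROM"], pos = as.numeric(fix[r, "POS"]),
                  ref = fix[r, "REF"], alt = alts[[a]],
                  id = if (fix[r, "ID"] %in% c(".", NA)) NA_character_ else fix[r, "ID"])
      for (p in panels) {
        rec[[paste0("ac_", p)]] <- nth_info_num(kv, paste0("AC_", p), a)
        rec[[paste0("an_", p)]] <- nth_info_num(kv, paste0("AN_", p), 1)
      }
      rows[[length(rows) + 1]] <- rec
      if (!is.null(gt_mat)) {
        key <- sprintf("%s:%s:%s:%s", rec$chrom,
                       format(rec$pos, scientific = FALSE, trim = TRUE),
                       rec$ref, rec$alt)
        for (s in colnames(gt_mat)) {
          calls[[length(calls) + 1]] <- list(
            sample = s, key = key,
            call = classify_gt(gt_mat[r, s], a))
        }
      }
    }
  }
  vdf <- do.call(rbind, lapply(rows, function(x) as.data.frame(x, stringsAsFactors = FALSE)))
  pc <- lapply(panels, function(p) list(ac = vdf[[paste0("ac_", p)]],
                                        an = vdf[[paste0("an_", p)]]))
  names(pc) <- panels
  vt <- variant_table(vdf$chrom, vdf$pos, vdf$ref, vdf$alt, vdf$id, pc)
  gdf <- do.call(rbind, lapply(calls, function(x) as.data.frame(x, stringsAsFactors = FALSE)))
  gts <- if (is.null(gdf)) genotype_table(character(), character(), character())
         else genotype_table(gdf$sample, gdf$key, gdf$call)
  list(variants = vt, genotypes = gts)
}

validate_vcf_lines <- function(path) {
  lines <- readLines(path)
  if (length(lines) == 0 || !grepl("^##fileformat=VCF", lines[[1]])) {
    stop("malformed VCF header at line 1: missing ##fileformat")
  }
  body <- !grepl("^#", lines)
  nf <- lengths(strsplit(lines[body], "\t", fixed = TRUE))
  bad <- which(body)[nf < 8]
  if (length(bad) > 0) {
    stop("malformed VCF record at line ", bad[[1]], ": fewer than 8 fields")
  }
  invisible(TRUE)
}

parse_info <- function(info) {
  if (is.na(info) || info == ".") return(character())
  fields <- strsplit(info, ";", fixed = TRUE)[[1]]
  kv <- sub("^[^=]*=?", "", fields)
  names(kv) <- sub("=.*$", "", fields)
  kv
}

nth_info_num <- function(kv, key, i) {
  if (!key %in% names(kv)) return(NA_real_)
  vals <- strsplit(kv[[key]], ",", fixed = TRUE)[[1]]
  as.numeric(vals[[min(i, length(vals))]])
}

classify_gt <- function(gt, allele_idx) {
  if (is.na(gt)) return("missing")
  alleles <- strsplit(gt, "[/|]")[[1]]
  if (any(alleles == ".")) return("missing")
  n <- sum(alleles == as.character(allele_idx))
  c("hom_ref", "het", "hom_alt")[n + 1]
}

#' Write variants and genotypes as a plain-text VCF 4.2 file
#'
#' Inverse of [read_vcf()]: panel counts go to `AC_<panel>` / `AN_<panel>`
#' INFO fields, calls to per-sample GT columns.
#'
#' @param variants a [variant_table()]
#' @param genotypes a [genotype_table()] (may be empty)
#' @param path output path
#' @param samples sample column order (default: order of appearance)
#' @export
write_vcf <- function(variants, genotypes, path, samples = NULL) {
  panels <- variant_panels(variants)
  if (is.null(samples)) samples <- gt_samples(genotypes)
  hdr <- c("##fileformat=VCFv4.2",
           sprintf("##INFO=<ID=AC_%s,Number=A,Type=Integer,Description=\"Allele count in %s panel\">", panels, panels),
           sprintf("##INFO=<ID=AN_%s,Number=1,Type=Integer,Description=\"Total alleles screened in %s panel\">", panels, panels),
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", if (length(samples)) "FORMAT", samples),
                 collapse = "\t"))
  keys <- variant_key(variants)
  body <- vapply(seq_len(nrow(variants)), function(r) {
    info <- character()
    for (p in panels) {
      ac <- variants[[paste0("ac_", p)]][r]
      an <- variants[[paste0("an_", p)]][r]
      if (!is.na(ac) && !is.na(an)) {
        info <- c(info, sprintf("AC_%s=%d;AN_%s=%d", p, as.integer(ac),
                                p, as.integer(an)))
      }
    }
    info <- if (length(info)) paste(info, collapse = ";") else "."
    fields <- c(variants$chrom[r],
                format(variants$pos[r], scientific = FALSE, trim = TRUE),
                ifelse(is.na(variants$id[r]), ".", variants$id[r]),
                variants$ref[r], variants$alt[r], ".", "PASS", info)
    if (length(samples)) {
      gts <- vapply(samples, function(s) {
        switch(gt_call(genotypes, s, keys[[r]]),
               hom_ref = "0/0", het = "0/1", hom_alt = "1/1", "./.")
      }, "")
      fields <- c(fields, "GT", gts)
    }
    paste(fields, collapse = "\t")
  }, "")
  writeLines(c(hdr, body), path)
  invisible(path)
}
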