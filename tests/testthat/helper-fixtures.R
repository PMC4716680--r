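# shared helpers: tiny in-code fixtures and independent oracles

write_lines_tmp <- function(lines, ext = ".txt") {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}

# minimal two-sample VCF with one heterozygous site
minimal_vcf <- function() {
  write_lines_tmp(c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tS1\tS2",
    "chr1\t100\t.\tA\tG\t.\tPASS\t.\tGT\t0/1\t0/0"), ".vcf")
}

toy_trio_ped <- function() {
  write_lines_tmp(c(
    "F1\tdad\t0\t0\t1\t1",
    "F1\tmum\t0\t0\t2\t1",
    "F1\tkid\tdad\tmum\t1\t2"), ".ped")
}

# pedigree of unrelated genotyped affecteds/unaffecteds (no parent info)
flat_pedigree <- function(n_aff, n_un = 0) {
  ids <- c(sprintf("AF%d", seq_len(n_aff)),
           if (n_un > 0) sprintf("UN%d", seq_len(n_un)))
  pedigree(fam = "T", id = ids, father = NA, mother = NA, sex = "unknown",
           affected = rep(c("yes", "no"), c(n_aff, n_un)))
}

# brute-force refinement oracle: enumerate every contiguous marker range,
# keep ranges free of empty-intersection markers, anchor each at its
# outermost uniquely-shared markers, and pick by (shared count, bp width,
# leftmost) -- an independent search over all haplotype-compatible ranges
oracle_refine <- function(markers, affecteds) {
  n <- nrow(markers)
  sets <- lapply(seq_len(n), function(j) {
    lapply(affecteds, function(s) strsplit(markers[[s]][j], "/")[[1]])
  })
  inter_size <- vapply(sets, function(x) length(Reduce(intersect, x)), 0L)
  best <- NULL
  for (i in seq_len(n)) {
    for (j in i:n) {
      if (any(inter_size[i:j] == 0)) next
      anchored <- (i:j)[inter_size[i:j] == 1]
      if (length(anchored) == 0) next
      cand <- list(start = markers$pos[min(anchored)],
                   end = markers$pos[max(anchored)],
                   n_shared = length(anchored))
      cand$width <- cand$end - cand$start
      if (is.null(best) || cand$n_shared > best$n_shared ||
          (cand$n_shared == best$n_shared && cand$width > best$width)) {
        best <- cand
      }
    }
  }
  best
}

random_marker_table <- function(seed, n_markers, n_aff, n_alleles = 4) {
  set.seed(seed)
  affs <- sprintf("AF%d", seq_len(n_aff))
  out <- data.frame(marker = sprintf("M%d", seq_len(n_markers)),
                    chrom = "chrT",
                    pos = sort(sample(1000:100000, n_markers)),
                    stringsAsFactors = FALSE)
  for (s in affs) {
    out[[s]] <- vapply(seq_len(n_markers), function(j) {
      paste(sort(sample(as.character(seq_len(n_alleles)), 2, replace = TRUE)),
            collapse = "/")
    }, "")
  }
  out
}

# independent window scorer for PWM scanning oracles
oracle_scan_scores <- function(seq, mat, background = rep(0.25, 4)) {
  chars <- strsplit(seq, "")[[1]]
  L <- ncol(mat)
  vapply(seq_len(length(chars) - L + 1), function(s) {
    sum(vapply(seq_len(L), function(k) {
      log2(mat[chars[s + k - 1], k] / background[[1]])
    }, 0))
  }, 0)
}

random_pwm <- function(seed, width = 6, name = "RND") {
  set.seed(seed)
  m <- matrix(stats::runif(4 * width, 0.05, 1), nrow = 4)
  m <- sweep(m, 2, colSums(m), "/")
  rownames(m) <- c("A", "C", "G", "T")
  pwm(name, m, threshold = 0.75)
}

unclass_df <- function(d) { rownames(d) <- NULL; class(d) <- "data.frame"; d }

random_dna <- function(seed, n) {
  set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}
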