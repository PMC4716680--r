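#' Run the full analysis pipeline over a fixture bundle
#'
#' End-to-end orchestration: locus refinement from marker genotypes, the
#' filter cascade for both cohorts (the founder cohort with the phase
#' step), class histograms of the survivors, regulatory overlap of the
#' union, differential motif scanning of the promoter variants,
#' segregation counts of the two causal candidates, and normalization +
#' one-way ANOVA of the reporter measurements. All inputs are read from
#' files in `fixture_dir` (as written by [build_paper_fixtures()]); reports
#' are written to `out_dir`.
#'
#' @param fixture_dir directory of fixture files; `NULL` builds the
#'   packaged case-study bundle in a temporary directory
#' @param out_dir report directory (created)
#' @param quiet suppress per-stage messages
#' @return (invisibly) a summary list with per-stage counts and results
#' @export
run_all <- function(fixture_dir = NULL, out_dir = tempfile("pedcascade-out"),
                    quiet = FALSE) {
  if (is.null(fixture_dir)) {
    fixture_dir <- tempfile("pedcascade-fixtures")
    build_paper_fixtures(fixture_dir)
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (!quiet) message(sprintf(...))
  fp <- function(f) file.path(fixture_dir, f)
  op <- function(f) file.path(out_dir, f)
  panels <- c("1000G", "UK10K", "GoNL", "ExAC", "UCL")

  br1_ped <- read_ped(fp("br1.ped"))
  markers <- read_markers(fp("br1_markers.tsv"))
  hap <- infer_disease_haplotype(markers, br1_ped)
  refined <- refine_interval(hap, chrom = markers$chrom[[1]])
  write_bed(list(refined$interval), op("refined_locus.bed"))
  say("refined locus: %s:%d-%d (%.1f Mb)", refined$interval$chrom,
      refined$interval$start, refined$interval$end,
      interval_length(refined$interval) / 1e6)

  models <- read_transcripts_yaml(fp("transcripts.yaml"))
  regulatory <- read_bed(fp("regulatory.bed"))

  br1 <- read_vcf(fp("br1.vcf"), panels = panels)
  res1 <- run_cascade(br1$variants, br1$genotypes, br1_ped,
                      br1_cascade_config(), quiet = TRUE)
  cls1 <- classify_survivors(res1$survivors, models)
  say("index-family cascade: %d survivors (%s)", nrow(res1$survivors),
      paste(names(cls1), cls1, sep = "=", collapse = ", "))

  cz_ped <- read_ped(fp("czech.ped"))
  cz <- read_vcf(fp("c2.vcf"), panels = panels)
  res2 <- run_cascade(cz$variants, cz$genotypes, cz_ped,
                      czech_cascade_config(), quiet = TRUE)
  cls2 <- classify_survivors(res2$survivors, models)
  say("founder-cohort cascade: %d survivors (%s)", nrow(res2$survivors),
      paste(names(cls2), cls2, sep = "=", collapse = ", "))

  shared_cols <- intersect(names(res1$survivors), names(res2$survivors))
  both <- rbind(res1$survivors[shared_cols], res2$survivors[shared_cols])
  reg_hits <- regulatory_overlap(both, regulatory)
  say("regulatory overlap over both survivor sets: %d variants", nrow(reg_hits))

  write_vcf(res1$survivors, br1$genotypes, op("br1_survivors.vcf"),
            samples = br1_samples)
  write_vcf(res2$survivors, cz$genotypes, op("c2_survivors.vcf"),
            samples = czech_samples)
  utils::write.table(res1$trace, op("br1_trace.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(res2$trace, op("c2_trace.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(
    data.frame(cohort = c(rep("br1", length(cls1)), rep("czech", length(cls2))),
               class = c(names(cls1), names(cls2)),
               count = c(unname(cls1), unname(cls2))),
    op("classes.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)

  wt <- read_fasta(fp("promoter_wt.fa"))[[1]]
  pwms <- read_jaspar(fp("promoter_pwms.jaspar"))
  diffs <- list()
  for (nm in names(fixture_promoter_variants())) {
    v <- fixture_promoter_variants()[[nm]]
    span <- variant_local_span(v, nchar(wt))
    d <- diff_scan(wt, apply_variant(wt, v), span[1], span[2], pwms)
    d$variant <- nm
    diffs[[nm]] <- d
  }
  motif_report <- do.call(rbind, diffs)
  utils::write.table(motif_report, op("motif_diff.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)

  seg <- lapply(c(br1 = "br1", czech = "czech"), function(w) {
    sx <- fixture_cohort_segregation(w)
    s <- segregation_count(sx$key, read_genotypes(
      fp(paste0(w, "_cohort_genotypes.tsv"))), sx$pedigree)
    c(as.list(s$counts), fully_segregates = s$fully_segregates)
  })
  jsonlite::write_json(seg, op("segregation.json"), auto_unbox = TRUE)

  lux <- utils::read.table(fp("luciferase.tsv"), header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  activities <- normalize_reporter(lux, wildtype = "WT")
  aov_res <- anova_one_way(reporter_groups(lux, wildtype = "WT"))
  say("reporter assay: one-way ANOVA F=%.2f p=%.3g", aov_res$F, aov_res$p)

  summary <- list(
    refined_locus = with(refined$interval,
                         sprintf("%s:%d-%d", chrom, start, end)),
    refined_length_mb = round(interval_length(refined$interval) / 1e6, 1),
    br1_survivors = nrow(res1$survivors),
    czech_survivors = nrow(res2$survivors),
    br1_classes = as.list(cls1),
    czech_classes = as.list(cls2),
    regulatory_overlap = nrow(reg_hits),
    segregation = seg,
    motif_effects = lapply(split(motif_report, motif_report$variant),
                           function(d) stats::setNames(d$effect, d$tf)),
    reporter_activities = stats::setNames(activities$activity,
                                          activities$construct),
    anova = aov_res[c("F", "p")]
  )
  jsonlite::write_json(summary, op("summary.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(summary)
}
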