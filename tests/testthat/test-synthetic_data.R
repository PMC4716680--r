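test_that("gene-drop pedigrees are fully penetrant and deterministic", {
  cfg <- simulation_config(seed = 1, generations = 3, sibship = 3)
  ped <- simulate_pedigree(cfg)
  expect_setequal(attr(ped, "carriers"), ped$id[ped$affected == "yes"])
  expect_identical(unclass_df(simulate_pedigree(cfg)), unclass_df(ped))
  for (seed in 2:6) {
    p <- simulate_pedigree(simulation_config(seed = seed, generations = 4))
    expect_setequal(attr(p, "carriers"), p$id[p$affected == "yes"])
  }
  expect_error(simulate_pedigree(simulation_config(generations = 1)),
               "2 generations")
  expect_error(simulate_pedigree(simulation_config(sibship = 0)), "impossible")
})

test_that("a seven-generation run can carry well over 36 affecteds", {
  ped <- simulate_pedigree(simulation_config(seed = 11, generations = 7,
                                             sibship = 4, n_background = 0))
  expect_gte(sum(ped$affected == "yes"), 36)
})

test_that("with no background variants the cascade returns exactly the causal", {
  cfg <- simulation_config(seed = 5, generations = 3, n_background = 0)
  ped <- simulate_pedigree(cfg)
  sim <- simulate_cohort_variants(ped, cfg)
  expect_equal(nrow(sim$variants), 1)
  cc <- cascade_config(locus = cfg$locus,
                       required_het = affected_ids(ped),
                       excluded_carrier = unaffected_ids(ped)[1])
  res <- run_cascade(sim$variants, sim$genotypes, ped, cc)
  expect_equal(variant_key(res$survivors), sim$truth)
})

test_that("an all-common background leaves only the causal variant", {
  cfg <- simulation_config(seed = 8, generations = 3, n_background = 40,
                           p_rare = 0)
  ped <- simulate_pedigree(cfg)
  sim <- simulate_cohort_variants(ped, cfg)
  cc <- cascade_config(locus = cfg$locus,
                       required_het = affected_ids(ped),
                       excluded_carrier = unaffected_ids(ped)[1])
  # brute-force: every background variant exceeds the threshold in a panel
  for (i in seq_len(nrow(sim$variants) - 1)) {
    mafs <- vapply(cc$maf_panels, function(p) compute_maf(sim$variants[i, ], p),
                   0)
    expect_true(any(mafs > cc$maf_threshold, na.rm = TRUE))
  }
  res <- run_cascade(sim$variants, sim$genotypes, ped, cc)
  expect_equal(variant_key(res$survivors), sim$truth)
})

test_that("cohort simulation is seed-deterministic and validates its locus", {
  cfg <- simulation_config(seed = 3, generations = 3, n_background = 25)
  ped <- simulate_pedigree(cfg)
  a <- simulate_cohort_variants(ped, cfg)
  b <- simulate_cohort_variants(ped, cfg)
  expect_identical(unclass_df(a$variants), unclass_df(b$variants))
  expect_identical(unclass_df(a$genotypes), unclass_df(b$genotypes))
  tiny <- simulation_config(seed = 3, n_background = 50,
                            locus = interval("chr20", 18058000, 18058010),
                            promoter = NULL)
  expect_error(simulate_cohort_variants(ped, tiny), "too small")
})

test_that("the causal variant is recovered across seeded simulations", {
  for (seed in 1:10) {
    cfg <- simulation_config(seed = seed, generations = 3, n_background = 30)
    ped <- simulate_pedigree(cfg)
    sim <- simulate_cohort_variants(ped, cfg)
    cc <- cascade_config(locus = cfg$locus,
                         required_het = affected_ids(ped),
                         excluded_carrier = unaffected_ids(ped)[1])
    res <- run_cascade(sim$variants, sim$genotypes, ped, cc)
    expect_true(sim$truth %in% variant_key(res$survivors))
    ann <- annotate_variant(list(chrom = "chr20", pos = cfg$causal$pos,
                                 ref = cfg$causal$ref, alt = cfg$causal$alt),
                            fixture_transcript_models())
    expect_equal(ann$class, "promoter")
  }
})

test_that("simulated marker genotypes refine to the span bounded by breakpoints", {
  ped <- flat_pedigree(4, 1)
  mk_df <- data.frame(id = paste0("M", 1:6), chrom = "chrT",
                      pos = c(100, 200, 300, 400, 500, 600))
  founder <- stats::setNames(rep("1", 6), mk_df$id)
  no_bp <- marker_panel(mk_df, founder)
  g <- simulate_marker_genotypes(ped, no_bp, seed = 2)
  res <- refine_interval(infer_disease_haplotype(g, ped), "chrT")
  expect_equal(c(res$interval$start, res$interval$end), c(100, 600))

  bp <- marker_panel(mk_df, founder, breakpoints = list(
    AF1 = list(pos = 250, side = "left"),
    AF2 = list(pos = 450, side = "right")))
  g2 <- simulate_marker_genotypes(ped, bp, seed = 2)
  res2 <- refine_interval(infer_disease_haplotype(g2, ped), "chrT")
  expect_equal(c(res2$interval$start, res2$interval$end), c(300, 400))

  expect_error(marker_panel(mk_df, founder, breakpoints = list(
    AF1 = list(pos = 9999, side = "left"))), "outside the marker span")
})

test_that("the seeded causal position always falls inside the refined interval", {
  ped <- flat_pedigree(5)
  mk_df <- data.frame(id = paste0("M", 1:7), chrom = "chr20",
                      pos = c(17400000, 17641482, 18000000, 18058004,
                              18500000, 18949130, 19300000))
  founder <- stats::setNames(rep("1", 7), mk_df$id)
  for (seed in 1:8) {
    panel <- marker_panel(mk_df, founder, breakpoints = list(
      AF1 = list(pos = 17500000, side = "left"),
      AF3 = list(pos = 19000000, side = "right")))
    g <- simulate_marker_genotypes(ped, panel, seed = seed)
    res <- refine_interval(infer_disease_haplotype(g, ped), "chr20")
    expect_true(interval_contains(res$interval, 18058004))
  }
})

test_that("luciferase simulation honors its contracts", {
  exact <- simulate_luciferase(c(WT = 1, M = 2), noise_cv = 0, seed = 1)
  r <- exact$firefly / exact$renilla
  expect_equal(unique(r[exact$construct == "M"]) /
                 unique(r[exact$construct == "WT"]), 2)
  a <- simulate_luciferase(c(WT = 1), seed = 7)
  b <- simulate_luciferase(c(WT = 1), seed = 7)
  expect_identical(a, b)
  expect_error(simulate_luciferase(c(WT = 1), n_bio = 1), "ANOVA undefined")
  expect_error(simulate_luciferase(c(WT = -1)), "effects > 0")
})

test_that("fixture builder writes a complete, re-readable bundle", {
  out <- tempfile("bundle")
  bundle <- build_paper_fixtures(out)
  files <- c("br1.vcf", "br1.ped", "c2.vcf", "czech.ped", "br1_markers.tsv",
             "br1_cohort_genotypes.tsv", "czech_cohort_genotypes.tsv",
             "promoter_wt.fa", "promoter_alignment.fa", "regulatory.bed",
             "promoter_pwms.jaspar", "transcripts.yaml", "luciferase.tsv")
  for (f in files) expect_true(file.exists(file.path(out, f)), info = f)
  models <- read_transcripts_yaml(file.path(out, "transcripts.yaml"))
  expect_equal(sort(names(models)), sort(names(fixture_transcript_models())))
  expect_equal(models$OVOL2$translation_start_g, 18057634)
  wt <- read_fasta(file.path(out, "promoter_wt.fa"))
  expect_equal(nchar(wt[[1]]), 1824)
})
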