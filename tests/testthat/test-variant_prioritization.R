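models <- fixture_transcript_models()

test_that("panel frequencies divide allele counts and honor absent panels", {
  v <- variant_table("chr20", 18396543, "T", "G",
                     panel_counts = list(ExAC = list(ac = 5, an = 120650),
                                         `1000G` = list(ac = NA, an = NA)))
  expect_equal(compute_maf(v[1, ], "ExAC"), 5 / 120650)  # 4.144e-5
  expect_true(is.na(compute_maf(v[1, ], "1000G")))       # not identified
  z <- variant_table("chr1", 1, "A", "G",
                     panel_counts = list(P = list(ac = 0, an = 1000)))
  expect_equal(compute_maf(z[1, ], "P"), 0)
  z$an_P <- 0
  expect_error(compute_maf(z[1, ], "P"), "zero")
})

test_that("frequency filter applies only to the configured panels", {
  cfg <- br1_cascade_config()
  rare <- variant_table("chr20", 1, "A", "G",
                        panel_counts = list(`1000G` = list(ac = NA, an = NA),
                                            ExAC = list(ac = 5, an = 120650)))
  expect_true(maf_filter(rare[1, ], cfg)$pass)
  common <- variant_table("chr20", 2, "A", "G",
                          panel_counts = list(`1000G` = list(ac = 100, an = 5008)))
  expect_false(maf_filter(common[1, ], cfg)$pass)
  # ~0.79% in an annotation panel must not fail the default configuration
  uk <- variant_table("chr20", 18870484, "C", "G",
                      panel_counts = list(`1000G` = list(ac = 10, an = 5008),
                                          UK10K = list(ac = 60, an = 7562)))
  expect_true(maf_filter(uk[1, ], cfg)$pass)
})

test_that("genotype pattern filter demands het sharing and excludes carriers", {
  cfg <- br1_cascade_config()
  g <- genotype_table(rep(c("VII:3", "VI:24", "VI:22"), 4),
                      rep(c("k1", "k2", "k3", "k4"), each = 3),
                      c("het", "het", "hom_ref",    # causal-like: pass
                        "het", "het", "het",        # carried by excluded
                        "het", "hom_ref", "hom_ref",# not shared
                        "hom_alt", "het", "hom_ref")) # hom in an affected
  expect_true(genotype_pattern_filter("k1", g, cfg)$pass)
  expect_false(genotype_pattern_filter("k2", g, cfg)$pass)
  expect_false(genotype_pattern_filter("k3", g, cfg)$pass)
  expect_false(genotype_pattern_filter("k4", g, cfg)$pass)
  # missing call in an excluded sample passes with a warning
  g2 <- genotype_table(c("VII:3", "VI:24"), "k5", c("het", "het"))
  expect_warning(res <- genotype_pattern_filter("k5", g2, cfg), "non-carrier")
  expect_true(res$pass)
  g3 <- genotype_table("VII:3", "k6", "het")
  expect_error(genotype_pattern_filter("k6", g3, cfg), "VI:24")
})

test_that("phase filter removes variants carried by the married-in parent", {
  ped <- fixture_czech_pedigree()
  g <- genotype_table(rep(c("V:11", "IV:17"), 2), rep(c("k1", "k2"), each = 2),
                      c("het", "het", "het", "hom_ref"))
  expect_false(phase_filter_married_in("k1", g, "IV:17", ped)$pass)
  expect_true(phase_filter_married_in("k2", g, "IV:17", ped)$pass)
  g3 <- genotype_table("V:11", "k3", "het")
  expect_warning(res <- phase_filter_married_in("k3", g3, "IV:17", ped),
                 "cannot be phased")
  expect_true(res$pass)
  expect_error(phase_filter_married_in("k1", g, "V:11", ped), "married-in")
})

test_that("annotation precedence and codon classification follow the models", {
  promoter_v <- list(chrom = "chr20", pos = 18058004, ref = "A", alt = "G")
  expect_equal(annotate_variant(promoter_v, models)$class, "promoter")

  mis <- list(chrom = "chr20", pos = 18396543, ref = "T", alt = "G")
  ann <- annotate_variant(mis, models)
  expect_equal(ann$class, "missense")   # ATA (Ile) -> CTA (Leu), minus strand
  expect_equal(ann$closest, "DZANK1")

  syn <- list(chrom = "chr20", pos = 18396541, ref = "T", alt = "G")
  expect_equal(annotate_variant(syn, models)$class, "synonymous")  # ATA -> ATC

  ncd <- list(chrom = "chr20", pos = 18810051, ref = "G", alt = "A")
  expect_equal(annotate_variant(ncd, models)$class, "non_coding_transcript")

  inter <- list(chrom = "chr20", pos = 18112700, ref = "T", alt = "A")
  expect_equal(annotate_variant(inter, models)$class, "intergenic")

  expect_error(annotate_variant(list(chrom = "chr1", pos = 1, ref = "A",
                                     alt = "G"), models), "chromosome")
})

test_that("deep-intronic calls need strictly more than the distance cutoff", {
  toy <- list(transcript_model("TOY", "chrT", "+",
                               data.frame(start = c(1000, 3000),
                                          end = c(1999, 3999))))
  probe <- function(pos) {
    annotate_variant(list(chrom = "chrT", pos = pos, ref = "A", alt = "G"),
                     toy)$class
  }
  expect_equal(probe(1999 + 101), "deep_intronic")
  expect_equal(probe(1999 + 100), "intronic_near_splice")
  expect_equal(probe(1999 + 99), "intronic_near_splice")
  expect_equal(probe(3000 - 99), "intronic_near_splice")
})

test_that("index-family cascade reproduces the published survivor set", {
  fx <- fixture_br1_cohort()
  res <- run_cascade(fx$variants, fx$genotypes, NULL, br1_cascade_config())
  expect_equal(nrow(res$survivors), 19)
  expect_setequal(variant_key(res$survivors), fx$truth)
  expect_false(is.unsorted(res$survivors$pos))
})

test_that("founder-cohort cascade with the phase step keeps 18 variants", {
  fx <- fixture_czech_cohort()
  res <- run_cascade(fx$variants, fx$genotypes, fixture_czech_pedigree(),
                     czech_cascade_config())
  expect_equal(nrow(res$survivors), 18)
  expect_setequal(variant_key(res$survivors), fx$truth)
})

test_that("every decoy fails exactly the one filter it was built to fail", {
  for (cohort in list(
    list(fx = fixture_br1_cohort(), ped = NULL, cfg = br1_cascade_config()),
    list(fx = fixture_czech_cohort(), ped = fixture_czech_pedigree(),
         cfg = czech_cascade_config()))) {
    res <- run_cascade(cohort$fx$variants, cohort$fx$genotypes, cohort$ped,
                       cohort$cfg)
    keys <- variant_key(cohort$fx$variants)
    fault_to_filter <- c(locus = "locus", frequency = "frequency",
                         excluded_carrier = "genotype_pattern",
                         not_shared = "genotype_pattern",
                         hom_alt = "genotype_pattern",
                         not_het = "genotype_pattern",
                         phase_married_in = "phase_married_in")
    for (i in seq_along(keys)) {
      fails <- res$trace[res$trace$key == keys[i] &
                           res$trace$outcome == "fail", "filter"]
      fault <- cohort$fx$variants$fault[i]
      if (fault == "none") {
        expect_length(fails, 0)
      } else {
        expect_equal(fails, unname(fault_to_filter[fault]),
                     info = paste(keys[i], fault))
      }
    }
  }
})

test_that("the survivor set is invariant to filter order", {
  fx <- fixture_czech_cohort()
  cfg <- czech_cascade_config()
  ped <- fixture_czech_pedigree()
  keys <- variant_key(fx$variants)
  predicates <- list(
    locus = function(i) fx$variants$chrom[i] == cfg$locus$chrom &&
      interval_contains(cfg$locus, fx$variants$pos[i], nchar(fx$variants$ref[i])),
    frequency = function(i) maf_filter(fx$variants[i, ], cfg)$pass,
    pattern = function(i) genotype_pattern_filter(keys[i], fx$genotypes, cfg)$pass,
    phase = function(i) phase_filter_married_in(keys[i], fx$genotypes,
                                                cfg$phase_parent, ped)$pass)
  reference <- run_cascade(fx$variants, fx$genotypes, ped, cfg)
  set.seed(42)
  for (rep in 1:3) {
    order <- sample(names(predicates))
    alive <- seq_len(nrow(fx$variants))
    for (f in order) {
      alive <- suppressWarnings(
        alive[vapply(alive, predicates[[f]], TRUE)])
    }
    expect_setequal(keys[alive], variant_key(reference$survivors))
  }
})

test_that("survivors plus failures conserve the input set", {
  fx <- fixture_br1_cohort()
  res <- run_cascade(fx$variants, fx$genotypes, NULL, br1_cascade_config())
  keys <- variant_key(fx$variants)
  failed <- unique(res$trace$key[res$trace$outcome == "fail"])
  expect_setequal(c(variant_key(res$survivors), failed), keys)
  expect_length(intersect(variant_key(res$survivors), failed), 0)
})

test_that("exonic non-synonymous mode isolates the coding candidate", {
  fx <- fixture_br1_cohort()
  cfg <- cascade_config(locus = interval("chr20", 17641482, 18949130),
                        required_het = c("VII:3", "VI:24"),
                        excluded_carrier = "VI:22", exonic_only = TRUE)
  res <- run_cascade(fx$variants, fx$genotypes, NULL, cfg, models = models)
  expect_equal(variant_key(res$survivors), "chr20:18396543:T:G")

  cz <- fixture_czech_cohort()
  cfg2 <- cascade_config(locus = interval("chr20", 17335789, 19665902),
                         required_het = "V:11", excluded_carrier = "V:10",
                         exonic_only = TRUE)
  res2 <- run_cascade(cz$variants, cz$genotypes, NULL, cfg2, models = models)
  expect_equal(nrow(res2$survivors), 0)
  expect_error(run_cascade(cz$variants, cz$genotypes, NULL, cfg2),
               "transcript models")
})

test_that("class histograms total the survivor counts", {
  fx <- fixture_br1_cohort()
  res <- run_cascade(fx$variants, fx$genotypes, NULL, br1_cascade_config())
  cls <- classify_survivors(res$survivors, models)
  expect_equal(sum(cls), nrow(res$survivors))
  expect_equal(classify_survivors(res$survivors[0, ], models), integer(0))
})

test_that("regulatory overlap uses closed intervals including terminal bases", {
  vt <- variant_table("chr20", c(100, 200, 201), "A", "G")
  reg <- list(interval("chr20", 150, 200))
  hit <- regulatory_overlap(vt, reg)
  expect_equal(hit$pos, 200)       # terminal base included, 201 excluded
  expect_equal(nrow(regulatory_overlap(vt, list())), 0)
})

test_that("segregation counts classify genotyped members by carriage", {
  seg <- fixture_cohort_segregation("br1")
  res <- segregation_count(seg$key, seg$genotypes, seg$pedigree)
  expect_equal(unname(res$counts), c(21, 0, 0, 12))
  expect_true(res$fully_segregates)
  # a variant absent everywhere: all genotyped members are non-carriers
  res0 <- segregation_count("chr20:1:A:G", seg$genotypes, seg$pedigree)
  expect_equal(unname(res0$counts), c(0, 21, 0, 12))
  expect_false(res0$fully_segregates)
})
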