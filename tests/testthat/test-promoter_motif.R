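ovol2 <- fixture_transcript_models()$OVOL2

test_that("the printed coordinate pairs round-trip on the minus-strand model", {
  expect_equal(c_to_genomic(-370, ovol2), 18058004)
  expect_equal(c_to_genomic(-307, ovol2), 18057941)
  expect_equal(c_to_genomic(-274, ovol2), 18057908)
  expect_equal(gene_strand_allele("T", "-"), "A")
  # bijection over the whole promoter
  offs <- -(1:1824)
  expect_equal(genomic_to_c(c_to_genomic(offs, ovol2), ovol2), offs)
  expect_equal(c_to_genomic(offs, ovol2), 18057634 + abs(offs))
  expect_error(c_to_genomic(0, ovol2), "no position 0")
})

test_that("plus-strand transcripts subtract the offset instead", {
  plus <- transcript_model("PLUS", "chr1", "+",
                           data.frame(start = 5000, end = 6000),
                           translation_start_g = 5000, cds_end_g = 5899,
                           promoter = interval("chr1", 4000, 4999))
  expect_equal(c_to_genomic(-10, plus), 4990)
  expect_equal(genomic_to_c(4990, plus), -10)
  expect_equal(gene_strand_allele("T", "+"), "T")
})

test_that("distance from a position to an interval handles edges", {
  dup <- interval("chr20", 18057974, 18057995)
  expect_equal(variant_distance(18058004, dup), 9)
  expect_equal(variant_distance(18057995, dup), 0)   # at the terminal base
  expect_equal(variant_distance(18057996, dup), 1)
  expect_error(variant_distance(5, dup, chrom = "chr1"), "chromosomes")
})

test_that("variant application substitutes, duplicates and checks references", {
  wt <- fixture_promoter_wt()
  muts <- fixture_promoter_variants()
  m370 <- apply_variant(wt, muts[["c.-370T>C"]])
  expect_equal(nchar(m370), 1824)
  idx <- 1824 - 370 + 1
  expect_equal(substr(wt, idx, idx), "T")
  expect_equal(substr(m370, idx, idx), "C")
  expect_equal(sum(strsplit(wt, "")[[1]] != strsplit(m370, "")[[1]]), 1)

  dup <- apply_variant(wt, muts[["c.-339_361dup"]])
  expect_equal(nchar(dup), 1824 + 22)
  i1 <- 1824 - 361 + 1; i2 <- 1824 - 340 + 1
  expect_equal(substr(dup, i2 + 1, i2 + 22), substr(wt, i1, i2))  # tandem copy
  expect_equal(substr(dup, 1, i2), substr(wt, 1, i2))

  expect_error(apply_variant(wt, promoter_snv(-370, "A", "G")),
               "reference mismatch")
})

test_that("the duplicated span matches the genome-plus-strand insert", {
  wt <- fixture_promoter_wt()
  i1 <- 1824 - 361 + 1; i2 <- 1824 - 340 + 1
  expect_equal(substr(wt, i1, i2), revcomp("CCGGTTCCGGCGGCCGGGGCTG"))
})

test_that("point-mass PWMs hit exactly their consensus occurrences", {
  consensus <- c("A", "C", "G", "G")  # non-palindromic
  m <- matrix(1e-9, nrow = 4, ncol = 4,
              dimnames = list(c("A", "C", "G", "T"), NULL))
  for (k in 1:4) m[consensus[k], k] <- 1 - 3e-9
  x <- pwm("ACGG", m)
  h1 <- scan_pwm("ACGG", x)
  expect_equal(nrow(h1), 1)
  expect_equal(h1$start, 1)
  expect_equal(h1$strand, "+")
  expect_equal(h1$score, pedcascade:::pwm_max_score(x), tolerance = 1e-6)
  h2 <- scan_pwm("ACGGACGG", x)
  expect_equal(h2$start[h2$strand == "+"], c(1, 5))
  # reverse complement target scores identically on the minus strand
  h3 <- scan_pwm(revcomp("ACGG"), x)
  expect_equal(h3$strand, "-")
  expect_equal(h3$score, h1$score, tolerance = 1e-9)
})

test_that("scanning agrees with an independent window scorer and Biostrings", {
  x <- random_pwm(7, width = 6)
  seq <- random_dna(8, 400)
  sc <- oracle_scan_scores(seq, x$mat)
  cut <- x$threshold * pedcascade:::pwm_max_score(x)
  mine <- scan_pwm(seq, x)
  expect_equal(mine$start[mine$strand == "+"], which(sc >= cut))
  bm <- Biostrings::matchPWM(pedcascade:::pwm_logodds(x),
                             Biostrings::DNAString(seq), min.score = cut)
  expect_equal(mine$start[mine$strand == "+"], BiocGenerics::start(bm))
})

test_that("strand symmetry: scanning S with M equals revcomp(S) with revcomp(M)", {
  for (seed in 1:5) {
    x <- random_pwm(seed, width = 5)
    seq <- random_dna(seed + 100, 200)
    a <- scan_pwm(seq, x)
    b <- scan_pwm(revcomp(seq), revcomp_pwm(x))
    # the double flip preserves each physical site: a hit at s reappears at
    # the mirrored window start n-L-s+2 with the same strand label and score
    n <- nchar(seq); L <- 5
    mirror <- function(h, strand) sort((n - L + 2) - h$start[h$strand == strand])
    expect_equal(mirror(a, "+"), sort(b$start[b$strand == "+"]))
    expect_equal(mirror(a, "-"), sort(b$start[b$strand == "-"]))
    expect_equal(sort(a$score), sort(b$score), tolerance = 1e-9)
  }
})

test_that("differential scan calls the packaged gain/loss pattern", {
  wt <- fixture_promoter_wt()
  pwms <- fixture_pwms()
  muts <- fixture_promoter_variants()
  effect_of <- function(variant, tf) {
    v <- muts[[variant]]
    span <- variant_local_span(v, nchar(wt))
    d <- diff_scan(wt, apply_variant(wt, v), span[1], span[2], pwms)
    d$effect[d$tf == tf]
  }
  expect_equal(effect_of("c.-370T>C", "ELK1like"), "gained")
  expect_equal(effect_of("c.-274T>G", "ZNF143like"), "lost")
  expect_equal(effect_of("c.-370T>C", "ZNF143like"), "unchanged")
})

test_that("differential scan of identical sequences is empty of effects", {
  wt <- fixture_promoter_wt()
  d <- diff_scan(wt, wt, 100, 110, c(fixture_pwms(),
                                     list(RND = random_pwm(3))))
  expect_true(all(d$effect == "unchanged"))
  empty <- diff_scan(wt, wt, 100, 110, list())
  expect_equal(nrow(empty), 0)
})

test_that("PWM readers parse JASPAR and MEME text formats identically", {
  jas <- fixture_pwms()
  expect_named(jas, c("ELK1like", "ZNF143like"))
  expect_equal(ncol(jas$ELK1like$mat), 8)
  expect_equal(colSums(jas$ELK1like$mat), rep(1, 8), ignore_attr = TRUE)
  meme <- write_lines_tmp(c(
    "MEME version 4", "", "ALPHABET= ACGT", "",
    "MOTIF ELK1like", "letter-probability matrix: alength= 4 w= 8",
    apply(t(jas$ELK1like$mat), 1, function(r) paste(sprintf("%.6f", r),
                                                    collapse = " "))))
  m <- read_meme(meme)
  expect_equal(m$ELK1like$mat, jas$ELK1like$mat, tolerance = 1e-5)
})

test_that("PWM invariants are enforced", {
  bad <- matrix(0.3, 4, 4, dimnames = list(c("A", "C", "G", "T"), NULL))
  expect_error(pwm("X", bad), "sum to 1")
  expect_error(scan_pwm("ACG", random_pwm(1, width = 6)), "shorter")
})

test_that("conservation profiles count matching rows per reference column", {
  aln <- c(r1 = "ACGT", r2 = "ACGT", r3 = "ACGT", r4 = "ACGT")
  prof <- conservation_profile(aln, "r1")
  expect_equal(prof$identity, rep(1, 4))
  aln["r4"] <- "ACTT"
  prof2 <- conservation_profile(aln, "r1")
  expect_equal(prof2$identity, c(1, 1, 0.75, 1))
})

test_that("the toy ortholog alignment keeps the mutated bases in one conserved window", {
  aln <- fixture_alignment()
  expect_equal(unique(nchar(aln)), 145)
  prof <- conservation_profile(aln, "human")
  cols <- fixture_mutation_columns()
  expect_true(all(prof$identity[cols] == 1))  # invariant across orthologs
  win <- conserved_window(prof, cols, cutoff = 0.8)
  expect_false(is.null(win))
  expect_true(win$start <= min(cols) && win$end >= max(cols))
  expect_gte(win$mean_identity, 0.8)
})
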