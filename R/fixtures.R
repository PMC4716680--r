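#' Read a FASTA file as a named character vector
#' @param path FASTA path
#' @return named character vector of sequences
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  stats::setNames(as.character(x), names(x))
}

#' Write named sequences as FASTA
#' @param seqs named character vector
#' @param path output path
#' @export
write_fasta <- function(seqs, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path)
  invisible(path)
}

#' Read a long-format genotype TSV (sample, key, call)
#' @param path TSV path
#' @return a [genotype_table()]
#' @export
read_genotypes <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  genotype_table(tab$sample, tab$key, tab$call)
}

#' Write a genotype table as TSV
#' @param gt a [genotype_table()]
#' @param path output path
#' @export
write_genotypes <- function(gt, path) {
  utils::write.table(gt, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

fixture_path <- function(file) {
  system.file("extdata", file, package = "pedcascade", mustWork = TRUE)
}

#' Packaged case-study variant tables
#'
#' The two published candidate tables of the corneal-dystrophy case study:
#' set 1 (19 rare heterozygous variants in the refined familial locus,
#' whole-genome design) and set 2 (18 variants in the wider founder locus,
#' targeted + whole-genome design with a phase step). Columns beyond the
#' variant fields carry the expected annotation (`closest`, `location`) for
#' cross-checking.
#'
#' @param which 1 or 2
#' @return a [variant_table()] with extra `closest`/`location` columns
#' @export
fixture_table <- function(which = 1) {
  tab <- utils::read.table(fixture_path(sprintf("table%d_variants.tsv", which)),
                           header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  panels <- c("1000G", "UK10K", "GoNL", "ExAC", "UCL")
  pc <- lapply(panels, function(p) list(ac = tab[[paste0("ac_", p)]],
                                        an = tab[[paste0("an_", p)]]))
  names(pc) <- panels
  vt <- variant_table("chr20", tab$pos, tab$ref, tab$alt, tab$id, pc)
  vt$closest <- tab$closest
  vt$location <- tab$location
  vt
}

#' Fixture transcript models for the case-study locus
#'
#' Single-isoform models placed so that every published variant receives its
#' published annotation class. Exon structures are synthetic (the published
#' tables give classes, not exon coordinates); the promoter transcript is a
#' minus-strand gene whose translation start anchors the HGVS c.-N
#' arithmetic, and the missense target carries a spliced CDS for codon
#' classification.
#'
#' @return named list of [transcript_model()]
#' @export
fixture_transcript_models <- function() {
  ex <- function(...) {
    m <- matrix(c(...), ncol = 2, byrow = TRUE)
    data.frame(start = m[, 1], end = m[, 2])
  }
  dz_codons <- rep("GCT", 535)
  dz_codons[1] <- "ATG"
  dz_codons[514] <- "ATA"   # Ile; first-base A>C gives CTA = Leu
  dz_codons[535] <- "TAA"
  list(
    OVOL2 = transcript_model("OVOL2", "chr20", "-",
      ex(18038000, 18039000, 18056800, 18057700),
      translation_start_g = 18057634, cds_end_g = 18056837,
      promoter = interval("chr20", 18057635, 18059458)),
    DZANK1 = transcript_model("DZANK1", "chr20", "-",
      ex(18396000, 18398500),
      translation_start_g = 18398082, cds_end_g = 18396478,
      cds_seq = paste(dz_codons, collapse = "")),
    ZNF133 = transcript_model("ZNF133", "chr20", "+",
      ex(18280000, 18281000, 18299000, 18300000)),
    LINC00851 = transcript_model("LINC00851", "chr20", "+",
      ex(18376000, 18376500, 18384500, 18385000)),
    POLR3F = transcript_model("POLR3F", "chr20", "+",
      ex(18470000, 18470500, 18479500, 18480000)),
    DTD1 = transcript_model("DTD1", "chr20", "+",
      ex(18640000, 18640500, 18649500, 18650000)),
    C20orf78 = transcript_model("C20orf78", "chr20", "+",
      ex(18805000, 18811000, 18824000, 18825000)),
    SNX5 = transcript_model("SNX5", "chr20", "+",
      ex(17958000, 17958500, 17965500, 17966000)),
    SLC24A3 = transcript_model("SLC24A3", "chr20", "+",
      ex(19300000, 19300500, 19649500, 19650000))
  )
}

# gene-strand position of c.-N in the 1,824 bp promoter (covering c.-1824..-1)
PROMOTER_LEN <- 1824L

#' Synthetic wild-type promoter sequence
#'
#' A 1,824 bp gene-strand sequence (c.-1824..-1) satisfying every published
#' sequence constraint of the case study: the four mutated positions carry
#' their wild-type bases, the 22 bp span duplicated in the index family
#' matches the published inserted sequence (given on the genome plus
#' strand), and the packaged binding-site designs are present exactly once.
#' It is a synthetic stand-in for the reference promoter, not genomic
#' sequence.
#'
#' @return character scalar of length 1824
#' @export
fixture_promoter_wt <- function() {
  set.seed(2020)
  chars <- sample(DNA_BASES, PROMOTER_LEN, replace = TRUE)
  idx <- function(c_off) promoter_index(c_off, PROMOTER_LEN)
  put <- function(at, s) {
    ss <- strsplit(s, "")[[1]]
    chars[at:(at + length(ss) - 1)] <<- ss
  }
  put(idx(-370), "TCGGAAGT")                  # ELK1-like site born by -370T>C
  put(idx(-361), revcomp(FIXTURE_DUP_INSERT)) # duplicated span, gene strand
  put(idx(-339), "T")                         # plus-strand anchor base is A
  put(idx(-307), "T")
  put(idx(-276), "ACTACAAT")                  # ZNF143-like site killed by -274T>G
  locked <- c(idx(-370):idx(-363), idx(-361):idx(-339), idx(-307),
              idx(-276):idx(-269))
  motifs <- c("CCGGAAGT", revcomp("CCGGAAGT"),
              "ACTACAAT", revcomp("ACTACAAT"))
  designated <- idx(-276)
  for (pass in 1:50) {
    s <- paste(chars, collapse = "")
    occ <- sort(unique(unlist(lapply(motifs, function(m) {
      o <- gregexpr(m, s, fixed = TRUE)[[1]]
      o[o > 0]
    }))))
    occ <- setdiff(occ, designated)
    if (length(occ) == 0) return(s)
    free <- setdiff(occ[[1]]:(occ[[1]] + 7), locked)
    if (length(free) == 0) stop("cannot scrub a constrained motif occurrence")
    chars[free[[1]]] <- setdiff(DNA_BASES, chars[free[[1]]])[[1]]
  }
  stop("promoter scrub did not converge")
}

FIXTURE_DUP_INSERT <- "CCGGTTCCGGCGGCCGGGGCTG"

#' The four case-study promoter variants
#'
#' HGVS labels are carried verbatim from the source annotations (the
#' duplication label is recorded as printed; the applied span follows the
#' genomic annotation, 22 bp).
#'
#' @return named list of [promoter_snv()] / [promoter_dup()]
#' @export
fixture_promoter_variants <- function() {
  list(
    "c.-339_361dup" = promoter_dup(-361, -340, label = "c.-339_361dup"),
    "c.-370T>C" = promoter_snv(-370, "T", "C"),
    "c.-307T>C" = promoter_snv(-307, "T", "C"),
    "c.-274T>G" = promoter_snv(-274, "T", "G")
  )
}

#' Packaged toy PWMs
#' @return named list of [pwm()] (ELK1-like and ZNF143-like)
#' @export
fixture_pwms <- function() {
  read_jaspar(fixture_path("promoter_pwms.jaspar"))
}

#' Index-family cohort pedigree (21 affected / 12 unaffected genotyped)
#'
#' Synthetic multi-generation structure: every affected member descends
#' from the founder through affected parents with married-in ungenotyped
#' spouses; genotyped unaffected members are siblings of affecteds. Ids of
#' the individuals named in the study (two whole-genome-sequenced affecteds,
#' one unaffected relative, eight marker-genotyped affecteds) are preserved.
#'
#' @return a [pedigree()]
#' @export
fixture_br1_pedigree <- function() {
  aff <- c("V:20", "VI:2", "VI:7", "VI:17", "VI:24", "VII:3", "VII:7",
           "VII:13", sprintf("A%02d", 9:21))
  una <- c("VI:22", sprintf("U%02d", 2:12))
  sp <- sprintf("SP%02d", 1:12)
  aff_sex <- ifelse(seq_along(aff) %% 2 == 1, "male", "female")
  sp_sex <- ifelse(aff_sex[1:12] == "male", "female", "male")
  ids <- c(aff, una, sp)
  sex <- c(aff_sex, rep("female", length(una)), sp_sex)
  father <- mother <- rep(NA_character_, length(ids))
  assign_parents <- function(child_idx, couple) {
    if (aff_sex[couple] == "male") {
      father[child_idx] <<- aff[couple]; mother[child_idx] <<- sp[couple]
    } else {
      father[child_idx] <<- sp[couple]; mother[child_idx] <<- aff[couple]
    }
  }
  for (i in 2:21) assign_parents(i, i %/% 2)
  for (j in 1:12) assign_parents(21 + j, j)
  pedigree(fam = "BR1", id = ids, father = father, mother = mother,
           sex = sex,
           affected = c(rep("yes", 21), rep("no", 12), rep("no", 12)),
           genotyped = c(rep(TRUE, 33), rep(FALSE, 12)))
}

#' Founder-cohort pedigree (16 families; 75 affected / 21 unaffected
#' genotyped)
#'
#' Each family has an affected genotyped parent, a married-in spouse
#' (ungenotyped except the directly sequenced father of the index family)
#' and a sibship of affected and unaffected genotyped children.
#'
#' @return a [pedigree()]
#' @export
fixture_czech_pedigree <- function() {
  n_aff_kids <- c(rep(4, 11), rep(3, 5))
  n_un_kids <- c(rep(2, 4), rep(1, 12))
  rows <- list()
  add <- function(fam, id, father, mother, sex, affected, genotyped) {
    rows[[length(rows) + 1]] <<- data.frame(
      fam = fam, id = id, father = father, mother = mother, sex = sex,
      affected = affected, genotyped = genotyped, stringsAsFactors = FALSE)
  }
  for (k in 1:16) {
    fam <- paste0("C", k)
    p <- if (k == 2) "IV:16" else paste0(fam, "-P")
    s <- if (k == 2) "IV:17" else paste0(fam, "-SP")
    add(fam, p, NA, NA, "female", "yes", TRUE)
    add(fam, s, NA, NA, "male", "no", k == 2)
    for (a in seq_len(n_aff_kids[k])) {
      id <- if (k == 2 && a == 1) "V:11" else paste0(fam, "-A", a)
      add(fam, id, s, p, "male", "yes", TRUE)
    }
    for (u in seq_len(n_un_kids[k])) {
      id <- if (k == 2 && u == 1) "V:10" else paste0(fam, "-U", u)
      add(fam, id, s, p, "female", "no", TRUE)
    }
  }
  df <- do.call(rbind, rows)
  pedigree(fam = df$fam, id = df$id, father = df$father, mother = df$mother,
           sex = df$sex, affected = df$affected, genotyped = df$genotyped)
}

br1_samples <- c("VII:3", "VI:24", "VI:22")
czech_samples <- c("V:11", "V:10", "IV:17")

#' Cascade configuration reproducing the index-family whole-genome design
#' @return a [cascade_config()]
#' @export
br1_cascade_config <- function() {
  cascade_config(locus = interval("chr20", 17641482, 18949130),
                 required_het = c("VII:3", "VI:24"),
                 excluded_carrier = "VI:22")
}

#' Cascade configuration reproducing the founder-cohort design (with the
#' married-in-parent phase step)
#' @return a [cascade_config()]
#' @export
czech_cascade_config <- function() {
  cascade_config(locus = interval("chr20", 17335789, 19665902),
                 required_het = "V:11",
                 excluded_carrier = "V:10",
                 phase_parent = "IV:17")
}

# assemble table rows + single-fault decoys into variants/genotypes for the
# three sequenced samples of a cohort
build_cohort_fixture <- function(tab, samples, decoys, pattern_by_fault) {
  panels <- c("1000G", "UK10K", "GoNL", "ExAC", "UCL")
  n_t <- nrow(tab)
  n_d <- nrow(decoys)
  pc <- lapply(panels, function(p) {
    list(ac = c(tab[[paste0("ac_", p)]], decoys[[paste0("ac_", p)]] %||%
                  rep(NA_real_, n_d)),
         an = c(tab[[paste0("an_", p)]], decoys[[paste0("an_", p)]] %||%
                  rep(NA_real_, n_d)))
  })
  names(pc) <- panels
  vt <- variant_table("chr20", c(tab$pos, decoys$pos),
                      c(tab$ref, decoys$ref %||% rep("A", n_d)),
                      c(tab$alt, decoys$alt %||% rep("G", n_d)),
                      c(tab$id, rep(NA_character_, n_d)), pc)
  vt$fault <- c(rep("none", n_t), decoys$fault)
  keys <- variant_key(vt)
  gts <- list()
  for (i in seq_len(nrow(vt))) {
    calls <- pattern_by_fault(vt$fault[i])
    for (s in seq_along(samples)) {
      gts[[length(gts) + 1]] <- data.frame(sample = samples[s],
                                           key = keys[i], call = calls[s],
                                           stringsAsFactors = FALSE)
    }
  }
  g <- do.call(rbind, gts)
  list(variants = vt, genotypes = genotype_table(g$sample, g$key, g$call),
       truth = keys[seq_len(n_t)])
}

#' Index-family fixture variant set (19 true rows + 22 single-fault decoys)
#'
#' Decoys each violate exactly one cascade filter: outside the refined
#' locus, common in a filter panel, carried by the unaffected relative, not
#' shared by both affecteds, or homozygous rather than heterozygous.
#'
#' @return list(variants, genotypes, truth) for samples VII:3, VI:24, VI:22
#' @export
fixture_br1_cohort <- function() {
  maf <- data.frame(
    pos = c(18150001, 18160001, 18170001, 18180001, 18190001, 18200001),
    fault = "frequency",
    ac_1000G = c(300, NA, 26, NA, 1000, NA),
    an_1000G = c(5008, NA, 5008, NA, 5008, NA),
    ac_ExAC = c(NA, 10000, NA, 604, NA, 60325),
    an_ExAC = c(NA, 120650, NA, 120650, NA, 120650),
    stringsAsFactors = FALSE)
  plain <- function(pos, fault) data.frame(pos = pos, fault = fault,
                                           stringsAsFactors = FALSE)
  decoys <- merge_decoys(list(
    plain(c(17000001, 17500000, 17641481, 18949131, 19200000, 19650000),
          "locus"),
    maf,
    plain(c(18210001, 18220001, 18230001, 18240001), "excluded_carrier"),
    plain(c(18250001, 18260001, 18270001, 18310001), "not_shared"),
    plain(c(18320001, 18330001), "hom_alt")))
  build_cohort_fixture(fixture_table(1), br1_samples, decoys,
    pattern_by_fault = function(fault) {
      switch(fault,
             excluded_carrier = c("het", "het", "het"),
             not_shared = c("het", "hom_ref", "hom_ref"),
             hom_alt = c("hom_alt", "het", "hom_ref"),
             c("het", "het", "hom_ref"))
    })
}

merge_decoys <- function(parts) {
  cols <- unique(unlist(lapply(parts, names)))
  do.call(rbind, lapply(parts, function(p) {
    for (c in setdiff(cols, names(p))) p[[c]] <- NA
    p[cols]
  }))
}

#' Founder-cohort fixture variant set (18 true rows + 20 single-fault
#' decoys)
#'
#' Decoys include variants carried by the unaffected sibling and variants
#' carried by the married-in unaffected father (which sit on the unaffected
#' haplotype and must fall to the phase filter).
#'
#' @return list(variants, genotypes, truth) for samples V:11, V:10, IV:17
#' @export
fixture_czech_cohort <- function() {
  maf <- data.frame(
    pos = c(17400001, 17450001, 17500001, 17550001, 17600001),
    fault = "frequency",
    ac_1000G = c(300, NA, 100, NA, 2504),
    an_1000G = c(5008, NA, 5008, NA, 5008),
    ac_ExAC = c(NA, 10000, NA, 1207, NA),
    an_ExAC = c(NA, 120650, NA, 120650, NA),
    stringsAsFactors = FALSE)
  plain <- function(pos, fault) data.frame(pos = pos, fault = fault,
                                           stringsAsFactors = FALSE)
  decoys <- merge_decoys(list(
    plain(c(17335788, 17100000, 19665903, 19800000), "locus"),
    maf,
    plain(c(17650001, 17700001, 17750001, 17800001), "excluded_carrier"),
    plain(c(17850001, 17900001), "not_het"),
    plain(c(18060001, 18070001, 18080001, 18090001, 18100001),
          "phase_married_in")))
  build_cohort_fixture(fixture_table(2), czech_samples, decoys,
    pattern_by_fault = function(fault) {
      switch(fault,
             excluded_carrier = c("het", "het", "hom_ref"),
             not_het = c("hom_ref", "hom_ref", "hom_ref"),
             phase_married_in = c("het", "hom_ref", "het"),
             c("het", "hom_ref", "hom_ref"))
    })
}

#' Cohort segregation genotypes for the causal variants
#'
#' Heterozygous in every genotyped affected member, absent in every
#' genotyped unaffected member, matching the published segregation counts.
#'
#' @param which "br1" (promoter duplication over the 21/12 cohort) or
#'   "czech" (founder promoter SNV over the 75/21 cohort)
#' @return list(key, genotypes, pedigree)
#' @export
fixture_cohort_segregation <- function(which = c("br1", "czech")) {
  which <- match.arg(which)
  if (which == "br1") {
    ped <- fixture_br1_pedigree()
    key <- sprintf("chr20:18057973:A:A%s", FIXTURE_DUP_INSERT)
  } else {
    ped <- fixture_czech_pedigree()
    key <- "chr20:18058004:A:G"
  }
  ids <- ped$id[ped$genotyped]
  call <- ifelse(ped$affected[ped$genotyped] == "yes", "het", "hom_ref")
  list(key = key, genotypes = genotype_table(ids, key, call), pedigree = ped)
}

#' Marker genotype fixture for the index family
#'
#' Eight genotyped affecteds over eight markers spanning 2.7 Mb. Two
#' planted obligate recombinations (one individual on each flank) bound the
#' shared haplotype at the inner marker pair, so refinement returns
#' chr20:17,641,482-18,949,130.
#'
#' @return marker genotype table ([read_markers()] layout)
#' @export
fixture_br1_markers <- function() {
  ids <- c("D20S_L2", "D20S_L1", "M_A", "M_B", "M_C", "M_D",
           "D20S_R1", "D20S_R2")
  pos <- c(17000000, 17400000, 17641482, 18058004, 18500000, 18949130,
           19300000, 19700000)
  affs <- c("V:20", "VI:2", "VI:7", "VI:17", "VI:24", "VII:3", "VII:7",
            "VII:13")
  out <- data.frame(marker = ids, chrom = "chr20", pos = pos,
                    stringsAsFactors = FALSE)
  for (i in seq_along(affs)) {
    gt <- vapply(seq_along(ids), function(j) {
      second <- as.character(2 + ((i + j) %% 3))
      paste(sort(c("1", second)), collapse = "/")
    }, "")
    if (affs[i] == "VII:7") gt[1:2] <- "5/6"     # recombined on the left flank
    if (affs[i] == "VII:13") gt[7:8] <- "5/6"    # recombined on the right flank
    out[[affs[i]]] <- gt
  }
  out
}

#' Toy promoter ortholog alignment
#'
#' Eleven aligned rows over the 145 bp region c.-390..-246 of the synthetic
#' promoter: highly conserved around the four mutated positions (which are
#' invariant across rows), divergent toward the edges. Emulates a
#' multi-species promoter alignment; gaps are not modelled.
#'
#' @return named character vector (reference row "human")
#' @export
fixture_alignment <- function() {
  wt <- fixture_promoter_wt()
  ref <- substr(wt, promoter_index(-390, PROMOTER_LEN),
                promoter_index(-246, PROMOTER_LEN))
  species <- c("chimp", "orangutan", "marmoset", "mouse", "rat", "dog",
               "horse", "bat", "armadillo", "opossum")
  protected <- fixture_mutation_columns()
  core <- 15:131
  set.seed(77)
  rows <- c(human = ref)
  for (sp in species) {
    chars <- strsplit(ref, "")[[1]]
    for (p in seq_along(chars)) {
      if (p %in% protected) next
      rate <- if (p %in% core) 0.03 else 0.45
      if (stats::runif(1) < rate) {
        chars[p] <- sample(setdiff(DNA_BASES, chars[p]), 1)
      }
    }
    rows[[sp]] <- paste(chars, collapse = "")
  }
  rows
}

#' Alignment columns of the four mutated promoter positions
#' @return integer vector of reference positions within the 145 bp window
#' @export
fixture_mutation_columns <- function() {
  first <- promoter_index(-390, PROMOTER_LEN)
  idx <- function(c_off) promoter_index(c_off, PROMOTER_LEN) - first + 1
  c(idx(-370), idx(-361):idx(-340), idx(-307), idx(-274))
}

#' True relative promoter activities used by the reporter-assay generator
#'
#' All four mutant promoters are more active than wild type (normalized to
#' 1), emulating the qualitative published outcome; the magnitudes are
#' generator conventions, not published values.
#'
#' @return named numeric vector
#' @export
fixture_effect_sizes <- function() {
  c("WT" = 1, "c.-339_361dup" = 2.5, "c.-370T>C" = 2.0,
    "c.-307T>C" = 1.8, "c.-274T>G" = 1.6)
}

#' Build every case-study fixture file
#'
#' Writes the complete input bundle for the pipeline into `outdir`: VCF +
#' PED pairs for both cohorts (published rows plus single-fault decoys),
#' cohort segregation genotype tables, the marker genotype fixture,
#' wild-type and mutant promoter FASTAs, the toy ortholog alignment, the
#' regulatory BED, the PWM file, transcript models (YAML) and simulated
#' reporter measurements.
#'
#' @param outdir output directory (created if needed)
#' @return (invisibly) a named list of the written paths plus the in-memory
#'   objects
#' @export
build_paper_fixtures <- function(outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(outdir)) stop("cannot create fixture directory ", outdir)
  p <- function(f) file.path(outdir, f)

  br1 <- fixture_br1_cohort()
  write_vcf(br1$variants, br1$genotypes, p("br1.vcf"), samples = br1_samples)
  write_ped(fixture_br1_pedigree(), p("br1.ped"))

  cz <- fixture_czech_cohort()
  write_vcf(cz$variants, cz$genotypes, p("c2.vcf"), samples = czech_samples)
  write_ped(fixture_czech_pedigree(), p("czech.ped"))

  for (w in c("br1", "czech")) {
    seg <- fixture_cohort_segregation(w)
    write_genotypes(seg$genotypes, p(paste0(w, "_cohort_genotypes.tsv")))
  }
  write_markers(fixture_br1_markers(), p("br1_markers.tsv"))

  wt <- fixture_promoter_wt()
  write_fasta(c(promoter_wt = wt), p("promoter_wt.fa"))
  muts <- fixture_promoter_variants()
  for (nm in names(muts)) {
    safe <- gsub("[^A-Za-z0-9]+", "_", nm)
    write_fasta(stats::setNames(apply_variant(wt, muts[[nm]]), nm),
                p(sprintf("promoter_%s.fa", safe)))
  }
  write_fasta(fixture_alignment(), p("promoter_alignment.fa"))

  write_bed(list(interval("chr20", 18057635, 18059458)), p("regulatory.bed"))
  file.copy(fixture_path("promoter_pwms.jaspar"), p("promoter_pwms.jaspar"),
            overwrite = TRUE)
  models <- fixture_transcript_models()
  write_transcripts_yaml(models, p("transcripts.yaml"))
  lux <- simulate_luciferase(fixture_effect_sizes(), n_bio = 3, n_tech = 3,
                             noise_cv = 0.05, seed = 4)
  utils::write.table(lux, p("luciferase.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)

  invisible(list(dir = outdir, br1 = br1, czech = cz, models = models,
                 promoter_wt = wt, promoter_variants = muts,
                 pwms = fixture_pwms(),
                 br1_config = br1_cascade_config(),
                 czech_config = czech_cascade_config()))
}

model_to_list <- function(m) {
  list(gene = m$gene, chrom = m$chrom, strand = m$strand,
       exons = lapply(m$exons, function(e) list(start = e$start, end = e$end)),
       translation_start_g = if (is.na(m$translation_start_g)) NULL else m$translation_start_g,
       cds_end_g = if (is.na(m$cds_end_g)) NULL else m$cds_end_g,
       promoter = if (is.null(m$promoter)) NULL else
         list(start = m$promoter$start, end = m$promoter$end),
       cds_seq = m$cds_seq)
}

#' Write transcript models as YAML
#' @param models named list of [transcript_model()]
#' @param path output path
#' @export
write_transcripts_yaml <- function(models, path) {
  yaml::write_yaml(lapply(unname(models), model_to_list), path)
  invisible(path)
}

#' Read transcript models from YAML
#' @param path YAML path written by [write_transcripts_yaml()]
#' @return named list of [transcript_model()]
#' @export
read_transcripts_yaml <- function(path) {
  raw <- yaml::read_yaml(path)
  out <- lapply(raw, function(x) {
    transcript_model(
      gene = x$gene, chrom = x$chrom, strand = x$strand,
      exons = data.frame(start = vapply(x$exons, `[[`, 0, "start"),
                         end = vapply(x$exons, `[[`, 0, "end")),
      translation_start_g = x$translation_start_g %||% NA_real_,
      cds_end_g = x$cds_end_g %||% NA_real_,
      promoter = if (is.null(x$promoter)) NULL else
        interval(x$chrom, x$promoter$start, x$promoter$end),
      cds_seq = x$cds_seq)
  })
  stats::setNames(out, vapply(out, `[[`, "", "gene"))
}
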