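#' Simulation configuration
#'
#' Bundles every knob of the synthetic-data generator. Penetrance is fixed
#' at 1 (the disease model throughout this package is fully penetrant
#' autosomal-dominant: carrier and affected are the same set), so it is not
#' a parameter.
#'
#' @param seed integer RNG seed
#' @param generations pedigree depth (>= 2)
#' @param sibship children per reproducing couple (> 0)
#' @param locus [interval()] containing all simulated variants
#' @param n_background number of non-causal variants
#' @param p_rare probability a background variant is rare (MAF < the default
#'   0.5% filter threshold) in every panel where it appears; the remainder
#'   are common in at least one filter panel (default 0.7)
#' @param p_absent probability a background variant is absent ("not
#'   identified") from any given panel (default 0.4)
#' @param panels reference panel names with total allele numbers
#' @param causal list(pos, ref, alt) for the seeded causal variant; must lie
#'   inside `promoter` when one is given
#' @param promoter optional promoter [interval()] constraining the causal
#'   position
#' @return list of class `simulation_config`
#' @export
simulation_config <- function(seed = 1, generations = 4, sibship = 3,
                              locus = interval("chr20", 17641482, 18949130),
                              n_background = 100, p_rare = 0.7,
                              p_absent = 0.4,
                              panels = c("1000G" = 5008, "UK10K" = 7562,
                                         "GoNL" = 998, "ExAC" = 120650,
                                         "UCL" = 200),
                              causal = list(pos = 18058004, ref = "A", alt = "G"),
                              promoter = interval("chr20", 18057635, 18059458)) {
  if (!is.null(promoter) && !interval_contains(promoter, causal$pos)) {
    stop("causal position must lie inside the promoter interval")
  }
  structure(list(seed = seed, generations = generations, sibship = sibship,
                 locus = locus, n_background = n_background, p_rare = p_rare,
                 p_absent = p_absent, panels = panels, causal = causal,
                 promoter = promoter, penetrance = 1.0),
            class = "simulation_config")
}

#' Simulate a fully penetrant autosomal-dominant pedigree
#'
#' Gene-drop simulation: one founder carries the causal allele; every
#' affected individual marries a married-in unaffected spouse and has
#' `sibship` children, each inheriting the causal allele with probability
#' 1/2 from the affected parent. Affection status equals carrier status
#' (penetrance 1 by construction). Unaffected offspring do not reproduce in
#' the simulation, mirroring disease-focused pedigree ascertainment.
#'
#' @param config a [simulation_config()]
#' @return a [pedigree()] with attribute `carriers` (ids carrying the
#'   causal allele)
#' @export
simulate_pedigree <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  if (config$generations < 2) stop("need at least 2 generations")
  if (config$sibship < 1) stop("impossible spec: no offspring anywhere")
  set.seed(config$seed)
  rows <- list()
  add <- function(id, father, mother, sex, affected) {
    rows[[length(rows) + 1]] <<- data.frame(
      id = id, father = father, mother = mother, sex = sex,
      affected = affected, stringsAsFactors = FALSE)
  }
  add("G1-1", NA, NA, "male", "yes")
  add("G1-1sp", NA, NA, "female", "no")
  current <- data.frame(id = "G1-1", sex = "male", spouse = "G1-1sp",
                        stringsAsFactors = FALSE)
  for (g in 2:config$generations) {
    nxt <- list()
    for (r in seq_len(nrow(current))) {
      par <- current[r, ]
      father <- if (par$sex == "male") par$id else par$spouse
      mother <- if (par$sex == "male") par$spouse else par$id
      for (k in seq_len(config$sibship)) {
        id <- sprintf("G%d-%d", g, length(rows) + 1)
        carrier <- stats::runif(1) < 0.5
        sex <- if (stats::runif(1) < 0.5) "male" else "female"
        add(id, father, mother, sex, if (carrier) "yes" else "no")
        if (carrier && g < config$generations) {
          sp <- paste0(id, "sp")
          add(sp, NA, NA, if (sex == "male") "female" else "male", "no")
          nxt[[length(nxt) + 1]] <- data.frame(id = id, sex = sex,
                                               spouse = sp,
                                               stringsAsFactors = FALSE)
        }
      }
    }
    if (length(nxt) == 0) break
    current <- do.call(rbind, nxt)
  }
  df <- do.call(rbind, rows)
  ped <- pedigree(fam = "SIM", id = df$id, father = df$father,
                  mother = df$mother, sex = df$sex, affected = df$affected,
                  genotyped = TRUE)
  attr(ped, "carriers") <- df$id[df$affected == "yes"]
  ped
}

#' Simulate a cohort variant set around a seeded causal variant
#'
#' Background variants get random in-locus positions, random rare/common
#' multi-panel allele frequencies (see [simulation_config()]) and random
#' het calls across samples; the causal variant is heterozygous in every
#' affected and absent from every unaffected individual, and absent from
#' all panels. The returned truth record names the causal key.
#'
#' @param ped a [pedigree()] (typically from [simulate_pedigree()])
#' @param config a [simulation_config()]
#' @return list(variants, genotypes, truth = causal key)
#' @export
simulate_cohort_variants <- function(ped, config) {
  set.seed(config$seed + 1L)
  n <- config$n_background
  span <- config$locus$end - config$locus$start + 1
  if (span < n + 1) stop("locus too small for requested background variants")
  pool <- setdiff(config$locus$start:config$locus$end, config$causal$pos)
  pos <- if (n > 0) sort(sample(pool, n)) else numeric(0)
  base_at <- function(excl, k) sample(setdiff(DNA_BASES, excl), k, replace = TRUE)
  ref <- sample(DNA_BASES, n, replace = TRUE)
  alt <- vapply(ref, function(b) base_at(b, 1), "")
  panels <- config$panels
  ac <- matrix(NA_real_, nrow = n + 1, ncol = length(panels))
  an <- matrix(NA_real_, nrow = n + 1, ncol = length(panels))
  colnames(ac) <- colnames(an) <- names(panels)
  rare <- stats::runif(n) < config$p_rare
  for (i in seq_len(n)) {
    present <- stats::runif(length(panels)) >= config$p_absent
    if (!rare[i]) present[1] <- TRUE  # common variants are seen in panel 1
    for (j in which(present)) {
      an[i, j] <- panels[[j]]
      ac[i, j] <- if (rare[i]) {
        sample(0:max(0, floor(0.004 * panels[[j]])), 1)
      } else {
        round(stats::runif(1, 0.01, 0.2) * panels[[j]])
      }
    }
  }
  pc <- lapply(names(panels), function(p) list(ac = ac[, p], an = an[, p]))
  names(pc) <- names(panels)
  variants <- variant_table(chrom = config$locus$chrom,
                            pos = c(pos, config$causal$pos),
                            ref = c(ref, config$causal$ref),
                            alt = c(alt, config$causal$alt),
                            panel_counts = pc)
  keys <- variant_key(variants)
  causal_key <- keys[[n + 1]]
  samples <- ped$id[ped$genotyped]
  carriers <- affected_ids(ped)
  gts <- list()
  for (i in seq_len(n)) {
    hets <- samples[stats::runif(length(samples)) < 0.3]
    for (s in samples) {
      gts[[length(gts) + 1]] <- data.frame(
        sample = s, key = keys[[i]],
        call = if (s %in% hets) "het" else "hom_ref",
        stringsAsFactors = FALSE)
    }
  }
  for (s in samples) {
    gts[[length(gts) + 1]] <- data.frame(
      sample = s, key = causal_key,
      call = if (s %in% carriers) "het" else "hom_ref",
      stringsAsFactors = FALSE)
  }
  g <- do.call(rbind, gts)
  list(variants = variants,
       genotypes = genotype_table(g$sample, g$key, g$call),
       truth = causal_key)
}

#' Marker panel for haplotype simulation
#'
#' @param markers data frame with columns id, chrom, pos (strictly
#'   increasing)
#' @param founder_alleles named character vector: disease-haplotype allele
#'   per marker id
#' @param n_alleles size of the allele pool for non-disease haplotypes
#' @param breakpoints named list: affected id -> list(pos, side) planting an
#'   obligate recombination; markers on `side` ("left"/"right") of `pos`
#'   leave the disease haplotype
#' @return list of class `marker_panel`
#' @export
marker_panel <- function(markers, founder_alleles, n_alleles = 6,
                         breakpoints = list()) {
  stopifnot(all(diff(markers$pos) > 0))
  for (bp in breakpoints) {
    if (bp$pos < min(markers$pos) || bp$pos > max(markers$pos)) {
      stop("breakpoint at ", bp$pos, " lies outside the marker span")
    }
    stopifnot(bp$side %in% c("left", "right"))
  }
  structure(list(markers = markers, founder_alleles = founder_alleles,
                 n_alleles = n_alleles, breakpoints = breakpoints),
            class = "marker_panel")
}

#' Simulate unphased marker genotypes over a pedigree
#'
#' Every affected individual carries the founder disease haplotype except at
#' markers distal to their planted breakpoint, where the disease chromosome
#' switches to random non-founder alleles; the second chromosome is random
#' throughout. Unaffected individuals get two random non-founder
#' chromosomes. Genotypes are unordered allele pairs (phase is inferred
#' downstream, as with real microsatellite data).
#'
#' @param ped a [pedigree()]
#' @param panel a [marker_panel()]
#' @param seed RNG seed
#' @return marker genotype table in the [read_markers()] layout
#' @export
simulate_marker_genotypes <- function(ped, panel, seed = 1) {
  set.seed(seed)
  mk <- panel$markers
  founder <- panel$founder_alleles[mk$id]
  others <- setdiff(as.character(seq_len(panel$n_alleles) + 1), founder)
  rand_allele <- function(k) sample(others, k, replace = TRUE)
  out <- data.frame(marker = mk$id, chrom = mk$chrom, pos = mk$pos,
                    stringsAsFactors = FALSE)
  for (s in ped$id[ped$genotyped]) {
    if (ped$affected[ped$id == s] == "yes") {
      h1 <- founder
      bp <- panel$breakpoints[[s]]
      if (!is.null(bp)) {
        off <- if (bp$side == "left") mk$pos < bp$pos else mk$pos > bp$pos
        h1[off] <- rand_allele(sum(off))
      }
    } else {
      h1 <- rand_allele(nrow(mk))
    }
    h2 <- rand_allele(nrow(mk))
    out[[s]] <- vapply(seq_len(nrow(mk)), function(j) {
      paste(sort(c(h1[[j]], h2[[j]])), collapse = "/")
    }, "")
  }
  out
}

#' Simulate dual-luciferase reporter measurements
#'
#' Firefly and Renilla signals with multiplicative log-normal noise; the
#' expected normalized activity of construct k equals `effects[k]`, so the
#' generator doubles as the ground truth for parameter-recovery checks.
#'
#' @param effects named numeric vector of true relative activities
#'   (wild-type = 1), all > 0
#' @param n_bio independent experiments per construct (>= 2; one-way ANOVA
#'   is undefined below that)
#' @param n_tech technical replicates per experiment
#' @param noise_cv coefficient of variation of the multiplicative noise
#' @param seed RNG seed
#' @return data frame construct / bio / tech / firefly / renilla
#' @export
simulate_luciferase <- function(effects, n_bio = 3, n_tech = 3,
                                noise_cv = 0.05, seed = 1) {
  stopifnot(all(effects > 0))
  if (n_bio < 2) stop("need >= 2 biological replicates (ANOVA undefined)")
  set.seed(seed)
  sdlog <- sqrt(log(1 + noise_cv^2))
  noise <- function(k) {
    if (noise_cv == 0) rep(1, k) else exp(stats::rnorm(k, -sdlog^2 / 2, sdlog))
  }
  rows <- list()
  for (cn in names(effects)) {
    for (b in seq_len(n_bio)) {
      ren <- 1e5 * noise(n_tech)
      fir <- effects[[cn]] * 2e5 * noise(n_tech) * ren / 1e5
      for (t in seq_len(n_tech)) {
        rows[[length(rows) + 1]] <- data.frame(
          construct = cn, bio = b, tech = t,
          firefly = fir[[t]], renilla = ren[[t]],
          stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, rows)
}
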