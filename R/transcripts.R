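#' Construct a transcript model
#'
#' Minimal single-isoform transcript description: ordered exons, strand,
#' genomic coordinate of the A of the ATG translation start (for coding
#' transcripts), an optional promoter interval, and optionally the spliced
#' CDS sequence on the gene strand (required for missense/synonymous
#' calling). For a minus-strand gene the promoter lies at higher genomic
#' coordinates than the translation start.
#'
#' @param gene gene name
#' @param chrom chromosome
#' @param strand "+" or "-"
#' @param exons list of [interval()] (or data frame with start/end), sorted,
#'   non-overlapping
#' @param translation_start_g genomic coordinate of the A of ATG (`NA` for
#'   non-coding transcripts)
#' @param cds_end_g genomic coordinate of the final CDS base (the far end of
#'   the stop codon); lower than `translation_start_g` on the minus strand
#' @param promoter optional [interval()]
#' @param cds_seq optional spliced CDS on the gene strand (5'->3'),
#'   length = spliced CDS span
#' @return object of class `transcript_model`
#' @export
transcript_model <- function(gene, chrom, strand, exons,
                             translation_start_g = NA_real_,
                             cds_end_g = NA_real_,
                             promoter = NULL, cds_seq = NULL) {
  stopifnot(strand %in% c("+", "-"))
  if (is.data.frame(exons)) {
    exons <- lapply(seq_len(nrow(exons)),
                    function(i) interval(chrom, exons$start[i], exons$end[i]))
  }
  starts <- vapply(exons, `[[`, 0, "start")
  ends <- vapply(exons, `[[`, 0, "end")
  o <- order(starts)
  exons <- exons[o]; starts <- starts[o]; ends <- ends[o]
  if (length(exons) > 1 && any(starts[-1] <= ends[-length(ends)])) {
    stop("exons overlap in transcript ", gene)
  }
  if (!is.na(translation_start_g) &&
      !any(translation_start_g >= starts & translation_start_g <= ends)) {
    stop("translation start of ", gene, " does not lie inside an exon")
  }
  if (!is.null(promoter) && strand == "-" && !is.na(translation_start_g) &&
      promoter$start <= translation_start_g) {
    stop("minus-strand promoter must lie above the translation start")
  }
  if (!is.null(promoter) && strand == "+" && !is.na(translation_start_g) &&
      promoter$end >= translation_start_g) {
    stop("plus-strand promoter must lie below the translation start")
  }
  structure(list(gene = gene, chrom = chrom, strand = strand, exons = exons,
                 translation_start_g = translation_start_g,
                 cds_end_g = cds_end_g, promoter = promoter,
                 cds_seq = cds_seq),
            class = "transcript_model")
}

transcript_span <- function(model) {
  interval(model$chrom,
           min(vapply(model$exons, `[[`, 0, "start")),
           max(vapply(model$exons, `[[`, 0, "end")))
}

is_coding <- function(model) !is.na(model$translation_start_g)

#' Annotation classes
#' @export
ANNOTATION_CLASSES <- c("promoter", "intergenic", "deep_intronic",
                        "intronic_near_splice", "missense", "synonymous",
                        "non_coding_transcript", "other_coding")

# spliced CDS coordinate (1-based from the A of ATG) of a genomic position
cds_position <- function(model, pos) {
  lo <- min(model$translation_start_g, model$cds_end_g)
  hi <- max(model$translation_start_g, model$cds_end_g)
  if (pos < lo || pos > hi) return(NA_integer_)
  parts <- Filter(Negate(is.null), lapply(model$exons, function(e) {
    s <- max(e$start, lo); en <- min(e$end, hi)
    if (s > en) NULL else c(s, en)
  }))
  if (model$strand == "+") {
    off <- 0L
    for (p in parts) {
      if (pos >= p[1] && pos <= p[2]) return(off + as.integer(pos - p[1]) + 1L)
      if (p[2] < pos) off <- off + as.integer(p[2] - p[1]) + 1L
    }
  } else {
    off <- 0L
    for (p in rev(parts)) {
      if (pos >= p[1] && pos <= p[2]) return(off + as.integer(p[2] - pos) + 1L)
      if (p[1] > pos) off <- off + as.integer(p[2] - p[1]) + 1L
    }
  }
  NA_integer_
}

classify_coding_snv <- function(model, pos, ref, alt) {
  idx <- cds_position(model, pos)
  if (is.na(idx) || is.null(model$cds_seq)) return("other_coding")
  gene_alt <- if (model$strand == "-") complement_base(alt) else alt
  gene_ref <- if (model$strand == "-") complement_base(ref) else ref
  cds <- strsplit(model$cds_seq, "")[[1]]
  if (idx > length(cds)) return("other_coding")
  if (cds[idx] != gene_ref) {
    stop("reference mismatch in CDS of ", model$gene, " at c.", idx,
         ": model has ", cds[idx], ", variant says ", gene_ref)
  }
  codon_i <- (idx - 1) %/% 3
  codon <- paste(cds[(codon_i * 3 + 1):(codon_i * 3 + 3)], collapse = "")
  mut <- cds
  mut[idx] <- gene_alt
  codon_mut <- paste(mut[(codon_i * 3 + 1):(codon_i * 3 + 3)], collapse = "")
  aa <- Biostrings::GENETIC_CODE[[codon]]
  aa_mut <- Biostrings::GENETIC_CODE[[codon_mut]]
  if (identical(aa, aa_mut)) "synonymous" else "missense"
}

# intron distance: bp from pos to the nearest exon-boundary base of the
# flanking exons; "deep" means strictly more than `deep_distance`
intron_distance <- function(model, pos) {
  ends <- vapply(model$exons, `[[`, 0, "end")
  starts <- vapply(model$exons, `[[`, 0, "start")
  left <- max(ends[ends < pos])
  right <- min(starts[starts > pos])
  min(pos - left, right - pos)
}

#' Classify one variant against transcript models and promoter intervals
#'
#' Precedence when a variant touches several features:
#' promoter > coding (missense/synonymous via the standard codon table on
#' the transcript strand) > intronic (deep iff the distance to the nearest
#' intron-exon boundary exceeds `deep_distance`) > non-coding-transcript
#' exon > intergenic. The nearest transcript is reported alongside the
#' class.
#'
#' @param variant one-row `variant_table` (or list with chrom/pos/ref/alt)
#' @param models list of [transcript_model()]
#' @param deep_distance bp threshold separating deep-intronic from
#'   near-splice positions (default 100; "deep" is strictly greater)
#' @return list with `class`, `closest` (gene name), `distance`
#' @export
annotate_variant <- function(variant, models, deep_distance = 100) {
  pos <- variant$pos
  width <- nchar(variant$ref)
  chroms <- vapply(models, `[[`, "", "chrom")
  if (!variant$chrom %in% chroms) {
    stop("variant chromosome ", variant$chrom,
         " not covered by any supplied transcript model")
  }
  models <- models[chroms == variant$chrom]
  cls <- character()
  for (m in models) {
    if (!is.null(m$promoter) && interval_contains(m$promoter, pos, width)) {
      cls <- c(cls, "promoter")
      next
    }
    span <- transcript_span(m)
    if (!interval_contains(span, pos)) next
    in_exon <- any(vapply(m$exons, interval_contains, TRUE, pos = pos))
    if (in_exon) {
      if (is_coding(m)) {
        lo <- min(m$translation_start_g, m$cds_end_g)
        hi <- max(m$translation_start_g, m$cds_end_g)
        if (pos >= lo && pos <= hi) {
          if (nchar(variant$ref) == 1 && nchar(variant$alt) == 1) {
            cls <- c(cls, classify_coding_snv(m, pos, variant$ref, variant$alt))
          } else {
            cls <- c(cls, "other_coding")
          }
        } else {
          cls <- c(cls, "other_coding")  # UTR exon
        }
      } else {
        cls <- c(cls, "non_coding_transcript")
      }
    } else {
      d <- intron_distance(m, pos)
      cls <- c(cls, if (d > deep_distance) "deep_intronic" else "intronic_near_splice")
    }
  }
  precedence <- c("promoter", "missense", "synonymous", "other_coding",
                  "deep_intronic", "intronic_near_splice",
                  "non_coding_transcript")
  chosen <- precedence[precedence %in% cls][1]
  if (is.na(chosen)) chosen <- "intergenic"
  dists <- vapply(models, function(m) variant_distance(pos, transcript_span(m)), 0L)
  nearest <- which.min(dists)
  list(class = chosen,
       closest = models[[nearest]]$gene,
       distance = dists[[nearest]])
}

#' Class histogram over cascade survivors
#'
#' Annotates every survivor and tabulates the classes; the histogram total
#' always equals the number of survivors.
#'
#' @param survivors a `variant_table`
#' @param models list of [transcript_model()]
#' @param deep_distance see [annotate_variant()]
#' @return named integer vector (observed classes only; empty input gives an
#'   empty vector)
#' @export
classify_survivors <- function(survivors, models, deep_distance = 100) {
  if (nrow(survivors) == 0) return(integer(0))
  cls <- vapply(seq_len(nrow(survivors)), function(i) {
    annotate_variant(survivors[i, ], models, deep_distance)$class
  }, "")
  tab <- table(cls)
  stats::setNames(as.integer(tab), names(tab))
}
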