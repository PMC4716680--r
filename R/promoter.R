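#' Convert an HGVS c.-N promoter offset to a genomic position
#'
#' +1 is the A of the ATG translation initiation codon; negative offsets
#' count upstream of it with no position 0. On a minus-strand gene,
#' upstream means higher genomic coordinates and gene-strand alleles are
#' the complement of the genome plus strand.
#'
#' @param c_offset negative integer offset (c.-N)
#' @param model a [transcript_model()] supplying strand and
#'   `translation_start_g`
#' @return genomic position (numeric)
#' @export
c_to_genomic <- function(c_offset, model) {
  if (any(c_offset == 0)) stop("HGVS c. has no position 0")
  if (any(c_offset > 0)) stop("only upstream (negative) offsets are supported")
  if (model$strand == "-") model$translation_start_g + abs(c_offset)
  else model$translation_start_g - abs(c_offset)
}

#' Convert a genomic position to an HGVS c.-N promoter offset
#'
#' Inverse of [c_to_genomic()] for positions upstream of the translation
#' start.
#'
#' @param pos genomic position
#' @param model a [transcript_model()]
#' @return negative integer offset
#' @export
genomic_to_c <- function(pos, model) {
  off <- if (model$strand == "-") model$translation_start_g - pos
         else pos - model$translation_start_g
  if (any(off >= 0)) stop("position is not upstream of the translation start")
  off
}

#' Convert an allele between gene strand and genome plus strand
#' @param base allele string
#' @param strand transcript strand
#' @return complemented string for minus-strand transcripts, unchanged
#'   otherwise
#' @export
gene_strand_allele <- function(base, strand) {
  if (strand == "-") complement_base(base) else base
}

#' Promoter SNV in transcript-relative coordinates
#' @param c_offset negative offset of the substituted base
#' @param ref,alt gene-strand alleles
#' @param label optional HGVS label carried verbatim
#' @return list of class `promoter_variant`
#' @export
promoter_snv <- function(c_offset, ref, alt, label = NULL) {
  stopifnot(c_offset < 0, nchar(ref) == 1, nchar(alt) == 1, ref != alt)
  structure(list(type = "snv", c_start = c_offset, c_end = c_offset,
                 ref = ref, alt = alt,
                 label = label %||% sprintf("c.%d%s>%s", c_offset, ref, alt)),
            class = "promoter_variant")
}

#' Promoter tandem duplication in transcript-relative coordinates
#'
#' `c_from` is the upstream (more negative) end of the duplicated span,
#' `c_to` the downstream end. The duplicated block is inserted immediately
#' 3' of the original span on the gene strand (HGVS dup semantics).
#'
#' @param c_from,c_to negative offsets bounding the duplicated span
#' @param label optional HGVS label carried verbatim (not re-validated)
#' @return list of class `promoter_variant`
#' @export
promoter_dup <- function(c_from, c_to, label = NULL) {
  stopifnot(c_from < 0, c_to < 0, c_from < c_to)
  structure(list(type = "dup", c_start = c_from, c_end = c_to,
                 ref = NA_character_, alt = NA_character_,
                 label = label %||% sprintf("c.%d_%ddup", c_from, c_to)),
            class = "promoter_variant")
}

promoter_index <- function(c_offset, promoter_len) {
  idx <- promoter_len - abs(c_offset) + 1
  if (any(idx < 1 | idx > promoter_len)) {
    stop("offset c.", c_offset, " outside the ", promoter_len, " bp promoter")
  }
  idx
}

#' Apply a promoter variant to the wild-type sequence
#'
#' The sequence is the gene-strand promoter covering c.-L..-1 (length L,
#' written 5'->3'). SNVs substitute in place after checking the stated
#' reference base; duplications insert a tandem copy immediately 3' of the
#' duplicated span.
#'
#' @param seq wild-type promoter sequence (character scalar)
#' @param variant a [promoter_snv()] or [promoter_dup()]
#' @return the mutant sequence
#' @export
apply_variant <- function(seq, variant) {
  stopifnot(inherits(variant, "promoter_variant"))
  L <- nchar(seq)
  chars <- strsplit(seq, "")[[1]]
  if (variant$type == "snv") {
    idx <- promoter_index(variant$c_start, L)
    if (chars[idx] != variant$ref) {
      stop("reference mismatch at c.", variant$c_start, ": expected ",
           variant$ref, ", found ", chars[idx])
    }
    chars[idx] <- variant$alt
    return(paste(chars, collapse = ""))
  }
  i1 <- promoter_index(variant$c_start, L)
  i2 <- promoter_index(variant$c_end, L)
  paste(c(chars[1:i2], chars[i1:i2],
          if (i2 < L) chars[(i2 + 1):L]), collapse = "")
}

#' Mutated span of a promoter variant in local coordinates
#'
#' The 1-based wild-type sequence positions altered by the variant; used to
#' restrict [diff_scan()] to the mutated neighbourhood.
#'
#' @param variant a `promoter_variant`
#' @param promoter_len wild-type promoter length
#' @return integer vector c(start, end)
#' @export
variant_local_span <- function(variant, promoter_len) {
  c(promoter_index(variant$c_start, promoter_len),
    promoter_index(variant$c_end, promoter_len))
}
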