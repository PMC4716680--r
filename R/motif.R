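#' Construct a position weight matrix
#'
#' @param tf transcription factor name
#' @param mat 4 x L numeric matrix, rows named A/C/G/T, each column a
#'   probability distribution (sums to 1 within 1e-9); L >= 4
#' @param background named base-probability vector (default uniform)
#' @param threshold score cutoff as a fraction of the maximal log-odds score
#'   (default 0.8)
#' @return object of class `pwm`
#' @export
pwm <- function(tf, mat, background = c(A = 0.25, C = 0.25, G = 0.25, T = 0.25),
                threshold = 0.8) {
  mat <- as.matrix(mat)
  stopifnot(nrow(mat) == 4, ncol(mat) >= 4)
  rownames(mat) <- DNA_BASES
  if (any(abs(colSums(mat) - 1) > 1e-9)) {
    stop("PWM columns must each sum to 1")
  }
  stopifnot(all(names(background) == DNA_BASES), threshold > 0, threshold <= 1)
  structure(list(tf = tf, mat = mat, background = background,
                 threshold = threshold), class = "pwm")
}

pwm_logodds <- function(x) log2(x$mat / x$background[rownames(x$mat)])

pwm_max_score <- function(x) sum(apply(pwm_logodds(x), 2, max))

#' Reverse complement of a PWM
#' @param x a [pwm()]
#' @return the [pwm()] modelling the reverse-complement motif
#' @export
revcomp_pwm <- function(x) {
  m <- x$mat[c("T", "G", "C", "A"), rev(seq_len(ncol(x$mat)))]
  rownames(m) <- DNA_BASES
  pwm(x$tf, m, x$background, x$threshold)
}

#' Read PWMs from a JASPAR-format file
#'
#' Expects blocks of the form `>ID name` followed by four lines
#' `A [ 1 2 3 ]` (counts or probabilities; columns are renormalized).
#'
#' @param path file path
#' @param threshold score threshold passed to every [pwm()]
#' @return named list of [pwm()] objects (by TF name)
#' @export
read_jaspar <- function(path, threshold = 0.8) {
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines)]
  heads <- grep("^>", lines)
  out <- list()
  for (h in heads) {
    id_name <- strsplit(sub("^>", "", lines[[h]]), "[ \t]+")[[1]]
    tf <- if (length(id_name) >= 2) id_name[[2]] else id_name[[1]]
    rows <- lines[(h + 1):(h + 4)]
    mat <- t(vapply(rows, function(l) {
      nums <- regmatches(l, gregexpr("[0-9.]+", l))[[1]]
      as.numeric(nums)
    }, numeric(length(regmatches(rows[1], gregexpr("[0-9.]+", rows[1]))[[1]]))))
    base_order <- substr(rows, 1, 1)
    if (!setequal(base_order, DNA_BASES)) {
      stop("JASPAR block for ", tf, " must have A/C/G/T rows")
    }
    mat <- mat[match(DNA_BASES, base_order), , drop = FALSE]
    mat <- sweep(mat, 2, colSums(mat), "/")
    rownames(mat) <- DNA_BASES
    out[[tf]] <- pwm(tf, mat, threshold = threshold)
  }
  out
}

#' Read PWMs from a MEME minimal-format file
#'
#' Supports the `MOTIF name` / `letter-probability matrix:` blocks of the
#' MEME minimal text format (alphabet ACGT).
#'
#' @inheritParams read_jaspar
#' @return named list of [pwm()] objects
#' @export
read_meme <- function(path, threshold = 0.8) {
  lines <- trimws(readLines(path))
  out <- list()
  i <- 1
  while (i <= length(lines)) {
    if (grepl("^MOTIF", lines[[i]])) {
      tf <- strsplit(lines[[i]], "[ \t]+")[[1]][[2]]
      j <- i + 1
      while (j <= length(lines) && !grepl("^letter-probability", lines[[j]])) j <- j + 1
      w <- as.integer(sub(".*w= *([0-9]+).*", "\\1", lines[[j]]))
      block <- lines[(j + 1):(j + w)]
      mat <- t(vapply(block, function(l) as.numeric(strsplit(l, "[ \t]+")[[1]]),
                      numeric(4)))
      mat <- t(mat)
      dimnames(mat) <- NULL
      out[[tf]] <- pwm(tf, mat, threshold = threshold)
      i <- j + w
    }
    i <- i + 1
  }
  out
}

#' Scan a sequence with a PWM on both strands
#'
#' Log-odds score of window w is `sum(log2(p_base / background))`; a hit is
#' any window scoring at least `threshold * max_score`. Minus-strand hits
#' are matches of the reverse-complement motif, reported at the forward
#' coordinate of the window start. Windows containing non-ACGT letters never
#' score as hits. Hits are ordered by (position, strand).
#'
#' @param seq character scalar (the promoter, 5'->3')
#' @param x a [pwm()]
#' @return data frame tf/start/strand/score
#' @export
scan_pwm <- function(seq, x) {
  L <- ncol(x$mat)
  if (nchar(seq) < L) stop("sequence shorter than the motif")
  idx <- match(strsplit(toupper(seq), "")[[1]], DNA_BASES)
  scores_for <- function(lom) {
    n <- length(idx) - L + 1
    vapply(seq_len(n), function(s) {
      win <- idx[s:(s + L - 1)]
      if (anyNA(win)) return(-Inf)
      sum(lom[cbind(win, seq_len(L))])
    }, 0)
  }
  hits <- list()
  for (strand in c("+", "-")) {
    m <- if (strand == "+") x else revcomp_pwm(x)
    sc <- scores_for(pwm_logodds(m))
    cut <- x$threshold * pwm_max_score(x)
    for (s in which(sc >= cut)) {
      hits[[length(hits) + 1]] <- data.frame(tf = x$tf, start = s,
                                             strand = strand,
                                             score = sc[[s]],
                                             stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, hits)
  if (is.null(out)) {
    return(data.frame(tf = character(), start = integer(),
                      strand = character(), score = numeric()))
  }
  out[order(out$start, out$strand), , drop = FALSE]
}

#' Differential motif scan of wild-type versus mutant promoter
#'
#' Scans both sequences with identical thresholds and compares hits in the
#' neighbourhood of the mutated span (the span widened by one motif length
#' on each side; mutant coordinates are mapped back through the insertion
#' offset first). A TF is `gained` iff the mutant has at least one hit
#' overlapping that window and the wild-type none, `lost` in the symmetric
#' case, otherwise `unchanged`.
#'
#' @param wt,mut wild-type and mutant sequences (gene strand)
#' @param var_start,var_end 1-based span of the mutated positions in
#'   wild-type coordinates (for an SNV, `var_start == var_end`; for a
#'   duplication, the duplicated span)
#' @param pwms list of [pwm()]
#' @return data frame of class `motif_diff_report`: tf, effect, wt_hits,
#'   mut_hits, positions
#' @export
diff_scan <- function(wt, mut, var_start, var_end, pwms) {
  ins_len <- nchar(mut) - nchar(wt)
  rows <- lapply(pwms, function(x) {
    L <- ncol(x$mat)
    lo <- var_start - L
    hi <- var_end + L
    wt_hits <- scan_pwm(wt, x)
    wt_hits <- wt_hits[wt_hits$start + L - 1 >= lo & wt_hits$start <= hi, ,
                       drop = FALSE]
    mut_hits <- scan_pwm(mut, x)
    # map mutant coordinates back through the insertion: positions past the
    # inserted block shift left by its length
    mapped <- ifelse(mut_hits$start > var_end, mut_hits$start - ins_len,
                     mut_hits$start)
    mut_hits <- mut_hits[mapped + L - 1 >= lo & mapped <= hi, , drop = FALSE]
    effect <- if (nrow(mut_hits) > 0 && nrow(wt_hits) == 0) "gained"
              else if (nrow(wt_hits) > 0 && nrow(mut_hits) == 0) "lost"
              else "unchanged"
    data.frame(tf = x$tf, effect = effect, wt_hits = nrow(wt_hits),
               mut_hits = nrow(mut_hits),
               positions = paste(unique(c(wt_hits$start, mut_hits$start)),
                                 collapse = ","),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(tf = character(), effect = character(),
                      wt_hits = integer(), mut_hits = integer(),
                      positions = character())
  }
  rownames(out) <- NULL
  class(out) <- c("motif_diff_report", "data.frame")
  out
}

#' Per-column conservation profile of a promoter alignment
#'
#' For every non-gap column of the reference row, the fraction of alignment
#' rows (reference included) matching the reference base.
#'
#' @param aln named character vector of equal-length aligned sequences
#'   (gaps as `-`)
#' @param ref name of the reference row
#' @return data frame `ref_pos` (ungapped position in the reference),
#'   `column` (alignment column), `identity`
#' @export
conservation_profile <- function(aln, ref) {
  stopifnot(ref %in% names(aln))
  lens <- nchar(aln)
  if (length(unique(lens)) != 1) stop("alignment rows differ in length")
  mat <- do.call(rbind, strsplit(toupper(aln), ""))
  ref_row <- mat[ref, ]
  cols <- which(ref_row != "-")
  identity <- vapply(cols, function(j) mean(mat[, j] == ref_row[j]), 0)
  data.frame(ref_pos = seq_along(cols), column = cols, identity = identity)
}

#' Maximal conserved window containing given positions
#'
#' The widest contiguous reference window whose mean identity reaches the
#' cutoff and which contains all the supplied reference positions (e.g. the
#' mutated promoter bases).
#'
#' @param profile result of [conservation_profile()]
#' @param positions reference positions the window must contain
#' @param cutoff mean-identity cutoff (default 0.8)
#' @return list(start, end, mean_identity) in reference positions, or NULL
#'   when no such window exists
#' @export
conserved_window <- function(profile, positions, cutoff = 0.8) {
  id <- profile$identity
  n <- length(id)
  lo <- min(positions); hi <- max(positions)
  if (lo < 1 || hi > n) stop("positions outside the reference")
  best <- NULL
  cs <- cumsum(c(0, id))
  for (i in seq_len(lo)) {
    for (j in hi:n) {
      m <- (cs[j + 1] - cs[i]) / (j - i + 1)
      if (m >= cutoff && (is.null(best) || (j - i) > (best$end - best$start))) {
        best <- list(start = i, end = j, mean_identity = m)
      }
    }
  }
  best
}
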