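#' Reads per kilobase of feature per million mapped reads
#'
#' `count * 1e9 / (length_bp * library_size)`: raw counts normalized by
#' feature length and a library-size factor.
#'
#' @param count non-negative read count (duplicates excluded upstream)
#' @param length_bp feature length in bp (> 0)
#' @param library_size total mapped reads in the library (> 0)
#' @return RPKM value(s)
#' @export
rpkm <- function(count, length_bp, library_size) {
  stopifnot(all(count >= 0), all(length_bp > 0), all(library_size > 0))
  count * 1e9 / (length_bp * library_size)
}

#' Presence call from an RPKM value
#' @param x RPKM value(s)
#' @param cutoff expression threshold (default 1.0)
#' @return logical
#' @export
expressed <- function(x, cutoff = 1.0) {
  stopifnot(all(x >= 0))
  x >= cutoff
}

#' Normalize dual-luciferase reporter measurements
#'
#' Per-well activity is the ratio of firefly to Renilla signal (Renilla
#' controls transfection efficiency). Technical replicates are averaged
#' within each biological replicate, construct activity is the mean of
#' biological-replicate means divided by the wild-type mean, so the
#' wild-type construct is normalized to 1. The reported SD is over
#' biological replicates, on the normalized scale.
#'
#' @param measurements data frame with columns construct, bio, tech,
#'   firefly, renilla (Renilla > 0)
#' @param wildtype label of the wild-type construct
#' @return data frame construct / n_bio / activity / sd, wild-type first
#' @export
normalize_reporter <- function(measurements, wildtype = "WT") {
  stopifnot(all(c("construct", "bio", "firefly", "renilla") %in%
                  names(measurements)))
  if (!wildtype %in% measurements$construct) {
    stop("wild-type construct '", wildtype, "' missing from measurements")
  }
  if (any(measurements$renilla <= 0)) stop("Renilla signals must be positive")
  measurements$ratio <- measurements$firefly / measurements$renilla
  bio_means <- stats::aggregate(ratio ~ construct + bio, measurements, mean)
  wt_mean <- mean(bio_means$ratio[bio_means$construct == wildtype])
  agg <- stats::aggregate(ratio ~ construct, bio_means,
                          function(x) c(n = length(x), mean = mean(x),
                                        sd = stats::sd(x)))
  out <- data.frame(construct = agg$construct,
                    n_bio = agg$ratio[, "n"],
                    activity = agg$ratio[, "mean"] / wt_mean,
                    sd = agg$ratio[, "sd"] / wt_mean,
                    stringsAsFactors = FALSE)
  out[order(out$construct != wildtype, out$construct), , drop = FALSE]
}

#' Per-biological-replicate normalized activities
#'
#' The replication unit for inference is the biological replicate
#' (independent experiment), each summarized as the mean of its technical
#' triplicate, normalized to the wild-type mean.
#'
#' @inheritParams normalize_reporter
#' @return named list of numeric vectors, one per construct
#' @export
reporter_groups <- function(measurements, wildtype = "WT") {
  measurements$ratio <- measurements$firefly / measurements$renilla
  bio_means <- stats::aggregate(ratio ~ construct + bio, measurements, mean)
  wt_mean <- mean(bio_means$ratio[bio_means$construct == wildtype])
  split(bio_means$ratio / wt_mean, bio_means$construct)
}

#' Classical one-way ANOVA
#'
#' Equal-variance fixed-effects one-way ANOVA: F is the ratio of between- to
#' within-group mean squares, p comes from the F distribution. Degenerate
#' input with zero between-group sum of squares returns F = 0, p = 1.
#'
#' @param groups list of numeric vectors (>= 2 groups, each >= 2 values)
#' @return list(F, p, df1, df2)
#' @export
anova_one_way <- function(groups) {
  k <- length(groups)
  n_i <- lengths(groups)
  if (k < 2 || any(n_i < 2)) {
    stop("one-way ANOVA needs >= 2 groups with >= 2 observations each")
  }
  n <- sum(n_i)
  grand <- mean(unlist(groups))
  ssb <- sum(n_i * (vapply(groups, mean, 0) - grand)^2)
  ssw <- sum(vapply(groups, function(g) sum((g - mean(g))^2), 0))
  df1 <- k - 1
  df2 <- n - k
  if (ssb <= .Machine$double.eps * max(1, ssw)) {
    return(list(F = 0, p = 1, df1 = df1, df2 = df2))
  }
  F <- (ssb / df1) / (ssw / df2)
  list(F = F, p = stats::pf(F, df1, df2, lower.tail = FALSE),
       df1 = df1, df2 = df2)
}
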