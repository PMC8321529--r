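as_granges <- function(df) {
  if (any(df$start < 0) || any(df$start >= df$end))
    stop("invalid interval coordinates (require 0 <= start < end)")
  GenomicRanges::GRanges(df$chrom,
                         IRanges::IRanges(start = df$start + 1, end = df$end))
}

granges_to_df <- function(gr) {
  data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr) - 1,
             end = GenomicRanges::end(gr),
             stringsAsFactors = FALSE)
}

#' Merge overlapping and bookended intervals
#'
#' Sorts intervals and merges overlapping or directly adjacent
#' (end == start) entries; total covered bases are preserved. Coordinates are
#' BED-convention 0-based half-open throughout.
#'
#' @param intervals data.frame with `chrom`, `start`, `end`.
#' @return Merged, sorted data.frame.
#' @export
merge_intervals <- function(intervals) {
  if (!nrow(intervals)) return(intervals[c("chrom", "start", "end")])
  granges_to_df(GenomicRanges::reduce(as_granges(intervals)))
}

#' Fraction of region bases covered by peaks
#'
#' `(bases of regions intersect peaks) / (bases of regions)`; both sets are
#' merged internally, so the result is invariant to input order and
#' fragmentation.
#'
#' @param regions,peaks Interval data.frames (`chrom`, `start`, `end`).
#' @return A fraction in `[0, 1]`.
#' @export
fraction_covered <- function(regions, peaks) {
  if (!nrow(regions)) stop("empty region set")
  rg <- GenomicRanges::reduce(as_granges(regions))
  if (!nrow(peaks)) return(0)
  pg <- GenomicRanges::reduce(as_granges(peaks))
  ov <- GenomicRanges::intersect(rg, pg)
  sum(as.numeric(GenomicRanges::width(ov))) /
    sum(as.numeric(GenomicRanges::width(rg)))
}

# Prefix-sum representation of a merged peak set, for the fast permutation
# path: covered(x) = number of covered bases in [0, x) per chrom.
peaks_prefix <- function(peaks) {
  pk <- merge_intervals(peaks)
  lapply(split(pk, pk$chrom), function(p) {
    o <- order(p$start)
    list(start = p$start[o], end = p$end[o],
         cum = c(0, cumsum(p$end[o] - p$start[o])))
  })
}

covered_upto <- function(prefix_chrom, x) {
  s <- prefix_chrom$start; e <- prefix_chrom$end; cum <- prefix_chrom$cum
  i <- findInterval(x, s) # index of last merged peak starting at or before x
  j <- pmax(i, 1L)        # for i = 0, cum[1] = 0 and the clip term vanishes
  cum[j] + pmin(pmax(x - s[j], 0), e[j] - s[j])
}

#' Random placement of regions within their chromosomes
#'
#' Each replicate preserves the multiset of region lengths; every region is
#' re-placed uniformly over valid start positions on its own chromosome,
#' independently across regions and replicates. Reproducible under `seed`.
#'
#' @param regions Interval data.frame.
#' @param genome data.frame with `chrom`, `length`.
#' @param n Number of replicates.
#' @param seed Integer seed.
#' @param cross_chromosome Place regions on a chromosome drawn with
#'   probability proportional to its length instead of their own (default
#'   FALSE).
#' @return List of `n` interval data.frames.
#' @export
permute_regions <- function(regions, genome, n, seed = 1L,
                            cross_chromosome = FALSE) {
  stopifnot(n >= 1)
  set.seed(as.integer(seed))
  len <- regions$end - regions$start
  glen <- stats::setNames(genome$length, genome$chrom)
  if (any(!(regions$chrom %in% names(glen))))
    stop("region chromosome absent from genome")
  if (!cross_chromosome && any(len > glen[regions$chrom]))
    stop("region longer than its chromosome")
  lapply(seq_len(n), function(i) {
    chrom <- if (cross_chromosome)
      sample(genome$chrom, nrow(regions), replace = TRUE,
             prob = genome$length) else regions$chrom
    maxstart <- glen[chrom] - len
    if (any(maxstart < 0)) stop("region longer than target chromosome")
    start <- floor(stats::runif(nrow(regions), 0, maxstart + 1))
    data.frame(chrom = chrom, start = start, end = start + len,
               stringsAsFactors = FALSE)
  })
}

#' Empirical permutation p-value for depletion
#'
#' `P = (M + 1) / (N + 1)` where `M` counts null replicates strictly below
#' the observed value and `N` is the number of replicates; bounded in
#' `[1/(N+1), 1]`.
#'
#' @param observed Observed fraction.
#' @param null_values Numeric vector of null replicate fractions (N >= 1).
#' @param side Only `"depletion"` (lower tail) is defined.
#' @return A list of class `"null_distribution"`: `observed`, `null_values`,
#'   `M`, `empirical_p`.
#' @export
empirical_p <- function(observed, null_values, side = "depletion") {
  side <- match.arg(side, "depletion")
  if (!length(null_values)) stop("empty null distribution")
  M <- sum(null_values < observed)
  structure(list(observed = observed, null_values = null_values, M = M,
                 empirical_p = (M + 1) / (length(null_values) + 1)),
            class = "null_distribution")
}

#' Permutation depletion test of peak coverage in a region set
#'
#' Computes the observed fraction of region bases covered by peaks, then
#' compares it against `n` replicates in which the regions are randomly
#' re-placed ([permute_regions()]); the one-sided depletion p-value is
#' `(M + 1)/(N + 1)`. A fast prefix-sum intersection is used inside the
#' permutation loop (identical results to the interval-algebra path).
#'
#' @inheritParams permute_regions
#' @param peaks Peak interval data.frame.
#' @param n Number of permutations (default 1000).
#' @return A `"null_distribution"` (see [empirical_p()]).
#' @export
depletion_test <- function(regions, peaks, genome, n = 1000L, seed = 1L,
                           cross_chromosome = FALSE) {
  regions <- merge_intervals(regions)
  observed <- fraction_covered(regions, peaks)
  prefix <- peaks_prefix(peaks)
  total <- sum(regions$end - regions$start)
  glen <- stats::setNames(genome$length, genome$chrom)
  if (any(!(regions$chrom %in% names(glen))))
    stop("region chromosome absent from genome")
  len <- regions$end - regions$start
  if (any(len > glen[regions$chrom]))
    stop("region longer than its chromosome")
  set.seed(as.integer(seed))
  covered <- numeric(n)
  for (k in seq_len(nrow(regions))) { # vectorized over replicates per region
    ch <- if (cross_chromosome)
      sample(genome$chrom, n, replace = TRUE, prob = genome$length)
    else rep(regions$chrom[k], n)
    start <- floor(stats::runif(n, 0, glen[ch] - len[k] + 1))
    for (cc in unique(ch)) {
      pc <- prefix[[cc]]
      if (is.null(pc)) next
      sel <- ch == cc
      covered[sel] <- covered[sel] +
        covered_upto(pc, start[sel] + len[k]) - covered_upto(pc, start[sel])
    }
  }
  empirical_p(observed, covered / total)
}

#' Extract merged HSD intervals from an SD annotation table
#'
#' Keeps rows whose fractional sequence identity (`fracMatch`) strictly
#' exceeds `threshold` (default 0.98), converts them to intervals and merges
#' overlaps. Accepts UCSC genomicSuperDups-style columns (`chrom`,
#' `chromStart`, `chromEnd`, `fracMatch`) or plain `start`/`end`.
#'
#' @param sd_table data.frame with coordinates and a `fracMatch` column.
#' @param threshold Identity threshold in `[0, 1]`.
#' @return Merged interval data.frame (possibly empty).
#' @export
filter_hsd <- function(sd_table, threshold = 0.98) {
  if (!"fracMatch" %in% names(sd_table))
    stop("missing fracMatch column")
  if (any(sd_table$fracMatch < 0 | sd_table$fracMatch > 1))
    stop("fracMatch values must be in [0, 1]")
  start_col <- if ("chromStart" %in% names(sd_table)) "chromStart" else "start"
  end_col <- if ("chromEnd" %in% names(sd_table)) "chromEnd" else "end"
  keep <- sd_table$fracMatch > threshold
  df <- data.frame(chrom = sd_table$chrom[keep],
                   start = sd_table[[start_col]][keep],
                   end = sd_table[[end_col]][keep],
                   stringsAsFactors = FALSE)
  if (!nrow(df)) return(df)
  merge_intervals(df)
}
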