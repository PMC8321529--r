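#' Construct a position weight matrix
#'
#' @param mat positions x 4 probability matrix with columns A, C, G, T; each
#'   row must sum to 1.
#' @param id Motif identifier.
#' @param background Background nucleotide frequencies (default uniform).
#' @return An object of class `"pwm"`.
#' @export
pwm <- function(mat, id = "motif", background = rep(0.25, 4)) {
  mat <- as.matrix(mat)
  if (ncol(mat) != 4L) stop("PWM must have 4 columns (A, C, G, T)")
  if (nrow(mat) < 2L) stop("PWM length must be >= 2")
  if (any(abs(rowSums(mat) - 1) > 1e-6)) stop("PWM rows must sum to 1")
  if (abs(sum(background) - 1) > 1e-6) stop("background must sum to 1")
  colnames(mat) <- c("A", "C", "G", "T")
  names(background) <- c("A", "C", "G", "T")
  structure(list(id = id, mat = mat, background = background),
            class = "pwm")
}

#' Read motifs in MEME minimal format
#'
#' Parses `MOTIF` blocks with their `letter-probability matrix` sections;
#' background frequencies are taken from the `Background letter frequencies`
#' line if present, else uniform.
#'
#' @param path MEME minimal motif file.
#' @return Named list of [pwm()] objects.
#' @export
read_meme <- function(path) {
  lines <- trimws(readLines(path))
  bg <- rep(0.25, 4)
  bg_at <- grep("^Background letter frequencies", lines)
  if (length(bg_at) && bg_at[1] < length(lines)) {
    toks <- strsplit(lines[bg_at[1] + 1L], "\\s+")[[1]]
    vals <- suppressWarnings(as.numeric(toks))
    freq <- vals[!is.na(vals)]
    lets <- toks[which(!is.na(vals)) - 1L]
    if (length(freq) == 4L) bg <- freq[match(c("A", "C", "G", "T"), lets)]
  }
  starts <- grep("^MOTIF\\b", lines)
  if (!length(starts)) stop("no MOTIF blocks in ", path)
  out <- list()
  for (s in starts) {
    id <- strsplit(lines[s], "\\s+")[[1]][2]
    hdr <- s + which(grepl("^letter-probability matrix",
                           lines[(s + 1):length(lines)]))[1]
    w <- suppressWarnings(
      as.integer(sub(".*w=\\s*(\\d+).*", "\\1", lines[hdr])))
    rows <- lines[(hdr + 1):(hdr + w)]
    mat <- do.call(rbind, lapply(strsplit(rows, "\\s+"), as.numeric))
    out[[id]] <- pwm(mat, id = id, background = bg)
  }
  out
}

revcomp <- function(s) {
  chartr("ACGTN", "TGCAN", paste(rev(strsplit(s, "")[[1]]), collapse = ""))
}

# Discretized null distribution of the log-odds score under the background:
# DP convolution over positions with per-letter scores binned at `bin`.
# Returns list(bins = integer score bins, tail = P(score >= bin)).
pwm_score_null <- function(p, bin = 1e-3, floor_p = 1e-6) {
  mat <- pmax(p$mat, floor_p)
  lod <- log2(mat / rep(p$background, each = nrow(mat)))
  ib <- round(lod / bin) # positions x 4, integer bins
  # DP over positions: dist[j] = P(partial score = run_lo + j - 1)
  run_lo <- 0L
  dist <- 1
  for (i in seq_len(nrow(ib))) {
    mn <- min(ib[i, ]); mx <- max(ib[i, ])
    new <- numeric(length(dist) + (mx - mn))
    for (b in 1:4) {
      sh <- ib[i, b] - mn
      new[(1 + sh):(length(dist) + sh)] <-
        new[(1 + sh):(length(dist) + sh)] + dist * p$background[b]
    }
    dist <- new
    run_lo <- run_lo + mn
  }
  tail <- rev(cumsum(rev(dist)))
  list(bin = bin, ib = ib, lo = run_lo, tail = tail)
}

# p-value of a discretized window score (integer-bin sum) from the null
pwm_score_p <- function(null, score_bins) {
  idx <- score_bins - null$lo + 1L
  idx <- pmin(pmax(idx, 1L), length(null$tail))
  p <- null$tail[idx]
  # scores above the maximum possible cannot occur; below minimum -> p = 1
  p[score_bins > null$lo + length(null$tail) - 1L] <- 0
  pmin(pmax(p, .Machine$double.xmin), 1)
}

scan_one_strand <- function(seq_chars, ib) {
  k <- nrow(ib); L <- length(seq_chars)
  if (L < k) return(NULL)
  code <- match(seq_chars, c("A", "C", "G", "T")) # NA for N
  n_win <- L - k + 1L
  sc <- integer(n_win); ok <- rep(TRUE, n_win)
  for (i in seq_len(k)) {
    ci <- code[i:(i + n_win - 1L)]
    ok <- ok & !is.na(ci)
    ci[is.na(ci)] <- 1L
    sc <- sc + ib[i, ci]
  }
  list(start = which(ok) - 1L, score_bins = sc[ok])
}

#' Scan a sequence with a PWM and assign exact match p-values
#'
#' Scores every window on both strands with the base-2 log-odds of the PWM
#' against its background, computes the exact p-value of each score from the
#' full null score distribution (dynamic programming over positions, scores
#' discretized to `bin`-sized steps), and applies Benjamini-Hochberg across
#' all scanned windows of the scan. Windows containing `N` are skipped.
#'
#' @param sequence Character string over A/C/G/T/N.
#' @param p A [pwm()].
#' @param alpha FDR threshold; hits with `q <= alpha` are returned.
#' @param return_all Return every scanned window regardless of significance.
#' @param bin Score discretization step (default 1e-3).
#' @return data.frame: `motif`, `start` (0-based, forward-strand
#'   coordinates), `strand`, `score`, `p`, `q`.
#' @export
scan_pwm <- function(sequence, p, alpha = 0.05, return_all = FALSE,
                     bin = 1e-3) {
  stopifnot(inherits(p, "pwm"), is.character(sequence),
            length(sequence) == 1L)
  sequence <- toupper(sequence)
  if (grepl("[^ACGTN]", sequence)) stop("sequence must be over A/C/G/T/N")
  k <- nrow(p$mat); L <- nchar(sequence)
  empty <- data.frame(motif = character(), start = integer(),
                      strand = character(), score = numeric(),
                      p = numeric(), q = numeric())
  if (L < k) return(empty)
  null <- pwm_score_null(p, bin = bin)
  fwd <- scan_one_strand(strsplit(sequence, "")[[1]], null$ib)
  rev <- scan_one_strand(strsplit(revcomp(sequence), "")[[1]], null$ib)
  hits <- rbind(
    if (!is.null(fwd) && length(fwd$start))
      data.frame(start = fwd$start, strand = "+",
                 score_bins = fwd$score_bins),
    if (!is.null(rev) && length(rev$start))
      data.frame(start = L - rev$start - k, strand = "-",
                 score_bins = rev$score_bins))
  if (is.null(hits) || !nrow(hits)) return(empty)
  hits$score <- hits$score_bins * bin
  hits$p <- pwm_score_p(null, hits$score_bins)
  hits$q <- stats::p.adjust(hits$p, method = "BH")
  hits <- hits[order(hits$start, hits$strand), ]
  out <- data.frame(motif = p$id, start = hits$start, strand = hits$strand,
                    score = hits$score, p = hits$p, q = hits$q,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  if (return_all) out else out[out$q <= alpha, , drop = FALSE]
}

#' Filter transcription factors by expression breadth
#'
#' Keeps a TF iff it is expressed above `tpm_threshold` in strictly more than
#' `fraction` of libraries.
#'
#' @param tf_tpm_matrix TFs x libraries TPM matrix.
#' @param tpm_threshold Expression threshold (default 1 TPM).
#' @param fraction Required library fraction (strict >; default 0.75).
#' @return Character vector of kept TF identifiers.
#' @export
tf_expression_filter <- function(tf_tpm_matrix, tpm_threshold = 1,
                                 fraction = 0.75) {
  m <- as.matrix(tf_tpm_matrix)
  if (!length(m)) stop("empty TF expression matrix")
  frac <- rowMeans(m > tpm_threshold)
  rownames(m)[frac > fraction]
}

# Map a 0-based ungapped position in `hom` to a 0-based ungapped position in
# `ref` through a pairwise gapped alignment; NA if it lands in a ref gap.
map_through_alignment <- function(aln_ref, aln_hom, pos0) {
  rc <- strsplit(aln_ref, "")[[1]]
  hc <- strsplit(aln_hom, "")[[1]]
  if (length(rc) != length(hc)) stop("alignment strings differ in length")
  hom_idx <- cumsum(hc != "-")
  col <- match(pos0 + 1L, hom_idx)
  if (is.na(col) || rc[col] == "-") return(NA_integer_)
  sum(rc[seq_len(col)] != "-") - 1L
}

#' Compare motif hits across homologous sequences
#'
#' Anchors every hit to the coordinate system of a reference homolog through
#' pairwise alignments, clusters hits of the same motif within
#' `col_window` reference positions into sites, and classifies each site:
#' `shared` (present in every homolog), `paralog_specific_gain` (present in
#' derived paralog(s) only, absent from ancestral and ortholog),
#' `paralog_specific_loss` (absent from exactly one paralog but present in
#' the ortholog and another paralog -- polarity by outgroup), otherwise
#' `unpolarized`. Hits falling in a reference-gap column are excluded from
#' classification and reported with a missing anchor.
#'
#' @param hits Named list of [scan_pwm()] hit tables, one per homolog.
#' @param alignments Named list (same names) of `list(ref=, hom=)` gapped
#'   string pairs aligning each homolog to the reference homolog.
#' @param roles Named character vector: `"ancestral"`, `"derived"`, or
#'   `"ortholog"` per homolog (exactly one ortholog).
#' @param col_window Anchor tolerance in reference positions (default 3).
#' @return data.frame: `motif`, `anchor`, per-homolog presence columns,
#'   `classification`, `gene` (the affected paralog for gains/losses).
#' @export
compare_homologs <- function(hits, alignments, roles, col_window = 3L) {
  homs <- names(roles)
  stopifnot(all(homs %in% names(hits)), all(homs %in% names(alignments)),
            sum(roles == "ortholog") == 1L)
  anchored <- do.call(rbind, lapply(homs, function(h) {
    hh <- hits[[h]]
    if (is.null(hh) || !nrow(hh)) return(NULL)
    aln <- alignments[[h]]
    anchor <- vapply(hh$start, function(s)
      map_through_alignment(aln$ref, aln$hom, s), NA_integer_)
    data.frame(homolog = h, motif = hh$motif, start = hh$start,
               anchor = anchor, stringsAsFactors = FALSE)
  }))
  if (is.null(anchored) || !nrow(anchored))
    return(data.frame(motif = character(), anchor = integer(),
                      classification = character(), gene = character()))
  usable <- anchored[!is.na(anchored$anchor), ]
  out <- list()
  for (m in unique(usable$motif)) {
    mm <- usable[usable$motif == m, ]
    anchors <- sort(unique(mm$anchor))
    grp <- cumsum(c(1L, diff(anchors) > col_window))
    for (g in unique(grp)) {
      site_anchors <- anchors[grp == g]
      present <- vapply(homs, function(h)
        any(mm$homolog == h & mm$anchor %in% site_anchors), NA)
      names(present) <- homs
      anc <- homs[roles == "ancestral"]
      der <- homs[roles == "derived"]
      ort <- homs[roles == "ortholog"]
      paralogs <- c(anc, der)
      cls <- "unpolarized"; gene <- NA_character_
      if (all(present)) {
        cls <- "shared"
      } else if (!present[[ort]] && !any(present[anc]) &&
                 any(present[der])) {
        cls <- "paralog_specific_gain"
        gene <- paste(der[present[der]], collapse = ",")
      } else if (present[[ort]] && sum(!present[paralogs]) == 1L &&
                 sum(present[paralogs]) >= 1L) {
        cls <- "paralog_specific_loss"
        gene <- paralogs[!present[paralogs]]
      }
      out[[length(out) + 1L]] <- data.frame(
        motif = m, anchor = min(site_anchors),
        t(as.data.frame(present)),
        classification = cls, gene = gene, stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
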