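#' EM allocation of multi-mapping reads across candidate loci
#'
#' Iteratively reweights each read's candidate placements by local mapping
#' support. A candidate's support is the unique-read coverage summed over a
#' `window_w`-bp window centered on the candidate start, plus the current
#' posterior mass of *other* multi-mapping reads whose candidates fall in
#' that window, plus a small `epsilon` pseudo-support that prevents absorbing
#' zeros. Responsibilities are renormalized per read each iteration until the
#' largest posterior change falls below `tol` or `max_iter` is reached.
#' Excluding a read's own allocation from its support prevents
#' self-justifying placements in unique-coverage deserts.
#'
#' @param candidates data.frame with columns `read_id`, `chrom`, `pos`
#'   (0-based candidate start), `strand`; one row per candidate placement;
#'   optional `score` column of log alignment-score weights (multiplies
#'   support as `exp(score)`).
#' @param unique_coverage Named list (by chrom) of per-position integer
#'   unique-read depth vectors (position 1 = coordinate 0).
#' @param window_w Odd window width in bp (default 101).
#' @param max_iter,tol Convergence controls.
#' @param epsilon Pseudo-support added to every candidate (default 0.1).
#' @return data.frame of class `"allocation_result"`: the candidate table
#'   plus `posterior`, with attributes `iterations` and `converged`.
#' @export
em_allocate <- function(candidates, unique_coverage, window_w = 101L,
                        max_iter = 200L, tol = 1e-6, epsilon = 0.1) {
  stopifnot(all(c("read_id", "chrom", "pos") %in% names(candidates)),
            window_w > 0, tol > 0, max_iter >= 1)
  if (!"strand" %in% names(candidates)) candidates$strand <- "+"
  if (anyDuplicated(candidates[c("read_id", "chrom", "pos", "strand")]))
    stop("duplicate candidate loci within a read")
  n <- nrow(candidates)
  half <- (as.integer(window_w) - 1L) %/% 2L
  read <- factor(candidates$read_id)
  nread_cand <- table(read)

  # unique-coverage support per candidate via per-chrom prefix sums
  ucov <- numeric(n)
  for (ch in unique(candidates$chrom)) {
    sel <- candidates$chrom == ch
    track <- unique_coverage[[ch]]
    if (is.null(track)) { ucov[sel] <- 0; next }
    cs <- c(0, cumsum(as.numeric(track)))
    L <- length(track)
    lo <- pmax(candidates$pos[sel] - half, 0L)        # 0-based inclusive
    hi <- pmin(candidates$pos[sel] + half + 1L, L)    # 0-based exclusive
    ucov[sel] <- cs[pmin(hi, L) + 1L] - cs[pmin(lo, L) + 1L]
  }
  score_w <- if ("score" %in% names(candidates)) exp(candidates$score) else 1

  # pairs of candidates of the SAME read within each other's window
  # (for the self-exclusion term); same-chrom only
  self_pairs <- NULL
  multi <- names(nread_cand)[nread_cand > 1L]
  if (length(multi)) {
    idx_by_read <- split(seq_len(n), read)
    pr <- lapply(idx_by_read[multi], function(ii) {
      g <- expand.grid(i = ii, j = ii)
      g <- g[g$i != g$j, ]
      same <- candidates$chrom[g$i] == candidates$chrom[g$j] &
        abs(candidates$pos[g$i] - candidates$pos[g$j]) <= half
      g[same, , drop = FALSE]
    })
    self_pairs <- do.call(rbind, pr)
  }

  r <- as.numeric(1 / nread_cand[read]) # uniform init
  iterations <- 0L; converged <- FALSE
  chroms <- unique(candidates$chrom)
  chrom_idx <- split(seq_len(n), candidates$chrom)

  for (it in seq_len(max_iter)) {
    iterations <- it
    # windowed multiread posterior mass around each candidate
    mass <- numeric(n)
    for (ch in chroms) {
      ii <- chrom_idx[[ch]]
      pos <- candidates$pos[ii]
      o <- order(pos)
      ps <- pos[o]
      cum <- c(0, cumsum(r[ii][o]))
      lo <- findInterval(pos - half - 0.5, ps)
      hi <- findInterval(pos + half + 0.5, ps)
      mass[ii] <- cum[hi + 1L] - cum[lo + 1L]
    }
    mass <- mass - r # remove the candidate's own mass (always in own window)
    if (!is.null(self_pairs) && nrow(self_pairs)) {
      sub <- rowsum(r[self_pairs$j], group = self_pairs$i)
      ids <- as.integer(rownames(sub))
      mass[ids] <- mass[ids] - sub[, 1]
    }
    s <- (ucov + pmax(mass, 0) + epsilon) * score_w
    tot <- as.numeric(tapply(s, read, sum))[as.integer(read)]
    r_new <- ifelse(tot > 0, s / tot, r)
    delta <- max(abs(r_new - r))
    r <- r_new
    if (delta < tol) { converged <- TRUE; break }
  }
  out <- candidates
  out$posterior <- r
  attr(out, "iterations") <- iterations
  attr(out, "converged") <- converged
  class(out) <- c("allocation_result", class(out))
  out
}

#' Select a single primary placement per read
#'
#' Argmax of the posterior; exact ties are broken lexicographically by
#' (chrom, position, strand).
#'
#' @param alloc An `"allocation_result"` from [em_allocate()].
#' @return data.frame with one row per read: `read_id`, `chrom`, `pos`,
#'   `strand`, `posterior`.
#' @export
select_primary <- function(alloc) {
  stopifnot(all(c("read_id", "chrom", "pos", "posterior") %in% names(alloc)))
  o <- order(alloc$read_id, -alloc$posterior, alloc$chrom, alloc$pos,
             alloc$strand)
  a <- alloc[o, ]
  out <- a[!duplicated(a$read_id),
           c("read_id", "chrom", "pos", "strand", "posterior")]
  rownames(out) <- NULL
  out
}
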