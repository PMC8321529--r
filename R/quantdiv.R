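#' Expression divergence between a derived and an ancestral paralog
#'
#' Computes the absolute log2 ratio of derived over ancestral expression,
#' `|log2((d + pc) / (a + pc))|`, on (typically median) TPM values. The
#' pseudocount keeps silent genes defined and forces the ratio of two zero
#' values to 1 (divergence 0).
#'
#' @param ancestral_median_tpm Non-negative ancestral expression (TPM).
#' @param derived_median_tpm Non-negative derived expression (TPM).
#' @param pseudocount Positive pseudocount added to both values; the default
#'   1e-4 sits roughly an order of magnitude below the smallest nonzero TPM
#'   seen in dense expression matrices.
#' @return A list of class `"divergence_stat"` with elements `value` (the
#'   absolute log2 ratio) and `pseudocount`.
#' @examples
#' expression_divergence(4, 1)$value  # ~ 2
#' @export
expression_divergence <- function(ancestral_median_tpm, derived_median_tpm,
                                  pseudocount = 1e-4) {
  stopifnot(is.numeric(ancestral_median_tpm), is.numeric(derived_median_tpm),
            length(ancestral_median_tpm) == 1L, length(derived_median_tpm) == 1L,
            is.numeric(pseudocount), pseudocount > 0)
  if (ancestral_median_tpm < 0 || derived_median_tpm < 0)
    stop("TPM values must be non-negative")
  value <- abs(log2((derived_median_tpm + pseudocount) /
                    (ancestral_median_tpm + pseudocount)))
  structure(list(value = value, pseudocount = pseudocount),
            class = "divergence_stat")
}

#' Tissue specificity index tau
#'
#' `tau = sum_i (1 - x_i / max(x)) / (n - 1)`: 0 for a uniform profile, 1 when
#' expression is confined to a single tissue.
#'
#' @param profile Non-negative per-tissue expression vector, length >= 2.
#' @return Tau in `[0, 1]`, or `NA_real_` for an all-zero profile (specificity
#'   is undefined for a silent gene).
#' @export
tau <- function(profile) {
  stopifnot(is.numeric(profile), length(profile) >= 2L)
  if (any(!is.finite(profile)) || any(profile < 0))
    stop("profile must be finite and non-negative")
  m <- max(profile)
  if (m == 0) return(NA_real_)
  sum(1 - profile / m) / (length(profile) - 1L)
}

#' Cross-tissue Pearson correlation between a paralog and the ortholog
#'
#' Standard Pearson correlation on matched per-tissue values. Profiles with
#' zero variance (e.g. a silent paralog) yield `NA_real_` rather than a
#' fabricated correlation, and are expected to be excluded downstream.
#'
#' @param paralog_profile,ortholog_profile Matched numeric vectors
#'   (length >= 3) of per-tissue expression.
#' @export
cross_tissue_correlation <- function(paralog_profile, ortholog_profile) {
  stopifnot(length(paralog_profile) == length(ortholog_profile),
            length(paralog_profile) >= 3L)
  if (any(!is.finite(paralog_profile)) || any(!is.finite(ortholog_profile)))
    stop("profiles must be finite")
  if (stats::sd(paralog_profile) == 0 || stats::sd(ortholog_profile) == 0)
    return(NA_real_)
  stats::cor(paralog_profile, ortholog_profile, method = "pearson")
}

#' Mean log2 expression ratio of a human gene versus its ortholog
#'
#' Per-tissue `log2((h + pc) / (o + pc))` averaged across tissues; the
#' cross-tissue summary of relative expression level between species.
#'
#' @inheritParams cross_tissue_correlation
#' @param human_profile,ortholog_profile matched per-tissue TPM vectors.
#' @param pseudocount positive pseudocount (default 1e-4).
#' @export
relative_expression <- function(human_profile, ortholog_profile,
                                pseudocount = 1e-4) {
  stopifnot(length(human_profile) == length(ortholog_profile),
            pseudocount > 0)
  if (any(human_profile < 0) || any(ortholog_profile < 0))
    stop("TPM values must be non-negative")
  mean(log2((human_profile + pseudocount) / (ortholog_profile + pseudocount)))
}

#' Promoter sequence divergence from a pairwise alignment
#'
#' Counts mismatch columns plus gap columns of a pairwise alignment within
#' +/- `window` columns of the transcription start site. Coordinates are
#' 1-based alignment columns; the window is inclusive at both ends.
#'
#' @param alignment Character vector of two equal-length gapped sequences
#'   (gap = `-`).
#' @param tss_position 1-based alignment column of the TSS.
#' @param window Half-window in columns (default 500).
#' @return Integer count of divergent columns.
#' @export
promoter_divergence <- function(alignment, tss_position, window = 500L) {
  stopifnot(is.character(alignment), length(alignment) == 2L)
  a <- strsplit(toupper(alignment[1]), "")[[1]]
  b <- strsplit(toupper(alignment[2]), "")[[1]]
  if (length(a) != length(b)) stop("aligned sequences must have equal length")
  if (tss_position < 1 || tss_position > length(a))
    stop("TSS position outside alignment")
  lo <- max(1L, as.integer(tss_position) - as.integer(window))
  hi <- min(length(a), as.integer(tss_position) + as.integer(window))
  idx <- lo:hi
  sum(a[idx] != b[idx] | a[idx] == "-" | b[idx] == "-")
}

#' Regress expression divergence on sequence identity
#'
#' Ordinary least-squares fit of divergence on identity with a two-sided test
#' of the slope, plus the Pearson correlation of the two quantities.
#'
#' @param divergences,identities Paired numeric vectors, n >= 3.
#' @return A list with `slope`, `intercept`, `r`, `p_slope`, `n`.
#' @export
divergence_identity_regression <- function(divergences, identities) {
  ok <- is.finite(divergences) & is.finite(identities)
  x <- identities[ok]; y <- divergences[ok]
  if (length(x) < 3L) stop("need at least 3 paired finite values")
  if (stats::sd(x) == 0) stop("identities are constant; slope undefined")
  fit <- stats::lm(y ~ x)
  sm <- summary(fit)$coefficients
  list(slope = unname(sm["x", "Estimate"]),
       intercept = unname(sm["(Intercept)", "Estimate"]),
       r = if (stats::sd(y) == 0) NA_real_ else stats::cor(x, y),
       p_slope = unname(sm["x", "Pr(>|t|)"]),
       n = length(x))
}

#' Double-delta Ct paralog abundance ratio
#'
#' rhAMP-style quantification of the relative abundance of two paralogs that
#' differ at a paralog-specific variant, assayed with two fluorophores
#' (FAM = A paralog, VIC = B paralog). `dCt = Ct_FAM - Ct_VIC` in the test
#' template (cDNA or ChIP) and in the reference template (gDNA or input);
#' `ddCt = dCt_test - dCt_reference`; the B:A abundance ratio is `2^ddCt`.
#'
#' @param ct_fam_test,ct_vic_test Ct values in the test template.
#' @param ct_fam_reference,ct_vic_reference Ct values in the reference
#'   (normalizer) template.
#' @return A list of class `"ddct_result"`: `dct_test`, `dct_reference`,
#'   `ddct`, `ratio` (= `2^ddct`, B relative to A).
#' @export
ddct_ratio <- function(ct_fam_test, ct_vic_test,
                       ct_fam_reference, ct_vic_reference) {
  vals <- c(ct_fam_test, ct_vic_test, ct_fam_reference, ct_vic_reference)
  if (any(!is.finite(vals))) stop("Ct values must be finite")
  dct_test <- ct_fam_test - ct_vic_test
  dct_ref <- ct_fam_reference - ct_vic_reference
  ddct <- dct_test - dct_ref
  structure(list(dct_test = dct_test, dct_reference = dct_ref,
                 ddct = ddct, ratio = 2^ddct),
            class = "ddct_result")
}

# Per-tissue mean TPM matrix (genes x tissues) from an expr_matrix.
tissue_means <- function(em) {
  stopifnot(inherits(em, "expr_matrix"))
  tissues <- unique(em$samples$tissue)
  out <- vapply(tissues, function(tt) {
    cols <- em$samples$sample[em$samples$tissue == tt]
    rowMeans(em$tpm[, cols, drop = FALSE])
  }, numeric(nrow(em$tpm)))
  if (is.null(dim(out))) out <- matrix(out, nrow = 1,
                                       dimnames = list(rownames(em$tpm), tissues))
  out
}

#' Per-family ortholog correlations for fate classification
#'
#' For each gene family, computes the Pearson correlation of each member's
#' cross-tissue profile -- and of the summed family profile -- with the
#' single-copy ortholog profile. Profiles are per-tissue means; by default
#' they are compared on the log2(TPM + pseudocount) scale, which keeps the
#' correlation from being dominated by the single most highly expressed
#' condition.
#'
#' @param human An `expr_matrix` of human paralog expression.
#' @param ortholog An `expr_matrix` of ortholog expression (genes named by
#'   ortholog identifier).
#' @param families Family table (columns `family`, `gene`, `role` with role in
#'   ancestral/derived/ortholog), as written by [simulate_families()].
#' @param log_scale Correlate on log2(TPM + pseudocount) (default) or raw TPM.
#' @param pseudocount Pseudocount for the log transform.
#' @return A data.frame with one row per family member plus one `sum` row:
#'   columns `family`, `gene`, `role`, `r`.
#' @export
family_correlations <- function(human, ortholog, families,
                                log_scale = TRUE, pseudocount = 1e-4) {
  stopifnot(inherits(human, "expr_matrix"), inherits(ortholog, "expr_matrix"))
  hm <- tissue_means(human)
  om <- tissue_means(ortholog)
  tiss <- intersect(colnames(hm), colnames(om))
  if (length(tiss) < 3L) stop("need at least 3 shared tissues")
  hm <- hm[, tiss, drop = FALSE]; om <- om[, tiss, drop = FALSE]
  tf <- if (log_scale) function(x) log2(x + pseudocount) else identity
  res <- lapply(split(families, families$family), function(fam) {
    ort_gene <- fam$gene[fam$role == "ortholog"]
    members <- fam[fam$role %in% c("ancestral", "derived"), , drop = FALSE]
    if (length(ort_gene) != 1L || !(ort_gene %in% rownames(om))) return(NULL)
    o <- tf(om[ort_gene, ])
    rows <- lapply(seq_len(nrow(members)), function(i) {
      g <- members$gene[i]
      r <- if (g %in% rownames(hm))
        cross_tissue_correlation(tf(hm[g, ]), o) else NA_real_
      data.frame(family = fam$family[1], gene = g, role = members$role[i],
                 r = r, stringsAsFactors = FALSE)
    })
    sum_prof <- colSums(hm[intersect(members$gene, rownames(hm)), ,
                           drop = FALSE])
    rows[[length(rows) + 1L]] <-
      data.frame(family = fam$family[1], gene = "sum", role = "sum",
                 r = cross_tissue_correlation(tf(sum_prof), o),
                 stringsAsFactors = FALSE)
    do.call(rbind, rows)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}
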