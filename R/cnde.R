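#' Paired Wilcoxon signed-rank test between paralogs
#'
#' Compares matched per-sample log2(TPM + pseudocount) values of an
#' ancestral-derived pair with a Wilcoxon signed-rank test; zero differences
#' are dropped. The effect is the median paired log2 difference
#' (derived - ancestral).
#'
#' @param ancestral_tpm,derived_tpm Per-sample TPM vectors over the same
#'   samples (n >= 6).
#' @param pseudocount Positive pseudocount (default 1e-4).
#' @return A list: `statistic` (V), `p`, `effect`, `n_nonzero`.
#' @export
pairwise_wilcoxon_de <- function(ancestral_tpm, derived_tpm,
                                 pseudocount = 1e-4) {
  stopifnot(length(ancestral_tpm) == length(derived_tpm),
            length(ancestral_tpm) >= 6L, pseudocount > 0)
  d <- log2(derived_tpm + pseudocount) - log2(ancestral_tpm + pseudocount)
  nz <- d[d != 0]
  if (!length(nz))
    return(list(statistic = 0, p = 1, effect = 0, n_nonzero = 0L))
  wt <- suppressWarnings(stats::wilcox.test(nz, mu = 0))
  list(statistic = unname(wt$statistic), p = wt$p.value,
       effect = stats::median(d), n_nonzero = length(nz))
}

#' Association of expression with copy number
#'
#' Least-squares regression of log2(TPM + pseudocount) on continuous CN with
#' a two-sided slope test. Constant CN is flagged untestable rather than
#' fitted.
#'
#' @param expr Per-sample TPM.
#' @param cn Per-sample continuous CN estimate.
#' @param pseudocount Positive pseudocount.
#' @return A list: `slope`, `p`, `untestable`.
#' @export
cn_expression_association <- function(expr, cn, pseudocount = 1e-4) {
  stopifnot(length(expr) == length(cn), length(expr) >= 10L)
  if (stats::sd(cn) == 0)
    return(list(slope = NA_real_, p = NA_real_, untestable = TRUE))
  y <- log2(expr + pseudocount)
  sm <- summary(stats::lm(y ~ cn))$coefficients
  list(slope = unname(sm["cn", "Estimate"]),
       p = unname(sm["cn", "Pr(>|t|)"]), untestable = FALSE)
}

#' CN-adjusted paralog differential expression test
#'
#' Stacks an ancestral-derived pair into long form and fits
#' `log2(TPM + pc) ~ paralog + CN + paralog:CN`. If the interaction is
#' detected (raw p <= `alpha_interaction`), the pair is reported as
#' `interaction_detected` and the paralog main effect is not tested
#' (paralog-specific CN effects make a single adjusted contrast
#' uninterpretable). Otherwise the model is refit without the interaction and
#' the paralog coefficient is tested.
#'
#' @param a_expr,d_expr Matched per-sample TPM for ancestral and derived.
#' @param a_cn,d_cn Matched per-sample CN for each paralog.
#' @param pseudocount Positive pseudocount.
#' @param alpha_interaction Raw-p screen for the interaction (default 0.05).
#' @return A list: `test` (one of `cn_adjusted_lm`, `interaction_detected`,
#'   `untestable`), `effect` (paralog coefficient, derived - ancestral),
#'   `p` (paralog test; NA when not tested), `p_interaction`.
#' @export
cn_adjusted_pair_test <- function(a_expr, d_expr, a_cn, d_cn,
                                  pseudocount = 1e-4,
                                  alpha_interaction = 0.05) {
  n <- length(a_expr)
  stopifnot(length(d_expr) == n, length(a_cn) == n, length(d_cn) == n)
  df <- data.frame(
    y = log2(c(a_expr, d_expr) + pseudocount),
    paralog = factor(rep(c("ancestral", "derived"), each = n),
                     levels = c("ancestral", "derived")),
    cn = c(a_cn, d_cn))
  if (stats::sd(df$cn) == 0) {
    # CN carries no information: reduce to a paralog location test
    fit <- stats::lm(y ~ paralog, data = df)
    sm <- summary(fit)$coefficients
    return(list(test = "cn_adjusted_lm",
                effect = unname(sm["paralogderived", "Estimate"]),
                p = unname(sm["paralogderived", "Pr(>|t|)"]),
                p_interaction = NA_real_))
  }
  fit1 <- stats::lm(y ~ paralog * cn, data = df)
  if (anyNA(stats::coef(fit1)))
    return(list(test = "untestable", effect = NA_real_, p = NA_real_,
                p_interaction = NA_real_))
  sm1 <- summary(fit1)$coefficients
  p_int <- unname(sm1["paralogderived:cn", "Pr(>|t|)"])
  if (is.finite(p_int) && p_int <= alpha_interaction)
    return(list(test = "interaction_detected",
                effect = unname(sm1["paralogderived:cn", "Estimate"]),
                p = NA_real_, p_interaction = p_int))
  fit0 <- stats::lm(y ~ paralog + cn, data = df)
  sm0 <- summary(fit0)$coefficients
  list(test = "cn_adjusted_lm",
       effect = unname(sm0["paralogderived", "Estimate"]),
       p = unname(sm0["paralogderived", "Pr(>|t|)"]),
       p_interaction = p_int)
}

#' CN-adjusted DE across all ancestral-derived pairs of a family table
#'
#' Runs [cn_adjusted_pair_test()] for every ancestral-derived pair with
#' expression and CN data, then applies Benjamini-Hochberg across the tested
#' pairs; pairs with a detected interaction are reported but carry no q.
#'
#' @param human An [expr_matrix()] of paralog expression.
#' @param cn samples x paralogs CN matrix (rownames = samples).
#' @param families Family/gene/role table.
#' @param pseudocount,alpha_interaction See [cn_adjusted_pair_test()].
#' @param fdr Significance threshold on q (default 0.05).
#' @return data.frame with one row per pair: `family`, `ancestral`,
#'   `derived`, `test`, `effect`, `p`, `q`, `significant`.
#' @export
cn_adjusted_de <- function(human, cn, families, pseudocount = 1e-4,
                           alpha_interaction = 0.05, fdr = 0.05) {
  stopifnot(inherits(human, "expr_matrix"))
  samples <- intersect(colnames(human$tpm), rownames(cn))
  if (length(samples) < 6L) stop("too few samples shared between TPM and CN")
  rows <- list()
  for (fid in unique(families$family)) {
    fam <- families[families$family == fid, ]
    anc <- fam$gene[fam$role == "ancestral"]
    ders <- fam$gene[fam$role == "derived"]
    if (length(anc) != 1L || !(anc %in% rownames(human$tpm)) ||
        !(anc %in% colnames(cn))) next
    for (d in ders) {
      if (!(d %in% rownames(human$tpm)) || !(d %in% colnames(cn))) next
      r <- cn_adjusted_pair_test(human$tpm[anc, samples],
                                 human$tpm[d, samples],
                                 cn[samples, anc], cn[samples, d],
                                 pseudocount = pseudocount,
                                 alpha_interaction = alpha_interaction)
      rows[[length(rows) + 1L]] <- data.frame(
        family = fid, ancestral = anc, derived = d, test = r$test,
        effect = r$effect, p = r$p, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) stop("no testable ancestral-derived pairs")
  out$q <- NA_real_
  tested <- !is.na(out$p)
  out$q[tested] <- stats::p.adjust(out$p[tested], method = "BH")
  out$significant <- !is.na(out$q) & out$q < fdr
  out
}

#' Paired Wilcoxon DE across all ancestral-derived pairs
#'
#' @inheritParams cn_adjusted_de
#' @return data.frame with `family`, `ancestral`, `derived`, `statistic`,
#'   `effect`, `p`, `q`, `significant`.
#' @export
paralog_de <- function(human, families, pseudocount = 1e-4, fdr = 0.05) {
  stopifnot(inherits(human, "expr_matrix"))
  rows <- list()
  for (fid in unique(families$family)) {
    fam <- families[families$family == fid, ]
    anc <- fam$gene[fam$role == "ancestral"]
    ders <- fam$gene[fam$role == "derived"]
    if (length(anc) != 1L || !(anc %in% rownames(human$tpm))) next
    for (d in intersect(ders, rownames(human$tpm))) {
      r <- pairwise_wilcoxon_de(human$tpm[anc, ], human$tpm[d, ],
                                pseudocount = pseudocount)
      rows[[length(rows) + 1L]] <- data.frame(
        family = fid, ancestral = anc, derived = d,
        statistic = r$statistic, effect = r$effect, p = r$p,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) stop("no testable ancestral-derived pairs")
  out$q <- stats::p.adjust(out$p, method = "BH")
  out$significant <- out$q < fdr
  out
}
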