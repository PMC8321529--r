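#' Classify a gene family's expression fate from ortholog correlations
#'
#' Implements the conservation logic: if the summed paralog profile
#' correlates with the ortholog at least `margin` better than the best
#' individual paralog, the family is a subfunctionalization candidate;
#' otherwise the best-correlated individual determines the call (ancestral ->
#' ancestral_conserved, derived -> derived_conserved_candidate). Families with
#' no finite correlation are unclassified. The default margin 0.05 reflects
#' treating sum-vs-best differences in Pearson's r below 0.05 as negligible.
#'
#' @param r_members Named numeric vector of per-paralog correlations with the
#'   ortholog (may contain NA, e.g. for silent paralogs).
#' @param roles Named character vector (same names) with values `"ancestral"`
#'   or `"derived"`.
#' @param r_sum Correlation of the summed family profile with the ortholog.
#' @param margin Required excess of `r_sum` over the best individual.
#' @param family_id Optional identifier carried into the result.
#' @return A list of class `"fate_call"`: `family_id`, `call`, `best_member`,
#'   `r_best`, `r_sum`, `margin_used`.
#' @export
classify_family <- function(r_members, roles, r_sum, margin = 0.05,
                            family_id = NA_character_) {
  stopifnot(length(r_members) == length(roles),
            all(names(r_members) == names(roles)))
  finite <- is.finite(r_members)
  if (!any(finite) && !is.finite(r_sum)) {
    call <- "unclassified"; best <- NA_character_; r_best <- NA_real_
  } else if (!any(finite)) {
    call <- "unclassified"; best <- NA_character_; r_best <- NA_real_
  } else {
    r_best <- max(r_members[finite])
    best <- names(r_members)[finite][which.max(r_members[finite])]
    if (is.finite(r_sum) && (r_sum - r_best) >= margin) {
      call <- "subfunctionalization_candidate"
      best <- "sum"; r_best <- r_sum
    } else {
      call <- if (roles[[best]] == "ancestral") "ancestral_conserved"
              else "derived_conserved_candidate"
    }
  }
  structure(list(family_id = family_id, call = call, best_member = best,
                 r_best = r_best, r_sum = r_sum, margin_used = margin),
            class = "fate_call")
}

#' Classify every family in a correlation table
#'
#' @param correlations Output of [family_correlations()].
#' @param families Family/gene/role table.
#' @param margin See [classify_family()].
#' @return data.frame with one row per family: `family`, `call`,
#'   `best_member`, `r_best`, `r_sum`.
#' @export
classify_families <- function(correlations, families, margin = 0.05) {
  out <- lapply(split(correlations, correlations$family), function(cc) {
    mem <- cc[cc$role %in% c("ancestral", "derived"), ]
    r_sum <- cc$r[cc$role == "sum"]
    if (!length(r_sum)) r_sum <- NA_real_
    r <- stats::setNames(mem$r, mem$gene)
    fc <- classify_family(r, stats::setNames(mem$role, mem$gene),
                          r_sum, margin = margin,
                          family_id = cc$family[1])
    data.frame(family = fc$family_id, call = fc$call,
               best_member = fc$best_member, r_best = fc$r_best,
               r_sum = fc$r_sum, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Fisher's exact test on DE proportions
#'
#' Two-sided exact test of association in a 2x2 contingency table of
#' non-DE / DE counts for ancestral vs. derived genes (or any 2x2 table),
#' summing hypergeometric probabilities not exceeding that of the observed
#' table.
#'
#' @param contingency 2x2 matrix of non-negative integer counts.
#' @return A list with `odds_ratio` (conditional MLE) and `p` (two-sided).
#' @export
fisher_de_proportions <- function(contingency) {
  m <- as.matrix(contingency)
  stopifnot(all(dim(m) == c(2L, 2L)))
  if (any(m < 0) || any(m != round(m))) stop("counts must be non-negative integers")
  if (any(rowSums(m) == 0) || any(colSums(m) == 0))
    stop("empty margin in contingency table")
  ft <- stats::fisher.test(m)
  list(odds_ratio = unname(ft$estimate), p = ft$p.value)
}

#' Enrichment test for the ancestral paralog being the most conserved
#'
#' Given `n_families` families where `k_ancestral_best` of them have the
#' ancestral paralog as their most expression-conserved member, tests the
#' null that the best member is chosen at random within each family.
#'
#' Under the `"equal_choice"` null (default), family i picks its ancestral
#' member with probability `1/size_i` and the tail `P(X >= k)` of the
#' resulting Poisson-binomial distribution is computed exactly by dynamic
#' programming. The `"hypergeometric"` option instead draws `n_families`
#' "best" genes without replacement from the pooled gene set containing one
#' ancestral gene per family.
#'
#' @param n_families Number of families scored.
#' @param k_ancestral_best Families whose best-conserved member is ancestral.
#' @param family_sizes Integer paralog counts per family (all >= 2).
#' @param null `"equal_choice"` or `"hypergeometric"`.
#' @return Upper-tail p-value `P(X >= k)`.
#' @export
most_conserved_enrichment <- function(n_families, k_ancestral_best,
                                      family_sizes,
                                      null = c("equal_choice",
                                               "hypergeometric")) {
  null <- match.arg(null)
  stopifnot(k_ancestral_best <= n_families,
            length(family_sizes) == n_families)
  if (any(family_sizes < 2) || any(family_sizes != round(family_sizes)))
    stop("family sizes must be integers >= 2")
  if (k_ancestral_best <= 0) return(1)
  if (null == "equal_choice") {
    p <- 1 / family_sizes
    dist <- 1 # P(X = 0) after 0 families
    for (pi in p) dist <- c(dist * (1 - pi), 0) + c(0, dist * pi)
    sum(dist[(k_ancestral_best + 1L):(n_families + 1L)])
  } else {
    pool <- sum(family_sizes)
    stats::phyper(k_ancestral_best - 1L, m = n_families,
                  n = pool - n_families, k = n_families, lower.tail = FALSE)
  }
}

# Dunn's post-hoc z tests on pooled ranks with tie correction.
dunn_pairwise <- function(values, groups) {
  N <- length(values)
  r <- rank(values)
  ties <- table(r)
  tie_term <- sum(ties^3 - ties) / (12 * (N - 1))
  rbar <- tapply(r, groups, mean)
  n <- tapply(r, groups, length)
  gs <- names(rbar)
  pairs <- utils::combn(gs, 2L)
  z <- apply(pairs, 2L, function(pr) {
    se <- sqrt((N * (N + 1) / 12 - tie_term) *
               (1 / n[[pr[1]]] + 1 / n[[pr[2]]]))
    (rbar[[pr[1]]] - rbar[[pr[2]]]) / se
  })
  data.frame(group1 = pairs[1, ], group2 = pairs[2, ], z = z,
             p = 2 * stats::pnorm(-abs(z)), stringsAsFactors = FALSE)
}

#' Kruskal-Wallis with Dunn's post-hoc comparisons
#'
#' Rank-based comparison of a statistic (e.g. ortholog correlation or
#' relative expression) across gene classes, followed by Dunn's pairwise
#' z-tests with Benjamini-Hochberg adjustment across pairs.
#'
#' @param values_by_class Named list of numeric vectors, one per class
#'   (e.g. ancestral / derived / sum). Classes with no finite values are
#'   dropped with a warning.
#' @return A list: `H`, `p_kw`, `dunn` (data.frame with z, p and BH `q`).
#' @export
groupwise_tests <- function(values_by_class) {
  keep <- vapply(values_by_class, function(v) any(is.finite(v)), NA)
  if (any(!keep))
    warning("dropping class(es) with no finite values: ",
            paste(names(values_by_class)[!keep], collapse = ", "))
  values_by_class <- lapply(values_by_class[keep],
                            function(v) v[is.finite(v)])
  if (length(values_by_class) < 2L) stop("need at least 2 classes")
  if (any(lengths(values_by_class) < 2L)) stop("each class needs n >= 2")
  values <- unlist(values_by_class, use.names = FALSE)
  groups <- factor(rep(names(values_by_class), lengths(values_by_class)))
  kw <- stats::kruskal.test(values, groups)
  dunn <- dunn_pairwise(values, groups)
  dunn$q <- stats::p.adjust(dunn$p, method = "BH")
  list(H = unname(kw$statistic), p_kw = kw$p.value, dunn = dunn)
}
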