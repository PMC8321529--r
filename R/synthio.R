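# Stage-level RNG: each generator draws from its own stream derived from the
# master seed, so regenerating one stage never perturbs another.
stage_seed <- function(seed, stage) {
  offset <- sum(utf8ToInt(stage)) * 7919
  as.integer((as.numeric(seed) %% 2147483647L * 48271 + offset) %% 2147483647)
}

#' Simulation configuration
#'
#' The stated world for all synthetic generators: 30 gene families of 2-4
#' paralogs (about 75 genes), 7 expression contexts, fate mixture over
#' conserved / pseudogenized / neofunctionalized / subfunctionalized,
#' ~99.5% paralog identity via Poisson paralog-specific variants (PSVs),
#' continuous copy-number genotypes, and a 10-Mb peak landscape with
#' segmental-duplication (SD) intervals.
#'
#' @param n_families Number of gene families.
#' @param paralogs_min,paralogs_max Range of paralogs per family (2-4).
#' @param n_tissues Number of cell/tissue expression contexts (default 7:
#'   emulating four tissues plus three cell lines).
#' @param n_replicates Replicate samples per tissue and species.
#' @param fate_mix Named proportions over the four fates; must sum to 1.
#' @param expression_noise_sd Gaussian noise SD on the log2(TPM + 1e-4) scale.
#' @param baseline_mean,baseline_sd Log2-TPM distribution of per-tissue
#'   ortholog baselines.
#' @param derived_shift Log2 shift of conserved-fate derived paralogs'
#'   independent baseline (expression reduction under relaxed selection).
#' @param psv_rate Substitutions per bp between paralogs (default 0.005,
#'   i.e. ~99.5% identity).
#' @param duplicon_length,read_length,n_reads Read-simulation geometry (bp).
#' @param origin_weights Relative read-sampling weights of the two paralogous
#'   loci; default `c(3, 1)` gives the asymmetric (>= 2:1) coverage world the
#'   allocator recovery property assumes.
#' @param cn_mean,cn_sd Per-paralog continuous copy-number distribution
#'   (Gaussian truncated at 0 around an integer mean).
#' @param genome_length,n_sd,sd_length,n_peaks,peak_width,depletion_factor
#'   Peak-landscape geometry; `depletion_factor` multiplies the retention
#'   probability of peaks overlapping SD intervals (1 = calibrated null,
#'   0 = total depletion).
#' @param seed Integer master seed.
#' @return A validated list of class `"sim_config"`.
#' @export
sim_config <- function(n_families = 30L, paralogs_min = 2L, paralogs_max = 4L,
                       n_tissues = 7L, n_replicates = 3L,
                       fate_mix = c(conserved = 0.40, pseudogenized = 0.25,
                                    neofunctionalized = 0.20,
                                    subfunctionalized = 0.15),
                       expression_noise_sd = 0.25,
                       baseline_mean = 3, baseline_sd = 1.5,
                       derived_shift = -3,
                       psv_rate = 0.005, duplicon_length = 10000L,
                       read_length = 100L, n_reads = 5000L,
                       origin_weights = c(3, 1),
                       cn_mean = 2, cn_sd = 0.5,
                       genome_length = 1e7, n_sd = 30L, sd_length = 5e4,
                       n_peaks = 5000L, peak_width = 400L,
                       depletion_factor = 1,
                       seed = 1L) {
  cfg <- as.list(environment())
  fates <- c("conserved", "pseudogenized", "neofunctionalized",
             "subfunctionalized")
  if (!setequal(names(fate_mix), fates))
    stop("fate_mix must be named over: ", paste(fates, collapse = ", "))
  if (abs(sum(fate_mix) - 1) > 1e-8)
    stop("fate_mix must sum to 1")
  counts <- c(n_families, paralogs_min, paralogs_max, n_tissues, n_replicates,
              duplicon_length, read_length, n_reads, n_sd, n_peaks, peak_width)
  if (any(counts <= 0)) stop("all counts must be positive")
  if (paralogs_min < 2L || paralogs_max > 4L || paralogs_min > paralogs_max)
    stop("paralogs per family must lie in 2-4")
  if (psv_rate < 0 || psv_rate >= 1) stop("psv_rate must be in [0, 1)")
  if (expression_noise_sd < 0) stop("expression_noise_sd must be >= 0")
  if (duplicon_length <= read_length)
    stop("duplicon_length must exceed read_length")
  if (depletion_factor < 0 || depletion_factor > 1)
    stop("depletion_factor must be in [0, 1]")
  cfg$fate_mix <- fate_mix[fates]
  class(cfg) <- "sim_config"
  cfg
}

# Near-binary complementary partition weights for a subfunctionalized family.
# The tissue -> paralog assignment is chosen by a small random search (under
# the family's RNG stream) minimizing the largest individual paralog-ortholog
# correlation on the analysis scale, so the subfunctionalization signature
# (sum correlates best, individuals weakly) holds by construction.
sub_partition <- function(o_log, k, eps = 0.02, n_cand = 200L,
                          pseudocount = 1e-4) {
  nt <- length(o_log)
  o_scale <- log2(2^o_log + pseudocount)
  best <- NULL; best_val <- Inf
  for (i in seq_len(n_cand)) {
    assign <- sample.int(k, nt, replace = TRUE)
    if (length(unique(assign)) < k) next
    w <- matrix(eps, k, nt)
    w[cbind(assign, seq_len(nt))] <- 1 - (k - 1) * eps
    val <- max(vapply(seq_len(k), function(j) {
      prof <- log2(w[j, ] * 2^o_log + pseudocount)
      abs(stats::cor(prof, o_scale))
    }, 0))
    if (val < best_val) { best_val <- val; best <- w }
  }
  if (is.null(best)) { # k == nt corner: one tissue each
    assign <- sample(rep_len(seq_len(k), nt))
    best <- matrix(eps, k, nt)
    best[cbind(assign, seq_len(nt))] <- 1 - (k - 1) * eps
  }
  best
}

# log2(TPM + pc) additive Gaussian noise, mapped back to the TPM scale.
add_expr_noise <- function(true_tpm, sd, pseudocount = 1e-4) {
  if (sd == 0) return(true_tpm)
  obs <- 2^(log2(true_tpm + pseudocount) +
              stats::rnorm(length(true_tpm), 0, sd)) - pseudocount
  pmax(obs, 0)
}

#' Simulate gene families with known expression fates
#'
#' Draws a per-tissue ortholog expression profile for each family, then
#' constructs human paralog profiles according to the family's fate:
#' conserved (ancestral tracks the ortholog, derived independent and
#' reduced), pseudogenized (derived silent), neofunctionalized (derived
#' uncorrelated but expressed), or subfunctionalized (paralogs partition the
#' ortholog profile across tissues so their sum tracks it). Gaussian noise is
#' applied on the log2(TPM + 1e-4) scale.
#'
#' @param config A [sim_config()].
#' @return A list: `human` and `ortholog` (both [expr_matrix()]), `families`
#'   (family/gene/role table), `truth` (list with `fates` per family and
#'   `baseline` true per-tissue TPM per gene).
#' @export
simulate_families <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(stage_seed(config$seed, "families"))
  nt <- config$n_tissues
  tissues <- sprintf("tissue%02d", seq_len(nt))
  ks <- config$paralogs_min:config$paralogs_max
  kprob <- rev(seq_along(ks)) / sum(rev(seq_along(ks))) # smaller families common

  fam_rows <- list(); truth_fates <- list(); base_rows <- list()
  for (i in seq_len(config$n_families)) {
    fid <- sprintf("fam%02d", i)
    k <- if (length(ks) == 1L) ks else sample(ks, 1L, prob = kprob)
    fate <- sample(names(config$fate_mix), 1L, prob = config$fate_mix)
    genes <- c(paste0(fid, "_A"),
               if (k > 1L) paste0(fid, "_D", seq_len(k - 1L)))
    roles <- c("ancestral", rep("derived", k - 1L))
    ort <- paste0(fid, "_ORT")
    o_log <- stats::rnorm(nt, config$baseline_mean, config$baseline_sd)
    o_tpm <- 2^o_log

    prof <- matrix(0, k, nt, dimnames = list(genes, tissues))
    if (fate == "subfunctionalized") {
      w <- sub_partition(o_log, k)
      prof <- w * rep(o_tpm, each = k)
      dimnames(prof) <- list(genes, tissues)
    } else {
      prof[1L, ] <- o_tpm
      if (k > 1L) for (j in 2:k) {
        prof[j, ] <- switch(fate,
          conserved = 2^stats::rnorm(nt, config$baseline_mean +
                                       config$derived_shift,
                                     config$baseline_sd),
          pseudogenized = 0,
          neofunctionalized = 2^stats::rnorm(nt, config$baseline_mean,
                                             config$baseline_sd))
      }
    }

    fam_rows[[i]] <- data.frame(
      family = fid, gene = c(genes, ort),
      role = c(roles, "ortholog"), stringsAsFactors = FALSE)
    truth_fates[[i]] <- data.frame(family = fid, fate = fate,
                                   n_paralogs = k, stringsAsFactors = FALSE)
    base_rows[[i]] <- data.frame(
      gene = rep(c(genes, ort), each = nt),
      tissue = rep(tissues, k + 1L),
      true_tpm = c(t(prof), o_tpm), stringsAsFactors = FALSE)
  }
  families <- do.call(rbind, fam_rows)
  baseline <- do.call(rbind, base_rows)

  make_em <- function(role_filter, prefix) {
    genes <- families$gene[families$role %in% role_filter]
    samples <- data.frame(
      sample = paste0(prefix, rep(tissues, each = config$n_replicates), "_r",
                      seq_len(config$n_replicates)),
      tissue = rep(tissues, each = config$n_replicates),
      stringsAsFactors = FALSE)
    base <- baseline[baseline$gene %in% genes, ]
    tm <- matrix(base$true_tpm[order(match(base$gene, genes))],
                 nrow = length(genes), ncol = nt, byrow = TRUE,
                 dimnames = list(genes, tissues))
    tpm <- tm[, samples$tissue, drop = FALSE]
    colnames(tpm) <- samples$sample
    tpm[] <- add_expr_noise(tpm, config$expression_noise_sd)
    expr_matrix(tpm, samples)
  }
  human <- make_em(c("ancestral", "derived"), "H_")
  ortholog <- make_em("ortholog", "C_")

  list(human = human, ortholog = ortholog, families = families,
       truth = list(fates = do.call(rbind, truth_fates), baseline = baseline))
}

#' Simulate continuous copy-number genotypes
#'
#' Per-sample, per-paralog CN estimates drawn as Gaussian truncated at 0
#' around `cn_mean` (emulating k-mer-based continuous genotypes rather than
#' integer calls).
#'
#' @param config A [sim_config()].
#' @param genes Paralog identifiers (columns).
#' @param samples Sample identifiers (rows); defaults to the expression
#'   sample naming of [simulate_families()].
#' @return samples x paralogs numeric matrix.
#' @export
simulate_cn <- function(config, genes, samples = NULL) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(stage_seed(config$seed, "cn"))
  if (is.null(samples)) {
    tissues <- sprintf("tissue%02d", seq_len(config$n_tissues))
    samples <- paste0("H_", rep(tissues, each = config$n_replicates), "_r",
                      seq_len(config$n_replicates))
  }
  m <- matrix(pmax(0, stats::rnorm(length(samples) * length(genes),
                                   config$cn_mean, config$cn_sd)),
              nrow = length(samples),
              dimnames = list(samples, genes))
  m
}

#' Simulate reads from a pair of near-identical duplicated loci
#'
#' Generates two paralogous sequences differing only at Poisson-placed PSVs,
#' samples reads from known origin loci with the configured coverage
#' asymmetry, and classifies each read as uniquely mapping (overlaps at least
#' one PSV) or multi-mapping (two candidate loci at the homologous offset).
#'
#' @param config A [sim_config()].
#' @return A list: `sequences` (named character, locusA/locusB), `candidates`
#'   (read_id/chrom/pos/strand table, one row per candidate placement),
#'   `unique_coverage` (per-locus integer depth vectors from uniquely mapped
#'   reads), `truth` (read_id, true chrom/pos, n_candidates), `psv_positions`.
#' @export
simulate_duplicated_reads <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(stage_seed(config$seed, "reads"))
  L <- as.integer(config$duplicon_length)
  rl <- as.integer(config$read_length)
  bases <- c("A", "C", "G", "T")
  seqA <- sample(bases, L, replace = TRUE)
  n_psv <- stats::rpois(1L, config$psv_rate * L)
  psv <- sort(sample.int(L, min(n_psv, L)))
  seqB <- seqA
  for (p in psv) seqB[p] <- sample(setdiff(bases, seqA[p]), 1L)

  n <- as.integer(config$n_reads)
  origin <- sample(c("locusA", "locusB"), n, replace = TRUE,
                   prob = config$origin_weights)
  start <- sample.int(L - rl + 1L, n, replace = TRUE) - 1L # 0-based
  # a read is unique iff it covers at least one PSV
  covers <- if (length(psv)) {
    ends <- start + rl # half-open
    vapply(seq_len(n), function(i)
      any(psv > start[i] & psv <= ends[i]), NA) # psv is 1-based
  } else rep(FALSE, n)
  if (all(covers))
    warning("psv_rate so high that no multi-mapping reads were produced")

  read_id <- sprintf("read%06d", seq_len(n))
  cand <- data.frame(read_id = read_id, chrom = origin, pos = start,
                     strand = "+", stringsAsFactors = FALSE)
  if (any(!covers))
    cand <- rbind(cand, data.frame(
      read_id = read_id[!covers],
      chrom = ifelse(origin[!covers] == "locusA", "locusB", "locusA"),
      pos = start[!covers], strand = "+", stringsAsFactors = FALSE))
  cand <- cand[order(cand$read_id, cand$chrom, cand$pos), ]
  rownames(cand) <- NULL

  cov_track <- function(locus) {
    sel <- covers & origin == locus
    cv <- integer(L)
    if (any(sel)) {
      d <- integer(L + 1L)
      s1 <- start[sel] + 1L
      e1 <- pmin(start[sel] + rl, L)
      for (i in seq_along(s1)) {
        d[s1[i]] <- d[s1[i]] + 1L
        d[e1[i] + 1L] <- d[e1[i] + 1L] - 1L
      }
      cv <- cumsum(d[seq_len(L)])
    }
    cv
  }

  list(sequences = c(locusA = paste(seqA, collapse = ""),
                     locusB = paste(seqB, collapse = "")),
       candidates = cand,
       unique_coverage = list(locusA = cov_track("locusA"),
                              locusB = cov_track("locusB")),
       truth = data.frame(read_id = read_id, chrom = origin, pos = start,
                          n_candidates = ifelse(covers, 1L, 2L),
                          stringsAsFactors = FALSE),
       psv_positions = psv)
}

#' Simulate a peak landscape with controlled depletion in SD intervals
#'
#' Places non-overlapping SD intervals on a single synthetic chromosome, then
#' scatters fixed-width peaks uniformly; peaks overlapping an SD are retained
#' with probability `depletion_factor` (1 = no depletion, a calibrated null;
#' 0 = no peak touches an SD).
#'
#' @param config A [sim_config()].
#' @return A list: `genome` (chrom/length table), `peaks` and `sd_intervals`
#'   (BED-convention data.frames), `truth` (per-peak `in_sd` state).
#' @export
simulate_peak_landscape <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(stage_seed(config$seed, "peaks"))
  G <- config$genome_length
  n_sd <- as.integer(config$n_sd)
  sdl <- config$sd_length
  block <- floor(G / n_sd)
  if (block <= sdl)
    stop("genome too small for the requested SD intervals")
  sd_start <- (seq_len(n_sd) - 1L) * block +
    floor(stats::runif(n_sd, 0, block - sdl))
  sds <- data.frame(chrom = "chrS", start = sd_start, end = sd_start + sdl)
  if (any(sds$end > G)) stop("SD interval exceeds chromosome bounds")

  w <- as.integer(config$peak_width)
  pstart <- floor(stats::runif(config$n_peaks, 0, G - w))
  pend <- pstart + w
  in_sd <- rep(FALSE, length(pstart))
  for (j in seq_len(n_sd))
    in_sd <- in_sd | (pstart < sds$end[j] & pend > sds$start[j])
  keep <- !in_sd | (stats::runif(length(pstart)) < config$depletion_factor)
  peaks <- data.frame(chrom = "chrS", start = pstart[keep], end = pend[keep])
  peaks <- peaks[order(peaks$start), ]
  rownames(peaks) <- NULL

  list(genome = data.frame(chrom = "chrS", length = G),
       peaks = peaks, sd_intervals = sds,
       truth = data.frame(start = pstart, end = pend, in_sd = in_sd,
                          kept = keep))
}

# Small three-homolog motif world for the pipeline smoke stage: a strong
# 6-mer site present in the derived paralog and the ortholog but destroyed in
# the ancestral paralog (an ancestral-specific loss, polarized by outgroup).
toy_motif_world <- function(seed = 1L) {
  set.seed(seed)
  bases <- c("A", "C", "G", "T")
  backbone <- sample(bases, 60, replace = TRUE)
  site <- c("T", "G", "A", "C", "T", "C")
  at <- 25:30
  derived <- ortholog <- ancestral <- backbone
  derived[at] <- site; ortholog[at] <- site
  ancestral[at] <- c("T", "G", "A", "A", "T", "C") # core position destroyed
  seqs <- vapply(list(ancestral = ancestral, derived = derived,
                      ortholog = ortholog), paste, "", collapse = "")
  mat <- matrix(0.02, 6, 4, dimnames = list(NULL, bases))
  for (i in seq_along(site)) mat[i, site[i]] <- 0.94
  aln <- lapply(seqs, function(s) list(ref = seqs[["ancestral"]], hom = s))
  list(sequences = seqs,
       pwm = pwm(mat, id = "toySITE"),
       alignments = aln,
       roles = c(ancestral = "ancestral", derived = "derived",
                 ortholog = "ortholog"))
}
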