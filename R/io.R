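#' Construct an expression matrix
#'
#' Container for a genes x samples TPM matrix plus a sample sheet mapping each
#' sample to its tissue / cell-type label.
#'
#' @param tpm Numeric matrix, rows = genes, columns = samples, values = TPM.
#' @param samples data.frame with columns `sample`, `tissue`; `sample` must
#'   match `colnames(tpm)`.
#' @return An object of class `"expr_matrix"`.
#' @export
expr_matrix <- function(tpm, samples) {
  stopifnot(is.matrix(tpm), is.numeric(tpm),
            is.data.frame(samples),
            all(c("sample", "tissue") %in% names(samples)))
  if (any(tpm < 0)) stop("TPM values must be non-negative")
  if (anyDuplicated(rownames(tpm))) stop("duplicate gene identifiers")
  if (anyDuplicated(colnames(tpm))) stop("duplicate sample identifiers")
  if (!setequal(colnames(tpm), samples$sample))
    stop("sample sheet does not match matrix columns")
  samples <- samples[match(colnames(tpm), samples$sample), , drop = FALSE]
  rownames(samples) <- NULL
  structure(list(tpm = tpm, samples = samples), class = "expr_matrix")
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("expr_matrix: %d genes x %d samples (%d tissues)\n",
              nrow(x$tpm), ncol(x$tpm), length(unique(x$samples$tissue))))
  invisible(x)
}

#' Read / write long-format expression TSV
#'
#' Format: tab-separated columns `gene`, `sample`, `tissue`, `TPM`.
#' Duplicate (gene, sample) rows and negative TPM are errors.
#'
#' @param path File path.
#' @return [read_expression()] returns an `expr_matrix`.
#' @export
read_expression <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("gene", "sample", "tissue", "TPM")
  missing <- setdiff(need, names(df))
  if (length(missing))
    stop("expression table is missing column(s): ",
         paste(missing, collapse = ", "))
  if (any(df$TPM < 0)) stop("negative TPM in ", path)
  if (anyDuplicated(df[c("gene", "sample")]))
    stop("duplicate (gene, sample) rows in ", path)
  genes <- unique(df$gene); samps <- unique(df$sample)
  tpm <- matrix(0, length(genes), length(samps),
                dimnames = list(genes, samps))
  tpm[cbind(match(df$gene, genes), match(df$sample, samps))] <- df$TPM
  sheet <- unique(df[c("sample", "tissue")])
  if (anyDuplicated(sheet$sample))
    stop("inconsistent tissue labels for a sample in ", path)
  expr_matrix(tpm, sheet)
}

#' @rdname read_expression
#' @param em An `expr_matrix`.
#' @export
write_expression <- function(em, path) {
  stopifnot(inherits(em, "expr_matrix"))
  df <- data.frame(
    gene = rep(rownames(em$tpm), times = ncol(em$tpm)),
    sample = rep(colnames(em$tpm), each = nrow(em$tpm)),
    tissue = rep(em$samples$tissue, each = nrow(em$tpm)),
    TPM = as.vector(em$tpm))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write gene-family TSV
#'
#' Columns `family`, `gene`, `role` with role one of ancestral / derived /
#' ortholog.
#' @param path File path.
#' @export
read_families <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("family", "gene", "role")
  missing <- setdiff(need, names(df))
  if (length(missing))
    stop("family table is missing column(s): ", paste(missing, collapse = ", "))
  bad <- setdiff(unique(df$role), c("ancestral", "derived", "ortholog"))
  if (length(bad)) stop("unknown role(s): ", paste(bad, collapse = ", "))
  df
}

#' @rdname read_families
#' @param families Family data.frame.
#' @export
write_families <- function(families, path) {
  utils::write.table(families, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a BED file of 0-based half-open intervals
#'
#' Minimal 3+ column BED reader: track/browser lines and `#` comments are
#' skipped; coordinates are validated and malformed lines are reported with
#' their line number.
#'
#' @param path File path.
#' @return data.frame with columns `chrom`, `start`, `end` (0-based
#'   half-open), plus `name` if a 4th column was present.
#' @export
read_bed <- function(path) {
  lines <- readLines(path)
  keep <- !grepl("^(track|browser|#)", lines) & nzchar(lines)
  idx <- which(keep)
  if (!length(idx))
    return(data.frame(chrom = character(), start = integer(),
                      end = integer()))
  parts <- strsplit(lines[idx], "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf < 3L))
    stop("malformed BED line ", idx[which(nf < 3L)[1]], " in ", path,
         ": fewer than 3 fields")
  chrom <- vapply(parts, `[[`, "", 1L)
  start <- suppressWarnings(as.numeric(vapply(parts, `[[`, "", 2L)))
  end <- suppressWarnings(as.numeric(vapply(parts, `[[`, "", 3L)))
  bad <- which(!is.finite(start) | !is.finite(end) | start < 0 | start >= end)
  if (length(bad))
    stop("malformed BED line ", idx[bad[1]], " in ", path,
         ": require 0 <= start < end")
  out <- data.frame(chrom = chrom, start = start, end = end,
                    stringsAsFactors = FALSE)
  if (all(nf >= 4L)) out$name <- vapply(parts, `[[`, "", 4L)
  out
}

#' @rdname read_bed
#' @param intervals data.frame with `chrom`, `start`, `end` (and optional
#'   `name`).
#' @export
write_bed <- function(intervals, path) {
  cols <- c("chrom", "start", "end")
  stopifnot(all(cols %in% names(intervals)))
  df <- intervals[c(cols, intersect("name", names(intervals)))]
  df$start <- format(df$start, scientific = FALSE, trim = TRUE)
  df$end <- format(df$end, scientific = FALSE, trim = TRUE)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Pipeline configuration
#'
#' All tunables of the pipeline with their defaults: pseudocount 1e-4,
#' subfunctionalization margin 0.05, EM window 101 bp, 1000 permutations,
#' HSD identity threshold 0.98, TF expression threshold 1 TPM in > 75% of
#' libraries. `...` overrides any field; unknown fields are an error.
#'
#' @param seed Integer master seed; every stage derives its stream from it.
#' @param ... Field overrides.
#' @export
pipeline_config <- function(seed = 1L, ...) {
  cfg <- list(
    seed = as.integer(seed),
    pseudocount = 1e-4,
    margin = 0.05,
    expressed_tpm = 1,
    window_w = 101L,
    em_epsilon = 0.1,
    em_max_iter = 200L,
    em_tol = 1e-6,
    n_permutations = 1000L,
    hsd_identity = 0.98,
    tf_tpm = 1,
    tf_fraction = 0.75,
    fdr = 0.05,
    stages = c("simulate", "stats", "fates", "cnde", "alloc",
               "depletion", "motifs"),
    sim = list())
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown))
    stop("unknown config field(s): ", paste(unknown, collapse = ", "))
  cfg[names(dots)] <- dots
  class(cfg) <- "pipeline_config"
  cfg
}

#' Read a pipeline configuration from JSON
#' @param path JSON file with any subset of [pipeline_config()] fields.
#' @export
read_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(pipeline_config, raw)
}

#' Run the full pipeline on synthetic data
#'
#' Drives simulate -> stats -> fates -> cnde -> alloc -> depletion -> motifs
#' as toggled in `config$stages`, writing one TSV per stage plus a run log
#' into `outdir`. All randomness derives from `config$seed`.
#'
#' @param config A [pipeline_config()].
#' @param outdir Output directory (created if needed).
#' @return Invisibly, a named list of per-stage results.
#' @export
run_pipeline <- function(config = pipeline_config(), outdir = tempfile("dupfate_")) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  stages <- config$stages
  res <- list()
  log <- c(sprintf("dupfate run, seed=%d", config$seed),
           sprintf("R version: %s", R.version.string),
           sprintf("params: pseudocount=%g margin=%g window_w=%d n_perm=%d hsd_identity=%g tf_tpm=%g tf_fraction=%g fdr=%g",
                   config$pseudocount, config$margin, config$window_w,
                   config$n_permutations, config$hsd_identity, config$tf_tpm,
                   config$tf_fraction, config$fdr))
  run_stage <- function(name, fun) {
    if (!(name %in% stages)) return(invisible(NULL))
    r <- tryCatch(fun(), error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
    res[[name]] <<- r
    log <<- c(log, sprintf("stage %s: ok", name))
    invisible(r)
  }

  scfg <- do.call(sim_config, c(list(seed = config$seed), config$sim))

  run_stage("simulate", function() {
    fam <- simulate_families(scfg)
    write_expression(fam$human, file.path(outdir, "expression_human.tsv"))
    write_expression(fam$ortholog, file.path(outdir, "expression_ortholog.tsv"))
    write_families(fam$families, file.path(outdir, "families.tsv"))
    utils::write.table(fam$truth$fates, file.path(outdir, "truth_fates.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    fam
  })
  sim <- res$simulate

  run_stage("stats", function() {
    if (is.null(sim)) stop("stats requires the simulate stage")
    cors <- family_correlations(sim$human, sim$ortholog, sim$families,
                                pseudocount = config$pseudocount)
    tm <- tissue_means(sim$human)
    taus <- data.frame(gene = rownames(tm),
                       tau = apply(tm, 1L, tau))
    utils::write.table(cors, file.path(outdir, "correlations.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(taus, file.path(outdir, "tau.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    list(correlations = cors, tau = taus)
  })

  run_stage("fates", function() {
    if (is.null(res$stats)) stop("fates requires the stats stage")
    calls <- classify_families(res$stats$correlations, sim$families,
                               margin = config$margin)
    utils::write.table(calls, file.path(outdir, "fate_calls.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    calls
  })

  run_stage("cnde", function() {
    if (is.null(sim)) stop("cnde requires the simulate stage")
    cn <- simulate_cn(scfg, genes = setdiff(
      sim$families$gene[sim$families$role != "ortholog"], character()))
    de <- cn_adjusted_de(sim$human, cn, sim$families,
                         pseudocount = config$pseudocount, fdr = config$fdr)
    utils::write.table(de, file.path(outdir, "cn_de.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    de
  })

  run_stage("alloc", function() {
    rd <- simulate_duplicated_reads(scfg)
    alloc <- em_allocate(rd$candidates, rd$unique_coverage,
                         window_w = config$window_w,
                         max_iter = config$em_max_iter,
                         tol = config$em_tol, epsilon = config$em_epsilon)
    prim <- select_primary(alloc)
    utils::write.table(prim, file.path(outdir, "primary_placements.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    list(reads = rd, alloc = alloc, primary = prim)
  })

  run_stage("depletion", function() {
    land <- simulate_peak_landscape(scfg)
    dep <- depletion_test(land$sd_intervals, land$peaks, land$genome,
                          n = config$n_permutations,
                          seed = stage_seed(config$seed, "depletion"))
    write_bed(land$peaks, file.path(outdir, "peaks.bed"))
    write_bed(land$sd_intervals, file.path(outdir, "sd.bed"))
    utils::write.table(
      data.frame(observed = dep$observed, null_mean = mean(dep$null_values),
                 M = dep$M, N = length(dep$null_values), p = dep$empirical_p),
      file.path(outdir, "depletion.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE)
    dep
  })

  run_stage("motifs", function() {
    toy <- toy_motif_world(seed = stage_seed(config$seed, "motifs"))
    hits <- lapply(toy$sequences, function(s)
      scan_pwm(s, toy$pwm, alpha = config$fdr))
    comp <- compare_homologs(hits, toy$alignments, toy$roles)
    utils::write.table(comp, file.path(outdir, "motif_comparison.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    comp
  })

  writeLines(log, file.path(outdir, "run_log.txt"))
  invisible(res)
}

#' Read / write FASTA sequences
#'
#' Thin wrappers over Biostrings for the plain-text FASTA files the pipeline
#' exchanges (paralogous loci, promoter sequences).
#'
#' @param path FASTA file.
#' @return [read_fasta()] returns a named character vector of sequences.
#' @export
read_fasta <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  stats::setNames(as.character(ss), names(ss))
}

#' @rdname read_fasta
#' @param sequences Named character vector.
#' @export
write_fasta <- function(sequences, path) {
  ss <- Biostrings::DNAStringSet(sequences)
  names(ss) <- names(sequences)
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}
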