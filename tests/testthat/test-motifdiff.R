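strong_pwm <- function(kmer, p_major = 0.94, id = "site") {
  bases <- c("A", "C", "G", "T")
  k <- nchar(kmer)
  m <- matrix((1 - p_major) / 3, k, 4, dimnames = list(NULL, bases))
  hit <- match(strsplit(kmer, "")[[1]], bases)
  m[cbind(seq_len(k), hit)] <- p_major
  pwm(m, id = id)
}

test_that("pwm constructor validates probability structure", {
  expect_error(pwm(matrix(0.3, 3, 4)), "sum to 1")
  expect_error(pwm(matrix(c(0.5, 0.5), 1, 2)), "4 columns")
  expect_error(pwm(matrix(0.25, 1, 4)), "length")
  expect_s3_class(strong_pwm("ACG"), "pwm")
})

test_that("scan_pwm scores and p-values match exhaustive enumeration", {
  set.seed(1)
  for (k in c(3, 5)) {
    m <- matrix(rexp(4 * k), k); m <- m / rowSums(m)
    p <- pwm(m, "rand")
    seqv <- paste(sample(c("A", "C", "G", "T"), 30, replace = TRUE),
                  collapse = "")
    hits <- scan_pwm(seqv, p, return_all = TRUE)
    # oracle: enumerate all 4^k windows with the same bin discretization
    bin <- 1e-3
    ib <- round(log2(pmax(m, 1e-6) / 0.25) / bin)
    grid <- as.matrix(expand.grid(rep(list(1:4), k)))
    wsc <- rowSums(matrix(ib[cbind(rep(seq_len(k), each = nrow(grid)),
                                   as.vector(grid))],
                          nrow = nrow(grid)))
    oracle_p <- vapply(round(hits$score / bin),
                       function(s) mean(wsc >= s), 0)
    expect_equal(hits$p, oracle_p, tolerance = 1e-12)
  }
})

test_that("reverse-complement scanning mirrors hit sets", {
  p <- strong_pwm("TGACT")
  seqv <- "GGTGACTTTCAAGTCACC"
  h <- scan_pwm(seqv, p, return_all = TRUE)
  hr <- scan_pwm(dupfate:::revcomp(seqv), p, return_all = TRUE)
  k <- 5; L <- nchar(seqv)
  mirrored <- data.frame(start = L - hr$start - k,
                         strand = ifelse(hr$strand == "+", "-", "+"),
                         score = hr$score)
  o1 <- order(h$start, h$strand); o2 <- order(mirrored$start, mirrored$strand)
  expect_equal(h$start[o1], mirrored$start[o2])
  expect_equal(h$strand[o1], mirrored$strand[o2])
  expect_equal(h$score[o1], mirrored$score[o2])
})

test_that("scan_pwm corner cases", {
  # background-equal PWM: zero information, all scores 0, nothing significant
  u <- scan_pwm("ACGTACGTAC", pwm(matrix(0.25, 3, 4)), return_all = TRUE)
  expect_true(all(u$score == 0))
  expect_equal(nrow(scan_pwm("ACGTACGTAC", pwm(matrix(0.25, 3, 4)))), 0)
  # near-degenerate PWM finds its k-mer exactly once on the forward strand
  p <- strong_pwm("CCGTA", p_major = 0.999)
  h <- scan_pwm("AACCGTAAA", p, return_all = TRUE)
  top <- h[which.max(h$score), ]
  expect_equal(top$start, 2L)
  expect_equal(top$strand, "+")
  # windows containing N are skipped
  hN <- scan_pwm("AANCGTAAA", p, return_all = TRUE)
  expect_true(all(hN$start > 2 | hN$start + 5 <= 2))
  # motif longer than sequence -> empty
  expect_equal(nrow(scan_pwm("ACG", strong_pwm("ACGTT"))), 0)
  expect_true(all(scan_pwm("ACGTGCAT", strong_pwm("ACG"),
                           return_all = TRUE)$p > 0))
})

test_that("MEME minimal round-trips through read_meme", {
  path <- tempfile(fileext = ".meme")
  writeLines(c(
    "MEME version 4", "",
    "ALPHABET= ACGT", "",
    "Background letter frequencies",
    "A 0.3 C 0.2 G 0.2 T 0.3", "",
    "MOTIF toy1", "",
    "letter-probability matrix: alength= 4 w= 3 nsites= 20 E= 0",
    " 0.8 0.1 0.05 0.05",
    " 0.1 0.7 0.1 0.1",
    " 0.25 0.25 0.25 0.25", "",
    "MOTIF toy2", "",
    "letter-probability matrix: alength= 4 w= 2 nsites= 5 E= 0",
    " 0.9 0.04 0.03 0.03",
    " 0.05 0.05 0.05 0.85"), path)
  ms <- read_meme(path)
  expect_named(ms, c("toy1", "toy2"))
  expect_equal(nrow(ms$toy1$mat), 3)
  expect_equal(unname(ms$toy2$mat[2, "T"]), 0.85)
  expect_equal(unname(ms$toy1$background), c(0.3, 0.2, 0.2, 0.3))
})

test_that("tf_expression_filter applies the strict breadth rule", {
  m <- rbind(high = rep(2, 8), low = rep(0.5, 8),
             boundary = c(rep(2, 6), rep(0.5, 2)), # exactly 75%
             above = c(rep(2, 7), 0.5))
  kept <- tf_expression_filter(m)
  expect_setequal(kept, c("high", "above"))
  expect_error(tf_expression_filter(matrix(numeric(0), 0, 0)), "empty")
})

test_that("compare_homologs anchors through alignments and polarizes", {
  p <- strong_pwm("TGACTC", id = "m1")
  backbone <- paste(rep("A", 20), collapse = "")
  seq_ref <- paste0(backbone, "TGACTC", backbone)
  hits_of <- function(s) scan_pwm(s, p, return_all = FALSE)
  # identical homologs: one shared site, no gains or losses
  roles <- c(anc = "ancestral", der = "derived", ort = "ortholog")
  aln_id <- list(ref = seq_ref, hom = seq_ref)
  comp <- compare_homologs(list(anc = hits_of(seq_ref),
                                der = hits_of(seq_ref),
                                ort = hits_of(seq_ref)),
                           list(anc = aln_id, der = aln_id, ort = aln_id),
                           roles)
  expect_true(all(comp$classification == "shared"))

  # site destroyed in the ancestral, intact in derived and ortholog:
  # an ancestral-specific loss
  seq_anc <- sub("TGACTC", "TGAATC", seq_ref)
  comp2 <- compare_homologs(list(anc = hits_of(seq_anc),
                                 der = hits_of(seq_ref),
                                 ort = hits_of(seq_ref)),
                            list(anc = list(ref = seq_ref, hom = seq_anc),
                                 der = aln_id, ort = aln_id),
                            roles)
  loss <- comp2[comp2$classification == "paralog_specific_loss", ]
  expect_equal(nrow(loss), 1)
  expect_equal(loss$gene, "anc")

  # site present only in the derived paralog: a derived-specific gain
  seq_nosite <- paste0(backbone, backbone)
  comp3 <- compare_homologs(list(anc = hits_of(seq_nosite),
                                 der = hits_of(seq_ref),
                                 ort = hits_of(seq_nosite)),
                            list(anc = list(ref = seq_ref,
                                            hom = paste0(backbone,
                                                         "------",
                                                         backbone)),
                                 der = aln_id,
                                 ort = list(ref = seq_ref,
                                            hom = paste0(backbone,
                                                         "------",
                                                         backbone))),
                            roles)
  gain <- comp3[comp3$classification == "paralog_specific_gain", ]
  expect_equal(nrow(gain), 1)
  expect_equal(gain$gene, "der")

  # a single-column gap upstream shifts raw coordinates but anchoring
  # through the alignment still identifies the same site
  seq_gapped <- paste0(substr(backbone, 1, 19), "TGACTC", backbone) # 1 bp del
  aln_gap <- list(ref = seq_ref,
                  hom = paste0(substr(backbone, 1, 19), "-TGACTC", backbone))
  comp4 <- compare_homologs(list(anc = hits_of(seq_ref),
                                 der = hits_of(seq_gapped),
                                 ort = hits_of(seq_ref)),
                            list(anc = aln_id, der = aln_gap, ort = aln_id),
                            roles)
  expect_true(all(comp4$classification == "shared"))
  expect_equal(nrow(comp4), 1)
})
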