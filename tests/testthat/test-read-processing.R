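test_that("quality filter applies the strict more-than-75% rule", {
  # 4-base read at Q40 passes (fraction 1.0)
  f1 <- write_test_fastq("ACGT", qstr(40L, 4L))
  expect_equal(quality_filter(f1)$n_pass, 1L)
  # 8-base read with exactly 6/8 bases >= Q20 sits at 0.75 and fails
  f2 <- write_test_fastq("ACGTACGT",
                         paste0(qstr(30L, 6L), qstr(10L, 2L)))
  r2 <- quality_filter(f2)
  expect_equal(r2$n_in, 1L)
  expect_equal(r2$n_pass, 0L)
  # 7/8 bases passes
  f3 <- write_test_fastq("ACGTACGT",
                         paste0(qstr(30L, 7L), qstr(10L, 1L)))
  expect_equal(quality_filter(f3)$n_pass, 1L)
})

test_that("quality filter preserves order and reports malformed input", {
  f <- write_test_fastq(c("AAAA", "CCCC", "GGGG"),
                        c(qstr(40L, 4L), qstr(2L, 4L), qstr(40L, 4L)))
  r <- quality_filter(f)
  expect_equal(unname(r$sequences), c("AAAA", "GGGG"))
  bad <- tempfile(fileext = ".fastq")
  writeLines(c("@r1", "ACGT", "+", "II"), bad)  # quality/sequence mismatch
  expect_error(quality_filter(bad), "malformed FASTQ")
})

test_that("simulator low-quality fraction is removed exactly", {
  design <- crc_cohort_design(exosomes_per_sample = 1500L,
                              substitution_rate = 0,
                              duplication_rate = 0,
                              low_quality_read_fraction = 0.10)
  design$groups$n_samples <- c(1L, 0L, 0L)
  truth <- simulate_exosomes(design, seed = 4L)
  em <- write_pba_reads(truth, crc_panel(), read_layout(),
                        dir = tempfile("lq"), seed = 5L)
  r <- quality_filter(em$fastq[1])
  # two-state quality model: the bad fraction fails, everything else passes
  expect_equal(r$n_pass / r$n_in, 0.90, tolerance = 0.02)
  lab <- suppressWarnings(
    Biostrings::readQualityScaledDNAStringSet(em$fastq[1]))
  q <- as(Biostrings::quality(lab), "IntegerList")
  frac_good <- sum(q >= 20L) / lengths(q)
  expect_equal(r$n_pass, sum(frac_good > 0.75))
})

test_that("parse_reads slices fields and rejects short or ambiguous reads", {
  lay <- read_layout()
  ptag <- strrep("A", 8); umi <- strrep("C", 10)
  anchor <- strrep("G", 12); etag <- strrep("T", 15)
  good <- paste0(ptag, umi, anchor, etag, strrep("A", 30))
  short <- strrep("A", 40)
  n_umi <- paste0(ptag, "CCCCNCCCCC", anchor, etag, strrep("A", 30))
  n_etag <- paste0(ptag, umi, anchor, "TTTTTTTNTTTTTTT", strrep("A", 30))
  n_ptag <- paste0("AAAANAAA", umi, anchor, etag, strrep("A", 30))
  out <- parse_reads(c(good, short, n_umi, n_etag, n_ptag), lay)
  expect_equal(attr(out, "n_in"), 5L)
  expect_equal(nrow(out), 2L)  # good + N-in-protein-tag survive
  expect_equal(out$protein_tag[1], ptag)
  expect_equal(out$umi[1], umi)
  expect_equal(out$exosome_tag[1], etag)
  expect_equal(out$protein_tag[2], "AAAANAAA")
})

test_that("protein tags match exactly, by unique Hamming-1, or reject", {
  panel <- pba_panel(c("a", "b", "c"),
                     c("AAAAAA", "CCCCCC", "AAACCC"))
  expect_equal(match_protein_tags("AAAAAA", panel), 1L)
  expect_equal(match_protein_tags("AAAAAC", panel), 1L)  # H1 from entry 1 only
  expect_equal(match_protein_tags("AAANAA", panel), 1L)  # N counts as mismatch
  # H2 from everything: reject
  expect_true(is.na(match_protein_tags("AAAAGG", panel)))
  expect_error(match_protein_tags("AAAA", panel), "tag length")
  expect_equal(match_protein_tags(character(0), panel), integer(0))
  # mismatch tolerance off
  expect_true(is.na(match_protein_tags("AAAAAC", panel, max_mismatch = 0L)))
})

test_that("ambiguous Hamming-1 ties reject, verified by enumeration", {
  panel <- tiny_panel(8L, 6L)
  chars <- do.call(rbind, strsplit(panel$protein_tag, ""))
  set.seed(42)
  bases <- c("A", "C", "G", "T")
  for (i in 1:200) {
    tag <- paste(sample(bases, 6L, replace = TRUE), collapse = "")
    d <- rowSums(chars != rep(strsplit(tag, "")[[1]], each = nrow(chars)))
    expected <- if (min(d) == 0L) which.min(d)
    else if (min(d) == 1L && sum(d == 1L) == 1L) which.min(d)
    else NA_integer_
    expect_identical(match_protein_tags(tag, panel), expected)
  }
})

test_that("UMI collapse deduplicates within (exosome, antibody) groups", {
  rec <- data.frame(exosome_tag = c("E1", "E1", "E2"),
                    antibody = c(1L, 1L, 1L),
                    umi = c("AAAA", "AAAA", "AAAA"))
  out <- collapse_umis(rec)
  out <- out[order(out$exosome_tag), ]
  expect_equal(out$n_molecules, c(1L, 1L))  # same UMI on two tags = 2 molecules
  # directional absorption: dominant UMI absorbs its 1-error satellite
  rec2 <- data.frame(exosome_tag = rep("E1", 101),
                     antibody = 1L,
                     umi = c(rep("AAAA", 100), "AAAT"))
  expect_equal(collapse_umis(rec2, "directional")$n_molecules, 1L)
  expect_equal(collapse_umis(rec2, "exact")$n_molecules, 2L)
  # count-1 satellites merge (1 >= 2*1 - 1 holds)
  rec3 <- data.frame(exosome_tag = rep("E1", 2), antibody = 1L,
                     umi = c("AAAA", "AAAT"))
  expect_equal(collapse_umis(rec3, "directional")$n_molecules, 1L)
  # a count-2 child needs a parent with count >= 3: stays separate
  rec4 <- data.frame(exosome_tag = rep("E1", 4), antibody = 1L,
                     umi = c("AAAA", "AAAA", "AAAT", "AAAT"))
  expect_equal(collapse_umis(rec4, "directional")$n_molecules, 2L)
})

test_that("directional collapse agrees with the brute-force oracle", {
  set.seed(99)
  bases <- c("A", "C", "G", "T")
  for (rep in 1:40) {
    n_umi <- sample(2:7, 1)
    umis <- unique(vapply(seq_len(n_umi), function(i)
      paste(sample(bases, 4L, replace = TRUE), collapse = ""), ""))
    counts <- sample(1:40, length(umis), replace = TRUE)
    rec <- data.frame(exosome_tag = "E",
                      antibody = 1L,
                      umi = rep(umis, counts))
    got <- collapse_umis(rec, "directional")$n_molecules
    expect_equal(got, oracle_directional(umis, counts))
    # exact-mode count is never below directional
    expect_gte(collapse_umis(rec, "exact")$n_molecules, got)
  }
})

test_that("UMI collapse is idempotent on deduplicated molecules", {
  set.seed(7)
  rec <- data.frame(
    exosome_tag = sample(c("E1", "E2"), 60, replace = TRUE),
    antibody = sample(1:2, 60, replace = TRUE),
    umi = sample(c("AAAA", "AAAT", "CCCC", "CCCA"), 60, replace = TRUE))
  once <- collapse_umis(rec)
  # one read per surviving molecule, with mutually separated UMIs as the
  # root representatives: a second collapse must be the identity
  seps <- exopba:::generate_separated_tags(sum(once$n_molecules), 6L,
                                           min_dist = 3L, seed = 2L)
  again <- collapse_umis(data.frame(
    exosome_tag = rep(once$exosome_tag, once$n_molecules),
    antibody = rep(once$antibody, once$n_molecules),
    umi = seps))
  expect_equal(again[order(again$exosome_tag, again$antibody), ],
               once[order(once$exosome_tag, once$antibody), ],
               ignore_attr = TRUE)
})

test_that("build_matrix counts molecules per exosome and protein", {
  panel <- tiny_panel(2L)
  mol <- data.frame(exosome_tag = c("E1", "E1", "E2"),
                    antibody = c(1L, 2L, 1L),
                    n_molecules = c(1L, 1L, 1L))
  m <- build_matrix(mol, panel, "s")
  expect_equal(dim(m$counts), c(2L, 2L))
  expect_equal(as.vector(m$counts["E1", ]), c(1, 1))
  expect_equal(as.vector(m$counts["E2", ]), c(1, 0))
  empty <- build_matrix(mol[0, ], panel, "s")
  expect_equal(nrow(empty$counts), 0L)
})

test_that("qc metrics compute the funnel and per-exosome protein mean", {
  panel <- tiny_panel(2L)
  mol <- data.frame(exosome_tag = c("E1", "E1", "E2"),
                    antibody = c(1L, 2L, 1L),
                    n_molecules = c(1L, 1L, 1L))
  m <- build_matrix(mol, panel, "s")
  qc <- qc_metrics(10L, 8L, 6L, 4L, m)
  expect_equal(qc$n_exosomes, 2L)
  expect_equal(qc$n_molecules, 3L)
  expect_equal(qc$mean_proteins_per_exosome, 1.5)
  empty <- build_matrix(mol[0, ], panel, "s")
  qc0 <- qc_metrics(0L, 0L, 0L, 0L, empty)
  expect_equal(qc0$mean_proteins_per_exosome, 0)
  expect_error(qc_metrics(5L, 8L, 6L, 4L, m))  # broken funnel
})

test_that("zero-error processing reproduces the simulated truth exactly", {
  panel <- crc_panel()
  design <- crc_cohort_design(exosomes_per_sample = 400L,
                              duplication_rate = 0, substitution_rate = 0,
                              low_quality_read_fraction = 0)
  design$groups$n_samples <- c(1L, 1L, 0L)
  truth <- simulate_exosomes(design, seed = 13L)
  em <- write_pba_reads(truth, panel, read_layout(),
                        dir = tempfile("fid"), seed = 14L)
  for (s in names(em$fastq)) {
    res <- process_sample(em$fastq[[s]], panel)
    got <- matrix_triplets(res$matrix$counts)
    rownames(got) <- NULL
    want <- truth_triplets(truth, em$tags, panel, s)
    expect_equal(got, want)
    # funnel monotone, molecule total equals matrix total
    qc <- res$qc
    expect_true(qc$n_reads_in >= qc$n_reads_pass_quality &&
                  qc$n_reads_pass_quality >= qc$n_parsed &&
                  qc$n_parsed >= qc$n_matched &&
                  qc$n_molecules <= qc$n_matched)
    expect_equal(sum(res$matrix$counts), qc$n_molecules)
  }
})

test_that("processing a noisy sample keeps the funnel monotone", {
  panel <- crc_panel()
  design <- crc_cohort_design(exosomes_per_sample = 500L)
  design$groups$n_samples <- c(1L, 0L, 0L)
  truth <- simulate_exosomes(design, seed = 15L)
  em <- write_pba_reads(truth, panel, read_layout(),
                        dir = tempfile("noisy"), seed = 16L)
  qc <- process_sample(em$fastq[[1]], panel)$qc
  expect_lt(qc$n_reads_pass_quality, qc$n_reads_in)
  expect_lte(qc$n_matched, qc$n_parsed)
  expect_gt(qc$mean_proteins_per_exosome, 1.5)
})
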