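test_that("non-conversion filter counts non-CG cytosines strictly above 3", {
  reads <- tibble::tibble(
    read_id = c("keep0", "drop4", "keep3"),
    seq = c("TTTTCGTT", "CACACACA", "CACACGCA"),
    library_id = "A", richness = "T"
  )
  out <- filter_nonconverted(reads)
  expect_setequal(out$read_id, c("keep0", "keep3"))
  expect_equal(attr(out, "n_dropped"), 1L)
  # trailing C with no following base counts as non-CG
  tr <- tibble::tibble(read_id = "t", seq = "TCTCTCTC",
                       library_id = "A", richness = "T")
  expect_equal(nrow(filter_nonconverted(tr)), 0)  # 4 non-CG Cs incl. trailing
  # A-rich reads are judged on the reverse complement
  ar <- tibble::tibble(read_id = "a", seq = "TGTGTGTG",  # revcomp CACACACA
                       library_id = "A", richness = "A")
  expect_equal(nrow(filter_nonconverted(ar)), 0)
})

test_that("three-letter conversion substitutes exactly one base class", {
  expect_equal(convert_three_letter("ACGT", "C2T"), "ATGT")
  expect_equal(convert_three_letter("ACGT", "G2A"), "ACAT")
  expect_equal(convert_three_letter("TTTT", "C2T"), "TTTT")
  expect_equal(convert_three_letter("TTTT", "G2A"), "TTTT")
  expect_equal(nchar(convert_three_letter(strrep("ACGT", 10), "C2T")), 40)
})

test_that("aligner places unique reads, drops ambiguous, enforces strand rules", {
  set.seed(31)
  base <- paste(sample(c("A", "C", "G", "T"), 4000, TRUE), collapse = "")
  dup <- substr(base, 101, 180)
  g <- toy_genome(c(z = paste0(base, dup)))  # 80-mer repeated at two places

  # read equal to a unique 40-mer of the C2T reference -> unique Watson hit
  r40 <- convert_three_letter(substr(base, 1001, 1040), "C2T")
  reads <- tibble::tibble(read_id = "u", seq = r40, library_id = "A",
                          richness = "T")
  aln <- align_bisulfite_reads(reads, g)
  expect_equal(nrow(aln), 1)
  expect_equal(aln$start, 1000L)
  expect_equal(aln$target_strand, "Watson")

  # read occurring at two reference positions -> ambiguous, dropped
  rdup <- convert_three_letter(dup, "C2T")
  aln2 <- align_bisulfite_reads(
    tibble::tibble(read_id = "d", seq = rdup, library_id = "A", richness = "T"), g
  )
  expect_equal(nrow(aln2), 0)
  expect_equal(attr(aln2, "drop_reasons")[["ambiguous"]], 1L)

  # Crick-strand read: revcomp of a G2A-converted segment
  seg <- substr(base, 2001, 2080)
  crick_read <- rc_chr(convert_three_letter(seg, "G2A"))
  aln3 <- align_bisulfite_reads(
    tibble::tibble(read_id = "c", seq = crick_read, library_id = "A",
                   richness = "T"), g
  )
  expect_equal(nrow(aln3), 1)
  expect_equal(aln3$start, 2000L)
  expect_equal(aln3$target_strand, "Crick")

  # empty genome errors
  expect_error(align_bisulfite_reads(reads, structure(list(contigs = list()),
                                                      class = "bs_genome")),
               "empty")
})

test_that("alignments of error-free simulated reads match the truth", {
  cfg <- sim_config(seed = 41, genome = list(n_contigs = 1L,
    contig_length_bp = 20000L, n_islands = 1L, n_genes = 2L, n_repeats = 2L,
    mito_length_bp = 2000L), methylome = list(n_dmrs = 1L),
    reads = list(mean_depth_per_strand = 1.5, error_rate_sequencing = 0,
                 clonal_fraction = 0))
  sim <- simulate_genome(cfg)
  tr <- simulate_methylome(sim, cfg)
  rd <- simulate_reads(sim, tr, cfg)
  aln <- align_bisulfite_reads(rd$reads, sim$genome)
  j <- dplyr::inner_join(aln, rd$truth_alignments, by = "read_id",
                         suffix = c("", "_t"))
  expect_gt(nrow(j) / nrow(rd$reads), 0.95)
  expect_true(all(j$contig == j$contig_t & j$start == j$start_t &
                    j$target_strand == j$target_strand_t))
})

test_that("clonal deduplication keeps the first read per library and position", {
  aln <- tibble::tibble(
    read_id = c("r1", "r2", "r3", "r4"),
    library_id = c("A", "A", "B", "A"),
    contig = "z", start = c(10L, 10L, 10L, 20L),
    target_strand = "Watson", mismatches = 0L, proj_seq = "ACGT"
  )
  d1 <- deduplicate_clonal(aln)
  expect_equal(d1$read_id, c("r1", "r3", "r4"))  # r2 clonal with r1; B kept
  expect_equal(attr(d1, "n_clonal_removed"), 1L)
  d2 <- deduplicate_clonal(d1)
  expect_equal(d2$read_id, d1$read_id)  # idempotent
})

test_that("pileup scores informative bases per strand and ignores the rest", {
  g <- toy_genome(c(z = "AACGTT"))
  sites <- annotate_contexts(g)
  mk_aln <- function(id, seq, strand) {
    tibble::tibble(read_id = id, library_id = "A", contig = "z", start = 0L,
                   target_strand = strand, mismatches = 0L, proj_seq = seq)
  }
  # 5 reads all C at the Watson site (pos 2) -> n = 5, m = 5
  a5 <- dplyr::bind_rows(lapply(1:5, function(i) {
    dplyr::mutate(mk_aln(paste0("r", i), "AACGTT", "Watson"), start = 0L)
  }))
  cnt <- pileup_counts(a5, g, sites)
  w <- cnt[cnt$strand == "+", ]
  expect_equal(c(w$m, w$n), c(5L, 5L))

  # 4 C + 6 T -> n = 10, m = 4, level 0.4
  a10 <- dplyr::bind_rows(
    lapply(1:4, function(i) mk_aln(paste0("c", i), "AACGTT", "Watson")),
    lapply(1:6, function(i) mk_aln(paste0("t", i), "AATGTT", "Watson"))
  )
  cnt <- pileup_counts(a10, g, sites)
  w <- cnt[cnt$strand == "+", ]
  expect_equal(c(w$m, w$n), c(4L, 10L))
  expect_equal(w$m / w$n, 0.4)

  # read with G at a Watson-C site is uninformative there
  ag <- mk_aln("g1", "AAGGTT", "Watson")
  cnt <- pileup_counts(ag, g, sites)
  expect_false(any(cnt$strand == "+" & cnt$pos == 2))

  # Crick site (pos 3, ref G): proj G -> methylated, proj A -> unmethylated
  ac <- dplyr::bind_rows(mk_aln("x1", "AACGTT", "Crick"),
                         mk_aln("x2", "AACATT", "Crick"))
  cnt <- pileup_counts(ac, g, sites)
  cr <- cnt[cnt$strand == "-", ]
  expect_equal(c(cr$pos, cr$m, cr$n), c(3L, 1L, 2L))

  # read overhanging the contig end: overhang ignored
  ov <- mk_aln("o1", "GTTACG", "Watson")
  ov$start <- 3L
  expect_silent(cnt <- pileup_counts(ov, g, sites))
  expect_true(all(cnt$pos < 6))
})

test_that("pileup conserves informative base incidences", {
  cfg <- sim_config(seed = 43, genome = list(n_contigs = 1L,
    contig_length_bp = 12000L, n_islands = 1L, n_genes = 1L, n_repeats = 1L,
    mito_length_bp = 2000L), methylome = list(n_dmrs = 0L),
    reads = list(mean_depth_per_strand = 2))
  sim <- simulate_genome(cfg)
  tr <- simulate_methylome(sim, cfg)
  rd <- simulate_reads(sim, tr, cfg)
  pr <- process_bisulfite_reads(rd$reads, sim$genome)
  # recount informative incidences directly from the retained alignments
  sites <- annotate_contexts(sim$genome)
  key_w <- paste(sites$contig[sites$strand == "+"], sites$pos[sites$strand == "+"])
  key_c <- paste(sites$contig[sites$strand == "-"], sites$pos[sites$strand == "-"])
  total <- 0L
  for (i in seq_len(nrow(pr$alignments))) {
    a <- pr$alignments[i, ]
    ch <- strsplit(a$proj_seq, "")[[1]]
    pos <- a$start + seq_along(ch) - 1L
    ok <- pos < nchar(sim$genome$contigs[[a$contig]])
    kk <- paste(a$contig, pos)
    if (a$target_strand == "Watson") {
      total <- total + sum(ok & ch %in% c("C", "T") & kk %in% key_w)
    } else {
      total <- total + sum(ok & ch %in% c("G", "A") & kk %in% key_c)
    }
  }
  expect_equal(sum(pr$counts$n), total)
})

test_that("dyad-symmetric truth yields symmetric strand levels", {
  # shared per-dyad levels in the generator make the two strands of a CpG
  # statistically exchangeable; check pooled levels agree within noise
  counts <- fx_counts_a()
  sites <- fx_sites()
  dy <- cg_dyads(sites)
  j <- dplyr::inner_join(counts, dy[, c("contig", "pos", "strand", "dyad_pos")],
                         by = c("contig", "pos", "strand"))
  agg <- j %>%
    dplyr::group_by(.data$strand) %>%
    dplyr::summarise(level = sum(m) / sum(n))
  expect_equal(agg$level[1], agg$level[2], tolerance = 0.02)
})

test_that("library statistics report coverage, conversion and chain counts", {
  sim <- fx_sim()
  counts <- fx_counts_a()
  sites <- fx_sites()
  st <- library_stats(counts, sim$genome, sites,
                      chain = c(reads_in = 100L, reads_after_filter = 90L))
  expect_equal(st$reads_in, 100L)
  # 14x depth leaves essentially every CpG covered
  expect_gt(st$cpg_coverage_fraction, 0.99)
  # conversion rate reflects the simulated 0.7 % error
  expect_equal(st$conversion_rate, 0.993, tolerance = 0.002)
  # all sites covered -> coverage 1 on a saturated fixture
  sat <- tibble::tibble(contig = sites$contig, pos = sites$pos,
                        strand = sites$strand, context = sites$context,
                        m = 0L, n = 1L)
  expect_equal(library_stats(sat, sim$genome, sites)$cpg_coverage_fraction, 1)
  # empty counts flagged (no coverage on the control and a degenerate library)
  w <- testthat::capture_warnings(st0 <- library_stats(sat[0, ], sim$genome, sites))
  expect_gte(length(w), 1)
  expect_equal(st0$cpg_coverage_fraction, 0)
})

test_that("richness inference spots T-rich and A-rich reads", {
  expect_equal(infer_richness(c("TTTTGG", "AAAACC")), c("T", "A"))
})

test_that("cytosine report round-trips through the 1-based text dialect", {
  counts <- utils::head(fx_counts_a(), 50)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_cytosine_report(counts, f)
  first <- readr::read_tsv(f, show_col_types = FALSE)
  expect_equal(first$pos, counts$pos + 1L)  # 1-based on disk
  back <- read_cytosine_report(f)
  expect_equal(as.data.frame(back), as.data.frame(counts))
})

test_that("post-alignment filter mode applies the same rule to aligned reads", {
  cfg <- sim_config(seed = 47, genome = list(n_contigs = 1L,
    contig_length_bp = 10000L, n_islands = 0L, n_genes = 1L, n_repeats = 1L,
    mito_length_bp = 2000L), methylome = list(n_dmrs = 0L),
    reads = list(mean_depth_per_strand = 1))
  sim <- simulate_genome(cfg)
  tr <- simulate_methylome(sim, cfg)
  rd <- simulate_reads(sim, tr, cfg)
  pre <- process_bisulfite_reads(rd$reads, sim$genome, filter_stage = "pre_alignment")
  post <- process_bisulfite_reads(rd$reads, sim$genome, filter_stage = "post_alignment")
  # with a converted, low-error library the two orders agree closely
  expect_equal(sum(pre$counts$n), sum(post$counts$n), tolerance = 0.02)
})
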