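test_that("identical config and seed reproduce identical output", {
  cfg <- sim_config(seed = 3, genome = list(n_contigs = 1L,
    contig_length_bp = 20000L, n_islands = 1L, n_genes = 2L,
    n_repeats = 2L, mito_length_bp = 2000L),
    methylome = list(n_dmrs = 1L), reads = list(mean_depth_per_strand = 2))
  s1 <- simulate_genome(cfg); s2 <- simulate_genome(cfg)
  expect_identical(s1$genome$contigs, s2$genome$contigs)
  expect_identical(s1$genes$exons, s2$genes$exons)
  t1 <- simulate_methylome(s1); t2 <- simulate_methylome(s2)
  expect_identical(t1$sites, t2$sites)
  expect_identical(t1$expression, t2$expression)
  r1 <- simulate_reads(s1, t1); r2 <- simulate_reads(s2, t2)
  expect_identical(r1$reads$seq, r2$reads$seq)
  c1 <- simulate_counts(t1, 10, 0.01, 5); c2 <- simulate_counts(t2, 10, 0.01, 5)
  expect_identical(c1, c2)
  # FASTQ bytes
  f1 <- withr::local_tempfile(); f2 <- withr::local_tempfile()
  write_fastq(r1$reads, f1); write_fastq(r2$reads, f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("simulated genome carries the requested features", {
  sim <- fx_sim()
  cfg <- fx_config()
  expect_equal(nchar(sim$genome$contigs[["chrM"]]), cfg$genome$mito_length_bp)
  expect_identical(sim$genome$mito, "chrM")
  expect_equal(nrow(sim$islands), cfg$genome$n_islands)
  expect_equal(nrow(sim$genes$genes), cfg$genome$n_genes)
  expect_equal(nrow(sim$repeats), cfg$genome$n_repeats)
  # every planted island satisfies the sequence criteria of the detector
  for (j in seq_len(nrow(sim$islands))) {
    ch <- strsplit(substr(sim$genome$contigs[[sim$islands$contig[j]]],
                          sim$islands$start[j] + 1, sim$islands$end[j]),
                   "")[[1]]
    gc <- mean(ch %in% c("C", "G"))
    ncg <- sum(ch[-length(ch)] == "C" & ch[-1] == "G")
    oe <- ncg * length(ch) / (sum(ch == "C") * sum(ch == "G"))
    expect_gt(gc, 0.55)
    expect_gte(oe, 0.65)
  }
})

test_that("a genome requested without islands has few background islands", {
  sim <- simulate_genome(sim_config(seed = 21,
    genome = list(n_contigs = 1L, contig_length_bp = 100000L, n_islands = 0L,
                  n_genes = 2L, n_repeats = 2L, mito_length_bp = 2000L)))
  isl <- find_cpg_islands(sim$genome)
  # CpG-depleted background at 42 % GC essentially never qualifies
  expect_lte(nrow(isl), 2)
})

test_that("infeasible feature requests error out", {
  expect_error(
    simulate_genome(sim_config(seed = 1, genome = list(
      n_contigs = 1L, contig_length_bp = 5000L, n_islands = 10L,
      island_length_bp = 2000L, n_genes = 0L, n_repeats = 0L,
      mito_length_bp = 1000L))),
    "capacity"
  )
})

test_that("methylome truth honours the configured structure", {
  truth <- fx_truth()
  st <- truth$sites
  cfg <- fx_config()
  # mito fully unmethylated
  expect_true(all(st$level_a[st$contig == "chrM"] == 0))
  # bimodal CG mixture: high fraction close to configured value away from
  # overridden promoters/islands/DMRs
  expect_true(all(st$level_a >= 0 & st$level_a <= 1))
  # planted DMRs separate the lines by exactly the configured delta
  for (j in seq_len(nrow(truth$dmrs))) {
    idx <- st$context == "CG" & st$contig == truth$dmrs$contig[j] &
      st$pos >= truth$dmrs$start[j] & st$pos < truth$dmrs$end[j]
    d <- mean(st$level_a[idx]) - mean(st$level_b[idx])
    expect_equal(abs(d), cfg$methylome$dmr_delta_level, tolerance = 1e-9)
    # detectability precondition: >= 4 CG sites per kb
    expect_gte(sum(idx), 4 * (truth$dmrs$end[j] - truth$dmrs$start[j]) / 1000)
  }
  # outside DMRs the two lines agree
  out <- !interval_member_test(st$contig, st$pos, truth$dmrs)
  expect_identical(st$level_a[out], st$level_b[out])
})

test_that("zero non-CG rate and zero DMRs give degenerate truth", {
  sim <- simulate_genome(sim_config(seed = 5, genome = list(
    n_contigs = 1L, contig_length_bp = 20000L, n_islands = 1L, n_genes = 2L,
    n_repeats = 1L, mito_length_bp = 2000L)))
  tr <- simulate_methylome(sim, sim_config(seed = 5,
    genome = sim$config$genome,
    methylome = list(non_cg_rate = 0, n_dmrs = 0L)))
  st <- tr$sites
  expect_true(all(st$level_a[st$context != "CG"] == 0))
  expect_identical(st$level_a, st$level_b)
  expect_equal(nrow(tr$dmrs), 0)
})

test_that("high-mode fraction of CG truth matches the mixture weight", {
  sim <- simulate_genome(sim_config(seed = 9, genome = list(
    n_contigs = 1L, contig_length_bp = 100000L, n_islands = 0L, n_genes = 0L,
    n_repeats = 0L, mito_length_bp = 2000L)))
  # no genes/islands/DMRs: the raw mixture is untouched
  tr <- simulate_methylome(sim, sim_config(seed = 9,
    genome = sim$config$genome,
    methylome = list(n_dmrs = 0L, cg_high_fraction = 0.6)))
  cg <- tr$sites[tr$sites$context == "CG" & tr$sites$contig != "chrM", ]
  dy <- unique(cg[, c("contig", "level_a")])  # per-dyad via shared levels
  frac <- mean(cg$level_a >= 0.7)
  expect_equal(frac, 0.6, tolerance = 0.03)
})

test_that("direct count simulation follows the binomial model", {
  truth <- fx_truth()
  # p = 0, error = 0 -> m = 0
  st0 <- truth$sites
  st0$level_a <- 0
  c0 <- simulate_counts(st0, 10, 0, seed = 1)
  expect_true(all(c0$m == 0))
  # p = 1 -> m = n
  st1 <- truth$sites
  st1$level_a <- 1
  c1 <- simulate_counts(st1, 10, 0, seed = 1)
  expect_true(all(c1$m == c1$n))
  # p = 0.5 at high depth concentrates near 0.5
  one <- tibble::tibble(contig = "z", pos = 0L, strand = "+", context = "CG",
                        level_a = 0.5)
  cc <- simulate_counts(one, 1000, 0, seed = 4)
  expect_lt(abs(cc$m / cc$n - 0.5), 0.05)
})

test_that("read simulation respects truth and error settings", {
  cfg <- sim_config(seed = 13, genome = list(n_contigs = 1L,
    contig_length_bp = 8000L, n_islands = 0L, n_genes = 1L, n_repeats = 0L,
    mito_length_bp = 2000L), methylome = list(n_dmrs = 0L),
    reads = list(mean_depth_per_strand = 3, error_rate_nonconversion = 0,
                 error_rate_sequencing = 0, clonal_fraction = 0))
  sim <- simulate_genome(cfg)
  tr <- simulate_methylome(sim, cfg)
  # all-unmethylated truth: Watson reads carry no C at reference-C positions
  tr0 <- tr; tr0$sites$level_a <- 0
  rd <- simulate_reads(sim, tr0, cfg, seed = 2)
  w <- rd$truth_alignments$target_strand == "Watson"
  ch <- strsplit(sim$genome$contigs[[1]], "")[[1]]
  for (i in which(w)[1:20]) {
    ref <- ch[rd$truth_alignments$start[i] + 1:80]
    if (rd$truth_alignments$contig[i] != names(sim$genome$contigs)[1]) next
    rch <- strsplit(rd$reads$seq[i], "")[[1]]
    expect_false(any(rch[ref == "C"] == "C"))
    expect_true(all(rch[ref != "C"] == ref[ref != "C"]))
  }
  # all-methylated truth: every reference-C position reads C
  tr1 <- tr; tr1$sites$level_a <- 1
  rd1 <- simulate_reads(sim, tr1, cfg, seed = 3)
  w1 <- which(rd1$truth_alignments$target_strand == "Watson" &
                rd1$truth_alignments$contig == names(sim$genome$contigs)[1])
  for (i in w1[1:20]) {
    ref <- ch[rd1$truth_alignments$start[i] + 1:80]
    rch <- strsplit(rd1$reads$seq[i], "")[[1]]
    expect_true(all(rch[ref == "C"] == "C"))
  }
})

test_that("clonal fraction is reflected in duplicated 5' positions", {
  cfg <- sim_config(seed = 17, genome = list(n_contigs = 1L,
    contig_length_bp = 30000L, n_islands = 0L, n_genes = 1L, n_repeats = 0L,
    mito_length_bp = 2000L), methylome = list(n_dmrs = 0L),
    reads = list(mean_depth_per_strand = 2, clonal_fraction = 0.2))
  sim <- simulate_genome(cfg)
  tr <- simulate_methylome(sim, cfg)
  rd <- simulate_reads(sim, tr, cfg, seed = 4)
  expect_equal(mean(rd$truth_alignments$clonal), 0.2, tolerance = 0.03)
})

test_that("read length beyond contig length errors", {
  cfg <- sim_config(seed = 1, genome = list(n_contigs = 1L,
    contig_length_bp = 8000L, n_islands = 0L, n_genes = 1L, n_repeats = 0L,
    mito_length_bp = 2000L), methylome = list(n_dmrs = 0L),
    reads = list(read_length_bp = 5000L))
  sim <- simulate_genome(cfg)
  tr <- simulate_methylome(sim, cfg)
  expect_error(simulate_reads(sim, tr, cfg), "exceeds contig")
})

test_that("expression is rank-anticorrelated with promoter truth methylation", {
  sim <- simulate_genome(sim_config(seed = 23, genome = list(
    contig_length_bp = 400000L, n_genes = 80L)))
  tr <- simulate_methylome(sim, sim_config(seed = 23,
    genome = sim$config$genome,
    expression = list(coupling_rho = 0.6)))
  j <- dplyr::inner_join(tr$expression, tr$promoter_truth, by = "gene_id")
  rho <- cor(j$expr_a, j$prom_a, method = "spearman")
  expect_lt(abs(rho - (-0.6)), 0.15)
  # null coupling
  tr0 <- simulate_methylome(sim, sim_config(seed = 23,
    genome = sim$config$genome,
    expression = list(coupling_rho = 0)))
  j0 <- dplyr::inner_join(tr0$expression, tr0$promoter_truth, by = "gene_id")
  expect_lt(abs(cor(j0$expr_a, j0$prom_a, method = "spearman")), 0.25)
})

test_that("infeasible DMR placement errors", {
  sim <- simulate_genome(sim_config(seed = 2, genome = list(
    n_contigs = 1L, contig_length_bp = 20000L, n_islands = 0L, n_genes = 2L,
    n_repeats = 0L, mito_length_bp = 2000L)))
  expect_error(
    simulate_methylome(sim, sim_config(seed = 2,
      genome = sim$config$genome,
      methylome = list(n_dmrs = 20L, dmr_length_bp = 2000L))),
    "DMR"
  )
})
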