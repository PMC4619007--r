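test_that("region metrics follow their definitions exactly", {
  # 10 CG sites (5 dyads), 6 called, 8 total calls incl. non-CG, length 1000
  dy <- seq(0L, 40L, by = 10L)
  sites <- dplyr::bind_rows(
    tibble::tibble(contig = "z", pos = dy, strand = "+", context = "CG"),
    tibble::tibble(contig = "z", pos = dy + 1L, strand = "-", context = "CG"),
    tibble::tibble(contig = "z", pos = c(100L, 200L), strand = "+", context = "CHH")
  )
  counts <- dplyr::mutate(sites, m = 5L, n = 5L)
  calls <- counts[c(1:6, 11:12), ]  # 6 CG + 2 CHH called
  region <- tibble::tibble(contig = "z", start = 0L, end = 1000L)
  rm_ <- region_methylation(region, calls, counts, sites)
  expect_equal(rm_$relative_level, 6 / 10)
  expect_equal(rm_$absolute_level, 8 / 1000)
  expect_equal(rm_$mean_degree, 1.0)
  expect_equal(rm_$n_cg_sites, 10L)

  # degree averages m/n over covered CG sites
  counts2 <- dplyr::mutate(counts, m = c(rep(4L, 5), rep(2L, 5), 5L, 5L))
  rm2 <- region_methylation(region, calls, counts2, sites)
  expect_equal(rm2$mean_degree, mean(c(rep(0.8, 5), rep(0.4, 5))))

  # region with no reads is flagged undefined but absolute still computes
  rm0 <- region_methylation(region, calls[0, ], counts[0, ], sites)
  expect_true(rm0$undefined)
  expect_true(is.na(rm0$relative_level))
  expect_equal(rm0$absolute_level, 0)
})

test_that("promoter regions are strand-aware and clipped", {
  g <- tibble::tibble(gene_id = c("p", "m", "edge"), contig = "z",
                      strand = c("+", "-", "+"),
                      start = c(10000L, 5000L, 500L), end = c(12000L, 10000L, 3000L),
                      tss = c(10000L, 10000L, 500L), tts = c(12000L, 5000L, 3000L),
                      n_exons = 1L)
  pr <- promoter_region(g)
  expect_equal(c(pr$start[1], pr$end[1]), c(8500L, 10500L))
  expect_equal(c(pr$start[2], pr$end[2]), c(9500L, 11500L))
  expect_equal(pr$start[3], 0L)  # clipped at the contig start
  prc <- promoter_region(g, contig_lengths = c(z = 10200L))
  expect_equal(prc$end[1], 10200L)
})

test_that("metagene profile is flat under uniform truth", {
  sim <- fx("qsim", function() simulate_genome(sim_config(seed = 29,
    genome = list(contig_length_bp = 400000L, n_genes = 80L))))
  tr <- fx("qtruth", function() simulate_methylome(sim))
  st <- tr$sites
  st$level_a <- 0.7
  cnt <- simulate_counts(st, 20, 0, seed = 301)
  em <- structure(list(p = 0.007, source_contig = "chrM", bases_observed = 1e5),
                  class = "error_model")
  mc <- call_methylcytosines(cnt, em)
  sites <- annotate_contexts(sim$genome)
  prof <- metagene_profile(sim$genes, mc, cnt, sites, metric = "degree")
  prof <- prof[prof$n_genes >= 10, ]  # bins with a stable standard error
  gm <- sum(prof$value * prof$n_genes) / sum(prof$n_genes)
  expect_true(all(abs(prof$value - gm) <= 3 * prof$se))
})

test_that("a promoter-low body-high methylome shows the step in the profile", {
  sim <- fx_sim()
  st <- fx_truth()$sites
  g <- sim$genes$genes
  prom <- promoter_region(g)
  st$level_a <- 0.9
  in_prom <- interval_member_test(st$contig, st$pos, prom)
  st$level_a[in_prom] <- 0.05
  cnt <- simulate_counts(st, 20, 0, seed = 302)
  mc <- call_methylcytosines(cnt, fx_error_model())
  prof <- metagene_profile(sim$genes, mc, cnt, fx_sites(), metric = "degree")
  up <- mean(prof$value[prof$segment == "upstream"])
  body <- mean(prof$value[prof$segment == "internal_exons"])
  expect_lt(up, body)
})

test_that("single-exon genes populate only the segments they possess", {
  ex <- tibble::tibble(gene_id = "solo", contig = "chr1", strand = "+",
                       start = 30000L, end = 31000L)
  gm <- gene_models(ex)
  sites <- fx_sites()
  prof <- metagene_profile(gm, tidy(fx_calls_a()), fx_counts_a(), sites)
  expect_setequal(as.character(unique(prof$segment)),
                  c("upstream", "first_exon", "downstream"))
})

test_that("element profile separates a methylated outside from a cold body", {
  sim <- fx_sim()
  st <- fx_truth()$sites
  st$level_a <- 0.8
  inside <- interval_member_test(st$contig, st$pos, sim$repeats)
  st$level_a[inside] <- 0
  cnt <- simulate_counts(st, 20, 0, seed = 303)
  mc <- call_methylcytosines(cnt, fx_error_model())
  prof <- element_profile(sim$repeats, mc, cnt, fx_sites(), genome = sim$genome)
  body <- prof[prof$region == "body", ]
  fl <- prof[prof$region != "body", ]
  expect_lt(mean(body$relative_level, na.rm = TRUE),
            mean(fl$relative_level, na.rm = TRUE))
  expect_lt(mean(body$absolute_level), mean(fl$absolute_level))
})

test_that("pooled element profile is the coverage-weighted mean of elements", {
  sim <- fx_sim()
  mc <- fx_calls_a(); cnt <- fx_counts_a(); sites <- fx_sites()
  all_p <- element_profile(sim$repeats, mc, cnt, sites, genome = sim$genome,
                           body_bins = 2L, flank_bins = 2L)
  parts <- lapply(seq_len(nrow(sim$repeats)), function(i) {
    element_profile(sim$repeats[i, ], mc, cnt, sites, genome = sim$genome,
                    body_bins = 2L, flank_bins = 2L)
  })
  # recombine numerators/denominators
  comb <- dplyr::bind_rows(parts) %>%
    dplyr::group_by(region, bin) %>%
    dplyr::summarise(abs2 = sum(absolute_level * n_bases) / sum(n_bases),
                     .groups = "drop")
  j <- dplyr::inner_join(all_p, comb, by = c("region", "bin"))
  expect_equal(j$absolute_level, j$abs2, tolerance = 1e-12)
})

test_that("random regions are matched, exclusion-clean and reproducible", {
  sim <- fx_sim()
  rr1 <- sample_random_regions(sim$genome, sim$repeats, sim$genes,
                               sim$repeats, seed = 71)
  rr2 <- sample_random_regions(sim$genome, sim$repeats, sim$genes,
                               sim$repeats, seed = 71)
  expect_identical(rr1, rr2)
  # length multiset preserved
  expect_equal(sort(rr1$end - rr1$start),
               sort(sim$repeats$end - sim$repeats$start))
  # zero overlap with repeats and genic +/- 2 kb, and among themselves
  g <- sim$genes$genes
  excl <- dplyr::bind_rows(
    sim$repeats[, c("contig", "start", "end")],
    dplyr::transmute(g, contig, start = pmax(0L, start - 2000L), end = end + 2000L)
  )
  for (i in seq_len(nrow(rr1))) {
    expect_false(any(excl$contig == rr1$contig[i] & excl$start < rr1$end[i] &
                       excl$end > rr1$start[i]))
  }
  ov_self <- sum(sapply(seq_len(nrow(rr1)), function(i) {
    sum(rr1$contig == rr1$contig[i] & rr1$start < rr1$end[i] &
          rr1$end > rr1$start[i])
  }))
  expect_equal(ov_self, nrow(rr1))  # each overlaps only itself
  expect_false(any(rr1$contig == "chrM"))
})

test_that("random-region sampler errors when space is exhausted", {
  sim <- fx_sim()
  big <- tibble::tibble(contig = "chr1", start = 0L, end = 60000L)
  expect_error(sample_random_regions(sim$genome, sim$repeats, sim$genes,
                                     dplyr::bind_rows(big, big), seed = 1),
               "exhausted|cannot place")
})

test_that("hyper/hypo classification is inclusive at both boundaries", {
  dy <- seq(0L, 90L, by = 10L)
  sites <- tibble::tibble(contig = "z", pos = dy, strand = "+", context = "CG")
  counts <- dplyr::mutate(sites, m = 5L, n = 5L)
  g <- tibble::tibble(gene_id = c("h70", "h50", "h30"), contig = "z",
                      strand = "+", start = c(0L, 0L, 0L), end = c(100L, 100L, 100L),
                      tss = 0L, tts = 100L, n_exons = 1L)
  # craft calls per gene via separate invocations
  cls <- function(k) {  # k of 10 sites called
    calls <- counts[seq_len(k), ]
    classify_hyper_hypo(g[1, ], calls, counts, sites, "gene_body")$class
  }
  expect_equal(cls(7), "hyper")         # 0.70 inclusive
  expect_equal(cls(5), "intermediate")
  expect_equal(cls(3), "hypo")          # 0.30 inclusive
  expect_equal(classify_hyper_hypo(g[1, ], counts[0, ], counts[0, ], sites,
                                   "gene_body")$class, "undefined")
})

test_that("expression quintiles partition deterministically", {
  ex <- tibble::tibble(gene_id = sprintf("g%02d", 1:10), expr = c(rep(1, 4), 5:10))
  g <- tibble::tibble(gene_id = ex$gene_id, contig = "chr1", strand = "+",
                      start = 30000L + 0:9 * 100L, end = 30050L + 0:9 * 100L,
                      tss = 30000L + 0:9 * 100L, tts = 30050L + 0:9 * 100L,
                      n_exons = 1L)
  qa <- expression_quintile_analysis(g, ex, tidy(fx_calls_a()), fx_counts_a(),
                                     fx_sites())
  expect_equal(sort(table(qa$assignment$quintile)), sort(rep(2L, 5)),
               ignore_attr = TRUE)
  # permuted input order gives the identical assignment (tie rule)
  qa2 <- expression_quintile_analysis(g[sample(10), ], ex[sample(10), ],
                                      tidy(fx_calls_a()), fx_counts_a(),
                                      fx_sites())
  j <- dplyr::inner_join(qa$assignment, qa2$assignment, by = "gene_id")
  expect_equal(j$quintile.x, j$quintile.y)
})

test_that("quintile analysis recovers the planted expression coupling", {
  sim <- fx("qsim", function() simulate_genome(sim_config(seed = 29,
    genome = list(contig_length_bp = 400000L, n_genes = 80L))))
  tr <- fx("qtruth", function() simulate_methylome(sim))
  cnt <- fx("qcounts", function() simulate_counts(tr, 14, 0.007, seed = 311))
  em <- estimate_error_rate(cnt, sim$genome)
  mc <- call_methylcytosines(cnt, em)
  sites <- annotate_contexts(sim$genome)
  qa <- expression_quintile_analysis(sim$genes,
                                     tr$expression[, c("gene_id", "expr_a")],
                                     mc, cnt, sites)
  expect_lt(abs(qa$spearman_promoter_expression - (-0.6)), 0.15)
  # monotone trend across quintiles: lowest-expression quintile most methylated
  expect_gt(qa$summary$promoter_mean_degree[1],
            qa$summary$promoter_mean_degree[5])
})

test_that("group comparison runs Welch tests with graceful degenerate cases", {
  set.seed(83)
  lv <- tibble::tibble(gene_id = sprintf("g%03d", 1:200),
                       level = c(rnorm(100, 0.5, 0.1), rnorm(100, 0.7, 0.1)))
  gr <- tibble::tibble(gene_id = lv$gene_id,
                       group = rep(c("old", "new"), each = 100))
  gc_ <- compare_methylation_between_groups(gr, lv)
  expect_lt(gc_$pairs$p_value, 1e-6)
  # identical groups: t = 0, p = 1
  same <- tibble::tibble(gene_id = sprintf("s%02d", 1:20), level = rep(0.4, 20))
  grs <- tibble::tibble(gene_id = same$gene_id, group = rep(c("x", "y"), 10))
  pc <- compare_methylation_between_groups(grs, same)
  expect_equal(pc$pairs$p_value, 1)
  # singleton groups are excluded with a warning
  gr1 <- tibble::tibble(gene_id = c("g001", "g002", "g003"),
                        group = c("a", "a", "lonely"))
  expect_warning(
    expect_error(compare_methylation_between_groups(gr1, lv), "two groups"),
    "fewer than 2"
  )
  # three groups give all three pairs
  gr3 <- dplyr::mutate(gr, group = rep(c("a", "b", "c"), length.out = 200))
  expect_equal(nrow(compare_methylation_between_groups(gr3, lv)$pairs), 3)
})

test_that("per-gene divergence chi-square matches the closed form", {
  # [[50,50],[10,90]] by hand: expectations from margins
  o <- matrix(c(50, 50, 10, 90), 2, byrow = TRUE)
  e <- outer(rowSums(o), colSums(o)) / sum(o)
  x2 <- sum((o - e)^2 / e)
  got <- mcseq:::chisq_2x2(50, 50, 10, 90)
  expect_equal(got[1], x2, tolerance = 1e-12)
  expect_equal(got[2], pchisq(x2, 1, lower.tail = FALSE), tolerance = 1e-12)
  # identical counts -> p = 1
  expect_equal(mcseq:::chisq_2x2(20, 30, 20, 30)[2], 1)
  # small expectation falls back to Fisher
  expect_equal(mcseq:::chisq_2x2(1, 0, 0, 1)[3], 1)
})

test_that("null divergence p-values are approximately uniform", {
  sim <- fx_sim()
  tr <- fx_truth()
  ca <- fx_counts_a()
  cb <- simulate_counts(tr, 14, 0.007, seed = 555)  # same line A truth: null
  ea <- tr$expression[, c("gene_id", "expr_a")]
  dv <- per_gene_divergence(ca, cb, ea, ea, sim$genes)
  p <- dv$meth_p[!is.na(dv$meth_p)]
  expect_gte(length(p), 5)
  expect_gt(stats::ks.test(p, "punif")$p.value, 0.01)
})
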