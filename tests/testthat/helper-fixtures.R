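# Shared simulation fixtures, built once per test run and cached.

.fixture_env <- new.env(parent = emptyenv())

fx <- function(name, builder) {
  if (!exists(name, envir = .fixture_env)) {
    assign(name, builder(), envir = .fixture_env)
  }
  get(name, envir = .fixture_env)
}

# a small but complete world: 1 x 80 kb contig + 6 kb mito, genes, islands,
# repeats, 2 planted DMRs
fx_config <- function() {
  sim_config(
    seed = 11,
    genome = list(n_contigs = 1L, contig_length_bp = 80000L, n_islands = 3L,
                  n_genes = 6L, n_repeats = 6L, mito_length_bp = 6000L),
    methylome = list(n_dmrs = 2L)
  )
}

fx_sim <- function() fx("sim", function() simulate_genome(fx_config()))
fx_truth <- function() fx("truth", function() simulate_methylome(fx_sim()))
fx_sites <- function() fx("sites", function() annotate_contexts(fx_sim()$genome))
fx_counts_a <- function() {
  fx("counts_a", function() simulate_counts(fx_truth(), 14, 0.007, seed = 501))
}
fx_counts_b <- function() {
  fx("counts_b", function() {
    simulate_counts(fx_truth(), 14, 0.007, seed = 502, level = "level_b")
  })
}
fx_error_model <- function() {
  fx("error_model", function() estimate_error_rate(fx_counts_a(), fx_sim()$genome))
}
fx_calls_a <- function() {
  fx("calls_a", function() {
    call_methylcytosines(fx_counts_a(), fx_error_model())
  })
}

# two replicates per line at 15x, pooled to line level (the differential
# testing conditions)
fx_counts_pooled <- function(line = c("a", "b")) {
  line <- match.arg(line)
  fx(paste0("pooled_", line), function() {
    lv <- paste0("level_", line)
    base <- if (line == "a") 601 else 603
    pool_counts(
      simulate_counts(fx_truth(), 15, 0.007, seed = base, level = lv),
      simulate_counts(fx_truth(), 15, 0.007, seed = base + 1, level = lv)
    )
  })
}

# deterministic toy genome assembled by hand for exact-arithmetic tests
toy_genome <- function(seq, mito = NULL) {
  bs_genome(setNames(toupper(seq), if (is.null(names(seq))) {
    paste0("c", seq_along(seq))
  } else names(seq)), mito = mito)
}

# independent reverse complement used by strand-symmetry oracles
rc_chr <- function(x) {
  paste(rev(chartr("ACGTN", "TGCAN", strsplit(x, "")[[1]])), collapse = "")
}

# local helper mirroring interval membership (kept independent of the
# package internals)
interval_member_test <- function(contig, pos, iv) {
  out <- logical(length(contig))
  for (j in seq_len(nrow(iv))) {
    out <- out | (contig == iv$contig[j] & pos >= iv$start[j] & pos < iv$end[j])
  }
  out
}
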