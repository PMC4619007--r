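#' Simulation configuration
#'
#' Bundles every knob of the synthetic-data generator. Defaults emulate a
#' desk-scale vertebrate methylome of the kind the package analyses: a
#' GC-depleted (~42 % GC) genome with CpG-depleted background and planted
#' CpG islands, an unmethylated mitochondrion-like contig, bimodal CG
#' methylation (a mode near 0 and a mode in 0.7–1.0, with slightly more
#' than half of CG sites in the high mode), trace non-CG methylation
#' (~0.12 %), ~14x per-strand read depth with a combined
#' non-conversion + sequencing error of ~0.7 % (bisulfite conversion
#' ~99.3 %), and expression negatively rank-correlated with promoter
#' methylation.
#'
#' @param seed Integer seed; identical config + seed reproduces identical
#'   output byte-for-byte.
#' @param genome,methylome,reads,expression Named lists overriding the
#'   defaults printed by `str(sim_config())`.
#' @return A `sim_config` list.
#' @export
sim_config <- function(seed = 1L, genome = list(), methylome = list(),
                       reads = list(), expression = list()) {
  def <- list(
    seed = as.integer(seed),
    genome = list(
      n_contigs = 2L, contig_length_bp = 300000L, gc_fraction = 0.42,
      cpg_enrichment_factor = 0.3, n_islands = 12L, island_length_bp = 2000L,
      n_genes = 40L, exons_per_gene = 4L, n_repeats = 40L,
      repeat_length_bp = 400L, mito_length_bp = 16000L
    ),
    methylome = list(
      cg_high_fraction = 0.55, cg_high_level_range = c(0.7, 1.0),
      cg_low_level_range = c(0.0, 0.1), non_cg_rate = 0.0012,
      n_dmrs = 10L, dmr_length_bp = 2000L, dmr_delta_level = 0.5
    ),
    reads = list(
      read_length_bp = 80L, mean_depth_per_strand = 14,
      error_rate_nonconversion = 0.006, error_rate_sequencing = 0.001,
      clonal_fraction = 0.05
    ),
    expression = list(coupling_rho = 0.6, noise_sd = 1.0)
  )
  cfg <- def
  cfg$genome <- utils::modifyList(def$genome, genome)
  cfg$methylome <- utils::modifyList(def$methylome, methylome)
  cfg$reads <- utils::modifyList(def$reads, reads)
  cfg$expression <- utils::modifyList(def$expression, expression)
  with(cfg$methylome, {
    stopifnot(cg_high_fraction >= 0, cg_high_fraction <= 1,
              non_cg_rate >= 0, non_cg_rate <= 1,
              dmr_delta_level > 0, dmr_delta_level <= 1)
  })
  with(cfg$reads, {
    stopifnot(mean_depth_per_strand > 0,
              error_rate_nonconversion >= 0, error_rate_nonconversion <= 1,
              error_rate_sequencing >= 0, error_rate_sequencing <= 1,
              clonal_fraction >= 0, clonal_fraction < 1)
  })
  stopifnot(cfg$expression$coupling_rho >= -1, cfg$expression$coupling_rho <= 1)
  structure(cfg, class = "sim_config")
}

# Random DNA with tunable GC content and CpG dinucleotide enrichment
# (factor < 1 depletes CpG, as in vertebrate bulk genome; ~1 keeps the
# independence expectation, as inside CpG islands). Returns a character
# vector of single bases.
random_dna <- function(n, gc, cpg_factor) {
  base <- c("A", "C", "G", "T")
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  ch <- sample(base, n, replace = TRUE, prob = p)
  after_c <- which(ch == "C") + 1L
  after_c <- after_c[after_c <= n]
  pc <- p
  pc[3] <- pc[3] * cpg_factor
  pc <- pc / sum(pc)
  ch[after_c] <- sample(base, length(after_c), replace = TRUE, prob = pc)
  ch
}

# Place `lengths` non-overlapping intervals uniformly at random on a contig
# of length `len`, keeping min_gap clearance from `occupied` (tibble
# start/end) and from each other. Placement is exact over the remaining
# free space (gap bookkeeping), so dense layouts still succeed whenever
# they fit.
place_intervals <- function(len, lengths, occupied = NULL, min_gap = 1L,
                            what = "interval") {
  occ <- if (is.null(occupied) || nrow(occupied) == 0) {
    tibble::tibble(start = integer(0), end = integer(0))
  } else {
    occupied[order(occupied$start), c("start", "end")]
  }
  gaps <- function(occ) {
    if (nrow(occ) == 0) {
      return(tibble::tibble(start = 0L, end = as.integer(len)))
    }
    ir <- IRanges::reduce(IRanges::IRanges(occ$start + 1L, occ$end))
    gp <- IRanges::gaps(ir, start = 1L, end = len)
    tibble::tibble(start = IRanges::start(gp) - 1L, end = IRanges::end(gp))
  }
  out <- vector("list", length(lengths))
  for (i in seq_along(lengths)) {
    L <- as.integer(lengths[i])
    gp <- gaps(occ)
    # candidate start ranges inside each gap, honouring the clearance on
    # sides bounded by occupied intervals (contig ends need none)
    lo <- ifelse(gp$start == 0L, 0L, gp$start + min_gap)
    hi <- ifelse(gp$end == len, len, gp$end - min_gap) - L
    k <- pmax(0L, hi - lo + 1L)
    if (sum(k) == 0) {
      stop("cannot place requested ", what, "s: contig capacity exceeded ",
           "(placed ", i - 1L, " of ", length(lengths), ")")
    }
    j <- sample.int(nrow(gp), 1L, prob = k)
    s <- lo[j] + sample.int(k[j], 1L) - 1L
    occ <- dplyr::bind_rows(occ, tibble::tibble(start = s, end = s + L))
    out[[i]] <- c(s, s + L)
  }
  m <- do.call(rbind, out)
  tibble::tibble(start = as.integer(m[, 1]), end = as.integer(m[, 2]))
}

# Sequence-level CpG-island check used when planting islands. Planted
# islands must clear the detection thresholds (GC > 0.55, obs/exp >= 0.65,
# length > 500) with a small safety margin so sampling noise cannot sink
# them below the criteria.
island_seq_ok <- function(ch) {
  ncg <- sum(ch[-length(ch)] == "C" & ch[-1] == "G")
  nc <- sum(ch == "C"); ng <- sum(ch == "G")
  gc <- (nc + ng) / length(ch)
  oe <- if (nc == 0 || ng == 0) 0 else ncg * length(ch) / (nc * ng)
  gc > 0.56 && oe >= 0.70 && length(ch) > 500
}

#' Simulate a genome with planted CpG islands, genes and repeats
#'
#' Generates `n_contigs` main contigs plus one mitochondrion-like contig
#' (`chrM`, flagged as the unmethylated control). CpG islands are planted
#' by splicing in locally GC- and CpG-enriched sequence verified to satisfy
#' the island criteria used by [find_cpg_islands()]. Multi-exon genes and
#' labelled repeat intervals are placed without overlap (repeats also avoid
#' genes +/- 2 kb and islands, so that matched random-region sampling has a
#' clean eligible space).
#'
#' @param config A [sim_config()].
#' @param seed Seed; defaults to `config$seed`.
#' @return A `sim_genome` list: `genome` ([bs_genome()]), `genes`
#'   ([gene_models()]), `repeats` and `islands` (interval tibbles).
#' @export
simulate_genome <- function(config = sim_config(), seed = config$seed) {
  set.seed(seed)
  g <- config$genome
  contig_names <- paste0("chr", seq_len(g$n_contigs))
  contigs <- character(0)
  islands_all <- list(); exons_all <- list(); repeats_all <- list()
  n_isl <- diff(round(seq(0, g$n_islands, length.out = g$n_contigs + 1)))
  n_gen <- diff(round(seq(0, g$n_genes, length.out = g$n_contigs + 1)))
  n_rep <- diff(round(seq(0, g$n_repeats, length.out = g$n_contigs + 1)))
  for (ci in seq_len(g$n_contigs)) {
    nm <- contig_names[ci]
    L <- g$contig_length_bp
    ch <- random_dna(L, g$gc_fraction, g$cpg_enrichment_factor)
    # islands
    isl <- if (n_isl[ci] > 0) {
      iv <- place_intervals(L, rep(g$island_length_bp, n_isl[ci]),
                            min_gap = 500L, what = "island")
      for (j in seq_len(nrow(iv))) {
        # modest contrast against the ~0.42-GC background keeps detected
        # island boundaries close to the planted ones (the scan extends a
        # boundary while window-averaged criteria still hold)
        for (k in 1:50) {
          seg <- random_dna(g$island_length_bp, 0.575, 1.0)
          if (island_seq_ok(seg)) break
        }
        if (!island_seq_ok(seg)) stop("failed to generate a qualifying island sequence")
        ch[(iv$start[j] + 1L):iv$end[j]] <- seg
      }
      dplyr::mutate(iv, contig = nm, .before = 1)
    } else NULL
    # genes: exon/intron ladders on random strands, separated by >= 2 kb so
    # promoters do not run into neighbouring genes
    gene_tbl <- NULL
    if (n_gen[ci] > 0) {
      k <- g$exons_per_gene
      ex_lens <- matrix(sample(150:400, n_gen[ci] * k, replace = TRUE), ncol = k)
      in_lens <- if (k > 1) {
        matrix(sample(300:900, n_gen[ci] * (k - 1), replace = TRUE), ncol = k - 1)
      } else matrix(0L, nrow = n_gen[ci], ncol = 0)
      spans <- rowSums(ex_lens) + if (k > 1) rowSums(in_lens) else 0L
      iv <- place_intervals(L, spans, occupied = isl, min_gap = 1600L, what = "gene")
      strands <- sample(c("+", "-"), n_gen[ci], replace = TRUE)
      gene_tbl <- purrr::map_dfr(seq_len(n_gen[ci]), function(j) {
        off <- iv$start[j]
        starts <- integer(k); ends <- integer(k)
        for (e in seq_len(k)) {
          starts[e] <- off
          ends[e] <- off + ex_lens[j, e]
          off <- ends[e] + if (e < k) in_lens[j, e] else 0L
        }
        tibble::tibble(
          gene_id = sprintf("g_%s_%03d", nm, j), contig = nm,
          strand = strands[j], start = starts, end = ends
        )
      })
    }
    # repeats avoid genes +/- 2 kb and islands
    reps <- if (n_rep[ci] > 0) {
      occ <- dplyr::bind_rows(
        isl,
        if (!is.null(gene_tbl)) {
          gene_tbl %>%
            dplyr::group_by(.data$gene_id) %>%
            dplyr::summarise(start = max(0L, min(.data$start) - 2000L),
                             end = max(.data$end) + 2000L, .groups = "drop") %>%
            dplyr::select("start", "end")
        }
      )
      iv <- place_intervals(L, rep(g$repeat_length_bp, n_rep[ci]),
                            occupied = occ, min_gap = 200L, what = "repeat")
      iv %>%
        dplyr::mutate(contig = nm, .before = 1) %>%
        dplyr::mutate(label = sample(c("CR1", "LTR", "LINE"), dplyr::n(),
                                     replace = TRUE))
    } else NULL
    contigs[nm] <- paste(ch, collapse = "")
    islands_all[[nm]] <- isl
    exons_all[[nm]] <- gene_tbl
    repeats_all[[nm]] <- reps
  }
  contigs[["chrM"]] <- paste(
    random_dna(g$mito_length_bp, g$gc_fraction, 0.5), collapse = ""
  )
  empty_iv <- tibble::tibble(contig = character(0), start = integer(0),
                             end = integer(0))
  reps <- dplyr::bind_rows(repeats_all)
  if (nrow(reps) == 0) reps <- dplyr::mutate(empty_iv, label = character(0))
  isls <- dplyr::bind_rows(islands_all)
  isls <- if (nrow(isls) == 0) empty_iv else isls[, c("contig", "start", "end")]
  structure(list(
    genome = bs_genome(contigs, mito = "chrM"),
    genes = gene_models(dplyr::bind_rows(exons_all)),
    repeats = reps,
    islands = isls,
    config = config
  ), class = "sim_genome")
}

#' @export
print.sim_genome <- function(x, ...) {
  cat("<sim_genome>\n")
  print(x$genome)
  cat("  genes: ", nrow(x$genes$genes), ", repeats: ", nrow(x$repeats),
      ", planted islands: ", nrow(x$islands), "\n", sep = "")
  invisible(x)
}

#' Simulate a two-line methylome truth with planted DMRs
#'
#' Draws per-dyad CG methylation probabilities from the configured bimodal
#' mixture (both strands of a CpG dyad share one level, giving the
#' symmetric strand pattern real methylomes show), sets planted islands to
#' the low mode, gives every gene promoter a gene-specific level (the
#' handle through which expression is coupled), leaves non-CG sites
#' methylated only at the trace `non_cg_rate`, and forces the mitochondrial
#' contig to zero. Line B is a copy of line A except inside `n_dmrs`
#' disjoint planted intervals where the two lines' CG levels are separated
#' by exactly `dmr_delta_level` (alternating direction). Per-gene
#' expression is drawn by a Gaussian copula so that its Spearman
#' correlation with promoter truth methylation is approximately
#' `-coupling_rho`.
#'
#' @param sim A `sim_genome` from [simulate_genome()].
#' @param config A [sim_config()]; defaults to the one stored in `sim`.
#' @param seed Seed; defaults to `config$seed + 1`.
#' @return A `methylome_truth` list: `sites` (site tibble with `level_a`,
#'   `level_b`), `dmrs` (planted intervals with `direction`), `expression`
#'   (`gene_id`, `expr_a`, `expr_b`), `promoter_truth`.
#' @export
simulate_methylome <- function(sim, config = sim$config, seed = config$seed + 1L) {
  set.seed(seed)
  me <- config$methylome
  genome <- sim$genome
  sites <- annotate_contexts(genome)
  genes <- as_genes_tbl(sim$genes)
  lens <- contig_lengths(genome)

  # per-dyad mixture levels
  cg <- cg_dyads(sites)
  dy <- dplyr::distinct(cg, .data$contig, .data$dyad_pos)
  hi <- runif(nrow(dy)) < me$cg_high_fraction
  dy$level <- ifelse(
    hi,
    runif(nrow(dy), me$cg_high_level_range[1], me$cg_high_level_range[2]),
    runif(nrow(dy), me$cg_low_level_range[1], me$cg_low_level_range[2])
  )
  # planted islands sit in the low mode
  if (nrow(sim$islands) > 0) {
    in_isl <- interval_member(dy$contig, dy$dyad_pos, sim$islands)
    dy$level[in_isl] <- runif(sum(in_isl), me$cg_low_level_range[1],
                              me$cg_low_level_range[2])
  }
  # gene-specific promoter levels
  prom <- promoter_region(genes, contig_lengths = lens)
  pi_g <- runif(nrow(prom), 0.05, 0.95)
  for (j in seq_len(nrow(prom))) {
    idx <- dy$contig == prom$contig[j] & dy$dyad_pos >= prom$start[j] &
      dy$dyad_pos < prom$end[j]
    dy$level[idx] <- pmin(1, pmax(0, pi_g[j] + rnorm(sum(idx), 0, 0.03)))
  }

  lvl <- numeric(nrow(sites))
  key <- dplyr::left_join(
    cg_dyads(sites)[, c("contig", "pos", "strand", "dyad_pos")],
    dy, by = c("contig", "dyad_pos")
  )
  is_cg <- sites$context == "CG"
  lvl[is_cg] <- key$level
  non_cg <- which(!is_cg)
  meth_non_cg <- runif(length(non_cg)) < me$non_cg_rate
  lvl[non_cg[meth_non_cg]] <- runif(sum(meth_non_cg), 0.5, 1.0)
  if (!is.null(genome$mito)) lvl[sites$contig == genome$mito] <- 0

  level_a <- lvl
  level_b <- lvl

  # plant DMRs: both lines overwritten inside so the separation is exact
  dmrs <- NULL
  if (me$n_dmrs > 0) {
    main <- setdiff(names(genome$contigs), genome$mito)
    per <- diff(round(seq(0, me$n_dmrs, length.out = length(main) + 1)))
    dmr_list <- list()
    for (ci in seq_along(main)) {
      if (per[ci] == 0) next
      nm <- main[ci]
      occ <- prom[prom$contig == nm, c("start", "end")]
      iv <- tryCatch(
        place_intervals(lens[[nm]], rep(me$dmr_length_bp, per[ci]),
                        occupied = occ, min_gap = 3000L, what = "DMR"),
        error = function(e) stop("cannot place ", me$n_dmrs,
                                 " disjoint DMR intervals: ", conditionMessage(e))
      )
      dmr_list[[nm]] <- dplyr::mutate(iv, contig = nm, .before = 1)
    }
    dmrs <- dplyr::bind_rows(dmr_list)
    dmrs$direction <- rep(c("hyper_in_A", "hyper_in_B"), length.out = nrow(dmrs))
    for (j in seq_len(nrow(dmrs))) {
      idx <- which(sites$context == "CG" & sites$contig == dmrs$contig[j] &
                     sites$pos >= dmrs$start[j] & sites$pos < dmrs$end[j])
      if (length(idx) < 4 * me$dmr_length_bp / 1000) {
        stop("planted DMR ", j, " overlaps too few CG sites; increase ",
             "cpg_enrichment_factor or dmr_length_bp")
      }
      # the planted shift lives at CG sites only, so the recorded truth
      # interval is anchored at the outermost shifted sites (trailing
      # CG-free sequence carries no between-line difference)
      dmrs$start[j] <- min(sites$pos[idx])
      dmrs$end[j] <- max(sites$pos[idx]) + 1L
      dpos <- ifelse(sites$strand[idx] == "+", sites$pos[idx], sites$pos[idx] - 1L)
      u <- stats::ave(runif(length(idx)), dpos, FUN = function(x) x[1])
      if (dmrs$direction[j] == "hyper_in_A") {
        a <- max(0.75, me$dmr_delta_level) +
          u * (1 - max(0.75, me$dmr_delta_level))
        level_a[idx] <- a
        level_b[idx] <- a - me$dmr_delta_level
      } else {
        a <- u * min(0.25, 1 - me$dmr_delta_level)
        level_a[idx] <- a
        level_b[idx] <- a + me$dmr_delta_level
      }
    }
  } else {
    dmrs <- tibble::tibble(contig = character(0), start = integer(0),
                           end = integer(0), direction = character(0))
  }

  truth_sites <- dplyr::mutate(sites, level_a = level_a, level_b = level_b)

  # promoter truth means and copula-coupled expression
  prom_mean <- function(levels) {
    vapply(seq_len(nrow(prom)), function(j) {
      idx <- sites$context == "CG" & sites$contig == prom$contig[j] &
        sites$pos >= prom$start[j] & sites$pos < prom$end[j]
      if (!any(idx)) NA_real_ else mean(levels[idx])
    }, numeric(1))
  }
  pa <- prom_mean(level_a)
  pb <- prom_mean(level_b)
  rho <- config$expression$coupling_rho
  r <- 2 * sin(pi * rho / 6)  # latent correlation hitting the target Spearman
  n_g <- nrow(prom)
  eps <- rnorm(n_g)
  z <- function(x) qnorm((rank(x, ties.method = "first") - 0.5) / length(x))
  lat_a <- -r * z(pa) + sqrt(1 - r^2) * eps
  lat_b <- -r * z(pb) + sqrt(1 - r^2) * eps
  expression <- tibble::tibble(
    gene_id = prom$gene_id,
    expr_a = round(exp(4.5 + config$expression$noise_sd * lat_a)),
    expr_b = round(exp(4.5 + config$expression$noise_sd * lat_b))
  )

  structure(list(
    sites = truth_sites,
    dmrs = dmrs,
    expression = expression,
    promoter_truth = tibble::tibble(gene_id = prom$gene_id, prom_a = pa, prom_b = pb),
    config = config
  ), class = "methylome_truth")
}

#' @export
print.methylome_truth <- function(x, ...) {
  cat("<methylome_truth> ", nrow(x$sites), " sites, ",
      nrow(x$dmrs), " planted DMRs, ", nrow(x$expression), " genes\n", sep = "")
  invisible(x)
}

# TRUE for each (contig, pos) lying inside any interval of `iv`.
interval_member <- function(contig, pos, iv) {
  out <- logical(length(contig))
  for (nm in unique(iv$contig)) {
    sub <- iv[iv$contig == nm, , drop = FALSE]
    sel <- which(contig == nm)
    if (length(sel) == 0) next
    for (j in seq_len(nrow(sub))) {
      out[sel][pos[sel] >= sub$start[j] & pos[sel] < sub$end[j]] <- TRUE
    }
  }
  out
}

# sites-with-level accessor
truth_sites <- function(truth) {
  if (inherits(truth, "methylome_truth")) truth$sites else tibble::as_tibble(truth)
}

#' Simulate per-cytosine counts directly from a truth methylome
#'
#' Fast path bypassing read simulation: per site the total depth is
#' Poisson(`depth`) and the methylated-read count is Binomial with success
#' probability `p + error (1 - p)`, folding non-conversion and sequencing
#' error into a single rate at cytosines. Sites drawing zero depth are
#' absent from the output, mirroring a real pileup.
#'
#' @param truth A `methylome_truth` or a site tibble carrying the level
#'   column named by `level`.
#' @param depth Mean per-site read depth.
#' @param error Combined non-conversion + sequencing error rate.
#' @param seed Integer seed.
#' @param level Which truth column to use (`"level_a"` or `"level_b"`).
#' @return Count tibble: `contig`, `pos`, `strand`, `context`, `m`, `n`.
#' @export
simulate_counts <- function(truth, depth, error, seed, level = "level_a") {
  stopifnot(depth > 0)
  st <- truth_sites(truth)
  if (!level %in% names(st)) stop("no column '", level, "' in truth sites")
  set.seed(seed)
  p <- st[[level]]
  n <- rpois(nrow(st), depth)
  m <- rbinom(nrow(st), n, p + error * (1 - p))
  tibble::tibble(
    contig = st$contig, pos = st$pos, strand = st$strand,
    context = st$context, m = m, n = n
  ) %>% dplyr::filter(.data$n > 0)
}

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Simulate bisulfite reads with truth alignments
#'
#' Fragments are placed uniformly on each strand of each contig at
#' `mean_depth_per_strand`. For a Watson-strand fragment every reference C
#' emits C with probability `p_site + error_rate_nonconversion (1 - p_site)`
#' and T otherwise; Crick-strand fragments behave symmetrically through the
#' reverse complement. Sequencing error then substitutes any base uniformly
#' at `error_rate_sequencing`. A `clonal_fraction` of the output consists of
#' exact duplicates at identical 5' positions (PCR clones). All reads are
#' emitted T-rich (directional library).
#'
#' @param sim A `sim_genome` (or a [bs_genome()]).
#' @param truth A `methylome_truth` for the same genome.
#' @param config A [sim_config()].
#' @param seed Seed; defaults to `config$seed + 2`.
#' @param level Truth level column to sequence.
#' @param library_id Library label carried on every read.
#' @return List with `reads` (tibble: `read_id`, `seq`, `library_id`,
#'   `richness`) and `truth_alignments` (tibble: `read_id`, `contig`,
#'   `start` 0-based on forward coordinates, `target_strand`, `clonal`).
#' @export
simulate_reads <- function(sim, truth, config = NULL, seed = NULL,
                           level = "level_a", library_id = "A") {
  genome <- if (inherits(sim, "sim_genome")) sim$genome else sim
  if (is.null(config)) config <- if (inherits(sim, "sim_genome")) sim$config else sim_config()
  if (is.null(seed)) seed <- config$seed + 2L
  set.seed(seed)
  rd <- config$reads
  rl <- rd$read_length_bp
  e_nc <- rd$error_rate_nonconversion
  e_seq <- rd$error_rate_sequencing
  st <- truth_sites(truth)
  reads_out <- list(); aln_out <- list()
  rid <- 0L
  for (nm in names(genome$contigs)) {
    ch <- seq_chars(genome$contigs[[nm]])
    L <- length(ch)
    if (rl > L) stop("read length ", rl, " exceeds contig ", nm, " length ", L)
    sub <- st[st$contig == nm, ]
    lvl_plus <- rep(0, L); lvl_minus <- rep(0, L)
    ip <- sub$strand == "+"
    lvl_plus[sub$pos[ip] + 1L] <- sub[[level]][ip]
    lvl_minus[sub$pos[!ip] + 1L] <- sub[[level]][!ip]
    for (target in c("Watson", "Crick")) {
      n_frag <- rpois(1, rd$mean_depth_per_strand * L / rl)
      if (n_frag == 0) next
      starts <- sample.int(L - rl + 1L, n_frag, replace = TRUE) - 1L
      idx <- rep(starts, each = rl) + seq_len(rl)  # 1-based ref positions
      b <- ch[idx]
      if (target == "Watson") {
        cpos <- which(b == "C")
        q <- lvl_plus[idx[cpos]]
        b[cpos] <- ifelse(runif(length(cpos)) < q + e_nc * (1 - q), "C", "T")
      } else {
        gpos <- which(b == "G")
        q <- lvl_minus[idx[gpos]]
        b[gpos] <- ifelse(runif(length(gpos)) < q + e_nc * (1 - q), "G", "A")
      }
      if (e_seq > 0) {
        err <- which(runif(length(b)) < e_seq)
        if (length(err)) {
          alt <- matrix(c("C","G","T", "A","G","T", "A","C","T", "A","C","G", "A","C","G"),
                        nrow = 3,
                        dimnames = list(NULL, c("A", "C", "G", "T", "N")))
          col <- match(b[err], colnames(alt))
          pick <- alt[cbind(sample.int(3, length(err), replace = TRUE), col)]
          b[err] <- pick
        }
      }
      mat <- matrix(b, nrow = rl)
      seqs <- apply(mat, 2, paste, collapse = "")
      if (target == "Crick") seqs <- revcomp(seqs)
      n_clone <- round(rd$clonal_fraction / (1 - rd$clonal_fraction) * n_frag)
      clone_of <- if (n_clone > 0) sample.int(n_frag, min(n_clone, n_frag), replace = TRUE) else integer(0)
      all_seq <- c(seqs, seqs[clone_of])
      all_start <- c(starts, starts[clone_of])
      clonal <- c(rep(FALSE, n_frag), rep(TRUE, length(clone_of)))
      ids <- sprintf("r%07d", rid + seq_along(all_seq))
      rid <- rid + length(all_seq)
      reads_out[[paste(nm, target)]] <- tibble::tibble(
        read_id = ids, seq = all_seq, library_id = library_id, richness = "T"
      )
      aln_out[[paste(nm, target)]] <- tibble::tibble(
        read_id = ids, contig = nm, start = all_start,
        target_strand = target, clonal = clonal
      )
    }
  }
  list(reads = dplyr::bind_rows(reads_out),
       truth_alignments = dplyr::bind_rows(aln_out))
}

#' Write reads to FASTQ
#' @param reads Read tibble (`read_id`, `seq`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("@", reads$read_id, "\n", reads$seq, "\n+\n",
                    strrep("I", nchar(reads$seq))), con, sep = "\n")
  invisible(path)
}

#' Read a FASTQ file into a read tibble
#' @param path FASTQ path.
#' @param library_id Library label to attach.
#' @return Tibble `read_id`, `seq`, `library_id`, `richness` (inferred).
#' @export
read_fastq <- function(path, library_id = "A") {
  ln <- readLines(path)
  if (length(ln) %% 4 != 0) stop("truncated FASTQ: ", path)
  ids <- sub("^@", "", ln[seq(1, length(ln), by = 4)])
  ids <- sub("\\s.*$", "", ids)
  seqs <- toupper(ln[seq(2, length(ln), by = 4)])
  tibble::tibble(read_id = ids, seq = seqs, library_id = library_id,
                 richness = infer_richness(seqs))
}
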