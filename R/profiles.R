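# Merge sites with coverage (m, n) and a called-methylcytosine flag.
# Returns the site tibble with columns m, n (NA when uncovered) and called.
build_site_data <- function(sites, calls = NULL, counts = NULL) {
  out <- sites
  if (!is.null(counts)) {
    out <- dplyr::left_join(
      out, counts[, c("contig", "pos", "strand", "m", "n")],
      by = c("contig", "pos", "strand")
    )
  } else {
    out$m <- NA_integer_; out$n <- NA_integer_
  }
  if (!is.null(calls)) {
    ct <- as_calls_tbl(calls)
    out$called <- paste(out$contig, out$pos, out$strand) %in%
      paste(ct$contig, ct$pos, ct$strand)
  } else {
    out$called <- FALSE
  }
  out
}

# region_id-annotated overlap join of site rows onto regions
site_region_join <- function(site_data, regions) {
  if (!"region_id" %in% names(regions)) {
    regions <- dplyr::mutate(regions, region_id = dplyr::row_number())
  }
  gr_s <- GenomicRanges::GRanges(site_data$contig,
                                 IRanges::IRanges(site_data$pos + 1L, width = 1L))
  gr_r <- GenomicRanges::GRanges(regions$contig,
                                 IRanges::IRanges(regions$start + 1L, regions$end))
  ov <- GenomicRanges::findOverlaps(gr_s, gr_r)
  dplyr::bind_cols(
    site_data[S4Vectors::queryHits(ov), , drop = FALSE],
    tibble::tibble(region_id = regions$region_id[S4Vectors::subjectHits(ov)])
  )
}

#' Region-level methylation metrics
#'
#' Three region metrics: the relative methylation level (called
#' methylcytosines over covered CG sites, mC/CG), the absolute methylation
#' level (called methylcytosines of any context per base pair, mC/Length),
#' and the average methylation degree (mean per-site m/n over covered CG
#' sites). Coverage means at least one informative read.
#'
#' @param regions Tibble with `contig`, `start`, `end` (0-based half-open);
#'   any other columns are carried through.
#' @param calls `mc_calls` or call tibble.
#' @param counts Count tibble.
#' @param sites Site tibble.
#' @return `regions` with `n_cg_sites`, `n_cg_covered`, `n_cg_called`,
#'   `n_called_all`, `relative_level`, `absolute_level`, `mean_degree`
#'   added (`NA` metrics, flagged by `undefined`, where no CG site is
#'   covered).
#' @export
region_methylation <- function(regions, calls, counts, sites) {
  regions <- dplyr::mutate(tibble::as_tibble(regions),
                           region_id = dplyr::row_number())
  sd <- build_site_data(sites, calls, counts)
  j <- site_region_join(sd, regions)
  agg <- j %>%
    dplyr::group_by(.data$region_id) %>%
    dplyr::summarise(
      n_cg_sites = sum(.data$context == "CG"),
      n_cg_covered = sum(.data$context == "CG" & !is.na(.data$n) & .data$n >= 1),
      n_cg_called = sum(.data$context == "CG" & .data$called),
      n_called_all = sum(.data$called),
      mean_degree = mean((.data$m / .data$n)[.data$context == "CG" &
                                               !is.na(.data$n) & .data$n >= 1]),
      .groups = "drop"
    )
  regions %>%
    dplyr::left_join(agg, by = "region_id") %>%
    dplyr::mutate(
      dplyr::across(c("n_cg_sites", "n_cg_covered", "n_cg_called", "n_called_all"),
                    ~ dplyr::coalesce(.x, 0L)),
      relative_level = ifelse(.data$n_cg_covered > 0,
                              .data$n_cg_called / .data$n_cg_covered, NA_real_),
      absolute_level = .data$n_called_all / (.data$end - .data$start),
      mean_degree = ifelse(.data$n_cg_covered > 0, .data$mean_degree, NA_real_),
      undefined = .data$n_cg_covered == 0
    ) %>%
    dplyr::select(-"region_id")
}

#' Promoter regions of genes
#'
#' The promoter is the interval from `upstream` bp before to `downstream`
#' bp after the transcription start site, strand-aware and clipped to the
#' contig.
#'
#' @param genes `gene_models` or genes tibble (needs `tss`, `strand`).
#' @param upstream,downstream Extents in bp (defaults 1500 and 500).
#' @param contig_lengths Optional named lengths used for clipping.
#' @return Tibble `gene_id`, `contig`, `strand`, `start`, `end`.
#' @export
promoter_region <- function(genes, upstream = 1500L, downstream = 500L,
                            contig_lengths = NULL) {
  g <- as_genes_tbl(genes)
  out <- g %>%
    dplyr::transmute(
      .data$gene_id, .data$contig, .data$strand,
      start = ifelse(.data$strand == "+", .data$tss - upstream,
                     .data$tss - downstream),
      end = ifelse(.data$strand == "+", .data$tss + downstream,
                   .data$tss + upstream)
    ) %>%
    dplyr::mutate(start = pmax(0L, as.integer(.data$start)),
                  end = as.integer(.data$end))
  if (!is.null(contig_lengths)) {
    out$end <- pmin(out$end, as.integer(contig_lengths[out$contig]))
  }
  out
}

# gene segment table: one row per genomic interval with its segment label,
# the interval's offset within the 5'->3' concatenation of that segment,
# and the segment's total length
gene_segments <- function(gene, exons, flank_bp) {
  k <- nrow(exons)
  ex <- exons[order(exons$exon_rank), , drop = FALSE]  # 5'->3'
  plus <- gene$strand == "+"
  segs <- list()
  add <- function(name, ivs) {
    if (nrow(ivs) == 0) return()
    ivs <- ivs[ivs$end > ivs$start, , drop = FALSE]
    if (nrow(ivs) == 0) return()
    len <- sum(ivs$end - ivs$start)
    off <- cumsum(c(0L, utils::head(ivs$end - ivs$start, -1)))
    segs[[name]] <<- dplyr::mutate(ivs, segment = name, seg_off = off,
                                   seg_len = len)
  }
  iv <- function(s, e) tibble::tibble(start = as.integer(pmax(0L, s)),
                                      end = as.integer(e))
  up <- if (plus) iv(gene$tss - flank_bp, gene$tss) else iv(gene$tss, gene$tss + flank_bp)
  dn <- if (plus) iv(gene$tts, gene$tts + flank_bp) else iv(gene$tts - flank_bp, gene$tts)
  add("upstream", up)
  add("first_exon", iv(ex$start[1], ex$end[1]))
  if (k >= 2) {
    # introns in 5'->3' order between consecutive exons
    intr <- purrr::map_dfr(seq_len(k - 1), function(i) {
      if (plus) iv(ex$end[i], ex$start[i + 1]) else iv(ex$end[i + 1], ex$start[i])
    })
    add("first_intron", intr[1, , drop = FALSE])
    if (k >= 3) {
      add("internal_exons", iv(ex$start[2:(k - 1)], ex$end[2:(k - 1)]))
      if (k >= 3 && nrow(intr) >= 2) {
        add("internal_introns", intr[2:(k - 1), , drop = FALSE])
      }
    }
    add("last_exon", iv(ex$start[k], ex$end[k]))
  }
  add("downstream", dn)
  dplyr::bind_rows(segs)
}

metagene_segment_levels <- function() {
  c("upstream", "first_exon", "first_intron", "internal_exons",
    "internal_introns", "last_exon", "downstream")
}

#' Metagene methylation profile
#'
#' Averages a methylation metric over genes in fixed segments: 5' flank,
#' first exon, first intron, internal exons, internal introns, last exon,
#' 3' flank. Each segment of each gene is length-normalised into
#' `bins_per_segment` bins (coordinates reversed for minus-strand genes);
#' the per-bin metric is then averaged across the genes contributing data
#' to that bin. Genes with fewer than three exons contribute only the
#' segments they possess (a single-exon gene's body is its `first_exon`).
#'
#' @param genes A `gene_models` (exon structure required).
#' @param calls,counts,sites Calls, counts and sites as elsewhere.
#' @param metric `"degree"` (mean per-site m/n) or `"relative"` (called
#'   over covered CG sites).
#' @param bins_per_segment Bins per segment (default 10).
#' @param flank_bp 5'/3' flank width (default 2000).
#' @return A `metagene_profile` tibble: `segment`, `bin`, `value`, `se`,
#'   `n_genes`.
#' @export
metagene_profile <- function(genes, calls, counts, sites,
                             metric = c("degree", "relative"),
                             bins_per_segment = 10L, flank_bp = 2000L) {
  metric <- match.arg(metric)
  stopifnot(inherits(genes, "gene_models"))
  sd <- build_site_data(sites, calls, counts) %>%
    dplyr::filter(.data$context == "CG")
  sd_split <- split(sd, sd$contig)
  gtbl <- genes$genes
  per_gene <- purrr::map_dfr(seq_len(nrow(gtbl)), function(gi) {
    gene <- gtbl[gi, ]
    ex <- genes$exons[genes$exons$gene_id == gene$gene_id, , drop = FALSE]
    segs <- gene_segments(gene, ex, flank_bp)
    scon <- sd_split[[gene$contig]]
    if (is.null(scon) || nrow(segs) == 0) return(NULL)
    rows <- purrr::map_dfr(seq_len(nrow(segs)), function(si) {
      lo <- findInterval(segs$start[si] - 0.5, scon$pos) + 1L
      hi <- findInterval(segs$end[si] - 0.5, scon$pos)
      if (hi < lo) return(NULL)
      s <- scon[lo:hi, , drop = FALSE]
      off_in <- if (gene$strand == "+") s$pos - segs$start[si]
                else segs$end[si] - 1L - s$pos
      dplyr::mutate(s, segment = segs$segment[si],
                    off = segs$seg_off[si] + off_in,
                    seg_len = segs$seg_len[si])
    })
    if (nrow(rows) == 0) return(NULL)
    rows %>%
      dplyr::mutate(bin = pmin(bins_per_segment - 1L,
                               floor(.data$off / .data$seg_len * bins_per_segment))) %>%
      dplyr::group_by(.data$segment, .data$bin) %>%
      dplyr::summarise(
        value = if (metric == "degree") {
          mean((.data$m / .data$n)[!is.na(.data$n) & .data$n >= 1])
        } else {
          cov <- sum(!is.na(.data$n) & .data$n >= 1)
          if (cov == 0) NaN else sum(.data$called) / cov
        },
        .groups = "drop"
      ) %>%
      dplyr::mutate(gene_id = gene$gene_id)
  })
  prof <- per_gene %>%
    dplyr::filter(is.finite(.data$value)) %>%
    dplyr::group_by(.data$segment, .data$bin) %>%
    dplyr::summarise(
      n_genes = dplyr::n(),
      se = stats::sd(.data$value) / sqrt(dplyr::n()),
      value = mean(.data$value),
      .groups = "drop"
    ) %>%
    dplyr::mutate(segment = factor(.data$segment,
                                   levels = metagene_segment_levels())) %>%
    dplyr::arrange(.data$segment, .data$bin) %>%
    dplyr::select("segment", "bin", "value", "se", "n_genes")
  structure(prof, class = c("metagene_profile", class(prof)),
            metric = metric, bins_per_segment = bins_per_segment)
}

#' Methylation profile across genomic elements and their flanks
#'
#' Pools absolute (mC/Length) and relative (mC/CG) methylation over a set
#' of intervals: element bodies are length-normalised into `body_bins`,
#' flanks are fixed-width windows of `flank_bp` split into `flank_bins`.
#' Per bin the pooled metric sums numerators and denominators over all
#' elements (so the profile of all elements is the coverage-weighted mean
#' of per-element profiles). Flank bins running off a contig contribute
#' nothing and are reported with `n_elements` reduced accordingly.
#'
#' @param intervals Tibble `contig`, `start`, `end`.
#' @param calls,counts,sites As elsewhere.
#' @param genome Optional [bs_genome()] for right-edge clipping.
#' @param flank_bp Flank width (default 2000).
#' @param body_bins,flank_bins Bin counts (defaults 20 and 20).
#' @return Tibble: `region` (`flank_5p`/`body`/`flank_3p`), `bin`,
#'   `absolute_level`, `relative_level`, `n_elements`, `n_bases`.
#' @export
element_profile <- function(intervals, calls, counts, sites, genome = NULL,
                            flank_bp = 2000L, body_bins = 20L,
                            flank_bins = 20L) {
  stopifnot(nrow(intervals) > 0)
  lens <- if (!is.null(genome)) contig_lengths(genome) else NULL
  sd <- build_site_data(sites, calls, counts)
  sd_split <- split(sd, sd$contig)
  fw <- flank_bp / flank_bins
  rows <- purrr::map_dfr(seq_len(nrow(intervals)), function(i) {
    ctg <- intervals$contig[i]
    a <- intervals$start[i]; b <- intervals$end[i]
    scon <- sd_split[[ctg]]
    L <- if (!is.null(lens)) lens[[ctg]] else Inf
    part <- function(region, lo, hi, nbins) {
      lo_c <- max(0L, lo); hi_c <- min(hi, L)
      bins <- tibble::tibble(
        region = region, bin = 0:(nbins - 1L),
        bstart = lo + (0:(nbins - 1L)) * (hi - lo) / nbins,
        bend = lo + (1:nbins) * (hi - lo) / nbins
      ) %>%
        dplyr::mutate(
          n_bases = pmax(0, pmin(.data$bend, hi_c) - pmax(.data$bstart, lo_c))
        )
      if (is.null(scon)) {
        bins$called_all <- 0L; bins$cg_cov <- 0L; bins$cg_called <- 0L
        return(bins)
      }
      sel <- scon[scon$pos >= lo_c & scon$pos < hi_c, , drop = FALSE]
      if (nrow(sel) == 0) {
        bins$called_all <- 0L; bins$cg_cov <- 0L; bins$cg_called <- 0L
        return(bins)
      }
      sb <- pmin(nbins - 1L, floor((sel$pos - lo) / (hi - lo) * nbins))
      agg <- tibble::tibble(bin = sb,
                            called = sel$called,
                            cg = sel$context == "CG",
                            cov = !is.na(sel$n) & sel$n >= 1) %>%
        dplyr::group_by(.data$bin) %>%
        dplyr::summarise(called_all = sum(.data$called),
                         cg_cov = sum(.data$cg & .data$cov),
                         cg_called = sum(.data$cg & .data$called & .data$cov),
                         .groups = "drop")
      bins %>%
        dplyr::left_join(agg, by = "bin") %>%
        dplyr::mutate(dplyr::across(c("called_all", "cg_cov", "cg_called"),
                                    ~ dplyr::coalesce(.x, 0L)))
    }
    dplyr::bind_rows(
      part("flank_5p", a - flank_bp, a, flank_bins),
      part("body", a, b, body_bins),
      part("flank_3p", b, b + flank_bp, flank_bins)
    )
  })
  rows %>%
    dplyr::group_by(.data$region, .data$bin) %>%
    dplyr::summarise(
      absolute_level = sum(.data$called_all) / sum(.data$n_bases),
      relative_level = ifelse(sum(.data$cg_cov) > 0,
                              sum(.data$cg_called) / sum(.data$cg_cov), NA_real_),
      n_elements = sum(.data$n_bases > 0),
      n_bases = sum(.data$n_bases),
      .groups = "drop"
    ) %>%
    dplyr::mutate(region = factor(.data$region,
                                  levels = c("flank_5p", "body", "flank_3p"))) %>%
    dplyr::arrange(.data$region, .data$bin)
}

#' Sample random regions matched to template elements
#'
#' Draws, for each template interval, one random region of identical
#' length placed uniformly in the eligible space: the complement of
#' repeats and of genic regions extended `flank_bp` up- and downstream,
#' on non-mitochondrial contigs. Sampled regions do not overlap each
#' other; the draw is fully reproducible from `seed`.
#'
#' @param genome A [bs_genome()].
#' @param repeats Interval tibble of repeats to exclude.
#' @param genes `gene_models` or genes tibble to exclude (with flanks).
#' @param template_intervals Tibble whose lengths are matched.
#' @param seed Integer seed.
#' @param flank_bp Genic exclusion flank (default 2000).
#' @return Tibble `contig`, `start`, `end`, `template_id`.
#' @export
sample_random_regions <- function(genome, repeats, genes, template_intervals,
                                  seed, flank_bp = 2000L) {
  set.seed(seed)
  g <- as_genes_tbl(genes)
  lens <- contig_lengths(genome)
  main <- setdiff(names(genome$contigs), genome$mito)
  excl <- dplyr::bind_rows(
    repeats[, c("contig", "start", "end")],
    g %>% dplyr::transmute(.data$contig,
                           start = pmax(0L, .data$start - flank_bp),
                           end = .data$end + flank_bp)
  )
  gaps <- purrr::map_dfr(main, function(nm) {
    ex <- excl[excl$contig == nm, , drop = FALSE]
    ir <- IRanges::reduce(IRanges::IRanges(ex$start + 1L, ex$end))
    gap <- IRanges::gaps(ir, start = 1L, end = lens[[nm]])
    tibble::tibble(contig = nm, start = IRanges::start(gap) - 1L,
                   end = IRanges::end(gap))
  })
  tlen <- template_intervals$end - template_intervals$start
  ord <- order(tlen, decreasing = TRUE)
  placed <- vector("list", length(tlen))
  for (i in ord) {
    L <- tlen[i]
    cand <- gaps %>% dplyr::filter(.data$end - .data$start >= L)
    if (nrow(cand) == 0) {
      stop("cannot place matched random region of length ", L,
           ": eligible space exhausted (", sum(is.na(placed)), " remaining)")
    }
    wts <- cand$end - cand$start - L + 1
    j <- sample.int(nrow(cand), 1, prob = wts)
    s <- cand$start[j] + sample.int(wts[j], 1) - 1L
    placed[[i]] <- tibble::tibble(contig = cand$contig[j], start = s,
                                  end = s + L, template_id = i)
    # split the used gap so later samples cannot overlap
    gaps <- dplyr::bind_rows(
      gaps[-which(gaps$contig == cand$contig[j] &
                    gaps$start == cand$start[j] &
                    gaps$end == cand$end[j])[1], , drop = FALSE],
      tibble::tibble(contig = cand$contig[j],
                     start = c(cand$start[j], s + L),
                     end = c(s, cand$end[j]))
    )
  }
  dplyr::bind_rows(placed) %>% dplyr::arrange(.data$template_id)
}

#' Classify genes as hyper- or hypo-methylated
#'
#' Uses the relative methylation level (mC/CG) of the chosen compartment:
#' at or above `hyper` (default 0.70) is hyper-methylated, at or below
#' `hypo` (default 0.30) hypo-methylated, in between neither. Genes whose
#' compartment has no covered CG site are `undefined` and counted.
#'
#' @param genes `gene_models` or genes tibble.
#' @param calls,counts,sites As elsewhere.
#' @param compartment `"promoter"` or `"gene_body"`.
#' @param hyper,hypo Inclusive class boundaries.
#' @param contig_lengths Optional clipping lengths for promoters.
#' @return Tibble `gene_id`, `relative_level`, `class` (hyper / hypo /
#'   intermediate / undefined).
#' @export
classify_hyper_hypo <- function(genes, calls, counts, sites,
                                compartment = c("promoter", "gene_body"),
                                hyper = 0.70, hypo = 0.30,
                                contig_lengths = NULL) {
  compartment <- match.arg(compartment)
  g <- as_genes_tbl(genes)
  regions <- if (compartment == "promoter") {
    promoter_region(g, contig_lengths = contig_lengths)
  } else {
    g[, c("gene_id", "contig", "start", "end")]
  }
  rm_ <- region_methylation(regions, calls, counts, sites)
  rm_ %>%
    dplyr::transmute(
      .data$gene_id,
      relative_level = .data$relative_level,
      class = dplyr::case_when(
        .data$undefined ~ "undefined",
        .data$relative_level >= hyper ~ "hyper",
        .data$relative_level <= hypo ~ "hypo",
        TRUE ~ "intermediate"
      )
    )
}

#' Expression-quintile methylation analysis
#'
#' Ranks genes into five expression quintiles (ties broken by gene id so
#' the partition is deterministic; quintile 1 is the lowest-expressed) and
#' summarises promoter and gene-body methylation degree per quintile,
#' together with a TSS-anchored per-quintile profile and the Spearman
#' correlation between promoter methylation degree and expression.
#'
#' @param genes `gene_models` or genes tibble.
#' @param expression Tibble `gene_id` plus one expression column.
#' @param calls,counts,sites As elsewhere.
#' @param profile_flank_bp Half-width of the TSS-anchored profile window.
#' @param profile_bin_bp Profile bin width.
#' @param contig_lengths Optional clipping lengths.
#' @return A `quintile_analysis` list: `assignment`, `summary`, `profile`,
#'   `spearman_promoter_expression`.
#' @export
expression_quintile_analysis <- function(genes, expression, calls, counts,
                                         sites, profile_flank_bp = 2000L,
                                         profile_bin_bp = 200L,
                                         contig_lengths = NULL) {
  g <- as_genes_tbl(genes)
  val <- setdiff(names(expression), "gene_id")[1]
  ex <- tibble::tibble(gene_id = expression$gene_id,
                       expr = as.numeric(expression[[val]])) %>%
    dplyr::semi_join(g, by = "gene_id")
  if (nrow(ex) < 5) stop("need expression for at least 5 genes")
  ord <- order(ex$expr, ex$gene_id)
  qt <- integer(nrow(ex))
  qt[ord] <- floor((seq_along(ord) - 1) * 5 / nrow(ex)) + 1L
  assignment <- dplyr::mutate(ex, quintile = qt)

  prom <- promoter_region(g, contig_lengths = contig_lengths)
  prom_m <- region_methylation(prom, calls, counts, sites) %>%
    dplyr::select("gene_id", prom_degree = "mean_degree")
  body_m <- region_methylation(g[, c("gene_id", "contig", "start", "end")],
                               calls, counts, sites) %>%
    dplyr::select("gene_id", body_degree = "mean_degree")
  per_gene <- assignment %>%
    dplyr::left_join(prom_m, by = "gene_id") %>%
    dplyr::left_join(body_m, by = "gene_id")
  summary <- per_gene %>%
    dplyr::group_by(.data$quintile) %>%
    dplyr::summarise(
      n_genes = dplyr::n(),
      promoter_mean_degree = mean(.data$prom_degree, na.rm = TRUE),
      gene_body_mean_degree = mean(.data$body_degree, na.rm = TRUE),
      .groups = "drop"
    )
  # TSS-anchored profile, strand-aware offsets
  sd <- build_site_data(sites, calls, counts) %>%
    dplyr::filter(.data$context == "CG", !is.na(.data$n), .data$n >= 1)
  gq <- g %>% dplyr::inner_join(assignment[, c("gene_id", "quintile")], by = "gene_id")
  prof <- purrr::map_dfr(seq_len(nrow(gq)), function(i) {
    sel <- sd[sd$contig == gq$contig[i] &
                sd$pos >= gq$tss[i] - profile_flank_bp &
                sd$pos < gq$tss[i] + profile_flank_bp, , drop = FALSE]
    if (nrow(sel) == 0) return(NULL)
    off <- if (gq$strand[i] == "+") sel$pos - gq$tss[i] else gq$tss[i] - sel$pos - 1L
    tibble::tibble(quintile = gq$quintile[i],
                   bin = floor(off / profile_bin_bp) * profile_bin_bp,
                   degree = sel$m / sel$n, gene_id = gq$gene_id[i])
  })
  profile <- if (nrow(prof) > 0) {
    prof %>%
      dplyr::group_by(.data$quintile, .data$bin, .data$gene_id) %>%
      dplyr::summarise(degree = mean(.data$degree), .groups = "drop") %>%
      dplyr::group_by(.data$quintile, .data$bin) %>%
      dplyr::summarise(mean_degree = mean(.data$degree),
                       n_genes = dplyr::n(), .groups = "drop")
  } else tibble::tibble()
  ok <- !is.na(per_gene$prom_degree)
  rho <- if (sum(ok) >= 3) {
    suppressWarnings(cor(per_gene$prom_degree[ok], per_gene$expr[ok],
                         method = "spearman"))
  } else NA_real_
  structure(list(assignment = assignment, summary = summary,
                 profile = profile, per_gene = per_gene,
                 spearman_promoter_expression = rho),
            class = "quintile_analysis")
}

#' @export
print.quintile_analysis <- function(x, ...) {
  cat("<quintile_analysis> ", nrow(x$assignment), " genes; Spearman(promoter",
      " methylation, expression) = ",
      signif(x$spearman_promoter_expression, 3), "\n", sep = "")
  print(x$summary)
  invisible(x)
}

# Welch t-test that degrades gracefully for zero-variance groups
welch_pair <- function(x, y) {
  out <- tryCatch(
    { tt <- t.test(x, y); c(tt$statistic, tt$p.value) },
    error = function(e) {
      if (mean(x) == mean(y)) c(0, 1) else c(Inf * sign(mean(x) - mean(y)), 0)
    }
  )
  unname(out)
}

#' Compare per-gene methylation levels between groups
#'
#' Welch's two-sample t-test on per-gene levels for every pair of groups
#' (gene grouping supplied externally, e.g. evolutionary age classes or
#' pseudogene/parent pairs). Groups with fewer than two genes are excluded
#' with a warning.
#'
#' @param group_assignment Tibble `gene_id`, `group`.
#' @param per_gene_levels Tibble `gene_id` plus one level column.
#' @return A `group_comparison` list: `pairs` (group1, group2, t,
#'   p_value), `groups` (per-group n, mean, sd).
#' @export
compare_methylation_between_groups <- function(group_assignment,
                                               per_gene_levels) {
  val <- setdiff(names(per_gene_levels), "gene_id")[1]
  lv <- tibble::tibble(gene_id = per_gene_levels$gene_id,
                       level = as.numeric(per_gene_levels[[val]]))
  d <- dplyr::inner_join(group_assignment, lv, by = "gene_id") %>%
    dplyr::filter(!is.na(.data$level))
  sizes <- d %>% dplyr::count(.data$group)
  small <- sizes$group[sizes$n < 2]
  if (length(small)) {
    warning("group(s) with fewer than 2 genes excluded: ",
            paste(small, collapse = ", "))
    d <- d[!d$group %in% small, , drop = FALSE]
  }
  grps <- sort(unique(d$group))
  if (length(grps) < 2) stop("need at least two groups of size >= 2")
  pairs <- utils::combn(grps, 2)
  res <- purrr::map_dfr(seq_len(ncol(pairs)), function(j) {
    x <- d$level[d$group == pairs[1, j]]
    y <- d$level[d$group == pairs[2, j]]
    w <- welch_pair(x, y)
    tibble::tibble(group1 = pairs[1, j], group2 = pairs[2, j],
                   t = w[1], p_value = w[2])
  })
  gsum <- d %>%
    dplyr::group_by(.data$group) %>%
    dplyr::summarise(n = dplyr::n(), mean = mean(.data$level),
                     sd = stats::sd(.data$level), .groups = "drop")
  structure(list(pairs = res, groups = gsum), class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat("<group_comparison>\n")
  print(x$pairs)
  invisible(x)
}

# chi-square (no continuity correction) on a 2x2; Fisher fallback when an
# expected cell drops below 1
chisq_2x2 <- function(a, b, c, d) {
  o <- matrix(c(a, b, c, d), nrow = 2, byrow = TRUE)
  tot <- sum(o)
  if (tot == 0) return(c(NA_real_, NA_real_, NA_real_))
  e <- outer(rowSums(o), colSums(o)) / tot
  if (any(e < 1)) {
    return(c(NA_real_, fisher_p_one(a, a + b, c, c + d), 1))
  }
  x2 <- sum((o - e)^2 / e)
  c(x2, pchisq(x2, df = 1, lower.tail = FALSE), 0)
}

#' Per-gene methylation and expression divergence between two lines
#'
#' For each gene, a chi-square test (no continuity correction) on the 2x2
#' table of methylated vs unmethylated CG read counts summed over the gene
#' span, and likewise on expression reads vs the remainder of each
#' library; genes with an expected cell below 1 fall back to Fisher's
#' exact test and are flagged.
#'
#' @param counts_a,counts_b Count tibbles for the two lines.
#' @param expression_a,expression_b Tibbles `gene_id` + reads.
#' @param genes `gene_models` or genes tibble.
#' @return Tibble per gene: `meth_stat`, `meth_p`, `meth_method`,
#'   `expr_stat`, `expr_p`, `expr_method`.
#' @export
per_gene_divergence <- function(counts_a, counts_b, expression_a,
                                expression_b, genes) {
  g <- as_genes_tbl(genes)
  regions <- g[, c("gene_id", "contig", "start", "end")]
  sum_counts <- function(counts) {
    cg <- counts %>% dplyr::filter(.data$context == "CG")
    j <- site_region_join(
      cg, dplyr::mutate(regions, region_id = dplyr::row_number())
    )
    j %>%
      dplyr::group_by(.data$region_id) %>%
      dplyr::summarise(u = sum(.data$n - .data$m), m = sum(.data$m),
                       .groups = "drop")
  }
  sa <- sum_counts(counts_a); sb <- sum_counts(counts_b)
  meth <- dplyr::inner_join(sa, sb, by = "region_id", suffix = c("_a", "_b"))
  meth_res <- purrr::map_dfr(seq_len(nrow(meth)), function(i) {
    r <- chisq_2x2(meth$m_a[i], meth$u_a[i], meth$m_b[i], meth$u_b[i])
    tibble::tibble(region_id = meth$region_id[i], meth_stat = r[1],
                   meth_p = r[2],
                   meth_method = ifelse(r[3] == 1, "fisher", "chisq"))
  })
  val_a <- setdiff(names(expression_a), "gene_id")[1]
  val_b <- setdiff(names(expression_b), "gene_id")[1]
  ea <- tibble::tibble(gene_id = expression_a$gene_id,
                       reads_a = as.numeric(expression_a[[val_a]]))
  eb <- tibble::tibble(gene_id = expression_b$gene_id,
                       reads_b = as.numeric(expression_b[[val_b]]))
  expr <- dplyr::inner_join(ea, eb, by = "gene_id")
  tot_a <- sum(expr$reads_a); tot_b <- sum(expr$reads_b)
  expr_res <- purrr::map_dfr(seq_len(nrow(expr)), function(i) {
    r <- chisq_2x2(expr$reads_a[i], tot_a - expr$reads_a[i],
                   expr$reads_b[i], tot_b - expr$reads_b[i])
    tibble::tibble(gene_id = expr$gene_id[i], expr_stat = r[1], expr_p = r[2],
                   expr_method = ifelse(r[3] == 1, "fisher", "chisq"))
  })
  regions %>%
    dplyr::mutate(region_id = dplyr::row_number()) %>%
    dplyr::left_join(meth_res, by = "region_id") %>%
    dplyr::left_join(expr_res, by = "gene_id") %>%
    dplyr::select(-"region_id", -"contig", -"start", -"end")
}
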