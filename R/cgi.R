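#' CpG island criteria
#'
#' Sequence criteria for an island: GC content above `min_gc` (default
#' 55 %), observed/expected CpG ratio of at least `min_obs_exp` (default
#' 0.65, with obs/exp = #CpG x L / (#C x #G)), and length strictly greater
#' than 500 bp. A fourth, data-dependent criterion classifies an island as
#' methylated when at least 70 % of its CpG dinucleotides carry a called
#' methylcytosine (see [classify_cgi_methylation()]).
#'
#' @param min_gc Minimum GC fraction (exclusive).
#' @param min_obs_exp Minimum observed/expected CpG ratio (inclusive).
#' @param min_length Minimum length in bp (exclusive; an island must exceed
#'   it, so the scan window is `min_length + 1`).
#' @return A `cgi_config` list.
#' @export
cgi_config <- function(min_gc = 0.55, min_obs_exp = 0.65, min_length = 500L) {
  structure(list(min_gc = min_gc, min_obs_exp = min_obs_exp,
                 min_length = as.integer(min_length)),
            class = "cgi_config")
}

# window statistics from cumulative sums; s = 0-based start, w = width
cgi_window_stats <- function(cs, s, w) {
  # cs: list of cumsums (c, g, cg, nn) each length L+1 (leading 0)
  nc <- cs$c[s + w + 1L] - cs$c[s + 1L]
  ng <- cs$g[s + w + 1L] - cs$g[s + 1L]
  # dinucleotides fully inside [s, s+w): anchors s .. s+w-2
  ncg <- cs$cg[s + w] - cs$cg[s + 1L]
  nn <- cs$nn[s + w + 1L] - cs$nn[s + 1L]
  gc <- (nc + ng) / w
  oe <- ifelse(nc > 0 & ng > 0, ncg * w / (nc * ng), 0)
  list(gc = gc, oe = oe, ncg = ncg, nn = nn)
}

cgi_cumsums <- function(ch) {
  n <- length(ch)
  cg <- c(0, cumsum(ch[-n] == "C" & ch[-1] == "G"))  # anchors 1..n-1
  list(
    c = c(0, cumsum(ch == "C")),
    g = c(0, cumsum(ch == "G")),
    cg = c(cg, cg[n]),  # pad to length n + 1
    nn = c(0, cumsum(ch == "N"))
  )
}

#' Find CpG islands in a genome
#'
#' A Takai–Jones-style scan with the package's criteria (the island
#' catalogue approach cannot be reproduced from sequence alone, the scan
#' can): a window of `min_length + 1` bp slides in 1-bp steps; windows
#' satisfying all sequence criteria (and containing no N) are marked;
#' overlapping or book-ended marked windows are merged; each merged region
#' is then trimmed to its longest (leftmost on ties) sub-interval that
#' itself satisfies all criteria. Output intervals are non-overlapping and
#' sorted.
#'
#' @param genome A [bs_genome()] or named character vector.
#' @param config A [cgi_config()].
#' @param contigs Optional subset of contigs to scan.
#' @return Tibble: `contig`, `start`, `end`, `length`, `gc_fraction`,
#'   `obs_exp`, `cpg_count`.
#' @export
find_cpg_islands <- function(genome, config = cgi_config(), contigs = NULL) {
  seqs <- if (inherits(genome, "bs_genome")) genome$contigs else toupper(genome)
  if (length(seqs) == 0) stop("genome is empty")
  if (!is.null(contigs)) seqs <- seqs[contigs]
  w <- config$min_length + 1L
  out <- purrr::map_dfr(names(seqs), function(nm) {
    ch <- seq_chars(seqs[[nm]])
    L <- length(ch)
    if (L < w) return(NULL)
    cs <- cgi_cumsums(ch)
    starts <- 0:(L - w)
    st <- cgi_window_stats(cs, starts, w)
    ok <- st$gc > config$min_gc & st$oe >= config$min_obs_exp & st$nn == 0
    qs <- starts[ok]
    if (length(qs) == 0) return(NULL)
    # merge overlapping/adjacent marked windows: runs with start gaps <= w
    brk <- which(diff(qs) > w)
    run_start <- qs[c(1, brk + 1)]
    run_end <- qs[c(brk, length(qs))] + w
    purrr::map_dfr(seq_along(run_start), function(i) {
      iv <- cgi_trim_region(cs, run_start[i], run_end[i], config)
      if (is.null(iv)) return(NULL)
      st1 <- cgi_window_stats(cs, iv[1], iv[2] - iv[1])
      tibble::tibble(contig = nm, start = iv[1], end = iv[2],
                     length = iv[2] - iv[1], gc_fraction = st1$gc,
                     obs_exp = st1$oe, cpg_count = st1$ncg)
    })
  })
  if (nrow(out) == 0) {
    return(tibble::tibble(contig = character(0), start = integer(0),
                          end = integer(0), length = integer(0),
                          gc_fraction = numeric(0), obs_exp = numeric(0),
                          cpg_count = numeric(0)))
  }
  dplyr::arrange(out, .data$contig, .data$start)
}

# longest qualifying sub-interval of [a, b); leftmost on ties
cgi_trim_region <- function(cs, a, b, config) {
  for (len in (b - a):(config$min_length + 1L)) {
    ss <- a:(b - len)
    st <- cgi_window_stats(cs, ss, len)
    hit <- which(st$gc > config$min_gc & st$oe >= config$min_obs_exp & st$nn == 0)
    if (length(hit)) {
      s <- ss[hit[1]]
      return(c(s, s + len))
    }
  }
  NULL
}

#' Classify the methylation state of CpG islands
#'
#' A CpG dyad counts as methylated when the cytosine on either strand is a
#' called methylcytosine; an island is `methylated` when the methylated
#' fraction of all its CpG dinucleotides reaches 0.70 (inclusive),
#' otherwise `unmethylated`. When counts are supplied, islands none of
#' whose dyads carry any read are classed `unknown`.
#'
#' @param islands Island tibble from [find_cpg_islands()].
#' @param calls `mc_calls` or call tibble.
#' @param sites Site tibble from [annotate_contexts()].
#' @param counts Optional count tibble used to flag uncovered islands.
#' @param threshold Methylated-dyad fraction boundary (default 0.70).
#' @return `islands` with `cpg_dyads`, `methylated_dyads`,
#'   `methylated_cpg_fraction`, `methylation_class` added.
#' @export
classify_cgi_methylation <- function(islands, calls, sites, counts = NULL,
                                     threshold = 0.70) {
  ct <- as_calls_tbl(calls)
  dy <- cg_dyads(sites)
  called_key <- paste(ct$contig, ct$pos, ct$strand)
  dy$called <- paste(dy$contig, dy$pos, dy$strand) %in% called_key
  if (!is.null(counts)) {
    cov_key <- paste(counts$contig, counts$pos, counts$strand)
    dy$covered <- paste(dy$contig, dy$pos, dy$strand) %in% cov_key
  } else {
    dy$covered <- TRUE
  }
  res <- purrr::map_dfr(seq_len(nrow(islands)), function(j) {
    sub <- dy[dy$contig == islands$contig[j] &
                dy$dyad_pos >= islands$start[j] &
                dy$dyad_pos + 2L <= islands$end[j], , drop = FALSE]
    agg <- sub %>%
      dplyr::group_by(.data$dyad_pos) %>%
      dplyr::summarise(meth = any(.data$called), cov = any(.data$covered),
                       .groups = "drop")
    tot <- nrow(agg)
    meth <- sum(agg$meth)
    frac <- if (tot == 0) NA_real_ else meth / tot
    cls <- if (tot == 0 || !any(agg$cov)) "unknown"
           else if (frac >= threshold) "methylated" else "unmethylated"
    tibble::tibble(cpg_dyads = tot, methylated_dyads = meth,
                   methylated_cpg_fraction = frac, methylation_class = cls)
  })
  if (any(res$methylation_class == "unknown")) {
    message(sum(res$methylation_class == "unknown"),
            " island(s) without covered dyads classed 'unknown'")
  }
  dplyr::bind_cols(islands, res)
}

#' Assign CpG islands to genomic region classes
#'
#' The island midpoint decides membership with precedence
#' gene_body > upstream > downstream > intergenic; upstream/downstream are
#' strand-aware flanks of `flank_bp`. Ties between genes within one class
#' resolve to the gene with the nearest TSS, deterministically.
#'
#' @param islands Island tibble.
#' @param genes A `gene_models` or genes tibble.
#' @param flank_bp Flank width (default 2000).
#' @return `islands` with `region_class` and `region_gene` added; the
#'   class proportions are in attribute `proportions`.
#' @export
assign_cgi_regions <- function(islands, genes, flank_bp = 2000L) {
  g <- as_genes_tbl(genes)
  up <- dplyr::mutate(
    g,
    rstart = ifelse(.data$strand == "+", .data$start - flank_bp, .data$end),
    rend = ifelse(.data$strand == "+", .data$start, .data$end + flank_bp)
  )
  dn <- dplyr::mutate(
    g,
    rstart = ifelse(.data$strand == "+", .data$end, .data$start - flank_bp),
    rend = ifelse(.data$strand == "+", .data$end + flank_bp, .data$start)
  )
  mid <- islands$start + (islands$end - islands$start) %/% 2L
  pick <- function(cand, m, contig) {
    hit <- cand[cand$contig == contig & cand$rstart <= m & m < cand$rend, , drop = FALSE]
    if (nrow(hit) == 0) return(NA_character_)
    d <- abs(hit$tss - m)
    hit$gene_id[order(d, hit$gene_id)][1]
  }
  cls <- character(nrow(islands)); gene <- character(nrow(islands))
  body <- dplyr::mutate(g, rstart = .data$start, rend = .data$end)
  for (j in seq_len(nrow(islands))) {
    m <- mid[j]; ctg <- islands$contig[j]
    gb <- pick(body, m, ctg)
    if (!is.na(gb)) { cls[j] <- "gene_body"; gene[j] <- gb; next }
    u <- pick(up, m, ctg)
    if (!is.na(u)) { cls[j] <- "upstream"; gene[j] <- u; next }
    d <- pick(dn, m, ctg)
    if (!is.na(d)) { cls[j] <- "downstream"; gene[j] <- d; next }
    cls[j] <- "intergenic"; gene[j] <- NA_character_
  }
  out <- dplyr::mutate(islands, region_class = cls, region_gene = gene)
  prop <- out %>%
    dplyr::count(.data$region_class) %>%
    dplyr::mutate(proportion = .data$n / sum(.data$n))
  attr(out, "proportions") <- prop
  out
}
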