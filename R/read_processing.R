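#' Infer bisulfite read richness from base composition
#'
#' A read sequenced from a converted strand is depleted in C (T-rich);
#' a read from its complement is depleted in G (A-rich).
#'
#' @param seq Character vector of read sequences.
#' @return Character vector of `"T"` or `"A"`.
#' @export
infer_richness <- function(seq) {
  nc <- nchar(gsub("[^C]", "", seq))
  ng <- nchar(gsub("[^G]", "", seq))
  ifelse(nc <= ng, "T", "A")
}

# non-CG cytosine count per read sequence (own orientation): a C whose
# read-internal following base is not G; a trailing C counts as non-CG.
count_noncg_c <- function(seq) {
  m <- gregexpr("C(?!G)", seq, perl = TRUE)
  vapply(m, function(x) if (x[1] == -1) 0L else length(x), integer(1))
}

#' Filter apparently unconverted bisulfite reads
#'
#' Reads with more than three cytosines in a non-CG read-internal context
#' are treated as having escaped bisulfite conversion and are removed. For
#' A-rich reads the rule is applied to the reverse complement (the
#' T-rich projection). The threshold is strictly greater than `max_noncg_c`.
#'
#' @param reads Read tibble with `seq` and (optionally) `richness`.
#' @param max_noncg_c Maximum tolerated non-CG cytosines (default 3).
#' @return The filtered tibble, with the number dropped in attribute
#'   `n_dropped`.
#' @export
filter_nonconverted <- function(reads, max_noncg_c = 3L) {
  rich <- if ("richness" %in% names(reads)) reads$richness else infer_richness(reads$seq)
  s <- reads$seq
  ar <- rich == "A"
  if (any(ar)) s[ar] <- revcomp(s[ar])
  keep <- count_noncg_c(s) <= max_noncg_c
  out <- reads[keep, , drop = FALSE]
  attr(out, "n_dropped") <- sum(!keep)
  out
}

#' Three-letter conversion of a sequence
#'
#' @param seq Character vector.
#' @param mode `"C2T"` (cytosines replaced by thymines) or `"G2A"`
#'   (guanines replaced by adenines).
#' @return Converted sequences of identical length.
#' @export
convert_three_letter <- function(seq, mode = c("C2T", "G2A")) {
  mode <- match.arg(mode)
  if (mode == "C2T") chartr("C", "T", seq) else chartr("G", "A", seq)
}

#' Build a three-letter seed index for a toy-scale genome
#'
#' Hashes every `seed_width`-mer of the C-to-T and G-to-A converted
#' reference, the candidate-generation structure of the built-in aligner.
#' Building it once and passing it to [align_bisulfite_reads()] amortises
#' the cost across libraries.
#'
#' @param genome A [bs_genome()].
#' @param seed_width Seed k-mer width (default 20).
#' @return A `bs_index` list.
#' @export
bs_genome_index <- function(genome, seed_width = 20L) {
  stopifnot(inherits(genome, "bs_genome"))
  if (sum(nchar(genome$contigs)) > 10e6) {
    stop("built-in aligner is for toy-scale genomes (<= ~10 Mb); ",
         "import external alignments instead")
  }
  idx <- lapply(names(genome$contigs), function(nm) {
    s <- genome$contigs[[nm]]
    L <- nchar(s)
    if (L < seed_width) return(NULL)
    mk <- function(conv) {
      starts <- 1:(L - seed_width + 1L)
      kmers <- substring(conv, starts, starts + seed_width - 1L)
      list2env(split(starts, kmers), hash = TRUE, size = length(starts))
    }
    list(ct = mk(chartr("C", "T", s)), ga = mk(chartr("G", "A", s)),
         chars = seq_chars(s))
  })
  names(idx) <- names(genome$contigs)
  structure(list(contigs = idx, seed_width = as.integer(seed_width)),
            class = "bs_index")
}

# bisulfite-aware mismatch count of a projected read placed at 0-based
# `start` on contig chars `g`: in the C2T space read T may cover reference
# C; in the G2A space read A may cover reference G. Positions off the
# contig count as mismatches.
bs_mismatches <- function(rch, g, start, space) {
  idx <- start + seq_along(rch)
  inb <- idx >= 1 & idx <= length(g)
  ref <- rch  # placeholder alloc
  ref[] <- NA_character_
  ref[inb] <- g[idx[inb]]
  ok <- !is.na(ref) & (ref == rch |
    if (space == "ct") ref == "C" & rch == "T" else ref == "G" & rch == "A")
  sum(!ok)
}

#' Align bisulfite reads to a toy-scale genome
#'
#' Implements the three-letter strategy on desk-scale references. Each
#' read's T-rich projection (A-rich reads are reverse-complemented first)
#' is converted C-to-T and G-to-A and seed-matched ungapped against the
#' correspondingly converted reference; the C2T space yields Watson-strand
#' candidates, the G2A space Crick-strand candidates, which enforces the
#' strand-consistency rule by construction. Candidates are then rescored
#' with bisulfite-aware mismatch counting (read T over reference C is a
#' match only in the Watson space, read A over reference G only in the
#' Crick space) and a read is kept only when exactly one position attains
#' the best score within `max_mismatch`; ties are dropped as ambiguous,
#' seedless/overscored reads as unmapped.
#'
#' @param reads Read tibble (`read_id`, `seq`, `library_id`, `richness`).
#' @param genome A [bs_genome()].
#' @param max_mismatch Mismatch cap for a reported placement (default 2).
#' @param index Optional prebuilt [bs_genome_index()].
#' @return Tibble of unique alignments: `read_id`, `library_id`, `contig`,
#'   `start` (0-based 5' position on forward coordinates), `target_strand`
#'   (`Watson`/`Crick`), `mismatches`, `proj_seq` (the read projected onto
#'   forward-strand orientation, used by [pileup_counts()]). Dropped reads
#'   are tallied in attribute `drop_reasons`.
#' @export
align_bisulfite_reads <- function(reads, genome, max_mismatch = 2L,
                                  index = NULL) {
  stopifnot(inherits(genome, "bs_genome"))
  if (length(genome$contigs) == 0) stop("empty genome")
  empty <- tibble::tibble(read_id = character(0), library_id = character(0),
                          contig = character(0), start = integer(0),
                          target_strand = character(0), mismatches = integer(0),
                          proj_seq = character(0))
  if (nrow(reads) == 0) return(empty)
  if (is.null(index)) index <- bs_genome_index(genome)
  k <- index$seed_width
  rich <- if ("richness" %in% names(reads)) reads$richness else infer_richness(reads$seq)
  lib <- if ("library_id" %in% names(reads)) reads$library_id else rep("A", nrow(reads))
  # T-rich projection in the read's own frame; its reverse complement is
  # the forward-coordinate projection of a Crick-strand placement
  trich <- ifelse(rich == "A", revcomp(reads$seq), reads$seq)
  trich_rc <- revcomp(trich)
  proj <- list(ct = trich, ga = trich_rc)
  q <- list(ct = chartr("C", "T", trich), ga = chartr("G", "A", trich_rc))
  strand_of <- c(ct = "Watson", ga = "Crick")
  out <- vector("list", nrow(reads))
  reasons <- c(unique_hit = 0L, ambiguous = 0L, unmapped = 0L)
  for (i in seq_len(nrow(reads))) {
    len <- nchar(trich[i])
    if (len < k) { reasons["unmapped"] <- reasons["unmapped"] + 1L; next }
    offs <- unique(c(seq(1L, len - k + 1L, by = k), len - k + 1L))
    hits <- list()
    for (space in c("ct", "ga")) {
      qi <- q[[space]][i]
      rch <- seq_chars(proj[[space]][i])
      for (nm in names(index$contigs)) {
        con <- index$contigs[[nm]]
        if (is.null(con)) next
        cand <- unique(unlist(lapply(offs, function(o) {
          p <- con[[space]][[substr(qi, o, o + k - 1L)]]
          if (is.null(p)) integer(0) else p - o  # 0-based read start
        }), use.names = FALSE))
        for (s in cand) {
          mm <- bs_mismatches(rch, con$chars, s, space)
          if (mm <= max_mismatch) {
            hits[[length(hits) + 1L]] <- list(nm, s, strand_of[[space]], mm,
                                              proj[[space]][i])
          }
        }
      }
    }
    if (length(hits) == 0) {
      reasons["unmapped"] <- reasons["unmapped"] + 1L
      next
    }
    mms <- vapply(hits, function(h) h[[4]], numeric(1))
    best <- which(mms == min(mms))
    if (length(best) > 1) {
      reasons["ambiguous"] <- reasons["ambiguous"] + 1L
      next
    }
    h <- hits[[best]]
    reasons["unique_hit"] <- reasons["unique_hit"] + 1L
    out[[i]] <- tibble::tibble(read_id = reads$read_id[i], library_id = lib[i],
                               contig = h[[1]], start = as.integer(h[[2]]),
                               target_strand = h[[3]],
                               mismatches = as.integer(h[[4]]),
                               proj_seq = h[[5]])
  }
  res <- dplyr::bind_rows(out)
  if (nrow(res) == 0) res <- empty
  attr(res, "drop_reasons") <- reasons
  res
}

#' Remove clonal (PCR duplicate) alignments
#'
#' Within each (library, contig, strand, 5'-position) group only the first
#' read in input order survives; applying the operation twice is a no-op.
#'
#' @param alignments Alignment tibble from [align_bisulfite_reads()].
#' @return The deduplicated tibble, with the removed count in attribute
#'   `n_clonal_removed`.
#' @export
deduplicate_clonal <- function(alignments) {
  key <- paste(alignments$library_id, alignments$contig,
               alignments$target_strand, alignments$start)
  keep <- !duplicated(key)
  out <- alignments[keep, , drop = FALSE]
  attr(out, "n_clonal_removed") <- sum(!keep)
  out
}

#' Pile up aligned reads into per-cytosine counts
#'
#' For each Watson-strand cytosine covered by a Watson-targeted read the
#' projected read base C counts as methylated (m and n) and T as
#' unmethylated (n only); any other base is uninformative and ignored.
#' Crick-strand sites are scored symmetrically through G/A on forward
#' coordinates. Read bases overhanging a contig end are ignored.
#'
#' @param alignments Unique, deduplicated alignments with `proj_seq`.
#' @param genome A [bs_genome()].
#' @param sites Site tibble from [annotate_contexts()].
#' @return Count tibble `contig`, `pos`, `strand`, `context`, `m`, `n`
#'   restricted to covered sites.
#' @export
pileup_counts <- function(alignments, genome, sites) {
  lens <- contig_lengths(genome)
  if (nrow(alignments) == 0) {
    return(sites[0, ] %>% dplyr::mutate(m = integer(0), n = integer(0)))
  }
  rl <- nchar(alignments$proj_seq)
  base <- unlist(strsplit(alignments$proj_seq, "", fixed = TRUE), use.names = FALSE)
  pos <- unlist(lapply(seq_len(nrow(alignments)), function(i) {
    alignments$start[i] + 0:(rl[i] - 1L)
  }), use.names = FALSE)
  contig <- rep(alignments$contig, rl)
  target <- rep(alignments$target_strand, rl)
  ok <- pos < lens[contig]
  bt <- tibble::tibble(contig = contig[ok], pos = pos[ok],
                       target = target[ok], base = base[ok])
  watson <- bt %>%
    dplyr::filter(.data$target == "Watson", .data$base %in% c("C", "T")) %>%
    dplyr::count(.data$contig, .data$pos, .data$base) %>%
    tidyr::pivot_wider(names_from = "base", values_from = "n", values_fill = 0L) %>%
    dplyr::mutate(strand = "+")
  crick <- bt %>%
    dplyr::filter(.data$target == "Crick", .data$base %in% c("G", "A")) %>%
    dplyr::count(.data$contig, .data$pos, .data$base) %>%
    tidyr::pivot_wider(names_from = "base", values_from = "n", values_fill = 0L) %>%
    dplyr::mutate(strand = "-")
  for (col in c("C", "T")) if (!col %in% names(watson)) watson[[col]] <- 0L
  for (col in c("G", "A")) if (!col %in% names(crick)) crick[[col]] <- 0L
  counts <- dplyr::bind_rows(
    watson %>% dplyr::transmute(.data$contig, .data$pos, .data$strand,
                                m = .data$C, n = .data$C + .data$T),
    crick %>% dplyr::transmute(.data$contig, .data$pos, .data$strand,
                               m = .data$G, n = .data$G + .data$A)
  )
  sites %>%
    dplyr::inner_join(counts, by = c("contig", "pos", "strand")) %>%
    dplyr::filter(.data$n > 0) %>%
    dplyr::arrange(.data$contig, .data$pos, .data$strand)
}

#' Run the full read-processing chain
#'
#' Non-conversion filter (pre- or post-alignment), three-letter unique
#' alignment, clonal deduplication, and pileup into per-cytosine counts,
#' with chain statistics collected along the way.
#'
#' @param reads Read tibble.
#' @param genome A [bs_genome()].
#' @param sites Site tibble; computed from `genome` when omitted.
#' @param max_mismatch Mismatch cap for the aligner.
#' @param filter_stage `"pre_alignment"` (the operative protocol) or
#'   `"post_alignment"` (apply the unconverted-read filter to uniquely
#'   aligned reads instead).
#' @param max_noncg_c Unconverted-read threshold (see
#'   [filter_nonconverted()]).
#' @return List with `counts`, `alignments`, and `stats` (a
#'   [library_stats()] tibble).
#' @export
process_bisulfite_reads <- function(reads, genome, sites = NULL,
                                    max_mismatch = 2L,
                                    filter_stage = c("pre_alignment", "post_alignment"),
                                    max_noncg_c = 3L) {
  filter_stage <- match.arg(filter_stage)
  if (is.null(sites)) sites <- annotate_contexts(genome)
  n_in <- nrow(reads)
  if (filter_stage == "pre_alignment") {
    reads <- filter_nonconverted(reads, max_noncg_c)
  }
  n_filtered <- nrow(reads)
  aln <- align_bisulfite_reads(reads, genome, max_mismatch = max_mismatch)
  if (filter_stage == "post_alignment") {
    keep_ids <- filter_nonconverted(
      reads[match(aln$read_id, reads$read_id), , drop = FALSE], max_noncg_c
    )$read_id
    aln <- aln[aln$read_id %in% keep_ids, , drop = FALSE]
    n_filtered <- length(keep_ids)
  }
  n_unique <- nrow(aln)
  aln <- deduplicate_clonal(aln)
  n_post <- nrow(aln)
  counts <- pileup_counts(aln, genome, sites)
  stats <- library_stats(
    counts, genome, sites,
    chain = c(reads_in = n_in, reads_after_filter = n_filtered,
              reads_unique = n_unique, reads_post_processed = n_post)
  )
  list(counts = counts, alignments = aln, stats = stats)
}

#' Library-level summary statistics
#'
#' CpG coverage is the fraction of CG-context sites seen by at least one
#' informative read. The bisulfite conversion rate is estimated from the
#' unmethylated mitochondrial contig as sum(n - m) / sum(n) over its
#' cytosines.
#'
#' @param counts Count tibble.
#' @param genome A [bs_genome()] with a mito contig designated (otherwise
#'   the conversion rate is reported as `NA` with a warning).
#' @param sites Site tibble (denominator for coverage).
#' @param chain Optional named vector of read counts along the processing
#'   chain.
#' @return One-row tibble: `cpg_coverage_fraction`, `conversion_rate`,
#'   `mean_depth`, plus any chain counts.
#' @export
library_stats <- function(counts, genome, sites, chain = NULL) {
  cg_all <- sum(sites$context == "CG")
  covered <- counts %>% dplyr::filter(.data$context == "CG", .data$n >= 1)
  cov_frac <- if (cg_all == 0) NA_real_ else nrow(covered) / cg_all
  conv <- NA_real_
  if (!is.null(genome$mito)) {
    mito <- counts %>% dplyr::filter(.data$contig == genome$mito)
    if (nrow(mito) > 0 && sum(mito$n) > 0) {
      conv <- sum(mito$n - mito$m) / sum(mito$n)
    } else {
      warning("no coverage on the mitochondrial contig; conversion rate unavailable")
    }
  } else {
    warning("no mitochondrial contig designated; conversion rate unavailable")
  }
  if (nrow(counts) == 0) warning("empty counts: library statistics are degenerate")
  out <- tibble::tibble(
    cpg_coverage_fraction = cov_frac,
    conversion_rate = conv,
    mean_depth = if (nrow(sites) == 0) NA_real_ else sum(counts$n) / nrow(sites)
  )
  if (!is.null(chain)) for (nm in names(chain)) out[[nm]] <- chain[[nm]]
  out
}

#' Write a per-cytosine count report
#'
#' Tab-separated with 1-based positions (the common cytosine-report
#' dialect): contig, position, strand, context, methylated reads, total
#' reads.
#'
#' @param counts Count tibble (0-based internal coordinates).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cytosine_report <- function(counts, path) {
  counts %>%
    dplyr::transmute(.data$contig, pos = .data$pos + 1L, .data$strand,
                     .data$context, .data$m, .data$n) %>%
    readr::write_tsv(path, col_names = TRUE)
  invisible(path)
}

#' Read a per-cytosine count report written by [write_cytosine_report()]
#' @param path Input path.
#' @return Count tibble with 0-based positions.
#' @export
read_cytosine_report <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE) %>%
    dplyr::mutate(pos = .data$pos - 1L)
}
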