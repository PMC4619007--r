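#' DMR-calling configuration
#'
#' Defaults follow the seed-extend-merge recipe: a 1 kb window moved in
#' 100 bp steps seeds on at least 4 differential mCGs, grows while the
#' trailing window at the moving edge still holds at least 4, and the
#' final region must hold at least 5 differential mCGs over at least 1 kb.
#' Differential sites themselves need Benjamini-Hochberg q below `fdr` and
#' at least a `fold`-fold difference in methylation level.
#'
#' @param window_bp,step_bp Window width and step.
#' @param seed_min_sites Differential mCGs required to seed/extend.
#' @param final_min_sites Differential mCGs required of a reported DMR.
#' @param min_length_bp Minimum DMR length.
#' @param fdr Site-level FDR for Fisher's exact test.
#' @param fold Minimum level ratio (inclusive) between the two lines.
#' @param fold_on `"level"` compares m/n ratios; `"pseudocount"` adds 0.5
#'   to both levels' numerators and denominators before the ratio, the
#'   conservative alternative when one level is 0.
#' @param boundary_refine_p After detection, the core boundary of a DMR is
#'   walked outward from the outermost genome-wide-significant site over
#'   consecutive member sites that still show site-local differential
#'   evidence (raw Fisher p at or below this value, fold satisfied); the
#'   walk stops at the first non-supporting site. `NULL` disables
#'   refinement. Rationale: detection uses the strict genome-wide FDR, but
#'   a boundary site of a true DMR can miss that bar by sampling noise, so
#'   relaxed local evidence sharpens the edge without admitting new DMRs.
#' @return A `dmr_config` list.
#' @export
dmr_config <- function(window_bp = 1000L, step_bp = 100L, seed_min_sites = 4L,
                       final_min_sites = 5L, min_length_bp = 1000L,
                       fdr = 0.05, fold = 2.0,
                       fold_on = c("level", "pseudocount"),
                       boundary_refine_p = 0.01) {
  fold_on <- match.arg(fold_on)
  stopifnot(window_bp > 0, step_bp > 0, step_bp <= window_bp,
            seed_min_sites > 0, final_min_sites > 0, min_length_bp > 0,
            fdr > 0, fdr < 1, fold >= 1,
            is.null(boundary_refine_p) ||
              (boundary_refine_p > 0 && boundary_refine_p < 1))
  structure(list(window_bp = as.integer(window_bp), step_bp = as.integer(step_bp),
                 seed_min_sites = as.integer(seed_min_sites),
                 final_min_sites = as.integer(final_min_sites),
                 min_length_bp = as.integer(min_length_bp),
                 fdr = fdr, fold = fold, fold_on = fold_on,
                 boundary_refine_p = boundary_refine_p),
            class = "dmr_config")
}

#' Two-sided Fisher's exact p-value for 2x2 count tables, vectorised
#'
#' Direct hypergeometric computation (sum of all table probabilities not
#' exceeding the observed one, with the customary relative tolerance
#' 1e-7), memoised over distinct tables so genome-scale site testing stays
#' fast.
#'
#' @param m_a,n_a,m_b,n_b Methylated and total read counts in samples A
#'   and B (the table is `[[m_a, n_a - m_a], [m_b, n_b - m_b]]`).
#' @return Numeric vector of p-values.
#' @export
fisher_exact_p <- function(m_a, n_a, m_b, n_b) {
  key <- paste(m_a, n_a, m_b, n_b)
  uk <- !duplicated(key)
  up <- vapply(which(uk), function(i) {
    fisher_p_one(m_a[i], n_a[i], m_b[i], n_b[i])
  }, numeric(1))
  unname(up[match(key, key[uk])])
}

fisher_p_one <- function(ma, na, mb, nb) {
  q <- ma + mb
  lo <- max(0L, q - nb)
  hi <- min(q, na)
  x <- lo:hi
  d <- dhyper(x, q, na + nb - q, na)
  sum(d[d <= d[x == ma] * (1 + 1e-7)])
}

#' Test per-site differential methylation between two lines
#'
#' CG-context sites covered in both lines are tested with a two-sided
#' Fisher's exact test on the 2x2 methylated/unmethylated read table,
#' corrected across all tested sites by Benjamini-Hochberg. A site is
#' `significant` when its q-value is at or below the FDR *and* the two
#' methylation levels differ by at least the configured fold (when the
#' smaller level is exactly 0 and the larger is positive the fold
#' criterion is treated as satisfied under the default `fold_on =
#' "level"`).
#'
#' @param counts_a,counts_b Count tibbles for the two lines
#'   (replicate-pooled).
#' @param config A [dmr_config()].
#' @return Tibble of tested sites with `m_a`, `n_a`, `m_b`, `n_b`,
#'   `level_a`, `level_b`, `fisher_p`, `q_value`, `fold_satisfied`,
#'   `significant`. Sites uncovered in either line are skipped and counted
#'   in attribute `n_skipped`.
#' @export
test_differential_sites <- function(counts_a, counts_b, config = dmr_config()) {
  cg_a <- counts_a %>% dplyr::filter(.data$context == "CG")
  cg_b <- counts_b %>% dplyr::filter(.data$context == "CG")
  joined <- dplyr::inner_join(
    cg_a, cg_b, by = c("contig", "pos", "strand", "context"),
    suffix = c("_a", "_b")
  ) %>% dplyr::filter(.data$n_a >= 1, .data$n_b >= 1)
  n_skipped <- nrow(cg_a) + nrow(cg_b) - 2L * nrow(joined)
  if (nrow(joined) == 0) {
    out <- tibble::tibble()
    attr(out, "n_skipped") <- n_skipped
    return(out)
  }
  out <- joined %>%
    dplyr::mutate(
      level_a = .data$m_a / .data$n_a,
      level_b = .data$m_b / .data$n_b,
      fisher_p = fisher_exact_p(.data$m_a, .data$n_a, .data$m_b, .data$n_b),
      q_value = p.adjust(.data$fisher_p, method = "BH")
    )
  lo <- pmin(out$level_a, out$level_b)
  hi <- pmax(out$level_a, out$level_b)
  if (config$fold_on == "level") {
    out$fold_satisfied <- ifelse(lo == 0, hi > 0, hi / lo >= config$fold)
  } else {
    la <- (out$m_a + 0.5) / (out$n_a + 0.5)
    lb <- (out$m_b + 0.5) / (out$n_b + 0.5)
    out$fold_satisfied <- pmax(la, lb) / pmin(la, lb) >= config$fold
  }
  out$significant <- out$q_value <= config$fdr & out$fold_satisfied
  attr(out, "n_skipped") <- n_skipped
  out
}

#' Find differentially methylated regions by seed-extend-merge
#'
#' Step-aligned windows of `window_bp` holding at least `seed_min_sites`
#' significant differential mCGs are seeds; a seed grows along consecutive
#' qualifying windows (equivalently, stops in a direction as soon as the
#' trailing window at the growing edge holds fewer). The grown span is
#' kept when it holds at least `final_min_sites` significant sites over at
#' least `min_length_bp`; kept spans that overlap or are book-ended are
#' merged. `start`/`end` give the detected window span (always at least
#' `min_length_bp`); `core_start`/`core_end` give the tight span of the
#' outermost member differential mCGs, which is the better boundary
#' estimate. Direction is the majority sign of `level_a - level_b` over
#' member sites (`mixed` on a tie).
#'
#' @param diff_sites Output of [test_differential_sites()].
#' @param config A [dmr_config()].
#' @return A `dmr_set` object; `tidy()` returns the DMR tibble.
#' @export
find_dmrs <- function(diff_sites, config = dmr_config()) {
  sig <- diff_sites %>%
    dplyr::filter(.data$significant) %>%
    dplyr::arrange(.data$contig, .data$pos)
  dmrs <- purrr::map_dfr(unique(sig$contig), function(nm) {
    sub <- sig[sig$contig == nm, , drop = FALSE]
    tested_con <- diff_sites[diff_sites$contig == nm, , drop = FALSE]
    tested_con <- tested_con[order(tested_con$pos), , drop = FALSE]
    pos <- sort(sub$pos)
    if (length(pos) < config$final_min_sites) return(NULL)
    step <- config$step_bp; w <- config$window_bp
    smax <- max(pos) %/% step * step
    starts <- seq(0L, smax, by = step)
    cnt <- findInterval(starts + w - 0.5, pos) - findInterval(starts - 0.5, pos)
    qs <- starts[cnt >= config$seed_min_sites]
    if (length(qs) == 0) return(NULL)
    brk <- which(diff(qs) > step)
    span_start <- qs[c(1, brk + 1)]
    span_end <- qs[c(brk, length(qs))] + w
    cand <- tibble::tibble(start = span_start, end = span_end) %>%
      dplyr::mutate(n_sites = vapply(seq_along(span_start), function(i) {
        sum(pos >= span_start[i] & pos < span_end[i])
      }, integer(1))) %>%
      dplyr::filter(.data$n_sites >= config$final_min_sites,
                    .data$end - .data$start >= config$min_length_bp)
    if (nrow(cand) == 0) return(NULL)
    # merge overlapping/book-ended candidates
    merged <- list()
    cur <- c(cand$start[1], cand$end[1])
    for (i in seq_len(nrow(cand))[-1]) {
      if (cand$start[i] <= cur[2]) {
        cur[2] <- max(cur[2], cand$end[i])
      } else {
        merged[[length(merged) + 1]] <- cur
        cur <- c(cand$start[i], cand$end[i])
      }
    }
    merged[[length(merged) + 1]] <- cur
    purrr::map_dfr(merged, function(iv) {
      member <- sub[sub$pos >= iv[1] & sub$pos < iv[2], , drop = FALSE]
      sgn <- sign(member$level_a - member$level_b)
      dir <- if (sum(sgn > 0) > sum(sgn < 0)) "hyper_in_A"
             else if (sum(sgn < 0) > sum(sgn > 0)) "hyper_in_B" else "mixed"
      core <- c(min(member$pos), max(member$pos))
      if (!is.null(config$boundary_refine_p)) {
        tested <- tested_con[tested_con$pos >= iv[1] & tested_con$pos < iv[2], ,
                             drop = FALSE]
        supp <- tested$fisher_p <= config$boundary_refine_p &
          tested$fold_satisfied
        for (ii in rev(which(tested$pos < core[1]))) {
          if (supp[ii]) core[1] <- tested$pos[ii] else break
        }
        for (ii in which(tested$pos > core[2])) {
          if (supp[ii]) core[2] <- tested$pos[ii] else break
        }
      }
      tibble::tibble(
        contig = nm, start = iv[1], end = iv[2], length = iv[2] - iv[1],
        core_start = core[1], core_end = core[2] + 1L,
        n_diff_sites = nrow(member), direction = dir
      )
    })
  })
  if (nrow(dmrs) == 0) {
    dmrs <- tibble::tibble(contig = character(0), start = integer(0),
                           end = integer(0), length = integer(0),
                           core_start = integer(0), core_end = integer(0),
                           n_diff_sites = integer(0), direction = character(0))
  }
  structure(list(dmrs = dmrs, config = config,
                 n_sites_tested = nrow(diff_sites),
                 n_sites_significant = nrow(sig)),
            class = "dmr_set")
}

#' @export
print.dmr_set <- function(x, ...) {
  cat("<dmr_set> ", nrow(x$dmrs), " DMRs from ", x$n_sites_significant,
      " differential mCGs (", x$n_sites_tested, " sites tested)\n", sep = "")
  if (nrow(x$dmrs)) print(utils::head(x$dmrs, 5))
  invisible(x)
}

#' @rdname find_dmrs
#' @param x A `dmr_set`.
#' @param ... Unused.
#' @export
tidy.dmr_set <- function(x, ...) x$dmrs

#' @rdname find_dmrs
#' @export
glance.dmr_set <- function(x, ...) {
  tibble::tibble(
    n_dmrs = nrow(x$dmrs),
    n_sites_tested = x$n_sites_tested,
    n_sites_significant = x$n_sites_significant,
    total_length = sum(x$dmrs$length),
    n_hyper_in_A = sum(x$dmrs$direction == "hyper_in_A"),
    n_hyper_in_B = sum(x$dmrs$direction == "hyper_in_B")
  )
}

as_dmr_tbl <- function(dmrs) {
  if (inherits(dmrs, "dmr_set")) dmrs$dmrs else tibble::as_tibble(dmrs)
}

#' Associate DMRs with genes
#'
#' A DMR is associated with every gene whose span, extended by `flank_bp`
#' on both sides, overlaps it by at least one base; a gene may collect
#' several DMRs and a DMR several genes.
#'
#' @param dmrs A `dmr_set` or DMR tibble.
#' @param genes A `gene_models` or genes tibble.
#' @param flank_bp Flank width (default 2 kb).
#' @return Tibble with one row per (gene, DMR) association.
#' @export
associate_dmrs_with_genes <- function(dmrs, genes, flank_bp = 2000L) {
  d <- as_dmr_tbl(dmrs)
  g <- as_genes_tbl(genes)
  if (nrow(d) == 0 || nrow(g) == 0) {
    return(tibble::tibble(gene_id = character(0), contig = character(0),
                          dmr_start = integer(0), dmr_end = integer(0),
                          direction = character(0)))
  }
  gr_d <- GenomicRanges::GRanges(d$contig, IRanges::IRanges(d$start + 1L, d$end))
  gr_g <- GenomicRanges::GRanges(
    g$contig,
    IRanges::IRanges(pmax(0L, g$start - flank_bp) + 1L, g$end + flank_bp)
  )
  ov <- GenomicRanges::findOverlaps(gr_g, gr_d)
  tibble::tibble(
    gene_id = g$gene_id[S4Vectors::queryHits(ov)],
    contig = d$contig[S4Vectors::subjectHits(ov)],
    dmr_start = d$start[S4Vectors::subjectHits(ov)],
    dmr_end = d$end[S4Vectors::subjectHits(ov)],
    n_diff_sites = d$n_diff_sites[S4Vectors::subjectHits(ov)],
    direction = d$direction[S4Vectors::subjectHits(ov)]
  )
}

#' Flag expression differences of DMR-associated genes
#'
#' Genes whose read counts are below 10 in both lines are flagged
#' `not_expressed`; for the rest the fold change is the larger count over
#' the smaller, and `two_fold` requires it to exceed 2 strictly. Genes
#' missing from an expression table are retained and flagged.
#'
#' @param dmr_genes Gene association tibble from
#'   [associate_dmrs_with_genes()] (or any tibble with `gene_id`).
#' @param expression_a,expression_b Tibbles `gene_id`, `reads` (a second
#'   column of any name is used as the read count).
#' @param min_reads Expression floor (default 10; below it in both lines a
#'   gene is not-expressed).
#' @param fold Fold-change boundary (exclusive; default 2).
#' @return One row per distinct gene: read counts, `status`
#'   (`ok`/`not_expressed`/`missing`), `fold_change`, `two_fold`,
#'   `higher_in`.
#' @export
integrate_expression_differences <- function(dmr_genes, expression_a,
                                             expression_b, min_reads = 10,
                                             fold = 2) {
  norm_expr <- function(x, nm) {
    stopifnot("gene_id" %in% names(x))
    val <- setdiff(names(x), "gene_id")[1]
    out <- tibble::tibble(gene_id = x$gene_id, reads = as.numeric(x[[val]]))
    names(out)[2] <- nm
    out
  }
  ea <- norm_expr(expression_a, "reads_a")
  eb <- norm_expr(expression_b, "reads_b")
  out <- dmr_genes %>%
    dplyr::distinct(.data$gene_id) %>%
    dplyr::left_join(ea, by = "gene_id") %>%
    dplyr::left_join(eb, by = "gene_id") %>%
    dplyr::mutate(
      status = dplyr::case_when(
        is.na(.data$reads_a) | is.na(.data$reads_b) ~ "missing",
        .data$reads_a < min_reads & .data$reads_b < min_reads ~ "not_expressed",
        TRUE ~ "ok"
      ),
      fold_change = ifelse(
        .data$status == "ok",
        pmax(.data$reads_a, .data$reads_b) /
          pmin(.data$reads_a, .data$reads_b),
        NA_real_
      ),
      two_fold = !is.na(.data$fold_change) & .data$fold_change > fold,
      higher_in = dplyr::case_when(
        .data$status != "ok" ~ NA_character_,
        .data$reads_a > .data$reads_b ~ "A",
        .data$reads_b > .data$reads_a ~ "B",
        TRUE ~ "equal"
      )
    )
  out
}
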