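#' Estimate the bisulfite error rate from the unmethylated control contig
#'
#' The probability p of the binomial null B(n, p) is the combined
#' non-conversion + sequencing error frequency, estimated as the fraction
#' of cytosine base calls observed at reference cytosine positions of the
#' unmethylated mitochondrion-like contig (both strands, all contexts).
#'
#' @param counts Count tibble covering the mito contig.
#' @param genome A [bs_genome()] with `mito` designated.
#' @return An `error_model` list: `p`, `source_contig`, `bases_observed`.
#' @export
estimate_error_rate <- function(counts, genome) {
  if (is.null(genome$mito)) stop("no mitochondrial contig designated")
  mito <- counts %>% dplyr::filter(.data$contig == genome$mito)
  tot <- sum(mito$n)
  if (tot == 0) stop("zero coverage on mitochondrial contig '", genome$mito, "'")
  p <- sum(mito$m) / tot
  if (p == 0) {
    p <- 1 / (tot + 1)
    warning("no methylated bases observed on the control contig; ",
            "error rate clamped to 1/(total bases + 1) = ", signif(p, 3))
  }
  if (p >= 1) stop("estimated error rate is 1: control contig appears fully methylated")
  structure(list(p = p, source_contig = genome$mito, bases_observed = tot),
            class = "error_model")
}

#' @export
print.error_model <- function(x, ...) {
  cat("<error_model> p = ", signif(x$p, 4), " from ", x$source_contig,
      " (", format(x$bases_observed, big.mark = ","), " bases)\n", sep = "")
  invisible(x)
}

#' Methylcytosine-calling configuration
#'
#' Two modes are available. `literal` applies, per site, the printed
#' inequality choose(n,m) p^m (1-p)^(n-m) < 0.01 m / (n - m), with the
#' right-hand side taken as +Inf when m = n (the only consistent reading of
#' the division by zero). `tail_fdr` (the default) instead controls the
#' expected number of false calls below `fdr_target` of all calls using
#' one-sided binomial tail probabilities and a genome-wide depth-stratified
#' threshold; this realises the stated guarantee that false positives stay
#' below 1 % of the methylcytosines identified.
#'
#' @param mode `"tail_fdr"` or `"literal"`.
#' @param fdr_target Target false-call fraction (default 0.01).
#' @param min_depth Minimum depth for a site to be testable (default 1).
#' @return A `calling_config` list.
#' @export
calling_config <- function(mode = c("tail_fdr", "literal"), fdr_target = 0.01,
                           min_depth = 1L) {
  mode <- match.arg(mode)
  stopifnot(fdr_target > 0, fdr_target < 1, min_depth >= 1)
  structure(list(mode = mode, fdr_target = fdr_target,
                 min_depth = as.integer(min_depth)),
            class = "calling_config")
}

# literal inequality, vectorised over m for one n
literal_satisfied <- function(n, p) {
  m <- seq_len(n)
  lhs <- dbinom(m, n, p)
  rhs <- ifelse(m == n, Inf, 0.01 * m / (n - m))
  lhs < rhs
}

#' Minimum methylated-read count that triggers a call
#'
#' In `literal` mode, the smallest m in 1..n satisfying the printed
#' inequality. Calls are required to be upward-closed in m: if the
#' satisfying set is not upward-closed for some (n, p) the threshold moves
#' to the smallest m from which it is, with a warning. In `tail_fdr` mode
#' the per-depth threshold is the smallest m whose one-sided tail
#' probability P(X >= m | n, p) falls below a genome-wide cutoff, which
#' must be supplied (see [tail_fdr_thresholds()]).
#'
#' @param n Read depth(s); vectorised.
#' @param error_model An [estimate_error_rate()] result (or a probability).
#' @param config A [calling_config()].
#' @param alpha Tail-probability cutoff (tail_fdr mode only).
#' @return Integer vector of thresholds; `NA` where no m in 1..n triggers.
#' @export
min_methylated_reads <- function(n, error_model, config = calling_config(),
                                 alpha = NULL) {
  p <- if (inherits(error_model, "error_model")) error_model$p else error_model
  vapply(as.integer(n), function(ni) {
    if (ni < 1) return(NA_integer_)
    if (config$mode == "literal") {
      sat <- literal_satisfied(ni, p)
      if (!any(sat)) return(NA_integer_)
      first <- which(sat)[1]
      if (all(sat[first:ni])) return(first)
      last_false <- ni + 1L - match(FALSE, rev(sat))
      if (last_false >= ni) return(NA_integer_)
      warning("literal criterion not upward-closed at n = ", ni,
              "; calling from m = ", last_false + 1L)
      return(as.integer(last_false + 1L))
    }
    if (is.null(alpha)) {
      stop("tail_fdr mode needs the genome-wide cutoff; use call_methylcytosines()",
           " or supply alpha")
    }
    tail <- pbinom(seq_len(ni) - 1L, ni, p, lower.tail = FALSE)
    idx <- which(tail <= alpha)
    if (length(idx) == 0) NA_integer_ else idx[1]
  }, integer(1))
}

#' Depth-stratified tail-FDR thresholds
#'
#' Chooses the largest tail-probability cutoff alpha such that the expected
#' number of false calls — the sum over all tested sites of
#' P(X >= m*(n_site) | n_site, p) — stays below `fdr_target` times the
#' number of sites actually called at that cutoff. Candidate cutoffs are
#' the distinct attainable tail probabilities.
#'
#' @param counts Count tibble of the tested sites (supplies the genome-wide
#'   depth spectrum and observed m).
#' @param error_model An [estimate_error_rate()] result (or a probability).
#' @param config A [calling_config()].
#' @return List: `alpha`, `thresholds` (tibble `n`, `m_star`, `tail_p`),
#'   `expected_fp`, `n_calls`.
#' @export
tail_fdr_thresholds <- function(counts, error_model, config = calling_config()) {
  p <- if (inherits(error_model, "error_model")) error_model$p else error_model
  tested <- counts %>% dplyr::filter(.data$n >= config$min_depth)
  if (nrow(tested) == 0) stop("no testable sites at min_depth = ", config$min_depth)
  depth_tab <- tested %>% dplyr::count(.data$n, name = "n_sites")
  obs_tab <- tested %>% dplyr::count(.data$n, .data$m, name = "n_obs")
  depths <- depth_tab$n
  tails <- lapply(depths, function(ni) {
    pbinom(seq_len(ni) - 1L, ni, p, lower.tail = FALSE)
  })
  names(tails) <- as.character(depths)
  cand <- sort(unique(unlist(tails)), decreasing = TRUE)
  cand <- cand[cand > 0]
  for (alpha in cand) {
    m_star <- vapply(seq_along(depths), function(i) {
      idx <- which(tails[[i]] <= alpha)
      if (length(idx) == 0) NA_integer_ else idx[1]
    }, integer(1))
    thr <- m_star[match(obs_tab$n, depths)]
    n_calls <- sum(obs_tab$n_obs[!is.na(thr) & obs_tab$m >= thr])
    efp <- sum(depth_tab$n_sites[!is.na(m_star)] *
                 vapply(which(!is.na(m_star)),
                        function(i) tails[[i]][m_star[i]], numeric(1)))
    if (n_calls > 0 && efp <= config$fdr_target * n_calls) {
      return(list(
        alpha = alpha,
        thresholds = tibble::tibble(
          n = depths, m_star = m_star,
          tail_p = vapply(seq_along(depths), function(i) {
            if (is.na(m_star[i])) NA_real_ else tails[[i]][m_star[i]]
          }, numeric(1))
        ),
        expected_fp = efp, n_calls = n_calls
      ))
    }
  }
  # no cutoff admits any call under the budget
  list(alpha = 0,
       thresholds = tibble::tibble(n = depths, m_star = NA_integer_,
                                   tail_p = NA_real_),
       expected_fp = 0, n_calls = 0)
}

#' Call methylcytosines by the binomial criterion
#'
#' A covered site is called methylated when its depth reaches `min_depth`
#' and its methylated-read count reaches the mode-specific threshold for
#' that depth (see [calling_config()]). Uncovered sites are absent from the
#' output.
#'
#' @param counts Count tibble.
#' @param error_model From [estimate_error_rate()].
#' @param config A [calling_config()].
#' @return An `mc_calls` object; `tidy()` returns the call tibble (with
#'   per-site `level = m/n` and the decision evidence), `glance()` a
#'   one-row summary.
#' @export
call_methylcytosines <- function(counts, error_model,
                                 config = calling_config()) {
  if (nrow(counts) == 0) stop("empty counts")
  p <- if (inherits(error_model, "error_model")) error_model$p else error_model
  tested <- counts %>% dplyr::filter(.data$n >= config$min_depth)
  if (config$mode == "tail_fdr") {
    cal <- tail_fdr_thresholds(tested, error_model, config)
    thr_tbl <- cal$thresholds
  } else {
    depths <- sort(unique(tested$n))
    thr_tbl <- tibble::tibble(
      n = depths,
      m_star = min_methylated_reads(depths, error_model, config)
    )
    cal <- list(alpha = NA_real_, thresholds = thr_tbl,
                expected_fp = NA_real_, n_calls = NA_integer_)
  }
  joined <- tested %>%
    dplyr::left_join(thr_tbl[, c("n", "m_star")], by = "n") %>%
    dplyr::filter(!is.na(.data$m_star), .data$m >= .data$m_star)
  calls <- joined %>%
    dplyr::mutate(level = .data$m / .data$n)
  if (config$mode == "literal") {
    calls <- calls %>%
      dplyr::mutate(
        lhs = dbinom(.data$m, .data$n, p),
        rhs = ifelse(.data$m == .data$n, Inf, 0.01 * .data$m / (.data$n - .data$m))
      )
  } else {
    calls <- calls %>%
      dplyr::mutate(tail_p = pbinom(.data$m - 1L, .data$n, p, lower.tail = FALSE))
  }
  structure(list(
    calls = calls, error_model = error_model, config = config,
    calibration = cal, n_tested = nrow(tested)
  ), class = "mc_calls")
}

#' @export
print.mc_calls <- function(x, ...) {
  cat("<mc_calls> ", nrow(x$calls), " methylcytosines from ", x$n_tested,
      " tested sites (mode ", x$config$mode, ")\n", sep = "")
  invisible(x)
}

#' @rdname call_methylcytosines
#' @param x An `mc_calls` object.
#' @param ... Unused.
#' @export
tidy.mc_calls <- function(x, ...) x$calls

#' @rdname call_methylcytosines
#' @export
glance.mc_calls <- function(x, ...) {
  p <- if (inherits(x$error_model, "error_model")) x$error_model$p else x$error_model
  tibble::tibble(
    n_calls = nrow(x$calls), n_tested = x$n_tested,
    error_p = p, mode = x$config$mode,
    fdr_target = x$config$fdr_target,
    alpha = x$calibration$alpha,
    expected_fp = x$calibration$expected_fp
  )
}

# accept an mc_calls object or a bare call/count tibble
as_calls_tbl <- function(calls) {
  if (inherits(calls, "mc_calls")) calls$calls else tibble::as_tibble(calls)
}

#' Pool per-cytosine counts across libraries or replicates
#'
#' Site-wise summation of methylated and total read counts, the operation
#' used to combine technical libraries before calling and biological
#' replicates before line-level differential testing.
#'
#' @param ... Count tibbles.
#' @return A single count tibble with summed `m` and `n`.
#' @export
pool_counts <- function(...) {
  dplyr::bind_rows(...) %>%
    dplyr::group_by(.data$contig, .data$pos, .data$strand, .data$context) %>%
    dplyr::summarise(m = sum(.data$m), n = sum(.data$n), .groups = "drop") %>%
    dplyr::arrange(.data$contig, .data$pos, .data$strand)
}

#' Consensus of two replicates' methylcytosine calls
#'
#' The site-wise intersection of the two call sets; per-site levels are
#' recomputed from the pooled counts (m1 + m2) / (n1 + n2).
#'
#' @param calls_rep1,calls_rep2 `mc_calls` objects or call tibbles.
#' @return Call tibble of the consensus sites.
#' @export
consensus_calls <- function(calls_rep1, calls_rep2) {
  a <- as_calls_tbl(calls_rep1)
  b <- as_calls_tbl(calls_rep2)
  dplyr::inner_join(
    a[, c("contig", "pos", "strand", "context", "m", "n")],
    b[, c("contig", "pos", "strand", "m", "n")],
    by = c("contig", "pos", "strand"), suffix = c("_1", "_2")
  ) %>%
    dplyr::transmute(
      .data$contig, .data$pos, .data$strand, .data$context,
      m = .data$m_1 + .data$m_2, n = .data$n_1 + .data$n_2,
      level = .data$m / .data$n
    )
}

#' Genome-wide methylome summary
#'
#' Context composition of the calls, the decile histogram of CG call
#' levels (right-closed top bin), and strand-signed methylcytosine density
#' in fixed windows (positive for the forward strand, negative for the
#' reverse), the representation used for chromosome-scale density plots.
#'
#' @param calls `mc_calls` or call tibble (needs `level`).
#' @param genome Optional [bs_genome()] supplying contig extents for the
#'   window track.
#' @param window_bp Window width (default 10 kb).
#' @return A `methylome_summary` list of tibbles: `context_fractions`,
#'   `level_histogram`, `window_density`.
#' @export
methylome_summary <- function(calls, genome = NULL, window_bp = 10000L) {
  ct <- as_calls_tbl(calls)
  if (nrow(ct) == 0) {
    warning("no calls: summary is all zero")
    return(structure(list(
      context_fractions = tibble::tibble(context = c("CG", "CHG", "CHH"),
                                         fraction = 0),
      level_histogram = tibble::tibble(bin_low = seq(0, 0.9, 0.1),
                                       bin_high = seq(0.1, 1, 0.1), fraction = 0),
      window_density = tibble::tibble()
    ), class = "methylome_summary"))
  }
  ctx <- ct %>%
    dplyr::filter(.data$context %in% c("CG", "CHG", "CHH")) %>%
    dplyr::count(.data$context) %>%
    dplyr::mutate(fraction = .data$n / sum(.data$n)) %>%
    dplyr::select("context", "fraction") %>%
    tidyr::complete(context = c("CG", "CHG", "CHH"),
                    fill = list(fraction = 0))
  lv <- ct %>% dplyr::filter(.data$context == "CG")
  bin <- pmin(floor(lv$level * 10), 9)
  hist <- tibble::tibble(bin = 0:9) %>%
    dplyr::left_join(tibble::tibble(bin = bin) %>% dplyr::count(.data$bin),
                     by = "bin") %>%
    dplyr::mutate(
      bin_low = .data$bin / 10, bin_high = (.data$bin + 1) / 10,
      fraction = dplyr::coalesce(.data$n, 0L) / nrow(lv)
    ) %>%
    dplyr::select("bin_low", "bin_high", "fraction")
  dens <- ct %>%
    dplyr::mutate(window_start = (.data$pos %/% window_bp) * window_bp) %>%
    dplyr::count(.data$contig, .data$window_start, .data$strand) %>%
    dplyr::mutate(density = ifelse(.data$strand == "+", 1, -1) *
                    .data$n / window_bp) %>%
    dplyr::select("contig", "window_start", "strand", "density")
  if (!is.null(genome)) {
    grid <- purrr::map_dfr(names(genome$contigs), function(nm) {
      tidyr::expand_grid(
        contig = nm,
        window_start = seq(0L, contig_lengths(genome)[[nm]] - 1L, by = window_bp),
        strand = c("+", "-")
      )
    })
    dens <- grid %>%
      dplyr::left_join(dens, by = c("contig", "window_start", "strand")) %>%
      dplyr::mutate(density = dplyr::coalesce(.data$density, 0))
  }
  structure(list(context_fractions = ctx, level_histogram = hist,
                 window_density = dens),
            class = "methylome_summary")
}

#' @export
print.methylome_summary <- function(x, ...) {
  cat("<methylome_summary>\ncontext fractions:\n")
  print(x$context_fractions)
  cat("CG level deciles:\n")
  print(x$level_histogram)
  invisible(x)
}
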