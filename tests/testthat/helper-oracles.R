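# Independent oracles shared by module and acceptance tests. These
# re-derive expected values by brute force (direct formulas, explicit
# loops, exhaustive enumeration) and share no code with the package
# implementation they check.

# Independent oracle for the literal calling inequality: direct evaluation
# with choose(), no shared code with the implementation.
literal_oracle_mstar <- function(n, p) {
  sat <- logical(n)
  for (m in 1:n) {
    lhs <- choose(n, m) * p^m * (1 - p)^(n - m)
    rhs <- if (m == n) Inf else 0.01 * m / (n - m)
    sat[m] <- lhs < rhs
  }
  if (!any(sat)) return(NA_integer_)
  # smallest m from which the satisfying set is upward-closed
  for (m in which(sat)) if (all(sat[m:n])) return(m)
  NA_integer_
}


# Independent oracle: per-window recomputation with explicit loops, naive
# merging, and exhaustive longest-subinterval search. Shares no code with
# the scanning implementation.
cgi_oracle <- function(seq, min_gc = 0.55, min_oe = 0.65, min_len = 500L) {
  ch <- strsplit(toupper(seq), "")[[1]]
  L <- length(ch)
  w <- min_len + 1L
  if (L < w) return(tibble::tibble(start = integer(0), end = integer(0)))
  ok_iv <- function(s, e) {  # 0-based half-open
    seg <- ch[(s + 1):e]
    if (any(seg == "N")) return(FALSE)
    nc <- sum(seg == "C"); ng <- sum(seg == "G")
    gc <- (nc + ng) / length(seg)
    ncg <- sum(seg[-length(seg)] == "C" & seg[-1] == "G")
    oe <- if (nc == 0 || ng == 0) 0 else ncg * length(seg) / (nc * ng)
    gc > min_gc && oe >= min_oe
  }
  marked <- vapply(0:(L - w), function(s) ok_iv(s, s + w), logical(1))
  qs <- which(marked) - 1L
  if (length(qs) == 0) return(tibble::tibble(start = integer(0), end = integer(0)))
  regions <- list(); cur <- c(qs[1], qs[1] + w)
  for (s in qs[-1]) {
    if (s <= cur[2]) cur[2] <- s + w
    else { regions[[length(regions) + 1]] <- cur; cur <- c(s, s + w) }
  }
  regions[[length(regions) + 1]] <- cur
  out <- list()
  for (r in regions) {
    found <- NULL
    for (len in (r[2] - r[1]):w) {
      for (s in r[1]:(r[2] - len)) {
        if (ok_iv(s, s + len)) { found <- c(s, s + len); break }
      }
      if (!is.null(found)) break
    }
    if (!is.null(found)) out[[length(out) + 1]] <- found
  }
  if (length(out) == 0) return(tibble::tibble(start = integer(0), end = integer(0)))
  m <- do.call(rbind, out)
  tibble::tibble(start = as.integer(m[, 1]), end = as.integer(m[, 2]))
}


# Independent Fisher oracle: hypergeometric enumeration via choose(), no
# dhyper, no shared code with fisher_exact_p().
fisher_oracle <- function(ma, na, mb, nb) {
  q <- ma + mb; tot <- na + nb
  lo <- max(0, q - nb); hi <- min(q, na)
  xs <- lo:hi
  pr <- choose(na, xs) * choose(nb, q - xs) / choose(tot, q)
  sum(pr[pr <= pr[xs == ma] * (1 + 1e-7)])
}

# Brute-force DMR oracle: explicit per-window counting loops, run merging,
# final thresholds, overlap merge.
dmr_oracle <- function(pos, window = 1000L, step = 100L, seed_min = 4L,
                       final_min = 5L, min_len = 1000L) {
  pos <- sort(pos)
  if (length(pos) == 0) return(tibble::tibble(start = integer(0), end = integer(0)))
  starts <- seq(0L, max(pos), by = step)
  qual <- vapply(starts, function(s) sum(pos >= s & pos < s + window) >= seed_min,
                 logical(1))
  qs <- starts[qual]
  if (length(qs) == 0) return(tibble::tibble(start = integer(0), end = integer(0)))
  runs <- list(); cur <- c(qs[1], qs[1] + window)
  for (s in qs[-1]) {
    if (s - (cur[2] - window) == step) cur[2] <- s + window
    else { runs[[length(runs) + 1]] <- cur; cur <- c(s, s + window) }
  }
  runs[[length(runs) + 1]] <- cur
  keep <- Filter(function(r) {
    sum(pos >= r[1] & pos < r[2]) >= final_min && r[2] - r[1] >= min_len
  }, runs)
  if (length(keep) == 0) return(tibble::tibble(start = integer(0), end = integer(0)))
  merged <- list(); cur <- keep[[1]]
  for (r in keep[-1]) {
    if (r[1] <= cur[2]) cur[2] <- max(cur[2], r[2])
    else { merged[[length(merged) + 1]] <- cur; cur <- r }
  }
  merged[[length(merged) + 1]] <- cur
  m <- do.call(rbind, merged)
  tibble::tibble(start = as.integer(m[, 1]), end = as.integer(m[, 2]))
}

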