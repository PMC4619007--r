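#' Construct a bisulfite genome object
#'
#' A `bs_genome` bundles the reference sequence of one or more contigs with
#' an optional soft-mask channel (intervals that were lowercase in the source
#' FASTA) and an optional designation of an unmethylated mitochondrion-like
#' contig, which downstream calling uses to estimate the combined
#' non-conversion + sequencing error rate.
#'
#' @param contigs Named character vector of DNA sequences (A, C, G, T, N).
#'   Sequences are uppercased on construction.
#' @param mito Optional name of the contig to treat as the unmethylated
#'   control (must name an existing contig).
#' @param mask Optional named list of tibbles with columns `start`, `end`
#'   (0-based half-open) giving soft-masked intervals per contig.
#' @return An object of class `bs_genome`.
#' @export
bs_genome <- function(contigs, mito = NULL, mask = NULL) {
  if (length(contigs) == 0) stop("genome must contain at least one contig")
  nm <- names(contigs)
  if (is.null(nm) || any(nm == "") || anyNA(nm)) {
    stop("all contigs must be named")
  }
  if (anyDuplicated(nm)) {
    stop("duplicate contig name: ", nm[duplicated(nm)][1])
  }
  contigs <- toupper(contigs)
  bad <- grepl("[^ACGTN]", contigs)
  if (any(bad)) {
    stop("contig '", nm[bad][1], "' contains characters outside A,C,G,T,N")
  }
  if (!is.null(mito) && !mito %in% nm) {
    stop("mito contig '", mito, "' is not a contig of this genome")
  }
  structure(
    list(contigs = contigs, mito = mito, mask = mask),
    class = "bs_genome"
  )
}

#' @export
print.bs_genome <- function(x, ...) {
  cat("<bs_genome> ", length(x$contigs), " contig(s), ",
      format(sum(nchar(x$contigs)), big.mark = ","), " bp total\n", sep = "")
  for (nm in names(x$contigs)) {
    cat("  ", nm, ": ", format(nchar(x$contigs[[nm]]), big.mark = ","), " bp",
        if (!is.null(x$mito) && nm == x$mito) "  [unmethylated control]" else "",
        "\n", sep = "")
  }
  invisible(x)
}

#' Lengths of the contigs of a genome
#' @param genome A [bs_genome()].
#' @return Named integer vector.
#' @export
contig_lengths <- function(genome) {
  stopifnot(inherits(genome, "bs_genome"))
  vapply(genome$contigs, nchar, integer(1))
}

#' Read a reference genome from FASTA
#'
#' Sequences are uppercased; runs of lowercase (soft-masked) bases in the
#' source are preserved as a separate mask channel on the returned object.
#'
#' @param path Path to a FASTA file.
#' @param mito Optional contig name to flag as the unmethylated control.
#' @return A [bs_genome()].
#' @export
read_fasta <- function(path, mito = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  first <- readLines(path, n = 1L)
  if (length(first) == 0 || !startsWith(first, ">")) {
    stop("malformed FASTA at line 1 of ", path, ": expected a '>' header")
  }
  seqs <- seqinr::read.fasta(path, as.string = TRUE, forceDNAtolower = FALSE,
                             seqtype = "DNA")
  raw <- vapply(seqs, function(s) as.character(s)[1], character(1))
  names(raw) <- vapply(seqs, function(s) attr(s, "name"), character(1))
  if (anyDuplicated(names(raw))) {
    stop("duplicate contig name in ", path, ": ",
         names(raw)[duplicated(names(raw))][1])
  }
  mask <- lapply(raw, function(s) {
    m <- gregexpr("[a-z]+", s)[[1]]
    if (m[1] == -1) {
      return(tibble::tibble(start = integer(0), end = integer(0)))
    }
    tibble::tibble(start = as.integer(m) - 1L,
                   end = as.integer(m) + attr(m, "match.length") - 1L)
  })
  bs_genome(raw, mito = mito, mask = mask)
}

#' Write a genome to FASTA
#'
#' Soft-mask intervals, when present, are written back as lowercase so that
#' a read/write round trip preserves both channels.
#'
#' @param genome A [bs_genome()].
#' @param path Output path.
#' @param width Line width for wrapping sequence.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(genome, path, width = 70L) {
  stopifnot(inherits(genome, "bs_genome"))
  con <- file(path, "w")
  on.exit(close(con))
  for (nm in names(genome$contigs)) {
    s <- genome$contigs[[nm]]
    msk <- genome$mask[[nm]]
    if (!is.null(msk) && nrow(msk) > 0) {
      ch <- strsplit(s, "", fixed = TRUE)[[1]]
      for (i in seq_len(nrow(msk))) {
        idx <- (msk$start[i] + 1L):msk$end[i]
        ch[idx] <- tolower(ch[idx])
      }
      s <- paste(ch, collapse = "")
    }
    writeLines(paste0(">", nm), con)
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

# Split a sequence into a character vector of single bases.
seq_chars <- function(s) strsplit(s, "", fixed = TRUE)[[1]]

#' Annotate every cytosine of a genome with its strand and context
#'
#' Every C on the forward (Watson) strand and every G on the forward strand
#' (a cytosine read on the reverse, Crick, strand) yields one site. The
#' context is taken from the two bases 3' of the cytosine *on its own
#' strand*: CG when the immediate next base is G, otherwise CHG/CHH from the
#' second base (H = A, C or T). Sites whose context bases run off the contig
#' end, or include N, are classed CNN — except that a terminal C immediately
#' followed by G still counts as CG.
#'
#' @param genome A [bs_genome()] or a named character vector of sequences.
#' @param contigs Optional subset of contig names to annotate.
#' @return Tibble with columns `contig`, `pos` (0-based position of the
#'   cytosine on forward-strand coordinates), `strand` (`+`/`-`) and
#'   `context` (`CG`, `CHG`, `CHH`, `CNN`), sorted by contig and position.
#' @export
annotate_contexts <- function(genome, contigs = NULL) {
  if (inherits(genome, "bs_genome")) seqs <- genome$contigs else seqs <- toupper(genome)
  if (length(seqs) == 0) stop("genome is empty")
  if (!is.null(contigs)) seqs <- seqs[contigs]
  out <- lapply(names(seqs), function(nm) {
    ch <- seq_chars(seqs[[nm]])
    n <- length(ch)
    ctx_of <- function(b1_is_G, b1, b2) {
      # b1, b2: the two own-strand downstream bases (NA beyond contig end)
      ctx <- rep("CNN", length(b1))
      h1 <- !is.na(b1) & b1 %in% c("A", "C", "T")
      ok2 <- !is.na(b2) & b2 %in% c("A", "C", "G", "T")
      ctx[h1 & ok2 & b2 == "G"] <- "CHG"
      ctx[h1 & ok2 & b2 != "G"] <- "CHH"
      ctx[b1_is_G] <- "CG"
      ctx
    }
    nxt1 <- c(ch[-1], NA_character_)
    nxt2 <- if (n >= 2) c(ch[-(1:2)], NA_character_, NA_character_) else rep(NA_character_, n)
    prv1 <- c(NA_character_, ch[-n])
    prv2 <- if (n >= 2) c(NA_character_, NA_character_, ch[-((n - 1):n)]) else rep(NA_character_, n)
    comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

    iC <- which(ch == "C")
    plus <- tibble::tibble(
      contig = nm, pos = iC - 1L, strand = "+",
      context = ctx_of(!is.na(nxt1[iC]) & nxt1[iC] == "G",
                       nxt1[iC], nxt2[iC])
    )
    iG <- which(ch == "G")
    # own-strand downstream bases of a Crick cytosine are the complements of
    # the forward-strand bases immediately 5' of the G
    b1 <- unname(comp[prv1[iG]]); b1[is.na(prv1[iG])] <- NA
    b2 <- unname(comp[prv2[iG]]); b2[is.na(prv2[iG])] <- NA
    minus <- tibble::tibble(
      contig = nm, pos = iG - 1L, strand = "-",
      context = ctx_of(!is.na(b1) & b1 == "G", b1, b2)
    )
    dplyr::arrange(dplyr::bind_rows(plus, minus), .data$pos, .data$strand)
  })
  dplyr::bind_rows(out)
}

#' CpG dyads of a site table
#'
#' Groups strand-specific CG-context sites into dyads: the forward-strand C
#' at position p and the reverse-strand C at position p + 1 form one CpG
#' dinucleotide anchored at `dyad_pos = p`.
#'
#' @param sites Site tibble from [annotate_contexts()].
#' @return `sites` filtered to CG context with an added `dyad_pos` column.
#' @export
cg_dyads <- function(sites) {
  sites %>%
    dplyr::filter(.data$context == "CG") %>%
    dplyr::mutate(dyad_pos = ifelse(.data$strand == "+", .data$pos, .data$pos - 1L))
}

#' Read gene models from GTF or BED12
#'
#' GTF exon records (1-based closed) are converted to 0-based half-open
#' intervals; BED12 blocks are used as exons directly. For minus-strand
#' genes the transcription start site is the annotated end coordinate.
#'
#' @param path Path to a `.gtf`/`.gff` or `.bed` (BED12) file.
#' @param genome Optional [bs_genome()]; records on unknown contigs are
#'   skipped with a warning.
#' @param format `"auto"` (by extension), `"gtf"` or `"bed"`.
#' @return A `gene_models` list with elements `genes` (tibble: `gene_id`,
#'   `contig`, `strand`, `start`, `end`, `tss`, `tts`, `n_exons`) and
#'   `exons` (tibble: `gene_id`, `contig`, `strand`, `start`, `end`,
#'   `exon_rank` in 5'→3' order).
#' @export
read_gene_models <- function(path, genome = NULL, format = c("auto", "gtf", "bed")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.(gtf|gff[23]?)$", path, ignore.case = TRUE)) "gtf" else "bed"
  }
  if (format == "gtf") {
    gr <- rtracklayer::import(path, format = "gtf")
    gr <- gr[!is.na(gr$type) & gr$type == "exon"]
    ids <- if (!is.null(gr$gene_id)) gr$gene_id else gr$transcript_id
    ex <- tibble::tibble(
      gene_id = as.character(ids),
      contig = as.character(GenomicRanges::seqnames(gr)),
      strand = as.character(GenomicRanges::strand(gr)),
      start = GenomicRanges::start(gr) - 1L,
      end = GenomicRanges::end(gr)
    )
  } else {
    gr <- rtracklayer::import(path, format = "bed")
    bl <- rtracklayer::blocks(gr)
    ids <- if (!is.null(gr$name)) gr$name else paste0("gene", seq_along(gr))
    ex <- purrr::map_dfr(seq_along(bl), function(i) {
      b <- bl[[i]]
      tibble::tibble(
        gene_id = ids[i],
        contig = as.character(GenomicRanges::seqnames(gr))[i],
        strand = as.character(GenomicRanges::strand(gr))[i],
        start = GenomicRanges::start(b) - 1L,
        end = GenomicRanges::end(b)
      )
    })
  }
  ex$strand[!ex$strand %in% c("+", "-")] <- "+"
  gene_models(ex, genome = genome)
}

#' Assemble gene models from an exon table
#'
#' @param exons Tibble with columns `gene_id`, `contig`, `strand`, `start`,
#'   `end` (0-based half-open exon intervals).
#' @param genome Optional [bs_genome()] used to validate contig names.
#' @return A `gene_models` object; see [read_gene_models()].
#' @export
gene_models <- function(exons, genome = NULL) {
  if (is.null(exons) || nrow(exons) == 0) {
    empty_ex <- tibble::tibble(gene_id = character(0), contig = character(0),
                               strand = character(0), start = integer(0),
                               end = integer(0), exon_rank = integer(0))
    empty_g <- tibble::tibble(gene_id = character(0), contig = character(0),
                              strand = character(0), start = integer(0),
                              end = integer(0), n_exons = integer(0),
                              tss = integer(0), tts = integer(0))
    return(structure(list(genes = empty_g, exons = empty_ex),
                     class = "gene_models"))
  }
  stopifnot(all(c("gene_id", "contig", "strand", "start", "end") %in% names(exons)))
  if (!is.null(genome)) {
    known <- names(genome$contigs)
    bad <- !exons$contig %in% known
    if (any(bad)) {
      skipped <- unique(exons$gene_id[bad])
      warning(length(skipped), " gene(s) on unknown contigs skipped: ",
              paste(utils::head(skipped, 5), collapse = ", "))
      exons <- exons[!exons$gene_id %in% skipped, , drop = FALSE]
    }
  }
  if (nrow(exons) == 0) stop("no gene models left after filtering")
  exons <- exons %>%
    dplyr::group_by(.data$gene_id) %>%
    dplyr::arrange(.data$start, .by_group = TRUE) %>%
    dplyr::mutate(
      exon_rank = if (.data$strand[1] == "+") dplyr::row_number()
                  else dplyr::n() - dplyr::row_number() + 1L
    ) %>%
    dplyr::ungroup()
  ov <- exons %>%
    dplyr::group_by(.data$gene_id) %>%
    dplyr::summarise(bad = any(.data$start[-1] < .data$end[-dplyr::n()]) ||
                       any(.data$start >= .data$end)) %>%
    dplyr::filter(.data$bad)
  if (nrow(ov) > 0) {
    stop("overlapping or empty exons in gene(s): ",
         paste(utils::head(ov$gene_id, 5), collapse = ", "))
  }
  genes <- exons %>%
    dplyr::group_by(.data$gene_id) %>%
    dplyr::summarise(
      contig = .data$contig[1], strand = .data$strand[1],
      start = min(.data$start), end = max(.data$end),
      n_exons = dplyr::n(), .groups = "drop"
    ) %>%
    dplyr::mutate(
      tss = ifelse(.data$strand == "+", .data$start, .data$end),
      tts = ifelse(.data$strand == "+", .data$end, .data$start)
    )
  structure(list(genes = genes, exons = dplyr::arrange(exons, .data$gene_id, .data$exon_rank)),
            class = "gene_models")
}

#' @export
print.gene_models <- function(x, ...) {
  cat("<gene_models> ", nrow(x$genes), " genes, ", nrow(x$exons), " exons\n", sep = "")
  print(utils::head(x$genes, 5))
  invisible(x)
}

# Accept either a gene_models object or a bare genes tibble.
as_genes_tbl <- function(genes) {
  if (inherits(genes, "gene_models")) genes$genes else tibble::as_tibble(genes)
}

#' Read labelled intervals from a BED file
#'
#' @param path Path to a BED3/BED6 file.
#' @param label Optional label applied to all records (otherwise the BED
#'   name column, or the file basename, is used).
#' @param genome Optional [bs_genome()]; records on unknown contigs are
#'   skipped with a warning.
#' @return Tibble with `contig`, `start`, `end` (0-based half-open), `label`.
#' @export
read_bed_intervals <- function(path, label = NULL, genome = NULL) {
  gr <- rtracklayer::import(path, format = "bed")
  out <- tibble::tibble(
    contig = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    label = if (!is.null(label)) label
            else if (!is.null(gr$name)) as.character(gr$name)
            else tools::file_path_sans_ext(basename(path))
  )
  if (!is.null(genome)) {
    bad <- !out$contig %in% names(genome$contigs)
    if (any(bad)) {
      warning(sum(bad), " interval(s) on unknown contigs skipped")
      out <- out[!bad, , drop = FALSE]
    }
  }
  out
}

#' Write an interval tibble to BED
#'
#' @param x Tibble with `contig`, `start`, `end` and optionally `label`/
#'   `name` and `score` columns (0-based half-open, written as-is per BED).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(x, path) {
  name <- if ("label" %in% names(x)) x$label else if ("name" %in% names(x)) x$name else "."
  score <- if ("score" %in% names(x)) x$score else 0
  strand <- if ("strand" %in% names(x)) x$strand else "."
  readr::write_tsv(
    tibble::tibble(x$contig, x$start, x$end, name, score, strand),
    path, col_names = FALSE
  )
  invisible(path)
}
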