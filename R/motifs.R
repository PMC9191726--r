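#' Build a position weight matrix from an IUPAC consensus
#'
#' Probability mass `match_prob` is split over the bases allowed at each
#' consensus position and the remainder over the others — a synthetic
#' idealization of a binding motif, useful where a curated matrix is not
#' shipped.
#'
#' @param consensus IUPAC string (ACGTRYSWKMBDHVN).
#' @param match_prob total probability of the allowed bases per position.
#' @return 4 x width probability matrix with rownames ACGT.
#' @export
consensus_pwm <- function(consensus, match_prob = 0.9) {
  iupac <- list(A = "A", C = "C", G = "G", T = "T",
                R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"),
                W = c("A", "T"), K = c("G", "T"), M = c("A", "C"),
                B = c("C", "G", "T"), D = c("A", "G", "T"),
                H = c("A", "C", "T"), V = c("A", "C", "G"),
                N = c("A", "C", "G", "T"))
  chars <- strsplit(toupper(consensus), "")[[1]]
  bases <- c("A", "C", "G", "T")
  pwm <- vapply(chars, function(ch) {
    allowed <- iupac[[ch]]
    if (is.null(allowed)) stop("invalid IUPAC character: ", ch)
    p <- rep((1 - match_prob) / (4 - length(allowed)), 4)
    if (length(allowed) == 4) p <- rep(0.25, 4)
    else p[match(allowed, bases)] <- match_prob / length(allowed)
    p
  }, numeric(4))
  rownames(pwm) <- bases
  pwm
}

#' Construct a scannable motif model
#'
#' Wraps a probability PWM with its background model and a log-odds score
#' threshold calibrated to a p-value under the background (the exact null
#' score distribution is computed by dynamic programming on a discretized
#' score scale, FIMO-style).
#'
#' @param name motif name.
#' @param family family label used for count aggregation (e.g. `"NFkB"`).
#' @param pwm 4 x width probability matrix (columns sum to 1).
#' @param background base frequencies (A, C, G, T).
#' @param pvalue hit-calling p-value under the background model.
#' @param granularity score discretization step (log2 units).
#' @return an object of class `pwm_motif`.
#' @export
pwm_motif <- function(name, family, pwm, background = rep(0.25, 4),
                      pvalue = 1e-4, granularity = 0.01) {
  stopifnot(nrow(pwm) == 4, all(abs(colSums(pwm) - 1) < 1e-6),
            abs(sum(background) - 1) < 1e-6)
  lo <- log2((pwm + 1e-4) / (colSums(pwm + 1e-4)[col(pwm)])) -
    log2(background)
  m_int <- round(lo / granularity)
  thr <- pwm_score_threshold(m_int, background, pvalue)
  structure(list(name = name, family = family, pwm = pwm,
                 background = background, logodds = lo,
                 int_scores = m_int, int_threshold = thr,
                 granularity = granularity, width = ncol(pwm),
                 pvalue = pvalue),
            class = "pwm_motif")
}

# exact null distribution of the integer-scaled score by convolution;
# returns the smallest integer score s with P(score >= s) <= pvalue
pwm_score_threshold <- function(m_int, background, pvalue) {
  dp <- 1       # distribution over scores: starts as point mass at 0
  offset <- 0   # score represented by dp[1]
  for (j in seq_len(ncol(m_int))) {
    new_min <- offset + min(m_int[, j])
    new_max <- offset + max(m_int[, j]) + length(dp) - 1
    nd <- numeric(new_max - new_min + 1)
    for (b in 1:4) {
      sh <- offset + m_int[b, j] - new_min
      idx <- seq_along(dp) + sh
      nd[idx] <- nd[idx] + dp * background[b]
    }
    dp <- nd
    offset <- new_min
  }
  tail_p <- rev(cumsum(rev(dp)))
  ok <- which(tail_p <= pvalue)
  # short degenerate motifs may not attain the requested p-value at all;
  # cap at the best achievable score so a perfect consensus site always hits
  if (length(ok) == 0) return(offset + length(dp) - 1)
  offset + ok[1] - 1
}

#' Built-in synthetic motif families
#'
#' Synthetic consensus-derived PWMs for the three motif families the
#' analysis compares: NF-kB (three kB-site variants), PU.1 (three
#' ETS-core variants) and the TATA box. These are idealized stand-ins
#' constructed from published consensus strings, not curated database
#' matrices.
#'
#' @param pvalue hit-calling p-value passed to [pwm_motif()].
#' @return named list of `pwm_motif` objects.
#' @export
builtin_motifs <- function(pvalue = 1e-4) {
  spec <- list(
    NFkB_p65_synthetic = list("NFkB", "GGGRNTTTCC"),
    NFkB_p50_synthetic = list("NFkB", "GGGGATYCCC"),
    NFkB_rel_synthetic = list("NFkB", "GGGAMTTYCC"),
    PU1_ets_synthetic  = list("PU1", "RCAGGAAGTG"),
    PU1_irf_synthetic  = list("PU1", "GGAAGTGAAAC"),
    PU1_core_synthetic = list("PU1", "AAAGAGGAAGTG"),
    TATA_synthetic     = list("TATA", "TATAWAWR"))
  out <- lapply(names(spec), function(nm)
    pwm_motif(nm, spec[[nm]][[1]], consensus_pwm(spec[[nm]][[2]]),
              pvalue = pvalue))
  setNames(out, names(spec))
}

# integer base codes; non-ACGTN characters error, N becomes NA
encode_dna <- function(seq) {
  chars <- strsplit(toupper(as.character(seq)), "")[[1]]
  code <- match(chars, c("A", "C", "G", "T"))
  bad <- is.na(code) & chars != "N"
  if (any(bad)) stop("non-DNA character in sequence: ", chars[which(bad)[1]])
  code
}

# hit count of one motif in one encoded sequence (one strand)
count_hits_encoded <- function(code, m_int, thr) {
  w <- ncol(m_int)
  n <- length(code)
  if (n < w) return(0L)
  idx <- seq_len(n - w + 1)
  sc <- numeric(length(idx))
  for (j in seq_len(w))
    sc <- sc + m_int[code[idx + j - 1] + (j - 1) * 4]
  sum(sc >= thr, na.rm = TRUE)  # windows containing N score NA and are skipped
}

# reverse-complement of the integer score matrix
revcomp_scores <- function(m_int) m_int[4:1, rev(seq_len(ncol(m_int))), drop = FALSE]

#' Scan sequences for motif occurrences
#'
#' Both strands are scanned (overlapping hits on opposite strands at the
#' same position both count); windows with log-odds score at or above the
#' motif's calibrated threshold are hits, and hits are summed over the
#' motifs of each family. Density is hits per 10^4 bp of sequence.
#'
#' @param sequences named character vector or `Biostrings::DNAStringSet`.
#' @param motifs list of [pwm_motif()] objects (e.g. [builtin_motifs()]).
#' @param both_strands scan the reverse complement too (default TRUE).
#' @return data.frame `region`, `family`, `count`, `length`, `density`.
#' @export
scan_motifs <- function(sequences, motifs, both_strands = TRUE) {
  if (is(sequences, "XStringSet")) sequences <- as.character(sequences)
  if (is.null(names(sequences)))
    names(sequences) <- sprintf("seq%03d", seq_along(sequences))
  fams <- unique(vapply(motifs, `[[`, character(1), "family"))
  rows <- lapply(names(sequences), function(rn) {
    code <- encode_dna(sequences[[rn]])
    counts <- setNames(integer(length(fams)), fams)
    for (m in motifs) {
      h <- count_hits_encoded(code, m$int_scores, m$int_threshold)
      if (both_strands)
        h <- h + count_hits_encoded(code, revcomp_scores(m$int_scores),
                                    m$int_threshold)
      counts[m$family] <- counts[m$family] + h
    }
    data.frame(region = rn, family = fams, count = unname(counts),
               length = length(code),
               density = unname(counts) * 1e4 / length(code))
  })
  do.call(rbind, rows)
}

#' Compare motif densities across region groups
#'
#' Per-group median density plus an undersampled group test (see
#' [compare_groups_undersampled()]).
#'
#' @param density numeric vector of per-region densities.
#' @param grouping factor of region groups (e.g. SE/TE, gained/lost).
#' @param test,seed passed to the undersampled test.
#' @return list `medians` (named), `p`, `n_per_group`.
#' @export
density_compare <- function(density, grouping, test = "anova", seed = 1) {
  gl <- split(density, grouping)
  if (length(gl) < 2) stop("need at least 2 groups")
  cmp <- compare_groups_undersampled(gl, test = test, seed = seed)
  list(medians = vapply(gl, median, numeric(1)),
       p = cmp$p, n_per_group = cmp$n_per_group)
}

#' TATA-box counts in promoter windows
#'
#' Extracts the strand-aware promoter window (default -300 bp to +50 bp
#' around the TSS in the direction of transcription, truncated at contig
#' boundaries), and counts motif-family hits in each.
#'
#' @param genome named character vector or `DNAStringSet` of contigs.
#' @param tss data.frame `gene`, `chrom`, `position` (0-based), `strand`.
#' @param motifs motif list; defaults to the TATA family of
#'   [builtin_motifs()].
#' @param upstream,downstream window extent in bp.
#' @return data.frame `gene`, `count` (summed over the family), `length`.
#' @export
promoter_tata <- function(genome, tss, motifs = NULL,
                          upstream = 300, downstream = 50) {
  if (is.null(motifs)) {
    bm <- builtin_motifs()
    motifs <- bm[vapply(bm, `[[`, character(1), "family") == "TATA"]
  }
  if (is(genome, "XStringSet")) genome <- as.character(genome)
  stopifnot(all(c("gene", "chrom", "position", "strand") %in% names(tss)))
  rows <- lapply(seq_len(nrow(tss)), function(i) {
    contig <- genome[[tss$chrom[i]]]
    len <- nchar(contig)
    pos1 <- tss$position[i] + 1                    # to 1-based
    if (tss$strand[i] == "+") {
      s <- max(1, pos1 - upstream); e <- min(len, pos1 + downstream)
      win <- substr(contig, s, e)
    } else {
      s <- max(1, pos1 - downstream); e <- min(len, pos1 + upstream)
      win <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(substr(contig, s, e))))
    }
    sc <- scan_motifs(setNames(win, tss$gene[i]), motifs)
    data.frame(gene = tss$gene[i], count = sum(sc$count), length = nchar(win))
  })
  do.call(rbind, rows)
}

#' Write motifs to a minimal MEME text file
#'
#' @param motifs list of [pwm_motif()] objects.
#' @param path output file.
#' @export
write_meme <- function(motifs, path) {
  con <- file(path, "w"); on.exit(close(con))
  writeLines(c("MEME version 4", "", "ALPHABET= ACGT", "", "strands: + -", "",
               "Background letter frequencies", "A 0.25 C 0.25 G 0.25 T 0.25", ""),
             con)
  for (m in motifs) {
    writeLines(sprintf("MOTIF %s", m$name), con)
    writeLines(sprintf("letter-probability matrix: alength= 4 w= %d nsites= 20 E= 0",
                       m$width), con)
    for (j in seq_len(m$width))
      writeLines(paste(sprintf("%.6f", m$pwm[, j]), collapse = " "), con)
    writeLines("", con)
  }
  invisible(path)
}

#' Read motifs from a minimal MEME text file
#'
#' @param path MEME file (as written by [write_meme()] or compatible).
#' @param family family assigned to all motifs read (default: name prefix
#'   before the first underscore).
#' @param pvalue hit-calling p-value for the rebuilt motifs.
#' @return named list of `pwm_motif` objects.
#' @export
read_meme <- function(path, family = NULL, pvalue = 1e-4) {
  lines <- readLines(path)
  bg <- rep(0.25, 4)
  bg_i <- grep("^Background letter frequencies", lines)
  if (length(bg_i)) {
    tok <- strsplit(trimws(lines[bg_i[1] + 1]), "\\s+")[[1]]
    bg <- as.numeric(tok[c(2, 4, 6, 8)])
  }
  idx <- grep("^MOTIF ", lines)
  out <- list()
  for (i in idx) {
    name <- strsplit(lines[i], "\\s+")[[1]][2]
    hdr <- lines[i + 1]
    w <- as.integer(sub(".*w=\\s*(\\d+).*", "\\1", hdr))
    mat <- vapply(seq_len(w), function(j)
      as.numeric(strsplit(trimws(lines[i + 1 + j]), "\\s+")[[1]]), numeric(4))
    rownames(mat) <- c("A", "C", "G", "T")
    fam <- if (is.null(family)) sub("_.*$", "", name) else family
    out[[name]] <- pwm_motif(name, fam, mat, background = bg, pvalue = pvalue)
  }
  out
}
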