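#' Threshold per-SNP local-ancestry probabilities
#'
#' A SNP on a haplotype is called introgressed when its probability of
#' carrying one copy from source population A reaches the certainty
#' threshold (0.9 in the analyses this package supports). Records carrying
#' the unknown-ancestry code 9 are neither introgressed nor
#' non-introgressed.
#'
#' @param track Data frame with columns `individual`, `haplotype`, `chrom`,
#'   `pos` (1-based bp), `prob_sourceA` (in \[0, 1\], or the literal code 9).
#' @param threshold Certainty threshold in (0, 1].
#' @return The track with an added logical column `call` (`NA` = unknown),
#'   sorted by individual, haplotype, chrom, pos.
#' @export
call_introgressed_snps <- function(track, threshold = 0.9) {
  if (threshold <= 0 || threshold > 1) stop("threshold must be in (0, 1]")
  p <- track$prob_sourceA
  bad <- which(!(p == 9 | (p >= 0 & p <= 1)))
  if (length(bad))
    stop("prob_sourceA outside [0,1] and != 9 at record ", bad[1],
         " (value ", p[bad[1]], ")")
  track <- track[order(track$individual, track$haplotype, track$chrom,
                       track$pos), , drop = FALSE]
  if (any(duplicated(track[c("individual", "haplotype", "chrom", "pos")])))
    stop("duplicated (individual, haplotype, chrom, pos) records")
  track$call <- ifelse(track$prob_sourceA == 9, NA,
                       track$prob_sourceA >= threshold)
  rownames(track) <- NULL
  track
}

#' Merge per-SNP introgression calls into blocks
#'
#' Maximal runs of consecutive introgressed SNPs on a haplotype become
#' blocks. A block starts at the position of its first SNP and ends at the
#' position of its last SNP + 1 (half-open bp convention): lengths are
#' resolution-honest, never extrapolated beyond observed SNPs. Under the
#' default `"bridge"` policy, unknown-ancestry SNPs inside a run do not
#' break it but can never start or end one; a single confidently
#' non-introgressed SNP always terminates a run. `"break"` treats unknowns
#' like non-introgressed SNPs.
#'
#' @param calls Output of [call_introgressed_snps()].
#' @param gap_policy `"bridge"` (default) or `"break"`.
#' @return Data frame of class `introgression_blocks`: `chrom`, `start`,
#'   `end` (bp, half-open, 1-based start), `individual`, `haplotype`,
#'   `n_snps`, `length`.
#' @export
merge_blocks <- function(calls, gap_policy = c("bridge", "break")) {
  gap_policy <- match.arg(gap_policy)
  out <- list()
  groups <- split(calls,
                  list(calls$individual, calls$haplotype, calls$chrom),
                  drop = TRUE)
  for (g in groups) {
    g <- g[order(g$pos), , drop = FALSE]
    call <- g$call
    if (gap_policy == "break") call[is.na(call)] <- FALSE
    keep <- !is.na(call)            # bridging: unknowns drop out of the scan
    call <- call[keep]
    pos <- g$pos[keep]
    if (!length(call) || !any(call)) next
    r <- rle(call)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (i in which(r$values)) {
      out[[length(out) + 1L]] <- data.frame(
        chrom = g$chrom[1], start = pos[starts[i]],
        end = pos[ends[i]] + 1,
        individual = g$individual[1], haplotype = g$haplotype[1],
        n_snps = ends[i] - starts[i] + 1L,
        stringsAsFactors = FALSE)
    }
  }
  blocks <- if (length(out)) do.call(rbind, out) else
    data.frame(chrom = character(), start = numeric(), end = numeric(),
               individual = character(), haplotype = integer(),
               n_snps = integer(), stringsAsFactors = FALSE)
  blocks <- blocks[order(blocks$chrom, blocks$start, blocks$individual,
                         blocks$haplotype), , drop = FALSE]
  blocks$length <- blocks$end - blocks$start
  rownames(blocks) <- NULL
  class(blocks) <- c("introgression_blocks", "data.frame")
  blocks
}

#' Cohort copy-number profile of introgressed blocks
#'
#' Sweep-line coverage: at every bp, the number of haplotypes in the cohort
#' whose blocks cover it, reported as maximal constant segments with
#' breakpoints exactly at block boundaries.
#'
#' @param blocks An `introgression_blocks` data frame (cohort-wide).
#' @param chrom_lengths Optional named vector; when given, zero-copy
#'   segments are emitted out to each chromosome end and block bounds are
#'   validated.
#' @return Data frame with `chrom`, `start`, `end` (half-open bp), and
#'   `n_copies`, sorted by chromosome and start; zero-copy gaps between
#'   blocks are included.
#' @export
copy_count_profile <- function(blocks, chrom_lengths = NULL) {
  # overlapping blocks on one haplotype violate the block invariant
  key <- split(blocks, list(blocks$individual, blocks$haplotype,
                            blocks$chrom), drop = TRUE)
  for (g in key) {
    g <- g[order(g$start), , drop = FALSE]
    if (nrow(g) > 1 && any(g$start[-1] < g$end[-nrow(g)]))
      stop("overlapping blocks on haplotype ", g$individual[1], "/",
           g$haplotype[1], " chrom ", g$chrom[1])
  }
  chroms <- if (!is.null(chrom_lengths)) names(chrom_lengths) else
    unique(blocks$chrom)
  out <- list()
  for (chrom in chroms) {
    b <- blocks[blocks$chrom == chrom, , drop = FALSE]
    clen <- if (!is.null(chrom_lengths)) chrom_lengths[[chrom]] else
      if (nrow(b)) max(b$end) - 1 else 0
    if (nrow(b) && any(b$end - 1 > clen))
      stop("block beyond end of chromosome ", chrom)
    if (nrow(b) == 0) {
      if (clen > 0)
        out[[length(out) + 1L]] <- data.frame(
          chrom = chrom, start = 1, end = clen + 1, n_copies = 0L,
          stringsAsFactors = FALSE)
      next
    }
    cov <- IRanges::coverage(
      IRanges::IRanges(start = b$start, end = b$end - 1),
      width = clen)
    seg_end <- cumsum(S4Vectors::runLength(cov))
    seg_start <- seg_end - S4Vectors::runLength(cov) + 1
    out[[length(out) + 1L]] <- data.frame(
      chrom = chrom, start = seg_start, end = seg_end + 1,
      n_copies = S4Vectors::runValue(cov), stringsAsFactors = FALSE)
  }
  profile <- do.call(rbind, out)
  if (is.null(profile))
    profile <- data.frame(chrom = character(), start = numeric(),
                          end = numeric(), n_copies = integer(),
                          stringsAsFactors = FALSE)
  rownames(profile) <- NULL
  profile
}

#' Genome fraction covered by introgressed haplotypes
#'
#' Fraction of the genome (the supplied chromosomes; pass autosomes only
#' when emulating autosome-wide admixture fractions) where at least
#' `min_copies` haplotypes carry the introgressed ancestry, plus the full
#' per-k table: the fraction is monotonically non-increasing in k.
#'
#' @param profile Output of [copy_count_profile()].
#' @param chrom_lengths Named vector of chromosome lengths in bp; the
#'   denominator is their sum.
#' @param min_copies Minimum copy number (k >= 1).
#' @return List of class `genome_summary`: `fraction` (for `min_copies`),
#'   `per_chromosome` (named vector), `per_k` (data frame `k`, `bp`,
#'   `fraction`), `min_copies`, `genome_bp`.
#' @export
genome_fraction <- function(profile, chrom_lengths, min_copies = 1L) {
  if (!all(unique(profile$chrom) %in% names(chrom_lengths)))
    stop("profile contains chromosomes absent from chrom_lengths")
  if (min_copies < 1L) stop("min_copies must be >= 1")
  bad <- profile$end - 1 > chrom_lengths[as.character(profile$chrom)]
  if (any(bad)) stop("profile segment beyond chromosome end")
  genome_bp <- sum(chrom_lengths)
  seg_bp <- profile$end - profile$start
  kmax <- max(c(profile$n_copies, min_copies))
  per_k <- data.frame(k = seq_len(kmax))
  per_k$bp <- vapply(per_k$k, function(k)
    sum(seg_bp[profile$n_copies >= k]), numeric(1))
  per_k$fraction <- per_k$bp / genome_bp
  per_chrom <- vapply(names(chrom_lengths), function(ch) {
    sel <- profile$chrom == ch & profile$n_copies >= min_copies
    sum(seg_bp[sel]) / chrom_lengths[[ch]]
  }, numeric(1))
  structure(
    list(fraction = per_k$fraction[min_copies],
         per_chromosome = per_chrom, per_k = per_k,
         min_copies = min_copies, genome_bp = genome_bp),
    class = "genome_summary")
}

#' @export
print.genome_summary <- function(x, ...) {
  cat(sprintf(
    "genome_summary: %.3f%% of %s bp at >= %d introgressed cop%s\n",
    100 * x$fraction, format(x$genome_bp, big.mark = ","), x$min_copies,
    if (x$min_copies == 1) "y" else "ies"))
  invisible(x)
}

#' Regions fixed for the introgressed ancestry
#'
#' Maximal intervals where every haplotype in the cohort (2N copies in N
#' individuals) carries the introgressed ancestry.
#'
#' @param profile Output of [copy_count_profile()].
#' @param total_haplotypes Total haplotype count, 2 x number of
#'   individuals.
#' @return Data frame `chrom`, `start`, `end` (half-open bp, 1-based
#'   start), `n_copies`; adjacent full-copy segments are merged.
#' @export
fixed_regions <- function(profile, total_haplotypes) {
  full <- profile[profile$n_copies == total_haplotypes, , drop = FALSE]
  if (nrow(full) == 0)
    return(data.frame(chrom = character(), start = numeric(),
                      end = numeric(), n_copies = integer(),
                      stringsAsFactors = FALSE))
  full <- full[order(full$chrom, full$start), , drop = FALSE]
  out <- full[1, , drop = FALSE]
  for (i in seq_len(nrow(full))[-1]) {
    last <- nrow(out)
    if (full$chrom[i] == out$chrom[last] && full$start[i] == out$end[last]) {
      out$end[last] <- full$end[i]
    } else {
      out <- rbind(out, full[i, ])
    }
  }
  rownames(out) <- NULL
  out[, c("chrom", "start", "end", "n_copies")]
}
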