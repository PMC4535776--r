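#' Simulate a star-genealogy mitochondrial cohort
#'
#' Generates a cohort of mitochondrial genomes descending independently from
#' a single founder haplotype, the generative model behind the
#' mutation-frequency clock: immediately after a colonization bottleneck the
#' genealogy is star-like, so each sampled genome carries its own private
#' Poisson number of new mutations and no internal branches are shared.
#'
#' Mutations are placed uniformly, with collision re-draw within each genome
#' (infinite-sites approximation per lineage: at realistic rates, of order
#' ten mutations over >100 kb of sequenced nucleotides, recurrent hits are
#' negligible).
#' Each mutation is emitted as a heteroplasmic double peak (IUPAC two-base
#' code of founder + derived base) with probability `heteroplasmy_prob`.
#'
#' @param founder_sequence Nucleotide string over A/C/G/T.
#' @param n_genomes Number of descendant genomes (>= 1).
#' @param mu Expected number of mutations per site per genome since
#'   founding (dimensionless).
#' @param control_region Half-open 0-based interval passed to
#'   [mito_alignment()]; mutations are still placed there but are flagged
#'   uncounted downstream. `NULL` for none.
#' @param heteroplasmy_prob Probability that a mutation is emitted as a
#'   double peak.
#' @param seed Optional integer seed; fixed seed gives byte-identical
#'   output.
#' @return List with `alignment` (a [mito_alignment()]) and `truth`, a list
#'   holding `founder_sequence`, `mutations` (data frame: `genome_id`,
#'   `position` 1-based, `derived_base`, `heteroplasmic`), `mu`, and
#'   `control_region`.
#' @export
simulate_mito_cohort <- function(founder_sequence, n_genomes, mu,
                                 control_region = NULL,
                                 heteroplasmy_prob = 0, seed = NULL) {
  founder <- strsplit(toupper(founder_sequence), "")[[1]]
  if (!all(founder %in% c("A", "C", "G", "T")))
    stop("founder_sequence must contain only A/C/G/T")
  if (n_genomes < 1L) stop("n_genomes must be >= 1")
  if (mu < 0) stop("mu must be >= 0")
  if (heteroplasmy_prob < 0 || heteroplasmy_prob > 1)
    stop("heteroplasmy_prob must be in [0, 1]")
  L <- length(founder)
  if (!is.null(seed)) set.seed(seed)
  ids <- sprintf("sim_%02d", seq_len(n_genomes))
  counts <- rpois(n_genomes, lambda = mu * L)
  if (any(counts > L))
    stop("more mutations than sites in one genome; reduce mu")
  total <- sum(counts)
  # positions unique within each genome (infinite-sites per lineage)
  positions <- unlist(lapply(counts, function(k) sample.int(L, k)))
  genome_of <- rep(seq_len(n_genomes), counts)
  bases <- c("A", "C", "G", "T")
  m <- matrix(rep(founder, each = n_genomes), nrow = n_genomes,
              dimnames = list(ids, NULL))
  derived <- character(total)
  het <- logical(total)
  if (total > 0) {
    for (k in seq_len(total)) {
      pos <- positions[k]
      derived[k] <- sample(setdiff(bases, founder[pos]), 1L)
      het[k] <- runif(1) < heteroplasmy_prob
      m[genome_of[k], pos] <- if (het[k])
        .iupac_code_for(c(founder[pos], derived[k])) else derived[k]
    }
  }
  truth <- list(
    founder_sequence = founder_sequence,
    mutations = data.frame(genome_id = ids[genome_of],
                           position = positions,
                           derived_base = derived,
                           heteroplasmic = het,
                           stringsAsFactors = FALSE),
    mu = mu,
    control_region = control_region
  )
  list(alignment = mito_alignment(m, control_region), truth = truth)
}

#' Simulate per-SNP local-ancestry probability tracks
#'
#' Emulates the output shape of haploid-mode local-ancestry inference: one
#' record per (individual, haplotype, chromosome, SNP) with the probability
#' that the haplotype carries one copy from source population A at that SNP,
#' or the literal code 9 for unknown ancestry. SNPs are placed on a regular
#' grid; inside truth blocks (for the listed haplotypes) probabilities are
#' drawn near 1, outside near 0, with Gaussian noise truncated to \[0, 1\].
#'
#' @param blocks Data frame of true introgressed blocks: columns `chrom`,
#'   `start`, `end` (bp, half-open, 1-based start), `individual`,
#'   `haplotype` (1 or 2). May have zero rows.
#' @param chrom_lengths Named numeric vector, chromosome -> length in bp.
#' @param n_individuals Number of individuals in the cohort.
#' @param snp_spacing Distance between consecutive SNPs in bp (> 0).
#' @param noise_sd Probability-scale noise standard deviation, in
#'   \[0, 0.5).
#' @param unknown_frac Fraction of records replaced by the unknown-ancestry
#'   code 9.
#' @param seed Optional integer seed.
#' @return Data frame with columns `individual`, `haplotype`, `chrom`,
#'   `pos` (1-based bp), `prob_sourceA`.
#' @export
simulate_ancestry_tracks <- function(blocks, chrom_lengths, n_individuals,
                                     snp_spacing, noise_sd = 0,
                                     unknown_frac = 0, seed = NULL) {
  if (length(chrom_lengths) == 0L) stop("chrom_lengths must be non-empty")
  if (is.null(names(chrom_lengths)))
    stop("chrom_lengths must be named by chromosome")
  if (snp_spacing <= 0) stop("snp_spacing must be > 0")
  if (noise_sd < 0 || noise_sd >= 0.5) stop("noise_sd must be in [0, 0.5)")
  if (nrow(blocks) > 0) {
    bad <- blocks$end <= blocks$start |
      blocks$end - 1 > chrom_lengths[as.character(blocks$chrom)] |
      blocks$start < 1
    if (any(is.na(bad)) || any(bad))
      stop("blocks must lie within chromosome bounds with end > start")
    if (any(!blocks$haplotype %in% c(1L, 2L)))
      stop("haplotype must be 1 or 2")
  }
  if (!is.null(seed)) set.seed(seed)
  ind_ids <- sprintf("ind_%02d", seq_len(n_individuals))
  recs <- list()
  for (chrom in names(chrom_lengths)) {
    pos <- seq(snp_spacing, chrom_lengths[[chrom]], by = snp_spacing)
    if (length(pos) == 0L) next
    for (ind in ind_ids) {
      for (hap in c(1L, 2L)) {
        inside <- rep(FALSE, length(pos))
        if (nrow(blocks) > 0) {
          b <- blocks[blocks$chrom == chrom & blocks$individual == ind &
                        blocks$haplotype == hap, , drop = FALSE]
          for (r in seq_len(nrow(b)))
            inside <- inside | (pos >= b$start[r] & pos < b$end[r])
        }
        p <- ifelse(inside, 1, 0)
        if (noise_sd > 0) p <- p + rnorm(length(p), sd = noise_sd)
        p <- pmin(pmax(p, 0), 1)
        recs[[length(recs) + 1L]] <- data.frame(
          individual = ind, haplotype = hap, chrom = chrom, pos = pos,
          prob_sourceA = p, stringsAsFactors = FALSE)
      }
    }
  }
  track <- do.call(rbind, recs)
  rownames(track) <- NULL
  if (unknown_frac > 0) {
    n9 <- round(unknown_frac * nrow(track))
    if (n9 > 0)
      track$prob_sourceA[sample.int(nrow(track), n9)] <- 9
  }
  track
}

#' Simulate microsatellite genotypes under Hardy-Weinberg equilibrium
#'
#' @param allele_freqs Named list, locus -> named numeric vector of allele
#'   frequencies (names are integer allele labels, e.g. repeat lengths);
#'   each vector must be non-negative and sum to 1.
#' @param n_individuals Number of diploid individuals.
#' @param population Population label attached to every individual.
#' @param seed Optional integer seed.
#' @return Data frame with columns `individual`, `population`, `locus`,
#'   `allele1`, `allele2` (integers).
#' @export
simulate_microsat_genotypes <- function(allele_freqs, n_individuals,
                                        population = "pop1", seed = NULL) {
  for (locus in names(allele_freqs)) {
    f <- allele_freqs[[locus]]
    if (any(f < 0)) stop("negative allele frequency at locus ", locus)
    if (abs(sum(f) - 1) > 1e-8)
      stop("allele frequencies at locus ", locus, " must sum to 1")
  }
  if (!is.null(seed)) set.seed(seed)
  ind_ids <- sprintf("ind_%03d", seq_len(n_individuals))
  out <- list()
  for (locus in names(allele_freqs)) {
    f <- allele_freqs[[locus]]
    alleles <- as.integer(names(f))
    a1 <- alleles[sample.int(length(alleles), n_individuals,
                             replace = TRUE, prob = f)]
    a2 <- alleles[sample.int(length(alleles), n_individuals,
                             replace = TRUE, prob = f)]
    out[[locus]] <- data.frame(individual = ind_ids,
                               population = population, locus = locus,
                               allele1 = a1, allele2 = a2,
                               stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Simulate 2-D landmark configurations
#'
#' Each specimen is its group's mean shape plus isotropic Gaussian landmark
#' noise, then pushed through a random nuisance similarity transform
#' (rotation, translation, scaling) that a Procrustes superimposition should
#' remove. The applied transforms are recorded as ground truth.
#'
#' @param mean_shapes Named list of k x 2 landmark matrices (one per
#'   group); all groups must share the same k (14 for the mandible data
#'   this emulates).
#' @param n_per_group Specimens per group (scalar, or vector named/ordered
#'   like `mean_shapes`).
#' @param noise_sd Isotropic landmark noise standard deviation (>= 0), in
#'   the units of the mean shapes.
#' @param rotation_range,translation_range,scale_range Nuisance ranges:
#'   rotation angle (radians) and translation drawn uniformly from
#'   `[-range, range]`, log-scale drawn uniformly so scale lies in
#'   `[1/scale_range, scale_range]` (`scale_range = 1` disables scaling).
#' @param seed Optional integer seed.
#' @return List with `coords` (n x k x 2 array), `group` (factor of length
#'   n), and `truth` (data frame of applied rotation, translation, scale per
#'   specimen).
#' @export
simulate_landmarks <- function(mean_shapes, n_per_group, noise_sd = 0,
                               rotation_range = pi, translation_range = 0,
                               scale_range = 1, seed = NULL) {
  if (is.null(names(mean_shapes))) stop("mean_shapes must be named by group")
  k <- nrow(mean_shapes[[1]])
  for (g in names(mean_shapes)) {
    ms <- mean_shapes[[g]]
    if (!is.matrix(ms) || ncol(ms) != 2L || nrow(ms) != k)
      stop("each mean shape must be a ", k, " x 2 matrix")
    if (all(abs(sweep(ms, 2, ms[1, ])) < 1e-12))
      stop("degenerate mean shape in group ", g,
           " (all landmarks coincident)")
  }
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if (scale_range < 1) stop("scale_range must be >= 1")
  if (length(n_per_group) == 1L)
    n_per_group <- setNames(rep(n_per_group, length(mean_shapes)),
                            names(mean_shapes))
  if (!is.null(seed)) set.seed(seed)
  n <- sum(n_per_group)
  coords <- array(NA_real_, dim = c(n, k, 2))
  group <- character(n)
  truth <- data.frame(specimen = character(n), group = character(n),
                      rotation = numeric(n), tx = numeric(n),
                      ty = numeric(n), scale = numeric(n),
                      stringsAsFactors = FALSE)
  i <- 0L
  for (g in names(mean_shapes)) {
    for (r in seq_len(n_per_group[[g]])) {
      i <- i + 1L
      x <- mean_shapes[[g]] +
        matrix(rnorm(2 * k, sd = noise_sd), k, 2)
      theta <- runif(1, -rotation_range, rotation_range)
      s <- exp(runif(1, -log(scale_range), log(scale_range)))
      tr <- runif(2, -translation_range, translation_range)
      R <- matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2, 2)
      coords[i, , ] <- sweep(s * (x %*% R), 2, tr, "+")
      group[i] <- g
      truth[i, ] <- list(sprintf("spec_%03d", i), g, theta, tr[1], tr[2], s)
    }
  }
  dimnames(coords) <- list(truth$specimen, NULL, c("x", "y"))
  list(coords = coords, group = factor(group, levels = names(mean_shapes)),
       truth = truth)
}
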