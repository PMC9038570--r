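#' Simulate one neutral window under the Kingman coalescent
#'
#' Standard neutral infinite-sites simulator used to build the
#' genome-wide null distribution for the windowed Tajima's D scan. For
#' j = n..2 an exponential coalescence time with rate j(j-1)/2 is drawn
#' (units of 2N generations), the genealogy is assembled, and mutations
#' are dropped as Poisson(theta/2 x total branch length), each assigned to
#' a branch with probability proportional to its length and to a distinct
#' uniform position inside the window (so E[S] = theta x a1).
#'
#' @param n number of haplotypes (>= 2).
#' @param theta scaled mutation rate 4Nmu per window (> 0).
#' @param seed optional integer seed (bit-identical output for identical
#'   seed and arguments).
#' @param window_bp window width in bp (default 10000).
#' @param chrom,offset_bp contig name and 0-based window offset; positions
#'   are 1-based in `(offset_bp, offset_bp + window_bp]`.
#' @return A [haplotype_matrix()] (possibly with zero sites).
#' @examples
#' hm <- simulate_neutral_window(10, theta = 5, seed = 1)
#' tajimas_d(hm)
#' @export
simulate_neutral_window <- function(n, theta, seed = NULL, window_bp = 10000,
                                    chrom = "chrSim", offset_bp = 0) {
  if (n < 2) stop("n must be >= 2")
  if (theta <= 0) stop("theta must be > 0")
  if (!is.null(seed)) set.seed(seed)
  tree <- sample_coalescent_branches(n)
  sites <- drop_mutations(tree, n, theta, window_bp)
  haplotype_matrix(sites$alleles, sites$positions + offset_bp, chrom = chrom)
}

## Kingman genealogy for n tips: returns a list of branches, each a tip
## set with its total length. The root branch is never created (mutations
## above the root are unobservable).
sample_coalescent_branches <- function(n) {
  tipsets <- as.list(seq_len(n))
  lens <- numeric(n)
  branches <- vector("list", 2L * n - 2L)
  blens <- numeric(2L * n - 2L)
  nb <- 0L
  while (length(tipsets) > 1L) {
    j <- length(tipsets)
    dt <- stats::rexp(1L, rate = j * (j - 1) / 2)
    lens <- lens + dt
    pair <- sample.int(j, 2L)
    for (k in pair) {
      nb <- nb + 1L
      branches[[nb]] <- tipsets[[k]]
      blens[nb] <- lens[k]
    }
    merged <- c(tipsets[[pair[1L]]], tipsets[[pair[2L]]])
    tipsets <- c(tipsets[-pair], list(merged))
    lens <- c(lens[-pair], 0)
  }
  list(tipsets = branches[seq_len(nb)], lengths = blens[seq_len(nb)])
}

## infinite-sites mutations on a genealogy; distinct integer positions
drop_mutations <- function(tree, n, theta, window_bp) {
  L <- sum(tree$lengths)
  S <- stats::rpois(1L, theta / 2 * L)
  S <- min(S, window_bp)  # infinite-sites on a finite integer grid
  if (S == 0L)
    return(list(alleles = matrix(integer(0), nrow = n, ncol = 0L),
                positions = numeric(0)))
  branch <- sample.int(length(tree$lengths), S, replace = TRUE,
                       prob = tree$lengths)
  alleles <- matrix(0L, nrow = n, ncol = S)
  for (s in seq_len(S)) alleles[tree$tipsets[[branch[s]]], s] <- 1L
  pos <- sort(sample.int(window_bp, S))  # distinct sites, ascending
  list(alleles = alleles, positions = pos)
}

#' Simulate a two-clade balanced region
#'
#' Generates the haplotype structure that carries the DMBT1
#' balancing-selection footprint: the sample is split into a "short" and a
#' "long" clade at intermediate frequency, `clade_divergence` sites are
#' planted as fixed differences between the clades, and each clade
#' receives its own neutral within-clade mutations from an independent
#' coalescent with rate `theta_within`. The deep intermediate-frequency
#' split inflates pairwise diversity relative to S/a1 and so produces a
#' strongly positive Tajima's D. The structure is generated directly
#' rather than by simulating selection dynamics, because the footprint is
#' a haplotype-structure pattern, not a trajectory.
#'
#' @param n number of haplotypes.
#' @param clade_freq fraction f of haplotypes in the "short" clade
#'   (0 < f < 1; `round(f n)` must be strictly between 0 and n).
#' @param clade_divergence number of fixed inter-clade differences d
#'   (>= 1).
#' @param theta_within within-clade scaled mutation rate (0 disables
#'   within-clade variation).
#' @param seed optional integer seed.
#' @param region_bp width of the mock region; the default 16501 bp
#'   mirrors the 16 kb region chr10:122555466-122571966.
#' @param chrom,offset_bp placement of the region (defaults mirror the
#'   GRCh38 coordinates).
#' @return List: `hapmat` (a [haplotype_matrix()]), `truth` (data.frame
#'   haplotype, clade), `fixed_positions` (positions of the planted
#'   inter-clade differences).
#' @export
simulate_balanced_region <- function(n, clade_freq = 0.5,
                                     clade_divergence = 20,
                                     theta_within = 2, seed = NULL,
                                     region_bp = 16501, chrom = "chr10",
                                     offset_bp = 122555465) {
  if (clade_freq <= 0 || clade_freq >= 1) stop("clade_freq must be in (0,1)")
  if (clade_divergence < 1) stop("clade_divergence must be >= 1")
  n_short <- round(clade_freq * n)
  if (n_short == 0L || n_short == n)
    stop("degenerate configuration: round(clade_freq * n) is 0 or n")
  if (!is.null(seed)) set.seed(seed)
  clade <- rep(c("short", "long"), c(n_short, n - n_short))

  blocks <- list()
  ## planted fixed differences: derived allele on the short clade
  fixed <- matrix(0L, nrow = n, ncol = clade_divergence)
  fixed[clade == "short", ] <- 1L
  blocks$fixed <- fixed
  ## within-clade neutral variation, one coalescent per clade
  if (theta_within > 0) {
    for (cl in c("short", "long")) {
      idx <- which(clade == cl)
      if (length(idx) >= 2L) {
        tree <- sample_coalescent_branches(length(idx))
        sites <- drop_mutations(tree, length(idx), theta_within, region_bp)
        if (ncol(sites$alleles) > 0L) {
          m <- matrix(0L, nrow = n, ncol = ncol(sites$alleles))
          m[idx, ] <- sites$alleles
          blocks[[cl]] <- m
        }
      }
    }
  }
  alleles <- do.call(cbind, blocks)
  S <- ncol(alleles)
  if (S > region_bp) stop("more sites than bp in region; lower theta_within")
  pos <- sort(sample.int(region_bp, S))
  ## random assignment of columns to positions
  colorder <- sample.int(S, S)
  alleles <- alleles[, colorder, drop = FALSE]
  fixed_cols <- which(colorder <= clade_divergence)
  hm <- haplotype_matrix(alleles, pos + offset_bp, chrom = chrom)
  list(hapmat = hm,
       truth = data.frame(haplotype = hm$haplotype_ids, clade = clade,
                          stringsAsFactors = FALSE),
       fixed_positions = pos[fixed_cols] + offset_bp)
}
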