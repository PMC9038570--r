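#' Constants of Tajima's D
#'
#' The standard normalizing constants for a sample of `n` haplotypes:
#' `a1 = sum 1/i`, `a2 = sum 1/i^2` (i = 1..n-1), `b1 = (n+1)/(3(n-1))`,
#' `b2 = 2(n^2+n+3)/(9n(n-1))`, `c1 = b1 - 1/a1`,
#' `c2 = b2 - (n+2)/(a1 n) + a2/a1^2`, `e1 = c1/a1`, `e2 = c2/(a1^2+a2)`.
#'
#' @param n number of haplotypes (>= 2).
#' @return Named list with a1, a2, b1, b2, c1, c2, e1, e2.
#' @export
tajima_constants <- function(n) {
  if (n < 2) stop("n must be >= 2")
  i <- seq_len(n - 1)
  a1 <- sum(1 / i)
  a2 <- sum(1 / i^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  list(a1 = a1, a2 = a2, b1 = b1, b2 = b2, c1 = c1, c2 = c2,
       e1 = c1 / a1, e2 = c2 / (a1^2 + a2))
}

window_stat <- function(chrom, start, end, n_hap, S, pi, theta_w, D,
                        excluded = FALSE, reason = NA_character_) {
  structure(list(chrom = chrom, start = start, end = end, n_hap = n_hap,
                 S = S, pi = pi, theta_w = theta_w, D = D,
                 excluded = excluded, reason = reason),
            class = "window_stat")
}

#' @export
print.window_stat <- function(x, ...) {
  cat(sprintf("window_stat %s:%s-%s  n=%d  S=%d  pi=%.4f  thetaW=%.4f  D=%s%s\n",
              x$chrom, format(x$start, scientific = FALSE),
              format(x$end, scientific = FALSE), x$n_hap, x$S, x$pi,
              x$theta_w, ifelse(is.na(x$D), "undefined", sprintf("%.4f", x$D)),
              if (isTRUE(x$excluded)) paste0("  [excluded: ", x$reason, "]")
              else ""))
  invisible(x)
}

#' Tajima's D for a haplotype matrix
#'
#' Computes the segregating-site count S, mean pairwise diversity
#' `pi = sum_sites 2 j (n-j) / (n(n-1))` (j = derived-allele count),
#' Watterson's `theta_w = S/a1`, and
#' `D = (pi - S/a1) / sqrt(e1 S + e2 S (S-1))`. Monomorphic sites are
#' ignored. D is undefined (NA, with the `excluded` flag set) when S = 0.
#'
#' @param hapmat a [haplotype_matrix()] (H >= 2; H >= 4 recommended).
#' @param start,end optional window bounds recorded in the result
#'   (0-based half-open); default to the span of the data.
#' @return A `window_stat`: list with chrom, start, end, n_hap, S, pi,
#'   theta_w, D, excluded, reason.
#' @examples
#' ladder <- haplotype_matrix(rbind(c(0,0,0), c(1,0,0), c(1,1,0), c(1,1,1)),
#'                            c(10, 20, 30))
#' tajimas_d(ladder)
#' @export
tajimas_d <- function(hapmat, start = NULL, end = NULL) {
  n <- n_haplotypes(hapmat)
  if (n < 2) stop("need at least 2 haplotypes")
  seg <- segregating_columns(hapmat)
  S <- length(seg)
  if (is.null(start))
    start <- if (length(hapmat$positions)) min(hapmat$positions) - 1 else 0
  if (is.null(end))
    end <- if (length(hapmat$positions)) max(hapmat$positions) else 0
  if (S == 0L)
    return(window_stat(hapmat$chrom, start, end, n, 0L, 0, 0, NA_real_,
                       excluded = TRUE, reason = "no segregating sites"))
  j <- colSums(hapmat$alleles[, seg, drop = FALSE])
  pi <- sum(2 * j * (n - j) / (n * (n - 1)))
  k <- tajima_constants(n)
  theta_w <- S / k$a1
  D <- (pi - theta_w) / sqrt(k$e1 * S + k$e2 * S * (S - 1))
  window_stat(hapmat$chrom, start, end, n, S, pi, theta_w, D)
}

#' Windowed scan of Tajima's D
#'
#' Tiles the contig into non-overlapping windows of `window_bp` using
#' 0-based half-open bounds `[k w, (k+1) w)`; a 1-based VCF position p
#' falls in window `floor((p-1)/w)`. One row is returned per window that
#' contains at least one site; empty windows are omitted but counted in
#' attribute `n_empty_windows` (windows between the first and last
#' occupied window).
#'
#' @param hapmat a [haplotype_matrix()].
#' @param window_bp window size in bp (default 10000, the scan scale used
#'   for the genome-wide null distribution).
#' @return A data.frame with columns chrom, start, end, n_hap, S, pi,
#'   theta_w, D, excluded, reason.
#' @export
window_scan <- function(hapmat, window_bp = 10000) {
  if (window_bp <= 0) stop("window_bp must be positive")
  if (n_sites(hapmat) == 0L)
    return(structure(data.frame(chrom = character(), start = numeric(),
                                end = numeric(), n_hap = integer(),
                                S = integer(), pi = numeric(),
                                theta_w = numeric(), D = numeric(),
                                excluded = logical(), reason = character(),
                                stringsAsFactors = FALSE),
                     n_empty_windows = 0L))
  win <- floor((hapmat$positions - 1) / window_bp)
  occupied <- sort(unique(win))
  rows <- lapply(occupied, function(w) {
    keep <- which(win == w)
    sub <- haplotype_matrix(hapmat$alleles[, keep, drop = FALSE],
                            hapmat$positions[keep], chrom = hapmat$chrom,
                            haplotype_ids = hapmat$haplotype_ids)
    ws <- tajimas_d(sub, start = w * window_bp, end = (w + 1) * window_bp)
    data.frame(chrom = ws$chrom, start = ws$start, end = ws$end,
               n_hap = ws$n_hap, S = ws$S, pi = ws$pi, theta_w = ws$theta_w,
               D = ws$D, excluded = ws$excluded, reason = ws$reason,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "n_empty_windows") <-
    as.integer(diff(range(occupied)) + 1L - length(occupied))
  out
}

#' Z-normalize a focal window against the genome-wide distribution
#'
#' The focal window's D is reported as a z score relative to the mean and
#' sample standard deviation (n-1 denominator) of the genome-wide D
#' distribution, restricted to windows with defined D and at least
#' `min_variable_sites` segregating sites. A focal window with fewer than
#' `min_variable_sites` variable sites is excluded (flag + reason), the
#' rule applied population by population in the original analysis.
#'
#' @param target a `window_stat` (or one-row data.frame with S and D).
#' @param genome data.frame of windows as returned by [window_scan()]
#'   (needs columns S and D).
#' @param min_variable_sites exclusion threshold (default 3).
#' @return List with class `zscan`: target, genome_mean, genome_sd, z,
#'   n_windows_used, excluded, reason.
#' @export
znormalize <- function(target, genome, min_variable_sites = 3) {
  if (inherits(genome, "window_stat")) genome <- list(genome)
  if (is.data.frame(genome)) {
    S <- genome$S; D <- genome$D
  } else {
    S <- vapply(genome, `[[`, numeric(1), "S")
    D <- vapply(genome, `[[`, numeric(1), "D")
  }
  use <- !is.na(D) & S >= min_variable_sites
  if (sum(use) < 2)
    stop("need at least 2 genome windows with defined D and S >= ",
         min_variable_sites)
  m <- mean(D[use])
  s <- stats::sd(D[use])
  if (s == 0) stop("degenerate genome-wide distribution (sd = 0)")
  tS <- if (is.data.frame(target)) target$S else target$S
  tD <- if (is.data.frame(target)) target$D else target$D
  excluded <- FALSE; reason <- NA_character_; z <- NA_real_
  if (is.na(tD) || tS < min_variable_sites) {
    excluded <- TRUE
    reason <- sprintf("fewer than %d variable sites", min_variable_sites)
  } else {
    z <- (tD - m) / s
  }
  structure(list(target = target, genome_mean = m, genome_sd = s, z = z,
                 n_windows_used = sum(use), excluded = excluded,
                 reason = reason),
            class = "zscan")
}

#' @export
print.zscan <- function(x, ...) {
  if (x$excluded)
    cat(sprintf("zscan: excluded (%s); null over %d windows (mean %.3f, sd %.3f)\n",
                x$reason, x$n_windows_used, x$genome_mean, x$genome_sd))
  else
    cat(sprintf("zscan: z = %.3f against %d windows (mean %.3f, sd %.3f)\n",
                x$z, x$n_windows_used, x$genome_mean, x$genome_sd))
  invisible(x)
}

#' Coordinates of the DMBT1 balancing-selection region
#'
#' The 16 kb region of elevated Tajima's D at the 5' end of DMBT1
#' (GRCh38), and the 10 kb scan window inside it that is z-normalized
#' against the genome-wide distribution.
#'
#' @return List with `chrom`, `start`, `end` (1-based inclusive, 16 kb
#'   region) and `focal_start`, `focal_end` (the 10 kb window).
#' @export
dmbt1_region <- function() {
  list(chrom = "chr10", start = 122555466, end = 122571966,
       focal_start = 122560000, focal_end = 122570000)
}

#' Scan the DMBT1 region of a phased VCF (external-data check)
#'
#' Convenience wrapper reproducing the headline analysis on real phased
#' genotypes: reads the 16 kb DMBT1 region from a VCF, computes Tajima's D
#' over the full region and over the focal 10 kb window, and, when a
#' genome-wide window table is supplied, the z-normalized focal score.
#' This requires externally obtained population genotypes (e.g. HGDP) and
#' is not exercised by the hermetic test-suite.
#'
#' @param vcf_path phased VCF covering the region.
#' @param samples optional sample subset (one population).
#' @param genome_windows optional data.frame from [window_scan()] run
#'   genome-wide for the same population.
#' @param region,focal region overrides; default [dmbt1_region()].
#' @return List with `region_stat`, `focal_stat`, and `focal_z` (NULL
#'   without `genome_windows`).
#' @export
scan_dmbt1_region <- function(vcf_path, samples = NULL, genome_windows = NULL,
                              region = dmbt1_region(), focal = region) {
  if (!file.exists(vcf_path))
    stop("VCF not found: ", vcf_path,
         " (this check needs externally downloaded population genotypes)")
  hm <- read_phased_vcf(vcf_path,
                        region = sprintf("%s:%d-%d", region$chrom,
                                         region$start, region$end),
                        samples = samples)
  region_stat <- tajimas_d(hm)
  focal_hm <- subset_region(hm, focal$focal_start + 1, focal$focal_end)
  focal_stat <- if (n_sites(focal_hm) > 0) {
    tajimas_d(focal_hm, start = focal$focal_start, end = focal$focal_end)
  } else {
    window_stat(hm$chrom, focal$focal_start, focal$focal_end,
                n_haplotypes(hm), 0L, 0, 0, NA_real_, TRUE,
                "no segregating sites")
  }
  focal_z <- if (!is.null(genome_windows))
    znormalize(focal_stat, genome_windows) else NULL
  list(region_stat = region_stat, focal_stat = focal_stat, focal_z = focal_z)
}
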