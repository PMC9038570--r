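#' Partition haplotypes into two divergent clades
#'
#' Agglomerative complete-linkage clustering on pairwise Hamming distance,
#' cut into exactly two groups. This formalizes the visual haplotype-clade
#' inspection used for the DMBT1 region: a deeply split sample yields two
#' clades whose between-clade divergence greatly exceeds the within-clade
#' divergence. Clade labels are normalized so that `clade0` is the clade
#' containing the lowest-index haplotype.
#'
#' @param hapmat a [haplotype_matrix()] of the focal region (H >= 4
#'   recommended, >= 1 segregating site required).
#' @return An object of class `clade_partition`: `assignment` (named
#'   factor `clade0`/`clade1`), `between_divergence` and
#'   `within_divergence` (mean pairwise Hamming differences),
#'   `concordant_sites` (positions of sites that perfectly separate the
#'   clades), and `tag_snp` (see [select_tag_snp()]).
#' @export
partition_clades <- function(hapmat) {
  H <- n_haplotypes(hapmat)
  if (H < 4) stop("need at least 4 haplotypes to partition")
  if (length(segregating_columns(hapmat)) < 1L)
    stop("no segregating sites: haplotypes carry no structure to partition")
  d <- stats::dist(hapmat$alleles, method = "manhattan")  # Hamming on 0/1
  if (all(d == 0))
    stop("all haplotypes identical: no structure to partition")
  hc <- stats::hclust(d, method = "complete")
  cl <- stats::cutree(hc, k = 2)
  ## normalize labels: clade0 holds haplotype 1
  if (cl[1L] != 1L) cl <- 3L - cl
  assignment <- factor(ifelse(cl == 1L, "clade0", "clade1"),
                       levels = c("clade0", "clade1"))
  names(assignment) <- hapmat$haplotype_ids
  dm <- as.matrix(d)
  same <- outer(cl, cl, "==")
  diag(same) <- NA
  within <- mean(dm[which(same & upper.tri(dm))])
  between <- mean(dm[which(!same & upper.tri(dm))])
  ## sites with zero within-clade allele sharing across clades: the site's
  ## allele split coincides exactly with the clade bipartition
  seg <- segregating_columns(hapmat)
  conc <- seg[vapply(seg, function(s) {
    a <- hapmat$alleles[, s]
    all(a[cl == 1L] == a[cl == 1L][1L]) && all(a[cl == 2L] == a[cl == 2L][1L]) &&
      a[cl == 1L][1L] != a[cl == 2L][1L]
  }, logical(1L))]
  out <- structure(
    list(assignment = assignment, between_divergence = between,
         within_divergence = if (is.nan(within)) 0 else within,
         concordant_sites = hapmat$positions[conc], tag_snp = NULL),
    class = "clade_partition")
  out$tag_snp <- select_tag_snp(out, hapmat)
  out
}

#' @export
print.clade_partition <- function(x, ...) {
  n <- table(x$assignment)
  cat(sprintf(paste0("clade_partition: %d | %d haplotypes; between = %.2f, ",
                     "within = %.2f; %d concordant site(s)\n"),
              n[1L], n[2L], x$between_divergence, x$within_divergence,
              length(x$concordant_sites)))
  if (!is.null(x$tag_snp))
    cat(sprintf("  tag SNP at %s (concordance %.3f)\n",
                format(x$tag_snp$position, scientific = FALSE),
                x$tag_snp$concordance))
  invisible(x)
}

#' Choose a tag SNP for a clade partition
#'
#' Scores every segregating site by concordance: the fraction of
#' haplotypes whose allele equals the majority allele of their own clade
#' at that site. The site with maximal concordance is returned; ties are
#' broken by leftmost position. A perfectly concordant site (concordance
#' 1.0) distinguishes the two clades exactly, the role rs11523871 plays
#' for the DMBT1 clades.
#'
#' @param partition a `clade_partition`.
#' @param hapmat the same region [haplotype_matrix()].
#' @return List: `position`, `site_index`, `concordance`, `allele_map`
#'   (majority allele per clade, names `clade0`/`clade1`), `reliable`
#'   (FALSE, with a warning, when no site exceeds concordance 0.5).
#' @export
select_tag_snp <- function(partition, hapmat) {
  cl <- as.integer(partition$assignment)
  seg <- segregating_columns(hapmat)
  if (!length(seg)) stop("no segregating sites to choose a tag SNP from")
  score_site <- function(s) {
    a <- hapmat$alleles[, s]
    maj <- vapply(1:2, function(k) {
      m <- mean(a[cl == k])
      if (m >= 0.5) 1L else 0L  # ties resolved to the derived allele
    }, integer(1L))
    list(conc = mean(a == maj[cl]), maj = maj)
  }
  scores <- lapply(seg, score_site)
  conc <- vapply(scores, `[[`, numeric(1L), "conc")
  best <- which.max(conc)  # ties: first = leftmost (positions are sorted)
  reliable <- conc[best] > 0.5
  if (!reliable)
    warning("no site with concordance > 0.5; tag SNP is unreliable")
  maj <- scores[[best]]$maj
  list(position = hapmat$positions[seg[best]], site_index = seg[best],
       concordance = conc[best],
       allele_map = c(clade0 = maj[1L], clade1 = maj[2L]),
       reliable = reliable)
}
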