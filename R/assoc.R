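#' Wilcoxon rank-sum test between clade allele distributions
#'
#' Tests whether repeat alleles on tag-SNP A haplotypes and C haplotypes
#' come from the same distribution. Mid-ranks are used for ties; the
#' normal approximation uses the tie-corrected variance and a 0.5
#' continuity correction, matching the analysis scale (~263 haplotypes).
#' An exact permutation mode (complete enumeration of group labelings) is
#' available for pooled n <= 20.
#'
#' @param group_a,group_c numeric repeat alleles on the two haplotype
#'   groups (both non-empty).
#' @param mode "normal" (default) or "exact".
#' @return List of class `rank_test`: W (rank-sum statistic of
#'   `group_a`, Mann-Whitney form), z (with continuity correction;
#'   NA in exact mode), p (two-sided), n_a, n_c, mode.
#' @export
rank_sum_test <- function(group_a, group_c, mode = c("normal", "exact")) {
  mode <- match.arg(mode)
  if (!length(group_a) || !length(group_c))
    stop("both groups must be non-empty")
  n1 <- length(group_a); n2 <- length(group_c); N <- n1 + n2
  r <- rank(c(group_a, group_c))
  W <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2  # Mann-Whitney U of group_a
  if (mode == "exact") {
    if (N > 20L) stop("exact mode is limited to pooled n <= 20")
    combos <- utils::combn(N, n1)
    mu <- n1 * n2 / 2
    stat <- apply(combos, 2L, function(ix) sum(r[ix]) - n1 * (n1 + 1) / 2)
    p <- mean(abs(stat - mu) >= abs(W - mu) - 1e-12)
    out <- list(W = W, z = NA_real_, p = p, n_a = n1, n_c = n2,
                mode = "exact")
    class(out) <- "rank_test"
    return(out)
  }
  mu <- n1 * n2 / 2
  ties <- table(r)
  sigma2 <- n1 * n2 / 12 * ((N + 1) - sum(ties^3 - ties) / (N * (N - 1)))
  if (sigma2 <= 0) {
    z <- 0; p <- 1
  } else {
    cc <- 0.5 * sign(W - mu)
    z <- (W - mu - cc) / sqrt(sigma2)
    if (W == mu) z <- 0
    p <- min(1, 2 * stats::pnorm(-abs(z)))
  }
  structure(list(W = W, z = z, p = p, n_a = n1, n_c = n2, mode = "normal"),
            class = "rank_test")
}

#' @export
print.rank_test <- function(x, ...) {
  cat(sprintf("rank_test (%s): W = %.1f, z = %s, p = %.4g (n = %d + %d)\n",
              x$mode, x$W,
              ifelse(is.na(x$z), "-", sprintf("%.3f", x$z)), x$p,
              x$n_a, x$n_c))
  invisible(x)
}

#' Rank-sum test from phased haplotype records
#'
#' Convenience wrapper over [rank_sum_test()] splitting a record table
#' (as produced by [attach_to_haplotypes()] or the simulation truth) by
#' tag allele.
#'
#' @param records data.frame with columns tag_allele (A/C) and
#'   repeat_allele.
#' @param ... passed to [rank_sum_test()].
#' @return A `rank_test` (group A first).
#' @export
clade_association_test <- function(records, ...) {
  rank_sum_test(records$repeat_allele[records$tag_allele == "A"],
                records$repeat_allele[records$tag_allele == "C"], ...)
}

parse_bands <- function(bands) {
  lapply(strsplit(as.character(bands), "[,/]"), as.numeric)
}

encode_isoform_response <- function(records,
                                    response = c("mean_band", "largest_band",
                                                 "smallest_band",
                                                 "class_rank")) {
  response <- match.arg(response)
  b <- parse_bands(records$bands)
  switch(response,
         mean_band = vapply(b, mean, numeric(1L)),
         largest_band = vapply(b, max, numeric(1L)),
         smallest_band = vapply(b, min, numeric(1L)),
         class_rank = {
           ## classes ordered by size: IV (287/345) < I (345) < II < III
           rank_map <- c(IV = 1, I = 2, II = 3, III = 4)
           unname(rank_map[as.character(records$isoform)])
         })
}

#' Linear model of isoform size on SRCR diploid copy number
#'
#' Ordinary least squares of protein size on diploid SRCR copy number,
#' optionally with a secretor-status indicator, plus Kendall's rank
#' correlation of size with copy number. Western-blot band sizes are an
#' ambiguous response for two-band (heterozygous-pattern) samples, so the
#' encoding is configurable: `"mean_band"` (mean of the listed bands, the
#' default), `"largest_band"` (the full-length glycoform),
#' `"smallest_band"`, or `"class_rank"` (size-ordered class IV < I < II
#' < III).
#'
#' @param records data.frame with columns srcr_diploid_cn, bands
#'   (comma-separated kDa values), isoform, and (for the secretor term)
#'   secretor coded "+" / "-".
#' @param include_secretor add the Se indicator to the design.
#' @param response band encoding (see above).
#' @return List of class `isoform_fit`: fit (the `lm`), r_squared,
#'   overall_p (F test), coef_p (named per-coefficient t tests),
#'   kendall_tau, kendall_p, response, include_secretor, n.
#' @export
isoform_model <- function(records, include_secretor = FALSE,
                          response = "mean_band") {
  if (nrow(records) < 3L) stop("need at least 3 records")
  y <- encode_isoform_response(records, response)
  cn <- records$srcr_diploid_cn
  if (length(unique(cn)) < 2L)
    stop("degenerate design: copy number is constant")
  df <- data.frame(y = y, cn = cn)
  if (include_secretor) {
    df$se <- as.integer(records$secretor == "+")
    if (length(unique(df$se)) < 2L)
      stop("degenerate design: secretor status is constant")
    fit <- stats::lm(y ~ cn + se, data = df)
  } else {
    fit <- stats::lm(y ~ cn, data = df)
  }
  sm <- summary(fit)
  fstat <- sm$fstatistic
  overall_p <- stats::pf(fstat[1L], fstat[2L], fstat[3L], lower.tail = FALSE)
  kt <- suppressWarnings(stats::cor.test(y, cn, method = "kendall"))
  structure(list(fit = fit, r_squared = sm$r.squared,
                 overall_p = unname(overall_p),
                 coef_p = sm$coefficients[, "Pr(>|t|)"],
                 kendall_tau = unname(kt$estimate),
                 kendall_p = kt$p.value,
                 response = response, include_secretor = include_secretor,
                 n = nrow(records)),
            class = "isoform_fit")
}

#' @export
print.isoform_fit <- function(x, ...) {
  cat(sprintf(paste0("isoform_fit (%s%s, n = %d): r^2 = %.3f, ",
                     "overall p = %.4g; Kendall tau = %.3f (p = %.4g)\n"),
              x$response,
              if (x$include_secretor) " + secretor" else "", x$n,
              x$r_squared, x$overall_p, x$kendall_tau, x$kendall_p))
  if (x$include_secretor)
    cat(sprintf("  secretor coefficient p = %.4g\n", x$coef_p[["se"]]))
  invisible(x)
}

#' Infer secretor status from a FUT2 genotype
#'
#' Secretor-negative (Se-) individuals are homozygous for the FUT2 null
#' allele; any other called genotype is Se+. The null allele is
#' configurable (default "A", the common European nonsense allele at the
#' G428A polymorphism).
#'
#' @param genotypes character vector like "G/A" or "A|A" (any of "/" or
#'   "|" as separator); NA yields "unknown".
#' @param null_allele the null (non-functional) allele.
#' @return Character vector in c("Se+", "Se-", "unknown").
#' @examples
#' infer_secretor(c("A/A", "G/A", "G/G", NA))
#' @export
infer_secretor <- function(genotypes, null_allele = "A") {
  vapply(genotypes, function(g) {
    if (is.na(g) || !nzchar(g)) return("unknown")
    al <- strsplit(g, "[/|]")[[1L]]
    if (length(al) != 2L || any(!nzchar(al))) return("unknown")
    if (all(al == null_allele)) "Se-" else "Se+"
  }, character(1L), USE.NAMES = FALSE)
}

#' Expression-genotype dosage trend test
#'
#' One-way ANOVA of normalized expression across rs-genotype classes,
#' plus an ordinary least-squares fit of expression on allele dosage with
#' a two-tailed F test for the linear term -- the analysis applied to the
#' duodenal ddPCR panel.
#'
#' @param records data.frame with columns dosage (0/1/2 copies of the
#'   focal allele) and expression (target/reference concentration ratio,
#'   >= 0).
#' @return List of class `dosage_trend`: anova_p, trend_p, slope,
#'   slope_sign, n, n_classes.
#' @export
dosage_trend_test <- function(records) {
  d <- records$dosage; e <- records$expression
  if (length(unique(d)) < 2L)
    stop("trend undefined: only one genotype class present")
  anova_tab <- summary(stats::aov(e ~ factor(d)))[[1L]]
  anova_p <- anova_tab[["Pr(>F)"]][1L]
  fit <- stats::lm(e ~ d)
  at <- stats::anova(fit)
  trend_p <- at[["Pr(>F)"]][1L]
  slope <- unname(stats::coef(fit)[["d"]])
  structure(list(anova_p = anova_p, trend_p = trend_p, slope = slope,
                 slope_sign = sign(slope), n = length(e),
                 n_classes = length(unique(d))),
            class = "dosage_trend")
}

#' @export
print.dosage_trend <- function(x, ...) {
  cat(sprintf(paste0("dosage_trend (n = %d, %d classes): ANOVA p = %.4g; ",
                     "linear trend p = %.4g (slope %s)\n"),
              x$n, x$n_classes, x$anova_p, x$trend_p,
              ifelse(x$slope_sign >= 0, "positive", "negative")))
  invisible(x)
}

#' Eight-sample salivary isoform panel
#'
#' The published panel of eight saliva donors with western-blot isoform
#' classes (I-IV), approximate band sizes, PRT-measured CNV1/CNV2 diploid
#' copy numbers, SRCR repeat diploid copy number, and FUT2-inferred
#' secretor status (2 Se-, 6 Se+). The `fut2_genotype` column is
#' reconstructed (synthetic) from the inferred status: Se- rows are
#' homozygous null, Se+ rows heterozygous.
#'
#' @return data.frame with columns sample, cnv1_diploid, cnv2_diploid,
#'   srcr_diploid_cn, secretor, fut2_genotype, isoform, bands,
#'   smutans_binding.
#' @export
dmbt1_isoform_panel <- function() {
  path <- system.file("extdata", "isoform_panel.tsv", package = "dmbtsel")
  utils::read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE,
                    colClasses = c(sample = "character", bands = "character"))
}
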