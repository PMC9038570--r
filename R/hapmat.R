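#' Phased haplotype matrix
#'
#' Container for phased biallelic sites: an H x L matrix of 0/1 alleles
#' (rows are haplotypes, columns are sites) together with 1-based genomic
#' positions (VCF convention). This is the substrate for all the
#' population-genetic statistics in the package.
#'
#' @param alleles integer/numeric matrix of 0/1 with haplotypes in rows.
#' @param positions numeric vector of strictly increasing 1-based site
#'   positions, one per column of `alleles`.
#' @param chrom single contig name.
#' @param haplotype_ids optional character vector of row names
#'   (`sample_hapIndex`); defaults to `hap1 ... hapH`.
#' @return An object of class `haplotype_matrix`: a list with elements
#'   `chrom`, `positions`, `alleles`, `haplotype_ids`.
#' @examples
#' hm <- haplotype_matrix(rbind(c(0, 0), c(1, 0), c(1, 1)), c(101, 205))
#' hm
#' @export
haplotype_matrix <- function(alleles, positions, chrom = "chrSim",
                             haplotype_ids = NULL) {
  alleles <- as.matrix(alleles)
  if (nrow(alleles) < 2L)
    stop("a haplotype matrix needs at least 2 haplotypes (H >= 2)")
  if (ncol(alleles) != length(positions))
    stop("length(positions) must equal ncol(alleles)")
  if (length(positions) && any(diff(positions) <= 0))
    stop("positions must be strictly increasing")
  if (length(alleles) && !all(alleles %in% c(0, 1)))
    stop("alleles must be coded 0/1")
  storage.mode(alleles) <- "integer"
  if (is.null(haplotype_ids))
    haplotype_ids <- paste0("hap", seq_len(nrow(alleles)))
  rownames(alleles) <- haplotype_ids
  structure(
    list(chrom = as.character(chrom)[1L], positions = as.numeric(positions),
         alleles = alleles, haplotype_ids = haplotype_ids),
    class = "haplotype_matrix")
}

#' @export
print.haplotype_matrix <- function(x, ...) {
  cat(sprintf("haplotype_matrix: %d haplotypes x %d sites on %s",
              nrow(x$alleles), ncol(x$alleles), x$chrom))
  if (length(x$positions))
    cat(sprintf(" (%s-%s)", format(min(x$positions), scientific = FALSE),
                format(max(x$positions), scientific = FALSE)))
  cat("\n")
  invisible(x)
}

#' Number of haplotypes and sites
#' @param x a `haplotype_matrix`.
#' @return Integer count.
#' @rdname haplotype_matrix_dims
#' @export
n_haplotypes <- function(x) nrow(x$alleles)

#' @rdname haplotype_matrix_dims
#' @export
n_sites <- function(x) ncol(x$alleles)

## columns that segregate (both alleles seen); monomorphic columns are kept
## in the object but ignored by the statistics
segregating_columns <- function(x) {
  if (ncol(x$alleles) == 0L) return(integer(0))
  j <- colSums(x$alleles)
  which(j > 0L & j < nrow(x$alleles))
}

#' Subset a haplotype matrix to a genomic interval
#'
#' @param x a `haplotype_matrix`.
#' @param start,end 1-based inclusive bounds.
#' @return A `haplotype_matrix` restricted to sites with
#'   `start <= pos <= end`.
#' @export
subset_region <- function(x, start, end) {
  keep <- which(x$positions >= start & x$positions <= end)
  haplotype_matrix(x$alleles[, keep, drop = FALSE], x$positions[keep],
                   chrom = x$chrom, haplotype_ids = x$haplotype_ids)
}

parse_region <- function(region) {
  m <- regmatches(region, regexec("^([^:]+):([0-9]+)-([0-9]+)$", region))[[1L]]
  if (length(m) != 4L)
    stop("region must be 'chrom:start-end' (1-based inclusive), got: ", region)
  list(chrom = m[2L], start = as.numeric(m[3L]), end = as.numeric(m[4L]))
}

#' Read phased haplotypes from a VCF file
#'
#' Loads phased, biallelic SNP genotypes into a [haplotype_matrix()].
#' Multiallelic, non-SNP, and unphased or missing records are skipped; the
#' number skipped is attached as attribute `n_skipped` and reported via a
#' message. Each sample contributes two haplotypes in stable order
#' (`sample_1`, `sample_2` = left and right of the `|` separator).
#'
#' @param path VCF file (plain or bgzipped).
#' @param region optional `"chrom:start-end"` filter (1-based inclusive).
#' @param samples optional character vector of sample names to keep; an
#'   error lists any absentees.
#' @return A `haplotype_matrix` with attribute `n_skipped`.
#' @export
read_phased_vcf <- function(path, region = NULL, samples = NULL) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1L,
                                       dimnames = list(NULL, names(fix)))
  chrom <- fix[, "CHROM"]
  pos <- as.numeric(fix[, "POS"])
  ref <- fix[, "REF"]
  alt <- fix[, "ALT"]

  keep <- rep(TRUE, length(pos))
  if (!is.null(region)) {
    r <- parse_region(region)
    keep <- keep & chrom == r$chrom & pos >= r$start & pos <= r$end
  }
  biallelic_snp <- nchar(ref) == 1L & nchar(alt) == 1L & !grepl(",", alt) &
    ref %in% c("A", "C", "G", "T") & alt %in% c("A", "C", "G", "T")
  n_skipped <- sum(keep & !biallelic_snp)
  keep <- keep & biallelic_snp

  gt <- vcfR::extract.gt(vcf, element = "GT")
  if (is.null(dim(gt))) gt <- matrix(gt, nrow = length(pos),
                                     dimnames = list(NULL, colnames(vcf@gt)[-1L]))
  if (!is.null(samples)) {
    missing_samples <- setdiff(samples, colnames(gt))
    if (length(missing_samples))
      stop("samples absent from VCF: ", paste(missing_samples, collapse = ", "))
    gt <- gt[, samples, drop = FALSE]
  }

  phased <- rep(FALSE, length(pos))
  idx <- which(keep)
  if (length(idx)) {
    g <- gt[idx, , drop = FALSE]
    ok <- matrix(grepl("^[01]\\|[01]$", g), nrow = nrow(g))
    phased[idx] <- apply(ok, 1L, all)
  }
  n_skipped <- n_skipped + sum(keep & !phased)
  keep <- keep & phased
  if (!any(keep))
    stop("no phased biallelic SNPs in the requested region of ", path)

  ord <- order(pos[keep])
  idx <- which(keep)[ord]
  g <- gt[idx, , drop = FALSE]
  sample_names <- colnames(g)
  h1 <- matrix(as.integer(substr(g, 1L, 1L)), nrow = nrow(g))
  h2 <- matrix(as.integer(substr(g, 3L, 3L)), nrow = nrow(g))
  alleles <- matrix(0L, nrow = 2L * length(sample_names), ncol = nrow(g))
  ids <- character(2L * length(sample_names))
  for (s in seq_along(sample_names)) {
    alleles[2L * s - 1L, ] <- h1[, s]
    alleles[2L * s, ] <- h2[, s]
    ids[2L * s - 1L] <- paste0(sample_names[s], "_1")
    ids[2L * s] <- paste0(sample_names[s], "_2")
  }
  if (n_skipped > 0L)
    message(n_skipped, " non-biallelic/non-SNP/unphased record(s) skipped")
  out <- haplotype_matrix(alleles, pos[idx], chrom = chrom[idx][1L],
                          haplotype_ids = ids)
  attr(out, "n_skipped") <- n_skipped
  out
}

#' Write a haplotype matrix as a phased VCF
#'
#' Haplotypes are paired in row order (rows 1,2 form sample 1, ...); H must
#' be even. Sites are written as biallelic SNPs (`REF=A`, `ALT=G`) with
#' phased `GT` (`h1|h2`).
#'
#' @param x a `haplotype_matrix` with an even number of rows.
#' @param path output file.
#' @param sample_names optional; defaults to the shared prefix of each
#'   haplotype pair or `S1 ... Sn`.
#' @return `path`, invisibly.
#' @export
write_phased_vcf <- function(x, path, sample_names = NULL) {
  H <- n_haplotypes(x)
  if (H %% 2L != 0L)
    stop("need an even number of haplotypes to form diploid samples")
  n <- H %/% 2L
  if (is.null(sample_names)) {
    pre <- sub("_[12]$", "", x$haplotype_ids[seq(1L, H, by = 2L)])
    sample_names <- if (anyDuplicated(pre) == 0L && all(nzchar(pre))) pre
                    else paste0("S", seq_len(n))
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               sprintf("##contig=<ID=%s>", x$chrom),
               '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", sample_names), collapse = "\t")), con)
  if (n_sites(x) > 0L) {
    gts <- vapply(seq_len(n), function(s)
      paste(x$alleles[2L * s - 1L, ], x$alleles[2L * s, ], sep = "|"),
      character(n_sites(x)))
    if (n_sites(x) == 1L) gts <- matrix(gts, nrow = 1L)
    lines <- vapply(seq_len(n_sites(x)), function(i)
      paste(c(x$chrom, format(x$positions[i], scientific = FALSE),
              ".", "A", "G", ".", "PASS", ".", "GT", gts[i, ]),
            collapse = "\t"), character(1L))
    writeLines(lines, con)
  }
  invisible(path)
}
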