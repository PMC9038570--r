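#' Simulation configuration
#'
#' Bundles every tunable of the synthetic-data module with validated
#' defaults chosen to mirror the statistical structure of the real
#' inputs: two haplotype clades at intermediate frequency over a 16 kb
#' region, a genome of neutral 10 kb windows, clade-conditional SRCR
#' repeat-allele spectra (short-clade modal allele 8, long-clade modal
#' allele 13, alleles bounded by the 7-21 repeat range), CEPH-style
#' three-generation pedigrees and parent-offspring trios, isoform sizes
#' linear in diploid copy number with a secretor offset, and long
#' transcript reads tiling the repeat array with occasional truncation.
#'
#' @param seed integer master seed.
#' @param n_haplotypes haplotypes per simulated region.
#' @param theta scaled mutation rate per window.
#' @param n_neutral_windows number of neutral windows in the simulated
#'   genome-wide null.
#' @param window_bp scan window width (bp).
#' @param clade_freq fraction of haplotypes in the "short" clade.
#' @param clade_divergence fixed inter-clade differences over the region.
#' @param cnv_spectrum_by_clade named list `short`/`long` of named
#'   probability vectors over repeat alleles (names are allele integers in
#'   `[kmin, kmax]`; each vector sums to 1 within 1e-9).
#' @param kmin,kmax repeat-allele range (defaults 7 and 21).
#' @param n_trios,n_pedigrees family structure counts (pedigrees are
#'   three-generation: 4 grandparents, 2 parents, `sibship` children).
#' @param sibship children per three-generation pedigree.
#' @param cn_measurement_error probability that a diploid total is
#'   reported off by +/-1 (PRT miscalls are near-integer).
#' @param isoform_intercept,isoform_slope,secretor_effect,isoform_noise_sd
#'   parameters of the isoform-size model (kDa scale).
#' @param secretor_null_freq population frequency of the FUT2 null
#'   allele (homozygous null = Se-).
#' @param n_reads,truncation_rate transcript-read simulation: read count
#'   and probability a read loses a random 5' or 3' portion.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_haplotypes = 100L,
                       theta = 5,
                       n_neutral_windows = 1000L,
                       window_bp = 10000L,
                       clade_freq = 0.5,
                       clade_divergence = 20L,
                       cnv_spectrum_by_clade = list(
                         short = c(`7` = 0.15, `8` = 0.55, `9` = 0.10,
                                   `11` = 0.12, `14` = 0.08),
                         long  = c(`11` = 0.18, `13` = 0.45, `14` = 0.25,
                                   `16` = 0.12)),
                       kmin = 7L, kmax = 21L,
                       n_trios = 66L,
                       n_pedigrees = 10L,
                       sibship = 8L,
                       cn_measurement_error = 0.02,
                       isoform_intercept = 245,
                       isoform_slope = 5,
                       secretor_effect = 10,
                       isoform_noise_sd = 10,
                       secretor_null_freq = 0.45,
                       n_reads = 1000L,
                       truncation_rate = 0.3) {
  cfg <- list(seed = as.integer(seed), n_haplotypes = as.integer(n_haplotypes),
              theta = theta, n_neutral_windows = as.integer(n_neutral_windows),
              window_bp = as.integer(window_bp), clade_freq = clade_freq,
              clade_divergence = as.integer(clade_divergence),
              cnv_spectrum_by_clade = cnv_spectrum_by_clade,
              kmin = as.integer(kmin), kmax = as.integer(kmax),
              n_trios = as.integer(n_trios),
              n_pedigrees = as.integer(n_pedigrees),
              sibship = as.integer(sibship),
              cn_measurement_error = cn_measurement_error,
              isoform_intercept = isoform_intercept,
              isoform_slope = isoform_slope,
              secretor_effect = secretor_effect,
              isoform_noise_sd = isoform_noise_sd,
              secretor_null_freq = secretor_null_freq,
              n_reads = as.integer(n_reads),
              truncation_rate = truncation_rate)
  validate_sim_config(cfg)
  class(cfg) <- "sim_config"
  cfg
}

validate_sim_config <- function(cfg) {
  stopifnot(cfg$kmin >= 1L, cfg$kmax >= cfg$kmin)
  if (cfg$clade_freq <= 0 || cfg$clade_freq >= 1)
    stop("clade_freq must lie strictly between 0 and 1")
  if (!all(c("short", "long") %in% names(cfg$cnv_spectrum_by_clade)))
    stop("cnv_spectrum_by_clade needs components 'short' and 'long'")
  for (cl in c("short", "long")) {
    p <- cfg$cnv_spectrum_by_clade[[cl]]
    k <- as.integer(names(p))
    if (anyNA(k) || any(k < cfg$kmin) || any(k > cfg$kmax))
      stop("spectrum alleles for clade '", cl, "' must be integers in [",
           cfg$kmin, ",", cfg$kmax, "]")
    if (any(p < 0) || abs(sum(p) - 1) > 1e-9)
      stop("spectrum for clade '", cl, "' must be a probability vector ",
           "summing to 1 within 1e-9")
  }
  if (cfg$cn_measurement_error < 0 || cfg$cn_measurement_error > 1 ||
      cfg$truncation_rate < 0 || cfg$truncation_rate > 1 ||
      cfg$secretor_null_freq < 0 || cfg$secretor_null_freq > 1)
    stop("rates must lie in [0,1]")
  if (cfg$isoform_slope <= 0) stop("isoform_slope must be > 0")
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf(paste0("sim_config: seed %d; %d haplotypes, theta %.3g, ",
                     "%d neutral windows of %d bp;\n  clade_freq %.2f, ",
                     "divergence %d; alleles %d-%d; %d trios + %d pedigrees; ",
                     "cn error %.3g\n"),
              x$seed, x$n_haplotypes, x$theta, x$n_neutral_windows,
              x$window_bp, x$clade_freq, x$clade_divergence, x$kmin, x$kmax,
              x$n_trios, x$n_pedigrees, x$cn_measurement_error))
  invisible(x)
}

#' Read / write a simulation configuration as key = value text
#'
#' Spectra are encoded as comma-separated `allele:probability` pairs
#' (`spectrum_short = 8:0.6,9:0.15,...`).
#'
#' @param cfg a [sim_config()].
#' @param path text file.
#' @return `write_sim_config` returns `path` invisibly; `read_sim_config`
#'   returns a `sim_config`.
#' @rdname sim_config_io
#' @export
write_sim_config <- function(cfg, path) {
  enc_spec <- function(p) paste(sprintf("%s:%.10g", names(p), p),
                                collapse = ",")
  scalars <- cfg[setdiff(names(cfg), "cnv_spectrum_by_clade")]
  lines <- c(sprintf("%s = %.10g", names(scalars), unlist(scalars)),
             sprintf("spectrum_short = %s",
                     enc_spec(cfg$cnv_spectrum_by_clade$short)),
             sprintf("spectrum_long = %s",
                     enc_spec(cfg$cnv_spectrum_by_clade$long)))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname sim_config_io
#' @export
read_sim_config <- function(path) {
  lines <- grep("=", readLines(path), fixed = TRUE, value = TRUE)
  kv <- regmatches(lines, regexec("^\\s*([A-Za-z_0-9]+)\\s*=\\s*(.*?)\\s*$",
                                  lines))
  keys <- vapply(kv, `[`, character(1L), 2L)
  vals <- vapply(kv, `[`, character(1L), 3L)
  dec_spec <- function(s) {
    parts <- strsplit(strsplit(s, ",")[[1L]], ":")
    stats::setNames(vapply(parts, function(p) as.numeric(p[2L]), numeric(1L)),
                    vapply(parts, `[`, character(1L), 1L))
  }
  args <- list()
  for (i in seq_along(keys)) {
    if (keys[i] == "spectrum_short" || keys[i] == "spectrum_long") next
    args[[keys[i]]] <- as.numeric(vals[i])
  }
  args$cnv_spectrum_by_clade <- list(short = dec_spec(vals[keys == "spectrum_short"]),
                                     long = dec_spec(vals[keys == "spectrum_long"]))
  do.call(sim_config, args)
}
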