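#' Simulate clade-linked CNV alleles through families
#'
#' Draws per-haplotype SRCR repeat alleles from the clade-conditional
#' spectrum (the clade doubles as the tag-SNP allele: short clade carries
#' rs-proxy allele "C", long clade "A"), builds founders, and transmits
#' haplotypes Mendelianly through `n_trios` parent-offspring trios and
#' `n_pedigrees` three-generation CEPH-style families (4 grandparents,
#' 2 parents, `sibship` children). Observed diploid totals are the sum of
#' the two haplotype alleles, perturbed by +/-1 with probability
#' `cn_measurement_error`.
#'
#' @param config a [sim_config()].
#' @param seed integer seed; defaults to `config$seed`.
#' @return List with:
#'   \describe{
#'     \item{pedigree}{data.frame family, individual, father, mother, sex
#'       ("0" marks a founder's absent parents).}
#'     \item{cn_obs}{data.frame individual, diploid_total (observed),
#'       true_total.}
#'     \item{snp_phase}{data.frame individual, allele1, allele2: phased
#'       tag-SNP alleles; allele1 is the paternal haplotype for
#'       non-founders.}
#'     \item{truth}{data.frame individual, hap (1/2), origin, clade,
#'       tag_allele, repeat_allele: one row per haplotype.}
#'   }
#' @export
simulate_cnv_and_families <- function(config, seed = config$seed) {
  validate_sim_config(config)
  if (!is.null(seed)) set.seed(seed)
  spec <- config$cnv_spectrum_by_clade

  draw_founder_hap <- function() {
    clade <- if (stats::runif(1L) < config$clade_freq) "short" else "long"
    p <- spec[[clade]]
    allele <- as.integer(sample(names(p), 1L, prob = p))
    list(clade = clade, tag = if (clade == "short") "C" else "A",
         allele = allele)
  }

  ped <- list(); truth <- list(); hap_store <- list()

  add_founder <- function(family, id, sex) {
    h1 <- draw_founder_hap(); h2 <- draw_founder_hap()
    hap_store[[id]] <<- list(h1, h2)
    ped[[length(ped) + 1L]] <<- data.frame(
      family = family, individual = id, father = "0", mother = "0",
      sex = sex, stringsAsFactors = FALSE)
    truth[[length(truth) + 1L]] <<- data.frame(
      individual = id, hap = 1:2, origin = "founder",
      clade = c(h1$clade, h2$clade), tag_allele = c(h1$tag, h2$tag),
      repeat_allele = c(h1$allele, h2$allele), stringsAsFactors = FALSE)
    id
  }
  add_child <- function(family, id, father, mother, sex) {
    hp <- hap_store[[father]][[sample.int(2L, 1L)]]
    hm <- hap_store[[mother]][[sample.int(2L, 1L)]]
    hap_store[[id]] <<- list(hp, hm)  # hap1 = paternal, hap2 = maternal
    ped[[length(ped) + 1L]] <<- data.frame(
      family = family, individual = id, father = father, mother = mother,
      sex = sex, stringsAsFactors = FALSE)
    truth[[length(truth) + 1L]] <<- data.frame(
      individual = id, hap = 1:2, origin = c("paternal", "maternal"),
      clade = c(hp$clade, hm$clade), tag_allele = c(hp$tag, hm$tag),
      repeat_allele = c(hp$allele, hm$allele), stringsAsFactors = FALSE)
    id
  }

  for (t in seq_len(config$n_trios)) {
    fam <- sprintf("T%03d", t)
    f <- add_founder(fam, paste0(fam, "_F"), 1L)
    m <- add_founder(fam, paste0(fam, "_M"), 2L)
    add_child(fam, paste0(fam, "_C"), f, m, sample(1:2, 1L))
  }
  for (p in seq_len(config$n_pedigrees)) {
    fam <- sprintf("P%03d", p)
    gf1 <- add_founder(fam, paste0(fam, "_GF1"), 1L)
    gm1 <- add_founder(fam, paste0(fam, "_GM1"), 2L)
    gf2 <- add_founder(fam, paste0(fam, "_GF2"), 1L)
    gm2 <- add_founder(fam, paste0(fam, "_GM2"), 2L)
    fa <- add_child(fam, paste0(fam, "_FA"), gf1, gm1, 1L)
    mo <- add_child(fam, paste0(fam, "_MO"), gf2, gm2, 2L)
    for (k in seq_len(config$sibship))
      add_child(fam, sprintf("%s_C%d", fam, k), fa, mo, sample(1:2, 1L))
  }

  pedigree <- do.call(rbind, ped)
  truth <- do.call(rbind, truth)
  rownames(truth) <- NULL

  ids <- pedigree$individual
  true_total <- vapply(ids, function(id)
    hap_store[[id]][[1L]]$allele + hap_store[[id]][[2L]]$allele, integer(1L))
  err <- stats::runif(length(ids)) < config$cn_measurement_error
  obs_total <- true_total +
    ifelse(err, sample(c(-1L, 1L), length(ids), replace = TRUE), 0L)
  cn_obs <- data.frame(individual = ids, diploid_total = as.integer(obs_total),
                       true_total = as.integer(true_total),
                       stringsAsFactors = FALSE)
  snp_phase <- data.frame(
    individual = ids,
    allele1 = vapply(ids, function(id) hap_store[[id]][[1L]]$tag, character(1L)),
    allele2 = vapply(ids, function(id) hap_store[[id]][[2L]]$tag, character(1L)),
    stringsAsFactors = FALSE)
  rownames(cn_obs) <- rownames(snp_phase) <- NULL
  list(pedigree = pedigree, cn_obs = cn_obs, snp_phase = snp_phase,
       truth = truth)
}

#' Round half away from zero
#' @noRd
round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

#' Classify an isoform band size into class I-IV
#'
#' Salivary DMBT1 western blots resolve four size classes with approximate
#' band sizes 345 (I), 375 (II), 389 (III) and 287/345 (IV) kDa.
#' Classification is by nearest-band thresholds on the primary (smallest
#' for IV) band.
#'
#' @param size_kda numeric vector of sizes in kDa.
#' @return Character vector in `c("IV","I","II","III")`.
#' @export
classify_isoform <- function(size_kda) {
  cut(size_kda, breaks = c(-Inf, (287 + 345) / 2, (345 + 375) / 2,
                           (375 + 389) / 2, Inf),
      labels = c("IV", "I", "II", "III")) |> as.character()
}

isoform_band_table <- c(I = "345", II = "375", III = "389", IV = "287,345")

#' Simulate a salivary isoform panel
#'
#' Protein size is linear in diploid SRCR copy number with a secretor
#' offset: `size = intercept + slope * CN + secretor_effect * 1[Se+] +
#' N(0, noise_sd)`. Secretor status follows Hardy-Weinberg at the FUT2
#' null-allele frequency; the isoform class is assigned from the size by
#' [classify_isoform()] and the class's canonical band size(s) reported.
#'
#' @param diploid_cns integer vector of diploid SRCR copy numbers, one per
#'   sample.
#' @param config a [sim_config()] (uses the isoform_* and
#'   secretor_null_freq fields).
#' @param seed optional integer seed.
#' @return data.frame: sample, srcr_diploid_cn, secretor ("+"/"-"),
#'   fut2_genotype, isoform, bands, size_kda (the continuous true size).
#' @export
simulate_isoform_panel <- function(diploid_cns, config = sim_config(),
                                   seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- length(diploid_cns)
  q <- config$secretor_null_freq
  nulls <- stats::rbinom(n, 2L, q)
  secretor <- ifelse(nulls == 2L, "-", "+")
  fut2 <- c("G/G", "G/A", "A/A")[nulls + 1L]
  size <- config$isoform_intercept + config$isoform_slope * diploid_cns +
    config$secretor_effect * (secretor == "+") +
    stats::rnorm(n, 0, config$isoform_noise_sd)
  iso <- classify_isoform(size)
  data.frame(sample = paste0("IS", seq_len(n)),
             srcr_diploid_cn = as.integer(diploid_cns),
             secretor = secretor, fut2_genotype = fut2, isoform = iso,
             bands = unname(isoform_band_table[iso]), size_kda = size,
             stringsAsFactors = FALSE)
}

#' Table writers for the synthetic-data module
#'
#' Plain tab-separated writers for the pedigree (PED-like: family,
#' individual, father, mother, sex with "0" marking founders' parents),
#' the copy-number observation table and the isoform panel.
#'
#' @param x the corresponding data.frame.
#' @param path output file.
#' @return `path`, invisibly.
#' @rdname sim_writers
#' @export
write_pedigree <- function(x, path) {
  utils::write.table(x[, c("family", "individual", "father", "mother", "sex")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname sim_writers
#' @export
write_cn_table <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname sim_writers
#' @export
write_isoform_table <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Readers for the tabular interfaces
#'
#' @param path tab-separated file written by the corresponding writer (or
#'   produced externally with the same columns).
#' @return data.frame.
#' @rdname sim_readers
#' @export
read_pedigree <- function(path)
  utils::read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE,
                    colClasses = "character")

#' @rdname sim_readers
#' @export
read_cn_table <- function(path)
  utils::read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)

#' @rdname sim_readers
#' @export
read_isoform_table <- function(path)
  utils::read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
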