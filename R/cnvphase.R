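#' Call integer diploid copy numbers from PRT ratios
#'
#' The paralogue ratio test (PRT) co-amplifies a copy-variable and a
#' reference locus with one primer pair; the amplicon ratio is linear in
#' copy number. For each assay a least-squares line `CN = a + b * ratio`
#' is fitted on calibration samples of known copy number; per-sample
#' estimates from multiple assays are averaged (unweighted) before
#' rounding. Half-integers round away from zero; a call whose continuous
#' consensus estimate is more than 0.35 from the nearest integer is
#' quality-flagged.
#'
#' @param ratios data.frame with columns individual, assay, ratio (one
#'   row per measurement).
#' @param calibration data.frame with columns assay, ratio, cn; every
#'   assay needs >= 2 calibration points spanning distinct copy numbers.
#' @return data.frame: individual, diploid_total (integer), estimate
#'   (continuous consensus), n_assays, quality_flag.
#' @examples
#' cal <- data.frame(assay = "PRT1", ratio = c(1, 2), cn = c(14, 28))
#' call_integer_cn(data.frame(individual = "s1", assay = "PRT1", ratio = 1.5),
#'                 cal)
#' @export
call_integer_cn <- function(ratios, calibration) {
  fits <- lapply(split(calibration, calibration$assay), function(cal) {
    if (nrow(cal) < 2L || length(unique(cal$cn)) < 2L)
      stop("assay ", cal$assay[1L],
           ": need >= 2 calibration points with distinct copy numbers")
    fit <- stats::lm(cn ~ ratio, data = cal)
    if (stats::coef(fit)[["ratio"]] <= 0)
      stop("assay ", cal$assay[1L],
           ": calibration slope is not positive; calibration error")
    fit
  })
  unknown <- setdiff(unique(ratios$assay), names(fits))
  if (length(unknown))
    stop("no calibration for assay(s): ", paste(unknown, collapse = ", "))
  ratios$est <- vapply(seq_len(nrow(ratios)), function(i)
    unname(stats::predict(fits[[ratios$assay[i]]],
                          data.frame(ratio = ratios$ratio[i]))), numeric(1L))
  per_ind <- split(ratios, ratios$individual)
  out <- do.call(rbind, lapply(per_ind, function(d) {
    est <- mean(d$est)  # consensus across assays before rounding
    cn <- as.integer(round_half_away(est))
    data.frame(individual = d$individual[1L], diploid_total = cn,
               estimate = est, n_assays = nrow(d),
               quality_flag = abs(est - cn) > 0.35,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out[match(unique(ratios$individual), out$individual), , drop = FALSE]
}

#' Enumerate haplotype allele pairs compatible with a diploid total
#'
#' All unordered pairs `{a, b}` with `kmin <= a <= b <= kmax` and
#' `a + b = T`. An empty result means the total is inconsistent with the
#' declared allele range (the caller decides how to treat it).
#'
#' @param T integer diploid total.
#' @param kmin,kmax allele range (defaults 7 and 21, the SRCR repeat
#'   range).
#' @return Integer matrix with columns `a`, `b` (possibly 0 rows).
#' @examples
#' enumerate_allele_pairs(16)   # (7,9), (8,8)
#' @export
enumerate_allele_pairs <- function(T, kmin = 7L, kmax = 21L) {
  lo <- max(kmin, T - kmax)
  hi <- floor(T / 2)
  if (lo > hi)
    return(matrix(integer(0), ncol = 2L, dimnames = list(NULL, c("a", "b"))))
  a <- seq.int(lo, hi)
  cbind(a = a, b = T - a)
}

## ordered candidate pairs (hap1, hap2) for one individual
ordered_pairs <- function(T, kmin, kmax) {
  p <- enumerate_allele_pairs(T, kmin, kmax)
  if (nrow(p) == 0L)
    return(matrix(integer(0), ncol = 2L))
  out <- rbind(p, p[p[, 1L] != p[, 2L], c(2L, 1L), drop = FALSE])
  colnames(out) <- c("h1", "h2")
  out[order(out[, 1L], out[, 2L]), , drop = FALSE]
}

## alleles a parent can place on a child haplotype carrying tag `tag`:
## union over the parent's candidate pairs of the entries whose haplotype
## slot carries that tag
transmissible_alleles <- function(pairs, tags, tag) {
  cols <- which(tags == tag)
  if (!length(cols)) return(integer(0))
  unique(as.vector(pairs[, cols, drop = FALSE]))
}

#' Phase CNV alleles through a pedigree by constraint propagation
#'
#' Formalizes "phasing by observing segregation": each individual starts
#' with every ordered allele pair compatible with its diploid total
#' (haplotype 1 = paternal for non-founders); transmission constraints --
#' a child's paternal (maternal) allele must be placeable by the father
#' (mother) on a haplotype carrying the child's transmitted tag-SNP
#' allele -- prune candidate sets to a fixpoint. For families of at most
#' `exhaustive_limit` members a depth-first enumeration of joint
#' assignments then verifies and refines the propagated sets. Haplotypes
#' whose candidate set has one allele are `unique`; several, `ambiguous`;
#' an empty set marks the family `inconsistent` with the offending
#' individual named (optionally retried with a single +/-1 total
#' relaxation when `relax_errors = TRUE`; relaxed calls are flagged).
#'
#' @param ped pedigree data.frame (family, individual, father, mother;
#'   "0"/NA parents mark founders).
#' @param obs data.frame individual, diploid_total.
#' @param snp data.frame individual, allele1, allele2: phased tag-SNP
#'   alleles per haplotype (allele1 paternal for non-founders).
#' @param kmin,kmax allele range.
#' @param exhaustive_limit family size up to which the joint enumeration
#'   refinement runs (default 12).
#' @param relax_errors retry inconsistent families with one +/-1
#'   diploid-total relaxation.
#' @return List of class `pedigree_phasing`:
#'   \describe{
#'     \item{assignments}{data.frame family, individual, hap, founder,
#'       tag_allele, allele (NA unless unique), candidates
#'       (comma-separated), status, method, relaxed.}
#'     \item{inconsistencies}{data.frame family, individual, detail.}
#'   }
#' @export
pedigree_phase <- function(ped, obs, snp, kmin = 7L, kmax = 21L,
                           exhaustive_limit = 12L, relax_errors = FALSE) {
  totals <- stats::setNames(obs$diploid_total, obs$individual)
  tag1 <- stats::setNames(snp$allele1, snp$individual)
  tag2 <- stats::setNames(snp$allele2, snp$individual)
  assignments <- list(); inconsistencies <- list()

  for (fam in unique(ped$family)) {
    fped <- ped[ped$family == fam, , drop = FALSE]
    res <- phase_family(fped, totals, tag1, tag2, kmin, kmax,
                        exhaustive_limit)
    relaxed_id <- NA_character_
    if (!is.null(res$inconsistent) && relax_errors) {
      fix <- relax_family(fped, totals, tag1, tag2, kmin, kmax,
                          exhaustive_limit)
      if (!is.null(fix)) {
        res <- fix$result
        relaxed_id <- fix$individual
      }
    }
    if (!is.null(res$inconsistent)) {
      inconsistencies[[fam]] <- data.frame(
        family = fam, individual = res$inconsistent, detail = res$detail,
        stringsAsFactors = FALSE)
      next
    }
    for (id in fped$individual) {
      pairs <- res$states[[id]]
      founder <- fped$father[fped$individual == id] %in% c("0", NA)
      for (h in 1:2) {
        cand <- sort(unique(pairs[, h]))
        assignments[[length(assignments) + 1L]] <- data.frame(
          family = fam, individual = id, hap = h, founder = founder,
          tag_allele = if (h == 1L) tag1[[id]] else tag2[[id]],
          allele = if (length(cand) == 1L) cand else NA_integer_,
          candidates = paste(cand, collapse = ","),
          status = if (length(cand) == 1L) "unique" else "ambiguous",
          method = "pedigree",
          relaxed = identical(id, relaxed_id),
          stringsAsFactors = FALSE)
      }
    }
  }
  structure(list(
    assignments = if (length(assignments)) do.call(rbind, assignments)
                  else NULL,
    inconsistencies = if (length(inconsistencies))
      do.call(rbind, inconsistencies) else NULL),
    class = "pedigree_phasing")
}

#' @export
print.pedigree_phasing <- function(x, ...) {
  a <- x$assignments
  cat(sprintf("pedigree_phasing: %d haplotypes (%d unique, %d ambiguous)",
              NROW(a), sum(a$status == "unique"),
              sum(a$status == "ambiguous")))
  if (!is.null(x$inconsistencies))
    cat(sprintf("; %d inconsistent famil%s",
                length(unique(x$inconsistencies$family)),
                ifelse(length(unique(x$inconsistencies$family)) == 1L,
                       "y", "ies")))
  cat("\n")
  invisible(x)
}

## core solver for one family; returns states (named list of ordered-pair
## matrices) or an inconsistency marker
phase_family <- function(fped, totals, tag1, tag2, kmin, kmax,
                         exhaustive_limit) {
  ids <- fped$individual
  miss <- ids[!(ids %in% names(totals)) | is.na(totals[ids])]
  if (length(miss))
    stop("no diploid total observed for: ", paste(miss, collapse = ", "))
  states <- lapply(stats::setNames(ids, ids), function(id)
    ordered_pairs(totals[[id]], kmin, kmax))
  for (id in ids)
    if (nrow(states[[id]]) == 0L)
      return(list(inconsistent = id,
                  detail = sprintf("total %d incompatible with range [%d,%d]",
                                   totals[[id]], kmin, kmax)))
  children <- fped[!(fped$father %in% c("0", NA)), , drop = FALSE]
  ## tag-SNP Mendelian screen
  for (i in seq_len(nrow(children))) {
    id <- children$individual[i]
    if (!(tag1[[id]] %in% c(tag1[[children$father[i]]],
                            tag2[[children$father[i]]])))
      return(list(inconsistent = id,
                  detail = "paternal tag allele absent from father"))
    if (!(tag2[[id]] %in% c(tag1[[children$mother[i]]],
                            tag2[[children$mother[i]]])))
      return(list(inconsistent = id,
                  detail = "maternal tag allele absent from mother"))
  }
  repeat {
    changed <- FALSE
    for (i in seq_len(nrow(children))) {
      id <- children$individual[i]
      fa <- children$father[i]; mo <- children$mother[i]
      ftags <- c(tag1[[fa]], tag2[[fa]]); mtags <- c(tag1[[mo]], tag2[[mo]])
      allow_p <- transmissible_alleles(states[[fa]], ftags, tag1[[id]])
      allow_m <- transmissible_alleles(states[[mo]], mtags, tag2[[id]])
      keep <- states[[id]][, 1L] %in% allow_p &
              states[[id]][, 2L] %in% allow_m
      if (!all(keep)) {
        states[[id]] <- states[[id]][keep, , drop = FALSE]
        changed <- TRUE
      }
      ## reverse constraint: a parent pair must be able to supply the
      ## child's transmitted allele on a matching-tag haplotype
      for (side in 1:2) {
        par <- if (side == 1L) fa else mo
        ptags <- if (side == 1L) ftags else mtags
        ctag <- if (side == 1L) tag1[[id]] else tag2[[id]]
        child_alleles <- unique(states[[id]][, side])
        cols <- which(ptags == ctag)
        ok <- vapply(seq_len(nrow(states[[par]])), function(r)
          any(states[[par]][r, cols] %in% child_alleles), logical(1L))
        if (!all(ok)) {
          states[[par]] <- states[[par]][ok, , drop = FALSE]
          changed <- TRUE
        }
      }
      for (who in c(id, fa, mo))
        if (nrow(states[[who]]) == 0L)
          return(list(inconsistent = who,
                      detail = "no allele pair survives transmission constraints"))
    }
    if (!changed) break
  }
  if (length(ids) <= exhaustive_limit) {
    refined <- enumerate_family(states, fped, tag1, tag2)
    if (is.null(refined))
      return(list(inconsistent = ids[1L],
                  detail = "no joint assignment satisfies the pedigree"))
    states <- refined
  }
  list(states = states)
}

## depth-first enumeration of all joint assignments consistent with
## transmission; exact (complete with pruning); returns per-individual
## unions of surviving pairs
enumerate_family <- function(states, fped, tag1, tag2) {
  ids <- fped$individual
  founder_first <- ids[order(!(fped$father %in% c("0", NA)))]
  child_rows <- which(!(fped$father %in% c("0", NA)))
  survivors <- lapply(states, function(s) rep(FALSE, nrow(s)))
  chosen <- list()
  consistent_so_far <- function(id) {
    ## check every child constraint whose members are all chosen
    for (i in child_rows) {
      cid <- fped$individual[i]
      fa <- fped$father[i]; mo <- fped$mother[i]
      if (!all(c(cid, fa, mo) %in% names(chosen))) next
      cp <- chosen[[cid]]
      for (side in 1:2) {
        par <- if (side == 1L) fa else mo
        ptags <- c(tag1[[par]], tag2[[par]])
        ctag <- if (side == 1L) tag1[[cid]] else tag2[[cid]]
        cols <- which(ptags == ctag)
        if (!any(chosen[[par]][cols] == cp[side])) return(FALSE)
      }
    }
    TRUE
  }
  found_any <- FALSE
  recurse <- function(k) {
    if (k > length(founder_first)) {
      found_any <<- TRUE
      for (id in names(chosen)) {
        s <- states[[id]]
        hit <- which(s[, 1L] == chosen[[id]][1L] & s[, 2L] == chosen[[id]][2L])
        survivors[[id]][hit] <<- TRUE
      }
      return(invisible(NULL))
    }
    id <- founder_first[k]
    for (r in seq_len(nrow(states[[id]]))) {
      chosen[[id]] <<- states[[id]][r, ]
      if (consistent_so_far(id)) recurse(k + 1L)
    }
    chosen[[id]] <<- NULL
    invisible(NULL)
  }
  recurse(1L)
  if (!found_any) return(NULL)
  lapply(stats::setNames(names(states), names(states)), function(id)
    states[[id]][survivors[[id]], , drop = FALSE])
}

## try single-individual +/-1 relaxations; accept only an unambiguous fix
relax_family <- function(fped, totals, tag1, tag2, kmin, kmax,
                         exhaustive_limit) {
  fixes <- list()
  for (id in fped$individual) {
    for (delta in c(-1L, 1L)) {
      t2 <- totals
      t2[[id]] <- t2[[id]] + delta
      res <- phase_family(fped, t2, tag1, tag2, kmin, kmax, exhaustive_limit)
      if (is.null(res$inconsistent))
        fixes[[paste0(id, delta)]] <- list(individual = id, result = res)
    }
  }
  if (length(fixes) == 1L) fixes[[1L]] else NULL
}

#' Attach resolved CNV alleles to tag-SNP haplotypes
#'
#' Emits one record per uniquely resolved haplotype, pairing the tag-SNP
#' allele (A/C) with the integer repeat allele. Ambiguous or inconsistent
#' haplotypes are excluded, and non-founders are excluded from
#' population-level sets to avoid double counting transmitted haplotypes;
#' exclusion counts are attached as attributes and reported.
#'
#' @param phasing a `pedigree_phasing` (or a compatible assignments
#'   data.frame with columns individual, hap, founder, tag_allele,
#'   allele, status).
#' @param founders_only drop non-founder haplotypes (default TRUE).
#' @return data.frame: haplotype (individual_hap), tag_allele,
#'   repeat_allele; attributes n_excluded_ambiguous,
#'   n_excluded_nonfounder.
#' @export
attach_to_haplotypes <- function(phasing, founders_only = TRUE) {
  a <- if (inherits(phasing, "pedigree_phasing")) phasing$assignments
       else phasing
  n_ambig <- sum(a$status != "unique")
  keep <- a$status == "unique"
  n_nonf <- 0L
  if (founders_only) {
    n_nonf <- sum(keep & !a$founder)
    keep <- keep & a$founder
  }
  out <- data.frame(haplotype = sprintf("%s_%d", a$individual[keep],
                                        a$hap[keep]),
                    tag_allele = a$tag_allele[keep],
                    repeat_allele = a$allele[keep],
                    stringsAsFactors = FALSE)
  if (n_ambig > 0L)
    message(n_ambig, " unresolved haplotype(s) excluded")
  attr(out, "n_excluded_ambiguous") <- n_ambig
  attr(out, "n_excluded_nonfounder") <- n_nonf
  out
}
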