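#' Trio EM for multiallelic CNV allele frequencies
#'
#' Expectation-maximization over population repeat-allele frequencies
#' using parent-offspring transmission, the approach used to phase the
#' YRI trios. Model: alleles are i.i.d. draws from `p` under random
#' mating; a trio configuration is father pair `{a,b}`, mother pair
#' `{c,d}` and transmitted alleles `x in {a,b}`, `y in {c,d}`, with the
#' four transmissions equiprobable, constrained to reproduce all three
#' diploid totals. The E-step computes the posterior over configurations
#' per trio; the M-step re-estimates `p` from expected founder allele
#' counts (4 per trio). The log-likelihood is asserted non-decreasing at
#' every iteration. Because the likelihood surface is multimodal for
#' multiallelic systems (diploid totals are sums, so shifted allele
#' supports can mimic each other), the EM is restarted from `n_starts`
#' deterministic initializations (uniform plus quasi-random points on the
#' simplex) and the run with the best final log-likelihood is kept.
#'
#' Trios whose child total is NA contribute only their founder totals
#' (no transmission constraint), so a founders-only input reduces to the
#' ordinary diploid-total EM.
#'
#' @param trios data.frame with integer columns father_T, mother_T,
#'   child_T (child_T may be NA).
#' @param kmin,kmax allele range.
#' @param tol log-likelihood convergence tolerance (default 1e-8).
#' @param max_iter iteration cap per start (default 1000).
#' @param n_starts number of deterministic initializations (default 10).
#' @param p_init optional initial frequency vector (named by allele);
#'   when given it replaces the multi-start schedule.
#' @return List of class `trio_em`:
#'   \describe{
#'     \item{freqs}{named probability vector over alleles with support.}
#'     \item{loglik, n_iter, converged, loglik_trace}{diagnostics of the
#'       best run.}
#'     \item{n_haplotypes}{founder haplotypes contributing (4 per used
#'       trio).}
#'     \item{assignments}{per-trio MAP configuration (father_a, father_b,
#'       mother_c, mother_d, child_x, child_y), its posterior, and an
#'       `ambiguous` flag for posterior ties (lexicographically smallest
#'       configuration reported).}
#'     \item{excluded}{indices of trios with no consistent configuration
#'       (flagged with a warning, excluded from the likelihood).}
#'   }
#' @examples
#' trio_em(data.frame(father_T = 14, mother_T = 14, child_T = 14))$freqs
#' @export
trio_em <- function(trios, kmin = 7L, kmax = 21L, tol = 1e-8,
                    max_iter = 1000L, n_starts = 10L, p_init = NULL) {
  if (nrow(trios) < 1L) stop("need at least one trio")
  alleles <- seq.int(kmin, kmax)
  K <- length(alleles)

  configs <- lapply(seq_len(nrow(trios)), function(i)
    trio_configurations(trios$father_T[i], trios$mother_T[i],
                        trios$child_T[i], kmin, kmax))
  excluded <- which(vapply(configs, function(cf) nrow(cf$table) == 0L,
                           logical(1L)))
  if (length(excluded)) {
    warning(length(excluded),
            " trio(s) with no consistent configuration excluded: ",
            paste(excluded, collapse = ", "))
    configs <- configs[-excluded]
  }
  if (!length(configs)) stop("no phasable trios remain")

  ## stack configurations across trios for vectorized E-steps
  CF <- do.call(rbind, lapply(configs, `[[`, "table"))
  trans_w <- unlist(lapply(configs, `[[`, "trans_w"), use.names = FALSE)
  trio_id <- rep(seq_along(configs),
                 vapply(configs, function(cf) nrow(cf$table), integer(1L)))
  aidx <- matrix(match(CF[, c("fa", "fb", "mc", "md")], alleles), ncol = 4L)
  het_f <- CF[, "fa"] != CF[, "fb"]
  het_m <- CF[, "mc"] != CF[, "md"]

  trio_weights <- function(p) {
    w <- trans_w * p[aidx[, 1L]] * p[aidx[, 2L]] * p[aidx[, 3L]] * p[aidx[, 4L]]
    w * (1 + het_f) * (1 + het_m)  # 2 p_a p_b for heterozygous pairs
  }
  em_run <- function(p) {
    ll_trace <- numeric(0)
    ll_old <- -Inf
    for (iter in seq_len(max_iter)) {
      w <- trio_weights(p)
      lt <- rowsum(w, trio_id)[, 1L]
      if (any(lt <= 0)) return(NULL)  # degenerate start for some trio
      ll <- sum(log(lt))
      if (ll < ll_old - 1e-9)
        stop("internal error: EM log-likelihood decreased")
      ll_trace <- c(ll_trace, ll)
      post <- w / lt[trio_id]
      counts <- rep(0, K)
      for (col in 1:4) {
        rs <- rowsum(post, aidx[, col])
        counts[as.integer(rownames(rs))] <-
          counts[as.integer(rownames(rs))] + rs[, 1L]
      }
      p <- counts / sum(counts)
      if (is.finite(ll_old) && ll - ll_old < tol) break
      ll_old <- ll
    }
    list(p = p, loglik = ll_trace[length(ll_trace)], n_iter = iter,
         converged = iter < max_iter, loglik_trace = ll_trace)
  }

  starts <- if (!is.null(p_init)) {
    stopifnot(all(names(p_init) %in% as.character(alleles)))
    v <- rep(0, K)
    v[match(as.integer(names(p_init)), alleles)] <- p_init
    list(v / sum(v))
  } else {
    ## uniform plus deterministic quasi-random simplex points
    primes <- c(2, 3, 5, 7, 11, 13, 17, 19, 23, 29, 31, 37)
    c(list(rep(1 / K, K)),
      lapply(seq_len(max(0L, n_starts - 1L)), function(r) {
        raw <- (seq_len(K) * sqrt(primes[(r - 1L) %% length(primes) + 1L]) +
                  r / 7) %% 1 + 0.05
        raw / sum(raw)
      }))
  }
  runs <- Filter(Negate(is.null), lapply(starts, em_run))
  if (!length(runs)) stop("all EM starts were degenerate")
  best <- runs[[which.max(vapply(runs, `[[`, numeric(1L), "loglik"))]]
  p <- best$p

  ## MAP configuration per retained trio under the final frequencies
  w <- trio_weights(p)
  assignments <- do.call(rbind, lapply(seq_along(configs), function(t) {
    rows <- which(trio_id == t)
    post <- w[rows] / sum(w[rows])
    tied <- which(post >= max(post) - 1e-12)
    pick <- rows[tied[1L]]  # config tables are in lexicographic order
    data.frame(trio = t, father_a = CF[pick, "fa"], father_b = CF[pick, "fb"],
               mother_c = CF[pick, "mc"], mother_d = CF[pick, "md"],
               child_x = CF[pick, "cx"], child_y = CF[pick, "cy"],
               posterior = post[tied[1L]], ambiguous = length(tied) > 1L)
  }))
  support <- p > 1e-12
  structure(list(freqs = stats::setNames(p, alleles)[support],
                 freqs_full = stats::setNames(p, alleles),
                 loglik = best$loglik, n_iter = best$n_iter,
                 converged = best$converged, loglik_trace = best$loglik_trace,
                 n_haplotypes = 4L * length(configs),
                 assignments = assignments, excluded = excluded),
            class = "trio_em")
}

#' @export
print.trio_em <- function(x, ...) {
  cat(sprintf("trio_em: %d founder haplotypes, loglik %.4f after %d iter%s\n",
              x$n_haplotypes, x$loglik, x$n_iter,
              if (x$converged) "" else " (not converged)"))
  print(round(x$freqs, 4))
  invisible(x)
}

## all configurations (fa<=fb, mc<=md, transmitted cx+cy = child_T) with
## transmission weights; child_T = NA drops the transmission constraint.
## pair probabilities are applied later (the table stores only which
## alleles are involved and the transmission multiplicity).
trio_configurations <- function(father_T, mother_T, child_T, kmin, kmax) {
  fp <- enumerate_allele_pairs(father_T, kmin, kmax)
  mp <- enumerate_allele_pairs(mother_T, kmin, kmax)
  rows <- list()
  for (i in seq_len(nrow(fp))) for (j in seq_len(nrow(mp))) {
    fpair <- unname(fp[i, ]); mpair <- unname(mp[j, ])
    if (is.na(child_T)) {
      rows[[length(rows) + 1L]] <-
        c(fa = fpair[1L], fb = fpair[2L], mc = mpair[1L], md = mpair[2L],
          cx = NA_integer_, cy = NA_integer_, w = 1)
      next
    }
    xy <- expand.grid(x = unique(fpair), y = unique(mpair))
    xy <- xy[xy$x + xy$y == child_T, , drop = FALSE]
    for (r in seq_len(nrow(xy))) {
      mult <- sum(fpair == xy$x[r]) * sum(mpair == xy$y[r])
      rows[[length(rows) + 1L]] <-
        c(fa = fpair[1L], fb = fpair[2L], mc = mpair[1L], md = mpair[2L],
          cx = xy$x[r], cy = xy$y[r], w = mult / 4)
    }
  }
  if (!length(rows))
    return(list(table = matrix(integer(0), ncol = 6L,
                               dimnames = list(NULL, c("fa", "fb", "mc",
                                                       "md", "cx", "cy"))),
                trans_w = numeric(0)))
  m <- do.call(rbind, rows)
  ord <- do.call(order, as.data.frame(m[, 1:6, drop = FALSE]))
  m <- m[ord, , drop = FALSE]
  list(table = m[, 1:6, drop = FALSE], trans_w = unname(m[, "w"]))
}
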