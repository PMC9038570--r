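#' Repeat-unit annotation
#'
#' Ordered, disjoint genomic intervals (0-based half-open) marking the
#' tandem SRCR repeat units of a gene model.
#'
#' @param starts,ends 0-based half-open unit bounds (sorted, disjoint).
#' @param contig contig name.
#' @param strand "+" or "-" (unit ordering for reporting follows strand;
#'   counting itself is strand-agnostic).
#' @return data.frame of class `repeat_annotation` with columns contig,
#'   start, end, strand, unit.
#' @export
repeat_annotation <- function(starts, ends, contig = "chr10", strand = "+") {
  if (length(starts) != length(ends) || length(starts) < 1L)
    stop("need at least one unit, with matching starts/ends")
  ord <- order(starts)
  starts <- starts[ord]; ends <- ends[ord]
  if (any(ends <= starts)) stop("unit intervals must have positive width")
  if (length(starts) > 1L && any(starts[-1L] < ends[-length(ends)]))
    stop("unit intervals must be disjoint")
  structure(data.frame(contig = contig, start = starts, end = ends,
                       strand = strand,
                       unit = if (strand == "-") rev(seq_along(starts))
                              else seq_along(starts),
                       stringsAsFactors = FALSE),
            class = c("repeat_annotation", "data.frame"))
}

#' Transcript alignment as an exon chain
#'
#' @param transcript_id identifier.
#' @param starts,ends 0-based half-open exon bounds (sorted, disjoint).
#' @param contig contig name.
#' @param five_prime_mappable,three_prime_mappable flags marking whether
#'   the read's ends mapped; a read is full-length when both are TRUE.
#' @return data.frame of class `transcript_alignment` with one row per
#'   exon and the flags as attributes-like columns.
#' @export
transcript_alignment <- function(transcript_id, starts, ends,
                                 contig = "chr10",
                                 five_prime_mappable = TRUE,
                                 three_prime_mappable = TRUE) {
  if (length(starts) != length(ends) || length(starts) < 1L)
    stop("need at least one exon")
  ord <- order(starts)
  starts <- starts[ord]; ends <- ends[ord]
  if (any(ends <= starts)) stop("exons must have positive width")
  if (length(starts) > 1L && any(starts[-1L] < ends[-length(ends)]))
    stop("exons must be disjoint")
  structure(data.frame(transcript_id = transcript_id, contig = contig,
                       start = starts, end = ends,
                       five_prime_mappable = five_prime_mappable,
                       three_prime_mappable = three_prime_mappable,
                       stringsAsFactors = FALSE),
            class = c("transcript_alignment", "data.frame"))
}

#' Count complete tandem repeat units covered by a transcript
#'
#' A unit is complete when the fraction of its length covered by the
#' transcript's exons is at least `coverage_frac`; a unit covered by any
#' exon but below the threshold is partial. A transcript is full-length
#' when both its 5' and 3' ends were mappable.
#'
#' @param aln a [transcript_alignment()].
#' @param ann a [repeat_annotation()] on the same contig.
#' @param coverage_frac completeness threshold (default 0.95).
#' @return List of class `repeat_count`: transcript_id, complete_units,
#'   partial_units, full_length, per-unit coverage fractions.
#' @export
count_repeat_units <- function(aln, ann, coverage_frac = 0.95) {
  if (aln$contig[1L] != ann$contig[1L])
    stop("transcript (", aln$contig[1L], ") and annotation (",
         ann$contig[1L], ") are on different contigs")
  cov <- vapply(seq_len(nrow(ann)), function(i) {
    o <- pmin(ann$end[i], aln$end) - pmax(ann$start[i], aln$start)
    sum(pmax(o, 0)) / (ann$end[i] - ann$start[i])
  }, numeric(1L))
  structure(list(transcript_id = aln$transcript_id[1L],
                 complete_units = sum(cov >= coverage_frac),
                 partial_units = sum(cov > 0 & cov < coverage_frac),
                 full_length = isTRUE(aln$five_prime_mappable[1L]) &&
                   isTRUE(aln$three_prime_mappable[1L]),
                 unit_coverage = stats::setNames(cov, ann$unit)),
            class = "repeat_count")
}

#' @export
print.repeat_count <- function(x, ...) {
  cat(sprintf("repeat_count %s: %d complete + %d partial unit(s)%s\n",
              x$transcript_id, x$complete_units, x$partial_units,
              if (x$full_length) " [full-length]" else " [truncated]"))
  invisible(x)
}

#' Summarize per-transcript repeat counts
#'
#' Restricts to full-length transcripts, tabulates complete-unit counts,
#' and reports the modal count (ties broken toward the smaller count).
#' When the genomic allele's unit count is supplied, concordance of the
#' transcript mode with the genomic allele is reported -- the comparison
#' used to show that transcript repeat number mirrors the genetically
#' encoded SRCR copy number.
#'
#' @param counts list of `repeat_count` objects (or a data.frame with
#'   columns complete_units and full_length).
#' @param genomic_allele optional integer unit count of the genomic
#'   allele.
#' @return List of class `transcript_summary`: n_total, n_full_length,
#'   histogram (named integer table), mode (NA when no full-length
#'   transcripts), genomic_allele, concordant.
#' @export
summarize_transcripts <- function(counts, genomic_allele = NULL) {
  if (is.data.frame(counts)) {
    cu <- counts$complete_units; fl <- counts$full_length
  } else {
    cu <- vapply(counts, `[[`, numeric(1L), "complete_units")
    fl <- vapply(counts, `[[`, logical(1L), "full_length")
  }
  full <- cu[fl]
  hist <- if (length(full)) table(full) else table(integer(0))
  mode <- if (length(full)) {
    best <- names(hist)[hist == max(hist)]
    as.integer(min(as.integer(best)))
  } else NA_integer_
  structure(list(n_total = length(cu), n_full_length = length(full),
                 histogram = hist, mode = mode,
                 genomic_allele = genomic_allele,
                 concordant = if (is.null(genomic_allele)) NA
                              else isTRUE(mode == genomic_allele)),
            class = "transcript_summary")
}

#' @export
print.transcript_summary <- function(x, ...) {
  cat(sprintf("transcript_summary: %d/%d full-length; mode = %s\n",
              x$n_full_length, x$n_total,
              ifelse(is.na(x$mode), "undefined", x$mode)))
  if (length(x$histogram)) {
    cat("  complete-unit histogram: ")
    cat(paste(sprintf("%s:%d", names(x$histogram), as.integer(x$histogram)),
              collapse = "  "), "\n")
  }
  if (!is.null(x$genomic_allele))
    cat(sprintf("  genomic allele %d: %s\n", x$genomic_allele,
                ifelse(isTRUE(x$concordant), "concordant", "discordant")))
  invisible(x)
}

#' Default tandem-repeat gene model
#'
#' A compact mock of the DMBT1 SRCR array: a 5' flanking exon, `n_units`
#' repeat-unit exons separated by short introns, and a 3' flanking exon.
#' The reference assembly allele carries 14 tandem units.
#'
#' @param n_units number of annotated units (default 14).
#' @param unit_bp,intron_bp,flank_bp component widths in bp.
#' @param contig,origin placement.
#' @return List: `annotation` (a [repeat_annotation()]), `five_prime` and
#'   `three_prime` flank exons (0-based half-open c(start, end)).
#' @export
dmbt1_gene_model <- function(n_units = 14L, unit_bp = 300L, intron_bp = 150L,
                             flank_bp = 500L, contig = "chr10",
                             origin = 124320000) {
  five <- c(origin, origin + flank_bp)
  ustart <- origin + flank_bp + intron_bp +
    (seq_len(n_units) - 1L) * (unit_bp + intron_bp)
  uend <- ustart + unit_bp
  three <- c(uend[n_units] + intron_bp, uend[n_units] + intron_bp + flank_bp)
  list(annotation = repeat_annotation(ustart, uend, contig = contig),
       five_prime = five, three_prime = three)
}

#' Simulate long transcript reads over a repeat array
#'
#' Each read is the exon chain of a transcript whose repeat array carries
#' `true_unit_count` units (5' flank exon, units 1..k, 3' flank exon).
#' With probability `truncation_rate` a read loses a uniform-random
#' prefix or suffix -- up to half the spliced transcript length -- and the
#' corresponding mappable-end flag is cleared.
#'
#' @param gene_model from [dmbt1_gene_model()]; its annotation must have
#'   at least `true_unit_count` units.
#' @param true_unit_count repeat units genetically encoded by the allele.
#' @param n_reads number of reads.
#' @param truncation_rate per-read truncation probability.
#' @param seed optional integer seed.
#' @return List of [transcript_alignment()] objects.
#' @export
simulate_transcript_reads <- function(gene_model, true_unit_count,
                                      n_reads = 100L, truncation_rate = 0,
                                      seed = NULL) {
  ann <- gene_model$annotation
  if (true_unit_count < 1L || true_unit_count > nrow(ann))
    stop("true_unit_count must lie in [1, ", nrow(ann), "]")
  if (!is.null(seed)) set.seed(seed)
  base_starts <- c(gene_model$five_prime[1L], ann$start[seq_len(true_unit_count)],
                   gene_model$three_prime[1L])
  base_ends <- c(gene_model$five_prime[2L], ann$end[seq_len(true_unit_count)],
                 gene_model$three_prime[2L])
  total <- sum(base_ends - base_starts)
  lapply(seq_len(n_reads), function(i) {
    aln <- transcript_alignment(sprintf("read%04d", i), base_starts,
                                base_ends, contig = ann$contig[1L])
    if (stats::runif(1L) < truncation_rate) {
      side <- sample(c("5p", "3p"), 1L)
      aln <- truncate_alignment(aln, side, stats::runif(1L, 0, total / 2))
    }
    aln
  })
}

#' Truncate a transcript alignment from one end
#'
#' Removes `bp` bases from the 5' or 3' end of the spliced transcript
#' (exonic coordinates) and clears the corresponding mappable-end flag.
#'
#' @param aln a [transcript_alignment()].
#' @param side "5p" or "3p" (transcript on the + strand: 5' = leftmost).
#' @param bp bases to remove (capped at the transcript length minus 1).
#' @return A truncated `transcript_alignment`.
#' @export
truncate_alignment <- function(aln, side = c("5p", "3p"), bp) {
  side <- match.arg(side)
  widths <- aln$end - aln$start
  bp <- round(bp)  # genomic coordinates stay integral
  bp <- min(bp, sum(widths) - 1)
  if (bp <= 0) return(aln)
  starts <- aln$start; ends <- aln$end
  if (side == "3p") {
    cum <- rev(cumsum(rev(widths)))  # bases from this exon to the 3' end
    drop <- cum <= bp
    keep <- !drop
    last <- max(which(keep))
    over <- bp - (if (last < length(widths)) cum[last + 1L] else 0)
    ends[last] <- ends[last] - over
  } else {
    cum <- cumsum(widths)
    drop <- cum <= bp
    keep <- !drop
    first <- min(which(keep))
    over <- bp - (if (first > 1L) cum[first - 1L] else 0)
    starts[first] <- starts[first] + over
  }
  transcript_alignment(aln$transcript_id[1L], starts[keep], ends[keep],
                       contig = aln$contig[1L],
                       five_prime_mappable = aln$five_prime_mappable[1L] &&
                         side != "5p",
                       three_prime_mappable = aln$three_prime_mappable[1L] &&
                         side != "3p")
}

#' Write / read repeat-unit annotation as BED
#'
#' @param ann a [repeat_annotation()].
#' @param path BED file (0-based half-open, matching the internal
#'   convention).
#' @return `path` invisibly; the reader returns a `repeat_annotation`.
#' @rdname repeat_annotation_io
#' @export
write_repeat_annotation <- function(ann, path) {
  bed <- data.frame(ann$contig, ann$start, ann$end,
                    paste0("SRCR_unit_", ann$unit), 0L, ann$strand)
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname repeat_annotation_io
#' @export
read_repeat_annotation <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  df <- as.data.frame(gr)
  strand <- as.character(df$strand)
  strand[strand == "*"] <- "+"
  repeat_annotation(df$start - 1L, df$end, contig = as.character(df$seqnames[1L]),
                    strand = strand[1L])
}

#' Write / read transcript exon chains as GFF3
#'
#' Transcript rows carry `five_prime_mappable` / `three_prime_mappable`
#' attributes; exon rows reference their transcript via `Parent`. The
#' reader also accepts plain GFF3 without the flags (both default TRUE)
#' and BED12 (blocks become exons; flags default TRUE).
#'
#' @param alignments list of [transcript_alignment()] objects.
#' @param path GFF3 (or, for the reader, BED12) file.
#' @return `path` invisibly; the reader returns a list of
#'   `transcript_alignment` objects.
#' @rdname transcript_io
#' @export
write_transcript_gff <- function(alignments, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  for (aln in alignments) {
    id <- aln$transcript_id[1L]
    fmt <- function(x) format(x, scientific = FALSE, trim = TRUE)
    writeLines(sprintf(
      "%s\tdmbtsel\ttranscript\t%s\t%s\t.\t+\t.\tID=%s;five_prime_mappable=%s;three_prime_mappable=%s",
      aln$contig[1L], fmt(min(aln$start) + 1L), fmt(max(aln$end)), id,
      tolower(aln$five_prime_mappable[1L]),
      tolower(aln$three_prime_mappable[1L])), con)
    for (i in seq_len(nrow(aln)))
      writeLines(sprintf("%s\tdmbtsel\texon\t%s\t%s\t.\t+\t.\tParent=%s",
                         aln$contig[1L], fmt(aln$start[i] + 1L),
                         fmt(aln$end[i]), id),
                 con)
  }
  invisible(path)
}

#' @rdname transcript_io
#' @export
read_transcript_alignments <- function(path) {
  fmt <- if (grepl("\\.bed(12)?$", path, ignore.case = TRUE)) "BED" else "GFF3"
  gr <- rtracklayer::import(path, format = fmt)
  df <- as.data.frame(gr)
  if (fmt == "BED") {
    return(lapply(seq_len(nrow(df)), function(i) {
      b <- df$blocks[[i]]
      bs <- df$start[i] - 1L + BiocGenerics::start(b) - 1L
      be <- df$start[i] - 1L + BiocGenerics::end(b)
      transcript_alignment(as.character(df$name[i]), bs, be,
                           contig = as.character(df$seqnames[i]))
    }))
  }
  tx <- df[df$type == "transcript", , drop = FALSE]
  ex <- df[df$type == "exon", , drop = FALSE]
  parent <- vapply(ex$Parent, function(p) as.character(p)[1L], character(1L))
  lapply(seq_len(nrow(tx)), function(i) {
    id <- as.character(tx$ID[i])
    e <- ex[parent == id, , drop = FALSE]
    flag <- function(col) {
      v <- if (col %in% names(tx)) tx[[col]][i] else NA
      if (is.na(v) || is.null(v)) TRUE else tolower(as.character(v)) == "true"
    }
    transcript_alignment(id, e$start - 1L, e$end,
                         contig = as.character(tx$seqnames[i]),
                         five_prime_mappable = flag("five_prime_mappable"),
                         three_prime_mappable = flag("three_prime_mappable"))
  })
}
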