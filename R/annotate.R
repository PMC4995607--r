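#' A minimal gene model for site classification
#'
#' @param gene_id gene identifier.
#' @param chrom chromosome label.
#' @param strand `"+"` or `"-"`.
#' @param tx_start,tx_end transcript span, 1-based inclusive.
#' @param exons data.frame with 1-based inclusive `start`, `end` columns;
#'   must be non-overlapping, sorted, within the span.
#' @param start_codon_pos position of the first base of the start codon.
#' @return A list of class `"gene_model"`.
#' @export
gene_model <- function(gene_id, chrom, strand, tx_start, tx_end, exons,
                       start_codon_pos) {
  stopifnot(strand %in% c("+", "-"), tx_start <= tx_end)
  exons <- as.data.frame(exons)
  stopifnot(all(c("start", "end") %in% names(exons)),
            all(exons$start <= exons$end),
            all(exons$start >= tx_start), all(exons$end <= tx_end))
  if (nrow(exons) > 1) {
    exons <- exons[order(exons$start), , drop = FALSE]
    if (any(exons$start[-1] <= exons$end[-nrow(exons)]))
      stop("exons must be non-overlapping")
  }
  if (start_codon_pos < tx_start || start_codon_pos > tx_end)
    stop("start codon must lie within the transcript span")
  structure(list(gene_id = gene_id, chrom = chrom, strand = strand,
                 tx_start = tx_start, tx_end = tx_end, exons = exons,
                 start_codon_pos = start_codon_pos),
            class = "gene_model")
}

#' Classify a site against a gene model
#'
#' Partition: `exonic` (inside an exon), `intronic` (inside the transcript
#' span but no exon), `upstream` / `downstream` (outside the span, within
#' `flank_bp` of it, on the 5' / 3' side respecting strand; the upstream
#' distance is measured to the start codon, as regulatory-variant reports
#' conventionally quote it), else `intergenic`. A site on another
#' chromosome is intergenic.
#'
#' @param model a [gene_model()].
#' @param chrom,pos site coordinate (1-based).
#' @param flank_bp flank width for upstream/downstream calls (default
#'   5,000 bp).
#' @return A list with `class` and `distance_bp` (to the start codon for
#'   upstream, to the span end for downstream; `NA` otherwise).
#' @export
classify_site <- function(model, chrom, pos, flank_bp = 5000) {
  stopifnot(inherits(model, "gene_model"))
  if (chrom != model$chrom)
    return(list(class = "intergenic", distance_bp = NA_real_))
  if (pos >= model$tx_start && pos <= model$tx_end) {
    inside_exon <- any(pos >= model$exons$start & pos <= model$exons$end)
    return(list(class = if (inside_exon) "exonic" else "intronic",
                distance_bp = NA_real_))
  }
  five_prime <- if (model$strand == "+") pos < model$tx_start
                else pos > model$tx_end
  if (five_prime) {
    dist <- abs(model$start_codon_pos - pos)
    edge <- if (model$strand == "+") model$tx_start - pos
            else pos - model$tx_end
    if (edge <= flank_bp)
      return(list(class = "upstream", distance_bp = dist))
  } else {
    dist <- if (model$strand == "+") pos - model$tx_end
            else model$tx_start - pos
    if (dist <= flank_bp)
      return(list(class = "downstream", distance_bp = dist))
  }
  list(class = "intergenic", distance_bp = NA_real_)
}

#' Conserved-element interval track
#'
#' @param intervals data.frame with `chrom`, `start`, `end` (0-based
#'   half-open, BED convention) and `score`.
#' @return A list of class `"conservation_track"` with sorted intervals.
#' @export
conservation_track <- function(intervals) {
  intervals <- as.data.frame(intervals)
  stopifnot(all(c("chrom", "start", "end", "score") %in% names(intervals)))
  if (any(intervals$start >= intervals$end))
    stop("intervals must satisfy start < end (0-based half-open)")
  intervals <- intervals[order(intervals$chrom, intervals$start), ,
                         drop = FALSE]
  rownames(intervals) <- NULL
  structure(list(intervals = intervals), class = "conservation_track")
}

#' Overlap sites with a conserved-element track
#'
#' A 1-based site at `pos` overlaps a 0-based half-open interval
#' `[start, end)` exactly when `start <= pos - 1 < end`. Interval search
#' uses IRanges; the coordinate conversion is centralized here.
#'
#' @param sites data.frame with `chrom`, `pos` (1-based).
#' @param track a [conservation_track()].
#' @return data.frame: `chrom`, `pos`, `overlaps` (logical), `score`
#'   (of the highest-scoring overlapping interval; `NA` when none).
#' @export
overlap_conserved <- function(sites, track) {
  stopifnot(inherits(track, "conservation_track"),
            all(c("chrom", "pos") %in% names(sites)))
  iv <- track$intervals
  overlaps <- rep(FALSE, nrow(sites))
  score <- rep(NA_real_, nrow(sites))
  for (chrom in unique(sites$chrom)) {
    si <- which(sites$chrom == chrom)
    ti <- which(iv$chrom == chrom)
    if (!length(ti)) next
    q <- IRanges::IRanges(start = sites$pos[si], width = 1L)       # 1-based
    s <- IRanges::IRanges(start = iv$start[ti] + 1L, end = iv$end[ti])
    hits <- IRanges::findOverlaps(q, s)
    if (!length(hits)) next
    qh <- S4Vectors::queryHits(hits)
    sh <- S4Vectors::subjectHits(hits)
    best <- tapply(iv$score[ti][sh], qh, max)
    idx <- si[as.integer(names(best))]
    overlaps[idx] <- TRUE
    score[idx] <- as.numeric(best)
  }
  data.frame(chrom = sites$chrom, pos = sites$pos, overlaps = overlaps,
             score = score, stringsAsFactors = FALSE)
}
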