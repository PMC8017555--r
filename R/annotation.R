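#' Construct a gene annotation object
#'
#' Container for gene models: one row per gene plus an exon table.
#' Coordinates are half-open 0-based throughout the package; the TSS is
#' \code{start} for '+' genes and \code{end - 1} for '-' genes.
#'
#' @param genes data.frame with \code{gene_id}, \code{symbol}, \code{chrom},
#'   \code{strand} ('+'/'-'), \code{start}, \code{end}.
#' @param exons data.frame with \code{gene_id}, \code{chrom}, \code{start},
#'   \code{end}; every exon must lie within its gene body.
#' @return object of class \code{gene_annotation}; genes gain a \code{tss}
#'   column.
#' @export
gene_annotation <- function(genes, exons) {
  stop_if(any(genes$start >= genes$end), "gene start must be < end")
  stop_if(!all(genes$strand %in% c("+", "-")), "strand must be '+' or '-'")
  m <- match(exons$gene_id, genes$gene_id)
  stop_if(any(is.na(m)), "exon references unknown gene_id")
  stop_if(any(exons$start < genes$start[m] | exons$end > genes$end[m]),
          "exons must lie within the gene body")
  genes$tss <- ifelse(genes$strand == "+", genes$start, genes$end - 1)
  structure(list(genes = genes, exons = exons), class = "gene_annotation")
}

#' @export
print.gene_annotation <- function(x, ...) {
  cat(sprintf("Gene annotation: %d genes, %d exons on %d chromosome(s)\n",
              nrow(x$genes), nrow(x$exons), length(unique(x$genes$chrom))))
  invisible(x)
}

# half-open 0-based intervals -> GRanges (1-based closed)
granges0 <- function(chrom, start, end) {
  GenomicRanges::GRanges(chrom, IRanges::IRanges(start + 1, end))
}

#' Strand-aware promoter windows around each TSS
#'
#' For '+' genes the window is \code{[TSS - upstream, TSS + downstream)};
#' for '-' genes it is mirrored around the TSS. Windows are clipped at 0
#' and, when chromosome sizes are supplied, at the chromosome end.
#'
#' @param annotation \code{gene_annotation} object.
#' @param upstream,downstream window extents in bp (defaults 2500 each,
#'   i.e. half a 5 kb bin on either side).
#' @param chrom_sizes optional named chromosome lengths for right-clipping.
#' @return data.frame with \code{gene_id}, \code{chrom}, \code{start},
#'   \code{end} (half-open 0-based).
#' @export
promoter_windows <- function(annotation, upstream = 2500, downstream = 2500,
                             chrom_sizes = NULL) {
  stop_if(upstream < 0 || downstream < 0, "promoter window must be >= 0 bp")
  g <- annotation$genes
  plus <- g$strand == "+"
  start <- ifelse(plus, g$tss - upstream, g$tss - downstream + 1)
  end <- ifelse(plus, g$tss + downstream, g$tss + upstream + 1)
  start <- pmax(start, 0)
  if (!is.null(chrom_sizes)) {
    lim <- chrom_sizes[g$chrom]
    end <- pmin(end, ifelse(is.na(lim), end, lim))
  }
  data.frame(gene_id = g$gene_id, chrom = g$chrom, start = start, end = end,
             stringsAsFactors = FALSE)
}

# Feature ranges per category, in precedence order.
annotation_features <- function(annotation, upstream = 2500,
                                downstream_prom = 2500, downstream_gene = 3000,
                                chrom_sizes = NULL) {
  g <- annotation$genes
  prom <- promoter_windows(annotation, upstream, downstream_prom, chrom_sizes)
  feats <- list(promoter = granges0(prom$chrom, prom$start, prom$end))
  for (utr in c("utr5", "utr3")) {
    nm <- if (utr == "utr5") "five_utr" else "three_utr"
    tab <- annotation[[utr]]
    feats[[nm]] <- if (is.null(tab) || nrow(tab) == 0L) {
      GenomicRanges::GRanges()
    } else granges0(tab$chrom, tab$start, tab$end)
  }
  ex <- annotation$exons
  feats$exon <- if (nrow(ex) > 0L) granges0(ex$chrom, ex$start, ex$end) else
    GenomicRanges::GRanges()
  bodies <- granges0(g$chrom, g$start, g$end)
  feats$intron <- GenomicRanges::setdiff(bodies, feats$exon)
  plus <- g$strand == "+"
  dstart <- ifelse(plus, g$end, pmax(g$start - downstream_gene, 0))
  dend <- ifelse(plus, g$end + downstream_gene, g$start)
  keep <- dend > dstart
  feats$downstream <- granges0(g$chrom[keep], dstart[keep], dend[keep])
  feats
}

#' Classify genomic anchors into functional categories
#'
#' Each anchor interval receives the category of the highest-precedence
#' feature it overlaps: promoter > five_utr > three_utr > exon > intron >
#' downstream (within 3 kb past the gene end) > distal_intergenic.
#' Anchors on chromosomes absent from the annotation fall through to
#' distal_intergenic with a warning.
#'
#' @param anchors data.frame with \code{chrom}, \code{start}, \code{end}
#'   (half-open 0-based).
#' @param annotation \code{gene_annotation} object.
#' @param upstream,downstream promoter window extents in bp.
#' @param chrom_sizes optional named chromosome lengths.
#' @return factor of categories, one per anchor, with the full level set.
#' @export
classify_anchors <- function(anchors, annotation, upstream = 2500,
                             downstream = 2500, chrom_sizes = NULL) {
  levels <- c("promoter", "five_utr", "three_utr", "exon", "intron",
              "downstream", "distal_intergenic")
  unknown <- !(anchors$chrom %in% unique(annotation$genes$chrom))
  if (any(unknown)) {
    warning(sprintf("%d anchor(s) on chromosomes absent from the annotation",
                    sum(unknown)))
  }
  feats <- annotation_features(annotation, upstream, downstream,
                               chrom_sizes = chrom_sizes)
  agr <- granges0(anchors$chrom, anchors$start, anchors$end)
  out <- rep("distal_intergenic", nrow(anchors))
  unassigned <- rep(TRUE, nrow(anchors))
  for (cat in names(feats)) {
    if (length(feats[[cat]]) == 0L) next
    # seqlevel mismatches (anchors on chromosomes without features) are
    # already reported above
    hit <- suppressWarnings(IRanges::overlapsAny(agr, feats[[cat]]))
    take <- unassigned & hit
    out[take] <- cat
    unassigned <- unassigned & !take
  }
  factor(out, levels = levels)
}

#' Classify a single anchor
#' @inheritParams classify_anchors
#' @param chrom,start,end anchor interval (half-open 0-based).
#' @return single category factor.
#' @export
classify_anchor <- function(chrom, start, end, annotation, ...) {
  classify_anchors(data.frame(chrom = chrom, start = start, end = end,
                              stringsAsFactors = FALSE), annotation, ...)
}

#' Classify loops into promoter-centric categories
#'
#' A loop with no promoter anchor is \code{non_promoter}. Otherwise the
#' category is read off the non-promoter anchor: both promoters gives
#' \code{promoter_promoter}; distal intergenic and intron map to their own
#' categories; UTR, exon and downstream collapse to \code{promoter_other}.
#'
#' @param loops \code{loops} table (see \code{\link{call_loops}}).
#' @param annotation \code{gene_annotation} object.
#' @param ... passed to \code{\link{classify_anchors}}.
#' @return factor with levels promoter_promoter, promoter_distal_intergenic,
#'   promoter_intron, promoter_other, non_promoter.
#' @export
classify_loops <- function(loops, annotation, ...) {
  a1 <- classify_anchors(
    data.frame(chrom = loops$chrom1, start = loops$start1, end = loops$end1,
               stringsAsFactors = FALSE), annotation, ...)
  a2 <- classify_anchors(
    data.frame(chrom = loops$chrom2, start = loops$start2, end = loops$end2,
               stringsAsFactors = FALSE), annotation, ...)
  p1 <- a1 == "promoter"
  p2 <- a2 == "promoter"
  other <- ifelse(p1, as.character(a2), as.character(a1))
  out <- ifelse(!p1 & !p2, "non_promoter",
         ifelse(p1 & p2, "promoter_promoter",
         ifelse(other == "distal_intergenic", "promoter_distal_intergenic",
         ifelse(other == "intron", "promoter_intron", "promoter_other"))))
  factor(out, levels = c("promoter_promoter", "promoter_distal_intergenic",
                         "promoter_intron", "promoter_other", "non_promoter"))
}

#' Genes whose promoter (or body) overlaps an anchor
#'
#' @param chrom,start,end anchor interval (half-open 0-based).
#' @param annotation \code{gene_annotation} object.
#' @param mode "promoter" (promoter-window overlap) or "body".
#' @param upstream,downstream promoter window extents in bp.
#' @return character vector of gene ids, sorted.
#' @export
genes_at_anchor <- function(chrom, start, end, annotation,
                            mode = c("promoter", "body"),
                            upstream = 2500, downstream = 2500) {
  mode <- match.arg(mode)
  hits <- anchor_gene_hits(
    data.frame(chrom = chrom, start = start, end = end,
               stringsAsFactors = FALSE),
    annotation, mode, upstream, downstream)
  sort(unique(hits$gene_id))
}

# Overlap join: which genes sit at which anchors. Returns a data.frame
# (anchor_idx, gene_id). In promoter mode a gene is "at" an anchor when its
# promoter window overlaps; in body mode when its body does. Body mode
# additionally includes promoter-window hits so it is a superset.
anchor_gene_hits <- function(anchors, annotation, mode = "promoter",
                             upstream = 2500, downstream = 2500) {
  g <- annotation$genes
  agr <- granges0(anchors$chrom, anchors$start, anchors$end)
  prom <- promoter_windows(annotation, upstream, downstream)
  pgr <- granges0(prom$chrom, prom$start, prom$end)
  ph <- GenomicRanges::findOverlaps(agr, pgr)
  hits <- data.frame(anchor_idx = S4Vectors::queryHits(ph),
                     gene_id = prom$gene_id[S4Vectors::subjectHits(ph)],
                     stringsAsFactors = FALSE)
  if (mode == "body") {
    bgr <- granges0(g$chrom, g$start, g$end)
    bh <- GenomicRanges::findOverlaps(agr, bgr)
    hits <- rbind(hits, data.frame(
      anchor_idx = S4Vectors::queryHits(bh),
      gene_id = g$gene_id[S4Vectors::subjectHits(bh)],
      stringsAsFactors = FALSE))
  }
  unique(hits)
}
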