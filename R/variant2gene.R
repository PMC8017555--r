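#' Map credible variants to target genes through loops
#'
#' A credible variant lying in one anchor of a significant loop is linked to
#' every gene annotated at the other anchor; the link distance is the
#' absolute difference between the variant position and the target TSS.
#' Links are deduplicated on (variant, gene, loop).
#'
#' @param cvs data.frame of credible variants with \code{variant_id},
#'   \code{chrom}, \code{pos} (1-based point), \code{locus_id} and
#'   optionally \code{pp} (see \code{\link{credible_variants}}).
#' @param loops \code{loops} table.
#' @param annotation \code{gene_annotation} object.
#' @param mode how genes are assigned to anchors: "promoter" or "body"
#'   (see \code{\link{genes_at_anchor}}).
#' @param upstream,downstream promoter window extents in bp.
#' @return data.frame of class \code{v2g_links} with \code{variant_id},
#'   \code{locus_id}, \code{gene_id}, \code{loop_id}
#'   (chrom:start1-start2), \code{source}, \code{distance} (bp).
#' @export
map_cvs_to_targets <- function(cvs, loops, annotation,
                               mode = c("promoter", "body"),
                               upstream = 2500, downstream = 2500) {
  mode <- match.arg(mode)
  empty <- data.frame(variant_id = character(), locus_id = character(),
                      gene_id = character(), loop_id = character(),
                      source = character(), distance = numeric(),
                      stringsAsFactors = FALSE)
  if (nrow(cvs) == 0L || nrow(loops) == 0L) {
    class(empty) <- c("v2g_links", "data.frame")
    return(empty)
  }
  vgr <- granges0(cvs$chrom, cvs$pos - 1, cvs$pos)  # 1 bp point
  loop_id <- paste0(loops$chrom1, ":", loops$start1, "-", loops$start2)
  link_side <- function(anchor_chrom, anchor_start, anchor_end,
                        other_chrom, other_start, other_end) {
    agr <- granges0(anchor_chrom, anchor_start, anchor_end)
    vh <- GenomicRanges::findOverlaps(vgr, agr)
    if (length(vh) == 0L) return(NULL)
    gh <- anchor_gene_hits(
      data.frame(chrom = other_chrom, start = other_start, end = other_end,
                 stringsAsFactors = FALSE),
      annotation, mode, upstream, downstream)
    if (nrow(gh) == 0L) return(NULL)
    li <- S4Vectors::subjectHits(vh)  # loop index per variant hit
    vi <- S4Vectors::queryHits(vh)
    rows <- merge(data.frame(loop = li, variant = vi),
                  data.frame(loop = gh$anchor_idx, gene_id = gh$gene_id),
                  by = "loop")
    if (nrow(rows) == 0L) return(NULL)
    tss <- annotation$genes$tss[match(rows$gene_id,
                                      annotation$genes$gene_id)]
    data.frame(
      variant_id = cvs$variant_id[rows$variant],
      locus_id = if ("locus_id" %in% names(cvs))
        cvs$locus_id[rows$variant] else NA_character_,
      gene_id = rows$gene_id,
      loop_id = loop_id[rows$loop],
      source = loops$source[rows$loop],
      distance = abs(cvs$pos[rows$variant] - tss),
      stringsAsFactors = FALSE
    )
  }
  out <- rbind(
    link_side(loops$chrom1, loops$start1, loops$end1,
              loops$chrom2, loops$start2, loops$end2),
    link_side(loops$chrom2, loops$start2, loops$end2,
              loops$chrom1, loops$start1, loops$end1)
  )
  if (is.null(out)) out <- empty
  out <- out[!duplicated(out[, c("variant_id", "gene_id", "loop_id")]), ,
             drop = FALSE]
  out <- out[order(out$variant_id, out$gene_id, out$loop_id), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("v2g_links", "data.frame")
  out
}

#' Filter variants (or links) by open chromatin
#'
#' Keeps variants whose position falls inside an accessibility peak in every
#' peak set (\code{require_all = TRUE}, the default) or in at least one set.
#' Output rows are always a subset of the input.
#'
#' @param x data.frame with \code{chrom} and \code{pos} columns (credible
#'   variants or v2g links carrying positions).
#' @param peak_sets list of peak tables, each a data.frame with
#'   \code{chrom}, \code{start}, \code{end} (half-open 0-based), or a
#'   \code{GRanges}.
#' @param require_all if TRUE a variant must be covered in every set.
#' @return filtered subset of \code{x}.
#' @export
filter_by_open_chromatin <- function(x, peak_sets, require_all = TRUE) {
  stop_if(length(peak_sets) == 0L, "at least one peak set is required")
  if (nrow(x) == 0L) return(x)
  vgr <- granges0(x$chrom, x$pos - 1, x$pos)
  in_set <- vapply(peak_sets, function(p) {
    if (!methods::is(p, "GRanges")) {
      if (nrow(p) == 0L) {
        if (require_all) warning("empty peak set with require_all = TRUE")
        return(rep(FALSE, nrow(x)))
      }
      p <- granges0(p$chrom, p$start, p$end)
    } else if (length(p) == 0L) {
      if (require_all) warning("empty peak set with require_all = TRUE")
      return(rep(FALSE, nrow(x)))
    }
    IRanges::overlapsAny(vgr, p)
  }, logical(nrow(x)))
  if (nrow(x) == 1L) in_set <- matrix(in_set, nrow = 1)
  keep <- if (require_all) rowSums(!in_set) == 0 else rowSums(in_set) > 0
  x[keep, , drop = FALSE]
}

#' Proximal target gene for each variant
#'
#' Assigns each variant the gene whose body contains it; otherwise the gene
#' with the nearest TSS. Ties are broken by the smaller genomic coordinate,
#' then gene id. Variants on chromosomes without genes get no assignment
#' and are reported via a message.
#'
#' @param cvs data.frame with \code{variant_id}, \code{chrom}, \code{pos}.
#' @param annotation \code{gene_annotation} object.
#' @return data.frame with \code{variant_id}, \code{gene_id},
#'   \code{distance} (0 when inside the body).
#' @export
proximal_targets <- function(cvs, annotation) {
  g <- annotation$genes
  stop_if(nrow(g) == 0L, "annotation contains no genes")
  out <- data.frame(variant_id = cvs$variant_id,
                    gene_id = NA_character_,
                    distance = NA_real_, stringsAsFactors = FALSE)
  for (i in seq_len(nrow(cvs))) {
    same <- which(g$chrom == cvs$chrom[i])
    if (length(same) == 0L) next
    p0 <- cvs$pos[i] - 1  # 0-based point
    inside <- same[g$start[same] <= p0 & p0 < g$end[same]]
    if (length(inside) > 0L) {
      pick <- inside[order(g$start[inside], g$gene_id[inside])][1]
      out$gene_id[i] <- g$gene_id[pick]
      out$distance[i] <- 0
    } else {
      d <- abs(cvs$pos[i] - g$tss[same])
      best <- same[d == min(d)]
      pick <- best[order(g$tss[best], g$gene_id[best])][1]
      out$gene_id[i] <- g$gene_id[pick]
      out$distance[i] <- min(d)
    }
  }
  if (anyNA(out$gene_id)) {
    message(sprintf("%d variant(s) on gene-free chromosomes left unassigned",
                    sum(is.na(out$gene_id))))
  }
  out
}

#' Compare HiChIP, eQTL and proximal target-gene sets
#'
#' Exact set algebra over case-normalized gene symbols, plus the fold
#' ratios of the HiChIP set size to the other two, reported to one decimal.
#'
#' @param hichip,eqtl,proximal character vectors of gene symbols.
#' @return list of class \code{target_set_comparison} with set sizes,
#'   pairwise overlaps, the triple overlap, and fold ratios (NA when the
#'   HiChIP set is empty or a denominator is zero).
#' @export
compare_target_sets <- function(hichip, eqtl, proximal) {
  norm <- function(x) unique(toupper(x))
  h <- norm(hichip); e <- norm(eqtl); p <- norm(proximal)
  fold <- function(a, b) {
    if (length(a) == 0L || length(b) == 0L) return(NA_real_)
    round(length(a) / length(b), 1)
  }
  structure(list(
    n_hichip = length(h), n_eqtl = length(e), n_proximal = length(p),
    overlap_hichip_eqtl = length(intersect(h, e)),
    overlap_hichip_proximal = length(intersect(h, p)),
    overlap_eqtl_proximal = length(intersect(e, p)),
    triple_overlap = length(Reduce(intersect, list(h, e, p))),
    fold_vs_eqtl = fold(h, e),
    fold_vs_proximal = fold(h, p),
    genes_in_all_three = sort(Reduce(intersect, list(h, e, p)))
  ), class = "target_set_comparison")
}

#' @export
print.target_set_comparison <- function(x, ...) {
  cat(sprintf("Targets: HiChIP %d, eQTL %d, proximal %d\n",
              x$n_hichip, x$n_eqtl, x$n_proximal))
  cat(sprintf("Overlaps: HiChIP*eQTL %d, HiChIP*proximal %d, all three %d\n",
              x$overlap_hichip_eqtl, x$overlap_hichip_proximal,
              x$triple_overlap))
  cat(sprintf("Fold: %.1fx vs eQTL, %.1fx vs proximal\n",
              x$fold_vs_eqtl, x$fold_vs_proximal))
  invisible(x)
}

#' Per-locus summary of variant-to-gene links
#'
#' Tabulates, per locus, the number of distinct credible variants appearing
#' in links and the sorted list of distinct target genes — the layout of a
#' per-locus target-gene table — together with grand totals (distinct CVs
#' and distinct genes across all loci) and per-source median and mean link
#' distances.
#'
#' @param links \code{v2g_links} table (or any data.frame with
#'   \code{variant_id}, \code{locus_id}, \code{gene_id}, and optionally
#'   \code{source} and \code{distance}).
#' @return list of class \code{locus_summary} with \code{per_locus}
#'   (data.frame: locus_id, cv_count, n_genes, genes), \code{total_cvs},
#'   \code{total_genes}, and \code{distance_by_source} (data.frame:
#'   source, median_bp, mean_bp).
#' @export
summarize_loci <- function(links) {
  if (nrow(links) == 0L) {
    return(structure(list(
      per_locus = data.frame(locus_id = character(), cv_count = integer(),
                             n_genes = integer(), genes = character(),
                             stringsAsFactors = FALSE),
      total_cvs = 0L, total_genes = 0L,
      distance_by_source = data.frame(source = character(),
                                      median_bp = numeric(),
                                      mean_bp = numeric())
    ), class = "locus_summary"))
  }
  per <- lapply(split(links, links$locus_id), function(sub) {
    data.frame(
      locus_id = sub$locus_id[1],
      cv_count = length(unique(sub$variant_id)),
      n_genes = length(unique(sub$gene_id)),
      genes = paste(sort(unique(sub$gene_id)), collapse = ","),
      stringsAsFactors = FALSE
    )
  })
  per <- do.call(rbind, per)
  rownames(per) <- NULL
  dist_tab <- if (all(c("source", "distance") %in% names(links))) {
    d <- lapply(split(links$distance, links$source), function(v)
      c(median = stats::median(v), mean = mean(v)))
    data.frame(source = names(d),
               median_bp = vapply(d, `[[`, 0, "median"),
               mean_bp = vapply(d, `[[`, 0, "mean"),
               row.names = NULL, stringsAsFactors = FALSE)
  } else {
    data.frame(source = character(), median_bp = numeric(),
               mean_bp = numeric())
  }
  structure(list(
    per_locus = per,
    total_cvs = length(unique(links$variant_id)),
    total_genes = length(unique(links$gene_id)),
    distance_by_source = dist_tab
  ), class = "locus_summary")
}

#' @export
print.locus_summary <- function(x, ...) {
  cat(sprintf("Locus summary: %d loci, %d distinct CVs, %d distinct genes\n",
              nrow(x$per_locus), x$total_cvs, x$total_genes))
  invisible(x)
}

#' Load the bundled published per-locus target-gene table
#'
#' The printed per-locus table of an epithelial ovarian cancer HiChIP
#' study: 14 risk loci with their credible-variant counts and HiChIP
#' target gene symbols (asterisks in the source marking differentially
#' expressed genes are split into a flag).
#'
#' @param path optional override of the bundled TSV.
#' @return data.frame with \code{locus}, \code{cv_count},
#'   \code{target_genes} (list column of clean symbols), \code{de_genes}
#'   (list column of the flagged subset).
#' @export
published_locus_table <- function(path = system.file(
    "extdata", "eoc_locus_table.tsv", package = "hichipTargets")) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  raw <- strsplit(df$target_genes, ",", fixed = TRUE)
  df$target_genes <- lapply(raw, function(g) sub("\\*$", "", g))
  df$de_genes <- lapply(raw, function(g)
    sub("\\*$", "", g[grepl("\\*$", g)]))
  df
}

#' Expand a per-locus count table into a minimal link table
#'
#' Builds one synthetic link row per (variant, gene) so that each locus
#' has exactly its printed number of distinct credible variants and its
#' printed gene list — the input shape the locus-summary stage expects.
#' Used to check that summing printed per-locus counts through
#' \code{\link{summarize_loci}} reproduces printed grand totals.
#'
#' @param tab data.frame from \code{\link{published_locus_table}} (or any
#'   table with \code{locus}, \code{cv_count}, \code{target_genes}).
#' @return data.frame with \code{variant_id}, \code{locus_id},
#'   \code{gene_id}.
#' @export
expand_locus_table <- function(tab) {
  out <- lapply(seq_len(nrow(tab)), function(i) {
    k <- tab$cv_count[i]
    genes <- unlist(tab$target_genes[i])
    vars <- sprintf("%s_cv%03d", tab$locus[i], seq_len(k))
    rbind(
      # every variant linked once (cycling over genes) ...
      data.frame(variant_id = vars, locus_id = tab$locus[i],
                 gene_id = genes[(seq_len(k) - 1L) %% length(genes) + 1L],
                 stringsAsFactors = FALSE),
      # ... and every gene linked at least once
      data.frame(variant_id = vars[1], locus_id = tab$locus[i],
                 gene_id = genes, stringsAsFactors = FALSE)
    )
  })
  out <- do.call(rbind, out)
  out[!duplicated(out), , drop = FALSE]
}
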