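#' @name pipeline_io
#' @title Readers and writers for the pipeline's text formats
#' @description
#' All on-disk coordinates follow the named standard: GTF and
#' allValidPairs positions are 1-based inclusive, BED/BEDPE are half-open
#' 0-based. Internally the package is half-open 0-based except for
#' variant positions, which are 1-based points as in summary-statistics
#' files. Every writer/reader pair round-trips losslessly; malformed
#' lines raise errors naming the offending line.
NULL

read_checked <- function(path, n_cols, what) {
  stop_if(!file.exists(path), "%s file not found: %s", what, path)
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
  stop_if(length(lines) == 0L, "%s file is empty: %s", what, path)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) < n_cols)
  stop_if(length(bad) > 0, "%s line %d: expected %d tab-separated fields",
          what, bad[1], n_cols)
  parts
}

#' Write / read GWAS summary statistics (TSV with header)
#' @param records data.frame with variant_id, chrom, pos, beta, se, locus_id.
#' @param path file path.
#' @rdname pipeline_io
#' @export
write_sumstats <- function(records, path) {
  utils::write.table(records, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname pipeline_io
#' @export
read_sumstats <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  req <- c("variant_id", "chrom", "pos", "beta", "se", "locus_id")
  miss <- setdiff(req, names(df))
  stop_if(length(miss) > 0, "summary stats missing columns: %s",
          paste(miss, collapse = ", "))
  df$chrom <- as.character(df$chrom)
  df$variant_id <- as.character(df$variant_id)
  df
}

#' Write / read HiC-Pro-style allValidPairs records (no header; 1-based)
#' @param pairs data.frame of valid pairs.
#' @rdname pipeline_io
#' @export
write_valid_pairs <- function(pairs, path) {
  utils::write.table(
    pairs[, c("read_id", "chrom1", "pos1", "strand1",
              "chrom2", "pos2", "strand2")],
    path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname pipeline_io
#' @export
read_valid_pairs <- function(path) {
  parts <- read_checked(path, 7L, "allValidPairs")
  get <- function(i) vapply(parts, `[`, "", i)
  pos1 <- suppressWarnings(as.integer(get(3)))
  pos2 <- suppressWarnings(as.integer(get(6)))
  bad <- which(is.na(pos1) | is.na(pos2) | pos1 < 1 | pos2 < 1)
  stop_if(length(bad) > 0, "allValidPairs line %d: invalid position", bad[1])
  data.frame(read_id = get(1), chrom1 = get(2), pos1 = pos1,
             strand1 = get(4), chrom2 = get(5), pos2 = pos2,
             strand2 = get(7), stringsAsFactors = FALSE)
}

#' Write / read binned contacts as a bins BED plus sparse triplet matrix
#'
#' Bins are numbered 1..n in the BED name column (HiC-Pro convention);
#' the matrix file holds (bin_a, bin_b, count) triplets.
#' @param binpairs \code{bin_pairs} table.
#' @param chrom_sizes named chromosome lengths.
#' @param bins_path,matrix_path output paths.
#' @rdname pipeline_io
#' @export
write_contact_matrix <- function(binpairs, chrom_sizes, bins_path,
                                 matrix_path) {
  res <- attr(binpairs, "resolution")
  stop_if(is.null(res), "binpairs must carry a resolution attribute")
  grid <- do.call(rbind, lapply(names(chrom_sizes), function(ch) {
    n_bins <- as.integer(ceiling(chrom_sizes[[ch]] / res))
    data.frame(chrom = ch, bin = 0:(n_bins - 1L), stringsAsFactors = FALSE)
  }))
  grid$id <- seq_len(nrow(grid))
  bed <- data.frame(grid$chrom, grid$bin * res,
                    pmin((grid$bin + 1) * res, chrom_sizes[grid$chrom]),
                    grid$id)
  utils::write.table(bed, bins_path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  key <- paste(grid$chrom, grid$bin)
  ida <- grid$id[match(paste(binpairs$chrom, binpairs$bin_i), key)]
  idb <- grid$id[match(paste(binpairs$chrom, binpairs$bin_j), key)]
  stop_if(anyNA(ida) || anyNA(idb), "bin beyond chromosome end")
  utils::write.table(data.frame(ida, idb, binpairs$count), matrix_path,
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(c(bins_path, matrix_path))
}

#' @rdname pipeline_io
#' @export
read_contact_matrix <- function(bins_path, matrix_path) {
  bparts <- read_checked(bins_path, 4L, "bins BED")
  bchrom <- vapply(bparts, `[`, "", 1)
  bstart <- as.numeric(vapply(bparts, `[`, "", 2))
  bend <- as.numeric(vapply(bparts, `[`, "", 3))
  bid <- as.integer(vapply(bparts, `[`, "", 4))
  bad <- which(is.na(bstart) | is.na(bend) | bstart >= bend)
  stop_if(length(bad) > 0, "bins BED line %d: invalid interval", bad[1])
  res <- max(bend - bstart)
  mparts <- read_checked(matrix_path, 3L, "triplet matrix")
  ida <- as.integer(vapply(mparts, `[`, "", 1))
  idb <- as.integer(vapply(mparts, `[`, "", 2))
  cnt <- suppressWarnings(as.numeric(vapply(mparts, `[`, "", 3)))
  bad <- which(is.na(cnt) | cnt < 0 | cnt != round(cnt))
  stop_if(length(bad) > 0, "triplet matrix line %d: non-integer count",
          bad[1])
  a <- match(ida, bid); b <- match(idb, bid)
  stop_if(anyNA(a) || anyNA(b), "triplet matrix references unknown bin id")
  stop_if(any(bchrom[a] != bchrom[b]),
          "trans triplets are not supported in the cis matrix")
  bin_a <- as.integer(bstart[a] / res)
  bin_b <- as.integer(bstart[b] / res)
  out <- data.frame(chrom = bchrom[a],
                    bin_i = pmin(bin_a, bin_b), bin_j = pmax(bin_a, bin_b),
                    count = as.integer(cnt), stringsAsFactors = FALSE)
  out$distance <- (out$bin_j - out$bin_i) * res
  out <- out[order(out$chrom, out$bin_i, out$bin_j), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "resolution") <- res
  attr(out, "chrom_sizes") <- tapply(bend, bchrom, max)
  class(out) <- c("bin_pairs", "data.frame")
  out
}

#' Write / read gene annotation as GTF (gene and exon features)
#' @param annotation \code{gene_annotation}.
#' @rdname pipeline_io
#' @export
write_gtf <- function(annotation, path) {
  g <- annotation$genes
  ex <- annotation$exons
  attr_str <- function(id, sym) {
    sprintf('gene_id "%s"; gene_name "%s";', id, sym)
  }
  gene_lines <- sprintf("%s\tsynthetic\tgene\t%d\t%d\t.\t%s\t.\t%s",
                        g$chrom, g$start + 1L, g$end, g$strand,
                        attr_str(g$gene_id, g$symbol))
  m <- match(ex$gene_id, g$gene_id)
  exon_lines <- sprintf("%s\tsynthetic\texon\t%d\t%d\t.\t%s\t.\t%s",
                        ex$chrom, ex$start + 1L, ex$end, g$strand[m],
                        attr_str(ex$gene_id, g$symbol[m]))
  writeLines(c(gene_lines, exon_lines), path)
  invisible(path)
}

#' @rdname pipeline_io
#' @export
read_gtf <- function(path) {
  gr <- rtracklayer::import(path, format = "gtf")
  df <- as.data.frame(gr)
  stop_if(!all(c("type", "gene_id") %in% names(df)),
          "GTF lacks type/gene_id attributes")
  gn <- df[df$type == "gene", , drop = FALSE]
  ex <- df[df$type == "exon", , drop = FALSE]
  stop_if(nrow(gn) == 0L, "GTF contains no gene features")
  genes <- data.frame(
    gene_id = gn$gene_id,
    symbol = if ("gene_name" %in% names(gn)) gn$gene_name else gn$gene_id,
    chrom = as.character(gn$seqnames),
    strand = as.character(gn$strand),
    start = gn$start - 1L,
    end = gn$end,
    stringsAsFactors = FALSE
  )
  exons <- data.frame(
    gene_id = ex$gene_id,
    chrom = as.character(ex$seqnames),
    start = ex$start - 1L,
    end = ex$end,
    stringsAsFactors = FALSE
  )
  ord <- order(genes$chrom, genes$start)
  gene_annotation(genes[ord, , drop = FALSE], exons)
}

#' Write / read BED3 interval files (e.g. accessibility peaks)
#' @param peaks data.frame with chrom, start, end (half-open 0-based).
#' @rdname pipeline_io
#' @export
write_peaks <- function(peaks, path) {
  utils::write.table(peaks[, c("chrom", "start", "end")], path, sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname pipeline_io
#' @export
read_peaks <- function(path) {
  parts <- read_checked(path, 3L, "BED")
  chrom <- vapply(parts, `[`, "", 1)
  start <- suppressWarnings(as.numeric(vapply(parts, `[`, "", 2)))
  end <- suppressWarnings(as.numeric(vapply(parts, `[`, "", 3)))
  bad <- which(is.na(start) | is.na(end) | start < 0 | start >= end)
  stop_if(length(bad) > 0,
          "BED line %d: start must be a number in [0, end)", bad[1])
  data.frame(chrom = chrom, start = start, end = end,
             stringsAsFactors = FALSE)
}

#' Write / read loops as 10-column BEDPE (plus statistic columns)
#'
#' Standard BEDPE columns chrom1 start1 end1 chrom2 start2 end2 name score
#' strand1 strand2 (q-value in score, '.' strands), followed by count, mu,
#' p_value, q_value, distance, source so the round-trip is lossless.
#' @param loops \code{loops} table.
#' @rdname pipeline_io
#' @export
write_loops_bedpe <- function(loops, path) {
  res <- attr(loops, "resolution")
  df <- data.frame(
    loops$chrom1, loops$start1, loops$end1,
    loops$chrom2, loops$start2, loops$end2,
    name = sprintf("loop_%d", seq_len(nrow(loops))),
    score = loops$q_value, s1 = ".", s2 = ".",
    count = loops$count, mu = loops$mu, p_value = loops$p_value,
    q_value = loops$q_value, distance = loops$distance,
    source = loops$source
  )
  header <- sprintf("#resolution=%d", as.integer(res))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(header, con)
  utils::write.table(df, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname pipeline_io
#' @export
read_loops_bedpe <- function(path) {
  first <- readLines(path, n = 1L)
  res <- if (startsWith(first, "#resolution=")) {
    as.integer(sub("#resolution=", "", first))
  } else NA_integer_
  parts <- read_checked(path, 16L, "BEDPE")
  get <- function(i) vapply(parts, `[`, "", i)
  num <- function(i) as.numeric(get(i))
  s1 <- num(2); e1 <- num(3); s2 <- num(5); e2 <- num(6)
  bad <- which(is.na(s1) | is.na(s2) | s1 >= e1 | s2 >= e2)
  stop_if(length(bad) > 0, "BEDPE line %d: invalid interval", bad[1])
  out <- data.frame(
    chrom1 = get(1), start1 = s1, end1 = e1,
    chrom2 = get(4), start2 = s2, end2 = e2,
    count = as.integer(num(11)), mu = num(12), p_value = num(13),
    q_value = num(14), distance = num(15), source = get(16),
    stringsAsFactors = FALSE
  )
  attr(out, "resolution") <- res
  class(out) <- c("loops", "data.frame")
  out
}

#' Write loops as WashU longrange text
#'
#' One record per loop direction (two lines per loop):
#' \code{chr<TAB>start<TAB>end<TAB>chr2:start2-end2,score} with
#' score = -log10(q) capped at 300. The output is plain text ready for
#' bgzip/tabix post-processing.
#' @rdname pipeline_io
#' @export
write_longrange <- function(loops, path) {
  score <- pmin(round(-log10(pmax(loops$q_value, 1e-300)), 4), 300)
  fwd <- sprintf("%s\t%d\t%d\t%s:%d-%d,%g",
                 loops$chrom1, as.integer(loops$start1),
                 as.integer(loops$end1), loops$chrom2,
                 as.integer(loops$start2), as.integer(loops$end2), score)
  rev <- sprintf("%s\t%d\t%d\t%s:%d-%d,%g",
                 loops$chrom2, as.integer(loops$start2),
                 as.integer(loops$end2), loops$chrom1,
                 as.integer(loops$start1), as.integer(loops$end1), score)
  out <- as.vector(rbind(fwd, rev))
  writeLines(out, path)
  invisible(path)
}

#' Write / read variant-to-gene links (TSV with header)
#' @param links \code{v2g_links} table.
#' @rdname pipeline_io
#' @export
write_links <- function(links, path) {
  utils::write.table(links, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname pipeline_io
#' @export
read_links <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  class(df) <- c("v2g_links", "data.frame")
  df
}

#' Write per-locus credible-set tables (TSV with header)
#' @param sets \code{credible_set} or list of them.
#' @rdname pipeline_io
#' @export
write_credible_sets <- function(sets, path) {
  if (inherits(sets, "credible_set")) sets <- list(sets)
  tabs <- lapply(sets, function(cs) {
    cbind(locus_id = cs$locus_id, cs$table)
  })
  utils::write.table(do.call(rbind, tabs), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write / read an expression matrix and its group labels
#' @param expr genes x samples matrix; \code{labels} factor per sample.
#' @rdname pipeline_io
#' @export
write_expression <- function(expr, labels, expr_path, labels_path) {
  df <- data.frame(gene_id = rownames(expr), expr, check.names = FALSE)
  utils::write.table(df, expr_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(
    data.frame(sample = colnames(expr), label = as.character(labels)),
    labels_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(expr_path, labels_path))
}

#' @rdname pipeline_io
#' @export
read_expression <- function(expr_path, labels_path) {
  df <- utils::read.table(expr_path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE)
  expr <- as.matrix(df[, -1, drop = FALSE])
  rownames(expr) <- df$gene_id
  lab <- utils::read.table(labels_path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  stop_if(!identical(lab$sample, colnames(expr)),
          "label file samples do not match expression columns")
  list(expr = expr, labels = factor(lab$label))
}

#' Read a one-column gene list (optionally with header 'gene')
#' @rdname pipeline_io
#' @export
read_gene_list <- function(path) {
  x <- readLines(path)
  x <- x[nzchar(x)]
  if (length(x) > 0 && tolower(x[1]) %in% c("gene", "gene_id", "symbol")) {
    x <- x[-1]
  }
  x
}

#' Read and validate a pipeline configuration YAML
#'
#' Known keys: resolution, d_min, d_max, fdr, level, prior_w, promoter_up,
#' promoter_down, peak_filter_mode, seed, plus input paths under
#' \code{paths}. Unknown keys are rejected; numeric fields are validated.
#' @param path YAML file.
#' @rdname pipeline_io
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  defaults <- list(resolution = 5000, d_min = 20000, d_max = 2e6,
                   fdr = 0.01, level = 0.99, prior_w = 0.04,
                   promoter_up = 2500, promoter_down = 2500,
                   peak_filter_mode = "all", seed = 1, paths = list())
  unknown <- setdiff(names(raw), names(defaults))
  stop_if(length(unknown) > 0, "unknown config key(s): %s",
          paste(unknown, collapse = ", "))
  cfg <- utils::modifyList(defaults, raw)
  num <- c("resolution", "d_min", "d_max", "fdr", "level", "prior_w",
           "promoter_up", "promoter_down", "seed")
  for (k in num) {
    stop_if(!is.numeric(cfg[[k]]) || length(cfg[[k]]) != 1L,
            "config field '%s' must be a single number", k)
  }
  stop_if(cfg$fdr <= 0 || cfg$fdr > 1, "fdr must be in (0, 1]")
  stop_if(cfg$level <= 0 || cfg$level > 1, "level must be in (0, 1]")
  stop_if(!cfg$peak_filter_mode %in% c("all", "any"),
          "peak_filter_mode must be 'all' or 'any'")
  cfg
}
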