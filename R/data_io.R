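# Readers and writers for marker maps, segmented copy-number cohorts (SEG),
# gene annotation (BED) and called-region tables.
#
# Coordinate conventions: SEG files are 1-based inclusive on disk (Broad
# dialect); everything internal, and BED, is 0-based half-open. Probes are
# indexed by `genome_order` (0-based) over chromosomes concatenated in a fixed
# declared order. A "boundary" b (1 <= b <= P-1) separates the probes with
# genome_order b-1 and b.

#' Karyotype-style chromosome ordering
#'
#' Orders chromosome names numerically (with or without a "chr" prefix),
#' followed by X, Y and M/MT, then any remaining names alphabetically.
#'
#' @param chroms character vector of chromosome names (duplicates allowed).
#' @return the unique names in karyotype order.
#' @export
karyotype_order <- function(chroms) {
  u <- unique(as.character(chroms))
  stripped <- sub("^chr", "", u)
  num <- suppressWarnings(as.numeric(stripped))
  rank <- ifelse(!is.na(num), num,
                 ifelse(stripped == "X", 1e6,
                 ifelse(stripped == "Y", 1e6 + 1,
                 ifelse(stripped %in% c("M", "MT"), 1e6 + 2, NA))))
  known <- u[!is.na(rank)][order(rank[!is.na(rank)])]
  c(known, sort(u[is.na(rank)]))
}

new_probe_map <- function(probe_id, chrom, pos, chrom_order) {
  chrom <- as.character(chrom)
  unknown <- setdiff(chrom, chrom_order)
  if (length(unknown) > 0)
    stop("unknown chromosome(s) in marker table: ", paste(unknown, collapse = ", "))
  o <- order(match(chrom, chrom_order), pos)
  pm <- data.frame(probe_id = as.character(probe_id)[o], chrom = chrom[o],
                   pos = as.numeric(pos)[o], stringsAsFactors = FALSE)
  dup <- duplicated(pm[, c("chrom", "pos")])
  if (any(dup))
    stop("duplicate probe position(s): ", paste(utils::head(
      paste0(pm$chrom[dup], ":", pm$pos[dup]), 3), collapse = ", "))
  if (nrow(pm) < 2) stop("a probe map needs at least 2 probes")
  pm$genome_order <- seq_len(nrow(pm)) - 1L
  ord <- chrom_order[chrom_order %in% pm$chrom]
  attr(pm, "chrom_order") <- ord
  attr(pm, "chrom_starts") <- c(0L, cumsum(as.integer(
    table(factor(pm$chrom, levels = ord)))))
  class(pm) <- c("probe_map", "data.frame")
  pm
}

#' Read a marker-position table
#'
#' Tab-separated file with columns `probe_id`, `chrom`, `pos` (0-based base
#' pairs). Markers are sorted by the declared chromosome order, then position;
#' the resulting row index minus one is the probe's `genome_order`.
#'
#' @param path file path.
#' @param chrom_order character vector declaring the chromosome concatenation
#'   order; default is the karyotype order of the names present.
#' @return a `probe_map` data frame (`probe_id`, `chrom`, `pos`, `genome_order`).
#' @export
read_markers <- function(path, chrom_order = NULL) {
  x <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE)
  if (ncol(x) < 3) stop("marker table needs columns probe_id, chrom, pos")
  names(x)[1:3] <- c("probe_id", "chrom", "pos")
  if (is.null(chrom_order)) chrom_order <- karyotype_order(x$chrom)
  new_probe_map(x$probe_id, x$chrom, x$pos, chrom_order)
}

# 0-based start index of each chromosome in genome order, plus P; input to the
# compiled routines. Cached on the probe map at construction.
chrom_starts <- function(probes) {
  cs <- attr(probes, "chrom_starts")
  if (!is.null(cs)) return(cs)
  n <- table(factor(probes$chrom, levels = attr(probes, "chrom_order")))
  c(0L, cumsum(as.integer(n)))
}

new_cn_matrix <- function(values, probes, sign_mode = "raw") {
  stopifnot(is.matrix(values), ncol(values) == nrow(probes))
  if (anyNA(values)) stop("copy-number matrix contains missing values")
  structure(list(sample_ids = rownames(values), values = values,
                 probes = probes, sign_mode = sign_mode),
            class = "cn_matrix")
}

#' @export
print.cn_matrix <- function(x, ...) {
  cat(sprintf("Copy-number matrix: %d sample(s) x %d probes (%s), %d chromosome(s)\n",
              nrow(x$values), ncol(x$values), x$sign_mode,
              length(attr(x$probes, "chrom_order"))))
  invisible(x)
}

#' Read a segmented copy-number cohort (SEG)
#'
#' Broad-dialect SEG: columns sample, chrom, start, end, n_probes, seg_mean,
#' 1-based inclusive coordinates. Every probe of `probes` must be covered by
#' exactly one segment per sample; each probe then carries the `seg_mean` of
#' its covering segment.
#'
#' @param path SEG file path.
#' @param probes a `probe_map` from [read_markers()].
#' @param impute if `TRUE`, probes covered by no segment take the value of the
#'   nearest covered probe on the same chromosome instead of raising an error.
#' @param clip optional positive number c: log2 ratios are clipped to
#'   `[-c, c]`. No capping by default.
#' @return a `cn_matrix` with `sign_mode = "raw"`.
#' @export
read_seg <- function(path, probes, impute = FALSE, clip = NULL) {
  x <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE)
  if (ncol(x) < 6) stop("SEG file needs 6 columns: sample, chrom, start, end, n_probes, seg_mean")
  names(x)[1:6] <- c("sample", "chrom", "start", "end", "n_probes", "seg_mean")
  x$chrom <- as.character(x$chrom)
  samples <- unique(x$sample)
  P <- nrow(probes)
  vals <- matrix(NA_real_, length(samples), P,
                 dimnames = list(samples, probes$probe_id))
  for (s in samples) {
    xs <- x[x$sample == s, , drop = FALSE]
    for (ch in unique(xs$chrom)) {
      seg <- xs[xs$chrom == ch, , drop = FALSE]
      seg <- seg[order(seg$start), , drop = FALSE]
      if (nrow(seg) > 1 && any(seg$start[-1] <= seg$end[-nrow(seg)]))
        stop("overlapping segments for sample ", s, " on ", ch)
      idx <- which(probes$chrom == ch)
      if (length(idx) == 0) next
      pos <- probes$pos[idx]                        # 0-based
      k <- findInterval(pos, seg$start - 1)         # segment covering pos, if any
      covered <- k >= 1 & pos < seg$end[pmax(k, 1)] # 0-based half-open [start-1, end)
      vals[s, idx[covered]] <- seg$seg_mean[k[covered]]
    }
  }
  if (anyNA(vals)) {
    if (!impute) {
      miss <- which(is.na(vals), arr.ind = TRUE)[1, ]
      stop("probe ", probes$probe_id[miss[2]], " not covered by any segment for sample ",
           samples[miss[1]], " (set impute = TRUE to fill from the nearest probe)")
    }
    cs <- chrom_starts(probes)
    for (s in seq_along(samples)) {
      for (c in seq_len(length(cs) - 1)) {
        idx <- (cs[c] + 1):cs[c + 1]
        v <- vals[s, idx]
        if (all(is.na(v)))
          stop("no covered probe on chromosome ", probes$chrom[idx[1]],
               " for sample ", samples[s])
        ok <- which(!is.na(v))
        fill <- vapply(which(is.na(v)), function(i) ok[which.min(abs(ok - i))], 1L)
        v[is.na(v)] <- v[fill]
        vals[s, idx] <- v
      }
    }
  }
  if (!is.null(clip)) {
    stopifnot(clip > 0)
    vals <- pmin(pmax(vals, -clip), clip)
  }
  new_cn_matrix(vals, probes, "raw")
}

#' Read gene annotation (BED)
#'
#' BED with at least 3 columns (0-based half-open); gene names from column 4,
#' auto-generated when absent. Lines with `start >= end` are dropped with a
#' warning; negative coordinates are an error.
#'
#' @param path BED file path.
#' @return a data frame with `gene_name`, `chrom`, `start`, `end`, sorted by
#'   position, unique names enforced.
#' @export
read_genes <- function(path) {
  x <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE,
                         comment.char = "#")
  if (ncol(x) < 3) stop("BED file needs at least 3 columns")
  nm <- if (ncol(x) >= 4) as.character(x[[4]]) else rep(NA_character_, nrow(x))
  auto <- is.na(nm) | nm == ""
  nm[auto] <- paste0("gene_", which(auto))
  g <- data.frame(gene_name = nm,
                  chrom = as.character(x[[1]]),
                  start = as.numeric(x[[2]]), end = as.numeric(x[[3]]),
                  stringsAsFactors = FALSE)
  if (any(g$start < 0)) stop("negative start coordinate in BED file")
  bad <- g$start >= g$end
  if (any(bad)) {
    warning(sum(bad), " BED line(s) with start >= end dropped")
    g <- g[!bad, , drop = FALSE]
  }
  if (anyDuplicated(g$gene_name))
    g$gene_name <- make.unique(g$gene_name)
  g <- g[order(match(g$chrom, karyotype_order(g$chrom)), g$start), , drop = FALSE]
  rownames(g) <- NULL
  g
}

#' Split a copy-number cohort into gains and losses
#'
#' Gains keep `max(x, 0)`; losses keep `max(-x, 0)`, so the downstream
#' machinery is identical for both directions and
#' `gains - losses` reconstructs the input.
#'
#' @param m a `cn_matrix` with `sign_mode = "raw"`.
#' @return list with elements `gains` and `losses` (both `cn_matrix`).
#' @export
split_gains_losses <- function(m) {
  stopifnot(inherits(m, "cn_matrix"))
  if (m$sign_mode != "raw") stop("matrix already split (sign_mode = ", m$sign_mode, ")")
  list(gains = new_cn_matrix(pmax(m$values, 0), m$probes, "gains"),
       losses = new_cn_matrix(pmax(-m$values, 0), m$probes, "losses"))
}

region_tsv_columns <- c("chrom", "start", "end", "direction", "amplitude",
                        "left_sig", "right_sig", "genes",
                        "start_probe", "end_probe", "left_boundary", "right_boundary")

fmt6 <- function(x) ifelse(is.na(x), "NA", sprintf("%.6g", x))

#' Write called regions to TSV and BED
#'
#' `<stem>.tsv` carries all columns; `<stem>.bed` is BED5 with the direction as
#' name and `-log10(min(left_sig, right_sig))` (clipped to \[0, 1000\]) as score.
#' Rows are ordered by genome position.
#'
#' @param regions a called-region table ([call_local_maxima()]).
#' @param stem output path stem (files `<stem>.tsv`, `<stem>.bed`).
#' @return invisibly, the two file paths.
#' @export
write_regions <- function(regions, stem) {
  o <- order(match(regions$chrom, karyotype_order(regions$chrom)), regions$start)
  regions <- regions[o, , drop = FALSE]
  tsv <- paste0(stem, ".tsv"); bed <- paste0(stem, ".bed")
  out <- regions[, intersect(region_tsv_columns, names(regions)), drop = FALSE]
  for (col in c("amplitude", "left_sig", "right_sig"))
    if (col %in% names(out)) out[[col]] <- fmt6(out[[col]])
  utils::write.table(out, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  score <- -log10(pmin(regions$left_sig, regions$right_sig, na.rm = TRUE))
  score[!is.finite(score)] <- 1000
  score <- pmin(pmax(score, 0), 1000)
  if (nrow(regions) == 0) {
    cat("", file = bed)
  } else {
    bedlines <- sprintf("%s\t%d\t%d\t%s\t%s", regions$chrom,
                        as.integer(regions$start), as.integer(regions$end),
                        regions$direction, fmt6(score))
    writeLines(bedlines, bed)
  }
  invisible(c(tsv = tsv, bed = bed))
}

#' Read back a called-region TSV written by [write_regions()]
#' @param path path to the `.tsv` file.
#' @return a called-region data frame.
#' @export
read_regions <- function(path) {
  x <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE,
                         colClasses = c(chrom = "character"))
  for (col in c("amplitude", "left_sig", "right_sig"))
    if (col %in% names(x)) x[[col]] <- as.numeric(x[[col]])
  if ("genes" %in% names(x)) x$genes[is.na(x$genes)] <- ""
  x
}
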