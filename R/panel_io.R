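#' Block definitions: construct and validate
#'
#' A methylation block is a cluster of neighbouring CpG sites quantified as a
#' unit by the targeted bisulfite panel. Coordinates follow the BED
#' convention: 0-based, half-open `[start, end)`.
#'
#' @param block_id character, unique identifiers.
#' @param chrom character chromosome names.
#' @param start,end non-negative integer coordinates with `start < end`.
#' @param n_cpg positive integer count of CpG positions per block.
#' @return A `data.frame` of class `block_defs` with one row per block.
#' @export
block_defs <- function(block_id, chrom, start, end, n_cpg) {
  df <- data.frame(block_id = as.character(block_id), chrom = as.character(chrom),
                   start = as.integer(start), end = as.integer(end),
                   n_cpg = as.integer(n_cpg), stringsAsFactors = FALSE)
  validate_block_defs(df)
}

validate_block_defs <- function(df, path = NULL) {
  check_cols(df, c("block_id", "chrom", "start", "end", "n_cpg"), "block definitions", path)
  if (anyNA(df$start) || anyNA(df$end) || anyNA(df$n_cpg)) {
    stop_timmrd("block definitions contain non-numeric start/end/n_cpg")
  }
  if (any(df$start < 0L)) stop_timmrd("negative start coordinate in block definitions")
  if (any(df$start >= df$end)) {
    bad <- df$block_id[df$start >= df$end][1L]
    stop_timmrd("block '%s' has start >= end (coordinates are 0-based half-open)", bad)
  }
  if (any(df$n_cpg < 1L)) stop_timmrd("n_cpg must be >= 1 for every block")
  dup <- unique(df$block_id[duplicated(df$block_id)])
  if (length(dup)) stop_timmrd("duplicate block_id in block definitions: %s",
                               paste(utils::head(dup, 5), collapse = ", "))
  class(df) <- c("block_defs", "data.frame")
  df
}

#' Read block definitions from a BED-like TSV
#'
#' Expects tab-separated columns `chrom, start, end, block_id, n_cpg` with no
#' header; lines starting with `#` are ignored. Row order is preserved.
#'
#' @param path path to the file.
#' @return A `block_defs` data frame.
#' @export
read_block_defs <- function(path) {
  if (!file.exists(path)) stop_timmrd("block definition file not found: '%s'", path)
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*#", lines) & nzchar(trimws(lines))
  lines <- lines[keep]
  lineno <- which(keep)
  if (!length(lines)) {
    return(validate_block_defs(data.frame(block_id = character(), chrom = character(),
                                          start = integer(), end = integer(),
                                          n_cpg = integer(), stringsAsFactors = FALSE)))
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf != 5L)) {
    stop_timmrd("malformed block definition row at line %d of '%s' (expected 5 tab-separated fields, got %d)",
                lineno[which(nf != 5L)[1L]], path, nf[nf != 5L][1L])
  }
  m <- do.call(rbind, parts)
  start <- suppressWarnings(as.integer(m[, 2]))
  end <- suppressWarnings(as.integer(m[, 3]))
  ncpg <- suppressWarnings(as.integer(m[, 5]))
  bad <- which(is.na(start) | is.na(end) | is.na(ncpg))
  if (length(bad)) stop_timmrd("malformed numeric field at line %d of '%s'", lineno[bad[1L]], path)
  validate_block_defs(data.frame(block_id = m[, 4], chrom = m[, 1], start = start,
                                 end = end, n_cpg = ncpg, stringsAsFactors = FALSE),
                      path = path)
}

#' Write block definitions as BED-like TSV
#'
#' @param blocks a `block_defs` data frame.
#' @param path output path.
#' @export
write_block_defs <- function(blocks, path) {
  blocks <- validate_block_defs(blocks)
  utils::write.table(blocks[, c("chrom", "start", "end", "block_id", "n_cpg")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Per-sample methylation counts: construct and validate
#'
#' Holds, for one plasma or tissue sample, the total number of CpG
#' observations `n_total` and the methylated observations `n_meth` per block.
#' Blocks absent from the table are treated downstream as `n_total = 0`.
#'
#' @param sample_id single sample identifier.
#' @param block_id character vector of block identifiers.
#' @param n_total,n_meth non-negative integer counts with `n_meth <= n_total`.
#' @return A `data.frame` of class `block_counts` with attribute `sample_id`.
#' @export
block_counts <- function(sample_id, block_id, n_total, n_meth) {
  stopifnot(length(sample_id) == 1L)
  df <- data.frame(block_id = as.character(block_id),
                   n_total = as.integer(n_total), n_meth = as.integer(n_meth),
                   stringsAsFactors = FALSE)
  validate_block_counts(df, sample_id)
}

validate_block_counts <- function(df, sample_id) {
  check_cols(df, c("block_id", "n_total", "n_meth"), "block counts")
  if (anyNA(df$n_total) || anyNA(df$n_meth)) stop_timmrd("NA counts for sample '%s'", sample_id)
  if (any(df$n_total < 0L) || any(df$n_meth < 0L)) {
    stop_timmrd("negative counts for sample '%s'", sample_id)
  }
  if (any(df$n_meth > df$n_total)) {
    bad <- df$block_id[df$n_meth > df$n_total][1L]
    stop_timmrd("n_meth > n_total for sample '%s', block '%s'", sample_id, bad)
  }
  dup <- unique(df$block_id[duplicated(df$block_id)])
  if (length(dup)) stop_timmrd("duplicate block_id for sample '%s': %s", sample_id, dup[1L])
  attr(df, "sample_id") <- as.character(sample_id)
  class(df) <- c("block_counts", "data.frame")
  df
}

#' Read per-sample methylation count tables
#'
#' Expects a header line and tab-separated columns
#' `sample_id, block_id, n_total, n_meth`; `#` comment lines are ignored.
#' Block identifiers must belong to `blocks` when supplied.
#'
#' @param path path to the TSV.
#' @param blocks optional `block_defs`; unknown block ids are rejected.
#' @return Named list with one `block_counts` per distinct `sample_id`.
#' @export
read_block_counts <- function(path, blocks = NULL) {
  if (!file.exists(path)) stop_timmrd("count file not found: '%s'", path)
  df <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  check_cols(df, c("sample_id", "block_id", "n_total", "n_meth"), "count table", path)
  if (!is.null(blocks)) {
    unknown <- setdiff(unique(df$block_id), blocks$block_id)
    if (length(unknown)) {
      stop_timmrd("count table '%s' references unknown block_id(s): %s", path,
                  paste(utils::head(unknown, 5), collapse = ", "))
    }
  }
  out <- lapply(split(df, df$sample_id), function(d) {
    validate_block_counts(d[, c("block_id", "n_total", "n_meth")], d$sample_id[1L])
  })
  out[unique(df$sample_id)]
}

#' Write a collection of per-sample counts as one TSV
#'
#' @param counts a `block_counts` or a (named) list of them.
#' @param path output path.
#' @export
write_block_counts <- function(counts, path) {
  if (inherits(counts, "block_counts")) counts <- list(counts)
  rows <- lapply(counts, function(d) {
    data.frame(sample_id = attr(d, "sample_id"), block_id = d$block_id,
               n_total = d$n_total, n_meth = d$n_meth, stringsAsFactors = FALSE)
  })
  utils::write.table(do.call(rbind, rows), path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Tissue methylome: construct and validate
#'
#' Per-block methylation fractions for a tissue sample (patient tumor,
#' matched tumor-adjacent normal, or healthy plasma). Levels are defined
#' only where supporting `depth >= 1`.
#'
#' @param sample_id single sample identifier.
#' @param block_id character vector.
#' @param level methylation fraction per block, in `[0, 1]`.
#' @param depth non-negative integer supporting observations.
#' @param tissue_role one of `"tumor"`, `"adjacent_normal"`, `"plasma_healthy"`.
#' @return A `data.frame` of class `tissue_methylome`.
#' @export
tissue_methylome <- function(sample_id, block_id, level, depth,
                             tissue_role = c("tumor", "adjacent_normal", "plasma_healthy")) {
  tissue_role <- match.arg(tissue_role)
  stopifnot(length(sample_id) == 1L)
  df <- data.frame(block_id = as.character(block_id), level = as.numeric(level),
                   depth = as.integer(depth), stringsAsFactors = FALSE)
  ok <- df$depth >= 1L
  if (any(!is_fraction(df$level[ok]))) stop_timmrd("tissue levels must lie in [0,1] where depth >= 1")
  if (any(df$depth < 0L)) stop_timmrd("negative depth in tissue methylome '%s'", sample_id)
  df$level[!ok] <- NA_real_
  attr(df, "sample_id") <- as.character(sample_id)
  attr(df, "tissue_role") <- tissue_role
  class(df) <- c("tissue_methylome", "data.frame")
  df
}

#' Read a somatic variant table
#'
#' Flat TSV with header `sample_id, variant_id, gene, allele_fraction`.
#' Variant calling itself is outside the package's scope; this consumes the
#' caller's output.
#'
#' @param path path to the TSV.
#' @return A data frame with one row per reported variant.
#' @export
read_variants <- function(path) {
  if (!file.exists(path)) stop_timmrd("variant file not found: '%s'", path)
  df <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  check_cols(df, c("sample_id", "variant_id", "gene", "allele_fraction"), "variant table", path)
  if (any(!is_fraction(df$allele_fraction))) {
    stop_timmrd("allele_fraction outside [0,1] in '%s'", path)
  }
  df
}

#' Read a sample manifest
#'
#' TSV with header `sample_id, patient_id, timepoint_label, day_from_surgery`.
#' Timepoint labels follow the perioperative sampling scheme: `A` preoperative
#' baseline, `B` days after surgery, `C` about one month after surgery, `F`
#' later follow-up draws. Negative `day_from_surgery` means preoperative.
#'
#' @param path path to the TSV.
#' @return A data frame, one row per sample.
#' @export
read_sample_manifest <- function(path) {
  if (!file.exists(path)) stop_timmrd("manifest not found: '%s'", path)
  df <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  check_cols(df, c("sample_id", "patient_id", "timepoint_label", "day_from_surgery"),
             "sample manifest", path)
  bad <- setdiff(unique(df$timepoint_label), c("A", "B", "C", "F"))
  if (length(bad)) stop_timmrd("unknown timepoint label(s) in '%s': %s", path,
                               paste(bad, collapse = ", "))
  df$day_from_surgery <- as.integer(df$day_from_surgery)
  df
}

#' Average cfDNA methylation level (MethylMean)
#'
#' Tumor-naive global summary of a plasma sample: the mean of per-block
#' methylated fractions `n_meth / n_total` over blocks with depth at least
#' `min_depth`. Unweighted by default; set `weighted = TRUE` to weight each
#' block by its depth.
#'
#' @param counts a `block_counts` object.
#' @param min_depth minimum `n_total` for a block to enter the mean.
#' @param weighted if `TRUE`, depth-weighted mean instead of the plain mean.
#' @return A fraction in `[0, 1]`.
#' @export
compute_methylmean <- function(counts, min_depth = 1L, weighted = FALSE) {
  stopifnot(min_depth >= 1L)
  keep <- counts$n_total >= min_depth
  if (!any(keep)) {
    stop_timmrd("MethylMean undefined: no block with depth >= %d in sample '%s'",
                min_depth, attr(counts, "sample_id") %||% "?")
  }
  r <- counts$n_meth[keep] / counts$n_total[keep]
  if (weighted) sum(r * counts$n_total[keep]) / sum(counts$n_total[keep]) else mean(r)
}

#' Maximum somatic allele fraction (maxAF)
#'
#' The highest mutant allele fraction reported for one sample; `0` when no
#' variant was detected, so `maxAF > 0` defines ctDNA-mutation positivity.
#'
#' @param variants data frame of variant calls for one sample (possibly
#'   zero rows), with column `allele_fraction`.
#' @return A fraction in `[0, 1]`.
#' @export
compute_maxaf <- function(variants) {
  af <- if (is.data.frame(variants)) variants$allele_fraction else as.numeric(variants)
  if (length(af) == 0L) return(0)
  if (any(!is_fraction(af))) stop_timmrd("allele fractions must lie in [0,1]")
  max(af)
}

#' Bisulfite conversion rate from non-CpG cytosines
#'
#' Non-CpG cytosines are essentially unmethylated in human DNA, so any
#' apparent methylation there measures incomplete conversion. The rate is
#' `1 - non_cpg_methylated / non_cpg_total`.
#'
#' @param non_cpg_total total non-CpG cytosine observations (`>= 1`).
#' @param non_cpg_methylated observations read as methylated.
#' @return Conversion rate in `[0, 1]`.
#' @export
bisulfite_conversion_rate <- function(non_cpg_total, non_cpg_methylated) {
  if (non_cpg_total < 1L) stop_timmrd("conversion rate undefined for zero non-CpG total")
  if (non_cpg_methylated < 0L || non_cpg_methylated > non_cpg_total) {
    stop_timmrd("need 0 <= non_cpg_methylated <= non_cpg_total")
  }
  1 - non_cpg_methylated / non_cpg_total
}
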