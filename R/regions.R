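#' Build promoter regions around transcription start sites
#'
#' For a plus-strand TSS at position `t` the promoter is the interval
#' `[t - 1500, t + 500)` (0-based half-open, clipped at the chromosome
#' start); on the minus strand the window is mirrored about the TSS,
#' `[t - 500, t + 1500)`, preserving the upstream/downstream asymmetry in
#' transcript orientation.
#'
#' @param tss data.frame with columns `chrom`, `position` (0-based TSS
#'   coordinate), `strand` ("+" or "-"), and optionally `name` used to form
#'   region ids.
#' @param upstream,downstream distances (bp) upstream/downstream of the TSS
#'   in transcript orientation.
#' @return a region-set data.frame with columns `chrom`, `start`, `end`,
#'   `region_id`, `kind` (all coordinates 0-based half-open).
#' @export
make_promoter_regions <- function(tss, upstream = 1500L, downstream = 500L) {
  stopifnot(is.data.frame(tss), all(c("chrom", "position", "strand") %in%
                                      names(tss)))
  if (any(tss$position < 0)) stop("TSS positions must be non-negative")
  if (!all(tss$strand %in% c("+", "-"))) stop("strand must be '+' or '-'")
  plus <- tss$strand == "+"
  start <- ifelse(plus, tss$position - upstream, tss$position - downstream)
  end <- ifelse(plus, tss$position + downstream, tss$position + upstream)
  start <- pmax(0L, start)
  ids <- if ("name" %in% names(tss)) as.character(tss$name)
         else sprintf("promoter%04d", seq_len(nrow(tss)))
  if (anyDuplicated(ids)) stop("region ids must be unique")
  data.frame(chrom = as.character(tss$chrom), start = as.integer(start),
             end = as.integer(end), region_id = ids, kind = "promoter",
             stringsAsFactors = FALSE)
}

#' Tile chromosomes with overlapping windows
#'
#' Generates 5 kb windows advancing by 2.5 kb (half a window), so that every
#' interior base is covered by exactly two windows. Windows are truncated at
#' the chromosome end and a final partial window is emitted whenever it
#' retains at least one base.
#'
#' @param chrom_sizes named numeric vector of chromosome lengths (bp).
#' @param width window width in bp.
#' @param step window step in bp (defaults to half the width).
#' @return a region-set data.frame (`chrom`, `start`, `end`, `region_id`,
#'   `kind = "window"`), 0-based half-open.
#' @export
make_windows <- function(chrom_sizes, width = 5000L, step = width %/% 2L) {
  if (is.null(names(chrom_sizes)) || any(!nzchar(names(chrom_sizes))))
    stop("chrom_sizes must be named by chromosome")
  if (any(chrom_sizes <= 0)) stop("chromosome lengths must be positive")
  out <- lapply(names(chrom_sizes), function(chr) {
    len <- chrom_sizes[[chr]]
    starts <- seq.int(0L, len - 1L, by = step)
    ends <- pmin(starts + width, len)
    data.frame(chrom = chr, start = as.integer(starts),
               end = as.integer(ends),
               region_id = sprintf("%s_w%06d", chr, starts),
               kind = "window", stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

validate_region_set <- function(regions) {
  stopifnot(is.data.frame(regions),
            all(c("chrom", "start", "end", "region_id") %in% names(regions)))
  if (any(regions$start < 0)) stop("region start must be >= 0")
  if (any(regions$end <= regions$start)) stop("region end must exceed start")
  if (anyDuplicated(regions$region_id)) stop("region ids must be unique")
  invisible(regions)
}

regions_to_granges <- function(df) {
  # internal 0-based half-open -> 1-based closed GRanges
  GenomicRanges::GRanges(df$chrom,
                         IRanges::IRanges(start = df$start + 1L,
                                          end = df$end))
}

#' Count fragments overlapping each region, per sample
#'
#' A fragment increments every region it overlaps by at least one base, so a
#' fragment inside the overlap zone of two moving windows is counted in
#' both. Overlap resolution is interval intersection on 0-based half-open
#' coordinates.
#'
#' @param fragments data.frame with columns `chrom`, `start`, `end`
#'   (0-based half-open) and `sample_id`.
#' @param regions a region-set data.frame.
#' @return integer count matrix, regions x samples, rownames = region ids.
#' @export
count_fragments <- function(fragments, regions) {
  validate_region_set(regions)
  stopifnot(all(c("chrom", "start", "end", "sample_id") %in%
                  names(fragments)))
  if (any(fragments$end <= fragments$start))
    stop("fragment end must exceed start")
  gr_regions <- regions_to_granges(regions)
  samples <- unique(as.character(fragments$sample_id))
  counts <- vapply(samples, function(s) {
    f <- fragments[fragments$sample_id == s, , drop = FALSE]
    gr_f <- regions_to_granges(f)
    GenomicRanges::countOverlaps(gr_regions, gr_f, minoverlap = 1L)
  }, integer(nrow(regions)))
  counts <- matrix(counts, nrow = nrow(regions),
                   dimnames = list(regions$region_id, samples))
  counts
}

#' Read fragment intervals from a BED3 file
#' @param path BED file (chrom, start, end; 0-based half-open).
#' @param sample_id sample identifier attached to all fragments.
#' @return data.frame with `chrom`, `start`, `end`, `sample_id`.
#' @export
read_fragments_bed <- function(path, sample_id) {
  df <- read.table(path, sep = "\t", header = FALSE,
                   stringsAsFactors = FALSE)[, 1:3]
  names(df) <- c("chrom", "start", "end")
  df$sample_id <- sample_id
  df
}

#' Write a region set as BED4
#' @param regions region-set data.frame.
#' @param path output file.
#' @export
write_regions_bed <- function(regions, path) {
  validate_region_set(regions)
  write.table(regions[, c("chrom", "start", "end", "region_id")], path,
              sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}
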