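#' Read GWAS summary statistics
#'
#' Reads a delimited text file of per-variant GWAS summary statistics and
#' returns a validated tibble. The file must have a header naming at least a
#' variant id, chromosome, position, effect size and standard error column
#' (`SNPID`/`id`, `CHR`/`chrom`, `POS`/`pos`, `BETA`/`beta`, `SE`/`se`;
#' matching is case-insensitive). Optional columns: `Z`/`z` and `F`/`freq`
#' (alternative-allele frequency).
#'
#' The Z score is defined as beta/se. When the file supplies its own `Z`
#' column it must agree with beta/se to within `1e-6`; discordant rows are
#' rejected. Rows with `se <= 0` are rejected.
#'
#' @param path Path to a tab- or whitespace-delimited file with a header.
#' @return A tibble with columns `variant_id`, `chrom`, `pos`, `beta`, `se`,
#'   `z` and, when present in the input, `freq`.
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' writeLines(c("SNPID\tCHR\tPOS\tBETA\tSE", "rs1\tchr1\t1000\t0.10\t0.05"), tf)
#' read_summary_stats(tf)
#' @export
read_summary_stats <- function(path) {
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  nm <- tolower(names(raw))
  find_col <- function(aliases, required = TRUE) {
    hit <- which(nm %in% aliases)
    if (length(hit) == 0L) {
      if (required) {
        stop(sprintf("summary-statistics file is missing a mandatory column (one of: %s)",
                     paste(aliases, collapse = ", ")), call. = FALSE)
      }
      return(NA_integer_)
    }
    hit[[1L]]
  }
  i_id    <- find_col(c("snpid", "id", "variant_id", "rsid"))
  i_chrom <- find_col(c("chr", "chrom", "chromosome"))
  i_pos   <- find_col(c("pos", "position", "bp"))
  i_beta  <- find_col(c("beta", "b"))
  i_se    <- find_col(c("se", "stderr"))
  i_z     <- find_col(c("z", "zscore"), required = FALSE)
  i_f     <- find_col(c("f", "freq", "af"), required = FALSE)

  num <- function(i, what) {
    v <- suppressWarnings(as.numeric(raw[[i]]))
    bad <- which(is.na(v) & !is.na(raw[[i]]))
    if (length(bad) > 0L) {
      stop(sprintf("non-numeric %s at line %d of %s", what, bad[[1L]] + 1L, path),
           call. = FALSE)
    }
    v
  }
  out <- tibble::tibble(
    variant_id = raw[[i_id]],
    chrom = raw[[i_chrom]],
    pos = num(i_pos, "position"),
    beta = num(i_beta, "beta"),
    se = num(i_se, "SE")
  )
  if (any(out$pos < 1, na.rm = TRUE)) {
    stop("positions must be 1-based (>= 1)", call. = FALSE)
  }
  bad_se <- which(!is.na(out$se) & out$se <= 0)
  if (length(bad_se) > 0L) {
    stop(sprintf("se <= 0 at line %d of %s", bad_se[[1L]] + 1L, path), call. = FALSE)
  }
  z_implied <- out$beta / out$se
  if (!is.na(i_z)) {
    z_given <- num(i_z, "Z")
    off <- which(abs(z_given - z_implied) >= 1e-6)
    if (length(off) > 0L) {
      stop(sprintf("Z inconsistent with beta/se (|diff| >= 1e-6) at line %d of %s",
                   off[[1L]] + 1L, path), call. = FALSE)
    }
  }
  out$z <- z_implied
  if (!is.na(i_f)) {
    out$freq <- num(i_f, "frequency")
    if (any(out$freq < 0 | out$freq > 1, na.rm = TRUE)) {
      stop("allele frequencies must lie in [0, 1]", call. = FALSE)
    }
  }
  out$pos <- as.integer(out$pos)
  out
}

#' Write GWAS summary statistics
#'
#' Inverse of [read_summary_stats()]: writes the tab-delimited format with
#' columns `SNPID`, `CHR`, `POS`, `BETA`, `SE`, `Z` (and `F` when a `freq`
#' column is present).
#'
#' @param variants Tibble as returned by [read_summary_stats()] or
#'   [simulate_gwas_dataset()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_summary_stats <- function(variants, path) {
  out <- tibble::tibble(
    SNPID = variants$variant_id,
    CHR = variants$chrom,
    POS = variants$pos,
    BETA = variants$beta,
    SE = variants$se,
    Z = if ("z" %in% names(variants)) variants$z else variants$beta / variants$se
  )
  if ("freq" %in% names(variants)) out$F <- variants$freq
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' Read a BED annotation track
#'
#' Reads a BED3+ file (0-based, half-open intervals), merges overlapping or
#' book-ended intervals, and returns a sorted annotation track.
#'
#' @param path Path to a BED file. May be empty (zero intervals is valid).
#' @param name Track name; defaults to the file name without extension.
#' @return A tibble with columns `name`, `chrom`, `start`, `end`
#'   (0-based half-open, sorted by chromosome then start, non-overlapping).
#' @export
read_bed <- function(path, name = NULL) {
  name <- name %||% sub("\\.[^.]*$", "", basename(path))
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) {
    return(tibble::tibble(name = character(), chrom = character(),
                          start = integer(), end = integer()))
  }
  parts <- strsplit(lines, "\t| +")
  chrom <- vapply(parts, `[[`, character(1), 1L)
  start <- suppressWarnings(as.integer(vapply(parts, `[[`, character(1), 2L)))
  end <- suppressWarnings(as.integer(vapply(parts, `[[`, character(1), 3L)))
  bad <- which(is.na(start) | is.na(end) | start >= end)
  if (length(bad) > 0L) {
    stop(sprintf("malformed BED interval (need 0-based start < end) at line %d of %s",
                 bad[[1L]], path), call. = FALSE)
  }
  bed_track(name, chrom, start, end)
}

# Build a merged, sorted track tibble from raw interval vectors.
bed_track <- function(name, chrom, start, end) {
  gr <- GenomicRanges::GRanges(factor(chrom, levels = sort(unique(chrom))),
                               IRanges::IRanges(start + 1L, end))
  gr <- GenomicRanges::reduce(GenomicRanges::sort(gr))
  tibble::tibble(
    name = name,
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr)
  )
}

#' Write an annotation track or peak set as BED
#'
#' @param track Tibble with `chrom`, `start`, `end` columns (0-based
#'   half-open), as produced by [read_bed()] or [simulate_peak_sets()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(track, path) {
  readr::write_tsv(track[, c("chrom", "start", "end")], path,
                   col_names = FALSE, progress = FALSE)
  invisible(path)
}

#' Read a variant-id list annotation
#'
#' Some annotations (missense or synonymous consequence, exon membership from
#' an external consequence caller) arrive as plain lists of variant ids, one
#' per line, rather than as intervals.
#'
#' @param path Path to a text file with one variant id per line.
#' @return Character vector of unique ids.
#' @export
read_variant_ids <- function(path) {
  ids <- readLines(path)
  unique(ids[nzchar(trimws(ids))])
}

#' Partition variants into consecutive genomic blocks
#'
#' Assigns every variant to a fixed window of `block_size` base pairs anchored
#' at coordinate 0 on its chromosome: 1-based position `p` maps to window
#' `floor((p - 1) / block_size)`. This is the block structure over which the
#' regional mixture likelihood is evaluated (consecutive ~1-Mb intervals
#' across the genome). Windows containing no variants are omitted.
#'
#' @param variants Tibble with at least `variant_id`, `chrom`, `pos`.
#' @param block_size Window width in base pairs (default 1 Mb).
#' @return The input tibble with added columns `block_id` (a dense integer,
#'   ordered by chromosome then window), `block_start` and `block_end`
#'   (0-based half-open window bounds).
#' @export
segment_blocks <- function(variants, block_size = 1e6) {
  if (nrow(variants) == 0L) stop("no variants to segment", call. = FALSE)
  assert_scalar_number(block_size, "block_size")
  win <- floor((variants$pos - 1) / block_size)
  key <- paste0(variants$chrom, ":", formatC(win, width = 12, flag = "0"))
  levels <- sort(unique(key))
  out <- dplyr::mutate(
    variants,
    block_id = match(key, levels),
    block_start = as.numeric(win * block_size),
    block_end = as.numeric((win + 1) * block_size)
  )
  dplyr::arrange(out, .data$block_id, .data$pos)
}

#' Build the binary variant-by-annotation incidence matrix
#'
#' A variant at 1-based position `p` is inside a 0-based half-open interval
#' `[start, end)` iff `start <= p - 1 < end`. Interval tracks are matched by
#' chromosome; variant-id list annotations are matched by id.
#'
#' @param variants Tibble with `variant_id`, `chrom`, `pos`.
#' @param tracks Named list of annotations. Each element is either a track
#'   tibble from [read_bed()] (or any tibble with `chrom`, `start`, `end`) or
#'   a character vector of variant ids (see [read_variant_ids()]). Names must
#'   be distinct.
#' @return The input tibble with one added 0/1 integer column per annotation.
#' @export
annotate_variants <- function(variants, tracks) {
  nms <- names(tracks)
  if (is.null(nms) || any(!nzchar(nms))) {
    stop("every annotation track must be named", call. = FALSE)
  }
  if (anyDuplicated(nms)) stop("duplicate annotation track names", call. = FALSE)
  vg <- GenomicRanges::GRanges(variants$chrom,
                               IRanges::IRanges(variants$pos, variants$pos))
  out <- variants
  for (nm in nms) {
    tr <- tracks[[nm]]
    if (is.character(tr)) {
      hit <- as.integer(variants$variant_id %in% tr)
    } else {
      if (nrow(tr) == 0L) {
        hit <- integer(nrow(variants))
      } else {
        tg <- GenomicRanges::GRanges(tr$chrom, IRanges::IRanges(tr$start + 1L, tr$end))
        lv <- union(GenomeInfoDb::seqlevels(vg), GenomeInfoDb::seqlevels(tg))
        GenomeInfoDb::seqlevels(vg) <- lv
        GenomeInfoDb::seqlevels(tg) <- lv
        hit <- as.integer(IRanges::overlapsAny(vg, tg))
      }
    }
    out[[nm]] <- hit
  }
  out
}
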