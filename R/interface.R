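#' Read a FASTA file
#'
#' @param path FASTA file.
#' @return named character vector of upper-case sequences, in file
#'   order.
#' @export
read_fasta <- function(path) {
  set <- Biostrings::readDNAStringSet(path)
  ids <- sub("\\s.*$", "", names(set))
  if (anyDuplicated(ids))
    stop("duplicate sequence ids in ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  setNames(toupper(as.character(set)), ids)
}

#' Write sequences as FASTA
#' @param sequences named character vector.
#' @param path output file.
#' @export
write_fasta <- function(sequences, path) {
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(sequences), path)
  invisible(path)
}

#' Read a conservation track into a dense per-position array
#'
#' Accepts 4-column bedGraph (0-based half-open intervals) or
#' fixed-step wiggle (1-based starts). Uncovered positions are `NA`
#' (missing); overlapping bedGraph intervals resolve last-wins with a
#' warning.
#'
#' @param path track file.
#' @param genome_length length of the target sequence.
#' @param chrom restrict to this chromosome (default: all lines).
#' @return numeric vector of length `genome_length` with `NA` for
#'   uncovered positions.
#' @export
read_track <- function(path, genome_length, chrom = NULL) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#") &
                   !startsWith(lines, "track")]
  out <- rep(NA_real_, genome_length)
  overlap_warned <- FALSE
  i <- 1L
  while (i <= length(lines)) {
    ln <- lines[i]
    if (startsWith(ln, "fixedStep")) {
      kv <- regmatches(ln, gregexpr("\\w+=[^ \t]+", ln))[[1]]
      opts <- setNames(sub("^\\w+=", "", kv), sub("=.*$", "", kv))
      getopt <- function(nm, def) if (nm %in% names(opts))
        opts[[nm]] else def
      start <- as.integer(getopt("start", NA)) # 1-based
      step <- as.integer(getopt("step", "1"))
      span <- as.integer(getopt("span", "1"))
      wig_chrom <- getopt("chrom", NA)
      i <- i + 1L
      k <- 0L
      while (i <= length(lines) && !startsWith(lines[i], "fixedStep") &&
             !grepl("\t| ", lines[i])) {
        if (is.null(chrom) || identical(wig_chrom, chrom)) {
          s <- start + k * step # 1-based position
          e <- s + span - 1L
          if (s < 1L || e > genome_length)
            stop(sprintf("wiggle value at line %d outside [1, %d]", i,
                         genome_length))
          out[s:e] <- as.numeric(lines[i])
        }
        k <- k + 1L; i <- i + 1L
      }
    } else {
      f <- strsplit(ln, "[ \t]+")[[1]]
      if (length(f) < 4L)
        stop(sprintf("malformed bedGraph line %d: '%s'", i, ln))
      if (is.null(chrom) || identical(f[1], chrom)) {
        s <- as.integer(f[2]); e <- as.integer(f[3]) # 0-based half-open
        if (is.na(s) || is.na(e) || s < 0L || e > genome_length || s >= e)
          stop(sprintf("bedGraph interval out of range at line %d", i))
        if (!overlap_warned && any(!is.na(out[(s + 1L):e]))) {
          warning("overlapping track intervals; last wins")
          overlap_warned <- TRUE
        }
        out[(s + 1L):e] <- as.numeric(f[4])
      }
      i <- i + 1L
    }
  }
  out
}

#' Write a numeric track as bedGraph
#'
#' Consecutive equal values are merged into intervals (0-based
#' half-open).
#'
#' @param values numeric per-position vector.
#' @param path output file.
#' @param chrom chromosome name.
#' @param digits rounding applied before run-merging.
#' @export
write_bedgraph <- function(values, path, chrom = "chr1", digits = 6L) {
  v <- round(values, digits)
  r <- rle(v)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths
  keep <- !is.na(r$values)
  df <- data.frame(chrom = chrom, start = starts[keep],
                   end = ends[keep], value = r$values[keep])
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Write predictions as BED6 (+ optional bedGraph tracks)
#'
#' Hairpin segments become BED6 intervals with
#' `score = round(1000 * max P^mi)`; 5'-end calls become 1-nt BED6
#' intervals. All coordinates on disk are 0-based half-open.
#'
#' @param prediction a [scan_genome()] result.
#' @param segments_path,five_prime_path BED6 output files.
#' @param chrom chromosome name.
#' @param p_mi_path,p_5end_path optional bedGraph outputs for the
#'   stitched probability tracks.
#' @export
write_predictions <- function(prediction, segments_path,
                              five_prime_path, chrom = "chr1",
                              p_mi_path = NULL, p_5end_path = NULL) {
  stopifnot(inherits(prediction, "prediction"))
  segs <- prediction$segments
  bed6 <- function(start0, end0, name, score, strand) {
    data.frame(chrom = rep(chrom, length(start0)), start = start0,
               end = end0, name = name, score = score, strand = strand)
  }
  seg_df <- if (nrow(segs))
    bed6(segs$start - 1L, segs$end,
         sprintf("hairpin_%d", seq_len(nrow(segs))),
         round(1000 * segs$score), segs$strand)
  else bed6(integer(), integer(), character(), integer(), character())
  write.table(seg_df, segments_path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  fps <- prediction$five_prime
  fp_df <- if (nrow(fps))
    bed6(fps$pos - 1L, fps$pos,
         sprintf("mature5p_%d", seq_len(nrow(fps))),
         round(1000 * fps$p), fps$strand)
  else bed6(integer(), integer(), character(), integer(), character())
  write.table(fp_df, five_prime_path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  if (!is.null(p_mi_path))
    write_bedgraph(prediction$p_mi, p_mi_path, chrom)
  if (!is.null(p_5end_path))
    write_bedgraph(prediction$p_5end, p_5end_path, chrom)
  invisible(prediction)
}

#' Read BED6 intervals
#' @param path BED file.
#' @return data.frame with 1-based inclusive `start`/`end`, `name`,
#'   `score`, `strand`.
#' @export
read_bed <- function(path) {
  df <- tryCatch(
    read.table(path, sep = "\t", stringsAsFactors = FALSE),
    error = function(e) data.frame())
  if (!nrow(df))
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), name = character(),
                      score = numeric(), strand = character()))
  names(df)[1:min(6, ncol(df))] <-
    c("chrom", "start", "end", "name", "score", "strand")[1:min(6, ncol(df))]
  df$start <- df$start + 1L # to 1-based inclusive
  df
}

#' Read a pairwise MAF alignment
#'
#' Minimal reader for two-sequence MAF blocks ("a" line followed by two
#' "s" lines); the first "s" line is the target.
#'
#' @param path MAF file.
#' @return list of blocks; each block has `src`, `start` (0-based),
#'   `size`, `strand`, `src_size` and `text` vectors of length 2.
#' @export
read_maf_pairwise <- function(path) {
  lines <- readLines(path)
  blocks <- list()
  i <- 1L; b <- 0L
  while (i <= length(lines)) {
    ln <- trimws(lines[i])
    if (startsWith(ln, "a")) {
      b <- b + 1L
      s_lines <- character()
      j <- i + 1L
      while (j <= length(lines) && startsWith(trimws(lines[j]), "s")) {
        s_lines <- c(s_lines, trimws(lines[j]))
        j <- j + 1L
      }
      if (length(s_lines) != 2L)
        stop(sprintf("malformed MAF block %d: expected 2 's' lines, got %d",
                     b, length(s_lines)))
      f <- lapply(s_lines, function(s) strsplit(s, "[ \t]+")[[1]])
      if (any(vapply(f, length, integer(1)) < 7L))
        stop(sprintf("malformed MAF block %d: short 's' line", b))
      blocks[[b]] <- list(
        src = vapply(f, `[`, character(1), 2L),
        start = as.integer(vapply(f, `[`, character(1), 3L)),
        size = as.integer(vapply(f, `[`, character(1), 4L)),
        strand = vapply(f, `[`, character(1), 5L),
        src_size = as.integer(vapply(f, `[`, character(1), 6L)),
        text = vapply(f, `[`, character(1), 7L))
      i <- j
    } else i <- i + 1L
  }
  blocks
}
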