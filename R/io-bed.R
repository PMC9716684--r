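#' Genomic regions (BED)
#'
#' Regions are data.frames with columns `contig_id`, `start`, `end`
#' (0-based half-open, the BED convention, which is also the package's
#' internal convention) and `name`.
#'
#' @param contig_id,start,end,name region fields; `name` defaults to
#'   `"contig:start-end"`.
#' @return A region data.frame.
#' @export
region <- function(contig_id, start, end, name = NULL) {
  start <- as.numeric(start); end <- as.numeric(end)
  if (any(start < 0) || any(start >= end))
    stop("invalid region: require 0 <= start < end")
  if (is.null(name)) name <- paste0(contig_id, ":", format_int(start), "-",
                                    format_int(end))
  name <- ifelse(is.na(name) | !nzchar(name),
                 paste0(contig_id, ":", format_int(start), "-",
                        format_int(end)), name)
  data.frame(contig_id = as.character(contig_id), start = start, end = end,
             name = as.character(name), stringsAsFactors = FALSE)
}

#' Read a BED3/BED4 file
#'
#' `track`, `browser` and `#` comment lines are skipped.
#'
#' @param path path to a BED file.
#' @return A region data.frame (see [region()]).
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "track") &
                 !startsWith(lines, "browser") & !startsWith(lines, "#")]
  if (!length(lines))
    return(region(character(), numeric(), numeric(), character()))
  f <- strsplit(lines, "\t", fixed = TRUE)
  ncol <- vapply(f, length, integer(1))
  if (any(ncol < 3L))
    stop("BED line with fewer than 3 columns at line ", which(ncol < 3L)[1])
  contig <- vapply(f, `[`, character(1), 1L)
  start <- as.numeric(vapply(f, `[`, character(1), 2L))
  end <- as.numeric(vapply(f, `[`, character(1), 3L))
  name <- ifelse(ncol >= 4L, vapply(f, `[`, character(1), 4L), NA_character_)
  bad <- is.na(start) | is.na(end) | start >= end | start < 0
  if (any(bad))
    stop("invalid region in BED at line ", which(bad)[1],
         " (require 0 <= start < end)")
  region(contig, start, end, name)
}

#' Write regions as BED4
#' @param regions a region data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(regions, path) {
  writeLines(paste(regions$contig_id, format_int(regions$start),
                   format_int(regions$end), regions$name, sep = "\t"), path)
  invisible(path)
}
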