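#' Filter prophage regions by length
#'
#' Retains regions strictly longer than `min_length` bases (order
#' preserved; idempotent).
#'
#' @param regions a region data.frame (see [region()]).
#' @param min_length length that must be exceeded (default 1000).
#' @return The retained regions.
#' @export
filter_prophages <- function(regions, min_length = 1000) {
  keep <- (regions$end - regions$start) > min_length
  out <- regions[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Per-base depth over a contig region
#'
#' `depth[i]` is the number of alignments whose target span contains
#' position `i`; target-consuming ops (`=`, `X`, `D`) count, so a read
#' still covers positions it deletes, while insertions add nothing.
#'
#' @param alignments `aln_tbl` rows (targets other than `contig_id` are
#'   ignored).
#' @param contig_id the contig.
#' @param contig_length its length.
#' @param reg optional single region row to restrict to (default: whole
#'   contig).
#' @return Integer vector of depths over the region.
#' @export
depth_profile <- function(alignments, contig_id, contig_length, reg = NULL) {
  if (is.null(reg)) {
    lo <- 0; hi <- contig_length
  } else {
    lo <- reg$start[1]; hi <- reg$end[1]
    if (lo < 0 || hi > contig_length)
      stop("region outside contig '", contig_id, "'")
  }
  a <- alignments[alignments$target_id == contig_id, , drop = FALSE]
  depth <- integer(contig_length + 1L)  # diff-array
  if (nrow(a)) {
    s <- pmax(as.integer(a$target_start), 0L)
    e <- pmin(as.integer(a$target_end), contig_length)
    ok <- e > s
    for (i in which(ok)) {
      depth[s[i] + 1L] <- depth[s[i] + 1L] + 1L
      depth[e[i] + 1L] <- depth[e[i] + 1L] - 1L
    }
  }
  cumsum(depth)[seq(lo + 1L, hi)]
}

#' Prophage activity call from coverage
#'
#' Compares mean depth over a prophage interval with mean depth over its
#' host contig (prophage interval, plus a configurable buffer, excluded
#' from the host side).  Active requires the depth ratio, the effect size
#' (Cohen's d with population variances, variance floored to keep it
#' finite on uniform coverage) and the host depth to all clear their
#' thresholds; the defaults mirror the published defaults of the standard
#' coverage-ratio prophage activity caller.  Either array shorter than
#' 100 positions, or zero host depth, yields `"not_determined"`.
#'
#' @param prophage_depth,host_depth per-base depth vectors (see
#'   [depth_profile()]); the host vector should exclude the prophage
#'   interval and buffer.
#' @param min_ratio minimum prophage:host depth ratio (default 1.65).
#' @param min_effect minimum Cohen's d (default 0.70).
#' @param min_host_depth minimum mean host depth (default 1.0).
#' @param var_floor variance floor for the effect size (default 0.25).
#' @return List of class `activity_call`: `prophage_depth`, `host_depth`
#'   (means), `ratio`, `effect_size`, `verdict` in
#'   `{"active","dormant","not_determined"}`.
#' @export
activity_call <- function(prophage_depth, host_depth, min_ratio = 1.65,
                          min_effect = 0.70, min_host_depth = 1.0,
                          var_floor = 0.25) {
  if (length(prophage_depth) == 0L || length(host_depth) == 0L)
    stop("empty depth array")
  mp <- mean(prophage_depth)
  mh <- mean(host_depth)
  guard <- length(prophage_depth) < 100L || length(host_depth) < 100L ||
    mh == 0
  vp <- max(pop_var(prophage_depth), var_floor)
  vh <- max(pop_var(host_depth), var_floor)
  d <- (mp - mh) / sqrt((vp + vh) / 2)
  ratio <- if (mh > 0) mp / mh else NA_real_
  verdict <- if (guard) "not_determined"
  else if (ratio >= min_ratio && d >= min_effect && mh >= min_host_depth)
    "active"
  else "dormant"
  structure(list(prophage_depth = mp, host_depth = mh, ratio = ratio,
                 effect_size = d, verdict = verdict),
            class = "activity_call")
}

pop_var <- function(x) mean((x - mean(x))^2)

#' @export
print.activity_call <- function(x, ...) {
  cat(sprintf(
    "activity_call: %s (prophage %.2fx vs host %.2fx, ratio %.2f, d %.2f)\n",
    x$verdict, x$prophage_depth, x$host_depth,
    ifelse(is.na(x$ratio), NaN, x$ratio), x$effect_size))
  invisible(x)
}

#' Call activity for a set of prophage regions
#'
#' Convenience wrapper: for each region, builds the prophage and host
#' depth arrays from the alignments (host = the contig minus the region
#' minus `buffer` bases on each side) and runs [activity_call()].
#'
#' @param regions prophage regions (see [region()]).
#' @param alignments `aln_tbl` of read alignments to the host contigs.
#' @param contig_lengths named vector of contig lengths.
#' @param buffer bases around the prophage excluded from the host side
#'   (default 500).
#' @param ... passed to [activity_call()].
#' @return data.frame: `name`, `contig_id`, `start`, `end`,
#'   `prophage_depth`, `host_depth`, `ratio`, `effect_size`, `verdict`.
#' @export
call_prophages <- function(regions, alignments, contig_lengths,
                           buffer = 500L, ...) {
  rows <- lapply(seq_len(nrow(regions)), function(i) {
    r <- regions[i, , drop = FALSE]
    clen <- contig_lengths[[r$contig_id]]
    if (is.null(clen) || is.na(clen))
      stop("unknown contig length for '", r$contig_id, "'")
    full <- depth_profile(alignments, r$contig_id, clen)
    idx <- seq_len(clen)
    inside <- idx > r$start & idx <= r$end
    buffered <- idx > max(0, r$start - buffer) &
      idx <= min(clen, r$end + buffer)
    host <- full[!buffered]
    pro <- full[inside]
    ac <- activity_call(pro, host, ...)
    data.frame(name = r$name, contig_id = r$contig_id, start = r$start,
               end = r$end, prophage_depth = ac$prophage_depth,
               host_depth = ac$host_depth, ratio = ac$ratio,
               effect_size = ac$effect_size, verdict = ac$verdict,
               stringsAsFactors = FALSE)
  })
  out <- if (length(rows)) do.call(rbind, rows)
  else data.frame(name = character(), contig_id = character(),
                  start = numeric(), end = numeric(),
                  prophage_depth = numeric(), host_depth = numeric(),
                  ratio = numeric(), effect_size = numeric(),
                  verdict = character(), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}
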