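#' @include AllClasses.R
NULL

#' Construct a binning specification
#'
#' @param lo,hi lowest and highest bin edge in arbitrary fluorescence units.
#' @param nBins number of bins.
#' @param scale \code{"log10"} (default) or \code{"linear"} bin spacing.
#' @return a [BinSpec-class] object. The default reproduces a 5-decade
#'   cytometer axis: 256 log10-spaced bins over \[1, 1e5\] a.u.
#' @examples
#' binSpec()
#' binSpec(1, 1e4, 2)           # two log-decade-sized bins of 2 decades each
#' @export
binSpec <- function(lo = 1, hi = 1e5, nBins = 256L, scale = c("log10", "linear")) {
  scale <- match.arg(scale)
  new("BinSpec", lo = as.numeric(lo), hi = as.numeric(hi),
      nBins = as.integer(nBins), scale = scale)
}

#' Bin edges implied by a BinSpec
#' @param spec a [BinSpec-class].
#' @return numeric vector of \code{nBins + 1} strictly increasing edges.
#' @export
binSpecEdges <- function(spec) {
  stopifnot(is(spec, "BinSpec"))
  if (spec@scale == "log10")
    10^seq(log10(spec@lo), log10(spec@hi), length.out = spec@nBins + 1L)
  else
    seq(spec@lo, spec@hi, length.out = spec@nBins + 1L)
}

#' Construct a FluorescenceHistogram from edges and counts
#'
#' @param edges strictly increasing positive bin edges (length = bins + 1).
#' @param counts non-negative event counts (length = bins).
#' @param threshold autofluorescence threshold, same units as \code{edges}.
#' @param label free-text provenance tag.
#' @return a validated [FluorescenceHistogram-class].
#' @export
fluorescenceHistogram <- function(edges, counts, threshold = 0, label = "") {
  new("FluorescenceHistogram", binEdges = as.numeric(edges),
      counts = as.numeric(counts), threshold = as.numeric(threshold),
      label = as.character(label))
}

#' Bin raw fluorescence events into a histogram
#'
#' Bins are half-open \code{[edge_i, edge_{i+1})}, lower-inclusive; the last
#' bin additionally includes its upper edge. Events outside
#' \code{[lo, hi]} are dropped and their number recorded in the returned
#' histogram's label.
#'
#' @param events numeric vector of per-event fluorescence values (a.u.,
#'   finite, non-negative).
#' @param spec a [BinSpec-class] describing the axis.
#' @param threshold autofluorescence threshold to carry on the histogram.
#' @param label optional provenance prefix.
#' @return a [FluorescenceHistogram-class]; \code{sum(binCounts())} equals the
#'   number of in-range events.
#' @examples
#' h <- buildHistogram(c(10, 50, 1000), binSpec(1, 1e4, 2), threshold = 5)
#' binCounts(h)  # 2 events in [1, 100), 1 in [100, 10000]
#' @export
buildHistogram <- function(events, spec, threshold = 0, label = "events") {
  if (!is(spec, "BinSpec")) stop("spec must be a BinSpec", call. = FALSE)
  validObject(spec)
  events <- as.numeric(events)
  if (anyNA(events) || any(!is.finite(events)) || any(events < 0))
    stop("events must be finite and >= 0", call. = FALSE)
  edges <- binSpecEdges(spec)
  idx <- findInterval(events, edges, rightmost.closed = TRUE)
  inRange <- idx >= 1L & idx <= spec@nBins
  counts <- tabulate(idx[inRange], nbins = spec@nBins)
  dropped <- sum(!inRange)
  fluorescenceHistogram(edges, counts, threshold,
    label = sprintf("%s: %d events binned, %d outside range dropped",
                    label, sum(inRange), dropped))
}

#' Truncate a histogram at its autofluorescence threshold
#'
#' Keeps exactly the bins whose lower edge is at or above the threshold; a bin
#' straddling the threshold is dropped entirely (no sub-bin mass is invented).
#' Idempotent. If the threshold exceeds every bin edge, an empty histogram is
#' returned with a warning.
#'
#' @param h a [FluorescenceHistogram-class].
#' @return the truncated histogram (same threshold, annotated label).
#' @export
truncateAtThreshold <- function(h) {
  stopifnot(is(h, "FluorescenceHistogram"))
  validObject(h)
  if (!length(h@counts)) return(h)
  thr <- h@threshold
  keep <- which(h@binEdges[-length(h@binEdges)] >= thr)
  if (!length(keep)) {
    warning("threshold ", thr, " lies above all bin edges; histogram is empty",
            call. = FALSE)
    return(fluorescenceHistogram(numeric(0), numeric(0), thr,
                                 label = paste0(h@label, " [truncated: empty]")))
  }
  first <- keep[1L]
  fluorescenceHistogram(h@binEdges[first:length(h@binEdges)],
                        h@counts[first:length(h@counts)], thr, h@label)
}

## shared-binning test used by hellinger()
.sameBinning <- function(e1, e2, tol = 1e-9) {
  length(e1) == length(e2) &&
    (length(e1) == 0L || max(abs(e1 - e2) / pmax(abs(e1), 1)) <= tol)
}

#' Hellinger distance between two fluorescence histograms
#'
#' The calibration fitness. In \code{"probability"} mode the counts are
#' unit-normalized and \eqn{H = \sqrt{1 - \sum_i \sqrt{p_i q_i}}} is returned,
#' a metric bounded in \[0, 1\]. In \code{"count"} mode (the default, matching
#' the unnormalized fitness magnitudes of the reference analysis)
#' \eqn{H_c = \sqrt{\sum_i (\sqrt{c_i} - \sqrt{d_i})^2}} is computed on the
#' raw counts and is unbounded above. Both are symmetric and zero iff the
#' inputs are equal. The histograms must share identical binning: align (and
#' truncate) first.
#'
#' @param h1,h2 [FluorescenceHistogram-class] objects on identical bin edges.
#' @param mode \code{"count"} (default) or \code{"probability"}.
#' @return a single non-negative number.
#' @examples
#' a <- fluorescenceHistogram(c(1, 10, 100), c(4, 0))
#' b <- fluorescenceHistogram(c(1, 10, 100), c(0, 4))
#' hellinger(a, b, mode = "count")        # 2 * sqrt(2)
#' hellinger(a, b, mode = "probability")  # 1: disjoint support
#' @export
hellinger <- function(h1, h2, mode = c("count", "probability")) {
  mode <- match.arg(mode)
  stopifnot(is(h1, "FluorescenceHistogram"), is(h2, "FluorescenceHistogram"))
  if (!.sameBinning(h1@binEdges, h2@binEdges))
    stop("histograms are not on identical bin edges; use alignBins() first",
         call. = FALSE)
  c1 <- h1@counts; c2 <- h2@counts
  if (mode == "probability") {
    t1 <- sum(c1); t2 <- sum(c2)
    if (t1 <= 0 || t2 <= 0)
      stop("probability-mode Hellinger is undefined for all-zero histograms",
           call. = FALSE)
    bc <- sum(sqrt((c1 / t1) * (c2 / t2)))
    sqrt(max(0, 1 - bc))
  } else {
    sqrt(sum((sqrt(c1) - sqrt(c2))^2))
  }
}

#' Align two histograms onto a common refined binning
#'
#' Restricts both histograms to their overlapping fluorescence range and
#' re-expresses each on the union of their bin edges within the overlap (the
#' finer common binning). The mass of a source bin is reassigned to the
#' refined bins proportionally to overlapped bin width on the log10 axis (the
#' histograms' native scale); total counts over the overlap are conserved.
#'
#' @param h1,h2 [FluorescenceHistogram-class] objects with overlapping ranges.
#' @return a list with elements \code{h1} and \code{h2} on identical edges.
#'   Identically binned inputs are returned unchanged.
#' @export
alignBins <- function(h1, h2) {
  stopifnot(is(h1, "FluorescenceHistogram"), is(h2, "FluorescenceHistogram"))
  validObject(h1); validObject(h2)
  if (!length(h1@counts) || !length(h2@counts))
    stop("cannot align an empty histogram", call. = FALSE)
  if (.sameBinning(h1@binEdges, h2@binEdges))
    return(list(h1 = h1, h2 = h2))
  lo <- max(h1@binEdges[1L], h2@binEdges[1L])
  hi <- min(h1@binEdges[length(h1@binEdges)], h2@binEdges[length(h2@binEdges)])
  if (lo >= hi)
    stop("histogram ranges are disjoint; cannot align", call. = FALSE)
  edges <- sort(unique(c(
    lo, hi,
    h1@binEdges[h1@binEdges > lo & h1@binEdges < hi],
    h2@binEdges[h2@binEdges > lo & h2@binEdges < hi])))
  list(h1 = .rebinLog(h1, edges), h2 = .rebinLog(h2, edges))
}

## Reassign counts of h onto `edges` (a refinement of h's edges within its
## range) proportionally to log10 bin width.
.rebinLog <- function(h, edges) {
  le <- log10(edges)
  src <- log10(h@binEdges)
  mids <- (le[-1L] + le[-length(le)]) / 2
  bin <- findInterval(mids, src, rightmost.closed = TRUE)
  width <- diff(le)
  srcWidth <- diff(src)[bin]
  counts <- h@counts[bin] * width / srcWidth
  fluorescenceHistogram(edges, counts, h@threshold,
                        label = paste0(h@label, " [aligned]"))
}

#' Read / write a fluorescence histogram as delimited text
#'
#' The on-disk format is a CSV with header \code{bin_lo,bin_hi,count} preceded
#' by a comment line \code{# threshold=<value>} (and optionally
#' \code{# label=<text>}); UTF-8, '.' decimal separator. Writing then reading
#' is the identity: counts are bit-exact and edges round-trip at full double
#' precision.
#'
#' @param path file path.
#' @param h a [FluorescenceHistogram-class].
#' @return \code{readHistogram} returns a [FluorescenceHistogram-class];
#'   \code{writeHistogram} invisibly returns \code{path}.
#' @export
readHistogram <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path, encoding = "UTF-8")
  comments <- lines[startsWith(lines, "#")]
  thr <- 0
  label <- ""
  m <- regmatches(comments, regexec("^#[ \t]*threshold=(.+)$", comments))
  thrVals <- vapply(m, function(x) if (length(x) == 2L) x[2L] else NA_character_,
                    character(1))
  if (any(!is.na(thrVals))) {
    thr <- suppressWarnings(as.numeric(trimws(thrVals[!is.na(thrVals)][1L])))
    if (is.na(thr)) stop("unparseable threshold comment in ", path, call. = FALSE)
  }
  m <- regmatches(comments, regexec("^#[ \t]*label=(.*)$", comments))
  labVals <- vapply(m, function(x) if (length(x) == 2L) x[2L] else NA_character_,
                    character(1))
  if (any(!is.na(labVals))) label <- labVals[!is.na(labVals)][1L]

  body <- lines[!startsWith(lines, "#") & nzchar(trimws(lines))]
  if (!length(body) || !identical(trimws(body[1L]), "bin_lo,bin_hi,count"))
    stop("missing 'bin_lo,bin_hi,count' header in ", path, call. = FALSE)
  rows <- body[-1L]
  if (!length(rows))
    return(fluorescenceHistogram(numeric(0), numeric(0), thr, label))
  parts <- strsplit(rows, ",", fixed = TRUE)
  for (i in seq_along(parts))
    if (length(parts[[i]]) != 3L)
      stop(sprintf("row %d of %s: expected 3 columns, found %d",
                   i, path, length(parts[[i]])), call. = FALSE)
  num <- matrix(suppressWarnings(as.numeric(unlist(parts))),
                ncol = 3L, byrow = TRUE)
  bad <- which(rowSums(is.na(num)) > 0)
  if (length(bad))
    stop(sprintf("row %d of %s: non-numeric value", bad[1L], path),
         call. = FALSE)
  lo <- num[, 1L]; hiCol <- num[, 2L]; counts <- num[, 3L]
  if (nrow(num) > 1L && any(abs(hiCol[-nrow(num)] - lo[-1L]) > 0)) {
    bad <- which(hiCol[-nrow(num)] != lo[-1L])[1L]
    stop(sprintf("row %d of %s: bins are not contiguous (bin_hi != next bin_lo)",
                 bad + 1L, path), call. = FALSE)
  }
  edges <- c(lo, hiCol[nrow(num)])
  if (any(diff(edges) <= 0)) {
    bad <- which(diff(edges) <= 0)[1L]
    stop(sprintf("row %d of %s: bin edges not strictly increasing", bad, path),
         call. = FALSE)
  }
  if (any(counts < 0)) {
    bad <- which(counts < 0)[1L]
    stop(sprintf("row %d of %s: negative count", bad, path), call. = FALSE)
  }
  fluorescenceHistogram(edges, counts, thr, label)
}

#' @rdname readHistogram
#' @export
writeHistogram <- function(h, path) {
  stopifnot(is(h, "FluorescenceHistogram"))
  validObject(h)
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(sprintf("# threshold=%s", .fmt(h@threshold)), con)
  if (nzchar(h@label)) writeLines(paste0("# label=", h@label), con)
  writeLines("bin_lo,bin_hi,count", con)
  if (length(h@counts)) {
    n <- length(h@counts)
    writeLines(paste(.fmt(h@binEdges[seq_len(n)]),
                     .fmt(h@binEdges[seq_len(n) + 1L]),
                     .fmt(h@counts), sep = ","), con)
  }
  invisible(path)
}

## full-precision decimal rendering that round-trips doubles
.fmt <- function(x) {
  out <- sprintf("%.17g", x)
  short <- sprintf("%.15g", x)
  roundtrips <- as.numeric(short) == x
  out[roundtrips] <- short[roundtrips]
  out
}
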