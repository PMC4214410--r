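# k-mer spectrum genome profiling: canonical k-mer depth histogram, error
# cutoff at the first local minimum, modal homozygous peak, and the spectrum
# genome-size estimate (total k-mer mass above the cutoff divided by the peak
# depth).

#' Compute the canonical k-mer depth spectrum of a read set
#'
#' Canonical k-mers (lexicographic minimum of a k-mer and its reverse
#' complement) are counted; k-mers containing N are skipped. The error cutoff
#' is placed at the first local minimum of the depth histogram and the peak at
#' the modal depth above the cutoff.
#'
#' @param reads character vector of reads.
#' @param k odd k-mer size, 11-31.
#' @return object of class `kmer_spectrum`: list(k, histogram data.frame
#'   (depth, count), error_cutoff, peak_depth).
#' @export
kmer_spectrum <- function(reads, k = 17) {
  check_that(k %% 2 == 1 && k >= 11 && k <= 31, "k must be odd and in 11..31")
  check_that(any(nchar(reads) >= k), "reads shorter than k")
  sp <- cpp_kmer_spectrum(reads, as.integer(k))
  hist <- data.frame(depth = sp$depth, count = sp$count)
  # densify up to a workable maximum for peak detection
  maxd <- min(max(hist$depth), max(10 * sum(hist$depth * hist$count) /
                                     sum(hist$count), 100))
  dense <- numeric(maxd)
  in_range <- hist$depth <= maxd
  dense[hist$depth[in_range]] <- hist$count[in_range]
  # first local minimum: first depth d with count(d) < count(d+1)
  cutoff <- NA_integer_
  for (d in seq_len(maxd - 1)) {
    if (dense[d] < dense[d + 1]) { cutoff <- d; break }
  }
  if (is.na(cutoff)) cutoff <- 1L
  peak <- which.max(dense[cutoff:maxd]) + cutoff - 1L
  if (cutoff > peak / 3) cutoff <- max(1L, floor(peak / 3))
  structure(list(k = k, histogram = hist, error_cutoff = as.integer(cutoff),
                 peak_depth = as.integer(peak)),
            class = "kmer_spectrum")
}

#' Estimate genome size from a k-mer spectrum
#'
#' Size = sum over depths >= error cutoff of depth x count, divided by the
#' homozygous peak depth (refined by a centroid over the modal neighbourhood).
#' A heterozygous half-depth peak, when detectable, is reported but not double
#' counted.
#'
#' @param spectrum a [kmer_spectrum()].
#' @return list with `size_bp`, `peak_depth` (refined), `error_cutoff`,
#'   `het_peak_depth` (NA if none detected).
#' @export
estimate_genome_size <- function(spectrum) {
  h <- spectrum$histogram
  cutoff <- spectrum$error_cutoff
  peak <- spectrum$peak_depth
  if (is.na(peak) || peak <= cutoff) {
    stop("genome-size estimation failed: no homozygous peak above the error cutoff",
         call. = FALSE)
  }
  # refined peak: centroid over mode +/- 20%
  win <- h$depth >= max(cutoff, floor(peak * 0.8)) & h$depth <= ceiling(peak * 1.2)
  if (!any(win)) stop("genome-size estimation failed: empty peak window",
                      call. = FALSE)
  peak_ref <- sum(h$depth[win] * h$count[win]) / sum(h$count[win])
  mass <- sum(as.numeric(h$depth[h$depth >= cutoff]) *
                h$count[h$depth >= cutoff])
  size <- mass / peak_ref
  # heterozygous half-depth peak: local maximum near peak/2, above the cutoff
  het <- NA_real_
  half <- peak / 2
  hw <- h$depth >= max(cutoff + 1, floor(half * 0.7)) & h$depth <= ceiling(half * 1.3)
  if (any(hw) && half > cutoff + 2) {
    cand <- h$depth[hw][which.max(h$count[hw])]
    # require it to be a genuine local bump relative to its shoulders
    c_at <- function(d) { i <- match(d, h$depth); if (is.na(i)) 0 else h$count[i] }
    if (c_at(cand) > 1.15 * min(c_at(cand - 2), c_at(cand + 2))) het <- cand
  }
  list(size_bp = size, peak_depth = peak_ref, error_cutoff = cutoff,
       het_peak_depth = het)
}
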