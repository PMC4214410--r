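# Variant discovery: heterozygous SNV/InDel calling from read pileups against
# the individual's own assembly, whole-genome comparison of two assemblies via
# unique-k-mer anchor chaining with per-segment alignment, and multi-set Venn
# partitions.

#' Call heterozygous variants from a read pileup
#'
#' Reads are placed by unique 31-mer seeds with ungapped verification and a
#' two-seed gapped fallback for short InDels. A heterozygous SNV is called
#' where a second allele reaches a fraction within
#' `[min_alt_fraction, max_alt_fraction]` at depth >= `min_depth`; InDel
#' observations are aggregated by position and called with the same fraction
#' rule. Rates are normalised by callable bases (positions at callable depth).
#'
#' @param assembly character scalar (one haplotype of the individual).
#' @param reads character vector of reads from the same individual.
#' @param min_depth minimum depth for a callable position.
#' @param min_alt_fraction,max_alt_fraction heterozygous allele-fraction band.
#' @param seed_k,max_mm,max_indel placement parameters.
#' @return list with `calls` (data.frame seqid, pos, ref, alt, type, zygosity,
#'   depth, alt_fraction) and `rates` (snv_per_kb, indel_per_kb, callable_bp).
#' @export
call_het_variants <- function(assembly, reads, min_depth = 10,
                              min_alt_fraction = 0.2, max_alt_fraction = 0.8,
                              seed_k = 31, max_mm = 5, max_indel = 10) {
  pp <- cpp_pileup(assembly, reads, as.integer(seed_k), as.integer(max_mm),
                   as.integer(max_indel))
  counts <- pp$counts
  L <- ncol(counts)
  depth <- .colSums(counts, 4, L)
  codes <- utf8ToInt(assembly)
  refrow <- integer(L)
  refrow[codes == 65L] <- 1L; refrow[codes == 67L] <- 2L
  refrow[codes == 71L] <- 3L; refrow[codes == 84L] <- 4L
  valid <- refrow > 0L
  refcount <- integer(L)
  refcount[valid] <- counts[cbind(refrow[valid], which(valid))]
  r1 <- counts[1, ]; r2 <- counts[2, ]; r3 <- counts[3, ]; r4 <- counts[4, ]
  r1[refrow == 1L] <- 0L; r2[refrow == 2L] <- 0L
  r3[refrow == 3L] <- 0L; r4[refrow == 4L] <- 0L
  altcount <- pmax(r1, r2, r3, r4)
  frac <- ifelse(depth > 0, altcount / depth, 0)
  is_snv <- valid & depth >= min_depth & frac >= min_alt_fraction &
    frac <= max_alt_fraction
  pos <- which(is_snv)
  bases <- c("A", "C", "G", "T")
  alt <- character(length(pos))
  if (length(pos)) {
    sub <- rbind(r1[pos], r2[pos], r3[pos], r4[pos])
    alt <- bases[max.col(t(sub), ties.method = "first")]
  }
  snv_calls <- if (length(pos)) data.frame(
    seqid = "assembly", pos = pos, ref = bases[refrow[pos]], alt = alt,
    type = "SNV", zygosity = "het", depth = depth[pos],
    alt_fraction = frac[pos], stringsAsFactors = FALSE) else
      data.frame(seqid = character(0), pos = integer(0), ref = character(0),
                 alt = character(0), type = character(0),
                 zygosity = character(0), depth = integer(0),
                 alt_fraction = numeric(0))
  # indels
  ind <- data.frame(pos = pp$indel_pos, len = pp$indel_len,
                    count = pp$indel_count)
  ind <- ind[ind$pos >= 1 & ind$pos <= L, , drop = FALSE]
  ind$depth <- depth[pmax(1L, ind$pos - 1L)]
  ind$frac <- ifelse(ind$depth > 0, ind$count / ind$depth, 0)
  ind <- ind[ind$depth >= min_depth & ind$frac >= min_alt_fraction &
               ind$frac <= max_alt_fraction & abs(ind$len) <= max_indel, ,
             drop = FALSE]
  indel_calls <- if (nrow(ind)) data.frame(
    seqid = "assembly", pos = ind$pos,
    ref = ifelse(ind$len > 0, substring(assembly, ind$pos,
                                        pmin(L, ind$pos + ind$len - 1L)), ""),
    alt = "", type = ifelse(ind$len > 0, "deletion", "insertion"),
    zygosity = "het", depth = ind$depth, alt_fraction = ind$frac,
    stringsAsFactors = FALSE) else
      data.frame(seqid = character(0), pos = integer(0), ref = character(0),
                 alt = character(0), type = character(0),
                 zygosity = character(0), depth = integer(0),
                 alt_fraction = numeric(0))
  callable <- sum(depth >= min_depth)
  if (callable == 0) stop("zero callable bases", call. = FALSE)
  rates <- list(snv_per_kb = nrow(snv_calls) / (callable / 1000),
                indel_per_kb = nrow(indel_calls) / (callable / 1000),
                callable_bp = callable)
  list(calls = rbind(snv_calls, indel_calls), rates = rates,
       n_mapped = pp$n_mapped, n_unmapped = pp$n_unmapped)
}

## chain anchors: thin to one per stride window, enforce strictly increasing
## and non-overlapping coordinates in both genomes
chain_anchors <- function(anc, k, stride = 64, max_jump = 5000) {
  keep <- anc$strand == 1
  df <- data.frame(pa = anc$pos_a[keep], pb = anc$pos_b[keep])
  df <- df[order(df$pa), , drop = FALSE]
  df <- df[!duplicated(df$pa %/% stride), , drop = FALSE]
  n <- nrow(df)
  if (n == 0) return(df)
  keep2 <- logical(n)
  last_a <- -1e18; last_b <- -1e18
  for (i in seq_len(n)) {
    da <- df$pa[i] - last_a
    db <- df$pb[i] - last_b
    if (da >= k && db >= k && abs(db - da) <= max_jump) {
      keep2[i] <- TRUE
      last_a <- df$pa[i]; last_b <- df$pb[i]
    }
  }
  df[keep2, , drop = FALSE]
}

#' Compare two assemblies base-by-base
#'
#' Unique-k-mer anchors shared by both genomes are chained into a collinear
#' backbone; the sequence between consecutive anchors is aligned (banded affine
#' alignment) to yield SNVs and short InDels. Rates are computed over aligned
#' bases only; InDels longer than `max_indel` are treated as structural and
#' excluded from the rate.
#'
#' @param query,reference character scalars (variants reported on reference
#'   coordinates: ref allele from `reference`, alt from `query`).
#' @param k anchor k-mer size.
#' @param max_indel maximum InDel length reported.
#' @param stride anchor thinning stride in bp.
#' @return list with `calls` (data.frame), `rates` (snv_per_kb, indel_per_kb,
#'   aligned_bp) and `n_anchors`.
#' @export
compare_assemblies <- function(query, reference, k = 21, max_indel = 10,
                               stride = 64) {
  anc <- cpp_unique_anchors(reference, query, as.integer(k))
  if (length(anc$pos_a) == 0) {
    warning("no anchors between the genomes")
    return(list(calls = data.frame(), rates = list(snv_per_kb = NA_real_,
                                                   indel_per_kb = NA_real_,
                                                   aligned_bp = 0),
                n_anchors = 0))
  }
  ch <- chain_anchors(anc, k, stride)
  n <- nrow(ch)
  check_that(n >= 2, "too few collinear anchors")
  sega <- substring(reference, ch$pa[-n] + k, ch$pa[-1] - 1)
  segb <- substring(query, ch$pb[-n] + k, ch$pb[-1] - 1)
  nonempty <- nchar(sega) > 0 | nchar(segb) > 0
  seg_start_a <- (ch$pa[-n] + k)[nonempty]
  al <- cpp_align_segments(sega[nonempty], segb[nonempty], 32L,
                           as.integer(max_indel))
  snv <- if (length(al$snv_seg)) data.frame(
    seqid = "reference", pos = seg_start_a[al$snv_seg] + al$snv_off_a,
    ref = al$snv_ref, alt = al$snv_alt, type = "SNV",
    stringsAsFactors = FALSE) else
      data.frame(seqid = character(0), pos = integer(0), ref = character(0),
                 alt = character(0), type = character(0))
  ind <- data.frame(seg = al$ind_seg, off = al$ind_off_a, len = al$ind_len)
  ind <- ind[abs(ind$len) <= max_indel, , drop = FALSE]
  indel <- if (nrow(ind)) data.frame(
    seqid = "reference", pos = seg_start_a[ind$seg] + ind$off,
    ref = "", alt = "", type = ifelse(ind$len > 0, "deletion", "insertion"),
    stringsAsFactors = FALSE) else
      data.frame(seqid = character(0), pos = integer(0), ref = character(0),
                 alt = character(0), type = character(0))
  aligned <- as.numeric(n) * k + sum(al$aligned)
  rates <- list(snv_per_kb = nrow(snv) / (aligned / 1000),
                indel_per_kb = nrow(indel) / (aligned / 1000),
                aligned_bp = aligned)
  calls <- rbind(snv, indel)
  calls <- calls[order(calls$pos), , drop = FALSE]
  rownames(calls) <- NULL
  list(calls = calls, rates = rates, n_anchors = n)
}

#' Venn partition of variant sets
#'
#' Variants are matched by (seqid, position, ref, alt); counts are returned for
#' every intersection region. Region counts sum to the size of the union.
#'
#' @param variant_sets named list of data.frames with columns seqid, pos, ref,
#'   alt.
#' @return list with `regions` (named integer vector, names like "A", "A&B")
#'   and `union_size`.
#' @export
variant_venn <- function(variant_sets) {
  nm <- names(variant_sets)
  check_that(!is.null(nm) && all(nzchar(nm)), "variant_sets must be named")
  keys <- lapply(variant_sets, function(v)
    unique(paste(v$seqid, v$pos, v$ref, v$alt, sep = "\r")))
  univ <- unique(unlist(keys))
  member <- vapply(keys, function(k) univ %in% k, logical(length(univ)))
  if (length(univ) == 1) member <- matrix(member, nrow = 1,
                                          dimnames = list(NULL, nm))
  combos <- apply(member, 1, function(r) paste(nm[r], collapse = "&"))
  all_regions <- unlist(lapply(seq_along(nm), function(sz)
    utils::combn(nm, sz, paste, collapse = "&", simplify = TRUE)))
  regions <- setNames(integer(length(all_regions)), all_regions)
  tb <- table(combos)
  regions[names(tb)] <- as.integer(tb)
  list(regions = regions, union_size = length(univ))
}
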