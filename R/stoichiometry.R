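#' Median intensity of the k brightest foci
#'
#' Sorts foci by descending integrated intensity, takes the first `k` and
#' returns their median (mean of the central pair for even `k`). Used as the
#' per-image representative intensity of the "more visible" foci: requiring
#' at least `k` foci mirrors acquisitions where at least 10 foci were present
#' in every image.
#'
#' @param x numeric intensities, or a focus data.frame with an
#'   `integrated_intensity` column.
#' @param k number of brightest foci to use (default 10).
#' @param use_all if `TRUE`, fall back to all foci when fewer than `k` are
#'   present (the result then carries attribute `used_all = TRUE`); by
#'   default a shortfall is an error.
#' @return median intensity of the top `k`.
#' @export
top_k_median <- function(x, k = 10, use_all = FALSE) {
  if (is.data.frame(x)) x <- x$integrated_intensity
  stopifnot(is.numeric(x), k >= 1)
  if (length(x) < k) {
    if (!use_all)
      stop("only ", length(x), " foci available but k = ", k,
           " required (enable use_all to fall back)")
    res <- stats::median(x)
    attr(res, "used_all") <- TRUE
    return(res)
  }
  topk <- sort(x, decreasing = TRUE)[seq_len(k)]
  stats::median(topk)
}

#' Between-condition intensity ratio over a time course
#'
#' Implements the in vivo stoichiometry procedure for two strains imaged
#' under identical settings with the same fluorophore, where abundance ratios
#' follow directly from intensity ratios. Per timepoint and condition: each
#' image contributes its `k` brightest foci; these are pooled within the
#' condition and their median taken; the reported ratio is
#' `median_a / median_b`. When images carry replicate labels the dispersion
#' is the standard error of replicate-level ratios.
#'
#' @param series_a,series_b data.frames with columns `timepoint`, `image`,
#'   `integrated_intensity` and optionally `replicate`.
#' @param k foci per image entering the ranking.
#' @param pool_first if `TRUE`, rank the pooled per-condition foci instead of
#'   per image (the alternative reading of "the k brightest").
#' @param use_all passed to [top_k_median()].
#' @return data.frame: timepoint, value_a, value_b, ratio, dispersion,
#'   k_used, n_foci_a, n_foci_b.
#' @export
ratio_timecourse <- function(series_a, series_b, k = 10, pool_first = FALSE,
                             use_all = FALSE) {
  need <- c("timepoint", "image", "integrated_intensity")
  stopifnot(all(need %in% names(series_a)), all(need %in% names(series_b)))
  tps <- sort(unique(series_a$timepoint))
  if (!setequal(tps, unique(series_b$timepoint)))
    stop("series do not share a timepoint grid")
  res <- lapply(tps, function(tp) {
    a <- series_a[series_a$timepoint == tp, , drop = FALSE]
    b <- series_b[series_b$timepoint == tp, , drop = FALSE]
    va <- condition_median(a, k, pool_first, use_all)
    vb <- condition_median(b, k, pool_first, use_all)
    disp <- NA_real_
    if ("replicate" %in% names(a) && "replicate" %in% names(b)) {
      reps <- intersect(unique(a$replicate), unique(b$replicate))
      if (length(reps) >= 2) {
        rr <- vapply(reps, function(r) {
          condition_median(a[a$replicate == r, ], k, pool_first, use_all) /
            condition_median(b[b$replicate == r, ], k, pool_first, use_all)
        }, numeric(1))
        disp <- stats::sd(rr) / sqrt(length(rr))
      }
    }
    data.frame(timepoint = tp, value_a = va, value_b = vb, ratio = va / vb,
               dispersion = disp, k_used = k,
               n_foci_a = nrow(a), n_foci_b = nrow(b))
  })
  do.call(rbind, res)
}

condition_median <- function(d, k, pool_first, use_all) {
  if (nrow(d) == 0) stop("no foci at a timepoint")
  if (pool_first) return(as.numeric(top_k_median(d, k, use_all)))
  pooled <- unlist(lapply(split(d$integrated_intensity, d$image), function(x) {
    if (length(x) < k && use_all) x
    else if (length(x) < k)
      stop("image with ", length(x), " foci; k = ", k, " required")
    else sort(x, decreasing = TRUE)[seq_len(k)]
  }), use.names = FALSE)
  stats::median(pooled)
}

#' Summary of a focus intensity distribution
#'
#' Deterministic summary used for between-genotype fold-change comparisons
#' (fold change between two summaries = ratio of their medians).
#'
#' @param foci numeric intensities or focus data.frame.
#' @return data.frame: n, mean, median, q25, q75.
#' @export
intensity_distribution <- function(foci) {
  if (is.data.frame(foci)) foci <- foci$integrated_intensity
  if (length(foci) == 0) stop("empty focus list")
  q <- stats::quantile(foci, c(0.25, 0.75), names = FALSE)
  data.frame(n = length(foci), mean = mean(foci),
             median = stats::median(foci), q25 = q[1], q75 = q[2])
}
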