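#' Mantel correlogram
#'
#' Profiles spatial autocorrelation in a site-level variable (e.g. mean
#' laying date, or pixel synchrony) as a sequence of Mantel statistics,
#' one per geographic distance class. For class k the statistic is the
#' negative Pearson correlation, over site pairs, between the value
#' dissimilarity (Euclidean distance on values) and the indicator of
#' membership in class k; the sign flip makes positive r mean "sites in
#' this class are more similar than average", the usual correlogram
#' orientation. Significance is assessed by permuting site labels of the
#' values, recomputing every class statistic each time; the two-sided
#' p-value counts permutations (plus the observed labelling) whose |r|
#' reaches the observed |r|.
#'
#' Distance classes default to equal-count bins (Sturges' number of
#' classes on the pair count), half-open `[lo, hi)` with the last edge
#' closed. A class whose pairs all have identical values has an undefined
#' statistic and is reported as `NA`, never silently 0.
#'
#' @param coords n x 2 matrix (or data frame) of projected coordinates in
#'   metres.
#' @param values numeric vector of length n; pre-adjusted residuals (e.g.
#'   corrected for year and female effects via
#'   [fit_breeding_lmm()] residuals) are accepted.
#' @param class_edges optional numeric vector of class boundaries in
#'   metres (length n_classes + 1, increasing).
#' @param n_perm number of permutations (default 999).
#' @param seed RNG seed for the permutations.
#' @return object of class `mantel_correlogram`: data frame with
#'   `class_lo`, `class_hi`, `midpoint`, `r`, `p`, `n_pairs`, and
#'   attributes `n_perm`, `seed`.
#' @export
mantel_correlogram <- function(coords, values, class_edges = NULL,
                               n_perm = 999, seed = 1) {
  coords <- as.matrix(coords)
  n <- nrow(coords)
  stopifnot(n >= 4, length(values) == n)
  dgeo <- as.vector(stats::dist(coords))
  if (is.null(class_edges)) {
    n_classes <- max(2L, ceiling(log2(length(dgeo))) + 1L)
    qs <- stats::quantile(dgeo, probs = seq(0, 1, length.out = n_classes + 1))
    class_edges <- unique(as.numeric(qs))
    if (length(class_edges) < 3) {
      class_edges <- c(min(dgeo), stats::median(dgeo), max(dgeo) + 1e-9)
    }
  }
  class_edges <- sort(class_edges)
  n_classes <- length(class_edges) - 1L
  # half-open bins [lo, hi); the final edge is nudged so the largest
  # distance falls inside the last class
  eps <- 1e-9 * max(1, abs(class_edges[n_classes + 1]))
  cls <- findInterval(dgeo, c(class_edges[1:n_classes],
                              class_edges[n_classes + 1] + eps),
                      rightmost.closed = FALSE)
  cls[cls < 1 | cls > n_classes] <- NA_integer_

  dv <- stats::dist(values)
  # index matrix to permute a dist object by site labels
  full <- as.matrix(dv)
  low <- lower.tri(full)

  class_r <- function(dval_vec) {
    vapply(seq_len(n_classes), function(k) {
      idx <- which(cls == k)
      if (length(idx) < 2) return(NA_real_)
      ind <- as.numeric(cls == k)
      ind[is.na(cls)] <- 0
      if (stats::sd(dval_vec) < 1e-12 || stats::sd(ind) < 1e-12) {
        return(NA_real_)
      }
      -stats::cor(dval_vec, ind)
    }, numeric(1))
  }

  r_obs <- class_r(as.vector(dv))

  set.seed(seed)
  exceed <- rep(0L, n_classes)
  valid_perm <- rep(0L, n_classes)
  for (b in seq_len(n_perm)) {
    p <- sample.int(n)
    dval_p <- full[p, p][low]
    r_p <- class_r(dval_p)
    cmp <- abs(r_p) >= abs(r_obs) - 1e-12
    exceed <- exceed + ifelse(is.na(cmp), 0L, as.integer(cmp))
    valid_perm <- valid_perm + as.integer(!is.na(r_p))
  }
  pval <- ifelse(is.na(r_obs), NA_real_, (exceed + 1) / (n_perm + 1))

  out <- data.frame(class_lo = class_edges[1:n_classes],
                    class_hi = class_edges[2:(n_classes + 1)],
                    midpoint = (class_edges[1:n_classes] +
                                  class_edges[2:(n_classes + 1)]) / 2,
                    r = r_obs, p = pval,
                    n_pairs = vapply(seq_len(n_classes),
                                     function(k) sum(cls == k, na.rm = TRUE),
                                     integer(1)))
  attr(out, "n_perm") <- n_perm
  attr(out, "seed") <- seed
  class(out) <- c("mantel_correlogram", "data.frame")
  out
}
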