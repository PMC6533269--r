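#' Select reliable voxels by split-half reliability
#'
#' Restricts analysis to voxels whose condition profiles replicate across
#' participants, mimicking the construction of a "social brain network"
#' style mask from person-specific patterns. Participants are repeatedly
#' split into random halves; each voxel's condition profile is correlated
#' between the two half-averages (voxelwise reliability, averaged over
#' splits). For every candidate threshold, the patternwise reliability of the
#' surviving voxels -- the mean over conditions and splits of the between-half
#' pattern correlation restricted to those voxels -- is computed, and the
#' threshold maximizing it is returned. Ties are broken toward the lowest
#' threshold, retaining more voxels.
#'
#' @param person_sets List of at least 4 per-participant [pattern_matrix()]
#'   objects sharing voxels and conditions (at least 2 conditions).
#' @param n_splits Number of random half-splits (default 10).
#' @param thresholds Numeric grid of voxelwise-reliability cutoffs. The
#'   default grid starts at -1 (a no-op threshold retaining all voxels), so
#'   the selected mask can never have lower patternwise reliability than the
#'   full voxel set.
#' @param seed Integer seed controlling the half-split assignment.
#'
#' @return An object of class `"voxel_mask"`: a list with `selected` (voxel
#'   ids), `threshold_used`, `patternwise_reliability`,
#'   `voxelwise_reliability` (named per-voxel vector), and the grid of
#'   per-threshold pattern reliabilities.
#' @export
select_reliable_voxels <- function(person_sets, n_splits = 10L,
                                   thresholds = seq(-1, 0.9, by = 0.1),
                                   seed = 1L) {
  if (!is.list(person_sets) || length(person_sets) < 4L) {
    stop("need at least 4 participants for split-half voxel selection",
         call. = FALSE)
  }
  n_splits <- .assert_count(n_splits, "n_splits", min = 1L)
  ref <- person_sets[[1L]]
  vox <- rownames(ref)
  conds <- colnames(ref)
  if (length(conds) < 2L) stop("need at least 2 conditions", call. = FALSE)
  mats <- lapply(person_sets, .align_pattern, voxel_ids = vox,
                 condition_labels = conds)
  n_p <- length(mats)
  n_half <- n_p %/% 2L

  halves <- .with_seed(seed, {
    lapply(seq_len(n_splits), function(i) sample.int(n_p))
  })
  # Per-split half averages and per-voxel profile correlations
  split_avgs <- vector("list", n_splits)
  vox_rel <- matrix(0, length(vox), n_splits)
  for (s in seq_len(n_splits)) {
    idx <- halves[[s]]
    a1 <- Reduce(`+`, mats[idx[seq_len(n_half)]]) / n_half
    a2 <- Reduce(`+`, mats[idx[(n_half + 1L):n_p]]) / (n_p - n_half)
    split_avgs[[s]] <- list(a1 = a1, a2 = a2)
    # row-wise correlation across conditions
    c1 <- a1 - rowMeans(a1)
    c2 <- a2 - rowMeans(a2)
    num <- rowSums(c1 * c2)
    den <- sqrt(rowSums(c1^2) * rowSums(c2^2))
    r <- num / den
    r[!is.finite(r)] <- 0 # flat profiles carry no reliable signal
    vox_rel[, s] <- r
  }
  voxelwise <- rowMeans(vox_rel)
  names(voxelwise) <- vox

  pattern_rel <- vapply(thresholds, function(th) {
    keep <- voxelwise >= th
    if (sum(keep) < 2L) return(NA_real_)
    rs <- vapply(split_avgs, function(sp) {
      m1 <- sp$a1[keep, , drop = FALSE]
      m2 <- sp$a2[keep, , drop = FALSE]
      mean(diag(stats::cor(m1, m2)))
    }, numeric(1))
    mean(rs)
  }, numeric(1))

  if (all(is.na(pattern_rel))) {
    stop("no voxel passes any threshold in the grid", call. = FALSE)
  }
  ord <- order(thresholds)
  best <- ord[which.max(pattern_rel[ord])] # first max over ascending grid
  keep <- voxelwise >= thresholds[best]
  structure(list(selected = vox[keep],
                 threshold_used = thresholds[best],
                 patternwise_reliability = pattern_rel[best],
                 voxelwise_reliability = voxelwise,
                 grid = data.frame(threshold = thresholds[ord],
                                   patternwise_reliability = pattern_rel[ord])),
            class = "voxel_mask")
}

#' @export
print.voxel_mask <- function(x, ...) {
  cat(sprintf("<voxel_mask> %d voxels at threshold %.3g (patternwise reliability %.3f)\n",
              length(x$selected), x$threshold_used, x$patternwise_reliability))
  invisible(x)
}

#' Apply a voxel mask to a pattern matrix
#'
#' @param m A [pattern_matrix()].
#' @param mask A `voxel_mask` from [select_reliable_voxels()].
#' @return The pattern matrix restricted to the selected voxels.
#' @export
apply_voxel_mask <- function(m, mask) {
  stopifnot(inherits(m, "pattern_matrix"), inherits(mask, "voxel_mask"))
  miss <- setdiff(mask$selected, rownames(m))
  if (length(miss)) {
    stop(sprintf("mask voxels absent from pattern: %s",
                 paste(utils::head(miss, 5L), collapse = ", ")), call. = FALSE)
  }
  pattern_matrix(as.matrix(m)[mask$selected, , drop = FALSE],
                 condition_labels = colnames(m), voxel_ids = mask$selected,
                 participant_id = attr(m, "participant_id"))
}
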