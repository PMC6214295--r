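#' Partition nodes into equal-width angular bins
#'
#' Bins cover \eqn{[0, 2\pi)}, left-closed right-open, so every node falls in
#' exactly one bin.
#'
#' @param net An \code{embedded_network} with coordinates.
#' @param n_bins Number of bins.
#' @return List with \code{breaks} (length \code{n_bins + 1}) and
#'   \code{bins} (list of node-id vectors, one per bin).
#' @export
bin_angles <- function(net, n_bins = 15) {
  co <- net_coords(net)
  breaks <- seq(0, 2 * pi, length.out = n_bins + 1)
  idx <- pmin(floor(co$theta / (2 * pi) * n_bins) + 1L, n_bins)
  bins <- lapply(seq_len(n_bins), function(b) co$node[idx == b])
  list(breaks = breaks, bins = bins)
}

#' Per-bin protein-class enrichment and merged angular sectors
#'
#' For every bin and class, a one-sided Fisher exact test on the 2x2 table
#' (in-bin and annotated with the class, in-bin not annotated, out-of-bin
#' annotated, out-of-bin not annotated). A bin is assigned the class with the
#' smallest p-value among classes with \code{p < alpha} and odds ratio > 1
#' (with \code{gate = FALSE}, simply the smallest-p class). Maximal runs of
#' adjacent bins sharing an assigned class are merged into sectors, wrapping
#' around at \eqn{2\pi}.
#'
#' @param binning Output of \code{\link{bin_angles}}.
#' @param annotations Named list node id -> classes.
#' @param classes Class vocabulary tested per bin.
#' @param alpha Significance gate.
#' @param gate If FALSE, every non-empty bin receives its smallest-p class
#'   regardless of significance.
#' @param correct Multiple-testing correction across all bin-class tests
#'   ("none" or "BH"); applied to the significance gate.
#' @return List with \code{per_bin} (data.frame: bin, lo, hi, class, p_value,
#'   odds_ratio) and \code{sectors} (data.frame: lo, hi, class, n_bins).
#' @export
class_enrichment <- function(binning, annotations,
                             classes = c("TF", "Rec", "RBP", "Trans",
                                         "Skel", "Ubi"),
                             alpha = 0.05, gate = TRUE,
                             correct = c("none", "BH")) {
  correct <- match.arg(correct)
  bins <- binning$bins
  n_bins <- length(bins)
  all_nodes <- unlist(bins, use.names = FALSE)
  n_total <- length(all_nodes)
  in_class <- lapply(classes, function(cl) {
    ids <- names(annotations)[vapply(annotations, function(x) cl %in% x,
                                     logical(1))]
    intersect(ids, all_nodes)
  })
  names(in_class) <- classes
  pmat <- matrix(NA_real_, n_bins, length(classes),
                 dimnames = list(NULL, classes))
  ormat <- pmat
  for (b in seq_len(n_bins)) {
    nb <- length(bins[[b]])
    if (nb == 0) next
    for (cl in classes) {
      a11 <- sum(bins[[b]] %in% in_class[[cl]])
      a12 <- nb - a11
      a21 <- length(in_class[[cl]]) - a11
      a22 <- (n_total - nb) - a21
      ft <- stats::fisher.test(matrix(c(a11, a12, a21, a22), 2, byrow = TRUE),
                               alternative = "greater")
      pmat[b, cl] <- ft$p.value
      ormat[b, cl] <- unname(ft$estimate)
    }
  }
  padj <- pmat
  if (correct == "BH") {
    padj[] <- stats::p.adjust(as.vector(pmat), method = "BH")
  }
  assigned <- rep(NA_character_, n_bins)
  best_p <- rep(NA_real_, n_bins)
  best_or <- rep(NA_real_, n_bins)
  for (b in seq_len(n_bins)) {
    if (all(is.na(pmat[b, ]))) next
    ok <- if (gate) which(padj[b, ] < alpha & ormat[b, ] > 1)
          else seq_along(classes)
    if (length(ok) == 0) next
    pick <- ok[which.min(pmat[b, ok])]
    assigned[b] <- classes[pick]
    best_p[b] <- pmat[b, pick]
    best_or[b] <- ormat[b, pick]
  }
  per_bin <- data.frame(
    bin = seq_len(n_bins),
    lo = binning$breaks[-(n_bins + 1)], hi = binning$breaks[-1],
    class = assigned, p_value = best_p, odds_ratio = best_or,
    stringsAsFactors = FALSE
  )
  list(per_bin = per_bin, sectors = merge_sectors(per_bin, n_bins))
}

# Merge maximal runs of adjacent same-class bins into sectors; the angular
# dimension is circular, so a run may wrap across the 0/2pi boundary.
merge_sectors <- function(per_bin, n_bins) {
  cls <- per_bin$class
  assigned <- which(!is.na(cls))
  if (length(assigned) == 0) {
    return(data.frame(lo = numeric(0), hi = numeric(0),
                      class = character(0), n_bins = integer(0)))
  }
  run_id <- integer(n_bins)
  cur <- 0L
  for (b in seq_len(n_bins)) {
    if (is.na(cls[b])) next
    if (b > 1 && !is.na(cls[b - 1]) && cls[b - 1] == cls[b]) {
      run_id[b] <- run_id[b - 1]
    } else {
      cur <- cur + 1L
      run_id[b] <- cur
    }
  }
  # wrap-around: join the run ending at the last bin with the one starting
  # at bin 1 when their classes match (and they are distinct runs)
  if (!is.na(cls[1]) && !is.na(cls[n_bins]) && cls[1] == cls[n_bins] &&
      run_id[1] != run_id[n_bins]) {
    run_id[run_id == run_id[1]] <- run_id[n_bins]
  }
  runs <- split(seq_len(n_bins)[run_id > 0], run_id[run_id > 0])
  out <- lapply(runs, function(bb) {
    wrapped <- any(bb == 1) && any(bb == n_bins) && length(bb) < n_bins
    if (wrapped) {
      # interval crosses 2*pi: starts at the first bin after the gap and
      # ends (hi < lo) at the last bin before it
      gap <- setdiff(seq_len(n_bins), bb)
      lo <- per_bin$lo[min(bb[bb > max(gap)])]
      hi <- per_bin$hi[max(bb[bb < min(gap)])]
    } else {
      lo <- per_bin$lo[min(bb)]
      hi <- per_bin$hi[max(bb)]
    }
    data.frame(lo = lo, hi = hi, class = per_bin$class[bb[1]],
               n_bins = length(bb), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out[order(out$lo), , drop = FALSE]
}
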