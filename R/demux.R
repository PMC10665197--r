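#' Cell-level quality-control filter
#'
#' Applies the three standard filters in order: (1) remove cells below a
#' lower UMI threshold; (2) among the survivors, remove cells whose UMI total
#' exceeds the mean by more than `sd_mult` standard deviations (a doublet
#' guard; with zero variance nothing is removed since the inequality is
#' strict); (3) remove cells with a mitochondrial fraction above `mito_max`.
#'
#' @param exp a [hashed_experiment()].
#' @param min_umi lower UMI threshold (experiments typically use 100-250;
#'   default 250).
#' @param mito_max maximal tolerated mitochondrial fraction (default 0.25).
#' @param sd_mult upper-outlier multiplier on the UMI standard deviation
#'   (default 4).
#' @return list with `keep` (logical mask over cells), `reason` (character:
#'   `ok`, `low_umi`, `umi_outlier`, `high_mito`) and a one-row `summary`
#'   data.frame of removal counts.
#' @export
qc_filter <- function(exp, min_umi = 250, mito_max = 0.25, sd_mult = 4) {
  stopifnot(inherits(exp, "hashed_experiment"))
  if (nrow(exp$gene_counts) == 0) stop("experiment has no cells")
  stopifnot(min_umi >= 0, mito_max > 0, mito_max <= 1, sd_mult > 0)
  n <- length(exp$umi)
  reason <- rep("ok", n)
  reason[exp$umi < min_umi] <- "low_umi"
  pass_lower <- reason == "ok"
  if (any(pass_lower)) {
    m <- mean(exp$umi[pass_lower])
    s <- sd(exp$umi[pass_lower])
    if (is.na(s)) s <- 0
    hi <- pass_lower & exp$umi > m + sd_mult * s
    reason[hi] <- "umi_outlier"
  }
  hi_mito <- reason == "ok" & exp$mito_fraction > mito_max
  reason[hi_mito] <- "high_mito"
  keep <- reason == "ok"
  summary <- data.frame(
    n_cells = n,
    low_umi = sum(reason == "low_umi"),
    umi_outlier = sum(reason == "umi_outlier"),
    high_mito = sum(reason == "high_mito"),
    kept = sum(keep)
  )
  list(keep = keep, reason = reason, summary = summary)
}

#' Assign cells to embryos by hash-oligo enrichment
#'
#' A cell is assigned to the embryo of its most abundant hash oligo when that
#' top count reaches `min_top` and the enrichment ratio
#' top / max(second, 1) reaches `min_ratio`. Ties for the top oligo are never
#' assigned (their ratio is 1). Cells failing QC are carried through with
#' their QC reason and never assigned.
#'
#' @param exp a [hashed_experiment()].
#' @param min_ratio minimal enrichment ratio (default 2.5).
#' @param min_top minimal top-oligo count (default 10).
#' @param qc optional result of [qc_filter()]; if supplied, only QC-passing
#'   cells are eligible for assignment.
#' @return a `demux_result`: data.frame with one row per cell -- `cell`,
#'   `top_oligo`, `top`, `second`, `ratio`, `embryo` (NA when unassigned) and
#'   `reason` (`ok`, `low_signal`, `low_ratio`, or the QC reason).
#' @export
assign_embryos <- function(exp, min_ratio = 2.5, min_top = 10, qc = NULL) {
  stopifnot(inherits(exp, "hashed_experiment"))
  stopifnot(min_ratio > 0, min_top > 0)
  h <- as.matrix(exp$hash_counts)
  unmapped <- setdiff(colnames(h), names(exp$oligo_to_embryo))
  if (length(unmapped)) {
    stop("hash oligo(s) without an embryo mapping: ",
         paste(unmapped, collapse = ", "))
  }
  n <- nrow(h)
  ord_top <- max.col(h, ties.method = "first")
  top <- h[cbind(seq_len(n), ord_top)]
  h2 <- h
  h2[cbind(seq_len(n), ord_top)] <- -Inf
  second <- apply(h2, 1, max)
  second[!is.finite(second)] <- 0   # single-oligo experiments
  tied <- rowSums(h == top) > 1L    # exact tie for the top oligo
  ratio <- top / pmax(second, 1)

  reason <- rep("ok", n)
  if (!is.null(qc)) reason[!qc$keep] <- qc$reason[!qc$keep]
  eligible <- reason == "ok"
  reason[eligible & top < min_top] <- "low_signal"
  eligible <- reason == "ok"
  reason[eligible & (tied | ratio < min_ratio)] <- "low_ratio"

  assigned <- reason == "ok"
  embryo <- rep(NA_character_, n)
  embryo[assigned] <- unname(exp$oligo_to_embryo[colnames(h)[ord_top[assigned]]])
  out <- data.frame(
    cell = rownames(h),
    top_oligo = colnames(h)[ord_top],
    top = top,
    second = second,
    ratio = ratio,
    embryo = embryo,
    reason = reason,
    stringsAsFactors = FALSE
  )
  class(out) <- c("demux_result", class(out))
  out
}

#' Summarize a demultiplexing result
#'
#' @param result a `demux_result` from [assign_embryos()].
#' @return list with `rate` (overall assignment rate), `by_reason` (counts per
#'   reason code) and `by_embryo` (assigned cells per embryo).
#' @export
demux_report <- function(result) {
  if (nrow(result) == 0) stop("empty demultiplexing result")
  assigned <- !is.na(result$embryo)
  list(
    rate = mean(assigned),
    by_reason = table(result$reason),
    by_embryo = table(result$embryo[assigned])
  )
}
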