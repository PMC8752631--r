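#' Empirical top-quantile threshold
#'
#' Threshold for selecting the top `(1-q)` fraction of a score distribution:
#' the empirical quantile with linear interpolation (R type 7), applied to
#' finite values only; selection downstream is inclusive (`value >=
#' threshold`), so ties at the threshold are all selected.
#'
#' @param values Numeric scores (NA/undefined entries are excluded first).
#' @param q Quantile (default 0.95, i.e. top 5%).
#' @param min_values Minimum number of finite values required.
#' @return The scalar threshold.
#' @export
percentile_threshold <- function(values, q = 0.95, min_values = 20) {
  v <- values[is.finite(values)]
  if (length(v) == 0) stop("all values are undefined", call. = FALSE)
  if (length(v) < min_values) {
    stop("need at least ", min_values, " finite values for a percentile ",
         "threshold (got ", length(v), ")", call. = FALSE)
  }
  unname(stats::quantile(v, q, type = 7))
}

#' Composite sweep calling on a window table
#'
#' The composite procedure for the final sweep set: a window is selected iff
#' its XP-CLR score is in the genome-wide top `(1-q_xpclr)` fraction AND its
#' FST is in the top `(1-q_fst)` fraction AND Tajima's D is strictly
#' negative in the cultivar population AND strictly positive in the wild
#' population. Windows with undefined statistics are excluded from ranking
#' and can never be selected. The intermediate sets (XP-CLR top windows and
#' the XP-CLR-and-FST overlap before the Tajima's D narrowing) are kept for
#' diagnostics.
#'
#' @param tbl Window table carrying columns `xpclr`, `fst`,
#'   `tajd_<cultivar>` and `tajd_<wild>` (a [window_stats()] table joined
#'   with an [xpclr_scan()]).
#' @param wild,cultivar Population labels used in the Tajima's D columns.
#' @param q_xpclr,q_fst Top-percentile quantiles (default 0.95 = top 5%).
#' @return An object of class `sweep_calls`: list with `selected`,
#'   `xpclr_selected`, `overlap` (window tibbles), `thresholds`, and counts.
#' @export
call_sweeps <- function(tbl, wild = "wild", cultivar = "cultivar",
                        q_xpclr = 0.95, q_fst = 0.95) {
  tajd_w <- paste0("tajd_", wild)
  tajd_c <- paste0("tajd_", cultivar)
  for (col in c("xpclr", "fst", tajd_w, tajd_c)) {
    if (!col %in% names(tbl)) {
      stop("window table is missing column `", col, "`", call. = FALSE)
    }
  }
  ok <- if ("defined" %in% names(tbl)) tbl$defined else
    rep(TRUE, nrow(tbl))
  thr_xpclr <- percentile_threshold(tbl$xpclr[ok], q_xpclr)
  thr_fst <- percentile_threshold(tbl$fst[ok], q_fst)

  pass_xpclr <- ok & is.finite(tbl$xpclr) & tbl$xpclr >= thr_xpclr
  pass_fst <- ok & is.finite(tbl$fst) & tbl$fst >= thr_fst
  pass_d <- ok & is.finite(tbl[[tajd_c]]) & is.finite(tbl[[tajd_w]]) &
    tbl[[tajd_c]] < 0 & tbl[[tajd_w]] > 0
  sel <- pass_xpclr & pass_fst & pass_d

  structure(
    list(selected = tbl[sel, , drop = FALSE],
         xpclr_selected = tbl[pass_xpclr, , drop = FALSE],
         overlap = tbl[pass_xpclr & pass_fst, , drop = FALSE],
         thresholds = c(xpclr = thr_xpclr, fst = thr_fst),
         wild = wild, cultivar = cultivar,
         n_windows = nrow(tbl), n_defined = sum(ok),
         n_selected = sum(sel)),
    class = "sweep_calls"
  )
}

#' @export
print.sweep_calls <- function(x, ...) {
  cat("<sweep_calls> ", x$n_selected, " of ", x$n_defined,
      " defined windows selected (thresholds: XP-CLR >= ",
      signif(x$thresholds["xpclr"], 4), ", FST >= ",
      signif(x$thresholds["fst"], 4), "; D < 0 in ", x$cultivar,
      ", D > 0 in ", x$wild, ")\n", sep = "")
  invisible(x)
}

#' Selected windows of a sweep call
#' @param x A [call_sweeps()] result.
#' @param ... Unused.
#' @return The selected-window tibble.
#' @method tidy sweep_calls
#' @export
tidy.sweep_calls <- function(x, ...) tibble::as_tibble(x$selected)

#' One-row summary of a sweep call
#' @param x A [call_sweeps()] result.
#' @param ... Unused.
#' @return One-row tibble with window counts per stage and the thresholds.
#' @method glance sweep_calls
#' @export
glance.sweep_calls <- function(x, ...) {
  tibble::tibble(
    n_windows = x$n_windows, n_defined = x$n_defined,
    n_xpclr_top = nrow(x$xpclr_selected), n_overlap = nrow(x$overlap),
    n_selected = x$n_selected,
    thr_xpclr = unname(x$thresholds["xpclr"]),
    thr_fst = unname(x$thresholds["fst"])
  )
}

#' Merge selected windows into sweep blocks
#'
#' Overlapping or book-ended selected windows on the same chromosome are
#' merged into maximal blocks. Evidence columns are aggregated: `xpclr` and
#' `fst` by their maximum, Tajima's D columns by their mean, plus the member
#' window count.
#'
#' @param windows Selected-window tibble (or a [call_sweeps()] result, whose
#'   `selected` set is used).
#' @return A block tibble: `chrom`, `start`, `end`, `n_windows`, `max_xpclr`,
#'   `max_fst`, and `mean_tajd_*` per D column present.
#' @export
merge_blocks <- function(windows) {
  if (inherits(windows, "sweep_calls")) windows <- windows$selected
  tajd_cols <- grep("^tajd_", names(windows), value = TRUE)
  empty <- tibble::tibble(chrom = character(), start = numeric(),
                          end = numeric(), n_windows = integer(),
                          max_xpclr = numeric(), max_fst = numeric())
  for (tc in tajd_cols) empty[[paste0("mean_", tc)]] <- numeric()
  if (nrow(windows) == 0) return(empty)
  windows <- dplyr::arrange(windows, .data$chrom, .data$start)

  out <- list()
  cur <- NULL
  flush <- function(cur) {
    row <- tibble::tibble(chrom = cur$chrom, start = cur$start,
                          end = cur$end, n_windows = length(cur$rows))
    mem <- windows[cur$rows, , drop = FALSE]
    row$max_xpclr <- if ("xpclr" %in% names(mem))
      max(mem$xpclr, na.rm = TRUE) else NA_real_
    row$max_fst <- if ("fst" %in% names(mem))
      max(mem$fst, na.rm = TRUE) else NA_real_
    for (tc in tajd_cols) {
      row[[paste0("mean_", tc)]] <- mean(mem[[tc]], na.rm = TRUE)
    }
    row
  }
  for (i in seq_len(nrow(windows))) {
    w <- windows[i, ]
    if (is.null(cur)) {
      cur <- list(chrom = w$chrom, start = w$start, end = w$end, rows = i)
    } else if (w$chrom == cur$chrom && w$start <= cur$end) {
      cur$end <- max(cur$end, w$end)
      cur$rows <- c(cur$rows, i)
    } else {
      out[[length(out) + 1]] <- flush(cur)
      cur <- list(chrom = w$chrom, start = w$start, end = w$end, rows = i)
    }
  }
  out[[length(out) + 1]] <- flush(cur)
  dplyr::bind_rows(out)
}

#' Assign genes to sweep blocks
#'
#' A gene is assigned to a block iff their (0-based half-open) intervals
#' overlap by at least 1 bp; a gene ending exactly at a block start does not
#' overlap. Also reports the selected-gene summary: counts and the
#' percentage of annotated genes under selection.
#'
#' @param blocks Block tibble from [merge_blocks()].
#' @param genes Gene tibble (as from [read_gff()] / [emit_annotation()]).
#' @return A list: `blocks` (with `gene_ids` list-column and `n_genes`),
#'   `genes` (flat tibble of assigned genes with their block), and `summary`
#'   (one-row tibble: `n_selected_genes`, `n_total_genes`, `pct_selected`).
#' @export
annotate_blocks <- function(blocks, genes) {
  gene_ids <- vector("list", nrow(blocks))
  flat <- list()
  for (i in seq_len(nrow(blocks))) {
    hit <- genes$chrom == blocks$chrom[i] &
      genes$start < blocks$end[i] & blocks$start[i] < genes$end
    gene_ids[[i]] <- genes$gene_id[hit]
    if (any(hit)) {
      flat[[length(flat) + 1]] <- dplyr::mutate(
        genes[hit, , drop = FALSE],
        block_chrom = blocks$chrom[i], block_start = blocks$start[i],
        block_end = blocks$end[i])
    }
  }
  blocks$gene_ids <- gene_ids
  blocks$n_genes <- lengths(gene_ids)
  flat <- if (length(flat) > 0) {
    dplyr::distinct(dplyr::bind_rows(flat))
  } else {
    tibble::tibble(chrom = character(), start = numeric(), end = numeric(),
                   strand = character(), gene_id = character(),
                   single_copy = logical(), block_chrom = character(),
                   block_start = numeric(), block_end = numeric())
  }
  n_sel <- length(unique(flat$gene_id))
  list(blocks = blocks, genes = flat,
       summary = tibble::tibble(
         n_selected_genes = n_sel,
         n_total_genes = nrow(genes),
         pct_selected = gene_percentage(n_sel, nrow(genes))))
}

#' Percentage of genes under selection
#'
#' `round(100 * n_selected / n_total, 2)` — the headline "x% of genes
#' available for selection" number of a sweep report.
#'
#' @param n_selected,n_total Gene counts.
#' @return Percentage rounded to 2 decimals (0 when `n_total` is 0).
#' @export
gene_percentage <- function(n_selected, n_total) {
  if (n_total == 0) return(0)
  round(100 * n_selected / n_total, 2)
}
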